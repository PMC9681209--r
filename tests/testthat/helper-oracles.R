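# Independent oracles used to cross-check the package implementations.
# Each is a direct, unoptimised transcription of the defining formula and
# shares no code with the functions it checks.

# Running-sum ssGSEA score for one sample, by explicit enumeration.
ssgsea_oracle <- function(expr_vec, set_genes, alpha = 0.25) {
  genes <- names(expr_vec)
  n <- length(genes)
  ord <- order(expr_vec, decreasing = TRUE)
  sorted_genes <- genes[ord]
  inset <- sorted_genes %in% set_genes
  m <- sum(inset)
  w_total <- 0
  for (i in seq_len(n)) if (inset[i]) w_total <- w_total + (n - i + 1)^alpha
  score <- 0
  cum_in <- 0
  cum_out <- 0
  for (i in seq_len(n)) {
    if (inset[i]) cum_in <- cum_in + (n - i + 1)^alpha else cum_out <- cum_out + 1
    p_in <- cum_in / w_total
    p_out <- if (m == n) 0 else cum_out / (n - m)
    score <- score + (p_in - p_out)
  }
  score
}

# Gaussian kernel-weighted mean at one probe, written out longhand.
kernel_smooth_oracle <- function(positions, delta, at, lambda, C) {
  sigma <- lambda / C
  num <- 0
  den <- 0
  for (j in seq_along(positions)) {
    d <- positions[j] - positions[at]
    if (abs(d) <= lambda) {
      k <- exp(-(d / sigma)^2 / 2)
      num <- num + k * delta[j]
      den <- den + k
    }
  }
  num / den
}

# Upper hypergeometric tail via the factorial formula (exact for small N).
hyper_tail_oracle <- function(k, n1, n2, N) {
  ch <- function(n, r) factorial(n) / (factorial(r) * factorial(n - r))
  total <- 0
  for (i in k:min(n1, n2)) {
    total <- total + ch(n1, i) * ch(N - n1, n2 - i) / ch(N, n2)
  }
  total
}

# Spearman permutation p by filtering the full n^n grid down to
# permutations (independent of the package's recursive generator).
spearman_perm_oracle <- function(x, y, alternative = "two.sided") {
  n <- length(x)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  is_perm <- apply(grid, 1L, function(r) length(unique(r)) == n)
  perms <- grid[is_perm, , drop = FALSE]
  rx <- rank(x)
  ry <- rank(y)
  obs <- cor(rx, ry)
  rho_all <- apply(perms, 1L, function(p) cor(rx, ry[p]))
  tol <- 1e-12
  switch(alternative,
    two.sided = mean(abs(rho_all) >= abs(obs) - tol),
    greater = mean(rho_all >= obs - tol),
    less = mean(rho_all <= obs + tol)
  )
}

# Small manifest/beta fixture: n probes on one chromosome at the given
# positions, with constant beta per group.
make_flat_pair <- function(positions, beta_t, beta_c, chrom = "chr1") {
  ids <- sprintf("p%03d", seq_along(positions))
  man <- probe_manifest(ids, chrom, positions)
  tum <- matrix(beta_t, length(ids), 2, dimnames = list(ids, c("t1", "t2")))
  ctl <- matrix(beta_c, length(ids), 2, dimnames = list(ids, c("c1", "c2")))
  list(manifest = man, tumour = tum, control = ctl)
}

# Disk mask helper for morphology tests (independent of gen_tumour_mask).
disk_mask <- function(image_size, pixel_size, radius_um,
                      cx = (image_size + 1) / 2, cy = (image_size + 1) / 2) {
  r_px <- radius_um / pixel_size
  m <- outer(seq_len(image_size), seq_len(image_size),
             function(i, j) ((i - cx)^2 + (j - cy)^2 <= r_px^2) * 1)
  calibrated_mask(m, pixel_size, role = "staining")
}

full_tissue <- function(image_size, pixel_size) {
  calibrated_mask(matrix(1, image_size, image_size), pixel_size,
                  role = "tissue")
}
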