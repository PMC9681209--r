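# Synthetic two-group methylome cohorts with planted direction-biased DMRs.
#
# The generator emulates the geometry a kernel-smoothed region caller
# relies on: planted regions are tight clusters of probes spaced well
# inside the grouping bandwidth, background probes are spaced beyond it so
# they can neither bridge regions nor be smoothed into them. Baseline
# betas are drawn from a bimodal array-like distribution; hypo regions are
# planted on methylated baseline (high beta) and hyper regions on
# unmethylated baseline, so the planted shift survives clamping to (0, 1).

#' Generate a synthetic methylation cohort with planted DMRs
#'
#' @param n_probes Total number of probes in the manifest.
#' @param n_pairs Number of tumour/control sample pairs sharing the same
#'   planted truth (independent noise per pair).
#' @param n_regions Number of planted regions.
#' @param hypo_fraction Fraction of planted regions shifted downwards
#'   (hypo); the planted hypo count is `round(hypo_fraction * n_regions)`.
#' @param delta_beta_magnitude Absolute beta shift planted in the tumour
#'   samples of each region (default 0.4).
#' @param noise_sd Per-sample Gaussian noise sd on the beta scale
#'   (default 0.05).
#' @param n_reps Replicates per group in each pair (default 2).
#' @param region_probes Probes per planted region (default 8).
#' @param region_spacing Probe spacing inside regions in bp (default 150,
#'   well inside the 1000 bp grouping bandwidth).
#' @param background_spacing Spacing of background probes in bp (default
#'   1500, beyond the bandwidth).
#' @param seed Integer seed; all output is a pure function of the
#'   arguments including the seed.
#' @return A list: `manifest` ([probe_manifest()]), `pairs` (list of
#'   `list(tumour=, control=)` beta matrices), and `truth` with
#'   `regions` (`chrom`, `start`, `end`, `n_probes`, `delta_beta`),
#'   `planted_hypo_fraction` (the realised fraction) and `seed`.
#' @export
gen_methyl_cohort <- function(n_probes, n_pairs, n_regions,
                              hypo_fraction,
                              delta_beta_magnitude = 0.4,
                              noise_sd = 0.05,
                              n_reps = 2L,
                              region_probes = 8L,
                              region_spacing = 150L,
                              background_spacing = 1500L,
                              seed = 1L) {
  if (hypo_fraction < 0 || hypo_fraction > 1) {
    stop("hypo_fraction must lie in [0, 1]")
  }
  if (region_probes < 2L) stop("region_probes must be >= 2")
  n_region_probes <- n_regions * region_probes
  if (n_region_probes > n_probes) {
    stop("cannot pack ", n_regions, " regions of ", region_probes,
         " probes into ", n_probes, " probes; increase n_probes")
  }

  withr::with_seed(seed, {
    # ---- manifest layout: background runs separating planted clusters ----
    n_bg <- n_probes - n_region_probes
    bg_per_gap <- diff(round(seq(0, n_bg, length.out = n_regions + 2L)))
    pos <- integer(0)
    region_idx <- vector("list", n_regions)
    cursor <- 1000L
    guard <- 1200L   # clearance between a region and flanking background
    for (r in seq_len(n_regions + 1L)) {
      nb <- bg_per_gap[r]
      if (nb > 0L) {
        pos <- c(pos, cursor + background_spacing * seq_len(nb))
        cursor <- pos[length(pos)]
      }
      if (r <= n_regions) {
        start <- cursor + guard
        rp <- start + region_spacing * (seq_len(region_probes) - 1L)
        region_idx[[r]] <- length(pos) + seq_len(region_probes)
        pos <- c(pos, rp)
        cursor <- rp[length(rp)] + guard
      }
    }
    manifest <- probe_manifest(
      probe_id = sprintf("cg%07d", seq_along(pos)),
      chrom = "chr1", pos = pos
    )

    # ---- planted directions ----
    n_hypo <- round(hypo_fraction * n_regions)
    dirs <- rep(1, n_regions)
    if (n_hypo > 0L) dirs[sample.int(n_regions, n_hypo)] <- -1
    delta_region <- dirs * delta_beta_magnitude

    # per-probe planted shift
    shift <- numeric(n_probes)
    for (r in seq_len(n_regions)) {
      shift[region_idx[[r]]] <- delta_region[r]
    }

    # ---- baseline betas: bimodal, direction-compatible inside regions ----
    base <- ifelse(rbinom(n_probes, 1L, 0.5) == 1L,
                   rbeta(n_probes, 10, 2), rbeta(n_probes, 2, 10))
    for (r in seq_len(n_regions)) {
      idx <- region_idx[[r]]
      base[idx] <- if (dirs[r] < 0) rbeta(length(idx), 10, 2)
                   else rbeta(length(idx), 2, 10)
    }

    clamp <- function(x) pmin(pmax(x, 1e-3), 1 - 1e-3)
    pairs <- lapply(seq_len(n_pairs), function(p) {
      noise <- function() {
        if (noise_sd == 0) 0 else rnorm(n_probes * n_reps, sd = noise_sd)
      }
      ctl <- clamp(matrix(base, n_probes, n_reps) + noise())
      tum <- clamp(matrix(base + shift, n_probes, n_reps) + noise())
      dimnames(ctl) <- list(manifest$probe_id,
                            sprintf("pair%02d_ctrl_%d", p, seq_len(n_reps)))
      dimnames(tum) <- list(manifest$probe_id,
                            sprintf("pair%02d_tum_%d", p, seq_len(n_reps)))
      list(tumour = tum, control = ctl)
    })

    regions <- data.frame(
      chrom = "chr1",
      start = vapply(region_idx, function(i) pos[i[1L]], integer(1)),
      end = vapply(region_idx, function(i) pos[i[length(i)]] + 1L, integer(1)),
      n_probes = region_probes,
      delta_beta = delta_region,
      stringsAsFactors = FALSE
    )
    list(
      manifest = manifest,
      pairs = pairs,
      truth = list(
        regions = regions,
        planted_hypo_fraction = if (n_regions > 0) n_hypo / n_regions
                                else NA_real_,
        seed = seed
      )
    )
  })
}

#' Planted-region recovery of a DMR call
#'
#' Matches called DMRs against planted truth regions by >= 1 bp interval
#' overlap with agreeing direction, and summarises precision and recall.
#'
#' @param dmrs A DMR table from [call_dmrs()].
#' @param truth_regions The `truth$regions` table from
#'   [gen_methyl_cohort()].
#' @return A list: `precision`, `recall`, `n_called`, `n_truth`,
#'   `estimated_hypo_fraction`.
#' @export
dmr_recovery <- function(dmrs, truth_regions) {
  n_truth <- nrow(truth_regions)
  n_called <- nrow(dmrs)
  if (n_called == 0L) {
    return(list(precision = NA_real_, recall = 0, n_called = 0L,
                n_truth = n_truth, estimated_hypo_fraction = NA_real_))
  }
  t_dir <- ifelse(truth_regions$delta_beta < 0, "hypo", "hyper")
  gr_t <- GenomicRanges::GRanges(
    truth_regions$chrom,
    IRanges::IRanges(truth_regions$start + 1L, truth_regions$end)
  )
  gr_c <- dmrs_to_granges(dmrs)
  hits <- GenomicRanges::findOverlaps(gr_c, gr_t)
  same_dir <- dmrs$direction[S4Vectors::queryHits(hits)] ==
    t_dir[S4Vectors::subjectHits(hits)]
  matched_called <- unique(S4Vectors::queryHits(hits)[same_dir])
  matched_truth <- unique(S4Vectors::subjectHits(hits)[same_dir])
  list(
    precision = length(matched_called) / n_called,
    recall = length(matched_truth) / n_truth,
    n_called = n_called,
    n_truth = n_truth,
    estimated_hypo_fraction = hypo_fraction(dmrs)
  )
}
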