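# Synthetic bulk expression (TPM) with planted signature up-regulation,
# and random disjoint gene signatures over a synthetic universe.

#' Generate disjoint random gene signatures
#'
#' Utility for building test signatures over a synthetic gene universe.
#'
#' @param universe Character vector of gene ids.
#' @param sizes Named integer vector; one signature per element.
#' @param seed Integer seed.
#' @return Named list of `gene_signature` objects with pairwise-disjoint
#'   gene sets.
#' @export
gen_signatures <- function(universe, sizes, seed = 1L) {
  if (sum(sizes) > length(universe)) {
    stop("signature sizes exceed the universe")
  }
  if (is.null(names(sizes))) stop("'sizes' must be named")
  withr::with_seed(seed, {
    picked <- sample(universe, sum(sizes))
    ends <- cumsum(sizes)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    out <- lapply(seq_along(sizes), function(i) {
      gene_signature(names(sizes)[i], picked[starts[i]:ends[i]])
    })
    names(out) <- names(sizes)
    out
  })
}

#' Generate a TPM expression matrix with planted signature up-regulation
#'
#' Baseline expression is log-normal per gene; in the enriched samples the
#' signature genes are multiplied by `2^planted_log2fc` before TPM
#' normalisation (each column sums to 1e6).
#'
#' @param n_genes Number of genes in the universe (ids `gene0001`, ...).
#' @param n_samples Total number of samples.
#' @param n_enriched Number of samples with the planted up-regulation
#'   (the first `n_enriched` sample columns; recorded in the truth table).
#' @param signature A `gene_signature` or character vector; must be a
#'   subset of the gene universe and non-empty.
#' @param planted_log2fc Planted log2 fold change (default 2).
#' @param noise_sd Log-normal sd of per-sample multiplicative noise
#'   (default 0.3).
#' @param seed Integer seed.
#' @return A list: `tpm` (genes x samples matrix, columns sum to 1e6),
#'   `truth` (`data.frame` with `sample_id`, `enriched`), `signature`,
#'   `seed`.
#' @export
gen_expression <- function(n_genes, n_samples, n_enriched, signature,
                           planted_log2fc = 2, noise_sd = 0.3, seed = 1L) {
  genes <- sprintf("gene%04d", seq_len(n_genes))
  sg <- sig_genes(signature)
  if (length(sg) == 0L) stop("signature must be non-empty")
  if (!all(sg %in% genes)) {
    stop("signature genes must be a subset of the gene universe")
  }
  if (n_enriched > n_samples) stop("n_enriched cannot exceed n_samples")
  withr::with_seed(seed, {
    mu <- exp(rnorm(n_genes, mean = 3, sd = 1.5))
    enriched <- c(rep(TRUE, n_enriched), rep(FALSE, n_samples - n_enriched))
    expr <- vapply(seq_len(n_samples), function(s) {
      e <- mu * exp(rnorm(n_genes, sd = noise_sd))
      if (enriched[s]) {
        idx <- match(sg, genes)
        e[idx] <- e[idx] * 2^planted_log2fc
      }
      e / sum(e) * 1e6
    }, numeric(n_genes))
    dimnames(expr) <- list(genes, sprintf("sample%02d", seq_len(n_samples)))
    list(
      tpm = expr,
      truth = data.frame(sample_id = colnames(expr), enriched = enriched,
                         stringsAsFactors = FALSE),
      signature = sg,
      seed = seed
    )
  })
}
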