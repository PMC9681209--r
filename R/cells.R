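# Single-cell signature scoring, arg-max assignment, and pseudo-bulk
# aggregation.

#' Log-normalise a UMI count matrix
#'
#' Standard library-size normalisation for single cells:
#' `log1p(count / library_size * scale)`.
#'
#' @param counts Genes x cells count matrix (dense or `Matrix` sparse).
#' @param scale Scale factor (default 1e4).
#' @return Dense genes x cells matrix of log-normalised expression.
#' @export
lognorm_cells <- function(counts, scale = 1e4) {
  lib <- Matrix::colSums(counts)
  if (any(lib == 0)) stop("cells with zero total counts cannot be normalised")
  m <- as.matrix(counts)
  log1p(sweep(m, 2L, lib, "/") * scale)
}

#' Additive module score per cell
#'
#' For each cell, the mean log-normalised expression of the signature genes
#' minus the mean expression of a control gene set. Controls are drawn from
#' expression-matched bins: all genes are binned into `n_bins`
#' equal-frequency bins by their cohort-average expression, and for every
#' signature gene `n_ctrl` control genes are sampled (seeded, without
#' replacement where the bin allows) from the same bin; the control set is
#' the union of these draws. Signature genes are excluded from the control
#' pool, making the score exactly linear in uniform shifts of the
#' signature genes.
#'
#' @param expr Genes x cells log-normalised matrix with gene-id row names.
#' @param signature A `gene_signature` or character vector. Genes absent
#'   from `expr` are dropped with a warning; an error if none remain.
#' @param n_bins Number of average-expression bins (default 24).
#' @param n_ctrl Control genes sampled per signature gene (default 100).
#' @param seed Integer seed for the control draw; the global RNG state is
#'   left untouched.
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(expr, signature, n_bins = 24L, n_ctrl = 100L,
                         seed = 1L) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) {
    stop("expression matrix needs gene ids as row names")
  }
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (n_ctrl < 1L) stop("n_ctrl must be >= 1")
  genes <- sig_genes(signature)
  present <- intersect(genes, rownames(expr))
  if (length(present) == 0L) {
    stop("no signature genes present in the expression matrix")
  }
  if (length(present) < length(genes)) {
    warning(length(genes) - length(present),
            " signature gene(s) absent from the expression matrix; dropped")
  }
  avg <- rowMeans(expr)
  n <- length(avg)
  bins <- ceiling(rank(avg, ties.method = "first") * n_bins / n)
  pool <- setdiff(rownames(expr), present)
  ctrl <- withr::with_seed(seed, {
    unique(unlist(lapply(present, function(g) {
      cand <- pool[bins[pool] == bins[[g]]]
      if (length(cand) == 0L) return(character(0))
      sample(cand, size = min(n_ctrl, length(cand)))
    })))
  })
  if (length(ctrl) == 0L) {
    stop("no control genes could be sampled; too few genes outside the signature")
  }
  colMeans(expr[present, , drop = FALSE]) -
    colMeans(expr[ctrl, , drop = FALSE])
}

#' Score cells for several signatures
#'
#' Convenience wrapper running [module_score()] per signature.
#'
#' @inheritParams module_score
#' @param signatures Named list of signatures.
#' @return Cells x signatures matrix of module scores.
#' @export
module_score_table <- function(expr, signatures, n_bins = 24L,
                               n_ctrl = 100L, seed = 1L) {
  nm <- vapply(seq_along(signatures), function(i) {
    s <- signatures[[i]]
    n <- names(signatures)[i]
    if (!is.null(n) && nzchar(n)) n
    else if (inherits(s, "gene_signature")) s$name else paste0("set", i)
  }, character(1))
  out <- vapply(seq_along(signatures), function(i) {
    module_score(expr, signatures[[i]], n_bins, n_ctrl, seed = seed + i - 1L)
  }, numeric(ncol(expr)))
  dimnames(out) <- list(colnames(expr), nm)
  out
}

#' Assign each cell the signature with the highest score
#'
#' Arg-max over the score columns; exact ties are broken by a fixed
#' priority order and flagged.
#'
#' @param scores Cells x signatures numeric matrix.
#' @param priority Character vector of signature names giving the
#'   tie-break order (default: column order of `scores`).
#' @return A `data.frame` with `cell`, `label` and logical `tie`.
#' @export
assign_cells <- function(scores, priority = colnames(scores)) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) {
    stop("score matrix needs signature names as column names")
  }
  if (!setequal(priority, colnames(scores))) {
    stop("'priority' must be a permutation of the score columns")
  }
  s <- scores[, priority, drop = FALSE]
  top <- max.col(s, ties.method = "first")
  rowmax <- s[cbind(seq_len(nrow(s)), top)]
  tie <- rowSums(s == rowmax) > 1L
  data.frame(
    cell = rownames(scores) %||% as.character(seq_len(nrow(scores))),
    label = priority[top],
    tie = tie,
    stringsAsFactors = FALSE
  )
}

#' Pseudo-bulk aggregation of single-cell counts
#'
#' Sums raw UMI counts per gene over each patient's (filtered) cells, then
#' normalises to counts per million and applies `log2(CPM + 1)`.
#'
#' @param counts Genes x cells count matrix (dense or sparse).
#' @param cell_patient Character/factor vector, one patient id per cell.
#' @param cells_keep Optional logical or index vector selecting the cells
#'   to aggregate (e.g. a cancer-cell mask).
#' @return Genes x patients matrix of `log2(CPM + 1)` values.
#' @export
pseudo_bulk <- function(counts, cell_patient, cells_keep = NULL) {
  if (length(cell_patient) != ncol(counts)) {
    stop("'cell_patient' must have one entry per cell")
  }
  if (!is.null(cells_keep)) {
    counts <- counts[, cells_keep, drop = FALSE]
    cell_patient <- cell_patient[cells_keep]
  }
  if (ncol(counts) == 0L) stop("no cells left after filtering")
  patients <- sort(unique(as.character(cell_patient)))
  summed <- vapply(patients, function(p) {
    Matrix::rowSums(counts[, cell_patient == p, drop = FALSE])
  }, numeric(nrow(counts)))
  lib <- colSums(summed)
  if (any(lib == 0)) stop("patient with zero total counts")
  cpm <- sweep(summed, 2L, lib, "/") * 1e6
  out <- log2(cpm + 1)
  dimnames(out) <- list(rownames(counts), patients)
  out
}

#' ACS to mean-OPC score ratio
#'
#' The composite astrocyte score divided by the mean of the two OPC
#' signature scores, the per-patient summary used against cell-type
#' composition.
#'
#' @param acs Numeric vector of ACS enrichment scores.
#' @param opc1,opc2 Numeric vectors of the two OPC signature scores.
#' @return Numeric vector `acs / ((opc1 + opc2) / 2)`; `NA_real_` where the
#'   OPC mean is zero.
#' @export
acs_opc_ratio <- function(acs, opc1, opc2) {
  denom <- (opc1 + opc2) / 2
  ifelse(denom == 0, NA_real_, acs / denom)
}
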