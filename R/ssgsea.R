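# Single-sample GSEA scoring, composite signature construction, and the
# enrichment classifier.
#
# ssGSEA follows the running-sum (area) formulation: per sample, genes are
# ranked by expression; walking down the ranked list, in-set genes add
# rank-weighted increments (weight |r|^alpha) and out-of-set genes subtract
# uniform increments; the score is the sum of the running difference over
# all positions. Scores are a pure rank statistic, invariant under any
# strictly increasing transformation of a sample's expression values.

#' Construct a gene signature
#'
#' @param name Signature name.
#' @param genes Character vector of gene identifiers; duplicates are
#'   removed, empty sets are an error.
#' @return A list with class `gene_signature` (`name`, `genes`).
#' @export
gene_signature <- function(name, genes) {
  genes <- unique(as.character(genes))
  genes <- genes[!is.na(genes) & genes != ""]
  if (length(genes) == 0L) {
    stop("gene signature '", name, "' is empty")
  }
  structure(list(name = name, genes = genes), class = "gene_signature")
}

sig_genes <- function(x) {
  if (inherits(x, "gene_signature")) x$genes else unique(as.character(x))
}

#' Build the astrocyte composite signature (ACS)
#'
#' Merges component astrocyte gene sets into one composite signature by
#' set union with deduplication.
#'
#' @param component_sigs Non-empty list of `gene_signature` objects (or
#'   plain character vectors).
#' @param name Name of the composite (default `"ACS"`).
#' @return A `gene_signature` holding the union of all component genes.
#' @export
build_acs <- function(component_sigs, name = "ACS") {
  if (length(component_sigs) == 0L) {
    stop("build_acs needs at least one component signature")
  }
  gene_signature(name, unlist(lapply(component_sigs, sig_genes)))
}

#' ssGSEA enrichment scores
#'
#' Computes the single-sample running-sum enrichment score of each
#' signature in each sample. Within a sample, genes are ordered by
#' decreasing expression (ties broken by gene order in `expr`); the gene at
#' descending position i carries rank value `N - i + 1`. In-set genes
#' contribute `rank^alpha` increments normalised by the total in-set
#' weight; out-of-set genes contribute `1 / (N - m)`. The score is the sum
#' over all positions of the running difference. With `normalize = TRUE`
#' all scores are divided by the range (max - min) of the full score table,
#' so the scale is cohort-relative.
#'
#' @param expr Genes x samples numeric matrix with gene-id row names.
#' @param signatures A `gene_signature`, character vector, or (named) list
#'   of either.
#' @param alpha Rank weighting exponent (default 0.25).
#' @param normalize Divide by the score-table range (default `TRUE`).
#' @return Samples x signatures numeric matrix.
#' @export
ssgsea <- function(expr, signatures, alpha = 0.25, normalize = TRUE) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) {
    stop("expression matrix needs gene ids as row names")
  }
  if (alpha < 0) stop("alpha must be >= 0")
  if (inherits(signatures, "gene_signature") || is.character(signatures)) {
    signatures <- list(signatures)
  }
  nm <- names(signatures)
  if (is.null(nm)) nm <- rep("", length(signatures))
  nm <- vapply(seq_along(signatures), function(i) {
    s <- signatures[[i]]
    if (nzchar(nm[i])) nm[i]
    else if (inherits(s, "gene_signature")) s$name
    else paste0("set", i)
  }, character(1))

  universe <- rownames(expr)
  n <- length(universe)
  memberships <- lapply(seq_along(signatures), function(i) {
    g <- sig_genes(signatures[[i]])
    idx <- which(universe %in% g)
    if (length(idx) < 2L) {
      stop("signature '", nm[i],
           "' shares fewer than 2 genes with the expression universe")
    }
    idx
  })

  scores <- matrix(NA_real_, ncol(expr), length(signatures),
                   dimnames = list(colnames(expr), nm))
  for (s in seq_len(ncol(expr))) {
    ord <- order(expr[, s], decreasing = TRUE)      # stable: ties by row order
    rank_val <- (n - seq_len(n) + 1)^alpha          # weight at each position
    for (k in seq_along(memberships)) {
      inset <- logical(n)
      inset[match(memberships[[k]], ord)] <- TRUE
      w <- rank_val * inset
      p_in <- cumsum(w) / sum(w)
      m <- sum(inset)
      p_out <- if (m == n) rep(0, n) else cumsum(!inset) / (n - m)
      scores[s, k] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  scores
}

#' Classify samples as enriched for the composite astrocyte signature
#'
#' A sample is enriched iff (1) its ACS score strictly exceeds the cohort
#' mean ACS score, and (2) the ACS score is at least `margin` times every
#' competing OPC signature score. The multiplicative margin assumes
#' non-negative (cohort-normalised) scores; when negative scores are
#' present a warning is raised and rule (2) falls back to an additive
#' margin of `(margin - 1) * |opc|` for the negative scores.
#'
#' @param score_table Samples x signatures matrix or data frame of
#'   enrichment scores (e.g. from [ssgsea()]).
#' @param acs Column name of the composite astrocyte signature
#'   (default `"ACS"`).
#' @param opc Column names of the competing OPC signatures.
#' @param margin Multiplicative margin (default 1.1, i.e. 10% greater).
#' @return A `data.frame` with one row per sample: `sample_id`,
#'   `acs_score`, `max_opc_score`, `cohort_mean_acs` and logical
#'   `enriched`.
#' @export
classify_enrichment <- function(score_table, acs = "ACS",
                                opc = c("OPC_Enriched_300",
                                        "OPC_Specific_300"),
                                margin = 1.1) {
  score_table <- as.matrix(score_table)
  missing <- setdiff(c(acs, opc), colnames(score_table))
  if (length(missing) > 0L) {
    stop("score table lacks columns: ", paste(missing, collapse = ", "))
  }
  acs_score <- score_table[, acs]
  opc_scores <- score_table[, opc, drop = FALSE]
  if (any(cbind(acs_score, opc_scores) < 0)) {
    warning("negative enrichment scores: using an additive margin of ",
            "(margin - 1) * |score| for negative OPC scores")
  }
  cohort_mean <- mean(acs_score)
  add <- margin - 1
  beats_opc <- vapply(seq_along(acs_score), function(i) {
    s <- opc_scores[i, ]
    req <- ifelse(s < 0, s + add * abs(s), margin * s)
    all(acs_score[i] >= req)
  }, logical(1))
  data.frame(
    sample_id = rownames(score_table) %||% as.character(seq_along(acs_score)),
    acs_score = unname(acs_score),
    max_opc_score = unname(apply(opc_scores, 1L, max)),
    cohort_mean_acs = cohort_mean,
    enriched = unname(acs_score > cohort_mean & beats_opc),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- GMT I/O ----------------------------------------------------------------

#' Read / write gene signatures in GMT format
#'
#' Reading delegates to `fgsea::gmtPathways()`; the second (description)
#' field is written as `"na"`.
#'
#' @param path GMT file path.
#' @return `read_gmt()` returns a named list of `gene_signature` objects.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  out <- lapply(names(sets), function(nm) gene_signature(nm, sets[[nm]]))
  names(out) <- names(sets)
  out
}

#' @rdname read_gmt
#' @param signatures Named list of `gene_signature` objects or character
#'   vectors.
#' @export
write_gmt <- function(signatures, path) {
  lines <- vapply(seq_along(signatures), function(i) {
    s <- signatures[[i]]
    nm <- if (inherits(s, "gene_signature")) s$name else names(signatures)[i]
    paste(c(nm, "na", sig_genes(s)), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
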