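# Beta/M-value data model and TSV I/O.
#
# Conventions used throughout the package:
#  * probe coordinates are 0-based point positions of the CpG; BED export is
#    0-based half-open,
#  * beta values are clamped to [1e-6, 1 - 1e-6] before log-odds conversion
#    so normalised data containing boundary values stay finite,
#  * probes absent from one side of a comparison are dropped listwise.

#' Convert beta values to M values
#'
#' The M value is the log2-odds of methylation, `M = log2(beta / (1 - beta))`.
#' Beta values at or near the boundaries are clamped to `[eps, 1 - eps]`
#' first so that the transform stays finite.
#'
#' @param beta Numeric vector or matrix of beta values in `[0, 1]`.
#' @param eps Clamping bound; betas are limited to `[eps, 1 - eps]`.
#' @return Object of the same shape as `beta`, holding M values.
#' @seealso [m_to_beta()] for the inverse transform.
#' @examples
#' beta_to_m(c(0.2, 0.5, 0.8))
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (any(!is.finite(beta))) {
    stop("beta values must be finite")
  }
  if (any(beta < 0 | beta > 1)) {
    stop("beta values must lie in [0, 1]")
  }
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Convert M values back to beta values
#'
#' Inverse of [beta_to_m()]: `beta = 2^M / (1 + 2^M)`.
#'
#' @param m Numeric vector or matrix of M values.
#' @return Beta values in `(0, 1)`.
#' @export
m_to_beta <- function(m) {
  2^m / (1 + 2^m)
}

#' Per-probe median delta M between two groups
#'
#' For every probe shared between the two matrices, computes the median of
#' all pairwise replicate differences `tumour_i - control_j`. With a single
#' sample on each side this reduces to the plain difference.
#'
#' @param tumour,control Probes x samples matrices of M values with probe
#'   ids as row names.
#' @return Named numeric vector of median delta M values, one per shared
#'   probe, in the row order of `tumour`.
#' @export
median_delta_m <- function(tumour, control) {
  tumour <- as.matrix(tumour)
  control <- as.matrix(control)
  if (is.null(rownames(tumour)) || is.null(rownames(control))) {
    stop("both matrices need probe ids as row names")
  }
  shared <- intersect(rownames(tumour), rownames(control))
  if (length(shared) == 0L) {
    stop("no shared probes between tumour and control matrices")
  }
  tm <- tumour[shared, , drop = FALSE]
  cm <- control[shared, , drop = FALSE]
  out <- vapply(seq_along(shared), function(i) {
    median(as.vector(outer(tm[i, ], cm[i, ], "-")))
  }, numeric(1))
  names(out) <- shared
  out
}

# ---- probe manifest ---------------------------------------------------------

#' Construct and validate a probe manifest
#'
#' The manifest is the genomic scaffold for DMR calling: one row per array
#' probe with its chromosome and 0-based position.
#'
#' @param probe_id Character vector of unique probe identifiers.
#' @param chrom Chromosome names.
#' @param pos 0-based integer positions (point coordinate of the CpG).
#' @param strand Strand, one of `"+"`, `"-"`, `"*"` (unknown).
#' @return A `data.frame` with class `probe_manifest`, sorted by
#'   (chrom, pos).
#' @export
probe_manifest <- function(probe_id, chrom, pos, strand = "*") {
  df <- data.frame(
    probe_id = as.character(probe_id),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    strand = rep_len(as.character(strand), length(probe_id)),
    stringsAsFactors = FALSE
  )
  validate_manifest(df)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("probe_manifest", "data.frame")
  df
}

validate_manifest <- function(df) {
  required <- c("probe_id", "chrom", "pos")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("manifest is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$probe_id)) {
    stop("manifest contains duplicated probe ids")
  }
  if (any(df$pos < 0)) {
    stop("manifest positions must be non-negative")
  }
  if (!all(df$strand %in% c("+", "-", "*"))) {
    stop("manifest strand must be one of '+', '-', '*'")
  }
  invisible(df)
}

#' Read / write a probe manifest as TSV
#'
#' Columns: `probe_id`, `chrom`, `pos` (0-based), `strand`.
#'
#' @param path File path.
#' @return `read_manifest()` returns a validated `probe_manifest`.
#' @export
read_manifest <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  df$pos <- suppressWarnings(as.integer(df$pos))
  if (any(is.na(df$pos))) {
    stop("manifest 'pos' column contains non-integer values")
  }
  if (is.null(df$strand)) df$strand <- "*"
  probe_manifest(df$probe_id, df$chrom, df$pos, df$strand)
}

#' @rdname read_manifest
#' @param manifest A `probe_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- beta matrices ----------------------------------------------------------

#' Validate a beta matrix against a manifest
#'
#' Checks that all values are numeric and within `[0, 1]` and that every row
#' id is present in the manifest.
#'
#' @param beta Probes x samples numeric matrix with probe-id row names.
#' @param manifest Optional `probe_manifest` to validate row ids against.
#' @return The matrix, invisibly.
#' @export
validate_beta <- function(beta, manifest = NULL) {
  if (!is.numeric(beta)) {
    stop("beta matrix must be numeric")
  }
  if (is.null(rownames(beta))) {
    stop("beta matrix needs probe ids as row names")
  }
  if (anyDuplicated(rownames(beta))) {
    stop("beta matrix contains duplicated probe ids")
  }
  if (any(!is.finite(beta)) || any(beta < 0 | beta > 1)) {
    stop("beta values must be finite and in [0, 1]")
  }
  if (!is.null(manifest)) {
    missing <- setdiff(rownames(beta), manifest$probe_id)
    if (length(missing) > 0L) {
      stop(
        "probes absent from manifest: ",
        paste(utils::head(missing, 5L), collapse = ", "),
        if (length(missing) > 5L) ", ..."
      )
    }
  }
  invisible(beta)
}

#' Read / write a beta matrix as TSV
#'
#' The TSV stores probes in rows (first column `probe_id`) and samples in
#' columns; round-trips are lossless up to numeric printing precision.
#'
#' @param path File path.
#' @param manifest Optional manifest used to validate probe ids on read.
#' @return `read_beta_matrix()` returns a numeric matrix with probe-id row
#'   names.
#' @export
read_beta_matrix <- function(path, manifest = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "probe_id") {
    stop("beta matrix TSV must have 'probe_id' as its first column")
  }
  ids <- as.character(df$probe_id)
  if (anyDuplicated(ids)) {
    stop("beta matrix contains duplicated probe ids")
  }
  vals <- df[, -1L, drop = FALSE]
  num <- vapply(vals, is.numeric, logical(1))
  if (!all(num)) {
    stop(
      "non-numeric beta values in columns: ",
      paste(names(vals)[!num], collapse = ", ")
    )
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  validate_beta(m, manifest)
  m
}

#' @rdname read_beta_matrix
#' @param beta Probes x samples numeric matrix with probe-id row names.
#' @export
write_beta_matrix <- function(beta, path) {
  validate_beta(beta)
  df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
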