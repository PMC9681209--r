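# Synthetic single-cell UMI mixtures with known cell-type composition.
#
# UMI counts follow a negative binomial with dispersion 0.5 (size = 2),
# overdispersed enough to exercise rank- and bin-based scoring. Each cell
# type up-regulates its marker signature(s) by a common fold change:
# cancer AC-like cells the composite astrocyte signature, cancer OPC-like
# cells both OPC signatures, and each immune type its own marker set.

#' Cell-type labels used by the single-cell generator
#' @return Character vector of the six labels.
#' @export
cell_type_labels <- function() {
  c("cancer_AC", "cancer_OPC", "TAM", "Tcell", "monocyte", "other")
}

#' Generate a synthetic single-cell cohort
#'
#' @param n_patients Number of patients.
#' @param cells_per_patient Cells per patient.
#' @param fractions Named numeric vector of cell-type proportions over
#'   [cell_type_labels()] (missing types get 0); must sum to 1. Per
#'   patient, cell counts are drawn multinomially and the realised
#'   fractions are recorded as truth.
#' @param n_genes Number of genes (default 800).
#' @param fold_change Marker up-regulation fold change (> 1, default 3).
#' @param dispersion Negative-binomial dispersion (default 0.5).
#' @param mean_counts Mean UMI count per gene per cell before
#'   marker effects (default 0.3).
#' @param seed Integer seed.
#' @return A list: `counts` (sparse genes x cells `dgCMatrix`),
#'   `cells` (`data.frame` with `cell`, `patient`, `label`),
#'   `signatures` (named list of `gene_signature`: `ACS`,
#'   `OPC_Enriched_300`, `OPC_Specific_300`, `TAM_markers`,
#'   `Tcell_markers`, `monocyte_markers`), and `truth` (per-patient
#'   realised fractions, `fold_change`, `seed`).
#' @export
gen_single_cell <- function(n_patients, cells_per_patient,
                            fractions = c(cancer_AC = 0.25,
                                          cancer_OPC = 0.25,
                                          TAM = 0.2, Tcell = 0.1,
                                          monocyte = 0.1, other = 0.1),
                            n_genes = 800L, fold_change = 3,
                            dispersion = 0.5, mean_counts = 0.3,
                            seed = 1L) {
  types <- cell_type_labels()
  fr <- setNames(numeric(length(types)), types)
  if (is.null(names(fractions)) || !all(names(fractions) %in% types)) {
    stop("'fractions' must be named with labels from cell_type_labels()")
  }
  fr[names(fractions)] <- fractions
  if (abs(sum(fr) - 1) > 1e-8) stop("fractions must sum to 1")
  if (fold_change <= 1) stop("fold_change must exceed 1")

  withr::with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    sig_sizes <- c(ACS = 100L, OPC_Enriched_300 = 50L,
                   OPC_Specific_300 = 50L, TAM_markers = 30L,
                   Tcell_markers = 30L, monocyte_markers = 30L)
    if (sum(sig_sizes) > n_genes) stop("n_genes too small for the signatures")
    picked <- sample(genes, sum(sig_sizes))
    ends <- cumsum(sig_sizes)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    signatures <- lapply(seq_along(sig_sizes), function(i) {
      gene_signature(names(sig_sizes)[i], picked[starts[i]:ends[i]])
    })
    names(signatures) <- names(sig_sizes)

    # marker sets up-regulated per type
    type_sigs <- list(
      cancer_AC = "ACS",
      cancer_OPC = c("OPC_Enriched_300", "OPC_Specific_300"),
      TAM = "TAM_markers",
      Tcell = "Tcell_markers",
      monocyte = "monocyte_markers",
      other = character(0)
    )

    mu0 <- mean_counts * exp(rnorm(n_genes, sd = 1))
    size <- 1 / dispersion

    n_cells <- n_patients * cells_per_patient
    labels <- character(n_cells)
    patient <- character(n_cells)
    counts <- matrix(0L, n_genes, n_cells)
    truth_fr <- matrix(0, n_patients, length(types),
                       dimnames = list(sprintf("patient%02d",
                                               seq_len(n_patients)), types))
    col <- 0L
    for (p in seq_len(n_patients)) {
      ncell_type <- as.vector(rmultinom(1L, cells_per_patient, fr))
      truth_fr[p, ] <- ncell_type / cells_per_patient
      for (t in seq_along(types)) {
        nt <- ncell_type[t]
        if (nt == 0L) next
        mu <- mu0
        for (s in type_sigs[[types[t]]]) {
          idx <- match(signatures[[s]]$genes, genes)
          mu[idx] <- mu[idx] * fold_change
        }
        block <- matrix(rnbinom(n_genes * nt, mu = mu, size = size),
                        n_genes, nt)
        counts[, col + seq_len(nt)] <- block
        labels[col + seq_len(nt)] <- types[t]
        patient[col + seq_len(nt)] <- rownames(truth_fr)[p]
        col <- col + nt
      }
    }
    cell_ids <- sprintf("cell%05d", seq_len(n_cells))
    dimnames(counts) <- list(genes, cell_ids)
    list(
      counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                           "CsparseMatrix"),
      cells = data.frame(cell = cell_ids, patient = patient,
                         label = labels, stringsAsFactors = FALSE),
      signatures = signatures,
      truth = list(fractions = truth_fr, fold_change = fold_change,
                   seed = seed)
    )
  })
}

#' Write a single-cell cohort as MTX plus barcode/feature tables
#'
#' @param sc Result of [gen_single_cell()].
#' @param dir Output directory (created if needed); writes `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv`, `labels.tsv`.
#' @return `dir`, invisibly.
#' @export
write_single_cell <- function(sc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(sc$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(sc$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(sc$counts), file.path(dir, "barcodes.tsv"))
  write.table(sc$cells, file.path(dir, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a single-cell cohort written by [write_single_cell()]
#'
#' @param dir Directory holding `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv` and optionally `labels.tsv`.
#' @return A list with `counts` and (if present) `cells`.
#' @export
read_single_cell <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  rownames(counts) <- readLines(file.path(dir, "features.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  out <- list(counts = counts)
  lab <- file.path(dir, "labels.tsv")
  if (file.exists(lab)) {
    out$cells <- read.delim(lab, stringsAsFactors = FALSE)
  }
  out
}
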