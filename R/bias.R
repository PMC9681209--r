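# Hypo-methylation bias statistic, classification rules and spectrum.
#
# A tumour line is "hypo-biased" when hypo-methylated DMRs dominate its
# comparisons against non-neoplastic comparators: strictly more than 60% of
# DMRs hypo-methylated in the syngeneic comparison, or strictly more than
# 50% in every comparison when several comparators are used. The mean
# fraction across comparators places each line on a six-level bias
# spectrum. All thresholds are strict exceedances; spectrum bins are
# half-open with the boundary in the upper bin.

#' Fraction of hypo-methylated DMRs
#'
#' @param dmrs A DMR table from [call_dmrs()].
#' @return `n_hypo / (n_hypo + n_hyper)`, or `NA_real_` when the table has
#'   no DMRs (never 0).
#' @export
hypo_fraction <- function(dmrs) {
  if (is.null(dmrs) || nrow(dmrs) == 0L) {
    return(NA_real_)
  }
  mean(dmrs$direction == "hypo")
}

#' Classify one syngeneic comparison
#'
#' A line is `"bias"` iff its hypo fraction strictly exceeds `threshold`.
#'
#' @param fraction Hypo-methylated DMR fraction(s); `NA` for comparisons
#'   with no DMRs.
#' @param threshold Strict exceedance threshold (default 0.60).
#' @return Character vector: `"bias"`, `"non-bias"` or `NA` when the
#'   fraction is missing.
#' @export
classify_syngeneic <- function(fraction, threshold = 0.60) {
  ifelse(is.na(fraction), NA_character_,
         ifelse(fraction > threshold, "bias", "non-bias"))
}

#' Classify a line from multiple comparator fractions
#'
#' With several comparators a more lenient per-comparison threshold
#' applies, but it must be exceeded in every comparison: `"bias"` iff all
#' (non-missing) fractions are strictly greater than `threshold`. A line
#' whose fractions are more than half missing is non-classifiable (`NA`).
#'
#' @param fractions Numeric vector of per-comparator hypo fractions
#'   (length >= 2).
#' @param threshold Strict per-comparison threshold (default 0.50).
#' @return `"bias"`, `"non-bias"` or `NA_character_`.
#' @export
classify_all_comparators <- function(fractions, threshold = 0.50) {
  if (length(fractions) < 2L) {
    stop("classify_all_comparators needs at least 2 comparators")
  }
  ok <- !is.na(fractions)
  if (sum(ok) < length(fractions) / 2) {
    return(NA_character_)
  }
  if (all(fractions[ok] > threshold)) "bias" else "non-bias"
}

#' Bias spectrum bin for a mean hypo fraction
#'
#' Half-open bins, boundary values falling in the upper bin:
#' `[0, 0.5)` none, `[0.5, 0.6)` very_low, `[0.6, 0.7)` low,
#' `[0.7, 0.8)` medium, `[0.8, 0.9)` high, `[0.9, 1]` very_high.
#'
#' @param mean_fraction Mean hypo-methylated DMR fraction(s) in `[0, 1]`.
#' @return Factor with levels `none`, `very_low`, `low`, `medium`, `high`,
#'   `very_high`; `NA` propagates.
#' @export
spectrum_bin <- function(mean_fraction) {
  if (any(mean_fraction < 0 | mean_fraction > 1, na.rm = TRUE)) {
    stop("mean_fraction must lie in [0, 1]")
  }
  cut(mean_fraction,
      breaks = c(0, 0.5, 0.6, 0.7, 0.8, 0.9, 1),
      labels = c("none", "very_low", "low", "medium", "high", "very_high"),
      right = FALSE, include.lowest = TRUE)
}

#' Run the bias classifier over a cohort
#'
#' @param comparisons Named list (one element per tumour line) of named
#'   lists of DMR tables, one per comparator. In `"syngeneic"` mode each
#'   line must have exactly one comparator.
#' @param mode `"syngeneic"` (single comparison, >60% rule) or
#'   `"all_comparators"` (>50% in every comparison).
#' @param thresholds Named list overriding the rule thresholds
#'   (`syngeneic`, `all_comparators`).
#' @return A `data.frame` with one row per line: `sample_id`,
#'   `n_comparators`, `mean_hypo_fraction` (ignoring missing fractions),
#'   `label`, `spectrum` and a list column `hypo_fractions` holding the
#'   named per-comparator fractions. Rows are ordered by `sample_id`;
#'   results are invariant to comparator ordering.
#' @export
run_bias_cohort <- function(comparisons,
                            mode = c("syngeneic", "all_comparators"),
                            thresholds = list(syngeneic = 0.60,
                                              all_comparators = 0.50)) {
  mode <- match.arg(mode)
  if (is.null(names(comparisons)) || any(names(comparisons) == "")) {
    stop("'comparisons' must be a named list, one element per line")
  }
  ids <- sort(names(comparisons))
  rows <- lapply(ids, function(id) {
    dmr_sets <- comparisons[[id]]
    fr <- vapply(dmr_sets, hypo_fraction, numeric(1))
    # deterministic ordering of comparators within a line
    if (!is.null(names(fr))) fr <- fr[order(names(fr))]
    label <- if (mode == "syngeneic") {
      if (length(fr) != 1L) {
        stop("syngeneic mode requires exactly one comparator per line (",
             id, " has ", length(fr), ")")
      }
      classify_syngeneic(fr, thresholds$syngeneic)
    } else {
      classify_all_comparators(fr, thresholds$all_comparators)
    }
    mean_fr <- if (all(is.na(fr))) NA_real_ else mean(fr, na.rm = TRUE)
    data.frame(
      sample_id = id,
      n_comparators = length(fr),
      mean_hypo_fraction = mean_fr,
      label = label,
      spectrum = as.character(spectrum_bin(mean_fr)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$hypo_fractions <- I(lapply(ids, function(id) {
    fr <- vapply(comparisons[[id]], hypo_fraction, numeric(1))
    if (!is.null(names(fr))) fr[order(names(fr))] else fr
  }))
  attr(out, "mode") <- mode
  out
}

#' Patient-specific DMRs
#'
#' Restricts each line's DMRs to those not overlapping (by at least 1 bp)
#' any DMR called in any other line's comparison. This sharpens
#' line-private methylation differences by removing regions recurrently
#' called across the cohort.
#'
#' @param dmr_list Named list of DMR tables, one per line.
#' @return Named list of filtered DMR tables in the same order.
#' @export
patient_specific_dmrs <- function(dmr_list) {
  if (length(dmr_list) < 2L) {
    return(dmr_list)
  }
  grs <- lapply(dmr_list, function(d) {
    if (nrow(d) == 0L) GenomicRanges::GRanges() else dmrs_to_granges(d)
  })
  out <- lapply(seq_along(dmr_list), function(i) {
    d <- dmr_list[[i]]
    if (nrow(d) == 0L) return(d)
    others <- suppressWarnings(do.call(c, unname(grs[-i])))
    if (length(others) == 0L) return(d)
    hits <- GenomicRanges::countOverlaps(grs[[i]], others) > 0L
    d[!hits, , drop = FALSE]
  })
  names(out) <- names(dmr_list)
  out
}
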