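# Run configuration and workflow composition: one object carrying every
# analysis default, and helpers tying the stages into the two workflows
# (methylation-bias cohort analysis; signature scoring).

#' Default run configuration
#'
#' Aggregates every tunable parameter of the pipeline with its default:
#' DMR calling (6 probes, beta cutoff 0.3, lambda 1000, C 2), bias rules
#' (>0.60 syngeneic, >0.50 in all comparisons), ssGSEA (alpha 0.25,
#' cohort-range normalisation), the enrichment margin (1.1), module-score
#' binning (24 bins, 100 controls), and the morphology radii/threshold
#' (35 um tissue margin; 10 um opening and 10,000 um^2 island filter;
#' 75/100/25 um gross recipe).
#'
#' @param ... Named overrides for any of the nested entries, e.g.
#'   `dmr = dmr_params(min_probes = 4)`.
#' @return A nested list with class `run_config`.
#' @export
default_params <- function(...) {
  cfg <- list(
    dmr = dmr_params(),
    bias = list(syngeneic = 0.60, all_comparators = 0.50),
    ssgsea = list(alpha = 0.25, normalize = TRUE),
    enrichment = list(margin = 1.1),
    module_score = list(n_bins = 24L, n_ctrl = 100L),
    morphology = list(tissue_margin = 35, open_radius = 10,
                      min_area = 10000, d1 = 75, e1 = 100, d2 = 25),
    seed = 1L
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "run_config")
}

#' Call DMRs and classify bias for a cohort of comparisons
#'
#' Composes [call_dmrs()] and [run_bias_cohort()]: for every line and
#' every comparator, DMRs are called between the line's tumour matrix and
#' the comparator's control matrix, then the cohort-level bias table is
#' produced.
#'
#' @param manifest A [probe_manifest()].
#' @param tumours Named list of tumour beta matrices (one per line).
#' @param controls Named list of control beta matrices (comparators). In
#'   syngeneic mode `controls` must be parallel to `tumours` (same names);
#'   in all-comparators mode every tumour is compared with every control.
#' @param mode `"syngeneic"` or `"all_comparators"`.
#' @param config A [default_params()] configuration.
#' @return A list: `bias` (the [run_bias_cohort()] table) and `dmrs`
#'   (nested list of DMR tables, line -> comparator).
#' @export
run_methylation_workflow <- function(manifest, tumours, controls,
                                     mode = c("syngeneic",
                                              "all_comparators"),
                                     config = default_params()) {
  mode <- match.arg(mode)
  if (mode == "syngeneic" && !identical(names(tumours), names(controls))) {
    stop("syngeneic mode requires parallel tumour/control lists")
  }
  dmrs <- lapply(names(tumours), function(id) {
    comps <- if (mode == "syngeneic") controls[id] else controls
    lapply(comps, function(ctl) {
      call_dmrs(manifest, tumours[[id]], ctl, config$dmr)
    })
  })
  names(dmrs) <- names(tumours)
  bias <- run_bias_cohort(dmrs, mode = mode, thresholds = config$bias)
  list(bias = bias, dmrs = dmrs)
}

#' Score a cohort and classify composite-signature enrichment
#'
#' Composes [ssgsea()] and [classify_enrichment()].
#'
#' @param expr Genes x samples expression matrix (e.g. TPM).
#' @param signatures Named list of signatures; must include the ACS and
#'   the OPC signature columns named in `acs` / `opc`.
#' @param acs,opc Signature names used by the enrichment rule.
#' @param config A [default_params()] configuration.
#' @return A list: `scores` (samples x signatures) and `enrichment`
#'   (the [classify_enrichment()] table).
#' @export
run_signature_workflow <- function(expr, signatures, acs = "ACS",
                                   opc = c("OPC_Enriched_300",
                                           "OPC_Specific_300"),
                                   config = default_params()) {
  scores <- ssgsea(expr, signatures, alpha = config$ssgsea$alpha,
                   normalize = config$ssgsea$normalize)
  list(scores = scores,
       enrichment = classify_enrichment(scores, acs = acs, opc = opc,
                                        margin = config$enrichment$margin))
}
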