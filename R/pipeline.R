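# End-to-end driver: from a fixture bundle (or the equivalent in-memory
# objects) through rate estimation, FA priors, the posterior scan over
# basal ages and clock models, and the cladogenesis-rate fits.

#' Estimate skyline rates from an occurrence table
#'
#' Convenience wrapper chaining [bin_collections()], [count_timers()],
#' per-interval [fit_sampling_lognormal()] and [estimate_rates()].
#'
#' @param occ an [occurrence_table()].
#' @param ts a [timescale()].
#' @param seed seed for collection binning.
#' @param level `"species"` (required for FBD priors) or `"genus"`.
#' @param min_taxa minimum sampled taxa for a per-interval lognormal fit.
#' @return a [skyline_rates()].
#' @export
occurrence_skyline <- function(occ, ts, seed = 1L, level = "species",
                               min_taxa = 5L) {
  pm <- bin_collections(occ, ts, seed = seed, level = level)
  tc <- count_timers(pm)
  dur <- ts$older - ts$younger
  sds <- lapply(seq_len(nrow(ts)), function(i) {
    cts <- pm$counts[, i]
    cts <- cts[cts > 0]
    if (length(cts) < min_taxa) return(NULL)
    suppressWarnings(fit_sampling_lognormal(cts, dur[i]))
  })
  estimate_rates(tc, sds, ts)
}

#' Run the full tip-dating pipeline on a fixture bundle
#'
#' Reads a directory written by [make_fixture_bundle()] (tree, characters,
#' occurrences, FA candidates, timescale, config), estimates skyline
#' rates, estimates the among-character lognormal scale from parsimony
#' change counts unless the config fixes it, runs the three-model
#' posterior scan, and fits constant and exponentially declining
#' cladogenesis rates on the best early-burst tree.
#'
#' @param dir bundle directory.
#' @param config optional [analysis_config()] overriding the bundled one.
#' @param models model labels passed to [scan_posterior()].
#' @return a list of class `pipeline_result`: `table` (the per-model
#'   posterior decomposition), `scan`, `rates`, `clado` (fits plus the
#'   likelihood-ratio test), `bayes_factors`.
#' @export
run_pipeline <- function(dir, config = NULL,
                         models = c("strict_fa", "strict_fbd",
                                    "early_burst_fbd")) {
  tree <- read_dated_tree(file.path(dir, "tree.nwk"))
  cm <- read_character_matrix(file.path(dir, "characters.nex"))
  occ <- read_occurrences(file.path(dir, "occurrences.csv"))
  fc <- read_fa_candidates(file.path(dir, "fa_candidates.csv"))
  ts <- read_timescale(file.path(dir, "timescale.yml"))
  cfg <- config %||% read_config(file.path(dir, "config.yml"))
  rates <- occurrence_skyline(occ, ts, seed = cfg$seed)
  scan <- scan_posterior(tree, cm, fc, rates, cfg, models = models)
  tab <- do.call(rbind, lapply(scan$posteriors, as.data.frame))
  rownames(tab) <- NULL
  bf <- list()
  surf <- function(m) scan$surfaces[scan$surfaces$model == m, ]
  if (all(c("strict_fa", "strict_fbd") %in% models))
    bf$fbd_vs_fa <- bayes_factor(surf("strict_fbd"), surf("strict_fa"))
  if (all(c("strict_fbd", "early_burst_fbd") %in% models))
    bf$eb_vs_strict <- bayes_factor(surf("early_burst_fbd"), surf("strict_fbd"))
  clado <- NULL
  if ("early_burst_fbd" %in% models) {
    best_tree <- scan$trees[["early_burst_fbd"]]
    cfit <- fit_clado_model(best_tree, rates, "constant")
    efit <- fit_clado_model(best_tree, rates, "exponential_decay")
    clado <- list(constant = cfit, exponential = efit,
                  lrt = likelihood_ratio_test(cfit, efit),
                  per_branch = per_branch_mle(best_tree, rates))
  }
  structure(list(table = tab, scan = scan, rates = rates, clado = clado,
                 bayes_factors = bf, config = cfg),
            class = "pipeline_result")
}
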