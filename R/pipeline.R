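# Cohort-level pipeline: simulate -> fit -> compare -> analyze -> report.
# These functions are the package's command surface; each stage returns a
# plain R object that serializes to CSV/JSON through the io helpers.

#' Fit response-time models across a cohort
#'
#' @param cohort an `msr_cohort`
#' @param models RT models to fit
#' @param profile sampler profile
#' @param seed master seed; per-(participant, model) child seeds are
#'   derived from it
#' @return nested list `fits[[participant]][[model]]` of `msr_draws`
#' @export
fit_cohort_rt <- function(cohort, models = c("null", "explicit", "mb", "sr"),
                          profile = "test", seed = 1L) {
  purrr::imap(cohort$logs, function(lg, id) {
    i <- match(id, names(cohort$logs))
    stats::setNames(lapply(seq_along(models), function(j)
      fit_rt_model(lg, cohort$mappings[[id]], model = models[j],
                   profile = profile, seed = seed + 1000L * i + j)), models)
  })
}

#' Fit choice models across a cohort
#'
#' @inheritParams fit_cohort_rt
#' @param models choice models to fit
#' @return nested list of `msr_draws`
#' @export
fit_cohort_choice <- function(cohort, models = c("null", "explicit", "mb", "sr"),
                              profile = "test", seed = 1L) {
  purrr::imap(cohort$logs, function(lg, id) {
    i <- match(id, names(cohort$logs))
    stats::setNames(lapply(seq_along(models), function(j)
      fit_choice_model(lg, cohort$mappings[[id]], model = models[j],
                       profile = profile, seed = seed + 2000L * i + j)), models)
  })
}

#' Model comparison across a cohort
#'
#' PSIS-LOO evidences, pseudo-BMA+ weights and random-effects group
#' selection in one call.
#'
#' @param fits nested fits from [fit_cohort_rt()] or [fit_cohort_choice()]
#' @param n_boot Bayesian-bootstrap replicates for pseudo-BMA+
#' @param seed RNG seed
#' @return list with `evidence`, `weights`, `bms`
#' @export
compare_models <- function(fits, n_boot = 1000L, seed = 1L) {
  ev <- evidence_table(fits)
  list(evidence = ev,
       weights = pseudo_bma_plus(ev, n_boot = n_boot, seed = seed),
       bms = group_bms(ev, seed = seed))
}

#' Modularity and performance analysis across a cohort
#'
#' For each participant: expected modularity under the fitted discount
#' posterior, the uniform-prior null modularity, between-community RT
#' slowing, and accumulated reward.
#'
#' @param cohort an `msr_cohort` with response times
#' @param sr_fits list of SR response-time `msr_draws` per participant
#' @param n_null prior draws for the null modularity
#' @param seed RNG seed
#' @return tibble, one row per participant
#' @export
analyze_cohort <- function(cohort, sr_fits, n_null = 200L, seed = 1L) {
  purrr::imap_dfr(cohort$logs, function(lg, id) {
    mp <- cohort$mappings[[id]]
    fit <- sr_fits[[id]]
    gdraws <- extract_draws(fit, "gamma")
    tibble::tibble(
      participant = id,
      modularity = expected_modularity(gdraws, lg, mp),
      modularity_null = null_modularity(lg, mp, n_draws = n_null,
                                        seed = seed + match(id, names(cohort$logs))),
      gamma_mean = mean(gdraws),
      slowing = rt_slowing(lg, mp),
      reward = accumulated_reward(lg)
    )
  })
}

#' Summary report of a cohort analysis
#'
#' Collects the statistics of the standard analysis battery into one
#' JSON-serializable list: group model selection (BOR, pxp), population
#' effects (posterior mean, HDI, evidence ratio), the fit-vs-null
#' modularity comparison, and the two-step modularity regressions.
#'
#' @param comparison output of [compare_models()]
#' @param population an `msr_draws` from [fit_population_summary()]
#' @param analysis output of [analyze_cohort()]
#' @param path optional JSON output path
#' @return the report list, invisibly if written
#' @export
report_cohort <- function(comparison, population = NULL, analysis = NULL,
                          path = NULL) {
  rep <- list(
    model_selection = list(
      bor = comparison$bms$bor,
      pxp = as.list(comparison$bms$pxp),
      dirichlet_alpha = as.list(comparison$bms$alpha)
    )
  )
  if (!is.null(population)) {
    td <- tidy(population)
    rep$population_effects <- lapply(seq_len(nrow(td)), function(i)
      list(term = td$term[i], mean = td$estimate[i],
           hdi95 = c(td$conf.low[i], td$conf.high[i]),
           evidence_ratio = td$evidence_ratio[i]))
  }
  if (!is.null(analysis)) {
    tt <- stats::t.test(analysis$modularity, analysis$modularity_null,
                        paired = TRUE)
    rep$modularity <- list(
      mean_fit = mean(analysis$modularity),
      mean_null = mean(analysis$modularity_null),
      fit_vs_null_t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value)
    rep$two_step_reward <- as.list(two_step_regression(
      analysis$reward, analysis$slowing, analysis$modularity))
  }
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
    return(invisible(rep))
  }
  rep
}
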