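# broom-style summaries of fitted objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries
#'
#' One row per parameter: posterior mean and sd, 95% highest-density
#' interval bounds, the evidence ratio in the favored direction, and
#' convergence diagnostics.
#'
#' @param x an `msr_draws`
#' @param prob HDI mass
#' @param ... unused
#' @return a tibble
#' @export
tidy.msr_draws <- function(x, prob = 0.95, ...) {
  pars <- dimnames(x$draws)[[3]]
  purrr::map_dfr(pars, function(p) {
    d <- extract_draws(x, p)
    h <- hdi(d, prob)
    er <- if (mean(d) >= 0) evidence_ratio(d, "+") else evidence_ratio(d, "-")
    tibble::tibble(term = p, estimate = mean(d), std.error = stats::sd(d),
                   conf.low = h[["lower"]], conf.high = h[["upper"]],
                   evidence_ratio = er)
  }) |>
    dplyr::left_join(dplyr::rename(x$diagnostics, term = "parameter"),
                     by = "term")
}

#' One-row fit summary
#' @param x an `msr_draws`
#' @param ... unused
#' @return a tibble with draw counts, convergence and acceptance statistics
#' @export
glance.msr_draws <- function(x, ...) {
  d <- dim(x$draws)
  tibble::tibble(model = x$model, iterations = d[1], chains = d[2],
                 parameters = d[3], max_rhat = max(x$diagnostics$rhat),
                 min_ess = min(x$diagnostics$ess),
                 divergences = x$divergences,
                 accept_rate = x$accept_rate,
                 converged = check_convergence(x))
}

#' Tidy group model-selection results
#' @param x an `msr_bms`
#' @param ... unused
#' @return tibble with per-model Dirichlet counts, frequencies, exceedance
#'   and protected exceedance probabilities
#' @export
tidy.msr_bms <- function(x, ...) {
  tibble::tibble(model = names(x$pxp), alpha = unname(x$alpha),
                 frequency = unname(x$freq), xp = unname(x$xp),
                 pxp = unname(x$pxp))
}

#' @export
glance.msr_bms <- function(x, ...) {
  tibble::tibble(bor = x$bor, free_energy = x$free_energy,
                 free_energy_null = x$free_energy_null,
                 n_models = length(x$pxp))
}

#' @export
tidy.msr_loo <- function(x, ...) {
  tibble::tibble(elpd_loo = x$elpd_loo, se = x$se,
                 n_obs = length(x$pointwise), n_high_k = x$n_high_k)
}
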