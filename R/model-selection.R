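# Model evidence and group-level model selection. PSIS-LOO follows the
# Pareto-smoothed importance-sampling estimator (generalized-Pareto tail
# fit by the Zhang-Stephens profile posterior); pseudo-BMA+ regularizes
# exp(elpd) weights by the Bayesian bootstrap; the random-effects group
# analysis is the variational Dirichlet scheme with Bayesian omnibus risk
# and protected exceedance probabilities.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Zhang-Stephens estimate of the generalized-Pareto shape/scale for
# exceedances x > 0
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  m <- 30L + floor(sqrt(n))
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  jj <- seq_len(m)
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  k_j <- vapply(theta, function(th) mean(log1p(-th * x)), numeric(1))
  l_j <- n * (log(-theta / k_j) - k_j - 1)
  l_j[!is.finite(l_j)] <- -Inf
  w <- exp(l_j - logsumexp(l_j))
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  # weakly-informative shrinkage of the shape toward 0.5
  k <- k * n / (n + 10) + 5 / (n + 10)
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma / k * ((1 - p)^(-k) - 1)
}

# Pareto-smooth one vector of log importance ratios
psis_smooth <- function(lr) {
  S <- length(lr)
  lr <- lr - max(lr)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  ord <- order(lr)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- lr[ord[S - M]]
  exc <- exp(lr[tail_ids]) - exp(cutoff)
  if (max(exc) <= 0) return(list(lw = lr - logsumexp(lr), k = -Inf))
  fit <- gpd_fit(exc[exc > 0])
  p <- (rank(lr[tail_ids], ties.method = "first") - 0.5) / M
  sm <- log(exp(cutoff) + vapply(p, qgpd, numeric(1), k = fit$k, sigma = fit$sigma))
  lr[tail_ids] <- pmin(sm, 0)  # truncate at the max raw (log) ratio, 0
  list(lw = lr - logsumexp(lr), k = fit$k)
}

#' PSIS-LOO estimate of the expected log pointwise predictive density
#'
#' @param loglik matrix of pointwise log-likelihood draws (draws x
#'   observations)
#' @return list of class `msr_loo` with `elpd_loo`, `se`, `pointwise`,
#'   `pareto_k` (observations with shape > 0.7 are flagged in
#'   `n_high_k`)
#' @export
psis_loo <- function(loglik) {
  stopifnot(is.matrix(loglik), nrow(loglik) > 1)
  if (any(apply(loglik, 2, stats::sd) < 1e-300))
    stop("degenerate (constant) log-likelihood draws")
  N <- ncol(loglik)
  pointwise <- numeric(N)
  k <- numeric(N)
  for (i in seq_len(N)) {
    sm <- psis_smooth(-loglik[, i])
    pointwise[i] <- logsumexp(sm$lw + loglik[, i])
    k[i] <- sm$k
  }
  structure(list(elpd_loo = sum(pointwise),
                 se = sqrt(N * stats::var(pointwise)),
                 pointwise = pointwise, pareto_k = k,
                 n_high_k = sum(k > 0.7)),
            class = "msr_loo")
}

#' @export
print.msr_loo <- function(x, ...) {
  cat("<msr_loo> elpd_loo = ", round(x$elpd_loo, 2), " (SE ", round(x$se, 2),
      "), ", x$n_high_k, " observations with Pareto k > 0.7\n", sep = "")
  invisible(x)
}

#' Collect per-participant model evidences
#'
#' @param fits nested list `fits[[participant]][[model]]` of `msr_draws`
#'   with pointwise log-likelihood attached
#' @return an evidence tibble: `participant`, `model`, `elpd_loo`, `se`,
#'   and list-columns `pointwise`, `pareto_k`
#' @export
evidence_table <- function(fits) {
  purrr::imap_dfr(fits, function(models, id) {
    purrr::imap_dfr(models, function(f, mname) {
      l <- psis_loo(f$loglik)
      tibble::tibble(participant = id, model = mname, elpd_loo = l$elpd_loo,
                     se = l$se, pointwise = list(l$pointwise),
                     pareto_k = list(l$pareto_k))
    })
  })
}

#' Pseudo-BMA+ model weights
#'
#' Akaike-like weights proportional to `exp(elpd_loo)`, regularized away
#' from 0 and 1 by the Bayesian bootstrap over the pointwise elpd
#' contributions.
#'
#' @param evidence an [evidence_table()] (one participant or several)
#' @param n_boot Bayesian-bootstrap replicates
#' @param seed RNG seed
#' @return tibble `participant`, `model`, `weight` (rows sum to 1 within
#'   participant)
#' @export
pseudo_bma_plus <- function(evidence, n_boot = 1000L, seed = 1L) {
  withr_seed(seed, {
    evidence |>
      dplyr::group_by(.data$participant) |>
      dplyr::group_modify(function(df, key) {
        P <- do.call(cbind, df$pointwise)  # N x K
        N <- nrow(P); K <- ncol(P)
        if (K < 2) stop("pseudo-BMA+ needs at least 2 models")
        wsum <- rep(0, K)
        for (b in seq_len(n_boot)) {
          g <- stats::rgamma(N, 1)
          wb <- g / sum(g)
          z <- N * colSums(wb * P)
          wsum <- wsum + exp(z - logsumexp(z))
        }
        tibble::tibble(model = df$model, weight = wsum / n_boot)
      }) |>
      dplyr::ungroup()
  })
}

#' Random-effects group-level Bayesian model selection
#'
#' Variational estimation of the Dirichlet posterior over population model
#' frequencies from per-participant log evidences, with exceedance
#' probabilities, the Bayesian omnibus risk (posterior probability that all
#' frequencies are equal) and protected exceedance probabilities
#' `pxp = (1 - BOR) * xp + BOR / K`.
#'
#' @param log_evidence participants x models matrix of log model evidences
#'   (e.g. `elpd_loo`), or an [evidence_table()]
#' @param alpha0 Dirichlet prior count (uniform prior by default)
#' @param n_mc Monte-Carlo draws for exceedance probabilities (exact Beta
#'   computation is used for 2 models)
#' @param tol free-energy convergence tolerance
#' @param seed RNG seed
#' @return list of class `msr_bms`: `alpha`, `model_prob` (per-participant
#'   posterior model probabilities), `xp`, `bor`, `pxp`, `freq`
#' @export
group_bms <- function(log_evidence, alpha0 = 1, n_mc = 1e5, tol = 1e-8,
                      seed = 1L) {
  if (inherits(log_evidence, "data.frame")) {
    wide <- tidyr::pivot_wider(log_evidence[, c("participant", "model", "elpd_loo")],
                               names_from = "model", values_from = "elpd_loo")
    L <- as.matrix(wide[, -1])
    rownames(L) <- wide$participant
  } else L <- as.matrix(log_evidence)
  n <- nrow(L); K <- ncol(L)
  if (K < 2) stop("group BMS needs at least 2 models")
  models <- colnames(L)
  if (is.null(models)) models <- paste0("m", seq_len(K))
  alpha <- rep(alpha0, K)
  fe <- -Inf
  u <- matrix(1 / K, n, K)
  for (it in seq_len(1000)) {
    lu <- sweep(L, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    u <- exp(lu - apply(lu, 1, logsumexp))
    alpha <- alpha0 + colSums(u)
    fe_new <- lgamma(K * alpha0) - K * lgamma(alpha0) -
      lgamma(sum(alpha)) + sum(lgamma(alpha)) +
      sum(u * (L - log(pmax(u, 1e-300))))
    if (abs(fe_new - fe) < tol) { fe <- fe_new; break }
    fe <- fe_new
  }
  f0 <- sum(apply(L, 1, logsumexp) - log(K))
  bor <- 1 / (1 + exp(fe - f0))
  xp <- exceedance_prob(alpha, n_mc = n_mc, seed = seed)
  pxp <- (1 - bor) * xp + bor / K
  structure(list(alpha = stats::setNames(alpha, models),
                 model_prob = `colnames<-`(u, models),
                 xp = stats::setNames(xp, models),
                 bor = bor,
                 pxp = stats::setNames(pxp, models),
                 freq = stats::setNames(alpha / sum(alpha), models),
                 free_energy = fe, free_energy_null = f0),
            class = "msr_bms")
}

#' @export
print.msr_bms <- function(x, ...) {
  cat("<msr_bms> BOR = ", signif(x$bor, 3), "; pxp: ",
      paste(names(x$pxp), signif(x$pxp, 3), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

exceedance_prob <- function(alpha, n_mc = 1e5, seed = 1L) {
  K <- length(alpha)
  if (K == 2L) {
    # exact: P(r1 > r2) = P(Beta(a1, a2) > 1/2)
    p1 <- stats::pbeta(0.5, alpha[1], alpha[2], lower.tail = FALSE)
    return(c(p1, 1 - p1))
  }
  withr_seed(seed, {
    g <- matrix(stats::rgamma(n_mc * K, shape = rep(alpha, each = n_mc)),
                n_mc, K)
    win <- max.col(g)
    tabulate(win, K) / n_mc
  })
}

#' Pairwise group BMS with Holm-scaled Bayesian omnibus risk
#'
#' @param evidence an [evidence_table()]
#' @param model_a,model_b models to compare
#' @param m_comparisons Holm multiplier applied to the BOR (the number of
#'   pairwise comparisons in the family, times the rank-dependent factor
#'   applied by the caller via [holm_bonferroni()] when several pairs are
#'   tested)
#' @return list with the `msr_bms` of the pair, `bor_raw`, `bor_adjusted`
#' @export
pairwise_bms <- function(evidence, model_a, model_b, m_comparisons = 1L) {
  sub <- dplyr::filter(evidence, .data$model %in% c(model_a, model_b))
  b <- group_bms(sub)
  list(bms = b, bor_raw = b$bor,
       bor_adjusted = min(1, b$bor * m_comparisons))
}
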