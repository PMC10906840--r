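# Adaptive-Metropolis sampler and posterior-draws container. The sampler
# works on an unconstrained parameter vector; model code supplies the log
# posterior (with transform Jacobians) and a back-transform for storage.
# "Divergences" are a Hamiltonian-specific diagnostic and are structurally
# zero for a Metropolis chain; they are reported for interface parity.

# Haario-style adaptive random-walk Metropolis. Adapts a global scale
# (targeting ~0.3 acceptance) and the proposal covariance during warmup,
# then freezes both.
run_adaptive_mh <- function(log_post, init, n_chains = 4L, warmup = 1000L,
                            iter = 1000L, thin = 2L) {
  n_par <- length(init(1L))
  kept <- floor(iter / thin)
  draws <- array(NA_real_, dim = c(kept, n_chains, n_par))
  accept <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    theta <- init(ch)
    lp <- log_post(theta)
    tries <- 0
    while (!is.finite(lp) && tries < 100) {
      theta <- init(ch); lp <- log_post(theta); tries <- tries + 1
    }
    if (!is.finite(lp)) stop("could not find a finite starting point")
    mu <- theta
    cov_acc <- diag(n_par) * 1e-4
    log_s <- log(2.38 / sqrt(n_par))
    L <- chol(cov_acc + diag(1e-8, n_par))
    n_acc <- 0L
    total <- warmup + iter
    k <- 0L
    for (i in seq_len(total)) {
      # mixture kernel: adapted random walk, plus occasional independence
      # jumps on one coordinate so chains can cross between separated modes
      # (the discount factor's marginal can be multimodal)
      if (stats::runif(1) < 0.1) {
        j <- sample.int(n_par, 1L)
        prop <- theta
        prop[j] <- stats::rnorm(1, 0, 2)
        hastings <- stats::dnorm(theta[j], 0, 2, log = TRUE) -
          stats::dnorm(prop[j], 0, 2, log = TRUE)
      } else {
        prop <- theta + exp(log_s) * drop(stats::rnorm(n_par) %*% L)
        hastings <- 0
      }
      lp_prop <- log_post(prop)
      if (is.finite(lp_prop) &&
          log(stats::runif(1)) < lp_prop - lp + hastings) {
        theta <- prop; lp <- lp_prop
        if (i > warmup) n_acc <- n_acc + 1L
        acc <- 1
      } else acc <- 0
      if (i <= warmup) {
        eta <- 1 / (i + 10)^0.6
        if (hastings == 0) log_s <- log_s + eta * (acc - 0.3)
        dm <- theta - mu
        mu <- mu + eta * dm
        cov_acc <- cov_acc + eta * (tcrossprod(dm) - cov_acc)
        if (i %% 25 == 0 || i == warmup)
          L <- chol(cov_acc + diag(1e-8, n_par))
      } else if ((i - warmup) %% thin == 0L) {
        k <- k + 1L
        draws[k, ch, ] <- theta
      }
    }
    accept[ch] <- n_acc / iter
  }
  list(draws = draws, accept_rate = mean(accept))
}

#' Posterior draws container
#'
#' Holds MCMC draws (iterations x chains x parameters) on the constrained
#' scale together with convergence diagnostics and, when available, the
#' pointwise log-likelihood matrix needed for PSIS-LOO.
#'
#' @param draws 3-d array `[iteration, chain, parameter]` with parameter
#'   dimnames
#' @param loglik optional matrix `[total draws, observations]`
#' @param model model label
#' @param accept_rate sampler acceptance rate
#' @param meta free-form metadata list
#' @return an object of class `msr_draws`
#' @export
msr_draws <- function(draws, loglik = NULL, model = "model",
                      accept_rate = NA_real_, meta = list()) {
  stopifnot(length(dim(draws)) == 3L)
  diag_tbl <- tibble::tibble(
    parameter = dimnames(draws)[[3]],
    rhat = apply(draws, 3, split_rhat),
    ess = apply(draws, 3, ess_basic)
  )
  structure(list(draws = draws, loglik = loglik, model = model,
                 diagnostics = diag_tbl, divergences = 0L,
                 accept_rate = accept_rate, meta = meta),
            class = "msr_draws")
}

#' @export
print.msr_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat("<msr_draws> model '", x$model, "': ", d[1], " iterations x ", d[2],
      " chains x ", d[3], " parameters; max split R-hat ",
      round(max(x$diagnostics$rhat), 4), "\n", sep = "")
  invisible(x)
}

#' Flatten the draws of one parameter across chains
#' @param x an `msr_draws`
#' @param parameter parameter name
#' @return numeric vector of draws
#' @export
extract_draws <- function(x, parameter) {
  stopifnot(parameter %in% dimnames(x$draws)[[3]])
  as.vector(x$draws[, , parameter])
}

# split Gelman-Rubin R-hat over an [iter, chain] matrix
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- floor(n / 2)
  sub <- cbind(x[seq_len(h), , drop = FALSE],
               x[(n - h + 1):n, , drop = FALSE])
  m <- ncol(sub)
  if (stats::var(as.vector(sub)) < 1e-300) return(1)
  W <- mean(apply(sub, 2, stats::var))
  B <- h * stats::var(colMeans(sub))
  sqrt(((h - 1) / h * W + B / h) / W)
}

# crude effective sample size from pooled autocorrelation (Geyer truncation)
ess_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (stats::var(as.vector(x)) < 1e-300) return(n * m)
  rho <- rep(0, n - 1)
  for (ch in seq_len(m)) {
    a <- stats::acf(x[, ch], lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
    rho[seq_along(a)] <- rho[seq_along(a)] + a / m
  }
  s <- 0
  for (k in seq_along(rho)) {
    if (rho[k] < 0.05) break
    s <- s + rho[k]
  }
  max(1, n * m / (1 + 2 * s))
}

check_convergence <- function(fit, rhat_max = 1.01) {
  max(fit$diagnostics$rhat, na.rm = TRUE) <= rhat_max
}

#' Highest-density interval of a set of draws
#'
#' Smallest continuous interval containing a fraction `p` of the draws.
#'
#' @param draws numeric vector (at least 1000 draws recommended)
#' @param p probability mass
#' @return named numeric vector `c(lower, upper)`
#' @export
hdi <- function(draws, p = 0.95) {
  x <- sort(draws)
  n <- length(x)
  k <- max(1L, ceiling(p * n))
  widths <- x[k:n] - x[seq_len(n - k + 1)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k - 1])
}

#' Evidence ratio of a posterior in a direction
#'
#' Ratio of posterior mass in the favored direction over the opposite mass;
#' infinite when every draw lies on the favored side. The conventional
#' significance rule is HDI95 excluding 0 together with an evidence ratio
#' above 19.
#'
#' @param draws numeric vector of draws
#' @param direction `"+"` (mass above 0 over mass below) or `"-"`
#' @return scalar, possibly `Inf`
#' @export
evidence_ratio <- function(draws, direction = c("+", "-")) {
  direction <- match.arg(direction)
  pos <- sum(draws > 0); neg <- sum(draws < 0)
  if (direction == "+") {
    if (neg == 0) return(Inf)
    pos / neg
  } else {
    if (pos == 0) return(Inf)
    neg / pos
  }
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param pvalues numeric vector of raw p-values (or Bayesian omnibus
#'   risks)
#' @return adjusted values, monotone in rank and capped at 1
#' @export
holm_bonferroni <- function(pvalues) {
  stats::p.adjust(pvalues, method = "holm")
}
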