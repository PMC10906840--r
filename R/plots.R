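# ggplot2 figures for the main result types

#' Plot the museum layout
#'
#' Rooms positioned by wing with edges drawn; boundary rooms are marked.
#'
#' @param graph an `msr_graph`
#' @return a ggplot
#' @export
plot_museum <- function(graph = build_task_graph()) {
  centers <- 6 * cbind(cos(2 * pi * (0:2) / 3 + pi / 2),
                       sin(2 * pi * (0:2) / 3 + pi / 2))
  within <- 2 * cbind(cos(2 * pi * (0:4) / 5), sin(2 * pi * (0:4) / 5))
  pos <- tibble::tibble(room = 1:15,
                        x = centers[graph$wing, 1] + within[local_pos(1:15), 1],
                        y = centers[graph$wing, 2] + within[local_pos(1:15), 2],
                        wing = factor(graph$wing),
                        boundary = 1:15 %in% graph$boundary)
  seg <- tibble::tibble(x = pos$x[graph$edges[, 1]], y = pos$y[graph$edges[, 1]],
                        xend = pos$x[graph$edges[, 2]], yend = pos$y[graph$edges[, 2]])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg, ggplot2::aes(x = .data$x, y = .data$y,
                                                   xend = .data$xend,
                                                   yend = .data$yend),
                          color = "grey70") +
    ggplot2::geom_point(data = pos, ggplot2::aes(.data$x, .data$y,
                                                 color = .data$wing,
                                                 shape = .data$boundary), size = 5) +
    ggplot2::geom_text(data = pos, ggplot2::aes(.data$x, .data$y,
                                                label = .data$room),
                       nudge_y = 0.45, size = 3) +
    ggplot2::coord_equal() + ggplot2::theme_void() +
    ggplot2::labs(color = "wing", shape = "boundary")
}

#' Posterior densities with HDI bounds
#'
#' @param object an `msr_draws`
#' @param pars parameters to show (default: all, or the `b_*` slopes when
#'   there are many)
#' @param prob HDI mass
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.msr_draws <- function(object, pars = NULL, prob = 0.95, ...) {
  all_pars <- dimnames(object$draws)[[3]]
  if (is.null(pars)) {
    pars <- if (length(all_pars) > 8) grep("^(b_|mu_)", all_pars, value = TRUE)
            else all_pars
    if (!length(pars)) pars <- all_pars
  }
  df <- purrr::map_dfr(pars, function(p)
    tibble::tibble(parameter = p, value = extract_draws(object, p)))
  hdis <- purrr::map_dfr(pars, function(p) {
    h <- hdi(extract_draws(object, p), prob)
    tibble::tibble(parameter = p, lower = h[["lower"]], upper = h[["upper"]])
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$value)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_vline(data = hdis, ggplot2::aes(xintercept = .data$lower),
                        linetype = 2, color = "darkorange") +
    ggplot2::geom_vline(data = hdis, ggplot2::aes(xintercept = .data$upper),
                        linetype = 2, color = "darkorange") +
    ggplot2::geom_vline(xintercept = 0, color = "grey50") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = "posterior density")
}

#' Per-participant posterior model probabilities as stacked bars
#'
#' @param object an `msr_bms`
#' @param ... unused
#' @return a ggplot (participants sorted by the first model's probability)
#' @export
autoplot.msr_bms <- function(object, ...) {
  u <- object$model_prob
  ids <- rownames(u)
  if (is.null(ids)) ids <- sprintf("p%02d", seq_len(nrow(u)))
  df <- tibble::as_tibble(u) |>
    dplyr::mutate(participant = factor(ids, levels = ids[order(u[, 1])])) |>
    tidyr::pivot_longer(-"participant", names_to = "model",
                        values_to = "probability")
  ggplot2::ggplot(df, ggplot2::aes(.data$probability, .data$participant,
                                   fill = .data$model)) +
    ggplot2::geom_col() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "posterior model probability", y = NULL)
}

#' Modularity as a function of the discount factor
#'
#' @param curve output of [modularity_curve()] (optionally several
#'   participants bound together with a `participant` column)
#' @return a ggplot with the modularity = 1 reference line
#' @export
plot_modularity_curve <- function(curve) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(.data$gamma, .data$modularity))
  if ("participant" %in% names(curve))
    p <- p + ggplot2::geom_line(ggplot2::aes(group = .data$participant),
                                alpha = 0.6)
  else p <- p + ggplot2::geom_line()
  p + ggplot2::geom_hline(yintercept = 1, color = "grey50", linetype = 2) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "discount factor", y = "modularity")
}

#' Free-sort distances by pair type
#'
#' @param table a FreesortTable from [pairwise_distances()]
#' @return a ggplot of standardized distances by structural pair label
#' @export
plot_freesort <- function(table) {
  ggplot2::ggplot(table, ggplot2::aes(.data$pair_type, .data$distance)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.25, size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "point", color = "darkorange",
                          size = 3) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = "standardized distance")
}
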