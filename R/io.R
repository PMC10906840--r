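# Flat-file interfaces: session logs as CSV with a JSON sidecar (mapping,
# seeds, ground truth), task serialization to JSON, regressor matrices as
# CSV with a JSON header, posterior draws in long (chain, draw, parameter)
# layout.

#' Serialize the task graph and mapping to JSON
#'
#' @param mapping an `msr_mapping`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_task_json <- function(mapping, path) {
  g <- mapping$graph
  doc <- list(
    rooms = 1:15,
    wings = g$wing,
    edges = unname(apply(g$edges, 1, function(e) as.list(e))),
    boundary = list(ccw = g$boundary[, "ccw"], cw = g$boundary[, "cw"]),
    outcomes = lapply(1:15, function(r) list(
      A1 = mapping$outcomes[r, 1, ], A2 = mapping$outcomes[r, 2, ])),
    key_of = as.list(mapping$key_of),
    rotation_direction = as.list(mapping$rotation_direction)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a task mapping from JSON
#' @param path file written by [write_task_json()]
#' @return an `msr_mapping`
#' @export
read_task_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  graph <- build_task_graph()
  outcomes <- array(NA_integer_, dim = c(15L, 2L, 2L),
                    dimnames = list(NULL, c("A1", "A2"), NULL))
  for (r in 1:15) {
    outcomes[r, 1, ] <- as.integer(doc$outcomes[[r]]$A1)
    outcomes[r, 2, ] <- as.integer(doc$outcomes[[r]]$A2)
  }
  mapping <- structure(list(
    graph = graph, outcomes = outcomes,
    key_of = unlist(doc$key_of),
    rotation_direction = unlist(doc$rotation_direction)
  ), class = "msr_mapping")
  validate_mapping(mapping)
  mapping
}

#' Write a session log to CSV (+ JSON sidecar)
#'
#' The sidecar records the key assignment, seeds and, for synthetic
#' sessions, the generative ground truth, so a session is exactly
#' reproducible and reloadable.
#'
#' @param log a session log
#' @param path CSV path; the sidecar is `<path>.json`
#' @param mapping the session's `msr_mapping` (stored in the sidecar)
#' @return `path`, invisibly
#' @export
write_session_csv <- function(log, path, mapping = NULL) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE)
  truth <- attr(log, "truth")
  side <- list(
    session_seed = attr(log, "session_seed"),
    budget_trace = attr(log, "budget_trace"),
    rest_after = attr(log, "rest_after"),
    truth = if (!is.null(truth)) as.list(truth[, !vapply(truth, is.list, logical(1))]),
    key_of = if (!is.null(mapping)) as.list(mapping$key_of)
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

.session_cols <- c("participant", "phase", "miniblock", "step", "room", "key",
                   "action", "outcome", "goal", "event", "rt")

#' Read a session log written by [write_session_csv()]
#' @param path CSV path
#' @return session-log tibble (sidecar fields restored as attributes when
#'   present)
#' @export
read_session_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  log <- validate_session(df)
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    attr(log, "session_seed") <- side$session_seed
    attr(log, "budget_trace") <- side$budget_trace
    attr(log, "rest_after") <- side$rest_after
  }
  log
}

#' Load externally collected sessions with a column mapping
#'
#' Renames columns of an external CSV to the package schema via
#' `column_map` (names = package columns, values = external columns) and
#' validates the result, reporting offending rows on schema violations.
#'
#' @param path CSV file
#' @param column_map named character vector; identity mapping by default
#' @return validated session-log tibble
#' @export
load_external_sessions <- function(path, column_map = NULL) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!is.null(column_map)) {
    missing <- setdiff(unname(column_map), names(df))
    if (length(missing)) stop("external columns not found: ",
                              paste(missing, collapse = ", "))
    for (nm in names(column_map)) df[[nm]] <- df[[column_map[[nm]]]]
  }
  validate_session(df)
}

validate_session <- function(df) {
  missing <- setdiff(setdiff(.session_cols, c("action", "rt")), names(df))
  if (length(missing)) stop("session log lacks columns: ",
                            paste(missing, collapse = ", "))
  if (!"rt" %in% names(df)) df$rt <- NA_real_
  df$rt <- as.numeric(df$rt)
  bad_room <- which(!(df$room %in% 1:15) | !(df$outcome %in% 1:15))
  if (length(bad_room)) stop("unknown rooms at rows ",
                             paste(utils::head(bad_room, 5), collapse = ", "))
  bad_key <- which(!(df$key %in% c("z", "m", "space")))
  if (length(bad_key)) stop("unknown keys at rows ",
                            paste(utils::head(bad_key, 5), collapse = ", "))
  if (!"action" %in% names(df)) df$action <- NA_character_
  # miniblock chaining: within participant and phase, each start room must
  # equal the previous miniblock's final room
  chain_bad <- df |>
    dplyr::group_by(.data$participant, .data$phase, .data$miniblock) |>
    dplyr::summarise(first_room = dplyr::first(.data$room),
                     last_room = dplyr::last(.data$outcome), .groups = "drop_last") |>
    dplyr::filter(dplyr::row_number() > 1 &
                    .data$first_room != dplyr::lag(.data$last_room)) |>
    dplyr::ungroup()
  if (nrow(chain_bad))
    stop("miniblocks do not chain into a continuous walk (participant ",
         paste(unique(chain_bad$participant), collapse = ", "), ")")
  tibble::as_tibble(df)
}

#' Write a regressor matrix to CSV with a JSON header sidecar
#' @param reg output of [build_regressors()]
#' @param path CSV path
#' @return `path`, invisibly
#' @export
write_regressors_csv <- function(reg, path) {
  utils::write.csv(as.data.frame(reg), path, row.names = FALSE)
  hdr <- list(model = attr(reg, "model"), gamma = attr(reg, "gamma"),
              lambda = attr(reg, "lambda"), variant = attr(reg, "variant"),
              orthogonalized = attr(reg, "orthogonalized"),
              standardized = attr(reg, "standardized"),
              orthogonalization_order = c("ev", "rpe", "conflict"))
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a regressor matrix written by [write_regressors_csv()]
#' @param path CSV path
#' @return tibble with header fields restored as attributes
#' @export
read_regressors_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  for (nm in names(hdr)) attr(df, nm) <- hdr[[nm]]
  df
}

#' Posterior draws in long (chain, draw, parameter) layout
#' @param fit an `msr_draws`
#' @return tibble `chain`, `draw`, `parameter`, `value`
#' @export
draws_long <- function(fit) {
  d <- fit$draws
  dn <- dimnames(d)[[3]]
  out <- tidyr::expand_grid(chain = seq_len(dim(d)[2]),
                            draw = seq_len(dim(d)[1]), parameter = dn)
  out$value <- as.vector(aperm(d, c(3, 1, 2)))
  out
}

#' Write posterior draws to CSV
#' @param fit an `msr_draws`
#' @param path CSV path
#' @return `path`, invisibly
#' @export
write_draws_csv <- function(fit, path) {
  utils::write.csv(as.data.frame(draws_long(fit)), path, row.names = FALSE)
  invisible(path)
}
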