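#' Session table columns
#'
#' Long-format schema for Sharing Game data: one row per trial, 48 rows per
#' participant-wave session (4 dictator blocks of 12 trials).
#' @return Character vector of column names in canonical order.
#' @export
session_columns <- function() {
  c("participant_id", "wave", "drug_group", "gender", "sses",
    "block_position", "dictator_id", "fairness_level", "ethnicity",
    "trial_index", "outcome", "expectation_report", "hi_report",
    "si_report", "question_order")
}

#' Schema configuration for reading session CSVs
#'
#' @param report_scale Maximum of the on-file report scale (1, 10 or 100);
#'   reports are divided by this on read so that they live on \[0,1\]
#'   internally.
#' @param aliases Named character vector mapping canonical column names to
#'   the names used in the file, e.g. `c(participant_id = "subj")`.
#' @return List of class `"cr_schema"`.
#' @export
session_schema <- function(report_scale = 1, aliases = character()) {
  stopifnot(report_scale > 0)
  structure(list(report_scale = report_scale, aliases = aliases),
            class = "cr_schema")
}

report_cols <- function() c("expectation_report", "hi_report", "si_report")

#' Validate a sessions table
#'
#' Checks the structural invariants of the task design: all reports in
#' \[0,1\]; every participant-wave session has exactly 4 blocks, two at each
#' fairness level (0.8 and 0.2); every block has exactly 12 trials indexed
#' 1..12; outcomes in `{fair, unfair}`; ethnicity in `{white, nonwhite}`.
#'
#' @param sessions Sessions tibble (see [session_columns()]).
#' @return The validated tibble, invisibly usable in a pipe.
#' @export
validate_sessions <- function(sessions) {
  sessions <- as_tibble(sessions)
  missing <- setdiff(session_columns(), names(sessions))
  if (length(missing) > 0) {
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "), call. = FALSE)
  }
  for (rc in report_cols()) {
    bad <- which(!is.finite(sessions[[rc]]) | sessions[[rc]] < 0 | sessions[[rc]] > 1)
    if (length(bad) > 0) {
      stop("validation error: ", rc, " outside [0,1] at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  if (!all(sessions$outcome %in% c("fair", "unfair"))) {
    stop("validation error: outcome must be 'fair' or 'unfair'", call. = FALSE)
  }
  if (!all(sessions$ethnicity %in% c("white", "nonwhite"))) {
    bad <- setdiff(unique(sessions$ethnicity), c("white", "nonwhite"))
    stop("validation error: ethnicity label(s) not in {white, nonwhite}: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  chk <- sessions |>
    dplyr::group_by(.data$participant_id, .data$wave, .data$block_position) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      idx_ok = length(.data$trial_index) == 12 &&
        all(sort(.data$trial_index) == 1:12),
      .groups = "drop"
    )
  bad <- dplyr::filter(chk, .data$n_trials != 12 | !.data$idx_ok)
  if (nrow(bad) > 0) {
    stop("structure error: block(s) without exactly 12 trials indexed 1..12: ",
         paste(sprintf("%s/%s block %s (%d trials)", bad$participant_id,
                       bad$wave, bad$block_position, bad$n_trials),
               collapse = "; "), call. = FALSE)
  }
  blk <- sessions |>
    dplyr::distinct(.data$participant_id, .data$wave, .data$block_position,
                    .data$fairness_level) |>
    dplyr::group_by(.data$participant_id, .data$wave) |>
    dplyr::summarise(
      n_blocks = dplyr::n(),
      n_fair = sum(.data$fairness_level == 0.8),
      n_unfair = sum(.data$fairness_level == 0.2),
      .groups = "drop"
    )
  bad <- dplyr::filter(blk, .data$n_blocks != 4 | .data$n_fair != 2 | .data$n_unfair != 2)
  if (nrow(bad) > 0) {
    stop("structure error: session(s) without 4 blocks (2 at 0.8, 2 at 0.2): ",
         paste(sprintf("%s/%s", bad$participant_id, bad$wave), collapse = "; "),
         call. = FALSE)
  }
  sessions
}

#' Read Sharing Game sessions from CSV
#'
#' Reads a long-format trial table, applies column aliases and report
#' rescaling from the schema, and validates the task structure. Row order
#' within a participant-wave block defines trial order.
#'
#' @param path CSV file path.
#' @param schema A [session_schema()].
#' @return Validated sessions tibble.
#' @export
read_sessions <- function(path, schema = session_schema()) {
  stopifnot(file.exists(path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (canon in names(schema$aliases)) {
    alias <- schema$aliases[[canon]]
    if (alias %in% names(df)) names(df)[names(df) == alias] <- canon
  }
  missing <- setdiff(session_columns(), names(df))
  if (length(missing) > 0) {
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[, session_columns()]
  if (schema$report_scale != 1) {
    for (rc in report_cols()) df[[rc]] <- df[[rc]] / schema$report_scale
  }
  df <- dplyr::mutate(df, dplyr::across(
    c("participant_id", "wave", "drug_group", "gender", "dictator_id",
      "ethnicity", "outcome", "question_order"), as.character))
  validate_sessions(df)
}

#' Write sessions to CSV
#'
#' Inverse of [read_sessions()] at `report_scale = 1`: writes one row per
#' trial with the canonical column order, so
#' `read_sessions(write_sessions(x))` round-trips.
#'
#' @param sessions Sessions tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  if (nrow(sessions) > 0) sessions <- validate_sessions(sessions)
  sessions <- as_tibble(sessions)[, session_columns()]
  readr::write_csv(sessions, path, progress = FALSE)
  invisible(path)
}

#' Simulate a dictator's split outcomes
#'
#' Independent Bernoulli draws at the dictator's fairness level: `"fair"`
#' (5:5 split) with probability `fairness_level`, else `"unfair"` (10:0).
#'
#' @param fairness_level Probability of a fair split.
#' @param n_trials Number of trials.
#' @param seed Optional integer seed for reproducibility.
#' @return Character vector of `"fair"`/`"unfair"` outcomes.
#' @examples
#' simulate_environment(0.8, 12, seed = 1)
#' @export
simulate_environment <- function(fairness_level, n_trials, seed = NULL) {
  if (!is.finite(fairness_level) || fairness_level < 0 || fairness_level > 1) {
    stop("fairness_level must be a probability in [0,1]", call. = FALSE)
  }
  stopifnot(n_trials >= 1)
  draw <- function() rbinom(n_trials, 1, fairness_level)
  x <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  ifelse(x == 1, "fair", "unfair")
}

# split a sessions table into per-session tibbles (participant x wave)
session_split <- function(sessions) {
  sessions |>
    dplyr::group_by(.data$participant_id, .data$wave) |>
    dplyr::group_split()
}

# Compact numeric view of one session for the likelihood engines:
# matrices are blocks x trials; outcomes coded 1 = fair; reports as nearest
# bin index (1-based) on the report scale.
compile_session <- function(session, scale = report_scale()) {
  blocks <- sort(unique(session$block_position))
  nb <- length(blocks)
  nt <- max(session$trial_index)
  out <- matrix(NA_integer_, nb, nt)
  eb <- hb <- sb <- matrix(NA_integer_, nb, nt)
  nonwhite <- integer(nb)
  fairness <- numeric(nb)
  for (i in seq_along(blocks)) {
    bi <- session[session$block_position == blocks[i], ]
    bi <- bi[order(bi$trial_index), ]
    out[i, ] <- as.integer(bi$outcome == "fair")
    eb[i, ] <- snap_to_bin(bi$expectation_report, scale)
    hb[i, ] <- snap_to_bin(bi$hi_report, scale)
    sb[i, ] <- snap_to_bin(bi$si_report, scale)
    nonwhite[i] <- as.integer(bi$ethnicity[1] == "nonwhite")
    fairness[i] <- bi$fairness_level[1]
  }
  list(outcomes = out, exp_bin = eb, hi_bin = hb, si_bin = sb,
       nonwhite = nonwhite, fairness = fairness, n_trials = nb * nt)
}
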