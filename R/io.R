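event_table_columns <- function() {
  c("cell_id", "time_days", "replicate", "condition", "viability",
    marker_names())
}

#' Read and validate a flow-cytometry-style event table
#'
#' Event tables are CSV files with one row per assayed cell and the fixed
#' column schema `cell_id, time_days, replicate, condition, viability` plus
#' the seven 0/1 marker columns. Validation names the offending column and
#' row on failure.
#'
#' @param path Path to a CSV file.
#' @return A validated event-table tibble.
#' @export
read_event_table <- function(path) {
  ev <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(event_table_columns(), names(ev))
  if (length(missing) > 0) {
    rlang::abort(paste0("event table is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (any(ev$time_days < 0)) {
    rlang::abort(sprintf("negative time_days at row %d",
                         which(ev$time_days < 0)[1]))
  }
  if (!all(ev$viability %in% c("alive", "dead"))) {
    rlang::abort("viability must be 'alive' or 'dead'")
  }
  for (m in marker_names()) {
    ev[[m]] <- as.integer(ev[[m]])
  }
  check_marker_columns(ev)
  tibble::as_tibble(ev)
}

#' Write an event table to CSV
#'
#' @param events An event-table tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  missing <- setdiff(event_table_columns(), names(events))
  if (length(missing) > 0) {
    rlang::abort(paste0("event table is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  readr::write_csv(events[event_table_columns()], path)
  invisible(path)
}

#' Read per-day differentiated counts
#'
#' @param path CSV with columns `time_days`, `n_assayed`, `n_differentiated`
#'   (and optionally `replicate`).
#' @return A tibble of daily counts.
#' @export
read_daily_counts <- function(path) {
  counts <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("time_days", "n_assayed", "n_differentiated")
  missing <- setdiff(req, names(counts))
  if (length(missing) > 0) {
    rlang::abort(paste0("counts table is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (any(counts$n_differentiated > counts$n_assayed)) {
    rlang::abort("n_differentiated exceeds n_assayed")
  }
  tibble::as_tibble(counts)
}
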