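#' Marker panel and fate levels
#'
#' The seven-marker panel used to call germ-layer fates in differentiating
#' embryoid bodies: Nanog (pluripotency), Foxa2 and Noggin (mesendoderm),
#' Hex (endoderm), Tbx6 (mesoderm), Ap-2alpha (ectoderm) and Sox3
#' (neuroectoderm). Event tables carry one 0/1 column per marker.
#'
#' @return `marker_names()` returns the seven marker column names in panel
#'   order; `fate_levels()` returns the fate categories in display order.
#' @export
marker_names <- function() {
  c("nanog", "foxa2", "hex", "noggin", "tbx6", "ap2a", "sox3")
}

#' @rdname marker_names
#' @export
fate_levels <- function() {
  c("undifferentiated", "mesendoderm", "endoderm", "mesoderm",
    "ectoderm", "neuroectoderm", "unclassified")
}

# Canonical differentiated marker patterns (Nanog negative in every row).
# One row per published pattern; the first pattern listed for each fate is
# the canonical expression state used by the simulator.
fate_patterns <- function() {
  tibble::tribble(
    ~fate,            ~foxa2, ~hex, ~noggin, ~tbx6, ~ap2a, ~sox3,
    "mesendoderm",    1L,     0L,   1L,      0L,    0L,    0L,
    "mesendoderm",    1L,     0L,   0L,      0L,    0L,    0L,
    "mesendoderm",    0L,     0L,   1L,      0L,    0L,    0L,
    "endoderm",       1L,     1L,   0L,      0L,    0L,    0L,
    "endoderm",       0L,     1L,   0L,      0L,    0L,    0L,
    "mesoderm",       0L,     0L,   1L,      1L,    0L,    0L,
    "mesoderm",       0L,     0L,   0L,      1L,    0L,    0L,
    "ectoderm",       0L,     0L,   0L,      0L,    1L,    1L,
    "neuroectoderm",  0L,     0L,   0L,      0L,    0L,    1L
  )
}

check_marker_columns <- function(data, call = rlang::caller_env()) {
  missing <- setdiff(marker_names(), names(data))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("missing marker column(s): ", paste(missing, collapse = ", ")),
      call = call
    )
  }
  for (m in marker_names()) {
    v <- data[[m]]
    if (!all(v %in% c(0, 1))) {
      bad <- which(!(v %in% c(0, 1)))[1]
      rlang::abort(
        sprintf("marker column '%s' must be 0/1; offending row %d", m, bad),
        call = call
      )
    }
  }
  invisible(data)
}

#' Classify differentiation status from marker calls
#'
#' A cell is undifferentiated while Nanog is expressed and differentiated once
#' Nanog is lost; the Foxa2/Noggin/Ap-2alpha antibody cocktail may be positive
#' or negative in either state, so the call rests on Nanog alone.
#'
#' @param data A data frame with 0/1 marker columns `nanog`, `foxa2`, `hex`,
#'   `noggin`, `tbx6`, `ap2a`, `sox3` (extra columns are preserved).
#' @return The input as a tibble with a `diff_status` column
#'   (`"undifferentiated"` or `"differentiated"`).
#' @examples
#' profiles <- tibble::tibble(
#'   nanog = c(1, 0), foxa2 = c(0, 1), hex = 0, noggin = c(0, 1),
#'   tbx6 = 0, ap2a = c(0, 1), sox3 = 0
#' )
#' classify_differentiation(profiles)
#' @export
classify_differentiation <- function(data) {
  check_marker_columns(data)
  out <- tibble::as_tibble(data)
  out$diff_status <- ifelse(out$nanog == 1, "undifferentiated", "differentiated")
  out
}

#' Classify germ-layer fate from marker calls
#'
#' Maps each cell's binary marker profile to a fate. Nanog positivity takes
#' absolute precedence: any Nanog+ cell is undifferentiated regardless of the
#' other six markers. Nanog- cells are matched exactly against the nine
#' published differentiated patterns (mesendoderm, endoderm, mesoderm,
#' ectoderm, neuroectoderm); a Nanog- profile matching none of them is
#' `"unclassified"`. The mapping is total: every one of the 128 possible
#' profiles receives exactly one category.
#'
#' @inheritParams classify_differentiation
#' @return The input as a tibble with a `fate` column (a factor with levels
#'   [fate_levels()]).
#' @examples
#' # the canonical endoderm pattern Foxa2+ Hex+
#' classify_fate(tibble::tibble(
#'   nanog = 0, foxa2 = 1, hex = 1, noggin = 0, tbx6 = 0, ap2a = 0, sox3 = 0
#' ))
#' @export
classify_fate <- function(data) {
  check_marker_columns(data)
  out <- tibble::as_tibble(data)
  pat <- fate_patterns()
  non_nanog <- setdiff(marker_names(), "nanog")
  pattern_key <- apply(as.matrix(pat[non_nanog]), 1, paste, collapse = "")
  key <- do.call(paste0, lapply(out[non_nanog], as.integer))
  fate <- pat$fate[match(key, pattern_key)]
  fate[is.na(fate)] <- "unclassified"
  fate[out$nanog == 1] <- "undifferentiated"
  out$fate <- factor(fate, levels = fate_levels())
  out
}

#' Enumerate the fate partition of all 128 marker profiles
#'
#' Exhaustively classifies every combination of the seven binary markers and
#' tabulates how many profiles fall in each fate category. Useful as a QA
#' surface for the classifier: the counts always sum to 128.
#'
#' @return A tibble with columns `fate` and `n`, one row per fate category.
#' @export
enumerate_fate_partition <- function() {
  grid <- do.call(
    tidyr::expand_grid,
    stats::setNames(rep(list(0:1), 7), marker_names())
  )
  classify_fate(grid) |>
    dplyr::count(.data$fate, .drop = FALSE)
}
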