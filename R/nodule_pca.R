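#' Likelihood ratio of a nodule feature
#'
#' The likelihood ratio (LR) of a radiologic or clinical feature is the count
#' of malignant nodules showing the feature divided by the count of benign
#' nodules showing it. An LR of 1.0 carries no information (a 50% chance of
#' malignancy on its own); LRs below 1 favour benignity, above 1 malignancy.
#'
#' @param n_malignant,n_benign Non-negative counts of malignant/benign
#'   nodules with the feature.
#' @param name Optional feature name.
#' @param smooth If `TRUE`, adds 0.5 to both counts (continuity correction)
#'   so a zero benign count does not error.
#' @return A tibble with columns `name` and `lr`.
#' @examples
#' likelihood_ratio(30, 20)   # LR 1.5
#' @export
likelihood_ratio <- function(n_malignant, n_benign, name = NA_character_,
                             smooth = FALSE) {
  if (n_malignant < 0 || n_benign < 0) {
    rlang::abort("counts must be non-negative")
  }
  if (smooth) {
    n_malignant <- n_malignant + 0.5
    n_benign <- n_benign + 0.5
  }
  if (n_benign == 0) {
    rlang::abort("no benign nodules with the feature; use smooth = TRUE")
  }
  tibble::tibble(name = name, lr = n_malignant / n_benign)
}

#' Probability of malignancy from feature likelihood ratios
#'
#' Combines feature LRs multiplicatively into the odds of malignancy,
#' `odds = prod(LRs)`, converts to the probability `pCa = odds / (1 + odds)`,
#' and applies the cost-effectiveness management rule: observation when pCa
#' is at most `observation_max` (default 0.05), resection when pCa is at
#' least `resection_min` (default 0.60), biopsy in between.
#'
#' @param lrs Likelihood ratios: a numeric vector, or a data frame with an
#'   `lr` column (e.g. rows from [likelihood_ratio()]).
#' @param observation_max,resection_min Decision thresholds on pCa.
#' @return A one-row tibble with `odds`, `pca` and `decision`.
#' @examples
#' nodule_pca(c(1.0))                 # pCa 0.5 -> biopsy
#' nodule_pca(c(0.2, 0.3, 0.5))       # low odds -> observation
#' @export
nodule_pca <- function(lrs, observation_max = 0.05, resection_min = 0.60) {
  if (is.data.frame(lrs)) lrs <- lrs$lr
  if (length(lrs) == 0) rlang::abort("at least one likelihood ratio is required")
  if (any(!is.finite(lrs)) || any(lrs < 0)) {
    rlang::abort("likelihood ratios must be finite and non-negative")
  }
  odds <- prod(lrs)
  pca <- odds / (1 + odds)
  decision <- if (pca <= observation_max) {
    "observation"
  } else if (pca >= resection_min) {
    "resection"
  } else {
    "biopsy"
  }
  tibble::tibble(odds = odds, pca = pca, decision = decision)
}
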