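#' Within-group z-scores
#'
#' Standardizes a per-fish metric within each sex-by-strain group:
#' `z = (value - group mean) / group sample SD` (n-1 denominator). Groups
#' must have at least 2 fish and non-zero variance.
#'
#' @param values Numeric vector, one value per fish.
#' @param groups Data frame (or factor) aligned with `values`; columns
#'   `sex` and `strain` define the groups when a data frame is given.
#' @return Numeric vector of z-scores, same order as the input.
#' @export
zscore_within_groups <- function(values, groups) {
  key <- group_key(groups, length(values))
  if (anyNA(values)) stop("values contain NA", call. = FALSE)
  out <- numeric(length(values))
  for (g in unique(key)) {
    idx <- key == g
    if (sum(idx) < 2)
      stop(sprintf("group '%s' has fewer than 2 fish", g), call. = FALSE)
    s <- sd(values[idx])
    if (s == 0)
      stop(sprintf("group '%s' has zero variance", g), call. = FALSE)
    out[idx] <- (values[idx] - mean(values[idx])) / s
  }
  out
}

group_key <- function(groups, n) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("sex", "strain") %in% names(groups)))
    if (any(!nzchar(groups$sex)) || any(!nzchar(groups$strain)))
      stop("group labels must be non-empty", call. = FALSE)
    key <- paste(groups$sex, groups$strain, sep = ":")
  } else {
    key <- as.character(groups)
  }
  if (length(key) != n)
    stop("groups and values lengths differ", call. = FALSE)
  key
}

#' Composite boldness index
#'
#' The boldness index of a fish is the sum of its within-group z-scores
#' for percent of tank explored and bottom distance — the two novel-tank
#' measures that best separate bold from shy fish. Z-scores are computed
#' within each sex-by-strain group, so the index has mean 0 in every
#' group. (Summing rather than averaging the two z-scores only rescales
#' the index by 2; every rank-based or correlation analysis downstream is
#' unaffected.)
#'
#' @param profiles Data frame with columns `fish_id, percent_explored,
#'   bottom_distance` (e.g. from [behavior_metrics_table()]).
#' @param groups Data frame aligned with `profiles` holding `sex` and
#'   `strain`.
#' @return Data frame `fish_id, z_percent_explored, z_bottom_distance,
#'   boldness_index`.
#' @export
boldness_index <- function(profiles, groups) {
  stopifnot(all(c("fish_id", "percent_explored", "bottom_distance") %in%
                  names(profiles)))
  z_exp <- zscore_within_groups(profiles$percent_explored, groups)
  z_bot <- zscore_within_groups(profiles$bottom_distance, groups)
  data.frame(
    fish_id = profiles$fish_id,
    z_percent_explored = z_exp,
    z_bottom_distance = z_bot,
    boldness_index = z_exp + z_bot,
    stringsAsFactors = FALSE
  )
}
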