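#' Blank-corrected oxygen consumption
#'
#' A closed-chamber session records dissolved O2 (mg/l) at trial start
#' (t1) and end (t2) in the fish tank and in a parallel fish-free blank
#' tank. Consumption is the fish-tank drop minus the blank-tank drop:
#'
#'   \[O2\]_consumed = (\[O2\]_f,t1 - \[O2\]_f,t2) -
#'                     (\[O2\]_b,t1 - \[O2\]_b,t2)
#'
#' so drift common to both tanks (degassing, temperature) cancels
#' identically.
#'
#' @param record A data frame with columns `o2_fish_t1, o2_fish_t2,
#'   o2_blank_t1, o2_blank_t2` (mg/l), e.g. from
#'   [simulate_respirometry()]; multiple rows allowed.
#' @return Numeric vector of consumption values, mg O2/l per trial. May be
#'   negative for bad records; see [compute_rmr()] for the QC rule.
#' @examples
#' compute_o2_consumed(data.frame(
#'   o2_fish_t1 = 8.0, o2_fish_t2 = 6.5,
#'   o2_blank_t1 = 8.0, o2_blank_t2 = 7.9))  # 1.4
#' @export
compute_o2_consumed <- function(record) {
  need <- c("o2_fish_t1", "o2_fish_t2", "o2_blank_t1", "o2_blank_t2")
  miss <- setdiff(need, names(record))
  if (length(miss))
    stop(sprintf("record is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  (record$o2_fish_t1 - record$o2_fish_t2) -
    (record$o2_blank_t1 - record$o2_blank_t2)
}

#' Routine metabolic rate with QC
#'
#' Mass-normalizes blank-corrected consumption: `rmr = o2_consumed /
#' mass_g`, in mg O2/l per g of fish per trial (no per-hour rescaling; the
#' trial duration is carried alongside so callers can rescale). QC fails a
#' record when consumption is <= 0 (a live fish must consume oxygen over a
#' 30-min trial; negative values indicate data-entry or meter error) or
#' when the record was flagged invalid upstream, or when a required
#' reading is missing (no imputation — the blank correction is the core of
#' the method).
#'
#' @param record Data frame of respirometry records with the four O2
#'   columns plus `fish_id, session_day, duration_min, mass_g` and
#'   optionally `valid` (upstream flag) and `feed_state`.
#' @return Data frame with one row per input record: `fish_id,
#'   session_day, o2_consumed, rmr, qc_pass, qc_reason` (plus `feed_state`
#'   when present). `rmr` is NA when QC fails.
#' @examples
#' rec <- data.frame(fish_id = "f1", session_day = 1,
#'   o2_fish_t1 = 8.0, o2_fish_t2 = 6.5, o2_blank_t1 = 8.0,
#'   o2_blank_t2 = 7.9, duration_min = 30, mass_g = 0.7)
#' compute_rmr(rec)  # rmr = 2.0
#' @export
compute_rmr <- function(record) {
  if (!all(c("mass_g", "fish_id", "session_day") %in% names(record)))
    stop("record needs fish_id, session_day and mass_g columns",
         call. = FALSE)
  if (any(!is.na(record$mass_g) & record$mass_g <= 0))
    stop("mass_g must be > 0", call. = FALSE)
  o2_cols <- c("o2_fish_t1", "o2_fish_t2", "o2_blank_t1", "o2_blank_t2")
  missing_reading <- !complete.cases(record[, o2_cols])
  consumed <- rep(NA_real_, nrow(record))
  consumed[!missing_reading] <-
    compute_o2_consumed(record[!missing_reading, , drop = FALSE])
  upstream_invalid <- if ("valid" %in% names(record))
    !is.na(record$valid) & !record$valid else rep(FALSE, nrow(record))

  qc_reason <- rep("", nrow(record))
  qc_reason[missing_reading] <- "missing reading"
  qc_reason[!missing_reading & upstream_invalid] <- "flagged invalid"
  nonpos <- !missing_reading & !upstream_invalid & consumed <= 0
  qc_reason[nonpos] <- ifelse(consumed[nonpos] < 0,
                              "negative consumption", "zero consumption")
  qc_pass <- qc_reason == ""

  out <- data.frame(
    fish_id = record$fish_id, session_day = record$session_day,
    o2_consumed = consumed,
    rmr = ifelse(qc_pass, consumed / record$mass_g, NA_real_),
    qc_pass = qc_pass, qc_reason = qc_reason,
    stringsAsFactors = FALSE
  )
  if ("feed_state" %in% names(record)) out$feed_state <- record$feed_state
  if ("mass_g" %in% names(record)) out$mass_g <- record$mass_g
  if ("duration_min" %in% names(record))
    out$duration_min <- record$duration_min
  out
}

#' Pair two-day respirometry results for repeatability analysis
#'
#' @param results A data frame from [compute_rmr()] covering session days
#'   1 and 2; at most one result per (fish, day).
#' @param value Column to pair, `"o2_consumed"` (default) or `"rmr"`.
#' @param qc_only Keep only QC-passing results before pairing.
#' @return A data frame `fish_id, day1, day2`, ordered by `fish_id`, with
#'   attribute `"dropped"` listing fish lacking either day.
#' @export
pair_sessions <- function(results, value = "o2_consumed", qc_only = TRUE) {
  stopifnot(value %in% names(results))
  if (anyDuplicated(results[, c("fish_id", "session_day")]))
    stop("duplicate (fish_id, session_day) in results", call. = FALSE)
  if (qc_only && "qc_pass" %in% names(results))
    results <- results[results$qc_pass, , drop = FALSE]
  d1 <- results[results$session_day == 1, c("fish_id", value)]
  d2 <- results[results$session_day == 2, c("fish_id", value)]
  names(d1)[2] <- "day1"; names(d2)[2] <- "day2"
  paired <- merge(d1, d2, by = "fish_id")
  paired <- paired[order(paired$fish_id), , drop = FALSE]
  rownames(paired) <- NULL
  all_ids <- unique(results$fish_id)
  attr(paired, "dropped") <- sort(setdiff(all_ids, paired$fish_id))
  paired
}
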