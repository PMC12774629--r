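.record_cols <- c("participant_id", "group", "site", "wave", "respondent",
                  "instrument", "score", "sessions_attended")

#' Read participant-level longitudinal records
#'
#' Long-format CSV: one row per participant x wave x respondent x instrument.
#' The header is validated strictly against
#' `participant_id, group, site, wave, respondent, instrument, score,
#' sessions_attended`. Empty scores are read as `NA` ("not reported").
#'
#' @param path CSV file path.
#' @return a data frame of participant records.
#' @export
read_participant_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), .record_cols)) {
    stop(sprintf("bad participant-record header:\n  expected: %s\n  found:    %s",
                 paste(.record_cols, collapse = ","),
                 paste(names(df), collapse = ",")), call. = FALSE)
  }
  df$score <- as.numeric(df$score)
  df$sessions_attended <- as.numeric(df$sessions_attended)
  df
}

#' Write participant records as CSV
#'
#' Canonical column order, `NA` scores written as empty fields. Output is
#' byte-deterministic for identical input.
#'
#' @param records participant-record data frame.
#' @param path output CSV path.
#' @export
write_participant_records <- function(records, path) {
  stopifnot(all(.record_cols %in% names(records)))
  utils::write.csv(records[, .record_cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Classify change between baseline and follow-up
#'
#' Deterministic classification of a (baseline, follow-up) score pair under
#' an indicator's direction and rule:
#'
#' * `strict_improvement` / `maintain_or_increase`: `improved` when the
#'   follow-up is strictly better than baseline (direction-aware),
#'   `maintained` when equal (ties are conservative: they never count as
#'   improvement), `declined` otherwise.
#' * `endorsed_at_followup`: classified from the follow-up alone —
#'   `improved` when endorsed (score > 0), else `maintained`; the baseline is
#'   ignored and may be `NA`.
#'
#' A missing required score yields `NA` ("not assessable"; the participant is
#' excluded from the outcome's denominator).
#'
#' @param baseline,followup numeric score vectors (recycled to a common
#'   length).
#' @param indicator a one-row [indicator()] data frame.
#' @return character vector: `"improved"`, `"maintained"`, `"declined"` or
#'   `NA`.
#' @examples
#' ind <- indicator("x", "score", "higher_is_better", "strict_improvement")
#' classify_change(80, 86, ind)  # "improved"
#' @export
classify_change <- function(baseline, followup, indicator) {
  stopifnot(is.data.frame(indicator), nrow(indicator) == 1L)
  n <- max(length(baseline), length(followup))
  baseline <- rep_len(as.numeric(baseline), n)
  followup <- rep_len(as.numeric(followup), n)
  in_range <- function(x) {
    is.na(x) | (x >= indicator$score_min & x <= indicator$score_max)
  }
  if (!all(in_range(baseline)) || !all(in_range(followup))) {
    stop(sprintf("score outside the declared range [%g, %g] of instrument '%s'",
                 indicator$score_min, indicator$score_max,
                 indicator$instrument), call. = FALSE)
  }
  if (indicator$rule == "endorsed_at_followup") {
    out <- ifelse(is.na(followup), NA_character_,
                  ifelse(followup > 0, "improved", "maintained"))
    return(out)
  }
  delta <- followup - baseline
  if (indicator$direction == "lower_is_better") delta <- -delta
  ifelse(is.na(delta), NA_character_,
         ifelse(delta > 0, "improved",
                ifelse(delta == 0, "maintained", "declined")))
}

#' Score classifications that qualify as the outcome occurring
#'
#' @param indicator a one-row [indicator()] data frame.
#' @return character vector of qualifying classifications.
#' @export
qualifying_set <- function(indicator) {
  switch(indicator$rule,
    strict_improvement = "improved",
    maintain_or_increase = c("improved", "maintained"),
    endorsed_at_followup = "improved",
    stop(sprintf("unknown rule '%s'", indicator$rule), call. = FALSE)
  )
}

#' Choose between self- and proxy-reported records
#'
#' For the records of one participant at one wave, returns the self-reported
#' rows when any self row carries a reported (non-missing) score; otherwise
#' the proxy rows (informant answering on the participant's behalf), tallied
#' as a substitution; otherwise an empty selection. The choice is idempotent
#' and independent of row order.
#'
#' @param records data frame of records for one participant/wave.
#' @return the chosen rows, with attribute `substituted` (`TRUE` when the
#'   proxy response was used).
#' @export
resolve_respondent <- function(records) {
  stopifnot(is.data.frame(records))
  reported <- records[!is.na(records$score), , drop = FALSE]
  self <- reported[reported$respondent == "self", , drop = FALSE]
  if (nrow(self)) return(structure(self, substituted = FALSE))
  proxy <- reported[reported$respondent == "proxy", , drop = FALSE]
  structure(proxy, substituted = nrow(proxy) > 0)
}

# reported score per participant for one wave x instrument, self preferred;
# returns data.frame(participant_id, score, substituted)
.wave_scores <- function(records, instrument, wave) {
  w <- records[records$instrument == instrument & records$wave == wave &
                 !is.na(records$score), , drop = FALSE]
  if (!nrow(w)) {
    return(data.frame(participant_id = character(0), score = numeric(0),
                      substituted = logical(0), stringsAsFactors = FALSE))
  }
  w <- w[order(w$participant_id, match(w$respondent, c("self", "proxy"))), ,
         drop = FALSE]
  keep <- !duplicated(w$participant_id)
  data.frame(participant_id = w$participant_id[keep], score = w$score[keep],
             substituted = w$respondent[keep] == "proxy",
             stringsAsFactors = FALSE)
}

#' Count an outcome's quantity from participant records
#'
#' Evidences one impact-map outcome: resolves self-vs-proxy respondents per
#' wave, classifies each participant's change under the outcome's indicator,
#' and counts. The denominator is the number of participants assessable for
#' this outcome (complete-case per outcome: a reported score pair, or a
#' reported follow-up for endorsement indicators); the numerator is those
#' whose classification falls in the indicator's qualifying set.
#'
#' @param records participant-record data frame.
#' @param outcome a one-row outcome data frame.
#' @param indicator the one-row indicator referenced by the outcome.
#' @param group optional participant group to restrict to (e.g. `"pwd"`);
#'   `NULL` uses all records (caller pre-filtered).
#' @return an `outcome_count`: list with `outcome_id`, `numerator`,
#'   `denominator`, `proportion`, `percent` (half-up to 1 decimal) and
#'   `n_proxy_substituted` (participants whose counted scores used a proxy
#'   response).
#' @export
count_outcome <- function(records, outcome, indicator, group = NULL) {
  stopifnot(is.data.frame(records), nrow(outcome) == 1L, nrow(indicator) == 1L)
  if (!identical(outcome$indicator_id, indicator$id)) {
    stop(sprintf("outcome '%s' references indicator '%s', not '%s'",
                 outcome$id, outcome$indicator_id, indicator$id), call. = FALSE)
  }
  if (!is.null(group)) {
    records <- records[records$group %in% group, , drop = FALSE]
  }
  fup <- .wave_scores(records, indicator$instrument, indicator$followup_time)
  if (indicator$rule == "endorsed_at_followup") {
    assess <- fup
    cls <- classify_change(NA_real_, assess$score, indicator)
    substituted <- assess$substituted
  } else {
    base <- .wave_scores(records, indicator$instrument, indicator$baseline_time)
    ids <- intersect(base$participant_id, fup$participant_id)
    b <- base$score[match(ids, base$participant_id)]
    f <- fup$score[match(ids, fup$participant_id)]
    cls <- classify_change(b, f, indicator)
    substituted <- base$substituted[match(ids, base$participant_id)] |
      fup$substituted[match(ids, fup$participant_id)]
  }
  denominator <- length(cls)
  if (denominator == 0L) {
    stop(sprintf("no assessable participants for outcome '%s'", outcome$id),
         call. = FALSE)
  }
  numerator <- sum(cls %in% qualifying_set(indicator))
  structure(list(
    outcome_id = outcome$id,
    numerator = numerator,
    denominator = denominator,
    proportion = numerator / denominator,
    percent = round_half_up(100 * numerator / denominator, 1),
    n_proxy_substituted = sum(substituted)
  ), class = "outcome_count")
}

#' @export
print.outcome_count <- function(x, ...) {
  cat(sprintf("<outcome_count> %s: %d/%d (%.1f%%), %d proxy-substituted\n",
              x$outcome_id, x$numerator, x$denominator, x$percent,
              x$n_proxy_substituted))
  invisible(x)
}

#' Evidence every outcome of an impact map from participant records
#'
#' Runs [count_outcome()] for each outcome and writes the counted numerator
#' and denominator back into the map's `quantity`/`denominator` columns.
#' Outcomes that cannot be counted (e.g. no assessable participants) keep
#' their fixture quantities; per-outcome status is recorded in the returned
#' map's `"evidence"` attribute (a data frame with outcome_id, source =
#' counted/fixture, numerator, denominator, proportion, percent,
#' n_proxy_substituted, error).
#'
#' @param records participant-record data frame.
#' @param map an `impact_map` whose stakeholders carry `group` labels.
#' @return the map with counted quantities, and attribute `"evidence"`.
#' @export
evidence_all <- function(records, map) {
  stopifnot(is.data.frame(records), inherits(map, "impact_map"))
  ev <- vector("list", nrow(map$outcomes))
  for (i in seq_len(nrow(map$outcomes))) {
    out <- map$outcomes[i, , drop = FALSE]
    ind <- map$indicators[map$indicators$id == out$indicator_id, , drop = FALSE]
    if (nrow(ind) != 1L) {
      stop(sprintf("outcome '%s': indicator '%s' is not registered",
                   out$id, out$indicator_id), call. = FALSE)
    }
    grp <- map$stakeholders$group[match(out$stakeholder_id, map$stakeholders$id)]
    cnt <- tryCatch(
      count_outcome(records, out, ind, group = if (!is.na(grp)) grp),
      error = function(e) e
    )
    if (inherits(cnt, "error")) {
      ev[[i]] <- data.frame(outcome_id = out$id, source = "fixture",
                            numerator = NA_real_, denominator = NA_real_,
                            proportion = NA_real_, percent = NA_real_,
                            n_proxy_substituted = NA_real_,
                            error = conditionMessage(cnt),
                            stringsAsFactors = FALSE)
    } else {
      map$outcomes$quantity[i] <- cnt$numerator
      map$outcomes$denominator[i] <- cnt$denominator
      ev[[i]] <- data.frame(outcome_id = out$id, source = "counted",
                            numerator = cnt$numerator,
                            denominator = cnt$denominator,
                            proportion = cnt$proportion, percent = cnt$percent,
                            n_proxy_substituted = cnt$n_proxy_substituted,
                            error = "", stringsAsFactors = FALSE)
    }
  }
  map <- validate_impact_map(map)
  attr(map, "evidence") <- if (length(ev)) do.call(rbind, ev) else NULL
  map
}
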