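#' Sensitivity scenarios as declarative impact-map edits
#'
#' A scenario is an ordered list of edit operations applied to a copy of an
#' impact map (the original is never mutated). Available edits:
#'
#' * `edit_zero_time_inputs(stakeholders)` — set the `total_value` of time
#'   input items to zero, for the named stakeholder ids or `"all"`.
#' * `edit_scale_outcomes(stakeholder_id, factor)` — scale the evidenced
#'   quantity of every outcome owned by one stakeholder (e.g. factor 0.5 for
#'   "only 50% of outcomes materialize").
#' * `edit_set_duration(years)` — set `duration_years` on every outcome (and
#'   the map residual, which represents first-year outcome value).
#' * `edit_scale_proxy(code, factor)` — scale one financial proxy's annual
#'   value.
#'
#' @param id token identifying the scenario.
#' @param label human-readable description.
#' @param edits list of edit operations.
#' @param verified logical; `TRUE` when the scenario's reported ratio is
#'   exactly reproducible from the packaged map.
#' @param note optional provenance note.
#' @return a `scenario` object.
#' @export
scenario <- function(id, label = id, edits = list(), verified = NA, note = NULL) {
  stopifnot(is.character(id), length(id) == 1L, is.list(edits))
  structure(list(id = id, label = label, edits = edits,
                 verified = verified, note = note),
            class = "scenario")
}

#' @rdname scenario
#' @param stakeholders character vector of stakeholder ids, or `"all"`.
#' @export
edit_zero_time_inputs <- function(stakeholders = "all") {
  list(op = "zero_time_inputs", stakeholders = stakeholders)
}

#' @rdname scenario
#' @param stakeholder_id a single stakeholder id.
#' @param factor non-negative scaling factor.
#' @export
edit_scale_outcomes <- function(stakeholder_id, factor) {
  stopifnot(factor >= 0)
  list(op = "scale_outcomes", stakeholder_id = stakeholder_id, factor = factor)
}

#' @rdname scenario
#' @param years integer >= 1 applied to all outcomes.
#' @export
edit_set_duration <- function(years) {
  stopifnot(years >= 1, years == as.integer(years))
  list(op = "set_duration", years = years)
}

#' @rdname scenario
#' @param code a financial proxy code.
#' @export
edit_scale_proxy <- function(code, factor) {
  stopifnot(factor >= 0)
  list(op = "scale_proxy", code = code, factor = factor)
}

#' Apply a scenario to an impact map
#'
#' Returns a new map with the scenario's edits applied in declared order; the
#' input map is unchanged (value semantics). Unknown stakeholder or proxy
#' references raise a reference error.
#'
#' @param map an `impact_map`.
#' @param scen a [scenario()].
#' @return a new validated `impact_map`.
#' @export
apply_scenario <- function(map, scen) {
  stopifnot(inherits(map, "impact_map"), inherits(scen, "scenario"))
  ref_error <- function(msg) {
    stop(structure(class = c("sroi_reference_error", "error", "condition"),
                   list(message = msg, call = NULL)))
  }
  for (e in scen$edits) {
    switch(e$op,
      zero_time_inputs = {
        who <- e$stakeholders
        if (!identical(who, "all")) {
          missing <- setdiff(who, map$stakeholders$id)
          if (length(missing)) {
            ref_error(paste("unknown stakeholder(s):", paste(missing, collapse = ", ")))
          }
        }
        hit <- map$inputs$kind == "time" &
          (identical(who, "all") | map$inputs$stakeholder_id %in% who)
        # valuing time at zero per hour: rate and total both drop to 0, so
        # the time-consistency invariant still holds
        map$inputs$total_value[hit] <- 0
        map$inputs$hourly_rate[hit] <- 0
      },
      scale_outcomes = {
        if (!e$stakeholder_id %in% map$stakeholders$id) {
          ref_error(paste("unknown stakeholder:", e$stakeholder_id))
        }
        hit <- map$outcomes$stakeholder_id == e$stakeholder_id
        map$outcomes$quantity[hit] <- map$outcomes$quantity[hit] * e$factor
      },
      set_duration = {
        if (nrow(map$outcomes)) map$outcomes$duration_years <- e$years
        if (!is.null(map$residual)) map$residual$duration_years <- e$years
      },
      scale_proxy = {
        if (!e$code %in% map$proxies$code) {
          ref_error(paste("unknown proxy:", e$code))
        }
        hit <- map$proxies$code == e$code
        map$proxies$annual_value[hit] <- map$proxies$annual_value[hit] * e$factor
      },
      stop(sprintf("unknown edit operation '%s'", e$op), call. = FALSE)
    )
  }
  validate_impact_map(map)
}

#' Compute the SROI ratio of an impact map
#'
#' The social return on investment: total present value of outputs divided by
#' total value of inputs. The full-precision ratio is kept in `ratio`;
#' `ratio_2dp` is the half-up two-decimal display value used in published
#' tables (e.g. 5.1753 prints as 5.18). A map with zero total outputs yields
#' ratio 0; zero total inputs is an error (undefined ratio).
#'
#' @param map an `impact_map`.
#' @param scenario_id label recorded on the result (default `"base"`).
#' @param convention discounting convention, see [present_value()].
#' @return an `sroi_result`: list with `scenario_id`, `total_inputs`,
#'   `total_outputs_pv` (both `money`), `ratio`, `ratio_2dp` and
#'   `per_outcome` (data frame of valued outcomes).
#' @examples
#' res <- sroi_ratio(fixture_dementia_imagination())
#' res$ratio_2dp  # 5.18
#' @export
sroi_ratio <- function(map, scenario_id = "base",
                       convention = c("after_year1", "from_year1")) {
  stopifnot(inherits(map, "impact_map"))
  inputs <- total_inputs(map)
  if (as.numeric(inputs) <= 0) {
    stop("undefined ratio: total inputs must be > 0", call. = FALSE)
  }
  outputs <- total_outputs(map, convention = match.arg(convention))
  ratio <- as.numeric(outputs$total) / as.numeric(inputs)
  structure(list(
    scenario_id = scenario_id,
    total_inputs = inputs,
    total_outputs_pv = outputs$total,
    ratio = ratio,
    ratio_2dp = round_half_up(ratio, 2),
    per_outcome = outputs$per_outcome,
    residual_pv = outputs$residual_pv
  ), class = "sroi_result")
}

#' @export
print.sroi_result <- function(x, ...) {
  cat(sprintf("<sroi_result> scenario '%s'\n", x$scenario_id))
  cat("  inputs:  ", format(x$total_inputs), "\n")
  cat("  outputs: ", format(x$total_outputs_pv), "(present value)\n")
  cat(sprintf("  SROI ratio: %.2f : 1\n", x$ratio_2dp))
  invisible(x)
}

#' Run a suite of sensitivity scenarios
#'
#' Evaluates the base case plus each scenario on its own edited copy of the
#' map. Per-scenario errors are recorded in the result row and the suite
#' continues. The returned table carries a `range` attribute with the
#' min/max ratio over successfully evaluated rows.
#'
#' @param map an `impact_map`.
#' @param scenarios list of [scenario()] objects (possibly empty: base case
#'   only).
#' @param convention discounting convention, see [present_value()].
#' @return a data frame of class `sroi_sensitivity` with one row per scenario
#'   plus the base case: scenario_id, label, total_inputs, total_outputs_pv,
#'   ratio, ratio_2dp, verified, note, error.
#' @export
sensitivity_suite <- function(map, scenarios = list(),
                              convention = c("after_year1", "from_year1")) {
  convention <- match.arg(convention)
  one <- function(id, label, m, verified = TRUE, note = NULL) {
    res <- tryCatch(sroi_ratio(m, id, convention), error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(scenario_id = id, label = label, total_inputs = NA_real_,
                 total_outputs_pv = NA_real_, ratio = NA_real_,
                 ratio_2dp = NA_real_, verified = verified,
                 note = note %||% "", error = conditionMessage(res),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(scenario_id = id, label = label,
                 total_inputs = as.numeric(res$total_inputs),
                 total_outputs_pv = as.numeric(res$total_outputs_pv),
                 ratio = res$ratio, ratio_2dp = res$ratio_2dp,
                 verified = verified, note = note %||% "", error = "",
                 stringsAsFactors = FALSE)
    }
  }
  rows <- list(one("base", "Base case", map))
  for (s in scenarios) {
    m <- tryCatch(apply_scenario(map, s), error = function(e) e)
    rows[[length(rows) + 1L]] <- if (inherits(m, "error")) {
      data.frame(scenario_id = s$id, label = s$label, total_inputs = NA_real_,
                 total_outputs_pv = NA_real_, ratio = NA_real_,
                 ratio_2dp = NA_real_, verified = isTRUE(s$verified),
                 note = s$note %||% "", error = conditionMessage(m),
                 stringsAsFactors = FALSE)
    } else {
      one(s$id, s$label, m, verified = isTRUE(s$verified), note = s$note)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ok <- !is.na(out$ratio)
  attr(out, "range") <- if (any(ok)) range(out$ratio_2dp[ok]) else c(NA_real_, NA_real_)
  class(out) <- c("sroi_sensitivity", "data.frame")
  out
}

#' @export
print.sroi_sensitivity <- function(x, ...) {
  df <- as.data.frame(x)
  df$ratio <- NULL
  print.data.frame(df, row.names = FALSE)
  r <- attr(x, "range")
  if (!any(is.na(r))) {
    cat(sprintf("range of SROI ratios: %.2f to %.2f per 1 invested\n", r[1], r[2]))
  }
  invisible(x)
}
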