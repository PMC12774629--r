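#' Default valuation settings
#'
#' The unit-cost assumptions used to value stakeholder time, and the annual
#' discount rate. Defaults reflect a 2015/16 UK costing year: participant
#' time at the National Minimum Wage (7.20 GBP/h), caregiver time at the
#' average cost of a home care worker (19 GBP/h), 3 h per session for a
#' person with dementia (2 h activity + 1 h travel/preparation), 2 h of
#' organizational tasks per session for a family caregiver, 0.5 h per
#' attendance for staff, and a 3.5%/year discount rate applied to outcomes
#' occurring after year 1.
#'
#' @param discount_rate annual discount rate in \[0, 1).
#' @param time_rate_pwd GBP/hour for participants living with dementia.
#' @param time_rate_caregiver GBP/hour for family and staff caregivers.
#' @param hours_pwd_per_session,hours_family_per_session,hours_staff_per_attendance
#'   time assumptions per session/attendance.
#' @return a list of class `valuation_settings`.
#' @export
valuation_settings <- function(discount_rate = 0.035,
                               time_rate_pwd = 7.20,
                               time_rate_caregiver = 19,
                               hours_pwd_per_session = 3,
                               hours_family_per_session = 2,
                               hours_staff_per_attendance = 0.5) {
  s <- list(
    discount_rate = discount_rate,
    time_rate_pwd = time_rate_pwd,
    time_rate_caregiver = time_rate_caregiver,
    hours_pwd_per_session = hours_pwd_per_session,
    hours_family_per_session = hours_family_per_session,
    hours_staff_per_attendance = hours_staff_per_attendance
  )
  if (any(vapply(s, function(v) !is.numeric(v) || length(v) != 1L || v < 0, logical(1)))) {
    stop("all valuation settings must be single non-negative numbers", call. = FALSE)
  }
  structure(s, class = "valuation_settings")
}

#' Value a time input
#'
#' Values volunteered/participant time as attendances x hours-per-unit x
#' hourly rate, rounded half-up to whole currency units (the convention of
#' published impact maps).
#'
#' @param attendances number of attendances (or persons, for per-person
#'   assumptions); >= 0.
#' @param hours_per_unit hours per attendance; >= 0.
#' @param rate hourly rate in GBP (a number or a [money()] value); >= 0.
#' @return a `money` value in GBP.
#' @examples
#' value_time_input(909, 3, 7.20)  # GBP 19,634
#' @export
value_time_input <- function(attendances, hours_per_unit, rate) {
  rate <- if (inherits(rate, "money")) as.numeric(rate) else rate
  args <- c(attendances = attendances, hours_per_unit = hours_per_unit, rate = rate)
  if (any(!is.finite(args)) || any(args < 0)) {
    stop("attendances, hours_per_unit and rate must all be finite and >= 0",
         call. = FALSE)
  }
  money(round_half_up(attendances * hours_per_unit * rate))
}

#' Total value of inputs
#'
#' Sums `total_value` over every input item whose stakeholder is not
#' excluded. Inputs are not discounted: all are incurred within the delivery
#' window (year 1).
#'
#' @param map an `impact_map`.
#' @return a `money` value in GBP.
#' @export
total_inputs <- function(map) {
  stopifnot(inherits(map, "impact_map"))
  if (nrow(map$inputs) == 0L) return(money(0))
  incl <- map$stakeholders$inclusion[match(map$inputs$stakeholder_id,
                                           map$stakeholders$id)]
  money(sum(map$inputs$total_value[incl != "excluded"]))
}

#' Combined impact-adjustment multiplier of outcome rows
#'
#' For each outcome row, returns the stored combined multiplier when present,
#' otherwise (1 - deadweight) x (1 - displacement) x attribution. The result
#' is the fraction of an outcome's raw value credited to the program.
#'
#' @param outcomes the `outcomes` data frame of an impact map (or one row).
#' @return numeric vector in \[0, 1\].
#' @export
combined_multiplier <- function(outcomes) {
  ifelse(!is.na(outcomes$multiplier), outcomes$multiplier,
         (1 - outcomes$deadweight) * (1 - outcomes$displacement) *
           outcomes$attribution)
}

#' Adjusted (first-year) value of an outcome
#'
#' quantity x annual proxy value x combined impact-adjustment multiplier.
#' Full precision is kept by default; pass `digits = 0` to reproduce the
#' whole-pound display convention.
#'
#' @param outcome a one-row outcome data frame.
#' @param proxy a one-row [financial_proxy()] data frame.
#' @param digits decimal places for half-up rounding, or `NULL` (default) for
#'   full precision.
#' @return a `money` value in GBP.
#' @export
adjusted_value <- function(outcome, proxy, digits = NULL) {
  stopifnot(nrow(outcome) == 1L, nrow(proxy) == 1L)
  if (!identical(outcome$proxy_code, proxy$code)) {
    stop(sprintf("outcome '%s' references proxy '%s', not '%s'",
                 outcome$id, outcome$proxy_code, proxy$code), call. = FALSE)
  }
  v <- outcome$quantity * proxy$annual_value * combined_multiplier(outcome)
  if (!is.null(digits)) v <- round_half_up(v, digits)
  money(v)
}

#' Present value of a recurring outcome
#'
#' Sums a first-year value over the outcome's duration, decaying by
#' `drop_off` per year after year 1 and discounting at `discount_rate`.
#' Under the default convention (`"after_year1"`) year 1 is undiscounted and
#' year t is divided by (1 + r)^(t-1), i.e. the discount applies to value
#' occurring after the first year:
#'
#' PV = sum over t = 1..D of V x (1 - drop_off)^(t-1) / (1 + r)^(t-1).
#'
#' The alternative convention (`"from_year1"`) divides year t by (1 + r)^t.
#' With all durations equal to 1 (the cautious base case for a progressive
#' condition) the two conventions coincide.
#'
#' @param first_year_value value accruing in year 1 (numeric or `money`).
#' @param duration_years integer >= 1.
#' @param drop_off per-year decay after year 1, in \[0, 1\].
#' @param discount_rate annual discount rate in \[0, 1).
#' @param convention discounting convention, see above.
#' @return same type as `first_year_value` (numeric, or `money`).
#' @examples
#' present_value(100, 2, 0, 0.035)  # 196.6184
#' present_value(100, 3, 0.5, 0)    # 175
#' @export
present_value <- function(first_year_value, duration_years, drop_off = 0,
                          discount_rate = 0.035,
                          convention = c("after_year1", "from_year1")) {
  convention <- match.arg(convention)
  stopifnot(length(first_year_value) == 1L, length(duration_years) == 1L,
            length(drop_off) == 1L, length(discount_rate) == 1L)
  if (is.na(duration_years) || duration_years < 1 ||
      duration_years != as.integer(duration_years)) {
    stop("duration_years must be an integer >= 1", call. = FALSE)
  }
  if (drop_off < 0 || drop_off > 1 || discount_rate < 0 || discount_rate >= 1) {
    stop("drop_off must lie in [0, 1] and discount_rate in [0, 1)", call. = FALSE)
  }
  v <- if (inherits(first_year_value, "money")) as.numeric(first_year_value) else first_year_value
  t <- seq_len(duration_years)
  shift <- if (convention == "after_year1") 1 else 0
  pv <- sum(v * (1 - drop_off)^(t - 1) / (1 + discount_rate)^(t - shift))
  if (inherits(first_year_value, "money")) money(pv) else pv
}

#' Value every outcome and total the outputs
#'
#' Computes, for each outcome row: the raw value (quantity x annual proxy
#' value), the adjusted first-year value (raw x combined multiplier) and the
#' present value over the outcome's duration with drop-off and discounting.
#' A map-level residual value, when present, receives the same
#' duration/drop-off treatment and is added to the total.
#'
#' @param map an `impact_map`.
#' @param convention discounting convention, see [present_value()].
#' @return a list of class `valued_outputs` with elements `total` (`money`),
#'   `per_outcome` (data frame of valued outcomes) and `residual_pv`
#'   (`money`, 0 when the map has no residual).
#' @export
total_outputs <- function(map, convention = c("after_year1", "from_year1")) {
  stopifnot(inherits(map, "impact_map"))
  convention <- match.arg(convention)
  out <- map$outcomes
  if (nrow(out) == 0L) {
    per <- data.frame(outcome_id = character(0), stakeholder_id = character(0),
                      description = character(0), quantity = numeric(0),
                      proxy_code = character(0), annual_value = numeric(0),
                      raw_value = numeric(0), multiplier = numeric(0),
                      adjusted_value = numeric(0), present_value = numeric(0),
                      stringsAsFactors = FALSE)
  } else {
    annual <- map$proxies$annual_value[match(out$proxy_code, map$proxies$code)]
    raw <- out$quantity * annual
    mult <- combined_multiplier(out)
    adj <- raw * mult
    pv <- vapply(seq_len(nrow(out)), function(i) {
      as.numeric(present_value(adj[i], out$duration_years[i], out$drop_off[i],
                               map$discount_rate, convention))
    }, numeric(1))
    per <- data.frame(
      outcome_id = out$id, stakeholder_id = out$stakeholder_id,
      description = out$description, quantity = out$quantity,
      proxy_code = out$proxy_code, annual_value = annual,
      raw_value = raw, multiplier = mult, adjusted_value = adj,
      present_value = pv, stringsAsFactors = FALSE
    )
  }
  residual_pv <- 0
  if (!is.null(map$residual)) {
    r <- map$residual
    residual_pv <- as.numeric(present_value(
      r$value, .lget(r, "duration_years", 1), .lget(r, "drop_off", 0),
      map$discount_rate, convention
    ))
  }
  structure(list(
    total = money(sum(per$present_value) + residual_pv),
    per_outcome = per,
    residual_pv = money(residual_pv)
  ), class = "valued_outputs")
}

#' @export
print.valued_outputs <- function(x, ...) {
  cat("<valued_outputs>", nrow(x$per_outcome), "outcomes; total PV",
      format(x$total), "\n")
  invisible(x)
}
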