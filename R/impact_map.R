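#' Impact-map building blocks
#'
#' Constructors for the rows of an SROI impact map. Each returns a one-row
#' data frame so that maps can be assembled with `rbind()` or passed as lists
#' to [impact_map()].
#'
#' @name impact_map_components
NULL

#' @describeIn impact_map_components A stakeholder: a person or organization
#'   materially affected by the activity. `inclusion` is one of `"included"`
#'   (inputs and outcomes counted), `"inputs_only"` (financial input counted,
#'   no material outcomes assumed) or `"excluded"`. `group` optionally names
#'   the participant-record group this stakeholder corresponds to
#'   (`"pwd"`, `"family_caregiver"`, `"staff_caregiver"`).
#' @param id unique token identifying the row.
#' @param label human-readable name.
#' @param inclusion inclusion status, see above.
#' @param rationale why the stakeholder was included or excluded.
#' @param group participant-record group, or `NA`.
#' @export
stakeholder <- function(id, label = id, inclusion = "included",
                        rationale = "", group = NA_character_) {
  data.frame(
    id = as.character(id), label = as.character(label),
    inclusion = as.character(inclusion), rationale = as.character(rationale),
    group = as.character(group), stringsAsFactors = FALSE
  )
}

#' @describeIn impact_map_components An input item: what a stakeholder
#'   invested. `kind` is `"cash"`, `"in_kind"` or `"time"`. For time inputs
#'   the value is hours-per-unit x unit-count x hourly-rate, rounded half-up
#'   to whole currency units; `unit_count` may be `NA` when only the total is
#'   known (the consistency check is then skipped).
#' @param stakeholder_id id of the owning stakeholder.
#' @param kind input kind, see above.
#' @param description free text.
#' @param total_value total value in whole GBP.
#' @param hours_per_unit hours per unit (time inputs only).
#' @param unit_count number of units, e.g. attendances (time inputs only).
#' @param hourly_rate GBP per hour (time inputs only).
#' @export
input_item <- function(stakeholder_id, kind, description, total_value,
                       hours_per_unit = NA_real_, unit_count = NA_real_,
                       hourly_rate = NA_real_) {
  data.frame(
    stakeholder_id = as.character(stakeholder_id), kind = as.character(kind),
    description = as.character(description),
    hours_per_unit = as.numeric(hours_per_unit),
    unit_count = as.numeric(unit_count),
    hourly_rate = as.numeric(hourly_rate),
    total_value = as.numeric(total_value), stringsAsFactors = FALSE
  )
}

#' @describeIn impact_map_components An indicator: how change in an outcome
#'   is measured on a (baseline, follow-up) score pair. `rule` is one of
#'   `"strict_improvement"` (only a beneficial change qualifies),
#'   `"maintain_or_increase"` (no deterioration qualifies) or
#'   `"endorsed_at_followup"` (a single follow-up endorsement qualifies, no
#'   baseline needed). `direction` says which way is beneficial on the score
#'   scale. `score_min`/`score_max` declare the instrument's valid range.
#' @param instrument instrument label, matched against the `instrument`
#'   column of participant records.
#' @param direction `"higher_is_better"` or `"lower_is_better"`.
#' @param rule classification rule, see above.
#' @param baseline_time,followup_time wave labels (e.g. `"T1"`, `"T3"`).
#' @param score_min,score_max declared instrument range.
#' @export
indicator <- function(id, instrument, direction = "higher_is_better",
                      rule = "strict_improvement",
                      baseline_time = "T1", followup_time = "T3",
                      score_min = -Inf, score_max = Inf) {
  data.frame(
    id = as.character(id), instrument = as.character(instrument),
    direction = as.character(direction), rule = as.character(rule),
    baseline_time = as.character(baseline_time),
    followup_time = as.character(followup_time),
    score_min = as.numeric(score_min), score_max = as.numeric(score_max),
    stringsAsFactors = FALSE
  )
}

#' @describeIn impact_map_components A financial proxy: a monetary stand-in
#'   for one person-year of a non-market outcome, e.g. a social-value-bank
#'   unit cost.
#' @param code proxy code token (unique within the map).
#' @param annual_value GBP per person-year, must be > 0.
#' @param source where the value comes from.
#' @export
financial_proxy <- function(code, label, annual_value, source = "") {
  data.frame(
    code = as.character(code), label = as.character(label),
    annual_value = as.numeric(annual_value), source = as.character(source),
    stringsAsFactors = FALSE
  )
}

#' @describeIn impact_map_components An outcome row: a material change for a
#'   stakeholder, with the evidenced quantity (people with material change out
#'   of `denominator` assessed), the proxy used to value it, and impact
#'   adjustments. Adjustments are given either as the three components
#'   (`deadweight`, `displacement`, `attribution`, each in \[0,1\]) or as a
#'   single pre-combined `multiplier` = (1-deadweight) x (1-displacement) x
#'   attribution. `drop_off` is the per-year decay of the effect after year 1.
#' @param indicator_id id of the measuring indicator.
#' @param quantity people with material change.
#' @param denominator people assessed for this outcome.
#' @param duration_years integer >= 1, how long the change lasts.
#' @param proxy_code code of the valuing proxy.
#' @param multiplier combined impact-adjustment multiplier, or `NA` if the
#'   three components are given.
#' @param deadweight,displacement,attribution adjustment components in \[0,1\].
#' @param drop_off per-year decay after year 1, in \[0,1\].
#' @export
outcome <- function(id, stakeholder_id, description, indicator_id,
                    quantity, denominator, proxy_code,
                    duration_years = 1, multiplier = NA_real_,
                    deadweight = NA_real_, displacement = NA_real_,
                    attribution = NA_real_, drop_off = 0) {
  data.frame(
    id = as.character(id), stakeholder_id = as.character(stakeholder_id),
    description = as.character(description),
    indicator_id = as.character(indicator_id),
    quantity = as.numeric(quantity), denominator = as.numeric(denominator),
    duration_years = as.numeric(duration_years),
    proxy_code = as.character(proxy_code),
    multiplier = as.numeric(multiplier),
    deadweight = as.numeric(deadweight),
    displacement = as.numeric(displacement),
    attribution = as.numeric(attribution),
    drop_off = as.numeric(drop_off), stringsAsFactors = FALSE
  )
}

.bind_rows <- function(x, empty) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L) ||
      (is.list(x) && !is.data.frame(x) && length(x) == 0L)) {
    return(empty)
  }
  if (is.data.frame(x)) x else do.call(rbind, x)
}

.zero_df <- function(chr, num) {
  cols <- c(
    stats::setNames(rep(list(character(0)), length(chr)), chr),
    stats::setNames(rep(list(numeric(0)), length(num)), num)
  )
  as.data.frame(cols, stringsAsFactors = FALSE)
}

.empty <- list(
  stakeholders = .zero_df(c("id", "label", "inclusion", "rationale", "group"),
                          character(0)),
  inputs = .zero_df(c("stakeholder_id", "kind", "description"),
                    c("hours_per_unit", "unit_count", "hourly_rate",
                      "total_value"))[, c("stakeholder_id", "kind", "description",
                                          "hours_per_unit", "unit_count",
                                          "hourly_rate", "total_value")],
  indicators = .zero_df(c("id", "instrument", "direction", "rule",
                          "baseline_time", "followup_time"),
                        c("score_min", "score_max"))[, c("id", "instrument",
                          "direction", "rule", "baseline_time", "followup_time",
                          "score_min", "score_max")],
  proxies = .zero_df(c("code", "label"), "annual_value")[
    , c("code", "label", "annual_value")],
  outcomes = .zero_df(c("id", "stakeholder_id", "description", "indicator_id",
                        "proxy_code"),
                      c("quantity", "denominator", "duration_years",
                        "multiplier", "deadweight", "displacement",
                        "attribution", "drop_off"))[
    , c("id", "stakeholder_id", "description", "indicator_id", "quantity",
        "denominator", "duration_years", "proxy_code", "multiplier",
        "deadweight", "displacement", "attribution", "drop_off")]
)
.empty$proxies$source <- character(0)
.empty$proxies <- .empty$proxies[, c("code", "label", "annual_value", "source")]

#' Assemble and validate an SROI impact map
#'
#' The impact map is the whole analysis specification: stakeholders, the
#' inputs they invested, the outcomes experienced, the indicators that
#' measure them, the financial proxies that value them, and global settings
#' (annual discount rate, currency table). All cross-references must resolve
#' and all invariants hold; violations are reported together with their field
#' paths.
#'
#' @param stakeholders,inputs,indicators,proxies,outcomes data frames (or
#'   lists of one-row data frames) built with the component constructors.
#' @param discount_rate annual discount rate in \[0, 1); default 0.035, the
#'   UK Treasury rate for costs and outcomes occurring after one year.
#' @param currency_table a [currency_table()].
#' @param residual optional list `(value, duration_years, drop_off, note)`:
#'   adjusted first-year social value documented in the source analysis but
#'   not attributable to any single outcome row; added to the output total.
#' @param schema_version document schema version string.
#' @return a validated object of class `impact_map`.
#' @seealso [load_impact_map()], [write_impact_map()],
#'   [fixture_dementia_imagination()]
#' @export
impact_map <- function(stakeholders = NULL, inputs = NULL, indicators = NULL,
                       proxies = NULL, outcomes = NULL,
                       discount_rate = 0.035,
                       currency_table = sroikit::currency_table(),
                       residual = NULL, schema_version = "1.0") {
  map <- structure(list(
    schema_version = schema_version,
    discount_rate = as.numeric(discount_rate),
    currency_table = currency_table,
    stakeholders = .bind_rows(stakeholders, .empty$stakeholders),
    inputs = .bind_rows(inputs, .empty$inputs),
    indicators = .bind_rows(indicators, .empty$indicators),
    proxies = .bind_rows(proxies, .empty$proxies),
    outcomes = .bind_rows(outcomes, .empty$outcomes),
    residual = residual
  ), class = "impact_map")
  rownames(map$stakeholders) <- rownames(map$inputs) <- NULL
  rownames(map$indicators) <- rownames(map$proxies) <- NULL
  rownames(map$outcomes) <- NULL
  validate_impact_map(map)
}

#' Validate an impact map
#'
#' Checks every invariant of the data model and raises a single error that
#' lists all failing field paths (condition class `sroi_validation_error`;
#' additionally `sroi_reference_error` when any dangling id is involved).
#'
#' @param map an `impact_map`.
#' @return the map, invisibly turned visible, when valid.
#' @export
validate_impact_map <- function(map) {
  stopifnot(inherits(map, "impact_map"))
  problems <- character(0)
  refs <- character(0)
  add <- function(path, msg) problems[[length(problems) + 1L]] <<- paste0(path, ": ", msg)
  add_ref <- function(path, msg) {
    refs[[length(refs) + 1L]] <<- paste0(path, ": ", msg)
  }

  if (!is.numeric(map$discount_rate) || length(map$discount_rate) != 1L ||
      is.na(map$discount_rate) || map$discount_rate < 0 || map$discount_rate >= 1) {
    add("discount_rate", "must be a single number in [0, 1)")
  }
  if (!inherits(map$currency_table, "currency_table")) {
    add("currency_table", "must be a currency_table object")
  }

  st <- map$stakeholders
  if (anyDuplicated(st$id)) add("stakeholders.id", "stakeholder ids must be unique")
  bad <- which(!st$inclusion %in% c("included", "inputs_only", "excluded"))
  for (i in bad) add(sprintf("stakeholders[%d].inclusion", i), "must be included/inputs_only/excluded")

  inp <- map$inputs
  for (i in seq_len(nrow(inp))) {
    path <- sprintf("inputs[%d]", i)
    if (!inp$stakeholder_id[i] %in% st$id) {
      add_ref(paste0(path, ".stakeholder_id"),
              sprintf("unknown stakeholder '%s'", inp$stakeholder_id[i]))
    } else if (st$inclusion[match(inp$stakeholder_id[i], st$id)] == "excluded") {
      add(paste0(path, ".stakeholder_id"), "an excluded stakeholder owns no input items")
    }
    if (!inp$kind[i] %in% c("cash", "in_kind", "time")) {
      add(paste0(path, ".kind"), "must be cash/in_kind/time")
    }
    if (is.na(inp$total_value[i]) || inp$total_value[i] < 0) {
      add(paste0(path, ".total_value"), "must be >= 0")
    }
    if (identical(inp$kind[i], "time") && !is.na(inp$unit_count[i]) &&
        !is.na(inp$hours_per_unit[i]) && !is.na(inp$hourly_rate[i])) {
      expect <- round_half_up(inp$hours_per_unit[i] * inp$unit_count[i] * inp$hourly_rate[i])
      if (!isTRUE(all.equal(expect, inp$total_value[i]))) {
        add(paste0(path, ".total_value"),
            sprintf("time input inconsistent: round(%g x %g x %g) = %g, stored %g",
                    inp$hours_per_unit[i], inp$unit_count[i], inp$hourly_rate[i],
                    expect, inp$total_value[i]))
      }
    }
  }

  ind <- map$indicators
  if (anyDuplicated(ind$id)) add("indicators.id", "indicator ids must be unique")
  for (i in seq_len(nrow(ind))) {
    if (!ind$direction[i] %in% c("higher_is_better", "lower_is_better")) {
      add(sprintf("indicators[%d].direction", i), "must be higher_is_better/lower_is_better")
    }
    if (!ind$rule[i] %in% c("strict_improvement", "maintain_or_increase", "endorsed_at_followup")) {
      add(sprintf("indicators[%d].rule", i), "unknown classification rule")
    }
    if (!is.na(ind$score_min[i]) && !is.na(ind$score_max[i]) &&
        ind$score_min[i] >= ind$score_max[i]) {
      add(sprintf("indicators[%d].score_min", i), "score_min must be < score_max")
    }
  }

  px <- map$proxies
  if (anyDuplicated(px$code)) add("proxies.code", "proxy codes must be unique")
  for (i in which(is.na(px$annual_value) | px$annual_value <= 0)) {
    add(sprintf("proxies[%d].annual_value", i), "must be > 0")
  }

  out <- map$outcomes
  if (anyDuplicated(out$id)) add("outcomes.id", "outcome ids must be unique")
  for (i in seq_len(nrow(out))) {
    path <- sprintf("outcomes[%d]", i)
    j <- match(out$stakeholder_id[i], st$id)
    if (is.na(j)) {
      add_ref(paste0(path, ".stakeholder_id"),
              sprintf("unknown stakeholder '%s'", out$stakeholder_id[i]))
    } else if (st$inclusion[j] != "included") {
      add(paste0(path, ".stakeholder_id"),
          sprintf("stakeholder '%s' (%s) owns no outcomes", st$id[j], st$inclusion[j]))
    }
    if (!out$indicator_id[i] %in% ind$id) {
      add_ref(paste0(path, ".indicator_id"),
              sprintf("unknown indicator '%s'", out$indicator_id[i]))
    }
    if (!out$proxy_code[i] %in% px$code) {
      add_ref(paste0(path, ".proxy_code"),
              sprintf("unknown proxy '%s'", out$proxy_code[i]))
    }
    if (is.na(out$quantity[i]) || is.na(out$denominator[i]) ||
        out$quantity[i] < 0 || out$quantity[i] > out$denominator[i]) {
      add(paste0(path, ".quantity"), "must satisfy 0 <= quantity <= denominator")
    }
    if (is.na(out$duration_years[i]) || out$duration_years[i] < 1 ||
        out$duration_years[i] != as.integer(out$duration_years[i])) {
      add(paste0(path, ".duration_years"), "must be an integer >= 1")
    }
    has_mult <- !is.na(out$multiplier[i])
    has_comp <- !is.na(out$deadweight[i]) || !is.na(out$displacement[i]) ||
      !is.na(out$attribution[i])
    if (!has_mult && !has_comp) {
      add(paste0(path, ".multiplier"),
          "either a combined multiplier or adjustment components are required")
    }
    if (has_mult && (out$multiplier[i] < 0 || out$multiplier[i] > 1)) {
      add(paste0(path, ".multiplier"), "must be in [0, 1]")
    }
    if (has_comp) {
      for (f in c("deadweight", "displacement", "attribution")) {
        v <- out[[f]][i]
        if (is.na(v) || v < 0 || v > 1) {
          add(paste0(path, ".", f),
              "all three adjustment components in [0, 1] are required together")
        }
      }
    }
    if (is.na(out$drop_off[i]) || out$drop_off[i] < 0 || out$drop_off[i] > 1) {
      add(paste0(path, ".drop_off"), "must be in [0, 1]")
    }
  }

  if (!is.null(map$residual)) {
    r <- map$residual
    if (!is.list(r) || is.null(r$value) || !is.finite(r$value)) {
      add("residual.value", "must be a finite number")
    }
    if (!is.null(r$duration_years) &&
        (r$duration_years < 1 || r$duration_years != as.integer(r$duration_years))) {
      add("residual.duration_years", "must be an integer >= 1")
    }
  }

  all_problems <- c(problems, refs)
  if (length(all_problems)) {
    cls <- c(if (length(refs)) "sroi_reference_error", "sroi_validation_error",
             "error", "condition")
    stop(structure(class = cls, list(
      message = paste0("invalid impact map (", length(all_problems), " problem",
                       if (length(all_problems) > 1L) "s", "):\n  ",
                       paste(all_problems, collapse = "\n  ")),
      call = NULL, problems = all_problems
    )))
  }
  map
}

#' @export
print.impact_map <- function(x, ...) {
  cat("<impact_map> schema", x$schema_version, "\n")
  cat(sprintf("  %d stakeholders, %d input items, %d outcomes, %d proxies, %d indicators\n",
              nrow(x$stakeholders), nrow(x$inputs), nrow(x$outcomes),
              nrow(x$proxies), nrow(x$indicators)))
  cat(sprintf("  discount rate %.1f%%/year; currencies: %s\n",
              100 * x$discount_rate, paste(names(x$currency_table), collapse = ", ")))
  if (!is.null(x$residual)) {
    cat(sprintf("  residual adjusted value: %s\n", format(money(x$residual$value))))
  }
  invisible(x)
}

# --- serialization ---------------------------------------------------------

.row_to_list <- function(df, i) {
  row <- lapply(df, `[[`, i)
  row[!vapply(row, function(v) is.na(v) || (is.character(v) && !nzchar(v)), logical(1))]
}

.df_to_list <- function(df) lapply(seq_len(nrow(df)), function(i) .row_to_list(df, i))

#' Serialize an impact map to JSON or YAML
#'
#' JSON is the canonical document format; YAML is accepted as an alternate
#' surface syntax. Numbers are written at full precision so that
#' `load_impact_map(write_impact_map(map))` reproduces every amount exactly.
#'
#' @param map an `impact_map`.
#' @param path output file; the extension selects the format (`.json`,
#'   `.yaml`/`.yml`). If `NULL`, the JSON text is returned as a string.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
write_impact_map <- function(map, path = NULL) {
  stopifnot(inherits(map, "impact_map"))
  out <- list(
    schema_version = map$schema_version,
    discount_rate = map$discount_rate,
    currency_table = as.list(unclass(map$currency_table)),
    stakeholders = .df_to_list(map$stakeholders),
    inputs = lapply(.df_to_list(map$inputs), function(r) {
      r$total_value <- r$total_value  # keep key order stable
      r
    }),
    indicators = .df_to_list(map$indicators),
    proxies = .df_to_list(map$proxies),
    outcomes = lapply(seq_len(nrow(map$outcomes)), function(i) {
      r <- .row_to_list(map$outcomes[, setdiff(names(map$outcomes),
        c("multiplier", "deadweight", "displacement", "attribution", "drop_off"))], i)
      adj <- .row_to_list(map$outcomes[, c("multiplier", "deadweight",
        "displacement", "attribution", "drop_off"), drop = FALSE], i)
      r$adjustments <- adj
      r
    })
  )
  if (!is.null(map$residual)) out$residual <- map$residual
  if (is.null(path)) {
    return(as.character(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                                         null = "null")))
  }
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(out, path, precision = 15)
  } else {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

.lget <- function(x, name, default = NA) {
  v <- x[[name]]
  if (is.null(v)) default else v
}

#' Load and validate an impact map from JSON or YAML
#'
#' Parses the document, rebuilds the typed structure and runs the full
#' validation. Schema violations raise a single `sroi_validation_error`
#' listing every failing field path; dangling ids additionally carry class
#' `sroi_reference_error`.
#'
#' @param path a file path, or a single string holding the document text.
#' @return a validated `impact_map`.
#' @export
load_impact_map <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (file.exists(path)) {
    doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path)
    }
  } else {
    doc <- tryCatch(jsonlite::parse_json(path),
                    error = function(e) yaml::yaml.load(path))
    if (!is.list(doc)) stop("document does not parse as JSON or YAML", call. = FALSE)
  }
  stk <- lapply(doc$stakeholders, function(s) stakeholder(
    id = .lget(s, "id"), label = .lget(s, "label", .lget(s, "id")),
    inclusion = .lget(s, "inclusion", "included"),
    rationale = .lget(s, "rationale", ""), group = .lget(s, "group", NA_character_)
  ))
  inp <- lapply(doc$inputs, function(x) input_item(
    stakeholder_id = .lget(x, "stakeholder_id"), kind = .lget(x, "kind"),
    description = .lget(x, "description", ""),
    total_value = .lget(x, "total_value", NA_real_),
    hours_per_unit = .lget(x, "hours_per_unit", NA_real_),
    unit_count = .lget(x, "unit_count", NA_real_),
    hourly_rate = .lget(x, "hourly_rate", NA_real_)
  ))
  ind <- lapply(doc$indicators, function(x) indicator(
    id = .lget(x, "id"), instrument = .lget(x, "instrument", .lget(x, "id")),
    direction = .lget(x, "direction", "higher_is_better"),
    rule = .lget(x, "rule", "strict_improvement"),
    baseline_time = .lget(x, "baseline_time", "T1"),
    followup_time = .lget(x, "followup_time", "T3"),
    score_min = .lget(x, "score_min", -Inf), score_max = .lget(x, "score_max", Inf)
  ))
  px <- lapply(doc$proxies, function(x) financial_proxy(
    code = .lget(x, "code"), label = .lget(x, "label", .lget(x, "code")),
    annual_value = .lget(x, "annual_value", NA_real_),
    source = .lget(x, "source", "")
  ))
  out <- lapply(doc$outcomes, function(x) {
    adj <- .lget(x, "adjustments", list())
    if (!is.list(adj)) adj <- list()
    outcome(
      id = .lget(x, "id"), stakeholder_id = .lget(x, "stakeholder_id"),
      description = .lget(x, "description", ""),
      indicator_id = .lget(x, "indicator_id"),
      quantity = .lget(x, "quantity", NA_real_),
      denominator = .lget(x, "denominator", NA_real_),
      proxy_code = .lget(x, "proxy_code"),
      duration_years = .lget(x, "duration_years", 1),
      multiplier = .lget(adj, "multiplier", NA_real_),
      deadweight = .lget(adj, "deadweight", NA_real_),
      displacement = .lget(adj, "displacement", NA_real_),
      attribution = .lget(adj, "attribution", NA_real_),
      drop_off = .lget(adj, "drop_off", 0)
    )
  })
  rates <- unlist(doc$currency_table %||% list(GBP = 1))
  residual <- doc$residual
  if (!is.null(residual)) {
    residual <- list(
      value = .lget(residual, "value", NA_real_),
      duration_years = .lget(residual, "duration_years", 1),
      drop_off = .lget(residual, "drop_off", 0),
      note = .lget(residual, "note", "")
    )
  }
  impact_map(
    stakeholders = stk, inputs = inp, indicators = ind, proxies = px,
    outcomes = out,
    discount_rate = .lget(doc, "discount_rate", 0.035),
    currency_table = currency_table(rates),
    residual = residual,
    schema_version = as.character(.lget(doc, "schema_version", "1.0"))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
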