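#' Write an impact-map report
#'
#' Tabulates an SROI result row by row: one row per outcome (stakeholder,
#' outcome, quantity, proxy, adjusted value, present value), a residual row
#' when the map carries one, and three totals rows (total inputs, total
#' outputs PV, SROI ratio). The CSV form keeps full numeric precision so it
#' round-trips with the result; the markdown form rounds monetary values
#' half-up to whole currency units and the ratio to two decimals, the
#' convention of published impact maps.
#'
#' @param map the `impact_map` the result was computed from.
#' @param result the [sroi_ratio()] result for that map.
#' @param path output file, or `NULL` to return the table/text.
#' @param format `"csv"` (RFC 4180, UTF-8) or `"markdown"`.
#' @return For `"csv"`: the report data frame (written to `path` when given).
#'   For `"markdown"`: a character vector of lines.
#' @export
write_impact_report <- function(map, result, path = NULL,
                                format = c("csv", "markdown")) {
  stopifnot(inherits(map, "impact_map"), inherits(result, "sroi_result"))
  format <- match.arg(format)
  per <- result$per_outcome
  stk_label <- map$stakeholders$label[match(per$stakeholder_id, map$stakeholders$id)]
  rows <- data.frame(
    section = rep("outcome", nrow(per)),
    stakeholder = stk_label,
    outcome = per$outcome_id,
    description = per$description,
    quantity = per$quantity,
    proxy = per$proxy_code,
    annual_value = per$annual_value,
    multiplier = per$multiplier,
    adjusted_value = per$adjusted_value,
    present_value = per$present_value,
    stringsAsFactors = FALSE
  )
  blank <- function(section, description, value) {
    data.frame(section = section, stakeholder = "", outcome = "",
               description = description, quantity = NA_real_, proxy = "",
               annual_value = NA_real_, multiplier = NA_real_,
               adjusted_value = NA_real_, present_value = value,
               stringsAsFactors = FALSE)
  }
  if (!is.null(map$residual)) {
    rows <- rbind(rows, blank("residual", "Residual adjusted value (see map documentation)",
                              as.numeric(result$residual_pv)))
  }
  rows <- rbind(
    rows,
    blank("total", "Total inputs", as.numeric(result$total_inputs)),
    blank("total", "Total outputs (present value)",
          as.numeric(result$total_outputs_pv)),
    blank("total", "SROI ratio (outputs / inputs)", result$ratio)
  )
  rownames(rows) <- NULL

  if (format == "csv") {
    if (!is.null(path)) {
      utils::write.csv(rows, path, row.names = FALSE, na = "")
      return(invisible(rows))
    }
    return(rows)
  }

  # markdown: display rounding, half-up
  disp <- rows
  for (col in c("annual_value", "adjusted_value", "present_value")) {
    disp[[col]] <- ifelse(is.na(disp[[col]]), "",
                          formatC(round_half_up(disp[[col]]),
                                  format = "d", big.mark = ","))
  }
  disp$present_value[disp$section == "total" &
                       grepl("ratio", disp$description)] <-
    sprintf("%.2f", result$ratio_2dp)
  disp$quantity <- ifelse(is.na(disp$quantity), "",
                          formatC(disp$quantity, format = "fg"))
  disp$multiplier <- ifelse(is.na(disp$multiplier), "",
                            sprintf("%.4f", disp$multiplier))
  disp$section <- NULL
  header <- names(disp)
  fmt_row <- function(v) paste0("| ", paste(v, collapse = " | "), " |")
  lines <- c(fmt_row(header),
             fmt_row(rep("---", length(header))),
             vapply(seq_len(nrow(disp)),
                    function(i) fmt_row(unlist(disp[i, ], use.names = FALSE)),
                    character(1)))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
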