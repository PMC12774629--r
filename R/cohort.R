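# Worked-example study parameterization: per-outcome improvement probability
# (numerator/denominator) and assessability (denominator/group size) for a
# cohort of 125 people with dementia, 88 family and 58 staff caregivers.
.study_counts <- data.frame(
  outcome_id = c("wellbeing", "art_engagement", "confidence", "control",
                 "loneliness", "liveliness", "family_art", "family_network",
                 "family_attitude", "staff_art", "staff_prof_dev",
                 "staff_attitude", "staff_network"),
  group = c(rep("pwd", 6), rep("family_caregiver", 3),
            rep("staff_caregiver", 4)),
  numerator = c(36, 53, 17, 18, 6, 21, 27, 13, 34, 23, 28, 18, 11),
  denominator = c(98, 100, 61, 61, 58, 98, 54, 47, 70, 29, 33, 45, 20),
  stringsAsFactors = FALSE
)

#' Specification of a synthetic three-wave cohort
#'
#' Defines the study conditions the generator emulates: group sizes,
#' per-outcome improvement probabilities (conditional on being assessable),
#' per-outcome assessability probabilities (a reported baseline/follow-up
#' pair), the probability that a wave's self-report is missing for a person
#' with dementia (triggering proxy substitution), and the attendance
#' distribution (truncated normal on \[0, 12\] sessions).
#'
#' Defaults reproduce the packaged worked example: 125 people with dementia,
#' 88 family and 58 staff caregivers; improvement and assessability
#' probabilities taken from the evidenced outcome table (e.g. well-being
#' 36/98 = 0.367 improving among 98/125 = 0.784 assessable); attendance mean
#' 7, SD 3.83; and a per-wave missing-self-report probability of 0.21, chosen
#' so that the expected number of proxy-substituted change scores among ~98
#' assessable pairs (1 - (1 - 0.21)^2 = 0.376 of them, about 37) matches the
#' substitution counts observed in the study.
#'
#' @param n_pwd,n_family,n_staff group sizes.
#' @param improvement_probs named vector, outcome id -> probability of
#'   improvement among assessable participants.
#' @param assessable_probs named vector, outcome id -> probability of a
#'   complete (reported) baseline/follow-up pair.
#' @param proxy_only_prob probability a PwD wave lacks a self-report and a
#'   proxy (informant) response is used instead.
#' @param attendance_mean,attendance_sd attendance distribution before
#'   truncation to \[0, 12\] and rounding.
#' @param seed integer seed; every draw in [generate_cohort()] is
#'   reproducible from it.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pwd = 125, n_family = 88, n_staff = 58,
                        improvement_probs = NULL, assessable_probs = NULL,
                        proxy_only_prob = 0.21,
                        attendance_mean = 7, attendance_sd = 3.83,
                        seed = 1L) {
  n_group <- c(pwd = n_pwd, family_caregiver = n_family,
               staff_caregiver = n_staff)
  if (is.null(improvement_probs)) {
    improvement_probs <- stats::setNames(
      .study_counts$numerator / .study_counts$denominator,
      .study_counts$outcome_id)
  }
  if (is.null(assessable_probs)) {
    assessable_probs <- stats::setNames(
      .study_counts$denominator / n_group[.study_counts$group],
      .study_counts$outcome_id)
  }
  probs <- c(improvement_probs, assessable_probs, proxy_only_prob)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(c(n_pwd, n_family, n_staff) < 0)) {
    stop("group sizes must be >= 0", call. = FALSE)
  }
  structure(list(
    n_pwd = n_pwd, n_family = n_family, n_staff = n_staff,
    improvement_probs = improvement_probs,
    assessable_probs = assessable_probs,
    proxy_only_prob = proxy_only_prob,
    attendance_mean = attendance_mean, attendance_sd = attendance_sd,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Cohort specification matching the worked example's outcome table
#'
#' Convenience wrapper: [cohort_spec()] with the default per-outcome
#' probabilities, i.e. those whose expected counts reproduce the evidenced
#' numerators and denominators (well-being 36/98, art engagement 53/100,
#' confidence 17/61, control 18/61, loneliness 6/58, liveliness 21/98;
#' family 27/54, 13/47, 34/70; staff 23/29, 28/33, 18/45, 11/20).
#'
#' @param seed integer seed passed through.
#' @return a `cohort_spec`.
#' @export
study_spec <- function(seed = 1L) cohort_spec(seed = seed)

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# draw (baseline, shift) pairs on an integer scale [lo, hi] oriented so that
# higher is better, such that the classification rule recovers `qualify`
# exactly: qualifiers get a qualifying shift, non-qualifiers a non-qualifying
# one
.draw_pair <- function(n, qualify, rule, lo, hi) {
  b <- integer(n); d <- integer(n)
  if (rule == "maintain_or_increase") {
    # qualifier: shift >= 0; non-qualifier: strict decline (needs b > lo)
    b <- ifelse(qualify,
                lo + floor(stats::runif(n) * (hi - lo)),        # [lo, hi-1]
                lo + 1 + floor(stats::runif(n) * (hi - lo)))    # [lo+1, hi]
    d <- ifelse(qualify,
                floor(stats::runif(n) * (hi - b + 1)),          # [0, hi-b]
                -(1 + floor(stats::runif(n) * (b - lo))))       # [-(b-lo), -1]
  } else {
    # strict improvement: qualifier shift > 0 (needs b < hi);
    # non-qualifier: shift <= 0 (maintained or declined)
    b <- ifelse(qualify,
                lo + floor(stats::runif(n) * (hi - lo)),        # [lo, hi-1]
                lo + floor(stats::runif(n) * (hi - lo + 1)))    # [lo, hi]
    d <- ifelse(qualify,
                1 + floor(stats::runif(n) * (hi - b)),          # [1, hi-b]
                -floor(stats::runif(n) * (b - lo + 1)))         # [-(b-lo), 0]
  }
  list(baseline = as.integer(b), shift = as.integer(d))
}

#' Generate a synthetic three-wave cohort with known ground truth
#'
#' Produces long-format participant records for the three waves (T1 baseline,
#' T2 post-program, T3 six-month follow-up) in which instrument scores are
#' drawn so that [classify_change()] recovers each participant's latent
#' improvement flag exactly; counted outcome proportions are therefore
#' binomial (or exact-count) with the specification's parameters — the
#' statistical contract every downstream test relies on.
#'
#' Two assignment methods:
#' * `"exact"` (default): exactly `round(n x assessable_prob)` participants
#'   are assessable and exactly `round(n_assessable x improvement_prob)` of
#'   them improve — the expected study counts are reproduced exactly, only
#'   *which* participants and their scores vary with the seed.
#' * `"binomial"`: independent per-participant Bernoulli draws; counted
#'   proportions are binomial around the specified probabilities.
#'
#' Missing self-reports for people with dementia are simulated per wave with
#' probability `proxy_only_prob`; the wave's records then carry
#' `respondent = "proxy"` (an informant reporting on the participant's
#' behalf) instead of `"self"`. Non-assessable participants have their
#' follow-up score missing. Attendance is drawn from a normal distribution
#' truncated to \[0, 12\] and rounded to whole sessions.
#'
#' @param spec a [cohort_spec()].
#' @param map an `impact_map` supplying the indicator registry and the
#'   outcome-to-group mapping; default [fixture_dementia_imagination()].
#' @param method `"exact"` or `"binomial"`, see above.
#' @return a list of class `synthetic_cohort`: `records` (long-format data
#'   frame, see [read_participant_records()] for the dialect) and `truth`
#'   (class `ground_truth`: per-outcome counts and true probabilities,
#'   per-participant latent flags, total attendances, the seed used).
#' @export
generate_cohort <- function(spec, map = fixture_dementia_imagination(),
                            method = c("exact", "binomial")) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(map, "impact_map"))
  method <- match.arg(method)
  set.seed(spec$seed)

  n_group <- c(pwd = spec$n_pwd, family_caregiver = spec$n_family,
               staff_caregiver = spec$n_staff)
  sites <- c("residential", "hospital", "community")
  participants <- do.call(rbind, lapply(names(n_group), function(g) {
    n <- n_group[[g]]
    if (n == 0L) return(NULL)
    data.frame(
      participant_id = sprintf("%s_%03d", sub("_caregiver", "", g), seq_len(n)),
      group = g,
      site = sample(sites, n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }))

  # attendance: truncated normal, whole sessions, people with dementia only
  att <- stats::setNames(rep(NA_real_, nrow(participants)),
                         participants$participant_id)
  is_pwd <- participants$group == "pwd"
  att[is_pwd] <- round(.clamp(
    stats::rnorm(sum(is_pwd), spec$attendance_mean, spec$attendance_sd), 0, 12))

  # per-wave missing self-report for people with dementia
  waves <- c("T1", "T2", "T3")
  proxy_wave <- matrix(FALSE, nrow(participants), 3,
                       dimnames = list(participants$participant_id, waves))
  proxy_wave[is_pwd, ] <- stats::runif(sum(is_pwd) * 3) < spec$proxy_only_prob

  rec <- list(); flags <- list(); counts <- list()
  for (i in seq_len(nrow(map$outcomes))) {
    out <- map$outcomes[i, , drop = FALSE]
    ind <- map$indicators[map$indicators$id == out$indicator_id, , drop = FALSE]
    grp <- map$stakeholders$group[match(out$stakeholder_id, map$stakeholders$id)]
    if (is.na(grp)) next
    ppl <- participants[participants$group == grp, , drop = FALSE]
    n <- nrow(ppl)
    if (n == 0L) next
    p <- spec$improvement_probs[[out$id]]
    a <- spec$assessable_probs[[out$id]]
    if (is.null(p) || is.null(a)) {
      stop(sprintf("cohort spec lacks probabilities for outcome '%s'", out$id),
           call. = FALSE)
    }
    if (method == "exact") {
      n_assess <- round(n * a)
      assessable <- rep(FALSE, n)
      assessable[sample.int(n, n_assess)] <- TRUE
      improved <- stats::runif(n) < p            # latent for everyone
      k <- round(n_assess * p)
      improved[assessable] <- FALSE
      idx <- which(assessable)
      improved[idx[sample.int(length(idx), k)]] <- TRUE
    } else {
      assessable <- stats::runif(n) < a
      improved <- stats::runif(n) < p
    }

    lo <- ind$score_min; hi <- ind$score_max
    if (ind$rule == "endorsed_at_followup") {
      score_t3 <- ifelse(assessable, as.numeric(improved), NA_real_)
      rec[[length(rec) + 1L]] <- data.frame(
        participant_id = ppl$participant_id, group = grp, site = ppl$site,
        wave = ind$followup_time, respondent = "self",
        instrument = ind$instrument, score = score_t3,
        sessions_attended = att[ppl$participant_id],
        stringsAsFactors = FALSE
      )
    } else {
      pair <- .draw_pair(n, improved, ind$rule, lo, hi)
      oriented <- cbind(T1 = pair$baseline,
                        T2 = pair$baseline + pair$shift %/% 2,
                        T3 = pair$baseline + pair$shift)
      scores <- if (ind$direction == "lower_is_better") lo + hi - oriented else oriented
      scores[!assessable, "T3"] <- NA_real_
      for (w in waves) {
        wv <- if (w == ind$baseline_time) "T1" else if (w == ind$followup_time) "T3" else "T2"
        rec[[length(rec) + 1L]] <- data.frame(
          participant_id = ppl$participant_id, group = grp, site = ppl$site,
          wave = w,
          respondent = ifelse(proxy_wave[ppl$participant_id, w], "proxy", "self"),
          instrument = ind$instrument, score = as.numeric(scores[, wv]),
          sessions_attended = att[ppl$participant_id],
          stringsAsFactors = FALSE
        )
      }
    }
    flags[[length(flags) + 1L]] <- data.frame(
      outcome_id = out$id, participant_id = ppl$participant_id,
      assessable = assessable, improved = improved, stringsAsFactors = FALSE
    )
    counts[[length(counts) + 1L]] <- data.frame(
      outcome_id = out$id, group = grp,
      n_improved = sum(improved & assessable), n_assessable = sum(assessable),
      true_p = p, true_assessable = a,
      empirical_p = sum(improved & assessable) / max(sum(assessable), 1),
      stringsAsFactors = FALSE
    )
  }

  records <- do.call(rbind, rec)
  records <- records[order(records$participant_id, records$instrument,
                           match(records$wave, waves)), , drop = FALSE]
  rownames(records) <- NULL
  truth <- structure(list(
    counts = do.call(rbind, counts),
    flags = do.call(rbind, flags),
    total_attendances = sum(att, na.rm = TRUE),
    seed = spec$seed,
    method = method
  ), class = "ground_truth")
  structure(list(records = records, truth = truth), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d records, %d participants, seed %d (%s)\n",
              nrow(x$records), length(unique(x$records$participant_id)),
              x$truth$seed, x$truth$method))
  invisible(x)
}

#' Parameter-recovery experiment for the evidencing stage
#'
#' Repeatedly generates a cohort (binomial assignment, seeds
#' `spec$seed + 0 .. replicates-1`), evidences every outcome and summarizes
#' how well the counted proportions recover the generator's true
#' probabilities. The reference band is the per-cohort binomial standard
#' error sqrt(p (1 - p) / n) at the expected denominator.
#'
#' @param spec a [cohort_spec()].
#' @param replicates number of replicates (>= 1).
#' @param map impact map supplying indicators and outcome-to-group mapping.
#' @return a data frame of class `recovery_summary`: outcome_id, true_p,
#'   mean_prop, sd_prop, se_binom, bias, within_2se; attribute `replicates`.
#' @export
recovery_experiment <- function(spec, replicates,
                                map = fixture_dementia_imagination()) {
  stopifnot(inherits(spec, "cohort_spec"), replicates >= 1)
  props <- matrix(NA_real_, nrow = replicates, ncol = nrow(map$outcomes),
                  dimnames = list(NULL, map$outcomes$id))
  for (r in seq_len(replicates)) {
    spec_r <- spec
    spec_r$seed <- spec$seed + r - 1L
    gen <- generate_cohort(spec_r, map, method = "binomial")
    evd <- attr(evidence_all(gen$records, map), "evidence")
    props[r, evd$outcome_id] <- evd$proportion
  }
  n_group <- c(pwd = spec$n_pwd, family_caregiver = spec$n_family,
               staff_caregiver = spec$n_staff)
  grp <- map$stakeholders$group[match(map$outcomes$stakeholder_id,
                                      map$stakeholders$id)]
  p <- spec$improvement_probs[map$outcomes$id]
  n_exp <- round(n_group[grp] * spec$assessable_probs[map$outcomes$id])
  out <- data.frame(
    outcome_id = map$outcomes$id,
    true_p = as.numeric(p),
    mean_prop = colMeans(props, na.rm = TRUE),
    sd_prop = apply(props, 2, stats::sd, na.rm = TRUE),
    se_binom = sqrt(as.numeric(p) * (1 - as.numeric(p)) / as.numeric(n_exp)),
    stringsAsFactors = FALSE
  )
  out$bias <- out$mean_prop - out$true_p
  out$within_2se <- abs(out$bias) <= 2 * out$se_binom
  rownames(out) <- NULL
  attr(out, "replicates") <- replicates
  class(out) <- c("recovery_summary", "data.frame")
  out
}
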