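#' Phenotyping configuration
#'
#' Tunable thresholds for visit classification and responder calling. Visits
#' are semiannual, so one year equals two inter-visit intervals and a
#' "trailing year" compares a visit with the one two positions earlier.
#'
#' @param max_imputed_run Longest run of consecutive missing values that may
#'   be imputed (visits; default 2).
#' @param smooth_window Centered smoothing window (visits; default 3: self
#'   plus up to one neighbor each side).
#' @param good_gain_per_year Minimum smoothed CD4 gain, evaluated per rolling
#'   year, for a good response (cells/mm3/yr; default 100).
#' @param poor_gain_per_year Gain below which a rolling year counts as poor
#'   (cells/mm3/yr; default 50).
#' @param min_good_years Minimum suppressed span for a good call (default 2).
#' @param min_poor_years Minimum suppressed span for a poor call (default 1).
#' @param suppression_rule `"below_detection_flag"` (use the per-visit assay
#'   flag) or `"vl_lt_limit"` (compare the measured VL with the limit).
#' @param decline_slope Trailing-year smoothed-CD4 change below which an
#'   off-therapy visit counts as declining (cells/mm3/yr; default -50).
#' @param short_off_cart_max Longest off-therapy gap between cART periods
#'   still coded as a short interruption (visits; default 2).
#' @return A list of class `phenotype_config`.
#' @export
phenotype_config <- function(max_imputed_run = 2L,
                             smooth_window = 3L,
                             good_gain_per_year = 100,
                             poor_gain_per_year = 50,
                             min_good_years = 2,
                             min_poor_years = 1,
                             suppression_rule = c("below_detection_flag", "vl_lt_limit"),
                             decline_slope = -50,
                             short_off_cart_max = 2L) {
  suppression_rule <- match.arg(suppression_rule)
  assert_that(good_gain_per_year > poor_gain_per_year,
              "good_gain_per_year must exceed poor_gain_per_year")
  assert_that(min_good_years >= min_poor_years,
              "min_good_years must be >= min_poor_years")
  structure(list(max_imputed_run = as.integer(max_imputed_run),
                 smooth_window = as.integer(smooth_window),
                 good_gain_per_year = good_gain_per_year,
                 poor_gain_per_year = poor_gain_per_year,
                 min_good_years = min_good_years,
                 min_poor_years = min_poor_years,
                 suppression_rule = suppression_rule,
                 decline_slope = decline_slope,
                 short_off_cart_max = as.integer(short_off_cart_max)),
            class = "phenotype_config")
}

#' Impute short gaps in CD4 and viral-load series
#'
#' Fills runs of at most `max_imputed_run` consecutive missing values, only
#' when measured visits flank the gap on both sides and cART status does not
#' change anywhere across the flank-to-flank span. CD4 is filled by linear
#' interpolation on visit index; viral-load suppression status is filled by
#' the shared flanking status (only when both flanks agree). Longer runs and
#' status-discordant or cART-discordant gaps pass through unchanged. Measured
#' values are never altered.
#'
#' @param visits Tibble of visit records (may hold many participants); needs
#'   `participant_id`, `visit_index`, `cd4`, `vl_below_detection`, `on_cart`.
#' @param config A [phenotype_config()].
#' @return `visits` with filled values plus logical columns `imputed_cd4` and
#'   `imputed_vl`.
#' @export
impute_gaps <- function(visits, config = phenotype_config()) {
  visits |>
    dplyr::arrange(.data$participant_id, .data$visit_index) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(~ impute_one(.x, config)) |>
    dplyr::ungroup()
}

impute_one <- function(v, config) {
  v$imputed_cd4 <- FALSE
  v$imputed_vl <- FALSE
  nv <- nrow(v)

  fill_runs <- function(is_na) {
    r <- rle(is_na)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values & r$lengths <= config$max_imputed_run &
                    starts > 1L & ends < nv)
    lapply(keep, function(k) c(starts[k], ends[k]))
  }

  for (run in fill_runs(is.na(v$cd4))) {
    lo <- run[1] - 1L; hi <- run[2] + 1L
    if (length(unique(v$on_cart[lo:hi])) != 1L) next
    idx <- run[1]:run[2]
    v$cd4[idx] <- stats::approx(x = v$visit_index[c(lo, hi)],
                                y = v$cd4[c(lo, hi)],
                                xout = v$visit_index[idx])$y
    v$imputed_cd4[idx] <- TRUE
  }

  for (run in fill_runs(is.na(v$vl_below_detection))) {
    lo <- run[1] - 1L; hi <- run[2] + 1L
    if (length(unique(v$on_cart[lo:hi])) != 1L) next
    if (!identical(v$vl_below_detection[lo], v$vl_below_detection[hi])) next
    idx <- run[1]:run[2]
    v$vl_below_detection[idx] <- v$vl_below_detection[lo]
    v$imputed_vl[idx] <- TRUE
  }
  v
}

#' Smooth CD4 counts over nearby visits
#'
#' Each non-missing CD4 value becomes the unweighted mean of the available
#' values in a centered window (`smooth_window` = 3: self plus up to one
#' neighbor each side; at a series endpoint or next to a missing neighbor the
#' mean is over two values, and over the value itself when no neighbor is
#' available). Visits with missing CD4 get a missing smoothed value.
#'
#' @inheritParams impute_gaps
#' @return `visits` with an added `smoothed_cd4` column.
#' @export
smooth_cd4 <- function(visits, config = phenotype_config()) {
  half <- (config$smooth_window - 1L) %/% 2L
  visits |>
    dplyr::arrange(.data$participant_id, .data$visit_index) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(smoothed_cd4 = smooth_series(.data$cd4, half)) |>
    dplyr::ungroup()
}

smooth_series <- function(x, half) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    if (is.na(x[i])) return(NA_real_)
    w <- x[max(1, i - half):min(n, i + half)]
    mean(w, na.rm = TRUE)
  }, numeric(1))
}

# Per-visit suppression status: TRUE / FALSE / NA (unknown).
suppression_status <- function(v, config) {
  if (config$suppression_rule == "vl_lt_limit") {
    ifelse(!is.na(v$vl), v$vl < v$detection_limit, v$vl_below_detection)
  } else {
    v$vl_below_detection
  }
}

#' Classify each visit into a treatment-response code
#'
#' Applies the visit-code taxonomy used in longitudinal response phenotyping:
#' the first on-therapy visit ever is `FIRST_CART`; an on-therapy visit that
#' follows an off-therapy gap after earlier cART is `REINITIATED_CART`; other
#' on-therapy visits split into `CART_SUPPRESSED` vs `CART_VIREMIC` by the
#' suppression rule, with `CART_SUPPRESSED_MINIMAL_GAIN` when the trailing
#' one-year smoothed CD4 gain falls below `poor_gain_per_year`. Off-therapy
#' viremic visits inside a short gap between cART periods are
#' `SHORT_OFF_ART_VIREMIC_DECLINING`; longer off-therapy spells are stable or
#' declining by the trailing-year smoothed CD4 slope. Visits whose required
#' inputs are missing, or whose history is too short to evaluate the rule,
#' are `NOT_DETERMINED`.
#'
#' @param visits Visit tibble after [impute_gaps()] and [smooth_cd4()].
#' @param config A [phenotype_config()].
#' @return `visits` with an added character `code` column.
#' @export
classify_visits <- function(visits, config = phenotype_config()) {
  assert_that("smoothed_cd4" %in% names(visits),
              "run smooth_cd4() before classify_visits()")
  visits |>
    dplyr::arrange(.data$participant_id, .data$visit_index) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(~ classify_one(.x, config)) |>
    dplyr::ungroup()
}

classify_one <- function(v, config) {
  nv <- nrow(v)
  supp <- suppression_status(v, config)
  sm <- v$smoothed_cd4
  trail_gain <- rep(NA_real_, nv)
  ok <- seq_len(nv) > 2
  trail_gain[ok] <- sm[which(ok)] - sm[which(ok) - 2L]

  off_run <- integer(nv) # id of the off-cART run a visit belongs to
  r <- rle(v$on_cart)
  run_id <- rep(seq_along(r$lengths), r$lengths)
  code <- character(nv)
  first_cart <- if (any(v$on_cart)) min(which(v$on_cart)) else NA_integer_

  for (i in seq_len(nv)) {
    if (v$on_cart[i]) {
      if (i == first_cart) {
        code[i] <- "FIRST_CART"
      } else if (i > 1 && !v$on_cart[i - 1]) {
        code[i] <- "REINITIATED_CART"
      } else if (is.na(supp[i])) {
        code[i] <- "NOT_DETERMINED"
      } else if (supp[i]) {
        code[i] <- if (!is.na(trail_gain[i]) && trail_gain[i] < config$poor_gain_per_year)
          "CART_SUPPRESSED_MINIMAL_GAIN" else "CART_SUPPRESSED"
      } else {
        code[i] <- "CART_VIREMIC"
      }
    } else {
      if (is.na(supp[i]) || isTRUE(supp[i])) {
        # off therapy with unknown or (anomalous) suppressed viremia
        code[i] <- "NOT_DETERMINED"
        next
      }
      run_len <- r$lengths[run_id[i]]
      internal <- run_id[i] > 1 && run_id[i] < length(r$lengths)
      if (internal && run_len <= config$short_off_cart_max) {
        code[i] <- "SHORT_OFF_ART_VIREMIC_DECLINING"
      } else if (is.na(trail_gain[i])) {
        code[i] <- "NOT_DETERMINED"
      } else if (trail_gain[i] < config$decline_slope) {
        code[i] <- "OFF_ART_VIREMIC_DECLINING"
      } else {
        code[i] <- "OFF_ART_VIREMIC_STABLE"
      }
    }
  }
  v$code <- code
  v
}

#' Call good/poor responder phenotypes
#'
#' Scans each participant's maximal runs of suppressed-on-cART visits
#' (`CART_SUPPRESSED` or `CART_SUPPRESSED_MINIMAL_GAIN`). A run qualifies
#' GOOD when it spans at least `min_good_years`, every evaluable rolling-year
#' smoothed CD4 gain inside it is at least `good_gain_per_year`, and the gain
#' above nadir is positive; it qualifies POOR when it spans at least
#' `min_poor_years` and every evaluable rolling-year gain is below
#' `poor_gain_per_year`. Participants with no qualifying run — or with
#' conflicting GOOD and POOR runs — are INDETERMINATE. Metrics are reported
#' for the earliest qualifying run.
#'
#' @param visits Classified visit tibble (from [classify_visits()]).
#' @param participants Tibble with `participant_id`, `nadir_cd4` and
#'   (optionally) `age`.
#' @param config A [phenotype_config()].
#' @return Tibble with one row per participant: `participant_id`, `group`
#'   (`"GOOD"`, `"POOR"`, `"INDETERMINATE"`), `window_start`, `window_end`,
#'   `suppressed_years`, `gain_per_year`, `gain_above_nadir`,
#'   `age_at_window_start`.
#' @export
call_responders <- function(visits, participants, config = phenotype_config()) {
  assert_that("code" %in% names(visits),
              "run classify_visits() before call_responders()")
  visits |>
    dplyr::arrange(.data$participant_id, .data$visit_index) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(function(v, key) {
      p <- participants[participants$participant_id == key$participant_id, ]
      call_one(v, nadir = p$nadir_cd4[1] %||% NA_real_,
               age = p$age[1] %||% NA_real_, config)
    }) |>
    dplyr::ungroup()
}

call_one <- function(v, nadir, age, config) {
  suppressed <- v$code %in% c("CART_SUPPRESSED", "CART_SUPPRESSED_MINIMAL_GAIN")
  r <- rle(suppressed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)

  eval_run <- function(s, e) {
    len <- e - s + 1L
    yrs <- visits_to_years(len)
    sm <- v$smoothed_cd4[s:e]
    gains <- if (len >= 3) sm[3:len] - sm[1:(len - 2)] else numeric(0)
    gains <- gains[!is.na(gains)]
    last_sm <- rev(sm[!is.na(sm)])[1] %||% NA_real_
    good <- yrs >= config$min_good_years && length(gains) > 0 &&
      all(gains >= config$good_gain_per_year) &&
      !is.na(last_sm) && !is.na(nadir) && (last_sm - nadir) > 0
    poor <- yrs >= config$min_poor_years && length(gains) > 0 &&
      all(gains < config$poor_gain_per_year)
    first_sm <- sm[!is.na(sm)][1] %||% NA_real_
    tibble::tibble(
      start = v$visit_index[s], end = v$visit_index[e],
      years = yrs, good = good, poor = poor,
      gain_per_year = if (yrs > 0 && !is.na(first_sm) && !is.na(last_sm))
        (last_sm - first_sm) / yrs else NA_real_,
      gain_above_nadir = last_sm - nadir
    )
  }

  cand <- purrr::map_dfr(runs, function(k) eval_run(starts[k], ends[k]))
  empty <- tibble::tibble(
    group = "INDETERMINATE", window_start = NA_integer_,
    window_end = NA_integer_, suppressed_years = NA_real_,
    gain_per_year = NA_real_, gain_above_nadir = NA_real_,
    age_at_window_start = NA_real_
  )
  if (nrow(cand) == 0) return(empty)
  any_good <- any(cand$good)
  any_poor <- any(cand$poor)
  if (any_good == any_poor) return(empty) # neither, or a conflict
  pick <- cand[if (any_good) cand$good else cand$poor, ][1, ]
  tibble::tibble(
    group = if (any_good) "GOOD" else "POOR",
    window_start = as.integer(pick$start),
    window_end = as.integer(pick$end),
    suppressed_years = pick$years,
    gain_per_year = pick$gain_per_year,
    gain_above_nadir = pick$gain_above_nadir,
    age_at_window_start = if (!is.na(age)) age + (pick$start - 1) / 2 else NA_real_
  )
}

#' Run the full phenotyping chain
#'
#' Convenience wrapper: [impute_gaps()] then [smooth_cd4()] then
#' [classify_visits()] then [call_responders()].
#'
#' @inheritParams call_responders
#' @param visits Raw visit tibble.
#' @return List with `visits` (classified, with imputation flags and smoothed
#'   CD4) and `calls` (the responder table).
#' @export
phenotype_cohort <- function(visits, participants, config = phenotype_config()) {
  v <- visits |>
    impute_gaps(config) |>
    smooth_cd4(config) |>
    classify_visits(config)
  list(visits = v, calls = call_responders(v, participants, config))
}

#' Frequency-match good responders to poor responders by stratum
#'
#' Within each race/ethnicity stratum, samples good responders without
#' replacement (seeded, hence reproducible) to approximate the poor-responder
#' stratum count at the requested ratio. Strata holding poor responders but no
#' good responders are dropped with a warning; strata where good responders
#' fall short of the target keep all of them.
#'
#' @param calls Responder-call tibble (from [call_responders()]).
#' @param participants Tibble with `participant_id` and `race_ethnicity`.
#' @param ratio Good:poor target ratio (default 1).
#' @param seed Integer seed for the stratified draw.
#' @return Tibble of matched participants with `participant_id`, `group`,
#'   `race_ethnicity`.
#' @export
match_groups <- function(calls, participants, ratio = 1, seed = 1) {
  df <- dplyr::inner_join(calls, participants, by = "participant_id") |>
    dplyr::filter(.data$group %in% c("GOOD", "POOR"))
  assert_that(any(df$group == "GOOD") && any(df$group == "POOR"),
              "need at least one GOOD and one POOR call to match")
  with_seed(child_seed(seed, 17), {
    out <- df |>
      dplyr::group_by(.data$race_ethnicity) |>
      dplyr::group_modify(function(d, key) {
        poor <- d[d$group == "POOR", ]
        good <- d[d$group == "GOOD", ]
        if (nrow(poor) == 0) return(good[0, ])
        if (nrow(good) == 0) {
          warn(paste0("stratum '", key$race_ethnicity,
                      "' has poor responders but no good responders; dropped"))
          return(d[0, ])
        }
        take <- min(nrow(good), round(nrow(poor) * ratio))
        dplyr::bind_rows(poor, good[sample.int(nrow(good), take), ])
      }) |>
      dplyr::ungroup()
    dplyr::select(out, "participant_id", "group", "race_ethnicity")
  })
}
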