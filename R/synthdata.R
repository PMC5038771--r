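# Seeded generator of synthetic PD cohorts: 10 patients, four treatment
# sessions (S1 med off/DBS off, S2 med off/DBS on, S3 med on/DBS off, S4 both
# on), with session-dependent UPDRS total, UPDRS III and reflexive-saccade
# latency moments, a shared patient random effect inducing UPDRS-latency
# co-movement, and clinical/well-being scales. All scores are clamped to
# their scale bounds and integer-rounded.

#' Default cohort parameters
#'
#' Per-session means and SDs for UPDRS total, UPDRS III and reflexive-saccade
#' latency, cohort age and disease-duration moments, the patient
#' random-effect share `rho` of the score SDs, the latency-side patient
#' share `gamma` (coupling latency to the same patient effect, which induces
#' the parallel UPDRS/latency profiles), ranges for the session-independent
#' saccade parameters, and well-being scale moments.
#'
#' @return A list of class `cohort_params`.
#' @export
default_params <- function() {
  structure(list(
    n_patients = 10L,
    sessions = c("1", "2", "3", "4"),
    updrs_mean = c(66.6, 30.0, 58.1, 22.3),
    updrs_sd = c(13.8, 16.3, 13.5, 13.6),
    updrs3_mean = c(42.7, 17.8, 34.1, 10.9),
    updrs3_sd = c(11.3, 10.6, 10.8, 8.3),
    latency_mean = c(291.2, 199.6, 232.9, 183.2),
    latency_sd = c(93.1, 39.5, 82.7, 30),
    age_mean = 51.1, age_sd = 10.2,
    duration_mean = 11.3, duration_sd = 3.2,
    rho = 0.7,     # patient random-effect share of the score SDs
    gamma = 0.85,  # patient share of the latency SDs (UPDRS-latency coupling)
    amp_mean = 10.5, amp_sd = 1.1, amp_range = c(6, 15),
    dur_mean = 44, dur_sd = 2.5, dur_range = c(36, 52),
    vel_intercept = 240, vel_slope = 27, vel_sd = 35, vel_range = c(300, 760),
    pdq_mean = 70, pdq_sd = 14,
    aims_mean = 5, aims_sd = 2.5,
    epworth_mean = 9, epworth_sd = 3.5,
    noise_scale = 1 # multiplies all auxiliary residual SDs (0 = deterministic)
  ), class = "cohort_params")
}

#' Schema of a generated cohort table
#'
#' The patient number is declared `nominal` with role `identifier`; the
#' experiment presets promote it to a condition attribute where the published
#' rule format conditions on it.
#' @return A schema data frame.
#' @export
cohort_schema <- function() {
  schema(
    attribute_spec("Pat", "nominal", "identifier"),
    attribute_spec("age", "numeric", "condition", "years"),
    attribute_spec("sex", "nominal", "condition"),
    attribute_spec("t_dur", "numeric", "condition", "years"),
    attribute_spec("Sess", "nominal", "condition"),
    attribute_spec("UPDRS", "numeric", "condition", "score points"),
    attribute_spec("UPDRS_II", "numeric", "condition", "score points"),
    attribute_spec("UPDRS_III", "numeric", "condition", "score points"),
    attribute_spec("UPDRS_IV", "numeric", "condition", "score points"),
    attribute_spec("HYsc", "numeric", "condition", "stage"),
    attribute_spec("SEngs", "numeric", "condition", "%"),
    attribute_spec("PDQ39", "numeric", "condition", "score points"),
    attribute_spec("AIMS", "numeric", "condition", "score points"),
    attribute_spec("Epworth", "numeric", "condition", "score points"),
    attribute_spec("SccDur", "numeric", "condition", "ms"),
    attribute_spec("SccLat", "numeric", "condition", "ms"),
    attribute_spec("SccAmp", "numeric", "condition", "deg"),
    attribute_spec("SccVel", "numeric", "condition", "deg/s"))
}

clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)

#' Generate a synthetic cohort
#'
#' One record per patient x session. The per-session UPDRS total, UPDRS III
#' and latency draws share a patient-level standard-normal effect `z_p`
#' (weights `rho` for the scores, `gamma` for latency), so patients who are
#' more affected also have longer latencies in every session. Duration,
#' amplitude and velocity of the saccades are session-independent. Hoehn-Yahr
#' tracks the DBS state, Schwab-England falls with UPDRS total, PDQ-39 is
#' mostly a patient trait, AIMS rises slightly on medication.
#'
#' @param params A [default_params()] list (possibly modified).
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @param decision Optional decision attribute; if given, a `decisiontable`
#'   is returned (conditions: every other non-identifier attribute).
#' @return An `infotable` (or `decisiontable`) over [cohort_schema()].
#' @export
generate_cohort <- function(params = default_params(), seed = 1L,
                            decision = NULL) {
  np <- params$n_patients
  ns <- params$noise_scale
  pat_ids <- c(11, 14, 25, 27, 28, 38, 41, 45, 63, 64)
  pat_ids <- if (np <= length(pat_ids)) pat_ids[seq_len(np)] else
    c(pat_ids, 100L + seq_len(np - length(pat_ids)))
  rows <- rpd_with_seed(seed, {
    z_p <- stats::rnorm(np)
    z_q <- stats::rnorm(np); z_a <- stats::rnorm(np)
    z_d <- stats::rnorm(np); z_v <- stats::rnorm(np)
    z_aims <- stats::rnorm(np); z_epw <- stats::rnorm(np)
    age <- round(clamp(stats::rnorm(np, params$age_mean, params$age_sd), 30, 78))
    t_dur <- round(clamp(stats::rnorm(np, params$duration_mean,
                                      params$duration_sd), 2, 25))
    sex <- sample(c("0", "1"), np, replace = TRUE)
    out <- list()
    rho <- params$rho; gam <- params$gamma
    for (p in seq_len(np)) {
      for (s in seq_along(params$sessions)) {
        med <- s %in% c(3L, 4L); dbs <- s %in% c(2L, 4L)
        e <- function(sd) stats::rnorm(1, 0, sd * ns)
        u3 <- clamp(round(params$updrs3_mean[s] + params$updrs3_sd[s] *
                            (rho * z_p[p] + sqrt(1 - rho^2) * stats::rnorm(1) * ns)),
                    0, 56)
        u <- clamp(round(params$updrs_mean[s] + params$updrs_sd[s] *
                           (rho * z_p[p] + sqrt(1 - rho^2) * stats::rnorm(1) * ns)),
                   0, 108)
        u2 <- clamp(round(0.22 * u + e(1.5)), 0, 52)
        u4 <- clamp(round(2 + 2 * med + 0.8 * z_p[p] + e(1)), 0, 16)
        hy <- clamp(round(2 * (1.2 + 0.9 * (!dbs) + 0.15 * (!med) +
                                 0.35 * z_p[p] + e(0.15))) / 2, 1, 3)
        sengs <- clamp(5 * round((95 - 0.45 * u + e(4)) / 5), 40, 100)
        pdq <- clamp(round(params$pdq_mean + params$pdq_sd *
                             (0.6 * z_p[p] + 0.8 * z_q[p]) +
                             0.15 * (u - 45) + e(4)), 0, 156)
        aims <- clamp(round(params$aims_mean + params$aims_sd * z_aims[p] +
                              1.2 * med + e(1)), 0, 40)
        epw <- clamp(round(params$epworth_mean + params$epworth_sd * z_epw[p] +
                             e(1)), 0, 24)
        lat <- clamp(round(params$latency_mean[s] + params$latency_sd[s] *
                             (gam * z_p[p] + sqrt(1 - gam^2) * stats::rnorm(1) * ns),
                           1), 80, 650)
        amp <- clamp(round(params$amp_mean + params$amp_sd * z_a[p] + e(0.8)),
                     params$amp_range[1], params$amp_range[2])
        dur <- clamp(round(params$dur_mean + params$dur_sd * z_d[p] + e(1.5)),
                     params$dur_range[1], params$dur_range[2])
        vel <- clamp(round(params$vel_intercept + params$vel_slope * amp +
                             params$vel_sd * z_v[p] + e(25), 1),
                     params$vel_range[1], params$vel_range[2])
        out[[length(out) + 1L]] <- data.frame(
          Pat = as.character(pat_ids[p]), age = age[p], sex = sex[p],
          t_dur = t_dur[p], Sess = params$sessions[s], UPDRS = u,
          UPDRS_II = u2, UPDRS_III = u3, UPDRS_IV = u4, HYsc = hy,
          SEngs = sengs, PDQ39 = pdq, AIMS = aims, Epworth = epw,
          SccDur = dur, SccLat = lat, SccAmp = amp, SccVel = vel,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
  tab <- information_table(rows, cohort_schema())
  if (!is.null(decision)) tab <- as_decision_table(tab, decision)
  tab
}

# Affine-match a vector to a target mean/sd on a rounding grid, then nudge
# grid steps so the sample mean agrees with the target beyond the grid
# resolution (used to pin the calibrated cohort to its reference moments).
calibrate_vec <- function(v, mu, sdv, digits, lo, hi) {
  n <- length(v)
  m <- mean(v); s <- stats::sd(v)
  v2 <- if (is.na(s) || s == 0) rep(mu, n) else (v - m) / s * sdv + mu
  v2 <- round(clamp(v2, lo, hi), digits)
  step <- 10^(-digits)
  units <- round((mu - mean(v2)) * n / step)
  sgn <- sign(units); units <- abs(units)
  if (sgn != 0) {
    ord <- if (sgn > 0) order(v2) else order(-v2)
    i <- 0L
    while (units > 0L && i < 100L * n) {
      j <- ord[(i %% n) + 1L]
      cand <- v2[j] + sgn * step
      if (cand >= lo && cand <= hi) {
        v2[j] <- cand
        units <- units - 1L
      }
      i <- i + 1L
    }
  }
  v2
}

#' Synthetic cohort calibrated to the reference per-session moments
#'
#' A stand-in for the study's full data table: a generated cohort whose
#' sample means (age and disease duration cohort-wide; UPDRS total, UPDRS III
#' and latency per session) are pinned to the default-parameter values to one
#' decimal by an affine moment match followed by grid-step nudging. Scores
#' stay integers, latency keeps one decimal.
#'
#' @param seed Integer seed (default fixed so the shipped fixture reproduces).
#' @param params Cohort parameters.
#' @return An `infotable` over [cohort_schema()].
#' @export
calibrated_cohort <- function(seed = 20160914L, params = default_params()) {
  tab <- generate_cohort(params, seed = seed)
  df <- tab$data
  # patient-level attributes: calibrate the per-patient values, re-expand
  pat <- unique(df$Pat)
  for (spec in list(list(col = "age", mu = params$age_mean, sd = params$age_sd,
                         lo = 30, hi = 78),
                    list(col = "t_dur", mu = params$duration_mean,
                         sd = params$duration_sd, lo = 2, hi = 25))) {
    per <- df[[spec$col]][match(pat, df$Pat)]
    per <- calibrate_vec(per, spec$mu, spec$sd, 0, spec$lo, spec$hi)
    df[[spec$col]] <- per[match(df$Pat, pat)]
  }
  for (s in seq_along(params$sessions)) {
    sel <- df$Sess == params$sessions[s]
    df$UPDRS[sel] <- calibrate_vec(df$UPDRS[sel], params$updrs_mean[s],
                                   params$updrs_sd[s], 0, 0, 108)
    df$UPDRS_III[sel] <- calibrate_vec(df$UPDRS_III[sel], params$updrs3_mean[s],
                                       params$updrs3_sd[s], 0, 0, 56)
    df$SccLat[sel] <- calibrate_vec(df$SccLat[sel], params$latency_mean[s],
                                    params$latency_sd[s], 1, 80, 650)
  }
  information_table(df, cohort_schema())
}
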