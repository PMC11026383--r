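#' Specification of a synthetic post-infarction cohort
#'
#' Defines the study conditions the generator emulates: cohort size, MACE
#' prevalence, per-class distributions (given as `median (q25--q75)`, drawn
#' lognormal for positive scales and truncated-normal for bounded fractions)
#' for the RR-interval, its variability, EDV, EF, the passive-filling fraction
#' of stroke volume, systolic time, diastasis duration and volume noise, the
#' per-class probability of a transient with no diastasis, and the follow-up
#' horizon. Defaults target a ~1000-patient acute-myocardial-infarction cohort
#' with ~7% 12-month MACE prevalence, shorter and more variable RR, lower EF
#' and shorter diastasis in the MACE class, and roughly a fifth of the cohort
#' without a detectable diastasis.
#'
#' @param n_patients cohort size.
#' @param mace_rate event prevalence in (0, 1).
#' @param seed integer RNG seed used by [generate_cohort()].
#' @param n_frames_range inclusive integer range of frames per cycle.
#' @param horizon_months follow-up horizon.
#' @param classes named list (`no_mace`, `mace`) of per-class parameter lists;
#'   see Details. Any supplied entry overrides the default.
#' @details Each class list holds `rr`, `rr_var`, `edv`, `ef`, `passive_frac`,
#'   `systolic`, `diastasis`, `active_time` as `c(median, q25, q75)`, plus
#'   scalars `noise_sd_ml` and `prob_no_diastasis`. `active_time` is the
#'   duration of the active (atrial) filling segment; passive filling takes
#'   whatever diastolic time remains, which keeps every phase physiologically
#'   resolvable at the scan frame rate.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 1000, mace_rate = 0.072, seed = 1,
                        n_frames_range = c(25, 30), horizon_months = 12,
                        classes = list()) {
  stopifnot(n_patients >= 2, mace_rate > 0, mace_rate < 1,
            length(n_frames_range) == 2, n_frames_range[1] >= 10,
            n_frames_range[2] >= n_frames_range[1], horizon_months > 0)
  default <- list(
    no_mace = list(
      rr = c(845, 741, 952), rr_var = c(18.9, 13.0, 25.6),
      edv = c(150, 125, 180), ef = c(51, 44, 58),
      passive_frac = c(0.664, 0.582, 0.730),
      systolic = c(298, 268, 328), diastasis = c(60, 30, 115),
      active_time = c(150, 130, 175),
      noise_sd_ml = 1.0, prob_no_diastasis = 0.17
    ),
    mace = list(
      rr = c(780, 674, 848), rr_var = c(24.6, 14.2, 36.7),
      edv = c(160, 130, 195), ef = c(43, 35, 50),
      passive_frac = c(0.673, 0.578, 0.789),
      systolic = c(284, 265, 321), diastasis = c(40, 18, 80),
      active_time = c(135, 115, 160),
      noise_sd_ml = 1.0, prob_no_diastasis = 0.22
    )
  )
  for (cl in names(classes)) {
    stopifnot(cl %in% names(default))
    default[[cl]][names(classes[[cl]])] <- classes[[cl]]
  }
  for (cl in default) {
    stopifnot(all(vapply(cl[c("rr", "rr_var", "edv", "ef", "passive_frac",
                              "systolic", "diastasis", "active_time")],
                         function(x) length(x) == 3 && all(is.finite(x)) &&
                           x[1] > 0, logical(1))),
              cl$noise_sd_ml >= 0,
              cl$prob_no_diastasis >= 0, cl$prob_no_diastasis <= 1)
  }
  out <- list(n_patients = as.integer(n_patients), mace_rate = mace_rate,
              seed = as.integer(seed),
              n_frames_range = as.integer(n_frames_range),
              horizon_months = horizon_months, classes = default)
  class(out) <- "cohort_spec"
  out
}

# Draw one patient's generator parameters for a given class. The diastolic
# partition is drawn feasibly and physiologically by construction: the active
# (atrial) segment keeps a realistic duration, diastasis is capped relative
# to the remaining diastole (short cycles lose their diastasis first), and
# passive filling takes the rest, so no phase collapses below what the frame
# rate can resolve.
draw_patient_params <- function(cl, n_frames_range) {
  rr <- rlnorm_mq(1, cl$rr[1], cl$rr[2], cl$rr[3])
  ts <- rlnorm_mq(1, cl$systolic[1], cl$systolic[2], cl$systolic[3])
  ts <- min(ts, 0.55 * rr)
  diastole <- rr - ts
  ta <- min(max(rlnorm_mq(1, cl$active_time[1], cl$active_time[2],
                          cl$active_time[3]), 80), 0.4 * diastole)
  td <- if (stats::runif(1) < cl$prob_no_diastasis) 0 else
    min(rlnorm_mq(1, cl$diastasis[1], cl$diastasis[2], cl$diastasis[3]),
        0.35 * (diastole - ta))
  tp <- diastole - ta - td
  list(
    rr_ms = rr,
    edv_ml = rlnorm_mq(1, cl$edv[1], cl$edv[2], cl$edv[3]),
    ef_pct = rtnorm_mq(1, cl$ef[1], cl$ef[2], cl$ef[3], lo = 15, hi = 75),
    systolic_ms = ts, passive_ms = tp, diastasis_ms = td,
    passive_fraction = rtnorm_mq(1, cl$passive_frac[1], cl$passive_frac[2],
                                 cl$passive_frac[3], lo = 0.3, hi = 0.95),
    rr_var_pct = rlnorm_mq(1, cl$rr_var[1], cl$rr_var[2], cl$rr_var[3]),
    n_frames = sample(seq(n_frames_range[1], n_frames_range[2]), 1),
    noise_sd_ml = cl$noise_sd_ml
  )
}

#' Generate a synthetic cohort of volume transients, covariates and outcomes
#'
#' Draws MACE labels Bernoulli(`mace_rate`), per-class generator parameters
#' from the spec distributions, samples each patient's transient with
#' [generate_transient()], builds a three-value RR metadata list realizing the
#' planted RR mean and variability, assigns event times uniform on
#' `(0, horizon]` for cases (controls censored at the horizon), and assembles
#' the cohort feature table (true ESV/EDV/EF analogues plus two noise
#' covariates). Fully reproducible under the spec seed.
#'
#' @param spec a [cohort_spec()].
#' @return list with `patients` (per-patient records incl. the transient, RR
#'   metadata and the planted ground truth), `transients`, `rr_lists`, and
#'   `features` (one row per patient: covariates, `outcome`, `time_months`,
#'   `censored`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  outcome <- stats::rbinom(n, 1, spec$mace_rate)
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- spec$classes[[if (outcome[i] == 1) "mace" else "no_mace"]]
    dp <- draw_patient_params(cl, spec$n_frames_range)
    p <- transient_params(dp$rr_ms, dp$edv_ml, dp$ef_pct, dp$systolic_ms,
                          dp$passive_ms, dp$diastasis_ms, dp$passive_fraction)
    id <- sprintf("S%04d", i)
    tr <- generate_transient(p, n_frames = dp$n_frames,
                             noise_sd_ml = dp$noise_sd_ml, patient_id = id)
    # three RR readings realizing the planted mean and (max-min)/mean
    rr_list <- dp$rr_ms * (1 + c(-1, 0, 1) * dp$rr_var_pct / 200)
    ev_time <- if (outcome[i] == 1) {
      stats::runif(1, 0, spec$horizon_months)
    } else {
      spec$horizon_months
    }
    if (ev_time == 0) ev_time <- .Machine$double.eps
    patients[[i]] <- list(
      patient_id = id,
      transient = tr,
      rr_ms = dp$rr_ms, rr_variability_pct = dp$rr_var_pct,
      rr_list = rr_list,
      covariates = c(esv_ml = p$esv_ml, edv_ml = p$edv_ml,
                     ef_pct = p$ef_pct,
                     noise1 = stats::rnorm(1), noise2 = stats::rnorm(1)),
      outcome = outcome[i],
      event_time_months = ev_time,
      censored = outcome[i] == 0,
      planted = attr(tr, "planted")
    )
  }
  features <- data.frame(
    patient_id = vapply(patients, `[[`, character(1), "patient_id"),
    do.call(rbind, lapply(patients, `[[`, "covariates")),
    outcome = outcome,
    time_months = vapply(patients, `[[`, numeric(1), "event_time_months"),
    censored = vapply(patients, `[[`, logical(1), "censored"),
    stringsAsFactors = FALSE
  )
  list(patients = patients,
       transients = lapply(patients, `[[`, "transient"),
       rr_lists = lapply(patients, `[[`, "rr_list"),
       features = features)
}

#' Write cohort transients as a long CSV
#'
#' Columns: `patient_id, trigger_time_ms, volume_ml, rr_ms`.
#'
#' @param transients list of [volume_transient()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_transients_csv <- function(transients, path) {
  rows <- lapply(transients, function(tr) {
    data.frame(patient_id = tr$patient_id,
               trigger_time_ms = tr$trigger_times_ms,
               volume_ml = tr$volumes_ml, rr_ms = tr$rr_ms,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read transients written by [write_transients_csv()]
#'
#' @param path CSV path.
#' @return named list of [volume_transient()] objects.
#' @export
read_transients_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("patient_id", "trigger_time_ms", "volume_ml", "rr_ms")
                %in% names(df)))
  ids <- unique(df$patient_id)
  out <- lapply(ids, function(id) {
    d <- df[df$patient_id == id, ]
    volume_transient(d$trigger_time_ms, d$volume_ml, rr_ms = d$rr_ms[1],
                     patient_id = id)
  })
  names(out) <- ids
  out
}
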