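#' Adjudicate the composite 12-month endpoint
#'
#' Combines per-patient component events (all-cause death, reinfarction, new
#' congestive heart failure) into the composite MACE outcome: a patient is a
#' case when any component occurs within the horizon, contributes only once,
#' with the component chosen by priority death > reinfarction > congestive
#' heart failure, and the event time is that component's time. Patients with
#' no qualifying event are controls censored at the horizon; events after the
#' horizon are ignored.
#'
#' @param records data.frame with `patient_id` and months-to-event columns
#'   `death_month`, `reinfarction_month`, `chf_month` (`NA` = no such event).
#' @param horizon_months follow-up horizon (default 12).
#' @return data.frame: `patient_id`, `outcome` (0/1), `event_type`
#'   (`"death"`, `"reinfarction"`, `"chf"` or `NA`), `time_months`,
#'   `censored`.
#' @export
adjudicate_endpoint <- function(records, horizon_months = 12) {
  need <- c("patient_id", "death_month", "reinfarction_month", "chf_month")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  comp <- c("death", "reinfarction", "chf")
  cols <- c("death_month", "reinfarction_month", "chf_month")
  out <- lapply(seq_len(nrow(records)), function(i) {
    times <- as.numeric(records[i, cols])
    times[!is.na(times) & (times > horizon_months | times <= 0)] <- NA
    hit <- which(!is.na(times))[1]  # priority = column order
    if (is.na(hit)) {
      data.frame(patient_id = records$patient_id[i], outcome = 0L,
                 event_type = NA_character_, time_months = horizon_months,
                 censored = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(patient_id = records$patient_id[i], outcome = 1L,
                 event_type = comp[hit], time_months = times[hit],
                 censored = FALSE, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Rank-based AUC (Mann-Whitney)
#'
#' Probability that a random case scores above a random control; ties count
#' one half. Equals the normalized Mann-Whitney U statistic.
#'
#' @param scores numeric risk scores.
#' @param labels binary outcome (0/1 or logical).
#' @return AUC in `[0, 1]`, `NA` (with a warning) when one class is absent.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- as.numeric(sum(labels == 1L)); n0 <- as.numeric(sum(labels == 0L))
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined: one class absent")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Harrell's concordance index
#'
#' Concordance over comparable pairs: a pair is comparable when the earlier
#' time is an observed event; it is concordant when the earlier-failing
#' patient has the higher risk score, with risk ties counted one half. Tied
#' event times are not comparable.
#'
#' @param risk numeric risk scores (higher = earlier expected failure).
#' @param time follow-up or event times.
#' @param event event indicator (1 = event, 0 = censored).
#' @return C-index in `[0, 1]`, `NA` (with a warning) without comparable
#'   pairs.
#' @export
c_index <- function(risk, time, event) {
  stopifnot(length(risk) == length(time), length(time) == length(event))
  event <- as.integer(as.logical(event))
  n <- length(risk)
  conc <- 0; comp <- 0
  # comparable pairs: i fails first (t_i < t_j, e_i = 1)
  for (i in which(event == 1L)) {
    later <- which(time > time[i])
    if (!length(later)) next
    comp <- comp + length(later)
    conc <- conc + sum(risk[i] > risk[later]) + 0.5 * sum(risk[i] == risk[later])
  }
  if (comp == 0) {
    warning("C-index undefined: no comparable pairs")
    return(NA_real_)
  }
  conc / comp
}

# ---- model fitting helpers ---------------------------------------------

# Fit one family on a data.frame with columns `vars` (+ outcome/time/censored)
# and return a scoring closure. family: "lda" (Fisher discriminant, scored by
# case posterior), "cox" (scored by linear predictor), "score" (no fitting:
# the single variable itself is the risk score).
fit_risk_model <- function(train, vars, family) {
  if (family == "score") {
    stopifnot(length(vars) == 1)
    v <- vars
    return(list(predict = function(newdata) newdata[[v]]))
  }
  if (family == "lda") {
    fit <- MASS::lda(x = as.matrix(train[, vars, drop = FALSE]),
                     grouping = factor(train$outcome, levels = c(0, 1)))
    return(list(
      fit = fit,
      predict = function(newdata) {
        stats::predict(fit,
                       newdata = as.matrix(newdata[, vars, drop = FALSE])
        )$posterior[, "1"]
      }))
  }
  if (family == "cox") {
    fml <- stats::as.formula(paste(
      "survival::Surv(time_months, 1 - censored) ~",
      paste(vars, collapse = " + ")))
    fit <- survival::coxph(fml, data = train)
    return(list(
      fit = fit,
      predict = function(newdata) {
        unname(stats::predict(fit, newdata = newdata, type = "lp"))
      }))
  }
  stop("unknown family: ", family)
}

# Wald p-values per variable for the selection refits. LDA significance is
# approximated by the binomial (logistic) GLM, Cox by the partial-likelihood
# Wald test. Returns list(p = named p-values, issue = name of a variable to
# drop for numerical reasons, or NULL).
selection_pvalues <- function(data, vars, family) {
  if (family == "lda") {
    fml <- stats::as.formula(paste("outcome ~", paste(vars, collapse = " + ")))
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(fml, data = data, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  conditionMessage(w))) {
          sep <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    sm <- stats::coef(summary(fit))
    coefs <- stats::coef(fit)[-1]
    aliased <- names(coefs)[is.na(coefs)]
    if (length(aliased)) {
      return(list(p = NULL, issue = utils::tail(aliased, 1),
                  reason = "collinear (aliased)"))
    }
    if (sep || !fit$converged) {
      se <- sm[-1, "Std. Error"]
      return(list(p = NULL, issue = names(which.max(se)),
                  reason = "separation/non-convergence"))
    }
    p <- sm[-1, "Pr(>|z|)"]
    names(p) <- rownames(sm)[-1]
    return(list(p = p, issue = NULL))
  }
  if (family == "cox") {
    fml <- stats::as.formula(paste(
      "survival::Surv(time_months, 1 - censored) ~",
      paste(vars, collapse = " + ")))
    fit <- tryCatch(survival::coxph(fml, data = data),
                    warning = function(w) w, error = function(e) e)
    if (inherits(fit, "condition")) {
      return(list(p = NULL, issue = utils::tail(vars, 1),
                  reason = paste("cox fit failed:",
                                 conditionMessage(fit))))
    }
    coefs <- stats::coef(fit)
    aliased <- names(coefs)[is.na(coefs)]
    if (length(aliased)) {
      return(list(p = NULL, issue = utils::tail(aliased, 1),
                  reason = "collinear (aliased)"))
    }
    sm <- stats::coef(summary(fit))
    p <- sm[, "Pr(>|z|)"]
    names(p) <- rownames(sm)
    return(list(p = p, issue = NULL))
  }
  stop("unknown family: ", family)
}

#' Backward stepwise variable selection
#'
#' Starts from all candidate predictors and iteratively removes the least
#' significant one until every retained variable meets the `alpha` threshold.
#' Significance is the Wald p-value from a binomial (logistic) GLM refit for
#' the discriminant family, and from the Cox partial likelihood for the
#' survival family. Patients with missing data in any candidate are excluded
#' (complete-case). Collinear (aliased) variables are dropped later-listed
#' first; perfect separation or non-convergence drops the offending variable
#' with a logged reason. An empty selection is a valid result.
#'
#' @param features feature data.frame with `outcome` (0/1) and, for the Cox
#'   family, `time_months` and `censored`.
#' @param candidates character vector of predictor columns.
#' @param family `"lda"` or `"cox"`.
#' @param alpha retention threshold on the per-variable p-value (default
#'   0.05).
#' @param standardize z-score continuous predictors before fitting (so Cox
#'   hazard ratios are per SD); default `TRUE`.
#' @return object of class `stepwise_model`: `family`, `selected`,
#'   `coefficients`, `p_values`, `n_used`, `trace` (one row per elimination:
#'   variable, p-value or reason), `alpha`, `scaling`. For `family = "lda"`
#'   the Fisher discriminant coefficients are exposed alongside the GLM
#'   coefficients.
#' @export
backward_stepwise <- function(features, candidates, family = c("lda", "cox"),
                              alpha = 0.05, standardize = TRUE) {
  family <- match.arg(family)
  stopifnot(length(candidates) >= 1, all(candidates %in% names(features)))
  need <- c(candidates, "outcome",
            if (family == "cox") c("time_months", "censored"))
  data <- features[stats::complete.cases(features[, need]), need, drop = FALSE]
  n_used <- nrow(data)
  if (n_used < 10 * length(candidates)) {
    warning("fewer than 10 complete cases per candidate variable")
  }
  scaling <- NULL
  if (standardize) {
    scaling <- lapply(candidates, function(v) {
      x <- data[[v]]
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0) s <- 1
      c(center = mean(x), scale = s)
    })
    names(scaling) <- candidates
    for (v in candidates) {
      data[[v]] <- (data[[v]] - scaling[[v]]["center"]) / scaling[[v]]["scale"]
    }
  }

  current <- candidates
  trace <- data.frame(step = integer(), variable = character(),
                      p_value = numeric(), reason = character(),
                      stringsAsFactors = FALSE)
  step <- 0L
  p <- NULL
  while (length(current)) {
    res <- selection_pvalues(data, current, family)
    step <- step + 1L
    if (!is.null(res$issue)) {
      trace <- rbind(trace, data.frame(step = step, variable = res$issue,
                                       p_value = NA_real_,
                                       reason = res$reason,
                                       stringsAsFactors = FALSE))
      current <- setdiff(current, res$issue)
      next
    }
    p <- res$p
    if (max(p) < alpha) break
    worst <- names(which.max(p))
    trace <- rbind(trace, data.frame(step = step, variable = worst,
                                     p_value = unname(max(p)),
                                     reason = sprintf("p >= %.2f", alpha),
                                     stringsAsFactors = FALSE))
    current <- setdiff(current, worst)
    p <- NULL
  }

  coefficients <- NULL
  lda_coefficients <- NULL
  p_values <- numeric(0)
  if (length(current)) {
    res <- selection_pvalues(data, current, family)
    p_values <- res$p
    if (family == "lda") {
      fml <- stats::as.formula(paste("outcome ~",
                                     paste(current, collapse = " + ")))
      coefficients <- stats::coef(
        stats::glm(fml, data = data, family = stats::binomial()))
      lda_fit <- MASS::lda(x = as.matrix(data[, current, drop = FALSE]),
                           grouping = factor(data$outcome,
                                             levels = c(0, 1)))
      lda_coefficients <- drop(lda_fit$scaling)
    } else {
      fml <- stats::as.formula(paste(
        "survival::Surv(time_months, 1 - censored) ~",
        paste(current, collapse = " + ")))
      coefficients <- stats::coef(survival::coxph(fml, data = data))
    }
  }
  out <- list(family = family, selected = current,
              coefficients = coefficients,
              lda_coefficients = lda_coefficients,
              p_values = p_values, n_used = n_used, trace = trace,
              alpha = alpha, scaling = scaling)
  class(out) <- "stepwise_model"
  out
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat(sprintf("Backward stepwise %s model (alpha = %.2f, n = %d)\n",
              toupper(x$family), x$alpha, x$n_used))
  if (length(x$selected)) {
    for (v in x$selected) {
      cat(sprintf("  %-24s p = %.3g\n", v, x$p_values[v]))
    }
  } else {
    cat("  (empty selection)\n")
  }
  if (nrow(x$trace)) {
    cat(sprintf("  eliminated: %s\n",
                paste(x$trace$variable, collapse = ", ")))
  }
  invisible(x)
}

#' Repeated stratified k-fold performance of a fixed variable list
#'
#' Evaluates a model (variables fixed in advance; selection is not re-run per
#' fold) in resubstitution and under repeated stratified k-fold
#' cross-validation: for each of `n_splits` random splits, folds are
#' stratified by outcome, coefficients are refit on the training folds,
#' out-of-fold risk scores are pooled, and one AUC (LDA) or C-index (Cox) is
#' recorded per split. Splits whose training folds lack a class or an event
#' are redrawn (logged in `n_redraws`). Split `s` uses RNG seed
#' `seed + s - 1`, so results are fully reproducible.
#'
#' @inheritParams backward_stepwise
#' @param vars character vector of model variables (fixed).
#' @param family `"lda"`, `"cox"`, or `"score"` (a single variable used as
#'   the risk score without fitting).
#' @param k folds (default 10).
#' @param n_splits random splits (default 100).
#' @param seed base RNG seed.
#' @param metric `"auc"` or `"c_index"`; default by family.
#' @return object of class `cv_performance`: `metric`, `resubstitution`,
#'   `splits` (one value per split), `median`, `iqr`, `k`, `n_splits`,
#'   `seed`, `n_used`, `n_redraws`.
#' @export
evaluate_cv <- function(features, vars, family = c("lda", "cox", "score"),
                        k = 10, n_splits = 100, seed = 1, metric = NULL) {
  family <- match.arg(family)
  stopifnot(k >= 2, n_splits >= 1, all(vars %in% names(features)))
  metric <- metric %||% if (family == "cox") "c_index" else "auc"
  stopifnot(metric %in% c("auc", "c_index"))
  need <- c(vars, "outcome",
            if (metric == "c_index" || family == "cox")
              c("time_months", "censored"))
  data <- features[stats::complete.cases(features[, unique(need)]),
                unique(c(need, "outcome")), drop = FALSE]
  n <- nrow(data)
  if (min(table(data$outcome)) < k) {
    stop("fewer outcome-class members than folds")
  }
  score_of <- function(model, d) model$predict(d)
  measure <- function(scores, d) {
    if (metric == "auc") auc(scores, d$outcome)
    else c_index(scores, d$time_months, 1 - d$censored)
  }

  full <- fit_risk_model(data, vars, family)
  resub <- measure(score_of(full, data), data)

  splits <- numeric(n_splits)
  n_redraws <- 0L
  for (s in seq_len(n_splits)) {
    set.seed(seed + s - 1L)
    repeat {
      fold <- integer(n)
      for (cls in unique(data$outcome)) {   # stratified fold assignment
        idx <- sample(which(data$outcome == cls))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
      ok <- TRUE
      oof <- rep(NA_real_, n)
      for (f in seq_len(k)) {
        tr <- data[fold != f, , drop = FALSE]
        if (length(unique(tr$outcome)) < 2 ||
            (family == "cox" && sum(1 - tr$censored) == 0)) {
          ok <- FALSE
          break
        }
        model <- if (family == "score") full else fit_risk_model(tr, vars, family)
        oof[fold == f] <- score_of(model, data[fold == f, , drop = FALSE])
      }
      if (ok) break
      n_redraws <- n_redraws + 1L
    }
    splits[s] <- measure(oof, data)
  }
  out <- list(metric = metric, resubstitution = resub, splits = splits,
              median = stats::median(splits),
              iqr = unname(stats::quantile(splits, c(0.25, 0.75))),
              k = as.integer(k), n_splits = as.integer(n_splits),
              seed = seed, n_used = n, n_redraws = n_redraws,
              family = family, vars = vars)
  class(out) <- "cv_performance"
  out
}

#' @export
print.cv_performance <- function(x, ...) {
  lab <- if (x$metric == "auc") "AUC" else "C-index"
  cat(sprintf(
    "%s (%s, %d vars, n = %d): resubstitution %.3f | %d x %d-fold CV median %.3f (IQR %.3f-%.3f)\n",
    lab, toupper(x$family), length(x$vars), x$n_used, x$resubstitution,
    x$n_splits, x$k, x$median, x$iqr[1], x$iqr[2]))
  invisible(x)
}

#' Compare two cross-validated performance distributions
#'
#' Two-sided Wilcoxon rank-sum test on the per-split metric values of two
#' models evaluated with the same metric and number of splits.
#'
#' @param a,b [evaluate_cv()] results.
#' @return the p-value.
#' @export
compare_performance <- function(a, b) {
  stopifnot(inherits(a, "cv_performance"), inherits(b, "cv_performance"))
  if (a$metric != b$metric) stop("mismatched metrics")
  if (a$n_splits != b$n_splits) stop("mismatched number of splits")
  suppressWarnings(
    stats::wilcox.test(a$splits, b$splits, exact = FALSE)$p.value)
}

#' Univariate prognostic summary of one feature
#'
#' One table row per feature: median (IQR) overall and per class, Wilcoxon
#' rank-sum p-value for the class comparison, the repeated cross-validated
#' univariate discriminant AUC, and the per-SD univariate Cox hazard ratio
#' with 95% CI and p-value. A constant feature yields p = 1, AUC = 0.5 and a
#' flagged undefined HR.
#'
#' @inheritParams evaluate_cv
#' @param feature feature column name.
#' @return one-row data.frame.
#' @export
univariate_summary <- function(features, feature, k = 10, n_splits = 100,
                               seed = 1) {
  stopifnot(feature %in% names(features))
  keep <- stats::complete.cases(features[, c(feature, "outcome")])
  d <- features[keep, , drop = FALSE]
  x <- d[[feature]]
  if (min(table(d$outcome)) < 2) stop("need >= 2 non-missing values per class")
  fmt <- function(v) {
    q <- stats::quantile(v, c(0.5, 0.25, 0.75), names = FALSE)
    sprintf("%.3g (%.3g-%.3g)", q[1], q[2], q[3])
  }
  if (stats::sd(x) == 0) {
    return(data.frame(
      feature = feature, all = fmt(x), mace = fmt(x[d$outcome == 1]),
      no_mace = fmt(x[d$outcome == 0]), auc_k = 0.5, p_value = 1,
      hr = NA_real_, hr_lo = NA_real_, hr_hi = NA_real_,
      hr_p_value = NA_real_, hr_undefined = TRUE, n = nrow(d),
      stringsAsFactors = FALSE))
  }
  pw <- suppressWarnings(
    stats::wilcox.test(x[d$outcome == 1], x[d$outcome == 0],
                       exact = FALSE)$p.value)
  cv <- evaluate_cv(d, feature, family = "lda", k = k, n_splits = n_splits,
                    seed = seed, metric = "auc")
  hr <- c(NA_real_, NA_real_, NA_real_, NA_real_)
  if (all(c("time_months", "censored") %in% names(d))) {
    z <- (x - mean(x)) / stats::sd(x)
    cf <- tryCatch({
      fit <- survival::coxph(
        survival::Surv(d$time_months, 1 - d$censored) ~ z)
      sm <- summary(fit)
      c(sm$conf.int[1, c("exp(coef)", "lower .95", "upper .95")],
        sm$coefficients[1, "Pr(>|z|)"])
    }, error = function(e) hr, warning = function(w) hr)
    hr <- as.numeric(cf)
  }
  data.frame(
    feature = feature, all = fmt(x), mace = fmt(x[d$outcome == 1]),
    no_mace = fmt(x[d$outcome == 0]), auc_k = cv$median, p_value = pw,
    hr = hr[1], hr_lo = hr[2], hr_hi = hr[3], hr_p_value = hr[4],
    hr_undefined = any(is.na(hr)), n = nrow(d), stringsAsFactors = FALSE)
}
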