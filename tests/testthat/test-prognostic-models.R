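test_that("composite endpoint adjudication applies the death > reinfarction > CHF priority", {
  rec <- data.frame(patient_id = c("a", "b", "c", "d"),
                    death_month = c(5, NA, NA, 14),
                    reinfarction_month = c(2, 3, NA, NA),
                    chf_month = c(NA, 1, NA, NA),
                    stringsAsFactors = FALSE)
  out <- adjudicate_endpoint(rec)
  # multiple events count once, as the highest-priority component
  expect_equal(out$event_type[1], "death")
  expect_equal(out$time_months[1], 5)
  expect_equal(out$event_type[2], "reinfarction")
  expect_equal(out$time_months[2], 3)
  # no events (or events beyond the horizon): control censored at 12 months
  expect_equal(out$outcome[3:4], c(0L, 0L))
  expect_true(all(out$censored[3:4]))
  expect_equal(out$time_months[3:4], c(12, 12))
})

test_that("component counts 20 CHF + 21 reinfarction + 32 deaths compose to 73 events", {
  n <- c(chf = 20, reinfarction = 21, death = 32)
  rec <- data.frame(
    patient_id = sprintf("p%03d", 1:100),
    death_month = c(seq(0.5, 11.5, length.out = n["death"]),
                    rep(NA, 100 - n["death"])),
    reinfarction_month = c(rep(NA, n["death"]),
                           seq(0.5, 11.5, length.out = n["reinfarction"]),
                           rep(NA, 100 - n["death"] - n["reinfarction"])),
    chf_month = c(rep(NA, n["death"] + n["reinfarction"]),
                  seq(0.5, 11.5, length.out = n["chf"]),
                  rep(NA, 100 - sum(n))),
    stringsAsFactors = FALSE)
  out <- adjudicate_endpoint(rec)
  expect_equal(sum(out$outcome), 73)
  expect_equal(as.integer(table(out$event_type)[c("chf", "reinfarction",
                                                  "death")]),
               c(20L, 21L, 32L))
})

test_that("rank AUC matches its closed forms and the Mann-Whitney statistic", {
  lab <- c(rep(0, 6), rep(1, 4))
  expect_equal(auc(seq_along(lab), lab), 1)
  expect_equal(auc(rev(seq_along(lab)), lab), 0)
  expect_equal(auc(rep(1, 10), lab), 0.5)
  set.seed(3)
  sc <- rnorm(60)
  lb <- rbinom(60, 1, 0.4)
  w <- stats::wilcox.test(sc[lb == 1], sc[lb == 0], exact = FALSE)
  expect_equal(auc(sc, lb),
               unname(w$statistic) / (sum(lb == 1) * sum(lb == 0)))
  expect_warning(expect_true(is.na(auc(sc, rep(1, 60)))), "absent")
})

test_that("Harrell's C matches brute-force enumeration and survival::concordance", {
  set.seed(5)
  n <- 20
  risk <- rnorm(n)
  time <- rexp(n, 0.1)
  event <- rbinom(n, 1, 0.6)
  brute <- function(risk, time, event) {
    conc <- 0; comp <- 0
    for (i in 1:n) for (j in 1:n) {
      if (i == j) next
      if (event[i] == 1 && time[i] < time[j]) {
        comp <- comp + 1
        conc <- conc + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
      }
    }
    conc / comp
  }
  expect_equal(c_index(risk, time, event), brute(risk, time, event))
  cs <- survival::concordance(survival::Surv(time, event) ~ risk,
                              reverse = TRUE)
  expect_equal(c_index(risk, time, event), unname(cs$concordance))
  # perfect ranking: higher risk fails strictly earlier
  expect_equal(c_index(-time, time, rep(1, n)), 1)
  expect_warning(expect_true(is.na(c_index(risk, rep(1, n), rep(1, n)))),
                 "comparable")
})

test_that("with binary outcomes at a fixed horizon, C reduces to the AUC of the risk", {
  set.seed(6)
  outcome <- rbinom(50, 1, 0.4)
  risk <- rnorm(50) + outcome
  time <- ifelse(outcome == 1, 6, 12)
  expect_equal(c_index(risk, time, outcome), auc(risk, outcome))
})

test_that("backward stepwise keeps planted effects, sheds noise, and stops at the 0.05 rule", {
  tab <- make_feature_table(1000, shifts = c(x1 = 1, x2 = 1), n_noise = 8,
                            seed = 7)
  for (fam in c("lda", "cox")) {
    fit <- backward_stepwise(tab, c("x1", "x2", paste0("z", 1:8)),
                             family = fam)
    expect_true(all(c("x1", "x2") %in% fit$selected))
    expect_true(all(fit$p_values < 0.05))
    expect_true(all(fit$trace$variable %in% paste0("z", 1:8)))
  }
})

test_that("stepwise elimination drops the currently least significant variable each time", {
  tab <- make_feature_table(800, shifts = c(x1 = 0.8), n_noise = 5, seed = 9)
  fit <- backward_stepwise(tab, c("x1", paste0("z", 1:5)), family = "lda")
  # every recorded elimination was at or above the threshold at its step
  expect_true(all(fit$trace$p_value >= 0.05 | is.na(fit$trace$p_value)))
  expect_equal(fit$trace$step, seq_len(nrow(fit$trace)))
})

test_that("collinear candidates are resolved by dropping the later-listed variable", {
  tab <- make_feature_table(500, shifts = c(x1 = 1), seed = 11)
  tab$x1_copy <- tab$x1
  fit <- backward_stepwise(tab, c("x1", "x1_copy"), family = "lda")
  expect_true("x1" %in% fit$selected)
  expect_false("x1_copy" %in% fit$selected)
  expect_match(fit$trace$reason[fit$trace$variable == "x1_copy"], "collinear")
})

test_that("an empty selection is a valid stepwise result", {
  tab <- make_feature_table(400, shifts = c(x1 = 0), seed = 13)  # x1 is noise
  fit <- backward_stepwise(tab, "x1", family = "lda")
  expect_true(length(fit$selected) %in% c(0L, 1L))  # retained ~5% of the time
})

test_that("repeated stratified k-fold evaluation is reproducible and sane", {
  tab <- make_feature_table(400, prevalence = 0.2, shifts = c(x1 = 1),
                            n_noise = 1, seed = 15)
  a <- evaluate_cv(tab, c("x1", "z1"), family = "lda", k = 10, n_splits = 20,
                   seed = 99)
  b <- evaluate_cv(tab, c("x1", "z1"), family = "lda", k = 10, n_splits = 20,
                   seed = 99)
  expect_identical(a$splits, b$splits)
  expect_true(all(a$splits > 0.5))             # planted signal
  expect_lte(a$median, a$resubstitution + 0.02) # optimism direction
  expect_gte(a$median, a$iqr[1])
  expect_lte(a$median, a$iqr[2])

  cx <- evaluate_cv(tab, "x1", family = "cox", k = 5, n_splits = 10, seed = 1)
  expect_equal(cx$metric, "c_index")
  expect_true(all(cx$splits > 0.5 & cx$splits < 1))
})

test_that("fixed-score models evaluate identically in CV and resubstitution", {
  tab <- make_feature_table(300, shifts = c(x1 = 0.8), seed = 17)
  cv <- evaluate_cv(tab, "x1", family = "score", k = 10, n_splits = 5,
                    seed = 3)
  expect_true(all(cv$splits == cv$resubstitution))
})

test_that("pure-noise models cross-validate to chance level", {
  # balanced classes: with rare events a single dataset's CV AUC has
  # sampling spread wider than the chance band being asserted
  tab <- make_feature_table(1000, prevalence = 0.5, shifts = c(x1 = 0),
                            n_noise = 2, seed = 19)  # all features are noise
  cv <- evaluate_cv(tab, c("x1", "z1", "z2"), family = "lda", k = 10,
                    n_splits = 30, seed = 7)
  expect_gt(cv$median, 0.45)
  expect_lt(cv$median, 0.55)
})

test_that("performance comparison is a rank-sum test on the split distributions", {
  tab <- make_feature_table(400, prevalence = 0.25,
                            shifts = c(x1 = 1.2, x2 = 0.1), seed = 21)
  strong <- evaluate_cv(tab, "x1", family = "lda", k = 5, n_splits = 30,
                        seed = 5)
  weak <- evaluate_cv(tab, "x2", family = "lda", k = 5, n_splits = 30,
                      seed = 5)
  expect_lt(compare_performance(strong, weak), 0.001)
  expect_equal(compare_performance(strong, strong), 1)
  weak$metric <- "c_index"
  expect_error(compare_performance(strong, weak), "metric")
})

test_that("univariate summaries expose medians, tests, CV AUC and per-SD hazard ratios", {
  tab <- make_feature_table(500, prevalence = 0.3, shifts = c(x1 = 1),
                            seed = 23)
  row <- univariate_summary(tab, "x1", n_splits = 10)
  expect_equal(names(row),
               c("feature", "all", "mace", "no_mace", "auc_k", "p_value",
                 "hr", "hr_lo", "hr_hi", "hr_p_value", "hr_undefined", "n"))
  expect_lt(row$p_value, 0.001)
  expect_gt(row$auc_k, 0.6)
  expect_gt(row$hr, 1)
  expect_false(row$hr_undefined)

  tab$flat <- 1
  flat <- univariate_summary(tab, "flat")
  expect_equal(flat$p_value, 1)
  expect_equal(flat$auc_k, 0.5)
  expect_true(flat$hr_undefined)
})
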