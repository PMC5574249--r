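test_that("confusion metrics follow their definitions", {
  met <- confusion_metrics(confusion_matrix(tp = 59, fn = 2, fp = 18,
                                            tn = 49))
  expect_equal(round(100 * met$sensitivity, 1), 96.7)
  expect_equal(round(100 * met$specificity, 1), 73.1)
  expect_equal(met$accuracy, (59 + 49) / 128)

  perfect <- confusion_metrics(confusion_matrix(1, 0, 0, 1))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  set.seed(6)
  cts <- sample(1:50, 4)
  met2 <- confusion_metrics(confusion_matrix(cts[1], cts[2], cts[3],
                                             cts[4]))
  expect_equal(met2$sensitivity, cts[1] / (cts[1] + cts[2]))
  expect_equal(met2$specificity, cts[4] / (cts[3] + cts[4]))
  expect_error(confusion_metrics(confusion_matrix(0, 0, 1, 2)),
               "reference classes")
  expect_error(confusion_matrix(-1, 0, 1, 2), "non-negative")
})

make_trial <- function(a, b, c, d, arm = "experimental") {
  # a: positive & pCR, b: positive & no pCR, c: negative & pCR, d: neg & no
  tibble::tibble(
    arm = arm,
    biomarker = rep(c("positive", "negative"), c(a + b, c + d)),
    pcr = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)))
}

test_that("arm association reproduces hand-computed Fisher results", {
  # balanced independence: OR 1, p 1
  t1 <- make_trial(10, 10, 10, 10)
  r1 <- arm_association(t1, "experimental")
  expect_equal(r1$or, 1)
  expect_equal(r1$fisher_p, 1)
  # diagonal table: two-sided p = 2/choose(10,5) = 2/252
  t2 <- make_trial(5, 0, 0, 5)
  r2 <- arm_association(t2, "experimental")
  expect_equal(r2$fisher_p, 2 / 252, tolerance = 1e-12)
  # the zero cells trigger the Haldane-Anscombe corrected OR
  expect_equal(r2$or, (5.5 * 5.5) / (0.5 * 0.5))
  # no correction when all cells are positive
  t3 <- make_trial(8, 4, 3, 9)
  expect_equal(arm_association(t3, "experimental")$or, (8 * 9) / (4 * 3))
  expect_error(arm_association(t3, "control"), "control")
})

test_that("Fisher p is invariant to transposing the 2x2 table", {
  t4 <- make_trial(7, 3, 2, 10)
  p1 <- arm_association(t4, "experimental")$fisher_p
  # transpose: swap the roles of biomarker and outcome
  t4t <- tibble::tibble(arm = "experimental",
                        biomarker = ifelse(t4$pcr == 1, "positive",
                                           "negative"),
                        pcr = as.integer(t4$biomarker == "positive"))
  expect_equal(arm_association(t4t, "experimental")$fisher_p, p1)
})

test_that("interaction coefficients reproduce the per-arm odds ratios", {
  set.seed(17)
  tt <- simulate_trial(trial_sim_config(n_experimental = 400,
                                        n_control = 300, seed = 17))
  it <- interaction_test(tt)
  or_exp <- arm_association(tt, "experimental")$or
  or_ctl <- arm_association(tt, "control")$or
  co <- setNames(it$coefficients$estimate, it$coefficients$term)
  expect_equal(exp(co[["armexperimental:biomarkerpositive"]]),
               or_exp / or_ctl, tolerance = 1e-6)
  expect_equal(exp(co[["biomarkerpositive"]]), or_ctl, tolerance = 1e-6)
  expect_true(it$p_value >= 0 && it$p_value <= 1)
})

test_that("the logistic log-likelihood matches an independent optimiser", {
  tt <- simulate_trial(trial_sim_config(seed = 29))
  it <- interaction_test(tt, covariates = "hr_status")
  # independent route: hand-coded Bernoulli log-likelihood over the same
  # design, maximised with BFGS
  X <- stats::model.matrix(~ arm * biomarker + hr_status, data = tt)
  y <- tt$pcr
  nll <- function(beta) {
    eta <- as.numeric(X %*% beta)
    -sum(y * eta - log1p(exp(eta)))
  }
  opt <- stats::optim(rep(0, ncol(X)), nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  expect_equal(it$loglik_full, -opt$value, tolerance = 1e-6)
})

test_that("missing tumour size is dropped only when that covariate is used", {
  tt <- simulate_trial(trial_sim_config(seed = 5))
  n_miss <- sum(is.na(tt$tumor_size_cat))
  expect_gt(n_miss, 0)
  it_plain <- interaction_test(tt, covariates = "hr_status")
  expect_equal(it_plain$n_used, nrow(tt))
  expect_message(
    it_size <- interaction_test(tt, c("hr_status", "tumor_size_cat")),
    "dropped")
  expect_equal(it_size$n_used, nrow(tt) - n_miss)
})

test_that("characteristics table reproduces the published treatment-row p", {
  # treatment x class [[27,17],[34,38]] and HR x class [[48,8],[13,47]];
  # per-variable tests only see the margins against biomarker class, so the
  # variables can be laid out independently (negatives first, then positives)
  tt <- tibble::tibble(
    biomarker = rep(c("negative", "positive"), c(61, 55)),
    arm = c(rep(c("control", "experimental"), c(27, 34)),
            rep(c("control", "experimental"), c(17, 38))),
    hr_status = c(rep(c("HR+", "TN"), c(48, 13)),
                  rep(c("HR+", "TN"), c(8, 47))),
    pcr = rep_len(0:1, 116))  # irrelevant to the characteristics table
  ct <- characteristics_table(tt)
  expect_equal(round(ct$p_value[ct$variable == "arm"], 3), 0.198)
  expect_lt(ct$p_value[ct$variable == "hr_status"], 0.05)
})

test_that("identical row proportions give statistic 0 and p 1", {
  tt <- tibble::tibble(
    arm = rep(c("control", "experimental"), each = 20),
    biomarker = rep(c("negative", "positive"), 20),
    pcr = 0L)
  ct <- characteristics_table(tt)
  # uncorrected statistic is 0; the Yates-corrected 2x2 version also
  # cannot exceed it, so p stays 1
  expect_equal(ct$p_value[ct$variable == "arm"], 1)
  # a single observed level yields a not-applicable row
  tt2 <- tt
  tt2$hr_status <- "TN"
  ct2 <- characteristics_table(tt2)
  expect_true(is.na(ct2$p_value[ct2$variable == "hr_status"]))
})

test_that("r x 2 tables use the uncorrected Pearson statistic", {
  tt <- simulate_trial(trial_sim_config(n_experimental = 300,
                                        n_control = 200, seed = 31))
  ct <- characteristics_table(tt)
  row <- ct[ct$variable == "tumor_size_cat", ]
  keep <- !is.na(tt$tumor_size_cat)
  tab <- table(droplevels(tt$tumor_size_cat[keep]), tt$biomarker[keep])
  tab <- tab[rowSums(tab) > 0, ]
  ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(row$statistic, as.numeric(ref$statistic))
  expect_equal(row$df, as.integer(ref$parameter))
})

test_that("the combined subset rule extends the TN-only rule coherently", {
  tt <- simulate_trial(trial_sim_config(n_experimental = 500,
                                        n_control = 400, seed = 43))
  so <- combined_subset_or(tt)
  n_tn <- sum(tt$hr_status == "TN")
  n_extra <- sum(tt$hr_status == "HR+" & tt$biomarker == "positive")
  expect_equal(so$rules$n, c(n_tn, n_tn + n_extra))
  expect_equal(so$prevalence_gain_pct, 100 * n_extra / nrow(tt))
  # with no HR+ biomarker-positive patients the two rules coincide
  tt2 <- tt
  tt2$biomarker[tt2$hr_status == "HR+"] <- "negative"
  so2 <- combined_subset_or(tt2)
  expect_equal(so2$rules$or[1], so2$rules$or[2])
  expect_equal(so2$prevalence_gain_pct, 0)
})

test_that("evaluate_trial bundles every component", {
  tt <- simulate_trial(trial_sim_config(seed = 57))
  ev <- suppressMessages(evaluate_trial(tt))
  expect_s3_class(ev, "trial_evaluation")
  expect_equal(nrow(ev$arms), 2)
  expect_true(all(c("unadjusted", "hr_adjusted") %in%
                    names(ev$interaction)))
  expect_true(all(ev$characteristics$p_value >= 0 &
                    ev$characteristics$p_value <= 1, na.rm = TRUE))
  gl <- glance(ev)
  expect_true(all(gl$p_value >= 0 & gl$p_value <= 1))
})
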