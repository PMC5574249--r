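# validate/coerce a per-patient trial table
check_trial <- function(table) {
  table <- as_tibble(table)
  need <- c("arm", "biomarker", "pcr")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0) {
    abort(paste0("Trial table is missing column: ", miss[1]),
          class = "brcaness_input_error")
  }
  table$arm <- factor(as.character(table$arm),
                      levels = c("control", "experimental"))
  table$biomarker <- factor(as.character(table$biomarker),
                            levels = c("negative", "positive"))
  table$pcr <- as.integer(table$pcr)
  if (anyNA(table$arm) || anyNA(table$biomarker) || anyNA(table$pcr) ||
      !all(table$pcr %in% 0:1)) {
    abort("`arm`, `biomarker` and `pcr` must be complete, with arm in {control, experimental}, biomarker in {negative, positive} and pcr in {0, 1}.",
          class = "brcaness_input_error")
  }
  if ("hr_status" %in% names(table)) {
    table$hr_status <- factor(as.character(table$hr_status),
                              levels = c("HR+", "TN"))
  }
  if ("tumor_size_cat" %in% names(table)) {
    table$tumor_size_cat <- factor(as.character(table$tumor_size_cat),
                                   levels = c("0-1", ">1-2", ">2-5", ">5"))
  }
  table
}

#' Confusion matrix of a dichotomous test against a reference
#'
#' @param tp,fn,fp,tn Non-negative counts (reference positive/negative down
#'   the columns, test positive/negative across the rows).
#' @return A `confusion_matrix` object.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (!is.numeric(cells) || anyNA(cells) || any(cells < 0) ||
      any(cells != round(cells))) {
    abort("Confusion counts must be non-negative integers.",
          class = "brcaness_input_error")
  }
  if (sum(cells) == 0) {
    abort("Confusion matrix must contain at least one observation.",
          class = "brcaness_input_error")
  }
  structure(as.list(cells), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(test = c("positive", "negative"),
                              reference = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Sensitivity, specificity and accuracy of a confusion matrix
#'
#' @param cm A [confusion_matrix()], or `tp` when counts are given
#'   directly.
#' @inheritParams confusion_matrix
#' @return A one-row tibble (`sensitivity`, `specificity`, `accuracy`), as
#'   fractions.
#' @export
#' @examples
#' confusion_metrics(confusion_matrix(tp = 59, fn = 2, fp = 18, tn = 49))
confusion_metrics <- function(cm, fn = NULL, fp = NULL, tn = NULL) {
  if (!inherits(cm, "confusion_matrix")) {
    cm <- confusion_matrix(tp = cm, fn = fn, fp = fp, tn = tn)
  }
  if (cm$tp + cm$fn == 0 || cm$fp + cm$tn == 0) {
    abort("Both reference classes must be represented.",
          class = "brcaness_input_error")
  }
  total <- cm$tp + cm$fn + cm$fp + cm$tn
  tibble(sensitivity = cm$tp / (cm$tp + cm$fn),
         specificity = cm$tn / (cm$tn + cm$fp),
         accuracy = (cm$tp + cm$tn) / total)
}

# cross-product odds ratio with Haldane-Anscombe +0.5 iff any zero cell
cross_product_or <- function(a, b, c, d) {
  if (min(a, b, c, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

#' Biomarker-response association within one trial arm
#'
#' Builds the 2x2 biomarker-by-pCR table for the requested arm and reports
#' the sample cross-product odds ratio (with the Haldane-Anscombe +0.5
#' correction only when a cell is zero) and the two-sided Fisher exact
#' p-value.
#'
#' @param table A per-patient trial table (see [simulate_trial()]).
#' @param arm `"experimental"` or `"control"`.
#' @return A one-row tibble: `arm`, `n`, the four cell counts
#'   (`pos_pcr`, `pos_nopcr`, `neg_pcr`, `neg_nopcr`), `or`, `fisher_p`.
#' @export
arm_association <- function(table, arm) {
  table <- check_trial(table)
  if (!arm %in% levels(table$arm)) {
    abort(paste0("Unknown arm: ", arm), class = "brcaness_input_error")
  }
  sub <- table[table$arm == arm, ]
  if (nrow(sub) == 0) {
    abort(paste0("Arm absent from table: ", arm),
          class = "brcaness_input_error")
  }
  a <- sum(sub$biomarker == "positive" & sub$pcr == 1)
  b <- sum(sub$biomarker == "positive" & sub$pcr == 0)
  c <- sum(sub$biomarker == "negative" & sub$pcr == 1)
  d <- sum(sub$biomarker == "negative" & sub$pcr == 0)
  tab <- matrix(c(a, c, b, d), 2, 2)
  p <- fisher.test(tab)$p.value
  tibble(arm = arm, n = nrow(sub), pos_pcr = a, pos_nopcr = b,
         neg_pcr = c, neg_nopcr = d,
         or = cross_product_or(a, b, c, d), fisher_p = p)
}

#' Biomarker-by-treatment interaction likelihood-ratio test
#'
#' Fits the logistic model `pcr ~ arm + biomarker + arm:biomarker` (plus
#' any covariates) by maximum likelihood and compares it against the same
#' model without the interaction term; the likelihood-ratio statistic is
#' referred to a chi-squared distribution with one degree of freedom.
#' Patients with a missing tumour-size category are dropped (complete-case)
#' only when that covariate is included.
#'
#' @param table A per-patient trial table.
#' @param covariates Character subset of `c("hr_status",
#'   "tumor_size_cat")` (default none).
#' @return An `interaction_test` object; see [tidy()] and [glance()]
#'   methods.
#' @export
interaction_test <- function(table, covariates = character()) {
  table <- check_trial(table)
  bad <- setdiff(covariates, c("hr_status", "tumor_size_cat"))
  if (length(bad) > 0) {
    abort(paste0("Unsupported covariate: ", bad[1]),
          class = "brcaness_config_error")
  }
  miss_cov <- setdiff(covariates, names(table))
  if (length(miss_cov) > 0) {
    abort(paste0("Covariate column absent from table: ", miss_cov[1]),
          class = "brcaness_input_error")
  }
  n_all <- nrow(table)
  if ("tumor_size_cat" %in% covariates) {
    table <- table[!is.na(table$tumor_size_cat), ]
    table$tumor_size_cat <- droplevels(table$tumor_size_cat)
  }
  n_dropped <- n_all - nrow(table)
  if (n_dropped > 0) {
    inform(sprintf(
      "interaction_test: dropped %d patients with missing tumour size.",
      n_dropped))
  }
  if (sum(table$pcr) == 0 || sum(table$pcr) == nrow(table)) {
    abort("Need at least one event and one non-event.",
          class = "brcaness_input_error")
  }
  rhs <- paste(c("arm * biomarker", covariates), collapse = " + ")
  full <- glm(stats::as.formula(paste("pcr ~", rhs)),
              family = binomial(), data = table)
  reduced <- stats::update(full, . ~ . - arm:biomarker)
  if (anyNA(coef(full))) {
    aliased <- names(coef(full))[is.na(coef(full))]
    abort(paste0("Rank-deficient design; aliased: ",
                 paste(aliased, collapse = ", ")),
          class = "brcaness_fit_error")
  }
  if (!full$converged || !reduced$converged ||
      any(abs(coef(full)) > 15)) {
    abort(paste0("Logistic fit did not converge (possible separation); ",
                 "use the continuity-corrected odds ratios from ",
                 "arm_association() instead."),
          class = "brcaness_fit_error")
  }
  lr <- as.numeric(2 * (logLik(full) - logLik(reduced)))
  coefs <- tibble(term = names(coef(full)),
                  estimate = as.numeric(coef(full)),
                  std_error = sqrt(diag(stats::vcov(full))))
  structure(list(lr_stat = lr, df = 1L,
                 p_value = pchisq(lr, df = 1, lower.tail = FALSE),
                 coefficients = coefs, covariates = covariates,
                 n_used = nrow(table), n_dropped = n_dropped,
                 loglik_full = as.numeric(logLik(full)),
                 loglik_reduced = as.numeric(logLik(reduced))),
            class = "interaction_test")
}

#' @export
print.interaction_test <- function(x, ...) {
  adj <- if (length(x$covariates) == 0) "unadjusted"
         else paste("adjusted for", paste(x$covariates, collapse = " + "))
  cat(sprintf(
    "<interaction_test> LR = %.3f on %d df, p = %.4g (%s, n = %d)\n",
    x$lr_stat, x$df, x$p_value, adj, x$n_used))
  invisible(x)
}

#' Baseline-characteristics tests against biomarker class
#'
#' For every baseline variable present (`arm`, `hr_status`,
#' `tumor_size_cat`) a contingency table against biomarker class is tested:
#' 2x2 tables with the continuity-corrected chi-squared statistic, larger
#' tables with the uncorrected Pearson statistic after dropping all-zero
#' rows. Variables observed at a single level get an `NA` p-value.
#'
#' @param table A per-patient trial table.
#' @return A tibble (`variable`, `statistic`, `df`, `p_value`, `method`).
#' @export
characteristics_table <- function(table) {
  table <- check_trial(table)
  vars <- intersect(c("arm", "hr_status", "tumor_size_cat"), names(table))
  rows <- map(vars, function(v) {
    keep <- !is.na(table[[v]])
    tab <- table(droplevels(table[[v]][keep]), table$biomarker[keep])
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) < 2 || ncol(tab) < 2) {
      return(tibble(variable = v, statistic = NA_real_, df = NA_integer_,
                    p_value = NA_real_, method = "not applicable"))
    }
    correct <- nrow(tab) == 2
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    tibble(variable = v, statistic = as.numeric(ct$statistic),
           df = as.integer(ct$parameter), p_value = ct$p.value,
           method = if (correct) "chi-squared (continuity-corrected)"
                    else "chi-squared (Pearson)")
  })
  bind_rows(rows)
}

#' Treatment odds ratio in the combined biomarker-positive subset
#'
#' Compares the treatment effect (pCR odds, experimental vs control) within
#' the subset selected by `TN or (HR+ and biomarker-positive)` against the
#' TN-only subset, and reports how many percentage points of the cohort the
#' combined rule adds to the selected ("biomarker-positive predicted
#' sensitive") group.
#'
#' @param table A per-patient trial table with `hr_status`.
#' @return A `subset_or` object: tibble `rules` (one row per rule with
#'   counts and treatment OR) plus `prevalence_gain_pct`.
#' @export
combined_subset_or <- function(table) {
  table <- check_trial(table)
  if (!"hr_status" %in% names(table)) {
    abort("`hr_status` is required for the combined subset rule.",
          class = "brcaness_input_error")
  }
  in_tn <- table$hr_status == "TN"
  in_comb <- in_tn | (table$hr_status == "HR+" &
                        table$biomarker == "positive")
  one_rule <- function(sel, name) {
    sub <- table[sel, ]
    a <- sum(sub$arm == "experimental" & sub$pcr == 1)
    b <- sum(sub$arm == "experimental" & sub$pcr == 0)
    c <- sum(sub$arm == "control" & sub$pcr == 1)
    d <- sum(sub$arm == "control" & sub$pcr == 0)
    if (sum(sub$arm == "experimental") == 0 ||
        sum(sub$arm == "control") == 0) {
      abort(paste0("Subset has an empty arm under rule: ", name),
            class = "brcaness_input_error")
    }
    if (min(a, b, c, d) == 0) {
      warn(paste0("Zero cell in subset 2x2 (", name,
                  "); Haldane-Anscombe corrected OR reported."))
    }
    tibble(rule = name, n = nrow(sub), exp_pcr = a, exp_nopcr = b,
           ctl_pcr = c, ctl_nopcr = d, or = cross_product_or(a, b, c, d))
  }
  rules <- bind_rows(one_rule(in_tn, "TN only"),
                     one_rule(in_comb, "TN + HR+ biomarker-positive"))
  structure(list(rules = rules,
                 prevalence_gain_pct =
                   100 * (sum(in_comb) - sum(in_tn)) / nrow(table)),
            class = "subset_or")
}

#' @export
print.subset_or <- function(x, ...) {
  print(x$rules)
  cat(sprintf("Selected-group prevalence gain: %.1f percentage points\n",
              x$prevalence_gain_pct))
  invisible(x)
}

#' Full biomarker evaluation of a two-arm trial table
#'
#' Convenience wrapper producing the per-arm associations, the
#' biomarker-by-treatment interaction tests (unadjusted, HR-adjusted and,
#' when tumour size is available, HR + size adjusted) and the
#' baseline-characteristics table.
#'
#' @param table A per-patient trial table.
#' @return A `trial_evaluation` list with elements `arms` (tibble),
#'   `interaction` (list of `interaction_test`), `characteristics`
#'   (tibble) and, when `hr_status` is present, `subset_or`.
#' @export
evaluate_trial <- function(table) {
  table <- check_trial(table)
  arms <- bind_rows(arm_association(table, "experimental"),
                    arm_association(table, "control"))
  try_it <- function(covs) {
    tryCatch(interaction_test(table, covs), error = function(e) NULL)
  }
  interaction <- list(unadjusted = try_it(character()))
  if ("hr_status" %in% names(table)) {
    interaction$hr_adjusted <- try_it("hr_status")
    if ("tumor_size_cat" %in% names(table) &&
        sum(!is.na(table$tumor_size_cat)) > 0) {
      interaction$hr_size_adjusted <-
        try_it(c("hr_status", "tumor_size_cat"))
    }
  }
  out <- list(arms = arms, interaction = interaction,
              characteristics = characteristics_table(table))
  if ("hr_status" %in% names(table)) {
    out$subset_or <- tryCatch(combined_subset_or(table),
                              error = function(e) NULL)
  }
  structure(out, class = "trial_evaluation")
}

#' @export
print.trial_evaluation <- function(x, ...) {
  cat("Per-arm biomarker-response association:\n")
  print(x$arms)
  cat("\nInteraction tests:\n")
  for (nm in names(x$interaction)) {
    if (!is.null(x$interaction[[nm]])) print(x$interaction[[nm]])
  }
  cat("\nBaseline characteristics (vs biomarker class):\n")
  print(x$characteristics)
  invisible(x)
}
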