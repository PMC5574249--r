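#' Fit per-class median centroids
#'
#' The portable diagnostic: for each signature gene, the positive and
#' negative centroids are the per-class medians over the training samples
#' (even-sized classes take the midpoint of the two central values).
#'
#' @inheritParams rank_genes_anova
#' @param genes Signature genes, in order (at least two; Pearson
#'   correlation needs two points).
#' @param threshold Decision cutoff on the correlation-difference score
#'   (default -0.3); see [score_samples()].
#' @return A `signature_model` with fields `genes`, `centroid_pos`,
#'   `centroid_neg`, `threshold`.
#' @export
fit_centroids <- function(expr, label, genes, threshold = -0.3) {
  expr <- as_expr_matrix(expr)
  ids <- sample_ids(expr)
  lab <- check_labels(expr, label)
  if (length(genes) < 2) {
    abort("A signature needs at least two genes.",
          class = "brcaness_input_error")
  }
  miss <- setdiff(genes, gene_ids(expr))
  if (length(miss) > 0) {
    abort(paste0("Gene not in expression matrix: ", miss[1]),
          class = "brcaness_input_error")
  }
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= -2 || threshold >= 2) {
    abort("`threshold` must lie in (-2, 2).",
          class = "brcaness_config_error")
  }
  v <- expr$values[genes, , drop = FALSE]
  centroid_pos <- apply(v[, lab, drop = FALSE], 1, median)
  centroid_neg <- apply(v[, !lab, drop = FALSE], 1, median)
  if (any(!is.finite(centroid_pos)) || any(!is.finite(centroid_neg))) {
    abort("Centroids must be finite.", class = "brcaness_fit_error")
  }
  structure(list(genes = genes,
                 centroid_pos = setNames(centroid_pos, genes),
                 centroid_neg = setNames(centroid_neg, genes),
                 threshold = threshold),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model> %d genes, threshold %.3g\n",
              length(x$genes), x$threshold))
  invisible(x)
}

#' Score samples against the signature centroids
#'
#' For each sample, the Pearson correlations across the signature genes
#' with the positive and negative centroid templates are combined into a
#' single continuous score, `score = r_pos - r_neg` (range \[-2, 2\]); a
#' sample is called positive when the score is at or above the model
#' threshold (the boundary goes to the positive class — the diagnostic is
#' sensitivity-first). Inputs must be preprocessed identically to the
#' training cohort; no re-normalisation is applied at scoring time.
#'
#' @param model A [fit_centroids()] model.
#' @param newdata An [expr_matrix] or genes-by-samples matrix covering all
#'   model genes, or a named per-gene vector for one sample. Sample and
#'   centroid profiles must have nonzero variance across the genes.
#' @return A tibble (`sample_id`, `r_pos`, `r_neg`, `score`, `call`).
#' @export
score_samples <- function(model, newdata) {
  if (!inherits(model, "signature_model")) {
    abort("`model` must be a signature_model.",
          class = "brcaness_input_error")
  }
  x <- newdata
  if (inherits(x, "expr_matrix")) x <- x$values
  if (is.vector(x) && is.numeric(x)) {
    x <- matrix(x, ncol = 1, dimnames = list(names(x), "sample_1"))
  }
  miss <- setdiff(model$genes, rownames(x))
  if (length(miss) > 0) {
    abort(paste0("Missing gene value: ", miss[1]),
          class = "brcaness_input_error")
  }
  x <- x[model$genes, , drop = FALSE]
  if (sd(model$centroid_pos) == 0 || sd(model$centroid_neg) == 0) {
    abort("Zero-variance centroid: correlation undefined.",
          class = "brcaness_score_error")
  }
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("Zero-variance sample profile: ",
                 colnames(x)[sds == 0][1]),
          class = "brcaness_score_error")
  }
  r_pos <- as.numeric(cor(x, model$centroid_pos))
  r_neg <- as.numeric(cor(x, model$centroid_neg))
  score <- r_pos - r_neg
  tibble(sample_id = colnames(x), r_pos = r_pos, r_neg = r_neg,
         score = score, call = score >= model$threshold)
}

#' Calibrate the score threshold for a target specificity
#'
#' Scans the midpoints between adjacent observed scores (plus cutoffs below
#' and above all scores) and returns the threshold that maximises
#' sensitivity subject to specificity at or above `target_specificity`;
#' when no cutoff attains the target, the one with maximal specificity is
#' returned (ties broken towards higher sensitivity). Calls are
#' `score >= threshold`.
#'
#' @param score Numeric vector of continuous scores.
#' @param label Binary reference labels (logical, `TRUE` = positive).
#' @param target_specificity Required specificity (default 0.75).
#' @return The calibrated threshold (a single number).
#' @export
calibrate_threshold <- function(score, label, target_specificity = 0.75) {
  label <- as.logical(label)
  if (length(score) != length(label) || anyNA(score) || anyNA(label)) {
    abort("`score` and `label` must be complete and the same length.",
          class = "brcaness_input_error")
  }
  if (length(unique(label)) < 2) {
    abort("Both classes must be present to calibrate.",
          class = "brcaness_input_error")
  }
  check_prob(target_specificity, "target_specificity")
  s <- sort(unique(score))
  cand <- c(s[1] - 1, (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1)
  sens <- map_dbl(cand, ~ mean(score[label] >= .x))
  spec <- map_dbl(cand, ~ mean(score[!label] < .x))
  ok <- spec >= target_specificity
  if (any(ok)) {
    # max sensitivity subject to the target; ties towards higher specificity
    best <- which(ok & sens == max(sens[ok]))
    best <- best[which.max(spec[best])]
  } else {
    best <- which(spec == max(spec))
    best <- best[which.max(sens[best])]
  }
  cand[best]
}

#' Summarise agreement between calls and reference labels
#'
#' @param call Logical predicted class.
#' @param label Logical reference class.
#' @return A `confusion_matrix` (fields `tp`, `fn`, `fp`, `tn`); see
#'   [confusion_metrics()].
#' @export
confusion_counts <- function(call, label) {
  call <- as.logical(call); label <- as.logical(label)
  if (length(call) != length(label) || anyNA(call) || anyNA(label)) {
    abort("`call` and `label` must be complete and the same length.",
          class = "brcaness_input_error")
  }
  confusion_matrix(tp = sum(call & label), fn = sum(!call & label),
                   fp = sum(call & !label), tn = sum(!call & !label))
}
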