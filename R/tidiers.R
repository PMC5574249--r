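#' Tidiers and plots for fitted objects
#'
#' broom-style [tidy()] and [glance()] methods plus ggplot2 [autoplot()]
#' methods for the package's result types.
#'
#' @param x The object.
#' @param ... Unused.
#' @return `tidy()` returns a tibble with one row per element (gene, term,
#'   size); `glance()` a one-row summary tibble; `autoplot()` a ggplot.
#' @name brcaness-tidiers
NULL

#' @rdname brcaness-tidiers
#' @export
tidy.cv_search <- function(x, ...) x$results

#' @rdname brcaness-tidiers
#' @export
glance.cv_search <- function(x, ...) {
  tibble(selected_size = x$selected_size,
         max_auc = max(x$results$auc),
         n_samples = nrow(x$posteriors),
         n_candidate_genes = nrow(x$ranking))
}

#' @rdname brcaness-tidiers
#' @export
autoplot.cv_search <- function(x, ...) {
  ggplot(x$results, aes(x = .data$size, y = .data$auc)) +
    geom_line(colour = "grey40") +
    geom_point(size = 0.8) +
    geom_vline(xintercept = x$selected_size, linetype = "dashed",
               colour = "firebrick") +
    labs(x = "Gene-set size", y = "LOOCV AUC",
         title = sprintf("Selected size: %d genes", x$selected_size)) +
    theme_minimal()
}

#' @rdname brcaness-tidiers
#' @export
tidy.dlda_model <- function(x, ...) {
  tibble(gene_id = x$genes,
         mean_pos = as.numeric(x$mean_pos),
         mean_neg = as.numeric(x$mean_neg),
         pooled_var = as.numeric(x$pooled_var))
}

#' @rdname brcaness-tidiers
#' @export
glance.dlda_model <- function(x, ...) {
  tibble(n_genes = length(x$genes), prior_pos = x$priors[["pos"]],
         prior_neg = x$priors[["neg"]])
}

#' @rdname brcaness-tidiers
#' @export
tidy.signature_model <- function(x, ...) {
  tibble(gene_id = x$genes,
         centroid_pos = as.numeric(x$centroid_pos),
         centroid_neg = as.numeric(x$centroid_neg))
}

#' @rdname brcaness-tidiers
#' @export
glance.signature_model <- function(x, ...) {
  tibble(n_genes = length(x$genes), threshold = x$threshold)
}

#' @rdname brcaness-tidiers
#' @export
autoplot.signature_model <- function(x, ...) {
  ggplot(tidy(x), aes(x = .data$centroid_neg, y = .data$centroid_pos)) +
    geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    geom_point(alpha = 0.7) +
    labs(x = "Negative-class centroid (median log2)",
         y = "Positive-class centroid (median log2)",
         title = sprintf("%d signature genes", length(x$genes))) +
    theme_minimal()
}

#' @rdname brcaness-tidiers
#' @export
tidy.interaction_test <- function(x, ...) x$coefficients

#' @rdname brcaness-tidiers
#' @export
glance.interaction_test <- function(x, ...) {
  tibble(lr_stat = x$lr_stat, df = x$df, p_value = x$p_value,
         n_used = x$n_used, n_dropped = x$n_dropped,
         covariates = paste(x$covariates, collapse = "+"))
}

#' @rdname brcaness-tidiers
#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble(tp = x$tp, fn = x$fn, fp = x$fp, tn = x$tn)
}

#' @rdname brcaness-tidiers
#' @export
glance.confusion_matrix <- function(x, ...) confusion_metrics(x)

#' @rdname brcaness-tidiers
#' @export
tidy.trial_evaluation <- function(x, ...) x$arms

#' @rdname brcaness-tidiers
#' @export
glance.trial_evaluation <- function(x, ...) {
  gl <- purrr::compact(x$interaction)
  tibble(test = names(gl),
         lr_stat = map_dbl(gl, "lr_stat"),
         p_value = map_dbl(gl, "p_value"))
}

#' @rdname brcaness-tidiers
#' @export
autoplot.trial_evaluation <- function(x, ...) {
  ggplot(x$arms, aes(x = .data$arm, y = .data$or)) +
    geom_hline(yintercept = 1, colour = "grey70") +
    geom_point(size = 3) +
    scale_y_log10() +
    labs(x = NULL, y = "Biomarker-response odds ratio (log scale)",
         title = "Per-arm biomarker-response association") +
    theme_minimal()
}

#' Plot the continuous score distribution by reference class
#'
#' @param scores A tibble from [score_samples()].
#' @param label Optional logical reference labels (named by sample or in
#'   row order) used to colour the histogram.
#' @param threshold Decision cutoff drawn as a dashed line (default -0.3).
#' @return A ggplot.
#' @export
plot_score_distribution <- function(scores, label = NULL,
                                    threshold = -0.3) {
  df <- as_tibble(scores)
  if (!is.null(label)) {
    if (!is.null(names(label))) label <- label[df$sample_id]
    df$reference <- ifelse(label, "positive", "negative")
  } else {
    df$reference <- "all"
  }
  ggplot(df, aes(x = .data$score, fill = .data$reference)) +
    geom_histogram(bins = 30, alpha = 0.7, position = "identity") +
    geom_vline(xintercept = threshold, linetype = "dashed") +
    labs(x = "Correlation-difference score", y = "Samples") +
    theme_minimal()
}
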