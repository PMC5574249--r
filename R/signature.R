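# align a label vector (logical, possibly named) with an expr_matrix
check_labels <- function(expr, label) {
  ids <- sample_ids(expr)
  if (is.data.frame(label)) {
    if (!all(c("sample_id", "label") %in% names(label))) {
      abort("A label table needs columns `sample_id` and `label`.",
            class = "brcaness_input_error")
    }
    label <- setNames(label$label, label$sample_id)
  }
  if (!is.null(names(label))) {
    if (!setequal(names(label), ids)) {
      abort("Label names must match the expression sample identifiers.",
            class = "brcaness_input_error")
    }
    label <- label[ids]
  } else if (length(label) != length(ids)) {
    abort("Need exactly one label per sample.",
          class = "brcaness_input_error")
  }
  label <- as.logical(label)
  if (anyNA(label)) {
    abort("Labels must be TRUE/FALSE with no missing values.",
          class = "brcaness_input_error")
  }
  if (length(unique(label)) < 2) {
    abort("Both classes must be present.", class = "brcaness_input_error")
  }
  setNames(label, ids)
}

#' Filter genes by across-sample variance
#'
#' @param expr A preprocessed [expr_matrix].
#' @param min_var Keep genes with unbiased sample variance strictly greater
#'   than this (default 1).
#' @return Character vector of gene identifiers, in input order.
#' @export
variance_filter <- function(expr, min_var = 1) {
  expr <- as_expr_matrix(expr)
  if (ncol(expr$values) < 2) {
    abort("Variance needs at least two samples.",
          class = "brcaness_input_error")
  }
  v <- expr$values
  vars <- rowSums((v - rowMeans(v))^2) / (ncol(v) - 1)
  gene_ids(expr)[vars > min_var]
}

# two-group per-gene F statistics, vectorised; returns f, p, std_diff
gene_f_stats <- function(v, lab) {
  n1 <- sum(lab); n0 <- sum(!lab); n <- n1 + n0
  m1 <- rowMeans(v[, lab, drop = FALSE])
  m0 <- rowMeans(v[, !lab, drop = FALSE])
  ss1 <- rowSums((v[, lab, drop = FALSE] - m1)^2)
  ss0 <- rowSums((v[, !lab, drop = FALSE] - m0)^2)
  sp2 <- (ss1 + ss0) / (n - 2)
  denom <- sp2 * (1 / n1 + 1 / n0)
  f <- ifelse(denom > 0, (m1 - m0)^2 / denom,
              ifelse(m1 == m0, 0, Inf))
  p <- ifelse(is.infinite(f), 0, pf(f, 1, n - 2, lower.tail = FALSE))
  # zero within-class variance in both classes with equal means: p = 1
  p[denom == 0 & m1 == m0] <- 1
  std_diff <- ifelse(sp2 > 0, (m1 - m0) / sqrt(sp2),
                     ifelse(m1 == m0, 0, Inf))
  list(f = f, p = p, std_diff = std_diff, mean_pos = m1, mean_neg = m0,
       pooled_var = sp2)
}

#' Rank genes by univariate two-group ANOVA
#'
#' Orders genes by ascending one-way ANOVA p-value (equivalently descending
#' F) for the two label classes. Ties are broken by descending absolute
#' standardised mean difference, then input order. For a binary grouping
#' the ANOVA F equals the squared pooled-variance t statistic.
#'
#' @param expr A preprocessed [expr_matrix].
#' @param label Per-sample binary reference label (logical; `TRUE` is the
#'   positive, BRCA1-like, class), named by sample or in column order; a
#'   tibble with `sample_id`/`label` columns also works.
#' @param genes Genes to rank (default: all genes in `expr`).
#' @return A tibble (`gene_id`, `f_stat`, `p_value`, `std_diff`) in rank
#'   order.
#' @export
rank_genes_anova <- function(expr, label, genes = gene_ids(expr)) {
  expr <- as_expr_matrix(expr)
  lab <- check_labels(expr, label)
  if (sum(lab) < 2 || sum(!lab) < 2) {
    abort("Each class needs at least two samples for ANOVA ranking.",
          class = "brcaness_input_error")
  }
  miss <- setdiff(genes, gene_ids(expr))
  if (length(miss) > 0) {
    abort(paste0("Gene not in expression matrix: ", miss[1]),
          class = "brcaness_input_error")
  }
  v <- expr$values[genes, , drop = FALSE]
  st <- gene_f_stats(v, lab)
  ord <- order(st$p, -abs(st$std_diff), seq_along(genes))
  tibble(gene_id = genes[ord], f_stat = unname(st$f[ord]),
         p_value = unname(st$p[ord]),
         std_diff = unname(st$std_diff[ord]))
}

#' Fit a diagonal linear discriminant model
#'
#' Gaussian discriminant with per-gene class means, a shared diagonal
#' covariance (the per-gene pooled within-class variance) and equal class
#' priors. Pooled variances are floored at `1e-8` times their median so
#' degenerate fixtures cannot divide by zero; the floor never binds on
#' realistic data.
#'
#' @inheritParams rank_genes_anova
#' @param genes Genes to include, in order.
#' @return A `dlda_model` with fields `genes`, `mean_pos`, `mean_neg`,
#'   `pooled_var`, `priors`.
#' @export
fit_dlda <- function(expr, label, genes) {
  expr <- as_expr_matrix(expr)
  lab <- check_labels(expr, label)
  if (sum(lab) < 2 || sum(!lab) < 2) {
    abort("Each class needs at least two samples to fit DLDA.",
          class = "brcaness_fit_error")
  }
  miss <- setdiff(genes, gene_ids(expr))
  if (length(miss) > 0) {
    abort(paste0("Gene not in expression matrix: ", miss[1]),
          class = "brcaness_input_error")
  }
  v <- expr$values[genes, , drop = FALSE]
  st <- gene_f_stats(v, lab)
  floor_var <- max(1e-8 * median(st$pooled_var), .Machine$double.xmin)
  structure(list(genes = genes,
                 mean_pos = setNames(st$mean_pos, genes),
                 mean_neg = setNames(st$mean_neg, genes),
                 pooled_var = setNames(pmax(st$pooled_var, floor_var),
                                       genes),
                 priors = c(pos = 0.5, neg = 0.5)),
            class = "dlda_model")
}

#' @export
print.dlda_model <- function(x, ...) {
  cat(sprintf("<dlda_model> %d genes, priors %.2f/%.2f\n",
              length(x$genes), x$priors[1], x$priors[2]))
  invisible(x)
}

#' Posterior class probabilities under a DLDA model
#'
#' Each class probability is proportional to
#' `prior * exp(-0.5 * sum((x - mean)^2 / pooled_var))`, normalised to sum
#' to one; computation is in the log domain. The class call is the argmax,
#' with exact ties going to the positive class.
#'
#' @param model A [fit_dlda()] model.
#' @param newdata An [expr_matrix] or genes-by-samples matrix covering all
#'   model genes, or a named per-gene vector for a single sample.
#' @return A tibble (`sample_id`, `p_pos`, `p_neg`, `call`).
#' @export
dlda_posterior <- function(model, newdata) {
  if (!inherits(model, "dlda_model")) {
    abort("`model` must be a dlda_model.", class = "brcaness_input_error")
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
  q_pos <- colSums((x - model$mean_pos)^2 / model$pooled_var)
  q_neg <- colSums((x - model$mean_neg)^2 / model$pooled_var)
  logit <- log(model$priors["pos"]) - log(model$priors["neg"]) +
    0.5 * (q_neg - q_pos)
  p_pos <- stats::plogis(as.numeric(logit))
  tibble(sample_id = colnames(x), p_pos = p_pos, p_neg = 1 - p_pos,
         call = p_pos >= 0.5)
}

#' ROC area under the curve (Mann-Whitney form)
#'
#' The probability that a randomly chosen positive-label score exceeds a
#' randomly chosen negative-label score, ties counted one half; invariant
#' to monotone transforms of the score.
#'
#' @param score Numeric scores.
#' @param label Logical labels (`TRUE` = positive); both classes required.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(score, label) {
  lab <- as.logical(label)
  if (length(score) != length(lab) || anyNA(score) || anyNA(lab)) {
    abort("`score` and `label` must be complete and the same length.",
          class = "brcaness_input_error")
  }
  n1 <- sum(lab); n0 <- sum(!lab)
  if (n1 == 0 || n0 == 0) {
    abort("Both classes must be present to compute an AUC.",
          class = "brcaness_input_error")
  }
  (sum(rank(score)[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

mann_whitney_auc <- function(score, lab) roc_auc(score, lab)

#' Leave-one-out search over nested gene-set sizes
#'
#' For each left-out sample, genes are re-ranked by two-group ANOVA on the
#' remaining samples (no selection leakage) and DLDA models on the top-N
#' genes, N = 1..`max_size`, score the left-out sample's posterior
#' probability of the positive class. Per size, performance is the ROC AUC
#' in Mann-Whitney form (ties counted 1/2); the selected size is the
#' smallest N attaining the maximum AUC, and the reported signature is the
#' top genes at that size ranked on the full cohort.
#'
#' @inheritParams rank_genes_anova
#' @param max_size Largest gene-set size to try (default 100); capped with
#'   a warning when fewer genes are available.
#' @param genes Candidate genes (default: all genes in `expr`, normally the
#'   output of [variance_filter()]).
#' @param rank_once If `TRUE`, rank genes once on the full cohort instead
#'   of per fold (the optimistic variant; for leakage demonstrations only).
#' @return A `cv_search`: list with `results` (tibble `size`, `auc`),
#'   `selected_size`, `selected_genes`, `ranking` (full-cohort ranking
#'   tibble) and `posteriors` (n-samples by `max_size` matrix of left-out
#'   posteriors).
#' @export
loocv_search <- function(expr, label, max_size = 100,
                         genes = gene_ids(expr), rank_once = FALSE) {
  expr <- as_expr_matrix(expr)
  lab <- check_labels(expr, label)
  if (sum(lab) < 3 || sum(!lab) < 3) {
    abort("LOOCV needs at least three samples in each class.",
          class = "brcaness_input_error")
  }
  if (length(genes) < max_size) {
    warn(sprintf("Only %d candidate genes; capping max_size at %d.",
                 length(genes), length(genes)))
    max_size <- length(genes)
  }
  v <- expr$values[genes, , drop = FALSE]
  n <- ncol(v)
  post <- matrix(NA_real_, n, max_size,
                 dimnames = list(colnames(v), NULL))
  full_rank_idx <- NULL
  if (rank_once) {
    st <- gene_f_stats(v, lab)
    full_rank_idx <- order(st$p, -abs(st$std_diff), seq_along(genes))
  }
  for (i in seq_len(n)) {
    vt <- v[, -i, drop = FALSE]
    lt <- lab[-i]
    st <- gene_f_stats(vt, lt)
    ord <- if (rank_once) full_rank_idx
           else order(st$p, -abs(st$std_diff), seq_along(genes))
    top <- ord[seq_len(max_size)]
    pooled <- st$pooled_var[top]
    pooled <- pmax(pooled, max(1e-8 * median(st$pooled_var),
                               .Machine$double.xmin))
    x <- v[top, i]
    # per-gene additive contribution to the positive-class logit
    d <- 0.5 * ((x - st$mean_neg[top])^2 - (x - st$mean_pos[top])^2) / pooled
    post[i, ] <- stats::plogis(cumsum(d))
  }
  auc <- apply(post, 2, mann_whitney_auc, lab = lab)
  selected_size <- which.max(auc)  # smallest N at the maximum
  ranking <- rank_genes_anova(expr, lab, genes)
  structure(list(
    results = tibble(size = seq_len(max_size), auc = as.numeric(auc)),
    selected_size = selected_size,
    selected_genes = ranking$gene_id[seq_len(selected_size)],
    ranking = ranking,
    posteriors = post,
    label = lab
  ), class = "cv_search")
}

#' @export
print.cv_search <- function(x, ...) {
  cat(sprintf(
    "<cv_search> sizes 1..%d, selected %d genes (LOOCV AUC %.3f)\n",
    nrow(x$results), x$selected_size, x$results$auc[x$selected_size]))
  invisible(x)
}
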