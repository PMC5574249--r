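#' Background offset and log2 transform
#'
#' Converts background-subtracted linear-scale intensities to log2 scale.
#' Over-subtracted (negative) intensities are floored at zero before the
#' offset is added, so the output is always finite: each value `v` becomes
#' `log2(max(v, 0) + offset)`.
#'
#' @param raw An [expr_matrix] (or bare matrix) of background-subtracted
#'   linear-scale intensities; values may be zero or negative.
#' @param offset Positive offset added before the log transform (default 10).
#' @return An [expr_matrix] on the log2 scale.
#' @export
background_log_transform <- function(raw, offset = 10) {
  raw <- as_expr_matrix(raw)
  if (!is.numeric(offset) || length(offset) != 1 || !is.finite(offset) ||
      offset <= 0) {
    abort("`offset` must be a single positive number.",
          class = "brcaness_config_error")
  }
  obs <- !raw$mask
  if (any(!is.finite(raw$values[obs]))) {
    abort("Non-finite intensities in input; clean or mask them first.",
          class = "brcaness_input_error")
  }
  v <- log2(pmax(raw$values, 0) + offset)
  update_expr(raw, values = v)
}

#' Quantile normalisation across samples
#'
#' Forces every sample's value distribution onto the common reference
#' distribution (the across-sample mean of the sorted columns). Ties within
#' a column receive the mean of the reference values at their tied ranks;
#' in columns with missing entries the observed values are placed by
#' interpolation on the reference distribution. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param m An [expr_matrix] with at least two samples.
#' @return An [expr_matrix]; the missingness mask is unchanged.
#' @export
quantile_normalize <- function(m) {
  m <- as_expr_matrix(m)
  if (ncol(m$values) < 2) {
    abort("Quantile normalisation needs at least two samples.",
          class = "brcaness_input_error")
  }
  all_missing <- colSums(!m$mask) == 0
  if (any(all_missing)) {
    abort(paste0("Sample entirely missing: ",
                 colnames(m$values)[all_missing][1]),
          class = "brcaness_input_error")
  }
  v <- masked_values(m)
  norm <- limma::normalizeQuantiles(v, ties = TRUE)
  # keep the (meaningless) stored numbers at masked positions
  norm[m$mask] <- m$values[m$mask]
  dimnames(norm) <- dimnames(m$values)
  update_expr(m, values = norm)
}

#' Flag low-signal entries as missing
#'
#' Entries with value strictly below `threshold` are marked missing in the
#' mask; the stored values are untouched. Intended for log2-scale data after
#' [background_log_transform()] and [quantile_normalize()].
#'
#' @param m An [expr_matrix].
#' @param threshold Entries `< threshold` are flagged (default 1).
#' @return An [expr_matrix] with an updated mask.
#' @export
flag_low_signal <- function(m, threshold = 1) {
  m <- as_expr_matrix(m)
  update_expr(m, mask = m$mask | (m$values < threshold))
}

#' k-nearest-neighbour imputation over gene rows
#'
#' Each missing entry (gene g, sample s) is replaced by the average, at
#' sample s, of the k gene rows nearest to g. Distance between rows is the
#' missing-aware Euclidean distance over co-observed samples, scaled by the
#' number of co-observed positions (root mean squared difference), the
#' standard convention for transcript imputation. Only rows observed at s
#' are candidate donors; when fewer than k exist all of them are used, and
#' when none exist the entry falls back to the row mean of g.
#'
#' @param m An [expr_matrix]; every gene row must have at least one
#'   observed value.
#' @param k Number of neighbours (default 10).
#' @return An [expr_matrix] with no missing entries.
#' @export
knn_impute <- function(m, k = 10) {
  m <- as_expr_matrix(m)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    abort("`k` must be a positive integer.", class = "brcaness_config_error")
  }
  v <- masked_values(m)
  obs <- !is.na(v)
  empty <- rowSums(obs) == 0
  if (any(empty)) {
    abort(paste0("Gene with no observed values: ",
                 rownames(v)[empty][1]),
          class = "brcaness_input_error")
  }
  out <- v
  need <- which(rowSums(!obs) > 0)
  if (length(need) > 0) {
    row_means <- rowMeans(v, na.rm = TRUE)
    for (g in need) {
      target <- v[g, ]
      # RMS difference over co-observed positions to every other row
      diff2 <- sweep(v, 2, target)^2
      co <- obs & rep(obs[g, ], each = nrow(v))
      diff2[!co] <- NA
      n_co <- rowSums(co)
      d <- sqrt(rowSums(diff2, na.rm = TRUE) / n_co)
      d[g] <- Inf
      d[n_co == 0] <- Inf
      ord <- order(d)
      for (s in which(!obs[g, ])) {
        donors <- ord[obs[ord, s] & is.finite(d[ord])]
        if (length(donors) == 0) {
          out[g, s] <- row_means[g]
        } else {
          out[g, s] <- mean(v[donors[seq_len(min(k, length(donors)))], s])
        }
      }
    }
  }
  expr_matrix(out, mask = matrix(FALSE, nrow(out), ncol(out)),
              batch = m$batch)
}

#' Batch adjustment by per-gene location/scale matching
#'
#' For each gene, every batch is standardised to the pooled values: the
#' batch mean is moved to the gene's grand mean and the batch standard
#' deviation rescaled to the pooled within-batch standard deviation. This
#' removes additive and multiplicative batch effects exactly (no
#' empirical-Bayes shrinkage) and preserves the per-gene grand mean.
#' Applying it twice equals applying it once.
#'
#' @param m An [expr_matrix] with batch labels and at least two samples per
#'   batch.
#' @return A batch-adjusted [expr_matrix].
#' @export
adjust_batch <- function(m) {
  m <- as_expr_matrix(m)
  if (is.null(m$batch)) {
    abort("Batch labels are required for batch adjustment.",
          class = "brcaness_input_error")
  }
  batches <- unique(m$batch)
  sizes <- table(m$batch)
  if (any(sizes < 2)) {
    abort(paste0("Batch with fewer than 2 samples: ",
                 names(sizes)[sizes < 2][1]),
          class = "brcaness_input_error")
  }
  if (length(batches) == 1) return(m)
  v <- m$values
  n <- ncol(v)
  grand <- rowMeans(v)
  # per-batch per-gene mean and sd
  bm <- sapply(batches, function(b) rowMeans(v[, m$batch == b, drop = FALSE]))
  bs <- sapply(batches, function(b) {
    vb <- v[, m$batch == b, drop = FALSE]
    sqrt(rowSums((vb - rowMeans(vb))^2) / (ncol(vb) - 1))
  })
  dfree <- as.numeric(sizes[batches]) - 1
  pooled_sd <- sqrt((bs^2 %*% dfree) / sum(dfree))[, 1]
  out <- v
  for (i in seq_along(batches)) {
    cols <- m$batch == batches[i]
    ratio <- ifelse(bs[, i] > 0, pooled_sd / bs[, i], 1)
    out[, cols] <- (v[, cols] - bm[, i]) * ratio + grand
  }
  update_expr(m, values = out)
}

#' Summarise probes to genes by first principal component
#'
#' Genes measured by a single probe pass through unchanged. For genes with
#' multiple probes, the probes whose Pearson correlation with the per-sample
#' mean probe profile is at least `min_corr` are retained (when none
#' qualify, the single probe closest to the mean profile is kept); the gene
#' value is the first principal component score of the retained probes
#' across samples, rescaled to the mean per-probe standard deviation,
#' sign-aligned to correlate positively with the mean probe profile, and
#' recentred at the mean profile's grand mean so it stays on the log2
#' expression scale.
#'
#' @param m A probe-level [expr_matrix] (complete; impute first).
#' @param map Probe-to-gene map: a data frame with columns `probe_id` and
#'   `gene_id` (many probes may map to one gene). Every probe in `m` must
#'   be covered.
#' @param min_corr Correlation cutoff for the "correlating subset"
#'   (default 0.5).
#' @return A gene-level [expr_matrix].
#' @export
summarize_probes <- function(m, map, min_corr = 0.5) {
  m <- as_expr_matrix(m)
  map <- as.data.frame(map)
  if (!all(c("probe_id", "gene_id") %in% names(map))) {
    abort("`map` needs columns `probe_id` and `gene_id`.",
          class = "brcaness_config_error")
  }
  if (anyDuplicated(map$probe_id)) {
    abort("Every probe must map to exactly one gene.",
          class = "brcaness_config_error")
  }
  probes <- rownames(m$values)
  hit <- match(probes, map$probe_id)
  if (anyNA(hit)) {
    abort(paste0("Probe absent from map: ", probes[is.na(hit)][1]),
          class = "brcaness_input_error")
  }
  gene_of <- map$gene_id[hit]
  genes <- unique(gene_of)
  out <- matrix(NA_real_, length(genes), ncol(m$values),
                dimnames = list(genes, colnames(m$values)))
  out_mask <- matrix(FALSE, length(genes), ncol(m$values),
                     dimnames = dimnames(out))
  for (gi in seq_along(genes)) {
    rows <- which(gene_of == genes[gi])
    if (length(rows) == 1) {
      out[gi, ] <- m$values[rows, ]
      out_mask[gi, ] <- m$mask[rows, ]
      next
    }
    P <- m$values[rows, , drop = FALSE]
    mean_prof <- colMeans(P)
    cors <- apply(P, 1, function(r) {
      if (sd(r) == 0 || sd(mean_prof) == 0) return(0)
      cor(r, mean_prof)
    })
    keep <- which(cors >= min_corr)
    if (length(keep) == 0) keep <- which.max(cors)
    if (length(keep) == 1) {
      out[gi, ] <- P[keep, ]
      next
    }
    X <- t(P[keep, , drop = FALSE])
    pc <- prcomp(X, center = TRUE, scale. = FALSE)
    score <- pc$x[, 1]
    probe_sds <- apply(P[keep, , drop = FALSE], 1, sd)
    if (sd(score) == 0) {
      out[gi, ] <- colMeans(P[keep, , drop = FALSE])
      next
    }
    score <- score * (mean(probe_sds) / sd(score))
    if (sd(mean_prof) > 0 && cor(score, mean_prof) < 0) score <- -score
    out[gi, ] <- score + mean(mean_prof)
  }
  expr_matrix(out, mask = out_mask, batch = m$batch)
}

#' Run the full expression preprocessing chain
#'
#' Applies, in order: background offset + log2 transform, quantile
#' normalisation, low-signal flagging, k-nearest-neighbour imputation,
#' batch adjustment (when batch labels are present) and probe-to-gene
#' summarisation (when a probe map is supplied).
#'
#' @param raw An [expr_matrix] of background-subtracted linear intensities.
#' @param probe_map Optional probe-to-gene map (see [summarize_probes()]).
#' @param offset Background offset (default 10).
#' @param low_signal Low-signal threshold on the log2 scale (default 1).
#' @param k Imputation neighbours (default 10).
#' @param min_corr Probe-summarisation correlation cutoff (default 0.5).
#' @param verbose Report stage-by-stage matrix shapes (default FALSE).
#' @return A preprocessed gene-level [expr_matrix].
#' @export
preprocess_expression <- function(raw, probe_map = NULL, offset = 10,
                                  low_signal = 1, k = 10, min_corr = 0.5,
                                  verbose = FALSE) {
  say <- function(stage, m) {
    if (verbose) {
      inform(sprintf("%s: %d x %d (%d missing)", stage, nrow(m$values),
                     ncol(m$values), sum(m$mask)))
    }
  }
  m <- background_log_transform(raw, offset = offset)
  say("background_log_transform", m)
  m <- quantile_normalize(m)
  say("quantile_normalize", m)
  m <- flag_low_signal(m, threshold = low_signal)
  say("flag_low_signal", m)
  m <- knn_impute(m, k = k)
  say("knn_impute", m)
  if (!is.null(m$batch) && length(unique(m$batch)) > 1) {
    m <- adjust_batch(m)
    say("adjust_batch", m)
  }
  if (!is.null(probe_map)) {
    m <- summarize_probes(m, probe_map, min_corr = min_corr)
    say("summarize_probes", m)
  }
  m
}
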