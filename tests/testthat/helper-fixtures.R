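# Small builders and independent brute-force oracles used across tests.
# Oracles are deliberately naive (loops, direct formulas) and share no code
# with the package internals they check.

make_expr <- function(values, batch = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  expr_matrix(values, batch = batch)
}

# a small separable two-class cohort: first `n_inf` genes shifted by `delta`
make_toy_cohort <- function(n_pos = 6, n_neg = 6, n_genes = 30, n_inf = 10,
                            delta = 2, noise = 1, seed = 1) {
  set.seed(seed)
  n <- n_pos + n_neg
  lab <- rep(c(TRUE, FALSE), c(n_pos, n_neg))
  v <- matrix(rnorm(n_genes * n, 5, noise), n_genes, n)
  v[seq_len(n_inf), lab] <- v[seq_len(n_inf), lab] + delta
  dimnames(v) <- list(sprintf("g%02d", seq_len(n_genes)),
                      sprintf("s%02d", seq_len(n)))
  list(expr = expr_matrix(v), label = setNames(lab, colnames(v)))
}

# --- independent oracles -------------------------------------------------

# quantile normalisation for complete matrices: reference = row means of
# sorted columns, placed back by rank (ties averaged)
oracle_quantile_normalize <- function(v) {
  ref <- rowMeans(apply(v, 2, sort))
  out <- v
  for (j in seq_len(ncol(v))) {
    r <- rank(v[, j], ties.method = "average")
    out[, j] <- stats::approx(seq_along(ref), ref, xout = r)$y
  }
  out
}

# naive kNN imputation over gene rows, RMS distance over co-observed samples
oracle_knn_impute <- function(v, k) {
  out <- v
  for (g in seq_len(nrow(v))) {
    for (s in seq_len(ncol(v))) {
      if (!is.na(v[g, s])) next
      d <- rep(Inf, nrow(v))
      for (j in seq_len(nrow(v))) {
        if (j == g) next
        co <- which(!is.na(v[g, ]) & !is.na(v[j, ]))
        if (length(co) == 0) next
        d[j] <- sqrt(mean((v[g, co] - v[j, co])^2))
      }
      cand <- order(d)
      cand <- cand[is.finite(d[cand]) & !is.na(v[cand, s])]
      if (length(cand) == 0) {
        out[g, s] <- mean(v[g, ], na.rm = TRUE)
      } else {
        out[g, s] <- mean(v[cand[seq_len(min(k, length(cand)))], s])
      }
    }
  }
  out
}

# DLDA posterior by direct Gaussian density ratio (not in the log domain)
oracle_dlda_posterior <- function(x, mean_pos, mean_neg, pooled_var,
                                  priors = c(0.5, 0.5)) {
  dp <- priors[1] * prod(stats::dnorm(x, mean_pos, sqrt(pooled_var)))
  dn <- priors[2] * prod(stats::dnorm(x, mean_neg, sqrt(pooled_var)))
  dp / (dp + dn)
}

# AUC by explicit pair counting, ties counted one half
oracle_auc <- function(score, lab) {
  pos <- score[lab]; neg <- score[!lab]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# full nested LOOCV gene-set-size search, naive loops throughout;
# per-fold ranking by two-sample pooled-t p-value (t^2 = F)
oracle_loocv <- function(v, lab, max_size) {
  n <- ncol(v)
  post <- matrix(NA_real_, n, max_size)
  for (i in seq_len(n)) {
    vt <- v[, -i, drop = FALSE]
    lt <- lab[-i]
    pvals <- apply(vt, 1, function(row) {
      stats::t.test(row[lt], row[!lt], var.equal = TRUE)$p.value
    })
    sdiff <- apply(vt, 1, function(row) {
      sp2 <- ((sum(lt) - 1) * stats::var(row[lt]) +
                (sum(!lt) - 1) * stats::var(row[!lt])) /
        (length(lt) - 2)
      (mean(row[lt]) - mean(row[!lt])) / sqrt(sp2)
    })
    ord <- order(pvals, -abs(sdiff), seq_len(nrow(vt)))
    for (N in seq_len(max_size)) {
      genes <- ord[seq_len(N)]
      mp <- rowMeans(vt[genes, lt, drop = FALSE])
      mn <- rowMeans(vt[genes, !lt, drop = FALSE])
      pv <- sapply(genes, function(g) {
        ((sum(lt) - 1) * stats::var(vt[g, lt]) +
           (sum(!lt) - 1) * stats::var(vt[g, !lt])) / (length(lt) - 2)
      })
      post[i, N] <- oracle_dlda_posterior(v[genes, i], mp, mn, pv)
    }
  }
  apply(post, 2, oracle_auc, lab = lab)
}

# temp paths for IO tests (fresh per call; tempdir is session-cleaned)
tmp_file <- function(name) {
  path <- file.path(tempdir(), paste0("brcaness_", name))
  if (file.exists(path)) unlink(path)
  path
}

tmp_dir <- function(name) {
  path <- file.path(tempdir(), paste0("brcaness_", name))
  unlink(path, recursive = TRUE)
  path
}
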