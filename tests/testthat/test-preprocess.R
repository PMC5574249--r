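test_that("background transform floors at zero and adds the offset", {
  v <- matrix(c(0, 6, -3, 54), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  out <- background_log_transform(make_expr(v), offset = 10)
  expect_equal(out$values["g1", "s1"], log2(10))
  expect_equal(out$values["g2", "s1"], 4)          # log2(6 + 10)
  expect_equal(out$values["g1", "s2"], log2(10))   # over-subtracted, floored
  expect_equal(out$values["g2", "s2"], 6)
  expect_true(all(is.finite(out$values)))
  expect_error(background_log_transform(make_expr(matrix(c(1, Inf, 2, 3),
                                                          2, 2))),
               "Non-finite")
  expect_error(background_log_transform(make_expr(v), offset = 0),
               "positive")
})

test_that("quantile normalisation matches the hand-computed reference", {
  v <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  rownames(v) <- paste0("g", 1:3)
  out <- quantile_normalize(make_expr(v))
  expect_equal(unname(out$values[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out$values[, "b"]), c(2.5, 3.5, 4.5))
})

test_that("identical columns are unchanged and sorted columns agree", {
  v <- cbind(a = c(3, 1, 7, 5), b = c(3, 1, 7, 5))
  rownames(v) <- paste0("g", 1:4)
  out <- quantile_normalize(make_expr(v))
  expect_equal(out$values, make_expr(v)$values)

  set.seed(7)
  r <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  qn <- quantile_normalize(make_expr(r))
  sorted <- apply(qn$values, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  # matches the independent oracle and is idempotent
  expect_equal(unname(qn$values), unname(oracle_quantile_normalize(r)))
  expect_equal(quantile_normalize(qn)$values, qn$values, tolerance = 1e-8)
})

test_that("ties receive the mean of the reference values at tied ranks", {
  v <- cbind(a = c(1, 1, 5), b = c(2, 4, 9))
  rownames(v) <- paste0("g", 1:3)
  out <- quantile_normalize(make_expr(v))
  ref <- rowMeans(apply(v, 2, sort))
  expect_equal(unname(out$values[1:2, "a"]),
               rep(mean(ref[1:2]), 2))
})

test_that("a fully missing sample is reported by name", {
  v <- cbind(a = c(1, 2), b = c(NA, NA))
  rownames(v) <- paste0("g", 1:2)
  expect_error(quantile_normalize(make_expr(v)), "b")
})

test_that("low-signal flagging is strict and leaves values untouched", {
  v <- matrix(c(0.99, 1.00, 1.5, 2), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  out <- flag_low_signal(make_expr(v), threshold = 1)
  expect_true(out$mask["g1", "s1"])    # 0.99 < 1
  expect_false(out$mask["g2", "s1"])   # boundary 1.00 not flagged
  expect_equal(out$values, v)
  clean <- flag_low_signal(make_expr(v + 10), threshold = 1)
  expect_equal(sum(clean$mask), 0)
})

test_that("kNN imputation matches the brute-force oracle", {
  set.seed(11)
  v <- matrix(rnorm(120, 6), 20, 6,
              dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:6)))
  holes <- sample(length(v), round(0.05 * length(v)))
  v[holes] <- NA
  out <- knn_impute(make_expr(v), k = 3)
  expect_equal(sum(out$mask), 0)
  expect_equal(unname(out$values), unname(oracle_knn_impute(v, 3)),
               tolerance = 1e-12)
  # observed entries never altered
  expect_equal(out$values[-holes], v[-holes])
})

test_that("a zero-distance duplicate row dominates the imputation", {
  v <- matrix(rnorm(24), 4, 6,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  v[2, ] <- v[1, ]          # duplicate of row 1
  v[1, 3] <- NA
  out <- knn_impute(make_expr(v), k = 1)
  expect_equal(out$values[1, 3], v[2, 3])
})

test_that("k larger than the candidate pool uses all candidates", {
  v <- matrix(c(1, 2, NA, 2, 3, 4, 3, 4, 5), 3, 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  out <- knn_impute(make_expr(v), k = 10)
  expect_equal(out$values[1, 3], mean(c(4, 5)))
  all_na <- v; all_na[2, ] <- NA
  expect_error(knn_impute(make_expr(all_na)), "g2")
})

test_that("batch adjustment matches locations and is idempotent", {
  set.seed(3)
  v <- matrix(rnorm(200, 5), 10, 20,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))
  batch <- rep(c("b1", "b2"), each = 10)
  shifted <- v
  shifted[, batch == "b2"] <- shifted[, batch == "b2"] + 2  # constant shift
  out <- adjust_batch(make_expr(shifted, batch = batch))
  m1 <- rowMeans(out$values[, batch == "b1"])
  m2 <- rowMeans(out$values[, batch == "b2"])
  expect_true(all(abs(m1 - m2) < 1e-10))
  # grand mean preserved
  expect_equal(rowMeans(out$values), rowMeans(shifted))
  # idempotent
  out2 <- adjust_batch(out)
  expect_equal(out2$values, out$values, tolerance = 1e-8)
  # single batch is the identity
  one <- make_expr(v, batch = rep("b1", 20))
  expect_equal(adjust_batch(one)$values, v)
  # singleton batch rejected
  expect_error(adjust_batch(make_expr(v, batch = c(rep("b1", 19), "b2"))),
               "fewer than 2")
})

test_that("batch adjustment shrinks the batch F statistic on nearly all genes", {
  set.seed(5)
  g <- 200; n <- 40
  batch <- rep(c("b1", "b2"), each = n / 2)
  v <- matrix(rnorm(g * n, 6), g, n,
              dimnames = list(sprintf("g%03d", 1:g), paste0("s", 1:n)))
  v[, batch == "b2"] <- v[, batch == "b2"] + rnorm(g, 0, 0.5)
  fstat <- function(m) {
    apply(m, 1, function(row) {
      summary(stats::aov(row ~ factor(batch)))[[1]]$`F value`[1]
    })
  }
  before <- fstat(v)
  after <- fstat(adjust_batch(make_expr(v, batch = batch))$values)
  expect_gte(mean(after < before), 0.99)
})

test_that("probe summarisation handles rank-1, single-probe and anti-correlated cases", {
  set.seed(9)
  base <- rnorm(12, 5)
  v <- rbind(p1 = base, p2 = 2 * base + 1,      # perfectly correlated pair
             p3 = rnorm(12, 5),                  # single-probe gene
             p4 = base + rnorm(12, 0, 0.1),      # geneC: correlated trio
             p5 = base + rnorm(12, 0, 0.1),
             p6 = -base + 10)                    # anti-correlated probe
  colnames(v) <- paste0("s", 1:12)
  map <- data.frame(probe_id = paste0("p", 1:6),
                    gene_id = c("geneA", "geneA", "geneB",
                                "geneC", "geneC", "geneC"))
  out <- summarize_probes(make_expr(v), map)
  expect_equal(rownames(out$values), c("geneA", "geneB", "geneC"))
  # rank-1 gene: summary correlates perfectly with both probes
  expect_equal(abs(cor(out$values["geneA", ], v["p1", ])), 1,
               tolerance = 1e-10)
  # single probe passes through unchanged
  expect_equal(unname(out$values["geneB", ]), unname(v["p3", ]))
  # the r = -1 probe is excluded: the summary tracks the correlated pair
  expect_gt(cor(out$values["geneC", ], v["p4", ]), 0.9)
  expect_lt(cor(out$values["geneC", ], v["p6", ]), 0)
  # unmapped probe is named in the error
  expect_error(summarize_probes(make_expr(v), map[-2, ]), "p2")
})

test_that("pipeline stages preserve dimensions except probe summarisation", {
  set.seed(21)
  v <- matrix(rexp(300, 0.02), 30, 10,
              dimnames = list(sprintf("g%02d", 1:30), paste0("s", 1:10)))
  batch <- rep(c("b1", "b2"), each = 5)
  m <- preprocess_expression(make_expr(v, batch = batch))
  expect_equal(dim(m), c(30L, 10L))
  expect_equal(sum(m$mask), 0)
})
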