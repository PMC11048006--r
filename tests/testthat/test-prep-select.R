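test_that("z-scoring standardises training data and freezes test transforms", {
  x <- matrix(rnorm(50), 10, 5, dimnames = list(NULL, paste0("f", 1:5)))
  p <- zscore_fit(x)
  z <- zscore_apply(p, x)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 2, function(v) sqrt(mean(v^2))) - 1)), 1e-9)
  # population-sd convention, checked by hand: train {1,2,3}, test value 4
  p2 <- zscore_fit(matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "a")))
  z4 <- zscore_apply(p2, matrix(4, 1, 1, dimnames = list(NULL, "a")))
  expect_equal(as.numeric(z4), (4 - 2) / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(as.numeric(z4), 2.4495, tolerance = 1e-4)
  # constant feature maps to 0 with a flag
  xc <- cbind(a = rnorm(5), b = rep(3, 5))
  pc <- zscore_fit(xc)
  expect_true(pc$constant["b"])
  zc <- zscore_apply(pc, xc)
  expect_true(all(zc[, "b"] == 0))
  expect_identical(attr(zc, "constant_features"), "b")
})

test_that("pearson_r matches closed forms and rejects degenerate input", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_r(x, rep(1, 4)), class = "subgrade_value_error")
  expect_error(pearson_r(1:2, 1:2), class = "subgrade_value_error")
})

test_that("the correlation filter drops the later feature of offending pairs", {
  withr::with_seed(1, {
    a <- rnorm(50)
    b <- rnorm(50)
    x <- cbind(f1 = a, f2 = a + rnorm(50, sd = 0.05), f3 = b,
               f4 = -a + rnorm(50, sd = 0.05))
  })
  rep <- correlation_filter(x, 0.8)
  expect_identical(rep$kept, c("f1", "f3"))
  expect_true(all(c("f2", "f4") %in% rep$dropped_by_correlation$feature))
  # survivors are pairwise below threshold
  expect_true(all(abs(cor(x[, rep$kept])[upper.tri(diag(2))]) <= 0.8))
  # duplicated column: exactly one copy dropped
  xd <- cbind(u = a, v = a)
  expect_identical(correlation_filter(xd)$kept, "u")
  # independent features survive untouched
  withr::with_seed(2, xi <- matrix(rnorm(300), 100, 3,
                                   dimnames = list(NULL, c("a", "b", "c"))))
  expect_identical(correlation_filter(xi)$kept, c("a", "b", "c"))
  # exhaustive oracle with the same order rule on random structures
  for (seed in 1:5) {
    withr::with_seed(seed, {
      base <- matrix(rnorm(200), 50, 4)
      xm <- cbind(base, base[, 1] + rnorm(50, sd = 0.1))
      colnames(xm) <- paste0("g", 1:5)
    })
    cm <- abs(cor(xm))
    dropped <- logical(5)
    for (i in 1:4) {
      if (dropped[i]) next
      for (j in (i + 1):5)
        if (!dropped[j] && cm[i, j] > 0.8) dropped[j] <- TRUE
    }
    expect_identical(correlation_filter(xm)$kept, colnames(xm)[!dropped])
  }
})

test_that("importance selection ranks the informative feature first", {
  withr::with_seed(3, {
    x <- matrix(rnorm(600), 100, 6, dimnames = list(NULL, paste0("f", 1:6)))
    y <- as.integer(x[, 4] > 0) # noiseless dependence on f4 only
  })
  rep <- importance_select(x, y, k = 2, seed = 1)
  expect_identical(rep$kept[1], "f4")
  # k = all features is the identity selection (as a set)
  rep_all <- importance_select(x, y, k = 6, seed = 1)
  expect_setequal(rep_all$kept, colnames(x))
  # same seed, same ranking
  expect_identical(importance_select(x, y, k = 3, seed = 9)$kept,
                   importance_select(x, y, k = 3, seed = 9)$kept)
  expect_warning(importance_select(x, y, k = 10, seed = 1), "clamped")
})

test_that("SMOTE balances classes with convex same-class synthetics", {
  withr::with_seed(4, {
    x <- rbind(matrix(rnorm(40, mean = 0), 20, 2),
               matrix(rnorm(12, mean = 4), 6, 2))
    colnames(x) <- c("a", "b")
    y <- c(rep(0L, 20), rep(1L, 6))
  })
  out <- smote(x, y, seed = 1)
  expect_equal(sum(out$y == 0), sum(out$y == 1))
  expect_identical(out$x[seq_along(y), ], x) # originals preserved
  syn <- out$x[out$synthetic, , drop = FALSE]
  minority <- x[y == 1L, , drop = FALSE]
  # every synthetic point lies on a segment between two minority originals:
  # with 2-d features, test convex-combination membership directly
  for (i in seq_len(nrow(syn))) {
    ok <- FALSE
    for (a in seq_len(nrow(minority) - 1))
      for (b in (a + 1):nrow(minority)) {
        pa <- minority[a, ]
        pb <- minority[b, ]
        lam <- if (abs(pb[1] - pa[1]) > 1e-12)
          (syn[i, 1] - pa[1]) / (pb[1] - pa[1]) else NA
        if (!is.na(lam) && lam >= -1e-9 && lam <= 1 + 1e-9 &&
            abs(pa[2] + lam * (pb[2] - pa[2]) - syn[i, 2]) < 1e-9)
          ok <- TRUE
      }
    expect_true(ok)
  }
  # two-point minority with k = 1: synthetics on the open segment
  x2 <- rbind(matrix(rnorm(20), 10, 2), c(0, 0), c(1, 1))
  y2 <- c(rep(0L, 10), 1L, 1L)
  out2 <- smote(x2, y2, k_neighbours = 1, seed = 2)
  syn2 <- out2$x[out2$synthetic, , drop = FALSE]
  expect_true(all(abs(syn2[, 1] - syn2[, 2]) < 1e-12))
  expect_true(all(syn2[, 1] >= 0 & syn2[, 1] <= 1))
  # balanced input is returned unchanged
  out3 <- smote(x2[c(1:2, 11:12), ], c(0L, 0L, 1L, 1L), seed = 3)
  expect_false(any(out3$synthetic))
  # deterministic under seed; clamping warns
  expect_identical(smote(x, y, seed = 5)$x, smote(x, y, seed = 5)$x)
  expect_warning(smote(x, y, k_neighbours = 10, seed = 1), "clamped")
  expect_error(smote(x[1:21, ], c(rep(0L, 20), 1L), seed = 1),
               class = "subgrade_balance_error")
})
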