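test_that("every classifier learns a separable toy and honours the score contract", {
  toy <- mk_separable(40)
  for (nm in names(default_model_specs())) {
    m <- train_model(model_spec(nm), toy$x, toy$y)
    pr <- predict(m, toy$x)
    expect_gte(mean(pr$label == toy$y), 0.9)
    expect_true(all(pr$score >= 0 & pr$score <= 1))
    expect_identical(pr$label, as.integer(pr$score >= 0.5))
  }
})

test_that("model specs validate names and carry the published defaults", {
  expect_error(model_spec("GBM"), class = "subgrade_config_error")
  s <- model_spec("SVM")
  expect_equal(s$hyperparameters$cost, 0.01)
  expect_equal(s$hyperparameters$gamma, 0.2)
  expect_equal(model_spec("RF")$hyperparameters$num_trees, 401L)
  expect_equal(model_spec("RF")$hyperparameters$max_depth, 3L)
  expect_equal(model_spec("XGBoost")$hyperparameters$nrounds, 401L)
  expect_equal(model_spec("XGBoost")$hyperparameters$gamma, 0.52)
  expect_equal(model_spec("CatBoost")$hyperparameters$nrounds, 50L)
  expect_equal(model_spec("LightGBM")$hyperparameters$nrounds, 9L)
  expect_equal(model_spec("AdaBoost")$hyperparameters$n_estimators, 201L)
  expect_equal(model_spec("AdaBoost")$hyperparameters$learning_rate, 0.01)
  expect_equal(model_spec("LR")$hyperparameters$maxit, 4L)
  expect_equal(model_spec("MLP")$hyperparameters$hidden, c(401L, 201L))
  expect_equal(model_spec("QDA")$hyperparameters$reg_param, 0.05)
  # hyperparameter overrides take effect
  s2 <- model_spec("RF", list(num_trees = 11L))
  expect_equal(s2$hyperparameters$num_trees, 11L)
  expect_error(train_model(model_spec("RF"), matrix(1:4, 2), c(2L, 3L)),
               class = "subgrade_label_error")
})

test_that("stochastic learners are reproducible under a fixed seed", {
  toy <- mk_separable(30, seed = 11)
  for (nm in c("RF", "MLP", "LSTM", "AdaBoost", "XGBoost")) {
    p1 <- predict(train_model(model_spec(nm, seed = 7), toy$x, toy$y), toy$x)
    p2 <- predict(train_model(model_spec(nm, seed = 7), toy$x, toy$y), toy$x)
    expect_identical(p1, p2)
  }
})

test_that("stratified splitting preserves class balance and is reusable", {
  y <- c(rep(0L, 30), rep(1L, 60))
  tr <- stratified_split(y, 0.67, seed = 1)
  expect_equal(sum(y[tr] == 0), round(0.67 * 30))
  expect_equal(sum(y[tr] == 1), round(0.67 * 60))
  expect_identical(tr, stratified_split(y, 0.67, seed = 1))
  expect_false(identical(tr, stratified_split(y, 0.67, seed = 2)))
})

test_that("the experiment grid reuses one split per cohort across all cells", {
  withr::with_seed(8, {
    mk_tables <- function(n) {
      ids <- sprintf("s%02d", 1:n)
      y <- rep_len(c(0L, 0L, 1L), n)
      lapply(setNames(nm = c("full", "core50")), function(r) {
        x <- matrix(rnorm(n * 6), n, 6,
                    dimnames = list(NULL, paste0("f", 1:6)))
        x[, 1] <- x[, 1] + 2 * y
        data.frame(subject_id = ids, grade_label = y, x,
                   check.names = FALSE)
      })
    }
    tabs <- list(c1 = mk_tables(30), c2 = mk_tables(33))
  })
  specs <- default_model_specs()[c("NB", "LR", "QDA")]
  grid <- run_grid(tabs, specs, k_selected = 4L)
  expect_equal(nrow(grid), 2 * 2 * 3) # cohorts x regions x models
  splits <- attr(grid, "splits")
  expect_named(splits, c("c1", "c2"))
  # split identity is recorded per cohort and shared across its cells
  expect_length(splits$c1$hash, 1)
  expect_true(all(c("ACC", "AUC", "MCC", "F1") %in% names(grid)))
  # misaligned region tables abort
  bad <- tabs
  bad$c1$core50 <- bad$c1$core50[c(2:30, 1), ]
  expect_error(run_grid(bad, specs), class = "subgrade_alignment_error")
})

test_that("external validation never touches test-cohort statistics", {
  withr::with_seed(9, {
    mk <- function(n, shift) {
      x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
      y <- rep_len(c(0L, 1L), n)
      x[, 2] <- x[, 2] + 1.5 * y + shift
      data.frame(subject_id = sprintf("e%02d", 1:n), grade_label = y, x,
                 check.names = FALSE)
    }
    train <- list(full = mk(40, 0))
    test <- list(full = mk(36, 0.3))
  })
  specs <- default_model_specs()[c("NB", "LR")]
  res1 <- external_validate(train, test, specs, k_selected = 3L)
  expect_equal(nrow(res1), 2)
  # swapping cohorts changes the outcome (no hidden state)
  res2 <- external_validate(test, train, specs, k_selected = 3L)
  expect_false(isTRUE(all.equal(res1$AUC, res2$AUC)))
  # schema mismatch is refused
  test_bad <- test
  names(test_bad$full)[3] <- "renamed"
  expect_error(external_validate(train, test_bad, specs),
               class = "subgrade_schema_error")
})

test_that("classifier averaging reproduces the core/periphery mean formula", {
  grid <- data.frame(
    cohort = "c1",
    region = rep(c("core25", "core50", "core75",
                   "periphery25", "periphery50", "periphery75", "full"), 1),
    model = "CatBoost",
    AUC = c(80.7, 80.7, 80.7, 79.3, 79.3, 79.3, 99))
  avg <- classifier_average_auc(grid)
  expect_equal(avg$AUC, 80.0)
  expect_equal(avg$core_avg, 80.7)
  expect_equal(avg$periphery_avg, 79.3)
})
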