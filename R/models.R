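# Uniform train/predict contract over the eleven-classifier zoo. Every
# model consumes a standardised, selected, SMOTE-balanced training matrix
# with binary labels (1 = high grade), exposes a continuous score in [0, 1]
# and thresholds it at 0.5 for the hard label. Hyperparameter defaults
# follow the published optimisation table verbatim, including deliberately
# tiny iteration caps (logistic regression max 4 IRLS steps, MLP max 5
# epochs); non-convergence there is logged, not fatal.

MODEL_NAMES <- c("SVM", "RF", "XGBoost", "NB", "MLP", "LSTM", "LR", "QDA",
                 "LightGBM", "CatBoost", "AdaBoost")

default_hyperparameters <- function(name) {
  switch(name,
    SVM = list(kernel = "radial", gamma = 0.2, cost = 0.01,
               probability = TRUE),
    RF = list(num_trees = 401L, max_depth = 3L),
    XGBoost = list(nrounds = 401L, eta = 0.01, gamma = 0.52),
    NB = list(),
    MLP = list(hidden = c(401L, 201L), maxit = 5L, learning_rate = 1e-3,
               batch_size = 200L),
    LSTM = list(hidden = 16L),
    LR = list(maxit = 4L),
    QDA = list(reg_param = 0.05),
    LightGBM = list(nrounds = 9L, eta = 0.1, max_leaves = 31L),
    CatBoost = list(nrounds = 50L, eta = 0.03, max_depth = 6L),
    AdaBoost = list(n_estimators = 201L, learning_rate = 0.01,
                    base_num_trees = 401L, base_max_depth = 3L),
    stop_subgrade(paste("unknown model:", name), "subgrade_config_error"))
}

#' Specification of one classifier in the model zoo
#'
#' @param name one of `"SVM"`, `"RF"`, `"XGBoost"`, `"NB"`, `"MLP"`,
#'   `"LSTM"`, `"LR"`, `"QDA"`, `"LightGBM"`, `"CatBoost"`, `"AdaBoost"`.
#' @param hyperparameters named overrides of the published defaults.
#' @param seed integer seed for stochastic learners.
#' @return A `model_spec` list.
#' @export
model_spec <- function(name, hyperparameters = list(), seed = 42L) {
  if (!name %in% MODEL_NAMES)
    stop_subgrade(paste("unknown model:", name), "subgrade_config_error")
  hp <- default_hyperparameters(name)
  hp[names(hyperparameters)] <- hyperparameters
  structure(list(name = name, hyperparameters = hp, seed = as.integer(seed)),
            class = "model_spec")
}

#' The eleven default classifier specifications
#' @param seed seed shared by all specs.
#' @return Named list of [model_spec()] objects.
#' @export
default_model_specs <- function(seed = 42L) {
  setNames(lapply(MODEL_NAMES, model_spec, seed = seed), MODEL_NAMES)
}

check_xy <- function(x, y) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (nrow(x) != length(y))
    stop_subgrade("x and y sizes differ", "subgrade_alignment_error")
  if (!all(y %in% c(0L, 1L)) || length(unique(y)) < 2L)
    stop_subgrade("y must be binary 0/1 with both classes present",
                  "subgrade_label_error")
  list(x = x, y = y)
}

#' Train one classifier
#'
#' @param spec a [model_spec()].
#' @param x numeric feature matrix (standardised, selected, balanced).
#' @param y binary labels (1 = high grade), both classes present.
#' @return A fitted `subgrade_model`; see [predict.subgrade_model()].
#' @export
train_model <- function(spec, x, y) {
  stopifnot(inherits(spec, "model_spec"))
  d <- check_xy(x, y)
  x <- d$x
  y <- d$y
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  hp <- spec$hyperparameters
  notes <- character(0)
  fit <- with_seed(spec$seed, switch(spec$name,
    SVM = e1071::svm(x, factor(y, levels = c(0, 1)), kernel = hp$kernel,
                     gamma = hp$gamma, cost = hp$cost, scale = FALSE),
    RF = ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                        num.trees = hp$num_trees, max.depth = hp$max_depth,
                        probability = TRUE, num.threads = 1L,
                        seed = spec$seed),
    XGBoost = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = hp$eta,
                    gamma = hp$gamma, nthread = 1L, seed = spec$seed),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1L),
      nrounds = hp$nrounds, verbose = 0),
    NB = e1071::naiveBayes(x, factor(y, levels = c(0, 1))),
    MLP = mlp_fit(x, y, hp),
    LSTM = lstm_fit(x, y, hp$hidden),
    LR = {
      df <- data.frame(y = y, x)
      withCallingHandlers(
        glm(y ~ ., data = df, family = binomial(),
            control = list(maxit = hp$maxit)),
        warning = function(w) {
          notes <<- c(notes, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    },
    QDA = qda_reg_fit(x, y, hp$reg_param),
    LightGBM = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = hp$eta,
                    tree_method = "hist", grow_policy = "lossguide",
                    max_leaves = hp$max_leaves, max_depth = 0L,
                    nthread = 1L, seed = spec$seed),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1L),
      nrounds = hp$nrounds, verbose = 0),
    CatBoost = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = hp$eta,
                    max_depth = hp$max_depth, nthread = 1L,
                    seed = spec$seed),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1L),
      nrounds = hp$nrounds, verbose = 0),
    AdaBoost = adaboost_fit(x, y, hp, spec$seed)))
  structure(list(spec = spec, fit = fit, features = colnames(x),
                 notes = notes),
            class = "subgrade_model")
}

#' Predict grade scores and labels
#'
#' Every model yields a continuous score in `[0, 1]` (a probability or
#' calibrated decision value for the high-grade class) and the hard label
#' `1[score >= 0.5]`.
#'
#' @param object a fitted `subgrade_model`.
#' @param newdata feature matrix with the training columns.
#' @param ... unused.
#' @return Data frame with columns `score` and `label`.
#' @export
predict.subgrade_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (is.null(colnames(x))) colnames(x) <- object$features
  x <- x[, object$features, drop = FALSE]
  fit <- object$fit
  score <- switch(object$spec$name,
    SVM = {
      # calibrated decision value: sigmoid of the signed margin, oriented
      # towards the high-grade class, so label = 1[score >= 0.5] matches
      # the decision-function sign (Platt probabilities at this heavily
      # regularised C hover arbitrarily around 0.5)
      dvm <- attr(predict(fit, x, decision.values = TRUE),
                  "decision.values")
      dv <- if (grepl("^0", colnames(dvm)[1])) -dvm[, 1] else dvm[, 1]
      1 / (1 + exp(-dv))
    },
    RF = predict(fit, data = x, num.threads = 1L)$predictions[, "1"],
    XGBoost = , LightGBM = , CatBoost =
      predict(fit, xgboost::xgb.DMatrix(x, nthread = 1L)),
    NB = predict(fit, x, type = "raw")[, "1"],
    MLP = mlp_score(fit, x),
    LSTM = lstm_score(fit, x),
    LR = {
      df <- data.frame(x)
      as.numeric(predict(fit, newdata = df, type = "response"))
    },
    QDA = qda_reg_score(fit, x),
    AdaBoost = adaboost_score(fit, x))
  score <- pmin(pmax(as.numeric(score), 0), 1)
  data.frame(score = score, label = as.integer(score >= 0.5))
}

# --- two-hidden-layer perceptron ------------------------------------------
# relu hidden layers, sigmoid output, binary cross-entropy, adam updates on
# mini-batches. The published configuration caps training at 5 epochs, so
# the net is deliberately under-trained; scores are still informative
# because even a few adam steps align the output layer with the dominant
# features. Deterministic given the seed wrapping train_model().
mlp_fit <- function(x, y, hp) {
  sizes <- c(ncol(x), hp$hidden, 1L)
  nl <- length(sizes) - 1L
  W <- list()
  b <- list()
  for (l in seq_len(nl)) {
    # He initialisation for relu layers
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(z) z * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- hp$learning_rate
  n <- nrow(x)
  bs <- min(hp$batch_size, n)
  step <- 0L
  for (epoch in seq_len(hp$maxit)) {
    idx <- sample.int(n)
    for (start in seq(1L, n, by = bs)) {
      rows <- idx[start:min(start + bs - 1L, n)]
      xb <- x[rows, , drop = FALSE]
      yb <- y[rows]
      # forward
      a <- list(xb)
      for (l in seq_len(nl)) {
        z <- sweep(a[[l]] %*% W[[l]], 2, b[[l]], `+`)
        a[[l + 1]] <- if (l < nl) pmax(z, 0) else 1 / (1 + exp(-z))
      }
      # backward (cross-entropy + sigmoid cancels to p - y)
      delta <- (a[[nl + 1]] - yb) / length(rows)
      step <- step + 1L
      for (l in rev(seq_len(nl))) {
        gW <- crossprod(a[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L)
          delta <- (delta %*% t(W[[l]])) * (a[[l]] > 0)
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        mhW <- mW[[l]] / (1 - beta1^step)
        vhW <- vW[[l]] / (1 - beta2^step)
        mhb <- mb[[l]] / (1 - beta1^step)
        vhb <- vb[[l]] / (1 - beta2^step)
        W[[l]] <- W[[l]] - lr * mhW / (sqrt(vhW) + eps)
        b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + eps)
      }
    }
  }
  list(W = W, b = b, nl = nl)
}

mlp_score <- function(fit, x) {
  a <- x
  for (l in seq_len(fit$nl)) {
    z <- sweep(a %*% fit$W[[l]], 2, fit$b[[l]], `+`)
    a <- if (l < fit$nl) pmax(z, 0) else 1 / (1 + exp(-z))
  }
  as.numeric(a)
}

# --- regularised quadratic discriminant analysis -------------------------
# Per-class Gaussian with covariance shrunk towards the identity:
# S_r = (1 - r) S + r I (features arrive z-scored, so unit scale).
qda_reg_fit <- function(x, y, reg_param) {
  classes <- c(0L, 1L)
  fits <- lapply(classes, function(k) {
    xk <- x[y == k, , drop = FALSE]
    mu <- colMeans(xk)
    s <- stats::cov(xk)
    s[!is.finite(s)] <- 0
    sr <- (1 - reg_param) * s + reg_param * diag(ncol(x))
    ch <- tryCatch(chol(sr), error = function(e) chol(sr + 1e-6 * diag(ncol(x))))
    list(mu = mu, chol = ch, logdet = 2 * sum(log(diag(ch))),
         logprior = log(nrow(xk) / nrow(x)))
  })
  list(fits = setNames(fits, classes))
}

qda_reg_score <- function(fit, x) {
  ll <- sapply(fit$fits, function(f) {
    z <- forwardsolve(t(f$chol), t(x) - f$mu)
    -0.5 * colSums(z^2) - 0.5 * f$logdet + f$logprior
  })
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1)
  1 / (1 + exp(ll[, "0"] - ll[, "1"]))
}

# --- LSTM with trained logistic readout ----------------------------------
# The feature vector is treated as a length-F sequence of scalars driving a
# randomly initialised LSTM cell; the mean-pooled hidden states (so early
# sequence positions are not forgotten) are read out by a logistic layer
# fitted to the labels. Deterministic given the seed that wraps
# train_model().
lstm_fit <- function(x, y, hidden) {
  h <- hidden
  init <- function(n) matrix(rnorm(n, sd = 0.5), nrow = h)
  par <- list(Wi = init(h), Wf = init(h), Wo = init(h), Wg = init(h),
              Ui = init(h * h) , Uf = init(h * h), Uo = init(h * h),
              Ug = init(h * h), b = rep(0, h))
  dim(par$Ui) <- dim(par$Uf) <- dim(par$Uo) <- dim(par$Ug) <- c(h, h)
  states <- lstm_states(par, x)
  df <- data.frame(y = y, states)
  readout <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
  list(par = par, readout = readout, hidden = h)
}

lstm_states <- function(par, x) {
  n <- nrow(x)
  h <- length(par$b)
  hs <- matrix(0, n, h)
  cs <- matrix(0, n, h)
  pool <- matrix(0, n, h)
  sig <- function(z) 1 / (1 + exp(-z))
  for (t in seq_len(ncol(x))) {
    xt <- x[, t]
    ig <- sig(outer(xt, par$Wi[, 1]) + hs %*% par$Ui)
    fg <- sig(outer(xt, par$Wf[, 1]) + hs %*% par$Uf)
    og <- sig(outer(xt, par$Wo[, 1]) + hs %*% par$Uo)
    gg <- tanh(outer(xt, par$Wg[, 1]) + hs %*% par$Ug +
                 matrix(par$b, n, h, byrow = TRUE))
    cs <- fg * cs + ig * gg
    hs <- og * tanh(cs)
    pool <- pool + hs
  }
  st <- as.data.frame(pool / ncol(x))
  names(st) <- paste0("h", seq_len(h))
  st
}

lstm_score <- function(fit, x) {
  st <- lstm_states(fit$par, x)
  as.numeric(predict(fit$readout, newdata = st, type = "response"))
}

# --- AdaBoost (discrete SAMME) over a random-forest base ------------------
adaboost_fit <- function(x, y, hp, seed) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  learners <- list()
  alphas <- numeric(0)
  seeds <- derive_seeds(seed, hp$n_estimators)
  for (m in seq_len(hp$n_estimators)) {
    base <- ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                           num.trees = hp$base_num_trees,
                           max.depth = hp$base_max_depth,
                           case.weights = w, num.threads = 1L,
                           seed = seeds[m])
    pred <- as.integer(as.character(
      predict(base, data = x, num.threads = 1L)$predictions))
    err <- sum(w * (pred != y))
    if (err >= 0.5) {
      if (length(learners) == 0L) { # keep one learner so scores exist
        learners[[1]] <- base
        alphas <- 1
      }
      break
    }
    alpha <- if (err <= 0) 10 else hp$learning_rate * log((1 - err) / err)
    learners[[length(learners) + 1L]] <- base
    alphas <- c(alphas, alpha)
    if (err <= 0) break
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
  }
  list(learners = learners, alphas = alphas)
}

adaboost_score <- function(fit, x) {
  votes <- 0
  for (m in seq_along(fit$learners)) {
    pred <- as.integer(as.character(
      predict(fit$learners[[m]], data = x, num.threads = 1L)$predictions))
    votes <- votes + fit$alphas[m] * (2 * pred - 1)
  }
  (votes / sum(fit$alphas) + 1) / 2
}
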