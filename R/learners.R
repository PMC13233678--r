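## Internal learner layer: a unified fit/predict interface over the
## regressors the pipeline uses. Latent-variable linear regression
## (SIMPLS) and the Bayesian ridge meta-learner are authored here; SVR,
## random forest, ridge and the boosted-tree learners go through e1071,
## ranger, glmnet and xgboost. The "gbdt" learner is a classical
## unregularized gradient-boosted tree configuration; "xgb" is the
## regularized variant (L2 penalty, row subsampling, column sampling).

## ---- SIMPLS --------------------------------------------------------------

# de Jong's SIMPLS for a univariate response. Returns a linear predictor
# (coefficients + intercept) using ncomp latent components.
.simpls <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  ncomp <- max(1L, min(ncomp, p, n - 1L))
  xm <- colMeans(X)
  ym <- mean(y)
  X0 <- sweep(X, 2, xm)
  y0 <- y - ym
  S <- crossprod(X0, y0)
  R <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  V <- matrix(0, p, ncomp)
  used <- 0L
  for (a in seq_len(ncomp)) {
    r <- S # univariate y: dominant direction is S itself
    t <- X0 %*% r
    nt <- sqrt(sum(t^2))
    if (!is.finite(nt) || nt < 1e-12) break
    t <- t / nt
    r <- r / nt
    pvec <- crossprod(X0, t)
    Q[a] <- as.numeric(crossprod(y0, t))
    v <- pvec
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pvec)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) break
    v <- v / nv
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r
    V[, a] <- v
    used <- a
  }
  if (used == 0L) {
    return(list(coef = numeric(p), intercept = ym, ncomp = 0L))
  }
  B <- R[, seq_len(used), drop = FALSE] %*% Q[seq_len(used)]
  list(coef = as.numeric(B), intercept = ym - sum(xm * B), ncomp = used)
}

## ---- Bayesian ridge ------------------------------------------------------

# Conjugate Bayesian linear regression with evidence maximization
# (MacKay updates of the noise precision `alpha` and weight precision
# `lambda`), on centered data.
.bayesRidge <- function(X, y, maxIter = 300L, tol = 1e-4) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  xm <- colMeans(X)
  ym <- mean(y)
  X0 <- sweep(X, 2, xm)
  y0 <- y - ym
  XtX <- crossprod(X0)
  Xty <- crossprod(X0, y0)
  eg <- eigen(XtX, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  Vt_Xty <- crossprod(eg$vectors, Xty)
  vy <- stats::var(y0)
  alpha <- if (vy > 0) 1 / vy else 1
  lambda <- 1
  w <- numeric(p)
  for (it in seq_len(maxIter)) {
    d <- lambda + alpha * ev
    w_new <- as.numeric(eg$vectors %*% (alpha * Vt_Xty / d))
    gamma <- sum(alpha * ev / d)
    rss <- sum((y0 - X0 %*% w_new)^2)
    ssw <- sum(w_new^2)
    lambda_new <- (gamma + 1e-10) / (ssw + 1e-10)
    alpha_new <- (n - gamma + 1e-10) / (rss + 1e-10)
    conv <- sum(abs(w_new - w)) < tol
    w <- w_new
    lambda <- lambda_new
    alpha <- alpha_new
    if (conv) break
  }
  list(coef = w, intercept = ym - sum(xm * w), center = xm,
    alphaPrecision = alpha, lambdaPrecision = lambda)
}

## ---- unified fit/predict -------------------------------------------------

.learnerNames <- c("plsr", "svr", "rf", "gbdt", "xgb", "ridge", "bayesridge")

.fitLearner <- function(name, X, y, params = list(), seed = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  obj <- switch(name,
    plsr = {
      ncomp <- params$ncomp %||% min(10L, ncol(X), nrow(X) - 1L)
      c(.simpls(X, y, ncomp), list(kind = "linear"))
    },
    ridge = {
      lambda <- params$lambda %||% 1
      Xg <- if (ncol(X) >= 2) X else cbind(X, .dummy0 = 0)
      fit <- glmnet::glmnet(Xg, y, alpha = 0, lambda = lambda,
        standardize = TRUE, thresh = 1e-12)
      b <- as.numeric(coef(fit, s = lambda))
      list(kind = "linear", coef = b[-1][seq_len(ncol(X))], intercept = b[1])
    },
    bayesridge = c(.bayesRidge(X, y), list(kind = "linear")),
    svr = {
      set.seed(seed)
      fit <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
        cost = params$cost %||% 10,
        gamma = params$gamma %||% (1 / ncol(X)),
        epsilon = params$epsilon %||% 0.1)
      list(kind = "svr", fit = fit)
    },
    rf = {
      df <- data.frame(X, check.names = FALSE)
      fit <- ranger::ranger(
        y = y, x = df,
        num.trees = params$num.trees %||% 300L,
        mtry = params$mtry %||% max(1L, floor(ncol(X) / 3)),
        min.node.size = params$min.node.size %||% 5L,
        importance = "impurity", seed = seed, num.threads = 1L
      )
      list(kind = "rf", fit = fit)
    },
    gbdt = .fitBoost(X, y, params, seed, regularized = FALSE),
    xgb = .fitBoost(X, y, params, seed, regularized = TRUE),
    stop("unknown learner: ", name)
  )
  obj$name <- name
  obj$featureNames <- colnames(X)
  class(obj) <- c(paste0("canopyn_", name), "canopyn_learner")
  obj
}

.fitBoost <- function(X, y, params, seed, regularized) {
  p <- list(
    objective = "reg:squarederror", booster = "gbtree",
    eta = params$eta %||% 0.1,
    max_depth = params$max_depth %||% 3L,
    nthread = 1L, seed = seed
  )
  if (regularized) {
    p$lambda <- params$lambda %||% 1
    p$subsample <- params$subsample %||% 0.8
    p$colsample_bytree <- params$colsample_bytree %||% 0.8
  } else {
    p$lambda <- 0
    p$alpha <- 0
    p$subsample <- 1
    p$colsample_bytree <- 1
  }
  nrounds <- params$nrounds %||% 150L
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  fit <- xgboost::xgb.train(params = p, data = dtrain, nrounds = nrounds,
    verbose = 0)
  list(kind = "boost", fit = fit, nrounds = nrounds)
}

.predictLearner <- function(obj, X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- obj$featureNames
  X <- X[, obj$featureNames, drop = FALSE]
  switch(obj$kind,
    linear = as.numeric(X %*% obj$coef + obj$intercept),
    svr = as.numeric(stats::predict(obj$fit, X)),
    rf = stats::predict(obj$fit,
      data = data.frame(X, check.names = FALSE))$predictions,
    boost = as.numeric(stats::predict(obj$fit, xgboost::xgb.DMatrix(X))),
    stop("unknown learner kind")
  )
}

## ---- cross-validation helpers --------------------------------------------

.makeFolds <- function(n, k, seed) {
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

# Mean CV-RMSE of the latent-variable linear regression on X restricted
# to `bands`; the inner fitness model for GA/SPA selection.
.cvRmsePls <- function(X, y, bands = seq_len(ncol(X)), folds = 5L,
                       ncompMax = 10L, seed = 0L) {
  Xs <- X[, bands, drop = FALSE]
  n <- nrow(Xs)
  k <- min(folds, n)
  id <- .makeFolds(n, k, seed)
  pred <- numeric(n)
  for (f in seq_len(k)) {
    tr <- id != f
    m <- .simpls(Xs[tr, , drop = FALSE], y[tr],
      min(ncompMax, ncol(Xs), sum(tr) - 1L))
    pred[!tr] <- Xs[!tr, , drop = FALSE] %*% m$coef + m$intercept
  }
  sqrt(mean((y - pred)^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
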