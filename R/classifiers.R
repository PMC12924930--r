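## Six classifier families behind one fit/predict-probability
## interface. All are self-contained: Gaussian naive Bayes, k-nearest
## neighbors, (ridge-)logistic regression via IRLS, a random forest of
## CART trees, a linear SVM trained by Pegasos with Platt-scaled
## probabilities, and gradient-boosted trees with logistic loss.
## Each fit consumes a numeric matrix of already-preprocessed features
## (imputation and Z-scoring happen upstream in the modeling pipeline).

CLASSIFIER_KINDS <- c("GNB", "KNN", "LR", "RFC", "SVM", "XGBOOST")

#' Fit a classifier
#'
#' @param kind one of `"GNB"`, `"KNN"`, `"LR"`, `"RFC"`, `"SVM"`,
#'   `"XGBOOST"`.
#' @param x numeric feature matrix (rows = samples).
#' @param y binary labels (0/1 or logical).
#' @param params named list of hyperparameters; unset entries use the
#'   documented defaults (see [default_hyperparameters()]).
#' @param seed integer seed for the stochastic learners (RFC, SVM
#'   epochs, XGBOOST subsampling).
#' @return an object of class `til_clf`.
#' @export
fit_classifier <- function(kind, x, y, params = list(), seed = NULL) {
  kind <- match.arg(kind, CLASSIFIER_KINDS)
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)), nrow(x) == length(y))
  p <- utils::modifyList(default_hyperparameters(kind), params)
  fit <- with_seed(seed, switch(kind,
    GNB = fit_gnb(x, y, p),
    KNN = fit_knn(x, y, p),
    LR = fit_lr(x, y, p),
    RFC = fit_rfc(x, y, p),
    SVM = fit_svm(x, y, p),
    XGBOOST = fit_xgb(x, y, p)))
  structure(list(kind = kind, fit = fit, params = p,
                 n_features = ncol(x)), class = "til_clf")
}

#' Predicted probability of the positive class
#'
#' @param clf a `til_clf` from [fit_classifier()].
#' @param x numeric feature matrix.
#' @return numeric vector in `[0, 1]`.
#' @export
predict_prob <- function(clf, x) {
  stopifnot(inherits(clf, "til_clf"))
  x <- as.matrix(x); storage.mode(x) <- "double"
  stopifnot(ncol(x) == clf$n_features)
  pr <- switch(clf$kind,
    GNB = predict_gnb(clf$fit, x),
    KNN = predict_knn(clf$fit, x),
    LR = predict_lr(clf$fit, x),
    RFC = predict_rfc(clf$fit, x),
    SVM = predict_svm(clf$fit, x),
    XGBOOST = predict_xgb(clf$fit, x))
  pmin(pmax(pr, 0), 1)
}

#' Default hyperparameters and randomized-search spaces
#'
#' @param kind classifier kind.
#' @return named list of defaults.
#' @export
default_hyperparameters <- function(kind) {
  switch(kind,
    GNB = list(var_smoothing = 1e-9),
    KNN = list(k = 5L, weight = "uniform"),
    LR = list(lambda = 1e-6),
    RFC = list(n_trees = 100L, mtry = NULL, max_depth = 8L, min_node = 2L),
    SVM = list(cost = 1, epochs = 30L),
    XGBOOST = list(nrounds = 100L, eta = 0.1, max_depth = 3L,
                   lambda = 1, subsample = 1))
}

# Draw one random configuration from the documented search space.
sample_hyperparameters <- function(kind, n_train, n_features) {
  switch(kind,
    GNB = list(var_smoothing = 10^stats::runif(1, -10, -2)),
    KNN = list(k = sample(seq_len(max(1L, min(30L, n_train - 1L))), 1),
               weight = sample(c("uniform", "distance"), 1)),
    LR = list(lambda = 10^stats::runif(1, -6, 1)),
    RFC = list(n_trees = sample(50:200, 1), mtry = sample(seq_len(n_features), 1),
               max_depth = sample(2:10, 1), min_node = sample(1:5, 1)),
    SVM = list(cost = 10^stats::runif(1, -2, 2), epochs = 30L),
    XGBOOST = list(nrounds = sample(25:150, 1), eta = stats::runif(1, 0.05, 0.3),
                   max_depth = sample(1:4, 1), lambda = 1,
                   subsample = stats::runif(1, 0.6, 1)))
}

sigmoid <- function(z) 1 / (1 + exp(-pmin(pmax(z, -35), 35)))

## ---- Gaussian naive Bayes ----------------------------------------------

fit_gnb <- function(x, y, p) {
  eps <- p$var_smoothing * max(apply(x, 2, stats::var), 1e-12)
  stats_for <- function(cls) {
    xs <- x[y == cls, , drop = FALSE]
    list(mu = colMeans(xs),
         var = apply(xs, 2, function(c) mean((c - mean(c))^2)) + eps,
         prior = nrow(xs) / nrow(x))
  }
  list(c0 = stats_for(0L), c1 = stats_for(1L))
}

predict_gnb <- function(fit, x) {
  loglik <- function(cl) {
    ll <- rep(log(cl$prior), nrow(x))
    for (j in seq_len(ncol(x))) {
      ll <- ll - 0.5 * log(2 * pi * cl$var[j]) -
        (x[, j] - cl$mu[j])^2 / (2 * cl$var[j])
    }
    ll
  }
  l0 <- loglik(fit$c0); l1 <- loglik(fit$c1)
  1 / (1 + exp(pmin(pmax(l0 - l1, -700), 700)))
}

## ---- k-nearest neighbors -----------------------------------------------

fit_knn <- function(x, y, p) {
  list(x = x, y = y, k = min(p$k, nrow(x)), weight = p$weight)
}

predict_knn <- function(fit, x) {
  nn <- FNN::get.knnx(fit$x, x, k = fit$k)
  vapply(seq_len(nrow(x)), function(i) {
    ys <- fit$y[nn$nn.index[i, ]]
    if (fit$weight == "distance") {
      w <- 1 / pmax(nn$nn.dist[i, ], 1e-12)
      sum(w * ys) / sum(w)
    } else mean(ys)
  }, numeric(1))
}

## ---- logistic regression (IRLS with optional ridge) --------------------

fit_lr <- function(x, y, p) {
  xb <- cbind(1, x)
  beta <- rep(0, ncol(xb))
  lam <- p$lambda
  pen <- diag(c(0, rep(lam, ncol(x))), ncol(xb)) # intercept unpenalized
  for (it in 1:100) {
    eta <- drop(xb %*% beta)
    mu <- sigmoid(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    xtw <- t(xb * w)
    new_beta <- tryCatch(
      solve(xtw %*% xb + pen + diag(1e-10, ncol(xb)), xtw %*% z),
      error = function(e) beta)
    if (max(abs(new_beta - beta)) < 1e-10) { beta <- new_beta; break }
    beta <- new_beta
  }
  list(beta = drop(beta))
}

predict_lr <- function(fit, x) sigmoid(drop(cbind(1, x) %*% fit$beta))

## ---- CART-style regression trees (shared by RFC and XGBOOST) -----------

# Greedy tree on gradient/hessian pairs; leaf value = -G/(H+lambda).
# With g = -y, h = 1, lambda = 0 the leaf value is the class fraction
# and the split gain is proportional to variance reduction (equivalent
# to the Gini criterion for binary labels).
grow_tree <- function(x, g, h, depth, max_depth, lambda, min_node, mtry) {
  G <- sum(g); H <- sum(h)
  leaf <- list(leaf = TRUE, value = -G / (H + lambda))
  n <- length(g)
  if (depth >= max_depth || n < 2 * min_node) return(leaf)
  feats <- if (mtry < ncol(x)) sample.int(ncol(x), mtry) else seq_len(ncol(x))
  base_score <- G^2 / (H + lambda)
  best <- list(gain = 1e-12)
  for (j in feats) {
    ord <- order(x[, j])
    xv <- x[ord, j]
    gl <- cumsum(g[ord]); hl <- cumsum(h[ord])
    i <- seq_len(n - 1)
    valid <- xv[i] < xv[i + 1] & i >= min_node & (n - i) >= min_node
    if (!any(valid)) next
    gain <- gl[i]^2 / (hl[i] + lambda) +
      (G - gl[i])^2 / (H - hl[i] + lambda) - base_score
    gain[!valid] <- -Inf
    k <- which.max(gain)
    if (gain[k] > best$gain) {
      best <- list(gain = gain[k], feat = j,
                   thr = (xv[k] + xv[k + 1]) / 2)
    }
  }
  if (is.null(best$feat)) return(leaf)
  left <- x[, best$feat] <= best$thr
  list(leaf = FALSE, feat = best$feat, thr = best$thr,
       left = grow_tree(x[left, , drop = FALSE], g[left], h[left],
                        depth + 1, max_depth, lambda, min_node, mtry),
       right = grow_tree(x[!left, , drop = FALSE], g[!left], h[!left],
                         depth + 1, max_depth, lambda, min_node, mtry))
}

predict_tree <- function(tree, x) {
  out <- numeric(nrow(x))
  rec <- function(node, idx) {
    if (length(idx) == 0) return()
    if (node$leaf) { out[idx] <<- node$value; return() }
    left <- x[idx, node$feat] <= node$thr
    rec(node$left, idx[left])
    rec(node$right, idx[!left])
  }
  rec(tree, seq_len(nrow(x)))
  out
}

## ---- random forest ------------------------------------------------------

fit_rfc <- function(x, y, p) {
  n <- nrow(x)
  mtry <- p$mtry %||% max(1L, floor(sqrt(ncol(x))))
  trees <- lapply(seq_len(p$n_trees), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    grow_tree(x[idx, , drop = FALSE], g = -as.numeric(y[idx]),
              h = rep(1, n), depth = 0L, max_depth = p$max_depth,
              lambda = 0, min_node = p$min_node, mtry = mtry)
  })
  list(trees = trees)
}

predict_rfc <- function(fit, x) {
  preds <- vapply(fit$trees, predict_tree, numeric(nrow(x)), x = x)
  if (nrow(x) == 1L) mean(preds) else rowMeans(matrix(preds, nrow = nrow(x)))
}

## ---- linear SVM (Pegasos) with Platt scaling ---------------------------

fit_svm <- function(x, y, p) {
  n <- nrow(x)
  yy <- ifelse(y == 1L, 1, -1)
  lam <- 1 / (p$cost * n)
  w <- rep(0, ncol(x)); b <- 0; t <- 0
  for (ep in seq_len(p$epochs)) {
    for (i in sample.int(n, n)) {
      t <- t + 1
      eta <- 1 / (lam * t)
      margin <- yy[i] * (sum(w * x[i, ]) + b)
      w <- (1 - eta * lam) * w
      if (margin < 1) {
        w <- w + eta * yy[i] * x[i, ]
        b <- b + eta * yy[i]
      }
    }
  }
  dec <- drop(x %*% w) + b
  platt <- fit_lr(matrix(dec, ncol = 1), y, list(lambda = 1e-6))
  list(w = w, b = b, platt = platt)
}

predict_svm <- function(fit, x) {
  dec <- drop(x %*% fit$w) + fit$b
  predict_lr(fit$platt, matrix(dec, ncol = 1))
}

## ---- gradient-boosted trees (logistic loss) ----------------------------

fit_xgb <- function(x, y, p) {
  n <- nrow(x)
  base <- log(max(mean(y), 1e-6) / max(1 - mean(y), 1e-6))
  raw <- rep(base, n)
  trees <- vector("list", p$nrounds)
  for (m in seq_len(p$nrounds)) {
    prob <- sigmoid(raw)
    g <- prob - y
    h <- pmax(prob * (1 - prob), 1e-12)
    idx <- if (p$subsample < 1) {
      sample.int(n, max(2L, floor(p$subsample * n)))
    } else seq_len(n)
    tr <- grow_tree(x[idx, , drop = FALSE], g[idx], h[idx], 0L,
                    p$max_depth, p$lambda, min_node = 1L,
                    mtry = ncol(x))
    trees[[m]] <- tr
    raw <- raw + p$eta * predict_tree(tr, x)
  }
  list(base = base, eta = p$eta, trees = trees)
}

predict_xgb <- function(fit, x) {
  raw <- rep(fit$base, nrow(x))
  for (tr in fit$trees) raw <- raw + fit$eta * predict_tree(tr, x)
  sigmoid(raw)
}
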