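test_that("AUC equals the Mann-Whitney pair probability", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.5, 8), rep(c(0, 1), 4)), 0.5)
  withr::with_seed(71, {
    y <- rep(c(0, 1), 250)
    s <- round(rnorm(500) + 0.4 * y, 1) # coarse grid forces exact ties
  })
  expect_equal(roc_auc(s, y), brute_auc(s, y), tolerance = 1e-12)
  # invariance under strictly increasing transforms
  expect_equal(roc_auc(exp(2 * s), y), roc_auc(s, y))
  expect_error(roc_auc(1:4, rep(1, 4)), "classes")
})

test_that("metric panel reproduces hand confusion arithmetic", {
  r <- metric_panel(c(0.9, 0.9, 0.2, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(r$accuracy, 1)
  expect_equal(r$f1, 1)
  expect_equal(r$sensitivity_pct, 100)
  expect_equal(r$specificity_pct, 100)

  r2 <- metric_panel(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(unname(r2$confusion), c(1, 1, 1, 1)) # tp fp fn tn
  expect_equal(r2$accuracy, 0.5)
  expect_equal(r2$sensitivity_pct, 50)
  expect_equal(r2$specificity_pct, 50)
  expect_equal(r2$prevalence, 0.5)
  # F1 is the harmonic mean of precision and sensitivity
  expect_equal(r2$f1, 2 * r2$precision * (r2$sensitivity_pct / 100) /
                 (r2$precision + r2$sensitivity_pct / 100))
  expect_warning(metric_panel(c(0.1, 0.2, 0.3, 0.4), c(0, 0, 1, 1), 0.9),
                 "undefined")
})

test_that("DeLong placement values match the O(n^2) oracle", {
  withr::with_seed(72, {
    y <- rep(c(0, 1), c(7, 5)) # n = 12 toy
    a <- rnorm(12) + y
  })
  pv <- tilgraph:::placement_values(a, y)
  pos <- a[y == 1]; neg <- a[y == 0]
  v10 <- sapply(pos, function(s) mean((s > neg) + 0.5 * (s == neg)))
  v01 <- sapply(neg, function(s) mean((pos > s) + 0.5 * (pos == s)))
  expect_equal(pv$v10, v10, tolerance = 1e-15)
  expect_equal(pv$v01, v01, tolerance = 1e-15)
  expect_equal(mean(pv$v10), roc_auc(a, y), tolerance = 1e-12)
})

test_that("DeLong test agrees with the stratified jackknife and is symmetric", {
  withr::with_seed(73, {
    n <- 60
    y <- rep(c(0, 1), each = 30)
    a <- rnorm(n) + 1.0 * y
    b <- rnorm(n) + 0.4 * y
  })
  dl <- delong_test(a, b, y)
  expect_equal(dl$auc_a, roc_auc(a, y), tolerance = 1e-12)
  # within-class delete-one jackknife is algebraically DeLong's variance
  dauc <- function(keep) roc_auc(a[keep], y[keep]) - roc_auc(b[keep], y[keep])
  jk_var <- function(idx) {
    th <- vapply(idx, function(i) dauc(setdiff(seq_len(n), i)), numeric(1))
    (length(idx) - 1) / length(idx) * sum((th - mean(th))^2)
  }
  v_jack <- jk_var(which(y == 1)) + jk_var(which(y == 0))
  p_jack <- 2 * pnorm(-abs(dl$delta) / sqrt(v_jack))
  expect_equal(dl$variance, v_jack, tolerance = 1e-10)
  expect_lt(abs(dl$p_value - p_jack), 1e-6)

  swapped <- delong_test(b, a, y)
  expect_equal(swapped$delta, -dl$delta)
  expect_equal(swapped$p_value, dl$p_value)

  same <- delong_test(a, a, y)
  expect_equal(same$delta, 0)
  expect_equal(same$p_value, 1)
})

test_that("AUC confidence intervals truncate, widen with small n, and cover", {
  y <- rep(c(0, 1), each = 10)
  s <- c(rep(0.1, 10), rep(0.9, 10))
  ci <- auc_confidence_interval(s, y)
  expect_equal(ci[2], 1)

  width <- function(n, seed) {
    withr::with_seed(seed, {
      yy <- rep(c(0, 1), each = n / 2)
      ss <- rnorm(n) + 1.19 * yy # population AUC ~ 0.8
      diff(auc_confidence_interval(ss, yy))
    })
  }
  w200 <- mean(vapply(1:30, function(s) width(200, s), numeric(1)))
  w50 <- mean(vapply(1:30, function(s) width(50, 100 + s), numeric(1)))
  expect_gt(w50, w200)

  withr::with_seed(74, {
    cover <- vapply(1:500, function(i) {
      yy <- rep(c(0, 1), each = 50)
      ss <- rnorm(100) + sqrt(2) * qnorm(0.8) * yy # true AUC exactly 0.8
      ci <- auc_confidence_interval(ss, yy)
      ci[1] <= 0.8 && 0.8 <= ci[2]
    }, logical(1))
  })
  expect_gte(mean(cover), 0.93)
  expect_lte(mean(cover), 0.97)
})

test_that("ensemble scan endpoints reproduce the component models", {
  withr::with_seed(75, {
    y <- rep(c(0, 1), each = 25)
    pc <- runif(50)
    pg <- ifelse(y == 1, runif(50, 0.6, 1), runif(50, 0, 0.4))
  })
  sc <- ensemble_scan(pc, pg, y, grid_size = 100)
  expect_equal(nrow(sc$scan), 100)
  expect_equal(sc$scan$weight[1], 0)
  expect_equal(sc$scan$weight[100], 1)
  expect_equal(sc$scan$auc[1], roc_auc(pc, y))
  expect_equal(sc$scan$auc[100], roc_auc(pg, y))
  # graph model separates perfectly: the scan attains AUC 1 (at w = 1,
  # and possibly already at smaller weights where the mix preserves order)
  expect_equal(sc$best_auc, 1)
  expect_equal(sc$scan$auc[100], 1)
  # ties resolve to the smaller weight
  tie <- ensemble_scan(pg, pg, y, 100)
  expect_equal(tie$best_weight, 0)
  expect_error(ensemble_scan(pc[1:10], pg, y), "aligned")
})

test_that("ensemble models mix bundle probabilities linearly", {
  withr::with_seed(76, {
    x <- matrix(rnorm(80 * 2), 80, 2, dimnames = list(NULL, c("a", "b")))
    y <- rep(c(0L, 1L), 40)
    x[y == 1, 1] <- x[y == 1, 1] + 2
  })
  bc <- train_model(x, y, "GNB", collinearity = FALSE, seed = 77)
  bg <- train_model(x, y, "LR", collinearity = FALSE, seed = 78)
  for (w in c(0, 0.4, 1)) {
    em <- ensemble_model(bc, bg, w)
    p <- predict(em, list(clinical = x, graph = x))
    expect_equal(p, (1 - w) * predict(bc, x) + w * predict(bg, x))
  }
})
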