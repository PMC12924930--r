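test_that("Theil's U matches hand entropy computations", {
  x <- c("a", "b", "a", "c")
  expect_equal(theils_u(x, x), 1)
  # balanced independent 2x2 table
  x2 <- rep(c("a", "b"), times = 10)
  y2 <- rep(c("u", "u", "v", "v"), times = 5)
  expect_equal(theils_u(x2, y2), 0, tolerance = 1e-12)
  # 3x2 table with counts {{20,10},{5,25},{10,10}} against brute force
  x3 <- rep(c("r1", "r1", "r2", "r2", "r3", "r3"), c(20, 10, 5, 25, 10, 10))
  y3 <- rep(c("c1", "c2", "c1", "c2", "c1", "c2"), c(20, 10, 5, 25, 10, 10))
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  n <- 80
  hx <- H(c(30, 30, 20) / n)
  hxy <- 35 / n * H(c(20, 5, 10) / 35) + 45 / n * H(c(10, 25, 10) / 45)
  expect_equal(theils_u(x3, y3), (hx - hxy) / hx, tolerance = 1e-12)
  # constant x is trivially determined
  expect_equal(theils_u(rep("a", 5), c("u", "v", "u", "v", "u")), 1)
})

test_that("collinearity filter removes the less target-associated member", {
  withr::with_seed(51, {
    y <- rep(c(0L, 1L), each = 40)
    a <- rnorm(80) + 1.2 * y       # strongly associated with target
    e <- rnorm(80, sd = 0.4)
    e <- e - ave(e, y)             # noise exactly orthogonal to the classes,
    b <- a + e                     # so b is a strictly diluted copy of a
    c_ <- rnorm(80)                # independent
    x <- data.frame(a = a, b = b, c = c_)
  })
  expect_gt(abs(cor(a, b)), 0.9)
  keep <- collinearity_filter(x, y, threshold = 0.9)
  expect_true(keep[["a"]])
  expect_true(keep[["c"]])
  expect_false(keep[["b"]] && keep[["a"]]) # only one of the pair survives
  expect_equal(sum(keep), 2)

  # exact duplicate: exactly one copy removed
  x2 <- data.frame(u = a, v = a, w = c_)
  keep2 <- collinearity_filter(x2, y)
  expect_equal(sum(keep2[c("u", "v")]), 1)

  # identical nominal columns: Theil's U = 1, one removed
  nom <- data.frame(n1 = rep(c("x", "y"), 40), n2 = rep(c("x", "y"), 40))
  keep3 <- collinearity_filter(nom, y, types = c("nominal", "nominal"))
  expect_equal(sum(keep3), 1)

  expect_warning(collinearity_filter(data.frame(k = rep(1, 80), a = a), y),
                 "constant")
})

test_that("Z-scoring retains training parameters for the test subset", {
  fit <- zscore_fit(matrix(c(2, 4, 6), ncol = 1))
  expect_equal(unname(fit$mu), 4)
  expect_equal(unname(fit$sigma), sqrt(8 / 3), tolerance = 1e-9) # population
  expect_equal(drop(zscore_apply(matrix(4), fit)), 0)

  withr::with_seed(52, tr <- matrix(rnorm(200, 5, 2), ncol = 2))
  f2 <- zscore_fit(tr)
  z <- zscore_apply(tr, f2)
  expect_equal(unname(colMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, function(c) sqrt(mean((c - mean(c))^2)))),
               c(1, 1), tolerance = 1e-12)
  # a shifted test split standardized with train parameters is off-center
  te <- tr + 3
  expect_gt(min(colMeans(zscore_apply(te, f2))), 1)
  expect_warning(zscore_fit(matrix(rep(1, 5))), "zero-variance")
})

test_that("stratified split reproduces the printed cohort arithmetic", {
  y85 <- rep(c(1, 0), c(30, 55)) # TNBC-like cohort
  sp <- stratified_split(y85, 0.8, seed = 1)
  expect_length(sp$train, 68)
  expect_length(sp$test, 17)
  expect_setequal(c(sp$train, sp$test), 1:85)
  expect_equal(sum(y85[sp$test]), 6) # 30 * 0.2

  y56 <- rep(c(1, 0), c(37, 19)) # HER2+-like cohort
  sp2 <- stratified_split(y56, 0.8, seed = 2)
  expect_length(sp2$train, 44)
  expect_length(sp2$test, 12)
  # class proportions preserved to within one patient
  expect_lt(abs(sum(y56[sp2$test]) - 37 * 12 / 56), 1)

  y10 <- rep(c(0, 1), 5)
  sp3 <- stratified_split(y10, 0.8, seed = 3)
  expect_length(sp3$train, 8)
  expect_equal(sort(y10[sp3$test]), c(0, 1))

  expect_error(stratified_split(rep(1, 10)), "classes")
})

test_that("feature cap rounds half up per ten training samples", {
  expect_equal(feature_cap(68), 7L)
  expect_equal(feature_cap(44), 4L)
  expect_equal(feature_cap(100), 10L)
  expect_equal(feature_cap(9), 1L)
  expect_equal(feature_cap(45), 5L) # round-half-up
})

test_that("SMOTE balances classes with on-segment synthetic points", {
  withr::with_seed(53, {
    x <- rbind(matrix(rnorm(160), 80, 2),
               matrix(rnorm(40, 5), 20, 2))
    y <- rep(c(0L, 1L), c(80, 20))
  })
  bal <- smote_oversample(x, y, seed = 7)
  expect_equal(as.vector(table(bal$y)), c(80, 80))
  expect_identical(bal$x[1:100, ], x) # originals untouched
  synth <- bal$x[101:160, , drop = FALSE]
  minority <- x[y == 1L, , drop = FALSE]
  seg_dist <- function(p, a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / max(sum(ab^2), 1e-300)
    t <- min(max(t, 0), 1)
    sqrt(sum((a + t * ab - p)^2))
  }
  for (s in seq_len(nrow(synth))) {
    dmin <- min(apply(expand.grid(i = 1:20, j = 1:20), 1, function(ij) {
      if (ij[1] == ij[2]) return(Inf)
      seg_dist(synth[s, ], minority[ij[1], ], minority[ij[2], ])
    }))
    expect_lt(dmin, 1e-9)
  }
  expect_identical(bal, smote_oversample(x, y, seed = 7))
  # tiny minority: k reduced with warning
  expect_warning(smote_oversample(x[c(1:20, 81:83), ], y[c(1:20, 81:83)],
                                  seed = 1), "minority")
})

test_that("SFFS recovers a planted feature and respects the cap", {
  pf <- planted_features(n = 80, p = 6, shift = 2.5, seed = 54)
  sel <- sffs_select(pf$x, pf$y, classifier = "GNB", cap = 2, folds = 5,
                     iterations = 15, seed = 55)
  expect_equal(sel$selected[1], "f1")
  expect_gte(sel$frequencies[["f1"]], 13)
  expect_gt(sel$single_auc[["f1"]], 0.85)

  sel1 <- sffs_select(pf$x, pf$y, classifier = "GNB", cap = 1, folds = 5,
                      iterations = 5, seed = 56)
  expect_length(sel1$selected, 1)
})

test_that("pure-noise features never dominate SFFS selection", {
  # On a FIXED noise dataset, SFFS legitimately re-selects whatever
  # column is accidentally best, so the uniform-selection null is tested
  # across fresh noise draws: no column position may be preferred.
  freq <- setNames(numeric(10), paste0("n", 1:10))
  withr::with_seed(57, {
    for (r in 1:30) {
      x <- matrix(rnorm(70 * 10), 70, 10,
                  dimnames = list(NULL, names(freq)))
      y <- rep(c(0L, 1L), length.out = 70)
      sel <- sffs_select(x, y, classifier = "GNB", cap = 2, folds = 5,
                         iterations = 1, seed = 58 + r)
      freq[sel$selected] <- freq[sel$selected] + 1
    }
  })
  # binomial 99th percentile under uniform choice of <= 2 of 10 per run
  cutoff <- qbinom(0.99, 30, 2 / 10)
  expect_lte(max(freq), cutoff)
})

test_that("hyperparameter search honors its budget contract", {
  pf <- planted_features(n = 60, p = 3, shift = 1.5, seed = 59)
  t0 <- tune_hyperparameters(pf$x, pf$y, "KNN", budget = 0)
  expect_equal(t0$params, default_hyperparameters("KNN"))

  t1 <- tune_hyperparameters(pf$x, pf$y, "KNN", budget = 1, folds = 5, seed = 60)
  expect_identical(t1, tune_hyperparameters(pf$x, pf$y, "KNN", budget = 1,
                                            folds = 5, seed = 60))
  t8 <- tune_hyperparameters(pf$x, pf$y, "KNN", budget = 8, folds = 5, seed = 61)
  degenerate <- suppressWarnings(
    tilgraph:::cv_auc(pf$x, pf$y, "KNN", list(k = 30L), k = 5L, seed = 62))
  expect_gte(t8$cv_auc, degenerate - 0.05)
})

test_that("every classifier kind separates a trivially separable toy", {
  withr::with_seed(63, {
    x <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 8), 30, 2))
    colnames(x) <- c("u", "v")
    y <- rep(c(0L, 1L), each = 30)
  })
  for (kind in c("GNB", "KNN", "LR", "RFC", "SVM", "XGBOOST")) {
    clf <- fit_classifier(kind, x, y, seed = 64)
    p <- predict_prob(clf, x)
    expect_true(all(p >= 0 & p <= 1), info = kind)
    expect_equal(roc_auc(p, y), 1.0, info = kind)
  }
})

test_that("permuted labels keep held-out AUC near chance", {
  withr::with_seed(65, {
    x <- matrix(rnorm(60 * 3), 60, 3)
    aucs <- vapply(1:20, function(s) {
      y <- sample(rep(c(0L, 1L), each = 30))
      suppressWarnings(tilgraph:::cv_auc(x, y, "GNB", k = 5L, seed = s))
    }, numeric(1))
  })
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("model bundles replay preprocessing and round-trip exactly", {
  withr::with_seed(66, {
    x <- cbind(matrix(rnorm(200), 100, 2), rnorm(100))
    colnames(x) <- c("s1", "s2", "noise")
    y <- rep(c(0L, 1L), each = 50)
    x[y == 1, 1:2] <- x[y == 1, 1:2] + 3
    x[sample(300, 10)] <- NA # missingness handled by median imputation
  })
  b <- train_model(x, y, classifier = "LR", collinearity = TRUE, seed = 67)
  p <- predict(b, x)
  expect_gt(roc_auc(p, y), 0.95)
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(b, path)
  expect_identical(predict(readRDS(path), x), p)
})

test_that("no preprocessing statistic leaks from the test split", {
  withr::with_seed(68, {
    x <- matrix(rnorm(50 * 2), 50, 2, dimnames = list(NULL, c("a", "b")))
    y <- rep(c(0L, 1L), 25)
  })
  tr <- 1:40; te <- 41:50
  outlier <- c(500, -500)

  fit_ref <- zscore_fit(x[tr, ])
  x_out_test <- x; x_out_test[45, ] <- outlier
  fit_te <- zscore_fit(x_out_test[tr, ])
  expect_identical(fit_te, fit_ref) # outlier in test: parameters unmoved

  x_out_train <- x; x_out_train[5, ] <- outlier
  fit_tr <- zscore_fit(x_out_train[tr, ])
  expect_gt(max(abs(fit_tr$mu - fit_ref$mu)), 1)

  # the full bundle inherits the same property
  b_ref <- train_model(x[tr, ], y[tr], "GNB", collinearity = FALSE,
                       smote = FALSE, seed = 69)
  b_te <- train_model(x_out_test[tr, ], y[tr], "GNB", collinearity = FALSE,
                      smote = FALSE, seed = 69)
  expect_identical(b_te$zscore, b_ref$zscore)
  expect_identical(b_te$medians, b_ref$medians)
})

test_that("clinical encoding types covariates as in the cohort table", {
  spec <- cohort_spec(30, pcr_fraction = 0.3,
                      base_params = process_params("CSR", intensity = 1e-4),
                      seed = 70)
  coh <- simulate_cohort(spec, new_window(100, 100), tile_size_px = 200)
  enc <- encode_clinical(cohort_clinical_table(coh))
  expect_equal(nrow(enc$x), 30)
  expect_true(all(enc$types %in% c("continuous", "nominal")))
  expect_true("age" %in% names(enc$x))
  expect_true(is.integer(enc$x$nottingham_grade) ||
              is.numeric(enc$x$nottingham_grade))
  # multi-level nominal one-hot against a reference level
  expect_true(any(grepl("^menopausal_status_", names(enc$x))))
  expect_false("menopausal_status" %in% names(enc$x))
  expect_equal(enc$y, cohort_clinical_table(coh)$pcr_label)
})
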