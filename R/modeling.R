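## Supervised pipeline: collinearity filtering, Z-scoring, stratified
## splitting, SFFS feature selection with fold-internal SMOTE,
## randomized hyperparameter search, and model bundles that replay
## their training-time preprocessing on unseen rows. Every fitted
## statistic (medians, mu/sigma, masks, selections) is computed on
## training rows only.

#' Theil's U (uncertainty coefficient)
#'
#' \eqn{U(x|y) = (H(x) - H(x|y)) / H(x)} with natural-log entropies:
#' the fraction of x's entropy explained by y. Asymmetric; 0 for
#' independent variables, 1 when y determines x. A constant `x`
#' (zero entropy) is trivially determined, so U is defined as 1.
#'
#' @param x,y vectors interpreted as nominal (factors or characters).
#' @return value in `[0, 1]`.
#' @examples
#' theils_u(c("a", "b", "a"), c("a", "b", "a")) # 1
#' @export
theils_u <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) > 0)
  entropy <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  px <- table(x) / length(x)
  hx <- entropy(as.numeric(px))
  if (hx == 0) return(1)
  hxy <- 0
  for (lv in unique(y)) {
    sel <- y == lv
    pxy <- table(x[sel]) / sum(sel)
    hxy <- hxy + mean(sel) * entropy(as.numeric(pxy))
  }
  (hx - hxy) / hx
}

# Association between two encoded columns given their types.
pairwise_assoc <- function(a, b, type_a, type_b) {
  if (type_a == "nominal" && type_b == "nominal") {
    max(theils_u(a, b), theils_u(b, a))
  } else {
    # Pearson; with a dichotomous member this is the point-biserial r
    abs(suppressWarnings(stats::cor(as.numeric(a), as.numeric(b))))
  }
}

target_assoc <- function(col, y, type) {
  if (type == "nominal") theils_u(y, col)
  else abs(suppressWarnings(stats::cor(as.numeric(col), as.numeric(y))))
}

#' Collinearity filter
#'
#' For every pair of columns whose association exceeds `threshold`
#' (Pearson for continuous-continuous, point-biserial for
#' continuous-dichotomous, Theil's U for nominal-nominal), the member
#' less associated with the target is removed. Constant columns are
#' dropped with a warning. Deterministic given column order (ties drop
#' the later column).
#'
#' @param x data.frame or matrix of encoded features.
#' @param y binary target.
#' @param types per-column types, `"continuous"` or `"nominal"`;
#'   defaults to all continuous.
#' @param threshold absolute association cutoff (default 0.90).
#' @return logical vector, `TRUE` = column retained.
#' @export
collinearity_filter <- function(x, y, types = NULL, threshold = 0.90) {
  x <- as.data.frame(x)
  p <- ncol(x)
  types <- types %||% rep("continuous", p)
  keep <- rep(TRUE, p)
  const <- vapply(x, function(c) length(unique(c[!is.na(c)])) < 2, logical(1))
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(names(x)[const], collapse = ", "))
    keep[const] <- FALSE
  }
  rel <- vapply(seq_len(p), function(j) {
    if (!keep[j]) return(0)
    r <- target_assoc(x[[j]], y, types[j])
    if (is.na(r)) 0 else r
  }, numeric(1))
  for (i in seq_len(p - 1)) {
    if (!keep[i]) next
    for (j in (i + 1):p) {
      if (!keep[j]) next
      a <- pairwise_assoc(x[[i]], x[[j]], types[i], types[j])
      if (!is.na(a) && a > threshold) {
        if (rel[j] < rel[i]) keep[j] <- FALSE else keep[i] <- FALSE
        if (!keep[i]) break
      }
    }
  }
  stats::setNames(keep, colnames(x))
}

#' Z-score standardization fitted on training rows
#'
#' @param x training feature matrix.
#' @return list with `mu` and `sigma` (population standard deviation)
#'   per column; zero-variance columns get `sigma = 1` (centered
#'   pass-through) with a warning.
#' @rdname zscore
#' @export
zscore_fit <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x, na.rm = TRUE)
  sigma <- apply(x, 2, function(c) {
    c <- c[!is.na(c)]
    sqrt(mean((c - mean(c))^2))
  })
  if (any(sigma == 0)) {
    warning("zero-variance column(s) passed through centered")
    sigma[sigma == 0] <- 1
  }
  list(mu = mu, sigma = sigma)
}

#' @param fit result of `zscore_fit`.
#' @rdname zscore
#' @export
zscore_apply <- function(x, fit) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, fit$mu), 2, fit$sigma, "/")
}

#' Stratified 80:20 split
#'
#' Test size is `ceiling((1 - train_fraction) * n)`; class counts in the
#' test set follow largest-remainder allocation, so class proportions
#' are preserved to within one patient. With the cohort sizes of the
#' original study this reproduces 68/17 (n = 85) and 44/12 (n = 56).
#'
#' @param labels binary label vector.
#' @param train_fraction training proportion (default 0.80).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.80, seed = NULL) {
  n <- length(labels)
  cls <- unique(labels)
  if (length(cls) < 2) stop("both classes must be present", call. = FALSE)
  if (any(table(labels) < 2)) stop("each class needs >= 2 members", call. = FALSE)
  n_test <- ceiling((1 - train_fraction) * n)
  frac <- n_test / n
  counts <- vapply(cls, function(c) sum(labels == c), numeric(1))
  raw <- counts * frac
  t_c <- floor(raw)
  rem <- n_test - sum(t_c)
  if (rem > 0) {
    ord <- order(raw - t_c, decreasing = TRUE)
    t_c[ord[seq_len(rem)]] <- t_c[ord[seq_len(rem)]] + 1L
  }
  with_seed(seed, {
    test <- unlist(lapply(seq_along(cls), function(ci) {
      idx <- which(labels == cls[ci])
      sample(idx, t_c[ci])
    }))
  })
  test <- sort(test)
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Feature cap: one feature per ten training samples
#'
#' Nearest-integer (round-half-up) of `n_train / 10`, minimum 1. This
#' rounding is the only rule consistent with caps of 4 at n = 44 and
#' 7 at n = 68.
#'
#' @param n_train number of training samples.
#' @return integer cap.
#' @export
feature_cap <- function(n_train) {
  if (n_train < 10) return(1L)
  as.integer(floor(n_train / 10 + 0.5))
}

#' SMOTE oversampling of the minority class
#'
#' Upsamples the minority class to the majority count; each synthetic
#' row is a convex combination of a minority row and one of its
#' `k_neighbors` nearest minority neighbors. Applied only inside
#' training folds, never to evaluation data.
#'
#' @param x feature matrix (no missing values).
#' @param y binary labels.
#' @param k_neighbors neighbor pool size (default 5; reduced with a
#'   warning when the minority class is too small).
#' @param seed integer seed.
#' @return list with balanced `x` and `y` (original rows first).
#' @export
smote_oversample <- function(x, y, k_neighbors = 5L, seed = NULL) {
  x <- as.matrix(x)
  y <- as.integer(y)
  tab <- table(factor(y, levels = c(0L, 1L)))
  if (any(tab == 0) || tab[1] == tab[2]) return(list(x = x, y = y))
  minority <- as.integer(names(tab)[which.min(tab)])
  n_new <- abs(diff(as.numeric(tab)))
  idx_min <- which(y == minority)
  k <- k_neighbors
  if (length(idx_min) <= k) {
    k <- max(length(idx_min) - 1L, 0L)
    warning(sprintf("minority class too small for k=%d; using k=%d",
                    k_neighbors, k))
  }
  with_seed(seed, {
    xm <- x[idx_min, , drop = FALSE]
    synth <- matrix(0, n_new, ncol(x))
    if (k == 0L) {
      synth <- xm[rep(1L, n_new), , drop = FALSE]
    } else {
      nn <- FNN::get.knn(xm, k = k)$nn.index
      base <- rep_len(seq_along(idx_min), n_new)
      for (s in seq_len(n_new)) {
        i <- base[s]
        j <- nn[i, sample.int(k, 1)]
        u <- stats::runif(1)
        synth[s, ] <- xm[i, ] + u * (xm[j, ] - xm[i, ])
      }
    }
    colnames(synth) <- colnames(x)
    list(x = rbind(x, synth), y = c(y, rep(minority, n_new)))
  })
}

## ---- cross-validation machinery ----------------------------------------

# Stratified fold assignment (1..k) for a binary label vector.
stratified_folds <- function(y, k, seed = NULL) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# Median imputation fitted on training rows.
impute_fit <- function(x) apply(as.matrix(x), 2, stats::median, na.rm = TRUE)
impute_apply <- function(x, med) {
  x <- as.matrix(x)
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- med[j]
  x
}

# Mean cross-validated AUC of a classifier on (x, y) with fold-internal
# median imputation and SMOTE. Folds with a single class are skipped
# with a warning.
cv_auc <- function(x, y, kind, params = list(), folds = NULL, k = 10L,
                   seed = NULL, smote = TRUE) {
  x <- as.matrix(x)
  folds <- folds %||% stratified_folds(y, k, seed)
  aucs <- c()
  for (f in sort(unique(folds))) {
    tr <- folds != f; te <- !tr
    if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2) {
      warning("single-class fold skipped")
      next
    }
    med <- impute_fit(x[tr, , drop = FALSE])
    xtr <- impute_apply(x[tr, , drop = FALSE], med)
    xte <- impute_apply(x[te, , drop = FALSE], med)
    ytr <- y[tr]
    if (smote) {
      bal <- smote_oversample(xtr, ytr, seed = child_seed(seed, f))
      xtr <- bal$x; ytr <- bal$y
    }
    clf <- fit_classifier(kind, xtr, ytr, params, seed = child_seed(seed, 100L + f))
    aucs <- c(aucs, roc_auc(predict_prob(clf, xte), y[te]))
  }
  if (length(aucs) == 0) return(NA_real_)
  mean(aucs)
}

## ---- SFFS feature selection --------------------------------------------

#' Sequential forward floating selection with frequency ranking
#'
#' Each iteration draws a fresh stratified fold assignment, runs SFFS
#' (greedy addition with conditional removal) maximizing mean CV AUC up
#' to `cap` features, and records the final subset. Across iterations,
#' features are ranked by selection frequency; the top `cap` are
#' retained (ties broken by single-feature CV AUC, then column order).
#'
#' @param x feature matrix (may contain `NA`; imputed fold-internally).
#' @param y binary labels.
#' @param classifier classifier kind driving the wrapper.
#' @param cap maximum subset size (see [feature_cap()]).
#' @param folds number of CV folds (default 10).
#' @param iterations number of SFFS repetitions (default 100).
#' @param seed integer seed.
#' @param params classifier hyperparameters used during selection.
#' @param smote apply fold-internal SMOTE (default TRUE).
#' @return list with `selected` (ordered feature names),
#'   `frequencies` (named counts), `single_auc` (per-feature CV AUC).
#' @export
sffs_select <- function(x, y, classifier = "GNB", cap = 5L, folds = 10L,
                        iterations = 100L, seed = NULL, params = list(),
                        smote = TRUE) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (p < 2) stop("need >= 2 candidate features", call. = FALSE)
  nm <- colnames(x) %||% paste0("f", seq_len(p))
  colnames(x) <- nm
  freq <- stats::setNames(numeric(p), nm)
  eval_subset <- function(cols, fold_id, it_seed) {
    suppressWarnings(cv_auc(x[, cols, drop = FALSE], y, classifier, params,
                            folds = fold_id, seed = it_seed, smote = smote))
  }
  single_auc <- NULL
  for (it in seq_len(iterations)) {
    it_seed <- child_seed(seed, it)
    fold_id <- stratified_folds(y, folds, it_seed)
    cur <- integer(0)
    cur_auc <- -Inf
    if (it == 1L) single_auc <- stats::setNames(numeric(p), nm)
    repeat {
      cand <- setdiff(seq_len(p), cur)
      if (length(cand) == 0 || length(cur) >= cap) break
      scores <- vapply(cand, function(j) {
        eval_subset(c(cur, j), fold_id, it_seed)
      }, numeric(1))
      if (it == 1L && length(cur) == 0L) single_auc[cand] <- scores
      best <- which.max(scores)
      if (length(cur) > 0 && scores[best] <= cur_auc) break
      cur <- c(cur, cand[best])
      cur_auc <- scores[best]
      # floating step: conditional removal of an earlier feature
      while (length(cur) > 2) {
        drop_scores <- vapply(seq_along(cur), function(r) {
          eval_subset(cur[-r], fold_id, it_seed)
        }, numeric(1))
        r <- which.max(drop_scores)
        if (drop_scores[r] > cur_auc && r != length(cur)) {
          cur <- cur[-r]
          cur_auc <- drop_scores[r]
        } else break
      }
    }
    freq[cur] <- freq[cur] + 1
  }
  ord <- order(-freq, -single_auc, seq_len(p))
  chosen <- ord[freq[ord] > 0]
  chosen <- chosen[seq_len(min(cap, length(chosen)))]
  list(selected = nm[chosen], frequencies = freq, single_auc = single_auc)
}

#' Randomized hyperparameter search
#'
#' Uniform random search over the documented per-classifier spaces (a
#' randomized-grid-search stand-in for tree-structured optimizers),
#' scored by stratified CV AUC with fold-internal SMOTE. Budget 0
#' returns the classifier defaults.
#'
#' @param x feature matrix restricted to the selected features.
#' @param y binary labels.
#' @param classifier classifier kind.
#' @param budget number of sampled configurations.
#' @param folds CV folds (default 10).
#' @param seed integer seed.
#' @return list with `params` (best configuration) and `cv_auc`.
#' @export
tune_hyperparameters <- function(x, y, classifier, budget = 20L,
                                 folds = 10L, seed = NULL) {
  best <- list(params = default_hyperparameters(classifier), cv_auc = NA_real_)
  if (budget <= 0) return(best)
  fold_id <- stratified_folds(y, folds, seed)
  best$cv_auc <- -Inf
  for (b in seq_len(budget)) {
    cfg <- with_seed(child_seed(seed, b),
                     sample_hyperparameters(classifier, nrow(x), ncol(x)))
    auc <- suppressWarnings(
      cv_auc(x, y, classifier, cfg, folds = fold_id,
             seed = child_seed(seed, 1000L + b)))
    if (!is.na(auc) && auc > best$cv_auc) {
      best$params <- cfg
      best$cv_auc <- auc
    }
  }
  best
}

## ---- model bundle -------------------------------------------------------

#' Train a full pipeline and package it as a model bundle
#'
#' Runs, in order and on training rows only: constant/collinearity
#' filtering, median imputation, Z-scoring, optional SFFS feature
#' selection, optional randomized hyperparameter search, SMOTE
#' balancing, and the final classifier fit. The returned bundle replays
#' imputation, scaling and selection on unseen rows.
#'
#' @param x training feature data.frame or matrix.
#' @param y binary training labels (0/1).
#' @param classifier classifier kind.
#' @param types per-column types for the collinearity filter.
#' @param collinearity apply the collinearity filter (default TRUE).
#' @param cor_threshold association cutoff (default 0.90).
#' @param select fixed feature names to use (skips SFFS), or `NULL`.
#' @param sffs list of SFFS settings (`iterations`, `folds`, `cap`),
#'   or `NULL` to keep all filtered features.
#' @param tune_budget configurations for randomized search (0 = defaults).
#' @param smote balance the final training set with SMOTE.
#' @param seed integer seed.
#' @return object of class `model_bundle`.
#' @export
train_model <- function(x, y, classifier = "LR", types = NULL,
                        collinearity = TRUE, cor_threshold = 0.90,
                        select = NULL, sffs = NULL, tune_budget = 0L,
                        smote = TRUE, seed = NULL) {
  x <- as.data.frame(x, check.names = FALSE)
  y <- as.integer(y)
  nm <- colnames(x)
  mask <- stats::setNames(rep(TRUE, ncol(x)), nm)
  if (collinearity) {
    mask <- suppressWarnings(collinearity_filter(x, y, types, cor_threshold))
  } else {
    const <- vapply(x, function(c) length(unique(c[!is.na(c)])) < 2, logical(1))
    mask[const] <- FALSE
  }
  xm <- as.matrix(x[, mask, drop = FALSE])
  med <- impute_fit(xm)
  xm <- impute_apply(xm, med)
  zs <- suppressWarnings(zscore_fit(xm))
  xz <- zscore_apply(xm, zs)
  selection <- NULL
  if (!is.null(select)) {
    selected <- intersect(select, colnames(xz))
  } else if (!is.null(sffs)) {
    cap <- sffs$cap %||% feature_cap(nrow(xz))
    selection <- sffs_select(xz, y, classifier, cap = cap,
                             folds = sffs$folds %||% 10L,
                             iterations = sffs$iterations %||% 100L,
                             seed = child_seed(seed, 7L), smote = smote)
    selected <- selection$selected
  } else {
    selected <- colnames(xz)
  }
  xs <- xz[, selected, drop = FALSE]
  tuned <- tune_hyperparameters(xs, y, classifier, budget = tune_budget,
                                seed = child_seed(seed, 11L))
  final <- list(x = xs, y = y)
  if (smote) {
    final <- suppressWarnings(
      smote_oversample(xs, y, seed = child_seed(seed, 13L)))
  }
  clf <- fit_classifier(classifier, final$x, final$y, tuned$params,
                        seed = child_seed(seed, 17L))
  structure(list(classifier = classifier, mask = mask, medians = med,
                 zscore = zs, selected = selected, selection = selection,
                 tuned = tuned, clf = clf, seed = seed),
            class = "model_bundle")
}

#' @export
predict.model_bundle <- function(object, newdata, ...) {
  x <- as.data.frame(newdata, check.names = FALSE)
  xm <- as.matrix(x[, names(object$mask)[object$mask], drop = FALSE])
  xm <- impute_apply(xm, object$medians)
  xz <- zscore_apply(xm, object$zscore)
  predict_prob(object$clf, xz[, object$selected, drop = FALSE])
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle> %s: %d/%d features retained, %d selected\n",
              x$classifier, sum(x$mask), length(x$mask), length(x$selected)))
  invisible(x)
}

## ---- clinical encoding --------------------------------------------------

#' Encode a clinical table for modeling
#'
#' Binary covariates become 0/1, multi-level nominals are one-hot
#' encoded against their first level, and stage/grade ordinals become
#' integers. Returns the encoded matrix plus per-column types for the
#' collinearity filter.
#'
#' @param clinical data.frame from [cohort_clinical_table()] (columns
#'   other than `patient_id` and `pcr_label` are covariates).
#' @return list with `x` (data.frame), `types` (character vector),
#'   `y` (labels, if present), `patient_id`.
#' @export
encode_clinical <- function(clinical) {
  ordinal <- c("clinical_t_stage", "clinical_n_stage", "nottingham_grade")
  ids <- clinical$patient_id
  y <- clinical$pcr_label
  covs <- clinical[setdiff(names(clinical), c("patient_id", "pcr_label"))]
  out <- list(); types <- c()
  for (nm in names(covs)) {
    v <- covs[[nm]]
    if (is.numeric(v)) {
      out[[nm]] <- v; types[nm] <- "continuous"
    } else if (nm %in% ordinal) {
      out[[nm]] <- as.integer(as.character(v)); types[nm] <- "continuous"
    } else {
      lv <- sort(unique(as.character(v)))
      if (length(lv) <= 2) {
        out[[nm]] <- as.integer(v == lv[length(lv)]); types[nm] <- "nominal"
      } else {
        for (l in lv[-1]) { # one-hot against the first (reference) level
          cn <- paste0(nm, "_", l)
          out[[cn]] <- as.integer(v == l); types[cn] <- "nominal"
        }
      }
    }
  }
  list(x = as.data.frame(out, check.names = FALSE), types = unname(types),
       y = y, patient_id = ids)
}
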