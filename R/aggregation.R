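## Patient-level aggregation of per-core feature vectors. Seven schemes
## are supported: per-core (one row per core, patient label inherited),
## max, min, mean, weighted-mean, median, and mean-min-max (three
## columns per feature). Reductions ignore missing values; a feature
## missing in every core stays missing.

AGG_METHODS <- c("per_core", "max", "min", "mean", "weighted_mean",
                 "median", "mean_min_max")

reduce_ignore_na <- function(x, f) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_real_ else f(x)
}

#' Aggregate one patient's core feature vectors
#'
#' @param vectors data.frame of per-core rows (feature columns only, one
#'   row per core), or a numeric matrix.
#' @param method one of `"per_core"`, `"max"`, `"min"`, `"mean"`,
#'   `"weighted_mean"`, `"median"`, `"mean_min_max"`.
#' @param weights per-core weights for `weighted_mean`; the pipeline
#'   default is the per-core lymphocyte count, so cores with more TILs
#'   count more.
#' @return for reducing schemes, a named numeric vector (length 371, or
#'   3 x 371 with `_mean`/`_min`/`_max` suffixes for `mean_min_max`);
#'   for `per_core`, the input matrix unchanged.
#' @examples
#' m <- rbind(a = c(f = 1), b = c(f = 3))
#' aggregate_patient(m, "mean") # f = 2
#' @export
aggregate_patient <- function(vectors, method = "mean", weights = NULL) {
  method <- match.arg(method, AGG_METHODS)
  m <- as.matrix(vectors)
  if (nrow(m) == 0) stop("no core vectors to aggregate", call. = FALSE)
  switch(method,
    per_core = m,
    max = apply(m, 2, reduce_ignore_na, max),
    min = apply(m, 2, reduce_ignore_na, min),
    mean = apply(m, 2, reduce_ignore_na, mean),
    median = apply(m, 2, reduce_ignore_na, stats::median),
    weighted_mean = {
      if (is.null(weights)) weights <- rep(1, nrow(m))
      if (length(weights) != nrow(m)) stop("one weight per core", call. = FALSE)
      apply(rbind(m), 2, function(col) {
        ok <- !is.na(col)
        if (!any(ok) || sum(weights[ok]) == 0) return(NA_real_)
        sum(col[ok] * weights[ok]) / sum(weights[ok])
      })
    },
    mean_min_max = {
      mn <- apply(m, 2, reduce_ignore_na, mean)
      mi <- apply(m, 2, reduce_ignore_na, min)
      ma <- apply(m, 2, reduce_ignore_na, max)
      stats::setNames(c(mn, mi, ma),
                      c(paste0(colnames(m), "_mean"),
                        paste0(colnames(m), "_min"),
                        paste0(colnames(m), "_max")))
    })
}

#' Aggregate a cohort feature matrix to patient level
#'
#' @param features data.frame with `patient_id`, `core_id` and feature
#'   columns (from [extract_cohort_features()]).
#' @param method aggregation scheme (see [aggregate_patient()]).
#' @param weight_feature feature used as the per-core weight for
#'   `weighted_mean` (default `"TIL-FREQ"`, proportional to the
#'   lymphocyte count at fixed tile area).
#' @return data.frame with one row per patient (`per_core`: one row per
#'   core, sorted by core id, with the patient id repeated).
#' @export
aggregate_cohort <- function(features, method = "mean",
                             weight_feature = "TIL-FREQ") {
  method <- match.arg(method, AGG_METHODS)
  feat_cols <- setdiff(names(features), c("patient_id", "core_id"))
  out <- list()
  for (pid in unique(features$patient_id)) {
    sub <- features[features$patient_id == pid, , drop = FALSE]
    sub <- sub[order(sub$core_id), , drop = FALSE]
    m <- as.matrix(sub[feat_cols])
    rownames(m) <- sub$core_id
    if (method == "per_core") {
      out[[pid]] <- cbind(data.frame(patient_id = pid, core_id = sub$core_id,
                                     stringsAsFactors = FALSE),
                          as.data.frame(m, check.names = FALSE))
    } else {
      w <- if (method == "weighted_mean") m[, weight_feature] else NULL
      v <- aggregate_patient(m, method, weights = w)
      out[[pid]] <- cbind(data.frame(patient_id = pid, stringsAsFactors = FALSE),
                          as.data.frame(as.list(v), check.names = FALSE))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
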