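#' Distributional summary used throughout the feature catalogue
#'
#' Every continuous spatial quantity (edge lengths, cell areas, neighbor
#' counts, ...) is reduced to the same four numbers: mean, population
#' standard deviation, min-max ratio (MMR), and disorder (DIS).
#'
#' Disorder is defined as \eqn{\sigma / (\mu + \sigma)}: 0 for a constant
#' sample and approaching 1 as the spread dominates the level. MMR is
#' \eqn{\min / \max}, defined as 0 when the maximum is 0. Both conventions
#' follow the classical nuclear-architecture feature literature.
#'
#' @param values numeric vector of non-negative values; must be non-empty
#'   and free of `NA`.
#' @return a list with components `mean`, `std` (population), `mmr`,
#'   `disorder`.
#' @examples
#' summary_stats(c(1, 3)) # mean 2, std 1, mmr 1/3, disorder 1/3
#' @export
summary_stats <- function(values) {
  if (length(values) == 0L || anyNA(values)) {
    stop("summary_stats() requires a non-empty vector without NA", call. = FALSE)
  }
  m <- mean(values)
  s <- sqrt(mean((values - m)^2)) # population sd
  mx <- max(values)
  mmr <- if (mx == 0) 0 else min(values) / mx
  dis <- if (m + s == 0) 0 else s / (m + s)
  list(mean = m, std = s, mmr = mmr, disorder = dis)
}

# Vector form in fixed statistic order, with an all-NA fallback for
# degenerate inputs (the documented missing-value policy).
summary_stats_vec <- function(values) {
  if (length(values) == 0L) {
    return(c(mean = NA_real_, std = NA_real_, mmr = NA_real_, disorder = NA_real_))
  }
  unlist(summary_stats(values))
}
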