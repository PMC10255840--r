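#' Pattern-feature-extraction parameters
#'
#' Controls the two-stage map denoiser: adaptive power thresholding
#' followed by a row-wise Hampel filter along the time axis.
#'
#' @param a adaptive threshold weight in `[0, 1]`; the threshold is
#'   `(1 - a) * mean(P) + a * (max(P) + min(P))`.
#' @param hampel_k Hampel half-window K in time cells.
#' @param hampel_nth Hampel replacement multiplier.
#' @return an object of class `pfe_params`.
#' @export
pfe_params <- function(a = 0.25, hampel_k = 5L, hampel_nth = 3) {
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 0 || a > 1)
    stopf("pfe_params: `a` must lie in [0, 1]")
  if (!is_count(hampel_k)) stopf("pfe_params: `hampel_k` must be a count >= 1")
  if (!is.numeric(hampel_nth) || hampel_nth <= 0)
    stopf("pfe_params: `hampel_nth` must be > 0")
  structure(list(a = a, hampel_k = as.integer(hampel_k),
                 hampel_nth = hampel_nth), class = "pfe_params")
}

#' Adaptive power threshold
#'
#' Computes `Pth = (1 - a) * mean(P) + a * (max(P) + min(P))` and floors
#' every cell below it to the map minimum; cells at or above the
#' threshold are untouched.  At `a = 0` the threshold is the mean power;
#' at `a = 1` it is `max(P) + min(P)` (which may exceed the maximum, in
#' which case only cells equal to it survive -- a documented consequence
#' of the additive form).
#'
#' @param map a `feature_map` or a numeric matrix.
#' @param a threshold weight in `[0, 1]`.
#' @return a list with `threshold` (the scalar Pth) and `map` (same type
#'   as the input, sub-threshold cells floored to the minimum).
#' @export
adaptive_threshold <- function(map, a) {
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 0 || a > 1)
    stopf("adaptive_threshold: `a` must lie in [0, 1]")
  v <- if (inherits(map, "feature_map")) map$values else map
  if (!is.numeric(v) || length(v) == 0L || any(!is.finite(v)))
    stopf("adaptive_threshold: map must be non-empty and finite")
  pth <- (1 - a) * mean(v) + a * (max(v) + min(v))
  v[v < pth] <- min(v)
  if (inherits(map, "feature_map")) map$values <- v else map <- v
  list(threshold = pth, map = map)
}

#' Hampel sliding-window outlier filter
#'
#' For each index k, the window `[k - K, k + K]` (truncated at the series
#' boundaries) yields the median `m_k` and the scaled median absolute
#' deviation `S_k = 1.4826 * median(|x_j - m_k|)`; `x_k` is replaced by
#' `m_k` when `|x_k - m_k| > nth * S_k`.  With `S_k = 0` (more than half
#' the window identical) any deviation from the median triggers
#' replacement.  The filter is non-recursive and never produces values
#' outside the window's original range.
#'
#' @param x numeric vector.
#' @param k half-window K (cells).
#' @param nth threshold multiplier.
#' @return the filtered vector, with attribute `n_replaced`.
#' @examples
#' hampel_filter(c(1, 1, 1, 100, 1, 1, 1), k = 2, nth = 3)
#' @export
hampel_filter <- function(x, k = 5L, nth = 3) {
  if (!is.numeric(x) || length(x) < 1L) stopf("hampel_filter: empty series")
  if (!is_count(k)) stopf("hampel_filter: `k` must be a count >= 1")
  if (!is.numeric(nth) || nth <= 0) stopf("hampel_filter: `nth` must be > 0")
  res <- .hampel_vec(as.numeric(x), as.integer(k), as.numeric(nth))
  structure(res$values, n_replaced = res$n_replaced)
}

#' Pattern feature extraction: threshold then Hampel
#'
#' The full PFE denoiser: adaptive power thresholding removes diffuse
#' low-power background, then a Hampel filter applied along the time axis
#' independently for each feature bin (each row as a time series) removes
#' the surviving isolated specks.  The threshold value and replacement
#' count are recorded in the map provenance (`provenance$pfe`).
#'
#' @param map a `feature_map`.
#' @param params a [pfe_params()].
#' @return the cleaned `feature_map`.
#' @export
pfe_clean <- function(map, params = pfe_params()) {
  stopifnot(inherits(map, "feature_map"), inherits(params, "pfe_params"))
  th <- adaptive_threshold(map$values, params$a)
  res <- .hampel_rows(th$map, params$hampel_k, params$hampel_nth)
  map$values <- res$values
  map$provenance$pfe <- list(a = params$a, hampel_k = params$hampel_k,
                             hampel_nth = params$hampel_nth,
                             threshold = th$threshold,
                             n_replaced = res$n_replaced)
  map
}
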