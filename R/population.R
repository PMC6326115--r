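#' Post-stratified population mean and total
#'
#' Combines plot-level estimates into a population estimate with the
#' textbook post-stratified estimator. With stratum area fractions
#' \eqn{W_h}, stratum plot counts \eqn{n_h} (total \eqn{n}), stratum means
#' \eqn{\bar y_h} and variances \eqn{s^2_h}:
#' \deqn{\hat{\bar Y} = \sum_h W_h \bar y_h}
#' \deqn{\hat V = \frac{1}{n}\left[\sum_h W_h s^2_h +
#'   \sum_h (1 - W_h) \frac{n_h}{n} \frac{s^2_h}{n}\right]}
#' This is the standard two-term post-stratification variance (the second
#' term is the lower-order penalty for the stratum sample sizes being
#' random); Monte-Carlo calibration of the nominal 95% interval against
#' simulated populations is part of the test suite. The production
#' inventory's exact formula lives in its estimation documentation and may
#' differ in finite-population details.
#'
#' @param values Numeric vector of plot-level estimates (one per plot).
#' @param stratum Stratum id per plot (same length as `values`).
#' @param weights Stratum area fractions: a named numeric vector
#'   (names = stratum ids) or a data.frame with columns `STRATUM`,
#'   `WEIGHT` (and optionally `AREA`). Must sum to 1 over the estimation
#'   unit.
#' @param area Total area of the estimation unit (any unit); when given,
#'   `total = mean * area` is reported in value-units times `area` units.
#' @return Object of class `dwm_popest`: list with `mean`, `se`,
#'   `variance`, `total`, `n`, and a per-stratum summary data.frame.
#' @examples
#' post_stratified_mean(c(1, 2, 3, 4), c("a", "a", "b", "b"),
#'                      c(a = 0.5, b = 0.5))
#' @export
post_stratified_mean <- function(values, stratum, weights, area = NULL) {
  stopifnot(length(values) == length(stratum))
  if (anyNA(values)) {
    stop("estimation error: NA plot estimates (undefined plot values ",
         "must be resolved before population estimation)", call. = FALSE)
  }
  if (is.data.frame(weights)) {
    if (is.null(area) && "AREA" %in% names(weights)) {
      area <- sum(weights$AREA)
    }
    w <- stats::setNames(weights$WEIGHT, as.character(weights$STRATUM))
  } else {
    w <- weights
  }
  stratum <- as.character(stratum)
  if (is.null(names(w)) || any(!nzchar(names(w)))) {
    stop("config error: stratum weights must be named by stratum id",
         call. = FALSE)
  }
  if (abs(sum(w) - 1) > 1e-8) {
    stop("config error: stratum weights sum to ", format(sum(w)),
         ", not 1", call. = FALSE)
  }
  missing_w <- setdiff(unique(stratum), names(w))
  if (length(missing_w)) {
    stop("config error: no weight for stratum ",
         paste(missing_w, collapse = ", "), call. = FALSE)
  }
  empty <- setdiff(names(w), unique(stratum))
  if (length(empty)) {
    stop("estimation error: stratum with 0 plots: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  n <- length(values)
  hs <- names(w)
  n_h <- vapply(hs, function(h) sum(stratum == h), numeric(1))
  ybar_h <- vapply(hs, function(h) mean(values[stratum == h]), numeric(1))
  s2_h <- vapply(hs, function(h) {
    if (n_h[h] < 2) NA_real_ else stats::var(values[stratum == h])
  }, numeric(1))
  m <- sum(w * ybar_h)
  v <- if (anyNA(s2_h)) {
    warning("stratum with a single plot: variance undefined")
    NA_real_
  } else {
    (sum(w * s2_h) + sum((1 - w) * (n_h / n) * (s2_h / n))) / n
  }
  out <- list(
    mean = m,
    variance = v,
    se = sqrt(v),
    total = if (is.null(area)) NA_real_ else m * area,
    area = area %||% NA_real_,
    n = n,
    strata = data.frame(STRATUM = hs, WEIGHT = as.numeric(w),
                        N_PLOTS = as.numeric(n_h), MEAN = ybar_h,
                        VAR = s2_h, row.names = NULL,
                        stringsAsFactors = FALSE)
  )
  class(out) <- "dwm_popest"
  out
}

#' @export
print.dwm_popest <- function(x, ...) {
  cat(sprintf("Post-stratified estimate: mean %.4f (SE %.4f), n = %d\n",
              x$mean, x$se, x$n))
  if (!is.na(x$total)) cat(sprintf("  total = %.2f over area %.2f\n",
                                   x$total, x$area))
  print(x$strata)
  invisible(x)
}

#' Nonresponse adjustment of plot estimates
#'
#' Divides each plot value by the proportion sampled \eqn{\bar p} of its
#' stratum, correcting for partially inaccessible plots. \eqn{\bar p = 1}
#' is the identity (the default elsewhere in the package: the plot
#' estimators do not fold this factor in).
#'
#' @param values Numeric plot estimates.
#' @param stratum Stratum id per plot.
#' @param pbar Named numeric vector of per-stratum sampled proportions,
#'   each in (0, 1].
#' @return Adjusted numeric vector.
#' @export
apply_nonresponse_adjustment <- function(values, stratum, pbar) {
  stratum <- as.character(stratum)
  if (any(pbar <= 0 | pbar > 1)) {
    stop("config error: pbar must be in (0, 1]", call. = FALSE)
  }
  miss <- setdiff(unique(stratum), names(pbar))
  if (length(miss)) {
    stop("config error: no pbar for stratum ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  values / as.numeric(pbar[stratum])
}
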