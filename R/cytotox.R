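#' Four-parameter logistic response
#'
#' `bottom + (top - bottom) / (1 + (dose/ic50)^hill)`. With `hill > 0`
#' the response falls from `top` toward `bottom` as dose increases, and
#' equals the midpoint `(top + bottom) / 2` at `dose = ic50`.
#'
#' @param dose dose (same unit as `ic50`, > 0).
#' @param top,bottom upper/lower asymptotes.
#' @param hill Hill slope.
#' @param ic50 half-maximal dose.
#' @return Predicted response.
#' @export
four_param_logistic <- function(dose, top, bottom, hill, ic50) {
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of viability against dose with Levenberg-Marquardt
#' iterations and multi-start initialization: Hill slopes
#' {-2, -1, -0.5, 0.5, 1, 2} crossed with the IC50 started at the
#' geometric mean of the doses and at each distinct dose; `top`/`bottom`
#' start at the max/min mean response. The IC50 is parameterized on the log scale so it stays
#' positive. The best start by residual sum of squares wins; if no start
#' converges, parameters from the best attempt are returned with
#' `converged = FALSE`.
#'
#' @param dr data.frame with `dose_uM` (> 0) and `response` columns
#'   (replicates as repeated rows), e.g. from
#'   [generate_dose_response()]. At least 4 distinct doses are required.
#' @param normalize_to_vehicle if `TRUE`, responses are first divided by
#'   the mean response at the lowest dose (vehicle-proxy normalization
#'   for raw absorbances). Default `FALSE`.
#' @return List of class `curve_fit`: `top`, `bottom`, `hill`,
#'   `ic50` (same unit as doses), `sse`, `converged`.
#' @export
fit_four_param_logistic <- function(dr, normalize_to_vehicle = FALSE) {
  stopifnot(all(c("dose_uM", "response") %in% names(dr)))
  if (any(dr$dose_uM <= 0)) stop("doses must be strictly positive")
  if (length(unique(dr$dose_uM)) < 4)
    stop("need >= 4 distinct doses to fit a 4PL")
  y <- dr$response
  if (normalize_to_vehicle) {
    ref <- mean(y[dr$dose_uM == min(dr$dose_uM)])
    if (ref <= 0) stop("vehicle-proxy mean response must be > 0")
    y <- y / ref
  }
  x <- dr$dose_uM
  dose_means <- tapply(y, x, mean)
  top0 <- max(dose_means)
  bottom0 <- min(dose_means)
  lic0 <- mean(log(unique(x)))  # geometric mean of doses
  residfun <- function(p) {
    y - (p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
           (1 + exp(p[["hill"]] * (log(x) - p[["lic"]]))))
  }
  best <- NULL
  for (hill0 in c(-2, -1, -0.5, 0.5, 1, 2)) {
    for (l0 in unique(c(lic0, log(unique(x))))) {
      fit <- tryCatch(
        minpack.lm::nls.lm(
          par = c(top = top0, bottom = bottom0, hill = hill0, lic = l0),
          fn = residfun,
          control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      sse <- fit$deviance
      if (is.null(best) || sse < best$sse) {
        cf <- fit$par
        best <- list(top = unname(cf["top"]),
                     bottom = unname(cf["bottom"]),
                     hill = unname(cf["hill"]),
                     ic50 = exp(unname(cf["lic"])), sse = sse,
                     converged = fit$info %in% 1:4)
      }
    }
  }
  if (is.null(best))
    stop("4PL fit failed from every start")
  if (best$bottom > best$top) {
    # reflect so bottom <= top (equivalent curve with negated hill)
    best <- list(top = best$bottom, bottom = best$top, hill = -best$hill,
                 ic50 = best$ic50, sse = best$sse,
                 converged = best$converged)
  }
  structure(best, class = "curve_fit")
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf(
    "curve_fit: IC50 = %.4g, hill = %.3g, top = %.3g, bottom = %.3g, SSE = %.3g%s\n",
    x$ic50, x$hill, x$top, x$bottom, x$sse,
    if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Scale a reference concentration range by a relative intensity ratio
#'
#' Circulating concentrations in ESKD are estimated by multiplying a
#' published healthy reference interval by the relative LC-MS intensity
#' ratio observed between cohorts (after normalization). E.g. a 12-fold
#' elevation applied to the healthy homocysteine interval 5-15 uM gives
#' 60-180 uM pre-dialysis.
#'
#' @param relative_ratio fold ratio (> 0).
#' @param reference_range numeric length-2 interval in uM, low <= high.
#' @return Scaled interval (uM), same ordering.
#' @export
scale_concentration <- function(relative_ratio, reference_range) {
  stopifnot(relative_ratio > 0, length(reference_range) == 2)
  if (reference_range[1] > reference_range[2])
    stop("reference range must be ordered low <= high")
  relative_ratio * reference_range
}
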