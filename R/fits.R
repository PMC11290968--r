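#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `y = bottom + (top - bottom) / (1 + (ec50/x)^hill)`
#' for inhibition-style data (response rising with dose when `hill > 0`).
#' Zero-dose (vehicle) wells are kept in the fit at the model's exact
#' `x -> 0` limit, `bottom`, so they anchor the lower asymptote without any
#' surrogate-dose approximation. For responses normalized to vehicle and
#' full kill (the usual 0-100% scale) the asymptotes can be constrained via
#' `fix_bottom` / `fix_top`, the standard normalized-response model, which
#' substantially tightens the EC50 estimate on noisy data. Initialization
#' is multi-start — EC50 starts at the nonzero-dose quantiles crossed with
#' several Hill slopes — and the converged start with the lowest residual
#' sum of squares wins. Failures are returned as a value
#' (`converged = FALSE`), never thrown.
#'
#' @param doses Numeric vector of doses (>= 5 points, >= 3 distinct
#'   nonzero); replicate doses allowed.
#' @param responses Numeric vector, same length.
#' @param fix_bottom,fix_top Optional fixed asymptote values (e.g. 0 and
#'   100 for normalized data); `NULL` estimates them.
#' @return List of class `curve_fit` with `model = "fourPL"`, `params`
#'   (bottom, top, ec50, hill), `ec50`, `rss`, `converged`.
#' @export
fit_4pl <- function(doses, responses, fix_bottom = NULL, fix_top = NULL) {
  if (length(doses) != length(responses)) abort_validation("doses/responses length mismatch")
  if (length(doses) < 5L) abort_validation("need >= 5 dose points, got %d", length(doses))
  nz <- unique(doses[doses > 0])
  if (length(nz) < 3L) abort_validation("need >= 3 distinct nonzero doses")
  if (any(doses < 0)) abort_validation("doses must be >= 0")
  failure <- structure(list(model = "fourPL", params = NULL, ec50 = NA_real_,
                            rss = NA_real_, converged = FALSE), class = "curve_fit")
  if (stats::sd(responses) == 0) return(failure)

  df <- data.frame(x = doses, y = responses)
  lo <- min(responses); hi <- max(responses)
  starts <- expand.grid(
    ec50 = stats::quantile(nz, probs = c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE),
    hill = c(0.5, 1, 2),
    KEEP.OUT.ATTRS = FALSE
  )
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15)
  free_b <- is.null(fix_bottom); free_t <- is.null(fix_top)
  if (!free_b) df$bottom <- fix_bottom
  if (!free_t) df$top <- fix_top
  formula <- y ~ ifelse(x == 0, bottom,
                        bottom + (top - bottom) / (1 + (ec50 / x)^hill))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    start <- c(if (free_b) list(bottom = lo), if (free_t) list(top = hi),
               list(ec50 = starts$ec50[[i]], hill = starts$hill[[i]]))
    bounds_lo <- c(if (free_b) -Inf, if (free_t) -Inf, min(nz) / 100, 1e-3)
    bounds_hi <- c(if (free_b) Inf, if (free_t) Inf, max(nz) * 100, 50)
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = df, start = start,
                        lower = bounds_lo, upper = bounds_hi, control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(failure)
  p <- as.list(stats::coef(best$fit))
  structure(
    list(model = "fourPL",
         params = list(bottom = if (free_b) p$bottom else fix_bottom,
                       top = if (free_t) p$top else fix_top,
                       ec50 = p$ec50, hill = p$hill),
         ec50 = p$ec50, rss = best$rss, converged = TRUE),
    class = "curve_fit"
  )
}

#' Fit a one-phase exponential decay
#'
#' Least-squares fit of `y(t) = (y0 - plateau) * exp(-k * t) + plateau` with
#' `k > 0`; the derived half-life is `ln(2) / k`. The plateau is estimated
#' unless `plateau_fixed` is supplied. A decaying signal is assumed: fits
#' driven to the `k` lower bound (non-decaying data) are reported with
#' `converged = FALSE` rather than a negative or meaningless half-life.
#'
#' @param times Numeric vector of times >= 0 (>= 4 points).
#' @param levels Numeric vector of signal levels, same length.
#' @param plateau_fixed Optional fixed plateau value.
#' @return List of class `curve_fit` with `model = "one_phase_decay"`,
#'   `params` (y0, plateau, k), `half_life`, `rss`, `converged`.
#' @export
fit_one_phase_decay <- function(times, levels, plateau_fixed = NULL) {
  if (length(times) != length(levels)) abort_validation("times/levels length mismatch")
  if (length(times) < 4L) abort_validation("need >= 4 time points, got %d", length(times))
  if (any(times < 0)) abort_validation("times must be >= 0")
  failure <- structure(list(model = "one_phase_decay", params = NULL,
                            half_life = NA_real_, rss = NA_real_, converged = FALSE),
                       class = "curve_fit")
  if (stats::sd(levels) == 0) return(failure)

  df <- data.frame(t = times, y = levels)
  span <- max(times)
  if (span <= 0) return(failure)
  k0 <- log(2) / (span / 3) # half-life a third of the observation window
  k_lo <- 1e-9
  fit <- NULL
  for (k_start in c(k0, k0 * 10, k0 / 10)) {
    fit <- tryCatch({
      if (is.null(plateau_fixed)) {
        minpack.lm::nlsLM(
          y ~ (y0 - plateau) * exp(-k * t) + plateau, data = df,
          start = list(y0 = levels[[which.min(times)]], plateau = min(levels), k = k_start),
          lower = c(y0 = -Inf, plateau = -Inf, k = k_lo),
          control = minpack.lm::nls.lm.control(maxiter = 500))
      } else {
        pl <- plateau_fixed
        minpack.lm::nlsLM(
          y ~ (y0 - pl) * exp(-k * t) + pl, data = df,
          start = list(y0 = levels[[which.min(times)]], k = k_start),
          lower = c(y0 = -Inf, k = k_lo),
          control = minpack.lm::nls.lm.control(maxiter = 500))
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(failure)
  p <- as.list(stats::coef(fit))
  k <- p$k
  plateau <- if (is.null(plateau_fixed)) p$plateau else plateau_fixed
  res <- structure(
    list(model = "one_phase_decay",
         params = list(y0 = p$y0, plateau = plateau, k = k),
         half_life = log(2) / k,
         rss = sum(stats::residuals(fit)^2),
         converged = TRUE),
    class = "curve_fit"
  )
  if (k <= k_lo * 10) res$converged <- FALSE       # pinned at bound: not a decay
  if (p$y0 <= plateau) res$converged <- FALSE      # growth, not decay
  res
}

#' @export
print.curve_fit <- function(x, ...) {
  if (!x$converged && is.null(x$params)) {
    cat(sprintf("<curve_fit> %s: fit failure (converged = FALSE)\n", x$model))
    return(invisible(x))
  }
  if (x$model == "fourPL") {
    cat(sprintf("<curve_fit> 4PL: EC50 = %.4g, hill = %.3g, rss = %.4g (converged = %s)\n",
                x$ec50, x$params$hill, x$rss, x$converged))
  } else {
    cat(sprintf("<curve_fit> one-phase decay: t1/2 = %.4g, k = %.4g, rss = %.4g (converged = %s)\n",
                x$half_life, x$params$k, x$rss, x$converged))
  }
  invisible(x)
}
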