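#' Nutrient retention curve
#'
#' Observed percentage of a nutrient retained in the stomach over digestion
#' time. Values up to 110% are allowed so that observation noise above
#' 100% is representable.
#'
#' @param times Non-negative, strictly increasing times, min.
#' @param retained_pct Percent retained at each time, in the 0 to 110 range.
#' @param nutrient `"protein"`, `"lipid"` or `"total"`.
#' @param sample_id Sample name.
#' @return An object of class `retention_curve`.
#' @export
retention_curve <- function(times, retained_pct,
                            nutrient = c("protein", "lipid", "total"),
                            sample_id = "") {
  nutrient <- match.arg(nutrient)
  times <- as.numeric(times); retained_pct <- as.numeric(retained_pct)
  if (length(times) != length(retained_pct))
    stop("times and retained_pct must have equal length", call. = FALSE)
  if (any(times < 0) || any(diff(times) <= 0))
    stop("times must be non-negative and strictly increasing", call. = FALSE)
  if (any(retained_pct < 0) || any(retained_pct > 110))
    stop("retained_pct must lie in [0, 110]", call. = FALSE)
  structure(list(times = times, retained_pct = retained_pct,
                 nutrient = nutrient, sample_id = sample_id),
            class = "retention_curve")
}

#' Modified power-exponential retention model
#'
#' Evaluates y(t) = alpha0 * exp(-(kappa * t)^beta), the modified
#' power-exponential gastric-retention curve: `alpha0` is the percentage
#' retained at t = 0 (100 for relative retention), `kappa` the gastric
#' emptying rate per minute, `beta` the shape index (beta = 1 is a single
#' exponential). The alternative parameterization
#' y(t) = alpha0 * exp(-kappa * t^beta) is available via
#' `form = "exp_power"`.
#'
#' @param t Time(s), min (>= 0).
#' @param alpha0 Retention at t = 0, percent.
#' @param kappa Emptying rate, 1/min (> 0).
#' @param beta Shape index (> 0).
#' @param form `"power_product"` (default) or `"exp_power"`.
#' @return Retention percentage(s), same length as `t`.
#' @export
elashoff <- function(t, alpha0 = 100, kappa, beta = 1,
                     form = c("power_product", "exp_power")) {
  form <- match.arg(form)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (kappa <= 0 || beta <= 0)
    stop("kappa and beta must be > 0", call. = FALSE)
  if (form == "power_product") alpha0 * exp(-(kappa * t)^beta)
  else alpha0 * exp(-kappa * t^beta)
}

#' Fit the retention model by least squares
#'
#' Unweighted nonlinear least squares of the modified power-exponential
#' model on a retention curve, via bounded Levenberg-Marquardt
#' (minpack.lm). By default `alpha0` is fixed at the observed t = 0 value
#' (100 when no t = 0 observation exists); `beta` is a free shape
#' parameter. Initialization: `kappa0` from the slope of a log-linear
#' regression of y/alpha0 on t, `beta0 = 1`; bounds kappa in (1e-6, 1),
#' beta in (0.1, 5).
#'
#' @param curve A [retention_curve()].
#' @param fix_alpha0 Fix alpha0 at the observed t = 0 value (default TRUE).
#' @param form Model parameterization, see [elashoff()].
#' @return An object of class `elashoff_fit`: `alpha0`, `kappa`, `beta`,
#'   `rss`, `converged`, `n_points`, `form`.
#' @export
fit_retention <- function(curve, fix_alpha0 = TRUE,
                          form = c("power_product", "exp_power")) {
  form <- match.arg(form)
  stopifnot(inherits(curve, "retention_curve"))
  t <- curve$times; y <- curve$retained_pct
  need <- if (fix_alpha0) 3L else 4L
  if (length(t) < need)
    stop("need at least ", need, " points", call. = FALSE)
  if (max(y) - min(y) < sqrt(.Machine$double.eps))
    stop("degenerate data: retained_pct is constant", call. = FALSE)
  a0_obs <- if (t[1] == 0) y[1] else 100

  # log-linear initial kappa (beta = 1 start); needs positive ratios
  pos <- y > 0 & t > 0
  k0 <- if (sum(pos) >= 2) {
    sl <- unname(stats::coef(stats::lm(log(y[pos] / a0_obs) ~ t[pos]))[2])
    min(max(-sl, 1e-5), 0.9)
  } else 0.01

  model <- function(t, alpha0, kappa, beta)
    elashoff(t, alpha0, kappa, beta, form = form)
  fit <- tryCatch({
    if (fix_alpha0)
      minpack.lm::nlsLM(y ~ model(t, a0_obs, kappa, beta),
                        start = list(kappa = k0, beta = 1),
                        lower = c(1e-6, 0.1), upper = c(1, 5),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-14, ptol = 1e-14))
    else
      minpack.lm::nlsLM(y ~ model(t, alpha0, kappa, beta),
                        start = list(alpha0 = a0_obs, kappa = k0, beta = 1),
                        lower = c(1, 1e-6, 0.1), upper = c(200, 1, 5),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  }, error = function(e) e)

  if (inherits(fit, "error")) {
    out <- list(alpha0 = a0_obs, kappa = k0, beta = 1, rss = NA_real_,
                converged = FALSE, n_points = length(t), form = form,
                message = conditionMessage(fit))
  } else {
    cf <- stats::coef(fit)
    out <- list(alpha0 = if (fix_alpha0) a0_obs else unname(cf["alpha0"]),
                kappa = unname(cf["kappa"]), beta = unname(cf["beta"]),
                rss = sum(stats::residuals(fit)^2),
                converged = fit$convInfo$isConv,
                n_points = length(t), form = form, message = NULL)
  }
  structure(out, class = "elashoff_fit")
}

#' Half-emptying time
#'
#' Time at which the fitted retention curve reaches half its initial value:
#' t_half = (ln 2)^(1/beta) / kappa for the power-product form.
#'
#' @param fit A converged `elashoff_fit`.
#' @return Half-emptying time, min.
#' @export
half_emptying_time <- function(fit) {
  stopifnot(inherits(fit, "elashoff_fit"))
  if (!isTRUE(fit$converged))
    stop("half-emptying time requires a converged fit", call. = FALSE)
  if (fit$form == "power_product") log(2)^(1 / fit$beta) / fit$kappa
  else (log(2) / fit$kappa)^(1 / fit$beta)
}

#' @export
print.elashoff_fit <- function(x, ...) {
  cat(sprintf(
    "<elashoff_fit> alpha0 = %.2f%%, kappa = %.4g /min (%.1f x10^-3), beta = %.3f\n",
    x$alpha0, x$kappa, 1000 * x$kappa, x$beta))
  cat(sprintf("  rss = %.4g on %d points; converged: %s\n",
              x$rss, x$n_points, x$converged))
  invisible(x)
}
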