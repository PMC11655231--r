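# Coefficient of determination without summary.lm's perfect-fit warning;
# a zero-variance response is a perfect fit by convention here.
r_squared <- function(fit, y) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(1)
  1 - sum(stats::resid(fit)^2) / tss
}

#' Emptied fraction from a retention curve
#'
#' Elementwise complement of retention: emptied = 100 - retained, clamped
#' to the 0 to 100 range (with a warning) when observation noise pushes retention
#' outside that range.
#'
#' @param curve A [retention_curve()].
#' @return Numeric vector of percent emptied, one value per time point.
#' @export
emptied_fraction <- function(curve) {
  stopifnot(inherits(curve, "retention_curve"))
  e <- 100 - curve$retained_pct
  if (any(e < 0) || any(e > 100)) {
    warning("emptied fraction clamped to [0, 100]", call. = FALSE)
    e <- pmin(pmax(e, 0), 100)
  }
  e
}

#' Destabilization index paired with nutrient emptying
#'
#' Pairs an aggregation or coalescence index series with the percent of a
#' nutrient emptied at the same sampling times, the input of the two-stage
#' analysis.
#'
#' @param emptied_pct Percent nutrient emptied, non-decreasing.
#' @param index_values AI or CI values at the same times.
#' @param index_kind `"AI"` or `"CI"`.
#' @param nutrient `"protein"` or `"lipid"`.
#' @param sample_id Sample name.
#' @return An object of class `emptying_index_series`.
#' @export
emptying_index_series <- function(emptied_pct, index_values,
                                  index_kind = c("AI", "CI"),
                                  nutrient = c("protein", "lipid"),
                                  sample_id = "") {
  index_kind <- match.arg(index_kind); nutrient <- match.arg(nutrient)
  if (length(emptied_pct) != length(index_values))
    stop("emptied_pct and index_values must have equal length", call. = FALSE)
  if (any(diff(emptied_pct) < 0))
    stop("emptied_pct must be non-decreasing", call. = FALSE)
  structure(list(emptied_pct = as.numeric(emptied_pct),
                 index_values = as.numeric(index_values),
                 index_kind = index_kind, nutrient = nutrient,
                 sample_id = sample_id),
            class = "emptying_index_series")
}

#' Two-stage destabilization-versus-emptying fit
#'
#' The destabilization trace against percent emptied has two regimes:
#' stage 1, steady emptying with the index on a near-zero plateau, and
#' stage 2, a near-linear rise of the index as aggregation/coalescence set
#' in. Stage 1 is the set of points with index at or below `index_floor`;
#' stage 2 points are fitted by ordinary least squares of index on percent
#' emptied. The stage-2 line's x-intercept (percent emptied at index = 0)
#' estimates where destabilization begins to accompany emptying.
#' `method = "grid"` instead chooses the stage boundary minimizing total
#' SSE of a flat-plateau + line model over all splits (sensitivity check).
#'
#' @param series An [emptying_index_series()] with >= 4 points, sorted by
#'   emptied percent.
#' @param index_floor Threshold separating plateau from rise.
#' @param method `"threshold"` (default) or `"grid"`.
#' @return An object of class `two_stage_fit`: `breakpoint_pct`,
#'   `stage2_slope`, `stage2_intercept_pct`, `r_squared_stage2`,
#'   `n_stage1`, `n_stage2`, `degenerate`.
#' @export
fit_two_stage <- function(series, index_floor = 0.5,
                          method = c("threshold", "grid")) {
  method <- match.arg(method)
  stopifnot(inherits(series, "emptying_index_series"))
  x <- series$emptied_pct; y <- series$index_values
  if (length(x) < 4L) stop("need >= 4 points", call. = FALSE)
  if (any(diff(x) < 0)) stop("emptied_pct must be sorted", call. = FALSE)

  in_stage1 <- if (method == "threshold") y <= index_floor else {
    # flat plateau + free line, split minimizing total SSE
    best <- NULL; best_sse <- Inf
    for (k in seq(2L, length(x) - 2L)) {
      s1 <- seq_len(k); s2 <- seq(k + 1L, length(x))
      sse <- sum((y[s1] - mean(y[s1]))^2) +
        sum(stats::resid(stats::lm(y[s2] ~ x[s2]))^2)
      if (sse < best_sse) { best_sse <- sse; best <- k }
    }
    seq_along(x) <= best
  }

  n1 <- sum(in_stage1); n2 <- sum(!in_stage1)
  out <- list(breakpoint_pct = if (n1 > 0) max(x[in_stage1]) else 0,
              stage2_slope = NA_real_, stage2_intercept_pct = NA_real_,
              r_squared_stage2 = NA_real_, n_stage1 = n1, n_stage2 = n2,
              degenerate = FALSE, method = method)
  if (n2 < 2L || n1 == 0L) {
    out$degenerate <- TRUE
    warning("two-stage fit degenerate: ", n1, " stage-1 / ", n2,
            " stage-2 points", call. = FALSE)
    return(structure(out, class = "two_stage_fit"))
  }
  x2 <- x[!in_stage1]; y2 <- y[!in_stage1]
  fit <- stats::lm(y2 ~ x2)
  sl <- unname(stats::coef(fit)[2]); ic <- unname(stats::coef(fit)[1])
  out$stage2_slope <- sl
  out$stage2_intercept_pct <- -ic / sl
  out$r_squared_stage2 <- r_squared(fit, y2)
  structure(out, class = "two_stage_fit")
}

#' @export
print.two_stage_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<two_stage_fit> degenerate (all points in one stage)\n")
  } else {
    cat(sprintf(
      "<two_stage_fit> breakpoint %.1f%% emptied; stage-2 slope %.3g, x-intercept %.1f%% (R2 = %.3f)\n",
      x$breakpoint_pct, x$stage2_slope, x$stage2_intercept_pct,
      x$r_squared_stage2))
  }
  invisible(x)
}

#' Lipid-versus-protein emptying regression
#'
#' Ordinary least squares of percent lipid emptied (y) on percent protein
#' emptied (x) with free intercept; a slope near 1 means the two
#' macronutrients are delivered in lockstep.
#'
#' @param protein_emptied,lipid_emptied Paired percent-emptied series
#'   (equal length >= 3).
#' @return An object of class `linear_fit`: `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
protein_lipid_regression <- function(protein_emptied, lipid_emptied) {
  if (length(protein_emptied) != length(lipid_emptied) ||
      length(protein_emptied) < 3L)
    stop("need paired series of equal length >= 3", call. = FALSE)
  if (stats::var(protein_emptied) == 0)
    stop("zero variance in protein_emptied", call. = FALSE)
  fit <- stats::lm(lipid_emptied ~ protein_emptied)
  r2 <- r_squared(fit, lipid_emptied)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n = length(protein_emptied)),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> slope = %.3f, intercept = %.3f, R2 = %.3f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Per-profile-group emptying regressions
#'
#' Pools paired protein/lipid emptied observations by profile group and
#' fits one lipid-on-protein regression per group plus an overall fit.
#'
#' @param emptied A data frame with columns `sample`, `protein_emptied`,
#'   `lipid_emptied`.
#' @param grouping Named character vector or data frame (`sample`,
#'   `profile`) mapping every sample to its profile group.
#' @return Named list of `linear_fit` objects, one per group plus
#'   `"overall"`.
#' @export
group_regressions <- function(emptied, grouping) {
  stopifnot(is.data.frame(emptied),
            all(c("sample", "protein_emptied", "lipid_emptied") %in%
                  names(emptied)))
  if (is.data.frame(grouping)) {
    stopifnot(all(c("sample", "profile") %in% names(grouping)))
    grouping <- stats::setNames(as.character(grouping$profile),
                                grouping$sample)
  }
  miss <- setdiff(unique(emptied$sample), names(grouping))
  if (length(miss))
    stop("no profile group for sample(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  grp <- grouping[emptied$sample]
  fits <- lapply(split(emptied, grp), function(d)
    protein_lipid_regression(d$protein_emptied, d$lipid_emptied))
  fits$overall <- protein_lipid_regression(emptied$protein_emptied,
                                           emptied$lipid_emptied)
  fits
}
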