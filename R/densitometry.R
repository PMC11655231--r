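#' Gel-band intensity table
#'
#' Densitometry readout of SDS-PAGE bands over digestion time: a band-by-time
#' matrix of non-negative intensities plus a per-time multiplicative dilution
#' factor accounting for the gastric secretion that dilutes the chyme before
#' the gel normalization.
#'
#' @param intensities Numeric matrix, rows = bands (rownames are band
#'   labels, e.g. `kappa_casein`, `beta_LG`), columns = times.
#' @param times Time points, min; must include t = 0.
#' @param dilution_factor Per-time factors >= 1; defaults to 1 (no
#'   correction). Typically obtained from [dilution_factor()] on a
#'   simulator run.
#' @return An object of class `band_intensity_table`.
#' @export
band_intensity_table <- function(intensities, times,
                                 dilution_factor = rep(1, length(times))) {
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities)))
    stop("intensities must have band labels as rownames", call. = FALSE)
  if (ncol(intensities) != length(times))
    stop("one intensity column per time required", call. = FALSE)
  if (any(intensities < 0)) stop("intensities must be >= 0", call. = FALSE)
  if (!any(times == 0)) stop("t = 0 column required", call. = FALSE)
  if (length(dilution_factor) != length(times) || any(dilution_factor < 1))
    stop("dilution_factor must be >= 1, one per time", call. = FALSE)
  o <- order(times)
  structure(list(intensities = intensities[, o, drop = FALSE],
                 times = times[o], dilution_factor = dilution_factor[o]),
            class = "band_intensity_table")
}

#' Secretion dilution factor from a simulation
#'
#' Ratio of the chyme mass to its meal-derived part at time `t`, computed
#' from the simulator's mass ledger (emptying removes secreted fluid in
#' proportion to its share of the emptiable phase, so the ratio is
#' continuous across emptying events). Equals 1 at t = 0 and under zero
#' secretion flows; multiplying a measured band intensity by it undoes the
#' secretion dilution.
#'
#' @param ts A `gastric_time_series` from [run_digestion()].
#' @param t Time(s), min, within the recorded range (linear interpolation
#'   between grid points).
#' @return Dimensionless factor(s) >= 1.
#' @export
dilution_factor <- function(ts, t) {
  stopifnot(inherits(ts, "gastric_time_series"))
  st <- ts$states
  if (any(t < min(st$time)) || any(t > max(st$time)))
    stop("t outside the recorded time range", call. = FALSE)
  chyme <- stats::approx(st$time, st$chyme_mass, xout = t)$y
  secr <- stats::approx(st$time, st$secreted_in_chyme_g, xout = t)$y
  chyme / (chyme - secr)
}

#' Residual intact protein per band
#'
#' Dilution-corrected intensity ratio to the t = 0 band:
#' residual(b, t) = intensity(b, t) * dilution_factor(t) / intensity(b, 0).
#' Bands with zero t = 0 intensity are undefined (NA). Residuals above 1
#' (noise) are kept with a warning, never clamped.
#'
#' @param table A [band_intensity_table()].
#' @return Band-by-time matrix of fractions in the non-negative range; attribute
#'   `times` carries the time grid.
#' @export
residual_intact <- function(table) {
  stopifnot(inherits(table, "band_intensity_table"))
  i0 <- table$intensities[, table$times == 0]
  res <- sweep(table$intensities, 2, table$dilution_factor, `*`)
  res <- sweep(res, 1, i0, `/`)
  res[i0 == 0, ] <- NA_real_
  if (any(res > 1 + 1e-9, na.rm = TRUE))
    warning("residual fractions above 1 retained (noise)", call. = FALSE)
  attr(res, "times") <- table$times
  res
}

#' Hydrolysis half-time of one band
#'
#' First crossing of residual intact fraction = 0.5, located by linear
#' interpolation on the sampling grid. Returns a censored result when the
#' residual never falls below 0.5 within the observation window, and flags
#' the boundary case where the series already starts below 0.5.
#'
#' @param residual Residual fractions for one band (non-increasing apart
#'   from noise).
#' @param times Matching times, min.
#' @return List with `halftime` (min or NA), `censored`, `at_boundary`.
#' @export
hydrolysis_halftime <- function(residual, times) {
  if (length(residual) != length(times))
    stop("residual and times must have equal length", call. = FALSE)
  if (anyNA(residual)) return(list(halftime = NA_real_, censored = TRUE,
                                   at_boundary = FALSE))
  if (residual[1] < 0.5)
    return(list(halftime = times[1], censored = FALSE, at_boundary = TRUE))
  below <- which(residual < 0.5)
  if (!length(below))
    return(list(halftime = NA_real_, censored = TRUE, at_boundary = FALSE))
  j <- below[1]; i <- j - 1L
  ht <- times[i] + (0.5 - residual[i]) / (residual[j] - residual[i]) *
    (times[j] - times[i])
  list(halftime = ht, censored = FALSE, at_boundary = FALSE)
}
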