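#' Binned particle-size distribution
#'
#' A laser-diffraction-style volume-density distribution: strictly
#' increasing diameter bin edges and a non-negative relative volume weight
#' per bin, normalized to sum to 1 on construction. The `dispersant`
#' dialect distinguishes measurements in water (flocs intact) from
#' measurements in SDS + EDTA buffer (casein micelles and protein-mediated
#' flocs dissolved, so only coalesced droplets stay large).
#'
#' @param bin_edges Strictly increasing positive diameters, um (>= 2 edges).
#' @param volume_density Non-negative weights, one per bin.
#' @param dispersant `"water"` or `"sds_edta"`.
#' @param sample_id Sample name.
#' @param time Digestion time, min.
#' @return An object of class `psd`.
#' @export
psd <- function(bin_edges, volume_density, dispersant = c("water", "sds_edta"),
                sample_id = "", time = 0) {
  dispersant <- match.arg(dispersant)
  bin_edges <- as.numeric(bin_edges)
  volume_density <- as.numeric(volume_density)
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0) ||
      any(bin_edges <= 0))
    stop("bin_edges must be >= 2 strictly increasing positive diameters",
         call. = FALSE)
  if (length(volume_density) != length(bin_edges) - 1L)
    stop("volume_density must have one entry per bin", call. = FALSE)
  if (any(volume_density < 0) || sum(volume_density) <= 0)
    stop("volume_density must be non-negative with positive total",
         call. = FALSE)
  structure(list(bin_edges = bin_edges,
                 volume_density = volume_density / sum(volume_density),
                 dispersant = dispersant, sample_id = sample_id,
                 time = time),
            class = "psd")
}

# Geometric bin midpoints: laser-diffraction bins are log-spaced, so the
# geometric mean of the edges is the natural bin representative.
psd_midpoints <- function(x) {
  sqrt(x$bin_edges[-length(x$bin_edges)] * x$bin_edges[-1])
}

#' Volume-weighted mean diameter d4,3
#'
#' The De Brouckere mean: with number counts n_i at diameters d_i,
#' d4,3 = sum(n_i d_i^4) / sum(n_i d_i^3). On a volume-weighted
#' representation (v_i proportional to n_i d_i^3) this is the
#' volume-weighted mean of the bin midpoint diameters,
#' sum(v_i d_i) / sum(v_i).
#'
#' @param x A [psd()].
#' @return An object of class `d43_value` (fields `value` in um,
#'   `dispersant`, `time`).
#' @export
d43 <- function(x) {
  stopifnot(inherits(x, "psd"))
  mid <- psd_midpoints(x)
  v <- x$volume_density
  structure(list(value = sum(v * mid) / sum(v),
                 dispersant = x$dispersant, time = x$time,
                 sample_id = x$sample_id),
            class = "d43_value")
}

#' @export
print.d43_value <- function(x, ...) {
  cat(sprintf("d4,3 = %.4g um (%s, t = %g min)\n",
              x$value, x$dispersant, x$time))
  invisible(x)
}

as_d43 <- function(x, dispersant) {
  if (inherits(x, "d43_value")) return(x)
  structure(list(value = as.numeric(x), dispersant = dispersant, time = NA,
                 sample_id = ""), class = "d43_value")
}

index_from_d43 <- function(current, initial, dialect, label) {
  current <- as_d43(current, dialect); initial <- as_d43(initial, dialect)
  if (current$dispersant != dialect || initial$dispersant != dialect)
    stop(label, " requires d4,3 values measured in ", dialect,
         " dispersion", call. = FALSE)
  val <- (current$value - initial$value) / initial$value
  if (val < 0)
    warning(label, " is negative (", signif(val, 3),
            "); reported as-is", call. = FALSE)
  val
}

#' Aggregation index
#'
#' Normalized growth of the chyme's water-dispersed d4,3 over the
#' undigested formula's: AI = (d43_chyme - d43_initial) / d43_initial.
#' Positive AI indicates flocculation and/or coalescence of the emulsion
#' during digestion; 0 means no size change. Negative values are reported
#' with a warning, never clamped.
#'
#' @param d43_chyme,d43_initial [d43()] values (or bare numbers, taken to
#'   be water-dispersed) for the gastric chyme and the undigested formula.
#' @return Dimensionless AI.
#' @export
aggregation_index <- function(d43_chyme, d43_initial) {
  index_from_d43(d43_chyme, d43_initial, "water", "AI")
}

#' Coalescence index
#'
#' Same normalized growth computed on SDS + EDTA-dispersed measurements:
#' the buffer dissolves protein-mediated flocs, so residual size increase
#' reflects true oil-droplet coalescence (a failed interfacial layer).
#'
#' @param d43_chyme_buf,d43_initial_buf Buffer-dispersed [d43()] values
#'   (or bare numbers) for chyme and undigested formula.
#' @return Dimensionless CI.
#' @export
coalescence_index <- function(d43_chyme_buf, d43_initial_buf) {
  index_from_d43(d43_chyme_buf, d43_initial_buf, "sds_edta", "CI")
}

#' Fit a power-law flow curve
#'
#' Least-squares fit of log(viscosity) = log(K) + (n - 1) log(shear rate),
#' the Ostwald-de Waele model. Classification: Newtonian when |n - 1| is
#' within `newtonian_tol`, shear-thinning when n is below, shear-thickening
#' above.
#'
#' @param shear_rates Shear rates, 1/s (> 0, length >= 3).
#' @param viscosities Apparent viscosities, mPa s (> 0).
#' @param newtonian_tol Half-width of the Newtonian band on n.
#' @return An object of class `flow_curve_fit` with fields `K` (consistency,
#'   mPa s^n), `n` (flow index), `classification`, `r_squared`.
#' @export
fit_flow_curve <- function(shear_rates, viscosities, newtonian_tol = 0.05) {
  if (length(shear_rates) < 3L || length(shear_rates) != length(viscosities))
    stop("need >= 3 paired (shear rate, viscosity) points", call. = FALSE)
  if (any(shear_rates <= 0)) stop("shear rates must be > 0", call. = FALSE)
  if (any(viscosities <= 0)) stop("viscosities must be > 0", call. = FALSE)
  fit <- stats::lm(log(viscosities) ~ log(shear_rates))
  n <- unname(stats::coef(fit)[2]) + 1
  K <- exp(unname(stats::coef(fit)[1]))
  r2 <- r_squared(fit, log(viscosities))
  cls <- if (abs(n - 1) <= newtonian_tol) "newtonian"
  else if (n < 1) "shear_thinning" else "shear_thickening"
  structure(list(K = K, n = n, classification = cls, r_squared = r2),
            class = "flow_curve_fit")
}

#' @export
print.flow_curve_fit <- function(x, ...) {
  cat(sprintf("<flow_curve_fit> K = %.4g mPa s^n, n = %.3f (%s), R2 = %.3f\n",
              x$K, x$n, x$classification, x$r_squared))
  invisible(x)
}
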