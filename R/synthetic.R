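#' Discretized lognormal (mixture) particle-size distribution
#'
#' Builds a binned volume-density distribution from one or more lognormal
#' volume-weighted modes on a log-spaced diameter grid, the shape produced
#' by laser diffraction on milk-type emulsions.
#'
#' @param medians Volume-median diameter of each mode, um.
#' @param gsd Geometric standard deviation(s), recycled across modes.
#' @param fractions Volume fraction of each mode (summing to 1).
#' @param n_bins Number of log-spaced bins.
#' @param d_range Length-2 diameter range, um.
#' @param dispersant,sample_id,time Passed to [psd()].
#' @return A [psd()] object.
#' @export
lognormal_psd <- function(medians, gsd = 1.5, fractions = 1,
                          n_bins = 120, d_range = c(0.01, 2000),
                          dispersant = "water", sample_id = "", time = 0) {
  k <- length(medians)
  gsd <- rep_len(gsd, k); fractions <- rep_len(fractions, k)
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("mode fractions must sum to 1", call. = FALSE)
  edges <- exp(seq(log(d_range[1]), log(d_range[2]), length.out = n_bins + 1))
  dens <- rep(0, n_bins)
  for (i in seq_len(k)) {
    p <- diff(stats::plnorm(edges, meanlog = log(medians[i]),
                            sdlog = log(gsd[i])))
    dens <- dens + fractions[i] * p
  }
  psd(edges, dens, dispersant = dispersant, sample_id = sample_id,
      time = time)
}

#' Analytic calibration of lognormal modes to a target d4,3
#'
#' A lognormal volume-density mode with volume-median m and geometric SD g
#' has volume-weighted mean diameter m * exp(log(g)^2 / 2).
#' `lognormal_median_for_d43` inverts that for a single mode;
#' `calibrate_bimodal_fractions` solves the coarse-mode volume fraction w
#' so that a two-mode mixture has the target mean:
#' w = (target - mean_fine) / (mean_coarse - mean_fine).
#'
#' @param target_d43 Target volume-weighted mean, um.
#' @param gsd Geometric standard deviation.
#' @return A median (um), or a length-2 fraction vector `c(fine, coarse)`.
#' @export
lognormal_median_for_d43 <- function(target_d43, gsd = 1.5) {
  target_d43 / exp(log(gsd)^2 / 2)
}

#' @rdname lognormal_median_for_d43
#' @param medians Length-2 vector of fine and coarse mode medians, um.
#' @export
calibrate_bimodal_fractions <- function(target_d43, medians, gsd = 1.5) {
  gsd <- rep_len(gsd, 2)
  means <- medians * exp(log(gsd)^2 / 2)
  w <- (target_d43 - means[1]) / (means[2] - means[1])
  if (w < 0 || w > 1)
    stop("target d4,3 not reachable with these modes", call. = FALSE)
  c(fine = 1 - w, coarse = w)
}

#' Profile template for synthetic study generation
#'
#' Bundles everything needed to emulate one colloidal profile class:
#' initial lognormal modes in each dispersant, aggregation/coalescence
#' onsets and rates (growth of a coarse mode), retention-model parameters,
#' curd parameters, per-band hydrolysis rates, and noise levels.
#'
#' @param profile Profile class name.
#' @param initial_modes Named list (`water`, `sds_edta`) of data frames
#'   with columns `median`, `gsd`, `fraction`.
#' @param aggregation_onset,aggregation_rate Onset (min) and first-order
#'   rate (1/min) of coarse-mode growth in water dispersion.
#' @param aggregation_plateau Limiting coarse-mode volume fraction (water).
#' @param coarse_median_water Coarse (aggregate) mode median, um.
#' @param coalescence_onset,coalescence_rate,coalescence_plateau,coarse_median_buffer
#'   Same for the SDS + EDTA dialect (coalesced-droplet mode).
#' @param kappa_protein,kappa_lipid Retention-model emptying rates, 1/min.
#' @param beta Retention-model shape index.
#' @param curd_params List (`protein`, `lipid`) of `c(onset, rate, plateau)`.
#' @param band_rates Named first-order hydrolysis rates (1/min) for bands.
#' @param psd_cv,retention_sigma,intensity_cv Noise levels (multiplicative
#'   CV per PSD bin; additive percent SD on retention; multiplicative CV on
#'   band intensities).
#' @return An object of class `profile_template`.
#' @export
profile_template <- function(profile, initial_modes,
                             aggregation_onset, aggregation_rate,
                             aggregation_plateau = 0.7,
                             coarse_median_water = 40,
                             coalescence_onset, coalescence_rate,
                             coalescence_plateau = 0.25,
                             coarse_median_buffer = 5,
                             kappa_protein, kappa_lipid, beta = 1,
                             curd_params,
                             band_rates,
                             psd_cv = 0.05, retention_sigma = 2,
                             intensity_cv = 0.05) {
  for (d in c("water", "sds_edta")) {
    m <- initial_modes[[d]]
    if (is.null(m) || abs(sum(m$fraction) - 1) > 1e-8)
      stop("initial_modes$", d, " fractions must sum to 1", call. = FALSE)
  }
  stopifnot(kappa_protein > 0, kappa_lipid > 0, beta > 0,
            aggregation_onset >= 0, aggregation_rate >= 0,
            coalescence_onset >= 0, coalescence_rate >= 0)
  structure(list(profile = profile, initial_modes = initial_modes,
                 aggregation_onset = aggregation_onset,
                 aggregation_rate = aggregation_rate,
                 aggregation_plateau = aggregation_plateau,
                 coarse_median_water = coarse_median_water,
                 coalescence_onset = coalescence_onset,
                 coalescence_rate = coalescence_rate,
                 coalescence_plateau = coalescence_plateau,
                 coarse_median_buffer = coarse_median_buffer,
                 kappa_protein = kappa_protein, kappa_lipid = kappa_lipid,
                 beta = beta, curd_params = curd_params,
                 band_rates = band_rates, psd_cv = psd_cv,
                 retention_sigma = retention_sigma,
                 intensity_cv = intensity_cv),
            class = "profile_template")
}

#' Default profile templates
#'
#' Three templates emulating the colloidal behavior of the profile
#' classes: casein-dominant formulae aggregate early (from 15 min) and
#' form a high curd plateau with slow emptying (protein kappa around
#' 11e-3 /min); whey-dominant formulae aggregate late (from 80 min) with
#' little curd and faster emptying (protein kappa around 16e-3 /min);
#' biopolymer-stabilized whey formulae start multimodal (coarse mode
#' persisting in buffer, initial d4,3 above 50 um), empty protein fast
#' but lipid slowly. Initial sizes are calibrated to representative
#' undigested d4,3 values (0.78/0.66 um casein, 0.98/0.61 um whey,
#' 59.65/54.62 um biopolymer; water/buffer).
#'
#' @return Named list of [profile_template()] objects.
#' @export
default_templates <- function() {
  gsd <- 1.5
  one_mode <- function(d43_target)
    data.frame(median = lognormal_median_for_d43(d43_target, gsd),
               gsd = gsd, fraction = 1)
  bimodal <- function(d43_target, med = c(1, 200)) {
    fr <- calibrate_bimodal_fractions(d43_target, med, gsd)
    data.frame(median = med, gsd = gsd, fraction = as.numeric(fr))
  }
  band_rates_casein <- c(kappa_casein = 0.15, alpha_s_casein = 0.005,
                         beta_casein = 0.005, alpha_LA = 0.006,
                         beta_LG = 0.002)
  band_rates_whey <- c(kappa_casein = 0.15, alpha_s_casein = 0.04,
                       beta_casein = 0.04, alpha_LA = 0.04,
                       beta_LG = 0.012)
  list(
    casein_dominant = profile_template(
      profile = "casein_dominant",
      initial_modes = list(water = one_mode(0.78), sds_edta = one_mode(0.66)),
      aggregation_onset = 15, aggregation_rate = 0.02,
      aggregation_plateau = 0.7, coarse_median_water = 40,
      coalescence_onset = 40, coalescence_rate = 0.01,
      coalescence_plateau = 0.3, coarse_median_buffer = 5,
      kappa_protein = 0.011, kappa_lipid = 0.0098, beta = 1,
      curd_params = list(protein = c(onset = 30, rate = 0.06, plateau = 0.20),
                         lipid   = c(onset = 40, rate = 0.05, plateau = 0.25)),
      band_rates = band_rates_casein),
    whey_dominant = profile_template(
      profile = "whey_dominant",
      initial_modes = list(water = one_mode(0.98), sds_edta = one_mode(0.61)),
      aggregation_onset = 80, aggregation_rate = 0.02,
      aggregation_plateau = 0.7, coarse_median_water = 40,
      coalescence_onset = 100, coalescence_rate = 0.01,
      coalescence_plateau = 0.2, coarse_median_buffer = 5,
      kappa_protein = 0.0162, kappa_lipid = 0.0153, beta = 1,
      curd_params = list(protein = c(onset = 120, rate = 0.05, plateau = 0.03),
                         lipid   = c(onset = 120, rate = 0.05, plateau = 0.08)),
      band_rates = band_rates_whey),
    biopolymer_whey = profile_template(
      profile = "biopolymer_whey",
      initial_modes = list(water = bimodal(59.65), sds_edta = bimodal(54.62)),
      aggregation_onset = 80, aggregation_rate = 0.002,
      aggregation_plateau = 0.2, coarse_median_water = 300,
      coalescence_onset = 100, coalescence_rate = 0.002,
      coalescence_plateau = 0.1, coarse_median_buffer = 300,
      kappa_protein = 0.0164, kappa_lipid = 0.011, beta = 1,
      curd_params = list(protein = c(onset = 120, rate = 0.05, plateau = 0.02),
                         lipid   = c(onset = 80, rate = 0.04, plateau = 0.12)),
      band_rates = band_rates_whey)
  )
}

# Limiting coarse-mode volume fraction at time t (0 before onset, then
# saturating growth toward the plateau).
coarse_fraction_at <- function(onset, rate, plateau, t) {
  ifelse(t <= onset, 0, plateau * (1 - exp(-rate * (t - onset))))
}

#' Synthetic particle-size-distribution time course
#'
#' Generates PSDs in both dispersants over time from a template: before
#' the onset the distribution equals the initial modes (plus multiplicative
#' per-bin noise); after it, a coarse mode (aggregates in water; coalesced
#' droplets in buffer) grows at the template's rate. Buffer-dialect
#' distributions shed flocculation by construction: their coarse mode grows
#' by the (slower) coalescence parameters only.
#'
#' @param template A [profile_template()].
#' @param times Times, min.
#' @param seed Integer seed; `NULL` leaves the RNG stream alone.
#' @param sample_id Sample name stamped on each PSD.
#' @param noise Add per-bin multiplicative noise at the template's CV.
#' @return List of [psd()] objects (all times x both dispersants).
#' @export
synth_psd_series <- function(template, times, seed = NULL, sample_id = "",
                             noise = !is.null(seed)) {
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (disp in c("water", "sds_edta")) {
    m0 <- template$initial_modes[[disp]]
    if (disp == "water") {
      onset <- template$aggregation_onset; rate <- template$aggregation_rate
      plateau <- template$aggregation_plateau
      cmed <- template$coarse_median_water
    } else {
      onset <- template$coalescence_onset; rate <- template$coalescence_rate
      plateau <- template$coalescence_plateau
      cmed <- template$coarse_median_buffer
    }
    for (t in times) {
      fc <- coarse_fraction_at(onset, rate, plateau, t)
      med <- c(m0$median, cmed)
      gsd <- c(m0$gsd, 1.5)
      fr <- c(m0$fraction * (1 - fc), fc)
      keep <- fr > 0
      p <- lognormal_psd(med[keep], gsd[keep], fr[keep] / sum(fr[keep]),
                         dispersant = disp, sample_id = sample_id, time = t)
      if (noise && template$psd_cv > 0) {
        noisy <- p$volume_density *
          exp(stats::rnorm(length(p$volume_density), 0, template$psd_cv))
        p <- psd(p$bin_edges, noisy, dispersant = disp,
                 sample_id = sample_id, time = t)
      }
      out[[length(out) + 1L]] <- p
    }
  }
  out
}

#' Synthetic nutrient-retention observations
#'
#' Retention values from the modified power-exponential model with the
#' template's (kappa, beta) and alpha0 = 100, plus i.i.d. Gaussian
#' observation noise, clamped to the 0 to 110 range.
#'
#' @param template A [profile_template()].
#' @param times Strictly increasing times, min.
#' @param nutrient `"protein"` or `"lipid"`.
#' @param sigma_pct Noise SD in percentage points; defaults to the
#'   template's level. Use 0 for noiseless curves.
#' @param seed Integer seed; `NULL` leaves the RNG stream alone.
#' @param sample_id Sample name.
#' @return A [retention_curve()].
#' @export
synth_retention <- function(template, times = seq(0, 160, by = 20),
                            nutrient = c("protein", "lipid"),
                            sigma_pct = NULL, seed = NULL, sample_id = "") {
  nutrient <- match.arg(nutrient)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sigma_pct)) sigma_pct <- template$retention_sigma
  kappa <- if (nutrient == "protein") template$kappa_protein
  else template$kappa_lipid
  y <- elashoff(times, 100, kappa, template$beta)
  if (sigma_pct > 0)
    y <- pmin(pmax(y + stats::rnorm(length(y), 0, sigma_pct), 0), 110)
  retention_curve(times, y, nutrient = nutrient, sample_id = sample_id)
}

#' Synthetic gel-band intensity table
#'
#' Per-band first-order decay at the template's hydrolysis rates with
#' multiplicative log-normal noise. The kappa-casein band decays fastest
#' in every profile (near-zero residual by 15 min); beta-lactoglobulin is
#' the most pepsin-resistant.
#'
#' @param template A [profile_template()].
#' @param times Times, min (must include 0).
#' @param seed Integer seed; `NULL` leaves the RNG stream alone.
#' @param base_intensity Undigested band intensity (arbitrary units).
#' @param noise Add multiplicative log-normal noise at the template's CV.
#' @return A [band_intensity_table()].
#' @export
synth_band_table <- function(template, times = c(0, 15, 40, 80, 120, 160),
                             seed = NULL, base_intensity = 1000,
                             noise = !is.null(seed)) {
  if (!is.null(seed)) set.seed(seed)
  rates <- template$band_rates
  m <- outer(rates, times, function(r, t) base_intensity * exp(-r * t))
  if (noise && template$intensity_cv > 0)
    m <- m * exp(matrix(stats::rnorm(length(m), 0, template$intensity_cv),
                        nrow = nrow(m)))
  m[, times == 0] <- base_intensity  # reference lane measured undiluted
  rownames(m) <- names(rates)
  band_intensity_table(m, times)
}

#' Generate a complete synthetic study
#'
#' Builds a full study bundle — formula specs, retention observations,
#' PSD time courses in both dispersants, band-intensity tables and group
#' labels — for `n_per_profile` formulae in each of the three profile
#' classes. Per-sample emptying rates are jittered around the template
#' values (multiplicative, 3% CV) so samples within a group differ the
#' way products on a shelf do. Deterministic for a fixed seed.
#'
#' @param n_per_profile Formulae per profile class (>= 1).
#' @param seed Integer seed.
#' @param templates Template set, defaulting to [default_templates()].
#' @param retention_times,psd_times,band_times Observation grids, min.
#' @param sigma_pct Retention noise SD; defaults to each template's level.
#' @return An object of class `synthetic_study`: list with data frames
#'   `retention`, `psd`, `bands`, `groups`, list `formulae`, and `manifest`
#'   (true parameters per sample, seed, noise levels).
#' @export
synth_study <- function(n_per_profile = 1, seed = 1,
                        templates = default_templates(),
                        retention_times = seq(0, 160, by = 20),
                        psd_times = c(0, 15, 40, 80, 120, 160),
                        band_times = c(0, 15, 40, 80, 120, 160),
                        sigma_pct = NULL) {
  stopifnot(n_per_profile >= 1)
  set.seed(seed)
  fat_by_profile <- list(casein_dominant = 0.0420, whey_dominant = 0.0378,
                         biopolymer_whey = 0.0378)
  wc_by_profile <- list(casein_dominant = c(30, 70),
                        whey_dominant = c(60, 40),
                        biopolymer_whey = c(80, 20))
  retention <- list(); psd_rows <- list(); bands <- list()
  groups <- list(); formulae <- list(); truth <- list()
  for (prof in names(templates)) {
    tpl <- templates[[prof]]
    for (i in seq_len(n_per_profile)) {
      id <- sprintf("%s_%02d", prof, i)
      jit <- exp(stats::rnorm(2, 0, 0.03))
      tpl_i <- tpl
      tpl_i$kappa_protein <- tpl$kappa_protein * jit[1]
      tpl_i$kappa_lipid <- tpl$kappa_lipid * jit[2]
      formulae[[id]] <- formula_spec(
        name = id, protein_frac = 0.017,
        fat_frac = fat_by_profile[[prof]],
        whey_casein_ratio = wc_by_profile[[prof]], profile = prof,
        curd_fraction_params = tpl$curd_params)
      for (nut in c("protein", "lipid")) {
        rc <- synth_retention(tpl_i, retention_times, nutrient = nut,
                              sigma_pct = sigma_pct, sample_id = id)
        retention[[length(retention) + 1L]] <- data.frame(
          sample = id, nutrient = nut, time_min = rc$times,
          retained_pct = rc$retained_pct)
      }
      for (p in synth_psd_series(tpl_i, psd_times, sample_id = id,
                                 noise = TRUE)) {
        nb <- length(p$volume_density)
        psd_rows[[length(psd_rows) + 1L]] <- data.frame(
          sample = id, time_min = p$time, dispersant = p$dispersant,
          bin_lo_um = p$bin_edges[-(nb + 1L)],
          bin_hi_um = p$bin_edges[-1L],
          volume_frac = p$volume_density)
      }
      bt <- synth_band_table(tpl_i, band_times, noise = TRUE)
      bands[[length(bands) + 1L]] <- data.frame(
        sample = id,
        band = rep(rownames(bt$intensities), times = ncol(bt$intensities)),
        time_min = rep(bt$times, each = nrow(bt$intensities)),
        intensity = as.vector(bt$intensities))
      groups[[length(groups) + 1L]] <- data.frame(sample = id,
                                                  profile = prof)
      truth[[id]] <- list(profile = prof,
                          kappa_protein = tpl_i$kappa_protein,
                          kappa_lipid = tpl_i$kappa_lipid,
                          beta = tpl_i$beta,
                          aggregation_onset = tpl$aggregation_onset,
                          band_rates = as.list(tpl$band_rates))
    }
  }
  structure(list(retention = do.call(rbind, retention),
                 psd = do.call(rbind, psd_rows),
                 bands = do.call(rbind, bands),
                 groups = do.call(rbind, groups),
                 formulae = formulae,
                 manifest = list(seed = seed,
                                 n_per_profile = n_per_profile,
                                 retention_sigma = if (is.null(sigma_pct))
                                   "template" else sigma_pct,
                                 generator = "gastrosim::synth_study",
                                 truth = truth)),
            class = "synthetic_study")
}
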