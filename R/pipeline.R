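#' Run the full analysis pipeline on a study bundle
#'
#' Orchestrates the analysis stages on a validated bundle: particle-size
#' indices (d4,3 in both dispersants, AI, CI per sample and time),
#' retention-model fits per sample and nutrient (with the kappa x 10^3
#' column convention), two-stage destabilization-versus-emptying fits,
#' per-profile-group lipid-on-protein regressions, and dilution-corrected
#' band residuals. Deterministic given the inputs. Results are returned
#' and, when `out_dir` is given, written as CSVs plus a run log.
#'
#' @param bundle A bundle directory path or the list from
#'   [read_study_bundle()].
#' @param out_dir Optional output directory.
#' @param index_floor Stage-1 plateau threshold for [fit_two_stage()].
#' @param exclude_biopolymer Drop biopolymer-stabilized samples from the
#'   two-stage fits (their large initial particle size makes the
#'   normalized indices uninformative); they stay in the group
#'   regressions.
#' @param protocol Protocol used for the dilution-correction mass ledger.
#' @return List of data frames: `indices`, `fits`, `two_stage`,
#'   `regressions`, `band_residuals`.
#' @export
run_pipeline <- function(bundle, out_dir = NULL, index_floor = 0.5,
                         exclude_biopolymer = TRUE,
                         protocol = digestion_protocol()) {
  if (is.character(bundle)) bundle <- read_study_bundle(bundle)
  log_lines <- c(sprintf("pipeline run %s", format(Sys.time(), "%Y-%m-%d")),
                 sprintf("protocol: meal %g g, basal %g g, flows %g+%g mL/min, emptying %g g / %g min, total %g min",
                         protocol$meal_mass, protocol$basal_sgf_mass,
                         protocol$sgf_flow, protocol$enzyme_flow,
                         protocol$emptying_mass, protocol$emptying_interval,
                         protocol$total_time))
  groups <- stats::setNames(bundle$groups$profile, bundle$groups$sample)

  ## stage 1: particle-size indices
  indices <- compute_indices(bundle$psd)
  log_lines <- c(log_lines, sprintf("indices: %d rows", nrow(indices)))

  ## stage 2: retention fits
  fits <- fit_all_retention(bundle$retention)
  log_lines <- c(log_lines, sprintf("fits: %d curves", nrow(fits)))

  ## stage 3: two-stage fits (AI vs protein emptied, CI vs lipid emptied)
  two_stage <- list()
  for (id in unique(indices$sample)) {
    if (exclude_biopolymer && identical(groups[[id]], "biopolymer_whey"))
      next
    for (kind in c("AI", "CI")) {
      nut <- if (kind == "AI") "protein" else "lipid"
      ret <- bundle$retention[bundle$retention$sample == id &
                                bundle$retention$nutrient == nut, ]
      if (!nrow(ret)) next
      idx <- indices[indices$sample == id, ]
      emptied <- 100 - stats::approx(ret$time_min, ret$retained_pct,
                                     xout = idx$time_min, rule = 2)$y
      o <- order(emptied)
      ser <- emptying_index_series(pmin(pmax(emptied[o], 0), 100),
                                   idx[[kind]][o], index_kind = kind,
                                   nutrient = nut, sample_id = id)
      fit <- suppressWarnings(fit_two_stage(ser, index_floor = index_floor))
      two_stage[[length(two_stage) + 1L]] <- data.frame(
        sample = id, index_kind = kind, nutrient = nut,
        breakpoint_pct = fit$breakpoint_pct,
        stage2_slope = fit$stage2_slope,
        stage2_intercept_pct = fit$stage2_intercept_pct,
        r_squared_stage2 = fit$r_squared_stage2,
        n_stage1 = fit$n_stage1, n_stage2 = fit$n_stage2,
        degenerate = fit$degenerate)
    }
  }
  two_stage <- if (length(two_stage)) do.call(rbind, two_stage)
  else data.frame()

  ## stage 4: lipid-vs-protein group regressions
  emp <- emptied_pairs(bundle$retention)
  reg <- group_regressions(emp, bundle$groups)
  regressions <- do.call(rbind, lapply(names(reg), function(g)
    data.frame(group = g, slope = reg[[g]]$slope,
               intercept = reg[[g]]$intercept,
               r_squared = reg[[g]]$r_squared, n = reg[[g]]$n)))

  ## stage 5: dilution-corrected band residuals
  dil_ts <- lapply(unique(groups), function(p)
    run_digestion(formula_spec(paste0("dilution_", p), profile = p),
                  protocol))
  names(dil_ts) <- unique(groups)
  band_residuals <- list()
  for (id in unique(bundle$bands$sample)) {
    b <- bundle$bands[bundle$bands$sample == id, ]
    times <- sort(unique(b$time_min))
    bands_u <- unique(b$band)
    im <- vapply(times, function(t) {
      rows_t <- b[b$time_min == t, ]
      rows_t$intensity[match(bands_u, rows_t$band)]
    }, numeric(length(bands_u)))
    im <- matrix(im, nrow = length(bands_u),
                 dimnames = list(bands_u, NULL))
    dfac <- dilution_factor(dil_ts[[groups[[id]]]], pmin(times,
                            protocol$total_time))
    bt <- band_intensity_table(im, times, pmax(dfac, 1))
    res <- suppressWarnings(residual_intact(bt))
    band_residuals[[length(band_residuals) + 1L]] <- data.frame(
      sample = id,
      band = rep(rownames(res), times = ncol(res)),
      time_min = rep(times, each = nrow(res)),
      residual = as.vector(res))
  }
  band_residuals <- do.call(rbind, band_residuals)

  results <- list(indices = indices, fits = fits, two_stage = two_stage,
                  regressions = regressions,
                  band_residuals = band_residuals)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(results))
      utils::write.csv(results[[nm]], file.path(out_dir,
                                                paste0(nm, ".csv")),
                       row.names = FALSE, quote = FALSE)
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  invisible(results)
}

#' Particle-size indices from a long-format PSD table
#'
#' Computes d4,3 per sample, time and dispersant, and the aggregation and
#' coalescence indices relative to each sample's t = 0 measurement in the
#' matching dispersant.
#'
#' @param psd_table Data frame in the `psd` schema.
#' @return Data frame: `sample`, `time_min`, `d43_water`, `d43_buffer`,
#'   `AI`, `CI`.
#' @export
compute_indices <- function(psd_table) {
  out <- list()
  for (id in unique(psd_table$sample)) {
    sub <- psd_table[psd_table$sample == id, ]
    times <- sort(unique(sub$time_min))
    d43s <- list()
    for (disp in c("water", "sds_edta")) for (t in times) {
      rows <- sub[sub$dispersant == disp & sub$time_min == t, ]
      if (!nrow(rows)) next
      d43s[[paste(disp, t)]] <- d43(psd_from_rows(rows))$value
    }
    d0w <- d43s[[paste("water", times[1])]]
    d0b <- d43s[[paste("sds_edta", times[1])]]
    for (t in times) {
      dw <- d43s[[paste("water", t)]]
      db <- d43s[[paste("sds_edta", t)]]
      out[[length(out) + 1L]] <- data.frame(
        sample = id, time_min = t,
        d43_water = if (is.null(dw)) NA_real_ else dw,
        d43_buffer = if (is.null(db)) NA_real_ else db,
        AI = if (is.null(dw) || is.null(d0w)) NA_real_
        else (dw - d0w) / d0w,
        CI = if (is.null(db) || is.null(d0b)) NA_real_
        else (db - d0b) / d0b)
    }
  }
  do.call(rbind, out)
}

#' Fit the retention model to every curve in a retention table
#'
#' @param retention_table Data frame in the `retention` schema.
#' @param ... Passed to [fit_retention()].
#' @return Data frame: `sample`, `nutrient`, `alpha0`, `kappa`,
#'   `kappa_e3` (kappa x 10^3, the conventional reporting scale), `beta`,
#'   `rss`, `converged`.
#' @export
fit_all_retention <- function(retention_table, ...) {
  out <- list()
  for (id in unique(retention_table$sample)) {
    for (nut in unique(retention_table$nutrient[
      retention_table$sample == id])) {
      sub <- retention_table[retention_table$sample == id &
                               retention_table$nutrient == nut, ]
      sub <- sub[order(sub$time_min), ]
      crv <- retention_curve(sub$time_min, sub$retained_pct,
                             nutrient = nut, sample_id = id)
      fit <- fit_retention(crv, ...)
      out[[length(out) + 1L]] <- data.frame(
        sample = id, nutrient = nut, alpha0 = fit$alpha0,
        kappa = fit$kappa, kappa_e3 = 1000 * fit$kappa, beta = fit$beta,
        rss = fit$rss, converged = fit$converged)
    }
  }
  do.call(rbind, out)
}

# Paired percent-emptied observations (protein x, lipid y) per sample/time.
emptied_pairs <- function(retention_table) {
  p <- retention_table[retention_table$nutrient == "protein",
                       c("sample", "time_min", "retained_pct")]
  l <- retention_table[retention_table$nutrient == "lipid",
                       c("sample", "time_min", "retained_pct")]
  m <- merge(p, l, by = c("sample", "time_min"),
             suffixes = c("_protein", "_lipid"))
  data.frame(sample = m$sample,
             protein_emptied = pmin(pmax(100 - m$retained_pct_protein, 0),
                                    100),
             lipid_emptied = pmin(pmax(100 - m$retained_pct_lipid, 0), 100))
}
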