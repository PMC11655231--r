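# Shared fixtures: everything built in code, no stored data.

default_formula <- function(name = "Casein_IF_1", fat_frac = 0.0394,
                            profile = "casein_dominant", curd = NULL) {
  formula_spec(name, protein_frac = 0.017, fat_frac = fat_frac,
               whey_casein_ratio = if (profile == "casein_dominant")
                 c(20, 80) else c(60, 40),
               profile = profile, curd_fraction_params = curd)
}

# PSD whose geometric bin midpoints are exactly `mids`. Contiguous
# log-spaced bins force the midpoints into a geometric progression, so
# `mids` must have a constant ratio (any single midpoint works).
psd_at_midpoints <- function(mids, volumes, ...) {
  if (length(mids) == 1L) {
    edges <- c(mids / 1.2, mids * 1.2)
  } else {
    q <- mids[2] / mids[1]
    stopifnot(all(abs(diff(log(mids)) - log(q)) < 1e-9))
    edges <- c(mids / sqrt(q), mids[length(mids)] * sqrt(q))
  }
  psd(edges, volumes, ...)
}

noiseless_curve <- function(kappa, beta = 1, alpha0 = 100,
                            times = seq(0, 160, by = 20), ...) {
  retention_curve(times, elashoff(times, alpha0, kappa, beta), ...)
}

# Exact hinge: index 0 up to `knee` percent emptied, linear rise beyond.
hinge_series <- function(knee, slope, emptied = seq(0, 100, by = 4)) {
  idx <- pmax(0, slope * (emptied - knee))
  emptying_index_series(emptied, idx, index_kind = "AI",
                        nutrient = "protein")
}
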