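#' Formula specification
#'
#' Describes one reconstituted infant formula: macronutrient composition,
#' whey:casein ratio, its colloidal profile class, and the phenomenological
#' curd (sieve-retained coagulate) parameters that govern how much of each
#' nutrient becomes non-emptiable over digestion time.
#'
#' @param name Sample name.
#' @param protein_frac Protein mass fraction of the reconstituted formula
#'   (g/g; formulae are reconstituted to 1.7% protein, i.e. 0.017).
#' @param fat_frac Fat mass fraction (g/g).
#' @param whey_casein_ratio Numeric length-2 vector of whey and casein parts;
#'   must sum to 100 (e.g. `c(60, 40)`).
#' @param profile Colloidal profile class: `"casein_dominant"`,
#'   `"whey_dominant"` or `"biopolymer_whey"`.
#' @param curd_fraction_params Named list with elements `protein` and `lipid`,
#'   each `c(onset, rate, plateau)` for the logistic time course of the curd
#'   fraction (min, 1/min, fraction between 0 and 1). `NULL` means no curd ever
#'   forms (both fractions identically zero).
#'
#' @return An object of class `formula_spec`.
#' @export
formula_spec <- function(name,
                         protein_frac = 0.017,
                         fat_frac = 0.035,
                         whey_casein_ratio = c(60, 40),
                         profile = c("casein_dominant", "whey_dominant",
                                     "biopolymer_whey"),
                         curd_fraction_params = NULL) {
  profile <- match.arg(profile)
  stopifnot(is.character(name), length(name) == 1L)
  if (!(protein_frac > 0 && protein_frac < 1))
    stop("protein_frac must lie in (0, 1)", call. = FALSE)
  if (!(fat_frac >= 0 && fat_frac < 1))
    stop("fat_frac must lie in [0, 1)", call. = FALSE)
  if (length(whey_casein_ratio) != 2L ||
      abs(sum(whey_casein_ratio) - 100) > 1e-8)
    stop("whey_casein_ratio must be two parts summing to 100", call. = FALSE)
  if (is.null(curd_fraction_params))
    curd_fraction_params <- list(protein = c(onset = 0, rate = 0, plateau = 0),
                                 lipid   = c(onset = 0, rate = 0, plateau = 0))
  for (nut in c("protein", "lipid")) {
    p <- curd_fraction_params[[nut]]
    if (is.null(p) || length(p) != 3L)
      stop("curd_fraction_params$", nut, " must be c(onset, rate, plateau)",
           call. = FALSE)
    names(curd_fraction_params[[nut]]) <- c("onset", "rate", "plateau")
    if (p[[3]] < 0 || p[[3]] > 1)
      stop("curd plateau must lie in [0, 1]", call. = FALSE)
    if (p[[2]] < 0) stop("curd rate must be >= 0", call. = FALSE)
  }
  structure(list(name = name,
                 protein_frac = protein_frac,
                 fat_frac = fat_frac,
                 whey_casein_ratio = whey_casein_ratio,
                 profile = profile,
                 curd_fraction_params = curd_fraction_params),
            class = "formula_spec")
}

#' Dynamic gastric digestion protocol
#'
#' Operating parameters of the dynamic infant gastric simulator: meal and
#' basal simulated gastric fluid (SGF) loads, continuous secretion flows,
#' the periodic sieved-emptying schedule, and enzyme/pH settings. Defaults
#' are the standard infant protocol (100 g meal, 10 g basal SGF at pH 3.0,
#' 0.4 mL/min SGF + 0.1 mL/min enzyme solution, 22 g emptied every 20 min
#' through a 1 mm sieve, 160 min total). All streams are taken to have a
#' density of 1 g/mL, so gram and millilitre amounts are interchangeable.
#'
#' @param meal_mass Ingested formula mass, g.
#' @param basal_sgf_mass Basal SGF added at t = 0, g.
#' @param sgf_flow Continuous SGF secretion rate, mL/min.
#' @param enzyme_flow Enzyme-solution secretion rate, mL/min.
#' @param emptying_mass Mass removed per emptying event, g.
#' @param emptying_interval Minutes between emptying events; the first event
#'   fires at `t = emptying_interval`.
#' @param total_time Total digestion time, min.
#' @param sieve_cutoff Sieve pore diameter, um; particles above it (curd)
#'   never appear in emptied aliquots.
#' @param sampling_times Analysis time points, min.
#' @param pepsin_activity,lipase_activity Enzyme activities, U/mL SGF.
#' @param sgf_ph,basal_sgf_ph pH of the secreted and basal SGF.
#' @param temperature Incubation temperature, degrees C.
#'
#' @return An object of class `digestion_protocol`.
#' @export
digestion_protocol <- function(meal_mass = 100,
                               basal_sgf_mass = 10,
                               sgf_flow = 0.4,
                               enzyme_flow = 0.1,
                               emptying_mass = 22,
                               emptying_interval = 20,
                               total_time = 160,
                               sieve_cutoff = 1000,
                               sampling_times = c(15, 40, 80, 120, 160),
                               pepsin_activity = 651,
                               lipase_activity = 60,
                               sgf_ph = 2.0,
                               basal_sgf_ph = 3.0,
                               temperature = 37) {
  if (meal_mass <= 0) stop("meal_mass must be > 0", call. = FALSE)
  if (basal_sgf_mass < 0) stop("basal_sgf_mass must be >= 0", call. = FALSE)
  if (sgf_flow < 0 || enzyme_flow < 0)
    stop("secretion flows must be >= 0", call. = FALSE)
  if (emptying_mass <= 0 || emptying_interval <= 0)
    stop("emptying schedule must be positive", call. = FALSE)
  if (total_time < 0) stop("total_time must be >= 0", call. = FALSE)
  sampling_times <- sort(unique(as.numeric(sampling_times)))
  if (length(sampling_times) &&
      (min(sampling_times) < 0 || max(sampling_times) > total_time))
    stop("sampling_times must lie within [0, total_time]", call. = FALSE)
  structure(list(meal_mass = meal_mass, basal_sgf_mass = basal_sgf_mass,
                 sgf_flow = sgf_flow, enzyme_flow = enzyme_flow,
                 emptying_mass = emptying_mass,
                 emptying_interval = emptying_interval,
                 total_time = total_time, sieve_cutoff = sieve_cutoff,
                 sampling_times = sampling_times,
                 pepsin_activity = pepsin_activity,
                 lipase_activity = lipase_activity,
                 sgf_ph = sgf_ph, basal_sgf_ph = basal_sgf_ph,
                 temperature = temperature),
            class = "digestion_protocol")
}

#' Simplified gastric buffering parameters
#'
#' Parameters of the linear-titration pH model: secreted acid lowers pH in
#' proportion to the acid delivered and inversely to the protein mass still
#' in the chyme, down to a floor. The model captures the qualitative ordering
#' (more buffering protein, higher pH) and is not a fitted titration curve.
#'
#' @param buffer_capacity mmol H+ needed to lower the chyme pH by one unit
#'   per gram of protein present.
#' @param acid_delivery mmol H+ delivered per mL of secreted SGF.
#' @param min_ph pH floor (the SGF pH, 2.0, by default).
#' @param initial_ph pH of the reconstituted formula at t = 0.
#'
#' @return An object of class `buffering_params`.
#' @export
buffering_params <- function(buffer_capacity = 1.0,
                             acid_delivery = 0.08,
                             min_ph = 2.0,
                             initial_ph = 6.8) {
  if (buffer_capacity < 0 || acid_delivery < 0)
    stop("buffering parameters must be >= 0", call. = FALSE)
  structure(list(buffer_capacity = buffer_capacity,
                 acid_delivery = acid_delivery,
                 min_ph = min_ph, initial_ph = initial_ph),
            class = "buffering_params")
}

# Logistic curd fraction normalized so f(0) = 0 and f(Inf) = plateau.
curd_fraction_at <- function(params, t) {
  onset <- params[["onset"]]; rate <- params[["rate"]]
  plateau <- params[["plateau"]]
  if (plateau <= 0 || rate <= 0) return(rep(0, length(t)))
  l  <- stats::plogis(rate * (t - onset))
  l0 <- stats::plogis(rate * (0 - onset))
  plateau * (l - l0) / (1 - l0)
}

#' @export
print.formula_spec <- function(x, ...) {
  cat(sprintf("<formula_spec> %s (%s)\n", x$name, x$profile))
  cat(sprintf("  protein %.2f%%, fat %.2f%%, whey:casein %g:%g\n",
              100 * x$protein_frac, 100 * x$fat_frac,
              x$whey_casein_ratio[1], x$whey_casein_ratio[2]))
  invisible(x)
}

#' @export
print.digestion_protocol <- function(x, ...) {
  cat("<digestion_protocol>\n")
  cat(sprintf("  meal %g g + basal SGF %g g; secretion %g + %g mL/min\n",
              x$meal_mass, x$basal_sgf_mass, x$sgf_flow, x$enzyme_flow))
  cat(sprintf("  emptying %g g per %g min; sieve %g um; total %g min\n",
              x$emptying_mass, x$emptying_interval, x$sieve_cutoff,
              x$total_time))
  invisible(x)
}
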