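#' Initialize the gastric state
#'
#' Mixes the meal with the basal SGF at t = 0. The chyme mass is the meal
#' plus the basal SGF; nutrient masses come from the formula composition
#' applied to the meal mass only (basal SGF is nutrient-free); curd pools
#' start empty.
#'
#' @param formula A [formula_spec()].
#' @param protocol A [digestion_protocol()].
#' @return A one-row data frame of class `gastric_state` with columns
#'   `time`, `chyme_mass`, `protein_g`, `lipid_g`, `curd_protein_g`,
#'   `curd_lipid_g`, `secreted_in_chyme_g`, `secreted_acid_mmol`.
#' @export
init_state <- function(formula, protocol) {
  stopifnot(inherits(formula, "formula_spec"),
            inherits(protocol, "digestion_protocol"))
  st <- data.frame(time = 0,
                   chyme_mass = protocol$meal_mass + protocol$basal_sgf_mass,
                   protein_g = protocol$meal_mass * formula$protein_frac,
                   lipid_g = protocol$meal_mass * formula$fat_frac,
                   curd_protein_g = 0, curd_lipid_g = 0,
                   secreted_in_chyme_g = 0, secreted_acid_mmol = 0)
  class(st) <- c("gastric_state", "data.frame")
  st
}

#' Advance the state by continuous secretion
#'
#' Adds `dt` minutes of SGF and enzyme-solution secretion (density 1 g/mL).
#' Secretions carry no protein or lipid, so nutrient masses are unchanged;
#' the secreted-acid ledger grows with the SGF stream. `dt` must not straddle
#' an emptying event — [run_digestion()] splits the grid accordingly.
#'
#' @param state A `gastric_state`.
#' @param dt Time step, min (> 0).
#' @param protocol A [digestion_protocol()].
#' @param buffering A [buffering_params()] (for the acid ledger).
#' @return The advanced `gastric_state`.
#' @export
advance_state <- function(state, dt, protocol,
                          buffering = buffering_params()) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  sec <- (protocol$sgf_flow + protocol$enzyme_flow) * dt
  state$time <- state$time + dt
  state$chyme_mass <- state$chyme_mass + sec
  state$secreted_in_chyme_g <- state$secreted_in_chyme_g + sec
  state$secreted_acid_mmol <- state$secreted_acid_mmol +
    protocol$sgf_flow * dt * buffering$acid_delivery
  state
}

#' Sieved emptying event
#'
#' Withdraws up to `emptying_mass` g of the emptiable (sub-sieve) phase.
#' Curd pools — coagulated particles larger than the sieve cutoff — are
#' excluded from the emptiable phase and never appear in aliquots. The
#' aliquot has the emptiable phase's composition (well-mixed assumption).
#'
#' @param state A `gastric_state`.
#' @param protocol A [digestion_protocol()].
#' @return A list with elements `state` (updated) and `aliquot` (one-row
#'   data frame: `time`, `mass_g`, `protein_g`, `lipid_g`).
#' @export
empty_event <- function(state, protocol) {
  emptiable <- state$chyme_mass - state$curd_protein_g - state$curd_lipid_g
  if (emptiable <= 0) {
    warning("no emptiable mass at t = ", state$time,
            " min; empty aliquot returned", call. = FALSE)
    aliquot <- data.frame(time = state$time, mass_g = 0,
                          protein_g = 0, lipid_g = 0)
    return(list(state = state, aliquot = aliquot))
  }
  a <- min(protocol$emptying_mass, emptiable)
  frac <- a / emptiable
  p_out <- frac * (state$protein_g - state$curd_protein_g)
  l_out <- frac * (state$lipid_g - state$curd_lipid_g)
  s_out <- frac * state$secreted_in_chyme_g
  aliquot <- data.frame(time = state$time, mass_g = a,
                        protein_g = p_out, lipid_g = l_out)
  state$chyme_mass <- state$chyme_mass - a
  state$protein_g <- state$protein_g - p_out
  state$lipid_g <- state$lipid_g - l_out
  state$secreted_in_chyme_g <- state$secreted_in_chyme_g - s_out
  list(state = state, aliquot = aliquot)
}

# Reassign curd pools from the formula's logistic curd-fraction time course.
# Curd fractions apply to the nutrient mass currently in the stomach, so the
# curd fraction is monotone in the parameters but the pools shrink as the
# stomach empties.
update_curd <- function(state, formula) {
  state$curd_protein_g <- state$protein_g *
    curd_fraction_at(formula$curd_fraction_params$protein, state$time)
  state$curd_lipid_g <- state$lipid_g *
    curd_fraction_at(formula$curd_fraction_params$lipid, state$time)
  state
}

#' Run a full dynamic gastric digestion
#'
#' Integrates continuous secretion and periodic sieved emptying on a 1-min
#' base grid augmented with all emptying and sampling times. At a time point
#' that is both an emptying and a recording time the order is: secrete over
#' the preceding interval, empty, then record, so the first aliquot at
#' t = 20 min is drawn from 110 + 10 = 120 g of chyme.
#'
#' @param formula A [formula_spec()].
#' @param protocol A [digestion_protocol()].
#' @param buffering A [buffering_params()].
#' @return An object of class `gastric_time_series`: list with `states`
#'   (data frame over the whole grid, including a `ph` column),
#'   `aliquots` (one row per emptying event), `inputs` (meal, basal and
#'   total secreted masses), and the three input objects.
#' @export
run_digestion <- function(formula, protocol,
                          buffering = buffering_params()) {
  st <- init_state(formula, protocol)
  tt <- protocol$total_time
  event_times <- if (tt >= protocol$emptying_interval)
    seq(protocol$emptying_interval, tt, by = protocol$emptying_interval)
  else numeric(0)
  grid <- sort(unique(c(0, seq(0, tt, by = 1), event_times,
                        protocol$sampling_times, tt)))
  if (any(grid < 0) || any(grid > tt))
    stop("time grid outside [0, total_time]", call. = FALSE)

  states <- vector("list", length(grid))
  aliquots <- list()
  st <- update_curd(st, formula)
  states[[1]] <- st
  for (i in seq_along(grid)[-1]) {
    dt <- grid[i] - grid[i - 1]
    st <- advance_state(st, dt, protocol, buffering)
    st <- update_curd(st, formula)
    if (any(abs(grid[i] - event_times) < 1e-9)) {
      ev <- empty_event(st, protocol)
      st <- ev$state
      aliquots[[length(aliquots) + 1L]] <- ev$aliquot
    }
    states[[i]] <- st
  }
  states <- do.call(rbind, states)
  aliquots <- if (length(aliquots)) do.call(rbind, aliquots)
  else data.frame(time = numeric(0), mass_g = numeric(0),
                  protein_g = numeric(0), lipid_g = numeric(0))
  secreted_total <- (protocol$sgf_flow + protocol$enzyme_flow) * tt
  states$ph <- ph_from_state(states, buffering)
  ts <- structure(list(states = states, aliquots = aliquots,
                       inputs = list(meal = protocol$meal_mass,
                                     basal = protocol$basal_sgf_mass,
                                     secreted = secreted_total),
                       formula = formula, protocol = protocol,
                       buffering = buffering),
                  class = "gastric_time_series")
  check_mass_balance(ts)
  ts
}

# Conservation check: meal + basal + secreted-to-t = chyme(t) + emptied-to-t.
check_mass_balance <- function(ts, tol = 1e-9) {
  p <- ts$protocol
  inflow <- p$meal_mass + p$basal_sgf_mass +
    (p$sgf_flow + p$enzyme_flow) * ts$states$time
  emptied <- vapply(ts$states$time, function(t)
    sum(ts$aliquots$mass_g[ts$aliquots$time <= t + 1e-9]), numeric(1))
  err <- max(abs(inflow - ts$states$chyme_mass - emptied))
  if (err > tol)
    stop(sprintf("mass balance violated by %.3g g", err), call. = FALSE)
  invisible(err)
}

#' Nutrient retention curve from a simulation
#'
#' Percentage of the initial nutrient mass still in the stomach (emptiable
#' plus curd) over time; 100% at t = 0.
#'
#' @param ts A `gastric_time_series` from [run_digestion()].
#' @param nutrient `"protein"` or `"lipid"`.
#' @param times Optional times (min) at which to report; defaults to the
#'   full recorded grid.
#' @return A [retention_curve()].
#' @export
nutrient_retention <- function(ts, nutrient = c("protein", "lipid"),
                               times = NULL) {
  nutrient <- match.arg(nutrient)
  stopifnot(inherits(ts, "gastric_time_series"))
  col <- if (nutrient == "protein") "protein_g" else "lipid_g"
  init <- ts$states[[col]][1]
  if (init <= 0)
    stop("initial ", nutrient, " mass is zero; retention undefined",
         call. = FALSE)
  st_t <- ts$states$time
  st_m <- ts$states[[col]]
  if (is.null(times)) times <- st_t
  idx <- match(times, st_t)
  if (anyNA(idx))
    stop("requested times not on the recorded grid", call. = FALSE)
  retention_curve(times = times, retained_pct = 100 * st_m[idx] / init,
                  nutrient = nutrient, sample_id = ts$formula$name)
}

ph_from_state <- function(states, buffering) {
  prot <- states$protein_g
  drop <- ifelse(prot > 0 & buffering$buffer_capacity > 0,
                 states$secreted_acid_mmol /
                   (buffering$buffer_capacity * pmax(prot, 1e-12)),
                 ifelse(states$secreted_acid_mmol > 0, Inf, 0))
  pmax(buffering$min_ph, buffering$initial_ph - drop)
}

#' pH trajectory of a digestion run
#'
#' Linear-titration pH model: the cumulative secreted acid divided by the
#' buffering capacity of the protein still in the chyme lowers the pH from
#' its initial value down to a floor. Used for qualitative ordering only
#' (a more strongly buffered chyme stays at higher pH).
#'
#' @param ts A `gastric_time_series`.
#' @param buffering A [buffering_params()]; defaults to the one used for
#'   the run.
#' @return Data frame with columns `time` and `ph`.
#' @export
ph_trajectory <- function(ts, buffering = NULL) {
  stopifnot(inherits(ts, "gastric_time_series"))
  if (is.null(buffering)) buffering <- ts$buffering
  data.frame(time = ts$states$time,
             ph = ph_from_state(ts$states, buffering))
}

#' @export
print.gastric_time_series <- function(x, ...) {
  cat(sprintf("<gastric_time_series> %s: %d states over %g min, %d aliquots\n",
              x$formula$name, nrow(x$states), max(x$states$time),
              nrow(x$aliquots)))
  cat(sprintf("  final chyme %.2f g (protein %.3f g, lipid %.3f g)\n",
              x$states$chyme_mass[nrow(x$states)],
              x$states$protein_g[nrow(x$states)],
              x$states$lipid_g[nrow(x$states)]))
  invisible(x)
}
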