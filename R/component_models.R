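#' Droplet generation envelope
#'
#' Operating envelope of the flow-focusing droplet generator (75 um
#' orifice): oil flows 4.16-166.7 uL/min and water flows 0.2-16.66 uL/min
#' produce monodisperse droplets 95-176 um in diameter at 4-368 Hz.
#' Outside these flows the device either fails to generate stable droplets
#' or breaks its adhesive bonding / produces polydisperse doublets, so
#' out-of-range flows are errors, not extrapolations.
#'
#' Only the envelope endpoints are characterized, so the response surface
#' is a calibrated power-law surrogate on log-normalized flows: with
#' `x`, `y` the positions of the oil and water flows in `[0, 1]` on log
#' scale, diameter scales with `(1 - x)^a * y^b` (droplets shrink with more
#' oil, grow with more water) and rate with `x^c * y^d` (both flows speed
#' up generation). Exponents default to 1 and are configurable; any choice
#' maps the flow rectangle exactly onto the characterized diameter and
#' rate ranges, attaining the endpoints on the domain boundary and never
#' exceeding them.
#'
#' @param oil_flow_range,water_flow_range admissible flow ranges (uL/min).
#' @param diameter_range droplet diameter range (um).
#' @param rate_range generation rate range (Hz).
#' @param diameter_exponents,rate_exponents length-2 positive exponents of
#'   the power-law surrogate (oil axis, water axis).
#' @return An object of class `generation_envelope`.
#' @export
generation_envelope <- function(oil_flow_range = c(4.16, 166.7),
                                water_flow_range = c(0.2, 16.66),
                                diameter_range = c(95, 176),
                                rate_range = c(4, 368),
                                diameter_exponents = c(1, 1),
                                rate_exponents = c(1, 1)) {
  stopifnot(all(diameter_exponents > 0), all(rate_exponents > 0),
            oil_flow_range[1] > 0, water_flow_range[1] > 0)
  structure(
    list(oil_flow_range = oil_flow_range,
         water_flow_range = water_flow_range,
         diameter_range = diameter_range, rate_range = rate_range,
         diameter_exponents = diameter_exponents,
         rate_exponents = rate_exponents),
    class = "generation_envelope"
  )
}

#' Predict droplet diameter and generation rate from flow rates
#'
#' @param oil_flow oil (continuous phase) flow, uL/min.
#' @param water_flow water (dispersed phase) flow, uL/min.
#' @param env a [generation_envelope()].
#' @return A list with `diameter_um` and `rate_hz` (vectorized over flows).
#' @examples
#' env <- generation_envelope()
#' predict_generation(4.16, 16.66, env)$diameter_um   # 176 (largest)
#' predict_generation(166.7, 16.66, env)$rate_hz      # 368 (fastest)
#' @export
predict_generation <- function(oil_flow, water_flow,
                               env = generation_envelope()) {
  check_range <- function(v, r, what) {
    if (any(v < r[1]))
      stop(what, " flow below envelope minimum ", r[1], " uL/min",
           call. = FALSE)
    if (any(v > r[2]))
      stop(what, " flow above envelope maximum ", r[2], " uL/min",
           call. = FALSE)
  }
  check_range(oil_flow, env$oil_flow_range, "oil")
  check_range(water_flow, env$water_flow_range, "water")
  lognorm <- function(v, r) (log(v) - log(r[1])) / (log(r[2]) - log(r[1]))
  x <- lognorm(oil_flow, env$oil_flow_range)
  y <- lognorm(water_flow, env$water_flow_range)
  de <- env$diameter_exponents
  re <- env$rate_exponents
  d01 <- (1 - x)^de[1] * y^de[2]
  r01 <- x^re[1] * y^re[2]
  list(
    diameter_um = env$diameter_range[1] + diff(env$diameter_range) * d01,
    rate_hz = env$rate_range[1] + diff(env$rate_range) * r01
  )
}

#' Poisson single-cell encapsulation statistics
#'
#' Random encapsulation of a dilute cell suspension into droplets is a
#' Poisson process with mean occupancy `lambda = concentration x droplet
#' volume`. `poisson_pmf()` is the exact pmf; `encapsulation_stats()`
#' reports the probabilities that drive single-cell workflows.
#'
#' @param lambda expected cells per droplet (>= 0).
#' @param k cell count(s).
#' @return `poisson_pmf()`: `P(K = k)`.
#' @examples
#' encapsulation_stats(0.1)$p_single  # 0.1 * exp(-0.1)
#' @export
poisson_pmf <- function(lambda, k) {
  if (any(lambda < 0)) stop("`lambda` must be >= 0", call. = FALSE)
  dpois(k, lambda)
}

#' @rdname poisson_pmf
#' @return `encapsulation_stats()`: list with `p_empty` = P(0), `p_single`
#'   = P(1), and `single_fraction_of_occupied` = P(1) / (1 - P(0)) (its
#'   `lambda -> 0` limit, 1, is returned at `lambda = 0`).
#' @export
encapsulation_stats <- function(lambda) {
  if (any(lambda < 0)) stop("`lambda` must be >= 0", call. = FALSE)
  p0 <- dpois(0, lambda)
  p1 <- dpois(1, lambda)
  frac <- ifelse(lambda == 0, 1, p1 / (1 - p0))
  list(p_empty = p0, p_single = p1, single_fraction_of_occupied = frac)
}

#' @rdname poisson_pmf
#' @param n number of droplets to simulate.
#' @param seed integer seed.
#' @return `simulate_encapsulation()`: integer vector of cells per droplet.
#' @export
simulate_encapsulation <- function(lambda, n, seed = 1L) {
  if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
  withr_rng(seed, rpois(n, lambda))
}

#' Convert optical density to cell count
#'
#' Species conversion factors: E. coli 2.88e8 cells/(mL*OD),
#' S. cerevisiae 1e7 cells/(mL*OD).
#'
#' @param od optical density (>= 0).
#' @param volume_mL culture volume in mL.
#' @param species `"e_coli"` or `"s_cerevisiae"`.
#' @return Cell count.
#' @examples
#' od_to_cells(1, 1, "e_coli")  # 2.88e8
#' @export
od_to_cells <- function(od, volume_mL, species = c("e_coli", "s_cerevisiae")) {
  if (any(od < 0)) stop("`od` must be >= 0", call. = FALSE)
  species <- match.arg(species)
  factor <- c(e_coli = 2.88e8, s_cerevisiae = 1e7)[[species]]
  od * volume_mL * factor
}

#' Expected cells per droplet from a suspension
#'
#' `lambda = concentration (cells/uL) x droplet volume (uL)`.
#' `droplet_volume_uL()` converts a droplet diameter to its volume.
#'
#' @param concentration_per_uL cell concentration, cells/uL.
#' @param droplet_volume_uL droplet volume, uL.
#' @return Expected cells per droplet.
#' @export
loading_lambda <- function(concentration_per_uL, droplet_volume_uL) {
  stopifnot(concentration_per_uL >= 0, droplet_volume_uL >= 0)
  concentration_per_uL * droplet_volume_uL
}

#' @rdname loading_lambda
#' @param diameter_um droplet diameter in micrometers.
#' @export
droplet_volume_uL <- function(diameter_um) {
  (pi / 6) * diameter_um^3 * 1e-9   # 1 uL = 1e9 um^3
}

#' Picoinjection volume-change model
#'
#' Picoinjection adds (or, below equilibrium pressure, withdraws) fluid
#' from passing droplets through an electric-field-gated reservoir at
#' ~100 Hz. The characterized average droplet volume change spans -3%
#' (pressure below equilibrium) to +50% at the top of the pressure range.
#' Absolute reservoir pressures are not characterized, so pressure is
#' normalized to [-1, 1] around equilibrium and mapped piecewise-linearly:
#' f(-1) = -0.03, f(0) = 0, f(+1) = +0.50; strictly monotone.
#'
#' @param min_fraction,max_fraction volume-change fractions at the pressure
#'   extremes.
#' @param rate_hz nominal operating rate (metadata; enforced by the
#'   workflow simulator as a rate limit, not here).
#' @return An object of class `picoinjection_model`.
#' @export
picoinjection_model <- function(min_fraction = -0.03, max_fraction = 0.50,
                                rate_hz = 100) {
  stopifnot(min_fraction < 0, max_fraction > 0)
  structure(list(min_fraction = min_fraction, max_fraction = max_fraction,
                 rate_hz = rate_hz),
            class = "picoinjection_model")
}

#' @rdname picoinjection_model
#' @param pressure normalized injection pressure in [-1, 1] (0 =
#'   equilibrium).
#' @param model a `picoinjection_model`.
#' @return `picoinjection_volume_change()`: fractional droplet volume
#'   change (e.g. 0.5 = +50%).
#' @examples
#' picoinjection_volume_change(1)    #  0.50
#' picoinjection_volume_change(-1)   # -0.03
#' @export
picoinjection_volume_change <- function(pressure,
                                        model = picoinjection_model()) {
  if (any(pressure < -1 | pressure > 1))
    stop("normalized `pressure` must lie in [-1, 1]", call. = FALSE)
  ifelse(pressure >= 0, pressure * model$max_fraction,
         -pressure * model$min_fraction)
}

#' @rdname picoinjection_model
#' @param droplet_volume droplet volume before injection (any volume unit).
#' @return `picoinject()`: list with the updated `droplet_volume` and the
#'   `injected_volume` (negative when fluid is withdrawn); volume is
#'   conserved: the droplet grows by exactly the injected volume.
#' @export
picoinject <- function(droplet_volume, pressure,
                       model = picoinjection_model()) {
  dv <- droplet_volume * picoinjection_volume_change(pressure, model)
  list(droplet_volume = droplet_volume + dv, injected_volume = dv)
}

#' Dielectrophoretic sorting regime map
#'
#' Sorting outcome depends on total flow rate and electrode voltage; three
#' regimes partition the voltage axis at any flow: too little force (no
#' deflection), successful deflection (sorted), and so much force that the
#' droplet is immobilized at the electrode and coalesces with passing
#' droplets (failure). At the characterized 1 mL/hr flow, voltages below
#' 100 V give no deflection and voltages above 400 V give failure. Faster
#' droplets need more force, so both boundaries scale monotonically
#' (linearly by default) with flow rate.
#'
#' @param v_low_at_1,v_high_at_1 regime boundaries (V) at 1 mL/hr.
#' @param flow_scaling function mapping flow rate (mL/hr) to the
#'   multiplicative boundary scale; must be positive and non-decreasing.
#' @param waveform drive waveform metadata for selective actuation
#'   (amplitude V, frequency Hz).
#' @param max_sort_rate_hz characterized sensing+sorting throughput cap,
#'   droplets/second (metadata; enforced by the workflow simulator).
#' @return An object of class `sorting_regime_map`.
#' @export
sorting_regime_map <- function(v_low_at_1 = 100, v_high_at_1 = 400,
                               flow_scaling = identity,
                               waveform = list(amplitude_v = 1200,
                                               frequency_hz = 45000),
                               max_sort_rate_hz = 80) {
  stopifnot(v_low_at_1 > 0, v_high_at_1 > v_low_at_1)
  structure(list(v_low_at_1 = v_low_at_1, v_high_at_1 = v_high_at_1,
                 flow_scaling = flow_scaling, waveform = waveform,
                 max_sort_rate_hz = max_sort_rate_hz),
            class = "sorting_regime_map")
}

#' @rdname sorting_regime_map
#' @param flow_rate total flow rate, mL/hr (> 0).
#' @param voltage electrode voltage, V (>= 0).
#' @param map a `sorting_regime_map`.
#' @return `classify_sorting()`: factor with levels `no_deflection`,
#'   `sorted`, `failure` (vectorized over `voltage`).
#' @examples
#' classify_sorting(1, c(99, 250, 401))
#' @export
classify_sorting <- function(flow_rate, voltage,
                             map = sorting_regime_map()) {
  stopifnot(all(flow_rate > 0), all(voltage >= 0))
  s <- map$flow_scaling(flow_rate)
  v_low <- map$v_low_at_1 * s
  v_high <- map$v_high_at_1 * s
  out <- ifelse(voltage < v_low, "no_deflection",
                ifelse(voltage <= v_high, "sorted", "failure"))
  factor(out, levels = c("no_deflection", "sorted", "failure"))
}

#' Anchor trapping outcome model
#'
#' A droplet reaching an anchor is transiently trapped and later knocked to
#' the next anchor only within a band of flow rates: too fast and it passes
#' the anchor untrapped; too slow and it is permanently stuck. Flow is
#' normalized so the correct band defaults to [0.5, 1.5].
#'
#' @param band length-2 numeric, the trap-and-knock flow band (inclusive).
#' @return An object of class `anchor_outcome_model`.
#' @export
anchor_outcome_model <- function(band = c(0.5, 1.5)) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1])
  structure(list(band = band), class = "anchor_outcome_model")
}

#' @rdname anchor_outcome_model
#' @param flow_param normalized flow parameter (>= 0).
#' @param model an `anchor_outcome_model`.
#' @return `anchor_outcome()`: factor with levels `stuck`,
#'   `trap_and_knock`, `pass` (ordered along increasing flow).
#' @export
anchor_outcome <- function(flow_param, model = anchor_outcome_model()) {
  stopifnot(all(flow_param >= 0))
  out <- ifelse(flow_param < model$band[1], "stuck",
                ifelse(flow_param <= model$band[2], "trap_and_knock", "pass"))
  factor(out, levels = c("stuck", "trap_and_knock", "pass"))
}
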