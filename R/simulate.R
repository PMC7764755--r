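# Mean-field label propagation through tissue metabolite pools.
#
# Each pool holds a fractional MID that relaxes toward its influx MID with
# first-order turnover: f <- (1 - lambda dt) f + lambda dt f_in. Influxes
# follow the central-carbon atom map: glycolysis halves glucose into
# 3-carbon units, PDH decarboxylates pyruvate to acetyl-CoA, citrate is the
# condensation of oxaloacetate (taken equal to malate) with acetyl-CoA,
# alpha-ketoglutarate/glutamate arise by decarboxylation of citrate, and
# the 4-carbon pools mix PDH, PC and malic-enzyme routes by the flux
# fractions phi. A scalar labeled-CO2 fraction accrues from the
# decarboxylation steps and feeds the malic-enzyme m+1 route.

init_pool_state <- function() {
  pools <- lapply(POOL_CARBONS, function(n) {
    mid(c(1, rep(0, n)), fractional = TRUE)
  })
  list(pools = pools, co2 = 0)
}

#' Advance tissue pools by one time step
#'
#' One explicit Euler step of the mean-field label-propagation model. Used
#' internally by [simulate_pools()]; exposed for inspection and testing of
#' the pathway wiring.
#'
#' @param state Pool state as produced by [simulate_pools()] internals:
#'   list with `pools` (named list of fractional `mid`s) and scalar `co2`
#'   labeled fraction.
#' @param plasma_m6 Fraction of plasma glucose that is fully labeled at the
#'   step start.
#' @param params A `sirm_params` object.
#' @param tissue One of `"plasma"`, `"liver"`, `"brain"`.
#' @param dt Time step in minutes; every `lambda * dt` must be <= 1.
#' @return Updated state.
#' @export
step_pools <- function(state, plasma_m6, params, tissue, dt = params$dt) {
  lam <- params$lambda[[tissue]]
  if (is.null(lam)) stop("unknown tissue: ", tissue)
  if (any(lam * dt > 1)) stop("unstable step: lambda * dt exceeds 1")
  gamma <- params$gamma[[tissue]]
  phi <- params$phi
  p <- state$pools

  # glucose-derived 3-carbon unit, diluted by unlabeled carbon sources
  g <- gamma * plasma_m6
  d3 <- mid(c(1 - g, 0, 0, g), fractional = TRUE)

  accoa <- decarboxylate(p$pyruvate)           # PDH: 3C -> 2C + CO2
  akg <- decarboxylate(p$citrate)              # 6C -> 5C + CO2
  gdec <- decarboxylate(p$glutamate)           # 5C -> 4C + CO2
  me_in <- convolve_mids(p$pyruvate,
                         mid(c(1 - state$co2, state$co2), fractional = TRUE))
  fm_in <- mix_mids(phi, list(gdec$mid, pad_mid(p$pyruvate, 1L), me_in))
  ser_in <- pad_mid(decarboxylate(d3)$mid, 1L) # one decarboxylate/re-add cycle

  influx <- list(
    pyruvate = d3,
    lactate = p$pyruvate,
    alanine = p$pyruvate,
    serine = ser_in,
    glycine = decarboxylate(p$serine)$mid,
    gap_3pg = d3,
    citrate = convolve_mids(p$malate, accoa$mid),  # OAA equilibrated w/ malate
    glutamate = akg$mid,
    fumarate = fm_in,
    malate = fm_in,
    aspartate = p$malate,
    gaba = gdec$mid,
    pyroglutamate = p$glutamate
  )

  new_pools <- lapply(names(p), function(nm) {
    w <- lam[[nm]] * dt
    mid((1 - w) * as.numeric(p[[nm]]) + w * as.numeric(influx[[nm]]),
        fractional = TRUE)
  })
  names(new_pools) <- names(p)

  co2_src <- mean(c(accoa$lost_label_prob, akg$lost_label_prob,
                    gdec$lost_label_prob))
  co2 <- state$co2 + params$co2_rate * dt * (co2_src - state$co2)
  list(pools = new_pools, co2 = co2)
}

#' Simulate tissue metabolite pools over time
#'
#' Integrates the mean-field label-propagation model for one tissue, driven
#' by the plasma glucose m+6 time course, and records pool MIDs at the
#' requested times. Fully deterministic (noise enters only in
#' [generate_sample_table()]).
#'
#' @inheritParams step_pools
#' @param times Output times in minutes; snapped to the `dt` grid.
#' @return Object of class `pool_sim`: list with `tissue`, `times`,
#'   `states` (one pool state per output time) and `params`.
#' @export
simulate_pools <- function(params, tissue, times, dt = params$dt) {
  stopifnot(inherits(params, "sirm_params"))
  if (!tissue %in% names(params$lambda)) stop("unknown tissue: ", tissue)
  times <- sort(unique(as.numeric(times)))
  if (any(times < 0)) stop("times must be nonnegative")
  n_steps <- ceiling(max(times) / dt + 1e-9)
  record_at <- round(times / dt)
  state <- init_pool_state()
  states <- vector("list", length(times))
  if (any(record_at == 0L)) states[record_at == 0L] <- list(state)
  if (n_steps > 0) {
    step_times <- (seq_len(n_steps) - 1L) * dt
    m6 <- plasma_m6_at(params, step_times)
    for (s in seq_len(n_steps)) {
      state <- step_pools(state, m6[s], params, tissue, dt)
      hit <- which(record_at == s)
      if (length(hit)) states[hit] <- list(state)
    }
  }
  structure(list(tissue = tissue, times = times, states = states,
                 params = params),
            class = "pool_sim")
}

#' @export
print.pool_sim <- function(x, ...) {
  cat("<pool_sim> tissue ", x$tissue, ", times [",
      paste(x$times, collapse = ", "), "] min\n", sep = "")
  invisible(x)
}

# Metabolites emitted from pools: identity map plus alpha-ketoglutarate,
# which shares the equilibrated aKG/glutamate pool.
metabolite_pool <- function(metabolite_id) {
  if (metabolite_id == "alpha_ketoglutarate") return("glutamate")
  if (metabolite_id %in% names(POOL_CARBONS)) return(metabolite_id)
  NA_character_
}

#' Extract a simulated metabolite MID
#'
#' @param sim A `pool_sim`.
#' @param metabolite_id A simulated pool, `"alpha_ketoglutarate"` (shares
#'   the aKG/glutamate pool) or `"glucose"` (built from the plasma m+6
#'   fraction).
#' @param time One of the simulation's output times (minutes).
#' @return Fractional `mid`.
#' @export
pool_mid <- function(sim, metabolite_id, time) {
  stopifnot(inherits(sim, "pool_sim"))
  i <- match(time, sim$times)
  if (is.na(i)) stop("time ", time, " was not recorded in this simulation")
  if (metabolite_id == "glucose") {
    m6 <- plasma_m6_at(sim$params, time)
    return(mid(c(1 - m6, rep(0, 5), m6), metabolite_id = "glucose",
               fractional = TRUE))
  }
  pool <- metabolite_pool(metabolite_id)
  if (is.na(pool)) stop("unknown metabolite: ", metabolite_id)
  out <- sim$states[[i]]$pools[[pool]]
  attr(out, "metabolite_id") <- metabolite_id
  out
}

#' Labeled fractions of simulated metabolites
#'
#' @inheritParams pool_mid
#' @param metabolite_ids Metabolites to report (default: all simulated
#'   pools).
#' @param times Output times (default: all recorded).
#' @return Tibble with `time_min`, `metabolite_id`, `labeled_fraction`.
#' @export
pool_labeled_fractions <- function(sim,
                                   metabolite_ids = names(POOL_CARBONS),
                                   times = sim$times) {
  rows <- lapply(times, function(t) {
    tibble::tibble(
      time_min = t,
      metabolite_id = metabolite_ids,
      labeled_fraction = vapply(metabolite_ids, function(m) {
        labeled_fraction(pool_mid(sim, m, t))
      }, numeric(1))
    )
  })
  dplyr::bind_rows(rows)
}
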