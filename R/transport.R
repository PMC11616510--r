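#' Mn(II) oxidation rate
#'
#' Rate of Mn(II) loss from solution by biotic oxidation,
#' `k1 * c_mn + k2 * c_mnox * c_mn` (mol/L/s). The autocatalytic second term
#' is zero under the default `k2 = 0`; it is retained only as an off-by-default
#' option because autocatalysis at the mineral surface is negligible at the
#' circumneutral pH of the treatment. Positive values are losses from
#' solution.
#'
#' @param c_mn aqueous Mn(II) (mol/L).
#' @param params a [kinetic_params] object.
#' @param c_mnox accumulated Mn oxide (mol/L), only used when `k2 > 0`.
#' @return oxidation rate (mol/L/s).
#' @examples
#' mn_rate(mg_to_mol(19, "mn"), kinetic_params(k1 = 1.03e-4))
#' @export
mn_rate <- function(c_mn, params, c_mnox = 0) {
  if (any(c_mn < 0)) stop("negative Mn concentration")
  params$k1 * c_mn + params$k2 * c_mnox * c_mn
}

#' Zn(II) linear-driving-force sorption rate
#'
#' Net sorption rate `km * (c_zn - s_zn / kd)` (mol/L/s): positive when the
#' aqueous concentration exceeds its equilibrium value against the current
#' sorbed loading (net sorption), negative on desorption.
#'
#' @param c_zn aqueous Zn(II) (mol/L).
#' @param s_zn sorbed Zn per sorbent mass (mol/g).
#' @param params a [kinetic_params] object; requires `kd > 0` when any
#'   `s_zn > 0`.
#' @return sorption rate (mol/L/s); positive = loss from solution.
#' @export
zn_rate <- function(c_zn, s_zn, params) {
  if (any(c_zn < 0) || any(s_zn < 0)) stop("negative concentration")
  if (params$kd == 0) {
    if (any(s_zn > 0)) stop("kd = 0 with a sorbed phase present")
    return(params$km * c_zn)
  }
  params$km * (c_zn - s_zn / params$kd)
}

#' Initial state of the reactor cells
#'
#' @param config a [reactor_config].
#' @param c_mn,c_zn initial aqueous concentrations (mol/L), recycled over
#'   cells.
#' @return a `cell_state` list of per-cell vectors: aqueous `c_mn`, `c_zn`
#'   (mol/L), sorbed inventory `q_zn` (mol per litre of pore water), sorbent
#'   mass `m_solid` (g/L) and cumulative precipitated `mnox` (mol/L).
#' @export
cell_state <- function(config, c_mn = 0, c_zn = 0) {
  n <- config$n_cells
  structure(list(c_mn = rep_len(c_mn, n), c_zn = rep_len(c_zn, n),
                 q_zn = rep_len(0, n),
                 m_solid = rep_len(config$initial_sorbent_g_l, n),
                 mnox = rep_len(0, n)),
            class = "cell_state")
}

#' Advance the reaction operator over one time step
#'
#' Integrates the coupled kinetics within each cell over `dt`: exact
#' exponential decay for Mn(II) (with the autocatalyst inventory frozen per
#' substep), closed-form linear-driving-force exchange for Zn(II) with the
#' sorbent mass frozen at the substep midpoint. The aqueous/sorbed Zn exchange
#' conserves Zn per litre of pore water exactly; oxidised Mn accrues to the
#' MnO2 inventory (one mole per mole of Mn) and, if `sorbent_growth` is on, to
#' the sorbent mass.
#'
#' @param state a [cell_state].
#' @param params a [kinetic_params].
#' @param config a [reactor_config].
#' @param dt time step (s).
#' @param nsub number of substeps (the scheme is exact for frozen
#'   coefficients; substeps only refine the slow sorbent-mass coupling).
#' @return the updated `cell_state`; attribute `"clip"` carries the largest
#'   positivity clip applied (mol/L).
#' @export
step_reaction <- function(state, params, config, dt, nsub = 2L) {
  stopifnot(dt > 0)
  if (params$km > 0 && params$kd == 0 && any(state$q_zn > 0))
    stop("kd = 0 with a sorbed phase present")
  out <- react_cells_cpp(state$c_mn, state$c_zn, state$q_zn, state$m_solid,
                         state$mnox, params$k1, params$k2, params$km,
                         params$kd, config$mno2_molar_mass,
                         config$sorbent_growth, dt, as.integer(nsub))
  if (out$clip_max > 1e-12)
    warning(sprintf("positivity clip of %.3g mol/L applied", out$clip_max))
  new <- structure(out[c("c_mn", "c_zn", "q_zn", "m_solid", "mnox")],
                   class = "cell_state")
  attr(new, "clip") <- out$clip_max
  new
}

# Normalise an inlet specification to a step function in engine units:
# either c(mn=, zn=) in mg/L, or a data.frame with columns day, mn, zn (mg/L).
inlet_step_fun <- function(inlet) {
  if (is.numeric(inlet) && !is.null(names(inlet))) {
    stopifnot(all(c("mn", "zn") %in% names(inlet)))
    return(list(t = 0, mn = mg_to_mol(unname(inlet["mn"]), "mn"),
                zn = mg_to_mol(unname(inlet["zn"]), "zn")))
  }
  stopifnot(is.data.frame(inlet), all(c("day", "mn", "zn") %in% names(inlet)))
  o <- order(inlet$day)
  list(t = inlet$day[o] * SECONDS_PER_DAY,
       mn = mg_to_mol(inlet$mn[o], "mn"),
       zn = mg_to_mol(inlet$zn[o], "zn"))
}

#' Simulate the reactor at a fixed hydraulic retention time
#'
#' Operator-split forward simulation: per step `dt = HRT/n_cells` the cell
#' contents advect one cell downstream (inlet entering cell 1, the sorbent
#' staying put), optional symmetric mixing represents dispersivity, and the
#' reaction operator [step_reaction] acts in every cell. The outlet series is
#' the sequence of parcels leaving the last cell, in mg/L.
#'
#' @param config a [reactor_config].
#' @param params a [kinetic_params].
#' @param inlet constant inlet `c(mn =, zn =)` in mg/L, or a data.frame
#'   `day, mn, zn` (step-interpolated).
#' @param hrt_days hydraulic retention time of the column (days).
#' @param duration_days simulated duration (days).
#' @param state optional starting [cell_state]; default: cells filled with
#'   the initial inlet water, pristine sorbent.
#' @param t0_days simulation start time (days).
#' @param warmup_flushes number of pore-volume replacements simulated before
#'   `t0_days` (with the inlet frozen at its initial value) to relax the
#'   initial fill; budgets cover the whole run including warm-up.
#' @param snapshot_every record per-cell state every this many steps
#'   (0 = never).
#' @param nsub reaction substeps per transport step.
#' @return an object of class `mdtreat_sim` with elements `times_days`,
#'   `outlet_mn_mg_l`, `outlet_zn_mg_l`, `mno2_cum_mol_l`, final `state`,
#'   solute `budget` (mol per cell volume), and optional `snapshots`.
#' @examples
#' cfg <- reactor_config()
#' par <- kinetic_params(k1 = 1.03e-4)
#' sim <- simulate_reactor(cfg, par, c(mn = 19, zn = 0), hrt_days = 0.5,
#'                         duration_days = 3)
#' tail(sim$outlet_mn_mg_l, 1) # ~ 19 * exp(-1.03e-4 * 43200)
#' @export
simulate_reactor <- function(config, params, inlet, hrt_days, duration_days,
                             state = NULL, t0_days = 0, warmup_flushes = 0,
                             snapshot_every = 0, nsub = 2L) {
  stopifnot(inherits(config, "reactor_config"), inherits(params, "kinetic_params"),
            hrt_days > 0, duration_days > 0)
  dt <- hrt_days * SECONDS_PER_DAY / config$n_cells
  if (dt <= 0) stop("non-positive time step")
  sf <- inlet_step_fun(inlet)
  if (is.null(state)) state <- cell_state(config, c_mn = sf$mn[1], c_zn = sf$zn[1])
  n_warm <- as.integer(round(warmup_flushes * config$n_cells))
  n_main <- as.integer(round(duration_days * SECONDS_PER_DAY / dt))
  t_start <- t0_days * SECONDS_PER_DAY - n_warm * dt
  mixf <- config$dispersivity_m / (config$length_m / config$n_cells)
  run_engine(config, params, state, sf, t_start, dt, n_warm + n_main, mixf,
             snapshot_every, nsub)
}

# Shared engine call + result assembly; budgets include the supplied state as
# the initial inventory.
run_engine <- function(config, params, state, sf, t_start, dt, n_steps, mixf,
                       snapshot_every, nsub) {
  init <- state
  out <- engine_cpp(state$c_mn, state$c_zn, state$q_zn, state$m_solid,
                    state$mnox, params$k1, params$k2, params$km, params$kd,
                    config$mno2_molar_mass, config$sorbent_growth,
                    sf$t, sf$mn, sf$zn, t_start, dt, as.integer(n_steps),
                    mixf, as.integer(nsub), as.integer(snapshot_every))
  res <- structure(list(
    times_days = out$times_s / SECONDS_PER_DAY,
    outlet_mn_mg_l = mol_to_mg(out$out_mn, "mn"),
    outlet_zn_mg_l = mol_to_mg(out$out_zn, "zn"),
    mno2_cum_mol_l = out$mnox_cum,
    state = structure(out$state, class = "cell_state"),
    initial_state = init,
    budget = as.list(out$budget),
    clip_max = out$clip_max,
    config = config, params = params), class = "mdtreat_sim")
  if (!is.null(out$snapshots)) res$snapshots <- out$snapshots
  res
}

#' Simulate a campaign over a staged HRT schedule
#'
#' Runs [simulate_reactor] regime by regime, carrying the cell state (and the
#' accumulated sorbent inventory) across regime boundaries. The warm-up
#' precedes the first regime only.
#'
#' @inheritParams simulate_reactor
#' @param schedule an [hrt_schedule] (columns `start_day`, `end_day`,
#'   `hrt_days`).
#' @return an `mdtreat_sim` spanning all regimes, with whole-run budgets.
#' @export
simulate_schedule <- function(config, params, inlet, schedule,
                              warmup_flushes = 2, snapshot_every = 0, nsub = 2L) {
  sch <- as_schedule_days(schedule)
  sf <- inlet_step_fun(inlet)
  state <- cell_state(config, c_mn = sf$mn[1], c_zn = sf$zn[1])
  init <- state
  pieces <- vector("list", nrow(sch))
  budget <- c(imp_mn = 0, exp_mn = 0, imp_zn = 0, exp_zn = 0)
  clip <- 0
  for (i in seq_len(nrow(sch))) {
    dt <- sch$hrt_days[i] * SECONDS_PER_DAY / config$n_cells
    n_warm <- if (i == 1) as.integer(round(warmup_flushes * config$n_cells)) else 0L
    n_main <- as.integer(round((sch$end_day[i] - sch$start_day[i]) *
                                 SECONDS_PER_DAY / dt))
    t_start <- sch$start_day[i] * SECONDS_PER_DAY - n_warm * dt
    mixf <- config$dispersivity_m / (config$length_m / config$n_cells)
    piece <- run_engine(config, params, state, sf, t_start, dt,
                        n_warm + n_main, mixf, snapshot_every, nsub)
    state <- piece$state
    budget <- budget + unlist(piece$budget)
    clip <- max(clip, piece$clip_max)
    pieces[[i]] <- piece
  }
  res <- structure(list(
    times_days = unlist(lapply(pieces, `[[`, "times_days")),
    outlet_mn_mg_l = unlist(lapply(pieces, `[[`, "outlet_mn_mg_l")),
    outlet_zn_mg_l = unlist(lapply(pieces, `[[`, "outlet_zn_mg_l")),
    mno2_cum_mol_l = unlist(lapply(pieces, `[[`, "mno2_cum_mol_l")),
    state = state, initial_state = init,
    budget = as.list(budget), clip_max = clip,
    config = config, params = params, schedule = sch), class = "mdtreat_sim")
  res
}

#' @export
print.mdtreat_sim <- function(x, ...) {
  cat("Reactive-transport simulation\n")
  cat(sprintf("  %d outlet records over %.4g-%.4g days\n",
              length(x$times_days), min(x$times_days), max(x$times_days)))
  cat(sprintf("  final outlet: Mn %.4g mg/L, Zn %.4g mg/L\n",
              x$outlet_mn_mg_l[length(x$outlet_mn_mg_l)],
              x$outlet_zn_mg_l[length(x$outlet_zn_mg_l)]))
  bal <- mass_balance(x)
  cat(sprintf("  budget closure: Mn %.2e, Zn %.2e (relative)\n",
              bal["mn"], bal["zn"]))
  invisible(x)
}

#' @export
as.data.frame.mdtreat_sim <- function(x, ...) {
  data.frame(time_days = x$times_days, outlet_mn_mg_l = x$outlet_mn_mg_l,
             outlet_zn_mg_l = x$outlet_zn_mg_l,
             mno2_cum_mol_per_l = x$mno2_cum_mol_l)
}

#' Relative mass-balance closure of a simulation
#'
#' For each analyte: imported minus exported solute, against the change in
#' aqueous inventory plus (Mn) cumulative MnO2 precipitated or (Zn) the change
#' in sorbed inventory, per cell volume. Values are relative to the imported
#' mass and should be at machine-precision level (<= 1e-8).
#'
#' @param sim an `mdtreat_sim`.
#' @return named numeric `c(mn =, zn =)` relative closure errors.
#' @export
mass_balance <- function(sim) {
  b <- sim$budget
  s0 <- sim$initial_state; s1 <- sim$state
  d_mn <- (sum(s1$c_mn) - sum(s0$c_mn)) + (sum(s1$mnox) - sum(s0$mnox))
  d_zn <- (sum(s1$c_zn) - sum(s0$c_zn)) + (sum(s1$q_zn) - sum(s0$q_zn))
  c(mn = abs(b$imp_mn - b$exp_mn - d_mn) / max(b$imp_mn, .Machine$double.xmin),
    zn = abs(b$imp_zn - b$exp_zn - d_zn) / max(b$imp_zn, .Machine$double.xmin))
}

#' Sample the simulated outlet at arbitrary times
#'
#' Linear interpolation of the recorded outlet series; queries outside the
#' recorded window take the nearest end value.
#'
#' @param sim an `mdtreat_sim`.
#' @param days numeric times (days).
#' @param analyte `"mn"` or `"zn"`.
#' @return outlet concentrations (mg/L).
#' @export
sample_outlet <- function(sim, days, analyte = c("mn", "zn")) {
  analyte <- match.arg(analyte)
  y <- if (analyte == "mn") sim$outlet_mn_mg_l else sim$outlet_zn_mg_l
  approx(sim$times_days, y, xout = days, rule = 2)$y
}

#' Plug-flow outlet concentration under first-order decay
#'
#' Closed-form `c_in * exp(-k1 * hrt)`: the analytic oracle the dispersion-free
#' transport scheme must reproduce at steady state.
#'
#' @param c_in inlet concentration (mg/L).
#' @param k1 first-order rate constant (1/s).
#' @param hrt_days residence time (days).
#' @return outlet concentration (mg/L).
#' @examples
#' plugflow_outlet(19, 1.03e-4, 0.5) # 0.222 mg/L
#' @export
plugflow_outlet <- function(c_in, k1, hrt_days) {
  stopifnot(all(c_in >= 0), all(k1 >= 0), all(hrt_days >= 0))
  c_in * exp(-k1 * hrt_days * SECONDS_PER_DAY)
}
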