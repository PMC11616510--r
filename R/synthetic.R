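#' Specification of a synthetic monitoring campaign
#'
#' Describes a season of pilot-plant monitoring with the statistical structure
#' of the 2022 field campaign: 152 days of operation, feed Mn rising from
#' 19 mg/L to about 25 mg/L and feed Zn from 8 to 9.5 mg/L late in the season
#' (day 120), column HRT staged at 2 d (days 0-16), 0.5 d (16-113) and 0.3 d
#' (113-152), periodic sampling and multiplicative measurement noise
#' (ICP-OES-like, error proportional to concentration). The generator owns a
#' known ground truth, so parameter-recovery experiments need no field data.
#'
#' @param duration_days campaign length (days).
#' @param sampling_interval_days days between samples (first sample one
#'   interval in).
#' @param mn_levels,zn_levels feed concentration before/after `change_day`
#'   (mg/L).
#' @param change_day day of the seasonal concentration shift.
#' @param inlet_mode `"step"` (default) or `"ramp"` (linear rise over the
#'   final `duration - change_day` window).
#' @param schedule an [hrt_schedule] in numeric days; default the three-stage
#'   pilot schedule.
#' @param noise_cv coefficient of variation of the multiplicative Gaussian
#'   measurement noise.
#' @param seed integer RNG seed.
#' @param true_params ground-truth [kinetic_params]; default the
#'   pilot-calibrated set.
#' @param start_date calendar date of day 0 (for CSV emission).
#' @return a `campaign_spec` list.
#' @export
campaign_spec <- function(duration_days = 152, sampling_interval_days = 5,
                          mn_levels = c(19, 25), zn_levels = c(8, 9.5),
                          change_day = 120, inlet_mode = c("step", "ramp"),
                          schedule = NULL, noise_cv = 0.05, seed = 42L,
                          true_params = NULL, start_date = as.Date("2022-06-01")) {
  inlet_mode <- match.arg(inlet_mode)
  stopifnot(duration_days > 0, sampling_interval_days > 0,
            all(mn_levels > 0), all(zn_levels > 0), noise_cv >= 0)
  if (is.null(schedule))
    schedule <- hrt_schedule(c(0, 16, 113), c(16, 113, duration_days),
                             c(2, 0.5, 0.3), c(6, 1.5, 1))
  sch <- as_schedule_days(schedule)
  if (max(sch$end_day) < duration_days)
    stop("HRT schedule does not cover the campaign duration")
  if (is.null(true_params)) true_params <- pilot_fitted_params(quiet = TRUE)
  structure(list(duration_days = duration_days,
                 sampling_interval_days = sampling_interval_days,
                 mn_levels = mn_levels, zn_levels = zn_levels,
                 change_day = change_day, inlet_mode = inlet_mode,
                 schedule = schedule, noise_cv = noise_cv,
                 seed = as.integer(seed), true_params = true_params,
                 start_date = start_date),
            class = "campaign_spec")
}

sampling_days <- function(spec) {
  seq(spec$sampling_interval_days, spec$duration_days,
      by = spec$sampling_interval_days)
}

inlet_level <- function(spec, analyte, day) {
  lv <- if (analyte == "mn") spec$mn_levels else spec$zn_levels
  if (spec$inlet_mode == "step") {
    ifelse(day < spec$change_day, lv[1], lv[2])
  } else {
    ramp <- (day - spec$change_day) / max(spec$duration_days - spec$change_day, 1)
    lv[1] + pmin(pmax(ramp, 0), 1) * (lv[2] - lv[1])
  }
}

# Multiplicative Gaussian noise truncated at 1 % of the level, keeping every
# generated concentration strictly positive.
noisy <- function(level, cv) pmax(level * (1 + cv * rnorm(length(level))),
                                  0.01 * level)

#' Generate the feed (inlet) series of a campaign
#'
#' Step- or ramp-shaped feed levels with seeded multiplicative noise at each
#' sampling date. Uses the spec's seed, so identical specs generate identical
#' series.
#'
#' @param spec a [campaign_spec].
#' @return a `station_series`-shaped data.frame (`date`, `day`, `mn`, `zn`,
#'   `regime`) for station A0.
#' @export
generate_inlet_series <- function(spec) {
  set.seed(spec$seed)
  d <- sampling_days(spec)
  out <- data.frame(date = spec$start_date + d, day = d,
                    mn = noisy(inlet_level(spec, "mn", d), spec$noise_cv),
                    zn = noisy(inlet_level(spec, "zn", d), spec$noise_cv),
                    regime = assign_regime(d, spec$schedule),
                    stringsAsFactors = FALSE)
  attr(out, "station") <- "A0"
  class(out) <- c("station_series", "data.frame")
  out
}

#' Generate a full synthetic monitoring campaign
#'
#' Draws the noisy feed series, simulates the column outlet under the
#' ground-truth parameters and the HRT schedule (driven by the noisy feed,
#' step-interpolated between samples), and overlays independent multiplicative
#' noise on the outlet observations. The noiseless outlet (simulated under the
#' noiseless feed skeleton) is kept as ground truth.
#'
#' @param spec a [campaign_spec].
#' @param config a [reactor_config]; default [reactor_config()].
#' @return a `campaign` list: `records` (monitoring data.frame for stations
#'   A0 and A1), `schedule`, `truth` (parameters, seed, noiseless outlet
#'   series), `spec`, `config`.
#' @export
generate_campaign <- function(spec, config = reactor_config()) {
  inlet <- generate_inlet_series(spec)
  sim <- simulate_schedule(config, spec$true_params,
                           inlet[, c("day", "mn", "zn")], spec$schedule)
  d <- sampling_days(spec)
  out_mn <- sample_outlet(sim, d, "mn")
  out_zn <- sample_outlet(sim, d, "zn")
  obs_mn <- noisy(out_mn, spec$noise_cv)
  obs_zn <- noisy(out_zn, spec$noise_cv)

  skel <- data.frame(day = d, mn = inlet_level(spec, "mn", d),
                     zn = inlet_level(spec, "zn", d))
  sim0 <- simulate_schedule(config, spec$true_params, skel, spec$schedule)
  noiseless <- data.frame(day = d, mn = sample_outlet(sim0, d, "mn"),
                          zn = sample_outlet(sim0, d, "zn"))

  aux <- function(n) data.frame(
    ph = noisy(rep(7.0, n), spec$noise_cv / 5),
    do = noisy(rep(9.3, n), spec$noise_cv),
    ec = noisy(rep(1138, n), spec$noise_cv),
    orp = noisy(rep(138, n), spec$noise_cv),
    temp = noisy(rep(15, n), spec$noise_cv))
  records <- rbind(
    cbind(data.frame(date = spec$start_date + d, station = "A0",
                     mn = inlet$mn, zn = inlet$zn), aux(length(d))),
    cbind(data.frame(date = spec$start_date + d, station = "A1",
                     mn = obs_mn, zn = obs_zn), aux(length(d))))
  records <- records[order(records$date, records$station), ]
  rownames(records) <- NULL
  class(records) <- c("mdtreat_monitoring", "data.frame")

  structure(list(records = records, schedule = spec$schedule,
                 truth = list(params = spec$true_params, seed = spec$seed,
                              noiseless = noiseless),
                 spec = spec, config = config), class = "campaign")
}

#' Build the calibration dataset of a campaign
#'
#' Pairs the campaign's A0 (feed) and A1 (column outlet) series into a
#' [fit_dataset] on the campaign's schedule.
#'
#' @param campaign output of [generate_campaign].
#' @param role,label passed to [fit_dataset].
#' @param regimes optional subset of regime labels to keep.
#' @return a [fit_dataset].
#' @export
campaign_fit_dataset <- function(campaign, role = "calibration",
                                 label = "synthetic", regimes = NULL) {
  sch <- campaign$schedule
  a0 <- campaign_station(campaign, "A0")
  a1 <- campaign_station(campaign, "A1")
  if (!is.null(regimes)) a1 <- a1[a1$regime %in% regimes, ]
  fit_dataset(a0, a1, sch, role = role, label = label)
}

#' Extract one station's series from a campaign
#'
#' @param campaign output of [generate_campaign].
#' @param station `"A0"` or `"A1"`.
#' @return data.frame `day, mn, zn, regime`.
#' @export
campaign_station <- function(campaign, station) {
  rec <- campaign$records[campaign$records$station == station, ]
  sch <- as_schedule_days(campaign$schedule)
  day <- as.numeric(rec$date - campaign$spec$start_date)
  data.frame(day = day, mn = rec$mn, zn = rec$zn,
             regime = assign_regime(day, campaign$schedule),
             stringsAsFactors = FALSE)
}

#' Write a campaign to disk
#'
#' Emits `monitoring.csv` and `hrt_schedule.csv` in the documented CSV
#' schemas plus `ground_truth.json` (parameters, seed, noiseless outlet).
#'
#' @param campaign output of [generate_campaign].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- campaign$records
  csv <- data.frame(date = format(rec$date), station = rec$station,
                    mn_mg_l = rec$mn, zn_mg_l = rec$zn, ph = rec$ph,
                    do_mg_l = rec$do, ec_us_cm = rec$ec, orp_mv = rec$orp,
                    temp_c = rec$temp)
  write.csv(csv, file.path(dir, "monitoring.csv"), row.names = FALSE,
            quote = FALSE)
  sch <- campaign$schedule
  start_date <- campaign$spec$start_date
  sch_csv <- data.frame(
    start_date = format(start_date + as.numeric(sch$start)),
    end_date = format(start_date + as.numeric(sch$end)),
    hrt_a1_days = sch$hrt_a1_days, hrt_total_days = sch$hrt_total_days)
  write.csv(sch_csv, file.path(dir, "hrt_schedule.csv"), row.names = FALSE,
            quote = FALSE)
  jsonlite::write_json(
    list(params = campaign$truth$params[c("k1", "km", "kd", "k2")],
         seed = campaign$truth$seed, start_date = format(start_date),
         noiseless_outlet = campaign$truth$noiseless),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  invisible(dir)
}
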