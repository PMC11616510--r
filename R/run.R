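#' Read a run configuration file
#'
#' YAML layout: a `reactor:` block (`length_m`, `n_cells`, `porosity`,
#' `dispersivity_m`, `initial_sorbent_g_per_l`, `sorbent_growth`), a `params:`
#' block (`k1_per_s`, `km_per_s`, `kd_l_per_g`, `k2`), and a `run:` block
#' (`hrt_a1_days`, `duration_days`). Missing entries fall back to the package
#' defaults.
#'
#' @param path YAML file.
#' @return list with `config` ([reactor_config]), `params`
#'   ([kinetic_params]) and `run` (list).
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read config files")
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  r <- y$reactor %||% list()
  p <- y$params %||% list()
  cfg <- reactor_config(
    length_m = r$length_m %||% 1.6, n_cells = r$n_cells %||% 16,
    porosity = r$porosity %||% 0.48,
    dispersivity_m = r$dispersivity_m %||% 0,
    initial_sorbent_g_l = r$initial_sorbent_g_per_l %||% 1.0,
    sorbent_growth = r$sorbent_growth %||% TRUE)
  kp <- kinetic_params(k1 = p$k1_per_s %||% 0, km = p$km_per_s %||% 0,
                       kd = p$kd_l_per_g %||% 1, k2 = p$k2 %||% 0)
  list(config = cfg, params = kp, run = y$run %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_manifest <- function(path, inputs = character(), seed = NA) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  jsonlite::write_json(
    list(package = "mdtreat",
         version = as.character(utils::packageVersion("mdtreat")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         seed = seed, inputs = hashes),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Workflow commands
#'
#' Thin, logged wrappers over the package stages, mirroring the analysis
#' workflow: synthesise or load a campaign, simulate, fit, optimise the HRT,
#' summarise, run an LCF. Each writes its outputs plus a `*.manifest.json`
#' citing input hashes, package version and seed, so any run is reproducible
#' from its manifest. These functions back the command-line entry point in
#' `inst/cli/mdtreat.R`.
#'
#' @param out_dir,out output locations.
#' @param seed integer seed for the generator.
#' @param spec a [campaign_spec]; its seed is overridden by `seed` when given.
#' @param config_path YAML run configuration (see [read_run_config]).
#' @param monitoring_csv,schedule_csv input CSVs in the documented schemas.
#' @param inlet_station station treated as the column feed.
#' @param analyte which fits to run.
#' @param params_json fit report JSON carrying the `parameters` block.
#' @param hrt_days HRT grid for the compliance curve (days).
#' @param limits an [effluent_limits].
#' @param sample_path,ref_paths,e0,window spectrum file inputs for the LCF.
#' @return the principal output path, invisibly.
#' @name workflow
NULL

#' @rdname workflow
#' @export
run_synth <- function(out_dir, seed = NULL, spec = campaign_spec()) {
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  camp <- generate_campaign(spec)
  write_campaign(camp, out_dir)
  write_manifest(file.path(out_dir, "run.manifest.json"), seed = spec$seed)
  message("campaign written to ", out_dir)
  invisible(out_dir)
}

#' @rdname workflow
#' @export
run_simulate <- function(config_path, monitoring_csv, out,
                         inlet_station = "A0", schedule_csv = NULL) {
  rc <- read_run_config(config_path)
  rec <- read_monitoring_csv(monitoring_csv)
  if (!is.null(schedule_csv)) {
    sch <- read_hrt_schedule(schedule_csv)
    inlet <- station_series(rec, inlet_station, sch)
    sim <- simulate_schedule(rc$config, rc$params,
                             inlet[, c("day", "mn", "zn")], sch)
  } else {
    inlet <- station_series(rec, inlet_station)
    sim <- simulate_reactor(rc$config, rc$params,
                            inlet[, c("day", "mn", "zn")],
                            hrt_days = rc$run$hrt_a1_days %||% 0.5,
                            duration_days = rc$run$duration_days %||%
                              max(inlet$day))
  }
  write.csv(as.data.frame(sim), out, row.names = FALSE)
  write_manifest(paste0(out, ".manifest.json"),
                 inputs = c(config_path, monitoring_csv))
  invisible(out)
}

#' @rdname workflow
#' @export
run_fit <- function(config_path, monitoring_csv, schedule_csv, out,
                    analyte = c("both", "mn", "zn"), seed = NA) {
  analyte <- match.arg(analyte)
  rc <- read_run_config(config_path)
  rec <- read_monitoring_csv(monitoring_csv)
  sch <- read_hrt_schedule(schedule_csv)
  ds <- fit_dataset(station_series(rec, "A0", sch),
                    station_series(rec, "A1", sch), sch,
                    role = "calibration", label = basename(monitoring_csv))
  init <- kinetic_params(k1 = if (rc$params$k1 > 0) rc$params$k1 else 1e-5,
                         km = if (rc$params$km > 0) rc$params$km else 1e-3,
                         kd = if (rc$params$kd > 0) rc$params$kd else 1)
  fits <- list()
  if (analyte %in% c("both", "mn"))
    fits$mn <- fit_kinetics(init, ds, rc$config, "mn")
  if (analyte %in% c("both", "zn")) {
    init_zn <- if (!is.null(fits$mn)) fits$mn$params else init
    fits$zn <- fit_kinetics(init_zn, ds, rc$config, "zn")
  }
  last <- fits[[length(fits)]]
  params <- if (!is.null(fits$zn)) fits$zn$params else fits$mn$params
  if (!is.null(fits$mn)) params$k1 <- fits$mn$params$k1
  rep <- list(parameters = params[c("k1", "km", "kd", "k2")],
              fits = lapply(fits, function(f)
                list(analyte = f$analyte, objective = f$objective,
                     niter = f$niter, converged = f$converged,
                     metrics = f$metrics)),
              seed = seed, config_hash = unname(tools::md5sum(config_path)))
  jsonlite::write_json(rep, out, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  write_manifest(paste0(out, ".manifest.json"),
                 inputs = c(config_path, monitoring_csv, schedule_csv),
                 seed = seed)
  invisible(out)
}

#' @rdname workflow
#' @export
run_optimise_hrt <- function(config_path, params_json, out,
                             hrt_days = c(0.05, 0.1, 0.12, 0.2, 0.3, 0.4,
                                          0.5, 1, 2),
                             limits = effluent_limits()) {
  rc <- read_run_config(config_path)
  pj <- jsonlite::read_json(params_json)$parameters
  kp <- kinetic_params(k1 = pj$k1, km = pj$km, kd = pj$kd,
                       k2 = pj$k2 %||% 0)
  curve <- hrt_curve(rc$config, kp, hrt_days, limits = limits)
  write.csv(curve, out, row.names = FALSE)
  write_manifest(paste0(out, ".manifest.json"),
                 inputs = c(config_path, params_json))
  invisible(out)
}

#' @rdname workflow
#' @export
run_summarise <- function(monitoring_csv, schedule_csv, out) {
  rec <- read_monitoring_csv(monitoring_csv)
  sch <- read_hrt_schedule(schedule_csv)
  stations <- intersect(STATIONS, unique(rec$station))
  tabs <- lapply(stations, function(st)
    cbind(station = st, summarise_station(station_series(rec, st, sch))))
  tab <- do.call(rbind, tabs)
  if (all(c("A0", "A1") %in% stations)) {
    a0 <- station_series(rec, "A0", sch); a1 <- station_series(rec, "A1", sch)
    eff <- do.call(rbind, lapply(sch$label, function(lab)
      do.call(rbind, lapply(c("mn", "zn"), function(an) data.frame(
        station = "A0->A1", regime = lab, analyte = an,
        mean = NA, min = NA, max = NA,
        n = sum(!is.na(a1$regime) & a1$regime == lab),
        n_missing = 0,
        removal_pct = tryCatch(removal_efficiency(a0, a1, lab, an),
                               error = function(e) NA_real_))))))
    tab$removal_pct <- NA_real_
    tab <- rbind(tab, eff)
  }
  write.csv(tab, out, row.names = FALSE)
  write_manifest(paste0(out, ".manifest.json"),
                 inputs = c(monitoring_csv, schedule_csv))
  invisible(out)
}

#' @rdname workflow
#' @export
run_lcf <- function(sample_path, ref_paths, out, e0, window = c(-20, 30)) {
  sample <- read_spectrum(sample_path, e0 = e0)
  refs <- lapply(ref_paths, read_spectrum)
  res <- lcf_fit(sample, refs, window = window)
  jsonlite::write_json(list(weights = as.list(res$weights),
                            r_factor = res$r_factor, window = res$window),
                       out, auto_unbox = TRUE, digits = NA)
  write_manifest(paste0(out, ".manifest.json"),
                 inputs = c(sample_path, ref_paths))
  invisible(out)
}
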