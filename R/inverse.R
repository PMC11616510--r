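#' Bundle inlet/outlet series for calibration or validation
#'
#' One monitoring window used by the inverse model: the inlet series drives
#' the forward simulation and the observed column-outlet series is compared
#' with the simulated outlet at the observation dates.
#'
#' @param inlet inlet (feed tank) series: data.frame with `day`, `mn`, `zn`
#'   (mg/L), e.g. a [station_series].
#' @param observed observed column-outlet series, same layout.
#' @param schedule the [hrt_schedule] in force.
#' @param role `"calibration"` (enters the objective) or `"validation"`
#'   (scored only).
#' @param label free-text dataset label.
#' @return a `fit_dataset` object.
#' @export
fit_dataset <- function(inlet, observed, schedule,
                        role = c("calibration", "validation"), label = "") {
  role <- match.arg(role)
  stopifnot(all(c("day", "mn", "zn") %in% names(inlet)),
            all(c("day", "mn", "zn") %in% names(observed)))
  sch <- as_schedule_days(schedule)
  if (role == "calibration" && nrow(observed) < 3)
    stop("calibration needs >= 3 observations (", label, ")")
  inside <- observed$day >= min(sch$start_day) & observed$day <= max(sch$end_day)
  if (!all(inside))
    stop("observation dates outside the HRT schedule (", label, ")")
  structure(list(inlet = inlet[, c("day", "mn", "zn")],
                 observed = observed[, c("day", "mn", "zn")],
                 schedule = schedule, role = role, label = label),
            class = "fit_dataset")
}

#' Residuals of the forward model against observations
#'
#' Simulates the column under the dataset's inlet series and HRT schedule and
#' returns simulated-minus-observed outlet concentration (mg/L) at each
#' observation date with a non-missing value.
#'
#' @param params a [kinetic_params].
#' @param dataset a [fit_dataset].
#' @param config a [reactor_config].
#' @param analyte `"mn"` or `"zn"`.
#' @param warmup_flushes warm-up pore volumes before the schedule start.
#' @return numeric residual vector (mg/L); attribute `"obs"`/`"pred"` carry
#'   the matched series.
#' @export
residuals_kinetics <- function(params, dataset, config,
                               analyte = c("mn", "zn"), warmup_flushes = 2) {
  analyte <- match.arg(analyte)
  obs <- dataset$observed[!is.na(dataset$observed[[analyte]]), ]
  sim <- tryCatch(
    simulate_schedule(config, params, dataset$inlet, dataset$schedule,
                      warmup_flushes = warmup_flushes),
    error = function(e) stop("simulation failed for dataset '",
                             dataset$label, "': ", conditionMessage(e)))
  pred <- sample_outlet(sim, obs$day, analyte)
  r <- pred - obs[[analyte]]
  attr(r, "obs") <- obs[[analyte]]
  attr(r, "pred") <- pred
  r
}

default_bounds <- function(analyte) {
  if (analyte == "mn") list(lower = c(k1 = 1e-8), upper = c(k1 = 1e-2))
  else list(lower = c(km = 1e-6, kd = 1e-3), upper = c(km = 1, kd = 1e3))
}

#' Estimate kinetic parameters by weighted least squares
#'
#' Levenberg-Marquardt minimisation (via [minpack.lm::nls.lm]) of the weighted
#' sum of squared outlet residuals over the calibration datasets. Parameters
#' are searched in log10 space within positivity bounds: `k1` for the Mn
#' fit; `km` and `kd` jointly for the Zn fit, with `k1` held at its previously
#' fitted value because the sorbent inventory grows with Mn oxidation.
#' Validation datasets are scored with the fitted parameters but never enter
#' the objective.
#'
#' @param initial a [kinetic_params] starting point (also supplies the fixed
#'   `k1`/`k2` for the Zn fit).
#' @param datasets a [fit_dataset] or list of them.
#' @param config a [reactor_config].
#' @param analyte `"mn"` (fits `k1`) or `"zn"` (fits `km`, `kd`).
#' @param bounds list with named `lower`/`upper` vectors on the natural scale;
#'   defaults: k1 in \[1e-8, 1e-2\] 1/s, km in \[1e-6, 1\] 1/s, kd in
#'   \[1e-3, 1e3\] L/g.
#' @param weights `"uniform"` (default) or `"inverse_obs"` (1/observation).
#' @param warmup_flushes warm-up pore volumes per simulation.
#' @param control passed to [minpack.lm::nls.lm.control]; defaults enforce
#'   relative objective change < 1e-8 and parameter step < 1e-6 (log units).
#' @return an object of class `mdtreat_fit`: fitted `params`, `objective`
#'   (weighted SSE), per-dataset `metrics` (MAE, RMSE, NRMSE, R2), iteration
#'   count and convergence diagnostics.
#' @examples
#' \donttest{
#' camp <- generate_campaign(campaign_spec(seed = 1))
#' ds <- campaign_fit_dataset(camp)
#' fit <- fit_kinetics(kinetic_params(k1 = 1e-5), ds, reactor_config(), "mn")
#' fit$params$k1 # ~ 1.03e-4
#' }
#' @export
fit_kinetics <- function(initial, datasets, config, analyte = c("mn", "zn"),
                         bounds = NULL, weights = c("uniform", "inverse_obs"),
                         warmup_flushes = 2, control = NULL) {
  analyte <- match.arg(analyte)
  weights <- match.arg(weights)
  if (inherits(datasets, "fit_dataset")) datasets <- list(datasets)
  cal <- Filter(function(d) d$role == "calibration", datasets)
  if (length(cal) == 0) stop("need at least one calibration dataset")
  if (is.null(bounds)) bounds <- default_bounds(analyte)
  free <- names(bounds$lower)

  wvec <- function(obs) switch(weights,
    uniform = rep(1, length(obs)),
    inverse_obs = 1 / pmax(abs(obs), 1e-3))

  par_to_kp <- function(par) {
    v <- 10^par
    if (analyte == "mn")
      kinetic_params(k1 = v[["k1"]], km = initial$km, kd = initial$kd,
                     k2 = initial$k2)
    else
      kinetic_params(k1 = initial$k1, km = v[["km"]], kd = v[["kd"]],
                     k2 = initial$k2)
  }
  resid_all <- function(par) {
    kp <- par_to_kp(par)
    unlist(lapply(cal, function(d) {
      r <- residuals_kinetics(kp, d, config, analyte, warmup_flushes)
      sqrt(wvec(attr(r, "obs"))) * as.numeric(r)
    }))
  }

  p0 <- log10(unlist(initial[free]))
  p0 <- pmin(pmax(p0, log10(bounds$lower)), log10(bounds$upper))
  ctrl <- do.call(minpack.lm::nls.lm.control,
                  modifyList(list(ftol = 1e-8, ptol = 1e-6, maxiter = 100),
                             as.list(control)))
  lm <- minpack.lm::nls.lm(par = p0, fn = resid_all,
                           lower = log10(bounds$lower),
                           upper = log10(bounds$upper), control = ctrl)
  converged <- lm$info %in% 1:4
  if (!converged)
    warning("fit did not converge (", lm$message, "); returning best-so-far")

  params_hat <- par_to_kp(lm$par)
  metrics <- do.call(rbind, lapply(datasets, function(d) {
    r <- residuals_kinetics(params_hat, d, config, analyte, warmup_flushes)
    cbind(data.frame(label = d$label, role = d$role,
                     stringsAsFactors = FALSE),
          metric_row(attr(r, "obs"), attr(r, "pred")))
  }))
  structure(list(params = params_hat, objective = lm$deviance,
                 analyte = analyte, free = free, metrics = metrics,
                 niter = lm$niter, info = lm$info, message = lm$message,
                 converged = converged, initial = initial,
                 weights = weights), class = "mdtreat_fit")
}

#' @export
print.mdtreat_fit <- function(x, ...) {
  cat(sprintf("Inverse fit (%s, %s weights): %s\n", x$analyte, x$weights,
              if (x$converged) sprintf("converged in %d iterations", x$niter)
              else "NOT converged"))
  for (nm in x$free)
    cat(sprintf("  %s = %.4g\n", nm, x$params[[nm]]))
  cat(sprintf("  objective (weighted SSE): %.4g\n", x$objective))
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Write a fit report as JSON
#'
#' @param fit an `mdtreat_fit`.
#' @param path output path.
#' @param seed optional seed to record.
#' @param config optional [reactor_config] to record (hashed).
#' @return `path`, invisibly.
#' @export
fit_report_json <- function(fit, path, seed = NA, config = NULL) {
  rep <- list(analyte = fit$analyte,
              parameters = fit$params[c("k1", "km", "kd", "k2")],
              objective = fit$objective, niter = fit$niter,
              converged = fit$converged, metrics = fit$metrics,
              weights = fit$weights, seed = seed)
  if (!is.null(config)) rep$config_hash <- object_md5(config)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}
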