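#' Model-evaluation metric suite
#'
#' Error metrics comparing observed and predicted concentration series:
#' mean absolute error (`mae`), root-mean-square error (`rmse`), range- (or
#' mean-) normalised RMSE in percent (`nrmse`), and the coefficient of
#' efficiency `r2 = 1 - SSres/SStot` (Nash-Sutcliffe form: 1 for a perfect
#' model, 0 for the observed-mean model, negative when worse than the mean).
#'
#' @param obs,pred numeric vectors of equal length (length >= 1; >= 2 for
#'   `nrmse` and `r2`).
#' @param normalise for `nrmse`: divide RMSE by the observed `"range"`
#'   (default) or `"mean"`.
#' @return a single numeric: mg/L for `mae`/`rmse`, percent for `nrmse`,
#'   dimensionless for `r2`.
#' @examples
#' obs <- c(1, 2, 3, 4); pred <- c(1.5, 2.5, 2.5, 3.5)
#' mae(obs, pred)   # 0.5
#' rmse(obs, pred)  # 0.5
#' nrmse(obs, pred) # 16.7 %
#' r2(obs, pred)    # 0.8
#' @name metrics
NULL

check_series <- function(obs, pred, min_n = 1) {
  if (length(obs) != length(pred)) stop("obs and pred lengths differ")
  if (length(obs) < min_n) stop("need at least ", min_n, " observations")
  if (anyNA(obs) || anyNA(pred)) stop("missing values in obs/pred")
  invisible(TRUE)
}

#' @rdname metrics
#' @export
mae <- function(obs, pred) {
  check_series(obs, pred)
  mean(abs(pred - obs))
}

#' @rdname metrics
#' @export
rmse <- function(obs, pred) {
  check_series(obs, pred)
  sqrt(mean((pred - obs)^2))
}

#' @rdname metrics
#' @export
nrmse <- function(obs, pred, normalise = c("range", "mean")) {
  normalise <- match.arg(normalise)
  check_series(obs, pred, min_n = 2)
  denom <- switch(normalise, range = max(obs) - min(obs), mean = mean(obs))
  if (denom <= 0) stop("degenerate observed series (zero ", normalise, ")")
  100 * rmse(obs, pred) / denom
}

#' @rdname metrics
#' @export
r2 <- function(obs, pred) {
  check_series(obs, pred, min_n = 2)
  sstot <- sum((obs - mean(obs))^2)
  if (sstot == 0) stop("degenerate observed series (zero variance)")
  1 - sum((pred - obs)^2) / sstot
}

metric_row <- function(obs, pred) {
  data.frame(n = length(obs), mae = mae(obs, pred), rmse = rmse(obs, pred),
             nrmse_pct = if (length(obs) >= 2 && max(obs) > min(obs))
               nrmse(obs, pred) else NA_real_,
             r2 = if (length(obs) >= 2 && sd(obs) > 0) r2(obs, pred)
             else NA_real_)
}
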