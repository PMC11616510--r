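STATIONS <- c("MD", "A0", "A1", "A2")

#' Staged hydraulic-retention-time schedule
#'
#' The operating schedule of the treatment: consecutive, non-overlapping
#' regimes each holding the column HRT constant. Intervals are half-open
#' (`start <= t < end`), so every observation date belongs to exactly one
#' regime.
#'
#' @param start,end regime boundaries: `Date`s or numeric days.
#' @param hrt_a1_days HRT of the limestone column per regime (days).
#' @param hrt_total_days optional total system HRT per regime (days).
#' @param label optional regime labels; default `"hrt<value>d"`.
#' @return an `hrt_schedule` data.frame.
#' @examples
#' hrt_schedule(c(0, 16, 113), c(16, 113, 152), c(2, 0.5, 0.3))
#' @export
hrt_schedule <- function(start, end, hrt_a1_days, hrt_total_days = NA,
                         label = NULL) {
  stopifnot(length(start) == length(end),
            length(hrt_a1_days) == length(start), all(hrt_a1_days > 0))
  if (any(as.numeric(end) <= as.numeric(start)))
    stop("regime end must be after start")
  o <- order(as.numeric(start))
  start <- start[o]; end <- end[o]
  hrt_a1_days <- hrt_a1_days[o]
  hrt_total_days <- rep_len(hrt_total_days, length(start))[o]
  if (length(start) > 1 &&
      any(as.numeric(start[-1]) < as.numeric(end[-length(end)])))
    stop("regime intervals overlap")
  if (is.null(label)) label <- paste0("hrt", hrt_a1_days, "d")
  structure(data.frame(start = start, end = end, hrt_a1_days = hrt_a1_days,
                       hrt_total_days = hrt_total_days, label = label,
                       stringsAsFactors = FALSE),
            class = c("hrt_schedule", "data.frame"))
}

# Internal canonical form: numeric days relative to the schedule origin.
as_schedule_days <- function(schedule) {
  stopifnot(inherits(schedule, "hrt_schedule") || is.data.frame(schedule))
  origin <- schedule_origin(schedule)
  data.frame(start_day = as.numeric(schedule$start) - as.numeric(origin),
             end_day = as.numeric(schedule$end) - as.numeric(origin),
             hrt_days = schedule$hrt_a1_days, label = schedule$label,
             stringsAsFactors = FALSE)
}

schedule_origin <- function(schedule) schedule$start[1]

#' Assign observations to HRT regimes
#'
#' Half-open interval matching: a date belongs to a regime when
#' `start <= date < end`.
#'
#' @param dates `Date`s or numeric days on the same scale as the schedule.
#' @param schedule an [hrt_schedule].
#' @return character regime labels (`NA` outside all regimes).
#' @export
assign_regime <- function(dates, schedule) {
  d <- as.numeric(dates)
  s <- as.numeric(schedule$start); e <- as.numeric(schedule$end)
  lab <- rep(NA_character_, length(d))
  for (i in seq_along(s)) lab[d >= s[i] & d < e[i]] <- schedule$label[i]
  lab
}

#' Read a monitoring campaign CSV
#'
#' Expected header:
#' `date,station,mn_mg_l,zn_mg_l,ph,do_mg_l,ec_us_cm,orp_mv,temp_c`
#' (UTF-8, ISO-8601 dates, empty cell = missing). Unparseable numeric cells
#' become `NA`, never silent zeros.
#'
#' @param path CSV file path.
#' @return a data.frame of monitoring records (class `mdtreat_monitoring`),
#'   one row per observation.
#' @export
read_monitoring_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  strip.white = TRUE)
  mandatory <- c("date", "station", "mn_mg_l", "zn_mg_l")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols))
    stop("monitoring CSV lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0)
    return(structure(data.frame(date = as.Date(character()),
                                station = character(), mn = numeric(),
                                zn = numeric()),
                     class = c("mdtreat_monitoring", "data.frame")))
  bad <- which(!raw$station %in% STATIONS)
  if (length(bad))
    stop(sprintf("unknown station code '%s' in row %d", raw$station[bad[1]],
                 bad[1]))
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  rec <- data.frame(date = as.Date(raw$date), station = raw$station,
                    mn = num(raw$mn_mg_l), zn = num(raw$zn_mg_l),
                    stringsAsFactors = FALSE)
  for (opt in c("ph", "do_mg_l", "ec_us_cm", "orp_mv", "temp_c"))
    rec[[sub("_mg_l|_us_cm|_mv|_c$", "", opt)]] <-
      if (opt %in% names(raw)) num(raw[[opt]]) else NA_real_
  names(rec)[names(rec) == "do"] <- "do"
  if (anyNA(rec$date)) stop("unparseable date in row ", which(is.na(rec$date))[1])
  neg <- which(rec$mn < 0 | rec$zn < 0)
  if (length(neg)) stop("negative concentration in row ", neg[1])
  badph <- which(!is.na(rec$ph) & (rec$ph < 0 | rec$ph > 14))
  if (length(badph)) stop("pH outside [0, 14] in row ", badph[1])
  structure(rec, class = c("mdtreat_monitoring", "data.frame"))
}

#' Read an HRT schedule CSV
#'
#' Expected header: `start_date,end_date,hrt_a1_days,hrt_total_days`
#' (ISO-8601 dates).
#'
#' @param path CSV file path.
#' @return an [hrt_schedule].
#' @export
read_hrt_schedule <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_date", "end_date", "hrt_a1_days")
  if (!all(need %in% names(raw)))
    stop("schedule CSV lacks mandatory column(s): ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  hrt_schedule(as.Date(raw$start_date), as.Date(raw$end_date),
               as.numeric(raw$hrt_a1_days),
               if ("hrt_total_days" %in% names(raw))
                 as.numeric(raw$hrt_total_days) else NA)
}

#' Extract one station's time series
#'
#' @param records monitoring records from [read_monitoring_csv].
#' @param station one of `"MD"`, `"A0"`, `"A1"`, `"A2"`.
#' @param schedule optional [hrt_schedule]; attaches a regime label per date
#'   and a `day` column relative to the schedule origin.
#' @return a `station_series` data.frame (`date`, `day`, `mn`, `zn`,
#'   `regime`), dates strictly increasing.
#' @export
station_series <- function(records, station, schedule = NULL) {
  stopifnot(station %in% STATIONS)
  s <- records[records$station == station, , drop = FALSE]
  s <- s[order(s$date), , drop = FALSE]
  if (anyDuplicated(s$date)) stop("duplicate dates for station ", station)
  origin <- if (!is.null(schedule)) schedule_origin(schedule) else
    if (nrow(s)) s$date[1] else 0
  out <- data.frame(date = s$date,
                    day = as.numeric(s$date) - as.numeric(origin),
                    mn = s$mn, zn = s$zn, stringsAsFactors = FALSE)
  out$regime <- if (!is.null(schedule)) assign_regime(s$date, schedule) else
    NA_character_
  attr(out, "station") <- station
  class(out) <- c("station_series", "data.frame")
  out
}

#' Removal efficiency of an analyte across the treatment
#'
#' `100 * (mean inlet - mean outlet) / mean inlet` over the observations of
#' one HRT regime (the default), or the mean of date-paired differences with
#' `method = "paired"`. Efficiencies are <= 100 % and can be negative if the
#' outlet exceeds the inlet.
#'
#' @param inlet,outlet `station_series` built with the same schedule.
#' @param regime regime label (see [hrt_schedule]); `NULL` pools all regimes.
#' @param analyte `"mn"` or `"zn"`.
#' @param method `"mean"` (regime means, the reported convention) or
#'   `"paired"` (same-day differences).
#' @return removal efficiency (percent).
#' @examples
#' # inlet mean 19 mg/L, outlet mean 0.5 mg/L -> 97.4 %
#' @export
removal_efficiency <- function(inlet, outlet, regime = NULL,
                               analyte = c("mn", "zn"),
                               method = c("mean", "paired")) {
  analyte <- match.arg(analyte); method <- match.arg(method)
  pick <- function(s) {
    v <- if (is.null(regime)) s else s[!is.na(s$regime) & s$regime == regime, ]
    v[!is.na(v[[analyte]]), ]
  }
  i <- pick(inlet); o <- pick(outlet)
  if (nrow(i) == 0 || nrow(o) == 0)
    stop("insufficient data in regime ",
         if (is.null(regime)) "(all)" else regime)
  if (method == "paired") {
    common <- i$date[i$date %in% o$date]
    if (length(common) == 0) stop("no paired dates in regime")
    iv <- i[[analyte]][match(common, i$date)]
    ov <- o[[analyte]][match(common, o$date)]
    if (mean(iv) <= 0) stop("non-positive mean inlet")
    return(100 * mean((iv - ov) / iv))
  }
  mi <- mean(i[[analyte]]); mo <- mean(o[[analyte]])
  if (mi <= 0) stop("non-positive mean inlet")
  100 * (mi - mo) / mi
}

#' Mn/Zn molar ratio
#'
#' `(mn / 54.938) / (zn / 65.38)` with concentrations in mg/L.
#'
#' @param mn,zn concentrations (mg/L); `zn` must be positive.
#' @return dimensionless mole ratio.
#' @examples
#' molar_ratio(20, 9.5) # ~ 2.51
#' @export
molar_ratio <- function(mn, zn) {
  if (any(zn <= 0)) stop("zn must be positive")
  (mn / MM[["mn"]]) / (zn / MM[["zn"]])
}

#' Summarise a station series per HRT regime
#'
#' Arithmetic mean, min, max and counts per analyte and regime; missing
#' values are excluded from the statistics and counted.
#'
#' @param series a [station_series] built with a schedule.
#' @param regimes optional subset of regime labels.
#' @return a data.frame with one row per regime and analyte.
#' @export
summarise_station <- function(series, regimes = NULL) {
  if (nrow(series) == 0) stop("empty series")
  labs <- unique(series$regime[!is.na(series$regime)])
  if (!is.null(regimes)) labs <- intersect(labs, regimes)
  if (length(labs) == 0) labs <- NA_character_
  rows <- list()
  for (lab in labs) {
    sel <- if (is.na(lab)) series else series[!is.na(series$regime) &
                                                series$regime == lab, ]
    for (an in c("mn", "zn")) {
      v <- sel[[an]]
      rows[[length(rows) + 1]] <- data.frame(
        regime = lab, analyte = an,
        mean = if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE),
        min = if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE),
        max = if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE),
        n = sum(!is.na(v)), n_missing = sum(is.na(v)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
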