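# Shared fixtures: everything is generated in code, no stored data.

pilot_params <- function() kinetic_params(k1 = 1.03e-4, km = 11.43 / 3600,
                                          kd = 4.49)

pilot_schedule <- function(duration = 152)
  hrt_schedule(c(0, 16, 113), c(16, 113, duration), c(2, 0.5, 0.3))

# A station series on numeric days, optionally regime-labelled.
mk_series <- function(day, mn, zn = mn, schedule = NULL) {
  s <- data.frame(date = as.Date("2022-06-01") + day, day = day,
                  mn = mn, zn = zn,
                  regime = if (!is.null(schedule)) assign_regime(day, schedule)
                  else rep(NA_character_, length(day)),
                  stringsAsFactors = FALSE)
  class(s) <- c("station_series", "data.frame")
  s
}

write_lines_tmp <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

monitoring_header <- "date,station,mn_mg_l,zn_mg_l,ph,do_mg_l,ec_us_cm,orp_mv,temp_c"

synth_refs <- function(grid = seq(6520, 6600, by = 0.25)) {
  wl <- c(6555, 6559, 6562)
  lapply(seq_along(wl), function(i)
    synth_reference_spectrum(grid, e0 = 6550, whiteline = wl[i],
                             peak_height = 1 + 0.2 * i,
                             peak_width = 2 + 0.5 * i,
                             label = paste0("ref", i)))
}
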