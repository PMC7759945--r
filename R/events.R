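## Ingestion of raw camera-trap detection records and the rules that turn
## them into independent detection events anchored on the diel cycle.

#' Read a camera-trap detection table
#'
#' Reads a delimited file of time-stamped detection records with columns
#' `site, station, species, datetime, count` (ISO-8601 local datetimes,
#' minute precision is enough). Additional columns are carried through.
#'
#' @param path path to a CSV file.
#' @return a `data.frame` of detection records with `datetime` parsed to
#'   `POSIXct`.
#' @export
read_detections <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("site", "station", "species", "datetime", "count")
  missing <- setdiff(needed, names(rec))
  if (length(missing) > 0) {
    stop("detection table lacks column(s): ", paste(missing, collapse = ", "))
  }
  rec$datetime <- parse_datetimes(rec$datetime)
  rec
}

## Parse character datetimes; unparseable entries become NA (callers warn).
## Clock times are treated as local wall-clock; parsed in a fixed zone so
## arithmetic never crosses DST rules.
parse_datetimes <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  x <- sub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(strptime(x, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  short <- is.na(out)
  if (any(short)) {
    out[short] <- as.POSIXct(strptime(x[short], "%Y-%m-%d %H:%M",
                                      tz = "UTC"))
  }
  out
}

## decimal hour of day from POSIXct
hour_of_day <- function(t) {
  lt <- as.POSIXlt(t, tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}

#' Filter raw detections to independent events
#'
#' Collapses repeat captures into independent detection events: within each
#' (station, species) pair, a record falling less than `window_min` minutes
#' after the previously *retained* record of that pair is discarded (greedy
#' forward scan). A photo of several conspecific individuals is one event
#' (`count` is kept as metadata); a photo of two species yields one event
#' per species because records are grouped by species.
#'
#' @param records data.frame with columns `site, station, species, datetime,
#'   count` (`datetime` `POSIXct` or parseable character).
#' @param window_min independence window in minutes (default 60).
#' @return a `data.frame` of independent events, one row per event, with an
#'   added column `time_rad`, the clock time as an angle on `[0, 2*pi)`.
#'   Records with unparseable timestamps are dropped with a warning, never
#'   silently.
#' @export
#' @examples
#' rec <- data.frame(site = "A", station = "A1", species = "sp",
#'                   datetime = c("2018-01-01 08:00", "2018-01-01 08:30",
#'                                "2018-01-01 09:31"),
#'                   count = 1)
#' nrow(filter_independent_events(rec))  # 2: 08:00 and 09:31
filter_independent_events <- function(records, window_min = 60) {
  stopifnot(window_min >= 0)
  records$datetime <- parse_datetimes(records$datetime)
  bad <- is.na(records$datetime)
  if (any(bad)) {
    warning(sum(bad), " record(s) with unparseable timestamps rejected")
    records <- records[!bad, , drop = FALSE]
  }
  if (nrow(records) == 0) {
    out <- records
    out$time_rad <- numeric(0)
    return(out)
  }
  ord <- order(records$station, records$species, records$datetime)
  records <- records[ord, , drop = FALSE]
  key <- paste(records$station, records$species, sep = "\r")
  keep <- logical(nrow(records))
  tsec <- as.numeric(records$datetime)
  wsec <- window_min * 60
  last_kept <- -Inf
  last_key <- ""
  for (i in seq_len(nrow(records))) {
    if (key[i] != last_key || tsec[i] - last_kept >= wsec) {
      keep[i] <- TRUE
      last_kept <- tsec[i]
      last_key <- key[i]
    }
  }
  out <- records[keep, , drop = FALSE]
  out$time_rad <- hours_to_radians(hour_of_day(out$datetime))
  rownames(out) <- NULL
  out
}

#' Retain camera stations that detected at least one target species
#'
#' Stations that never produced an identifiable detection are dropped from
#' all downstream analyses; the retention fraction is the usual survey
#' quality figure (reported as a percentage to one decimal).
#'
#' @param records detection or event data.frame with `station` column.
#' @param deployed character vector of all deployed station ids (defaults
#'   to the stations present in `records`, in which case retention is 100%).
#' @return list with `stations` (kept ids), `n_kept`, `n_deployed`, and
#'   `retention_pct` (percent, one decimal).
#' @export
retain_informative_stations <- function(records, deployed = NULL) {
  if (is.null(deployed)) deployed <- unique(records$station)
  if (length(deployed) == 0) stop("no stations deployed")
  kept <- intersect(deployed, unique(records$station))
  if (length(kept) == 0) {
    stop("no station captured an identifiable detection; nothing to analyse")
  }
  list(stations = sort(kept),
       n_kept = length(kept),
       n_deployed = length(deployed),
       retention_pct = round_half_up(100 * length(kept) / length(deployed), 1))
}

#' Define a solar schedule for diel classification
#'
#' @param sunrise,sunset clock times in decimal hours; defaults 06:00 and
#'   18:00, the study-area average over all sites.
#' @param twilight_halfwidth half-width of the crepuscular window around
#'   sunrise and sunset, hours (default 1).
#' @return an object of class `solar_schedule`.
#' @export
solar_schedule <- function(sunrise = 6, sunset = 18, twilight_halfwidth = 1) {
  stopifnot(sunrise < sunset, twilight_halfwidth > 0)
  if (sunset - sunrise <= 2 * twilight_halfwidth ||
      24 - (sunset - sunrise) <= 2 * twilight_halfwidth) {
    stop("twilight windows overlap; shrink twilight_halfwidth")
  }
  structure(list(sunrise = sunrise, sunset = sunset,
                 twilight_halfwidth = twilight_halfwidth),
            class = "solar_schedule")
}

#' Read a per-site solar schedule table
#'
#' A CSV with columns `site, date, sunrise, sunset` (dates ISO, clock
#' times `HH:MM`). When supplied to [diel_summary_events()], each record
#' is classified against its own site and date; dates or sites missing
#' from the table fall back to the default schedule.
#'
#' @param path CSV path.
#' @param twilight_halfwidth twilight half-width in hours applied to all
#'   rows.
#' @return data.frame with `site`, `date` (Date), `sunrise`, `sunset`
#'   (decimal hours), and the twilight half-width as an attribute.
#' @export
read_solar_schedule <- function(path, twilight_halfwidth = 1) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("site", "date", "sunrise", "sunset")
  if (!all(needed %in% names(tab))) {
    stop("solar table needs columns: ", paste(needed, collapse = ", "))
  }
  hm <- function(x) {
    p <- strsplit(as.character(x), ":", fixed = TRUE)
    vapply(p, function(v) as.numeric(v[1]) + as.numeric(v[2]) / 60,
           numeric(1))
  }
  out <- data.frame(site = tab$site, date = as.Date(tab$date),
                    sunrise = hm(tab$sunrise), sunset = hm(tab$sunset),
                    stringsAsFactors = FALSE)
  if (any(out$sunrise >= out$sunset)) stop("sunrise must precede sunset")
  attr(out, "twilight_halfwidth") <- twilight_halfwidth
  out
}

#' Per-species diel summaries for an event table
#'
#' Classifies every species in an event table. `solar` may be a single
#' [solar_schedule()] (applied to all events) or a per-site, per-date
#' table from [read_solar_schedule()], in which case each record is
#' classified against its own site and date and unmatched records fall
#' back to `default_solar`.
#'
#' @param events event data.frame from [filter_independent_events()].
#' @param solar a `solar_schedule` or a solar table.
#' @param default_solar fallback schedule for records without a table row.
#' @return data.frame with one row per species: counts, percentages and
#'   category as in [classify_diel()].
#' @export
diel_summary_events <- function(events, solar = solar_schedule(),
                                default_solar = solar_schedule()) {
  per_record <- is.data.frame(solar)
  if (per_record) {
    key <- paste(events$site, as.Date(events$datetime, tz = "UTC"))
    idx <- match(key, paste(solar$site, solar$date))
    sunrise <- ifelse(is.na(idx), default_solar$sunrise, solar$sunrise[idx])
    sunset <- ifelse(is.na(idx), default_solar$sunset, solar$sunset[idx])
    tw <- attr(solar, "twilight_halfwidth") %||%
      default_solar$twilight_halfwidth
  }
  do.call(rbind, lapply(sort(unique(events$species)), function(sp) {
    sel <- events$species == sp
    if (per_record) {
      h <- radians_to_hours(events$time_rad[sel])
      sr <- sunrise[sel]; ss <- sunset[sel]
      diurnal <- h >= sr & h < ss
      twl <- (abs(h - sr) < tw) | (abs(h - ss) < tw) |
        (abs(h - 24 - sr) < tw) | (abs(h + 24 - ss) < tw)
      s <- diel_summary_from_counts(sum(sel), sum(!diurnal), sum(twl))
    } else {
      s <- classify_diel(events$time_rad[sel], solar)
    }
    data.frame(species = sp, n = s$n_total, n_nocturnal = s$n_nocturnal,
               n_twilight = s$n_twilight, pct_diurnal = s$pct_diurnal,
               pct_nocturnal = s$pct_nocturnal,
               pct_twilight = s$pct_twilight, category = s$category,
               stringsAsFactors = FALSE)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify diel activity of an event series
#'
#' An event is diurnal if its clock time falls in `[sunrise, sunset)` and
#' nocturnal otherwise; it is additionally crepuscular (twilight) if it
#' falls within `twilight_halfwidth` hours of sunrise or sunset. The
#' diel category follows the nocturnal fraction \eqn{p_n}:
#' strongly diurnal (\eqn{p_n \le 0.10}), mostly diurnal
#' (\eqn{0.10 < p_n < 0.30}), cathemeral (\eqn{0.30 \le p_n < 0.70}),
#' mostly nocturnal (\eqn{0.70 \le p_n < 0.90}) and strongly nocturnal
#' (\eqn{p_n \ge 0.90}); the "at least 90%" tails are inclusive.
#'
#' @param times event clock times as angles in radians on `[0, 2*pi)`.
#' @param solar a [solar_schedule()].
#' @return a `diel_summary` list: counts (`n_total`, `n_diurnal`,
#'   `n_nocturnal`, `n_twilight`), percentages (integer, rounded half-up),
#'   and `category`.
#' @export
#' @examples
#' s <- classify_diel(hours_to_radians(c(8, 10, 14, 22)))
#' s$category
classify_diel <- function(times, solar = solar_schedule()) {
  if (length(times) == 0) stop("no events: diel category undefined")
  h <- radians_to_hours(times)
  diurnal <- h >= solar$sunrise & h < solar$sunset
  tw <- solar$twilight_halfwidth
  twilight <- (abs(h - solar$sunrise) < tw) | (abs(h - solar$sunset) < tw) |
    (abs(h - 24 - solar$sunrise) < tw) | (abs(h + 24 - solar$sunset) < tw)
  diel_summary_from_counts(n_total = length(h),
                           n_nocturnal = sum(!diurnal),
                           n_twilight = sum(twilight))
}

#' Diel summary from event counts
#'
#' The arithmetic backbone of [classify_diel()], usable directly when only
#' tabulated counts are available (e.g. published totals). Twilight events
#' straddle the day/night boundary so `n_twilight` overlaps both counts;
#' percentages use total events as denominator.
#'
#' @param n_total total independent events.
#' @param n_nocturnal events between sunset and sunrise.
#' @param n_twilight events within the crepuscular windows (default `NA`).
#' @return a `diel_summary` list; see [classify_diel()].
#' @export
#' @examples
#' diel_summary_from_counts(2562, 2562 - 2474, 666)  # 97% diurnal, 26% twilight
diel_summary_from_counts <- function(n_total, n_nocturnal, n_twilight = NA) {
  stopifnot(n_total >= 1, n_nocturnal >= 0, n_nocturnal <= n_total)
  p_n <- n_nocturnal / n_total
  category <- if (p_n <= 0.10) "strongly_diurnal"
  else if (p_n < 0.30) "mostly_diurnal"
  else if (p_n < 0.70) "cathemeral"
  else if (p_n < 0.90) "mostly_nocturnal"
  else "strongly_nocturnal"
  structure(list(
    n_total = n_total,
    n_diurnal = n_total - n_nocturnal,
    n_nocturnal = n_nocturnal,
    n_twilight = n_twilight,
    pct_diurnal = round_half_up(100 * (1 - p_n)),
    pct_nocturnal = round_half_up(100 * p_n),
    pct_twilight = if (is.na(n_twilight)) NA_real_ else
      round_half_up(100 * n_twilight / n_total),
    category = category
  ), class = "diel_summary")
}

#' @export
print.diel_summary <- function(x, ...) {
  cat(sprintf("Diel summary: %d events, %d%% diurnal / %d%% nocturnal",
              x$n_total, x$pct_diurnal, x$pct_nocturnal))
  if (!is.na(x$n_twilight)) cat(sprintf(", %d%% twilight", x$pct_twilight))
  cat(sprintf("\nCategory: %s\n", gsub("_", " ", x$category)))
  invisible(x)
}

#' Extract the circular time series of one species from an event table
#'
#' @param events event data.frame from [filter_independent_events()].
#' @param species species label.
#' @return list with `species`, `times` (radians), `stations`, `n`.
#' @export
event_series <- function(events, species) {
  sel <- events$species == species
  if (!any(sel)) stop("no events for species '", species, "'")
  list(species = species,
       times = events$time_rad[sel],
       stations = events$station[sel],
       n = sum(sel))
}
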