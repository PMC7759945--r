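## Synthetic camera-trap survey generator. Emulates the statistical
## structure a multi-site duiker survey produces: station-level occupancy
## with controllable pairwise association, detection times driven by an
## inhomogeneous Poisson process whose diel intensity is a von Mises
## mixture, multi-individual photos, and sub-hour photo bursts that
## exercise the independence filter.

#' Define a species' simulation profile
#'
#' @param name species label.
#' @param peaks data.frame with columns `mean_hour`, `kappa`, `weight`
#'   describing the von Mises mixture of the diel activity schedule;
#'   weights must sum to 1 and concentrations be positive.
#' @param daily_rate expected detections per occupied station-day (used
#'   when the simulation is not calibrated to target totals).
#' @param occupancy probability that an available station is occupied.
#' @param group_size_probs named numeric vector of probabilities over
#'   individuals per photo, e.g. `c("1" = .86, "2" = .13, "3" = .01)`.
#' @return a `species_profile` list.
#' @export
species_profile <- function(name, peaks, daily_rate = 0.05, occupancy = 0.3,
                            group_size_probs = c("1" = 1)) {
  stopifnot(is.data.frame(peaks),
            all(c("mean_hour", "kappa", "weight") %in% names(peaks)),
            all(peaks$kappa > 0), all(peaks$weight >= 0),
            abs(sum(peaks$weight) - 1) < 1e-8,
            daily_rate >= 0, occupancy >= 0, occupancy <= 1,
            abs(sum(group_size_probs) - 1) < 1e-8)
  structure(list(name = name, peaks = peaks, daily_rate = daily_rate,
                 occupancy = occupancy,
                 group_size_probs = group_size_probs),
            class = "species_profile")
}

## true diel mixture density of a profile, at angles theta
profile_density <- function(profile, theta) {
  p <- profile$peaks
  mu <- hours_to_radians(p$mean_hour)
  out <- numeric(length(theta))
  for (i in seq_len(nrow(p))) {
    out <- out + p$weight[i] * dvonmises(theta, mu[i], p$kappa[i])
  }
  out
}

## draw n diel times (radians) from a profile's mixture
profile_times <- function(profile, n) {
  p <- profile$peaks
  comp <- sample.int(nrow(p), n, replace = TRUE, prob = p$weight)
  out <- numeric(n)
  for (i in seq_len(nrow(p))) {
    sel <- comp == i
    if (any(sel)) {
      out[sel] <- rvonmises(sum(sel), hours_to_radians(p$mean_hour[i]),
                            p$kappa[i])
    }
  }
  out
}

#' Assemble a survey simulation configuration
#'
#' @param species list of [species_profile()] objects.
#' @param n_sites number of survey sites.
#' @param stations_per_site integer scalar or length-`n_sites` vector.
#' @param days_per_station deployment length, days.
#' @param association S x S symmetric matrix of pairwise occupancy odds
#'   ratios (unit diagonal); `NULL` for independence.
#' @param site_weights optional `n_sites x S` non-negative matrix of
#'   relative detection rates per site (rows = sites); a zero entry makes
#'   a species unavailable at that site. `NULL` = uniform.
#' @param target_totals optional named vector of expected independent-event
#'   totals per species; when present, per-station detection rates are
#'   calibrated to the realised occupancy so that expected totals match.
#' @param burst_prob probability that a detection spawns a within-the-hour
#'   photo burst (non-independent repeats removed by the event filter).
#' @param start_date first deployment date (character, ISO).
#' @param seed default integer seed used by the simulation functions.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(species, n_sites = 12, stations_per_site = 36,
                              days_per_station = 42, association = NULL,
                              site_weights = NULL, target_totals = NULL,
                              burst_prob = 0, start_date = "2017-03-01",
                              seed = NULL) {
  s <- length(species)
  stopifnot(s >= 1, n_sites >= 1, days_per_station >= 1)
  if (length(stations_per_site) == 1) {
    stations_per_site <- rep.int(stations_per_site, n_sites)
  }
  stopifnot(length(stations_per_site) == n_sites)
  if (is.null(association)) association <- matrix(1, s, s)
  stopifnot(nrow(association) == s, ncol(association) == s,
            all(abs(association - t(association)) < 1e-12),
            all(diag(association) == 1), all(association > 0))
  if (!is.null(site_weights)) {
    stopifnot(nrow(site_weights) == n_sites, ncol(site_weights) == s,
              all(site_weights >= 0))
  }
  sp_names <- vapply(species, function(x) x$name, character(1))
  names(species) <- sp_names
  if (!is.null(site_weights)) colnames(site_weights) <- sp_names
  if (!is.null(target_totals)) {
    stopifnot(setequal(names(target_totals), sp_names))
    target_totals <- target_totals[sp_names]
  }
  sites <- if (!is.null(site_weights) && !is.null(rownames(site_weights))) {
    rownames(site_weights)
  } else sprintf("site%02d", seq_len(n_sites))
  structure(list(species = species, n_sites = n_sites, sites = sites,
                 stations_per_site = stations_per_site,
                 days_per_station = days_per_station,
                 association = association, site_weights = site_weights,
                 target_totals = target_totals, burst_prob = burst_prob,
                 start_date = start_date, seed = seed),
            class = "simulation_config")
}

config_stations <- function(config) {
  site <- rep(config$sites, config$stations_per_site)
  id <- unlist(lapply(seq_len(config$n_sites), function(k) {
    sprintf("%s-%03d", config$sites[k], seq_len(config$stations_per_site[k]))
  }))
  data.frame(station = id, site = site, stringsAsFactors = FALSE)
}

#' Simulate station-level occupancy with pairwise association
#'
#' Species are placed sequentially: each species' occupancy log-odds at a
#' station is a calibrated intercept plus `log(OR)` per already-present
#' associated species, with the intercept solved (per species, against the
#' realised presence of its predecessors) so the marginal occupancy matches
#' the profile's target. A species with zero site weight at a site is
#' structurally absent there.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return binary station x species matrix with a `site` attribute.
#' @export
simulate_occupancy <- function(config, seed = config$seed) {
  if (is.null(seed)) stop("a seed is required for reproducible simulation")
  st <- config_stations(config)
  n <- nrow(st)
  sp <- names(config$species)
  s <- length(sp)
  site_idx <- match(st$site, config$sites)
  z <- matrix(0L, n, s, dimnames = list(st$station, sp))
  withr::with_seed(seed, {
    for (j in seq_len(s)) {
      avail <- if (is.null(config$site_weights)) rep(TRUE, n)
      else config$site_weights[site_idx, j] > 0
      if (!any(avail)) next
      target <- config$species[[j]]$occupancy
      if (target <= 0) next
      lo <- log(config$association[j, seq_len(s) < j])
      offset <- if (j == 1) rep(0, sum(avail))
      else as.numeric(z[avail, seq_len(j - 1), drop = FALSE] %*% lo)
      f <- function(a) mean(stats::plogis(a + offset)) - target
      if (f(-30) > 0 || f(30) < 0) {
        stop("infeasible occupancy/odds-ratio combination for species '",
             sp[j], "' (target ", target, ")")
      }
      a <- stats::uniroot(f, c(-30, 30), tol = 1e-8)$root
      z[avail, j] <- stats::rbinom(sum(avail), 1, stats::plogis(a + offset))
    }
  })
  attr(z, "site") <- st$site
  z
}

#' Simulate time-stamped detection records
#'
#' For every occupied station-species pair, detections arrive as a Poisson
#' process over the deployment whose time-of-day law is the species' von
#' Mises mixture. Expected counts follow the per-site weights and either
#' the profile's `daily_rate` or, when `target_totals` is set, a rate
#' calibrated to the realised occupancy so the expected community totals
#' match the targets. Photo bursts (repeat records 5-40 minutes after a
#' detection) are injected with probability `burst_prob` per detection and
#' should be removed again by [filter_independent_events()].
#'
#' @param config a [simulation_config()].
#' @param presence occupancy matrix from [simulate_occupancy()].
#' @param seed integer seed (defaults to `config$seed + 1`).
#' @return raw detection `data.frame`: `site, station, species, datetime,
#'   count`, sorted by station/species/time.
#' @export
simulate_detections <- function(config, presence,
                                seed = if (!is.null(config$seed))
                                  config$seed + 1L else NULL) {
  if (is.null(seed)) stop("a seed is required for reproducible simulation")
  st <- config_stations(config)
  site_idx <- match(st$site, config$sites)
  sp <- names(config$species)
  days <- config$days_per_station
  t0 <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC")
  recs <- list(); k <- 0L
  withr::with_seed(seed, {
    for (j in seq_along(sp)) {
      prof <- config$species[[j]]
      occ <- which(presence[, j] == 1L)
      if (length(occ) == 0) next
      w <- if (is.null(config$site_weights)) rep(1, length(occ))
      else config$site_weights[site_idx[occ], j]
      if (sum(w) == 0) next
      if (!is.null(config$target_totals)) {
        ## community totals fixed at the target: a Poisson process
        ## conditioned on its total is a multinomial allocation over
        ## stations weighted by their rates
        n_ev <- as.integer(stats::rmultinom(1, config$target_totals[[j]],
                                            prob = w))
      } else {
        n_ev <- stats::rpois(length(occ), prof$daily_rate * days *
                               w / mean(w[w > 0]))
      }
      tot <- sum(n_ev)
      if (tot == 0) next
      stn <- rep(occ, n_ev)
      tod <- profile_times(prof, tot)                 # radians
      day <- sample.int(days, tot, replace = TRUE) - 1L
      when <- t0 + day * 86400 + radians_to_hours(tod) * 3600
      gs <- as.integer(names(prof$group_size_probs))[
        sample.int(length(prof$group_size_probs), tot, replace = TRUE,
                   prob = prof$group_size_probs)]
      k <- k + 1L
      recs[[k]] <- data.frame(site = st$site[stn], station = st$station[stn],
                              species = sp[j], datetime = when, count = gs,
                              stringsAsFactors = FALSE)
      if (config$burst_prob > 0) {
        nb <- stats::rbinom(tot, 1, config$burst_prob) *
          sample(1:2, tot, replace = TRUE)
        if (sum(nb) > 0) {
          idx <- rep(seq_len(tot), nb)
          offs <- stats::runif(sum(nb), 5, 40) * 60
          k <- k + 1L
          recs[[k]] <- data.frame(site = st$site[stn[idx]],
                                  station = st$station[stn[idx]],
                                  species = sp[j],
                                  datetime = when[idx] + offs,
                                  count = 1L, stringsAsFactors = FALSE)
        }
      }
    }
  })
  if (k == 0L) {
    return(data.frame(site = character(), station = character(),
                      species = character(),
                      datetime = as.POSIXct(character(), tz = "UTC"),
                      count = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, recs)
  out <- out[order(out$station, out$species, out$datetime), , drop = FALSE]
  out$datetime <- as.POSIXct(round(as.numeric(out$datetime)),
                             origin = "1970-01-01", tz = "UTC")
  rownames(out) <- NULL
  out
}

#' Write simulated detection records to CSV
#'
#' Deterministic formatting (ISO datetimes, fixed column order) so that
#' identical seeds give byte-identical files.
#'
#' @param records data.frame from [simulate_detections()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_detections <- function(records, path) {
  out <- records
  out$datetime <- format(out$datetime, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  utils::write.csv(out[, c("site", "station", "species", "datetime", "count")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
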