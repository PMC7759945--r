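# shared builders for the test suite

# detection records at one station from a vector of minute offsets
records_at <- function(minutes, station = "A1", species = "sp1",
                       site = "A", start = "2018-01-01 08:00:00",
                       count = 1) {
  data.frame(site = site, station = station, species = species,
             datetime = as.POSIXct(start, tz = "UTC") + minutes * 60,
             count = count, stringsAsFactors = FALSE)
}

# random record table across stations/species for property tests
random_records <- function(n, n_stations = 4, n_species = 3) {
  data.frame(
    site = "S",
    station = sample(sprintf("st%02d", seq_len(n_stations)), n, TRUE),
    species = sample(sprintf("sp%d", seq_len(n_species)), n, TRUE),
    datetime = as.POSIXct("2018-03-01", tz = "UTC") +
      runif(n, 0, 20 * 86400),
    count = 1L, stringsAsFactors = FALSE)
}

# brute-force co-occurrence null: fix species A on the first N1 stations,
# enumerate every way to place species B on N2 of N stations
enumerate_cooccurrence <- function(N, N1, N2) {
  placements <- utils::combn(N, N2)
  q <- apply(placements, 2, function(cols) sum(cols <= N1))
  tabulate(q + 1L, nbins = min(N1, N2) + 1L) / ncol(placements)
}

# draw diel times from a von Mises mixture given as (hour, kappa, weight)
mixture_times <- function(n, comps) {
  idx <- sample.int(nrow(comps), n, TRUE, comps[, 3])
  out <- numeric(n)
  for (i in seq_len(nrow(comps))) {
    sel <- idx == i
    if (any(sel)) {
      out[sel] <- rvm(sum(sel), hours_to_radians(comps[i, 1]), comps[i, 2])
    }
  }
  out
}
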