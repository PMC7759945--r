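two_species_config <- function(occ = c(0.4, 0.4), or = 1, n_stations = 250,
                               rate = 0.2) {
  assoc <- matrix(c(1, or, or, 1), 2, 2)
  simulation_config(
    species = list(
      species_profile("sp1", data.frame(mean_hour = 12, kappa = 4,
                                        weight = 1),
                      daily_rate = rate, occupancy = occ[1]),
      species_profile("sp2", data.frame(mean_hour = c(2, 14),
                                        kappa = c(3, 3),
                                        weight = c(0.5, 0.5)),
                      daily_rate = rate, occupancy = occ[2])),
    n_sites = 2, stations_per_site = n_stations / 2, days_per_station = 30,
    association = assoc)
}

test_that("identical seeds reproduce the survey byte for byte", {
  cfg <- study_replica_config()
  a <- simulate_survey(cfg, seed = 5)
  b <- simulate_survey(cfg, seed = 5)
  expect_identical(a$presence, b$presence)
  expect_identical(a$records, b$records)
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_detections(a$records, fa)
  write_detections(b$records, fb)
  expect_identical(readLines(fa), readLines(fb))
  c2 <- simulate_survey(cfg, seed = 6)
  expect_false(identical(a$records, c2$records))
})

test_that("occupancy marginals are calibrated and independence holds at OR 1", {
  cfg <- two_species_config(n_stations = 1000)
  z <- simulate_occupancy(cfg, seed = 71)
  expect_lt(abs(mean(z[, 1]) - 0.4), 0.03)
  expect_lt(abs(mean(z[, 2]) - 0.4), 0.03)
  tab <- table(factor(z[, 1], 0:1), factor(z[, 2], 0:1))
  or_hat <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  expect_gt(or_hat, 0.6)
  expect_lt(or_hat, 1.6)
})

test_that("an induced association is recovered by the co-occurrence test", {
  cfg <- two_species_config(occ = c(0.35, 0.35), or = 5, n_stations = 316)
  z <- simulate_occupancy(cfg, seed = 72)
  tails <- cooccurrence_test(nrow(z), sum(z[, 1]), sum(z[, 2]),
                             sum(z[, 1] * z[, 2]))
  expect_lt(tails$p_gt, 0.05)
  # repulsion is detectable too
  cfg_neg <- two_species_config(occ = c(0.5, 0.5), or = 0.15,
                                n_stations = 316)
  z2 <- simulate_occupancy(cfg_neg, seed = 73)
  tails2 <- cooccurrence_test(nrow(z2), sum(z2[, 1]), sum(z2[, 2]),
                              sum(z2[, 1] * z2[, 2]))
  expect_lt(tails2$p_lt, 0.05)
})

test_that("detection counts follow rates and the diel law", {
  cfg <- two_species_config(rate = 0)
  z <- simulate_occupancy(cfg, seed = 74)
  expect_equal(nrow(simulate_detections(cfg, z, seed = 75)), 0)
  cfg2 <- two_species_config(rate = 0.4)
  z2 <- simulate_occupancy(cfg2, seed = 74)
  rec <- simulate_detections(cfg2, z2, seed = 75)
  h <- as.POSIXlt(rec$datetime, tz = "UTC")$hour
  day_frac <- mean(h[rec$species == "sp1"] >= 6 &
                   h[rec$species == "sp1"] < 18)
  expect_gt(day_frac, 0.95)  # vM(12:00, kappa 4) mass inside daylight
})

test_that("photo bursts are removed again by the independence filter", {
  mk <- function(bp) {
    cfg <- two_species_config(rate = 0.3)
    cfg$burst_prob <- bp
    z <- simulate_occupancy(cfg, seed = 76)
    rec <- simulate_detections(cfg, z, seed = 77)
    nrow(filter_independent_events(rec)) / nrow(rec)
  }
  r0 <- mk(0); r3 <- mk(0.3); r6 <- mk(0.6)
  # without bursts only genuinely clustered arrivals are removed
  expect_gt(r0, 0.9)
  expect_lt(r3, r0)
  expect_lt(r6, r3)
})

test_that("the survey replica matches the published survey's scale", {
  cfg <- study_replica_config()
  expect_equal(sum(cfg$stations_per_site), 428)
  expect_equal(unname(cfg$target_totals),
               c(945, 469, 61, 42, 279, 2562))
  sim <- simulate_survey(cfg, seed = 78)
  ev <- filter_independent_events(sim$records)
  totals <- table(ev$species)[names(cfg$target_totals)]
  expect_true(all(abs(totals - cfg$target_totals) /
                    cfg$target_totals < 0.15))
  kept <- retain_informative_stations(ev, deployed = rownames(sim$presence))
  expect_gt(kept$retention_pct, 60)
  expect_lt(kept$retention_pct, 90)
  # non-uniform diel schedules are detectable in every species
  p <- vapply(names(cfg$target_totals), function(sp) {
    tt <- ev$time_rad[ev$species == sp]
    if (length(tt) > 200) tt <- tt[1:200]  # quadratic statistic
    hermans_rasson_test(tt, n_boot = 200, seed = 79)$p_value
  }, numeric(1))
  expect_true(all(p < 0.01))
})

test_that("profile and configuration invariants are enforced", {
  expect_error(species_profile("x", data.frame(mean_hour = 1, kappa = 2,
                                               weight = 0.5)))
  expect_error(simulation_config(
    species = list(species_profile("x", data.frame(mean_hour = 1,
                                                   kappa = 2, weight = 1))),
    association = matrix(c(1, 2, 3, 1), 2, 2)))
  cfg <- two_species_config()
  expect_error(simulate_occupancy(cfg, seed = NULL), "seed")
})

test_that("a moderate odds ratio is detected with high power at survey scale", {
  cfg <- two_species_config(occ = c(0.35, 0.35), or = 3, n_stations = 316)
  hits <- vapply(1:10, function(i) {
    z <- simulate_occupancy(cfg, seed = 900 + i)
    cooccurrence_test(nrow(z), sum(z[, 1]), sum(z[, 2]),
                      sum(z[, 1] * z[, 2]))$p_gt < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
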