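test_that("field generation is deterministic and SSH honours eddies", {
  lon <- seq(-92, -86, by = 0.5)
  lat <- seq(24, 29, by = 0.5)
  dates <- as.Date("2012-06-01") + 0:3

  ed <- eddy_spec(-89, 26.5, "anticyclonic", amplitude = 0.3,
                  radius_km = 100)
  a <- generate_env_fields(lon, lat, dates, eddies = list(ed), seed = 7)
  b <- generate_env_fields(lon, lat, dates, eddies = list(ed), seed = 7)
  expect_identical(a, b)

  # zero noise, no eddies: SSH constant everywhere
  flat <- generate_env_fields(lon, lat, dates, noise_sd = 0, seed = 1)
  expect_equal(diff(range(flat$layers$SSH)), 0)

  # with one anticyclonic eddy and zero noise the SSH maximum sits within
  # one cell of the eddy centre (closed-form argmax of the Gaussian bump)
  bump <- generate_env_fields(lon, lat, dates, eddies = list(ed),
                              noise_sd = 0, seed = 1)
  ssh <- bump$layers$SSH[, , 1]
  ij <- arrayInd(which.max(ssh), dim(ssh))
  expect_lte(abs(lon[ij[1]] - ed$lon), 0.5)
  expect_lte(abs(lat[ij[2]] - ed$lat), 0.5)

  # cyclonic polarity depresses SSH
  cy <- eddy_spec(-89, 26.5, "cyclonic", amplitude = 0.3, radius_km = 100)
  dip <- generate_env_fields(lon, lat, dates, eddies = list(cy),
                             noise_sd = 0, seed = 1)
  expect_lt(min(dip$layers$SSH), min(flat$layers$SSH))

  # positivity and shared-shape invariants
  for (nm in c("CHL", "MLD", "CUR")) expect_true(all(a$layers[[nm]] > 0))
  dims <- vapply(a$layers, function(x) paste(dim(x), collapse = "x"),
                 character(1))
  expect_length(unique(dims), 1L)
  expect_error(generate_env_fields(numeric(0), lat, dates), "empty grid")
  expect_error(generate_env_fields(lon, lat, as.Date(character(0))),
               "at least one day")
})

test_that("true density surface follows the log-link closed form", {
  env <- generate_env_fields(seq(-92, -86, 0.5), seq(24, 29, 0.5),
                             as.Date("2012-06-01"), seed = 2)
  # all effects zero: density equals exp(intercept) everywhere
  d0 <- generate_true_density(env, intercept = log(5))
  expect_equal(unique(as.vector(d0$values)), 5)

  # single linear SSH effect: log-density differences equal b * delta SSH
  b <- 2.3
  d1 <- generate_true_density(env, intercept = 0,
                              effects = list(SSH = function(x) b * x))
  ssh <- env$layers$SSH
  expect_equal(log(d1$values[1, 1, 1]) - log(d1$values[5, 3, 1]),
               b * (ssh[1, 1, 1] - ssh[5, 3, 1]), tolerance = 1e-12)

  # strongly negative intercept: density vanishes
  dneg <- generate_true_density(env, intercept = -50)
  expect_true(all(dneg$values < 1e-15))

  expect_error(
    generate_true_density(env, effects = list(DEPTH = identity)),
    "unknown covariates"
  )
})

test_that("visual survey simulator matches its Poisson-thinning model", {
  # zero density: empty sighting process
  none <- simulate_visual_survey(0, n_segments = 50, seed = 1)
  expect_equal(nrow(none$sightings), 0L)

  # uniform detection, D = 20, s = 1, g0 = 1, W = 5, L = 10:
  # expected sightings per segment = (D/1000) * 2WL = 2.0
  sim <- simulate_visual_survey(
    20, n_segments = 1000, segment_length_km = 10,
    detection = list(form = "uniform"), g0 = 1, strip_halfwidth_km = 5,
    mean_group_size = 1, seed = 42
  )
  expect_equal(nrow(sim$sightings) / 1000, 2.0, tolerance = 0.08)
  expect_true(all(sim$sightings$group_size >= 1))

  # determinism
  sim2 <- simulate_visual_survey(
    20, n_segments = 1000, segment_length_km = 10,
    detection = list(form = "uniform"), g0 = 1, strip_halfwidth_km = 5,
    mean_group_size = 1, seed = 42
  )
  expect_identical(sim, sim2)

  expect_error(
    simulate_visual_survey(5, segment_length_km = 0, seed = 1),
    "segment_length_km"
  )
})

test_that("simulated sighting distances follow the detection curve", {
  # retained distances have density proportional to g(x) on [0, W]
  sigma <- 2; W <- 8
  sim <- simulate_visual_survey(
    400, n_segments = 2000, detection = list(form = "half-normal",
                                             sigma = sigma),
    strip_halfwidth_km = W, mean_group_size = 1, seed = 5
  )
  x <- sim$sightings$perp_distance_km
  expect_gt(length(x), 5000)
  cdf <- function(q) {
    (stats::pnorm(q / sigma) - 0.5) / (stats::pnorm(W / sigma) - 0.5)
  }
  ks <- suppressWarnings(stats::ks.test(x, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("group sizes follow a zero-truncated Poisson with the given mean", {
  sim <- simulate_visual_survey(
    300, n_segments = 1500, detection = list(form = "uniform"),
    strip_halfwidth_km = 5, mean_group_size = 3.5, seed = 8
  )
  gs <- sim$sightings$group_size
  expect_true(all(gs >= 1))
  expect_equal(mean(gs), 3.5, tolerance = 0.05)
})

test_that("PAM simulator matches its Bernoulli-window model", {
  sites <- data.frame(site_id = "A", lon = -88, lat = 27, c_k = 0,
                      p_k = 0.5, p_v = 0.8, w_km = 3, s_bar = 2)
  # zero density and no false positives: nothing detected
  zero <- simulate_pam_deployment(0, sites,
                                  dates = as.Date("2012-01-01") + 0:49,
                                  seed = 1)
  expect_true(all(zero$n_windows_detected == 0))

  # D = 5, s = 2, w = 3, P_k = 0.5, P_v = 0.8, T = 288:
  # q = 0.0025 * pi * 9 * 0.4 = 0.028274, E[n] = 288 q = 8.143
  days <- simulate_pam_deployment(5, sites,
                                  dates = as.Date("2012-01-01") + 0:999,
                                  seed = 3)
  expect_true(all(days$n_windows_detected <= days$n_windows_total))
  expect_equal(mean(days$n_windows_detected), 288 * 0.028274334,
               tolerance = 0.04)

  # c = 0.5 injects false positives at rate qc/(1-c) = q, doubling the
  # expected count at small q
  sites_fp <- transform(sites, c_k = 0.5)
  fp <- simulate_pam_deployment(5, sites_fp,
                                dates = as.Date("2012-01-01") + 0:999,
                                seed = 3)
  expect_equal(mean(fp$n_windows_detected) / mean(days$n_windows_detected),
               2, tolerance = 0.1)

  # determinism and saturation warning
  again <- simulate_pam_deployment(5, sites,
                                   dates = as.Date("2012-01-01") + 0:999,
                                   seed = 3)
  expect_identical(days, again)
  expect_warning(
    simulate_pam_deployment(1e6, sites, dates = as.Date("2012-01-01"),
                            seed = 1),
    "saturated"
  )
})

test_that("survey tables and field series round-trip through CSV", {
  env <- generate_env_fields(seq(-92, -86, 0.5), seq(24, 29, 0.5),
                             as.Date("2012-06-01") + 0:1, seed = 4)
  path <- tempfile(fileext = ".csv")
  write_env_csv(env, path)
  back <- read_env_csv(path)
  expect_equal(back$layers$SST, env$layers$SST, tolerance = 1e-10)
  expect_equal(back$dates, env$dates)

  sim <- simulate_visual_survey(20, n_segments = 20, seed = 2)
  dir <- tempfile()
  paths <- write_survey_tables(dir, segments = sim$segments,
                               sightings = sim$sightings)
  expect_true(all(file.exists(file.path(dir, c("segments.csv",
                                               "sightings.csv")))))
  seg <- utils::read.csv(file.path(dir, "segments.csv"))
  expect_equal(nrow(seg), 20L)
})
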