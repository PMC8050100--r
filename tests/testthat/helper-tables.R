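# Shared fixture builders. All data are generated in code at test time.

# A table of the nine covariates, iid uniform on [-1, 1] (no structure).
make_cov_table <- function(n, seed = 1, lo = -1, hi = 1) {
  set.seed(seed)
  d <- as.data.frame(matrix(stats::runif(n * 9, lo, hi), ncol = 9))
  names(d) <- covariate_names()
  d
}

# Zero-inflated (Tweedie) density response driven by a subset of covariates
# through a log link; `effects` is a named list of functions of one
# covariate, as in generate_true_density.
make_tweedie_table <- function(n, seed = 1, intercept = log(3),
                               effects = list(), p = 1.5, phi = 1.5) {
  d <- make_cov_table(n, seed)
  eta <- rep(intercept, n)
  for (nm in names(effects)) eta <- eta + effects[[nm]](d[[nm]])
  d$density <- mgcv::rTweedie(exp(eta), p = p, phi = phi)
  d
}

# Full-pipeline joint-modeling scenario: a seasonal SST-driven and
# eddy/SSH-driven true density surface, a summer-only visual survey (so
# visual training truncates the SST range) and fixed PAM sites (so acoustic
# training truncates the spatial SSH range); the test year combines a summer
# visual survey with year-round acoustic monitoring.
sim_joint_case <- function(seed = 1,
                           n_vis_train = 300, n_vis_test = 150,
                           train_day_step = 3, test_day_step = 7) {
  lon <- seq(-92, -85, by = 0.5)
  lat <- seq(24, 31, by = 0.5)
  dates <- seq(as.Date("2011-01-05"), by = 7, length.out = 104)
  eddies <- list(
    eddy_spec(-86.5, 26, "anticyclonic", amplitude = 0.30, radius_km = 120,
              drift_east_km_day = -0.5),
    eddy_spec(-90.5, 25.5, "anticyclonic", amplitude = 0.22, radius_km = 90,
              drift_east_km_day = 0.3, drift_north_km_day = 0.2),
    eddy_spec(-89, 29.5, "cyclonic", amplitude = 0.25, radius_km = 100,
              drift_east_km_day = -0.3),
    eddy_spec(-91.5, 28, "cyclonic", amplitude = 0.20, radius_km = 80,
              drift_east_km_day = 0.4, drift_north_km_day = -0.2)
  )
  env <- generate_env_fields(lon, lat, dates, eddies = eddies, seed = seed)
  truth <- generate_true_density(
    env, intercept = log(6),
    effects = list(SST = function(x) 0.15 * (25 - x),
                   SSH = function(x) 1.5 * (x - 0.05))
  )

  vis_table <- function(year, n_seg, sim_seed) {
    july <- dates[format(dates, "%Y") == year &
                    format(dates, "%m") %in% c("06", "07", "08")]
    sim <- simulate_visual_survey(
      truth, n_segments = n_seg,
      detection = list(form = "half-normal", sigma = 2),
      strip_halfwidth_km = 6, mean_group_size = 2,
      lon_range = range(lon), lat_range = range(lat),
      dates = july, seed = sim_seed
    )
    tab <- build_visual_density_table(sim$segments, sim$sightings, "species")
    cov <- transform_covariates(match_covariates(tab, env))
    cov$density <- tab$density_per_1000km2
    cov$modality <- "visual"
    cov <- cov[, c("date", "lon", "lat", covariate_names(),
                   "density", "modality")]
    cov[stats::complete.cases(cov[covariate_names()]), , drop = FALSE]
  }

  sites <- data.frame(
    site_id = c("MC", "GC", "DT"),
    lon = c(-90.5, -88.5, -86.5), lat = c(28.5, 27.5, 25.5),
    c_k = 0.15, p_k = 0.4, p_v = 0.7, w_km = 4, s_bar = 2,
    stringsAsFactors = FALSE
  )
  pam_table <- function(year, step, sim_seed) {
    yr_dates <- dates[format(dates, "%Y") == year]
    days <- seq(min(yr_dates), max(yr_dates), by = step)
    recs <- simulate_pam_deployment(truth, sites, dates = days,
                                    seed = sim_seed)
    tab <- build_acoustic_density_table(recs, sites, "species")
    cov <- transform_covariates(match_covariates(tab, env))
    cov$density <- tab$density_per_1000km2
    cov$modality <- "acoustic"
    cov <- cov[, c("date", "lon", "lat", covariate_names(),
                   "density", "modality")]
    cov[stats::complete.cases(cov[covariate_names()]), , drop = FALSE]
  }

  train_visual <- vis_table("2011", n_vis_train, seed + 101)
  train_acoustic <- pam_table("2011", train_day_step, seed + 202)
  test <- rbind(vis_table("2012", n_vis_test, seed + 303),
                pam_table("2012", test_day_step, seed + 404))
  list(env = env, truth = truth, sites = sites,
       train_visual = train_visual, train_acoustic = train_acoustic,
       test = test)
}
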