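# Synthetic study system: smooth environmental fields with drifting
# Gaussian-bump eddies, a known log-link density surface, and simulated
# visual line-transect and passive-acoustic observations whose statistical
# structure matches the assumptions of the two density estimators. Every
# downstream stage of the pipeline can therefore be tested by parameter
# recovery against known truth.

#' Specify a mesoscale eddy for field generation
#'
#' An eddy appears in generated SSH fields as a Gaussian bump
#' \code{A * exp(-d^2 / (2 * radius^2))} centred on (lon, lat), where d is the
#' great-circle distance to the centre. Cyclonic eddies are sea-surface-height
#' depressions (negative anomaly), anticyclonic eddies are elevations. The
#' centre drifts linearly over time.
#'
#' @param lon,lat Centre coordinates (decimal degrees, WGS84).
#' @param polarity "cyclonic" or "anticyclonic".
#' @param amplitude Positive anomaly magnitude (m); the sign is set by
#'   \code{polarity}.
#' @param radius_km Gaussian scale of the bump (km); must be positive.
#' @param drift_east_km_day,drift_north_km_day Centre drift velocity (km/day).
#' @return An object of class \code{"eddy_spec"}.
#' @export
eddy_spec <- function(lon, lat, polarity = c("anticyclonic", "cyclonic"),
                      amplitude = 0.2, radius_km = 80,
                      drift_east_km_day = 0, drift_north_km_day = 0) {
  polarity <- match.arg(polarity)
  check_number(amplitude, "amplitude", lower = 0, open_lower = TRUE)
  check_number(radius_km, "radius_km", lower = 0, open_lower = TRUE)
  structure(
    list(lon = lon, lat = lat, polarity = polarity, amplitude = amplitude,
         radius_km = radius_km,
         drift_east_km_day = drift_east_km_day,
         drift_north_km_day = drift_north_km_day),
    class = "eddy_spec"
  )
}

# Signed SSH anomaly of one eddy, evaluated over grid nodes at a date offset.
eddy_anomaly <- function(eddy, lon_grid, lat_grid, days_elapsed) {
  # advect the centre; convert km drift to degrees at the centre latitude
  dlat <- eddy$drift_north_km_day * days_elapsed / 111.19
  clat <- eddy$lat + dlat
  dlon <- eddy$drift_east_km_day * days_elapsed /
    (111.19 * cos(clat * pi / 180))
  clon <- eddy$lon + dlon
  d <- haversine_km(lon_grid, lat_grid, clon, clat)
  sgn <- if (eddy$polarity == "anticyclonic") 1 else -1
  sgn * eddy$amplitude * exp(-d^2 / (2 * eddy$radius_km^2))
}

# Smooth Gaussian random field on the unit square via random low-frequency
# Fourier features; unit marginal variance in expectation.
smooth_field_sampler <- function(k = 8, max_freq = 3) {
  omega <- matrix(stats::runif(2 * k, -max_freq, max_freq) * 2 * pi, ncol = 2)
  phase <- stats::runif(k, 0, 2 * pi)
  amp <- stats::rnorm(k, sd = sqrt(2 / k))
  function(u, v) {
    f <- numeric(length(u))
    for (j in seq_len(k)) {
      f <- f + amp[j] * cos(omega[j, 1] * u + omega[j, 2] * v + phase[j])
    }
    f
  }
}

#' Generate a synthetic series of gridded environmental fields
#'
#' Produces the seven stored covariate fields (SSH, SST, CHL, MLD, Upwell,
#' SAL, CUR) on a regular lon/lat grid over a series of dates. Each field is
#' a climatological mean plus a deterministic seasonal cycle plus a smooth
#' spatial random field evolving as an AR(1) process in time. SSH is a
#' constant background plus the superposed anomalies of the supplied eddies
#' (advected by their drift velocities) plus noise, so that with no eddies
#' and zero noise the SSH layer is constant. CHL, MLD and CUR are generated
#' on the log scale and are therefore strictly positive.
#'
#' @param lon,lat Grid node coordinates (increasing numeric vectors,
#'   decimal degrees); the grid must have at least 10 x 10 nodes unless
#'   \code{allow_small_grid} is TRUE.
#' @param dates A \code{Date} vector (ordered, at least one day).
#' @param eddies List of \code{\link{eddy_spec}} objects (possibly empty).
#' @param noise_sd Global multiplier on the stochastic component of every
#'   layer (0 disables noise).
#' @param seed Integer seed; identical seeds give bit-identical fields.
#' @param allow_small_grid Allow grids below 10 x 10 (used in small examples).
#' @return An object of class \code{"env_fields"}: a list with \code{lon},
#'   \code{lat}, \code{dates} and \code{layers}, the latter a named list of
#'   arrays with dimensions (lon, lat, time).
#' @export
generate_env_fields <- function(lon, lat, dates, eddies = list(),
                                noise_sd = 1, seed = 1,
                                allow_small_grid = FALSE) {
  if (length(lon) == 0 || length(lat) == 0) {
    stop_invalid("empty grid: `lon` and `lat` must be non-empty")
  }
  if (!allow_small_grid && (length(lon) < 10 || length(lat) < 10)) {
    stop_invalid("grid must have at least 10 x 10 cells")
  }
  if (length(dates) < 1) stop_invalid("`dates` must span at least one day")
  dates <- as.Date(dates)
  check_number(noise_sd, "noise_sd", lower = 0)

  nlon <- length(lon); nlat <- length(lat); nt <- length(dates)
  lon_grid <- rep(lon, times = nlat)
  lat_grid <- rep(lat, each = nlon)
  # normalized coordinates for the random-field sampler
  u <- (lon_grid - min(lon)) / max(diff(range(lon)), 1e-9)
  v <- (lat_grid - min(lat)) / max(diff(range(lat)), 1e-9)
  doy <- as.numeric(format(dates, "%j"))
  season <- cos(2 * pi * (doy - 200) / 365.25)   # peaks in mid-July

  # per-layer generation parameters: climatological mean, seasonal amplitude,
  # spatial-noise sd; positive layers are built on the log scale
  cfg <- list(
    SSH    = list(mean = 0.05,     seas = 0,    sd = 0.04, log = FALSE),
    SST    = list(mean = 25,       seas = 4,    sd = 0.8,  log = FALSE),
    CHL    = list(mean = log(0.2), seas = -0.4, sd = 0.5,  log = TRUE),
    MLD    = list(mean = log(20),  seas = 0.5,  sd = 0.5,  log = TRUE),
    Upwell = list(mean = 0,        seas = 0,    sd = 1e-4, log = FALSE),
    SAL    = list(mean = 35,       seas = 0.3,  sd = 0.5,  log = FALSE),
    CUR    = list(mean = log(0.3), seas = 0,    sd = 0.4,  log = TRUE)
  )

  set.seed(seed)
  rho <- 0.8   # day-to-day autocorrelation of the spatial noise
  layers <- vector("list", length(cfg))
  names(layers) <- names(cfg)
  for (nm in names(cfg)) {
    p <- cfg[[nm]]
    arr <- array(0, dim = c(nlon, nlat, nt))
    state <- smooth_field_sampler()(u, v)
    for (t in seq_len(nt)) {
      if (t > 1) {
        innov <- smooth_field_sampler()(u, v)
        state <- rho * state + sqrt(1 - rho^2) * innov
      }
      val <- p$mean + p$seas * season[t] + noise_sd * p$sd * state
      if (nm == "SSH" && length(eddies) > 0) {
        days <- as.numeric(dates[t] - dates[1])
        for (ed in eddies) {
          val <- val + eddy_anomaly(ed, lon_grid, lat_grid, days)
        }
      }
      if (p$log) val <- exp(val)
      arr[, , t] <- val
    }
    layers[[nm]] <- arr
  }
  structure(
    list(lon = lon, lat = lat, dates = dates, layers = layers),
    class = "env_fields"
  )
}

#' @export
print.env_fields <- function(x, ...) {
  cat(sprintf(
    "Environmental field series: %d x %d grid, %d dates (%s to %s)\n",
    length(x$lon), length(x$lat), length(x$dates),
    format(min(x$dates)), format(max(x$dates))
  ))
  cat("Layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a known true density surface over environmental fields
#'
#' Builds the deterministic density surface
#' \code{D = exp(intercept + sum_c f_c(layer_c))} in animals per 1000 km^2,
#' cell by cell and date by date. This is the ground truth against which the
#' visual and acoustic estimators and the distribution models are tested.
#'
#' @param env An \code{\link{env_fields}} object.
#' @param intercept Intercept on the log scale.
#' @param effects Named list of vectorized functions, one per stored
#'   covariate used (names must exist among \code{env$layers}).
#' @return An object of class \code{"density_field"}: the grid/date vectors
#'   plus a \code{values} array (lon, lat, time) of nonnegative densities.
#' @export
generate_true_density <- function(env, intercept = log(5), effects = list()) {
  stopifnot(inherits(env, "env_fields"))
  bad <- setdiff(names(effects), names(env$layers))
  if (length(bad) > 0) {
    stop_invalid("effects reference unknown covariates: ",
                 paste(bad, collapse = ", "))
  }
  eta <- array(intercept, dim = dim(env$layers[[1]]))
  for (nm in names(effects)) {
    eta <- eta + effects[[nm]](env$layers[[nm]])
  }
  structure(
    list(lon = env$lon, lat = env$lat, dates = env$dates, values = exp(eta)),
    class = "density_field"
  )
}

# Resolve a density specification at given points/dates. Accepts a scalar,
# a function(lon, lat, date), or a density_field (nearest cell and day).
density_at <- function(density, lon, lat, date) {
  if (is.numeric(density) && length(density) == 1) {
    return(rep(density, length(lon)))
  }
  if (is.function(density)) return(density(lon, lat, date))
  if (inherits(density, "density_field")) {
    date <- as.Date(date)
    out <- numeric(length(lon))
    for (i in seq_along(lon)) {
      ii <- which.min(abs(density$lon - lon[i]))
      jj <- which.min(abs(density$lat - lat[i]))
      tt <- which.min(abs(as.numeric(density$dates - date[min(i, length(date))])))
      out[i] <- density$values[ii, jj, tt]
    }
    return(out)
  }
  stop_invalid("`density` must be a scalar, a function, or a density_field")
}

#' Simulate a visual line-transect survey
#'
#' Groups are placed along each transect segment strip as a homogeneous
#' Poisson process with intensity D/s_bar per km^2 evaluated at the segment
#' midpoint (D in animals per 1000 km^2 is converted internally), over the
#' strip of width 2W. Each group is retained with probability
#' \code{g0 * g(x)} where x ~ Uniform(0, W) is its perpendicular distance and
#' g the detection function. Retained groups become sightings carrying x and
#' a group size drawn from a zero-truncated Poisson with mean
#' \code{mean_group_size}.
#'
#' @param density Scalar density (animals per 1000 km^2), a function
#'   \code{(lon, lat, date)}, or a \code{density_field}.
#' @param n_segments Number of segments to generate when \code{segments} is
#'   NULL.
#' @param segment_length_km Segment length L (km); must be in (0, 10].
#' @param detection List with \code{form} ("half-normal", "hazard-rate" or
#'   "uniform") and its parameters (\code{sigma}, and \code{b} for
#'   hazard-rate).
#' @param g0 Probability of detection on the transect line, in (0, 1].
#' @param strip_halfwidth_km Maximum strip half-width W (km) within which
#'   groups are generated.
#' @param mean_group_size Mean group size s_bar (>= 1).
#' @param species Species label written on sightings.
#' @param segments Optional pre-built segments data frame (columns
#'   segment_id, cruise, date, lon, lat, length_km); otherwise midpoints are
#'   drawn uniformly over \code{lon_range} x \code{lat_range} with dates
#'   sampled from \code{dates}.
#' @param lon_range,lat_range Survey box for generated midpoints.
#' @param dates Candidate segment dates.
#' @param cruise Cruise label for generated segments.
#' @param seed Integer seed.
#' @return List with \code{segments} and \code{sightings} data frames.
#' @export
simulate_visual_survey <- function(density, n_segments = 100,
                                   segment_length_km = 10,
                                   detection = list(form = "half-normal",
                                                    sigma = 2),
                                   g0 = 1, strip_halfwidth_km = 5,
                                   mean_group_size = 1,
                                   species = "species",
                                   segments = NULL,
                                   lon_range = c(-92, -86),
                                   lat_range = c(25, 29),
                                   dates = as.Date("2009-07-01"),
                                   cruise = "sim",
                                   seed = 1) {
  check_number(segment_length_km, "segment_length_km",
               lower = 0, upper = 10, open_lower = TRUE)
  check_number(strip_halfwidth_km, "strip_halfwidth_km",
               lower = 0, open_lower = TRUE)
  check_number(g0, "g0", lower = 0, upper = 1, open_lower = TRUE)
  check_number(mean_group_size, "mean_group_size", lower = 1)
  set.seed(seed)
  dates <- as.Date(dates)

  if (is.null(segments)) {
    segments <- data.frame(
      segment_id = sprintf("seg%05d", seq_len(n_segments)),
      cruise = cruise,
      date = sample(dates, n_segments, replace = TRUE),
      lon = stats::runif(n_segments, lon_range[1], lon_range[2]),
      lat = stats::runif(n_segments, lat_range[1], lat_range[2]),
      length_km = segment_length_km,
      stringsAsFactors = FALSE
    )
  } else {
    check_columns(segments,
                  c("segment_id", "cruise", "date", "lon", "lat", "length_km"),
                  "segments")
    if (any(segments$length_km <= 0)) {
      stop_invalid("segment lengths must be positive")
    }
  }

  W <- strip_halfwidth_km
  D <- density_at(density, segments$lon, segments$lat, segments$date)
  # groups per km^2: density is animals per 1000 km^2
  lambda <- (D / 1000 / mean_group_size) * 2 * W * segments$length_km
  n_groups <- stats::rpois(nrow(segments), lambda)

  sightings <- vector("list", nrow(segments))
  for (i in seq_len(nrow(segments))) {
    ng <- n_groups[i]
    if (ng == 0) next
    x <- stats::runif(ng, 0, W)
    p_keep <- g0 * detection_g(x, detection$form, detection)
    keep <- stats::runif(ng) < p_keep
    nk <- sum(keep)
    if (nk == 0) next
    sightings[[i]] <- data.frame(
      segment_id = segments$segment_id[i],
      species = species,
      perp_distance_km = x[keep],
      group_size = rztpois(nk, mean_group_size),
      stringsAsFactors = FALSE
    )
  }
  sightings <- do.call(rbind, sightings[!vapply(sightings, is.null, logical(1))])
  if (is.null(sightings)) {
    sightings <- data.frame(segment_id = character(0), species = character(0),
                            perp_distance_km = numeric(0),
                            group_size = integer(0))
  }
  rownames(sightings) <- NULL
  list(segments = segments, sightings = sightings)
}

#' Simulate a passive acoustic monitoring deployment
#'
#' For each site-day, a 5-minute window registers a true group detection with
#' probability \code{q = min(1, (D/s_bar) * pi * w^2 * P_k * P_v)} (densities
#' converted from animals per 1000 km^2) and, independently, a false
#' detection with probability \code{q * c_k / (1 - c_k)}, so that the
#' realized false-positive fraction equals \code{c_k} in expectation and the
#' group-counting estimator's \code{(1 - c_k)} correction is exactly the
#' right inverse. A day's detection count \code{n_windows_detected} is the
#' number of windows with any detection; at most one detection is recorded
#' per window. A warning is raised if q had to be clamped at 1 (saturation).
#'
#' @param density Scalar, function or \code{density_field} (animals per
#'   1000 km^2).
#' @param sites Data frame with columns site_id, lon, lat, c_k, p_k, p_v,
#'   w_km, s_bar (the site/species acoustic parameter set).
#' @param dates Date vector of monitored days.
#' @param windows_per_day Number of 5-minute windows sampled per day
#'   (288 for continuous recording).
#' @param seed Integer seed.
#' @return Data frame of day records: site_id, date, n_windows_detected,
#'   n_windows_total, effort_hours.
#' @export
simulate_pam_deployment <- function(density, sites,
                                    dates = as.Date("2012-01-01") + 0:9,
                                    windows_per_day = 288, seed = 1) {
  check_columns(sites,
                c("site_id", "lon", "lat", "c_k", "p_k", "p_v", "w_km", "s_bar"),
                "sites")
  if (windows_per_day < 1) stop_invalid("`windows_per_day` must be >= 1")
  check_number(sites$c_k, "c_k", lower = 0, upper = 1, open_upper = TRUE)
  check_number(sites$p_k, "p_k", lower = 0, upper = 1, open_lower = TRUE)
  check_number(sites$p_v, "p_v", lower = 0, upper = 1, open_lower = TRUE)
  check_number(sites$w_km, "w_km", lower = 0, open_lower = TRUE)
  check_number(sites$s_bar, "s_bar", lower = 1)
  set.seed(seed)
  dates <- as.Date(dates)

  grid <- expand.grid(site = seq_len(nrow(sites)), day = seq_along(dates))
  s <- sites[grid$site, ]
  day <- dates[grid$day]
  D <- density_at(density, s$lon, s$lat, day)
  q_raw <- (D / 1000 / s$s_bar) * pi * s$w_km^2 * s$p_k * s$p_v
  if (any(q_raw > 1)) {
    warning(sprintf(
      "per-window detection probability saturated (q > 1) for %d site-day(s); clamped",
      sum(q_raw > 1)
    ))
  }
  q <- pmin(1, q_raw)
  f <- q * s$c_k / (1 - s$c_k)
  p_any <- 1 - (1 - q) * (1 - pmin(1, f))
  n_det <- stats::rbinom(nrow(grid), windows_per_day, p_any)
  data.frame(
    site_id = s$site_id,
    date = day,
    n_windows_detected = n_det,
    n_windows_total = windows_per_day,
    effort_hours = 24,
    stringsAsFactors = FALSE
  )
}

#' Write simulated survey tables to plain CSV files
#'
#' Writes segments.csv, sightings.csv, pam_sites.csv and pam_days.csv (those
#' supplied) into a directory.
#'
#' @param dir Output directory (created if needed).
#' @param segments,sightings,pam_sites,pam_days Data frames as produced by
#'   the simulators; any may be NULL.
#' @return Invisibly, the paths written.
#' @export
write_survey_tables <- function(dir, segments = NULL, sightings = NULL,
                                pam_sites = NULL, pam_days = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(segments = segments, sightings = sightings,
               pam_sites = pam_sites, pam_days = pam_days)
  paths <- character(0)
  for (nm in names(tabs)) {
    if (!is.null(tabs[[nm]])) {
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(tabs[[nm]], p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Write / read an environmental field series as long-format CSV
#'
#' Plain-text interchange for \code{\link{env_fields}} objects: one row per
#' (lon, lat, date) with one column per layer.
#'
#' @param env An \code{env_fields} object.
#' @param path CSV file path.
#' @return \code{write_env_csv}: the path, invisibly. \code{read_env_csv}:
#'   an \code{env_fields} object.
#' @export
write_env_csv <- function(env, path) {
  stopifnot(inherits(env, "env_fields"))
  grid <- expand.grid(lon = env$lon, lat = env$lat, date = env$dates)
  for (nm in names(env$layers)) grid[[nm]] <- as.vector(env$layers[[nm]])
  utils::write.csv(grid, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_env_csv
#' @export
read_env_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lon <- sort(unique(df$lon)); lat <- sort(unique(df$lat))
  dates <- sort(unique(as.Date(df$date)))
  ord <- order(match(as.Date(df$date), dates), match(df$lat, lat),
               match(df$lon, lon))
  df <- df[ord, ]
  layer_names <- setdiff(names(df), c("lon", "lat", "date"))
  layers <- lapply(layer_names, function(nm) {
    array(df[[nm]], dim = c(length(lon), length(lat), length(dates)))
  })
  names(layers) <- layer_names
  structure(list(lon = lon, lat = lat, dates = dates, layers = layers),
            class = "env_fields")
}
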