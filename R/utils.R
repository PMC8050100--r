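# Shared helpers: spherical distances, samplers, argument checks.

#' Names of the nine environmental model covariates
#'
#' The covariate set used throughout the package: sea surface height anomaly
#' (SSH, m), sea surface temperature (SST, degrees C), chlorophyll-a
#' concentration (CHL, mg/m^3, log-transformed before modeling), mixed layer
#' depth (MLD, m, log-transformed), vertical water velocity at 50 m
#' (Upwell, m/s), surface salinity (SAL, PSU), surface current magnitude
#' (CUR, m/s, log-transformed), distance to the nearest cyclonic eddy
#' (posEddyDist, km) and distance to the nearest anticyclonic eddy
#' (negEddyDist, km).
#'
#' @return Character vector of the nine covariate names, in canonical order.
#' @export
covariate_names <- function() {
  c("SSH", "SST", "CHL", "MLD", "Upwell", "SAL", "CUR",
    "posEddyDist", "negEddyDist")
}

# Names of the seven gridded fields (eddy distances are derived, not stored).
env_layer_names <- function() {
  c("SSH", "SST", "CHL", "MLD", "Upwell", "SAL", "CUR")
}

# Earth radius used for all great-circle distances (km).
EARTH_RADIUS_KM <- 6371

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km. Inputs are recycled to a
#' common length; coordinates are WGS84 decimal degrees.
#'
#' @param lon1,lat1 Coordinates of the first point(s).
#' @param lon2,lat2 Coordinates of the second point(s).
#' @return Numeric vector of distances in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  n <- max(length(lon1), length(lat1), length(lon2), length(lat2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM * 1000) / 1000
}

# Zero-truncated Poisson sample with a given mean (>= 1). The underlying
# Poisson rate lambda solves lambda / (1 - exp(-lambda)) = mean; mean 1 is the
# degenerate all-ones case (lambda -> 0).
rztpois <- function(n, mean) {
  stopifnot(mean >= 1)
  if (n == 0L) return(integer(0))
  if (mean < 1 + 1e-9) return(rep(1L, n))
  lam <- stats::uniroot(
    function(l) l / (1 - exp(-l)) - mean,
    lower = 1e-9, upper = mean * 2, tol = 1e-10
  )$root
  # inverse-CDF conditioned on X >= 1
  u <- stats::runif(n, min = exp(-lam), max = 1)
  as.integer(stats::qpois(u, lam))
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_invalid(sprintf("`%s` must be finite numeric", name))
  }
  lo_ok <- if (open_lower) all(x > lower) else all(x >= lower)
  hi_ok <- if (open_upper) all(x < upper) else all(x <= upper)
  if (!lo_ok || !hi_ok) {
    stop_invalid(sprintf(
      "`%s` must lie in %s%s, %s%s", name,
      if (open_lower) "(" else "[", format(lower),
      format(upper), if (open_upper) ")" else "]"
    ))
  }
  invisible(x)
}

check_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_invalid(sprintf(
      "`%s` is missing column(s): %s", name, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Derive a deterministic stream of sub-seeds (< 2^31) from a master seed.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
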