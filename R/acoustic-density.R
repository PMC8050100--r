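# Acoustic branch: group-counting density estimation from fixed passive
# acoustic monitoring sites. Window-level detections are binned into UTC
# days; only days with a full 24 h of recording effort are used, and each
# retained site-day yields D = 1000 * n (1 - c) s / (pi w^2 P_k P_v T) in
# animals per 1000 km^2.

#' Bin window-level acoustic detections into daily records
#'
#' Counts, per site and UTC calendar day, the total number of sampled
#' 5-minute windows and those with detections, computes daily recording
#' effort from an effort log of intervals, and keeps only days with full
#' 24-hour effort (tolerance: effort >= 23.999 h to absorb rounding in the
#' logs). Partial-effort days are dropped with a message; overlapping effort
#' intervals for a site are an error.
#'
#' @param windows Data frame with columns site_id, time (POSIXct, UTC) and
#'   detected (logical or 0/1): one row per sampled window.
#' @param effort Data frame with columns site_id, start, end (POSIXct, UTC):
#'   recording intervals; must not overlap within a site.
#' @param full_day_hours Effort threshold for retaining a day (default
#'   23.999).
#' @return Data frame of day records: site_id, date, n_windows_detected,
#'   n_windows_total, effort_hours. Full-effort days with zero detections
#'   are retained.
#' @export
bin_daily_detections <- function(windows, effort, full_day_hours = 23.999) {
  check_columns(windows, c("site_id", "time", "detected"), "windows")
  check_columns(effort, c("site_id", "start", "end"), "effort")
  windows$time <- as.POSIXct(windows$time, tz = "UTC")
  effort$start <- as.POSIXct(effort$start, tz = "UTC")
  effort$end <- as.POSIXct(effort$end, tz = "UTC")
  if (any(effort$end <= effort$start)) {
    stop_invalid("effort intervals must have end > start")
  }
  # overlapping-interval check per site
  for (sid in unique(effort$site_id)) {
    e <- effort[effort$site_id == sid, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])) {
      stop_invalid(sprintf("overlapping effort intervals for site '%s'", sid))
    }
  }

  # per-site-day effort hours: sum of interval intersections with each day
  effort_day <- do.call(rbind, lapply(seq_len(nrow(effort)), function(i) {
    s <- effort$start[i]; e <- effort$end[i]
    days <- seq(as.Date(s, tz = "UTC"), as.Date(e - 1e-6, tz = "UTC"), by = "day")
    h <- vapply(days, function(d) {
      d0 <- as.POSIXct(paste(d, "00:00:00"), tz = "UTC")
      as.numeric(difftime(min(e, d0 + 86400), max(s, d0), units = "hours"))
    }, numeric(1))
    data.frame(site_id = effort$site_id[i], date = days, hours = h)
  }))
  eff <- stats::aggregate(hours ~ site_id + date, data = effort_day, FUN = sum)

  windows$date <- as.Date(windows$time, tz = "UTC")
  tot <- stats::aggregate(detected ~ site_id + date, data = windows,
                          FUN = length)
  names(tot)[3] <- "n_windows_total"
  det <- stats::aggregate(detected ~ site_id + date, data = windows,
                          FUN = function(z) sum(z > 0))
  names(det)[3] <- "n_windows_detected"

  rec <- merge(merge(tot, det, by = c("site_id", "date")), eff,
               by = c("site_id", "date"), all.x = TRUE)
  rec$hours[is.na(rec$hours)] <- 0
  full <- rec$hours >= full_day_hours
  if (any(!full)) {
    message(sprintf("excluded %d partial-effort site-day(s) (< 24 h)",
                    sum(!full)))
  }
  rec <- rec[full, , drop = FALSE]
  out <- data.frame(
    site_id = rec$site_id, date = rec$date,
    n_windows_detected = rec$n_windows_detected,
    n_windows_total = rec$n_windows_total,
    effort_hours = rec$hours,
    stringsAsFactors = FALSE
  )
  out[order(out$site_id, out$date), , drop = FALSE]
}

#' Daily acoustic density by group counting
#'
#' \code{D = 1000 * n (1 - c) s / (pi w^2 P_k P_v T)} in animals per
#' 1000 km^2: the count of 5-minute windows with group detections, corrected
#' for false positives (c), scaled by mean group size (s), and normalized by
#' the monitored area (pi w^2, km^2), the probability of detecting a group
#' within range w (P_k), the probability that a group is vocally active in a
#' window (P_v), and the number of windows sampled (T).
#'
#' @param n Windows with detections (0 <= n <= t_windows).
#' @param c False-positive fraction, in [0, 1).
#' @param s Mean group size (>= 1).
#' @param w Maximum horizontal detection range (km), positive.
#' @param p_k Group detection probability, in (0, 1].
#' @param p_v Vocal-activity probability, in (0, 1].
#' @param t_windows Total windows sampled (positive).
#' @return Density in animals per 1000 km^2.
#' @export
daily_density <- function(n, c, s, w, p_k, p_v, t_windows) {
  check_number(n, "n", lower = 0)
  check_number(c, "c", lower = 0, upper = 1, open_upper = TRUE)
  check_number(s, "s", lower = 1)
  check_number(w, "w", lower = 0, open_lower = TRUE)
  check_number(p_k, "p_k", lower = 0, upper = 1, open_lower = TRUE)
  check_number(p_v, "p_v", lower = 0, upper = 1, open_lower = TRUE)
  check_number(t_windows, "t_windows", lower = 0, open_lower = TRUE)
  if (any(n > t_windows)) stop_invalid("`n` cannot exceed `t_windows`")
  1000 * n * (1 - c) * s / (pi * w^2 * p_k * p_v * t_windows)
}

#' Build the daily acoustic density table for one species
#'
#' Applies the group-counting estimator to every site-day record using the
#' site-specific parameter set (c_k, p_k, p_v, w_km, s_bar) from the sites
#' table.
#'
#' @param days Day records (site_id, date, n_windows_detected,
#'   n_windows_total, ...), e.g. from \code{\link{bin_daily_detections}} or
#'   \code{\link{simulate_pam_deployment}}.
#' @param sites Sites table (site_id, lon, lat, c_k, p_k, p_v, w_km, s_bar).
#' @param species Species label written on the records.
#' @return Data frame with one row per site-day: site_id, species, date,
#'   lon, lat, density_per_1000km2.
#' @export
build_acoustic_density_table <- function(days, sites, species = "species") {
  check_columns(days, c("site_id", "date", "n_windows_detected",
                        "n_windows_total"), "days")
  check_columns(sites, c("site_id", "lon", "lat", "c_k", "p_k", "p_v",
                         "w_km", "s_bar"), "sites")
  idx <- match(days$site_id, sites$site_id)
  if (any(is.na(idx))) {
    bad <- unique(days$site_id[is.na(idx)])
    stop_invalid(sprintf(
      "no parameter set for site(s) %s (species '%s')",
      paste(bad, collapse = ", "), species
    ))
  }
  s <- sites[idx, ]
  data.frame(
    site_id = days$site_id,
    species = species,
    date = days$date,
    lon = s$lon,
    lat = s$lat,
    density_per_1000km2 = daily_density(
      days$n_windows_detected, s$c_k, s$s_bar, s$w_km, s$p_k, s$p_v,
      days$n_windows_total
    ),
    stringsAsFactors = FALSE
  )
}
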