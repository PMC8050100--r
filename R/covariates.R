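# Covariate assembly: nearest-in-space-and-time matching of the seven
# stored environmental fields, derivation of the two eddy-distance
# covariates from SSH, the log transforms, and the [-1, 1] rescaling used by
# the neural networks.

#' Detect mesoscale eddy centres in an SSH field
#'
#' Eddy centres are local extrema of the SSH anomaly (the field minus its
#' spatial mean, a no-op safeguard when the product is already an anomaly)
#' under an 8-neighbour rule, whose absolute anomaly exceeds a threshold.
#' Cyclonic eddies are minima (negative anomaly), anticyclonic eddies are
#' maxima.
#'
#' @param ssh Matrix of SSH values, dimensions (lon, lat).
#' @param lon,lat Grid node coordinates matching \code{ssh}.
#' @param polarity "cyclonic" or "anticyclonic".
#' @param threshold Minimum absolute anomaly (m) for a centre (default 0.10).
#' @return Data frame of centres (lon, lat, anomaly); zero rows if none.
#' @export
detect_eddies <- function(ssh, lon, lat,
                          polarity = c("cyclonic", "anticyclonic"),
                          threshold = 0.10) {
  polarity <- match.arg(polarity)
  if (length(ssh) == 0) stop_invalid("empty SSH grid")
  stopifnot(nrow(ssh) == length(lon), ncol(ssh) == length(lat))
  anom <- ssh - mean(ssh)
  if (polarity == "cyclonic") anom <- -anom  # search maxima of -anomaly
  nr <- nrow(anom); nc <- ncol(anom)
  centres <- list()
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      v <- anom[i, j]
      if (v <= threshold) next
      nb <- anom[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
      if (v >= max(nb)) {
        centres[[length(centres) + 1]] <-
          c(lon = lon[i], lat = lat[j], anomaly = if (polarity == "cyclonic") -v else v)
      }
    }
  }
  if (length(centres) == 0) {
    return(data.frame(lon = numeric(0), lat = numeric(0),
                      anomaly = numeric(0)))
  }
  as.data.frame(do.call(rbind, centres))
}

#' Distance to the nearest eddy centre
#'
#' Haversine distance (km, R = 6371 km) from each point to its nearest
#' centre; ties go to the first centre in scan order. With no centres the
#' result is NA (the record is flagged missing and later dropped from model
#' tables).
#'
#' @param lon,lat Point coordinates (vectors).
#' @param centers Data frame of centres with lon and lat columns.
#' @return Numeric vector of distances (km), NA if \code{centers} is empty.
#' @export
eddy_distance <- function(lon, lat, centers) {
  n <- max(length(lon), length(lat))
  if (is.null(centers) || nrow(centers) == 0) return(rep(NA_real_, n))
  vapply(seq_len(n), function(i) {
    d <- haversine_km(rep(lon[min(i, length(lon))], nrow(centers)),
                      rep(lat[min(i, length(lat))], nrow(centers)),
                      centers$lon, centers$lat)
    d[which.min(d)]
  }, numeric(1))
}

#' Attach the nine environmental covariates to dated points
#'
#' For each point, selects the nearest time slice by absolute day difference
#' (ties to the earlier slice) and the nearest grid node by great-circle
#' distance (ties to the lower node index), reads the seven stored layers
#' there, and derives the two eddy-distance covariates from that slice's SSH
#' field. Points farther than \code{max_day_gap} days from any slice get all
#' covariates NA (missing flag).
#'
#' @param points Data frame with lon, lat and date columns.
#' @param env An \code{\link{env_fields}} object.
#' @param max_day_gap Maximum tolerated time gap in days (default 8).
#' @param eddy_threshold Anomaly threshold for
#'   \code{\link{detect_eddies}} (m).
#' @return \code{points} with the nine covariate columns appended
#'   (untransformed; see \code{\link{transform_covariates}}).
#' @export
match_covariates <- function(points, env, max_day_gap = 8,
                             eddy_threshold = 0.10) {
  stopifnot(inherits(env, "env_fields"))
  check_columns(points, c("lon", "lat", "date"), "points")
  dates <- as.Date(points$date)
  np <- nrow(points)

  # nearest time slice; ties break toward the earlier slice
  tdiff <- abs(outer(as.numeric(dates), as.numeric(env$dates), "-"))
  t_idx <- apply(tdiff, 1, which.min)  # which.min takes the first (earlier)
  gap <- tdiff[cbind(seq_len(np), t_idx)]
  ok <- gap <= max_day_gap

  # nearest grid node; ties break toward the lower node index
  nodes <- cbind(lon = rep(env$lon, times = length(env$lat)),
                 lat = rep(env$lat, each = length(env$lon)))
  node_idx <- vapply(seq_len(np), function(i) {
    d <- haversine_km(rep(points$lon[i], nrow(nodes)),
                      rep(points$lat[i], nrow(nodes)),
                      nodes[, 1], nodes[, 2])
    which.min(d)
  }, integer(1))
  ij <- arrayInd(node_idx, c(length(env$lon), length(env$lat)))

  out <- points
  for (nm in covariate_names()) out[[nm]] <- NA_real_
  for (nm in env_layer_names()) {
    out[[nm]][ok] <- env$layers[[nm]][cbind(ij[ok, 1, drop = FALSE],
                                            ij[ok, 2, drop = FALSE],
                                            t_idx[ok])]
  }

  # eddy distances, per unique matched slice
  for (t in unique(t_idx[ok])) {
    rows <- which(ok & t_idx == t)
    ssh <- env$layers$SSH[, , t]
    cyc <- detect_eddies(ssh, env$lon, env$lat, "cyclonic", eddy_threshold)
    anti <- detect_eddies(ssh, env$lon, env$lat, "anticyclonic",
                          eddy_threshold)
    out$posEddyDist[rows] <- eddy_distance(points$lon[rows],
                                           points$lat[rows], cyc)
    out$negEddyDist[rows] <- eddy_distance(points$lon[rows],
                                           points$lat[rows], anti)
  }
  n_missing <- sum(!stats::complete.cases(out[covariate_names()]))
  if (n_missing > 0) {
    message(sprintf(
      "%d point(s) have missing covariates (time gap or no eddy present)",
      n_missing
    ))
  }
  out
}

#' Log-transform the skewed covariates
#'
#' Applies the natural log to CHL, MLD and CUR (which must be strictly
#' positive); all other covariates pass through unchanged.
#'
#' @param table Data frame containing CHL, MLD and CUR columns.
#' @return The table with those columns log-transformed.
#' @export
transform_covariates <- function(table) {
  for (nm in c("CHL", "MLD", "CUR")) {
    if (!nm %in% names(table)) next
    v <- table[[nm]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad) > 0) {
      stop_invalid(sprintf(
        "non-positive %s at record(s) %s cannot be log-transformed",
        nm, paste(utils::head(bad, 5), collapse = ", ")
      ))
    }
    table[[nm]] <- log(v)
  }
  table
}

#' Observed covariate ranges of a training table
#'
#' Per-covariate minimum and maximum over a (training) table; these ranges
#' drive both the [-1, 1] neural-network rescaling and out-of-range
#' prediction masking.
#'
#' @param table Data frame containing the nine covariate columns.
#' @param covariates Covariate names (default the canonical nine).
#' @return Data frame with covariate, min, max.
#' @export
covariate_ranges <- function(table, covariates = covariate_names()) {
  check_columns(table, covariates, "table")
  data.frame(
    covariate = covariates,
    min = vapply(covariates, function(nm) min(table[[nm]], na.rm = TRUE),
                 numeric(1)),
    max = vapply(covariates, function(nm) max(table[[nm]], na.rm = TRUE),
                 numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Rescale covariates to [-1, 1] by training ranges
#'
#' Affine map \code{x' = 2 (x - min) / (max - min) - 1} per covariate, with
#' min/max taken from a training table's ranges: training minima map to -1
#' and maxima to +1 exactly. Values outside the training range map outside
#' [-1, 1] (used later for masking). A degenerate covariate (max = min) is
#' an error.
#'
#' @param table Data frame with the covariate columns.
#' @param ranges Ranges from \code{\link{covariate_ranges}}.
#' @return The table with covariate columns rescaled.
#' @export
scale_for_nn <- function(table, ranges) {
  check_columns(ranges, c("covariate", "min", "max"), "ranges")
  for (i in seq_len(nrow(ranges))) {
    nm <- ranges$covariate[i]
    lo <- ranges$min[i]; hi <- ranges$max[i]
    if (hi <= lo) {
      stop_invalid(sprintf("degenerate predictor '%s': max equals min", nm))
    }
    table[[nm]] <- 2 * (table[[nm]] - lo) / (hi - lo) - 1
  }
  table
}
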