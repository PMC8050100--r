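# Visual branch: line-transect distance sampling. Perpendicular sighting
# distances determine a truncation distance w (95th percentile), a detection
# function selected by AIC among the standard candidate forms, and
# per-segment densities D = 1000 * G_tot / (2 w L * g0 * P_vis) in animals
# per 1000 km^2.

#' Evaluate a detection function g(x)
#'
#' Probability of detecting a group at perpendicular distance x for the
#' supported forms: \code{"uniform"} (g = 1), \code{"half-normal"}
#' (\code{exp(-x^2 / (2 sigma^2))}), \code{"hazard-rate"}
#' (\code{1 - exp(-(x/sigma)^-b)}), and \code{"hazard-rate-poly"}, the
#' hazard-rate key with a second-order simple polynomial adjustment
#' \code{(1 + a2 (x/w)^2)}; with this parameterization g(0) = 1 for every
#' form.
#'
#' @param x Perpendicular distances (km), nonnegative.
#' @param form One of the form names above.
#' @param pars List with the needed elements among \code{sigma}, \code{b},
#'   \code{a2}, \code{w} (w scales the polynomial adjustment).
#' @return Numeric vector of detection probabilities (clamped to [0, Inf);
#'   the adjustment can formally exceed 1 away from the line).
#' @export
detection_g <- function(x, form, pars = list()) {
  g <- switch(form,
    "uniform" = rep(1, length(x)),
    "half-normal" = exp(-x^2 / (2 * pars$sigma^2)),
    "hazard-rate" = ,
    "hazard-rate-poly" = {
      key <- ifelse(x <= 0, 1, 1 - exp(-(x / pars$sigma)^(-pars$b)))
      if (form == "hazard-rate-poly") {
        key <- key * (1 + pars$a2 * (x / pars$w)^2)
      }
      key
    },
    stop_invalid("unknown detection form: ", form)
  )
  pmax(g, 0)
}

# Mean of g over [0, w] (average detection probability within the strip).
mean_detection_probability <- function(form, pars, w) {
  if (form == "uniform") return(1)
  stats::integrate(function(x) detection_g(x, form, pars),
                   lower = 0, upper = w, rel.tol = 1e-9)$value / w
}

#' Effective strip half-width from sighting distances
#'
#' The truncation distance w: the empirical 95th percentile of the
#' perpendicular sighting distances, using the linear-interpolation quantile
#' rule (type 7).
#'
#' @param distances Perpendicular distances (km); at least one.
#' @param prob Quantile level (default 0.95).
#' @return w in km.
#' @export
effective_strip_halfwidth <- function(distances, prob = 0.95) {
  if (length(distances) == 0) {
    stop_invalid("`distances` must contain at least one value")
  }
  check_number(distances, "distances", lower = 0)
  unname(stats::quantile(distances, probs = prob, type = 7))
}

# Negative log-likelihood of distances under f(x) = g(x) / integral(g).
# Invalid parameter regions get a large finite penalty (L-BFGS-B requires
# finite objective values).
detfun_nll <- function(x, form, pars, w) {
  BIG <- 1e10
  g <- detection_g(x, form, pars)
  if (any(g <= 0)) return(BIG)
  mu <- tryCatch(
    stats::integrate(function(z) detection_g(z, form, pars),
                     lower = 0, upper = w, rel.tol = 1e-8)$value,
    error = function(e) NA_real_
  )
  if (!is.finite(mu) || mu <= 0) return(BIG)
  nll <- -sum(log(g)) + length(x) * log(mu)
  if (!is.finite(nll)) BIG else nll
}

fit_one_form <- function(x, form, w) {
  n <- length(x)
  if (form == "uniform") {
    ll <- -n * log(w)
    return(list(form = form, par = list(), loglik = ll, npar = 0L,
                aic = -2 * ll))
  }
  sig_starts <- unique(pmax(stats::quantile(x, c(0.3, 0.6)), w / 50))
  if (form == "half-normal") {
    fits <- lapply(sig_starts, function(s0) {
      stats::optim(log(s0),
                   function(p) detfun_nll(x, form, list(sigma = exp(p)), w),
                   method = "Brent",
                   lower = log(w / 100), upper = log(10 * w))
    })
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
    par <- list(sigma = exp(best$par))
    npar <- 1L
  } else if (form == "hazard-rate") {
    starts <- expand.grid(ls = log(sig_starts), lb = log(c(2, 5)))
    fits <- lapply(seq_len(nrow(starts)), function(i) {
      stats::optim(
        as.numeric(starts[i, ]),
        function(p) detfun_nll(x, form,
                               list(sigma = exp(p[1]), b = exp(p[2])), w),
        method = "L-BFGS-B",
        lower = c(log(w / 100), log(1)), upper = c(log(10 * w), log(20))
      )
    })
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
    par <- list(sigma = exp(best$par[1]), b = exp(best$par[2]))
    npar <- 2L
  } else if (form == "hazard-rate-poly") {
    hr <- fit_one_form(x, "hazard-rate", w)
    best <- stats::optim(
      c(log(hr$par$sigma), log(hr$par$b), 0),
      function(p) detfun_nll(
        x, form,
        list(sigma = exp(p[1]), b = exp(p[2]), a2 = p[3], w = w), w
      ),
      method = "L-BFGS-B",
      lower = c(log(w / 100), log(1), -1), upper = c(log(10 * w), log(20), 5)
    )
    par <- list(sigma = exp(best$par[1]), b = exp(best$par[2]),
                a2 = best$par[3], w = w)
    npar <- 3L
  } else {
    stop_invalid("unknown detection form: ", form)
  }
  if (!is.finite(best$value)) stop("non-finite likelihood")
  ll <- -best$value
  list(form = form, par = par, loglik = ll, npar = npar,
       aic = 2 * npar - 2 * ll)
}

#' Fit and select a detection function by AIC
#'
#' Fits each candidate form to the perpendicular distances within [0, w] by
#' maximum likelihood (multi-start over sigma for the parametric forms) and
#' returns the form with the lowest AIC, together with its average detection
#' probability \code{P_vis = (1/w) integral_0^w g(x) dx}. Forms whose
#' optimizer fails are excluded with a warning; an error is raised if every
#' form fails.
#'
#' @param distances Perpendicular distances (km).
#' @param truncation Truncation distance w (km); defaults to the 95th
#'   percentile of \code{distances} via
#'   \code{\link{effective_strip_halfwidth}}. Distances beyond w are
#'   discarded before fitting.
#' @param forms Candidate forms (see \code{\link{detection_g}}).
#' @param min_n Minimum number of distances required for parametric forms.
#' @return An object of class \code{"detection_fit"}: list with \code{form},
#'   \code{par}, \code{loglik}, \code{aic}, \code{p_vis}, \code{truncation},
#'   \code{n} and the full \code{aic_table}.
#' @export
fit_detection_function <- function(distances, truncation = NULL,
                                   forms = c("half-normal", "hazard-rate",
                                             "hazard-rate-poly", "uniform"),
                                   min_n = 10) {
  if (length(distances) == 0) stop_invalid("no distances supplied")
  w <- if (is.null(truncation)) effective_strip_halfwidth(distances) else truncation
  check_number(w, "truncation", lower = 0, open_lower = TRUE)
  x <- distances[distances <= w]
  parametric <- setdiff(forms, "uniform")
  if (length(x) < min_n && length(parametric) > 0) {
    forms <- intersect(forms, "uniform")
    if (length(forms) == 0) {
      stop_invalid(sprintf(
        "need at least %d distances within the truncation for parametric forms",
        min_n
      ))
    }
  }
  fits <- list()
  for (f in forms) {
    fit <- tryCatch(fit_one_form(x, f, w), error = function(e) {
      warning(sprintf("detection form '%s' failed to converge: %s",
                      f, conditionMessage(e)))
      NULL
    })
    if (!is.null(fit)) fits[[f]] <- fit
  }
  if (length(fits) == 0) stop("all detection-function forms failed to fit")
  aic_table <- data.frame(
    form = vapply(fits, `[[`, character(1), "form"),
    npar = vapply(fits, `[[`, integer(1), "npar"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  best <- fits[[which.min(aic_table$aic)]]
  p_vis <- mean_detection_probability(best$form, best$par, w)
  if (p_vis > 1) {
    warning("average detection probability exceeded 1; capped at 1")
    p_vis <- 1
  }
  structure(
    list(form = best$form, par = best$par, loglik = best$loglik,
         aic = best$aic, p_vis = p_vis, truncation = w, n = length(x),
         aic_table = aic_table[order(aic_table$aic), ]),
    class = "detection_fit"
  )
}

#' @export
print.detection_fit <- function(x, ...) {
  cat(sprintf("Detection function: %s (n = %d, w = %.3f km)\n",
              x$form, x$n, x$truncation))
  if (length(x$par) > 0) {
    cat("  parameters:",
        paste(sprintf("%s = %.4g", names(x$par),
                      unlist(x$par)), collapse = ", "), "\n")
  }
  cat(sprintf("  logLik = %.3f, AIC = %.3f, P_vis = %.4f\n",
              x$loglik, x$aic, x$p_vis))
  invisible(x)
}

#' Area monitored visually along a segment
#'
#' \code{A_vis = 2 w L}: twice the effective strip half-width times the
#' segment length.
#'
#' @param w Effective strip half-width (km), nonnegative.
#' @param L Segment length (km), positive.
#' @return Area in km^2.
#' @export
segment_area <- function(w, L) {
  check_number(w, "w", lower = 0)
  check_number(L, "L", lower = 0, open_lower = TRUE)
  2 * w * L
}

#' Per-segment visual density estimate
#'
#' \code{D = 1000 * G_tot / (A_vis * g0 * P_vis)} in animals per 1000 km^2,
#' where G_tot is the summed best group sizes of the segment's sightings,
#' A_vis the monitored area (km^2), g0 the trackline detection probability
#' and P_vis the average detection probability within the strip.
#'
#' @param g_tot Total animals sighted on the segment (>= 0).
#' @param a_vis Monitored area (km^2), positive.
#' @param g0,p_vis Probabilities in (0, 1].
#' @return Density in animals per 1000 km^2.
#' @export
segment_density <- function(g_tot, a_vis, g0 = 1, p_vis = 1) {
  check_number(g_tot, "g_tot", lower = 0)
  check_number(a_vis, "a_vis", lower = 0, open_lower = TRUE)
  check_number(g0, "g0", lower = 0, upper = 1, open_lower = TRUE)
  check_number(p_vis, "p_vis", lower = 0, upper = 1, open_lower = TRUE)
  1000 * g_tot / (a_vis * g0 * p_vis)
}

#' Build the per-segment visual density table for one species
#'
#' Computes the species truncation distance w and fitted detection function
#' once from all supplied sightings, then produces one record per segment:
#' segments without sightings of the species get density zero, and sightings
#' beyond w are excluded from G_tot.
#'
#' @param segments Segments data frame (segment_id, cruise, date, lon, lat,
#'   length_km).
#' @param sightings Sightings data frame (segment_id, species,
#'   perp_distance_km, group_size).
#' @param species Species label; must occur in \code{sightings} unless the
#'   sightings table is empty.
#' @param g0 Trackline detection probability for the species, in (0, 1].
#' @param forms Candidate detection forms passed to
#'   \code{\link{fit_detection_function}}.
#' @param truncation Optional fixed truncation distance (km); default is the
#'   95th-percentile rule.
#' @return Data frame with one row per segment (segment_id, species, date,
#'   lon, lat, density_per_1000km2, g_tot, a_vis_km2), with the
#'   \code{detection_fit} object attached as attribute
#'   \code{"detection_fit"}.
#' @export
build_visual_density_table <- function(segments, sightings, species,
                                       g0 = 1,
                                       forms = c("half-normal", "hazard-rate",
                                                 "hazard-rate-poly",
                                                 "uniform"),
                                       truncation = NULL) {
  check_columns(segments,
                c("segment_id", "cruise", "date", "lon", "lat", "length_km"),
                "segments")
  check_columns(sightings,
                c("segment_id", "species", "perp_distance_km", "group_size"),
                "sightings")
  check_number(g0, "g0", lower = 0, upper = 1, open_lower = TRUE)
  if (nrow(sightings) > 0 && !species %in% sightings$species) {
    stop_invalid(sprintf("unknown species label '%s' in sightings", species))
  }
  sp <- sightings[sightings$species == species, , drop = FALSE]
  unknown_seg <- setdiff(sp$segment_id, segments$segment_id)
  if (length(unknown_seg) > 0) {
    stop_invalid("sightings reference unknown segment(s): ",
                 paste(utils::head(unknown_seg, 5), collapse = ", "))
  }

  out <- data.frame(
    segment_id = segments$segment_id,
    species = species,
    date = segments$date,
    lon = segments$lon,
    lat = segments$lat,
    density_per_1000km2 = 0,
    g_tot = 0,
    a_vis_km2 = NA_real_,
    stringsAsFactors = FALSE
  )

  if (nrow(sp) == 0) {
    attr(out, "detection_fit") <- NULL
    return(out)
  }

  fit <- fit_detection_function(sp$perp_distance_km, truncation = truncation,
                                forms = forms)
  w <- fit$truncation
  kept <- sp[sp$perp_distance_km <= w, , drop = FALSE]
  g_tot <- tapply(kept$group_size, kept$segment_id, sum)
  idx <- match(names(g_tot), out$segment_id)
  out$g_tot[idx] <- as.numeric(g_tot)
  out$a_vis_km2 <- segment_area(w, segments$length_km)
  out$density_per_1000km2 <- segment_density(out$g_tot, out$a_vis_km2,
                                             g0 = g0, p_vis = fit$p_vis)
  attr(out, "detection_fit") <- fit
  out
}
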