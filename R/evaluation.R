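# Model evaluation: RMSE scoring, the 2-framework x 3-training-set
# experiment with per-framework best-model flags, gridded prediction maps
# and per-site prediction time series.

#' Root-mean-square error
#'
#' \code{sqrt(mean((y - yhat)^2))} over the pairs that survive masking:
#' pairs where \code{masked} is TRUE or either value is NA are excluded
#' pairwise.
#'
#' @param observations,predictions Numeric vectors of equal length.
#' @param masked Optional logical vector; TRUE rows are excluded.
#' @return RMSE as a single number.
#' @export
rmse <- function(observations, predictions, masked = NULL) {
  if (length(observations) != length(predictions)) {
    stop_invalid("`observations` and `predictions` must have equal length")
  }
  if (length(observations) == 0) stop_invalid("empty input")
  keep <- !is.na(observations) & !is.na(predictions)
  if (!is.null(masked)) keep <- keep & !masked
  if (!any(keep)) stop_invalid("no usable pairs remain after masking")
  sqrt(mean((observations[keep] - predictions[keep])^2))
}

#' Run the full model-comparison experiment for one species
#'
#' Trains every requested framework (GAM, NN) on every requested training
#' set (acoustic-only, visual-only, joint = the unweighted concatenation of
#' the two modality tables), evaluates each fitted model on the combined
#' test table with out-of-range rows excluded pairwise, and returns the
#' comparison table with the per-framework minimum RMSE flagged, Table-3
#' style. Per-modality test RMSEs are included as diagnostics. Fully
#' reproducible given \code{seed}.
#'
#' @param train_acoustic,train_visual Modality training tables
#'   (\code{density} + the nine covariates; a \code{modality} column is
#'   added/overwritten).
#' @param test Combined test table with a \code{modality} column
#'   ("visual"/"acoustic").
#' @param species Species label for the output rows.
#' @param frameworks Subset of c("GAM", "NN").
#' @param training_sets Subset of c("acoustic", "visual", "joint").
#' @param covariates Covariate names.
#' @param seed Integer seed driving the NN fits.
#' @param gam_args,nn_args Extra arguments for \code{\link{fit_density_gam}}
#'   / \code{\link{fit_nn_ensemble}}.
#' @return List with \code{comparison} (species, framework, training_set,
#'   rmse, rmse_visual, rmse_acoustic, n_test_used, n_masked, best),
#'   \code{models} (named list of fitted models) and \code{predictions}
#'   (named list of prediction data frames on the test table).
#' @export
run_experiment <- function(train_acoustic, train_visual, test,
                           species = "species",
                           frameworks = c("GAM", "NN"),
                           training_sets = c("acoustic", "visual", "joint"),
                           covariates = covariate_names(),
                           seed = 1, gam_args = list(), nn_args = list()) {
  frameworks <- match.arg(frameworks, c("GAM", "NN"), several.ok = TRUE)
  training_sets <- match.arg(training_sets,
                             c("acoustic", "visual", "joint"),
                             several.ok = TRUE)
  check_columns(test, c("density", "modality", covariates), "test")
  train_acoustic$modality <- "acoustic"
  train_visual$modality <- "visual"
  shared <- intersect(names(train_acoustic), names(train_visual))
  trains <- list(
    acoustic = train_acoustic,
    visual = train_visual,
    joint = rbind(train_acoustic[, shared, drop = FALSE],
                  train_visual[, shared, drop = FALSE])
  )

  rows <- list(); models <- list(); predictions <- list()
  for (fw in frameworks) {
    for (ts in training_sets) {
      tag <- paste(fw, ts, sep = "_")
      model <- tryCatch(
        if (fw == "GAM") {
          do.call(fit_density_gam,
                  c(list(train = trains[[ts]], covariates = covariates),
                    gam_args))
        } else {
          do.call(fit_nn_ensemble,
                  c(list(train = trains[[ts]], eval_table = test,
                         covariates = covariates, seed = seed,
                         leakage_warning = FALSE),
                    nn_args))
        },
        error = function(e) {
          stop(sprintf("model stage '%s' failed: %s", tag,
                       conditionMessage(e)), call. = FALSE)
        }
      )
      pred <- stats::predict(model, test)
      vis <- test$modality == "visual"
      rows[[tag]] <- data.frame(
        species = species, framework = fw, training_set = ts,
        rmse = rmse(test$density, pred$estimate, pred$masked),
        rmse_visual = if (any(vis & !pred$masked)) {
          rmse(test$density[vis], pred$estimate[vis], pred$masked[vis])
        } else NA_real_,
        rmse_acoustic = if (any(!vis & !pred$masked)) {
          rmse(test$density[!vis], pred$estimate[!vis], pred$masked[!vis])
        } else NA_real_,
        n_test_used = sum(!pred$masked),
        n_masked = sum(pred$masked),
        stringsAsFactors = FALSE
      )
      models[[tag]] <- model
      predictions[[tag]] <- pred
    }
  }
  comparison <- do.call(rbind, rows)
  rownames(comparison) <- NULL
  comparison$best <- FALSE
  for (fw in unique(comparison$framework)) {
    sel <- comparison$framework == fw
    comparison$best[sel] <- comparison$rmse[sel] == min(comparison$rmse[sel])
  }
  list(comparison = comparison, models = models, predictions = predictions)
}

#' Gridded prediction map for one time slice
#'
#' Assembles the nine covariates for every grid cell of an environmental
#' slice (eddy distances derived from that slice's SSH), applies the
#' covariate transforms, and predicts with the fitted model; cells outside
#' the training covariate ranges are masked (whitespace on a plotted map).
#'
#' @param model A fitted \code{density_gam} or \code{density_nn}.
#' @param env An \code{\link{env_fields}} object covering the date.
#' @param date Date of the slice to map.
#' @param eddy_threshold Eddy-detection threshold (m).
#' @return Data frame with lon, lat, estimate, masked (and sd for NN
#'   models).
#' @export
prediction_map <- function(model, env, date, eddy_threshold = 0.10) {
  stopifnot(inherits(env, "env_fields"))
  cells <- expand.grid(lon = env$lon, lat = env$lat)
  cells$date <- as.Date(date)
  cov <- match_covariates(cells, env, max_day_gap = Inf,
                          eddy_threshold = eddy_threshold)
  cov <- transform_covariates(cov)
  usable <- stats::complete.cases(cov[, model$covariates, drop = FALSE])
  pred <- data.frame(estimate = rep(NA_real_, nrow(cov)),
                     masked = rep(TRUE, nrow(cov)))
  if (inherits(model, "density_nn")) pred$sd <- NA_real_
  if (any(usable)) {
    pred[usable, names(pred)] <-
      stats::predict(model, cov[usable, , drop = FALSE])[, names(pred)]
  }
  cbind(cells[, c("lon", "lat")], pred)
}

#' Daily prediction time series at a monitoring site
#'
#' Predicts density for each day of a covariate series (one row per date
#' with the nine covariates). Days with missing covariates yield gaps (NA
#' estimates, masked), never zeros, so plotted series preserve recording
#' gaps.
#'
#' @param model A fitted density model.
#' @param covariate_series Data frame with a \code{date} column and the
#'   model's covariates.
#' @return Data frame with date, estimate, masked (and sd for NN models),
#'   one row per input day, in input order.
#' @export
prediction_timeseries <- function(model, covariate_series) {
  check_columns(covariate_series, "date", "covariate_series")
  n <- nrow(covariate_series)
  out <- data.frame(date = covariate_series$date,
                    estimate = rep(NA_real_, n),
                    masked = rep(TRUE, n))
  if (inherits(model, "density_nn")) out$sd <- NA_real_
  if (n == 0) return(out)
  check_columns(covariate_series, model$covariates, "covariate_series")
  usable <- stats::complete.cases(
    covariate_series[, model$covariates, drop = FALSE]
  )
  if (any(usable)) {
    pred <- stats::predict(model, covariate_series[usable, , drop = FALSE])
    out$estimate[usable] <- pred$estimate
    out$masked[usable] <- pred$masked
    if (inherits(model, "density_nn")) out$sd[usable] <- pred$sd
  }
  out
}
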