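# Distribution models. Two frameworks share one contract: they consume a
# model table (a `density` response plus the nine covariate columns), store
# the training covariate ranges, and predict with out-of-range masking.
#
# GAM: Tweedie family with log link; every covariate enters as a shrinkage
# smooth (bs = "ts") on a 3-knot basis, so uninformative terms can shrink to
# zero; after the first fit, uninformative terms are dropped and the model
# refit once.
#
# NN: an averaged ensemble of 25 single-hidden-layer networks per candidate
# hidden size (4..14 by default), inputs rescaled to [-1, 1] by training
# ranges, response log(density + delta), weight decay 1e-4, at most 500
# training iterations, initial weights in [-0.7, 0.7]; the hidden size
# minimizing RMSE on a held-out evaluation table is selected.

check_model_table <- function(table, covariates, need_response = TRUE) {
  cols <- covariates
  if (need_response) cols <- c("density", cols)
  check_columns(table, cols, "table")
  cc <- stats::complete.cases(table[, cols, drop = FALSE])
  if (any(!cc)) {
    stop_invalid(sprintf(
      "table has %d row(s) with missing values; drop them before fitting",
      sum(!cc)
    ))
  }
  invisible(table)
}

#' Fit a Tweedie shrinkage-smooth GAM density model
#'
#' Fits \code{density ~ s(SSH, bs = "ts", k = 3) + ...} over the nine
#' covariates with a Tweedie family (log link; the power p is estimated
#' during fitting, or fixed via \code{tweedie_p}). Terms judged
#' uninformative after the first fit -- effective degrees of freedom below
#' \code{drop_edf} or approximate p-value above \code{drop_p} -- are removed
#' and the model refit once.
#'
#' @param train Model table: a \code{density} column (animals per
#'   1000 km^2) plus the nine covariate columns (transformed scale).
#' @param covariates Covariate names (default \code{\link{covariate_names}}).
#' @param k Smooth basis dimension (default 3).
#' @param tweedie_p Optional fixed Tweedie power in (1, 2); default NULL
#'   estimates it (REML).
#' @param drop_edf,drop_p Term-removal thresholds: a term is uninformative
#'   when its edf < \code{drop_edf} or its approximate p-value >
#'   \code{drop_p}.
#' @param min_rows Minimum training rows (default 50).
#' @return Object of class \code{"density_gam"}: the mgcv fit, the retained
#'   term list, the training covariate ranges and the removal thresholds.
#' @export
fit_density_gam <- function(train, covariates = covariate_names(), k = 3,
                            tweedie_p = NULL, drop_edf = 0.5, drop_p = 0.05,
                            min_rows = 50) {
  check_model_table(train, covariates)
  if (nrow(train) < min_rows) {
    stop_invalid(sprintf("need at least %d training rows", min_rows))
  }
  fam <- if (is.null(tweedie_p)) {
    mgcv::tw(link = "log")
  } else {
    check_number(tweedie_p, "tweedie_p", lower = 1, upper = 2,
                 open_lower = TRUE, open_upper = TRUE)
    mgcv::Tweedie(p = tweedie_p, link = "log")
  }
  method <- if (is.null(tweedie_p)) "REML" else "GCV.Cp"
  gam_formula <- function(terms) {
    if (length(terms) == 0) return(stats::as.formula("density ~ 1"))
    stats::as.formula(paste(
      "density ~", paste(sprintf("s(%s, bs = 'ts', k = %d)", terms, k),
                         collapse = " + ")
    ))
  }
  fit <- mgcv::gam(gam_formula(covariates), family = fam, data = train,
                   method = method)
  st <- summary(fit)$s.table
  edf <- st[, "edf"]
  pval <- st[, "p-value"]
  keep <- edf >= drop_edf & pval <= drop_p
  retained <- covariates[keep]
  removed <- covariates[!keep]
  if (length(removed) > 0) {
    fit <- mgcv::gam(gam_formula(retained), family = fam, data = train,
                     method = method)
  }
  structure(
    list(fit = fit, retained = retained, removed = removed,
         covariates = covariates, ranges = covariate_ranges(train, covariates),
         k = k, drop_edf = drop_edf, drop_p = drop_p,
         n_train = nrow(train)),
    class = "density_gam"
  )
}

#' @export
print.density_gam <- function(x, ...) {
  cat(sprintf("Tweedie GAM density model (n = %d)\n", x$n_train))
  cat("  retained terms:",
      if (length(x$retained) > 0) paste(x$retained, collapse = ", ")
      else "(intercept only)", "\n")
  if (length(x$removed) > 0) {
    cat("  removed terms: ", paste(x$removed, collapse = ", "), "\n")
  }
  invisible(x)
}

# Rows with any covariate outside the stored training ranges.
out_of_range_mask <- function(table, ranges) {
  masked <- rep(FALSE, nrow(table))
  for (i in seq_len(nrow(ranges))) {
    x <- table[[ranges$covariate[i]]]
    masked <- masked | is.na(x) | x < ranges$min[i] | x > ranges$max[i]
  }
  masked
}

#' Predict from a fitted GAM density model
#'
#' Back-transformed (response-scale) predictions; rows with any covariate
#' outside the training range are masked and carry no estimate.
#'
#' @param object A \code{density_gam} model.
#' @param newdata Table with the model's covariate columns.
#' @param ... Unused.
#' @return Data frame with \code{estimate} (animals per 1000 km^2, NA where
#'   masked) and \code{masked}.
#' @export
predict.density_gam <- function(object, newdata, ...) {
  check_columns(newdata, object$covariates, "newdata")
  masked <- out_of_range_mask(newdata, object$ranges)
  est <- rep(NA_real_, nrow(newdata))
  if (any(!masked)) {
    est[!masked] <- as.numeric(mgcv::predict.gam(
      object$fit, newdata = newdata[!masked, , drop = FALSE],
      type = "response"
    ))
  }
  data.frame(estimate = est, masked = masked)
}

#' Fit an averaged neural-network ensemble density model
#'
#' For each candidate hidden-layer size, trains \code{n_nets} independent
#' single-hidden-layer networks on inputs rescaled to [-1, 1] by the
#' training ranges and the response \code{log(density + delta)}, each with
#' weight decay, an iteration cap and random initial weights in
#' \code{[-weight_range, weight_range]}. The ensemble output is the mean of
#' the member network outputs (log scale), back-transformed to a density;
#' the hidden size minimizing RMSE on the evaluation table (its
#' out-of-range rows excluded) is selected. The use of a held-out evaluation table for hidden-size
#' selection follows the original procedure and leaks test information into
#' that one choice; a warning notes this.
#'
#' @param train Model table (\code{density} + nine covariates).
#' @param eval_table Held-out table of the same schema used to select the
#'   hidden size.
#' @param covariates Covariate names.
#' @param hidden_sizes Candidate hidden-layer sizes (default 4:14).
#' @param n_nets Ensemble size per hidden size (default 25).
#' @param decay Weight decay (default 1e-4).
#' @param maxit Training iteration cap (default 500).
#' @param weight_range Initial weights drawn from
#'   \code{[-weight_range, weight_range]} (default 0.7).
#' @param delta Offset of the log response transform,
#'   \code{log(density + delta)} (default 1).
#' @param seed Integer seed; member seeds are derived deterministically.
#' @param leakage_warning Emit the hidden-size selection leakage warning
#'   (default TRUE).
#' @return Object of class \code{"density_nn"}: the 25 selected member
#'   networks, the per-size RMSE table, training ranges and scaling
#'   parameters.
#' @export
fit_nn_ensemble <- function(train, eval_table,
                            covariates = covariate_names(),
                            hidden_sizes = 4:14, n_nets = 25,
                            decay = 1e-4, maxit = 500, weight_range = 0.7,
                            delta = 1, seed = 1, leakage_warning = TRUE) {
  check_model_table(train, covariates)
  check_model_table(eval_table, covariates)
  if (nrow(eval_table) == 0) stop_invalid("`eval_table` must be non-empty")
  ranges <- covariate_ranges(train, covariates)
  x_train <- as.matrix(scale_for_nn(train[, covariates, drop = FALSE],
                                    ranges))
  y_train <- log(train$density + delta)
  masked_eval <- out_of_range_mask(eval_table, ranges)
  x_eval <- as.matrix(scale_for_nn(eval_table[, covariates, drop = FALSE],
                                   ranges))
  if (all(masked_eval)) {
    stop_invalid("every evaluation row is outside the training ranges")
  }
  if (leakage_warning) {
    warning(paste(
      "hidden-size selection uses the held-out evaluation table;",
      "its RMSE is not an unbiased skill estimate"
    ), call. = FALSE)
  }

  seeds <- matrix(derive_seeds(seed, length(hidden_sizes) * n_nets),
                  nrow = length(hidden_sizes))
  rmse_by_size <- numeric(length(hidden_sizes))
  nets_by_size <- vector("list", length(hidden_sizes))
  for (hi in seq_along(hidden_sizes)) {
    h <- hidden_sizes[hi]
    nets <- vector("list", n_nets)
    outputs <- matrix(NA_real_, nrow(x_eval), n_nets)
    for (m in seq_len(n_nets)) {
      set.seed(seeds[hi, m])
      nets[[m]] <- nnet::nnet(x_train, y_train, size = h, linout = TRUE,
                              decay = decay, maxit = maxit,
                              rang = weight_range, trace = FALSE,
                              MaxNWts = 5000)
      outputs[, m] <- as.numeric(stats::predict(nets[[m]], x_eval))
    }
    # members are averaged on the network-output (log) scale; only the
    # averaged output is back-transformed to a density
    ens <- pmax(exp(rowMeans(outputs)) - delta, 0)
    rmse_by_size[hi] <- rmse(eval_table$density[!masked_eval],
                             ens[!masked_eval])
    nets_by_size[[hi]] <- nets
  }
  best <- which.min(rmse_by_size)
  structure(
    list(nets = nets_by_size[[best]], hidden_size = hidden_sizes[best],
         size_table = data.frame(hidden_size = hidden_sizes,
                                 rmse = rmse_by_size),
         covariates = covariates, ranges = ranges, delta = delta,
         decay = decay, maxit = maxit, weight_range = weight_range,
         n_nets = n_nets, seed = seed, n_train = nrow(train)),
    class = "density_nn"
  )
}

#' @export
print.density_nn <- function(x, ...) {
  cat(sprintf(
    "Averaged NN ensemble density model (n = %d, %d members, hidden size %d)\n",
    x$n_train, x$n_nets, x$hidden_size
  ))
  cat(sprintf("  selection RMSE: %.4f\n",
              min(x$size_table$rmse)))
  invisible(x)
}

#' Predict from a fitted NN ensemble density model
#'
#' The ensemble output is the arithmetic mean of the member network outputs
#' (which live on the log(density + delta) scale); the averaged output is
#' then back-transformed to a density. The per-row \code{sd} is the
#' standard deviation across the member outputs, i.e. an uncertainty on the
#' log-density scale. Rows with any covariate outside the training range
#' are masked.
#'
#' @param object A \code{density_nn} model.
#' @param newdata Table with the model's covariate columns.
#' @param ... Unused.
#' @return Data frame with \code{estimate} (animals per 1000 km^2),
#'   \code{masked} and \code{sd} (member spread on the log scale; NA where
#'   masked).
#' @export
predict.density_nn <- function(object, newdata, ...) {
  check_columns(newdata, object$covariates, "newdata")
  masked <- out_of_range_mask(newdata, object$ranges)
  est <- rep(NA_real_, nrow(newdata))
  sdv <- rep(NA_real_, nrow(newdata))
  if (any(!masked)) {
    xs <- as.matrix(scale_for_nn(
      newdata[!masked, object$covariates, drop = FALSE], object$ranges
    ))
    outputs <- vapply(object$nets, function(net) {
      as.numeric(stats::predict(net, xs))
    }, numeric(nrow(xs)))
    outputs <- matrix(outputs, nrow = nrow(xs))
    est[!masked] <- pmax(exp(rowMeans(outputs)) - object$delta, 0)
    sdv[!masked] <- apply(outputs, 1, stats::sd)
  }
  data.frame(estimate = est, masked = masked, sd = sdv)
}

#' Variable importance of a fitted density model
#'
#' GAM: the effective degrees of freedom of each retained smooth (zero for
#' removed terms) with its approximate p-value. NN: the Olden
#' connection-weight product -- for each input, the sum over hidden nodes of
#' the input-to-hidden weight times the hidden-to-output weight, averaged
#' over the ensemble members -- which is signed.
#'
#' @param model A \code{density_gam} or \code{density_nn} model.
#' @return Data frame (covariate, importance, and p_value for GAMs), sorted
#'   by decreasing absolute importance.
#' @export
variable_importance <- function(model) {
  UseMethod("variable_importance")
}

#' @export
variable_importance.density_gam <- function(model) {
  imp <- stats::setNames(numeric(length(model$covariates)),
                         model$covariates)
  pv <- stats::setNames(rep(NA_real_, length(model$covariates)),
                        model$covariates)
  if (length(model$retained) > 0) {
    st <- summary(model$fit)$s.table
    term_names <- sub("^s\\((.*)\\)$", "\\1", rownames(st))
    imp[term_names] <- st[, "edf"]
    pv[term_names] <- st[, "p-value"]
  }
  out <- data.frame(covariate = names(imp), importance = unname(imp),
                    p_value = unname(pv), stringsAsFactors = FALSE)
  out[order(-abs(out$importance)), ]
}

#' @export
variable_importance.density_nn <- function(model) {
  covs <- model$covariates
  member_imp <- vapply(model$nets, function(net) {
    cf <- stats::coef(net)
    h <- model$hidden_size
    vapply(seq_along(covs), function(j) {
      sum(vapply(seq_len(h), function(k) {
        cf[[paste0("i", j, "->h", k)]] * cf[[paste0("h", k, "->o")]]
      }, numeric(1)))
    }, numeric(1))
  }, numeric(length(covs)))
  member_imp <- matrix(member_imp, nrow = length(covs))
  out <- data.frame(covariate = covs, importance = rowMeans(member_imp),
                    stringsAsFactors = FALSE)
  out[order(-abs(out$importance)), ]
}
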