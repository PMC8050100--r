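test_that("GAM shrinks pure-noise terms and calibrates to the mean", {
  # response fluctuates around a constant mean; all covariates are noise
  tab <- make_tweedie_table(400, seed = 1, intercept = log(4))
  fit <- fit_density_gam(tab)
  pred <- predict(fit, tab)
  expect_true(all(!pred$masked))
  # null model: predictions sit near the sample mean
  expect_lt(max(abs(pred$estimate - mean(tab$density))) / mean(tab$density),
            0.25)
  expect_equal(mean(pred$estimate), mean(tab$density), tolerance = 0.05)
  # most noise terms are shrunk away
  expect_lte(length(fit$retained), 3)

  # training-mean calibration of the Tweedie log link
  inf <- make_tweedie_table(400, seed = 2, intercept = log(3),
                            effects = list(SSH = function(x) 1.2 * x))
  fit2 <- fit_density_gam(inf)
  expect_equal(mean(predict(fit2, inf)$estimate), mean(inf$density),
               tolerance = 0.02)
})

test_that("GAM retains a strongly informative term and refits cleanly", {
  tab <- make_tweedie_table(500, seed = 3, intercept = log(3),
                            effects = list(SST = function(x) 1.5 * x))
  fit <- fit_density_gam(tab)
  expect_true("SST" %in% fit$retained)
  # the retained and removed lists partition the covariates
  expect_setequal(c(fit$retained, fit$removed), covariate_names())
  expect_length(intersect(fit$retained, fit$removed), 0)

  imp <- variable_importance(fit)
  expect_equal(imp$covariate[1], "SST")
  # removed terms carry zero importance
  expect_true(all(imp$importance[imp$covariate %in% fit$removed] == 0))

  expect_error(fit_density_gam(tab[1:20, ]), "at least 50")
})

test_that("GAM predictions mask exactly the out-of-range rows", {
  tab <- make_tweedie_table(300, seed = 4, intercept = log(3),
                            effects = list(SSH = function(x) x))
  fit <- fit_density_gam(tab)
  new <- tab[1:10, ]
  new$SSH[3] <- max(tab$SSH) + 1     # beyond the training maximum
  new$SST[7] <- min(tab$SST) - 0.5   # below the training minimum
  pred <- predict(fit, new)
  expect_equal(which(pred$masked), c(3L, 7L))
  expect_true(all(is.na(pred$estimate[pred$masked])))
  expect_true(all(pred$estimate[!pred$masked] >= 0))
  # a row identical to a training row is unmasked and finite
  expect_true(is.finite(pred$estimate[1]))
})

test_that("NN ensemble fits a constant response and is reproducible", {
  tab <- make_cov_table(120, seed = 5)
  tab$density <- 7
  ev <- make_cov_table(60, seed = 6, lo = -0.9, hi = 0.9)
  ev$density <- 7
  fit <- fit_nn_ensemble(tab, ev, hidden_sizes = 4, n_nets = 5,
                         seed = 2, leakage_warning = FALSE)
  pred <- predict(fit, ev)
  expect_lt(max(abs(pred$estimate - 7)) / 7, 0.01)
  expect_true(all(is.finite(pred$sd)) && all(pred$sd >= 0))

  # determinism: same seed, same selection and predictions
  fit2 <- fit_nn_ensemble(tab, ev, hidden_sizes = 4, n_nets = 5,
                          seed = 2, leakage_warning = FALSE)
  expect_identical(fit$hidden_size, fit2$hidden_size)
  expect_identical(predict(fit2, ev), pred)

  # the selection leakage warning is emitted by default
  expect_warning(
    fit_nn_ensemble(tab, ev, hidden_sizes = 4, n_nets = 2, seed = 2),
    "held-out"
  )
})

test_that("NN ensemble averages the member outputs arithmetically", {
  tab <- make_tweedie_table(150, seed = 7, intercept = log(3),
                            effects = list(SSH = function(x) x))
  ev <- make_tweedie_table(80, seed = 8, intercept = log(3),
                           effects = list(SSH = function(x) x))
  fit <- fit_nn_ensemble(tab, ev, hidden_sizes = c(4, 5), n_nets = 6,
                         seed = 3, leakage_warning = FALSE)
  expect_true(fit$hidden_size %in% c(4, 5))
  pred <- predict(fit, ev)

  # member networks output log(density + delta); the ensemble output is
  # their arithmetic mean and only that mean is back-transformed
  xs <- as.matrix(scale_for_nn(ev[, covariate_names()], fit$ranges))
  member <- sapply(fit$nets, function(net) as.numeric(predict(net, xs)))
  expect_equal(pred$estimate[!pred$masked],
               pmax(exp(rowMeans(member)) - fit$delta, 0)[!pred$masked],
               tolerance = 1e-12)
  expect_equal(pred$sd[!pred$masked],
               apply(member, 1, sd)[!pred$masked], tolerance = 1e-12)
})

test_that("ensemble spread shrinks as the ensemble grows", {
  # refitting the whole ensemble under different seeds: the averaged
  # prediction varies less between refits when more members are averaged
  refit_var <- function(tab, ev, n_nets, seeds) {
    preds <- sapply(seeds, function(s) {
      fit <- fit_nn_ensemble(tab, ev, hidden_sizes = 4, n_nets = n_nets,
                             seed = s, leakage_warning = FALSE)
      predict(fit, ev)$estimate
    })
    mean(apply(preds, 1, var), na.rm = TRUE)
  }
  deltas <- vapply(1:4, function(r) {
    tab <- make_tweedie_table(150, seed = 700 + r, intercept = log(3),
                              effects = list(SST = function(x) 0.8 * x))
    ev <- make_tweedie_table(60, seed = 800 + r, intercept = log(3),
                             effects = list(SST = function(x) 0.8 * x))
    seeds <- 900 + r * 10 + 1:3
    refit_var(tab, ev, 25, seeds) - refit_var(tab, ev, 5, seeds)
  }, numeric(1))
  expect_lt(median(deltas), 0)
})

test_that("NN importance is the signed Olden connection-weight product", {
  tab <- make_tweedie_table(200, seed = 9, intercept = log(3),
                            effects = list(SSH = function(x) 1.5 * x))
  ev <- make_tweedie_table(80, seed = 10, intercept = log(3),
                           effects = list(SSH = function(x) 1.5 * x))
  fit <- fit_nn_ensemble(tab, ev, hidden_sizes = 4, n_nets = 5,
                         seed = 4, leakage_warning = FALSE)
  imp <- variable_importance(fit)
  expect_setequal(imp$covariate, covariate_names())
  # the single driver dominates, with a positive sign
  expect_equal(imp$covariate[1], "SSH")
  expect_gt(imp$importance[imp$covariate == "SSH"], 0)

  # zeroing every connection from one input zeroes its importance
  h <- fit$hidden_size
  for (m in seq_along(fit$nets)) {
    cf <- coef(fit$nets[[m]])
    cf[grep("^i2->", names(cf))] <- 0
    fit$nets[[m]]$wts <- as.numeric(cf)
  }
  imp0 <- variable_importance(fit)
  expect_equal(imp0$importance[imp0$covariate == covariate_names()[2]], 0)
})

test_that("degenerate predictors are rejected at the scaling stage", {
  tab <- make_cov_table(100, seed = 11)
  tab$SAL <- 35                       # constant column
  tab$density <- 1
  ev <- tab[1:20, ]
  expect_error(
    fit_nn_ensemble(tab, ev, hidden_sizes = 4, n_nets = 2, seed = 1,
                    leakage_warning = FALSE),
    "degenerate"
  )
})
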