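# Exponential response-surface model: transform, design, prediction, fit.

test_that("mod transform and its inverse are exact", {
  expect_identical(mod_transform(0), 0.1)
  expect_equal(mod_transform(0.5), 50.1)
  expect_equal(mod_transform(1), 100.1)
  x <- seq(0, 1, by = 0.05)
  expect_equal(mod_inverse(mod_transform(x)), x, tolerance = 1e-14)
})

test_that("design rows match an independent term-by-term evaluation", {
  # log terms vanish at 1 ppm
  X1 <- design_matrix(data.frame(ligand = "MEE", size = 3, concentration = 1))
  expect_equal(unname(X1[1, c("log_conc", "log_conc_x_sasa_over_polar",
                              "log_conc_sq")]), c(0, 0, 0))

  # descriptor entries for TMAT
  Xt <- design_matrix(data.frame(ligand = "TMAT", size = 2,
                                 concentration = 0.2))
  expect_equal(unname(Xt[1, c("sasa_over_polar", "refractivity",
                              "band_gap")]), c(7.39, 48.38, -215.8))

  # independent oracle: every term written out longhand for MES, size 10,
  # concentration e (so ln C = 1)
  d <- gold_ligand_descriptors()
  mes <- d[d$ligand == "MES", ]
  Xm <- design_matrix(data.frame(ligand = "MES", size = 10,
                                 concentration = exp(1)))
  longhand <- c(1, 1, 10, mes$sasa_over_polar, mes$refractivity, mes$band_gap,
                1 * mes$sasa_over_polar, 10 * mes$band_gap, 1, 100)
  expect_equal(unname(Xm[1, ]), longhand, tolerance = 1e-12)

  expect_error(design_matrix(data.frame(ligand = "MES", size = 1,
                                        concentration = 0)), "positive")
  expect_error(design_matrix(data.frame(ligand = "XYZ", size = 1,
                                        concentration = 1)), "XYZ")
})

test_that("predictions equal the longhand linear predictor exponentiated", {
  beta0 <- stats::setNames(rep(0, 10), names(reference_model_coefficients()))
  expect_equal(predict_mod_ez(beta0, data.frame(ligand = "MEE", size = 5,
                                                concentration = 3)), 1.0)

  beta <- reference_model_coefficients()
  d <- gold_ligand_descriptors()
  tm <- d[d$ligand == "TMAT", ]
  lc <- log(0.2)
  eta <- beta[["intercept"]] + beta[["log_conc"]] * lc +
    beta[["size"]] * 2 + beta[["sasa_over_polar"]] * tm$sasa_over_polar +
    beta[["refractivity"]] * tm$refractivity +
    beta[["band_gap"]] * tm$band_gap +
    beta[["log_conc_x_sasa_over_polar"]] * lc * tm$sasa_over_polar +
    beta[["size_x_band_gap"]] * 2 * tm$band_gap +
    beta[["log_conc_sq"]] * lc^2 + beta[["size_sq"]] * 4
  expect_equal(
    predict_mod_ez(beta, data.frame(ligand = "TMAT", size = 2,
                                    concentration = 0.2)),
    exp(eta), tolerance = 1e-9)

  # shifting the intercept scales every prediction by the same factor
  obs <- data.frame(ligand = c("MEE", "MES"), size = c(1, 4),
                    concentration = c(0.5, 100))
  beta2 <- beta; beta2[["intercept"]] <- beta[["intercept"]] + 0.7
  expect_equal(predict_mod_ez(beta2, obs),
               exp(0.7) * predict_mod_ez(beta, obs), tolerance = 1e-12)
  expect_true(all(predict_mod_ez(beta, obs) > 0))

  # overflow guard clips with a warning instead of returning Inf
  beta_big <- beta; beta_big[["intercept"]] <- 2000
  expect_warning(p <- predict_mod_ez(beta_big, obs), "clipped")
  expect_true(all(is.finite(p)))
})

test_that("noise-free model data are refit exactly from the OLS start", {
  obs <- simulate_model_observations(noise_sd = 0)
  fit <- fit_response_model(obs)
  truth <- reference_model_coefficients()
  expect_equal(unname(fit$coefficients), unname(truth), tolerance = 1e-6)
  expect_lt(max(abs(fit$coefficients - truth) / abs(truth)), 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_lte(fit$iterations, 2)
  expect_length(detect_outliers(fit), 0)
})

test_that("rank-deficient designs fail with the collinear column named", {
  obs <- simulate_model_observations(sizes = 2)  # single size: size^2 aliased
  expect_error(fit_response_model(obs), "size")
})

test_that("gross contamination is flagged and removable by refitting", {
  obs <- simulate_model_observations(noise_sd = 0)
  obs$mod_ez[42] <- obs$mod_ez[42] * 1000
  fit <- fit_response_model(obs)
  flagged <- detect_outliers(fit)
  expect_identical(flagged, "42")
  # a looser threshold can only grow the flagged set
  expect_true(all(flagged %in% detect_outliers(fit, threshold = 2)))

  refit <- fit_response_model(obs, remove_outliers = TRUE)
  expect_identical(refit$outliers_removed, "42")
  expect_equal(refit$n_used, nrow(obs) - 1)
  expect_equal(unname(refit$coefficients),
               unname(reference_model_coefficients()), tolerance = 1e-6)

  # extreme contamination distorts the least-squares fit enough to drag
  # clean points over the threshold (swamping); the contaminant is still
  # flagged, and remove-and-refit still recovers the generating surface
  obs2 <- simulate_model_observations(noise_sd = 0)
  obs2$mod_ez[42] <- obs2$mod_ez[42] * 1e6
  fit2 <- suppressWarnings(fit_response_model(obs2))
  expect_true("42" %in% detect_outliers(fit2))
  refit2 <- suppressWarnings(fit_response_model(obs2,
                                                remove_outliers = TRUE))
  expect_true("42" %in% refit2$outliers_removed)
  expect_equal(unname(refit2$coefficients),
               unname(reference_model_coefficients()), tolerance = 1e-6)
})

test_that("noisy fits agree with the reference NLS implementation", {
  obs <- simulate_model_observations(noise_sd = 2, seed = 99)
  fit <- fit_response_model(obs)
  X <- design_matrix(obs)
  df <- cbind(as.data.frame(X), y = obs$mod_ez)
  form <- stats::as.formula(paste(
    "y ~ exp(", paste(sprintf("b%d*%s", 1:10, colnames(X)), collapse = "+"),
    ")"))
  start <- stats::setNames(as.list(fit$coefficients * 0.999),
                           paste0("b", 1:10))
  ref <- minpack.lm::nlsLM(form, data = df, start = start,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 500, ftol = 1e-12))
  # both optimizers stop inside the same flat valley; agreement well within
  # a small fraction of a standard error is what matters
  expect_lt(max(abs(fit$coefficients - stats::coef(ref)) /
                  fit$standard_errors), 0.05)
  expect_equal(unname(fit$standard_errors),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-2)
})

test_that("response surfaces follow the model over grids", {
  beta <- reference_model_coefficients()
  # a 1x1 grid is a single prediction
  s <- response_surface(beta, "TMAT", 2, 0.2)
  expect_equal(unname(s[1, 1]),
               predict_mod_ez(beta, data.frame(ligand = "TMAT", size = 2,
                                               concentration = 0.2)))
  # toxicity of small cationic particles: decreasing in size at low dose
  s2 <- response_surface(beta, "TMAT", c(0.8, 2, 10), 0.05, scale = "ez")
  expect_true(all(diff(s2[, 1]) < 0))
  # grid ordering does not change cell values
  s3 <- response_surface(beta, "MEE", c(1, 5), c(0.1, 10))
  s4 <- response_surface(beta, "MEE", c(5, 1), c(10, 0.1))
  expect_equal(s3["1", "10"], s4["1", "10"])
  expect_equal(s3["5", "0.1"], s4["5", "0.1"])
  expect_true(all(s3 > 0))
  expect_error(response_surface(beta, "MEE", c(-1, 5), 1), "positive")
})
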