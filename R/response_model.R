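# Exponential response-surface model of gold-nanoparticle toxicity.
#
# The modified score mod = 100 * EZ + 0.1 (the offset avoids log(0)) is
# modelled as
#
#   mod = exp(b0 + b1 ln C + b2 S + b3 SASA/Polar + b4 Refr + b5 Gap
#             + b13 ln C * SASA/Polar + b25 S * Gap + b11 (ln C)^2
#             + b22 S^2),
#
# with C the exposure concentration in ppm (natural log; the unit choice
# shifts only the intercept), S the primary particle diameter in nm, and the
# three ligand descriptors taken from the packaged table. Coefficients are
# estimated by unweighted nonlinear least squares (Levenberg-Marquardt with
# the analytic Jacobian), initialized at the ordinary least-squares fit of
# ln(mod) on the design matrix -- for noise-free model data that start is
# already the optimum and the fitter stops immediately.

.EZ_MODEL_TERMS <- c("intercept", "log_conc", "size", "sasa_over_polar",
                     "refractivity", "band_gap", "log_conc_x_sasa_over_polar",
                     "size_x_band_gap", "log_conc_sq", "size_sq")

# Linear predictors above this bound are clipped before exponentiation to
# guard against overflow (exp(700) is near the double limit).
.EZ_ETA_MAX <- 700

#' Modified EZ score transformation
#'
#' Maps a raw EZ score to the strictly positive model scale:
#' `100 * score + 0.1`. The 0.1 offset avoids the discontinuity of taking a
#' logarithm of zero scores. `mod_inverse()` is the exact inverse.
#'
#' @param ez_score Raw weighted EZ score(s).
#' @return Numeric of the same length.
#' @export
#' @examples
#' mod_transform(0)    # 0.1
#' mod_transform(0.5)  # 50.1
mod_transform <- function(ez_score) {
  stopifnot(all(is.finite(ez_score)))
  100 * ez_score + 0.1
}

#' @rdname mod_transform
#' @param mod_ez Modified score(s).
#' @export
mod_inverse <- function(mod_ez) {
  (mod_ez - 0.1) / 100
}

#' Design matrix for the response-surface model
#'
#' Builds the ten-term design rows `[1, ln C, S, SASA/Polar, Refr, Gap,
#' ln C * SASA/Polar, S * Gap, (ln C)^2, S^2]` for a set of observations,
#' joining ligand descriptors by ligand name.
#'
#' @param obs Data.frame with columns `ligand`, `size` (nm) and
#'   `concentration` (ppm, strictly positive).
#' @param descriptors Ligand descriptor table; defaults to
#'   [gold_ligand_descriptors()].
#' @return Numeric matrix with one row per observation and columns named by
#'   model term.
#' @export
design_matrix <- function(obs, descriptors = gold_ligand_descriptors()) {
  req <- c("ligand", "size", "concentration")
  missing <- setdiff(req, names(obs))
  if (length(missing) > 0) {
    stop("observations lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(obs$concentration <= 0)) {
    stop("concentrations must be strictly positive for the log transform",
         call. = FALSE)
  }
  hit <- match(obs$ligand, descriptors$ligand)
  if (anyNA(hit)) {
    stop("no descriptors for ligand(s): ",
         paste(unique(obs$ligand[is.na(hit)]), collapse = ", "),
         call. = FALSE)
  }
  d <- descriptors[hit, , drop = FALSE]
  lc <- log(obs$concentration)
  X <- cbind(1, lc, obs$size, d$sasa_over_polar, d$refractivity, d$band_gap,
             lc * d$sasa_over_polar, obs$size * d$band_gap, lc^2, obs$size^2)
  colnames(X) <- .EZ_MODEL_TERMS
  X
}

#' Predict modified EZ scores from model coefficients
#'
#' Evaluates `exp(X beta)` for a set of observations. The linear predictor is
#' clipped at 700 (with a warning) to guard exp overflow.
#'
#' @param beta Named numeric vector of 10 coefficients (see
#'   [reference_model_coefficients()] for term order).
#' @inheritParams design_matrix
#' @return Strictly positive numeric vector of predictions on the mod scale.
#' @export
predict_mod_ez <- function(beta, obs, descriptors = gold_ligand_descriptors()) {
  beta <- beta[.EZ_MODEL_TERMS]
  if (anyNA(beta)) stop("beta must name all 10 model terms", call. = FALSE)
  eta <- drop(design_matrix(obs, descriptors) %*% beta)
  if (any(eta > .EZ_ETA_MAX)) {
    warning("linear predictor clipped at ", .EZ_ETA_MAX, " to avoid overflow")
    eta <- pmin(eta, .EZ_ETA_MAX)
  }
  exp(eta)
}

# Levenberg-Marquardt minimization of sum((y - exp(X b))^2) with analytic
# Jacobian J = exp(X b) * X. The damped step min ||r - J d||^2 + l ||D d||^2
# (D = column norms of J, Marquardt scaling) is solved through the QR of the
# augmented Jacobian, which keeps the effective condition at cond(J) rather
# than cond(J)^2 -- fitted values here span many orders of magnitude.
# Returns beta, SSE, iterations, convergence flag.
lm_exp_fit <- function(X, y, beta0, tol = 1e-10, max_iter = 500) {
  clip_eta <- function(eta) pmin(eta, .EZ_ETA_MAX)
  p <- ncol(X)
  beta <- beta0
  f <- exp(clip_eta(drop(X %*% beta)))
  sse <- sum((y - f)^2)
  # data consistent with the model to machine precision (e.g. noise-free
  # log-linear data, where the OLS start is already the optimum)
  sse_floor <- .Machine$double.eps^1.5 * max(sum(y^2), 1)
  lambda <- 1e-4
  converged <- sse <= sse_floor
  it <- 0
  while (!converged && it < max_iter) {
    it <- it + 1
    J <- f * X
    r <- y - f
    d <- sqrt(colSums(J^2))
    d[d == 0] <- 1
    improved <- FALSE
    for (try in 1:50) {
      A <- rbind(J, diag(sqrt(lambda) * d, p))
      delta <- tryCatch(qr.coef(qr(A), c(r, numeric(p))),
                        error = function(e) NULL)
      if (!is.null(delta) && !anyNA(delta)) {
        beta_new <- beta + delta
        f_new <- exp(clip_eta(drop(X %*% beta_new)))
        sse_new <- sum((y - f_new)^2)
        if (is.finite(sse_new) && sse_new <= sse) {
          rel <- (sse - sse_new) / max(sse, .Machine$double.eps)
          beta <- beta_new; f <- f_new; sse <- sse_new
          lambda <- max(lambda / 10, 1e-14)
          improved <- TRUE
          if (rel < tol || sse <= sse_floor) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e14) break
    }
    if (!improved) converged <- TRUE  # no descent direction left
  }
  list(beta = beta, fitted = f, sse = sse, iterations = it,
       converged = converged)
}

#' Fit the exponential response-surface model
#'
#' Estimates the ten coefficients by unweighted nonlinear least squares on
#' the mod scale (see the model description above). Standard errors come from
#' `s^2 (J'J)^-1` at the optimum with `J` the analytic Jacobian; p-values
#' from the t distribution with `n - 10` degrees of freedom; `r_squared` is
#' `1 - SSE/SST` on the mod scale (an R^2 on the log scale is reported
#' alongside, as the scale on which goodness of fit is judged is a
#' modelling choice). With `remove_outliers = TRUE` observations with
#' externally studentized residuals beyond `outlier_threshold` are dropped
#' once and the model refit (mirroring a remove-then-refit screening flow).
#'
#' @param obs Data.frame with columns `ligand`, `size`, `concentration` and
#'   either `mod_ez` or `ez_score` (the latter is mod-transformed).
#' @param descriptors Ligand descriptor table (default
#'   [gold_ligand_descriptors()]).
#' @param remove_outliers Screen and refit once? Default `FALSE`.
#' @param outlier_threshold Absolute externally studentized residual above
#'   which an observation is flagged (default 3).
#' @param tol Relative SSE convergence tolerance (default 1e-10).
#' @param max_iter Iteration cap (default 500).
#' @return Object of class `ez_model_fit`: `coefficients`,
#'   `standard_errors`, `t_values`, `p_values`, `r_squared`,
#'   `r_squared_log`, `sigma`, `n_used`, `outliers_removed`, `fitted`,
#'   `residuals`, `iterations`, `converged`, plus the design matrix.
#' @export
fit_response_model <- function(obs, descriptors = gold_ligand_descriptors(),
                               remove_outliers = FALSE, outlier_threshold = 3,
                               tol = 1e-10, max_iter = 500) {
  obs <- as.data.frame(obs)
  if (!"mod_ez" %in% names(obs)) {
    if (!"ez_score" %in% names(obs)) {
      stop("observations need a 'mod_ez' or 'ez_score' column", call. = FALSE)
    }
    obs$mod_ez <- mod_transform(obs$ez_score)
  }
  ids <- rownames(obs)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(obs)))
  keep <- obs$concentration > 0
  obs <- obs[keep, , drop = FALSE]; ids <- ids[keep]
  if (any(obs$mod_ez <= 0)) {
    stop("mod_ez values must be strictly positive", call. = FALSE)
  }
  fit1 <- fit_core(obs, ids, descriptors, tol, max_iter)
  if (!remove_outliers) return(fit1)
  out <- detect_outliers(fit1, threshold = outlier_threshold)
  if (length(out) == 0) return(fit1)
  keep <- !(ids %in% out)
  fit2 <- fit_core(obs[keep, , drop = FALSE], ids[keep], descriptors,
                   tol, max_iter)
  fit2$outliers_removed <- out
  fit2
}

fit_core <- function(obs, ids, descriptors, tol, max_iter) {
  X <- design_matrix(obs, descriptors)
  y <- obs$mod_ez
  n <- nrow(X); p <- ncol(X)
  if (n < p + 1) stop("need at least ", p + 1, " observations", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta0 <- qr.coef(qrX, log(y))
  fit <- lm_exp_fit(X, y, beta0, tol = tol, max_iter = max_iter)
  if (!is.finite(fit$sse)) {
    stop("nonlinear least squares failed: non-finite objective after ",
         fit$iterations, " iterations", call. = FALSE)
  }
  if (!fit$converged) {
    warning("iteration cap (", max_iter, ") reached before the relative ",
            "SSE tolerance; returning the best fit found (SSE ",
            format(fit$sse), ")")
  }
  beta <- stats::setNames(fit$beta, colnames(X))
  r <- y - fit$fitted
  dfree <- n - p
  s2 <- fit$sse / dfree
  J <- fit$fitted * X
  # (J'J)^-1 via the QR of J: numerically safer than inverting J'J when
  # fitted values span many orders of magnitude
  Rm <- qr.R(qr(J))
  cov_beta <- s2 * chol2inv(Rm)
  se <- sqrt(diag(cov_beta))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = dfree)
  eta <- log(fit$fitted)
  structure(list(
    coefficients = beta, standard_errors = se, t_values = tval,
    p_values = pval,
    r_squared = 1 - fit$sse / sum((y - mean(y))^2),
    r_squared_log = 1 - sum((log(y) - eta)^2) / sum((log(y) - mean(log(y)))^2),
    sigma = sqrt(s2), n_used = n, df = dfree,
    outliers_removed = character(0),
    fitted = fit$fitted, residuals = r, ids = ids,
    design = X, y = y, iterations = fit$iterations,
    converged = fit$converged
  ), class = "ez_model_fit")
}

#' @export
print.ez_model_fit <- function(x, ...) {
  cat("Exponential response-surface model fit\n")
  cat(sprintf("  n = %d, R-squared (mod scale) = %.4f, sigma = %.4g\n",
              x$n_used, x$r_squared, x$sigma))
  if (length(x$outliers_removed) > 0) {
    cat("  outliers removed:", paste(x$outliers_removed, collapse = ", "),
        "\n")
  }
  tab <- data.frame(estimate = x$coefficients, std_error = x$standard_errors,
                    p_value = signif(x$p_values, 3))
  print(tab, ...)
  invisible(x)
}

#' Flag outlying observations of a model fit
#'
#' Computes externally studentized residuals using the leverage of the
#' Jacobian at the optimum and flags observations whose absolute value
#' exceeds `threshold`.
#'
#' @param fit An `ez_model_fit` from [fit_response_model()].
#' @param threshold Absolute studentized-residual cutoff (default 3); a lower
#'   threshold flags a superset.
#' @return Character vector of observation ids (row names of the input).
#' @export
detect_outliers <- function(fit, threshold = 3) {
  stopifnot(inherits(fit, "ez_model_fit"))
  sse <- sum(fit$residuals^2)
  # residuals at machine precision relative to the response scale are
  # numerical noise, not outliers
  if (sse <= .Machine$double.eps^1.5 * max(sum(fit$y^2), 1)) {
    return(character(0))
  }
  J <- fit$fitted * fit$design
  h <- rowSums(qr.Q(qr(J))^2)  # leverage of the Jacobian
  h <- pmin(h, 1 - 1e-10)
  n <- fit$n_used; p <- ncol(fit$design)
  r <- fit$residuals
  sse <- sum(r^2)
  s2_i <- (sse - r^2 / (1 - h)) / (n - p - 1)
  s2_i <- pmax(s2_i, .Machine$double.eps)
  t_ext <- r / sqrt(s2_i * (1 - h))
  fit$ids[abs(t_ext) > threshold]
}

#' Prediction surface over size and concentration grids
#'
#' Evaluates the model for one ligand over all combinations of particle sizes
#' and concentrations.
#'
#' @param beta Named coefficient vector, or an `ez_model_fit`.
#' @param ligand Ligand name present in `descriptors`.
#' @param sizes Positive particle sizes (nm).
#' @param concentrations Positive concentrations (ppm).
#' @param descriptors Ligand descriptor table.
#' @param scale `"mod"` (default) or `"ez"` (inverse-transformed).
#' @return Numeric matrix `length(sizes)` x `length(concentrations)` with
#'   dimnames from the grids.
#' @export
response_surface <- function(beta, ligand, sizes, concentrations,
                             descriptors = gold_ligand_descriptors(),
                             scale = c("mod", "ez")) {
  scale <- match.arg(scale)
  if (inherits(beta, "ez_model_fit")) beta <- beta$coefficients
  if (any(sizes <= 0) || any(concentrations <= 0)) {
    stop("grids must be strictly positive", call. = FALSE)
  }
  grid <- expand.grid(size = sizes, concentration = concentrations,
                      KEEP.OUT.ATTRS = FALSE)
  grid$ligand <- ligand
  pred <- predict_mod_ez(beta, grid, descriptors)
  if (scale == "ez") pred <- mod_inverse(pred)
  matrix(pred, nrow = length(sizes), ncol = length(concentrations),
         dimnames = list(as.character(sizes), as.character(concentrations)))
}
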