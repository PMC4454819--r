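# Effect-concentration estimation and hazard ranking.
#
# Many materials never reach a 50% integrated effect at the highest tested
# dose, which rules out logistic/sigmoidal model fits; effect concentrations
# are therefore read off the empirical profile by linear interpolation on
# log10 concentration, scanning for the first crossing from below. Materials
# whose EC50 is not reached fall back to the concentration giving a score of
# 0.1 for ranking purposes.

#' Estimate an effect concentration by interpolation
#'
#' Scans the treatment points of a profile in ascending concentration and, at
#' the first adjacent pair whose scores straddle `target_score` from below
#' (`score_j < t <= score_j+1`), linearly interpolates the target on the
#' log10-concentration axis. No extrapolation is performed: if the lowest
#' treatment score is already at or above the target the status is
#' `below_range` and the lowest tested concentration is reported as a
#' conservative bound; if no crossing exists the status is `not_reached` and
#' the value is `NA`. The 0-ppm control point is excluded (log undefined).
#'
#' @param profile An `ez_profile` (see [build_profile()]), or any data.frame
#'   with `concentration` and `score` columns.
#' @param target_score Target EZ score in (0, 1); 0.5 gives the EC50.
#' @return An object of class `ec_estimate`: list with `material_id`,
#'   `target_score`, `value` (ppm or `NA`), `status` (one of `"reached"`,
#'   `"below_range"`, `"not_reached"`) and `bracket` (the two profile rows
#'   used, when reached).
#' @export
#' @examples
#' prof <- structure(
#'   data.frame(concentration = c(1, 10), score = c(0.4, 0.6),
#'              n_exposed = 12),
#'   material_id = "NP", class = c("ez_profile", "data.frame"))
#' estimate_ec(prof, 0.5)$value  # 10^0.5 ~ 3.162 ppm
estimate_ec <- function(profile, target_score = 0.5) {
  stopifnot(is.data.frame(profile),
            all(c("concentration", "score") %in% names(profile)))
  if (!is.finite(target_score) || target_score <= 0 || target_score >= 1) {
    stop("target_score must lie in (0, 1)", call. = FALSE)
  }
  treat <- profile[profile$concentration > 0, , drop = FALSE]
  treat <- treat[order(treat$concentration), , drop = FALSE]
  if (nrow(treat) < 2) {
    stop("need at least 2 treatment points for EC estimation", call. = FALSE)
  }
  if (any(!is.finite(treat$score))) {
    stop("profile contains non-finite scores", call. = FALSE)
  }
  mat <- attr(profile, "material_id")
  if (is.null(mat)) mat <- NA_character_
  res <- list(material_id = mat, target_score = target_score,
              value = NA_real_, status = "not_reached", bracket = NULL)
  if (treat$score[1] >= target_score) {
    res$value <- treat$concentration[1]
    res$status <- "below_range"
    return(structure(res, class = "ec_estimate"))
  }
  for (j in seq_len(nrow(treat) - 1)) {
    s0 <- treat$score[j]; s1 <- treat$score[j + 1]
    if (s0 < target_score && target_score <= s1) {
      l0 <- log10(treat$concentration[j])
      l1 <- log10(treat$concentration[j + 1])
      x <- l0 + (target_score - s0) / (s1 - s0) * (l1 - l0)
      res$value <- 10^x
      res$status <- "reached"
      res$bracket <- treat[c(j, j + 1), c("concentration", "score")]
      break
    }
  }
  structure(res, class = "ec_estimate")
}

#' Effect-concentration table for a set of profiles
#'
#' Applies [estimate_ec()] at each target score to every profile.
#'
#' @param profiles Named list of `ez_profile` objects (see [ez_profiles()]).
#' @param targets Numeric vector of target scores; defaults to the EC50
#'   (0.5) and the fallback EC at score 0.1.
#' @return A data.frame with columns `material_id`, `target_score`, `value`,
#'   `status`.
#' @export
estimate_ec_table <- function(profiles, targets = c(0.5, 0.1)) {
  rows <- lapply(profiles, function(p) {
    do.call(rbind, lapply(targets, function(t) {
      e <- estimate_ec(p, t)
      data.frame(material_id = e$material_id, target_score = t,
                 value = e$value, status = e$status,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank materials by toxicity
#'
#' Orders materials from most to least toxic. Materials with a usable EC50
#' (status `reached` or `below_range`) come first, ascending in EC50;
#' materials for which only the fallback EC at score 0.1 is available follow,
#' ascending in that value; materials reaching neither target come last.
#' Ties are broken lexicographically by material id.
#'
#' @param ec_table Output of [estimate_ec_table()] with targets 0.5 and 0.1.
#' @return A data.frame with columns `rank`, `material_id`, `criterion`
#'   (`"EC50"`, `"EC0.1"` or `"none"`), `value` (ppm) and `status`.
#' @export
rank_hazard <- function(ec_table) {
  stopifnot(all(c("material_id", "target_score", "value", "status")
                %in% names(ec_table)))
  mats <- unique(ec_table$material_id)
  rows <- lapply(mats, function(m) {
    sub <- ec_table[ec_table$material_id == m, , drop = FALSE]
    e50 <- sub[sub$target_score == 0.5, , drop = FALSE]
    e01 <- sub[sub$target_score == 0.1, , drop = FALSE]
    usable <- function(e) nrow(e) == 1 && e$status %in% c("reached",
                                                          "below_range")
    if (usable(e50)) {
      data.frame(material_id = m, criterion = "EC50", value = e50$value,
                 status = e50$status, block = 1L, stringsAsFactors = FALSE)
    } else if (usable(e01)) {
      data.frame(material_id = m, criterion = "EC0.1", value = e01$value,
                 status = e01$status, block = 2L, stringsAsFactors = FALSE)
    } else {
      data.frame(material_id = m, criterion = "none", value = NA_real_,
                 status = "not_reached", block = 3L, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$block, out$value, out$material_id,
                   na.last = TRUE), , drop = FALSE]
  out$block <- NULL
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation with mid-ranks
#'
#' Computes Spearman's rho as the Pearson correlation of mid-ranks, with a
#' p-value from the t approximation on n - 2 degrees of freedom. Categorical
#' inputs must be numerically encoded by the caller; the choice of encoding
#' affects the result and no default is imposed.
#'
#' @param x,y Numeric (or rankable) vectors of equal length >= 3.
#' @return List with `rho`, `p_value`, `n`. A constant vector yields
#'   `rho = NA` with a warning.
#' @export
spearman_rank <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("constant vector: Spearman's rho is undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- stats::cor(rx, ry)
  tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(rho = rho, p_value = min(p, 1), n = n)
}
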