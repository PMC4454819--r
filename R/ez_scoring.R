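# Weighted EZ Metric scoring.
#
# For an exposure group (one material at one concentration) the score is the
# mean over embryos of a per-embryo severity: 1.0 if dead at 24 hpf, 0.95 if
# dead by 120 hpf, otherwise the sum of the weights of the sub-lethal
# endpoints the embryo displays. Equivalently, in frequency form,
#
#   score = w24 * f_dead24 + w120 * f_dead120 + (1/n) * sum_i w_i * c_i ,
#
# where c_i counts viable embryos showing endpoint i. This per-embryo-mean
# form bounds the score in [0, 1] (the 19 sub-lethal weights sum to 0.94),
# making 0.5 readable as a 50% integrated effect. The unscaled variant, which
# divides sub-lethal frequencies by the viable count alone and can exceed 1
# when mortality and malformations co-occur, is available via
# `scale_survival = FALSE` for sensitivity analysis.
#
# Sub-lethal observations on embryos that die by 120 hpf are discarded: such
# embryos contribute only the 0.95 mortality weight, which already dominates
# the full sub-lethal sum.

#' Tally endpoint frequencies for one exposure group
#'
#' Partitions the embryos of a single material-by-concentration group into
#' dead at 24 hpf, dead between 24 and 120 hpf, and viable at 120 hpf, and
#' counts each sub-lethal endpoint among the viable embryos.
#'
#' @param records Embryo records (one material, one concentration).
#' @return An object of class `ez_tally`: list with `material_id`,
#'   `concentration`, `n_exposed`, `n_dead_24`, `n_dead_120`, `n_viable`,
#'   and `sublethal_counts` (named integer vector over [ez_endpoints()]).
#' @export
tally_group <- function(records) {
  records <- validate_embryo_records(records)
  if (nrow(records) == 0) stop("empty exposure group", call. = FALSE)
  if (length(unique(records$material_id)) != 1 ||
      length(unique(records$concentration)) != 1) {
    stop("tally_group expects a single material at a single concentration",
         call. = FALSE)
  }
  dead24 <- !records$alive_24hpf
  dead120 <- records$alive_24hpf & !records$alive_120hpf
  viable <- records$alive_120hpf
  epm <- as.matrix(records[viable, ez_endpoints(), drop = FALSE])
  counts <- if (nrow(epm) > 0) colSums(epm) else
    stats::setNames(rep(0, length(ez_endpoints())), ez_endpoints())
  structure(list(
    material_id = records$material_id[1],
    concentration = records$concentration[1],
    n_exposed = nrow(records),
    n_dead_24 = sum(dead24),
    n_dead_120 = sum(dead120),
    n_viable = sum(viable),
    sublethal_counts = stats::setNames(as.integer(counts), names(counts))
  ), class = "ez_tally")
}

#' Weighted EZ Metric score of an exposure group
#'
#' Combines mortality fractions and viable-embryo endpoint frequencies into
#' a single weighted score (see the scoring description above). With the
#' default scaled form the score lies in [0, 1] and equals 1 exactly when
#' every embryo died at 24 hpf.
#'
#' @param tally An `ez_tally` from [tally_group()].
#' @param weights An `ez_weights` table (default [ez_weights()]).
#' @param scale_survival If `TRUE` (default) sub-lethal frequencies are
#'   additionally scaled by the surviving fraction (per-embryo-mean form,
#'   bounded in \[0, 1\]); if `FALSE` they are divided by the viable count
#'   alone and the score may exceed 1.
#' @return An object of class `ez_score`: list with `material_id`,
#'   `concentration`, `score`, `n_exposed`.
#' @export
#' @examples
#' recs <- data.frame(material_id = "NP", concentration = 10,
#'                    well_id = 1:4, alive_24hpf = TRUE, alive_120hpf = TRUE,
#'                    check.names = FALSE)
#' recs[["heart malformation"]] <- c(TRUE, TRUE, FALSE, FALSE)
#' weighted_ez_score(tally_group(recs))$score  # 0.12 * 2/4 = 0.06
weighted_ez_score <- function(tally, weights = ez_weights(),
                              scale_survival = TRUE) {
  stopifnot(inherits(tally, "ez_tally"))
  weights <- validate_weights(unclass(weights))
  n <- tally$n_exposed
  w24 <- weights[[.EZ_MORTALITY_24]]
  w120 <- weights[[.EZ_MORTALITY_120]]
  wsub <- weights[ez_endpoints()]
  mortality <- (w24 * tally$n_dead_24 + w120 * tally$n_dead_120) / n
  sub <- if (tally$n_viable == 0) 0 else {
    s <- sum(wsub * tally$sublethal_counts[ez_endpoints()]) / tally$n_viable
    if (scale_survival) s * tally$n_viable / n else s
  }
  structure(list(
    material_id = tally$material_id,
    concentration = tally$concentration,
    score = unname(mortality + sub),
    n_exposed = n
  ), class = "ez_score")
}

#' Score a whole plate table
#'
#' Groups records by material and concentration, tallies each group and
#' returns one row per exposure group with the weighted score and raw
#' frequency counts.
#'
#' @inheritParams weighted_ez_score
#' @param records Validated embryo records for any number of materials.
#' @param counts Include the per-endpoint viable counts as extra columns?
#' @return A data.frame with columns `material_id`, `concentration`,
#'   `n_exposed`, `n_dead_24`, `n_dead_120`, `n_viable`, `ez_score`,
#'   sorted by material then concentration.
#' @export
score_plate <- function(records, weights = ez_weights(),
                        scale_survival = TRUE, counts = FALSE) {
  records <- validate_embryo_records(records)
  key <- interaction(records$material_id, records$concentration, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(records)), key), function(idx) {
    tl <- tally_group(records[idx, , drop = FALSE])
    sc <- weighted_ez_score(tl, weights, scale_survival)
    base <- data.frame(
      material_id = tl$material_id, concentration = tl$concentration,
      n_exposed = tl$n_exposed, n_dead_24 = tl$n_dead_24,
      n_dead_120 = tl$n_dead_120, n_viable = tl$n_viable,
      ez_score = sc$score, stringsAsFactors = FALSE
    )
    if (counts) base <- cbind(base, as.data.frame(t(tl$sublethal_counts),
                                                  check.names = FALSE))
    base
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$material_id, out$concentration), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a concentration-response profile for one material
#'
#' Pools all records of a material by concentration (replicate plates at the
#' same concentration are merged before scoring), scores each pooled group,
#' and returns the profile sorted by ascending concentration. A 0-ppm control
#' point is kept in the profile but excluded from [sum_ez()] and from EC
#' interpolation. At least two distinct treatment concentrations are
#' required.
#'
#' @inheritParams weighted_ez_score
#' @param records Embryo records of a single material.
#' @return An object of class `ez_profile`: data.frame with columns
#'   `concentration`, `score`, `n_exposed`, attribute `material_id`.
#' @export
build_profile <- function(records, weights = ez_weights(),
                          scale_survival = TRUE) {
  records <- validate_embryo_records(records)
  if (length(unique(records$material_id)) != 1) {
    stop("build_profile expects records of a single material", call. = FALSE)
  }
  concs <- sort(unique(records$concentration))
  if (sum(concs > 0) < 2) {
    stop("a profile needs at least 2 distinct treatment concentrations",
         call. = FALSE)
  }
  pts <- lapply(concs, function(cc) {
    sc <- weighted_ez_score(
      tally_group(records[records$concentration == cc, , drop = FALSE]),
      weights, scale_survival)
    data.frame(concentration = cc, score = sc$score, n_exposed = sc$n_exposed)
  })
  out <- do.call(rbind, pts)
  rownames(out) <- NULL
  structure(out, material_id = records$material_id[1],
            class = c("ez_profile", "data.frame"))
}

#' Concentration-response profiles for every material in a table
#'
#' @inheritParams build_profile
#' @param records Embryo records for any number of materials.
#' @return Named list of `ez_profile` objects, one per material.
#' @export
ez_profiles <- function(records, weights = ez_weights(),
                        scale_survival = TRUE) {
  records <- validate_embryo_records(records)
  by_mat <- split(seq_len(nrow(records)), records$material_id)
  lapply(by_mat, function(idx) {
    build_profile(records[idx, , drop = FALSE], weights, scale_survival)
  })
}

#' Summed EZ Metric score of a profile
#'
#' Sums the weighted EZ scores over a material's treatment concentrations
#' (the 0-ppm control point, when present, is excluded). Used as the
#' cluster-level toxicity summary: the sum lies between 0 and the number of
#' treatment concentrations.
#'
#' @param profile An `ez_profile` from [build_profile()].
#' @return List with `material_id`, `value`, `n_concentrations`.
#' @export
sum_ez <- function(profile) {
  stopifnot(inherits(profile, "ez_profile"))
  treat <- profile[profile$concentration > 0, , drop = FALSE]
  list(material_id = attr(profile, "material_id"),
       value = sum(treat$score),
       n_concentrations = nrow(treat))
}
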