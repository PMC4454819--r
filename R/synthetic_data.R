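# Synthetic plate-data generation.
#
# Emulates the screening design: 96-well plates with one dechorionated
# embryo per well, fivefold serial dilutions from 250 ppm plus a fishwater
# control, and per-embryo binary outcomes. Each endpoint follows a Hill
# dose-response curve H(c) = c^h / (ed50^h + c^h); an embryo dies by 24 hpf
# with probability H24(c), a survivor dies by 120 hpf with probability
# H120(c), and each sub-lethal endpoint is drawn independently among
# survivors with its own curve. A material's potency rescales every ed50
# (potency p divides all ed50s by p), giving a one-knob toxicity dial for
# panel simulation. Controls are clean by default (background rate 0,
# configurable). Independence across endpoints is the simplest structure
# that exercises every pipeline stage; real malformation endpoints
# co-occur, which this generator does not emulate.

#' Serial dilution series
#'
#' Descending geometric concentration series `top, top/factor, ...,
#' top/factor^(n-1)`; the default screening design uses fivefold dilutions
#' from 250 ppm (seven levels end at 0.016 ppm = 16 ppb).
#'
#' @param top Highest concentration (ppm), > 0.
#' @param factor Dilution factor, > 1 (default 5).
#' @param n Number of concentrations, >= 1.
#' @return Numeric vector of length `n`, descending.
#' @export
#' @examples
#' dilution_series(250, 5, 7)  # ends at 0.016 ppm
dilution_series <- function(top = 250, factor = 5, n = 8) {
  if (!is.finite(top) || top <= 0) stop("top must be > 0", call. = FALSE)
  if (!is.finite(factor) || factor <= 1) stop("factor must be > 1",
                                              call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  top / factor^(0:(n - 1))
}

#' Simulation configuration for plate generation
#'
#' Collects the design parameters and per-endpoint Hill curves of the
#' generator. Defaults mirror the screening design: 12 embryos per exposure
#' group, eight fivefold dilutions from 250 ppm plus a control, and a
#' moderately toxic baseline (24-hpf mortality ed50 80 ppm, 120-hpf
#' mortality ed50 40 ppm, sub-lethal ed50s 25-120 ppm with the more severe
#' malformations the more sensitive, Hill slope 2).
#'
#' @param embryos_per_group Embryos per material-by-concentration group.
#' @param top_concentration Top of the dilution series (ppm).
#' @param dilution_factor Serial dilution factor.
#' @param n_dilutions Number of treatment concentrations.
#' @param hill Default Hill slope for all endpoints.
#' @param ed50_mortality_24,ed50_mortality_120 Mortality curve midpoints
#'   (ppm) at potency 1.
#' @param ed50_sublethal Named numeric vector of sub-lethal ed50s (ppm);
#'   defaults cover all 19 endpoints.
#' @param background Probability of each outcome in 0-ppm controls
#'   (default 0).
#' @return List of class `ez_sim_config`.
#' @export
sim_config <- function(embryos_per_group = 12, top_concentration = 250,
                       dilution_factor = 5, n_dilutions = 8, hill = 2,
                       ed50_mortality_24 = 80, ed50_mortality_120 = 40,
                       ed50_sublethal = NULL, background = 0) {
  if (dilution_factor <= 1) stop("dilution_factor must be > 1", call. = FALSE)
  if (hill <= 0) stop("hill must be > 0", call. = FALSE)
  defaults <- c(
    "heart malformation" = 25, "brain malformation" = 30,
    "yolk sac edema" = 25, "notochord malformation" = 40,
    "curved axis" = 40, "trunk malformation" = 50,
    "delayed developmental progression" = 35, "occluded circulation" = 60,
    "eye malformation" = 60, "jaw malformation" = 60,
    "lack of spontaneous movement" = 50, "somite malformation" = 80,
    "motility" = 70, "lack of touch response" = 70,
    "snout malformation" = 90, "otic malformation" = 100,
    "caudal/pectoral fin malformation" = 90, "atypical pigmentation" = 120,
    "atypical swim bladder inflation" = 80
  )
  if (!is.null(ed50_sublethal)) {
    ed50_sublethal <- validate_weights_like(ed50_sublethal)
    defaults[names(ed50_sublethal)] <- ed50_sublethal
  }
  if (any(defaults <= 0) || ed50_mortality_24 <= 0 || ed50_mortality_120 <= 0) {
    stop("ed50 values must be > 0", call. = FALSE)
  }
  structure(list(
    embryos_per_group = embryos_per_group,
    top_concentration = top_concentration,
    dilution_factor = dilution_factor,
    n_dilutions = n_dilutions,
    hill = hill,
    ed50_mortality_24 = ed50_mortality_24,
    ed50_mortality_120 = ed50_mortality_120,
    ed50_sublethal = defaults,
    background = background
  ), class = "ez_sim_config")
}

validate_weights_like <- function(x) {
  names(x) <- canonical_endpoint(names(x))
  unknown <- setdiff(names(x), ez_endpoints())
  if (length(unknown) > 0) {
    stop("unknown endpoint(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  x
}

hill_curve <- function(conc, ed50, hill) {
  ifelse(conc <= 0, 0, conc^hill / (ed50^hill + conc^hill))
}

# Per-endpoint response probabilities at one concentration for one material.
plate_probs <- function(config, potency, conc) {
  eff <- function(ed50) ed50 / potency
  p <- c(
    mortality_24 = hill_curve(conc, eff(config$ed50_mortality_24),
                              config$hill),
    mortality_120 = hill_curve(conc, eff(config$ed50_mortality_120),
                               config$hill),
    vapply(config$ed50_sublethal, function(e)
      hill_curve(conc, eff(e), config$hill), numeric(1))
  )
  if (conc <= 0) p[] <- config$background
  p
}

#' Simulate a plate series for one material
#'
#' Draws per-embryo outcomes for every concentration of the dilution series
#' plus a fishwater control: death by 24 hpf, then death by 120 hpf among
#' survivors, then independent sub-lethal endpoints among viable embryos,
#' each from its Hill curve (see the module description). Well ids encode the
#' concentration level (row letter) and embryo index (column number).
#'
#' @param config An `ez_sim_config` (default [sim_config()]).
#' @param material_id Material identifier for the records.
#' @param potency Potency multiplier; every ed50 is divided by it, so
#'   `potency > 1` is more toxic than baseline.
#' @param seed Optional integer seed for reproducibility.
#' @param include_control Include a 0-ppm control group? Default `TRUE`.
#' @return List with `records` (a validated `ez_embryo_tbl`) and `truth`
#'   (data.frame of the generating ed50/hill per endpoint at this potency).
#' @export
simulate_plate <- function(config = sim_config(), material_id = "NP-1",
                           potency = 1, seed = NULL, include_control = TRUE) {
  stopifnot(inherits(config, "ez_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  concs <- dilution_series(config$top_concentration, config$dilution_factor,
                           config$n_dilutions)
  if (include_control) concs <- c(concs, 0)
  concs <- sort(concs)  # ascending; control first
  n <- config$embryos_per_group
  groups <- lapply(seq_along(concs), function(ci) {
    conc <- concs[ci]
    p <- plate_probs(config, potency, conc)
    dead24 <- stats::runif(n) < p[["mortality_24"]]
    dead120 <- !dead24 & (stats::runif(n) < p[["mortality_120"]])
    viable <- !dead24 & !dead120
    rec <- data.frame(
      material_id = material_id, concentration = conc,
      well_id = sprintf("%s%02d", LETTERS[ci], seq_len(n)),
      alive_24hpf = !dead24, alive_120hpf = viable,
      stringsAsFactors = FALSE, check.names = FALSE
    )
    for (e in ez_endpoints()) {
      rec[[e]] <- viable & (stats::runif(n) < p[[e]])
    }
    rec
  })
  records <- validate_embryo_records(do.call(rbind, groups))
  truth <- data.frame(
    endpoint = c("24 hpf mortality", "120 hpf mortality",
                 names(config$ed50_sublethal)),
    ed50 = c(config$ed50_mortality_24, config$ed50_mortality_120,
             unname(config$ed50_sublethal)) / potency,
    hill = config$hill, stringsAsFactors = FALSE
  )
  list(records = records, truth = truth)
}

#' Simulate a nanomaterial panel with surface-chemistry-driven potency
#'
#' Generates a panel (default 68 materials) in two potency strata: each
#' material carries one of the four toxicity-associated surface groups
#' (TMAT, phosphate, phosphatidylcholine, amine) with probability `p_toxic`,
#' and carriers receive `potency_toxic` (strongly toxic: default effective
#' mortality ed50s of a few ppm) while non-carriers receive `potency_benign`
#' (essentially inert over the tested range). `label_noise` decouples a
#' fraction of materials from their stratum by swapping their potency,
#' emulating the minor misfits seen in real panels. Plate data, material
#' annotations and ground-truth stratum labels are returned together.
#'
#' @param n_materials Panel size (default 68).
#' @param p_toxic Probability a material carries a toxic surface group.
#' @param potency_toxic,potency_benign Potency multipliers of the two strata
#'   (defaults 20 and 0.02).
#' @param label_noise Fraction of materials whose potency is swapped across
#'   strata (default 0).
#' @param config An `ez_sim_config`.
#' @param seed Integer seed.
#' @return List with `records` (all embryo records), `materials` (annotation
#'   data.frame with surface-group flags) and `truth` (data.frame:
#'   `material_id`, `toxic` logical ground truth from the surface groups,
#'   `potency` actually applied).
#' @export
simulate_panel <- function(n_materials = 68, p_toxic = 0.5,
                           potency_toxic = 20, potency_benign = 0.02,
                           label_noise = 0, config = sim_config(),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_materials < 2) stop("need at least 2 materials", call. = FALSE)
  groups <- .EZ_SURFACE_GROUPS
  toxic <- stats::runif(n_materials) < p_toxic
  carried <- ifelse(toxic, sample(groups, n_materials, replace = TRUE), NA)
  cores <- c("gold", "silver", "dendrimer", "metal oxide", "quantum dot")
  benign_surfaces <- c("MEE", "MEEE", "MES", "citrate", "PEG")
  ids <- sprintf("NP-%03d", seq_len(n_materials))
  materials <- data.frame(
    material_id = ids,
    core = sample(cores, n_materials, replace = TRUE),
    primary_size = round(exp(stats::runif(n_materials, log(0.8), log(100))),
                         1),
    surface_chemistry = ifelse(toxic,
                               c(tmat = "TMAT", phosphate = "phosphate",
                                 phosphatidylcholine = "phosphatidylcholine",
                                 amine = "amine")[carried],
                               sample(benign_surfaces, n_materials,
                                      replace = TRUE)),
    stringsAsFactors = FALSE
  )
  for (g in groups) materials[[g]] <- !is.na(carried) & carried == g
  materials$charge <- ifelse(materials$tmat | materials$amine, "positive",
                             sample(c("neutral", "negative"), n_materials,
                                    replace = TRUE))
  potency <- ifelse(toxic, potency_toxic, potency_benign)
  if (label_noise > 0) {
    flip <- stats::runif(n_materials) < label_noise
    potency[flip] <- ifelse(toxic[flip], potency_benign, potency_toxic)
  }
  plate_seeds <- sample.int(.Machine$integer.max, n_materials)
  records <- do.call(rbind, lapply(seq_len(n_materials), function(i) {
    simulate_plate(config, material_id = ids[i], potency = potency[i],
                   seed = plate_seeds[i])$records
  }))
  list(records = validate_embryo_records(records),
       materials = validate_material_table(materials),
       truth = data.frame(material_id = ids, toxic = toxic,
                          potency = potency, stringsAsFactors = FALSE))
}

#' Simulate observations from the response-surface model
#'
#' Inverts the exponential model: for every ligand-by-size-by-concentration
#' cell, draws `mod_ez = exp(x beta) + N(0, noise_sd)` floored at `floor`
#' (the mod scale's lower bound; set `floor = -Inf` with care). With
#' `noise_sd = 0` the data are exactly log-linear and a refit recovers the
#' generating coefficients.
#'
#' @param beta Named coefficient vector (default
#'   [reference_model_coefficients()]).
#' @param descriptors Ligand descriptor table.
#' @param sizes Particle sizes (nm); defaults to the modelled gold series.
#' @param concentrations Exposure concentrations (ppm); defaults to the
#'   eight-step fivefold series from 250 ppm.
#' @param noise_sd Gaussian noise standard deviation on the mod scale.
#' @param floor Lower truncation of the noisy response (default 0.1, the mod
#'   transform of a zero score).
#' @param seed Integer seed.
#' @return Data.frame with columns `ligand`, `size`, `concentration`,
#'   `mod_ez`, `ez_score`.
#' @export
simulate_model_observations <- function(beta = reference_model_coefficients(),
                                        descriptors = gold_ligand_descriptors(),
                                        sizes = c(0.8, 1.5, 2, 10),
                                        concentrations = dilution_series(),
                                        noise_sd = 0, floor = 0.1,
                                        seed = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  obs <- expand.grid(ligand = descriptors$ligand, size = sizes,
                     concentration = sort(concentrations),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- predict_mod_ez(beta, obs, descriptors)
  obs$mod_ez <- if (noise_sd > 0) {
    pmax(mu + stats::rnorm(nrow(obs), 0, noise_sd), floor)
  } else mu
  obs$ez_score <- mod_inverse(obs$mod_ez)
  obs
}
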