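# Endpoint vocabulary and weighting scheme for the EZ Metric assay.
#
# The assay scores each embryo for viability at 24 and 120 hpf and for 19
# binary sub-lethal endpoints (morphology at 120 hpf, early development and
# behaviour). Each endpoint carries a severity weight in [0, 1]; mortality at
# 24 hpf weighs 1.0 and mortality by 120 hpf 0.95, so death always dominates
# any combination of sub-lethal effects (the 19 sub-lethal weights sum to
# 0.94).

.EZ_MORTALITY_24 <- "24 hpf mortality"
.EZ_MORTALITY_120 <- "120 hpf mortality"

.EZ_DEFAULT_WEIGHTS <- c(
  "24 hpf mortality" = 1.0,
  "120 hpf mortality" = 0.95,
  "heart malformation" = 0.12,
  "brain malformation" = 0.12,
  "yolk sac edema" = 0.10,
  "notochord malformation" = 0.08,
  "curved axis" = 0.08,
  "trunk malformation" = 0.06,
  "delayed developmental progression" = 0.06,
  "occluded circulation" = 0.04,
  "eye malformation" = 0.04,
  "jaw malformation" = 0.04,
  "lack of spontaneous movement" = 0.04,
  "somite malformation" = 0.02,
  "motility" = 0.02,
  "lack of touch response" = 0.02,
  "snout malformation" = 0.02,
  "otic malformation" = 0.02,
  "caudal/pectoral fin malformation" = 0.02,
  "atypical pigmentation" = 0.02,
  "atypical swim bladder inflation" = 0.02
)

# Synonyms occasionally seen in plate exports; applied only on request.
.EZ_ENDPOINT_SYNONYMS <- c(
  "pericardial edema" = "heart malformation",
  "axis malformation" = "curved axis",
  "touch response" = "lack of touch response",
  "pigment malformation" = "atypical pigmentation",
  "swim bladder malformation" = "atypical swim bladder inflation"
)

#' Names of the sub-lethal EZ Metric endpoints
#'
#' Returns the canonical names of the 19 binary sub-lethal endpoints scored at
#' 24 or 120 hours post fertilization (hpf). Mortality is carried separately
#' by the two viability flags (`alive_24hpf`, `alive_120hpf`) and does not
#' appear in this list.
#'
#' @return Character vector of length 19, in decreasing weight order.
#' @seealso [ez_weights()] for the full 21-entry weight table.
#' @export
#' @examples
#' ez_endpoints()
ez_endpoints <- function() {
  setdiff(names(.EZ_DEFAULT_WEIGHTS), c(.EZ_MORTALITY_24, .EZ_MORTALITY_120))
}

#' Default EZ Metric endpoint weights
#'
#' The consensus severity weighting of the 21 assay endpoints: mortality at
#' 24 hpf (1.0), mortality by 120 hpf (0.95), and 19 sub-lethal endpoints
#' whose weights sum to 0.94, so that death always outweighs any combination
#' of malformations.
#'
#' @return Named numeric vector of length 21 with class `ez_weights`.
#' @export
#' @examples
#' w <- ez_weights()
#' w[["heart malformation"]]
ez_weights <- function() {
  structure(.EZ_DEFAULT_WEIGHTS, class = "ez_weights")
}

# Canonicalize endpoint names: lowercase, underscores/dots to spaces,
# collapse whitespace; optionally apply the synonym map.
canonical_endpoint <- function(x, synonyms = FALSE) {
  x <- tolower(trimws(gsub("[_.]+", " ", x)))
  x <- gsub("[[:space:]]+", " ", x)
  if (synonyms) {
    hit <- match(x, names(.EZ_ENDPOINT_SYNONYMS))
    x[!is.na(hit)] <- unname(.EZ_ENDPOINT_SYNONYMS[hit[!is.na(hit)]])
  }
  x
}

validate_weights <- function(w) {
  if (is.null(names(w)) || any(names(w) == "")) {
    stop("weight table entries must be named by endpoint", call. = FALSE)
  }
  names(w) <- canonical_endpoint(names(w))
  known <- names(.EZ_DEFAULT_WEIGHTS)
  unknown <- setdiff(names(w), known)
  if (length(unknown) > 0) {
    stop("unknown endpoint name(s) in weight table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(known, names(w))
  if (length(missing) > 0) {
    stop("weight table is missing endpoint(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  w <- w[known]
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("weights must be finite and nonnegative", call. = FALSE)
  }
  structure(w, class = "ez_weights")
}

#' Read an endpoint weight configuration
#'
#' Reads a weight table mapping each of the 21 assay endpoints to a
#' nonnegative weight. `"default"` returns the packaged consensus weights
#' (see [ez_weights()]). Files may be YAML (`.yaml`/`.yml`), JSON (`.json`)
#' or a two-column CSV (`endpoint,weight`). Partial tables are rejected: all
#' 21 endpoints must be present, and unknown endpoint names are an error.
#'
#' @param path `"default"`, or path to a YAML/JSON/CSV weight file.
#' @return Named numeric vector of length 21 with class `ez_weights`.
#' @export
read_weight_config <- function(path = "default") {
  if (identical(path, "default")) {
    return(ez_weights())
  }
  if (!file.exists(path)) {
    stop("weight config not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  w <- switch(ext,
    "yaml" = ,
    "yml" = unlist(yaml::read_yaml(path)),
    "json" = unlist(jsonlite::read_json(path)),
    "csv" = {
      tab <- utils::read.csv(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
      if (!all(c("endpoint", "weight") %in% names(tab))) {
        stop("CSV weight config needs columns 'endpoint' and 'weight'",
             call. = FALSE)
      }
      stats::setNames(as.numeric(tab$weight), tab$endpoint)
    },
    stop("unsupported weight config format: .", ext, call. = FALSE)
  )
  validate_weights(w)
}

#' Surface-ligand molecular descriptors for modelled gold nanoparticles
#'
#' Quantum-chemical and topographical descriptors for the four thiol surface
#' ligands (MEE, MEEE, TMAT, MES) used by the exponential response-surface
#' model: solvent-accessible surface area (SASA, square Angstrom), the
#' unitless ratio of SASA to polar surface area, molar refractivity
#' (m^3/mol), and the HOMO-LUMO band gap (kcal/mol). Shipped as a plain-text
#' fixture; computing such descriptors (ab initio geometry optimisation) is
#' outside the scope of this package.
#'
#' @return A data.frame with columns `ligand`, `sasa`, `sasa_over_polar`,
#'   `refractivity`, `band_gap`, one row per ligand.
#' @export
#' @examples
#' gold_ligand_descriptors()
gold_ligand_descriptors <- function() {
  path <- system.file("extdata", "gold_ligand_descriptors.csv",
                      package = "ezmetric", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reference coefficients of the gold-nanoparticle response-surface model
#'
#' Published point estimates for the ten terms of the exponential
#' response-surface model (see [fit_response_model()]): intercept, natural-log
#' concentration, particle size (nm), three ligand descriptors, two
#' interactions, and two quadratic terms. Useful as ground truth for the
#' synthetic observation generator and for drawing prediction surfaces.
#'
#' @return Named numeric vector of length 10 in design-matrix term order.
#' @seealso [simulate_model_observations()], [response_surface()]
#' @export
reference_model_coefficients <- function() {
  c(
    intercept = 67.2828,
    log_conc = 0.8128,
    size = 14.7335,
    sasa_over_polar = 4.1535,
    refractivity = -0.2974,
    band_gap = 0.3715,
    log_conc_x_sasa_over_polar = -0.0547,
    size_x_band_gap = 0.0682,
    log_conc_sq = -0.0343,
    size_sq = -0.0255
  )
}
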