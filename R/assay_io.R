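# Reading, validation and writing of per-embryo plate records and material
# annotation tables.
#
# An embryo table holds one row per embryo-well: material_id, exposure
# concentration (ppm; 0 = fishwater control), well_id, the two viability
# flags alive_24hpf / alive_120hpf, and one 0/1 column per sub-lethal
# endpoint (canonical names from ez_endpoints()). Concentrations are ppm
# throughout; an optional `unit` column may mark individual rows as ppb.

.EZ_CORE_COLS <- c("material_id", "concentration", "well_id",
                   "alive_24hpf", "alive_120hpf")

parse_flag <- function(x, col) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    bad <- !(x %in% c(0, 1) | is.na(x))
    if (any(bad)) stop("column '", col, "': values must be 0/1", call. = FALSE)
    return(x == 1)
  }
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("1", "true", "t", "yes", "y")] <- TRUE
  out[v %in% c("0", "false", "f", "no", "n")] <- FALSE
  bad <- is.na(out) & !(v %in% c("", "na"))
  if (any(bad)) {
    stop("column '", col, "': cannot parse '", v[which(bad)[1]],
         "' as a boolean", call. = FALSE)
  }
  out
}

#' Validate a table of per-embryo assay records
#'
#' Checks the structural invariants of an embryo table: required columns
#' present, endpoint columns limited to the 19 canonical sub-lethal
#' endpoints, no embryo alive at 120 hpf but dead at 24 hpf, and no
#' sub-lethal flag set on an embryo dead at 24 hpf (observations on dead
#' embryos are invalid input and are rejected rather than silently zeroed).
#'
#' @param records A data.frame of embryo records.
#' @return The validated data.frame, invisibly-coerced flags, with class
#'   `ez_embryo_tbl` prepended.
#' @export
validate_embryo_records <- function(records) {
  if (!is.data.frame(records)) stop("records must be a data.frame",
                                    call. = FALSE)
  missing <- setdiff(.EZ_CORE_COLS, names(records))
  if (length(missing) > 0) {
    stop("embryo table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  eps <- setdiff(names(records), c(.EZ_CORE_COLS, "unit"))
  unknown <- setdiff(eps, ez_endpoints())
  if (length(unknown) > 0) {
    stop("unknown endpoint column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  # absent endpoint columns are treated as all-FALSE
  for (e in setdiff(ez_endpoints(), eps)) {
    records[[e]] <- logical(nrow(records))
  }
  for (col in c("alive_24hpf", "alive_120hpf", ez_endpoints())) {
    records[[col]] <- parse_flag(records[[col]], col)
    if (anyNA(records[[col]])) {
      stop("column '", col, "' contains missing values", call. = FALSE)
    }
  }
  records$concentration <- as.numeric(records$concentration)
  if ("unit" %in% names(records)) {
    u <- tolower(trimws(records$unit))
    if (!all(u %in% c("ppm", "ppb"))) {
      stop("unit column may only contain 'ppm' or 'ppb'", call. = FALSE)
    }
    records$concentration[u == "ppb"] <- records$concentration[u == "ppb"] / 1000
    records$unit <- NULL
  }
  if (any(!is.finite(records$concentration) | records$concentration < 0)) {
    stop("concentrations must be finite and nonnegative ppm", call. = FALSE)
  }
  bad_viab <- which(records$alive_120hpf & !records$alive_24hpf)
  if (length(bad_viab) > 0) {
    stop("viability contradiction (dead at 24 hpf, alive at 120 hpf) in row(s): ",
         paste(bad_viab, collapse = ", "), call. = FALSE)
  }
  epm <- as.matrix(records[, ez_endpoints(), drop = FALSE])
  bad_dead <- which(!records$alive_24hpf & rowSums(epm) > 0)
  if (length(bad_dead) > 0) {
    stop("sub-lethal endpoint flagged on embryo dead at 24 hpf in row(s): ",
         paste(bad_dead, collapse = ", "), call. = FALSE)
  }
  records <- records[, c(.EZ_CORE_COLS, ez_endpoints())]
  class(records) <- c("ez_embryo_tbl", "data.frame")
  records
}

#' Read a per-embryo assay table from CSV
#'
#' Reads a comma-separated, UTF-8, headered table with one row per
#' embryo-well and validates it (see [validate_embryo_records()]). Endpoint
#' column headers are canonicalized (lowercased, underscores to spaces);
#' `schema` renames nonstandard headers before validation, e.g.
#' `c(sample = "material_id", conc_ppm = "concentration")`.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector mapping file column names to
#'   canonical ones (`file_name = "canonical_name"`).
#' @param synonyms Apply the endpoint synonym map (e.g. "pericardial edema"
#'   to "heart malformation")? Default `FALSE`.
#' @return A validated `ez_embryo_tbl` data.frame.
#' @export
read_embryo_table <- function(path, schema = NULL, synonyms = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    hit <- match(names(schema), names(tab))
    if (anyNA(hit)) {
      stop("schema names column(s) absent from file: ",
           paste(names(schema)[is.na(hit)], collapse = ", "), call. = FALSE)
    }
    names(tab)[hit] <- unname(schema)
  }
  keep_as_is <- names(tab) %in% c(.EZ_CORE_COLS, "unit")
  names(tab)[!keep_as_is] <- canonical_endpoint(names(tab)[!keep_as_is],
                                                synonyms = synonyms)
  validate_embryo_records(tab)
}

#' Write a per-embryo assay table to CSV
#'
#' Inverse of [read_embryo_table()]: writes canonical columns with 0/1
#' endpoint flags, so that a read/write round trip is field-identical.
#'
#' @param records A validated `ez_embryo_tbl` (or coercible data.frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_embryo_table <- function(records, path) {
  records <- validate_embryo_records(records)
  out <- as.data.frame(records)
  for (col in c("alive_24hpf", "alive_120hpf", ez_endpoints())) {
    out[[col]] <- as.integer(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

.EZ_SURFACE_GROUPS <- c("tmat", "phosphate", "phosphatidylcholine", "amine")

#' Read a material annotation table from CSV
#'
#' Reads per-material annotations: `material_id`, `core` composition,
#' `primary_size` (nm, positive), `surface_chemistry`, the four surface
#' functional-group flags (`tmat`, `phosphate`, `phosphatidylcholine`,
#' `amine`; parsed from 0/1/true/false/yes/no case-insensitively) and an
#' optional `charge` category. Material ids must be unique.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with one row per material, logical group flags.
#' @export
read_material_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  validate_material_table(tab)
}

#' @rdname read_material_table
#' @param materials A data.frame of material annotations to validate.
#' @export
validate_material_table <- function(materials) {
  req <- c("material_id", "core", "primary_size", "surface_chemistry",
           .EZ_SURFACE_GROUPS)
  missing <- setdiff(req, names(materials))
  if (length(missing) > 0) {
    stop("material table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dup <- unique(materials$material_id[duplicated(materials$material_id)])
  if (length(dup) > 0) {
    stop("duplicate material_id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  materials$primary_size <- as.numeric(materials$primary_size)
  if (any(!is.finite(materials$primary_size) | materials$primary_size <= 0)) {
    stop("primary_size must be positive (nm)", call. = FALSE)
  }
  for (g in .EZ_SURFACE_GROUPS) {
    materials[[g]] <- parse_flag(materials[[g]], g)
  }
  if (!"charge" %in% names(materials)) materials$charge <- "unknown"
  materials
}
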