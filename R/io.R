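# Schema registry for the tabular interchange formats. Each schema lists
# its columns, their types, and per-column validators; readers reject
# unknown columns and report the location of the first violation.

.schemas <- list(
  psd = list(
    cols = c(sample = "character", time_min = "numeric",
             dispersant = "character", bin_lo_um = "numeric",
             bin_hi_um = "numeric", volume_frac = "numeric"),
    checks = list(
      time_min = function(v) v >= 0,
      dispersant = function(v) v %in% c("water", "sds_edta"),
      bin_lo_um = function(v) v > 0,
      bin_hi_um = function(v) v > 0,
      volume_frac = function(v) v >= 0)),
  retention = list(
    cols = c(sample = "character", nutrient = "character",
             time_min = "numeric", retained_pct = "numeric"),
    checks = list(
      nutrient = function(v) v %in% c("protein", "lipid", "total"),
      time_min = function(v) v >= 0,
      retained_pct = function(v) v >= 0 & v <= 110)),
  bands = list(
    cols = c(sample = "character", band = "character",
             time_min = "numeric", intensity = "numeric"),
    checks = list(time_min = function(v) v >= 0,
                  intensity = function(v) v >= 0)),
  groups = list(
    cols = c(sample = "character", profile = "character"),
    checks = list(profile = function(v)
      v %in% c("casein_dominant", "whey_dominant", "biopolymer_whey"))),
  dilution = list(
    cols = c(time_min = "numeric", factor = "numeric"),
    checks = list(time_min = function(v) v >= 0,
                  factor = function(v) v >= 1)),
  timeseries = list(
    cols = c(sample = "character", time_min = "numeric",
             compartment = "character", mass_g = "numeric",
             protein_g = "numeric", lipid_g = "numeric", ph = "numeric"),
    checks = list(compartment = function(v) v %in% c("chyme", "emptied"),
                  mass_g = function(v) v >= 0))
)

#' Read a schema-validated CSV table
#'
#' Reads one of the package's interchange CSVs (`psd`, `retention`,
#' `bands`, `groups`, `dilution`, `timeseries`), coercing columns to their
#' schema types. Unknown or missing columns are rejected; value violations
#' report the row and column of the first offending cell.
#'
#' @param path CSV path (UTF-8, header row, dot decimal separator).
#' @param schema_name Schema to validate against.
#' @return A validated data frame.
#' @export
read_table <- function(path, schema_name = names(.schemas)) {
  schema_name <- match.arg(schema_name)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sc <- .schemas[[schema_name]]
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  unknown <- setdiff(names(df), names(sc$cols))
  if (length(unknown))
    stop("unknown column(s) in ", basename(path), ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(names(sc$cols), names(df))
  if (length(missing))
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- df[names(sc$cols)]
  for (cn in names(sc$cols)) {
    coerced <- switch(sc$cols[[cn]],
                      numeric = suppressWarnings(as.numeric(df[[cn]])),
                      character = as.character(df[[cn]]))
    if (sc$cols[[cn]] == "numeric" && anyNA(coerced) && !anyNA(df[[cn]]))
      stop(sprintf("column '%s' of %s is not numeric (first bad row: %d)",
                   cn, basename(path),
                   which(is.na(coerced))[1]), call. = FALSE)
    df[[cn]] <- coerced
    chk <- sc$checks[[cn]]
    if (!is.null(chk)) {
      ok <- chk(df[[cn]])
      if (!all(ok, na.rm = FALSE))
        stop(sprintf("invalid value in column '%s', row %d of %s",
                     cn, which(!ok)[1], basename(path)), call. = FALSE)
    }
  }
  df
}

#' Write an interchange CSV
#'
#' @param df Data frame conforming to the named schema.
#' @param path Output path.
#' @param schema_name Schema to validate against before writing.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, schema_name = names(.schemas)) {
  schema_name <- match.arg(schema_name)
  sc <- .schemas[[schema_name]]
  if (!setequal(names(df), names(sc$cols)))
    stop("data frame does not match schema '", schema_name, "'",
         call. = FALSE)
  utils::write.csv(df[names(sc$cols)], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a digestion-protocol YAML config
#'
#' YAML is the one canonical config dialect; keys mirror the arguments of
#' [digestion_protocol()] field-for-field and unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A [digestion_protocol()].
#' @export
read_protocol_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  allowed <- names(formals(digestion_protocol))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown protocol key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(digestion_protocol, cfg)
}

#' Read a formula-spec YAML config
#'
#' @param path YAML file path; keys mirror [formula_spec()] arguments.
#' @return A [formula_spec()].
#' @export
read_formula_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  allowed <- names(formals(formula_spec))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown formula key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(formula_spec, cfg)
}

#' Export a simulation as a tidy time-series CSV
#'
#' Long format with one row per (time, compartment): the chyme state at
#' every recorded grid point and every emptied aliquot.
#'
#' @param ts A `gastric_time_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "gastric_time_series"))
  ch <- data.frame(sample = ts$formula$name, time_min = ts$states$time,
                   compartment = "chyme", mass_g = ts$states$chyme_mass,
                   protein_g = ts$states$protein_g,
                   lipid_g = ts$states$lipid_g, ph = ts$states$ph)
  em <- if (nrow(ts$aliquots))
    data.frame(sample = ts$formula$name, time_min = ts$aliquots$time,
               compartment = "emptied", mass_g = ts$aliquots$mass_g,
               protein_g = ts$aliquots$protein_g,
               lipid_g = ts$aliquots$lipid_g, ph = NA_real_)
  else NULL
  write_table(rbind(ch, em), path, "timeseries")
}

#' Write a synthetic study bundle to disk
#'
#' Writes the four interchange CSVs plus a JSON manifest of file paths,
#' provenance (seed, generator) and true generating parameters.
#'
#' @param study A `synthetic_study` from [synth_study()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_study_bundle <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list(psd = "psd.csv", retention = "retention.csv",
                bands = "bands.csv", groups = "groups.csv")
  write_table(study$psd, file.path(dir, files$psd), "psd")
  write_table(study$retention, file.path(dir, files$retention), "retention")
  write_table(study$bands, file.path(dir, files$bands), "bands")
  write_table(study$groups, file.path(dir, files$groups), "groups")
  manifest <- c(list(files = files), study$manifest)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mp)
}

#' Read a study bundle directory
#'
#' Validates and loads the CSVs referenced by a bundle's `manifest.json`
#' (or the default file names when no manifest is present). All files must
#' exist and pass schema validation before anything is returned.
#'
#' @param dir Bundle directory.
#' @return List with `psd`, `retention`, `bands`, `groups` data frames and
#'   `manifest` (or `NULL`).
#' @export
read_study_bundle <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(mp)) jsonlite::read_json(mp) else NULL
  files <- if (!is.null(manifest)) manifest$files
  else list(psd = "psd.csv", retention = "retention.csv",
            bands = "bands.csv", groups = "groups.csv")
  paths <- lapply(files, function(f) file.path(dir, f))
  missing <- !vapply(paths, file.exists, logical(1))
  if (any(missing))
    stop("bundle incomplete; missing: ",
         paste(unlist(files)[missing], collapse = ", "), call. = FALSE)
  list(psd = read_table(paths$psd, "psd"),
       retention = read_table(paths$retention, "retention"),
       bands = read_table(paths$bands, "bands"),
       groups = read_table(paths$groups, "groups"),
       manifest = manifest)
}

# Rebuild psd objects from long-format rows for one sample/time/dispersant.
psd_from_rows <- function(rows) {
  rows <- rows[order(rows$bin_lo_um), ]
  edges <- c(rows$bin_lo_um, rows$bin_hi_um[nrow(rows)])
  if (any(abs(rows$bin_hi_um[-nrow(rows)] - rows$bin_lo_um[-1]) > 1e-9))
    stop("PSD bins are not contiguous", call. = FALSE)
  psd(edges, rows$volume_frac, dispersant = rows$dispersant[1],
      sample_id = rows$sample[1], time = rows$time_min[1])
}
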