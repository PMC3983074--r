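## Plain-text parameter (.prm) files control the command-line workflows:
## one `KEY value` pair per line, `#` comments, values kept as strings and
## coerced by the consumer. Recognised keys are documented in the CLI help
## (RECEPTOR_FILE, REF_MOL, SITE_MAPPER, RADIUS, SMALL_SPHERE, LARGE_SPHERE,
## GRID_STEP, SCORING_FUNCTION, WEIGHT.*, LIGAND_FILE, CAVITY_FILE, NRUNS,
## PROTOCOL, SEED, ...).

#' Read a parameter (.prm) file
#'
#' @param path file path.
#' @return named character vector of key/value pairs (later duplicates
#'   override earlier ones).
#' @export
readPrmFile <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- character()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^(\\S+)\\s+(.*)$", ln))[[1]]
    if (length(m) < 3) stop("malformed .prm line: ", ln)
    out[m[2]] <- trimws(m[3])
  }
  out
}

prmGet <- function(prm, key, default = NULL) {
  if (key %in% names(prm)) prm[[key]] else default
}

prmNum <- function(prm, key, default = NULL) {
  v <- prmGet(prm, key, default)
  if (is.null(v)) NULL else as.numeric(v)
}

#' Build a scoring configuration from .prm keys
#'
#' Honours \code{SCORING_FUNCTION} (SF3|SF5), \code{VDW_FORM} and any
#' \code{WEIGHT.<name>} overrides.
#'
#' @param prm named character vector from [readPrmFile()].
#' @return a [ScoringConfig-class].
#' @export
scoringConfigFromPrm <- function(prm) {
  sf <- toupper(prmGet(prm, "SCORING_FUNCTION", "SF3"))
  w <- c()
  wkeys <- grep("^WEIGHT\\.", names(prm), value = TRUE)
  if (length(wkeys)) {
    w <- as.numeric(prm[wkeys])
    names(w) <- tolower(sub("^WEIGHT\\.", "", wkeys))
  }
  scoringConfig(sf = sf, vdwForm = prmGet(prm, "VDW_FORM", "6-12"),
                weights = w)
}

#' Write / read a vdW grid set
#'
#' Portable JSON container (lattice geometry plus one flattened value
#' vector per ligand class, column-major).
#'
#' @param grids a [VdwGridSet-class].
#' @param path file path.
#' @return `writeVdwGrids`: invisibly, the path; `readVdwGrids`: the
#'   reconstructed [VdwGridSet-class].
#' @export
writeVdwGrids <- function(grids, path) {
  obj <- list(format = "moldock-vdwgrid-1", origin = grids@origin,
              spacing = grids@spacing, dims = grids@dims,
              classes = names(grids@grids),
              values = lapply(grids@grids, as.numeric))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeVdwGrids
#' @export
readVdwGrids <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "moldock-vdwgrid-1"))
    stop("not a vdW grid file: ", path)
  dims <- as.integer(obj$dims)
  grids <- lapply(obj$values, function(v) array(as.numeric(v), dim = dims))
  names(grids) <- obj$classes
  new("VdwGridSet", origin = as.numeric(obj$origin),
      spacing = as.numeric(obj$spacing), dims = dims, grids = grids)
}
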