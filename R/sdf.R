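## MDL SDF (V2000) reading and writing. Implemented in-package because the
## engine's contract requires formal charges from M CHG lines and byte-
## faithful round-tripping of data fields, which the available readers do not
## preserve. Only the V2000 connection table is supported.

sdfBondOrder <- c("1" = "1", "2" = "2", "3" = "3", "4" = "ar")
sdfOrderCode <- c("1" = 1L, "2" = 2L, "3" = 3L, "ar" = 4L, "am" = 1L)

#' Read ligands from an MDL SD file
#'
#' Parses every V2000 record into a [Ligand-class]: atoms, bonds, formal
#' charges (from \code{M  CHG} lines, falling back to the legacy atom-block
#' charge column), and all SD data fields verbatim. Rotatable dihedrals are
#' perceived on each ligand.
#'
#' @param path SD file path.
#' @return list of [Ligand-class]; an empty file yields an empty list with a
#'   warning.
#' @export
readSdf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ## strip trailing blank lines
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (!length(lines)) {
    warning("empty SD file: ", path)
    return(list())
  }
  recs <- split(lines, cumsum(c(TRUE, head(lines, -1) == "$$$$")))
  out <- vector("list", 0)
  for (ri in seq_along(recs)) {
    rec <- recs[[ri]]
    rec <- rec[rec != "$$$$"]
    if (!length(rec) || all(!nzchar(trimws(rec)))) next
    out[[length(out) + 1L]] <- parseSdfRecord(rec, ri)
  }
  if (!length(out)) warning("no records in SD file: ", path)
  out
}

parseSdfRecord <- function(rec, recordIndex) {
  if (length(rec) < 4)
    stop("SDF record ", recordIndex, ": truncated header")
  name <- rec[1]
  counts <- rec[4]
  nA <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nB <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(nA) || is.na(nB))
    stop("SDF record ", recordIndex, ": bad counts line")
  if (length(rec) < 4 + nA + nB)
    stop("SDF record ", recordIndex,
         ": counts line inconsistent with record length")
  atomLines <- rec[4 + seq_len(nA)]
  bondLines <- if (nB > 0) rec[4 + nA + seq_len(nB)] else character()

  xyz <- matrix(0, nA, 3)
  el <- character(nA)
  legacyChg <- integer(nA)
  legacyMap <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L,
                 `7` = -3L)
  for (k in seq_len(nA)) {
    ln <- atomLines[k]
    xyz[k, 1] <- as.numeric(substr(ln, 1, 10))
    xyz[k, 2] <- as.numeric(substr(ln, 11, 20))
    xyz[k, 3] <- as.numeric(substr(ln, 21, 30))
    el[k] <- trimws(substr(ln, 31, 34))
    cc <- trimws(substr(ln, 37, 39))
    if (nzchar(cc) && cc %in% names(legacyMap)) legacyChg[k] <- legacyMap[[cc]]
    if (any(is.na(xyz[k, ])) || !nzchar(el[k]))
      stop("SDF record ", recordIndex, ": malformed atom line ", k)
  }
  bi <- integer(nB); bj <- integer(nB); bo <- character(nB)
  for (k in seq_len(nB)) {
    ln <- bondLines[k]
    bi[k] <- as.integer(substr(ln, 1, 3))
    bj[k] <- as.integer(substr(ln, 4, 6))
    code <- trimws(substr(ln, 7, 9))
    bo[k] <- if (code %in% names(sdfBondOrder)) sdfBondOrder[[code]] else "1"
    if (is.na(bi[k]) || is.na(bj[k]) || bi[k] > nA || bj[k] > nA)
      stop("SDF record ", recordIndex, ": malformed bond line ", k)
  }

  rest <- rec[-seq_len(4 + nA + nB)]
  charges <- legacyChg
  mEndAt <- which(trimws(rest) == "M  END" | trimws(rest) == "M END")
  props <- if (length(mEndAt)) rest[seq_len(mEndAt[1])] else character()
  chgLines <- props[startsWith(props, "M  CHG")]
  if (length(chgLines)) {
    charges <- integer(nA)  # M CHG supersedes the legacy column entirely
    for (ln in chgLines) {
      toks <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))),
                                  "\\s+")[[1]])
      cnt <- toks[1]
      for (p in seq_len(cnt)) {
        charges[toks[2 * p]] <- toks[2 * p + 1]
      }
    }
  }

  fieldPart <- if (length(mEndAt)) rest[-seq_len(mEndAt[1])] else rest
  sdFields <- parseSdFields(fieldPart)

  mol <- buildMolecule(el, xyz,
                       data.frame(i = bi, j = bj, order = bo,
                                  stringsAsFactors = FALSE),
                       formalCharges = charges, name = name,
                       sdFields = sdFields)
  new("Ligand", molecule = mol,
      rotatableDihedrals = perceiveRotatableDihedrals(mol))
}

parseSdFields <- function(lines) {
  out <- character()
  nms <- character()
  k <- 1
  while (k <= length(lines)) {
    ln <- lines[k]
    if (startsWith(ln, ">")) {
      m <- regmatches(ln, regexec("<([^>]*)>", ln))[[1]]
      nm <- if (length(m) >= 2) m[2] else trimws(sub("^>", "", ln))
      vals <- character()
      k <- k + 1
      while (k <= length(lines) && nzchar(trimws(lines[k])) &&
             !startsWith(lines[k], ">")) {
        vals <- c(vals, lines[k])
        k <- k + 1
      }
      nms <- c(nms, nm)
      out <- c(out, paste(vals, collapse = "\n"))
    } else {
      k <- k + 1
    }
  }
  names(out) <- nms
  out
}

#' Write ligand poses to an MDL SD file
#'
#' Writes V2000 records with the current coordinates. Original input data
#' fields are preserved; when a [ScoreBreakdown-class] accompanies a pose,
#' the fields \code{SCORE}, \code{SCORE.INTER}, \code{SCORE.INTRA},
#' \code{SCORE.SITE} and \code{SCORE.RESTR} are appended. Output is
#' deterministic (no timestamps).
#'
#' @param ligands list of [Ligand-class] (or a single Ligand).
#' @param path output file path.
#' @param scores optional list of [ScoreBreakdown-class], one per ligand, or
#'   NULL.
#' @return invisibly, the path.
#' @export
writeSdf <- function(ligands, path, scores = NULL) {
  if (is(ligands, "Ligand")) ligands <- list(ligands)
  if (!is.null(scores) && is(scores, "ScoreBreakdown")) scores <- list(scores)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(ligands)) {
    sb <- if (!is.null(scores)) scores[[k]] else NULL
    writeLines(formatSdfRecord(ligands[[k]], sb), con)
  }
  invisible(path)
}

formatSdfRecord <- function(lig, breakdown = NULL) {
  mol <- molecule(lig)
  at <- mol@atoms
  bd <- mol@bonds
  nA <- nrow(at); nB <- nrow(bd)
  out <- c(mol@name, "  moldock", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nA, nB))
  for (k in seq_len(nA)) {
    out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                          at$x[k], at$y[k], at$z[k], at$element[k]))
  }
  for (k in seq_len(nB)) {
    code <- sdfOrderCode[[bd$order[k]]]
    out <- c(out, sprintf("%3d%3d%3d%3d", bd$i[k], bd$j[k], code, 0L))
  }
  chg <- which(at$formalCharge != 0L)
  while (length(chg)) {
    take <- head(chg, 8)
    chg <- chg[-seq_along(take)]
    out <- c(out, paste0("M  CHG", sprintf("%3d", length(take)),
                         paste0(sprintf("%4d%4d", take,
                                        at$formalCharge[take]),
                                collapse = "")))
  }
  out <- c(out, "M  END")
  fields <- mol@sdFields
  if (!is.null(breakdown)) {
    sc <- c(SCORE = breakdown@total,
            SCORE.INTER = breakdown@inter,
            SCORE.INTRA = breakdown@intra,
            SCORE.SITE = breakdown@site,
            SCORE.RESTR = breakdown@restraint)
    sv <- vapply(sc, function(x) formatC(x, digits = 6, format = "f"), "")
    fields <- c(fields[setdiff(names(fields), names(sv))], sv)
  }
  for (nm in names(fields)) {
    out <- c(out, sprintf(">  <%s>", nm),
             strsplit(fields[[nm]], "\n", fixed = TRUE)[[1]], "")
  }
  c(out, "$$$$")
}
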