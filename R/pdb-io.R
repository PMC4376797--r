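# Fixed-width PDB record parsing (columns per the PDB format spec):
# name 13-16, altLoc 17, resName 18-20, chain 22, resSeq 23-26, iCode 27,
# x/y/z 31-38/39-46/47-54, occupancy 55-60, bfactor 61-66, element 77-78.
parseAtomRecords <- function(lines, lineno) {
  num <- function(txt, what) {
    v <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(v) & nzchar(trimws(txt)) | !nzchar(trimws(txt)))
    if (length(bad))
      stop("malformed ATOM record at line ", lineno[bad[1]], ": bad ", what,
           " field", call. = FALSE)
    v
  }
  data.frame(
    record = trimws(substr(lines, 1, 6)),
    name = trimws(substr(lines, 13, 16)),
    altloc = substr(lines, 17, 17),
    resname = trimws(substr(lines, 18, 20)),
    chain = substr(lines, 22, 22),
    resno = as.integer(num(substr(lines, 23, 26), "residue number")),
    icode = trimws(substr(lines, 27, 27)),
    x = num(substr(lines, 31, 38), "x coordinate"),
    y = num(substr(lines, 39, 46), "y coordinate"),
    z = num(substr(lines, 47, 54), "z coordinate"),
    line = lineno,
    stringsAsFactors = FALSE
  )
}

atomKey <- function(df)
  sprintf("%s:%d%s:%s", df$chain, df$resno, df$icode, df$name)

# split file lines into models; a file without MODEL records is one model
splitModels <- function(lines) {
  isModel <- startsWith(lines, "MODEL")
  isEnd <- startsWith(lines, "ENDMDL")
  if (!any(isModel)) return(list(seq_along(lines)))
  starts <- which(isModel)
  ends <- which(isEnd)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines) + 1L)
  Map(function(s, e) if (s + 1L <= e - 1L) (s + 1L):(e - 1L) else integer(),
      starts, ends[seq_along(starts)])
}

selectAtoms <- function(df, selection) {
  keep <- df$altloc %in% c(" ", "A", "")
  if (identical(selection, "calpha")) {
    # CA *atoms*, not calcium: calcium ions carry residue name CA (and are
    # HETATM records); both are excluded here
    keep <- keep & df$record == "ATOM" & df$name == "CA" & df$resname != "CA"
  } else if (is.list(selection)) {
    keep <- keep & df$record == "ATOM"
    if (!is.null(selection$name)) keep <- keep & df$name %in% selection$name
    if (!is.null(selection$chain)) keep <- keep & df$chain %in% selection$chain
  } else {
    stop("selection must be \"calpha\" or a list(name=, chain=)", call. = FALSE)
  }
  df[keep, , drop = FALSE]
}

#' Read a multi-model PDB trajectory
#'
#' Parses MODEL/ENDMDL blocks of a PDB file with fixed-width columns and
#' returns the selected atoms of every model as a [Trajectory-class].  A file
#' without MODEL records is treated as a single-frame trajectory.  Alternate
#' locations other than blank or `A` are dropped.  The atom roster is taken
#' from the first model; every later model must present exactly the same
#' roster in the same order.
#'
#' @param path PDB file path.
#' @param selection `"calpha"` (default: `ATOM` records named `CA`, excluding
#'   calcium ions) or a `list(name =, chain =)` filter over `ATOM` records.
#' @return a [Trajectory-class].
#' @seealso [writeAnnotatedPDB()], [writePDBTrajectory()]
#' @export
readPDBTrajectory <- function(path, selection = "calpha") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  models <- splitModels(lines)
  isAtom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  frames <- vector("list", length(models))
  roster <- NULL
  modelLabels <- numeric(length(models))
  for (m in seq_along(models)) {
    idx <- models[[m]][isAtom[models[[m]]]]
    if (length(models) > 1 || startsWith(lines[max(1, models[[m]][1] - 1)], "MODEL")) {
      lab <- suppressWarnings(as.numeric(trimws(substr(
        lines[models[[m]][1] - 1L], 7, 80))))
      modelLabels[m] <- if (length(lab) == 1 && !is.na(lab)) lab else m
    } else modelLabels[m] <- m
    df <- selectAtoms(parseAtomRecords(lines[idx], idx), selection)
    if (nrow(df) == 0L)
      stop("no atoms match the selection in model ", m, " of ", path,
           call. = FALSE)
    ids <- atomKey(df)
    if (m == 1L) {
      if (anyDuplicated(ids))
        stop("duplicate atom id in model 1: ", ids[duplicated(ids)][1],
             call. = FALSE)
      roster <- data.frame(id = ids, name = df$name, resname = df$resname,
                           chain = df$chain, resno = df$resno,
                           icode = df$icode, stringsAsFactors = FALSE)
    } else if (!identical(ids, roster$id)) {
      bad <- which(!(seq_along(ids) <= length(roster$id) &
                     ids == roster$id[seq_along(ids)]))[1]
      stop("atom roster mismatch in model ", m, ": atom ",
           if (is.na(bad)) "(count differs)" else ids[bad],
           " does not match the first model", call. = FALSE)
    }
    frames[[m]] <- cbind(df$x, df$y, df$z)
  }
  Trajectory(frames, roster, modelLabels)
}

#' Read occupancy and b-factor annotations from a PDB trajectory
#'
#' Companion to [readPDBTrajectory()]: returns the occupancy and b-factor
#' fields of the selected atoms for every model, as written by
#' [writeAnnotatedPDB()] (occupancy = per-frame low-set membership, b-factor
#' = per-frame displacement in Angstrom).
#'
#' @inheritParams readPDBTrajectory
#' @return list with `occupancy` and `bfactor`, each an
#'   `nAtoms x nFrames` numeric matrix with atom ids as rownames.
#' @export
readPDBAnnotations <- function(path, selection = "calpha") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  models <- splitModels(lines)
  isAtom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  cols <- lapply(models, function(mi) {
    idx <- mi[isAtom[mi]]
    df <- selectAtoms(parseAtomRecords(lines[idx], idx), selection)
    cbind(occ = as.numeric(substr(lines[df$line], 55, 60)),
          b = as.numeric(substr(lines[df$line], 61, 66)))
  })
  occ <- vapply(cols, function(m) m[, "occ"], numeric(nrow(cols[[1]])))
  b <- vapply(cols, function(m) m[, "b"], numeric(nrow(cols[[1]])))
  occ <- matrix(occ, nrow = nrow(cols[[1]]))
  b <- matrix(b, nrow = nrow(cols[[1]]))
  ids <- atomKey(selectAtoms(parseAtomRecords(
    lines[models[[1]][isAtom[models[[1]]]]],
    models[[1]][isAtom[models[[1]]]]), selection))
  rownames(occ) <- rownames(b) <- ids
  list(occupancy = occ, bfactor = b)
}

formatAtomName <- function(name) {
  ifelse(nchar(name) >= 4, sprintf("%-4s", name), sprintf(" %-3s", name))
}

guessElement <- function(name) {
  e <- sub("[0-9'].*$", "", name)
  substr(e, 1, ifelse(nchar(e) > 1 & e %in% c("CL", "BR", "FE", "MG", "ZN",
                                              "NA", "MN", "CU"), 2, 1))
}

formatAtomLine <- function(serial, name, resname, chain, resno, icode,
                           xyz, occ, b) {
  sprintf("ATOM  %5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, formatAtomName(name), resname, chain, resno,
          ifelse(nzchar(icode), icode, " "),
          xyz[, 1], xyz[, 2], xyz[, 3], occ, b, guessElement(name))
}

clampB <- function(b) {
  if (any(b > 999.99)) {
    warning("b-factor exceeds the PDB field width; clamped to 999.99")
    b <- pmin(b, 999.99)
  }
  b
}

#' Write an aligned, mobility-annotated PDB trajectory
#'
#' Writes one MODEL per frame.  The occupancy field is 1.00 for atoms in the
#' frame's low (least-mobile) set and 0.00 otherwise; the b-factor field
#' carries the per-atom displacement from the reference (Angstrom) in that
#' frame, clamped to the field width.  By default only the analyzed atoms
#' (the C-alpha trace) are written from the report's aligned coordinates.
#' When `source` names the original all-atom PDB file, every atom of each
#' model is written instead, transformed by that frame's rigid motion, with
#' non-analyzed atoms inheriting the annotation of their residue's analyzed
#' atom.
#'
#' @param report a [MobilityReport-class].
#' @param path output file path.
#' @param source optional path of the all-atom multi-model PDB the trajectory
#'   was read from.
#' @return `path`, invisibly.
#' @export
writeAnnotatedPDB <- function(report, path, source = NULL) {
  if (is.null(source)) {
    dev <- clampB(deviationSeries(report))
    at <- report@atoms
    con <- file(path, "w")
    on.exit(close(con))
    for (f in seq_len(nFrames(report))) {
      writeLines(sprintf("MODEL     %4d", f), con)
      writeLines(formatAtomLine(seq_len(nrow(at)), at$name, at$resname,
                                at$chain, at$resno, at$icode,
                                report@alignedCoords[, , f],
                                ifelse(report@lowMembership[, f], 1, 0),
                                dev[, f]), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
    return(invisible(path))
  }
  writeAllAtomAnnotated(report, path, source)
}

writeAllAtomAnnotated <- function(report, path, source) {
  lines <- readLines(source)
  models <- splitModels(lines)
  if (length(models) != nFrames(report))
    stop("source has ", length(models), " models but the report has ",
         nFrames(report), " frames", call. = FALSE)
  isAtom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  dev <- clampB(deviationSeries(report))
  resKey <- sprintf("%s:%d%s", report@atoms$chain, report@atoms$resno,
                    report@atoms$icode)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(models)) {
    idx <- models[[f]][isAtom[models[[f]]]]
    df <- parseAtomRecords(lines[idx], idx)
    tr <- frameTransform(report, f)
    xyz <- applyTransform(tr, cbind(df$x, df$y, df$z))
    m <- match(sprintf("%s:%d%s", df$chain, df$resno, df$icode), resKey)
    occ <- ifelse(!is.na(m) & report@lowMembership[ifelse(is.na(m), 1, m), f],
                  1, 0)
    b <- ifelse(is.na(m), 0, dev[ifelse(is.na(m), 1, m), f])
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(formatAtomLine(seq_len(nrow(df)), df$name, df$resname,
                              df$chain, df$resno, df$icode, xyz, occ, b), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a plain multi-model PDB trajectory
#'
#' Writes a [Trajectory-class] (e.g. a synthetic one) as MODEL/ENDMDL blocks
#' with unit occupancy and zero b-factors.
#'
#' @param traj a [Trajectory-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePDBTrajectory <- function(traj, path) {
  at <- atomData(traj)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nFrames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(formatAtomLine(seq_len(nrow(at)), at$name, at$resname,
                              at$chain, at$resno, at$icode,
                              frameCoords(traj, f), 1, 0), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
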