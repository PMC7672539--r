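#' Read a multi-model PDB file into an Ensemble
#'
#' Parses a multi-model (MODEL/ENDMDL) PDB file. All models must contain the
#' same atoms in the same order; a mismatch is a hard error naming the model.
#' Alternate locations are resolved by keeping the highest-occupancy
#' conformer; insertion codes are rejected. Masses and van der Waals radii
#' are filled from the package's fixed element table ([elementTable()]).
#'
#' State labels and replica ids written by [writeEnsemble()] are recovered
#' from `REMARK 299 STATE` / `REMARK 299 REPLICA_IDS` lines; when no REMARK
#' ids are present, a sidecar JSON file `<path>.replicas.json` (an array of
#' one integer per model) is honoured if it exists.
#'
#' @param path path to a PDB file.
#' @param format only `"pdb_multimodel"` is supported.
#' @return An [Ensemble-class].
#' @seealso [writeEnsemble()], [selectAtoms()]
#' @export
readEnsemble <- function(path, format = "pdb_multimodel") {
  format <- match.arg(format, "pdb_multimodel")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  isAtom <- grepl("^(ATOM  |HETATM)", lines)
  modelStarts <- grep("^MODEL", lines)
  if (length(modelStarts) > 1) {
    modelEnds <- grep("^ENDMDL", lines)
    if (length(modelEnds) != length(modelStarts))
      stop("inconsistent MODEL/ENDMDL blocks in ", path)
    counts <- vapply(seq_along(modelStarts), function(i)
      sum(isAtom[modelStarts[i]:modelEnds[i]]), 0L)
    if (length(unique(counts)) > 1) {
      ref <- counts[1]
      bad <- which(counts != ref)[1]
      stop(sprintf("model %d has %d atoms, expected %d", bad, counts[bad], ref))
    }
  }

  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (any(!is.na(at$insert) & at$insert != ""))
    stop("insertion codes are not supported (residue ",
         at$resno[which(!is.na(at$insert) & at$insert != "")[1]], ")")

  keep <- seq_len(nrow(at))
  alt <- at$alt
  if (any(!is.na(alt) & alt != "")) {
    key <- paste(at$chain, at$resno, at$resid, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    ord <- order(key, -occ)
    keep <- sort(ord[!duplicated(key[ord])])
  }

  elesy <- at$elesy[keep]
  miss <- is.na(elesy) | elesy == ""
  if (any(miss))  # fall back to the first letter of the atom name
    elesy[miss] <- substr(gsub("[0-9]", "", at$elety[keep][miss]), 1, 1)
  params <- .elementParams(elesy, at$elety[keep])

  atoms <- data.frame(
    serial = seq_along(keep),
    name = at$elety[keep],
    element = toupper(elesy),
    resno = at$resno[keep],
    resname = at$resid[keep],
    chain = ifelse(is.na(at$chain[keep]), "A", at$chain[keep]),
    mass = params$mass,
    vdw = params$vdw,
    stringsAsFactors = FALSE
  )

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nm <- nrow(xyz)
  cols <- as.vector(rbind(keep * 3 - 2, keep * 3 - 1, keep * 3))
  co <- array(NA_real_, c(length(keep), 3, nm))
  for (m in seq_len(nm)) co[, , m] <- matrix(xyz[m, cols], ncol = 3, byrow = TRUE)

  state <- "unlabelled"
  repl <- integer(0)
  rem <- lines[grepl("^REMARK 299", lines)]
  st <- sub("^REMARK 299 STATE +", "", rem[grepl("^REMARK 299 STATE ", rem)])
  if (length(st)) state <- trimws(st[1])
  ri <- rem[grepl("^REMARK 299 REPLICA_IDS", rem)]
  if (length(ri)) {
    repl <- as.integer(unlist(strsplit(trimws(
      sub("^REMARK 299 REPLICA_IDS", "", ri)), " +")))
  } else if (file.exists(paste0(path, ".replicas.json"))) {
    repl <- as.integer(jsonlite::read_json(paste0(path, ".replicas.json"),
                                           simplifyVector = TRUE))
  }
  if (length(repl) && length(repl) != nm)
    stop("replica id list has ", length(repl), " entries for ", nm, " models")

  new("Ensemble", atoms = atoms, coords = co, stateLabel = state,
      replicaId = repl, source = normalizePath(path))
}

#' Write an Ensemble as a multi-model PDB file
#'
#' Writes standard MODEL/ENDMDL blocks preserving model order. The state
#' label and any replica ids are recorded in `REMARK 299` lines (a package
#' convention that [readEnsemble()] understands; foreign software ignores
#' REMARKs). Coordinates are written with the standard 3-decimal PDB
#' precision, so round-trips are exact to 1e-3 Angstrom.
#'
#' @param e an [Ensemble-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEnsemble <- function(e, path) {
  stopifnot(is(e, "Ensemble"))
  if (nModels(e) < 1) stop("ensemble has no models")
  X <- .coordMatrix(e)
  a <- e@atoms
  bio3d::write.pdb(file = path, xyz = X, type = "ATOM",
                   resno = a$resno, resid = a$resname,
                   eleno = a$serial, elety = a$name,
                   chain = a$chain, elesy = a$element)
  body <- readLines(path, warn = FALSE)
  rem <- paste("REMARK 299 STATE", e@stateLabel)
  if (length(e@replicaId)) {
    ids <- e@replicaId
    chunks <- split(ids, ceiling(seq_along(ids) / 20))
    rem <- c(rem, vapply(chunks, function(ch)
      paste("REMARK 299 REPLICA_IDS", paste(ch, collapse = " ")), ""))
  }
  writeLines(c(rem, body), path)
  invisible(path)
}

# Logical mask of atoms matched by a selection.
.matchSelection <- function(atoms, sel) {
  m <- rep(TRUE, nrow(atoms))
  if (length(sel@resno)) m <- m & atoms$resno %in% sel@resno
  if (length(sel@atomNames)) m <- m & atoms$name %in% sel@atomNames
  if (length(sel@chains)) m <- m & atoms$chain %in% sel@chains
  if (sel@heavyOnly) m <- m & atoms$element != "H"
  m
}

#' Restrict an Ensemble to a subset of models
#'
#' Keeps the given models (in the given order) together with their replica
#' ids.
#'
#' @param e an [Ensemble-class].
#' @param idx model indices.
#' @return An [Ensemble-class] with `length(idx)` models.
#' @export
subsetModels <- function(e, idx) {
  stopifnot(is(e, "Ensemble"))
  idx <- as.integer(idx)
  if (any(idx < 1 | idx > nModels(e))) stop("model index out of range")
  new("Ensemble", atoms = e@atoms,
      coords = e@coords[, , idx, drop = FALSE],
      stateLabel = e@stateLabel,
      replicaId = if (length(e@replicaId)) e@replicaId[idx] else integer(0),
      source = e@source)
}

#' Restrict an Ensemble to an atom selection
#'
#' All models are sliced identically and atom order is preserved, so
#' applying the same selection twice is a no-op.
#'
#' @param e an [Ensemble-class].
#' @param sel an [atomSelection()].
#' @return A new, restricted [Ensemble-class].
#' @examples
#' # Calpha trace of the structured core:
#' # selectAtoms(e, atomSelection(resno = 310:394, atomNames = "CA"))
#' @export
selectAtoms <- function(e, sel) {
  stopifnot(is(e, "Ensemble"), is(sel, "AtomSelection"))
  m <- .matchSelection(e@atoms, sel)
  if (!any(m)) stop("selection matches no atoms")
  idx <- which(m)
  atoms <- e@atoms[idx, , drop = FALSE]
  rownames(atoms) <- NULL
  new("Ensemble", atoms = atoms,
      coords = e@coords[idx, , , drop = FALSE],
      stateLabel = e@stateLabel, replicaId = e@replicaId,
      source = e@source)
}
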