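#' Ensemble: a multi-model coordinate ensemble
#'
#' An ordered set of conformers (models) sharing one atom table. Coordinates
#' are stored in Angstrom in a `natoms x 3 x nmodels` array. Each ensemble
#' carries a free-text state label (e.g. `"ff"`, `"fd"`, `"cf"`, `"cd"` for
#' free/complex x full/truncated) and, optionally, one replica id per model
#' for ensembles concatenated from parallel trajectories.
#'
#' @slot atoms data.frame with columns `serial`, `name`, `element`, `resno`,
#'   `resname`, `chain`, `mass` (amu), `vdw` (Angstrom).
#' @slot coords numeric array, `dim = c(natoms, 3, nmodels)`, Angstrom.
#' @slot stateLabel character scalar tag.
#' @slot replicaId integer vector of length `nmodels`, or `integer(0)`.
#' @slot source character provenance string.
#' @export
setClass("Ensemble", representation(
  atoms = "data.frame",
  coords = "array",
  stateLabel = "character",
  replicaId = "integer",
  source = "character"
))

setValidity("Ensemble", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "element", "resno", "resname", "chain",
            "mass", "vdw")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  d <- dim(object@coords)
  if (length(d) != 3 || d[2] != 3)
    return("coords must be a natoms x 3 x nmodels array")
  if (d[1] != nrow(a))
    return(sprintf("coords has %d atoms but atom table has %d", d[1], nrow(a)))
  if (d[3] < 1) return("an Ensemble needs at least one model")
  if (!all(is.finite(object@coords))) return("all coordinates must be finite")
  if (any(a$mass <= 0)) return("all masses must be > 0")
  if (any(a$vdw <= 0)) return("all vdW radii must be > 0")
  key <- paste(a$chain, a$resno, a$name)
  if (anyDuplicated(key))
    return(paste("duplicated (chain, resno, name) atom key:",
                 key[duplicated(key)][1]))
  if (length(object@replicaId) &&
      length(object@replicaId) != d[3])
    return("replicaId must have one entry per model (or be empty)")
  TRUE
})

#' Construct an Ensemble
#'
#' @param atoms atom table (see [Ensemble-class]); `mass`/`vdw` are filled
#'   from [elementTable()] when absent.
#' @param coords `natoms x 3 x nmodels` array, or a single `natoms x 3`
#'   matrix, in Angstrom.
#' @param stateLabel free-text state tag.
#' @param replicaId optional integer replica id per model.
#' @param source provenance string.
#' @return An [Ensemble-class] object.
#' @export
Ensemble <- function(atoms, coords, stateLabel = "unlabelled",
                     replicaId = integer(0), source = "in-memory") {
  if (is.matrix(coords)) coords <- array(coords, c(nrow(coords), 3, 1))
  if (!("mass" %in% names(atoms)) || !("vdw" %in% names(atoms))) {
    p <- .elementParams(atoms$element, atoms$name)
    atoms$mass <- p$mass
    atoms$vdw <- p$vdw
  }
  if (!("serial" %in% names(atoms))) atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  new("Ensemble", atoms = atoms, coords = coords,
      stateLabel = as.character(stateLabel),
      replicaId = as.integer(replicaId), source = as.character(source))
}

#' @describeIn Ensemble Number of models (conformers).
#' @param x,object an `Ensemble`.
#' @export
nModels <- function(x) dim(x@coords)[3]

#' @describeIn Ensemble Number of atoms.
#' @export
nAtoms <- function(x) dim(x@coords)[1]

#' @describeIn Ensemble Atom table accessor.
#' @export
atomTable <- function(x) x@atoms

#' @describeIn Ensemble Coordinate array accessor (`natoms x 3 x nmodels`).
#' @export
coords <- function(x) x@coords

#' @describeIn Ensemble State label accessor.
#' @export
stateLabel <- function(x) x@stateLabel

#' @describeIn Ensemble Replica id accessor (may be `integer(0)`).
#' @export
replicaIds <- function(x) x@replicaId

#' @describeIn Ensemble Coordinates of one model as a `natoms x 3` matrix.
#' @param i model index.
#' @export
modelCoords <- function(x, i) {
  x@coords[, , i, drop = TRUE]
}

setMethod("show", "Ensemble", function(object) {
  cat("Ensemble '", object@stateLabel, "': ", nModels(object), " models x ",
      nAtoms(object), " atoms (", length(unique(object@atoms$resno)),
      " residues)\n", sep = "")
  if (length(object@replicaId))
    cat("  replicas:", paste(unique(object@replicaId), collapse = " "), "\n")
  cat("  source:", object@source, "\n")
})

#' AtomSelection: a declarative atom selection
#'
#' Selections are predicates on the atom table; applying one preserves atom
#' order and is idempotent. Empty criteria match everything.
#'
#' @slot resno integer residue numbers to keep (empty = all).
#' @slot atomNames atom names to keep (empty = all).
#' @slot chains chains to keep (empty = all).
#' @slot heavyOnly drop hydrogens when `TRUE`.
#' @export
setClass("AtomSelection", representation(
  resno = "integer", atomNames = "character", chains = "character",
  heavyOnly = "logical"
))

#' @describeIn AtomSelection-class Constructor.
#' @param resno,atomNames,chains,heavyOnly selection criteria; `NULL` means
#'   "no restriction".
#' @export
atomSelection <- function(resno = NULL, atomNames = NULL, chains = NULL,
                          heavyOnly = FALSE) {
  new("AtomSelection",
      resno = as.integer(resno %||% integer(0)),
      atomNames = as.character(atomNames %||% character(0)),
      chains = as.character(chains %||% character(0)),
      heavyOnly = isTRUE(heavyOnly))
}

setMethod("show", "AtomSelection", function(object) {
  bit <- function(lab, v) if (length(v)) paste0(lab, "=",
    paste(v, collapse = ",")) else NULL
  parts <- c(bit("resno", .rangeLabel(object@resno)),
             bit("name", object@atomNames), bit("chain", object@chains),
             if (object@heavyOnly) "heavy-only")
  cat("AtomSelection(", paste(parts, collapse = "; "), ")\n", sep = "")
})

#' CovarianceModel: coordinate covariance of an ensemble selection
#'
#' Population (1/N) covariance of the 3N coordinate vector of an atom
#' selection across models, with the per-atom masses needed for
#' mass-weighted entropy estimators.
#'
#' @slot mean numeric 3N mean coordinate vector, Angstrom.
#' @slot sigma 3N x 3N covariance matrix, Angstrom^2.
#' @slot masses numeric per-atom masses, amu (all 1 when unweighted).
#' @slot nModels integer number of models used.
#' @slot selection character descriptor of the atom selection.
#' @export
setClass("CovarianceModel", representation(
  mean = "numeric", sigma = "matrix", masses = "numeric",
  nModels = "integer", selection = "character"
))

setValidity("CovarianceModel", function(object) {
  p <- length(object@mean)
  if (!all(dim(object@sigma) == c(p, p)))
    return("sigma must be 3N x 3N matching mean")
  if (length(object@masses) * 3 != p)
    return("masses must have one entry per atom")
  if (max(abs(object@sigma - t(object@sigma))) > 1e-8 * (1 + max(abs(object@sigma))))
    return("sigma must be symmetric")
  TRUE
})

setMethod("show", "CovarianceModel", function(object) {
  cat("CovarianceModel:", length(object@masses), "atoms,",
      object@nModels, "models;", object@selection, "\n")
  cat("  trace:", format(sum(diag(object@sigma))), "A^2\n")
})

#' ModeSpace: principal components of a (combined) ensemble
#'
#' Eigenvectors/eigenvalues of the fitted coordinate covariance of a pooled
#' ensemble, with per-conformer projections labelled by source ensemble and
#' replica.
#'
#' @slot mean numeric 3N mean coordinate vector (Angstrom).
#' @slot vectors 3N x k orthonormal eigenvector matrix, descending eigenvalue.
#' @slot values numeric eigenvalues, Angstrom^2.
#' @slot totalVariance numeric, total fitted coordinate variance (Angstrom^2).
#' @slot projections numeric nConformers x k matrix of projections (Angstrom).
#' @slot info data.frame with one row per conformer: `ensemble`, `replica`,
#'   `model`.
#' @slot atoms atom table of the analysed selection.
#' @export
setClass("ModeSpace", representation(
  mean = "numeric", vectors = "matrix", values = "numeric",
  totalVariance = "numeric", projections = "matrix", info = "data.frame",
  atoms = "data.frame"
))

setValidity("ModeSpace", function(object) {
  k <- length(object@values)
  if (ncol(object@vectors) != k) return("vectors/values size mismatch")
  if (k > 1 && any(diff(object@values) > 1e-9))
    return("eigenvalues must be in descending order")
  if (any(object@values < -1e-9)) return("eigenvalues must be non-negative")
  g <- crossprod(object@vectors)
  if (max(abs(g - diag(k))) > 1e-8)
    return("eigenvectors must be orthonormal within 1e-8")
  if (nrow(object@projections) != nrow(object@info))
    return("projections/info row mismatch")
  TRUE
})

setMethod("show", "ModeSpace", function(object) {
  k <- length(object@values)
  cat("ModeSpace:", k, "modes over", nrow(object@atoms), "atoms;",
      nrow(object@info), "conformers from",
      length(unique(object@info$ensemble)), "ensemble(s)\n")
  kk <- min(5, k)
  cat("  leading variance fractions:",
      paste(sprintf("%.3f", object@values[seq_len(kk)] / object@totalVariance),
            collapse = " "), "\n")
})

#' @describeIn ModeSpace-class Eigenvalues (Angstrom^2).
#' @param x a `ModeSpace`.
#' @export
modeValues <- function(x) x@values

#' @describeIn ModeSpace-class Eigenvector matrix (3N x k).
#' @export
modeVectors <- function(x) x@vectors

#' @describeIn ModeSpace-class Projections with conformer metadata, as a
#'   data.frame with columns `ensemble`, `replica`, `model`, `PC1`, ...
#' @param k number of leading modes to include.
#' @export
modeProjections <- function(x, k = ncol(x@projections)) {
  k <- min(k, ncol(x@projections))
  p <- as.data.frame(x@projections[, seq_len(k), drop = FALSE])
  names(p) <- paste0("PC", seq_len(k))
  cbind(x@info, p)
}

#' AlignmentBlock: a multiple (structure) alignment
#'
#' Aligned sequences plus, for every structure, a residue-number track that
#' maps each non-gap column to a `(chain, resno)` in the source structure.
#'
#' @slot sequences named character vector of aligned strings (gaps `-`).
#' @slot track named list of data.frames (`chain`, `resno`), one row per
#'   non-gap position, in sequence order.
#' @export
setClass("AlignmentBlock", representation(
  sequences = "character", track = "list"
))

setValidity("AlignmentBlock", function(object) {
  if (!length(object@sequences)) return("empty alignment")
  if (is.null(names(object@sequences)) || anyDuplicated(names(object@sequences)))
    return("sequences must have unique names")
  L <- unique(nchar(object@sequences))
  if (length(L) != 1) return("all aligned strings must have equal length")
  if (!identical(sort(names(object@track)), sort(names(object@sequences))))
    return("track must have one entry per sequence")
  for (id in names(object@sequences)) {
    nres <- sum(strsplit(object@sequences[[id]], "")[[1]] != "-")
    if (nrow(object@track[[id]]) != nres)
      return(sprintf("track for '%s' has %d rows but sequence has %d residues",
                     id, nrow(object@track[[id]]), nres))
  }
  TRUE
})

#' @describeIn AlignmentBlock-class Constructor.
#' @param sequences named character vector of aligned strings.
#' @param track optional named list of `(chain, resno)` data.frames; when
#'   `NULL`, residues are numbered 1..n on chain "A".
#' @export
alignmentBlock <- function(sequences, track = NULL) {
  if (is.null(track)) {
    track <- lapply(sequences, function(s) {
      n <- sum(strsplit(s, "")[[1]] != "-")
      data.frame(chain = "A", resno = seq_len(n), stringsAsFactors = FALSE)
    })
    names(track) <- names(sequences)
  }
  new("AlignmentBlock", sequences = sequences, track = track)
}

setMethod("show", "AlignmentBlock", function(object) {
  cat("AlignmentBlock:", length(object@sequences), "structures x",
      nchar(object@sequences[[1]]), "columns\n")
  for (id in head(names(object@sequences), 6))
    cat(" ", format(id, width = 12), object@sequences[[id]], "\n")
  if (length(object@sequences) > 6) cat("  ...\n")
})

#' CoreMapping: consensus numbering of alignment-core residues
#'
#' Columns ungapped in every aligned structure, renumbered 1..K, with the
#' per-structure mapping back to `(chain, resno)` in the source coordinates.
#'
#' @slot coreColumns integer alignment column index of each core position.
#' @slot map named list of data.frames (`core`, `chain`, `resno`).
#' @export
setClass("CoreMapping", representation(
  coreColumns = "integer", map = "list"
))

setValidity("CoreMapping", function(object) {
  K <- length(object@coreColumns)
  for (id in names(object@map)) {
    m <- object@map[[id]]
    if (nrow(m) != K) return(sprintf("structure '%s' maps %d of %d core positions",
                                     id, nrow(m), K))
    if (anyDuplicated(paste(m$chain, m$resno)))
      return(sprintf("mapping for '%s' is not injective", id))
  }
  TRUE
})

setMethod("show", "CoreMapping", function(object) {
  cat("CoreMapping:", length(object@coreColumns), "core positions x",
      length(object@map), "structures\n")
})

#' ContactNetwork: graph of discriminative residue contacts
#'
#' Undirected, unweighted graph whose nodes are residues and whose edges are
#' selected (discriminative) contacts, with connected components and Brandes
#' betweenness centrality.
#'
#' @slot graph an `igraph` object.
#' @slot nodes data.frame: `residue`, `component`, `betweenness` (raw),
#'   `betweennessNorm` (x 2/((n-1)(n-2))).
#' @slot componentSizes integer vector, sorted decreasing.
#' @export
setClass("ContactNetwork", representation(
  graph = "ANY", nodes = "data.frame", componentSizes = "integer"
))

setMethod("show", "ContactNetwork", function(object) {
  cat("ContactNetwork:", nrow(object@nodes), "residues,",
      igraph::ecount(object@graph), "contacts;",
      length(object@componentSizes), "component(s) of size",
      paste(object@componentSizes, collapse = ", "), "\n")
  cat("  residues with nonzero betweenness:",
      sum(object@nodes$betweenness > 0), "\n")
})
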