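`%||%` <- function(a, b) if (is.null(a)) b else a

# Compact "301-364" style label for integer sets (display only).
.rangeLabel <- function(x) {
  if (!length(x)) return(character(0))
  x <- sort(unique(x))
  if (length(x) == 1) return(as.character(x))
  brk <- c(0, which(diff(x) != 1), length(x))
  paste(vapply(seq_len(length(brk) - 1), function(i) {
    seg <- x[(brk[i] + 1):brk[i + 1]]
    if (length(seg) == 1) as.character(seg) else
      paste0(seg[1], "-", seg[length(seg)])
  }, ""), collapse = ",")
}

# Run an expression under a fixed seed without disturbing the caller's RNG
# stream. All package-level randomness flows through this helper.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Flatten a natoms x 3 matrix into the (x1,y1,z1,x2,...) vector convention
# used throughout covariance/PCA code, and back.
.flattenXYZ <- function(m) as.vector(t(m))
.unflattenXYZ <- function(v) matrix(v, ncol = 3, byrow = TRUE)

# Stack an ensemble (optionally a subset of atoms/models) into an
# nmodels x 3N matrix, rows = conformers.
.coordMatrix <- function(e, atomIdx = NULL, modelIdx = NULL) {
  co <- e@coords
  if (!is.null(atomIdx)) co <- co[atomIdx, , , drop = FALSE]
  if (!is.null(modelIdx)) co <- co[, , modelIdx, drop = FALSE]
  d <- dim(co)
  out <- matrix(NA_real_, d[3], d[1] * 3)
  for (m in seq_len(d[3])) out[m, ] <- .flattenXYZ(co[, , m, drop = TRUE])
  out
}

# Rebuild an Ensemble from a model x 3N matrix plus a template ensemble.
.matrixToEnsemble <- function(X, template, atomIdx = NULL) {
  atoms <- template@atoms
  if (!is.null(atomIdx)) atoms <- atoms[atomIdx, , drop = FALSE]
  rownames(atoms) <- NULL
  co <- array(NA_real_, c(nrow(atoms), 3, nrow(X)))
  for (m in seq_len(nrow(X))) co[, , m] <- .unflattenXYZ(X[m, ])
  new("Ensemble", atoms = atoms, coords = co,
      stateLabel = template@stateLabel, replicaId = template@replicaId,
      source = template@source)
}

# Population (1/N) column covariance of a conformer x 3N matrix.
.popCov <- function(X) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  crossprod(Xc) / n
}
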