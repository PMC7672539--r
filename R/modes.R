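#' Principal component analysis of a combined ensemble
#'
#' Pools several ensembles (which must share the selection's atom layout),
#' superposes the pooled set onto its iteratively refined mean, and
#' diagonalizes the population covariance of the selected coordinates
#' (Calpha-only by default, unweighted). Projections are computed for every
#' conformer with its source ensemble label and replica id retained, so
#' downstream state partitioning can report per-ensemble and per-replica
#' occupancies.
#'
#' Eigenvector signs are fixed by a reference convention: each retained mode
#' is oriented so that the conformers of the reference ensembles (default:
#' any state labelled `cf`/`cd`, i.e. the ligand-bound states; otherwise
#' the first ensemble) have non-positive mean projection. With the default
#' state semantics this places "open" and "narrow" on the positive side of
#' modes 1 and 2.
#'
#' @param ensembles a single [Ensemble-class] or a list of them.
#' @param selection an [atomSelection()]; default Calpha atoms.
#' @param referenceStates state labels used for the sign convention.
#' @param retainTol smallest eigenvalue (Angstrom^2) retained as a mode.
#' @return A [ModeSpace-class].
#' @export
combinedPCA <- function(ensembles, selection = atomSelection(atomNames = "CA"),
                        referenceStates = NULL, retainTol = 1e-9) {
  if (is(ensembles, "Ensemble")) ensembles <- list(ensembles)
  stopifnot(length(ensembles) >= 1)
  sub <- lapply(ensembles, selectAtoms, sel = selection)

  ref <- sub[[1]]@atoms
  for (i in seq_along(sub)[-1]) {
    a <- sub[[i]]@atoms
    if (nrow(a) != nrow(ref) ||
        any(a$name != ref$name) || any(a$resno != ref$resno)) {
      bad <- if (nrow(a) != nrow(ref)) 1 else
        which(a$name != ref$name | a$resno != ref$resno)[1]
      stop(sprintf(
        "atom layout mismatch between ensembles 1 and %d (first at atom %d: %s%d vs %s%d)",
        i, bad, ref$name[min(bad, nrow(ref))], ref$resno[min(bad, nrow(ref))],
        a$name[min(bad, nrow(a))], a$resno[min(bad, nrow(a))]))
    }
  }

  labels <- vapply(sub, stateLabel, "")
  nms <- vapply(sub, nModels, 0L)
  if (sum(nms) < 2) stop("need at least 2 conformers in total")
  pooledCoords <- array(NA_real_, c(nrow(ref), 3, sum(nms)))
  off <- 0L
  repl <- integer(0)
  for (i in seq_along(sub)) {
    pooledCoords[, , off + seq_len(nms[i])] <- sub[[i]]@coords
    repl <- c(repl, if (length(sub[[i]]@replicaId)) sub[[i]]@replicaId
              else rep(NA_integer_, nms[i]))
    off <- off + nms[i]
  }
  pooled <- new("Ensemble", atoms = ref, coords = pooledCoords,
                stateLabel = "combined", replicaId = integer(0),
                source = "combinedPCA pool")
  pooled <- fitEnsemble(pooled)

  X <- .coordMatrix(pooled)
  mu <- colMeans(X)
  S <- .popCov(X)
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  keep <- which(eg$values > retainTol)
  values <- eg$values[keep]
  vectors <- eg$vectors[, keep, drop = FALSE]

  Xc <- sweep(X, 2, mu)
  proj <- Xc %*% vectors

  info <- data.frame(
    ensemble = rep(labels, nms),
    replica = repl,
    model = unlist(lapply(nms, seq_len)),
    stringsAsFactors = FALSE
  )

  refStates <- referenceStates %||% {
    cand <- intersect(c("cf", "cd"), labels)
    if (length(cand)) cand else labels[1]
  }
  refRows <- info$ensemble %in% refStates
  if (any(refRows)) {
    flip <- colMeans(proj[refRows, , drop = FALSE]) > 0
    if (any(flip)) {
      vectors[, flip] <- -vectors[, flip]
      proj[, flip] <- -proj[, flip]
    }
  }

  new("ModeSpace", mean = mu, vectors = vectors, values = values,
      totalVariance = sum(eg$values), projections = proj, info = info,
      atoms = ref)
}

#' Variance coverage of leading modes
#'
#' Reports both the share of mode 1 within the first `k` modes
#' (\eqn{\lambda_1 / \sum_{i \le k} \lambda_i}) and the cumulative fraction
#' of total variance captured by the first `k` modes.
#'
#' @param m a [ModeSpace-class].
#' @param k number of leading modes (default 10).
#' @return list with `leadingShare` and `cumulativeFraction`.
#' @export
varianceCoverage <- function(m, k = 10) {
  stopifnot(is(m, "ModeSpace"))
  if (k < 1) stop("k must be at least 1")
  k <- min(k, length(m@values))
  lead <- m@values[1] / sum(m@values[seq_len(k)])
  cum <- sum(m@values[seq_len(k)]) / m@totalVariance
  list(leadingShare = lead, cumulativeFraction = cum)
}

#' Partition conformers into binary states along the first two modes
#'
#' Each conformer is labelled by the sign of its projection relative to a
#' per-mode threshold (default 0 Angstrom): mode 1 separates open (positive)
#' from closed, mode 2 narrow (positive) from wide. Projections exactly at
#' the threshold are assigned to the negative side (deterministic
#' tie-break). Occupancies are reported per ensemble and, where replica ids
#' exist, per replica, so that state visiting of individual trajectories can
#' be inspected.
#'
#' Co-occurrence is reported as the symmetric two-way matching coefficient
#' \deqn{\max[P(o \wedge n) + P(c \wedge w),\; P(o \wedge w) + P(c \wedge n)]}
#' which is 1 when the two binary states are perfectly coupled and close to
#' 1/2 for independent balanced states. This is one documented reading of
#' "how jointly the two states are populated"; the empirical joint 2x2
#' table is always returned alongside so any alternative can be applied.
#'
#' @param m a [ModeSpace-class] with at least two modes.
#' @param thresholds numeric length-2, Angstrom.
#' @param labels1,labels2 `c(positive, negative)` state names for modes 1
#'   and 2.
#' @return A list of class `StatePartition`: `conformers` (data.frame with
#'   per-conformer labels), `occupancy` (per ensemble: fraction positive per
#'   mode), `replicaOccupancy` (or `NULL`), `joint` (list of 2x2 tables per
#'   ensemble), `coOccurrence` (named numeric), `thresholds`.
#' @export
partitionStates <- function(m, thresholds = c(0, 0),
                            labels1 = c("open", "closed"),
                            labels2 = c("narrow", "wide")) {
  stopifnot(is(m, "ModeSpace"))
  if (ncol(m@projections) < 2) stop("need at least two modes to partition")
  p1 <- m@projections[, 1]
  p2 <- m@projections[, 2]
  pos1 <- p1 > thresholds[1]          # ties go to the negative side
  pos2 <- p2 > thresholds[2]
  conf <- cbind(m@info, data.frame(
    proj1 = p1, proj2 = p2,
    state1 = ifelse(pos1, labels1[1], labels1[2]),
    state2 = ifelse(pos2, labels2[1], labels2[2]),
    stringsAsFactors = FALSE))

  ens <- unique(m@info$ensemble)
  occ <- data.frame(ensemble = ens,
                    mode1Positive = NA_real_, mode2Positive = NA_real_)
  joint <- list()
  co <- setNames(numeric(length(ens)), ens)
  for (i in seq_along(ens)) {
    r <- m@info$ensemble == ens[i]
    occ$mode1Positive[i] <- mean(pos1[r])
    occ$mode2Positive[i] <- mean(pos2[r])
    tab <- matrix(c(mean(pos1[r] & pos2[r]), mean(pos1[r] & !pos2[r]),
                    mean(!pos1[r] & pos2[r]), mean(!pos1[r] & !pos2[r])),
                  2, 2, byrow = TRUE,
                  dimnames = list(labels1, labels2))
    joint[[ens[i]]] <- tab
    co[i] <- max(tab[1, 1] + tab[2, 2], tab[1, 2] + tab[2, 1])
  }
  names(occ)[2:3] <- c(paste0("frac_", labels1[1]), paste0("frac_", labels2[1]))

  replOcc <- NULL
  if (!all(is.na(m@info$replica))) {
    key <- interaction(m@info$ensemble, m@info$replica, drop = TRUE)
    replOcc <- do.call(rbind, lapply(levels(key), function(k) {
      r <- key == k
      data.frame(ensemble = m@info$ensemble[r][1],
                 replica = m@info$replica[r][1],
                 n = sum(r),
                 frac1 = mean(pos1[r]), frac2 = mean(pos2[r]),
                 stringsAsFactors = FALSE)
    }))
    names(replOcc)[4:5] <- c(paste0("frac_", labels1[1]),
                             paste0("frac_", labels2[1]))
  }

  structure(list(conformers = conf, occupancy = occ,
                 replicaOccupancy = replOcc, joint = joint,
                 coOccurrence = co, thresholds = thresholds,
                 labels = list(mode1 = labels1, mode2 = labels2)),
            class = "StatePartition")
}

#' @export
print.StatePartition <- function(x, ...) {
  cat("StatePartition (thresholds",
      paste(x$thresholds, collapse = ", "), "A)\n")
  print(cbind(x$occupancy, coOccurrence = unname(x$coOccurrence[
    x$occupancy$ensemble])), row.names = FALSE)
  invisible(x)
}

#' Project external conformers into an existing mode space
#'
#' Each conformer is superposed onto the mode-space mean structure (Kabsch
#' fit on the analysed atoms) and projected onto the existing eigenvectors.
#' The structures must already present the same atoms as the mode space's
#' selection (use the core-mapping tools to renumber/reduce foreign
#' domains first).
#'
#' @param m a [ModeSpace-class].
#' @param e an [Ensemble-class] with the same atom count as `m`'s selection.
#' @param k number of leading modes to report.
#' @return data.frame: `model`, `PC1..PCk`.
#' @export
projectExternal <- function(m, e, k = min(10, length(m@values))) {
  stopifnot(is(m, "ModeSpace"), is(e, "Ensemble"))
  if (nAtoms(e) != nrow(m@atoms))
    stop("atom count mismatch (", nAtoms(e), " vs ", nrow(m@atoms),
         "); map the structures onto the mode space's core first")
  meanXYZ <- .unflattenXYZ(m@mean)
  k <- min(k, ncol(m@vectors))
  out <- matrix(NA_real_, nModels(e), k)
  for (i in seq_len(nModels(e))) {
    co <- e@coords[, , i, drop = TRUE]
    f <- kabschFit(co, meanXYZ)
    out[i, ] <- (.flattenXYZ(applyFit(co, f)) - m@mean) %*%
      m@vectors[, seq_len(k), drop = FALSE]
  }
  df <- as.data.frame(out)
  names(df) <- paste0("PC", seq_len(k))
  cbind(data.frame(model = seq_len(nModels(e))), df)
}

#' Overlap between two mode spaces
#'
#' Computes the absolute inner products \eqn{O_{ij} = |u_i \cdot v_j|}
#' between the leading `k` eigenvectors of two mode spaces and the
#' root-mean-square inner product
#' \deqn{\mathrm{RMSIP}(k) = \sqrt{\frac{1}{k}\sum_{i,j\le k}(u_i\cdot v_j)^2}.}
#'
#' @param a,b [ModeSpace-class] objects of identical coordinate dimension.
#' @param k number of leading modes compared.
#' @return A list of class `OverlapReport`: `overlap` (k x k matrix),
#'   `cumulative` (per mode of `a`, its summed squared overlap onto `b`'s
#'   first k), `rmsip`.
#' @export
modeOverlap <- function(a, b, k = 10) {
  stopifnot(is(a, "ModeSpace"), is(b, "ModeSpace"))
  if (nrow(a@vectors) != nrow(b@vectors))
    stop("mode spaces have different coordinate dimensionality")
  k <- min(k, ncol(a@vectors), ncol(b@vectors))
  U <- a@vectors[, seq_len(k), drop = FALSE]
  V <- b@vectors[, seq_len(k), drop = FALSE]
  M <- crossprod(U, V)
  structure(list(overlap = abs(M),
                 cumulative = rowSums(M^2),
                 rmsip = sqrt(sum(M^2) / k), k = k),
            class = "OverlapReport")
}

#' @export
print.OverlapReport <- function(x, ...) {
  cat("OverlapReport: RMSIP(", x$k, ") = ", sprintf("%.4f", x$rmsip),
      "\n", sep = "")
  invisible(x)
}
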