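#' Kabsch least-squares superposition of two coordinate sets
#'
#' Finds the proper rotation and translation minimizing the (optionally
#' weighted) RMSD between `mobile` and `reference`. Reflections are
#' corrected, so the returned rotation always has determinant +1.
#'
#' @param mobile,reference `n x 3` coordinate matrices (Angstrom), equal `n`
#'   of at least 3 non-collinear points.
#' @param weights optional per-point weights (e.g. masses); uniform when
#'   `NULL`.
#' @return A list of class `FitResult` with elements `rotation` (3 x 3,
#'   `det = +1`), `translation` (length-3, Angstrom) and `rmsd` (Angstrom).
#'   The fitted coordinates are `mobile %*% rotation + translation` (row
#'   vectors).
#' @export
kabschFit <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n != nrow(reference)) stop("point counts differ")
  if (n < 3) stop("need at least 3 points to define a superposition")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) <= 0) stop("invalid weights")
  w <- w / sum(w)

  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  Xm <- sweep(mobile, 2, cm)
  Xr <- sweep(reference, 2, cr)

  sv <- svd(Xm * sqrt(w))
  if (sv$d[2] <= 1e-8 * max(sv$d[1], 1e-12))
    stop("degenerate (collinear) configuration; rotation is not defined")

  C <- crossprod(Xm * w, Xr)            # 3x3 weighted cross-covariance
  s <- svd(C)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)

  fitted <- Xm %*% R
  rmsd <- sqrt(sum(w * rowSums((fitted - Xr)^2)))
  tr <- as.numeric(cr - cm %*% R)
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "FitResult")
}

#' @export
print.FitResult <- function(x, ...) {
  cat("FitResult: rmsd", format(x$rmsd), "A; translation",
      paste(sprintf("%.3f", x$translation), collapse = " "), "\n")
  invisible(x)
}

# Apply a FitResult to an n x 3 coordinate matrix.
applyFit <- function(coords, fit) {
  sweep(as.matrix(coords) %*% fit$rotation, 2, fit$translation, "+")
}

#' Iteratively superpose all models of an ensemble onto their mean
#'
#' Removes rigid-body motion by fitting every model to the current mean
#' structure of the fit selection, recomputing the mean, and repeating until
#' the mean moves by less than `tol` (RMS) or `maxIter` iterations. The
#' transformation determined on the fit group is applied to *all* atoms.
#' This fit-to-iterative-mean convention makes the result independent of
#' model order, as required for covariance analysis.
#'
#' @param e an [Ensemble-class].
#' @param fitSelection an [atomSelection()] defining the fit group (default:
#'   all atoms).
#' @param massWeighted use atomic masses as fit weights.
#' @param tol convergence tolerance on the mean structure, Angstrom RMS.
#' @param maxIter maximum number of mean-refinement iterations.
#' @return The superposed [Ensemble-class]; the mean residual RMSD and
#'   iteration count are attached as attributes `"rmsd"` and `"iterations"`.
#' @export
fitEnsemble <- function(e, fitSelection = NULL, massWeighted = FALSE,
                        tol = 1e-6, maxIter = 100) {
  stopifnot(is(e, "Ensemble"))
  sel <- fitSelection %||% atomSelection()
  idx <- which(.matchSelection(e@atoms, sel))
  if (!length(idx)) stop("fit selection matches no atoms")
  if (length(idx) < 3) stop("fit selection needs at least 3 atoms")
  nm <- nModels(e)
  w <- if (massWeighted) e@atoms$mass[idx] else NULL

  co <- e@coords
  if (nm == 1) {
    out <- e
    attr(out, "rmsd") <- 0; attr(out, "iterations") <- 0L
    return(out)
  }

  mean_fit <- apply(co[idx, , , drop = FALSE], c(1, 2), mean)
  converged <- FALSE
  rmsds <- numeric(nm)
  for (it in seq_len(maxIter)) {
    for (m in seq_len(nm)) {
      f <- kabschFit(co[idx, , m, drop = TRUE], mean_fit, weights = w)
      co[, , m] <- applyFit(co[, , m, drop = TRUE], f)
      rmsds[m] <- f$rmsd
    }
    newMean <- apply(co[idx, , , drop = FALSE], c(1, 2), mean)
    shift <- sqrt(mean((newMean - mean_fit)^2))
    mean_fit <- newMean
    if (shift < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("ensemble fit did not converge in ", maxIter,
            " iterations; returning best superposition")

  out <- new("Ensemble", atoms = e@atoms, coords = co,
             stateLabel = e@stateLabel, replicaId = e@replicaId,
             source = e@source)
  attr(out, "rmsd") <- mean(rmsds)
  attr(out, "iterations") <- it
  out
}
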