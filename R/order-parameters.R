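#' Bond-vector definitions for S2 back-calculation
#'
#' Builds the vector table used by [backCalculateS2()]. Backbone amide
#' vectors run N to H for every residue that has both atoms; methyl-axis
#' vectors run from the methyl carbon's heavy-atom neighbour to the methyl
#' carbon (the symmetry axis), by default CB to CG. Residues lacking the
#' atoms (e.g. no methyl) simply contribute no row.
#'
#' @param e an [Ensemble-class].
#' @param classes which vector classes to include.
#' @param methylFrom,methylTo atom names defining the methyl axis.
#' @return data.frame with columns `resno`, `class`, `atomFrom`, `atomTo`.
#' @export
s2Vectors <- function(e, classes = c("backbone_NH", "methyl_axis"),
                      methylFrom = "CB", methylTo = "CG") {
  classes <- match.arg(classes, several.ok = TRUE)
  a <- e@atoms
  out <- list()
  if ("backbone_NH" %in% classes) {
    res <- intersect(a$resno[a$name == "N"], a$resno[a$name == "H"])
    if (length(res))
      out$bb <- data.frame(resno = sort(res), class = "backbone_NH",
                           atomFrom = "N", atomTo = "H",
                           stringsAsFactors = FALSE)
  }
  if ("methyl_axis" %in% classes) {
    res <- intersect(a$resno[a$name == methylFrom],
                     a$resno[a$name == methylTo])
    if (length(res))
      out$me <- data.frame(resno = sort(res), class = "methyl_axis",
                           atomFrom = methylFrom, atomTo = methylTo,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE))) %||%
    data.frame(resno = integer(0), class = character(0),
               atomFrom = character(0), atomTo = character(0))
}

#' Back-calculate S2 order parameters from an ensemble
#'
#' For each bond vector, the generalized order parameter is computed from
#' the ensemble-averaged second moments of the unit internuclear vector
#' \eqn{\mu}:
#' \deqn{S^2 = \frac{3}{2}\left[\langle\mu_x^2\rangle^2 +
#'   \langle\mu_y^2\rangle^2 + \langle\mu_z^2\rangle^2 +
#'   2\langle\mu_x\mu_y\rangle^2 + 2\langle\mu_x\mu_z\rangle^2 +
#'   2\langle\mu_y\mu_z\rangle^2\right] - \frac{1}{2}}
#' The ensemble must already be superposed ([fitEnsemble()]): the measure is
#' then invariant to rigid-body transformations of the raw input models.
#'
#' @param e a fitted [Ensemble-class].
#' @param vectors a vector-definition table from [s2Vectors()] (the
#'   default), or any data.frame with columns `resno`, `class`, `atomFrom`,
#'   `atomTo`.
#' @return An order-parameter table: data.frame with columns `resno`,
#'   `class`, `s2` (dimensionless, in `[0, 1]`), unique on (resno, class).
#' @export
backCalculateS2 <- function(e, vectors = s2Vectors(e)) {
  stopifnot(is(e, "Ensemble"))
  if (!nrow(vectors)) stop("no vectors to evaluate")
  a <- e@atoms
  nm <- nModels(e)
  s2 <- numeric(nrow(vectors))
  for (i in seq_len(nrow(vectors))) {
    v <- vectors[i, ]
    iFrom <- which(a$resno == v$resno & a$name == v$atomFrom)
    iTo <- which(a$resno == v$resno & a$name == v$atomTo)
    if (length(iFrom) != 1 || length(iTo) != 1)
      stop("cannot resolve ", v$class, " vector ", v$atomFrom, "->", v$atomTo,
           " for residue ", v$resno)
    d <- e@coords[iTo, , , drop = TRUE] - e@coords[iFrom, , , drop = TRUE]
    if (nm == 1) d <- matrix(d, ncol = 1)
    len <- sqrt(colSums(d^2))
    if (any(len < 1e-8))
      stop("zero-length vector for residue ", v$resno, " in model ",
           which(len < 1e-8)[1])
    u <- sweep(d, 2, len, "/")
    s2[i] <- .s2FromUnitVectors(t(u))
  }
  data.frame(resno = vectors$resno, class = vectors$class, s2 = s2,
             stringsAsFactors = FALSE)
}

# Core second-moment formula; `u` is an n x 3 matrix of unit vectors.
.s2FromUnitVectors <- function(u) {
  mxx <- mean(u[, 1]^2); myy <- mean(u[, 2]^2); mzz <- mean(u[, 3]^2)
  mxy <- mean(u[, 1] * u[, 2]); mxz <- mean(u[, 1] * u[, 3])
  myz <- mean(u[, 2] * u[, 3])
  1.5 * (mxx^2 + myy^2 + mzz^2 + 2 * mxy^2 + 2 * mxz^2 + 2 * myz^2) - 0.5
}

#' Analytic S2 of the cone-rim wobble model
#'
#' For a bond vector uniformly distributed over the rim of a cone of
#' semi-angle `theta` about a fixed axis,
#' \eqn{S^2 = \frac{3}{2}(\sin^4\theta / 2 + \cos^4\theta) - \frac{1}{2}},
#' equivalently \eqn{P_2(\cos\theta)^2}. Used as the ground truth for the
#' synthetic generator's planted wobble.
#'
#' @param thetaDeg cone semi-angle in degrees.
#' @return S2 value(s) in `[0, 1]`.
#' @export
coneRimS2 <- function(thetaDeg) {
  th <- thetaDeg * pi / 180
  1.5 * (sin(th)^4 / 2 + cos(th)^4) - 0.5
}

#' Compare calculated and experimental order parameters
#'
#' Merges two order-parameter tables on (residue, class) and reports, per
#' vector class, the Pearson correlation, RMS deviation, number of shared
#' residues and per-residue residuals. Backbone and side-chain classes are
#' evaluated separately.
#'
#' @param calculated,experimental order-parameter tables (`resno`, `class`,
#'   `s2`).
#' @return A list with one entry per shared class, each containing `r`,
#'   `rmsd`, `n` and a `residuals` data.frame (`resno`, `calculated`,
#'   `experimental`, `residual`).
#' @export
correlateS2 <- function(calculated, experimental) {
  m <- merge(calculated, experimental, by = c("resno", "class"),
             suffixes = c(".calc", ".exp"))
  if (nrow(m) < 3) stop("fewer than 3 shared (residue, class) keys")
  out <- list()
  for (cl in unique(m$class)) {
    sub <- m[m$class == cl, ]
    if (nrow(sub) < 3) {
      warning("class '", cl, "' has fewer than 3 shared residues; skipped")
      next
    }
    resid <- sub$s2.calc - sub$s2.exp
    out[[cl]] <- list(
      r = cor(sub$s2.calc, sub$s2.exp),
      rmsd = sqrt(mean(resid^2)),
      n = nrow(sub),
      residuals = data.frame(resno = sub$resno, calculated = sub$s2.calc,
                             experimental = sub$s2.exp, residual = resid)
    )
  }
  if (!length(out)) stop("no vector class has 3 or more shared residues")
  out
}

#' Read / write order-parameter tables as TSV
#'
#' The on-disk format is tab-separated with a `#`-prefixed header line and
#' columns `resno`, `class`, `s2` (experimental tables for this kind of data
#' have no standard file format; this one is deliberately minimal).
#'
#' @param path file path.
#' @return `readS2Table`: the order-parameter data.frame.
#' @export
readS2Table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  df <- read.table(text = lines, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("resno", "class", "s2"))
  df$resno <- as.integer(df$resno)
  df
}

#' @rdname readS2Table
#' @param table an order-parameter data.frame.
#' @export
writeS2Table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#resno\tclass\ts2", con)
  write.table(table[, c("resno", "class", "s2")], con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
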