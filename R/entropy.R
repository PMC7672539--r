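#' Coordinate covariance of an ensemble selection
#'
#' Superposes the ensemble on the fit group ([fitEnsemble()]) and computes
#' the population (1/N) covariance of the analysis-group coordinates across
#' models. Coordinates are kept in Angstrom; the entropy estimators convert
#' to SI internally. With `massWeighted = TRUE` (the default, matching the
#' usual convention for configurational entropy) the superposition is
#' mass-weighted and atomic masses are stored for the estimators; otherwise
#' all masses are set to 1.
#'
#' @param e an [Ensemble-class] with at least 2 models.
#' @param fitSelection [atomSelection()] for the superposition (default:
#'   backbone N/CA/C atoms present in the ensemble, falling back to all
#'   atoms).
#' @param analysisSelection [atomSelection()] for the covariance (default:
#'   heavy atoms).
#' @param massWeighted logical.
#' @param fitted set `TRUE` if `e` is already superposed to skip the
#'   internal fit.
#' @return A [CovarianceModel-class].
#' @export
covarianceModel <- function(e, fitSelection = NULL, analysisSelection = NULL,
                            massWeighted = TRUE, fitted = FALSE) {
  stopifnot(is(e, "Ensemble"))
  if (nModels(e) < 2) stop("covariance needs at least 2 models")
  fitSel <- fitSelection %||% .defaultFitSelection(e)
  anaSel <- analysisSelection %||% atomSelection(heavyOnly = TRUE)
  if (!fitted) e <- fitEnsemble(e, fitSel, massWeighted = massWeighted)
  idx <- which(.matchSelection(e@atoms, anaSel))
  if (!length(idx)) stop("analysis selection matches no atoms")
  X <- .coordMatrix(e, atomIdx = idx)
  sigma <- .popCov(X)
  sigma <- (sigma + t(sigma)) / 2
  masses <- if (massWeighted) e@atoms$mass[idx] else rep(1, length(idx))
  new("CovarianceModel", mean = colMeans(X), sigma = sigma,
      masses = masses, nModels = nModels(e),
      selection = sprintf("%d atoms (%s)", length(idx),
                          if (anaSel@heavyOnly) "heavy" else "custom"))
}

.defaultFitSelection <- function(e) {
  bb <- intersect(c("N", "CA", "C"), unique(e@atoms$name))
  if (length(bb) >= 2) atomSelection(atomNames = bb) else atomSelection()
}

# Eigenvalues of the mass-weighted covariance M^{1/2} sigma M^{1/2},
# in amu * Angstrom^2. `floor` values below it (and non-positive values)
# are dropped; negative eigenvalues beyond -psdTol * max are an error.
.massWeightedEigen <- function(cm, floor = 1e-12, psdTol = 1e-8) {
  sm <- sqrt(rep(cm@masses, each = 3))
  B <- cm@sigma * outer(sm, sm)
  ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  top <- max(abs(ev), 1e-300)
  if (min(ev) < -psdTol * top)
    stop("covariance is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")")
  ev[ev > floor]
}

#' Schlitter upper-bound conformational entropy
#'
#' Evaluates the determinant formula
#' \deqn{S = \frac{k_B}{2}\,\ln\det\!\left[\mathbf{1} +
#'   \frac{k_B T e^2}{\hbar^2}\,M^{1/2}\sigma M^{1/2}\right]}
#' via the eigenvalues of the mass-weighted covariance (log-sum form, which
#' is numerically stable for large matrices). Eigenvalues below
#' `eigenvalueFloor` (amu Angstrom^2) are skipped; rank-deficient sample
#' covariances are therefore handled gracefully.
#'
#' @param cm a [CovarianceModel-class].
#' @param temperature temperature in K (default 300).
#' @param perMole report J/mol/K (multiplied by Avogadro's number, default)
#'   rather than J/K.
#' @param eigenvalueFloor smallest mass-weighted eigenvalue retained,
#'   amu Angstrom^2.
#' @return Entropy in J/mol/K (or J/K), a non-negative scalar.
#' @references Schlitter's determinant formula for configurational entropy
#'   from a mass-weighted coordinate covariance.
#' @export
schlitterEntropy <- function(cm, temperature = 300, perMole = TRUE,
                             eigenvalueFloor = 1e-12) {
  stopifnot(is(cm, "CovarianceModel"), temperature > 0)
  ev <- .massWeightedEigen(cm, floor = eigenvalueFloor)
  if (!length(ev)) return(0)
  k <- .const
  scale <- k$kB * temperature * exp(2) * k$amu * k$A2_m2 / k$hbar^2
  s <- 0.5 * sum(log1p(scale * ev))            # in units of kB
  if (perMole) s * k$R else s * k$kB
}

#' Quasi-harmonic conformational entropy
#'
#' Treats each eigenmode of the mass-weighted coordinate covariance as a
#' quantum harmonic oscillator of frequency
#' \eqn{\omega_i = \sqrt{k_B T / \lambda_i}} and sums the oscillator
#' entropies
#' \deqn{S = R \sum_i \left[\frac{\alpha_i}{e^{\alpha_i} - 1} -
#'   \ln(1 - e^{-\alpha_i})\right], \quad \alpha_i = \hbar\omega_i / k_B T.}
#' Modes with eigenvalue below `eigenvalueFloor` are skipped. The Schlitter
#' value is an upper bound for this estimator, mode by mode.
#'
#' @inheritParams schlitterEntropy
#' @return Entropy in J/mol/K (or J/K), a non-negative scalar.
#' @export
quasiharmonicEntropy <- function(cm, temperature = 300, perMole = TRUE,
                                 eigenvalueFloor = 1e-12) {
  stopifnot(is(cm, "CovarianceModel"), temperature > 0)
  ev <- .massWeightedEigen(cm, floor = eigenvalueFloor)
  if (!length(ev)) return(0)
  k <- .const
  lambdaSI <- ev * k$amu * k$A2_m2
  alpha <- k$hbar / sqrt(k$kB * temperature * lambdaSI)
  term <- alpha / expm1(alpha) - log1p(-exp(-alpha))
  s <- sum(term)
  if (perMole) s * k$R else s * k$kB
}

#' Binding-entropy ratio across four functional states
#'
#' Computes conformational entropies for the four states of a
#' free/complex x full/truncated study and the ratio
#' \deqn{(S_{cd} - S_{fd}) / (S_{cf} - S_{ff})}
#' which compares the entropy loss upon ligand binding in the truncated
#' versus the full-length domain. Convergence is traced over growing
#' model-count prefixes (models in stored order, which for concatenated
#' replica trajectories is provenance-defined).
#'
#' The atom selection must be common to all four states (any ligand or
#' C-terminal extension has to be excluded by the caller's selection).
#'
#' @param ensembles named list with elements `ff`, `fd`, `cf`, `cd`
#'   (free-full, free-truncated, complex-full, complex-truncated).
#' @param fitSelection,analysisSelection selections passed to
#'   [covarianceModel()].
#' @param temperature temperature in K.
#' @param estimator `"schlitter"` (default, the usual reporting choice) or
#'   `"quasiharmonic"`.
#' @param schedule fractions of each ensemble used for the convergence
#'   trace; the last entry must be 1.
#' @param denominatorTol smallest acceptable `|S_cf - S_ff|` (J/mol/K)
#'   before the ratio is declared degenerate.
#' @param massWeighted logical, passed to [covarianceModel()].
#' @return A list of class `BindingEntropyRatio`: per-state entropies
#'   (`s_ff`, `s_fd`, `s_cf`, `s_cd`, J/mol/K), `ratio`, `temperature`,
#'   `estimator` and a `convergence` data.frame (`fraction`, `nModels`,
#'   `ratio`).
#' @export
bindingEntropyRatio <- function(ensembles, fitSelection = NULL,
                                analysisSelection = NULL, temperature = 300,
                                estimator = c("schlitter", "quasiharmonic"),
                                schedule = seq(0.1, 1, by = 0.1),
                                denominatorTol = 1e-6, massWeighted = TRUE) {
  estimator <- match.arg(estimator)
  need <- c("ff", "fd", "cf", "cd")
  if (!all(need %in% names(ensembles)))
    stop("ensembles must be a named list with states: ",
         paste(setdiff(need, names(ensembles)), collapse = ", "), " missing")
  if (abs(schedule[length(schedule)] - 1) > 1e-12)
    stop("the last schedule entry must be 1 (full ensembles)")
  efun <- if (estimator == "schlitter") schlitterEntropy else
    quasiharmonicEntropy

  # fit once per state; prefixes reuse the superposed coordinates
  fitted <- lapply(ensembles[need], function(e)
    fitEnsemble(e, fitSelection %||% .defaultFitSelection(e),
                massWeighted = massWeighted))

  # each prefix is re-fitted to its own mean; starting from the pre-fitted
  # coordinates this converges in a step or two
  entropyAt <- function(frac) {
    vapply(fitted, function(e) {
      n <- max(2, floor(nModels(e) * frac))
      sub <- new("Ensemble", atoms = e@atoms,
                 coords = e@coords[, , seq_len(n), drop = FALSE],
                 stateLabel = e@stateLabel, replicaId = integer(0),
                 source = e@source)
      cm <- covarianceModel(sub, fitSelection = fitSelection,
                            analysisSelection = analysisSelection,
                            massWeighted = massWeighted)
      efun(cm, temperature = temperature)
    }, 0)
  }

  conv <- data.frame(fraction = schedule,
                     nModels = NA_integer_, ratio = NA_real_)
  sFull <- NULL
  for (i in seq_along(schedule)) {
    s <- entropyAt(schedule[i])
    conv$nModels[i] <- max(2, floor(nModels(fitted$ff) * schedule[i]))
    den <- s["cf"] - s["ff"]
    conv$ratio[i] <- if (abs(den) < denominatorTol) NA_real_ else
      (s["cd"] - s["fd"]) / den
    if (i == length(schedule)) sFull <- s
  }
  den <- sFull["cf"] - sFull["ff"]
  if (abs(den) < denominatorTol)
    stop("denominator degenerate: |S_cf - S_ff| = ", format(abs(den)),
         " J/mol/K")
  structure(list(
    s_ff = unname(sFull["ff"]), s_fd = unname(sFull["fd"]),
    s_cf = unname(sFull["cf"]), s_cd = unname(sFull["cd"]),
    ratio = unname((sFull["cd"] - sFull["fd"]) / den),
    temperature = temperature, estimator = estimator,
    convergence = conv
  ), class = "BindingEntropyRatio")
}

#' @export
print.BindingEntropyRatio <- function(x, ...) {
  cat("BindingEntropyRatio (", x$estimator, ", ", x$temperature, " K)\n",
      sep = "")
  cat(sprintf("  S_ff=%.1f S_fd=%.1f S_cf=%.1f S_cd=%.1f J/mol/K\n",
              x$s_ff, x$s_fd, x$s_cf, x$s_cd))
  cat(sprintf("  (S_cd - S_fd)/(S_cf - S_ff) = %.3f\n", x$ratio))
  invisible(x)
}
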