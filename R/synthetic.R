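#' Specification of a synthetic four-state ensemble study
#'
#' Defines the study conditions for [generateStudy()]: a four-state
#' (free/complex x full/truncated) design with two planted collective modes
#' carrying per-state mixture occupancies, per-residue bond-vector wobble
#' with analytic S2, per-state covariance scalings giving a designed
#' binding-entropy ratio, and a planted side-chain contact difference.
#'
#' The defaults are the package's reference study: 4 x 808 conformers in 8
#' replicas on a 64-residue scaffold; mode-1 ("open/closed") open weights
#' 0.95/0.50/0.10/0.10 for ff/fd/cf/cd with component means +-2 Angstrom
#' (sd 0.5, i.e. 8 sd separation); mode-2 ("narrow/wide") narrow weights
#' 0.70 for full-length and 0.30 for truncated states with means
#' +-1.5 Angstrom; isotropic coordinate noise sd 0.3 Angstrom; covariance
#' scales 1 / 1.4 / 0.85 for ff / fd / cf and the cd scale solved so the
#' analytic Schlitter entropies satisfy
#' `(S_cd - S_fd)/(S_cf - S_ff) = entropyRatioTarget` (default 4).
#'
#' @param nResidues scaffold length.
#' @param nModels conformers per state.
#' @param nReplicas replica blocks per state (must divide `nModels` or the
#'   last block is shorter).
#' @param firstResidue first residue number.
#' @param states named list (`ff`, `fd`, `cf`, `cd`) of per-state designs;
#'   each a list with `mode1`/`mode2` mixtures (`weights`, `means`, `sds`)
#'   and `scale` (`NA` = solve from `entropyRatioTarget`).
#' @param noiseSd isotropic per-coordinate noise sd, Angstrom.
#' @param backboneTheta per-residue backbone N-H cone semi-angle, degrees
#'   (scalar or length `nResidues`).
#' @param methylTheta methyl-axis cone semi-angle, degrees (scalar or one
#'   per methyl residue).
#' @param contactPerturbation list(`resI`, `resJ`, `displacement`,
#'   `states`) or `NULL`; `resI`/`resJ = NA` picks the closest side-chain
#'   pair at sequence separation >= 6.
#' @param expNoiseSd sd of the noise added to the analytic S2 values to
#'   emulate an experimental order-parameter table.
#' @param entropyRatioTarget designed binding-entropy ratio.
#' @param temperature temperature (K) at which the designed entropies are
#'   evaluated.
#' @param seed integer seed; a fixed seed makes [generateStudy()] output
#'   byte-identical.
#' @return A list of class `SyntheticSpec`.
#' @export
syntheticSpec <- function(nResidues = 64, nModels = 808, nReplicas = 8,
                          firstResidue = 301, states = NULL, noiseSd = 0.3,
                          backboneTheta = NULL, methylTheta = NULL,
                          contactPerturbation = list(resI = NA, resJ = NA,
                                                     displacement = 2.5,
                                                     states = c("cf", "cd")),
                          expNoiseSd = 0.02, entropyRatioTarget = 4,
                          temperature = 300, seed = 1) {
  mix <- function(w, mu, sd) list(weights = w, means = mu, sds = sd)
  defaults <- list(
    ff = list(mode1 = mix(c(0.95, 0.05), c(2, -2), c(0.5, 0.5)),
              mode2 = mix(c(0.70, 0.30), c(1.5, -1.5), c(0.5, 0.5)),
              scale = 1.0),
    fd = list(mode1 = mix(c(0.50, 0.50), c(2, -2), c(0.5, 0.5)),
              mode2 = mix(c(0.30, 0.70), c(1.5, -1.5), c(0.5, 0.5)),
              scale = 1.4),
    cf = list(mode1 = mix(c(0.10, 0.90), c(2, -2), c(0.5, 0.5)),
              mode2 = mix(c(0.70, 0.30), c(1.5, -1.5), c(0.5, 0.5)),
              scale = 0.85),
    cd = list(mode1 = mix(c(0.10, 0.90), c(2, -2), c(0.5, 0.5)),
              mode2 = mix(c(0.30, 0.70), c(1.5, -1.5), c(0.5, 0.5)),
              scale = NA)
  )
  if (!is.null(states)) defaults <- modifyList(defaults, states)
  for (st in defaults) for (md in st[c("mode1", "mode2")]) {
    if (any(md$weights < 0) || abs(sum(md$weights) - 1) > 1e-9)
      stop("mixture weights must be in [0,1] and sum to 1")
    if (any(md$sds <= 0)) stop("mixture sds must be > 0")
  }
  spec <- list(nResidues = nResidues, nModels = nModels,
               nReplicas = nReplicas, firstResidue = firstResidue,
               states = defaults, noiseSd = noiseSd,
               backboneTheta = backboneTheta, methylTheta = methylTheta,
               contactPerturbation = contactPerturbation,
               expNoiseSd = expNoiseSd,
               entropyRatioTarget = entropyRatioTarget,
               temperature = temperature, seed = as.integer(seed))
  class(spec) <- "SyntheticSpec"
  spec
}

# ---------------------------------------------------------------------------
# Scaffold: a deterministic, compact serpentine fold. Per residue: N, H, CA,
# CB; every 3rd residue also carries a methyl-like CG (axis CB->CG).
.buildScaffold <- function(spec) {
  n <- spec$nResidues
  i <- seq_len(n)
  row <- (i - 1) %/% 8
  col <- (i - 1) %% 8
  col <- ifelse(row %% 2 == 1, 7 - col, col)
  layer <- row %/% 8
  row <- row %% 8
  ca <- cbind(3.8 * col, 5.0 * row + 1.1 * sin(i * 1.7),
              5.5 * layer + 1.2 * sin(i * 2.1))

  unitize <- function(v) v / sqrt(sum(v^2))
  nhDir <- t(vapply(i, function(k)
    unitize(c(sin(0.7 * k), cos(0.7 * k), 0.4)), numeric(3)))
  meDir <- t(vapply(i, function(k)
    unitize(c(cos(0.5 * k), sin(0.5 * k), 0.8 * (-1)^k)), numeric(3)))

  nPos <- ca + matrix(rep(c(-0.8, 1.0, 0.6), each = n), ncol = 3)
  cbDir <- cbind(0.25, 0.2, ifelse(row %% 2 == 0, 1, -1))
  cbDir <- cbDir / sqrt(rowSums(cbDir^2))
  cbPos <- ca + 1.53 * cbDir

  methyl <- (i %% 3) == 0
  thB <- spec$backboneTheta %||% {
    th <- 10 + 15 * sin(pi * (i - 1) / (n - 1))^2
    th[round(n / 4)] <- 55          # two mobile "loop" sites
    th[round(3 * n / 4)] <- 58
    th
  }
  if (length(thB) == 1) thB <- rep(thB, n)
  thM0 <- spec$methylTheta %||% (25 + 10 * cos(i[methyl])^2)
  thM <- numeric(n)
  thM[methyl] <- if (length(thM0) == 1) rep(thM0, sum(methyl)) else thM0

  resno <- spec$firstResidue + i - 1
  rows <- list()
  for (k in i) {
    at <- data.frame(
      name = c("N", "H", "CA", "CB", if (methyl[k]) "CG"),
      element = c("N", "H", "C", "C", if (methyl[k]) "C"),
      resno = resno[k],
      resname = if (methyl[k]) "VAL" else "ALA",
      chain = "A", stringsAsFactors = FALSE)
    rows[[k]] <- at
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  p <- .elementParams(atoms$element, atoms$name)
  atoms$mass <- p$mass
  atoms$vdw <- p$vdw

  mean0 <- matrix(NA_real_, nrow(atoms), 3)
  resOfAtom <- match(atoms$resno, resno)
  for (k in i) {
    rowsK <- which(resOfAtom == k)
    for (r in rowsK) {
      mean0[r, ] <- switch(atoms$name[r],
        N = nPos[k, ], H = nPos[k, ] + 1.02 * nhDir[k, ],
        CA = ca[k, ], CB = cbPos[k, ],
        CG = cbPos[k, ] + 1.53 * meDir[k, ])
    }
  }

  list(atoms = atoms, mean = mean0, resno = resno, resOfAtom = resOfAtom,
       methyl = methyl, nhDir = nhDir, meDir = meDir,
       thetaBackbone = thB, thetaMethyl = thM, caIdx = which(atoms$name == "CA"),
       nIdx = which(atoms$name == "N"), hIdx = which(atoms$name == "H"),
       cbIdx = which(atoms$name == "CB"),
       cgIdx = which(atoms$name == "CG"),
       baseIdx = which(atoms$name %in% c("N", "CA", "CB")))
}

# Planted collective modes: smooth per-residue displacement profiles,
# projected out of the rigid-body space of the Calpha scaffold (so that
# superposition cannot absorb them - they are genuinely internal motions)
# and orthonormalized on the Calpha coordinates.
.buildModes <- function(scaffold) {
  n <- length(scaffold$resno)
  i <- seq_len(n)
  ca <- scaffold$mean[scaffold$caIdx, , drop = FALSE]
  cen <- sweep(ca, 2, colMeans(ca))
  rigid <- matrix(0, 3 * n, 6)
  for (k in 1:3) rigid[seq(k, 3 * n, by = 3), k] <- 1      # translations
  for (r in seq_len(n)) {                                   # rotations
    p <- cen[r, ]
    rigid[(r - 1) * 3 + 1:3, 4] <- c(0, -p[3], p[2])
    rigid[(r - 1) * 3 + 1:3, 5] <- c(p[3], 0, -p[1])
    rigid[(r - 1) * 3 + 1:3, 6] <- c(-p[2], p[1], 0)
  }
  Q <- qr.Q(qr(rigid))

  shape <- function(v) {                # nres x 3 profile -> internal mode
    x <- as.vector(t(v))
    x <- x - Q %*% crossprod(Q, x)
    matrix(x, ncol = 3, byrow = TRUE)
  }
  g1 <- shape(cbind(0.3 * cos(2 * pi * i / n), 0, sin(2 * pi * i / n)))
  g2 <- shape(cbind(0, 0.3 * sin(4 * pi * i / n), cos(4 * pi * i / n)))
  g1 <- g1 / sqrt(sum(g1^2))                      # unit on Calpha coords
  g2 <- g2 - sum(g1 * g2) * g1
  g2 <- g2 / sqrt(sum(g2^2))
  list(g1 = g1, g2 = g2)
}

.mixtureVar <- function(m) {
  mu <- sum(m$weights * m$means)
  sum(m$weights * (m$sds^2 + m$means^2)) - mu^2
}

.mixturePositiveProb <- function(m, extraVar = 0) {
  sum(m$weights * pnorm(m$means / sqrt(m$sds^2 + extraVar)))
}

# Orthonormal frame perpendicular to a unit axis.
.perpFrame <- function(d) {
  a <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- c(d[2] * a[3] - d[3] * a[2], d[3] * a[1] - d[1] * a[3],
          d[1] * a[2] - d[2] * a[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2], d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# Analytic coordinate covariance of one state over the heavy atoms
# (N, CA, CB, CG), in Angstrom^2: the planted modes plus isotropic noise
# (with CG riding on CB) plus the CG cone-rim wobble term.
.analyticHeavyCovariance <- function(scaffold, modes, state, noiseSd) {
  heavy <- which(scaffold$atoms$element != "H")
  res <- scaffold$resOfAtom[heavy]
  nh <- length(heavy)
  U1 <- matrix(t(modes$g1[res, , drop = FALSE]), ncol = 1)
  U2 <- matrix(t(modes$g2[res, , drop = FALSE]), ncol = 1)
  V1 <- .mixtureVar(state$mode1)
  V2 <- .mixtureVar(state$mode2)

  # noise lift: identity, except CG copies CB's noise
  LLt <- diag(3 * nh)
  names_h <- scaffold$atoms$name[heavy]
  for (k in which(names_h == "CG")) {
    cb <- which(names_h == "CB" & res == res[k])
    ib <- (cb - 1) * 3 + 1:3
    ig <- (k - 1) * 3 + 1:3
    LLt[ig, ib] <- diag(3)
    LLt[ib, ig] <- diag(3)
  }

  base <- V1 * tcrossprod(U1) + V2 * tcrossprod(U2) + noiseSd^2 * LLt

  W <- matrix(0, 3 * nh, 3 * nh)
  for (k in which(names_h == "CG")) {
    r <- res[k]
    d <- scaffold$meDir[r, ]
    th <- scaffold$thetaMethyl[r] * pi / 180
    ig <- (k - 1) * 3 + 1:3
    W[ig, ig] <- 1.53^2 * sin(th)^2 / 2 * (diag(3) - tcrossprod(d))
  }
  list(sigma = function(scale) scale^2 * base + W,
       masses = scaffold$atoms$mass[heavy], heavy = heavy)
}

.analyticSchlitter <- function(cov, scale, temperature) {
  cm <- new("CovarianceModel", mean = numeric(nrow(cov$sigma(1))),
            sigma = cov$sigma(scale), masses = cov$masses,
            nModels = 2L, selection = "analytic")
  schlitterEntropy(cm, temperature = temperature)
}

# Solve the cd covariance scale so the analytic Schlitter entropies hit the
# designed binding-entropy ratio.
.solveEntropyScales <- function(scaffold, modes, states, noiseSd, target,
                                temperature) {
  covs <- lapply(states, function(st)
    .analyticHeavyCovariance(scaffold, modes, st, noiseSd))
  s <- vapply(c("ff", "fd", "cf"), function(nm)
    .analyticSchlitter(covs[[nm]], states[[nm]]$scale, temperature), 0)
  sTarget <- s[["fd"]] + target * (s[["cf"]] - s[["ff"]])
  scale_cd <- states$cd$scale
  if (is.na(scale_cd)) {
    f <- function(x) .analyticSchlitter(covs$cd, x, temperature) - sTarget
    scale_cd <- stats::uniroot(f, c(0.02, max(2, states$fd$scale * 1.5)),
                               tol = 1e-6)$root
  }
  s_cd <- .analyticSchlitter(covs$cd, scale_cd, temperature)
  list(scale_cd = scale_cd,
       entropies = c(ff = unname(s[["ff"]]), fd = unname(s[["fd"]]),
                     cf = unname(s[["cf"]]), cd = s_cd),
       ratio = (s_cd - s[["fd"]]) / (s[["cf"]] - s[["ff"]]))
}

#' Generate a ground-truth-annotated synthetic four-state study
#'
#' Builds four labelled ensembles (`ff`, `fd`, `cf`, `cd`) of
#' `spec$nModels` conformers each on a shared scaffold: every conformer is
#' `mean + s(a1 u1 + a2 u2 + eps)` with `a1`, `a2` drawn from the state's
#' mode mixtures, `eps` isotropic Gaussian noise and `s` the state's
#' covariance scale; amide H and methyl CG atoms are then rebuilt on cone
#' rims of the per-residue semi-angles (so their S2 values are analytic);
#' the contact perturbation displaces the side-chain atoms (CB and its CG)
#' of one residue in the designated states; replica ids are assigned in
#' contiguous blocks.
#'
#' Everything needed to verify the pipeline is recorded in the returned
#' `manifest`: planted mode vectors, analytic per-state occupancies and
#' co-occurrences, analytic S2 per vector, analytic Schlitter entropies and
#' the implied binding-entropy ratio, the planted contact pair, pooled
#' variances of the two modes, and the seed.
#'
#' @param spec a [syntheticSpec()].
#' @return list with `ensembles` (named list of [Ensemble-class]),
#'   `observedS2` (an S2 table with `expNoiseSd` noise, standing in for an
#'   experimental table), and `manifest`.
#' @export
generateStudy <- function(spec = syntheticSpec()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  scaffold <- .buildScaffold(spec)
  modes <- .buildModes(scaffold)
  n <- spec$nModels
  nres <- spec$nResidues

  solved <- .solveEntropyScales(scaffold, modes, spec$states, spec$noiseSd,
                                spec$entropyRatioTarget, spec$temperature)
  states <- spec$states
  states$cd$scale <- solved$scale_cd

  pert <- spec$contactPerturbation
  if (!is.null(pert) && (is.na(pert$resI) || is.na(pert$resJ))) {
    cb <- scaffold$mean[scaffold$cbIdx, , drop = FALSE]
    best <- c(NA, NA, Inf)
    for (a in seq_len(nres)) for (b in seq_len(nres)) {
      if (b - a < 6) next
      d <- sqrt(sum((cb[a, ] - cb[b, ])^2))
      if (d < best[3]) best <- c(a, b, d)
    }
    pert$resI <- scaffold$resno[best[1]]
    pert$resJ <- scaffold$resno[best[2]]
  }

  ensembles <- withSeed(spec$seed, {
    out <- list()
    for (nm in names(states)) {
      st <- states[[nm]]
      comp1 <- sample.int(2, n, replace = TRUE, prob = st$mode1$weights)
      a1 <- rnorm(n, st$mode1$means[comp1], st$mode1$sds[comp1])
      comp2 <- sample.int(2, n, replace = TRUE, prob = st$mode2$weights)
      a2 <- rnorm(n, st$mode2$means[comp2], st$mode2$sds[comp2])
      nBase <- length(scaffold$baseIdx)
      eps <- array(rnorm(nBase * 3 * n, 0, spec$noiseSd), c(nBase, 3, n))
      phiNH <- matrix(runif(nres * n, 0, 2 * pi), nres, n)
      phiMe <- matrix(runif(nres * n, 0, 2 * pi), nres, n)

      co <- array(NA_real_, c(nrow(scaffold$atoms), 3, n))
      resBase <- scaffold$resOfAtom[scaffold$baseIdx]
      pertHere <- !is.null(pert) && nm %in% pert$states
      if (pertHere) {
        iRes <- match(pert$resI, scaffold$resno)
        jRes <- match(pert$resJ, scaffold$resno)
        dir <- scaffold$mean[scaffold$cbIdx[jRes], ] -
          scaffold$mean[scaffold$cbIdx[iRes], ]
        pertVec <- pert$displacement * dir / sqrt(sum(dir^2))
      }
      frames <- lapply(seq_len(nres), function(r)
        list(nh = .perpFrame(scaffold$nhDir[r, ]),
             me = .perpFrame(scaffold$meDir[r, ])))

      for (m in seq_len(n)) {
        disp <- a1[m] * modes$g1 + a2[m] * modes$g2    # nres x 3
        base <- scaffold$mean[scaffold$baseIdx, , drop = FALSE] +
          st$scale * (disp[resBase, , drop = FALSE] + eps[, , m])
        co[scaffold$baseIdx, , m] <- base
        if (pertHere) {
          cbRow <- which(scaffold$baseIdx == scaffold$cbIdx[iRes])
          co[scaffold$cbIdx[iRes], , m] <- base[cbRow, ] + pertVec
        }
        # amide H on the cone rim around the mean N-H axis
        for (r in seq_len(nres)) {
          th <- scaffold$thetaBackbone[r] * pi / 180
          fr <- frames[[r]]$nh
          u <- cos(th) * scaffold$nhDir[r, ] +
            sin(th) * (cos(phiNH[r, m]) * fr$e1 + sin(phiNH[r, m]) * fr$e2)
          co[scaffold$hIdx[r], , m] <- co[scaffold$nIdx[r], , m] + 1.02 * u
          if (scaffold$methyl[r]) {
            thm <- scaffold$thetaMethyl[r] * pi / 180
            frm <- frames[[r]]$me
            um <- cos(thm) * scaffold$meDir[r, ] +
              sin(thm) * (cos(phiMe[r, m]) * frm$e1 +
                            sin(phiMe[r, m]) * frm$e2)
            cg <- scaffold$cgIdx[which(which(scaffold$methyl) == r)]
            co[cg, , m] <- co[scaffold$cbIdx[r], , m] + 1.53 * um
          }
        }
      }
      repl <- rep(seq_len(spec$nReplicas),
                  each = ceiling(n / spec$nReplicas))[seq_len(n)]
      out[[nm]] <- new("Ensemble", atoms = scaffold$atoms, coords = co,
                       stateLabel = nm, replicaId = as.integer(repl),
                       source = sprintf("synthetic study seed %d", spec$seed))
    }
    out
  })

  # analytic S2 (cone-rim closed form)
  s2true <- rbind(
    data.frame(resno = scaffold$resno, class = "backbone_NH",
               s2 = coneRimS2(scaffold$thetaBackbone)),
    data.frame(resno = scaffold$resno[scaffold$methyl], class = "methyl_axis",
               s2 = coneRimS2(scaffold$thetaMethyl[scaffold$methyl]))
  )
  observedS2 <- withSeed(spec$seed + 104729L, {
    obs <- s2true
    obs$s2 <- pmin(1, pmax(0.01, obs$s2 + rnorm(nrow(obs), 0, spec$expNoiseSd)))
    obs
  })

  occ <- lapply(states, function(st) c(
    open = .mixturePositiveProb(st$mode1, extraVar = spec$noiseSd^2),
    narrow = .mixturePositiveProb(st$mode2, extraVar = spec$noiseSd^2)))
  coTrue <- vapply(occ, function(o)
    max(o["open"] * o["narrow"] + (1 - o["open"]) * (1 - o["narrow"]),
        o["open"] * (1 - o["narrow"]) + (1 - o["open"]) * o["narrow"]), 0)

  pooledModeVar <- vapply(c("mode1", "mode2"), function(md) {
    mu <- vapply(states, function(st)
      st$scale * sum(st[[md]]$weights * st[[md]]$means), 0)
    wv <- vapply(states, function(st)
      st$scale^2 * (.mixtureVar(st[[md]]) + spec$noiseSd^2), 0)
    mean(wv) + mean((mu - mean(mu))^2)
  }, 0)

  manifest <- list(
    seed = spec$seed,
    nModels = n, nResidues = nres, nReplicas = spec$nReplicas,
    modeVectorsCA = list(mode1 = modes$g1, mode2 = modes$g2),
    occupancy = occ,
    coOccurrence = coTrue,
    pooledModeVariance = pooledModeVar,
    s2 = s2true,
    entropies = solved$entropies,
    entropyRatio = solved$ratio,
    entropyRatioTarget = spec$entropyRatioTarget,
    scales = vapply(states, `[[`, 0, "scale"),
    contactPerturbation = pert,
    noiseSd = spec$noiseSd,
    temperature = spec$temperature
  )
  list(ensembles = ensembles, observedS2 = observedS2, manifest = manifest)
}

#' Write a synthetic study to disk
#'
#' Writes the four multi-model PDB files (with replica REMARKs), the
#' observed S2 TSV and a JSON manifest into a directory.
#'
#' @param study output of [generateStudy()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(study$ensembles))
    writeEnsemble(study$ensembles[[nm]], file.path(dir, paste0(nm, ".pdb")))
  writeS2Table(study$observedS2, file.path(dir, "s2_observed.tsv"))
  man <- study$manifest
  man$modeVectorsCA <- lapply(man$modeVectorsCA, function(m) unclass(m))
  man$s2 <- as.list(man$s2)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Generate alignment fixtures with known core columns
#'
#' Builds an [AlignmentBlock-class] from caller-designed aligned strings
#' (the gap layout *is* the ground truth for core extraction) together with
#' matching toy Calpha ensembles whose residue numbering follows the
#' block's default 1..n track, so core mapping and pooled PCA can be
#' exercised end to end.
#'
#' @param sequences named character vector of aligned strings.
#' @param nModels models per toy ensemble.
#' @param jitter coordinate jitter (Angstrom) distinguishing the models.
#' @param seed seed for the jitter.
#' @return list with `block` and `ensembles` (named list of
#'   [Ensemble-class]).
#' @export
generateAlignmentFixture <- function(sequences, nModels = 2, jitter = 0.1,
                                     seed = 1) {
  block <- alignmentBlock(sequences)
  ensembles <- withSeed(seed, {
    lapply(names(sequences), function(id) {
      nresI <- sum(strsplit(sequences[[id]], "")[[1]] != "-")
      i <- seq_len(nresI)
      ca <- cbind(3.8 * i, 1.5 * sin(i), 1.5 * cos(i))
      atoms <- data.frame(serial = i, name = "CA", element = "C",
                          resno = i, resname = "GLY", chain = "A",
                          stringsAsFactors = FALSE)
      co <- array(NA_real_, c(nresI, 3, nModels))
      for (m in seq_len(nModels))
        co[, , m] <- ca + matrix(rnorm(nresI * 3, 0, jitter), ncol = 3)
      Ensemble(atoms, co, stateLabel = id, source = "alignment fixture")
    })
  })
  names(ensembles) <- names(sequences)
  list(block = block, ensembles = ensembles)
}
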