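# Hand-built ModeSpace over an orthonormal canonical basis.
handModeSpace <- function(values, dim = 12, projections = NULL,
                          info = NULL, shift = 0) {
  k <- length(values)
  vecs <- diag(dim)[, shift + seq_len(k), drop = FALSE]
  proj <- projections %||% matrix(0, 0, k)
  inf <- info %||% data.frame(ensemble = character(0), replica = integer(0),
                              model = integer(0))
  new("ModeSpace", mean = numeric(dim), vectors = vecs, values = values,
      totalVariance = sum(values), projections = proj, info = inf,
      atoms = data.frame(name = rep("CA", dim / 3),
                         resno = seq_len(dim / 3)))
}

# A displacement profile orthogonal to the rigid-body space of `base`.
internalMode <- function(base) {
  n <- nrow(base)
  cen <- sweep(base, 2, colMeans(base))
  rigid <- matrix(0, 3 * n, 6)
  for (k in 1:3) rigid[seq(k, 3 * n, by = 3), k] <- 1
  for (r in seq_len(n)) {
    p <- cen[r, ]
    rigid[(r - 1) * 3 + 1:3, 4] <- c(0, -p[3], p[2])
    rigid[(r - 1) * 3 + 1:3, 5] <- c(p[3], 0, -p[1])
    rigid[(r - 1) * 3 + 1:3, 6] <- c(-p[2], p[1], 0)
  }
  Q <- qr.Q(qr(rigid))
  raw <- rnorm(3 * n)
  v <- raw - Q %*% crossprod(Q, raw)
  v <- v / sqrt(sum(v^2))
  matrix(v, ncol = 3, byrow = TRUE)
}

test_that("an ensemble varying along one internal direction yields a single mode", {
  withr::local_seed(51)
  base <- randomCloud(8)
  u <- internalMode(base)
  amps <- 0.01 * c(-1, -0.5, 0, 0.5, 1)
  e <- toyEnsemble(base, nCopies = length(amps), state = "one")
  for (m in seq_along(amps)) e@coords[, , m] <- base + amps[m] * u
  ms <- combinedPCA(e, selection = atomSelection())
  expect_equal(length(modeValues(ms)), 1)
  expect_equal(varianceCoverage(ms, 1)$cumulativeFraction, 1,
               tolerance = 1e-6)
  expect_gt(abs(sum(modeVectors(ms)[, 1] * as.vector(t(u)))), 0.999)
})

test_that("two planted orthogonal modes are recovered with a 4:1 eigenvalue ratio", {
  withr::local_seed(52)
  base <- randomCloud(20)
  u1 <- internalMode(base)
  u2 <- internalMode(base)
  u2 <- u2 - sum(u1 * u2) * u1
  u2 <- u2 / sqrt(sum(u2^2))
  n <- 808
  a1 <- rnorm(n, 0, 2); a2 <- rnorm(n, 0, 1)
  e <- toyEnsemble(base, nCopies = n, state = "two")
  for (m in seq_len(n))
    e@coords[, , m] <- base + a1[m] * u1 + a2[m] * u2 +
      matrix(rnorm(60, 0, 0.05), 20, 3)
  ms <- combinedPCA(e, selection = atomSelection())
  expect_equal(modeValues(ms)[1] / modeValues(ms)[2], 4, tolerance = 0.2)
  expect_gt(abs(sum(modeVectors(ms)[, 1] * as.vector(t(u1)))), 0.95)
  expect_gt(abs(sum(modeVectors(ms)[, 2] * as.vector(t(u2)))), 0.95)

  # orthonormality and total-variance bookkeeping on a nontrivial input
  G <- crossprod(modeVectors(ms))
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  expect_equal(sum(modeValues(ms)), ms@totalVariance, tolerance = 1e-6)
})

test_that("pooled PCA is invariant to ensemble input order", {
  st <- generateStudy(syntheticSpec(nResidues = 10, nModels = 40,
                                    nReplicas = 2, seed = 8))
  ens <- unname(st$ensembles)
  a <- combinedPCA(ens)
  b <- combinedPCA(rev(ens))
  expect_equal(modeValues(a), modeValues(b), tolerance = 1e-9)
  pa <- modeProjections(a); pb <- modeProjections(b)
  pa <- pa[order(pa$ensemble, pa$model), ]
  pb <- pb[order(pb$ensemble, pb$model), ]
  expect_equal(abs(pa$PC1), abs(pb$PC1), tolerance = 1e-8)
})

test_that("mismatched atom layouts across ensembles are rejected", {
  e1 <- toyEnsemble(randomCloud(5), nCopies = 2, names = rep("CA", 5))
  e2 <- toyEnsemble(randomCloud(4), nCopies = 2, names = rep("CA", 4))
  expect_error(combinedPCA(list(e1, e2), selection = atomSelection()),
               "layout mismatch")
})

test_that("variance coverage follows the eigenvalue arithmetic", {
  ms <- handModeSpace(c(4, 3, 2, 1))
  expect_equal(varianceCoverage(ms, 4)$leadingShare, 0.4)
  expect_equal(varianceCoverage(ms, 4)$cumulativeFraction, 1)
  expect_equal(varianceCoverage(ms, 2)$leadingShare, 4 / 7)
  expect_error(varianceCoverage(ms, 0), "at least 1")

  single <- handModeSpace(5)
  expect_equal(varianceCoverage(single, 10)$leadingShare, 1)
})

test_that("threshold-0 partition labels hand-listed projections exactly", {
  proj <- cbind(c(-1, 2, 3, -0.5), c(1, -1, 1, -1))
  info <- data.frame(ensemble = "e1", replica = NA_integer_, model = 1:4)
  ms <- handModeSpace(c(2, 1), dim = 12, projections = proj, info = info)
  p <- partitionStates(ms)
  expect_equal(p$occupancy$frac_open, 0.5)
  expect_equal(p$conformers$state1, c("closed", "open", "open", "closed"))

  # all positive
  msAll <- handModeSpace(c(2, 1), projections = cbind(c(1, 2), c(3, 4)),
                         info = data.frame(ensemble = "e1",
                                           replica = NA_integer_,
                                           model = 1:2))
  expect_equal(partitionStates(msAll)$occupancy$frac_open, 1)

  # exact threshold goes to the negative side
  msTie <- handModeSpace(c(2, 1), projections = cbind(c(0, 1), c(0, -1)),
                         info = data.frame(ensemble = "e1",
                                           replica = NA_integer_,
                                           model = 1:2))
  pt <- partitionStates(msTie)
  expect_equal(pt$conformers$state1, c("closed", "open"))
  expect_equal(pt$conformers$state2, c("wide", "wide"))
})

test_that("perfectly sign-coupled modes give co-occurrence 1", {
  proj <- cbind(c(-2, -1, 1, 2), c(-1, -3, 2, 0.5))
  info <- data.frame(ensemble = "e1", replica = NA_integer_, model = 1:4)
  p <- partitionStates(handModeSpace(c(2, 1), projections = proj,
                                     info = info))
  expect_equal(unname(p$coOccurrence["e1"]), 1)

  # anti-coupled is also perfect matching under the symmetric definition
  projA <- cbind(c(-2, -1, 1, 2), -c(-1, -3, 2, 0.5))
  pA <- partitionStates(handModeSpace(c(2, 1), projections = projA,
                                      info = info))
  expect_equal(unname(pA$coOccurrence["e1"]), 1)
})

test_that("external projection is consistent with stored projections", {
  st <- generateStudy(syntheticSpec(nResidues = 10, nModels = 50,
                                    nReplicas = 2, seed = 12))
  ms <- combinedPCA(unname(st$ensembles))

  # the mean structure projects to zero
  meanEns <- toyEnsemble(matrix(ms@mean, ncol = 3, byrow = TRUE),
                         names = ms@atoms$name, resno = ms@atoms$resno)
  expect_lt(max(abs(projectExternal(ms, meanEns)[, -1])), 1e-8)

  # a conformer from the pooled set reproduces its stored projection
  one <- selectAtoms(subsetModels(st$ensembles$ff, 3),
                     atomSelection(atomNames = "CA"))
  got <- projectExternal(ms, one, k = 3)
  stored <- modeProjections(ms, 3)
  stored <- stored[stored$ensemble == "ff" & stored$model == 3, ]
  expect_equal(unlist(got[, c("PC1", "PC2", "PC3")]),
               unlist(stored[, c("PC1", "PC2", "PC3")]), tolerance = 1e-4,
               ignore_attr = TRUE)

  # mean + a * u1 projects to a on PC1 and ~0 elsewhere
  a <- 0.5
  disp <- matrix(ms@mean + a * modeVectors(ms)[, 1], ncol = 3, byrow = TRUE)
  dispEns <- toyEnsemble(disp, names = ms@atoms$name, resno = ms@atoms$resno)
  pr <- projectExternal(ms, dispEns, k = 3)
  expect_equal(pr$PC1, a, tolerance = 1e-3)
  expect_lt(max(abs(pr[, c("PC2", "PC3")])), 1e-3)

  wrong <- toyEnsemble(randomCloud(4), names = rep("CA", 4))
  expect_error(projectExternal(ms, wrong), "atom count mismatch")
})

test_that("mode overlap reports identity, orthogonality and planted rotations", {
  a <- handModeSpace(c(3, 2))
  self <- modeOverlap(a, a, k = 2)
  expect_equal(self$overlap, diag(2), ignore_attr = TRUE)
  expect_equal(self$rmsip, 1)

  b <- handModeSpace(c(3, 2), shift = 2)       # orthogonal complement
  ortho <- modeOverlap(a, b, k = 2)
  expect_equal(max(ortho$overlap), 0)
  expect_equal(ortho$rmsip, 0)

  # b's modes = a's rotated 45 degrees within their plane
  c45 <- handModeSpace(c(3, 2))
  rot <- cbind(c(1, 1) / sqrt(2), c(-1, 1) / sqrt(2))
  c45@vectors <- a@vectors %*% rot
  ov <- modeOverlap(a, c45, k = 2)
  expect_equal(as.vector(ov$overlap), rep(sqrt(2) / 2, 4), tolerance = 1e-12)
  expect_equal(ov$rmsip, 1, tolerance = 1e-12)
})
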