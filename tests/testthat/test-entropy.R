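# Covariance model built directly (no fitting) for closed-form checks.
directCovariance <- function(sigma, massesAmu) {
  new("CovarianceModel", mean = numeric(nrow(sigma)), sigma = sigma,
      masses = massesAmu, nModels = 2L, selection = "direct")
}

test_that("covariance of identical models is zero and single models are rejected", {
  e <- toyEnsemble(randomCloud(5), nCopies = 4)
  cm <- covarianceModel(e)
  expect_equal(max(abs(cm@sigma)), 0, tolerance = 1e-20)
  expect_equal(schlitterEntropy(cm), 0)
  expect_equal(quasiharmonicEntropy(cm), 0)
  expect_error(covarianceModel(toyEnsemble(randomCloud(5))), "at least 2")
})

test_that("population normalization: two 1D displacements of +-1 A give variance 1", {
  atoms <- data.frame(serial = 1, name = "CA", element = "C", resno = 1,
                      resname = "GLY", chain = "A", stringsAsFactors = FALSE)
  co <- array(0, c(1, 3, 2))
  co[1, 1, ] <- c(-1, 1)
  e <- Ensemble(atoms, co)
  cm <- covarianceModel(e, fitted = TRUE)
  expect_equal(cm@sigma[1, 1], 1)               # 1/N, not 1/(N-1)
  expect_equal(sum(abs(cm@sigma)) - abs(cm@sigma[1, 1]), 0)
})

test_that("sampled covariance of a known Gaussian is accurate at n = 1e5", {
  withr::local_seed(41)
  truth <- diag(c(0.5, 1, 2))
  n <- 1e5
  atoms <- data.frame(serial = 1, name = "CA", element = "C", resno = 1,
                      resname = "GLY", chain = "A", stringsAsFactors = FALSE)
  co <- array(t(matrix(rnorm(3 * n), n, 3) %*% chol(truth)), c(1, 3, n))
  cm <- covarianceModel(Ensemble(atoms, co), fitted = TRUE)
  expect_lt(max(abs(cm@sigma - truth) / max(truth)), 0.02)
})

test_that("both estimators match independent single-mode closed forms to 1e-9 relative", {
  for (v in c(0.01, 0.4, 3)) for (mass in c(1.008, 12.011)) {
    sigma <- diag(c(v, 0, 0))
    cm <- directCovariance(sigma, mass)
    expect_equal(schlitterEntropy(cm, 300), oracleSchlitter1D(mass, v, 300),
                 tolerance = 1e-9)
    expect_equal(quasiharmonicEntropy(cm, 300),
                 oracleQuasiharmonic1D(mass, v, 300), tolerance = 1e-9)
    expect_equal(schlitterEntropy(cm, 310, perMole = FALSE) * 6.02214076e23,
                 oracleSchlitter1D(mass, v, 310), tolerance = 1e-9)
  }
})

test_that("Schlitter bounds the quasi-harmonic estimate on random PSD covariances", {
  withr::local_seed(42)
  for (i in 1:100) {
    p <- sample(2:5, 1) * 3
    A <- matrix(rnorm(p * p, 0, 0.3), p, p)
    sigma <- crossprod(A) / p
    cm <- directCovariance(sigma, runif(p / 3, 1, 20))
    expect_gte(schlitterEntropy(cm), quasiharmonicEntropy(cm) - 1e-6)
  }
})

test_that("Gaussian-sample entropy matches the closed form within 0.5% at n = 1e5", {
  withr::local_seed(43)
  vars <- c(0.3, 0.8, 1.6)
  mass <- 12.011
  n <- 1e5
  atoms <- data.frame(serial = 1, name = "CA", element = "C", resno = 1,
                      resname = "GLY", chain = "A", stringsAsFactors = FALSE)
  co <- array(t(sweep(matrix(rnorm(3 * n), n, 3), 2, sqrt(vars), "*")),
              c(1, 3, n))
  cm <- covarianceModel(Ensemble(atoms, co), fitted = TRUE)
  closed <- sum(vapply(vars, function(v) oracleSchlitter1D(mass, v, 300), 0))
  closedQH <- sum(vapply(vars, function(v)
    oracleQuasiharmonic1D(mass, v, 300), 0))
  expect_equal(schlitterEntropy(cm, 300), closed, tolerance = 0.005)
  expect_equal(quasiharmonicEntropy(cm, 300), closedQH, tolerance = 0.005)
})

test_that("entropy is monotone under covariance scaling and invariant to rigid moves", {
  withr::local_seed(44)
  A <- matrix(rnorm(81, 0, 0.4), 9, 9)
  sigma <- crossprod(A) / 9
  masses <- runif(3, 5, 15)
  s1 <- schlitterEntropy(directCovariance(sigma, masses))
  for (c in c(1, 1.5, 4)) {
    expect_gte(schlitterEntropy(directCovariance(c * sigma, masses)), s1)
    expect_gte(quasiharmonicEntropy(directCovariance(c * sigma, masses)),
               quasiharmonicEntropy(directCovariance(sigma, masses)) - 1e-9)
  }

  st <- generateStudy(syntheticSpec(nResidues = 8, nModels = 30,
                                    nReplicas = 2, seed = 6))
  e <- st$ensembles$ff
  scr <- e
  for (m in seq_len(nModels(e))) {
    R <- rotationMatrix(rnorm(3), runif(1, 0, 2 * pi))
    scr@coords[, , m] <- sweep(coords(e)[, , m] %*% R, 2, rnorm(3, 0, 9), "+")
  }
  expect_equal(schlitterEntropy(covarianceModel(e)),
               schlitterEntropy(covarianceModel(scr)), tolerance = 1e-6)
})

test_that("non-PSD covariances are rejected", {
  sigma <- diag(c(1, 1, -0.5))
  expect_error(schlitterEntropy(directCovariance(sigma, 12)),
               "positive semi-definite")
})

test_that("binding-entropy ratio handles degenerate and equal-state cases", {
  withr::local_seed(45)
  base <- generateStudy(syntheticSpec(nResidues = 8, nModels = 40,
                                      nReplicas = 2, seed = 9))$ensembles$ff
  scale <- function(e, c) {
    mu <- apply(e@coords, c(1, 2), mean)
    out <- e
    for (m in seq_len(nModels(e)))
      out@coords[, , m] <- mu + c * (e@coords[, , m] - mu)
    out
  }
  ens <- list(ff = base, fd = scale(base, 1.5), cf = scale(base, 0.7),
              cd = scale(base, 1.5))
  r <- bindingEntropyRatio(ens, schedule = 1)
  expect_equal(r$ratio, 0, tolerance = 1e-9)     # S_cd == S_fd exactly

  ens$cf <- base                                  # S_cf == S_ff
  expect_error(bindingEntropyRatio(ens, schedule = 1),
               "denominator degenerate")

  expect_error(bindingEntropyRatio(list(ff = base, fd = base, cf = base)),
               "cd")
  expect_error(bindingEntropyRatio(ens, schedule = c(0.5, 0.9)),
               "must be 1")
})
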