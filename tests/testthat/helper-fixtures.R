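# Shared fixtures, built in code.

# A minimal ensemble: `n` atoms at given coordinates, all carbon.
toyEnsemble <- function(xyz, nCopies = 1, resno = NULL, names = NULL,
                        elements = NULL, state = "toy") {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  atoms <- data.frame(
    serial = seq_len(n),
    name = names %||% paste0("C", seq_len(n)),
    element = elements %||% rep("C", n),
    resno = resno %||% seq_len(n),
    resname = "GLY", chain = "A", stringsAsFactors = FALSE)
  co <- array(rep(xyz, nCopies), c(n, 3, nCopies))
  Ensemble(atoms, co, stateLabel = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random non-degenerate point cloud.
randomCloud <- function(n, scale = 5) matrix(rnorm(n * 3, 0, scale), n, 3)

# Rotation matrix about an axis by angle (radians).
rotationMatrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# One hand-formatted fixed-width PDB ATOM line.
pdbLine <- function(serial, name, resn, chain, resno, xyz,
                    occ = 1, b = 0, alt = " ", icode = " ", ele = "C") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", name), alt, resn, chain, resno, icode,
          xyz[1], xyz[2], xyz[3], occ, b, ele)
}

# Cached full-scale synthetic studies (shared between acceptance blocks so
# each study is generated once per test run).
.studyCache <- new.env(parent = emptyenv())

cachedStudy <- function(seed) {
  key <- paste0("study", seed)
  if (is.null(.studyCache[[key]]))
    .studyCache[[key]] <- generateStudy(syntheticSpec(seed = seed))
  .studyCache[[key]]
}

cachedRatio <- function(seed) {
  key <- paste0("ratio", seed)
  if (is.null(.studyCache[[key]])) {
    st <- cachedStudy(seed)
    .studyCache[[key]] <- bindingEntropyRatio(
      st$ensembles, fitSelection = atomSelection(atomNames = c("N", "CA")),
      schedule = c(0.1, 0.5, 1))
  }
  .studyCache[[key]]
}

cachedModeSpace <- function(seed) {
  key <- paste0("modes", seed)
  if (is.null(.studyCache[[key]]))
    .studyCache[[key]] <- combinedPCA(unname(cachedStudy(seed)$ensembles))
  .studyCache[[key]]
}

# Sign with which a recovered mode points along a planted Calpha mode.
modeSign <- function(ms, plantedProfile, mode) {
  u <- as.vector(t(plantedProfile))
  sign(sum(modeVectors(ms)[, mode] * u))
}
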