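# Independent brute-force oracles used to cross-check the implementation.

# Betweenness centrality by exhaustive enumeration of all shortest paths
# (feasible for graphs of <= 12 nodes). `edges` is a 2-column matrix of
# 1-based node indices; returns raw betweenness per node (each unordered
# source-target pair counted once).
bruteBetweenness <- function(edges, nNodes) {
  adj <- vector("list", nNodes)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  bfsDist <- function(s) {
    dist <- rep(Inf, nNodes); dist[s] <- 0; q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) if (!is.finite(dist[w])) {
        dist[w] <- dist[v] + 1; q <- c(q, w)
      }
    }
    dist
  }
  btw <- numeric(nNodes)
  for (s in seq_len(nNodes - 1)) {
    dist <- bfsDist(s)
    for (t in (s + 1):nNodes) {
      if (!is.finite(dist[t])) next
      paths <- list()
      rec <- function(path) {
        v <- path[length(path)]
        if (v == t) { paths[[length(paths) + 1]] <<- path; return(invisible()) }
        for (w in adj[[v]])
          if (dist[w] == dist[v] + 1 && dist[w] <= dist[t]) rec(c(path, w))
      }
      rec(s)
      sigma <- length(paths)
      if (sigma == 0) next
      through <- numeric(nNodes)
      for (p in paths) {
        inner <- setdiff(p, c(s, t))
        through[inner] <- through[inner] + 1
      }
      btw <- btw + through / sigma
    }
  }
  btw
}

# The discriminative-contact rule evaluated by naive triple loop.
bruteDiscriminative <- function(stats, statePairs) {
  pairs <- unique(stats[, c("resI", "resJ")])
  sel <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    for (sp in statePairs) {
      a <- stats[stats$state == sp[1] & stats$resI == pairs$resI[i] &
                   stats$resJ == pairs$resJ[i], ]
      b <- stats[stats$state == sp[2] & stats$resI == pairs$resI[i] &
                   stats$resJ == pairs$resJ[i], ]
      if (nrow(a) == 1 && nrow(b) == 1 &&
          abs(a$mean - b$mean) > a$sd + b$sd) {
        sel[i] <- TRUE
        break
      }
    }
  }
  pairs[sel, , drop = FALSE]
}

# Soft-sphere residue contact areas by naive atom-pair loops.
bruteContactAreas <- function(e, model, waterRadius = 1.4, minSeqSep = 2) {
  a <- atomTable(e)
  heavy <- which(a$element != "H")
  co <- coords(e)[, , model, drop = TRUE]
  res <- sort(unique(a$resno[heavy]))
  out <- list()
  for (i in seq_along(res)) for (j in seq_along(res)) {
    if (j <= i || abs(res[j] - res[i]) < minSeqSep) next
    ai <- heavy[a$resno[heavy] == res[i]]
    aj <- heavy[a$resno[heavy] == res[j]]
    area <- 0
    for (p in ai) for (q in aj) {
      d <- sqrt(sum((co[p, ] - co[q, ])^2))
      ov <- a$vdw[p] + a$vdw[q] + 2 * waterRadius - d
      if (ov > 0) area <- area + pi * ov^2
    }
    if (area > 0)
      out[[length(out) + 1]] <- data.frame(resI = res[i], resJ = res[j],
                                           area = area)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(resI = integer(0), resJ = integer(0), area = numeric(0))
}

# S2 of a set of unit vectors straight from the second-moment definition
# (kept separate from the package internals on purpose).
oracleS2 <- function(u) {
  m <- crossprod(u) / nrow(u)
  1.5 * (m[1, 1]^2 + m[2, 2]^2 + m[3, 3]^2 +
           2 * m[1, 2]^2 + 2 * m[1, 3]^2 + 2 * m[2, 3]^2) - 0.5
}

# Per-mode closed forms for the entropy estimators, with constants written
# out independently of the package.
oracleSchlitter1D <- function(massAmu, varA2, temperatureK) {
  kB <- 1.380649e-23; hbar <- 1.054571817e-34; Rgas <- 8.314462618
  amu <- 1.66053906660e-27
  lam <- massAmu * amu * varA2 * 1e-20
  (Rgas / 2) * log(1 + kB * temperatureK * exp(1)^2 * lam / hbar^2)
}

oracleQuasiharmonic1D <- function(massAmu, varA2, temperatureK) {
  kB <- 1.380649e-23; hbar <- 1.054571817e-34; Rgas <- 8.314462618
  amu <- 1.66053906660e-27
  lam <- massAmu * amu * varA2 * 1e-20
  omega <- sqrt(kB * temperatureK / lam)
  alpha <- hbar * omega / (kB * temperatureK)
  Rgas * (alpha / (exp(alpha) - 1) - log(1 - exp(-alpha)))
}
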