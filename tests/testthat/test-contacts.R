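test_that("the soft-sphere pair area matches hand arithmetic", {
  # two carbons, r = 1.7 each, probe 1.4: reach = 1.7 + 1.7 + 2.8 = 6.2;
  # at d = 5.2 the overlap is 1.0 and the area is pi * 1^2
  e <- toyEnsemble(rbind(c(0, 0, 0), c(5.2, 0, 0)), resno = c(1, 3),
                   names = c("CB", "CB"))
  a <- contactAreas(e)
  expect_equal(nrow(a), 1)
  expect_equal(a$area, pi, tolerance = 1e-12)
  expect_equal(c(a$resI, a$resJ), c(1, 3))

  # beyond reach: no contact rows
  far <- toyEnsemble(rbind(c(0, 0, 0), c(6.3, 0, 0)), resno = c(1, 3),
                     names = c("CB", "CB"))
  expect_equal(nrow(contactAreas(far)), 0)

  # sequence neighbours are excluded
  adj <- toyEnsemble(rbind(c(0, 0, 0), c(5.2, 0, 0)), resno = c(1, 2),
                     names = c("CB", "CB"))
  expect_equal(nrow(contactAreas(adj)), 0)
})

test_that("contact areas agree with a naive atom-pair loop on random structures", {
  withr::local_seed(61)
  for (rep in 1:3) {
    n <- 12
    e <- toyEnsemble(randomCloud(n, scale = 3), nCopies = 2,
                     resno = rep(1:(n / 2), each = 2),
                     names = rep(c("CA", "CB"), n / 2))
    e@coords[, , 2] <- e@coords[, , 2] + matrix(rnorm(n * 3, 0, 0.4), n, 3)
    got <- contactAreas(e)
    for (m in 1:2) {
      want <- bruteContactAreas(e, m)
      want <- want[order(want$resI, want$resJ), ]
      sub <- got[got$model == m, c("resI", "resJ", "area")]
      sub <- sub[order(sub$resI, sub$resJ), ]
      rownames(sub) <- rownames(want) <- NULL
      expect_equal(sub, want, tolerance = 1e-10)
    }
  }
})

test_that("contact statistics use population moments and count absent pairs as zero", {
  mk <- function(model, resI, resJ, area)
    data.frame(model = model, resI = resI, resJ = resJ, area = area)
  a <- rbind(mk(1, 1, 3, 4), mk(2, 1, 3, 6))
  attr(a, "nModels") <- 2
  b <- rbind(mk(1, 1, 3, 5), mk(2, 1, 3, 5), mk(1, 2, 5, 4))
  attr(b, "nModels") <- 2
  st <- contactStatistics(list(A = a, B = b))

  sA <- st[st$state == "A" & st$resI == 1, ]
  expect_equal(sA$mean, 5)
  expect_equal(sA$sd, 1)                      # population sd of {4, 6}
  sB <- st[st$state == "B" & st$resI == 1, ]
  expect_equal(sB$mean, 5)
  expect_equal(sB$sd, 0)
  # pair (2,5) unseen in state A: reported as mean 0, sd 0; in B it appears
  # in 1 of 2 models, so mean 2 and sd 2
  expect_equal(st[st$state == "A" & st$resI == 2, c("mean", "sd")],
               data.frame(mean = 0, sd = 0), ignore_attr = TRUE)
  expect_equal(st[st$state == "B" & st$resI == 2, c("mean", "sd")],
               data.frame(mean = 2, sd = 2), ignore_attr = TRUE)

  one <- mk(1, 1, 3, 4); attr(one, "nModels") <- 1
  expect_error(contactStatistics(list(A = one, B = b)), "fewer than 2")
})

test_that("the discriminative rule is strict, symmetric, and matches brute force", {
  mkStats <- function(state, mean, sd)
    data.frame(state = state, resI = 1, resJ = 5, mean = mean, sd = sd)
  # |10 - 20| = 10 > 1 + 2: selected
  st1 <- rbind(mkStats("A", 10, 1), mkStats("B", 20, 2))
  expect_equal(nrow(discriminativeContacts(st1)), 1)
  # boundary |10 - 15| = 5 = 2 + 3: NOT selected (strict inequality)
  st2 <- rbind(mkStats("A", 10, 2), mkStats("B", 15, 3))
  expect_equal(nrow(discriminativeContacts(st2)), 0)
  # identical distributions: not selected
  st3 <- rbind(mkStats("A", 7, 1), mkStats("B", 7, 1))
  expect_equal(nrow(discriminativeContacts(st3)), 0)
  # symmetric in state order
  expect_equal(discriminativeContacts(st1, list(c("A", "B")))[, 1:2],
               discriminativeContacts(st1, list(c("B", "A")))[, 1:2])
  expect_error(discriminativeContacts(st1, list(c("A", "Z"))),
               "unknown state")

  withr::local_seed(62)
  for (rep in 1:5) {
    pairs <- expand.grid(resI = 1:4, resJ = 6:8)
    states <- c("w", "x", "y")
    stats <- do.call(rbind, lapply(states, function(s)
      data.frame(state = s, resI = pairs$resI, resJ = pairs$resJ,
                 mean = runif(nrow(pairs), 0, 10),
                 sd = runif(nrow(pairs), 0, 3))))
    sp <- list(c("w", "x"), c("w", "y"), c("x", "y"))
    got <- discriminativeContacts(stats, sp)[, c("resI", "resJ")]
    want <- bruteDiscriminative(stats, sp)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got[order(got$resI, got$resJ), ],
                 want[order(want$resI, want$resJ), ], ignore_attr = TRUE)
  }
})

test_that("network metrics match hand-checked cases", {
  # path a-b-c: b carries the single a..c geodesic
  path <- data.frame(resI = c(1, 2), resJ = c(2, 3))
  net <- buildContactNetwork(path)
  expect_equal(net@componentSizes, 3L)
  expect_equal(net@nodes$betweenness[net@nodes$residue == 2], 1)
  expect_equal(sum(net@nodes$betweenness > 0), 1)

  # two disjoint edges: two components, no betweenness
  disj <- data.frame(resI = c(1, 10), resJ = c(2, 11))
  net2 <- buildContactNetwork(disj)
  expect_equal(net2@componentSizes, c(2L, 2L))
  expect_equal(max(net2@nodes$betweenness), 0)

  empty <- buildContactNetwork(data.frame(resI = integer(0),
                                          resJ = integer(0)))
  expect_equal(nrow(empty@nodes), 0)
  expect_equal(length(empty@componentSizes), 0)
})

test_that("betweenness equals exhaustive shortest-path enumeration on random graphs", {
  withr::local_seed(63)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    maxE <- n * (n - 1) / 2
    nE <- sample(seq_len(maxE), 1)
    all <- t(combn(n, 2))
    edges <- all[sample(maxE, nE), , drop = FALSE]
    net <- buildContactNetwork(data.frame(resI = edges[, 1],
                                          resJ = edges[, 2]))
    want <- bruteBetweenness(edges, n)
    for (r in seq_len(nrow(net@nodes))) {
      v <- net@nodes$residue[r]
      expect_equal(net@nodes$betweenness[r], want[v], tolerance = 1e-9)
    }
    # normalization bookkeeping
    nn <- nrow(net@nodes)
    if (nn > 2)
      expect_equal(net@nodes$betweennessNorm,
                   net@nodes$betweenness * 2 / ((nn - 1) * (nn - 2)))
  }
})

test_that("contact areas round-trip through the precomputed TSV reader", {
  d <- data.frame(model = c(1, 1, 2), resI = c(1, 2, 1), resJ = c(5, 6, 5),
                  area = c(3.5, 1.25, 4))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#model\tresI\tresJ\tarea",
               apply(d, 1, function(r) paste(r, collapse = "\t"))), f)
  got <- readContactAreas(f)
  expect_equal(got$area, d$area)
  expect_equal(attr(got, "nModels"), 2)
  viaApi <- contactAreas(NULL, metric = "precomputed", precomputed = got)
  expect_equal(viaApi$area, d$area)
})
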