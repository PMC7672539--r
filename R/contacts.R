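#' Per-conformer residue-residue contact areas
#'
#' For the default `soft_sphere` metric, the contact area between residues
#' i and j in one model is the sum over their heavy-atom pairs (a, b) of
#' \deqn{\pi \,\max(0,\; r_a + r_b + 2 r_w - d_{ab})^2}
#' with van der Waals radii from the atom table and a solvent (water) probe
#' radius `waterRadius` (1.4 Angstrom). The metric is a smooth, monotone
#' proxy for surface-tessellation contact areas: suitable for detecting
#' contact *changes* between states, but its absolute values are not
#' comparable to Voronoi tessellation areas. Genuine tessellation output can
#' be supplied instead via [readContactAreas()] (`metric = "precomputed"`).
#'
#' Sequence neighbours with `|i - j| <= minSeqSep - 1` are excluded
#' (default: self and immediate neighbours).
#'
#' @param e an [Ensemble-class] with heavy atoms and vdW radii.
#' @param metric `"soft_sphere"` or `"precomputed"` (the latter requires
#'   `precomputed`).
#' @param waterRadius solvent probe radius, Angstrom.
#' @param minSeqSep smallest residue-number separation reported (2 excludes
#'   `|i - j| <= 1`).
#' @param models optional model indices to evaluate (default: all).
#' @param precomputed a data.frame `model, resI, resJ, area` when
#'   `metric = "precomputed"`.
#' @return data.frame `model`, `resI`, `resJ` (resI < resJ), `area`
#'   (Angstrom^2); only nonzero areas are listed. The number of models
#'   evaluated is attached as attribute `"nModels"`.
#' @export
contactAreas <- function(e, metric = c("soft_sphere", "precomputed"),
                         waterRadius = 1.4, minSeqSep = 2, models = NULL,
                         precomputed = NULL) {
  metric <- match.arg(metric)
  if (metric == "precomputed") {
    if (is.null(precomputed)) stop("metric 'precomputed' needs `precomputed`")
    out <- precomputed
    attr(out, "nModels") <- length(unique(out$model))
    return(out)
  }
  stopifnot(is(e, "Ensemble"))
  heavy <- which(e@atoms$element != "H")
  if (!length(heavy)) stop("no heavy atoms in ensemble")
  if (any(is.na(e@atoms$vdw[heavy]))) stop("missing vdW radii")
  models <- models %||% seq_len(nModels(e))

  rads <- e@atoms$vdw[heavy]
  resno <- e@atoms$resno[heavy]
  resLevels <- sort(unique(resno))
  nres <- length(resLevels)
  resIdx <- match(resno, resLevels)
  # residue indicator matrix for atom-pair -> residue-pair aggregation
  Rind <- matrix(0, nres, length(heavy))
  Rind[cbind(resIdx, seq_along(heavy))] <- 1
  reach <- outer(rads, rads, "+") + 2 * waterRadius
  sepOK <- abs(outer(resLevels, resLevels, "-")) >= minSeqSep
  ut <- upper.tri(matrix(0, nres, nres))

  res <- vector("list", length(models))
  for (k in seq_along(models)) {
    X <- e@coords[heavy, , models[k], drop = TRUE]
    sq <- rowSums(X^2)
    d2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
    d2[d2 < 0] <- 0
    ov <- reach - sqrt(d2)
    ov[ov < 0] <- 0
    diag(ov) <- 0
    A <- pi * ov^2
    resA <- Rind %*% A %*% t(Rind)
    resA[!sepOK] <- 0
    hit <- which(ut & resA > 0, arr.ind = TRUE)
    if (nrow(hit)) {
      ord <- order(hit[, 1], hit[, 2])
      hit <- hit[ord, , drop = FALSE]
      res[[k]] <- data.frame(model = models[k],
                             resI = resLevels[hit[, 1]],
                             resJ = resLevels[hit[, 2]],
                             area = resA[hit])
    }
  }
  out <- do.call(rbind, res) %||%
    data.frame(model = integer(0), resI = integer(0), resJ = integer(0),
               area = numeric(0))
  rownames(out) <- NULL
  attr(out, "nModels") <- length(models)
  out
}

#' Read contact areas produced by an external tessellation tool
#'
#' Accepts a TSV with a `#`-prefixed header and columns
#' `model`, `resI`, `resJ`, `area`, e.g. converted Voronoi-tessellation
#' output.
#'
#' @param path file path.
#' @return data.frame suitable as `precomputed` input to the contact
#'   statistics.
#' @export
readContactAreas <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  df <- read.table(text = lines, sep = "\t",
                   col.names = c("model", "resI", "resJ", "area"))
  attr(df, "nModels") <- length(unique(df$model))
  df
}

#' Per-state contact statistics
#'
#' Computes, for each residue pair and each state, the mean and population
#' standard deviation of the contact area across that state's conformers.
#' Models in which a pair has no contact contribute area 0. States can be
#' whole ensembles or any other conformer grouping (e.g. regions of a PCA
#' plot); the caller controls the grouping by what it passes in.
#'
#' @param areasByState named list of [contactAreas()] outputs, one per
#'   state (each must carry its `"nModels"` attribute or have it supplied
#'   via `nModels`).
#' @param nModels optional named integer vector overriding the per-state
#'   model counts.
#' @return data.frame `state`, `resI`, `resJ`, `mean`, `sd`; every pair
#'   observed in any state is reported for all states (absent = mean 0,
#'   sd 0).
#' @export
contactStatistics <- function(areasByState, nModels = NULL) {
  stopifnot(is.list(areasByState), length(names(areasByState)) > 0)
  counts <- vapply(names(areasByState), function(s) {
    n <- if (!is.null(nModels) && s %in% names(nModels)) nModels[[s]] else
      attr(areasByState[[s]], "nModels")
    if (is.null(n) || is.na(n)) stop("unknown model count for state ", s)
    as.integer(n)
  }, 0L)
  if (any(counts < 2)) stop("state(s) with fewer than 2 conformers: ",
                            paste(names(counts)[counts < 2], collapse = ", "))
  pairs <- unique(do.call(rbind, lapply(areasByState, function(d)
    d[, c("resI", "resJ")])))
  pairs <- pairs[order(pairs$resI, pairs$resJ), , drop = FALSE]
  key <- paste(pairs$resI, pairs$resJ)
  out <- list()
  for (s in names(areasByState)) {
    d <- areasByState[[s]]
    dk <- paste(d$resI, d$resJ)
    n <- counts[[s]]
    sums <- tapply(d$area, dk, sum)
    sq <- tapply(d$area^2, dk, sum)
    s1 <- ifelse(key %in% names(sums), sums[key], 0)
    s2v <- ifelse(key %in% names(sq), sq[key], 0)
    mu <- s1 / n
    varr <- pmax(0, s2v / n - mu^2)       # population variance incl. zeros
    out[[s]] <- data.frame(state = s, resI = pairs$resI, resJ = pairs$resJ,
                           mean = unname(mu), sd = unname(sqrt(varr)),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select contacts that discriminate between states
#'
#' A residue pair is discriminative for a state pair (A, B) when
#' \eqn{|mean_A - mean_B| > sd_A + sd_B} (strict inequality). A pair is
#' selected when the rule holds for at least one of the listed state pairs.
#' The rule is symmetric in state order.
#'
#' @param stats output of [contactStatistics()].
#' @param statePairs a list of length-2 character vectors; default all
#'   unordered state pairs present in `stats`.
#' @return data.frame of selected pairs: `resI`, `resJ`, `statePairs`
#'   (semicolon-joined list of discriminating comparisons), `maxExcess`
#'   (largest value of `|dMean| - (sdA + sdB)`).
#' @export
discriminativeContacts <- function(stats, statePairs = NULL) {
  states <- unique(stats$state)
  if (is.null(statePairs)) {
    statePairs <- if (length(states) > 1) {
      cmb <- utils::combn(states, 2)
      lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
    } else list()
  }
  for (sp in statePairs)
    if (!all(sp %in% states))
      stop("unknown state name: ", paste(setdiff(sp, states), collapse = ", "))
  pairs <- unique(stats[, c("resI", "resJ")])
  key <- paste(pairs$resI, pairs$resJ)
  hits <- setNames(vector("list", length(key)), key)
  excess <- setNames(rep(-Inf, length(key)), key)
  byState <- split(stats, stats$state)
  for (sp in statePairs) {
    a <- byState[[sp[1]]]; b <- byState[[sp[2]]]
    ka <- paste(a$resI, a$resJ); kb <- paste(b$resI, b$resJ)
    ia <- match(key, ka); ib <- match(key, kb)
    dm <- abs(a$mean[ia] - b$mean[ib])
    ss <- a$sd[ia] + b$sd[ib]
    sel <- !is.na(dm) & dm > ss
    exc <- dm - ss
    upd <- !is.na(exc) & exc > excess
    excess[upd] <- exc[upd]
    for (i in which(sel))
      hits[[i]] <- c(hits[[i]], paste(sp[1], sp[2], sep = "-"))
  }
  selected <- which(vapply(hits, length, 0L) > 0)
  out <- data.frame(resI = pairs$resI[selected], resJ = pairs$resJ[selected],
                    statePairs = vapply(hits[selected], paste,
                                        "", collapse = ";"),
                    maxExcess = unname(excess[selected]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build the contact network from selected contacts
#'
#' Constructs an undirected, unweighted graph whose nodes are residues and
#' whose edges are the selected contacts, reports connected components
#' sorted by size and Brandes betweenness centrality per node (raw, i.e.
#' each unordered source-target pair counted once, and normalized by
#' `2 / ((n - 1)(n - 2))`).
#'
#' @param selected data.frame with columns `resI`, `resJ` (e.g. from
#'   [discriminativeContacts()]).
#' @return A [ContactNetwork-class]; an empty network when no contacts are
#'   selected.
#' @export
buildContactNetwork <- function(selected) {
  if (!nrow(selected)) {
    return(new("ContactNetwork",
               graph = igraph::make_empty_graph(directed = FALSE),
               nodes = data.frame(residue = integer(0), component = integer(0),
                                  betweenness = numeric(0),
                                  betweennessNorm = numeric(0)),
               componentSizes = integer(0)))
  }
  edges <- unique(data.frame(from = as.character(selected$resI),
                             to = as.character(selected$resJ),
                             stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(g)
  sizes <- sort(as.integer(comp$csize), decreasing = TRUE)
  rankBySize <- match(comp$membership,
                      order(comp$csize, decreasing = TRUE))
  btw <- igraph::betweenness(g, directed = FALSE)
  n <- igraph::vcount(g)
  norm <- if (n > 2) btw * 2 / ((n - 1) * (n - 2)) else btw * 0
  nodes <- data.frame(residue = as.integer(igraph::V(g)$name),
                      component = as.integer(rankBySize),
                      betweenness = as.numeric(btw),
                      betweennessNorm = as.numeric(norm))
  nodes <- nodes[order(nodes$component, nodes$residue), ]
  rownames(nodes) <- NULL
  new("ContactNetwork", graph = g, nodes = nodes, componentSizes = sizes)
}

#' Export a contact network as an edge list TSV
#'
#' @param net a [ContactNetwork-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeContactNetwork <- function(net, path) {
  el <- igraph::as_edgelist(net@graph)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#resI\tresJ", con)
  if (nrow(el))
    write.table(el, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(path)
}
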