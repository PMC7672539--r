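#' Read an aligned FASTA file into an AlignmentBlock
#'
#' Record ids may encode the chain as `structureId|chain` (chain defaults
#' to "A"). Residue numbering defaults to 1..n per structure unless a
#' sidecar residue-track TSV is supplied: tab-separated with a `#` header
#' and columns `structure`, `position` (1-based index among non-gap
#' characters), `chain`, `resno`.
#'
#' @param path aligned FASTA path (gaps as `-`).
#' @param trackPath optional residue-track TSV path.
#' @return An [AlignmentBlock-class].
#' @export
readAlignedFasta <- function(path, trackPath = NULL) {
  seqs <- Biostrings::readBStringSet(path)
  ids <- names(seqs)
  structure_id <- vapply(strsplit(ids, "|", fixed = TRUE), `[`, "", 1)
  chain <- vapply(strsplit(ids, "|", fixed = TRUE), function(p)
    if (length(p) > 1) p[2] else "A", "")
  s <- as.character(seqs)
  names(s) <- structure_id
  track <- lapply(seq_along(s), function(i) {
    n <- sum(strsplit(s[[i]], "")[[1]] != "-")
    data.frame(chain = chain[i], resno = seq_len(n), stringsAsFactors = FALSE)
  })
  names(track) <- structure_id
  if (!is.null(trackPath)) {
    lines <- readLines(trackPath, warn = FALSE)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    tr <- read.table(text = lines, sep = "\t", stringsAsFactors = FALSE,
                     col.names = c("structure", "position", "chain", "resno"))
    for (id in unique(tr$structure)) {
      sub <- tr[tr$structure == id, ]
      sub <- sub[order(sub$position), ]
      track[[id]] <- data.frame(chain = as.character(sub$chain),
                                resno = as.integer(sub$resno),
                                stringsAsFactors = FALSE)
    }
  }
  alignmentBlock(s, track)
}

# Column index of each non-gap position of one aligned string.
.nonGapColumns <- function(alignedString) {
  which(strsplit(alignedString, "")[[1]] != "-")
}

#' Concatenate alignment blocks through a pivot structure
#'
#' Merges several multiple-alignment blocks that all contain one common
#' (pivot) structure. The pivot's ungapped sequence must be identical in
#' every block; its residue positions define the reconciled columns.
#' Columns in which the pivot is gapped cannot be reconciled across blocks
#' and are dropped (with a message listing how many were lost per block).
#' Blocks that are exactly identical reconcile trivially and are returned
#' unchanged.
#'
#' @param blocks list of [AlignmentBlock-class] objects.
#' @param pivot structure id present in every block.
#' @return A single [AlignmentBlock-class] containing the pivot plus all
#'   other structures, with one column per pivot residue.
#' @export
concatenateAlignments <- function(blocks, pivot) {
  stopifnot(length(blocks) >= 1)
  for (i in seq_along(blocks)) {
    if (!pivot %in% names(blocks[[i]]@sequences))
      stop("pivot '", pivot, "' missing from block ", i)
  }
  # identical blocks reconcile trivially
  if (length(blocks) > 1 &&
      all(vapply(blocks[-1], function(b)
        identical(b@sequences, blocks[[1]]@sequences) &&
          identical(b@track, blocks[[1]]@track), TRUE)))
    return(blocks[[1]])
  if (length(blocks) == 1) return(blocks[[1]])

  ungapped <- vapply(blocks, function(b)
    gsub("-", "", b@sequences[[pivot]]), "")
  if (length(unique(ungapped)) > 1) {
    a <- strsplit(ungapped[1], "")[[1]]
    jBad <- which(vapply(ungapped[-1], function(u) !identical(u, ungapped[1]),
                         TRUE))[1] + 1
    b <- strsplit(ungapped[jBad], "")[[1]]
    n <- min(length(a), length(b))
    at <- which(a[seq_len(n)] != b[seq_len(n)])
    at <- if (length(at)) at[1] else n + 1
    stop(sprintf(
      "pivot sequences disagree between blocks 1 and %d at pivot residue %d ('%s' vs '%s')",
      jBad, at, if (at <= length(a)) a[at] else "-",
      if (at <= length(b)) b[at] else "-"))
  }
  L <- nchar(ungapped[1])

  seqs <- character(0)
  track <- list()
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    pivCols <- .nonGapColumns(b@sequences[[pivot]])  # length L
    dropped <- nchar(b@sequences[[pivot]]) - L
    if (dropped > 0)
      message("block ", i, ": dropped ", dropped,
              " column(s) not covered by the pivot")
    for (id in names(b@sequences)) {
      if (id %in% names(track)) {
        if (id != pivot)
          warning("structure '", id,
                  "' appears in multiple blocks; keeping the first")
        next
      }
      chars <- strsplit(b@sequences[[id]], "")[[1]]
      newSeq <- chars[pivCols]
      # residue track: keep residues whose column survives
      resIdxAll <- cumsum(chars != "-")
      keptRes <- resIdxAll[pivCols][newSeq != "-"]
      seqs[[id]] <- paste(newSeq, collapse = "")
      track[[id]] <- b@track[[id]][keptRes, , drop = FALSE]
      rownames(track[[id]]) <- NULL
    }
  }
  new("AlignmentBlock", sequences = seqs, track = track)
}

#' Extract the common core of an alignment
#'
#' The core is the ordered set of alignment columns with no gap in *any*
#' sequence, renumbered to consensus indices 1..K, together with each
#' structure's mapping from consensus index back to its own
#' `(chain, resno)`.
#'
#' @param block an [AlignmentBlock-class] with at least 2 structures.
#' @return A [CoreMapping-class].
#' @export
extractCore <- function(block) {
  stopifnot(is(block, "AlignmentBlock"))
  if (length(block@sequences) < 2)
    stop("need at least 2 structures to define a core")
  mat <- do.call(rbind, strsplit(unname(block@sequences), ""))
  coreCols <- which(colSums(mat == "-") == 0)
  if (!length(coreCols)) stop("no common core: every column is gapped somewhere")
  map <- list()
  for (id in names(block@sequences)) {
    chars <- strsplit(block@sequences[[id]], "")[[1]]
    resIdx <- cumsum(chars != "-")
    tr <- block@track[[id]][resIdx[coreCols], , drop = FALSE]
    map[[id]] <- data.frame(core = seq_along(coreCols),
                            chain = tr$chain, resno = tr$resno,
                            stringsAsFactors = FALSE)
  }
  new("CoreMapping", coreColumns = as.integer(coreCols), map = map)
}

#' Rewrite an ensemble to core-only Calpha atoms with consensus numbering
#'
#' Retains one Calpha per core position, in consensus order, renumbered to
#' consensus indices 1..K on chain "A". Ensembles from different domains
#' mapped through the same [CoreMapping-class] therefore have identical
#' atom layouts and can be pooled directly by [combinedPCA()].
#'
#' @param e an [Ensemble-class].
#' @param mapping a [CoreMapping-class].
#' @param structureId which structure's mapping to apply.
#' @return A Calpha-only [Ensemble-class] with `nrow(map)` atoms per model.
#' @export
applyCore <- function(e, mapping, structureId) {
  stopifnot(is(e, "Ensemble"), is(mapping, "CoreMapping"))
  if (!structureId %in% names(mapping@map))
    stop("structure '", structureId, "' not present in the core mapping")
  m <- mapping@map[[structureId]]
  a <- e@atoms
  idx <- integer(nrow(m))
  for (i in seq_len(nrow(m))) {
    hit <- which(a$chain == m$chain[i] & a$resno == m$resno[i] &
                   a$name == "CA")
    if (length(hit) != 1)
      stop("missing Calpha for mapped residue ", m$chain[i], ":", m$resno[i],
           " (core position ", m$core[i], ") in structure '", structureId, "'")
    idx[i] <- hit
  }
  atoms <- a[idx, , drop = FALSE]
  atoms$resno <- m$core
  atoms$chain <- "A"
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  new("Ensemble", atoms = atoms, coords = e@coords[idx, , , drop = FALSE],
      stateLabel = e@stateLabel, replicaId = e@replicaId,
      source = paste0(e@source, " [core:", structureId, "]"))
}
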