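.edgeKey <- function(v1, v2) {
  a <- pmin(v1, v2); b <- pmax(v1, v2)
  paste(a, b, sep = "~")
}

#' Build deduplicated per-sample rearrangement graphs
#'
#' Cluster centers become vertices, identified by their genomic locus key
#' \code{"chrom:peak_pos"}; every adjacency contributes an edge between the
#' clusters holding its two breakends. Multiple adjacencies between one
#' cluster pair collapse to a single edge (provenance keeps the contributing
#' adjacency ids); adjacencies with both ends in one cluster would be
#' self-loops and are dropped with a count (the loop filter upstream should
#' already have removed them).
#'
#' @param svc an [SVClusters-class] from [twoStepClustering()].
#' @return a [SampleGraphSet-class].
#' @export
buildSampleGraphs <- function(svc) {
  cl <- clusters(svc)
  asg <- assignments(svc)
  adj <- adjacencies(svc)
  locus <- stats::setNames(
    paste0(cl$chrom, ":", format(cl$peak_pos, scientific = FALSE,
                                 trim = TRUE)),
    cl$cluster_id)
  vertices <- data.frame(
    sample = cl$sample, vertex = unname(locus[cl$cluster_id]),
    chrom = cl$chrom, peak_pos = cl$peak_pos,
    cluster_id = cl$cluster_id, n_members = cl$n_members,
    stringsAsFactors = FALSE)

  if (!nrow(adj)) {
    return(new("SampleGraphSet", vertices = vertices,
               edges = data.frame(sample = character(), v1 = character(),
                                  v2 = character(), key = character(),
                                  stringsAsFactors = FALSE),
               provenance = list(), droppedLoops = 0L))
  }
  clusterOf <- stats::setNames(asg$cluster_id, paste0(asg$adj_id, ":",
                                                      asg$end))
  ca <- clusterOf[paste0(adj$id, ":a")]
  cb <- clusterOf[paste0(adj$id, ":b")]
  if (any(is.na(ca)) || any(is.na(cb)))
    stop("every breakend must be assigned to a final cluster")
  va <- unname(locus[ca]); vb <- unname(locus[cb])
  loops <- va == vb
  if (any(loops))
    message(sum(loops), " self-loop adjacency(ies) dropped at graph build")
  keep <- !loops
  sample <- adj$sample[keep]
  key <- .edgeKey(va[keep], vb[keep])
  sk <- paste(sample, key, sep = "\r")
  firsts <- !duplicated(sk)
  edges <- data.frame(sample = sample[firsts],
                      v1 = pmin(va[keep], vb[keep])[firsts],
                      v2 = pmax(va[keep], vb[keep])[firsts],
                      key = key[firsts], stringsAsFactors = FALSE)
  provenance <- split(adj$id[keep], sk)
  names(provenance) <- sub("\r", " ", names(provenance), fixed = TRUE)
  new("SampleGraphSet", vertices = vertices, edges = edges,
      provenance = provenance, droppedLoops = sum(loops))
}

#' Canonical key of a simple cycle
#'
#' The key of a cycle is its sorted edge-key set, joined by \code{";"} — an
#' identifier invariant to rotation and reflection of the cycle and to edge
#' ordering. Two cycles share a key if and only if they have identical edge
#' sets. The input is validated to be one simple closed cycle (every vertex
#' of degree exactly 2, single connected component).
#'
#' @param v1,v2 endpoint vectors of the cycle's edges.
#' @return a character key.
#' @export
canonicalCycleKey <- function(v1, v2) {
  verts <- c(v1, v2)
  deg <- table(verts)
  if (any(deg != 2) || length(deg) != length(v1))
    stop("edge set is not a simple closed cycle")
  ## connectivity: walk from the first vertex
  nbr <- split(c(v2, v1), c(v1, v2))
  seen <- names(deg)[1]; frontier <- seen
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(nbr[frontier])), seen)
    seen <- c(seen, nxt); frontier <- nxt
  }
  if (length(seen) != length(deg))
    stop("edge set is not a single connected cycle")
  paste(sort(.edgeKey(v1, v2)), collapse = ";")
}

## Deterministic vertex iteration order: genomic (chrom, position) when ids
## are locus keys "chrom:pos", plain lexicographic otherwise.
.orderVertexIds <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)$", ids))
  if (all(lengths(m) == 3)) {
    chrom <- vapply(m, `[`, character(1), 2)
    pos <- as.numeric(vapply(m, `[`, character(1), 3))
    ids[order(chrom, pos)]
  } else {
    sort(ids)
  }
}

## DFS cycle enumeration on one graph given as an adjacency list of integer
## neighbor vectors. Cycles through vertices {s, ...} with s the smallest
## cycle vertex are found from start s, so per-start searches are independent
## and can be merged. Each cycle surfaces twice (both directions); callers
## deduplicate by canonical key.
.dfsCycles <- function(adjList, kMin, kMax) {
  found <- list()
  nV <- length(adjList)
  path <- integer(kMax)
  inPath <- logical(nV)
  recurse <- function(s, v, depth) {
    for (w in adjList[[v]]) {
      if (w == s && depth >= kMin) {
        found[[length(found) + 1L]] <<- path[seq_len(depth)]
      } else if (w > s && !inPath[w] && depth < kMax) {
        path[depth + 1L] <<- w
        inPath[w] <<- TRUE
        recurse(s, w, depth + 1L)
        inPath[w] <<- FALSE
      }
    }
  }
  for (s in seq_len(nV)) {
    path[1L] <- s
    inPath[s] <- TRUE
    recurse(s, s, 1L)
    inPath[s] <- FALSE
  }
  found
}

#' Enumerate simple closed cycles of size 3-6 in the sample graphs
#'
#' Depth-first path extension from every start vertex (vertices ordered by
#' chromosome and peak position): a path closes into a cycle occurrence when
#' its last vertex neighbors its first and the path holds between
#' \code{k_min} and \code{k_max} distinct vertices. Every vertex of a
#' reported cycle has degree exactly 2 within the cycle's edge set.
#' Occurrences are deduplicated by canonical edge-set key, so each distinct
#' cycle is reported exactly once per sample; a dense vertex set may
#' contribute several distinct cycles.
#'
#' @param graphs a [SampleGraphSet-class], or a plain edge data.frame with
#'   columns \code{sample}, \code{v1}, \code{v2} (e.g. a randomized edge list
#'   from [switchEdges()]).
#' @param k_min,k_max cycle size bounds (defaults 3 and 6).
#' @param samples optional character vector naming the full sample universe
#'   (defaults to the samples present in \code{graphs}).
#' @return a [CycleSet-class].
#' @export
enumerateCycles <- function(graphs, k_min = 3, k_max = 6, samples = NULL) {
  if (is(graphs, "SampleGraphSet")) {
    edges <- graphEdges(graphs)
    if (is.null(samples)) samples <- unique(graphVertices(graphs)$sample)
  } else {
    edges <- graphs
    if (is.null(samples)) samples <- unique(edges$sample)
  }
  allSamples <- sort(samples)
  occ <- list()
  for (s in allSamples) {
    es <- edges[edges$sample == s, , drop = FALSE]
    if (nrow(es) < k_min) next
    vid <- .orderVertexIds(unique(c(es$v1, es$v2)))
    i1 <- match(es$v1, vid); i2 <- match(es$v2, vid)
    adjList <- vector("list", length(vid))
    for (v in seq_along(vid)) adjList[[v]] <- integer(0)
    for (e in seq_along(i1)) {
      adjList[[i1[e]]] <- c(adjList[[i1[e]]], i2[e])
      adjList[[i2[e]]] <- c(adjList[[i2[e]]], i1[e])
    }
    adjList <- lapply(adjList, sort)
    cyc <- .dfsCycles(adjList, k_min, k_max)
    if (!length(cyc)) next
    keys <- character(length(cyc))
    rows <- vector("list", length(cyc))
    for (i in seq_along(cyc)) {
      vseq <- vid[cyc[[i]]]
      eKeys <- .edgeKey(vseq, c(vseq[-1], vseq[1]))
      keys[i] <- paste(sort(eKeys), collapse = ";")
      rows[[i]] <- data.frame(
        sample = s, size = length(vseq),
        vertices = paste(vseq, collapse = "|"),
        edges = paste(sort(eKeys), collapse = ";"),
        canonical_key = keys[i], stringsAsFactors = FALSE)
    }
    occ[[length(occ) + 1L]] <- do.call(rbind, rows[!duplicated(keys)])
  }
  occurrences <- if (length(occ)) do.call(rbind, occ) else
    data.frame(sample = character(), size = integer(),
               vertices = character(), edges = character(),
               canonical_key = character(), stringsAsFactors = FALSE)
  rownames(occurrences) <- NULL
  new("CycleSet", occurrences = occurrences, samples = allSamples)
}

#' Per-sample average of a pattern
#'
#' The reported "average" of a pattern is its total frequency divided by its
#' confidence (the number of samples carrying it), truncated toward zero at
#' two decimals for table reporting. A confidence of zero reports 0.
#'
#' @param frequency total occurrences across the dataset.
#' @param confidence number of samples with at least one occurrence.
#' @return the truncated average.
#' @examples
#' patternAverage(3817, 814)
#' @export
patternAverage <- function(frequency, confidence) {
  ifelse(confidence > 0, trunc(frequency / confidence * 100) / 100, 0)
}

#' Cohort statistics of the mined cycle patterns
#'
#' For every cycle size: confidence = number of samples with at least one
#' occurrence; frequency = total occurrences across the dataset; average =
#' frequency / confidence, reported truncated to two decimals.
#'
#' @param cycleSet a [CycleSet-class].
#' @param sizes sizes to report (default 3:6).
#' @return data.frame with columns \code{pattern}, \code{confidence},
#'   \code{average}, \code{frequency}, \code{no_occurrence} (flag for
#'   patterns never observed).
#' @export
patternStatistics <- function(cycleSet, sizes = 3:6) {
  occ <- cycles(cycleSet)
  rows <- lapply(sizes, function(k) {
    ok <- occ[occ$size == k, , drop = FALSE]
    conf <- length(unique(ok$sample))
    freq <- nrow(ok)
    data.frame(pattern = paste0("cycle_", k), size = k,
               confidence = conf,
               average = patternAverage(freq, conf),
               frequency = freq, no_occurrence = conf == 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
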