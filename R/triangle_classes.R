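#' Is a junction inverted?
#'
#' A junction is inverted when both of its breakends have the same
#' orientation (head-to-head or tail-to-tail); a deletion- or tandem-
#' duplication-like junction joins opposite orientations and is not
#' inverted.
#'
#' @param adj adjacency data.frame (columns \code{side1}, \code{side2}).
#' @return logical vector, one flag per adjacency.
#' @export
junctionInversionFlag <- function(adj) {
  if (any(is.na(adj$side1)) || any(is.na(adj$side2)) ||
      !all(c(adj$side1, adj$side2) %in% .SIDES))
    stop("both breakends of every junction must carry a valid side")
  adj$side1 == adj$side2
}

#' Copy-number state at a breakpoint cluster
#'
#' Compares the total copy number of the segment containing the cluster peak
#' against the median copy number of the other segments within
#' \code{window} bp: \code{gain} at a difference of at least
#' \code{+gain_threshold} copies, \code{loss} at \code{-loss_threshold} or
#' below, otherwise \code{neutral}. A peak not covered by any segment is
#' \code{neutral} with the \code{uncovered} flag set.
#'
#' @param sample,chrom,pos locus of the cluster peak.
#' @param seg copy-number segment data.frame (see [readCnSegments()]).
#' @param window flank half-width in bp (default 1e6).
#' @param gain_threshold,loss_threshold copy-difference thresholds
#'   (default 1 each).
#' @return list with \code{state} and \code{uncovered}.
#' @export
breakpointCnState <- function(sample, chrom, pos, seg, window = 1e6,
                              gain_threshold = 1, loss_threshold = 1) {
  sc <- seg[seg$sample == sample & seg$chrom == chrom, , drop = FALSE]
  cov <- which(sc$start <= pos & sc$end >= pos)
  if (!length(cov))
    return(list(state = "neutral", uncovered = TRUE))
  localCn <- sc$total_cn[cov[1]]
  flank <- which(sc$end >= pos - window & sc$start <= pos + window)
  flank <- setdiff(flank, cov[1])
  ref <- if (length(flank)) stats::median(sc$total_cn[flank]) else localCn
  d <- localCn - ref
  state <- if (d >= gain_threshold) "gain"
           else if (d <= -loss_threshold) "loss"
           else "neutral"
  list(state = state, uncovered = FALSE)
}

## Oscillation around a cycle: the states alternate between exactly two
## levels. Three conditions: (a) exactly two distinct states; (b) the cyclic
## arrangement is maximally alternating — the number of equal adjacent pairs
## (wrap included) is 0 for even k and the unavoidable 1 for odd k; (c) when
## one of the two states is neutral, the altered state carries the
## oscillation's peaks and must appear at least as often as neutral
## (copy number 3,2,3 oscillates; 3,2,2 is a lone gain, not an oscillation).
.isOscillating <- function(states) {
  k <- length(states)
  if (length(unique(states)) != 2) return(FALSE)
  nxt <- c(seq_len(k)[-1], 1L)
  if (sum(states == states[nxt]) != k %% 2) return(FALSE)
  if ("neutral" %in% states) {
    altered <- states[states != "neutral"]
    if (length(altered) < sum(states == "neutral")) return(FALSE)
  }
  TRUE
}

.labelTriangle <- function(nInverted, states, oscillating, hasCn) {
  if (!hasCn)
    return(if (nInverted >= 2) "chromotrikona" else "chromoplexy")
  anyGain <- any(states == "gain")
  allNeutral <- all(states == "neutral")
  if (nInverted >= 2) {
    if (oscillating) return("noncanonical_chromothripsis")
    if (anyGain) return("templated_insertion_cycle")
    if (allNeutral) return("chromotrikona")
    return("unclassified")
  }
  if (!anyGain) return("chromoplexy")
  "unclassified"
}

#' Subclassify size-3 cycles into the four triangle types
#'
#' Every triangle (size-3 cycle) is labeled from the orientations of its
#' three junctions and the copy-number states of its three breakpoint
#' clusters, with I = the number of inverted junctions:
#' \enumerate{
#'   \item I >= 2 with oscillating states: non-canonical chromothripsis
#'     (frequently inverted junctions, copy number oscillating between two
#'     levels around the cycle);
#'   \item I >= 2 with a gain state: templated-insertion cycle (inverted
#'     junctions with copy-number gain);
#'   \item I >= 2 with all states neutral: chromotrikona (frequent inverted
#'     junctions, no significant gain or loss of DNA);
#'   \item I <= 1 with no gain state: chromoplexy (balanced rearrangement
#'     chain, at most minimal loss);
#'   \item otherwise unclassified.
#' }
#' Without copy-number data the labels reduce to chromoplexy (I <= 1) versus
#' chromotrikona (I >= 2), flagged \code{no_cn}.
#'
#' @param cycleSet a [CycleSet-class]; only size-3 occurrences are used.
#' @param graphs the [SampleGraphSet-class] the cycles were mined from (edge
#'   provenance resolves each edge to a supporting adjacency).
#' @param adj adjacency data.frame carrying the junction orientations.
#' @param seg optional copy-number segment data.frame.
#' @param window,gain_threshold,loss_threshold see [breakpointCnState()].
#' @return data.frame with one row per triangle: \code{sample},
#'   \code{vertices}, \code{canonical_key}, \code{n_inverted},
#'   \code{cn_states}, \code{oscillating}, \code{label}, \code{no_cn},
#'   \code{uncovered}.
#' @export
classifyTriangles <- function(cycleSet, graphs, adj, seg = NULL,
                              window = 1e6, gain_threshold = 1,
                              loss_threshold = 1) {
  occ <- cycles(cycleSet)
  occ <- occ[occ$size == 3, , drop = FALSE]
  prov <- edgeProvenance(graphs)
  hasCn <- !is.null(seg) && nrow(seg) > 0
  inv <- stats::setNames(junctionInversionFlag(adj), adj$id)
  rows <- vector("list", nrow(occ))
  for (i in seq_len(nrow(occ))) {
    sampleId <- occ$sample[i]
    vseq <- strsplit(occ$vertices[i], "|", fixed = TRUE)[[1]]
    eKeys <- .edgeKey(vseq, c(vseq[-1], vseq[1]))
    adjIds <- vapply(eKeys, function(k) {
      p <- prov[[paste(sampleId, k)]]
      if (is.null(p)) NA_character_ else p[1]
    }, character(1))
    if (any(is.na(adjIds)))
      stop("missing edge provenance for a triangle edge")
    nInv <- sum(inv[adjIds])
    uncovered <- FALSE
    if (hasCn) {
      st <- character(3)
      for (v in seq_along(vseq)) {
        loc <- regmatches(vseq[v],
                          regexec("^(.+):([0-9]+)$", vseq[v]))[[1]]
        cn <- breakpointCnState(sampleId, loc[2], as.numeric(loc[3]), seg,
                                window, gain_threshold, loss_threshold)
        st[v] <- cn$state
        uncovered <- uncovered || cn$uncovered
      }
      osc <- .isOscillating(st)
    } else {
      st <- rep(NA_character_, 3)
      osc <- NA
    }
    rows[[i]] <- data.frame(
      sample = sampleId, vertices = occ$vertices[i],
      canonical_key = occ$canonical_key[i],
      n_inverted = nInv,
      cn_states = paste(st, collapse = "|"),
      oscillating = osc,
      label = .labelTriangle(nInv, st, isTRUE(osc), hasCn),
      no_cn = !hasCn, uncovered = uncovered,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample = character(), vertices = character(),
               canonical_key = character(), n_inverted = integer(),
               cn_states = character(), oscillating = logical(),
               label = character(), no_cn = logical(),
               uncovered = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cluster-sharing matrix between triangle types
#'
#' For every pair of triangle types, the number of breakpoint clusters
#' (sample + locus) that take part in at least one triangle of each type;
#' the diagonal counts the distinct clusters of each type. Symmetric by
#' construction.
#'
#' @param calls output of [classifyTriangles()].
#' @return 4x4 symmetric integer matrix over the triangle types.
#' @export
triangleOverlapMatrix <- function(calls) {
  sets <- lapply(.TRIANGLE_TYPES, function(ty) {
    tc <- calls[calls$label == ty, , drop = FALSE]
    if (!nrow(tc)) return(character())
    unique(unlist(lapply(seq_len(nrow(tc)), function(i)
      paste(tc$sample[i],
            strsplit(tc$vertices[i], "|", fixed = TRUE)[[1]]))))
  })
  names(sets) <- .TRIANGLE_TYPES
  m <- matrix(0L, 4, 4, dimnames = list(.TRIANGLE_TYPES, .TRIANGLE_TYPES))
  for (i in 1:4) for (j in 1:4)
    m[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  m
}

#' Per-cancer-type summary of triangle-type frequencies
#'
#' Restricted to cancer types with at least \code{min_samples}
#' triangle-bearing samples (samples holding at least one triangle of any
#' type). For each included cancer type and triangle type: the mean
#' per-sample triangle count over the type's triangle-bearing samples, with
#' a normal-approximation 95 percent confidence interval
#' (mean +/- 1.96 sd / sqrt(n)). Excluded cancer types are reported in the
#' \code{excluded} attribute.
#'
#' @param calls output of [classifyTriangles()].
#' @param cancer_map named character vector, sample id to cancer type; must
#'   cover every sample in \code{calls}.
#' @param min_samples inclusion threshold (default 10).
#' @return data.frame: \code{cancer_type}, \code{triangle_type},
#'   \code{mean_frequency}, \code{ci_halfwidth}, \code{n_samples}.
#' @export
triangleTypeCancerSummary <- function(calls, cancer_map, min_samples = 10) {
  if (!all(calls$sample %in% names(cancer_map)))
    stop("cancer_map must cover every sample with triangles")
  bearing <- unique(calls$sample)
  byType <- split(bearing, unname(cancer_map[bearing]))
  included <- names(byType)[lengths(byType) >= min_samples]
  excluded <- setdiff(names(byType), included)
  rows <- list()
  for (ct in included) {
    ss <- byType[[ct]]
    for (ty in .TRIANGLE_TYPES) {
      counts <- vapply(ss, function(s)
        sum(calls$sample == s & calls$label == ty), numeric(1))
      n <- length(counts)
      sdv <- if (n > 1) stats::sd(counts) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        cancer_type = ct, triangle_type = ty,
        mean_frequency = mean(counts),
        ci_halfwidth = 1.96 * sdv / sqrt(n),
        n_samples = n, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cancer_type = character(), triangle_type = character(),
               mean_frequency = numeric(), ci_halfwidth = numeric(),
               n_samples = integer(), stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}
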