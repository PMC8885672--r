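#' Clustering parameters for the two-step KDE scheme
#'
#' @param h1 Gaussian kernel bandwidth (bp) for the first, coarse clustering
#'   round. Default 1000.
#' @param h2 bandwidth (bp) for the second round run inside every surviving
#'   round-1 cluster. Default 400.
#' @param grid_step_factor density evaluation grid spacing as a fraction of
#'   the bandwidth. Default 0.1.
#' @param grid_pad half-width of the evaluation window around the data, in
#'   bandwidth units. Default 4 (beyond 4 standard deviations the kernel mass
#'   is negligible).
#' @return list of validated parameters.
#' @export
clusteringConfig <- function(h1 = 1000, h2 = 400, grid_step_factor = 0.1,
                             grid_pad = 4) {
  stopifnot(h1 > 0, h2 > 0,
            grid_step_factor > 0, grid_step_factor <= 0.5, grid_pad > 0)
  list(h1 = h1, h2 = h2, grid_step_factor = grid_step_factor,
       grid_pad = grid_pad)
}

## Evaluation grid: union of windows [x - pad*h, x + pad*h] around the data,
## merged where they overlap, sampled at step = grid_step_factor * h. Each
## merged window is a separate segment so peak finding never bridges gaps.
.kdeGrid <- function(positions, h, stepFactor = 0.1, pad = 4) {
  step <- stepFactor * h
  x <- sort(unique(positions))
  lo <- x - pad * h
  hi <- x + pad * h
  ## merge overlapping windows
  segLo <- lo[1]; segHi <- hi[1]
  grids <- list(); segs <- integer(0); s <- 0L
  flush <- function(a, b, s) {
    g <- seq(a, b, by = step)
    if (length(g) < 3) g <- seq(a, b, length.out = 3)
    g
  }
  for (i in seq_along(x)[-1]) {
    if (lo[i] <= segHi) segHi <- max(segHi, hi[i])
    else {
      s <- s + 1L
      g <- flush(segLo, segHi, s)
      grids[[s]] <- g; segs <- c(segs, rep(s, length(g)))
      segLo <- lo[i]; segHi <- hi[i]
    }
  }
  s <- s + 1L
  g <- flush(segLo, segHi, s)
  grids[[s]] <- g; segs <- c(segs, rep(s, length(g)))
  list(grid = unlist(grids), segment = segs)
}

#' Gaussian kernel density estimate at query points
#'
#' Evaluates the estimator
#' \deqn{\hat f(x) = \frac{1}{n h \sqrt{2\pi}} \sum_i
#'       \exp\!\left(-\frac{(x - x_i)^2}{2 h^2}\right)}
#' at the given query points.
#'
#' @param positions numeric vector of breakpoint coordinates (non-empty).
#' @param bandwidth kernel standard deviation in bp (> 0).
#' @param query_points coordinates at which to evaluate the density; if
#'   \code{NULL}, a grid covering the data plus \code{grid_pad} bandwidths,
#'   with spacing \code{grid_step_factor * bandwidth}, is built.
#' @param config see [clusteringConfig()] (grid parameters only).
#' @return data.frame with columns \code{grid} and \code{density}, attributes
#'   \code{bandwidth} and \code{segment} (grid window id, used by
#'   [findDensityPeaks()]).
#' @examples
#' p <- gaussianKdeDensity(0, 1, query_points = 0)
#' p$density  # 1/sqrt(2*pi)
#' @export
gaussianKdeDensity <- function(positions, bandwidth, query_points = NULL,
                               config = clusteringConfig()) {
  if (!length(positions)) stop("positions must be non-empty")
  stopifnot(bandwidth > 0)
  if (is.null(query_points)) {
    g <- .kdeGrid(positions, bandwidth, config$grid_step_factor,
                  config$grid_pad)
    query_points <- g$grid
    segment <- g$segment
  } else {
    segment <- rep(1L, length(query_points))
  }
  dens <- numeric(length(query_points))
  for (x in positions)
    dens <- dens + stats::dnorm(query_points, mean = x, sd = bandwidth)
  dens <- dens / length(positions)
  out <- data.frame(grid = query_points, density = dens)
  attr(out, "bandwidth") <- bandwidth
  attr(out, "segment") <- segment
  out
}

#' Locate density peaks (modes) on an evaluated profile
#'
#' Returns the coordinates of strict local maxima of the density over the
#' grid, in ascending order. Plateaus collapse to their leftmost grid point.
#' Disjoint grid windows are scanned independently.
#'
#' @param profile a density profile from [gaussianKdeDensity()].
#' @return numeric vector of peak coordinates.
#' @export
findDensityPeaks <- function(profile) {
  if (nrow(profile) < 3) stop("profile needs at least 3 grid points")
  segment <- attr(profile, "segment")
  if (is.null(segment)) segment <- rep(1L, nrow(profile))
  peaks <- numeric(0)
  for (s in unique(segment)) {
    idx <- which(segment == s)
    d <- profile$density[idx]
    r <- rle(d)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    nv <- length(r$values)
    leftN <- c(-Inf, r$values[-nv])
    rightN <- c(r$values[-1], -Inf)
    isPeak <- r$values > leftN & r$values > rightN
    peaks <- c(peaks, profile$grid[idx][starts[isPeak]])
  }
  sort(peaks)
}

#' Assign breakpoints to the nearest density peak
#'
#' Every position is assigned to the closest peak by absolute distance; ties
#' go to the lower-coordinate peak.
#'
#' @param positions numeric vector of breakpoint coordinates.
#' @param peaks ascending peak coordinates (non-empty).
#' @return integer vector of peak indices, one per position.
#' @export
assignBreakpoints <- function(positions, peaks) {
  if (!length(peaks)) stop("peak list must be non-empty")
  if (length(peaks) == 1L) return(rep(1L, length(positions)))
  peaks <- sort(peaks)
  mids <- (peaks[-1] + peaks[-length(peaks)]) / 2
  ## (a, b] intervals: a position exactly at a midpoint goes to the lower
  ## (left) peak
  findInterval(positions, mids, left.open = TRUE) + 1L
}

## Mode-hunting clustering of one position vector. Positions separated by
## more than the full window width (2 * pad * h) cannot interact through the
## kernel at any meaningful level, so the vector is cut at such gaps and
## each block is density-scanned on its own; peak assignment stays global.
## Returns the peak coordinates actually holding members (empty peaks
## dropped, indices remapped) and the per-position cluster index.
.modeCluster <- function(positions, bandwidth, config) {
  n <- length(positions)
  if (n == 1L)
    return(list(peaks = positions, assignment = 1L))
  ux <- sort(unique(positions))
  if (length(ux) == 1L)
    return(list(peaks = ux, assignment = rep(1L, n)))
  cut <- 2 * config$grid_pad * bandwidth
  block <- cumsum(c(1, diff(ux) > cut))
  peaks <- numeric(0)
  for (b in unique(block)) {
    bx <- ux[block == b]
    if (length(bx) == 1L) {
      peaks <- c(peaks, bx)
    } else {
      w <- positions[positions >= bx[1] & positions <= bx[length(bx)]]
      prof <- gaussianKdeDensity(w, bandwidth, config = config)
      bp <- findDensityPeaks(prof)
      if (!length(bp)) bp <- prof$grid[which.max(prof$density)]
      peaks <- c(peaks, bp)
    }
  }
  peaks <- sort(peaks)
  asg <- assignBreakpoints(positions, peaks)
  used <- sort(unique(asg))
  list(peaks = peaks[used], assignment = match(asg, used))
}

#' Cluster the breakpoints of one sample chromosome
#'
#' One round of KDE mode hunting: estimate the density, locate peaks, assign
#' every breakpoint to its nearest peak. Peaks left without members are
#' dropped. The clusters partition the input positions and their spans are
#' disjoint.
#'
#' @param positions breakpoint coordinates of one sample on one chromosome.
#' @param bandwidth kernel bandwidth in bp.
#' @param config see [clusteringConfig()].
#' @return data.frame with one row per cluster (\code{peak_pos},
#'   \code{n_members}, \code{span_lo}, \code{span_hi}) and attribute
#'   \code{assignment}: the cluster index of each input position.
#' @export
clusterChromosome <- function(positions, bandwidth,
                              config = clusteringConfig()) {
  if (!length(positions)) stop("positions must be non-empty")
  mc <- .modeCluster(positions, bandwidth, config)
  k <- length(mc$peaks)
  lo <- hi <- numeric(k); nm <- integer(k)
  for (j in seq_len(k)) {
    m <- positions[mc$assignment == j]
    lo[j] <- min(m); hi[j] <- max(m); nm[j] <- length(m)
  }
  out <- data.frame(peak_pos = mc$peaks, n_members = nm,
                    span_lo = lo, span_hi = hi)
  attr(out, "assignment") <- mc$assignment
  out
}

#' Discard adjacencies looping inside one round-1 cluster
#'
#' An adjacency is discarded if and only if both of its breakends were
#' assigned to the same round-1 cluster — junctions looping over one region
#' belong to already-described local complex events (e.g. chromothripsis) and
#' would only add noise to the second clustering round.
#'
#' @param adj adjacency data.frame.
#' @param cluster_of named character vector mapping breakend ids
#'   (\code{"<adj_id>:a"} / \code{":b"}) to round-1 cluster ids; every
#'   breakend of every adjacency must be present.
#' @return list with \code{kept} and \code{discarded} adjacency data.frames.
#' @export
filterIntraClusterAdjacencies <- function(adj, cluster_of) {
  if (!nrow(adj))
    return(list(kept = adj, discarded = adj))
  ca <- cluster_of[paste0(adj$id, ":a")]
  cb <- cluster_of[paste0(adj$id, ":b")]
  if (any(is.na(ca)) || any(is.na(cb)))
    stop("every breakend must be assigned to a round-1 cluster")
  loop <- ca == cb
  list(kept = adj[!loop, , drop = FALSE],
       discarded = adj[loop, , drop = FALSE])
}

#' Recursive two-step KDE clustering of an SV dataset
#'
#' Round 1 clusters the breakpoints of every sample chromosome at bandwidth
#' \code{h1}; adjacencies with both breakends in one round-1 cluster are
#' discarded; round 2 re-clusters the surviving breakpoints at bandwidth
#' \code{h2} independently inside each surviving round-1 cluster. Round-1
#' clusters are then discarded: the result holds round-2 clusters only, and
#' every surviving breakend belongs to exactly one of them.
#'
#' @param dataset an [SVDataset-class] (or an adjacency data.frame).
#' @param config see [clusteringConfig()].
#' @return An [SVClusters-class] object.
#' @export
twoStepClustering <- function(dataset, config = clusteringConfig()) {
  adj <- if (is(dataset, "SVDataset")) adjacencies(dataset) else dataset
  nAdj <- nrow(adj)
  be <- .breakendsFromAdjacencies(adj)
  emptyClusters <- data.frame(
    cluster_id = character(), sample = character(), chrom = character(),
    peak_pos = numeric(), n_members = integer(), round = integer(),
    span_lo = numeric(), span_hi = numeric(), stringsAsFactors = FALSE)
  emptyAsg <- data.frame(adj_id = character(), end = character(),
                         cluster_id = character(), stringsAsFactors = FALSE)
  if (!nAdj)
    return(new("SVClusters", clusters = emptyClusters,
               assignments = emptyAsg, adjacencies = adj,
               discarded = character(), params = config))

  ## round 1 at h1, per sample/chromosome
  r1 <- character(nrow(be))
  g1 <- split(seq_len(nrow(be)), paste(be$sample, be$chrom, sep = "\r"))
  for (key in names(g1)) {
    idx <- g1[[key]]
    mc <- .modeCluster(be$pos[idx], config$h1, config)
    r1[idx] <- paste0(key, "\r", mc$assignment)
  }

  ## loop filtering: both ends in the same round-1 cluster
  loop <- r1[seq_len(nAdj)] == r1[nAdj + seq_len(nAdj)]
  kept <- adj[!loop, , drop = FALSE]
  discarded <- adj$id[loop]

  keepBe <- c(which(!loop), nAdj + which(!loop))
  if (!length(keepBe))
    return(new("SVClusters", clusters = emptyClusters,
               assignments = emptyAsg, adjacencies = kept,
               discarded = discarded, params = config))

  ## round 2 at h2, independently inside each surviving round-1 cluster
  g2 <- split(keepBe, r1[keepBe])
  recs <- vector("list", length(g2))
  asgCluster <- character(nrow(be))
  for (j in seq_along(g2)) {
    idx <- g2[[j]]
    mc <- .modeCluster(be$pos[idx], config$h2, config)
    tag <- paste0(names(g2)[j], "\r", mc$assignment)  # provisional id
    asgCluster[idx] <- tag
    recs[[j]] <- data.frame(
      tmp_id = paste0(names(g2)[j], "\r", seq_along(mc$peaks)),
      sample = be$sample[idx[1]], chrom = be$chrom[idx[1]],
      peak_pos = mc$peaks, stringsAsFactors = FALSE)
  }
  cl <- do.call(rbind, recs)

  ## final ids: rank by peak position within sample/chromosome
  ord <- order(cl$sample, cl$chrom, cl$peak_pos)
  cl <- cl[ord, , drop = FALSE]
  grp <- paste(cl$sample, cl$chrom, sep = "\r")
  rank <- stats::ave(seq_len(nrow(cl)), grp, FUN = seq_along)
  cl$cluster_id <- paste(cl$sample, cl$chrom, rank, sep = "|")
  finalId <- stats::setNames(cl$cluster_id, cl$tmp_id)
  asgFinal <- finalId[asgCluster[keepBe]]

  mlo <- tapply(be$pos[keepBe], asgFinal, min)
  mhi <- tapply(be$pos[keepBe], asgFinal, max)
  mn <- tapply(be$pos[keepBe], asgFinal, length)
  clusters <- data.frame(
    cluster_id = cl$cluster_id, sample = cl$sample, chrom = cl$chrom,
    peak_pos = cl$peak_pos,
    n_members = as.integer(mn[cl$cluster_id]),
    round = 2L,
    span_lo = as.numeric(mlo[cl$cluster_id]),
    span_hi = as.numeric(mhi[cl$cluster_id]),
    stringsAsFactors = FALSE)
  rownames(clusters) <- NULL
  assignments <- data.frame(
    adj_id = be$adj_id[keepBe], end = be$end[keepBe],
    cluster_id = unname(asgFinal), stringsAsFactors = FALSE)
  new("SVClusters", clusters = clusters, assignments = assignments,
      adjacencies = kept, discarded = discarded, params = config)
}

#' Intra- and inter-cluster distances on one chromosome
#'
#' For the clusters of one sample chromosome, sorted by peak position:
#' the intra-cluster distance of a cluster is the largest distance between
#' two of its breakpoints (its span); the inter-cluster distance of two
#' adjacent clusters is the smallest distance between a breakpoint of one
#' and a breakpoint of the next.
#'
#' @param cl cluster data.frame (rows of [clusters()] for one sample and one
#'   chromosome, with \code{span_lo}/\code{span_hi}).
#' @return list with \code{intra} (per cluster) and \code{inter} (per
#'   adjacent pair) data.frames.
#' @export
clusterDistances <- function(cl) {
  if (length(unique(paste(cl$sample, cl$chrom))) > 1)
    stop("clusterDistances expects clusters of one sample chromosome")
  cl <- cl[order(cl$peak_pos), , drop = FALSE]
  intra <- data.frame(cluster_id = cl$cluster_id,
                      intra = cl$span_hi - cl$span_lo,
                      stringsAsFactors = FALSE)
  k <- nrow(cl)
  if (k > 1) {
    if (any(cl$span_lo[-1] <= cl$span_hi[-k]))
      stop("overlapping cluster spans violate the partition invariant")
    inter <- data.frame(left = cl$cluster_id[-k], right = cl$cluster_id[-1],
                        inter = cl$span_lo[-1] - cl$span_hi[-k],
                        stringsAsFactors = FALSE)
  } else {
    inter <- data.frame(left = character(), right = character(),
                        inter = numeric(), stringsAsFactors = FALSE)
  }
  list(intra = intra, inter = inter)
}

.totalDistances <- function(clusters) {
  totalIntra <- sum(clusters$span_hi - clusters$span_lo)
  totalInter <- 0
  for (idx in split(seq_len(nrow(clusters)),
                    paste(clusters$sample, clusters$chrom, sep = "\r"))) {
    if (length(idx) < 2) next
    cc <- clusters[idx, , drop = FALSE]
    cc <- cc[order(cc$peak_pos), , drop = FALSE]
    totalInter <- totalInter +
      sum(cc$span_lo[-1] - cc$span_hi[-nrow(cc)])
  }
  c(total_intra = totalIntra, total_inter = totalInter)
}

#' Sweep round-2 bandwidth values and total the distance diagnostics
#'
#' Runs the full two-step clustering once per candidate \code{h2} and sums
#' the intra-cluster and inter-cluster distances over every sample and
#' chromosome of the dataset. The preferred bandwidth keeps total intra low
#' while total inter stays high.
#'
#' @param dataset an [SVDataset-class].
#' @param h2_values numeric vector of candidate round-2 bandwidths (bp).
#' @param config base parameters; \code{h2} is overridden per sweep point.
#' @return data.frame with columns \code{h2}, \code{total_intra},
#'   \code{total_inter}.
#' @export
bandwidthSweep <- function(dataset, h2_values, config = clusteringConfig()) {
  stopifnot(length(h2_values) >= 1)
  rows <- lapply(h2_values, function(h2) {
    cfg <- config; cfg$h2 <- h2
    cl <- twoStepClustering(dataset, cfg)
    td <- .totalDistances(clusters(cl))
    data.frame(h2 = h2, total_intra = td[["total_intra"]],
               total_inter = td[["total_inter"]])
  })
  do.call(rbind, rows)
}
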