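#' Simulate a dataset by pooling and re-pairing breakpoints
#'
#' Null model for the clustering validation: all breakends of the dataset are
#' pooled (each keeps its chromosome and position, so the recurrent genomic
#' locations of SVs are preserved), randomly re-distributed to samples
#' preserving every sample's breakend count, and then paired uniformly at
#' random within each sample into new adjacencies. A sample left with an odd
#' number of breakends drops its last unpaired breakend with a warning.
#'
#' @param dataset an [SVDataset-class] or adjacency data.frame.
#' @return an adjacency data.frame of the simulated dataset (ids
#'   \code{sim_1, sim_2, ...}).
#' @export
simulateBreakpointDataset <- function(dataset) {
  adj <- if (is(dataset, "SVDataset")) adjacencies(dataset) else dataset
  if (!nrow(adj)) stop("dataset must be non-empty")
  be <- .breakendsFromAdjacencies(adj)
  n <- nrow(be)
  perm <- sample.int(n)            # breakend i gets slot perm^-1... reassign:
  newSample <- be$sample           # per-sample counts preserved by permuting
  be <- be[perm, , drop = FALSE]   # breakends over the fixed sample slots
  be$sample <- newSample
  out <- vector("list", 0)
  k <- 0L
  pieces <- list()
  for (idx in split(seq_len(n), be$sample)) {
    idx <- idx[sample.int(length(idx))]   # uniform pairing within sample
    if (length(idx) %% 2 == 1) {
      warning("sample ", be$sample[idx[1]],
              " has an odd breakend count; one breakend dropped")
      idx <- idx[-length(idx)]
    }
    if (!length(idx)) next
    a <- idx[seq(1, length(idx), by = 2)]
    b <- idx[seq(2, length(idx), by = 2)]
    pieces[[length(pieces) + 1L]] <- data.frame(
      id = paste0("sim_", k + seq_along(a)),
      sample = be$sample[a],
      chrom1 = be$chrom[a], pos1 = be$pos[a], side1 = be$side[a],
      chrom2 = be$chrom[b], pos2 = be$pos[b], side2 = be$side[b],
      stringsAsFactors = FALSE)
    k <- k + length(a)
  }
  .canonicalizeAdjacencies(do.call(rbind, pieces))
}

.popSd <- function(x) sqrt(mean((x - mean(x))^2))

#' Average breakpoint dispersion of a dataset
#'
#' For every sample chromosome carrying at least 3 breakpoints, the dispersion
#' is the population standard deviation (divisor n) of the base-pair gaps
#' between adjacent sorted breakpoints; the statistic is the unweighted mean
#' of these dispersions. Clustered breakpoints produce a few huge gaps among
#' many tiny ones and hence a larger gap SD than evenly spread breakpoints.
#'
#' @param dataset an [SVDataset-class] or adjacency data.frame.
#' @return the average dispersion (bp).
#' @export
dispersionStatistic <- function(dataset) {
  adj <- if (is(dataset, "SVDataset")) adjacencies(dataset) else dataset
  be <- .breakendsFromAdjacencies(adj)
  vals <- c()
  for (idx in split(seq_len(nrow(be)), paste(be$sample, be$chrom))) {
    if (length(idx) < 3) next
    gaps <- diff(sort(be$pos[idx]))
    vals <- c(vals, .popSd(gaps))
  }
  if (!length(vals))
    stop("no sample chromosome with >= 3 breakpoints")
  mean(vals)
}

#' Average cluster density
#'
#' The average number of breakpoints per final cluster: total cluster members
#' divided by the number of clusters.
#'
#' @param x an [SVClusters-class] or its cluster data.frame.
#' @return average members per cluster.
#' @export
clusterDensityStatistic <- function(x) {
  cl <- if (is(x, "SVClusters")) clusters(x) else x
  if (!nrow(cl)) stop("no clusters")
  sum(cl$n_members) / nrow(cl)
}

#' One-sample Z-test of an observed statistic against simulated values
#'
#' \code{z = (observed - mean(sim)) / sd(sim)} with the sample standard
#' deviation (divisor n-1); p-values from the standard normal.
#'
#' @param observed observed value of the statistic.
#' @param sim_values statistic evaluated on the simulated datasets (>= 2
#'   values).
#' @return data.frame with \code{observed}, \code{sim_mean}, \code{sim_sd},
#'   \code{z}, \code{p_two_sided}, \code{p_lower}, \code{p_upper},
#'   \code{degenerate}.
#' @export
oneSampleZTest <- function(observed, sim_values) {
  stopifnot(length(sim_values) >= 2)
  m <- mean(sim_values)
  s <- stats::sd(sim_values)
  if (s == 0) {
    return(data.frame(observed = observed, sim_mean = m, sim_sd = 0,
                      z = NA_real_, p_two_sided = NA_real_,
                      p_lower = NA_real_, p_upper = NA_real_,
                      degenerate = TRUE))
  }
  z <- (observed - m) / s
  data.frame(observed = observed, sim_mean = m, sim_sd = s, z = z,
             p_two_sided = 2 * stats::pnorm(-abs(z)),
             p_lower = stats::pnorm(z), p_upper = stats::pnorm(z,
                                                              lower.tail = FALSE),
             degenerate = FALSE)
}

#' Permutation validation of the clustering
#'
#' Generates \code{n_datasets} pooled-breakpoint simulations (see
#' [simulateBreakpointDataset()]) and compares the observed dataset against
#' them with one-sample Z-tests on two statistics: the average breakpoint
#' dispersion and the average cluster density (the latter requires running
#' the full two-step clustering on every simulated dataset).
#'
#' @param dataset an [SVDataset-class].
#' @param config clustering parameters, see [clusteringConfig()].
#' @param n_datasets number of simulated datasets (default 100).
#' @param seed optional integer seed for reproducibility.
#' @param statistics which statistics to test (default both).
#' @return data.frame with one row per statistic
#'   (\code{"dispersion"}, \code{"cluster_density"}) and the Z-test columns
#'   of [oneSampleZTest()].
#' @export
clusterPermutationTest <- function(dataset, config = clusteringConfig(),
                                   n_datasets = 100, seed = NULL,
                                   statistics = c("dispersion",
                                                  "cluster_density")) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  doDisp <- "dispersion" %in% statistics
  doDens <- "cluster_density" %in% statistics
  obsDisp <- if (doDisp) dispersionStatistic(dataset)
  obsDens <- if (doDens)
    clusterDensityStatistic(twoStepClustering(dataset, config))
  simDisp <- numeric(n_datasets)
  simDens <- numeric(n_datasets)
  for (i in seq_len(n_datasets)) {
    sim <- simulateBreakpointDataset(dataset)
    if (doDisp) simDisp[i] <- dispersionStatistic(sim)
    if (doDens)
      simDens[i] <- clusterDensityStatistic(twoStepClustering(sim, config))
  }
  res <- rbind(
    if (doDisp) cbind(statistic = "dispersion",
                      oneSampleZTest(obsDisp, simDisp)),
    if (doDens) cbind(statistic = "cluster_density",
                      oneSampleZTest(obsDens, simDens)))
  rownames(res) <- NULL
  res
}
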