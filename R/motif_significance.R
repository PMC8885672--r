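#' Parameters of the edge-switching null model
#'
#' @param n_datasets number of randomized datasets N (default 100).
#' @param multiplier switching moves per dataset as a multiple of E, the
#'   total edge count across all samples (default 100, i.e. 100 x E
#'   attempted switches).
#' @param epsilon pseudo-count (Laplace smoothing) of the Abundance ratio
#'   (default 1).
#' @param seed optional integer seed.
#' @return validated parameter list.
#' @export
switchingConfig <- function(n_datasets = 100, multiplier = 100, epsilon = 1,
                            seed = NULL) {
  stopifnot(n_datasets >= 1, multiplier >= 1, epsilon >= 0)
  list(n_datasets = n_datasets, multiplier = multiplier, epsilon = epsilon,
       seed = seed)
}

#' Degree-preserving randomization of the pooled edge list
#'
#' Repeatedly selects two random edges A-B and C-D from the pooled
#' cross-sample edge list and exchanges their ends to form A-D and C-B.
#' Every edge keeps its sample tag, so per-sample edge counts are preserved;
#' the pooled vertex degree multiset is preserved by construction. A move
#' that would create a self-loop, or a duplicate edge within either affected
#' sample's graph, is rejected — rejected moves still count toward
#' \code{n_switches}.
#'
#' @param edges data.frame with columns \code{sample}, \code{v1}, \code{v2}
#'   (an undirected simple edge per row within each sample).
#' @param n_switches number of attempted switching moves.
#' @return data.frame of the same shape with randomized edges; attribute
#'   \code{accepted} counts accepted moves.
#' @export
switchEdges <- function(edges, n_switches) {
  E <- nrow(edges)
  if (E < 2) {
    warning("fewer than 2 edges; nothing to switch")
    return(edges)
  }
  sampleLv <- unique(edges$sample)
  vertexLv <- unique(c(edges$v1, edges$v2))
  V <- length(vertexLv)
  s <- match(edges$sample, sampleLv)
  a0 <- match(edges$v1, vertexLv)
  b0 <- match(edges$v2, vertexLv)
  a <- pmin(a0, b0); b <- pmax(a0, b0)
  ## membership index of (sample, v_lo, v_hi); dense for O(1) lookups
  idx <- function(si, lo, hi) ((si - 1) * V + (lo - 1)) * V + hi
  seen <- new.env(hash = TRUE, size = 2L * E)
  dense <- length(sampleLv) * as.double(V)^2 <= 5e7
  if (dense) {
    seenVec <- logical(length(sampleLv) * V * V)
    seenVec[idx(s, a, b)] <- TRUE
    has <- function(k) seenVec[k]
    put <- function(k, val) seenVec[k] <<- val
  } else {
    for (e in seq_len(E)) assign(as.character(idx(s[e], a[e], b[e])),
                                 TRUE, envir = seen)
    has <- function(k) exists(as.character(k), envir = seen,
                              inherits = FALSE)
    put <- function(k, val) {
      k <- as.character(k)
      if (val) assign(k, TRUE, envir = seen) else rm(list = k, envir = seen)
    }
  }
  accepted <- 0L
  for (t in seq_len(n_switches)) {
    ij <- sample.int(E, 2L)
    i <- ij[1L]; j <- ij[2L]
    ## the move A-B, C-D -> A-D, C-B on the canonically stored endpoint
    ## order; the remaining pairing is reachable through two moves
    A <- a[i]; B <- b[i]
    C <- a[j]; D <- b[j]
    if (A == D || C == B) next                       # self-loop
    n1a <- if (A < D) A else D; n1b <- if (A < D) D else A
    n2a <- if (C < B) C else B; n2b <- if (C < B) B else C
    if (n1a == a[i] && n1b == b[i]) next             # no-op rewiring
    k1 <- idx(s[i], n1a, n1b)
    k2 <- idx(s[j], n2a, n2b)
    if (k1 == k2) next                               # identical new edges
    if (has(k1) || has(k2)) next                     # duplicate in a sample
    put(idx(s[i], a[i], b[i]), FALSE)
    put(idx(s[j], a[j], b[j]), FALSE)
    a[i] <- n1a; b[i] <- n1b
    a[j] <- n2a; b[j] <- n2b
    put(k1, TRUE)
    put(k2, TRUE)
    accepted <- accepted + 1L
  }
  v1 <- vertexLv[a]; v2 <- vertexLv[b]
  lo <- pmin(v1, v2); hi <- pmax(v1, v2)
  out <- data.frame(sample = sampleLv[s], v1 = lo, v2 = hi,
                    key = paste(lo, hi, sep = "~"),
                    stringsAsFactors = FALSE)
  attr(out, "accepted") <- accepted
  out
}

#' Ensemble of edge-switched randomized datasets
#'
#' Generates \code{n_datasets} randomized edge lists, each obtained
#' independently from the ORIGINAL edges by \code{multiplier * E} attempted
#' switches.
#'
#' @param graphs a [SampleGraphSet-class] or an edge data.frame.
#' @param config see [switchingConfig()].
#' @return list of randomized edge data.frames.
#' @export
randomizedEnsemble <- function(graphs, config = switchingConfig()) {
  edges <- if (is(graphs, "SampleGraphSet")) graphEdges(graphs) else graphs
  if (!is.null(config$seed)) set.seed(config$seed)
  E <- nrow(edges)
  lapply(seq_len(config$n_datasets),
         function(i) switchEdges(edges, config$multiplier * E))
}

#' Abundance of a pattern against a randomized ensemble
#'
#' \deqn{\Delta = \frac{f_{input} - \bar f_{random}}
#'                     {f_{input} + \bar f_{random} + \varepsilon}}
#' where \eqn{f_{input}} is the pattern frequency in the real data,
#' \eqn{\bar f_{random}} the mean frequency over the randomized datasets and
#' \eqn{\varepsilon \ge 0} a pseudo-count (Laplace smoothing) keeping the
#' ratio defined for rare patterns. \eqn{\Delta} ranges from -1
#' (underrepresented) to +1 (overrepresented); 0 means equal representation.
#'
#' @param f_input non-negative observed frequency.
#' @param f_random_values non-negative frequencies over the ensemble.
#' @param epsilon pseudo-count (default 1).
#' @return the Abundance value; \code{NA} (with a warning) only in the
#'   degenerate case \code{epsilon == 0} and both frequencies zero.
#' @export
abundance <- function(f_input, f_random_values, epsilon = 1) {
  stopifnot(f_input >= 0, all(f_random_values >= 0), epsilon >= 0)
  fbar <- mean(f_random_values)
  denom <- f_input + fbar + epsilon
  if (denom == 0) {
    warning("abundance undefined: epsilon = 0 and all frequencies zero")
    return(NA_real_)
  }
  (f_input - fbar) / denom
}

.cycleFrequencies <- function(cycleSet, sizes, sampleFilter = NULL) {
  occ <- cycles(cycleSet)
  if (!is.null(sampleFilter))
    occ <- occ[occ$sample %in% sampleFilter, , drop = FALSE]
  vapply(sizes, function(k) sum(occ$size == k), numeric(1))
}

#' Abundance report for cycle patterns
#'
#' Computes the Abundance of every cycle size (3-6 by default) by mining each
#' randomized edge list of the ensemble and comparing frequencies with the
#' real data, plus a single-edge control row: the null conserves per-sample
#' edge counts, so the frequency of the 1-edge pattern is identical in every
#' randomized dataset and its Abundance is exactly 0. With
#' \code{cancer_type} set, frequencies are restricted to that type's samples
#' (the globally randomized ensemble is restricted the same way).
#'
#' @param realCycles a [CycleSet-class] mined from the real graphs.
#' @param graphs the real [SampleGraphSet-class] (for edge counts).
#' @param ensemble list of randomized edge data.frames from
#'   [randomizedEnsemble()].
#' @param sizes cycle sizes to report (default 3:6).
#' @param epsilon Abundance pseudo-count (default 1).
#' @param cancer_type optional cancer-type label to restrict to.
#' @param cancer_map named character vector sample -> cancer type (required
#'   when \code{cancer_type} is given).
#' @return data.frame: \code{pattern}, \code{f_input}, \code{f_random_mean},
#'   \code{delta}, \code{n_datasets}, \code{epsilon}.
#' @export
motifAbundanceReport <- function(realCycles, graphs, ensemble, sizes = 3:6,
                                 epsilon = 1, cancer_type = NULL,
                                 cancer_map = NULL) {
  edges <- graphEdges(graphs)
  sampleFilter <- NULL
  if (!is.null(cancer_type)) {
    if (is.null(cancer_map))
      stop("cancer_map is required when cancer_type is given")
    sampleFilter <- names(cancer_map)[cancer_map == cancer_type]
    if (!length(sampleFilter)) {
      warning("no samples for cancer type '", cancer_type, "'; skipped")
      return(NULL)
    }
  }
  countEdges <- function(e) {
    if (is.null(sampleFilter)) nrow(e)
    else sum(e$sample %in% sampleFilter)
  }
  fIn <- .cycleFrequencies(realCycles, sizes, sampleFilter)
  fRand <- matrix(0, nrow = length(ensemble), ncol = length(sizes))
  eRand <- numeric(length(ensemble))
  for (i in seq_along(ensemble)) {
    cs <- enumerateCycles(ensemble[[i]], k_min = min(sizes),
                          k_max = max(sizes))
    fRand[i, ] <- .cycleFrequencies(cs, sizes, sampleFilter)
    eRand[i] <- countEdges(ensemble[[i]])
  }
  rows <- data.frame(
    pattern = c("edge", paste0("cycle_", sizes)),
    f_input = c(countEdges(edges), fIn),
    f_random_mean = c(mean(eRand), colMeans(fRand)),
    stringsAsFactors = FALSE)
  rows$delta <- vapply(seq_len(nrow(rows)), function(r) {
    fr <- if (r == 1) eRand else fRand[, r - 1]
    abundance(rows$f_input[r], fr, epsilon)
  }, numeric(1))
  rows$n_datasets <- length(ensemble)
  rows$epsilon <- epsilon
  rows
}
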