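## Shared fixtures and independent oracles for the test suite. Everything is
## generated in code; no data files.

makeAdj <- function(id, sample, chrom1, pos1, side1, chrom2, pos2, side2) {
  data.frame(id = id, sample = sample,
             chrom1 = chrom1, pos1 = pos1, side1 = side1,
             chrom2 = chrom2, pos2 = pos2, side2 = side2,
             stringsAsFactors = FALSE)
}

## Adjacencies whose breakends sit exactly at the given positions of one
## sample, paired consecutively (helper to realize a target breakpoint
## multiset).
adjFromPositions <- function(positions, chrom = "chr1", sample = "s1",
                             prefix = "a") {
  stopifnot(length(positions) %% 2 == 0)
  n <- length(positions) / 2
  makeAdj(paste0(prefix, seq_len(n)), sample,
          chrom, positions[2 * seq_len(n) - 1], "extends_right",
          chrom, positions[2 * seq_len(n)], "extends_left")
}

## Erdos-Renyi edge list over n vertices named V01..Vnn for one sample.
erEdges <- function(n, p, sample = "s1") {
  v <- sprintf("V%02d", seq_len(n))
  pairs <- t(utils::combn(n, 2))
  keep <- which(stats::runif(nrow(pairs)) < p)
  data.frame(sample = rep(sample, length(keep)),
             v1 = v[pairs[keep, 1]],
             v2 = v[pairs[keep, 2]], stringsAsFactors = FALSE)
}

adjacencyMatrixOf <- function(edges) {
  v <- sort(unique(c(edges$v1, edges$v2)))
  A <- matrix(0, length(v), length(v), dimnames = list(v, v))
  A[cbind(edges$v1, edges$v2)] <- 1
  A[cbind(edges$v2, edges$v1)] <- 1
  A
}

.permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in .permutations(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], p)
  out
}

## Independent brute-force oracle: every simple cycle of size k in [kMin,
## kMax], enumerated as vertex subsets x cyclic orders (first vertex fixed,
## reflections removed), checked against the adjacency matrix. Returns the
## set of canonical edge-set keys per size.
bruteForceCycles <- function(edges, kMin = 3, kMax = 6) {
  A <- adjacencyMatrixOf(edges)
  v <- rownames(A)
  res <- stats::setNames(vector("list", kMax - kMin + 1),
                         as.character(kMin:kMax))
  for (k in kMin:kMax) {
    keys <- character(0)
    if (length(v) >= k) {
      subsets <- utils::combn(length(v), k, simplify = FALSE)
      for (sub in subsets) {
        rest <- sub[-1]
        for (p in .permutations(rest)) {
          if (length(p) > 1 && p[1] > p[length(p)]) next  # reflection
          seq <- c(sub[1], p)
          nxt <- c(seq[-1], seq[1])
          if (all(A[cbind(seq, nxt)] == 1)) {
            ek <- sort(paste(pmin(v[seq], v[nxt]), pmax(v[seq], v[nxt]),
                             sep = "~"))
            keys <- c(keys, paste(ek, collapse = ";"))
          }
        }
      }
    }
    res[[as.character(k)]] <- unique(keys)
  }
  res
}

## Small, fast synthetic dataset for plumbing tests.
smallSimConfig <- function(seed = 5, n_samples = 8, n_triangles = 4,
                           background_rate = 3) {
  simulationConfig(n_samples = n_samples,
                   background_rate = background_rate,
                   planted = defaultPlantedCycles(n_triangles, n_samples),
                   seed = seed)
}
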