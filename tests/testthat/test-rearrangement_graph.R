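## builds an SVClusters-like input via the real pipeline on exact positions
.graphFixture <- function() {
  ## three samples of adjacencies between far-apart loci at exact positions
  adj <- rbind(
    ## s1: 3 parallel junctions between the same two loci + a triangle
    makeAdj(paste0("par", 1:3), "s1", "chr1", c(1e5, 1e5 + 10, 1e5 - 10),
            "extends_right", "chr2", c(5e5, 5e5 + 5, 5e5 - 5),
            "extends_left"),
    makeAdj("t1", "s1", "chr1", 3e5, "extends_right", "chr2", 5e5 + 2,
            "extends_left"),
    makeAdj("t2", "s1", "chr1", 3e5 + 4, "extends_right", "chr1", 1e5 + 4,
            "extends_left"))
  SVDataset(adj, genome = c(chr1 = 1e6, chr2 = 1e6))
}

test_that("parallel junctions deduplicate into one graph edge", {
  g <- buildSampleGraphs(twoStepClustering(.graphFixture()))
  e <- graphEdges(g)
  expect_equal(nrow(e), 3)  # par* collapse; t1, t2 distinct
  prov <- edgeProvenance(g)
  parEdge <- prov[[which.max(lengths(prov))]]
  expect_setequal(parEdge, paste0("par", 1:3))
  ## graph keeps isolated vertices when a sample has no kept adjacencies
  expect_true(all(c("v1", "v2") %in% names(e)))
})

test_that("cycle enumeration matches hand counts on canonical graphs", {
  k3 <- data.frame(sample = "s", v1 = c("A", "B", "A"),
                   v2 = c("B", "C", "C"), stringsAsFactors = FALSE)
  cs <- enumerateCycles(k3)
  expect_equal(nrow(cycles(cs)), 1)
  expect_equal(cycles(cs)$size, 3)

  ## K4: choose(4,3) = 4 triangles and (4-1)!/2 = 3 Hamiltonian 4-cycles
  p <- t(utils::combn(LETTERS[1:4], 2))
  k4 <- data.frame(sample = "s", v1 = p[, 1], v2 = p[, 2],
                   stringsAsFactors = FALSE)
  tab <- table(cycles(enumerateCycles(k4))$size)
  expect_equal(as.integer(tab[c("3", "4")]), c(4, 3))

  ## 6-ring: exactly one cycle, of size 6
  ring <- data.frame(sample = "s", v1 = LETTERS[1:6],
                     v2 = LETTERS[c(2:6, 1)], stringsAsFactors = FALSE)
  cs6 <- enumerateCycles(ring)
  expect_equal(cycles(cs6)$size, 6)
})

test_that("cycle counts equal the brute-force subset oracle", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(5:10, 1)
    e <- erEdges(n, runif(1, 0.25, 0.6))
    if (nrow(e) < 3) next
    mined <- cycles(enumerateCycles(e))
    oracle <- bruteForceCycles(e)
    for (k in 3:6) {
      keys <- mined$edges[mined$size == k]
      expect_setequal(keys, oracle[[as.character(k)]])
    }
    ## triangle identity: count == trace(A^3) / 6
    A <- adjacencyMatrixOf(e)
    expect_equal(sum(mined$size == 3),
                 sum(diag(A %*% A %*% A)) / 6)
  }
})

test_that("mining is idempotent and per-sample independent", {
  set.seed(55)
  e1 <- erEdges(8, 0.5, sample = "sA")
  e2 <- e1; e2$sample <- "sB"
  both <- rbind(e1, e2)
  cs <- enumerateCycles(both)
  occ <- cycles(cs)
  ## the same graph under two sample ids yields identical per-sample sets
  expect_equal(sort(occ$canonical_key[occ$sample == "sA"]),
               sort(occ$canonical_key[occ$sample == "sB"]))
  ## idempotence
  expect_identical(cycles(enumerateCycles(both)), occ)
  ## no duplicate occurrences within a sample
  expect_equal(anyDuplicated(paste(occ$sample, occ$canonical_key)), 0)
})

test_that("canonical keys are rotation/reflection invariant", {
  orders <- list(c("A", "B", "C"), c("B", "C", "A"), c("C", "B", "A"))
  keys <- vapply(orders, function(o)
    canonicalCycleKey(o, c(o[-1], o[1])), character(1))
  expect_equal(length(unique(keys)), 1)
  expect_false(canonicalCycleKey(c("A", "B", "C"), c("B", "C", "A")) ==
               canonicalCycleKey(c("A", "B", "D"), c("B", "D", "A")))
  ## a path is not a cycle
  expect_error(canonicalCycleKey(c("A", "B"), c("B", "C")), "cycle")
  ## two disjoint triangles are not a single cycle
  expect_error(canonicalCycleKey(c("A", "B", "C", "X", "Y", "Z"),
                                 c("B", "C", "A", "Y", "Z", "X")),
               "connected")
})

test_that("pattern statistics count confidence, frequency and average", {
  e <- rbind(
    data.frame(sample = "s1", v1 = c("A", "B", "A"), v2 = c("B", "C", "C")),
    data.frame(sample = "s2", v1 = c("A", "B", "A"), v2 = c("B", "C", "C")))
  cs <- enumerateCycles(e, samples = c("s1", "s2", "s3"))
  st <- patternStatistics(cs)
  tri <- st[st$size == 3, ]
  expect_equal(tri$confidence, 2)
  expect_equal(tri$frequency, 2)
  expect_equal(tri$average, 1.0)
  ## absent sizes are flagged, average 0
  expect_true(all(st$no_occurrence[st$size > 3]))
  expect_true(all(st$average[st$size > 3] == 0))
})
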