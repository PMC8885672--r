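test_that("Gaussian KDE matches its closed form and normalizes", {
  ## single point: density at the point is the kernel maximum 1/(h sqrt(2pi))
  for (h in c(1, 400, 1000)) {
    p <- gaussianKdeDensity(0, h, query_points = 0)
    expect_equal(p$density, 1 / (h * sqrt(2 * pi)))
  }
  ## symmetry of a symmetric configuration
  grid <- seq(-10, 10, by = 0.05)
  p <- gaussianKdeDensity(c(-5, 5), 1, query_points = grid)
  expect_equal(p$density, rev(p$density))
  ## unit mass over the padded evaluation window
  set.seed(1)
  x <- rnorm(40, 1000, 30)
  prof <- gaussianKdeDensity(x, 25)
  step <- diff(prof$grid[1:2])
  expect_equal(sum(prof$density) * step, 1, tolerance = 1e-3)
})

test_that("peak finding reports strict local maxima, leftmost on plateaus", {
  p <- gaussianKdeDensity(c(100, 105, 110), 20)
  expect_length(findDensityPeaks(p), 1)
  ## two equal-weight points: modes merge below the critical separation 2h
  p2 <- gaussianKdeDensity(c(0, 10), 1)
  expect_length(findDensityPeaks(p2), 2)
  p1 <- gaussianKdeDensity(c(0, 0.5), 1)
  expect_length(findDensityPeaks(p1), 1)
  ## plateau collapses to its leftmost grid point
  prof <- data.frame(grid = 1:7, density = c(0, 1, 2, 2, 2, 1, 0))
  attr(prof, "segment") <- rep(1L, 7)
  expect_equal(findDensityPeaks(prof), 3)
  ## flat-zero tails yield no peaks
  prof2 <- data.frame(grid = 1:9, density = c(0, 0, 0, 1, 3, 1, 0, 0, 0))
  attr(prof2, "segment") <- rep(1L, 9)
  expect_equal(findDensityPeaks(prof2), 5)
})

test_that("breakpoints map to the nearest peak, ties to the lower one", {
  expect_equal(assignBreakpoints(200, c(100, 900)), 1L)
  expect_equal(assignBreakpoints(200, c(100, 300)), 1L)  # tie-break
  expect_equal(assignBreakpoints(c(5, 50, 500), 42), rep(1L, 3))
  expect_error(assignBreakpoints(5, numeric(0)), "non-empty")
})

test_that("chromosome clustering recovers well-separated groups exactly", {
  set.seed(7)
  centers <- c(2e5, 3e5)
  pos <- c(centers[1] + sample(-100:100, 12),
           centers[2] + sample(-100:100, 9))
  cl <- clusterChromosome(pos, 1000)
  expect_equal(nrow(cl), 2)
  ## brute-force nearest-group oracle
  expect_equal(attr(cl, "assignment"),
               apply(abs(outer(pos, centers, "-")), 1, which.min))
  expect_equal(cl$n_members, c(12, 9))
  ## peak lies inside (or within a grid step of) the member span
  step <- 0.1 * 1000
  expect_true(all(cl$peak_pos >= cl$span_lo - step &
                  cl$peak_pos <= cl$span_hi + step))
})

test_that("degenerate inputs: singleton and identical positions", {
  cl <- clusterChromosome(12345, 400)
  expect_equal(cl$peak_pos, 12345)
  cl2 <- clusterChromosome(rep(777, 5), 400)
  expect_equal(nrow(cl2), 1)
  expect_equal(cl2$peak_pos, 777)
  expect_equal(cl2$n_members, 5)
})

test_that("loop filtering removes exactly the within-cluster adjacencies", {
  adj <- rbind(
    makeAdj("loop", "s1", "chr1", 1000, "extends_right",
            "chr1", 1200, "extends_left"),
    makeAdj("far", "s1", "chr1", 1100, "extends_right",
            "chr1", 9e5, "extends_left"),
    makeAdj("inter", "s1", "chr1", 1050, "extends_right",
            "chr2", 5e5, "extends_left"))
  cluster_of <- c("loop:a" = "c1", "loop:b" = "c1",
                  "far:a" = "c1", "far:b" = "c2",
                  "inter:a" = "c1", "inter:b" = "c3")
  fl <- filterIntraClusterAdjacencies(adj, cluster_of)
  expect_equal(fl$discarded$id, "loop")
  expect_setequal(fl$kept$id, c("far", "inter"))
  expect_error(filterIntraClusterAdjacencies(adj, cluster_of[-1]),
               "assigned")
  empty <- adj[0, ]
  fl0 <- filterIntraClusterAdjacencies(empty, character(0))
  expect_equal(nrow(fl0$kept), 0)
  expect_equal(nrow(fl0$discarded), 0)
})

test_that("two-step clustering splits round-1 clusters at h2 resolution", {
  ## two sub-groups 3 kb apart merge at h1 = 1000 into neighbouring round-1
  ## structure but must be split by the h2 = 400 round
  set.seed(21)
  subA <- 5e5 + sample(-80:80, 6)
  subB <- 5e5 + 3000 + sample(-80:80, 6)
  pos <- c(subA, subB)
  ## partner breakends far away on another chromosome
  adj <- makeAdj(paste0("j", 1:12), "s1", "chr1", pos, "extends_right",
                 "chr2", seq(1e5, by = 2e5, length.out = 12),
                 "extends_left")
  svc <- twoStepClustering(SVDataset(adj,
                                     genome = c(chr1 = 1e6, chr2 = 1e7)))
  cl1 <- clusters(svc)
  chr1cl <- cl1[cl1$chrom == "chr1", ]
  expect_equal(nrow(chr1cl), 2)
  expect_equal(sort(chr1cl$n_members), c(6, 6))
  ## partition: every surviving breakend in exactly one final cluster
  asg <- assignments(svc)
  expect_equal(nrow(asg), 2 * nrow(adjacencies(svc)))
  expect_equal(anyDuplicated(paste(asg$adj_id, asg$end)), 0)
})

test_that("a dataset of only intra-cluster loops filters to nothing", {
  adj <- makeAdj(paste0("l", 1:3), "s1", "chr1", c(1000, 1100, 1200),
                 "extends_right", "chr1", c(1300, 1250, 1390),
                 "extends_left")
  svc <- twoStepClustering(SVDataset(adj, genome = c(chr1 = 1e6)))
  expect_equal(length(svc@discarded), 3)
  expect_equal(nrow(clusters(svc)), 0)
  expect_equal(nrow(adjacencies(svc)), 0)
})

test_that("mode count is non-increasing in bandwidth", {
  set.seed(13)
  for (rep in 1:6) {
    pos <- sort(sample.int(2e5, 30))
    nModes <- vapply(c(50, 100, 200, 400, 1000, 4000, 16000),
                     function(h) nrow(clusterChromosome(pos, h)),
                     numeric(1))
    expect_true(all(diff(nModes) <= 0))
  }
  ## tiny bandwidth limit: one cluster per distinct coordinate
  pos <- c(100, 5000, 20000, 20000)
  expect_equal(nrow(clusterChromosome(pos, 5)), 3)
})

test_that("cluster distance diagnostics follow their definitions", {
  cl <- data.frame(cluster_id = c("a", "b"), sample = "s1", chrom = "chr1",
                   peak_pos = c(50, 550), n_members = c(3L, 2L),
                   round = 2L, span_lo = c(10, 500), span_hi = c(100, 600))
  d <- clusterDistances(cl)
  expect_equal(d$intra$intra, c(90, 100))
  expect_equal(d$inter$inter, 400)
  ## singleton cluster has zero intra distance
  cl1 <- cl[1, ]; cl1$span_lo <- cl1$span_hi <- 42
  expect_equal(clusterDistances(cl1)$intra$intra, 0)
  ## overlapping spans violate the partition invariant
  clBad <- cl; clBad$span_lo[2] <- 90
  expect_error(clusterDistances(clBad), "overlap")
})

test_that("bandwidth sweep totals respond monotonically on fixed data", {
  gen <- generateDataset(smallSimConfig(seed = 19))
  sw <- bandwidthSweep(gen$dataset, c(100, 400, 1600, 6400))
  expect_equal(nrow(sw), 4)
  expect_true(all(diff(sw$total_intra) >= 0))
  sw1 <- bandwidthSweep(gen$dataset, 400)
  expect_equal(nrow(sw1), 1)
  expect_equal(sw1$total_intra, sw$total_intra[2])
})
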