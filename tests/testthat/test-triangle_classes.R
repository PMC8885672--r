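.segRow <- function(sample, chrom, start, end, cn) {
  data.frame(sample = sample, chrom = chrom, start = start, end = end,
             total_cn = cn, stringsAsFactors = FALSE)
}

test_that("junction inversion means both breakends share a side", {
  adj <- makeAdj(c("del", "hh", "tt"), "s1", "chr1", c(1, 2, 3),
                 c("extends_right", "extends_right", "extends_left"),
                 "chr2", c(9, 8, 7),
                 c("extends_left", "extends_right", "extends_left"))
  expect_equal(junctionInversionFlag(adj), c(FALSE, TRUE, TRUE))
  bad <- adj; bad$side2[1] <- NA
  expect_error(junctionInversionFlag(bad), "side")
})

test_that("copy-number state compares local segment against flank median", {
  seg <- rbind(.segRow("s1", "chr1", 1, 9e5, 2),
               .segRow("s1", "chr1", 9e5 + 1, 11e5, 3),
               .segRow("s1", "chr1", 11e5 + 1, 5e6, 2))
  expect_equal(breakpointCnState("s1", "chr1", 1e6, seg)$state, "gain")
  segLoss <- seg; segLoss$total_cn[2] <- 1
  expect_equal(breakpointCnState("s1", "chr1", 1e6, segLoss)$state, "loss")
  segFlat <- seg; segFlat$total_cn[2] <- 2
  expect_equal(breakpointCnState("s1", "chr1", 1e6, segFlat)$state,
               "neutral")
  ## sub-threshold change is neutral
  segHalf <- seg; segHalf$total_cn[2] <- 2.5
  expect_equal(breakpointCnState("s1", "chr1", 1e6, segHalf)$state,
               "neutral")
  ## no covering segment: neutral + uncovered flag
  st <- breakpointCnState("s1", "chr2", 100, seg)
  expect_equal(st$state, "neutral")
  expect_true(st$uncovered)
})

## classify a single constructed triangle with chosen inversions/CN states
.classifyOne <- function(inverted, states) {
  loci <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                     pos = c(1e6, 5e6, 3e6))
  sides <- lapply(inverted, function(i)
    if (i) c("extends_right", "extends_right")
    else c("extends_right", "extends_left"))
  nxt <- c(2, 3, 1)
  adj <- do.call(rbind, lapply(1:3, function(j)
    makeAdj(paste0("j", j), "s1",
            loci$chrom[j], loci$pos[j], sides[[j]][1],
            loci$chrom[nxt[j]], loci$pos[nxt[j]], sides[[j]][2])))
  d <- SVDataset(adj, genome = c(chr1 = 1e7, chr2 = 1e7))
  svc <- twoStepClustering(d)
  g <- buildSampleGraphs(svc)
  cs <- enumerateCycles(g)
  stopifnot(nrow(cycles(cs)) == 1)
  cnOf <- c(gain = 3, neutral = 2, loss = 1)
  seg <- do.call(rbind, lapply(1:3, function(v)
    .segRow("s1", loci$chrom[v], loci$pos[v] - 5e4, loci$pos[v] + 5e4,
            cnOf[[states[v]]])))
  base <- rbind(.segRow("s1", "chr1", 1, 1e6 - 5e4 - 1, 2),
                .segRow("s1", "chr1", 1e6 + 5e4 + 1, 5e6 - 5e4 - 1, 2),
                .segRow("s1", "chr1", 5e6 + 5e4 + 1, 1e7, 2),
                .segRow("s1", "chr2", 1, 3e6 - 5e4 - 1, 2),
                .segRow("s1", "chr2", 3e6 + 5e4 + 1, 1e7, 2))
  classifyTriangles(cs, g, adjacencies(svc), rbind(seg, base))
}

test_that("triangle decision rules reproduce the four classes", {
  ## balanced chain, no inversion, no gain: chromoplexy
  expect_equal(.classifyOne(c(FALSE, FALSE, FALSE),
                            c("neutral", "neutral", "neutral"))$label,
               "chromoplexy")
  ## minimal loss still allowed in chromoplexy
  expect_equal(.classifyOne(c(TRUE, FALSE, FALSE),
                            c("loss", "neutral", "neutral"))$label,
               "chromoplexy")
  ## inverted with uniform gain: templated-insertion cycle
  expect_equal(.classifyOne(c(TRUE, TRUE, FALSE),
                            c("gain", "gain", "gain"))$label,
               "templated_insertion_cycle")
  ## inverted with a lone gain: still templated insertion, not oscillation
  expect_equal(.classifyOne(c(TRUE, TRUE, FALSE),
                            c("gain", "neutral", "neutral"))$label,
               "templated_insertion_cycle")
  ## inverted with copy number alternating 2-3-2: chromothripsis-like
  call <- .classifyOne(c(TRUE, TRUE, FALSE),
                       c("gain", "neutral", "gain"))
  expect_true(call$oscillating)
  expect_equal(call$label, "noncanonical_chromothripsis")
  ## fully inverted, all neutral: chromotrikona
  expect_equal(.classifyOne(c(TRUE, TRUE, TRUE),
                            c("neutral", "neutral", "neutral"))$label,
               "chromotrikona")
  ## leftover combination: unclassified
  expect_equal(.classifyOne(c(FALSE, FALSE, FALSE),
                            c("gain", "gain", "gain"))$label,
               "unclassified")
})

test_that("classification is invariant to junction order", {
  perms <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
  labels <- vapply(perms, function(p) {
    inv <- c(TRUE, TRUE, FALSE)[p]
    st <- c("gain", "neutral", "gain")
    .classifyOne(inv, st)$label
  }, character(1))
  expect_equal(length(unique(labels)), 1)
})

test_that("without CN data labels reduce to the orientation dichotomy", {
  loci <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                     pos = c(1e6, 5e6, 3e6))
  adj <- do.call(rbind, lapply(1:3, function(j)
    makeAdj(paste0("j", j), "s1", loci$chrom[j], loci$pos[j],
            "extends_right", loci$chrom[c(2, 3, 1)[j]],
            loci$pos[c(2, 3, 1)[j]], "extends_right")))
  d <- SVDataset(adj, genome = c(chr1 = 1e7, chr2 = 1e7))
  svc <- twoStepClustering(d)
  g <- buildSampleGraphs(svc)
  calls <- classifyTriangles(enumerateCycles(g), g, adjacencies(svc),
                             seg = NULL)
  expect_equal(calls$label, "chromotrikona")  # I = 3
  expect_true(calls$no_cn)
})

test_that("overlap matrix counts shared clusters symmetrically", {
  calls <- data.frame(
    sample = c("s1", "s1", "s2"),
    vertices = c("chr1:100|chr1:500|chr2:300",
                 "chr1:100|chr3:700|chr4:900",   # shares chr1:100 with 1st
                 "chr1:100|chr1:500|chr2:300"),  # other sample: no sharing
    label = c("chromoplexy", "chromotrikona", "chromoplexy"),
    stringsAsFactors = FALSE)
  m <- triangleOverlapMatrix(calls)
  expect_true(isSymmetric(m))
  expect_equal(m["chromoplexy", "chromotrikona"], 1L)
  expect_equal(m["chromoplexy", "chromoplexy"], 6L)  # distinct clusters
  expect_equal(m["chromotrikona", "chromotrikona"], 3L)
  expect_equal(m["templated_insertion_cycle", "chromoplexy"], 0L)
})

test_that("cancer summary excludes sparse types and uses the CI formula", {
  calls <- data.frame(
    sample = rep(sprintf("s%02d", 1:12), each = 2),
    vertices = "chr1:1|chr1:2|chr2:3",
    label = rep(c("chromoplexy", "chromotrikona"), 12),
    stringsAsFactors = FALSE)
  cmap <- setNames(c(rep("Big", 10), rep("Small", 2)),
                   sprintf("s%02d", 1:12))
  summ <- triangleTypeCancerSummary(calls, cmap, min_samples = 10)
  expect_equal(attr(summ, "excluded"), "Small")
  expect_setequal(unique(summ$cancer_type), "Big")
  cp <- summ[summ$triangle_type == "chromoplexy", ]
  expect_equal(cp$mean_frequency, 1)
  expect_equal(cp$ci_halfwidth, 0)  # constant counts
  expect_equal(cp$n_samples, 10)
  ## CI matches mean +/- 1.96 sd/sqrt(n) on mixed counts
  calls2 <- calls[calls$sample %in% sprintf("s%02d", 1:10), ]
  calls2$label[1] <- "chromotrikona"  # s01: 0 chromoplexy, 2 chromotrikona
  s2 <- triangleTypeCancerSummary(calls2, cmap, min_samples = 10)
  counts <- c(0, rep(1, 9))
  row <- s2[s2$triangle_type == "chromoplexy", ]
  expect_equal(row$mean_frequency, mean(counts))
  expect_equal(row$ci_halfwidth, 1.96 * sd(counts) / sqrt(10))
})
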