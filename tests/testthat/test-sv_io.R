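test_that("breakend ALT bracket forms decode to the hand-derived table", {
  ## hand-decoded against the four VCF 4.2 bracket forms: the bracket tells
  ## which flank of the mate is joined, the anchor position tells which
  ## flank of the local breakend is retained
  cases <- list(
    list(alt = "N[chr5:1000[", here = "extends_right",
         mate = "extends_left"),
    list(alt = "N]chr5:1000]", here = "extends_right",
         mate = "extends_right"),
    list(alt = "]chr5:1000]N", here = "extends_left",
         mate = "extends_right"),
    list(alt = "[chr5:1000[N", here = "extends_left",
         mate = "extends_left"))
  for (cs in cases) {
    dec <- parseBreakendAlt(cs$alt, "chr1", 500)
    expect_equal(dec$mate_chrom, "chr5")
    expect_equal(dec$mate_pos, 1000)
    expect_equal(dec$side_here, cs$here, info = cs$alt)
    expect_equal(dec$side_mate, cs$mate, info = cs$alt)
  }
})

test_that("reciprocal BND records decode consistently", {
  ## one junction, two records: each must see the other's orientation
  sides <- expand.grid(s1 = c("extends_right", "extends_left"),
                       s2 = c("extends_right", "extends_left"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(sides))) {
    adj <- makeAdj("j1", "s1", "chr1", 500, sides$s1[i],
                   "chr2", 900, sides$s2[i])
    f <- tempfile(fileext = ".vcf")
    writeVcfBreakends(adj, f, genome = c(chr1 = 1e6, chr2 = 1e6))
    lines <- readLines(f)
    recs <- lines[!startsWith(lines, "#")]
    alt <- vapply(strsplit(recs, "\t"), `[`, character(1), 5)
    d1 <- parseBreakendAlt(alt[1], "chr1", 500)
    d2 <- parseBreakendAlt(alt[2], "chr2", 900)
    expect_equal(d1$side_here, d2$side_mate)
    expect_equal(d1$side_mate, d2$side_here)
    unlink(f)
  }
})

test_that("non-breakend ALT alleles are rejected with a parse error", {
  expect_error(parseBreakendAlt("N<INS>", "chr1", 10), "malformed")
  expect_error(parseBreakendAlt("ACGT", "chr1", 10), "malformed")
})

test_that("VCF BND mate pairs collapse to single adjacencies", {
  adj <- makeAdj(c("sv1", "sv2"), "s1",
                 c("chr1", "chr2"), c(100, 5000),
                 c("extends_right", "extends_left"),
                 c("chr2", "chr2"), c(200, 9000),
                 c("extends_left", "extends_left"))
  f <- tempfile(fileext = ".vcf")
  writeVcfBreakends(adj, f, genome = c(chr1 = 1e6, chr2 = 1e6))
  back <- readVcfBreakends(f, "s1")
  expect_equal(nrow(back), 2)  # 4 BND records -> 2 adjacencies
  expect_equal(back[order(back$id), c("chrom1", "pos1", "side1", "chrom2",
                                      "pos2", "side2")],
               adj[order(adj$id), c("chrom1", "pos1", "side1", "chrom2",
                                    "pos2", "side2")],
               ignore_attr = TRUE)
  ## drop one mate: its partner must be dropped with a warning
  lines <- readLines(f)
  writeLines(lines[-length(lines)], f)
  expect_warning(back2 <- readVcfBreakends(f, "s1"), "unmatched")
  expect_equal(nrow(back2), 1)
  unlink(f)
})

test_that("VCF with an empty body yields an empty adjacency set", {
  f <- tempfile(fileext = ".vcf")
  writeVcfBreakends(makeAdj(character(), character(), character(),
                            numeric(), character(), character(), numeric(),
                            character()),
                    f, genome = c(chr1 = 1e6))
  expect_equal(nrow(readVcfBreakends(f, "s1")), 0)
  unlink(f)
})

test_that("BEDPE coordinates shift from 0-based half-open to 1-based", {
  f <- tempfile(fileext = ".bedpe")
  writeLines("chr1\t99\t100\tchr2\t199\t200\tsv1\t.\t+\t-", f)
  adj <- readBedpe(f, "s1")
  expect_equal(adj$pos1, 100)
  expect_equal(adj$pos2, 200)
  expect_equal(adj$side1, "extends_right")
  expect_equal(adj$side2, "extends_left")
  unlink(f)
})

test_that("BEDPE round-trip preserves chrom, position and side exactly", {
  set.seed(3)
  n <- 25
  adj <- makeAdj(paste0("sv", 1:n), "s1",
                 sample(c("chr1", "chr2"), n, TRUE),
                 sample.int(1e6, n),
                 sample(c("extends_right", "extends_left"), n, TRUE),
                 sample(c("chr1", "chr2"), n, TRUE),
                 sample.int(1e6, n),
                 sample(c("extends_right", "extends_left"), n, TRUE))
  adj <- adjacencies(SVDataset(adj, genome = c(chr1 = 1e6, chr2 = 1e6)))
  f <- tempfile(fileext = ".bedpe")
  writeBedpe(adj, f)
  back <- readBedpe(f, "s1")
  cols <- c("chrom1", "pos1", "side1", "chrom2", "pos2", "side2")
  expect_equal(back[order(back$id), cols], adj[order(adj$id), cols],
               ignore_attr = TRUE)
  unlink(f)
})

test_that("BEDPE edge cases: empty file, duplicate names, bad columns", {
  f <- tempfile()
  writeLines(character(0), f)
  expect_equal(nrow(readBedpe(f, "s1")), 0)
  writeLines(c("chr1\t10\t11\tchr2\t20\t21\tdup\t.\t+\t+",
               "chr1\t30\t31\tchr2\t40\t41\tdup\t.\t-\t-"), f)
  adj <- readBedpe(f, "s1")
  expect_equal(anyDuplicated(adj$id), 0)
  writeLines(c("chr1\t10\t11\tchr2\t20\t21\tsv\t.\t+\t+",
               "chr1\t10\t11\tchr2"), f)
  expect_error(readBedpe(f, "s1"), "line 2")
  unlink(f)
})

test_that("copy-number segment validation sorts and rejects bad tables", {
  f <- tempfile()
  writeLines(c("sample\tchrom\tstart\tend\ttotal_cn",
               "s1\tchr1\t5000\t9000\t3",
               "s1\tchr1\t1\t4999\t2"), f)
  seg <- readCnSegments(f)
  expect_equal(seg$start, c(1, 5000))  # sorted per sample/chromosome
  writeLines(c("sample\tchrom\tstart\tend\ttotal_cn",
               "s1\tchr1\t1\t5000\t2",
               "s1\tchr1\t4000\t9000\t3"), f)
  expect_error(readCnSegments(f), "overlap")
  writeLines(c("sample\tchrom\tstart\tend\ttotal_cn",
               "s1\tchr1\t1\t5000\t-1"), f)
  expect_error(readCnSegments(f), "negative")
  unlink(f)
})

test_that("SVDataset canonicalizes pairs and drops off-genome contigs", {
  adj <- rbind(
    makeAdj("a1", "s1", "chr2", 500, "extends_left",
            "chr1", 100, "extends_right"),
    makeAdj("a2", "s1", "chrUn_x", 10, "extends_right",
            "chr1", 50, "extends_left"))
  expect_message(d <- SVDataset(adj, genome = c(chr1 = 1e6, chr2 = 1e6)),
                 "dropped")
  a <- adjacencies(d)
  expect_equal(nrow(a), 1)
  ## canonical order: lexicographically smaller breakend first
  expect_equal(a$chrom1, "chr1")
  expect_equal(a$chrom2, "chr2")
  expect_error(SVDataset(makeAdj("x", "s1", "chr1", 0, "extends_right",
                                 "chr1", 5, "extends_left"),
                         genome = c(chr1 = 1e6)),
               "positions")
})
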