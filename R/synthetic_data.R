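.ARCHETYPES <- c(.TRIANGLE_TYPES, "none")

#' Default planted-cycle specification
#'
#' A balanced set of triangles across the four archetypes, dealt to samples
#' round-robin.
#'
#' @param n_triangles total number of planted triangles (default 20).
#' @param n_samples number of samples they are dealt across.
#' @return data.frame with columns \code{sample_index}, \code{size},
#'   \code{archetype}.
#' @export
defaultPlantedCycles <- function(n_triangles = 20, n_samples = 30) {
  data.frame(
    sample_index = rep_len(seq_len(n_samples), n_triangles),
    size = rep_len(3L, n_triangles),
    archetype = rep_len(.TRIANGLE_TYPES, n_triangles),
    stringsAsFactors = FALSE)
}

#' Configuration of the synthetic SV dataset generator
#'
#' The generator emulates the structure the pipeline is built to detect:
#' breakpoints concentrated at recurrent genomic loci shared across samples,
#' per-sample junction chains closing into cycles of 3-6 clusters with
#' archetype-specific junction orientations, step-wise copy-number profiles
#' around the planted cycles over a diploid baseline, and a uniform
#' background of unrelated junctions.
#'
#' @param genome named numeric vector of chromosome lengths (default two
#'   chromosomes of 80 and 70 Mb — a compact miniature that keeps the
#'   per-chromosome breakpoint occupancy of the dataset in the range where
#'   complex rearrangements live in real cohorts).
#' @param n_samples number of samples (default 30).
#' @param background_rate expected background adjacencies per sample
#'   (default 200/30); the total \code{round(background_rate * n_samples)}
#'   is dealt to samples as evenly as possible.
#' @param background_cluster_frac probability that a background breakend
#'   falls at one of its sample's active loci (jittered) rather than at a
#'   uniform genomic position (default 0.5). Tumor breakpoints concentrate
#'   at recurrent loci and co-occur within a sample; fully uniform
#'   background would miss that dependency.
#' @param active_loci_per_sample number of recurrent loci around which a
#'   sample's clustered background concentrates (default 3).
#' @param centers_per_chrom recurrent breakpoint loci per chromosome
#'   (default 8); centers are spread so that any two are at least a fifth of
#'   a chromosome bin apart (several Mb here), keeping clusters and
#'   copy-number flanks well separated.
#' @param jitter_sd standard deviation (bp) of breakend scatter around a
#'   cluster center (default 50, well below the round-2 bandwidth of 400).
#' @param planted data.frame of planted cycles (\code{sample_index},
#'   \code{size}, \code{archetype}); default [defaultPlantedCycles()].
#' @param cn_baseline baseline total copy number (default 2).
#' @param cn_segment_halfwidth half-width (bp) of an altered copy-number
#'   segment around a cluster center (default 5e4).
#' @param cancer_types labels dealt round-robin to samples (default
#'   \code{c("TypeA", "TypeB")}).
#' @param seed integer seed making the dataset reproducible.
#' @return validated configuration list.
#' @export
simulationConfig <- function(genome = c(chr1 = 80e6, chr2 = 70e6),
                             n_samples = 30,
                             background_rate = 200 / 30,
                             background_cluster_frac = 0.5,
                             active_loci_per_sample = 3,
                             centers_per_chrom = 12,
                             jitter_sd = 50,
                             planted = defaultPlantedCycles(20, n_samples),
                             cn_baseline = 2,
                             cn_segment_halfwidth = 5e4,
                             cancer_types = c("TypeA", "TypeB"),
                             seed = 1L) {
  problems <- character()
  if (!length(genome) || is.null(names(genome)) || any(genome <= 0))
    problems <- c(problems, "genome must be named positive lengths")
  if (n_samples < 1) problems <- c(problems, "n_samples must be >= 1")
  if (jitter_sd < 0) problems <- c(problems, "jitter_sd must be >= 0")
  if (background_rate < 0)
    problems <- c(problems, "background_rate must be >= 0")
  if (background_cluster_frac < 0 || background_cluster_frac > 1)
    problems <- c(problems, "background_cluster_frac must be in [0, 1]")
  if (active_loci_per_sample < 1)
    problems <- c(problems, "active_loci_per_sample must be >= 1")
  if (cn_baseline < 0) problems <- c(problems, "cn_baseline must be >= 0")
  if (nrow(planted)) {
    if (any(planted$size < 3 | planted$size > 6))
      problems <- c(problems, "planted cycle sizes must be in [3, 6]")
    if (!all(planted$archetype %in% .ARCHETYPES))
      problems <- c(problems, paste("archetypes must be one of:",
                                    paste(.ARCHETYPES, collapse = ", ")))
    if (any(planted$sample_index < 1 | planted$sample_index > n_samples))
      problems <- c(problems, "planted sample_index out of range")
    if (any(planted$archetype != "none" & planted$size != 3))
      problems <- c(problems, "triangle archetypes require size 3")
  }
  if (length(problems))
    stop("invalid simulation config:\n  ",
         paste(problems, collapse = "\n  "))
  list(genome = genome, n_samples = n_samples,
       background_rate = background_rate,
       background_cluster_frac = background_cluster_frac,
       active_loci_per_sample = active_loci_per_sample,
       centers_per_chrom = centers_per_chrom, jitter_sd = jitter_sd,
       planted = planted, cn_baseline = cn_baseline,
       cn_segment_halfwidth = cn_segment_halfwidth,
       cancer_types = cancer_types, seed = seed)
}

## Recurrent loci: one uniform draw inside the middle 60% of each of
## centers_per_chrom equal bins, guaranteeing inter-center gaps of at least
## 40% of a bin.
.drawCenters <- function(genome, perChrom) {
  rows <- lapply(names(genome), function(ch) {
    bin <- genome[[ch]] / perChrom
    pos <- round((seq_len(perChrom) - 1) * bin +
                 bin * (0.2 + 0.6 * stats::runif(perChrom)))
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## Orientation and copy-number profile of each triangle archetype. Junction
## sides: an inverted junction joins two same-side breakends.
.archetypeProfile <- function(archetype, k) {
  switch(archetype,
    chromoplexy = list(inverted = rep(FALSE, 3),
                       states = rep("neutral", 3)),
    templated_insertion_cycle = list(inverted = c(TRUE, TRUE, FALSE),
                                     states = rep("gain", 3)),
    noncanonical_chromothripsis = list(inverted = c(TRUE, TRUE, FALSE),
                                       states = c("gain", "neutral",
                                                  "gain")),
    chromotrikona = list(inverted = rep(TRUE, 3),
                         states = rep("neutral", 3)),
    none = list(inverted = stats::runif(k) < 0.5,
                states = rep("neutral", k)))
}

#' Plant one closed cycle of junctions over k cluster centers
#'
#' Builds k adjacencies chaining the given centers into a closed cycle, each
#' breakend jittered by N(0, jitter_sd^2), with junction orientations and a
#' per-center copy-number profile realizing the requested archetype.
#'
#' @param centers data.frame with k rows (\code{chrom}, \code{pos}), the
#'   cycle's cluster centers in cycle order.
#' @param sample sample id.
#' @param archetype one of \code{"chromoplexy"},
#'   \code{"templated_insertion_cycle"},
#'   \code{"noncanonical_chromothripsis"}, \code{"chromotrikona"},
#'   \code{"none"}.
#' @param jitter_sd breakend scatter SD in bp.
#' @param id_prefix prefix for the adjacency ids.
#' @return list with \code{adjacencies} (k rows) and \code{cn_alterations}
#'   (data.frame \code{chrom}, \code{pos}, \code{state}; neutral centers
#'   omitted).
#' @export
plantCycle <- function(centers, sample, archetype = "none", jitter_sd = 50,
                       id_prefix = "p") {
  k <- nrow(centers)
  if (k < 3) stop("a planted cycle needs at least 3 distinct centers")
  prof <- .archetypeProfile(archetype, k)
  nxt <- c(seq_len(k)[-1], 1L)
  jitter <- function(n) round(stats::rnorm(n, 0, jitter_sd))
  sideFor <- function(inverted) {
    if (inverted) c("extends_right", "extends_right")
    else c("extends_right", "extends_left")
  }
  rows <- lapply(seq_len(k), function(j) {
    sides <- sideFor(prof$inverted[j])
    data.frame(
      id = paste0(id_prefix, "_", j), sample = sample,
      chrom1 = centers$chrom[j],
      pos1 = max(1, centers$pos[j] + jitter(1)), side1 = sides[1],
      chrom2 = centers$chrom[nxt[j]],
      pos2 = max(1, centers$pos[nxt[j]] + jitter(1)), side2 = sides[2],
      stringsAsFactors = FALSE)
  })
  altered <- prof$states != "neutral"
  list(adjacencies = do.call(rbind, rows),
       cn_alterations = data.frame(chrom = centers$chrom[altered],
                                   pos = centers$pos[altered],
                                   state = prof$states[altered],
                                   stringsAsFactors = FALSE),
       inverted = prof$inverted, states = prof$states)
}

## Baseline-2 segment cover of every sample chromosome, with altered windows
## of +/- halfwidth around gain/loss centers cut out of the baseline.
.buildCnSegments <- function(genome, samples, alterations, baseline,
                             halfwidth) {
  rows <- list()
  for (s in samples) {
    alt <- alterations[alterations$sample == s, , drop = FALSE]
    for (ch in names(genome)) {
      L <- genome[[ch]]
      a <- alt[alt$chrom == ch, , drop = FALSE]
      a <- a[order(a$pos), , drop = FALSE]
      cursor <- 1
      for (i in seq_len(nrow(a))) {
        lo <- max(1, a$pos[i] - halfwidth)
        hi <- min(L, a$pos[i] + halfwidth)
        if (lo > cursor)
          rows[[length(rows) + 1L]] <- data.frame(
            sample = s, chrom = ch, start = cursor, end = lo - 1,
            total_cn = baseline, stringsAsFactors = FALSE)
        cn <- baseline + if (a$state[i] == "gain") 1 else -1
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, chrom = ch, start = lo, end = hi,
          total_cn = max(0, cn), stringsAsFactors = FALSE)
        cursor <- hi + 1
      }
      if (cursor <= L)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, chrom = ch, start = cursor, end = L,
          total_cn = baseline, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic SV dataset with ground truth
#'
#' Draws recurrent cluster centers, plants the configured cycles (junction
#' chains closing over 3-6 centers, archetype orientations, copy-number
#' profiles), adds uniformly random background adjacencies, and returns the
#' dataset together with an exhaustive ground-truth manifest. Deterministic
#' under the configured seed.
#'
#' @param config see [simulationConfig()].
#' @return list with \code{dataset} (an [SVDataset-class] carrying
#'   copy-number segments and a cancer-type map) and \code{manifest} (list:
#'   \code{centers}, \code{cycles}, \code{sample_counts}, \code{config}
#'   essentials).
#' @export
generateDataset <- function(config = simulationConfig()) {
  set.seed(config$seed)
  samples <- sprintf("S%03d", seq_len(config$n_samples))
  centers <- .drawCenters(config$genome, config$centers_per_chrom)

  adjRows <- list()
  altRows <- list()
  cycleRows <- list()
  usedBySample <- stats::setNames(
    rep(list(integer(0)), length(samples)), samples)

  planted <- config$planted
  for (i in seq_len(nrow(planted))) {
    s <- samples[planted$sample_index[i]]
    k <- planted$size[i]
    avail <- setdiff(seq_len(nrow(centers)), usedBySample[[s]])
    if (length(avail) < k)
      stop("not enough unused centers for sample ", s)
    ## a planted cycle spans two chromosomes: ceiling(k/2) centers on one,
    ## the rest on another (complex rearrangement chains concentrate on a
    ## few chromosomes rather than scattering genome-wide)
    avail <- avail[order(stats::runif(length(avail)))]
    chromOf <- centers$chrom[avail]
    byChrom <- split(avail, chromOf)
    byChrom <- byChrom[order(-lengths(byChrom))]
    n1 <- ceiling(k / 2)
    pick <- if (length(byChrom) >= 2 && length(byChrom[[1]]) >= n1 &&
                length(byChrom[[2]]) >= k - n1)
      c(byChrom[[1]][seq_len(n1)], byChrom[[2]][seq_len(k - n1)])
    else avail[seq_len(k)]
    usedBySample[[s]] <- c(usedBySample[[s]], pick)
    cc <- centers[pick, , drop = FALSE]
    pc <- plantCycle(cc, s, planted$archetype[i], config$jitter_sd,
                     id_prefix = paste0("p", i))
    adjRows[[length(adjRows) + 1L]] <- pc$adjacencies
    if (nrow(pc$cn_alterations))
      altRows[[length(altRows) + 1L]] <-
        cbind(sample = s, pc$cn_alterations)
    cycleRows[[length(cycleRows) + 1L]] <- data.frame(
      sample = s, size = k, archetype = planted$archetype[i],
      vertices = paste(paste0(cc$chrom, ":", cc$pos), collapse = "|"),
      n_inverted = sum(pc$inverted),
      cn_states = paste(pc$states, collapse = "|"),
      stringsAsFactors = FALSE)
  }

  ## background: a mixture of junction breakends at the sample's few
  ## active recurrent loci (within-sample dependency) and uniformly
  ## scattered positions
  totalBg <- round(config$background_rate * config$n_samples)
  bgPerSample <- diff(floor(seq(0, totalBg, length.out =
                                  config$n_samples + 1)))
  chromProb <- config$genome / sum(config$genome)
  bgId <- 0L
  for (si in seq_along(samples)) {
    nb <- bgPerSample[si]
    if (!nb) next
    active <- sample.int(nrow(centers),
                         min(config$active_loci_per_sample, nrow(centers)))
    ch <- sample(names(config$genome), 2 * nb, replace = TRUE,
                 prob = chromProb)
    pos <- floor(stats::runif(2 * nb, 1, config$genome[ch] + 1))
    atLocus <- stats::runif(2 * nb) < config$background_cluster_frac
    if (any(atLocus)) {
      loci <- active[sample.int(length(active), sum(atLocus),
                                replace = TRUE)]
      ch[atLocus] <- centers$chrom[loci]
      pos[atLocus] <- pmax(1, centers$pos[loci] +
                              round(stats::rnorm(sum(atLocus), 0,
                                                 config$jitter_sd)))
    }
    side <- sample(.SIDES, 2 * nb, replace = TRUE)
    adjRows[[length(adjRows) + 1L]] <- data.frame(
      id = paste0("bg_", bgId + seq_len(nb)), sample = samples[si],
      chrom1 = ch[seq_len(nb)], pos1 = pos[seq_len(nb)],
      side1 = side[seq_len(nb)],
      chrom2 = ch[nb + seq_len(nb)], pos2 = pos[nb + seq_len(nb)],
      side2 = side[nb + seq_len(nb)], stringsAsFactors = FALSE)
    bgId <- bgId + nb
  }

  adj <- do.call(rbind, c(adjRows,
                          list(.emptyAdjacencies())))
  alterations <- if (length(altRows)) do.call(rbind, altRows) else
    data.frame(sample = character(), chrom = character(), pos = numeric(),
               state = character(), stringsAsFactors = FALSE)
  cn <- .buildCnSegments(config$genome, samples, alterations,
                         config$cn_baseline, config$cn_segment_halfwidth)
  cancerMap <- stats::setNames(
    rep_len(config$cancer_types, length(samples)), samples)
  dataset <- SVDataset(adj, genome = config$genome, cnSegments = cn,
                       cancerType = cancerMap)
  manifest <- list(
    centers = centers,
    cycles = if (length(cycleRows)) do.call(rbind, cycleRows) else
      data.frame(sample = character(), size = integer(),
                 archetype = character(), vertices = character(),
                 n_inverted = integer(), cn_states = character(),
                 stringsAsFactors = FALSE),
    sample_counts = as.list(table(adjacencies(dataset)$sample)),
    jitter_sd = config$jitter_sd,
    seed = config$seed)
  list(dataset = dataset, manifest = manifest)
}

.parseLoci <- function(vertexString) {
  v <- strsplit(vertexString, "|", fixed = TRUE)[[1]]
  m <- regmatches(v, regexec("^(.+):([0-9]+)$", v))
  data.frame(chrom = vapply(m, `[`, character(1), 2),
             pos = as.numeric(vapply(m, `[`, character(1), 3)),
             stringsAsFactors = FALSE)
}

#' Match mined cycles against the ground-truth manifest
#'
#' A planted cycle counts as recovered when the same sample holds a mined
#' cycle of the same size whose vertex loci match the planted centers one to
#' one within \code{tol} bp on the same chromosome.
#'
#' @param cycleSet a [CycleSet-class] mined from the generated dataset.
#' @param manifest the generator's ground-truth manifest.
#' @param tol matching tolerance in bp (default 500, ten jitter SDs).
#' @return logical vector, one flag per planted cycle; the recovered
#'   fraction is its mean.
#' @export
recoverPlantedCycles <- function(cycleSet, manifest, tol = 500) {
  occ <- cycles(cycleSet)
  planted <- manifest$cycles
  vapply(seq_len(nrow(planted)), function(i) {
    truth <- .parseLoci(planted$vertices[i])
    cand <- occ[occ$sample == planted$sample[i] &
                occ$size == planted$size[i], , drop = FALSE]
    for (j in seq_len(nrow(cand))) {
      mined <- .parseLoci(cand$vertices[j])
      used <- logical(nrow(mined))
      ok <- TRUE
      for (t in seq_len(nrow(truth))) {
        hit <- which(!used & mined$chrom == truth$chrom[t] &
                     abs(mined$pos - truth$pos[t]) <= tol)
        if (!length(hit)) { ok <- FALSE; break }
        used[hit[1]] <- TRUE
      }
      if (ok) return(TRUE)
    }
    FALSE
  }, logical(1))
}

#' Verify that a manifest is consistent with its dataset
#'
#' Independent consistency check of the generator output: per-sample
#' adjacency counts must match the manifest, and every junction of every
#' planted cycle must be present in the dataset with both breakends within
#' \code{tol} bp of its centers.
#'
#' @param dataset the generated [SVDataset-class].
#' @param manifest the accompanying manifest.
#' @param tol breakend-to-center tolerance in bp (default 500).
#' @return \code{TRUE}, or a character vector of problems.
#' @export
verifyManifest <- function(dataset, manifest, tol = 500) {
  problems <- character()
  adj <- adjacencies(dataset)
  counts <- table(adj$sample)
  for (s in names(manifest$sample_counts)) {
    if (!identical(as.integer(counts[[s]]),
                   as.integer(manifest$sample_counts[[s]])))
      problems <- c(problems, paste0("sample ", s, " adjacency count ",
                                     counts[[s]], " != manifest ",
                                     manifest$sample_counts[[s]]))
  }
  planted <- manifest$cycles
  for (i in seq_len(nrow(planted))) {
    truth <- .parseLoci(planted$vertices[i])
    k <- nrow(truth)
    nxt <- c(seq_len(k)[-1], 1L)
    sAdj <- adj[adj$sample == planted$sample[i], , drop = FALSE]
    for (j in seq_len(k)) {
      c1 <- truth[j, ]; c2 <- truth[nxt[j], ]
      hit <- (sAdj$chrom1 == c1$chrom & abs(sAdj$pos1 - c1$pos) <= tol &
              sAdj$chrom2 == c2$chrom & abs(sAdj$pos2 - c2$pos) <= tol) |
             (sAdj$chrom1 == c2$chrom & abs(sAdj$pos1 - c2$pos) <= tol &
              sAdj$chrom2 == c1$chrom & abs(sAdj$pos2 - c1$pos) <= tol)
      if (!any(hit))
        problems <- c(problems,
                      paste0("planted junction ", planted$sample[i], " ",
                             c1$chrom, ":", c1$pos, " - ", c2$chrom, ":",
                             c2$pos, " missing from dataset"))
    }
  }
  if (length(problems)) problems else TRUE
}

#' Write a generated dataset to standard formats
#'
#' Emits one BEDPE (or VCF-BND) file per sample plus the copy-number TSV,
#' the cancer-type map TSV and the manifest JSON into a directory.
#'
#' @param gen output of [generateDataset()].
#' @param dir output directory (created if needed).
#' @param format \code{"bedpe"} or \code{"vcf"}.
#' @return the directory, invisibly.
#' @export
writeSyntheticDataset <- function(gen, dir, format = c("bedpe", "vcf")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dataset <- gen$dataset
  adj <- adjacencies(dataset)
  for (s in sampleIds(dataset)) {
    sAdj <- adj[adj$sample == s, , drop = FALSE]
    if (format == "bedpe")
      writeBedpe(sAdj, file.path(dir, paste0(s, ".bedpe")))
    else
      writeVcfBreakends(sAdj, file.path(dir, paste0(s, ".vcf")),
                        svGenome(dataset))
  }
  utils::write.table(cnSegments(dataset), file.path(dir, "cn_segments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ct <- cancerTypes(dataset)
  utils::write.table(data.frame(sample = names(ct), cancer_type = ct),
                     file.path(dir, "cancer_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(gen$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
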