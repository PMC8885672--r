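.emptyAdjacencies <- function() {
  data.frame(id = character(), sample = character(),
             chrom1 = character(), pos1 = numeric(), side1 = character(),
             chrom2 = character(), pos2 = numeric(), side2 = character(),
             stringsAsFactors = FALSE)
}

.emptyCnSegments <- function() {
  data.frame(sample = character(), chrom = character(),
             start = numeric(), end = numeric(), total_cn = numeric(),
             stringsAsFactors = FALSE)
}

## Canonical storage order of the unordered breakend pair:
## lexicographic by (chrom, pos, side).
.canonicalizeAdjacencies <- function(adj) {
  if (!nrow(adj)) return(adj)
  key1 <- paste(adj$chrom1, formatC(adj$pos1, width = 12, flag = "0",
                                    format = "d"), adj$side1)
  key2 <- paste(adj$chrom2, formatC(adj$pos2, width = 12, flag = "0",
                                    format = "d"), adj$side2)
  swap <- key2 < key1
  if (any(swap)) {
    tmp <- adj[swap, c("chrom1", "pos1", "side1")]
    adj[swap, c("chrom1", "pos1", "side1")] <-
      adj[swap, c("chrom2", "pos2", "side2")]
    adj[swap, c("chrom2", "pos2", "side2")] <- tmp
  }
  rownames(adj) <- NULL
  adj
}

#' Construct an SVDataset
#'
#' Validates and canonicalizes a table of adjacencies against a declared
#' genome. Breakends on chromosomes absent from the genome (unplaced or alt
#' contigs) are dropped with a message reporting the count.
#'
#' @param adjacencies data.frame with columns \code{id, sample, chrom1, pos1,
#'   side1, chrom2, pos2, side2}.
#' @param genome named numeric vector of chromosome lengths in bp.
#' @param cnSegments optional copy-number segment data.frame (see
#'   [readCnSegments()]).
#' @param cancerType optional named character vector, sample id to label.
#' @return An [SVDataset-class] object.
#' @examples
#' adj <- data.frame(id = "sv1", sample = "s1",
#'                   chrom1 = "chr1", pos1 = 100, side1 = "extends_right",
#'                   chrom2 = "chr2", pos2 = 200, side2 = "extends_left")
#' SVDataset(adj, genome = c(chr1 = 1e6, chr2 = 1e6))
#' @export
SVDataset <- function(adjacencies = .emptyAdjacencies(), genome = numeric(),
                      cnSegments = .emptyCnSegments(),
                      cancerType = character()) {
  adjacencies <- as.data.frame(adjacencies, stringsAsFactors = FALSE)
  if (length(genome) && nrow(adjacencies)) {
    keep <- adjacencies$chrom1 %in% names(genome) &
            adjacencies$chrom2 %in% names(genome)
    if (!all(keep)) {
      message(sum(!keep),
              " adjacency(ies) on chromosomes outside the genome dropped")
      adjacencies <- adjacencies[keep, , drop = FALSE]
    }
  }
  adjacencies <- .canonicalizeAdjacencies(adjacencies)
  new("SVDataset", adjacencies = adjacencies, genome = genome,
      cnSegments = as.data.frame(cnSegments, stringsAsFactors = FALSE),
      cancerType = cancerType)
}

#' @rdname SVDataset-class
#' @export
setMethod("adjacencies", "SVDataset", function(x) x@adjacencies)

#' @rdname SVDataset-class
#' @export
setMethod("svGenome", "SVDataset", function(x) x@genome)

#' @rdname SVDataset-class
#' @export
setMethod("cnSegments", "SVDataset", function(x) x@cnSegments)

#' @rdname SVDataset-class
#' @export
setMethod("cancerTypes", "SVDataset", function(x) x@cancerType)

#' @rdname SVDataset-class
#' @export
setMethod("sampleIds", "SVDataset",
          function(x) sort(unique(x@adjacencies$sample)))

## Long view: one row per breakend, with a stable breakend id "<adj_id>:a|b".
.breakendsFromAdjacencies <- function(adj) {
  if (!nrow(adj)) {
    return(data.frame(bid = character(), adj_id = character(),
                      end = character(), sample = character(),
                      chrom = character(), pos = numeric(),
                      side = character(), stringsAsFactors = FALSE))
  }
  data.frame(
    bid = c(paste0(adj$id, ":a"), paste0(adj$id, ":b")),
    adj_id = c(adj$id, adj$id),
    end = rep(c("a", "b"), each = nrow(adj)),
    sample = c(adj$sample, adj$sample),
    chrom = c(adj$chrom1, adj$chrom2),
    pos = c(adj$pos1, adj$pos2),
    side = c(adj$side1, adj$side2),
    stringsAsFactors = FALSE
  )
}

#' @rdname SVDataset-class
#' @export
setMethod("breakends", "SVDataset",
          function(x) .breakendsFromAdjacencies(x@adjacencies))

#' @rdname SVDataset-class
#' @export
setMethod("breakends", "data.frame",
          function(x) .breakendsFromAdjacencies(x))

setMethod("show", "SVDataset", function(object) {
  adj <- object@adjacencies
  cat("SVDataset:", nrow(adj), "adjacencies in",
      length(unique(adj$sample)), "sample(s);",
      length(object@genome), "chromosome(s)\n")
  if (nrow(object@cnSegments))
    cat("  copy-number segments:", nrow(object@cnSegments), "\n")
  if (length(object@cancerType))
    cat("  cancer types:",
        length(unique(object@cancerType)), "label(s)\n")
})

#' @rdname SVClusters-class
#' @export
setMethod("clusters", "SVClusters", function(x) x@clusters)

#' @rdname SVClusters-class
#' @export
setMethod("assignments", "SVClusters", function(x) x@assignments)

#' @rdname SVClusters-class
#' @export
setMethod("adjacencies", "SVClusters", function(x) x@adjacencies)

setMethod("show", "SVClusters", function(object) {
  cat("SVClusters:", nrow(object@clusters), "final cluster(s),",
      nrow(object@assignments), "assigned breakend(s),",
      length(object@discarded), "loop adjacency(ies) discarded\n")
})

#' @rdname SampleGraphSet-class
#' @export
setMethod("graphVertices", "SampleGraphSet", function(x) x@vertices)

#' @rdname SampleGraphSet-class
#' @export
setMethod("graphEdges", "SampleGraphSet", function(x) x@edges)

#' @rdname SampleGraphSet-class
#' @export
setMethod("edgeProvenance", "SampleGraphSet", function(x) x@provenance)

setMethod("show", "SampleGraphSet", function(object) {
  cat("SampleGraphSet:", length(unique(object@vertices$sample)),
      "sample graph(s),", nrow(object@vertices), "vertices,",
      nrow(object@edges), "deduplicated edges\n")
})

#' @rdname CycleSet-class
#' @export
setMethod("cycles", "CycleSet", function(x) x@occurrences)

setMethod("show", "CycleSet", function(object) {
  occ <- object@occurrences
  cat("CycleSet:", nrow(occ), "cycle occurrence(s) over",
      length(object@samples), "sample(s)\n")
  if (nrow(occ)) {
    tab <- table(factor(occ$size, levels = 3:6))
    cat("  by size:", paste(paste0("k=", names(tab), ": ", as.integer(tab)),
                            collapse = ", "), "\n")
  }
})
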