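#' @import methods
NULL

## Junction orientation vocabulary: each breakend records which way the
## retained/joined flank points. extends_right corresponds to BEDPE strand "+",
## extends_left to "-".
.SIDES <- c("extends_right", "extends_left")

.ADJ_COLS <- c("id", "sample", "chrom1", "pos1", "side1",
               "chrom2", "pos2", "side2")

.TRIANGLE_TYPES <- c("chromoplexy", "templated_insertion_cycle",
                     "noncanonical_chromothripsis", "chromotrikona")

#' SVDataset: a cohort of structural-variant adjacencies
#'
#' Container for per-sample SV junctions (adjacencies) over a declared genome,
#' optionally carrying total copy-number segments and a sample-to-cancer-type
#' map. An adjacency ties together two oriented breakends of one sample; the
#' pair is unordered and is stored canonically with its lexicographically
#' smaller breakend first.
#'
#' @slot adjacencies data.frame with columns \code{id}, \code{sample},
#'   \code{chrom1}, \code{pos1}, \code{side1}, \code{chrom2}, \code{pos2},
#'   \code{side2}. Positions are 1-based; sides are \code{"extends_right"}
#'   (BEDPE \code{+}) or \code{"extends_left"} (BEDPE \code{-}).
#' @slot genome named numeric vector of chromosome lengths in bp.
#' @slot cnSegments data.frame of total copy-number segments (columns
#'   \code{sample}, \code{chrom}, \code{start}, \code{end}, \code{total_cn};
#'   1-based inclusive) or a zero-row data.frame when absent.
#' @slot cancerType named character vector mapping sample ids to cancer-type
#'   labels; may be empty.
#'
#' @seealso [SVDataset()] for the validating constructor, [breakends()] for
#'   the long (one row per breakend) view.
#' @export
setClass("SVDataset",
  representation(
    adjacencies = "data.frame",
    genome = "numeric",
    cnSegments = "data.frame",
    cancerType = "character"
  )
)

setValidity("SVDataset", function(object) {
  adj <- object@adjacencies
  msg <- character()
  if (!all(.ADJ_COLS %in% names(adj)))
    msg <- c(msg, paste("adjacencies must have columns:",
                        paste(.ADJ_COLS, collapse = ", ")))
  else {
    if (anyDuplicated(adj$id))
      msg <- c(msg, "adjacency ids must be unique")
    if (nrow(adj) > 0) {
      if (!all(c(adj$side1, adj$side2) %in% .SIDES))
        msg <- c(msg, "sides must be 'extends_right' or 'extends_left'")
      if (any(adj$pos1 < 1) || any(adj$pos2 < 1))
        msg <- c(msg, "positions must be >= 1")
      if (length(object@genome) &&
          !all(c(adj$chrom1, adj$chrom2) %in% names(object@genome)))
        msg <- c(msg, "adjacency chromosomes must exist in the genome")
    }
  }
  if (length(object@genome)) {
    if (is.null(names(object@genome)) || any(!nzchar(names(object@genome))))
      msg <- c(msg, "genome must be a named vector of chromosome lengths")
    if (any(object@genome <= 0))
      msg <- c(msg, "chromosome lengths must be positive")
  }
  if (length(object@cancerType) &&
      (is.null(names(object@cancerType)) || any(!nzchar(object@cancerType))))
    msg <- c(msg, "cancerType must be a named vector of non-empty labels")
  if (length(msg)) msg else TRUE
})

#' SVClusters: result of the two-step KDE clustering
#'
#' Holds the final (round-2) breakpoint clusters, the assignment of every
#' surviving breakend to its cluster, the adjacencies kept after intra-cluster
#' loop filtering, and the ids of the discarded loop adjacencies.
#'
#' @slot clusters data.frame: \code{cluster_id}, \code{sample}, \code{chrom},
#'   \code{peak_pos}, \code{n_members}, \code{round}, \code{span_lo},
#'   \code{span_hi}.
#' @slot assignments data.frame: \code{adj_id}, \code{end} (\code{"a"} or
#'   \code{"b"}), \code{cluster_id}.
#' @slot adjacencies data.frame of kept adjacencies (same columns as in
#'   [SVDataset-class]).
#' @slot discarded character vector of loop-filtered adjacency ids.
#' @slot params list of clustering parameters used (see [clusteringConfig()]).
#' @export
setClass("SVClusters",
  representation(
    clusters = "data.frame",
    assignments = "data.frame",
    adjacencies = "data.frame",
    discarded = "character",
    params = "list"
  )
)

#' SampleGraphSet: per-sample rearrangement graphs
#'
#' Vertices are cluster centers identified by their genomic locus key
#' (\code{"chrom:peak_pos"}); edges are deduplicated junctions between two
#' distinct vertices of one sample. Edge provenance records which adjacencies
#' support each edge.
#'
#' @slot vertices data.frame: \code{sample}, \code{vertex} (locus key),
#'   \code{chrom}, \code{peak_pos}, \code{cluster_id}, \code{n_members}.
#' @slot edges data.frame: \code{sample}, \code{v1}, \code{v2} (locus keys,
#'   \code{v1 < v2}), \code{key}.
#' @slot provenance named list mapping \code{key} to adjacency ids.
#' @slot droppedLoops integer count of self-loop adjacencies dropped at graph
#'   construction.
#' @export
setClass("SampleGraphSet",
  representation(
    vertices = "data.frame",
    edges = "data.frame",
    provenance = "list",
    droppedLoops = "integer"
  )
)

setValidity("SampleGraphSet", function(object) {
  e <- object@edges
  msg <- character()
  if (nrow(e)) {
    if (any(e$v1 == e$v2)) msg <- c(msg, "self-loop edges are not allowed")
    if (anyDuplicated(paste(e$sample, e$key)))
      msg <- c(msg, "duplicate edges within a sample are not allowed")
    vk <- paste(object@vertices$sample, object@vertices$vertex)
    if (!all(c(paste(e$sample, e$v1), paste(e$sample, e$v2)) %in% vk))
      msg <- c(msg, "every edge endpoint must be a declared vertex")
  }
  if (length(msg)) msg else TRUE
})

#' CycleSet: mined simple closed cycles
#'
#' One row per deduplicated cycle occurrence. A cycle of size k visits k
#' distinct vertices, every one of degree exactly 2 within the cycle's edge
#' set. Occurrences are identified by their edge set (canonical key), so a
#' dense subgraph may legitimately contribute several distinct cycles over the
#' same vertices.
#'
#' @slot occurrences data.frame: \code{sample}, \code{size}, \code{vertices}
#'   (cycle order, \code{"|"}-joined locus keys), \code{edges}
#'   (\code{";"}-joined sorted edge keys), \code{canonical_key}.
#' @slot samples character vector of all sample ids in the mined dataset
#'   (including cycle-free samples), the denominator universe for confidence.
#' @export
setClass("CycleSet",
  representation(
    occurrences = "data.frame",
    samples = "character"
  )
)
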