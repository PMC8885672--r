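#' Decode a VCF breakend ALT bracket string
#'
#' VCF 4.x encodes one side of a structural-variant junction per BND record,
#' using one of four bracket forms: \code{t[p[}, \code{t]p]}, \code{]p]t},
#' \code{[p[t}, where \code{t} contains the anchor base and \code{p} is the
#' mate locus \code{chrom:pos}. The form determines which flank of each
#' breakend is retained in the derived junction:
#' \itemize{
#'   \item \code{t[p[}: local \code{extends_right}, mate \code{extends_left}
#'   \item \code{t]p]}: local \code{extends_right}, mate \code{extends_right}
#'   \item \code{]p]t}: local \code{extends_left}, mate \code{extends_right}
#'   \item \code{[p[t}: local \code{extends_left}, mate \code{extends_left}
#' }
#' \code{extends_right} is the orientation of a breakend whose retained
#' segment lies to its left (BEDPE strand \code{+}); \code{extends_left} the
#' reverse (\code{-}).
#'
#' @param alt the ALT field of a BND record.
#' @param chrom,pos locus of the record itself (used in error messages).
#' @return list with \code{mate_chrom}, \code{mate_pos}, \code{side_here},
#'   \code{side_mate}.
#' @examples
#' parseBreakendAlt("N[chr5:1000[", "chr1", 500)
#' @export
parseBreakendAlt <- function(alt, chrom = "?", pos = NA) {
  locus <- "([^:]+):([0-9]+)"
  forms <- c(
    right_left  = paste0("^([A-Za-z.*]+)\\[", locus, "\\[$"),   # t[p[
    right_right = paste0("^([A-Za-z.*]+)\\]", locus, "\\]$"),   # t]p]
    left_right  = paste0("^\\]", locus, "\\]([A-Za-z.*]+)$"),   # ]p]t
    left_left   = paste0("^\\[", locus, "\\[([A-Za-z.*]+)$")    # [p[t
  )
  for (form in names(forms)) {
    m <- regmatches(alt, regexec(forms[[form]], alt))[[1]]
    if (length(m)) {
      sides <- strsplit(form, "_")[[1]]
      anchorFirst <- startsWith(form, "right")  # t precedes the bracket
      mc <- if (anchorFirst) m[3] else m[2]
      mp <- if (anchorFirst) m[4] else m[3]
      return(list(mate_chrom = mc, mate_pos = as.numeric(mp),
                  side_here = paste0("extends_", sides[1]),
                  side_mate = paste0("extends_", sides[2])))
    }
  }
  stop("malformed breakend ALT '", alt, "' in record ", chrom, ":", pos)
}

.infoField <- function(info, field) {
  m <- regmatches(info,
                  regexec(paste0("(?:^|;)", field, "=([^;]+)"), info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
         character(1))
}

#' Read breakend (BND) records from a VCF into adjacencies
#'
#' BND mate pairs are joined on the MATEID INFO field and each pair is emitted
#' exactly once as one adjacency. Records lacking MATEID, or whose mate is not
#' present in the file, are dropped with a warning reporting their ids.
#'
#' @param path path to a VCF 4.x file.
#' @param sample_id sample id to attach to the adjacencies.
#' @return data.frame of adjacencies (see [SVDataset-class]).
#' @export
readVcfBreakends <- function(path, sample_id) {
  if (!file.exists(path)) stop("cannot read VCF file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  if (!nrow(fix)) return(.emptyAdjacencies())
  isBnd <- grepl("\\[|\\]", fix$ALT)
  fix <- fix[isBnd, , drop = FALSE]
  if (!nrow(fix)) return(.emptyAdjacencies())
  fix$MATEID <- .infoField(fix$INFO, "MATEID")
  noMate <- is.na(fix$MATEID)
  if (any(noMate)) {
    warning(sum(noMate), " BND record(s) without MATEID dropped: ",
            paste(utils::head(fix$ID[noMate], 5), collapse = ", "))
    fix <- fix[!noMate, , drop = FALSE]
  }
  matched <- fix$MATEID %in% fix$ID
  if (any(!matched)) {
    warning(sum(!matched), " BND record(s) with unmatched mate dropped: ",
            paste(utils::head(fix$ID[!matched], 5), collapse = ", "))
    fix <- fix[matched, , drop = FALSE]
  }
  if (!nrow(fix)) return(.emptyAdjacencies())
  ## emit each mate pair once, from its lexicographically first record
  first <- pmin(fix$ID, fix$MATEID) == fix$ID
  fix <- fix[first, , drop = FALSE]
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    dec <- parseBreakendAlt(fix$ALT[i], fix$CHROM[i], fix$POS[i])
    out[[i]] <- data.frame(
      id = fix$ID[i], sample = sample_id,
      chrom1 = fix$CHROM[i], pos1 = as.numeric(fix$POS[i]),
      side1 = dec$side_here,
      chrom2 = dec$mate_chrom, pos2 = dec$mate_pos, side2 = dec$side_mate,
      stringsAsFactors = FALSE
    )
  }
  .canonicalizeAdjacencies(do.call(rbind, out))
}

.strandToSide <- function(strand) {
  side <- c("+" = "extends_right", "-" = "extends_left")[strand]
  if (any(is.na(side)))
    stop("invalid strand value(s): ",
         paste(unique(strand[is.na(side)]), collapse = ", "))
  unname(side)
}

.sideToStrand <- function(side) {
  unname(c(extends_right = "+", extends_left = "-")[side])
}

#' Read a 10-column BEDPE file into adjacencies
#'
#' Expects \code{chrom1 start1 end1 chrom2 start2 end2 name score strand1
#' strand2}. BEDPE 0-based half-open starts are converted to 1-based
#' breakpoint positions (\code{start + 1}); strands map \code{+} to
#' \code{extends_right} and \code{-} to \code{extends_left}. Duplicate names
#' are made unique so adjacency ids stay distinct.
#'
#' @param path path to a BEDPE file; lines starting with \code{#} are skipped.
#' @param sample_id sample id to attach.
#' @return data.frame of adjacencies.
#' @export
readBedpe <- function(path, sample_id) {
  if (!file.exists(path)) stop("cannot read BEDPE file: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(.emptyAdjacencies())
  fields <- strsplit(lines, "[ \t]+")
  bad <- which(lengths(fields) != 10L)
  if (length(bad))
    stop("BEDPE line ", lineNo[bad[1]], " has ", lengths(fields)[bad[1]],
         " columns; expected 10")
  m <- do.call(rbind, fields)
  ids <- make.unique(m[, 7], sep = "_dup")
  adj <- data.frame(
    id = ids, sample = sample_id,
    chrom1 = m[, 1], pos1 = as.numeric(m[, 2]) + 1,
    side1 = .strandToSide(m[, 9]),
    chrom2 = m[, 4], pos2 = as.numeric(m[, 5]) + 1,
    side2 = .strandToSide(m[, 10]),
    stringsAsFactors = FALSE
  )
  .canonicalizeAdjacencies(adj)
}

#' Write adjacencies as 10-column BEDPE
#'
#' Inverse of [readBedpe()]: 1-based positions become 0-based half-open
#' single-base intervals, sides become strands.
#'
#' @param x an [SVDataset-class] or an adjacency data.frame.
#' @param path output path.
#' @export
writeBedpe <- function(x, path) {
  adj <- if (is(x, "SVDataset")) adjacencies(x) else x
  df <- data.frame(
    chrom1 = adj$chrom1, start1 = format(adj$pos1 - 1, scientific = FALSE),
    end1 = format(adj$pos1, scientific = FALSE),
    chrom2 = adj$chrom2, start2 = format(adj$pos2 - 1, scientific = FALSE),
    end2 = format(adj$pos2, scientific = FALSE),
    name = adj$id, score = ".",
    strand1 = .sideToStrand(adj$side1), strand2 = .sideToStrand(adj$side2),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write adjacencies of one sample as a minimal VCF with BND records
#'
#' Each adjacency becomes a reciprocal pair of BND records (\code{<id>_1},
#' \code{<id>_2}) with SVTYPE and MATEID INFO fields and bracket ALT alleles
#' per [parseBreakendAlt()].
#'
#' @param adj adjacency data.frame of a single sample.
#' @param path output path.
#' @param genome named numeric vector of chromosome lengths (contig header
#'   lines); optional.
#' @export
writeVcfBreakends <- function(adj, path, genome = numeric()) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=svcycles",
           paste0("##contig=<ID=", names(genome), ",length=",
                  format(genome, scientific = FALSE, trim = TRUE), ">"),
           '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
           '##INFO=<ID=MATEID,Number=1,Type=String,Description="ID of mate breakend">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  recs <- character(0)
  altFor <- function(sideHere, sideMate, mc, mp) {
    p <- paste0(mc, ":", format(mp, scientific = FALSE, trim = TRUE))
    if (sideHere == "extends_right") {
      if (sideMate == "extends_left") paste0("N[", p, "[")
      else paste0("N]", p, "]")
    } else {
      if (sideMate == "extends_right") paste0("]", p, "]N")
      else paste0("[", p, "[N")
    }
  }
  for (i in seq_len(nrow(adj))) {
    a <- adj[i, ]
    id1 <- paste0(a$id, "_1"); id2 <- paste0(a$id, "_2")
    recs <- c(recs,
      paste(a$chrom1, format(a$pos1, scientific = FALSE, trim = TRUE), id1,
            "N", altFor(a$side1, a$side2, a$chrom2, a$pos2), ".", "PASS",
            paste0("SVTYPE=BND;MATEID=", id2), sep = "\t"),
      paste(a$chrom2, format(a$pos2, scientific = FALSE, trim = TRUE), id2,
            "N", altFor(a$side2, a$side1, a$chrom1, a$pos1), ".", "PASS",
            paste0("SVTYPE=BND;MATEID=", id1), sep = "\t"))
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read total copy-number segments
#'
#' Tab-delimited with header \code{sample chrom start end total_cn};
#' coordinates 1-based inclusive. Segments are sorted per sample/chromosome;
#' overlapping segments or negative copy numbers are rejected.
#'
#' @param path input path.
#' @return sorted data.frame of segments.
#' @export
readCnSegments <- function(path) {
  seg <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample", "chrom", "start", "end", "total_cn")
  if (!all(required %in% names(seg)))
    stop("copy-number table must have columns: ",
         paste(required, collapse = ", "))
  validateCnSegments(seg)
}

#' @rdname readCnSegments
#' @param seg a segment data.frame to validate and sort.
#' @export
validateCnSegments <- function(seg) {
  if (any(seg$start > seg$end))
    stop("copy-number segments with start > end")
  if (any(seg$total_cn < 0))
    stop("negative copy number in segment table")
  seg <- seg[order(seg$sample, seg$chrom, seg$start), , drop = FALSE]
  bySc <- split(seq_len(nrow(seg)), paste(seg$sample, seg$chrom))
  for (idx in bySc) {
    if (length(idx) > 1 &&
        any(seg$start[idx][-1] <= seg$end[idx][-length(idx)]))
      stop("overlapping copy-number segments in ",
           seg$sample[idx[1]], "/", seg$chrom[idx[1]])
  }
  rownames(seg) <- NULL
  seg
}

#' Read a sample-to-cancer-type map
#'
#' Tab-delimited, two columns with header \code{sample} and
#' \code{cancer_type}.
#'
#' @param path input path.
#' @return named character vector (names = sample ids).
#' @export
readCancerTypeMap <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "cancer_type") %in% names(m)))
    stop("cancer-type map must have columns 'sample' and 'cancer_type'")
  if (any(!nzchar(m$cancer_type))) stop("empty cancer-type label")
  stats::setNames(m$cancer_type, m$sample)
}
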