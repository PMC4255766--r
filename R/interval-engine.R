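# Interval arithmetic shared by every stage. All coordinates are held as
# GRanges (1-based closed, the Bioconductor convention); the BED/BEDPE
# readers translate from 0-based half-open on the way in and out.

#' Convert raw BED coordinates to GRanges
#'
#' @param chrom character chromosome names.
#' @param start,end numeric 0-based half-open coordinates.
#' @param seqinfo optional \code{Seqinfo} genome model; unknown chromosomes
#'   raise an error naming the offender.
#' @return \code{GRanges}.
#' @export
grFromBed <- function(chrom, start, end, seqinfo = NULL) {
  if (any(bad <- !(end > start)))
    stop(sprintf("%d interval(s) with end <= start", sum(bad)))
  if (!is.null(seqinfo)) {
    unknown <- setdiff(unique(chrom), seqlevels(seqinfo))
    if (length(unknown))
      stop("unknown chromosome: ", paste(unknown, collapse = ", "))
    gr <- GRanges(chrom, IRanges(start + 1, end), seqinfo = seqinfo)
    over <- end(gr) > seqlengths(seqinfo)[as.character(seqnames(gr))]
    if (any(over))
      stop(sprintf("%d interval(s) exceed chromosome length", sum(over)))
    gr
  } else {
    GRanges(chrom, IRanges(start + 1, end))
  }
}

#' Read a chrom-sizes file into a genome model
#'
#' Two-column whitespace-delimited text (chromosome name, length in bp).
#' Chromosome order in the file fixes the chromosome order of the model.
#'
#' @param path file path (gzip transparent).
#' @return \code{Seqinfo}.
#' @export
readChromSizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  if (any(df$length <= 0)) stop("chromosome lengths must be positive")
  if (anyDuplicated(df$chrom)) stop("duplicate chromosome names")
  Seqinfo(df$chrom, df$length)
}

#' Read a BED 3-5 column track
#'
#' Columns beyond chrom/start/end are kept as \code{name} and \code{score}
#' metadata. Malformed coordinate rows raise an error citing the line.
#'
#' @param path file path (gzip transparent).
#' @param seqinfo optional \code{Seqinfo} genome model.
#' @return \code{GRanges}, with a \code{name} metadata column when present.
#' @export
readBedTrack <- function(path, seqinfo = NULL) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character", fill = TRUE,
                          quote = "", comment.char = "#")
  if (nrow(df) == 0) {
    return(GRanges(seqinfo = if (is.null(seqinfo)) Seqinfo() else seqinfo))
  }
  if (ncol(df) < 3) stop("BED track needs at least 3 columns: ", path)
  s <- suppressWarnings(as.numeric(df[[2]]))
  e <- suppressWarnings(as.numeric(df[[3]]))
  bad <- which(is.na(s) | is.na(e) | e <= s)
  if (length(bad))
    stop(sprintf("malformed BED coordinates at line(s) %s of %s",
                 paste(utils::head(bad, 5), collapse = ","), path))
  gr <- grFromBed(df[[1]], s, e, seqinfo = seqinfo)
  if (ncol(df) >= 4) mcols(gr)$name <- df[[4]]
  if (ncol(df) >= 5) mcols(gr)$score <- suppressWarnings(as.numeric(df[[5]]))
  gr
}

#' Fraction of a query interval covered by a track
#'
#' Computes, for every query interval, the fraction of its bases covered by
#' the union of the track intervals (overlapping track records are never
#' double counted, so the result is always in [0, 1]).
#'
#' @param query \code{GRanges} of query intervals.
#' @param track \code{GRanges} track.
#' @param genome optional \code{Seqinfo}; query chromosomes absent from it
#'   raise an error naming the chromosome.
#' @return numeric vector in [0, 1], one value per query interval.
#' @examples
#' q <- GRanges("chr1", IRanges(101, 200))           # BED [100, 200)
#' tr <- GRanges("chr1", IRanges(151, 250))          # BED [150, 250)
#' overlapFraction(q, tr)                            # 0.5
#' @export
overlapFraction <- function(query, track, genome = NULL) {
  if (!is.null(genome)) {
    unknown <- setdiff(unique(as.character(seqnames(query))),
                       seqlevels(genome))
    if (length(unknown))
      stop("unknown chromosome: ", paste(unknown, collapse = ", "))
  }
  out <- numeric(length(query))
  if (length(track) == 0 || length(query) == 0) return(out)
  red <- reduce(granges(track), ignore.strand = TRUE)
  hits <- findOverlaps(query, red, ignore.strand = TRUE)
  if (length(hits)) {
    ov <- width(pintersect(query[queryHits(hits)], red[subjectHits(hits)]))
    cov <- tapply(ov, queryHits(hits), sum)
    idx <- as.integer(names(cov))
    out[idx] <- as.numeric(cov) / width(query)[idx]
  }
  out
}

#' Merge intervals closer than a gap
#'
#' Single-linkage union: output intervals are pairwise separated by more
#' than \code{max_gap} bases; with \code{max_gap = 0} only overlapping or
#' directly abutting intervals merge and the union of covered bases is
#' preserved. Idempotent.
#'
#' @param intervals \code{GRanges}.
#' @param max_gap non-negative integer gap (bp) up to which intervals merge.
#' @return merged \code{GRanges}.
#' @export
mergeIntervals <- function(intervals, max_gap = 0) {
  if (length(max_gap) != 1 || is.na(max_gap) || max_gap < 0)
    stop("'max_gap' must be a single non-negative number")
  reduce(granges(intervals), min.gapwidth = max_gap + 1,
         ignore.strand = TRUE)
}

#' Genome bins overlapped by intervals
#'
#' The genome is tiled with fixed-width bins; bin \code{i} of a chromosome
#' spans BED coordinates \code{[i*bin_size, (i+1)*bin_size)}. Every bin with
#' at least 1 bp of overlap is returned (any-overlap membership), in
#' ascending order, so each base of a query maps to exactly one of its bins.
#'
#' @param query \code{GRanges}.
#' @param bin_size bin width in bp (> 0); default 200.
#' @return \code{data.frame} with columns \code{query} (index into
#'   \code{query}), \code{chrom}, \code{bin} (0-based bin index).
#' @export
binsOverlapped <- function(query, bin_size = 200) {
  if (length(bin_size) != 1 || is.na(bin_size) || bin_size <= 0)
    stop("'bin_size' must be a single positive number")
  first <- (start(query) - 1L) %/% bin_size   # BED start of fragment
  last  <- (end(query) - 1L) %/% bin_size     # BED end - 1 (last base)
  nbin <- last - first + 1L
  idx <- rep(seq_along(query), nbin)
  bin <- unlist(lapply(seq_along(query),
                       function(i) seq.int(first[i], last[i])),
                use.names = FALSE)
  if (is.null(bin)) bin <- integer(0)
  data.frame(query = idx,
             chrom = as.character(seqnames(query))[idx],
             bin = as.integer(bin),
             stringsAsFactors = FALSE)
}

#' Fraction of the genome covered by a set of intervals
#'
#' @param intervals \code{GRanges}.
#' @param genome \code{Seqinfo} supplying chromosome lengths; coverage is
#'   the union of interval bases divided by the total length of the model's
#'   chromosomes.
#' @return single numeric in [0, 1].
#' @export
unionCoverage <- function(intervals, genome) {
  total <- sum(as.numeric(seqlengths(genome)))
  if (total <= 0) stop("genome model has no positive chromosome lengths")
  keep <- as.character(seqnames(intervals)) %in% seqlevels(genome)
  red <- reduce(granges(intervals[keep]), ignore.strand = TRUE)
  sum(as.numeric(width(red))) / total
}
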