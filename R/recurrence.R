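# Recurrent-exchange detection: carrier rates for region pairs (known
# recurrent translocation loci), genome-wide 200-bp bin-pair detection
# rates, occurrence-threshold hot-region clustering, and partner profiles
# of hot regions. Carrier semantics are per-subject presence/absence: a
# subject either carries at least one qualifying pair or it does not.

#' @import data.table
NULL

.datatable.aware <- TRUE

#' Carrier detection rates for a region pair
#'
#' A subject is a carrier iff it has at least one pair with one fragment
#' overlapping \code{region_a} and the other overlapping \code{region_b}
#' (either orientation, any-overlap). Rates are reported per cohort group
#' and pooled, with a chi-square test for rate differences among groups.
#'
#' @param pairs \code{TranslocationPairs}.
#' @param cohort cohort data.frame; the cohort size is the denominator.
#' @param region_a,region_b single-interval \code{GRanges}.
#' @return list: \code{groups} data.frame (group, n, carriers, rate),
#'   \code{overall} (n, carriers, rate), \code{p_value} chi-square p for
#'   group differences (NA with < 2 groups).
#' @export
regionPairDetection <- function(pairs, cohort, region_a, region_b) {
  if (nrow(cohort) == 0) stop("empty cohort")
  a1 <- overlapsAny(firstFragment(pairs), region_a, ignore.strand = TRUE)
  b1 <- overlapsAny(firstFragment(pairs), region_b, ignore.strand = TRUE)
  a2 <- overlapsAny(secondFragment(pairs), region_a, ignore.strand = TRUE)
  b2 <- overlapsAny(secondFragment(pairs), region_b, ignore.strand = TRUE)
  qual <- (a1 & b2) | (b1 & a2)
  carriers <- unique(subjectIds(pairs)[qual])
  carrier <- cohort$subject %in% carriers
  groups <- unique(cohort$group)
  g <- data.frame(group = groups,
                  n = vapply(groups, function(x) sum(cohort$group == x),
                             integer(1)),
                  carriers = vapply(groups, function(x)
                    sum(carrier[cohort$group == x]), integer(1)),
                  stringsAsFactors = FALSE)
  g$rate <- g$carriers / g$n
  p <- if (nrow(g) >= 2)
    groupRateTest(g$carriers, g$n)$p.value else NA_real_
  list(groups = g,
       overall = list(n = nrow(cohort), carriers = sum(carrier),
                      rate = sum(carrier) / nrow(cohort)),
       p_value = p)
}

#' Genome-wide bin-pair detection rates
#'
#' The genome is tiled with fixed-width bins (default 200 bp, about twice
#' the average fragment size) and exchanges between different bins are
#' considered. A subject carries bin pair (i, j) iff at least one of its
#' pairs has one fragment overlapping bin i and the other overlapping bin
#' j; bin membership is any-overlap, the bin pair is canonicalized, pairs
#' with both fragments in one bin are excluded, and a subject is counted at
#' most once per bin pair.
#'
#' @param pairs \code{TranslocationPairs}.
#' @param cohort cohort data.frame (denominator = cohort size).
#' @param bin_size bin width in bp (default 200).
#' @param min_rate minimum detection rate to report (default 0.2).
#' @return data.frame sorted by rate (desc), ties by genomic order, with
#'   columns chrom_a, bin_a, start_a, end_a, chrom_b, bin_b, start_b,
#'   end_b (BED coordinates), carriers, rate.
#' @export
binPairDetection <- function(pairs, cohort, bin_size = 200, min_rate = 0.2) {
  n_cohort <- nrow(cohort)
  if (n_cohort == 0) stop("empty cohort")
  lev <- unique(c(seqlevels(firstFragment(pairs)),
                  seqlevels(secondFragment(pairs))))
  ba <- binsOverlapped(firstFragment(pairs), bin_size)
  bb <- binsOverlapped(secondFragment(pairs), bin_size)
  da <- data.table::data.table(pair = ba$query, chrom_a = ba$chrom,
                               bin_a = ba$bin)
  db <- data.table::data.table(pair = bb$query, chrom_b = bb$chrom,
                               bin_b = bb$bin)
  dt <- merge(da, db, by = "pair", allow.cartesian = TRUE)
  dt[, subject := subjectIds(pairs)[pair]]
  # canonical bin-pair order: chromosome rank, then bin index
  ra <- match(dt$chrom_a, lev); rb <- match(dt$chrom_b, lev)
  swap <- rb < ra | (rb == ra & dt$bin_b < dt$bin_a)
  if (any(swap)) {
    tmp_c <- dt$chrom_a[swap]; tmp_b <- dt$bin_a[swap]
    dt[swap, `:=`(chrom_a = chrom_b, bin_a = bin_b)]
    dt[swap, `:=`(chrom_b = tmp_c, bin_b = tmp_b)]
  }
  dt <- dt[!(chrom_a == chrom_b & bin_a == bin_b)]
  if (nrow(dt) == 0)
    return(data.frame(chrom_a = character(0), bin_a = integer(0),
                      start_a = numeric(0), end_a = numeric(0),
                      chrom_b = character(0), bin_b = integer(0),
                      start_b = numeric(0), end_b = numeric(0),
                      carriers = integer(0), rate = numeric(0)))
  agg <- unique(dt[, .(subject, chrom_a, bin_a, chrom_b, bin_b)])[
    , .(carriers = .N), by = .(chrom_a, bin_a, chrom_b, bin_b)]
  agg[, rate := carriers / n_cohort]
  agg <- agg[rate >= min_rate]
  agg <- agg[order(-rate, match(chrom_a, lev), bin_a,
                   match(chrom_b, lev), bin_b)]
  out <- as.data.frame(agg)
  out$start_a <- out$bin_a * bin_size; out$end_a <- out$start_a + bin_size
  out$start_b <- out$bin_b * bin_size; out$end_b <- out$start_b + bin_size
  out[, c("chrom_a", "bin_a", "start_a", "end_a",
          "chrom_b", "bin_b", "start_b", "end_b", "carriers", "rate")]
}

#' Translocation hot regions
#'
#' Fragments from all pairs are pooled across subjects (each pair
#' contributes both fragments) and clustered by single-linkage merge:
#' fragments overlapping or within \code{merge_gap} bp of each other join
#' one cluster. Clusters whose member count (occurrence) is strictly
#' greater than \code{min_occurrence} are returned, sorted by occurrence
#' descending.
#'
#' @param pairs \code{TranslocationPairs}.
#' @param min_occurrence occurrence threshold (default 1000; strict
#'   "greater than").
#' @param merge_gap single-linkage merge distance in bp (default 0 =
#'   overlap or abut).
#' @return \code{GRanges} of hot regions with metadata column
#'   \code{occurrence}; the span of a region is the [min start, max end)
#'   hull of its member fragments.
#' @export
hotRegions <- function(pairs, min_occurrence = 1000, merge_gap = 0) {
  frag <- c(granges(firstFragment(pairs)), granges(secondFragment(pairs)))
  if (length(frag) == 0)
    return(GRanges(occurrence = integer(0)))
  clusters <- mergeIntervals(frag, max_gap = merge_gap)
  occ <- countOverlaps(clusters, frag, ignore.strand = TRUE)
  mcols(clusters)$occurrence <- occ
  hot <- clusters[occ > min_occurrence]
  hot[order(-mcols(hot)$occurrence)]
}

#' Annotate hot regions with stain class, genes, CDS and repeat content
#'
#' @param regions \code{GRanges} from \code{\link{hotRegions}}.
#' @param cytoband cytoband \code{GRanges} (see \code{\link{readCytoband}});
#'   the stain of the band holding the region midpoint is reported.
#' @param genes,cds,repeats optional \code{GRanges} tracks; overlapping
#'   \code{name}s are collapsed comma-separated.
#' @return \code{regions} with added metadata columns \code{gieStain},
#'   \code{genes}, \code{cds}, \code{repeats}.
#' @export
annotateHotRegions <- function(regions, cytoband = NULL, genes = NULL,
                               cds = NULL, repeats = NULL) {
  collapse_names <- function(track) {
    if (is.null(track)) return(rep(NA_character_, length(regions)))
    hits <- findOverlaps(regions, track, ignore.strand = TRUE)
    nm <- mcols(track)$name %||% rep("+", length(track))
    out <- rep("", length(regions))
    if (length(hits)) {
      agg <- tapply(nm[subjectHits(hits)], queryHits(hits),
                    function(x) paste(unique(x), collapse = ","))
      out[as.integer(names(agg))] <- as.character(agg)
    }
    out
  }
  if (!is.null(cytoband)) {
    mid <- GRanges(seqnames(regions),
                   IRanges(start(regions) + width(regions) %/% 2, width = 1))
    hits <- findOverlaps(mid, cytoband, ignore.strand = TRUE)
    stain <- rep(NA_character_, length(regions))
    stain[queryHits(hits)] <- mcols(cytoband)$gieStain[subjectHits(hits)]
    mcols(regions)$gieStain <- stain
  }
  mcols(regions)$genes <- collapse_names(genes)
  mcols(regions)$cds <- collapse_names(cds)
  mcols(regions)$repeats <- collapse_names(repeats)
  regions
}

#' Partner profile of a hot region
#'
#' For every pair with one fragment inside the region, the partner fragment
#' is assigned to a genome-wide bin (by its midpoint; default 1-Mb bins) so
#' each pair contributes once. The concentration statistic is the share of
#' partnered pairs falling into the modal bin: 1 for a fully concentrated
#' partner locus, about 1/k for partners uniform over k bins.
#'
#' @param region single-interval \code{GRanges}.
#' @param pairs \code{TranslocationPairs}.
#' @param bin_size partner bin width in bp (default 1e6).
#' @return list: \code{bins} data.frame (chrom, bin, start, end, count)
#'   sorted by count desc, \code{top_share}, \code{n_pairs}.
#' @export
partnerProfile <- function(region, pairs, bin_size = 1e6) {
  inA <- overlapsAny(firstFragment(pairs), region, ignore.strand = TRUE)
  inB <- overlapsAny(secondFragment(pairs), region, ignore.strand = TRUE)
  sel <- inA | inB
  if (!any(sel)) stop("no pairs have a fragment in the region")
  partner <- c(firstFragment(pairs)[inB & !inA],
               secondFragment(pairs)[inA])
  mid <- start(partner) + width(partner) %/% 2 - 1L  # BED midpoint
  dt <- data.table::data.table(
    chrom = as.character(seqnames(partner)),
    bin = as.integer(mid %/% bin_size))
  agg <- dt[, .(count = .N), by = .(chrom, bin)][order(-count)]
  out <- as.data.frame(agg)
  out$start <- out$bin * bin_size; out$end <- out$start + bin_size
  list(bins = out[, c("chrom", "bin", "start", "end", "count")],
       top_share = out$count[1] / sum(out$count),
       n_pairs = sum(out$count))
}
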