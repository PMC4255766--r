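# Cohort-level descriptive characterization of a filtered call set:
# fragment-size distribution, per-subject burden and genome coverage, and
# overlap with annotation tracks (genes, CDS, Giemsa stain classes).

#' Fragment-size summary
#'
#' Each pair contributes both fragment lengths to the distribution; the
#' large-size count is per pair, triggered when either fragment exceeds the
#' threshold.
#'
#' @param pairs \code{TranslocationPairs}, non-empty.
#' @param large_threshold bp above which a pair counts as large
#'   (default 1000).
#' @param bin_width histogram bin width in bp (default 25).
#' @return list: \code{n_fragments}, \code{mean}, \code{median}, \code{min},
#'   \code{max}, \code{histogram} (data.frame lower/upper/count),
#'   \code{n_large_pairs}.
#' @export
sizeSummary <- function(pairs, large_threshold = 1000, bin_width = 25) {
  if (length(pairs) == 0) stop("no pairs supplied")
  wa <- width(firstFragment(pairs))
  wb <- width(secondFragment(pairs))
  len <- c(wa, wb)
  edges <- seq(bin_width * (min(len) %/% bin_width),
               bin_width * (max(len) %/% bin_width + 1), by = bin_width)
  counts <- tabulate(findInterval(len, edges), nbins = length(edges) - 1)
  list(n_fragments = length(len),
       mean = mean(len), median = stats::median(len),
       min = min(len), max = max(len),
       histogram = data.frame(lower = edges[-length(edges)],
                              upper = edges[-1], count = counts),
       n_large_pairs = sum(wa > large_threshold | wb > large_threshold))
}

#' Per-subject burden and genome coverage
#'
#' @param pairs \code{TranslocationPairs}.
#' @param cohort cohort data.frame (see \code{\link{readCohort}}); subjects
#'   present in \code{pairs} but absent from the cohort are listed in
#'   \code{unresolved} and excluded from the summary.
#' @param genome \code{Seqinfo} used for per-subject union coverage.
#' @return list: \code{per_subject} data.frame (subject, group, n_pairs,
#'   coverage), \code{mean_pairs}, \code{ci95} central 95% interval
#'   (2.5--97.5 percentiles of per-subject counts), \code{pooled_coverage},
#'   \code{unresolved}.
#' @export
subjectSummary <- function(pairs, cohort, genome) {
  subj <- subjectIds(pairs)
  unresolved <- setdiff(unique(subj), cohort$subject)
  keep <- !(subj %in% unresolved)
  pairs <- pairs[keep]; subj <- subj[keep]
  counts <- table(factor(subj, levels = cohort$subject))
  frag <- c(firstFragment(pairs), secondFragment(pairs))
  frag_subj <- factor(c(subj, subj), levels = cohort$subject)
  per_subj <- GenomicRanges::reduce(
    GenomicRanges::split(frag, frag_subj), ignore.strand = TRUE)
  total_bp <- sum(as.numeric(seqlengths(genome)))
  cov <- vapply(S4Vectors::width(per_subj),
                function(w) sum(as.numeric(w)), numeric(1)) / total_bp
  per <- data.frame(subject = cohort$subject, group = cohort$group,
                    n_pairs = as.integer(counts), coverage = cov,
                    stringsAsFactors = FALSE)
  list(per_subject = per,
       mean_pairs = mean(per$n_pairs),
       ci95 = stats::quantile(per$n_pairs, c(0.025, 0.975), names = FALSE),
       pooled_coverage = unionCoverage(frag, genome),
       unresolved = unresolved)
}

#' Fraction of fragments (and covered bases) overlapping a track
#'
#' Both pair fragments enter the denominator. Two variants are reported:
#' the fraction of fragments with any (>= 1 bp) overlap, and the fraction
#' of fragment-covered genome bases lying in the track; the fragment
#' fraction is the headline number. For stain tracks, pass
#' \code{classes = gPositiveClasses()} to restrict to G-positive bands.
#'
#' @param pairs \code{TranslocationPairs}.
#' @param track \code{GRanges}; if \code{classes} is given, intervals are
#'   restricted to those whose \code{gieStain} (or \code{class}) metadata
#'   column is in \code{classes}.
#' @param classes optional character vector of class labels.
#' @return list with \code{fragment_fraction} and \code{base_fraction}.
#' @export
annotationOverlap <- function(pairs, track, classes = NULL) {
  if (!is.null(classes)) {
    lab <- mcols(track)$gieStain %||% mcols(track)$class
    if (is.null(lab)) stop("track has no class/gieStain metadata column")
    track <- track[lab %in% classes]
  }
  frag <- c(firstFragment(pairs), secondFragment(pairs))
  if (length(frag) == 0)
    return(list(fragment_fraction = NA_real_, base_fraction = NA_real_))
  hit <- overlapsAny(frag, track, ignore.strand = TRUE)
  covered <- reduce(granges(frag), ignore.strand = TRUE)
  inter <- GenomicRanges::intersect(covered, reduce(granges(track)),
                                    ignore.strand = TRUE)
  list(fragment_fraction = mean(hit),
       base_fraction = sum(as.numeric(width(inter))) /
         sum(as.numeric(width(covered))))
}

#' Giemsa-positive stain classes
#'
#' @return the four G-positive stain class labels.
#' @export
gPositiveClasses <- function() c("gpos25", "gpos50", "gpos75", "gpos100")
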