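# Two-stage false-positive filter for translocation call sets, as used for
# low-coverage short-read data: a threshold-free simple-repeat filter and a
# low-mappability overlap filter with kind-specific thresholds
# (intrachromosomal 85%, interchromosomal 50%), preceded by per-subject
# exact-duplicate removal. Removal order is fixed (dedupe -> repeat ->
# mappability) for attribution only; the predicates are independent, so the
# surviving set does not depend on the order.

#' Filter configuration
#'
#' @param intra_lowmap_threshold low-mappability overlap fraction at or
#'   above which an intrachromosomal pair is removed (default 0.85).
#' @param inter_lowmap_threshold same for interchromosomal pairs
#'   (default 0.50).
#' @param dedupe logical: remove per-subject exact duplicates first.
#' @return list of class \code{filter_config}.
#' @export
filterConfig <- function(intra_lowmap_threshold = 0.85,
                         inter_lowmap_threshold = 0.50,
                         dedupe = TRUE) {
  if (intra_lowmap_threshold <= 0 || intra_lowmap_threshold > 1 ||
      inter_lowmap_threshold <= 0 || inter_lowmap_threshold > 1)
    stop("thresholds must lie in (0, 1]")
  structure(list(intra_lowmap_threshold = intra_lowmap_threshold,
                 inter_lowmap_threshold = inter_lowmap_threshold,
                 dedupe = isTRUE(dedupe)),
            class = "filter_config")
}

.pair_key <- function(pairs) {
  paste(subjectIds(pairs),
        as.character(seqnames(firstFragment(pairs))),
        start(firstFragment(pairs)), end(firstFragment(pairs)),
        as.character(seqnames(secondFragment(pairs))),
        start(secondFragment(pairs)), end(secondFragment(pairs)),
        sep = "\r")
}

#' Remove per-subject exact-duplicate calls
#'
#' Two calls are duplicates iff they share the subject id and both fragment
#' coordinates after canonicalization. The first occurrence (input order) is
#' kept; identical coordinates in different subjects are not duplicates.
#'
#' @param pairs \code{TranslocationPairs}.
#' @return list with \code{pairs} (deduplicated) and \code{removed} (count).
#' @export
dedupePairs <- function(pairs) {
  dup <- duplicated(.pair_key(pairs))
  list(pairs = pairs[!dup], removed = sum(dup))
}

#' Simple-repeat filter
#'
#' Removes a pair when either fragment overlaps any repeat interval by at
#' least 1 bp (threshold-free any-overlap).
#'
#' @param pairs \code{TranslocationPairs}.
#' @param repeat_track \code{GRanges} of simple-repeat intervals.
#' @return list with \code{pairs} (survivors) and \code{removed} (count).
#' @export
repeatFilter <- function(pairs, repeat_track) {
  hit <- overlapsAny(firstFragment(pairs), repeat_track,
                     ignore.strand = TRUE) |
         overlapsAny(secondFragment(pairs), repeat_track,
                     ignore.strand = TRUE)
  list(pairs = pairs[!hit], removed = sum(hit))
}

#' Low-mappability filter
#'
#' For each pair the overlap fraction of each fragment with the union of
#' the low-mappability track is computed; the pair is removed iff the
#' larger of the two fractions is at least the threshold for its kind
#' (intrachromosomal 0.85, interchromosomal 0.50 by default; comparisons
#' are inclusive, "at least").
#'
#' @param pairs \code{TranslocationPairs}.
#' @param lowmap_track \code{GRanges} of low-mappability intervals.
#' @param config \code{\link{filterConfig}}.
#' @return list with \code{pairs} and \code{removed}.
#' @export
mappabilityFilter <- function(pairs, lowmap_track, config = filterConfig()) {
  fa <- overlapFraction(firstFragment(pairs), lowmap_track)
  fb <- overlapFraction(secondFragment(pairs), lowmap_track)
  thr <- ifelse(pairKind(pairs) == "intra",
                config$intra_lowmap_threshold,
                config$inter_lowmap_threshold)
  drop <- pmax(fa, fb) >= thr
  list(pairs = pairs[!drop], removed = sum(drop))
}

#' Run the full filter chain with a report
#'
#' Order: dedupe, simple-repeat, low-mappability. Passing \code{NULL} for a
#' track disables that stage (both disabled with dedupe off is the
#' identity).
#'
#' @param pairs \code{TranslocationPairs}.
#' @param repeat_track,lowmap_track \code{GRanges} or \code{NULL}.
#' @param config \code{\link{filterConfig}}.
#' @return list with \code{pairs} (survivors) and \code{report}
#'   (\code{\linkS4class{FilterReport}}).
#' @export
runFilters <- function(pairs, repeat_track = NULL, lowmap_track = NULL,
                       config = filterConfig()) {
  n_in <- length(pairs)
  n_dup <- n_rep <- n_map <- 0L
  if (config$dedupe) {
    st <- dedupePairs(pairs); pairs <- st$pairs; n_dup <- st$removed
  }
  if (!is.null(repeat_track)) {
    st <- repeatFilter(pairs, repeat_track)
    pairs <- st$pairs; n_rep <- st$removed
  }
  if (!is.null(lowmap_track)) {
    st <- mappabilityFilter(pairs, lowmap_track, config)
    pairs <- st$pairs; n_map <- st$removed
  }
  list(pairs = pairs,
       report = FilterReport(n_in, removedDuplicate = n_dup,
                             removedRepeat = n_rep,
                             removedMappability = n_map))
}
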