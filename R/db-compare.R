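# Comparison with external translocation catalogs: cytoband designations
# are converted to base-pair intervals with a UCSC-style cytoband track,
# then each catalog record is scored with the same carrier semantics as
# the recurrence module.

#' Convert a cytoband designation to a base-pair interval
#'
#' Band matching is prefix-hierarchical: query band "q11" matches
#' sub-bands "q11.1", "q11.21", ...; the result is the [min start,
#' max end) union of all bands whose name starts with the query on that
#' chromosome.
#'
#' @param chrom chromosome name (e.g. "chr11").
#' @param band band designation (e.g. "q23", "q11.21", "p1").
#' @param cytoband cytoband \code{GRanges} (see \code{\link{readCytoband}}).
#' @return single-interval \code{GRanges}.
#' @export
bandToInterval <- function(chrom, band, cytoband) {
  on_chrom <- cytoband[as.character(seqnames(cytoband)) == chrom]
  hit <- on_chrom[startsWith(mcols(on_chrom)$band, band)]
  if (length(hit) == 0)
    stop("no cytoband matching ", chrom, ":", band)
  GRanges(chrom, IRanges(min(start(hit)), max(end(hit))))
}

#' Overlap of a call set with a translocation catalog
#'
#' Every catalog record (band-level records converted to bp via
#' \code{\link{bandToInterval}}) is scored with
#' \code{\link{regionPairDetection}}: its carrier count and detection rate
#' in the cohort. The summary reports the fraction of records carried by
#' at least \code{min_carriers} subjects and the mean per-record rate.
#' Records that cannot be converted (unresolvable band) are excluded and
#' listed.
#'
#' @param pairs \code{TranslocationPairs}.
#' @param cohort cohort data.frame.
#' @param catalog parsed catalog data.frame from \code{\link{readCatalog}}.
#' @param cytoband cytoband \code{GRanges} for band conversion.
#' @param min_carriers carrier count at which a record counts as
#'   "overlapped" (default 1).
#' @return list: \code{records} data.frame (record, source, carriers,
#'   rate), \code{fraction_overlapped}, \code{mean_rate},
#'   \code{excluded} character vector of unconvertible record ids.
#' @export
catalogOverlap <- function(pairs, cohort, catalog, cytoband,
                           min_carriers = 1) {
  res <- data.frame(record = catalog$record, source = catalog$source,
                    carriers = NA_integer_, rate = NA_real_,
                    stringsAsFactors = FALSE)
  excluded <- character(0)
  for (i in seq_len(nrow(catalog))) {
    rec <- catalog[i, ]
    loc <- tryCatch({
      ra <- if (!is.na(rec$band_a))
        bandToInterval(rec$chrom_a, rec$band_a, cytoband)
      else GRanges(rec$chrom_a, IRanges(rec$start_a + 1, rec$end_a))
      rb <- if (!is.na(rec$band_b))
        bandToInterval(rec$chrom_b, rec$band_b, cytoband)
      else GRanges(rec$chrom_b, IRanges(rec$start_b + 1, rec$end_b))
      list(a = ra, b = rb)
    }, error = function(e) NULL)
    if (is.null(loc)) { excluded <- c(excluded, rec$record); next }
    det <- regionPairDetection(pairs, cohort, loc$a, loc$b)
    res$carriers[i] <- det$overall$carriers
    res$rate[i] <- det$overall$rate
  }
  ok <- !is.na(res$carriers)
  list(records = res[ok, , drop = FALSE],
       fraction_overlapped = if (any(ok))
         mean(res$carriers[ok] >= min_carriers) else NA_real_,
       mean_rate = if (any(ok)) mean(res$rate[ok]) else NA_real_,
       excluded = excluded)
}
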