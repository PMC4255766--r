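# Readers and writers for the external formats the pipeline touches:
# BEDPE call sets, UCSC cytoBand.txt, cohort tables and translocation
# catalogs. All readers are gzip-transparent and reject malformed rows
# explicitly instead of coercing them.

.CYTOBAND_STAINS <- c("gpos100", "gpos75", "gpos50", "gpos25",
                      "gneg", "acen", "gvar", "stalk")

.read_tsv <- function(path, ...) {
  utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                    comment.char = "#", colClasses = "character",
                    fill = TRUE, ...)
}

#' Read a BEDPE translocation call set
#'
#' Expects at least 7 tab-separated columns: chromA, startA, endA, chromB,
#' startB, endB, name. The name column carries the subject id, so one file
#' may hold one subject or a whole cohort. Coordinates are 0-based
#' half-open. Rows with unparseable or empty intervals are collected into a
#' reject report (available as \code{metadata(x)$rejects}) rather than
#' silently dropped; pairs are canonicalized on the way in.
#'
#' @param path BEDPE file (gzip transparent).
#' @param seqinfo optional \code{Seqinfo} genome model used to validate
#'   chromosome names and bounds.
#' @return \code{TranslocationPairs}; the reject report is a data.frame
#'   with columns \code{line}, \code{reason}.
#' @export
readBedpe <- function(path, seqinfo = NULL) {
  df <- tryCatch(.read_tsv(path), error = function(e) NULL)
  empty <- TranslocationPairs(GRanges(seqinfo = seqinfo %||% Seqinfo()),
                              GRanges(seqinfo = seqinfo %||% Seqinfo()),
                              character(0),
                              metadata = list(rejects = .empty_rejects()))
  if (is.null(df) || nrow(df) == 0) {
    warning("empty BEDPE file: ", path)
    return(empty)
  }
  if (ncol(df) < 7) stop("BEDPE needs >= 7 columns: ", path)
  sa <- suppressWarnings(as.numeric(df[[2]]))
  ea <- suppressWarnings(as.numeric(df[[3]]))
  sb <- suppressWarnings(as.numeric(df[[5]]))
  eb <- suppressWarnings(as.numeric(df[[6]]))
  reason <- rep(NA_character_, nrow(df))
  bad_num <- is.na(sa) | is.na(ea) | is.na(sb) | is.na(eb)
  reason[bad_num] <- "unparseable coordinates"
  degen <- !bad_num & (ea <= sa | eb <= sb)
  reason[degen] <- "empty interval"
  if (!is.null(seqinfo)) {
    known <- seqlevels(seqinfo)
    bad_chr <- is.na(reason) &
      (!(df[[1]] %in% known) | !(df[[4]] %in% known))
    reason[bad_chr] <- "unknown chromosome"
    lens <- seqlengths(seqinfo)
    oob <- is.na(reason) &
      (ea > lens[df[[1]]] | eb > lens[df[[4]]] | sa < 0 | sb < 0)
    reason[oob] <- "outside chromosome bounds"
  }
  keep <- is.na(reason)
  rejects <- data.frame(line = which(!keep), reason = reason[!keep],
                        stringsAsFactors = FALSE)
  if (!any(keep)) {
    empty@metadata$rejects <- rejects
    return(empty)
  }
  a <- grFromBed(df[[1]][keep], sa[keep], ea[keep], seqinfo = seqinfo)
  b <- grFromBed(df[[4]][keep], sb[keep], eb[keep], seqinfo = seqinfo)
  TranslocationPairs(a, b, df[[7]][keep],
                     metadata = list(rejects = rejects))
}

.empty_rejects <- function() {
  data.frame(line = integer(0), reason = character(0),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a translocation call set as BEDPE
#'
#' Round-trips losslessly with \code{\link{readBedpe}} on canonical records.
#'
#' @param pairs \code{TranslocationPairs}.
#' @param path output path; a \code{.gz} suffix writes gzip.
#' @return \code{path}, invisibly.
#' @export
writeBedpe <- function(pairs, path) {
  df <- as.data.frame(pairs)[, c("chromA", "startA", "endA",
                                 "chromB", "startB", "endB", "subject")]
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE,
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Read a UCSC cytoBand.txt file
#'
#' Five tab-separated columns: chrom, start, end, band name, Giemsa stain
#' class. Stain classes must come from the eight-class vocabulary
#' (gpos100, gpos75, gpos50, gpos25, gneg, acen, gvar, stalk), and bands
#' must not overlap within a chromosome.
#'
#' @param path cytoband file (gzip transparent).
#' @param seqinfo optional \code{Seqinfo}.
#' @return \code{GRanges} with metadata columns \code{band} and
#'   \code{gieStain}.
#' @export
readCytoband <- function(path, seqinfo = NULL) {
  df <- .read_tsv(path)
  if (ncol(df) < 5) stop("cytoband file needs 5 columns: ", path)
  bad <- !(df[[5]] %in% .CYTOBAND_STAINS)
  if (any(bad))
    stop(sprintf("unknown stain label '%s' at line %d",
                 df[[5]][which(bad)[1]], which(bad)[1]))
  gr <- grFromBed(df[[1]], as.numeric(df[[2]]), as.numeric(df[[3]]),
                  seqinfo = seqinfo)
  mcols(gr)$band <- df[[4]]
  mcols(gr)$gieStain <- df[[5]]
  cov <- GenomicRanges::coverage(gr)
  if (any(vapply(cov, function(x) any(S4Vectors::runValue(x) > 1), logical(1))))
    stop("overlapping cytobands within a chromosome")
  gr
}

#' Read a cohort table
#'
#' Tab-separated with header: subject, group, and optionally subgroup and
#' gender (M/F/unknown). Subject ids must be unique.
#'
#' @param path cohort TSV (gzip transparent).
#' @return data.frame with columns subject, group, subgroup, gender.
#' @export
readCohort <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character")
  if (!all(c("subject", "group") %in% names(df)))
    stop("cohort table needs 'subject' and 'group' columns")
  if (anyDuplicated(df$subject))
    stop("duplicate subject ids in cohort table")
  if (is.null(df$subgroup)) df$subgroup <- NA_character_
  if (is.null(df$gender)) df$gender <- "unknown"
  df$gender[!df$gender %in% c("M", "F")] <- "unknown"
  df[, c("subject", "group", "subgroup", "gender")]
}

#' Parse cytogenetic translocation notation
#'
#' Parses \code{t(A;B)(bandA;bandB)} into its two cytoband loci, e.g.
#' \code{t(11;22)(q23;q11)} into chr11 band q23 and chr22 band q11.
#'
#' @param text notation string.
#' @return list with \code{chrom_a}, \code{band_a}, \code{chrom_b},
#'   \code{band_b}; chromosome names carry a \code{chr} prefix.
#' @export
parseTranslocationNotation <- function(text) {
  m <- regmatches(text, regexec(
    "^t\\(([0-9XY]+);([0-9XY]+)\\)\\(([pq][0-9.]*);([pq][0-9.]*)\\)$",
    trimws(text)))[[1]]
  if (length(m) != 5)
    stop("malformed translocation notation: '", text, "'")
  list(chrom_a = paste0("chr", m[2]), band_a = m[4],
       chrom_b = paste0("chr", m[3]), band_b = m[5])
}

#' Read a translocation catalog
#'
#' Tab-separated with header; columns \code{record}, \code{source}, and
#' either a \code{notation} column (cytogenetic \code{t(..)(..)} strings)
#' or explicit 0-based bp columns \code{chrom_a,start_a,end_a,chrom_b,
#' start_b,end_b}. Each record resolves to exactly one representation;
#' malformed records are returned in the \code{rejects} attribute rather
#' than dropped silently.
#'
#' @param path catalog TSV (gzip transparent).
#' @return data.frame with one row per parsed record and columns
#'   \code{record}, \code{source}, \code{chrom_a}, \code{band_a},
#'   \code{start_a}, \code{end_a} (bands NA for bp records and vice versa)
#'   plus the \code{_b} counterparts; attribute \code{rejects} lists
#'   unparseable records.
#' @export
readCatalog <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", fill = TRUE)
  parseCatalog(df)
}

#' @rdname readCatalog
#' @param df a raw catalog data.frame with the same columns as the TSV.
#' @export
parseCatalog <- function(df) {
  if (!all(c("record", "source") %in% names(df)))
    stop("catalog needs 'record' and 'source' columns")
  out <- data.frame(record = df$record, source = df$source,
                    chrom_a = NA_character_, band_a = NA_character_,
                    start_a = NA_real_, end_a = NA_real_,
                    chrom_b = NA_character_, band_b = NA_character_,
                    start_b = NA_real_, end_b = NA_real_,
                    stringsAsFactors = FALSE)
  rejects <- character(0)
  for (i in seq_len(nrow(df))) {
    if (!is.null(df$notation) && nzchar(df$notation[i]) &&
        !is.na(df$notation[i])) {
      loc <- tryCatch(parseTranslocationNotation(df$notation[i]),
                      error = function(e) NULL)
      if (is.null(loc)) { rejects <- c(rejects, df$record[i]); next }
      out$chrom_a[i] <- loc$chrom_a; out$band_a[i] <- loc$band_a
      out$chrom_b[i] <- loc$chrom_b; out$band_b[i] <- loc$band_b
    } else {
      cc <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b")
      if (!all(cc %in% names(df))) { rejects <- c(rejects, df$record[i]); next }
      sa <- suppressWarnings(as.numeric(df$start_a[i]))
      ea <- suppressWarnings(as.numeric(df$end_a[i]))
      sb <- suppressWarnings(as.numeric(df$start_b[i]))
      eb <- suppressWarnings(as.numeric(df$end_b[i]))
      if (anyNA(c(sa, ea, sb, eb)) || ea <= sa || eb <= sb) {
        rejects <- c(rejects, df$record[i]); next
      }
      out$chrom_a[i] <- df$chrom_a[i]; out$start_a[i] <- sa; out$end_a[i] <- ea
      out$chrom_b[i] <- df$chrom_b[i]; out$start_b[i] <- sb; out$end_b[i] <- eb
    }
  }
  keep <- !(out$record %in% rejects)
  res <- out[keep, , drop = FALSE]
  attr(res, "rejects") <- rejects
  res
}
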