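#' @import methods
#' @importFrom S4Vectors metadata DataFrame queryHits subjectHits
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   findOverlaps countOverlaps pintersect reduce granges mcols mcols<-
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom GenomeInfoDb Seqinfo seqlevels seqlengths seqinfo seqinfo<-
NULL

#' TranslocationPairs: paired translocated DNA fragments
#'
#' The atomic record of the pipeline: each element is one called exchange of
#' chromosomal material in one subject, represented by two genomic fragments.
#' Fragments are stored in canonical order (the first fragment is the lesser
#' of the two by chromosome order, then start coordinate), so exact duplicate
#' calls are detectable by coordinate identity. Coordinates are 0-based
#' half-open internally (BED convention); rendering for reports converts to
#' 1-based inclusive.
#'
#' @slot first,second \code{GRanges} of equal length holding the two
#'   fragments of every pair, canonically ordered within each pair.
#' @slot subject character vector of subject identifiers, one per pair.
#' @slot provenance character vector of generator labels (empty or one of
#'   \code{"background"}, \code{"hot"}, \code{"recurrent"},
#'   \code{"track-overlap"}, \code{"duplicate"}); \code{NA} for real data.
#' @slot metadata list of free-form annotations (e.g. the reject report
#'   produced by \code{\link{readBedpe}}).
#'
#' @seealso \code{\link{TranslocationPairs}} for the constructor,
#'   \code{\link{pairKind}}, \code{\link{readBedpe}}.
#' @export
setClass("TranslocationPairs",
  slots = c(
    first      = "GRanges",
    second     = "GRanges",
    subject    = "character",
    provenance = "character",
    metadata   = "list"
  )
)

setValidity("TranslocationPairs", function(object) {
  msg <- NULL
  n <- length(object@first)
  if (length(object@second) != n)
    msg <- c(msg, "first and second fragments differ in length")
  if (length(object@subject) != n)
    msg <- c(msg, "subject vector length differs from pair count")
  if (length(object@provenance) != n)
    msg <- c(msg, "provenance vector length differs from pair count")
  if (n > 0L) {
    if (any(width(object@first) < 1L) || any(width(object@second) < 1L))
      msg <- c(msg, "fragments must have width >= 1 bp")
    ord <- .pairOrderOk(object@first, object@second)
    if (!all(ord))
      msg <- c(msg, sprintf("%d pair(s) not in canonical fragment order",
                            sum(!ord)))
  }
  if (is.null(msg)) TRUE else msg
})

# canonical order: fragment_a <= fragment_b by seqlevel rank then start
.pairOrderOk <- function(a, b) {
  ra <- match(as.character(seqnames(a)), seqlevels(a))
  rb <- match(as.character(seqnames(b)), seqlevels(b))
  ra < rb | (ra == rb & start(a) <= start(b))
}

#' Construct a TranslocationPairs object
#'
#' Builds the container from two fragment \code{GRanges} and a subject id
#' vector, canonicalizing fragment order within each pair (so that
#' \code{first <= second} by chromosome order then start).
#'
#' @param first,second \code{GRanges} of equal length; fragment coordinates
#'   are 0-based half-open, i.e. a BED interval \code{[s, e)} is supplied as
#'   \code{GRanges(chrom, IRanges(s + 1, e))}. Use \code{\link{grFromBed}}
#'   to convert raw BED coordinates.
#' @param subject character vector of subject ids (recycled if length 1).
#' @param provenance optional character vector of generator labels.
#' @param metadata optional list of annotations.
#' @return A \code{TranslocationPairs} object.
#' @examples
#' si <- Seqinfo(c("chr1", "chr2"), c(1e6, 1e6))
#' a <- GRanges("chr2", IRanges(501, 600), seqinfo = si)
#' b <- GRanges("chr1", IRanges(101, 200), seqinfo = si)
#' tp <- TranslocationPairs(a, b, "S1")   # swapped into canonical order
#' pairKind(tp)
#' @export
TranslocationPairs <- function(first, second, subject,
                               provenance = NA_character_,
                               metadata = list()) {
  n <- length(first)
  if (length(second) != n)
    stop("'first' and 'second' must have equal length")
  subject <- rep_len(as.character(subject), n)
  provenance <- rep_len(as.character(provenance), n)
  if (n > 0L) {
    ok <- .pairOrderOk(first, second)
    if (!all(ok)) {
      tmp <- first[!ok]
      first[!ok] <- second[!ok]
      second[!ok] <- tmp
    }
  }
  new("TranslocationPairs", first = granges(first), second = granges(second),
      subject = subject, provenance = provenance, metadata = metadata)
}

#' @describeIn TranslocationPairs-accessors first fragment of every pair
#' @export
firstFragment <- function(x) x@first

#' @describeIn TranslocationPairs-accessors second fragment of every pair
#' @export
secondFragment <- function(x) x@second

#' @describeIn TranslocationPairs-accessors subject id of every pair
#' @export
subjectIds <- function(x) x@subject

#' @describeIn TranslocationPairs-accessors generator provenance labels
#' @export
pairProvenance <- function(x) x@provenance

#' Accessors for TranslocationPairs
#'
#' @param x a \code{TranslocationPairs} object.
#' @name TranslocationPairs-accessors
#' @aliases pairKind
#' @return \code{pairKind} returns a factor with levels \code{intra} /
#'   \code{inter}: a pair is intrachromosomal iff both fragments lie on the
#'   same chromosome.
#' @export
pairKind <- function(x) {
  k <- ifelse(as.character(seqnames(x@first)) ==
              as.character(seqnames(x@second)), "intra", "inter")
  factor(k, levels = c("intra", "inter"))
}

#' @export
setMethod("length", "TranslocationPairs", function(x) length(x@first))

#' @export
setMethod("[", "TranslocationPairs", function(x, i, j, ..., drop = TRUE) {
  initialize(x, first = x@first[i], second = x@second[i],
             subject = x@subject[i], provenance = x@provenance[i])
})

#' @export
setMethod("show", "TranslocationPairs", function(object) {
  n <- length(object)
  k <- table(pairKind(object))
  cat(sprintf(
    "TranslocationPairs with %d pair(s) (%d intra, %d inter), %d subject(s)\n",
    n, k[["intra"]], k[["inter"]], length(unique(object@subject))))
  if (n > 0L) {
    head_n <- min(n, 5L)
    df <- as.data.frame(object)[seq_len(head_n), , drop = FALSE]
    print(df)
    if (n > head_n) cat(sprintf("... and %d more pair(s)\n", n - head_n))
  }
  invisible(object)
})

#' @export
setMethod("c", "TranslocationPairs", function(x, ...) {
  args <- c(list(x), list(...))
  new("TranslocationPairs",
      first = do.call(c, lapply(args, firstFragment)),
      second = do.call(c, lapply(args, secondFragment)),
      subject = unlist(lapply(args, subjectIds)),
      provenance = unlist(lapply(args, pairProvenance)),
      metadata = x@metadata)
})

#' @export
setMethod("as.data.frame", "TranslocationPairs", function(x, ...) {
  data.frame(
    chromA = as.character(seqnames(x@first)),
    startA = start(x@first) - 1L,   # back to BED 0-based
    endA   = end(x@first),
    chromB = as.character(seqnames(x@second)),
    startB = start(x@second) - 1L,
    endB   = end(x@second),
    subject = x@subject,
    kind = as.character(pairKind(x)),
    stringsAsFactors = FALSE)
})

#' FilterReport: accounting for the two-stage false-positive filter
#'
#' Removal counts are attributed to the first applicable stage in the fixed
#' order dedupe -> repeat -> mappability, and always satisfy
#' \code{input == surviving + sum(removed)}.
#'
#' @slot input,surviving pair counts before/after filtering.
#' @slot removedDuplicate,removedRepeat,removedMappability per-stage counts.
#' @export
setClass("FilterReport",
  slots = c(input = "numeric", removedDuplicate = "numeric",
            removedRepeat = "numeric", removedMappability = "numeric",
            surviving = "numeric"))

setValidity("FilterReport", function(object) {
  tot <- object@removedDuplicate + object@removedRepeat +
    object@removedMappability
  if (!isTRUE(all.equal(object@input, object@surviving + tot)))
    "input != surviving + sum(removed)" else TRUE
})

#' @rdname FilterReport-class
#' @param input,removedDuplicate,removedRepeat,removedMappability,surviving
#'   counts; \code{surviving} defaults to the balance.
#' @export
FilterReport <- function(input, removedDuplicate = 0, removedRepeat = 0,
                         removedMappability = 0,
                         surviving = input - removedDuplicate -
                           removedRepeat - removedMappability) {
  new("FilterReport", input = as.numeric(input),
      removedDuplicate = as.numeric(removedDuplicate),
      removedRepeat = as.numeric(removedRepeat),
      removedMappability = as.numeric(removedMappability),
      surviving = as.numeric(surviving))
}

#' @rdname FilterReport-class
#' @param x a \code{FilterReport}.
#' @return \code{fractionRemoved} returns \code{1 - surviving/input}.
#' @export
fractionRemoved <- function(x) {
  stopifnot(is(x, "FilterReport"))
  if (x@input == 0) 0 else 1 - x@surviving / x@input
}

#' @export
setMethod("show", "FilterReport", function(object) {
  cat("FilterReport\n",
      sprintf("  input:               %d\n", as.integer(object@input)),
      sprintf("  removed (duplicate): %d\n",
              as.integer(object@removedDuplicate)),
      sprintf("  removed (repeat):    %d\n", as.integer(object@removedRepeat)),
      sprintf("  removed (lowmap):    %d\n",
              as.integer(object@removedMappability)),
      sprintf("  surviving:           %d (%.2f%% removed)\n",
              as.integer(object@surviving), 100 * fractionRemoved(object)),
      sep = "")
  invisible(object)
})

#' @rdname FilterReport-class
#' @export
setMethod("as.list", "FilterReport", function(x, ...) {
  list(input = x@input, removed_duplicate = x@removedDuplicate,
       removed_repeat = x@removedRepeat,
       removed_mappability = x@removedMappability,
       surviving = x@surviving, fraction_removed = fractionRemoved(x))
})
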