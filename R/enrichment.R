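# Statistics: the interchromosomal enrichment-score matrix, chi-square
# homogeneity of carrier rates across groups, Giemsa stain-class
# enrichment (Fisher), gender effect on per-subject burden (Welch t), and
# hypergeometric gene-set enrichment with Benjamini-Hochberg adjustment.

#' EnrichmentMatrix: observed/expected interchromosomal exchange scores
#'
#' For chromosomes i != j the score is the observed interchromosomal pair
#' count N_ij divided by its expectation under independent marginals,
#' N_i * N_j / N, where N_i is the number of interchromosomal pairs
#' involving chromosome i and N the total interchromosomal pair count:
#' score_ij = N_ij * N / (N_i * N_j).
#'
#' @slot counts symmetric matrix of N_ij (diagonal NA).
#' @slot scores symmetric matrix of scores; NA where undefined (N_i = 0).
#' @slot marginals named vector N_i.
#' @slot total N, the total interchromosomal pair count.
#' @export
setClass("EnrichmentMatrix",
  slots = c(counts = "matrix", scores = "matrix",
            marginals = "numeric", total = "numeric"))

#' @export
setMethod("show", "EnrichmentMatrix", function(object) {
  sc <- object@scores[upper.tri(object@scores)]
  cat(sprintf(
    "EnrichmentMatrix: %d chromosomes, %d interchromosomal pairs\n",
    nrow(object@scores), as.integer(object@total)))
  cat(sprintf("  scores: median %.3f, max %.3f (%d undefined)\n",
              stats::median(sc, na.rm = TRUE), max(sc, na.rm = TRUE),
              sum(is.na(sc))))
  invisible(object)
})

#' @rdname EnrichmentMatrix-class
#' @param x an \code{EnrichmentMatrix}.
#' @export
enrichmentScores <- function(x) x@scores

#' @rdname EnrichmentMatrix-class
#' @export
enrichmentCounts <- function(x) x@counts

#' Interchromosomal enrichment-score matrix
#'
#' Intrachromosomal pairs are excluded. Chromosomes with no
#' interchromosomal pairs get NA (undefined) scores, not 0.
#'
#' @param pairs \code{TranslocationPairs} with at least one
#'   interchromosomal pair.
#' @param chromosomes optional character vector fixing the chromosome set
#'   and order (default: seqlevels of the fragments).
#' @return \code{\linkS4class{EnrichmentMatrix}}.
#' @export
enrichmentMatrix <- function(pairs, chromosomes = NULL) {
  inter <- pairs[pairKind(pairs) == "inter"]
  if (length(inter) == 0) stop("no interchromosomal pairs")
  if (is.null(chromosomes))
    chromosomes <- unique(c(seqlevels(firstFragment(inter)),
                            seqlevels(secondFragment(inter))))
  ca <- factor(as.character(seqnames(firstFragment(inter))), chromosomes)
  cb <- factor(as.character(seqnames(secondFragment(inter))), chromosomes)
  tab <- table(ca, cb)
  counts <- unclass(tab + t(tab))   # symmetric N_ij
  diag(counts) <- NA_real_
  marg <- rowSums(counts, na.rm = TRUE)
  N <- length(inter)
  expected <- outer(marg, marg) / N
  scores <- counts * N / (marg %o% marg)
  scores[expected == 0 | is.nan(scores)] <- NA_real_
  diag(scores) <- NA_real_
  new("EnrichmentMatrix", counts = counts, scores = scores,
      marginals = marg, total = as.numeric(N))
}

#' Chi-square homogeneity test of carrier rates across groups
#'
#' Pearson chi-square (no continuity correction) on the 2 x k table of
#' carriers vs non-carriers, df = k - 1.
#'
#' @param carriers integer vector of carrier counts per group.
#' @param sizes integer vector of group sizes (>= carriers, > 0).
#' @return list: \code{statistic}, \code{df}, \code{p.value}.
#' @export
groupRateTest <- function(carriers, sizes) {
  if (length(carriers) != length(sizes) || length(carriers) < 2)
    stop("need carrier and size vectors for >= 2 groups")
  if (any(sizes <= 0)) stop("group sizes must be positive")
  if (any(carriers > sizes)) stop("carriers exceed group size")
  tab <- rbind(carriers, sizes - carriers)
  if (any(rowSums(tab) == 0)) {        # all or none carriers everywhere
    return(list(statistic = 0, df = length(carriers) - 1L, p.value = 1))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}

#' Stain-class enrichment of translocated fragments
#'
#' Tests whether fragments preferentially fall in a set of Giemsa stain
#' classes. The 2 x 2 table contrasts the fragments (overlapping the class
#' union vs not) with the genome's base composition, rescaled to
#' fragment-equivalent units (class bp and non-class bp each divided by the
#' mean fragment length and rounded), and applies a two-sided Fisher exact
#' test. The table is returned so alternative constructions can be
#' substituted.
#'
#' @param pairs \code{TranslocationPairs}.
#' @param cytoband cytoband \code{GRanges} tiling the genome.
#' @param classes stain classes of interest (default the G-positive set).
#' @return list: \code{table} (2 x 2), \code{odds_ratio} (sample odds
#'   ratio; Inf reported when a cell is empty), \code{p.value}.
#' @export
stainEnrichment <- function(pairs, cytoband,
                            classes = gPositiveClasses()) {
  if (!any(mcols(cytoband)$gieStain %in% classes))
    stop("class absent from cytoband track: ",
         paste(classes, collapse = ","))
  cls <- cytoband[mcols(cytoband)$gieStain %in% classes]
  frag <- c(firstFragment(pairs), secondFragment(pairs))
  hit <- overlapsAny(frag, cls, ignore.strand = TRUE)
  mean_len <- mean(width(frag))
  in_bp <- sum(as.numeric(width(reduce(granges(cls)))))
  tot_bp <- sum(as.numeric(width(reduce(granges(cytoband)))))
  tab <- matrix(c(sum(hit), sum(!hit),
                  round(in_bp / mean_len), round((tot_bp - in_bp) / mean_len)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("fragments", "genome"),
                                c("in_class", "out_class")))
  ht <- stats::fisher.test(tab)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(table = tab, odds_ratio = or, p.value = ht$p.value)
}

#' Gender effect on per-subject translocation burden
#'
#' Welch two-sample t-test of per-subject pair counts between males and
#' females; subjects with unknown gender are excluded.
#'
#' @param counts named numeric vector of per-subject pair counts, or the
#'   \code{per_subject} data.frame from \code{\link{subjectSummary}}.
#' @param cohort cohort data.frame with a \code{gender} column.
#' @return list: \code{statistic}, \code{p.value}, \code{mean_m},
#'   \code{mean_f}.
#' @export
genderTest <- function(counts, cohort) {
  if (is.data.frame(counts))
    counts <- stats::setNames(counts$n_pairs, counts$subject)
  g <- cohort$gender[match(names(counts), cohort$subject)]
  m <- counts[g %in% "M"]; f <- counts[g %in% "F"]
  if (length(m) < 2 || length(f) < 2)
    stop("need >= 2 subjects of each gender")
  if (stats::sd(c(m, f)) == 0)
    return(list(statistic = 0, p.value = 1,
                mean_m = mean(m), mean_f = mean(f)))
  ht <- stats::t.test(m, f)
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       mean_m = mean(m), mean_f = mean(f))
}

#' Hypergeometric gene-set enrichment
#'
#' For every annotation term with C reference genes inside the size bounds,
#' computes the overlap O with the query set, the expectation
#' E = C * k / M (k query genes, M reference genes), the enrichment ratio
#' R = O / E, the hypergeometric upper-tail P[X >= O], and
#' Benjamini-Hochberg adjusted p-values across the surviving terms.
#'
#' @param query character vector of query genes (must be a subset of
#'   \code{reference}).
#' @param annotation data.frame with columns \code{term} and \code{gene}.
#' @param reference character vector: the reference gene universe.
#' @param min_genes,max_genes term size bounds (defaults 15 and 250);
#'   terms outside the bounds are dropped before testing.
#' @return data.frame sorted by rawP with columns term, C, O, E, R,
#'   rawP, adjP.
#' @export
geneSetEnrichment <- function(query, annotation, reference,
                              min_genes = 15, max_genes = 250) {
  query <- unique(query)
  reference <- unique(reference)
  if (length(query) == 0) stop("empty query gene set")
  if (!all(query %in% reference))
    stop("query genes missing from the reference universe")
  annotation <- annotation[annotation$gene %in% reference, , drop = FALSE]
  M <- length(reference); k <- length(query)
  terms <- split(unique(annotation[, c("term", "gene")])$gene,
                 unique(annotation[, c("term", "gene")])$term)
  C <- lengths(terms)
  keep <- C >= min_genes & C <= max_genes
  terms <- terms[keep]; C <- C[keep]
  if (length(terms) == 0)
    return(data.frame(term = character(0), C = integer(0), O = integer(0),
                      E = numeric(0), R = numeric(0), rawP = numeric(0),
                      adjP = numeric(0)))
  O <- vapply(terms, function(g) sum(query %in% g), integer(1))
  E <- C * k / M
  rawP <- stats::phyper(O - 1, C, M - C, k, lower.tail = FALSE)
  out <- data.frame(term = names(terms), C = as.integer(C),
                    O = as.integer(O), E = E, R = O / E, rawP = rawP,
                    adjP = stats::p.adjust(rawP, method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$rawP, out$term), , drop = FALSE]
}
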