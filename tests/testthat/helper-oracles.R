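# Independent brute-force oracles and shared fixtures. The oracles count
# bases or enumerate candidates directly and never call the code paths they
# check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(GenomeInfoDb)
})

# per-base fraction of a single 1-based closed interval covered by a track
bruteOverlapFraction <- function(query, track) {
  vapply(seq_along(query), function(i) {
    q <- query[i]
    pos <- seq(start(q), end(q))
    on_chr <- track[as.character(seqnames(track)) ==
                      as.character(seqnames(q))]
    if (length(on_chr) == 0) return(0)
    covered <- rep(FALSE, length(pos))
    for (j in seq_along(on_chr))
      covered <- covered | (pos >= start(on_chr)[j] & pos <= end(on_chr)[j])
    mean(covered)
  }, numeric(1))
}

# per-base union coverage of a single-chromosome genome
bruteUnionCoverage <- function(intervals, chrom_len) {
  covered <- rep(FALSE, chrom_len)
  for (j in seq_along(intervals))
    covered[seq(start(intervals)[j], end(intervals)[j])] <- TRUE
  mean(covered)
}

# exhaustive (l, d) planted-motif search over all 4^l candidates
bruteMotifSearch <- function(seqs, l, d) {
  alph <- c("A", "C", "G", "T")
  cand <- do.call(paste0, expand.grid(rep(list(alph), l),
                                      stringsAsFactors = FALSE))
  enc <- lapply(seqs, function(s) match(strsplit(s, "")[[1]], alph))
  cm <- t(vapply(strsplit(cand, ""), function(ch) match(ch, alph),
                 integer(l)))
  ok <- rep(TRUE, length(cand))
  for (e in enc) {
    nw <- length(e) - l + 1L
    best <- rep.int(l + 1L, length(cand))
    for (w in seq_len(nw)) {
      win <- e[w:(w + l - 1L)]
      best <- pmin(best,
                   rowSums(cm != matrix(win, nrow(cm), l, byrow = TRUE)))
    }
    ok <- ok & best <= d
  }
  sort(cand[ok])
}

randomDnaSeqs <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
}

# random small call set + tracks on a 2-chromosome toy genome
toyGenome <- function() Seqinfo(c("chr1", "chr2"), c(100000, 100000))

randomPairs <- function(n, genome = toyGenome(), width_range = c(50, 200)) {
  lev <- seqlevels(genome)
  mk <- function() {
    ch <- sample(lev, n, replace = TRUE)
    w <- sample(seq(width_range[1], width_range[2]), n, replace = TRUE)
    st <- floor(runif(n, 0, seqlengths(genome)[ch] - w))
    grFromBed(ch, st, st + w, seqinfo = genome)
  }
  TranslocationPairs(mk(), mk(), sample(paste0("S", 1:5), n, replace = TRUE))
}

randomTrack <- function(n, genome = toyGenome(), width_range = c(30, 400)) {
  lev <- seqlevels(genome)
  ch <- sample(lev, n, replace = TRUE)
  w <- sample(seq(width_range[1], width_range[2]), n, replace = TRUE)
  st <- floor(runif(n, 0, seqlengths(genome)[ch] - w))
  grFromBed(ch, st, st + w, seqinfo = genome)
}

# background-only simulation (no planted structure); used where clean
# Poisson burden or null behaviour is needed
backgroundOnlyConfig <- function(seed, group_sizes, pairs_per_subject,
                                 ...) {
  empty_hot <- data.frame(name = character(0), chrom = character(0),
                          start = numeric(0), end = numeric(0),
                          mode = character(0), occurrence = numeric(0),
                          carrier_prob = numeric(0),
                          partner_chrom = character(0),
                          partner_start = numeric(0),
                          partner_end = numeric(0),
                          stringsAsFactors = FALSE)
  empty_rec <- data.frame(name = character(0), chrom_a = character(0),
                          start_a = numeric(0), end_a = numeric(0),
                          chrom_b = character(0), start_b = numeric(0),
                          end_b = numeric(0), stringsAsFactors = FALSE)
  simulationConfig(seed = seed, group_sizes = group_sizes,
                   pairs_per_subject = pairs_per_subject,
                   hot_regions = empty_hot, recurrent_pairs = empty_rec,
                   recurrent_probs = matrix(numeric(0), nrow = 0,
                                            ncol = length(group_sizes)),
                   catalog_planted = 0, ...)
}

# one desk-scale simulation + filtered call set shared across acceptance
# checks (computed once per test run)
.desk_cache <- new.env(parent = emptyenv())
deskRun <- function(seed = 101) {
  key <- paste0("s", seed)
  if (is.null(.desk_cache[[key]])) {
    sim <- simulateStudy(simulationConfig(seed = seed))
    fl <- runFilters(sim$pairs, sim$tracks$repeats, sim$tracks$lowmap)
    .desk_cache[[key]] <- list(sim = sim, filtered = fl$pairs,
                               report = fl$report)
  }
  .desk_cache[[key]]
}
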