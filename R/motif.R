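# Motif analysis over hot-region sequences: exact/mismatch occurrence
# scanning on both strands, and a brute-force planted (l,d) motif search
# (all l-mers present within Hamming distance d in every sequence) at desk
# scale, replacing optimized planted-motif-search implementations.

#' @importFrom Biostrings DNAStringSet DNAString reverseComplement
#'   vmatchPattern readDNAStringSet writeXStringSet
NULL

.as_dss <- function(sequences) {
  if (is(sequences, "DNAStringSet")) return(sequences)
  out <- DNAStringSet(toupper(as.character(sequences)))
  names(out) <- names(sequences)
  out
}

.check_motif <- function(motif) {
  if (!grepl("^[ACGT]+$", toupper(motif)))
    stop("motif contains invalid characters: ", motif)
  toupper(motif)
}

#' Motif occurrence across sequences
#'
#' Scans every sequence for the motif with up to \code{max_mismatch}
#' mismatches. Both strands are scanned by default (a hit of the reverse
#' complement on the forward sequence is a minus-strand hit); ambiguity
#' codes (N) never match. Positions are 1-based offsets on the forward
#' sequence.
#'
#' @param sequences named character vector or \code{DNAStringSet}.
#' @param motif DNA string over A/C/G/T.
#' @param max_mismatch maximum Hamming mismatches (default 0).
#' @param both_strands scan the reverse complement too (default TRUE).
#' @return list: \code{hits} data.frame (sequence, start, strand,
#'   mismatches), \code{fraction} of sequences with >= 1 hit.
#' @export
motifOccurrence <- function(sequences, motif, max_mismatch = 0,
                            both_strands = TRUE) {
  seqs <- .as_dss(sequences)
  motif <- .check_motif(motif)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (nchar(motif) > min(Biostrings::width(seqs)))
    stop("motif longer than the shortest sequence")
  pats <- list(`+` = DNAString(motif))
  if (both_strands)
    pats$`-` <- reverseComplement(DNAString(motif))
  hits <- list()
  for (strand in names(pats)) {
    mi <- vmatchPattern(pats[[strand]], seqs,
                        max.mismatch = max_mismatch, fixed = TRUE)
    n_hit <- lengths(mi)
    if (sum(n_hit) == 0) next
    st <- unlist(lapply(mi, IRanges::start), use.names = FALSE)
    hits[[strand]] <- data.frame(
      sequence = rep(names(seqs), n_hit), start = st, strand = strand,
      mismatches = .count_mismatches(seqs, rep(seq_along(seqs), n_hit),
                                     st, as.character(pats[[strand]])),
      stringsAsFactors = FALSE)
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(sequence = character(0), start = integer(0),
               strand = character(0), mismatches = integer(0))
  hits <- hits[order(match(hits$sequence, names(seqs)), hits$start), ,
               drop = FALSE]
  rownames(hits) <- NULL
  list(hits = hits,
       fraction = mean(names(seqs) %in% hits$sequence))
}

.count_mismatches <- function(seqs, seq_idx, starts, pattern) {
  l <- nchar(pattern)
  pat <- strsplit(pattern, "")[[1]]
  vapply(seq_along(seq_idx), function(i) {
    w <- strsplit(as.character(Biostrings::subseq(
      seqs[[seq_idx[i]]], starts[i], starts[i] + l - 1)), "")[[1]]
    sum(w != pat)
  }, integer(1))
}

#' Hamming d-neighborhood of a DNA word
#'
#' @param word DNA string over A/C/G/T.
#' @param d maximum Hamming distance (>= 0).
#' @return character vector of all words within distance \code{d},
#'   including \code{word} itself.
#' @export
hammingNeighborhood <- function(word, d) {
  word <- .check_motif(word)
  alph <- c("A", "C", "G", "T")
  cur <- word
  if (d == 0) return(cur)
  out <- cur
  for (step in seq_len(d)) {
    nxt <- unique(unlist(lapply(out, function(w) {
      ch <- strsplit(w, "")[[1]]
      unlist(lapply(seq_along(ch), function(i) {
        vapply(alph[alph != ch[i]], function(a) {
          x <- ch; x[i] <- a; paste(x, collapse = "")
        }, character(1))
      }))
    })))
    out <- unique(c(out, nxt))
  }
  out
}

# min Hamming distance from each candidate (rows of integer matrix) to any
# window of an integer-encoded sequence
.min_dist_to_seq <- function(cand_mat, seq_int, l) {
  n_win <- length(seq_int) - l + 1L
  best <- rep.int(l + 1L, nrow(cand_mat))
  for (w in seq_len(n_win)) {
    win <- seq_int[w:(w + l - 1L)]
    d <- rowSums(cand_mat != matrix(win, nrow(cand_mat), l, byrow = TRUE))
    best <- pmin(best, d)
  }
  best
}

.encode_seq <- function(s) {
  match(strsplit(toupper(s), "")[[1]], c("A", "C", "G", "T"))
}

.encode_words <- function(words) {
  t(vapply(strsplit(words, ""),
           function(ch) match(ch, c("A", "C", "G", "T")),
           integer(nchar(words[1]))))
}

#' Brute-force planted (l,d) motif search
#'
#' Returns every l-mer that occurs within Hamming distance \code{d} in
#' every input sequence. Candidates are the union of the d-neighborhoods
#' of the observed l-mers (sufficient: any solution is within d of a
#' window of every sequence); each candidate is verified against all
#' sequences. Output is deterministic, sorted lexicographically.
#' Feasibility is guarded at l <= 14, d <= 3.
#'
#' @param sequences named character vector or \code{DNAStringSet} (>= 2
#'   sequences over A/C/G/T).
#' @param l motif length.
#' @param d maximum mismatches per occurrence.
#' @return character vector of motifs, lexicographic order.
#' @export
plantedMotifSearch <- function(sequences, l, d) {
  if (l > 14 || d > 3)
    stop("brute-force guard: need l <= 14 and d <= 3")
  seqs <- toupper(as.character(.as_dss(sequences)))
  if (length(seqs) < 2) stop("need >= 2 sequences")
  if (any(!grepl("^[ACGT]+$", seqs)))
    stop("sequences must be over A/C/G/T")
  if (any(nchar(seqs) < l)) stop("sequence shorter than motif length")
  d <- min(d, l)
  enc <- lapply(seqs, .encode_seq)
  # seed from the sequence with fewest windows; its windows' neighborhoods
  # cover every possible solution
  pivot <- which.min(nchar(seqs))
  s <- seqs[[pivot]]
  wins <- unique(vapply(seq_len(nchar(s) - l + 1L),
                        function(i) substr(s, i, i + l - 1L), character(1)))
  cand <- unique(unlist(lapply(wins, hammingNeighborhood, d = d)))
  cand_mat <- .encode_words(cand)
  ok <- rep(TRUE, length(cand))
  for (e in enc) {
    if (!any(ok)) break
    ok[ok] <- .min_dist_to_seq(cand_mat[ok, , drop = FALSE], e, l) <= d
  }
  sort(cand[ok])
}
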