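# Ground-truthed synthetic study generator. Emits every input the pipeline
# consumes -- per-subject BEDPE call sets, repeat/low-mappability/gene/CDS
# tracks, a cytoband file, a cohort table, a translocation catalog and
# hot-region FASTA -- with planted structure (hot regions, recurrent region
# pairs with group-specific carrier probabilities, a planted motif) and a
# per-pair provenance label, so every stage can be checked against known
# truth without any external download.

#' Simulation configuration
#'
#' Defaults are the desk-scale study conditions: a 5 x 10 Mb genome, 200
#' subjects in 5 groups, about 2,000 calls per subject, fragment sizes from
#' a truncated lognormal calibrated to mean 102 bp / median 101 bp on
#' [65, 2000] with a small uniform heavy-tail component above 1 kb, an
#' intrachromosomal share of 0.11% of surviving calls, planted
#' track-overlapping calls sized so the filter chain removes about 18.7%,
#' one concentrated hot-region pair carried by 76.9% of subjects plus one
#' dispersed hot region (occurrence 1,500 each), two further recurrent
#' region pairs with group-specific carrier probabilities, and the 10-mer
#' motif CCCAGGCTGG planted in 75% of hot-region sequences.
#'
#' @param seed integer RNG seed; every output is reproducible bit-for-bit
#'   under a fixed seed.
#' @param n_chromosomes,chrom_length genome model.
#' @param group_sizes named integer vector of cohort group sizes.
#' @param pairs_per_subject Poisson mean of background calls per subject.
#' @param intra_fraction share of surviving calls that are
#'   intrachromosomal (fixed composition, so the target is met exactly up
#'   to rounding).
#' @param frag_meanlog,frag_sdlog,frag_min,frag_max,frag_tail_p,frag_tail_range
#'   fragment-size model: truncated lognormal body plus a
#'   \code{frag_tail_p} uniform tail on \code{frag_tail_range}.
#' @param repeat_overlap_fraction,lowmap_overlap_fraction shares of each
#'   subject's background calls planted to overlap the repeat /
#'   low-mappability track (and hence be removed by the filters).
#' @param duplicate_fraction share of calls duplicated verbatim to give the
#'   dedupe stage work.
#' @param repeats_per_chrom,repeat_length,lowmap_per_chrom,lowmap_length
#'   track geometry.
#' @param genes_per_chrom,gene_length gene-track geometry (CDS exons are
#'   placed inside genes).
#' @param hot_regions data.frame of planted hot regions: chrom, start, end
#'   (BED), mode ("concentrated" pairs the region with a fixed partner
#'   locus; "spread" draws uniform partners), occurrence, carrier_prob and
#'   partner locus columns (concentrated mode only).
#' @param recurrent_pairs data.frame of planted recurrent region pairs
#'   (name + both loci, BED coordinates).
#' @param recurrent_probs matrix of per-group carrier probabilities, one
#'   row per recurrent pair, columns the cohort groups.
#' @param motif,motif_fraction planted motif and the fraction of hot-region
#'   sequences carrying it.
#' @param catalog_planted,catalog_empty catalog record counts referencing
#'   planted loci / deliberately uncarried loci.
#' @return list of class \code{simulation_config}.
#' @export
simulationConfig <- function(
    seed = 1,
    n_chromosomes = 5,
    chrom_length = 1e7,
    group_sizes = c(AFR = 40, AMR = 40, ASN = 40, EUR = 40, SAN = 40),
    pairs_per_subject = 2000,
    intra_fraction = 0.0011,
    frag_meanlog = 4.615117, frag_sdlog = 0.108569,
    frag_min = 65, frag_max = 2000,
    frag_tail_p = 3e-4, frag_tail_range = c(1000, 1886),
    repeat_overlap_fraction = 0.105,
    lowmap_overlap_fraction = 0.078,
    duplicate_fraction = 0.005,
    repeats_per_chrom = 120, repeat_length = 1250,
    lowmap_per_chrom = 100, lowmap_length = 1500,
    genes_per_chrom = 40, gene_length = 1e5,
    hot_regions = NULL,
    recurrent_pairs = NULL,
    recurrent_probs = NULL,
    motif = "CCCAGGCTGG", motif_fraction = 0.75,
    catalog_planted = 15, catalog_empty = 5,
    n_terms = 12, term_size_range = c(15, 60)) {
  if (is.null(hot_regions))
    hot_regions <- data.frame(
      name = c("hotB", "hotD"),
      chrom = c("chr2", "chr1"),
      start = c(2000000, 5000000), end = c(2000400, 5000400),
      mode = c("concentrated", "spread"),
      occurrence = c(1500, 1500),
      carrier_prob = c(0.769, NA),
      partner_chrom = c("chr4", NA),
      partner_start = c(6000000, NA), partner_end = c(6000400, NA),
      stringsAsFactors = FALSE)
  if (is.null(recurrent_pairs))
    recurrent_pairs <- data.frame(
      name = c("R2", "R3"),
      chrom_a = c("chr3", "chr1"), start_a = c(4000000, 1000000),
      end_a = c(4000200, 1000200),
      chrom_b = c("chr5", "chr2"), start_b = c(8000000, 7000000),
      end_b = c(8000200, 7000200),
      stringsAsFactors = FALSE)
  if (is.null(recurrent_probs)) {
    base <- list(c(0.45, 0.40, 0.35, 0.30, 0.35), rep(0.25, 5))
    recurrent_probs <- t(vapply(
      rep_len(base, nrow(recurrent_pairs)),
      function(p) rep_len(p, length(group_sizes)),
      numeric(length(group_sizes))))
    dimnames(recurrent_probs) <- list(recurrent_pairs$name,
                                      names(group_sizes))
  }
  stopifnot(intra_fraction >= 0, intra_fraction <= 1,
            all(recurrent_probs >= 0), all(recurrent_probs <= 1),
            motif_fraction >= 0, motif_fraction <= 1)
  cfg <- list(seed = seed, n_chromosomes = n_chromosomes,
              chrom_length = chrom_length, group_sizes = group_sizes,
              pairs_per_subject = pairs_per_subject,
              intra_fraction = intra_fraction,
              frag_meanlog = frag_meanlog, frag_sdlog = frag_sdlog,
              frag_min = frag_min, frag_max = frag_max,
              frag_tail_p = frag_tail_p, frag_tail_range = frag_tail_range,
              repeat_overlap_fraction = repeat_overlap_fraction,
              lowmap_overlap_fraction = lowmap_overlap_fraction,
              duplicate_fraction = duplicate_fraction,
              repeats_per_chrom = repeats_per_chrom,
              repeat_length = repeat_length,
              lowmap_per_chrom = lowmap_per_chrom,
              lowmap_length = lowmap_length,
              genes_per_chrom = genes_per_chrom, gene_length = gene_length,
              hot_regions = hot_regions,
              recurrent_pairs = recurrent_pairs,
              recurrent_probs = recurrent_probs,
              motif = motif, motif_fraction = motif_fraction,
              catalog_planted = catalog_planted,
              catalog_empty = catalog_empty,
              n_terms = n_terms, term_size_range = term_size_range)
  class(cfg) <- "simulation_config"
  cfg
}

.sim_genome <- function(config) {
  Seqinfo(paste0("chr", seq_len(config$n_chromosomes)),
          rep(config$chrom_length, config$n_chromosomes))
}

.sim_cohort <- function(config) {
  n <- sum(config$group_sizes)
  data.frame(
    subject = sprintf("S%04d", seq_len(n)),
    group = rep(names(config$group_sizes), config$group_sizes),
    subgroup = paste0(rep(names(config$group_sizes), config$group_sizes),
                      "_1"),
    gender = rep(c("M", "F"), length.out = n),
    stringsAsFactors = FALSE)
}

# fragment lengths: truncated-lognormal body + uniform heavy tail
.sim_fraglen <- function(n, config) {
  if (n == 0) return(integer(0))
  tail <- stats::runif(n) < config$frag_tail_p
  out <- numeric(n)
  need <- sum(!tail)
  acc <- numeric(0)
  while (length(acc) < need) {
    x <- stats::rlnorm(max(need, 1000), config$frag_meanlog,
                       config$frag_sdlog)
    acc <- c(acc, x[x >= config$frag_min & x <= config$frag_max])
  }
  out[!tail] <- acc[seq_len(need)]
  out[tail] <- stats::runif(sum(tail), config$frag_tail_range[1],
                            config$frag_tail_range[2])
  pmax(as.integer(round(out)), config$frag_min)
}

# n intervals of fixed length per chromosome, avoiding 'forbidden'
.sim_track <- function(config, genome, n_per_chrom, len, forbidden) {
  out <- GRanges(seqinfo = genome)
  for (chrom in seqlevels(genome)) {
    got <- GRanges(seqinfo = genome)
    guard <- 0
    while (length(got) < n_per_chrom && guard < 50) {
      m <- (n_per_chrom - length(got)) * 2
      st <- as.integer(stats::runif(m, 1, config$chrom_length - len))
      cand <- GRanges(chrom, IRanges(st, width = len), seqinfo = genome)
      cand <- cand[!overlapsAny(cand, forbidden, ignore.strand = TRUE)]
      cand <- cand[!overlapsAny(cand, got, ignore.strand = TRUE)]
      cand <- sort(cand[!duplicated(start(cand))])
      if (length(cand) > 1) {   # drop within-batch overlaps greedily
        keep <- c(TRUE, start(cand)[-1] >
                    cummax(end(cand))[-length(cand)])
        cand <- cand[keep]
      }
      got <- c(got, cand)
      guard <- guard + 1
    }
    out <- c(out, utils::head(sort(got), n_per_chrom))
  }
  out
}

# uniform clean fragments of given lengths avoiding 'forbidden'; optional
# fixed chromosome per fragment
.sim_clean_frags <- function(lens, genome, forbidden, chrom = NULL) {
  n <- length(lens)
  if (n == 0) return(GRanges(seqinfo = genome))
  lev <- seqlevels(genome)
  res <- GRanges(rep("chr1", n), IRanges(rep(1, n), width = 1),
                 seqinfo = genome)
  todo <- seq_len(n)
  guard <- 0
  while (length(todo) && guard < 100) {
    m <- length(todo)
    if (is.null(chrom)) {
      ch <- sample(lev, m, replace = TRUE)
    } else {
      ch <- chrom[todo]
      ch[is.na(ch)] <- sample(lev, sum(is.na(ch)), replace = TRUE)
    }
    maxlen <- seqlengths(genome)[ch]
    st <- as.integer(1 + floor(stats::runif(m) * (maxlen - lens[todo])))
    cand <- GRanges(ch, IRanges(st, width = lens[todo]), seqinfo = genome)
    ok <- !overlapsAny(cand, forbidden, ignore.strand = TRUE)
    res[todo[ok]] <- cand[ok]
    todo <- todo[!ok]
    guard <- guard + 1
  }
  if (length(todo)) stop("could not place ", length(todo),
                         " fragments outside the forbidden regions")
  res
}

# fragments confined to a locus (BED coords); lengths clipped to fit
.sim_locus_frags <- function(n, chrom, start_bed, end_bed, lens, genome) {
  if (n == 0) return(GRanges(seqinfo = genome))
  w <- end_bed - start_bed
  lens <- pmin(lens, w)
  st <- start_bed + floor(stats::runif(n) * (w - lens + 1))
  GRanges(chrom, IRanges(as.integer(st) + 1L, width = as.integer(lens)),
          seqinfo = genome)
}

.sim_cytoband <- function(config, genome) {
  frac <- c(0, 0.12, 0.24, 0.36, 0.50, 0.62, 0.74, 0.87, 1)
  bands <- c("p13", "p12", "p11", "q11.1", "q11.21", "q11.23", "q12", "q13")
  stains <- c("gneg", "gpos50", "acen", "acen", "gpos100", "gneg",
              "gpos75", "gpos25")
  out <- lapply(seqlevels(genome), function(chrom) {
    L <- seqlengths(genome)[[chrom]]
    b <- round(frac * L)
    GRanges(chrom, IRanges(b[-length(b)] + 1, b[-1]),
            band = bands, gieStain = stains, seqinfo = genome)
  })
  do.call(c, out)
}

.sim_genes <- function(config, genome) {
  pitch <- floor(config$chrom_length / config$genes_per_chrom)
  out <- lapply(seqlevels(genome), function(chrom) {
    st <- (seq_len(config$genes_per_chrom) - 1) * pitch + 10000
    g <- GRanges(chrom, IRanges(st + 1, width = config$gene_length),
                 seqinfo = genome)
    mcols(g)$name <- sprintf("GENE_%s_%02d", sub("chr", "", chrom),
                             seq_along(g))
    g
  })
  do.call(c, out)
}

.sim_cds <- function(genes, genome) {
  # 5 exons of 6 kb per gene, evenly spaced within the gene body
  out <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    ex_st <- start(g) + round(seq(0, 0.8, by = 0.2) * width(g))
    cds <- GRanges(seqnames(g), IRanges(ex_st, width = 6000),
                   seqinfo = genome)
    mcols(cds)$name <- rep(mcols(g)$name, 5)
    cds
  })
  do.call(c, out)
}

# term -> gene annotation over the simulated gene universe; one deliberately
# undersized term exercises the size filter
.sim_annotation <- function(config, genes) {
  universe <- mcols(genes)$name
  sizes <- sample(seq(config$term_size_range[1], config$term_size_range[2]),
                  config$n_terms, replace = TRUE)
  rows <- lapply(seq_len(config$n_terms), function(i) {
    data.frame(term = sprintf("T%03d", i),
               gene = sample(universe, sizes[i]),
               stringsAsFactors = FALSE)
  })
  rows[[length(rows) + 1]] <- data.frame(
    term = "T_SMALL", gene = sample(universe, 5),
    stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

.sim_sequences <- function(config, hot_loci) {
  if (is.null(hot_loci) || nrow(hot_loci) == 0)
    return(list(sequences = DNAStringSet(), planted = character(0)))
  n <- nrow(hot_loci)
  lens <- hot_loci$end - hot_loci$start
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  n_plant <- round(config$motif_fraction * n)
  planted <- sort(sample.int(n, n_plant))
  for (i in planted) {
    off <- sample.int(lens[i] - nchar(config$motif) + 1L, 1)
    substr(seqs[i], off, off + nchar(config$motif) - 1L) <- config$motif
  }
  names(seqs) <- sprintf("hot_%s_%d_%d", hot_loci$chrom, hot_loci$start,
                         hot_loci$end)
  list(sequences = DNAStringSet(seqs), planted = names(seqs)[planted])
}

# catalog: records referencing planted recurrent loci (bp and band level)
# plus records placed inside repeat intervals, which filtered call sets can
# never carry
.sim_catalog <- function(config, truth, cytoband, repeats) {
  loci <- truth$recurrent
  n_pl <- config$catalog_planted
  rows <- list()
  band_of <- function(chrom, pos) {
    cb <- cytoband[as.character(seqnames(cytoband)) == chrom]
    mcols(cb)$band[pos >= start(cb) - 1 & pos < end(cb)][1]
  }
  for (i in seq_len(n_pl)) {
    r <- loci[((i - 1) %% nrow(loci)) + 1, ]
    id <- sprintf("R%02d", i)
    if (i %% 2 == 0) {   # band-level record via notation
      rows[[i]] <- data.frame(
        record = id, source = "synthDB",
        notation = sprintf("t(%s;%s)(%s;%s)",
                           sub("chr", "", r$chrom_a), sub("chr", "", r$chrom_b),
                           band_of(r$chrom_a, r$start_a),
                           band_of(r$chrom_b, r$start_b)),
        chrom_a = "", start_a = "", end_a = "",
        chrom_b = "", start_b = "", end_b = "",
        stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(
        record = id, source = "synthDB", notation = "",
        chrom_a = r$chrom_a, start_a = r$start_a, end_a = r$end_a,
        chrom_b = r$chrom_b, start_b = r$start_b, end_b = r$end_b,
        stringsAsFactors = FALSE)
    }
  }
  rep_pick <- sample(seq_along(repeats), 2 * config$catalog_empty)
  for (j in seq_len(config$catalog_empty)) {
    a <- repeats[rep_pick[2 * j - 1]]; b <- repeats[rep_pick[2 * j]]
    rows[[n_pl + j]] <- data.frame(
      record = sprintf("R%02d", n_pl + j), source = "synthDB",
      notation = "",
      chrom_a = as.character(seqnames(a)), start_a = start(a) + 9,
      end_a = start(a) + 209,
      chrom_b = as.character(seqnames(b)), start_b = start(b) + 9,
      end_b = start(b) + 209,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate a full synthetic study
#'
#' Generates the genome model, cohort, tracks, cytobands, call set with
#' planted structure, catalog and hot-region sequences described by the
#' configuration, optionally writing every input file to \code{dir} in its
#' standard format. All randomness derives from \code{config$seed}; two
#' runs with one seed are identical.
#'
#' @param config \code{\link{simulationConfig}}.
#' @param dir optional output directory; created if missing.
#' @return list: \code{genome} (Seqinfo), \code{cohort} (data.frame),
#'   \code{pairs} (\code{TranslocationPairs}, unfiltered, with provenance
#'   labels), \code{tracks} (list of GRanges: repeats, lowmap, genes, cds),
#'   \code{cytoband} (GRanges), \code{catalog} (raw data.frame),
#'   \code{sequences} (DNAStringSet), \code{truth} (ground-truth list:
#'   hot_loci, recurrent with realized carrier counts, planted motif
#'   sequence names, composition counts), \code{files} (named paths when
#'   \code{dir} given).
#' @export
simulateStudy <- function(config = simulationConfig(), dir = NULL) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(config$seed)

  genome <- .sim_genome(config)
  cohort <- .sim_cohort(config)
  n_subj <- nrow(cohort)

  hr <- config$hot_regions
  # planted loci (hot regions + their partners + recurrent pair ends)
  planted_df <- rbind(
    data.frame(chrom = hr$chrom, start = hr$start, end = hr$end),
    data.frame(chrom = hr$partner_chrom[!is.na(hr$partner_chrom)],
               start = hr$partner_start[!is.na(hr$partner_chrom)],
               end = hr$partner_end[!is.na(hr$partner_chrom)]),
    data.frame(chrom = config$recurrent_pairs$chrom_a,
               start = config$recurrent_pairs$start_a,
               end = config$recurrent_pairs$end_a),
    data.frame(chrom = config$recurrent_pairs$chrom_b,
               start = config$recurrent_pairs$start_b,
               end = config$recurrent_pairs$end_b))
  bad <- planted_df$end > seqlengths(genome)[planted_df$chrom] |
    planted_df$start < 0
  if (any(bad)) stop("planted locus outside the genome model")
  planted_gr <- grFromBed(planted_df$chrom, planted_df$start,
                          planted_df$end, seqinfo = genome)
  avoid <- planted_gr + 5000   # keep tracks clear of planted loci

  repeats <- .sim_track(config, genome, config$repeats_per_chrom,
                        config$repeat_length, avoid)
  lowmap <- .sim_track(config, genome, config$lowmap_per_chrom,
                       config$lowmap_length,
                       c(avoid, granges(repeats)))
  tracks_forbidden <- reduce(c(granges(repeats), granges(lowmap)))
  genes <- .sim_genes(config, genome)
  cds <- .sim_cds(genes, genome)
  cytoband <- .sim_cytoband(config, genome)

  frag_a <- list(); frag_b <- list(); subj <- list(); prov <- list()
  truth_rec <- list()

  # planted recurrent region pairs (carrier = Bernoulli per subject)
  add_rec_pair <- function(name, ca, sa, ea, cb, sb, eb, probs,
                           total_occurrence = NA) {
    p <- probs[cohort$group]
    carrier <- stats::runif(n_subj) < p
    ids <- cohort$subject[carrier]
    n_car <- length(ids)
    if (n_car == 0)
      return(data.frame(name = name, chrom_a = ca, start_a = sa, end_a = ea,
                        chrom_b = cb, start_b = sb, end_b = eb,
                        carriers = 0L, rate = 0))
    reps <- rep(1L, n_car)
    if (!is.na(total_occurrence) && total_occurrence > n_car) {
      extra <- table(factor(sample.int(n_car, total_occurrence - n_car,
                                       replace = TRUE), seq_len(n_car)))
      reps <- reps + as.integer(extra)
    }
    n_pairs <- sum(reps)
    la <- .sim_fraglen(n_pairs, config)
    lb <- .sim_fraglen(n_pairs, config)
    frag_a[[length(frag_a) + 1]] <<-
      .sim_locus_frags(n_pairs, ca, sa, ea, la, genome)
    frag_b[[length(frag_b) + 1]] <<-
      .sim_locus_frags(n_pairs, cb, sb, eb, lb, genome)
    subj[[length(subj) + 1]] <<- rep(ids, reps)
    prov[[length(prov) + 1]] <<-
      rep(if (!is.na(total_occurrence)) "hot" else "recurrent", n_pairs)
    data.frame(name = name, chrom_a = ca, start_a = sa, end_a = ea,
               chrom_b = cb, start_b = sb, end_b = eb,
               carriers = n_car, rate = n_car / n_subj,
               stringsAsFactors = FALSE)
  }

  hot_loci <- list()
  for (i in seq_len(nrow(hr))) {
    h <- hr[i, ]
    if (h$mode == "concentrated") {
      probs <- stats::setNames(rep(h$carrier_prob,
                                   length(config$group_sizes)),
                               names(config$group_sizes))
      truth_rec[[length(truth_rec) + 1]] <- add_rec_pair(
        h$name, h$chrom, h$start, h$end,
        h$partner_chrom, h$partner_start, h$partner_end,
        probs, total_occurrence = h$occurrence)
      hot_loci[[length(hot_loci) + 1]] <- data.frame(
        name = c(h$name, paste0(h$name, "_partner")),
        chrom = c(h$chrom, h$partner_chrom),
        start = c(h$start, h$partner_start),
        end = c(h$end, h$partner_end),
        mode = "concentrated", occurrence = h$occurrence,
        stringsAsFactors = FALSE)
    } else {  # spread: partners uniform over the other chromosomes
      n_pairs <- h$occurrence
      la <- .sim_fraglen(n_pairs, config)
      lb <- .sim_fraglen(n_pairs, config)
      frag_a[[length(frag_a) + 1]] <-
        .sim_locus_frags(n_pairs, h$chrom, h$start, h$end, la, genome)
      pchrom <- sample(setdiff(seqlevels(genome), h$chrom), n_pairs,
                       replace = TRUE)
      frag_b[[length(frag_b) + 1]] <-
        .sim_clean_frags(lb, genome, tracks_forbidden, chrom = pchrom)
      subj[[length(subj) + 1]] <- sample(cohort$subject, n_pairs,
                                         replace = TRUE)
      prov[[length(prov) + 1]] <- rep("hot", n_pairs)
      hot_loci[[length(hot_loci) + 1]] <- data.frame(
        name = h$name, chrom = h$chrom, start = h$start, end = h$end,
        mode = "spread", occurrence = h$occurrence,
        stringsAsFactors = FALSE)
    }
  }
  rp <- config$recurrent_pairs
  for (i in seq_len(nrow(rp))) {
    truth_rec[[length(truth_rec) + 1]] <- add_rec_pair(
      rp$name[i], rp$chrom_a[i], rp$start_a[i], rp$end_a[i],
      rp$chrom_b[i], rp$start_b[i], rp$end_b[i],
      config$recurrent_probs[rp$name[i], ])
  }
  truth_rec <- do.call(rbind, truth_rec)
  hot_loci <- do.call(rbind, hot_loci)
  n_planted <- sum(lengths(subj))

  # background calls with fixed per-subject composition
  n_bg <- stats::rpois(n_subj, config$pairs_per_subject)
  n_rep <- round(config$repeat_overlap_fraction * n_bg)
  n_low <- round(config$lowmap_overlap_fraction * n_bg)
  n_clean <- n_bg - n_rep - n_low
  tot_clean <- sum(n_clean)
  n_intra <- round(config$intra_fraction * (tot_clean + n_planted))

  la <- .sim_fraglen(tot_clean, config)
  lb <- .sim_fraglen(tot_clean, config)
  a_clean <- .sim_clean_frags(la, genome, tracks_forbidden)
  intra_sel <- rep(FALSE, tot_clean)
  intra_sel[sample.int(tot_clean, n_intra)] <- TRUE
  chrom_b_vec <- as.character(seqnames(a_clean))
  chrom_b_vec[!intra_sel] <- NA
  b_clean <- .sim_clean_frags(lb, genome, tracks_forbidden,
                              chrom = ifelse(intra_sel, chrom_b_vec, NA))
  # non-intra fragments: resample any that landed on the same chromosome
  redo <- which(!intra_sel &
                as.character(seqnames(b_clean)) ==
                as.character(seqnames(a_clean)))
  guard <- 0
  while (length(redo) && guard < 50) {
    b_clean[redo] <- .sim_clean_frags(lb[redo], genome, tracks_forbidden)
    redo <- redo[as.character(seqnames(b_clean[redo])) ==
                 as.character(seqnames(a_clean[redo]))]
    guard <- guard + 1
  }
  frag_a[[length(frag_a) + 1]] <- a_clean
  frag_b[[length(frag_b) + 1]] <- b_clean
  subj[[length(subj) + 1]] <- rep(cohort$subject, n_clean)
  prov[[length(prov) + 1]] <- rep("background", tot_clean)

  # planted track-overlapping calls (removed by the filters)
  plant_overlap <- function(track, n_per_subj) {
    tot <- sum(n_per_subj)
    if (tot == 0) return(invisible())
    pick <- track[sample.int(length(track), tot, replace = TRUE)]
    lens <- pmin(.sim_fraglen(tot, config), width(pick))
    off <- floor(stats::runif(tot) * (width(pick) - lens + 1))
    a <- GRanges(seqnames(pick), IRanges(start(pick) + off,
                                         width = lens), seqinfo = genome)
    b <- .sim_clean_frags(.sim_fraglen(tot, config), genome,
                          tracks_forbidden)
    frag_a[[length(frag_a) + 1]] <<- a
    frag_b[[length(frag_b) + 1]] <<- b
    subj[[length(subj) + 1]] <<- rep(cohort$subject, n_per_subj)
    prov[[length(prov) + 1]] <<- rep("track-overlap", tot)
  }
  plant_overlap(repeats, n_rep)
  plant_overlap(lowmap, n_low)

  all_a <- do.call(c, frag_a)
  all_b <- do.call(c, frag_b)
  all_s <- unlist(subj)
  all_p <- unlist(prov)

  # verbatim duplicate calls for the dedupe stage
  n_dup <- round(config$duplicate_fraction * length(all_a))
  n_dup_actual <- 0L
  if (n_dup > 0) {
    keep <- which(all_p != "track-overlap")
    di <- sample(keep, min(n_dup, length(keep)))
    n_dup_actual <- length(di)
    all_a <- c(all_a, all_a[di]); all_b <- c(all_b, all_b[di])
    all_s <- c(all_s, all_s[di])
    all_p <- c(all_p, rep("duplicate", n_dup_actual))
  }

  pairs <- TranslocationPairs(all_a, all_b, all_s, provenance = all_p)
  sim_seq <- .sim_sequences(config, hot_loci)
  truth <- list(hot_loci = hot_loci, recurrent = truth_rec,
                motif = config$motif,
                motif_planted_in = sim_seq$planted,
                intra_fraction_target = config$intra_fraction,
                n_intra = n_intra,
                composition = c(clean_background = tot_clean,
                                planted = n_planted,
                                repeat_overlap = sum(n_rep),
                                lowmap_overlap = sum(n_low),
                                duplicate = n_dup_actual))
  catalog <- .sim_catalog(config, truth, cytoband, repeats)
  annotation <- .sim_annotation(config, genes)

  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fp <- function(x) file.path(dir, x)
    files <- c(chrom_sizes = fp("genome.chrom.sizes"),
               bedpe = fp("calls.bedpe"), repeats = fp("repeats.bed"),
               lowmap = fp("lowmap.bed"), genes = fp("genes.bed"),
               cds = fp("cds.bed"), cytoband = fp("cytoband.txt"),
               cohort = fp("cohort.tsv"), catalog = fp("catalog.tsv"),
               annotation = fp("annotation.tsv"),
               fasta = fp("hot_regions.fa"))
    write.table2 <- function(df, path, col.names = FALSE)
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = col.names)
    write.table2(data.frame(seqnames(genome), seqlengths(genome)),
                 files[["chrom_sizes"]])
    writeBedpe(pairs, files[["bedpe"]])
    bed_df <- function(gr, name = NULL) {
      df <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr))
      if (!is.null(name)) df$name <- name
      df
    }
    write.table2(bed_df(repeats), files[["repeats"]])
    write.table2(bed_df(lowmap), files[["lowmap"]])
    write.table2(bed_df(genes, mcols(genes)$name), files[["genes"]])
    write.table2(bed_df(cds, mcols(cds)$name), files[["cds"]])
    write.table2(cbind(bed_df(cytoband), mcols(cytoband)$band,
                       mcols(cytoband)$gieStain), files[["cytoband"]])
    write.table2(cohort, files[["cohort"]], col.names = TRUE)
    write.table2(catalog, files[["catalog"]], col.names = TRUE)
    write.table2(annotation, files[["annotation"]], col.names = TRUE)
    writeXStringSet(sim_seq$sequences, files[["fasta"]])
  }

  list(genome = genome, cohort = cohort, pairs = pairs,
       tracks = list(repeats = repeats, lowmap = lowmap,
                     genes = genes, cds = cds),
       cytoband = cytoband, catalog = catalog, annotation = annotation,
       sequences = sim_seq$sequences, truth = truth, files = files)
}
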