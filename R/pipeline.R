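# End-to-end orchestration. The stages run in a fixed order --
# simulate (or load) -> filter -> landscape -> recurrence -> enrichment ->
# catalog comparison -> motif -- and every report bundle carries the tool
# version and a hash of the configuration, so reruns are auditable and a
# fixed seed reproduces the bundle byte for byte.

#' Run the full analysis pipeline
#'
#' With a \code{\link{simulationConfig}} the inputs are generated in
#' memory; with \code{input_dir} the standard-format files written by
#' \code{\link{simulateStudy}} (or equivalent real inputs) are loaded
#' instead. Reports are returned as a bundle and, when \code{out_dir} is
#' given, written as TSV/JSON files.
#'
#' @param config \code{\link{simulationConfig}} (ignored when
#'   \code{input_dir} is given).
#' @param input_dir optional directory of input files with the layout
#'   produced by \code{simulateStudy(config, dir)}.
#' @param out_dir optional report output directory.
#' @param filter_config \code{\link{filterConfig}}.
#' @param bin_size,min_rate bin-pair detection parameters (200 bp, 0.2).
#' @param min_occurrence,merge_gap hot-region parameters (1000, 0).
#' @param large_threshold large-pair size threshold in bp (1000).
#' @param top_gene_fraction fraction of genes (by fragment count) forming
#'   the gene-set-enrichment query (default 0.05).
#' @param min_term,max_term annotation-term size bounds (15, 250).
#' @return list of reports: \code{manifest}, \code{filter},
#'   \code{sizes}, \code{subjects}, \code{annotation_overlap},
#'   \code{region_pairs}, \code{bin_pairs}, \code{hot_regions},
#'   \code{partner_profiles}, \code{enrichment}, \code{stain},
#'   \code{gender}, \code{gene_sets}, \code{catalog}, \code{motif},
#'   plus \code{pairs} (the filtered call set) and \code{sim} (the
#'   simulation object when simulated).
#' @export
runPipeline <- function(config = simulationConfig(), input_dir = NULL,
                        out_dir = NULL, filter_config = filterConfig(),
                        bin_size = 200, min_rate = 0.2,
                        min_occurrence = 1000, merge_gap = 0,
                        large_threshold = 1000,
                        top_gene_fraction = 0.05,
                        min_term = 15, max_term = 250) {
  if (is.null(input_dir)) {
    sim <- simulateStudy(config)
    genome <- sim$genome; cohort <- sim$cohort; pairs0 <- sim$pairs
    tracks <- sim$tracks; cytoband <- sim$cytoband
    catalog <- parseCatalog(sim$catalog); annotation <- sim$annotation
    sequences <- sim$sequences
    motif <- config$motif
  } else {
    sim <- NULL
    f <- function(x) file.path(input_dir, x)
    need <- c("genome.chrom.sizes", "calls.bedpe", "repeats.bed",
              "lowmap.bed", "genes.bed", "cds.bed", "cytoband.txt",
              "cohort.tsv", "catalog.tsv", "annotation.tsv",
              "hot_regions.fa")
    missing <- need[!file.exists(file.path(input_dir, need))]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "))
    genome <- readChromSizes(f("genome.chrom.sizes"))
    pairs0 <- readBedpe(f("calls.bedpe"), seqinfo = genome)
    tracks <- list(repeats = readBedTrack(f("repeats.bed"), genome),
                   lowmap = readBedTrack(f("lowmap.bed"), genome),
                   genes = readBedTrack(f("genes.bed"), genome),
                   cds = readBedTrack(f("cds.bed"), genome))
    cytoband <- readCytoband(f("cytoband.txt"), seqinfo = genome)
    cohort <- readCohort(f("cohort.tsv"))
    catalog <- readCatalog(f("catalog.tsv"))
    annotation <- utils::read.table(f("annotation.tsv"), header = TRUE,
                                    sep = "\t", colClasses = "character")
    sequences <- readDNAStringSet(f("hot_regions.fa"))
    motif <- config$motif
  }

  # filter
  fl <- runFilters(pairs0, tracks$repeats, tracks$lowmap, filter_config)
  pairs <- fl$pairs

  # landscape
  sizes <- sizeSummary(pairs, large_threshold = large_threshold)
  subjects <- subjectSummary(pairs, cohort, genome)
  ann_overlap <- list(
    genic = annotationOverlap(pairs, tracks$genes),
    cds = annotationOverlap(pairs, tracks$cds),
    g_positive = annotationOverlap(pairs, cytoband,
                                   classes = gPositiveClasses()))
  intra_share <- mean(pairKind(pairs) == "intra")

  # recurrence
  region_pairs <- NULL
  if (!is.null(sim) && NROW(sim$truth$recurrent) > 0) {
    region_pairs <- do.call(rbind, lapply(
      seq_len(nrow(sim$truth$recurrent)), function(i) {
        r <- sim$truth$recurrent[i, ]
        det <- regionPairDetection(
          pairs, cohort,
          grFromBed(r$chrom_a, r$start_a, r$end_a, genome),
          grFromBed(r$chrom_b, r$start_b, r$end_b, genome))
        data.frame(name = r$name, carriers = det$overall$carriers,
                   rate = det$overall$rate, p_value = det$p_value,
                   stringsAsFactors = FALSE)
      }))
  }
  bin_pairs <- binPairDetection(pairs, cohort, bin_size = bin_size,
                                min_rate = min_rate)
  hot <- hotRegions(pairs, min_occurrence = min_occurrence,
                    merge_gap = merge_gap)
  hot <- annotateHotRegions(hot, cytoband, tracks$genes, tracks$cds,
                            tracks$repeats)
  partner <- lapply(seq_along(hot), function(i)
    partnerProfile(hot[i], pairs))
  names(partner) <- sprintf("%s:%d-%d", seqnames(hot),
                            start(hot) - 1L, end(hot))

  # enrichment statistics
  em <- enrichmentMatrix(pairs, chromosomes = seqlevels(genome))
  stain <- stainEnrichment(pairs, cytoband)
  gender <- tryCatch(genderTest(subjects$per_subject, cohort),
                     error = function(e) NULL)
  frag <- c(firstFragment(pairs), secondFragment(pairs))
  per_gene <- countOverlaps(tracks$genes, frag, ignore.strand = TRUE)
  universe <- mcols(tracks$genes)$name
  n_top <- max(1L, ceiling(top_gene_fraction * length(universe)))
  query <- universe[order(-per_gene)][seq_len(n_top)]
  gene_sets <- geneSetEnrichment(query, annotation, universe,
                                 min_genes = min_term,
                                 max_genes = max_term)

  # catalog comparison
  cat_cmp <- catalogOverlap(pairs, cohort, catalog, cytoband)

  # motif scan
  motif_scan <- if (length(sequences) > 0)
    motifOccurrence(sequences, motif)
  else
    list(hits = data.frame(sequence = character(0), start = integer(0),
                           strand = character(0), mismatches = integer(0)),
         fraction = NA_real_)

  manifest <- list(
    tool = "TransloScape",
    version = as.character(utils::packageVersion("TransloScape")),
    config_hash = .config_hash(config),
    n_input = length(pairs0), n_surviving = length(pairs))

  bundle <- list(
    manifest = manifest, filter = as.list(fl$report), sizes = sizes,
    subjects = subjects,
    annotation_overlap = c(ann_overlap, intra_share = intra_share),
    region_pairs = region_pairs, bin_pairs = bin_pairs,
    hot_regions = hot, partner_profiles = partner, enrichment = em,
    stain = stain, gender = gender, gene_sets = gene_sets,
    catalog = cat_cmp, motif = motif_scan,
    pairs = pairs, sim = sim)

  if (!is.null(out_dir)) .write_bundle(bundle, out_dir)
  bundle
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(config)), tmp)
  unname(tools::md5sum(tmp))
}

.write_bundle <- function(bundle, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fp <- function(x) file.path(out_dir, x)
  wj <- function(x, name)
    jsonlite::write_json(x, fp(name), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  wt <- function(df, name)
    utils::write.table(df, fp(name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wj(bundle$manifest, "manifest.json")
  wj(bundle$filter, "filter_report.json")
  wj(bundle$sizes[setdiff(names(bundle$sizes), "histogram")],
     "size_summary.json")
  wt(bundle$sizes$histogram, "size_histogram.tsv")
  wt(bundle$subjects$per_subject, "subjects.tsv")
  wj(list(mean_pairs = bundle$subjects$mean_pairs,
          ci95 = bundle$subjects$ci95,
          pooled_coverage = bundle$subjects$pooled_coverage),
     "subject_summary.json")
  wj(bundle$annotation_overlap, "annotation_overlap.json")
  if (!is.null(bundle$region_pairs))
    wt(bundle$region_pairs, "region_pairs.tsv")
  wt(bundle$bin_pairs, "bin_pairs.tsv")
  hot_df <- as.data.frame(bundle$hot_regions)
  if (nrow(hot_df)) hot_df$start <- hot_df$start - 1L  # render BED
  wt(hot_df, "hot_regions.tsv")
  wj(lapply(bundle$partner_profiles, function(p)
    list(top_share = p$top_share, n_pairs = p$n_pairs,
         modal = p$bins[1, ])), "partner_profiles.json")
  sc <- enrichmentScores(bundle$enrichment)
  wt(data.frame(chrom = rownames(sc), sc, check.names = FALSE),
     "enrichment_scores.tsv")
  wj(list(odds_ratio = bundle$stain$odds_ratio,
          p_value = bundle$stain$p.value,
          table = as.data.frame(bundle$stain$table)), "stain.json")
  if (!is.null(bundle$gender)) wj(bundle$gender, "gender.json")
  wt(bundle$gene_sets, "gene_sets.tsv")
  wt(bundle$catalog$records, "catalog_overlap.tsv")
  wj(list(fraction_overlapped = bundle$catalog$fraction_overlapped,
          mean_rate = bundle$catalog$mean_rate), "catalog_summary.json")
  wt(bundle$motif$hits, "motif_hits.tsv")
  wj(list(fraction = bundle$motif$fraction), "motif_summary.json")
  invisible(out_dir)
}
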