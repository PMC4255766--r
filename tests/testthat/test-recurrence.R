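g2 <- toyGenome()

# n subjects; 'carrier' subjects get a pair linking locus A and locus B,
# everyone gets one background pair elsewhere
carrierSet <- function(n, carriers, genome = g2) {
  la <- grFromBed("chr1", 1000, 1200, genome)
  lb <- grFromBed("chr2", 5000, 5200, genome)
  subj <- sprintf("S%03d", seq_len(n))
  a <- grFromBed(rep("chr1", n), rep(50000, n), rep(50100, n), genome)
  b <- grFromBed(rep("chr2", n), rep(70000, n), rep(70100, n), genome)
  bg <- TranslocationPairs(a, b, subj)
  idx <- seq_len(carriers)
  car <- TranslocationPairs(
    grFromBed(rep("chr1", carriers), rep(1050, carriers),
              rep(1150, carriers), genome),
    grFromBed(rep("chr2", carriers), rep(5050, carriers),
              rep(5150, carriers), genome), subj[idx])
  list(pairs = c(bg, car), cohort = data.frame(
    subject = subj, group = rep(c("G1", "G2"), length.out = n),
    subgroup = NA, gender = "unknown"),
    region_a = la, region_b = lb)
}

test_that("regionPairDetection counts carriers in either orientation", {
  cs <- carrierSet(10, 10)
  det <- regionPairDetection(cs$pairs, cs$cohort, cs$region_a, cs$region_b)
  expect_equal(det$overall$rate, 1)
  expect_true(all(det$groups$rate == 1))
  # swapped query regions give the same carriers
  det2 <- regionPairDetection(cs$pairs, cs$cohort, cs$region_b, cs$region_a)
  expect_equal(det2$overall$carriers, det$overall$carriers)
  expect_error(regionPairDetection(cs$pairs, cs$cohort[0, ],
                                   cs$region_a, cs$region_b), "empty")
})

test_that("pooled rate is the size-weighted mean of group rates", {
  cs <- carrierSet(20, 7)
  det <- regionPairDetection(cs$pairs, cs$cohort, cs$region_a, cs$region_b)
  with(det, expect_equal(overall$rate,
                         sum(groups$rate * groups$n) / overall$n))
})

test_that("planted carrier probability is recovered within binomial error", {
  p_true <- c(0.45, 0.40, 0.35, 0.30, 0.35)
  sim <- simulateStudy(simulationConfig(seed = 51))
  r2 <- sim$truth$recurrent[sim$truth$recurrent$name == "R2", ]
  det <- regionPairDetection(
    sim$pairs, sim$cohort,
    grFromBed(r2$chrom_a, r2$start_a, r2$end_a, sim$genome),
    grFromBed(r2$chrom_b, r2$start_b, r2$end_b, sim$genome))
  p_pool <- mean(p_true)
  n <- det$overall$n
  expect_lt(abs(det$overall$rate - p_pool),
            3 * sqrt(p_pool * (1 - p_pool) / n))
})

test_that("bin-pair detection finds planted links once per subject", {
  # 10 subjects, 8 with a pair linking chr1 bin 5 <-> chr2 bin 3
  subj <- sprintf("S%02d", 1:10)
  a <- grFromBed(rep("chr1", 8), rep(5 * 200 + 20, 8),
                 rep(5 * 200 + 120, 8), g2)
  b <- grFromBed(rep("chr2", 8), rep(3 * 200 + 20, 8),
                 rep(3 * 200 + 120, 8), g2)
  tp <- TranslocationPairs(a, b, subj[1:8])
  co <- data.frame(subject = subj, group = "G", subgroup = NA,
                   gender = "unknown")
  top <- binPairDetection(tp, co, min_rate = 0.1)
  expect_equal(nrow(top), 1)
  expect_equal(top$rate, 0.8)
  expect_equal(c(top$chrom_a, top$bin_a, top$chrom_b, top$bin_b),
               c("chr1", "5", "chr2", "3"))
  # a straddling fragment joins both bin pairs but counts once per pair
  strad <- TranslocationPairs(
    grFromBed("chr1", 5 * 200 + 150, 5 * 200 + 250, g2),  # bins 5 and 6
    grFromBed("chr2", 3 * 200 + 20, 3 * 200 + 120, g2), "S09")
  top2 <- binPairDetection(c(tp, strad, strad), co, min_rate = 0.05)
  expect_equal(top2$carriers[top2$bin_a == 5], 9)
  expect_equal(top2$carriers[top2$bin_a == 6], 1)
})

test_that("same-bin pairs are excluded from bin-pair records", {
  tp <- TranslocationPairs(grFromBed("chr1", 20, 80, g2),
                           grFromBed("chr1", 100, 160, g2), "S1")
  co <- data.frame(subject = "S1", group = "G", subgroup = NA,
                   gender = "unknown")
  expect_equal(nrow(binPairDetection(tp, co, min_rate = 0)), 0)
})

test_that("huge bins degenerate to per-chromosome-pair carrier rates", {
  set.seed(52)
  tp <- randomPairs(120)
  co <- data.frame(subject = paste0("S", 1:5), group = "G",
                   subgroup = NA, gender = "unknown")
  coarse <- binPairDetection(tp, co, bin_size = 1e5, min_rate = 0)
  inter <- tp[pairKind(tp) == "inter"]
  expected <- length(unique(subjectIds(inter))) / 5
  expect_equal(nrow(coarse), 1)            # only chr1 <-> chr2 possible
  expect_equal(coarse$rate, expected)
})

test_that("hot-region clustering applies a strict occurrence threshold", {
  g <- Seqinfo("chr1", 1e6)
  stack <- function(n, s) grFromBed(rep("chr1", n), rep(s, n),
                                    rep(s + 100, n), g)
  partner <- function(n) grFromBed(rep("chr1", n),
                                   seq(500000, by = 200, length.out = n),
                                   seq(500100, by = 200, length.out = n), g)
  tp <- TranslocationPairs(stack(600, 1000), partner(600), "S1")
  hr <- hotRegions(tp, min_occurrence = 599)
  expect_length(hr, 1)
  expect_equal(mcols(hr)$occurrence, 600)
  expect_equal(start(hr) - 1, 1000)
  # boundary: occurrence == threshold is not hot
  expect_length(hotRegions(tp, min_occurrence = 600), 0)
})

test_that("hot-region merge gap controls single-linkage chaining", {
  g <- Seqinfo("chr1", 1e6)
  a <- grFromBed(rep("chr1", 6), rep(c(1000, 1250), 3),
                 rep(c(1100, 1350), 3), g)      # two stacks 150 bp apart
  b <- grFromBed(rep("chr1", 6), seq(600000, by = 1000, length.out = 6),
                 seq(600100, by = 1000, length.out = 6), g)
  tp <- TranslocationPairs(a, b, "S1")
  expect_length(hotRegions(tp, min_occurrence = 2, merge_gap = 0), 2)
  expect_length(hotRegions(tp, min_occurrence = 2, merge_gap = 200), 1)
  # occurrence conservation: totals never exceed 2 x pair count
  hr <- hotRegions(tp, min_occurrence = 0)
  expect_lte(sum(mcols(hr)$occurrence), 2 * length(tp))
})

test_that("partner profiles separate concentrated from spread regions", {
  g <- toyGenome()
  region <- grFromBed("chr1", 1000, 1400, g)
  # all partners in one 1-Mb bin
  conc <- TranslocationPairs(
    grFromBed(rep("chr1", 20), rep(1100, 20), rep(1200, 20), g),
    grFromBed(rep("chr2", 20), rep(30000, 20), rep(30100, 20), g), "S1")
  expect_equal(partnerProfile(region, conc, bin_size = 1e4)$top_share, 1)
  # partners uniform over 10 bins of 10 kb
  starts <- rep(seq(0, 90000, by = 10000), each = 2) + 500
  unif <- TranslocationPairs(
    grFromBed(rep("chr1", 20), rep(1100, 20), rep(1200, 20), g),
    grFromBed(rep("chr2", 20), starts, starts + 100, g), "S1")
  expect_equal(partnerProfile(region, unif, bin_size = 1e4)$top_share, 0.1)
  expect_error(partnerProfile(grFromBed("chr2", 90000, 91000, g), conc),
               "no pairs")
})
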