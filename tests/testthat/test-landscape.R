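test_that("sizeSummary statistics and large-pair counting", {
  g <- toyGenome()
  p <- TranslocationPairs(grFromBed("chr1", 0, 100, g),
                          grFromBed("chr2", 0, 100, g), "S1")
  s <- sizeSummary(p)
  expect_equal(s$mean, 100)
  expect_equal(s$median, 100)
  expect_equal(s$n_large_pairs, 0)
  expect_equal(sum(s$histogram$count), s$n_fragments)
  # fragments {65, 101, 101, 1886}
  p2 <- TranslocationPairs(
    grFromBed(c("chr1", "chr1"), c(0, 0), c(65, 101), g),
    grFromBed(c("chr2", "chr2"), c(0, 0), c(101, 1886), g),
    c("S1", "S1"))
  s2 <- sizeSummary(p2)
  expect_equal(c(s2$min, s2$max, s2$median), c(65, 1886, 101))
  expect_equal(s2$n_large_pairs, 1)    # per pair, either fragment
  expect_error(sizeSummary(p[integer(0)]), "no pairs")
})

test_that("fragment-size generator hits its calibrated mean", {
  sim <- simulateStudy(backgroundOnlyConfig(
    seed = 41, group_sizes = c(A = 5), pairs_per_subject = 1000,
    repeat_overlap_fraction = 0, lowmap_overlap_fraction = 0,
    duplicate_fraction = 0))
  s <- sizeSummary(sim$pairs)
  expect_gte(s$n_fragments, 9000)
  expect_equal(s$mean, 102, tolerance = 2 / 102)
  expect_gte(s$min, 65)
})

test_that("subjectSummary counts, coverage and unresolved subjects", {
  g <- Seqinfo("chr1", 1000000)
  co <- data.frame(subject = c("S1", "S2"), group = "A",
                   subgroup = NA, gender = "unknown")
  p <- TranslocationPairs(
    grFromBed(rep("chr1", 3), c(0, 100, 10000), c(100, 200, 10100), g),
    grFromBed(rep("chr1", 3), c(500000, 600000, 700000),
              c(500345, 600345, 700000 + 345), g),
    c("S1", "S1", "S1"))
  s <- subjectSummary(p, co, g)
  expect_equal(s$per_subject$n_pairs, c(3L, 0L))
  # S1 fragment union: 300 + 1035 bases -> not 0.069%; build exact case
  p2 <- TranslocationPairs(grFromBed("chr1", 0, 345, g),
                           grFromBed("chr1", 500000, 500345, g), "S1")
  s2 <- subjectSummary(p2, co, g)
  expect_equal(s2$per_subject$coverage[1], 0.00069)
  # unknown subject listed and excluded
  p3 <- TranslocationPairs(grFromBed("chr1", 0, 100, g),
                           grFromBed("chr1", 900, 1000, g), "S9")
  s3 <- subjectSummary(p3, co, g)
  expect_equal(s3$unresolved, "S9")
  expect_equal(sum(s3$per_subject$n_pairs), 0)
})

test_that("per-subject burden recovers the Poisson mean", {
  lambda <- 80
  sim <- simulateStudy(backgroundOnlyConfig(
    seed = 42, group_sizes = c(A = 50, B = 50),
    pairs_per_subject = lambda, repeat_overlap_fraction = 0,
    lowmap_overlap_fraction = 0, duplicate_fraction = 0))
  s <- subjectSummary(sim$pairs, sim$cohort, sim$genome)
  expect_equal(s$mean_pairs, lambda, tolerance = 3 * sqrt(lambda / 100) / lambda)
  expect_true(s$ci95[1] <= median(s$per_subject$n_pairs) &&
              median(s$per_subject$n_pairs) <= s$ci95[2])
  # pooled coverage dominates every single subject's coverage
  expect_true(all(s$pooled_coverage >= s$per_subject$coverage))
})

test_that("annotationOverlap fractions and fragmentation invariance", {
  g <- toyGenome()
  p <- TranslocationPairs(
    grFromBed(rep("chr1", 4), c(0, 1000, 2000, 3000),
              c(100, 1100, 2100, 3100), g),
    grFromBed(rep("chr2", 4), c(0, 1000, 2000, 3000),
              c(100, 1100, 2100, 3100), g),
    "S1")
  inside <- grFromBed(c("chr1", "chr2"), c(0, 0), c(5000, 5000), g)
  expect_equal(annotationOverlap(p, inside)$fragment_fraction, 1)
  away <- grFromBed("chr1", 50000, 60000, g)
  expect_equal(annotationOverlap(p, away)$fragment_fraction, 0)
  # track covering 2 of 8 fragments
  two <- grFromBed("chr1", 0, 1100, g)
  expect_equal(annotationOverlap(p, two)$fragment_fraction, 0.25)
  # splitting a track interval never changes either fraction
  split2 <- grFromBed(c("chr1", "chr1"), c(0, 600), c(600, 1100), g)
  expect_equal(annotationOverlap(p, split2),
               annotationOverlap(p, two))
})

test_that("stain-class restriction selects G-positive bands", {
  g <- toyGenome()
  cb <- grFromBed(c("chr1", "chr1"), c(0, 50000), c(50000, 100000), g)
  mcols(cb)$band <- c("p11", "q11")
  mcols(cb)$gieStain <- c("gpos100", "gneg")
  p <- TranslocationPairs(grFromBed("chr1", 100, 200, g),
                          grFromBed("chr1", 60000, 60100, g), "S1")
  ov <- annotationOverlap(p, cb, classes = gPositiveClasses())
  expect_equal(ov$fragment_fraction, 0.5)
})
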