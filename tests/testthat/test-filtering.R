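mkPair <- function(ca, sa, ea, cb, sb, eb, subject = "S1",
                   genome = toyGenome()) {
  TranslocationPairs(grFromBed(ca, sa, ea, genome),
                     grFromBed(cb, sb, eb, genome), subject)
}

test_that("dedupe keeps first occurrence, scoped per subject", {
  p1 <- mkPair("chr1", 100, 200, "chr2", 500, 600)
  d <- dedupePairs(c(p1, p1))
  expect_length(d$pairs, 1)
  expect_equal(d$removed, 1)
  # same coordinates, different subjects: both kept
  p2 <- mkPair("chr1", 100, 200, "chr2", 500, 600, subject = "S2")
  d2 <- dedupePairs(c(p1, p2))
  expect_length(d2$pairs, 2)
  # 5 records, 2 duplicated -> 3 kept
  p3 <- mkPair("chr1", 900, 1000, "chr2", 100, 220)
  d3 <- dedupePairs(c(p1, p3, p1, p3, p1))
  expect_length(d3$pairs, 2)
  expect_equal(d3$removed, 3)
})

test_that("repeat filter is any-overlap with half-open boundaries", {
  p <- mkPair("chr1", 100, 200, "chr2", 500, 600)
  expect_equal(repeatFilter(p, grFromBed("chr1", 199, 300))$removed, 1)
  # BED [200, 300) abuts [100, 200): no shared base, kept
  expect_equal(repeatFilter(p, grFromBed("chr1", 200, 300))$removed, 0)
})

test_that("repeat filter matches a per-base brute force", {
  set.seed(31)
  for (i in 1:15) {
    tp <- randomPairs(10)
    tr <- randomTrack(6)
    got <- repeatFilter(tp, tr)
    fa <- bruteOverlapFraction(firstFragment(tp), tr)
    fb <- bruteOverlapFraction(secondFragment(tp), tr)
    expect_identical(as.data.frame(got$pairs),
                     as.data.frame(tp[fa == 0 & fb == 0]))
  }
})

test_that("mappability thresholds are inclusive and kind-specific", {
  # inter pair: fragment_a [100,200) half inside lowmap [150,250) -> 0.50
  inter <- mkPair("chr1", 100, 200, "chr2", 500, 600)
  low <- grFromBed("chr1", 150, 250)
  expect_equal(mappabilityFilter(inter, low)$removed, 1)   # >= 0.50
  # intra pair at 0.50 is below the 0.85 intra threshold -> kept
  intra <- mkPair("chr1", 100, 200, "chr1", 5000, 5100)
  expect_equal(mappabilityFilter(intra, low)$removed, 0)
  # intra pair with both fragments at 0.84 -> kept
  low84 <- grFromBed(c("chr1", "chr1"), c(100, 5000), c(184, 5084))
  expect_equal(mappabilityFilter(intra, low84)$removed, 0)
  # either fragment over threshold removes the pair
  low_b <- grFromBed("chr1", 5000, 5085)                    # 0.85 of b
  expect_equal(mappabilityFilter(intra, low_b)$removed, 1)
})

test_that("mappability filter matches a per-base fraction oracle", {
  set.seed(32)
  cfg <- filterConfig()
  for (i in 1:10) {
    tp <- randomPairs(50)
    tr <- randomTrack(12)
    got <- mappabilityFilter(tp, tr, cfg)
    fa <- bruteOverlapFraction(firstFragment(tp), tr)
    fb <- bruteOverlapFraction(secondFragment(tp), tr)
    thr <- ifelse(pairKind(tp) == "intra", 0.85, 0.50)
    expect_identical(as.data.frame(got$pairs),
                     as.data.frame(tp[pmax(fa, fb) < thr]))
  }
})

test_that("filter chain report balances and filters are order-insensitive", {
  set.seed(33)
  tp <- randomPairs(200)
  rep_tr <- randomTrack(8)
  low_tr <- randomTrack(8)
  out <- runFilters(tp, rep_tr, low_tr)
  r <- out$report
  expect_equal(r@input,
               r@surviving + r@removedDuplicate + r@removedRepeat +
                 r@removedMappability)
  # survivors never hit either predicate
  surv <- out$pairs
  expect_equal(repeatFilter(surv, rep_tr)$removed, 0)
  expect_equal(mappabilityFilter(surv, low_tr)$removed, 0)
  # swapped stage order leaves the surviving set unchanged
  alt <- mappabilityFilter(dedupePairs(tp)$pairs, low_tr)
  alt <- repeatFilter(alt$pairs, rep_tr)
  expect_setequal(TransloScape:::.pair_key(alt$pairs),
                  TransloScape:::.pair_key(surv))
})

test_that("disabled filters are the identity; empty input stays empty", {
  tp <- mkPair("chr1", 100, 200, "chr2", 500, 600)
  out <- runFilters(tp, NULL, NULL, filterConfig(dedupe = FALSE))
  expect_length(out$pairs, 1)
  expect_equal(fractionRemoved(out$report), 0)
  empty <- tp[integer(0)]
  out0 <- runFilters(empty, randomTrack(3), randomTrack(3))
  expect_length(out0$pairs, 0)
  expect_equal(out0$report@input, 0)
})

test_that("planted track-overlap share is recovered by the filters", {
  cfg <- backgroundOnlyConfig(seed = 34, group_sizes = c(A = 10, B = 10),
                              pairs_per_subject = 300,
                              repeat_overlap_fraction = 0.12,
                              lowmap_overlap_fraction = 0.08,
                              duplicate_fraction = 0)
  sim <- simulateStudy(cfg)
  out <- runFilters(sim$pairs, sim$tracks$repeats, sim$tracks$lowmap)
  expect_equal(fractionRemoved(out$report), 0.20, tolerance = 0.02)
  # generation-time labels coincide with filter attribution
  removed_truth <- sum(pairProvenance(sim$pairs) == "track-overlap")
  expect_equal(out$report@removedRepeat + out$report@removedMappability,
               removed_truth)
})
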