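test_that("a single inter pair has score 1; intra pairs are excluded", {
  g <- toyGenome()
  one <- TranslocationPairs(grFromBed("chr1", 100, 200, g),
                            grFromBed("chr2", 500, 600, g), "S1")
  em <- enrichmentMatrix(one)
  expect_equal(enrichmentScores(em)["chr1", "chr2"], 1)
  intra <- TranslocationPairs(grFromBed("chr1", 100, 200, g),
                              grFromBed("chr1", 5000, 5100, g), "S1")
  expect_error(enrichmentMatrix(intra), "no interchromosomal")
})

test_that("uniform counts give the closed-form score n/(2(n-1))", {
  for (n in c(4, 10, 23)) {
    chroms <- paste0("chr", seq_len(n))
    g <- Seqinfo(chroms, rep(1e6, n))
    combos <- utils::combn(n, 2)
    a <- grFromBed(chroms[combos[1, ]], 100, 200, g)
    b <- grFromBed(chroms[combos[2, ]], 500, 600, g)
    em <- enrichmentMatrix(TranslocationPairs(a, b, "S1"))
    sc <- enrichmentScores(em)
    expect_equal(unique(round(sc[upper.tri(sc)], 10)),
                 round(n / (2 * (n - 1)), 10))
  }
})

test_that("scores satisfy the weighted conservation identity", {
  set.seed(61)
  n <- 6
  g <- Seqinfo(paste0("chr", 1:n), rep(1e6, n))
  ca <- sample(paste0("chr", 1:n), 400, replace = TRUE)
  cb <- sample(paste0("chr", 1:n), 400, replace = TRUE)
  keep <- ca != cb
  tp <- TranslocationPairs(grFromBed(ca[keep], 100, 200, g),
                           grFromBed(cb[keep], 500, 600, g), "S1")
  em <- enrichmentMatrix(tp)
  sc <- enrichmentScores(em)
  m <- em@marginals
  N <- em@total
  idx <- which(upper.tri(sc), arr.ind = TRUE)
  lhs <- sum(sc[idx] * m[idx[, 1]] * m[idx[, 2]] / N, na.rm = TRUE)
  expect_equal(lhs, N)
  # chromosomes without pairs are NA, not zero
  g2 <- Seqinfo(paste0("chr", 1:3), rep(1e6, 3))
  tp2 <- TranslocationPairs(grFromBed("chr1", 100, 200, g2),
                            grFromBed("chr2", 500, 600, g2), "S1")
  sc2 <- enrichmentScores(enrichmentMatrix(tp2, paste0("chr", 1:3)))
  expect_true(is.na(sc2["chr1", "chr3"]))
})

test_that("group rate test is the uncorrected Pearson chi-square", {
  # identical rates -> statistic 0
  same <- groupRateTest(c(10, 20), c(100, 200))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  # hand-computed 2x2: [[10,90],[30,70]] -> X2 = 12.5, df 1
  ht <- groupRateTest(c(10, 30), c(100, 100))
  expect_equal(ht$statistic, 12.5)
  expect_equal(ht$df, 1)
  expect_equal(ht$p.value, 4.07e-4, tolerance = 1e-2)
  # permutation invariance
  ht5 <- groupRateTest(c(16, 10, 9, 25, 4), c(238, 224, 340, 602, 77))
  perm <- c(3, 5, 1, 2, 4)
  ht5p <- groupRateTest(c(16, 10, 9, 25, 4)[perm],
                        c(238, 224, 340, 602, 77)[perm])
  expect_equal(ht5$statistic, ht5p$statistic)
  expect_equal(ht5$df, 4)
  expect_error(groupRateTest(c(1, 2), c(0, 10)), "positive")
})

test_that("stain enrichment behaves at the null and under planting", {
  g <- Seqinfo("chr1", 1e6)
  half <- grFromBed(c("chr1", "chr1"), c(0, 5e5), c(5e5, 1e6), g)
  mcols(half)$band <- c("p11", "q11")
  mcols(half)$gieStain <- c("gpos100", "gneg")
  set.seed(62)
  # null: fragments uniform on a 50/50 genome
  st0 <- sapply(1:20, function(i) {
    s <- floor(runif(200, 0, 1e6 - 100))
    tp <- TranslocationPairs(grFromBed(rep("chr1", 100), s[1:100],
                                       s[1:100] + 100, g),
                             grFromBed(rep("chr1", 100), s[101:200],
                                       s[101:200] + 100, g), "S1")
    stainEnrichment(tp, half)$p.value
  })
  expect_gt(mean(st0 > 0.05), 0.7)
  # all fragments in-class: OR infinite, p tiny
  sall <- floor(runif(100, 0, 5e5 - 100))
  tp1 <- TranslocationPairs(grFromBed(rep("chr1", 50), sall[1:50],
                                      sall[1:50] + 100, g),
                            grFromBed(rep("chr1", 50), sall[51:100],
                                      sall[51:100] + 100, g), "S1")
  st1 <- stainEnrichment(tp1, half)
  expect_true(is.infinite(st1$odds_ratio))
  expect_lt(st1$p.value, 1e-6)
  expect_error(stainEnrichment(tp1, half, classes = "gvar"), "absent")
})

test_that("gender test is Welch and degenerate-safe", {
  co <- data.frame(subject = paste0("S", 1:6),
                   group = "G", subgroup = NA,
                   gender = rep(c("M", "F"), each = 3))
  same <- setNames(rep(c(1, 2, 3), 2), co$subject)
  gt <- genderTest(same, co)
  expect_equal(gt$statistic, 0)
  flat <- setNames(rep(5, 6), co$subject)
  expect_equal(genderTest(flat, co)$p.value, 1)
  # power grows with the mean shift
  set.seed(63)
  co2 <- data.frame(subject = paste0("S", 1:40), group = "G",
                    subgroup = NA, gender = rep(c("M", "F"), each = 20))
  pv <- sapply(c(0, 1, 3), function(shift) {
    x <- setNames(c(rnorm(20, 10 + shift), rnorm(20, 10)), co2$subject)
    genderTest(x, co2)$p.value
  })
  expect_true(pv[1] > pv[3])
  expect_error(genderTest(same[1:3], co), ">= 2 subjects")
})

test_that("hypergeometric enrichment matches enumeration and conventions", {
  # toy universe M = 20, k = 5, C = 4, O = 3: exhaustive tail probability
  M <- 20; k <- 5; C <- 4; O <- 3
  p_exact <- sum(choose(C, 3:4) * choose(M - C, k - (3:4))) / choose(M, k)
  universe <- paste0("g", 1:M)
  ann <- data.frame(term = "T1", gene = universe[1:C])
  query <- c(universe[1:O], universe[(C + 1):(C + k - O)])
  res <- geneSetEnrichment(query, ann, universe, min_genes = 1,
                           max_genes = 20)
  expect_equal(res$rawP, p_exact)
  expect_equal(res$E, C * k / M)
  expect_equal(res$R, O / (C * k / M))
  # O == E gives R = 1
  expect_equal(res$R * res$E, res$O)
  expect_error(geneSetEnrichment(character(0), ann, universe), "empty")
  expect_error(geneSetEnrichment("zz", ann, universe), "missing")
})

test_that("term size bounds and BH adjustment hold", {
  set.seed(64)
  universe <- paste0("g", 1:200)
  ann <- rbind(
    data.frame(term = "small", gene = universe[1:5]),
    data.frame(term = "big", gene = universe),
    do.call(rbind, lapply(1:6, function(i)
      data.frame(term = paste0("T", i),
                 gene = sample(universe, 30)))))
  res <- geneSetEnrichment(sample(universe, 20), ann, universe,
                           min_genes = 15, max_genes = 150)
  expect_false(any(c("small", "big") %in% res$term))
  expect_true(all(res$adjP >= res$rawP))
  expect_true(all(res$adjP <= 1))
  expect_true(!is.unsorted(res$rawP))
})
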