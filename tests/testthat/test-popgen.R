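test_that("variant filters match a hand count and are idempotent", {
  set.seed(201)
  n <- 100
  codes <- matrix(0L, 10, n)
  for (i in 1:6) codes[i, ] <- rbinom(n, 2, 0.3)   # ordinary SNPs
  codes[7, ] <- rbinom(n, 2, 0.4)                  # indel
  codes[8, ] <- rbinom(n, 2, 0.4)                  # indel
  codes[9, ] <- rbinom(n, 2, 0.3); codes[9, 1:30] <- NA  # 30% missing
  codes[10, ] <- 0L; codes[10, 1] <- 1L            # MAF 0.5%
  gm <- gm_from_codes(codes, is_indel = c(rep(FALSE, 6), TRUE, TRUE,
                                          FALSE, FALSE))
  out <- filter_variants(gm)
  expect_equal(n_loci(out), 6)
  log <- attr(out, "filter_log")
  expect_equal(unname(log["input"]), 10)
  expect_equal(unname(log["after_missingness"]), 9)

  # identity settings return every locus
  ident <- filter_variants(gm, maf_min = 0, max_missing = 1,
                           drop_indels = FALSE)
  expect_equal(n_loci(ident), 10)

  # idempotent, and independent of locus order
  twice <- filter_variants(out)
  expect_equal(twice$variants, out$variants)
  perm <- sample(10)
  gm_perm <- gm_from_codes(codes[perm, ], pos = (1:10 * 100L)[perm],
                           is_indel = c(rep(FALSE, 6), TRUE, TRUE, FALSE,
                                        FALSE)[perm])
  out_perm <- filter_variants(gm_perm)
  expect_equal(out_perm$variants$position, out$variants$position)
})

test_that("He and PIC match brute-force evaluation of their sums", {
  he_bf <- function(p) {
    s <- 0
    for (pi in p) s <- s + pi^2
    1 - s
  }
  pic_bf <- function(p) {
    s <- he_bf(p)
    for (i in seq_along(p)) for (j in seq_along(p)) if (j > i)
      s <- s - 2 * p[i]^2 * p[j]^2
    s
  }
  set.seed(202)
  pa <- runif(1000)
  freq <- data.frame(p_ref = 1 - pa, p_alt = pa, n_called = 50)
  he <- gene_diversity(freq)
  pc <- pic(freq)
  for (i in seq_len(1000)) {
    expect_equal(he[i], he_bf(c(1 - pa[i], pa[i])), tolerance = 1e-12)
    expect_equal(pc[i], pic_bf(c(1 - pa[i], pa[i])), tolerance = 1e-12)
  }
  expect_true(all(pc <= he + 1e-15))
  # biallelic maxima at p = 0.5; monomorphic loci are zero
  m <- data.frame(p_ref = c(0.5, 1, 0.9895, 0.99),
                  p_alt = c(0.5, 0, 0.0105, 0.01), n_called = 50)
  expect_equal(gene_diversity(m)[1:2], c(0.5, 0))
  expect_equal(pic(m)[1:2], c(0.375, 0))
  expect_equal(gene_diversity(m)[3], 0.0208, tolerance = 1e-3)
  expect_equal(pic(m)[4], 0.0196, tolerance = 1e-3)
  # zero calls -> undefined
  expect_true(is.na(gene_diversity(
    data.frame(p_ref = NA, p_alt = NA, n_called = 0))))
})

test_that("Nei D_A distance has the right fixed points and handles missing", {
  same <- gm_from_codes(matrix(c(0L, 0L, 2L, 2L), 2, 2, byrow = TRUE))
  expect_equal(unname(nei_da_distance(same)), matrix(0, 2, 2))

  opposite <- gm_from_codes(matrix(c(0L, 2L, 0L, 2L, 2L, 0L), 3, 2,
                                   byrow = TRUE))
  expect_equal(unname(nei_da_distance(opposite)[1, 2]), 1)

  hom_het <- gm_from_codes(matrix(c(0L, 1L), 1, 2))
  expect_equal(unname(nei_da_distance(hom_het)[1, 2]), 1 - sqrt(0.5),
               tolerance = 1e-12)

  # brute-force cross-check with missing data skipped pairwise
  set.seed(203)
  codes <- matrix(sample(c(0:2, NA), 40 * 6, replace = TRUE,
                         prob = c(.4, .2, .3, .1)), 40, 6)
  gm <- gm_from_codes(codes)
  d <- nei_da_distance(gm)
  for (i in 1:5) for (j in (i + 1):6) {
    ok <- !is.na(codes[, i]) & !is.na(codes[, j])
    s <- 0
    for (l in which(ok)) {
      xi <- c(1 - codes[l, i] / 2, codes[l, i] / 2)
      yj <- c(1 - codes[l, j] / 2, codes[l, j] / 2)
      s <- s + sqrt(xi[1] * yj[1]) + sqrt(xi[2] * yj[2])
    }
    expect_equal(d[i, j], 1 - s / sum(ok), tolerance = 1e-12)
  }
  expect_equal(d, t(d))

  # a pair with no shared loci is an error naming the pair
  codes2 <- matrix(c(0L, NA, NA, 2L), 2, 2)
  expect_error(nei_da_distance(gm_from_codes(codes2)), "s1 / s2")
})

test_that("NJ recovers additive trees and validates input", {
  set.seed(204)
  tr <- ape::rtree(4)
  d <- ape::cophenetic.phylo(tr)
  out <- nj_tree(d)
  expect_equal(ape::dist.topo(ape::unroot(tr), out), 0,
               ignore_attr = TRUE)
  expect_equal(as.matrix(ape::cophenetic.phylo(out))[rownames(d),
                                                     colnames(d)],
               d, tolerance = 1e-9)

  # ultrametric 3-taxon matrix: star with the unique length solution
  d3 <- matrix(c(0, 2, 2, 2, 0, 2, 2, 2, 0), 3,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  star <- nj_tree(d3)
  expect_equal(sort(star$edge.length), rep(1, 3))

  dn <- d3; dn[1, 2] <- NaN
  expect_error(nj_tree(dn), "non-finite")
  expect_error(nj_tree(d3[1:2, 1:2]), "at least 3")
})

test_that("PCoA separates clusters and reports variance fractions", {
  set.seed(205)
  pts <- rbind(matrix(rnorm(20 * 2, 0, .1), 20), matrix(rnorm(20 * 2, 5, .1), 20))
  d <- as.matrix(dist(pts))
  pc <- pcoa(d)
  expect_equal(sum(pc$var_frac), 1, tolerance = 1e-12)
  expect_gt(pc$var_frac[1], 0.9)
  grp <- rep(1:2, each = 20)
  expect_gt(abs(mean(pc$points[grp == 1, 1]) -
                  mean(pc$points[grp == 2, 1])), 4)

  # equilateral triangle: the two axes carry equal eigenvalues
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  pc3 <- pcoa(d3)
  ev <- pc3$eig[pc3$eig > 1e-9]
  expect_equal(ev[1], ev[2], tolerance = 1e-9)
})

test_that("PhiPT matches an independent brute-force AMOVA", {
  set.seed(206)
  codes <- matrix(sample(0:2, 3 * 8, replace = TRUE), 3, 8)
  gm <- gm_from_codes(codes)
  pops <- rep(c("P1", "P2"), each = 4)
  res <- amova_phipt(gm, pops)
  d2 <- genotype_sq_distance(gm)
  expect_equal(res$phipt_raw[res$pop1 == "P1"],
               bruteforce_phipt(d2, pops), tolerance = 1e-12)

  # fixed points: identical populations give 0 ...
  dup <- gm_from_codes(cbind(codes, codes))
  expect_equal(amova_phipt(dup, rep(c("A", "B"), each = 8))$phipt[1], 0)
  # ... and populations fixed for alternate alleles give 1
  fixed <- gm_from_codes(matrix(c(rep(0L, 18), rep(2L, 18)), 3, 12))
  expect_equal(amova_phipt(fixed, rep(c("A", "B"), each = 6))$phipt[1], 1)

  expect_error(amova_phipt(gm, c(rep("A", 7), "B")), "fewer than 2.*B")

  # permutation p-value is seeded and deterministic
  p1 <- amova_phipt(fixed, rep(c("A", "B"), each = 6),
                    permutations = 99, seed = 5)$p_value[1]
  p2 <- amova_phipt(fixed, rep(c("A", "B"), each = 6),
                    permutations = 99, seed = 5)$p_value[1]
  expect_equal(p1, p2)
  expect_lt(p1, 0.05)
})

test_that("PhiPT on random splits of one population stays near zero", {
  set.seed(207)
  codes <- matrix(rbinom(200 * 40, 2, runif(200, .1, .9)), 200, 40)
  gm <- gm_from_codes(codes)
  raws <- replicate(100, {
    labels <- sample(rep(c("A", "B"), each = 20))
    amova_phipt(gm, labels)$phipt_raw[1]
  })
  expect_true(all(abs(raws) < 0.02))
})

test_that("the windowed scan is consistent with the genome-wide estimate", {
  set.seed(208)
  sim <- simulate_genotypes(c(A = 15, B = 15), n_loci = 300,
                            fst_target = 0.2, seed = 208,
                            reference = c(chr1 = 2e6))
  gm <- sim$genotypes
  pops <- sim$truth$pops
  scan <- fst_scan(gm, pops, window_bp = 1e9)
  expect_equal(nrow(scan), 1)
  expect_equal(scan$phipt, amova_phipt(gm, pops)$phipt[1],
               tolerance = 1e-12)

  # identical populations: an all-zero track
  codes <- matrix(rbinom(100 * 10, 2, 0.4), 100, 10)
  dup <- gm_from_codes(cbind(codes, codes),
                       chrom = rep("chr1", 100),
                       pos = as.integer(seq(1e4, 1e6, length.out = 100)))
  scan0 <- fst_scan(dup, rep(c("A", "B"), each = 10), window_bp = 2e5)
  expect_true(all(scan0$phipt[scan0$n_loci > 0] == 0))
})

test_that("minor-allele catalog matches hand enumeration", {
  # 12 samples in 3 groups of 4; threshold 0.3 so one homozygote in four
  # (0.25) qualifies
  L <- function(...) as.integer(c(...))
  codes <- rbind(
    L(2,0,0,0, 0,0,0,0, 0,0,0,0),   # private to g1
    L(2,0,0,0, 0,2,0,0, 0,0,0,0),   # g1 and g2
    L(0,2,0,0, 2,0,0,0, 0,0,2,0),   # all three
    L(0,0,0,0, 0,0,0,0, 0,0,0,2),   # private to g3
    L(0,0,0,0, 2,2,0,0, 0,0,0,0),   # g2 hom fraction 0.5: too common
    L(0,0,0,0, 0,0,2,0, 2,0,0,0))   # g2 and g3
  gm <- gm_from_codes(codes)
  groups <- rep(c("g1", "g2", "g3"), each = 4)
  cat3 <- minor_allele_catalog(gm, groups, hom_threshold = 0.3)
  expect_equal(unname(cat3$venn[c("100", "110", "111", "001", "011")]),
               rep(1L, 5))
  expect_equal(unname(cat3$venn[c("010", "101")]), c(0L, 0L))
  expect_equal(cat3$n_union, 5)
  expect_equal(sum(cat3$venn), cat3$n_union)
  # absent allele (frequency zero in the group) never qualifies
  expect_false(gm$variants$position[1] %in%
                 as.integer(sub(".*:(\\d+):.*", "\\1", cat3$sets$g2)))
  expect_error(minor_allele_catalog(gm, c(groups[-12], NA),
                                    hom_threshold = 0.3), "group label")
})

test_that("admixture classification applies the Q cutoff", {
  q <- rbind(c(0.8, 0.1, 0.1), c(0.5, 0.3, 0.2), c(0.7, 0.2, 0.1))
  dimnames(q) <- list(c("a", "b", "c"), c("CG1", "CG2", "CG3"))
  res <- classify_admixture(q, cutoff = 0.70)
  expect_equal(res$assignment, c("CG1", "ADMIXED", "CG1"))
})
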