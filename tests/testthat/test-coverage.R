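ref <- synthetic_reference()
map <- camelina_subgenome_map()

uniform_cov <- function(count = 50, reference = ref) {
  bins <- do.call(rbind, lapply(names(reference), function(chr) {
    br <- seq(0, reference[[chr]], by = 1e5)
    data.frame(chromosome = chr, start = br[-length(br)], end = br[-1],
               count = count, stringsAsFactors = FALSE)
  }))
  binned_coverage("uniform", bins, reference_index = reference)
}

test_that("normalization is unit-free, robust and scale invariant", {
  cov <- uniform_cov(50)
  norm <- normalize_coverage(cov)
  expect_equal(norm$depth, rep(1, nrow(norm)))

  # scaling all counts by 10 leaves the normalized depths unchanged
  cov10 <- cov; cov10$bins$count <- cov$bins$count * 10
  expect_equal(normalize_coverage(cov10)$depth, norm$depth)

  # a chromosome at double dosage sits at ~2, the rest at ~1
  cov2 <- cov
  i <- cov2$bins$chromosome == "Csa14"
  cov2$bins$count[i] <- cov2$bins$count[i] * 2
  n2 <- normalize_coverage(cov2)
  expect_equal(unique(n2$depth[n2$chromosome == "Csa14"]), 2)
  expect_equal(unique(n2$depth[n2$chromosome == "Csa01"]), 1)

  cov0 <- cov; cov0$bins$count[] <- 0
  expect_error(normalize_coverage(cov0), "all-zero")
})

test_that("presence calls recover simulated chromosome sets", {
  set.seed(101)
  cov <- simulate_accession_coverage("DIPLOID_SG1", ref, map,
                                     base_depth = 30, dropout = 0)
  pres <- chromosome_presence(normalize_coverage(cov))
  expect_setequal(pres$chromosome[pres$present], sg_chromosomes(map, "SG1"))

  cov_all <- uniform_cov(30)
  pres_all <- chromosome_presence(normalize_coverage(cov_all))
  expect_true(all(pres_all$present))

  # a zero-depth chromosome is absent
  cov_all$bins$count[cov_all$bins$chromosome == "Csa02"] <- 0
  pres0 <- chromosome_presence(normalize_coverage(cov_all))
  expect_false(pres0$present[pres0$chromosome == "Csa02"])
  expect_equal(sum(pres0$present), 19)
})

test_that("subgenome affinity fractions behave and sum to one", {
  set.seed(102)
  cov <- simulate_accession_coverage("DIPLOID_SG1", ref, map, dropout = 0)
  aff <- subgenome_affinity(normalize_coverage(cov), map)
  expect_equal(sum(aff$fraction), 1, tolerance = 1e-9)
  expect_equal(aff$fraction[aff$subgenome == "SG1"], 1)
  expect_equal(aff$fraction[aff$subgenome == "SG3"], 0)

  # equal depth everywhere: fractions proportional to subgenome bp lengths
  aff_u <- subgenome_affinity(normalize_coverage(uniform_cov(40)), map)
  sg_len <- vapply(c("SG1", "SG2", "SG3"), function(k)
    sum(ref[sg_chromosomes(map, k)]), numeric(1))
  expect_equal(aff_u$fraction[1:3], unname(sg_len / sum(ref)),
               tolerance = 1e-9)

  # the C. hispida pattern: ~57% of reads drawn to the third subgenome
  set.seed(103)
  cov_h <- simulate_accession_coverage("DIPLOID_SG3_AFFINE", ref, map,
                                       base_depth = 30, dropout = 0)
  aff_h <- subgenome_affinity(normalize_coverage(cov_h), map)
  expect_equal(aff_h$fraction[aff_h$subgenome == "SG3"], 0.57,
               tolerance = 0.03)
})

test_that("karyotype rules separate the ploidy series", {
  set.seed(104)
  for (cls in c("DIPLOID_SG1", "TETRAPLOID_SG1SG2", "HEXAPLOID_TYPE2",
                "HEXAPLOID_REFERENCE", "DIPLOID_SG3_AFFINE")) {
    cov <- simulate_accession_coverage(cls, ref, map, base_depth = 25)
    expect_equal(call_karyotype(cov, map)$class, cls)
  }
})

test_that("subgenome map inference follows the ploidy ladder", {
  # presence sets built from the diploid and tetraploid relatives give the
  # refined 6/7/7 structure
  sg1 <- c("Csa14", "Csa07", "Csa19", "Csa04", "Csa08", "Csa11")
  sg2 <- c("Csa03", "Csa16", "Csa01", "Csa06", "Csa13", "Csa10", "Csa18")
  sg3 <- c("Csa17", "Csa05", "Csa15", "Csa09", "Csa20", "Csa02", "Csa12")
  inferred <- infer_subgenome_map(sg1, c(sg1, sg2), names(ref))
  expect_setequal(sg_chromosomes(inferred, "SG1"), sg1)
  expect_setequal(sg_chromosomes(inferred, "SG2"), sg2)
  expect_setequal(sg_chromosomes(inferred, "SG3"), sg3)
  expect_equal(attr(inferred, "provenance"), "inferred")

  # degenerate ladder: tetraploid adds nothing -> empty SG2, warning
  expect_warning(m2 <- infer_subgenome_map(sg1, sg1, names(ref)),
                 "SG2 is empty")
  expect_length(sg_chromosomes(m2, "SG2"), 0)

  # one discordant chromosome tolerated as UNPLACED, more is an error
  expect_warning(
    m3 <- infer_subgenome_map(c(sg1, "Csa02"), c(sg1, sg2), names(ref)),
    "UNPLACED")
  expect_equal(sg_chromosomes(m3, "UNPLACED"), "Csa02")
  expect_error(
    infer_subgenome_map(c(sg1, "Csa02", "Csa12"), c(sg1, sg2), names(ref)),
    "not nested")
})

test_that("random 6/7/7 partitions are recovered exactly from clean sets", {
  set.seed(105)
  for (b in 1:25) {
    perm <- sample(names(ref))
    truth <- subgenome_map(perm, rep(c("SG1", "SG2", "SG3"), c(6, 7, 7)))
    inf <- infer_subgenome_map(sg_chromosomes(truth, "SG1"),
                               c(sg_chromosomes(truth, "SG1"),
                                 sg_chromosomes(truth, "SG2")),
                               names(ref))
    for (k in c("SG1", "SG2", "SG3"))
      expect_setequal(sg_chromosomes(inf, k), sg_chromosomes(truth, k))
  }
})

test_that("depth anomalies are flagged only when planted", {
  ref_s <- synthetic_reference(n_scaffolds = 1)
  map_s <- subgenome_map(c(map$chromosome, "Scf_1"),
                         c(map$subgenome, "SG3"))
  set.seed(106)
  clean <- simulate_accession_coverage("HEXAPLOID_REFERENCE", ref_s, map_s,
                                       base_depth = 100, dropout = 0)
  call <- call_karyotype(clean, map_s)
  norm <- normalize_coverage(clean)
  expect_equal(nrow(detect_anomalies(norm, map_s, call)), 0)
  expect_equal(nrow(detect_anomalies(norm, map_s, call,
                                     z_threshold = Inf)), 0)

  # a Type-2 accession with one SG3 scaffold riding at SG1 depth
  set.seed(107)
  anom <- simulate_accession_coverage(
    "HEXAPLOID_TYPE2", ref_s, map_s, base_depth = 100, dropout = 0,
    dosage_override = c(Scf_1 = 2))
  call2 <- call_karyotype(anom, map_s)
  expect_equal(call2$class, "HEXAPLOID_TYPE2")
  rep2 <- detect_anomalies(normalize_coverage(anom), map_s, call2)
  expect_true("Scf_1" %in% rep2$chromosome)

  amb <- call2; amb$class <- "AMBIGUOUS"
  expect_error(detect_anomalies(norm, map_s, amb), "AMBIGUOUS")
})
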