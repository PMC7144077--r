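test_that("the expression floor drops triplets with a silent homoeolog", {
  sim <- simulate_triplets(n_triplets = 200, seed = 301, tissues = "GS",
                           silent_fraction = 0.3)
  kept <- filter_triplets(sim$expression, "GS")
  truth <- sim$truth
  expect_setequal(unique(kept$triplet_id),
                  truth$triplet_id[is.na(truth$silent_homoeolog)])
  # every replicate comfortably above the floor -> kept
  clean <- simulate_triplets(n_triplets = 20, seed = 302, tissues = "GS")
  expect_equal(length(unique(filter_triplets(clean$expression,
                                             "GS")$triplet_id)), 20)
  expect_error(filter_triplets(clean$expression, "NOT_A_TISSUE"),
               "unknown tissue")
})

test_that("dominance ANOVA matches aov with replicate as block", {
  sim <- simulate_triplets(n_triplets = 8, seed = 303, tissues = "GS",
                           dominant_fraction = c(SG1 = 0, SG2 = 0,
                                                 SG3 = 0.5))
  dc <- call_dominance(sim$expression, "GS")
  x <- as.data.frame(sim$expression)
  x$l <- log2(x$tpm + 0.01)
  for (t in unique(x$triplet_id)) {
    xi <- x[x$triplet_id == t, ]
    fit <- stats::aov(l ~ factor(replicate) + subgenome, data = xi)
    p_aov <- summary(fit)[[1]]["subgenome", "Pr(>F)"]
    expect_equal(dc$p_omnibus[dc$triplet_id == t], p_aov,
                 tolerance = 1e-10)
  }
})

test_that("dominance calls behave at the degenerate limits", {
  # identical values across subgenomes: NONE, undefined omnibus
  flat <- data.frame(triplet_id = "T1",
                     subgenome = rep(c("SG1", "SG2", "SG3"), each = 3),
                     gene_id = "g", tissue = "GS", replicate = rep(1:3, 3),
                     tpm = 4)
  dc <- call_dominance(triplet_expression(flat), "GS")
  expect_equal(dc$dominant, "NONE")

  # zero residual variance with unequal means: decided by means, p = 0
  det <- flat
  det$tpm <- rep(c(2, 2, 8), each = 3)
  dc2 <- call_dominance(triplet_expression(det), "GS")
  expect_equal(dc2$dominant, "SG3")
  expect_equal(dc2$p_omnibus, 0)
  expect_true(dc2$zero_variance)

  # a large injected effect is always detected
  sim <- simulate_triplets(n_triplets = 50, seed = 304, tissues = "GS",
                           n_reps = 6,
                           dominant_fraction = c(SG1 = 0, SG2 = 0, SG3 = 1),
                           effect = 5 * 0.5, noise_sd = 0.5)
  dc3 <- call_dominance(sim$expression, "GS")
  expect_true(all(dc3$dominant == "SG3"))
})

test_that("dominance is invariant to replicate relabeling and scaling", {
  sim <- simulate_triplets(n_triplets = 40, seed = 305, tissues = "GS",
                           dominant_fraction = c(SG1 = 0.1, SG2 = 0.1,
                                                 SG3 = 0.2))
  base <- call_dominance(sim$expression, "GS")

  relab <- as.data.frame(sim$expression)
  relab$replicate <- c(3, 1, 2)[relab$replicate]
  expect_equal(call_dominance(triplet_expression(relab), "GS")$dominant,
               base$dominant)

  scaled <- as.data.frame(sim$expression)
  scaled$tpm <- scaled$tpm * 1000
  # on the log scale a global TPM rescaling shifts every cell equally;
  # use a vanishing offset so the shift is exact
  dc_s <- call_dominance(triplet_expression(scaled), "GS", offset = 1e-9)
  dc_b <- call_dominance(sim$expression, "GS", offset = 1e-9)
  expect_equal(dc_s$dominant, dc_b$dominant)
  expect_equal(dc_s$p_omnibus, dc_b$p_omnibus, tolerance = 1e-8)
})

test_that("dominance summaries count, test and ratio correctly", {
  mk <- function(n1, n2, n3) {
    data.frame(triplet_id = paste0("T", seq_len(n1 + n2 + n3 + 5)),
               tissue = "GS",
               dominant = c(rep("SG1", n1), rep("SG2", n2),
                            rep("SG3", n3), rep("NONE", 5)),
               stringsAsFactors = FALSE)
  }
  s0 <- summarize_dominance(mk(100, 100, 100))
  expect_equal(s0$chisq, 0)
  expect_equal(s0$p_value, 1)

  s1 <- summarize_dominance(mk(90, 100, 110))
  expect_equal(s1$chisq, 2.0, tolerance = 1e-12)
  expect_equal(s1$p_value, 0.368, tolerance = 1e-3)
  expect_equal(s1$ratio_SG3_SG1, 110 / 90)
  expect_equal(s1$ratio_SG2_SG1, 100 / 90)

  # all-NONE: chi-square undefined
  s2 <- summarize_dominance(mk(0, 0, 0))
  expect_true(is.na(s2$chisq))
})

test_that("injected SG3 dominance surfaces in every tissue", {
  sim <- simulate_triplets(n_triplets = 400, seed = 306,
                           dominant_fraction = c(SG1 = 0, SG2 = 0,
                                                 SG3 = 0.25), effect = 2)
  res <- dominance_analysis(sim$expression)
  expect_equal(nrow(res$summary), 12)
  expect_true(all(res$summary$n_dom_SG3 > res$summary$n_dom_SG1))
  expect_true(all(res$summary$n_dom_SG3 > res$summary$n_dom_SG2))
  expect_true(all(res$summary$p_value < 0.05))
})

test_that("the generator refuses dominance labels without an effect", {
  expect_error(simulate_triplets(n_triplets = 10, seed = 307, effect = 0,
                                 dominant_fraction = c(SG1 = 0, SG2 = 0,
                                                       SG3 = 0.5)),
               "positive effect")
})
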