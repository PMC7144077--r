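#' Simulate binned coverage for one accession
#'
#' Per-bin read counts are drawn negative-binomially (Poisson in the
#' zero-dispersion limit) with mean \code{base_depth} scaled by the
#' chromosome's dosage under the karyotype class and by bin length.
#' Dosages: \code{DIPLOID_SG1} covers only SG1; \code{TETRAPLOID_SG1SG2}
#' covers SG1+SG2 evenly; \code{HEXAPLOID_TYPE2} covers SG1+SG2 with SG1
#' at \code{type2_multiplier} (cross-mapping of its unrepresented third
#' subgenome); \code{HEXAPLOID_REFERENCE} covers everything evenly;
#' \code{DIPLOID_SG3_AFFINE} spreads \code{sg3_fraction} of reads over
#' SG3 and the rest diffusely over the other chromosomes.
#'
#' @param class karyotype class label (see above)
#' @param reference named vector of sequence lengths, e.g.
#'   [synthetic_reference()]
#' @param map a [subgenome_map] over those sequences
#' @param accession_id label for the accession
#' @param base_depth mean per-100kb-bin read count at dosage 1
#'   (default 20)
#' @param dispersion negative-binomial dispersion (variance = mu +
#'   dispersion * mu^2); 0 gives Poisson counts
#' @param dropout per-bin probability of a missing (zero) bin
#'   (default 0.01)
#' @param type2_multiplier SG1 dosage multiplier for Type-2 accessions
#'   (default 2)
#' @param sg3_fraction read fraction on SG3 for the affinity-based
#'   diploid (default 0.57)
#' @param dosage_override named vector of per-sequence dosage overrides
#'   (e.g. to plant a depth anomaly on a scaffold)
#' @param bin_size bin width in bp (default 1e5)
#' @return a [binned_coverage]
#' @export
simulate_accession_coverage <- function(class, reference, map,
                                        accession_id = class,
                                        base_depth = 20, dispersion = 0,
                                        dropout = 0.01,
                                        type2_multiplier = 2,
                                        sg3_fraction = 0.57,
                                        dosage_override = NULL,
                                        bin_size = 1e5) {
  sg <- map$subgenome[match(names(reference), map$chromosome)]
  dose <- stats::setNames(numeric(length(reference)), names(reference))
  if (class == "DIPLOID_SG1") {
    dose[sg == "SG1"] <- 1
  } else if (class == "TETRAPLOID_SG1SG2") {
    dose[sg %in% c("SG1", "SG2")] <- 1
  } else if (class == "HEXAPLOID_TYPE2") {
    dose[sg == "SG2"] <- 1
    dose[sg == "SG1"] <- type2_multiplier
  } else if (class == "HEXAPLOID_REFERENCE") {
    dose[] <- 1
  } else if (class == "DIPLOID_SG3_AFFINE") {
    len_sg3 <- sum(reference[sg == "SG3"])
    len_rest <- sum(reference[sg != "SG3"])
    total <- sum(reference)
    dose[sg == "SG3"] <- sg3_fraction * total / len_sg3
    dose[sg != "SG3"] <- (1 - sg3_fraction) * total / len_rest
  } else stop("unknown karyotype class: ", class)
  if (!is.null(dosage_override))
    dose[names(dosage_override)] <- dosage_override

  bins <- do.call(rbind, lapply(names(reference), function(chr) {
    br <- seq(0, reference[[chr]], by = bin_size)
    if (br[length(br)] < reference[[chr]]) br <- c(br, reference[[chr]])
    data.frame(chromosome = chr, start = br[-length(br)], end = br[-1],
               stringsAsFactors = FALSE)
  }))
  mu <- base_depth * dose[bins$chromosome] * (bins$end - bins$start) / bin_size
  bins$count <- if (dispersion > 0)
    stats::rnbinom(nrow(bins), mu = mu, size = 1 / dispersion)
  else stats::rpois(nrow(bins), mu)
  drop <- stats::runif(nrow(bins)) < dropout
  bins$count[drop] <- 0
  binned_coverage(accession_id, bins, bin_size = bin_size,
                  reference_index = reference)
}

#' Simulate a cohort of accessions with known karyotype classes
#'
#' @param n_per_class named integer vector: accessions per karyotype
#'   class
#' @param seed RNG seed (mandatory; same seed, same output)
#' @inheritParams simulate_accession_coverage
#' @param ... further arguments to [simulate_accession_coverage()]
#' @return list with \code{coverage} (list of [binned_coverage]) and
#'   \code{truth} (data.frame accession_id, class)
#' @export
simulate_coverage <- function(n_per_class, seed,
                              reference = synthetic_reference(),
                              map = camelina_subgenome_map(), ...) {
  set.seed(seed)
  classes <- rep(names(n_per_class), n_per_class)
  ids <- sprintf("sim_%03d_%s", seq_along(classes), classes)
  covs <- mapply(function(cl, id)
    simulate_accession_coverage(cl, reference, map, accession_id = id, ...),
    classes, ids, SIMPLIFY = FALSE)
  names(covs) <- ids
  list(coverage = covs,
       truth = data.frame(accession_id = ids, class = classes,
                          stringsAsFactors = FALSE))
}

#' Simulate structured genotypes under the F-model
#'
#' Ancestral allele frequencies are drawn uniformly on
#' \code{freq_range}; each population's frequency is drawn from the
#' Beta distribution \code{Beta(p(1-F)/F, (1-p)(1-F)/F)} with divergence
#' parameter F, and genotypes are Binomial(2, p_k) within populations.
#' Because the AMOVA PhiPT of codominant genotype codes under this model
#' is \code{2F/(1+F)} in expectation, a requested \code{fst_target}
#' \eqn{\phi} is converted internally to \code{F = phi / (2 - phi)}.
#'
#' Optional features: admixed samples whose per-locus ancestry is drawn
#' from a Dirichlet Q vector; uniform genotype missingness; a fraction
#' of loci flagged as indels; a divergent genomic region with its own
#' (higher) target; and species-private minor-allele loci appended per
#' group, each carrying exactly one homozygote of a group-private allele
#' (choose group sizes above \code{1/hom_threshold} so the carrier
#' fraction stays below the cataloguing threshold).
#'
#' @param n_per_pop named integer vector of samples per population
#' @param n_loci number of F-model loci
#' @param fst_target genome-wide pairwise PhiPT target (default 0.1)
#' @param seed RNG seed (mandatory)
#' @param reference named vector of chromosome lengths for variant
#'   positions (default [synthetic_reference()])
#' @param freq_range ancestral-frequency range (default c(0.1, 0.9))
#' @param missing_rate per-call missing probability (default 0)
#' @param indel_fraction fraction of loci flagged as indels (default 0)
#' @param n_admixed number of additional admixed samples (default 0)
#' @param n_private_per_group species-private minor-allele loci appended
#'   per population (default 0)
#' @param divergent_region optional list(chromosome, start, end,
#'   fst_target) marking a high-divergence window
#' @return list with \code{genotypes} ([genotype_matrix]),
#'   \code{samples}, \code{q} ([validate_q_matrix]d ancestry matrix) and
#'   \code{truth} (pops, private locus sets, divergent loci, targets)
#' @export
simulate_genotypes <- function(n_per_pop, n_loci = 2000, fst_target = 0.1,
                               seed, reference = synthetic_reference(),
                               freq_range = c(0.1, 0.9),
                               missing_rate = 0, indel_fraction = 0,
                               n_admixed = 0, n_private_per_group = 0,
                               divergent_region = NULL) {
  set.seed(seed)
  k <- length(n_per_pop)
  popnames <- names(n_per_pop)
  if (is.null(popnames)) popnames <- paste0("pop", seq_len(k))
  phi2F <- function(phi) if (phi <= 0) 0 else phi / (2 - phi)

  chroms <- names(reference)
  chr <- sample(chroms, n_loci, replace = TRUE,
                prob = reference / sum(reference))
  pos <- floor(stats::runif(n_loci, 1, reference[chr])) + 1
  o <- order(chr, pos)
  chr <- chr[o]; pos <- pos[o]

  F_loc <- rep(phi2F(fst_target), n_loci)
  div_loci <- integer(0)
  if (!is.null(divergent_region)) {
    div_loci <- which(chr == divergent_region$chromosome &
                        pos >= divergent_region$start &
                        pos <= divergent_region$end)
    F_loc[div_loci] <- phi2F(divergent_region$fst_target)
  }

  p_anc <- stats::runif(n_loci, freq_range[1], freq_range[2])
  p_pop <- matrix(NA_real_, n_loci, k)
  for (j in seq_len(k)) {
    f <- F_loc
    p_pop[, j] <- ifelse(f == 0, p_anc,
                         stats::rbeta(n_loci, p_anc * (1 - f) / pmax(f, 1e-12),
                                      (1 - p_anc) * (1 - f) / pmax(f, 1e-12)))
    p_pop[f == 0, j] <- p_anc[f == 0]
  }

  pops <- rep(popnames, n_per_pop)
  n_pure <- length(pops)
  calls <- matrix(NA_integer_, n_loci, n_pure + n_admixed)
  q <- matrix(0, n_pure + n_admixed, k)
  for (i in seq_len(n_pure)) {
    j <- match(pops[i], popnames)
    calls[, i] <- stats::rbinom(n_loci, 2, p_pop[, j])
    q[i, j] <- 1
  }
  if (n_admixed > 0) {
    for (i in seq_len(n_admixed)) {
      a <- stats::rgamma(k, 1); a <- a / sum(a)
      # keep admixed samples genuinely mixed (top ancestry < 0.7)
      while (max(a) >= 0.7) { a <- stats::rgamma(k, 1); a <- a / sum(a) }
      q[n_pure + i, ] <- a
      z <- sample.int(k, n_loci, replace = TRUE, prob = a)
      calls[, n_pure + i] <- stats::rbinom(n_loci, 2,
                                           p_pop[cbind(seq_len(n_loci), z)])
    }
    pops <- c(pops, rep("ADMIXED", n_admixed))
  }
  ids <- sprintf("S%03d", seq_len(ncol(calls)))

  is_indel <- stats::runif(n_loci) < indel_fraction
  variants <- data.frame(chromosome = chr, position = pos,
                         ref = "A", alt = ifelse(is_indel, "AT", "G"),
                         is_indel = is_indel, stringsAsFactors = FALSE)

  private_sets <- stats::setNames(vector("list", k), popnames)
  if (n_private_per_group > 0) {
    for (j in seq_len(k)) {
      pchr <- sample(chroms, n_private_per_group, replace = TRUE)
      ppos <- floor(stats::runif(n_private_per_group, 1, reference[pchr])) + 1
      pv <- data.frame(chromosome = pchr, position = ppos, ref = "C",
                       alt = "T", is_indel = FALSE, stringsAsFactors = FALSE)
      pc <- matrix(0L, n_private_per_group, ncol(calls))
      grp_idx <- which(pops == popnames[j])
      carrier <- grp_idx[sample.int(length(grp_idx), n_private_per_group,
                                    replace = TRUE)]
      pc[cbind(seq_len(n_private_per_group), carrier)] <- 2L
      private_sets[[j]] <- paste(pchr, ppos, "T", sep = ":")
      variants <- rbind(variants, pv)
      calls <- rbind(calls, pc)
    }
  }

  if (missing_rate > 0)
    calls[stats::runif(length(calls)) < missing_rate] <- NA_integer_

  gm <- genotype_matrix(variants, calls, ids)
  samples <- data.frame(accession_id = ids, species_label = pops,
                        group_label = pops, habit = "unknown",
                        stringsAsFactors = FALSE)
  colnames(q) <- popnames
  qm <- validate_q_matrix(q, ids)
  list(genotypes = gm, samples = samples, q = qm,
       truth = list(pops = stats::setNames(pops, ids),
                    private_sets = private_sets,
                    divergent_loci = paste(chr[div_loci], pos[div_loci],
                                           sep = ":"),
                    fst_target = fst_target,
                    divergent_region = divergent_region))
}

#' Simulate homoeolog-triplet expression with injected dominance
#'
#' log2 TPM values follow \code{base + effect x 1[subgenome is the
#' triplet's dominant one] + replicate effect + noise}; non-dominant
#' triplets share means across subgenomes. Dominant labels are drawn per
#' triplet with the configured per-subgenome fractions and are identical
#' across tissues. Optionally a fraction of triplets get one silent
#' homoeolog (all replicates at 0 TPM) to exercise the expression floor.
#'
#' @param n_triplets number of triplets
#' @param seed RNG seed (mandatory)
#' @param tissues tissue labels (default the 12-tissue atlas)
#' @param n_reps replicates per tissue (default 3)
#' @param dominant_fraction named fractions of triplets dominated by each
#'   subgenome, e.g. \code{c(SG1 = 0, SG2 = 0, SG3 = 0.25)}; must sum to
#'   at most 1
#' @param effect dominance effect in log2 units (default 2); must be
#'   positive whenever any dominant fraction is positive
#' @param noise_sd residual SD on the log2 scale (default 0.5)
#' @param rep_sd replicate (block) effect SD (default 0.2)
#' @param base_range range of triplet baseline log2 TPM (default c(1, 8))
#' @param silent_fraction fraction of triplets with one silent homoeolog
#' @return list with \code{expression} ([triplet_expression]) and
#'   \code{truth} (dominant label and silent flag per triplet)
#' @export
simulate_triplets <- function(n_triplets = 1000, seed,
                              tissues = expression_tissues(), n_reps = 3,
                              dominant_fraction = c(SG1 = 0, SG2 = 0,
                                                    SG3 = 0.25),
                              effect = 2, noise_sd = 0.5, rep_sd = 0.2,
                              base_range = c(1, 8), silent_fraction = 0) {
  set.seed(seed)
  if (sum(dominant_fraction) > 1)
    stop("dominant fractions sum to more than 1")
  if (any(dominant_fraction > 0) && effect <= 0)
    stop("a positive dominant fraction requires a positive effect size")
  sgs <- c("SG1", "SG2", "SG3")
  dom <- sample(c(sgs, "NONE"), n_triplets, replace = TRUE,
                prob = c(dominant_fraction[sgs], 1 - sum(dominant_fraction)))
  silent <- stats::runif(n_triplets) < silent_fraction
  silent_sg <- ifelse(silent, sample(sgs, n_triplets, replace = TRUE),
                      NA_character_)
  base <- stats::runif(n_triplets, base_range[1], base_range[2])
  trip_ids <- sprintf("T%05d", seq_len(n_triplets))

  grid <- expand.grid(replicate = seq_len(n_reps), subgenome = sgs,
                      triplet = seq_len(n_triplets), tissue = tissues,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rep_eff <- array(stats::rnorm(length(tissues) * n_reps, 0, rep_sd),
                   dim = c(n_reps, length(tissues)),
                   dimnames = list(NULL, tissues))
  mu <- base[grid$triplet] +
    effect * (grid$subgenome == dom[grid$triplet]) +
    rep_eff[cbind(grid$replicate, match(grid$tissue, tissues))]
  log2tpm <- mu + stats::rnorm(nrow(grid), 0, noise_sd)
  tpm <- 2^log2tpm
  tpm[grid$subgenome == silent_sg[grid$triplet] &
        !is.na(silent_sg[grid$triplet])] <- 0
  df <- data.frame(
    triplet_id = trip_ids[grid$triplet], subgenome = grid$subgenome,
    gene_id = paste0(trip_ids[grid$triplet], "_", grid$subgenome),
    tissue = grid$tissue, replicate = grid$replicate, tpm = tpm,
    stringsAsFactors = FALSE)
  list(expression = triplet_expression(df),
       truth = data.frame(triplet_id = trip_ids, dominant = dom,
                          silent_homoeolog = silent_sg,
                          stringsAsFactors = FALSE))
}
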