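#' Normalize binned coverage to unit-free depth
#'
#' Converts per-bin read counts to per-bp depth (count / bin length) and
#' divides by the median per-bp depth over bins with at least one read.
#' The nonzero-bin median makes the scaling robust to subgenomes that are
#' entirely absent from an accession (their zero bins would otherwise drag
#' a mean down). Zero-count bins stay exactly 0, and the result is
#' invariant to global scaling of the counts.
#'
#' @param cov a [binned_coverage]
#' @return data.frame of bins with columns \code{chromosome}, \code{start},
#'   \code{end}, \code{count} and normalized \code{depth}
#' @export
normalize_coverage <- function(cov) {
  b <- cov$bins
  if (sum(b$count) <= 0)
    stop("all-zero coverage for ", cov$accession_id)
  raw <- b$count / (b$end - b$start)
  med <- stats::median(raw[b$count > 0])
  b$depth <- raw / med
  attr(b, "accession_id") <- cov$accession_id
  b
}

#' Per-chromosome presence calls
#'
#' A chromosome is called present when the fraction of its bins with
#' normalized depth at or above \code{depth_floor} exceeds
#' \code{frac_present}. Defaults (0.25, 0.5) mean: at least half the
#' chromosome covered at a quarter of the typical depth.
#'
#' @param norm output of [normalize_coverage()]
#' @param depth_floor minimum normalized depth for a bin to count as covered
#' @param frac_present minimum fraction of covered bins
#' @return data.frame with \code{chromosome}, \code{present},
#'   \code{mean_depth}, \code{frac_covered}
#' @export
chromosome_presence <- function(norm, depth_floor = 0.25,
                                frac_present = 0.5) {
  sp <- split(norm$depth, norm$chromosome)
  out <- data.frame(
    chromosome = names(sp),
    mean_depth = vapply(sp, mean, numeric(1)),
    frac_covered = vapply(sp, function(d) mean(d >= depth_floor), numeric(1)),
    stringsAsFactors = FALSE)
  out$present <- out$frac_covered > frac_present
  rownames(out) <- NULL
  out[, c("chromosome", "present", "mean_depth", "frac_covered")]
}

#' Read fraction and median depth per subgenome
#'
#' The affinity fraction of subgenome k is the share of all mapped reads
#' falling in bins of chromosomes assigned to k. Fractions over
#' SG1/SG2/SG3 plus UNPLACED sum to 1 and are invariant to global depth
#' scaling.
#'
#' @param norm output of [normalize_coverage()]
#' @param map a [subgenome_map] covering every sequence carrying reads
#' @return data.frame with \code{subgenome}, \code{fraction},
#'   \code{median_depth}
#' @export
subgenome_affinity <- function(norm, map) {
  sg <- map$subgenome[match(norm$chromosome, map$chromosome)]
  if (anyNA(sg) && any(norm$count[is.na(sg)] > 0))
    stop("reads on sequences absent from the subgenome map: ",
         paste(unique(norm$chromosome[is.na(sg) & norm$count > 0]),
               collapse = ", "))
  total <- sum(norm$count)
  lev <- c("SG1", "SG2", "SG3", "UNPLACED")
  out <- data.frame(
    subgenome = lev,
    fraction = vapply(lev, function(k)
      sum(norm$count[which(sg == k)]) / total, numeric(1)),
    median_depth = vapply(lev, function(k) {
      d <- norm$depth[which(sg == k)]
      if (length(d)) stats::median(d) else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify an accession's genome composition
#'
#' Applies, in order, the decision rules distinguishing the karyotype
#' classes seen across the *Camelina* ploidy series:
#' \enumerate{
#'   \item \code{DIPLOID_SG1} — present chromosomes all lie in SG1 and at
#'     least 5 of the 6 SG1 chromosomes are present (the *C. neglecta*
#'     pattern: reads on six chromosomes only);
#'   \item \code{TETRAPLOID_SG1SG2} — present set is (at least 12 of) the
#'     13 SG1+SG2 chromosomes with balanced SG1/SG2 depth;
#'   \item \code{HEXAPLOID_TYPE2} — same 13-chromosome presence but SG1
#'     depth elevated by at least \code{ratio_hi} relative to SG2 (a
#'     cryptic hexaploid whose third, unrepresented subgenome cross-maps
#'     onto SG1);
#'   \item \code{HEXAPLOID_REFERENCE} — all 20 chromosomes present at
#'     balanced depth (the *C. sativa* / Type 1 pattern);
#'   \item \code{DIPLOID_SG3_AFFINE} — none of the above but more than
#'     \code{affinity_min} of reads fall on SG3 (the *C. hispida* pattern:
#'     diffuse mapping with ~57\% of reads on the third subgenome);
#'   \item otherwise \code{AMBIGUOUS} (a value, not an error).
#' }
#'
#' @param presence output of [chromosome_presence()]
#' @param affinity output of [subgenome_affinity()]
#' @param map the [subgenome_map] both were computed against
#' @param accession_id label carried into the result
#' @param ratio_hi SG1:SG2 median-depth ratio separating balanced
#'   tetraploids from Type-2 hexaploids (default 1.5, between the 1:1
#'   tetraploid and ~2:1 cross-mapping expectations)
#' @param affinity_min minimum SG3 read fraction for the affinity-based
#'   diploid call (default 0.5)
#' @return object of class \code{karyotype_call}
#' @export
classify_karyotype <- function(presence, affinity, map,
                               accession_id = "accession",
                               ratio_hi = 1.5, affinity_min = 0.5) {
  sg1 <- sg_chromosomes(map, "SG1")
  sg2 <- sg_chromosomes(map, "SG2")
  sg3 <- sg_chromosomes(map, "SG3")
  placed <- c(sg1, sg2, sg3)
  pres <- intersect(presence$chromosome[presence$present], placed)
  med <- function(k) affinity$median_depth[affinity$subgenome == k]
  ratio12 <- if (isTRUE(med("SG2") > 0)) med("SG1") / med("SG2") else Inf
  meds <- c(med("SG1"), med("SG2"), med("SG3"))
  max_ratio <- if (all(meds > 0)) max(meds) / min(meds) else Inf
  sg3_frac <- affinity$fraction[affinity$subgenome == "SG3"]

  # the 13-chromosome rules tolerate one stray present sequence (e.g. a
  # cross-mapping scaffold) so long as >= 12 of SG1+SG2 are covered
  in12 <- length(setdiff(pres, c(sg1, sg2))) <= 1 &&
    length(intersect(pres, c(sg1, sg2))) >= 12
  cls <-
    if (all(pres %in% sg1) && length(intersect(pres, sg1)) >= 5)
      "DIPLOID_SG1"
    else if (in12 && ratio12 < ratio_hi)
      "TETRAPLOID_SG1SG2"
    else if (in12 && ratio12 >= ratio_hi)
      "HEXAPLOID_TYPE2"
    else if (length(pres) == length(placed) && max_ratio < ratio_hi)
      "HEXAPLOID_REFERENCE"
    else if (sg3_frac > affinity_min)
      "DIPLOID_SG3_AFFINE"
    else "AMBIGUOUS"

  structure(list(accession_id = accession_id, class = cls,
                 presence = presence, affinity = affinity,
                 evidence = list(ratio_hi = ratio_hi,
                                 affinity_min = affinity_min,
                                 sg1_sg2_depth_ratio = ratio12,
                                 max_pairwise_depth_ratio = max_ratio,
                                 sg3_fraction = sg3_frac,
                                 n_present = length(pres))),
            class = "karyotype_call")
}

#' @exportS3Method base::print
print.karyotype_call <- function(x, ...) {
  cat(sprintf("Karyotype call for %s: %s\n", x$accession_id, x$class))
  cat(sprintf("  present chromosomes: %d; SG fractions: %s\n",
              sum(x$presence$present),
              paste(sprintf("%s=%.3f", x$affinity$subgenome,
                            x$affinity$fraction), collapse = " ")))
  cat(sprintf("  SG1/SG2 depth ratio %.2f (ratio_hi %.2f)\n",
              x$evidence$sg1_sg2_depth_ratio, x$evidence$ratio_hi))
  invisible(x)
}

#' One-call classification from a coverage object
#'
#' Convenience wrapper: normalize, call presence and affinity, classify.
#'
#' @param cov a [binned_coverage]
#' @param map a [subgenome_map]
#' @param ... thresholds passed on to [chromosome_presence()] and
#'   [classify_karyotype()]
#' @inheritParams chromosome_presence
#' @inheritParams classify_karyotype
#' @return a \code{karyotype_call}
#' @export
call_karyotype <- function(cov, map, depth_floor = 0.25, frac_present = 0.5,
                           ratio_hi = 1.5, affinity_min = 0.5) {
  norm <- normalize_coverage(cov)
  pres <- chromosome_presence(norm, depth_floor, frac_present)
  aff <- subgenome_affinity(norm, map)
  classify_karyotype(pres, aff, map, accession_id = cov$accession_id,
                     ratio_hi = ratio_hi, affinity_min = affinity_min)
}

#' Infer the subgenome map from a ploidy ladder
#'
#' Under the step-wise model of hexaploid origin — diploid (SG1 relative)
#' crossed up to a tetraploid (SG1+SG2), then to the hexaploid — the
#' chromosomes present in a diploid representative define SG1, those added
#' in a tetraploid representative define SG2, and the remainder of the
#' reference defines SG3.
#'
#' @param diploid_present chromosomes present in the diploid representative
#' @param tetraploid_present chromosomes present in the tetraploid
#'   representative
#' @param chromosomes all reference chromosome names (the 20-sequence set)
#' @param tolerance maximum number of diploid chromosomes allowed to be
#'   missing from the tetraploid set before inference fails (default 1;
#'   such discordant chromosomes are carried as \code{UNPLACED} with a
#'   warning)
#' @return an inferred [subgenome_map]
#' @export
infer_subgenome_map <- function(diploid_present, tetraploid_present,
                                chromosomes, tolerance = 1L) {
  diploid_present <- intersect(diploid_present, chromosomes)
  tetraploid_present <- intersect(tetraploid_present, chromosomes)
  discordant <- setdiff(diploid_present, tetraploid_present)
  if (length(discordant) > tolerance)
    stop("diploid presence set is not nested in the tetraploid set; ",
         "offending chromosomes: ", paste(discordant, collapse = ", "))
  if (length(discordant))
    warning("chromosome(s) present in diploid but not tetraploid left ",
            "UNPLACED: ", paste(discordant, collapse = ", "))
  sg1 <- setdiff(diploid_present, discordant)
  sg2 <- setdiff(tetraploid_present, sg1)
  if (!length(sg2))
    warning("tetraploid presence set adds no chromosomes over the diploid; ",
            "SG2 is empty")
  sg3 <- setdiff(chromosomes, c(sg1, sg2, discordant))
  subgenome_map(
    c(sg1, sg2, sg3, discordant),
    rep(c("SG1", "SG2", "SG3", "UNPLACED"),
        c(length(sg1), length(sg2), length(sg3), length(discordant))),
    provenance = "inferred")
}

#' Flag sequences whose depth departs from their subgenome's expectation
#'
#' For each sequence in the map, the observed statistic is its median
#' normalized depth; the expected value is the median of those medians
#' across its assigned subgenome. The deviation score is
#' \code{|obs - exp| / scale} with \code{scale} the MAD of the subgenome's
#' sequence medians, floored at 0.05 normalized-depth units (so that a
#' fully absent subgenome, whose medians are identically zero, can still
#' expose a high-depth scaffold). Only entries exceeding
#' \code{z_threshold} are reported.
#'
#' @param norm output of [normalize_coverage()]
#' @param map a [subgenome_map]
#' @param call the accession's \code{karyotype_call}; anomaly screening is
#'   refused for \code{AMBIGUOUS} calls
#' @param z_threshold robust deviation cutoff (default 3)
#' @return data.frame (possibly empty) with \code{chromosome},
#'   \code{subgenome}, \code{observed}, \code{expected}, \code{score}
#' @export
detect_anomalies <- function(norm, map, call, z_threshold = 3) {
  if (call$class == "AMBIGUOUS")
    stop("anomaly screening requires a non-AMBIGUOUS karyotype call")
  meds <- vapply(split(norm$depth, norm$chromosome), stats::median,
                 numeric(1))
  sg <- map$subgenome[match(names(meds), map$chromosome)]
  out <- data.frame(chromosome = names(meds), subgenome = sg,
                    observed = unname(meds), expected = NA_real_,
                    score = NA_real_, stringsAsFactors = FALSE)
  for (k in unique(sg)) {
    i <- which(sg == k)
    grp <- if (k == "UNPLACED") seq_along(meds) else i
    expct <- stats::median(meds[grp])
    scale <- max(stats::mad(meds[grp]), 0.05)
    out$expected[i] <- expct
    out$score[i] <- abs(meds[i] - expct) / scale
  }
  out <- out[is.finite(out$score) & out$score > z_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}
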