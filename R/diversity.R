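#' Per-locus allele frequencies from genotype calls
#'
#' Frequencies are computed from non-missing calls only.
#'
#' @param gm a [genotype_matrix]
#' @return data.frame of class \code{frequency_table} with \code{p_ref},
#'   \code{p_alt}, \code{n_called}, \code{missing_fraction},
#'   \code{hom_ref_fraction}, \code{hom_alt_fraction} per locus
#' @export
allele_freqs <- function(gm) {
  calls <- gm$calls
  n <- ncol(calls)
  n_called <- rowSums(!is.na(calls))
  alt_count <- rowSums(calls, na.rm = TRUE)
  p_alt <- ifelse(n_called > 0, alt_count / (2 * n_called), NA_real_)
  out <- data.frame(
    chromosome = gm$variants$chromosome,
    position = gm$variants$position,
    p_ref = 1 - p_alt,
    p_alt = p_alt,
    n_called = n_called,
    missing_fraction = 1 - n_called / n,
    hom_ref_fraction = ifelse(n_called > 0,
                              rowSums(calls == 0L, na.rm = TRUE) / n_called,
                              NA_real_),
    hom_alt_fraction = ifelse(n_called > 0,
                              rowSums(calls == 2L, na.rm = TRUE) / n_called,
                              NA_real_),
    stringsAsFactors = FALSE)
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' Nei's gene diversity (expected heterozygosity) per locus
#'
#' \eqn{H_e = 1 - \sum_i p_i^2} over the allele frequencies at the locus;
#' for a biallelic SNP this is \eqn{2pq}, with maximum 0.5 at p = 0.5.
#' Loci with no called genotypes return \code{NA}.
#'
#' @param freq a \code{frequency_table} from [allele_freqs()]
#' @return numeric vector of He values in [0, 0.5]
#' @export
gene_diversity <- function(freq) {
  ifelse(freq$n_called > 0, 1 - freq$p_ref^2 - freq$p_alt^2, NA_real_)
}

#' Polymorphic information content per locus
#'
#' Botstein's PIC: \eqn{1 - \sum_i p_i^2 - \sum_i \sum_{j>i} 2 p_i^2
#' p_j^2}. For a biallelic locus, \eqn{2pq - 2p^2q^2}, with maximum 0.375
#' at p = 0.5. Always \eqn{\le H_e}.
#'
#' @inheritParams gene_diversity
#' @return numeric vector of PIC values
#' @export
pic <- function(freq) {
  p <- freq$p_ref; q <- freq$p_alt
  ifelse(freq$n_called > 0, 1 - p^2 - q^2 - 2 * p^2 * q^2, NA_real_)
}

#' Filter variants on missingness, minor allele frequency and indel status
#'
#' Filters are applied in a fixed, logged order: (1) missingness
#' (fraction of missing genotypes \eqn{\le} \code{max_missing}); (2)
#' minor allele frequency strictly greater than \code{maf_min}, computed
#' over all samples from non-missing calls; (3) indels removed when
#' \code{drop_indels}. With \code{maf_min = 0}, \code{max_missing = 1},
#' \code{drop_indels = FALSE} the function is the identity. An empty
#' result is a warning, not an error.
#'
#' @param gm a [genotype_matrix]
#' @param maf_min strict lower bound on minor allele frequency
#'   (default 0.01)
#' @param max_missing maximum missing-call fraction (default 0.20)
#' @param drop_indels drop loci flagged as indels (default TRUE)
#' @return filtered [genotype_matrix]; attribute \code{"filter_log"}
#'   records locus counts after each step
#' @export
filter_variants <- function(gm, maf_min = 0.01, max_missing = 0.20,
                            drop_indels = TRUE) {
  log <- c(input = n_loci(gm))
  fr <- allele_freqs(gm)
  keep <- fr$missing_fraction <= max_missing
  log <- c(log, after_missingness = sum(keep))
  maf <- pmin(fr$p_ref, fr$p_alt)
  keep <- keep & !is.na(maf) & maf > maf_min
  log <- c(log, after_maf = sum(keep))
  if (drop_indels) keep <- keep & !gm$variants$is_indel
  log <- c(log, after_indels = sum(keep))
  if (!any(keep)) warning("no variants pass the filters")
  out <- genotype_matrix(gm$variants[keep, , drop = FALSE],
                         gm$calls[keep, , drop = FALSE],
                         gm$sample_ids)
  attr(out, "filter_log") <- log
  out
}
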