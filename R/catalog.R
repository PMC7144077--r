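#' Catalogue species-level minor alleles
#'
#' For each species group and locus, an allele is a minor allele of the
#' group when the fraction of non-missing group samples homozygous for it
#' is strictly below \code{hom_threshold} but strictly above zero (the
#' allele must actually occur as a homozygote in the group). A locus
#' enters a group's set when either its alternate or its reference allele
#' qualifies. The alternative \code{criterion = "allele_freq"} applies
#' the same (0, threshold) band to the within-group allele frequency
#' instead of the homozygote-carrier fraction.
#'
#' @param gm a [genotype_matrix]
#' @param groups species label per sample (character, in sample order or
#'   named by sample id); exactly the groups to catalogue, all non-empty
#' @param hom_threshold strict upper bound (default 0.05)
#' @param criterion \code{"hom_fraction"} (default) or
#'   \code{"allele_freq"}
#' @return object of class \code{minor_allele_catalog}: list with
#'   \code{sets} (locus-id character vectors per group) and, when there
#'   are exactly three groups, \code{venn} (counts over the 7 regions,
#'   named by membership pattern such as \code{"110"}) and \code{n_union}
#' @export
minor_allele_catalog <- function(gm, groups, hom_threshold = 0.05,
                                 criterion = c("hom_fraction",
                                               "allele_freq")) {
  criterion <- match.arg(criterion)
  groups <- resolve_pops(gm, groups)
  if (any(table(groups) == 0) || anyNA(groups))
    stop("every sample must carry a group label")
  locus_id <- paste(gm$variants$chromosome, gm$variants$position,
                    gm$variants$alt, sep = ":")
  lev <- sort(unique(groups))
  sets <- stats::setNames(vector("list", length(lev)), lev)
  for (grp in lev) {
    calls <- gm$calls[, groups == grp, drop = FALSE]
    if (ncol(calls) == 0) stop("empty group: ", grp)
    n_called <- rowSums(!is.na(calls))
    if (criterion == "hom_fraction") {
      f_alt <- rowSums(calls == 2L, na.rm = TRUE) / n_called
      f_ref <- rowSums(calls == 0L, na.rm = TRUE) / n_called
    } else {
      p_alt <- rowSums(calls, na.rm = TRUE) / (2 * n_called)
      f_alt <- p_alt; f_ref <- 1 - p_alt
    }
    qual <- function(f) !is.na(f) & f > 0 & f < hom_threshold
    sets[[grp]] <- locus_id[qual(f_alt) | qual(f_ref)]
  }
  out <- list(sets = sets, groups = lev, criterion = criterion,
              hom_threshold = hom_threshold)
  if (length(lev) == 3) {
    uni <- unique(unlist(sets))
    member <- matrix(unlist(lapply(sets, function(s) uni %in% s)),
                     ncol = 3)
    pattern <- if (length(uni))
      apply(member, 1, function(m) paste(as.integer(m), collapse = ""))
    else character(0)
    regions <- c("100", "010", "001", "110", "101", "011", "111")
    out$venn <- stats::setNames(
      vapply(regions, function(r) sum(pattern == r), integer(1)), regions)
    out$n_union <- length(uni)
  }
  class(out) <- "minor_allele_catalog"
  out
}

#' @exportS3Method base::print
print.minor_allele_catalog <- function(x, ...) {
  cat("Minor-allele catalog (", x$criterion, " < ", x$hom_threshold,
      "):\n", sep = "")
  for (g in x$groups)
    cat(sprintf("  %-20s %d loci\n", g, length(x$sets[[g]])))
  if (!is.null(x$venn)) {
    cat("  union:", x$n_union, "loci; shared by all three:",
        x$venn[["111"]], "\n")
  }
  invisible(x)
}

#' Assign samples to populations from a Q matrix
#'
#' A sample is assigned to its highest-ancestry population when that
#' ancestry proportion reaches \code{cutoff}; otherwise it is classed
#' \code{ADMIXED}.
#'
#' @param q a Q matrix (samples x K), e.g. from [read_q_matrix()]
#' @param cutoff minimum top ancestry proportion (default 0.70)
#' @return data.frame with \code{sample_id}, \code{assignment}
#'   (population column name or \code{"ADMIXED"}) and \code{max_q}
#' @export
classify_admixture <- function(q, cutoff = 0.70) {
  q <- as.matrix(q)
  popnames <- colnames(q)
  if (is.null(popnames)) popnames <- paste0("pop", seq_len(ncol(q)))
  top <- max.col(q, ties.method = "first")
  maxq <- q[cbind(seq_len(nrow(q)), top)]
  data.frame(
    sample_id = if (is.null(rownames(q))) as.character(seq_len(nrow(q)))
                else rownames(q),
    assignment = ifelse(maxq >= cutoff, popnames[top], "ADMIXED"),
    max_q = maxq, stringsAsFactors = FALSE, row.names = NULL)
}
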