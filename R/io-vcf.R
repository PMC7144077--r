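GT_MISSING <- NA_integer_  # missingness sentinel; never conflated with hom-ref

#' Biallelic genotype matrix
#'
#' Loci-by-samples diploid genotype codes: 0 = homozygous reference,
#' 1 = heterozygous, 2 = homozygous alternate, \code{NA} = missing.
#'
#' @param variants data.frame with columns \code{chromosome},
#'   \code{position} (1-based), \code{ref}, \code{alt}, \code{is_indel}.
#' @param calls integer matrix (loci x samples) of codes in
#'   \code{c(0,1,2,NA)}.
#' @param sample_ids character vector of sample names (columns of
#'   \code{calls}).
#' @return object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(variants, calls, sample_ids) {
  stopifnot(nrow(variants) == nrow(calls),
            length(sample_ids) == ncol(calls))
  need <- c("chromosome", "position", "ref", "alt", "is_indel")
  stopifnot(all(need %in% names(variants)))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  ok <- calls %in% c(0L, 1L, 2L) | is.na(calls)
  if (!all(ok)) stop("genotype codes must be 0, 1, 2 or NA")
  # positions sorted within chromosome (split multi-allelics may tie)
  o <- order(variants$chromosome, variants$position)
  variants <- variants[o, , drop = FALSE]
  calls <- calls[o, , drop = FALSE]
  rownames(variants) <- NULL
  dimnames(calls) <- list(NULL, sample_ids)
  structure(list(variants = variants, calls = calls,
                 sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$variants), "loci x",
      length(x$sample_ids), "samples;",
      sum(x$variants$is_indel), "indels;",
      sprintf("%.1f%% missing calls\n", 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Number of loci / samples
#' @param gm a [genotype_matrix]
#' @return integer
#' @export
n_loci <- function(gm) nrow(gm$variants)

#' @rdname n_loci
#' @export
n_samples <- function(gm) length(gm$sample_ids)

parse_gt_codes <- function(gt, sample_ids, alt_index = 1L) {
  # gt: character matrix of GT strings; returns integer codes wrt alt_index
  g <- gsub("\\|", "/", gt)
  miss <- is.na(g) | g == "." | g == "./."
  hap <- !miss & !grepl("/", g)
  if (any(hap)) {
    bad <- sample_ids[which(colSums(hap) > 0)[1]]
    stop("haploid GT encountered for sample ", bad)
  }
  a1 <- sub("/.*", "", g); a2 <- sub(".*/", "", g)
  miss <- miss | a1 == "." | a2 == "."
  code <- (a1 == as.character(alt_index)) + (a2 == as.character(alt_index))
  code[miss] <- NA_integer_
  storage.mode(code) <- "integer"
  dim(code) <- dim(gt)
  code
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Diploid GT fields are mapped to codes 0/1/2 with missing calls kept as
#' a dedicated \code{NA} sentinel. Indels are flagged when either allele
#' is longer than one base. Multi-allelic records are, by default, split
#' into one biallelic locus per alternate allele (sharing the position;
#' the code at a split locus counts copies of that alternate), or dropped
#' with \code{multiallelic = "drop"}.
#'
#' @param path VCF 4.x file (plain text or bgzipped).
#' @param multiallelic \code{"split"} (default) or \code{"drop"}.
#' @return list with elements \code{genotypes} (a [genotype_matrix]) and
#'   \code{samples} (a stub sample table with accession ids only).
#' @export
read_vcf <- function(path, multiallelic = c("split", "drop")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(v@gt) < 2) stop("VCF has no sample columns")
  fmt <- v@gt[, 1]
  if (!all(vapply(strsplit(fmt, ":"), function(f) "GT" %in% f, logical(1))))
    stop("VCF record missing GT in FORMAT")
  gt <- vcfR::extract.gt(v, element = "GT")
  sample_ids <- colnames(v@gt)[-1]
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (!is.matrix(gt)) gt <- matrix(gt, nrow = 1,
                                   dimnames = list(NULL, names(gt)))
  chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  alt_list <- strsplit(alt, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)

  keep_bi <- n_alt == 1L
  rows <- list(); codes <- list()
  if (any(keep_bi)) {
    codes[[1]] <- parse_gt_codes(gt[keep_bi, , drop = FALSE], sample_ids)
    rows[[1]] <- data.frame(
      chromosome = chrom[keep_bi], position = pos[keep_bi],
      ref = ref[keep_bi], alt = alt[keep_bi],
      is_indel = nchar(ref[keep_bi]) > 1 |
        nchar(unlist(alt_list[keep_bi])) > 1,
      stringsAsFactors = FALSE)
  }
  if (multiallelic == "split" && any(!keep_bi)) {
    for (i in which(!keep_bi)) {
      for (a in seq_len(n_alt[i])) {
        codes[[length(codes) + 1L]] <-
          parse_gt_codes(gt[i, , drop = FALSE], sample_ids, alt_index = a)
        rows[[length(rows) + 1L]] <- data.frame(
          chromosome = chrom[i], position = pos[i],
          ref = ref[i], alt = alt_list[[i]][a],
          is_indel = nchar(ref[i]) > 1 | nchar(alt_list[[i]][a]) > 1,
          stringsAsFactors = FALSE)
      }
    }
  }
  variants <- do.call(rbind, rows)
  calls <- do.call(rbind, codes)
  gm <- genotype_matrix(variants, calls, sample_ids)
  list(genotypes = gm,
       samples = data.frame(accession_id = sample_ids,
                            species_label = NA_character_,
                            group_label = NA_character_,
                            habit = "unknown",
                            stringsAsFactors = FALSE))
}

#' Write a genotype matrix as a minimal VCF 4.2 file
#' @param gm a [genotype_matrix]
#' @param path output path (plain text .vcf)
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", gm$sample_ids),
                     collapse = "\t")), con)
  gtstr <- matrix(c("0/0", "0/1", "1/1")[gm$calls + 1L], nrow = n_loci(gm))
  gtstr[is.na(gtstr)] <- "./."
  v <- gm$variants
  lines <- paste(v$chromosome, v$position, ".", v$ref, v$alt, ".", "PASS",
                 ".", "GT", apply(gtstr, 1, paste, collapse = "\t"),
                 sep = "\t")
  writeLines(lines, con)
  invisible(path)
}
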