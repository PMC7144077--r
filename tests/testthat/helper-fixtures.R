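# Fixtures are built in code at test time; nothing binary is stored.

toy_reference <- function() {
  c(chrA = 5e5, chrB = 3e5, chrC = 2e5)
}

# A 4-sample toy VCF: 10 records, 2 of them multi-allelic, 2 indels,
# one record with 30% (here: 2/4) missing genotypes is built separately
# where needed.
write_toy_vcf <- function(path, records = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", paste0("s", 1:4)), collapse = "\t"))
  if (is.null(records)) {
    rec <- function(chrom, pos, ref, alt, gts)
      paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
            collapse = "\t")
    records <- c(
      rec("chrA", 100, "A", "G",   c("0/0", "0/1", "1/1", "./.")),
      rec("chrA", 200, "A", "AT",  c("0/0", "0/0", "0/1", "0/1")),
      rec("chrA", 300, "C", "G,T", c("0/1", "1/2", "2/2", "0/0")),
      rec("chrA", 400, "G", "C",   c("0/0", "0/0", "0/0", "0/1")),
      rec("chrB", 100, "T", "A",   c("1/1", "1/1", "0/0", "0/0")),
      rec("chrB", 200, "TA", "T",  c("0/0", "0/1", "0/0", "0/0")),
      rec("chrB", 300, "C", "A,G", c("0/0", "0/1", "0/2", "1/2")),
      rec("chrB", 400, "A", "C",   c("0/1", "0/1", "1/1", "0/0")),
      rec("chrC", 100, "G", "A",   c("0/0", "./.", "./.", "0/1")),
      rec("chrC", 200, "T", "C",   c("1/1", "0/1", "0/0", "0/1")))
  }
  writeLines(c(hdr, records), path)
  path
}

# Build a genotype_matrix directly from a loci x samples code matrix.
gm_from_codes <- function(codes, chrom = NULL, pos = NULL,
                          is_indel = NULL, ids = NULL) {
  n <- nrow(codes)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(is_indel)) is_indel <- rep(FALSE, n)
  if (is.null(ids)) ids <- paste0("s", seq_len(ncol(codes)))
  genotype_matrix(
    data.frame(chromosome = chrom, position = pos, ref = "A", alt = "G",
               is_indel = is_indel, stringsAsFactors = FALSE),
    codes, ids)
}

# Independent brute-force AMOVA on a squared-distance matrix: explicit
# pair loops, no shared code with the package internals.
bruteforce_phipt <- function(d2, pops) {
  pops <- as.character(pops)
  n <- length(pops)
  lev <- unique(pops)
  ss_tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) ss_tot <- ss_tot + d2[i, j]
  ss_tot <- ss_tot / n
  ss_wp <- 0
  for (lv in lev) {
    idx <- which(pops == lv)
    s <- 0
    if (length(idx) > 1)
      for (a in 1:(length(idx) - 1)) for (b in (a + 1):length(idx))
        s <- s + d2[idx[a], idx[b]]
    ss_wp <- ss_wp + s / length(idx)
  }
  ms_a <- (ss_tot - ss_wp) / (length(lev) - 1)
  ms_w <- ss_wp / (n - length(lev))
  sizes <- table(pops)
  n0 <- (n - sum(sizes^2) / n) / (length(lev) - 1)
  sig_a <- (ms_a - ms_w) / n0
  sig_a / (sig_a + ms_w)
}
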