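#' Chromosome-to-subgenome assignment for a hexaploid reference
#'
#' A `subgenome_map` assigns each reference chromosome (and, optionally,
#' unanchored scaffolds) to one of the three ancestral subgenomes
#' \code{SG1}, \code{SG2}, \code{SG3}, or to \code{UNPLACED}.
#'
#' @param chromosomes character vector of chromosome/scaffold names.
#' @param subgenome character vector, same length, with values in
#'   \code{c("SG1","SG2","SG3","UNPLACED")}.
#' @param provenance either \code{"given"} (a published map) or
#'   \code{"inferred"} (from [infer_subgenome_map()]).
#' @return an object of class \code{subgenome_map}: a data.frame with
#'   columns \code{chromosome} and \code{subgenome} plus attributes.
#' @seealso [camelina_subgenome_map()], [infer_subgenome_map()]
#' @export
subgenome_map <- function(chromosomes, subgenome, provenance = "given") {
  stopifnot(length(chromosomes) == length(subgenome))
  if (anyDuplicated(chromosomes))
    stop("duplicate chromosome names in subgenome map")
  bad <- setdiff(unique(subgenome), c("SG1", "SG2", "SG3", "UNPLACED"))
  if (length(bad))
    stop("invalid subgenome labels: ", paste(bad, collapse = ", "))
  out <- data.frame(chromosome = as.character(chromosomes),
                    subgenome = as.character(subgenome),
                    stringsAsFactors = FALSE)
  attr(out, "provenance") <- match.arg(provenance, c("given", "inferred"))
  class(out) <- c("subgenome_map", "data.frame")
  out
}

#' The refined C. sativa subgenome structure
#'
#' The chromosome-to-subgenome assignment obtained by the step-wise
#' argument that the hexaploid arose through hybridization of lower
#' chromosome-number relatives: SG1 is the six-chromosome set shared with
#' diploid *C. neglecta*; SG2 the seven additional chromosomes shared with
#' the tetraploid *C. microcarpa*; SG3 the remaining seven, shared with
#' *C. hispida*.
#'
#' @return a [subgenome_map] over Csa01..Csa20 (6/7/7 partition).
#' @export
camelina_subgenome_map <- function() {
  sg1 <- c("Csa14", "Csa07", "Csa19", "Csa04", "Csa08", "Csa11")
  sg2 <- c("Csa03", "Csa16", "Csa01", "Csa06", "Csa13", "Csa10", "Csa18")
  sg3 <- c("Csa17", "Csa05", "Csa15", "Csa09", "Csa20", "Csa02", "Csa12")
  subgenome_map(c(sg1, sg2, sg3),
                rep(c("SG1", "SG2", "SG3"), c(6L, 7L, 7L)),
                provenance = "given")
}

#' @exportS3Method base::print
print.subgenome_map <- function(x, ...) {
  cat("Subgenome map (", attr(x, "provenance"), ") over ",
      nrow(x), " sequences\n", sep = "")
  for (sg in c("SG1", "SG2", "SG3", "UNPLACED")) {
    chr <- x$chromosome[x$subgenome == sg]
    if (length(chr))
      cat(sprintf("  %-8s (%2d): %s\n", sg, length(chr),
                  paste(chr, collapse = " ")))
  }
  invisible(x)
}

#' Subset of chromosomes assigned to a subgenome
#' @param map a [subgenome_map]
#' @param sg subgenome label
#' @return character vector of chromosome names
#' @export
sg_chromosomes <- function(map, sg) map$chromosome[map$subgenome == sg]

#' Scaled-down synthetic reference karyotype
#'
#' A 20-chromosome reference index for simulation and testing: chromosomes
#' of 2 Mb (20 bins of 100 kb) except one longer "fusion-like" chromosome
#' (Csa11, 3 Mb) mirroring the larger fused chromosome of the real
#' karyotype, so that length normalization is exercised. A
#' \code{"paper"} scale preset with ~30 Mb chromosomes exists for realism
#' checks.
#'
#' @param scale \code{"small"} (default; 2 Mb chromosomes) or
#'   \code{"paper"} (~30 Mb chromosomes).
#' @param n_scaffolds number of unanchored scaffolds (length one bin each)
#'   appended as \code{Scf_1}, ... They are \code{UNPLACED} in the default
#'   map unless assigned explicitly.
#' @return named integer-ish numeric vector of sequence lengths (bp).
#' @export
synthetic_reference <- function(scale = c("small", "paper"), n_scaffolds = 0L) {
  scale <- match.arg(scale)
  base <- if (scale == "small") 2e6 else 30e6
  chroms <- sprintf("Csa%02d", 1:20)
  len <- rep(base, 20)
  names(len) <- chroms
  len["Csa11"] <- 1.5 * base   # fusion-like long chromosome
  if (n_scaffolds > 0) {
    scf <- stats::setNames(rep(5e5, n_scaffolds),
                           sprintf("Scf_%d", seq_len(n_scaffolds)))
    len <- c(len, scf)
  }
  len
}
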