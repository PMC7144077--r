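#' Read a sample metadata table
#'
#' TSV with header columns \code{accession_id}, \code{species_label},
#' \code{group_label}, \code{habit}. \code{group_label} may be empty;
#' \code{habit} must be one of spring/winter/unknown.
#'
#' @param path TSV path
#' @return data.frame of class \code{sample_table}
#' @export
read_samples <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, na.strings = "")
  need <- c("accession_id", "species_label", "group_label", "habit")
  if (!all(need %in% names(x)))
    stop("sample table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(x$accession_id))
    stop("duplicate accession_id in sample table")
  x$habit[is.na(x$habit)] <- "unknown"
  bad <- setdiff(unique(x$habit), c("spring", "winter", "unknown"))
  if (length(bad)) stop("invalid habit value(s): ", paste(bad, collapse = ", "))
  class(x) <- c("sample_table", "data.frame")
  x
}

#' @rdname read_samples
#' @param samples sample data.frame to write
#' @export
write_samples <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an ancestry (Q) matrix
#'
#' TSV with header: \code{sample_id} then K ancestry-proportion columns.
#' Each row must sum to 1 within 1e-6 and all entries lie in [0, 1].
#'
#' @param path TSV path
#' @return matrix (samples x K) with rownames = sample ids, of class
#'   \code{q_matrix}
#' @export
read_q_matrix <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  ids <- as.character(x[[1]])
  q <- as.matrix(x[, -1, drop = FALSE])
  validate_q_matrix(q, ids)
}

validate_q_matrix <- function(q, ids) {
  storage.mode(q) <- "double"
  if (any(q < 0 | q > 1)) stop("Q entries must lie in [0, 1]")
  rs <- rowSums(q)
  bad <- which(abs(rs - 1) > 1e-6)
  if (length(bad))
    stop("Q rows must sum to 1; offending sample(s): ",
         paste(ids[bad], collapse = ", "))
  rownames(q) <- ids
  class(q) <- c("q_matrix", class(q))
  q
}

#' @rdname read_q_matrix
#' @param q Q matrix to write (samples x K, rownames = sample ids)
#' @export
write_q_matrix <- function(q, path) {
  df <- data.frame(sample_id = rownames(q), unclass(q), check.names = FALSE)
  names(df)[-1] <- paste0("Q", seq_len(ncol(q)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Homoeolog-triplet expression container
#'
#' Long-format TPM values for homoeologous gene triplets (one gene per
#' subgenome) across tissues and replicates. Every triplet must have
#' exactly three homoeologs (SG1, SG2, SG3) and every tissue at least two
#' replicates.
#'
#' @param df data.frame with columns \code{triplet_id}, \code{subgenome}
#'   (SG1/SG2/SG3), \code{gene_id}, \code{tissue}, \code{replicate},
#'   \code{tpm}.
#' @return data.frame of class \code{triplet_expression}
#' @export
triplet_expression <- function(df) {
  need <- c("triplet_id", "subgenome", "gene_id", "tissue", "replicate", "tpm")
  stopifnot(all(need %in% names(df)))
  if (any(df$tpm < 0)) stop("negative TPM values")
  bad_sg <- setdiff(unique(df$subgenome), c("SG1", "SG2", "SG3"))
  if (length(bad_sg)) stop("invalid subgenome labels in expression table")
  chk <- unique(df[, c("triplet_id", "subgenome")])
  n_homo <- table(chk$triplet_id)
  if (any(n_homo != 3L))
    stop("triplet(s) without exactly 3 homoeologs: ",
         paste(names(n_homo)[n_homo != 3L][1:min(5, sum(n_homo != 3L))],
               collapse = ", "))
  nrep <- tapply(df$replicate, df$tissue, function(r) length(unique(r)))
  if (any(nrep < 2L))
    stop("tissue(s) with fewer than 2 replicates: ",
         paste(names(nrep)[nrep < 2L], collapse = ", "))
  df <- df[order(df$triplet_id, df$tissue, df$subgenome, df$replicate), ]
  rownames(df) <- NULL
  class(df) <- c("triplet_expression", "data.frame")
  df
}

#' The 12 tissue labels of the expression atlas
#' @return character vector (germinating seed through late seed development)
#' @export
expression_tissues <- function() {
  c("GS", "C", "YL", "R", "S", "SL", "BUD", "F", "ESD", "EMSD", "LMSD", "LSD")
}

#' Read / write the triplet expression TSV
#' @param path TSV path with the [triplet_expression] columns
#' @return a [triplet_expression]
#' @export
read_expression <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  triplet_expression(x)
}

#' @rdname read_expression
#' @param expr a [triplet_expression] to write
#' @export
write_expression <- function(expr, path) {
  utils::write.table(as.data.frame(expr), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a phylogenetic tree in Newick format
#'
#' Serializes an \pkg{ape} \code{phylo} tree with branch lengths to six
#' significant digits, terminated by \code{";"}. Single-leaf trees are
#' written as \code{"A;"}.
#'
#' @param tree an \code{ape::phylo} object with unique tip labels
#' @param path output file
#' @export
write_newick <- function(tree, path) {
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
  if (length(tree$tip.label) == 1) {
    writeLines(paste0(tree$tip.label, ";"), path)
    return(invisible(path))
  }
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}
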