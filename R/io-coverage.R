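#' Binned read-coverage container
#'
#' Per-accession read counts in fixed-width genomic bins (BED convention:
#' 0-based half-open coordinates). The terminal bin of each chromosome may
#' be shorter than \code{bin_size}; such bins are retained and flagged, and
#' all downstream depths are length-normalized.
#'
#' @param accession_id accession identifier.
#' @param bins data.frame with columns \code{chromosome}, \code{start},
#'   \code{end}, \code{count}.
#' @param bin_size nominal bin width in bp (default 100000).
#' @param reference_index named vector of chromosome lengths; chromosomes
#'   absent from \code{bins} are zero-filled so the object always covers
#'   the full reference.
#' @return object of class \code{binned_coverage}.
#' @export
binned_coverage <- function(accession_id, bins, bin_size = 1e5,
                            reference_index = NULL) {
  stopifnot(all(c("chromosome", "start", "end", "count") %in% names(bins)))
  bins <- bins[, c("chromosome", "start", "end", "count")]
  bins$chromosome <- as.character(bins$chromosome)
  bins$start <- as.numeric(bins$start); bins$end <- as.numeric(bins$end)
  bins$count <- as.numeric(bins$count)
  if (any(bins$start >= bins$end))
    stop("coverage bins must satisfy start < end (0-based half-open)")
  if (any(bins$count < 0)) stop("negative read counts")
  if (!is.null(reference_index)) {
    missing_chr <- setdiff(names(reference_index), unique(bins$chromosome))
    if (length(missing_chr)) {
      zero <- do.call(rbind, lapply(missing_chr, function(chr) {
        br <- seq(0, reference_index[[chr]], by = bin_size)
        if (br[length(br)] < reference_index[[chr]])
          br <- c(br, reference_index[[chr]])
        data.frame(chromosome = chr, start = br[-length(br)],
                   end = br[-1], count = 0)
      }))
      bins <- rbind(bins, zero)
    }
    extra <- setdiff(unique(bins$chromosome), names(reference_index))
    if (length(extra))
      stop("chromosomes absent from reference index: ",
           paste(extra, collapse = ", "))
  }
  bins <- bins[order(bins$chromosome, bins$start), , drop = FALSE]
  rownames(bins) <- NULL
  # per-chromosome invariants: non-overlap, full bin width except terminal
  for (chr in unique(bins$chromosome)) {
    b <- bins[bins$chromosome == chr, ]
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)]))
      stop("overlapping bins on ", chr)
    w <- b$end - b$start
    if (any(w[-length(w)] != bin_size))
      stop("non-terminal bin on ", chr, " has width != bin_size")
    if (w[length(w)] > bin_size)
      stop("terminal bin on ", chr, " wider than bin_size")
  }
  bins$terminal_short <- (bins$end - bins$start) < bin_size
  structure(list(accession_id = accession_id, bins = bins,
                 bin_size = bin_size),
            class = "binned_coverage")
}

#' @exportS3Method base::print
print.binned_coverage <- function(x, ...) {
  cat("Binned coverage for", x$accession_id, "-",
      nrow(x$bins), "bins of", format(x$bin_size, scientific = FALSE),
      "bp on", length(unique(x$bins$chromosome)), "sequences;",
      format(sum(x$bins$count), scientific = FALSE), "reads\n")
  invisible(x)
}

#' Read a binned-coverage table
#'
#' Reads the 4-column TSV (\code{chrom}, \code{start}, \code{end},
#' \code{count}) produced by binning mapped reads (e.g. a BEDTools
#' intersect/coverage recipe) into a [binned_coverage] object covering the
#' full reference: chromosomes missing from the file are zero-filled.
#'
#' @param path TSV file path (with or without a header line).
#' @param reference_index named vector of chromosome lengths (bp).
#' @param accession_id accession label; defaults to the file base name.
#' @param bin_size nominal bin width (bp).
#' @return a [binned_coverage].
#' @export
read_coverage <- function(path, reference_index, accession_id = NULL,
                          bin_size = 1e5) {
  if (is.null(accession_id))
    accession_id <- sub("\\.[^.]*$", "", basename(path))
  first <- readLines(path, n = 1)
  has_header <- length(first) == 1 && grepl("chrom", first, ignore.case = TRUE)
  if (length(first) == 0 || (has_header && length(readLines(path, n = 2)) == 1)) {
    return(binned_coverage(accession_id,
                           data.frame(chromosome = character(),
                                      start = numeric(), end = numeric(),
                                      count = numeric()),
                           bin_size = bin_size,
                           reference_index = reference_index))
  }
  raw <- utils::read.table(path, sep = "\t", header = has_header,
                           stringsAsFactors = FALSE,
                           col.names = c("chromosome", "start", "end", "count"),
                           colClasses = c("character", "numeric", "numeric",
                                          "numeric"))
  if (nrow(raw)) {
    bad <- which(!is.finite(raw$start) | !is.finite(raw$end) |
                   !is.finite(raw$count))
    if (length(bad))
      stop("malformed coverage row at line ",
           bad[1] + as.integer(has_header), " of ", path)
  }
  if (nrow(raw) == 0)
    raw <- data.frame(chromosome = character(), start = numeric(),
                      end = numeric(), count = numeric())
  binned_coverage(accession_id, raw, bin_size = bin_size,
                  reference_index = reference_index)
}

#' Write a binned-coverage table
#' @param cov a [binned_coverage]
#' @param path output TSV path
#' @export
write_coverage <- function(cov, path) {
  utils::write.table(
    data.frame(chrom = cov$bins$chromosome, start = cov$bins$start,
               end = cov$bins$end, count = cov$bins$count),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
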