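#' Nei (1983) D_A genetic distance between individuals
#'
#' Each individual is treated as a per-locus allele-frequency vector
#' (0, 0.5 or 1 per allele, from its diploid genotype). For a pair of
#' samples, \eqn{D_A = 1 - (1/L) \sum_{loci} \sum_{alleles}
#' \sqrt{x_a y_a}}, where L counts loci called in both samples (loci
#' missing in either member of a pair are skipped and L adjusted).
#'
#' @param gm a [genotype_matrix] with at least two samples
#' @return symmetric matrix (samples x samples) with zero diagonal and
#'   values in [0, 1]
#' @export
nei_da_distance <- function(gm) {
  if (n_samples(gm) < 2) stop("need at least 2 samples")
  g <- gm$calls
  m <- !is.na(g)
  xref <- sqrt(1 - g / 2); xalt <- sqrt(g / 2)
  xref[!m] <- 0; xalt[!m] <- 0
  sim <- crossprod(xref) + crossprod(xalt)   # sum over shared loci
  L <- crossprod(m * 1)
  if (any(L == 0)) {
    idx <- which(L == 0 & upper.tri(L), arr.ind = TRUE)[1, ]
    stop("no shared called loci for sample pair ",
         gm$sample_ids[idx[1]], " / ", gm$sample_ids[idx[2]])
  }
  d <- 1 - sim / L
  d <- pmin(pmax(d, 0), 1)
  diag(d) <- 0
  dimnames(d) <- list(gm$sample_ids, gm$sample_ids)
  d
}

#' Simple mismatch dissimilarity between individuals
#'
#' Alternative metric: mean absolute genotype-code difference divided
#' by 2, over pairwise-complete loci.
#'
#' @inheritParams nei_da_distance
#' @return symmetric matrix with values in [0, 1]
#' @export
mismatch_distance <- function(gm) {
  g <- gm$calls
  m <- !is.na(g)
  x <- g; x[!m] <- 0
  # sum |g_i - g_j| over shared loci via the identity on squared codes is
  # not available for absolute values; use the three indicator matrices
  lev <- lapply(0:2, function(v) (x == v & m) * 1)
  L <- crossprod(m * 1)
  absdiff <- matrix(0, ncol(g), ncol(g))
  for (a in 1:3) for (b in 1:3)
    absdiff <- absdiff + abs(a - b) * crossprod(lev[[a]], lev[[b]])
  d <- absdiff / (2 * L)
  diag(d) <- 0
  dimnames(d) <- list(gm$sample_ids, gm$sample_ids)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (Studier-Keppler criterion). On additive
#' matrices the returned unrooted tree reproduces every pairwise path
#' length to numerical precision.
#'
#' @param d symmetric non-negative distance matrix, n >= 3, no NaN
#' @return an unrooted \code{ape::phylo} tree with branch lengths
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (any(!is.finite(d))) stop("distance matrix contains non-finite values")
  if (nrow(d) < 3) stop("neighbor-joining needs at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  ape::nj(stats::as.dist(d))
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling: Gower double-centering of the squared
#' distances followed by eigendecomposition. Coordinates are returned for
#' positive-eigenvalue axes, ordered by eigenvalue; the variance fraction
#' of axis i is \eqn{\lambda_i / \sum_{\lambda > 0} \lambda}. Negative
#' eigenvalues (from non-Euclidean distances) are reported but excluded
#' from the denominator.
#'
#' @param d symmetric distance matrix with zero diagonal
#' @return object of class \code{pcoa_result}: list with \code{points}
#'   (samples x axes), \code{eig} (all eigenvalues), \code{var_frac}
#'   (per retained axis)
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  # cmdscale warns when fewer than k eigenvalues are positive; the
  # eigenvalue bookkeeping below handles that case explicitly
  sc <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1,
                                         eig = TRUE))
  eig <- sc$eig
  pos <- which(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  pts <- sc$points[, seq_along(pos), drop = FALSE]
  colnames(pts) <- paste0("Axis", seq_along(pos))
  structure(list(points = pts, eig = eig,
                 var_frac = eig[pos] / sum(eig[pos])),
            class = "pcoa_result")
}

#' @exportS3Method base::print
print.pcoa_result <- function(x, ...) {
  k <- min(3, length(x$var_frac))
  cat("PCoA:", nrow(x$points), "samples,", ncol(x$points),
      "retained axes\n  variance explained:",
      paste(sprintf("axis %d = %.2f%%", seq_len(k),
                    100 * x$var_frac[seq_len(k)]), collapse = ", "), "\n")
  invisible(x)
}
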