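#' Squared Euclidean genotype distances
#'
#' Codominant-genotypic coding: the squared distance between two samples
#' is the sum over loci of squared differences of genotype codes
#' (0/1/2). Loci missing in either sample are skipped and the sum is
#' rescaled by L / L_shared so pairs with different completeness remain
#' comparable.
#'
#' @param gm a [genotype_matrix]
#' @return symmetric matrix of squared distances
#' @export
genotype_sq_distance <- function(gm) {
  g <- gm$calls
  m <- (!is.na(g)) * 1
  x <- g; x[is.na(x)] <- 0
  t1 <- crossprod(x^2, m)           # sum_l g_i^2 over loci called in both
  d2 <- t1 + t(t1) - 2 * crossprod(x)
  L <- crossprod(m)
  if (any(L == 0)) stop("sample pair with no shared called loci")
  d2 <- d2 * (nrow(g) / L)
  d2 <- pmax(d2, 0)
  diag(d2) <- 0
  dimnames(d2) <- list(gm$sample_ids, gm$sample_ids)
  d2
}

# AMOVA variance components from a squared-distance matrix and a factor
# of population labels. Distance-based AMOVA: SS_total is the mean
# squared distance over all pairs, SS_within sums within-population pair
# terms; sigma components follow the standard unbalanced-design
# coefficient n0.
phipt_components <- function(d2, pops) {
  pops <- as.factor(pops)
  n <- length(pops)
  k <- nlevels(pops)
  ss_tot <- sum(d2[upper.tri(d2)]) / n
  ss_wp <- 0
  for (lv in levels(pops)) {
    i <- which(pops == lv)
    ss_wp <- ss_wp + sum(d2[i, i][upper.tri(d2[i, i])]) / length(i)
  }
  ss_ap <- ss_tot - ss_wp
  df_a <- k - 1
  df_w <- n - k
  ms_a <- ss_ap / df_a
  ms_w <- ss_wp / df_w
  sizes <- tabulate(pops)
  n0 <- (n - sum(sizes^2) / n) / df_a
  sigma_w <- ms_w
  sigma_a <- (ms_a - ms_w) / n0
  denom <- sigma_a + sigma_w
  raw <- if (denom > 0) sigma_a / denom else 0
  list(phipt = min(max(raw, 0), 1), phipt_raw = raw,
       sigma_among = sigma_a, sigma_within = sigma_w,
       ss_among = ss_ap, ss_within = ss_wp, df_among = df_a, df_within = df_w)
}

#' Distance-based AMOVA and pairwise PhiPT
#'
#' Partitions squared Euclidean genotype distances among and within
#' populations and reports \eqn{\Phi_{PT} = \sigma^2_{among} /
#' (\sigma^2_{among} + \sigma^2_{within})}, the distance-based AMOVA
#' analogue of F_ST used for codominant data, for every population pair
#' and for all populations jointly. Estimates are deterministic;
#' significance is assessed by permuting population labels.
#'
#' @param gm a [genotype_matrix]
#' @param pops population label per sample (character/factor, in sample
#'   order or named by sample id)
#' @param permutations number of label permutations for the p-value
#'   (0 = no test; 999 is the conventional choice)
#' @param seed RNG seed for the permutation test
#' @return object of class \code{phipt_result}: data.frame with one row
#'   per population pair plus an \code{"overall"} row; columns include
#'   \code{phipt}, raw estimate, variance components and optional
#'   \code{p_value}
#' @export
amova_phipt <- function(gm, pops, permutations = 0, seed = 1L) {
  pops <- resolve_pops(gm, pops)
  sizes <- table(pops)
  if (any(sizes < 2))
    stop("population(s) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  d2 <- genotype_sq_distance(gm)
  lev <- levels(as.factor(pops))
  pairs <- if (length(lev) > 1) utils::combn(lev, 2, simplify = FALSE) else list()
  rows <- lapply(pairs, function(pr) {
    i <- which(pops %in% pr)
    one_phipt_row(d2[i, i], droplevels(factor(pops[i])), pr[1], pr[2],
                  permutations, seed)
  })
  rows <- c(rows, list(one_phipt_row(d2, factor(pops), "overall", "",
                                     permutations, seed)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("phipt_result", "data.frame")
  out
}

one_phipt_row <- function(d2, pops, lab1, lab2, permutations, seed) {
  cmp <- phipt_components(d2, pops)
  p <- NA_real_
  if (permutations > 0) {
    set.seed(seed)
    obs <- cmp$phipt_raw
    exceed <- 0L
    for (b in seq_len(permutations)) {
      perm <- sample(seq_along(pops))
      if (phipt_components(d2[perm, perm], pops)$phipt_raw >= obs)
        exceed <- exceed + 1L
    }
    p <- (exceed + 1) / (permutations + 1)
  }
  data.frame(pop1 = lab1, pop2 = lab2, phipt = cmp$phipt,
             phipt_raw = cmp$phipt_raw, sigma_among = cmp$sigma_among,
             sigma_within = cmp$sigma_within, p_value = p,
             stringsAsFactors = FALSE)
}

resolve_pops <- function(gm, pops) {
  if (!is.null(names(pops))) {
    miss <- setdiff(gm$sample_ids, names(pops))
    if (length(miss)) stop("no population label for sample(s): ",
                           paste(miss, collapse = ", "))
    pops <- pops[gm$sample_ids]
  } else stopifnot(length(pops) == n_samples(gm))
  as.character(pops)
}

#' @exportS3Method base::print
print.phipt_result <- function(x, ...) {
  cat("Pairwise PhiPT (distance-based AMOVA):\n")
  print(format(as.data.frame(x)[, c("pop1", "pop2", "phipt", "p_value")],
               digits = 3), row.names = FALSE)
  invisible(x)
}

#' Windowed PhiPT scan along the genome
#'
#' Computes PhiPT between two (or more) populations in non-overlapping
#' windows of \code{window_bp}, using only the loci falling in each
#' window. Windows without loci are emitted with \code{NA}; windows whose
#' loci carry no variance yield 0. A window larger than the genome
#' reproduces the genome-wide estimate.
#'
#' @inheritParams amova_phipt
#' @param window_bp window size in bp (default 1e6)
#' @return data.frame with \code{chromosome}, \code{start}, \code{end},
#'   \code{n_loci}, \code{phipt}
#' @export
fst_scan <- function(gm, pops, window_bp = 1e6) {
  pops <- resolve_pops(gm, pops)
  v <- gm$variants
  out <- list()
  for (chr in unique(v$chromosome)) {
    idx <- which(v$chromosome == chr)
    maxpos <- max(v$position[idx])
    starts <- seq(0, maxpos, by = window_bp)
    for (s in starts) {
      in_win <- idx[v$position[idx] > s & v$position[idx] <= s + window_bp]
      phi <- NA_real_
      if (length(in_win)) {
        sub <- genotype_matrix(v[in_win, , drop = FALSE],
                               gm$calls[in_win, , drop = FALSE],
                               gm$sample_ids)
        phi <- phipt_components(genotype_sq_distance(sub),
                                factor(pops))$phipt
      }
      out[[length(out) + 1L]] <-
        data.frame(chromosome = chr, start = s, end = s + window_bp,
                   n_loci = length(in_win), phipt = phi,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
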