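#' Filter homoeolog triplets on an expression floor
#'
#' Restricts to one tissue and drops every triplet with a silent
#' homoeolog: a homoeolog fails the floor when \emph{all} of its
#' replicates are below \code{min_tpm}; a triplet needs all three
#' homoeologs expressed, so one failing homoeolog drops the triplet.
#'
#' @param expr a [triplet_expression]
#' @param tissue tissue label (must be present in the data)
#' @param min_tpm expression floor in TPM (default 0.01)
#' @return [triplet_expression] subset for that tissue
#' @export
filter_triplets <- function(expr, tissue, min_tpm = 0.01) {
  if (!tissue %in% expr$tissue) stop("unknown tissue: ", tissue)
  x <- expr[expr$tissue == tissue, , drop = FALSE]
  key <- paste(x$triplet_id, x$subgenome)
  all_low <- tapply(x$tpm, key, function(v) all(v < min_tpm))
  bad_trip <- unique(sub(" .*", "", names(all_low)[all_low]))
  out <- x[!(x$triplet_id %in% bad_trip), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(expr)
  out
}

# Reshape one tissue's long table into an R x 3 x T array (replicate,
# subgenome, triplet); requires a balanced design.
triplet_array <- function(x) {
  x <- x[order(x$triplet_id, x$subgenome, x$replicate), , drop = FALSE]
  trip <- unique(x$triplet_id)
  reps <- sort(unique(x$replicate))
  R <- length(reps)
  if (nrow(x) != length(trip) * 3L * R)
    stop("unbalanced replicate structure in expression table")
  arr <- array(x$tpm, dim = c(R, 3L, length(trip)),
               dimnames = list(reps, c("SG1", "SG2", "SG3"), trip))
  arr
}

#' Call expression dominance per homoeolog triplet
#'
#' Fits, per triplet, a randomized-complete-block ANOVA of (by default)
#' \code{log2(TPM + offset)} with subgenome as the fixed 3-level factor
#' and replicate as the block (the balanced-design equivalent of keeping
#' replicate effects random). When the omnibus test rejects at
#' \code{alpha}, the top-expressed subgenome is contrasted against each
#' of the other two using the ANOVA error term; a subgenome is called
#' dominant only when its mean strictly exceeds both others and both
#' contrasts reject at \code{alpha}. Triplets with zero residual variance
#' but unequal means are decided by the means with p recorded as 0 and a
#' flag; fully constant triplets are \code{NONE}.
#'
#' All sums of squares are evaluated in closed form across triplets at
#' once; the algebra is identical to per-triplet \code{aov()} fits for
#' this balanced design.
#'
#' @param expr a [triplet_expression], typically from [filter_triplets()]
#' @param tissue tissue label
#' @param alpha significance level (default 0.05, unadjusted, matching
#'   the raw p < 0.05 convention; use \code{adjust = "BH"} for
#'   Benjamini-Hochberg on the omnibus p-values)
#' @param log_scale analyze log2(TPM + offset) (default) or raw TPM
#' @param offset pseudocount for the log transform (default 0.01)
#' @param adjust \code{"none"} (default) or \code{"BH"}
#' @return data.frame of class \code{dominance_calls} with one row per
#'   triplet: dominant subgenome (or \code{"NONE"}), omnibus and contrast
#'   p-values, subgenome means, zero-variance flag
#' @export
call_dominance <- function(expr, tissue, alpha = 0.05, log_scale = TRUE,
                           offset = 0.01, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  x <- expr[expr$tissue == tissue, , drop = FALSE]
  if (!nrow(x)) stop("unknown tissue: ", tissue)
  arr <- triplet_array(x)
  if (log_scale) arr <- log2(arr + offset)
  R <- dim(arr)[1]; Tn <- dim(arr)[3]
  if (R < 2) stop("need at least 2 replicates")
  mn <- t(apply(arr, c(2, 3), mean))          # T x 3 subgenome means
  repmean <- t(apply(arr, c(1, 3), mean))     # T x R replicate means
  grand <- rowMeans(mn)
  ss_geno <- R * rowSums((mn - grand)^2)
  ss_block <- 3 * rowSums((repmean - grand)^2)
  ss_tot <- apply(sweep(arr, 3, grand)^2, 3, sum)
  ss_err <- pmax(ss_tot - ss_geno - ss_block, 0)
  df_err <- 2 * (R - 1)
  mse <- ss_err / df_err
  f <- (ss_geno / 2) / mse
  p_omni <- stats::pf(f, 2, df_err, lower.tail = FALSE)

  zero_var <- mse < 1e-12
  constant <- zero_var & ss_geno < 1e-12
  p_omni[zero_var & !constant] <- 0
  p_omni[constant] <- NA_real_
  if (adjust == "BH") p_omni <- stats::p.adjust(p_omni, "BH")

  top <- max.col(mn, ties.method = "first")
  others <- cbind((top %% 3) + 1, ((top + 1) %% 3) + 1)
  se <- sqrt(2 * mse / R)
  pc <- matrix(NA_real_, Tn, 2)
  strict <- logical(Tn)
  for (j in 1:2) {
    diff <- mn[cbind(seq_len(Tn), top)] - mn[cbind(seq_len(Tn), others[, j])]
    tstat <- diff / se
    pj <- 2 * stats::pt(abs(tstat), df_err, lower.tail = FALSE)
    pj[zero_var & diff > 0] <- 0
    pj[zero_var & diff <= 0] <- 1
    pc[, j] <- pj
    strict <- if (j == 1) diff > 0 else strict & diff > 0
  }
  dominant <- ifelse(!constant & !is.na(p_omni) & p_omni < alpha &
                       strict & pc[, 1] < alpha & pc[, 2] < alpha,
                     c("SG1", "SG2", "SG3")[top], "NONE")
  out <- data.frame(
    triplet_id = dimnames(arr)[[3]], tissue = tissue, dominant = dominant,
    p_omnibus = p_omni, p_contrast1 = pc[, 1], p_contrast2 = pc[, 2],
    mean_SG1 = mn[, 1], mean_SG2 = mn[, 2], mean_SG3 = mn[, 3],
    zero_variance = zero_var, stringsAsFactors = FALSE)
  class(out) <- c("dominance_calls", "data.frame")
  out
}

#' Summarize dominance calls for a tissue
#'
#' Counts dominant triplets per subgenome, tests the counts against the
#' balanced 1:1:1 expectation with a chi-square test (df = 2), and
#' reports the pairwise dominant-count ratios SG3/SG1, SG3/SG2 and
#' SG2/SG1. With no dominant triplets at all the chi-square is undefined
#' and reported missing.
#'
#' @param calls a \code{dominance_calls} data.frame (one tissue)
#' @param n_tested number of triplets tested (defaults to
#'   \code{nrow(calls)})
#' @return one-row data.frame of class \code{dominance_summary}
#' @export
summarize_dominance <- function(calls, n_tested = nrow(calls)) {
  stopifnot(length(unique(calls$tissue)) <= 1)
  n <- vapply(c("SG1", "SG2", "SG3"),
              function(k) sum(calls$dominant == k), integer(1))
  if (sum(n) > 0) {
    cs <- suppressWarnings(stats::chisq.test(n))
    chisq <- unname(cs$statistic); p <- unname(cs$p.value)
  } else {
    chisq <- NA_real_; p <- NA_real_
  }
  rat <- function(a, b) if (n[b] > 0) n[a] / n[b] else Inf
  out <- data.frame(
    tissue = if (nrow(calls)) calls$tissue[1] else NA_character_,
    n_tested = n_tested, n_dom_SG1 = n[1], n_dom_SG2 = n[2],
    n_dom_SG3 = n[3], chisq = chisq, p_value = p,
    ratio_SG3_SG1 = rat(3, 1), ratio_SG3_SG2 = rat(3, 2),
    ratio_SG2_SG1 = rat(2, 1), row.names = NULL)
  class(out) <- c("dominance_summary", "data.frame")
  out
}

#' Dominance analysis across tissues
#'
#' Convenience wrapper: for each requested tissue, apply the expression
#' floor, call per-triplet dominance and summarize.
#'
#' @inheritParams call_dominance
#' @inheritParams filter_triplets
#' @param tissues tissue labels (default: all tissues present)
#' @return list with \code{calls} (per-triplet, all tissues) and
#'   \code{summary} (one row per tissue)
#' @export
dominance_analysis <- function(expr, tissues = NULL, alpha = 0.05,
                               min_tpm = 0.01, log_scale = TRUE,
                               offset = 0.01) {
  if (is.null(tissues)) tissues <- unique(expr$tissue)
  calls <- list(); summ <- list()
  for (ts in tissues) {
    sub <- filter_triplets(expr, ts, min_tpm)
    dc <- call_dominance(sub, ts, alpha = alpha, log_scale = log_scale,
                         offset = offset)
    calls[[ts]] <- dc
    summ[[ts]] <- summarize_dominance(dc)
  }
  list(calls = do.call(rbind, calls), summary = do.call(rbind, summ))
}
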