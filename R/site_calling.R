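#' Estimate the false methylation rate from spike-in counts
#'
#' The FMR (bisulfite conversion-failure rate) is the pooled fraction of
#' apparently methylated reads over the unmethylated spike-in genome:
#' sum(n_meth) / sum(n_total). Optional per-coverage-bin estimates are
#' reported alongside for diagnostics; the pooled value is what the site
#' caller uses.
#'
#' @param spikein data.frame of spike-in cytosine records.
#' @param coverage_bins optional numeric breaks for per-bin estimates.
#' @return list with `fmr`, `n_total`, `n_meth` and optionally
#'   `per_coverage_bin`.
#' @export
estimate_fmr <- function(spikein, coverage_bins = NULL) {
  if (is.null(spikein) || nrow(spikein) == 0 || sum(spikein$n_total) == 0) {
    stop("cannot estimate FMR: no spike-in reads")
  }
  fmr <- sum(spikein$n_meth) / sum(spikein$n_total)
  out <- list(fmr = fmr, n_total = sum(spikein$n_total),
              n_meth = sum(spikein$n_meth))
  if (!is.null(coverage_bins)) {
    bin <- cut(spikein$n_total, coverage_bins, include.lowest = TRUE)
    tot <- tapply(spikein$n_total, bin, sum)
    met <- tapply(spikein$n_meth, bin, sum)
    out$per_coverage_bin <- data.frame(bin = names(tot),
                                       fmr = as.numeric(met / tot),
                                       n_total = as.numeric(tot))
  }
  out
}

# Upper-tail binomial p-value P(X >= k | n, p0). Log-safe at p0 = 0:
# pbinom returns exactly 0 for k >= 1 and 1 for k = 0.
binom_upper_p <- function(k, n, p0) {
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Call significantly methylated cytosines
#'
#' Tests each cytosine with coverage `>= min_cov` against the null that its
#' reads are methylated only through conversion failure, with a one-sided
#' upper-tail binomial test at rate `fmr`. P-values are FDR-adjusted
#' (Benjamini-Hochberg) over all tested sites; a site is called methylated
#' when its q-value is at most `alpha` and its methylation rate reaches
#' `min_rate` in at least one of the four tissue-treatment combinations
#' (supply `rates_across_combinations`; by default the site's own rate is
#' used).
#'
#' @param table a [sample_table()] (typically replicate-merged).
#' @param fmr false methylation rate from [estimate_fmr()].
#' @param min_cov minimum coverage to test (default 3).
#' @param alpha FDR level (default 0.05).
#' @param min_rate minimum methylation rate in some combination (default
#'   0.20).
#' @param rates_across_combinations optional numeric vector, per record,
#'   of the maximum methylation rate over the four tissue-treatment
#'   combinations of this species.
#' @return data.frame: the records plus rate, tested, p, q, is_methylated.
#' @export
call_methylated_sites <- function(table, fmr, min_cov = 3L, alpha = 0.05,
                                  min_rate = 0.20,
                                  rates_across_combinations = NULL) {
  stopifnot(inherits(table, "sample_table"), fmr >= 0, fmr <= 1)
  rec <- table$records
  rate <- ifelse(rec$n_total > 0, rec$n_meth / rec$n_total, NA_real_)
  tested <- rec$n_total >= min_cov
  p <- rep(NA_real_, nrow(rec))
  p[tested] <- binom_upper_p(rec$n_meth[tested], rec$n_total[tested], fmr)
  q <- rep(NA_real_, nrow(rec))
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  maxrate <- if (is.null(rates_across_combinations)) rate else
    rates_across_combinations
  is_meth <- tested & !is.na(q) & q <= alpha & !is.na(maxrate) &
    maxrate >= min_rate
  out <- rec
  out$rate <- rate
  out$tested <- tested
  out$p <- p
  out$q <- q
  out$is_methylated <- is_meth
  out
}

#' Merge two biological replicates
#'
#' Sites differentially methylated between the replicates (two-sided
#' Fisher's exact test on the replicate counts, prefiltered to sites where
#' either replicate has a rate of at least `min_rate` and both reach
#' `min_cov`, FDR-adjusted at `alpha`) are removed; at remaining shared
#' sites the read counts are summed. Sites covered in only one replicate
#' cannot be tested for disagreement and are retained with that
#' replicate's counts; their number is reported as an attribute.
#'
#' @param rep1,rep2 [sample_table()]s identical up to the replicate index.
#' @param alpha FDR level for replicate-DMP removal (default 0.05).
#' @param min_cov,min_rate Fisher prefilter (defaults 3 and 0.20).
#' @return merged [sample_table()] with replicate index 0; attributes
#'   `n_removed` (replicate-DMPs dropped) and `n_single` (single-replicate
#'   sites retained).
#' @export
merge_replicates <- function(rep1, rep2, alpha = 0.05, min_cov = 3L,
                             min_rate = 0.20) {
  k1 <- rep1$key; k2 <- rep2$key
  if (!identical(k1$species, k2$species) || !identical(k1$tissue, k2$tissue)
      || !identical(k1$treatment, k2$treatment)) {
    stop("replicates disagree in species, tissue or treatment")
  }
  a <- rep1$records; b <- rep2$records
  ka <- paste(a$chrom, a$pos, a$strand)
  kb <- paste(b$chrom, b$pos, b$strand)
  ia <- match(kb, ka)
  shared_b <- which(!is.na(ia))
  shared_a <- ia[shared_b]
  # replicate-DMP test on shared sites
  n1 <- a$n_total[shared_a]; m1 <- a$n_meth[shared_a]
  n2 <- b$n_total[shared_b]; m2 <- b$n_meth[shared_b]
  r1 <- ifelse(n1 > 0, m1 / n1, 0); r2 <- ifelse(n2 > 0, m2 / n2, 0)
  test_it <- n1 >= min_cov & n2 >= min_cov & pmax(r1, r2) >= min_rate
  drop <- rep(FALSE, length(shared_a))
  if (any(test_it)) {
    idx <- which(test_it)
    pv <- fisher_p_vec(m1[idx], n1[idx] - m1[idx], m2[idx], n2[idx] - m2[idx])
    qv <- stats::p.adjust(pv, method = "BH")
    drop[idx] <- qv <= alpha
  }
  merged <- data.frame(chrom = a$chrom[shared_a], pos = a$pos[shared_a],
                       strand = a$strand[shared_a],
                       context = a$context[shared_a],
                       n_total = n1 + n2, n_meth = m1 + m2,
                       stringsAsFactors = FALSE)[!drop, , drop = FALSE]
  only_a <- a[-shared_a, , drop = FALSE]
  only_b <- b[-shared_b, , drop = FALSE]
  if (length(shared_a) == 0) { only_a <- a; only_b <- b }
  out <- rbind(merged, only_a, only_b)
  spike <- NULL
  if (!is.null(rep1$spikein) && !is.null(rep2$spikein)) {
    sa <- rep1$spikein; sb <- rep2$spikein
    i <- match(paste(sb$chrom, sb$pos, sb$strand),
               paste(sa$chrom, sa$pos, sa$strand))
    if (!anyNA(i) && length(i) == nrow(sa)) {
      spike <- sa
      spike$n_total[i] <- sa$n_total[i] + sb$n_total
      spike$n_meth[i] <- sa$n_meth[i] + sb$n_meth
    } else spike <- rbind(sa, sb)
  } else spike <- rep1$spikein %||% rep2$spikein
  key <- sample_key(k1$species, k1$tissue, k1$treatment, 0L)
  res <- sample_table(key, out, spike)
  attr(res, "n_removed") <- sum(drop)
  attr(res, "n_single") <- nrow(only_a) + nrow(only_b)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Vectorised two-sided Fisher exact p for 2x2 tables given as four count
# vectors [[x11, x12], [x21, x22]]. Uses the point-probability rule: sum of
# hypergeometric probabilities not exceeding that of the observed table
# (with a small relative tolerance), identical to stats::fisher.test.
fisher_p_vec <- function(x11, x12, x21, x22) {
  vapply(seq_along(x11), function(i) {
    fisher_p(x11[i], x12[i], x21[i], x22[i])
  }, numeric(1))
}

fisher_p <- function(x11, x12, x21, x22) {
  m <- x11 + x21        # first-column margin
  n <- x12 + x22
  k <- x11 + x12        # first-row margin
  lo <- max(0L, k - n); hi <- min(k, m)
  supp <- lo:hi
  d <- stats::dhyper(supp, m, n, k)
  sum(d[d <= d[x11 - lo + 1] * (1 + 1e-7)])
}
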