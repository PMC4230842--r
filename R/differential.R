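#' The four sanctioned pairwise comparisons of the design
#'
#' Differential testing is restricted to comparisons that change exactly
#' one factor: root vs shoot at each temperature (axis `tissue`) and
#' control vs cold in each tissue (axis `treatment`). Combination labels
#' are `"tissue.treatment"` as produced by the design helpers.
#'
#' @return data.frame with columns a, b, axis.
#' @export
sanctioned_comparisons <- function() {
  data.frame(
    a = c("root.control23", "root.cold4", "root.control23", "shoot.control23"),
    b = c("shoot.control23", "shoot.cold4", "root.cold4", "shoot.cold4"),
    axis = c("tissue", "tissue", "treatment", "treatment"),
    stringsAsFactors = FALSE)
}

#' Call differentially methylated positions between two samples
#'
#' Two-sided Fisher's exact test on the 2x2 table of methylated vs
#' unmethylated read counts at each site covered (>= `min_cov`) in both
#' replicate-merged samples. Only positions whose methylation rate reaches
#' `min_rate` in at least one of the two samples are tested - the
#' prefilter that keeps the multiple-testing burden down. Q-values are
#' Benjamini-Hochberg within the comparison.
#'
#' @param table_a,table_b replicate-merged [sample_table()]s.
#' @param min_cov minimum coverage in both samples (default 3).
#' @param min_rate prefilter rate threshold (default 0.20).
#' @param alpha FDR level defining a DMP (default 0.05).
#' @return data.frame of tested sites: chrom, pos, strand, context, counts,
#'   rates, p, q, direction (sign of rateA - rateB), is_dmp; attribute
#'   `n_skipped` counts sites covered in only one sample.
#' @export
call_dmps <- function(table_a, table_b, min_cov = 3L, min_rate = 0.20,
                      alpha = 0.05) {
  a <- table_a$records; b <- table_b$records
  ka <- paste(a$chrom, a$pos, a$strand)
  kb <- paste(b$chrom, b$pos, b$strand)
  ib <- match(ka, kb)
  shared <- which(!is.na(ib))
  n_skipped <- (nrow(a) - length(shared)) + (nrow(b) - length(shared))
  a2 <- a[shared, , drop = FALSE]
  b2 <- b[ib[shared], , drop = FALSE]
  covered <- a2$n_total >= min_cov & b2$n_total >= min_cov
  a2 <- a2[covered, , drop = FALSE]; b2 <- b2[covered, , drop = FALSE]
  ra <- a2$n_meth / a2$n_total
  rb <- b2$n_meth / b2$n_total
  test <- pmax(ra, rb) >= min_rate
  out <- data.frame(chrom = a2$chrom, pos = a2$pos, strand = a2$strand,
                    context = a2$context,
                    n_meth_a = a2$n_meth, n_total_a = a2$n_total,
                    n_meth_b = b2$n_meth, n_total_b = b2$n_total,
                    rate_a = ra, rate_b = rb,
                    stringsAsFactors = FALSE)[test, , drop = FALSE]
  if (nrow(out)) {
    out$p <- fisher_p_vec(out$n_meth_a, out$n_total_a - out$n_meth_a,
                          out$n_meth_b, out$n_total_b - out$n_meth_b)
    out$q <- stats::p.adjust(out$p, method = "BH")
  } else {
    out$p <- numeric(0); out$q <- numeric(0)
  }
  out$direction <- sign(out$rate_a - out$rate_b)
  out$is_dmp <- out$q <= alpha
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Select candidate regions for differential methylation testing
#'
#' The union of all samples' methylated regions is flattened into disjoint
#' intervals; an interval is a candidate when at least one sample's MR
#' covers it and at least one sample's does not (variable methylation
#' state), and it contains at least `min_c` cytosines covered in every
#' sample. This filter plays the role of the MR reduction that precedes
#' region testing.
#'
#' @param mrs_by_sample named list (one entry per tissue-treatment
#'   combination) of region frames from [segment_methylome()].
#' @param tables named list of the matching [sample_table()]s, used for
#'   the coverage requirement.
#' @param min_c minimum number of commonly covered cytosines (default 4).
#' @param min_cov per-sample coverage floor for "covered" (default 1).
#' @return data.frame of candidates: chrom, start, end, covered_by
#'   (comma-separated samples whose MR covers the interval), n_common.
#' @export
select_dmr_candidates <- function(mrs_by_sample, tables, min_c = 4L,
                                  min_cov = 1L) {
  nm <- names(mrs_by_sample)
  stopifnot(!is.null(nm), all(nm %in% names(tables)))
  all_gr <- list()
  for (s in nm) {
    m <- mrs_by_sample[[s]]
    if (nrow(m) == 0) next
    all_gr[[s]] <- GenomicRanges::GRanges(
      m$chrom, IRanges::IRanges(m$start + 1L, m$end), sample = s)
  }
  if (length(all_gr) == 0) return(empty_candidate_frame())
  u <- do.call(c, unname(all_gr))
  dj <- GenomicRanges::disjoin(u)
  hits <- GenomicRanges::findOverlaps(dj, u)
  cov_by <- tapply(u$sample[S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits),
                   function(x) sort(unique(x)))
  n_cov <- vapply(cov_by, length, 0L)
  is_cand <- n_cov >= 1 & n_cov < length(nm)
  idx <- as.integer(names(cov_by))[is_cand]
  if (length(idx) == 0) return(empty_candidate_frame())
  cand <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(dj))[idx],
    start = GenomicRanges::start(dj)[idx] - 1L,
    end = GenomicRanges::end(dj)[idx],
    covered_by = vapply(cov_by[is_cand], paste, character(1),
                        collapse = ","),
    stringsAsFactors = FALSE)
  # disjoin() splits at every MR endpoint; abutting pieces covered by the
  # same sample set are one candidate interval
  cand <- cand[order(cand$chrom, cand$start), , drop = FALSE]
  if (nrow(cand) > 1) {
    new_run <- c(TRUE, !(cand$chrom[-1] == cand$chrom[-nrow(cand)] &
                           cand$start[-1] == cand$end[-nrow(cand)] &
                           cand$covered_by[-1] ==
                             cand$covered_by[-nrow(cand)]))
    run <- cumsum(new_run)
    cand <- data.frame(
      chrom = tapply(cand$chrom, run, `[`, 1),
      start = as.integer(tapply(cand$start, run, min)),
      end = as.integer(tapply(cand$end, run, max)),
      covered_by = tapply(cand$covered_by, run, `[`, 1),
      stringsAsFactors = FALSE)
  }
  # common-coverage filter
  cand$n_common <- vapply(seq_len(nrow(cand)), function(i) {
    common <- NULL
    for (s in nm) {
      r <- tables[[s]]$records
      inside <- r$chrom == cand$chrom[i] & r$pos > cand$start[i] &
        r$pos <= cand$end[i] & r$n_total >= min_cov
      key <- paste(r$pos[inside], r$strand[inside])
      common <- if (is.null(common)) key else intersect(common, key)
    }
    length(common)
  }, 0L)
  out <- cand[cand$n_common >= min_c, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_candidate_frame <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             covered_by = character(), n_common = integer(),
             stringsAsFactors = FALSE)
}

# Sites of one sample falling in a 0-based half-open interval.
sites_in_region <- function(table, chrom, start, end, min_cov = 1L) {
  r <- table$records
  r[r$chrom == chrom & r$pos > start & r$pos <= end &
      r$n_total >= min_cov, , drop = FALSE]
}

#' Beta-binomial log-odds test for differential methylation of a region
#'
#' For each sequence context present in the region, a beta-binomial
#' distribution is fitted by maximum likelihood to each group's sites and
#' to the pooled sites; the log-odds statistic is the summed gain in log
#' likelihood of the separate fits over the joint fit. Twice the statistic
#' is referred to a chi-squared distribution with 2 degrees of freedom per
#' context per additional group (each separate distribution adds an
#' (alpha, beta) pair).
#'
#' @param site_groups list (length >= 2) of data.frames of cytosine records
#'   (one per group/sample) restricted to the region.
#' @return list with `lod`, `df`, `p`, `contexts`.
#' @export
test_dmr <- function(site_groups) {
  stopifnot(length(site_groups) >= 2)
  ctxs <- sort(unique(unlist(lapply(site_groups, `[[`, "context"))))
  k <- length(site_groups)
  lod <- 0
  used_ctx <- character(0)
  for (ctx in ctxs) {
    per <- lapply(site_groups, function(g) g[g$context == ctx, ,
                                             drop = FALSE])
    n_per <- vapply(per, nrow, 0L)
    if (sum(n_per > 0) < 2) next  # context informative in < 2 groups
    ll_sep <- 0
    for (g in per) {
      if (nrow(g) == 0) next
      ll_sep <- ll_sep + fit_betabinom(g$n_meth, g$n_total)$loglik
    }
    pooled <- do.call(rbind, per)
    ll_joint <- fit_betabinom(pooled$n_meth, pooled$n_total)$loglik
    lod <- lod + (ll_sep - ll_joint)
    used_ctx <- c(used_ctx, ctx)
  }
  df <- 2L * length(used_ctx) * (k - 1L)
  if (df == 0) return(list(lod = 0, df = 0L, p = 1, contexts = character(0)))
  lod <- max(lod, 0)
  p <- stats::pchisq(2 * lod, df, lower.tail = FALSE)
  list(lod = lod, df = df, p = p, contexts = used_ctx)
}

#' Group samples at a candidate region and confirm the grouping
#'
#' Pairwise region tests are run for the four sanctioned comparisons;
#' samples connected by a non-significant pair (p >= `p_group`) are merged
#' greedily (single linkage) into groups, so significantly different
#' samples land in different groups. Counts are then summed within groups
#' and the same log-odds test is re-run between the combined groups; the
#' confirmation p-value is what enters the region-level FDR. Candidates
#' whose samples form a single group are `filtered`. Non-transitive
#' pairwise significance is resolved by the greedy merge and flagged.
#'
#' @param candidate one row of [select_dmr_candidates()] output.
#' @param tables named list of the four combination [sample_table()]s.
#' @param p_group pairwise significance threshold for separation
#'   (default 0.01).
#' @param min_cov coverage floor for sites entering the test.
#' @return list: `status` ("tested" or "filtered"), `groups` (named
#'   membership vector), `p` (confirmation p, NA if filtered), `lod`,
#'   `df`, `pairwise` (per-comparison p), `n_sig_samples`,
#'   `nontransitive` flag.
#' @export
group_and_confirm <- function(candidate, tables, p_group = 0.01,
                              min_cov = 1L) {
  nm <- names(tables)
  sites <- lapply(tables, function(t) {
    sites_in_region(t, candidate$chrom, candidate$start, candidate$end,
                    min_cov)
  })
  cmp <- sanctioned_comparisons()
  cmp <- cmp[cmp$a %in% nm & cmp$b %in% nm, , drop = FALSE]
  pw <- rep(NA_real_, nrow(cmp))
  for (i in seq_len(nrow(cmp))) {
    ga <- sites[[cmp$a[i]]]; gb <- sites[[cmp$b[i]]]
    if (nrow(ga) == 0 || nrow(gb) == 0) next
    pw[i] <- test_dmr(list(ga, gb))$p
  }
  # greedy single-linkage: start each sample in its own group, merge
  # groups connected by any non-significant (or untested) sanctioned pair
  group <- stats::setNames(seq_along(nm), nm)
  for (i in order(pw, decreasing = TRUE)) {  # most-similar pairs first
    if (!is.na(pw[i]) && pw[i] < p_group) next
    ga <- group[cmp$a[i]]; gb <- group[cmp$b[i]]
    if (ga != gb) group[group == gb] <- ga
  }
  # flag non-transitivity: a significant pair that ended up merged
  nontrans <- any(!is.na(pw) & pw < p_group &
                    group[cmp$a] == group[cmp$b])
  group <- stats::setNames(match(group, unique(group)), nm)
  n_groups <- length(unique(group))
  sig_samples <- unique(c(cmp$a[!is.na(pw) & pw < p_group],
                          cmp$b[!is.na(pw) & pw < p_group]))
  if (n_groups < 2) {
    return(list(status = "filtered", groups = group, p = NA_real_,
                lod = NA_real_, df = NA_integer_, pairwise = pw,
                n_sig_samples = length(sig_samples),
                nontransitive = nontrans))
  }
  combined <- lapply(seq_len(n_groups), function(g) {
    do.call(rbind, sites[names(group)[group == g]])
  })
  conf <- test_dmr(combined)
  list(status = "tested", groups = group, p = conf$p, lod = conf$lod,
       df = conf$df, pairwise = pw, n_sig_samples = length(sig_samples),
       nontransitive = nontrans)
}

#' Storey q-values
#'
#' Estimates the proportion of true nulls pi0 on the lambda grid
#' 0.05, 0.10, ..., 0.95 with a cubic smoothing spline evaluated at the
#' largest lambda (clamped into (0, 1]), then computes
#' q_i = min over {j : p_j >= p_i} of pi0 * m * p_j / rank(p_j). With
#' fewer than 100 p-values the pi0 estimate is unstable and the function
#' falls back to pi0 = 1 (Benjamini-Hochberg) with a warning; forcing
#' `pi0 = 1` reproduces BH exactly.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param lambda grid for pi0 estimation.
#' @param pi0 optionally force the null proportion.
#' @return numeric vector of q-values, monotone in p; attribute `pi0`.
#' @export
storey_fdr <- function(p, lambda = seq(0.05, 0.95, by = 0.05), pi0 = NULL) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  ok <- !is.na(p)
  m <- sum(ok)
  if (m == 0) return(p)
  if (is.null(pi0)) {
    if (m < 100) {
      warning("fewer than 100 p-values; using pi0 = 1 (BH-equivalent)")
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p[ok] > l) / (1 - l),
                      numeric(1))
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
      pi0 <- min(max(pi0, 1e-8), 1)
    }
  }
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  o <- order(pv, decreasing = TRUE)
  qv <- numeric(m)
  rank_desc <- m:1  # rank of sorted-descending p-values
  qv[o] <- cummin(pi0 * m * pv[o] / rank_desc)
  q[ok] <- pmin(qv, 1)
  attr(q, "pi0") <- pi0
  q
}

#' Resolve overlapping regions by maximum total support
#'
#' Among mutually overlapping regions a maximum-weight non-overlapping
#' subset is retained, the weight being the number of samples with
#' significant differential methylation. Exact dynamic-programming
#' solution of the weighted interval scheduling problem per chromosome;
#' ties in total weight are broken toward larger total region length, then
#' leftmost starts.
#'
#' @param dmrs data.frame with chrom, start, end and a `weight` column.
#' @return the retained subset, original row order.
#' @export
resolve_overlaps <- function(dmrs) {
  if (nrow(dmrs) == 0) return(dmrs)
  keep <- logical(nrow(dmrs))
  for (ch in unique(dmrs$chrom)) {
    idx <- which(dmrs$chrom == ch)
    d <- dmrs[idx, , drop = FALSE]
    o <- order(d$end, d$start)
    d <- d[o, , drop = FALSE]
    n <- nrow(d)
    # p[i]: last interval (in end order) ending at or before d$start[i]
    pred <- vapply(seq_len(n), function(i) {
      j <- which(d$end <= d$start[i])
      if (length(j)) max(j) else 0L
    }, 0L)
    # DP over lexicographic value (weight, total length, -sum of starts)
    val <- matrix(0, n + 1, 3)
    take <- logical(n)
    better <- function(x, y) {
      for (c in 1:3) {
        if (x[c] > y[c] + 1e-9) return(TRUE)
        if (x[c] < y[c] - 1e-9) return(FALSE)
      }
      FALSE
    }
    for (i in seq_len(n)) {
      with_i <- val[pred[i] + 1, ] +
        c(d$weight[i], d$end[i] - d$start[i], -d$start[i])
      without_i <- val[i, ]
      if (better(with_i, without_i)) {
        val[i + 1, ] <- with_i
        take[i] <- TRUE
      } else {
        val[i + 1, ] <- without_i
      }
    }
    sel <- logical(n)
    i <- n
    while (i >= 1) {
      if (take[i]) { sel[i] <- TRUE; i <- pred[i] } else i <- i - 1L
    }
    keep[idx[o][sel]] <- TRUE
  }
  out <- dmrs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call differentially methylated regions for one species
#'
#' Full region pipeline: candidate selection over the four combinations'
#' MRs, grouping + confirmation test per candidate, Storey FDR over the
#' confirmation p-values (regions with q below `fdr` are DMRs), and
#' overlap resolution by maximum significant-sample support.
#'
#' @param mrs_by_sample named list of trimmed MR frames per combination.
#' @param tables named list of the matching replicate-merged tables.
#' @param fdr region-level FDR threshold (default 0.01).
#' @param p_group pairwise grouping threshold (default 0.01).
#' @param min_c,min_cov candidate filters (defaults 4 and 1).
#' @return list: `dmrs` (confirmed, non-overlapping regions with p, q,
#'   groups, weight), `candidates` (all candidates with test results),
#'   `pi0`.
#' @export
call_dmrs <- function(mrs_by_sample, tables, fdr = 0.01, p_group = 0.01,
                      min_c = 4L, min_cov = 1L) {
  cand <- select_dmr_candidates(mrs_by_sample, tables, min_c, min_cov)
  if (nrow(cand) == 0) {
    return(list(dmrs = cand, candidates = cand, pi0 = NA_real_))
  }
  res <- lapply(seq_len(nrow(cand)), function(i) {
    group_and_confirm(cand[i, , drop = FALSE], tables, p_group, min_cov)
  })
  cand$status <- vapply(res, `[[`, character(1), "status")
  cand$p <- vapply(res, `[[`, numeric(1), "p")
  cand$lod <- vapply(res, `[[`, numeric(1), "lod")
  cand$n_sig_samples <- vapply(res, `[[`, integer(1), "n_sig_samples")
  cand$groups <- vapply(res, function(r) {
    paste(names(r$groups), r$groups, sep = "=", collapse = ",")
  }, character(1))
  cand$q <- suppressWarnings(storey_fdr(cand$p))
  pi0 <- attr(cand$q, "pi0")
  cand$status[!is.na(cand$q) & cand$q < fdr &
                cand$status == "tested"] <- "confirmed"
  dmrs <- cand[cand$status == "confirmed", , drop = FALSE]
  if (nrow(dmrs)) {
    dmrs$weight <- dmrs$n_sig_samples
    dmrs <- resolve_overlaps(dmrs)
  }
  list(dmrs = dmrs, candidates = cand, pi0 = pi0)
}
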