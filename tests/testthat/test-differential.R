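test_that("Fisher p-values match stats::fisher.test and the enumeration oracle", {
  set.seed(41)
  for (i in 1:50) {
    x <- matrix(rpois(4, 8), 2)
    p_ours <- cometh:::fisher_p(x[1, 1], x[1, 2], x[2, 1], x[2, 2])
    expect_equal(p_ours, fisher.test(x)$p.value, tolerance = 1e-9)
    expect_equal(p_ours, enum_fisher_p(x[1, 1], x[1, 2], x[2, 1], x[2, 2]),
                 tolerance = 1e-9)
  }
})

test_that("DMP calling applies the prefilter and is symmetric", {
  k <- design_combinations("sp1")
  a <- sample_table(k[[1]], make_records(c(10, 20, 30), c(10, 20, 10),
                                         c(5, 3, 8)))
  b <- sample_table(k[[2]], make_records(c(10, 20, 30), c(10, 20, 10),
                                         c(5, 2, 1)))
  d <- call_dmps(a, b, min_cov = 3, min_rate = 0.20)
  # pos 20: rates 0.15 vs 0.10 -> below prefilter, not tested
  expect_false(20 %in% d$pos)
  # identical counts give p = 1
  expect_equal(d$p[d$pos == 10], 1.0)
  d2 <- call_dmps(b, a, min_cov = 3, min_rate = 0.20)
  expect_equal(d$p, d2$p)
  expect_equal(d$direction, -d2$direction)
})

test_that("sites covered in one sample only are skipped and counted", {
  k <- design_combinations("sp1")
  a <- sample_table(k[[1]], make_records(c(10, 20), c(10, 10), c(9, 0)))
  b <- sample_table(k[[2]], make_records(10, 10, 0))
  d <- call_dmps(a, b)
  expect_equal(nrow(d), 1)
  expect_equal(attr(d, "n_skipped"), 1)
})

test_that("candidate selection keeps intervals of variable methylation state", {
  k <- design_combinations("sp1")
  rec <- make_records(seq(5, 295, by = 10), n_total = 10, n_meth = 5)
  tables <- lapply(k, function(key) sample_table(key, rec))
  mr <- function(s, e) data.frame(chrom = "chr1", start = s, end = e,
                                  stringsAsFactors = FALSE)
  # identical MR sets across samples: nothing to test
  same <- lapply(tables, function(x) mr(100, 200))
  expect_equal(nrow(select_dmr_candidates(same, tables)), 0)
  # an MR in exactly one sample is a candidate
  one <- list(mr(100, 200), mr(0, 0)[0, ], mr(0, 0)[0, ], mr(0, 0)[0, ])
  names(one) <- names(tables)
  cand <- select_dmr_candidates(one, tables, min_c = 4)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$start, 100)
  expect_equal(cand$end, 200)
  # too few commonly covered cytosines: filtered out
  expect_equal(nrow(select_dmr_candidates(one, tables, min_c = 50)), 0)
})

test_that("candidate intervals equal an independent sweep-line recount", {
  set.seed(42)
  k <- design_combinations("sp1")
  rec <- make_records(seq(1, 999, by = 2), n_total = 10, n_meth = 5)
  tables <- lapply(k, function(key) sample_table(key, rec))
  for (trial in 1:5) {
    mrs <- lapply(k, function(key) {
      n <- sample(0:4, 1)
      s <- sort(sample(seq(0, 900, by = 10), n))
      data.frame(chrom = rep("chr1", n), start = s,
                 end = s + sample(seq(20, 80, by = 10), n, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    names(mrs) <- names(tables)
    cand <- select_dmr_candidates(mrs, tables, min_c = 1)
    # oracle: per-base sample-coverage profile, runs with 1..3 covering
    # samples are candidate intervals
    prof <- matrix(FALSE, 1000, 4)
    for (j in 1:4) {
      m <- mrs[[j]]
      for (r in seq_len(nrow(m))) {
        prof[(m$start[r] + 1):m$end[r], j] <- TRUE
      }
    }
    nc <- rowSums(prof)
    in_cand <- nc >= 1 & nc < 4
    # within a candidate run the covering-sample *set* must be constant
    sig <- apply(prof, 1, paste, collapse = "")
    sig[!in_cand] <- "out"
    r <- rle(sig)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    keep <- r$values != "out"
    oracle <- data.frame(start = starts[keep] - 1, end = ends[keep])
    # sites are at odd positions every 2 bp, so min_c = 1 needs >= 1 site
    n_sites <- vapply(seq_len(nrow(oracle)), function(i) {
      sum(rec$pos > oracle$start[i] & rec$pos <= oracle$end[i])
    }, 0L)
    oracle <- oracle[n_sites >= 1, , drop = FALSE]
    expect_equal(cand$start, oracle$start)
    expect_equal(cand$end, oracle$end)
  }
})

test_that("the region log-odds test is null at identical data, powerful apart", {
  sites <- function(rate, n = 20, cov = 20, ctx = "CG") {
    make_records(seq(10, 10 * n, by = 10), n_total = cov,
                 n_meth = rbinom(n, cov, rate), context = ctx)
  }
  set.seed(43)
  a <- sites(0.5)
  same <- test_dmr(list(a, a))
  expect_lt(same$lod, 0.51)
  expect_gt(same$p, 0.3)
  strong <- test_dmr(list(sites(0.8), sites(0.1)))
  expect_lt(strong$p, 1e-6)
  expect_equal(strong$df, 2L)
  # df grows with the number of contexts present
  two_ctx <- test_dmr(list(rbind(sites(0.8), sites(0.7, ctx = "CHG")),
                           rbind(sites(0.1), sites(0.1, ctx = "CHG"))))
  expect_equal(two_ctx$df, 4L)
})

test_that("grouping separates tissues and confirmation tests combined counts", {
  k <- design_combinations("sp1")
  set.seed(44)
  mk <- function(rate) {
    make_records(seq(105, 195, by = 10), n_total = 30,
                 n_meth = rbinom(10, 30, rate))
  }
  tables <- list(
    root.control23 = sample_table(k$root.control23, mk(0.8)),
    root.cold4 = sample_table(k$root.cold4, mk(0.8)),
    shoot.control23 = sample_table(k$shoot.control23, mk(0.05)),
    shoot.cold4 = sample_table(k$shoot.cold4, mk(0.05)))
  cand <- data.frame(chrom = "chr1", start = 100, end = 200)
  res <- group_and_confirm(cand, tables)
  expect_equal(res$status, "tested")
  g <- res$groups
  expect_equal(g[["root.control23"]], g[["root.cold4"]])
  expect_equal(g[["shoot.control23"]], g[["shoot.cold4"]])
  expect_false(g[["root.control23"]] == g[["shoot.control23"]])
  expect_lt(res$p, 1e-6)
  expect_equal(res$n_sig_samples, 4)
  # all samples alike: one group, filtered
  alike <- lapply(k, function(key) sample_table(key, mk(0.5)))
  res2 <- group_and_confirm(cand, alike)
  expect_equal(res2$status, "filtered")
  expect_true(is.na(res2$p))
})

test_that("Storey q-values reduce to BH at pi0 = 1 and are monotone", {
  set.seed(45)
  p <- runif(500)^1.5
  q <- storey_fdr(p, pi0 = 1)
  expect_equal(as.numeric(q), p.adjust(p, "BH"), tolerance = 1e-12)
  q2 <- suppressWarnings(storey_fdr(runif(50)))  # small m falls back to BH
  expect_equal(attr(q2, "pi0"), 1)
  p3 <- c(runif(2000), rbeta(500, 0.2, 5))
  q3 <- storey_fdr(p3)
  expect_true(all(diff(q3[order(p3)]) > -1e-12))
  expect_lt(attr(q3, "pi0"), 1 + 1e-9)
})

test_that("pi0 is estimated near one for uniform p-values", {
  set.seed(46)
  p <- runif(1e4)
  q <- storey_fdr(p)
  expect_gte(attr(q, "pi0"), 0.9)
  expect_lte(attr(q, "pi0"), 1.0)
})

test_that("overlap resolution keeps the maximum-support independent set", {
  d <- data.frame(chrom = "chr1", start = c(0, 50), end = c(40, 90),
                  weight = c(2, 3))
  expect_equal(nrow(resolve_overlaps(d)), 2)  # disjoint: both kept
  d2 <- data.frame(chrom = "chr1", start = c(0, 20), end = c(40, 60),
                   weight = c(3, 1))
  kept <- resolve_overlaps(d2)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$weight, 3)
  # random instances against exhaustive subset search
  set.seed(47)
  for (trial in 1:20) {
    n <- sample(3:12, 1)
    s <- sample(0:100, n, TRUE)
    dd <- data.frame(chrom = "chr1", start = s,
                     end = s + sample(5:40, n, TRUE),
                     weight = sample(1:4, n, TRUE))
    kept <- resolve_overlaps(dd)
    best <- -1
    for (mask in 0:(2^n - 1)) {
      sel <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
      if (length(sel) > 1) {
        o <- order(dd$start[sel]); ss <- sel[o]
        if (any(dd$end[ss][-length(ss)] > dd$start[ss][-1])) next
      }
      best <- max(best, sum(dd$weight[sel]))
    }
    expect_equal(sum(kept$weight), best)
    o <- order(kept$start)
    if (nrow(kept) > 1) {
      expect_true(all(kept$end[o][-nrow(kept)] <= kept$start[o][-1]))
    }
  }
})
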