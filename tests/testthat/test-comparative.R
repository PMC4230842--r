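make_map <- function(ctx, st) {
  n <- nrow(ctx)
  data.frame(chrom_1 = "c1", pos_1 = seq_len(n) * 10, strand_1 = "+",
             context_1 = ctx[, 1],
             chrom_2 = "c2", pos_2 = seq_len(n) * 10, strand_2 = "+",
             context_2 = ctx[, 2],
             chrom_3 = "c3", pos_3 = seq_len(n) * 10, strand_3 = "+",
             context_3 = ctx[, 3],
             status_1 = st[, 1], status_2 = st[, 2], status_3 = st[, 3],
             stringsAsFactors = FALSE)
}

test_that("context matching keeps same-label sites and drops transitions", {
  ctx <- rbind(c("CG", "CG", "CG"),      # identical CG: keep
               c("CHH", "CHH", "CHH"),   # H differences invisible: keep
               c("CHH", "CHH", "CHG"),   # transition (H->G): drop
               c("CHG", "CG", "CHG"))    # transition: drop
  st <- matrix("unmethylated", 4, 3)
  expect_equal(match_context(make_map(ctx, st)), c(TRUE, TRUE, FALSE, FALSE))
})

test_that("conservation classes follow the gain/loss definitions", {
  ctx <- matrix("CG", 6, 3)
  st <- rbind(c("methylated", "methylated", "methylated"),
              c("unmethylated", "methylated", "unmethylated"),
              c("methylated", "methylated", "unmethylated"),
              c("unmethylated", "unmethylated", "unmethylated"),
              c("methylated", "untestable", "methylated"),
              c("methylated", "unmethylated", "unmethylated"))
  cl <- classify_sites(make_map(ctx, st))
  expect_equal(cl$class,
               c("conserved3", "gain_sp2", "loss_sp3", "unmethylated",
                 "untestable", "gain_sp1"))
  tal <- attr(cl, "tally")
  # classes partition the kept, fully-testable sites
  expect_equal(sum(tal), 5)
})

test_that("classification reproduces the generator tally on simulated maps", {
  g <- simulate_genome(1, 20000, seed = 51)
  am <- simulate_alignment_map(g$catalogue, n_sites = 2000,
                               divergence = 0.1, seed = 52)
  cl <- classify_sites(am$map)
  tal <- attr(cl, "tally")
  expect_identical(as.vector(tal[names(am$tally)]), as.vector(am$tally))
  # exclusions are exactly the H->G substituted sites
  expect_equal(sum(cl$class == "excluded"), am$n_h_to_g)
})

test_that("gain density is gains over gains plus losses per window", {
  ctx <- matrix("CG", 9, 3)
  st <- matrix("unmethylated", 9, 3)
  st[1:3, 1] <- "methylated"              # 3 gains in species 1
  st[4, ] <- "methylated"; st[4, 2] <- "unmethylated"  # one loss
  st[5:9, ] <- "methylated"               # conserved, not gain/loss
  m <- make_map(ctx, st)
  m$pos_1 <- c(rep(100, 4), rep(15000, 5))
  cl <- classify_sites(m)
  gd <- gain_density(cl, window = 10000)
  expect_equal(nrow(gd), 1)  # second window has no gains or losses
  expect_equal(gd$density, 0.75)
  # all-loss window scores zero
  st2 <- matrix("methylated", 5, 3)
  st2[, 3] <- c("unmethylated")[rep(1, 5)]
  m2 <- make_map(matrix("CG", 5, 3), st2)
  gd2 <- gain_density(classify_sites(m2), window = 10000)
  expect_equal(gd2$density, 0)
  # windowed recount oracle on a random classification
  g <- simulate_genome(1, 15000, seed = 53)
  am <- simulate_alignment_map(g$catalogue, n_sites = 1500,
                               divergence = 0.05, seed = 54)
  cl3 <- classify_sites(am$map)
  gd3 <- gain_density(cl3, window = 5000)
  for (i in seq_len(nrow(gd3))) {
    s <- cl3$pos_1 > gd3$win_start[i] & cl3$pos_1 <= gd3$win_end[i]
    gains <- sum(grepl("^gain", cl3$class[s]))
    losses <- sum(grepl("^loss", cl3$class[s]))
    expect_equal(gd3$gains[i], gains)
    expect_equal(gd3$density[i], gains / (gains + losses))
  }
})

test_that("gene body methylation is the methylated fraction of CG sites", {
  calls <- data.frame(chrom = "chr1", pos = seq(10, 200, by = 10),
                      context = rep(c("CG", "CHH"), 10),
                      tested = TRUE, rate = 0.1,
                      is_methylated = FALSE, stringsAsFactors = FALSE)
  calls$is_methylated[calls$pos %in% c(10, 50)] <- TRUE  # 2 of 10 CG
  gene <- data.frame(chrom = "chr1", start = 0, end = 200)
  expect_equal(gene_body_methylation(gene, calls), 0.2)
  # shuffled input order gives the same answer
  expect_equal(gene_body_methylation(gene, calls[sample(nrow(calls)), ]),
               0.2)
  # no testable CG in span -> NA
  gene2 <- data.frame(chrom = "chr2", start = 0, end = 200)
  expect_true(is.na(gene_body_methylation(gene2, calls)))
})

test_that("feature methylation averages rates including unmethylated sites", {
  calls <- data.frame(chrom = "chr1", pos = c(10, 20, 30, 40),
                      context = "CG", tested = TRUE,
                      rate = c(0, 0, 1, 1), stringsAsFactors = FALSE)
  feats <- data.frame(chrom = "chr1", start = 0, end = 100, kind = "exon")
  expect_equal(feature_methylation_rate(feats, calls, "CG"), 0.5)
  # outgroup normalisation divides by the reference rate
  expect_equal(feature_methylation_rate(feats, calls, "CG",
                                        norm_rate = 0.25), 2)
  expect_true(is.na(feature_methylation_rate(feats[0, ], calls, "CG")))
})

test_that("site annotation is total and follows the precedence order", {
  feats <- data.frame(
    chrom = "chr1",
    start = c(100, 100, 150, 300),
    end = c(250, 140, 170, 400),
    kind = c("intron", "exon", "TE", "exon"),
    stringsAsFactors = FALSE)
  sites <- data.frame(chrom = "chr1", pos = c(120, 160, 200, 350, 999))
  lab <- annotate_sites(sites, feats)
  expect_equal(lab, c("exon",      # exon beats intron
                      "TE",        # TE beats intron
                      "intron",
                      "exon",
                      "intergenic"))
  expect_length(lab, nrow(sites))
})

test_that("hypergeometric overlap p equals the tail-sum oracle", {
  # N = 100 orthologs, 10 bearing regions in each species, 5 shared
  p <- phyper(4, 10, 90, 10, lower.tail = FALSE)
  oracle <- sum(choose(10, 5:10) * choose(90, 10 - (5:10))) / choose(100, 10)
  expect_equal(p, oracle, tolerance = 1e-12)
  om <- data.frame(sp1 = sprintf("a%d", 1:100), sp2 = sprintf("b%d", 1:100),
                   sp3 = sprintf("c%d", 1:100), stringsAsFactors = FALSE)
  genes <- lapply(c("a", "b", "c"), function(pre) {
    data.frame(chrom = "chr1", start = (0:99) * 100, end = (0:99) * 100 + 50,
               kind = "gene", gene_id = sprintf("%s%d", pre, 1:100),
               stringsAsFactors = FALSE)
  })
  names(genes) <- c("sp1", "sp2", "sp3")
  mk_reg <- function(idx) {
    data.frame(chrom = "chr1", start = (idx - 1) * 100,
               end = (idx - 1) * 100 + 50, stringsAsFactors = FALSE)
  }
  regs <- list(sp1 = mk_reg(1:10), sp2 = mk_reg(6:15), sp3 = mk_reg(1:3))
  res <- ortholog_overlap_tests(regs, om, genes, B = 200, seed = 7)
  pw <- res$pairwise[res$pairwise$species_a == "sp1" &
                       res$pairwise$species_b == "sp2", ]
  expect_equal(pw$overlap, 5)
  expect_equal(pw$p, oracle, tolerance = 1e-12)
  # certain event: overlap 0 with K = n = 1 has p = 1
  regs2 <- list(sp1 = mk_reg(1), sp2 = mk_reg(2), sp3 = mk_reg(3))
  res2 <- ortholog_overlap_tests(regs2, om, genes, B = 10, seed = 7)
  expect_true(all(res2$pairwise$p == 1))
})

test_that("permutation results are seeded, bounded and reproducible", {
  om <- data.frame(sp1 = sprintf("a%d", 1:50), sp2 = sprintf("b%d", 1:50),
                   sp3 = sprintf("c%d", 1:50), stringsAsFactors = FALSE)
  genes <- lapply(c("a", "b", "c"), function(pre) {
    data.frame(chrom = "chr1", start = (0:49) * 100, end = (0:49) * 100 + 50,
               kind = "gene", gene_id = sprintf("%s%d", pre, 1:50),
               stringsAsFactors = FALSE)
  })
  names(genes) <- c("sp1", "sp2", "sp3")
  mk_reg <- function(idx) {
    data.frame(chrom = "chr1", start = (idx - 1) * 100,
               end = (idx - 1) * 100 + 50, stringsAsFactors = FALSE)
  }
  regs <- list(sp1 = mk_reg(1:20), sp2 = mk_reg(1:20), sp3 = mk_reg(1:20))
  r1 <- ortholog_overlap_tests(regs, om, genes, B = 300, seed = 9)
  r2 <- ortholog_overlap_tests(regs, om, genes, B = 300, seed = 9)
  expect_identical(r1$multiway, r2$multiway)
  expect_true(all(r1$multiway$p_perm >= 1 / 301))
  expect_true(all(r1$multiway$p_perm <= 1))
  expect_error(ortholog_overlap_tests(regs, om, genes, B = 0), "at least 1")
})
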