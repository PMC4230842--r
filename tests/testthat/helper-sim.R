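# Shared fixtures, built in code.

# Well-separated generating truth used across recovery tests.
truth_params <- function(mean_u = 0.05, mean_m = 0.85, precision = 8,
                         stay = 0.97) {
  default_hmm_params(mean_u, mean_m, precision, stay)
}

# A small single-sample methylome with known truth.
small_methylome <- function(len = 20000, seed = 2, mean_cov = 20,
                            fmr = 0.005) {
  g <- simulate_genome(1, len, seed = seed)
  des <- list(sample_key("sp1", "root", "control23", 1))
  sim <- simulate_methylome(g$catalogue, truth_params(), mean_cov = mean_cov,
                            fmr = fmr, design = des, seed = seed + 1)
  list(genome = g, table = sim$tables[[1]], truth = sim$truth)
}

# Hand-built cytosine records.
make_records <- function(pos, n_total, n_meth, context = "CG",
                         chrom = "chr1", strand = "+") {
  data.frame(chrom = chrom, pos = pos, strand = strand, context = context,
             n_total = n_total, n_meth = n_meth, stringsAsFactors = FALSE)
}

make_table <- function(records, key = sample_key("sp1", "root", "control23"),
                       spikein = NULL) {
  sample_table(key, records, spikein)
}

# A tiny GFF3 written to a temp file: one 2-exon gene, one exonless gene,
# one TE.
write_test_gff <- function(path = tempfile(fileext = ".gff3"),
                           exonless = FALSE) {
  lines <- c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1500\t2400\t.\t+\t.\tID=g1",
    "chr1\ttest\texon\t1500\t1700\t.\t+\t.\tID=g1.e1;Parent=g1",
    "chr1\ttest\texon\t2000\t2400\t.\t+\t.\tID=g1.e2;Parent=g1",
    "chr1\ttest\ttransposable_element\t3000\t3500\t.\t+\t.\tID=te1")
  if (exonless) {
    lines <- c(lines, "chr1\ttest\tgene\t5000\t5600\t.\t-\t.\tID=g2")
  }
  writeLines(lines, path)
  path
}

# Independent brute-force Viterbi: enumerate all 2^n paths.
brute_force_viterbi <- function(seg, params) {
  n <- nrow(seg)
  ll <- cometh:::emission_loglik(seg, params)
  lt <- log(params$trans); ls <- log(params$start)
  best <- -Inf; best_path <- NULL
  grid <- as.matrix(expand.grid(rep(list(1:2), n)))
  for (r in seq_len(nrow(grid))) {
    path <- grid[r, ]
    lp <- ls[path[1]] + ll[1, path[1]]
    if (n > 1) for (t in 2:n) {
      lp <- lp + lt[path[t - 1], path[t]] + ll[t, path[t]]
    }
    if (lp > best + 1e-12) { best <- lp; best_path <- path }
  }
  list(path = unname(best_path), logprob = best)
}

# Independent two-sided Fisher p by direct enumeration with lchoose.
enum_fisher_p <- function(x11, x12, x21, x22) {
  m <- x11 + x21; n <- x12 + x22; k <- x11 + x12
  lo <- max(0, k - n); hi <- min(k, m)
  supp <- lo:hi
  lp <- lchoose(m, supp) + lchoose(n, k - supp) - lchoose(m + n, k)
  pr <- exp(lp)
  obs <- pr[supp == x11]
  sum(pr[pr <= obs * (1 + 1e-7)])
}
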