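#' Simulate a genome and its cytosine context catalogue
#'
#' Draws i.i.d. nucleotide sequences at a given GC content and catalogues
#' every cytosine on both strands with its trinucleotide context: a C
#' followed by G is CG, by H then G is CHG, otherwise CHH (H = A, C or T).
#' Minus-strand cytosines are genomic Gs read on the reverse complement.
#' Cytosines closer than two bases to the chromosome end have an undefined
#' context and are omitted.
#'
#' @param n_chrom number of chromosomes.
#' @param lengths chromosome lengths in bp (recycled), each >= 1000.
#' @param gc GC fraction.
#' @param seed integer seed; the catalogue is deterministic given it.
#' @return list with `seqs` (character vector of chromosome sequences) and
#'   `catalogue` (data.frame chrom, pos (1-based), strand, context, sorted).
#' @export
simulate_genome <- function(n_chrom = 1L, lengths = 100000L, gc = 0.36,
                            seed = 1L) {
  stopifnot(all(lengths >= 1000), gc > 0, gc < 1)
  lengths <- rep_len(lengths, n_chrom)
  set.seed(seed)
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(lengths, function(L) {
    paste(sample(names(prob), L, replace = TRUE, prob = prob), collapse = "")
  }, character(1))
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  cat_list <- lapply(seq_len(n_chrom), function(i) {
    context_catalogue(seqs[[i]], names(seqs)[i])
  })
  catalogue <- do.call(rbind, cat_list)
  rownames(catalogue) <- NULL
  list(seqs = seqs, catalogue = catalogue)
}

# Context of every cytosine in one chromosome sequence (both strands).
context_catalogue <- function(seq, chrom) {
  b <- strsplit(seq, "")[[1]]
  L <- length(b)
  out <- list()
  # + strand: C at i, context from b[i+1], b[i+2]
  ip <- which(b == "C")
  ip <- ip[ip <= L - 2]
  if (length(ip)) {
    ctx <- ifelse(b[ip + 1] == "G", "CG",
                  ifelse(b[ip + 2] == "G", "CHG", "CHH"))
    out$p <- data.frame(chrom = chrom, pos = ip, strand = "+", context = ctx,
                        stringsAsFactors = FALSE)
  }
  # - strand: G at i is a C on the reverse complement; next bases are the
  # complements of b[i-1], b[i-2]
  im <- which(b == "G")
  im <- im[im >= 3]
  if (length(im)) {
    ctx <- ifelse(b[im - 1] == "C", "CG",
                  ifelse(b[im - 2] == "C", "CHG", "CHH"))
    out$m <- data.frame(chrom = chrom, pos = im, strand = "-", context = ctx,
                        stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df[order(df$pos, df$strand), , drop = FALSE]
}

#' Simulate bisulfite count tables under a two-state segment structure
#'
#' Draws a hidden unmethylated/methylated state path along consecutive
#' cytosines from the Markov chain in `params` (restarting on each
#' chromosome), a per-site methylation level from the state- and
#' context-specific beta distribution, then per sample a Poisson coverage
#' and binomial methylated-read count. Conversion failure acts as additive
#' false methylation on the unmethylated fraction of molecules: the
#' observed rate is `level + (1 - level) * fmr`. Spike-in cytosines
#' (1/1000 of the genome catalogue, floor 50) have level 0 so their
#' apparent methylation estimates `fmr`. Replicates share the hidden truth
#' and differ only in count noise. `dmr_spec` injects tissue-specific
#' differentially methylated regions: inside each region the designated
#' tissue draws its level from the methylated-state beta and the other
#' tissue from the unmethylated-state beta.
#'
#' @param catalogue cytosine catalogue from [simulate_genome()].
#' @param params an [hmm_params()] object used as generating truth.
#' @param mean_cov mean Poisson read coverage per cytosine.
#' @param fmr conversion-failure probability.
#' @param design list of [sample_key()]s to emit.
#' @param dmr_spec optional data.frame(chrom, start, end, tissue) of
#'   injected tissue DMRs (0-based half-open).
#' @param chrom_lengths named chromosome lengths, required to validate
#'   `dmr_spec` bounds.
#' @param seed integer seed.
#' @return list with `tables` (named list of [sample_table()]) and `truth`
#'   (state path, per-combination levels, params, fmr, injected DMRs).
#' @export
simulate_methylome <- function(catalogue, params, mean_cov = 20, fmr = 0.005,
                               design, dmr_spec = NULL, chrom_lengths = NULL,
                               seed = 1L) {
  stopifnot(inherits(params, "hmm_params"))
  set.seed(seed)
  n <- nrow(catalogue)
  # hidden state path per chromosome: 1 = U, 2 = M
  state <- integer(n)
  for (ch in unique(catalogue$chrom)) {
    idx <- which(catalogue$chrom == ch)
    s <- integer(length(idx))
    s[1] <- sample(1:2, 1, prob = params$start)
    for (i in seq_along(idx)[-1]) {
      s[i] <- sample(1:2, 1, prob = params$trans[s[i - 1], ])
    }
    state[idx] <- s
  }
  ctx_i <- match(catalogue$context, c("CG", "CHG", "CHH"))
  draw_levels <- function(st) {
    a <- params$emis[cbind(st, ctx_i, 1L)]
    b <- params$emis[cbind(st, ctx_i, 2L)]
    stats::rbeta(n, a, b)
  }
  base_level <- draw_levels(state)
  # per-combination level maps (tissue effects only; treatment never alters
  # the truth, matching a design with no injected treatment DMRs)
  levels_by_tissue <- list(root = base_level, shoot = base_level)
  if (!is.null(dmr_spec) && nrow(dmr_spec)) {
    if (!is.null(chrom_lengths)) {
      bad <- dmr_spec$start < 0 |
        dmr_spec$end > chrom_lengths[dmr_spec$chrom]
      if (any(bad)) stop("dmr_spec region outside chromosome bounds")
    }
    lev_m <- draw_levels(rep(2L, n))
    lev_u <- draw_levels(rep(1L, n))
    for (r in seq_len(nrow(dmr_spec))) {
      inside <- catalogue$chrom == dmr_spec$chrom[r] &
        catalogue$pos > dmr_spec$start[r] & catalogue$pos <= dmr_spec$end[r]
      tt <- dmr_spec$tissue[r]
      other <- setdiff(c("root", "shoot"), tt)
      levels_by_tissue[[tt]][inside] <- lev_m[inside]
      levels_by_tissue[[other]][inside] <- lev_u[inside]
    }
  }
  n_spike <- max(50L, round(n / 1000))
  tables <- list()
  for (key in design) {
    lev <- levels_by_tissue[[key$tissue]]
    p_obs <- lev + (1 - lev) * fmr
    n_total <- stats::rpois(n, mean_cov)
    n_meth <- stats::rbinom(n, n_total, p_obs)
    rec <- data.frame(chrom = catalogue$chrom, pos = catalogue$pos,
                      strand = catalogue$strand, context = catalogue$context,
                      n_total = n_total, n_meth = n_meth,
                      stringsAsFactors = FALSE)
    sp_total <- stats::rpois(n_spike, mean_cov)
    spike <- data.frame(chrom = "lambda", pos = seq_len(n_spike),
                        strand = "+", context = "CHH",
                        n_total = sp_total,
                        n_meth = stats::rbinom(n_spike, sp_total, fmr),
                        stringsAsFactors = FALSE)
    tables[[format(key)]] <- sample_table(key, rec, spike)
  }
  truth <- list(state_path = state, true_params = params,
                levels_by_tissue = levels_by_tissue,
                injected_dmrs = dmr_spec, fmr_true = fmr,
                catalogue = catalogue)
  list(tables = tables, truth = truth)
}

#' Simulate a three-way aligned-cytosine map with context divergence
#'
#' Starts from one species' cytosine catalogue as the ancestral state,
#' marks a subset of sites as 1:1:1 aligned, and independently mutates the
#' H positions of degenerate contexts (CHG, CHH) in species 2 and 3 with
#' probability `divergence`; a mutation hits G with probability 1/3, which
#' changes the context label and must later be excluded by context
#' matching. Methylation statuses are assigned per conservation class with
#' the stated mixing proportions, and the generator's own class tally is
#' returned as the oracle for classification tests.
#'
#' @param catalogue ancestral cytosine catalogue.
#' @param n_sites number of aligned sites to emit (capped at catalogue size).
#' @param divergence per-species H-position substitution probability in
#'   `[0, 0.5)`.
#' @param class_probs named probabilities for conserved3, gain, loss,
#'   unmethylated (gain/loss species drawn uniformly).
#' @param p_untestable probability a species' status is untestable.
#' @param seed integer seed.
#' @return list: `map` (per-species chrom/pos/strand/context + statuses),
#'   `tally` (generator bookkeeping of emitted classes among kept,
#'   fully-testable sites), `n_h_to_g` (sites excluded by an H->G hit).
#' @export
simulate_alignment_map <- function(catalogue, n_sites = 2000,
                                   divergence = 0.05,
                                   class_probs = c(conserved3 = 0.15,
                                                   gain = 0.2, loss = 0.15,
                                                   unmethylated = 0.5),
                                   p_untestable = 0.02, seed = 1L) {
  stopifnot(divergence >= 0, divergence < 0.5)
  set.seed(seed)
  n_sites <- min(n_sites, nrow(catalogue))
  anc <- catalogue[sort(sample.int(nrow(catalogue), n_sites)), , drop = FALSE]
  mutate_ctx <- function(ctx) {
    # one H position of a degenerate context mutates; G with prob 1/3
    hit <- ctx != "CG" & stats::runif(length(ctx)) < divergence
    to_g <- hit & stats::runif(length(ctx)) < 1 / 3
    new <- ctx
    # H->G: CHH mutated at its last H becomes CHG; CHG's H to G gives a CG
    # dyad at the next position, i.e. the site reads as CG context
    new[to_g & ctx == "CHH"] <- "CHG"
    new[to_g & ctx == "CHG"] <- "CG"
    list(ctx = new, h_changed = hit & !to_g, h_to_g = to_g)
  }
  m2 <- mutate_ctx(anc$context)
  m3 <- mutate_ctx(anc$context)
  map <- data.frame(
    chrom_1 = anc$chrom, pos_1 = anc$pos, strand_1 = anc$strand,
    context_1 = anc$context,
    chrom_2 = paste0("sp2_", anc$chrom), pos_2 = anc$pos,
    strand_2 = anc$strand, context_2 = m2$ctx,
    chrom_3 = paste0("sp3_", anc$chrom), pos_3 = anc$pos,
    strand_3 = anc$strand, context_3 = m3$ctx,
    stringsAsFactors = FALSE)
  # assign statuses by class
  cls <- sample(names(class_probs), n_sites, replace = TRUE,
                prob = class_probs)
  status <- matrix("unmethylated", n_sites, 3)
  which_sp <- sample.int(3, n_sites, replace = TRUE)
  status[cls == "conserved3", ] <- "methylated"
  g <- cls == "gain"
  status[cbind(which(g), which_sp[g])] <- "methylated"
  l <- cls == "loss"
  status[l, ] <- "methylated"
  status[cbind(which(l), which_sp[l])] <- "unmethylated"
  untest <- matrix(stats::runif(3 * n_sites) < p_untestable, n_sites, 3)
  status[untest] <- "untestable"
  map$status_1 <- status[, 1]; map$status_2 <- status[, 2]
  map$status_3 <- status[, 3]
  kept <- map$context_1 == map$context_2 & map$context_1 == map$context_3
  testable <- rowSums(untest) == 0
  lab <- character(n_sites)
  lab[cls == "conserved3"] <- "conserved3"
  lab[g] <- paste0("gain_sp", which_sp[g])
  lab[l] <- paste0("loss_sp", which_sp[l])
  lab[cls == "unmethylated"] <- "unmethylated"
  tally <- table(lab[kept & testable])
  map$true_class <- lab
  list(map = map, tally = tally,
       kept = kept, testable = testable,
       n_h_to_g = sum((m2$h_to_g | m3$h_to_g)))
}

#' Simulate RNA-seq counts under a factorial negative-binomial GLM
#'
#' Counts are NB with mean `lib_size * exp(X beta)` under the model matrix
#' of `~ tissue * treatment` (one species) or `~ species * tissue *
#' treatment`. `coef_spec` lists genes with non-null effects.
#'
#' @param n_genes number of genes.
#' @param design data.frame of sample factors (tissue, treatment, optional
#'   species), one row per sample.
#' @param coef_spec optional data.frame(gene, term, value) of non-zero
#'   coefficients (natural-log scale); remaining coefficients are 0 except
#'   the intercept.
#' @param base_log_mean intercept (natural-log mean count at lib size 1e6
#'   reference; genes vary around it).
#' @param dispersions per-gene NB dispersion (recycled).
#' @param lib_sizes per-sample library sizes (recycled).
#' @param seed integer seed.
#' @return list: `counts` (genes x samples), `design`, `truth` (coefficient
#'   matrix, dispersions, library sizes, and the DE gene index per term).
#' @export
simulate_expression <- function(n_genes = 1000, design, coef_spec = NULL,
                                base_log_mean = log(100), dispersions = 0.1,
                                lib_sizes = 1e6, seed = 1L) {
  stopifnot(all(dispersions > 0))
  set.seed(seed)
  for (j in seq_along(design)) design[[j]] <- factor(design[[j]])
  form <- if ("species" %in% names(design)) {
    ~ species * tissue * treatment
  } else ~ tissue * treatment
  X <- stats::model.matrix(form, design)
  n_s <- nrow(X)
  dispersions <- rep_len(dispersions, n_genes)
  lib_sizes <- rep_len(lib_sizes, n_s)
  beta <- matrix(0, n_genes, ncol(X), dimnames = list(NULL, colnames(X)))
  beta[, 1] <- base_log_mean + stats::rnorm(n_genes, 0, 0.5)
  if (!is.null(coef_spec) && nrow(coef_spec)) {
    for (r in seq_len(nrow(coef_spec))) {
      term <- coef_spec$term[r]
      cols <- which(attr(X, "assign") ==
                      match(term, attr(stats::terms(form), "term.labels")))
      if (length(cols) == 0) stop("unknown term in coef_spec: ", term)
      beta[coef_spec$gene[r], cols] <- coef_spec$value[r]
    }
  }
  log_mu <- beta %*% t(X) + matrix(log(lib_sizes / 1e6), n_genes, n_s,
                                   byrow = TRUE)
  mu <- exp(log_mu)
  counts <- matrix(stats::rnbinom(n_genes * n_s, mu = mu,
                                  size = rep(1 / dispersions, n_s)),
                   n_genes, n_s)
  rownames(counts) <- sprintf("g%05d", seq_len(n_genes))
  colnames(counts) <- sprintf("s%02d", seq_len(n_s))
  list(counts = counts, design = design,
       truth = list(beta = beta, dispersions = dispersions,
                    lib_sizes = lib_sizes, coef_spec = coef_spec))
}
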