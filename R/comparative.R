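#' Context-matching rule for three-way aligned cytosines
#'
#' A site enters the cross-species comparison only if its sequence context
#' agrees in all three species. CG sites must be CG everywhere; degenerate
#' contexts (CHG, CHH) tolerate substitutions at the H positions - which
#' leave the context label unchanged - but an H that mutates to G changes
#' the label (CHH becomes CHG, CHG becomes CG), so any context transition
#' excludes the site.
#'
#' @param map aligned-site data.frame with `context_1..3` columns.
#' @return logical vector, TRUE for sites to keep.
#' @export
match_context <- function(map) {
  map$context_1 == map$context_2 & map$context_1 == map$context_3
}

#' Classify aligned cytosines into conservation classes
#'
#' Using per-species methylation statuses (methylated / unmethylated /
#' untestable), each context-matched site that is testable in all three
#' species is classified: methylated in all three = `conserved3`;
#' methylated in exactly one = `gain_spK` (a lineage-specific gain in
#' species K); methylated in exactly two = `loss_spK` (a lineage-specific
#' loss in the unmethylated species K); methylated in none =
#' `unmethylated`. Sites failing context matching are `excluded`; sites
#' untestable in any species are tallied separately as `untestable`.
#'
#' @param map aligned-site data.frame with `context_1..3` and
#'   `status_1..3` columns.
#' @return the map with a `class` column plus attribute `tally` (table of
#'   classes among kept, fully-testable sites).
#' @export
classify_sites <- function(map) {
  kept <- match_context(map)
  st <- cbind(map$status_1, map$status_2, map$status_3)
  testable <- rowSums(st == "untestable") == 0
  n_meth <- rowSums(st == "methylated")
  cls <- rep(NA_character_, nrow(map))
  cls[!kept] <- "excluded"
  cls[kept & !testable] <- "untestable"
  use <- kept & testable
  cls[use & n_meth == 3] <- "conserved3"
  cls[use & n_meth == 0] <- "unmethylated"
  one <- use & n_meth == 1
  cls[one] <- paste0("gain_sp", max.col(st[one, , drop = FALSE] ==
                                          "methylated"))
  two <- use & n_meth == 2
  cls[two] <- paste0("loss_sp", max.col(st[two, , drop = FALSE] ==
                                          "unmethylated"))
  map$class <- cls
  attr(map, "tally") <- table(cls[use])
  map
}

#' Windowed gain density along a genome
#'
#' Per non-overlapping window, the fraction of lineage-specific
#' methylation changes that are gains: gains / (gains + losses). Windows
#' without any gain or loss are omitted (the statistic is undefined
#' there).
#'
#' @param classified a classified aligned-site map ([classify_sites()]);
#'   coordinates of species 1 are used.
#' @param window window size in bp (default 10000).
#' @param species which species' gains/losses to count (1, 2 or 3); by
#'   default all species-specific gains and losses are pooled.
#' @return data.frame chrom, win_start, win_end, gains, losses, density.
#' @export
gain_density <- function(classified, window = 10000L, species = NULL) {
  gain_lab <- if (is.null(species)) paste0("gain_sp", 1:3) else
    paste0("gain_sp", species)
  loss_lab <- if (is.null(species)) paste0("loss_sp", 1:3) else
    paste0("loss_sp", species)
  df <- data.frame(chrom = classified$chrom_1,
                   win = (classified$pos_1 - 1L) %/% window,
                   gain = classified$class %in% gain_lab,
                   loss = classified$class %in% loss_lab)
  agg <- stats::aggregate(cbind(gains = gain, losses = loss) ~ chrom + win,
                          df, sum)
  agg <- agg[agg$gains + agg$losses > 0, , drop = FALSE]
  out <- data.frame(chrom = agg$chrom, win_start = agg$win * window,
                    win_end = (agg$win + 1L) * window,
                    gains = agg$gains, losses = agg$losses,
                    density = agg$gains / (agg$gains + agg$losses),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$win_start), , drop = FALSE]
}

#' Gene body methylation fraction
#'
#' Fraction of methylated CG sites among testable CG sites within the gene
#' span (start to stop codon). Returns NA when the span holds no testable
#' CG site.
#'
#' @param gene one feature row (0-based half-open `start`/`end`, `chrom`).
#' @param calls site-call frame from [call_methylated_sites()].
#' @return numeric fraction or NA.
#' @export
gene_body_methylation <- function(gene, calls) {
  s <- calls$chrom == gene$chrom & calls$pos > gene$start &
    calls$pos <= gene$end & calls$context == "CG" & calls$tested
  if (!any(s)) return(NA_real_)
  sum(calls$is_methylated[s]) / sum(s)
}

#' Average methylation rate over a feature set
#'
#' Mean of per-site methylation rates over all testable sites of one
#' context falling in the features - unmethylated sites included with
#' their (low) rates, so sparsely methylated features score low. With
#' `norm_rate` the mean is divided by a reference (e.g. the outgroup
#' species' rate for the same feature class).
#'
#' @param features feature data.frame (0-based half-open intervals).
#' @param calls site-call frame.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param norm_rate optional normalising rate.
#' @return numeric rate (or NA for an empty feature set).
#' @export
feature_methylation_rate <- function(features, calls, context = "CG",
                                     norm_rate = NULL) {
  if (nrow(features) == 0) return(NA_real_)
  gr_f <- GenomicRanges::GRanges(features$chrom,
                                 IRanges::IRanges(features$start + 1L,
                                                  features$end))
  use <- calls$context == context & calls$tested
  if (!any(use)) return(NA_real_)
  cc <- calls[use, , drop = FALSE]
  gr_s <- GenomicRanges::GRanges(cc$chrom, IRanges::IRanges(cc$pos, cc$pos))
  hit <- unique(S4Vectors::queryHits(
    GenomicRanges::findOverlaps(gr_s, gr_f)))
  if (length(hit) == 0) return(NA_real_)
  r <- mean(cc$rate[hit])
  if (!is.null(norm_rate)) r <- r / norm_rate
  r
}

#' Annotate sites or regions with one genomic feature label
#'
#' Every item gets exactly one label by the fixed precedence
#' TE > exon > intron > five_prime_UTR > three_prime_UTR > upstream1kb >
#' intergenic, so e.g. a transposon inserted in an intron counts as TE.
#' The precedence is configurable.
#'
#' @param items data.frame with either `pos` (1-based sites) or
#'   `start`/`end` (0-based half-open regions) plus `chrom`.
#' @param features feature data.frame from [read_gff()].
#' @param precedence character vector of kinds, highest first.
#' @return character vector of labels, one per item.
#' @export
annotate_sites <- function(items, features,
                           precedence = c("TE", "exon", "intron",
                                          "five_prime_UTR",
                                          "three_prime_UTR",
                                          "upstream1kb")) {
  if (nrow(items) == 0) return(character(0))
  gr_i <- if ("pos" %in% names(items)) {
    GenomicRanges::GRanges(items$chrom,
                           IRanges::IRanges(items$pos, items$pos))
  } else {
    GenomicRanges::GRanges(items$chrom,
                           IRanges::IRanges(items$start + 1L, items$end))
  }
  lab <- rep("intergenic", nrow(items))
  for (kind in rev(precedence)) {
    f <- features[features$kind == kind, , drop = FALSE]
    if (nrow(f) == 0) next
    gr_f <- GenomicRanges::GRanges(f$chrom,
                                   IRanges::IRanges(f$start + 1L, f$end))
    hit <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(gr_i, gr_f)))
    lab[hit] <- kind
  }
  lab
}

#' Methylated-region sharing at orthologous genes
#'
#' Maps each species' regions to its genes, restricts to the 1:1:1
#' ortholog universe, and tests co-occurrence: pairwise with the
#' hypergeometric upper tail (does the overlap of the two species'
#' region-bearing ortholog sets exceed chance given the universe size),
#' and two/three-way against a permutation null in which each species'
#' region-presence labels are shuffled across the orthologs `B` times
#' (maximum sharing count across permutations reported; an observed count
#' above the permutation maximum "exceeds permutation values").
#'
#' @param regions_by_species named list (one per species) of region frames.
#' @param orthologs ortholog map (one gene-id column per species, same
#'   order as `regions_by_species`).
#' @param genes_by_species named list of gene feature frames (kind
#'   "gene") used to map regions to gene ids.
#' @param B number of permutations (default 10000).
#' @param seed integer seed for the permutations.
#' @return list: `n_orthologs`, `presence` (logical matrix orthologs x
#'   species), `pairwise` (data.frame with observed overlap and
#'   hypergeometric p per species pair), `multiway` (observed 2/3-way
#'   sharing counts, permutation maxima and empirical p).
#' @export
ortholog_overlap_tests <- function(regions_by_species, orthologs,
                                   genes_by_species, B = 10000L, seed = 1L) {
  if (B < 1) stop("B must be at least 1")
  sp <- names(regions_by_species)
  stopifnot(length(sp) == 3, ncol(orthologs) >= 3)
  N <- nrow(orthologs)
  presence <- matrix(FALSE, N, 3, dimnames = list(NULL, sp))
  for (i in 1:3) {
    g <- genes_by_species[[sp[i]]]
    g <- g[g$kind == "gene", , drop = FALSE]
    reg <- regions_by_species[[sp[i]]]
    hit_genes <- character(0)
    if (nrow(reg) && nrow(g)) {
      gr_g <- GenomicRanges::GRanges(g$chrom,
                                     IRanges::IRanges(g$start + 1L, g$end))
      gr_r <- GenomicRanges::GRanges(reg$chrom,
                                     IRanges::IRanges(reg$start + 1L,
                                                      reg$end))
      hit <- GenomicRanges::findOverlaps(gr_g, gr_r)
      hit_genes <- unique(g$gene_id[S4Vectors::queryHits(hit)])
    }
    presence[, i] <- orthologs[[i]] %in% hit_genes
  }
  pairs <- utils::combn(3, 2)
  pairwise <- data.frame(species_a = sp[pairs[1, ]],
                         species_b = sp[pairs[2, ]],
                         k_a = colSums(presence)[pairs[1, ]],
                         k_b = colSums(presence)[pairs[2, ]],
                         overlap = NA_integer_, p = NA_real_,
                         stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    a <- presence[, pairs[1, j]]; b <- presence[, pairs[2, j]]
    k <- sum(a & b)
    pairwise$overlap[j] <- k
    # upper-tail hypergeometric: P(overlap >= k)
    pairwise$p[j] <- stats::phyper(k - 1, sum(a), N - sum(a), sum(b),
                                   lower.tail = FALSE)
  }
  obs2 <- sum(rowSums(presence) >= 2)
  obs3 <- sum(rowSums(presence) == 3)
  set.seed(seed)
  perm2 <- integer(B); perm3 <- integer(B)
  for (b in seq_len(B)) {
    pm <- apply(presence, 2, sample)
    rs <- rowSums(pm)
    perm2[b] <- sum(rs >= 2)
    perm3[b] <- sum(rs == 3)
  }
  multiway <- data.frame(
    sharing = c("two_way", "three_way"),
    observed = c(obs2, obs3),
    perm_max = c(max(perm2), max(perm3)),
    perm_mean = c(mean(perm2), mean(perm3)),
    p_perm = c((1 + sum(perm2 >= obs2)) / (B + 1),
               (1 + sum(perm3 >= obs3)) / (B + 1)),
    exceeds_perm = c(obs2 > max(perm2), obs3 > max(perm3)),
    stringsAsFactors = FALSE)
  list(n_orthologs = N, presence = presence, pairwise = pairwise,
       multiway = multiway)
}
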