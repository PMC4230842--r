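#' Sample identity in the factorial design
#'
#' The study design crosses species x tissue (root/shoot) x treatment
#' (control at 23C / 23-hour cold at 4C) x replicate. A `sample_key`
#' identifies one library.
#'
#' @param species species identifier.
#' @param tissue `"root"` or `"shoot"`.
#' @param treatment `"control23"` or `"cold4"`.
#' @param replicate positive integer (0 is reserved for merged replicates).
#' @return object of class `sample_key`.
#' @export
sample_key <- function(species, tissue, treatment, replicate = 1L) {
  tissue <- match.arg(tissue, c("root", "shoot"))
  treatment <- match.arg(treatment, c("control23", "cold4"))
  stopifnot(length(species) == 1, nchar(species) > 0,
            length(replicate) == 1, replicate >= 0)
  structure(list(species = species, tissue = tissue, treatment = treatment,
                 replicate = as.integer(replicate)),
            class = "sample_key")
}

#' @export
format.sample_key <- function(x, ...) {
  sprintf("%s/%s/%s/rep%d", x$species, x$tissue, x$treatment, x$replicate)
}

#' @export
print.sample_key <- function(x, ...) {
  cat("<sample_key>", format(x), "\n"); invisible(x)
}

# the four tissue-treatment combinations of the design
combo_label <- function(key) paste(key$tissue, key$treatment, sep = ".")

#' All four tissue-treatment combinations for a species
#' @param species species identifier.
#' @param replicate replicate index applied to each key.
#' @return list of four `sample_key` objects (root/shoot x control23/cold4).
#' @export
design_combinations <- function(species, replicate = 0L) {
  out <- list()
  for (ti in c("root", "shoot")) for (tr in c("control23", "cold4")) {
    out[[paste(ti, tr, sep = ".")]] <- sample_key(species, ti, tr, replicate)
  }
  out
}

validate_records <- function(records, what = "records") {
  need <- c("chrom", "pos", "strand", "context", "n_total", "n_meth")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop(what, " missing columns: ", paste(miss, collapse = ", "))
  }
  bad <- which(records$n_meth > records$n_total | records$n_meth < 0 |
                 records$n_total < 0)
  if (length(bad)) {
    stop(what, ": n_meth > n_total (or negative counts) at row ", bad[1])
  }
  if (!all(records$context %in% c("CG", "CHG", "CHH"))) {
    stop(what, ": context must be one of CG, CHG, CHH")
  }
  if (!all(records$strand %in% c("+", "-"))) {
    stop(what, ": strand must be '+' or '-'")
  }
  invisible(records)
}

sort_records <- function(records) {
  records[order(records$chrom, records$pos, records$strand), , drop = FALSE]
}

#' Per-sample container of cytosine counts
#'
#' Bundles a sample's per-cytosine bisulfite counts with its identity and
#' its unmethylated spike-in ("lambda") counts. Records are kept sorted by
#' (chrom, pos, strand) with 1-based positions; duplicates are rejected.
#'
#' @param key a [sample_key()].
#' @param records data.frame with columns chrom, pos, strand, context,
#'   n_total, n_meth.
#' @param spikein data.frame with the same columns, on the reserved
#'   spike-in chromosome (`"lambda"`).
#' @return object of class `sample_table`.
#' @export
sample_table <- function(key, records, spikein = NULL) {
  stopifnot(inherits(key, "sample_key"))
  records <- as.data.frame(records)
  validate_records(records)
  o <- order(records$chrom, records$pos, records$strand)
  if (is.unsorted(o)) records <- records[o, , drop = FALSE]
  rownames(records) <- NULL
  dup <- duplicated(records[c("chrom", "pos", "strand")])
  if (any(dup)) stop("duplicate (chrom, pos, strand) in records")
  if (any(records$chrom == "lambda")) {
    stop("chromosome name 'lambda' is reserved for spike-in records")
  }
  if (!is.null(spikein)) {
    spikein <- as.data.frame(spikein)
    validate_records(spikein, "spikein")
  }
  structure(list(key = key, records = records, spikein = spikein),
            class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  cat("<sample_table>", format(x$key), "-", nrow(x$records), "cytosines",
      if (!is.null(x$spikein)) sprintf("(+%d spike-in)", nrow(x$spikein))
      else "", "\n")
  invisible(x)
}

#' Read a per-cytosine count table
#'
#' Reads a TSV with columns chrom, pos (1-based), strand, context, n_total,
#' n_meth. Rows on the reserved chromosome `"lambda"` are routed to the
#' spike-in slot. Unsorted input is sorted with a warning; rows violating
#' `n_meth <= n_total` raise an error naming the first offending line.
#'
#' @param path file path.
#' @param key [sample_key()] for the sample.
#' @return a [sample_table()].
#' @export
read_cytosine_table <- function(path, key) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer", "character",
                                         "character", "integer", "integer"),
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "strand", "context", "n_total", "n_meth")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("malformed table ", path, ": missing ",
                         paste(miss, collapse = ", "))
  bad <- which(df$n_meth > df$n_total)
  if (length(bad)) {
    stop("malformed row at line ", bad[1] + 1L, " of ", path,
         ": n_meth > n_total")
  }
  is_spike <- df$chrom == "lambda"
  rec <- df[!is_spike, , drop = FALSE]
  o <- order(rec$chrom, rec$pos, rec$strand)
  if (!identical(o, seq_len(nrow(rec)))) {
    warning("input not sorted by (chrom, pos, strand); sorting on load")
    rec <- rec[o, , drop = FALSE]
  }
  spike <- if (any(is_spike)) df[is_spike, , drop = FALSE] else NULL
  sample_table(key, rec, spike)
}

#' Write a per-cytosine count table
#'
#' Inverse of [read_cytosine_table()]: spike-in rows are appended on the
#' reserved `"lambda"` chromosome.
#'
#' @param table a [sample_table()].
#' @param path output file path.
#' @export
write_cytosine_table <- function(table, path) {
  stopifnot(inherits(table, "sample_table"))
  df <- table$records
  if (!is.null(table$spikein)) df <- rbind(df, table$spikein)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GFF3 annotation into a feature table
#'
#' Imports genes, exons, UTRs and transposable elements from GFF3 and
#' derives two feature kinds the annotation does not carry explicitly:
#' introns (gaps between a gene's exons) and the 1 kb upstream of the start
#' codon on the coding strand. All output intervals are 0-based half-open.
#'
#' @param path GFF3 file.
#' @param upstream_bp width of the derived upstream feature (default 1000).
#' @return data.frame with columns chrom, start, end, strand, kind, gene_id;
#'   kind is one of gene, exon, intron, five_prime_UTR, three_prime_UTR, TE,
#'   upstream1kb.
#' @export
read_gff <- function(path, upstream_bp = 1000L) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    kind = as.character(gr$type),
    stringsAsFactors = FALSE
  )
  df$id <- if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_
  par <- gr$Parent
  df$parent <- if (!is.null(par)) {
    vapply(as.list(par), function(p) if (length(p)) as.character(p[1])
           else NA_character_, character(1))
  } else NA_character_
  kind_map <- c(gene = "gene", exon = "exon",
                five_prime_UTR = "five_prime_UTR",
                three_prime_UTR = "three_prime_UTR",
                transposable_element = "TE", repeat_region = "TE",
                TE = "TE")
  df <- df[df$kind %in% names(kind_map), , drop = FALSE]
  df$kind <- unname(kind_map[df$kind])
  genes <- df[df$kind == "gene", , drop = FALSE]
  # resolve each child feature to its gene (possibly via an mRNA parent,
  # which our synthetic GFFs do not emit; direct parents suffice)
  gene_of <- stats::setNames(genes$id, genes$id)
  df$gene_id <- ifelse(df$kind == "gene", df$id,
                       ifelse(df$parent %in% names(gene_of),
                              gene_of[df$parent], NA_character_))
  # child containment check
  kids <- df[df$kind %in% c("exon", "five_prime_UTR", "three_prime_UTR") &
               !is.na(df$gene_id), , drop = FALSE]
  if (nrow(kids)) {
    gi <- match(kids$gene_id, genes$id)
    bad <- which(is.na(gi) | kids$start < genes$start[gi] |
                   kids$end > genes$end[gi])
    if (length(bad)) {
      stop("feature ", kids$id[bad[1]], " outside bounds of its parent gene")
    }
  }
  out <- df[, c("chrom", "start", "end", "strand", "kind", "gene_id")]
  # derive introns per gene
  introns <- list()
  for (g in seq_len(nrow(genes))) {
    ex <- kids[kids$kind == "exon" & kids$gene_id == genes$id[g], ,
               drop = FALSE]
    if (nrow(ex) == 0) {
      warning("gene ", genes$id[g], " has no exons; no introns derived")
      next
    }
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1) {
      istart <- ex$end[-nrow(ex)]
      iend <- ex$start[-1]
      ok <- istart < iend
      if (any(ok)) {
        introns[[length(introns) + 1L]] <- data.frame(
          chrom = genes$chrom[g], start = istart[ok], end = iend[ok],
          strand = genes$strand[g], kind = "intron",
          gene_id = genes$id[g], stringsAsFactors = FALSE)
      }
    }
  }
  # derive 1 kb upstream of the start codon on the coding strand
  if (nrow(genes)) {
    up <- genes
    plus <- up$strand != "-"
    up$end[plus] <- up$start[plus]
    up$start[plus] <- pmax(0L, up$start[plus] - upstream_bp)
    up$start[!plus] <- up$end[!plus]
    up$end[!plus] <- up$end[!plus] + upstream_bp
    up$kind <- "upstream1kb"
    up$gene_id <- up$id
    up <- up[up$start < up$end, c("chrom", "start", "end", "strand",
                                  "kind", "gene_id")]
  } else up <- NULL
  out <- rbind(out, do.call(rbind, introns), up)
  rownames(out) <- NULL
  out
}

#' Write regions as BED6
#'
#' Regions use 0-based half-open coordinates, matching BED. The score
#' column carries the region's overall methylation rate scaled by 1000 and
#' rounded.
#'
#' @param regions data.frame with chrom, start, end and optionally `rate`
#'   and `strand` columns.
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  if (nrow(regions) == 0) { file.create(path); return(invisible(path)) }
  score <- if ("rate" %in% names(regions)) round(regions$rate * 1000) else 0L
  strand <- if ("strand" %in% names(regions)) regions$strand else "+"
  bed <- data.frame(regions$chrom, regions$start, regions$end, ".",
                    score, strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 region file written by [write_regions_bed()]
#' @param path BED file.
#' @return data.frame with chrom, start, end, rate, strand.
#' @export
read_regions_bed <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), rate = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = df[[1]], start = df[[2]], end = df[[3]],
             rate = df[[5]] / 1000, strand = df[[6]],
             stringsAsFactors = FALSE)
}

#' Read a 1:1:1 ortholog map
#' @param path TSV with one gene id column per species.
#' @return data.frame of gene id triples; ids must be unique per species.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("ortholog map needs one column per species")
  for (j in seq_len(ncol(df))) {
    if (anyDuplicated(df[[j]])) {
      stop("ortholog map column ", names(df)[j], " has duplicate ids")
    }
  }
  df
}

#' Read a three-way aligned-cytosine map
#'
#' One row per aligned cytosine with per-species chrom, pos, strand and
#' context columns, suffixed `_1`, `_2`, `_3`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_aligned_sites <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- as.vector(outer(c("chrom", "pos", "strand", "context"), 1:3,
                          paste, sep = "_"))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("aligned-site map missing columns: ",
                         paste(miss, collapse = ", "))
  df
}

#' Write a three-way aligned-cytosine map
#' @param map data.frame as returned by the alignment simulator.
#' @param path output TSV path.
#' @export
write_aligned_sites <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene x sample count matrix
#' @param path TSV with a gene_id column followed by one column per sample.
#' @return integer matrix with gene ids as rownames.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write a gene x sample count matrix
#' @param counts integer matrix with gene rownames.
#' @param path output TSV path.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
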