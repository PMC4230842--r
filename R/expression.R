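#' Reads per kilobase per million mapped reads
#'
#' RPKM = 1e9 * count / (library_size * gene_length). With
#' `by_species` the counts and library sizes are first summed within each
#' species, giving one species-level RPKM per gene.
#'
#' @param counts gene x sample integer matrix.
#' @param gene_lengths per-gene lengths in bp (> 0).
#' @param library_sizes per-sample mapped-read totals (> 0); defaults to
#'   column sums.
#' @param by_species optional factor of length ncol(counts); RPKM is then
#'   computed per species from summed counts and summed library sizes.
#' @return numeric matrix of RPKM values.
#' @export
rpkm <- function(counts, gene_lengths, library_sizes = colSums(counts),
                 by_species = NULL) {
  stopifnot(all(gene_lengths > 0), length(gene_lengths) == nrow(counts))
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  if (!is.null(by_species)) {
    by_species <- factor(by_species)
    counts <- t(rowsum(t(counts), by_species))
    library_sizes <- as.numeric(rowsum(matrix(library_sizes), by_species))
    colnames(counts) <- levels(by_species)
  }
  1e9 * sweep(counts, 2, library_sizes, "/") / gene_lengths
}

#' Expressed-gene filter
#'
#' A gene counts as expressed when at least `min_samples` samples reach an
#' RPKM of `min_rpkm` (boundary inclusive).
#'
#' @param rpkm_matrix gene x sample RPKM matrix.
#' @param min_rpkm RPKM threshold (default 3).
#' @param min_samples number of samples required at the threshold
#'   (default 3).
#' @return logical vector per gene.
#' @export
expressed_filter <- function(rpkm_matrix, min_rpkm = 3, min_samples = 3L) {
  rowSums(rpkm_matrix >= min_rpkm) >= min_samples
}

# NB log likelihood at fixed means, parameterised by dispersion phi
# (variance = mu + phi mu^2), plus the Cox-Reid adjustment -0.5 log det
# (X' W X), W = mu / (1 + phi mu).
apl_one <- function(log_phi, y, mu, X) {
  phi <- exp(log_phi)
  ll <- sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  W <- mu / (1 + phi * mu)
  XtWX <- crossprod(X * sqrt(W))
  cr <- determinant(XtWX, logarithm = TRUE)$modulus
  as.numeric(ll - 0.5 * cr)
}

#' Estimate per-gene negative-binomial dispersions
#'
#' For each gene the dispersion is estimated by maximising the Cox-Reid
#' adjusted profile likelihood under the fitted design (means from a
#' Poisson-family IRLS fit, refined once at the gene's interim
#' dispersion), then shrunk on the log scale toward a lowess trend of
#' dispersion on mean expression with a fixed prior weight: the final
#' estimate weights the gene's own maximiser by its residual degrees of
#' freedom against `prior_weight` pseudo-observations at the trend.
#' Dispersions are floored at 1e-6; all-zero genes return NA.
#'
#' @param counts gene x sample matrix.
#' @param design data.frame of sample factors (tissue, treatment, optional
#'   species).
#' @param lib_sizes library sizes for the offset (default column sums).
#' @param prior_weight shrinkage weight toward the trend (default 10).
#' @return numeric vector of dispersions; attribute `trend` holds the
#'   trended values.
#' @export
estimate_dispersion <- function(counts, design, lib_sizes = colSums(counts),
                                prior_weight = 10) {
  X <- design_matrix(design)
  off <- log(lib_sizes)
  n_gene <- nrow(counts)
  raw <- rep(NA_real_, n_gene)
  lmean <- rep(NA_real_, n_gene)
  rng <- c(log(1e-6), log(10))
  for (g in seq_len(n_gene)) {
    y <- counts[g, ]
    if (all(y == 0)) next
    fit0 <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::poisson(), offset = off))
    mu <- pmax(fit0$fitted.values, 1e-8)
    opt <- stats::optimize(apl_one, rng, y = y, mu = mu, X = X,
                           maximum = TRUE)
    # one refinement pass: refit means at the interim dispersion
    phi1 <- exp(opt$maximum)
    fit1 <- suppressWarnings(
      stats::glm.fit(X, y, family = MASS::negative.binomial(1 / phi1),
                     offset = off))
    mu <- pmax(fit1$fitted.values, 1e-8)
    opt <- stats::optimize(apl_one, rng, y = y, mu = mu, X = X,
                           maximum = TRUE)
    raw[g] <- opt$maximum
    lmean[g] <- log(mean(y / exp(off)) + 1e-8)
  }
  ok <- !is.na(raw)
  trend <- rep(NA_real_, n_gene)
  if (sum(ok) >= 10) {
    lo <- stats::lowess(lmean[ok], raw[ok], f = 0.5)
    trend[ok] <- stats::approx(lo$x, lo$y, xout = lmean[ok], rule = 2)$y
  } else {
    trend[ok] <- stats::median(raw[ok])
  }
  df_res <- ncol(counts) - ncol(X)
  shrunk <- (df_res * raw + prior_weight * trend) / (df_res + prior_weight)
  out <- pmax(exp(shrunk), 1e-6)
  attr(out, "trend") <- pmax(exp(trend), 1e-6)
  out
}

design_matrix <- function(design) {
  for (j in seq_along(design)) design[[j]] <- factor(design[[j]])
  form <- if ("species" %in% names(design)) {
    ~ species * tissue * treatment
  } else ~ tissue * treatment
  stats::model.matrix(form, design)
}

#' Fit the negative-binomial GLM and test every term by deviance ANOVA
#'
#' Fits, per gene, an NB GLM with log link and library-size offset under
#' `~ tissue * treatment` (or `~ species * tissue * treatment` when a
#' species column is present), with the gene's dispersion supplied. Each
#' factor and interaction term is then assessed simultaneously: a reduced
#' model omitting the term's columns is fitted and the deviance difference
#' referred to a chi-squared distribution with the term's degrees of
#' freedom - the analysis-of-deviance analogue of a factorial ANOVA,
#' yielding one p-value per term rather than one per factor level.
#'
#' @param counts gene x sample matrix.
#' @param design data.frame of sample factors.
#' @param dispersions per-gene dispersions (e.g. from
#'   [estimate_dispersion()]); recycled.
#' @param lib_sizes library sizes for the offset.
#' @return list: `p` (gene x term matrix), `coef` (gene x coefficient
#'   matrix), `deviance` (full-model deviance), `converged` (logical per
#'   gene; non-converged genes carry NA p-values).
#' @export
fit_and_test <- function(counts, design, dispersions,
                         lib_sizes = colSums(counts)) {
  X <- design_matrix(design)
  asgn <- attr(X, "assign")
  terms_lab <- attr(stats::terms(
    if ("species" %in% names(design)) ~ species * tissue * treatment
    else ~ tissue * treatment), "term.labels")
  off <- log(lib_sizes)
  n_gene <- nrow(counts)
  dispersions <- rep_len(dispersions, n_gene)
  p <- matrix(NA_real_, n_gene, length(terms_lab),
              dimnames = list(rownames(counts), terms_lab))
  coefs <- matrix(NA_real_, n_gene, ncol(X),
                  dimnames = list(rownames(counts), colnames(X)))
  dev_full <- rep(NA_real_, n_gene)
  conv <- rep(FALSE, n_gene)
  for (g in seq_len(n_gene)) {
    y <- counts[g, ]
    if (all(y == 0) || is.na(dispersions[g])) next
    fam <- MASS::negative.binomial(theta = 1 / dispersions[g])
    full <- tryCatch(suppressWarnings(
      stats::glm.fit(X, y, family = fam, offset = off)),
      error = function(e) NULL)
    if (is.null(full) || !full$converged) next
    conv[g] <- TRUE
    dev_full[g] <- full$deviance
    coefs[g, ] <- full$coefficients
    for (t in seq_along(terms_lab)) {
      drop_cols <- which(asgn == t)
      Xr <- X[, -drop_cols, drop = FALSE]
      red <- tryCatch(suppressWarnings(
        stats::glm.fit(Xr, y, family = fam, offset = off)),
        error = function(e) NULL)
      if (is.null(red)) next
      dd <- red$deviance - full$deviance
      p[g, t] <- stats::pchisq(max(dd, 0), df = length(drop_cols),
                               lower.tail = FALSE)
    }
  }
  list(p = p, coef = coefs, deviance = dev_full, converged = conv)
}

#' Correlate differential methylation with expression change
#'
#' Spearman rank correlation (midrank ties) between a per-gene
#' differential-methylation summary and the matched comparison's log2
#' fold change, reported per feature class. For position-level input the
#' methylation summary is the DMP direction (+/-1); for region-level
#' input it is the methylation-rate difference. Classes with fewer than
#' `min_genes` genes are reported as NA.
#'
#' @param meth data.frame with columns gene_id, feature (class label) and
#'   either `direction` or `rate_diff`.
#' @param log2fc named numeric vector of log2 fold changes per gene.
#' @param min_genes minimum class size (default 10).
#' @return data.frame feature, n, rho.
#' @export
methylation_expression_correlation <- function(meth, log2fc,
                                               min_genes = 10L) {
  val <- if ("direction" %in% names(meth)) meth$direction else
    meth$rate_diff
  fc <- log2fc[meth$gene_id]
  ok <- !is.na(fc) & !is.na(val)
  classes <- sort(unique(meth$feature))
  out <- data.frame(feature = classes, n = NA_integer_, rho = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(classes)) {
    s <- ok & meth$feature == classes[i]
    out$n[i] <- sum(s)
    if (sum(s) >= min_genes) {
      out$rho[i] <- stats::cor(val[s], fc[s], method = "spearman")
    }
  }
  out
}

#' Per-term log2 fold changes from a factorial fit
#'
#' Convenience accessor: log2 of the fitted effect for a main-effect term
#' (second level vs first), from the natural-log coefficients of
#' [fit_and_test()].
#'
#' @param fit result of [fit_and_test()].
#' @param term coefficient name (e.g. `"tissueshoot"`).
#' @return named numeric vector per gene.
#' @export
log2_fold_change <- function(fit, term) {
  if (!term %in% colnames(fit$coef)) {
    stop("unknown coefficient: ", term, "; available: ",
         paste(colnames(fit$coef), collapse = ", "))
  }
  fit$coef[, term] / log(2)
}
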