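design_12 <- function() {
  expand.grid(replicate = 1:3, treatment = c("control23", "cold4"),
              tissue = c("root", "shoot"))[, c("tissue", "treatment")]
}

test_that("RPKM is reads per kb per million and scale-invariant", {
  counts <- matrix(10L, 1, 1, dimnames = list("g1", "s1"))
  expect_equal(as.numeric(rpkm(counts, 1000, 1e6)), 10)
  set.seed(61)
  cm <- matrix(rpois(40, 50), 10, 4)
  len <- sample(500:3000, 10)
  lib <- colSums(cm)
  expect_equal(rpkm(cm * 3, len, lib * 3), rpkm(cm, len, lib))
  # independent recount
  oracle <- t(vapply(1:10, function(g) 1e9 * cm[g, ] / (lib * len[g]),
                     numeric(4)))
  expect_equal(unname(rpkm(cm, len, lib)), oracle)
  # species-level RPKM pools counts and library sizes
  sp <- c("a", "a", "b", "b")
  r_sp <- rpkm(cm, len, lib, by_species = sp)
  expect_equal(unname(r_sp[, "a"]),
               1e9 * (cm[, 1] + cm[, 2]) / ((lib[1] + lib[2]) * len))
  expect_error(rpkm(cm, len, c(0, lib[-1])), "positive")
})

test_that("the expressed filter is boundary-inclusive and monotone", {
  r <- matrix(0, 2, 12)
  r[1, 1:3] <- 3        # exactly 3 RPKM in exactly 3 samples
  r[2, ] <- 2.9
  expect_equal(expressed_filter(r), c(TRUE, FALSE))
  set.seed(62)
  r2 <- matrix(rexp(600, 1 / 4), 50, 12)
  e_lo <- expressed_filter(r2, min_rpkm = 2)
  e_hi <- expressed_filter(r2, min_rpkm = 5)
  expect_true(all(which(e_hi) %in% which(e_lo)))
})

test_that("dispersion estimates recover the simulation truth", {
  d <- design_12()
  sim <- simulate_expression(300, d, dispersions = 0.4, seed = 63)
  est <- estimate_dispersion(sim$counts, d)
  expect_gt(median(est, na.rm = TRUE), 0.2)
  expect_lt(median(est, na.rm = TRUE), 0.6)
  # near-Poisson data estimate near zero
  simp <- simulate_expression(200, d, dispersions = 1e-5, seed = 64)
  estp <- estimate_dispersion(simp$counts, d)
  expect_lt(median(estp, na.rm = TRUE), 0.05)
  # duplicated samples (zero within-cell variance) hit the floor
  dup <- simp$counts[, rep(1, 12)]
  dd <- d; dd$tissue <- rep(c("root", "shoot"), 6)
  estd <- suppressWarnings(estimate_dispersion(dup, dd))
  expect_true(all(estd >= 1e-6))
  # all-zero gene is skipped
  z <- simp$counts; z[1, ] <- 0L
  expect_true(is.na(suppressWarnings(estimate_dispersion(z, d))[1]))
})

test_that("full-model deviance never exceeds a reduced model's", {
  d <- design_12()
  sim <- simulate_expression(50, d, dispersions = 0.2, seed = 65)
  fit <- fit_and_test(sim$counts, d, sim$truth$dispersions)
  # p-values exist for every converged gene and term
  expect_true(all(!is.na(fit$p[fit$converged, ])))
  expect_true(all(fit$p >= 0 & fit$p <= 1, na.rm = TRUE))
  # nesting, checked directly for one gene and the tissue term
  X <- cometh:::design_matrix(d)
  g <- which(fit$converged)[1]
  fam <- MASS::negative.binomial(1 / sim$truth$dispersions[g])
  off <- log(colSums(sim$counts))
  full <- glm.fit(X, sim$counts[g, ], family = fam, offset = off)
  red <- glm.fit(X[, -2, drop = FALSE], sim$counts[g, ], family = fam,
                 offset = off)
  expect_lte(full$deviance, red$deviance + 1e-8)
})

test_that("the NB fit agrees with edgeR's glmFit at fixed dispersion", {
  skip_if_not_installed("edgeR")
  d <- design_12()
  sim <- simulate_expression(30, d, dispersions = 0.15, seed = 66)
  X <- cometh:::design_matrix(d)
  lib <- colSums(sim$counts)
  fit <- fit_and_test(sim$counts, d, 0.15, lib)
  ef <- edgeR::glmFit(sim$counts, X, dispersion = 0.15, lib.size = lib,
                      prior.count = 0)
  ok <- fit$converged
  expect_lt(max(abs(fit$deviance[ok] - ef$deviance[ok])), 1e-4)
  expect_lt(max(abs(fit$coef[ok, ] - ef$coefficients[ok, ])), 1e-4)
})

test_that("an injected tissue effect is detected with high power", {
  d <- design_12()
  spec <- data.frame(gene = 1:60, term = "tissue", value = log(4))
  sim <- simulate_expression(200, d, coef_spec = spec, dispersions = 0.1,
                             seed = 67)
  # use the generative library sizes: with 30% strongly DE genes the column
  # totals are tissue-confounded and would bias the offset
  fit <- fit_and_test(sim$counts, d, 0.1, sim$truth$lib_sizes)
  power <- mean(fit$p[1:60, "tissue"] < 0.05, na.rm = TRUE)
  expect_gt(power, 0.9)
  # null genes are not flagged wholesale
  expect_lt(mean(fit$p[61:200, "tissue"] < 0.05, na.rm = TRUE), 0.12)
  # tissue-only truth loads on the tissue term, mirroring tissue-dominant
  # differential expression
  n_tis <- sum(fit$p[, "tissue"] < 0.05, na.rm = TRUE)
  n_trt <- sum(fit$p[, "treatment"] < 0.05, na.rm = TRUE)
  expect_gt(n_tis, n_trt)
})

test_that("deviance tests approach the Poisson GLM as dispersion vanishes", {
  d <- design_12()
  sim <- simulate_expression(40, d, dispersions = 1e-6, seed = 68)
  lib <- colSums(sim$counts)
  fit <- fit_and_test(sim$counts, d, 1e-8, lib)
  X <- cometh:::design_matrix(d)
  asgn <- attr(X, "assign")
  for (g in which(fit$converged)[1:10]) {
    y <- sim$counts[g, ]
    full <- glm.fit(X, y, family = poisson(), offset = log(lib))
    red <- glm.fit(X[, asgn != 1, drop = FALSE], y, family = poisson(),
                   offset = log(lib))
    p_pois <- pchisq(red$deviance - full$deviance, 1, lower.tail = FALSE)
    expect_equal(fit$p[g, "tissue"], p_pois, tolerance = 1e-3)
  }
})

test_that("methylation-expression correlation uses midranks and class floors", {
  meth <- data.frame(gene_id = sprintf("g%02d", 1:20),
                     feature = rep(c("exon", "upstream1kb"), each = 10),
                     rate_diff = seq(-0.9, 1, by = 0.1))
  # perfectly anticorrelated: hypermethylated genes are downregulated
  fc <- setNames(-rank(meth$rate_diff) - runif(20), meth$gene_id)
  res <- methylation_expression_correlation(meth, fc, min_genes = 5)
  expect_equal(res$rho, c(-1, -1))
  # small classes are unavailable
  res2 <- methylation_expression_correlation(meth, fc, min_genes = 50)
  expect_true(all(is.na(res2$rho)))
  # ties handled by midranks: agree with an explicit rank computation
  set.seed(69)
  meth3 <- data.frame(gene_id = sprintf("g%02d", 1:20), feature = "exon",
                      direction = sample(c(-1, 0, 1), 20, TRUE))
  fc3 <- setNames(rnorm(20), meth3$gene_id)
  res3 <- methylation_expression_correlation(meth3, fc3, min_genes = 5)
  oracle <- cor(rank(meth3$direction), rank(fc3[meth3$gene_id]))
  expect_equal(res3$rho, oracle, tolerance = 1e-12)
  # independent methylation and expression stay near zero
  set.seed(70)
  meth4 <- data.frame(gene_id = sprintf("g%04d", 1:1000), feature = "exon",
                      direction = sample(c(-1, 1), 1000, TRUE))
  fc4 <- setNames(rnorm(1000), meth4$gene_id)
  res4 <- methylation_expression_correlation(meth4, fc4)
  expect_lt(abs(res4$rho), 0.1)
})
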