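#' Beta-binomial log density
#'
#' Density of the beta-binomial distribution, the binomial with a
#' Beta(alpha, beta) prior on the success probability. Used throughout the
#' package to model overdispersed methylation counts: `k` methylated reads
#' out of `n` at a cytosine whose underlying methylation level varies from
#' site to site.
#'
#' @param k integer vector, number of successes (methylated reads).
#' @param n integer vector, number of trials (total reads).
#' @param alpha,beta positive shape parameters.
#' @param log logical, return log density.
#' @return numeric vector of (log) densities.
#' @export
dbetabinom <- function(k, n, alpha, beta, log = FALSE) {
  stopifnot(all(alpha > 0), all(beta > 0))
  ll <- lchoose(n, k) + lbeta(k + alpha, n - k + beta) - lbeta(alpha, beta)
  ll[k < 0 | k > n] <- -Inf
  if (log) ll else exp(ll)
}

# Weighted beta-binomial log likelihood (constant lchoose term included so
# values are comparable across parameter sets, not across data sets).
bb_loglik <- function(k, n, alpha, beta, w = NULL) {
  ll <- dbetabinom(k, n, alpha, beta, log = TRUE)
  if (is.null(w)) sum(ll) else sum(w * ll)
}

# Method-of-moments starting values for (alpha, beta) from (possibly
# weighted) per-site rates. The beta variance is approximated by the excess
# of the rate variance over the average binomial sampling variance; when the
# data look underdispersed the precision is capped rather than infinite.
bb_moment_start <- function(k, n, w = NULL) {
  keep <- n > 0
  k <- k[keep]; n <- n[keep]
  if (is.null(w)) w <- rep(1, length(k)) else w <- w[keep]
  if (length(k) == 0 || sum(w) <= 0) return(c(alpha = 1, beta = 1))
  r <- k / n
  m <- sum(w * r) / sum(w)
  v <- sum(w * (r - m)^2) / sum(w)
  m <- min(max(m, 1e-4), 1 - 1e-4)
  # subtract the expected binomial noise at the observed coverages
  v_bin <- sum(w * m * (1 - m) / n) / sum(w)
  v_beta <- v - v_bin
  if (!is.finite(v_beta) || v_beta <= 1e-8) {
    s <- 1e3
  } else {
    s <- m * (1 - m) / v_beta - 1
  }
  s <- min(max(s, 0.05), 1e4)
  c(alpha = m * s, beta = (1 - m) * s)
}

#' Maximum-likelihood fit of a beta-binomial distribution
#'
#' Fits (alpha, beta) to count pairs by Newton iteration on the digamma-form
#' score in log-parameter space, starting from a method-of-moments estimate.
#' Optional per-observation weights support the posterior-weighted M-step of
#' the segmentation HMM. Parameters are clamped to `[1e-3, 1e6]`; a fit that
#' hits the boundary is flagged.
#'
#' @param k,n numeric vectors of successes and trials.
#' @param w optional non-negative weights.
#' @param max_iter Newton iteration cap.
#' @param tol convergence tolerance on the log-likelihood gain.
#' @return list with `alpha`, `beta`, `loglik`, `converged`, `boundary`.
#' @export
fit_betabinom <- function(k, n, w = NULL, max_iter = 50, tol = 1e-8) {
  keep <- n > 0 & (if (is.null(w)) TRUE else w > 0)
  k <- k[keep]; n <- n[keep]
  if (!is.null(w)) w <- w[keep]
  if (length(k) == 0) {
    return(list(alpha = 1, beta = 1, loglik = 0, converged = FALSE,
                boundary = FALSE))
  }
  ww <- if (is.null(w)) rep(1, length(k)) else w
  start <- bb_moment_start(k, n, ww)
  a <- clamp_ab(start[["alpha"]]); b <- clamp_ab(start[["beta"]])
  ll <- bb_loglik(k, n, a, b, ww)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # score in (alpha, beta)
    da <- sum(ww * (digamma(k + a) - digamma(n + a + b) -
                      digamma(a) + digamma(a + b)))
    db <- sum(ww * (digamma(n - k + b) - digamma(n + a + b) -
                      digamma(b) + digamma(a + b)))
    # hessian in (alpha, beta)
    tab <- sum(ww * (trigamma(a + b) - trigamma(n + a + b)))
    haa <- sum(ww * (trigamma(k + a) - trigamma(a))) + tab
    hbb <- sum(ww * (trigamma(n - k + b) - trigamma(b))) + tab
    # Newton step in (log alpha, log beta) via chain rule
    g <- c(da * a, db * b)
    H <- matrix(c(haa * a * a + da * a, tab * a * b,
                  tab * a * b, hbb * b * b + db * b), 2, 2)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) step <- g * 0.1
    step <- -step  # ascend
    step <- pmin(pmax(step, -2), 2)
    ok <- FALSE
    for (h in c(1, 0.5, 0.25, 0.1, 0.02)) {
      a2 <- clamp_ab(exp(log(a) + h * step[1]))
      b2 <- clamp_ab(exp(log(b) + h * step[2]))
      ll2 <- bb_loglik(k, n, a2, b2, ww)
      if (is.finite(ll2) && ll2 >= ll) { ok <- TRUE; break }
    }
    if (!ok) { converged <- TRUE; break }
    gain <- ll2 - ll
    a <- a2; b <- b2; ll <- ll2
    if (gain < tol) { converged <- TRUE; break }
  }
  boundary <- a <= 1e-3 || a >= 1e6 || b <= 1e-3 || b >= 1e6
  list(alpha = unname(a), beta = unname(b), loglik = unname(ll),
       converged = converged, boundary = boundary)
}

clamp_ab <- function(x) min(max(x, 1e-3), 1e6)

# log(exp(x) + exp(y)) for scalars/vectors, safe against -Inf
logsumexp2 <- function(x, y) {
  m <- pmax(x, y)
  r <- m + log1p(exp(pmin(x, y) - m))
  r[!is.finite(m)] <- m[!is.finite(m)]
  r
}
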