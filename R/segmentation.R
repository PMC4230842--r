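#' Two-state HMM parameters with context-specific beta-binomial emissions
#'
#' The methylome segmentation model has two hidden states, unmethylated (U)
#' and methylated (M), a 2x2 transition matrix over consecutive covered
#' cytosines, and one beta-binomial emission distribution per state and
#' sequence context (CG, CHG, CHH) - six (alpha, beta) pairs in total.
#' Plant methylomes need the per-context emissions because CG, CHG and CHH
#' methylation levels differ strongly even within a methylated region.
#'
#' @param trans 2x2 row-stochastic matrix, rows/cols ordered (U, M).
#' @param start length-2 initial state distribution.
#' @param emis numeric array `[2 states, 3 contexts, 2]` of alpha
#'   (`[,,1]`) and beta (`[,,2]`), contexts ordered (CG, CHG, CHH).
#' @return object of class `hmm_params`.
#' @export
hmm_params <- function(trans, start, emis) {
  trans <- as.matrix(trans)
  stopifnot(all(dim(trans) == c(2, 2)),
            all(abs(rowSums(trans) - 1) < 1e-9),
            length(start) == 2, abs(sum(start) - 1) < 1e-9,
            all(dim(emis) == c(2, 3, 2)), all(emis > 0))
  dimnames(trans) <- list(c("U", "M"), c("U", "M"))
  dimnames(emis) <- list(c("U", "M"), c("CG", "CHG", "CHH"),
                         c("alpha", "beta"))
  structure(list(trans = trans, start = as.numeric(start), emis = emis),
            class = "hmm_params")
}

#' Default weakly-informative starting parameters
#'
#' U-state emission means at 0.05 and M-state at 0.7, total precision
#' alpha + beta = 10, transition diagonal 0.9. Well separated and
#' deliberately generic; training adapts them to the sample.
#'
#' @param mean_u,mean_m initial per-state emission means.
#' @param precision alpha + beta of every emission.
#' @param stay diagonal of the transition matrix.
#' @return an [hmm_params()].
#' @export
default_hmm_params <- function(mean_u = 0.05, mean_m = 0.7, precision = 10,
                               stay = 0.9) {
  emis <- array(0, c(2, 3, 2))
  for (ctx in 1:3) {
    emis[1, ctx, ] <- c(mean_u, 1 - mean_u) * precision
    emis[2, ctx, ] <- c(mean_m, 1 - mean_m) * precision
  }
  hmm_params(matrix(c(stay, 1 - stay, 1 - stay, stay), 2, 2, byrow = TRUE),
             c(0.5, 0.5), emis)
}

#' @export
print.hmm_params <- function(x, ...) {
  mu <- x$emis[, , 1] / (x$emis[, , 1] + x$emis[, , 2])
  cat("<hmm_params> emission means:\n")
  print(round(mu, 3))
  cat("transition matrix:\n")
  print(round(x$trans, 4))
  invisible(x)
}

#' Split a methylome into segments of contiguously covered cytosines
#'
#' The HMM chain must not run across stretches of the genome without any
#' covered cytosine, so the genome is split wherever `max_gap` or more
#' adjacent base pairs lack a covered position (and at chromosome
#' boundaries). Only records with `n_total > 0` enter segments.
#'
#' @param table a [sample_table()].
#' @param max_gap minimum run of uncovered base pairs that forces a split
#'   (default 50).
#' @return list of data.frames (chrom, pos, strand, context, n_total,
#'   n_meth), one per segment.
#' @export
split_segments <- function(table, max_gap = 50L) {
  rec <- table$records
  rec <- rec[rec$n_total > 0, , drop = FALSE]
  if (nrow(rec) == 0) return(list())
  segs <- list()
  for (ch in unique(rec$chrom)) {
    r <- rec[rec$chrom == ch, , drop = FALSE]
    # uncovered bases between consecutive covered positions; positions on
    # both strands count as covered positions
    upos <- sort(unique(r$pos))
    gap_before <- c(Inf, diff(upos) - 1)
    seg_id_of_pos <- cumsum(gap_before >= max_gap)
    seg_id <- seg_id_of_pos[match(r$pos, upos)]
    for (s in unique(seg_id)) {
      segs[[length(segs) + 1L]] <- r[seg_id == s, , drop = FALSE]
    }
  }
  segs
}

# Per-site emission log-likelihood matrix (n x 2 states) for one segment.
emission_loglik <- function(seg, params, floor = 1e-300) {
  ctx <- match(seg$context, c("CG", "CHG", "CHH"))
  ll <- matrix(0, nrow(seg), 2)
  for (s in 1:2) {
    a <- params$emis[s, ctx, 1]
    b <- params$emis[s, ctx, 2]
    ll[, s] <- dbetabinom(seg$n_meth, seg$n_total, a, b, log = TRUE)
  }
  pmax(ll, log(floor))
}

# Log-space forward-backward for one segment. Returns posteriors gamma
# (n x 2), expected transition counts xi_sum (2 x 2) and the log-likelihood.
forward_backward <- function(ll, log_trans, log_start) {
  n <- nrow(ll)
  la <- matrix(-Inf, n, 2)
  lb <- matrix(0, n, 2)
  la[1, ] <- log_start + ll[1, ]
  if (n > 1) {
    for (t in 2:n) {
      for (s in 1:2) {
        la[t, s] <- logsumexp2(la[t - 1, 1] + log_trans[1, s],
                               la[t - 1, 2] + log_trans[2, s]) + ll[t, s]
      }
    }
    for (t in (n - 1):1) {
      for (s in 1:2) {
        lb[t, s] <- logsumexp2(
          log_trans[s, 1] + ll[t + 1, 1] + lb[t + 1, 1],
          log_trans[s, 2] + ll[t + 1, 2] + lb[t + 1, 2])
      }
    }
  }
  loglik <- logsumexp2(la[n, 1], la[n, 2])
  gamma <- exp(la + lb - loglik)
  gamma <- gamma / rowSums(gamma)
  xi_sum <- matrix(0, 2, 2)
  if (n > 1) {
    for (i in 1:2) for (j in 1:2) {
      xi_sum[i, j] <- sum(exp(la[1:(n - 1), i] + log_trans[i, j] +
                                ll[2:n, j] + lb[2:n, j] - loglik))
    }
  }
  list(gamma = gamma, xi_sum = xi_sum, loglik = loglik)
}

#' Train the segmentation HMM by Baum-Welch
#'
#' Runs EM jointly over all segments of a sample: the E-step is log-space
#' forward-backward with beta-binomial emission likelihoods selected by
#' each cytosine's context; the M-step re-normalises expected transition
#' counts and refits each of the six (alpha, beta) pairs by
#' posterior-weighted maximum likelihood (method-of-moments start, Newton
#' refinement capped at 50 iterations). A candidate emission update is
#' only accepted if it does not decrease the weighted emission likelihood,
#' so the log-likelihood trace is non-decreasing.
#'
#' @param segments list of segment data.frames from [split_segments()].
#' @param init starting [hmm_params()] (default [default_hmm_params()]).
#' @param max_iter maximum EM iterations.
#' @param tol stop when the log-likelihood gain drops below this.
#' @return list with `params`, `loglik_trace`, `converged`, `n_iter`.
#' @export
train_hmm <- function(segments, init = default_hmm_params(), max_iter = 50L,
                      tol = 1e-3) {
  segments <- Filter(function(s) nrow(s) > 0, segments)
  if (length(segments) == 0 || sum(vapply(segments, nrow, 0L)) < 2) {
    stop("need at least one segment with at least 2 cytosines")
  }
  params <- init
  trace <- numeric(0)
  all_k <- unlist(lapply(segments, `[[`, "n_meth"))
  all_n <- unlist(lapply(segments, `[[`, "n_total"))
  all_ctx <- match(unlist(lapply(segments, `[[`, "context")),
                   c("CG", "CHG", "CHH"))
  degenerate <- all(all_k == 0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    log_trans <- log(params$trans)
    log_start <- log(params$start)
    gam_list <- vector("list", length(segments))
    xi <- matrix(0, 2, 2)
    start_acc <- c(0, 0)
    ll_total <- 0
    for (i in seq_along(segments)) {
      ll <- emission_loglik(segments[[i]], params)
      fb <- forward_backward(ll, log_trans, log_start)
      gam_list[[i]] <- fb$gamma
      xi <- xi + fb$xi_sum
      start_acc <- start_acc + fb$gamma[1, ]
      ll_total <- ll_total + fb$loglik
    }
    trace <- c(trace, ll_total)
    if (iter > 1 && trace[iter] - trace[iter - 1] < tol) {
      converged <- TRUE
      break
    }
    # M-step
    gamma_all <- do.call(rbind, gam_list)
    new_trans <- xi / pmax(rowSums(xi), .Machine$double.xmin)
    if (any(rowSums(xi) == 0)) new_trans <- params$trans
    new_start <- start_acc / sum(start_acc)
    new_emis <- params$emis
    for (s in 1:2) for (ctx in 1:3) {
      sel <- all_ctx == ctx
      if (!any(sel)) next
      w <- gamma_all[sel, s]
      if (sum(w) < 1e-8) next
      if (degenerate && s == 2) next  # keep M-state at initialisation
      cur_a <- params$emis[s, ctx, 1]; cur_b <- params$emis[s, ctx, 2]
      fit <- fit_betabinom(all_k[sel], all_n[sel], w)
      cur_ll <- bb_loglik(all_k[sel][all_n[sel] > 0 & w > 0],
                          all_n[sel][all_n[sel] > 0 & w > 0],
                          cur_a, cur_b, w[all_n[sel] > 0 & w > 0])
      if (fit$loglik >= cur_ll) {
        new_emis[s, ctx, ] <- c(fit$alpha, fit$beta)
      }
    }
    params <- hmm_params(new_trans, new_start, new_emis)
  }
  if (degenerate) {
    warning("all methylated counts are zero; M-state emissions kept at ",
            "initialisation values")
  }
  list(params = params, loglik_trace = trace, converged = converged,
       n_iter = length(trace))
}

# Viterbi decoding of one segment; returns the integer state path
# (1 = U, 2 = M).
viterbi <- function(ll, log_trans, log_start) {
  n <- nrow(ll)
  delta <- matrix(-Inf, n, 2)
  psi <- matrix(0L, n, 2)
  delta[1, ] <- log_start + ll[1, ]
  if (n > 1) {
    for (t in 2:n) {
      for (s in 1:2) {
        cand <- delta[t - 1, ] + log_trans[, s]
        psi[t, s] <- which.max(cand)
        delta[t, s] <- cand[psi[t, s]] + ll[t, s]
      }
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

#' Decode methylated regions from trained parameters
#'
#' Viterbi-decodes the single most probable state path of every segment and
#' turns each maximal run of the methylated state into an (untrimmed)
#' region spanning its first to last cytosine. Posterior decoding
#' (per-site argmax of the forward-backward posterior) is available behind
#' `method = "posterior"`.
#'
#' @param segments list of segment data.frames.
#' @param params trained [hmm_params()].
#' @param method `"viterbi"` (default) or `"posterior"`.
#' @return data.frame of regions: chrom, start, end (0-based half-open),
#'   per-context cytosine counts and mean rates, overall `rate`, plus a
#'   `sites` list-column with the member cytosines.
#' @export
decode_mrs <- function(segments, params, method = c("viterbi", "posterior")) {
  method <- match.arg(method)
  log_trans <- log(params$trans)
  log_start <- log(params$start)
  out <- list()
  for (seg in segments) {
    if (nrow(seg) == 0) next
    ll <- emission_loglik(seg, params)
    path <- if (method == "viterbi") {
      viterbi(ll, log_trans, log_start)
    } else {
      max.col(forward_backward(ll, log_trans, log_start)$gamma)
    }
    r <- rle(path)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values == 2)) {
      sites <- seg[starts[j]:ends[j], , drop = FALSE]
      out[[length(out) + 1L]] <- mr_row(sites)
    }
  }
  if (length(out) == 0) return(empty_mr_frame())
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

mr_row <- function(sites) {
  ctxs <- c("CG", "CHG", "CHH")
  n_ctx <- vapply(ctxs, function(c) sum(sites$context == c), 0L)
  rate_ctx <- vapply(ctxs, function(c) {
    s <- sites$context == c
    if (!any(s)) return(NA_real_)
    mean(sites$n_meth[s] / sites$n_total[s])
  }, numeric(1))
  df <- data.frame(chrom = sites$chrom[1],
                   start = min(sites$pos) - 1L,  # 1-based site -> 0-based
                   end = max(sites$pos),
                   n_cg = n_ctx[1], n_chg = n_ctx[2], n_chh = n_ctx[3],
                   rate_cg = rate_ctx[1], rate_chg = rate_ctx[2],
                   rate_chh = rate_ctx[3],
                   rate = mean(sites$n_meth / sites$n_total),
                   stringsAsFactors = FALSE)
  df$sites <- list(sites)
  df
}

empty_mr_frame <- function() {
  df <- data.frame(chrom = character(), start = integer(), end = integer(),
                   n_cg = integer(), n_chg = integer(), n_chh = integer(),
                   rate_cg = numeric(), rate_chg = numeric(),
                   rate_chh = numeric(), rate = numeric(),
                   stringsAsFactors = FALSE)
  df$sites <- list()
  df
}

#' Trim a methylated region at low-rate boundary cytosines
#'
#' Iteratively removes cytosines with a methylation rate below `min_rate`
#' from both ends of the region and recomputes the boundaries; the region
#' is dropped (NULL) if nothing remains. Boundary sites below `min_cov`
#' cannot demonstrate the required rate and are trimmed as well.
#'
#' @param region one row of the frame from [decode_mrs()] (with its
#'   `sites`).
#' @param min_rate boundary rate threshold (default 0.10).
#' @param min_cov coverage floor for a site's rate to count (default 1).
#' @return a one-row region data.frame, or NULL if the region empties.
#' @export
trim_mr <- function(region, min_rate = 0.10, min_cov = 1L) {
  sites <- region$sites[[1]]
  ok <- function(i) {
    sites$n_total[i] >= min_cov &&
      sites$n_meth[i] / sites$n_total[i] >= min_rate
  }
  lo <- 1L; hi <- nrow(sites)
  while (lo <= hi && !ok(lo)) lo <- lo + 1L
  while (hi >= lo && !ok(hi)) hi <- hi - 1L
  if (lo > hi) return(NULL)
  mr_row(sites[lo:hi, , drop = FALSE])
}

#' Trim a whole set of regions
#' @param mrs region frame from [decode_mrs()].
#' @inheritParams trim_mr
#' @return trimmed region frame (possibly with fewer rows).
#' @export
trim_mrs <- function(mrs, min_rate = 0.10, min_cov = 1L) {
  kept <- list()
  for (i in seq_len(nrow(mrs))) {
    t <- trim_mr(mrs[i, , drop = FALSE], min_rate, min_cov)
    if (!is.null(t)) kept[[length(kept) + 1L]] <- t
  }
  if (length(kept) == 0) return(empty_mr_frame())
  df <- do.call(rbind, kept)
  rownames(df) <- NULL
  df
}

#' Segment one sample end to end
#'
#' Convenience wrapper: split into segments, train the HMM genome-wide on
#' this sample, Viterbi-decode and trim. One parameter set and one
#' segmentation per (tissue, treatment) combination, run on
#' replicate-merged counts.
#'
#' @param table replicate-merged [sample_table()].
#' @param max_gap segment split gap (default 50 bp).
#' @param trim_rate boundary trim threshold (default 0.10).
#' @param init,max_iter,tol passed to [train_hmm()].
#' @return list with `mrs` (trimmed region frame), `params`, `trace`.
#' @export
segment_methylome <- function(table, max_gap = 50L, trim_rate = 0.10,
                              init = default_hmm_params(), max_iter = 30L,
                              tol = 1e-3) {
  segs <- split_segments(table, max_gap)
  fit <- train_hmm(segs, init, max_iter, tol)
  mrs <- decode_mrs(segs, fit$params)
  list(mrs = trim_mrs(mrs, trim_rate), params = fit$params,
       trace = fit$loglik_trace)
}
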