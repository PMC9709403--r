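# Reproducibility assessment: pseudo-replicate splits, peak matching
# between replicates, the two-component Gaussian copula mixture fitted by
# EM (local and global irreproducible discovery rates), and the
# ENCODE-style consistent-peak decision procedure.

#' IDR configuration
#'
#' The three cutoffs are the recommended operating points for plant
#' ATAC-seq: 0.05 for true replicates, 0.02 for self-pseudo-replicates,
#' 0.01 for pooled pseudo-replicates.
#'
#' @param cutoff_true_reps global IDR cutoff for original replicates
#'   (default 0.05).
#' @param cutoff_self_pseudo cutoff for pseudo-replicates split from a
#'   single replicate (default 0.02).
#' @param cutoff_pooled_pseudo cutoff for pseudo-replicates split from the
#'   pooled library (default 0.01).
#' @param em_tol EM convergence tolerance on the log-likelihood
#'   (default 1e-6).
#' @param max_iter maximum EM iterations (default 1000).
#' @param min_pairs minimum matched pairs required to fit (default 50).
#' @param init starting values for (pi, mu, sigma, rho).
#' @return an `idr_config` list.
#' @export
idr_config <- function(cutoff_true_reps = 0.05, cutoff_self_pseudo = 0.02,
                       cutoff_pooled_pseudo = 0.01, em_tol = 1e-6,
                       max_iter = 1000, min_pairs = 50,
                       init = c(pi = 0.5, mu = 2, sigma = 1, rho = 0.5)) {
  cuts <- c(cutoff_true_reps, cutoff_self_pseudo, cutoff_pooled_pseudo)
  stopifnot(all(cuts > 0 & cuts < 1), em_tol > 0, max_iter >= 1)
  structure(list(cutoff_true_reps = cutoff_true_reps,
                 cutoff_self_pseudo = cutoff_self_pseudo,
                 cutoff_pooled_pseudo = cutoff_pooled_pseudo,
                 em_tol = em_tol, max_iter = max_iter,
                 min_pairs = min_pairs, init = init), class = "idr_config")
}

#' Randomly split tags into pseudo-replicates
#'
#' Uniform random partition into two halves whose sizes differ by at most
#' one; together the halves reproduce the input multiset exactly.
#'
#' @param tags tag data.frame with >= 2 rows.
#' @param seed integer seed; the split is deterministic given the seed.
#' @return list of two tag data.frames `a` and `b`.
#' @export
split_pseudoreplicates <- function(tags, seed) {
  n <- nrow(tags)
  if (n < 2) stop("need >= 2 tags to split")
  # permute then cut: |a| and |b| differ by <= 1 (odd n: the extra tag
  # goes to a or b by a fair coin, fixed by the seed)
  draws <- with_seed(seed, list(perm = sample.int(n),
                                coin = sample.int(2, 1)))
  a_size <- n %/% 2 + (if (n %% 2) draws$coin - 1 else 0)
  a <- sort(draws$perm[seq_len(a_size)])
  b <- sort(draws$perm[(a_size + 1):n])
  list(a = tags[a, , drop = FALSE], b = tags[b, , drop = FALSE])
}

#' Match peaks between two replicates
#'
#' Peaks are paired by >= 1 bp overlap, one-to-one by best mutual overlap
#' (ties broken toward the higher-scoring partner).  Unmatched peaks are
#' excluded from model fitting but reported.
#'
#' @param peaks1,peaks2 peak data.frames on the same genome.
#' @param score_col column used as the ranking score (default "pvalue",
#'   the -log10 p).
#' @return list with `pairs` (data.frame: i, j, overlap, score1, score2),
#'   `unmatched1`, `unmatched2` (row indices).
#' @export
match_peaks <- function(peaks1, peaks2, score_col = "pvalue") {
  if (!nrow(peaks1) || !nrow(peaks2)) {
    warning("empty peak set; no pairs to match")
    return(list(pairs = data.frame(i = integer(), j = integer(),
                                   overlap = numeric(), score1 = numeric(),
                                   score2 = numeric()),
                unmatched1 = seq_len(nrow(peaks1)),
                unmatched2 = seq_len(nrow(peaks2))))
  }
  cand <- overlap_pairs(peaks1, peaks2)
  if (!nrow(cand)) {
    return(list(pairs = data.frame(i = integer(), j = integer(),
                                   overlap = numeric(), score1 = numeric(),
                                   score2 = numeric()),
                unmatched1 = seq_len(nrow(peaks1)),
                unmatched2 = seq_len(nrow(peaks2))))
  }
  cand$score1 <- peaks1[[score_col]][cand$i]
  cand$score2 <- peaks2[[score_col]][cand$j]
  # greedy best-overlap matching: largest overlap first, ties to the pair
  # with the higher combined score
  ord <- order(-cand$overlap, -(cand$score1 + cand$score2), cand$i, cand$j)
  cand <- cand[ord, , drop = FALSE]
  used1 <- logical(nrow(peaks1)); used2 <- logical(nrow(peaks2))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (!used1[i] && !used2[j]) {
      keep[r] <- TRUE; used1[i] <- TRUE; used2[j] <- TRUE
    }
  }
  pairs <- cand[keep, , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, unmatched1 = which(!used1), unmatched2 = which(!used2))
}

# all overlapping index pairs between two interval sets (per chromosome
# sweep; intervals are 0-based half-open)
overlap_pairs <- function(a, b) {
  res <- list()
  for (chrom in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == chrom)
    ib <- which(b$chrom == chrom)
    ia <- ia[order(a$start[ia])]
    ib <- ib[order(b$start[ib])]
    # two-pointer sweep
    out_i <- integer(0); out_j <- integer(0); out_ov <- numeric(0)
    jlo <- 1
    for (ii in ia) {
      while (jlo <= length(ib) && b$end[ib[jlo]] <= a$start[ii]) jlo <- jlo + 1
      jj <- jlo
      while (jj <= length(ib) && b$start[ib[jj]] < a$end[ii]) {
        ov <- min(a$end[ii], b$end[ib[jj]]) - max(a$start[ii], b$start[ib[jj]])
        if (ov > 0) {
          out_i <- c(out_i, ii); out_j <- c(out_j, ib[jj])
          out_ov <- c(out_ov, ov)
        }
        jj <- jj + 1
      }
    }
    res[[chrom]] <- data.frame(i = out_i, j = out_j, overlap = out_ov)
  }
  if (!length(res)) return(data.frame(i = integer(), j = integer(),
                                      overlap = numeric()))
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

# mixture marginal CDF G(z) = pi * Phi((z-mu)/sigma) + (1-pi) * Phi(z),
# inverted on a grid to map empirical quantiles to pseudo-values
pseudo_values <- function(u, p) {
  lo <- min(qnorm(min(u)), p["mu"] + p["sigma"] * qnorm(min(u))) - 1
  hi <- max(qnorm(max(u)), p["mu"] + p["sigma"] * qnorm(max(u))) + 1
  grid <- seq(lo, hi, length.out = 4096)
  G <- p["pi"] * pnorm(grid, p["mu"], p["sigma"]) +
    (1 - p["pi"]) * pnorm(grid)
  approx(G, grid, xout = u, rule = 2, ties = "ordered")$y
}

# log bivariate normal density with common mean/sd and correlation rho
log_dbvn <- function(z1, z2, mu, sigma, rho) {
  d1 <- (z1 - mu) / sigma
  d2 <- (z2 - mu) / sigma
  -log(2 * pi * sigma^2 * sqrt(1 - rho^2)) -
    (d1^2 - 2 * rho * d1 * d2 + d2^2) / (2 * (1 - rho^2))
}

#' Fit the IDR copula mixture to paired peak scores
#'
#' Scores are rank-transformed and mapped through the inverse mixture
#' marginal CDF to pseudo-values `z`.  The pair (z1, z2) is modelled as a
#' two-component mixture: with probability `pi` the pair is reproducible
#' and bivariate normal with mean (mu, mu), sd sigma, correlation rho;
#' otherwise it is irreproducible, independent standard normal.  Parameters
#' are estimated by EM.  The local idr of a pair is its posterior
#' probability of the irreproducible component; the global IDR at rank i is
#' the running mean of the i smallest local idrs.
#'
#' @param scores1,scores2 paired scores (higher = stronger peak), e.g. the
#'   `score1`/`score2` columns of [match_peaks].
#' @param config an [idr_config].
#' @return an `idr_fit` list: `pi`, `mu`, `sigma`, `rho`, `local_idr`,
#'   `global_idr` (both in input order), `loglik`, `lrt` (copula
#'   likelihood-ratio statistic against independence), `degenerate` (TRUE
#'   when the data show no reproducible component, in which case pi = 0
#'   and all local idrs are 1), `converged`, `n_iter`.
#' @export
fit_idr <- function(scores1, scores2, config = idr_config()) {
  n <- length(scores1)
  stopifnot(length(scores2) == n)
  if (n < config$min_pairs)
    stop("need >= ", config$min_pairs,
         " matched pairs to fit the IDR model; got ", n,
         " (provide deeper libraries or more lenient matching)")
  # mid-ranks -> uniform quantiles in (0,1)
  u1 <- (rank(scores1, ties.method = "average") - 0.5) / n
  u2 <- (rank(scores2, ties.method = "average") - 0.5) / n

  # The EM surface has well-known bad local optima (a collapsed tiny-sigma
  # component swallowing the top ranks, or the rho -> 0 ridge), so the fit
  # is run from several starts and the best is selected by the copula
  # likelihood-ratio statistic against independence, which is comparable
  # across fits (the independence model scores exactly 0 on any ranks).
  starts <- list(config$init,
                 c(pi = 0.9, mu = 1.5, sigma = 0.8, rho = 0.8),
                 c(pi = 0.2, mu = 3, sigma = 1, rho = 0.3))
  best <- NULL
  for (p0 in starts) {
    cand <- idr_em_run(u1, u2, p0, config)
    if (is.null(best) || cand$lrt > best$lrt) best <- cand
  }
  p <- best$p
  e <- best$e
  iter <- best$iter
  converged <- best$converged
  ll_old <- best$loglik
  lrt <- best$lrt
  # Degeneracy guard.  When the data carry no reproducible component the
  # EM drifts onto an identifiability ridge (rho -> 0, the two components
  # merge, pi arbitrary).  The fitted copula is then indistinguishable
  # from independence: 2 * sum(log c(u1, u2)) ~ chi-square(4) under
  # independence.  Below the 99% quantile the fit is declared signal-free:
  # pi = 0 and every pair is irreproducible.
  degenerate <- lrt < stats::qchisq(0.99, df = 4)
  if (degenerate) {
    p["pi"] <- 0
    e <- rep(0, n)
    converged <- TRUE
  }
  if (!converged)
    warning("IDR EM did not converge in ", iter,
            " iterations; returning best estimate")
  local_idr <- 1 - e
  ord <- order(local_idr)
  global_sorted <- cumsum(local_idr[ord]) / seq_len(n)
  global_idr <- numeric(n)
  global_idr[ord] <- global_sorted
  structure(list(pi = unname(p["pi"]), mu = unname(p["mu"]),
                 sigma = unname(p["sigma"]), rho = unname(p["rho"]),
                 local_idr = local_idr, global_idr = global_idr,
                 loglik = ll_old, lrt = unname(lrt),
                 degenerate = unname(degenerate),
                 converged = converged, n_iter = iter),
            class = "idr_fit")
}

# one EM run of the copula mixture from a given start.  Outer loop
# refreshes pseudo-values from the current marginal mixture, inner loop is
# a proper monotone EM with the pseudo-values held fixed; stops when the
# parameters stabilize across outer refreshes.
idr_em_run <- function(u1, u2, p, config) {
  n <- length(u1)
  converged <- FALSE
  iter <- 0
  ll_out <- NA_real_
  e <- rep(p["pi"], n)
  for (outer in seq_len(100)) {
    z1 <- pseudo_values(u1, p)
    z2 <- pseudo_values(u2, p)
    p_prev <- p
    ll_old <- -Inf
    while (iter < config$max_iter) {
      iter <- iter + 1
      l_rep <- log(p["pi"]) + log_dbvn(z1, z2, p["mu"], p["sigma"], p["rho"])
      l_null <- log(1 - p["pi"]) + dnorm(z1, log = TRUE) +
        dnorm(z2, log = TRUE)
      m <- pmax(l_rep, l_null)
      ll <- sum(m + log(exp(l_rep - m) + exp(l_null - m)))
      e <- 1 / (1 + exp(l_null - l_rep))
      # M-step: weighted moments of the reproducible component; the
      # variance floor (sigma >= 0.1) blocks point-mass collapse
      se <- sum(e)
      if (se < 1e-8) { p["pi"] <- 1e-6; break }
      mu <- sum(e * (z1 + z2)) / (2 * se)
      s2 <- sum(e * ((z1 - mu)^2 + (z2 - mu)^2)) / (2 * se)
      rho <- sum(e * (z1 - mu) * (z2 - mu)) / (se * s2)
      p["pi"] <- min(1 - 1e-6, max(1e-6, se / n))
      p["mu"] <- mu
      p["sigma"] <- sqrt(max(s2, 0.01))
      p["rho"] <- min(0.999, max(0, rho))
      if (is.finite(ll) && abs(ll - ll_old) < config$em_tol * abs(ll_old))
        break
      ll_old <- ll
    }
    ll_out <- ll_old
    # pseudo-value refreshes perturb the parameters at O(1/sqrt(n)) scale
    # indefinitely; 5e-3 is below the sampling error of the estimates
    if (max(abs(p - p_prev)) < 5e-3) { converged <- TRUE; break }
    if (iter >= config$max_iter) break
  }
  # copula log-likelihood-ratio vs independence at the final parameters
  z1 <- pseudo_values(u1, p)
  z2 <- pseudo_values(u2, p)
  l_rep <- log(p["pi"]) + log_dbvn(z1, z2, p["mu"], p["sigma"], p["rho"])
  l_null <- log(1 - p["pi"]) + dnorm(z1, log = TRUE) + dnorm(z2, log = TRUE)
  m <- pmax(l_rep, l_null)
  l_joint <- m + log(exp(l_rep - m) + exp(l_null - m))
  lg1 <- log(p["pi"] * dnorm(z1, p["mu"], p["sigma"]) +
               (1 - p["pi"]) * dnorm(z1))
  lg2 <- log(p["pi"] * dnorm(z2, p["mu"], p["sigma"]) +
               (1 - p["pi"]) * dnorm(z2))
  lrt <- unname(2 * sum(l_joint - lg1 - lg2))
  list(p = p, e = e, iter = iter, converged = converged,
       loglik = ll_out, lrt = lrt)
}

# run one IDR stage on two peak sets; returns the count passing `cutoff`
# and the fit (NULL when too few pairs)
idr_stage <- function(peaks1, peaks2, cutoff, config) {
  mp <- suppressWarnings(match_peaks(peaks1, peaks2))
  if (nrow(mp$pairs) < config$min_pairs)
    return(list(n_pass = NA_integer_, fit = NULL,
                n_pairs = nrow(mp$pairs), skipped = TRUE))
  fit <- suppressWarnings(fit_idr(mp$pairs$score1, mp$pairs$score2, config))
  list(n_pass = sum(fit$global_idr <= cutoff), fit = fit,
       n_pairs = nrow(mp$pairs), skipped = FALSE)
}

#' Select consistent peaks across replicates (ENCODE-style IDR procedure)
#'
#' Runs three IDR analyses: (1) true replicates against each other at
#' `cutoff_true_reps`, giving N_t; (2) self-pseudo-replicates of each
#' replicate at `cutoff_self_pseudo`, giving per-replicate counts whose
#' minimum is N_s; (3) pooled pseudo-replicates at `cutoff_pooled_pseudo`,
#' giving N_p.  The optimal final set is the top `max(N_t, N_p)` pooled
#' peaks by score; `conservative = TRUE` gives the top N_t instead.
#'
#' @param rep_peaks list of two peak data.frames (true replicates).
#' @param pooled_peaks peaks called on the pooled tags.
#' @param rep_tags list of two tag data.frames (deduplicated), parallel to
#'   `rep_peaks`; used to build pseudo-replicates.
#' @param chrom_sizes [chrom_sizes].
#' @param peak_config [peak_call_config] used for pseudo-replicate calls.
#' @param config an [idr_config].
#' @param seed integer seed for the pseudo-replicate splits.
#' @param conservative use N_t instead of max(N_t, N_p) (default FALSE).
#' @return list with `peaks` (final consistent set), `report` (data.frame
#'   of stage counts), `n_t`, `n_s`, `n_p`, `rescue_ratio`,
#'   `self_consistency_ratio`, `flags` (character vector of warnings such
#'   as replicate imbalance).
#' @export
consistent_peaks <- function(rep_peaks, pooled_peaks, rep_tags, chrom_sizes,
                             peak_config = peak_call_config(),
                             config = idr_config(), seed = 1,
                             conservative = FALSE) {
  stopifnot(length(rep_peaks) >= 2, length(rep_tags) == length(rep_peaks))
  if (length(rep_peaks) > 2)
    stop("only 2 true replicates are supported")
  flags <- character()

  true_stage <- idr_stage(rep_peaks[[1]], rep_peaks[[2]],
                          config$cutoff_true_reps, config)
  if (true_stage$skipped) flags <- c(flags, "true-replicate stage skipped")

  self_counts <- integer(length(rep_tags))
  for (r in seq_along(rep_tags)) {
    halves <- split_pseudoreplicates(rep_tags[[r]], seed = seed + r)
    pk_a <- call_peaks(halves$a, chrom_sizes, peak_config)
    pk_b <- call_peaks(halves$b, chrom_sizes, peak_config)
    st <- idr_stage(pk_a, pk_b, config$cutoff_self_pseudo, config)
    if (st$skipped) {
      flags <- c(flags, sprintf("self-pseudo stage skipped for replicate %d", r))
      self_counts[r] <- NA_integer_
    } else self_counts[r] <- st$n_pass
  }

  pooled_tags <- do.call(rbind, rep_tags)
  halves <- split_pseudoreplicates(pooled_tags, seed = seed + 100)
  pk_a <- call_peaks(halves$a, chrom_sizes, peak_config)
  pk_b <- call_peaks(halves$b, chrom_sizes, peak_config)
  pooled_stage <- idr_stage(pk_a, pk_b, config$cutoff_pooled_pseudo, config)
  if (pooled_stage$skipped) flags <- c(flags, "pooled-pseudo stage skipped")

  n_t <- true_stage$n_pass
  n_p <- pooled_stage$n_pass
  n_s <- if (all(is.na(self_counts))) NA_integer_
         else min(self_counts, na.rm = TRUE)
  rescue <- if (!is.na(n_t) && !is.na(n_p) && n_t > 0) n_p / n_t else NA_real_
  selfc <- if (!anyNA(self_counts) && min(self_counts) > 0)
    max(self_counts) / min(self_counts) else NA_real_
  if (!is.na(rescue) && (rescue > 2 || rescue < 0.5))
    flags <- c(flags, "rescue ratio outside [0.5, 2]: replicate imbalance")
  if (!is.na(selfc) && selfc > 2)
    flags <- c(flags, "self-consistency ratio > 2: replicate imbalance")

  n_final <- if (conservative) n_t else max(n_t, n_p, na.rm = TRUE)
  if (is.na(n_final) || n_final < 0) n_final <- 0
  n_final <- min(n_final, nrow(pooled_peaks))
  ord <- order(-pooled_peaks$pvalue, -pooled_peaks$signal)
  final <- pooled_peaks[ord[seq_len(n_final)], , drop = FALSE]
  final <- final[order(final$chrom, final$start), , drop = FALSE]
  rownames(final) <- NULL

  report <- data.frame(
    stage = c("true_reps", paste0("self_pseudo_rep", seq_along(self_counts)),
              "pooled_pseudo"),
    cutoff = c(config$cutoff_true_reps,
               rep(config$cutoff_self_pseudo, length(self_counts)),
               config$cutoff_pooled_pseudo),
    n_pass = c(n_t, self_counts, n_p), stringsAsFactors = FALSE)
  list(peaks = final, report = report, n_t = n_t, n_s = n_s, n_p = n_p,
       rescue_ratio = rescue, self_consistency_ratio = selfc, flags = flags)
}
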