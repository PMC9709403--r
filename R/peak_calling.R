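# Native Poisson local-background peak caller.  Per-base cut-site pileup is
# scored against a local Poisson rate (max of a sliding-window mean and the
# genome-wide rate), p-values are BH-corrected over all tested positions,
# and significant positions are merged into peaks.

#' Peak-calling configuration
#'
#' @param pileup a [pileup_config]; SPMR is ignored here (the caller always
#'   scores raw counts).
#' @param local_window width in bp of the sliding local-background window
#'   (default 10000).  The local rate at a position is the window mean of
#'   the pileup, floored at the genome-wide rate.
#' @param qvalue_cutoff BH q-value threshold for significant positions
#'   (default 0.05).
#' @param min_length minimum peak length in bp; defaults to the pileup
#'   extension size (a peak narrower than one smoothing window is noise).
#' @param merge_gap significant runs closer than this many bp are merged
#'   (default 30).
#' @return a `peak_call_config` list.
#' @export
peak_call_config <- function(pileup = pileup_config(spmr = FALSE),
                             local_window = 10000, qvalue_cutoff = 0.05,
                             min_length = NULL, merge_gap = 30) {
  stopifnot(local_window > pileup$extsize,
            qvalue_cutoff > 0, qvalue_cutoff < 1, merge_gap >= 0)
  if (is.null(min_length)) min_length <- pileup$extsize
  structure(list(pileup = pileup, local_window = local_window,
                 qvalue_cutoff = qvalue_cutoff, min_length = min_length,
                 merge_gap = merge_gap), class = "peak_call_config")
}

#' Poisson upper-tail probability
#'
#' P(X >= k) for X ~ Poisson(lambda), the significance kernel of the peak
#' caller.  Exact at k = 1 (equals 1 - exp(-lambda)) and stable for large
#' k via R's incomplete-gamma implementation.
#'
#' @param k observed count(s), non-negative.
#' @param lambda Poisson rate(s), > 0.
#' @return P(X >= k) in (0, 1].
#' @export
poisson_tail <- function(k, lambda) {
  if (any(lambda <= 0)) stop("lambda must be > 0")
  if (any(k < 0)) stop("k must be >= 0")
  ppois(k - 1, lambda, lower.tail = FALSE)
}

# centred sliding-window mean with partial windows at chromosome ends
window_mean <- function(v, window) {
  half <- window %/% 2
  n <- length(v)
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Call peaks with a Poisson local-background model
#'
#' Builds the unnormalized cut-site pileup (shift/extsize smoothing), scores
#' every base against `lambda_local = max(lambda_bg, local window mean)`
#' where `lambda_bg = n_tags * extsize / effective nuclear genome length`,
#' converts Poisson upper-tail p-values to q-values by Benjamini-Hochberg
#' over all tested positions, and merges significant positions into peaks
#' (gap <= `merge_gap`), dropping peaks shorter than `min_length`.  The
#' summit is the leftmost pileup maximum; the reported p/q/fold enrichment
#' are taken at the summit.
#'
#' @param tags tag data.frame (deduplicated).
#' @param chrom_sizes [chrom_sizes]; organelle chromosomes are excluded
#'   from calling and from the effective genome length.
#' @param config a [peak_call_config].
#' @return peak data.frame (see [peak_table]) sorted by position, with
#'   `pvalue`/`qvalue` on the -log10 scale and `signal` = fold enrichment
#'   at the summit.
#' @export
call_peaks <- function(tags, chrom_sizes, config = peak_call_config()) {
  nuc <- chrom_sizes[!chrom_sizes$organelle, , drop = FALSE]
  tags <- tags[tags$chrom %in% nuc$chrom, , drop = FALSE]
  if (!nrow(tags)) return(peak_table(character(), numeric(), numeric()))
  pconf <- config$pileup
  pconf$spmr <- FALSE
  track <- pileup(tags, nuc, pconf)
  extsize <- pconf$extsize
  lambda_bg <- nrow(tags) * extsize / nuclear_length(chrom_sizes)

  # per-chromosome per-base scores, then a genome-wide BH correction
  pvals <- vector("list", nrow(nuc))
  lambdas <- vector("list", nrow(nuc))
  for (i in seq_len(nrow(nuc))) {
    v <- track[[i]]
    lam <- pmax(lambda_bg, window_mean(v, config$local_window))
    pvals[[i]] <- poisson_tail(v, lam)
    lambdas[[i]] <- lam
  }
  qvals_all <- p.adjust(unlist(pvals, use.names = FALSE), method = "BH")
  offsets <- cumsum(c(0, nuc$length))

  out <- vector("list", nrow(nuc))
  for (i in seq_len(nrow(nuc))) {
    L <- nuc$length[i]
    q <- qvals_all[(offsets[i] + 1):(offsets[i] + L)]
    sig <- q <= config$qvalue_cutoff
    if (!any(sig)) next
    runs <- rle(sig)
    rend <- cumsum(runs$lengths)
    rstart <- rend - runs$lengths + 1
    s <- rstart[runs$values]
    e <- rend[runs$values]
    # merge runs separated by <= merge_gap
    if (length(s) > 1) {
      merged_s <- c(); merged_e <- c()
      cur_s <- s[1]; cur_e <- e[1]
      for (j in seq_along(s)[-1]) {
        if (s[j] - cur_e - 1 <= config$merge_gap) {
          cur_e <- e[j]
        } else {
          merged_s <- c(merged_s, cur_s); merged_e <- c(merged_e, cur_e)
          cur_s <- s[j]; cur_e <- e[j]
        }
      }
      merged_s <- c(merged_s, cur_s); merged_e <- c(merged_e, cur_e)
      s <- merged_s; e <- merged_e
    }
    w <- e - s + 1
    keep <- w >= config$min_length
    s <- s[keep]; e <- e[keep]
    if (!length(s)) next
    v <- track[[i]]
    lam <- lambdas[[i]]
    p <- pvals[[i]]
    summit <- integer(length(s))
    for (j in seq_along(s)) {
      seg <- v[s[j]:e[j]]
      summit[j] <- s[j] + which.max(seg) - 1   # leftmost maximum
    }
    out[[i]] <- data.frame(
      chrom = nuc$chrom[i], start = s - 1, end = e,
      signal = v[summit] / lam[summit],
      pvalue = -log10(pmax(p[summit], .Machine$double.xmin)),
      qvalue = -log10(pmax(q[summit], .Machine$double.xmin)),
      summit = summit - s, pile = v[summit],
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(peak_table(character(), numeric(), numeric()))
  df <- do.call(rbind, out)
  peak_table(df$chrom, df$start, df$end,
             name = paste0("peak_", seq_len(nrow(df))),
             score = pmin(1000, round(10 * df$qvalue)),
             signal = df$signal, pvalue = df$pvalue, qvalue = df$qvalue,
             summit = df$summit)
}
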