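# Sequencing-saturation analysis: subsample the library over a fraction
# grid, call peaks at each depth, fit a saturating (Michaelis-Menten)
# curve, extrapolate to virtual depths, and locate the depth where the
# marginal gain in called peaks drops below a threshold.

#' Random subsample of a tag library
#'
#' Binomial thinning: each tag is kept independently with probability
#' `fraction` (O(1) memory, streaming-friendly).  With `exact = TRUE` an
#' exact `round(n * fraction)`-sized sample without replacement is drawn
#' instead.
#'
#' @param tags tag data.frame.
#' @param fraction keep probability in (0, 1].
#' @param seed integer seed; deterministic given the seed.
#' @param exact draw an exact-size sample (default FALSE).
#' @return subsampled tag data.frame (file order preserved).
#' @export
subsample_tags <- function(tags, fraction, seed, exact = FALSE) {
  if (fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  if (fraction == 1) return(tags)
  n <- nrow(tags)
  keep <- with_seed(seed, if (exact) {
    sort(sample.int(n, round(n * fraction)))
  } else {
    which(runif(n) < fraction)
  })
  tags[keep, , drop = FALSE]
}

#' Fit a saturating peak-count curve
#'
#' Fits `N(f) = Vmax * f / (K + f)` (Michaelis-Menten) to observed peak
#' counts by least squares, with a robust fallback for degenerate
#' (near-constant) counts.
#'
#' @param fractions observed depth fractions.
#' @param counts observed peak counts at those fractions.
#' @return list with `vmax`, `k`, `fitted` function(f), `ok` (FALSE when
#'   even the fallback failed).
#' @export
fit_saturation <- function(fractions, counts) {
  stopifnot(length(fractions) == length(counts), length(counts) >= 3)
  df <- data.frame(f = fractions, n = counts)
  vmax0 <- max(counts) * 1.2 + 1
  k0 <- 0.3
  fit <- tryCatch(
    nls(n ~ vmax * f / (k + f), data = df,
        start = list(vmax = vmax0, k = k0),
        control = list(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- coef(fit)
    vmax <- unname(cf["vmax"]); k <- unname(cf["k"])
  } else {
    # fallback: direct search on log-parameters (handles constant counts,
    # where the MM surface is flat in k as k -> 0)
    rss <- function(par) {
      v <- exp(par[1]); kk <- exp(par[2])
      sum((counts - v * fractions / (kk + fractions))^2)
    }
    op <- tryCatch(optim(c(log(vmax0), log(k0)), rss,
                         method = "Nelder-Mead",
                         control = list(maxit = 2000)),
                   error = function(e) NULL)
    if (is.null(op)) return(list(vmax = NA_real_, k = NA_real_,
                                 fitted = NULL, ok = FALSE))
    vmax <- exp(op$par[1]); k <- exp(op$par[2])
  }
  if (!is.finite(vmax) || !is.finite(k) || vmax <= 0 || k < 0)
    return(list(vmax = NA_real_, k = NA_real_, fitted = NULL, ok = FALSE))
  list(vmax = vmax, k = k,
       fitted = function(f) vmax * f / (k + f), ok = TRUE)
}

#' Sequencing-saturation analysis
#'
#' For each observed fraction the library is randomly thinned and peaks are
#' called; the peak counts are fitted with [fit_saturation] and
#' extrapolated over the full grid including the virtual fractions above
#' 1.  The saturation fraction `f*` is the smallest grid fraction where
#' the marginal relative gain `(N(f + step) - N(f)) / N(f)` drops below
#' `gain_threshold`.  When `f*` exceeds 1 the library is flagged as not
#' saturated at the observed depth.
#'
#' @param tags tag data.frame (deduplicated).
#' @param chrom_sizes [chrom_sizes].
#' @param peak_config [peak_call_config].
#' @param fractions observed subsampling grid (default 0.1..1.0).
#' @param virtual_fractions extrapolation grid (default 1.1..2.0).
#' @param seed integer seed for the subsampling.
#' @param gain_threshold marginal-gain cutoff defining saturation
#'   (default 0.01, i.e. < 1% more peaks per extra grid step).
#' @param gigabases_at_full optional sequencing yield (Gb) of the full
#'   library, used to express `f*` in data units.
#' @return a `saturation_curve` list: `fractions`, `counts` (observed),
#'   `grid`, `predicted`, `vmax`, `k`, `f_star`, `saturated_gb` (NA unless
#'   `gigabases_at_full` given), `flag` ("ok", "not saturated at observed
#'   depth", or "fit failed").
#' @export
saturation_analysis <- function(tags, chrom_sizes,
                                peak_config = peak_call_config(),
                                fractions = seq(0.1, 1, by = 0.1),
                                virtual_fractions = seq(1.1, 2, by = 0.1),
                                seed = 1, gain_threshold = 0.01,
                                gigabases_at_full = NULL) {
  stopifnot(all(fractions > 0 & fractions <= 1))
  counts <- vapply(seq_along(fractions), function(i) {
    sub <- subsample_tags(tags, fractions[i], seed = derive_seed(seed, i))
    nrow(call_peaks(sub, chrom_sizes, peak_config))
  }, numeric(1))
  grid <- c(fractions, virtual_fractions)
  fit <- fit_saturation(fractions, counts)
  if (!fit$ok) {
    return(structure(list(fractions = fractions, counts = counts,
                          grid = grid, predicted = rep(NA_real_,
                                                       length(grid)),
                          vmax = NA_real_, k = NA_real_, f_star = NA_real_,
                          saturated_gb = NA_real_, flag = "fit failed"),
                     class = "saturation_curve"))
  }
  predicted <- fit$fitted(grid)
  step <- diff(grid)[1]
  f_star <- NA_real_
  for (i in seq_len(length(grid) - 1)) {
    gain <- (predicted[i + 1] - predicted[i]) / predicted[i]
    if (is.finite(gain) && gain < gain_threshold) { f_star <- grid[i]; break }
  }
  flag <- if (is.na(f_star)) "not saturated within grid"
          else if (f_star > 1) "not saturated at observed depth" else "ok"
  gb <- if (!is.null(gigabases_at_full) && !is.na(f_star))
    f_star * gigabases_at_full else NA_real_
  structure(list(fractions = fractions, counts = counts, grid = grid,
                 predicted = predicted, vmax = fit$vmax, k = fit$k,
                 f_star = f_star, saturated_gb = gb, flag = flag),
            class = "saturation_curve")
}
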