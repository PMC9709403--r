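# Signal-to-noise scores (FRiP, SPOT) and fragment-length diagnostics.

# merge overlapping/adjacent intervals within a data.frame(chrom,start,end)
merge_intervals <- function(df) {
  if (!nrow(df)) return(df[, c("chrom", "start", "end")])
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  out_chrom <- character(); out_s <- numeric(); out_e <- numeric()
  cur_c <- df$chrom[1]; cur_s <- df$start[1]; cur_e <- df$end[1]
  for (i in seq_len(nrow(df))[-1]) {
    if (df$chrom[i] == cur_c && df$start[i] <= cur_e) {
      cur_e <- max(cur_e, df$end[i])
    } else {
      out_chrom <- c(out_chrom, cur_c); out_s <- c(out_s, cur_s)
      out_e <- c(out_e, cur_e)
      cur_c <- df$chrom[i]; cur_s <- df$start[i]; cur_e <- df$end[i]
    }
  }
  data.frame(chrom = c(out_chrom, cur_c), start = c(out_s, cur_s),
             end = c(out_e, cur_e), stringsAsFactors = FALSE)
}

# which positions (chrom, pos) fall inside any interval of df
points_in_intervals <- function(chrom, pos, df) {
  hit <- logical(length(chrom))
  for (cc in unique(df$chrom)) {
    iv <- df[df$chrom == cc, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    sel <- which(chrom == cc)
    if (!length(sel)) next
    # findInterval on sorted starts; inside iff pos < end of that interval
    k <- findInterval(pos[sel], iv$start)
    inside <- k >= 1 & pos[sel] < iv$end[pmax(k, 1)]
    hit[sel] <- inside
  }
  hit
}

#' Fraction of reads in peaks (FRiP)
#'
#' The fraction of tag cut sites falling inside the (merged) peak regions.
#' With `mode = "overlap"` a tag counts when its full interval overlaps a
#' peak instead.
#'
#' @param tags tag data.frame.
#' @param peaks peak data.frame; overlapping peaks are merged first so
#'   FRiP is invariant to how a region is split into abutting peaks.
#' @param mode "cut" (default, ENCODE-style read counting on the cut site)
#'   or "overlap".
#' @return fraction in \[0, 1\]; NA for an empty library.
#' @export
frip <- function(tags, peaks, mode = c("cut", "overlap")) {
  mode <- match.arg(mode)
  if (!nrow(tags)) return(NA_real_)
  if (!nrow(peaks)) return(0)
  merged <- merge_intervals(peaks)
  if (mode == "cut") {
    mean(points_in_intervals(tags$chrom, cut_site(tags), merged))
  } else {
    hit_s <- points_in_intervals(tags$chrom, tags$start, merged)
    # a tag overlaps a peak iff some peak start lies before its end and
    # the peak end after its start; approximate via both endpoints plus
    # containment of a peak within the tag
    hit_e <- points_in_intervals(tags$chrom, tags$end - 1, merged)
    contains <- vapply(seq_len(nrow(tags)), function(i) {
      iv <- merged[merged$chrom == tags$chrom[i], , drop = FALSE]
      any(iv$start >= tags$start[i] & iv$end <= tags$end[i])
    }, logical(1))
    mean(hit_s | hit_e | contains)
  }
}

#' SPOT configuration
#' @param window_bp hotspot window width (default 250).
#' @param background_bp local background window width (default 50000).
#' @param z_threshold z-score above which a window is a hotspot
#'   (default 2).
#' @return a `spot_config` list.
#' @export
spot_config <- function(window_bp = 250, background_bp = 50000,
                        z_threshold = 2) {
  stopifnot(background_bp > window_bp, window_bp > 0)
  structure(list(window_bp = window_bp, background_bp = background_bp,
                 z_threshold = z_threshold), class = "spot_config")
}

#' Signal portion of tags (SPOT)
#'
#' Tiles the nuclear genome into `window_bp` windows and tests each
#' window's tag count against a binomial local-background expectation: of
#' the tags in the surrounding `background_bp` window, each falls into the
#' focal window with probability w/W, so
#' `z = (obs - exp) / sqrt(exp * (1 - w/W))`.  Windows with
#' `z >= z_threshold` are merged into hotspots; SPOT is the fraction of
#' all tags whose cut site lies in a hotspot.  The local background
#' auto-corrects for broad-scale regional coverage differences.
#'
#' @param tags tag data.frame (deduplicated).
#' @param chrom_sizes [chrom_sizes].
#' @param config a [spot_config].
#' @return fraction in \[0, 1\]; NA for an empty library.
#' @export
spot <- function(tags, chrom_sizes, config = spot_config()) {
  if (!nrow(tags)) return(NA_real_)
  nuc <- chrom_sizes[!chrom_sizes$organelle, , drop = FALSE]
  w <- config$window_bp
  ratio_bins <- config$background_bp %/% w
  in_hot <- 0
  total <- nrow(tags)
  cut <- cut_site(tags)
  for (i in seq_len(nrow(nuc))) {
    sel <- tags$chrom == nuc$chrom[i]
    if (!any(sel)) next
    L <- nuc$length[i]
    nbin <- ceiling(L / w)
    bin <- pmin(cut[sel] %/% w + 1, nbin)
    obs <- tabulate(bin, nbins = nbin)
    # local background: running sum over the surrounding ratio_bins bins
    half <- ratio_bins %/% 2
    cs <- c(0, cumsum(obs))
    lo <- pmax(seq_len(nbin) - half, 1)
    hi <- pmin(seq_len(nbin) + half, nbin)
    local_tags <- cs[hi + 1] - cs[lo]
    p <- 1 / (hi - lo + 1)
    expd <- local_tags * p
    z <- ifelse(expd > 0, (obs - expd) / sqrt(expd * (1 - p)), 0)
    in_hot <- in_hot + sum(obs[z >= config$z_threshold])
  }
  in_hot / total
}

#' Fragment-length profile
#'
#' Histogram of fragment lengths (1..`max_len` bp) with the
#' nucleosome-band fractions and a periodicity score.  The score is the
#' amplitude of the ~`period_bp` component of the detrended histogram's
#' autocorrelation, clamped to \[0, 1\]: tagmentation of intact chromatin
#' produces fragment-length bands at multiples of the nucleosome repeat
#' (~190 bp), so a high score indicates proper Tn5 digestion.
#'
#' @param fragments fragment data.frame (chrom, start, end).
#' @param max_len histogram upper bound (default 1000; longer fragments
#'   are counted in the top bin).
#' @param nfr_max NFR band upper bound, exclusive (default 100).
#' @param mono_range mono-nucleosome band, inclusive (default c(180, 247)).
#' @param period_bp nucleosome repeat length searched for (default 190,
#'   +/- 40 bp).
#' @return a `fragment_length_profile` list: `histogram` (counts, names =
#'   length), `n`, `nfr_fraction`, `mono_fraction`, `periodicity`,
#'   `low_confidence` (TRUE when n < 100).
#' @export
fragment_length_profile <- function(fragments, max_len = 1000,
                                    nfr_max = 100,
                                    mono_range = c(180, 247),
                                    period_bp = 190) {
  n <- nrow(fragments)
  if (!n) stop("no fragments; profile undefined")
  len <- pmin(fragments$end - fragments$start, max_len)
  stopifnot(all(len > 0))
  h <- tabulate(len, nbins = max_len)
  low_confidence <- n < 100
  if (low_confidence)
    warning("fewer than 100 fragments; periodicity is low-confidence")
  # detrend with a wide moving average, then autocorrelate
  trend <- window_mean(h, 101)
  det <- h - trend
  lag_max <- min(period_bp + 40, max_len - 1)
  ac <- acf(det, lag.max = lag_max, plot = FALSE)$acf[, 1, 1]
  lags <- (period_bp - 40):(period_bp + 40)
  lags <- lags[lags >= 1 & lags <= lag_max]
  periodicity <- max(0, min(1, max(ac[lags + 1])))
  structure(list(histogram = setNames(h, seq_len(max_len)), n = n,
                 nfr_fraction = mean(len < nfr_max),
                 mono_fraction = mean(len >= mono_range[1] &
                                        len <= mono_range[2]),
                 periodicity = periodicity,
                 low_confidence = low_confidence),
            class = "fragment_length_profile")
}
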