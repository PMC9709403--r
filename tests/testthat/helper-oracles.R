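# Independent oracles and tiny fixture builders shared across the suite.
# Everything here is deliberately written with naive per-element loops and
# closed forms, not with the package's vectorized internals.

# term-by-term Poisson upper tail: P(X >= k) = sum_{j>=k} e^-l l^j / j!
oracle_poisson_tail <- function(k, lambda) {
  if (k == 0) return(1)
  j <- k
  total <- 0
  repeat {
    term <- exp(j * log(lambda) - lambda - lgamma(j + 1))
    total <- total + term
    j <- j + 1
    if (term < total * 1e-17 || j > k + 10000) break
    if (total == 0 && j > k + 200) break
  }
  total
}

# hand-rolled Benjamini-Hochberg, mirroring the definition (not p.adjust)
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  q
}

# brute-force per-base Poisson scan peak caller on a single-chromosome toy
# genome; per-position pileup and window means computed by direct counting
oracle_call_peaks <- function(tags, chrom_sizes, config) {
  stopifnot(nrow(chrom_sizes) == 1)
  L <- chrom_sizes$length[1]
  shift <- config$pileup$shift
  extsize <- config$pileup$extsize
  cut <- ifelse(tags$strand == "+", tags$start, tags$end - 1)
  ws <- ifelse(tags$strand == "+", cut + shift, cut - shift - extsize + 1)
  we <- ws + extsize
  pile <- vapply(0:(L - 1), function(pos) sum(ws <= pos & pos < we),
                 numeric(1))
  lambda_bg <- nrow(tags) * extsize / L
  half <- config$local_window %/% 2
  lam <- vapply(seq_len(L), function(i) {
    lo <- max(1, i - half); hi <- min(L, i + half)
    max(lambda_bg, mean(pile[lo:hi]))
  }, numeric(1))
  p <- vapply(seq_len(L), function(i) oracle_poisson_tail(pile[i], lam[i]),
              numeric(1))
  q <- oracle_bh(p)
  sig <- q <= config$qvalue_cutoff
  # collect significant runs by position scan
  runs <- list(); cur <- NULL
  for (i in seq_len(L)) {
    if (sig[i]) {
      if (is.null(cur)) cur <- c(i, i) else cur[2] <- i
    } else if (!is.null(cur)) {
      runs[[length(runs) + 1]] <- cur; cur <- NULL
    }
  }
  if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
  if (!length(runs)) {
    return(data.frame(start = numeric(), end = numeric(),
                      summit_pos = numeric(), pvalue = numeric(),
                      qvalue = numeric()))
  }
  # merge runs separated by <= merge_gap
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- merged[[length(merged)]]
    if (r[1] - last[2] - 1 <= config$merge_gap) {
      merged[[length(merged)]][2] <- r[2]
    } else merged[[length(merged) + 1]] <- r
  }
  out <- NULL
  for (r in merged) {
    if (r[2] - r[1] + 1 < config$min_length) next
    seg <- pile[r[1]:r[2]]
    smt <- r[1] + which(seg == max(seg))[1] - 1
    out <- rbind(out, data.frame(
      start = r[1] - 1, end = r[2], summit_pos = smt - 1,
      pvalue = -log10(max(p[smt], .Machine$double.xmin)),
      qvalue = -log10(max(q[smt], .Machine$double.xmin))))
  }
  if (is.null(out))
    out <- data.frame(start = numeric(), end = numeric(),
                      summit_pos = numeric(), pvalue = numeric(),
                      qvalue = numeric())
  out
}

# random toy instance for the caller oracle: one chromosome, uniform
# background plus enriched windows
make_toy_instance <- function(seed) {
  set.seed(seed)
  L <- sample(5000:15000, 1)
  cs <- chrom_sizes(setNames(L, "toy"))
  n_bg <- sample(200:500, 1)
  n_windows <- sample(1:3, 1)
  pos <- floor(runif(n_bg, 0, L - 1))
  strand <- sample(c("+", "-"), n_bg, replace = TRUE)
  for (w in seq_len(n_windows)) {
    wlen <- sample(200:400, 1)
    wstart <- sample(0:(L - wlen - 1), 1)
    n_in <- sample(60:150, 1)
    pos <- c(pos, floor(runif(n_in, wstart, wstart + wlen)))
    strand <- c(strand, sample(c("+", "-"), n_in, replace = TRUE))
  }
  start <- ifelse(strand == "+", pos, pmax(0, pos - 49))
  end <- ifelse(strand == "+", pmin(L, pos + 50), pos + 1)
  start <- pmax(0, start); end <- pmin(L, pmax(end, start + 1))
  tags <- tag_table("toy", start, end, strand, 60)
  list(tags = tags, chrom_sizes = cs)
}

# small deterministic gene table on one 100 kb chromosome
make_test_genes <- function() {
  data.frame(
    gene_id = c("gA", "gB"), chrom = c("chr1", "chr1"),
    start = c(20000, 60000), end = c(26000, 68000),
    strand = c("+", "-"),
    tss = c(20000, 67999), tes = c(25999, 60000),
    stringsAsFactors = FALSE)
}

uniform_track <- function(value, lengths) {
  structure(lapply(lengths, function(L) rep(value, L)),
            n_tags = NA_integer_, spmr = FALSE, extsize = 150,
            class = "coverage_track")
}
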