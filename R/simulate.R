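# Ground-truth synthetic ATAC-seq libraries.  The generator emulates the
# statistical structure the pipeline assumes — nucleosome-periodic fragment
# lengths, promoter-enriched cut density, organelle contamination, PCR
# duplicates — with every quantity known, so recovery can be asserted.
# A "world" (genome, genes, truth peaks) is generated separately from the
# tag noise, so independent replicates over the same truth are available.

#' Simulation configuration
#'
#' Defaults describe a desk-scale wheat-like world: two 2 Mb nuclear
#' chromosomes plus a 100 kb mitochondrial contig, 200 genes, one truth
#' peak per promoter, 40% of nuclear cut sites inside truth peaks, 200,000
#' fragments, a three-band nucleosomal fragment-length mixture
#' (NFR N(75,15), mono N(265,20), di N(460,25); weights .55/.35/.10,
#' truncated to \[20, 1000\]), 10% PCR duplicates and 5% organelle
#' contamination (the contamination level of a well-prepared wheat
#' library).
#'
#' @param seed integer master seed; all randomness derives from it.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param organelle_regex regex flagging organelle chromosomes by name.
#' @param n_genes number of genes, split evenly across nuclear
#'   chromosomes.
#' @param gene_length_range uniform range of gene lengths in bp.
#' @param n_distal_peaks truth peaks outside promoter windows (default 0:
#'   the default truth-peak count equals `n_genes`).
#' @param peak_width truth peak width in bp.
#' @param alpha fraction of non-organelle cut sites inside truth peaks.
#' @param n_fragments total fragments including duplicates.
#' @param frag_means,frag_sds,frag_weights fragment-length mixture.
#' @param len_range truncation range of fragment lengths.
#' @param dup_rate PCR duplicate rate d.
#' @param contamination organelle contamination rate c.
#' @param peak_intensity_sdlog sd (log scale) of per-peak lognormal
#'   intensity weights; 1 spreads peak strengths over roughly two orders
#'   of magnitude, as observed in real accessibility data.
#' @param read_length mate length used for tags/BEDPE.
#' @param mapq_low_rate fraction of tags given MAPQ below 5.
#' @param expr_gamma,expr_sd log-expression model: TPM =
#'   exp(gamma * has-promoter-peak + N(0, expr_sd)).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 42,
                       chrom_lengths = c(chr1A = 2e6, chr2A = 2e6,
                                         chrMt = 1e5),
                       organelle_regex = "Mt|Pt",
                       n_genes = 200, gene_length_range = c(1500, 4000),
                       n_distal_peaks = 0, peak_width = 300,
                       alpha = 0.4, n_fragments = 200000,
                       frag_means = c(75, 265, 460),
                       frag_sds = c(15, 20, 25),
                       frag_weights = c(0.55, 0.35, 0.10),
                       len_range = c(20, 1000),
                       dup_rate = 0.1, contamination = 0.05,
                       peak_intensity_sdlog = 1,
                       read_length = 50, mapq_low_rate = 0.02,
                       expr_gamma = 1.5, expr_sd = 1) {
  stopifnot(alpha >= 0, alpha <= 1, dup_rate >= 0, dup_rate < 1,
            contamination >= 0, contamination <= 1,
            abs(sum(frag_weights) - 1) < 1e-9, n_fragments > 0,
            peak_width > 0, n_genes >= 0, n_distal_peaks >= 0)
  structure(as.list(environment()), class = "sim_config")
}

# truncated mixture draw of fragment lengths
sim_fragment_lengths <- function(n, config) {
  comp <- sample.int(length(config$frag_weights), n, replace = TRUE,
                     prob = config$frag_weights)
  len <- rnorm(n, config$frag_means[comp], config$frag_sds[comp])
  bad <- len < config$len_range[1] | len > config$len_range[2]
  while (any(bad)) {
    len[bad] <- rnorm(sum(bad), config$frag_means[comp[bad]],
                      config$frag_sds[comp[bad]])
    bad <- len < config$len_range[1] | len > config$len_range[2]
  }
  round(len)
}

# gene models + truth peaks (call inside with_seed)
sim_world <- function(config, cs) {
  nuc <- cs[!cs$organelle, , drop = FALSE]
  genes_per_chr <- table(rep(seq_len(nrow(nuc)),
                             length.out = config$n_genes))
  glist <- list()
  gid <- 0
  for (i in seq_len(nrow(nuc))) {
    ng <- genes_per_chr[as.character(i)]
    ng <- if (is.na(ng)) 0L else as.integer(ng)
    if (!ng) next
    # one gene per slot with jitter: spans stay >= 12 kb apart so promoter
    # windows and truth peaks never collide across neighbours
    slot <- floor((nuc$length[i] - 20000) / ng)
    glen <- round(runif(ng, config$gene_length_range[1],
                        config$gene_length_range[2]))
    jitter <- round(runif(ng, 0, pmax(1, slot - glen - 12000)))
    start <- 10000 + (seq_len(ng) - 1) * slot + jitter
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    gid_new <- gid + seq_len(ng)
    glist[[i]] <- data.frame(
      gene_id = sprintf("gene%04d", gid_new), chrom = nuc$chrom[i],
      start = start, end = start + glen, strand = strand,
      stringsAsFactors = FALSE)
    gid <- gid + ng
  }
  genes <- do.call(rbind, glist)
  rownames(genes) <- NULL
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  genes$tes <- ifelse(genes$strand == "+", genes$end - 1, genes$start)

  w <- config$peak_width
  off <- runif(nrow(genes), -3000, 1000)   # peak centre offset from TSS
  centre <- ifelse(genes$strand == "+", genes$tss + off, genes$tss - off)
  pk_start <- pmax(0, round(centre - w / 2))
  pk_start <- pmin(pk_start, chrom_length(cs, genes$chrom) - w)
  truth <- data.frame(chrom = genes$chrom, start = pk_start,
                      end = pk_start + w, type = "promoter",
                      stringsAsFactors = FALSE)
  if (config$n_distal_peaks > 0) {
    dc <- sample.int(nrow(nuc), config$n_distal_peaks, replace = TRUE)
    ds <- round(runif(config$n_distal_peaks, 0, nuc$length[dc] - w))
    truth <- rbind(truth, data.frame(chrom = nuc$chrom[dc], start = ds,
                                     end = ds + w, type = "distal",
                                     stringsAsFactors = FALSE))
  }
  # peak intensities span ~2 orders of magnitude, as in real chromatin:
  # the resulting strength heterogeneity is what makes replicate score
  # ranks informative for reproducibility analysis
  truth$weight <- rlnorm(nrow(truth), 0, config$peak_intensity_sdlog)
  list(genes = genes, truth_peaks = truth)
}

# fragments, tags and expression over a fixed world (call inside with_seed)
sim_library_draw <- function(world, config, cs) {
  nuc <- cs[!cs$organelle, , drop = FALSE]
  org <- cs[cs$organelle, , drop = FALSE]
  truth <- world$truth_peaks
  genes <- world$genes

  n <- config$n_fragments
  n_orig <- round(n * (1 - config$dup_rate))
  is_org <- runif(n_orig) < config$contamination & nrow(org) > 0
  n_org <- sum(is_org)
  in_peak <- runif(n_orig - n_org) < config$alpha
  len <- sim_fragment_lengths(n_orig, config)

  chrom <- character(n_orig); fstart <- numeric(n_orig)
  if (n_org > 0) {
    oc <- sample.int(nrow(org), n_org, replace = TRUE)
    chrom[is_org] <- org$chrom[oc]
    fstart[is_org] <- floor(runif(n_org, 0, org$length[oc] - 1))
  }
  nuc_idx <- which(!is_org)
  pk_idx <- nuc_idx[in_peak]
  bg_idx <- nuc_idx[!in_peak]
  if (length(pk_idx)) {
    pp <- sample.int(nrow(truth), length(pk_idx), replace = TRUE,
                     prob = truth$weight)
    chrom[pk_idx] <- truth$chrom[pp]
    fstart[pk_idx] <- floor(runif(length(pk_idx), truth$start[pp],
                                  truth$end[pp]))
  }
  if (length(bg_idx)) {
    bc <- sample.int(nrow(nuc), length(bg_idx), replace = TRUE,
                     prob = nuc$length)
    chrom[bg_idx] <- nuc$chrom[bc]
    fstart[bg_idx] <- floor(runif(length(bg_idx), 0, nuc$length[bc] - 1))
  }
  L <- chrom_length(cs, chrom)
  fstart <- pmin(fstart, pmax(0, L - len))
  fragments <- data.frame(chrom = chrom, start = fstart,
                          end = pmin(fstart + len, L),
                          stringsAsFactors = FALSE)
  n_dup <- n - n_orig
  if (n_dup > 0) {
    di <- sample.int(n_orig, n_dup, replace = TRUE)
    fragments <- rbind(fragments, fragments[di, , drop = FALSE])
  }
  fragments <- fragments[sample.int(nrow(fragments)), , drop = FALSE]
  rownames(fragments) <- NULL

  rl <- pmin(config$read_length, fragments$end - fragments$start)
  nt <- 2 * nrow(fragments)
  tchrom <- rep(fragments$chrom, 2)
  tstart <- c(fragments$start, fragments$end - rl)
  tend <- c(fragments$start + rl, fragments$end)
  tstrand <- rep(c("+", "-"), each = nrow(fragments))
  mapq <- ifelse(runif(nt) < config$mapq_low_rate,
                 floor(runif(nt, 0, 5)), 60)
  tord <- sample.int(nt)
  tags <- tag_table(tchrom[tord], tstart[tord], tend[tord], tstrand[tord],
                    mapq[tord])

  # promoter truth peaks are generated one per gene, in gene order
  has_pk <- as.numeric(seq_len(nrow(genes)) <= sum(truth$type == "promoter"))
  tpm <- exp(config$expr_gamma * has_pk +
               rnorm(nrow(genes), 0, config$expr_sd))
  expression <- data.frame(gene_id = genes$gene_id, tpm = tpm,
                           stringsAsFactors = FALSE)
  list(fragments = fragments, tags = tags, expression = expression,
       n_unique_fragments = n_orig)
}

#' Simulate a complete ATAC-seq library with known ground truth
#'
#' Generates a genome, gene models, truth peaks (one per promoter plus
#' optional distal peaks), a fragment library with the configured in-peak
#' fraction, duplicate rate and organelle contamination, per-fragment tag
#' pairs, and a gene-expression table coupled to promoter-peak presence.
#' Fully deterministic given `config$seed`.  When `outdir` is given, the
#' standard file set (chrom.sizes, genes.gff3, truth_peaks.bed,
#' fragments.bedpe.gz, tags.tagAlign.gz, expr.tsv) is written there.
#'
#' @param config a [sim_config].
#' @param outdir optional output directory (created if missing).
#' @return list with `chrom_sizes`, `genes`, `truth_peaks` (chrom, start,
#'   end, type), `fragments`, `tags`, `expression`, `paths` (when written)
#'   and `truth` (the generating quantities: alpha, dup_rate,
#'   contamination, n_unique_fragments).
#' @export
simulate_library <- function(config = sim_config(), outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cs <- chrom_sizes(config$chrom_lengths,
                    organelle_regex = config$organelle_regex)
  out <- with_seed(config$seed, {
    world <- sim_world(config, cs)
    c(world, sim_library_draw(world, config, cs))
  })
  res <- list(chrom_sizes = cs, genes = out$genes,
              truth_peaks = out$truth_peaks, fragments = out$fragments,
              tags = out$tags, expression = out$expression,
              truth = list(alpha = config$alpha,
                           dup_rate = config$dup_rate,
                           contamination = config$contamination,
                           n_unique_fragments = out$n_unique_fragments),
              paths = NULL)
  if (!is.null(outdir)) res$paths <- write_sim_files(res, config, outdir)
  res
}

#' Simulate replicate libraries over one shared truth
#'
#' Generates the world (genome, genes, truth peaks) once from
#' `config$seed`, then draws an independent fragment library per entry of
#' `seeds` — the "same truth, different noise" setting used to validate
#' the reproducibility pipeline.
#'
#' @param config a [sim_config].
#' @param seeds integer seeds, one per replicate.
#' @return list with `chrom_sizes`, `genes`, `truth_peaks`, and
#'   `replicates` (a list of per-replicate lists: fragments, tags,
#'   expression).
#' @export
simulate_replicates <- function(config = sim_config(), seeds = c(1, 2)) {
  stopifnot(inherits(config, "sim_config"), length(seeds) >= 1)
  cs <- chrom_sizes(config$chrom_lengths,
                    organelle_regex = config$organelle_regex)
  world <- with_seed(config$seed, sim_world(config, cs))
  reps <- lapply(seeds, function(s)
    with_seed(s, sim_library_draw(world, config, cs)))
  list(chrom_sizes = cs, genes = world$genes,
       truth_peaks = world$truth_peaks, replicates = reps)
}

write_sim_files <- function(res, config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    chrom_sizes = file.path(outdir, "chrom.sizes"),
    genes = file.path(outdir, "genes.gff3"),
    truth_peaks = file.path(outdir, "truth_peaks.bed"),
    fragments = file.path(outdir, "fragments.bedpe.gz"),
    tags = file.path(outdir, "tags.tagAlign.gz"),
    expression = file.path(outdir, "expr.tsv"))
  write_chrom_sizes(res$chrom_sizes, paths$chrom_sizes)
  write_gff3_genes(res$genes, paths$genes)
  con <- open_out(paths$truth_peaks)
  writeLines(paste(res$truth_peaks$chrom, format_int(res$truth_peaks$start),
                   format_int(res$truth_peaks$end), res$truth_peaks$type,
                   sep = "\t"), con)
  close(con)
  write_bedpe_fragments(res$fragments, paths$fragments,
                        read_length = config$read_length)
  write_tagalign(res$tags, paths$tags)
  write.table(res$expression, paths$expression, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths
}

#' Simulate paired scores from the IDR copula mixture
#'
#' Draws `n` score pairs exactly as the [fit_idr] model assumes: with
#' probability `pi` a pair is bivariate normal (mean `mu`, sd `sigma`,
#' correlation `rho`); otherwise independent standard normal.  The latent
#' normals are returned directly as scores (the fit is rank-based, so any
#' monotone transform is equivalent).
#'
#' @param pi reproducible-component weight in \[0, 1\].
#' @param rho reproducible-component correlation in \[0, 1).
#' @param mu,sigma reproducible-component mean and sd.
#' @param n number of pairs.
#' @param seed integer seed.
#' @return data.frame with columns score1, score2, reproducible (logical
#'   ground truth).
#' @export
simulate_idr_scores <- function(pi = 0.7, rho = 0.9, mu = 2.5, sigma = 1,
                                n = 10000, seed = 1) {
  stopifnot(pi >= 0, pi <= 1, rho >= 0, rho < 1, sigma > 0, n > 0)
  with_seed(seed, {
    rep_comp <- runif(n) < pi
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    n1 <- rnorm(n); n2 <- rnorm(n)
    s1 <- ifelse(rep_comp, mu + sigma * z1, n1)
    s2 <- ifelse(rep_comp, mu + sigma * z2, n2)
    data.frame(score1 = s1, score2 = s2, reproducible = rep_comp)
  })
}
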