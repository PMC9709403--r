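# End-to-end orchestration: filtered tags -> pseudo-replicates -> peaks ->
# consistent peak set, plus the consolidated QC report.

fmt6 <- function(x) formatC(x, digits = 6, format = "g")

write_tsv6 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt6)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full open-chromatin pipeline
#'
#' Executes, for each library in the manifest: tag filtering (MAPQ,
#' chromosome membership), duplicate removal with library-complexity
#' metrics, organelle-contamination accounting, fragment-length profiling
#' (when BEDPE is supplied), SPMR signal tracks, TSS enrichment, peak
#' calling, FRiP and SPOT.  With two libraries it then pools tags, calls
#' pooled peaks, and runs the three-stage IDR procedure to produce the
#' final consistent peak set, which is annotated against the gene models.
#' All intermediates and a consolidated QC table are written under
#' `outdir`.
#'
#' @param manifest data.frame with columns `name`, `tags` (tagAlign path)
#'   and optionally `fragments` (BEDPE path); or a named list of tag
#'   data.frames (plus optional `fragments` attribute) for in-memory use.
#' @param genes gene data.frame or GFF3 path.
#' @param chrom_sizes [chrom_sizes] or chrom.sizes path.
#' @param outdir output directory.
#' @param seed integer seed driving pseudo-replication (and saturation).
#' @param filter a [filter_config].
#' @param peak_config a [peak_call_config].
#' @param idr a [idr_config].
#' @param annot an [annotation_config].
#' @param expression optional expression table (data.frame or TSV path)
#'   joined per gene.
#' @param saturate also run saturation analysis per library (roughly 10x
#'   the peak-calling cost; default FALSE).
#' @return list with `qc` (one row per library), `peaks` (per-library),
#'   `final_peaks`, `idr` (the [consistent_peaks] result or NULL),
#'   `correlation`, `annotations`, `gene_report`, `saturation`, `paths`.
#' @export
run_pipeline <- function(manifest, genes, chrom_sizes, outdir, seed = 1,
                         filter = filter_config(),
                         peak_config = peak_call_config(),
                         idr = idr_config(),
                         annot = annotation_config(),
                         expression = NULL, saturate = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(chrom_sizes)) chrom_sizes <- read_chrom_sizes(chrom_sizes)
  if (is.character(genes)) genes <- read_gff3_genes(genes, chrom_sizes)
  if (is.character(expression))
    expression <- read.table(expression, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)

  if (is.data.frame(manifest)) {
    stopifnot(all(c("name", "tags") %in% names(manifest)))
    libs <- lapply(seq_len(nrow(manifest)), function(i) {
      list(name = manifest$name[i],
           tags = read_tagalign(manifest$tags[i], chrom_sizes),
           fragments = if ("fragments" %in% names(manifest) &&
                           !is.na(manifest$fragments[i]) &&
                           nzchar(manifest$fragments[i]))
             read_bedpe_fragments(manifest$fragments[i], chrom_sizes)
           else NULL)
    })
  } else {
    stopifnot(is.list(manifest))
    libs <- manifest
  }
  if (!length(libs)) stop("manifest lists no libraries")

  qc_rows <- list()
  tracks <- list()
  rep_peaks <- list()
  rep_tags <- list()
  sat_curves <- list()
  for (i in seq_along(libs)) {
    lb <- libs[[i]]
    nm <- lb$name
    flt <- filter_tags(lb$tags, filter, chrom_sizes)
    dd <- deduplicate(flt$tags)
    org_frac <- organelle_fraction(dd$tags, chrom_sizes)
    nuc_tags <- dd$tags[!dd$tags$chrom %in%
                          chrom_sizes$chrom[chrom_sizes$organelle], ,
                        drop = FALSE]
    write_tagalign(nuc_tags, file.path(outdir,
                                       paste0(nm, ".filtered.tagAlign.gz")))
    track <- pileup(nuc_tags, chrom_sizes[!chrom_sizes$organelle, ,
                                          drop = FALSE],
                    pileup_config(spmr = TRUE))
    write_bedgraph(track, file.path(outdir, paste0(nm, ".spmr.bedGraph.gz")))
    tracks[[nm]] <- track
    pk <- call_peaks(nuc_tags, chrom_sizes, peak_config)
    write_narrowpeak(pk, file.path(outdir, paste0(nm, ".narrowPeak")))
    tsse <- tryCatch(tss_enrichment(track, genes), warning = function(w) NA_real_)
    fl <- if (!is.null(lb$fragments) && nrow(lb$fragments))
      suppressWarnings(fragment_length_profile(lb$fragments)) else NULL
    qc_rows[[i]] <- data.frame(
      library = nm,
      input_tags = unname(flt$stats["input"]),
      kept_tags = unname(flt$stats["kept"]),
      unique_tags = nrow(dd$tags),
      NRF = unname(dd$complexity["NRF"]),
      PBC1 = unname(dd$complexity["PBC1"]),
      PBC2 = unname(dd$complexity["PBC2"]),
      organelle_fraction = org_frac,
      n_peaks = nrow(pk),
      frip = frip(nuc_tags, pk),
      spot = spot(nuc_tags, chrom_sizes),
      tss_enrichment = tsse,
      nfr_fraction = if (is.null(fl)) NA_real_ else fl$nfr_fraction,
      mono_fraction = if (is.null(fl)) NA_real_ else fl$mono_fraction,
      periodicity = if (is.null(fl)) NA_real_ else fl$periodicity,
      stringsAsFactors = FALSE)
    rep_peaks[[nm]] <- pk
    rep_tags[[nm]] <- nuc_tags
    if (saturate) {
      sat_curves[[nm]] <- saturation_analysis(
        nuc_tags, chrom_sizes, peak_config,
        seed = derive_seed(seed, 7000 + i))
      sat_df <- data.frame(fraction = sat_curves[[nm]]$grid,
                           predicted = sat_curves[[nm]]$predicted)
      sat_df$observed <- c(sat_curves[[nm]]$counts,
                           rep(NA_real_,
                               nrow(sat_df) - length(sat_curves[[nm]]$counts)))
      write_tsv6(sat_df, file.path(outdir, paste0(nm, ".saturation.tsv")))
    }
  }
  qc <- do.call(rbind, qc_rows)

  corr <- NULL
  idr_res <- NULL
  if (length(libs) >= 2) {
    corr <- binned_correlation(tracks)
    if (length(libs) > 2)
      stop("IDR stage supports exactly 2 replicates; got ", length(libs))
    pooled_tags <- do.call(rbind, rep_tags)
    pooled_peaks <- call_peaks(pooled_tags, chrom_sizes, peak_config)
    write_narrowpeak(pooled_peaks, file.path(outdir, "pooled.narrowPeak"))
    idr_res <- consistent_peaks(rep_peaks, pooled_peaks, rep_tags,
                                chrom_sizes, peak_config, idr,
                                seed = derive_seed(seed, 500))
    final <- idr_res$peaks
    write_tsv6(idr_res$report, file.path(outdir, "idr_report.tsv"))
  } else {
    final <- rep_peaks[[1]]
  }
  write_narrowpeak(final, file.path(outdir, "final.narrowPeak"))

  ann <- classify_peaks(final, genes, annot)
  write_tsv6(ann, file.path(outdir, "annotations.tsv"))
  gene_rep <- accessibility_related_genes(final, genes, annot)
  if (!is.null(expression)) {
    je <- suppressWarnings(join_expression(gene_rep, expression))
    gene_rep <- merge(gene_rep, je$joined[, c("gene_id", "expression",
                                              "group")],
                      by = "gene_id", all.x = TRUE)
    write_tsv6(je$summary, file.path(outdir, "expression_by_peaks.tsv"))
  }
  write_tsv6(gene_rep, file.path(outdir, "genes.tsv"))
  write_tsv6(qc, file.path(outdir, "qc_report.tsv"))
  if (!is.null(corr)) {
    cdf <- data.frame(library = rownames(corr), corr,
                      stringsAsFactors = FALSE)
    write_tsv6(cdf, file.path(outdir, "correlation.tsv"))
  }

  list(qc = qc, peaks = rep_peaks, final_peaks = final, idr = idr_res,
       correlation = corr, annotations = ann, gene_report = gene_rep,
       saturation = if (length(sat_curves)) sat_curves else NULL,
       paths = list(outdir = outdir))
}
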