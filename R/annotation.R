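## Custom gene annotation: abundance-based transcript selection, reduced
## exon/intron gene models, biotype and length stratification, gene sets.

#' Select transcripts by abundance
#'
#' Applies the abundance filters used to build the custom annotation: all
#' transcripts of genes whose summed TPM is below `gene_tpm_min` are dropped;
#' within retained genes, transcripts contributing less than `frac_min` of
#' the gene's TPM are dropped unless their own TPM exceeds `rescue_tpm`.
#'
#' @param quant data.frame with columns `transcript_id`, `gene_id`, `tpm`.
#' @param gene_tpm_min Minimum summed gene TPM (default 2).
#' @param frac_min Minimum fraction of the gene's TPM (default 0.2).
#' @param rescue_tpm Transcript TPM above which a low-fraction transcript is
#'   kept anyway (default 5).
#' @return Character vector of retained transcript ids.
#' @export
select_transcripts <- function(quant, gene_tpm_min = 2, frac_min = 0.2,
                               rescue_tpm = 5) {
  req <- c("transcript_id", "gene_id", "tpm")
  if (!all(req %in% names(quant))) {
    stopf("quant must have columns %s", paste(req, collapse = ", "))
  }
  bad <- !complete.cases(quant[req])
  if (any(bad)) {
    warnf("skipping %d incomplete quantification rows", sum(bad))
    quant <- quant[!bad, , drop = FALSE]
  }
  if (any(quant$tpm < 0)) stopf("negative TPM values are not allowed")
  gene_tpm <- tapply(quant$tpm, quant$gene_id, sum)
  keep_gene <- names(gene_tpm)[gene_tpm >= gene_tpm_min]
  q <- quant[quant$gene_id %in% keep_gene, , drop = FALSE]
  if (nrow(q) == 0L) return(character(0))
  frac <- q$tpm / as.numeric(gene_tpm[q$gene_id])
  keep <- frac >= frac_min | q$tpm > rescue_tpm
  q$transcript_id[keep]
}

#' Reduce one gene's transcripts to an exon/intron model
#'
#' Merges the exon intervals of all (retained) transcripts of a gene into a
#' reduced exonic representation; introns are the gaps between merged exons
#' within the gene span.
#'
#' @param exons `GRanges` of exon intervals of a single gene (any transcript
#'   structure), all on one strand and sequence.
#' @param gene_id Gene identifier used in error messages.
#' @return List with elements `span`, `exons`, `introns` (`GRanges`).
#' @export
reduce_gene_model <- function(exons, gene_id = "gene") {
  if (length(exons) == 0L) stopf("gene %s has no exons", gene_id)
  if (length(unique(as.character(GenomicRanges::strand(exons)))) != 1L ||
      length(unique(as.character(GenomeInfoDb::seqnames(exons)))) != 1L) {
    stopf("gene %s has transcripts on mixed strands or sequences", gene_id)
  }
  red <- GenomicRanges::reduce(exons)
  span <- range(red)
  introns <- GenomicRanges::setdiff(span, red)
  list(span = span, exons = red, introns = introns)
}

#' Build reduced gene models from a GTF annotation
#'
#' Reads exon records from a GTF file (or pre-imported `GRanges`), optionally
#' restricts to a retained transcript set, and reduces each gene to merged
#' exons and complementary introns. The representative isoform per gene is
#' the transcript with the highest 3'UTR-assigned poly(A) read sum when
#' `utr_reads` is supplied; ties (and the default) fall back to the longest
#' transcript, then lexicographically smallest id.
#'
#' @param gtf Path to a GTF file or a `GRanges` as returned by
#'   `rtracklayer::import`.
#' @param keep_transcripts Optional character vector of transcript ids to
#'   retain (e.g. from [select_transcripts()]).
#' @param utr_reads Optional named numeric vector of per-transcript 3'UTR
#'   poly(A) read sums used to pick the representative isoform.
#' @return Object of class `gene_models`: list with `genes` (data.frame),
#'   `exons` and `introns` (`GRanges` with a `gene_id` column).
#' @export
build_gene_models <- function(gtf, keep_transcripts = NULL,
                              utr_reads = NULL) {
  gr <- if (is.character(gtf)) rtracklayer::import(gtf) else gtf
  if (!"type" %in% names(S4Vectors::mcols(gr))) {
    stopf("GTF input lacks a 'type' column")
  }
  ex <- gr[gr$type == "exon"]
  bt_col <- intersect(c("gene_type", "gene_biotype"),
                      names(S4Vectors::mcols(ex)))
  biotype <- if (length(bt_col)) S4Vectors::mcols(ex)[[bt_col[1]]] else
    rep(NA_character_, length(ex))
  if (!is.null(keep_transcripts)) {
    sel <- ex$transcript_id %in% keep_transcripts
    biotype <- biotype[sel]
    ex <- ex[sel]
  }
  if (length(ex) == 0L) stopf("no exons left after transcript selection")

  gene_ids <- sort(unique(ex$gene_id))
  exl <- S4Vectors::split(ex, factor(ex$gene_id, levels = gene_ids))
  genes <- vector("list", length(gene_ids))
  exon_out <- vector("list", length(gene_ids))
  intron_out <- vector("list", length(gene_ids))
  for (i in seq_along(gene_ids)) {
    gid <- gene_ids[i]
    e <- exl[[i]]
    red <- reduce_gene_model(e, gid)
    tx_len <- tapply(GenomicRanges::width(e), e$transcript_id, sum)
    rep_tx <- pick_representative(names(tx_len), tx_len, utr_reads)
    bt <- biotype[match(gid, ex$gene_id)]
    genes[[i]] <- data.frame(
      gene_id = gid,
      seqnames = as.character(GenomeInfoDb::seqnames(red$span))[1],
      start = GenomicRanges::start(red$span),
      end = GenomicRanges::end(red$span),
      strand = as.character(GenomicRanges::strand(red$span))[1],
      length = GenomicRanges::width(red$span),
      biotype = bt,
      n_exons = length(red$exons),
      n_introns = length(red$introns),
      representative_transcript = rep_tx,
      stringsAsFactors = FALSE
    )
    S4Vectors::mcols(red$exons)$gene_id <- rep(gid, length(red$exons))
    S4Vectors::mcols(red$introns)$gene_id <- rep(gid, length(red$introns))
    exon_out[[i]] <- red$exons
    intron_out[[i]] <- red$introns
  }
  out <- list(
    genes = do.call(rbind, genes),
    exons = unlist(methods::as(exon_out, "GRangesList")),
    introns = unlist(methods::as(intron_out, "GRangesList"))
  )
  class(out) <- "gene_models"
  out
}

pick_representative <- function(tx_ids, tx_len, utr_reads = NULL) {
  score <- rep(0, length(tx_ids))
  if (!is.null(utr_reads)) {
    score <- ifelse(tx_ids %in% names(utr_reads), utr_reads[tx_ids], 0)
    score[is.na(score)] <- 0
  }
  ord <- order(-score, -as.numeric(tx_len), tx_ids)
  tx_ids[ord[1]]
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d reduced exons, %d introns\n",
              nrow(x$genes), length(x$exons), length(x$introns)))
  invisible(x)
}

#' Stratify genes into length classes
#'
#' Protein-coding genes are divided into quartiles of the length
#' distribution (long / medium_long / medium_short / short); the short
#' quartile is further split at its 0.33 and 0.66 quantiles into short /
#' very_short / ultra_short. Boundaries are computed from the input
#' distribution with type-7 quantiles; genes exactly on a boundary fall into
#' the lower (shorter) class.
#'
#' @param lengths Numeric vector of gene lengths in bp (optionally named).
#' @return List with `class` (factor, levels ultra_short..long) and
#'   `boundaries` (named numeric vector of cut points in bp).
#' @export
stratify_lengths <- function(lengths) {
  if (length(lengths) < 8L) stopf("need at least 8 genes to form quartiles")
  if (any(lengths <= 0)) stopf("gene lengths must be positive")
  q <- quantile(lengths, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  lab <- rep("short", length(lengths))
  lab[lengths > q[1]] <- "medium_short"
  lab[lengths > q[2]] <- "medium_long"
  lab[lengths > q[3]] <- "long"
  short <- lab == "short"
  qs <- quantile(lengths[short], c(0.33, 0.66), type = 7, names = FALSE)
  sub <- rep("ultra_short", sum(short))
  sub[lengths[short] > qs[1]] <- "very_short"
  sub[lengths[short] > qs[2]] <- "short"
  lab[short] <- sub
  cls <- factor(lab, levels = c("ultra_short", "very_short", "short",
                                "medium_short", "medium_long", "long"))
  names(cls) <- names(lengths)
  list(
    class = cls,
    boundaries = c(ultra_short_max = qs[1], very_short_max = qs[2],
                   short_max = q[1], medium_short_max = q[2],
                   medium_long_max = q[3])
  )
}

#' Group gene biotypes into coding / long / short non-coding
#'
#' Raw biotype labels with fewer than `min_members` genes are set aside as
#' `unclassified`. Protein-coding genes form their own group; the remaining
#' non-coding genes are split into long vs short non-coding by k-means
#' (k = 2) on log10 gene length, the cluster with the larger centroid being
#' `long_noncoding`. Lloyd's algorithm seeded at fixed quantile centers makes
#' the split deterministic and invariant to gene order.
#'
#' @param genes data.frame with columns `gene_id`, `biotype`, `length`.
#' @param min_members Minimum genes per raw biotype (default 20).
#' @param seed RNG seed guarding the clustering call (default 1729).
#' @return Factor of groups (`protein_coding`, `long_noncoding`,
#'   `short_noncoding`, `unclassified`) named by gene id.
#' @export
classify_biotypes <- function(genes, min_members = 20, seed = 1729) {
  req <- c("gene_id", "biotype", "length")
  if (!all(req %in% names(genes))) {
    stopf("genes must have columns %s", paste(req, collapse = ", "))
  }
  n_bt <- table(genes$biotype)
  grp <- rep("unclassified", nrow(genes))
  eligible <- genes$biotype %in% names(n_bt)[n_bt >= min_members]
  grp[eligible & genes$biotype == "protein_coding"] <- "protein_coding"
  nc <- eligible & genes$biotype != "protein_coding"
  if (sum(nc) >= 2L && length(unique(genes$length[nc])) >= 2L) {
    x <- log10(genes$length[nc])
    centers <- matrix(quantile(x, c(0.25, 0.75), type = 7, names = FALSE))
    km <- with_seed(seed, kmeans(x, centers = centers, iter.max = 200,
                                 algorithm = "Lloyd"))
    long_cluster <- which.max(km$centers)
    grp[nc] <- ifelse(km$cluster == long_cluster,
                      "long_noncoding", "short_noncoding")
  } else if (sum(nc) > 0L) {
    warnf("too few non-coding genes to cluster; all assigned long_noncoding")
    grp[nc] <- "long_noncoding"
  }
  out <- factor(grp, levels = c("protein_coding", "long_noncoding",
                                "short_noncoding", "unclassified"))
  names(out) <- genes$gene_id
  out
}

#' Attach biotype groups and length classes to gene models
#'
#' Convenience wrapper running [classify_biotypes()] on all genes and
#' [stratify_lengths()] on the protein-coding subset, recording the computed
#' length-class boundaries as an attribute of the returned object.
#'
#' @param models A `gene_models` object.
#' @inheritParams classify_biotypes
#' @return The input with `biotype_group` and `length_class` columns added
#'   to `models$genes` and a `length_boundaries` attribute.
#' @export
annotate_gene_classes <- function(models, min_members = 20, seed = 1729) {
  g <- models$genes
  g$biotype_group <- as.character(classify_biotypes(g, min_members, seed))
  g$length_class <- NA_character_
  pc <- g$biotype_group == "protein_coding"
  if (sum(pc) >= 8L) {
    strat <- stratify_lengths(setNames(g$length[pc], g$gene_id[pc]))
    g$length_class[pc] <- as.character(strat$class)
    attr(models, "length_boundaries") <- strat$boundaries
  }
  models$genes <- g
  models
}

#' Load and aggregate gene sets
#'
#' Reads one or more plain-text gene lists (one id per line, `#` comments),
#' takes their union and intersects it with the annotation's gene universe.
#'
#' @param paths Character vector of file paths.
#' @param universe Character vector of annotated gene ids.
#' @param name Set name (default "geneset").
#' @return List with `name`, `members` (character), `n_unmatched` (ids
#'   dropped because absent from the annotation).
#' @export
load_gene_set <- function(paths, universe, name = "geneset") {
  ids <- character(0)
  for (p in paths) {
    ln <- readLines(p, warn = FALSE)
    ln <- sub("#.*$", "", ln)
    ln <- trimws(ln)
    ids <- c(ids, ln[nzchar(ln)])
  }
  ids <- unique(ids)
  if (length(ids) == 0L) stopf("gene set union is empty")
  members <- intersect(ids, universe)
  if (length(members) == 0L) stopf("no gene-set members match the annotation")
  list(name = name, members = members,
       n_unmatched = length(ids) - length(members))
}

#' Write gene models to BED12 and TSV
#'
#' @param models A `gene_models` object (ideally after
#'   [annotate_gene_classes()]).
#' @param bed12_path Output BED12 path (one row per gene; blocks = reduced
#'   exons).
#' @param tsv_path Output TSV path of per-gene metadata.
#' @return Invisibly, the two paths.
#' @export
write_gene_models <- function(models, bed12_path, tsv_path) {
  g <- models$genes
  exl <- S4Vectors::split(models$exons,
                          factor(models$exons$gene_id, levels = g$gene_id))
  block_count <- lengths(exl)
  block_sizes <- vapply(seq_along(exl), function(i) {
    paste0(GenomicRanges::width(exl[[i]]), collapse = ",")
  }, character(1))
  block_starts <- vapply(seq_along(exl), function(i) {
    paste0(GenomicRanges::start(exl[[i]]) - g$start[i], collapse = ",")
  }, character(1))
  bed <- data.frame(
    chrom = g$seqnames, start = g$start - 1L, end = g$end,
    name = g$gene_id, score = 0L, strand = g$strand,
    thickStart = g$start - 1L, thickEnd = g$end, rgb = "0,0,0",
    blockCount = block_count, blockSizes = block_sizes,
    blockStarts = block_starts
  )
  write.table(bed, bed12_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  cols <- intersect(c("gene_id", "length", "biotype", "biotype_group",
                      "length_class", "representative_transcript"),
                    names(g))
  write_tsv0(g[cols], tsv_path)
  invisible(c(bed12_path, tsv_path))
}

#' Read a transcript abundance table
#'
#' @param path TSV with columns `transcript_id`, `gene_id`, `tpm`.
#' @return data.frame.
#' @export
read_transcript_quant <- function(path) {
  q <- read_tsv0(path)
  req <- c("transcript_id", "gene_id", "tpm")
  if (!all(req %in% names(q))) {
    stopf("%s must have columns %s", path, paste(req, collapse = ", "))
  }
  q
}
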