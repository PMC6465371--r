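## Poly(A) 3'-seq peak filtering (internal-priming artifacts), hierarchical
## annotation, condition-specific peak calling and genomic distributions.

#' Read a poly(A) peak table
#'
#' BED-like TSV with header: `chrom`, `start`, `end`, `name`, `qscore`,
#' `strand`, then one count column per sample. The peak position is the
#' `summit` column when present, else the interval midpoint.
#'
#' @param path Path to the TSV.
#' @param count_cols Names of the per-sample count columns; defaults to all
#'   columns after `strand` (minus `summit`).
#' @return data.frame with a `position` column and a `count_cols` attribute.
#' @export
read_peaks <- function(path, count_cols = NULL) {
  pk <- read_tsv0(path)
  req <- c("chrom", "start", "end", "name", "qscore", "strand")
  if (!all(req %in% names(pk))) {
    stopf("%s must have columns %s", path, paste(req, collapse = ", "))
  }
  pk$position <- if ("summit" %in% names(pk)) pk$summit else
    (pk$start + pk$end + 1L) %/% 2L
  if (is.null(count_cols)) {
    count_cols <- setdiff(names(pk), c(req, "summit", "position"))
  }
  attr(pk, "count_cols") <- count_cols
  pk
}

peak_count_cols <- function(peaks, count_cols = NULL) {
  count_cols %||% attr(peaks, "count_cols") %||%
    stop("count columns not declared", call. = FALSE)
}

#' Filter internal-priming artifact peaks
#'
#' Flags, for each peak, (1) the presence of any of the 12 polyadenylation
#' signal hexamers (AATAAA, ATTAAA, AGTAAA, TATAAA, AATATA, AATACA, CATAAA,
#' GATAAA, AATGAA, ACTAAA, AAGAAA, AATAGA) in the strand-specific 100 bp
#' window upstream of the cleavage position, and (2) a genomic A-stretch
#' (any 25-mer with at least 22 adenines on the peak's strand) in the
#' strand-specific 50 bp window downstream. Peaks with no upstream signal
#' but a downstream A-stretch are internal-priming artifacts and removed.
#'
#' @param peaks data.frame from [read_peaks()] (columns `chrom`,
#'   `position`, `strand`).
#' @param genome A `DNAStringSet` (or FASTA path).
#' @param pas_window Upstream scan window in bp (default 100).
#' @param a_window Downstream scan window in bp (default 50).
#' @param a_len,a_min A-stretch window length and minimum adenine count
#'   (defaults 25 and 22, i.e. up to 3 mismatches).
#' @return List with `retained` and `removed` data.frames, each with
#'   `pas_motif` (first matching hexamer in the printed scan order, or NA)
#'   and `a_stretch` columns added.
#' @export
filter_internal_priming <- function(peaks, genome, pas_window = 100,
                                    a_window = 50, a_len = 25, a_min = 22) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  seqlens <- setNames(Biostrings::width(genome), names(genome))
  if (!all(peaks$chrom %in% names(genome))) {
    stopf("peak sequence name absent from the genome")
  }
  if (any(peaks$position < 1 | peaks$position > seqlens[peaks$chrom])) {
    stopf("peak position outside sequence bounds")
  }
  n <- nrow(peaks)
  pas_motif <- rep(NA_character_, n)
  a_stretch <- logical(n)
  for (i in seq_len(n)) {
    chrom <- genome[[peaks$chrom[i]]]
    len <- length(chrom)
    pos <- peaks$position[i]
    minus <- peaks$strand[i] == "-"
    up_rng <- if (!minus) c(pos - pas_window, pos - 1L) else
      c(pos + 1L, pos + pas_window)
    dn_rng <- if (!minus) c(pos + 1L, pos + a_window) else
      c(pos - a_window, pos - 1L)
    up_rng <- pmin(pmax(up_rng, 1L), len)
    dn_rng <- pmin(pmax(dn_rng, 1L), len)
    up <- Biostrings::subseq(chrom, up_rng[1], up_rng[2])
    dn <- Biostrings::subseq(chrom, dn_rng[1], dn_rng[2])
    if (minus) {
      up <- Biostrings::reverseComplement(up)
      dn <- Biostrings::reverseComplement(dn)
    }
    for (m in PAS_MOTIFS) {
      if (Biostrings::countPattern(m, up) > 0L) {
        pas_motif[i] <- m
        break
      }
    }
    if (length(dn) >= a_len) {
      amax <- max(Biostrings::letterFrequencyInSlidingView(dn, a_len, "A"))
      a_stretch[i] <- amax >= a_min
    }
  }
  peaks$pas_motif <- pas_motif
  peaks$a_stretch <- a_stretch
  removed <- is.na(pas_motif) & a_stretch
  cc <- attr(peaks, "count_cols")
  out <- list(retained = peaks[!removed, , drop = FALSE],
              removed = peaks[removed, , drop = FALSE])
  attr(out$retained, "count_cols") <- cc
  attr(out$removed, "count_cols") <- cc
  out
}

#' Annotate peaks against the reduced gene models
#'
#' Hierarchical assignment: peaks within the strand-aware TES window (200 bp
#' upstream to 600 bp downstream of a gene's transcription end site, in
#' transcription direction) are `tes_utr`; remaining peaks overlapping a
#' gene are `exon` or `intron` by the reduced model; the rest are
#' `intergenic`. When several genes overlap a peak, protein-coding genes
#' take priority, then the longer gene, then the lexicographically smaller
#' id.
#'
#' @param peaks data.frame with `chrom`, `position`, `strand`.
#' @param models A `gene_models` object.
#' @param tes_upstream,tes_downstream TES window extent in bp (defaults 200
#'   and 600).
#' @return The peaks data.frame with `category` and `gene_id` columns.
#' @export
annotate_peaks <- function(peaks, models, tes_upstream = 200,
                           tes_downstream = 600) {
  genes <- models$genes
  cc <- attr(peaks, "count_cols")
  pk_gr <- GenomicRanges::GRanges(peaks$chrom,
                                  IRanges::IRanges(peaks$position, width = 1L))
  plus <- genes$strand == "+"
  tes_start <- ifelse(plus, genes$end - tes_upstream,
                      genes$start - tes_downstream)
  tes_end <- ifelse(plus, genes$end + tes_downstream,
                    genes$start + tes_upstream)
  tes_gr <- GenomicRanges::GRanges(genes$seqnames,
                                   IRanges::IRanges(pmax(tes_start, 1L),
                                                    tes_end))
  gene_gr <- GenomicRanges::GRanges(genes$seqnames,
                                    IRanges::IRanges(genes$start, genes$end))
  is_pc <- if ("biotype" %in% names(genes)) {
    genes$biotype %in% "protein_coding"
  } else rep(TRUE, nrow(genes))
  pick_gene <- function(cand) {
    cand[order(-as.integer(is_pc[cand]), -genes$length[cand],
               genes$gene_id[cand])][1]
  }
  category <- rep("intergenic", nrow(peaks))
  gene_id <- rep(NA_character_, nrow(peaks))
  ov_tes <- GenomicRanges::findOverlaps(pk_gr, tes_gr)
  for (i in unique(S4Vectors::queryHits(ov_tes))) {
    g <- pick_gene(S4Vectors::subjectHits(ov_tes)[
      S4Vectors::queryHits(ov_tes) == i])
    category[i] <- "tes_utr"
    gene_id[i] <- genes$gene_id[g]
  }
  rest <- which(category == "intergenic")
  ov_g <- GenomicRanges::findOverlaps(pk_gr[rest], gene_gr)
  exon_by_gene <- S4Vectors::split(
    models$exons, factor(models$exons$gene_id, levels = genes$gene_id))
  for (i in unique(S4Vectors::queryHits(ov_g))) {
    g <- pick_gene(S4Vectors::subjectHits(ov_g)[
      S4Vectors::queryHits(ov_g) == i])
    pi <- rest[i]
    gene_id[pi] <- genes$gene_id[g]
    in_exon <- GenomicRanges::countOverlaps(
      pk_gr[pi], exon_by_gene[[genes$gene_id[g]]]) > 0L
    category[pi] <- if (in_exon) "exon" else "intron"
  }
  peaks$category <- factor(category,
                           levels = c("tes_utr", "exon", "intron",
                                      "intergenic"))
  peaks$gene_id <- gene_id
  attr(peaks, "count_cols") <- cc
  peaks
}

#' Condition-specific poly(A) peaks
#'
#' Drops peaks below the q-score threshold, computes the log-ratio
#' log2((a + 1)/(b + 1)) of the two conditions' read counts, and labels
#' peaks with sufficient reads and |log-ratio| above the threshold as
#' specific to the respective condition.
#'
#' @param peaks Annotated peak data.frame.
#' @param a_col,b_col Names of the two count columns (a = treated by
#'   convention).
#' @param min_qscore Minimum -log10 q-score (default 5).
#' @param min_reads Minimum read count (default 64).
#' @param lr_threshold Log-ratio threshold (default 1).
#' @param combined_reads Interpret `min_reads` as the combined count of both
#'   conditions (default TRUE); otherwise the larger single-sample count
#'   must reach it.
#' @return The retained peaks with `log_ratio` and `status` (`a_specific`,
#'   `b_specific`, `unchanged`) columns; the number of q-score-dropped peaks
#'   is attached as attribute `n_low_q`.
#' @export
differential_peaks <- function(peaks, a_col, b_col, min_qscore = 5,
                               min_reads = 64, lr_threshold = 1,
                               combined_reads = TRUE) {
  keep <- peaks$qscore >= min_qscore
  out <- peaks[keep, , drop = FALSE]
  a <- out[[a_col]]
  b <- out[[b_col]]
  lr <- log2((a + 1) / (b + 1))
  enough <- if (combined_reads) (a + b) >= min_reads else
    pmax(a, b) >= min_reads
  status <- rep("unchanged", nrow(out))
  status[enough & lr > lr_threshold] <- "a_specific"
  status[enough & lr < -lr_threshold] <- "b_specific"
  out$log_ratio <- lr
  out$status <- factor(status,
                       levels = c("a_specific", "b_specific", "unchanged"))
  attr(out, "n_low_q") <- sum(!keep)
  attr(out, "count_cols") <- attr(peaks, "count_cols")
  out
}

#' Genomic distribution of top-ranked peaks
#'
#' Ranks annotated peaks by total intensity, keeps the top `top_n`, splits
#' them into intensity bins of equal size and tabulates the fraction of
#' each genomic category per bin.
#'
#' @param peaks Annotated peak data.frame (has `category`).
#' @param count_cols Count columns summed into the intensity (default: the
#'   table's declared count columns).
#' @param top_n Number of top peaks kept (default 5000; all, with a
#'   warning, when fewer are available).
#' @param n_bins Number of intensity bins (default 10).
#' @return data.frame with `bin`, `category`, `fraction`, `n`; per-bin
#'   fractions sum to 1.
#' @export
peak_region_distribution <- function(peaks, count_cols = NULL, top_n = 5000,
                                     n_bins = 10) {
  count_cols <- peak_count_cols(peaks, count_cols)
  total <- rowSums(peaks[, count_cols, drop = FALSE])
  if (top_n > nrow(peaks)) {
    warnf("top_n (%d) exceeds available peaks (%d); using all",
          top_n, nrow(peaks))
    top_n <- nrow(peaks)
  }
  ord <- order(-total)[seq_len(top_n)]
  sel <- peaks[ord, , drop = FALSE]
  bin <- ceiling(seq_len(top_n) / (top_n / n_bins))
  tab <- table(bin, sel$category)
  frac <- prop.table(tab, margin = 1)
  df <- as.data.frame(frac, responseName = "fraction",
                      stringsAsFactors = FALSE)
  names(df)[1:2] <- c("bin", "category")
  df$bin <- as.integer(df$bin)
  df$n <- as.integer(as.data.frame(tab)$Freq)
  df[order(df$bin, df$category), , drop = FALSE]
}
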