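## Gene-architecture determinants of PCPA: U1/PAS motif content, GC,
## intron structure, poly(A)-site-vs-length regression and splice-site
## position-weight-matrix conservation.

gene_sense_seq <- function(genome, chrom, start, end, strand) {
  s <- Biostrings::subseq(genome[[chrom]], start, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  s
}

#' Per-gene genetic determinants
#'
#' Computes, over each gene's sense-strand sequence from TSS to TES: counts
#' of the U1-binding motifs (GGTGAG, GGTAAG, GTGAGT) and the canonical PAS
#' hexamer (AATAAA), the GC fraction, the pseudocounted U1/PAS ratio
#' (u1 + 1)/(pas + 1), plus first-intron length, intron number, expression
#' and the number of annotated intronic poly(A) sites.
#'
#' @param models A `gene_models` object.
#' @param genome `DNAStringSet` (or FASTA path).
#' @param tpm Optional named per-gene TPM (control condition).
#' @param peaks Optional annotated peak data.frame; intronic peaks are
#'   counted per gene.
#' @return data.frame of class-augmented determinant records, one row per
#'   gene.
#' @export
compute_determinants <- function(models, genome, tpm = NULL, peaks = NULL) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genes <- models$genes
  seqlens <- setNames(Biostrings::width(genome), names(genome))
  if (any(!genes$seqnames %in% names(genome)) ||
      any(genes$end > seqlens[genes$seqnames])) {
    stopf("gene span outside the genome sequence")
  }
  n <- nrow(genes)
  u1 <- integer(n)
  pas <- integer(n)
  gc <- numeric(n)
  for (i in seq_len(n)) {
    s <- gene_sense_seq(genome, genes$seqnames[i], genes$start[i],
                        genes$end[i], genes$strand[i])
    u1[i] <- sum(vapply(U1_MOTIFS, function(m) {
      Biostrings::countPattern(m, s)
    }, integer(1)))
    pas[i] <- Biostrings::countPattern("AATAAA", s)
    gc[i] <- sum(Biostrings::letterFrequency(s, c("G", "C"))) / length(s)
  }
  first_intron <- vapply(seq_len(n), function(i) {
    ii <- models$introns[models$introns$gene_id == genes$gene_id[i]]
    if (length(ii) == 0L) return(NA_real_)
    ii <- sort(ii)
    first <- if (genes$strand[i] == "+") ii[1] else ii[length(ii)]
    as.numeric(GenomicRanges::width(first))
  }, numeric(1))
  n_ipas <- rep(0L, n)
  if (!is.null(peaks)) {
    tab <- table(peaks$gene_id[peaks$category %in% "intron"])
    hit <- genes$gene_id %in% names(tab)
    n_ipas[hit] <- as.integer(tab[genes$gene_id[hit]])
  }
  expr <- rep(NA_real_, n)
  if (!is.null(tpm)) {
    expr <- unname(ifelse(genes$gene_id %in% names(tpm),
                          tpm[genes$gene_id], NA_real_))
  }
  data.frame(gene_id = genes$gene_id, length = genes$length,
             first_intron_length = first_intron,
             n_introns = genes$n_introns, gc_fraction = gc,
             expression = expr, u1_count = u1, pas_count = pas,
             u1_pas_ratio = (u1 + 1) / (pas + 1),
             n_intronic_pas_sites = n_ipas, stringsAsFactors = FALSE)
}

cohen_d <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  nx <- length(x)
  ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  if (!is.finite(sp2) || sp2 == 0) return(NA_real_)
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Compare determinants between all genes and PCPA genes
#'
#' For each determinant, a two-sided Wilcoxon rank-sum test and Cohen's d
#' (pooled SD, Bessel-corrected) between the PCPA group and all genes;
#' positive d means the determinant is larger in PCPA genes. An optional
#' DDR subset is summarized within the PCPA group.
#'
#' @param records Determinant data.frame from [compute_determinants()].
#' @param pcpa_genes Character vector of PCPA gene ids.
#' @param ddr_genes Optional character vector of DDR gene ids.
#' @param determinants Columns to compare (default: the six gene-axis
#'   determinants).
#' @return data.frame with `determinant`, `p`, `d`, group medians, and the
#'   DDR-within-PCPA median when a DDR set is given.
#' @export
compare_determinants <- function(records, pcpa_genes, ddr_genes = NULL,
                                 determinants = c("length",
                                                  "first_intron_length",
                                                  "n_introns", "gc_fraction",
                                                  "expression",
                                                  "u1_pas_ratio",
                                                  "n_intronic_pas_sites")) {
  in_pcpa <- records$gene_id %in% pcpa_genes
  if (!any(in_pcpa)) stopf("PCPA group is empty")
  rows <- lapply(determinants, function(dt) {
    all_v <- records[[dt]]
    pcpa_v <- all_v[in_pcpa]
    p <- tryCatch(
      suppressWarnings(wilcox.test(pcpa_v, all_v)$p.value),
      error = function(e) NA_real_)
    d <- cohen_d(pcpa_v, all_v)
    small <- sum(is.finite(pcpa_v)) < 10
    out <- data.frame(determinant = dt, p = p, d = d,
                      median_all = median(all_v, na.rm = TRUE),
                      median_pcpa = median(pcpa_v, na.rm = TRUE),
                      small_sample = small, stringsAsFactors = FALSE)
    if (!is.null(ddr_genes)) {
      ddr_v <- all_v[in_pcpa & records$gene_id %in% ddr_genes]
      out$median_ddr_pcpa <- if (length(ddr_v)) {
        median(ddr_v, na.rm = TRUE)
      } else NA_real_
    }
    out
  })
  do.call(rbind, rows)
}

#' Intronic poly(A) sites versus transcript length regression
#'
#' Fits a degree-2 polynomial of the number of intronic poly(A) sites on
#' gene length, once for all genes and once for DDR genes only, and tests
#' the per-DDR-gene difference of predictions (DDR model minus all-genes
#' model) with a Wilcoxon signed-rank test.
#'
#' @param records Determinant data.frame.
#' @param ddr_genes Character vector of DDR gene ids.
#' @param length_col,response_col Column names (defaults `length`,
#'   `n_intronic_pas_sites`).
#' @return List with `fit_all`, `fit_ddr` (`lm` objects; raw polynomial
#'   coefficients), `prediction_diff` (per DDR gene), `p` (signed-rank),
#'   and `median_diff`. The DDR test is skipped with a warning when fewer
#'   than 3 DDR genes are present.
#' @export
pas_length_regression <- function(records, ddr_genes = NULL,
                                  length_col = "length",
                                  response_col = "n_intronic_pas_sites") {
  x <- records[[length_col]]
  y <- records[[response_col]]
  if (length(x) < 10L) stopf("need at least 10 genes for the regression")
  if (any(x <= 0)) stopf("gene lengths must be positive")
  dat <- data.frame(x = x, y = y)
  fit_all <- lm(y ~ x + I(x^2), data = dat)
  out <- list(fit_all = fit_all, fit_ddr = NULL, prediction_diff = NULL,
              p = NA_real_, median_diff = NA_real_)
  ddr_idx <- which(records$gene_id %in% ddr_genes)
  if (length(ddr_idx) < 3L) {
    if (!is.null(ddr_genes)) warnf("fewer than 3 DDR genes; test skipped")
    return(out)
  }
  ddr_dat <- dat[ddr_idx, , drop = FALSE]
  fit_ddr <- lm(y ~ x + I(x^2), data = ddr_dat)
  pred_all <- predict(fit_all, newdata = ddr_dat)
  pred_ddr <- predict(fit_ddr, newdata = ddr_dat)
  diffs <- pred_ddr - pred_all
  wt <- suppressWarnings(wilcox.test(diffs, mu = 0))
  out$fit_ddr <- fit_ddr
  out$prediction_diff <- diffs
  out$p <- wt$p.value
  out$median_diff <- median(diffs)
  out
}

## sense sequences of all reduced introns with flanking exonic context
intron_sense_windows <- function(models, genome, donor_exonic = 3,
                                 donor_intronic = 6, acceptor_len = 15) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  ii <- models$introns
  genes <- models$genes
  st <- genes$strand[match(ii$gene_id, genes$gene_id)]
  n <- length(ii)
  donors <- character(n)
  acceptors <- character(n)
  first2 <- character(n)
  last2 <- character(n)
  width <- GenomicRanges::width(ii)
  for (i in seq_len(n)) {
    chrom <- as.character(GenomeInfoDb::seqnames(ii))[i]
    s <- GenomicRanges::start(ii)[i]
    e <- GenomicRanges::end(ii)[i]
    if (st[i] == "+") {
      don <- Biostrings::subseq(genome[[chrom]], s - donor_exonic,
                                s + donor_intronic - 1L)
      acc <- Biostrings::subseq(genome[[chrom]], e - acceptor_len + 1L, e)
      intr <- Biostrings::subseq(genome[[chrom]], s, e)
    } else {
      don <- Biostrings::reverseComplement(
        Biostrings::subseq(genome[[chrom]], e - donor_intronic + 1L,
                           e + donor_exonic))
      acc <- Biostrings::reverseComplement(
        Biostrings::subseq(genome[[chrom]], s, s + acceptor_len - 1L))
      intr <- Biostrings::reverseComplement(
        Biostrings::subseq(genome[[chrom]], s, e))
    }
    donors[i] <- as.character(don)
    acceptors[i] <- as.character(acc)
    first2[i] <- as.character(Biostrings::subseq(intr, 1L, 2L))
    last2[i] <- as.character(Biostrings::subseq(intr, length(intr) - 1L,
                                                length(intr)))
  }
  data.frame(gene_id = ii$gene_id, chrom = as.character(
    GenomeInfoDb::seqnames(ii)), start = GenomicRanges::start(ii),
    end = GenomicRanges::end(ii), strand = st, width = width,
    donor = donors, acceptor = acceptors, canonical = first2 == "GT" &
      last2 == "AG", stringsAsFactors = FALSE)
}

#' Build splice-site position weight matrices
#'
#' From all canonical (GT..AG) introns, builds a donor PWM over a 9-mer
#' (3 exonic + 6 intronic bases around the 5' splice site) and an acceptor
#' PWM over the 15-mer ending at the intron's last base, with a pseudocount
#' per base; columns sum to 1. Introns shorter than `min_intron` bp are
#' excluded so the two windows cannot overlap.
#'
#' @param models A `gene_models` object.
#' @param genome `DNAStringSet` or FASTA path.
#' @param pseudocount Per-base pseudocount (default 0.5).
#' @param min_qualifying Minimum canonical introns required (default 20).
#' @param min_intron Minimum intron width in bp (default 24).
#' @return List of class `splice_pwms` with `donor` (4 x 9) and `acceptor`
#'   (4 x 15) probability matrices, `n_introns`, `pseudocount`,
#'   `background` (0.25).
#' @export
build_splice_pwms <- function(models, genome, pseudocount = 0.5,
                              min_qualifying = 20, min_intron = 24) {
  win <- intron_sense_windows(models, genome)
  win <- win[win$canonical & win$width >= min_intron, , drop = FALSE]
  if (nrow(win) < min_qualifying) {
    stopf("only %d qualifying GT..AG introns (< %d)", nrow(win),
          min_qualifying)
  }
  pwm_from <- function(seqs) {
    cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs))
    cm <- cm[DNA_BASES, , drop = FALSE]
    sweep(cm + pseudocount, 2, colSums(cm) + 4 * pseudocount, "/")
  }
  out <- list(donor = pwm_from(win$donor), acceptor = pwm_from(win$acceptor),
              n_introns = nrow(win), pseudocount = pseudocount,
              background = 0.25)
  class(out) <- "splice_pwms"
  out
}

#' @export
print.splice_pwms <- function(x, ...) {
  cat(sprintf(
    "splice_pwms: donor 4x%d, acceptor 4x%d, built from %d introns\n",
    ncol(x$donor), ncol(x$acceptor), x$n_introns))
  invisible(x)
}

pwm_logodds <- function(pwm, seqs, background = 0.25) {
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    idx <- match(ch, rownames(pwm))
    if (anyNA(idx)) return(NA_real_)
    sum(log2(pwm[cbind(idx, seq_along(idx))] / background))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Score introns against the splice-site PWMs
#'
#' Each canonical intron's combined conservation score is the sum of the
#' donor and acceptor log2 odds (PWM probability over a uniform 0.25
#' background). When a map of introns with intronic poly(A) sites is given,
#' the with- and without-site groups are compared by Wilcoxon rank-sum test
#' and Cohen's d.
#'
#' @param models A `gene_models` object.
#' @param genome `DNAStringSet` or FASTA path.
#' @param pwms A `splice_pwms` object.
#' @param intronic_pas Optional annotated peak data.frame (intronic
#'   category rows mark their host introns) or a `GRanges` of intronic
#'   poly(A) positions.
#' @param min_intron Minimum intron width scored (default 24; shorter
#'   introns are excluded and counted).
#' @return List with `scores` (per-intron data.frame incl. `has_pas` when
#'   available), `n_excluded`, and `comparison` (p, d) when groups exist.
#' @export
score_introns <- function(models, genome, pwms, intronic_pas = NULL,
                          min_intron = 24) {
  win <- intron_sense_windows(models, genome)
  usable <- win$canonical & win$width >= min_intron
  n_excluded <- sum(win$width < min_intron)
  sc <- win[usable, , drop = FALSE]
  sc$donor_score <- pwm_logodds(pwms$donor, sc$donor, pwms$background)
  sc$acceptor_score <- pwm_logodds(pwms$acceptor, sc$acceptor,
                                   pwms$background)
  sc$score <- sc$donor_score + sc$acceptor_score
  comparison <- NULL
  if (!is.null(intronic_pas)) {
    pas_gr <- if (is.data.frame(intronic_pas)) {
      ip <- intronic_pas[intronic_pas$category %in% "intron", , drop = FALSE]
      GenomicRanges::GRanges(ip$chrom, IRanges::IRanges(ip$position,
                                                        width = 1L))
    } else intronic_pas
    intron_gr <- GenomicRanges::GRanges(sc$chrom,
                                        IRanges::IRanges(sc$start, sc$end))
    sc$has_pas <- GenomicRanges::countOverlaps(intron_gr, pas_gr) > 0L
    if (any(sc$has_pas) && any(!sc$has_pas)) {
      p <- suppressWarnings(wilcox.test(sc$score[sc$has_pas],
                                        sc$score[!sc$has_pas])$p.value)
      comparison <- data.frame(
        p = p, d = cohen_d(sc$score[sc$has_pas], sc$score[!sc$has_pas]),
        n_with = sum(sc$has_pas), n_without = sum(!sc$has_pas))
    }
  }
  keep <- setdiff(names(sc), c("donor", "acceptor", "canonical"))
  list(scores = sc[keep], n_excluded = n_excluded, comparison = comparison)
}
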