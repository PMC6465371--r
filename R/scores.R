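## Core per-gene statistics: intron-retention index, PCPA exon-/iQ-scores,
## intronic polyadenylation usage odds ratios, differential expression and
## the gene-set permutation z-score.

#' Intron retention index
#'
#' IR index = log2(intron ratio / exon ratio) where each ratio is
#' (treated coverage + 1)/(control coverage + 1). Genes qualify when at
#' least one condition has both `min_exon` exonic and `min_intron` intronic
#' reads; a Fisher's exact test on the 2x2 exon/intron x treated/control
#' table, BH-adjusted across tested genes, classifies significant loss
#' (adjusted p < `p_max`, IR < -`ir_threshold`) or retention (adjusted
#' p < `p_max`, IR > `ir_threshold`).
#'
#' @param counts data.frame with columns `gene_id`, `exon_treated`,
#'   `exon_control`, `intron_treated`, `intron_control` (integer read
#'   counts).
#' @param min_exon,min_intron Coverage minima (defaults 10 and 5).
#' @param ir_threshold Index magnitude threshold (default 1).
#' @param p_max Adjusted-p threshold (default 0.05).
#' @return data.frame with `ir_index`, `ir_p`, `ir_p_adj`, `ir_tested`,
#'   `ir_class` (`loss`/`retention`/`none`).
#' @export
intron_retention_index <- function(counts, min_exon = 10, min_intron = 5,
                                   ir_threshold = 1, p_max = 0.05) {
  req <- c("gene_id", "exon_treated", "exon_control", "intron_treated",
           "intron_control")
  if (!all(req %in% names(counts))) {
    stopf("counts must have columns %s", paste(req, collapse = ", "))
  }
  m <- counts[, req[-1]]
  if (any(m < 0)) stopf("negative counts are not allowed")
  m <- round(m)
  tested <- (m$exon_treated >= min_exon & m$intron_treated >= min_intron) |
    (m$exon_control >= min_exon & m$intron_control >= min_intron)
  exon_ratio <- (m$exon_treated + 1) / (m$exon_control + 1)
  intron_ratio <- (m$intron_treated + 1) / (m$intron_control + 1)
  ir <- log2(intron_ratio / exon_ratio)
  ir[!tested] <- NA_real_
  p <- rep(NA_real_, nrow(m))
  for (i in which(tested)) {
    tab <- matrix(c(m$exon_treated[i], m$intron_treated[i],
                    m$exon_control[i], m$intron_control[i]),
                  nrow = 2, byrow = TRUE)
    p[i] <- fisher.test(tab)$p.value
  }
  p_adj <- rep(NA_real_, nrow(m))
  p_adj[tested] <- p.adjust(p[tested], method = "BH")
  cls <- rep("none", nrow(m))
  cls[tested & !is.na(p_adj) & p_adj < p_max & ir < -ir_threshold] <- "loss"
  cls[tested & !is.na(p_adj) & p_adj < p_max & ir > ir_threshold] <-
    "retention"
  data.frame(gene_id = counts$gene_id, ir_index = ir, ir_p = p,
             ir_p_adj = p_adj, ir_tested = tested,
             ir_class = factor(cls, levels = c("loss", "retention", "none")),
             stringsAsFactors = FALSE)
}

#' PCPA exon- and iQ-scores from counts
#'
#' exon-score = log2 fold change (treated/control) of the last exon minus
#' that of the first exon; iQ-score = log2(iQ1/iQ4) on treated counts in
#' the first vs last quarter of the internal gene region (first 5' splice
#' site to last 3' splice site). A pseudocount keeps both defined at zero
#' coverage. A gene undergoes PCPA when exon-score < -1 and iQ-score > 1.
#'
#' @param first_treated,first_control,last_treated,last_control Read counts
#'   over the first and last exon.
#' @param iq1,iq4 Treated read counts in the first and last quarter of the
#'   internal region.
#' @param pseudocount Added to every count (default 1; set 0 to disable).
#' @param exon_threshold,iq_threshold Call thresholds (defaults -1 and 1).
#' @return data.frame with `exon_score`, `iq_score`, `iq1`, `iq4`, `pcpa`.
#' @export
pcpa_scores <- function(first_treated, first_control, last_treated,
                        last_control, iq1, iq4, pseudocount = 1,
                        exon_threshold = -1, iq_threshold = 1) {
  pc <- pseudocount
  exon_score <- log2((last_treated + pc) / (last_control + pc)) -
    log2((first_treated + pc) / (first_control + pc))
  iq_score <- log2((iq1 + pc) / (iq4 + pc))
  data.frame(exon_score = exon_score, iq_score = iq_score,
             iq1 = iq1, iq4 = iq4,
             pcpa = exon_score < exon_threshold & iq_score > iq_threshold)
}

## first/last exon and internal-region quarters, strand-aware
gene_score_regions <- function(models) {
  genes <- models$genes
  exl <- S4Vectors::split(models$exons,
                          factor(models$exons$gene_id,
                                 levels = genes$gene_id))
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    e <- exl[[i]]
    if (length(e) < 2L) {
      out[[i]] <- NULL
      next
    }
    e <- sort(e)
    plus <- genes$strand[i] == "+"
    first <- if (plus) e[1] else e[length(e)]
    last <- if (plus) e[length(e)] else e[1]
    iq_start <- GenomicRanges::end(e[1]) + 1L
    iq_end <- GenomicRanges::start(e[length(e)]) - 1L
    if (iq_end < iq_start) {
      out[[i]] <- NULL
      next
    }
    w <- iq_end - iq_start + 1L
    q <- floor(w / 4)
    if (q < 1L) {
      out[[i]] <- NULL
      next
    }
    q1_rng <- c(iq_start, iq_start + q - 1L)
    q4_rng <- c(iq_end - q + 1L, iq_end)
    if (!plus) {
      tmp <- q1_rng
      q1_rng <- q4_rng
      q4_rng <- tmp
    }
    out[[i]] <- data.frame(
      gene_id = genes$gene_id[i], seqnames = genes$seqnames[i],
      first_start = GenomicRanges::start(first),
      first_end = GenomicRanges::end(first),
      last_start = GenomicRanges::start(last),
      last_end = GenomicRanges::end(last),
      q1_start = q1_rng[1], q1_end = q1_rng[2],
      q4_start = q4_rng[1], q4_end = q4_rng[2],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Call PCPA genes from coverage tracks
#'
#' Counts reads over each gene's first and last exon in both conditions and
#' over the first/last quarter of its internal region in the treated
#' condition, then applies [pcpa_scores()]. Single-exon genes are returned
#' with NA scores (not assessable).
#'
#' @param models A `gene_models` object.
#' @param control,treated Lists with `plus`/`minus` raw bedGraph `GRanges`
#'   (score = per-bp read depth) or `coverage_track` objects.
#' @param pseudocount,exon_threshold,iq_threshold Passed to [pcpa_scores()].
#' @return data.frame keyed by `gene_id` with exon-/iQ-scores and the
#'   `pcpa` flag (NA where not assessable).
#' @export
pcpa_call <- function(models, control, treated, pseudocount = 1,
                      exon_threshold = -1, iq_threshold = 1) {
  genes <- models$genes
  reg <- gene_score_regions(models)
  res <- data.frame(gene_id = genes$gene_id, exon_score = NA_real_,
                    iq_score = NA_real_, iq1 = NA_real_, iq4 = NA_real_,
                    pcpa = NA, stringsAsFactors = FALSE)
  if (is.null(reg) || nrow(reg) == 0L) return(res)
  gr <- function(chr, s, e) {
    GenomicRanges::GRanges(chr, IRanges::IRanges(s, e))
  }
  count_both <- function(track_set, regions) {
    ## regions inherit each gene's strand-matched track
    st <- genes$strand[match(reg$gene_id, genes$gene_id)]
    v <- numeric(nrow(reg))
    for (side in c("+", "-")) {
      idx <- which(st == side)
      if (!length(idx)) next
      trk <- if (side == "+") track_set$plus else track_set$minus
      v[idx] <- region_counts(trk, regions[idx])
    }
    round(v)
  }
  first_rng <- gr(reg$seqnames, reg$first_start, reg$first_end)
  last_rng <- gr(reg$seqnames, reg$last_start, reg$last_end)
  q1_rng <- gr(reg$seqnames, reg$q1_start, reg$q1_end)
  q4_rng <- gr(reg$seqnames, reg$q4_start, reg$q4_end)
  sc <- pcpa_scores(
    first_treated = count_both(treated, first_rng),
    first_control = count_both(control, first_rng),
    last_treated = count_both(treated, last_rng),
    last_control = count_both(control, last_rng),
    iq1 = count_both(treated, q1_rng),
    iq4 = count_both(treated, q4_rng),
    pseudocount = pseudocount, exon_threshold = exon_threshold,
    iq_threshold = iq_threshold)
  idx <- match(reg$gene_id, res$gene_id)
  res$exon_score[idx] <- sc$exon_score
  res$iq_score[idx] <- sc$iq_score
  res$iq1[idx] <- sc$iq1
  res$iq4[idx] <- sc$iq4
  res$pcpa[idx] <- sc$pcpa
  res
}

#' Intronic polyadenylation usage odds ratios
#'
#' For each expressed gene (TPM above `tpm_min`), sums reads of intronic and
#' 3'UTR-associated poly(A) peaks per condition and computes the odds ratio
#' OR = [(intronic_t + c)/(utr_t + c)] / [(intronic_c + c)/(utr_c + c)] with
#' a Haldane-Anscombe correction c = 0.5. Genes with zero intronic reads in
#' both conditions are excluded.
#'
#' @param peaks Annotated peak data.frame (from [annotate_peaks()]).
#' @param tpm Named numeric vector of per-gene TPM.
#' @param treated_col,control_col Count column names.
#' @param tpm_min Expression threshold (default 1).
#' @param correction Haldane-Anscombe pseudocount (default 0.5).
#' @return data.frame with per-gene sums, `odds_ratio` and `excluded`.
#' @export
intronic_usage_or <- function(peaks, tpm, treated_col, control_col,
                              tpm_min = 1, correction = 0.5) {
  expressed <- names(tpm)[tpm > tpm_min]
  if (!length(expressed)) stopf("no gene passes the expression threshold")
  pk <- peaks[!is.na(peaks$gene_id) & peaks$gene_id %in% expressed &
                peaks$category %in% c("intron", "tes_utr"), , drop = FALSE]
  if (nrow(pk) == 0L) stopf("no intronic or 3'UTR peaks on expressed genes")
  agg <- function(col, cat) {
    x <- tapply(pk[[col]][pk$category == cat], pk$gene_id[pk$category == cat],
                sum)
    x
  }
  gids <- sort(unique(pk$gene_id))
  get0 <- function(tab) ifelse(gids %in% names(tab), tab[gids], 0)
  it <- get0(agg(treated_col, "intron"))
  ic <- get0(agg(control_col, "intron"))
  ut <- get0(agg(treated_col, "tes_utr"))
  uc <- get0(agg(control_col, "tes_utr"))
  excluded <- it == 0 & ic == 0
  or <- ((it + correction) / (ut + correction)) /
    ((ic + correction) / (uc + correction))
  or[excluded] <- NA_real_
  data.frame(gene_id = gids, intronic_treated = unname(it),
             intronic_control = unname(ic), utr_treated = unname(ut),
             utr_control = unname(uc), odds_ratio = unname(or),
             excluded = unname(excluded), stringsAsFactors = FALSE)
}

#' Compare two odds-ratio distributions
#'
#' Two-sample Kolmogorov-Smirnov test between the (finite) odds ratios of
#' two contrasts, on the log2 scale.
#'
#' @param or_a,or_b Numeric vectors of odds ratios.
#' @return `htest` object from [stats::ks.test()].
#' @export
or_ks_test <- function(or_a, or_b) {
  a <- log2(or_a[is.finite(or_a) & or_a > 0])
  b <- log2(or_b[is.finite(or_b) & or_b > 0])
  suppressWarnings(ks.test(a, b))
}

#' Differential expression by a negative-binomial Wald test
#'
#' Counts are normalized by the supplied size factors; per-gene dispersion
#' is estimated by the method of moments (stabilized toward the cohort
#' median) and a Wald test is applied to the log2 fold change. Genes with
#' fewer than `min_total` reads across all samples are reported as not
#' significant without a test.
#'
#' @param counts Gene x sample integer count matrix.
#' @param condition Factor/character of sample conditions (two levels).
#' @param size_factors Named per-sample size factors (default all 1).
#' @param treated,control Condition labels; fold changes are
#'   treated/control.
#' @param lfc_threshold Absolute log2 fold-change threshold (default 1).
#' @param p_max Adjusted-p threshold (default 0.1).
#' @param min_total Minimum summed raw counts to test a gene (default 10).
#' @return data.frame with `log2fc`, `p`, `p_adj`, `tested`, `significant`.
#' @export
differential_expression <- function(counts, condition, size_factors = NULL,
                                    treated = "thz", control = "ctrl",
                                    lfc_threshold = 1, p_max = 0.1,
                                    min_total = 10) {
  counts <- as.matrix(counts)
  condition <- as.character(condition)
  if (!all(c(treated, control) %in% condition)) {
    stopf("both conditions need at least one replicate")
  }
  if (is.null(size_factors)) size_factors <- rep(1, ncol(counts))
  norm <- sweep(counts, 2, size_factors, "/")
  ti <- which(condition == treated)
  ci <- which(condition == control)
  mu_t <- rowMeans(norm[, ti, drop = FALSE])
  mu_c <- rowMeans(norm[, ci, drop = FALSE])
  lfc <- log2((mu_t + 0.5) / (mu_c + 0.5))
  ## method-of-moments dispersion, pooled within conditions and stabilized
  ## toward the cohort median (few replicates make per-gene estimates noisy)
  var_within <- function(idx) {
    if (length(idx) < 2L) return(rep(NA_real_, nrow(norm)))
    apply(norm[, idx, drop = FALSE], 1, var)
  }
  v_t <- var_within(ti)
  v_c <- var_within(ci)
  mu_all <- (mu_t + mu_c) / 2
  s2 <- rowMeans(cbind(v_t, v_c), na.rm = TRUE)
  alpha <- (s2 - mu_all) / pmax(mu_all, 0.5)^2
  alpha[!is.finite(alpha)] <- NA
  alpha_med <- median(alpha[alpha > 0], na.rm = TRUE)
  if (!is.finite(alpha_med)) alpha_med <- 0.01
  alpha <- pmin(pmax((ifelse(is.na(alpha), alpha_med, alpha) + alpha_med) / 2,
                     1e-8), 10)
  se_log_mu <- function(mu, n) sqrt((1 / pmax(mu, 0.5) + alpha) / n)
  se_lfc <- sqrt(se_log_mu(mu_t, length(ti))^2 +
                   se_log_mu(mu_c, length(ci))^2) / log(2)
  z <- lfc / se_lfc
  p <- 2 * pnorm(-abs(z))
  tested <- rowSums(counts) >= min_total
  p[!tested] <- NA_real_
  p_adj <- rep(NA_real_, length(p))
  p_adj[tested] <- p.adjust(p[tested], method = "BH")
  significant <- tested & !is.na(p_adj) & p_adj < p_max &
    abs(lfc) > lfc_threshold
  data.frame(gene_id = rownames(counts) %||% seq_len(nrow(counts)),
             log2fc = lfc, p = p, p_adj = p_adj, tested = tested,
             significant = significant, stringsAsFactors = FALSE)
}

#' Flanking windows around genes
#'
#' Builds the strand-aware 2 kb windows 50 bp away from each gene's TSS
#' (upstream) and TES (downstream), removes portions overlapping any gene
#' on the same strand and drops fragments below the minimum length.
#'
#' @param models A `gene_models` object.
#' @param offset Gap between gene boundary and window (default 50 bp).
#' @param width Window width (default 2000 bp).
#' @param min_width Minimum retained fragment length (default 200 bp).
#' @return `GRanges` with `gene_id` and `side` (upstream/downstream)
#'   metadata.
#' @export
build_flanking_windows <- function(models, offset = 50, width = 2000,
                                   min_width = 200) {
  genes <- models$genes
  plus <- genes$strand == "+"
  up_start <- ifelse(plus, genes$start - offset - width, genes$end + offset)
  up_end <- ifelse(plus, genes$start - offset - 1L, genes$end + offset +
                     width - 1L)
  dn_start <- ifelse(plus, genes$end + offset, genes$start - offset - width)
  dn_end <- ifelse(plus, genes$end + offset + width - 1L,
                   genes$start - offset - 1L)
  mk <- function(s, e, side) {
    GenomicRanges::GRanges(genes$seqnames,
                           IRanges::IRanges(pmax(s, 1L), pmax(e, 1L)),
                           strand = genes$strand, gene_id = genes$gene_id,
                           side = side)
  }
  win <- c(mk(up_start, up_end, "upstream"), mk(dn_start, dn_end,
                                                "downstream"))
  gene_gr <- GenomicRanges::GRanges(genes$seqnames,
                                    IRanges::IRanges(genes$start, genes$end),
                                    strand = genes$strand)
  frag <- GenomicRanges::subtract(win, gene_gr, ignore.strand = FALSE)
  lens <- lengths(frag)
  out <- unlist(frag)
  S4Vectors::mcols(out)$gene_id <- rep(win$gene_id, lens)
  S4Vectors::mcols(out)$side <- rep(win$side, lens)
  out[GenomicRanges::width(out) >= min_width]
}

#' Gene-set permutation z-score
#'
#' Compares the mean expression change of a gene set to the distribution of
#' means of `n_random` equal-sized sets drawn uniformly without replacement
#' from the scored universe.
#'
#' @param changes Named numeric vector of per-gene expression changes.
#' @param members Character vector of gene-set members (subset of
#'   `names(changes)`).
#' @param n_random Number of random sets (default 1000).
#' @param seed RNG seed (default 1); recorded on the result.
#' @return List with `z`, `set_mean`, `null_mean`, `null_sd`, `n_set`,
#'   `seed`.
#' @export
geneset_zscore <- function(changes, members, n_random = 1000, seed = 1) {
  members <- intersect(members, names(changes))
  m <- length(members)
  if (m == 0L) stopf("no gene-set member is scored")
  if (m > length(changes) / 2) {
    stopf("gene set larger than half the scored universe")
  }
  set_mean <- mean(changes[members])
  null_means <- with_seed(seed, vapply(seq_len(n_random), function(i) {
    mean(sample(changes, m))
  }, numeric(1)))
  z <- (set_mean - mean(null_means)) / sd(null_means)
  list(z = z, set_mean = set_mean, null_mean = mean(null_means),
       null_sd = sd(null_means), n_set = m, seed = seed)
}

#' Correlation of gene length and expression change
#'
#' Spearman correlation between log2 gene length and log2 fold change, plus
#' a loess smooth for reporting.
#'
#' @param log2fc Numeric vector of per-gene log2 fold changes.
#' @param lengths Matching vector of gene lengths in bp.
#' @param span Loess span (default 0.75).
#' @return List with `rho`, `p`, `n`, and `smooth` (data.frame of
#'   `log2_length`, `fitted`); `rho` is NA when undefined (constant input).
#' @export
length_expression_correlation <- function(log2fc, lengths, span = 0.75) {
  ok <- is.finite(log2fc) & is.finite(lengths) & lengths > 0
  x <- log2(lengths[ok])
  y <- log2fc[ok]
  if (length(x) < 10L) stopf("need at least 10 genes")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(list(rho = NA_real_, p = NA_real_, n = length(x),
                smooth = NULL, degenerate = TRUE))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  lo <- loess(y ~ x, span = span)
  ord <- order(x)
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
       smooth = data.frame(log2_length = x[ord], fitted = fitted(lo)[ord]),
       degenerate = FALSE)
}
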