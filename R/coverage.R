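## Spike-in normalization, strand-specific binning, metagene profiles and
## TSS-proximal transcription dynamics.

#' Read a bedGraph track
#'
#' @param path Path to a 4-column bedGraph file.
#' @param seqlengths Optional named vector of sequence lengths.
#' @return `GRanges` with a `score` column.
#' @export
read_bedgraph <- function(path, seqlengths = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

#' Write a bedGraph track
#'
#' @param gr `GRanges` with a `score` column.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_bedgraph <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   score = format(gr$score, trim = TRUE, scientific = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Spike-in size factors by median-of-ratios
#'
#' Per sample, the factor is the median over spike-in species of the ratio
#' of the sample's count to the species' geometric mean across samples.
#' Species with a zero count in any sample are excluded from the reference
#' (optionally rescued with a pseudocount).
#'
#' @param counts Spike-in species x sample count matrix.
#' @param pseudocount Added to all counts before the computation (default
#'   0; advised when no species has all-positive counts).
#' @return Named numeric vector of size factors (> 0).
#' @export
estimate_size_factors <- function(counts, pseudocount = 0) {
  counts <- as.matrix(counts) + pseudocount
  if (any(counts < 0)) stopf("spike-in counts must be non-negative")
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    stopf(paste("no spike-in has positive counts in every sample;",
                "consider pseudocount > 0"))
  }
  m <- counts[all_pos, , drop = FALSE]
  ref <- exp(rowMeans(log(m)))
  apply(m / ref, 2, median)
}

#' Bin a coverage track
#'
#' Aggregates a bedGraph signal into fixed-width bins: each bin's value is
#' the interval-length-weighted sum of the signal over the bin, divided by
#' the bin width and the sample's size factor, optionally scaled to reads
#' per million (using the raw track's total signal mass as library size).
#'
#' @param gr `GRanges` bedGraph track (per-bp signal in `score`).
#' @param bin_size Bin width in bp (100 for TT-seq, 50 for poly(A) 3'-seq).
#' @param size_factor Sample size factor (default 1).
#' @param seqlengths Named vector of sequence lengths; defaults to the
#'   track's own seqlengths (error if absent).
#' @param per_million Scale values to per-million (default FALSE).
#' @param sample_id,condition,strand Metadata carried on the track.
#' @return Object of class `coverage_track`.
#' @export
bin_coverage <- function(gr, bin_size = 100, size_factor = 1,
                         seqlengths = NULL, per_million = FALSE,
                         sample_id = NA_character_,
                         condition = NA_character_,
                         strand = NA_character_) {
  if (is.null(seqlengths)) seqlengths <- GenomeInfoDb::seqlengths(gr)
  if (any(is.na(seqlengths))) {
    stopf("sequence lengths are required to tile the genome")
  }
  ends <- tapply(GenomicRanges::end(gr),
                 as.character(GenomeInfoDb::seqnames(gr)), max)
  if (any(ends > seqlengths[names(ends)])) {
    stopf("coverage interval extends beyond its sequence length")
  }
  GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
  GenomeInfoDb::seqlengths(gr) <- seqlengths
  total_mass <- sum(as.numeric(gr$score) * GenomicRanges::width(gr))
  cov <- GenomicRanges::coverage(gr, weight = "score")
  bins <- GenomicRanges::tileGenome(seqlengths, tilewidth = bin_size,
                                    cut.last.tile.in.chrom = TRUE)
  sums <- GenomicRanges::binnedAverage(bins, cov, "mean")$mean *
    GenomicRanges::width(bins)
  vals <- sums / bin_size / size_factor
  if (per_million && total_mass > 0) vals <- vals * 1e6 / total_mass
  bins$score <- vals
  out <- list(bins = bins, bin_size = bin_size, size_factor = size_factor,
              total_mass = total_mass, per_million = per_million,
              sample_id = sample_id, condition = condition, strand = strand,
              seqlengths = seqlengths)
  class(out) <- "coverage_track"
  out
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "coverage_track: %s (%s, %s strand), %d bins of %d bp, factor %.3g\n",
    x$sample_id, x$condition, x$strand, length(x$bins), x$bin_size,
    x$size_factor))
  invisible(x)
}

## per-bp RleList from a coverage_track or a raw bedGraph GRanges
track_rle <- function(x) {
  gr <- if (inherits(x, "coverage_track")) x$bins else x
  GenomicRanges::coverage(gr, weight = "score")
}

track_bin_size <- function(x) {
  if (inherits(x, "coverage_track")) x$bin_size else NA_integer_
}

## mean signal over a region per bp, zero-padded beyond sequence ends;
## returned 5'->3' in the sense of `strand`
region_values <- function(rle_list, chrom, start, end, strand = "+") {
  len <- length(rle_list[[chrom]])
  lo <- max(1L, start)
  hi <- min(len, end)
  v <- if (hi >= lo) {
    as.numeric(S4Vectors::window(rle_list[[chrom]], lo, hi))
  } else numeric(0)
  v <- c(numeric(max(0L, lo - start)), v, numeric(max(0L, end - hi)))
  if (strand == "-") v <- rev(v)
  v
}

## area-weighted resampling of a per-bp vector into n equal bins
resample_mean <- function(v, n) {
  cs <- c(0, cumsum(v))
  b <- seq(0, length(v), length.out = n + 1)
  at <- stats::approx(seq(0, length(v)), cs, xout = b)$y
  diff(at) / diff(b)
}

## sum of signal*width over each region (read counts when the track holds
## per-bp read depth)
region_counts <- function(x, regions) {
  rl <- track_rle(x)
  vapply(seq_along(regions), function(i) {
    chrom <- as.character(GenomeInfoDb::seqnames(regions))[i]
    if (!chrom %in% names(rl)) return(0)
    sum(region_values(rl, chrom, GenomicRanges::start(regions)[i],
                      GenomicRanges::end(regions)[i]))
  }, numeric(1))
}

## sum several bedGraph GRanges tracks (replicate merging)
merge_tracks <- function(grs) {
  rl <- Reduce(`+`, lapply(grs, track_rle))
  gr <- methods::as(rl, "GRanges")
  gr <- gr[gr$score != 0]
  sl <- GenomeInfoDb::seqlengths(grs[[1]])
  if (!any(is.na(sl))) GenomeInfoDb::seqlengths(gr) <- sl
  gr
}

#' Metagene profile over gene bodies
#'
#' Each gene body (TSS to TES) is resampled into `n_body_bins` equal bins by
#' area-weighted aggregation; flanking regions of `flank_bp` are binned at
#' `flank_bin` bp. Profiles are strand-aware (bin 1 is at the TSS for both
#' strands); the sense curve uses the track matching the gene's strand and
#' the antisense curve the opposite track. Genes are averaged with equal
#' weight; genes shorter than `n_body_bins` bp are excluded and counted.
#'
#' @param tracks List with elements `plus` and `minus`: `coverage_track`
#'   objects or raw bedGraph `GRanges`.
#' @param models A `gene_models` object (or its `genes` data.frame).
#' @param n_body_bins Number of body bins (default 50).
#' @param flank_bp Flank width in bp (default 2000).
#' @param flank_bin Flank bin width in bp (default 100).
#' @param rescale Also return curves linearly rescaled to [1, 100]
#'   (default FALSE).
#' @return data.frame with `bin`, `region` (upstream/body/downstream),
#'   `sense`, `antisense` (and rescaled columns when requested); the number
#'   of excluded genes is attached as attribute `n_excluded`.
#' @export
metagene_profile <- function(tracks, models, n_body_bins = 50,
                             flank_bp = 2000, flank_bin = 100,
                             rescale = FALSE) {
  genes <- if (inherits(models, "gene_models")) models$genes else models
  if (nrow(genes) == 0L) stopf("no genes supplied")
  keep <- genes$length >= n_body_bins
  n_excluded <- sum(!keep)
  genes <- genes[keep, , drop = FALSE]
  if (nrow(genes) == 0L) stopf("all genes shorter than the body bin count")
  rl <- list("+" = track_rle(tracks$plus), "-" = track_rle(tracks$minus))
  n_flank <- flank_bp %/% flank_bin
  prof_len <- n_body_bins + 2L * n_flank
  acc <- matrix(0, nrow = prof_len, ncol = 2,
                dimnames = list(NULL, c("sense", "antisense")))
  for (i in seq_len(nrow(genes))) {
    st <- genes$strand[i]
    anti <- if (st == "+") "-" else "+"
    s <- genes$start[i]; e <- genes$end[i]
    up <- if (st == "+") c(s - flank_bp, s - 1L) else c(e + 1L, e + flank_bp)
    dn <- if (st == "+") c(e + 1L, e + flank_bp) else c(s - flank_bp, s - 1L)
    for (side in c("sense", "antisense")) {
      use <- if (side == "sense") st else anti
      vu <- region_values(rl[[use]], genes$seqnames[i], up[1], up[2], st)
      vb <- region_values(rl[[use]], genes$seqnames[i], s, e, st)
      vd <- region_values(rl[[use]], genes$seqnames[i], dn[1], dn[2], st)
      prof <- c(resample_mean(vu, n_flank), resample_mean(vb, n_body_bins),
                resample_mean(vd, n_flank))
      acc[, side] <- acc[, side] + prof
    }
  }
  acc <- acc / nrow(genes)
  out <- data.frame(
    bin = seq_len(prof_len),
    region = rep(c("upstream", "body", "downstream"),
                 c(n_flank, n_body_bins, n_flank)),
    sense = acc[, "sense"], antisense = acc[, "antisense"])
  if (rescale) {
    out$sense_rescaled <- rescale_1_100(out$sense)
    out$antisense_rescaled <- rescale_1_100(out$antisense)
  }
  attr(out, "n_excluded") <- n_excluded
  out
}

rescale_1_100 <- function(x) {
  r <- range(x)
  if (diff(r) == 0) return(rep(1, length(x)))
  1 + 99 * (x - r[1]) / diff(r)
}

#' TSS-proximal transcription dynamics
#'
#' Computes, in fixed bins over a window around the TSS, the mean change in
#' read density between treated and control tracks across genes, the rate
#' of change (first difference between consecutive bins, linearly rescaled
#' to the range of the change values), and loess-smoothed curves of both.
#'
#' @param control,treated Lists with `plus`/`minus` tracks
#'   (`coverage_track` or raw bedGraph `GRanges`); binned inputs must share
#'   a bin size.
#' @param models A `gene_models` object or genes data.frame.
#' @param upstream,downstream Window around the TSS in bp (defaults 500 and
#'   10000).
#' @param bin Bin width in bp (default 50).
#' @param span Loess span for the smoothed curves (default 0.2, degree 2).
#' @return data.frame with `center` (bp relative to TSS), `change`,
#'   `change_smooth`, `rate`, `rate_rescaled`, `rate_smooth` (`rate*` is NA
#'   for the first bin).
#' @export
tss_dynamics <- function(control, treated, models, upstream = 500,
                         downstream = 10000, bin = 50, span = 0.2) {
  bs <- c(track_bin_size(control$plus), track_bin_size(control$minus),
          track_bin_size(treated$plus), track_bin_size(treated$minus))
  bs <- bs[!is.na(bs)]
  if (length(bs) && length(unique(bs)) > 1L) {
    stopf("control and treated tracks have mismatched bin sizes")
  }
  genes <- if (inherits(models, "gene_models")) models$genes else models
  rl_c <- list("+" = track_rle(control$plus), "-" = track_rle(control$minus))
  rl_t <- list("+" = track_rle(treated$plus), "-" = track_rle(treated$minus))
  n_bins <- (upstream + downstream) %/% bin
  acc <- numeric(n_bins)
  for (i in seq_len(nrow(genes))) {
    st <- genes$strand[i]
    tss <- if (st == "+") genes$start[i] else genes$end[i]
    win <- if (st == "+") c(tss - upstream, tss + downstream - 1L) else
      c(tss - downstream + 1L, tss + upstream)
    vc <- region_values(rl_c[[st]], genes$seqnames[i], win[1], win[2], st)
    vt <- region_values(rl_t[[st]], genes$seqnames[i], win[1], win[2], st)
    d <- vt - vc
    acc <- acc + colMeans(matrix(d, nrow = bin))
  }
  change <- acc / nrow(genes)
  center <- seq(-upstream, by = bin, length.out = n_bins) + bin / 2
  rate <- diff(change)
  rate_rescaled <- rescale_to(rate, range(change))
  sm_change <- fitted(loess(change ~ center, span = span, degree = 2))
  rc <- center[-1]
  sm_rate <- fitted(loess(rate_rescaled ~ rc, span = span, degree = 2))
  data.frame(center = center, change = change, change_smooth = sm_change,
             rate = c(NA, rate), rate_rescaled = c(NA, rate_rescaled),
             rate_smooth = c(NA, sm_rate))
}

rescale_to <- function(x, target) {
  r <- range(x)
  if (diff(r) == 0) return(rep(mean(target), length(x)))
  target[1] + diff(target) * (x - r[1]) / diff(r)
}

#' Pairwise replicate correlation of binned tracks
#'
#' @param tracks Named list of `coverage_track` objects on identical
#'   binning.
#' @param method Correlation method (default Spearman's rank coefficient).
#' @return Symmetric correlation matrix with unit diagonal; entries
#'   involving a constant track are NA.
#' @export
replicate_correlation <- function(tracks, method = "spearman") {
  if (length(tracks) < 2L) stopf("need at least two tracks")
  vals <- lapply(tracks, function(t) t$bins$score)
  n <- lengths(vals)
  if (length(unique(n)) != 1L) stopf("tracks are not on identical binning")
  m <- do.call(cbind, vals)
  colnames(m) <- names(tracks) %||% paste0("track", seq_along(tracks))
  const <- apply(m, 2, function(x) length(unique(x)) == 1L)
  cc <- suppressWarnings(cor(m, method = method))
  cc[const, ] <- NA
  cc[, const] <- NA
  diag(cc) <- 1
  cc
}
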