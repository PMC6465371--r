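## Synthetic-data generator: a miniature single-chromosome genome with
## planted PCPA truncations, intron retention, expression changes, poly(A)
## sites, U1/PAS motif architecture, internal-priming decoys and spike-ins,
## plus a ground-truth table for every planted effect.

DNA_BASES <- c("A", "C", "G", "T")
DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A")

PAS_MOTIFS <- c("AATAAA", "ATTAAA", "AGTAAA", "TATAAA", "AATATA", "AATACA",
                "CATAAA", "GATAAA", "AATGAA", "ACTAAA", "AAGAAA", "AATAGA")
U1_MOTIFS <- c("GGTGAG", "GGTAAG", "GTGAGT")

#' Simulation configuration
#'
#' Assembles and validates the parameter set driving the synthetic-data
#' generator. Defaults describe the study conditions emulated throughout the
#' package: paired control/treated nascent-RNA coverage with a 5'-proximal
#' signal gain in treated cells, gene-length-dependent truncation at planted
#' intronic poly(A) sites in a quarter of the cohort, intron
#' retention/loss in short genes, a minority of purely differentially
#' expressed genes, internal-priming decoy peaks over planted A-runs, and
#' spike-ins with known per-sample scaling.
#'
#' @param n_genes Number of genes (default 200).
#' @param length_meanlog,length_sdlog Log-normal gene-length parameters in
#'   bp (defaults log(4000), 0.45; lengths clamped to 1.5-30 kb and rounded
#'   to the 50 bp grid).
#' @param noncoding_fraction Fraction of genes given non-coding biotypes,
#'   split between lincRNA (gene-like lengths) and snRNA (short,
#'   single-exon) (default 0.2). Effects are planted on protein-coding genes
#'   only.
#' @param fraction_pcpa Proportion of the longer half of protein-coding
#'   genes given a planted truncation (default 0.5).
#' @param truncation_survival Fraction of pre-truncation coverage remaining
#'   downstream of the planted cleavage site in treated samples (default
#'   0.1).
#' @param fraction_ir Proportion of the shorter half of protein-coding genes
#'   given planted intron retention or loss, split evenly (default 0.4).
#' @param ir_fold Intron coverage multiplier in treated samples for
#'   retention genes (loss genes use its reciprocal; default 4).
#' @param tss_accumulation List with `amplitude` (gain relative to the
#'   gene's base rate), `center` and `width` in bp of the treated 5'
#'   proximal Gaussian signal gain (defaults 2, 1000, 300).
#' @param fraction_de Fraction of otherwise unaffected protein-coding genes
#'   given a pure expression change (default 0.15).
#' @param de_log2fc Planted log2 fold change for those genes (default -2).
#' @param n_artifact_peaks Number of internal-priming decoy peaks placed in
#'   intergenic spacers (default 50).
#' @param artifact_highq_fraction Fraction of decoys drawn with a -log10
#'   q-score above the retention threshold of 5 (default 0.5).
#' @param spikein_scaling Named per-sample scaling factors applied to all
#'   counts of a sample (default 1 for the four TT-seq samples).
#' @param n_spikeins Number of spike-in species (default 50).
#' @param read_depth Expected control exonic TT-seq reads per 50 bp chunk
#'   for a gene of unit expression (default 20).
#' @param intron_level Control intron coverage relative to exons
#'   (default 0.5).
#' @param polya_depth Expected poly(A) 3'-seq reads per gene per sample
#'   (default 200).
#' @param pcpa_shift Fraction of treated poly(A) reads redirected to
#'   intronic sites in truncated genes (default 0.8).
#' @param intronic_pas_per_kb Baseline planted intronic poly(A) sites per kb
#'   (default 0.3).
#' @param pcpa_extra_pas Additional intronic sites planted in truncated
#'   genes (default 2).
#' @param u1_per_kb Named vector of planted U1-motif rates per kb for
#'   truncated (`pcpa`) and other genes (defaults 0.5 and 2; the contrast
#'   plants a lower U1/PAS ratio in truncated genes).
#' @param gc_content Named vector of sequence GC fractions for truncated and
#'   other genes (defaults 0.40 and 0.46).
#' @param spacer Intergenic spacer in bp (default 2000, so flanking-window
#'   logic is exercised without gene overlap).
#' @param seed Integer RNG seed recorded in all outputs (default 1).
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 200,
                              length_meanlog = log(4000),
                              length_sdlog = 0.45,
                              noncoding_fraction = 0.2,
                              fraction_pcpa = 0.5,
                              truncation_survival = 0.1,
                              fraction_ir = 0.4,
                              ir_fold = 4,
                              tss_accumulation = list(amplitude = 2,
                                                      center = 1000,
                                                      width = 300),
                              fraction_de = 0.15,
                              de_log2fc = -2,
                              n_artifact_peaks = 50,
                              artifact_highq_fraction = 0.5,
                              spikein_scaling = c(ctrl_rep1 = 1, ctrl_rep2 = 1,
                                                  thz_rep1 = 1, thz_rep2 = 1),
                              n_spikeins = 50,
                              read_depth = 20,
                              intron_level = 0.5,
                              polya_depth = 200,
                              pcpa_shift = 0.8,
                              intronic_pas_per_kb = 0.3,
                              pcpa_extra_pas = 2,
                              u1_per_kb = c(pcpa = 0.5, other = 2),
                              gc_content = c(pcpa = 0.40, other = 0.46),
                              spacer = 2000,
                              seed = 1) {
  cfg <- as.list(environment())
  props <- c(cfg$noncoding_fraction, cfg$fraction_pcpa,
             cfg$truncation_survival, cfg$fraction_ir, cfg$fraction_de,
             cfg$artifact_highq_fraction, cfg$pcpa_shift)
  if (any(props < 0 | props > 1)) stopf("proportions must lie in [0, 1]")
  if (cfg$read_depth <= 0 || cfg$polya_depth <= 0) {
    stopf("read depths must be positive")
  }
  if (cfg$n_genes < 8) stopf("need at least 8 genes")
  if (cfg$n_artifact_peaks > cfg$n_genes - 1) {
    stopf("more artifact peaks than intergenic spacers")
  }
  class(cfg) <- "simulation_config"
  cfg
}

## random composition of `total` 50-bp units into k parts of >= min_units
rand_units <- function(total, k, min_units) {
  if (k == 1L) return(total)
  extra <- total - k * min_units
  cuts <- sort(sample.int(extra + 1L, k - 1L, replace = TRUE) - 1L)
  diff(c(0L, cuts, extra)) + min_units
}

mutate_motif <- function(motif, noise, fixed = integer(0)) {
  ch <- strsplit(motif, "")[[1]]
  hit <- runif(length(ch)) < noise
  hit[fixed] <- FALSE
  ch[hit] <- sample(DNA_BASES, sum(hit), replace = TRUE)
  ch
}

## draw `n` sense positions from `candidates`, each at least `min_dist`
## from every position in `taken` and from each other
place_positions <- function(n, candidates, taken, min_dist = 60,
                            max_tries = 100) {
  out <- integer(0)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      p <- candidates[sample.int(length(candidates), 1L)]
      if (all(abs(p - c(taken, out)) >= min_dist)) {
        out <- c(out, p)
        ok <- TRUE
        break
      }
    }
    if (!ok) stopf("motif placement collision persisted after %d retries",
                   max_tries)
  }
  sort(out)
}

## Build one gene: exon/intron layout (sense, 50-bp units), planted sites,
## sense sequence.  Returns a list consumed by simulate_genome().
build_gene <- function(len, biotype, is_pcpa, ir_status, de_log2fc, cfg) {
  units <- len %/% 50L
  if (biotype == "snRNA") {
    n_ex <- 1L
    exon_units <- units
    intron_units <- integer(0)
  } else {
    max_ex <- min(12L, (units + 4L) %/% 6L)
    n_ex <- sample(2:max_ex, 1L)
    e_total <- max(2L * n_ex,
                   min(round(0.45 * units), units - 4L * (n_ex - 1L)))
    exon_units <- rand_units(e_total, n_ex, 2L)
    intron_units <- rand_units(units - e_total, n_ex - 1L, 4L)
  }
  widths <- integer(2L * n_ex - 1L)
  widths[seq(1L, length(widths), by = 2L)] <- exon_units * 50L
  if (n_ex > 1L) {
    widths[seq(2L, length(widths), by = 2L)] <- intron_units * 50L
  }
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  is_exon <- rep(c(TRUE, FALSE), length.out = length(widths))
  exons <- cbind(starts[is_exon], ends[is_exon])
  introns <- if (n_ex > 1L) cbind(starts[!is_exon], ends[!is_exon]) else
    matrix(integer(0), ncol = 2)

  ## planted poly(A) architecture (sense coordinates)
  utr_pas <- len - 50L
  taken <- c(utr_pas, as.vector(introns))   # keep sites off junctions
  n_ipas <- 0L
  ipas <- integer(0)
  ipas_intron <- integer(0)
  pcpa_site <- NA_integer_
  pcpa_intron <- NA_integer_
  if (nrow(introns) > 0L && biotype == "protein_coding") {
    cand <- unlist(lapply(seq_len(nrow(introns)), function(j) {
      s <- introns[j, 1] + 50L
      e <- min(introns[j, 2] - 50L, len - 250L)
      if (e >= s) seq(s, e) else integer(0)
    }))
    if (length(cand)) {
      lambda <- cfg$intronic_pas_per_kb * len / 1000
      n_ipas <- rpois(1L, lambda) + if (is_pcpa) cfg$pcpa_extra_pas else 0L
      n_ipas <- min(n_ipas, max(0L, length(cand) %/% 150L))
      if (is_pcpa) n_ipas <- max(n_ipas, 1L)
      if (n_ipas > 0L) {
        ipas <- place_positions(n_ipas, cand, taken)
        taken <- c(taken, ipas)
      }
      if (is_pcpa) {
        k_max <- min(4L, nrow(introns))
        in_early <- vapply(ipas, function(p) {
          j <- which(introns[, 1] <= p & p <= introns[, 2])
          length(j) == 1L && j <= k_max
        }, logical(1))
        if (!any(in_early)) {
          cand_early <- cand[cand <= introns[min(k_max, nrow(introns)), 2]]
          extra <- place_positions(1L, cand_early, taken)
          ipas <- sort(c(ipas, extra))
          taken <- c(taken, extra)
          n_ipas <- n_ipas + 1L
        }
        early <- ipas[vapply(ipas, function(p) {
          j <- which(introns[, 1] <= p & p <= introns[, 2])
          j <= k_max
        }, logical(1))]
        pcpa_site <- early[1]
      }
      ipas_intron <- vapply(ipas, function(p) {
        which(introns[, 1] <= p & p <= introns[, 2])
      }, integer(1))
      if (is_pcpa) pcpa_intron <- ipas_intron[match(pcpa_site, ipas)]
    }
  }

  ## sequence: random background at the gene's GC level
  gc <- if (isTRUE(is_pcpa)) cfg$gc_content[["pcpa"]] else
    cfg$gc_content[["other"]]
  pb <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqv <- sample(DNA_BASES, len, replace = TRUE, prob = pb)

  ## splice sites: donor = 3 exonic + 6 intronic bases, acceptor = last 15
  ## intronic bases; introns destined to carry a poly(A) site get noisier
  ## (less conserved) sites
  if (nrow(introns) > 0L) {
    for (j in seq_len(nrow(introns))) {
      noise <- if (j %in% ipas_intron) 0.35 else 0.1
      s <- introns[j, 1]; e <- introns[j, 2]
      seqv[(s - 3):(s + 5)] <- mutate_motif("CAGGTAAGT", noise,
                                            fixed = c(4L, 5L))
      seqv[(e - 14):e] <- mutate_motif("TTTTTTTTTTTTCAG", noise,
                                       fixed = c(14L, 15L))
    }
  }

  ## PAS hexamers 20-25 bp upstream of each planted cleavage site
  for (p in c(utr_pas, ipas)) seqv[(p - 25):(p - 20)] <- strsplit("AATAAA",
                                                                  "")[[1]]

  ## U1 motifs at the configured per-gene rate
  n_u1 <- 0L
  if (biotype == "protein_coding") {
    rate <- if (isTRUE(is_pcpa)) cfg$u1_per_kb[["pcpa"]] else
      cfg$u1_per_kb[["other"]]
    n_u1 <- rpois(1L, rate * len / 1000)
    if (n_u1 > 0L) {
      cand <- seq(60L, len - 60L)
      pos <- tryCatch(place_positions(n_u1, cand, taken, min_dist = 40),
                      error = function(e) integer(0))
      for (p in pos) {
        m <- sample(U1_MOTIFS, 1L)
        seqv[p:(p + 5L)] <- strsplit(m, "")[[1]]
      }
      n_u1 <- length(pos)
    }
  }

  list(len = len, biotype = biotype, n_exons = n_ex, exons = exons,
       introns = introns, seq = seqv, utr_pas = utr_pas, ipas = ipas,
       ipas_intron = ipas_intron, pcpa_site = pcpa_site,
       pcpa_intron = pcpa_intron, is_pcpa = is_pcpa, ir_status = ir_status,
       de_log2fc = de_log2fc)
}

sense_to_genome <- function(p, start, end, strand) {
  as.integer(if (strand == "+") start + p - 1L else end - p + 1L)
}

revcomp_chars <- function(ch) rev(unname(DNA_COMP[ch]))

## remove every PAS motif occurrence from a sense-oriented character window
scrub_pas <- function(win) {
  repl <- strsplit("CGTCGC", "")[[1]]
  for (iter in 1:10) {
    s <- paste0(win, collapse = "")
    hit <- FALSE
    for (m in PAS_MOTIFS) {
      mm <- gregexpr(m, s, fixed = TRUE)[[1]]
      if (mm[1] != -1L) {
        hit <- TRUE
        for (p in mm) win[p:(p + 5L)] <- repl
        s <- paste0(win, collapse = "")
      }
    }
    if (!hit) return(win)
  }
  stopf("could not scrub PAS motifs from a decoy window")
}

#' Simulate a miniature genome with planted effects
#'
#' Generates a single-chromosome (`chrS`) genome in which genes with 2-12
#' exons and canonical GT..AG introns are separated by fixed intergenic
#' spacers. Each gene carries a 3'UTR poly(A) site (AATAAA planted
#' upstream); truncated genes additionally carry intronic sites in their
#' first four introns and a lower U1/PAS motif ratio. Internal-priming decoy
#' positions are planted over >=22A/25 bp runs in spacers with all PAS
#' motifs scrubbed from their upstream windows.
#'
#' @param config A [simulation_config()].
#' @return List of class `pcpa_simulation` with `genome` (`DNAStringSet`),
#'   `gtf` (data.frame of exon records), `truth` (list with `genes` and
#'   `peaks` data.frames), and `config`.
#' @export
simulate_genome <- function(config = simulation_config()) {
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_genes
    n_nc <- round(cfg$noncoding_fraction * n)
    n_sn <- n_nc %/% 2L
    n_li <- n_nc - n_sn
    biotype <- sample(c(rep("protein_coding", n - n_nc),
                        rep("lincRNA", n_li), rep("snRNA", n_sn)))
    len <- round(rlnorm(n, cfg$length_meanlog, cfg$length_sdlog) / 50) * 50L
    len <- pmin(pmax(len, 1500L), 30000L)
    len[biotype == "snRNA"] <- round(runif(sum(biotype == "snRNA"),
                                           200, 600) / 50) * 50L

    ## plant effects on protein-coding genes: truncation in the longer half,
    ## intron retention/loss in the shorter half, pure DE among the rest
    pc <- which(biotype == "protein_coding")
    ord <- pc[order(-len[pc], pc)]
    long_pc <- ord[seq_len(floor(length(pc) / 2))]
    short_pc <- setdiff(pc, long_pc)
    pcpa_idx <- sort(sample(long_pc, round(cfg$fraction_pcpa *
                                             length(long_pc))))
    ir_idx <- sort(sample(short_pc, round(cfg$fraction_ir *
                                            length(short_pc))))
    ir_status <- rep("none", n)
    if (length(ir_idx)) {
      half <- seq_len(ceiling(length(ir_idx) / 2))
      ir_status[ir_idx[half]] <- "retention"
      ir_status[setdiff(ir_idx, ir_idx[half])] <- "loss"
    }
    rest <- setdiff(pc, c(pcpa_idx, ir_idx))
    de_idx <- sort(sample(rest, round(cfg$fraction_de * n)))
    de <- rep(0, n)
    de[de_idx] <- cfg$de_log2fc
    expr <- rlnorm(n, 0, 0.4)

    genes <- vector("list", n)
    for (i in seq_len(n)) {
      genes[[i]] <- build_gene(len[i], biotype[i], i %in% pcpa_idx,
                               ir_status[i], de[i], cfg)
    }

    ## assemble chromosome: 3 kb lead, `spacer` between genes, 12 kb tail
    lead <- 3000L
    tail_len <- 12000L
    starts <- integer(n)
    pos <- lead
    for (i in seq_len(n)) {
      starts[i] <- pos + 1L
      pos <- pos + len[i] + cfg$spacer
    }
    chrlen <- pos - cfg$spacer + tail_len
    strand <- sample(c("+", "-"), n, replace = TRUE)
    chrom <- sample(DNA_BASES, chrlen, replace = TRUE)
    for (i in seq_len(n)) {
      s <- starts[i]; e <- s + len[i] - 1L
      chrom[s:e] <- if (strand[i] == "+") genes[[i]]$seq else
        revcomp_chars(genes[[i]]$seq)
    }

    ## decoy peaks at spacer centers: planted A-run downstream, PAS-free
    ## upstream window (both in the decoy's sense orientation)
    spacer_mid <- starts[-1L] - cfg$spacer %/% 2L
    decoy_at <- sort(sample(seq_along(spacer_mid), cfg$n_artifact_peaks))
    decoy_pos <- spacer_mid[decoy_at]
    decoy_strand <- sample(c("+", "-"), cfg$n_artifact_peaks, replace = TRUE)
    for (k in seq_len(cfg$n_artifact_peaks)) {
      p <- decoy_pos[k]
      if (decoy_strand[k] == "+") {
        chrom[(p + 5L):(p + 29L)] <- "A"
        win <- scrub_pas(chrom[(p - 100L):(p - 1L)])
        chrom[(p - 100L):(p - 1L)] <- win
      } else {
        chrom[(p - 29L):(p - 5L)] <- "T"
        win <- scrub_pas(revcomp_chars(chrom[(p + 1L):(p + 100L)]))
        chrom[(p + 1L):(p + 100L)] <- revcomp_chars(win)
      }
    }

    genome <- Biostrings::DNAStringSet(paste0(chrom, collapse = ""))
    names(genome) <- "chrS"

    ## truth tables + GTF rows
    gid <- sprintf("g%03d", seq_len(n))
    gtf_rows <- vector("list", n)
    peak_rows <- vector("list", n + 1L)
    g_truth <- vector("list", n)
    for (i in seq_len(n)) {
      g <- genes[[i]]
      s0 <- starts[i]; e0 <- s0 + len[i] - 1L
      ex <- g$exons
      ex_g <- cbind(sense_to_genome(ex[, 1], s0, e0, strand[i]),
                    sense_to_genome(ex[, 2], s0, e0, strand[i]))
      ex_start <- pmin(ex_g[, 1], ex_g[, 2])
      ex_end <- pmax(ex_g[, 1], ex_g[, 2])
      ord <- order(ex_start)
      gtf_rows[[i]] <- data.frame(
        seqnames = "chrS", source = "sim", type = "exon",
        start = ex_start[ord], end = ex_end[ord], score = ".",
        strand = strand[i], frame = ".",
        gene_id = gid[i], transcript_id = paste0(gid[i], ".t1"),
        gene_type = g$biotype, stringsAsFactors = FALSE)
      utr_g <- sense_to_genome(g$utr_pas, s0, e0, strand[i])
      ipas_g <- if (length(g$ipas)) {
        vapply(g$ipas, sense_to_genome, integer(1), s0, e0, strand[i])
      } else integer(0)
      pcpa_g <- if (!is.na(g$pcpa_site)) {
        sense_to_genome(g$pcpa_site, s0, e0, strand[i])
      } else NA_integer_
      sense_seq <- Biostrings::subseq(genome[["chrS"]], s0, e0)
      if (strand[i] == "-") {
        sense_seq <- Biostrings::reverseComplement(sense_seq)
      }
      u1 <- sum(vapply(U1_MOTIFS, function(m) {
        Biostrings::countPattern(m, sense_seq)
      }, integer(1)))
      pas <- Biostrings::countPattern("AATAAA", sense_seq)
      g_truth[[i]] <- data.frame(
        gene_id = gid[i], seqnames = "chrS", start = s0, end = e0,
        strand = strand[i], length = len[i], biotype = g$biotype,
        n_exons = g$n_exons, expression = expr[i],
        pcpa = g$is_pcpa, pcpa_site = pcpa_g,
        pcpa_intron = g$pcpa_intron, ir_status = g$ir_status,
        de_log2fc = g$de_log2fc, utr_pas = utr_g,
        n_intronic_pas = length(ipas_g),
        intronic_pas = paste0(sort(ipas_g), collapse = ";"),
        u1_count = u1, pas_count = pas, stringsAsFactors = FALSE)
      pk <- data.frame(
        position = c(utr_g, sort(ipas_g)),
        strand = strand[i],
        type = c("utr", rep("intronic", length(ipas_g))),
        gene_id = gid[i], artifact = FALSE, stringsAsFactors = FALSE)
      peak_rows[[i]] <- pk
    }
    peak_rows[[n + 1L]] <- data.frame(
      position = decoy_pos, strand = decoy_strand, type = "artifact",
      gene_id = NA_character_, artifact = TRUE, stringsAsFactors = FALSE)
    peaks <- do.call(rbind, peak_rows)
    peaks$peak_id <- sprintf("pk%04d", seq_len(nrow(peaks)))

    out <- list(
      genome = genome,
      gtf = do.call(rbind, gtf_rows),
      truth = list(genes = do.call(rbind, g_truth), peaks = peaks,
                   seed = cfg$seed),
      config = cfg
    )
    class(out) <- "pcpa_simulation"
    out
  })
}

#' @export
print.pcpa_simulation <- function(x, ...) {
  cat(sprintf(
    "pcpa_simulation: %d genes on %s (%d bp), %d planted peaks, seed %d\n",
    nrow(x$truth$genes), names(x$genome)[1], Biostrings::width(x$genome)[1],
    nrow(x$truth$peaks), x$truth$seed))
  invisible(x)
}

tt_sample_names <- function(cfg) names(cfg$spikein_scaling)

## per-gene expected TT-seq read counts per 50-bp sense chunk
gene_chunk_lambda <- function(g, cfg) {
  nchunk <- g$length %/% 50L
  mid <- seq_len(nchunk) * 50L - 25L
  exonic <- rep(FALSE, nchunk)
  ex <- g$exons_sense
  for (j in seq_len(nrow(ex))) {
    exonic[((ex[j, 1] - 1L) %/% 50L + 1L):(ex[j, 2] %/% 50L)] <- TRUE
  }
  base <- cfg$read_depth * g$expression * ifelse(exonic, 1, cfg$intron_level)
  ctrl <- base
  trt <- base * 2^g$de_log2fc
  if (g$ir_status == "retention") trt[!exonic] <- trt[!exonic] * cfg$ir_fold
  if (g$ir_status == "loss") trt[!exonic] <- trt[!exonic] / cfg$ir_fold
  if (isTRUE(g$pcpa) && !is.na(g$pcpa_site_sense)) {
    trt[mid > g$pcpa_site_sense] <- trt[mid > g$pcpa_site_sense] *
      cfg$truncation_survival
  }
  ## treated 5'-proximal accumulation scales with the local polymerase
  ## density (multiplicative), so exon/intron balance is preserved
  acc <- cfg$tss_accumulation
  trt <- trt * (1 + acc$amplitude *
                  exp(-(mid - acc$center)^2 / (2 * acc$width^2)))
  list(ctrl = ctrl, trt = trt, exonic = exonic)
}

## sense exon layout + sense pcpa site recovered from truth genome coords
sense_gene_geometry <- function(tg, gtf) {
  ex <- gtf[gtf$gene_id == tg$gene_id, , drop = FALSE]
  if (tg$strand == "+") {
    es <- ex$start - tg$start + 1L
    ee <- ex$end - tg$start + 1L
  } else {
    es <- tg$end - ex$end + 1L
    ee <- tg$end - ex$start + 1L
  }
  ord <- order(es)
  pc_sense <- if (!is.na(tg$pcpa_site)) {
    if (tg$strand == "+") tg$pcpa_site - tg$start + 1L else
      tg$end - tg$pcpa_site + 1L
  } else NA_integer_
  list(gene_id = tg$gene_id, length = tg$length,
       expression = tg$expression, de_log2fc = tg$de_log2fc,
       ir_status = tg$ir_status, pcpa = tg$pcpa,
       exons_sense = cbind(es[ord], ee[ord]), pcpa_site_sense = pc_sense)
}

#' Simulate TT-seq coverage tracks and spike-in counts
#'
#' Control coverage is uniform over the gene body (introns at a configured
#' relative level) with Poisson noise per 50 bp chunk; treated coverage adds
#' a Gaussian 5'-proximal gain, multiplies coverage downstream of planted
#' truncation sites by the survival fraction, and scales intron coverage of
#' retention/loss genes. Two replicates per condition are independent draws
#' from the same expectation. All counts of a sample (including its
#' spike-ins) are multiplied by the configured per-sample scaling.
#'
#' @param sim A `pcpa_simulation` from [simulate_genome()].
#' @return List with `tracks` (per sample, list of `plus`/`minus` `GRanges`
#'   bedGraph-style tracks whose score is per-bp read depth) and `spikeins`
#'   (species x sample count matrix).
#' @export
simulate_tt_coverage <- function(sim) {
  cfg <- sim$config
  with_seed(cfg$seed + 1L, {
    chrlen <- Biostrings::width(sim$genome)[1]
    nchunk <- chrlen %/% 50L
    lam <- list("+" = list(ctrl = numeric(nchunk), trt = numeric(nchunk)),
                "-" = list(ctrl = numeric(nchunk), trt = numeric(nchunk)))
    tg <- sim$truth$genes
    for (i in seq_len(nrow(tg))) {
      g <- sense_gene_geometry(tg[i, ], sim$gtf)
      lg <- gene_chunk_lambda(g, cfg)
      first <- (tg$start[i] - 1L) %/% 50L + 1L
      idx <- first:(first + length(lg$ctrl) - 1L)
      if (tg$strand[i] == "-") {
        lg$ctrl <- rev(lg$ctrl)
        lg$trt <- rev(lg$trt)
      }
      st <- tg$strand[i]
      lam[[st]]$ctrl[idx] <- lam[[st]]$ctrl[idx] + lg$ctrl
      lam[[st]]$trt[idx] <- lam[[st]]$trt[idx] + lg$trt
    }
    samples <- tt_sample_names(cfg)
    cond <- ifelse(grepl("^ctrl", samples), "ctrl", "trt")
    tracks <- list()
    for (s in seq_along(samples)) {
      sc <- cfg$spikein_scaling[[samples[s]]]
      per_strand <- list()
      for (st in c("+", "-")) {
        mu <- if (cond[s] == "ctrl") lam[[st]]$ctrl else lam[[st]]$trt
        counts <- rpois(nchunk, mu * sc)
        keep <- counts > 0L
        gr <- GenomicRanges::GRanges(
          "chrS",
          IRanges::IRanges(start = (which(keep) - 1L) * 50L + 1L, width = 50L),
          score = counts[keep] / 50)
        GenomeInfoDb::seqlengths(gr) <- chrlen
        per_strand[[if (st == "+") "plus" else "minus"]] <- gr
      }
      tracks[[samples[s]]] <- per_strand
    }
    ab <- rlnorm(cfg$n_spikeins, log(2000), 0.5)
    spike <- vapply(seq_along(samples), function(s) {
      rpois(cfg$n_spikeins, ab * cfg$spikein_scaling[[samples[s]]])
    }, numeric(cfg$n_spikeins))
    dimnames(spike) <- list(sprintf("spike%02d", seq_len(cfg$n_spikeins)),
                            samples)
    list(tracks = tracks, spikeins = spike)
  })
}

#' Simulate a poly(A) 3'-seq peak table
#'
#' Control reads concentrate at the 3'UTR site of each gene (a small
#' fraction at intronic sites); for truncated genes the treated sample
#' redistributes `pcpa_shift` of the reads to intronic sites, weighted
#' toward the planted truncation site. Artifact decoys receive moderate
#' counts; q-scores are drawn so all true peaks pass the retention
#' threshold and a configured fraction of decoys does too.
#'
#' @param sim A `pcpa_simulation`.
#' @return data.frame with BED-like columns (`chrom`, `start`, `end`,
#'   `name`, `qscore`, `strand`) and per-sample count columns `dmso`, `thz`.
#' @export
simulate_polya <- function(sim) {
  cfg <- sim$config
  with_seed(cfg$seed + 2L, {
    tg <- sim$truth$genes
    pk <- sim$truth$peaks
    counts <- matrix(0L, nrow(pk), 2, dimnames = list(NULL, c("dmso", "thz")))
    for (i in seq_len(nrow(tg))) {
      rows <- which(!pk$artifact & pk$gene_id == tg$gene_id[i])
      ut <- rows[pk$type[rows] == "utr"]
      intr <- rows[pk$type[rows] == "intronic"]
      eps <- if (length(intr)) 0.05 else 0
      w_ctrl <- numeric(length(rows))
      w_ctrl[match(ut, rows)] <- 1 - eps
      if (length(intr)) w_ctrl[match(intr, rows)] <- eps / length(intr)
      w_trt <- w_ctrl
      if (isTRUE(tg$pcpa[i]) && length(intr)) {
        w_int <- rep(0.4 / length(intr), length(intr))
        hit <- which(pk$position[intr] == tg$pcpa_site[i])
        if (length(hit)) {
          w_int <- rep(if (length(intr) > 1) 0.4 / (length(intr) - 1) else 0,
                       length(intr))
          w_int[hit] <- 0.6
        }
        w_trt[match(intr, rows)] <- cfg$pcpa_shift * w_int / sum(w_int)
        w_trt[match(ut, rows)] <- 1 - cfg$pcpa_shift
      }
      n_dmso <- rpois(1L, cfg$polya_depth * tg$expression[i])
      n_thz <- rpois(1L, cfg$polya_depth * tg$expression[i])
      counts[rows, "dmso"] <- as.integer(rmultinom(1, n_dmso, w_ctrl))
      counts[rows, "thz"] <- as.integer(rmultinom(1, n_thz, w_trt))
    }
    art <- which(pk$artifact)
    counts[art, "dmso"] <- rpois(length(art), 30)
    counts[art, "thz"] <- rpois(length(art), 30)
    qscore <- numeric(nrow(pk))
    qscore[!pk$artifact] <- round(runif(sum(!pk$artifact), 5, 100), 2)
    hi <- runif(length(art)) < cfg$artifact_highq_fraction
    qscore[art[hi]] <- round(runif(sum(hi), 5, 60), 2)
    qscore[art[!hi]] <- round(runif(sum(!hi), 0, 4.9), 2)
    data.frame(chrom = "chrS", start = pk$position - 1L, end = pk$position,
               name = pk$peak_id, qscore = qscore, strand = pk$strand,
               dmso = counts[, "dmso"], thz = counts[, "thz"],
               stringsAsFactors = FALSE)
  })
}

#' Write the truth table to TSV
#'
#' @param truth The `truth` element of a `pcpa_simulation`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
emit_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- truth$genes
  g$seed <- truth$seed
  p1 <- file.path(dir, "truth_genes.tsv")
  p2 <- file.path(dir, "truth_peaks.tsv")
  write_tsv0(g, p1)
  write_tsv0(truth$peaks, p2)
  invisible(c(p1, p2))
}

#' Read back an emitted truth table
#'
#' @param dir Directory written by [emit_truth()].
#' @return List with `genes`, `peaks`, `seed`.
#' @export
read_truth <- function(dir) {
  g <- read_tsv0(file.path(dir, "truth_genes.tsv"))
  seed <- unique(g$seed)
  g$seed <- NULL
  g$intronic_pas[is.na(g$intronic_pas)] <- ""
  list(genes = g, peaks = read_tsv0(file.path(dir, "truth_peaks.tsv")),
       seed = seed)
}

#' Generate and optionally write a full synthetic dataset
#'
#' Runs [simulate_genome()], [simulate_tt_coverage()] and
#' [simulate_polya()], and, when `dir` is given, writes genome FASTA, GTF,
#' per-sample strand-specific bedGraph tracks (`.plus`/`.minus` suffixes),
#' spike-in and abundance TSVs, the peak table and the truth tables.
#'
#' @param config A [simulation_config()].
#' @param dir Optional output directory.
#' @return List of class `pcpa_dataset` with elements `sim`, `coverage`,
#'   `peaks`, `abundance`, and `paths` (when written).
#' @export
simulate_dataset <- function(config = simulation_config(), dir = NULL) {
  sim <- simulate_genome(config)
  cov <- simulate_tt_coverage(sim)
  peaks <- simulate_polya(sim)
  tg <- sim$truth$genes
  abundance <- data.frame(transcript_id = paste0(tg$gene_id, ".t1"),
                          gene_id = tg$gene_id,
                          tpm = round(tg$expression * 10, 4),
                          stringsAsFactors = FALSE)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(sim$genome, fa)
    gtf <- file.path(dir, "annotation.gtf")
    write_gtf(sim$gtf, gtf)
    track_paths <- character(0)
    for (s in names(cov$tracks)) {
      for (st in c("plus", "minus")) {
        p <- file.path(dir, sprintf("%s.%s.bedGraph", s, st))
        write_bedgraph(cov$tracks[[s]][[st]], p)
        track_paths <- c(track_paths, p)
      }
    }
    sp <- file.path(dir, "spikeins.tsv")
    write_tsv0(data.frame(spikein_id = rownames(cov$spikeins),
                          cov$spikeins, check.names = FALSE), sp)
    pk <- file.path(dir, "peaks.tsv")
    write_tsv0(peaks, pk)
    ab <- file.path(dir, "abundance.tsv")
    write_tsv0(abundance, ab)
    tr <- emit_truth(sim$truth, dir)
    paths <- list(genome = fa, gtf = gtf, tracks = track_paths,
                  spikeins = sp, peaks = pk, abundance = ab, truth = tr)
  }
  out <- list(sim = sim, coverage = cov, peaks = peaks,
              abundance = abundance, paths = paths)
  class(out) <- "pcpa_dataset"
  out
}

write_gtf <- function(gtf_df, path) {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_type "%s";',
                   gtf_df$gene_id, gtf_df$transcript_id, gtf_df$gene_type)
  lines <- paste(gtf_df$seqnames, gtf_df$source, gtf_df$type, gtf_df$start,
                 gtf_df$end, gtf_df$score, gtf_df$strand, gtf_df$frame,
                 attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
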