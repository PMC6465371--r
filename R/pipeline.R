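## End-to-end orchestration: simulate -> annotate -> normalize -> peaks ->
## scores -> determinants -> report, with config validation, logging and
## deterministic outputs.

#' Pipeline configuration
#'
#' Collects paths, thresholds and seeds for [run_pipeline()]. Every printed
#' analysis threshold is a named key with its default value so deviations
#' are visible in the run log. Unknown keys are rejected (they would be
#' unused arguments).
#'
#' @param outdir Output directory.
#' @param simulate Generate inputs with the synthetic-data module
#'   (default TRUE).
#' @param sim A [simulation_config()] used when `simulate` is TRUE.
#' @param paths Named list of input paths when `simulate` is FALSE:
#'   `genome`, `gtf`, `abundance`, `spikeins`, `peaks`, `tracks` (named
#'   list per sample with `plus`/`minus` bedGraph paths), optional `ddr`
#'   (character vector of gene-list files).
#' @param tt_bin,polya_bin Coverage bin sizes in bp (defaults 100, 50).
#' @param flank_bp Metagene flank in bp (default 2000).
#' @param dyn_upstream,dyn_downstream,dyn_bin TSS-dynamics window and bin
#'   (defaults 500, 10000, 50).
#' @param loess_span Loess span for smoothed dynamics curves (default 0.2).
#' @param gene_tpm_min,frac_min,rescue_tpm Transcript selection thresholds
#'   (defaults 2, 0.2, 5).
#' @param qscore_min,diff_min_reads,lr_threshold Differential-peak
#'   thresholds (defaults 5, 64, 1).
#' @param top_n_peaks Peaks ranked in the distribution (default 5000).
#' @param ir_min_exon,ir_min_intron,ir_threshold,ir_p_max Intron-retention
#'   thresholds (defaults 10, 5, 1, 0.05).
#' @param exon_score_threshold,iq_threshold PCPA call thresholds (defaults
#'   -1, 1).
#' @param de_lfc_threshold,de_p_max Differential-expression significance
#'   rule (defaults 1, 0.1).
#' @param usage_tpm_min Expression floor for usage odds ratios (default 1).
#' @param n_random_sets Random sets for the gene-set z-score (default
#'   1000).
#' @param seed Master seed (default 1).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            simulate = TRUE,
                            sim = simulation_config(),
                            paths = NULL,
                            tt_bin = 100, polya_bin = 50,
                            flank_bp = 2000,
                            dyn_upstream = 500, dyn_downstream = 10000,
                            dyn_bin = 50, loess_span = 0.2,
                            gene_tpm_min = 2, frac_min = 0.2,
                            rescue_tpm = 5,
                            qscore_min = 5, diff_min_reads = 64,
                            lr_threshold = 1, top_n_peaks = 5000,
                            ir_min_exon = 10, ir_min_intron = 5,
                            ir_threshold = 1, ir_p_max = 0.05,
                            exon_score_threshold = -1, iq_threshold = 1,
                            de_lfc_threshold = 1, de_p_max = 0.1,
                            usage_tpm_min = 1, n_random_sets = 1000,
                            seed = 1) {
  cfg <- as.list(environment())
  if (!simulate && is.null(paths)) {
    stopf("either simulate = TRUE or input paths are required")
  }
  if (simulate) cfg$sim$seed <- seed
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments
#'   (unknown keys are rejected).
#' @return `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(simulation_config, y$sim)
  do.call(pipeline_config, y)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

combine_normalized <- function(grs, sfs) {
  norm <- mapply(function(g, f) {
    g$score <- g$score / f
    g
  }, grs, sfs, SIMPLIFY = FALSE)
  out <- merge_tracks(norm)
  out$score <- out$score / length(grs)
  out
}

read_named_tracks <- function(track_paths, seqlengths) {
  lapply(track_paths, function(p) {
    list(plus = read_bedgraph(p$plus, seqlengths),
         minus = read_bedgraph(p$minus, seqlengths))
  })
}

#' Run the full analysis pipeline
#'
#' Executes the stages annotation -> coverage -> poly(A) peaks -> per-gene
#' scores -> determinants on simulated or user-supplied inputs, writing
#' every stage's tables under `config$outdir` together with a run log
#' (thresholds, seeds, input checksums). Outputs are deterministic for a
#' fixed config and seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the result bundle (list of all stage outputs).
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  inputs <- stage("inputs", {
    if (cfg$simulate) {
      ds <- simulate_dataset(cfg$sim, file.path(cfg$outdir, "data"))
      samples <- names(ds$coverage$tracks)
      list(genome = ds$sim$genome,
           gtf = ds$paths$gtf,
           abundance = ds$abundance,
           spikeins = ds$coverage$spikeins,
           peaks = ds$peaks,
           tracks = ds$coverage$tracks,
           samples = samples,
           truth = ds$sim$truth,
           files = ds$paths)
    } else {
      p <- cfg$paths
      for (key in c("genome", "gtf", "abundance", "spikeins", "peaks")) {
        if (is.null(p[[key]]) || !file.exists(p[[key]])) {
          stopf("missing input file for '%s'", key)
        }
      }
      genome <- Biostrings::readDNAStringSet(p$genome)
      names(genome) <- sub("\\s.*$", "", names(genome))
      sl <- setNames(Biostrings::width(genome), names(genome))
      sp <- read_tsv0(p$spikeins)
      spikeins <- as.matrix(sp[, -1, drop = FALSE])
      rownames(spikeins) <- sp[[1]]
      list(genome = genome, gtf = p$gtf,
           abundance = read_transcript_quant(p$abundance),
           spikeins = spikeins,
           peaks = read_peaks(p$peaks),
           tracks = read_named_tracks(p$tracks, sl),
           samples = names(p$tracks), truth = NULL,
           files = p)
    }
  })
  genome <- inputs$genome
  seqlens <- setNames(Biostrings::width(genome), names(genome))

  annot <- stage("annotation", {
    keep <- select_transcripts(inputs$abundance, cfg$gene_tpm_min,
                               cfg$frac_min, cfg$rescue_tpm)
    models <- build_gene_models(inputs$gtf, keep_transcripts = keep)
    models <- annotate_gene_classes(models)
    write_gene_models(models, file.path(cfg$outdir, "gene_models.bed12"),
                      file.path(cfg$outdir, "gene_models.tsv"))
    models
  })
  pc_models <- subset_models(annot, annot$genes$gene_id[
    annot$genes$biotype %in% "protein_coding"])

  coverage <- stage("coverage", {
    sf <- estimate_size_factors(inputs$spikeins)
    write_tsv0(data.frame(sample = names(sf), size_factor = sf),
               file.path(cfg$outdir, "size_factors.tsv"))
    samples <- inputs$samples
    cond <- ifelse(grepl("ctrl", samples), "ctrl", "trt")
    binned <- list()
    for (s in samples) {
      for (st in c("plus", "minus")) {
        binned[[paste0(s, ".", st)]] <- bin_coverage(
          inputs$tracks[[s]][[st]], bin_size = cfg$tt_bin,
          size_factor = sf[[s]], seqlengths = seqlens,
          sample_id = s, condition = cond[match(s, samples)], strand = st)
      }
    }
    repcor <- replicate_correlation(binned)
    write_tsv0(data.frame(track = rownames(repcor), round(repcor, 4),
                          check.names = FALSE),
               file.path(cfg$outdir, "replicate_correlation.tsv"))
    merged <- list()
    for (cd in unique(cond)) {
      reps <- samples[cond == cd]
      merged[[cd]] <- list(
        plus = combine_normalized(lapply(inputs$tracks[reps], `[[`, "plus"),
                                  sf[reps]),
        minus = combine_normalized(lapply(inputs$tracks[reps], `[[`,
                                          "minus"), sf[reps]))
    }
    raw_merged <- list()
    for (cd in unique(cond)) {
      reps <- samples[cond == cd]
      raw_merged[[cd]] <- list(
        plus = merge_tracks(lapply(inputs$tracks[reps], `[[`, "plus")),
        minus = merge_tracks(lapply(inputs$tracks[reps], `[[`, "minus")))
    }
    prof <- lapply(merged, metagene_profile, models = annot,
                   flank_bp = cfg$flank_bp, rescale = TRUE)
    for (cd in names(prof)) {
      write_tsv0(prof[[cd]], file.path(cfg$outdir,
                                       sprintf("metagene_%s.tsv", cd)))
    }
    dyn <- tss_dynamics(merged$ctrl, merged$trt, pc_models,
                        upstream = cfg$dyn_upstream,
                        downstream = cfg$dyn_downstream,
                        bin = cfg$dyn_bin, span = cfg$loess_span)
    write_tsv0(dyn, file.path(cfg$outdir, "tss_dynamics.tsv"))
    list(size_factors = sf, binned = binned, merged = merged,
         raw_merged = raw_merged, metagene = prof, dynamics = dyn,
         replicate_correlation = repcor)
  })

  polya <- stage("polya", {
    pk <- if (cfg$simulate) {
      p <- inputs$peaks
      p$position <- p$end
      attr(p, "count_cols") <- c("dmso", "thz")
      p
    } else inputs$peaks
    flt <- filter_internal_priming(pk, genome)
    ann <- annotate_peaks(flt$retained, annot)
    cc <- attr(ann, "count_cols")
    diff <- differential_peaks(ann, a_col = cc[length(cc)], b_col = cc[1],
                               min_qscore = cfg$qscore_min,
                               min_reads = cfg$diff_min_reads,
                               lr_threshold = cfg$lr_threshold)
    dist <- peak_region_distribution(ann, top_n = min(cfg$top_n_peaks,
                                                      nrow(ann)))
    write_tsv0(ann, file.path(cfg$outdir, "peaks_annotated.tsv"))
    write_tsv0(flt$removed, file.path(cfg$outdir, "peaks_removed.tsv"))
    write_tsv0(diff, file.path(cfg$outdir, "peaks_differential.tsv"))
    write_tsv0(dist, file.path(cfg$outdir, "peak_distribution.tsv"))
    list(annotated = ann, removed = flt$removed, differential = diff,
         distribution = dist)
  })

  scores <- stage("scores", {
    genes <- annot$genes
    exon_by_gene <- region_list(annot, "exons")
    intron_by_gene <- region_list(annot, "introns")
    cond_counts <- function(tracks, regions_by_gene) {
      vapply(seq_len(nrow(genes)), function(i) {
        r <- regions_by_gene[[genes$gene_id[i]]]
        if (is.null(r) || length(r) == 0L) return(0)
        trk <- if (genes$strand[i] == "+") tracks$plus else tracks$minus
        round(sum(region_counts(trk, r)))
      }, numeric(1))
    }
    ir_counts <- data.frame(
      gene_id = genes$gene_id,
      exon_treated = cond_counts(coverage$raw_merged$trt, exon_by_gene),
      exon_control = cond_counts(coverage$raw_merged$ctrl, exon_by_gene),
      intron_treated = cond_counts(coverage$raw_merged$trt, intron_by_gene),
      intron_control = cond_counts(coverage$raw_merged$ctrl, intron_by_gene))
    ir <- intron_retention_index(ir_counts, cfg$ir_min_exon,
                                 cfg$ir_min_intron, cfg$ir_threshold,
                                 cfg$ir_p_max)
    pcpa <- pcpa_call(pc_models, coverage$raw_merged$ctrl,
                      coverage$raw_merged$trt,
                      exon_threshold = cfg$exon_score_threshold,
                      iq_threshold = cfg$iq_threshold)
    samples <- inputs$samples
    exonic <- vapply(samples, function(s) {
      cond_counts(inputs$tracks[[s]], exon_by_gene)
    }, numeric(nrow(genes)))
    rownames(exonic) <- genes$gene_id
    de <- differential_expression(
      exonic, ifelse(grepl("ctrl", samples), "ctrl", "thz"),
      coverage$size_factors[samples], treated = "thz", control = "ctrl",
      lfc_threshold = cfg$de_lfc_threshold, p_max = cfg$de_p_max)
    flank <- build_flanking_windows(annot)
    write_tsv0(as.data.frame(flank),
               file.path(cfg$outdir, "flanking_windows.tsv"))
    tpm <- tapply(inputs$abundance$tpm, inputs$abundance$gene_id, sum)
    cc <- attr(polya$annotated, "count_cols")
    usage <- intronic_usage_or(polya$annotated, tpm,
                               treated_col = cc[length(cc)],
                               control_col = cc[1],
                               tpm_min = cfg$usage_tpm_min)
    write_tsv0(usage, file.path(cfg$outdir, "usage_odds_ratio.tsv"))
    zres <- NULL
    ddr <- pipeline_ddr_set(cfg, inputs, annot)
    if (!is.null(ddr)) {
      changes <- setNames(de$log2fc, de$gene_id)
      changes <- changes[is.finite(changes)]
      if (length(intersect(ddr$members, names(changes))) >= 1 &&
          length(ddr$members) <= length(changes) / 2) {
        zres <- geneset_zscore(changes, ddr$members,
                               n_random = cfg$n_random_sets,
                               seed = cfg$seed)
        write_tsv0(data.frame(set = ddr$name, n = zres$n_set, z = zres$z,
                              set_mean = zres$set_mean,
                              null_mean = zres$null_mean,
                              null_sd = zres$null_sd),
                   file.path(cfg$outdir, "geneset_zscore.tsv"))
      }
    }
    lc <- NULL
    pc_ids <- pc_models$genes$gene_id
    de_pc <- de[match(pc_ids, de$gene_id), ]
    if (sum(is.finite(de_pc$log2fc)) >= 10) {
      lc <- length_expression_correlation(
        de_pc$log2fc, genes$length[match(pc_ids, genes$gene_id)])
    }
    list(ir_counts = ir_counts, ir = ir, pcpa = pcpa, de = de,
         flanking = flank, usage = usage, geneset_z = zres,
         length_correlation = lc, ddr = ddr)
  })

  determinants <- stage("determinants", {
    tpm <- tapply(inputs$abundance$tpm, inputs$abundance$gene_id, sum)
    rec <- compute_determinants(pc_models, genome, tpm, polya$annotated)
    write_tsv0(rec, file.path(cfg$outdir, "determinants.tsv"))
    pcpa_genes <- scores$pcpa$gene_id[scores$pcpa$pcpa %in% TRUE]
    tests <- NULL
    if (length(pcpa_genes) > 0) {
      tests <- compare_determinants(rec, pcpa_genes,
                                    ddr_genes = scores$ddr$members)
      write_tsv0(tests, file.path(cfg$outdir, "determinant_tests.tsv"))
    }
    reg <- pas_length_regression(rec, ddr_genes = scores$ddr$members)
    pwms <- tryCatch(build_splice_pwms(pc_models, genome),
                     error = function(e) NULL)
    isc <- NULL
    if (!is.null(pwms)) {
      write_tsv0(data.frame(base = rownames(pwms$donor),
                            round(pwms$donor, 5), check.names = FALSE),
                 file.path(cfg$outdir, "pwm_donor.tsv"))
      write_tsv0(data.frame(base = rownames(pwms$acceptor),
                            round(pwms$acceptor, 5), check.names = FALSE),
                 file.path(cfg$outdir, "pwm_acceptor.tsv"))
      isc <- score_introns(pc_models, genome, pwms,
                           intronic_pas = polya$annotated)
      write_tsv0(isc$scores, file.path(cfg$outdir, "intron_scores.tsv"))
    }
    list(records = rec, tests = tests, regression = reg, pwms = pwms,
         intron_scores = isc)
  })

  bundle <- list(config = cfg, inputs = inputs, models = annot,
                 coverage = coverage, polya = polya, scores = scores,
                 determinants = determinants)
  class(bundle) <- "pcpa_bundle"
  export_report(bundle, cfg$outdir)
  write_run_log(bundle, file.path(cfg$outdir, "run_log.yaml"))
  invisible(bundle)
}

subset_models <- function(models, gene_ids) {
  out <- list(genes = models$genes[models$genes$gene_id %in% gene_ids, ,
                                   drop = FALSE],
              exons = models$exons[models$exons$gene_id %in% gene_ids],
              introns = models$introns[models$introns$gene_id %in% gene_ids])
  attr(out, "length_boundaries") <- attr(models, "length_boundaries")
  class(out) <- "gene_models"
  out
}

region_list <- function(models, what) {
  gr <- models[[what]]
  lst <- S4Vectors::split(gr, factor(gr$gene_id,
                                     levels = models$genes$gene_id))
  as.list(lst)
}

pipeline_ddr_set <- function(cfg, inputs, models) {
  if (!is.null(cfg$paths$ddr)) {
    return(load_gene_set(cfg$paths$ddr, models$genes$gene_id, "DDR"))
  }
  if (cfg$simulate && !is.null(inputs$truth)) {
    ## demonstration set: the genes with a planted expression change
    mem <- inputs$truth$genes$gene_id[inputs$truth$genes$de_log2fc != 0]
    if (length(mem) >= 3) return(list(name = "planted_de", members = mem,
                                      n_unmatched = 0L))
  }
  NULL
}

#' Export the per-gene master report
#'
#' Joins every per-gene score onto the annotation (one row per gene; a
#' left join, so the annotation's gene count is preserved) and writes the
#' master table together with a machine-readable column schema. Missing
#' stages leave their columns absent and are listed in the schema file.
#'
#' @param bundle Result bundle from [run_pipeline()].
#' @param dir Output directory.
#' @return Invisibly, the master table.
#' @export
export_report <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- bundle$models$genes
  master <- g[, intersect(c("gene_id", "seqnames", "start", "end", "strand",
                            "length", "biotype", "biotype_group",
                            "length_class", "n_exons", "n_introns",
                            "representative_transcript"), names(g))]
  missing_stages <- character(0)
  merge_in <- function(master, df, stage_name, drop = "gene_id") {
    if (is.null(df)) {
      missing_stages <<- c(missing_stages, stage_name)
      return(master)
    }
    merge(master, df, by = "gene_id", all.x = TRUE, sort = TRUE)
  }
  sc <- bundle$scores
  master <- merge_in(master, sc$ir, "intron_retention")
  master <- merge_in(master, sc$pcpa, "pcpa")
  master <- merge_in(master,
                     if (is.null(sc$de)) NULL else
                       sc$de[c("gene_id", "log2fc", "p_adj", "significant")],
                     "differential_expression")
  master <- merge_in(master,
                     if (is.null(sc$usage)) NULL else
                       sc$usage[c("gene_id", "odds_ratio", "excluded")],
                     "usage_odds_ratio")
  det <- bundle$determinants$records
  master <- merge_in(master,
                     if (is.null(det)) NULL else
                       det[setdiff(names(det), c("length"))],
                     "determinants")
  write_tsv0(master, file.path(dir, "master_gene_table.tsv"))
  schema <- data.frame(column = names(master),
                       class = vapply(master, function(x) class(x)[1],
                                      character(1)))
  write_tsv0(schema, file.path(dir, "master_gene_table.schema.tsv"))
  if (length(missing_stages)) {
    writeLines(sprintf("missing stage: %s", unique(missing_stages)),
               file.path(dir, "master_gene_table.missing.txt"))
  }
  n_pcpa <- sum(master$pcpa %in% TRUE)
  message(sprintf("report: %d genes, %d called PCPA", nrow(master), n_pcpa))
  invisible(master)
}

write_run_log <- function(bundle, path) {
  cfg <- bundle$config
  thresholds <- cfg[setdiff(names(cfg), c("outdir", "sim", "paths"))]
  thresholds$simulate <- NULL
  files <- unlist(bundle$inputs$files, use.names = TRUE)
  checksums <- if (length(files)) {
    f <- files[file.exists(files)]
    as.list(setNames(unname(tools::md5sum(f)), basename(f)))
  } else list()
  log <- list(
    package = "pcpatools",
    version = as.character(utils::packageVersion("pcpatools")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    simulate = cfg$simulate,
    thresholds = thresholds,
    sim = if (cfg$simulate) unclass(cfg$sim) else NULL,
    input_checksums = checksums
  )
  yaml::write_yaml(log, path)
  invisible(path)
}
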