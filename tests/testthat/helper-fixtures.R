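# Shared fixtures built in code: hand-sized gene models, genomes and
# bedGraph tracks for exercising the interval and motif machinery.

# gene_models object from a genes data.frame and a named list of exon
# data.frames (start, end)
make_gene_models <- function(genes, exons) {
  ex_list <- lapply(names(exons), function(gid) {
    e <- exons[[gid]]
    i <- match(gid, genes$gene_id)
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      genes$seqnames[i], IRanges::IRanges(e$start, e$end),
      strand = genes$strand[i]))
    S4Vectors::mcols(gr)$gene_id <- rep(gid, length(gr))
    gr
  })
  in_list <- lapply(seq_along(ex_list), function(k) {
    i <- match(names(exons)[k], genes$gene_id)
    span <- GenomicRanges::GRanges(
      genes$seqnames[i], IRanges::IRanges(genes$start[i], genes$end[i]),
      strand = genes$strand[i])
    gr <- GenomicRanges::setdiff(span, ex_list[[k]])
    S4Vectors::mcols(gr)$gene_id <- rep(names(exons)[k], length(gr))
    gr
  })
  genes$length <- genes$end - genes$start + 1L
  genes$n_exons <- vapply(ex_list, length, integer(1))[
    match(genes$gene_id, names(exons))]
  genes$n_introns <- vapply(in_list, length, integer(1))[
    match(genes$gene_id, names(exons))]
  out <- list(genes = genes,
              exons = unlist(methods::as(ex_list, "GRangesList")),
              introns = unlist(methods::as(in_list, "GRangesList")))
  class(out) <- "gene_models"
  out
}

# bedGraph-style GRanges with seqlengths
make_track <- function(start, end, score, chrom = "chrT", seqlen = 10000) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               score = score)
  GenomeInfoDb::seqlengths(gr) <- stats::setNames(seqlen, chrom)
  gr
}

# DNAStringSet genome from a plain string
make_genome <- function(seq, name = "chrT") {
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- name
  g
}

# random DNA string
random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small simulated dataset shared by several files (built lazily, cached)
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(simulation_config(
        n_genes = 40, n_artifact_peaks = 10, seed = 42))
    }
    cache
  }
})

merged_condition_tracks <- function(ds) {
  tr <- ds$coverage$tracks
  list(
    ctrl = list(plus = pcpatools:::merge_tracks(list(tr$ctrl_rep1$plus,
                                                     tr$ctrl_rep2$plus)),
                minus = pcpatools:::merge_tracks(list(tr$ctrl_rep1$minus,
                                                      tr$ctrl_rep2$minus))),
    trt = list(plus = pcpatools:::merge_tracks(list(tr$thz_rep1$plus,
                                                    tr$thz_rep2$plus)),
               minus = pcpatools:::merge_tracks(list(tr$thz_rep1$minus,
                                                     tr$thz_rep2$minus))))
}

models_from_dataset <- function(ds) {
  gtf <- tempfile(fileext = ".gtf")
  pcpatools:::write_gtf(ds$sim$gtf, gtf)
  build_gene_models(gtf)
}
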