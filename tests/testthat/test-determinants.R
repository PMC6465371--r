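# a two-gene fixture genome with fully controlled sequence content
det_fixture <- function() {
  # gp (+): 120 bp, two exons [1,40],[81,120], intron [41,80] with GT..AG
  gp <- paste0(
    strrep("C", 20), "GGTGAGGGTAAG", strrep("C", 8),       # 2x U1 in exon 1
    "GTAAGT", strrep("C", 10), "AATAAA", strrep("C", 13), "TTCAG",  # intron
    "AATAAA", strrep("G", 34))                              # exon 2
  stopifnot(nchar(gp) == 120)
  # gm (-): sense sequence with one U1 and no AATAAA, single exon
  gm_sense <- paste0(strrep("C", 30), "GTGAGT", strrep("G", 44))
  gm <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(gm_sense)))
  genome <- make_genome(paste0(gp, strrep("T", 10), gm))
  genes <- data.frame(
    gene_id = c("gp", "gm"), seqnames = "chrT",
    start = c(1, 131), end = c(120, 210), strand = c("+", "-"),
    biotype = "protein_coding")
  exons <- list(gp = data.frame(start = c(1, 81), end = c(40, 120)),
                gm = data.frame(start = 131, end = 210))
  list(genome = genome, models = make_gene_models(genes, exons))
}

test_that("determinants count motifs on the sense strand with overlap", {
  fx <- det_fixture()
  rec <- compute_determinants(fx$models, fx$genome,
                              tpm = c(gp = 12, gm = 3))
  gp <- rec[rec$gene_id == "gp", ]
  # planted: GGTGAG + GGTAAG back to back in exon 1 (the intron's GTAAGT
  # donor is not a recognized U1 motif)
  expect_equal(gp$u1_count, 2L)
  expect_equal(gp$pas_count, 2L)
  expect_equal(gp$u1_pas_ratio, 1)
  expect_equal(gp$first_intron_length, 40)
  expect_equal(gp$n_introns, 1L)
  expect_equal(gp$expression, 12)

  gm <- rec[rec$gene_id == "gm", ]
  # motifs counted on the transcribed (minus) strand
  expect_equal(gm$u1_count, 1L)
  expect_equal(gm$pas_count, 0L)
  expect_equal(gm$u1_pas_ratio, 2)  # (1 + 1)/(0 + 1)
  expect_true(is.na(gm$first_intron_length))
})

test_that("overlapping motif occurrences are all counted", {
  genome <- make_genome(paste0("GGTGAGTGAGT", strrep("C", 89)))
  genes <- data.frame(gene_id = "g", seqnames = "chrT", start = 1,
                      end = 100, strand = "+", biotype = "protein_coding")
  m <- make_gene_models(genes, list(g = data.frame(start = 1, end = 100)))
  rec <- compute_determinants(m, genome)
  # GGTGAG at 1 and GTGAGT at 2 and 6 overlap
  expect_equal(rec$u1_count, 3L)
})

test_that("GC fraction reflects base composition exactly", {
  genome <- make_genome(paste0(strrep("G", 25), strrep("C", 25),
                               strrep("A", 25), strrep("T", 25)))
  genes <- data.frame(gene_id = "g", seqnames = "chrT", start = 1,
                      end = 100, strand = "+", biotype = "protein_coding")
  m <- make_gene_models(genes, list(g = data.frame(start = 1, end = 100)))
  rec <- compute_determinants(m, genome)
  expect_equal(rec$gc_fraction, 0.5)
  expect_equal(rec$pas_count, 0L)
  expect_equal(rec$u1_pas_ratio, 1)  # pseudocount identity for motif-free
  expect_error(compute_determinants(
    make_gene_models(transform(genes, end = 500),
                     list(g = data.frame(start = 1, end = 500))), genome),
    "outside")
})

test_that("determinant group comparisons report calibrated effect sizes", {
  set.seed(17)
  n <- 400
  rec <- data.frame(
    gene_id = paste0("g", 1:n),
    length = rlnorm(n, log(2e4), 0.6),
    first_intron_length = rlnorm(n, log(2e3), 0.8),
    n_introns = rpois(n, 8), gc_fraction = runif(n, 0.35, 0.6),
    expression = rlnorm(n, 2, 1), u1_pas_ratio = rlnorm(n, 0, 0.5),
    n_intronic_pas_sites = rpois(n, 2))
  # identical groups: d = 0 and p near 1
  res0 <- compare_determinants(rec, rec$gene_id)
  expect_true(all(abs(res0$d) < 1e-12))
  expect_true(all(res0$p > 0.5))

  # shift a small flagged group's length by one pooled SD; d against all
  # genes is slightly diluted by the group's own membership
  rec1 <- rec
  grp <- paste0("g", 1:40)
  sdl <- sd(rec1$length)
  rec1$length[1:40] <- rec1$length[1:40] + sdl
  res1 <- compare_determinants(rec1, grp)
  d_len <- res1$d[res1$determinant == "length"]
  expect_gt(d_len, 0.6)
  expect_lt(d_len, 1.2)

  # d changes sign when the shift sits in the complement instead
  rec2 <- rec
  rec2$length[41:400] <- rec2$length[41:400] + sdl
  res2 <- compare_determinants(rec2, grp)
  expect_lt(res2$d[res2$determinant == "length"], 0)

  # single-member group: p computable, small-sample caveat flagged
  res3 <- compare_determinants(rec, "g1")
  expect_true(all(res3$small_sample))
  expect_true(all(is.finite(res3$p)))
})

test_that("quadratic regression recovers planted coefficients", {
  set.seed(23)
  x <- runif(400, 0, 4)
  y <- 1 + 2 * x + 0.5 * x^2 + rnorm(400, 0, 0.1)
  rec <- data.frame(gene_id = paste0("g", 1:400), length = x,
                    n_intronic_pas_sites = y)
  fit <- pas_length_regression(rec)$fit_all
  est <- coef(summary(fit))
  expect_lt(abs(est[1, "Estimate"] - 1), 3 * est[1, "Std. Error"])
  expect_lt(abs(est[2, "Estimate"] - 2), 3 * est[2, "Std. Error"])
  expect_lt(abs(est[3, "Estimate"] - 0.5), 3 * est[3, "Std. Error"])

  # flagged genes with +2 excess sites at all lengths
  rec2 <- rec
  ddr <- paste0("g", 1:60)
  rec2$n_intronic_pas_sites[1:60] <- rec2$n_intronic_pas_sites[1:60] + 2
  # the all-genes fit absorbs part of the planted offset, so the median
  # prediction difference sits near +2 without matching it exactly
  reg <- pas_length_regression(rec2, ddr_genes = ddr)
  expect_lt(abs(reg$median_diff - 2), 0.5)
  expect_lt(reg$p, 0.01)

  # a random subset deviates around zero
  reg0 <- pas_length_regression(rec, ddr_genes = sample(rec$gene_id, 60))
  expect_lt(abs(reg0$median_diff), 0.1)

  expect_warning(pas_length_regression(rec, ddr_genes = c("g1", "g2")),
                 "skipped")
})

test_that("regression predictions converge with sample size", {
  rmse_at <- function(n, seed) {
    set.seed(seed)
    x <- runif(n, 0, 4)
    y <- 1 + 2 * x + 0.5 * x^2 + rnorm(n, 0, 0.5)
    rec <- data.frame(gene_id = seq_len(n), length = x,
                      n_intronic_pas_sites = y)
    fit <- pas_length_regression(rec)$fit_all
    sqrt(mean((predict(fit) - (1 + 2 * x + 0.5 * x^2))^2))
  }
  small <- mean(vapply(1:5, function(s) rmse_at(50, s), numeric(1)))
  large <- mean(vapply(1:5, function(s) rmse_at(2000, s), numeric(1)))
  expect_lt(large, small)
})

test_that("splice-site PWMs are anchored, normalized and tally counts", {
  ds <- small_dataset()
  models <- models_from_dataset(ds)
  pc <- ds$sim$truth$genes$gene_id[
    ds$sim$truth$genes$biotype == "protein_coding"]
  models_pc <- pcpatools:::subset_models(models, pc)
  pwms <- build_splice_pwms(models_pc, ds$sim$genome)
  expect_equal(dim(pwms$donor), c(4L, 9L))
  expect_equal(dim(pwms$acceptor), c(4L, 15L))
  expect_true(all(abs(colSums(pwms$donor) - 1) < 1e-12))
  expect_true(all(abs(colSums(pwms$acceptor) - 1) < 1e-12))
  # intron +1/+2 are G,T in every contributing donor (columns 4 and 5)
  expect_gt(pwms$donor["G", 4], 0.99)
  expect_gt(pwms$donor["T", 5], 0.99)
  # acceptor ends in A,G
  expect_gt(pwms$acceptor["A", 14], 0.99)
  expect_gt(pwms$acceptor["G", 15], 0.99)
})

test_that("PWM frequencies match a hand tally with pseudocounts", {
  # four hand-written donors; column 1 tallies C,C,A,G
  genes <- data.frame(
    gene_id = paste0("g", 1:4), seqnames = "chrT",
    start = c(1, 201, 401, 601), end = c(100, 300, 500, 700),
    strand = "+", biotype = "protein_coding")
  exon_of <- function(s) list(data.frame(start = c(s, s + 70),
                                         end = c(s + 29, s + 99)))
  exons <- c(exon_of(1), exon_of(201), exon_of(401), exon_of(601))
  names(exons) <- genes$gene_id
  donors <- c("CAGGTAAGT", "CTGGTAAGA", "AAGGTGAGT", "GCGGTAAGT")
  seqs <- vapply(seq_len(4), function(i) {
    intron <- paste0(substr(donors[i], 4, 9), strrep("C", 19),
                     "TTTTTTTTTTTTCAG")
    paste0(strrep("G", 27), substr(donors[i], 1, 3), intron,
           strrep("G", 30))
  }, character(1))
  genome <- make_genome(paste0(seqs[1], strrep("T", 100), seqs[2],
                               strrep("T", 100), seqs[3],
                               strrep("T", 100), seqs[4]))
  m <- make_gene_models(genes, exons)
  pwms <- build_splice_pwms(m, genome, min_qualifying = 4)
  # column 1: two C, one A, one G; pseudocount 0.5, denominator 4 + 2
  expect_equal(unname(pwms$donor[, 1]),
               c(1.5, 2.5, 1.5, 0.5) / 6)
  # column 4 (intron +1) is all G
  expect_equal(unname(pwms$donor["G", 4]), 4.5 / 6)
  expect_error(build_splice_pwms(m, genome, min_qualifying = 20), "20")

  # scoring identities: uniform PWM scores 0; consensus scores maximally
  sc <- score_introns(m, genome, pwms)
  uniform <- pwms
  uniform$donor[] <- 0.25
  uniform$acceptor[] <- 0.25
  sc0 <- score_introns(m, genome, uniform)
  expect_true(all(abs(sc0$scores$score) < 1e-12))
  # hand log-odds for the first intron, donor part
  expected_donor <- sum(log2(pwms$donor[cbind(
    match(strsplit("CAGGTAAGT", "")[[1]], c("A", "C", "G", "T")),
    1:9)] / 0.25))
  expect_equal(sc$scores$donor_score[1], expected_donor)
})

test_that("intron scores separate groups with planted splice-site decay", {
  ds <- small_dataset()
  models <- models_from_dataset(ds)
  pc <- ds$sim$truth$genes$gene_id[
    ds$sim$truth$genes$biotype == "protein_coding"]
  models_pc <- pcpatools:::subset_models(models, pc)
  pwms <- build_splice_pwms(models_pc, ds$sim$genome)
  pk <- ds$peaks
  pk$position <- pk$end
  ann <- annotate_peaks(pk, models)
  res <- score_introns(models_pc, ds$sim$genome, pwms, intronic_pas = ann)
  expect_false(is.null(res$comparison))
  # the generator plants noisier splice sites in poly(A)-carrying introns
  expect_lt(res$comparison$d, 0)
})
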