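test_that("IR index arithmetic matches hand evaluation", {
  counts <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    exon_treated = c(9, 40, 8), exon_control = c(4, 40, 8),
    intron_treated = c(4, 40, 40), intron_control = c(9, 40, 40))
  # g1: exon ratio 10/5 = 2, intron ratio 5/10 = 0.5, IR = log2(0.25) = -2
  res <- intron_retention_index(counts, min_exon = 0, min_intron = 0)
  expect_equal(res$ir_index[1], -2)
  # all equal counts: IR exactly 0, class none
  expect_equal(res$ir_index[2], 0)
  expect_equal(as.character(res$ir_class[2]), "none")
  # the coverage minimum excludes genes with 8 exonic reads in both
  strict <- intron_retention_index(counts)
  expect_false(strict$ir_tested[3])
  expect_true(is.na(strict$ir_index[3]))
  expect_error(intron_retention_index(transform(counts,
                                                exon_treated = -1)),
               "negative")
})

test_that("IR index is antisymmetric under condition swap", {
  set.seed(21)
  counts <- data.frame(
    gene_id = paste0("g", 1:30),
    exon_treated = rpois(30, 200), exon_control = rpois(30, 150),
    intron_treated = rpois(30, 80), intron_control = rpois(30, 120))
  fwd <- intron_retention_index(counts, min_exon = 0, min_intron = 0)
  swapped <- counts
  names(swapped) <- c("gene_id", "exon_control", "exon_treated",
                      "intron_control", "intron_treated")
  rev <- intron_retention_index(swapped, min_exon = 0, min_intron = 0)
  expect_equal(rev$ir_index, -fwd$ir_index)
  expect_equal(rev$ir_p, fwd$ir_p)
})

test_that("PCPA scores match hand arithmetic and the call is a conjunction", {
  # last exon lfc log2(26/101), first exon lfc 0, iQ log2(81/11)
  s <- pcpa_scores(first_treated = 100, first_control = 100,
                   last_treated = 25, last_control = 100,
                   iq1 = 80, iq4 = 10)
  expect_equal(s$exon_score, log2(26 / 101), tolerance = 1e-12)
  expect_equal(round(s$exon_score, 2), -1.96)
  expect_equal(round(s$iq_score, 2), 2.88)
  expect_true(s$pcpa)

  # perfect null: both scores zero
  s0 <- pcpa_scores(50, 50, 50, 50, 30, 30)
  expect_equal(s0$exon_score, 0)
  expect_equal(s0$iq_score, 0)
  expect_false(s0$pcpa)

  # exon-score alone is not enough
  s1 <- pcpa_scores(800, 100, 100, 100, 20, 14)
  expect_lt(s1$exon_score, -1)
  expect_lt(s1$iq_score, 1)
  expect_false(s1$pcpa)

  # without the pseudocount the scores are the raw log ratios
  s2 <- pcpa_scores(100, 100, 25, 100, 80, 10, pseudocount = 0)
  expect_equal(s2$exon_score, -2)
  expect_equal(s2$iq_score, 3)
})

test_that("PCPA counting is strand-aware and skips single-exon genes", {
  genes <- data.frame(
    gene_id = c("gm", "single"), seqnames = "chrT",
    start = c(1001, 8001), end = c(5000, 9000), strand = c("-", "+"),
    biotype = "protein_coding")
  exons <- list(
    gm = data.frame(start = c(1001, 4001), end = c(2000, 5000)),
    single = data.frame(start = 8001, end = 9000))
  m <- make_gene_models(genes, exons)
  # for the minus-strand gene the first exon is the rightmost one; plant
  # treated loss on the genomic left (sense last exon) and a treated
  # surplus in the sense-first quarter of the intron (genomic right part)
  ctrl <- list(plus = make_track(1, 10000, 1),
               minus = make_track(1, 10000, 1))
  trt_minus <- make_track(c(1001, 2001, 3501, 4001),
                          c(2000, 3500, 4000, 5000),
                          c(0.1, 0.2, 3, 1))
  trt <- list(plus = make_track(1, 10000, 1), minus = trt_minus)
  res <- pcpa_call(m, ctrl, trt)
  gm <- res[res$gene_id == "gm", ]
  expect_lt(gm$exon_score, -1)
  expect_gt(gm$iq_score, 1)
  expect_true(gm$pcpa)
  expect_true(is.na(res$pcpa[res$gene_id == "single"]))
})

test_that("usage odds ratios follow the corrected cross-ratio", {
  pk <- data.frame(
    chrom = "c", position = 1:6, strand = "+", name = paste0("p", 1:6),
    qscore = 10,
    category = factor(c("intron", "tes_utr", "intron", "tes_utr",
                        "intron", "tes_utr"),
                      levels = c("tes_utr", "exon", "intron", "intergenic")),
    gene_id = c("g1", "g1", "g2", "g2", "g3", "g3"),
    thz = c(20, 5, 10, 10, 0, 30), dmso = c(5, 20, 10, 10, 0, 25))
  tpm <- c(g1 = 10, g2 = 10, g3 = 10, g4 = 0.5)
  res <- intronic_usage_or(pk, tpm, treated_col = "thz",
                           control_col = "dmso")
  # (20.5/5.5)/(5.5/20.5)
  expect_equal(res$odds_ratio[res$gene_id == "g1"],
               (20.5 / 5.5) / (5.5 / 20.5), tolerance = 1e-12)
  expect_equal(round(res$odds_ratio[res$gene_id == "g1"], 1), 13.9)
  # identical counts across conditions -> OR 1
  expect_equal(res$odds_ratio[res$gene_id == "g2"], 1)
  # zero intronic reads in both conditions -> excluded
  expect_true(res$excluded[res$gene_id == "g3"])
  expect_true(is.na(res$odds_ratio[res$gene_id == "g3"]))
  # TPM filter removes low-expression genes up front
  expect_false("g4" %in% res$gene_id)

  ks <- or_ks_test(c(1, 2, 4, 8, 16), c(1, 1.1, 0.9, 1.2, 1))
  expect_s3_class(ks, "htest")
})

test_that("differential expression respects the printed significance rule", {
  # identical replicate counts across conditions: lfc 0, not significant
  m <- matrix(rep(c(100, 200, 100, 200), each = 6), nrow = 6,
              dimnames = list(paste0("g", 1:6), NULL))
  de <- differential_expression(m, c("ctrl", "ctrl", "thz", "thz"))
  expect_true(all(de$log2fc == 0))
  expect_false(any(de$significant))

  # |lfc| below 1 is never significant no matter how small the p-value
  set.seed(8)
  base <- rpois(50, 10000)
  m2 <- cbind(base, rpois(50, base), rpois(50, base * 2^0.9),
              rpois(50, base * 2^0.9))
  rownames(m2) <- paste0("g", 1:50)
  de2 <- differential_expression(m2, c("ctrl", "ctrl", "thz", "thz"))
  expect_true(all(abs(de2$log2fc) < 1))
  expect_false(any(de2$significant))

  # low-count genes are reported untested and not significant
  m3 <- rbind(g_low = c(1, 0, 2, 1), g_ok = c(500, 520, 100, 110))
  de3 <- differential_expression(m3, c("ctrl", "ctrl", "thz", "thz"))
  expect_false(de3$tested[1])
  expect_false(de3$significant[1])
  expect_true(de3$significant[2])
  expect_error(differential_expression(m3, rep("ctrl", 4)), "condition")
})

test_that("planted expression changes are recovered with the right sign", {
  set.seed(14)
  n <- 100
  base <- rpois(n, 600)
  down <- rep(c(TRUE, FALSE), each = n / 2)
  mu_t <- ifelse(down, base / 4, base)
  m <- cbind(rpois(n, base), rpois(n, base), rpois(n, mu_t), rpois(n, mu_t))
  rownames(m) <- paste0("g", 1:n)
  de <- differential_expression(m, c("ctrl", "ctrl", "thz", "thz"))
  hit <- de$significant & de$log2fc < 0
  expect_gte(mean(hit[down]), 0.9)
  expect_lte(mean(de$significant[!down]), 0.05)
})

test_that("flanking windows subtract same-strand neighbors only", {
  genes <- data.frame(
    gene_id = c("iso", "a", "b_same", "c", "d_opp"), seqnames = "chrT",
    start = c(5001, 20001, 26001, 40001, 46001),
    end = c(10000, 25000, 30000, 45000, 50000),
    strand = c("+", "+", "+", "+", "-"),
    biotype = "protein_coding")
  exons <- lapply(seq_len(nrow(genes)), function(i) {
    data.frame(start = genes$start[i], end = genes$end[i])
  })
  names(exons) <- genes$gene_id
  m <- make_gene_models(genes, exons)
  w <- build_flanking_windows(m)
  iso_up <- w[w$gene_id == "iso" & w$side == "upstream"]
  iso_dn <- w[w$gene_id == "iso" & w$side == "downstream"]
  expect_equal(GenomicRanges::start(iso_up), 5001 - 50 - 2000)
  expect_equal(GenomicRanges::end(iso_up), 5001 - 51)
  expect_equal(GenomicRanges::start(iso_dn), 10000 + 50)
  expect_equal(GenomicRanges::end(iso_dn), 10000 + 50 + 1999)

  # same-strand neighbor 1 kb downstream truncates the window to the gap
  a_dn <- w[w$gene_id == "a" & w$side == "downstream"]
  expect_equal(GenomicRanges::start(a_dn), 25050)
  expect_equal(GenomicRanges::end(a_dn), 26000)

  # opposite-strand neighbor leaves the window untouched
  c_dn <- w[w$gene_id == "c" & w$side == "downstream"]
  expect_equal(GenomicRanges::width(c_dn), 2000)

  # a fragment shrunk below 200 bp is dropped
  genes2 <- genes[1:2, ]
  genes2$start[2] <- 10151   # gap of 100 bp after the 50 bp offset
  genes2$end[2] <- 15000
  exons2 <- list(iso = exons$iso,
                 a = data.frame(start = 10151, end = 15000))
  m2 <- make_gene_models(genes2, exons2)
  w2 <- build_flanking_windows(m2)
  expect_length(w2[w2$gene_id == "iso" & w2$side == "downstream"], 0)
})

test_that("gene-set z-scores are calibrated and detect planted shifts", {
  set.seed(4)
  changes <- setNames(rnorm(2000, 0, 0.5), paste0("g", 1:2000))
  null_set <- sample(names(changes), 100)
  z0 <- geneset_zscore(changes, null_set, seed = 11)
  expect_lt(abs(z0$z), 3)

  shifted <- changes
  shifted[null_set] <- shifted[null_set] - 1
  z1 <- geneset_zscore(shifted, null_set, seed = 11)
  expect_lt(z1$z, -3)

  # a set mean equal to the global mean gives |z| < 0.5
  ranked <- sort(changes)
  balanced <- names(ranked)[c(seq(1, 2000, by = 40),
                              seq(2000, 1, by = -40))]
  zb <- geneset_zscore(changes, balanced, seed = 11)
  expect_lt(abs(zb$z), 0.5)

  expect_error(geneset_zscore(changes, names(changes)[1:1500]), "half")
})

test_that("length-expression correlation recovers planted trends", {
  set.seed(6)
  len <- exp(runif(300, log(2e3), log(2e5)))
  lfc <- -0.5 * log2(len) + rnorm(300, 0, 0.2)
  res <- length_expression_correlation(lfc, len)
  expect_lt(res$rho, -0.8)
  expect_lt(res$p, 1e-10)
  shuf <- length_expression_correlation(sample(lfc), len)
  expect_lt(abs(shuf$rho), 0.1)
  flat <- length_expression_correlation(rep(1, 300), len)
  expect_true(flat$degenerate)
  expect_error(length_expression_correlation(lfc[1:5], len[1:5]), "10")
})
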