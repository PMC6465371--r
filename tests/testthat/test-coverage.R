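test_that("size factors follow the median-of-ratios construction", {
  m <- cbind(A = c(10, 20, 40), B = c(10, 20, 40))
  expect_equal(unname(estimate_size_factors(m)), c(1, 1))

  m2 <- cbind(A = c(10, 20, 40), B = 2 * c(10, 20, 40))
  sf <- estimate_size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)

  # hand oracle: per-species geometric means sqrt(200), sqrt(200), 40;
  # ratios A = {0.707, 1.414, 1}, B = {1.414, 0.707, 1}; medians 1 and 1
  m3 <- cbind(A = c(10, 20, 40), B = c(20, 10, 40))
  sf3 <- estimate_size_factors(m3)
  expect_equal(unname(sf3), c(1, 1))

  # scale equivariance: scaling one sample by c scales the factor ratio by
  # c (the geometric-mean reference absorbs a common constant)
  m4 <- cbind(A = c(30, 50, 80, 120), B = c(25, 60, 70, 140))
  sf4 <- estimate_size_factors(m4)
  m5 <- m4; m5[, "B"] <- m5[, "B"] * 3
  sf5 <- estimate_size_factors(m5)
  expect_equal(sf5[["B"]] / sf5[["A"]], 3 * sf4[["B"]] / sf4[["A"]])

  z <- cbind(A = c(0, 5), B = c(3, 0))
  expect_error(estimate_size_factors(z), "pseudocount")
  expect_silent(estimate_size_factors(z, pseudocount = 1))
})

test_that("size factors agree with the DESeq2 reference implementation", {
  set.seed(31)
  m <- matrix(rpois(200, lambda = rep(c(200, 400, 800, 1600), each = 50)),
              ncol = 4, dimnames = list(NULL, paste0("s", 1:4)))
  ours <- estimate_size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-4)
})

test_that("coverage binning weights intervals and rescales linearly", {
  # constant unit signal: every complete bin equals 1
  gr <- make_track(1, 1000, 1, seqlen = 1000)
  tr <- bin_coverage(gr, bin_size = 100)
  expect_true(all(tr$bins$score == 1))

  # one interval [1,50] of value 2 inside a 100 bp bin -> bin value 1
  gr2 <- make_track(1, 50, 2, seqlen = 200)
  tr2 <- bin_coverage(gr2, bin_size = 100)
  expect_equal(tr2$bins$score, c(1, 0))

  # doubling the size factor halves every bin
  tr3 <- bin_coverage(gr2, bin_size = 100, size_factor = 2)
  expect_equal(tr3$bins$score, tr2$bins$score / 2)

  # mass conservation: sum(bin value x width) = interval mass / factor
  gr4 <- make_track(c(10, 120, 305), c(70, 260, 420), c(3, 0.5, 7),
                    seqlen = 500)
  tr4 <- bin_coverage(gr4, bin_size = 100, size_factor = 1.7)
  mass_in <- sum(gr4$score * GenomicRanges::width(gr4)) / 1.7
  mass_out <- sum(tr4$bins$score * GenomicRanges::width(tr4$bins))
  expect_equal(mass_out, mass_in)

  out_of_bounds <- GenomicRanges::GRanges("chrT",
                                          IRanges::IRanges(990, 1200),
                                          score = 1)
  expect_error(bin_coverage(out_of_bounds, 100,
                            seqlengths = c(chrT = 1000)), "beyond")
})

test_that("metagene profiles are strand-aware and average across genes", {
  genes <- data.frame(
    gene_id = c("gp", "gm"), seqnames = "chrT",
    start = c(3001, 3001), end = c(4000, 4000), strand = c("+", "-"),
    biotype = "protein_coding")
  exons <- list(gp = data.frame(start = 3001, end = 4000),
                gm = data.frame(start = 3001, end = 4000))

  # uniform signal -> flat body profile
  flat <- list(plus = make_track(1, 10000, 2),
               minus = make_track(1, 10000, 2))
  m1 <- make_gene_models(genes[1, ], exons["gp"])
  p1 <- metagene_profile(flat, m1)
  expect_true(all(abs(p1$sense[p1$region == "body"] - 2) < 1e-12))

  # minus-strand gene with signal only near its TSS (genomic end):
  # profile peaks in the first body bin, not the last
  tss_sig <- list(plus = make_track(1, 1, 0),
                  minus = make_track(3951, 4000, 10))
  m2 <- make_gene_models(genes[2, ], exons["gm"])
  p2 <- metagene_profile(tss_sig, m2)
  body <- p2$sense[p2$region == "body"]
  expect_equal(which.max(body), 1L)
  expect_equal(body[50], 0)

  # two genes with body means 2 and 4 -> averaged body of 3
  two <- data.frame(
    gene_id = c("g1", "g2"), seqnames = "chrT",
    start = c(3001, 6001), end = c(4000, 7000), strand = "+",
    biotype = "protein_coding")
  tr <- list(plus = make_track(c(3001, 6001), c(4000, 7000), c(2, 4)),
             minus = make_track(1, 1, 0))
  m3 <- make_gene_models(two, list(g1 = data.frame(start = 3001, end = 4000),
                                   g2 = data.frame(start = 6001,
                                                   end = 7000)))
  p3 <- metagene_profile(tr, m3)
  expect_true(all(abs(p3$sense[p3$region == "body"] - 3) < 1e-12))
  # equal flanks on both sides, rescaling spans [1, 100]
  p4 <- metagene_profile(tr, m3, rescale = TRUE)
  expect_equal(range(p4$sense_rescaled), c(1, 100))
  expect_equal(sum(p3$region == "upstream"), 20)
  expect_equal(sum(p3$region == "downstream"), 20)
})

test_that("short genes are excluded from metagenes with a count", {
  genes <- data.frame(gene_id = c("ok", "tiny"), seqnames = "chrT",
                      start = c(1001, 5001), end = c(2000, 5030),
                      strand = "+", biotype = "protein_coding")
  m <- make_gene_models(genes,
                        list(ok = data.frame(start = 1001, end = 2000),
                             tiny = data.frame(start = 5001, end = 5030)))
  tr <- list(plus = make_track(1, 10000, 1), minus = make_track(1, 1, 0))
  p <- metagene_profile(tr, m)
  expect_equal(attr(p, "n_excluded"), 1L)
})

test_that("TSS dynamics obey null, localization and difference identities", {
  genes <- data.frame(gene_id = "g", seqnames = "chrT", start = 1001,
                      end = 9000, strand = "+", biotype = "protein_coding")
  m <- make_gene_models(genes, list(g = data.frame(start = 1001,
                                                   end = 9000)))
  base <- make_track(1, 10000, 1)
  # treated == control -> change and rate identically zero
  d0 <- tss_dynamics(list(plus = base, minus = base),
                     list(plus = base, minus = base), m,
                     downstream = 5000)
  expect_true(all(d0$change == 0))
  expect_true(all(d0$rate[-1] == 0))

  # linear change in position -> constant rate
  pos <- seq(1, 10000, by = 50)
  lin <- make_track(pos, pos + 49, 1 + pos / 1000)
  dl <- tss_dynamics(list(plus = base, minus = base),
                     list(plus = lin, minus = lin), m, downstream = 5000)
  expect_lt(diff(range(dl$rate[-1])), 1e-9)

  # planted Gaussian gain centered +1000 -> argmax within one bin
  gain_pos <- seq(1, 10000, by = 50)
  gauss <- 1 + 5 * exp(-((gain_pos + 25) - 2000)^2 / (2 * 300^2))
  gained <- make_track(gain_pos, gain_pos + 49, gauss)
  dg <- tss_dynamics(list(plus = base, minus = base),
                     list(plus = gained, minus = gained), m,
                     downstream = 5000)
  # gene TSS at 1001, so genomic 2000 is +1000 of the TSS
  expect_lt(abs(dg$center[which.max(dg$change)] - 1000), 100)

  # rescaled rate spans the range of the change values
  expect_equal(range(dg$rate_rescaled[-1]), range(dg$change))

  ct50 <- bin_coverage(base, 50)
  ct100 <- bin_coverage(base, 100)
  expect_error(tss_dynamics(list(plus = ct50, minus = ct50),
                            list(plus = ct100, minus = ct100), m),
               "mismatch")
})

test_that("replicate correlations are rank-based, symmetric and guarded", {
  gr_a <- make_track(seq(1, 901, by = 100), seq(100, 1000, by = 100),
                     c(5, 3, 8, 1, 9, 2, 7, 4, 6, 10), seqlen = 1000)
  # antitone transform: bin ranks exactly reversed
  gr_b <- make_track(seq(1, 901, by = 100), seq(100, 1000, by = 100),
                     11 - c(5, 3, 8, 1, 9, 2, 7, 4, 6, 10), seqlen = 1000)
  ta <- bin_coverage(gr_a, 100)
  tb <- bin_coverage(gr_b, 100)
  cc <- replicate_correlation(list(a = ta, b = tb))
  expect_equal(diag(cc), c(a = 1, b = 1))
  expect_equal(cc["a", "b"], -1)
  expect_equal(cc, t(cc))

  const <- bin_coverage(make_track(1, 1000, 2, seqlen = 1000), 100)
  cc2 <- replicate_correlation(list(a = ta, k = const))
  expect_true(is.na(cc2["a", "k"]))
  expect_equal(cc2["a", "a"], 1)
})

test_that("independent replicates of one expectation correlate strongly", {
  ds <- small_dataset()
  sl <- setNames(Biostrings::width(ds$sim$genome), "chrS")
  t1 <- bin_coverage(ds$coverage$tracks$ctrl_rep1$plus, 100,
                     seqlengths = sl)
  t2 <- bin_coverage(ds$coverage$tracks$ctrl_rep2$plus, 100,
                     seqlengths = sl)
  cc <- replicate_correlation(list(r1 = t1, r2 = t2))
  expect_gt(cc["r1", "r2"], 0.8)
})
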