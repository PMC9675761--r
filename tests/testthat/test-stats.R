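test_that("TE density is base-wise window coverage", {
  ann <- data.frame(chrom = "chr1",
                    start = c(0, 30000), end = c(25000, 55000),
                    family = "Alu")
  sv <- data.frame(chrom = "chr1", start = 24000, end = 26000)
  # window [0, 50000): covered [0,25000) + [30000,50000) = 45 kbp
  expect_equal(te_density(sv, ann, "Alu"), 100 * 45000 / 50000)
  expect_equal(te_density(sv, ann, "LINE-1"), 0)
  full <- data.frame(chrom = "chr1", start = 0, end = 1e6, family = "Alu")
  expect_equal(te_density(sv, full, "Alu"), 100)
  # clipping at the chromosome start renormalizes the denominator
  sv2 <- data.frame(chrom = "chr1", start = 0, end = 10000)
  expect_equal(te_density(sv2, ann, "Alu", chrom_length = 1e6),
               100 * 25000 / 30000)
})

test_that("tiled window densities conserve the genome-wide TE fraction", {
  co <- fixture_result()$cohort
  L <- nchar(co$reference$sequence)
  ann <- co$annotation[co$annotation$family == "Alu", ]
  w <- 50000
  mids <- seq(w / 2, L - w / 2, by = w)
  dens <- vapply(seq_along(mids), function(i) {
    sv <- data.frame(chrom = "chrS", start = mids[i], end = mids[i])
    te_density(sv, co$annotation, "Alu", window = w)
  }, 0)
  genome_frac <- 100 * sum(ann$end - ann$start) / L
  expect_equal(mean(dens), genome_frac, tolerance = 0.02)
})

test_that("control windows satisfy the TE-count constraint", {
  co <- fixture_result()$cohort
  sizes <- c(chrS = nchar(co$reference$sequence))
  d <- sample_control_windows(25, sizes, co$annotation, "Alu", seed = 10)
  expect_length(d, 25)
  expect_true(all(d >= 0 & d <= 100))
  expect_identical(d, sample_control_windows(25, sizes, co$annotation,
                                             "Alu", seed = 10))
  none <- co$annotation[co$annotation$family == "none", ]
  expect_error(sample_control_windows(5, sizes, none, "Alu"), "rare")
})

test_that("Welch t matches the textbook formula and degenerates safely", {
  w <- welch_t(c(1, 2, 3, 4), c(2, 3, 4, 5))
  o <- welch_oracle(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(w$t, unname(o["t"]), tolerance = 1e-10)
  expect_equal(w$df, unname(o["df"]), tolerance = 1e-10)
  expect_equal(round(w$t, 3), -1.095)
  expect_equal(w$df, 6)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  ident <- welch_t(c(2, 2), c(2, 2))
  expect_true(ident$degenerate)
  expect_equal(ident$p, 1)
})

test_that("exact binomial p-values match enumeration", {
  expect_equal(binom_two_tailed(1, 10), 0.021484375)
  expect_equal(binom_two_tailed(5, 10), 1.0)
  expect_equal(binom_two_tailed(0, 10), 0.001953125)
  for (k in 0:10)
    expect_equal(binom_two_tailed(k, 10), binom_oracle(k, 10))
  for (k in c(0, 3, 7, 12))
    expect_equal(binom_two_tailed(k, 17, 0.3), binom_oracle(k, 17, 0.3))
  # symmetry under p0 = 0.5
  for (k in 0:6)
    expect_equal(binom_two_tailed(k, 13), binom_two_tailed(13 - k, 13))
  expect_error(binom_two_tailed(0, 0), "positive")
})

test_that("Fisher exact matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1.0)
  expect_equal(fisher_exact_2x2(1, 9, 9, 1), 202 / 184756)
  set.seed(12)
  for (i in 1:25) {
    t <- sample(0:12, 4, replace = TRUE)
    if (sum(t[1:2]) == 0 || sum(t[3:4]) == 0 ||
        sum(t[c(1, 3)]) == 0 || sum(t[c(2, 4)]) == 0) next
    expect_equal(fisher_exact_2x2(t[1], t[2], t[3], t[4]),
                 fisher_oracle(t[1], t[2], t[3], t[4]), tolerance = 1e-9)
    # invariance under simultaneous row and column swaps
    expect_equal(fisher_exact_2x2(t[1], t[2], t[3], t[4]),
                 fisher_exact_2x2(t[4], t[3], t[2], t[1]), tolerance = 1e-12)
  }
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "all-zero")
})

test_that("Spearman handles monotone, tied and constant input", {
  expect_equal(spearman(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman(1:10, -(1:10)^3)$rho, -1)
  x <- c(1, 2, 2, 3, 5, 5, 5, 8)
  y <- c(2, 1, 4, 4, 6, 7, 7, 9)
  rho <- spearman(x, y)$rho
  expect_equal(rho, stats::cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_true(spearman(rep(1, 5), 1:5)$degenerate)
})

test_that("GC content is exact on known strings", {
  expect_equal(gc_content("GCGC"), 100)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("GCAT"), 50)
  expect_error(gc_content(""), "empty")
})

test_that("callable density counts midpoints per 10 Mbp", {
  callable <- data.frame(chrom = c("chr1", "chr2"),
                         start = c(0, 0), end = c(2e7, 1e7))
  ev <- data.frame(chrom = c(rep("chr1", 10), "chr2"),
                   start = c(seq(1e6, 1e7, length.out = 10), 2e7),
                   end = c(seq(1e6, 1e7, length.out = 10) + 1000, 2e7 + 10))
  d <- callable_density(ev, callable)
  expect_equal(d$per_chrom$density[d$per_chrom$chrom == "chr1"], 5.0)
  # the chr2 event midpoint lies outside callable space
  expect_equal(d$per_chrom$n[d$per_chrom$chrom == "chr2"], 0)
  expect_equal(d$genome, 10 / 3e7 * 1e7)
  expect_error(callable_density(ev, callable[0, ]), "empty")
})

test_that("read-depth copy number recovers planted CN and flags low-unique", {
  expect_equal(depth_copy_number(rep(30, 100), 30)$copy_number, 2L)
  r <- depth_copy_number(rep(90, 100), 30)
  expect_equal(r$ratio, 3.0)
  expect_equal(r$copy_number, 6L)
  set.seed(3)
  for (cn in 2:6) {
    depth <- pmax(0, rnorm(2000, 30 * cn / 2, 30 * 0.1))
    expect_equal(depth_copy_number(depth, 30)$copy_number, cn)
  }
  ann <- data.frame(chrom = "c", start = 0, end = 950, family = "Alu")
  r2 <- depth_copy_number(rep(30, 100), 30, locus = c(0, 1000),
                          te_annotation = ann, chrom = "c")
  expect_true(r2$low_unique)
  expect_equal(r2$unique_fraction, 0.05)
  expect_error(depth_copy_number(rep(1, 5), 0), "positive")
})

test_that("ancestral deletion matching applies the 90% size rule", {
  dels <- data.frame(chrom = "chr1", start = c(1000, 5000, 9000),
                     end = c(2000, 6000, 9500), size = c(1000, 1000, 500))
  ins <- data.frame(chrom = "chr1", pos = c(1100, 5100, 9100),
                    size = c(920, 850, 500))
  m <- match_ancestral(dels, ins, window = 300)
  expect_identical(nrow(m), 2L)
  expect_equal(m$size_ratio[1], 0.92)
  expect_equal(m$size_ratio[2], 1.0)
  far <- data.frame(chrom = "chr1", pos = 4000, size = 1000)
  expect_identical(nrow(match_ancestral(dels[1, ], far, window = 300)), 0L)
})

test_that("genic categories partition the callset with exon precedence", {
  genes <- data.frame(chrom = "chr1", start = c(10000, 50000),
                      end = c(30000, 70000), gene = c("G1", "G2"))
  exons <- data.frame(chrom = "chr1",
                      start = c(10000, 25000, 50000),
                      end = c(11000, 26000, 51000),
                      gene = c("G1", "G1", "G2"))
  svs <- data.frame(chrom = "chr1",
                    start = c(12000, 10999, 33000, 80000, 24000),
                    end = c(14000, 12000, 34000, 81000, 27000))
  a <- annotate_genic(svs, genes, exons)
  expect_identical(as.character(a$genic_category),
                   c("intronic", "exonic", "proximal", "intergenic",
                     "exonic"))
  expect_equal(sum(table(a$genic_category)), nrow(svs))
  enr <- genic_enrichment(a$genic_category[1:4],
                          factor(rep("intergenic", 4),
                                 levels = levels(a$genic_category)))
  expect_equal(enr$table["TEMR", "genic"], 3)
  expect_true(enr$p <= 1)
})
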