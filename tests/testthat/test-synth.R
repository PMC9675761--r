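test_that("consensus mutation: identity, strand symmetry, and rate", {
  cons <- fixture_consensus()$Alu
  m0 <- mutate_from_consensus(cons, 0, "+", seed = 1)
  expect_identical(m0$sequence, cons$sequence)
  expect_identical(nrow(m0$substitutions), 0L)

  mrc <- mutate_from_consensus(cons, 0, "-", seed = 1)
  expect_identical(mrc$sequence, revcomp(cons$sequence))

  m <- mutate_from_consensus(cons, 0.1, "+", seed = 7)
  d <- hamming(m$sequence, cons$sequence)
  expect_identical(d, nrow(m$substitutions))
  # binomial(311, 0.1) 99% interval
  ci <- qbinom(c(0.005, 0.995), cons$length, 0.1)
  expect_gte(d, ci[1]); expect_lte(d, ci[2])
  # substitution log permits exact reconstruction
  b <- strsplit(cons$sequence, "")[[1]]
  b[m$substitutions$pos0 + 1L] <- m$substitutions$alt
  expect_identical(paste(b, collapse = ""), m$sequence)
})

test_that("mutation respects truncation, protected and forced positions", {
  cons <- fixture_consensus()$`LINE-1`
  m <- mutate_from_consensus(cons, 0.1, "+", truncate_5p = 400L, seed = 3,
                             protect = 500:520, force_mismatch = 600L)
  expect_identical(nchar(m$sequence), cons$length - 400L)
  expect_false(any(m$substitutions$pos0 %in% 500:520))
  expect_true(600L %in% m$substitutions$pos0)
  expect_false(any(m$substitutions$pos0 < 400L))
  expect_error(mutate_from_consensus(cons, 1.2), "divergence")
})

test_that("build_reference round-trips planted copies and realized divergence", {
  cons <- fixture_consensus()
  pl <- data.frame(position = seq(1000, 91000, by = 10000),
                   family = "Alu",
                   divergence = 0.08, strand = rep(c("+", "-"), 5),
                   truncate_5p = 0L)
  ref <- build_reference(1e5, pl, cons, seed = 21)
  expect_identical(nrow(ref$annotation), 10L)
  expect_identical(nchar(ref$sequence), 100000L)
  for (i in seq_len(10)) {
    a <- ref$annotation[i, ]
    planted <- seq_slice(ref$sequence, a$start, a$end)
    log <- ref$mutation_log[[a$copy_id]]
    b <- strsplit(cons$Alu$sequence, "")[[1]]
    b[log$pos0 + 1L] <- log$alt
    rebuilt <- paste(b, collapse = "")
    if (a$strand == "-") rebuilt <- revcomp(rebuilt)
    expect_identical(planted, rebuilt)
    # realized divergence = substitution count / aligned length
    expect_equal(a$divergence, round(100 * nrow(log) / cons$Alu$length, 2))
  }

  empty <- build_reference(5000, NULL, cons, seed = 2)
  expect_identical(nrow(empty$annotation), 0L)
  expect_identical(nchar(empty$sequence), 5000L)

  bad <- data.frame(position = c(100, 200), family = "Alu",
                    divergence = 0, strand = "+", truncate_5p = 0L)
  expect_error(build_reference(5000, bad, cons), "overlapping")
})

test_that("plant_spec enforces the mechanism contract", {
  expect_error(plant_spec("DEL", "HR", mh_length = 3), "mh_length >= 5")
  expect_error(plant_spec("DEL", "NHE", mh_length = 9), "mh_length <= 4")
  expect_error(plant_spec("INV", "HR", te_orientation = "direct"),
               "opposite orientation")
  expect_error(plant_spec("DEL", "HR", te_orientation = "inverted"),
               "direct orientation")
  sp <- plant_spec("mCNV", "HR", copy_number = 4L)
  expect_identical(sp$copy_number, 4L)
})

test_that("HR deletion planting reproduces the requested microhomology", {
  fx <- fixture_hr_del(mh = 15L)
  tr <- fx$truth
  jc <- compute_microhomology(fx$ref$sequence, tr$start, tr$end, "DEL")
  expect_identical(jc$mh_length, 15L)
  expect_identical(jc$mh_sequence, tr$mh_sequence)
})

test_that("NHE planting carries the junction insertion and no homology", {
  cons <- fixture_consensus()
  sp <- plant_spec("DEL", "NHE", mh_length = 0L, junction_insertion = "ACT")
  pl <- make_te_pair(cons$Alu, sp, seed = 31)
  ref <- build_reference(10000, pl, cons, seed = 32)
  tr <- plant_temr(ref, sp, seed = 33)
  alt <- apply_truth_edit(ref$sequence, tr)
  expect_identical(seq_slice(alt, tr$start, tr$start + 3L), "ACT")
  jc <- compute_microhomology(ref$sequence, tr$start, tr$end, "DEL")
  expect_identical(jc$mh_length, 0L)
})

test_that("inversion planting reverse-complements the inner segment", {
  cons <- fixture_consensus()
  sp <- plant_spec("INV", "HR", mh_length = 8L)
  pl <- make_te_pair(cons$Alu, sp, seed = 41)
  ref <- build_reference(10000, pl, cons, seed = 42)
  tr <- plant_temr(ref, sp, seed = 43)
  alt <- apply_truth_edit(ref$sequence, tr)
  inner_ref <- seq_slice(ref$sequence, tr$start, tr$end)
  inner_alt <- seq_slice(alt, tr$start, tr$end)
  expect_identical(inner_alt, revcomp(inner_ref))
})

test_that("truth edits round-trip into the emitted alternate segment", {
  co <- fixture_result()$cohort
  ref <- co$reference$sequence
  for (i in seq_len(nrow(co$truth))) {
    tr <- co$truth[i, ]
    full <- apply_truth_edit(ref, tr)
    delta <- nchar(ref) - nchar(full)
    expect_identical(seq_slice(full, tr$window_start, tr$window_end - delta),
                     tr$alt_segment)
  }
})

test_that("cohort generation is deterministic under a fixed seed", {
  a <- simulate_temr_cohort(n_events = 6, background_length = 4e5, seed = 9,
                            n_decoys = 5)
  b <- simulate_temr_cohort(n_events = 6, background_length = 4e5, seed = 9,
                            n_decoys = 5)
  expect_identical(a$reference$sequence, b$reference$sequence)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth, b$truth)
})

test_that("jitter-free callsets equal the truth intervals exactly", {
  co <- fixture_result()$cohort
  cs <- simulate_callsets(co$truth, nchar(co$reference$sequence),
                          jitter_sd = 0, fp_rate = 0, seed = 5)
  expect_identical(length(cs), 6L)
  for (d in cs) {
    expect_identical(d$start, co$truth$start)
    expect_identical(d$end, co$truth$end)
  }
})

test_that("forced low support removes an event in filtering", {
  co <- fixture_result()$cohort
  cs <- simulate_callsets(co$truth, nchar(co$reference$sequence),
                          support = list(fixed = list(SR = 4, PR = 9)),
                          seed = 6)
  flt <- filter_calls(do.call(rbind, cs))
  # SR=4 / PR=9 fails the short-read support rule for every SRS caller
  expect_true(all(flt$rejected$technology == "SRS"))
  expect_true(all(flt$rejected$reason == "support"))
  expect_identical(sum(flt$kept$technology == "SRS"), 0L)
  expect_identical(sum(flt$kept$technology == "LRS"), 3L * nrow(co$truth))
})

test_that("jittered callsets perturb breakpoints at the requested scale", {
  co <- fixture_result()$cohort
  cs <- simulate_callsets(co$truth, nchar(co$reference$sequence),
                          jitter_sd = 10, seed = 8)
  dev <- unlist(lapply(cs, function(d) d$start - co$truth$start))
  expect_gt(stats::sd(dev), 5)
  expect_lt(stats::sd(dev), 15)
})
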