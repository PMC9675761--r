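test_that("local alignment matches the exhaustive DP oracle", {
  cons <- fixture_consensus()$Alu
  self <- local_align(cons$sequence, cons)
  expect_equal(self$identity_percent, 100)
  expect_identical(self$consensus_span, c(0L, cons$length))

  # a slice of the right monomer maps inside the right monomer
  rm <- cons$monomer_bounds$right
  slice <- seq_slice(cons$sequence, rm[1] + 5L, rm[1] + 105L)
  a <- local_align(slice, cons)
  expect_gte(a$consensus_span[1], rm[1])
  expect_lte(a$consensus_span[2], rm[2] + 1L)

  one_mm <- local_align("ACGTACGTACGT", "ACGTACTTACGT")
  expect_equal(one_mm$score, sw_oracle("ACGTACGTACGT", "ACGTACTTACGT"))
  expect_equal(one_mm$identity_percent, 100 * 11 / 12)

  set.seed(55)
  for (i in 1:200) {
    q <- random_dna(sample(8:30, 1))
    s <- random_dna(sample(8:30, 1))
    expect_equal(local_align(q, s)$score, sw_oracle(q, s))
  }
  expect_error(local_align("", "ACGT"), "empty")
})

test_that("percent similarity is column-wise identity and symmetric", {
  expect_equal(percent_similarity("ACGTACGT", "ACGTACGT"), 100)
  expect_equal(percent_similarity("ACGTACGT", "ACGAACGT"), 87.5)
  set.seed(66)
  cons <- fixture_consensus()$Alu
  sims <- replicate(20, {
    a <- mutate_from_consensus(cons, 0.05)$sequence
    b <- mutate_from_consensus(cons, 0.05)$sequence
    c(percent_similarity(a, b), percent_similarity(b, a))
  })
  expect_equal(sims[1, ], sims[2, ])
  # two copies at 5% divergence each differ at ~9.75% of positions
  p_same <- 0.95^2 + 0.05^2 / 3
  ci <- qbinom(c(0.005, 0.995), cons$length, p_same) / cons$length * 100
  expect_gte(mean(sims[1, ]), ci[1] - 2)
  expect_lte(mean(sims[1, ]), ci[2] + 2)
})

test_that("flank extraction is consensus-oriented with correct spans", {
  fx <- fixture_hr_del()
  tr <- fx$truth
  ref <- fx$ref
  jc <- compute_microhomology(ref$sequence, tr$start, tr$end, "DEL")
  fl <- extract_flanks(ref$sequence, tr, ref$annotation, jc)
  ws <- tr$consensus_junction_position
  expect_equal(fl$span5, c(0, ws + 15))
  expect_equal(fl$span3, c(ws, 311))
  expect_equal(nchar(fl$flank5), ws + 15)
  # chimera reconstruction: flank5 ++ flank3 minus the shared tract
  chim <- paste0(fl$flank5, substr(fl$flank3, 15 + 1, nchar(fl$flank3)))
  expect_identical(nchar(chim), 311L)
  a <- local_align(chim, fx$cons$Alu)
  expect_gte(diff(a$consensus_span) / 311, 0.95)
  expect_gte(a$identity_percent, 85)
})

test_that("minus-strand flanks are reverse-complemented genomic slices", {
  cons <- fixture_consensus()
  sp <- plant_spec("INV", "HR", mh_length = 10L)
  pl <- make_te_pair(cons$Alu, sp, seed = 71)
  ref <- build_reference(10000, pl, cons, seed = 72)
  tr <- plant_temr(ref, sp, seed = 73)
  jc <- compute_microhomology(ref$sequence, tr$start, tr$end, "INV")
  fl <- extract_flanks(ref$sequence, tr, ref$annotation, jc)
  ann3 <- ref$annotation[ref$annotation$copy_id == tr$te3_id, ]
  expect_identical(ann3$strand, "-")
  gslice <- seq_slice(ref$sequence, ann3$start, tr$end + jc$left_extension)
  expect_identical(fl$flank3, revcomp(gslice))
  mc <- infer_mechanism(fl, jc$mh_length, jc$mh_sequence, "Alu", cons$Alu)
  expect_identical(mc$label, "HR")
  expect_identical(mc$overlap_bp, 10L)
})

test_that("planted HR and NHE events are labelled from consensus overlap", {
  cons <- fixture_consensus()
  hr <- fixture_hr_del()
  jc <- compute_microhomology(hr$ref$sequence, hr$truth$start,
                              hr$truth$end, "DEL")
  fl <- extract_flanks(hr$ref$sequence, hr$truth, hr$ref$annotation, jc)
  mc <- infer_mechanism(fl, jc$mh_length, jc$mh_sequence, "Alu", cons$Alu)
  expect_identical(mc$label, "HR")
  expect_identical(mc$overlap_bp, 15L)
  expect_identical(mc$consensus_junction_position,
                   hr$truth$consensus_junction_position)

  sp <- plant_spec("DEL", "NHE", mh_length = 0L)
  pl <- make_te_pair(cons$Alu, sp, seed = 81)
  ref <- build_reference(10000, pl, cons, seed = 82)
  tr <- plant_temr(ref, sp, seed = 83)
  jc <- compute_microhomology(ref$sequence, tr$start, tr$end, "DEL")
  fl <- extract_flanks(ref$sequence, tr, ref$annotation, jc)
  mc <- infer_mechanism(fl, jc$mh_length, jc$mh_sequence, "Alu", cons$Alu)
  expect_identical(mc$label, "NHE")
  expect_lte(mc$overlap_bp, 0L)
})

test_that("poly-A microhomologies are routed to manual review", {
  cons <- fixture_consensus()$Alu
  fl <- list(flank5 = seq_slice(cons$sequence, 0, 290),
             flank3 = seq_slice(cons$sequence, 281, 311))
  mc <- infer_mechanism(fl, 10L, strrep("A", 10), "Alu", cons)
  expect_identical(mc$label, "MANUAL_REVIEW")
  expect_identical(mc$review_reason, "polyA")
  # 1 bp adenine microhomologies carry no poly-A signal
  fl2 <- list(flank5 = seq_slice(cons$sequence, 0, 60),
              flank3 = seq_slice(cons$sequence, 120, 280))
  mc2 <- infer_mechanism(fl2, 1L, "A", "Alu", cons)
  expect_false(mc2$review_reason == "polyA")
})

test_that("short LINE-1 flank alignments are flagged as truncated", {
  cons <- fixture_consensus()$`LINE-1`
  good <- seq_slice(cons$sequence, 0, 700)
  junk <- paste0(seq_slice(cons$sequence, 0, 200), random_dna(500))
  fl <- list(flank5 = junk, flank3 = seq_slice(cons$sequence, 700, 1470))
  mc <- infer_mechanism(fl, 8L, "GCGCGCGC", "LINE-1", cons)
  expect_identical(mc$label, "MANUAL_REVIEW")
  expect_identical(mc$review_reason, "truncated")
})

test_that("discordant consensus overlap is flagged for review", {
  cons <- fixture_consensus()$Alu
  # flanks overlap by ~30 bp on the consensus but microhomology is 4
  fl <- list(flank5 = seq_slice(cons$sequence, 0, 120),
             flank3 = seq_slice(cons$sequence, 90, 280))
  mc <- infer_mechanism(fl, 4L, "ACGT", "Alu", cons)
  expect_identical(mc$label, "MANUAL_REVIEW")
  expect_identical(mc$review_reason, "discordant")
})

test_that("monomer retry recovers cross-monomer Alu chimeras", {
  cons <- fixture_consensus()$Alu
  mb <- cons$monomer_bounds
  shift <- mb$right[1] - mb$left[1]
  mh <- 12L
  # pick a monomer offset where both monomers carry the same base, so the
  # copied tract is not end-trimmed by the aligner
  p <- 35L
  while (substr(cons$sequence, p + 1, p + 1) !=
         substr(cons$sequence, p + shift + 1, p + shift + 1)) p <- p + 1L
  # flank5 ends in the left monomer, flank3 starts at the homologous
  # offset of the right monomer; window content copied so both flanks
  # share an identical tract
  tract <- seq_slice(cons$sequence, p, p + mh)
  flank5 <- seq_slice(cons$sequence, 0, p + mh)
  flank3 <- paste0(tract,
                   seq_slice(cons$sequence, p + shift + mh, cons$length))
  mc <- infer_mechanism(list(flank5 = flank5, flank3 = flank3),
                        mh, tract, "Alu", cons)
  expect_identical(mc$label, "HR")
  expect_identical(mc$monomer_cross, "left-to-right")
  expect_identical(mc$overlap_bp, mh)
  # the resulting chimera is about one monomer shorter than the dimer
  chim_len <- nchar(flank5) + nchar(flank3) - mh
  expect_lt(abs(chim_len - (cons$length - shift)), 20)

  # opposite cross direction: flank5 in the right monomer, flank3 in the
  # left; the chimera gains a monomer (~3-monomer Alu)
  tract2 <- seq_slice(cons$sequence, p + shift, p + shift + mh)
  flank5b <- seq_slice(cons$sequence, 0, p + shift + mh)
  flank3b <- paste0(tract2, seq_slice(cons$sequence, p + mh, cons$length))
  mcb <- infer_mechanism(list(flank5 = flank5b, flank3 = flank3b),
                         mh, tract2, "Alu", cons)
  expect_identical(mcb$label, "HR")
  expect_identical(mcb$monomer_cross, "right-to-left")
  chim_lenb <- nchar(flank5b) + nchar(flank3b) - mh
  expect_lt(abs(chim_lenb - (cons$length + shift)), 20)
})

test_that("microhomology maps onto the consensus with box annotation", {
  cons <- fixture_consensus()$Alu
  call <- list(label = "HR", consensus_junction_position = 50L)
  m <- map_mh_to_consensus(call, 10L, cons)
  expect_identical(m$interval, c(50L, 60L))
  expect_true("A_box" %in% m$boxes_touched)
  call2 <- list(label = "HR", consensus_junction_position = 120L)
  expect_length(map_mh_to_consensus(call2, 5L, cons)$boxes_touched, 0L)
  expect_error(map_mh_to_consensus(list(label = "NHE"), 5L, cons), "HR")
})

test_that("HR junction positions distribute uniformly over the window range", {
  res <- fixture_result()
  # enlarge with a second cohort for power
  res2 <- run_temr_pipeline(seed = 302, n_events = 40,
                            background_length = 1.6e6, n_decoys = 10)
  pos <- c(res$temr$consensus_junction_position[res$temr$mechanism_label == "HR" &
                                                res$temr$family == "Alu" &
                                                res$temr$monomer_cross == "none"],
           res2$temr$consensus_junction_position[res2$temr$mechanism_label == "HR" &
                                                 res2$temr$family == "Alu" &
                                                 res2$temr$monomer_cross == "none"])
  pos <- pos[!is.na(pos)]
  expect_gte(length(pos), 30)
  # generator draws window starts uniformly on [40, 241 - mh]
  bins <- cut(pos, breaks = seq(40, 240, length.out = 5),
              include.lowest = TRUE)
  p <- chisq.test(table(bins))$p.value
  expect_gt(p, 0.001)
})

test_that("cohort tabulation reports both Alu HR denominators", {
  temrs <- data.frame(
    mechanism_label = c(rep("HR", 8), rep("NHE", 2)),
    family = c(rep("Alu", 7), "LINE-1", "Alu", "LINE-1"),
    monomer_cross = c("left-to-right", rep("right-to-left", 2),
                      rep("none", 7)),
    review_reason = "none")
  cc <- classify_cohort(temrs)
  expect_identical(cc$monomer_chimeras,
                   c(single_monomer = 1L, three_monomer = 2L))
  expect_equal(cc$hr_alu_of_hr_percent, round(100 * 7 / 8, 1))
  expect_equal(cc$hr_alu_of_alu_percent, round(100 * 7 / 8, 1))
  expect_equal(cc$percent_manual, 0)
  all_rev <- data.frame(mechanism_label = "MANUAL_REVIEW", family = "Alu",
                        monomer_cross = "none", review_reason = "polyA")
  expect_equal(classify_cohort(all_rev)$percent_manual, 100)
})

test_that("mechanism recovery exceeds 95% on a benchmark cohort", {
  # >= 100 events per mechanism class at divergence <= 0.15
  co <- simulate_temr_cohort(n_events = 210, background_length = 6e6,
                             seed = 500, p_hr = 0.5, n_decoys = 20)
  expect_gte(min(table(co$truth$mechanism)), 100)
  res <- run_temr_pipeline(seed = 500, cohort = co)
  sc <- score_against_truth(res)
  expect_gte(sc$mechanism_accuracy_percent, 95)
})
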