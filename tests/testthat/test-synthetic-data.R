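test_that("transcriptome generator respects lengths and determinism", {
  tx <- makeTranscriptome(1, list(utr5 = 50, cds = 300, utr3 = 100),
                          seed = 7)
  expect_equal(length(tx), 1L)
  expect_equal(Biostrings::width(transcriptSeqs(tx)), 450L)
  anno <- transcriptAnno(tx)
  expect_equal(anno$utr5_len + anno$cds_len + anno$utr3_len, 450L)

  ## byte-identical FASTA for a fixed seed
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  a1 <- withr::local_tempfile(); a2 <- withr::local_tempfile()
  writeTranscriptome(makeTranscriptome(5, seed = 3), f1, a1)
  writeTranscriptome(makeTranscriptome(5, seed = 3), f2, a2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(a1), readLines(a2))

  expect_error(makeTranscriptome(0), "n_genes")
  expect_error(makeTranscriptome(2, list(utr5 = -5, cds = 10, utr3 = 1)),
               "length")
})

test_that("GC gradient produces the requested 5'-to-3' trend", {
  tx <- makeTranscriptome(200, list(utr5 = 100, cds = 500, utr3 = 400),
                          gc_gradient = c(0.60, 0.40), seed = 1)
  layout <- deriveLayout(tx, 10)
  gc <- gcProfile(tx, layout)
  expect_gt(gc$gc[1], gc$gc[nrow(gc)])
  ## realized GC near the ends within 3 percentage points of the target
  expect_lt(abs(gc$gc[1] - 0.60), 0.03)
  expect_lt(abs(gc$gc[nrow(gc)] - 0.40), 0.03)
})

test_that("truth planting places classifiable sites at requested mix", {
  ## forced placement: a single eligible C with an editable downstream
  tx <- Transcriptome(c(t1 = "AAAAACAAAAAA"),
                      data.frame(transcript_id = "t1", gene_id = "g1",
                                 utr5_len = 2L, cds_len = 8L,
                                 utr3_len = 2L))
  pl <- plantTruth(tx, 1, type_mix = 1.0, level_dist = 0.5, seed = 1)
  expect_equal(nrow(pl$truth), 1L)
  expect_equal(pl$truth$position, 5L)
  expect_equal(pl$truth$planted_type, "TypeII")
  expect_equal(pl$truth$true_level, 0.5)
  s <- unname(as.character(transcriptSeqs(pl$transcriptome)))
  expect_identical(substr(s, 6, 6), "C")
  expect_identical(substr(s, 7, 7), "U")   # +1
  expect_identical(substr(s, 8, 8), "C")   # +2
  expect_identical(substr(s, 10, 10), "A") # +4

  ## capacity error when more sites than eligible Cs are requested
  expect_error(plantTruth(tx, 5, seed = 1), "capacity")

  ## realized Type II fraction within binomial error of the requested mix
  big <- makeTranscriptome(100, list(utr5 = 100, cds = 600, utr3 = 200),
                           seed = 2)
  pl2 <- plantTruth(big, 1000, type_mix = 0.237, seed = 2)
  frac <- mean(pl2$truth$planted_type == "TypeII")
  expect_lt(abs(frac - 0.237), 3 * sqrt(0.237 * 0.763 / 1000))

  ## truth sites are a subset of transcript C positions
  seqs <- as.character(transcriptSeqs(pl2$transcriptome))
  for (i in seq_len(20)) {
    r <- pl2$truth[i, ]
    expect_identical(substr(seqs[[r$transcript_id]], r$position + 1,
                            r$position + 1), "C")
  }
})

test_that("read simulator matches its binomial noise model", {
  tx <- makeTranscriptome(2, list(utr5 = 30, cds = 200, utr3 = 30),
                          seed = 4)
  ## perfect conversion, no bad reads, no truth: no C anywhere
  sim0 <- simulateReads(tx, NULL, simulationConfig(
    coverage_mean = 30, conversion_rate = 1.0, bad_read_fraction = 0,
    seed = 5))
  expect_equal(sum(sim0$obs$state == "C"), 0L)

  ## non-site unconverted fraction at conversion 0.995
  sim1 <- simulateReads(tx, NULL, simulationConfig(
    coverage_mean = 400, conversion_rate = 0.995, bad_read_fraction = 0,
    seed = 6))
  n <- nrow(sim1$obs)
  frac <- mean(sim1$obs$state == "C")
  expect_lt(abs(frac - 0.005), 3 * sqrt(0.005 * 0.995 / n))

  ## planted site at level 0.5 under perfect conversion
  pl <- plantTruth(tx, 1, type_mix = 0, level_dist = 0.5, seed = 7)
  sim2 <- simulateReads(pl$transcriptome, pl$truth, simulationConfig(
    coverage_mean = 400, conversion_rate = 1.0, bad_read_fraction = 0,
    seed = 8))
  at <- sim2$obs[sim2$obs$transcript_id == pl$truth$transcript_id &
                   sim2$obs$pos == pl$truth$position, ]
  expect_lt(abs(mean(at$state == "C") - 0.5),
            3 * sqrt(0.25 / nrow(at)))

  ## mean interior coverage within 10% of the target
  pile <- pileupFromReads(sim1, min_base_qual = 0)
  interior <- pile[pile$pos >= 100 & pile$pos <= 160, ]
  expect_gt(nrow(interior), 20)
  expect_lt(abs(mean(interior$cov_hq + 0) - 400) / 400, 0.10)

  ## base-quality mixture leaves ~99% at Q >= 30
  expect_gt(mean(sim1$obs$qual >= 30), 0.985)

  ## observations stay inside transcript bounds
  w <- setNames(Biostrings::width(transcriptSeqs(tx)),
                names(transcriptSeqs(tx)))
  expect_true(all(sim1$obs$pos >= 0 &
                    sim1$obs$pos < w[sim1$obs$transcript_id]))

  ## determinism
  simA <- simulateReads(tx, NULL, simulationConfig(seed = 9))
  simB <- simulateReads(tx, NULL, simulationConfig(seed = 9))
  expect_identical(simA$obs, simB$obs)

  expect_error(simulationConfig(conversion_rate = 0), "conversion_rate")
  expect_error(simulationConfig(bad_read_fraction = 1), "bad_read_fraction")
})

test_that("bad reads leave every covered C unconverted", {
  tx <- makeTranscriptome(1, list(utr5 = 20, cds = 150, utr3 = 20),
                          seed = 10)
  sim <- simulateReads(tx, NULL, simulationConfig(
    coverage_mean = 50, conversion_rate = 1.0, bad_read_fraction = 0.3,
    seed = 11))
  obs <- merge(sim$obs, sim$reads[, c("read_id", "bad")], by = "read_id")
  expect_true(all(obs$state[obs$bad] == "C"))
  expect_true(all(obs$state[!obs$bad] == "T"))
})

test_that("SAM and TSV round trips reproduce pileup counts exactly", {
  tx <- makeTranscriptome(3, list(utr5 = 30, cds = 150, utr3 = 30),
                          seed = 12)
  pl <- plantTruth(tx, 5, type_mix = 0.4, seed = 12)
  sim <- simulateReads(pl$transcriptome, pl$truth,
                       simulationConfig(coverage_mean = 15, seed = 13))
  sam <- withr::local_tempfile(fileext = ".sam")
  writeReadsSam(sim, pl$transcriptome, sam)
  obs2 <- readsFromSam(sam, pl$transcriptome)
  p1 <- pileupFromReads(sim)
  p2 <- pileupFromReads(obs2)
  expect_equal(as.data.frame(p1), as.data.frame(p2))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeReadsTsv(sim, tsv)
  obs3 <- readReadsTsv(tsv)
  p3 <- pileupFromReads(obs3)
  expect_equal(as.data.frame(p1), as.data.frame(p3))
})

test_that("species pair generator honors its logistic gain/loss model", {
  tx <- makeTranscriptome(40, list(utr5 = 60, cds = 500, utr3 = 100),
                          seed = 14)
  pl <- plantTruth(tx, 300, type_mix = 0, min_flank = 50, seed = 14)

  ## sub_rate = 0: identity map, no substitutions, no forced losses
  p0 <- makeSpeciesPair(pl$transcriptome, pl$truth, sub_rate = 0,
                        glm_coefs = c("(Intercept)" = 0), seed = 15)
  expect_true(all(p0$ortholog_map$baseA == p0$ortholog_map$baseB))
  expect_identical(as.character(transcriptSeqs(p0$transcriptome_b)),
                   as.character(transcriptSeqs(pl$transcriptome)))
  expect_false(any(p0$site_truth$forced_lost))
  ## intercept 0, no feature effects: retention ~ 0.5
  expect_lt(abs(mean(p0$site_truth$methylated_b) - 0.5),
            3 * sqrt(0.25 / nrow(p0$site_truth)))

  ## a strongly negative +1=U coefficient makes +1->U sites lose more
  pU <- makeSpeciesPair(pl$transcriptome, pl$truth, sub_rate = 0.15,
                        glm_coefs = c("(Intercept)" = 1.5,
                                      base_p1_U = -4),
                        seed = 16)
  st <- pU$site_truth
  ctxb <- pU$contexts[pU$contexts$species == "B", ]
  ctxb <- ctxb[match(st$site_id, ctxb$site_id), ]
  plus1 <- substr(ctxb$seq, 52, 52)
  ok <- !st$forced_lost
  loss_u <- mean(!st$methylated_b[ok & plus1 == "U"])
  loss_other <- mean(!st$methylated_b[ok & plus1 != "U"])
  expect_gt(loss_u, loss_other + 0.2)

  ## a C->non-C substitution at the site forces the lost label
  pS <- makeSpeciesPair(pl$transcriptome, pl$truth, sub_rate = 0.2,
                        glm_coefs = c("(Intercept)" = 10), seed = 17)
  forced <- pS$site_truth$forced_lost
  expect_gt(sum(forced), 0)
  expect_true(all(!pS$site_truth$methylated_b[forced]))
  expect_true(all(pS$site_truth$baseB[forced] != "C"))
})
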