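test_that("pairing metaprofile averages aligned pairing vectors", {
  hp <- "(((...)))"
  prof <- pairingMetaprofile(rep(hp, 5), window = 4)
  expect_equal(prof$frequency, as.numeric(pairingVector(hp)))
  ## site (center) unpaired in every context
  expect_equal(prof$frequency[prof$offset == 0], 0)
  ## 50/50 mix at a position
  mix <- c(rep("(((...)))", 5), rep(".((...)).", 5))
  prof2 <- pairingMetaprofile(mix, window = 4)
  expect_equal(prof2$frequency[prof2$offset == -4], 0.5)
  expect_true(all(prof2$frequency >= 0 & prof2$frequency <= 1))
  ## concatenated lists give the weighted mean of sub-profiles
  a <- rep("(((...)))", 3); b <- rep(".........", 7)
  pa <- pairingMetaprofile(a, 4)$frequency
  pb <- pairingMetaprofile(b, 4)$frequency
  pab <- pairingMetaprofile(c(a, b), 4)$frequency
  expect_equal(pab, (3 * pa + 7 * pb) / 10)
  expect_error(pairingMetaprofile(character()), "at least one")
})

test_that("bootstrap structure test is calibrated and detects differences", {
  w <- folded_random_windows(200, seed = 60)
  bt <- bootstrapPairingTest(w$dbs, w$dbs, window = 50, seed = 61)
  rate <- mean(bt$p_one_sided < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(bt)))

  ## deterministic given the seed
  bt2 <- bootstrapPairingTest(w$dbs, w$dbs, window = 50, seed = 61)
  expect_identical(bt$p_one_sided, bt2$p_one_sided)

  ## planted 0.9 vs 0.1 pairing probability at matched positions
  set.seed(62)
  mk <- function(n, p) vapply(seq_len(n), function(i) {
    k <- max(1L, rbinom(1L, 48L, p))
    paste(c(rep("(", k), rep(".", 101L - 2L * k), rep(")", k)),
          collapse = "")
  }, character(1))
  hi <- mk(200, 0.9); lo <- mk(200, 0.1)
  bt3 <- bootstrapPairingTest(hi, lo, window = 50, seed = 63)
  expect_lt(min(bt3$p_one_sided), 1e-6)

  expect_error(bootstrapPairingTest(w$dbs[1:50], w$dbs, n_sample = 100),
               "n_sample")
})

test_that("substitution-rate profiles reflect the generator truth", {
  ## identical sequences: all rates zero
  s <- c("AAAAACAAAAA", "GGGGGCGGGGG")
  sr0 <- substitutionRateProfile(s, s, groups = c("x", "x"), window = 5)
  expect_true(all(sr0$rate == 0))

  ## flank rates near the simulated substitution rate
  tx <- makeTranscriptome(40, list(utr5 = 60, cds = 500, utr3 = 100),
                          seed = 64)
  pl <- plantTruth(tx, 400, type_mix = 0, min_flank = 50, seed = 64)
  pair <- makeSpeciesPair(pl$transcriptome, pl$truth, sub_rate = 0.1,
                          glm_coefs = c("(Intercept)" = 0), seed = 65)
  ca <- pair$contexts[pair$contexts$species == "A", ]
  cb <- pair$contexts[pair$contexts$species == "B", ]
  sr <- substitutionRateProfile(ca$seq, cb$seq,
                                groups = rep("all", nrow(ca)),
                                window = 10)
  flank <- sr$rate[abs(sr$offset) >= 6]
  expect_lt(abs(mean(flank) - 0.1), 3 * sqrt(0.1 * 0.9 / (400 * 10)))

  ## selection against motif mutation: conserved sites keep their motif
  sel <- makeSpeciesPair(pl$transcriptome, pl$truth, sub_rate = 0.15,
                         glm_coefs = c("(Intercept)" = -1.5,
                                       base_p1_G = 4, base_p2_G = 2,
                                       base_p3_G = 2),
                         seed = 66)
  st <- sel$site_truth
  grp <- ifelse(st$methylated_b, "conserved", "lost")
  ca2 <- sel$contexts[sel$contexts$species == "A", ]
  cb2 <- sel$contexts[sel$contexts$species == "B", ]
  sr2 <- substitutionRateProfile(ca2$seq, cb2$seq, groups = grp,
                                 window = 10)
  cons <- sr2[sr2$group == "conserved", ]
  motif <- cons$rate[cons$offset %in% 1:3]
  flank2 <- cons$rate[abs(cons$offset) >= 6]
  expect_lt(mean(motif), mean(flank2))
})

test_that("feature matrices have the specified shape and coding", {
  w <- folded_random_windows(10, seed = 67)
  X2 <- featureMatrix(w$seqs, w$dbs, mode = "TypeII")
  expect_equal(ncol(X2), 41L)  # pairing bits -20..+20 inclusive
  X1 <- featureMatrix(w$seqs, w$dbs, mode = "TypeI")
  expect_equal(ncol(X1), 7L * 3L + 101L)
  expect_true(all(X1 %in% c(0, 1)))

  ## one-hot coding at +1: a U sets exactly the +1=U indicator
  seq <- paste0(strrep("A", 50), "C", "U", strrep("G", 49))
  db <- strrep(".", 101)
  X <- featureMatrix(seq, db, mode = "TypeI", reference = "A")
  expect_equal(unname(X[1, "base_p1_U"]), 1)
  expect_equal(unname(X[1, "base_p1_C"]), 0)
  expect_equal(unname(X[1, "base_p1_G"]), 0)
  expect_equal(unname(X[1, "base_p2_G"]), 1)
  ## reference category has no column
  expect_false("base_p1_A" %in% colnames(X))
})

test_that("design construction uses the methylated species as positives", {
  tx <- makeTranscriptome(30, list(utr5 = 60, cds = 400, utr3 = 100),
                          seed = 68)
  pl <- plantTruth(tx, 200, type_mix = 0, min_flank = 50, seed = 68)
  pair <- makeSpeciesPair(pl$transcriptome, pl$truth, sub_rate = 0.05,
                          glm_coefs = c("(Intercept)" = 0), seed = 69)
  des <- buildDesign(pair, mode = "TypeI")
  n_disc <- sum(!pair$site_truth$methylated_b &
                  pair$site_truth$baseB == "C")
  expect_equal(length(des$y), 2L * n_disc)
  expect_equal(sum(des$y == 1), n_disc)  # A contexts are positives
  expect_equal(ncol(des$X), 122L)
})

test_that("logistic IRLS matches closed forms and the glm oracle", {
  ## labels independent of features: coefficients near zero, intercept
  ## near logit of the label mean
  set.seed(70)
  X <- matrix(rbinom(4000, 1, 0.5), ncol = 2)
  colnames(X) <- c("f1", "f2")
  y <- rbinom(2000, 1, 0.7)
  fit <- fitLogistic(X, y, ridge = 0)
  expect_lt(abs(coef(fit)[["(Intercept)"]] - qlogis(mean(y))), 0.35)
  expect_lt(max(abs(coef(fit)[c("f1", "f2")])), 0.3)

  ## 2x2 table: coefficient equals the log odds ratio log(9)
  f <- c(rep(1, 40), rep(0, 40))
  y2 <- c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30))
  fit2 <- fitLogistic(matrix(f, dimnames = list(NULL, "f")), y2,
                      ridge = 0)
  expect_lt(abs(coef(fit2)[["f"]] - log(9)), 1e-8)

  ## oracle equivalence on small instances
  for (i in 1:5) {
    set.seed(70 + i)
    p <- sample(2:6, 1)
    Xi <- matrix(rnorm(60 * p), ncol = p,
                 dimnames = list(NULL, paste0("x", seq_len(p))))
    eta <- Xi %*% rnorm(p, sd = 0.8)
    yi <- rbinom(60, 1, plogis(eta))
    if (length(unique(yi)) < 2) next
    ours <- fitLogistic(Xi, yi, ridge = 0)
    oracle <- glm(yi ~ Xi, family = binomial())
    expect_true(isConverged(ours))
    expect_lt(max(abs(coef(ours) - coef(oracle))), 1e-6)
  }

  ## complete separation without ridge is flagged, not silent
  Xs <- matrix(c(rep(0, 10), rep(1, 10)), dimnames = list(NULL, "s"))
  ys <- c(rep(0, 10), rep(1, 10))
  expect_warning(fs <- fitLogistic(Xs, ys, ridge = 0), "converge")
  expect_false(isConverged(fs))
  ## and ridge stabilizes it
  fr <- fitLogistic(Xs, ys, ridge = 1e-2)
  expect_true(isConverged(fr))
  expect_error(fitLogistic(Xs, rep(1, 20)), "classes")
})
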