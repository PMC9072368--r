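test_that("pileup tallies observations exactly and enforces quality", {
  obs <- make_obs(list(
    list(id = "r1", pos = 10, state = "C"),
    list(id = "r2", pos = 10, state = "C"),
    list(id = "r3", pos = 10, state = "C")))
  p <- pileupFromReads(obs)
  expect_equal(p$c_hq, 3L)
  expect_equal(p$t_hq, 0L)

  obs2 <- make_obs(list(list(id = "r1", pos = 10, state = "C", qual = 20)))
  p2 <- pileupFromReads(obs2, min_base_qual = 30)
  expect_equal(p2$c_hq, 0L)
  expect_equal(p2$c_all, 1L)

  empty <- make_obs(list())
  expect_equal(nrow(pileupFromReads(empty)), 0L)

  bad <- make_obs(list(list(id = "rX", pos = 1, state = "G")))
  expect_error(pileupFromReads(bad), "rX")
})

test_that("Gini coefficient equals the pairwise mean-difference oracle", {
  expect_equal(giniCoefficient(c(1, 1, 1, 1)), 0)
  expect_equal(giniCoefficient(c(0, 1)), 0.5)
  expect_equal(giniCoefficient(c(0, 0, 0, 1)), 0.75)
  gini_oracle <- function(x) {
    n <- length(x)
    sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
  }
  set.seed(1)
  for (i in 1:20) {
    x <- runif(sample(2:40, 1))
    expect_lt(abs(giniCoefficient(x) - gini_oracle(x)), 1e-12)
  }
  expect_error(giniCoefficient(numeric()), "non-empty")
  expect_error(giniCoefficient(c(0, 0)), "all-zero")
})

test_that("C-cutoff removes whole reads strictly above the cutoff", {
  reads <- make_obs(list(
    list(id = "bad5", pos = 1:5, state = "C"),
    list(id = "edge3", pos = c(1, 3, 5), state = "C"),
    list(id = "clean", pos = c(2, 4), state = "T")))
  f <- applyCCutoff(reads, 3)
  expect_identical(f$removed_reads, "bad5")
  expect_false("bad5" %in% f$obs$read_id)     # removal is read-global
  expect_true("edge3" %in% f$obs$read_id)     # boundary: > not >=
  f0 <- applyCCutoff(make_obs(list(list(id = "t", pos = 1, state = "T"))), 0)
  expect_equal(nrow(f0$log), 0L)
  expect_error(applyCCutoff(reads, -1), "cutoff")
})

test_that("signal ratio measures C signal surviving the read filter", {
  ## 10 C-reads at pos 50, none over the cutoff
  clean <- obs_at(50, 10, 10)
  expect_equal(signalRatio(clean, "t1", 50), 1.0)
  ## 2 of the 10 C-reads are conversion failures (4 extra Cs each)
  extra <- make_obs(list(
    list(id = "r_c001", pos = c(10, 20, 30, 40), state = "C"),
    list(id = "r_c002", pos = c(11, 21, 31, 41), state = "C")))
  dirty <- rbind(clean, extra)
  expect_equal(signalRatio(dirty, "t1", 50, cutoff = 3), 0.8)
  ## exactly one removed: boundary 0.9
  one <- rbind(clean, make_obs(list(
    list(id = "r_c001", pos = c(10, 20, 30, 40), state = "C"))))
  expect_equal(signalRatio(one, "t1", 50, cutoff = 3), 0.9)
  expect_error(signalRatio(obs_at(50, 0, 5), "t1", 50), "undefined")
})

test_that("cutoff selection stabilizes and prefers the smaller cutoff", {
  ## every read carries <= 1 C: all cutoffs >= 1 give identical sets
  obs <- obs_at(10, 25, 25)
  sel <- selectCCutoff(obs, candidate_cutoffs = c(1, 2, 3))
  expect_equal(sel$chosen, 1)
  expect_equal(length(unique(round(sel$diagnostic$gini, 12))), 1L)

  ## conversion-failure-heavy simulation: chosen cutoff is small
  tx <- makeTranscriptome(30, list(utr5 = 100, cds = 500, utr3 = 200),
                          seed = 1)
  pl <- plantTruth(tx, 60, type_mix = 0.2,
                   level_dist = function(n) runif(n, 0.2, 0.8), seed = 1)
  sim <- simulateReads(pl$transcriptome, pl$truth, simulationConfig(
    coverage_mean = 60, bad_read_fraction = 0.2, seed = 1))
  sel2 <- selectCCutoff(sim, candidate_cutoffs = c(1:6, 8, 10))
  expect_lte(sel2$chosen, 4)
  d <- sel2$diagnostic
  ## adjacent Gini differences shrink as the filter stabilizes
  expect_lt(abs(d$gini[d$cutoff == 3] - d$gini[d$cutoff == 4]), 0.02)
  expect_error(selectCCutoff(obs, candidate_cutoffs = 3), "at least two")
})

test_that("gene conversion statistics exclude candidates and flag outliers", {
  ## 995 T + 5 C on one gene
  obs <- rbind(obs_at(10, 5, 495), obs_at(20, 0, 500, prefix = "q"))
  gs <- estimateGeneConversion(obs, one_gene_anno(), NULL)
  expect_equal(gs$conversion_rate, 0.995)
  expect_false(gs$resistant)

  ## all observations at candidate positions: global rate substituted
  anno2 <- rbind(one_gene_anno(), one_gene_anno("t2", "g2"))
  obs2 <- rbind(obs_at(10, 5, 495),
                obs_at(30, 10, 10, tid = "t2", prefix = "z"))
  gs2 <- estimateGeneConversion(obs2, anno2,
                                data.frame(transcript_id = "t2", pos = 30))
  g2 <- gs2[gs2$gene_id == "g2", ]
  expect_true(g2$low_confidence)
  expect_equal(g2$conversion_rate, attr(gs2, "global_rate"))

  ## rate 0.90 with resistant threshold 0.05 non-conversion
  obs3 <- obs_at(10, 50, 450)
  gs3 <- estimateGeneConversion(obs3, one_gene_anno(), NULL)
  expect_equal(gs3$conversion_rate, 0.9)
  expect_true(gs3$resistant)
})

test_that("binomial site test equals direct tail summation", {
  expect_equal(binomialSiteTest(0, 20, 0.005), 1.0)
  expect_equal(binomialSiteTest(20, 20, 0.005), 0.005^20)
  direct <- function(c, n, p) {
    sum(vapply(c:n, function(k) choose(n, k) * p^k * (1 - p)^(n - k), 0))
  }
  expect_lt(abs(binomialSiteTest(3, 20, 0.005) - direct(3, 20, 0.005)),
            1e-12)
  set.seed(2)
  for (i in 1:20) {
    n <- sample(10:60, 1); c <- sample(0:n, 1); p <- runif(1, 0.001, 0.2)
    expect_lt(abs(binomialSiteTest(c, n, p) - direct(c, n, p)), 1e-12)
  }
  ## monotone non-increasing in c_count
  ps <- binomialSiteTest(0:30, 30, 0.01)
  expect_true(all(diff(ps) <= 0))
  expect_error(binomialSiteTest(3, 20, 0), "nonconversion_rate")
  expect_error(binomialSiteTest(3, 20, 1), "nonconversion_rate")
  expect_error(binomialSiteTest(21, 20, 0.01), "coverage")
})

test_that("Stouffer combination matches the normal-CDF closed form", {
  expect_equal(stoufferCombine(0.5, 0.5), 0.5)
  oracle <- pnorm(sqrt(2) * qnorm(1 - 0.05), lower.tail = FALSE)
  expect_lt(abs(stoufferCombine(0.05, 0.05) - oracle), 1e-10)
  expect_equal(round(stoufferCombine(0.05, 0.05), 4), 0.0100)
  set.seed(3)
  for (i in 1:20) {
    p <- runif(2, 0.001, 0.999)
    expect_equal(stoufferCombine(p[1], p[2]), stoufferCombine(p[2], p[1]))
    closed <- pnorm((qnorm(1 - p[1]) + qnorm(1 - p[2])) / sqrt(2),
                    lower.tail = FALSE)
    expect_lt(abs(stoufferCombine(p[1], p[2]) - closed), 1e-10)
  }
  expect_error(stoufferCombine(0, 0.5), "strictly inside")
  expect_error(stoufferCombine(0.5, 1), "strictly inside")
})

test_that("caller emits planted sites and audits every candidate once", {
  tx <- makeTranscriptome(10, list(utr5 = 60, cds = 400, utr3 = 100),
                          seed = 20)
  pl <- plantTruth(tx, 25, type_mix = 0.3,
                   level_dist = function(n) runif(n, 0.3, 0.8), seed = 20)
  cfgs <- function(seed) simulationConfig(coverage_mean = 60,
                                          bad_read_fraction = 0.02,
                                          seed = seed)
  sim1 <- simulateReads(pl$transcriptome, pl$truth, cfgs(21))
  sim2 <- simulateReads(pl$transcriptome, pl$truth, cfgs(22))
  cs <- callSites(sim1, sim2, pl$transcriptome)
  s <- sites(cs)
  aud <- filterAudit(cs)

  ## audit partition: every candidate exactly once
  expect_false(any(duplicated(aud[, c("transcript_id", "pos")])))
  expect_equal(sum(aud$first_fail == "emitted"), nrow(s))
  expect_true(all(aud$first_fail %in%
                    c("emitted", "coverage", "variant_count", "level",
                      "c_cutoff", "signal_ratio", "resistant_gene",
                      "binomial_p", "single_rep_variant", "combined_p")))

  ## no calls at unplanted positions
  key_t <- paste(pl$truth$transcript_id, pl$truth$position)
  expect_true(all(paste(s$transcript_id, s$pos) %in% key_t))

  ## emitted sites obey their own invariants
  expect_true(all(s$level >= 0.1))
  expect_true(all(is.na(s$combined_p) | s$combined_p < 0.001))

  ## monotonicity: tightening thresholds cannot add calls
  cs_strict <- callSites(sim1, sim2, pl$transcriptome,
                         callerConfig(min_level = 0.3))
  expect_lte(nrow(sites(cs_strict)), nrow(s))
  cs_cov <- callSites(sim1, sim2, pl$transcriptome,
                      callerConfig(min_coverage = 40L))
  expect_lte(nrow(sites(cs_cov)), nrow(s))
})

test_that("single-replicate coverage invokes the five-variant rule", {
  anno <- one_gene_anno()
  mk_rep <- function(n_c, site_cov, prefix) {
    site <- obs_at(100, n_c, site_cov - n_c, prefix = prefix)
    bkg <- obs_at(200, 0, 200, prefix = paste0(prefix, "b"))
    rbind(site, bkg)
  }
  rep1 <- mk_rep(4, 30, "a")              # 4 C-reads, covered
  rep2 <- obs_at(200, 0, 200, prefix = "c") # site uncovered in rep 2
  cs <- callSites(rep1, rep2, anno)
  aud <- filterAudit(cs)
  at <- aud[aud$pos == 100, ]
  expect_equal(at$first_fail, "single_rep_variant")

  rep1b <- mk_rep(6, 30, "d")             # 6 C-reads pass the rule
  cs2 <- callSites(rep1b, rep2, anno)
  expect_equal(sites(cs2)$pos, 100L)
  expect_true(is.na(sites(cs2)$combined_p))
})
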