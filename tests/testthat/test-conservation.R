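mk_map <- function(n, baseA = "C", baseB = "C") {
  data.frame(tidA = "a1", posA = seq_len(n) - 1L, tidB = "b1",
             posB = seq_len(n) - 1L, baseA = baseA, baseB = baseB)
}

mk_sites <- function(tid, pos, level, cov) {
  data.frame(transcript_id = tid, pos = pos, level = level,
             coverage = cov)
}

test_that("methylation status applies the published thresholds", {
  expect_equal(methylationStatus(0.12, 30), "methylated")
  expect_equal(methylationStatus(0.04, 25), "unmethylated")
  expect_equal(methylationStatus(0.04, 15), "indeterminate")
  expect_equal(methylationStatus(0.07, 40), "indeterminate")
  expect_equal(methylationStatus(NA, 40), "indeterminate")
  expect_error(methylationStatus(-0.1, 30), "negative")
})

test_that("pair calls match the conservation rules", {
  map <- mk_map(3)
  sa <- mk_sites("a1", 0:2, c(0.12, 0.12, 0.12), c(30, 30, 30))
  sb <- mk_sites("b1", 0:2, c(0.06, 0.04, 0.04), c(25, 40, 15))
  calls <- pairSites(sa, sb, map)
  expect_equal(calls$status, c("conserved", "A_specific", "indeterminate"))

  ## symmetry: swapping species exchanges the specific labels
  swapped <- pairSites(sb, sa, data.frame(
    tidA = map$tidB, posA = map$posB, tidB = map$tidA, posB = map$posA,
    baseA = map$baseB, baseB = map$baseA))
  expect_equal(swapped$status,
               c("conserved", "B_specific", "indeterminate"))

  ## duplicate map entries are rejected
  expect_error(pairSites(sa, sb, rbind(map, map[1, ])), "duplicate")

  ## non-C bases are excluded from the methylation comparison
  mapx <- mk_map(1, baseB = "U")
  cx <- pairSites(mk_sites("a1", 0, 0.5, 30), mk_sites("b1", 0, 0.5, 30),
                  mapx)
  expect_true(is.na(cx$status))
  expect_equal(cx$reason, "non_C_base")
})

test_that("status combinations map exhaustively to pair calls", {
  ## representative levels per status, including both sub-cases of a
  ## methylated/indeterminate pair (level above or below 5%)
  cases <- list(
    M  = c(level = 0.30, cov = 30),   # methylated
    U  = c(level = 0.02, cov = 40),   # unmethylated
    I1 = c(level = 0.06, cov = 40),   # intermediate level
    I2 = c(level = 0.02, cov = 15))   # insufficient coverage
  expected <- function(a, b) {
    if (a == "M" && b == "M") return("conserved")
    if ((a == "M" && b == "I1") || (a == "I1" && b == "M")) {
      return("conserved")  # level > 5% in the second species
    }
    if (a == "M" && b == "U") return("A_specific")
    if (a == "U" && b == "M") return("B_specific")
    if (a == "U" && b == "U") return("unmethylated_both")
    "indeterminate"
  }
  for (a in names(cases)) {
    for (b in names(cases)) {
      call <- pairSites(
        mk_sites("a1", 0, cases[[a]]["level"], cases[[a]]["cov"]),
        mk_sites("b1", 0, cases[[b]]["level"], cases[[b]]["cov"]),
        mk_map(1))
      expect_equal(call$status, expected(a, b),
                   info = paste(a, b))
    }
  }
})

test_that("summary percentages use both denominators and ignore order", {
  status <- c(rep("conserved", 10), rep("A_specific", 50),
              rep("B_specific", 40), rep("indeterminate", 20))
  calls <- data.frame(status = status)
  s <- conservationSummary(calls)
  expect_equal(s$pct_conserved_determinate[s$type == "all"], 10)
  expect_equal(s$pct_conserved_all[s$type == "all"], 100 * 10 / 120)
  s2 <- conservationSummary(calls[sample(nrow(calls)), , drop = FALSE])
  expect_equal(s2, s)
  empty <- conservationSummary(data.frame(status = "indeterminate"))
  expect_equal(empty$n_conserved, 0L)
})

test_that("planted methylation retention is recovered", {
  tx <- makeTranscriptome(50, list(utr5 = 60, cds = 500, utr3 = 100),
                          seed = 50)
  pl <- plantTruth(tx, 500, type_mix = 0, min_flank = 50,
                   level_dist = function(n) runif(n, 0.3, 0.8), seed = 50)
  pair <- makeSpeciesPair(pl$transcriptome, pl$truth, sub_rate = 0,
                          glm_coefs = c("(Intercept)" = qlogis(0.2)),
                          seed = 51)
  st <- pair$site_truth
  sa <- mk_sites(st$transcript_id, st$position, st$true_level, 50)
  sb <- mk_sites(st$transcript_id, st$position,
                 ifelse(st$methylated_b, st$true_level, 0.0), 50)
  site_map <- pair$ortholog_map[
    paste(pair$ortholog_map$tidA, pair$ortholog_map$posA) %in%
      paste(st$transcript_id, st$position), ]
  calls <- pairSites(sa, sb, site_map)
  summ <- conservationSummary(calls)
  pct <- summ$pct_conserved_determinate[summ$type == "all"] / 100
  expect_lt(abs(pct - 0.2), 3 * sqrt(0.2 * 0.8 / nrow(st)))
})
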