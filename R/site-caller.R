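## m5C site calling from read-level bisulfite observations.
##
## The cascade mirrors the analysis used for transcriptome-wide RNA
## BS-seq: per-site tallies of high-quality bases, removal of poorly
## converted reads via the Gini-guided C-cutoff filter, a signal-ratio
## check, suppression of conversion-resistant genes, a one-sided binomial
## test against the gene-specific non-conversion rate, and replicate
## combination with Stouffer's method.

#' Caller configuration
#'
#' Thresholds of the site-calling cascade. Defaults match the published
#' analysis: coverage (C+T) >= 20, mismatch frequency >= 0.1, >= 3
#' variant nucleotides at base quality >= 30, C-cutoff = 3, signal ratio
#' >= 0.9, binomial and combined p below 0.001, and >= 5 variant
#' nucleotides when a site is adequately covered in only one replicate.
#'
#' @param min_coverage Minimum high-quality C+T coverage.
#' @param min_level Minimum methylation (mismatch) level.
#' @param min_variant_reads Minimum high-quality C observations.
#' @param min_base_qual Phred threshold for "high quality".
#' @param c_cutoff Reads with more than this many unconverted Cs are
#'   removed (conversion failures).
#' @param min_signal_ratio Minimum fraction of a site's C signal that
#'   survives the C-cutoff read removal.
#' @param p_threshold Per-replicate binomial p-value threshold.
#' @param combined_p_threshold Stouffer combined p-value threshold.
#' @param single_rep_min_variant Minimum C count when covered in only one
#'   replicate.
#' @param resistant_gene_max_nonconversion Genes whose non-conversion
#'   exceeds this (with enough data) are conversion-resistant and their
#'   sites suppressed.
#' @param min_gene_obs Informative observations required for a
#'   gene-specific conversion rate; genes below it inherit the global
#'   rate.
#' @return A list of class `CallerConfig`.
#' @export
callerConfig <- function(min_coverage = 20L, min_level = 0.1,
                         min_variant_reads = 3L, min_base_qual = 30L,
                         c_cutoff = 3L, min_signal_ratio = 0.9,
                         p_threshold = 0.001, combined_p_threshold = 0.001,
                         single_rep_min_variant = 5L,
                         resistant_gene_max_nonconversion = 0.05,
                         min_gene_obs = 50L) {
  cfg <- list(min_coverage = as.integer(min_coverage),
              min_level = min_level,
              min_variant_reads = as.integer(min_variant_reads),
              min_base_qual = as.integer(min_base_qual),
              c_cutoff = c_cutoff,
              min_signal_ratio = min_signal_ratio,
              p_threshold = p_threshold,
              combined_p_threshold = combined_p_threshold,
              single_rep_min_variant = as.integer(single_rep_min_variant),
              resistant_gene_max_nonconversion =
                resistant_gene_max_nonconversion,
              min_gene_obs = as.integer(min_gene_obs))
  if (cfg$min_level < 0 || cfg$min_level > 1 ||
      cfg$min_signal_ratio < 0 || cfg$min_signal_ratio > 1 ||
      cfg$p_threshold <= 0 || cfg$p_threshold >= 1 ||
      cfg$min_coverage < 1 || cfg$min_variant_reads < 0) {
    stop("caller thresholds out of range", call. = FALSE)
  }
  structure(cfg, class = "CallerConfig")
}

#' Pile up cytosine observations per site
#'
#' Exact tallies of converted/unconverted observations per reference C,
#' split into all observations and high-quality (Q >= `min_base_qual`)
#' observations. Positions with no coverage are absent.
#'
#' @param reads A [simulateReads()] result or an observation table
#'   (read_id, transcript_id, pos, state, qual).
#' @param min_base_qual Phred quality threshold.
#' @return `data.table` with transcript_id, pos, c_hq, t_hq, c_all,
#'   t_all, cov_hq.
#' @export
pileupFromReads <- function(reads, min_base_qual = 30L) {
  obs <- as_read_obs(reads)
  if (nrow(obs) == 0L) {
    return(data.table(transcript_id = character(), pos = integer(),
                      c_hq = integer(), t_hq = integer(),
                      c_all = integer(), t_all = integer(),
                      cov_hq = integer()))
  }
  if (any(!obs$state %in% c("C", "T")) || any(obs$qual < 0)) {
    bad <- obs$read_id[!obs$state %in% c("C", "T") | obs$qual < 0][1]
    stop("malformed read observation in read ", bad, call. = FALSE)
  }
  pile <- obs[, .(
    c_hq = sum(state == "C" & qual >= min_base_qual),
    t_hq = sum(state == "T" & qual >= min_base_qual),
    c_all = sum(state == "C"),
    t_all = sum(state == "T")), by = .(transcript_id, pos)]
  pile[, cov_hq := c_hq + t_hq]
  setorder(pile, transcript_id, pos)
  pile[]
}

#' Gini coefficient
#'
#' Mean absolute pairwise difference divided by twice the mean; the
#' dispersion diagnostic used both for C-cutoff selection and for
#' assessing site-level credibility.
#'
#' @param values Non-negative numbers, not all zero.
#' @return Gini coefficient in `[0, 1)`.
#' @examples
#' giniCoefficient(c(0, 1))  # 0.5
#' @export
giniCoefficient <- function(values) {
  if (length(values) == 0L || any(is.na(values)) || any(values < 0)) {
    stop("values must be non-negative and non-empty", call. = FALSE)
  }
  s <- sum(values)
  if (s == 0) stop("Gini undefined for all-zero values", call. = FALSE)
  n <- length(values)
  x <- sort(values)
  (2 * sum(seq_len(n) * x) - (n + 1) * s) / (n * s)
}

#' Remove poorly converted reads (C-cutoff filter)
#'
#' A read is removed, with all of its observations, iff it carries more
#' than `cutoff` unconverted (state C) observations. This targets reads
#' that escaped bisulfite conversion, whose spurious C signal would
#' otherwise mimic methylation.
#'
#' @param reads Observation container (see [pileupFromReads()]).
#' @param cutoff Non-negative C-count cutoff (strictly greater-than rule);
#'   `Inf` disables filtering.
#' @return List with `obs` (retained observations), `removed_reads`
#'   (ids) and `log` (read_id, c_count of removed reads).
#' @export
applyCCutoff <- function(reads, cutoff = 3L) {
  if (cutoff < 0) stop("cutoff must be >= 0", call. = FALSE)
  obs <- as_read_obs(reads)
  if (nrow(obs) == 0L) {
    return(list(obs = obs, removed_reads = character(),
                log = data.table(read_id = character(), c_count = integer())))
  }
  per_read <- obs[, .(c_count = sum(state == "C")), by = read_id]
  removed <- per_read[c_count > cutoff]
  list(obs = obs[!read_id %in% removed$read_id],
       removed_reads = removed$read_id,
       log = removed)
}

#' Signal ratio of a site under the C-cutoff filter
#'
#' Fraction of a site's high-quality C signal carried by reads that
#' survive the C-cutoff read removal. A low ratio means the apparent
#' methylation is driven by conversion-failure reads.
#'
#' @param reads Observation container.
#' @param transcript_id,position Site coordinates (0-based position).
#' @param cutoff C-cutoff value.
#' @param min_base_qual Phred threshold for the counts.
#' @return Ratio in `[0, 1]`; error if the site has no high-quality C.
#' @export
signalRatio <- function(reads, transcript_id, position, cutoff = 3L,
                        min_base_qual = 30L) {
  obs <- as_read_obs(reads)
  tid <- transcript_id
  at <- obs[obs$transcript_id == tid & obs$pos == position &
              obs$state == "C" & obs$qual >= min_base_qual, ]
  if (nrow(at) == 0L) {
    stop("signal ratio undefined: no high-quality C at the site",
         call. = FALSE)
  }
  kept <- applyCCutoff(obs, cutoff)$obs
  at_pf <- kept[kept$transcript_id == tid & kept$pos == position &
                  kept$state == "C" & kept$qual >= min_base_qual, ]
  nrow(at_pf) / nrow(at)
}

#' Select the C-cutoff by Gini stabilization
#'
#' For each candidate cutoff the observations are filtered, candidate
#' sites (pre-filter level >= `min_level`, coverage >= `min_coverage`)
#' are re-quantified, and the Gini coefficient of their post-filter
#' levels (or, alternatively, of per-read C counts) is computed. The
#' chosen cutoff is the smallest whose Gini differs from the next larger
#' cutoff's by less than `tolerance`.
#'
#' @param reads Observation container.
#' @param candidate_cutoffs At least two cutoffs, e.g. `c(1:6, 8, 10)`.
#' @param tolerance Stabilization tolerance on adjacent Gini values.
#' @param statistic `"site_levels"` (default) or `"read_c_counts"`.
#' @param min_coverage,min_level,min_base_qual Candidate-site definition.
#' @return List with `chosen` (cutoff or `NA`) and `diagnostic`
#'   (`data.frame`: cutoff, gini, n_candidates).
#' @export
selectCCutoff <- function(reads, candidate_cutoffs = c(1:6, 8, 10),
                          tolerance = 0.02,
                          statistic = c("site_levels", "read_c_counts"),
                          min_coverage = 20L, min_level = 0.1,
                          min_base_qual = 30L) {
  statistic <- match.arg(statistic)
  cutoffs <- sort(unique(candidate_cutoffs))
  if (length(cutoffs) < 2L) {
    stop("need at least two candidate cutoffs", call. = FALSE)
  }
  obs <- as_read_obs(reads)
  pile <- pileupFromReads(obs, min_base_qual)
  cand <- pile[cov_hq >= min_coverage & c_hq / cov_hq >= min_level &
                 c_hq > 0]
  gini <- rep(NA_real_, length(cutoffs))
  ncand <- integer(length(cutoffs))
  for (i in seq_along(cutoffs)) {
    kept <- applyCCutoff(obs, cutoffs[i])$obs
    if (statistic == "read_c_counts") {
      cc <- kept[, .(c_count = sum(state == "C")), by = read_id]$c_count
      ncand[i] <- length(cc)
      if (length(cc) > 0L && sum(cc) > 0) gini[i] <- giniCoefficient(cc)
      next
    }
    if (nrow(cand) == 0L) next
    pf <- pileupFromReads(kept, min_base_qual)
    lv <- pf[cand, on = c("transcript_id", "pos")]
    lv <- lv[!is.na(cov_hq) & cov_hq > 0]
    ncand[i] <- nrow(lv)
    levels <- lv$c_hq / lv$cov_hq
    if (length(levels) > 0L && sum(levels) > 0) {
      gini[i] <- giniCoefficient(levels)
    }
  }
  diagnostic <- data.frame(cutoff = cutoffs, gini = gini,
                           n_candidates = ncand)
  chosen <- NA_real_
  ok <- which(!is.na(gini))
  for (i in seq_len(length(cutoffs) - 1L)) {
    if (!is.na(gini[i]) && !is.na(gini[i + 1L]) &&
        abs(gini[i] - gini[i + 1L]) < tolerance) {
      chosen <- cutoffs[i]
      break
    }
  }
  list(chosen = chosen, diagnostic = diagnostic)
}

#' Gene-specific bisulfite conversion statistics
#'
#' Conversion rate per gene over high-quality observations, excluding
#' candidate methylation positions to avoid circularity. Genes with
#' fewer than `min_gene_obs` informative observations are marked
#' low-confidence and inherit the library-wide rate. Genes whose
#' non-conversion exceeds `resistant_gene_max_nonconversion` (with
#' enough data) are flagged conversion-resistant.
#'
#' @param reads Observation container.
#' @param annotation Transcript annotation (transcript_id, gene_id).
#' @param candidate_positions `data.frame` (transcript_id, pos) to
#'   exclude, or `NULL`.
#' @param min_base_qual,min_gene_obs,resistant_gene_max_nonconversion
#'   See [callerConfig()].
#' @return `data.frame`: gene_id, converted, unconverted, informative,
#'   conversion_rate, low_confidence, resistant; the library-wide rate is
#'   attached as attribute `global_rate`.
#' @export
estimateGeneConversion <- function(reads, annotation,
                                   candidate_positions = NULL,
                                   min_base_qual = 30L, min_gene_obs = 50L,
                                   resistant_gene_max_nonconversion = 0.05) {
  obs <- as_read_obs(reads)
  hq <- obs[qual >= min_base_qual]
  if (!is.null(candidate_positions) && nrow(candidate_positions) > 0L) {
    cand <- as.data.table(candidate_positions)[, .(transcript_id, pos)]
    hq <- hq[!cand, on = c("transcript_id", "pos")]
  }
  gene_of <- setNames(annotation$gene_id, annotation$transcript_id)
  hq[, gene_id := gene_of[transcript_id]]
  per_gene <- hq[, .(converted = sum(state == "T"),
                     unconverted = sum(state == "C")), by = gene_id]
  all_genes <- unique(annotation$gene_id)
  per_gene <- merge(data.table(gene_id = all_genes), per_gene,
                    by = "gene_id", all.x = TRUE)
  per_gene[is.na(converted), converted := 0L]
  per_gene[is.na(unconverted), unconverted := 0L]
  per_gene[, informative := converted + unconverted]
  tot_conv <- sum(per_gene$converted)
  tot_inf <- sum(per_gene$informative)
  global_rate <- if (tot_inf > 0) tot_conv / tot_inf else NA_real_
  per_gene[, low_confidence := informative < min_gene_obs]
  per_gene[, conversion_rate :=
             fifelse(low_confidence, global_rate, converted / informative)]
  per_gene[, resistant := !low_confidence &
             (1 - conversion_rate) > resistant_gene_max_nonconversion]
  out <- as.data.frame(per_gene)
  attr(out, "global_rate") <- global_rate
  out
}

#' One-sided binomial site test
#'
#' Exact upper-tail probability `P(X >= c_count)` for
#' `X ~ Binomial(coverage, nonconversion_rate)`: the chance of seeing at
#' least the observed number of unconverted Cs if the site were
#' unmethylated and only conversion noise operated.
#'
#' @param c_count Observed unconverted (C) count.
#' @param coverage C+T coverage.
#' @param nonconversion_rate Gene-specific non-conversion rate, in (0,1).
#' @return p-value (vectorized over the first two arguments).
#' @examples
#' binomialSiteTest(3, 20, 0.005)
#' @export
binomialSiteTest <- function(c_count, coverage, nonconversion_rate) {
  if (any(nonconversion_rate <= 0) || any(nonconversion_rate >= 1)) {
    stop("nonconversion_rate must be strictly inside (0, 1)", call. = FALSE)
  }
  if (any(c_count < 0) || any(c_count > coverage)) {
    stop("need 0 <= c_count <= coverage", call. = FALSE)
  }
  pbinom(c_count - 1, coverage, nonconversion_rate, lower.tail = FALSE)
}

#' Combine two replicate p-values (Stouffer's Z method)
#'
#' `z_i = qnorm(1 - p_i)`; combined `p = 1 - pnorm((z1 + z2)/sqrt(2))`.
#'
#' @param p1,p2 p-values strictly inside (0, 1).
#' @return Combined p-value (vectorized).
#' @examples
#' stoufferCombine(0.05, 0.05)
#' @export
stoufferCombine <- function(p1, p2) {
  if (any(p1 <= 0) || any(p1 >= 1) || any(p2 <= 0) || any(p2 >= 1)) {
    stop("p-values must be strictly inside (0, 1)", call. = FALSE)
  }
  z1 <- qnorm(p1, lower.tail = FALSE)
  z2 <- qnorm(p2, lower.tail = FALSE)
  pnorm((z1 + z2) / sqrt(2), lower.tail = FALSE)
}

## ordered filter names; first_fail reports the earliest violated one
FILTER_ORDER <- c("coverage", "variant_count", "level", "c_cutoff",
                  "signal_ratio", "resistant_gene", "binomial_p",
                  "single_rep_variant", "combined_p")

## per-replicate candidate table with all per-site statistics; when
## `positions` is given the table covers exactly those positions (zero
## rows filled in), so both replicates can be audited at the union of
## candidate positions
replicate_stats <- function(obs, annotation, cfg, positions = NULL,
                            pile = NULL) {
  if (is.null(pile)) pile <- pileupFromReads(obs, cfg$min_base_qual)
  if (is.null(positions)) {
    cand <- pile[c_hq > 0L]
  } else {
    cand <- pile[as.data.table(positions), on = c("transcript_id", "pos")]
    for (col in c("c_hq", "t_hq", "c_all", "t_all", "cov_hq")) {
      cand[is.na(get(col)), (col) := 0L]
    }
  }
  filt <- applyCCutoff(obs, cfg$c_cutoff)
  pf <- pileupFromReads(filt$obs, cfg$min_base_qual)
  setnames(pf, c("c_hq", "t_hq", "cov_hq"), c("c_pf", "t_pf", "cov_pf"))
  cand <- pf[, .(transcript_id, pos, c_pf, t_pf, cov_pf)][
    cand, on = c("transcript_id", "pos")]
  cand[is.na(c_pf), `:=`(c_pf = 0L, t_pf = 0L, cov_pf = 0L)]
  cand[, level := fifelse(cov_hq > 0L, c_hq / cov_hq, 0)]
  cand[, level_pf := fifelse(cov_pf > 0L, c_pf / cov_pf, 0)]
  cand[, signal_ratio := fifelse(c_hq > 0L, c_pf / c_hq, NA_real_)]
  ## gene conversion from post-cutoff observations, candidates excluded
  pre_cand <- cand[cov_hq >= cfg$min_coverage & level >= cfg$min_level &
                     c_hq >= cfg$min_variant_reads,
                   .(transcript_id, pos)]
  gs <- estimateGeneConversion(
    filt$obs, annotation, pre_cand, cfg$min_base_qual, cfg$min_gene_obs,
    cfg$resistant_gene_max_nonconversion)
  gene_of <- setNames(annotation$gene_id, annotation$transcript_id)
  cand[, gene_id := gene_of[transcript_id]]
  gdt <- as.data.table(gs)[, .(gene_id, conversion_rate, resistant,
                               informative)]
  cand <- gdt[cand, on = "gene_id"]
  ## clamp non-conversion away from 0 for the exact test (perfectly
  ## converted genes would otherwise make the binomial degenerate)
  cand[, nonconv := pmax(1 - conversion_rate,
                         0.5 / (pmax(informative, 1L) + 1L))]
  cand[, p_value := binomialSiteTest(c_pf, pmax(cov_pf, c_pf), nonconv)]
  list(cand = cand, gene_stats = gs)
}

## first failing per-replicate filter (NA when all pass)
first_fail_idx <- function(cand, cfg) {
  fails <- cbind(
    coverage = cand$cov_hq < cfg$min_coverage,
    variant_count = cand$c_hq < cfg$min_variant_reads,
    level = cand$level < cfg$min_level,
    c_cutoff = cand$cov_pf < cfg$min_coverage |
      cand$c_pf < cfg$min_variant_reads | cand$level_pf < cfg$min_level,
    signal_ratio = cand$signal_ratio < cfg$min_signal_ratio,
    resistant_gene = cand$resistant,
    binomial_p = cand$p_value >= cfg$p_threshold)
  idx <- apply(fails, 1L, function(f) {
    w <- which(f)
    if (length(w) == 0L) NA_integer_ else w[1L]
  })
  as.integer(idx)
}

#' Call high-confidence m5C sites
#'
#' Runs the full filter cascade over one or two replicate read streams
#' and emits high-confidence sites together with a complete audit: every
#' candidate position (>= 1 high-quality C in either replicate) appears
#' exactly once, either as `emitted` or with its first failing filter.
#'
#' Per replicate where the position is adequately covered, a site must
#' have coverage >= 20, >= 3 high-quality Cs, level >= 0.1, still satisfy
#' those bounds after C-cutoff read removal, keep a signal ratio >= 0.9,
#' not sit in a conversion-resistant gene, and beat the gene-specific
#' binomial test at p < 0.001. With two covered replicates the Stouffer
#' combined p must be < 0.001; with one covered replicate at least five
#' variant Cs are required.
#'
#' @param reads1 Replicate-1 observation container.
#' @param reads2 Optional replicate-2 container.
#' @param transcriptome A [Transcriptome-class] (or an annotation
#'   `data.frame` with transcript_id, gene_id).
#' @param config A [callerConfig()].
#' @return A [MethylationCallSet-class].
#' @export
callSites <- function(reads1, reads2 = NULL, transcriptome,
                      config = callerConfig()) {
  stopifnot(inherits(config, "CallerConfig"))
  annotation <- if (is(transcriptome, "Transcriptome")) {
    transcriptAnno(transcriptome)
  } else {
    as.data.frame(transcriptome)
  }
  if (!all(c("transcript_id", "gene_id") %in% names(annotation))) {
    stop("annotation must provide transcript_id and gene_id", call. = FALSE)
  }
  obs1 <- as_read_obs(reads1)
  if (!all(unique(obs1$transcript_id) %in% annotation$transcript_id)) {
    stop("replicate annotation mismatch: unknown transcripts in reads1",
         call. = FALSE)
  }
  two_reps <- !is.null(reads2)
  if (two_reps) {
    obs2 <- as_read_obs(reads2)
    if (!all(unique(obs2$transcript_id) %in% annotation$transcript_id)) {
      stop("replicate annotation mismatch: unknown transcripts in reads2",
           call. = FALSE)
    }
    pile1 <- pileupFromReads(obs1, config$min_base_qual)
    pile2 <- pileupFromReads(obs2, config$min_base_qual)
    cand_pos <- unique(rbind(pile1[c_hq > 0L, .(transcript_id, pos)],
                             pile2[c_hq > 0L, .(transcript_id, pos)]))
    r1 <- replicate_stats(obs1, annotation, config, cand_pos, pile1)
    r2 <- replicate_stats(obs2, annotation, config, cand_pos, pile2)
  } else {
    r1 <- replicate_stats(obs1, annotation, config)
  }

  c1 <- r1$cand
  c1[, fail1 := first_fail_idx(c1, config)]
  if (two_reps) {
    c2 <- r2$cand
    c2[, fail2 := first_fail_idx(c2, config)]
    keys <- c("transcript_id", "pos")
    m <- merge(c1, c2, by = keys, all = TRUE, suffixes = c("_1", "_2"))
    cov1 <- fifelse(is.na(m$cov_hq_1), 0L, m$cov_hq_1)
    cov2 <- fifelse(is.na(m$cov_hq_2), 0L, m$cov_hq_2)
    covered1 <- cov1 >= config$min_coverage
    covered2 <- cov2 >= config$min_coverage
    f1 <- m$fail1
    f2 <- m$fail2

    n <- nrow(m)
    first_fail <- character(n)
    emitted <- logical(n)
    combined_p <- rep(NA_real_, n)
    both <- covered1 & covered2
    one <- xor(covered1, covered2)
    none <- !covered1 & !covered2
    first_fail[none] <- "coverage"
    ## both covered: every per-replicate filter must pass in both
    worst <- pmin(fifelse(is.na(f1), .Machine$integer.max, f1),
                  fifelse(is.na(f2), .Machine$integer.max, f2))
    worst_name <- FILTER_ORDER[pmin(worst, length(FILTER_ORDER))]
    bb <- both & (!is.na(f1) | !is.na(f2))
    first_fail[bb] <- worst_name[bb]
    pass_both <- both & is.na(f1) & is.na(f2)
    if (any(pass_both)) {
      cp <- stoufferCombine(pmin(pmax(m$p_value_1[pass_both], 1e-300),
                                 1 - 1e-16),
                            pmin(pmax(m$p_value_2[pass_both], 1e-300),
                                 1 - 1e-16))
      combined_p[pass_both] <- cp
      ok <- cp < config$combined_p_threshold
      emitted[pass_both][ok] <- TRUE
      first_fail[pass_both][!ok] <- "combined_p"
    }
    ## covered in exactly one replicate
    if (any(one)) {
      fo <- fifelse(covered1[one], f1[one], f2[one])
      co <- fifelse(covered1[one], m$c_pf_1[one], m$c_pf_2[one])
      co[is.na(co)] <- 0L
      fail_name <- rep(NA_character_, sum(one))
      fail_name[!is.na(fo)] <- FILTER_ORDER[fo[!is.na(fo)]]
      need5 <- is.na(fo) & co < config$single_rep_min_variant
      fail_name[need5] <- "single_rep_variant"
      pass <- is.na(fo) & !need5
      emitted[one][pass] <- TRUE
      first_fail[one][!pass] <- fail_name[!pass]
    }
    first_fail[emitted] <- "emitted"

    lvl1 <- m$c_hq_1; lvl1[is.na(lvl1)] <- 0L
    lvl2 <- m$c_hq_2; lvl2[is.na(lvl2)] <- 0L
    covp1 <- fifelse(covered1, cov1, 0L)
    covp2 <- fifelse(covered2, cov2, 0L)
    c_pool <- fifelse(covered1, lvl1, 0L) + fifelse(covered2, lvl2, 0L)
    audit <- data.table(
      transcript_id = m$transcript_id, pos = m$pos,
      gene_id = fifelse(is.na(m$gene_id_1), m$gene_id_2, m$gene_id_1),
      cov_rep1 = cov1, cov_rep2 = cov2,
      c_rep1 = lvl1, c_rep2 = lvl2,
      level_rep1 = fifelse(cov1 > 0L, lvl1 / cov1, NA_real_),
      level_rep2 = fifelse(cov2 > 0L, lvl2 / cov2, NA_real_),
      p_rep1 = m$p_value_1, p_rep2 = m$p_value_2,
      combined_p = combined_p,
      first_fail = first_fail)
    audit[, coverage := covp1 + covp2]
    audit[, c_count := c_pool]
    audit[, level := fifelse(coverage > 0L, c_count / coverage, NA_real_)]
    sites_dt <- audit[first_fail == "emitted",
      .(transcript_id, pos, gene_id, coverage, c_count, level,
        level_rep1, level_rep2, p_rep1, p_rep2, combined_p)]
    gene_stats <- merge(as.data.table(r1$gene_stats),
                        as.data.table(r2$gene_stats),
                        by = "gene_id", suffixes = c("_1", "_2"))
  } else {
    n <- nrow(c1)
    covered <- c1$cov_hq >= config$min_coverage
    first_fail <- rep(NA_character_, n)
    emitted <- logical(n)
    f <- c1$fail1
    first_fail[!is.na(f)] <- FILTER_ORDER[f[!is.na(f)]]
    need5 <- is.na(f) & c1$c_pf < config$single_rep_min_variant
    first_fail[need5] <- "single_rep_variant"
    emitted[is.na(f) & !need5] <- TRUE
    first_fail[emitted] <- "emitted"
    audit <- data.table(
      transcript_id = c1$transcript_id, pos = c1$pos, gene_id = c1$gene_id,
      coverage = c1$cov_hq, c_count = c1$c_hq, level = c1$level,
      level_rep1 = c1$level, level_rep2 = NA_real_,
      p_rep1 = c1$p_value, p_rep2 = NA_real_,
      combined_p = NA_real_, first_fail = first_fail)
    sites_dt <- audit[first_fail == "emitted",
      .(transcript_id, pos, gene_id, coverage, c_count, level,
        level_rep1, level_rep2, p_rep1, p_rep2, combined_p)]
    gene_stats <- as.data.table(r1$gene_stats)
  }
  setorder(sites_dt, transcript_id, pos)
  setorder(audit, transcript_id, pos)
  new("MethylationCallSet",
      sites = as.data.frame(sites_dt),
      audit = as.data.frame(audit),
      geneStats = as.data.frame(gene_stats),
      config = unclass(config))
}
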