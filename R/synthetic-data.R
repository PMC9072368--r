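## Synthetic bisulfite data with planted truth.
##
## The generator reproduces the statistical structure the caller assumes:
## per-gene conversion rates in the high-90s, a small minority of reads
## that escape conversion entirely (all covered Cs left unconverted),
## planted methylation >= 10% in Type I (downstream G-rich) and Type II
## (downstream U,C,N,A) contexts, two replicates per sample, and paired
## "species" transcriptomes related by point substitutions.

#' Simulation configuration for bisulfite reads
#'
#' @param coverage_mean Target mean per-position read coverage.
#' @param conversion_rate Bisulfite conversion rate for unmethylated Cs,
#'   either a single value or a named per-gene vector (names = gene ids).
#' @param bad_read_fraction Fraction of reads drawn as conversion
#'   failures: every covered C in such a read stays unconverted.
#' @param read_len Read length in nt (single-end, transcript space).
#' @param seed Integer seed; all randomness in [simulateReads()] flows
#'   from it.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(coverage_mean = 60, conversion_rate = 0.995,
                             bad_read_fraction = 0.02, read_len = 100L,
                             seed = 1L) {
  if (any(conversion_rate <= 0) || any(conversion_rate > 1)) {
    stop("conversion_rate must be in (0, 1]", call. = FALSE)
  }
  if (bad_read_fraction < 0 || bad_read_fraction >= 1) {
    stop("bad_read_fraction must be in [0, 1)", call. = FALSE)
  }
  if (coverage_mean <= 0) stop("coverage_mean must be > 0", call. = FALSE)
  if (read_len < 1) stop("read_len must be >= 1", call. = FALSE)
  structure(list(coverage_mean = coverage_mean,
                 conversion_rate = conversion_rate,
                 bad_read_fraction = bad_read_fraction,
                 read_len = as.integer(read_len),
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

## draw one region length from a scalar (fixed) or c(lo, hi) (uniform)
draw_lengths <- function(spec, n, what) {
  if (!is.numeric(spec) || length(spec) < 1L || length(spec) > 2L ||
      any(is.na(spec)) || any(spec < 0)) {
    stop(sprintf("invalid length specification for %s", what), call. = FALSE)
  }
  if (length(spec) == 1L) return(rep(as.integer(spec), n))
  if (spec[2] < spec[1]) {
    stop(sprintf("degenerate length range for %s", what), call. = FALSE)
  }
  as.integer(round(runif(n, spec[1], spec[2])))
}

#' Generate a synthetic transcriptome
#'
#' Draws `n_genes` transcripts (one per gene) with 5'UTR/CDS/3'UTR lengths
#' taken from `length_params` and bases sampled independently per
#' position. When `gc_gradient` is supplied, the per-position probability
#' of drawing G or C follows a linear gradient along the transcript, which
#' emulates the 5'-end GC enrichment seen in higher-animal transcriptomes.
#'
#' @param n_genes Number of transcripts/genes (>= 1).
#' @param length_params List with elements `utr5`, `cds`, `utr3`; each a
#'   fixed length or a `c(lo, hi)` range sampled uniformly.
#' @param gc_gradient Optional `c(gc5, gc3)` GC targets at the 5' and 3'
#'   transcript ends (linear interpolation in between); `NULL` for
#'   uniform base composition.
#' @param seed Integer seed; output is byte-identical for a fixed seed.
#' @return A [Transcriptome-class] object.
#' @examples
#' tx <- makeTranscriptome(3, list(utr5 = 50, cds = 300, utr3 = 100), seed = 7)
#' transcriptAnno(tx)
#' @export
makeTranscriptome <- function(n_genes,
                              length_params = list(utr5 = 150L, cds = 1350L,
                                                   utr3 = 500L),
                              gc_gradient = NULL, seed = 1L) {
  if (n_genes < 1) stop("n_genes must be >= 1", call. = FALSE)
  with_seed(seed, {
    u5 <- draw_lengths(length_params$utr5, n_genes, "utr5")
    cds <- draw_lengths(length_params$cds, n_genes, "cds")
    u3 <- draw_lengths(length_params$utr3, n_genes, "utr3")
    if (any(cds <= 0L)) stop("cds length must be > 0", call. = FALSE)
    L <- u5 + cds + u3
    total <- sum(L)
    if (is.null(gc_gradient)) {
      p_gc <- rep(0.5, total)
    } else {
      if (length(gc_gradient) != 2L || any(gc_gradient <= 0) ||
          any(gc_gradient >= 1)) {
        stop("gc_gradient must be c(gc5, gc3) with values in (0, 1)",
             call. = FALSE)
      }
      frac <- unlist(lapply(L, function(l) {
        if (l == 1L) 0 else (seq_len(l) - 1) / (l - 1)
      }), use.names = FALSE)
      p_gc <- gc_gradient[1] + (gc_gradient[2] - gc_gradient[1]) * frac
    }
    is_gc <- runif(total) < p_gc
    half <- runif(total) < 0.5
    base <- ifelse(is_gc, ifelse(half, "G", "C"), ifelse(half, "A", "U"))
    ends <- cumsum(L)
    starts <- ends - L + 1L
    seqs <- vapply(seq_len(n_genes), function(i) {
      paste(base[starts[i]:ends[i]], collapse = "")
    }, character(1))
    ids <- sprintf("tx%04d", seq_len(n_genes))
    names(seqs) <- ids
    Transcriptome(seqs,
      data.frame(transcript_id = ids,
                 gene_id = sprintf("g%04d", seq_len(n_genes)),
                 utr5_len = u5, cds_len = cds, utr3_len = u3,
                 stringsAsFactors = FALSE))
  })
}

#' Plant methylation truth into a transcriptome
#'
#' Selects `n_sites` cytosine positions, rewrites the local downstream
#' context to the motif of the planted class (Type I: downstream GGG;
#' Type II: downstream U, C, N, A) and assigns each site a true
#' methylation level. Planted sites are kept at least `min_separation` nt
#' apart so motif edits never overlap.
#'
#' @param transcriptome A [Transcriptome-class].
#' @param n_sites Number of sites to plant.
#' @param type_mix Probability that a planted site is Type II.
#' @param level_dist True-level distribution: a single value in `[0.1, 1]`
#'   (point mass) or a function `f(n)` returning `n` levels.
#' @param min_flank Minimum distance from both transcript ends (use 50 or
#'   more when downstream structure windows must be complete).
#' @param min_separation Minimum spacing between planted sites on the
#'   same transcript.
#' @param seed Integer seed.
#' @return A list with elements `transcriptome` (motif-edited copy) and
#'   `truth` (`data.frame`: transcript_id, position (0-based),
#'   true_level, planted_type).
#' @export
plantTruth <- function(transcriptome, n_sites, type_mix = 0.0,
                       level_dist = function(n) runif(n, 0.2, 0.8),
                       min_flank = 0L, min_separation = 10L, seed = 1L) {
  if (is.numeric(level_dist) && length(level_dist) == 1L) {
    lv <- level_dist
    if (lv < 0.1 || lv > 1) {
      stop("point-mass true level must be in [0.1, 1]", call. = FALSE)
    }
    level_dist <- function(n) rep(lv, n)
  }
  anno <- transcriptAnno(transcriptome)
  seqs <- tx_strings(transcriptome)
  with_seed(seed, {
    elig <- rbindlist(lapply(seq_along(seqs), function(i) {
      chars <- seq_chars(seqs[[i]])
      L <- length(chars)
      pos <- which(chars == "C") - 1L
      pos <- pos[pos >= min_flank & pos + 4L <= L - 1L &
                 pos + max(4L, min_flank) <= L - 1L]
      if (length(pos) == 0L) return(NULL)
      data.table(tid = names(seqs)[i], pos = pos)
    }))
    if (is.null(elig) || nrow(elig) == 0L) {
      stop("no eligible C positions for planting", call. = FALSE)
    }
    ## greedy pick in shuffled order, enforcing per-transcript separation
    elig <- elig[sample.int(nrow(elig))]
    chosen <- vector("list", n_sites)
    n_taken <- 0L
    taken <- list()
    for (r in seq_len(nrow(elig))) {
      tid <- elig$tid[r]; p <- elig$pos[r]
      prev <- taken[[tid]]
      if (is.null(prev) || all(abs(prev - p) >= min_separation)) {
        taken[[tid]] <- c(prev, p)
        n_taken <- n_taken + 1L
        chosen[[n_taken]] <- list(tid = tid, pos = p)
        if (n_taken == n_sites) break
      }
    }
    if (n_taken < n_sites) {
      stop(sprintf(
        "capacity error: only %d of %d requested sites could be planted",
        n_taken, n_sites), call. = FALSE)
    }
    truth <- data.table(
      transcript_id = vapply(chosen[seq_len(n_sites)], `[[`, "", "tid"),
      position = vapply(chosen[seq_len(n_sites)], function(x) x$pos, 0L))
    truth[, planted_type := ifelse(runif(.N) < type_mix, "TypeII", "TypeI")]
    truth[, true_level := level_dist(.N)]
    if (any(truth$true_level < 0.1 | truth$true_level > 1)) {
      stop("level_dist must produce levels in [0.1, 1]", call. = FALSE)
    }
    ## rewrite downstream contexts
    for (tid in unique(truth$transcript_id)) {
      chars <- seq_chars(seqs[[tid]])
      tsites <- truth[transcript_id == tid]
      for (r in seq_len(nrow(tsites))) {
        p1 <- tsites$position[r] + 2L  # 1-based index of +1
        if (tsites$planted_type[r] == "TypeII") {
          chars[p1] <- "U"; chars[p1 + 1L] <- "C"
          chars[p1 + 2L] <- sample(RNA_BASES, 1L); chars[p1 + 3L] <- "A"
        } else {
          chars[p1] <- "G"; chars[p1 + 1L] <- "G"; chars[p1 + 2L] <- "G"
        }
      }
      seqs[[tid]] <- paste(chars, collapse = "")
    }
    list(transcriptome = Transcriptome(seqs, anno),
         truth = as.data.frame(setorder(truth, transcript_id, position)))
  })
}

#' Simulate bisulfite reads over a transcriptome
#'
#' Single-end reads in transcript (sense) space. At a planted site the
#' probability that a read shows C equals
#' `true_level + (1 - true_level) * (1 - conversion_rate)`; at any other
#' C it equals `1 - conversion_rate`. A `bad_read_fraction` of reads
#' model complete conversion failure (all covered Cs read as C). Base
#' qualities are a two-point Phred mixture (Q37 w.p. 0.99, Q20 w.p.
#' 0.01) so the Q >= 30 filter is exercised.
#'
#' @param transcriptome A [Transcriptome-class] (post-[plantTruth()]).
#' @param truth Truth `data.frame` from [plantTruth()] (or `NULL`).
#' @param config A [simulationConfig()].
#' @return A list of class `m5c_reads` with `reads` (read_id,
#'   transcript_id, start, bad) and `obs` (read_id, transcript_id, pos,
#'   state, qual) data.tables. `obs` holds one row per covered reference
#'   C; `state` is `"C"` (unconverted) or `"T"` (converted).
#' @export
simulateReads <- function(transcriptome, truth, config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (length(transcriptome) == 0L) {
    stop("empty transcriptome", call. = FALSE)
  }
  anno <- transcriptAnno(transcriptome)
  seqs <- tx_strings(transcriptome)
  conv <- config$conversion_rate
  if (length(conv) == 1L) {
    conv <- setNames(rep(conv, nrow(anno)), anno$gene_id)
  } else if (is.null(names(conv)) || !all(anno$gene_id %in% names(conv))) {
    stop("per-gene conversion_rate must be named by gene_id", call. = FALSE)
  }
  with_seed(config$seed, {
    per_tx <- lapply(seq_len(nrow(anno)), function(i) {
      tid <- anno$transcript_id[i]
      L <- nchar(seqs[[tid]])
      rl <- min(config$read_len, L)
      n_starts <- L - rl + 1L
      n_reads <- max(1L, as.integer(round(config$coverage_mean *
                                            n_starts / rl)))
      start <- sample.int(n_starts, n_reads, replace = TRUE) - 1L
      cpos <- c_positions(seqs[[tid]])
      reads <- data.table(tid = tid,
                          rid = sprintf("%s_r%05d", tid, seq_len(n_reads)),
                          start = start, rl = rl)
      if (length(cpos) == 0L) return(list(reads = reads, obs = NULL))
      lo <- findInterval(start - 1L, cpos) + 1L
      hi <- findInterval(start + rl - 1L, cpos)
      nobs <- pmax(hi - lo + 1L, 0L)
      keep <- nobs > 0L
      idx <- sequence(nobs[keep], from = lo[keep])
      obs <- data.table(rid = rep(reads$rid[keep], nobs[keep]),
                        tid = tid, pos = cpos[idx])
      list(reads = reads, obs = obs)
    })
    reads <- rbindlist(lapply(per_tx, `[[`, "reads"))
    obs <- rbindlist(lapply(per_tx, `[[`, "obs"))
    reads[, bad := runif(.N) < config$bad_read_fraction]
    ## per-observation methylation / conversion outcome
    gene_of <- setNames(anno$gene_id, anno$transcript_id)
    if (nrow(obs) > 0L) {
      obs[, true_level := 0]
      if (!is.null(truth) && nrow(truth) > 0L) {
        tr <- as.data.table(truth)[, .(tid = transcript_id, pos = position,
                                       lvl = true_level)]
        obs[tr, true_level := i.lvl, on = c("tid", "pos")]
      }
      obs[reads, bad := i.bad, on = c(rid = "rid")]
      nonconv <- 1 - conv[gene_of[obs$tid]]
      meth <- runif(nrow(obs)) < obs$true_level
      unconv <- obs$bad | meth | (runif(nrow(obs)) < nonconv)
      obs[, state := fifelse(unconv, "C", "T")]
      obs[, qual := fifelse(runif(.N) < 0.99, 37L, 20L)]
      obs[, c("true_level", "bad") := NULL]
      setnames(obs, c("rid", "tid"), c("read_id", "transcript_id"))
    } else {
      obs <- data.table(read_id = character(), transcript_id = character(),
                        pos = integer(), state = character(),
                        qual = integer())
    }
    setnames(reads, c("tid", "rid"), c("transcript_id", "read_id"))
    structure(list(reads = reads[, .(read_id, transcript_id, start, rl, bad)],
                   obs = obs),
              class = "m5c_reads")
  })
}

## accept either a simulateReads() result or a bare obs data.table
as_read_obs <- function(x) {
  if (inherits(x, "m5c_reads")) return(x$obs)
  if (is.data.frame(x)) {
    dt <- as.data.table(x)
    need <- c("read_id", "transcript_id", "pos", "state", "qual")
    if (!all(need %in% names(dt))) {
      stop("read observations need columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    return(dt)
  }
  stop("unsupported read container", call. = FALSE)
}

#' Derive an orthologous "species" pair with gain/loss truth
#'
#' Mutates a transcriptome by independent point substitutions, emits the
#' position-level ortholog map, and draws per-site methylation retention
#' in the second species from a logistic model over the sequence and
#' structure features of [featureMatrix()]. A substitution of the site
#' cytosine itself forces the label `lost`.
#'
#' @param transcriptome Species-A [Transcriptome-class] (post-planting).
#' @param truth Species-A truth from [plantTruth()].
#' @param sub_rate Per-nucleotide substitution probability in `[0, 1)`.
#' @param glm_coefs Named coefficient vector over [featureMatrix()]
#'   feature names plus `"(Intercept)"`; unnamed features get 0. The
#'   linear predictor gives the probability that the B-species site is
#'   methylated (retained).
#' @param flank Half-window (nt) used for folding the structural context.
#' @param reference Reference base dropped in dummy coding (kept fixed so
#'   generated and fitted designs align).
#' @param seed Integer seed.
#' @return List with `transcriptome_b`, `ortholog_map` (tidA, posA, tidB,
#'   posB, baseA, baseB for every aligned position), `site_truth`
#'   (per-site baseB, methylated_b, forced_lost and linear predictor) and
#'   `contexts` (site_id, species, seq, db of the +/- `flank` window,
#'   N/"."-padded at transcript ends).
#' @export
makeSpeciesPair <- function(transcriptome, truth, sub_rate = 0.05,
                            glm_coefs = c("(Intercept)" = 0), flank = 50L,
                            reference = "A", seed = 1L) {
  if (sub_rate < 0 || sub_rate >= 1) {
    stop("sub_rate must be in [0, 1)", call. = FALSE)
  }
  seqs_a <- tx_strings(transcriptome)
  anno <- transcriptAnno(transcriptome)
  with_seed(seed, {
    chars_a <- lapply(seqs_a, seq_chars)
    lens <- lengths(chars_a)
    flat <- unlist(chars_a, use.names = FALSE)
    mut <- runif(length(flat)) < sub_rate
    if (any(mut)) {
      cur <- match(flat[mut], RNA_BASES)
      off <- sample.int(3L, sum(mut), replace = TRUE)
      flat[mut] <- RNA_BASES[((cur - 1L + off) %% 4L) + 1L]
    }
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    seqs_b <- setNames(vapply(seq_along(lens), function(i) {
      paste(flat[starts[i]:ends[i]], collapse = "")
    }, character(1)), names(seqs_a))
    tx_b <- Transcriptome(seqs_b, anno)
    map <- rbindlist(lapply(names(seqs_a), function(tid) {
      a <- seq_chars(seqs_a[[tid]])
      b <- seq_chars(seqs_b[[tid]])
      data.table(tidA = tid, posA = seq_along(a) - 1L, tidB = tid,
                 posB = seq_along(a) - 1L, baseA = a, baseB = b)
    }))
    truth <- as.data.table(truth)
    n <- nrow(truth)
    site_id <- sprintf("site%05d", seq_len(n))
    ctx <- rbindlist(lapply(seq_len(n), function(i) {
      tid <- truth$transcript_id[i]; p <- truth$position[i]
      rbind(
        data.table(site_id = site_id[i], species = "A",
                   seq = window_string(seqs_a[[tid]], p, flank)),
        data.table(site_id = site_id[i], species = "B",
                   seq = window_string(seqs_b[[tid]], p, flank)))
    }))
    ctx[, db := vapply(seq, fold_padded, character(1))]
    base_b <- vapply(seq_len(n), function(i) {
      substr(seqs_b[[truth$transcript_id[i]]], truth$position[i] + 1L,
             truth$position[i] + 1L)
    }, character(1))
    ## linear predictor over B contexts, per planted type
    eta <- numeric(n)
    ctx_b_all <- as.data.frame(ctx)[ctx$species == "B", ]
    for (type in unique(truth$planted_type)) {
      sel <- which(truth$planted_type == type)
      ctx_b <- ctx_b_all[match(site_id[sel], ctx_b_all$site_id), ]
      X <- featureMatrix(ctx_b$seq, ctx_b$db, mode = type,
                         reference = reference)
      beta <- setNames(rep(0, ncol(X)), colnames(X))
      common <- intersect(names(glm_coefs), names(beta))
      beta[common] <- glm_coefs[common]
      intercept <- if ("(Intercept)" %in% names(glm_coefs)) {
        glm_coefs[["(Intercept)"]]
      } else 0
      eta[sel] <- intercept + as.vector(X %*% beta)
    }
    forced_lost <- base_b != "C"
    keep <- runif(n) < plogis(eta)
    keep[forced_lost] <- FALSE
    site_truth <- data.frame(site_id = site_id,
                             transcript_id = truth$transcript_id,
                             position = truth$position,
                             planted_type = truth$planted_type,
                             true_level = truth$true_level,
                             baseB = base_b,
                             eta = eta,
                             forced_lost = forced_lost,
                             methylated_b = keep,
                             stringsAsFactors = FALSE)
    list(transcriptome_b = tx_b, ortholog_map = as.data.frame(map),
         site_truth = site_truth, contexts = as.data.frame(ctx))
  })
}

## +/- flank window around a 0-based position, N-padded at transcript ends
window_string <- function(seq, pos, flank) {
  L <- nchar(seq)
  lo <- pos - flank; hi <- pos + flank
  left_pad <- max(0L, -lo); right_pad <- max(0L, hi - (L - 1L))
  core <- substr(seq, max(1L, lo + 1L), min(L, hi + 1L))
  paste0(strrep("N", left_pad), core, strrep("N", right_pad))
}

## fold an N-padded window: pads stay unpaired
fold_padded <- function(seq) {
  chars <- seq_chars(seq)
  core <- chars != "N"
  db <- rep(".", length(chars))
  if (any(core)) {
    db[core] <- seq_chars(foldMinimal(paste(chars[core], collapse = "")))
  }
  paste(db, collapse = "")
}
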