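## Cross-species conservation of individual m5C sites through an
## ortholog position map.

#' Methylation status of a site
#'
#' A site is `methylated` when its level reaches the calling threshold
#' (>= 10%); `unmethylated` only when adequately covered (>= 20 reads)
#' with a level below 5%; anything else (including missing data) is
#' `indeterminate`.
#'
#' @param level Methylation level (fraction) or `NA`.
#' @param cov C+T read coverage or `NA`.
#' @param min_meth_level,max_unmeth_level,min_unmeth_cov Thresholds.
#' @return Character vector in
#'   `c("methylated", "unmethylated", "indeterminate")`.
#' @export
methylationStatus <- function(level, cov, min_meth_level = 0.10,
                              max_unmeth_level = 0.05, min_unmeth_cov = 20L) {
  if (any(level < 0, na.rm = TRUE) || any(cov < 0, na.rm = TRUE)) {
    stop("negative level or coverage", call. = FALSE)
  }
  n <- max(length(level), length(cov))
  level <- rep_len(level, n); cov <- rep_len(cov, n)
  out <- rep("indeterminate", n)
  out[!is.na(level) & level >= min_meth_level] <- "methylated"
  out[!is.na(level) & !is.na(cov) & cov >= min_unmeth_cov &
        level < max_unmeth_level] <- "unmethylated"
  out
}

#' Pair orthologous cytosines and call conservation status
#'
#' Joins per-position methylation levels of two species through an
#' ortholog map and classifies each pair: `conserved` when one species
#' is methylated (level >= 10%) and the other has a level > 5%, both
#' covered by at least `min_pair_coverage` reads; `A_specific` /
#' `B_specific` when methylated in one species and certifiably
#' unmethylated (>= 20 reads, < 5%) in the other; `unmethylated_both`;
#' otherwise `indeterminate`. Pairs whose base is not C in both species
#' are excluded from the methylation comparison (status `NA`, reason
#' `non_C_base`) but retained for substitution-rate analysis.
#'
#' @param sitesA,sitesB Per-position tables (transcript_id, pos, level,
#'   coverage) for species A and B. Positions absent from a table are
#'   treated as having no data (indeterminate).
#' @param ortholog_map `data.frame`: tidA, posA, tidB, posB, baseA,
#'   baseB.
#' @param min_pair_coverage Pair-inclusion coverage gate (>= 10 reads).
#' @param min_meth_level,max_unmeth_level,min_unmeth_cov Status
#'   thresholds, see [methylationStatus()].
#' @return `data.frame`: the map columns plus levelA, covA, levelB,
#'   covB, statusA, statusB, status, reason.
#' @export
pairSites <- function(sitesA, sitesB, ortholog_map, min_pair_coverage = 10L,
                      min_meth_level = 0.10, max_unmeth_level = 0.05,
                      min_unmeth_cov = 20L) {
  map <- as.data.table(ortholog_map)
  dup <- duplicated(map[, .(tidA, posA)]) | duplicated(map[, .(tidB, posB)])
  if (any(dup)) {
    stop("duplicate ortholog map entries: ",
         paste(utils::head(paste0(map$tidA[dup], ":", map$posA[dup]), 5L),
               collapse = ", "), call. = FALSE)
  }
  getl <- function(sites, tid_col, pos_col) {
    s <- as.data.table(as.data.frame(sites))
    if (!"pos" %in% names(s) && "position" %in% names(s)) {
      setnames(s, "position", "pos")
    }
    s[, .(transcript_id, pos, level, coverage)]
  }
  sa <- getl(sitesA); sb <- getl(sitesB)
  out <- as.data.frame(map)
  ia <- match(paste(map$tidA, map$posA), paste(sa$transcript_id, sa$pos))
  ib <- match(paste(map$tidB, map$posB), paste(sb$transcript_id, sb$pos))
  out$levelA <- sa$level[ia]; out$covA <- sa$coverage[ia]
  out$levelB <- sb$level[ib]; out$covB <- sb$coverage[ib]
  out$statusA <- methylationStatus(out$levelA, out$covA, min_meth_level,
                                   max_unmeth_level, min_unmeth_cov)
  out$statusB <- methylationStatus(out$levelB, out$covB, min_meth_level,
                                   max_unmeth_level, min_unmeth_cov)
  both_c <- out$baseA == "C" & out$baseB == "C"
  covered <- !is.na(out$covA) & !is.na(out$covB) &
    out$covA >= min_pair_coverage & out$covB >= min_pair_coverage
  la <- out$levelA; lb <- out$levelB
  conserved <- covered & !is.na(la) & !is.na(lb) &
    ((la >= min_meth_level & lb > max_unmeth_level) |
       (lb >= min_meth_level & la > max_unmeth_level))
  a_spec <- out$statusA == "methylated" & out$statusB == "unmethylated"
  b_spec <- out$statusB == "methylated" & out$statusA == "unmethylated"
  unmeth <- out$statusA == "unmethylated" & out$statusB == "unmethylated"
  status <- rep("indeterminate", nrow(out))
  status[unmeth] <- "unmethylated_both"
  status[a_spec] <- "A_specific"
  status[b_spec] <- "B_specific"
  status[conserved] <- "conserved"
  reason <- rep("", nrow(out))
  reason[status == "indeterminate"] <- "coverage_or_intermediate_level"
  status[!both_c] <- NA_character_
  reason[!both_c] <- "non_C_base"
  out$status <- status
  out$reason <- reason
  out
}

#' Summarize conservation calls
#'
#' Counts and percentages of conserved sites, overall and per site
#' type. Two denominators are reported: determinate pairs
#' (conserved + species-specific) and all paired Cs.
#'
#' @param calls Output of [pairSites()].
#' @param types Optional per-call site type vector (e.g. planted or
#'   classified TypeI/TypeII); `NULL` summarizes overall only.
#' @return `data.frame`: type, n_conserved, n_specific,
#'   n_unmethylated_both, n_indeterminate, n_paired,
#'   pct_conserved_determinate, pct_conserved_all.
#' @export
conservationSummary <- function(calls, types = NULL) {
  st <- calls$status[!is.na(calls$status)]
  tp <- if (is.null(types)) rep("all", length(calls$status)) else types
  tp <- tp[!is.na(calls$status)]
  if (length(st) == 0L) {
    return(data.frame(type = "all", n_conserved = 0L, n_specific = 0L,
                      n_unmethylated_both = 0L, n_indeterminate = 0L,
                      n_paired = 0L, pct_conserved_determinate = NA_real_,
                      pct_conserved_all = NA_real_))
  }
  groups <- unique(c("all", tp))
  rows <- lapply(groups, function(g) {
    s <- if (g == "all") st else st[tp == g]
    ncons <- sum(s == "conserved")
    nspec <- sum(s %in% c("A_specific", "B_specific"))
    data.frame(type = g, n_conserved = ncons, n_specific = nspec,
               n_unmethylated_both = sum(s == "unmethylated_both"),
               n_indeterminate = sum(s == "indeterminate"),
               n_paired = length(s),
               pct_conserved_determinate =
                 if (ncons + nspec > 0) 100 * ncons / (ncons + nspec)
                 else NA_real_,
               pct_conserved_all = 100 * ncons / length(s))
  })
  do.call(rbind, rows)
}
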