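## shared fixture builders (everything generated in code; no data files)

library(data.table)

## observation table from a compact read description:
## list(list(id=, tid=, pos=c(...), state=c(...), qual=c(...)), ...)
make_obs <- function(reads) {
  if (length(reads) == 0L) {
    return(data.table(read_id = character(), transcript_id = character(),
                      pos = integer(), state = character(),
                      qual = integer()))
  }
  rbindlist(lapply(reads, function(r) {
    n <- length(r$pos)
    data.table(read_id = r$id,
               transcript_id = r$tid %||% "t1",
               pos = as.integer(r$pos),
               state = rep_len(r$state, n),
               qual = as.integer(rep_len(r$qual %||% 37L, n)))
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## n reads each carrying a single observation at `pos`
obs_at <- function(pos, n_c, n_t, tid = "t1", qual = 37L, prefix = "r") {
  reads <- c(
    lapply(seq_len(n_c), function(i) {
      list(id = sprintf("%s_c%03d", prefix, i), tid = tid, pos = pos,
           state = "C", qual = qual)
    }),
    lapply(seq_len(n_t), function(i) {
      list(id = sprintf("%s_t%03d", prefix, i), tid = tid, pos = pos,
           state = "T", qual = qual)
    }))
  make_obs(reads)
}

one_gene_anno <- function(tid = "t1", gene = "g1") {
  data.frame(transcript_id = tid, gene_id = gene,
             utr5_len = 100L, cds_len = 800L, utr3_len = 100L)
}

rand_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

## independent maximum-pairing oracle: recursion on whether the first
## base of the interval pairs, pure R, no shared code with the DP
can_pair_r <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

enum_max_pairs <- function(seq, min_loop = 3L) {
  chars <- strsplit(seq, "")[[1]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (can_pair_r(chars[i], chars[k])) {
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    best
  }
  rec(1L, length(chars))
}

## structural validity of a dot-bracket for a sequence
check_structure <- function(seq, db, min_loop = 3L) {
  chars <- strsplit(seq, "")[[1]]
  br <- strsplit(db, "")[[1]]
  stack <- integer()
  n_pairs <- 0L
  for (i in seq_along(br)) {
    if (br[i] == "(") stack <- c(stack, i)
    if (br[i] == ")") {
      if (length(stack) == 0L) return(list(ok = FALSE, n_pairs = NA))
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (!can_pair_r(chars[j], chars[i])) {
        return(list(ok = FALSE, n_pairs = NA))
      }
      interior <- if (i - j > 1L) br[(j + 1L):(i - 1L)] else character()
      if (all(interior == ".") && length(interior) < min_loop) {
        ## hairpin loop shorter than the minimum
        return(list(ok = FALSE, n_pairs = NA))
      }
      n_pairs <- n_pairs + 1L
    }
  }
  list(ok = length(stack) == 0L, n_pairs = n_pairs)
}

## dot-brackets of folded random windows (site centered), for the
## structure metaprofile tests
folded_random_windows <- function(n, width = 101L, seed = 5L) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) rand_rna(width), character(1))
  list(seqs = seqs,
       dbs = vapply(seqs, foldMinimal, character(1), USE.NAMES = FALSE))
}
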