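## Motif-based classification of called sites into Type I (NSUN2-type,
## downstream G-rich, 5' end of hairpins) and Type II (NSUN6-type,
## downstream U,C,N,A, hairpin loops).

#' Extract flanking sequence contexts for sites
#'
#' Pulls the site base and its upstream/downstream flanks from the
#' transcript sequences. Flanks are clipped (never padded) at transcript
#' ends and the realized lengths recorded.
#'
#' @param transcriptome A [Transcriptome-class].
#' @param sites `data.frame` with transcript_id and 0-based `pos` (or
#'   `position`).
#' @param flank Flank length in nt (default 25).
#' @return `data.frame`: transcript_id, pos, core, upstream, downstream,
#'   up_len, down_len.
#' @export
siteContexts <- function(transcriptome, sites, flank = 25L) {
  seqs <- tx_strings(transcriptome)
  sites <- as.data.frame(sites)
  if (!"pos" %in% names(sites) && "position" %in% names(sites)) {
    sites$pos <- sites$position
  }
  n <- nrow(sites)
  up <- character(n); down <- character(n); core <- character(n)
  for (i in seq_len(n)) {
    s <- seqs[[sites$transcript_id[i]]]
    p <- sites$pos[i]  # 0-based
    L <- nchar(s)
    core[i] <- substr(s, p + 1L, p + 1L)
    up[i] <- substr(s, max(1L, p + 1L - flank), p)
    down[i] <- substr(s, p + 2L, min(L, p + 1L + flank))
  }
  data.frame(transcript_id = sites$transcript_id, pos = sites$pos,
             core = core, upstream = up, downstream = down,
             up_len = nchar(up), down_len = nchar(down),
             stringsAsFactors = FALSE)
}

#' Classify m5C sites as Type I or Type II
#'
#' Under the default `"downstream_ucna"` registration a site is Type II
#' iff the four downstream bases read U, C, N, A (+1 = U, +2 = C, +4 = A,
#' +3 free); every other site, including any site whose downstream flank
#' is shorter than 4 nt, is Type I. The alternative `"cucna_centered"`
#' registration instead requires -2 = C, -1 = U, +2 = A around the site.
#'
#' @param contexts Output of [siteContexts()] (or a transcriptome plus
#'   sites via `transcriptome=`/`sites=`).
#' @param registration Motif registration (see Details).
#' @param transcriptome,sites Convenience inputs forwarded to
#'   [siteContexts()] when `contexts` is missing.
#' @return `contexts` with an added `type` column (`"TypeI"`/`"TypeII"`).
#' @export
classifySites <- function(contexts = NULL,
                          registration = c("downstream_ucna",
                                           "cucna_centered"),
                          transcriptome = NULL, sites = NULL) {
  registration <- match.arg(registration)
  if (is.null(contexts)) {
    contexts <- siteContexts(transcriptome, sites)
  }
  if (any(contexts$core != "C")) {
    stop("site core base must be C", call. = FALSE)
  }
  d <- contexts$downstream
  u <- contexts$upstream
  if (registration == "downstream_ucna") {
    is2 <- contexts$down_len >= 4L &
      substr(d, 1L, 1L) == "U" & substr(d, 2L, 2L) == "C" &
      substr(d, 4L, 4L) == "A"
  } else {
    ul <- contexts$up_len
    is2 <- ul >= 2L & contexts$down_len >= 2L &
      substr(u, ul - 1L, ul - 1L) == "C" & substr(u, ul, ul) == "U" &
      substr(d, 2L, 2L) == "A"
  }
  contexts$type <- ifelse(is2, "TypeII", "TypeI")
  contexts
}

#' Position frequency matrix of site contexts
#'
#' Counts of A/C/G/U at each offset around the site. Truncated flanks
#' contribute only the positions they actually carry, so column sums
#' equal the number of contexts with that offset present.
#'
#' @param contexts Output of [siteContexts()].
#' @param flank Offset range `-flank..+flank`.
#' @return Integer matrix, rows A/C/G/U, columns named by offset.
#' @export
positionFrequencyMatrix <- function(contexts, flank = 25L) {
  offsets <- -flank:flank
  pfm <- matrix(0L, nrow = 4L, ncol = length(offsets),
                dimnames = list(RNA_BASES, offsets))
  for (i in seq_len(nrow(contexts))) {
    up <- seq_chars(contexts$upstream[i])
    down <- seq_chars(contexts$downstream[i])
    add <- function(base, off) {
      j <- match(off, offsets)
      k <- match(base, RNA_BASES)
      ok <- !is.na(j) & !is.na(k)
      for (m in which(ok)) pfm[k[m], j[m]] <<- pfm[k[m], j[m]] + 1L
    }
    if (length(up) > 0L) add(up, -length(up):-1L)
    add(contexts$core[i], 0L)
    if (length(down) > 0L) add(down, seq_along(down))
  }
  pfm
}
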