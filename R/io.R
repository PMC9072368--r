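## File interchange: FASTA + annotation TSV for transcriptomes, SAM and
## a canonical read TSV for bisulfite reads, TSV exports for sites.

#' Write / read a transcriptome as FASTA + annotation TSV
#'
#' @param transcriptome A [Transcriptome-class].
#' @param fasta_path,anno_path Output paths.
#' @return The paths, invisibly.
#' @export
writeTranscriptome <- function(transcriptome, fasta_path, anno_path) {
  Biostrings::writeXStringSet(transcriptSeqs(transcriptome), fasta_path)
  write.table(transcriptAnno(transcriptome), anno_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, anno_path))
}

#' @rdname writeTranscriptome
#' @export
readTranscriptome <- function(fasta_path, anno_path) {
  seqs <- Biostrings::readRNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  anno <- read.table(anno_path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  Transcriptome(seqs[anno$transcript_id], anno)
}

phred_chars <- function(quals) {
  vapply(quals, function(q) intToUtf8(q + 33L), character(1))
}

## reconstruct full read sequences (DNA letters) from the reference and
## the per-C observations
read_seq_from_obs <- function(reads, obs, seqs) {
  obs <- as.data.table(obs)
  setkey(obs, read_id)
  out_seq <- character(nrow(reads))
  out_qual <- character(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    tid <- reads$transcript_id[i]
    start <- reads$start[i]
    rl <- reads$rl[i]
    chars <- seq_chars(substr(seqs[[tid]], start + 1L, start + rl))
    chars[chars == "U"] <- "T"
    quals <- rep(37L, rl)
    ro <- obs[J(reads$read_id[i]), nomatch = NULL]
    if (nrow(ro) > 0L) {
      k <- ro$pos - start + 1L
      chars[k] <- ro$state
      quals[k] <- ro$qual
    }
    out_seq[i] <- paste(chars, collapse = "")
    out_qual[i] <- intToUtf8(quals + 33L)
  }
  list(seq = out_seq, qual = out_qual)
}

#' Write simulated reads as SAM
#'
#' Single-end sense-strand alignments against the transcriptome
#' (1-based POS, full-match CIGAR). Read bases at reference C positions
#' reflect the conversion outcome (C = unconverted, T = converted);
#' reference Us are written as T.
#'
#' @param sim A [simulateReads()] result.
#' @param transcriptome The (planted) [Transcriptome-class] the reads
#'   were simulated from.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
writeReadsSam <- function(sim, transcriptome, path) {
  stopifnot(inherits(sim, "m5c_reads"))
  seqs <- tx_strings(transcriptome)
  widths <- nchar(seqs)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(seqs), widths))
  rs <- read_seq_from_obs(sim$reads, sim$obs, seqs)
  body <- sprintf("%s\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s",
                  sim$reads$read_id, sim$reads$transcript_id,
                  sim$reads$start + 1L, sim$reads$rl, rs$seq, rs$qual)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Ingest reads from a SAM/BAM alignment
#'
#' Reads sense-strand transcriptome alignments and recovers the
#' per-cytosine conversion status by comparing read bases to the
#' original (unconverted) transcript sequence: reference-C positions
#' showing C are unconverted, showing T converted.
#'
#' @param path SAM or BAM file.
#' @param transcriptome The original [Transcriptome-class].
#' @return An observation table (read_id, transcript_id, pos, state,
#'   qual) as used by [pileupFromReads()].
#' @export
readsFromSam <- function(path, transcriptome) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else {
    bam <- path
  }
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "seq", "qual")))[[1]]
  seqs <- tx_strings(transcriptome)
  cpos_by_tid <- lapply(seqs, c_positions)
  n <- length(res$qname)
  out <- vector("list", n)
  read_str <- as.character(res$seq)
  qual_str <- as.character(res$qual)
  for (i in seq_len(n)) {
    tid <- as.character(res$rname[i])
    start <- res$pos[i] - 1L
    rl <- nchar(read_str[i])
    cp <- cpos_by_tid[[tid]]
    cp <- cp[cp >= start & cp < start + rl]
    if (length(cp) == 0L) next
    chars <- seq_chars(read_str[i])
    quals <- utf8ToInt(qual_str[i]) - 33L
    k <- cp - start + 1L
    state <- chars[k]
    keep <- state %in% c("C", "T")
    if (!any(keep)) next
    out[[i]] <- data.table(read_id = res$qname[i], transcript_id = tid,
                           pos = cp[keep], state = state[keep],
                           qual = as.integer(quals[k[keep]]))
  }
  obs <- rbindlist(out)
  if (nrow(obs) == 0L) {
    obs <- data.table(read_id = character(), transcript_id = character(),
                      pos = integer(), state = character(),
                      qual = integer())
  }
  obs
}

#' Canonical read TSV interchange
#'
#' One row per read: read_id, transcript_id, start (0-based) and the
#' covered-C list `pos:state:qual;...`.
#'
#' @param sim A [simulateReads()] result (or a list with `reads`/`obs`).
#' @param path Output path.
#' @return `path` invisibly; `readReadsTsv` returns an observation
#'   table.
#' @export
writeReadsTsv <- function(sim, path) {
  obs <- as.data.table(sim$obs)
  packed <- obs[, .(obs = paste(sprintf("%d:%s:%d", pos, state, qual),
                                collapse = ";")),
                by = .(read_id, transcript_id)]
  reads <- as.data.table(sim$reads)
  packed <- merge(reads[, .(read_id, transcript_id, start)], packed,
                  by = c("read_id", "transcript_id"), all.x = TRUE)
  packed[is.na(obs), obs := ""]
  write.table(packed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeReadsTsv
#' @export
readReadsTsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  df <- df[nzchar(df$obs), , drop = FALSE]
  parts <- strsplit(df$obs, ";", fixed = TRUE)
  nper <- lengths(parts)
  flat <- strsplit(unlist(parts), ":", fixed = TRUE)
  data.table(read_id = rep(df$read_id, nper),
             transcript_id = rep(df$transcript_id, nper),
             pos = as.integer(vapply(flat, `[`, "", 1L)),
             state = vapply(flat, `[`, "", 2L),
             qual = as.integer(vapply(flat, `[`, "", 3L)))
}

#' Export called sites as TSV / BED-like tables
#'
#' The TSV uses 1-based positions; the BED-like export is 6 columns
#' with 0-based half-open coordinates and the level as score.
#'
#' @param callset A [MethylationCallSet-class].
#' @param path Output path.
#' @param meta Optional named character vector written as `# key=value`
#'   header comments.
#' @return `path`, invisibly.
#' @export
writeSitesTsv <- function(callset, path, meta = NULL) {
  df <- sites(callset)
  df$pos_1based <- df$pos + 1L
  df <- df[, c("transcript_id", "pos_1based",
               setdiff(names(df), c("transcript_id", "pos", "pos_1based")))]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) {
    writeLines(sprintf("# %s=%s", names(meta), meta), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSitesTsv
#' @export
writeSitesBed <- function(callset, path) {
  df <- sites(callset)
  bed <- data.frame(chrom = df$transcript_id, start = df$pos,
                    end = df$pos + 1L,
                    name = sprintf("m5C_%s_%d", df$transcript_id, df$pos),
                    score = round(1000 * df$level),
                    strand = "+")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
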