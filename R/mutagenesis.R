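## Targeted bisulfite sequencing of synthesized substrate pools
## (high-throughput mutagenesis assay): read-to-variant assignment,
## barcode deduplication, per-variant methylation levels, motif series.

DNA_BASES <- c("A", "C", "G", "T")

## RNA reference -> DNA-space bisulfite-converted reference: unmethylated
## Cs read as T; the assayed site position is left as C
convert_reference <- function(seq, site_offset) {
  chars <- seq_chars(seq)
  out <- chars
  out[out == "U"] <- "T"
  is_c <- chars == "C"
  keep <- seq_along(chars) == site_offset + 1L
  out[is_c & !keep] <- "T"
  paste(out, collapse = "")
}

## DNA-space unconverted reference (the DNA library view)
dna_reference <- function(seq) {
  gsub("U", "T", seq, fixed = TRUE)
}

#' Generate a synthetic substrate pool
#'
#' Builds `n_variants` substrate sequences (~140 nt) sharing a backbone
#' and differing in the 4-nt motif immediately downstream of the
#' assayed C (all 4-mers over A/C/G/U in fixed order). Because motif Cs
#' and Us collide after bisulfite conversion, each variant additionally
#' carries a unique identifier tag drawn from {A,G,U} (unaffected by
#' conversion) so that converted references are mutually
#' distinguishable; the pool is validated for collisions.
#'
#' @param n_variants Number of variants (<= 256 uses the first 4-mers in
#'   lexicographic order).
#' @param length Substrate length (nt).
#' @param site_offset 0-based position of the assayed C.
#' @param tag_offset 0-based position of the identifier tag.
#' @param tag_len Tag length (3^tag_len must cover n_variants).
#' @param seed Integer seed for the backbone.
#' @return `data.frame`: variant_id, sequence (RNA), site_offset, motif,
#'   n_motif_G, mutation_tags.
#' @export
makeSubstratePool <- function(n_variants = 256L, length = 140L,
                              site_offset = 60L, tag_offset = 20L,
                              tag_len = 6L, seed = 1L) {
  if (3^tag_len < n_variants) {
    stop("tag_len too small for n_variants", call. = FALSE)
  }
  if (n_variants > 256L) stop("at most 256 motif variants", call. = FALSE)
  with_seed(seed, {
    backbone <- sample(RNA_BASES, length, replace = TRUE)
    backbone[site_offset + 1L] <- "C"
    motifs <- do.call(expand.grid,
                      rep(list(RNA_BASES), 4L))[, 4:1, drop = FALSE]
    motifs <- apply(motifs, 1L, paste, collapse = "")
    motifs <- motifs[seq_len(n_variants)]
    tag_alpha <- c("A", "G", "U")
    tags <- vapply(seq_len(n_variants) - 1L, function(k) {
      digits <- integer(tag_len)
      for (d in seq_len(tag_len)) {
        digits[d] <- k %% 3L
        k <- k %/% 3L
      }
      paste(tag_alpha[digits + 1L], collapse = "")
    }, character(1))
    seqs <- vapply(seq_len(n_variants), function(i) {
      chars <- backbone
      chars[tag_offset + seq_len(tag_len)] <- seq_chars(tags[i])
      chars[site_offset + 1L + seq_len(4L)] <- seq_chars(motifs[i])
      paste(chars, collapse = "")
    }, character(1))
    pool <- data.frame(
      variant_id = sprintf("var%03d", seq_len(n_variants)),
      sequence = seqs, site_offset = site_offset, motif = motifs,
      n_motif_G = vapply(motifs,
                         function(m) sum(seq_chars(m) == "G"), 0L),
      mutation_tags = vapply(motifs, function(m) {
        paste(sprintf("motif_p%d=%s", 1:4, seq_chars(m)), collapse = ",")
      }, character(1)),
      stringsAsFactors = FALSE)
    conv <- vapply(seq_len(n_variants), function(i) {
      convert_reference(pool$sequence[i], site_offset)
    }, character(1))
    if (anyDuplicated(conv)) {
      stop("converted-reference collisions in substrate pool",
           call. = FALSE)
    }
    pool
  })
}

#' Simulate targeted BS-seq amplicon reads from a substrate pool
#'
#' Each BS read carries a random barcode, matches its variant's
#' converted reference exactly, and shows C at the assayed site with
#' probability equal to the variant's planted level. The paired DNA
#' library holds one unconverted read per barcode.
#'
#' @param pool A [makeSubstratePool()] result.
#' @param levels Named per-variant true methylation levels (fractions).
#' @param reads_per_variant Reads per variant.
#' @param barcode_len Barcode length (nt, DNA alphabet).
#' @param seed Integer seed.
#' @return List with `bs_reads` and `dna_reads` data.frames (read_id,
#'   barcode, seq, true_variant).
#' @export
simulateAmpliconReads <- function(pool, levels, reads_per_variant = 200L,
                                  barcode_len = 12L, seed = 1L) {
  if (is.null(names(levels)) || !all(pool$variant_id %in% names(levels))) {
    stop("levels must be named by variant_id", call. = FALSE)
  }
  with_seed(seed, {
    n <- nrow(pool) * reads_per_variant
    variant <- rep(pool$variant_id, each = reads_per_variant)
    conv_ref <- setNames(vapply(seq_len(nrow(pool)), function(i) {
      convert_reference(pool$sequence[i], pool$site_offset[i])
    }, character(1)), pool$variant_id)
    dna_ref <- setNames(dna_reference(pool$sequence), pool$variant_id)
    site <- setNames(pool$site_offset, pool$variant_id)
    meth <- runif(n) < levels[variant]
    seqs <- conv_ref[variant]
    unmeth <- !meth
    substr(seqs[unmeth],
           site[variant[unmeth]] + 1L, site[variant[unmeth]] + 1L) <- "T"
    barcodes <- vapply(seq_len(n), function(i) {
      paste(sample(DNA_BASES, barcode_len, replace = TRUE), collapse = "")
    }, character(1))
    ids <- sprintf("read%06d", seq_len(n))
    list(bs_reads = data.frame(read_id = ids, barcode = barcodes,
                               seq = unname(seqs), true_variant = variant,
                               stringsAsFactors = FALSE),
         dna_reads = data.frame(read_id = paste0(ids, "_dna"),
                                barcode = barcodes,
                                seq = unname(dna_ref[variant]),
                                true_variant = variant,
                                stringsAsFactors = FALSE))
  })
}

#' Retain reads with barcodes unique in both libraries
#'
#' Keeps BS reads whose barcode occurs exactly once in the BS library
#' and exactly once in the DNA library; the operation is idempotent.
#'
#' @param dna_reads,bs_reads Read tables with a `barcode` column.
#' @return The retained subset of `bs_reads`.
#' @export
dedupeBarcodes <- function(dna_reads, bs_reads) {
  bs_n <- table(bs_reads$barcode)
  dna_n <- table(dna_reads$barcode)
  keep <- bs_n[bs_reads$barcode] == 1L &
    !is.na(dna_n[bs_reads$barcode]) & dna_n[bs_reads$barcode] == 1L
  bs_reads[as.vector(keep), , drop = FALSE]
}

hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  as.numeric(sum(utf8ToInt(a) != utf8ToInt(b)))
}

#' Assign BS reads to substrate variants
#'
#' Matches each read against the C-to-T converted references (Hamming
#' distance over the aligned length, maximum `max_dist`); ambiguous best
#' matches are discarded and counted. The variant set is validated for
#' converted-reference collisions first. The C/T call at the assayed
#' site is extracted per assigned read.
#'
#' @param bs_reads BS read table (read_id, barcode, seq).
#' @param pool A [makeSubstratePool()]-shaped variant table.
#' @param max_dist Maximum allowed Hamming distance (default 5).
#' @return `data.frame` (read_id, barcode, variant_id, call) with the
#'   number of unassigned reads as attribute `n_unassigned`.
#' @export
assignReads <- function(bs_reads, pool, max_dist = 5L) {
  conv_ref <- vapply(seq_len(nrow(pool)), function(i) {
    convert_reference(pool$sequence[i], pool$site_offset[i])
  }, character(1))
  if (anyDuplicated(conv_ref)) {
    dup <- pool$variant_id[duplicated(conv_ref) |
                             duplicated(conv_ref, fromLast = TRUE)]
    stop("converted-reference collisions: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  ## exact match against both site states first (C or T at the site)
  ref_c <- conv_ref
  ref_t <- vapply(seq_len(nrow(pool)), function(i) {
    s <- conv_ref[i]
    substr(s, pool$site_offset[i] + 1L, pool$site_offset[i] + 1L) <- "T"
    s
  }, character(1))
  lut <- c(setNames(seq_len(nrow(pool)), ref_c),
           setNames(seq_len(nrow(pool)), ref_t))
  vidx <- unname(lut[bs_reads$seq])
  miss <- which(is.na(vidx))
  n_unassigned <- 0L
  for (i in miss) {
    d <- vapply(ref_c, hamming, 0, b = bs_reads$seq[i])
    dt2 <- vapply(ref_t, hamming, 0, b = bs_reads$seq[i])
    d <- pmin(d, dt2)
    best <- min(d)
    if (best <= max_dist && sum(d == best) == 1L) {
      vidx[i] <- which.min(d)
    } else {
      n_unassigned <- n_unassigned + 1L
    }
  }
  ok <- !is.na(vidx)
  call <- substr(bs_reads$seq[ok],
                 pool$site_offset[vidx[ok]] + 1L,
                 pool$site_offset[vidx[ok]] + 1L)
  call[!call %in% c("C", "T")] <- NA_character_
  out <- data.frame(read_id = bs_reads$read_id[ok],
                    barcode = bs_reads$barcode[ok],
                    variant_id = pool$variant_id[vidx[ok]],
                    call = call, stringsAsFactors = FALSE)
  attr(out, "n_unassigned") <- n_unassigned
  out
}

#' Per-variant methylation level
#'
#' Level = C / (C + T) at the assayed site over assigned reads; reads
#' with neither call are excluded. Variants with zero informative reads
#' are reported with `NA` level.
#'
#' @param assigned Output of [assignReads()].
#' @param pool Variant table (for the complete variant list).
#' @return `data.frame`: variant_id, n_C, n_T, level.
#' @export
variantLevel <- function(assigned, pool = NULL) {
  dt <- as.data.table(assigned)[!is.na(call)]
  per <- dt[, .(n_C = sum(call == "C"), n_T = sum(call == "T")),
            by = variant_id]
  if (!is.null(pool)) {
    per <- merge(data.table(variant_id = pool$variant_id), per,
                 by = "variant_id", all.x = TRUE)
    per[is.na(n_C), n_C := 0L]
    per[is.na(n_T), n_T := 0L]
  }
  per[, level := fifelse(n_C + n_T > 0L, n_C / (n_C + n_T), NA_real_)]
  as.data.frame(per)
}

#' Motif series summaries of variant levels
#'
#' Groups per-variant methylation levels by the number of Gs in the
#' motif, and by the base present at each motif position.
#'
#' @param levels Output of [variantLevel()].
#' @param pool Variant table with `n_motif_G` and `motif`.
#' @return List of two data.frames: `by_g_count` (n_motif_G, n, median,
#'   q25, q75) and `by_position` (motif_pos, base, n, median, q25, q75).
#' @export
motifSeries <- function(levels, pool) {
  m <- merge(as.data.table(levels), as.data.table(pool),
             by = "variant_id")
  m <- m[!is.na(level)]
  by_g <- m[, .(n = .N, median = median(level),
                q25 = quantile(level, 0.25), q75 = quantile(level, 0.75)),
            by = .(n_motif_G)][order(n_motif_G)]
  long <- rbindlist(lapply(1:4, function(p) {
    data.table(motif_pos = p,
               base = substr(m$motif, p, p),
               level = m$level)
  }))
  by_pos <- long[, .(n = .N, median = median(level),
                     q25 = quantile(level, 0.25),
                     q75 = quantile(level, 0.75)),
                 by = .(motif_pos, base)][order(motif_pos, base)]
  list(by_g_count = as.data.frame(by_g), by_position = as.data.frame(by_pos))
}
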