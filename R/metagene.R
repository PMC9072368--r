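## Metagene density and GC profiles over region-proportional
## 5'UTR/CDS/3'UTR bins.

#' Overall m5C density per thousand covered Cs
#'
#' @param n_sites Number of called m5C sites.
#' @param n_covered_c Number of Cs passing the coverage filter.
#' @return `1000 * n_sites / n_covered_c`.
#' @export
overallDensity <- function(n_sites, n_covered_c) {
  if (n_covered_c <= 0) stop("zero background C count", call. = FALSE)
  1000 * n_sites / n_covered_c
}

#' Derive a region-proportional bin layout
#'
#' The 5'UTR is fixed at `n_utr5` bins; CDS and 3'UTR bin counts are
#' their mean lengths relative to the mean 5'UTR length, rounded half
#' away from zero (minimum 1). Mean lengths 100/500/400 with ten 5'UTR
#' bins give the 10:50:40 layout.
#'
#' @param transcriptome A [Transcriptome-class] (or annotation
#'   `data.frame`).
#' @param n_utr5 Number of 5'UTR bins (>= 1).
#' @return A [BinLayout-class].
#' @export
deriveLayout <- function(transcriptome, n_utr5 = 10L) {
  anno <- if (is(transcriptome, "Transcriptome")) {
    transcriptAnno(transcriptome)
  } else as.data.frame(transcriptome)
  if (nrow(anno) == 0L) stop("no annotated transcripts", call. = FALSE)
  if (n_utr5 < 1L) stop("n_utr5 must be >= 1", call. = FALSE)
  m5 <- mean(anno$utr5_len)
  if (m5 <= 0) stop("mean 5'UTR length must be > 0", call. = FALSE)
  n_cds <- max(1L, as.integer(round_half_up(n_utr5 * mean(anno$cds_len) / m5)))
  n_utr3 <- max(1L, as.integer(round_half_up(n_utr5 * mean(anno$utr3_len) / m5)))
  BinLayout(n_utr5, n_cds, n_utr3)
}

#' Assign transcript positions to metagene bins
#'
#' Positions map through their region-local fractional coordinate
#' `f = offset / region_len` to `floor(f * n_region)`, clamped to the
#' region's last bin; bins are contiguous (5'UTR bins, then CDS, then
#' 3'UTR). Positions in a zero-length annotated region are unbinnable
#' and returned as `NA`.
#'
#' @param positions 0-based transcript positions.
#' @param transcript_ids Transcript id per position.
#' @param transcriptome A [Transcriptome-class] (or annotation).
#' @param layout A [BinLayout-class].
#' @return Integer vector of 0-based bin indices (NA = unbinnable).
#' @export
assignBin <- function(positions, transcript_ids, transcriptome, layout) {
  anno <- if (is(transcriptome, "Transcriptome")) {
    transcriptAnno(transcriptome)
  } else as.data.frame(transcriptome)
  idx <- match(transcript_ids, anno$transcript_id)
  if (any(is.na(idx))) stop("unknown transcript id", call. = FALSE)
  u5 <- anno$utr5_len[idx]; cds <- anno$cds_len[idx]
  u3 <- anno$utr3_len[idx]
  L <- u5 + cds + u3
  if (any(positions < 0L | positions >= L)) {
    stop("position outside transcript", call. = FALSE)
  }
  n5 <- layout@n_utr5; nc <- layout@n_cds; n3 <- layout@n_utr3
  region <- ifelse(positions < u5, 1L, ifelse(positions < u5 + cds, 2L, 3L))
  offset <- ifelse(region == 1L, positions,
                   ifelse(region == 2L, positions - u5, positions - u5 - cds))
  rlen <- ifelse(region == 1L, u5, ifelse(region == 2L, cds, u3))
  nreg <- ifelse(region == 1L, n5, ifelse(region == 2L, nc, n3))
  base <- ifelse(region == 1L, 0L, ifelse(region == 2L, n5, n5 + nc))
  bin <- ifelse(rlen > 0L,
                base + pmin(floor(offset / rlen * nreg), nreg - 1L),
                NA_integer_)
  as.integer(bin)
}

#' Binned metagene density profile
#'
#' Per-bin density = m5C count / background C count, with an optional
#' max-normalized variant (highest-density bin = 1). Bins without
#' background are reported with `NA` density, not 0.
#'
#' @param sites `data.frame` of m5C sites (transcript_id, pos/position).
#' @param background `data.frame` of background covered Cs
#'   (transcript_id, pos).
#' @param transcriptome A [Transcriptome-class].
#' @param layout A [BinLayout-class].
#' @return `data.frame`: bin, region, m5c_count, background_c, density,
#'   density_normalized.
#' @export
densityProfile <- function(sites, background, transcriptome, layout) {
  sites <- as.data.frame(sites)
  if (!"pos" %in% names(sites) && "position" %in% names(sites)) {
    sites$pos <- sites$position
  }
  nb <- nBins(layout)
  sb <- assignBin(sites$pos, sites$transcript_id, transcriptome, layout)
  bb <- assignBin(background$pos, background$transcript_id, transcriptome,
                  layout)
  m5c <- tabulate(sb + 1L, nbins = nb)
  bg <- tabulate(bb + 1L, nbins = nb)
  density <- ifelse(bg > 0L, m5c / bg, NA_real_)
  mx <- suppressWarnings(max(density, na.rm = TRUE))
  norm <- if (is.finite(mx) && mx > 0) density / mx else rep(NA_real_, nb)
  region <- rep(c("UTR5", "CDS", "UTR3"),
                c(layout@n_utr5, layout@n_cds, layout@n_utr3))
  out <- data.frame(bin = seq_len(nb) - 1L, region = region,
                    m5c_count = m5c, background_c = bg,
                    density = density, density_normalized = norm)
  attr(out, "n_unbinnable_sites") <- sum(is.na(sb))
  out
}

#' Per-bin GC content of a transcriptome
#'
#' GC fraction over all transcript nucleotides falling into each
#' metagene bin.
#'
#' @param transcriptome A [Transcriptome-class].
#' @param layout A [BinLayout-class].
#' @return `data.frame`: bin, region, n_nt, gc.
#' @export
gcProfile <- function(transcriptome, layout) {
  anno <- transcriptAnno(transcriptome)
  seqs <- tx_strings(transcriptome)
  nb <- nBins(layout)
  gc_count <- integer(nb); nt_count <- integer(nb)
  for (i in seq_len(nrow(anno))) {
    tid <- anno$transcript_id[i]
    chars <- seq_chars(seqs[[tid]])
    pos <- seq_along(chars) - 1L
    bins <- assignBin(pos, rep(tid, length(pos)), anno, layout)
    ok <- !is.na(bins)
    gc <- chars %in% c("G", "C")
    gc_count <- gc_count + tabulate(bins[ok & gc] + 1L, nbins = nb)
    nt_count <- nt_count + tabulate(bins[ok] + 1L, nbins = nb)
  }
  region <- rep(c("UTR5", "CDS", "UTR3"),
                c(layout@n_utr5, layout@n_cds, layout@n_utr3))
  data.frame(bin = seq_len(nb) - 1L, region = region, n_nt = nt_count,
             gc = ifelse(nt_count > 0L, gc_count / nt_count, NA_real_))
}

#' Pearson coefficient of determination between density and GC profiles
#'
#' @param density,gc Per-bin vectors of equal length (NA bins dropped
#'   pairwise).
#' @return Squared Pearson correlation; `NA` (with a warning) when
#'   either vector is constant.
#' @export
densityGcR2 <- function(density, gc) {
  ok <- !is.na(density) & !is.na(gc)
  if (sum(ok) < 3L) stop("need at least 3 bins", call. = FALSE)
  if (sd(density[ok]) == 0 || sd(gc[ok]) == 0) {
    warning("correlation undefined for constant profile")
    return(NA_real_)
  }
  cor(density[ok], gc[ok])^2
}
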