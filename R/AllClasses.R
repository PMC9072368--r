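#' Transcriptome container
#'
#' Holds transcript sequences together with their 5'UTR/CDS/3'UTR
#' annotation. Sequences are RNA (`A`/`C`/`G`/`U`) stored as a
#' [Biostrings::RNAStringSet]; the annotation carries one row per
#' transcript with the region lengths that drive metagene binning.
#'
#' @slot sequences An [Biostrings::RNAStringSet], one element per
#'   transcript, names equal to `transcript_id`.
#' @slot annotation A `data.frame` with columns `transcript_id`,
#'   `gene_id`, `utr5_len`, `cds_len`, `utr3_len`. Region lengths are in
#'   nucleotides and must sum to the sequence length; `cds_len` must be
#'   positive.
#'
#' @importClassesFrom Biostrings RNAStringSet
#' @export
setClass("Transcriptome",
  representation(sequences = "RNAStringSet", annotation = "data.frame"))

setValidity("Transcriptome", function(object) {
  anno <- object@annotation
  need <- c("transcript_id", "gene_id", "utr5_len", "cds_len", "utr3_len")
  if (!all(need %in% names(anno))) {
    return(paste("annotation must have columns:", paste(need, collapse = ", ")))
  }
  if (length(object@sequences) != nrow(anno)) {
    return("one annotation row per sequence required")
  }
  if (!identical(names(object@sequences), anno$transcript_id)) {
    return("sequence names must equal annotation$transcript_id (same order)")
  }
  tot <- anno$utr5_len + anno$cds_len + anno$utr3_len
  if (!all(tot == Biostrings::width(object@sequences))) {
    return("utr5_len + cds_len + utr3_len must equal sequence length")
  }
  if (any(anno$cds_len <= 0L)) return("cds_len must be > 0")
  if (any(anno$utr5_len < 0L) || any(anno$utr3_len < 0L)) {
    return("UTR lengths must be non-negative")
  }
  TRUE
})

#' Construct a Transcriptome
#'
#' @param sequences Named character vector of RNA sequences or an
#'   `RNAStringSet`.
#' @param annotation Annotation `data.frame` (see [Transcriptome-class]).
#' @return A [Transcriptome-class] object.
#' @examples
#' tx <- Transcriptome(
#'   c(t1 = "AACGUCGAUUGC"),
#'   data.frame(transcript_id = "t1", gene_id = "g1",
#'              utr5_len = 3L, cds_len = 6L, utr3_len = 3L))
#' transcriptAnno(tx)
#' @export
Transcriptome <- function(sequences, annotation) {
  if (is.character(sequences)) {
    sequences <- Biostrings::RNAStringSet(sequences)
  }
  annotation <- as.data.frame(annotation)
  annotation$utr5_len <- as.integer(annotation$utr5_len)
  annotation$cds_len <- as.integer(annotation$cds_len)
  annotation$utr3_len <- as.integer(annotation$utr3_len)
  new("Transcriptome", sequences = sequences, annotation = annotation)
}

#' @describeIn Transcriptome Number of transcripts.
#' @param x A `Transcriptome`.
#' @export
setMethod("length", "Transcriptome", function(x) length(x@sequences))

setMethod("show", "Transcriptome", function(object) {
  anno <- object@annotation
  cat("Transcriptome with", length(object), "transcripts,",
      length(unique(anno$gene_id)), "genes\n")
  cat("  total length:", sum(Biostrings::width(object@sequences)), "nt;",
      "mean UTR5/CDS/UTR3:",
      paste(round(c(mean(anno$utr5_len), mean(anno$cds_len),
                    mean(anno$utr3_len)), 1), collapse = "/"), "\n")
})

#' @rdname Transcriptome
#' @export
setGeneric("transcriptSeqs", function(x) standardGeneric("transcriptSeqs"))

#' @rdname Transcriptome
#' @export
setMethod("transcriptSeqs", "Transcriptome", function(x) x@sequences)

#' @rdname Transcriptome
#' @export
setGeneric("transcriptAnno", function(x) standardGeneric("transcriptAnno"))

#' @rdname Transcriptome
#' @export
setMethod("transcriptAnno", "Transcriptome", function(x) x@annotation)

## character sequences, named by transcript_id (internal convenience)
tx_strings <- function(tx) {
  setNames(as.character(tx@sequences), names(tx@sequences))
}

#' Metagene bin layout
#'
#' Region-proportional bin counts for the 5'UTR, CDS and 3'UTR segments of
#' a metagene profile (e.g. the human layout 10:50:40).
#'
#' @slot n_utr5,n_cds,n_utr3 Integer bin counts, all at least 1.
#' @export
setClass("BinLayout",
  representation(n_utr5 = "integer", n_cds = "integer", n_utr3 = "integer"))

setValidity("BinLayout", function(object) {
  if (object@n_utr5 < 1L || object@n_cds < 1L || object@n_utr3 < 1L) {
    return("all bin counts must be >= 1")
  }
  TRUE
})

#' @rdname BinLayout-class
#' @param n_utr5,n_cds,n_utr3 Bin counts per region.
#' @return A `BinLayout`.
#' @examples
#' BinLayout(10, 50, 40)
#' @export
BinLayout <- function(n_utr5, n_cds, n_utr3) {
  new("BinLayout", n_utr5 = as.integer(n_utr5), n_cds = as.integer(n_cds),
      n_utr3 = as.integer(n_utr3))
}

setMethod("show", "BinLayout", function(object) {
  cat(sprintf("BinLayout 5'UTR:CDS:3'UTR = %d:%d:%d (%d bins)\n",
              object@n_utr5, object@n_cds, object@n_utr3, nBins(object)))
})

#' @rdname BinLayout-class
#' @param x A `BinLayout`.
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname BinLayout-class
#' @export
setMethod("nBins", "BinLayout", function(x) x@n_utr5 + x@n_cds + x@n_utr3)

#' Called methylation sites with filter audit
#'
#' Result container of [callSites()]: the emitted high-confidence m5C
#' sites, the per-candidate filter audit (every candidate position appears
#' exactly once, either emitted or with its first failing filter), the
#' per-gene bisulfite conversion statistics, and the caller configuration
#' used.
#'
#' @slot sites `data.frame` of emitted sites (transcript_id, pos, gene_id,
#'   coverage, c_count, level, p_value, combined_p, replicate levels).
#' @slot audit `data.frame` with one row per candidate position and a
#'   `first_fail` column (`"emitted"` for called sites).
#' @slot geneStats `data.frame` of per-gene conversion statistics.
#' @slot config The [callerConfig()] list used for the run.
#' @export
setClass("MethylationCallSet",
  representation(sites = "data.frame", audit = "data.frame",
                 geneStats = "data.frame", config = "list"))

setMethod("show", "MethylationCallSet", function(object) {
  cat("MethylationCallSet:", nrow(object@sites), "sites called from",
      nrow(object@audit), "candidate positions\n")
  if (nrow(object@audit) > 0) {
    tab <- table(object@audit$first_fail)
    cat("  first-failing filter counts:\n")
    for (nm in names(tab)) cat(sprintf("    %-16s %d\n", nm, tab[[nm]]))
  }
})

#' @rdname MethylationCallSet-class
#' @param x A `MethylationCallSet`.
#' @export
setGeneric("sites", function(x) standardGeneric("sites"))

#' @rdname MethylationCallSet-class
#' @export
setMethod("sites", "MethylationCallSet", function(x) x@sites)

#' @rdname MethylationCallSet-class
#' @export
setGeneric("filterAudit", function(x) standardGeneric("filterAudit"))

#' @rdname MethylationCallSet-class
#' @export
setMethod("filterAudit", "MethylationCallSet", function(x) x@audit)

#' @rdname MethylationCallSet-class
#' @export
setGeneric("geneConversionStats",
           function(x) standardGeneric("geneConversionStats"))

#' @rdname MethylationCallSet-class
#' @export
setMethod("geneConversionStats", "MethylationCallSet", function(x) x@geneStats)

#' Logistic GLM fit
#'
#' Coefficients, standard errors and convergence state of the
#' methylation gain/loss logistic model fitted by [fitLogistic()].
#'
#' @slot coefficients Named numeric vector (includes `(Intercept)`).
#' @slot se Standard errors from the observed Fisher information.
#' @slot converged Logical convergence flag.
#' @slot n_pos,n_neg Class counts.
#' @slot iterations IRLS iterations used.
#' @export
setClass("GLMFit",
  representation(coefficients = "numeric", se = "numeric",
                 converged = "logical", n_pos = "integer", n_neg = "integer",
                 iterations = "integer"))

setMethod("show", "GLMFit", function(object) {
  cat(sprintf("GLMFit: %d features, %d/%d pos/neg, %s after %d iterations\n",
              length(object@coefficients) - 1L, object@n_pos, object@n_neg,
              if (object@converged) "converged" else "NOT converged",
              object@iterations))
})

#' @rdname GLMFit-class
#' @param object A `GLMFit`.
#' @param ... Unused.
#' @export
setMethod("coef", "GLMFit", function(object, ...) object@coefficients)

#' @rdname GLMFit-class
#' @param x A `GLMFit`.
#' @export
setGeneric("stdErrors", function(x) standardGeneric("stdErrors"))

#' @rdname GLMFit-class
#' @export
setMethod("stdErrors", "GLMFit", function(x) x@se)

#' @rdname GLMFit-class
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname GLMFit-class
#' @export
setMethod("isConverged", "GLMFit", function(x) x@converged)
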