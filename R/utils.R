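## Internal helpers shared across modules.

#' @import methods
#' @importFrom stats pbinom pnorm qnorm rbinom runif rnorm plogis qlogis
#'   binom.test sd cor median quantile setNames pt coef var
#' @importFrom utils head tail write.table read.table
#' @importFrom data.table data.table as.data.table setDT setkey setorder :=
#'   rbindlist fifelse setnames J .N .SD
#' @useDynLib m5Cquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

RNA_BASES <- c("A", "C", "G", "U")

## round-half-away-from-zero; base round() is banker's rounding
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

## split an RNA string into a character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

## 0-based positions of C in an RNA string
c_positions <- function(x) {
  which(seq_chars(x) == "C") - 1L
}

check_rna_alphabet <- function(x, what = "sequence") {
  bad <- setdiff(unique(seq_chars(x)), RNA_BASES)
  if (length(bad) > 0L) {
    stop(sprintf("%s contains non-RNA characters: %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

## deterministic child seed derived from a root seed and a label,
## kept below 2^31 so it is a valid R integer seed
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) %% 1000003L) * 1009L + (h %% 100003L)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  }
}
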