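#' Maximum base-pairing RNA folding (minimal folder)
#'
#' A maximum-pairing dynamic program (Nussinov recurrence) over the
#' canonical pairs AU/UA/GC/CG/GU/UG with a minimum hairpin loop length.
#' It supplies dot-bracket structures for the structure-dependent
#' analyses when externally computed (thermodynamic) structures are not
#' provided; the pairing count is the dynamic-program optimum, not a
#' free-energy minimum.
#'
#' @param seq RNA string over `A`/`C`/`G`/`U`.
#' @param min_loop Minimum number of unpaired bases enclosed by a pair.
#' @return Dot-bracket string of the same length as `seq`.
#' @examples
#' foldMinimal("GGGAAACCC")  # "(((...)))"
#' @export
foldMinimal <- function(seq, min_loop = 3L) {
  if (length(seq) != 1L || !is.character(seq)) {
    stop("seq must be a single RNA string", call. = FALSE)
  }
  if (nchar(seq) == 0L) return("")
  check_rna_alphabet(seq, "seq")
  .nussinov_fold(seq, as.integer(min_loop))
}

#' Pairing vector of a dot-bracket structure
#'
#' @param dotbracket Balanced dot-bracket string.
#' @return Integer vector with 1 at paired (bracket) positions and 0 at
#'   unpaired (dot) positions.
#' @examples
#' pairingVector("(((...)))")
#' @export
pairingVector <- function(dotbracket) {
  chars <- seq_chars(dotbracket)
  bad <- setdiff(unique(chars), c("(", ")", "."))
  if (length(bad) > 0L) {
    stop("invalid dot-bracket characters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0L) || (length(depth) && depth[length(depth)] != 0L)) {
    stop("unbalanced dot-bracket string", call. = FALSE)
  }
  as.integer(chars != ".")
}

#' Parse Vienna-style dot-bracket records
#'
#' Reads triplet records (`>id`, sequence, structure) as written by
#' common folding tools.
#'
#' @param path File of Vienna-style triplets.
#' @return `data.frame` with columns `id`, `seq`, `db`.
#' @export
readDotBracket <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 3L != 0L) {
    stop("dot-bracket file must consist of (id, sequence, structure) triplets",
         call. = FALSE)
  }
  idx <- seq(1L, length(lines), by = 3L)
  data.frame(id = sub("^>", "", lines[idx]),
             seq = lines[idx + 1L],
             db = sub("\\s.*$", "", lines[idx + 2L]),
             stringsAsFactors = FALSE)
}

#' @rdname readDotBracket
#' @param records `data.frame` with `id`, `seq`, `db`.
#' @export
writeDotBracket <- function(records, path) {
  stopifnot(all(c("id", "seq", "db") %in% names(records)))
  out <- as.vector(rbind(paste0(">", records$id), records$seq, records$db))
  writeLines(out, path)
  invisible(path)
}
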