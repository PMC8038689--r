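#' @importFrom utils head tail read.delim write.table
#' @importFrom stats setNames
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Create a normalized DNA sequence record
#'
#' A `seq_record` holds one DNA sequence over the alphabet `{A,C,G,T,N}`.
#' Input is uppercased; `U` is mapped to `T` and the substitution recorded in
#' the `u_mapped` field (a warning is also emitted). Any other character is an
#' error naming the record and the 1-based offending position.
#'
#' @param id Record identifier (non-empty string).
#' @param seq DNA sequence (non-empty string).
#' @param description Optional free-text description.
#' @return An object of class `seq_record` with fields `id`, `description`,
#'   `seq` and `u_mapped`.
#' @export
seq_record <- function(id, seq, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  u_mapped <- grepl("U", seq, fixed = TRUE)
  if (u_mapped) {
    seq <- gsub("U", "T", seq, fixed = TRUE)
    warning(sprintf("record '%s': U bases mapped to T", id), call. = FALSE)
  }
  if (!nzchar(seq)) {
    stop(sprintf("record '%s': empty sequence", id), call. = FALSE)
  }
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop(sprintf(
      "record '%s': illegal character '%s' at position %d",
      id, substr(seq, bad, bad), bad
    ), call. = FALSE)
  }
  structure(
    list(id = id, description = description, seq = seq, u_mapped = u_mapped),
    class = "seq_record"
  )
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf(
    "<seq_record> %s (%d nt)%s\n", x$id, nchar(x$seq),
    if (nzchar(x$description)) paste0(" - ", x$description) else ""
  ))
  invisible(x)
}

#' @export
length.seq_record <- function(x) nchar(x$seq)

as_seq_record <- function(x, id = "seq") {
  if (inherits(x, "seq_record")) x else seq_record(id, x)
}

#' Read a FASTA file into a list of sequence records
#'
#' Sequences are normalized as in [seq_record()]; entry order is preserved.
#' The header up to the first whitespace becomes the `id`, the remainder the
#' `description`.
#'
#' @param path Path to a FASTA file.
#' @return A list of `seq_record` objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  lapply(seq_along(ss), function(i) {
    seq_record(ids[i], as.character(ss[[i]]), descs[i])
  })
}

#' Write sequence records to a FASTA file
#'
#' Sequences are wrapped at 60 columns so that a read/write round trip is
#' byte-identical.
#'
#' @param records A `seq_record` or list of them.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "seq_record")) records <- list(records)
  seqs <- vapply(records, function(r) r$seq, character(1))
  hdrs <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, character(1))
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- hdrs
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' Watson-Crick complement, reversed; `N` maps to `N`. The operation is an
#' involution: `reverse_complement(reverse_complement(s)) == s`.
#'
#' @param seq DNA string over `{A,C,G,T,N}`.
#' @return The reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (grepl("[^ACGTN]", seq)) {
    stop("reverse_complement: sequence contains non-{A,C,G,T,N} characters",
         call. = FALSE)
  }
  if (!nzchar(seq)) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Plain character reverse (no complement); the mirror operation of
# reverse-Hoogsteen hairpin arms.
str_reverse <- function(seq) {
  paste(rev(strsplit(seq, "", fixed = TRUE)[[1L]]), collapse = "")
}
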