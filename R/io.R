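#' Read a clone library from FASTA
#'
#' Reads a FASTA file into a \linkS4class{CloneLibrary}. Sequences are
#' uppercased, U is mapped to T, and any character outside A/C/G/T/N raises an
#' error naming the record and position. Record order is preserved; duplicate
#' identifiers are an error.
#'
#' @param path Path to a FASTA file.
#' @param name Library name; defaults to the file base name.
#' @return A \linkS4class{CloneLibrary}.
#' @export
readFastaLibrary <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  s <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(s) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(s))
  if (anyDuplicated(ids))
    stop("duplicate id in FASTA: ", ids[duplicated(ids)][1L])
  ch <- chartr("U", "T", toupper(as.character(s)))
  names(ch) <- ids
  bad <- .checkAlphabet(ch)
  if (!is.null(bad)) stop(bad)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  CloneLibrary(ch, name = name)
}

#' Write a clone library (or any named sequence set) as FASTA
#'
#' @param x A CloneLibrary, DNAStringSet or named character vector.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeFastaLibrary <- function(x, path) {
  if (is(x, "CloneLibrary")) x <- clones(x)
  if (is.character(x)) {
    ids <- names(x)
    x <- DNAStringSet(x)
    names(x) <- ids
  }
  writeXStringSet(x, filepath = path, format = "fasta")
  invisible(path)
}

#' Read a labeled repeat panel from FASTA
#'
#' Panel FASTA headers carry the entry name, repeat class and optional
#' accession separated by '|': \code{>name|class|accession}.
#'
#' @param path Path to the panel FASTA.
#' @return A \linkS4class{RepeatPanel}.
#' @export
readRepeatPanel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  s <- readDNAStringSet(path, format = "fasta")
  if (length(s) == 0L) stop("empty panel FASTA: ", path)
  parts <- strsplit(sub("\\s.*$", "", names(s)), "|", fixed = TRUE)
  nm <- vapply(parts, `[`, "", 1L)
  cls <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else "other", "")
  acc <- vapply(parts, function(p) if (length(p) >= 3L) p[3L] else NA_character_, "")
  ch <- stats::setNames(chartr("U", "T", toupper(as.character(s))), nm)
  RepeatPanel(ch, repeatClass = cls, accession = acc)
}

#' Write a repeat panel as FASTA with name|class|accession headers
#' @param panel A RepeatPanel.
#' @param path Output path.
#' @export
writeRepeatPanel <- function(panel, path) {
  acc <- panel@accession
  acc[is.na(acc)] <- ""
  hdr <- paste(names(panel), panel@repeatClass, acc, sep = "|")
  s <- panelSeqs(panel)
  names(s) <- hdr
  writeXStringSet(s, filepath = path, format = "fasta")
  invisible(path)
}

# TSV writer with fixed column order and no quoting
.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
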