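#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that enforces the
#' conventions used throughout the package: sequences are upper-cased, record
#' order is preserved, multi-line records are concatenated, names are the
#' first whitespace-delimited token of the header, and duplicate names or
#' empty sequences are format errors.
#'
#' @param path path to a FASTA file.
#' @return A named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  empty <- names(seqs)[nchar(seqs) == 0L | nchar(names(seqs)) == 0L]
  if (length(empty) > 0)
    stop("FASTA format error: empty sequence or header for record(s): ",
         paste(sQuote(empty), collapse = ", "))
  dups <- unique(names(seqs)[duplicated(names(seqs))])
  if (length(dups) > 0)
    stop("FASTA format error: duplicate record name(s): ",
         paste(sQuote(dups), collapse = ", "))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, format = "fasta")
  invisible(path)
}

#' Read a FASTQ file
#'
#' Returns read sequences only. Base qualities are not modelled anywhere in
#' the package (the simulators emit a constant quality), so they are dropped
#' on input.
#'
#' @param path path to a FASTQ file.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write reads to FASTQ
#'
#' Reads are written with a constant base quality of `Q40` (`"I"`), the
#' package-wide convention.
#'
#' @param reads named character vector of read sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.character(reads), !is.null(names(reads)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(reads) > 0) {
    qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
    writeLines(paste0("@", names(reads), "\n", reads, "\n+\n", qual), con)
  }
  invisible(path)
}

#' Construct a genomic interval
#'
#' Coordinates are 0-based, half-open throughout the package.
#'
#' @param contig contig identifier.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must exceed `start`.
#' @param strand `"+"`, `"-"` or `"*"` (unstranded).
#' @return A one-row data frame.
#' @export
genomic_interval <- function(contig, start, end, strand = "*") {
  stopifnot(all(start >= 0), all(end > start),
            all(strand %in% c("+", "-", "*")))
  data.frame(contig = contig, start = as.integer(start),
             end = as.integer(end), strand = strand,
             stringsAsFactors = FALSE)
}

# internal: reverse complement for plain character vectors
rc <- function(x) revcomp_cpp(x)
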