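#' TE consensus sequence
#'
#' Container for a transposable-element consensus: the reference sequence
#' against which short reads, piRNAs and assembly hits are interpreted.
#' Long terminal repeat (LTR) coordinates can be attached with
#' [detect_ltrs()] / [set_ltrs()]; they are required by
#' [classify_full_length()].
#'
#' @param name element name (e.g. `"Spoink"`).
#' @param sequence nucleotide string over A/C/G/T/N.
#' @return An object of class `"te_consensus"` with fields `name`,
#'   `sequence`, `length` and (once detected) `ltr_length`, `ltr5`, `ltr3`
#'   (0-based half-open intervals on the consensus).
#' @export
te_consensus <- function(name, sequence) {
  stopifnot(is.character(name), length(name) == 1L, nchar(name) > 0,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("empty consensus sequence for ", sQuote(name))
  if (grepl("[^ACGTN]", sequence))
    stop("consensus ", sQuote(name), " contains characters outside A/C/G/T/N")
  structure(list(name = name, sequence = sequence,
                 length = nchar(sequence),
                 ltr_length = NULL, ltr5 = NULL, ltr3 = NULL),
            class = "te_consensus")
}

#' @export
print.te_consensus <- function(x, ...) {
  cat("<te_consensus>", x$name, "-", x$length, "nt")
  if (!is.null(x$ltr_length)) cat(", LTR", x$ltr_length, "nt")
  cat("\n")
  invisible(x)
}

# coerce a te_consensus or single named sequence to a named character scalar
as_consensus_seq <- function(x) {
  if (inherits(x, "te_consensus")) return(setNames(x$sequence, x$name))
  if (is.character(x) && length(x) == 1L && !is.null(names(x))) return(toupper(x))
  stop("expected a te_consensus object or a single named sequence")
}

#' Detect long terminal repeats by terminal self-comparison
#'
#' An intact LTR retrotransposon starts and ends with near-identical direct
#' repeats. Detection compares the 5' terminal window with the 3' terminal
#' window at every candidate length and returns the longest pair of
#' equal-length terminal intervals whose identity is at least
#' `1 - max_mismatch_frac`. Only substitutions are considered (the two LTR
#' copies of a young element are near-identical, so indel handling adds
#' nothing) and `N` bases count as mismatches.
#'
#' @param consensus a [te_consensus()] object.
#' @param min_ltr minimum LTR length to report, in nt; must be at least 20.
#' @param max_mismatch_frac maximum fraction of mismatched positions between
#'   the two terminal copies.
#' @return A list with elements `ltr5`, `ltr3` (integer `c(start, end)`,
#'   0-based half-open) and `ltr_length`, or `NULL` if no terminal repeat of
#'   length `>= min_ltr` qualifies.
#' @examples
#' ltr <- strrep("ACGTG", 30)                      # 150 nt terminal repeat
#' core <- strrep("TTGCA", 100)
#' te <- te_consensus("toy", paste0(ltr, core, ltr))
#' detect_ltrs(te)$ltr_length
#' @export
detect_ltrs <- function(consensus, min_ltr = 100L, max_mismatch_frac = 0.05) {
  stopifnot(inherits(consensus, "te_consensus"))
  if (min_ltr < 20L)
    stop("min_ltr must be at least 20 nt; shorter terminal matches are not ",
         "meaningful repeats")
  n <- consensus$length
  if (n <= 2L * min_ltr)
    stop("consensus shorter than 2 * min_ltr; cannot carry two terminal repeats")
  v <- strsplit(consensus$sequence, "", fixed = TRUE)[[1]]
  informative <- v %in% c("A", "C", "G", "T")
  l_max <- n %/% 2L  # the two copies must not overlap
  for (L in seq(l_max, min_ltr)) {
    a <- v[seq_len(L)]
    b <- v[seq(n - L + 1L, n)]
    mism <- sum(!(a == b & informative[seq_len(L)]))
    if (mism <= L * max_mismatch_frac) {
      return(list(ltr5 = c(0L, L), ltr3 = c(n - L, n), ltr_length = L))
    }
  }
  NULL
}

#' Attach LTR coordinates to a consensus
#'
#' @param consensus a [te_consensus()] object.
#' @param ltrs result of [detect_ltrs()]; when `NULL` (the default) the
#'   detection is run with its default parameters.
#' @param ... passed on to [detect_ltrs()].
#' @return The consensus with `ltr5`, `ltr3` and `ltr_length` filled in.
#' @export
set_ltrs <- function(consensus, ltrs = NULL, ...) {
  stopifnot(inherits(consensus, "te_consensus"))
  if (is.null(ltrs)) ltrs <- detect_ltrs(consensus, ...)
  if (is.null(ltrs))
    stop("no terminal repeat detected for ", sQuote(consensus$name))
  consensus$ltr5 <- as.integer(ltrs$ltr5)
  consensus$ltr3 <- as.integer(ltrs$ltr3)
  consensus$ltr_length <- as.integer(ltrs$ltr_length)
  stopifnot(consensus$ltr5[1] == 0L,
            consensus$ltr3[2] == consensus$length,
            diff(consensus$ltr5) == consensus$ltr_length,
            diff(consensus$ltr3) == consensus$ltr_length,
            consensus$ltr5[2] <= consensus$ltr3[1])
  consensus
}

#' Export LTR coordinates as GFF3
#'
#' Writes the detected terminal repeats of a consensus as
#' `long_terminal_repeat` features (GFF3, 1-based coordinates as required by
#' the format).
#'
#' @param consensus a [te_consensus()] with detected LTRs.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
ltr_gff <- function(consensus, path) {
  stopifnot(inherits(consensus, "te_consensus"))
  if (is.null(consensus$ltr_length))
    stop("consensus has no LTR coordinates; run detect_ltrs() first")
  gr <- GenomicRanges::GRanges(
    seqnames = consensus$name,
    ranges = IRanges::IRanges(
      start = c(consensus$ltr5[1], consensus$ltr3[1]) + 1L,
      end = c(consensus$ltr5[2], consensus$ltr3[2])),
    strand = "+",
    type = "long_terminal_repeat",
    ID = paste0(consensus$name, c("_LTR5", "_LTR3")))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
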