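#' Trim the small-RNA 3' sequencing adaptor
#'
#' Removes the adaptor and everything 3' of it at its first occurrence,
#' allowing `max_mismatch` mismatches, then drops reads whose trimmed
#' length falls outside the piRNA size range.
#'
#' @param reads named character vector of raw small-RNA reads (or a FASTQ
#'   path).
#' @param adaptor 3' adaptor sequence.
#' @param min_len,max_len retained length range after trimming, in nt.
#' @param max_mismatch mismatches tolerated when locating the adaptor.
#' @return Named character vector of trimmed reads.
#' @export
trim_adaptor <- function(reads, adaptor = "GAATTCTCGGGTGCCAAGG",
                         min_len = 18L, max_len = 35L, max_mismatch = 1L) {
  stopifnot(nchar(adaptor) > 0)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq(reads)
  if (length(reads) == 0L) return(reads)
  hits <- Biostrings::vmatchPattern(adaptor, Biostrings::DNAStringSet(reads),
                                    max.mismatch = max_mismatch)
  first <- vapply(hits, function(h)
    if (length(h) == 0L) NA_integer_ else min(IRanges::start(h)), integer(1))
  out <- ifelse(is.na(first), reads, substring(reads, 1L, first - 1L))
  names(out) <- names(reads)
  len <- nchar(out)
  out[len >= min_len & len <= max_len]
}

#' Map small RNAs to a TE consensus
#'
#' Full-length matching on both strands, exact first and with one mismatch
#' as a fallback for reads without an exact hit. A read matching several
#' positions within the TE is assigned to all of them with fractional
#' weight `1/n`.
#'
#' @param reads named character vector of trimmed reads (18--35 nt).
#' @param consensus a [te_consensus()] object.
#' @param max_mismatch mismatches tolerated in the fallback pass (0 or 1).
#' @return Data frame of stranded alignments: `read_id`, `strand`, `start`
#'   (0-based footprint start on the consensus), `width`, `five_prime`
#'   (genomic coordinate of the read's 5' terminus: footprint start on the
#'   sense strand, footprint end - 1 on the antisense strand), `weight`.
#'   The number of unmapped reads is attached as attribute `"n_unmapped"`.
#' @export
map_small_rnas <- function(reads, consensus, max_mismatch = 1L) {
  stopifnot(inherits(consensus, "te_consensus"))
  if (length(reads) == 0L)
    return(structure(data.frame(read_id = character(0), strand = character(0),
                                start = integer(0), width = integer(0),
                                five_prime = integer(0), weight = numeric(0),
                                stringsAsFactors = FALSE), n_unmapped = 0L))
  widths <- nchar(reads)
  if (any(widths < 18L | widths > 35L))
    stop("reads must be 18-35 nt after trimming")
  L <- consensus$length
  cons <- consensus$sequence
  rows <- list()
  unmatched <- logical(length(reads))

  for (w in sort(unique(widths))) {
    idx <- which(widths == w)
    if (L < w) { unmatched[idx] <- TRUE; next }
    starts <- seq_len(L - w + 1L)
    subs <- substring(cons, starts, starts + w - 1L)
    # all footprint starts hashed by substring, one table per strand
    sense_map <- split(starts - 1L, subs)
    anti_map <- split(starts - 1L, rc(subs))
    sp <- sense_map[match(reads[idx], names(sense_map))]
    ap <- anti_map[match(reads[idx], names(anti_map))]
    ns <- lengths(sp); na <- lengths(ap); n <- ns + na
    unmatched[idx[n == 0L]] <- TRUE
    hit <- n > 0L
    if (any(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = c(rep(names(reads)[idx][hit], unname(ns[hit])),
                    rep(names(reads)[idx][hit], unname(na[hit]))),
        strand = c(rep("+", sum(ns[hit])), rep("-", sum(na[hit]))),
        start = c(unlist(sp[hit], use.names = FALSE),
                  unlist(ap[hit], use.names = FALSE)),
        width = w,
        weight = unname(c(rep(1 / n[hit], unname(ns[hit])),
                          rep(1 / n[hit], unname(na[hit])))),
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }

  # 1-mismatch fallback for reads without an exact full-length hit
  n_unmapped <- 0L
  if (max_mismatch > 0L && any(unmatched)) {
    cons_dna <- Biostrings::DNAString(cons)
    for (i in which(unmatched)) {
      r <- reads[[i]]
      w <- nchar(r)
      sp <- IRanges::start(Biostrings::matchPattern(
        r, cons_dna, max.mismatch = max_mismatch)) - 1L
      ap <- IRanges::start(Biostrings::matchPattern(
        rc(r), cons_dna, max.mismatch = max_mismatch)) - 1L
      n <- length(sp) + length(ap)
      if (n == 0L) { n_unmapped <- n_unmapped + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = names(reads)[i],
        strand = c(rep("+", length(sp)), rep("-", length(ap))),
        start = c(sp, ap), width = w, weight = 1 / n,
        stringsAsFactors = FALSE)
    }
  } else {
    n_unmapped <- sum(unmatched)
  }

  aln <- do.call(rbind, rows)
  if (is.null(aln))
    aln <- data.frame(read_id = character(0), strand = character(0),
                      start = integer(0), width = integer(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
  aln$five_prime <- ifelse(aln$strand == "+", aln$start,
                           aln$start + aln$width - 1L)
  structure(aln, n_unmapped = n_unmapped, consensus_length = L,
            te = consensus$name)
}

#' Strand distribution of mapped piRNAs
#'
#' @param aln alignment data frame from [map_small_rnas()].
#' @param consensus_length consensus length; taken from the alignment
#'   attributes when omitted.
#' @return List: `sense_fraction` (weighted) and `coverage` (data frame
#'   `pos`, `sense`, `antisense` of weighted depth along the consensus).
#' @export
strand_profile <- function(aln, consensus_length = NULL) {
  if (nrow(aln) == 0L) stop("no mapped reads; no strand profile")
  if (is.null(consensus_length)) consensus_length <- attr(aln, "consensus_length")
  L <- consensus_length
  cov_one <- function(sub) {
    d <- numeric(L + 1L)
    if (nrow(sub) > 0) {
      for (i in seq_len(nrow(sub))) {
        d[sub$start[i] + 1L] <- d[sub$start[i] + 1L] + sub$weight[i]
        d[sub$start[i] + sub$width[i] + 1L] <-
          d[sub$start[i] + sub$width[i] + 1L] - sub$weight[i]
      }
    }
    cumsum(d)[seq_len(L)]
  }
  sense_w <- sum(aln$weight[aln$strand == "+"])
  list(sense_fraction = sense_w / sum(aln$weight),
       coverage = data.frame(pos = seq_len(L) - 1L,
                             sense = cov_one(aln[aln$strand == "+", ]),
                             antisense = cov_one(aln[aln$strand == "-", ])))
}

#' Ping-pong signature
#'
#' For every sense/antisense read pair whose footprints overlap, the 5'-5'
#' overlap is the distance from the sense read's 5' end to the antisense
#' read's 5' end, inclusive. Secondary piRNA biogenesis (the ping-pong
#' cycle) leaves a hallmark excess of 10-nt overlaps; `z10` measures the
#' overlap-10 count against the background overlaps 1-9 and 11-20.
#'
#' @param aln alignment data frame from [map_small_rnas()].
#' @param max_overlap largest overlap length tallied.
#' @return Object of class `"pingpong_profile"`: `te`, `overlap_counts`
#'   (weighted counts for overlaps `1..max_overlap`), `z10` (`NA` when
#'   undefined: a single-strand pool or zero background variance),
#'   `sense_fraction`, `per_position_coverage`.
#' @export
ping_pong_signature <- function(aln, max_overlap = 20L) {
  L <- attr(aln, "consensus_length")
  if (is.null(L)) L <- max(aln$start + aln$width, 0L)
  sense <- aln[aln$strand == "+", , drop = FALSE]
  anti <- aln[aln$strand == "-", , drop = FALSE]
  S <- numeric(L); A <- numeric(L)
  if (nrow(sense) > 0) {
    agg <- tapply(sense$weight, sense$five_prime, sum)
    S[as.integer(names(agg)) + 1L] <- agg
  }
  if (nrow(anti) > 0) {
    agg <- tapply(anti$weight, anti$five_prime, sum)
    A[as.integer(names(agg)) + 1L] <- agg
  }
  counts <- vapply(seq_len(max_overlap), function(d) {
    if (d - 1L >= L) return(0)
    sum(S[seq_len(L - d + 1L)] * A[seq(d, L)])
  }, numeric(1))
  names(counts) <- seq_len(max_overlap)
  z10 <- NA_real_
  if (nrow(sense) > 0 && nrow(anti) > 0 && max_overlap >= 10L) {
    bg <- counts[-10L]
    if (sd(bg) > 0) z10 <- (counts[[10L]] - mean(bg)) / sd(bg)
  }
  prof <- if (nrow(aln) > 0) strand_profile(aln, L) else
    list(sense_fraction = NA_real_, coverage = NULL)
  structure(list(te = attr(aln, "te"), overlap_counts = counts, z10 = z10,
                 sense_fraction = prof$sense_fraction,
                 per_position_coverage = prof$coverage),
            class = "pingpong_profile")
}

#' @export
print.pingpong_profile <- function(x, ...) {
  cat("<pingpong_profile>", if (!is.null(x$te)) x$te else "", "\n")
  cat("  z10:", format(x$z10, digits = 3),
      " sense fraction:", format(x$sense_fraction, digits = 3), "\n")
  invisible(x)
}

#' Profile a small-RNA pool against a TE
#'
#' Convenience pipeline: adaptor trimming, consensus mapping, strand
#' profile and ping-pong signature.
#'
#' @param reads raw small-RNA reads (named character vector or FASTQ path).
#' @param consensus a [te_consensus()].
#' @param adaptor 3' adaptor; `NULL` skips trimming.
#' @param out_dir optional output directory for the profile TSVs and a
#'   JSON summary.
#' @param ... passed to [trim_adaptor()].
#' @return A `"pingpong_profile"` (see [ping_pong_signature()]).
#' @export
pingpong_profile <- function(reads, consensus, adaptor = "GAATTCTCGGGTGCCAAGG",
                             out_dir = NULL, ...) {
  if (!is.null(adaptor)) reads <- trim_adaptor(reads, adaptor, ...)
  aln <- map_small_rnas(reads, consensus)
  prof <- ping_pong_signature(aln)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(prof$per_position_coverage,
                file.path(out_dir, "strand_coverage.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(overlap = as.integer(names(prof$overlap_counts)),
                           count = unname(prof$overlap_counts)),
                file.path(out_dir, "overlap_histogram.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(te = prof$te, z10 = prof$z10,
                              sense_fraction = prof$sense_fraction),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  prof
}
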