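#' Trim short reads to a fixed length
#'
#' Reads longer than `target_length` are truncated from the 3' end; shorter
#' reads are discarded. Trimming to a common length removes the coverage
#' bias that heterogeneous read lengths would otherwise introduce into the
#' copy-number normalisation.
#'
#' @param reads named character vector of read sequences (or a FASTQ path).
#' @param target_length target read length in nt (at least 30).
#' @return Named character vector of trimmed reads; the number of dropped
#'   reads is reported via `message()` and attached as attribute
#'   `"n_dropped"`.
#' @export
trim_reads <- function(reads, target_length = 100L) {
  if (target_length < 30L) stop("target_length must be at least 30 nt")
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq(reads)
  if (length(reads) == 0L) {
    warning("no input reads")
    return(structure(character(0), n_dropped = 0L))
  }
  len <- nchar(reads)
  keep <- len >= target_length
  out <- substring(reads[keep], 1L, target_length)
  names(out) <- names(reads)[keep]
  n_drop <- sum(!keep)
  message(n_drop, " read(s) shorter than ", target_length, " nt dropped")
  structure(out, n_dropped = n_drop)
}

#' Map short reads to TE consensus and single-copy gene references
#'
#' Built-in seed-and-extend mapper: exact `k`-mer seeds locate candidate
#' reference diagonals and each candidate is aligned by affine-gap dynamic
#' programming that is end-to-end in the read (terminal read bases are kept
#' as matches or mismatches rather than clipped, so pileup columns near
#' read ends retain their minor alleles) and local in the reference; query
#' overhangs, e.g. on reads spanning an insertion junction, become soft
#' clips. Reads whose mismatches leave no clean `k`-mer fall back to
#' disjoint 16-mer rescue seeds. The single best hit is kept (no
#' fractional assignment); both strands are searched; alignments whose
#' identity over aligned columns falls below `min_identity` are reported
#' unmapped. Ties are broken by reference order in `references`, then by
#' leftmost position.
#'
#' Any externally produced SAM can be used instead via [read_sam()]; the
#' pileup honours standard flags and CIGARs either way.
#'
#' @param reads named character vector of (trimmed) read sequences.
#' @param references named character vector of reference sequences, TE
#'   consensus first, then single-copy genes; order defines tie-breaking.
#' @param k seed length (default 31; long enough that background reads have
#'   essentially no seed by chance).
#' @param min_identity minimum identity over aligned columns.
#' @param scoring an [alignment_scoring()].
#' @param seed_stride spacing of seed offsets along each read.
#' @param pad extra reference context around a seeded diagonal for the
#'   gapped extension.
#' @return A data frame of class `"te_alignments"`: `qname`, `rname`, `pos`
#'   (0-based), `strand`, `cigar` (with soft clips), `score`, `identity`,
#'   `seq` (alignment-oriented), `mapped`. Reference names and lengths are
#'   kept in attributes.
#' @export
map_reads <- function(reads, references, k = 31L, min_identity = 0.85,
                      scoring = alignment_scoring(), seed_stride = 10L,
                      pad = 30L) {
  stopifnot(length(references) > 0, !is.null(names(references)))
  if (any(grepl("[^ACGTN]", references)))
    stop("reference format error: sequences must contain only A/C/G/T/N")
  if (length(reads) == 0L)
    stop("no reads to map")
  aln <- map_reads_cpp(unname(reads), names(reads),
                       unname(references), names(references),
                       as.integer(k), min_identity,
                       scoring$match, scoring$mismatch,
                       scoring$gap_open, scoring$gap_ext,
                       as.integer(seed_stride), as.integer(pad))
  structure(aln,
            ref_names = names(references),
            ref_lengths = setNames(nchar(references), names(references)),
            class = c("te_alignments", "data.frame"))
}

#' Write alignments as SAM
#'
#' @param aln a `"te_alignments"` data frame from [map_reads()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path) {
  ref_len <- attr(aln, "ref_lengths")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(ref_len), ref_len), con)
  flag <- ifelse(!aln$mapped, 4L, ifelse(aln$strand == "-", 16L, 0L))
  out <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                 aln$qname, flag,
                 ifelse(aln$mapped, aln$rname, "*"),
                 ifelse(aln$mapped, aln$pos + 1L, 0L),
                 ifelse(aln$mapped, 60L, 0L),
                 ifelse(aln$mapped, aln$cigar, "*"),
                 ifelse(aln$mapped, aln$seq, "N"))
  writeLines(out, con)
  invisible(path)
}

#' Read alignments from SAM
#'
#' Ingests an externally produced SAM (converted through
#' [Rsamtools::asBam()]) into the same alignment table the built-in mapper
#' emits, so downstream pileup and quantification accept either source.
#' Secondary and supplementary alignments are dropped.
#'
#' @param path path to a SAM file with `@SQ` header lines.
#' @return A `"te_alignments"` data frame (see [map_reads()]); `score` and
#'   `identity` are `NA` for external alignments.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "cigar", "seq"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- bitwAnd(x$flag, 256L) == 0L & bitwAnd(x$flag, 2048L) == 0L
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  aln <- data.frame(
    qname = x$qname[keep],
    rname = as.character(x$rname)[keep],
    pos = x$pos[keep] - 1L,
    strand = as.character(x$strand)[keep],
    cigar = x$cigar[keep],
    score = NA_integer_, identity = NA_real_,
    seq = as.character(x$seq)[keep],
    mapped = bitwAnd(x$flag[keep], 4L) == 0L,
    stringsAsFactors = FALSE)
  aln$rname[!aln$mapped] <- NA_character_
  structure(aln, ref_names = names(hdr),
            ref_lengths = hdr,
            class = c("te_alignments", "data.frame"))
}

#' Build per-position pileups
#'
#' One column per reference position; only aligned (match/mismatch) bases
#' are counted, deletions skip columns, insertions and soft clips are
#' ignored. `N` bases are excluded from the counts, so column depth always
#' equals the sum of the A/C/G/T counts.
#'
#' @param aln a `"te_alignments"` data frame.
#' @param references optional named character vector restricting/ordering
#'   the references; defaults to all references seen at mapping time.
#' @return A named list of class `"te_pileup"`; one `4 x L` integer matrix
#'   (rows A, C, G, T) per reference.
#' @export
pileup <- function(aln, references = NULL) {
  ref_len <- attr(aln, "ref_lengths")
  if (!is.null(references)) {
    ref_len <- if (is.character(references) && !is.null(names(references)))
      setNames(nchar(references), names(references)) else ref_len[references]
  }
  if (is.null(ref_len)) stop("no reference lengths available")
  m <- aln[aln$mapped, , drop = FALSE]
  out <- lapply(names(ref_len), function(rn) {
    sub <- m[m$rname == rn, , drop = FALSE]
    cnt <- pileup_cpp(sub$seq, sub$pos, sub$cigar, sub$qname,
                      as.integer(ref_len[[rn]]))
    rownames(cnt) <- c("A", "C", "G", "T")
    cnt
  })
  structure(setNames(out, names(ref_len)), class = "te_pileup")
}

pileup_depth <- function(mat) colSums(mat)

#' Estimate the normalised TE copy number
#'
#' The haploid-equivalent copy number is the mean read depth over all TE
#' consensus positions divided by the unweighted mean of the per-gene mean
#' depths of the single-copy genes. A TE is called present when the
#' estimate is strictly greater than 1, which ignores sub-unit background
#' signal from degraded ancient fragments.
#'
#' @param pileups a `"te_pileup"` list from [pileup()].
#' @param te name of the TE reference.
#' @param scg character vector of single-copy gene reference names.
#' @param strain strain identifier carried into the output.
#' @return One-row data frame: `strain`, `te`, `copy_number`,
#'   `te_mean_depth`, `present`; per-gene mean depths are attached as
#'   attribute `"scg_mean_depths"`.
#' @export
estimate_copy_number <- function(pileups, te, scg, strain = "sample") {
  stopifnot(inherits(pileups, "te_pileup"), te %in% names(pileups),
            all(scg %in% names(pileups)))
  te_depth <- mean(pileup_depth(pileups[[te]]))
  scg_means <- vapply(scg, function(g) mean(pileup_depth(pileups[[g]])),
                      numeric(1))
  if (all(scg_means == 0))
    stop("all single-copy gene depths are zero; normalisation impossible ",
         "(failed sequencing or mapping?)")
  if (any(scg_means == 0))
    warning("single-copy gene(s) with zero depth: ",
            paste(scg[scg_means == 0], collapse = ", "))
  cn <- te_depth / mean(scg_means)
  structure(
    data.frame(strain = strain, te = te, copy_number = cn,
               te_mean_depth = te_depth, present = cn > 1,
               stringsAsFactors = FALSE),
    scg_mean_depths = scg_means)
}

#' Call TE-internal SNPs from a consensus pileup
#'
#' A consensus position is a SNP among the dispersed copies of the TE iff
#' its depth reaches `min_depth` and the second-most-frequent base exceeds
#' a minor allele frequency of `maf_threshold` (strictly).
#'
#' @param pileups a `"te_pileup"` list, or a single `4 x L` count matrix.
#' @param te TE reference name (used to select from the list and carried
#'   into the output).
#' @param maf_threshold minor allele frequency call threshold (strict `>`).
#' @param min_depth minimum column depth; below it binomial noise makes the
#'   MAF threshold meaningless.
#' @return Data frame: `te`, `pos` (0-based), `major`, `minor`, `maf`.
#' @export
call_te_snps <- function(pileups, te = NULL, maf_threshold = 0.1,
                         min_depth = 10L) {
  mat <- if (inherits(pileups, "te_pileup")) {
    stopifnot(!is.null(te), te %in% names(pileups))
    pileups[[te]]
  } else pileups
  if (is.null(te)) te <- "te"
  depth <- colSums(mat)
  bases <- rownames(mat)
  ord <- apply(mat, 2L, order, decreasing = TRUE)
  major_cnt <- mat[cbind(ord[1L, ], seq_len(ncol(mat)))]
  minor_cnt <- mat[cbind(ord[2L, ], seq_len(ncol(mat)))]
  maf <- ifelse(depth > 0, minor_cnt / depth, 0)
  is_snp <- depth >= min_depth & maf > maf_threshold
  data.frame(te = rep(te, sum(is_snp)), pos = which(is_snp) - 1L,
             major = bases[ord[1L, is_snp]],
             minor = bases[ord[2L, is_snp]],
             maf = unname(maf[is_snp]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Quantify one sample end to end
#'
#' Convenience pipeline: trim, map (or ingest an external SAM), pile up,
#' estimate copy numbers for every TE and call TE-internal SNPs.
#'
#' @param reads named character vector of reads, or a FASTQ path.
#' @param te_refs named character vector of TE consensus sequences.
#' @param scg_refs named character vector of single-copy gene sequences.
#' @param strain strain identifier.
#' @param sam optional path to an externally produced SAM used instead of
#'   the built-in mapper.
#' @param maf_threshold,min_depth passed to [call_te_snps()].
#' @param target_length passed to [trim_reads()].
#' @param out_dir optional directory; when given, copy-number and SNP TSVs,
#'   a per-position coverage TSV and (for the built-in mapper) a SAM are
#'   written there.
#' @param ... passed to [map_reads()].
#' @return List with `copy_numbers` (one row per TE), `snps`, `pileups`,
#'   `alignments`.
#' @export
quantify_sample <- function(reads, te_refs, scg_refs, strain = "sample",
                            sam = NULL, maf_threshold = 0.1, min_depth = 10L,
                            target_length = 100L, out_dir = NULL, ...) {
  refs <- c(te_refs, scg_refs)
  if (is.null(sam)) {
    reads <- trim_reads(reads, target_length)
    aln <- map_reads(reads, refs, ...)
  } else {
    aln <- read_sam(sam)
  }
  pl <- pileup(aln, refs)
  cn <- do.call(rbind, lapply(names(te_refs), function(te)
    estimate_copy_number(pl, te, names(scg_refs), strain = strain)))
  snps <- do.call(rbind, lapply(names(te_refs), function(te)
    call_te_snps(pl, te, maf_threshold = maf_threshold,
                 min_depth = min_depth)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(cn, file.path(out_dir, "copy_numbers.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(snps, file.path(out_dir, "te_snps.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cov <- do.call(rbind, lapply(names(pl), function(rn)
      data.frame(ref = rn, pos = seq_len(ncol(pl[[rn]])) - 1L,
                 depth = colSums(pl[[rn]]), stringsAsFactors = FALSE)))
    write.table(cov, file.path(out_dir, "coverage.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (is.null(sam)) write_sam(aln, file.path(out_dir, "alignments.sam"))
  }
  list(copy_numbers = cn, snps = snps, pileups = pl, alignments = aln)
}
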