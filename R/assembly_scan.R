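#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' Full dynamic-programming local alignment with the package scoring scheme.
#' Divergence is the RepeatMasker-style substitution percentage: mismatched
#' columns over aligned match/mismatch columns, gap columns excluded.
#'
#' @param query,target nucleotide strings (non-empty).
#' @param scoring an [alignment_scoring()].
#' @return List: `score`, `q_start`, `q_end`, `t_start`, `t_end` (0-based,
#'   half-open), `matches`, `mismatches`, `gap_cols`, `aligned_cols`,
#'   `divergence` (percent), `cigar` (query vs target).
#' @export
smith_waterman <- function(query, target, scoring = alignment_scoring()) {
  stopifnot(is.character(query), length(query) == 1L, nchar(query) > 0,
            is.character(target), length(target) == 1L, nchar(target) > 0)
  r <- sw_align_cpp(query, target, scoring$match, scoring$mismatch,
                    scoring$gap_open, scoring$gap_ext)
  r$divergence <- if (r$aligned_cols > 0) 100 * r$mismatches / r$aligned_cols else NA_real_
  r
}

# cluster seed hits into candidate loci: seeds are first grouped into
# diagonal runs (gaps in sorted diagonals larger than max_diag_drift separate
# distinct copies, which sit at least one element length apart), then each
# run is split on large target-position gaps
cluster_seeds <- function(qpos, tpos, max_gap = 400L, max_diag_drift = 400L) {
  if (length(tpos) == 0L) return(list())
  diag <- tpos - qpos
  o <- order(diag, tpos)
  qpos <- qpos[o]; tpos <- tpos[o]; diag <- diag[o]
  dgrp <- cumsum(c(1L, diff(diag) > max_diag_drift))
  out <- list()
  for (g in unique(dgrp)) {
    sel <- which(dgrp == g)
    sel <- sel[order(tpos[sel])]
    brk <- c(0L, which(diff(tpos[sel]) > max_gap), length(sel))
    brk <- unique(brk)
    for (i in seq_len(length(brk) - 1L)) {
      idx <- sel[(brk[i] + 1L):brk[i + 1L]]
      out[[length(out) + 1L]] <- list(qpos = qpos[idx], tpos = tpos[idx])
    }
  }
  out
}

scan_one_strand <- function(query, contig_seq, contig, te, strand, k,
                            scoring, min_score) {
  seeds <- seed_hits_cpp(query, contig_seq, as.integer(k))
  clusters <- cluster_seeds(seeds$qpos, seeds$tpos)
  Lq <- nchar(query)
  hits <- list()
  seen <- character(0)
  for (cl in clusters) {
    t_lo <- max(0L, min(cl$tpos - cl$qpos) - 150L)
    t_hi <- min(nchar(contig_seq), max(cl$tpos + (Lq - cl$qpos)) + 150L)
    key <- paste(t_lo, t_hi)
    if (key %in% seen) next
    seen <- c(seen, key)
    window <- substring(contig_seq, t_lo + 1L, t_hi)
    a <- smith_waterman(query, window, scoring)
    if (a$score < min_score || a$aligned_cols == 0L) next
    qs <- a$q_start; qe <- a$q_end
    if (strand == "-") { tmp <- qs; qs <- Lq - qe; qe <- Lq - tmp }
    hits[[length(hits) + 1L]] <- data.frame(
      contig = contig, start = t_lo + a$t_start, end = t_lo + a$t_end,
      strand = strand, te = te, score = a$score,
      divergence = a$divergence,
      consensus_start = qs, consensus_end = qe,
      aligned_len = a$t_end - a$t_start,
      aligned_cols = a$aligned_cols,
      stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L) return(NULL)
  do.call(rbind, hits)
}

# chain same-contig, same-strand hits whose genomic intervals overlap or lie
# within merge_gap of one another into one insertion; contained duplicates
# collapse to the best-scoring member, chained fragments sum their scores
merge_hits <- function(hits, merge_gap = 100L) {
  if (is.null(hits) || nrow(hits) == 0L) return(hits)
  out <- list()
  for (grp in split(hits, paste(hits$contig, hits$strand, hits$te))) {
    grp <- grp[order(grp$start, -grp$score), , drop = FALSE]
    cl_id <- cumsum(c(1L, cummax(head(grp$end, -1))[seq_len(nrow(grp) - 1L)] +
                        merge_gap < grp$start[-1L]))
    for (cl in split(grp, cl_id)) {
      # drop members contained in a higher-scoring member
      keep <- rep(TRUE, nrow(cl))
      for (i in seq_len(nrow(cl))) {
        contained <- cl$start >= cl$start[i] & cl$end <= cl$end[i] &
          seq_len(nrow(cl)) != i & cl$score <= cl$score[i]
        keep[contained] <- FALSE
      }
      cl <- cl[keep, , drop = FALSE]
      best <- which.max(cl$score)
      merged <- cl[best, , drop = FALSE]
      if (nrow(cl) > 1L) {
        merged$start <- min(cl$start); merged$end <- max(cl$end)
        merged$consensus_start <- min(cl$consensus_start)
        merged$consensus_end <- max(cl$consensus_end)
        merged$score <- sum(cl$score)
        merged$divergence <- sum(cl$divergence * cl$aligned_cols) /
          sum(cl$aligned_cols)
        merged$aligned_len <- sum(cl$aligned_len)
        merged$aligned_cols <- sum(cl$aligned_cols)
      }
      out[[length(out) + 1L]] <- merged
    }
  }
  res <- do.call(rbind, out)
  res[order(res$contig, res$start), , drop = FALSE]
}

#' Scan a genome assembly for TE insertions
#'
#' Seed-and-extend homology search of the consensus against every contig on
#' both strands: exact `k`-mer seeds are clustered into candidate loci,
#' each locus is aligned by full local dynamic programming, nearby
#' fragments are chained, and the retained hits must satisfy the strict
#' insertion filters: aligned length on the assembly `> min_len` and
#' substitution divergence `< max_div` percent.
#'
#' @param assembly named character vector of contig sequences (or a FASTA
#'   path).
#' @param consensus a [te_consensus()] object.
#' @param min_len length filter in bp (strict `>`).
#' @param max_div divergence filter in percent (strict `<`).
#' @param k seed length; 13 gives abundant clean seeds up to ~10%
#'   divergence.
#' @param merge_gap chain hits separated by at most this many bp.
#' @param scoring an [alignment_scoring()].
#' @param keep_all when `TRUE`, return unfiltered hits with a `retained`
#'   column instead of applying the filters.
#' @return Data frame of hits: `contig`, `start`, `end` (0-based
#'   half-open), `strand`, `te`, `score`, `divergence`,
#'   `consensus_start`, `consensus_end`, `fraction_of_consensus`,
#'   `aligned_len`.
#' @export
scan_assembly <- function(assembly, consensus, min_len = 750L, max_div = 10,
                          k = 13L, merge_gap = 100L,
                          scoring = alignment_scoring(), keep_all = FALSE) {
  if (is.character(assembly) && length(assembly) == 1L && is.null(names(assembly)))
    assembly <- read_fasta(assembly)
  stopifnot(inherits(consensus, "te_consensus"))
  fwd <- consensus$sequence
  rev <- rc(fwd)
  all_hits <- list()
  for (contig in names(assembly)) {
    cseq <- assembly[[contig]]
    for (strand in c("+", "-")) {
      q <- if (strand == "+") fwd else rev
      h <- scan_one_strand(q, cseq, contig, consensus$name, strand,
                           k = k, scoring = scoring,
                           min_score = max(20L, 2L * k))
      if (!is.null(h)) all_hits[[length(all_hits) + 1L]] <- h
    }
  }
  empty <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      te = character(0), score = integer(0),
                      divergence = numeric(0), consensus_start = integer(0),
                      consensus_end = integer(0),
                      fraction_of_consensus = numeric(0),
                      aligned_len = integer(0), stringsAsFactors = FALSE)
  if (length(all_hits) == 0L) return(empty)
  hits <- merge_hits(do.call(rbind, all_hits), merge_gap = merge_gap)
  hits$fraction_of_consensus <-
    (hits$consensus_end - hits$consensus_start) / consensus$length
  hits$aligned_cols <- NULL
  filter_insertions(hits, min_len = min_len, max_div = max_div,
                    keep_all = keep_all)
}

#' Insertion filters
#'
#' The countable-insertion filters applied to scan hits: aligned length on
#' the assembly strictly greater than `min_len` bp and substitution
#' divergence strictly below `max_div` percent. A 750-bp or 10%-divergence
#' hit is excluded.
#'
#' @param hits data frame with `aligned_len` and `divergence` columns.
#' @param min_len length filter in bp (strict `>`).
#' @param max_div divergence filter in percent (strict `<`).
#' @param keep_all when `TRUE`, return all hits with a logical `retained`
#'   column instead of subsetting.
#' @return Filtered hits (or annotated hits with `keep_all = TRUE`).
#' @export
filter_insertions <- function(hits, min_len = 750L, max_div = 10,
                              keep_all = FALSE) {
  retained <- hits$aligned_len > min_len & hits$divergence < max_div
  if (keep_all) {
    hits$retained <- retained
    return(hits)
  }
  hits[retained, , drop = FALSE]
}

#' Classify hits as full-length (complete) insertions
#'
#' A complete insertion spans more than 80% of the consensus length
#' (strict) and covers at least 80% of each of the two LTR intervals.
#'
#' @param hits data frame from [scan_assembly()].
#' @param consensus a [te_consensus()] with detected LTRs (see
#'   [detect_ltrs()]).
#' @return Logical vector (one element per hit).
#' @export
classify_full_length <- function(hits, consensus) {
  stopifnot(inherits(consensus, "te_consensus"))
  if (is.null(consensus$ltr_length))
    stop("consensus has no LTR coordinates; run detect_ltrs()/set_ltrs() first")
  cov_frac <- function(span_lo, span_hi, iv) {
    pmax(0L, pmin(span_hi, iv[2]) - pmax(span_lo, iv[1])) / diff(iv)
  }
  hits$fraction_of_consensus > 0.8 &
    cov_frac(hits$consensus_start, hits$consensus_end, consensus$ltr5) >= 0.8 &
    cov_frac(hits$consensus_start, hits$consensus_end, consensus$ltr3) >= 0.8
}

#' Cross-assembly similarity statistic
#'
#' For each assembly, `s = best_score / max_score`, where `best_score` is
#' the highest alignment score of the TE in that assembly and `max_score`
#' the highest score in any of the analysed assemblies. `s = 0` means no
#' hit; `s = 1` marks the assembly (or assemblies, on ties) carrying the
#' best-preserved copy.
#'
#' @param hits data frame of scan hits with an `assembly` column (see
#'   [scan_assemblies()]).
#' @param assemblies character vector of all analysed assembly identifiers
#'   (assemblies without hits receive `s = 0`); defaults to those present
#'   in `hits`.
#' @param te TE name; defaults to the single TE in `hits`.
#' @return Data frame: `assembly`, `te`, `s`, `best_score`, `max_score`.
#' @export
similarity_scores <- function(hits, assemblies = NULL, te = NULL) {
  if (is.null(te)) {
    te <- unique(hits$te)
    if (length(te) > 1L) stop("hits contain several TEs; pass `te`")
    if (length(te) == 0L) te <- NA_character_
  } else {
    hits <- hits[hits$te == te, , drop = FALSE]
  }
  if (is.null(assemblies)) assemblies <- unique(hits$assembly)
  best <- vapply(assemblies, function(a) {
    s <- hits$score[hits$assembly == a]
    if (length(s) == 0L) 0 else max(s)
  }, numeric(1))
  max_score <- if (length(best) > 0) max(best) else 0
  if (max_score == 0) {
    warning("no hits in any assembly; all similarity scores are 0")
    s <- rep(0, length(best))
  } else {
    s <- best / max_score
  }
  data.frame(assembly = assemblies, te = te, s = s, best_score = best,
             max_score = max_score, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Scan several assemblies
#'
#' @param assemblies named list of assemblies (each a named character
#'   vector of contigs, or a FASTA path).
#' @param consensus a [te_consensus()].
#' @param ... passed to [scan_assembly()].
#' @return Combined hit data frame with an `assembly` column.
#' @export
scan_assemblies <- function(assemblies, consensus, ...) {
  stopifnot(is.list(assemblies), !is.null(names(assemblies)))
  out <- lapply(names(assemblies), function(a) {
    h <- scan_assembly(assemblies[[a]], consensus, ...)
    if (nrow(h) > 0) cbind(assembly = a, h, stringsAsFactors = FALSE)
    else NULL
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L)
    return(cbind(assembly = character(0),
                 scan_assembly(paste0(strrep("A", 40)), consensus, ...)[0, ]))
  do.call(rbind, out)
}

#' Extract the genomic sequence of a hit
#'
#' @param assembly named character vector of contigs.
#' @param hit one-row hit data frame.
#' @return The insertion sequence, reverse-complemented for `-` strand
#'   hits so it reads in consensus orientation.
#' @export
hit_sequence <- function(assembly, hit) {
  s <- substring(assembly[[hit$contig]], hit$start + 1L, hit$end)
  if (hit$strand == "-") s <- rc(s)
  s
}

#' Genic context of insertions
#'
#' Classifies each insertion by its position relative to the gene
#' annotation. An insertion within `promoter_window` bp upstream of a
#' transcription start site (strand-aware) is a promoter insertion, taking
#' precedence over everything else; otherwise the innermost overlapping
#' feature wins (UTRs before exon before intron); no overlap is intergenic.
#'
#' @param hits data frame of hits (`contig`, `start`, `end`).
#' @param genes a GFF3 path or a [GenomicRanges::GRanges] with `type` in
#'   gene/exon/five_prime_UTR/three_prime_UTR; gene features must be
#'   stranded.
#' @param promoter_window promoter width upstream of the TSS, in bp.
#' @return Character vector with values `promoter`, `five_prime_utr`,
#'   `exon`, `intron`, `three_prime_utr`, `intergenic`.
#' @export
genic_context <- function(hits, genes, promoter_window = 1000L) {
  if (is.character(genes)) genes <- rtracklayer::import(genes, format = "gff3")
  type <- as.character(genes$type)
  g <- genes[type == "gene"]
  if (length(g) > 0 && any(as.character(GenomicRanges::strand(g)) == "*")) {
    bad <- g$ID[as.character(GenomicRanges::strand(g)) == "*"]
    stop("gene record(s) without strand: ",
         paste(bad, collapse = ", "))
  }
  q <- GenomicRanges::GRanges(hits$contig,
                              IRanges::IRanges(hits$start + 1L, hits$end))
  ov <- function(subject) {
    if (length(subject) == 0L) return(rep(FALSE, length(q)))
    IRanges::overlapsAny(q, subject, ignore.strand = TRUE)
  }
  prom <- if (length(g) > 0)
    GenomicRanges::promoters(g, upstream = promoter_window, downstream = 0L)
  else GenomicRanges::GRanges()
  prom <- GenomicRanges::trim(prom)
  res <- rep("intergenic", length(q))
  res[ov(g)] <- "intron"
  res[ov(genes[type == "exon"])] <- "exon"
  res[ov(genes[type %in% c("three_prime_UTR", "3_prime_UTR")])] <- "three_prime_utr"
  res[ov(genes[type %in% c("five_prime_UTR", "5_prime_UTR")])] <- "five_prime_utr"
  res[ov(prom)] <- "promoter"
  res
}

#' Count insertions in a piRNA cluster
#'
#' Counts hits whose genomic interval overlaps any cluster interval by at
#' least 1 bp. Intervals belonging to a cluster and its duplicates are
#' counted together, matching the trap-model expectation of a single
#' trapping insertion per genome.
#'
#' @param hits data frame of scan hits.
#' @param clusters a BED path or data frame (`contig`, `start`, `end`,
#'   optional `name`) of piRNA-cluster coordinates on the same assembly.
#' @param cluster_name identifier for the cluster (e.g. `"flamenco"`).
#' @param assembly assembly identifier carried into the output.
#' @return List of class `"cluster_count"`: `assembly`, `cluster`, `te`,
#'   `n_insertions` and `insertion_sites` (hit rows overlapping the
#'   cluster).
#' @export
count_in_cluster <- function(hits, clusters, cluster_name = "flamenco",
                             assembly = "assembly") {
  if (is.character(clusters)) {
    bed <- rtracklayer::import(clusters, format = "bed")
    clusters <- data.frame(contig = as.character(GenomicRanges::seqnames(bed)),
                           start = GenomicRanges::start(bed) - 1L,
                           end = GenomicRanges::end(bed),
                           stringsAsFactors = FALSE)
  }
  if (nrow(hits) == 0L) {
    sites <- hits
  } else {
    in_cluster <- vapply(seq_len(nrow(hits)), function(i) {
      any(clusters$contig == hits$contig[i] &
            clusters$start < hits$end[i] & hits$start[i] < clusters$end)
    }, logical(1))
    sites <- hits[in_cluster, , drop = FALSE]
  }
  structure(list(assembly = assembly, cluster = cluster_name,
                 te = if (nrow(hits) > 0) unique(hits$te)[1] else NA_character_,
                 n_insertions = nrow(sites), insertion_sites = sites),
            class = "cluster_count")
}

#' Trap-model check of a cluster count
#'
#' Under the trap model a somatic TE stays active until exactly one copy
#' inserts into the somatic piRNA cluster (or one of its duplicates).
#'
#' @param count a `"cluster_count"` from [count_in_cluster()], or an
#'   integer count.
#' @return `"consistent"` (exactly one insertion), `"pre_trap"` (none) or
#'   `"multi"` (two or more).
#' @export
trap_check <- function(count) {
  n <- if (inherits(count, "cluster_count")) count$n_insertions else count
  if (n == 1L) "consistent" else if (n == 0L) "pre_trap" else "multi"
}

# ordered TE names in the flanking windows of a site (the site itself and
# anything overlapping it excluded)
flank_signature <- function(site, annotations, flank_window = 2000L) {
  ann <- annotations[annotations$contig == site$contig, , drop = FALSE]
  ann <- ann[!(ann$start < site$end & site$start < ann$end), , drop = FALSE]
  left <- ann[ann$end <= site$start & ann$end > site$start - flank_window, ,
              drop = FALSE]
  right <- ann[ann$start >= site$end & ann$start < site$end + flank_window, ,
               drop = FALSE]
  c(left = paste(left$te[order(left$start)], collapse = ","),
    right = paste(right$te[order(right$start)], collapse = ","))
}

#' Count independent cluster-insertion events across strains
#'
#' Two strains' cluster insertions descend from the same insertion event
#' iff the ordered TE annotations flanking them match on at least one side
#' (flank synteny); lack of synteny on both sides is evidence for
#' independent insertion. Events are the connected components of the
#' resulting "same event" relation.
#'
#' @param sites data frame with one cluster insertion per strain:
#'   `strain`, `contig`, `start`, `end`.
#' @param annotations data frame of per-strain TE annotations: `strain`,
#'   `contig`, `start`, `end`, `te`.
#' @param flank_window flank width in bp on each side.
#' @return List: `n_events`, `event` (integer event id per site, parallel
#'   to `sites`), `signatures` (left/right flank strings per site).
#' @export
independent_insertion_sites <- function(sites, annotations,
                                        flank_window = 2000L) {
  n <- nrow(sites)
  sig <- t(vapply(seq_len(n), function(i)
    flank_signature(sites[i, ], annotations[annotations$strain ==
                                              sites$strain[i], , drop = FALSE],
                    flank_window),
    character(2)))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (sig[i, "left"] == sig[j, "left"] || sig[i, "right"] == sig[j, "right"]) {
      parent[find(j)] <- find(i)
    }
  }
  event <- vapply(seq_len(n), find, integer(1))
  event <- match(event, unique(event))
  list(n_events = length(unique(event)), event = event,
       signatures = data.frame(strain = sites$strain, left = sig[, "left"],
                               right = sig[, "right"], event = event,
                               row.names = NULL, stringsAsFactors = FALSE))
}

#' Pairwise identity of two insertion sequences
#'
#' Identity over the best local alignment: `100 * matches / aligned
#' match+mismatch columns`, reported together with the aligned column
#' count (the "over N bp" figure).
#'
#' @param a,b insertion sequences (each longer than 100 nt).
#' @param scoring an [alignment_scoring()].
#' @return List: `identity` (percent), `aligned_bp`.
#' @export
pairwise_identity <- function(a, b, scoring = alignment_scoring()) {
  stopifnot(nchar(a) > 100L, nchar(b) > 100L)
  r <- smith_waterman(a, b, scoring)
  list(identity = if (r$aligned_cols > 0) 100 * r$matches / r$aligned_cols
       else NA_real_,
       aligned_bp = r$aligned_cols)
}

#' Horizontal-transfer divergence test
#'
#' A TE whose cross-species identity exceeds that of every host ortholog
#' cannot have diverged vertically with the hosts; the comparison is the
#' classical divergence-based evidence for horizontal transfer.
#'
#' @param te_identity percent identity of the TE between the species pair.
#' @param host_identities percent identities of at least 10 host
#'   orthologs between the same pair.
#' @return List: `status` (`"supported"` iff `te_identity` strictly
#'   exceeds the best host ortholog) and `margin` (percentage points).
#' @export
ht_divergence_test <- function(te_identity, host_identities) {
  if (length(host_identities) < 10L)
    stop("need at least 10 host ortholog identities")
  m <- te_identity - max(host_identities)
  list(status = if (m > 0) "supported" else "not_supported", margin = m)
}

#' Write scan hits as GFF3
#'
#' @param hits data frame from [scan_assembly()], optionally with a
#'   `full_length` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
hits_gff <- function(hits, path) {
  gr <- GenomicRanges::GRanges(
    hits$contig, IRanges::IRanges(hits$start + 1L, hits$end),
    strand = hits$strand, type = "transposable_element",
    te = hits$te, score = hits$score, divergence = hits$divergence,
    full_length = if ("full_length" %in% names(hits)) hits$full_length else NA)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
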