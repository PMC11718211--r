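#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators. Defaults emulate
#' the kind of data the downstream analyses assume: 100-nt single-end reads
#' at 30-fold coverage with a 0.5% substitution error rate, young TE
#' insertions with 1% divergence from the consensus, and a post-invasion
#' copy-number growth of 3 copies/year capped at 30 haploid copies.
#'
#' @param seed integer seed; every generator derives its random stream from
#'   it, so equal configurations give byte-identical output.
#' @param genome_length background genome length in nt.
#' @param n_insertions number of planted TE copies.
#' @param insertion_divergence per-base substitution rate applied to each
#'   planted copy (young invasions: copies are near-identical).
#' @param te_snp_spec `NULL` or a data frame with columns `pos` (0-based
#'   consensus position), `alt` (alternate base) and `freq` (population
#'   frequency in `[0, 1]`); alleles are sampled per planted copy.
#' @param read_length read length in nt (at least 30).
#' @param depth target fold coverage of the genome.
#' @param error_rate per-base substitution error rate of simulated reads.
#' @param pirna_n number of simulated piRNA reads.
#' @param pingpong_fraction fraction of piRNA reads generated as
#'   sense/antisense pairs with an exact 10-nt 5'-5' overlap.
#' @param antisense_fraction strand bias of the unpaired piRNA reads.
#' @param invasion_year calendar year the TE enters the population.
#' @param growth_rate copies gained per year after the invasion.
#' @param copy_cap maximum copy number reached after an invasion.
#' @param scg_length length of each simulated single-copy gene.
#' @param n_scg number of single-copy genes planted in the genome.
#' @return A list with class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, genome_length = 50000L, n_insertions = 5L,
                       insertion_divergence = 0.01, te_snp_spec = NULL,
                       read_length = 100L, depth = 30, error_rate = 0.005,
                       pirna_n = 20000L, pingpong_fraction = 0,
                       antisense_fraction = 0.5,
                       invasion_year = 2000L, growth_rate = 3, copy_cap = 30,
                       scg_length = 2000L, n_scg = 3L) {
  frac <- c(insertion_divergence = insertion_divergence,
            error_rate = error_rate, pingpong_fraction = pingpong_fraction,
            antisense_fraction = antisense_fraction)
  bad <- names(frac)[frac < 0 | frac > 1]
  if (length(bad) > 0)
    stop("fractions must lie in [0, 1]: ", paste(bad, collapse = ", "))
  if (depth <= 0) stop("depth must be positive")
  if (read_length < 30L) stop("read_length must be at least 30 nt")
  if (!is.null(te_snp_spec)) {
    stopifnot(is.data.frame(te_snp_spec),
              all(c("pos", "alt", "freq") %in% names(te_snp_spec)),
              all(te_snp_spec$freq >= 0 & te_snp_spec$freq <= 1),
              all(te_snp_spec$alt %in% c("A", "C", "G", "T")))
  }
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 n_insertions = as.integer(n_insertions),
                 insertion_divergence = insertion_divergence,
                 te_snp_spec = te_snp_spec,
                 read_length = as.integer(read_length), depth = depth,
                 error_rate = error_rate, pirna_n = as.integer(pirna_n),
                 pingpong_fraction = pingpong_fraction,
                 antisense_fraction = antisense_fraction,
                 invasion_year = as.integer(invasion_year),
                 growth_rate = growth_rate, copy_cap = copy_cap,
                 scg_length = as.integer(scg_length),
                 n_scg = as.integer(n_scg)),
            class = "sim_config")
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute each position with probability `rate` by one of the other bases;
# positions in `protect` (1-based) are left untouched
mutate_seq <- function(seq, rate, protect = integer(0)) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(v)) < rate)
  hit <- setdiff(hit, protect)
  if (length(hit) > 0) {
    bases <- c("A", "C", "G", "T")
    v[hit] <- vapply(v[hit], function(b) sample(setdiff(bases, b), 1L),
                     character(1))
  }
  paste(v, collapse = "")
}

# sample non-overlapping placement intervals (0-based half-open) for segments
# of the given lengths inside a genome of length glen; the segments are laid
# out in random order with uniformly distributed gaps, which samples uniformly
# from all non-overlapping arrangements
place_segments <- function(lengths, glen) {
  k <- length(lengths)
  if (k == 0L) return(data.frame(start = integer(0), end = integer(0)))
  free <- glen - sum(lengths)
  if (free < 0L)
    stop("placement error: segments total ", sum(lengths),
         " nt but the genome is only ", glen, " nt")
  ord <- sample.int(k)
  cuts <- sort(as.integer(floor(runif(k) * (free + 1))))
  starts_ordered <- cuts + c(0L, cumsum(lengths[ord])[-k])
  starts <- integer(k)
  starts[ord] <- starts_ordered
  data.frame(start = starts, end = starts + lengths)
}

#' Simulate a genome with planted TE insertions
#'
#' Builds an i.i.d.-base background genome, plants `n_insertions`
#' non-overlapping copies of the consensus (each independently mutated at
#' `insertion_divergence` and carrying the `te_snp_spec` alleles sampled at
#' their stated population frequencies), and plants one copy of each
#' simulated single-copy gene. Planted segments replace background slices,
#' so the genome length equals `config$genome_length`. Every planted feature
#' is recorded in the returned truth set.
#'
#' @param consensus a [te_consensus()] object.
#' @param config a [sim_config()].
#' @param contig name of the simulated contig.
#' @param scg optional named character vector of single-copy gene sequences
#'   to plant instead of generating them; lets several simulated strains of
#'   one species share the same gene orthologs.
#' @return A list with elements
#'   \describe{
#'     \item{genome}{named character vector of length 1 (the contig).}
#'     \item{references}{named character vector: the TE consensus followed by
#'       the single-copy gene sequences (the mapping references).}
#'     \item{truth}{list with `insertions` (0-based intervals plus per-copy
#'       divergence positions), `scg` intervals, `snp_alleles` (copies x spec
#'       matrix of 0/1) and `true_copy_number`.}
#'   }
#' @export
make_genome <- function(consensus, config, contig = "chrSim", scg = NULL) {
  stopifnot(inherits(consensus, "te_consensus"), inherits(config, "sim_config"))
  te_len <- consensus$length
  if (config$n_insertions * te_len >= config$genome_length / 2)
    stop("n_insertions * consensus length must stay below half the genome ",
         "length")
  set.seed(config$seed)
  glen <- config$genome_length
  genome <- random_seq(glen)
  if (is.null(scg)) {
    scg <- setNames(
      vapply(seq_len(config$n_scg), function(i) random_seq(config$scg_length),
             character(1)),
      if (config$n_scg > 0) paste0("scg", seq_len(config$n_scg))
      else character(0))
  } else {
    stopifnot(is.character(scg), !is.null(names(scg)))
    config$n_scg <- length(scg)
  }

  spec <- config$te_snp_spec
  n_ins <- config$n_insertions
  snp_alleles <- NULL
  protect <- integer(0)
  if (!is.null(spec) && nrow(spec) > 0) {
    snp_alleles <- matrix(0L, nrow = n_ins, ncol = nrow(spec))
    protect <- spec$pos + 1L
  }
  copies <- character(n_ins)
  div_sites <- vector("list", n_ins)
  for (i in seq_len(n_ins)) {
    s <- consensus$sequence
    if (!is.null(snp_alleles)) {
      carry <- rbinom(nrow(spec), 1L, spec$freq)
      snp_alleles[i, ] <- carry
      if (any(carry == 1L)) {
        v <- strsplit(s, "", fixed = TRUE)[[1]]
        v[spec$pos[carry == 1L] + 1L] <- spec$alt[carry == 1L]
        s <- paste(v, collapse = "")
      }
    }
    before <- strsplit(s, "", fixed = TRUE)[[1]]
    s <- mutate_seq(s, config$insertion_divergence, protect = protect)
    div_sites[[i]] <- which(strsplit(s, "", fixed = TRUE)[[1]] != before) - 1L
    copies[i] <- s
  }

  lengths <- c(rep(te_len, n_ins), unname(nchar(scg)))
  pos <- place_segments(lengths, glen)
  segs <- c(copies, unname(scg))
  v <- strsplit(genome, "", fixed = TRUE)[[1]]
  for (i in seq_along(segs)) {
    v[(pos$start[i] + 1L):pos$end[i]] <- strsplit(segs[i], "", fixed = TRUE)[[1]]
  }
  genome <- paste(v, collapse = "")

  ins_truth <- if (n_ins > 0) {
    data.frame(contig = contig, start = pos$start[seq_len(n_ins)],
               end = pos$end[seq_len(n_ins)], strand = "+",
               te = consensus$name, copy = seq_len(n_ins),
               stringsAsFactors = FALSE)
  } else {
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               strand = character(0), te = character(0), copy = integer(0),
               stringsAsFactors = FALSE)
  }
  scg_truth <- if (config$n_scg > 0) {
    idx <- n_ins + seq_len(config$n_scg)
    data.frame(contig = contig, start = pos$start[idx], end = pos$end[idx],
               name = names(scg), stringsAsFactors = FALSE)
  } else NULL

  list(genome = setNames(genome, contig),
       references = c(setNames(consensus$sequence, consensus$name), scg),
       truth = list(insertions = ins_truth, scg = scg_truth,
                    snp_alleles = snp_alleles, snp_spec = spec,
                    divergence_sites = div_sites,
                    true_copy_number = n_ins))
}

#' Simulate uniform-coverage single-end short reads
#'
#' Draws `round(depth * genome_length / read_length)` reads at uniform
#' positions from both strands, applies per-base substitution errors at
#' `error_rate`, and is fully deterministic under `config$seed` (the same
#' configuration yields byte-identical FASTQ output).
#'
#' @param genome named character vector of contig sequences (typically from
#'   [make_genome()]).
#' @param config a [sim_config()].
#' @param path optional FASTQ output path; when given, reads are also written
#'   to it.
#' @return Named character vector of read sequences (invisibly returns the
#'   same if `path` is given).
#' @export
simulate_reads <- function(genome, config, path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seq <- paste(genome, collapse = "")
  glen <- nchar(seq)
  if (glen == 0L) stop("genome is empty")
  rl <- config$read_length
  if (glen < rl) stop("genome shorter than the read length")
  n <- round(config$depth * glen / rl)
  if (n < 1L) {
    warning("requested coverage yields fewer than one read; emitting 1 read")
    n <- 1L
  }
  set.seed(config$seed + 1L)
  starts <- sample.int(glen - rl + 1L, n, replace = TRUE)
  reads <- substring(seq, starts, starts + rl - 1L)
  rev <- runif(n) < 0.5
  if (any(rev)) reads[rev] <- rc(reads[rev])
  if (config$error_rate > 0) {
    n_err <- rbinom(n, rl, config$error_rate)
    for (i in which(n_err > 0L)) {
      v <- strsplit(reads[i], "", fixed = TRUE)[[1]]
      at <- sample.int(rl, n_err[i])
      v[at] <- vapply(v[at],
                      function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                      character(1))
      reads[i] <- paste(v, collapse = "")
    }
  }
  names(reads) <- sprintf("read_%06d", seq_len(n))
  if (!is.null(path)) {
    write_fastq(reads, path)
    return(invisible(reads))
  }
  reads
}

#' Simulate a piRNA pool with tunable ping-pong pairing and strand bias
#'
#' Generates `pirna_n` reads of 23--29 nt from the consensus. A
#' `pingpong_fraction` of the reads is emitted as sense/antisense pairs whose
#' 5' ends overlap by exactly 10 nt (the ping-pong geometry); the remainder
#' is positioned uniformly with strand drawn from `antisense_fraction`.
#' Reads are error-free copies of the consensus (or its reverse complement).
#'
#' @param consensus a [te_consensus()] object (longer than 50 nt).
#' @param config a [sim_config()].
#' @return A list with `reads` (named character vector) and `truth`
#'   (data frame with 0-based footprint `start`, `width`, `strand`,
#'   `five_prime` and `paired`).
#' @export
simulate_pirnas <- function(consensus, config) {
  stopifnot(inherits(consensus, "te_consensus"), inherits(config, "sim_config"))
  L <- consensus$length
  if (L <= 50L) stop("consensus must be longer than 50 nt")
  set.seed(config$seed + 2L)
  n <- config$pirna_n
  n_pair <- floor(config$pingpong_fraction * n / 2)
  n_rest <- n - 2L * n_pair

  ws <- sample(23:29, n_pair, replace = TRUE)   # sense widths
  wa <- sample(23:29, n_pair, replace = TRUE)   # antisense widths
  lo <- pmax(0L, wa - 10L)
  hi <- L - pmax(ws, 10L)
  s <- lo + floor(runif(n_pair) * (hi - lo + 1L))     # sense 5' (0-based)
  a <- s + 9L                                          # antisense 5'
  pair_sense <- data.frame(start = as.integer(s), width = as.integer(ws),
                           strand = rep("+", n_pair), paired = rep(TRUE, n_pair),
                           stringsAsFactors = FALSE)
  pair_anti <- data.frame(start = as.integer(a - wa + 1L),
                          width = as.integer(wa),
                          strand = rep("-", n_pair), paired = rep(TRUE, n_pair),
                          stringsAsFactors = FALSE)

  wr <- sample(23:29, n_rest, replace = TRUE)
  anti <- runif(n_rest) < config$antisense_fraction
  st <- as.integer(floor(runif(n_rest) * (L - wr + 1L)))
  rest <- data.frame(start = st, width = as.integer(wr),
                     strand = ifelse(anti, "-", "+"),
                     paired = rep(FALSE, n_rest), stringsAsFactors = FALSE)

  truth <- rbind(pair_sense, pair_anti, rest)
  truth$five_prime <- ifelse(truth$strand == "+", truth$start,
                             truth$start + truth$width - 1L)
  seqs <- substring(consensus$sequence, truth$start + 1L,
                    truth$start + truth$width)
  seqs[truth$strand == "-"] <- rc(seqs[truth$strand == "-"])
  names(seqs) <- sprintf("pirna_%06d", seq_len(nrow(truth)))
  truth$read_id <- names(seqs)
  list(reads = seqs, truth = truth)
}

#' Simulate a multi-species, multi-strain time-series cohort
#'
#' For every sampled strain the true haploid TE copy number follows the
#' invasion model: 0 before the species' invasion year and
#' `min(copy_cap, growth_rate * (year - invasion_year))` after. A
#' contaminated strain (an early sampling year paired with a positive copy
#' number, mimicking a mislabelled or contaminated sequencing run) can be
#' injected with a truth flag. Optionally, per-strain genomes and short
#' reads are generated so the full quantification pipeline can be exercised
#' end to end.
#'
#' @param species named list; one entry per species, each a list with
#'   `years` (sampling years, at least two distinct), `invasion_year`, and
#'   optionally `growth_rate`, `copy_cap`, `locations` (recycled over
#'   strains).
#' @param config a [sim_config()] providing the sequencing parameters and
#'   base seed.
#' @param consensus a [te_consensus()]; required when `write_reads = TRUE`.
#' @param contaminant `NULL` or a list with `species`, `year`,
#'   `copy_number` describing an injected contaminated strain.
#' @param write_reads when `TRUE`, simulate a genome and FASTQ per strain
#'   under `out_dir`.
#' @param out_dir output directory for FASTQ files and the sample sheet.
#' @return A list with `samples` (the sample sheet: `strain`, `species`,
#'   `year`, `location`, `fastq_path`, plus truth columns
#'   `true_copy_number`, `present_truth`, `is_contaminant`) and `truth`
#'   (per-species invasion years).
#' @export
simulate_cohort <- function(species, config, consensus = NULL,
                            contaminant = NULL, write_reads = FALSE,
                            out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"), is.list(species),
            !is.null(names(species)))
  rows <- list()
  for (sp in names(species)) {
    cfg <- species[[sp]]
    stopifnot(!is.null(cfg$years), !is.null(cfg$invasion_year))
    if (length(unique(cfg$years)) < 2L)
      stop("species ", sQuote(sp), " needs at least two distinct sampling years")
    growth <- if (is.null(cfg$growth_rate)) config$growth_rate else cfg$growth_rate
    cap <- if (is.null(cfg$copy_cap)) config$copy_cap else cfg$copy_cap
    loc <- if (is.null(cfg$locations)) "pop1" else cfg$locations
    loc <- rep_len(loc, length(cfg$years))
    cn <- ifelse(cfg$years > cfg$invasion_year,
                 pmin(cap, growth * (cfg$years - cfg$invasion_year)), 0)
    rows[[sp]] <- data.frame(
      strain = sprintf("%s_%d_%02d", sp, cfg$years, seq_along(cfg$years)),
      species = sp, year = as.integer(cfg$years), location = loc,
      true_copy_number = cn, is_contaminant = FALSE,
      stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(contaminant)) {
    samples <- rbind(samples, data.frame(
      strain = sprintf("%s_%d_contam", contaminant$species, contaminant$year),
      species = contaminant$species, year = as.integer(contaminant$year),
      location = "contam", true_copy_number = contaminant$copy_number,
      is_contaminant = TRUE, stringsAsFactors = FALSE))
  }
  samples$present_truth <- samples$true_copy_number > 1
  samples$fastq_path <- NA_character_

  if (write_reads) {
    if (is.null(consensus) || is.null(out_dir))
      stop("write_reads = TRUE requires `consensus` and `out_dir`")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    # the single-copy gene orthologs are shared by every strain of the cohort
    set.seed(config$seed)
    scg <- setNames(
      vapply(seq_len(config$n_scg), function(i) random_seq(config$scg_length),
             character(1)),
      if (config$n_scg > 0) paste0("scg", seq_len(config$n_scg))
      else character(0))
    for (i in seq_len(nrow(samples))) {
      cfg_i <- config
      cfg_i$seed <- config$seed + 100L * i
      cfg_i$n_insertions <- as.integer(round(samples$true_copy_number[i]))
      sim <- make_genome(consensus, cfg_i, scg = scg)
      fq <- file.path(out_dir, paste0(samples$strain[i], ".fastq"))
      simulate_reads(sim$genome, cfg_i, path = fq)
      samples$fastq_path[i] <- fq
      if (i == 1L)
        write_fasta(sim$references, file.path(out_dir, "references.fasta"))
    }
    write.table(samples, file.path(out_dir, "samples.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  truth <- data.frame(
    species = names(species),
    invasion_year = vapply(species, function(x) as.integer(x$invasion_year),
                           integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(samples = samples, truth = truth)
}
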