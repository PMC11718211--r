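test_that("smith_waterman matches independent oracles exactly", {
  set.seed(41)
  # identical sequences: perfect score, zero divergence
  s <- rand_seq(1000)
  r <- smith_waterman(s, s)
  expect_equal(r$score, 1000L)
  expect_equal(r$divergence, 0)
  expect_equal(c(r$q_start, r$q_end), c(0L, 1000L))

  # brute-force O(nm) dynamic-programming oracle on small random pairs
  for (i in 1:10) {
    a <- rand_seq(sample(40:120, 1))
    b <- rand_seq(sample(40:120, 1))
    expect_equal(smith_waterman(a, b)$score, sw_bruteforce(a, b))
  }

  # Biostrings local alignment as a second, independent implementation
  for (i in 1:10) {
    a <- rand_seq(sample(200:800, 1))
    b <- rand_seq(sample(200:800, 1))
    expect_equal(smith_waterman(a, b)$score, biostrings_sw_score(a, b))
  }

  # planted 5% substitutions: divergence within 1 percentage point of truth
  core <- rand_seq(1500)
  div <- smith_waterman(core, mutate_exact(core, 75))$divergence
  expect_lt(abs(div - 5), 1)

  expect_error(smith_waterman("", "ACGT"))
})

test_that("scan_assembly recovers planted copies on both strands", {
  set.seed(42)
  te <- te_consensus("TEs", rand_seq(2000))
  cfg <- sim_config(seed = 43, genome_length = 60000, n_insertions = 5,
                    insertion_divergence = 0.05)
  sim <- make_genome(te, cfg)
  hits <- scan_assembly(sim$genome, te)
  tr <- sim$truth$insertions[order(sim$truth$insertions$start), ]
  expect_equal(nrow(hits), 5L)
  expect_true(all(abs(hits$start - tr$start) <= 10))
  expect_true(all(abs(hits$end - tr$end) <= 10))
  expect_true(all(abs(hits$divergence - 5) < 1.5))

  # strand-flip invariance: the reverse-complemented assembly gives the
  # same hits with identical scores, on the opposite strand
  flipped <- setNames(tecascade:::rc(sim$genome), names(sim$genome))
  hits2 <- scan_assembly(flipped, te)
  expect_equal(nrow(hits2), 5L)
  expect_equal(sort(hits2$score), sort(hits$score))
  expect_true(all(hits2$strand == "-"))
  glen <- nchar(sim$genome[[1]])
  expect_equal(sort(glen - hits2$end), sort(hits$start))
})

test_that("seeded scanner agrees with the full-DP best score on small instances", {
  set.seed(44)
  te <- te_consensus("TEs", rand_seq(1000))
  for (i in 1:10) {
    target <- paste0(rand_seq(400),
                     mutate_exact(te$sequence, sample(0:80, 1)),
                     rand_seq(400))
    full <- smith_waterman(te$sequence, target)$score
    hits <- scan_assembly(setNames(target, "t"), te, keep_all = TRUE)
    expect_equal(max(hits$score), full)
  }
})

test_that("insertion filters are strict at both boundaries", {
  # synthetic hits exactly at the filter boundaries
  hits <- data.frame(aligned_len = c(750L, 751L, 2000L, 2000L),
                     divergence = c(0, 0, 10.0, 9.9))
  kept <- filter_insertions(hits)
  expect_equal(nrow(kept), 2L)
  expect_equal(kept$aligned_len, c(751L, 2000L))
  expect_equal(kept$divergence, c(0, 9.9))

  # through the scanner: an exact 750-bp fragment is excluded, 751 retained
  set.seed(45)
  te <- te_consensus("TEs", rand_seq(2000))
  for (frag_len in c(750L, 751L)) {
    asm <- setNames(paste0(rand_seq(300),
                           substring(te$sequence, 1, frag_len),
                           rand_seq(300)), "c1")
    h <- scan_assembly(asm, te)
    expect_equal(nrow(h), as.integer(frag_len == 751L))
  }
})

test_that("full-length classification needs >80% span and both LTRs", {
  set.seed(46)
  te <- set_ltrs(make_ltr_te(ltr_len = 300, core_len = 1400))  # length 2000
  hit <- function(cs, ce) {
    data.frame(consensus_start = cs, consensus_end = ce,
               fraction_of_consensus = (ce - cs) / te$length)
  }
  expect_true(classify_full_length(hit(0L, 2000L), te))
  expect_false(classify_full_length(hit(0L, 300L), te))      # solo LTR
  expect_false(classify_full_length(hit(150L, 1730L), te))   # 79% internal
  # 85% span missing the 3' LTR entirely
  expect_false(classify_full_length(hit(0L, 1700L), te))
  no_ltr <- te_consensus("x", rand_seq(2000))
  expect_error(classify_full_length(hit(0L, 2000L), no_ltr), "detect_ltrs")
})

test_that("similarity statistic is a best/max score ratio over assemblies", {
  set.seed(47)
  te <- te_consensus("TEs", rand_seq(2000))
  divs <- c(exact = 0, d2 = 0.02, d5 = 0.05, d8 = 0.08)
  assemblies <- lapply(names(divs), function(nm) {
    copy <- mutate_exact(te$sequence, round(divs[[nm]] * te$length))
    setNames(paste0(rand_seq(500), copy, rand_seq(500)), "c1")
  })
  names(assemblies) <- names(divs)
  assemblies$none <- setNames(rand_seq(3000), "c1")
  hits <- scan_assemblies(assemblies, te)
  s <- similarity_scores(hits, assemblies = names(assemblies))
  s <- setNames(s$s, s$assembly)
  expect_equal(s[["exact"]], 1.0)
  expect_equal(s[["none"]], 0.0)
  # monotone non-increasing in planted divergence at fixed length
  expect_true(all(diff(s[c("exact", "d2", "d5", "d8")]) <= 0))
  expect_true(all(s >= 0 & s <= 1))

  expect_warning(
    s0 <- similarity_scores(hits[0, ], assemblies = c("a", "b"), te = "TEs"),
    "no hits")
  expect_true(all(s0$s == 0))
})

test_that("similarity ordering is robust to the scoring scheme", {
  set.seed(48)
  te <- te_consensus("TEs", rand_seq(1500))
  mk <- function(d) setNames(paste0(rand_seq(200),
                                    mutate_exact(te$sequence, d),
                                    rand_seq(200)), "c1")
  assemblies <- list(a0 = mk(0), a1 = mk(30), a2 = mk(90))
  ord <- lapply(list(alignment_scoring(),
                     alignment_scoring(2, -3, -5, -2)), function(sc) {
    h <- scan_assemblies(assemblies, te, scoring = sc)
    s <- similarity_scores(h, assemblies = names(assemblies))
    s$assembly[order(-s$s)]
  })
  expect_equal(ord[[1]], ord[[2]])
})

test_that("genic context classifies promoter, genic and intergenic hits", {
  genes <- GenomicRanges::GRanges(
    "c1",
    IRanges::IRanges(start = c(10001, 10001, 10001, 12001, 14001, 30001,
                               30001),
                     end = c(15000, 10200, 10400, 12500, 15000, 35000,
                             35000)),
    strand = c("+", "+", "+", "+", "+", "-", "-"),
    type = c("gene", "five_prime_UTR", "exon", "exon", "three_prime_UTR",
             "gene", "exon"),
    ID = c("g1", "u5", "e1", "e2", "u3", "g2", "e3"))
  hit <- function(s, e) data.frame(contig = "c1", start = s, end = e)
  # 500 bp upstream of the + strand TSS (TSS at 0-based 10000)
  expect_equal(genic_context(hit(9500, 9600), genes), "promoter")
  # inside the gene but not in any exon: intron (and > 1 kb from the TSS)
  expect_equal(genic_context(hit(13000, 13100), genes), "intron")
  expect_equal(genic_context(hit(12100, 12200), genes), "exon")
  expect_equal(genic_context(hit(10050, 10100), genes), "five_prime_utr")
  expect_equal(genic_context(hit(14500, 14600), genes), "three_prime_utr")
  # 5 kb away from every gene
  expect_equal(genic_context(hit(20000, 20100), genes), "intergenic")
  # minus-strand promoter is downstream in genome coordinates
  expect_equal(genic_context(hit(35500, 35600), genes), "promoter")

  bad <- genes
  GenomicRanges::strand(bad)[1] <- "*"
  expect_error(genic_context(hit(9500, 9600), bad), "without strand")
})

test_that("cluster counting and the trap-model check work at 1-bp overlap", {
  clusters <- data.frame(contig = "c1", start = c(1000L, 9000L),
                         end = c(3000L, 9500L))     # cluster + duplicate
  hit <- function(s, e) data.frame(contig = "c1", start = s, end = e,
                                   strand = "+", te = "TEs", score = 100L,
                                   divergence = 1, stringsAsFactors = FALSE)
  one <- count_in_cluster(hit(2999, 4000), clusters)   # 1-bp overlap counts
  expect_equal(one$n_insertions, 1L)
  expect_equal(trap_check(one), "consistent")
  expect_equal(trap_check(count_in_cluster(hit(3000, 4000), clusters)),
               "pre_trap")                             # abutting, no overlap
  expect_equal(trap_check(count_in_cluster(rbind(hit(1500, 2000),
                                                 hit(9100, 9400)), clusters)),
               "multi")
})

test_that("flank synteny separates shared from independent cluster insertions", {
  ann <- function(strain, starts, tes) {
    data.frame(strain = strain, contig = "c1", start = starts,
               end = starts + 500L, te = tes, stringsAsFactors = FALSE)
  }
  # strains A and B share the flanking TE arrangement; C and D differ on
  # both sides; E matches nothing
  sites <- data.frame(strain = c("A", "B", "C", "D"),
                      contig = "c1", start = 10000L, end = 11000L,
                      stringsAsFactors = FALSE)
  annotations <- rbind(
    ann("A", c(8500L, 11200L), c("roo", "jockey")),
    ann("B", c(8600L, 11300L), c("roo", "jockey")),
    ann("C", c(8500L, 11200L), c("copia", "blood")),
    ann("D", c(8500L, 11200L), c("412", "gtwin")))
  res <- independent_insertion_sites(sites, annotations)
  expect_equal(res$n_events, 3L)
  expect_equal(res$event[1], res$event[2])
  expect_false(res$event[3] == res$event[4])

  # 1 shared + 3 private insertions across 4 strains -> 4 distinct events
  sites2 <- data.frame(strain = c("s1", "s2", "s3", "s4", "s1"),
                       contig = "c1",
                       start = c(10000L, 10000L, 40000L, 60000L, 80000L),
                       end = c(11000L, 11000L, 41000L, 61000L, 81000L),
                       stringsAsFactors = FALSE)
  annotations2 <- rbind(
    ann("s1", c(8500L, 11200L), c("roo", "jockey")),
    ann("s2", c(8500L, 11200L), c("roo", "jockey")),
    ann("s3", c(38500L, 41200L), c("copia", "blood")),
    ann("s4", c(58500L, 61200L), c("412", "gtwin")),
    ann("s1", c(78500L, 81200L), c("hobo", "Fw")))
  expect_equal(independent_insertion_sites(sites2, annotations2)$n_events, 4L)
})

test_that("pairwise identity reports percent identity over aligned columns", {
  set.seed(49)
  s <- rand_seq(1000)
  id <- pairwise_identity(s, s)
  expect_equal(id$identity, 100)
  expect_equal(id$aligned_bp, 1000L)

  one_sub <- mutate_exact(s, 1)
  id2 <- pairwise_identity(s, one_sub)
  expect_equal(id2$identity, 99.9, tolerance = 0.02)

  diverged <- mutate_exact(s, 5)   # 0.5% divergence
  id3 <- pairwise_identity(s, diverged)
  expect_lt(abs(id3$identity - 99.5), 0.2)

  expect_error(pairwise_identity("ACGT", s))
})

test_that("HT divergence test: TE identity must beat every host ortholog", {
  r <- ht_divergence_test(99.6, c(rep(90, 9), 95.0))
  expect_equal(r$status, "supported")
  expect_equal(r$margin, 4.6)
  expect_equal(ht_divergence_test(95.0, c(rep(90, 9), 95.0))$status,
               "not_supported")                       # strict >
  expect_error(ht_divergence_test(99, rep(90, 5)), "at least 10")

  # vertical transmission: TE and hosts diverge at the same per-site rate;
  # the long TE alignment has less sampling noise than the shorter host
  # genes, so it essentially never exceeds the noisiest host ortholog
  set.seed(50)
  status <- replicate(100, {
    q <- 0.90
    te_id <- 100 * rbinom(1, 5000, q) / 5000
    host_id <- 100 * rbinom(10, 1500, q) / 1500
    ht_divergence_test(te_id, host_id)$status
  })
  expect_gte(mean(status == "not_supported"), 0.95)
})

test_that("hits export as GFF3 transposable_element features", {
  hits <- data.frame(contig = "c1", start = 100L, end = 2100L, strand = "+",
                     te = "TEs", score = 1800L, divergence = 2.5,
                     full_length = TRUE, stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".gff3")
  hits_gff(hits, f)
  gr <- rtracklayer::import(f, format = "gff3")
  expect_equal(as.character(gr$type), "transposable_element")
  expect_equal(GenomicRanges::start(gr), 101L)
  expect_equal(gr$te, "TEs")
})
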