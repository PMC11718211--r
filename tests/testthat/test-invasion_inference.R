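test_that("invasion windows are bounded by last-absent and first-present years", {
  s <- data.frame(strain = c("old", "new"), year = c(1961L, 2012L),
                  present = c(FALSE, TRUE))
  w <- infer_invasion_window(s)
  expect_equal(w$last_absent_year, 1961L)
  expect_equal(w$first_present_year, 2012L)
  expect_equal(w$status, "invaded")
  expect_equal(w$outliers, "")

  all_absent <- data.frame(strain = letters[1:4], year = c(1980L, 1990L,
                                                           2000L, 2010L),
                           present = FALSE)
  w2 <- infer_invasion_window(all_absent)
  expect_equal(w2$status, "not_invaded")
  expect_true(is.na(w2$last_absent_year) && is.na(w2$first_present_year))

  same_year <- data.frame(strain = c("a", "b"), year = 2000L,
                          present = c(TRUE, FALSE))
  expect_warning(w3 <- infer_invasion_window(same_year), "same year")
  expect_equal(w3$status, "undated")
})

test_that("isolated early positives are flagged as contamination outliers", {
  # hand-traced: present 1975; absent 1980/1985/1990; present 1995.
  # 1995 - 1975 = 20 > 10 and 3 absents in between -> 1975 is an outlier,
  # the window becomes (1990, 1995)
  s <- data.frame(strain = c("ken75", "a", "b", "c", "d"),
                  year = c(1975L, 1980L, 1985L, 1990L, 1995L),
                  present = c(TRUE, FALSE, FALSE, FALSE, TRUE))
  w <- infer_invasion_window(s)
  expect_equal(w$outliers, "ken75")
  expect_equal(w$last_absent_year, 1990L)
  expect_equal(w$first_present_year, 1995L)

  # with only one intervening absent sample the early positive stands
  s2 <- data.frame(strain = c("ken75", "a", "d"),
                   year = c(1975L, 1985L, 1995L),
                   present = c(TRUE, FALSE, TRUE))
  w2 <- infer_invasion_window(s2)
  expect_equal(w2$outliers, "")
  expect_equal(w2$first_present_year, 1975L)

  # within the gap threshold the early positive also stands
  s3 <- data.frame(strain = c("x", "a", "b", "d"),
                   year = c(1988L, 1990L, 1993L, 1995L),
                   present = c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(infer_invasion_window(s3)$first_present_year, 1988L)
})

test_that("window inference is order-invariant and monotone in present samples", {
  set.seed(81)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    s <- data.frame(strain = paste0("s", 1:n),
                    year = sample(1950:2020, n),
                    present = sample(c(TRUE, FALSE), n, TRUE))
    if (!any(s$present)) s$present[n] <- TRUE
    w1 <- infer_invasion_window(s)
    w2 <- infer_invasion_window(s[sample(n), ])
    expect_equal(w1, w2)
    if (!is.na(w1$last_absent_year))
      expect_lt(w1$last_absent_year, w1$first_present_year)
    # adding a present sample never moves first_present_year later
    extra <- rbind(s, data.frame(strain = "extra",
                                 year = sample(1950:2020, 1), present = TRUE))
    w3 <- infer_invasion_window(extra)
    expect_lte(w3$first_present_year, w1$first_present_year)
  }
})

test_that("invasion_windows groups by species and TE", {
  s <- expand.grid(species = c("sp1", "sp2"), te = c("teA", "teB"),
                   year = c(1980L, 2010L), stringsAsFactors = FALSE)
  s$strain <- paste0("s", seq_len(nrow(s)))
  s$present <- s$year > 1995
  w <- invasion_windows(s)
  expect_equal(nrow(w), 4L)
  expect_true(all(w$last_absent_year == 1980L))
  expect_true(all(w$first_present_year == 2010L))
})

test_that("cooccurrence concordance and Fisher p match the enumeration oracle", {
  expect_equal(cooccurrence(c(TRUE, TRUE, FALSE, FALSE),
                            c(TRUE, TRUE, FALSE, FALSE))$concordance, 1.0)
  expect_equal(cooccurrence(c(TRUE, TRUE, FALSE, FALSE),
                            c(FALSE, FALSE, TRUE, TRUE))$concordance, 0.0)

  # perfectly concordant 6/6 table: two-sided p = 2/924 by enumeration
  a <- rep(c(TRUE, FALSE), each = 6)
  r <- cooccurrence(a, a)
  expect_equal(r$p_value, 2 / 924, tolerance = 1e-12)
  expect_equal(r$p_value, fisher_oracle(6, 0, 0, 6), tolerance = 1e-12)

  expect_warning(rc <- cooccurrence(rep(TRUE, 6), rep(c(TRUE, FALSE), 3)),
                 "constant")
  expect_true(is.na(rc$p_value))
  expect_equal(rc$concordance, 0.5)
  expect_error(cooccurrence(c(TRUE, FALSE), c(TRUE, FALSE)), "at least 4")
})

test_that("shared TE SNPs intersect on consensus coordinates", {
  snp <- function(pos, minor, te = "Shellder") {
    data.frame(te = te, pos = pos, major = "A", minor = minor,
               maf = 0.2, stringsAsFactors = FALSE)
  }
  A <- snp(100L, "G")
  expect_equal(nrow(shared_te_snps(A, snp(100L, "G"))), 1L)
  expect_equal(nrow(shared_te_snps(A, snp(250L, "T"))), 0L)
  expect_equal(nrow(shared_te_snps(A, A)), nrow(A))   # self-intersection

  # coordinate-only matching by default; allele matching as strict option
  expect_equal(nrow(shared_te_snps(A, snp(100L, "T"))), 1L)
  expect_equal(nrow(shared_te_snps(A, snp(100L, "T"),
                                   require_allele_match = TRUE)), 0L)
  expect_error(shared_te_snps(A, snp(100L, "G", te = "Spoink")),
               "different TEs")
})

test_that("cascade rules link donors and recipients with ranked evidence", {
  wins <- data.frame(species = c("donor", "recipient"), te = "teA",
                     last_absent_year = c(NA, 1994L),
                     first_present_year = c(1985L, 1995L),
                     status = "invaded", stringsAsFactors = FALSE)
  cg <- contact_graph(data.frame(a = "donor", b = "recipient",
                                 type = "hybridization"))
  cas <- reconstruct_cascade(wins, cg)
  expect_equal(nrow(cas$events), 1L)
  expect_equal(cas$events$donor, "donor")
  expect_equal(cas$events$evidence, "time_order,hybridization")
  expect_equal(cas$events$year_lo, 1994L)
  # the earliest species has no eligible donor: unresolved
  expect_equal(cas$unresolved$species, "donor")

  # no contact path: recipient unresolved too
  cg2 <- contact_graph(data.frame(a = "donor", b = "other",
                                  type = "range_overlap")[0, ])
  cas2 <- reconstruct_cascade(wins, cg2)
  expect_equal(nrow(cas2$events), 0L)
  expect_true("recipient" %in% cas2$unresolved$species)

  expect_error(contact_graph(data.frame(a = "x", b = "x", type = "range_overlap")),
               "self edges")
  expect_error(contact_graph(data.frame(a = "x", b = "y", type = "mystery")),
               "edge type")
})

test_that("cascade output is acyclic and respects donor-before-recipient order", {
  set.seed(82)
  for (i in 1:10) {
    n_sp <- sample(4:7, 1)
    sp <- paste0("sp", seq_len(n_sp))
    wins <- data.frame(species = sp, te = "teA",
                       last_absent_year = NA_integer_,
                       first_present_year = sample(seq(1960, 2020, by = 3),
                                                   n_sp),
                       status = "invaded", stringsAsFactors = FALSE)
    pairs <- t(combn(sp, 2))
    keep <- runif(nrow(pairs)) < 0.6
    if (!any(keep)) keep[1] <- TRUE
    cg <- contact_graph(data.frame(a = pairs[keep, 1], b = pairs[keep, 2],
                                   type = sample(c("range_overlap",
                                                   "hybridization"),
                                                 sum(keep), TRUE),
                                   stringsAsFactors = FALSE))
    cas <- reconstruct_cascade(wins, cg)
    if (nrow(cas$events) == 0) next
    fp <- setNames(wins$first_present_year, wins$species)
    expect_true(all(fp[cas$events$donor] <= fp[cas$events$recipient]))
    # distinct first-present years: every edge goes strictly forward in
    # time, so the event graph cannot contain a cycle
    expect_true(all(fp[cas$events$donor] < fp[cas$events$recipient]))
    expect_true(all(grepl("time_order", cas$events$evidence)))
  }
})

test_that("geographic patchiness classifies island groups", {
  s <- data.frame(strain = paste0("s", 1:8),
                  location = rep(c("denis", "praslin", "mahe", "ladigue"),
                                 each = 2),
                  present = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE,
                              FALSE))
  p <- geographic_patchiness(s)
  expect_true(p$patchy)
  expect_setequal(p$fixed_present, c("denis", "praslin"))
  expect_setequal(p$fixed_absent, c("mahe", "ladigue"))

  all_pres <- data.frame(strain = paste0("s", 1:4),
                         location = rep(c("x", "y"), 2), present = TRUE)
  expect_false(geographic_patchiness(all_pres)$patchy)

  mixed <- data.frame(strain = paste0("s", 1:4),
                      location = c("x", "x", "y", "y"),
                      present = c(TRUE, FALSE, TRUE, TRUE))
  pm <- geographic_patchiness(mixed)
  expect_false(pm$patchy)
  expect_equal(pm$mixed, "x")
  expect_error(geographic_patchiness(data.frame(strain = "a", location = "x",
                                                present = TRUE)),
               "two location")
})
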