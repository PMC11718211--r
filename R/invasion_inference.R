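#' Infer the invasion window of a TE in one species
#'
#' The invasion window is the interval between the latest sampled year
#' without the TE and the earliest sampled year with it. Isolated early
#' positives (contaminated or mislabelled strains) are flagged as outliers
#' first: a present sample is an outlier iff the next-oldest present
#' sample lies more than `outlier_gap_years` later *and* at least
#' `min_absent_between` absent samples fall in between. The rule is
#' applied repeatedly from the oldest present sample until stable.
#'
#' @param samples data frame with columns `strain`, `year` and either
#'   `present` (logical) or `copy_number` (presence is then
#'   `copy_number > 1`); one species and one TE at a time.
#' @param outlier_gap_years minimum gap to the next present sample for an
#'   outlier call.
#' @param min_absent_between minimum number of intervening absent samples.
#' @return One-row data frame: `last_absent_year`, `first_present_year`
#'   (`NA` when undefined), `status`
#'   (`"invaded"`/`"not_invaded"`/`"undated"`), `outliers`
#'   (comma-separated flagged strains, `""` if none).
#' @export
infer_invasion_window <- function(samples, outlier_gap_years = 10L,
                                  min_absent_between = 2L) {
  stopifnot(is.data.frame(samples), all(c("strain", "year") %in% names(samples)))
  if (!"present" %in% names(samples)) {
    if (!"copy_number" %in% names(samples))
      stop("samples need a `present` or `copy_number` column")
    samples$present <- samples$copy_number > 1
  }
  if (nrow(samples) < 2L || length(unique(samples$year)) < 1L)
    stop("need at least 2 samples")
  win <- function(last_absent, first_present, status, outliers) {
    data.frame(last_absent_year = last_absent,
               first_present_year = first_present, status = status,
               outliers = paste(outliers, collapse = ","),
               stringsAsFactors = FALSE)
  }
  if (!any(samples$present))
    return(win(NA_integer_, NA_integer_, "not_invaded", character(0)))
  if (length(unique(samples$year)) == 1L) {
    warning("all samples from the same year; window undated")
    return(win(NA_integer_, NA_integer_, "undated", character(0)))
  }
  active <- samples
  outliers <- character(0)
  repeat {
    pres <- active[active$present, , drop = FALSE]
    pres <- pres[order(pres$year), , drop = FALSE]
    if (nrow(pres) < 2L) break
    gap <- pres$year[2L] - pres$year[1L]
    n_absent_between <- sum(!active$present &
                              active$year > pres$year[1L] &
                              active$year < pres$year[2L])
    if (gap > outlier_gap_years && n_absent_between >= min_absent_between) {
      outliers <- c(outliers, pres$strain[1L])
      active <- active[active$strain != pres$strain[1L], , drop = FALSE]
    } else break
  }
  first_present <- min(active$year[active$present])
  absent_before <- active$year[!active$present & active$year < first_present]
  last_absent <- if (length(absent_before) > 0) max(absent_before) else NA_integer_
  win(last_absent, first_present, "invaded", outliers)
}

#' Invasion windows for every species/TE combination
#'
#' @param samples data frame with `strain`, `species`, `te`, `year` and
#'   `present` or `copy_number`.
#' @param ... passed to [infer_invasion_window()].
#' @return Data frame with one row per species x TE: `species`, `te`, and
#'   the [infer_invasion_window()] columns.
#' @export
invasion_windows <- function(samples, ...) {
  stopifnot(all(c("species", "te") %in% names(samples)))
  combos <- unique(samples[, c("species", "te")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- samples[samples$species == combos$species[i] &
                     samples$te == combos$te[i], , drop = FALSE]
    cbind(combos[i, , drop = FALSE], infer_invasion_window(sub, ...))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Presence co-occurrence of two TEs across strains
#'
#' Tests whether two TEs are jointly present or absent across strains, as
#' expected when both spread through the same gene flow.
#'
#' @param presence_a,presence_b logical presence vectors over the same
#'   strains (at least 4).
#' @return List: `concordance` (fraction of strains with equal presence
#'   state), `p_value` (two-sided Fisher exact; `NA` with a warning when a
#'   TE is constant across strains), `table` (the 2x2 table).
#' @export
cooccurrence <- function(presence_a, presence_b) {
  stopifnot(length(presence_a) == length(presence_b))
  if (length(presence_a) < 4L) stop("need at least 4 strains")
  a <- factor(presence_a, levels = c(FALSE, TRUE))
  b <- factor(presence_b, levels = c(FALSE, TRUE))
  tab <- table(a, b)
  conc <- mean(presence_a == presence_b)
  p <- if (length(unique(presence_a)) < 2L || length(unique(presence_b)) < 2L) {
    warning("one TE is constant across strains; Fisher p undefined")
    NA_real_
  } else {
    fisher.test(tab)$p.value
  }
  list(concordance = conc, p_value = p, table = tab)
}

#' Shared TE SNPs between two species
#'
#' TE-internal SNPs segregating in two species at the same consensus
#' position indicate that the same TE variants were transmitted; several
#' shared SNPs point to multi-variant transfer (e.g. via hybridisation)
#' rather than a single-copy horizontal transfer event.
#'
#' @param snps_a,snps_b SNP data frames from [call_te_snps()] called on
#'   the same consensus coordinate system.
#' @param require_allele_match when `TRUE`, the minor allele must match as
#'   well as the position.
#' @return The shared subset of `snps_a` (with `minor_b` when allele
#'   matching is off); the count is `nrow()` of the result.
#' @export
shared_te_snps <- function(snps_a, snps_b, require_allele_match = FALSE) {
  if (nrow(snps_a) > 0 && nrow(snps_b) > 0 &&
      !identical(unique(snps_a$te), unique(snps_b$te)))
    stop("SNP sets come from different TEs: ",
         unique(snps_a$te), " vs ", unique(snps_b$te))
  key_a <- if (require_allele_match) paste(snps_a$pos, snps_a$minor) else snps_a$pos
  key_b <- if (require_allele_match) paste(snps_b$pos, snps_b$minor) else snps_b$pos
  hit <- match(key_a, key_b)
  out <- snps_a[!is.na(hit), , drop = FALSE]
  if (!require_allele_match)
    out$minor_b <- snps_b$minor[hit[!is.na(hit)]]
  rownames(out) <- NULL
  out
}

#' Contact graph between species
#'
#' @param edges data frame with columns `a`, `b`, `type`
#'   (`"range_overlap"` or `"hybridization"`); undirected, no self edges.
#' @return Validated data frame of class `"contact_graph"`.
#' @export
contact_graph <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("a", "b", "type") %in% names(edges)))
  if (any(edges$a == edges$b)) stop("contact graph must not contain self edges")
  if (!all(edges$type %in% c("range_overlap", "hybridization")))
    stop("edge type must be range_overlap or hybridization")
  structure(edges, class = c("contact_graph", "data.frame"))
}

contact_type <- function(graph, x, y) {
  hit <- (graph$a == x & graph$b == y) | (graph$a == y & graph$b == x)
  if (!any(hit)) return(NA_character_)
  types <- graph$type[hit]
  if ("hybridization" %in% types) "hybridization" else "range_overlap"
}

#' Reconstruct the cascade of horizontal-transfer events
#'
#' A transparent rule engine over the invasion windows: every invaded
#' recipient is linked to the eligible donor - an invaded species in
#' contact with the recipient whose first-present year does not exceed the
#' recipient's. Candidate donors are ranked by evidence class (more than
#' `snp_evidence_threshold` shared segregating TE SNPs beats a
#' hybridisation edge, which beats plain range overlap), then by earliest
#' first-present year. Recipients with no eligible donor are reported
#' unresolved (external or unsampled donor). When donor and recipient
#' share the same first-present year the direction is ambiguous: both
#' orderings are emitted without `time_order` evidence.
#'
#' @param windows data frame from [invasion_windows()] (`species`, `te`,
#'   `last_absent_year`, `first_present_year`, `status`).
#' @param contacts a [contact_graph()].
#' @param shared_snps `NULL` or data frame `species_a`, `species_b`, `te`,
#'   `n_shared` (undirected).
#' @param snp_evidence_threshold shared-SNP count that must be exceeded to
#'   count as multi-variant (hybridisation-compatible) evidence.
#' @return List: `events` (data frame `donor`, `recipient`, `te`,
#'   `year_lo`, `year_hi`, `evidence` comma-joined from
#'   {`time_order`, `contact`, `hybridization`, `shared_snps`}) and
#'   `unresolved` (data frame `species`, `te`).
#' @export
reconstruct_cascade <- function(windows, contacts, shared_snps = NULL,
                                snp_evidence_threshold = 1L) {
  stopifnot(inherits(contacts, "contact_graph"))
  n_shared <- function(x, y, te) {
    if (is.null(shared_snps)) return(0L)
    hit <- shared_snps$te == te &
      ((shared_snps$species_a == x & shared_snps$species_b == y) |
         (shared_snps$species_a == y & shared_snps$species_b == x))
    if (!any(hit)) 0L else max(shared_snps$n_shared[hit])
  }
  events <- list()
  unresolved <- list()
  for (te in unique(windows$te)) {
    w <- windows[windows$te == te & windows$status == "invaded" &
                   !is.na(windows$first_present_year), , drop = FALSE]
    if (nrow(w) < 2L) {
      if (nrow(w) == 1L)
        unresolved[[length(unresolved) + 1L]] <-
          data.frame(species = w$species, te = te, stringsAsFactors = FALSE)
      next
    }
    fp <- setNames(w$first_present_year, w$species)
    la <- setNames(w$last_absent_year, w$species)
    for (r in w$species[order(fp[w$species])]) {
      cand <- list()
      for (d in setdiff(w$species, r)) {
        if (fp[[d]] > fp[[r]]) next
        ct <- contact_type(contacts, d, r)
        if (is.na(ct)) next
        ns <- n_shared(d, r, te)
        rank <- if (ns > snp_evidence_threshold) 3L
                else if (ct == "hybridization") 2L else 1L
        cand[[length(cand) + 1L]] <-
          list(donor = d, rank = rank, fp = fp[[d]], contact = ct, n_snp = ns)
      }
      if (length(cand) == 0L) {
        unresolved[[length(unresolved) + 1L]] <-
          data.frame(species = r, te = te, stringsAsFactors = FALSE)
        next
      }
      ranks <- vapply(cand, `[[`, integer(1), "rank")
      fps <- vapply(cand, function(x) as.numeric(x$fp), numeric(1))
      dn <- vapply(cand, `[[`, character(1), "donor")
      ord <- order(-ranks, fps, dn)
      best <- cand[[ord[1L]]]
      ev <- character(0)
      if (best$fp < fp[[r]]) ev <- "time_order"
      ev <- c(ev, if (best$contact == "hybridization") "hybridization"
              else "contact")
      if (best$n_snp > snp_evidence_threshold) ev <- c(ev, "shared_snps")
      events[[length(events) + 1L]] <- data.frame(
        donor = best$donor, recipient = r, te = te,
        year_lo = la[[r]], year_hi = fp[[r]],
        evidence = paste(ev, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  bind <- function(x, proto) if (length(x) == 0L) proto else
    do.call(rbind, c(x, list(make.row.names = FALSE)))
  ev_proto <- data.frame(donor = character(0), recipient = character(0),
                         te = character(0), year_lo = integer(0),
                         year_hi = integer(0), evidence = character(0),
                         stringsAsFactors = FALSE)
  un_proto <- data.frame(species = character(0), te = character(0),
                         stringsAsFactors = FALSE)
  list(events = bind(events, ev_proto), unresolved = bind(unresolved, un_proto))
}

#' Geographic patchiness of a TE
#'
#' During an ongoing invasion some demes carry the TE while others do not;
#' a patchy presence pattern across sampling locations is therefore
#' evidence of a recent invasion even without time-series data.
#'
#' @param samples data frame with `strain`, `location` and `present` (or
#'   `copy_number`); one species and TE at a time, at least two locations.
#' @return List: `groups` (per-location classification
#'   `all_present`/`all_absent`/`mixed` with strain counts), `patchy`
#'   (`TRUE` iff at least one all-present and one all-absent location
#'   exist), and the location name vectors `fixed_present`,
#'   `fixed_absent`, `mixed`.
#' @export
geographic_patchiness <- function(samples) {
  stopifnot(all(c("location") %in% names(samples)))
  if (!"present" %in% names(samples)) samples$present <- samples$copy_number > 1
  if (length(unique(samples$location)) < 2L)
    stop("need at least two location groups")
  cls <- vapply(split(samples$present, samples$location), function(p) {
    if (all(p)) "all_present" else if (!any(p)) "all_absent" else "mixed"
  }, character(1))
  n <- vapply(split(samples$present, samples$location), length, integer(1))
  groups <- data.frame(location = names(cls), n = unname(n),
                       status = unname(cls), stringsAsFactors = FALSE)
  list(groups = groups,
       patchy = any(cls == "all_present") && any(cls == "all_absent"),
       fixed_present = groups$location[cls == "all_present"],
       fixed_absent = groups$location[cls == "all_absent"],
       mixed = groups$location[cls == "mixed"])
}

#' Copy-number time-series plot
#'
#' Year versus copy number per species, the standard visualisation of an
#' invasion time series. Requires ggplot2.
#'
#' @param samples data frame with `year`, `copy_number`, `species` and
#'   optionally `te`.
#' @return A ggplot object.
#' @export
plot_invasion_timeseries <- function(samples) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  p <- ggplot2::ggplot(samples,
                       ggplot2::aes(x = year, y = copy_number,
                                    colour = species)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "collection year", y = "normalised copy number")
  if ("te" %in% names(samples)) p <- p + ggplot2::facet_wrap(~te)
  p
}
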