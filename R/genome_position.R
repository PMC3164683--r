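# Centromere-relative event coordinates, binned distributions along
# chromosomal arms, and congruence with recombination hotspots.

#' Centromere table constructor
#'
#' @param chrom chromosome ids.
#' @param centromere_bp centromere position (1-based bp).
#' @param length_bp chromosome length (bp).
#' @return validated data.frame with arm lengths.
#' @export
centromere_table <- function(chrom, centromere_bp, length_bp) {
  stopifnot(length(chrom) == length(centromere_bp),
            length(chrom) == length(length_bp),
            all(centromere_bp > 0), all(centromere_bp < length_bp))
  data.frame(chrom = chrom, centromere_bp = centromere_bp,
             length_bp = length_bp,
             p_arm_bp = centromere_bp, q_arm_bp = length_bp - centromere_bp)
}

#' Read a centromere table from TSV
#'
#' Headered TSV with columns `chrom`, `centromere_bp`, `length_bp`
#' (e.g. derived from the UCSC Table Browser gap track).
#'
#' @param path file path.
#' @return centromere table data.frame.
#' @export
read_centromeres <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  centromere_table(tab$chrom, tab$centromere_bp, tab$length_bp)
}

#' Centromere-relative position of events
#'
#' Maps each event to its position along the chromosomal arm containing
#' its interval midpoint, rescaled so 0 is the centromere and 1 the
#' telomere of that arm. An event whose interval spans the centromere is
#' assigned by its midpoint and flagged. The value is scale-invariant:
#' doubling every physical coordinate leaves it unchanged.
#'
#' @param events event data.frame with `chrom`, `left_bp`, `right_bp`.
#' @param centromeres a [centromere_table()].
#' @return `events` with added columns `rel_pos` in \[0, 1\], `arm`
#'   (`"p"`/`"q"`), and `spans_centromere`.
#' @export
relative_position <- function(events, centromeres) {
  idx <- match(events$chrom, centromeres$chrom)
  if (anyNA(idx)) stop("event chromosome(s) missing from centromere table: ",
                       paste(unique(events$chrom[is.na(idx)]), collapse = ", "))
  cen <- centromeres$centromere_bp[idx]
  mid <- (events$left_bp + events$right_bp) / 2
  on_q <- mid >= cen
  arm_len <- ifelse(on_q, centromeres$q_arm_bp[idx], centromeres$p_arm_bp[idx])
  events$rel_pos <- pmin(abs(mid - cen) / arm_len, 1)
  events$arm <- ifelse(on_q, "q", "p")
  events$spans_centromere <- events$left_bp < cen & events$right_bp > cen
  events
}

# Bin index for relative positions: floor(rel/width), last bin closed.
.bin_index <- function(rel, width) {
  n_bins <- round(1 / width)
  pmin(floor(rel / width), n_bins - 1) + 1L
}

#' Binned distribution of events along chromosomal arms
#'
#' Groups positioned events into bins of relative distance from the
#' centromere and reports, per parent sex and age group, the mean number
#' of events per transmission in each bin. Per-bin shifts between the
#' under-30 and over-30 groups (a parent of exactly 30 is "old") are
#' tested by permuting the age-group labels of transmissions.
#'
#' @param events positioned events (see [relative_position()]) with
#'   `parent_id`, `child_id`, `parent`, `rel_pos`.
#' @param records transmission records data.frame with `parent_id`,
#'   `child_id`, `parent`, `age` (one row per transmission contributing
#'   events).
#' @param width bin width in relative-distance units (0.05 or 0.1;
#'   other widths are allowed with a warning).
#' @param threshold age-group cut (default 30).
#' @param n_perm per-bin label permutations (0 skips the shift tests).
#' @param seed optional seed.
#' @return list with `bins` (long data.frame: `parent`, `age_group`,
#'   `bin`, `bin_mid`, `mean_per_transmission`, `n_transmissions`) and
#'   `shift_tests` (per parent and bin: `delta`, `p_perm`).
#' @export
bin_distribution <- function(events, records, width = 0.05, threshold = 30,
                             n_perm = 0, seed = NULL) {
  if (!width %in% c(0.05, 0.1))
    warning("non-standard bin width: ", width)
  if (is.null(events$rel_pos)) stop("events lack rel_pos; run relative_position()")
  n_bins <- round(1 / width)
  events$bin <- .bin_index(events$rel_pos, width)
  records$old <- records$age >= threshold
  out_bins <- list(); out_shift <- list()
  for (par in unique(records$parent)) {
    rec_p <- records[records$parent == par, , drop = FALSE]
    ev_p <- events[events$parent == par &
                   !is.na(events$child_id), , drop = FALSE]
    key_rec <- paste(rec_p$parent_id, rec_p$child_id)
    # transmissions x bins count matrix
    Cm <- matrix(0, nrow(rec_p), n_bins)
    ki <- match(paste(ev_p$parent_id, ev_p$child_id), key_rec)
    keep <- !is.na(ki)
    for (i in which(keep)) Cm[ki[i], ev_p$bin[i]] <- Cm[ki[i], ev_p$bin[i]] + 1
    for (grp in c(FALSE, TRUE)) {
      sel <- rec_p$old == grp
      if (!any(sel)) next
      out_bins[[length(out_bins) + 1L]] <- data.frame(
        parent = par, age_group = if (grp) "old" else "young",
        bin = seq_len(n_bins), bin_mid = (seq_len(n_bins) - 0.5) * width,
        mean_per_transmission = colMeans(Cm[sel, , drop = FALSE]),
        n_transmissions = sum(sel))
    }
    if (n_perm > 0 && any(rec_p$old) && !all(rec_p$old)) {
      st <- .shift_test_matrix(Cm, rec_p$old, n_perm, seed,
                               alternative = "less")
      out_shift[[length(out_shift) + 1L]] <- data.frame(
        parent = par, bin = seq_len(n_bins),
        bin_mid = (seq_len(n_bins) - 0.5) * width,
        delta = st$delta, p_perm = st$p)
    }
  }
  list(bins = do.call(rbind, out_bins),
       shift_tests = if (length(out_shift)) do.call(rbind, out_shift) else NULL)
}

#' Correlation between centromere distance and recombination
#'
#' Pearson correlation between bin midpoint distances and per-bin mean
#' counts, with a permutation p-value obtained by shuffling the counts
#' across bins.
#'
#' @param bin_mids bin midpoint relative distances.
#' @param bin_means per-bin mean events per transmission.
#' @param n_perm count permutations (default 10000).
#' @param seed optional seed.
#' @param alternative extremeness rule.
#' @return list with `pearson_r` and `p`.
#' @export
distance_count_correlation <- function(bin_mids, bin_means, n_perm = 10000,
                                       seed = NULL,
                                       alternative = c("two_sided", "less",
                                                       "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(bin_mids) == length(bin_means), length(bin_mids) >= 3)
  r <- stats::cor(bin_mids, bin_means)
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_perm), function(j)
    stats::cor(bin_mids, bin_means[sample.int(length(bin_means))]), 1.0)
  list(pearson_r = r, p = .perm_pvalue(r, null, alternative))
}

#' Read / write BED3 interval files
#'
#' Standard 0-based half-open BED; intervals are converted to 1-based
#' closed coordinates on read (`start + 1`, `end`) and back on write.
#'
#' @param path file path.
#' @return `read_bed3`: data.frame `chrom`, `start`, `end` (1-based
#'   closed).
#' @export
read_bed3 <- function(path) {
  bed <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(chrom = bed[[1]], start = bed[[2]] + 1, end = bed[[3]])
}

#' @param intervals data.frame `chrom`, `start`, `end` (1-based closed).
#' @rdname read_bed3
#' @export
write_bed3 <- function(intervals, path) {
  utils::write.table(
    data.frame(intervals$chrom, intervals$start - 1, intervals$end),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Merge overlapping/adjacent intervals per chromosome (1-based closed).
.merge_intervals <- function(iv) {
  out <- lapply(split(iv, iv$chrom), function(z) {
    ir <- IRanges::reduce(IRanges::IRanges(z$start, z$end))
    data.frame(chrom = z$chrom[1], start = IRanges::start(ir),
               end = IRanges::end(ir))
  })
  do.call(rbind, out)
}

#' Hotspot congruence of well-localized events
#'
#' Restricts to events whose flanking-marker interval is narrower than
#' `max_interval_bp` (well-localized events), and reports the fraction
#' overlapping at least one hotspot together with the fraction expected if
#' events were placed uniformly at random on their chromosome. The
#' expected fraction uses the interval-dilation argument: a uniformly
#' placed interval of length `w` hits a hotspot set of total dilated
#' length `sum(len_h + w)` with probability `min(1, sum(len_h + w) / L)`
#' (edge effects ignored, capped at 1). Hotspots are merged before
#' computing either quantity.
#'
#' @param events event data.frame (`chrom`, `left_bp`, `right_bp`).
#' @param hotspots hotspot intervals, 1-based closed (`chrom`, `start`,
#'   `end`), e.g. from [read_bed3()].
#' @param chrom_lengths data.frame `chrom`, `length_bp`.
#' @param max_interval_bp maximum event interval width (default 30 kb).
#' @return list with `observed_fraction`, `expected_fraction`, `n_events`.
#' @export
hotspot_overlap <- function(events, hotspots, chrom_lengths,
                            max_interval_bp = 30000) {
  w <- events$right_bp - events$left_bp
  ev <- events[w < max_interval_bp, , drop = FALSE]
  n <- nrow(ev)
  if (n == 0) return(list(observed_fraction = NA_real_,
                          expected_fraction = NA_real_, n_events = 0L))
  if (nrow(hotspots) == 0)
    return(list(observed_fraction = 0, expected_fraction = 0, n_events = n))
  hs <- .merge_intervals(hotspots)
  len_of <- stats::setNames(chrom_lengths$length_bp, chrom_lengths$chrom)
  hit <- logical(n); expct <- numeric(n)
  for (cc in unique(ev$chrom)) {
    sel <- ev$chrom == cc
    hsc <- hs[hs$chrom == cc, , drop = FALSE]
    L <- len_of[as.character(cc)]
    if (is.na(L)) stop("no length for chromosome ", cc)
    wlen <- ev$right_bp[sel] - ev$left_bp[sel]
    if (nrow(hsc) == 0) { expct[sel] <- 0; next }
    ov <- IRanges::countOverlaps(
      IRanges::IRanges(ev$left_bp[sel], ev$right_bp[sel]),
      IRanges::IRanges(hsc$start, hsc$end))
    hit[sel] <- ov > 0
    expct[sel] <- pmin(1, (sum(hsc$end - hsc$start + 1) +
                             nrow(hsc) * wlen) / L)
  }
  list(observed_fraction = mean(hit), expected_fraction = mean(expct),
       n_events = n)
}

#' Hotspot usage by age group
#'
#' Splits well-localized events by the parent's age group, reports each
#' group's hotspot-overlap fraction, and tests whether the two groups
#' place their hotspot-overlapping events differently along chromosomal
#' arms: the statistic is the summed absolute difference of the groups'
#' binned relative-position distributions, with the null obtained by
#' permuting group labels across events.
#'
#' @inheritParams hotspot_overlap
#' @param events positioned events including `rel_pos` and `age` (parental
#'   age at birth of the transmission).
#' @param threshold age-group cut (default 30).
#' @param width bin width for the positional comparison.
#' @param n_perm label permutations.
#' @param seed optional seed.
#' @return list with `fractions` (per group), `statistic`, `p`.
#' @export
hotspot_usage_by_group <- function(events, hotspots, chrom_lengths,
                                   max_interval_bp = 30000, threshold = 30,
                                   width = 0.1, n_perm = 2000, seed = NULL) {
  w <- events$right_bp - events$left_bp
  ev <- events[w < max_interval_bp & !is.na(events$age), , drop = FALSE]
  if (is.null(ev$rel_pos)) stop("events lack rel_pos; run relative_position()")
  old <- ev$age >= threshold
  frac <- c(
    young = hotspot_overlap(ev[!old, ], hotspots, chrom_lengths,
                            max_interval_bp)$observed_fraction,
    old = hotspot_overlap(ev[old, ], hotspots, chrom_lengths,
                          max_interval_bp)$observed_fraction)
  bins <- .bin_index(ev$rel_pos, width)
  n_bins <- round(1 / width)
  dist_stat <- function(lab) {
    if (!any(lab) || all(lab)) return(0)
    p1 <- tabulate(bins[lab], n_bins) / sum(lab)
    p2 <- tabulate(bins[!lab], n_bins) / sum(!lab)
    sum(abs(p1 - p2))
  }
  obs <- dist_stat(old)
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_perm), function(j)
    dist_stat(old[sample.int(length(old))]), 1.0)
  list(fractions = frac, statistic = obs,
       p = .perm_pvalue(obs, null, "greater"))
}
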