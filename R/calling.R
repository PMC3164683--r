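# Crossover calling by sibling-comparison phasing in nuclear families.
#
# At markers where one parent is heterozygous and the other homozygous, the
# allele each child received from the heterozygous parent is unambiguous.
# Children are phased relative to a reference sibling; a switch in the
# relative inheritance state marks a crossover in that child's meiosis,
# except that a switch shared by ALL non-reference siblings in the same
# inter-marker interval is attributed to the reference child instead. The
# caller then (i) removes markers creating tight double recombinants
# (genotyping artifacts), (ii) drops events shared between siblings, and
# (iii) averages counts over 3-child reduced families to remove family-size
# bias.

#' Find informative markers for one parent in a nuclear family
#'
#' A marker is informative for `parent` when that parent is heterozygous,
#' the co-parent is homozygous, no family member has a missing call there,
#' and every child's implied transmitted allele is Mendelian-consistent.
#'
#' @param gm a [genotype_matrix].
#' @param family a `nuclear_family` from [extract_nuclear_families()].
#' @param parent `"mother"` or `"father"`.
#' @return list per chromosome of marker row indices into `gm$map`.
#' @export
find_informative_markers <- function(gm, family, parent = c("mother", "father")) {
  parent <- match.arg(parent)
  inf <- .informative(gm, family, parent)
  split(inf$rows, gm$map$chrom[inf$rows])
}

# Shared informative-marker computation: returns row indices and the
# transmitted-allele matrix (markers x children).
.informative <- function(gm, family, parent) {
  focal <- if (parent == "mother") family$mother else family$father
  co <- if (parent == "mother") family$father else family$mother
  need <- c(focal, co, family$children)
  miss <- setdiff(need, colnames(gm$geno))
  if (length(miss)) stop("family members not genotyped: ",
                         paste(miss, collapse = ", "))
  gp <- gm$geno[, focal]
  gc_ <- gm$geno[, co]
  kids <- gm$geno[, family$children, drop = FALSE]
  cand <- !is.na(gp) & gp == 1L & !is.na(gc_) & gc_ %in% c(0L, 2L) &
    rowSums(is.na(kids)) == 0
  tr <- kids[cand, , drop = FALSE] - gc_[cand] / 2
  ok <- rowSums(tr == 0 | tr == 1) == ncol(tr)   # Mendelian-consistent
  rows <- which(cand)[ok]
  list(rows = rows, transmitted = tr[ok, , drop = FALSE])
}

#' Phase a nuclear family for one parent
#'
#' Builds the per-chromosome inheritance-state track for the focal parent's
#' meioses. The first child is the reference and starts in state 1 on each
#' chromosome; every other child is in state 1 where it received the same
#' allele as the reference, state 2 otherwise. With three or more children,
#' a state switch occurring simultaneously in all non-reference children at
#' the same inter-marker interval is attributed to the reference child and
#' removed from the others. With exactly two children switches cannot be
#' assigned to a child; they are counted at the family level.
#'
#' @inheritParams find_informative_markers
#' @return an `informative_track`: per-chromosome marker positions and a
#'   markers x children state matrix (values 1/2).
#' @export
phase_family <- function(gm, family, parent = c("mother", "father")) {
  parent <- match.arg(parent)
  if (length(family$children) < 2)
    stop("phasing requires at least two children")
  inf <- .informative(gm, family, parent)
  chrom <- gm$map$chrom[inf$rows]
  pos <- gm$map$pos[inf$rows]
  n_kid <- length(family$children)
  per_chrom <- lapply(split(seq_along(inf$rows), chrom), function(ii) {
    T_ <- inf$transmitted[ii, , drop = FALSE]       # M x n_kid, values 0/1
    M <- nrow(T_)
    if (M == 0)
      return(list(pos = numeric(0), rows = integer(0),
                  S = matrix(integer(0), 0, n_kid)))
    r <- T_ != T_[, 1]                              # TRUE = differs from ref
    phi <- integer(M)
    if (n_kid >= 3 && M >= 2) {
      x <- r[-1, -1, drop = FALSE] != r[-M, -1, drop = FALSE]
      all_switch <- rowSums(x) == (n_kid - 1)
      phi <- cumsum(c(0L, as.integer(all_switch))) %% 2L
    }
    S <- (r + phi) %% 2L                            # recycles phi by column
    S[, 1] <- phi
    list(pos = pos[ii], rows = inf$rows[ii], S = S + 1L)
  })
  structure(list(family_id = family$family_id,
                 parent = parent,
                 parent_id = if (parent == "mother") family$mother else
                   family$father,
                 children = family$children,
                 assigned = n_kid >= 3,
                 chrom = per_chrom),
            class = "informative_track")
}

#' @export
print.informative_track <- function(x, ...) {
  cat("informative_track:", x$parent, x$parent_id, "in family",
      x$family_id, "-", sum(vapply(x$chrom, function(z) length(z$pos), 1L)),
      "informative markers on", length(x$chrom), "chromosome(s)\n")
  invisible(x)
}

#' Remove markers creating tight double recombinants
#'
#' A single marker whose state in some child differs from both its
#' neighbours implies two crossovers around it; when the flanking markers
#' are less than `window_bp` apart such tight double recombinants are
#' almost always genotyping artifacts. The marker (not the events) is
#' removed from the track for all children; passes run left to right and
#' repeat until no flagged marker remains.
#'
#' @param track an [phase_family()] track.
#' @param window_bp maximum span of the two implied switches (default 1 Mb,
#'   roughly 1 cM at the genomic average).
#' @return the pre-treated track, with a `removed` element listing the
#'   dropped marker rows per chromosome.
#' @export
pretreat_double_recombinants <- function(track, window_bp = 1e6) {
  removed <- integer(0)
  track$chrom <- lapply(track$chrom, function(z) {
    pos <- z$pos; S <- z$S; rows <- z$rows
    repeat {
      M <- length(pos)
      if (M < 3) break
      mid <- 2:(M - 1)
      blip <- (S[mid - 1, , drop = FALSE] == S[mid + 1, , drop = FALSE]) &
        (S[mid, , drop = FALSE] != S[mid - 1, , drop = FALSE])
      tight <- (pos[mid + 1] - pos[mid - 1]) < window_bp
      bad <- mid[rowSums(blip) > 0 & tight]
      if (!length(bad)) break
      removed <<- c(removed, rows[bad])
      pos <- pos[-bad]; S <- S[-bad, , drop = FALSE]; rows <- rows[-bad]
    }
    list(pos = pos, rows = rows, S = S)
  })
  track$removed <- removed
  track
}

#' Call crossover events from a phased track
#'
#' One event per state switch per child, located between the two
#' informative markers flanking the switch (1-based closed interval).
#' `n_share` counts the children of the family switching in the same
#' inter-marker interval. For two-child families switches cannot be
#' assigned to a child and `child_id` is `NA`.
#'
#' @param track a (pre-treated) [phase_family()] track.
#' @return data.frame of events: `family`, `parent_id`, `parent`,
#'   `child_id`, `chrom`, `left_bp`, `right_bp`, `n_share`.
#' @export
call_events <- function(track) {
  out <- list()
  for (cc in names(track$chrom)) {
    z <- track$chrom[[cc]]
    M <- length(z$pos)
    if (M < 2) next
    sw <- z$S[-1, , drop = FALSE] != z$S[-M, , drop = FALSE]  # (M-1) x kids
    n_share <- rowSums(sw)
    hit <- which(sw, arr.ind = TRUE)
    if (!nrow(hit)) next
    out[[cc]] <- data.frame(
      family = track$family_id,
      parent_id = track$parent_id,
      parent = track$parent,
      child_id = if (track$assigned) track$children[hit[, 2]] else
        NA_character_,
      chrom = as.integer(cc),
      left_bp = z$pos[hit[, 1]],
      right_bp = z$pos[hit[, 1] + 1],
      n_share = n_share[hit[, 1]],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(.empty_events())
  ev <- do.call(rbind, out)
  rownames(ev) <- NULL
  ev
}

.empty_events <- function() {
  data.frame(family = character(0), parent_id = character(0),
             parent = character(0), child_id = character(0),
             chrom = integer(0), left_bp = numeric(0), right_bp = numeric(0),
             n_share = integer(0), stringsAsFactors = FALSE)
}

#' Keep only crossovers unique within a family
#'
#' Events seen in two or more children of the same family at the same
#' inter-marker interval are far more often phase or genotyping artifacts
#' than genuine coincident crossovers; all copies are removed. Applying the
#' rule in families of every size avoids the small-family downward bias of
#' counting shared events only in large families.
#'
#' @param events event data.frame from [call_events()].
#' @return filtered event data.frame.
#' @export
deduplicate_events <- function(events) {
  events[events$n_share < 2, , drop = FALSE]
}

#' Call crossovers in one nuclear family
#'
#' Runs phase -> pre-treat -> call (-> deduplicate) for one or both
#' parents.
#'
#' @inheritParams find_informative_markers
#' @param parents parents to call (default both).
#' @param window_bp pre-treatment window (see
#'   [pretreat_double_recombinants()]); `0` disables pre-treatment.
#' @param unique_only apply [deduplicate_events()].
#' @return event data.frame.
#' @export
call_family <- function(gm, family, parents = c("mother", "father"),
                        window_bp = 1e6, unique_only = TRUE) {
  out <- lapply(parents, function(p) {
    tr <- phase_family(gm, family, p)
    if (window_bp > 0) tr <- pretreat_double_recombinants(tr, window_bp)
    call_events(tr)
  })
  ev <- do.call(rbind, out)
  if (unique_only) ev <- deduplicate_events(ev)
  rownames(ev) <- NULL
  ev
}

#' Unbiased per-child counts from reduced families
#'
#' Removing shared events penalizes large sibships, where coincidental
#' sharing is more likely. Large families are therefore partitioned into
#' all 3-child subsets ("reduced families"); the full caller runs on each
#' subset and each child's unbiased count is the mean of its counts over
#' the `choose(n-1, 2)` subsets containing it. Families with fewer than 4
#' children return their standard counts unchanged.
#'
#' @inheritParams call_family
#' @return data.frame `parent_id`, `parent`, `child_id`, `unbiased`.
#' @export
reduced_family_counts <- function(gm, family, parents = c("mother", "father"),
                                  window_bp = 1e6, unique_only = TRUE) {
  n <- length(family$children)
  if (n < 4) {
    ev <- call_family(gm, family, parents, window_bp, unique_only)
    tab <- .count_by_child(ev, family, parents)
    names(tab)[names(tab) == "total"] <- "unbiased"
    return(tab)
  }
  subsets <- utils::combn(family$children, 3, simplify = FALSE)
  acc <- list()
  for (s in subsets) {
    fam_s <- family; fam_s$children <- s
    ev <- call_family(gm, fam_s, parents, window_bp, unique_only)
    acc[[length(acc) + 1L]] <- .count_by_child(ev, fam_s, parents)
  }
  all_counts <- do.call(rbind, acc)
  agg <- stats::aggregate(total ~ parent_id + parent + child_id,
                          data = all_counts, FUN = mean)
  names(agg)[names(agg) == "total"] <- "unbiased"
  agg
}

# Per-child totals, including zero rows for children without events.
.count_by_child <- function(events, family, parents) {
  grid <- expand.grid(child_id = family$children, parent = parents,
                      stringsAsFactors = FALSE)
  grid$parent_id <- ifelse(grid$parent == "mother", family$mother,
                           family$father)
  key_ev <- paste(events$parent_id, events$child_id)
  cnt <- table(key_ev)
  key <- paste(grid$parent_id, grid$child_id)
  grid$total <- as.numeric(cnt[key])
  grid$total[is.na(grid$total)] <- 0
  grid[, c("parent_id", "parent", "child_id", "total")]
}

#' Count crossovers per transmission
#'
#' Runs the full caller over a set of nuclear families and tabulates one
#' record per (parent, child) transmission for families with at least three
#' genotyped children -- with only two children the events of a meiosis
#' cannot be assigned to a child, so two-child families contribute events
#' (flagged unassigned) but no transmission records. Parental ages at birth
#' are attached from the pedigree's ages table when present; a missing age
#' for a required transmission is an error.
#'
#' @param gm a [genotype_matrix].
#' @param ped a [pedigree] (its `ages` table, if any, supplies ages).
#' @param families nuclear families; default
#'   `extract_nuclear_families(ped, gm)`.
#' @param window_bp,unique_only caller settings, see [call_family()].
#' @param reduced compute unbiased counts via [reduced_family_counts()] for
#'   families with four or more children.
#' @return list with `records` (per-transmission data.frame: `family`,
#'   `parent_id`, `parent`, `child_id`, `age`, `total`, `unbiased`),
#'   `per_chrom` (long data.frame of per-chromosome counts), and `events`
#'   (all called events, two-child families included).
#' @export
count_transmissions <- function(gm, ped, families = NULL, window_bp = 1e6,
                                unique_only = TRUE, reduced = TRUE) {
  if (is.null(families)) families <- extract_nuclear_families(ped, gm)
  chroms <- sort(unique(gm$map$chrom))
  events <- list(); records <- list(); per_chrom <- list()
  for (fam in families) {
    ev <- call_family(gm, fam, window_bp = window_bp,
                      unique_only = unique_only)
    events[[length(events) + 1L]] <- ev
    if (length(fam$children) < 3) next
    tab <- .count_by_child(ev, fam, c("mother", "father"))
    tab$family <- fam$family_id
    if (reduced && length(fam$children) >= 4) {
      ub <- reduced_family_counts(gm, fam, window_bp = window_bp,
                                  unique_only = unique_only)
      tab <- merge(tab, ub, by = c("parent_id", "parent", "child_id"))
    } else tab$unbiased <- tab$total
    records[[length(records) + 1L]] <- tab
    pc <- expand.grid(child_id = fam$children,
                      parent = c("mother", "father"), chrom = chroms,
                      stringsAsFactors = FALSE)
    pc$parent_id <- ifelse(pc$parent == "mother", fam$mother, fam$father)
    key_ev <- paste(ev$parent_id, ev$child_id, ev$chrom)
    cnt <- table(key_ev)
    pc$count <- as.numeric(cnt[paste(pc$parent_id, pc$child_id, pc$chrom)])
    pc$count[is.na(pc$count)] <- 0
    pc$family <- fam$family_id
    per_chrom[[length(per_chrom) + 1L]] <- pc
  }
  records <- if (length(records)) do.call(rbind, records) else NULL
  if (!is.null(records)) {
    records <- records[, c("family", "parent_id", "parent", "child_id",
                           "total", "unbiased")]
    if (!is.null(ped$ages)) {
      key <- paste(ped$ages$parent_id, ped$ages$child_id)
      idx <- match(paste(records$parent_id, records$child_id), key)
      if (anyNA(idx)) {
        bad <- records[is.na(idx), c("parent_id", "child_id")]
        stop("missing parental age for transmission(s): ",
             paste(paste(bad$parent_id, bad$child_id, sep = "->"),
                   collapse = ", "))
      }
      records$age <- ped$ages$age[idx]
    } else records$age <- NA_real_
    rownames(records) <- NULL
  }
  per_chrom <- if (length(per_chrom)) do.call(rbind, per_chrom) else NULL
  ev_all <- if (length(events)) do.call(rbind, events) else .empty_events()
  rownames(ev_all) <- NULL
  list(records = records, per_chrom = per_chrom, events = ev_all)
}

#' Write called events as BED6-like text
#'
#' Output coordinates are BED half-open (`left_bp - 1`, `right_bp`);
#' internal logic is 1-based closed, converted only here.
#'
#' @param events event data.frame.
#' @param path output path.
#' @export
write_events_bed <- function(events, path) {
  bed <- data.frame(
    chrom = events$chrom,
    start = events$left_bp - 1,
    end = events$right_bp,
    name = paste0(events$parent_id, ":",
                  ifelse(is.na(events$child_id), ".", events$child_id)),
    score = events$n_share,
    parent = events$parent)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
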