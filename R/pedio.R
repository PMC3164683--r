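# Pedigree genotype containers, PLINK bed/bim/fam input/output, and the
# SNP quality-control filters applied before crossover calling.

#' Construct a genotype matrix with its marker map
#'
#' Bundles a per-SNP marker map with a SNP x individual matrix of allele-B
#' dosages. Genotypes are coded 0/1/2 as copies of `allele_b`, with `NA` for
#' missing calls; missing is never conflated with a numeric code. Only
#' autosomes (chromosomes 1-22) are retained, markers are sorted by
#' chromosome and position, and SNP identifiers must be unique.
#'
#' @param map data.frame with columns `snp`, `chrom` (integer 1-22), `pos`
#'   (1-based physical bp), `allele_a`, `allele_b`.
#' @param geno integer matrix, one row per SNP (in `map` order) and one
#'   column per individual; values in `c(0, 1, 2, NA)`. Row names are SNP
#'   ids, column names individual ids.
#' @return An object of class `genotype_matrix`: a list with elements `map`
#'   and `geno`.
#' @export
genotype_matrix <- function(map, geno) {
  stopifnot(is.data.frame(map), is.matrix(geno))
  need <- c("snp", "chrom", "pos", "allele_a", "allele_b")
  if (!all(need %in% names(map)))
    stop("marker map must have columns: ", paste(need, collapse = ", "))
  if (nrow(map) != nrow(geno))
    stop("map rows (", nrow(map), ") != geno rows (", nrow(geno), ")")
  if (anyDuplicated(map$snp)) stop("SNP ids must be unique")
  keep <- map$chrom %in% 1:22
  if (!all(keep)) {
    map <- map[keep, , drop = FALSE]
    geno <- geno[keep, , drop = FALSE]
  }
  ord <- order(map$chrom, map$pos)
  map <- map[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  rownames(map) <- NULL
  rownames(geno) <- map$snp
  structure(list(map = map, geno = geno, n_dropped_nonautosomal = sum(!keep)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$geno), "SNPs x", ncol(x$geno),
      "individuals on", length(unique(x$map$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Construct a pedigree
#'
#' @param ind data.frame with columns `fid`, `id`, `father`, `mother`,
#'   `sex` (1 = male, 2 = female, 0 = unknown), `phen` (affection status,
#'   carried but unused). Founders have `father`/`mother` equal to `"0"`.
#' @param ages optional data.frame of parental ages at each child's birth,
#'   columns `family_id`, `parent_id`, `child_id`, `age` (years, fractional
#'   allowed); optional columns `parent_age`, `child_age` carry current ages
#'   used by [round_ages()].
#' @return An object of class `pedigree`.
#' @export
pedigree <- function(ind, ages = NULL) {
  stopifnot(is.data.frame(ind))
  need <- c("fid", "id", "father", "mother", "sex", "phen")
  if (!all(need %in% names(ind)))
    stop("pedigree needs columns: ", paste(need, collapse = ", "))
  ind[] <- lapply(ind, function(col) if (is.factor(col)) as.character(col) else col)
  for (col in c("fid", "id", "father", "mother"))
    ind[[col]] <- as.character(ind[[col]])
  if (anyDuplicated(ind$id)) stop("individual ids must be unique")
  # Fathers must be male, mothers female, where sex is recorded.
  sex_of <- stats::setNames(ind$sex, ind$id)
  fa <- ind$father[ind$father %in% ind$id]
  mo <- ind$mother[ind$mother %in% ind$id]
  if (any(sex_of[fa] == 2)) stop("a linked father is recorded as female")
  if (any(sex_of[mo] == 1)) stop("a linked mother is recorded as male")
  .check_acyclic(ind)
  if (!is.null(ages)) {
    need_a <- c("family_id", "parent_id", "child_id", "age")
    if (!all(need_a %in% names(ages)))
      stop("ages table needs columns: ", paste(need_a, collapse = ", "))
  }
  structure(list(ind = ind, ages = ages), class = "pedigree")
}

.check_acyclic <- function(ind) {
  parent_of <- rbind(
    data.frame(child = ind$id, parent = ind$father, stringsAsFactors = FALSE),
    data.frame(child = ind$id, parent = ind$mother, stringsAsFactors = FALSE))
  parent_of <- parent_of[parent_of$parent %in% ind$id, , drop = FALSE]
  for (start in unique(parent_of$child)) {
    seen <- character(0)
    frontier <- start
    while (length(frontier)) {
      frontier <- unique(parent_of$parent[parent_of$child %in% frontier])
      if (start %in% frontier) stop("pedigree cycle: ", start,
                                    " is its own ancestor")
      frontier <- setdiff(frontier, seen)
      seen <- c(seen, frontier)
    }
  }
  invisible(TRUE)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("pedigree:", nrow(x$ind), "individuals in",
      length(unique(x$ind$fid)), "families",
      if (!is.null(x$ages)) sprintf("(%d parental ages)", nrow(x$ages)) else
        "(no ages)", "\n")
  invisible(x)
}

# ---- PLINK binary I/O ------------------------------------------------------

.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))  # v1 magic + SNP-major mode

# Two-bit PLINK codes -> allele-B dosage: 00 hom A1 -> 0, 01 missing -> NA,
# 10 het -> 1, 11 hom A2 -> 2 (A2 is allele_b).
.bed_decode <- c(0L, NA, 1L, 2L)

#' Read a PLINK bed/bim/fam fileset
#'
#' Reads SNP-major PLINK v1 binary genotypes. Genotype codes are mapped to
#' allele-B (bim column 6, "A2") dosages 0/1/2 with `NA` for missing.
#' Non-autosomal markers are dropped with a message. FAM parental links
#' populate the returned pedigree.
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim`, `.fam` must exist.
#'   Alternatively pass the three paths explicitly.
#' @param bed,bim,fam explicit file paths overriding `prefix`.
#' @return list with elements `ped` ([pedigree]) and `gm`
#'   ([genotype_matrix]).
#' @export
read_plink <- function(prefix = NULL, bed = NULL, bim = NULL, fam = NULL) {
  if (!is.null(prefix)) {
    bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
    fam <- paste0(prefix, ".fam")
  }
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing file: ", f)
  bim_df <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("chrom", "snp", "cm", "pos",
                                            "allele_a", "allele_b"))
  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("fid", "id", "father", "mother",
                                            "sex", "phen"))
  n <- nrow(fam_df); m <- nrow(bim_df)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || !identical(raw[1:2], .bed_magic[1:2]))
    stop("not a PLINK bed file (bad magic bytes): ", bed)
  if (raw[3] != .bed_magic[3])
    stop("bed file is not SNP-major (mode byte != 0x01): ", bed)
  bpv <- ceiling(n / 4)  # bytes per variant
  body <- raw[-(1:3)]
  if (length(body) != bpv * m)
    stop("bed size inconsistent with fam x bim dimensions (",
         length(body), " body bytes, expected ", bpv * m, ")")
  ints <- matrix(as.integer(body), nrow = bpv, ncol = m)
  slots <- matrix(NA_integer_, nrow = 4 * bpv, ncol = m)
  for (k in 0:3) {
    code <- bitwAnd(bitwShiftR(ints, 2L * k), 3L)
    slots[seq(k + 1L, by = 4L, length.out = bpv), ] <- code
  }
  geno <- t(matrix(.bed_decode[slots[seq_len(n), , drop = FALSE] + 1L],
                   nrow = n, ncol = m))
  colnames(geno) <- fam_df$id
  n_nonauto <- sum(!(bim_df$chrom %in% 1:22))
  if (n_nonauto > 0)
    message("dropping ", n_nonauto, " non-autosomal SNP(s)")
  gm <- genotype_matrix(
    data.frame(snp = bim_df$snp, chrom = bim_df$chrom, pos = bim_df$pos,
               allele_a = bim_df$allele_a, allele_b = bim_df$allele_b,
               stringsAsFactors = FALSE),
    geno)
  list(ped = pedigree(fam_df), gm = gm)
}

#' Write a PLINK bed/bim/fam fileset
#'
#' Inverse of [read_plink()]: writes SNP-major PLINK v1 binary genotypes,
#' coding allele-B dosage 0/1/2 back to the two-bit scheme.
#'
#' @param gm a [genotype_matrix].
#' @param ped a [pedigree] whose individuals match `colnames(gm$geno)`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(gm, ped, prefix) {
  ind <- ped$ind[match(colnames(gm$geno), ped$ind$id), , drop = FALSE]
  if (anyNA(ind$id)) stop("pedigree is missing genotyped individuals")
  utils::write.table(
    data.frame(gm$map$chrom, gm$map$snp, 0, gm$map$pos,
               gm$map$allele_a, gm$map$allele_b),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    ind[, c("fid", "id", "father", "mother", "sex", "phen")],
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  n <- ncol(gm$geno); m <- nrow(gm$geno); bpv <- ceiling(n / 4)
  # dosage -> 2-bit code; NA -> 01; pad slots with hom-A1 (00)
  code <- matrix(0L, nrow = 4 * bpv, ncol = m)
  enc <- c(0L, 2L, 3L)
  g <- t(gm$geno)                      # n x m
  cd <- enc[g + 1L]; cd[is.na(g)] <- 1L
  code[seq_len(n), ] <- cd
  ints <- matrix(0L, nrow = bpv, ncol = m)
  for (k in 0:3)
    ints <- ints + code[seq(k + 1L, by = 4L, length.out = bpv), , drop = FALSE] *
      bitwShiftL(1L, 2L * k)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  writeBin(as.raw(ints), con)
  invisible(prefix)
}

#' Read or write a parental-ages table
#'
#' Headered TSV with columns `family_id`, `parent_id`, `child_id`, `age`
#' and optionally `parent_age`, `child_age` (current ages, used by
#' [round_ages()]).
#'
#' @param path file path.
#' @return `read_ages`: the ages data.frame.
#' @export
read_ages <- function(path) {
  ages <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  need <- c("family_id", "parent_id", "child_id", "age")
  if (!all(need %in% names(ages)))
    stop("ages file needs columns: ", paste(need, collapse = ", "))
  ages
}

#' @param ages ages data.frame.
#' @rdname read_ages
#' @export
write_ages <- function(ages, path) {
  utils::write.table(ages, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- Nuclear families ------------------------------------------------------

#' Extract nuclear families from a pedigree
#'
#' One nuclear family per (father, mother) couple with at least
#' `min_children` genotyped children; multi-generation pedigrees decompose
#' into overlapping nuclear families (an individual can be a child in one
#' and a parent in another). When `gm` is given, parents must be genotyped
#' and only genotyped children count, since the caller needs genotypes for
#' every member.
#'
#' @param ped a [pedigree].
#' @param gm optional [genotype_matrix] restricting membership to genotyped
#'   individuals.
#' @param min_children minimum number of (genotyped) children; the
#'   sibling-comparison caller needs at least two.
#' @return list of `nuclear_family` objects: `list(family_id, father,
#'   mother, children)`.
#' @export
extract_nuclear_families <- function(ped, gm = NULL, min_children = 2) {
  ind <- ped$ind
  has_both <- ind$father %in% ind$id & ind$mother %in% ind$id
  kids <- ind[has_both, , drop = FALSE]
  if (!is.null(gm)) {
    samp <- colnames(gm$geno)
    kids <- kids[kids$id %in% samp &
                 kids$father %in% samp & kids$mother %in% samp, , drop = FALSE]
  }
  if (nrow(kids) == 0) return(list())
  key <- paste(kids$father, kids$mother, sep = "\r")
  fams <- split(kids, key)
  out <- lapply(fams, function(k) {
    structure(list(family_id = k$fid[1], father = k$father[1],
                   mother = k$mother[1], children = k$id),
              class = "nuclear_family")
  })
  out <- out[vapply(out, function(f) length(f$children), 1L) >= min_children]
  names(out) <- NULL
  out[order(vapply(out, function(f) f$family_id, ""))]
}

# ---- Hardy-Weinberg exact test --------------------------------------------

#' Exact test of Hardy-Weinberg proportions
#'
#' Conditional on the observed allele counts, sums the probabilities of all
#' heterozygote counts whose conditional probability does not exceed that of
#' the observed table (the standard two-sided exact test). Monomorphic SNPs
#' return p = 1.
#'
#' @param n_aa,n_ab,n_bb genotype counts (allele-A homozygote, heterozygote,
#'   allele-B homozygote).
#' @return exact p-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2L * n_aa + n_ab
  n_b <- 2L * n_bb + n_ab
  if (n_a == 0 || n_b == 0) return(1)
  hets <- seq.int(n_a %% 2L, min(n_a, n_b), by = 2L)
  # log P(h | n_a, n) up to a common constant
  lp <- n * log(2) * 0 + hets * log(2) +
    lfactorial(n) - lfactorial((n_a - hets) / 2) -
    lfactorial(hets) - lfactorial((n_b - hets) / 2)
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  p_obs <- pr[match(n_ab, hets)]
  sum(pr[pr <= p_obs * (1 + 1e-9)])
}

# ---- Mendelian consistency -------------------------------------------------

# Feasible child dosages given parental dosages: the child inherits one
# allele from each parent, so dose(child) must lie in
# [ (f==2)+(m==2), 2-((f==0)+(m==0)) ]. NA anywhere -> consistent (unknown).
.mendel_ok <- function(f, m, c) {
  lo <- (f == 2L) + (m == 2L)
  hi <- 2L - ((f == 0L) + (m == 0L))
  ok <- c >= lo & c <= hi
  ok[is.na(ok)] <- TRUE
  ok
}

# ---- QC filter -------------------------------------------------------------

#' SNP quality-control filter
#'
#' Applies, in order: (1) Mendelian-error screening over all genotyped
#' trios -- inconsistent child calls are set to missing, and SNPs with
#' inconsistencies in more than `max_mendel_families` families are removed;
#' (2) a per-SNP call-rate filter; (3) an exact Hardy-Weinberg test computed
#' on founders only (children would distort the genotype frequencies).
#' Running Mendelian masking before the call-rate filter makes the whole
#' filter idempotent.
#'
#' @param gm a [genotype_matrix].
#' @param ped a [pedigree]; founders (no parents in the pedigree) define the
#'   HWE sample, parent-child links define the trios.
#' @param call_rate_min minimum fraction of non-missing calls (default 0.95).
#' @param hwe_alpha HWE exact-test removal threshold (default 0.01).
#' @param drop_mendelian_errors mask inconsistent trio calls and remove
#'   recurrently inconsistent SNPs.
#' @param max_mendel_families SNPs inconsistent in more than this many
#'   families are removed (default 1).
#' @return list with the filtered `gm` and a `report` (class `qc_report`)
#'   of per-filter removal counts.
#' @export
qc_filter <- function(gm, ped, call_rate_min = 0.95, hwe_alpha = 0.01,
                      drop_mendelian_errors = TRUE, max_mendel_families = 1) {
  stopifnot(call_rate_min > 0, call_rate_min < 1,
            hwe_alpha > 0, hwe_alpha < 1)
  geno <- gm$geno
  ind <- ped$ind
  m0 <- nrow(geno)
  n_mendel_masked <- 0L; n_mendel_removed <- 0L

  keep <- rep(TRUE, m0)
  if (drop_mendelian_errors) {
    samp <- colnames(geno)
    trio <- ind[ind$id %in% samp & ind$father %in% samp & ind$mother %in% samp,
                , drop = FALSE]
    if (nrow(trio) > 0) {
      bad_fam <- matrix(FALSE, nrow = m0, ncol = length(unique(trio$fid)),
                        dimnames = list(NULL, unique(trio$fid)))
      for (i in seq_len(nrow(trio))) {
        ok <- .mendel_ok(geno[, trio$father[i]], geno[, trio$mother[i]],
                         geno[, trio$id[i]])
        if (!all(ok)) {
          geno[!ok, trio$id[i]] <- NA_integer_
          n_mendel_masked <- n_mendel_masked + sum(!ok)
          bad_fam[!ok, trio$fid[i]] <- TRUE
        }
      }
      n_bad_fams <- rowSums(bad_fam)
      keep <- n_bad_fams <= max_mendel_families
      n_mendel_removed <- sum(!keep)
    }
  }

  cr <- rowMeans(!is.na(geno))
  fail_cr <- keep & cr < call_rate_min
  n_cr <- sum(fail_cr)
  keep <- keep & !fail_cr

  founders <- ind$id[!(ind$father %in% ind$id) & !(ind$mother %in% ind$id)]
  founders <- intersect(founders, colnames(geno))
  n_hwe <- 0L
  if (length(founders) > 0) {
    fg <- geno[, founders, drop = FALSE]
    idx <- which(keep)
    hwe_p <- vapply(idx, function(i) {
      g <- fg[i, ]
      hwe_exact_test(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                     sum(g == 2, na.rm = TRUE))
    }, 1.0)
    fail_h <- idx[hwe_p < hwe_alpha]
    n_hwe <- length(fail_h)
    keep[fail_h] <- FALSE
  }

  if (!any(keep)) stop("no SNPs survive QC filtering")
  out <- genotype_matrix(gm$map[keep, , drop = FALSE],
                         geno[keep, , drop = FALSE])
  report <- structure(list(
    n_input = m0, n_retained = sum(keep),
    n_mendel_masked_calls = n_mendel_masked,
    n_removed_mendel = n_mendel_removed,
    n_removed_call_rate = n_cr,
    n_removed_hwe = n_hwe), class = "qc_report")
  list(gm = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC: ", x$n_input, " SNPs in, ", x$n_retained, " retained\n",
      "  removed: ", x$n_removed_mendel, " Mendelian, ",
      x$n_removed_call_rate, " call-rate, ", x$n_removed_hwe, " HWE\n",
      "  trio calls masked as missing: ", x$n_mendel_masked_calls, "\n",
      sep = "")
  invisible(x)
}

#' Remove SNPs with missing data in any calling-eligible family
#'
#' So that the same SNPs are evaluated in every family, a SNP is removed if
#' any member (either parent or any child) of any listed nuclear family has
#' a missing call there. The surviving SNP set is therefore identical across
#' families.
#'
#' @param gm a [genotype_matrix].
#' @param families list of nuclear families from
#'   [extract_nuclear_families()].
#' @return list with filtered `gm` and `removed_count`.
#' @export
filter_family_missing <- function(gm, families) {
  members <- unique(unlist(lapply(families, function(f)
    c(f$father, f$mother, f$children))))
  missing_members <- setdiff(members, colnames(gm$geno))
  if (length(missing_members))
    stop("family members not in genotype matrix: ",
         paste(missing_members, collapse = ", "))
  if (length(members) == 0)
    return(list(gm = gm, removed_count = 0L))
  any_na <- rowSums(is.na(gm$geno[, members, drop = FALSE])) > 0
  out <- genotype_matrix(gm$map[!any_na, , drop = FALSE],
                         gm$geno[!any_na, , drop = FALSE])
  list(gm = out, removed_count = sum(any_na))
}
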