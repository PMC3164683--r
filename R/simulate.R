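# Pedigree genotype simulator with fully known crossover truth and a
# configurable age-dependent recombination model.

#' Simulation configuration
#'
#' Defines the cohort and meiosis model for [simulate_cohort()]. Per
#' chromosome and sex, the expected crossover count for a meiosis at
#' parental age `a` is `max(0, base + slope * a)`, drawn as Poisson.
#' Defaults describe a desk-scale cohort of 40 three-child nuclear families
#' genotyped on 4 chromosomes of 2,000 SNPs each, with a maternal
#' genome-wide age slope of -0.5 crossovers/year split evenly across
#' chromosomes and no paternal age effect.
#'
#' @param n_families number of nuclear families.
#' @param n_children children per family: a single integer or a vector
#'   sampled from (one draw per family).
#' @param chrom_lengths_bp physical chromosome lengths.
#' @param snps_per_chrom markers simulated per chromosome.
#' @param maternal_base,maternal_slope per-chromosome intercept and slope
#'   (crossovers, crossovers/year) of the maternal expected count; recycled
#'   across chromosomes.
#' @param paternal_base,paternal_slope same for paternal meioses.
#' @param first_birth_mean,first_birth_sd mother's age at first birth,
#'   normal draw (years).
#' @param spacing_range inter-birth spacing, uniform draw (years).
#' @param father_age_offset_mean,father_age_offset_sd father's age minus
#'   mother's age, normal draw.
#' @param maf_range minor-allele frequencies, uniform draw per SNP.
#' @param genotyping_error_rate per-call probability of a code flip
#'   (single-step 0<->1, 2<->1, with rare 0<->2), generating the spurious
#'   tight double recombinants the pre-treatment targets.
#' @param missing_rate per-call missingness probability.
#' @param obligate_crossover force at least one crossover per meiosis per
#'   chromosome.
#' @param hotspots optional data.frame (`chrom`, `start`, `end`, 1-based
#'   closed) of hotspot intervals for hotspot-weighted placement.
#' @param hotspot_fraction fraction `h` of crossovers placed inside a
#'   (length-weighted) hotspot; the rest are uniform on the chromosome.
#' @param seed mandatory integer seed; identical seeds give identical
#'   cohorts.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_families = 40,
                       n_children = 3,
                       chrom_lengths_bp = rep(1.5e8, 4),
                       snps_per_chrom = 2000,
                       maternal_base = 6,
                       maternal_slope = -0.125,
                       paternal_base = 2,
                       paternal_slope = 0,
                       first_birth_mean = 26,
                       first_birth_sd = 4,
                       spacing_range = c(1.5, 3.5),
                       father_age_offset_mean = 2,
                       father_age_offset_sd = 2,
                       maf_range = c(0.1, 0.5),
                       genotyping_error_rate = 0,
                       missing_rate = 0,
                       obligate_crossover = FALSE,
                       hotspots = NULL,
                       hotspot_fraction = 0,
                       seed = 1L) {
  n_chrom <- length(chrom_lengths_bp)
  cfg <- list(
    n_families = as.integer(n_families),
    n_children = n_children,
    chrom_lengths_bp = chrom_lengths_bp,
    snps_per_chrom = rep_len(snps_per_chrom, n_chrom),
    maternal_base = rep_len(maternal_base, n_chrom),
    maternal_slope = rep_len(maternal_slope, n_chrom),
    paternal_base = rep_len(paternal_base, n_chrom),
    paternal_slope = rep_len(paternal_slope, n_chrom),
    first_birth_mean = first_birth_mean, first_birth_sd = first_birth_sd,
    spacing_range = spacing_range,
    father_age_offset_mean = father_age_offset_mean,
    father_age_offset_sd = father_age_offset_sd,
    maf_range = maf_range,
    genotyping_error_rate = genotyping_error_rate,
    missing_rate = missing_rate,
    obligate_crossover = isTRUE(obligate_crossover),
    hotspots = hotspots,
    hotspot_fraction = hotspot_fraction,
    seed = as.integer(seed))
  stopifnot(cfg$n_families >= 1, all(cfg$snps_per_chrom >= 1),
            genotyping_error_rate >= 0, genotyping_error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            hotspot_fraction >= 0, hotspot_fraction <= 1,
            length(cfg$seed) == 1, !is.na(cfg$seed))
  class(cfg) <- "sim_config"
  cfg
}

# One crossover-position draw for a meiosis on one chromosome.
.draw_xo_positions <- function(n_xo, len, hs, h) {
  if (n_xo == 0) return(numeric(0))
  pos <- stats::runif(n_xo, 1, len)
  if (!is.null(hs) && nrow(hs) > 0 && h > 0) {
    in_hot <- stats::runif(n_xo) < h
    if (any(in_hot)) {
      w <- hs$end - hs$start + 1
      pick <- sample.int(nrow(hs), sum(in_hot), replace = TRUE, prob = w)
      pos[in_hot] <- stats::runif(sum(in_hot), hs$start[pick], hs$end[pick])
    }
  }
  sort(pos)
}

# Recombine two parental haplotypes at given positions; the starting
# haplotype is chosen at random (Mendel's first law).
.make_gamete <- function(hap1, hap2, marker_pos, xo_pos) {
  start <- sample.int(2L, 1L)
  seg <- findInterval(marker_pos, xo_pos)  # 0..n_xo
  use1 <- (seg + start) %% 2L == 1L
  ifelse(use1, hap1, hap2)
}

#' Simulate a pedigree genotype cohort with known crossover truth
#'
#' Founder (parental) haplotypes are drawn from per-SNP allele frequencies;
#' each meiosis draws a Poisson crossover count per chromosome with mean
#' `max(0, base + slope * age)`, places crossovers (uniformly, or
#' hotspot-weighted), and transmits a mosaic gamete. Child genotypes are the
#' sum of the maternal and paternal gametes; genotyping errors and
#' missingness are then applied independently. All true crossover positions
#' and error locations are returned.
#'
#' @param cfg a [sim_config()].
#' @return list with `ped` ([pedigree], ages attached), `gm`
#'   ([genotype_matrix]), `truth` (data.frame `parent_id`, `child_id`,
#'   `chrom`, `pos_bp`, `age`), and `errors` (data.frame `snp`, `id` of
#'   flipped calls).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_chrom <- length(cfg$chrom_lengths_bp)

  # Marker map: sorted uniform positions, uniform MAFs.
  maps <- lapply(seq_len(n_chrom), function(cc) {
    m <- cfg$snps_per_chrom[cc]
    pos <- sort(sample.int(cfg$chrom_lengths_bp[cc] - 1L, m)) + 0
    data.frame(snp = sprintf("c%d_s%04d", cc, seq_len(m)),
               chrom = cc, pos = pos, allele_a = "A", allele_b = "B",
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, maps)
  m_tot <- nrow(map)
  maf <- stats::runif(m_tot, cfg$maf_range[1], cfg$maf_range[2])
  chrom_rows <- split(seq_len(m_tot), map$chrom)

  nf <- cfg$n_families
  nkid <- if (length(cfg$n_children) == 1) rep(cfg$n_children, nf) else
    sample(cfg$n_children, nf, replace = TRUE)

  geno_cols <- list(); fam_rows <- list()
  truth <- list(); ages_rows <- list()

  for (f in seq_len(nf)) {
    fid <- sprintf("F%03d", f)
    fa <- paste0(fid, "_P"); mo <- paste0(fid, "_M")
    kids <- sprintf("%s_C%d", fid, seq_len(nkid[f]))
    # Two haplotypes per parent
    hap <- list(
      fa = cbind(stats::rbinom(m_tot, 1, maf), stats::rbinom(m_tot, 1, maf)),
      mo = cbind(stats::rbinom(m_tot, 1, maf), stats::rbinom(m_tot, 1, maf)))
    geno_cols[[fa]] <- as.integer(hap$fa[, 1] + hap$fa[, 2])
    geno_cols[[mo]] <- as.integer(hap$mo[, 1] + hap$mo[, 2])

    mother_first <- stats::rnorm(1, cfg$first_birth_mean, cfg$first_birth_sd)
    mother_first <- max(mother_first, 16)
    father_off <- stats::rnorm(1, cfg$father_age_offset_mean,
                               cfg$father_age_offset_sd)
    spacing <- stats::runif(nkid[f], cfg$spacing_range[1], cfg$spacing_range[2])
    mo_ages <- mother_first + c(0, cumsum(spacing))[seq_len(nkid[f])]
    fa_ages <- mo_ages + father_off

    for (k in seq_len(nkid[f])) {
      child <- kids[k]
      g_child <- integer(m_tot)
      for (side in c("mo", "fa")) {
        age <- if (side == "mo") mo_ages[k] else fa_ages[k]
        base <- if (side == "mo") cfg$maternal_base else cfg$paternal_base
        slope <- if (side == "mo") cfg$maternal_slope else cfg$paternal_slope
        pid <- if (side == "mo") mo else fa
        for (cc in seq_len(n_chrom)) {
          rows <- chrom_rows[[cc]]
          lam <- max(0, base[cc] + slope[cc] * age)
          n_xo <- stats::rpois(1, lam)
          if (cfg$obligate_crossover) n_xo <- max(1L, n_xo)
          hs <- cfg$hotspots
          if (!is.null(hs)) hs <- hs[hs$chrom == cc, , drop = FALSE]
          xo <- .draw_xo_positions(n_xo, cfg$chrom_lengths_bp[cc], hs,
                                   cfg$hotspot_fraction)
          if (n_xo > 0)
            truth[[length(truth) + 1L]] <- data.frame(
              parent_id = pid, child_id = child, chrom = cc, pos_bp = xo,
              age = age, stringsAsFactors = FALSE)
          gam <- .make_gamete(hap[[side]][rows, 1], hap[[side]][rows, 2],
                              map$pos[rows], xo)
          g_child[rows] <- g_child[rows] + gam
        }
      }
      geno_cols[[child]] <- g_child
      ages_rows[[length(ages_rows) + 1L]] <- data.frame(
        family_id = fid,
        parent_id = c(mo, fa), child_id = child,
        age = c(mo_ages[k], fa_ages[k]),
        stringsAsFactors = FALSE)
    }
    # Current ages at study time: youngest child is 5-15, the rest follow
    # from the birth spacing so every parent has one consistent current age.
    ch_now <- (mo_ages[nkid[f]] + stats::runif(1, 5, 15)) - mo_ages
    fam_rows[[f]] <- data.frame(
      fid = fid,
      id = c(fa, mo, kids),
      father = c("0", "0", rep(fa, nkid[f])),
      mother = c("0", "0", rep(mo, nkid[f])),
      sex = c(1L, 2L, sample(1:2, nkid[f], replace = TRUE)),
      phen = -9L,
      child_now = c(NA, NA, ch_now),
      stringsAsFactors = FALSE)
  }

  geno <- do.call(cbind, geno_cols)
  rownames(geno) <- map$snp

  # Genotyping errors: symmetric single-step flips, rare double-step.
  err <- data.frame(snp = character(0), id = character(0),
                    stringsAsFactors = FALSE)
  if (cfg$genotyping_error_rate > 0) {
    hit <- which(matrix(stats::runif(length(geno)) <
                          cfg$genotyping_error_rate, nrow = nrow(geno)))
    if (length(hit)) {
      old <- geno[hit]
      new <- old
      u <- stats::runif(length(hit))
      new[old == 1] <- ifelse(u[old == 1] < 0.5, 0L, 2L)
      hom <- old != 1
      new[hom] <- ifelse(u[hom] < 0.95, 1L, 2L - old[hom])
      geno[hit] <- new
      err <- data.frame(
        snp = rownames(geno)[(hit - 1) %% nrow(geno) + 1],
        id = colnames(geno)[(hit - 1) %/% nrow(geno) + 1],
        stringsAsFactors = FALSE)
    }
  }
  if (cfg$missing_rate > 0)
    geno[matrix(stats::runif(length(geno)) < cfg$missing_rate,
                nrow = nrow(geno))] <- NA_integer_

  fam <- do.call(rbind, fam_rows)
  ages <- do.call(rbind, ages_rows)
  # Current ages support round_ages(): parent_age = age at birth + child_age.
  child_now <- stats::setNames(fam$child_now, fam$id)
  ages$child_age <- unname(child_now[ages$child_id])
  ages$parent_age <- ages$age + ages$child_age
  fam$child_now <- NULL

  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(parent_id = character(0), child_id = character(0),
               chrom = integer(0), pos_bp = numeric(0), age = numeric(0))
  list(ped = pedigree(fam, ages),
       gm = genotype_matrix(map, geno),
       truth = truth, errors = err)
}

#' Write / read a crossover truth table
#'
#' TSV with one row per true crossover (`parent_id`, `child_id`, `chrom`,
#' `pos_bp`, `age`); an empty truth table writes a header-only file.
#'
#' @param truth truth data.frame from [simulate_cohort()].
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Randomly thin markers
#'
#' Each SNP is retained independently with probability `fraction`, so the
#' expected retained fraction equals `fraction` (matching PLINK's `--thin`).
#'
#' @param gm a [genotype_matrix].
#' @param fraction retention probability in (0, 1].
#' @param seed integer seed; the same seed selects the same subset.
#' @return thinned [genotype_matrix].
#' @export
thin_markers <- function(gm, fraction, seed = NULL) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  if (fraction == 1) return(gm)
  if (!is.null(seed)) set.seed(seed)
  keep <- stats::runif(nrow(gm$geno)) < fraction
  if (!any(keep)) stop("thinning removed every marker")
  genotype_matrix(gm$map[keep, , drop = FALSE], gm$geno[keep, , drop = FALSE])
}

#' Round ages up to a multiple and recompute ages at birth
#'
#' Emulates studies where individual ages are only known to coarse
#' precision: both the parent's and the child's current ages are rounded up
#' to the nearest `multiple` years and the parental age at birth is
#' recomputed as their difference. Rounding never decreases an age.
#'
#' @param ages ages data.frame with `parent_age` and `child_age` columns
#'   (current ages), as produced by [simulate_cohort()].
#' @param multiple rounding step in years (default 5).
#' @return ages data.frame with `age` replaced by the coarsened value.
#' @export
round_ages <- function(ages, multiple = 5) {
  if (!all(c("parent_age", "child_age") %in% names(ages)))
    stop("ages table lacks current-age columns parent_age/child_age")
  up <- function(x) ceiling(x / multiple) * multiple
  ages$age <- up(ages$parent_age) - up(ages$child_age)
  ages
}
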