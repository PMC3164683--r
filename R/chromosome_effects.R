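# Per-chromosome age-group shift tests, count normalization, and the
# redistribution simulations calibrating how many chromosomes should reach
# significance by chance under a purely genome-wide effect.

#' Normalize per-chromosome counts by cohort chromosome means
#'
#' Divides each transmission's count on a chromosome by the cohort mean
#' count for that chromosome, so every chromosome has mean 1 and shifts
#' are comparable across chromosomes of different genetic lengths.
#'
#' @param counts matrix of counts, transmissions x chromosomes.
#' @return matrix of normalized counts.
#' @export
normalize_counts <- function(counts) {
  stopifnot(is.matrix(counts))
  mu <- colMeans(counts)
  if (any(mu == 0)) stop("chromosome(s) with zero mean count: ",
                         paste(which(mu == 0), collapse = ", "))
  sweep(counts, 2, mu, "/")
}

# Vectorized one-sided (decrease) permutation shift test: for each column
# of C, statistic = mean(old) - mean(young); null by permuting the old/young
# labels. Returns observed deltas and p-values.
.shift_test_matrix <- function(C, old, n_perm, seed = NULL,
                               alternative = "less") {
  if (!is.null(seed)) set.seed(seed)
  C <- as.matrix(C)
  n <- nrow(C); k_old <- sum(old)
  if (k_old == 0 || k_old == n) stop("one age group is empty")
  tot <- colSums(C)
  obs_old <- colSums(C[old, , drop = FALSE]) / k_old
  obs_young <- (tot - obs_old * k_old) / (n - k_old)
  obs <- obs_old - obs_young
  L <- matrix(0, n, n_perm)
  for (j in seq_len(n_perm)) L[sample.int(n, k_old), j] <- 1
  old_sums <- crossprod(L, C)                      # n_perm x ncol
  null <- old_sums / k_old -
    sweep(-old_sums, 2, tot, "+") / (n - k_old)    # delta per perm
  p <- vapply(seq_len(ncol(C)), function(cc)
    .perm_pvalue(obs[cc], null[, cc], alternative), 1.0)
  list(delta = obs, mean_old = obs_old, mean_young = obs_young, p = p)
}

#' Age-group shift test for one chromosome
#'
#' Splits transmissions into mothers under 30 and 30-or-over (the age
#' threshold is inclusive on the old side: a parent of exactly 30 is in
#' the over-30 group) and tests whether the mean count shifted between the
#' groups, by permuting the group labels across transmissions. The default
#' alternative is one-sided for a decrease in the older group.
#'
#' @param counts per-transmission counts for the chromosome (raw or
#'   normalized).
#' @param ages parental ages at birth.
#' @param threshold age cut (default 30; `age >= threshold` is "old").
#' @param n_perm label permutations.
#' @param seed optional seed.
#' @param alternative `"less"` (decrease with age, default), `"greater"`,
#'   or `"two_sided"`.
#' @return list of class `shift_result`: `mean_young`, `mean_old`, `delta`
#'   (`mean_old - mean_young`), `se_young`, `se_old`, `n_young`, `n_old`,
#'   `p_perm`.
#' @export
age_group_shift <- function(counts, ages, threshold = 30, n_perm = 10000,
                            seed = NULL,
                            alternative = c("less", "greater", "two_sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(counts) == length(ages))
  old <- ages >= threshold
  if (!any(old) || all(old)) stop("both age groups must be non-empty")
  st <- .shift_test_matrix(matrix(counts, ncol = 1), old, n_perm, seed,
                           alternative)
  sefun <- function(v) stats::sd(v) / sqrt(length(v))
  structure(list(mean_young = st$mean_young[1], mean_old = st$mean_old[1],
                 delta = st$delta[1],
                 se_young = sefun(counts[!old]), se_old = sefun(counts[old]),
                 n_young = sum(!old), n_old = sum(old),
                 threshold = threshold, p_perm = st$p[1]),
            class = "shift_result")
}

#' @export
print.shift_result <- function(x, ...) {
  cat(sprintf(
    "shift: mean <%g = %.3f (n=%d), mean >=%g = %.3f (n=%d), delta = %.3f, p_perm = %.4g\n",
    x$threshold, x$mean_young, x$n_young, x$threshold, x$mean_old, x$n_old,
    x$delta, x$p_perm))
  invisible(x)
}

#' Shift tests for all chromosomes at once
#'
#' Convenience wrapper running the one-sided age-group shift test on every
#' column of a transmissions x chromosomes count matrix (typically
#' normalized), reusing one set of label permutations across chromosomes.
#'
#' @inheritParams age_group_shift
#' @param counts transmissions x chromosomes matrix.
#' @return data.frame with one row per chromosome: means, `delta`, `p_perm`.
#' @export
chromosome_shift_tests <- function(counts, ages, threshold = 30,
                                   n_perm = 10000, seed = NULL,
                                   alternative = c("less", "greater",
                                                   "two_sided")) {
  alternative <- match.arg(alternative)
  old <- ages >= threshold
  st <- .shift_test_matrix(counts, old, n_perm, seed, alternative)
  data.frame(chrom = if (!is.null(colnames(counts)))
    colnames(counts) else seq_len(ncol(counts)),
    mean_young = st$mean_young, mean_old = st$mean_old,
    delta = st$delta, p_perm = st$p, row.names = NULL)
}

#' Redistribution simulation of per-chromosome significance counts
#'
#' Under the null that an age effect is shared genome-wide rather than
#' chromosome-specific, each transmission's total count is reallocated
#' across chromosomes by a multinomial draw -- with probabilities
#' proportional to the cohort per-chromosome means (`proportional`) or
#' equal (`uniform`) -- and the per-chromosome shift tests are rerun. The
#' distribution of the number of significant chromosomes calibrates how
#' many would be expected by chance given the genome-wide effect.
#'
#' @param counts transmissions x chromosomes count matrix (raw).
#' @param ages parental ages at birth.
#' @param mode `"proportional"` or `"uniform"` reallocation.
#' @param n_sim number of simulated cohorts.
#' @param alpha per-chromosome significance level.
#' @param n_perm label permutations inside each shift test.
#' @param threshold age-group cut (default 30).
#' @param normalize run the shift tests on normalized counts.
#' @param observed_significant optionally, the observed number of
#'   significant chromosomes; when given, a one-tailed
#'   `P(simulated >= observed)` is returned.
#' @param seed optional seed.
#' @return list with `n_significant` (vector over simulations), `expected`
#'   (its mean), and `p_observed` (or NA).
#' @export
redistribute_simulation <- function(counts, ages,
                                    mode = c("proportional", "uniform"),
                                    n_sim = 1000, alpha = 0.05,
                                    n_perm = 199, threshold = 30,
                                    normalize = TRUE,
                                    observed_significant = NULL,
                                    seed = NULL) {
  mode <- match.arg(mode)
  if (n_sim < 100) warning("n_sim < 100 gives a coarse calibration")
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is.matrix(counts), nrow(counts) == length(ages))
  n_chrom <- ncol(counts)
  totals <- rowSums(counts)
  prob <- if (mode == "proportional") colMeans(counts) / sum(colMeans(counts))
          else rep(1 / n_chrom, n_chrom)
  old <- ages >= threshold
  n_sig <- integer(n_sim)
  for (s in seq_len(n_sim)) {
    sim <- t(vapply(totals, function(tt)
      as.numeric(stats::rmultinom(1, tt, prob)), numeric(n_chrom)))
    stopifnot(all(rowSums(sim) == totals))
    simn <- if (normalize) {
      mu <- colMeans(sim)
      mu[mu == 0] <- 1    # empty chromosome: counts are all zero anyway
      sweep(sim, 2, mu, "/")
    } else sim
    st <- .shift_test_matrix(simn, old, n_perm, alternative = "less")
    n_sig[s] <- sum(st$p <= alpha)
  }
  p_obs <- if (is.null(observed_significant)) NA_real_ else
    (sum(n_sig >= observed_significant) + 1) / (n_sim + 1)
  list(n_significant = n_sig, expected = mean(n_sig), p_observed = p_obs,
       mode = mode, alpha = alpha)
}

#' Compare mean shifts between two chromosome groups
#'
#' Tests whether the mean (normalized) age-group shift of one set of
#' chromosomes differs from that of another, by permuting chromosome group
#' membership. One-tailed by default: the alternative is that group A's
#' shift is more negative (a stronger decrease) than group B's.
#'
#' @param shifts named vector of per-chromosome shifts (`delta` from
#'   [chromosome_shift_tests()]).
#' @param group_a,group_b disjoint chromosome name/index sets.
#' @param n_perm membership permutations.
#' @param seed optional seed.
#' @return list with `statistic` (`mean(shift_a) - mean(shift_b)`) and the
#'   one-tailed `p`.
#' @export
compare_shift_groups <- function(shifts, group_a, group_b, n_perm = 10000,
                                 seed = NULL) {
  if (length(intersect(group_a, group_b)) > 0)
    stop("chromosome groups must be disjoint")
  a <- shifts[group_a]; b <- shifts[group_b]
  if (anyNA(a) || anyNA(b)) stop("unknown chromosome in group")
  obs <- mean(a) - mean(b)
  pool <- c(a, b); na <- length(a)
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_perm), function(j) {
    idx <- sample.int(length(pool), na)
    mean(pool[idx]) - mean(pool[-idx])
  }, 1.0)
  list(statistic = obs, p = .perm_pvalue(obs, null, "less"))
}

#' Enrichment of a chromosome class among significant chromosomes
#'
#' Hypergeometric test of whether chromosomes of a given structural class
#' (e.g. submetacentric) are overrepresented among the significant set,
#' for a user-supplied classification. Chromosome structural classes vary
#' between sources, so no classification table ships with the package.
#'
#' @param significant chromosome ids found significant.
#' @param class_members chromosome ids belonging to the class.
#' @param all_chroms all chromosome ids considered (default 1-22).
#' @return one-sided hypergeometric p-value for enrichment.
#' @export
chromosome_class_enrichment <- function(significant, class_members,
                                        all_chroms = 1:22) {
  stopifnot(all(significant %in% all_chroms),
            all(class_members %in% all_chroms))
  q <- length(intersect(significant, class_members))
  stats::phyper(q - 1, length(class_members),
                length(all_chroms) - length(class_members),
                length(significant), lower.tail = FALSE)
}
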