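# End-to-end orchestration: simulate (or read) -> QC -> family-missingness
# filter -> crossover calling -> maternal-age statistics, with seeded
# determinism, filter-count bookkeeping and file outputs; plus the
# marker-thinning / age-rounding power recipes and family-level resampling.

#' Run the full pipeline
#'
#' Executes the enabled stages in order and writes the report bundle to
#' `out_dir`: the called events (`events.bed`), per-transmission records
#' (`records.tsv`), a JSON stats report (`stats.json`) and a run log with
#' the SNP counts at every filter. Identical configurations (including
#' `seed`) produce identical output bytes.
#'
#' @param config a list, or path to a YAML file, with elements:
#'   \describe{
#'     \item{`seed`}{integer; seeds every stochastic stage.}
#'     \item{`out_dir`}{output directory (created if needed); `NULL` skips
#'       file output.}
#'     \item{`simulate`}{list of [sim_config()] arguments, or `NULL` to
#'       read data instead;}
#'     \item{`input`}{list with `prefix` (PLINK fileset) and `ages` (TSV
#'       path), used when `simulate` is `NULL`;}
#'     \item{`qc`}{`list(enabled=, call_rate_min=, hwe_alpha=)`;}
#'     \item{`family_missing`}{`list(enabled=)`;}
#'     \item{`call`}{`list(window_bp=, unique_only=, min_children=)`;}
#'     \item{`stats`}{`list(n_perm=)` for the family-adjusted regression.}
#'   }
#' @return list (invisibly) with `gm`, `ped`, `counts` (records /
#'   per-chromosome / events), `regression`, `log` (character lines),
#'   `filter_counts`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    seed = 1L, out_dir = NULL, simulate = list(), input = NULL,
    qc = list(enabled = TRUE, call_rate_min = 0.95, hwe_alpha = 0.01),
    family_missing = list(enabled = TRUE),
    call = list(window_bp = 1e6, unique_only = TRUE, min_children = 2),
    stats = list(n_perm = 1000)), config)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  if (!is.null(cfg$simulate)) {
    sim_args <- utils::modifyList(list(seed = cfg$seed), cfg$simulate)
    sim <- simulate_cohort(do.call(sim_config, sim_args))
    gm <- sim$gm; ped <- sim$ped
    say("simulate: %d SNPs x %d individuals", nrow(gm$geno), ncol(gm$geno))
  } else {
    if (is.null(cfg$input)) stop("config needs either 'simulate' or 'input'")
    pl <- read_plink(cfg$input$prefix)
    gm <- pl$gm; ped <- pl$ped
    if (!is.null(cfg$input$ages)) ped$ages <- read_ages(cfg$input$ages)
    say("input: %d SNPs x %d individuals from %s",
        nrow(gm$geno), ncol(gm$geno), cfg$input$prefix)
  }

  n_in <- nrow(gm$geno)
  filter_counts <- list(snps_in = n_in)
  if (isTRUE(cfg$qc$enabled)) {
    qc <- qc_filter(gm, ped, call_rate_min = cfg$qc$call_rate_min,
                    hwe_alpha = cfg$qc$hwe_alpha)
    gm <- qc$gm
    filter_counts$removed_qc <- n_in - nrow(gm$geno)
    say("qc: removed %d (%d mendel, %d call-rate, %d hwe); %d retained",
        filter_counts$removed_qc, qc$report$n_removed_mendel,
        qc$report$n_removed_call_rate, qc$report$n_removed_hwe,
        nrow(gm$geno))
  } else filter_counts$removed_qc <- 0L

  families <- extract_nuclear_families(ped, gm,
                                       min_children = cfg$call$min_children)
  say("families: %d nuclear families eligible for calling", length(families))
  if (isTRUE(cfg$family_missing$enabled)) {
    fm <- filter_family_missing(gm, families)
    gm <- fm$gm
    filter_counts$removed_family_missing <- fm$removed_count
    say("family-missingness: removed %d SNPs; %d retained",
        fm$removed_count, nrow(gm$geno))
  } else filter_counts$removed_family_missing <- 0L
  filter_counts$snps_retained <- nrow(gm$geno)

  counts <- count_transmissions(gm, ped, families,
                                window_bp = cfg$call$window_bp,
                                unique_only = cfg$call$unique_only)
  say("calling: %d events, %d transmission records",
      nrow(counts$events),
      if (is.null(counts$records)) 0L else nrow(counts$records))

  regression <- NULL
  mat <- counts$records[counts$records$parent == "mother", , drop = FALSE]
  if (!is.null(mat) && nrow(mat) >= 3 && !anyNA(mat$age)) {
    set.seed(cfg$seed + 1L)
    regression <- adjusted_regression(mat$total, mat$age, mat$parent_id,
                                      n_perm = cfg$stats$n_perm)
    say("maternal age effect: beta = %.4f, r = %.4f, p_perm = %s",
        regression$beta, regression$pearson_r, format(regression$p_perm))
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_events_bed(counts$events, file.path(cfg$out_dir, "events.bed"))
    if (!is.null(counts$records))
      utils::write.table(counts$records,
                         file.path(cfg$out_dir, "records.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    rep_json <- list(filter_counts = filter_counts,
                     regression = if (is.null(regression)) NULL else
                       regression[c("beta", "se", "pearson_r", "r_squared",
                                    "p_param", "p_perm", "n")])
    jsonlite::write_json(rep_json, file.path(cfg$out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log, file.path(cfg$out_dir, "run.log"))
  }
  invisible(list(gm = gm, ped = ped, counts = counts,
                 regression = regression, log = log,
                 filter_counts = filter_counts))
}

#' Marker-thinning and age-rounding power analysis
#'
#' Quantifies how marker density and coarsened ages attenuate a detected
#' age effect: for each thinning fraction and replicate, markers are
#' randomly thinned, crossovers re-called, and the family-adjusted
#' regression re-evaluated (optionally with ages rounded up to 5-year
#' multiples, in which case the categorical ANOVA is also reported).
#' A fraction of 1 reproduces the base analysis.
#'
#' @param gm,ped genotypes and pedigree (with ages) of the base dataset.
#' @param thin_fractions marker retention fractions.
#' @param n_reps replicates per fraction.
#' @param round_ages_flag evaluate with ages rounded up to 5-year
#'   multiples.
#' @param window_bp,unique_only caller settings.
#' @param n_perm permutations for each regression p-value.
#' @param seed integer seed.
#' @return data.frame per (fraction, replicate): `beta`, `p_perm`,
#'   `pearson_r`, `n` and, when rounding, `anova_p_perm`.
#' @export
power_analysis <- function(gm, ped,
                           thin_fractions = c(0.8, 0.4, 0.3, 0.2, 0.05),
                           n_reps = 4, round_ages_flag = FALSE,
                           window_bp = 1e6, unique_only = TRUE,
                           n_perm = 1000, seed = 1L) {
  if (!length(thin_fractions)) stop("thin_fractions must be non-empty")
  set.seed(seed)
  ped_use <- ped
  if (round_ages_flag) ped_use$ages <- round_ages(ped$ages)
  out <- list()
  for (fr in thin_fractions) {
    for (rep_i in seq_len(n_reps)) {
      gm_t <- thin_markers(gm, fr)
      counts <- count_transmissions(gm_t, ped_use, window_bp = window_bp,
                                    unique_only = unique_only)
      mat <- counts$records[counts$records$parent == "mother", , drop = FALSE]
      row <- data.frame(fraction = fr, rep = rep_i, beta = NA_real_,
                        pearson_r = NA_real_, p_perm = NA_real_,
                        n = if (is.null(mat)) 0L else nrow(mat))
      if (!is.null(mat) && nrow(mat) >= 3) {
        reg <- adjusted_regression(mat$total, mat$age, mat$parent_id,
                                   n_perm = n_perm)
        row$beta <- reg$beta; row$pearson_r <- reg$pearson_r
        row$p_perm <- reg$p_perm
        if (round_ages_flag) {
          act <- age_category_tests(mat$total, mat$age, n_perm = n_perm)
          row$anova_p_perm <- act$anova_p_perm
        }
      }
      out[[length(out) + 1L]] <- row
      if (fr == 1) break  # thinning at 1 is deterministic: one replicate
    }
  }
  do.call(rbind, out)
}

#' Bootstrap over families
#'
#' Resamples whole families (not transmissions) with replacement, so the
#' within-family correlation of counts is respected, and returns the
#' percentile confidence interval of any statistic of the records.
#'
#' @param records transmission records data.frame with a `family` column.
#' @param statistic function of a records data.frame returning a scalar.
#' @param n_boot bootstrap replicates.
#' @param conf confidence level (default 0.95).
#' @param seed optional seed.
#' @return list with `estimate`, `ci` (length 2), and the vector of
#'   bootstrap `replicates`.
#' @export
bootstrap_families <- function(records, statistic, n_boot = 1000,
                               conf = 0.95, seed = NULL) {
  fams <- unique(records$family)
  if (length(fams) < 2) warning("fewer than two families to resample")
  if (!is.null(seed)) set.seed(seed)
  by_fam <- split(records, records$family)
  boot <- vapply(seq_len(n_boot), function(b) {
    pick <- sample(fams, length(fams), replace = TRUE)
    statistic(do.call(rbind, by_fam[pick]))
  }, 1.0)
  alpha <- (1 - conf) / 2
  list(estimate = statistic(records),
       ci = unname(stats::quantile(boot, c(alpha, 1 - alpha))),
       replicates = boot)
}

#' Leave-one-family-out jackknife
#'
#' @inheritParams bootstrap_families
#' @return data.frame with the family left out and the statistic.
#' @export
jackknife_families <- function(records, statistic) {
  fams <- unique(records$family)
  out <- vapply(fams, function(f)
    statistic(records[records$family != f, , drop = FALSE]), 1.0)
  data.frame(left_out = fams, statistic = out, row.names = NULL)
}
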