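# Statistics for the effect of parental age at birth on crossover counts:
# family-adjusted regression, random-intercept mixed model, penalized
# linear spline fitted by REML, rank statistics, categorical age analyses,
# closed-form binomial tests, and the permutation machinery behind their
# p-values.

# ---- permutation engine ----------------------------------------------------

.perm_pvalue <- function(obs, null, alternative) {
  eps <- 1e-12 * max(1, abs(obs))
  b <- switch(alternative,
    two_sided = sum(abs(null) >= abs(obs) - eps),
    less = sum(null <= obs + eps),
    greater = sum(null >= obs - eps))
  (b + 1) / (length(null) + 1)
}

# Permutation of indices within groups (identity for singleton groups).
.perm_within <- function(groups) {
  idx <- seq_along(groups)
  for (g in split(idx, groups)) {
    if (length(g) > 1) idx[g] <- g[sample.int(length(g))]
  }
  idx
}

#' Permutation test of a statistic over transmission records
#'
#' Computes `statistic(data)` on the observed records and on `n_perm`
#' permuted datasets, and returns the add-one p-value
#' `(b + 1) / (n_perm + 1)` where `b` counts permuted statistics at least
#' as extreme as the observed one. The permutation `scheme` sets the
#' exchangeability unit:
#' \describe{
#'   \item{`across_transmissions`}{maternal/paternal age permuted across
#'     all transmissions;}
#'   \item{`within_family`}{age permuted only among transmissions of the
#'     same mother (for family-adjusted analyses);}
#'   \item{`child_reassignment`}{counts permuted across transmissions,
#'     i.e. children randomly reassigned to parents without modifying
#'     family sizes (for among-parent variation tests).}
#' }
#'
#' @param data data.frame of transmission records; must contain `age` for
#'   the age-permuting schemes (plus `mother` for `within_family`) and
#'   `count` for `child_reassignment`.
#' @param statistic function of `data` returning a scalar.
#' @param scheme permutation scheme, see above.
#' @param n_perm number of permutations (default 10000).
#' @param seed optional integer seed.
#' @param alternative `"two_sided"` (extremeness by absolute value),
#'   `"less"` or `"greater"`.
#' @return list with `p`, `observed`, and the vector of `null` statistics.
#' @export
permutation_test <- function(data, statistic,
                             scheme = c("across_transmissions",
                                        "within_family",
                                        "child_reassignment"),
                             n_perm = 10000, seed = NULL,
                             alternative = c("two_sided", "less", "greater")) {
  scheme <- match.arg(scheme)
  alternative <- match.arg(alternative)
  if (!is.null(seed)) set.seed(seed)
  obs <- statistic(data)
  null <- vapply(seq_len(n_perm), function(j) {
    d <- data
    if (scheme == "across_transmissions") {
      d$age <- d$age[sample.int(nrow(d))]
    } else if (scheme == "within_family") {
      d$age <- d$age[.perm_within(d$mother)]
    } else {
      d$count <- d$count[sample.int(nrow(d))]
    }
    statistic(d)
  }, 1.0)
  list(p = .perm_pvalue(obs, null, alternative), observed = obs, null = null)
}

# ---- family adjustment and regression -------------------------------------

#' Family-adjusted values
#'
#' Subtracts from each value the mean over all values of its group
#' (typically all children of one mother), removing between-mother
#' differences so that age effects are evaluated within families. The
#' adjustment is a projection: group means of adjusted values are zero and
#' applying it twice equals applying it once.
#'
#' @param values numeric vector.
#' @param groups grouping vector (e.g. mother id), same length.
#' @return numeric vector of adjusted values.
#' @export
family_adjust <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  values - stats::ave(values, groups, FUN = mean)
}

#' Family-adjusted linear regression of counts on age
#'
#' Ordinary least squares of family-adjusted crossover counts on
#' family-adjusted parental age at birth, with the Pearson correlation and
#' both a parametric and a within-family permutation p-value. Because both
#' variables are centered within mothers, the detected effect cannot be
#' driven by differences among mothers.
#'
#' @param counts crossover counts per transmission.
#' @param ages parental ages at birth.
#' @param groups mother (or family) id per transmission.
#' @param n_perm within-family permutations for `p_perm` (0 to skip).
#' @param seed optional seed.
#' @param alternative extremeness rule for the permutation p-value.
#' @return list of class `adjusted_regression`: `beta` (crossovers/year),
#'   `intercept`, `se`, `pearson_r`, `r_squared`, `p_param`, `p_perm`, `n`,
#'   `degenerate` flag (TRUE when the response has zero variance, in which
#'   case `pearson_r` is reported as 0).
#' @export
adjusted_regression <- function(counts, ages, groups, n_perm = 10000,
                                seed = NULL,
                                alternative = c("two_sided", "less",
                                                "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(counts) == length(ages), length(ages) == length(groups))
  y <- family_adjust(counts, groups)
  x <- family_adjust(ages, groups)
  sxx <- sum(x^2)
  if (sxx == 0)
    stop("all groups are singletons (or ages constant within families): ",
         "family-adjusted regression is degenerate")
  n <- length(y)
  beta <- sum(x * y) / sxx
  degenerate <- stats::sd(y) == 0
  r <- if (degenerate) 0 else stats::cor(x, y)
  resid <- y - beta * x
  se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  p_param <- if (degenerate) 1 else
    2 * stats::pt(-abs(beta / se), df = n - 2)
  p_perm <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    null <- vapply(seq_len(n_perm), function(j) {
      xp <- x[.perm_within(groups)]
      sum(xp * y) / sxx
    }, 1.0)
    p_perm <- .perm_pvalue(beta, null, alternative)
  }
  structure(list(beta = beta, intercept = 0, se = se, pearson_r = r,
                 r_squared = r^2, p_param = p_param, p_perm = p_perm,
                 n = n, degenerate = degenerate),
            class = "adjusted_regression")
}

#' @export
print.adjusted_regression <- function(x, ...) {
  cat(sprintf(
    "family-adjusted regression: beta = %.3f crossovers/year (se %.3f), r = %.3f, p_param = %.3g, p_perm = %s, n = %d\n",
    x$beta, x$se, x$pearson_r, x$p_param, format(x$p_perm), x$n))
  invisible(x)
}

#' Mixed model of counts on age with a mother random intercept
#'
#' Fits `count = b0 + b_age * age (+ b_nc * n_children) + u_mother + e` by
#' REML, allowing for correlated recombination counts within a mother. The
#' number of children of the mother can be added as a covariate to adjust
#' for the selection of high-recombination oocytes in large families. The
#' permutation p-value permutes ages across transmissions and refits.
#'
#' @inheritParams adjusted_regression
#' @param mothers mother id per transmission.
#' @param n_children_covariate add the mother's number of transmissions as
#'   a covariate.
#' @param n_perm permutations for `p_perm` (0 to skip; refitting is
#'   moderately expensive).
#' @return list of class `mixed_model_result`: `beta_age`, `se`,
#'   `beta_n_children` (or NA), `var_mother`, `var_resid`, `p_param`
#'   (normal approximation on t), `p_perm`, `n`, `converged`.
#' @export
mixed_model <- function(counts, ages, mothers, n_children_covariate = FALSE,
                        n_perm = 0, seed = NULL,
                        alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(unique(mothers)) < 2) stop("need at least two mothers")
  df <- data.frame(count = counts, age = ages,
                   mother = as.factor(mothers))
  df$nc <- stats::ave(df$count, df$mother, FUN = length)
  if (n_children_covariate && stats::var(df$nc) == 0) {
    warning("number of children is constant across mothers; covariate dropped")
    n_children_covariate <- FALSE
  }
  form <- if (n_children_covariate)
    count ~ age + nc + (1 | mother) else count ~ age + (1 | mother)
  fit_one <- function(d) {
    suppressMessages(suppressWarnings(
      lme4::lmer(form, data = d, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular =
                   lme4::.makeCC(action = "ignore", tol = 1e-4)))))
  }
  fit <- tryCatch(fit_one(df), error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(beta_age = NA_real_, se = NA_real_,
                          beta_n_children = NA_real_, var_mother = NA_real_,
                          var_resid = NA_real_, p_param = NA_real_,
                          p_perm = NA_real_, n = nrow(df), converged = FALSE,
                          message = conditionMessage(fit)),
                     class = "mixed_model_result"))
  }
  co <- summary(fit)$coefficients
  beta_age <- co["age", "Estimate"]; se <- co["age", "Std. Error"]
  vc <- lme4::VarCorr(fit)
  var_mother <- as.numeric(vc$mother[1])
  var_resid <- attr(vc, "sc")^2
  p_param <- 2 * stats::pnorm(-abs(co["age", "t value"]))
  p_perm <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    null <- vapply(seq_len(n_perm), function(j) {
      d <- df; d$age <- d$age[sample.int(nrow(d))]
      f <- tryCatch(fit_one(d), error = function(e) NULL)
      if (is.null(f)) return(NA_real_)
      lme4::fixef(f)[["age"]]
    }, 1.0)
    p_perm <- .perm_pvalue(beta_age, null[!is.na(null)], alternative)
  }
  structure(list(
    beta_age = beta_age, se = se,
    beta_n_children = if (n_children_covariate)
      co["nc", "Estimate"] else NA_real_,
    var_mother = var_mother, var_resid = var_resid,
    p_param = p_param, p_perm = p_perm, n = nrow(df), converged = TRUE),
    class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf(
    "mixed model: beta_age = %.3f (se %.3f), var_mother = %.3f, var_resid = %.3f, p_param = %.3g, n = %d%s\n",
    x$beta_age, x$se, x$var_mother, x$var_resid, x$p_param, x$n,
    if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

# ---- penalized linear spline ----------------------------------------------

#' Penalized linear spline via its mixed-model representation
#'
#' Fits `count = b0 + b1 * age + sum_j u_j (age - knot_j)_+ + m_mother + e`
#' with truncated-line basis functions at each distinct age, the spline
#' coefficients `u_j` treated as i.i.d. random effects with common variance
#' and a mother random intercept, all variances estimated by REML. The
#' smoothing parameter is reported as `lambda = var_resid / var_spline`;
#' large `lambda` shrinks the fit to the linear mixed model.
#'
#' @inheritParams mixed_model
#' @param n_perm permutations (ages across transmissions) for the test of
#'   improvement over the linear fit; the statistic is the REML likelihood
#'   ratio between the spline and linear models (0 to skip).
#' @return list of class `spline_fit`: `knots`, `beta` (intercept, linear),
#'   `u` (spline BLUPs), `lambda`, `var_spline`, `var_mother`, `var_resid`,
#'   `fitted` (population-level), `p_vs_linear`, `converged`.
#' @export
spline_fit <- function(counts, ages, mothers, n_perm = 0, seed = NULL) {
  if (length(unique(ages)) < 4) stop("need at least 4 distinct ages")
  df <- data.frame(count = counts, age = ages, mother = as.factor(mothers),
                   all = factor(rep(1, length(counts))))
  knots <- sort(unique(ages))
  knots <- knots[-length(knots)]  # (age - max)_+ is identically zero
  Z <- outer(df$age, knots, function(a, k) pmax(a - k, 0))
  colnames(Z) <- paste0("k", seq_along(knots))
  df$Z <- Z
  fit_pair <- function(d) {
    sp <- nlme::lme(count ~ age, data = d,
                    random = list(all = nlme::pdIdent(~ Z - 1),
                                  mother = ~1),
                    method = "REML",
                    control = nlme::lmeControl(returnObject = TRUE))
    ln <- nlme::lme(count ~ age, data = d, random = ~ 1 | mother,
                    method = "REML",
                    control = nlme::lmeControl(returnObject = TRUE))
    list(sp = sp, ln = ln,
         lrt = 2 * (as.numeric(stats::logLik(sp)) -
                      as.numeric(stats::logLik(ln))))
  }
  fits <- tryCatch(fit_pair(df), error = function(e) e)
  if (inherits(fits, "error"))
    return(structure(list(knots = knots, beta = c(NA, NA), u = NULL,
                          lambda = NA_real_, var_spline = NA_real_,
                          var_mother = NA_real_, var_resid = NA_real_,
                          fitted = NULL, p_vs_linear = NA_real_,
                          converged = FALSE,
                          message = conditionMessage(fits)),
                     class = "spline_fit"))
  sp <- fits$sp
  sig2 <- sp$sigma^2
  rel_spline <- nlme::pdMatrix(sp$modelStruct$reStruct$all)[1, 1]
  rel_mother <- nlme::pdMatrix(sp$modelStruct$reStruct$mother)[1, 1]
  var_spline <- rel_spline * sig2
  var_mother <- rel_mother * sig2
  lambda <- if (var_spline > 0) sig2 / var_spline else Inf
  beta <- nlme::fixef(sp)
  u <- as.numeric(nlme::ranef(sp)$all[1, ])
  p_vs_linear <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    null <- vapply(seq_len(n_perm), function(j) {
      d <- df
      idx <- sample.int(nrow(d))
      d$age <- d$age[idx]; d$Z <- d$Z[idx, , drop = FALSE]
      tryCatch(fit_pair(d)$lrt, error = function(e) NA_real_)
    }, 1.0)
    p_vs_linear <- .perm_pvalue(fits$lrt, null[!is.na(null)], "greater")
  }
  structure(list(knots = knots, beta = beta, u = u, lambda = lambda,
                 var_spline = var_spline, var_mother = var_mother,
                 var_resid = sig2,
                 fitted = as.numeric(beta[1] + beta[2] * df$age + Z %*% u),
                 lrt = fits$lrt, p_vs_linear = p_vs_linear,
                 converged = TRUE),
            class = "spline_fit")
}

#' Population-level prediction from a spline fit
#'
#' @param fit a [spline_fit()] result.
#' @param ages ages to predict at.
#' @param lambda optional smoothing override; `Inf` drops the spline part,
#'   reproducing the linear fixed-effect fit.
#' @return predicted mean counts.
#' @export
spline_predict <- function(fit, ages, lambda = NULL) {
  u <- fit$u
  if (!is.null(lambda) && is.infinite(lambda)) u <- rep(0, length(fit$knots))
  Z <- outer(ages, fit$knots, function(a, k) pmax(a - k, 0))
  as.numeric(fit$beta[1] + fit$beta[2] * ages + Z %*% u)
}

#' Ridge-penalized linear spline at fixed smoothing
#'
#' Direct penalized least-squares fit of the truncated-line spline for a
#' given `lambda` (no random intercepts): minimizes
#' `||y - X b - Z u||^2 + lambda ||u||^2`. As `lambda -> Inf` the fit
#' approaches the ordinary linear regression.
#'
#' @param y,x response and covariate.
#' @param lambda penalty on the spline coefficients.
#' @param knots spline knots; default all distinct `x` but the largest.
#' @return list with `beta`, `u`, `fitted`, and `predict(newx)` function.
#' @export
penalized_spline <- function(y, x, lambda, knots = NULL) {
  if (is.null(knots)) {
    knots <- sort(unique(x)); knots <- knots[-length(knots)]
  }
  X <- cbind(1, x)
  Z <- outer(x, knots, function(a, k) pmax(a - k, 0))
  C <- cbind(X, Z)
  D <- diag(c(0, 0, rep(1, ncol(Z))))
  coef <- solve(crossprod(C) + lambda * D, crossprod(C, y))
  beta <- coef[1:2]; u <- coef[-(1:2)]
  list(beta = beta, u = u, fitted = as.numeric(C %*% coef),
       predict = function(newx) {
         Zn <- outer(newx, knots, function(a, k) pmax(a - k, 0))
         as.numeric(cbind(1, newx) %*% beta + Zn %*% u)
       })
}

# ---- rank and closed-form tests -------------------------------------------

#' Spearman rank correlation with permutation p-value
#'
#' Ties are handled by average ranks.
#'
#' @param x,y numeric vectors of equal length.
#' @param n_perm permutations of `y` (default 10000).
#' @param seed optional seed.
#' @param alternative extremeness rule.
#' @return list with `rho` and `p`.
#' @export
rank_correlation <- function(x, y, n_perm = 10000, seed = NULL,
                             alternative = c("two_sided", "less",
                                             "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_perm), function(j)
    stats::cor(rx, ry[sample.int(length(ry))]), 1.0)
  list(rho = rho, p = .perm_pvalue(rho, null, alternative))
}

#' One-sided sign test
#'
#' Probability of at least `n_negative` of `n_total` independent shifts
#' falling in the observed direction when each direction is equally likely:
#' `P(X >= n_negative)` with `X ~ Binomial(n_total, 1/2)`. With all shifts
#' in one direction this is `0.5^n_total` exactly.
#'
#' @param n_negative number of shifts in the tested direction.
#' @param n_total number of shifts.
#' @return one-sided binomial p-value.
#' @export
sign_test <- function(n_negative, n_total) {
  stopifnot(n_negative >= 0, n_negative <= n_total)
  stats::pbinom(n_negative - 1, n_total, 0.5, lower.tail = FALSE)
}

#' Probability that at least two chromosomes reach significance by chance
#'
#' For `n_chrom` chromosomes each reaching a two-sided per-chromosome
#' p-value `per_chrom_p` independently by chance, the probability that at
#' least two do so with the observed (e.g. negative) shift direction is
#' `[1 - P(X = 0) - P(X = 1)] * 0.5^2` with
#' `X ~ Binomial(n_chrom, per_chrom_p)`, assuming a shift is equally
#' likely to be positive or negative.
#'
#' @param n_chrom number of chromosomes (22 autosomes).
#' @param per_chrom_p per-chromosome significance level reached.
#' @return the corrected chance probability.
#' @export
p_chr_at_least_two <- function(n_chrom, per_chrom_p) {
  stopifnot(per_chrom_p > 0, per_chrom_p < 1)
  p <- per_chrom_p; n <- n_chrom
  (1 - (1 - p)^n - n * p * (1 - p)^(n - 1)) * 0.25
}

# ---- categorical and variation tests --------------------------------------

#' Maternal-age category tests
#'
#' Groups transmissions into age categories (default: under 25, 25-29,
#' 30-34, 35 and above; bins closed on the left, so an age of exactly 30
#' falls in 30-34) and tests for differences in mean counts by one-way
#' ANOVA and the Kruskal-Wallis rank-sum test, with permutation p-values
#' obtained by permuting ages across transmissions.
#'
#' @inheritParams adjusted_regression
#' @param breaks bin edges passed to [cut()] with `right = FALSE`.
#' @param n_perm permutations (0 skips the permutation p-values).
#' @return list with `anova_F`, `anova_p`, `anova_p_perm`, `kruskal_chisq`,
#'   `kruskal_p`, `kruskal_p_perm`, and `by_category`
#'   (mean/se/n per non-empty category).
#' @export
age_category_tests <- function(counts, ages, breaks = c(-Inf, 25, 30, 35, Inf),
                               n_perm = 10000, seed = NULL) {
  cat_of <- function(a) cut(a, breaks = breaks, right = FALSE)
  cats <- cat_of(ages)
  non_empty <- table(cats) > 0
  if (sum(non_empty) < 2) stop("need at least two non-empty age categories")
  f_stat <- function(cnt, cg) {
    cg <- droplevels(cg)
    summary(stats::aov(cnt ~ cg))[[1]]$`F value`[1]
  }
  kw_stat <- function(cnt, cg) {
    cg <- droplevels(cg)
    unname(stats::kruskal.test(cnt, cg)$statistic)
  }
  aovfit <- summary(stats::aov(counts ~ droplevels(cats)))[[1]]
  kw <- stats::kruskal.test(counts, droplevels(cats))
  p_f <- NA_real_; p_kw <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    null_f <- numeric(n_perm); null_kw <- numeric(n_perm)
    for (j in seq_len(n_perm)) {
      cg <- cat_of(ages[sample.int(length(ages))])
      null_f[j] <- f_stat(counts, cg)
      null_kw[j] <- kw_stat(counts, cg)
    }
    p_f <- .perm_pvalue(aovfit$`F value`[1], null_f, "greater")
    p_kw <- .perm_pvalue(unname(kw$statistic), null_kw, "greater")
  }
  by_cat <- do.call(rbind, lapply(split(counts, cats), function(v)
    data.frame(mean = mean(v), se = stats::sd(v) / sqrt(length(v)),
               n = length(v))))
  by_cat$category <- rownames(by_cat); rownames(by_cat) <- NULL
  list(anova_F = aovfit$`F value`[1], anova_p = aovfit$`Pr(>F)`[1],
       anova_p_perm = p_f,
       kruskal_chisq = unname(kw$statistic), kruskal_p = kw$p.value,
       kruskal_p_perm = p_kw,
       by_category = by_cat[!is.na(by_cat$mean), ])
}

#' Variation in mean crossover counts among parents
#'
#' One-way ANOVA of per-transmission counts among parents, with the
#' permutation p-value obtained by randomly reassigning children to
#' parents without modifying family sizes.
#'
#' @param counts per-transmission crossover counts.
#' @param parents parent id per transmission.
#' @param n_perm permutations (0 skips).
#' @param seed optional seed.
#' @return list with `F`, `p_param`, `p_perm`.
#' @export
variation_among_parents <- function(counts, parents, n_perm = 10000,
                                    seed = NULL) {
  sizes <- table(parents)
  if (sum(sizes >= 2) < 2)
    stop("need at least two parents with at least two transmissions")
  df <- data.frame(count = counts, parent = as.factor(parents),
                   age = NA_real_)
  f_stat <- function(d) summary(stats::aov(count ~ parent, d))[[1]]$`F value`[1]
  obs <- f_stat(df)
  p_perm <- NA_real_
  if (n_perm > 0) {
    pt <- permutation_test(df, f_stat, scheme = "child_reassignment",
                           n_perm = n_perm, seed = seed,
                           alternative = "greater")
    p_perm <- pt$p
  }
  p_param <- summary(stats::aov(count ~ parent, df))[[1]]$`Pr(>F)`[1]
  list(F = obs, p_param = p_param, p_perm = p_perm)
}
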