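# Family adjustment, regressions, mixed models, splines, permutation and
# closed-form tests for the maternal-age effect.

test_that("family adjustment centers within mothers and is a projection", {
  expect_equal(family_adjust(c(40, 44), c("m1", "m1")), c(-2, 2))
  expect_equal(family_adjust(5, "m1"), 0)
  set.seed(1)
  v <- rnorm(30); g <- rep(letters[1:6], each = 5)
  adj <- family_adjust(v, g)
  expect_equal(as.numeric(tapply(adj, g, mean)), rep(0, 6))
  expect_equal(mean(adj), 0)
  expect_equal(family_adjust(adj, g), adj)  # projection
})

test_that("adjusted regression recovers a simulated within-family slope", {
  set.seed(2)
  n_mothers <- 60
  mothers <- rep(seq_len(n_mothers), each = 3)
  ages <- 24 + rep(runif(n_mothers, 0, 8), each = 3) + rep(c(0, 2.5, 5), n_mothers)
  mu_mother <- rep(rnorm(n_mothers, 40, 3), each = 3)
  counts <- mu_mother - 0.5 * ages + rnorm(length(ages), 0, 2)
  reg <- adjusted_regression(counts, ages, mothers, n_perm = 499, seed = 3)
  expect_lt(abs(reg$beta - (-0.5)), 2 * reg$se)
  expect_lt(reg$p_perm, 0.05)
  expect_equal(reg$r_squared, reg$pearson_r^2)
})

test_that("degenerate regressions are flagged or rejected", {
  # constant response: slope 0, r reported as 0 with flag
  reg <- adjusted_regression(rep(5, 6), c(20, 25, 30, 22, 27, 32),
                             rep(c("a", "b"), each = 3), n_perm = 0)
  expect_true(reg$degenerate)
  expect_equal(reg$beta, 0)
  expect_equal(reg$pearson_r, 0)
  # all singleton groups: no within-family information
  expect_error(adjusted_regression(1:3, c(20, 25, 30), c("a", "b", "c"),
                                   n_perm = 0), "singleton")
})

test_that("permutation p-values follow the add-one convention", {
  d <- data.frame(age = c(1, 2, 3, 4), count = c(1, 1, 1, 1),
                  mother = c("a", "a", "b", "b"))
  # statistic constant under permutation -> p = 1
  pt <- permutation_test(d, function(x) 1, "across_transmissions",
                         n_perm = 50, seed = 1)
  expect_equal(pt$p, 1)
  # n_perm = 1 -> p in {0.5, 1}
  ps <- replicate(20, permutation_test(
    d, function(x) sum(x$age * c(1, 2, 3, 4)), "across_transmissions",
    n_perm = 1)$p)
  expect_true(all(ps %in% c(0.5, 1)))
  expect_error(permutation_test(d, function(x) 1, "bogus"), "arg")
})

test_that("permutation p-values are uniform under the null", {
  # family-adjusted regression on null data: p ~ U(0,1)
  set.seed(4)
  ps <- replicate(1500, {
    mothers <- rep(1:12, each = 3)
    ages <- 22 + rep(runif(12, 0, 8), each = 3) + rep(c(0, 2, 4), 12)
    counts <- rpois(36, 40)
    adjusted_regression(counts, ages, mothers, n_perm = 99)$p_perm
  })
  # discrete grid of (b+1)/100 values: chi-square GOF over deciles
  obs <- table(cut(ps, seq(0, 1, 0.1), include.lowest = TRUE))
  expect_gt(chisq.test(obs)$p.value, 0.01)
})

test_that("the mixed model collapses to simple regression without mother variance", {
  set.seed(5)
  ages <- runif(60, 20, 40)
  mothers <- rep(1:20, each = 3)
  # noise centered within each mother: the REML mother variance hits the
  # zero boundary and the fit collapses to ordinary least squares
  eps <- rnorm(60, 0, 2)
  eps <- eps - ave(eps, mothers)
  counts <- 45 - 0.4 * ages + eps
  mm <- mixed_model(counts, ages, mothers)
  ols <- lm(counts ~ ages)
  expect_true(mm$converged)
  expect_lt(abs(mm$beta_age - coef(ols)[2]), 1e-6)
  expect_lt(mm$var_mother, 1e-6)
  expect_error(mixed_model(1:3, 1:3, rep("m", 3)), "two mothers")
})

test_that("the mixed model recovers the slope with real mother variance", {
  set.seed(6)
  n_mothers <- 50
  sizes <- rep(3:5, length.out = n_mothers)   # varying family sizes
  mothers <- rep(seq_len(n_mothers), times = sizes)
  ages <- 22 + rep(runif(n_mothers, 0, 10), times = sizes) +
    unlist(lapply(sizes, function(s) 2 * (seq_len(s) - 1)))
  u <- rep(rnorm(n_mothers, 0, 3), times = sizes)
  counts <- 42 - 0.4 * ages + u + rnorm(length(ages), 0, 2)
  mm <- mixed_model(counts, ages, mothers)
  expect_lt(abs(mm$beta_age - (-0.4)), 2 * mm$se)
  expect_gt(mm$var_mother, 0.5)
  # an uncorrelated number-of-children covariate leaves beta_age stable
  mm2 <- mixed_model(counts, ages, mothers, n_children_covariate = TRUE)
  expect_lt(abs(mm2$beta_age - mm$beta_age), mm$se)
})

test_that("the ridge spline approaches the ordinary line as lambda grows", {
  set.seed(7)
  x <- runif(40, 20, 40)
  y <- 30 - 0.5 * x + rnorm(40, 0, 2)
  fit <- penalized_spline(y, x, lambda = 1e10)
  ols <- lm(y ~ x)
  expect_lt(max(abs(fit$beta - coef(ols))), 1e-3)
  # at any finite lambda the penalized fit has no worse residual sum of
  # squares than the line (the line is the u = 0 member of the family)
  fit1 <- penalized_spline(y, x, lambda = 1)
  expect_lte(sum((y - fit1$fitted)^2), sum(resid(ols)^2))
})

test_that("REML spline shrinks to the line on linear data", {
  set.seed(8)
  n_mothers <- 40
  mothers <- rep(seq_len(n_mothers), each = 3)
  ages <- round(22 + rep(runif(n_mothers, 0, 10), each = 3) +
                  rep(c(0, 2, 4), n_mothers))
  counts <- 44 - 0.45 * ages + rep(rnorm(n_mothers, 0, 2), each = 3) +
    rnorm(length(ages), 0, 2)
  sf <- spline_fit(counts, ages, mothers)
  expect_true(sf$converged)
  # fitted curve close to the generating line across the age range
  grid <- seq(min(ages), max(ages), length.out = 20)
  pred <- spline_predict(sf, grid)
  expect_lt(max(abs(pred - (44 - 0.45 * grid))), 2.5)
  # lambda = Inf override reproduces the fixed linear part exactly
  lin <- spline_predict(sf, grid, lambda = Inf)
  expect_equal(lin, as.numeric(sf$beta[1] + sf$beta[2] * grid))
})

test_that("the spline beats the line on kinked truth at held-out points", {
  set.seed(9)
  x <- rep(seq(20, 40, by = 1), 4)
  truth_fn <- function(a) ifelse(a < 30, 50 - 1.2 * (a - 20), 38 - 0.1 * (a - 30))
  y <- truth_fn(x) + rnorm(length(x), 0, 1.5)
  sf <- spline_fit(y, x, mothers = rep(1:12, length.out = length(x)))
  grid <- seq(20.5, 39.5, by = 0.5)   # held-out ages
  rmse_spline <- sqrt(mean((spline_predict(sf, grid) - truth_fn(grid))^2))
  ols <- lm(y ~ x)
  rmse_line <- sqrt(mean((predict(ols, data.frame(x = grid)) - truth_fn(grid))^2))
  expect_lt(rmse_spline, rmse_line)
  expect_error(spline_fit(y[1:6], rep(1:2, 3), rep(1, 6)), "distinct ages")
})

test_that("rank correlation behaves on monotone and reversed data", {
  x <- 1:20
  y <- x^2
  rc <- rank_correlation(x, y, n_perm = 199, seed = 10)
  expect_equal(rc$rho, 1)
  expect_lt(rc$p, 0.05)
  rc_rev <- rank_correlation(x, -y, n_perm = 199, seed = 10)
  expect_equal(rc_rev$rho, -1)
})

test_that("the sign test matches its closed binomial form", {
  expect_equal(sign_test(13, 13), 0.5^13)
  expect_equal(sign_test(13, 13), 1.22e-4, tolerance = 5e-3)
  expect_equal(sign_test(1, 1), 0.5)
  expect_equal(sign_test(2, 2), 0.25)
  for (k in c(3, 7, 10)) expect_equal(sign_test(k, k), 0.5^k)
  expect_equal(sign_test(0, 5), 1)
})

test_that("p_chr matches brute-force binomial summation and limits", {
  brute <- function(n, p) sum(dbinom(2:n, n, p)) * 0.25
  expect_equal(p_chr_at_least_two(10, 0.1), brute(10, 0.1), tolerance = 1e-12)
  expect_equal(p_chr_at_least_two(22, 0.0355), brute(22, 0.0355),
               tolerance = 1e-12)
  expect_lt(p_chr_at_least_two(22, 1e-9), 1e-12)  # p -> 0 limit
})

test_that("age categories use left-closed bins and detect real trends", {
  set.seed(11)
  counts <- rpois(200, 40)
  ages <- runif(200, 18, 42)
  act <- age_category_tests(counts, ages, n_perm = 0)
  expect_equal(nrow(act$by_category), 4)
  # boundary convention: 24.9 -> bin 1, 25 -> bin 2, 30 -> bin 3, 35 -> bin 4
  cats <- cut(c(24.9, 25, 30, 35), breaks = c(-Inf, 25, 30, 35, Inf),
              right = FALSE)
  expect_equal(as.integer(cats), 1:4)
  # strong simulated decrease: both tests significant
  counts2 <- rpois(200, 50 - 0.6 * ages)
  act2 <- age_category_tests(counts2, ages, n_perm = 299, seed = 12)
  expect_lt(act2$anova_p_perm, 0.01)
  expect_lt(act2$kruskal_p_perm, 0.01)
  expect_error(age_category_tests(1:5, rep(27, 5), n_perm = 0),
               "non-empty")
})

test_that("variation among parents is detected and contracts enforced", {
  set.seed(13)
  parents <- rep(paste0("p", 1:12), each = 8)
  counts <- rpois(96, 40)
  counts[parents == "p3"] <- rpois(8, 55)  # one parent strongly shifted
  vp <- variation_among_parents(counts, parents, n_perm = 499, seed = 14)
  expect_lt(vp$p_perm, 0.01)
  expect_error(variation_among_parents(1:5, paste0("p", 1:5), n_perm = 0),
               "two transmissions")
})
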