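# Protection-against-non-disjunction model: an age-invariant oocyte
# crossover-count distribution combined with age-dependent disjunction
# probabilities implies opposite age trends for the mean crossover count
# in properly disjoined (normal) and non-disjoined (aneuploid) oocytes.

#' Non-disjunction protection model
#'
#' The model assumes the proportion of oocytes with `r` crossovers (on the
#' chromosome under study) stays the same across age periods, while the
#' probability `P_k(r)` that an oocyte with `r` crossovers disjoins
#' properly depends on the age period `k`. When protection weakens with
#' age preferentially for low-crossover oocytes, the mean crossover count
#' among normal conceptions decreases with age and the mean among
#' aneuploid conceptions increases.
#'
#' @param pi probability vector over crossover counts `r = 0..r_max`
#'   (sums to 1).
#' @param P matrix of proper-disjunction probabilities, one row per age
#'   period `k`, one column per crossover count `r` (entries in \[0, 1\]).
#' @return an `ndj_model` object.
#' @export
ndj_model <- function(pi, P) {
  P <- as.matrix(P)
  stopifnot(length(pi) == ncol(P), all(pi >= 0), all(P >= 0), all(P <= 1))
  if (abs(sum(pi) - 1) > 1e-8) stop("pi must sum to 1")
  structure(list(pi = pi, P = P, r = seq_along(pi) - 1,
                 K = nrow(P)), class = "ndj_model")
}

#' Preset protection-probability families
#'
#' Three parametric families of `P_k(r)` in which the protection that
#' recombination confers becomes less efficient with the age period `k`.
#' What must weaken for the model's predicted trends is the *selectivity*
#' of protection -- the gradient of `P_k` in `r` -- not merely its overall
#' level: when high-crossover oocytes lose their disjunction advantage,
#' the surviving (normal) pool is less enriched in high `r`, so `E_N`
#' falls toward the population mean, while the aneuploid pool gains
#' high-`r` members and `E_A` rises toward it. A uniform drop of `P_k`
#' that preserves the gradient would instead sharpen the selection and
#' push `E_N` up with age.
#' \describe{
#'   \item{`linear`}{`P_k(r) = b + s_k * r` with the slope `s_k`
#'     shrinking with `k`;}
#'   \item{`logistic`}{`P_k(r) = plogis((r - m) / s_k) * d_k` with the
#'     scale `s_k` widening (gradient flattening) and a mild overall
#'     decline `d_k`;}
#'   \item{`mixture`}{`P_k(r) = (1 - w_k) * r / (r + c) + w_k * p_flat`,
#'     an age-increasing admixture `w_k` of indiscriminate disjunction.}
#' }
#'
#' @param preset family name.
#' @param pi crossover-count distribution (default: Poisson with mean 2
#'   truncated at `r_max`, renormalized).
#' @param K number of age periods.
#' @param r_max maximum crossover count.
#' @return an [ndj_model()].
#' @export
ndj_preset <- function(preset = c("linear", "logistic", "mixture"),
                       pi = NULL, K = 3, r_max = 6) {
  preset <- match.arg(preset)
  r <- 0:r_max
  if (is.null(pi)) {
    pi <- stats::dpois(r, 2); pi <- pi / sum(pi)
  }
  P <- switch(preset,
    linear = t(vapply(seq_len(K), function(k)
      0.3 + 0.1 / k * r, numeric(length(r)))),
    logistic = t(vapply(seq_len(K), function(k)
      stats::plogis((r - 1.5) / (0.5 + 0.5 * (k - 1))) *
        (1 - 0.05 * (k - 1)), numeric(length(r)))),
    mixture = t(vapply(seq_len(K), function(k)
      (1 - 0.3 * (k - 1)) * r / (r + 0.5) + 0.3 * (k - 1) * 0.6,
      numeric(length(r)))))
  ndj_model(pi, P)
}

#' Expected crossover counts in normal and aneuploid conceptions
#'
#' For each age period `k`:
#' `E_N(k) = sum_r r pi(r) P_k(r) / sum_r pi(r) P_k(r)` and
#' `E_A(k) = sum_r r pi(r) (1 - P_k(r)) / sum_r pi(r) (1 - P_k(r))`,
#' with the aneuploidy rate `1 - sum_r pi(r) P_k(r)`. The law of total
#' expectation ties them together:
#' `sum_r r pi(r) = (1 - rate) E_N + rate E_A` for every `k`.
#'
#' @param model an [ndj_model()].
#' @return data.frame per age period: `k`, `E_N`, `E_A`,
#'   `aneuploidy_rate`.
#' @export
ndj_expectations <- function(model) {
  stopifnot(inherits(model, "ndj_model"))
  r <- model$r; pi <- model$pi; P <- model$P
  out <- lapply(seq_len(model$K), function(k) {
    wN <- pi * P[k, ]; wA <- pi * (1 - P[k, ])
    sN <- sum(wN); sA <- sum(wA)
    if (sN == 0) stop("degenerate model: no disjoined oocytes in period ", k)
    if (sA == 0) stop("degenerate model: no non-disjoined oocytes in period ",
                      k)
    data.frame(k = k, E_N = sum(r * wN) / sN, E_A = sum(r * wA) / sA,
               aneuploidy_rate = sA)
  })
  do.call(rbind, out)
}

#' Check the expected age trends of E_N and E_A
#'
#' Evaluates whether the mean crossover count among normal conceptions is
#' non-increasing and that among aneuploid conceptions non-decreasing
#' across age periods, reporting the per-step differences. The model
#' structure does not guarantee these trends for arbitrary `P`; this
#' function reports rather than assumes them.
#'
#' @param model an [ndj_model()] with at least two age periods.
#' @return list with `E_N_diff`, `E_A_diff` (per-step differences),
#'   `E_N_trend`, `E_A_trend`, and `satisfied` (both trends hold, weakly).
#' @export
check_monotonicity <- function(model) {
  if (model$K < 2) stop("need at least two age periods")
  ex <- ndj_expectations(model)
  dN <- diff(ex$E_N); dA <- diff(ex$E_A)
  tol <- 1e-12
  list(E_N_diff = dN, E_A_diff = dA,
       E_N_trend = if (all(dN <= tol)) "non-increasing" else "increasing somewhere",
       E_A_trend = if (all(dA >= -tol)) "non-decreasing" else "decreasing somewhere",
       satisfied = all(dN <= tol) && all(dA >= -tol))
}

#' Monte-Carlo simulation of conceptions under the model
#'
#' Draws oocyte crossover counts from `pi` and disjunction outcomes from
#' `Bernoulli(P_k(r))`, returning empirical conditional means that
#' converge to [ndj_expectations()].
#'
#' @param model an [ndj_model()].
#' @param n_per_period oocytes simulated per age period.
#' @param seed optional seed.
#' @return data.frame per age period: `k`, `E_N`, `E_A`,
#'   `aneuploidy_rate`, `n` (plus the analytic values for reference).
#' @export
simulate_conceptions <- function(model, n_per_period, seed = NULL) {
  stopifnot(inherits(model, "ndj_model"), n_per_period >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(model$K), function(k) {
    r <- sample(model$r, n_per_period, replace = TRUE, prob = model$pi)
    disjoin <- stats::runif(n_per_period) < model$P[k, r + 1]
    data.frame(k = k,
               E_N = mean(r[disjoin]), E_A = mean(r[!disjoin]),
               aneuploidy_rate = mean(!disjoin), n = n_per_period)
  })
  do.call(rbind, out)
}
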