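# Sibling-comparison crossover caller: informative markers, phasing with
# reference-child attribution, double-recombinant pre-treatment,
# deduplication, reduced families, and minimum-recombinant equivalence.

test_that("informative markers require one het parent and a hom co-parent", {
  # markers: (mother, father) = (1,0) informative for mother; (1,1) neither;
  # (0,2) neither (mother hom); (1,2) informative for mother
  geno <- rbind(c(1L, 0L, 0L, 1L),
                c(1L, 1L, 1L, 1L),
                c(0L, 2L, 1L, 1L),
                c(1L, 2L, 1L, 2L))
  colnames(geno) <- c("MO", "FA", "C1", "C2")
  fx <- make_informative_family(matrix(0L, 1, 2))  # reuse ped/family shape
  gm <- make_gm(geno)
  inf <- find_informative_markers(gm, fx$family, "mother")
  expect_equal(unname(unlist(inf)), c(1L, 4L))
  inf_f <- find_informative_markers(gm, fx$family, "father")
  expect_length(unlist(inf_f), 0)
  # a missing child call drops the marker
  geno[1, "C2"] <- NA
  inf2 <- find_informative_markers(make_gm(geno), fx$family, "mother")
  expect_equal(unname(unlist(inf2)), 4L)
})

test_that("phasing calls a single switch in the right child and interval", {
  # 3 children over 5 markers: child2 switches between markers 3 and 4,
  # child3 identical to the reference
  tr <- cbind(c(0, 0, 0, 0, 0),
              c(0, 0, 0, 1, 1),
              c(0, 0, 0, 0, 0))
  fx <- make_informative_family(tr)
  ev <- call_family(fx$gm, fx$family, parents = "mother", window_bp = 0,
                    unique_only = FALSE)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$child_id, "C2")
  expect_equal(ev$left_bp, 3 * 2e6)
  expect_equal(ev$right_bp, 4 * 2e6)
  expect_equal(oracle_min_recombinants(tr), 1)

  # all children identical to the reference: no events
  tr0 <- matrix(0L, 6, 3)
  fx0 <- make_informative_family(tr0)
  expect_equal(nrow(call_family(fx0$gm, fx0$family, parents = "mother",
                                window_bp = 0, unique_only = FALSE)), 0)
})

test_that("a simultaneous switch in all non-reference children goes to the reference", {
  # both non-reference children appear to switch at the same interval:
  # the parsimonious explanation is one crossover in the reference child
  tr <- cbind(c(0, 0, 0, 0, 0),
              c(0, 0, 1, 1, 1),
              c(0, 0, 1, 1, 1))
  fx <- make_informative_family(tr)
  ev <- call_family(fx$gm, fx$family, parents = "mother", window_bp = 0,
                    unique_only = FALSE)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$child_id, "C1")
  expect_equal(ev$n_share, 1L)
  expect_equal(oracle_min_recombinants(tr), 1)
})

test_that("pre-treatment removes tight single-marker blips but not supported switches", {
  # blip: ...0 1 0... with outer markers 200 kb apart -> marker removed
  tr <- matrix(c(0, 0, 1, 0, 0), ncol = 1)
  tr <- cbind(tr, 0)  # second child constant
  fx <- make_informative_family(tr, pos = c(1e6, 1.1e6, 1.2e6, 1.3e6, 1.4e6))
  track <- phase_family(fx$gm, fx$family, "mother")
  pre <- pretreat_double_recombinants(track, window_bp = 1e6)
  expect_length(pre$removed, 1)
  expect_equal(nrow(call_events(pre)), 0)

  # two-marker support spanning 5 Mb: 0 1 1 0 retained -> two events
  tr2 <- cbind(c(0, 1, 1, 0), 0)
  fx2 <- make_informative_family(tr2, pos = c(1e6, 3e6, 6e6, 9e6))
  track2 <- pretreat_double_recombinants(
    phase_family(fx2$gm, fx2$family, "mother"), window_bp = 1e6)
  expect_length(track2$removed, 0)
  expect_equal(nrow(call_events(track2)), 2)
})

test_that("deduplication removes all copies of shared events", {
  ev <- data.frame(family = "F", parent_id = "M", parent = "mother",
                   child_id = paste0("C", c(1, 2, 3, 1, 2, 3, 1)),
                   chrom = 1L, left_bp = 1:7 * 1e6, right_bp = 1:7 * 1e6 + 1e5,
                   n_share = c(2L, 2L, 2L, 1L, 1L, 1L, 1L),
                   stringsAsFactors = FALSE)
  kept <- deduplicate_events(ev)
  expect_equal(nrow(kept), 4)
  expect_true(all(kept$n_share == 1))
})

test_that("reduced families average counts over all 3-child subsets", {
  # 4 children, no shared events: unbiased equals standard counts
  set.seed(61)
  tr <- matrix(0L, 12, 4)
  tr[7:12, 2] <- 1L   # child 2: one switch
  tr[3:12, 4] <- 1L   # child 4: one switch elsewhere
  fx <- make_informative_family(tr)
  ub <- reduced_family_counts(fx$gm, fx$family, parents = "mother",
                              window_bp = 0)
  std <- call_family(fx$gm, fx$family, parents = "mother", window_bp = 0)
  std_counts <- table(factor(std$child_id, levels = paste0("C", 1:4)))
  expect_equal(ub$unbiased[match(paste0("C", 1:4), ub$child_id)],
               as.numeric(std_counts))
  # each child appears in choose(3, 2) = 3 of the 4 subsets
  expect_equal(nrow(ub), 4)
})

test_that("two-child families yield family-level, unassigned events only", {
  tr <- cbind(c(0, 0, 0, 1, 1), c(0, 0, 0, 0, 0))[, 1:2]
  fx <- make_informative_family(tr[, 1:2])
  ct <- count_transmissions(fx$gm, fx$ped)
  expect_null(ct$records)
  expect_equal(nrow(ct$events), 1)
  expect_true(is.na(ct$events$child_id))
})

test_that("totals equal the sum of per-chromosome counts on simulated data", {
  sim <- simulate_cohort(sim_config(n_families = 4, snps_per_chrom = 400,
                                    chrom_lengths_bp = rep(8e7, 3),
                                    seed = 77))
  ct <- count_transmissions(sim$gm, sim$ped)
  agg <- aggregate(count ~ parent_id + child_id, ct$per_chrom, sum)
  m <- merge(ct$records, agg, by = c("parent_id", "child_id"))
  expect_equal(m$total, m$count)
})

test_that("called totals equal the exhaustive minimum-recombinant solution", {
  set.seed(71)
  for (rep_i in 1:40) {
    k <- sample(2:4, 1)
    M <- sample(3:12, 1)
    tr <- matrix(rbinom(M * k, 1, 0.5), M, k)
    fx <- make_informative_family(tr)
    ev <- call_family(fx$gm, fx$family, parents = "mother", window_bp = 0,
                      unique_only = FALSE)
    expect_equal(nrow(ev), oracle_min_recombinants(tr),
                 info = paste("children:", k, "markers:", M, "rep:", rep_i))
  }
})

test_that("family totals are invariant to the choice of reference child", {
  set.seed(81)
  for (rep_i in 1:10) {
    k <- sample(3:4, 1)
    M <- sample(4:10, 1)
    tr <- matrix(rbinom(M * k, 1, 0.5), M, k)
    fx <- make_informative_family(tr)
    totals <- vapply(seq_len(k), function(first) {
      fam <- fx$family
      fam$children <- c(fam$children[first], fam$children[-first])
      nrow(call_family(fx$gm, fam, parents = "mother", window_bp = 0,
                       unique_only = FALSE))
    }, 1L)
    expect_true(all(totals == totals[1]))
  }
})

test_that("phasing refuses single-child families", {
  fx <- make_informative_family(matrix(0L, 3, 2))
  fam1 <- fx$family; fam1$children <- fam1$children[1]
  expect_error(phase_family(fx$gm, fam1, "mother"), "two children")
})

test_that("events written as BED use half-open output coordinates", {
  tr <- cbind(c(0, 0, 1, 1), c(0, 0, 0, 0), c(0, 0, 0, 0))
  fx <- make_informative_family(tr)
  ev <- call_family(fx$gm, fx$family, parents = "mother", window_bp = 0)
  path <- file.path(tempdir(), "events.bed")
  write_events_bed(ev, path)
  bed <- read.table(path, sep = "\t")
  expect_equal(bed$V2, ev$left_bp - 1)
  expect_equal(bed$V3, ev$right_bp)
})
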