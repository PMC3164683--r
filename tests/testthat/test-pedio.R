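# PLINK I/O, pedigree structure and the SNP quality-control filters.

test_that("PLINK bed/bim/fam round-trips, including the coding convention", {
  # 3 SNPs x 2 individuals with a het call: value 1 for that cell
  geno <- matrix(c(0L, 1L, 2L, 2L, NA, 0L), nrow = 3,
                 dimnames = list(NULL, c("A1", "A2")))
  gm <- make_gm(geno)
  ind <- data.frame(fid = "F1", id = c("A1", "A2"), father = "0",
                    mother = "0", sex = c(1L, 2L), phen = -9L,
                    stringsAsFactors = FALSE)
  ped <- pedigree(ind)
  prefix <- file.path(tempdir(), "rt_small")
  write_plink(gm, ped, prefix)
  rt <- read_plink(prefix)
  expect_identical(rt$gm$geno, gm$geno)
  expect_identical(rt$gm$map$pos, gm$map$pos)
  expect_identical(rt$gm$geno["s002", "A1"], 1L)
  expect_identical(rt$ped$ind$father, ped$ind$father)

  # random larger fixture with missingness, odd individual count (padding)
  set.seed(11)
  geno2 <- matrix(sample(c(0L, 1L, 2L, NA), 200 * 7, replace = TRUE), 200)
  colnames(geno2) <- paste0("I", 1:7)
  gm2 <- make_gm(geno2, chrom = rep(1:4, each = 50))
  ped2 <- pedigree(data.frame(fid = "F1", id = colnames(geno2),
                              father = "0", mother = "0", sex = 0L,
                              phen = -9L, stringsAsFactors = FALSE))
  prefix2 <- file.path(tempdir(), "rt_big")
  write_plink(gm2, ped2, prefix2)
  expect_identical(read_plink(prefix2)$gm$geno, gm2$geno)
})

test_that("malformed bed files are rejected", {
  prefix <- file.path(tempdir(), "badmagic")
  geno <- matrix(0L, 2, 2, dimnames = list(NULL, c("A", "B")))
  ped <- pedigree(data.frame(fid = "F", id = c("A", "B"), father = "0",
                             mother = "0", sex = 0L, phen = -9L,
                             stringsAsFactors = FALSE))
  write_plink(make_gm(geno), ped, prefix)
  raw <- readBin(paste0(prefix, ".bed"), "raw", 100)
  raw[1] <- as.raw(0xff)
  writeBin(raw, paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "magic")

  # individual-count mismatch between fam and bed
  prefix2 <- file.path(tempdir(), "mismatch")
  write_plink(make_gm(geno), ped, prefix2)
  fam <- read.table(paste0(prefix2, ".fam"))
  extra <- fam[c(1, 1, 1), ]; extra$V2 <- paste0("X", 1:3)
  write.table(rbind(fam, extra), paste0(prefix2, ".fam"),
              col.names = FALSE, row.names = FALSE, quote = FALSE)
  expect_error(read_plink(prefix2), "inconsistent")
})

test_that("non-autosomal markers are dropped on construction", {
  geno <- matrix(0L, 3, 1, dimnames = list(NULL, "A"))
  gm <- suppressMessages(make_gm(geno, chrom = c(1L, 23L, 2L)))
  expect_equal(nrow(gm$geno), 2)
  expect_true(all(gm$map$chrom %in% 1:22))
})

test_that("qc_filter removes low call-rate, HWE-departing and Mendelian-error SNPs", {
  set.seed(21)
  n_founders <- 40
  # founders in HWE at freq 0.5 for most SNPs
  founder_ids <- paste0("U", seq_len(n_founders))
  m <- 10
  geno <- matrix(rbinom(m * n_founders, 2, 0.5), m, n_founders,
                 dimnames = list(NULL, founder_ids))
  # SNP 1: 10% missing (below 0.95 call rate)
  geno[1, 1:4] <- NA
  # SNP 2: extreme heterozygote deficit (20, 0, 20)
  geno[2, ] <- rep(c(0L, 2L), each = 20)
  ped <- pedigree(data.frame(fid = paste0("F", seq_len(n_founders)),
                             id = founder_ids, father = "0", mother = "0",
                             sex = 0L, phen = -9L, stringsAsFactors = FALSE))
  res <- qc_filter(make_gm(geno), ped)
  expect_false("s001" %in% res$gm$map$snp)   # call rate 0.90 < 0.95
  expect_false("s002" %in% res$gm$map$snp)   # HWE exact p << 0.01
  expect_gte(res$report$n_removed_call_rate, 1)
  expect_gte(res$report$n_removed_hwe, 1)

  # trio father=0, mother=0, child=2 is an impossible transmission
  trio_geno <- matrix(c(0L, 0L, 2L,
                        1L, 1L, 1L), nrow = 2, byrow = TRUE,
                      dimnames = list(NULL, c("FA", "MO", "CH")))
  trio_ped <- pedigree(data.frame(
    fid = "T1", id = c("FA", "MO", "CH"), father = c("0", "0", "FA"),
    mother = c("0", "0", "MO"), sex = c(1L, 2L, 0L), phen = -9L,
    stringsAsFactors = FALSE))
  res2 <- qc_filter(make_gm(trio_geno), trio_ped, max_mendel_families = 0)
  expect_equal(res2$report$n_mendel_masked_calls, 1)
  expect_equal(res2$report$n_removed_mendel, 1)
  expect_equal(res2$gm$map$snp, "s002")
})

test_that("the HWE exact test matches an allele-permutation oracle", {
  set.seed(31)
  expect_lt(hwe_exact_test(20, 0, 20), 1e-6)
  cases <- list(c(5, 5, 5), c(10, 4, 1), c(3, 14, 3), c(8, 8, 8))
  for (cs in cases) {
    p_exact <- hwe_exact_test(cs[1], cs[2], cs[3])
    p_mc <- hwe_mc_oracle(cs[1], cs[2], cs[3])
    expect_lt(abs(p_exact - p_mc), 0.02)
  }
  expect_equal(hwe_exact_test(10, 0, 0), 1)  # monomorphic
})

test_that("qc_filter and filter_family_missing are idempotent", {
  set.seed(41)
  sim <- simulate_cohort(sim_config(n_families = 4, snps_per_chrom = 150,
                                    chrom_lengths_bp = rep(5e7, 2),
                                    genotyping_error_rate = 0.01,
                                    missing_rate = 0.02, seed = 42))
  fams <- extract_nuclear_families(sim$ped, sim$gm)
  q1 <- qc_filter(sim$gm, sim$ped)
  q2 <- qc_filter(q1$gm, sim$ped)
  expect_identical(q2$gm$geno, q1$gm$geno)
  expect_equal(q2$report$n_removed_mendel + q2$report$n_removed_call_rate +
                 q2$report$n_removed_hwe, 0)
  f1 <- filter_family_missing(q1$gm, fams)
  f2 <- filter_family_missing(f1$gm, fams)
  expect_identical(f2$gm$geno, f1$gm$geno)
  expect_equal(f2$removed_count, 0L)
})

test_that("family-missingness filter matches a brute-force scan", {
  # 5 SNPs, 2 families; missingness pattern covering 2 SNPs
  ids <- c("F1P", "F1M", "F1C1", "F1C2", "F2P", "F2M", "F2C1", "F2C2")
  geno <- matrix(1L, 5, 8, dimnames = list(NULL, ids))
  geno[2, "F1C2"] <- NA       # child of family 1 -> SNP 2 removed
  geno[4, "F2M"] <- NA        # parent of family 2 -> SNP 4 removed
  gm <- make_gm(geno)
  ind <- data.frame(
    fid = rep(c("F1", "F2"), each = 4), id = ids,
    father = c("0", "0", "F1P", "F1P", "0", "0", "F2P", "F2P"),
    mother = c("0", "0", "F1M", "F1M", "0", "0", "F2M", "F2M"),
    sex = rep(c(1L, 2L, 0L, 0L), 2), phen = -9L, stringsAsFactors = FALSE)
  fams <- extract_nuclear_families(pedigree(ind), gm)
  res <- filter_family_missing(gm, fams)
  expect_equal(res$removed_count, 2L)
  expect_equal(res$gm$map$snp, c("s001", "s003", "s005"))
  # brute force: any NA among members of any family
  brute <- sum(apply(is.na(geno), 1, any))
  expect_equal(res$removed_count, brute)
})

test_that("nuclear families decompose from a three-generation pedigree", {
  # grandparents (2 children incl. one parent) + parents with 3 children
  ind <- data.frame(
    fid = "F1",
    id = c("GF", "GM", "P1", "U1", "SP", "C1", "C2", "C3"),
    father = c("0", "0", "GF", "GF", "0", "P1", "P1", "P1"),
    mother = c("0", "0", "GM", "GM", "0", "SP", "SP", "SP"),
    sex = c(1L, 2L, 1L, 0L, 2L, 0L, 0L, 0L), phen = -9L,
    stringsAsFactors = FALSE)
  ped <- pedigree(ind)
  fams <- extract_nuclear_families(ped)
  expect_length(fams, 2)
  sizes <- sort(vapply(fams, function(f) length(f$children), 1L))
  expect_equal(sizes, c(2L, 3L))
  # a couple with one child is excluded at min_children = 2
  ind1 <- ind[ind$id %in% c("GF", "GM", "P1"), ]
  expect_length(extract_nuclear_families(pedigree(ind1)), 0)
  # min_children = 3 excludes the 2-child grandparental family
  expect_length(extract_nuclear_families(ped, min_children = 3), 1)
})

test_that("ages tables round-trip and pedigree validation catches errors", {
  ages <- data.frame(family_id = "F1", parent_id = "M", child_id = "C1",
                     age = 27.5, stringsAsFactors = FALSE)
  path <- file.path(tempdir(), "ages.tsv")
  write_ages(ages, path)
  expect_equal(read_ages(path), ages)
  # father recorded as female
  bad <- data.frame(fid = "F", id = c("FA", "CH"), father = c("0", "FA"),
                    mother = c("0", "0"), sex = c(2L, 0L), phen = -9L,
                    stringsAsFactors = FALSE)
  expect_error(pedigree(bad), "father")
})
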