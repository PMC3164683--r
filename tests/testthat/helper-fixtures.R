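# Fixture builders and independent oracles used across test files.

# A genotype_matrix from an explicit SNP x individual matrix.
make_gm <- function(geno, chrom = NULL, pos = NULL) {
  m <- nrow(geno)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(pos)) pos <- seq_len(m) * 2e6
  map <- data.frame(snp = sprintf("s%03d", seq_len(m)), chrom = chrom,
                    pos = pos, allele_a = "A", allele_b = "B",
                    stringsAsFactors = FALSE)
  rownames(geno) <- map$snp
  genotype_matrix(map, geno)
}

# A nuclear family where every marker is informative for the mother:
# mother het (1), father hom-ref (0), child genotype = transmitted allele.
# transmitted: M x n_children matrix of 0/1.
make_informative_family <- function(transmitted, pos = NULL, chrom = NULL) {
  M <- nrow(transmitted); k <- ncol(transmitted)
  kids <- paste0("C", seq_len(k))
  geno <- cbind(matrix(1L, M, 1), matrix(0L, M, 1),
                matrix(as.integer(transmitted), M, k))
  colnames(geno) <- c("MO", "FA", kids)
  gm <- make_gm(geno, chrom = chrom, pos = pos)
  ind <- data.frame(
    fid = "FAM1", id = c("FA", "MO", kids),
    father = c("0", "0", rep("FA", k)),
    mother = c("0", "0", rep("MO", k)),
    sex = c(1L, 2L, rep(0L, k)), phen = -9L, stringsAsFactors = FALSE)
  fam <- structure(list(family_id = "FAM1", father = "FA", mother = "MO",
                        children = kids), class = "nuclear_family")
  list(gm = gm, ped = pedigree(ind), family = fam)
}

# Exhaustive minimum-recombinant oracle: enumerate every parental phase
# over M informative markers and count the fewest total inheritance-state
# switches consistent with the transmitted alleles.
oracle_min_recombinants <- function(transmitted) {
  M <- nrow(transmitted); k <- ncol(transmitted)
  stopifnot(M <= 16)
  best <- Inf
  for (code in 0:(2^M - 1)) {
    h <- bitwAnd(bitwShiftR(code, 0:(M - 1)), 1L)
    tot <- 0
    for (cc in seq_len(k)) {
      s <- xor(transmitted[, cc] == 1, h == 1)
      tot <- tot + sum(s[-1] != s[-M])
    }
    best <- min(best, tot)
  }
  best
}

# Monte-Carlo oracle for the exact Hardy-Weinberg test: probability, under
# random pairing of the observed alleles, of a heterozygote count whose
# frequency is no higher than the observed one.
hwe_mc_oracle <- function(n_aa, n_ab, n_bb, B = 40000) {
  n <- n_aa + n_ab + n_bb
  alleles <- c(rep(0L, 2L * n_aa + n_ab), rep(1L, 2L * n_bb + n_ab))
  hets <- replicate(B, {
    a <- sample(alleles)
    sum(a[seq(1, 2 * n, 2)] != a[seq(2, 2 * n, 2)])
  })
  pmf <- table(hets) / B
  p_obs <- pmf[as.character(n_ab)]
  if (is.na(p_obs)) p_obs <- 0
  sum(pmf[pmf <= p_obs + 1e-12])
}

# Mendelian feasibility used as an independent check in simulator tests.
mendel_feasible <- function(f, m, c) {
  c >= (f == 2) + (m == 2) & c <= 2 - ((f == 0) + (m == 0))
}
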