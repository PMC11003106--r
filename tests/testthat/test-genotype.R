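make_counts <- function(nA, nB, labels = c("B73", "Mo17")) {
  dt <- data.table::data.table(barcode = paste0("c", seq_along(nA)))
  dt[[labels[1]]] <- nA
  dt[[labels[2]]] <- nB
  dt$n <- nA + nB
  dt
}

test_that("allele counting matches a brute-force per-read lookup", {
  sim <- sim_small()
  snps <- ref_small()$snps
  counts <- count_alleles(sim$fragments, snps)

  fr <- sim$fragments[!is.na(allele)]
  skey <- paste0(snps$chrom, ":", snps$pos)
  si <- match(paste0(fr$snp_chrom, ":", fr$snp_pos), skey)
  brute <- list(B73 = tapply(as.numeric(fr$allele == snps$B73[si]),
                             fr$barcode, sum),
                Mo17 = tapply(as.numeric(fr$allele == snps$Mo17[si]),
                              fr$barcode, sum))
  m <- match(counts$barcode, names(brute$B73))
  expect_equal(counts$B73, as.numeric(brute$B73[m]))
  expect_equal(counts$Mo17, as.numeric(brute$Mo17[m]))
  expect_equal(counts$n, counts$B73 + counts$Mo17)
})

test_that("noiseless singlets, SNP-free reads and foreign alleles", {
  snps <- data.table::data.table(chrom = "chr1", pos = c(100L, 200L),
                                 ref = c("A", "C"), alt = c("G", "T"),
                                 B73 = c("A", "C"), Mo17 = c("G", "T"))
  fr <- data.table::data.table(
    barcode = "cell",
    snp_chrom = c("chr1", "chr1", NA, "chr1"),
    snp_pos = c(100L, 200L, NA, 100L),
    allele = c("A", "C", NA, "T"))   # last read carries neither allele
  cnt <- count_alleles(fr, snps)
  expect_equal(cnt$B73, 2)
  expect_equal(cnt$Mo17, 0)
  expect_equal(cnt$n, 2)

  # a SNP identical across genotypes is excluded with a warning
  snps2 <- rbind(snps, data.table::data.table(
    chrom = "chr1", pos = 300L, ref = "A", alt = "G",
    B73 = "A", Mo17 = "A"))
  expect_warning(count_alleles(fr, snps2), "identical")
})

test_that("posterior calls match direct likelihood evaluation", {
  p <- genotype_params()
  # pure genotype-A cell: overwhelming singlet posterior
  a <- genotype_posterior(make_counts(100, 0), p)
  expect_equal(a$call, "B73")
  expect_gt(a$posterior_max, 0.999)
  # 50/50 cell: collision dominates
  b <- genotype_posterior(make_counts(50, 50), p)
  expect_equal(b$call, "collision")
  # below the 50-read floor: unassigned
  c_ <- genotype_posterior(make_counts(30, 19), p)
  expect_equal(c_$call, "unassigned")
  expect_equal(genotype_posterior(make_counts(0, 0), p)$call, "unassigned")
})

test_that("posteriors agree with a brute-force per-read product (n <= 20)", {
  eps <- 0.05
  brute_post <- function(cnt, G) {
    singlet_p <- function(g) {
      p <- rep(eps / (G - 1), G); p[g] <- 1 - eps; p
    }
    lik <- numeric(G + 1)
    for (g in 1:G) lik[g] <- prod(singlet_p(g)^cnt)
    pairs <- utils::combn(G, 2)
    best <- 0
    for (j in seq_len(ncol(pairs))) {
      p <- 0.5 * singlet_p(pairs[1, j]) + 0.5 * singlet_p(pairs[2, j])
      best <- max(best, prod(p^cnt))
    }
    lik[G + 1] <- best
    lik / sum(lik)
  }
  set.seed(5)
  params <- genotype_params(min_reads = 1)
  for (G in 2:3) {
    labels <- paste0("g", 1:G)
    for (i in 1:25) {
      cnt <- as.numeric(rmultinom(1, sample(1:20, 1), runif(G)))
      dt <- data.table::data.table(barcode = "x")
      for (j in 1:G) dt[[labels[j]]] <- cnt[j]
      dt$n <- sum(cnt)
      res <- genotype_posterior(dt, params)
      got <- unlist(res[, paste0("posterior_", c(labels, "collision")),
                        with = FALSE])
      expect_equal(unname(got), brute_post(cnt, G), tolerance = 1e-10)
    }
  }
})

test_that("calls are invariant under genotype label permutation", {
  set.seed(8)
  nA <- rbinom(200, 80, 0.6) + 20
  nB <- 100 - nA + rbinom(200, 10, 0.5)
  d1 <- make_counts(nA, nB, c("g1", "g2"))
  d2 <- make_counts(nB, nA, c("g2", "g1"))   # swapped columns and labels
  data.table::setcolorder(d2, c("barcode", "g2", "g1", "n"))
  r1 <- genotype_posterior(d1, genotype_params(min_reads = 1))
  r2 <- genotype_posterior(d2, genotype_params(min_reads = 1))
  expect_identical(r1$call, r2$call)
  expect_equal(r1$posterior_max, r2$posterior_max)
  # posteriors always sum to 1
  ps <- as.matrix(r1[, c("posterior_g1", "posterior_g2",
                         "posterior_collision"), with = FALSE])
  expect_equal(unname(rowSums(ps)), rep(1, nrow(ps)))
})

test_that("contamination is the mismatching-read fraction of singlets", {
  cnt <- make_counts(c(97, 50), c(3, 50))
  res <- genotype_posterior(cnt)
  expect_equal(res$contamination[1], 0.03)
  expect_true(is.na(res$contamination[2]))       # collision: undefined
  expect_equal(contamination_rate(cnt, res), res$contamination)
})

test_that("noiseless single-genotype singlets show zero contamination", {
  r <- make_reference(seed = 44L, chrom_lengths = c(chr1 = 6e5),
                      n_genes = 10L, n_acrs = 40L,
                      genotype_labels = c("B73", "Mo17"), snp_rate = 1e-3)
  d <- sim_design(n_nuclei = 60L, lambda = 1, frags_mean = 800,
                  frags_size = 20, hopping_rate = 0, seq_error = 0,
                  genotype_probs = c(1, 0), seed = 12L)
  sim <- simulate_experiment(r, d, emit_reads = FALSE)
  cnt <- count_alleles(sim$fragments, r$snps)
  res <- genotype_posterior(cnt)
  singlet <- res$call %in% c("B73", "Mo17")
  expect_true(any(singlet))
  expect_true(all(res$contamination[singlet] == 0))
})

test_that("expected-genotype assignment follows the well map", {
  schema <- default_barcode_schema()
  labels <- rep(paste0("G", 1:8), each = 12)     # 8-sample plate layout
  wm <- build_well_map(schema, samples = labels)
  expect_false(anyNA(wm$map$sample))             # map totality

  counts <- data.table::data.table(
    barcode = c("AAA-1", "BBB-1", "CCC-13"),
    G1 = c(98, 50, 10), G2 = c(2, 50, 90))
  counts$n <- counts$G1 + counts$G2
  # wells 1..12 -> G1, wells 13..24 -> G2
  res <- assign_expected_genotype(counts, wm)
  expect_equal(res$expected_genotype, c("G1", "G1", "G2"))
  expect_equal(res$call, c("expected", "collision", "expected"))
  expect_equal(res$contamination, c(0.02, NA, 0.10))

  # unlabelled wells are a configuration error
  wm2 <- build_well_map(schema)
  expect_error(assign_expected_genotype(counts, wm2), "sample")
  wm3 <- build_well_map(schema, samples = c("1" = "G1"))
  expect_error(assign_expected_genotype(counts, wm3), "label")
})
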