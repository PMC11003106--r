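test_that("gene windows follow strand-relative flanks", {
  genes <- data.table::data.table(
    chrom = "chr1", start = 1000L, end = 2000L, strand = "+",
    gene_id = "gA")
  sites <- data.table::data.table(
    chrom = "chr1", pos = c(600L, 2050L, 499L, 2100L),
    group = "ct1")
  m <- gene_accessibility(sites, genes)
  expect_equal(m["gA", "ct1"], 2L)     # [500, 2100): 600 and 2050 inside

  gm <- data.table::data.table(
    chrom = "chr1", start = 1000L, end = 2000L, strand = "-",
    gene_id = "gB")
  # minus strand: [900, 2500)
  m2 <- gene_accessibility(
    data.table::data.table(chrom = "chr1",
                           pos = c(899L, 900L, 2499L, 2500L),
                           group = "ct1"), gm)
  expect_equal(m2["gB", "ct1"], 2L)

  expect_warning(
    gene_accessibility(sites, genes[, .(chrom, start, end, gene_id)]),
    "unstranded")
  # no matching sites -> zero row
  far <- data.table::data.table(chrom = "chr9", pos = 1L, group = "ct1")
  empty <- gene_accessibility(far, genes)
  expect_equal(unname(empty["gA", "ct1"]), 0L)
})

test_that("gene counts equal a brute-force overlap scan", {
  set.seed(10)
  ng <- 40L
  genes <- data.table::data.table(
    chrom = "chr1", start = seq(0L, by = 5000L, length.out = ng),
    strand = sample(c("+", "-"), ng, TRUE),
    gene_id = paste0("g", 1:ng))
  genes[, end := start + 2000L]
  sites <- data.table::data.table(
    chrom = "chr1", pos = sample.int(2e5, 3000L) - 1L,
    group = sample(c("x", "y"), 3000L, TRUE))
  m <- gene_accessibility(sites, genes)
  for (i in c(1L, 7L, 25L)) {
    lo <- if (genes$strand[i] == "+") genes$start[i] - 500L else
      genes$start[i] - 100L
    hi <- if (genes$strand[i] == "+") genes$end[i] + 100L else
      genes$end[i] + 500L
    for (grp in c("x", "y")) {
      brute <- sum(sites$group == grp & sites$pos >= lo & sites$pos < hi)
      expect_equal(unname(m[genes$gene_id[i], grp]), brute)
    }
  }
})

test_that("CPM and Z-score normalisation behave as defined", {
  mat <- rbind(f1 = c(1, 2, 3), f2 = c(99, 98, 97))
  colnames(mat) <- c("a", "b", "c")
  res <- cpm_zscore(mat)
  expect_equal(unname(colSums(res$cpm)), rep(1e6, 3))
  # feature with CPM 1e4/2e4/3e4 -> Z (-1, 0, 1) under sample sd
  expect_equal(unname(res$z["f1", ]), c(-1, 0, 1))
  # identical columns -> all Z zero
  same <- cbind(a = c(5, 10), b = c(5, 10))
  expect_equal(unname(cpm_zscore(same)$z), matrix(0, 2, 2))
  # CPM-then-Z is invariant to positive column scaling
  scaled <- mat
  scaled[, 2] <- scaled[, 2] * 7
  expect_equal(cpm_zscore(scaled)$z, res$z)
  # zero-count group excluded with a warning
  withzero <- cbind(mat, d = c(0, 0))
  expect_warning(res2 <- cpm_zscore(withzero), "zero total")
  expect_equal(colnames(res2$cpm), c("a", "b", "c"))
})

test_that("the ACR master list merges greedily and filters on CPM", {
  chrlen <- c(chr1 = 100000L)
  acrs <- data.table::data.table(
    chrom = "chr1",
    summit = c(10000L, 10600L, 30000L, 30100L, 60000L),
    score = c(50, 40, 10, 90, 5),
    group = "ct1")
  # plenty of sites in the kept 10000/10600/30100 windows, none at 60000
  sites <- data.table::data.table(
    chrom = "chr1",
    pos = c(9900L + 1:30, 10550L + 1:30, 30090L + 1:30),
    group = rep(c("ct1", "ct2"), length.out = 90))
  ml <- build_acr_master_list(acrs, sites, chrom_lengths = chrlen)
  # 600 bp apart -> both kept; 100 bp apart -> higher score (30100) wins;
  # 60000 has zero counts in every group -> removed by the CPM filter
  expect_setequal(ml$summit, c(10000L, 10600L, 30100L))
  # windows are exactly 500 bp and pairwise non-overlapping
  expect_true(all(ml$end - ml$start == 500L))
  m <- ml[order(start)]
  expect_true(all(m$start[-1] >= m$end[-nrow(m)]))

  # missing summit falls back to the interval midpoint with a flag
  acr2 <- data.table::data.table(
    chrom = "chr1", start = 5000L, end = 6000L, summit = NA_integer_,
    score = 1, group = "ct1")
  site2 <- data.table::data.table(chrom = "chr1", pos = 5490L + 1:10,
                                  group = "ct1")
  ml2 <- build_acr_master_list(acr2, site2, chrom_lengths = chrlen)
  expect_equal(ml2$summit, 5500L)
  expect_true(ml2$midpoint_summit)
})

test_that("master-list windows never overlap on random input", {
  set.seed(20)
  acrs <- data.table::data.table(
    chrom = sample(c("chr1", "chr2"), 300L, TRUE),
    summit = sample.int(50000L, 300L),
    score = runif(300L), group = "g")
  sites <- data.table::data.table(
    chrom = sample(c("chr1", "chr2"), 5000L, TRUE),
    pos = sample.int(50000L, 5000L, TRUE), group = "g")
  ml <- build_acr_master_list(acrs, sites)
  for (cc in unique(ml$chrom)) {
    m <- ml[chrom == cc][order(start)]
    if (nrow(m) > 1) expect_true(all(m$start[-1] >= m$end[-nrow(m)]))
  }
})

test_that("specificity calls recover planted structure", {
  z <- matrix(0, 4, 3, dimnames = list(paste0("f", 1:4), c("a", "b", "c")))
  z[1, 1] <- 2.5
  z[2, ] <- c(1.5, 1.4, 0)        # max Z 1.5: specific nowhere
  sf <- specific_features(z)
  expect_equal(sf$sets$a, "f1")
  expect_equal(length(sf$sets$b), 0L)
  expect_equal(specific_features(z, Inf)$counts$n, c(0L, 0L, 0L))

  # planted 20% spiked features over eight groups
  set.seed(30)
  nfeat <- 500L
  spiked <- sample(nfeat, 100L)
  counts <- matrix(rpois(nfeat * 8, 50), nfeat, 8,
                   dimnames = list(paste0("f", 1:nfeat), paste0("g", 1:8)))
  for (f in spiked) {
    j <- sample(8, 1)
    counts[f, j] <- counts[f, j] + 500L
  }
  zz <- cpm_zscore(counts)$z
  frac <- sum(specific_features(zz)$counts$n) / nfeat
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / nfeat))
  # counts are monotone non-increasing in the threshold
  n1 <- sum(specific_features(zz, 1)$counts$n)
  n2 <- sum(specific_features(zz, 2)$counts$n)
  n3 <- sum(specific_features(zz, 3)$counts$n)
  expect_true(n1 >= n2 && n2 >= n3)
})

test_that("library correlation is rank-based with average ties", {
  set.seed(50)
  mat <- matrix(rnorm(400), 100, 4,
                dimnames = list(NULL, paste0("lib", 1:4)))
  mat[sample(400, 40)] <- round(mat[sample(400, 40)])   # introduce ties
  got <- library_correlation(mat)
  ranks <- apply(mat, 2, rank)
  want <- stats::cor(ranks)
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(unname(diag(got)), rep(1, 4))
  # reversed ranks give -1
  two <- cbind(a = 1:10, b = 10:1)
  expect_equal(library_correlation(two)["a", "b"], -1)
  # constant column: undefined, NA with warning
  cc <- cbind(a = 1:10, b = rep(2, 10))
  expect_warning(r <- library_correlation(cc), "constant")
  expect_true(is.na(r["a", "b"]))
})
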