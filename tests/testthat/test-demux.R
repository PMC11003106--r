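test_that("the well map enumerates the full A x B cross product", {
  expect_equal(build_well_map(default_barcode_schema())$n_wells, 96L)

  s1 <- barcode_schema("AAAAA", "CCCCC")
  expect_equal(build_well_map(s1)$n_wells, 1L)

  a <- c("AAAAA", "CCCCC", "GGGGG")
  b <- c("TTTTT", "ACACA")
  suppressWarnings(wm <- build_well_map(barcode_schema(a, b)))
  expect_equal(wm$n_wells, 6L)
  # brute-force cross product
  brute <- expand.grid(b = b, a = a, stringsAsFactors = FALSE)
  expect_setequal(paste0(wm$map$a_barcode, ".", wm$map$b_barcode),
                  paste0(brute$a, ".", brute$b))
  expect_equal(sort(wm$map$well_id), 1:6)

  expect_error(barcode_schema(c("AAAAA", "AAAAA"), "CCCCC"), "duplicate")
})

test_that("barcode correction obeys the radius and ambiguity rules", {
  wl <- c("AATAG", "ACGTT", "CGACA")
  expect_equal(correct_barcode("AATAG", wl), "AATAG")
  expect_equal(correct_barcode("AATAC", wl), "AATAG")      # one substitution
  expect_true(is.na(correct_barcode("AATTT", wl)))         # distance 2
  expect_error(correct_barcode("AATA", wl), "length")

  # equidistant tie between two entries is rejected
  wl2 <- c("AAAAA", "AAAAT")
  expect_true(is.na(correct_barcode("AAAAC", wl2)))
})

test_that("correction agrees with an exhaustive Hamming scan", {
  set.seed(42)
  nt <- c("A", "C", "G", "T")
  for (mm in 1:2) {
    wl <- unique(replicate(8, paste0(sample(nt, 6, TRUE), collapse = "")))
    obs <- replicate(300, paste0(sample(nt, 6, TRUE), collapse = ""))
    got <- correct_barcode(obs, wl, max_mismatch = mm)
    want <- vapply(obs, correct_oracle, character(1), whitelist = wl,
                   max_mismatch = mm)
    expect_identical(unname(got), unname(want))
  }
})

test_that("error-free synthetic reads demultiplex to their true identity", {
  sim <- sim_small()
  idx <- 1:20000
  dm <- demux_reads(sim$reads[idx], sim$schema, sim$well_map)
  expect_true(all(dm$status == "assigned"))
  tf <- sim$truth$fragments[idx]
  nuc <- sim$truth$nuclei
  expect_identical(dm$bead, tf$obs_bead)
  expect_identical(dm$well, nuc$well_id[tf$nucleus_id])
  # demultiplexing corrected reads again changes nothing (idempotence)
  again <- demux_reads(
    data.table::data.table(read_id = dm$read_id,
                           name = paste0(dm$read_id, "_", dm$bead),
                           seq1 = sim$reads$seq1[idx],
                           seq2 = sim$reads$seq2[idx]),
    sim$schema, sim$well_map)
  expect_identical(again$cell_barcode, dm$cell_barcode)
})

test_that("reads with correctable and uncorrectable errors are handled", {
  sim <- sim_small()
  r <- sim$reads[1:4]
  flip <- function(s, i, to) {
    substr(s, i, i) <- to
    s
  }
  # one substitution in the A-barcode: corrected
  r1 <- data.table::copy(r)
  b1 <- substr(r1$seq1[1], 1, 1)
  r1$seq1[1] <- flip(r1$seq1[1], 1L, setdiff(c("A", "C", "G", "T"), b1)[1])
  dm <- demux_reads(r1, sim$schema, sim$well_map)
  expect_equal(dm$status[1], "assigned")
  # two substitutions: rejected as bad_a
  r2 <- data.table::copy(r)
  for (i in 1:2) {
    bi <- substr(r2$seq1[1], i, i)
    r2$seq1[1] <- flip(r2$seq1[1], i, setdiff(c("A", "C", "G", "T"), bi)[1])
  }
  dm2 <- demux_reads(r2, sim$schema, sim$well_map)
  expect_equal(dm2$status[1], "bad_a")
  # malformed read name
  r3 <- data.table::copy(r)
  r3$name[1] <- "noseparator"
  expect_error(demux_reads(r3, sim$schema, sim$well_map), "malformed")
})

test_that("demux recovers >= 99% true wells under 1% per-base errors", {
  sim <- sim_small()
  idx <- 1:10000
  reads <- data.table::copy(sim$reads[idx])
  set.seed(7)
  nt <- c("A", "C", "G", "T")
  mutate <- function(s, positions) {
    for (j in seq_along(s)) {
      for (p in positions) {
        if (runif(1) < 0.01) {
          cur <- substr(s[j], p, p)
          substr(s[j], p, p) <- sample(setdiff(nt, cur), 1)
        }
      }
    }
    s
  }
  reads$seq1 <- mutate(reads$seq1, 1:5)
  reads$seq2 <- mutate(reads$seq2, 1:5)
  bead <- sub(".*_", "", reads$name)
  bead <- mutate(bead, 1:16)
  reads$name <- paste0(reads$read_id, "_", bead)

  dm <- demux_reads(reads, sim$schema, sim$well_map)
  tf <- sim$truth$fragments[idx]
  truew <- sim$truth$nuclei$well_id[tf$nucleus_id]
  ok <- dm$status == "assigned"
  expect_gt(mean(ok), 0.95)
  expect_gte(mean(dm$well[ok] == truew[ok]), 0.99)
  expect_gte(mean(dm$bead[ok] == tf$obs_bead[ok]), 0.99)
})

test_that("combo filtering separates nuclei from hopped background", {
  combos <- data.table::data.table(
    bead = c("b1", "b1", "b2", "b2"),
    well = c(1L, 2L, 1L, 3L),
    reads = c(980L, 5L, 600L, 550L))
  out <- filter_bead_well_combos(combos, min_reads = 100, min_frac = 0.05)
  expect_identical(out$retained, c(TRUE, FALSE, TRUE, TRUE))
  expect_error(filter_bead_well_combos(combos, min_frac = 2), "min_frac")
})

test_that("flagged background reads are overwhelmingly truly hopped", {
  d <- sim_design(n_nuclei = 500L, lambda = 2, frags_mean = 400,
                  frags_size = 20, hopping_rate = 0.02, seed = 17L)
  sim <- simulate_experiment(ref_small(), d, emit_reads = FALSE)
  combos <- combo_counts(sim)
  fc <- filter_bead_well_combos(combos, min_reads = 100, min_frac = 0.02)
  bc <- split_cell_barcode(sim$fragments$barcode)
  key <- paste0(bc$bead, "-", bc$well)
  flagged_keys <- fc[retained == FALSE, paste0(bead, "-", well)]
  flagged <- key %in% flagged_keys
  expect_gte(mean(sim$truth$fragments$hopped[flagged]), 0.95)
  # conservation: every read is retained or flagged, none lost
  expect_equal(sum(fc$reads), nrow(sim$fragments))
  expect_equal(sum(flagged) + sum(key %in%
                                    fc[retained == TRUE,
                                       paste0(bead, "-", well)]),
               nrow(sim$fragments))
})

test_that("with zero simulated errors demux recovers every truth assignment", {
  r <- make_reference(seed = 9L, chrom_lengths = c(chr1 = 3e5),
                      n_genes = 10L, n_acrs = 20L, snp_rate = 0)
  d <- sim_design(n_nuclei = 80L, lambda = 2, frags_mean = 50,
                  hopping_rate = 0, seq_error = 0, seed = 10L)
  sim <- simulate_experiment(r, d, emit_reads = TRUE)
  dm <- demux_reads(sim$reads, sim$schema, sim$well_map)
  nuc <- sim$truth$nuclei
  tf <- sim$truth$fragments
  expect_true(all(dm$status == "assigned"))
  expect_identical(dm$cell_barcode,
                   paste0(nuc$bead_barcode[tf$nucleus_id], "-",
                          nuc$well_id[tf$nucleus_id]))
})
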