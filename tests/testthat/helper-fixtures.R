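# Shared fixtures, built once per test run and memoised.
.fix <- new.env(parent = emptyenv())

ref_small <- function() {
  if (is.null(.fix$ref)) {
    .fix$ref <- make_reference(
      seed = 11L,
      chrom_lengths = c(chr1 = 1e6, chr2 = 8e5),
      organelle_lengths = c(org1 = 5e4),
      n_genes = 40L, n_acrs = 150L,
      genotype_labels = c("B73", "Mo17"), snp_rate = 7e-4)
  }
  .fix$ref
}

# 400 nuclei, lambda 2, modest fragment depth, reads emitted
sim_small <- function() {
  if (is.null(.fix$sim)) {
    d <- sim_design(n_nuclei = 400L, lambda = 2, frags_mean = 200,
                    frags_size = 10, hopping_rate = 0.02,
                    seq_error = 0.01, seed = 5L)
    .fix$sim <- simulate_experiment(ref_small(), d, emit_reads = TRUE)
  }
  .fix$sim
}

# (bead, well) read counts of a simulation's fragment records
combo_counts <- function(sim) {
  bc <- split_cell_barcode(sim$fragments$barcode)
  data.table::data.table(bc)[, .(reads = .N), by = .(bead, well)]
}

# brute-force Hamming distance between equal-length strings
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# brute-force whitelist correction oracle
correct_oracle <- function(obs, whitelist, max_mismatch) {
  d <- vapply(whitelist, hamming, integer(1), a = obs)
  dm <- min(d)
  if (dm <= max_mismatch && sum(d == dm) == 1L) whitelist[which.min(d)]
  else NA_character_
}
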