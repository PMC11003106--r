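#' Simulation design for a synthetic scifi-ATAC-seq experiment
#'
#' Bundles every tunable of the generator. Defaults reproduce the
#' overloaded-droplet regime of a pre-indexed experiment: a zero-truncated
#' Poisson droplet occupancy whose mean is about 3.4 nuclei per occupied
#' droplet (lambda = 3.27), 96 Tn5 wells, negative-binomially dispersed
#' fragment counts, a bimodal fragment-size mixture (nucleosome-free +
#' mononucleosome), 5x fragment enrichment inside ACRs, an index-hopping
#' rate of 3% of reads and a 1% per-informative-read allele error.
#'
#' @param n_nuclei Number of nuclei loaded (recovered into droplets).
#' @param lambda Zero-truncated Poisson parameter for nuclei per occupied
#'   droplet; the realised mean occupancy is `lambda / (1 - exp(-lambda))`.
#' @param n_wells Number of Tn5 pre-indexing wells (default 96).
#' @param well_probs Optional per-well loading probabilities (length
#'   `n_wells`, need not be normalised); `NULL` = uniform.
#' @param well_sample_map Optional named character vector `well_id ->
#'   genotype label` enabling multiplexed mode: a nucleus's genotype is
#'   determined by its well. `NULL` = genotypes drawn per nucleus.
#' @param genotype_probs Optional sampling weights over the reference's
#'   genotype labels (ignored in multiplexed mode); `NULL` = uniform.
#' @param frags_mean,frags_size Negative-binomial mean and size
#'   (dispersion) of fragments per nucleus.
#' @param hopping_rate Probability that a read is emitted under the bead
#'   barcode of *another* occupied droplet, drawn in proportion to that
#'   droplet's fragment abundance (its Tn5 well barcodes are untouched).
#' @param seq_error Probability that a read overlapping a SNP reports the
#'   other allele (applied per informative read).
#' @param organelle_frac Probability a fragment derives from an organelle
#'   scaffold.
#' @param acr_enrichment Fold enrichment of fragment density inside ACRs
#'   relative to the nuclear background.
#' @param frag_sizes List with `short_mean`, `short_sd`, `mono_mean`,
#'   `mono_sd`, `w_short`: the nucleosome-free/mononucleosome size mixture.
#' @param dup_rate PCR duplication knob: fraction of fragments re-emitted
#'   once as exact duplicates.
#' @param seed Integer seed; one RNG stream drives all draws.
#'
#' @return An object of class `scifi_design` (a validated list).
#' @export
sim_design <- function(n_nuclei = 5000L,
                       lambda = 3.27,
                       n_wells = 96L,
                       well_probs = NULL,
                       well_sample_map = NULL,
                       genotype_probs = NULL,
                       frags_mean = 1000,
                       frags_size = 4,
                       hopping_rate = 0.03,
                       seq_error = 0.01,
                       organelle_frac = 0.08,
                       acr_enrichment = 5,
                       frag_sizes = list(short_mean = 80, short_sd = 20,
                                         mono_mean = 200, mono_sd = 30,
                                         w_short = 0.6),
                       dup_rate = 0,
                       seed = 1L) {
  if (!is.numeric(lambda) || lambda <= 0)
    stop("lambda must be > 0")
  if (hopping_rate < 0 || hopping_rate >= 1)
    stop("hopping_rate must be in [0, 1)")
  if (seq_error < 0 || seq_error >= 0.5)
    stop("seq_error must be in [0, 0.5)")
  stopifnot(n_nuclei >= 1, n_wells >= 1, frags_mean > 0, frags_size > 0,
            organelle_frac >= 0, organelle_frac < 1, acr_enrichment > 0,
            dup_rate >= 0, dup_rate < 1)
  if (!is.null(well_probs)) {
    stopifnot(length(well_probs) == n_wells, all(well_probs >= 0),
              sum(well_probs) > 0)
  }
  if (!is.null(well_sample_map)) {
    if (is.null(names(well_sample_map)))
      stop("well_sample_map must be named by well id")
  }
  structure(list(
    n_nuclei = as.integer(n_nuclei), lambda = lambda,
    n_wells = as.integer(n_wells), well_probs = well_probs,
    well_sample_map = well_sample_map, genotype_probs = genotype_probs,
    frags_mean = frags_mean, frags_size = frags_size,
    hopping_rate = hopping_rate, seq_error = seq_error,
    organelle_frac = organelle_frac, acr_enrichment = acr_enrichment,
    frag_sizes = frag_sizes, dup_rate = dup_rate, seed = as.integer(seed)
  ), class = "scifi_design")
}

#' @export
print.scifi_design <- function(x, ...) {
  cat("scifi-ATAC-seq simulation design\n")
  cat(sprintf("  nuclei loaded       : %d\n", x$n_nuclei))
  cat(sprintf("  occupancy           : zero-truncated Poisson(%.3g), mean %.3f\n",
              x$lambda, .ztpois_mean(x$lambda)))
  cat(sprintf("  Tn5 wells           : %d%s\n", x$n_wells,
              if (is.null(x$well_probs)) " (uniform)" else " (weighted)"))
  cat(sprintf("  fragments/nucleus   : NB(mean %.0f, size %.2g)\n",
              x$frags_mean, x$frags_size))
  cat(sprintf("  hopping / seq error : %.3g / %.3g\n",
              x$hopping_rate, x$seq_error))
  cat(sprintf("  organelle fraction  : %.3g;  ACR enrichment: %.3gx\n",
              x$organelle_frac, x$acr_enrichment))
  if (!is.null(x$well_sample_map))
    cat(sprintf("  multiplexed         : %d wells mapped to %d samples\n",
                length(x$well_sample_map),
                length(unique(x$well_sample_map))))
  cat(sprintf("  seed                : %d\n", x$seed))
  invisible(x)
}

#' Read / write a simulation design as YAML
#'
#' @param design A `scifi_design`.
#' @param path File path.
#' @return `design_to_yaml` returns `path` invisibly; `design_from_yaml`
#'   returns a validated `scifi_design`.
#' @export
design_to_yaml <- function(design, path) {
  stopifnot(inherits(design, "scifi_design"))
  x <- unclass(design)
  x$well_sample_map <- if (is.null(x$well_sample_map)) NULL else
    as.list(x$well_sample_map)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname design_to_yaml
#' @export
design_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$well_sample_map))
    x$well_sample_map <- unlist(x$well_sample_map)
  if (!is.null(x$well_probs)) x$well_probs <- as.numeric(x$well_probs)
  x$frag_sizes <- as.list(x$frag_sizes)
  do.call(sim_design, x)
}
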