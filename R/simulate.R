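#' Simulate a complete scifi-ATAC-seq experiment with ground truth
#'
#' Draws droplet occupancies from a zero-truncated Poisson, assigns each
#' nucleus a Tn5 well (and a genotype, either per nucleus or through a
#' multiplexing well->sample map), emits per-nucleus fragments with
#' ACR-enriched genomic placement, an organelle component and a bimodal
#' size mixture, applies index hopping (a read is re-emitted under the
#' bead barcode of another occupied droplet drawn in proportion to its
#' fragment abundance, the inline Tn5 barcodes untouched) and per-read
#' allele errors at overlapped SNPs,
#' and returns fragment records, optional FASTQ-style read records, and a
#' complete truth table.
#'
#' @param ref A [make_reference()] object.
#' @param design A [sim_design()] object.
#' @param schema A [barcode_schema()] used to emit inline Tn5 barcodes;
#'   defaults to [default_barcode_schema()] when the design has 96 wells.
#' @param well_map A [build_well_map()] map consistent with `schema`.
#' @param emit_reads If `FALSE`, skip building read sequences (fragment
#'   records and truth are sufficient for all barcode-level analyses).
#'
#' @return An object of class `scifi_sim`: list with
#'   * `fragments`: `data.table(frag_id, chrom, start, end, barcode,
#'     snp_chrom, snp_pos, allele)` where `barcode` is the *observed*
#'     combined `"<bead>-<well>"` barcode (hopping included);
#'   * `reads`: `data.table(read_id, name, seq1, seq2)` or `NULL`;
#'   * `truth`: list of `nuclei` (nucleus_id, droplet_id, bead_barcode,
#'     well_id, genotype, n_fragments) and `fragments` (frag_id,
#'     nucleus_id, hopped, allele_error, obs_bead);
#'   * `bead_whitelist`, `schema`, `well_map`, `design`, `ref`.
#' @export
simulate_experiment <- function(ref, design, schema = NULL, well_map = NULL,
                                emit_reads = TRUE) {
  stopifnot(inherits(ref, "scifi_reference"), inherits(design, "scifi_design"))
  if (design$lambda <= 0) stop("lambda must be > 0")
  set.seed(design$seed)
  N <- design$n_nuclei

  ## ---- droplet loading: zero-truncated Poisson occupancy ----
  sizes <- integer(0)
  while (sum(sizes) < N) {
    need <- ceiling((N - sum(sizes)) / .ztpois_mean(design$lambda) * 1.1) + 16L
    sizes <- c(sizes, .rztpois(need, design$lambda))
  }
  cut <- which(cumsum(sizes) >= N)[1]
  sizes <- sizes[seq_len(cut)]
  sizes[cut] <- sizes[cut] - (sum(sizes) - N)
  if (sizes[cut] == 0L) sizes <- sizes[-cut]
  D <- length(sizes)
  bead <- .random_barcodes(D, 16L)

  ## ---- nuclei ----
  droplet <- rep.int(seq_len(D), sizes)
  well <- sample.int(design$n_wells, N, replace = TRUE,
                     prob = design$well_probs)
  if (!is.null(design$well_sample_map)) {
    geno <- unname(design$well_sample_map[as.character(well)])
    if (anyNA(geno)) stop("well_sample_map does not cover all wells in use")
    if (!all(unique(geno) %in% ref$genotype_labels))
      stop("well_sample_map labels not in reference genotype labels")
  } else {
    geno <- sample(ref$genotype_labels, N, replace = TRUE,
                   prob = design$genotype_probs)
  }
  n_frags <- rnbinom(N, size = design$frags_size, mu = design$frags_mean)
  nuclei <- data.table(nucleus_id = seq_len(N), droplet_id = droplet,
                       bead_barcode = bead[droplet], well_id = well,
                       genotype = geno, n_fragments = n_frags)

  ## ---- fragments: genomic placement ----
  M <- sum(n_frags)
  if (M == 0L) stop("no fragments emitted; increase frags_mean")
  nuc_of <- rep.int(seq_len(N), n_frags)

  nuc_chr <- setdiff(names(ref$chromosomes), ref$organelle_scaffolds)
  nuc_len <- ref$chromosomes[nuc_chr]
  L <- sum(nuc_len)

  fs <- design$frag_sizes
  short <- runif(M) < fs$w_short
  len <- integer(M)
  len[short] <- pmax(35L, as.integer(round(rnorm(sum(short), fs$short_mean,
                                                 fs$short_sd))))
  len[!short] <- pmax(35L, as.integer(round(rnorm(sum(!short), fs$mono_mean,
                                                  fs$mono_sd))))

  org <- runif(M) < design$organelle_frac
  chrom <- character(M)
  mid <- integer(M)

  n_org <- sum(org)
  if (n_org > 0) {
    olen <- ref$chromosomes[ref$organelle_scaffolds]
    oi <- sample.int(length(olen), n_org, replace = TRUE, prob = olen)
    chrom[org] <- ref$organelle_scaffolds[oi]
    mid[org] <- as.integer(floor(runif(n_org) * olen[oi]))
  }

  n_nucfrag <- M - n_org
  if (n_nucfrag > 0) {
    acr <- ref$acrs
    if (nrow(acr) > 0) {
      aw <- acr$end - acr$start
      A <- sum(aw)
      w_acr <- design$acr_enrichment * A /
        (design$acr_enrichment * A + (L - A))
      in_acr <- runif(n_nucfrag) < w_acr
    } else {
      in_acr <- rep(FALSE, n_nucfrag)
    }
    idx_nuc <- which(!org)
    # inside ACRs: midpoint uniform within an ACR chosen by width
    n_in <- sum(in_acr)
    if (n_in > 0) {
      ai <- sample.int(nrow(acr), n_in, replace = TRUE, prob = aw)
      chrom[idx_nuc[in_acr]] <- acr$chrom[ai]
      mid[idx_nuc[in_acr]] <- acr$start[ai] +
        as.integer(floor(runif(n_in) * aw[ai]))
    }
    # background: midpoint uniform over the non-ACR nuclear space
    n_bg <- n_nucfrag - n_in
    if (n_bg > 0) {
      gaps <- .acr_complement(ref)
      gw <- gaps$end - gaps$start
      gi <- sample.int(nrow(gaps), n_bg, replace = TRUE, prob = gw)
      chrom[idx_nuc[!in_acr]] <- gaps$chrom[gi]
      mid[idx_nuc[!in_acr]] <- gaps$start[gi] +
        as.integer(floor(runif(n_bg) * gw[gi]))
    }
  }

  start <- mid - len %/% 2L
  end <- start + len
  clen <- unname(ref$chromosomes[chrom])
  start <- pmax(start, 0L)
  end <- pmin(end, as.integer(clen))
  bad <- end - start < 35L          # clipped into degeneracy at edges
  if (any(bad)) {
    start[bad] <- pmax(0L, end[bad] - 35L)
    end[bad] <- start[bad] + 35L
  }

  ## ---- PCR duplication knob ----
  keep_id <- seq_len(M)
  if (design$dup_rate > 0) {
    dup <- which(runif(M) < design$dup_rate)
    keep_id <- c(keep_id, dup)
    nuc_of <- nuc_of[keep_id]; chrom <- chrom[keep_id]
    start <- start[keep_id]; end <- end[keep_id]
    M <- length(keep_id)
  }

  ## ---- index hopping: reassign bead barcode of single reads ----
  ## the stray read acquires another droplet's bead barcode in proportion
  ## to that droplet's fragment abundance (swaps draw from the library
  ## pool), never its own
  true_drop <- nuclei$droplet_id[nuc_of]
  obs_drop <- true_drop
  hopped <- rep(FALSE, M)
  if (design$hopping_rate > 0 && D >= 2) {
    hopped <- runif(M) < design$hopping_rate
    n_hop <- sum(hopped)
    if (n_hop > 0) {
      pool <- tabulate(true_drop, nbins = D)
      tgt <- sample.int(D, n_hop, replace = TRUE, prob = pool)
      redo <- which(tgt == true_drop[hopped])
      while (length(redo) > 0) {
        tgt[redo] <- sample.int(D, length(redo), replace = TRUE,
                                prob = pool)
        redo <- redo[tgt[redo] == true_drop[hopped][redo]]
      }
      obs_drop[hopped] <- tgt
    }
  }

  ## ---- SNP alleles carried by reads ----
  snp_idx <- rep(NA_integer_, M)
  allele <- rep(NA_character_, M)
  allele_err <- rep(FALSE, M)
  if (nrow(ref$snps) > 0) {
    fr_gr <- GenomicRanges::GRanges(chrom,
                                    IRanges::IRanges(start + 1L, end))
    snp_gr <- GenomicRanges::GRanges(ref$snps$chrom,
                                     IRanges::IRanges(ref$snps$pos + 1L,
                                                      width = 1L))
    # first overlapped SNP (lowest coordinate within the fragment)
    snp_idx <- GenomicRanges::findOverlaps(fr_gr, snp_gr, select = "first")
    hit <- !is.na(snp_idx)
    if (any(hit)) {
      gsub_geno <- nuclei$genotype[nuc_of[hit]]
      smat <- as.matrix(ref$snps[snp_idx[hit],
                                 ref$genotype_labels, with = FALSE])
      true_allele <- smat[cbind(seq_len(sum(hit)),
                                match(gsub_geno, ref$genotype_labels))]
      flip <- runif(sum(hit)) < design$seq_error
      other <- ifelse(true_allele == ref$snps$ref[snp_idx[hit]],
                      ref$snps$alt[snp_idx[hit]],
                      ref$snps$ref[snp_idx[hit]])
      allele[hit] <- ifelse(flip, other, true_allele)
      allele_err[hit] <- flip
    }
  }

  frag_id <- seq_len(M)
  obs_bead <- bead[obs_drop]
  fragments <- data.table(
    frag_id = frag_id, chrom = chrom, start = start, end = end,
    barcode = paste0(obs_bead, "-", well[nuc_of]),
    snp_chrom = ifelse(is.na(snp_idx), NA_character_,
                       ref$snps$chrom[snp_idx]),
    snp_pos = ifelse(is.na(snp_idx), NA_integer_, ref$snps$pos[snp_idx]),
    allele = allele
  )
  truth_frag <- data.table(frag_id = frag_id, nucleus_id = nuc_of,
                           hopped = hopped, allele_error = allele_err,
                           obs_bead = obs_bead)

  ## ---- reads ----
  reads <- NULL
  if (emit_reads) {
    if (is.null(schema)) {
      if (design$n_wells != 96L)
        stop("supply a barcode_schema/well_map for non-96-well designs")
      schema <- default_barcode_schema(bead_whitelist = bead)
    }
    if (is.null(well_map)) well_map <- build_well_map(schema)
    wm <- well_map$map
    a_of_well <- wm$a_barcode[match(seq_len(design$n_wells), wm$well_id)]
    b_of_well <- wm$b_barcode[match(seq_len(design$n_wells), wm$well_id)]
    me <- "AGATGTGTATAAGAGACAG"   # Tn5 mosaic end
    filler <- strrep("T", 30L)
    wr <- well[nuc_of]
    reads <- data.table(
      read_id = paste0("read", frag_id),
      name = paste0("read", frag_id, "_", obs_bead),
      seq1 = paste0(a_of_well[wr], me, filler),
      seq2 = paste0(b_of_well[wr], me, filler)
    )
  } else {
    if (is.null(schema) && design$n_wells == 96L)
      schema <- default_barcode_schema(bead_whitelist = bead)
    if (is.null(well_map) && !is.null(schema))
      well_map <- build_well_map(schema)
  }

  structure(list(fragments = fragments, reads = reads,
                 truth = list(nuclei = nuclei, fragments = truth_frag),
                 bead_whitelist = bead, schema = schema,
                 well_map = well_map, design = design, ref = ref),
            class = "scifi_sim")
}

# non-ACR nuclear intervals (0-based half-open), used for background draws
.acr_complement <- function(ref) {
  nuc_chr <- setdiff(names(ref$chromosomes), ref$organelle_scaffolds)
  out <- vector("list", length(nuc_chr))
  for (i in seq_along(nuc_chr)) {
    cl <- ref$chromosomes[[nuc_chr[i]]]
    a <- ref$acrs[chrom == nuc_chr[i]]
    if (nrow(a) == 0) {
      out[[i]] <- data.table(chrom = nuc_chr[i], start = 0L,
                             end = as.integer(cl))
      next
    }
    ir <- IRanges::reduce(IRanges::IRanges(a$start + 1L, a$end))
    gap <- IRanges::gaps(ir, start = 1L, end = as.integer(cl))
    out[[i]] <- data.table(chrom = nuc_chr[i],
                           start = IRanges::start(gap) - 1L,
                           end = IRanges::end(gap))
  }
  rbindlist(out)
}

#' @export
print.scifi_sim <- function(x, ...) {
  cat("Synthetic scifi-ATAC-seq experiment\n")
  cat(sprintf("  nuclei / droplets   : %d / %d (mean occupancy %.3f)\n",
              nrow(x$truth$nuclei),
              length(unique(x$truth$nuclei$droplet_id)),
              nrow(x$truth$nuclei) /
                length(unique(x$truth$nuclei$droplet_id))))
  cat(sprintf("  fragments           : %d (%.2f%% hopped)\n",
              nrow(x$fragments), 100 * mean(x$truth$fragments$hopped)))
  cat(sprintf("  reads emitted       : %s\n",
              if (is.null(x$reads)) "no" else format(nrow(x$reads))))
  invisible(x)
}
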