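#' Build a synthetic reference for a pre-indexed scATAC-seq experiment
#'
#' Creates a small multi-chromosome reference with gene annotation
#' (non-overlapping gene bodies and their TSSs), accessible chromatin
#' regions (ACRs), organelle scaffolds and a table of homozygous biallelic
#' SNPs distinguishing the designed genotypes. The reference mimics the
#' inputs a real analysis would load from a GFF gene annotation, an ACR
#' BED file and a filtered variant panel: a SNP density of about 0.70
#' per kb is the field-typical value for a diverse maize panel.
#'
#' Genes are laid out on a per-chromosome grid (one gene per slot) so they
#' never overlap. A configurable fraction of ACRs is promoter-proximal,
#' i.e. centred within +/-1750 bp of a TSS (at most three per gene), with
#' the remainder placed distally on a grid; this yields nuclei whose TSS
#' and FRiP fractions resemble real chromatin data once fragments are
#' drawn with ACR enrichment (see [simulate_experiment()]).
#'
#' @param seed Integer seed; the same seed reproduces the reference exactly.
#' @param chrom_lengths Named integer vector of nuclear chromosome lengths
#'   (bp).
#' @param organelle_lengths Named integer vector of organelle scaffold
#'   lengths; organelle scaffolds carry no genes, ACRs or SNPs.
#' @param n_genes,n_acrs Number of genes / ACRs to place genome-wide.
#' @param genotype_labels Character vector of genotype names (>= 1).
#' @param snp_rate Expected SNPs per bp (0.0007 = 0.70/kb).
#' @param gene_length_range Min/max gene body length, bp.
#' @param acr_width ACR width in bp (default 500).
#' @param frac_acr_promoter Fraction of ACRs placed promoter-proximally.
#'
#' @return An object of class `scifi_reference`: a list with elements
#'   `chromosomes` (named lengths incl. organelles), `organelle_scaffolds`,
#'   `genes`, `tss`, `acrs`, `snps` (all `data.table`s, BED-style 0-based
#'   half-open coordinates), and `genotype_labels`.
#' @export
make_reference <- function(seed = 1L,
                           chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                           organelle_lengths = c(scaf_organelle1 = 150000,
                                                 scaf_organelle2 = 200000),
                           n_genes = 320L,
                           n_acrs = 1600L,
                           genotype_labels = c("B73", "Mo17"),
                           snp_rate = 7e-4,
                           gene_length_range = c(1000L, 5000L),
                           acr_width = 500L,
                           frac_acr_promoter = 0.6) {
  stopifnot(length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)),
            snp_rate >= 0, length(genotype_labels) >= 1,
            n_genes >= 0, n_acrs >= 0)
  chrom_lengths <- round(chrom_lengths)
  organelle_lengths <- round(organelle_lengths)
  set.seed(seed)

  chroms <- names(chrom_lengths)
  total_len <- sum(chrom_lengths)

  ## ---- genes: one per grid slot, never overlapping ----
  genes <- data.table(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      gene_id = character(0))
  if (n_genes > 0) {
    n_per <- round(n_genes * chrom_lengths / total_len)
    # fix rounding so totals match
    n_per[1] <- n_per[1] + n_genes - sum(n_per)
    glist <- vector("list", length(chroms))
    for (i in seq_along(chroms)) {
      ni <- n_per[i]
      if (ni == 0) next
      L <- chrom_lengths[i]
      slot <- L / ni
      if (slot < gene_length_range[1] + 2)
        stop("chromosome ", chroms[i], " too short to host ", ni, " genes")
      len <- round(runif(ni, gene_length_range[1],
                         min(gene_length_range[2], slot - 1)))
      start <- floor((seq_len(ni) - 1) * slot +
                       runif(ni, 0, slot - len - 1))
      glist[[i]] <- data.table(chrom = chroms[i], start = as.integer(start),
                               end = as.integer(start + len),
                               strand = sample(c("+", "-"), ni, replace = TRUE))
    }
    genes <- rbindlist(glist)
    genes[, gene_id := sprintf("gene%04d", seq_len(nrow(genes)))]
  }
  tss <- if (nrow(genes)) {
    genes[, .(chrom, pos = ifelse(strand == "+", start, end - 1L), gene_id)]
  } else {
    data.table(chrom = character(0), pos = integer(0), gene_id = character(0))
  }

  ## ---- ACRs: promoter-proximal + distal grid ----
  acrs <- data.table(chrom = character(0), start = integer(0),
                     end = integer(0), promoter = logical(0))
  if (n_acrs > 0) {
    half <- acr_width %/% 2
    n_prom <- min(round(frac_acr_promoter * n_acrs), 3L * nrow(genes))
    alist <- list()
    if (n_prom > 0) {
      # three candidate slots per gene, offsets keep windows disjoint
      slots <- data.table(gene = rep(seq_len(nrow(tss)), each = 3L),
                          off = rep(c(-1250L, 0L, 1250L), nrow(tss)))
      pick <- slots[sample(.N, n_prom)]
      centre <- tss$pos[pick$gene] + pick$off +
        as.integer(round(runif(n_prom, -300, 300)))
      alist$prom <- data.table(chrom = tss$chrom[pick$gene],
                               start = centre - half,
                               end = centre - half + acr_width,
                               promoter = TRUE)
    }
    n_dist <- n_acrs - n_prom
    if (n_dist > 0) {
      n_per <- round(n_dist * chrom_lengths / total_len)
      n_per[1] <- n_per[1] + n_dist - sum(n_per)
      dlist <- vector("list", length(chroms))
      for (i in seq_along(chroms)) {
        ni <- n_per[i]
        if (ni == 0) next
        L <- chrom_lengths[i]
        slot <- L / ni
        if (slot < acr_width + 2)
          stop("chromosome ", chroms[i], " too short to host ", ni, " ACRs")
        start <- floor((seq_len(ni) - 1) * slot +
                         runif(ni, 0, slot - acr_width - 1))
        dlist[[i]] <- data.table(chrom = chroms[i],
                                 start = as.integer(start),
                                 end = as.integer(start + acr_width),
                                 promoter = FALSE)
      }
      alist$dist <- rbindlist(dlist)
    }
    acrs <- rbindlist(alist)
    # clip to chromosome bounds
    acrs[, start := pmax(start, 0L)]
    acrs[, end := pmin(end, as.integer(chrom_lengths[chrom]))]
    setorder(acrs, chrom, start)
  }

  ## ---- SNPs: Binomial(L, rate) per chromosome, biallelic, homozygous ----
  slist <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    n_snp <- rbinom(1L, chrom_lengths[i], snp_rate)
    if (n_snp == 0) next
    p <- sort(sample.int(chrom_lengths[i], n_snp)) - 1L
    slist[[i]] <- data.table(chrom = chroms[i], pos = p)
  }
  snps <- rbindlist(slist[!vapply(slist, is.null, TRUE)])
  if (is.null(snps) || nrow(snps) == 0) {
    snps <- data.table(chrom = character(0), pos = integer(0),
                       ref = character(0), alt = character(0))
    for (g in genotype_labels) snps[, (g) := character(0)]
  } else {
    nt <- c("A", "C", "G", "T")
    ref <- sample(nt, nrow(snps), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1L), character(1))
    snps[, `:=`(ref = ref, alt = unname(alt))]
    G <- length(genotype_labels)
    take_alt <- matrix(runif(nrow(snps) * G) < 0.5, ncol = G)
    if (G >= 2) {
      # every SNP must be informative: not all genotypes identical
      mono <- rowSums(take_alt) %in% c(0L, G)
      while (any(mono)) {
        take_alt[mono, ] <- matrix(runif(sum(mono) * G) < 0.5, ncol = G)
        mono <- rowSums(take_alt) %in% c(0L, G)
      }
    }
    for (j in seq_len(G)) {
      snps[, (genotype_labels[j]) := ifelse(take_alt[, j], alt, ref)]
    }
  }
  snps[, snp_id := seq_len(.N)]

  structure(list(
    chromosomes = c(chrom_lengths, organelle_lengths),
    organelle_scaffolds = names(organelle_lengths),
    genes = genes, tss = tss, acrs = acrs, snps = snps,
    genotype_labels = genotype_labels,
    seed = seed
  ), class = "scifi_reference")
}

#' @export
print.scifi_reference <- function(x, ...) {
  nuc <- setdiff(names(x$chromosomes), x$organelle_scaffolds)
  cat("Synthetic scifi-ATAC-seq reference\n")
  cat(sprintf("  nuclear chromosomes : %d (%.2f Mb)\n", length(nuc),
              sum(x$chromosomes[nuc]) / 1e6))
  cat(sprintf("  organelle scaffolds : %d (%.2f Mb)\n",
              length(x$organelle_scaffolds),
              sum(x$chromosomes[x$organelle_scaffolds]) / 1e6))
  cat(sprintf("  genes / TSSs        : %d\n", nrow(x$genes)))
  cat(sprintf("  ACRs                : %d (%d promoter-proximal)\n",
              nrow(x$acrs), sum(x$acrs$promoter)))
  cat(sprintf("  SNPs                : %d (%.2f/kb) over genotypes: %s\n",
              nrow(x$snps),
              nrow(x$snps) / sum(x$chromosomes[nuc]) * 1000,
              paste(x$genotype_labels, collapse = ", ")))
  invisible(x)
}
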