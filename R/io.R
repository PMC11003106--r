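#' Write a simulated experiment to plain-text fixture files
#'
#' Materialises a [simulate_experiment()] result in the formats a real
#' pipeline would exchange: paired FASTQ (bead barcode appended to the
#' read name after `"_"`, inline Tn5 barcodes at the insert starts), a
#' BED-style fragment file with the combined barcode column (plus SNP
#' observation columns), TSV truth tables, the bead whitelist, the
#' design as YAML and, when the reference is attached, gene/ACR/SNP/
#' chromosome tables. All files round-trip losslessly through the
#' module's readers.
#'
#' @param sim A `scifi_sim` object.
#' @param dir Output directory (created if needed).
#' @param write_reads Write FASTQ files when the simulation carries
#'   reads (default `TRUE`).
#' @return Named character vector of the files written (invisibly).
#' @export
write_fixtures <- function(sim, dir, write_reads = TRUE) {
  stopifnot(inherits(sim, "scifi_sim"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory ", dir)
  files <- c(
    fragments = file.path(dir, "fragments.bed"),
    truth_nuclei = file.path(dir, "truth_nuclei.tsv"),
    truth_fragments = file.path(dir, "truth_fragments.tsv"),
    bead_whitelist = file.path(dir, "bead_whitelist.txt"),
    design = file.path(dir, "design.yaml")
  )
  write_fragments(sim$fragments, files["fragments"])
  fwrite(sim$truth$nuclei, files["truth_nuclei"], sep = "\t", na = "NA")
  fwrite(sim$truth$fragments, files["truth_fragments"], sep = "\t",
         na = "NA")
  writeLines(sim$bead_whitelist, files["bead_whitelist"])
  design_to_yaml(sim$design, files["design"])
  if (write_reads && !is.null(sim$reads)) {
    files <- c(files, r1 = file.path(dir, "reads_R1.fastq"),
               r2 = file.path(dir, "reads_R2.fastq"))
    write_read_pairs(sim$reads, files["r1"], files["r2"])
  }
  if (!is.null(sim$ref)) {
    ref <- sim$ref
    files <- c(files, genes = file.path(dir, "genes.tsv"),
               acrs = file.path(dir, "acrs.bed"),
               snps = file.path(dir, "snps.tsv"),
               chroms = file.path(dir, "chroms.tsv"))
    fwrite(ref$genes, files["genes"], sep = "\t")
    fwrite(ref$acrs[, .(chrom, start, end)], files["acrs"], sep = "\t",
           col.names = FALSE)
    fwrite(ref$snps, files["snps"], sep = "\t")
    fwrite(data.table(chrom = names(ref$chromosomes),
                      length_bp = unname(ref$chromosomes),
                      is_organelle = names(ref$chromosomes) %in%
                        ref$organelle_scaffolds),
           files["chroms"], sep = "\t")
  }
  invisible(files)
}

#' Fragment file I/O (BED6+ with barcode and SNP columns)
#'
#' Tab-separated, 0-based half-open: `chrom start end barcode count
#' strand frag_id snp_chrom snp_pos allele` with a header line.
#'
#' @param fragments Fragment `data.table` (as in `scifi_sim$fragments`).
#' @param path File path.
#' @return `read_fragments` returns the fragment `data.table`.
#' @export
write_fragments <- function(fragments, path) {
  fragments <- as.data.table(fragments)
  out <- data.table(chrom = fragments$chrom, start = fragments$start,
                    end = fragments$end, barcode = fragments$barcode,
                    count = 1L, strand = ".")
  for (cc in c("frag_id", "snp_chrom", "snp_pos", "allele"))
    if (cc %in% names(fragments)) out[, (cc) := fragments[[cc]]]
  fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_fragments
#' @export
read_fragments <- function(path) {
  dt <- fread(path, sep = "\t",
              colClasses = list(character = "chrom"))
  stopifnot(all(c("chrom", "start", "end", "barcode") %in% names(dt)))
  dt
}

#' Paired FASTQ I/O for synthetic reads
#'
#' @param reads `data.table(read_id, name, seq1, seq2)`.
#' @param r1,r2 FASTQ paths for the two mates.
#' @return `read_read_pairs` returns a `data.table(read_id, name, seq1,
#'   seq2)`.
#' @export
write_read_pairs <- function(reads, r1, r2) {
  reads <- as.data.table(reads)
  s1 <- Biostrings::DNAStringSet(reads$seq1)
  s2 <- Biostrings::DNAStringSet(reads$seq2)
  names(s1) <- reads$name
  names(s2) <- reads$name
  Biostrings::writeXStringSet(s1, r1, format = "fastq")
  Biostrings::writeXStringSet(s2, r2, format = "fastq")
  invisible(c(r1, r2))
}

#' @rdname write_read_pairs
#' @export
read_read_pairs <- function(r1, r2) {
  s1 <- Biostrings::readDNAStringSet(r1, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(r2, format = "fastq")
  stopifnot(identical(names(s1), names(s2)))
  data.table(read_id = sub("_[^_]*$", "", names(s1)),
             name = names(s1),
             seq1 = as.character(s1), seq2 = as.character(s2))
}

#' Read truth tables written by [write_fixtures()]
#'
#' @param dir Fixture directory.
#' @return List with `nuclei` and `fragments` truth `data.table`s.
#' @export
read_truth <- function(dir) {
  list(nuclei = fread(file.path(dir, "truth_nuclei.tsv"), sep = "\t"),
       fragments = fread(file.path(dir, "truth_fragments.tsv"), sep = "\t"))
}

#' Read a SNP table from TSV
#'
#' Expected columns: `chrom`, `pos` (0-based), `ref`, `alt`, plus one
#' allele column per genotype.
#'
#' @param path TSV path.
#' @return SNP `data.table`.
#' @export
read_snp_table <- function(path) {
  dt <- fread(path, sep = "\t", colClasses = list(character = "chrom"))
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(dt)))
  dt
}

#' Read a SNP table from a VCF with one sample column per genotype
#'
#' Keeps biallelic SNV rows with homozygous genotypes in every sample
#' and converts them to the package's SNP table layout (0-based `pos`,
#' one allele column per genotype). Non-biallelic, non-SNV or
#' heterozygous rows are dropped.
#'
#' @param path VCF path.
#' @return SNP `data.table` (`chrom, pos, ref, alt, <genotype...>`).
#' @export
read_snp_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  bi <- lengths(altl) == 1L
  alt <- rep(NA_character_, length(ref))
  alt[bi] <- as.character(unlist(altl[bi]))
  snv <- bi & nchar(ref) == 1L & nchar(alt) == 1L & !is.na(alt)
  gt <- VariantAnnotation::geno(vcf)$GT
  hom <- gt %in% c("0/0", "0|0", "1/1", "1|1", "0", "1")
  dim(hom) <- dim(gt)
  keep <- snv & rowSums(hom) == ncol(gt)
  dt <- data.table(
    chrom = as.character(GenomicRanges::seqnames(rr))[keep],
    pos = GenomicRanges::start(rr)[keep] - 1L,    # VCF is 1-based
    ref = ref[keep], alt = alt[keep])
  for (s in colnames(gt)) {
    is_alt <- gt[keep, s] %in% c("1/1", "1|1", "1")
    dt[, (s) := ifelse(is_alt, alt[keep], ref[keep])]
  }
  dt
}

#' Read gene annotation from TSV or GFF3
#'
#' The TSV layout is `chrom, start, end, strand, gene_id` (0-based
#' half-open). `read_genes_gff` extracts `gene`-type records from a
#' GFF3 file (1-based closed coordinates converted to 0-based
#' half-open; the `ID` attribute becomes `gene_id`).
#'
#' @param path File path.
#' @return Gene `data.table(chrom, start, end, strand, gene_id)`.
#' @export
read_genes_tsv <- function(path) {
  dt <- fread(path, sep = "\t", colClasses = list(character = "chrom"))
  stopifnot(all(c("chrom", "start", "end", "strand", "gene_id") %in%
                  names(dt)))
  dt
}

#' @rdname read_genes_tsv
#' @export
read_genes_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             gene_id = if (!is.null(gr$ID)) gr$ID else
               as.character(seq_along(gr)))
}

#' Read a BED file of ACR intervals
#'
#' @param path BED path (first three columns used).
#' @return `data.table(chrom, start, end)` (0-based half-open).
#' @export
read_acrs_bed <- function(path) {
  dt <- fread(path, sep = "\t", header = FALSE)
  dt <- dt[, 1:3]
  setnames(dt, c("chrom", "start", "end"))
  dt[, chrom := as.character(chrom)]
  dt
}
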