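#' Per-nucleus QC thresholds
#'
#' The standard high-quality-nucleus criteria for plant scATAC-seq: at
#' least 1000 unique Tn5 insertion sites, at least 20% of sites within
#' 2 kb of a TSS, at least 20% of sites inside ACRs, and at most 30% of
#' sites on organelle scaffolds. All comparisons are inclusive.
#'
#' @param min_sites,min_frac_tss,min_frip,max_frac_organelle Thresholds.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_sites = 1000L, min_frac_tss = 0.20,
                          min_frip = 0.20, max_frac_organelle = 0.30) {
  stopifnot(min_sites >= 0,
            min_frac_tss >= 0, min_frac_tss <= 1,
            min_frip >= 0, min_frip <= 1,
            max_frac_organelle >= 0, max_frac_organelle <= 1)
  structure(list(min_sites = min_sites, min_frac_tss = min_frac_tss,
                 min_frip = min_frip,
                 max_frac_organelle = max_frac_organelle),
            class = "qc_thresholds")
}

#' Compute per-nucleus QC metrics from unique insertion sites
#'
#' For every cell barcode: the number of unique sites, the fraction of
#' sites within `tss_window` bp of any TSS (window inclusive of both
#' endpoints), the fraction inside ACRs (FRiP) and the fraction on
#' organelle scaffolds. All fractions use the *total* unique site count
#' (organelle sites included) as denominator; an empty cell reports all
#' fractions as 0.
#'
#' @param sites Deduplicated insertion sites (`chrom`, `pos`, `barcode`).
#' @param tss `data.table` with `chrom`, `pos` (0-based TSS positions),
#'   or a `scifi_reference` (its `tss`, `acrs` and organelle list are
#'   then used and the remaining arguments may be omitted).
#' @param acrs `data.table` with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param organelle Character vector of organelle scaffold names.
#' @param tss_window Half-width of the TSS window in bp (default 2000).
#' @param barcodes Optional barcode superset to report; barcodes without
#'   any site get `n_unique_sites = 0` and all fractions 0.
#' @return `data.table(barcode, n_unique_sites, frac_tss, frip,
#'   frac_organelle)`.
#' @export
compute_qc <- function(sites, tss, acrs = NULL, organelle = NULL,
                       tss_window = 2000L, barcodes = NULL) {
  sites <- as.data.table(sites)
  if (inherits(tss, "scifi_reference")) {
    ref <- tss
    tss <- ref$tss
    if (is.null(acrs)) acrs <- ref$acrs
    if (is.null(organelle)) organelle <- ref$organelle_scaffolds
  }
  tss <- as.data.table(tss)
  acrs <- as.data.table(acrs)

  s_gr <- GenomicRanges::GRanges(sites$chrom,
                                 IRanges::IRanges(sites$pos + 1L, width = 1L))
  in_tss <- rep(FALSE, nrow(sites))
  if (nrow(tss) > 0) {
    t_gr <- GenomicRanges::GRanges(
      tss$chrom, IRanges::IRanges(pmax(tss$pos - tss_window, 0L) + 1L,
                                  tss$pos + tss_window + 1L))
    in_tss <- suppressWarnings(IRanges::overlapsAny(s_gr, t_gr))
  }
  in_acr <- rep(FALSE, nrow(sites))
  if (nrow(acrs) > 0) {
    a_gr <- GenomicRanges::GRanges(acrs$chrom,
                                   IRanges::IRanges(acrs$start + 1L,
                                                    acrs$end))
    in_acr <- suppressWarnings(IRanges::overlapsAny(s_gr, a_gr))
  }
  in_org <- if (is.null(organelle)) rep(FALSE, nrow(sites)) else
    sites$chrom %in% organelle

  dt <- data.table(barcode = sites$barcode, in_tss = in_tss,
                   in_acr = in_acr, in_org = in_org)
  qc <- dt[, .(n_unique_sites = .N,
               frac_tss = mean(in_tss),
               frip = mean(in_acr),
               frac_organelle = mean(in_org)), by = barcode]
  if (!is.null(barcodes)) {
    missing_bc <- setdiff(barcodes, qc$barcode)
    if (length(missing_bc))
      qc <- rbind(qc, data.table(barcode = missing_bc, n_unique_sites = 0L,
                                 frac_tss = 0, frip = 0,
                                 frac_organelle = 0))
  }
  qc[]
}

#' Call high-quality nuclei from a QC table
#'
#' @param qc QC table from [compute_qc()].
#' @param thresholds A [qc_thresholds()] object.
#' @return The QC table with a logical `pass` column; the
#'   `"qc_summary"` attribute holds counts of nuclei failing each
#'   criterion (a nucleus can fail several) and the pass total.
#' @export
call_nuclei <- function(qc, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  qc <- as.data.table(qc)
  fail_sites <- qc$n_unique_sites < thresholds$min_sites
  fail_tss <- qc$frac_tss < thresholds$min_frac_tss
  fail_frip <- qc$frip < thresholds$min_frip
  fail_org <- qc$frac_organelle > thresholds$max_frac_organelle
  qc[, pass := !(fail_sites | fail_tss | fail_frip | fail_org)]
  data.table::setattr(qc, "qc_summary", list(
    n = nrow(qc), n_pass = sum(qc$pass),
    fail_sites = sum(fail_sites), fail_tss = sum(fail_tss),
    fail_frip = sum(fail_frip), fail_organelle = sum(fail_org)))
  qc[]
}
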