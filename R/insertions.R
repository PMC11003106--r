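#' Convert aligned fragments to single-base Tn5 insertion sites
#'
#' Each sequenced fragment arises from two Tn5 integration events, 9 bp
#' apart on opposite strands; the canonical correction shifts the
#' fragment start by +4 and the end by -5 to centre each event. With
#' 0-based half-open fragment coordinates `[start, end)`, the two
#' single-base sites are `start + 4` (plus strand) and `end - 5` (minus
#' strand).
#'
#' Fragments shorter than 10 bp produce a minus-side site at or left of
#' the plus-side site; both sites are still emitted but flagged
#' `degenerate`.
#' Sites falling outside the chromosome are clipped to the nearest valid
#' base and flagged `clipped` when chromosome lengths are supplied.
#'
#' @param fragments `data.table`/data.frame with `chrom`, `start`, `end`
#'   and a `barcode` column.
#' @param chrom_lengths Optional named vector of chromosome lengths used
#'   for bounds clipping.
#' @return `data.table(chrom, pos, barcode, strand, degenerate, clipped)`
#'   with two rows per input fragment (0-based single positions).
#' @export
fragment_to_insertions <- function(fragments, chrom_lengths = NULL) {
  fragments <- as.data.table(fragments)
  stopifnot(all(c("chrom", "start", "end", "barcode") %in% names(fragments)),
            all(fragments$end > fragments$start))
  plus <- fragments$start + 4L
  minus <- fragments$end - 5L
  degen <- minus <= plus          # sites overlap or invert: fragment < 10 bp
  sites <- data.table(
    chrom = rep(fragments$chrom, 2L),
    pos = c(plus, minus),
    barcode = rep(fragments$barcode, 2L),
    strand = rep(c("+", "-"), each = nrow(fragments)),
    degenerate = rep(degen, 2L),
    clipped = FALSE
  )
  if (!is.null(chrom_lengths)) {
    lim <- unname(chrom_lengths[sites$chrom])
    clip <- sites$pos < 0L | sites$pos >= lim
    sites[clip, pos := pmin(pmax(pos, 0L), as.integer(lim[clip]) - 1L)]
    sites[, clipped := clip]
  }
  sites[]
}

#' Retain unique Tn5 insertion sites within each cell
#'
#' Duplicate insertion events (PCR or re-ligation artefacts) are
#' collapsed to one record per `(barcode, chrom, pos)`; the same genomic
#' position observed in two different cells is kept in both. Per-cell
#' site counts before and after deduplication are attached as the
#' `"dedup_counts"` attribute.
#'
#' @param sites Insertion sites from [fragment_to_insertions()].
#' @return Deduplicated `data.table` (same columns), with attribute
#'   `dedup_counts`: `data.table(barcode, n_before, n_after)`.
#' @export
dedupe_insertions <- function(sites) {
  sites <- as.data.table(sites)
  before <- sites[, .(n_before = .N), by = barcode]
  out <- unique(sites, by = c("barcode", "chrom", "pos"))
  after <- out[, .(n_after = .N), by = barcode]
  counts <- merge(before, after, by = "barcode", all = TRUE)
  counts[is.na(n_after), n_after := 0L]
  data.table::setattr(out, "dedup_counts", counts[])
  out[]
}
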