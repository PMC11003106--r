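#' Gene chromatin-accessibility counts
#'
#' Counts unique Tn5 insertion sites per gene and group within the gene
#' body extended 500 bp upstream and 100 bp downstream of transcription
#' (flanks are strand-relative; unstranded genes are treated as plus
#' strand with a warning). Windows are clipped at chromosome edges when
#' lengths are supplied.
#'
#' @param sites Insertion sites: `chrom`, `pos`, and a grouping column.
#' @param genes Gene table: `chrom`, `start`, `end`, `strand`,
#'   `gene_id` (0-based half-open).
#' @param group Name of the grouping column in `sites` (cell type,
#'   genotype or library); default `"group"`.
#' @param upstream,downstream Flank sizes in bp (defaults 500/100).
#' @param chrom_lengths Optional named lengths for clipping.
#' @return Integer matrix: genes x groups (dimnames set).
#' @export
gene_accessibility <- function(sites, genes, group = "group",
                               upstream = 500L, downstream = 100L,
                               chrom_lengths = NULL) {
  sites <- as.data.table(sites)
  genes <- as.data.table(genes)
  stopifnot(group %in% names(sites),
            all(c("chrom", "start", "end", "gene_id") %in% names(genes)))
  if (!"strand" %in% names(genes) || anyNA(genes$strand)) {
    warning("unstranded gene(s) treated as plus strand")
    if (!"strand" %in% names(genes)) genes[, strand := "+"]
    genes[is.na(strand), strand := "+"]
  }
  plus <- genes$strand != "-"
  ws <- ifelse(plus, genes$start - upstream, genes$start - downstream)
  we <- ifelse(plus, genes$end + downstream, genes$end + upstream)
  ws <- pmax(ws, 0L)
  if (!is.null(chrom_lengths))
    we <- pmin(we, unname(chrom_lengths[genes$chrom]))

  groups <- sort(unique(sites[[group]]))
  mat <- matrix(0L, nrow(genes), length(groups),
                dimnames = list(genes$gene_id, as.character(groups)))
  if (nrow(sites) == 0) return(mat)
  g_gr <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(ws + 1L, we))
  s_gr <- GenomicRanges::GRanges(sites$chrom,
                                 IRanges::IRanges(sites$pos + 1L,
                                                  width = 1L))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(s_gr, g_gr))
  if (length(ov)) {
    tab <- data.table(gene = S4Vectors::subjectHits(ov),
                      grp = match(sites[[group]][S4Vectors::queryHits(ov)],
                                  groups))[, .N, by = .(gene, grp)]
    mat[cbind(tab$gene, tab$grp)] <- tab$N
  }
  mat
}

#' CPM-normalise a count matrix and compute per-feature Z-scores
#'
#' Counts-per-million normalisation per column followed by row-wise
#' standardisation across groups (sample standard deviation, n-1);
#' zero-variance features get Z = 0 everywhere. Groups with zero total
#' counts are excluded with a warning.
#'
#' @param mat Raw count matrix (features x groups, >= 2 groups).
#' @return List with `cpm` and `z` matrices (excluded groups dropped
#'   from both).
#' @export
cpm_zscore <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  tot <- colSums(mat)
  if (any(tot == 0)) {
    warning("group(s) with zero total counts excluded: ",
            paste(colnames(mat)[tot == 0], collapse = ", "))
    mat <- mat[, tot > 0, drop = FALSE]
    if (ncol(mat) < 2) stop("fewer than two groups with non-zero counts")
  }
  cpm <- edgeR::cpm(mat)
  mu <- rowMeans(cpm)
  s <- apply(cpm, 1L, stats::sd)
  z <- (cpm - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  list(cpm = cpm, z = z)
}

#' Build a unified ACR master list from per-group peak calls
#'
#' Per-group ACRs are redefined as fixed-width windows centred on their
#' coverage summit (missing summits fall back to the interval midpoint,
#' flagged). Overlapping windows are resolved greedily: windows are
#' visited in decreasing summit-signal order and a window is kept only
#' if it overlaps no previously kept window, so the master list is
#' pairwise non-overlapping. Finally, windows whose accessibility is
#' below `min_cpm` CPM in *every* group are removed.
#'
#' @param acrs Per-group ACRs: `chrom`, `summit` (0-based position, may
#'   be `NA` if `start`/`end` given), `score` (summit signal used for
#'   the greedy ordering) and `group`.
#' @param sites Insertion sites with `chrom`, `pos` and the grouping
#'   column used for the CPM filter.
#' @param group Grouping column name in `sites` (default `"group"`).
#' @param width Window width in bp (default 500).
#' @param min_cpm CPM threshold (default 3): windows below it in all
#'   groups are dropped.
#' @param chrom_lengths Optional named lengths; windows are clipped at
#'   chromosome edges (flagged `clipped`).
#' @return `data.table(chrom, start, end, summit, score, group,
#'   midpoint_summit, clipped)` plus one `cpm_<group>` column per
#'   group, sorted by position; attribute `"counts"` holds the raw
#'   window x group count matrix.
#' @export
build_acr_master_list <- function(acrs, sites, group = "group",
                                  width = 500L, min_cpm = 3,
                                  chrom_lengths = NULL) {
  acrs <- copy(as.data.table(acrs))
  sites <- as.data.table(sites)
  stopifnot("chrom" %in% names(acrs), "score" %in% names(acrs))
  if (!"summit" %in% names(acrs)) acrs[, summit := NA_integer_]
  acrs[, midpoint_summit := is.na(summit)]
  if (any(acrs$midpoint_summit)) {
    if (!all(c("start", "end") %in% names(acrs)))
      stop("missing summits require start/end for the midpoint fallback")
    acrs[midpoint_summit == TRUE,
         summit := as.integer((start + end) %/% 2L)]
  }
  half <- width %/% 2L
  win <- data.table(chrom = acrs$chrom,
                    start = acrs$summit - half,
                    end = acrs$summit - half + width,
                    summit = acrs$summit, score = acrs$score,
                    group = if ("group" %in% names(acrs)) acrs$group else NA,
                    midpoint_summit = acrs$midpoint_summit)
  win[, clipped := FALSE]
  win[start < 0, `:=`(start = 0L, clipped = TRUE)]
  if (!is.null(chrom_lengths)) {
    lim <- unname(chrom_lengths[win$chrom])
    over <- which(win$end > lim)
    if (length(over))
      win[over, `:=`(end = as.integer(lim[over]), clipped = TRUE)]
  }

  ## greedy overlap resolution, highest score first
  ord <- order(-win$score)
  gr <- GenomicRanges::GRanges(win$chrom,
                               IRanges::IRanges(win$start + 1L, win$end))
  ov <- GenomicRanges::findOverlaps(gr, gr)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  nbr <- split(sh[qh != sh], qh[qh != sh])
  removed <- rep(FALSE, nrow(win))
  kept <- logical(nrow(win))
  for (i in ord) {
    if (removed[i]) next
    kept[i] <- TRUE
    ni <- nbr[[as.character(i)]]
    if (!is.null(ni)) removed[ni] <- TRUE
  }
  master <- win[kept]
  setorder(master, chrom, start)

  ## CPM filter over per-group insertion counts within the windows
  groups <- sort(unique(sites[[group]]))
  cnt <- matrix(0L, nrow(master), length(groups),
                dimnames = list(NULL, as.character(groups)))
  if (nrow(sites) > 0 && nrow(master) > 0) {
    m_gr <- GenomicRanges::GRanges(master$chrom,
                                   IRanges::IRanges(master$start + 1L,
                                                    master$end))
    s_gr <- GenomicRanges::GRanges(sites$chrom,
                                   IRanges::IRanges(sites$pos + 1L,
                                                    width = 1L))
    ovc <- suppressWarnings(GenomicRanges::findOverlaps(s_gr, m_gr))
    if (length(ovc)) {
      tab <- data.table(win = S4Vectors::subjectHits(ovc),
                        grp = match(sites[[group]][S4Vectors::queryHits(ovc)],
                                    groups))[, .N, by = .(win, grp)]
      cnt[cbind(tab$win, tab$grp)] <- tab$N
    }
  }
  tot <- colSums(cnt)
  cpm <- sweep(cnt, 2L, ifelse(tot > 0, tot, 1), "/") * 1e6
  keep <- rowSums(cpm >= min_cpm) > 0
  master <- master[keep]
  cpm <- cpm[keep, , drop = FALSE]
  for (j in seq_along(groups))
    master[, (paste0("cpm_", groups[j])) := cpm[, j]]
  data.table::setattr(master, "counts", cnt[keep, , drop = FALSE])
  master[]
}

#' Group-specific features from a Z-score matrix
#'
#' A feature is specific to a group when its Z-score there exceeds
#' `z_threshold` (strictly); a feature may be specific to several
#' groups.
#'
#' @param z Z-score matrix (features x groups) from [cpm_zscore()].
#' @param z_threshold Threshold (default 2).
#' @return List with `sets` (named list of feature ids per group) and
#'   `counts` (`data.table(group, n, frac)`).
#' @export
specific_features <- function(z, z_threshold = 2) {
  stopifnot(is.matrix(z))
  ids <- rownames(z)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(z)))
  sets <- lapply(seq_len(ncol(z)), function(j) ids[z[, j] > z_threshold])
  names(sets) <- colnames(z)
  counts <- data.table(group = colnames(z),
                       n = vapply(sets, length, integer(1)),
                       frac = vapply(sets, length, integer(1)) / nrow(z))
  list(sets = sets, counts = counts)
}

#' Spearman correlation among pseudobulk libraries
#'
#' Rank-based correlation (average ranks on ties) between the columns of
#' a pseudobulk accessibility matrix. Constant columns have undefined
#' correlation and are reported as `NA` with a warning.
#'
#' @param mat Numeric matrix (features x libraries, >= 2 columns).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
library_correlation <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  const <- apply(mat, 2L, function(x) length(unique(x)) == 1L)
  if (any(const))
    warning("constant column(s), correlation undefined: ",
            paste(colnames(mat)[const], collapse = ", "))
  suppressWarnings(stats::cor(mat, method = "spearman"))
}
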