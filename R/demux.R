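#' Barcode schema for combined bead + two-sided Tn5 cell barcodes
#'
#' A scifi-ATAC-seq cell barcode combines the 16-bp droplet (bead)
#' barcode with the pre-indexing well, encoded by a pair of inline 5-nt
#' Tn5 barcodes: one on the A/s7 ("row") adapter and one on the B/s5
#' ("column") adapter. Twelve A-barcodes crossed with eight B-barcodes
#' give the 96 well combinations of a standard plate.
#'
#' @param a_barcodes Character vector of distinct 5-nt A-side barcodes.
#' @param b_barcodes Character vector of distinct 5-nt B-side barcodes.
#' @param bead_whitelist Optional character vector of valid 16-nt bead
#'   barcodes (e.g. the droplet whitelist from [simulate_experiment()]).
#' @param max_mismatch Per-barcode Hamming correction radius (default 1).
#'   A warning is issued when a whitelist's minimum pairwise Hamming
#'   distance is not greater than `2 * max_mismatch` (correction then
#'   cannot be guaranteed unambiguous).
#'
#' @return An object of class `barcode_schema`.
#' @export
barcode_schema <- function(a_barcodes, b_barcodes, bead_whitelist = NULL,
                           max_mismatch = 1L) {
  stopifnot(length(a_barcodes) >= 1, length(b_barcodes) >= 1,
            max_mismatch >= 0)
  if (anyDuplicated(a_barcodes)) stop("duplicate A-barcodes")
  if (anyDuplicated(b_barcodes)) stop("duplicate B-barcodes")
  if (length(unique(nchar(a_barcodes))) != 1 ||
      length(unique(nchar(b_barcodes))) != 1)
    stop("barcodes within a list must share one length")
  if (!is.null(bead_whitelist) && anyDuplicated(bead_whitelist))
    stop("duplicate bead barcodes in whitelist")
  for (nm in c("a_barcodes", "b_barcodes")) {
    wl <- get(nm)
    if (length(wl) > 1 && .min_hamming(wl) <= 2L * max_mismatch)
      warning(nm, ": minimum pairwise Hamming distance <= 2*max_mismatch; ",
              "correction may reject ambiguous barcodes")
  }
  structure(list(a_barcodes = a_barcodes, b_barcodes = b_barcodes,
                 bead_whitelist = bead_whitelist,
                 max_mismatch = as.integer(max_mismatch)),
            class = "barcode_schema")
}

#' Default two-sided Tn5 barcode schema (12 A x 8 B)
#'
#' Synthetic 5-nt barcode sets with minimum pairwise Hamming distance 3,
#' so single-substitution correction is always unambiguous.
#'
#' @inheritParams barcode_schema
#' @return A `barcode_schema` with 12 A- and 8 B-barcodes.
#' @export
default_barcode_schema <- function(bead_whitelist = NULL, max_mismatch = 1L) {
  barcode_schema(
    a_barcodes = c("AATAG", "ACGTT", "AAACC", "AGCGA", "CGACA", "TAGTA",
                   "TTTCA", "GTGAC", "TCCAA", "GCACT", "CTGCG", "CATCT"),
    b_barcodes = c("GTTTT", "TGCCT", "CGTAC", "CCCGC", "TCAGG", "TCTTC",
                   "GCCTG", "GAAAA"),
    bead_whitelist = bead_whitelist, max_mismatch = max_mismatch)
}

.min_hamming <- function(wl) {
  m <- do.call(rbind, strsplit(wl, ""))
  n <- nrow(m)
  best <- ncol(m)
  for (i in seq_len(n - 1)) {
    d <- rowSums(m[(i + 1):n, , drop = FALSE] !=
                   matrix(m[i, ], n - i, ncol(m), byrow = TRUE))
    best <- min(best, d)
  }
  best
}

#' @export
print.barcode_schema <- function(x, ...) {
  cat(sprintf("Barcode schema: %d A x %d B Tn5 barcodes (%d wells)",
              length(x$a_barcodes), length(x$b_barcodes),
              length(x$a_barcodes) * length(x$b_barcodes)))
  cat(sprintf(", max_mismatch = %d\n", x$max_mismatch))
  if (!is.null(x$bead_whitelist))
    cat(sprintf("  bead whitelist: %d x %d nt\n", length(x$bead_whitelist),
                nchar(x$bead_whitelist[1])))
  invisible(x)
}

#' Map (A, B) Tn5 barcode pairs to plate wells
#'
#' Enumerates all `|A| x |B|` combinations, assigning well ids
#' `1..|A|*|B|` in row-major order (B varies fastest within each A), and
#' optionally attaches a well -> sample label map for multiplexed designs.
#'
#' @param schema A [barcode_schema()].
#' @param samples Optional character vector of sample/genotype labels,
#'   either length 1 per well (named by well id or positional).
#' @return An object of class `well_map`: list with `map` (data.table
#'   `a_barcode, b_barcode, well_id[, sample]`) and `n_wells`.
#' @export
build_well_map <- function(schema, samples = NULL) {
  stopifnot(inherits(schema, "barcode_schema"))
  a <- schema$a_barcodes; b <- schema$b_barcodes
  map <- data.table(
    a_barcode = rep(a, each = length(b)),
    b_barcode = rep(b, times = length(a)),
    well_id = seq_len(length(a) * length(b))
  )
  wm <- structure(list(map = map, n_wells = nrow(map)), class = "well_map")
  if (!is.null(samples)) wm <- add_well_samples(wm, samples)
  wm
}

#' @rdname build_well_map
#' @param wm A `well_map`.
#' @export
add_well_samples <- function(wm, samples) {
  stopifnot(inherits(wm, "well_map"))
  if (!is.null(names(samples))) {
    idx <- match(as.character(wm$map$well_id), names(samples))
    lab <- unname(samples[idx])
  } else {
    if (length(samples) != wm$n_wells)
      stop("samples must be named by well id or have one label per well")
    lab <- samples[wm$map$well_id]
  }
  wm$map[, sample := lab]
  wm
}

#' @export
print.well_map <- function(x, ...) {
  cat(sprintf("Well map: %d wells (%d A x %d B)\n", x$n_wells,
              length(unique(x$map$a_barcode)),
              length(unique(x$map$b_barcode))))
  if ("sample" %in% names(x$map))
    cat(sprintf("  samples: %s\n",
                paste(unique(stats::na.omit(x$map$sample)), collapse = ", ")))
  invisible(x)
}

#' Correct observed barcodes against a whitelist
#'
#' Returns, for each observed barcode, the unique whitelist entry within
#' Hamming distance `max_mismatch`, or `NA` (unassigned) when no entry or
#' two or more entries tie at the minimum distance. Exact matches win
#' immediately. All observed barcodes must have the whitelist's length.
#'
#' @param observed Character vector of observed barcodes.
#' @param whitelist Character vector of valid barcodes (one length).
#' @param max_mismatch Correction radius (default 1).
#' @return Character vector: corrected barcode or `NA` per element.
#' @export
correct_barcode <- function(observed, whitelist, max_mismatch = 1L) {
  stopifnot(length(whitelist) >= 1)
  wlen <- unique(nchar(whitelist))
  if (length(wlen) != 1) stop("whitelist entries must share one length")
  if (length(observed) == 0) return(character(0))
  if (any(nchar(observed) != wlen))
    stop("observed barcode length differs from whitelist length")
  out <- whitelist[match(observed, whitelist)]
  todo <- which(is.na(out) & !is.na(observed))
  if (length(todo) == 0 || max_mismatch == 0) return(out)
  if (max_mismatch == 1L) {
    # enumerate all single-substitution neighbours and hash into whitelist
    uo <- unique(observed[todo])
    hits <- .neighbour_hits(uo, whitelist, wlen)
    out[todo] <- hits[match(observed[todo], uo)]
  } else {
    uo <- unique(observed[todo])
    om <- do.call(rbind, strsplit(uo, ""))
    wm <- do.call(rbind, strsplit(whitelist, ""))
    res <- rep(NA_character_, length(uo))
    for (i in seq_along(uo)) {
      d <- rowSums(wm != matrix(om[i, ], nrow(wm), wlen, byrow = TRUE))
      dm <- min(d)
      if (dm <= max_mismatch && sum(d == dm) == 1L)
        res[i] <- whitelist[which.min(d)]
    }
    out[todo] <- res[match(observed[todo], uo)]
  }
  out
}

# unique-within-distance-1 lookup via neighbour enumeration
.neighbour_hits <- function(uo, whitelist, wlen) {
  nt <- c("A", "C", "G", "T", "N")
  n <- length(uo)
  cand <- rep(NA_character_, n)
  nhit <- integer(n)
  for (p in seq_len(wlen)) {
    pre <- substr(uo, 1L, p - 1L)
    mid <- substr(uo, p, p)
    post <- substr(uo, p + 1L, wlen)
    for (b in nt) {
      sub <- b != mid
      if (!any(sub)) next
      var <- paste0(pre[sub], b, post[sub])
      m <- match(var, whitelist)
      ok <- !is.na(m)
      if (any(ok)) {
        ii <- which(sub)[ok]
        newhit <- whitelist[m[ok]]
        fresh <- is.na(cand[ii]) | cand[ii] != newhit
        nhit[ii] <- nhit[ii] + as.integer(fresh)
        cand[ii] <- newhit
      }
    }
  }
  cand[nhit != 1L] <- NA_character_
  cand
}

#' Demultiplex read records into combined cell barcodes
#'
#' Parses the 16-bp bead barcode from the read name (appended after the
#' final `"_"`, mirroring the UMI-tools extraction convention), reads the
#' two inline 5-nt Tn5 barcodes from the starts of the paired inserts,
#' corrects all three against their whitelists and maps the (A, B) pair
#' to a well. Rejection reasons are `bad_bead`, `bad_a`, `bad_b` and
#' `invalid_pair` (pair absent from the well map).
#'
#' @param reads `data.table`/data.frame with columns `read_id`, `name`,
#'   `seq1`, `seq2` (as produced by [simulate_experiment()] or read back
#'   with [read_read_pairs()]).
#' @param schema A [barcode_schema()]. If its `bead_whitelist` is `NULL`
#'   the bead barcode is taken as observed (no correction).
#' @param well_map A [build_well_map()] for `schema`.
#' @param me_len Length of the mosaic-end sequence separating the Tn5
#'   barcode from the genomic insert (default 19).
#' @return `data.table(read_id, status, bead, well, cell_barcode,
#'   insert1, insert2)` where `status` is `"assigned"` or a rejection
#'   reason and `cell_barcode` is `"<bead>-<well>"`.
#' @export
demux_reads <- function(reads, schema, well_map, me_len = 19L) {
  stopifnot(inherits(schema, "barcode_schema"), inherits(well_map, "well_map"))
  reads <- as.data.table(reads)
  alen <- nchar(schema$a_barcodes[1])
  blen <- nchar(schema$b_barcodes[1])
  if (!all(grepl("_", reads$name, fixed = TRUE)))
    stop("malformed read name: no '_<bead barcode>' suffix")
  bead_obs <- sub(".*_", "", reads$name)
  if (!is.null(schema$bead_whitelist)) {
    blen16 <- unique(nchar(schema$bead_whitelist))
    if (any(nchar(bead_obs) != blen16))
      stop("malformed read name: bead barcode length mismatch")
    bead <- correct_barcode(bead_obs, schema$bead_whitelist,
                            schema$max_mismatch)
  } else {
    bead <- bead_obs
  }
  a <- correct_barcode(substr(reads$seq1, 1L, alen), schema$a_barcodes,
                       schema$max_mismatch)
  b <- correct_barcode(substr(reads$seq2, 1L, blen), schema$b_barcodes,
                       schema$max_mismatch)
  key <- paste0(a, ".", b)
  wm <- well_map$map
  well <- wm$well_id[match(key, paste0(wm$a_barcode, ".", wm$b_barcode))]

  status <- rep("assigned", nrow(reads))
  status[!is.na(a) & !is.na(b) & is.na(well)] <- "invalid_pair"
  status[is.na(b)] <- "bad_b"
  status[is.na(a)] <- "bad_a"
  status[is.na(bead)] <- "bad_bead"
  ok <- status == "assigned"

  out <- data.table(
    read_id = reads$read_id, status = status,
    bead = ifelse(ok, bead, NA_character_),
    well = ifelse(ok, well, NA_integer_),
    cell_barcode = ifelse(ok, paste0(bead, "-", well), NA_character_),
    insert1 = substr(reads$seq1, alen + me_len + 1L, nchar(reads$seq1)),
    insert2 = substr(reads$seq2, blen + me_len + 1L, nchar(reads$seq2))
  )
  out
}

#' Separate candidate nuclei from hopped background
#'
#' In a pre-indexed experiment every genuine nucleus produces one
#' dominant (bead, well) read-count combination per droplet, while index
#' hopping scatters trace counts across wells the droplet never
#' contained. A combination is retained as a candidate nucleus iff its
#' read count is at least `min_reads` *and* at least `min_frac` of all
#' reads carrying that bead barcode; everything else is flagged as
#' hopped background and excluded from nucleus-level accounting.
#'
#' @param combos `data.table`/data.frame with columns `bead`, `well`,
#'   `reads` (non-negative counts), e.g. from
#'   `fragments[, .N, by = .(bead, well)]`.
#' @param min_reads Minimum absolute read count (default 100).
#' @param min_frac Minimum fraction of the bead barcode's reads
#'   (default 0.05).
#' @return The input with a logical `retained` column.
#' @export
filter_bead_well_combos <- function(combos, min_reads = 100L,
                                    min_frac = 0.05) {
  if (min_frac < 0 || min_frac > 1) stop("min_frac must be in [0, 1]")
  combos <- as.data.table(combos)
  stopifnot(all(c("bead", "well", "reads") %in% names(combos)),
            all(combos$reads >= 0))
  combos[, retained := reads >= min_reads &
           reads >= min_frac * sum(reads), by = bead]
  combos[]
}

#' Split a combined cell barcode back into bead barcode and well id
#'
#' @param cell_barcode Character vector `"<bead>-<well>"`.
#' @return `data.table(bead, well)`.
#' @export
split_cell_barcode <- function(cell_barcode) {
  data.table(bead = sub("-[0-9]+$", "", cell_barcode),
             well = as.integer(sub(".*-", "", cell_barcode)))
}
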