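#' Genotype-model parameters
#'
#' @param epsilon Assumed per-informative-read sequencing/assignment
#'   error rate (default 0.05, a deliberately conservative value).
#' @param min_reads Minimum informative reads (reads covering a
#'   homozygous biallelic SNP) required to attempt a call (default 50).
#' @param priors Optional prior over hypotheses (singlet per genotype,
#'   then collision); `NULL` = flat. Must sum to 1.
#' @param mixture_weight Assumed contribution of the first nucleus in a
#'   collision (default 0.5, an equal two-nucleus mixture).
#' @return A list of class `genotype_params`.
#' @export
genotype_params <- function(epsilon = 0.05, min_reads = 50L, priors = NULL,
                            mixture_weight = 0.5) {
  if (epsilon <= 0 || epsilon >= 0.5) stop("epsilon must be in (0, 0.5)")
  if (min_reads < 1) stop("min_reads must be >= 1")
  if (mixture_weight <= 0 || mixture_weight >= 1)
    stop("mixture_weight must be in (0, 1)")
  if (!is.null(priors)) {
    if (abs(sum(priors) - 1) > 1e-8) stop("priors must sum to 1")
    if (any(priors < 0)) stop("priors must be non-negative")
  }
  structure(list(epsilon = epsilon, min_reads = as.integer(min_reads),
                 priors = priors, mixture_weight = mixture_weight),
            class = "genotype_params")
}

#' Count genotype-supporting reads at homozygous biallelic SNPs
#'
#' Each read (fragment) that overlaps at least one SNP contributes one
#' count to the genotype(s) whose allele it carries at its first
#' overlapped SNP; when several genotypes share that allele the count is
#' split equally among them so that the per-cell total equals the number
#' of informative reads. Reads carrying neither allele are ignored.
#' SNPs with identical alleles across all genotypes are uninformative
#' and excluded with a warning.
#'
#' @param fragments Fragment records with columns `barcode`,
#'   `snp_chrom`, `snp_pos`, `allele` (as emitted by
#'   [simulate_experiment()] or read back from fixtures).
#' @param snps SNP table with `chrom`, `pos`, `ref`, `alt` and one
#'   allele column per genotype label.
#' @param genotypes Character vector of genotype labels (defaults to the
#'   allele columns present in `snps`).
#' @return `data.table` with `barcode`, one count column per genotype,
#'   and `n` (total informative reads).
#' @export
count_alleles <- function(fragments, snps, genotypes = NULL) {
  fragments <- as.data.table(fragments)
  snps <- as.data.table(snps)
  if (is.null(genotypes))
    genotypes <- setdiff(names(snps),
                         c("chrom", "pos", "ref", "alt", "snp_id"))
  stopifnot(length(genotypes) >= 1,
            all(genotypes %in% names(snps)))
  amat <- as.matrix(snps[, genotypes, with = FALSE])
  mono <- rowSums(amat != amat[, 1L]) == 0L
  if (length(genotypes) >= 2 && any(mono)) {
    warning(sum(mono), " SNP(s) identical across all genotypes excluded")
    snps <- snps[!mono]
    amat <- amat[!mono, , drop = FALSE]
  }
  inf <- fragments[!is.na(allele),
                   .(barcode, snp_chrom, snp_pos, allele)]
  key <- paste0(inf$snp_chrom, ":", inf$snp_pos)
  skey <- paste0(snps$chrom, ":", snps$pos)
  si <- match(key, skey)
  keep <- !is.na(si)
  inf <- inf[keep]; si <- si[keep]
  hit <- amat[si, , drop = FALSE] == inf$allele     # reads x genotypes
  nmatch <- rowSums(hit)
  ok <- nmatch > 0                                   # neither allele -> drop
  inf <- inf[ok]; hit <- hit[ok, , drop = FALSE]
  w <- hit / rowSums(hit)
  dt <- data.table(barcode = inf$barcode)
  for (j in seq_along(genotypes)) dt[, (genotypes[j]) := w[, j]]
  counts <- dt[, lapply(.SD, sum), by = barcode, .SDcols = genotypes]
  counts[, n := rowSums(as.matrix(.SD)), .SDcols = genotypes]
  counts[]
}

# log-likelihood matrix over hypotheses (G singlets + collision) for a
# counts matrix C (cells x genotypes). Multinomial kernel without the
# coefficient (identical across hypotheses, cancels in the posterior).
.hypothesis_loglik <- function(C, epsilon, mixture_weight) {
  G <- ncol(C)
  singlet_p <- function(g) {
    p <- rep(epsilon / max(G - 1L, 1L), G)
    p[g] <- 1 - epsilon
    p
  }
  ll <- matrix(NA_real_, nrow(C), G + 1L)
  for (g in seq_len(G)) ll[, g] <- C %*% log(singlet_p(g))
  # collision: best equal(-weight) mixture of two singlet distributions
  pairs <- utils::combn(G, 2L)
  w <- mixture_weight
  coll <- matrix(-Inf, nrow(C), ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    p <- w * singlet_p(pairs[1L, j]) + (1 - w) * singlet_p(pairs[2L, j])
    coll[, j] <- C %*% log(p)
    if (abs(w - 0.5) > 1e-12) {
      p2 <- (1 - w) * singlet_p(pairs[1L, j]) + w * singlet_p(pairs[2L, j])
      coll[, j] <- pmax(coll[, j], C %*% log(p2))
    }
  }
  ll[, G + 1L] <- do.call(pmax, as.data.frame(coll))
  ll
}

#' Posterior genotype / collision calls from allele counts
#'
#' Models the per-cell informative-read counts as draws from either a
#' single genotype (each read supports that genotype with probability
#' `1 - epsilon`, the error mass spread over the others) or a barcode
#' collision (an equal mixture of two such singlet distributions; with
#' two genotypes and `mixture_weight = 0.5` this is the classical
#' Binomial(n, 0.5) collision model). Posterior probabilities follow
#' from Bayes' theorem under the configured priors (flat by default);
#' the call is the maximum-posterior hypothesis. Cells with fewer than
#' `min_reads` informative reads — or exact posterior ties — are left
#' unassigned. Likelihoods are evaluated in log space.
#'
#' @param counts Output of [count_alleles()] (or any data.frame with
#'   `barcode`, per-genotype count columns and `n`).
#' @param params A [genotype_params()] object.
#' @param genotypes Genotype labels; default: all columns except
#'   `barcode` and `n`.
#' @return `data.table(barcode, call, posterior_max, n, contamination)`
#'   plus one `posterior_<hypothesis>` column per hypothesis. `call` is
#'   a genotype label, `"collision"` or `"unassigned"`; `contamination`
#'   is the fraction of informative reads not supporting the called
#'   genotype (singlet calls only, `NA` otherwise).
#' @export
genotype_posterior <- function(counts, params = genotype_params(),
                               genotypes = NULL) {
  stopifnot(inherits(params, "genotype_params"))
  counts <- as.data.table(counts)
  if (is.null(genotypes))
    genotypes <- setdiff(names(counts), c("barcode", "n"))
  G <- length(genotypes)
  stopifnot(G >= 2)
  C <- as.matrix(counts[, genotypes, with = FALSE])
  n <- if ("n" %in% names(counts)) counts$n else rowSums(C)

  ll <- .hypothesis_loglik(C, params$epsilon, params$mixture_weight)
  hyp <- c(genotypes, "collision")
  priors <- if (is.null(params$priors)) rep(1 / (G + 1L), G + 1L) else
    params$priors
  if (length(priors) != G + 1L)
    stop("priors must have one entry per hypothesis (", G + 1L, ")")
  lp <- sweep(ll, 2L, log(priors), "+")
  norm <- apply(lp, 1L, .logsumexp)
  post <- exp(lp - norm)

  best <- max.col(post, ties.method = "first")
  pmax_ <- post[cbind(seq_len(nrow(post)), best)]
  tie <- rowSums(post == pmax_) > 1L
  call <- hyp[best]
  call[tie] <- "unassigned"
  call[n < params$min_reads | n == 0] <- "unassigned"

  res <- data.table(barcode = counts$barcode, call = call,
                    posterior_max = ifelse(call == "unassigned", NA_real_,
                                           pmax_),
                    n = n)
  singlet <- call %in% genotypes
  contam <- rep(NA_real_, nrow(res))
  contam[singlet] <- (n[singlet] -
                        C[cbind(which(singlet),
                                match(call[singlet], genotypes))]) /
    n[singlet]
  res[, contamination := contam]
  for (j in seq_along(hyp))
    res[, (paste0("posterior_", hyp[j])) := post[, j]]
  res[]
}

#' Contamination fraction of an assigned singlet
#'
#' The proportion of informative reads that do not support the assigned
#' genotype among all reads covering biallelic SNPs: `(n - n_call) / n`.
#' Undefined (NA) for collision or unassigned calls.
#'
#' @param counts Allele counts ([count_alleles()]).
#' @param calls Calls from [genotype_posterior()] (matched by row).
#' @param genotypes Genotype labels; default: count columns.
#' @return Numeric vector of contamination fractions.
#' @export
contamination_rate <- function(counts, calls, genotypes = NULL) {
  counts <- as.data.table(counts)
  if (is.null(genotypes))
    genotypes <- setdiff(names(counts), c("barcode", "n"))
  C <- as.matrix(counts[, genotypes, with = FALSE])
  n <- if ("n" %in% names(counts)) counts$n else rowSums(C)
  call <- if (is.data.frame(calls)) calls$call else calls
  stopifnot(length(call) == nrow(counts))
  out <- rep(NA_real_, nrow(counts))
  singlet <- call %in% genotypes
  out[singlet] <- (n[singlet] -
                     C[cbind(which(singlet),
                             match(call[singlet], genotypes))]) / n[singlet]
  out
}

#' Expected-genotype assignment for multiplexed designs
#'
#' In a multiplexed run each Tn5 well holds one sample, so a nucleus's
#' expected genotype follows from its well via the well -> sample map.
#' Reads not matching the expected genotype are treated as belonging to
#' another genotype, and the usual binomial machinery tests
#' expected-singlet vs other-singlet vs collision; the mismatching-read
#' fraction of expected-singlet calls is the index-hopping
#' contamination.
#'
#' @param counts Allele counts ([count_alleles()]); barcodes must be
#'   combined `"<bead>-<well>"` strings.
#' @param well_map A [build_well_map()] with sample labels attached
#'   (see [add_well_samples()]).
#' @param params A [genotype_params()].
#' @param genotypes Genotype labels; default: count columns.
#' @return `data.table(barcode, well, expected_genotype, call,
#'   posterior_max, n, contamination)`; `call` is `"expected"`,
#'   `"other"`, `"collision"` or `"unassigned"`.
#' @export
assign_expected_genotype <- function(counts, well_map,
                                     params = genotype_params(),
                                     genotypes = NULL) {
  stopifnot(inherits(well_map, "well_map"))
  if (!"sample" %in% names(well_map$map))
    stop("well_map carries no sample labels; see add_well_samples()")
  counts <- as.data.table(counts)
  if (is.null(genotypes))
    genotypes <- setdiff(names(counts), c("barcode", "n"))
  C <- as.matrix(counts[, genotypes, with = FALSE])
  n <- if ("n" %in% names(counts)) counts$n else rowSums(C)

  well <- split_cell_barcode(counts$barcode)$well
  expct <- well_map$map$sample[match(well, well_map$map$well_id)]
  if (anyNA(expct))
    stop("well(s) without a sample label: ",
         paste(unique(well[is.na(expct)]), collapse = ", "))
  gi <- match(expct, genotypes)
  if (anyNA(gi)) stop("expected genotype not among count columns")
  n_exp <- C[cbind(seq_len(nrow(C)), gi)]
  two <- data.table(barcode = counts$barcode, expected = n_exp,
                    other = n - n_exp, n = n)
  res <- genotype_posterior(two, params, genotypes = c("expected", "other"))
  out <- data.table(barcode = counts$barcode, well = well,
                    expected_genotype = expct, call = res$call,
                    posterior_max = res$posterior_max, n = n,
                    contamination = ifelse(res$call == "expected",
                                           (n - n_exp) / n, NA_real_))
  out[]
}
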