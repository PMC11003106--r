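#' Droplet occupancy from retained (bead, well) combinations
#'
#' Each retained (bead, well) combination is one candidate nucleus; the
#' number of distinct retained wells per bead barcode is the droplet's
#' observed occupancy. (Nuclei that collide — same droplet, same well —
#' merge into one combination, so observed occupancy slightly
#' underestimates true loading at high collision rates.)
#'
#' @param combos Retained combinations: a `data.table`/data.frame with
#'   `bead` and `well` columns (e.g. the `retained == TRUE` rows from
#'   [filter_bead_well_combos()]).
#' @return Object of class `droplet_occupancy`: list with `distribution`
#'   (`data.table(k, n_droplets)`), `mean`, `n_droplets`, `n_nuclei`.
#' @export
droplet_occupancy <- function(combos) {
  combos <- as.data.table(combos)
  if (nrow(combos) == 0) {
    return(structure(list(distribution = data.table(k = integer(0),
                                                    n_droplets = integer(0)),
                          mean = NA_real_, n_droplets = 0L, n_nuclei = 0L),
                     class = "droplet_occupancy"))
  }
  stopifnot(all(c("bead", "well") %in% names(combos)))
  per <- unique(combos[, .(bead, well)])[, .(k = .N), by = bead]
  dist <- per[, .(n_droplets = .N), keyby = k]
  structure(list(distribution = dist[],
                 mean = mean(per$k),
                 n_droplets = nrow(per),
                 n_nuclei = sum(per$k)),
            class = "droplet_occupancy")
}

#' @export
print.droplet_occupancy <- function(x, ...) {
  cat(sprintf("Droplet occupancy: %d droplets, %d nuclei, mean %.3f\n",
              x$n_droplets, x$n_nuclei, x$mean))
  if (nrow(x$distribution))
    print(x$distribution, topn = 12)
  invisible(x)
}

#' Probability that >= 2 of k nuclei in a droplet share a Tn5 well
#'
#' The birthday problem over wells. For uniform well use the exact
#' falling-factorial product `1 - prod_{i=0}^{k-1} (W - i)/W`; for
#' non-uniform well probabilities the probability that all k wells
#' differ is `k! * e_k(p)`, with `e_k` the elementary symmetric
#' polynomial of degree k over the well probabilities, computed exactly
#' via Newton's identities for `k <= exact_max`; beyond that a seeded
#' Monte-Carlo estimate is used.
#'
#' @param k Droplet occupancy (vectorised).
#' @param well_probs Well loading distribution (normalised internally);
#'   `NULL` = uniform over `n_wells`.
#' @param n_wells Number of wells when `well_probs` is `NULL`.
#' @param exact_max Largest k for the exact symmetric-polynomial route
#'   (default 10).
#' @param mc_draws,mc_seed Monte-Carlo fallback settings.
#' @return Numeric vector of collision probabilities; `k >` number of
#'   wells with non-zero probability gives 1.
#' @export
same_well_collision_prob <- function(k, well_probs = NULL, n_wells = 96L,
                                     exact_max = 10L, mc_draws = 1e5,
                                     mc_seed = 1L) {
  stopifnot(all(k >= 0))
  if (is.null(well_probs)) {
    W <- n_wells
    vapply(k, function(ki) {
      if (ki < 2) return(0)
      if (ki > W) return(1)
      1 - prod((W - seq_len(ki) + 1) / W)
    }, numeric(1))
  } else {
    stopifnot(all(well_probs >= 0), sum(well_probs) > 0)
    p <- well_probs / sum(well_probs)
    W <- sum(p > 0)
    vapply(k, function(ki) {
      if (ki < 2) return(0)
      if (ki > W) return(1)
      if (ki <= exact_max) {
        1 - factorial(ki) * .esp(p, ki)
      } else {
        set.seed(mc_seed)
        draws <- matrix(sample.int(length(p), mc_draws * ki, replace = TRUE,
                                   prob = p), ncol = ki)
        dup <- rep(FALSE, mc_draws)
        for (i in seq_len(ki - 1)) {
          for (j in seq(i + 1, ki)) {
            dup <- dup | (draws[, i] == draws[, j])
          }
        }
        mean(dup)
      }
    }, numeric(1))
  }
}

# elementary symmetric polynomial e_k(p) via Newton's identities
.esp <- function(p, k) {
  ps <- vapply(seq_len(k), function(j) sum(p^j), numeric(1))
  e <- numeric(k + 1L)
  e[1L] <- 1
  for (m in seq_len(k)) {
    j <- seq_len(m)
    e[m + 1L] <- sum((-1)^(j - 1) * e[m - j + 1L] * ps[j]) / m
  }
  e[k + 1L]
}

#' Expected fraction of nuclei lost to same-well collisions
#'
#' Given the droplet-occupancy distribution and the well loading
#' probabilities, computes for each occupancy k the expected fraction
#' q(k) of the k nuclei that share their well with at least one other
#' nucleus of the droplet — by linearity of expectation,
#' `q(k) = 1 - sum_w p_w (1 - p_w)^(k-1)` exactly — and returns the
#' nucleus-weighted dataset expectation
#' `sum_k P(k) k q(k) / sum_k P(k) k`.
#'
#' @param occupancy A [droplet_occupancy()] object, or a
#'   `data.table`/data.frame with columns `k` and `n_droplets` (raw
#'   counts or probabilities; normalised internally, with a warning if a
#'   probability vector does not sum to 1).
#' @param well_probs Well distribution; `NULL` = uniform over `n_wells`.
#' @param n_wells Number of wells when `well_probs` is `NULL`.
#' @return List with `rate` (expected collided-nucleus fraction),
#'   `per_k` (`data.table(k, q)`), `mean_occupancy`.
#' @export
dataset_collision_rate <- function(occupancy, well_probs = NULL,
                                   n_wells = 96L) {
  if (inherits(occupancy, "droplet_occupancy"))
    occupancy <- occupancy$distribution
  occ <- as.data.table(occupancy)
  stopifnot(all(c("k", "n_droplets") %in% names(occ)), all(occ$k >= 0))
  pk <- occ$n_droplets
  if (all(pk <= 1) && abs(sum(pk) - 1) > 1e-6) {
    warning("occupancy distribution not normalised; normalising")
  }
  pk <- pk / sum(pk)
  if (is.null(well_probs)) well_probs <- rep(1 / n_wells, n_wells)
  p <- well_probs / sum(well_probs)
  q <- vapply(occ$k, function(ki) {
    if (ki < 2) return(0)
    1 - sum(p * (1 - p)^(ki - 1))
  }, numeric(1))
  wk <- pk * occ$k
  rate <- if (sum(wk) == 0) 0 else sum(wk * q) / sum(wk)
  list(rate = rate, per_k = data.table(k = occ$k, q = q),
       mean_occupancy = sum(pk * occ$k))
}

#' Correct an observed cross-genotype collision rate for unseen
#' same-genotype collisions
#'
#' Genotype-based collision detection only sees collisions between
#' *different* genotypes; collisions of nuclei sharing a genotype look
#' like singlets. If the genotype fractions are `f_g`, a random pair is
#' same-genotype with probability `sum f_g^2`, so the total rate is
#' `observed / (1 - sum f_g^2)` — the familiar doubling (x2) for an
#' equal two-genotype mixture.
#'
#' @param observed Observed (identified) cross-genotype collision
#'   rate(s); any scale (fraction or percent) — the correction is
#'   multiplicative.
#' @param genotype_fractions Numeric vector of genotype proportions
#'   (must sum to 1, length >= 2).
#' @return Corrected total collision rate(s), same scale as `observed`.
#' @export
total_collision_from_observed <- function(observed, genotype_fractions) {
  if (length(genotype_fractions) < 2)
    stop("at least two genotypes are required; with one genotype the ",
         "cross-genotype correction is undefined")
  if (abs(sum(genotype_fractions) - 1) > 1e-6)
    stop("genotype_fractions must sum to 1")
  stopifnot(all(genotype_fractions >= 0), all(observed >= 0))
  denom <- 1 - sum(genotype_fractions^2)
  if (denom <= 0) stop("degenerate genotype fractions")
  observed / denom
}

#' One-stop collision report for a demultiplexed experiment
#'
#' Chains [droplet_occupancy()] and [dataset_collision_rate()]; well
#' probabilities are estimated from the per-well retained-nucleus counts
#' (the wells' loading need not be uniform) unless `well_probs =
#' "uniform"`.
#'
#' @param combos Retained (bead, well) combinations.
#' @param n_wells Total number of wells on the plate.
#' @param well_probs `"estimate"` (default), `"uniform"`, or a numeric
#'   vector of length `n_wells`.
#' @return Object of class `collision_report`: list with `occupancy`,
#'   `well_probs`, `rate`, `per_k`.
#' @export
collision_report <- function(combos, n_wells = 96L,
                             well_probs = "estimate") {
  combos <- as.data.table(combos)
  occ <- droplet_occupancy(combos)
  if (identical(well_probs, "estimate")) {
    cnt <- combos[, .N, by = well]
    p <- numeric(n_wells)
    p[cnt$well] <- cnt$N
    p <- p / sum(p)
  } else if (identical(well_probs, "uniform")) {
    p <- rep(1 / n_wells, n_wells)
  } else {
    stopifnot(is.numeric(well_probs), length(well_probs) == n_wells)
    p <- well_probs / sum(well_probs)
  }
  est <- dataset_collision_rate(occ, well_probs = p)
  structure(list(occupancy = occ, well_probs = p, rate = est$rate,
                 per_k = est$per_k), class = "collision_report")
}

#' @export
print.collision_report <- function(x, ...) {
  cat("Barcode-collision report\n")
  cat(sprintf("  droplets / nuclei    : %d / %d\n", x$occupancy$n_droplets,
              x$occupancy$n_nuclei))
  cat(sprintf("  mean occupancy       : %.3f\n", x$occupancy$mean))
  cat(sprintf("  est. collided nuclei : %.3f%%\n", 100 * x$rate))
  invisible(x)
}
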