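#' Null ensemble specification
#'
#' Bundle of null-model settings shared by [beta_nti()],
#' [raup_crick_bray()] and [nst()].  The seed is recorded in all outputs.
#'
#' @param n_null Number of null replicates (>= 99 recommended for process
#'   classification; default 999).
#' @param seed Integer seed.
#' @return A `null_ensemble_spec` list.
#' @export
null_ensemble_spec <- function(n_null = 999, seed = 1) {
  stopifnot(n_null >= 1, is.finite(seed))
  if (n_null < 99)
    warning("n_null < 99: too few null replicates for process classification")
  structure(list(n_null = as.integer(n_null), seed = as.integer(seed)),
            class = "null_ensemble_spec")
}

#' Beta nearest taxon index (betaNTI)
#'
#' z-score of observed betaMNTD against a null ensemble generated by
#' shuffling tip labels across the whole tree (taxa-labels randomisation;
#' abundances untouched).  `betaNTI = (obs - mean(null)) / sd(null)`.
#' Pairs with a zero null standard deviation (e.g., a star phylogeny) are
#' undefined and returned as `NA`.
#'
#' @param table A [count_table()].
#' @param tree Matched [ape::phylo] tree.
#' @param spec A [null_ensemble_spec()].
#' @param weighted Abundance-weight betaMNTD (default `TRUE`).
#' @return A [pairwise_matrix()] with metric `"beta_nti"` and attributes
#'   `obs`, `null_mean`, `null_sd`, `n_null`, `seed`.
#' @export
beta_nti <- function(table, tree, spec = null_ensemble_spec(),
                     weighted = TRUE) {
  x <- unclass(table)
  if (nrow(x) < 2) stop("need at least 2 samples")
  d <- .patristic(tree, colnames(x))
  obs <- .beta_mntd_engine(x, d, weighted)
  n <- nrow(x); Tt <- ncol(x)
  sum_null <- matrix(0, n, n)
  sumsq_null <- matrix(0, n, n)
  old <- .seed_state(spec$seed)
  on.exit(.restore_seed(old))
  for (r in seq_len(spec$n_null)) {
    perm <- sample.int(Tt)
    b <- .beta_mntd_engine(x, d[perm, perm], weighted)
    sum_null <- sum_null + b
    sumsq_null <- sumsq_null + b * b
  }
  mu <- sum_null / spec$n_null
  sd_null <- sqrt(pmax((sumsq_null - spec$n_null * mu^2) /
                         (spec$n_null - 1), 0))
  z <- (obs - mu) / sd_null
  z[sd_null < 1e-12] <- NA_real_
  if (anyNA(z[upper.tri(z)]))
    warning("betaNTI undefined (zero null sd) for ",
            sum(is.na(z[upper.tri(z)])), " pair(s)")
  dimnames(z) <- dimnames(mu) <- dimnames(sd_null) <- dimnames(obs) <-
    list(rownames(x), rownames(x))
  out <- pairwise_matrix(z, "beta_nti", diagonal = NA_real_)
  attr(out, "obs") <- obs
  attr(out, "null_mean") <- mu
  attr(out, "null_sd") <- sd_null
  attr(out, "n_null") <- spec$n_null
  attr(out, "seed") <- spec$seed
  out
}

# one null community constrained to the observed richness and total of its
# real counterpart: taxa drawn without replacement with probability
# proportional to regional occupancy, then remaining individuals assigned
# with probability proportional to regional relative abundance
.rc_null_sample <- function(richness, total, occ_w, abund_w) {
  k <- length(occ_w)
  taxa <- sample.int(k, richness, replace = FALSE, prob = occ_w)
  counts <- numeric(k)
  counts[taxa] <- 1
  extra <- total - richness
  if (extra > 0) {
    w <- abund_w[taxa]
    counts[taxa] <- counts[taxa] +
      as.numeric(stats::rmultinom(1, extra, w / sum(w)))
  }
  counts
}

.bc_pair <- function(a, b) 1 - 2 * sum(pmin(a, b)) / sum(a + b)

#' Bray-Curtis-based Raup-Crick (RC_bray)
#'
#' For each sample pair, the observed Bray-Curtis dissimilarity is
#' compared with a null distribution of dissimilarities between null
#' communities that preserve each sample's observed richness and total
#' abundance, with taxon identities drawn by regional occupancy and
#' abundances by regional relative abundance (the "regional pool" is the
#' whole analysed table by default).  `RC = 2 * [P(null < obs) + 0.5 *
#' P(null = obs)] - 1`, in [-1, 1].
#'
#' Per-pair null draws use sub-seeds derived from `(spec$seed, pair
#' index)` so results are independent of pair evaluation order.
#'
#' @param table A [count_table()] with integer counts.
#' @param spec A [null_ensemble_spec()].
#' @param pool_samples Optional character vector of sample ids defining the
#'   regional pool for occupancy/abundance weights (default: all samples).
#' @return A [pairwise_matrix()] with metric `"rc_bray"` and attributes
#'   `obs_bc`, `n_null`, `seed`.
#' @export
raup_crick_bray <- function(table, spec = null_ensemble_spec(),
                            pool_samples = NULL) {
  x <- unclass(table)
  if (nrow(x) < 2) stop("need at least 2 samples")
  pool <- if (is.null(pool_samples)) x else {
    stopifnot(all(pool_samples %in% rownames(x)))
    x[pool_samples, , drop = FALSE]
  }
  occ_w <- colSums(pool > 0)
  abund_w <- colSums(pool)
  rich <- rowSums(x > 0)
  tot <- rowSums(x)
  n <- nrow(x)
  obs <- bray_curtis(count_table(x))
  rc <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  pair_index <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pair_index <- pair_index + 1L
    old <- .seed_state(.sub_seed(spec$seed, pair_index))
    less <- 0; equal <- 0
    oij <- obs[i, j]
    for (r in seq_len(spec$n_null)) {
      a <- .rc_null_sample(rich[i], tot[i], occ_w, abund_w)
      b <- .rc_null_sample(rich[j], tot[j], occ_w, abund_w)
      bc <- .bc_pair(a, b)
      if (abs(bc - oij) < 1e-12) equal <- equal + 1
      else if (bc < oij) less <- less + 1
    }
    .restore_seed(old)
    rc[i, j] <- rc[j, i] <- 2 * (less + 0.5 * equal) / spec$n_null - 1
  }
  out <- pairwise_matrix(rc, "rc_bray", diagonal = NA_real_)
  attr(out, "obs_bc") <- unclass(obs)
  attr(out, "n_null") <- spec$n_null
  attr(out, "seed") <- spec$seed
  out
}

#' Classify community assembly processes from betaNTI and RC_bray
#'
#' Five-way rule (strict inequalities): `betaNTI > 2` variable selection;
#' `betaNTI < -2` homogeneous selection; otherwise `RC > 0.95` dispersal
#' limitation; `RC < -0.95` homogenizing dispersal; else undominated.
#' The stochastic fraction is dispersal limitation + homogenizing
#' dispersal + undominated; the deterministic fraction is the two
#' selection processes.  Pairs with undefined betaNTI are excluded and
#' counted.
#'
#' @param bnti betaNTI [pairwise_matrix()].
#' @param rc RC_bray [pairwise_matrix()].
#' @param pairs Optional 2-column matrix of sample-id pairs to summarise
#'   (e.g., from [within_group_pairs()]); default all pairs.
#' @return A `process_summary` list: `pairs` (per-pair data frame),
#'   `counts`, `fractions`, `stochastic_fraction`,
#'   `deterministic_fraction`, `n_excluded`.
#' @export
classify_processes <- function(bnti, rc, pairs = NULL) {
  if (!identical(rownames(bnti), rownames(rc)))
    stop("betaNTI and RC matrices must share ids")
  if (is.null(pairs)) pairs <- .all_pairs(rownames(bnti))
  stopifnot(ncol(pairs) == 2)
  b <- bnti[cbind(pairs[, 1], pairs[, 2])]
  r <- rc[cbind(pairs[, 1], pairs[, 2])]
  lab <- ifelse(b > 2, "variable_selection",
         ifelse(b < -2, "homogeneous_selection",
         ifelse(r > 0.95, "dispersal_limitation",
         ifelse(r < -0.95, "homogenizing_dispersal", "undominated"))))
  excluded <- is.na(b) | is.na(r)
  if (any(excluded))
    warning(sum(excluded), " pair(s) with undefined statistics excluded")
  lab[excluded] <- NA_character_
  levels <- c("variable_selection", "homogeneous_selection",
              "dispersal_limitation", "homogenizing_dispersal",
              "undominated")
  counts <- table(factor(lab, levels = levels))
  n_lab <- sum(counts)
  fractions <- if (n_lab > 0) as.numeric(counts) / n_lab
               else rep(NA_real_, 5)
  names(fractions) <- levels
  structure(list(
    pairs = data.frame(sample_1 = pairs[, 1], sample_2 = pairs[, 2],
                       beta_nti = b, rc_bray = r, process = lab,
                       stringsAsFactors = FALSE),
    counts = counts,
    fractions = fractions,
    stochastic_fraction = sum(fractions[3:5]),
    deterministic_fraction = sum(fractions[1:2]),
    n_excluded = sum(excluded)),
    class = "process_summary")
}

#' @export
print.process_summary <- function(x, ...) {
  cat("process_summary over", nrow(x$pairs), "pairs",
      if (x$n_excluded > 0) paste0("(", x$n_excluded, " excluded)"), "\n")
  print(round(100 * x$fractions, 1))
  cat("stochastic:", round(100 * x$stochastic_fraction, 1), "%\n")
  invisible(x)
}
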