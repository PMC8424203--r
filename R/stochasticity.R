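#' Normalized stochasticity ratio (NST)
#'
#' For each sample pair, observed dissimilarity `D_ij` is compared with
#' the expectation `E_ij` under a null that preserves each sample's
#' richness and total abundance and draws taxa by regional occupancy and
#' abundances by regional relative abundance (the same null engine as
#' [raup_crick_bray()], applied table-wide).  Selection strength is
#' `SS = (D - E) / (D_max - E)` when `D >= E`, else `(E - D) / E`
#' (`D_max = 1` for bounded metrics), and `NST_ij = 1 - SS`.  The group
#' value is the arithmetic mean of within-group pairwise NST, in percent;
#' 50% is the conventional boundary between more deterministic (<50%) and
#' more stochastic (>50%) assembly.
#'
#' @param table A [count_table()].
#' @param groups Named vector of group labels (names = sample ids).
#' @param metric `"bray_curtis"` or `"jaccard"` (binary).
#' @param spec A [null_ensemble_spec()].
#' @return An `nst_result` list: `pairwise` data frame (D, E, SS, NST per
#'   within-group pair), `group_nst` (percent, per group), `metric`,
#'   `n_null`, `seed`.
#' @export
nst <- function(table, groups, metric = c("bray_curtis", "jaccard"),
                spec = null_ensemble_spec()) {
  metric <- match.arg(metric)
  x <- unclass(table)
  if (is.null(names(groups))) stop("groups must be named by sample id")
  groups <- groups[rownames(x)]
  if (any(tabulate(factor(groups)) < 3))
    stop("each group needs >= 3 samples")
  dis <- function(m) {
    if (metric == "bray_curtis") unclass(bray_curtis(count_table(m)))
    else as.matrix(vegan::vegdist(m > 0, method = "jaccard"))
  }
  D <- dis(x)
  occ_w <- colSums(x > 0)
  abund_w <- colSums(x)
  rich <- rowSums(x > 0)
  tot <- rowSums(x)
  n <- nrow(x)
  Esum <- matrix(0, n, n, dimnames = dimnames(D))
  old <- .seed_state(spec$seed)
  on.exit(.restore_seed(old))
  # null rows are drawn in sorted sample-id order so the result does not
  # depend on the input row order
  ord <- order(rownames(x))
  for (r in seq_len(spec$n_null)) {
    nullx <- t(vapply(ord, function(i)
      .rc_null_sample(rich[i], tot[i], occ_w, abund_w), numeric(ncol(x))))
    rownames(nullx) <- rownames(x)[ord]
    colnames(nullx) <- colnames(x)
    Esum <- Esum + dis(nullx)[rownames(D), colnames(D)]
  }
  E <- Esum / spec$n_null
  pairs <- within_group_pairs(groups)
  d_obs <- D[cbind(pairs[, 1], pairs[, 2])]
  e_null <- E[cbind(pairs[, 1], pairs[, 2])]
  ss <- .selection_strength(d_obs, e_null)
  undef <- e_null <= 0 | e_null >= 1
  if (any(undef))
    warning(sum(undef), " pair(s) with degenerate null expectation excluded")
  ss[undef] <- NA_real_
  nst_ij <- 1 - ss
  grp <- groups[pairs[, 1]]
  group_nst <- 100 * vapply(split(nst_ij, grp), mean, numeric(1),
                            na.rm = TRUE)
  structure(list(
    pairwise = data.frame(sample_1 = pairs[, 1], sample_2 = pairs[, 2],
                          group = as.character(grp), d_obs = d_obs,
                          e_null = e_null, ss = ss, nst = nst_ij,
                          stringsAsFactors = FALSE),
    group_nst = group_nst, metric = metric,
    n_null = spec$n_null, seed = spec$seed),
    class = "nst_result")
}

# normalized selection strength: how far the observed dissimilarity sits
# from its null expectation, scaled by the attainable range on that side
.selection_strength <- function(d_obs, e_null, d_max = 1) {
  ifelse(d_obs >= e_null, (d_obs - e_null) / (d_max - e_null),
         (e_null - d_obs) / e_null)
}

# Sloan predicted occurrence frequency for mean relative abundance p,
# immigration parameter Nm and detection limit d
.sloan_freq <- function(p, Nm, d) {
  1 - stats::pbeta(d, Nm * p, Nm * (1 - p))
}

#' Fit the Sloan neutral community model
#'
#' Predicts each taxon's occurrence frequency across local communities
#' from its mean relative abundance `p` under neutral drift with
#' immigration: `F(p) = 1 - Beta_CDF(d; Nm p, Nm (1 - p))`, with `d` the
#' detection limit (default `1/N`, `N` = mean sample total) and `Nm` the
#' metacommunity-size x migration product.  `Nm` is fitted by least
#' squares on the observed frequencies (log-scale line search over
#' `[1e-3 N, 1e6]`); the 95% band is the Wilson binomial interval of the
#' predicted frequency over the number of samples.
#'
#' @param table A [count_table()].
#' @param detection_limit Relative-abundance detection limit, or
#'   `"auto"` for `1/N`.
#' @return A `neutral_fit` list: `Nm`, `m`, `N`, `R2`, `detection_limit`,
#'   `taxa` (per-taxon p, freq_obs, freq_pred, band, position flag),
#'   `fraction_inside`.
#' @export
sloan_fit <- function(table, detection_limit = "auto") {
  x <- unclass(table)
  n_samples <- nrow(x)
  p <- colMeans(x / rowSums(x))
  keep <- p > 0
  if (sum(keep) < 10) stop("need >= 10 taxa with nonzero mean abundance")
  p <- p[keep]
  freq <- colMeans(x[, keep, drop = FALSE] > 0)
  if (stats::var(freq) == 0)
    stop("occurrence frequencies have zero variance; model cannot be fitted")
  N <- mean(rowSums(x))
  d <- if (identical(detection_limit, "auto")) 1 / N
       else as.numeric(detection_limit)
  sse <- function(logNm) {
    pred <- .sloan_freq(p, exp(logNm), d)
    sum((freq - pred)^2)
  }
  lo <- log(1e-3 * N); hi <- log(1e6)
  opt <- stats::optimize(sse, c(lo, hi), tol = 1e-8)
  if (opt$minimum > hi - 1e-4 || opt$minimum < lo + 1e-4)
    stop("Nm fit did not converge inside the search bracket [",
         signif(exp(lo), 3), ", ", signif(exp(hi), 3), "]")
  Nm <- exp(opt$minimum)
  pred <- .sloan_freq(p, Nm, d)
  r2 <- 1 - sum((freq - pred)^2) / sum((freq - mean(freq))^2)
  band <- .wilson(pred, n_samples)
  position <- ifelse(freq > band[, "upper"], "above",
              ifelse(freq < band[, "lower"], "below", "inside"))
  taxa <- data.frame(taxon_id = names(p), p = as.numeric(p),
                     freq_obs = as.numeric(freq),
                     freq_pred = as.numeric(pred),
                     lower = band[, "lower"], upper = band[, "upper"],
                     position = position,
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(Nm = Nm, m = Nm / N, N = N, R2 = r2,
                 detection_limit = d, taxa = taxa,
                 fraction_inside = mean(position == "inside")),
            class = "neutral_fit")
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat("Sloan neutral community model: Nm =", signif(x$Nm, 4),
      " m =", signif(x$m, 4), " R2 =", round(x$R2, 3), "\n")
  cat("taxa inside 95% band:", round(100 * x$fraction_inside, 1), "%\n")
  invisible(x)
}

#' Levins' niche breadth
#'
#' For taxon i with distribution `q_ij` across samples, `B_i = 1 /
#' sum_j q_ij^2` (inverse Simpson concentration, between 1 and the number
#' of samples); `Bcom` is the unweighted mean of `B_i` over taxa.
#'
#' @param table A [count_table()].
#' @return A list: `per_taxon` data frame (`taxon_id`, `B`) and `Bcom`.
#' @export
levins_breadth <- function(table) {
  x <- unclass(table)
  cs <- colSums(x)
  if (any(cs == 0)) stop("taxon occurring in no sample")
  q <- t(x) / cs
  B <- 1 / rowSums(q^2)
  list(per_taxon = data.frame(taxon_id = colnames(x), B = as.numeric(B),
                              stringsAsFactors = FALSE),
       Bcom = mean(B))
}

#' Abundance-weighted niche values of taxa
#'
#' The niche value of taxon i for environmental variable v is the
#' abundance-weighted mean of the (z-standardised) variable over samples:
#' `n_iv = sum_j (x_ij / sum_j x_ij) * env_jv`.  Taxa occurring in fewer
#' than 2 samples are excluded with a warning.
#'
#' @param table A [count_table()].
#' @param env Data frame of numeric covariates, rows = samples.
#' @param standardize z-score the covariates first (default `TRUE`).
#' @return Matrix taxa x variables of niche values.
#' @export
niche_values <- function(table, env, standardize = TRUE) {
  x <- unclass(table)
  env <- as.matrix(env[rownames(x), , drop = FALSE])
  if (!is.numeric(env)) stop("env columns must be numeric")
  if (standardize) {
    env <- scale(env)
    env[, attr(env, "scaled:scale") == 0] <- 0  # constant covariates
  }
  occ <- colSums(x > 0)
  if (any(occ < 2)) {
    warning(sum(occ < 2), " taxa occurring in < 2 samples excluded")
    x <- x[, occ >= 2, drop = FALSE]
  }
  q <- t(x) / colSums(x)
  q %*% env
}

#' Phylogenetic-signal Mantel correlogram
#'
#' Tests whether ecologically similar taxa (similar niche values) are
#' phylogenetically close: per phylogenetic-distance class, the Mantel
#' correlation between the Euclidean niche-distance matrix and the class
#' membership matrix, with taxon-label permutation p-values and
#' progressive Holm correction (vegan's `mantel.correlog`).  A positive r
#' in the shortest classes indicates phylogenetically conserved niches —
#' the precondition for interpreting betaNTI.
#'
#' @param table A [count_table()].
#' @param tree Matched [ape::phylo] tree.
#' @param env Data frame of numeric covariates (rows = samples), or a
#'   precomputed niche matrix via `niche` (overrides `table`/`env`).
#' @param niche Optional taxa x variables niche matrix (e.g., a trait).
#' @param n_classes Number of distance classes; `NULL` = Sturges' rule.
#' @param n_perm Permutations for the per-class tests.
#' @param seed Integer seed for the permutations.
#' @param min_pairs Classes with fewer pairs are masked to `NA`
#'   (default 30; set 0 to keep all).
#' @return A `correlogram_result` list: `classes` data frame
#'   (`class_index` midpoints, `n_pairs`, `mantel_r`, `p`, `p_corrected`),
#'   `breaks`, `n_perm`, `seed`.
#' @export
phylo_signal_correlogram <- function(table = NULL, tree, env = NULL,
                                     niche = NULL, n_classes = NULL,
                                     n_perm = 999, seed = 1,
                                     min_pairs = 30) {
  if (is.null(niche)) {
    if (is.null(table) || is.null(env))
      stop("supply either a niche matrix or a table plus env covariates")
    niche <- niche_values(table, env)
  }
  niche <- as.matrix(niche)
  taxa <- rownames(niche)
  if (is.null(taxa)) stop("niche matrix needs taxon row names")
  dn <- stats::dist(niche)
  if (max(dn) == 0) {
    warning("zero variance in niche distances; correlogram undefined")
    return(structure(list(classes = NULL, breaks = NULL,
                          n_perm = n_perm, seed = seed, undefined = TRUE),
                     class = "correlogram_result"))
  }
  dp <- stats::as.dist(.patristic(tree, taxa))
  old <- .seed_state(seed)
  on.exit(.restore_seed(old))
  res <- vegan::mantel.correlog(dn, D.geo = dp,
                                n.class = if (is.null(n_classes)) 0
                                          else n_classes,
                                nperm = n_perm, cutoff = FALSE,
                                mult = "holm", progressive = TRUE)
  m <- res$mantel.res
  cls <- data.frame(class_index = m[, "class.index"],
                    n_pairs = m[, "n.dist"] / 2,  # vegan counts both triangles
                    mantel_r = m[, "Mantel.cor"],
                    p = m[, "Pr(Mantel)"],
                    p_corrected = m[, "Pr(corrected)"],
                    row.names = NULL)
  if (min_pairs > 0) {
    mask <- cls$n_pairs < min_pairs
    cls$mantel_r[mask] <- NA_real_
    cls$p[mask] <- cls$p_corrected[mask] <- NA_real_
  }
  structure(list(classes = cls, breaks = res$break.pts,
                 n_perm = n_perm, seed = seed, undefined = FALSE),
            class = "correlogram_result")
}
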