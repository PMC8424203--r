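#' Alpha diversity per sample
#'
#' Richness (taxa with count > 0), Shannon entropy and, when a tree is
#' supplied, Faith's phylogenetic diversity (total branch length of the
#' minimal subtree spanning the observed tips; by rooted convention the
#' path to the root is included, switchable via `include_root`).
#'
#' @param table A [count_table()].
#' @param tree Optional matched [ape::phylo] tree (see
#'   [match_tree_table()]).
#' @param base Logarithm base for Shannon; default natural log (nats).
#' @param include_root Include the root connection in Faith's PD.
#' @return Data frame with one row per sample: `sample_id`, `richness`,
#'   `shannon` and (if `tree` given) `faith_pd`.
#' @export
alpha_diversity <- function(table, tree = NULL, base = exp(1),
                            include_root = TRUE) {
  x <- unclass(table)
  if (any(rowSums(x) == 0)) stop("empty sample")
  rich <- rowSums(x > 0)
  shan <- vegan::diversity(x, index = "shannon", base = base)
  out <- data.frame(sample_id = rownames(x), richness = as.integer(rich),
                    shannon = as.numeric(shan),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(tree)) {
    if (!all(colnames(x) %in% tree$tip.label))
      stop("tree does not cover all taxa; run match_tree_table() first")
    pd <- picante::pd(x, tree, include.root = include_root)
    out$faith_pd <- pd[rownames(x), "PD"]
  }
  out
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC_ij = 1 - 2 * sum_k min(x_ik, x_jk) / sum_k (x_ik + x_jk)`.
#'
#' @param table A [count_table()] (typically post-rarefaction).
#' @param normalize Convert each sample to relative abundance first.
#' @return A [pairwise_matrix()] with metric `"bray_curtis"`.
#' @export
bray_curtis <- function(table, normalize = FALSE) {
  x <- unclass(table)
  if (nrow(x) < 2) stop("need at least 2 samples")
  if (any(rowSums(x) == 0)) stop("all-zero sample")
  if (normalize) x <- x / rowSums(x)
  n <- nrow(x)
  m <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <-
      1 - 2 * sum(pmin(x[i, ], x[j, ])) / sum(x[i, ] + x[j, ])
  }
  pairwise_matrix(m, "bray_curtis")
}

# patristic (cophenetic) distances, ordered to the table's taxa
.patristic <- function(tree, taxa) {
  d <- ape::cophenetic.phylo(tree)
  if (!all(taxa %in% rownames(d)))
    stop("tree does not cover all taxa")
  d[taxa, taxa]
}

# betaMNTD for all sample pairs given a patristic matrix; used by both the
# observed statistic and the betaNTI null ensemble
.beta_mntd_engine <- function(x, d, weighted) {
  pres <- apply(x > 0, 1, which, simplify = FALSE)
  f <- if (weighted) x / rowSums(x) else (x > 0) / rowSums(x > 0)
  M <- .min_dist_to_samples(d, pres)        # taxa x samples
  B <- f %*% M                              # B[i,j] = sum_k f_ik min->j
  0.5 * (B + t(B))
}

#' Beta mean nearest taxon distance (betaMNTD)
#'
#' For samples i and j, the mean over taxa in i of the patristic distance
#' to the closest taxon present in j, and vice versa, averaged; taxa
#' shared by both samples contribute distance 0 (self counts as nearest).
#' Weights are relative abundances when `weighted = TRUE` (default, the
#' convention of the betaNTI framework), else 1/richness.
#'
#' @param table A [count_table()].
#' @param tree Matched [ape::phylo] tree.
#' @param weighted Abundance-weight the taxon contributions.
#' @return A [pairwise_matrix()] with metric `"beta_mntd"`.
#' @export
beta_mntd <- function(table, tree, weighted = TRUE) {
  x <- unclass(table)
  if (any(rowSums(x) == 0)) stop("sample with zero taxa")
  d <- .patristic(tree, colnames(x))
  m <- .beta_mntd_engine(x, d, weighted)
  dimnames(m) <- list(rownames(x), rownames(x))
  pairwise_matrix(m, "beta_mntd")
}
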