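# RNG scoping: every stochastic operation takes an explicit seed and leaves
# the global generator as it found it.
.seed_state <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  old
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# deterministic per-component sub-seed, kept inside 32-bit integer range
.sub_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + as.numeric(index) * 69621) %% 2147483587 + 1
}

#' Construct a pairwise matrix
#'
#' Symmetric id-indexed matrix carrying a named metric (Bray-Curtis,
#' betaMNTD, betaNTI, RC_bray, correlation, ...).  Dissimilarities carry a
#' zero diagonal; signed statistics may use `diagonal = NA`.
#'
#' @param mat Square numeric matrix with identical row/column names.
#' @param metric Character name of the metric.
#' @param diagonal Diagonal value convention, written onto the diagonal.
#' @return A `pairwise_matrix`.
#' @export
pairwise_matrix <- function(mat, metric, diagonal = 0) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat) ||
      !identical(rownames(mat), colnames(mat)))
    stop("pairwise matrix must be square with matching id names")
  if (isTRUE(any(abs(mat - t(mat)) > 1e-8, na.rm = TRUE)))
    stop("pairwise matrix must be symmetric")
  diag(mat) <- diagonal
  structure(mat, metric = metric,
            class = c("pairwise_matrix", "matrix", "array"))
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat("pairwise_matrix [", attr(x, "metric"), "]: ", nrow(x), " ids\n",
      sep = "")
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

#' Write a pairwise matrix as labelled square tsv
#' @param x A [pairwise_matrix()].
#' @param path Output path.
#' @export
write_pairwise_matrix <- function(x, path) {
  df <- data.frame(id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# all unordered sample pairs of a set of ids, as a 2-column character matrix
.all_pairs <- function(ids) {
  if (length(ids) < 2) stop("need at least 2 ids")
  t(utils::combn(ids, 2))
}

#' Within-group sample pairs
#'
#' Helper building the pair set consumed by [classify_processes()] and
#' [nst()]: all unordered pairs of samples sharing a group label.
#'
#' @param groups Named character/factor vector (names = sample ids).
#' @return Two-column character matrix of sample id pairs.
#' @export
within_group_pairs <- function(groups) {
  if (is.null(names(groups))) stop("groups must be named by sample id")
  out <- do.call(rbind, lapply(split(names(groups), groups), function(ids) {
    if (length(ids) < 2) return(NULL)
    .all_pairs(ids)
  }))
  if (is.null(out)) stop("no group has >= 2 samples")
  rownames(out) <- NULL
  out
}

# minimum patristic distance from every taxon (rows of d) into each sample's
# taxon set; returns taxa x samples matrix
.min_dist_to_samples <- function(d, presence) {
  vapply(presence, function(idx) {
    if (length(idx) == 1L) d[, idx]
    else do.call(pmin, lapply(idx, function(j) d[, j]))
  }, numeric(nrow(d)))
}

# Wilson score interval for a binomial proportion
.wilson <- function(p, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  cbind(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}
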