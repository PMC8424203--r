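#' Construct a count table
#'
#' A `count_table` is the universal currency of all analyses in this
#' package: a samples x taxa matrix of non-negative integer counts with
#' unique sample ids as row names and unique taxon ids as column names.
#'
#' @param counts Numeric matrix, samples in rows, taxa in columns. Row and
#'   column names are required and must be unique.
#' @param allow_float If `TRUE`, non-integer entries are floored with a
#'   warning instead of raising an error.
#' @return A `count_table` object (an integer-valued matrix with class
#'   attribute).
#' @export
count_table <- function(counts, allow_float = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count table needs sample ids (rownames) and taxon ids (colnames)")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate taxon ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric and non-missing")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(counts != floor(counts))) {
    if (allow_float) {
      warning("non-integer counts floored")
      counts <- floor(counts)
    } else {
      stop("non-integer counts found; use allow_float = TRUE to floor them")
    }
  }
  empty <- rownames(counts)[rowSums(counts) == 0]
  if (length(empty) > 0)
    stop("empty sample(s): ", paste(empty, collapse = ", "))
  storage.mode(counts) <- "double"
  structure(counts, class = c("count_table", "matrix", "array"))
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x), "samples x", ncol(x), "taxa; total counts",
      format(sum(x), big.mark = ","), "\n")
  invisible(x)
}

#' Read a count table from disk
#'
#' Tab-separated layout follows the amplicon convention: taxa as rows,
#' samples as columns, first column the taxon id.  `orientation =
#' "samples_x_taxa"` flips this for tables already stored the other way.
#' BIOM (JSON) tables are read through the biomformat package.
#'
#' @param path File path.
#' @param format `"tsv"` or `"biom-json"`.
#' @param orientation For tsv input, `"taxa_x_samples"` (default) or
#'   `"samples_x_taxa"`.
#' @param allow_float Passed to [count_table()].
#' @return A [count_table()].
#' @export
read_count_table <- function(path, format = c("tsv", "biom-json"),
                             orientation = c("taxa_x_samples",
                                             "samples_x_taxa"),
                             allow_float = FALSE) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom-json") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("biomformat package required for BIOM input")
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))  # taxa x samples
    return(count_table(t(m), allow_float = allow_float))
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate ids in first column: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  if (orientation == "taxa_x_samples") m <- t(m)
  count_table(m, allow_float = allow_float)
}

#' Write a count table to tab-separated text
#'
#' Writes taxa as rows and samples as columns (the reading convention of
#' [read_count_table()]), with integer formatting so that a
#' read/write cycle is byte-identical.
#'
#' @param table A [count_table()].
#' @param path Output path.
#' @param id_column Header of the first (taxon id) column.
#' @export
write_count_table <- function(table, path, id_column = "taxon_id") {
  m <- t(unclass(table))  # taxa x samples
  df <- data.frame(id = rownames(m), format(m, scientific = FALSE,
                                            trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata
#'
#' @param path Tab-separated file whose first column holds sample ids.
#' @param table Optional [count_table()]; if given, metadata rows are
#'   checked and reordered to match its samples.
#' @return A data frame with sample ids as row names.
#' @export
read_sample_metadata <- function(path, table = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate sample ids in metadata")
  rownames(df) <- ids
  df <- df[, -1, drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  if (any(vapply(df[num], function(z) any(!is.finite(z)), logical(1))))
    stop("non-finite numeric covariate in metadata")
  if (!is.null(table)) {
    missing <- setdiff(rownames(table), ids)
    if (length(missing) > 0)
      stop("metadata missing sample(s): ", paste(missing, collapse = ", "))
    df <- df[rownames(table), , drop = FALSE]
  }
  df
}

#' Rarefy a count table to even depth
#'
#' Random subsampling without replacement within each sample (multivariate
#' hypergeometric), one independent draw per sample from a single seeded
#' generator, taken in stored sample order.  Samples whose total is below
#' `depth` are dropped with a warning; taxa left with all-zero columns are
#' removed.
#'
#' @param table A [count_table()].
#' @param depth Target depth (positive integer).
#' @param seed Integer seed.
#' @return A rarefied [count_table()] with attribute `dropped_samples`.
#' @export
rarefy <- function(table, depth, seed) {
  stopifnot(depth >= 1, depth == floor(depth))
  totals <- rowSums(table)
  if (all(totals < depth))
    stop("depth ", depth, " exceeds every sample's total (max ",
         max(totals), ")")
  drop <- rownames(table)[totals < depth]
  if (length(drop) > 0)
    warning("dropping sample(s) below depth ", depth, ": ",
            paste(drop, collapse = ", "))
  keep <- setdiff(rownames(table), drop)
  out <- matrix(0, length(keep), ncol(table),
                dimnames = list(keep, colnames(table)))
  old <- .seed_state(seed)
  on.exit(.restore_seed(old))
  for (s in keep) {
    x <- unclass(table)[s, ]
    if (sum(x) == depth) {
      out[s, ] <- x
    } else {
      pool <- rep.int(seq_along(x), x)
      take <- sample(pool, depth, replace = FALSE)
      out[s, ] <- tabulate(take, nbins = length(x))
    }
  }
  out <- out[, colSums(out) > 0, drop = FALSE]
  res <- count_table(out)
  attr(res, "dropped_samples") <- drop
  res
}

#' Read a rooted Newick tree
#'
#' Zero-length branches and polytomies are permitted.  Unrooted trees are
#' an error unless `midpoint_root = TRUE`, in which case the tree is
#' midpoint-rooted.
#'
#' @param path Newick file.
#' @param midpoint_root Root an unrooted input at its midpoint.
#' @return An [ape::phylo] tree.
#' @export
read_tree <- function(path, midpoint_root = FALSE) {
  tr <- ape::read.tree(path)
  if (is.null(tr$edge.length))
    stop("tree has no branch lengths")
  if (any(tr$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels")
  if (!ape::is.rooted(tr)) {
    if (!midpoint_root)
      stop("tree is unrooted; re-root it or pass midpoint_root = TRUE")
    tr <- phangorn::midpoint(tr)
  }
  tr
}

#' Reconcile a count table and a tree
#'
#' Prunes both objects to the intersection of taxon ids and tip labels.
#'
#' @param table A [count_table()].
#' @param tree An [ape::phylo] tree.
#' @return List with elements `table`, `tree`, `dropped_taxa`,
#'   `dropped_tips`.
#' @export
match_tree_table <- function(table, tree) {
  shared <- intersect(colnames(table), tree$tip.label)
  if (length(shared) == 0)
    stop("no shared labels between count table and tree")
  dropped_taxa <- setdiff(colnames(table), shared)
  dropped_tips <- setdiff(tree$tip.label, shared)
  tab <- unclass(table)[, shared, drop = FALSE]
  keep_rows <- rowSums(tab) > 0
  if (!all(keep_rows))
    warning("sample(s) emptied by pruning: ",
            paste(rownames(tab)[!keep_rows], collapse = ", "))
  tab <- count_table(tab[keep_rows, , drop = FALSE])
  tr <- if (length(dropped_tips) > 0)
    ape::drop.tip(tree, dropped_tips) else tree
  list(table = tab, tree = tr,
       dropped_taxa = dropped_taxa, dropped_tips = dropped_tips)
}
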