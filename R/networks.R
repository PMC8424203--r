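#' Prepare a count table for network construction
#'
#' Square-root transforms the counts and keeps only taxa detected in more
#' than half of the samples (majority rule).
#'
#' @param table A [count_table()].
#' @return A plain numeric matrix (samples x taxa) of transformed
#'   abundances for the retained taxa.
#' @export
prepare_nodes <- function(table) {
  x <- unclass(table)
  if (nrow(x) < 6) stop("need >= 6 samples for correlation networks")
  keep <- colSums(x > 0) > nrow(x) / 2
  if (sum(keep) < 2) stop("fewer than 2 taxa survive the majority rule")
  sqrt(x[, keep, drop = FALSE])
}

#' Pearson correlations between taxa
#'
#' @param prepared Matrix from [prepare_nodes()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A [pairwise_matrix()] with metric `"correlation"`, diagonal 1.
#' @export
taxon_correlations <- function(prepared, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  r <- stats::cor(prepared, method = method)
  pairwise_matrix(r, "correlation", diagonal = 1)
}

# unfold a spectrum: distinct sorted eigenvalues -> unfolded levels with
# unit mean spacing, via a monotone 5-point smoothing of the cumulative
# level count
.unfold_spectrum <- function(ev, window = 5) {
  lam <- sort(unique(round(ev, 10)))
  n <- length(lam)
  if (n < 3) return(NULL)
  idx <- seq_len(n)
  # smooth the staircase N(lambda) with a low-df spline (so local
  # fluctuations survive the unfolding), then monotonize the prediction
  fit <- stats::smooth.spline(lam, idx, df = min(n - 1, 8))
  eps <- cummax(stats::predict(fit, lam)$y)
  s <- diff(eps)
  s / mean(s)
}

# chi-square goodness of fit of unit-mean spacings against the Poisson
# form exp(-s) on [0, smax] with nbins bins; returns the p-value
.poisson_gof <- function(s, smax = 3, nbins = 10) {
  s <- s[is.finite(s)]
  s <- pmin(s, smax)  # fold the tail into the last bin
  br <- seq(0, smax, length.out = nbins + 1)
  obs <- as.numeric(graphics::hist(s, breaks = br, plot = FALSE)$counts)
  pr <- exp(-br[-length(br)]) - exp(-br[-1])
  pr[nbins] <- pr[nbins] + exp(-smax)  # folded tail mass
  # merge bins until every expected count is >= 5 (chi-square validity)
  exp_ct <- length(s) * pr
  grp <- cumsum(exp_ct >= 5 | c(TRUE, exp_ct[-nbins] >= 5))
  o <- tapply(obs, grp, sum)
  e <- tapply(exp_ct, grp, sum)
  keep <- e > 0
  stat <- sum((o[keep] - e[keep])^2 / e[keep])
  df <- max(1, sum(keep) - 1)
  stats::pchisq(stat, df, lower.tail = FALSE)
}

#' Random-matrix-theory similarity threshold
#'
#' Scans candidate thresholds `t`; at each, correlations with `|r| < t`
#' are zeroed and the eigenvalue nearest-neighbour spacing distribution
#' (NNSD) of the thresholded matrix (restricted to non-isolated taxa) is
#' tested against the Poisson form `exp(-s)`.  The selected threshold
#' `St` is the smallest `t` whose NNSD is consistent with Poisson
#' statistics (chi-square goodness of fit p > 0.05), i.e., where random
#' noise correlations have been removed and only modular structure
#' remains.  Spectra with too few distinct levels to exhibit level
#' repulsion are treated as Poisson-consistent.
#'
#' @param corr A correlation [pairwise_matrix()].
#' @param scan List `list(start, stop, step)` in (0, 1).
#' @param alpha Goodness-of-fit level (default 0.05).
#' @return List: `St`, `trace` data frame (threshold, n_nodes,
#'   n_spacings, p_poisson, poisson_ok).
#' @export
rmt_threshold <- function(corr, scan = list(start = 0.5, stop = 0.95,
                                            step = 0.01), alpha = 0.05) {
  r <- unclass(corr)
  stopifnot(scan$start > 0, scan$stop < 1, scan$step > 0)
  if (nrow(r) < 30)
    warning("matrix has < 30 nodes; RMT threshold selection is unreliable")
  ts <- seq(scan$start, scan$stop, by = scan$step)
  trace <- data.frame(threshold = ts, n_nodes = NA_integer_,
                      n_spacings = NA_integer_, p_poisson = NA_real_,
                      poisson_ok = NA)
  St <- NA_real_
  for (k in seq_along(ts)) {
    a <- r
    a[abs(a) < ts[k]] <- 0
    diag(a) <- 0
    live <- rowSums(a != 0) > 0
    trace$n_nodes[k] <- sum(live)
    if (sum(live) < 3) {
      # no (or degenerate) off-diagonal structure left: nothing exhibits
      # level repulsion, consistent with Poisson statistics
      trace$poisson_ok[k] <- TRUE
      if (is.na(St)) St <- ts[k]
      next
    }
    ev <- eigen(a[live, live], symmetric = TRUE, only.values = TRUE)$values
    s <- .unfold_spectrum(ev)
    if (is.null(s) || length(s) < 40) {
      # degenerate spectrum: no level repulsion observable
      trace$n_spacings[k] <- if (is.null(s)) 0L else length(s)
      trace$p_poisson[k] <- NA_real_
      trace$poisson_ok[k] <- TRUE
    } else {
      p <- .poisson_gof(s)
      trace$n_spacings[k] <- length(s)
      trace$p_poisson[k] <- p
      trace$poisson_ok[k] <- p > alpha
    }
    if (is.na(St) && trace$poisson_ok[k]) St <- ts[k]
  }
  if (is.na(St))
    stop("no threshold in the scan gave Poisson NNSD; widen the scan")
  list(St = St, trace = trace)
}

#' Build a signed co-association network
#'
#' Edge (i, j) iff `|r_ij| >= St`; edge sign is the correlation sign;
#' isolated nodes are dropped.  Modules are found by deterministic greedy
#' modularity maximisation (fast-greedy agglomeration on the unsigned
#' graph).
#'
#' @param corr A correlation [pairwise_matrix()].
#' @param St Similarity threshold in (0, 1).
#' @return An `assoc_network` list: `graph` (igraph, edge attributes
#'   `weight` = |r| and `sign`), `modules` (named membership vector),
#'   `St`.
#' @export
build_network <- function(corr, St) {
  stopifnot(St > 0, St < 1)
  r <- unclass(corr)
  diag(r) <- 0
  adj <- abs(r) >= St
  if (!any(adj)) stop("zero edges at threshold ", St)
  keep <- rowSums(adj) > 0
  r <- r[keep, keep, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(abs(r) * (abs(r) >= St),
                                           mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  sgn <- vapply(seq_len(igraph::ecount(g)), function(e) {
    ends <- igraph::ends(g, e)
    sign(r[ends[1], ends[2]])
  }, numeric(1))
  igraph::E(g)$sign <- sgn
  structure(list(graph = g, modules = .find_modules(g), St = St),
            class = "assoc_network")
}

#' @export
print.assoc_network <- function(x, ...) {
  cat("assoc_network:", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges, St =", x$St, ",",
      max(x$modules), "modules\n")
  invisible(x)
}

# deterministic unweighted greedy modularity maximisation; falls back to
# the connected-component partition when agglomeration leaves a
# non-positive-Q split (e.g., tiny complete graphs)
.find_modules <- function(g) {
  ones <- rep(1, igraph::ecount(g))
  fg <- igraph::membership(igraph::cluster_fast_greedy(g, weights = NA))
  comp <- igraph::components(g)$membership
  q_fg <- igraph::modularity(g, fg, weights = ones)
  q_comp <- igraph::modularity(g, comp, weights = ones)
  if (q_comp >= q_fg) comp else fg
}

# stress centrality: number of shortest paths passing through each node
.stress_centrality <- function(g) {
  n <- igraph::vcount(g)
  stress <- numeric(n)
  for (s in seq_len(n - 1)) {
    sp <- igraph::all_shortest_paths(g, from = s, to = (s + 1):n,
                                     weights = NA)$res
    for (p in sp) {
      v <- as.integer(p)
      if (length(v) > 2) {
        inner <- v[-c(1, length(v))]
        stress[inner] <- stress[inner] + 1
      }
    }
  }
  stress
}

# Freeman centralization: sum(max - c_i) / theoretical star-graph maximum
.freeman <- function(cvals, star_max) {
  sum(max(cvals) - cvals) / star_max
}

#' Topology metrics of a co-association network
#'
#' The standard molecular-ecological-network metric set: average
#' connectivity `avgK = 2E/N`, average clustering coefficient (nodes of
#' degree < 2 contribute 0), average path distance GD (mean geodesic over
#' connected pairs), diameter (max geodesic within components), density
#' `2E/(N(N-1))`, geodesic efficiency (mean of `1/d` over ordered pairs,
#' unreachable pairs contribute 0), harmonic geodesic distance `HD =
#' 1/efficiency`, maximal degree, Freeman centralization of degree,
#' betweenness and stress, Newman modularity Q of the module partition,
#' module count, and positive/negative link percentages.
#'
#' @param net An `assoc_network` from [build_network()].
#' @return A one-row data frame of metrics.
#' @export
topology <- function(net) {
  g <- net$graph
  n <- igraph::vcount(g); e <- igraph::ecount(g)
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  dmat <- igraph::distances(g, weights = NA)
  finite_off <- dmat[upper.tri(dmat)][is.finite(dmat[upper.tri(dmat)])]
  gd <- mean(finite_off)
  diam <- max(finite_off)
  inv <- 1 / dmat                      # unreachable: 1/Inf = 0
  eff <- mean(inv[row(inv) != col(inv)])
  q <- igraph::modularity(g, net$modules, weights = rep(1, e))
  stress <- .stress_centrality(g)
  star_btw <- (n - 1) * ((n - 1) * (n - 2) / 2)
  cs <- if (n > 2) .freeman(stress, star_btw) else 0
  sgn <- igraph::E(g)$sign
  data.frame(
    n_nodes = n, n_links = e,
    positive_links_pct = 100 * mean(sgn > 0),
    negative_links_pct = 100 * mean(sgn < 0),
    st = net$St,
    avg_k = 2 * e / n,
    avg_cc = mean(cc),
    gd = gd,
    diameter = diam,
    density = 2 * e / (n * (n - 1)),
    efficiency = eff,
    hd = 1 / eff,
    max_degree = max(deg),
    centralization_degree = igraph::centr_degree(g, loops = FALSE)$centralization,
    centralization_betweenness = igraph::centr_betw(g)$centralization,
    centralization_stress = cs,
    modularity = q,
    n_modules = max(net$modules))
}

#' Within- and among-module connectivity (Zi-Pi) and node roles
#'
#' `Zi` is the z-score of a node's within-module degree relative to its
#' module (`sd = 0` gives `Zi = 0`); `Pi = 1 - sum_m (k_im / k_i)^2` over
#' modules m.  Roles: network hub (`Zi > 2.5`, `Pi > 0.62`), module hub
#' (`Zi > 2.5`, `Pi <= 0.62`), connector (`Zi <= 2.5`, `Pi > 0.62`),
#' else peripheral.
#'
#' @param net An `assoc_network`.
#' @return Data frame: `taxon_id`, `module`, `degree`, `zi`, `pi`, `role`.
#' @export
zi_pi <- function(net) {
  g <- net$graph
  mods <- net$modules
  vn <- igraph::V(g)$name
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  adj <- (adj != 0) * 1
  deg <- rowSums(adj)
  mod_ids <- sort(unique(mods))
  # k_im: links of node i into module m
  kim <- vapply(mod_ids, function(m) rowSums(adj[, mods == m, drop = FALSE]),
                numeric(length(deg)))
  kin <- kim[cbind(seq_along(deg), match(mods, mod_ids))]
  zi <- numeric(length(deg))
  for (m in mod_ids) {
    sel <- mods == m
    mu <- mean(kin[sel]); sdv <- stats::sd(kin[sel])
    zi[sel] <- if (is.na(sdv) || sdv == 0) 0 else (kin[sel] - mu) / sdv
  }
  pi <- 1 - rowSums((kim / deg)^2)
  role <- ifelse(zi > 2.5 & pi > 0.62, "network_hub",
          ifelse(zi > 2.5, "module_hub",
          ifelse(pi > 0.62, "connector", "peripheral")))
  data.frame(taxon_id = vn, module = as.integer(mods),
             degree = as.integer(deg), zi = zi, pi = pi, role = role,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Degree-preserving random-network ensemble
#'
#' Maslov-Sneppen edge rewiring (degree sequence preserved, `10 * E`
#' swap attempts per replicate); for each replicate the average
#' clustering coefficient, average path distance and modularity (greedy
#' partition of the rewired graph) are recomputed.
#'
#' @param net An `assoc_network`.
#' @param n Number of replicates (>= 100 recommended).
#' @param seed Integer seed.
#' @return List: `summary` data frame (metric, mean, sd, formatted
#'   "mean (sd)"), `replicates` data frame.
#' @export
random_ensemble <- function(net, n = 100, seed = 1) {
  g <- net$graph
  ed <- igraph::as_edgelist(g, names = FALSE)
  has_disjoint <- FALSE
  for (i in seq_len(min(nrow(ed), 200))) {
    if (any(rowSums(matrix(ed[-i, ] %in% ed[i, ], ncol = 2)) == 0)) {
      has_disjoint <- TRUE; break
    }
  }
  if (nrow(ed) < 2 || !has_disjoint)
    stop("graph has no two independent swappable edge pairs")
  old <- .seed_state(seed)
  on.exit(.restore_seed(old))
  reps <- lapply(seq_len(n), function(r) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(
      loops = FALSE, niter = 10 * igraph::ecount(g)))
    cc <- mean(igraph::transitivity(gr, type = "localundirected",
                                    isolates = "zero"))
    dmat <- igraph::distances(gr, weights = NA)
    fo <- dmat[upper.tri(dmat)][is.finite(dmat[upper.tri(dmat)])]
    mods <- .find_modules(gr)
    data.frame(avg_cc = cc, gd = mean(fo),
               modularity = igraph::modularity(gr, mods,
                 weights = rep(1, igraph::ecount(gr))))
  })
  reps <- do.call(rbind, reps)
  summ <- data.frame(
    metric = c("avg_cc", "gd", "modularity"),
    mean = colMeans(reps), sd = apply(reps, 2, stats::sd),
    row.names = NULL)
  summ$formatted <- sprintf("%.3f (%.3f)", summ$mean, summ$sd)
  list(summary = summ, replicates = reps)
}
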