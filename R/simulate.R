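#' Simulate a Yule phylogeny
#'
#' Rooted ultrametric pure-birth tree with tips labelled `t0001`, ...
#'
#' @param n_tips Number of tips (>= 3).
#' @param model Branching model (only `"yule"`).
#' @param seed Integer seed.
#' @return An [ape::phylo] tree.
#' @export
simulate_tree <- function(n_tips, model = "yule", seed = 1) {
  stopifnot(n_tips >= 3, model == "yule")
  old <- .seed_state(seed)
  on.exit(.restore_seed(old))
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  tr$tip.label <- sprintf("t%04d", seq_len(n_tips))
  tr
}

#' Regime specification for community simulation
#'
#' @param regime One of `"neutral"`, `"homogeneous_selection"`,
#'   `"variable_selection"`, `"dispersal_limited"`.
#' @param n_samples Number of local communities.
#' @param n_taxa Metacommunity richness (must match the tree).
#' @param N Local community size (individuals per sample).
#' @param m Migration probability in (0, 1]; the Sloan immigration
#'   parameter is `Nm = N * m`.
#' @param sigma Selection width in standardised trait units; smaller =
#'   stronger environmental filtering.
#' @param env Optional per-sample environmental optima in trait units;
#'   defaults depend on the regime (a constant upper-quantile optimum for
#'   homogeneous selection, an evenly spaced trait-range gradient for
#'   variable selection).
#' @param bm_rate Brownian-motion rate for trait evolution on the tree.
#' @param trait_delta Early-burst exponent for trait evolution: node
#'   depths are raised to this power (< 1 concentrates trait divergence
#'   on deep branches, making the niche phylogenetically conserved at
#'   clade level; 1 = plain Brownian motion).
#' @param target_richness Expected number of taxa per sample under the
#'   selection regimes; membership is Bernoulli with probability
#'   proportional to the filter weight (ecological drift in composition).
#' @param evenness Gamma shape of the within-sample abundance draw for
#'   selection regimes; larger = more even communities.
#' @param fisher_alpha Log-series shape of the metacommunity abundance
#'   distribution.
#' @param n_clusters Isolated metacommunity clusters for the
#'   dispersal-limited regime.
#' @param seed Integer seed (mandatory).
#' @return A `regime_spec` list.
#' @export
regime_spec <- function(regime = c("neutral", "homogeneous_selection",
                                   "variable_selection",
                                   "dispersal_limited"),
                        n_samples = 12, n_taxa = 300, N = 5000, m = 0.3,
                        sigma = 0.25, env = NULL, bm_rate = 1,
                        trait_delta = 0.3, target_richness = 40,
                        evenness = 5, fisher_alpha = 0.999,
                        n_clusters = 2, seed) {
  regime <- match.arg(regime)
  stopifnot(n_samples >= 2, n_taxa >= 3, N >= 10, m > 0, m <= 1,
            bm_rate > 0, trait_delta > 0, target_richness >= 2,
            evenness > 0, fisher_alpha > 0, fisher_alpha < 1)
  if (missing(seed)) stop("seed is mandatory")
  if (regime %in% c("homogeneous_selection", "variable_selection") &&
      sigma <= 0)
    stop("sigma must be > 0 for selection regimes (degenerate filter)")
  structure(list(regime = regime, n_samples = n_samples, n_taxa = n_taxa,
                 N = N, m = m, sigma = sigma, env = env, bm_rate = bm_rate,
                 trait_delta = trait_delta,
                 target_richness = target_richness, evenness = evenness,
                 fisher_alpha = fisher_alpha, n_clusters = n_clusters,
                 seed = as.integer(seed)),
            class = "regime_spec")
}

# early-burst depth transform: node depths raised to the power delta so
# that delta < 1 concentrates branch length (hence Brownian variance) on
# the deep part of the tree
.delta_transform <- function(tree, delta) {
  if (delta == 1) return(tree)
  dep <- ape::node.depth.edgelength(tree)
  H <- max(dep)
  p <- tree$edge[, 1]; ch <- tree$edge[, 2]
  out <- tree
  out$edge.length <- ((dep[ch] / H)^delta - (dep[p] / H)^delta) * H
  out
}

# log-series metacommunity relative abundances for K taxa
.logseries_meta <- function(K, p = 0.999) {
  # inverse-cdf sampling of the log-series pmf C p^n / n, truncated
  nmax <- 1e5
  pmf <- p^(1:nmax) / (1:nmax)
  cdf <- cumsum(pmf / sum(pmf))
  ab <- findInterval(stats::runif(K), cdf) + 1
  ab / sum(ab)
}

#' Simulate one community table under a known assembly regime
#'
#' Neutral: each sample is a multinomial draw of size `N` from a
#' Dirichlet(`N m p`) composition around the log-series metacommunity
#' `p` — the stationary island-model distribution, so each taxon's local
#' relative abundance is marginally Beta(`Nm p_k`, `Nm (1 - p_k)`),
#' matching the Sloan model.  Selection: a niche trait evolves by
#' Brownian motion on the (optionally early-burst-transformed) tree and
#' the environmental filter weights taxa by
#' `exp(-(trait - env_j)^2 / (2 sigma^2))`; sample membership is a
#' Bernoulli draw proportional to the filter weight (compositional
#' drift around the deterministic filter, expected richness
#' `target_richness`), abundances are an even Gamma draw over the
#' members, and counts are multinomial of size `N`.  Identical `env_j`
#' gives homogeneous selection, divergent `env_j` variable selection.
#' Dispersal-limited:
#' neutral dynamics but sample clusters draw from independent, isolated
#' metacommunities.
#'
#' @param tree Tree from [simulate_tree()] with `n_taxa` tips.
#' @param spec A [regime_spec()].
#' @return List: `table` ([count_table()]), `metadata` (data frame with
#'   `env`, `regime`, and `cluster` for dispersal-limited runs),
#'   `trait` (named vector, selection regimes only).
#' @export
simulate_community <- function(tree, spec) {
  stopifnot(inherits(spec, "regime_spec"))
  K <- length(tree$tip.label)
  if (K != spec$n_taxa)
    stop("tree has ", K, " tips but spec$n_taxa = ", spec$n_taxa)
  S <- spec$n_samples
  old <- .seed_state(spec$seed)
  on.exit(.restore_seed(old))
  ids <- sprintf("s%03d", seq_len(S))
  x <- matrix(0, S, K, dimnames = list(ids, tree$tip.label))
  trait <- NULL
  cluster <- rep(NA_integer_, S)
  env <- spec$env
  if (spec$regime %in% c("neutral", "dispersal_limited")) {
    if (is.null(env)) env <- rep(0, S)
    if (spec$regime == "neutral") {
      meta <- list(.logseries_meta(K, spec$fisher_alpha))
      cluster <- rep(1L, S)
    } else {
      meta <- lapply(seq_len(spec$n_clusters), function(c)
        .logseries_meta(K, spec$fisher_alpha))
      cluster <- rep(seq_len(spec$n_clusters), length.out = S)
      cluster <- sort(cluster)
    }
    Nm <- spec$N * spec$m
    for (j in seq_len(S)) {
      p <- meta[[cluster[j]]]
      comp <- stats::rgamma(K, shape = Nm * p)
      if (sum(comp) == 0) comp[which.max(p)] <- 1
      x[j, ] <- stats::rmultinom(1, spec$N, comp / sum(comp))
    }
  } else {
    trait <- ape::rTraitCont(.delta_transform(tree, spec$trait_delta),
                             model = "BM", sigma = sqrt(spec$bm_rate))
    trait <- (trait - mean(trait)) / stats::sd(trait)
    if (is.null(env)) {
      env <- if (spec$regime == "homogeneous_selection")
        rep(stats::quantile(trait, 0.85), S)
      else seq(stats::quantile(trait, 0.1), stats::quantile(trait, 0.9),
               length.out = S)
    }
    for (j in seq_len(S)) {
      w <- exp(-(trait - env[j])^2 / (2 * spec$sigma^2))
      # drift in membership: Bernoulli inclusion proportional to the
      # filter weight, centred on the target richness
      pres <- stats::runif(K) < pmin(1, spec$target_richness * w / sum(w))
      if (sum(pres) < 2) pres[order(w, decreasing = TRUE)[1:2]] <- TRUE
      comp <- numeric(K)
      comp[pres] <- stats::rgamma(sum(pres), shape = spec$evenness)
      x[j, ] <- stats::rmultinom(1, spec$N, comp / sum(comp))
    }
  }
  metadata <- data.frame(sample_id = ids, env = env,
                         regime = spec$regime, cluster = cluster,
                         stringsAsFactors = FALSE)
  rownames(metadata) <- ids
  list(table = count_table(x), metadata = metadata, trait = trait)
}

#' Simulate a community directly from the Sloan neutral model
#'
#' Each taxon's local relative abundance in each sample is an independent
#' Beta(`Nm p`, `Nm (1 - p)`) draw around its log-series metacommunity
#' abundance `p` (the stationary island-model marginal), converted to
#' counts by rounding `q * N`.  Rounding makes detection exactly
#' `q >= 0.5 / N`, so fits on this table should use
#' `detection_limit = 0.5 / N`.
#'
#' @param n_samples,n_taxa Table dimensions.
#' @param Nm Immigration parameter (metacommunity size x migration).
#' @param N Local community size (reads per sample).
#' @param logseries_p Log-series shape of the metacommunity.
#' @param seed Integer seed.
#' @return List: `table` ([count_table()]), `meta_p` (true metacommunity
#'   relative abundances), `Nm`, `detection_limit`.
#' @export
simulate_sloan_community <- function(n_samples = 50, n_taxa = 500,
                                     Nm = 1000, N = 10000,
                                     logseries_p = 0.9999, seed) {
  if (missing(seed)) stop("seed is mandatory")
  old <- .seed_state(seed)
  on.exit(.restore_seed(old))
  p <- .logseries_meta(n_taxa, logseries_p)
  names(p) <- sprintf("t%04d", seq_len(n_taxa))
  x <- matrix(0, n_samples, n_taxa,
              dimnames = list(sprintf("s%03d", seq_len(n_samples)),
                              names(p)))
  for (j in seq_len(n_samples)) {
    q <- stats::rbeta(n_taxa, Nm * p, Nm * (1 - p))
    x[j, ] <- round(q * N)
  }
  keep <- colSums(x) > 0
  list(table = count_table(x[, keep, drop = FALSE]), meta_p = p,
       Nm = Nm, detection_limit = 0.5 / N)
}

#' Simulate a two-site, two-treatment study
#'
#' Emulates a factorial N-addition design: 2 sites x {control,
#' N-addition} cells, each cell an independent community of `n_per_cell`
#' samples simulated under its configured assembly regime over one shared
#' phylogeny.  Environmental covariates `pH` and `NO3` are linear
#' functions of each sample's selection optimum plus noise, so
#' niche-based downstream checks have signal.
#'
#' @param n_per_cell Samples per cell (>= 3; default 6).
#' @param n_taxa Shared metacommunity richness.
#' @param N Local community size.
#' @param regimes Named character vector of regimes for the four cells
#'   `site1_control`, `site1_n`, `site2_control`, `site2_n`.
#' @param m,sigma Passed to [regime_spec()].
#' @param seed Integer seed.
#' @return List: `table`, `tree`, `metadata` (site, treatment, cell,
#'   pH, NO3, env, regime), `trait`.
#' @export
simulate_study <- function(n_per_cell = 6, n_taxa = 400, N = 5000,
                           regimes = c(site1_control = "homogeneous_selection",
                                       site1_n = "neutral",
                                       site2_control = "homogeneous_selection",
                                       site2_n = "neutral"),
                           m = 0.3, sigma = 0.25, seed = 42) {
  stopifnot(n_per_cell >= 3,
            all(c("site1_control", "site1_n", "site2_control",
                  "site2_n") %in% names(regimes)))
  tree <- simulate_tree(n_taxa, seed = .sub_seed(seed, 1))
  cells <- names(regimes)
  tabs <- list(); metas <- list()
  trait <- NULL
  for (k in seq_along(cells)) {
    cell <- cells[k]
    sp <- regime_spec(regimes[[cell]], n_samples = n_per_cell,
                      n_taxa = n_taxa, N = N, m = m, sigma = sigma,
                      seed = .sub_seed(seed, k + 1))
    sim <- simulate_community(tree, sp)
    x <- unclass(sim$table)
    full <- matrix(0, nrow(x), n_taxa,
                   dimnames = list(NULL, tree$tip.label))
    full[, colnames(x)] <- x
    rownames(full) <- paste0(cell, "_", rownames(x))
    tabs[[cell]] <- full
    md <- sim$metadata
    md$sample_id <- rownames(full)
    md$site <- if (grepl("site1", cell)) "short_term" else "long_term"
    md$treatment <- if (grepl("_n$", cell)) "n_addition" else "control"
    md$cell <- cell
    metas[[cell]] <- md
    if (!is.null(sim$trait)) trait <- sim$trait
  }
  meta <- do.call(rbind, metas)
  rownames(meta) <- meta$sample_id
  old <- .seed_state(.sub_seed(seed, 99))
  on.exit(.restore_seed(old))
  meta$pH <- 4.2 - 0.5 * meta$env + stats::rnorm(nrow(meta), 0, 0.1)
  meta$NO3 <- 10 + 6 * meta$env +
    4 * (meta$treatment == "n_addition") + stats::rnorm(nrow(meta), 0, 1)
  tab <- do.call(rbind, tabs)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  list(table = count_table(tab), tree = tree,
       metadata = meta[, c("sample_id", "site", "treatment", "cell",
                           "regime", "env", "pH", "NO3")],
       trait = trait)
}
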