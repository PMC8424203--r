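test_that("selection strength and NST follow the normalized-ratio formula", {
  ss <- assemblyscope:::.selection_strength
  expect_equal(ss(0.5, 0.5), 0)          # D = E -> SS 0 -> NST 1
  expect_equal(ss(1, 0.5), 1)            # D = 1, E = 0.5 -> SS 1 -> NST 0
  expect_equal(ss(0.25, 0.5), 0.5)       # convergent side scales by E
  expect_equal(ss(0.75, 0.5), 0.5)
  expect_true(all(ss(runif(50), 0.5) >= 0 & ss(runif(50), 0.5) <= 1))
})

test_that("NST is invariant to sample order and bounded in [0, 1]", {
  tr <- simulate_tree(40, seed = 81)
  sp <- regime_spec("neutral", n_samples = 8, n_taxa = 40, N = 500,
                    seed = 82)
  tab <- simulate_community(tr, sp)$table
  grp <- stats::setNames(rep(c("g1", "g2"), each = 4), rownames(tab))
  r1 <- nst(tab, grp, spec = null_ensemble_spec(99, seed = 5))
  perm <- rev(rownames(tab))
  tab2 <- count_table(unclass(tab)[perm, ])
  r2 <- nst(tab2, grp[perm], spec = null_ensemble_spec(99, seed = 5))
  key <- function(r) {
    k <- paste(pmin(r$pairwise$sample_1, r$pairwise$sample_2),
               pmax(r$pairwise$sample_1, r$pairwise$sample_2))
    stats::setNames(r$pairwise$nst, k)
  }
  k1 <- key(r1); k2 <- key(r2)
  expect_setequal(names(k1), names(k2))
  expect_equal(k1[names(k2)], k2, tolerance = 1e-12)
  expect_true(all(r1$pairwise$nst >= 0 & r1$pairwise$nst <= 1, na.rm = TRUE))
  expect_true(all(r1$group_nst >= 0 & r1$group_nst <= 100))

  rj <- nst(tab, grp, metric = "jaccard",
            spec = null_ensemble_spec(99, seed = 5))
  expect_true(all(rj$pairwise$nst >= 0 & rj$pairwise$nst <= 1, na.rm = TRUE))
})

test_that("Sloan predicted frequency is monotone and hits its limits", {
  sf <- assemblyscope:::.sloan_freq
  p <- exp(seq(log(1e-6), log(0.2), length.out = 60))
  fr <- sf(p, Nm = 1000, d = 1e-4)
  expect_true(all(diff(fr) >= -1e-12))
  expect_true(all(fr >= 0 & fr <= 1))
  # large p >> d with Nm*p >> 1: predicted frequency -> 1
  expect_gt(sf(0.5, 1000, 1e-4), 0.999999)
})

test_that("Sloan fit recovers its generating parameter at moderate scale", {
  sim <- simulate_sloan_community(n_samples = 30, n_taxa = 200, Nm = 500,
                                  N = 5000, seed = 91)
  fit <- sloan_fit(sim$table, detection_limit = sim$detection_limit)
  expect_lt(abs(fit$Nm - 500) / 500, 0.25)
  expect_gt(fit$R2, 0.85)
  expect_true(all(fit$taxa$freq_pred >= 0 & fit$taxa$freq_pred <= 1))
  # predictions are non-decreasing in p
  o <- order(fit$taxa$p)
  expect_true(all(diff(fit$taxa$freq_pred[o]) >= -1e-12))
  # degenerate all-present table is rejected
  allp <- count_table(matrix(5, 4, 12,
                             dimnames = list(paste0("s", 1:4),
                                             paste0("t", 1:12))))
  expect_error(sloan_fit(allp), "variance")
})

test_that("Levins' niche breadth matches hand values and its bounds", {
  x <- matrix(c(1, 3, 2, 10,
                1, 1, 0, 10,
                1, 0, 0, 10,
                1, 0, 2, 10), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), c("u", "v", "w", "z")))
  nb <- levins_breadth(count_table(x))
  B <- stats::setNames(nb$per_taxon$B, nb$per_taxon$taxon_id)
  expect_equal(unname(B["u"]), 4)               # uniform across 4 samples
  expect_equal(unname(B["z"]), 4)
  expect_equal(unname(B["v"]), 1.6)             # counts (3,1): 1/(0.75^2+0.25^2)
  expect_equal(unname(B["w"]), 2)               # counts (2,0,0,2)
  expect_true(all(B >= 1 & B <= 4))
  # taxon in exactly one sample
  y <- matrix(c(3, 1, 0, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("only", "both")))
  nb2 <- levins_breadth(count_table(y))
  expect_equal(nb2$per_taxon$B[nb2$per_taxon$taxon_id == "only"], 1)
  # taxon with counts (3, 1): B = 1 / (0.75^2 + 0.25^2) = 1.6
  z <- matrix(c(3, 2, 1, 2), 2, 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("t31", "even")))
  nb3 <- levins_breadth(count_table(z))
  expect_equal(nb3$per_taxon$B[nb3$per_taxon$taxon_id == "t31"], 1.6)
  # every taxon uniform -> Bcom = number of samples
  u <- count_table(matrix(2, 5, 7, dimnames = list(paste0("s", 1:5),
                                                   paste0("t", 1:7))))
  expect_equal(levins_breadth(u)$Bcom, 5)
})

test_that("correlogram r matches a brute-force per-class Mantel statistic", {
  tr <- simulate_tree(10, seed = 4)
  set.seed(5)
  niche <- cbind(a = rnorm(10), b = rnorm(10))
  rownames(niche) <- tr$tip.label
  res <- phylo_signal_correlogram(tree = tr, niche = niche, n_perm = 49,
                                  seed = 1, min_pairs = 0)
  dn <- as.matrix(stats::dist(niche))
  dp <- ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label]
  br <- res$breaks
  for (k in seq_len(length(br) - 1)) {
    ind <- (dp > br[k] & dp <= br[k + 1]); diag(ind) <- FALSE
    if (!any(ind)) next
    r_bf <- -stats::cor(ind[lower.tri(ind)], dn[lower.tri(dn)])
    expect_equal(res$classes$mantel_r[k], r_bf, tolerance = 1e-10)
  }
})

test_that("correlogram flags degenerate niche input and detects Brownian signal", {
  tr <- simulate_tree(20, seed = 6)
  x <- matrix(rpois(4 * 20, 3) + 1, 4, 20,
              dimnames = list(paste0("s", 1:4), tr$tip.label))
  env_const <- data.frame(pH = rep(5, 4), row.names = paste0("s", 1:4))
  expect_warning(
    res <- phylo_signal_correlogram(count_table(x), tr, env = env_const),
    "zero variance|undefined")
  expect_true(res$undefined)

  # Brownian trait as niche: positive shortest-class correlation
  hits <- 0
  for (s in 1:10) {
    tr2 <- simulate_tree(40, seed = 100 + s)
    set.seed(200 + s)
    trait <- cbind(t = ape::rTraitCont(tr2, model = "BM"))
    r2 <- phylo_signal_correlogram(tree = tr2, niche = trait, n_perm = 99,
                                   seed = s, min_pairs = 0)
    hits <- hits + (r2$classes$mantel_r[1] > 0 &&
                      !is.na(r2$classes$p_corrected[1]) &&
                      r2$classes$p_corrected[1] < 0.05)
  }
  expect_gte(hits, 8)
})
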