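test_that("betaNTI is undefined on a star phylogeny and <= 0 for identical communities", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  x <- matrix(c(3, 1, 0, 0,
                0, 0, 2, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("A", "B", "C", "D")))
  expect_warning(
    bn <- beta_nti(count_table(x), star, null_ensemble_spec(99, seed = 1)),
    "undefined")
  expect_true(is.na(bn[1, 2]))

  tr <- fixture_tree5()
  xi <- matrix(c(2, 1, 3, 0, 1,
                 2, 1, 3, 0, 1), nrow = 2, byrow = TRUE,
               dimnames = list(c("s1", "s2"), paste0("t", 1:5)))
  bn2 <- suppressWarnings(
    beta_nti(count_table(xi), tr, null_ensemble_spec(199, seed = 2)))
  expect_true(is.na(bn2[1, 2]) || bn2[1, 2] <= 0)
})

test_that("Monte-Carlo betaNTI matches the exhaustive tip-permutation null", {
  tr <- fixture_tree5()
  x <- matrix(c(4, 1, 0, 2, 0,
                0, 3, 5, 0, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), paste0("t", 1:5)))
  d <- ape::cophenetic.phylo(tr)[paste0("t", 1:5), paste0("t", 1:5)]
  obs <- brute_beta_mntd(x[1, ], x[2, ], d)
  nulls <- vapply(all_perms(1:5), function(p)
    brute_beta_mntd(x[1, ], x[2, ], d[p, p]), numeric(1))
  z_exact <- (obs - mean(nulls)) / stats::sd(nulls)
  bn <- beta_nti(count_table(x), tr, null_ensemble_spec(5000, seed = 9))
  expect_lt(abs(bn[1, 2] - z_exact), 0.15)
})

test_that("betaNTI is invariant under uniform branch-length scaling", {
  tr <- simulate_tree(15, seed = 41)
  set.seed(42)
  x <- matrix(rpois(4 * 15, 2), 4, 15,
              dimnames = list(paste0("s", 1:4), tr$tip.label))
  x[rowSums(x) == 0, 1] <- 1
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 7.3
  b1 <- beta_nti(count_table(x), tr, null_ensemble_spec(99, seed = 5))
  b2 <- beta_nti(count_table(x), tr2, null_ensemble_spec(99, seed = 5))
  expect_equal(unclass(b1), unclass(b2), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("RC_bray hits its boundaries and stays within [-1, 1]", {
  # near-disjoint samples whose richness sum exceeds the taxon pool:
  # every null pair shares a taxon substantially, so the observed BC
  # (0.99) exceeds every null draw -> RC = +1
  x <- matrix(c(99, 1, 0,
                0, 1, 99,
                50, 50, 50), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), paste0("t", 1:3)))
  rc <- raup_crick_bray(count_table(x), null_ensemble_spec(199, seed = 4))
  expect_equal(rc[1, 2], 1)
  expect_true(all(abs(rc[upper.tri(rc)]) <= 1))

  # identical samples with large totals: observed BC = 0 falls below
  # every (almost surely distinct) null pair -> RC = -1
  xi <- matrix(c(50, 50, 30, 30,
                 50, 50, 30, 30,
                 10, 0, 80, 10), nrow = 3, byrow = TRUE,
               dimnames = list(c("s1", "s2", "s3"), paste0("t", 1:4)))
  rci <- raup_crick_bray(count_table(xi), null_ensemble_spec(199, seed = 4))
  expect_equal(rci[1, 2], -1)
})

test_that("RC_bray is near-uniform for communities generated by its own null", {
  # null self-consistency: mean |RC| <= 0.6 and P(|RC| > 0.95) <= 0.10
  set.seed(61)
  K <- 12
  occ_w <- sample(1:5, K, replace = TRUE)
  ab_w <- occ_w * sample(1:3, K, replace = TRUE)
  gen <- function() {
    rich <- 6; tot <- 40
    k <- sample(K, rich, prob = occ_w)
    cnt <- numeric(K); cnt[k] <- 1
    w <- ab_w[k]
    cnt[k] <- cnt[k] + as.numeric(stats::rmultinom(1, tot - rich, w / sum(w)))
    cnt
  }
  x <- t(replicate(21, gen()))
  dimnames(x) <- list(sprintf("s%02d", 1:21), paste0("t", 1:K))
  rc <- raup_crick_bray(count_table(x), null_ensemble_spec(99, seed = 5))
  rcs <- rc[upper.tri(rc)]        # 210 null-generated pairs
  expect_lte(mean(abs(rcs)), 0.6)
  expect_lte(mean(abs(rcs) > 0.95), 0.10)
})

test_that("process classification follows the quoted rules, including boundaries", {
  ids <- c("s1", "s2")
  mk <- function(b, r) {
    bm <- matrix(c(NA, b, b, NA), 2, 2, dimnames = list(ids, ids))
    rm <- matrix(c(NA, r, r, NA), 2, 2, dimnames = list(ids, ids))
    classify_processes(pairwise_matrix(bm, "beta_nti", diagonal = NA),
                       pairwise_matrix(rm, "rc_bray", diagonal = NA))
  }
  cases <- list(
    list(2.5, 0.1, "variable_selection"),
    list(-2.5, 0.99, "homogeneous_selection"),
    list(-1.0, 0.99, "dispersal_limitation"),
    list(0.3, -0.99, "homogenizing_dispersal"),
    list(0.3, 0.2, "undominated"),
    # boundary values fall on the non-significant side
    list(2.0, 0.2, "undominated"),
    list(-2.0, 0.2, "undominated"),
    list(0.0, 0.95, "undominated"),
    list(0.0, -0.95, "undominated"))
  for (cs in cases)
    expect_equal(mk(cs[[1]], cs[[2]])$pairs$process[1], cs[[3]])
})

test_that("process fractions sum to one exactly and track exclusions", {
  set.seed(71)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    ids <- paste0("s", 1:n)
    b <- matrix(0, n, n, dimnames = list(ids, ids))
    r <- matrix(0, n, n, dimnames = list(ids, ids))
    b[upper.tri(b)] <- rnorm(sum(upper.tri(b)), 0, 3)
    r[upper.tri(r)] <- runif(sum(upper.tri(r)), -1, 1)
    b <- b + t(b); r <- r + t(r)
    cl <- classify_processes(pairwise_matrix(b, "beta_nti", diagonal = NA),
                             pairwise_matrix(r, "rc_bray", diagonal = NA))
    # exact as ratios of counts; fractions to floating-point resolution
    expect_identical(as.integer(sum(cl$counts)), nrow(cl$pairs))
    expect_equal(sum(cl$fractions), 1, tolerance = 1e-12)
    expect_equal(cl$stochastic_fraction + cl$deterministic_fraction, 1)
  }
  # undefined pairs are excluded and counted
  ids <- paste0("s", 1:3)
  b <- matrix(c(NA, NA, 3, NA, NA, 0, 3, 0, NA), 3, 3,
              dimnames = list(ids, ids))
  r <- matrix(0.2, 3, 3, dimnames = list(ids, ids))
  expect_warning(
    cl <- classify_processes(pairwise_matrix(b, "beta_nti", diagonal = NA),
                             pairwise_matrix(r, "rc_bray", diagonal = NA)),
    "excluded")
  expect_equal(cl$n_excluded, 1L)
  expect_equal(sum(cl$fractions), 1, tolerance = 1e-12)
})
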