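test_that("node preparation applies the majority rule and sqrt transform", {
  set.seed(101)
  x <- matrix(0, 12, 3, dimnames = list(paste0("s", 1:12),
                                        c("rare5", "mid7", "common")))
  x[1:5, "rare5"] <- 4          # 5 of 12 <= 6 -> removed
  x[1:7, "mid7"] <- 9           # 7 of 12 > 6 -> retained
  x[, "common"] <- 16
  prep <- prepare_nodes(count_table(x))
  expect_setequal(colnames(prep), c("mid7", "common"))
  expect_equal(unname(prep[1, "mid7"]), 3)   # sqrt(9)
  # 0/1 table: transform idempotent
  b <- matrix(0, 12, 6,
              dimnames = list(paste0("s", 1:12), paste0("t", 1:6)))
  b[1:8, 1:3] <- 1
  b[5:12, 4:6] <- 1
  pb <- prepare_nodes(count_table(b))
  expect_true(all(pb %in% c(0, 1)))
  expect_error(prepare_nodes(count_table(x[1:4, , drop = FALSE])), ">= 6")
})

test_that("network construction thresholds, signs and drops isolated nodes", {
  r <- diag(4)
  dimnames(r) <- list(paste0("t", 1:4), paste0("t", 1:4))
  r[1, 2] <- r[2, 1] <- 0.92
  r[2, 3] <- r[3, 2] <- -0.95
  r[3, 4] <- r[4, 3] <- 0.5
  cm <- pairwise_matrix(r, "correlation", diagonal = 1)
  net <- build_network(cm, 0.9)
  g <- net$graph
  expect_equal(igraph::vcount(g), 3)          # t4 isolated at St = 0.9
  expect_equal(igraph::ecount(g), 2)
  signs <- stats::setNames(igraph::E(g)$sign,
                           apply(igraph::as_edgelist(g), 1, paste,
                                 collapse = "-"))
  expect_equal(unname(signs["t1-t2"]), 1)
  expect_equal(unname(signs["t2-t3"]), -1)
  expect_error(build_network(cm, 0.99), "zero edges")

  # all pairwise r = 0.9, St = 0.8 -> positive triangle
  r3 <- matrix(0.9, 3, 3, dimnames = list(paste0("t", 1:3), paste0("t", 1:3)))
  tri <- build_network(pairwise_matrix(r3, "correlation", diagonal = 1), 0.8)
  expect_equal(igraph::ecount(tri$graph), 3)
  expect_true(all(igraph::E(tri$graph)$sign == 1))
})

test_that("topology metrics match hand-computed values", {
  r3 <- matrix(0.9, 3, 3, dimnames = list(paste0("t", 1:3), paste0("t", 1:3)))
  tri <- build_network(pairwise_matrix(r3, "correlation", diagonal = 1), 0.8)
  tt <- topology(tri)
  expect_equal(tt$avg_k, 2)
  expect_equal(tt$avg_cc, 1)
  expect_equal(tt$density, 1)
  expect_equal(tt$gd, 1)
  expect_equal(tt$diameter, 1)
  expect_equal(tt$efficiency, 1)
  expect_equal(tt$hd, 1)

  # path A-B-C
  rp <- diag(3); dimnames(rp) <- dimnames(r3)
  rp[1, 2] <- rp[2, 1] <- 0.9; rp[2, 3] <- rp[3, 2] <- 0.9
  p3 <- build_network(pairwise_matrix(rp, "correlation", diagonal = 1), 0.8)
  tp <- topology(p3)
  expect_equal(tp$avg_cc, 0)
  expect_equal(tp$gd, 4 / 3)

  # two disjoint triangles: Newman Q of the 2-module partition = 0.5
  r6 <- diag(6); dimnames(r6) <- list(paste0("t", 1:6), paste0("t", 1:6))
  for (i in 1:2) for (j in (i + 1):3) {
    r6[i, j] <- r6[j, i] <- 0.9
    r6[i + 3, j + 3] <- r6[j + 3, i + 3] <- 0.9
  }
  two <- build_network(pairwise_matrix(r6, "correlation", diagonal = 1), 0.8)
  t2 <- topology(two)
  expect_equal(t2$modularity, 0.5)
  expect_equal(t2$n_modules, 2)
  expect_equal(t2$positive_links_pct + t2$negative_links_pct, 100)

  # relabeling invariance
  perm <- c(4, 5, 6, 1, 2, 3)
  r6p <- r6[perm, perm]
  dimnames(r6p) <- list(paste0("x", 1:6), paste0("x", 1:6))
  twop <- build_network(pairwise_matrix(r6p, "correlation", diagonal = 1), 0.8)
  expect_equal(topology(twop), t2)
})

test_that("Zi-Pi follows its formulas and role thresholds", {
  # two triangles bridged by a hub with degree 4 split 2/2
  ids <- c(paste0("a", 1:3), paste0("b", 1:3), "hub")
  r <- diag(7); dimnames(r) <- list(ids, ids)
  link <- function(i, j) r[i, j] <<- r[j, i] <<- 0.9
  for (i in 1:2) for (j in (i + 1):3) { link(ids[i], ids[j]); link(ids[i + 3], ids[j + 3]) }
  link("hub", "a1"); link("hub", "a2"); link("hub", "b1"); link("hub", "b2")
  net <- build_network(pairwise_matrix(r, "correlation", diagonal = 1), 0.8)
  # fix the module partition to the two triangles; hub assigned to module 1
  net$modules <- stats::setNames(c(1, 1, 1, 2, 2, 2, 1)[
    match(igraph::V(net$graph)$name, ids)], igraph::V(net$graph)$name)
  zp <- zi_pi(net)
  hub <- zp[zp$taxon_id == "hub", ]
  expect_equal(hub$degree, 4L)
  expect_equal(hub$pi, 0.5)             # 1 - (0.5^2 + 0.5^2)
  # all links inside own module -> Pi = 0
  expect_equal(zp$pi[zp$taxon_id == "b3"], 0)
  # role counts partition the node set
  expect_equal(sum(table(zp$role)), nrow(zp))
  # threshold logic
  role_of <- function(zi, pi) {
    ifelse(zi > 2.5 & pi > 0.62, "network_hub",
    ifelse(zi > 2.5, "module_hub",
    ifelse(pi > 0.62, "connector", "peripheral")))
  }
  expect_equal(role_of(3.0, 0.7), "network_hub")
  expect_equal(role_of(3.0, 0.5), "module_hub")
  expect_equal(role_of(1.0, 0.7), "connector")
  expect_equal(role_of(2.5, 0.62), "peripheral")
  expect_true(all(zp$role %in% c("peripheral", "connector",
                                 "module_hub", "network_hub")))
})

test_that("degree-preserving rewiring keeps the degree sequence and errors on triangles", {
  r3 <- matrix(0.9, 3, 3, dimnames = list(paste0("t", 1:3), paste0("t", 1:3)))
  tri <- build_network(pairwise_matrix(r3, "correlation", diagonal = 1), 0.8)
  expect_error(random_ensemble(tri, 5, seed = 1), "swappable")

  set.seed(111)
  g <- igraph::sample_gnm(60, 150)
  igraph::V(g)$name <- paste0("n", 1:60)
  igraph::E(g)$weight <- 1; igraph::E(g)$sign <- 1
  net <- structure(list(graph = g,
                        modules = assemblyscope:::.find_modules(g),
                        St = 0.5), class = "assoc_network")
  re <- random_ensemble(net, n = 20, seed = 7)
  expect_equal(nrow(re$replicates), 20)
  expect_true(all(c("avg_cc", "gd", "modularity") %in% re$summary$metric))
  expect_match(re$summary$formatted[1], "^[0-9.]+ \\([0-9.]+\\)$")
})

test_that("RMT threshold detects planted structure and degenerate spectra", {
  id <- diag(30); dimnames(id) <- list(paste0("t", 1:30), paste0("t", 1:30))
  sid <- suppressWarnings(
    rmt_threshold(pairwise_matrix(id, "correlation", diagonal = 1),
                  scan = list(start = 0.1, stop = 0.9, step = 0.1)))
  expect_equal(sid$St, 0.1)  # no structure: Poisson from the scan start

  cm <- planted_block_corr(block_size = 40, n_blocks = 4, seed = 17)
  st <- rmt_threshold(cm, scan = list(start = 0.1, stop = 0.9, step = 0.05))
  expect_gt(st$St, 0.1)      # above the pure-noise floor
  expect_lt(st$St, 0.75)     # below the within-block correlation level
  expect_true(st$St > 0 && st$St < 1)
  expect_true(all(c("threshold", "p_poisson", "poisson_ok") %in%
                    names(st$trace)))
})
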