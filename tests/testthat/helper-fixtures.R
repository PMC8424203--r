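# shared fixtures and independent brute-force oracles

fixture_tree4 <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

fixture_tree5 <- function() {
  ape::read.tree(text = "((t1:1,t2:1):2,((t3:0.5,t4:0.5):1.5,t5:2):1);")
}

fixture_table <- function() {
  count_table(matrix(c(5, 3, 0, 2,
                       0, 4, 4, 1,
                       2, 0, 6, 4),
                     nrow = 3, byrow = TRUE,
                     dimnames = list(c("a", "b", "c"), paste0("t", 1:4))))
}

# brute-force abundance-weighted betaMNTD for one sample pair
brute_beta_mntd <- function(xi, xj, d, weighted = TRUE) {
  Pi <- which(xi > 0); Pj <- which(xj > 0)
  fi <- if (weighted) xi / sum(xi) else (xi > 0) / sum(xi > 0)
  fj <- if (weighted) xj / sum(xj) else (xj > 0) / sum(xj > 0)
  s1 <- sum(vapply(Pi, function(k) fi[k] * min(d[k, Pj]), numeric(1)))
  s2 <- sum(vapply(Pj, function(k) fj[k] * min(d[k, Pi]), numeric(1)))
  0.5 * (s1 + s2)
}

# all permutations of a small vector (exhaustive null enumeration)
all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out <- c(out, list(c(v[i], p)))
  out
}

brute_bray_curtis <- function(u, v) 1 - 2 * sum(pmin(u, v)) / sum(u + v)

# planted 4-block correlation matrix: perfect-ish within-block correlation
# plus weak symmetric noise
planted_block_corr <- function(block_size = 40, n_blocks = 4,
                               block_lo = 0.75, noise = 0.3, seed = 7) {
  K <- block_size * n_blocks
  set.seed(seed)
  r <- matrix(0, K, K)
  for (b in seq_len(n_blocks) - 1) {
    idx <- (b * block_size + 1):((b + 1) * block_size)
    r[idx, idx] <- stats::runif(block_size^2, block_lo, 0.95)
  }
  r <- (r + t(r)) / 2
  nz <- matrix(stats::runif(K * K, -noise, noise), K, K)
  nz <- (nz + t(nz)) / 2
  r[r == 0] <- nz[r == 0]
  diag(r) <- 1
  dimnames(r) <- list(sprintf("t%03d", 1:K), sprintf("t%03d", 1:K))
  pairwise_matrix(r, "correlation", diagonal = 1)
}
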