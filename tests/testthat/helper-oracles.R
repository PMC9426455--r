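# Independent oracles, deliberately implemented by different routes than
# the package code they check.

# Horn's closed-form quaternion method for the optimal-superposition RMSD:
# the largest eigenvalue of the 4x4 key matrix gives the residual directly.
quaternion_rmsd <- function(A, B) {
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  S <- crossprod(B0, A0)
  K <- matrix(c(
    S[1, 1] + S[2, 2] + S[3, 3], S[2, 3] - S[3, 2],
    S[3, 1] - S[1, 3], S[1, 2] - S[2, 1],
    S[2, 3] - S[3, 2], S[1, 1] - S[2, 2] - S[3, 3],
    S[1, 2] + S[2, 1], S[1, 3] + S[3, 1],
    S[3, 1] - S[1, 3], S[1, 2] + S[2, 1],
    -S[1, 1] + S[2, 2] - S[3, 3], S[2, 3] + S[3, 2],
    S[1, 2] - S[2, 1], S[1, 3] + S[3, 1],
    S[2, 3] + S[3, 2], -S[1, 1] - S[2, 2] + S[3, 3]
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  e0 <- sum(A0^2) + sum(B0^2)
  sqrt(max(0, (e0 - 2 * lam) / nrow(A)))
}

# Brute-force nontrivial splits via graph components after removing each
# internal edge (no reuse of the package's split machinery).
brute_splits <- function(tree) {
  tips <- tree$tip.label
  ntip <- length(tips)
  edges <- tree$edge
  out <- character(0)
  for (e in seq_len(nrow(edges))) {
    adj <- edges[-e, , drop = FALSE]
    # flood fill from the child endpoint
    seen <- edges[e, 2]
    repeat {
      nxt <- unique(c(adj[adj[, 1] %in% seen, 2], adj[adj[, 2] %in% seen, 1]))
      nxt <- setdiff(nxt, seen)
      if (length(nxt) == 0) break
      seen <- c(seen, nxt)
    }
    side <- sort(tips[intersect(seen, seq_len(ntip))])
    if (length(side) <= 1 || length(side) >= ntip - 1) next
    if (min(tips) %in% side) side <- sort(setdiff(tips, side))
    out <- c(out, paste(side, collapse = "|"))
  }
  unique(out)
}

brute_rf <- function(t1, t2) {
  s1 <- brute_splits(t1)
  s2 <- brute_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# splits with branch lengths, keyed canonically, for edge-length comparison
# (leaf edges keyed by leaf name)
split_lengths <- function(tree) {
  tips <- tree$tip.label
  ntip <- length(tips)
  sp <- tree_splits(tree, include_trivial = TRUE)
  out <- numeric(0)
  for (key in names(sp)) {
    side <- as.character(sp[[key]])
    k <- if (length(side) == 1) side else if (length(side) == ntip - 1) {
      setdiff(tips, side)
    } else {
      key
    }
    out[paste(sort(unlist(k)), collapse = "|")] <- attr(sp[[key]], "length")
  }
  out
}

# numerical helix arc length by fine quadrature (independent of the
# closed-form capacity)
numeric_spool_capacity <- function(radius, pitch, n_turns, rise) {
  tmax <- n_turns * 2 * pi
  tt <- seq(0, tmax, length.out = 20001)
  zslope <- pitch / (2 * pi)
  # |r'(t)| = sqrt(radius^2 + zslope^2), integrate numerically anyway
  speed <- sqrt(radius^2 * (sin(tt)^2 + cos(tt)^2) + zslope^2)
  h <- tmax / (length(tt) - 1)
  arc <- h * (sum(speed) - (speed[1] + speed[length(speed)]) / 2)
  floor(arc / rise)
}

random_rigid <- function(seed) {
  set.seed(seed)
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  R <- matrix(c(
    a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
    2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
    2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2
  ), 3, 3, byrow = TRUE)
  list(R = R, t = runif(3, -30, 30))
}

apply_rigid <- function(xyz, rig) {
  sweep(xyz %*% rig$R, 2, rig$t, "+")
}
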