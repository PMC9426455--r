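# RNG discipline: every generator takes a seed, runs under an isolated RNG
# state, and restores the caller's state on exit.
with_isolated_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a compact beta-rich CA backbone
#'
#' Builds a deterministic, self-avoiding C-alpha trace shaped like a
#' beta-meander: extended zig-zag strands (about 3.3 Angstrom of axial
#' advance per residue) stacked 4.8 Angstrom apart, connected by short
#' arc-shaped loops, with a small seeded jitter. Consecutive CA distances
#' are kept in the canonical 3.8 +/- 0.1 Angstrom window by construction
#' (steps are re-scaled into [3.65, 3.95] after jitter), emulating the
#' compact fold cores that structure-based phylogenies compare.
#'
#' @param n_residues Number of residues (>= 30).
#' @param seed Integer seed; the same seed always yields the same trace.
#' @param label Trace label.
#' @return A `core_trace` with an additional attribute `"ss"`: a character
#'   vector (`"E"` strand / `"L"` loop) used by the indel model.
#' @export
simulate_backbone <- function(n_residues, seed = 1, label = "sim") {
  if (n_residues < 30) stop("n_residues must be >= 30")
  # real beta-sandwiches have unequal strands; a fixed irregular pattern
  # avoids the register ambiguity of a perfectly periodic meander
  strand_pattern <- c(9L, 12L, 8L, 11L, 10L, 13L)
  loop_pattern <- c(3L, 5L, 4L, 3L, 5L, 4L)
  step_x <- 3.3
  amp_y <- 0.95
  dz <- 4.8

  xyz <- matrix(NA_real_, n_residues, 3)
  ss <- character(n_residues)
  i <- 0L
  strand_idx <- 0L
  x <- 0
  while (i < n_residues) {
    dirn <- if (strand_idx %% 2L == 0L) 1 else -1
    z <- strand_idx * dz
    strand_len <- strand_pattern[strand_idx %% length(strand_pattern) + 1L]
    loop_len <- loop_pattern[strand_idx %% length(loop_pattern) + 1L]
    # strand
    nfill <- min(strand_len, n_residues - i)
    for (j in seq_len(nfill)) {
      i <- i + 1L
      xyz[i, ] <- c(x, amp_y * (-1)^(j - 1), z)
      ss[i] <- "E"
      if (j < nfill) x <- x + dirn * step_x
    }
    if (i >= n_residues) break
    # loop: circular arc from strand end to next strand start, bulging
    # outward beyond the sheet edge
    p_end <- xyz[i, ]
    p_next <- c(x, amp_y, z + dz)  # next strand starts at same x, j = 1
    nfill <- min(loop_len, n_residues - i)
    arc <- loop_arc(p_end, p_next, n_interior = loop_len,
                    bulge_dir = c(dirn, 0, 0), step = 3.8)
    for (j in seq_len(nfill)) {
      i <- i + 1L
      xyz[i, ] <- arc[j, ]
      ss[i] <- "L"
    }
    strand_idx <- strand_idx + 1L
  }

  xyz <- with_isolated_seed(seed, {
    jit <- matrix(stats::rnorm(n_residues * 3, 0, 0.015), n_residues, 3)
    xyz + jit
  })
  # clamp consecutive distances into [3.65, 3.95]
  for (k in 2:n_residues) {
    v <- xyz[k, ] - xyz[k - 1, ]
    d <- sqrt(sum(v^2))
    d2 <- min(max(d, 3.65), 3.95)
    xyz[k, ] <- xyz[k - 1, ] + v * d2 / d
  }
  out <- core_trace(label, xyz,
                    tibble::tibble(chain = "A", resno = seq_len(n_residues),
                                   ins = "", aa = "ALA"))
  attr(out, "ss") <- ss
  out
}

# interior points of a circular arc from p to q with (n_interior + 1)
# segments of given arc step, bulging toward bulge_dir
loop_arc <- function(p, q, n_interior, bulge_dir, step) {
  chord_v <- q - p
  c_len <- sqrt(sum(chord_v^2))
  arc_len <- (n_interior + 1) * step
  # solve sin(theta/2)/(theta/2) = c/L for the subtended angle
  f <- function(th) sin(th / 2) / (th / 2) - c_len / arc_len
  theta <- stats::uniroot(f, lower = 1e-9, upper = 2 * pi - 1e-9,
                          tol = 1e-12)$root
  R <- arc_len / theta
  mid <- (p + q) / 2
  # bulge direction made orthogonal to the chord
  wdir <- bulge_dir - sum(bulge_dir * chord_v) / c_len^2 * chord_v
  wdir <- wdir / sqrt(sum(wdir^2))
  O <- mid - R * cos(theta / 2) * wdir
  u1 <- (p - O) / sqrt(sum((p - O)^2))
  qo <- q - O
  u2 <- qo - sum(qo * u1) * u1
  u2 <- u2 / sqrt(sum(u2^2))
  # the sweep must satisfy point(theta) == q; for theta > pi the sin is
  # negative and u2 flips
  if (sin(theta) < 0) u2 <- -u2
  phis <- theta * seq_len(n_interior) / (n_interior + 1)
  t(vapply(phis, function(phi) O + R * (cos(phi) * u1 + sin(phi) * u2),
           numeric(3)))
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(
    a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
    2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
    2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2
  ), 3, 3, byrow = TRUE)
}

#' Specification for evolving structures along a tree
#'
#' @param tree `ape::phylo` with branch lengths in divergence units.
#' @param sigma_per_unit Per-coordinate Gaussian noise (Angstrom) per unit
#'   of branch length (Brownian-on-coordinates divergence).
#' @param n_residues Residues in the ancestral backbone (>= 30).
#' @param indel_rate Per-residue, per-unit-branch-length probability of an
#'   indel (loop residues only; half deletions, half duplications); must be
#'   below 0.2.
#' @param seed Integer seed.
#' @return An `evolution_spec` list.
#' @export
evolution_spec <- function(tree, sigma_per_unit = 0.3, n_residues = 150,
                           indel_rate = 0.01, seed = 1) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (sigma_per_unit < 0) stop("sigma_per_unit must be >= 0")
  if (indel_rate < 0 || indel_rate >= 0.2) stop("indel_rate must be in [0, 0.2)")
  if (n_residues < 30) stop("n_residues must be >= 30")
  structure(list(tree = tree, sigma_per_unit = sigma_per_unit,
                 n_residues = as.integer(n_residues),
                 indel_rate = indel_rate, seed = as.integer(seed)),
            class = "evolution_spec")
}

#' Evolve CA structures along a known tree
#'
#' The root backbone comes from [simulate_backbone()]. Along each branch of
#' length b the child inherits the parent coordinates plus i.i.d. Gaussian
#' noise of per-coordinate sd `sigma_per_unit * sqrt(b)`, indels are applied
#' to loop residues at rate `indel_rate * b` (deletion or duplication with
#' equal probability), and finally an arbitrary proper rigid motion
#' (uniform random rotation, translation within a 100 Angstrom box) is
#' applied. The whole process is reproducible from the spec's seed alone.
#'
#' @param spec An [evolution_spec()].
#' @return Named list of `core_trace`, one per leaf (names = tip labels).
#'   Each trace keeps its ancestral residue numbering in `tags$resno`
#'   (duplicated residues share their template's number) so that
#'   construction oracles can check recovered correspondences.
#' @export
evolve_along_tree <- function(spec) {
  stopifnot(inherits(spec, "evolution_spec"))
  tree <- ape::reorder.phylo(spec$tree, "cladewise")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L

  with_isolated_seed(spec$seed, {
    base <- simulate_backbone(spec$n_residues, seed = spec$seed)
    states <- vector("list", ntip + tree$Nnode)
    states[[root]] <- list(xyz = base$xyz, ss = attr(base, "ss"),
                           resno = seq_len(spec$n_residues))
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      b <- tree$edge.length[e]
      st <- states[[parent]]
      n <- nrow(st$xyz)
      xyz <- st$xyz + matrix(stats::rnorm(n * 3, 0,
                                          spec$sigma_per_unit * sqrt(b)),
                             n, 3)
      ss <- st$ss
      resno <- st$resno
      # indels in loops only, so the strand core persists
      p_indel <- min(spec$indel_rate * b, 0.5)
      if (p_indel > 0) {
        hit <- which(stats::runif(n) < p_indel & ss == "L")
        if (length(hit) > 0) {
          dup <- stats::runif(length(hit)) < 0.5
          del_idx <- hit[!dup]
          keep <- if (length(del_idx)) setdiff(seq_len(n), del_idx) else seq_len(n)
          dup_idx <- intersect(hit[dup], keep)
          rows <- sort(c(keep, dup_idx))  # duplicates insert next to template
          off <- matrix(0, length(rows), 3)
          extra <- duplicated(rows)
          off[extra, ] <- matrix(stats::rnorm(3 * sum(extra), 0, 0.3),
                                 ncol = 3)
          xyz <- xyz[rows, , drop = FALSE] + off
          ss <- ss[rows]
          resno <- resno[rows]
        }
      }
      rot <- random_rotation()
      shift <- stats::runif(3, -50, 50)
      xyz <- sweep(xyz %*% rot, 2, shift, "+")
      states[[child]] <- list(xyz = xyz, ss = ss, resno = resno)
    }
    leaves <- lapply(seq_len(ntip), function(i) {
      st <- states[[i]]
      tr <- core_trace(tree$tip.label[i], st$xyz,
                       tibble::tibble(chain = "A", resno = st$resno,
                                      ins = "", aa = "ALA"))
      attr(tr, "ss") <- st$ss
      tr
    })
    names(leaves) <- tree$tip.label
    leaves
  })
}

#' Additive (patristic) distance matrix of a tree
#'
#' Entries are path-length sums between leaves; by construction the matrix
#' satisfies the four-point condition, so [neighbor_joining()] recovers the
#' tree exactly.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @return A `distance_matrix` with rows/columns in tip-label order.
#' @export
make_additive_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  m <- ape::cophenetic.phylo(tree)
  m <- m[tree$tip.label, tree$tip.label]
  distance_matrix(m, tree$tip.label)
}

#' Random unrooted binary tree with uniform branch lengths
#'
#' Convenience generator for topology-recovery experiments.
#'
#' @param n_leaves Number of leaves (>= 4).
#' @param min_edge,max_edge Branch length range.
#' @param seed Integer seed.
#' @return `ape::phylo`, unrooted (trifurcating root), labels `t1..tn`.
#' @export
random_additive_tree <- function(n_leaves, min_edge = 0.1, max_edge = 5,
                                 seed = 1) {
  stopifnot(n_leaves >= 4)
  with_isolated_seed(seed, {
    tr <- ape::rtree(n_leaves, rooted = FALSE)
    tr$edge.length <- stats::runif(nrow(tr$edge), min_edge, max_edge)
    tr
  })
}
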