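test_that("kabsch recovers exact superpositions and refuses reflections", {
  a <- simulate_backbone(40, seed = 1)$xyz
  fit0 <- kabsch(a, a)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)

  th <- pi / 2
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  b <- sweep(a %*% Rz, 2, c(5, 5, 5), "+")
  fit <- kabsch(a, b)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(apply_transform(fit, b), a, tolerance = 1e-9)

  # a mirrored set must still yield a proper rotation
  fitm <- kabsch(a, a %*% diag(c(-1, 1, 1)))
  expect_equal(det(fitm$rotation), 1, tolerance = 1e-12)
  expect_gt(fitm$rmsd, 0)
})

test_that("kabsch matches the quaternion closed form on random instances", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(4:60, 1)
    A <- matrix(rnorm(3 * n, sd = 5), ncol = 3)
    B <- matrix(rnorm(3 * n, sd = 5), ncol = 3)
    expect_equal(kabsch(A, B)$rmsd, quaternion_rmsd(A, B), tolerance = 1e-8)
  }
})

test_that("the four-point perturbation example agrees with the oracle", {
  A <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  B <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 2))
  expect_equal(kabsch(A, B)$rmsd, quaternion_rmsd(A, B), tolerance = 1e-6)
})

test_that("degenerate point sets are flagged but still minimised", {
  line <- cbind(1:5, 0, 0)
  fit <- kabsch(line, line)
  expect_true(fit$degenerate)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
})

test_that("identical traces give the identity correspondence", {
  tr <- simulate_backbone(80, seed = 3)
  p <- find_correspondence(tr, tr)
  expect_equal(nrow(p), 80)
  expect_equal(p[, 1], p[, 2])
})

test_that("a deletion is bridged and the deleted indices are omitted", {
  tr <- simulate_backbone(100, seed = 7, label = "a")
  del <- 41:45
  tr2 <- core_trace("b", tr$xyz[-del, ], tr$tags[-del, ])
  p <- find_correspondence(tr, tr2)
  expect_false(any(del %in% p[, 1]))
  expect_equal(nrow(p), 95)
  fit <- kabsch(tr$xyz[p[, 1], ], tr2$xyz[p[, 2], ])
  expect_equal(fit$rmsd, 0, tolerance = 1e-6)
  # recovered mapping is the construction's
  expect_equal(p[, 1][p[, 1] > 45], p[, 2][p[, 1] > 45] + 5)
})

test_that("one_to_one mode forces the positional identity", {
  tr <- simulate_backbone(60, seed = 2, label = "a")
  rig <- random_rigid(11)
  tr2 <- core_trace("b", apply_rigid(tr$xyz[60:1, ], rig), tr$tags)
  p <- find_correspondence(tr, tr2, align_params(mode = "one_to_one"))
  expect_equal(p[, 1], 1:60)
  expect_equal(p[, 2], 1:60)
  tr3 <- core_trace("c", tr$xyz[1:50, ], tr$tags[1:50, ])
  expect_error(find_correspondence(tr, tr3,
                                   align_params(mode = "one_to_one")),
               "equal-length")
})

test_that("correspondences are strictly increasing in both traces", {
  tree <- random_additive_tree(4, 0.5, 2, seed = 5)
  leaves <- evolve_along_tree(evolution_spec(tree, 0.3, 90, 0.02, 13))
  for (i in 1:3) {
    for (j in (i + 1):4) {
      p <- find_correspondence(leaves[[i]], leaves[[j]])
      expect_true(all(diff(p[, 1]) > 0))
      expect_true(all(diff(p[, 2]) > 0))
    }
  }
})

test_that("pairwise_core_rmsd is symmetric and rigid-invariant", {
  tree <- random_additive_tree(4, 0.5, 2, seed = 8)
  leaves <- evolve_along_tree(evolution_spec(tree, 0.2, 90, 0.01, 21))
  a <- leaves[[1]]
  b <- leaves[[2]]
  r_ab <- pairwise_core_rmsd(a, b)
  r_ba <- pairwise_core_rmsd(b, a)
  expect_identical(as.numeric(r_ab), as.numeric(r_ba))
  for (s in 1:5) {
    rig <- random_rigid(100 + s)
    b_moved <- core_trace(b$label, apply_rigid(b$xyz, rig), b$tags)
    expect_equal(as.numeric(pairwise_core_rmsd(a, b_moved)),
                 as.numeric(r_ab), tolerance = 1e-9)
  }
})

test_that("rmsd under isotropic noise concentrates near sigma * sqrt(3)", {
  sigma <- 0.4
  n <- 120
  params <- align_params(mode = "one_to_one")
  vals <- vapply(1:100, function(rep) {
    set.seed(rep)
    a <- simulate_backbone(n, seed = 500)
    b <- core_trace("b", a$xyz + matrix(rnorm(3 * n, 0, sigma), n, 3),
                    a$tags)
    as.numeric(pairwise_core_rmsd(a, b, params))
  }, numeric(1))
  expect_true(all(vals > 0.5 * sigma * sqrt(3)))
  expect_true(all(vals < 1.5 * sigma * sqrt(3)))
})

test_that("fixed-correspondence rmsd satisfies the triangle inequality", {
  n <- 50
  params <- align_params(mode = "one_to_one")
  set.seed(99)
  base <- simulate_backbone(n, seed = 77)
  for (rep in 1:25) {
    tr <- lapply(1:3, function(k) {
      core_trace(paste0("t", k),
                 base$xyz + matrix(rnorm(3 * n, 0, 1), n, 3), base$tags)
    })
    d12 <- as.numeric(pairwise_core_rmsd(tr[[1]], tr[[2]], params))
    d13 <- as.numeric(pairwise_core_rmsd(tr[[1]], tr[[3]], params))
    d23 <- as.numeric(pairwise_core_rmsd(tr[[2]], tr[[3]], params))
    expect_lte(d12, d13 + d23 + 1e-9)
    expect_lte(d13, d12 + d23 + 1e-9)
    expect_lte(d23, d12 + d13 + 1e-9)
  }
})

test_that("multiple superposition of identical traces keeps the full core", {
  tr <- simulate_backbone(70, seed = 4)
  traces <- lapply(c("x", "y", "z"), function(lb) {
    core_trace(lb, tr$xyz, tr$tags)
  })
  al <- multiple_superpose(traces)
  expect_equal(length(al$common_columns), 70)
  d <- build_distance_matrix(al)
  expect_equal(max(abs(unclass(d))), 0, tolerance = 1e-9)
})

test_that("an insertion in one trace is excluded from the common core", {
  tr <- simulate_backbone(90, seed = 6)
  ins <- matrix(rep(tr$xyz[45, ], 10), ncol = 3, byrow = TRUE) +
    matrix(rnorm(30, 0, 20), ncol = 3)
  with_ins <- rbind(tr$xyz[1:45, ], ins, tr$xyz[46:90, ])
  traces <- list(
    core_trace("plain1", tr$xyz, tr$tags),
    core_trace("plain2", tr$xyz, tr$tags),
    core_trace("inserted", with_ins)
  )
  al <- multiple_superpose(traces)
  expect_lte(length(al$common_columns), 90)
  expect_gte(length(al$common_columns), 70)
  d <- build_distance_matrix(al)
  expect_equal(d["plain1", "plain2"], 0, tolerance = 1e-9)
})

test_that("rigid motions alone leave all pairwise RMSDs at zero", {
  tree <- random_additive_tree(5, 0.5, 2, seed = 31)
  leaves <- evolve_along_tree(evolution_spec(tree, 0, 80, 0, 17))
  al <- multiple_superpose(leaves)
  d <- build_distance_matrix(al)
  expect_equal(max(abs(unclass(d))), 0, tolerance = 1e-8)
})

test_that("every returned rotation is proper to machine precision", {
  set.seed(123)
  for (rep in 1:50) {
    A <- matrix(rnorm(30), ncol = 3)
    B <- matrix(rnorm(30), ncol = 3)
    expect_equal(det(kabsch(A, B)$rotation), 1, tolerance = 1e-12)
  }
})
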