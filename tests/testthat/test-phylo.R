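four_taxon_matrix <- function() {
  labs <- c("A", "B", "C", "D")
  m <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4, dimnames = list(labs, labs))
  distance_matrix(m)
}

test_that("distance_matrix validates symmetry, diagonal and finiteness", {
  m <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_s3_class(distance_matrix(m), "distance_matrix")
  m2 <- m; m2[1, 2] <- 2
  expect_error(distance_matrix(m2), "not symmetric")
  m3 <- m; m3[1, 1] <- 1
  expect_error(distance_matrix(m3), "diagonal")
  m4 <- m; m4[1, 2] <- m4[2, 1] <- NaN
  expect_error(distance_matrix(m4), "non-finite")
})

test_that("the 3-taxon worked example gives branches 1, 2, 4", {
  labs <- c("A", "B", "C")
  d <- distance_matrix(matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
                              dimnames = list(labs, labs)))
  tr <- neighbor_joining(d)
  expect_equal(ape::Ntip(tr), 3)
  bl <- split_lengths(tr)
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 2, 4))
})

test_that("the 4-taxon additive example recovers split AB|CD exactly", {
  tr <- neighbor_joining(four_taxon_matrix())
  expect_true(as.logical(is_monophyletic(tr, c("A", "B"))))
  expect_true(as.logical(is_monophyletic(tr, c("C", "D"))))
  bl <- split_lengths(tr)
  expect_equal(unname(bl[c("A", "B", "C", "D")]), c(1, 2, 3, 4))
  internal <- bl[setdiff(names(bl), c("A", "B", "C", "D"))]
  expect_equal(unname(internal), 1.0)
})

test_that("equidistant taxa give a zero internal edge, deterministically", {
  labs <- c("A", "B", "C", "D")
  m <- matrix(2, 4, 4, dimnames = list(labs, labs))
  diag(m) <- 0
  d <- distance_matrix(m)
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d)
  expect_identical(write_newick(t1), write_newick(t2))
  bl <- split_lengths(t1)
  internal <- bl[setdiff(names(bl), labs)]
  expect_equal(unname(internal), 0)
  expect_true(all(bl >= 0))
})

test_that("NJ recovers random additive trees exactly", {
  for (rep in 1:30) {
    n <- 4 + (rep %% 9)
    tree <- random_additive_tree(n, 0.1, 5, seed = 1000 + rep)
    d <- make_additive_matrix(tree)
    rec <- neighbor_joining(d)
    expect_equal(robinson_foulds(rec, tree), 0)
    expect_equal(split_lengths(rec)[names(split_lengths(tree))],
                 split_lengths(tree), tolerance = 1e-9)
  }
})

test_that("NJ agrees topologically with an independent implementation", {
  set.seed(7)
  for (rep in 1:10) {
    n <- 5 + rep %% 4
    tree <- random_additive_tree(n, 0.2, 4, seed = 400 + rep)
    noisy <- unclass(make_additive_matrix(tree)) +
      matrix(runif(n * n, 0, 0.05), n, n)
    noisy <- (noisy + t(noisy)) / 2
    diag(noisy) <- 0
    d <- distance_matrix(noisy, rownames(make_additive_matrix(tree)))
    mine <- neighbor_joining(d)
    theirs <- ape::nj(as.dist(unclass(d)))
    expect_equal(robinson_foulds(mine, theirs), 0)
  }
})

test_that("permuting matrix labels leaves the tree unchanged", {
  tree <- random_additive_tree(8, 0.3, 4, seed = 77)
  d <- make_additive_matrix(tree)
  set.seed(3)
  perm <- sample(nrow(d))
  dp <- distance_matrix(unclass(d)[perm, perm], rownames(d)[perm])
  expect_equal(robinson_foulds(neighbor_joining(d), neighbor_joining(dp)), 0)
})

test_that("branch lengths are never negative after clamping", {
  set.seed(15)
  for (rep in 1:10) {
    n <- 6
    m <- matrix(runif(n * n, 0.5, 4), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    labs <- paste0("x", 1:n)
    tr <- neighbor_joining(distance_matrix(m, labs))
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("n < 3 and asymmetric inputs are rejected", {
  m <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(neighbor_joining(distance_matrix(m)), "at least 3")
})

test_that("monophyly corresponds to an edge bipartition", {
  tr <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_true(as.logical(is_monophyletic(tr, c("A", "B"))))
  expect_false(as.logical(is_monophyletic(tr, c("A", "C"))))
  expect_true(as.logical(is_monophyletic(tr, c("A", "B", "C", "D"))))
  expect_true(as.logical(is_monophyletic(tr, "A")))
  expect_error(is_monophyletic(tr, c("A", "Zz")), "unknown label")
  # nested clades in a caterpillar tree
  cat_tree <- read_newick(text = "(((((A:1,B:1):1,C:1):1,D:1):1,E:1):1,F:1,G:1);")
  expect_true(as.logical(is_monophyletic(cat_tree, c("A", "B"))))
  expect_true(as.logical(is_monophyletic(cat_tree, c("A", "B", "C"))))
})

test_that("Robinson-Foulds matches brute-force split enumeration", {
  t1 <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  t2 <- read_newick(text = "((A:1,C:1):1,(B:1,D:1):1);")
  expect_equal(robinson_foulds(t1, t1), 0)
  expect_equal(robinson_foulds(t1, t2), 2)
  for (rep in 1:10) {
    a <- random_additive_tree(10, 0.5, 2, seed = 600 + rep)
    b <- random_additive_tree(10, 0.5, 2, seed = 700 + rep)
    expect_equal(robinson_foulds(a, b), brute_rf(a, b))
  }
  t3 <- read_newick(text = "((A:1,B:1):1,(C:1,E:1):1);")
  expect_error(robinson_foulds(t1, t3), "leaf sets")
})

test_that("RF also agrees with phangorn on random tree pairs", {
  skip_if_not_installed("phangorn")
  for (rep in 1:10) {
    a <- random_additive_tree(9, 0.5, 2, seed = 800 + rep)
    b <- random_additive_tree(9, 0.5, 2, seed = 900 + rep)
    expect_equal(robinson_foulds(a, b),
                 as.integer(phangorn::RF.dist(a, b)))
  }
})

test_that("Newick round trip preserves topology and branch lengths", {
  tr <- neighbor_joining(four_taxon_matrix())
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  back <- read_newick(path)
  expect_equal(robinson_foulds(tr, back), 0)
  expect_equal(split_lengths(back), split_lengths(tr), tolerance = 1e-6)

  tr2 <- read_newick(text = "(A:1,B:2,(C:3,D:4):1);")
  expect_true(as.logical(is_monophyletic(tr2, c("C", "D"))))
  expect_error(read_newick(text = "(A:1,B:2"), "malformed|parse")
})

test_that("PHYLIP round trip reproduces the matrix", {
  d <- four_taxon_matrix()
  path <- withr::local_tempfile(fileext = ".phy")
  write_phylip(d, path)
  back <- read_phylip(path)
  expect_equal(unclass(back), unclass(d), tolerance = 1e-6)
  expect_error(read_phylip(text = "2\nA 0.0 1.0"), "malformed")
  expect_error(read_phylip(text = "x\nA 0"), "taxon count")
})
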