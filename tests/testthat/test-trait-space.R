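test_that("Gower distance matches its definition on hand-built and random matrices", {
  # hand-built 3 x (2 binary + 2 continuous)
  vals <- rbind(c(1, 0, 0.0, 2),
                c(0, 0, 0.5, 4),
                c(1, 1, 1.0, 8))
  dimnames(vals) <- list(c("a", "b", "c"), c("b1", "b2", "c1", "c2"))
  tm <- trait_matrix(vals, c("binary", "binary", "continuous", "continuous"))
  D <- gower_distance(tm)
  expect_equal(D, oracle_gower(tm), tolerance = 1e-12)
  # d(a,b): mismatch b1 + 0.5 range + 2/6 range over 4 traits
  expect_equal(D["a", "b"], (1 + 0 + 0.5 + 2 / 6) / 4, tolerance = 1e-12)

  for (s in 1:20) {
    tm <- random_small_traits(n = sample(3:10, 1), seed = s)
    expect_equal(gower_distance(tm), oracle_gower(tm), tolerance = 1e-12)
  }
})

test_that("Gower attains 0 for identical species and 1 for maximal mismatch", {
  vals <- rbind(sp1 = c(1, 0, 1, 0.0, 5),
                sp2 = c(1, 0, 1, 0.0, 5),
                sp3 = c(0, 1, 0, 1.0, 9))
  colnames(vals) <- c("b1", "b2", "b3", "c1", "c2")
  tm <- trait_matrix(vals, c(rep("binary", 3), "continuous", "continuous"))
  D <- gower_distance(tm)
  expect_identical(D["sp1", "sp2"], 0)
  expect_equal(D["sp1", "sp3"], 1)    # opposite in all binary and both ranges
})

test_that("Gower equals mismatch fraction on all-binary data and is permutation invariant", {
  set.seed(7)
  vals <- matrix(rbinom(8 * 6, 1, 0.5), 8, 6,
                 dimnames = list(sprintf("sp%02d", 1:8), paste0("b", 1:6)))
  tm <- trait_matrix(vals, rep("binary", 6))
  D <- gower_distance(tm)
  hamming <- as.matrix(dist(vals, method = "manhattan")) / 6
  expect_equal(D, hamming, tolerance = 1e-12, ignore_attr = TRUE)

  perm <- sample(8)
  tm_p <- trait_matrix(vals[perm, sample(6)], rep("binary", 6))
  expect_equal(gower_distance(tm_p)[rownames(D), colnames(D)], D,
               tolerance = 1e-12)
})

test_that("Gower agrees with an independent mixed-data implementation", {
  skip_if_not_installed("cluster")
  tm <- random_small_traits(10, n_bin = 4, n_cont = 3, seed = 11)
  df <- as.data.frame(tm$values)
  for (j in 1:4) df[[j]] <- factor(df[[j]], levels = c(0, 1))
  ref <- as.matrix(cluster::daisy(df, metric = "gower"))
  expect_equal(unname(gower_distance(tm)), unname(ref), tolerance = 1e-10)
})

test_that("Gower errors on zero-range continuous traits, naming the trait", {
  vals <- cbind(b1 = c(1, 0, 1), flatc = c(2, 2, 2))
  rownames(vals) <- paste0("s", 1:3)
  tm <- trait_matrix(vals, c("binary", "continuous"))
  expect_error(gower_distance(tm), "flatc")
})

test_that("per-group weighting gives each exclusive character total weight one", {
  vals <- cbind(g1a = c(1, 0), g1b = c(0, 1), solo = c(1, 0))
  rownames(vals) <- c("x", "y")
  tm <- trait_matrix(vals, rep("binary", 3), groups = c("g1", "g1", NA))
  # flat: (1 + 1 + 1)/3; grouped: (0.5 + 0.5 + 1)/2
  expect_equal(gower_distance(tm)["x", "y"], 1)
  expect_equal(gower_distance(tm, group_weights = TRUE)["x", "y"], 1)
  vals2 <- cbind(g1a = c(1, 0), g1b = c(0, 1), solo = c(1, 1))
  rownames(vals2) <- c("x", "y")
  tm2 <- trait_matrix(vals2, rep("binary", 3), groups = c("g1", "g1", NA))
  expect_equal(gower_distance(tm2)["x", "y"], 2 / 3)
  expect_equal(gower_distance(tm2, group_weights = TRUE)["x", "y"], 1 / 2)
})

test_that("UPGMA reproduces the worked four-species agglomeration", {
  d <- matrix(0.8, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 0.2
  d["C", "D"] <- d["D", "C"] <- 0.3
  tr <- build_dendrogram(d, "UPGMA")
  expect_equal(tr$height, c(0.1, 0.15, 0.4))
  expect_equal(cophenetic(tr)["A", "B"], 0.2)
  expect_equal(cophenetic(tr)["C", "D"], 0.3)
  expect_equal(cophenetic(tr)["A", "C"], 0.8)
  # two-species base case
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr2 <- build_dendrogram(d2, "UPGMA")
  expect_equal(tr2$height, 0.2)
  expect_equal(cophenetic(tr2)["a", "b"], 0.4)
})

test_that("dendrograms are ultrametric and match independent cophenetic derivations", {
  for (s in 1:25) {
    tm <- random_small_traits(8, seed = 100 + s)
    D <- gower_distance(tm)
    tr <- build_dendrogram(D, "UPGMA")
    # heights non-decreasing (ultrametric), leaves equidistant from root
    expect_true(all(diff(tr$height) >= -1e-12))
    # cophenetic matches the definitional (non-recurrence) UPGMA oracle
    expect_equal(cophenetic(tr), oracle_upgma_cophenetic(D), tolerance = 1e-9)
    # and the reference library implementation
    h <- stats::hclust(stats::as.dist(D), "average")
    expect_equal(cophenetic(tr)[rownames(D), colnames(D)],
                 as.matrix(stats::cophenetic(h))[rownames(D), colnames(D)],
                 tolerance = 1e-9)
  }
})

test_that("all linkage rules produce valid ultrametric trees", {
  tm <- random_small_traits(9, seed = 5)
  D <- gower_distance(tm)
  for (l in c("single", "complete", "UPGMA", "WPGMA", "Ward")) {
    tr <- build_dendrogram(D, l)
    expect_true(all(diff(tr$height) >= -1e-12), info = l)
    expect_true(all(tr$edge_length >= -1e-12), info = l)
    C <- cophenetic(tr)
    # deepest pair merges at the root: every leaf is root-height deep
    expect_equal(max(C) / 2, tr$height[length(tr$height)], tolerance = 1e-12)
    expect_equal(C, t(C))
    expect_true(all(diag(C) == 0))
  }
  # single/complete bracket UPGMA cophenetic heights
  expect_true(all(cophenetic(build_dendrogram(D, "single")) <=
                  cophenetic(build_dendrogram(D, "complete")) + 1e-12))
})

test_that("dendrogram rejects malformed distance input", {
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(build_dendrogram(bad), "symmetric")
  neg <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(build_dendrogram(neg), "negative")
})

test_that("phylo export preserves cophenetic distances (Newick round trip)", {
  tm <- random_small_traits(7, seed = 42)
  tr <- build_dendrogram(gower_distance(tm), "UPGMA")
  phy <- as.phylo.functional_dendrogram(tr)
  pc <- ape::cophenetic.phylo(phy)[tr$labels, tr$labels]
  expect_equal(pc, cophenetic(tr), tolerance = 1e-9)
  f <- tempfile(fileext = ".nwk")
  write_dendrogram(tr, f)
  tr2 <- read_dendrogram(f)
  expect_equal(cophenetic(tr2)[tr$labels, tr$labels], cophenetic(tr),
               tolerance = 1e-6)
})

test_that("clustering selection recovers UPGMA exactly on ultrametric input", {
  for (s in 1:5) {
    C <- random_ultrametric_cophenetic(8, seed = s)
    sel <- select_clustering(C)
    expect_equal(unname(sel$criterion["UPGMA"]), 0, tolerance = 1e-18)
    expect_identical(sel$selected, "UPGMA")
  }
})

test_that("selection picks the argmin criterion and honours degenerate candidate lists", {
  for (s in 1:10) {
    tm <- random_small_traits(8, seed = 300 + s)
    sel <- select_clustering(gower_distance(tm))
    expect_true(all(sel$criterion[sel$selected] <= sel$criterion + 1e-12))
  }
  tm <- random_small_traits(6, seed = 1)
  sel1 <- select_clustering(gower_distance(tm), candidates = "Ward")
  expect_identical(sel1$selected, "Ward")
  expect_length(sel1$criterion, 1L)
})

test_that("fd follows the spanning-subtree definition", {
  tm <- random_small_traits(8, seed = 9)
  tr <- build_dendrogram(gower_distance(tm), "UPGMA")
  # singleton and pair conventions
  expect_identical(fd(tr, tr$labels[3]), 0)
  expect_equal(fd(tr, tr$labels[c(2, 5)]), cophenetic(tr)[2, 5])
  # full pool = total branch length
  expect_equal(fd(tr, tr$labels), sum(tr$edge_length))
  # error handling
  expect_error(fd(tr, character(0)), "empty")
  expect_error(fd(tr, "nosuch"), "unknown")
})

test_that("fd agrees with the path-union oracle on random trees and subsets", {
  set.seed(123)
  count <- 0
  for (s in 1:20) {
    tm <- random_small_traits(8, seed = 400 + s)
    tr <- build_dendrogram(gower_distance(tm), "UPGMA")
    for (k in 1:10) {
      members <- sample(tr$labels, sample(2:8, 1))
      expect_equal(fd(tr, members), oracle_fd(tr, members), tolerance = 1e-9)
      count <- count + 1
    }
  }
  expect_gte(count, 200)
})

test_that("fd agrees with an independent phylogenetic-diversity implementation", {
  skip_if_not_installed("picante")
  tm <- generate_trait_matrix(seed = 21)
  tr <- build_dendrogram(gower_distance(tm), "UPGMA")
  phy <- as.phylo.functional_dendrogram(tr)
  cm <- generate_communities(tm, assembly_scenario("neutral", seed = 22))
  P <- unclass(cm)[, phy$tip.label]
  ref <- picante::pd(P, phy, include.root = FALSE)
  expect_equal(fd_table(tr, cm)$FD, ref$PD, tolerance = 1e-9)
})

test_that("fd is set-monotone and order invariant", {
  set.seed(77)
  tm <- random_small_traits(9, seed = 55)
  tr <- build_dendrogram(gower_distance(tm), "UPGMA")
  for (i in 1:30) {
    A <- sample(tr$labels, sample(1:7, 1))
    B <- union(A, sample(tr$labels, sample(1:9, 1)))
    expect_lte(fd(tr, A), fd(tr, B) + 1e-12)
    expect_identical(fd(tr, sample(A)), fd(tr, A))
  }
})
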