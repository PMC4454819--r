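# Profile alignment, Ward clustering, two-cluster cut, tree classification.

test_that("profile_matrix aligns on the grid and honours fill policies", {
  profs <- list(
    A = structure(data.frame(concentration = c(1, 5, 25), score = c(0.1, 0.2,
                                                                    0.4),
                             n_exposed = 12), material_id = "A",
                  class = c("ez_profile", "data.frame")),
    B = structure(data.frame(concentration = c(0, 1, 5, 25),
                             score = c(0, 0.3, 0.5, 0.9), n_exposed = 12),
                  material_id = "B", class = c("ez_profile", "data.frame"))
  )
  m <- profile_matrix(profs)
  expect_equal(dim(m), c(2, 3))
  expect_equal(m["B", ], c("1" = 0.3, "5" = 0.5, "25" = 0.9))

  # a gap: error by default, zero with warning, log-linear interpolation
  profs$C <- structure(data.frame(concentration = c(1, 25),
                                  score = c(0.2, 0.8), n_exposed = 12),
                       material_id = "C",
                       class = c("ez_profile", "data.frame"))
  expect_error(profile_matrix(profs), "C.*5")
  expect_warning(mz <- profile_matrix(profs, fill = "zero"), "missing")
  expect_equal(unname(mz["C", "5"]), 0)
  mi <- profile_matrix(profs, fill = "interpolate")
  # 5 is exactly midway between 1 and 25 on the log scale
  expect_equal(unname(mi["C", "5"]), 0.5)
})

test_that("ward_cluster merges identical rows at zero and separates far
           pairs", {
  x <- rbind(a = c(0, 0), b = c(0, 0), c = c(10, 10), d = c(10.5, 10))
  hc <- ward_cluster(x)
  expect_equal(hc$height[1], 0)
  expect_true(all(diff(hc$height) >= 0))
  ct <- stats::cutree(structure(unclass(hc), class = "hclust"), k = 2)
  expect_equal(unname(ct[c("a", "b")]), c(1, 1))
  expect_equal(unname(ct[c("c", "d")]), c(2, 2))
  expect_error(ward_cluster(x[1, , drop = FALSE]), "at least 2")
  x[1, 1] <- NA
  expect_error(ward_cluster(x), "non-finite")
})

test_that("ward merge sequence and costs equal the brute-force SSE oracle", {
  set.seed(19)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    x <- matrix(rnorm(n * 4), n)
    hc <- ward_cluster(x)
    oracle <- brute_ward(x)
    expect_equal(hc$height, oracle$heights, tolerance = 1e-9)
    expect_identical(hclust_merged_sets(hc), oracle$merged_sets)
  }
})

test_that("ward heights are half the ward.D heights of squared distances", {
  set.seed(20)
  x <- matrix(rnorm(12 * 8), 12)
  hc <- ward_cluster(x)
  ref <- stats::hclust(stats::dist(x)^2, method = "ward.D")
  expect_equal(hc$height, ref$height / 2, tolerance = 1e-9)
  for (k in 2:5) {
    a <- stats::cutree(structure(unclass(hc), class = "hclust"), k)
    b <- stats::cutree(ref, k)
    expect_equal(length(unique(paste(a, b))), k)  # identical partitions
  }
})

test_that("clustering is row-order invariant up to relabeling", {
  set.seed(21)
  x <- matrix(rnorm(10 * 5), 10,
              dimnames = list(paste0("m", 1:10), NULL))
  perm <- sample(10)
  h1 <- ward_cluster(x)
  h2 <- ward_cluster(x[perm, ])
  expect_equal(sort(h1$height), sort(h2$height), tolerance = 1e-9)
  c1 <- stats::cutree(structure(unclass(h1), class = "hclust"), k = 3)
  c2 <- stats::cutree(structure(unclass(h2), class = "hclust"), k = 3)
  expect_equal(length(unique(paste(c1[names(c2)], c2))), 3)
})

test_that("dendrogram tree nodes satisfy member and height invariants", {
  set.seed(22)
  x <- matrix(rnorm(8 * 3), 8, dimnames = list(letters[1:8], NULL))
  hc <- ward_cluster(x)
  check <- function(node) {
    if (is.null(node$children)) {
      expect_equal(node$height, 0)
      expect_length(node$members, 1)
    } else {
      expect_setequal(node$members, c(node$children[[1]]$members,
                                      node$children[[2]]$members))
      for (ch in node$children) {
        expect_gte(node$height, ch$height)
        check(ch)
      }
    }
  }
  root <- dendrogram_tree(hc)
  expect_setequal(root$members, letters[1:8])
  check(root)
})

test_that("newick export round-trips tip labels through ape", {
  set.seed(23)
  x <- matrix(rnorm(6 * 4), 6, dimnames = list(paste0("NP", 1:6), NULL))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(ward_cluster(x), path)
  tr <- ape::read.tree(path)
  expect_setequal(tr$tip.label, paste0("NP", 1:6))
  expect_equal(ape::Ntip(tr), 6)
})

test_that("cut_two labels the more toxic cluster B and summarizes sumEZ", {
  x <- rbind(a = c(0.1, 0.1), b = c(0.2, 0.1), c = c(3, 4), d = c(3.1, 4))
  hc <- ward_cluster(x)
  sz <- c(a = 0.4, b = 0.6, c = 6, d = 7)
  ct <- cut_two(hc, sz)
  expect_identical(unname(ct$assignment[c("a", "b", "c", "d")]),
                   c("A", "A", "B", "B"))
  expect_equal(unname(ct$means["B"]), 6.5)
  expect_equal(ct$summary$n, c(2, 2))
  expect_equal(ct$summary$mean, c(0.5, 6.5))
  expect_equal(ct$summary$min, c(0.4, 6))
  expect_equal(ct$summary$max, c(0.6, 7))

  # a tie in mean sumEZ falls back to the smallest id, with a warning
  sz_tie <- c(a = 1, b = 1, c = 1, d = 1)
  expect_warning(ct2 <- cut_two(hc, sz_tie), "tie")
  expect_identical(unname(ct2$assignment["a"]), "B")
  expect_error(cut_two(hc, sz[1:3]), "d")
})

test_that("gain-ratio tree represents the any-group rule exactly", {
  pats <- expand.grid(tmat = c(FALSE, TRUE), phosphate = c(FALSE, TRUE),
                      phosphatidylcholine = c(FALSE, TRUE),
                      amine = c(FALSE, TRUE))
  feats <- pats[rep(seq_len(nrow(pats)), 3), ]
  rownames(feats) <- sprintf("NP-%02d", seq_len(nrow(feats)))
  labels <- ifelse(rowSums(feats) > 0, "B", "A")
  tr <- build_tree(feats, labels)
  expect_identical(unname(predict(tr, feats)), unname(labels))
  expect_lte(tree_depth(tr), 4)

  # all labels identical: a single leaf
  leaf <- build_tree(feats, rep("A", nrow(feats)))
  expect_identical(leaf$root$type, "leaf")
  expect_identical(predict(leaf, feats[1:3, ]), rep("A", 3))
})

test_that("the perfectly separating feature is chosen at the root", {
  set.seed(31)
  n <- 40
  feats <- data.frame(tmat = sample(c(TRUE, FALSE), n, replace = TRUE),
                      phosphate = sample(c(TRUE, FALSE), n, replace = TRUE),
                      phosphatidylcholine = runif(n) < 0.5,
                      amine = runif(n) < 0.5)
  labels <- ifelse(feats$phosphate, "B", "A")
  tr <- build_tree(feats, labels)
  expect_identical(tr$root$feature, "phosphate")
  expect_identical(tr$root$branch_true$type, "leaf")
  # hand entropy check: a perfect split has gain = H(labels) and split
  # information = H(feature), so its gain ratio exceeds any noisy feature's
  h <- function(p) ifelse(p %in% c(0, 1), 0, -p * log2(p) -
                            (1 - p) * log2(1 - p))
  expect_gt(h(mean(labels == "B")) / h(mean(feats$phosphate)), 0.99)

  # agreement with a recursive-partitioning reference on the separable case
  rp <- rpart::rpart(y ~ ., data = cbind(feats, y = factor(labels)),
                     method = "class", minsplit = 2, cp = 0)
  expect_identical(as.character(predict(rp, feats, type = "class")),
                   predict(tr, feats))
})

test_that("cross-validation is deterministic, exact on noiseless rules, and
           chance-level on random labels", {
  pats <- expand.grid(tmat = c(FALSE, TRUE), phosphate = c(FALSE, TRUE),
                      phosphatidylcholine = c(FALSE, TRUE),
                      amine = c(FALSE, TRUE))
  feats <- pats[rep(seq_len(nrow(pats)), 4), ]
  rownames(feats) <- sprintf("NP-%02d", seq_len(nrow(feats)))
  labels <- ifelse(rowSums(feats) > 0, "B", "A")

  cv <- cross_validate(feats, labels, scheme = "loo")
  expect_equal(cv$accuracy, 1.0)
  expect_length(cv$misclassified, 0)
  expect_equal(cv$n, nrow(feats))

  k1 <- cross_validate(feats, labels, scheme = "kfold", k = 10, seed = 17)
  k2 <- cross_validate(feats, labels, scheme = "kfold", k = 10, seed = 17)
  expect_identical(k1$accuracy, k2$accuracy)
  expect_identical(k1$misclassified, k2$misclassified)
  expect_equal(1 - length(k1$misclassified) / k1$n, k1$accuracy)

  # labels independent of features: accuracy near the majority fraction
  set.seed(33)
  n <- 200
  rf <- data.frame(tmat = runif(n) < 0.5, phosphate = runif(n) < 0.5,
                   phosphatidylcholine = runif(n) < 0.5, amine = runif(n) < 0.5)
  rl <- sample(c("A", "B"), n, replace = TRUE, prob = c(0.6, 0.4))
  cvr <- cross_validate(rf, rl, scheme = "kfold", k = 10, seed = 1)
  expect_lt(abs(cvr$accuracy - max(table(rl)) / n), 0.1)
})
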