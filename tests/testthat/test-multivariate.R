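test_that("a single perfectly informative feature gives R2X = 1, VIP = 1", {
  y <- factor(rep(c("a", "b"), each = 10))
  X <- matrix(ifelse(y == "b", 1, -1), ncol = 1,
              dimnames = list(NULL, "marker"))
  f <- fit_plsda(X, y, n_components = 1)
  expect_equal(f$r2x, 1, tolerance = 1e-12)
  expect_equal(unname(f$vip), 1, tolerance = 1e-12)
})

test_that("mean squared VIP is exactly 1 across random fits", {
  set.seed(5)
  for (i in 1:100) {
    n <- sample(10:25, 1); p <- sample(3:12, 1)
    a <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- factor(rep_len(c("a", "b"), n))
    f <- fit_plsda(X, y, n_components = min(a, n - 1, p))
    expect_equal(mean(f$vip^2), 1, tolerance = 1e-8)
  }
})

test_that("scores are orthogonal and component 1 matches the eigen oracle", {
  set.seed(6)
  X <- matrix(rnorm(5 * 3), 5, 3)
  y <- factor(c("a", "a", "a", "b", "b"))
  f <- fit_plsda(X, y, n_components = 2, standardize = FALSE)
  G <- crossprod(f$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-10)

  # first weight vector = dominant eigenvector of X'y y'X (rank-one)
  Xc <- scale(X, scale = FALSE)
  yc <- ifelse(y == "b", 1, -1); yc <- yc - mean(yc)
  M <- crossprod(Xc, yc) %*% t(crossprod(Xc, yc))
  ev <- eigen(M, symmetric = TRUE)$vectors[, 1]
  w1 <- f$weights[, 1]
  expect_equal(abs(sum(w1 * ev)), 1, tolerance = 1e-10)
})

test_that("the fit agrees with the mixOmics reference implementation", {
  set.seed(7)
  X <- matrix(rnorm(30 * 12), 30, 12,
              dimnames = list(NULL, paste0("f", 1:12)))
  y <- factor(rep(c("a", "b"), 15))
  f <- fit_plsda(X, y, n_components = 3)
  ref <- mixOmics::plsda(X, y, ncomp = 3, scale = TRUE)
  for (a in 1:3)
    expect_equal(abs(cor(f$scores[, a], ref$variates$X[, a])), 1,
                 tolerance = 1e-8)
  expect_equal(unname(f$vip), unname(mixOmics::vip(ref)[, 3]),
               tolerance = 1e-8)
})

test_that("degenerate PLS-DA inputs are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_plsda(X, factor(rep("a", 10))), "two classes")
  expect_error(fit_plsda(X, factor(rep_len(c("a", "b"), 10)),
                         n_components = 5), "exceeds")
})

test_that("Q2Y separates predictive from permuted models", {
  set.seed(8)
  n <- 40
  y <- factor(rep(c("a", "b"), each = n / 2))
  X <- matrix(rnorm(n * 10, sd = 0.2), n, 10)
  X[, 1] <- X[, 1] + ifelse(y == "b", 2, -2)
  X[, 2] <- X[, 2] + ifelse(y == "b", 1.5, -1.5)
  expect_gt(q2y(X, y, n_components = 2, k_folds = 5, seed = 1), 0.9)

  perms <- replicate(20, {
    q2y(X, sample(y), n_components = 2, k_folds = 5, seed = 1)
  })
  expect_lte(mean(perms), 0.1)
})

test_that("rdCV-RF recovers planted features and keeps sets nested", {
  set.seed(13)
  hits <- 0L
  for (s in 1:5) {
    n <- 60
    y <- factor(rep(c("a", "b"), each = n / 2))
    X <- matrix(rnorm(n * 50), n, 50,
                dimnames = list(NULL, paste0("f", 1:50)))
    X[, 1:2] <- X[, 1:2] + ifelse(y == "b", 1, -1)  # 2 log-units apart
    rf <- rdcv_rf_select(X, y, params = list(n_rep = 2, n_outer = 5,
                                             num_trees = 150), seed = s)
    expect_true(all(rf$min_set %in% rf$mid_set))
    expect_true(all(rf$mid_set %in% rf$max_set))
    if (all(c("f1", "f2") %in% rf$min_set) && rf$auroc[["max"]] >= 0.9)
      hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("rdCV-RF outer AUROC is honest on uninformative data", {
  # selection happens strictly inside the training folds; if held-out
  # information leaked into selection, pure-noise labels would show
  # optimistic AUROC well above chance
  set.seed(14)
  aucs <- vapply(1:10, function(s) {
    n <- 40
    y <- factor(rep(c("a", "b"), each = n / 2))
    X <- matrix(rnorm(n * 30), n, 30)
    rdcv_rf_select(X, sample(y),
                   params = list(n_rep = 1, n_outer = 4, num_trees = 100),
                   seed = s)$auroc[["max"]]
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("the rank-based AUROC matches the pROC reference", {
  set.seed(16)
  for (i in 1:10) {
    y <- rbinom(50, 1, 0.4) == 1
    s <- rnorm(50) + y
    ref <- suppressMessages(as.numeric(pROC::auc(y, s,
                                                 direction = "<",
                                                 quiet = TRUE)))
    expect_equal(lipidmets:::.auroc(s, y), ref, tolerance = 1e-12)
  }
})

test_that("consensus intersections and UpSet cardinalities are exact", {
  sets <- list(m1 = c("A", "B", "C"), m2 = c("B", "C"),
               m3 = c("B", "C", "D"), m4 = c("B", "C"))
  cs <- consensus_features(sets, universe = LETTERS[1:5])
  expect_equal(cs$intersection, c("B", "C"))
  # A is in m1 only; D in m3 only; B,C in all four
  up <- cs$upset
  expect_equal(up$count[up$combination == "m1"], 1)
  expect_equal(up$count[up$combination == "m3"], 1)
  expect_equal(up$count[up$combination == "m1&m2&m3&m4"], 2)
  expect_equal(sum(up$count), 4)  # every selected feature counted once

  cs2 <- consensus_features(list(a = character(0), b = c("A")),
                            universe = LETTERS[1:3])
  expect_length(cs2$intersection, 0)

  expect_error(consensus_features(list(a = "A", b = "Z"),
                                  universe = LETTERS[1:3]), "Z")
  expect_error(consensus_features(list(a = "A"), universe = "A"),
               "at least 2")
})

test_that("not all features can clear VIP > 1 unless all VIPs equal 1", {
  set.seed(15)
  X <- matrix(rnorm(20 * 8), 20, 8)
  y <- factor(rep_len(c("a", "b"), 20))
  f <- fit_plsda(X, y)
  if (any(f$vip != 1)) expect_lt(sum(f$vip > 1), length(f$vip))
})
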