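test_that("Mann-Whitney switches between exact and approximate correctly", {
  # exact enumeration: U = 0 and p = 2 * 1/6 = 1/3
  mt <- mann_whitney_test(c(1, 2), c(3, 4))
  expect_equal(mt$U, 0)
  expect_equal(mt$p, 1 / 3, tolerance = 1e-12)

  # identical multisets: symmetric null, p = 1
  expect_equal(mann_whitney_test(c(1, 3, 5), c(1, 3, 5))$p, 1)

  expect_error(mann_whitney_test(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney is invariant to strictly monotone transforms", {
  set.seed(4)
  a <- rnorm(30); b <- rnorm(25, 0.5)
  p1 <- mann_whitney_test(a, b)$p
  p2 <- mann_whitney_test(exp(a), exp(b))$p
  p3 <- mann_whitney_test(a^3, b^3)$p
  expect_equal(p1, p2)
  expect_equal(p1, p3)
})

test_that("Mann-Whitney holds its nominal level on large-sample nulls", {
  set.seed(9)
  reps <- 1000
  rej <- mean(replicate(reps, {
    mann_whitney_test(rnorm(100), rnorm(100))$p < 0.05
  }))
  band <- qbinom(c(0.005, 0.995), reps, 0.05) / reps
  expect_gte(rej, band[1])
  expect_lte(rej, band[2])
})

test_that("BH adjustment matches the hand step-up rule", {
  # independent step-up oracle: q_(i) = min_{j >= i} p_(j) * m / j
  bh_oracle <- function(p) {
    m <- length(p)
    ord <- order(p)
    q_sorted <- pmin(1, rev(cummin(rev(p[ord] * m / seq_len(m)))))
    q <- numeric(m); q[ord] <- q_sorted
    q
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.001, 0.5)), c(0.002, 0.5))
  expect_equal(bh_adjust(0.3), 0.3)
  set.seed(2)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
    expect_true(all(bh_adjust(p) >= p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1)), "\\[0, 1\\]")
})

test_that("moderated t reduces to the ordinary t when d0 is forced to 0", {
  set.seed(10)
  v <- matrix(rnorm(50 * 16, sd = rep(runif(50, 0.5, 2), 16)), 50)
  m <- make_abund(v, scale = "log")
  fm <- fit_moderated(m, d0_override = 0)
  mets <- m$group == "MetS"
  for (i in c(1, 17, 50)) {
    tt <- t.test(v[i, mets], v[i, !mets], var.equal = TRUE)
    expect_equal(fm$table$statistic[i], unname(tt$statistic),
                 tolerance = 1e-12)
    expect_equal(fm$table$p[i], tt$p.value, tolerance = 1e-12)
  }
})

test_that("equal residual variances make moderation a no-op", {
  set.seed(11)
  n1 <- 8; n2 <- 8
  v <- matrix(rnorm(40 * (n1 + n2)), 40)
  # rescale every feature to exactly the same pooled within-group SS
  for (i in seq_len(nrow(v))) {
    x1 <- v[i, 1:n1] - mean(v[i, 1:n1])
    x2 <- v[i, -(1:n1)] - mean(v[i, -(1:n1)])
    sc <- sqrt((n1 + n2 - 2) / (sum(x1^2) + sum(x2^2)))
    v[i, ] <- c(x1, x2) * sc
  }
  grp <- factor(rep(c("noMetS", "MetS"), c(n1, n2)),
                levels = c("noMetS", "MetS"))
  fm <- fit_moderated(make_abund(v, group = grp, scale = "log"))
  expect_true(is.infinite(fm$d0))
  expect_equal(fm$table$s_tilde_sq, fm$table$s2, tolerance = 1e-6)
})

test_that("posterior variances match a direct evaluation of the prior formula", {
  # toy with known per-feature variances; the oracle re-estimates the prior
  # by solving the trigamma moment equation with uniroot, independently of
  # the fitting code, then applies the shrinkage formula directly
  set.seed(12)
  n1 <- 3; n2 <- 3; d <- n1 + n2 - 2
  target <- c(1, 4, 9)
  v <- matrix(rnorm(3 * 6), 3)
  for (i in 1:3) {
    x1 <- v[i, 1:3] - mean(v[i, 1:3]); x2 <- v[i, 4:6] - mean(v[i, 4:6])
    v[i, ] <- c(x1, x2) * sqrt(target[i] * d / (sum(x1^2) + sum(x2^2)))
  }
  grp <- factor(rep(c("noMetS", "MetS"), each = 3),
                levels = c("noMetS", "MetS"))
  fm <- fit_moderated(make_abund(v, group = grp, scale = "log"))
  expect_equal(fm$table$s2, target, tolerance = 1e-10)

  e <- log(target) - digamma(d / 2) + log(d / 2)
  evar <- var(e) - trigamma(d / 2)
  d0_oracle <- 2 * uniroot(function(y) trigamma(y) - evar,
                           c(1e-3, 1e3), tol = 1e-12)$root
  s0_oracle <- exp(mean(e) + digamma(d0_oracle / 2) - log(d0_oracle / 2))
  expect_equal(fm$d0, d0_oracle, tolerance = 1e-6)
  stilde_oracle <- (d0_oracle * s0_oracle + d * target) / (d0_oracle + d)
  expect_equal(fm$table$s_tilde_sq, stilde_oracle, tolerance = 1e-6)
  # posterior variances sit between the prior and the observed variance
  expect_true(all(fm$table$s_tilde_sq >= pmin(target, fm$s0_sq) &
                    fm$table$s_tilde_sq <= pmax(target, fm$s0_sq)))
})

test_that("the moderated fit matches the limma reference on random data", {
  set.seed(42)
  p <- 200; n1 <- 8; n2 <- 8
  v <- matrix(rnorm(p * (n1 + n2), sd = rep(sqrt(rchisq(p, 4) / 4), n1 + n2)), p)
  v[1:20, 1:n1] <- v[1:20, 1:n1] + 1
  rownames(v) <- paste0("f", 1:p); colnames(v) <- paste0("s", 1:(n1 + n2))
  grp <- factor(rep(c("MetS", "noMetS"), c(n1, n2)),
                levels = c("noMetS", "MetS"))
  fm <- fit_moderated(abundance_matrix(v, grp, scale = "log"))
  ref <- limma::eBayes(limma::lmFit(v, model.matrix(~grp)))
  expect_equal(fm$d0, unname(ref$df.prior), tolerance = 1e-8)
  expect_equal(fm$s0_sq, unname(ref$s2.prior), tolerance = 1e-8)
  expect_equal(fm$table$statistic, unname(ref$t[, 2]), tolerance = 1e-10)
  expect_equal(fm$table$p, unname(ref$p.value[, 2]), tolerance = 1e-10)
})

test_that("differential arms control FDR under the null and have power", {
  # global null: no feature passes q < 0.05 in most seeds
  n_pass <- 0L
  for (s in 1:5) {
    co <- generate_cohort(cohort_config(
      n_per_group = 30, category_counts = c(glycerolipid = 150),
      effect_fraction = 0, missing_rate = 0, block_correlation = 0,
      seed = 100 + s))
    cen <- impute_and_center(co$lipids)
    lg <- log_transform(cen)
    hits <- sum(fit_moderated(lg)$table$q < 0.05) +
      sum(diff_mann_whitney(cen)$table$q < 0.05)
    if (hits == 0) n_pass <- n_pass + 1L
  }
  expect_gte(n_pass, 4L)

  # planted effects at the design size are recovered at q < 0.001
  co <- generate_cohort(cohort_config(
    n_per_group = 100, category_counts = c(glycerolipid = 200),
    effect_fraction = 0.1, effect_log2fc = 1, noise_sd = 0.3,
    missing_rate = 0, seed = 31))
  cen <- impute_and_center(co$lipids)
  lg <- log_transform(cen)
  mw <- diff_mann_whitney(cen, q_cut = 0.001)
  mo <- fit_moderated(lg, q_cut = 0.001)
  expect_gte(mean(co$truth %in% mw$selected), 0.9)
  expect_gte(mean(co$truth %in% mo$selected), 0.9)
})

test_that("zero-variance features are excluded from the moderated fit", {
  v <- rbind(flat = rep(1, 12), ok = rnorm(12), ok2 = rnorm(12))
  m <- make_abund(v, scale = "log")
  expect_warning(fm <- fit_moderated(m), "zero-variance")
  expect_equal(fm$table$feature_id, c("ok", "ok2"))
  expect_error(fit_moderated(make_abund(matrix(rnorm(4), 1,
    dimnames = list("a", letters[1:4])),
    group = factor(c("x", "x", "y", "y")), scale = "log"),
    q_cut = 0.001), NA)
  short <- abundance_matrix(matrix(rnorm(3), 1,
                                   dimnames = list("a", letters[1:3])),
                            factor(c("x", "x", "y")), scale = "log")
  expect_error(fit_moderated(short), "at least 2")
})
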