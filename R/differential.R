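#' Two-sided Mann-Whitney U test
#'
#' Thin wrapper around [stats::wilcox.test()] with a fixed small-sample
#' policy: the exact null distribution is used when the pooled sample size is
#' at most 20 and the data carry no ties; otherwise the normal approximation
#' with tie correction and continuity correction applies.
#'
#' @param a,b Numeric vectors, one per group (each non-empty).
#' @return List with `U` (the U statistic for `a`) and `p` (two-sided).
#' @export
#' @examples
#' mann_whitney_test(c(1, 2), c(3, 4))  # U = 0, p = 1/3
mann_whitney_test <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b)) <= 20L && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in the original order, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# common result container for the four selection arms
differential_result <- function(method, table, selected, threshold_rule) {
  stopifnot(all(c("feature_id", "effect", "statistic", "p", "q") %in%
                  names(table)))
  structure(list(method = method, table = table,
                 selected = selected, threshold_rule = threshold_rule),
            class = "differential_result")
}

#' @export
print.differential_result <- function(x, ...) {
  cat(sprintf("<differential_result> method=%s, %d features, %d selected (%s)\n",
              x$method, nrow(x$table), length(x$selected), x$threshold_rule))
  invisible(x)
}

#' Per-feature Mann-Whitney differential abundance
#'
#' Applied to raw-scale concentrations (rank-based, hence invariant to
#' monotone transforms). Effect is the difference of group medians
#' (case minus control).
#'
#' @param m An [abundance_matrix()]; the second group level is the case.
#' @param q_cut BH-adjusted selection threshold (default 0.001).
#' @return A `differential_result` with method `"mann_whitney"`.
#' @export
diff_mann_whitney <- function(m, q_cut = 0.001) {
  stopifnot(inherits(m, "abundance_matrix"))
  case <- m$group == levels(m$group)[2]
  rows <- lapply(seq_len(nrow(m$values)), function(i) {
    x <- m$values[i, ]
    mt <- mann_whitney_test(x[case], x[!case])
    data.frame(feature_id = rownames(m$values)[i],
               effect = stats::median(x[case]) - stats::median(x[!case]),
               statistic = mt$U, p = mt$p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q <- bh_adjust(tab$p)
  sel <- tab$feature_id[tab$q < q_cut]
  differential_result("mann_whitney", tab, sel,
                      sprintf("BH q < %g", q_cut))
}

# Newton solve of trigamma(y) = x (x > 0), monotone decreasing trigamma
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (iter in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Fit the empirical-Bayes moderated two-group model
#'
#' For log-scale data, computes the per-feature group difference
#' `beta = mean(case) - mean(control)` and pooled residual variance `s2` on
#' `d = n - 2` degrees of freedom, shrinks the variances towards a prior
#' `(d0, s0_sq)` estimated by method of moments on the log variances
#' (mean and spread of `log s2` matched to their digamma/trigamma
#' expressions; the trigamma equation is solved by monotone Newton
#' iteration), and tests `beta` with the moderated t on `d0 + d` degrees of
#' freedom, where the posterior variance is
#' `s_tilde_sq = (d0 * s0_sq + d * s2) / (d0 + d)`.
#'
#' When the log variances show no excess spread over chi-square sampling
#' noise, the prior degrees of freedom are infinite and the posterior
#' variance is the common variance itself (moderation is a no-op).
#'
#' @param m A log-scale [abundance_matrix()]; both groups need >= 2 samples.
#' @param q_cut BH selection threshold (default 0.001).
#' @param d0_override Optional prior degrees of freedom forced on the fit;
#'   `0` reduces the moderated t to the ordinary equal-variance t.
#' @return An object of class `moderated_fit`: a `differential_result`
#'   (method `"moderated_t"`) with extra fields `d0`, `s0_sq`, and per-feature
#'   `s2`, `s_tilde_sq`, `df_total` in the table.
#' @export
fit_moderated <- function(m, q_cut = 0.001, d0_override = NULL) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (m$scale != "log") stop("fit_moderated expects log-scale data")
  case <- m$group == levels(m$group)[2]
  n1 <- sum(case); n2 <- sum(!case)
  if (n1 < 2 || n2 < 2) stop("both groups need at least 2 samples")
  d <- n1 + n2 - 2

  v <- m$values
  m1 <- rowMeans(v[, case, drop = FALSE])
  m2 <- rowMeans(v[, !case, drop = FALSE])
  beta <- m1 - m2
  ss <- rowSums((v[, case, drop = FALSE] - m1)^2) +
    rowSums((v[, !case, drop = FALSE] - m2)^2)
  s2 <- ss / d

  keep <- s2 > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance feature(s) excluded from the ",
            "moderated fit")
  }
  ids <- rownames(v)[keep]
  beta <- beta[keep]; s2 <- s2[keep]

  if (!is.null(d0_override)) {
    d0 <- d0_override
    s0_sq <- if (d0 > 0 && is.finite(d0)) mean(s2) else NA_real_
  } else {
    # moments of e = log(s2) under s2 ~ s_g^2 * chisq_d / d
    e <- log(s2) - digamma(d / 2) + log(d / 2)
    e_bar <- mean(e)
    e_var <- stats::var(e) - trigamma(d / 2)
    if (is.na(e_var) || e_var <= 0) {
      d0 <- Inf
      s0_sq <- mean(s2)
    } else {
      d0 <- 2 * .trigamma_inverse(e_var)
      s0_sq <- exp(e_bar + digamma(d0 / 2) - log(d0 / 2))
    }
  }

  s_tilde_sq <- if (is.infinite(d0)) {
    rep(s0_sq, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * s0_sq + d * s2) / (d0 + d)
  }
  se <- sqrt(s_tilde_sq * (1 / n1 + 1 / n2))
  tstat <- beta / se
  df_total <- min(d0 + d, .Machine$double.xmax)
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  q <- bh_adjust(p)

  tab <- data.frame(feature_id = ids, effect = beta, statistic = tstat,
                    p = p, q = q, s2 = s2, s_tilde_sq = s_tilde_sq,
                    df_total = df_total, stringsAsFactors = FALSE)
  sel <- tab$feature_id[tab$q < q_cut]
  out <- differential_result("moderated_t", tab, sel,
                             sprintf("BH q < %g", q_cut))
  out$d0 <- d0
  out$s0_sq <- s0_sq
  class(out) <- c("moderated_fit", class(out))
  out
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat(sprintf("<moderated_fit> %d features; prior d0=%.3g, s0^2=%.3g; %d selected (%s)\n",
              nrow(x$table), x$d0, x$s0_sq, length(x$selected),
              x$threshold_rule))
  invisible(x)
}

#' Write a differential result table as TSV
#'
#' Columns: feature_id, class, category, effect, statistic, p, q, selected,
#' method. Class and category come from the parsed feature metadata; features
#' absent from `meta` (e.g. metabolites) get NA.
#'
#' @param result A `differential_result`.
#' @param meta Feature metadata from [parse_lipid_names()], or NULL.
#' @param path Output path.
#' @export
write_differential <- function(result, meta = NULL, path) {
  stopifnot(inherits(result, "differential_result"))
  tab <- result$table[, c("feature_id", "effect", "statistic", "p", "q")]
  if (!is.null(meta)) {
    idx <- match(tab$feature_id, meta$name)
    tab$class <- meta$class[idx]
    tab$category <- meta$category[idx]
  } else {
    tab$class <- NA_character_
    tab$category <- NA_character_
  }
  tab$selected <- tab$feature_id %in% result$selected
  tab$method <- result$method
  tab <- tab[, c("feature_id", "class", "category", "effect", "statistic",
                 "p", "q", "selected", "method")]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
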