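# samples x features view of an abundance matrix
.as_sample_matrix <- function(X) {
  if (inherits(X, "abundance_matrix")) t(X$values) else as.matrix(X)
}

#' Fit a PLS-DA model (NIPALS, single binary response)
#'
#' Sequential NIPALS components with X deflation on a centered (and by
#' default unit-variance scaled) feature matrix; the class labels are coded
#' +/-1 and centered. Per component the fraction of X variance explained
#' (R2X) and the response variance captured (SSY) are recorded, and variable
#' importance in projection is
#' `VIP_j = sqrt(p * sum_a w_ja^2 SSY_a / sum_a SSY_a)`,
#' so the mean of squared VIPs over features is exactly 1.
#'
#' @param X Samples x features numeric matrix, or an [abundance_matrix()]
#'   (transposed internally).
#' @param y Binary factor/vector of length `nrow(X)`; the second level (or
#'   larger value) is the case class.
#' @param n_components Number of components (must not exceed
#'   `min(n_samples - 1, n_features)`).
#' @param standardize Scale features to unit variance (default TRUE).
#' @return An object of class `plsda_fit` with fields `scores`, `loadings`,
#'   `weights`, `y_loadings`, `r2x`, `ssy`, `vip`, `coefficients` (regression
#'   vector on the scaled X), centering/scaling vectors and the class coding.
#' @export
fit_plsda <- function(X, y, n_components = 2, standardize = TRUE) {
  if (inherits(X, "abundance_matrix") && missing(y)) y <- X$group
  X <- .as_sample_matrix(X)
  y <- as.factor(y)
  if (nlevels(y) != 2L) stop("y must have exactly two classes")
  if (n_components > min(nrow(X) - 1L, ncol(X)))
    stop("n_components exceeds min(n_samples - 1, n_features)")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))

  center <- colMeans(X)
  scale_ <- if (standardize) {
    s <- apply(X, 2, stats::sd)
    s[s == 0] <- 1
    s
  } else rep(1, ncol(X))
  Xc <- sweep(sweep(X, 2, center), 2, scale_, "/")
  y_num <- ifelse(y == levels(y)[2], 1, -1)
  yc <- y_num - mean(y_num)

  n <- nrow(Xc); p <- ncol(Xc)
  ssx0 <- sum(Xc^2)
  W <- P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  q <- r2x <- ssy <- numeric(n_components)
  Xd <- Xc; yd <- yc
  for (a in seq_len(n_components)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stop("degenerate component ", a, ": X'y vanished")
    w <- w / nw
    tt <- Xd %*% w
    tt2 <- sum(tt^2)
    pl <- crossprod(Xd, tt) / tt2
    qa <- sum(yd * tt) / tt2
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- tt; q[a] <- qa
    r2x[a] <- tt2 * sum(pl^2) / ssx0
    ssy[a] <- qa^2 * tt2
    Xd <- Xd - tt %*% t(pl)
    yd <- yd - tt * qa
  }
  rownames(W) <- rownames(P) <- colnames(X)

  vip <- sqrt(p * as.vector(W^2 %*% ssy) / sum(ssy))
  names(vip) <- colnames(X)
  # PLS1 regression vector on the scaled X: B = W (P'W)^{-1} q
  B <- W %*% solve(crossprod(P, W), q)

  structure(list(scores = Tm, loadings = P, weights = W, y_loadings = q,
                 r2x = r2x, ssy = ssy, vip = vip,
                 coefficients = as.vector(B),
                 center = center, scale = scale_, y_mean = mean(y_num),
                 levels = levels(y), n_components = n_components,
                 standardize = standardize),
            class = "plsda_fit")
}

#' @export
print.plsda_fit <- function(x, ...) {
  cat(sprintf("<plsda_fit> %d components over %d features; R2X = %s\n",
              x$n_components, length(x$vip),
              paste(sprintf("%.3f", x$r2x), collapse = ", ")))
  cat(sprintf("  %d features with VIP > 1\n", sum(x$vip > 1)))
  invisible(x)
}

#' Predict continuous class scores from a PLS-DA fit
#'
#' @param object A `plsda_fit`.
#' @param newdata Samples x features matrix with the training feature set.
#' @param ... Unused.
#' @return Numeric vector of predicted (centered +/-1 coded) responses.
#' @export
predict.plsda_fit <- function(object, newdata, ...) {
  Xc <- sweep(sweep(.as_sample_matrix(newdata), 2, object$center),
              2, object$scale, "/")
  as.vector(Xc %*% object$coefficients)
}

# stratified fold assignment: both classes spread over folds
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- sample(which(y == lev))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated Q2Y of a PLS-DA model
#'
#' `Q2Y = 1 - PRESS / TSS`, with PRESS accumulated from k-fold
#' cross-validated predictions of the centered +/-1 response and TSS the
#' total sum of squares of that response. May be negative for models with no
#' predictive power.
#'
#' @inheritParams fit_plsda
#' @param k_folds Number of stratified folds (>= 2).
#' @param seed Integer seed for the fold split.
#' @return Q2Y as a single number.
#' @export
q2y <- function(X, y, n_components = 2, k_folds = 7, seed = 1,
                standardize = TRUE) {
  if (inherits(X, "abundance_matrix") && missing(y)) y <- X$group
  X <- .as_sample_matrix(X)
  y <- as.factor(y)
  if (k_folds < 2) stop("k_folds must be at least 2")
  set.seed(seed)
  fold <- .stratified_folds(y, k_folds)
  y_num <- ifelse(y == levels(y)[2], 1, -1)
  yc <- y_num - mean(y_num)
  press <- 0
  for (k in seq_len(k_folds)) {
    tr <- fold != k
    if (nlevels(droplevels(y[tr])) < 2)
      stop("fold ", k, " leaves a single-class training set")
    fit <- fit_plsda(X[tr, , drop = FALSE], y[tr],
                     n_components = min(n_components, sum(tr) - 1L),
                     standardize = standardize)
    pred <- predict(fit, X[!tr, , drop = FALSE]) + fit$y_mean - mean(y_num)
    press <- press + sum((yc[!tr] - pred)^2)
  }
  1 - press / sum(yc^2)
}

# AUROC of scores for a binary response via the rank (Mann-Whitney) identity
.auroc <- function(scores, y_case) {
  n1 <- sum(y_case); n0 <- sum(!y_case)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated double cross-validated random-forest feature selection
#'
#' Nested resampling in the style of rdCV: within each repetition the
#' samples are split into `n_outer` stratified folds; each fold in turn is
#' held out entirely while recursive feature elimination runs on the
#' remaining training set. At every elimination step one random forest is
#' fitted on the training set; its out-of-bag misclassification provides the
#' inner validation signal and its permutation importance ranks the
#' features, of which the lowest `1 - var_ratio` fraction is dropped.
#' Held-out fold predictions are recorded per step and used, exclusively,
#' for the reported AUROCs, so feature selection never sees them.
#'
#' The validation curve (mean out-of-bag misclassification versus feature
#' count) determines three models: `min` (fewest features within `tol` of
#' the curve minimum), `max` (most features within `tol`) and `mid` (rounded
#' geometric mean of the two counts). Final feature sets are the top-ranked
#' features by average elimination order, hence nested min within mid within
#' max.
#'
#' @inheritParams fit_plsda
#' @param params List of `n_rep` (repetitions, default 5), `n_outer` (outer
#'   folds, default 6), `var_ratio` (fraction kept per elimination step,
#'   default 0.75), `tol` (relative tolerance on the curve minimum, default
#'   0.05) and `num_trees` (default 150).
#' @param seed Integer seed.
#' @return An object of class `rdcv_rf` with fields `min_set`, `mid_set`,
#'   `max_set`, `auroc` (named vector, outer-fold predictions only),
#'   `validation_curve` (data.frame: n_features, misclass), `rank`
#'   (average elimination rank, higher = retained longer) and `params`.
#' @export
rdcv_rf_select <- function(X, y, params = list(), seed = 1) {
  if (inherits(X, "abundance_matrix") && missing(y)) y <- X$group
  X <- .as_sample_matrix(X)
  y <- as.factor(y)
  if (nlevels(y) != 2L) stop("y must have exactly two classes")
  pr <- utils::modifyList(list(n_rep = 5L, n_outer = 6L, var_ratio = 0.75,
                               tol = 0.05, num_trees = 150L), params)
  if (min(table(y)) < pr$n_outer)
    stop("each class needs at least n_outer samples")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  p <- ncol(X)

  # elimination schedule, shared by every fold
  counts <- p
  while (counts[length(counts)] > 2) {
    nxt <- max(2L, min(counts[length(counts)] - 1L,
                       round(counts[length(counts)] * pr$var_ratio)))
    counts <- c(counts, nxt)
  }
  n_steps <- length(counts)

  err <- matrix(NA_real_, pr$n_rep * pr$n_outer, n_steps)
  elim <- matrix(NA_real_, pr$n_rep * pr$n_outer, p,
                 dimnames = list(NULL, colnames(X)))
  # outer-fold predicted case probabilities per step
  outer_pred <- array(NA_real_, c(nrow(X), n_steps, pr$n_rep))
  case_level <- levels(y)[2]

  row <- 0L
  for (r in seq_len(pr$n_rep)) {
    set.seed(seed + r)
    fold <- .stratified_folds(y, pr$n_outer)
    for (k in seq_len(pr$n_outer)) {
      row <- row + 1L
      tr <- fold != k
      if (nlevels(droplevels(y[tr])) < 2 || nlevels(droplevels(y[!tr])) < 2)
        stop("degenerate outer fold (single class)")
      feats <- colnames(X)
      for (s in seq_len(n_steps)) {
        fit <- ranger::ranger(
          x = X[tr, feats, drop = FALSE], y = y[tr],
          num.trees = pr$num_trees, importance = "permutation",
          probability = TRUE, seed = seed + 1000L * r + k,
          num.threads = 1
        )
        oob <- fit$predictions[, case_level]
        err[row, s] <- mean((oob > 0.5) != (y[tr] == case_level))
        pred <- stats::predict(fit, X[!tr, feats, drop = FALSE],
                               num.threads = 1)$predictions[, case_level]
        outer_pred[which(!tr), s, r] <- pred
        imp <- fit$variable.importance
        if (s < n_steps) {
          keep_n <- counts[s + 1L]
          dropped <- names(sort(imp))[seq_len(length(feats) - keep_n)]
          elim[row, dropped] <- s
          feats <- setdiff(feats, dropped)
        } else {
          elim[row, feats] <- n_steps + imp / (max(abs(imp)) + 1e-12)
        }
      }
    }
  }

  curve <- colMeans(err)
  cmin <- min(curve)
  ok <- which(curve <= cmin * (1 + pr$tol) + 1e-12)
  n_min <- min(counts[ok]); n_max <- max(counts[ok])
  n_mid <- round(sqrt(n_min * n_max))

  avg_rank <- colMeans(elim)
  ord <- order(-avg_rank, colnames(X))
  ranked <- colnames(X)[ord]
  pick <- function(n) sort(ranked[seq_len(min(n, p))])

  step_for <- function(n) which.min(abs(counts - n))
  auroc_at <- function(n) {
    s <- step_for(n)
    mean(vapply(seq_len(pr$n_rep), function(r) {
      .auroc(outer_pred[, s, r], y == case_level)
    }, numeric(1)))
  }

  structure(list(min_set = pick(n_min), mid_set = pick(n_mid),
                 max_set = pick(n_max),
                 n_features = c(min = n_min, mid = n_mid, max = n_max),
                 auroc = c(min = auroc_at(n_min), mid = auroc_at(n_mid),
                           max = auroc_at(n_max)),
                 validation_curve = data.frame(n_features = counts,
                                               misclass = curve),
                 rank = avg_rank, params = pr, seed = seed),
            class = "rdcv_rf")
}

#' @export
print.rdcv_rf <- function(x, ...) {
  cat(sprintf("<rdcv_rf> min/mid/max = %d/%d/%d features; outer AUROC = %.3f/%.3f/%.3f\n",
              x$n_features["min"], x$n_features["mid"], x$n_features["max"],
              x$auroc["min"], x$auroc["mid"], x$auroc["max"]))
  invisible(x)
}

#' Four-method consensus feature selection
#'
#' Intersects the per-method selected sets and reports UpSet-style exclusive
#' intersection cardinalities (one count per non-empty method combination).
#'
#' @param sets Named list (>= 2 entries) of character vectors of selected
#'   feature ids, e.g. Mann-Whitney q < 0.001, moderated q < 0.001, VIP > 1,
#'   and the rdCV-RF `max` set.
#' @param universe Character vector of testable feature ids; every selected
#'   set must be contained in it.
#' @return An object of class `consensus_set`: list with `sets`,
#'   `intersection` (sorted) and `upset` (data.frame: combination, degree,
#'   count).
#' @export
consensus_features <- function(sets, universe) {
  if (length(sets) < 2L) stop("need at least 2 method sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named by method")
  for (nm in names(sets)) {
    extra <- setdiff(sets[[nm]], universe)
    if (length(extra) > 0)
      stop("method '", nm, "' selects features outside the universe: ",
           paste(utils::head(extra, 5), collapse = ", "))
  }
  inter <- Reduce(intersect, sets)
  members <- unique(unlist(sets))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  names(combos) <- names(sets)
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  upset <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    inc <- unlist(combos[i, ])
    pattern <- vapply(members, function(f) {
      all(vapply(names(sets), function(nm) {
        (f %in% sets[[nm]]) == inc[[nm]]
      }, logical(1)))
    }, logical(1))
    data.frame(combination = paste(names(sets)[inc], collapse = "&"),
               degree = sum(inc), count = sum(pattern),
               stringsAsFactors = FALSE)
  }))
  structure(list(sets = sets, intersection = sort(inter), upset = upset),
            class = "consensus_set")
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf("<consensus_set> %d methods; intersection of %d features\n",
              length(x$sets), length(x$intersection)))
  if (length(x$intersection) > 0)
    cat(" ", paste(utils::head(x$intersection, 15), collapse = ", "),
        if (length(x$intersection) > 15) "..." else "", "\n")
  invisible(x)
}
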