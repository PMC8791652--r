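#' Construct an abundance matrix
#'
#' The common container for lipid and metabolite concentration data:
#' a features x samples numeric matrix with unique feature ids (rownames),
#' sample ids (colnames), a binary per-sample group factor and a scale tag
#' recording where the matrix sits in the preprocessing chain.
#'
#' @param values Numeric matrix, features in rows, samples in columns;
#'   rownames and colnames required.
#' @param group Factor (or coercible) of length `ncol(values)` with exactly
#'   two levels; the second level is the case group (MetS).
#' @param scale One of `"raw"`, `"median_centered"`, `"log"`.
#' @return An object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, group,
                             scale = c("raw", "median_centered", "log")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("values must have unique rownames (feature ids)")
  if (is.null(colnames(values)))
    stop("values must have colnames (sample ids)")
  group <- as.factor(group)
  if (length(group) != ncol(values))
    stop("group must have one label per sample")
  if (nlevels(group) != 2L)
    stop("group must have exactly two levels")
  structure(list(values = values, group = group, scale = scale),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix> %d features x %d samples, scale=%s\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat("  groups:", paste(sprintf("%s=%d", levels(x$group),
                                 tabulate(x$group)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' Minimum-impute and median-center an abundance matrix
#'
#' Per feature, missing entries (NA, and zeros when `zeros_as_missing`) are
#' replaced by that feature's minimum observed positive value; the feature is
#' then divided by its median, so every feature's median becomes 1.
#'
#' @param m An [abundance_matrix()] on the raw scale.
#' @param zeros_as_missing Treat zeros as below-LOD missing values (default
#'   TRUE).
#' @return The imputed, median-centered `abundance_matrix`
#'   (`scale = "median_centered"`).
#' @export
impute_and_center <- function(m, zeros_as_missing = TRUE) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (m$scale != "raw") stop("impute_and_center expects a raw-scale matrix")
  v <- m$values
  for (i in seq_len(nrow(v))) {
    x <- v[i, ]
    miss <- is.na(x) | (zeros_as_missing & x == 0)
    obs <- x[!miss & x > 0]
    if (length(obs) == 0L)
      stop("feature '", rownames(v)[i], "' has no observed positive value")
    x[miss] <- min(obs)
    med <- stats::median(x)
    if (med <= 0)
      stop("feature '", rownames(v)[i], "' has nonpositive median; ",
           "treat zeros as missing or clean the input")
    v[i, ] <- x / med
  }
  abundance_matrix(v, m$group, scale = "median_centered")
}

#' Remove zero and near-zero-variance features
#'
#' A feature is removed when its variance is exactly zero, or when both the
#' frequency ratio of its most common to second most common value is at least
#' `freq_ratio_cut` and its percentage of distinct values over samples is
#' below `unique_cut_pct` (the classical `freqRatio`/`uniqueCut` convention).
#'
#' @param m An [abundance_matrix()].
#' @param freq_ratio_cut Frequency-ratio cutoff (default 19, i.e. 95/5).
#' @param unique_cut_pct Percent-unique cutoff (default 10).
#' @return A list with `matrix` (the filtered `abundance_matrix`) and
#'   `removed` (sorted character vector of removed feature ids).
#' @export
filter_near_zero_variance <- function(m, freq_ratio_cut = 19,
                                      unique_cut_pct = 10) {
  stopifnot(inherits(m, "abundance_matrix"))
  v <- m$values
  if (nrow(v) == 0L) stop("matrix has no features")
  n <- ncol(v)
  drop <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    x <- v[i, !is.na(v[i, ])]
    tab <- sort(table(x), decreasing = TRUE)
    if (length(tab) == 1L) { drop[i] <- TRUE; next }   # zero variance
    freq_ratio <- tab[1] / tab[2]
    pct_unique <- 100 * length(tab) / n
    drop[i] <- freq_ratio >= freq_ratio_cut && pct_unique < unique_cut_pct
  }
  removed <- sort(rownames(v)[drop])
  kept <- abundance_matrix(v[!drop, , drop = FALSE], m$group, scale = m$scale)
  list(matrix = kept, removed = removed)
}

#' Natural-log transform an abundance matrix
#'
#' @param m An [abundance_matrix()] with all entries strictly positive
#'   (i.e. post-imputation).
#' @return The log-scale `abundance_matrix`.
#' @export
log_transform <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  bad <- which(!(m$values > 0), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("nonpositive entry at feature '", rownames(m$values)[bad[1, 1]],
         "', sample '", colnames(m$values)[bad[1, 2]],
         "'; impute before log-transforming")
  }
  abundance_matrix(log(m$values), m$group, scale = "log")
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS test of each feature against a normal distribution with that
#' feature's estimated mean and standard deviation. Because the parameters
#' are estimated from the same data, the p-values are conservative
#' (Lilliefors caveat); they are intended as a screening summary, never as a
#' gate.
#'
#' @param m An [abundance_matrix()] with at least 8 samples.
#' @param alpha Rejection level for the summary fraction (default 0.05).
#' @return A list with `table` (data.frame: feature, D, p, tested) and
#'   `rejection_fraction` (share of tested features with p < alpha).
#' @export
ks_normality <- function(m, alpha = 0.05) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (ncol(m$values) < 8L) stop("ks_normality needs at least 8 samples")
  res <- lapply(seq_len(nrow(m$values)), function(i) {
    x <- m$values[i, ]
    x <- x[!is.na(x)]
    if (stats::sd(x) == 0) {
      return(data.frame(feature = rownames(m$values)[i], D = NA_real_,
                        p = NA_real_, tested = FALSE))
    }
    kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
    data.frame(feature = rownames(m$values)[i], D = unname(kt$statistic),
               p = kt$p.value, tested = TRUE)
  })
  tab <- do.call(rbind, res)
  rownames(tab) <- NULL
  frac <- mean(tab$p[tab$tested] < alpha)
  list(table = tab, rejection_fraction = frac)
}

#' Read an abundance matrix from CSV/TSV
#'
#' Features in rows, samples in columns, first column the feature id.
#'
#' @param path File path; delimiter inferred from the extension (`.tsv`
#'   tab, otherwise comma).
#' @param group Per-sample group labels (length = number of sample columns).
#' @param scale Scale tag, see [abundance_matrix()].
#' @return An [abundance_matrix()].
#' @export
read_abundance <- function(path, group, scale = "raw") {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  storage.mode(v) <- "double"
  abundance_matrix(v, group, scale = scale)
}

#' Write an abundance matrix to CSV/TSV
#'
#' @param m An [abundance_matrix()].
#' @param path Output path; delimiter inferred from the extension.
#' @export
write_abundance <- function(m, path) {
  stopifnot(inherits(m, "abundance_matrix"))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- data.frame(feature_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
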