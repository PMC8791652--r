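#' Pearson chi-square test on a 2 x k contingency table
#'
#' Yates continuity correction is applied iff the table is 2 x 2;
#' df = k - 1. Tables with a zero margin are rejected with a pointer to
#' [fisher_exact()].
#'
#' @param counts 2 x k matrix of nonnegative integers.
#' @return List with `statistic`, `df`, `p`.
#' @export
#' @examples
#' chi_square_test(matrix(c(14, 86, 13, 87), 2, 2, byrow = TRUE))
chi_square_test <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2L || ncol(counts) < 2L)
    stop("counts must be a 2 x k table with k >= 2")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin: use fisher_exact() for sparse tables")
  ct <- suppressWarnings(stats::chisq.test(counts,
                                           correct = ncol(counts) == 2L))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Two-sided Fisher exact test on a 2 x 2 table
#'
#' Sums the hypergeometric probabilities of all tables no more probable
#' than the observed one (the standard two-sided convention of
#' [stats::fisher.test()]).
#'
#' @param counts 2 x 2 matrix of nonnegative integers.
#' @return Two-sided p-value.
#' @export
#' @examples
#' fisher_exact(matrix(c(5, 0, 0, 5), 2, 2))  # 2/252
fisher_exact <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L)))
    stop("counts must be a 2 x 2 table")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  stats::fisher.test(counts)$p.value
}

# format p-values the way clinical tables print them
.format_p <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "<0.001", sprintf("%.2f", p)))
}

#' Group comparison table of clinical characteristics
#'
#' Continuous variables are compared by the Mann-Whitney U test with
#' mean (sd) descriptives per group; categorical variables by the chi-square
#' test (Yates-corrected on 2 x 2) with n (%) descriptives, falling back to
#' Fisher's exact test for 2 x 2 tables with any expected cell below 1 or
#' any empty observed cell. Constant variables are reported without a
#' p-value.
#'
#' @param clinical Data.frame with a binary `group` column; an optional
#'   `sample_id` column is ignored. Numeric columns with more than two
#'   distinct values are treated as continuous, everything else as
#'   categorical.
#' @return An object of class `cohort_comparison`: data.frame with columns
#'   `variable`, `type`, `test`, `statistic`, `p`, `p_formatted`, and one
#'   descriptive column per group.
#' @export
cohort_table <- function(clinical) {
  stopifnot(is.data.frame(clinical), "group" %in% names(clinical))
  grp <- as.factor(clinical$group)
  if (nlevels(grp) != 2L) stop("group must be binary")
  if (min(table(grp)) < 2L) stop("need at least 2 samples per group")
  vars <- setdiff(names(clinical), c("group", "sample_id"))
  g1 <- levels(grp)[1]; g2 <- levels(grp)[2]

  rows <- lapply(vars, function(v) {
    x <- clinical[[v]]
    continuous <- is.numeric(x) && length(unique(x[!is.na(x)])) > 2
    if (continuous) {
      mt <- mann_whitney_test(x[grp == g2], x[grp == g1])
      desc <- vapply(c(g1, g2), function(g) {
        sprintf("%.1f (%.1f)", mean(x[grp == g], na.rm = TRUE),
                stats::sd(x[grp == g], na.rm = TRUE))
      }, character(1))
      data.frame(variable = v, type = "continuous", test = "mann-whitney",
                 statistic = mt$U, p = mt$p,
                 group1 = desc[1], group2 = desc[2],
                 stringsAsFactors = FALSE)
    } else {
      xf <- as.factor(x)
      tab <- t(table(xf, grp))            # groups in rows, 2 x k
      desc <- vapply(c(g1, g2), function(g) {
        paste(sprintf("%s %d (%.1f%%)", colnames(tab), tab[g, ],
                      100 * tab[g, ] / sum(tab[g, ])), collapse = "; ")
      }, character(1))
      if (nlevels(xf) < 2L) {
        return(data.frame(variable = v, type = "categorical",
                          test = "none", statistic = NA_real_, p = NA_real_,
                          group1 = desc[1], group2 = desc[2],
                          stringsAsFactors = FALSE))
      }
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      use_fisher <- ncol(tab) == 2L &&
        (any(expected < 1) || any(tab == 0))
      if (use_fisher) {
        data.frame(variable = v, type = "categorical", test = "fisher",
                   statistic = NA_real_, p = fisher_exact(tab),
                   group1 = desc[1], group2 = desc[2],
                   stringsAsFactors = FALSE)
      } else {
        ct <- chi_square_test(tab)
        data.frame(variable = v, type = "categorical", test = "chi-square",
                   statistic = ct$statistic, p = ct$p,
                   group1 = desc[1], group2 = desc[2],
                   stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, rows)
  out$p_formatted <- .format_p(out$p)
  names(out)[names(out) == "group1"] <- g1
  names(out)[names(out) == "group2"] <- g2
  rownames(out) <- NULL
  class(out) <- c("cohort_comparison", "data.frame")
  out
}

#' @export
print.cohort_comparison <- function(x, ...) {
  df <- as.data.frame(x)
  df$p <- NULL
  df$statistic <- NULL
  print(df, right = FALSE)
  invisible(x)
}
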