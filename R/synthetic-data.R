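#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study conditions the pipeline was designed for:
#' two groups of 100 plasma samples, a 917-species lipid panel composed of
#' 602 glycerolipids, 228 glycerophospholipids, 61 sphingolipids and 26
#' steroids, 11 key metabolites, and an up-shift of a small set of DAG/TAG
#' species in the case (MetS) group. Generation is a pure function of the
#' configuration, including its `seed`.
#'
#' @param n_per_group Samples per group (default 100).
#' @param category_counts Named integer vector of lipid counts per category.
#' @param n_metabolites Number of metabolites (default 11, the key-metabolite
#'   panel).
#' @param effect_fraction Fraction of DAG/TAG species planted with a group
#'   effect (default 0.0224, i.e. 13 species under the default panel).
#' @param effect_log2fc Planted log2 fold change, case over control
#'   (default 1).
#' @param noise_sd Residual standard deviation on the natural-log scale
#'   (default 0.5).
#' @param block_correlation Within-block pairwise correlation of the latent
#'   Gaussian copula (default 0.5).
#' @param missing_rate Expected fraction of below-LOD zeros per feature
#'   (default 0.02); zeros replace the smallest draws (MNAR at the low end).
#' @param seed Integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 100,
                          category_counts = c(glycerolipid = 602,
                                              glycerophospholipid = 228,
                                              sphingolipid = 61,
                                              steroid = 26),
                          n_metabolites = 11,
                          effect_fraction = 0.0224,
                          effect_log2fc = 1.0,
                          noise_sd = 0.5,
                          block_correlation = 0.5,
                          missing_rate = 0.02,
                          seed = 1L) {
  stopifnot(n_per_group >= 2, all(category_counts >= 0),
            n_metabolites >= 0,
            effect_fraction >= 0, effect_fraction <= 1,
            missing_rate >= 0, missing_rate <= 1,
            block_correlation >= 0, block_correlation < 1,
            noise_sd > 0)
  structure(list(n_per_group = as.integer(n_per_group),
                 category_counts = category_counts,
                 n_metabolites = as.integer(n_metabolites),
                 effect_fraction = effect_fraction,
                 effect_log2fc = effect_log2fc,
                 noise_sd = noise_sd,
                 block_correlation = block_correlation,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# apportion n among shares by largest remainder
.apportion <- function(n, shares) {
  raw <- n * shares / sum(shares)
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    idx <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[idx] <- k[idx] + 1
  }
  as.integer(k)
}

# candidate name pools per class, all parseable by parse_lipid_name()
.name_pool <- function(class) {
  fa <- c("14:0", "16:0", "16:1", "18:0", "18:1", "18:2", "18:3",
          "20:2", "20:3", "20:4", "22:5", "22:6")
  fa_c <- as.integer(sub(":.*", "", fa))
  fa_d <- as.integer(sub(".*:", "", fa))
  switch(class,
    TAG = {
      g <- expand.grid(c = 40:60, d = 0:8, i = seq_along(fa))
      g <- g[fa_c[g$i] <= g$c - 24 & fa_d[g$i] <= g$d, ]
      sprintf("TAG(%d:%d)-FA(%s)", g$c, g$d, fa[g$i])
    },
    DAG = {
      g <- expand.grid(i = seq_along(fa), j = seq_along(fa))
      g <- g[g$i <= g$j, ]
      sprintf("DAG(%s/%s)", fa[g$i], fa[g$j])
    },
    MAG = sprintf("MAG(%d:%d)", rep(14:24, each = 7), rep(0:6, 11)),
    PC = sprintf("PC(%d:%d)", rep(28:44, each = 9), rep(0:8, 17)),
    PE = sprintf("PE(%d:%d)", rep(28:44, each = 9), rep(0:8, 17)),
    PI = sprintf("PI(%d:%d)", rep(30:40, each = 7), rep(0:6, 11)),
    LPC = sprintf("LPC(%d:%d)", rep(14:22, each = 5), rep(0:4, 9)),
    LPE = sprintf("LPE(%d:%d)", rep(14:22, each = 5), rep(0:4, 9)),
    SM = sprintf("SM(d18:1/%d:%d)", rep(14:26, each = 4), rep(0:3, 13)),
    CER = sprintf("CER(d18:1/%d:%d)", rep(14:26, each = 3), rep(0:2, 13)),
    DCER = sprintf("DCER(d18:0/%d:%d)", rep(14:26, each = 2), rep(0:1, 13)),
    HCER = sprintf("HCER(d18:1/%d:%d)", rep(14:26, each = 2), rep(0:1, 13)),
    LCER = sprintf("LCER(d18:1/%d:%d)", rep(14:26, each = 2), rep(0:1, 13)),
    CE = sprintf("CE(%d:%d)", rep(14:22, each = 7), rep(0:6, 9)),
    stop("no name pool for class ", class)
  )
}

# class inventory within each category (shares chosen once; TAG dominates
# the glycerolipids as in typical complex-lipid panels)
.category_classes <- list(
  glycerolipid = c(TAG = 0.85, DAG = 0.11, MAG = 0.04),
  glycerophospholipid = c(PC = 0.38, PE = 0.30, PI = 0.16,
                          LPC = 0.09, LPE = 0.07),
  sphingolipid = c(SM = 0.38, CER = 0.28, DCER = 0.12,
                   HCER = 0.12, LCER = 0.10),
  steroid = c(CE = 1)
)

#' Generate a synthetic lipid name list
#'
#' Draws unique, parseable shorthand names matching the configured category
#' composition. Deterministic given the configuration (seed included).
#'
#' @param config A [cohort_config()].
#' @return Character vector of `sum(category_counts)` unique lipid names.
#' @export
generate_lipid_names <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  out <- character(0)
  for (cat in names(config$category_counts)) {
    n_cat <- config$category_counts[[cat]]
    if (n_cat == 0) next
    shares <- .category_classes[[cat]]
    if (is.null(shares)) stop("unknown lipid category '", cat, "'")
    counts <- .apportion(n_cat, shares)
    names(counts) <- names(shares)
    for (cls in names(counts)) {
      if (counts[[cls]] == 0) next
      pool <- .name_pool(cls)
      if (length(pool) < counts[[cls]])
        stop("name pool for class ", cls, " too small (",
             length(pool), " < ", counts[[cls]], ")")
      out <- c(out, sample(pool, counts[[cls]]))
    }
  }
  out
}

.key_metabolites <- c("1-carboxyethylisoleucine", "4-cholesten-3-one",
                      "4-hydroxyglutamate", "alpha-ketoglutarate",
                      "carotene diol (2)", "gamma-glutamylglutamate",
                      "glutamate", "glycerate", "isoleucine",
                      "PC/3-MAPC", "PSP")

# glutamate-pathway-like sub-block that co-varies with the planted lipids
.glutamate_block <- c("glutamate", "4-hydroxyglutamate",
                      "alpha-ketoglutarate", "gamma-glutamylglutamate",
                      "isoleucine", "1-carboxyethylisoleucine")

# lognormal draws matched to a target mean/sd on the original scale
.rlnorm_matched <- function(n, mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic case-control cohort
#'
#' Produces a lipid abundance matrix, a metabolite matrix, a clinical table
#' and the set of planted differential features (`truth`). Concentrations are
#' multiplicative log-normal; a configurable fraction of DAG/TAG species
#' receives an additive case-group shift of `effect_log2fc * log(2)` on the
#' natural-log scale. Correlation structure is a block-diagonal Gaussian
#' copula on the log scale: the planted lipids share a latent factor with a
#' glutamate-pathway-like metabolite sub-block, and two background blocks
#' (non-planted glycerolipids; glycerophospholipids) provide additional
#' network communities. The clinical table follows the marginal composition
#' of the target cohort (sex 90% male, visceral adipose tissue shifted
#' upwards in the case group, early-generation ART more frequent in cases).
#'
#' @param config A [cohort_config()].
#' @return An object of class `synthetic_cohort`: list with `lipids`,
#'   `metabolites` (both [abundance_matrix()], raw scale), `clinical`
#'   (data.frame, 13 variables), `truth` (character), `lipid_meta`
#'   (parsed feature metadata) and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  lipid_names <- generate_lipid_names(config)
  meta <- parse_lipid_names(lipid_names)
  set.seed(config$seed + 1L)

  n <- 2L * config$n_per_group
  group <- factor(rep(c("noMetS", "MetS"), each = config$n_per_group),
                  levels = c("noMetS", "MetS"))
  sample_ids <- sprintf("S%03d", seq_len(n))
  p <- length(lipid_names)

  dagtag <- meta$name[meta$class %in% c("TAG", "DAG")]
  n_eff <- round(config$effect_fraction * length(dagtag))
  if (config$effect_fraction > 0 && length(dagtag) == 0)
    stop("effect_fraction > 0 but the panel contains no DAG/TAG species")
  truth <- if (n_eff > 0) sort(sample(dagtag, n_eff)) else character(0)

  met_names <- if (config$n_metabolites <= length(.key_metabolites)) {
    .key_metabolites[seq_len(config$n_metabolites)]
  } else {
    c(.key_metabolites,
      sprintf("metabolite_%02d",
              seq_len(config$n_metabolites - length(.key_metabolites))))
  }

  # block memberships over lipids + metabolites
  all_names <- c(lipid_names, met_names)
  block <- integer(length(all_names))          # 0 = independent
  names(block) <- all_names
  block[truth] <- 1L
  block[intersect(.glutamate_block, met_names)] <- 1L
  bg_pool <- setdiff(dagtag, truth)
  if (length(bg_pool) > 0)
    block[sample(bg_pool, min(60L, length(bg_pool)))] <- 2L
  gpl <- meta$name[meta$category == "glycerophospholipid"]
  if (length(gpl) > 0)
    block[sample(gpl, min(40L, length(gpl)))] <- 3L

  rho <- config$block_correlation
  factors <- matrix(stats::rnorm(3L * n), nrow = 3L)
  mu <- stats::rnorm(length(all_names), 0, 0.75)
  logx <- matrix(NA_real_, length(all_names), n,
                 dimnames = list(all_names, sample_ids))
  for (i in seq_along(all_names)) {
    eps <- stats::rnorm(n)
    z <- if (block[i] > 0) {
      sqrt(rho) * factors[block[i], ] + sqrt(1 - rho) * eps
    } else eps
    logx[i, ] <- mu[i] + config$noise_sd * z
  }
  shift <- config$effect_log2fc * log(2)
  if (length(truth) > 0)
    logx[truth, group == "MetS"] <- logx[truth, group == "MetS"] + shift
  met_shifted <- intersect(.glutamate_block, met_names)
  if (length(met_shifted) > 0)
    logx[met_shifted, group == "MetS"] <-
      logx[met_shifted, group == "MetS"] + shift / 2

  conc <- exp(logx)
  # MNAR missingness: the smallest draws per feature fall below LOD
  if (config$missing_rate > 0) {
    for (i in seq_len(nrow(conc))) {
      k <- stats::rbinom(1, n, config$missing_rate)
      if (k > 0 && k < n)
        conc[i, order(conc[i, ])[seq_len(k)]] <- 0
    }
  }

  lipids <- abundance_matrix(conc[lipid_names, , drop = FALSE], group, "raw")
  mets <- abundance_matrix(conc[met_names, , drop = FALSE], group, "raw")

  clinical <- .generate_clinical(group, sample_ids)

  structure(list(lipids = lipids, metabolites = mets, clinical = clinical,
                 truth = truth, lipid_meta = meta, config = config),
            class = "synthetic_cohort")
}

# Table-1-like marginals: matched sex/age, VAT/SAT shifted upwards in MetS,
# early-generation ART more frequent in MetS
.generate_clinical <- function(group, sample_ids) {
  mets <- group == "MetS"
  n <- length(group)
  rb <- function(p0, p1) stats::rbinom(n, 1, ifelse(mets, p1, p0))
  data.frame(
    sample_id = sample_ids,
    group = group,
    sex = factor(ifelse(stats::rbinom(n, 1, 0.9) == 1, "male", "female")),
    age = stats::rnorm(n, ifelse(mets, 54.6, 54.4), ifelse(mets, 8.5, 9.5)),
    ethnicity = factor(sample(c("caucasian", "asian", "black", "other"), n,
                              replace = TRUE,
                              prob = c(0.87, 0.025, 0.05, 0.055))),
    immunodeficiency = rb(0.14, 0.13),
    early_art = rb(0.34, 0.46),
    vat = ifelse(mets, .rlnorm_matched(n, 149.4, 71.0),
                 .rlnorm_matched(n, 76.1, 53.6)),
    sat = ifelse(mets, .rlnorm_matched(n, 150.6, 77.1),
                 .rlnorm_matched(n, 111.1, 71.1)),
    art_nrti = rb(0.95, 0.96),
    art_nnrti = rb(0.54, 0.45),
    art_pi = rb(0.37, 0.47),
    art_insti = rb(0.16, 0.21),
    art_other = rb(0.00, 0.03),
    stringsAsFactors = FALSE
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d lipids + %d metabolites x %d samples; %d planted effects\n",
              nrow(x$lipids$values), nrow(x$metabolites$values),
              ncol(x$lipids$values), length(x$truth)))
  invisible(x)
}

#' Write synthetic cohort inputs to disk
#'
#' Writes `lipids.csv`, `metabolites.csv`, `clinical.csv` and `truth.json`
#' into `dir`, the file set consumed by [run_pipeline()].
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_abundance(cohort$lipids, file.path(dir, "lipids.csv"))
  write_abundance(cohort$metabolites, file.path(dir, "metabolites.csv"))
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
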