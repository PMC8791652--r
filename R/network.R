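#' Build a weighted positive-Spearman biomolecular network
#'
#' Computes all pairwise Spearman rank correlations (midranks, so ties are
#' handled) across samples, derives two-sided p-values from the
#' t approximation, adjusts them BH across all pairs, and keeps the edges
#' with `q <= fdr_cut` and `rho >= rho_cut`. Only positive correlations
#' become edges; the edge weight is rho.
#'
#' @param combined An [abundance_matrix()] holding lipids and metabolites
#'   together (>= 10 samples). Constant features are excluded with a warning.
#' @param node_type Optional named character vector (`"lipid"` /
#'   `"metabolite"`) attached to the vertices.
#' @param fdr_cut BH threshold on edge q-values (default 1e-07).
#' @param rho_cut Minimum Spearman rho (default 0.38).
#' @return An object of class `biomolecular_network`: list with `graph`
#'   (an igraph with `weight` edge attribute), `thresholds` and `edges`
#'   (data.frame: source, target, rho, p, q).
#' @export
spearman_network <- function(combined, node_type = NULL,
                             fdr_cut = 1e-07, rho_cut = 0.38) {
  stopifnot(inherits(combined, "abundance_matrix"))
  v <- combined$values
  n <- ncol(v)
  if (n < 10) stop("need at least 10 samples")
  const <- apply(v, 1, function(x) stats::sd(x, na.rm = TRUE) == 0)
  if (any(const)) {
    warning(sum(const), " constant feature(s) excluded from the network")
    v <- v[!const, , drop = FALSE]
  }
  rk <- t(apply(v, 1, rank))
  rho <- stats::cor(t(rk))
  pr <- upper.tri(rho)
  r <- rho[pr]
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  q <- bh_adjust(p)
  idx <- which(pr, arr.ind = TRUE)
  keep <- q <= fdr_cut & r >= rho_cut
  edges <- data.frame(source = rownames(v)[idx[keep, 1]],
                      target = rownames(v)[idx[keep, 2]],
                      rho = r[keep], p = p[keep], q = q[keep],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target")], directed = FALSE,
    vertices = data.frame(name = rownames(v), stringsAsFactors = FALSE))
  igraph::E(g)$weight <- edges$rho
  if (!is.null(node_type))
    igraph::V(g)$type <- unname(node_type[igraph::V(g)$name])
  structure(list(graph = g,
                 thresholds = c(fdr_cut = fdr_cut, rho_cut = rho_cut),
                 edges = edges),
            class = "biomolecular_network")
}

#' @export
print.biomolecular_network <- function(x, ...) {
  cat(sprintf("<biomolecular_network> %d nodes, %d edges (q <= %g, rho >= %g)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$thresholds["fdr_cut"], x$thresholds["rho_cut"]))
  invisible(x)
}

# topological summaries used for the null comparison
.graph_metrics <- function(g) {
  comp <- igraph::components(g)
  big <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  c(degree_variance = stats::var(igraph::degree(g)),
    clustering = igraph::transitivity(g, type = "global"),
    mean_path = igraph::mean_distance(big, directed = FALSE, weights = NA))
}

#' Compare a network against the Erdos-Renyi G(n, m) null
#'
#' Draws random graphs with the same node and edge counts and contrasts the
#' observed degree variance, global clustering coefficient, mean shortest
#' path (largest component) and degree distribution against the null
#' ensemble. A metric is flagged when the observed value falls outside the
#' null 99% envelope (0.5% and 99.5% quantiles).
#'
#' @param net A [spearman_network()] result (>= 1 edge).
#' @param n_draws Number of null draws (default 200).
#' @param seed Integer seed.
#' @return An object of class `er_null_comparison`: data.frame with one row
#'   per metric (`observed`, `null_mean`, `null_sd`, `lower`, `upper`,
#'   `outside_envelope`) plus a `degree_ks` attribute (KS statistic between
#'   observed and pooled null degree distributions) and
#'   `markedly_distinct` attribute (any metric outside its envelope).
#' @export
er_null_compare <- function(net, n_draws = 200, seed = 1) {
  stopifnot(inherits(net, "biomolecular_network"))
  g <- net$graph
  m <- igraph::ecount(g)
  n <- igraph::vcount(g)
  if (m < 1) stop("network has no edges")
  set.seed(seed)
  null_metrics <- matrix(NA_real_, n_draws, 3)
  null_degrees <- vector("list", n_draws)
  null_ecount <- integer(n_draws)
  for (i in seq_len(n_draws)) {
    gn <- igraph::sample_gnm(n, m)
    null_metrics[i, ] <- .graph_metrics(gn)
    null_degrees[[i]] <- igraph::degree(gn)
    null_ecount[i] <- igraph::ecount(gn)
  }
  obs <- .graph_metrics(g)
  colnames(null_metrics) <- names(obs)
  tab <- data.frame(
    metric = names(obs), observed = unname(obs),
    null_mean = colMeans(null_metrics, na.rm = TRUE),
    null_sd = apply(null_metrics, 2, stats::sd, na.rm = TRUE),
    lower = apply(null_metrics, 2, stats::quantile, 0.005, na.rm = TRUE),
    upper = apply(null_metrics, 2, stats::quantile, 0.995, na.rm = TRUE),
    stringsAsFactors = FALSE)
  tab$outside_envelope <- tab$observed < tab$lower | tab$observed > tab$upper
  rownames(tab) <- NULL
  ks <- suppressWarnings(
    stats::ks.test(igraph::degree(g), unlist(null_degrees))$statistic)
  structure(tab, class = c("er_null_comparison", "data.frame"),
            degree_ks = unname(ks),
            null_ecount = null_ecount,
            markedly_distinct = any(tab$outside_envelope, na.rm = TRUE))
}

#' Detect communities with the Leiden algorithm
#'
#' Weighted modularity-optimizing Leiden partition at the given resolution;
#' disconnected components are handled independently by the algorithm. The
#' seed is fixed and recorded so partitions are reproducible. Per community
#' the size, the average full-network degree of its members, and (when
#' species metadata are supplied) the mean total carbons and double bonds of
#' its glycerolipid members are attached.
#'
#' @param net A [spearman_network()] result with at least one node.
#' @param resolution Leiden resolution parameter (default 1).
#' @param seed Integer seed (default 1).
#' @param species Optional feature metadata from [parse_lipid_names()].
#' @return An object of class `community_partition`: list with `membership`
#'   (named integer vector), `summary` (per-community data.frame),
#'   `modularity`, `resolution` and `seed`.
#' @export
detect_communities <- function(net, resolution = 1, seed = 1,
                               species = NULL) {
  stopifnot(inherits(net, "biomolecular_network"))
  g <- net$graph
  if (igraph::vcount(g) == 0) stop("empty graph")
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution,
                               weights = igraph::E(g)$weight,
                               n_iterations = 10)
  membership <- igraph::membership(cl)
  names(membership) <- igraph::V(g)$name
  deg <- igraph::degree(g)
  summ <- do.call(rbind, lapply(sort(unique(membership)), function(cid) {
    mem <- names(membership)[membership == cid]
    row <- data.frame(community = cid, size = length(mem),
                      avg_degree = mean(deg[mem]),
                      mean_carbons_gl = NA_real_,
                      mean_double_bonds_gl = NA_real_,
                      stringsAsFactors = FALSE)
    if (!is.null(species)) {
      gl <- species[species$name %in% mem &
                      species$category == "glycerolipid", ]
      if (nrow(gl) > 0) {
        row$mean_carbons_gl <- mean(gl$total_carbons)
        row$mean_double_bonds_gl <- mean(gl$total_double_bonds)
      }
    }
    row
  }))
  summ <- summ[order(-summ$size), ]
  rownames(summ) <- NULL
  structure(list(membership = membership, summary = summ,
                 modularity = igraph::modularity(
                   g, membership, weights = igraph::E(g)$weight),
                 resolution = resolution, seed = seed),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities over %d nodes; modularity %.3f (resolution %g, seed %d)\n",
              nrow(x$summary), length(x$membership), x$modularity,
              x$resolution, x$seed))
  print(utils::head(x$summary, 5))
  invisible(x)
}

#' Rank network hubs by degree
#'
#' Nodes sorted by degree, breaking ties by weighted degree (strength) and
#' then lexicographic id; the top `ceil(top_fraction * n)` are returned.
#'
#' @param net A [spearman_network()] result.
#' @param top_fraction Fraction of nodes to return, in (0, 1] (default 0.1).
#' @return Data.frame with `node`, `degree`, `strength`, in rank order.
#' @export
centrality_rank <- function(net, top_fraction = 0.1) {
  stopifnot(inherits(net, "biomolecular_network"),
            top_fraction > 0, top_fraction <= 1)
  g <- net$graph
  deg <- igraph::degree(g)
  str <- igraph::strength(g)
  ord <- order(-deg, -str, igraph::V(g)$name)
  k <- ceiling(top_fraction * igraph::vcount(g))
  data.frame(node = igraph::V(g)$name[ord][seq_len(k)],
             degree = deg[ord][seq_len(k)],
             strength = str[ord][seq_len(k)],
             row.names = NULL, stringsAsFactors = FALSE)
}

# per-sample community scores: mean of z-scored member abundances (or PC1)
.community_scores <- function(partition, combined,
                              score_type = c("mean_z", "pc1")) {
  score_type <- match.arg(score_type)
  v <- combined$values
  sds <- apply(v, 1, stats::sd)
  z <- sweep(sweep(v, 1, rowMeans(v)), 1, ifelse(sds == 0, 1, sds), "/")
  ids <- sort(unique(partition$membership))
  scores <- vapply(ids, function(cid) {
    mem <- intersect(names(partition$membership)[partition$membership == cid],
                     rownames(z))
    if (length(mem) == 0) return(rep(NA_real_, ncol(z)))
    zm <- z[mem, , drop = FALSE]
    if (score_type == "mean_z" || length(mem) == 1) {
      colMeans(zm)
    } else {
      pc <- stats::prcomp(t(zm), center = FALSE, scale. = FALSE)
      s <- pc$x[, 1]
      # orient PC1 along the mean-z score for a stable sign
      if (stats::cor(s, colMeans(zm)) < 0) s <- -s
      s
    }
  }, numeric(ncol(v)))
  colnames(scores) <- paste0("c", ids)
  rownames(scores) <- colnames(v)
  scores
}

# one regression row: clinical variable on a single score/feature
.assoc_row <- function(y, x) {
  if (is.factor(y) || is.character(y)) y <- as.factor(y)
  if (is.factor(y) || length(unique(y[!is.na(y)])) == 2) {
    yf <- as.factor(y)
    if (nlevels(droplevels(yf)) < 2) return(NULL)
    fit <- suppressWarnings(
      stats::glm(yf ~ x, family = stats::binomial()))
    co <- summary(fit)$coefficients
    if (nrow(co) < 2) return(NULL)
    # likelihood-ratio p: unlike the Wald test it stays informative when
    # the score separates the classes (near-)perfectly
    p <- stats::pchisq(fit$null.deviance - fit$deviance, df = 1,
                       lower.tail = FALSE)
    list(model = "logistic", estimate = co[2, 1], p = p)
  } else {
    if (stats::sd(y, na.rm = TRUE) == 0) return(NULL)
    fit <- stats::lm(y ~ x)
    co <- summary(fit)$coefficients
    if (nrow(co) < 2) return(NULL)
    list(model = "linear", estimate = co[2, 1], p = co[2, 4])
  }
}

#' Associate network communities with clinical variables
#'
#' Each community is summarised per sample as the mean of its members'
#' z-scored abundances (or the sign-oriented first principal component).
#' Binary clinical variables are regressed on the score by logistic
#' regression, continuous ones by linear regression; p-values are BH
#' adjusted across all community x variable tests. Constant clinical
#' variables are skipped with a warning.
#'
#' @param partition A [detect_communities()] result.
#' @param combined The [abundance_matrix()] the network was built from.
#' @param clinical Data.frame of clinical variables, rows aligned with
#'   samples; an optional `sample_id` column is dropped.
#' @param score_type `"mean_z"` (default) or `"pc1"`.
#' @param min_size Smallest community to test (default 3).
#' @return A data.frame (`clinical_association` class) with columns `unit`,
#'   `variable`, `model`, `estimate`, `p`, `q`.
#' @export
community_clinical_assoc <- function(partition, combined, clinical,
                                     score_type = "mean_z", min_size = 3) {
  stopifnot(inherits(partition, "community_partition"),
            inherits(combined, "abundance_matrix"))
  if (nrow(clinical) != ncol(combined$values))
    stop("clinical rows must match samples")
  clinical <- clinical[, setdiff(names(clinical), "sample_id"),
                       drop = FALSE]
  scores <- .community_scores(partition, combined, score_type)
  sizes <- table(partition$membership)
  test_ids <- names(sizes)[sizes >= min_size]
  rows <- list()
  for (cid in test_ids) {
    sc <- scores[, paste0("c", cid)]
    for (var in names(clinical)) {
      res <- .assoc_row(clinical[[var]], sc)
      if (is.null(res)) {
        warning("skipping constant clinical variable '", var, "'")
        next
      }
      rows[[length(rows) + 1L]] <-
        data.frame(unit = paste0("c", cid), variable = var,
                   model = res$model, estimate = res$estimate, p = res$p,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable community/variable pair")
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  class(out) <- c("clinical_association", "data.frame")
  out
}

#' Associate individual features with one clinical variable
#'
#' Univariate regression of the clinical variable on each feature's
#' abundance (logistic for binary, linear for continuous), BH adjusted
#' across features.
#'
#' @param combined An [abundance_matrix()].
#' @param clinical_var Vector of length `n_samples`.
#' @param q_cut Selection threshold (default 0.01).
#' @return A `clinical_association` data.frame with columns `unit`
#'   (feature id), `variable`, `model`, `estimate`, `p`, `q`, `selected`.
#' @export
feature_clinical_assoc <- function(combined, clinical_var, q_cut = 0.01) {
  stopifnot(inherits(combined, "abundance_matrix"))
  if (length(clinical_var) != ncol(combined$values))
    stop("clinical_var length must match samples")
  rows <- list()
  for (i in seq_len(nrow(combined$values))) {
    res <- .assoc_row(clinical_var, combined$values[i, ])
    if (is.null(res)) next
    rows[[length(rows) + 1L]] <-
      data.frame(unit = rownames(combined$values)[i],
                 variable = "clinical_var", model = res$model,
                 estimate = res$estimate, p = res$p,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable feature")
  out$q <- bh_adjust(out$p)
  out$selected <- out$q <= q_cut
  rownames(out) <- NULL
  class(out) <- c("clinical_association", "data.frame")
  out
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of each annotation term's overlap with a
#' member set against a background, BH adjusted across terms. Annotation
#' sets are intersected with the background first.
#'
#' @param member_set Character vector, subset of `background`.
#' @param annotation Named list: term -> character vector of members.
#' @param background Character vector of all eligible features (non-empty).
#' @return Data.frame with `term`, `overlap`, `term_size`, `set_size`,
#'   `background_size`, `p`, `q`.
#' @export
ora_enrichment <- function(member_set, annotation, background) {
  if (length(background) == 0) stop("empty background")
  background <- unique(background)
  if (!all(member_set %in% background))
    stop("member_set must be a subset of the background")
  member_set <- unique(member_set)
  n_bg <- length(background)
  n_set <- length(member_set)
  rows <- lapply(names(annotation), function(term) {
    term_members <- intersect(annotation[[term]], background)
    k <- length(intersect(member_set, term_members))
    K <- length(term_members)
    p <- stats::phyper(k - 1, K, n_bg - K, n_set, lower.tail = FALSE)
    data.frame(term = term, overlap = k, term_size = K,
               set_size = n_set, background_size = n_bg, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Write a network as GraphML
#'
#' @param net A [spearman_network()] result.
#' @param path Output path.
#' @export
write_network_graphml <- function(net, path) {
  stopifnot(inherits(net, "biomolecular_network"))
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}

#' Write a network as a weighted edge list (TSV: source, target, weight)
#'
#' @param net A [spearman_network()] result.
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "biomolecular_network"))
  utils::write.table(
    data.frame(source = net$edges$source, target = net$edges$target,
               weight = net$edges$rho),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
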