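# shared fixtures, all generated in code

# a compact cohort for fast end-to-end style tests
small_config <- function(seed = 1, ...) {
  defaults <- list(
    n_per_group = 40,
    category_counts = c(glycerolipid = 120, glycerophospholipid = 40,
                        sphingolipid = 12, steroid = 6),
    effect_fraction = 0.08,   # ~8 planted DAG/TAG species
    seed = seed
  )
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

# wrap an arbitrary igraph in the network container for topology tests
as_test_network <- function(g, fdr_cut = 1e-07, rho_cut = 0.38) {
  if (is.null(igraph::E(g)$weight)) igraph::E(g)$weight <- 1
  el <- igraph::as_data_frame(g, what = "edges")
  structure(list(graph = g,
                 thresholds = c(fdr_cut = fdr_cut, rho_cut = rho_cut),
                 edges = data.frame(source = el$from, target = el$to,
                                    rho = if (nrow(el)) el$weight
                                          else numeric(0),
                                    p = rep(NA_real_, nrow(el)),
                                    q = rep(NA_real_, nrow(el)))),
            class = "biomolecular_network")
}

# abundance matrix from a plain numeric matrix, with default labels
make_abund <- function(v, group = NULL, scale = "raw") {
  if (is.null(rownames(v))) rownames(v) <- paste0("f", seq_len(nrow(v)))
  if (is.null(colnames(v))) colnames(v) <- paste0("s", seq_len(ncol(v)))
  if (is.null(group))
    group <- factor(rep(c("noMetS", "MetS"), length.out = ncol(v)),
                    levels = c("noMetS", "MetS"))
  abundance_matrix(v, group, scale = scale)
}

# enumerate all set partitions of 1..n (Bell-number many)
all_partitions <- function(n) {
  if (n == 1) return(list(c(1L)))
  out <- list()
  for (p in all_partitions(n - 1)) {
    k <- max(p)
    for (b in seq_len(k + 1)) out[[length(out) + 1L]] <- c(p, b)
  }
  out
}
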