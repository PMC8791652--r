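#' Structural composition map of group differences
#'
#' Aggregates per-species differential statistics onto a per-class grid of
#' total carbon number (lipid size) by total double-bond count (saturation),
#' the layout used for structural heatmaps. Cell effect is the mean log-scale
#' group difference of the species in the cell; cell q is the minimum
#' adjusted p among them (a cell is significant when any member passes the
#' cut).
#'
#' @param stats A data.frame with columns `feature_id`, `effect`, `q`
#'   (e.g. the table of a [fit_moderated()] result), covering every species.
#' @param species Feature metadata from [parse_lipid_names()] for the lipids
#'   to map.
#' @param q_cut Significance cut on the cell q (default 0.01).
#' @return An object of class `composition_map`: a data.frame with columns
#'   `class`, `total_carbons`, `total_double_bonds`, `effect`, `q`,
#'   `significant`, `n_species`.
#' @export
composition_map <- function(stats, species, q_cut = 0.01) {
  stopifnot(is.data.frame(stats),
            all(c("feature_id", "effect", "q") %in% names(stats)))
  missing <- setdiff(species$name, stats$feature_id)
  if (length(missing) > 0)
    stop("species absent from stats: ",
         paste(utils::head(missing, 5), collapse = ", "))
  idx <- match(species$name, stats$feature_id)
  df <- data.frame(class = species$class,
                   total_carbons = species$total_carbons,
                   total_double_bonds = species$total_double_bonds,
                   effect = stats$effect[idx], q = stats$q[idx],
                   stringsAsFactors = FALSE)
  key <- interaction(df$class, df$total_carbons, df$total_double_bonds,
                     drop = TRUE)
  agg <- do.call(rbind, lapply(split(df, key), function(cell) {
    data.frame(class = cell$class[1],
               total_carbons = cell$total_carbons[1],
               total_double_bonds = cell$total_double_bonds[1],
               effect = mean(cell$effect), q = min(cell$q),
               n_species = nrow(cell), stringsAsFactors = FALSE)
  }))
  agg$significant <- agg$q < q_cut
  agg <- agg[order(agg$class, agg$total_carbons, agg$total_double_bonds), ]
  rownames(agg) <- NULL
  structure(agg, class = c("composition_map", "data.frame"),
            q_cut = q_cut)
}

#' Per-class direction summary of a composition map
#'
#' For each class with at least one significant cell, reports the direction
#' of the significant-cell effects (`increase` when at least two thirds are
#' positive, `decrease` when at least two thirds are negative, `mixed`
#' otherwise) and the fraction of the class's cells that are significant.
#'
#' @param map A [composition_map()].
#' @return A data.frame with columns `class`, `direction`,
#'   `fraction_significant`, `n_significant`.
#' @export
class_trend_summary <- function(map) {
  stopifnot(inherits(map, "composition_map"))
  if (nrow(map) == 0) stop("empty composition map")
  out <- do.call(rbind, lapply(split(as.data.frame(map), map$class),
                               function(cl) {
    sig <- cl[cl$significant, ]
    if (nrow(sig) == 0) return(NULL)
    pos <- mean(sig$effect > 0)
    dir <- if (pos >= 2 / 3) "increase"
           else if (pos <= 1 / 3) "decrease" else "mixed"
    data.frame(class = cl$class[1], direction = dir,
               fraction_significant = nrow(sig) / nrow(cl),
               n_significant = nrow(sig), stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    return(data.frame(class = character(0), direction = character(0),
                      fraction_significant = numeric(0),
                      n_significant = integer(0)))
  }
  rownames(out) <- NULL
  out
}

#' Write a composition map as long-format TSV
#'
#' @param map A [composition_map()].
#' @param path Output path.
#' @export
write_composition_map <- function(map, path) {
  utils::write.table(as.data.frame(map)[, c("class", "total_carbons",
                                            "total_double_bonds", "effect",
                                            "q", "significant", "n_species")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
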