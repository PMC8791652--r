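#' Default lipid class vocabulary
#'
#' Maps complex-lipid-panel class abbreviations to the four lipid categories
#' used throughout the package. The table is an ordinary data frame, so panels
#' carrying additional classes can extend it and pass the result to
#' [parse_lipid_name()] via `class_table`.
#'
#' @return A data.frame with columns `class` and `category`.
#' @export
#' @examples
#' lipid_class_table()
lipid_class_table <- function() {
  data.frame(
    class = c("TAG", "DAG", "MAG",
              "PC", "PE", "PI", "LPC", "LPE",
              "CER", "DCER", "HCER", "LCER", "SM",
              "CE", "FFA"),
    category = c(rep("glycerolipid", 3),
                 rep("glycerophospholipid", 5),
                 rep("sphingolipid", 5),
                 "steroid", "other"),
    stringsAsFactors = FALSE
  )
}

# Parse one "c:d" motif, tolerating a long-chain-base prefix letter ("d18:1").
.parse_cd <- function(part, name) {
  m <- regmatches(part, regexec("^[a-z]?([0-9]+):([0-9]+)$", part))[[1]]
  if (length(m) != 3L) {
    stop("malformed carbon:double-bond motif '", part, "' in lipid name '",
         name, "'", call. = FALSE)
  }
  c(carbons = as.integer(m[2]), double_bonds = as.integer(m[3]))
}

#' Parse a complex-lipid-panel shorthand name
#'
#' Understands the three name forms used by the panel: acyl-sum names such as
#' `"CE(18:2)"`, acyl-enumerated names such as `"DAG(16:0/18:1)"` (totals are
#' the sums over the listed chains; a sphingoid `d`-prefix as in
#' `"SM(d18:1/16:0)"` is stripped before summing), and triacylglycerol
#' neutral-loss names such as `"TAG(52:2)-FA(16:0)"`, where the parenthesised
#' totals already describe the whole molecule and the trailing `-FA()` names
#' one constituent fatty acid.
#'
#' Unknown class prefixes degrade to `lipid_class = "other"`,
#' `category = "other"`, with carbons and double bonds still parsed whenever
#' the `(c:d)` motif is present; a name without any parsable motif is an
#' error naming the offending string.
#'
#' @param name A single lipid name.
#' @param class_table Class vocabulary, see [lipid_class_table()].
#' @return An object of class `lipid_species`: a list with fields `name`,
#'   `lipid_class`, `category`, `total_carbons`, `total_double_bonds` and
#'   `annotated_fas` (a two-column integer matrix, possibly with zero rows).
#' @export
#' @examples
#' parse_lipid_name("TAG(52:2)-FA(16:0)")
#' parse_lipid_name("DAG(16:0/18:1)")
parse_lipid_name <- function(name, class_table = lipid_class_table()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))

  m <- regmatches(name, regexec("^([A-Za-z0-9]+)\\(([^)]+)\\)(-FA\\(([^)]+)\\))?$",
                                name))[[1]]
  if (length(m) == 0L) {
    stop("cannot parse lipid name '", name,
         "': no '(c:d)' motif found", call. = FALSE)
  }
  cls <- m[2]
  body <- m[3]
  fa_part <- if (nzchar(m[5])) m[5] else NULL

  idx <- match(cls, class_table$class)
  category <- if (is.na(idx)) "other" else class_table$category[idx]
  lipid_class <- if (is.na(idx)) "other" else cls

  parts <- strsplit(body, "/", fixed = TRUE)[[1]]
  parsed <- lapply(parts, .parse_cd, name = name)
  total_c <- sum(vapply(parsed, `[[`, integer(1), "carbons"))
  total_db <- sum(vapply(parsed, `[[`, integer(1), "double_bonds"))

  fas <- matrix(integer(0), ncol = 2,
                dimnames = list(NULL, c("carbons", "double_bonds")))
  if (length(parts) > 1L) {
    # enumerated acyls are themselves the annotation
    fas <- do.call(rbind, parsed)
    rownames(fas) <- NULL
  }
  if (!is.null(fa_part)) {
    fa <- .parse_cd(fa_part, name)
    if (fa["carbons"] > total_c || fa["double_bonds"] > total_db) {
      stop("neutral-loss fatty acid FA(", fa_part, ") exceeds totals in '",
           name, "'", call. = FALSE)
    }
    fas <- rbind(fas, fa)
    rownames(fas) <- NULL
  }

  structure(
    list(name = name,
         lipid_class = lipid_class,
         category = category,
         total_carbons = total_c,
         total_double_bonds = total_db,
         annotated_fas = fas),
    class = "lipid_species"
  )
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(sprintf("<lipid_species> %s  class=%s (%s)  C%d:%d",
              x$name, x$lipid_class, x$category,
              x$total_carbons, x$total_double_bonds))
  if (nrow(x$annotated_fas) > 0) {
    cat("  FA:", paste(sprintf("%d:%d", x$annotated_fas[, 1],
                               x$annotated_fas[, 2]), collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Parse many lipid names into a feature-metadata table
#'
#' @param names Character vector of lipid names.
#' @inheritParams parse_lipid_name
#' @return A data.frame with one row per name and columns `name`, `class`,
#'   `category`, `total_carbons`, `total_double_bonds`.
#' @export
parse_lipid_names <- function(names, class_table = lipid_class_table()) {
  stopifnot(is.character(names))
  rows <- vector("list", length(names))
  for (i in seq_along(names)) {
    sp <- tryCatch(parse_lipid_name(names[i], class_table),
                   error = function(e) {
                     stop("failed to parse lipid name at index ", i, ": ",
                          conditionMessage(e), call. = FALSE)
                   })
    rows[[i]] <- data.frame(name = sp$name, class = sp$lipid_class,
                            category = sp$category,
                            total_carbons = sp$total_carbons,
                            total_double_bonds = sp$total_double_bonds,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(name = character(0), class = character(0),
                      category = character(0), total_carbons = integer(0),
                      total_double_bonds = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Count lipid categories in a set of names
#'
#' @param names Character vector of lipid names; all must parse.
#' @inheritParams parse_lipid_name
#' @return Named integer vector of counts over the categories present
#'   (empty for empty input). Counts always sum to `length(names)`.
#' @export
#' @examples
#' summarize_categories(c("TAG(52:2)-FA(16:0)", "DAG(16:0/18:1)", "SM(d18:1/16:0)"))
summarize_categories <- function(names, class_table = lipid_class_table()) {
  meta <- parse_lipid_names(names, class_table)
  if (nrow(meta) == 0L) return(integer(0))
  tab <- table(meta$category)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Write a feature-metadata table as TSV
#'
#' Columns: name, class, category, total_carbons, total_double_bonds.
#'
#' @param names Character vector of lipid names.
#' @param path Output file path.
#' @inheritParams parse_lipid_name
#' @return The metadata data.frame, invisibly.
#' @export
write_feature_metadata <- function(names, path,
                                   class_table = lipid_class_table()) {
  meta <- parse_lipid_names(names, class_table)
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(meta)
}
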