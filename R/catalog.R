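SPECIES_TOKENS <- c("mouse", "rat")
MODEL_TOKENS <- c("SNI", "ScNI", "SpNI")
TISSUE_TOKENS <- c("tissue", "neuron")
SEX_TOKENS <- c("female", "male", "mixed", "unknown")

#' Construct a study catalog
#'
#' Metadata for every injury-vs-control comparison in the integration:
#' dataset accession, species (mouse or rat), injury model (SNI spared,
#' ScNI sciatic, SpNI spinal nerve injury), timepoint in hours post-injury,
#' whether the library is bulk tissue or sorted neurons, the sex composition,
#' and whether the dataset has biological replicates. The species x model
#' pairs define the analysis groups.
#'
#' @param comparisons data frame with columns \code{comparison_id},
#'   \code{dataset_accession}, \code{species}, \code{model},
#'   \code{timepoint_h}, \code{tissue}, \code{sex}, and optionally
#'   \code{has_replicates} (default \code{TRUE}).
#' @return An object of class \code{study_catalog} (a tibble).
#' @export
study_catalog <- function(comparisons) {
  x <- tibble::as_tibble(comparisons)
  need <- c("comparison_id", "dataset_accession", "species", "model",
            "timepoint_h", "tissue", "sex")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("study_catalog: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"has_replicates" %in% names(x)) x$has_replicates <- TRUE
  if (anyDuplicated(x$comparison_id)) {
    stop("study_catalog: duplicate comparison_id", call. = FALSE)
  }
  check_tokens <- function(col, allowed) {
    bad <- setdiff(unique(x[[col]]), allowed)
    if (length(bad)) {
      stop("study_catalog: unknown ", col, " token(s): ",
           paste(bad, collapse = ", "), " (allowed: ",
           paste(allowed, collapse = ", "), ")", call. = FALSE)
    }
  }
  check_tokens("species", SPECIES_TOKENS)
  check_tokens("model", MODEL_TOKENS)
  check_tokens("tissue", TISSUE_TOKENS)
  check_tokens("sex", SEX_TOKENS)
  x$timepoint_h <- as.numeric(x$timepoint_h)
  structure(x[, c(need, "has_replicates")],
            class = c("study_catalog", class(x)))
}

#' Read / write a study catalog as TSV
#'
#' The \code{timepoint} column may use mixed units (\code{9h}, \code{1d},
#' \code{2m}); it is converted to hours on read.
#'
#' @param path file path.
#' @return \code{read_study_catalog}: a \code{\link{study_catalog}}.
#' @export
read_study_catalog <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if ("timepoint" %in% names(raw) && !"timepoint_h" %in% names(raw)) {
    raw$timepoint_h <- parse_timepoint(raw$timepoint)
    raw$timepoint <- NULL
  }
  study_catalog(raw)
}

#' @param catalog a \code{\link{study_catalog}}.
#' @rdname read_study_catalog
#' @export
write_study_catalog <- function(catalog, path) {
  readr::write_tsv(tibble::as_tibble(unclass_catalog(catalog)), path)
  invisible(path)
}

unclass_catalog <- function(catalog) {
  class(catalog) <- setdiff(class(catalog), "study_catalog")
  catalog
}

#' Partition a catalog's comparisons into species x model groups
#'
#' The integration analyses each species x injury-model combination as one
#' group (the full rodent design has four: mouse SNI, mouse ScNI, rat ScNI,
#' rat SpNI). Groups with no comparisons are omitted.
#'
#' @param catalog a \code{\link{study_catalog}}.
#' @return Named list of character vectors of \code{comparison_id}, with
#'   names \code{"<species>_<model>"}.
#' @export
group_comparisons <- function(catalog) {
  stopifnot(inherits(catalog, "study_catalog"))
  if (nrow(catalog) == 0L) {
    stop("group_comparisons: empty catalog", call. = FALSE)
  }
  key <- paste(catalog$species, catalog$model, sep = "_")
  split(catalog$comparison_id, factor(key, levels = unique(key)))
}
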