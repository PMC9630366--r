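#' Analysis configuration
#'
#' Bundles the thresholds used across the pipeline. Defaults follow the
#' conventional values for rodent DRG injury meta-analysis: genes are DEGs at
#' adjusted p <= 0.05 and |log2 fold-change| >= log2(1.5); adjusted p-values
#' are floored at 1e-20 before the -log10 transform so that underflowed
#' DESeq2 p-values (reported as 0) do not produce infinite pi-values; the top
#' 15 ranked genes per comparison feed the occurrence-frequency summaries; a
#' gene is robust in a group when its summed +/-1 vote reaches 50% of the
#' group's comparison count; time-series DEGs are soft-clustered into eight
#' groups; cluster correspondence edges require at least 10 shared genes.
#'
#' @param fc_threshold fold-change cutoff on the linear scale (default 1.5).
#' @param p_threshold adjusted-p cutoff (default 0.05).
#' @param p_cap lower cap applied to adjusted p before -log10 (default 1e-20).
#' @param top_k ranking depth for frequency summaries (default 15).
#' @param robust_fraction fraction of a group's comparisons the |vote score|
#'   must reach, inclusive (default 0.5).
#' @param n_clusters fuzzy cluster count (default 8).
#' @param correspondence_min minimum shared genes for a correspondence edge
#'   (default 10).
#' @param other_species_max_ratio species-preference calls require the other
#'   species' up-vote ratio to fall below this fraction (default 0.2).
#' @param low_expr expression level (normalized RPKM/FPKM scale) below which
#'   the other species counts as lowly expressed (default 1.0).
#' @param marker_threshold expression threshold for Y-marker sex inference
#'   (default 1.0).
#' @param fuzzifier fuzzy c-means fuzzifier m > 1 (default 2, classical FCM;
#'   Mfuzz-style estimates for expression data are typically 1.1-1.3).
#' @param seed integer seed used wherever the configured analysis draws
#'   random numbers.
#' @return An object of class \code{analysis_config} (a named list).
#' @export
analysis_config <- function(fc_threshold = 1.5,
                            p_threshold = 0.05,
                            p_cap = 1e-20,
                            top_k = 15,
                            robust_fraction = 0.5,
                            n_clusters = 8,
                            correspondence_min = 10,
                            other_species_max_ratio = 0.2,
                            low_expr = 1.0,
                            marker_threshold = 1.0,
                            fuzzifier = 2,
                            seed = 1L) {
  cfg <- list(
    fc_threshold = fc_threshold, p_threshold = p_threshold, p_cap = p_cap,
    top_k = as.integer(top_k), robust_fraction = robust_fraction,
    n_clusters = as.integer(n_clusters),
    correspondence_min = as.integer(correspondence_min),
    other_species_max_ratio = other_species_max_ratio,
    low_expr = low_expr, marker_threshold = marker_threshold,
    fuzzifier = fuzzifier, seed = as.integer(seed)
  )
  num <- c("fc_threshold", "p_threshold", "p_cap", "top_k",
           "robust_fraction", "n_clusters", "correspondence_min")
  for (nm in num) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L ||
        !is.finite(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop("analysis_config: `", nm, "` must be a single positive number",
           call. = FALSE)
    }
  }
  if (cfg$robust_fraction > 1) {
    stop("analysis_config: `robust_fraction` must lie in (0, 1]", call. = FALSE)
  }
  if (cfg$fuzzifier <= 1) {
    stop("analysis_config: `fuzzifier` must be > 1", call. = FALSE)
  }
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Convert mixed-unit timepoint labels to hours
#'
#' Study metadata quotes injury timepoints in hours, days, or months; the
#' catalog stores them uniformly in hours (1 d = 24 h, 1 m = 720 h).
#' Bare numbers are taken as hours already.
#'
#' @param x character vector such as \code{c("9h", "1d", "2m", "72")}.
#' @return numeric vector of hours.
#' @examples
#' parse_timepoint(c("9h", "1d", "7d", "2m"))
#' @export
parse_timepoint <- function(x) {
  x <- tolower(trimws(as.character(x)))
  m <- regmatches(x, regexec("^([0-9]*\\.?[0-9]+)\\s*([hdm]?)$", x))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    stop("parse_timepoint: unparseable timepoint(s): ",
         paste(x[bad], collapse = ", "), call. = FALSE)
  }
  val <- as.numeric(vapply(m, `[`, character(1), 2L))
  unit <- vapply(m, `[`, character(1), 3L)
  mult <- c(h = 1, d = 24, m = 720)[match(unit, c("h", "d", "m"))]
  mult[unit == ""] <- 1
  unname(val * mult)
}
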