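#' Y-chromosome marker genes used for sex inference
#'
#' Uty, Eif2s3y, Kdm5d and Ddx3y are chromosome-Y genes expressed in DRG and
#' male-specific; rat annotation names the last one Ddx3, which is accepted
#' as an alias.
#' @export
Y_MARKERS <- c("Uty", "Eif2s3y", "Kdm5d", "Ddx3y")

#' Infer sample sex from Y-marker expression
#'
#' A sample is called \code{male} when at least 3 of the 4 Y markers exceed
#' the expression threshold, \code{female} when at least 3 fall at or below
#' it, and \code{ambiguous} otherwise. The 3-of-4 rule tolerates a single
#' marker dropout or annotation gap. Unmeasured markers are treated as
#' below threshold with a warning; a sample with no measured marker is
#' \code{ambiguous}.
#'
#' @param marker_expr named numeric vector of normalized expression for (a
#'   subset of) \code{\link{Y_MARKERS}}; the rat alias \code{Ddx3} is
#'   accepted for \code{Ddx3y}.
#' @param threshold expression threshold (default 1.0).
#' @return List with \code{call} (\code{"male"}, \code{"female"} or
#'   \code{"ambiguous"}), \code{n_above}, \code{n_measured}, and
#'   \code{marker_expression} (the four markers, NA where unmeasured).
#' @export
infer_sex <- function(marker_expr, threshold = 1.0) {
  stopifnot(is.numeric(marker_expr), !is.null(names(marker_expr)))
  nm <- names(marker_expr)
  nm[tolower(nm) == "ddx3"] <- "Ddx3y"
  known <- nm %in% Y_MARKERS
  expr <- setNames(rep(NA_real_, 4L), Y_MARKERS)
  expr[nm[known]] <- marker_expr[known]
  n_measured <- sum(!is.na(expr))
  if (n_measured == 0L) {
    warning("infer_sex: no Y marker measured; call is ambiguous",
            call. = FALSE)
    return(list(call = "ambiguous", n_above = 0L, n_measured = 0L,
                marker_expression = expr))
  }
  if (n_measured < 4L) {
    warning("infer_sex: ", 4L - n_measured,
            " unmeasured marker(s) treated as below threshold",
            call. = FALSE)
  }
  above <- !is.na(expr) & expr > threshold
  n_above <- sum(above)
  n_below <- 4L - n_above  # unmeasured counts as below
  call <- if (n_above >= 3L) "male" else if (n_below >= 3L) "female"
          else "ambiguous"
  list(call = call, n_above = as.integer(n_above),
       n_measured = as.integer(n_measured), marker_expression = expr)
}

#' Batch sex inference with per-dataset consistency report
#'
#' Runs \code{\link{infer_sex}} over a sample table and flags datasets whose
#' samples receive conflicting calls (the situation where, e.g., a study's
#' injury libraries are male but its controls female, which confounds
#' injury DEGs with sex DEGs).
#'
#' @param samples data frame with columns \code{sample_id}, \code{dataset},
#'   and one column per measured Y marker.
#' @param threshold expression threshold (default 1.0).
#' @return List with \code{calls} (tibble: sample_id, dataset, call,
#'   n_above) and \code{consistency} (tibble: dataset, n_male, n_female,
#'   n_ambiguous, consistent).
#' @export
infer_sex_batch <- function(samples, threshold = 1.0) {
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("sample_id", "dataset") %in% names(samples)))
  marker_cols <- names(samples)[tolower(names(samples)) %in%
                                  tolower(c(Y_MARKERS, "Ddx3"))]
  calls <- vapply(seq_len(nrow(samples)), function(i) {
    expr <- unlist(samples[i, marker_cols])
    infer_sex(expr, threshold)$call
  }, character(1))
  call_tab <- tibble::tibble(sample_id = samples$sample_id,
                             dataset = samples$dataset, call = calls)
  agg <- lapply(split(call_tab$call, call_tab$dataset), function(v) {
    c(n_male = sum(v == "male"), n_female = sum(v == "female"),
      n_ambiguous = sum(v == "ambiguous"))
  })
  consistency <- tibble::tibble(
    dataset = names(agg),
    n_male = vapply(agg, `[[`, numeric(1), "n_male"),
    n_female = vapply(agg, `[[`, numeric(1), "n_female"),
    n_ambiguous = vapply(agg, `[[`, numeric(1), "n_ambiguous")
  )
  consistency$consistent <- with(consistency, n_male == 0 | n_female == 0)
  list(calls = call_tab, consistency = consistency)
}

SEX_SCHEMA <- c("female_injury", "male_injury", "sex_control", "sex_injury")

#' Partition genes by the four-comparison sex-dimorphism design
#'
#' The design crosses sex and injury into four comparisons: female injury
#' vs female control (\code{female_injury}), male injury vs male control
#' (\code{male_injury}), male control vs female control
#' (\code{sex_control}), male injury vs female injury (\code{sex_injury}).
#' Over the genes differentially expressed in at least one comparison:
#' \itemize{
#'   \item \code{injury-only}: DE in the same direction in both injury
#'     comparisons and not DE in either sex comparison;
#'   \item \code{sex-only}: DE in >= 1 sex comparison and in neither injury
#'     comparison;
#'   \item \code{mixed}: DE in both an injury and a sex comparison, or DE
#'     with conflicting directions in the two injury comparisons;
#'   \item \code{none}: remaining genes (e.g. DE in only one injury
#'     comparison with no sex signal).
#' }
#'
#' @param tables named list of four \code{\link{comparison_table}} objects
#'   with names \code{female_injury}, \code{male_injury},
#'   \code{sex_control}, \code{sex_injury}.
#' @param cfg an \code{\link{analysis_config}}.
#' @return Tibble: gene_id, label, and the four per-comparison directions.
#' @export
four_way_partition <- function(tables, cfg = analysis_config()) {
  miss <- setdiff(SEX_SCHEMA, names(tables))
  if (length(miss)) {
    stop("four_way_partition: missing comparison slot(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  calls <- lapply(tables[SEX_SCHEMA], call_degs, cfg = cfg)
  genes <- unique(unlist(lapply(calls, `[[`, "gene_id"), use.names = FALSE))
  dir_of <- function(slot) {
    d <- calls[[slot]]
    out <- d$direction[match(genes, d$gene_id)]
    out[is.na(out)] <- "none"  # unmeasured counts as not DE
    out
  }
  fi <- dir_of("female_injury"); mi <- dir_of("male_injury")
  sc <- dir_of("sex_control"); si <- dir_of("sex_injury")
  inj_de <- (fi != "none") | (mi != "none")
  inj_both_same <- fi != "none" & fi == mi
  inj_conflict <- fi != "none" & mi != "none" & fi != mi
  sex_de <- (sc != "none") | (si != "none")
  label <- rep("none", length(genes))
  label[inj_both_same & !sex_de] <- "injury-only"
  label[sex_de & !inj_de] <- "sex-only"
  label[(inj_de & sex_de) | inj_conflict] <- "mixed"
  keep <- inj_de | sex_de
  tibble::tibble(gene_id = genes, label = label,
                 female_injury = fi, male_injury = mi,
                 sex_control = sc, sex_injury = si)[keep, , drop = FALSE]
}

#' Correlation of injury responses between the sexes
#'
#' Pearson correlation (two-sided t-test p-value) of the female and male
#' injury log2 fold-changes over the injury-only genes. A strong
#' correlation indicates a shared, sex-independent injury program.
#'
#' @param female_lfc,male_lfc numeric vectors of equal length (>= 3),
#'   aligned by gene.
#' @return List with \code{r}, \code{p_value}, \code{n}.
#' @export
injury_only_correlation <- function(female_lfc, male_lfc) {
  stopifnot(length(female_lfc) == length(male_lfc))
  if (length(female_lfc) < 3L) {
    stop("injury_only_correlation: need at least 3 genes", call. = FALSE)
  }
  ct <- cor.test(female_lfc, male_lfc, method = "pearson",
                 alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value,
       n = length(female_lfc))
}

OCTANT_LEVELS <- c("up-up", "down-down", "up-down", "down-up",
                   "female-up-only", "female-down-only",
                   "male-up-only", "male-down-only", "none")

#' Eight-region fold-change split of the female/male injury plane
#'
#' Cuts the (female lfc, male lfc) plane at +/- log2(fc_threshold) on each
#' axis. The four diagonal regions hold genes exceeding the cutoff in both
#' sexes (same or opposite direction); the four axis regions hold genes
#' exceeding it in one sex only. Genes inside the centre square are
#' \code{none}.
#'
#' @param female_lfc,male_lfc numeric vectors, aligned by gene.
#' @param fc_threshold linear fold-change cutoff (default 1.5).
#' @return Factor with the nine region labels (\code{"up-up"},
#'   \code{"down-down"}, \code{"up-down"} = female up / male down,
#'   \code{"down-up"}, \code{"female-up-only"}, \code{"female-down-only"},
#'   \code{"male-up-only"}, \code{"male-down-only"}, \code{"none"}).
#' @export
octant_split <- function(female_lfc, male_lfc, fc_threshold = 1.5) {
  stopifnot(length(female_lfc) == length(male_lfc))
  t <- log2(fc_threshold)
  f_big <- abs(female_lfc) >= t
  m_big <- abs(male_lfc) >= t
  lab <- rep("none", length(female_lfc))
  both <- f_big & m_big
  lab[both & female_lfc > 0 & male_lfc > 0] <- "up-up"
  lab[both & female_lfc < 0 & male_lfc < 0] <- "down-down"
  lab[both & female_lfc > 0 & male_lfc < 0] <- "up-down"
  lab[both & female_lfc < 0 & male_lfc > 0] <- "down-up"
  lab[f_big & !m_big & female_lfc > 0] <- "female-up-only"
  lab[f_big & !m_big & female_lfc < 0] <- "female-down-only"
  lab[!f_big & m_big & male_lfc > 0] <- "male-up-only"
  lab[!f_big & m_big & male_lfc < 0] <- "male-down-only"
  factor(lab, levels = OCTANT_LEVELS)
}
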