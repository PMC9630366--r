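#' Call differentially expressed genes at fixed thresholds
#'
#' Replicated datasets: a gene is \code{up} when adjusted p <=
#' \code{p_threshold} and lfc >= log2(\code{fc_threshold}); \code{down}
#' symmetrically; otherwise \code{none}. Genes whose adjusted p is missing
#' (e.g. filtered by independent filtering) are \code{none}. No-replicate
#' datasets are called on the fold-change criterion alone, in both
#' directions.
#'
#' @param tab a \code{\link{comparison_table}}.
#' @param cfg an \code{\link{analysis_config}}.
#' @return Tibble with columns \code{gene_id} and \code{direction}
#'   (\code{"up"}, \code{"down"}, or \code{"none"}), one row per gene.
#' @export
call_degs <- function(tab, cfg = analysis_config()) {
  stopifnot(inherits(tab, "comparison_table"))
  rec <- tab$records
  lfc_min <- log2(cfg$fc_threshold)
  fc_up <- rec$lfc >= lfc_min
  fc_down <- rec$lfc <= -lfc_min
  if (tab$has_replicates) {
    sig <- !is.na(rec$adj_p) & rec$adj_p <= cfg$p_threshold
    fc_up <- fc_up & sig
    fc_down <- fc_down & sig
  }
  direction <- rep("none", nrow(rec))
  direction[fc_up] <- "up"
  direction[fc_down] <- "down"
  tibble::tibble(gene_id = rec$gene_id, direction = direction)
}

#' Atf3 injury-timepoint gate
#'
#' Atf3 is the canonical neuronal injury marker; only comparisons where it
#' is significantly up-regulated reflect an injured state and enter the
#' group analyses. Returns \code{TRUE} when the (harmonized) Atf3 record is
#' called \code{up} by \code{\link{call_degs}}; a table without an Atf3
#' record fails the gate with a warning.
#'
#' @inheritParams call_degs
#' @return Logical scalar.
#' @export
atf3_gate <- function(tab, cfg = analysis_config()) {
  stopifnot(inherits(tab, "comparison_table"))
  calls <- call_degs(tab, cfg)
  hit <- calls$direction[calls$gene_id == "Atf3"]
  if (length(hit) == 0L) {
    warning("atf3_gate: no Atf3 record in `", tab$comparison_id,
            "`; comparison fails the gate", call. = FALSE)
    return(FALSE)
  }
  identical(hit, "up")
}

#' Keep only comparisons passing the Atf3 gate
#'
#' @param tables list of \code{\link{comparison_table}} objects.
#' @inheritParams call_degs
#' @return The gated-in subset of \code{tables}; exclusions are reported
#'   with a message.
#' @export
apply_atf3_gate <- function(tables, cfg = analysis_config()) {
  keep <- vapply(tables, atf3_gate, logical(1), cfg = cfg)
  if (any(!keep)) {
    dropped <- vapply(tables[!keep], `[[`, character(1), "comparison_id")
    message("apply_atf3_gate: excluded ", sum(!keep), " comparison(s): ",
            paste(dropped, collapse = ", "))
  }
  tables[keep]
}

#' Vote score over a group's DEG calls for one gene
#'
#' Each comparison contributes weight +1 (up), -1 (down) or 0 (not a DEG or
#' not measured); the score is the sum over the group's N comparisons. The
#' gene is robust up when score >= robust_fraction x N (inclusive), robust
#' down when -score >= robust_fraction x N.
#'
#' @param calls character vector in \code{c("up", "down", "none")}, one
#'   entry per comparison in the group (length N >= 1).
#' @param robust_fraction fraction of N the |score| must reach (default 0.5).
#' @return List with \code{score} (integer), \code{n} (N), and
#'   \code{robust} (\code{"up"}, \code{"down"}, or \code{"none"}).
#' @export
vote_score <- function(calls, robust_fraction = 0.5) {
  n <- length(calls)
  stopifnot(n >= 1L)
  bad <- setdiff(unique(calls), c("up", "down", "none"))
  if (length(bad)) {
    stop("vote_score: unknown call token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  score <- sum(calls == "up") - sum(calls == "down")
  cut <- robust_fraction * n
  robust <- if (score >= cut) "up" else if (-score >= cut) "down" else "none"
  list(score = as.integer(score), n = as.integer(n), robust = robust)
}

#' Robust up/down gene sets for one species x model group
#'
#' Applies \code{\link{call_degs}} to every comparison in the group (after
#' Atf3 gating) and sums the +/-1 votes per gene over all N comparisons;
#' genes absent from a comparison contribute 0 there while N stays fixed at
#' the group size. Genes with |score| >= robust_fraction x N are robust.
#'
#' @param tables list of \code{\link{comparison_table}} objects forming one
#'   group.
#' @param cfg an \code{\link{analysis_config}}.
#' @param gate apply the Atf3 gate before voting (default \code{TRUE}).
#' @return List with \code{robust_up} and \code{robust_down} (character
#'   vectors of gene ids), \code{votes} (tibble: gene_id, score, n_up,
#'   n_down, n, robust), and \code{n} (group comparison count after gating).
#' @export
robust_sets <- function(tables, cfg = analysis_config(), gate = TRUE) {
  if (gate) tables <- apply_atf3_gate(tables, cfg)
  if (length(tables) == 0L) {
    stop("robust_sets: no comparisons left after Atf3 gating", call. = FALSE)
  }
  call_list <- lapply(tables, call_degs, cfg = cfg)
  genes <- unique(unlist(lapply(call_list, `[[`, "gene_id"),
                         use.names = FALSE))
  n <- length(tables)
  if (length(genes) == 0L) {
    votes <- tibble::tibble(gene_id = character(), score = integer(),
                            n_up = integer(), n_down = integer(),
                            n = integer(), robust = character())
    return(list(robust_up = character(), robust_down = character(),
                votes = votes, n = n))
  }
  n_up <- integer(length(genes))
  n_down <- integer(length(genes))
  for (calls in call_list) {
    idx <- match(calls$gene_id, genes)
    n_up[idx] <- n_up[idx] + (calls$direction == "up")
    n_down[idx] <- n_down[idx] + (calls$direction == "down")
  }
  score <- n_up - n_down
  cut <- cfg$robust_fraction * n
  robust <- rep("none", length(genes))
  robust[score >= cut] <- "up"
  robust[-score >= cut] <- "down"
  votes <- tibble::tibble(gene_id = genes, score = as.integer(score),
                          n_up = n_up, n_down = n_down, n = n,
                          robust = robust)
  votes <- votes[order(-votes$score, votes$gene_id), , drop = FALSE]
  list(robust_up = votes$gene_id[votes$robust == "up"],
       robust_down = votes$gene_id[votes$robust == "down"],
       votes = votes, n = n)
}

#' Intersect robust sets across groups: conserved injury genes
#'
#' Genes robust in every supplied group (e.g. in mouse SNI, mouse ScNI, rat
#' ScNI, and rat SpNI) are the conserved injury-response set. Pairwise
#' overlap counts and percentages (|A intersect B| / |A| x 100) are also
#' reported for UpSet-style summaries.
#'
#' @param sets named list (>= 2 entries) of character vectors of gene ids,
#'   one per group, all for the same direction.
#' @param direction label carried through to the output (default
#'   \code{"up"}).
#' @return List with \code{conserved} (character vector), \code{direction},
#'   and \code{pairwise} (tibble: set_a, set_b, size_a, size_b, shared,
#'   pct_of_a).
#' @export
intersect_groups <- function(sets, direction = "up") {
  if (length(sets) < 2L) {
    stop("intersect_groups: need at least two groups", call. = FALSE)
  }
  if (is.null(names(sets))) names(sets) <- paste0("group", seq_along(sets))
  conserved <- Reduce(intersect, sets)
  pairs <- utils::combn(names(sets), 2L)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    shared <- length(intersect(sets[[a]], sets[[b]]))
    tibble::tibble(
      set_a = a, set_b = b,
      size_a = length(sets[[a]]), size_b = length(sets[[b]]),
      shared = shared,
      pct_of_a = if (length(sets[[a]])) 100 * shared / length(sets[[a]])
                 else NA_real_
    )
  }))
  list(conserved = conserved, direction = direction, pairwise = pairwise)
}
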