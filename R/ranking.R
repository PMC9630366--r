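#' Signed pi-value: significance times fold-change
#'
#' The pi-value ranks genes by combining statistical significance and effect
#' size: \eqn{\pi = -\log_{10}(\max(p_{adj}, cap)) \times \mathrm{LFC}}.
#' The cap (default 1e-20) bounds the contribution of underflowed adjusted
#' p-values, so any p below the cap saturates at the same -log10 factor.
#' The sign of the result equals the sign of the log2 fold-change.
#'
#' @param lfc log2 fold-change (injury over control), vectorized.
#' @param adj_p adjusted p-value in [0, 1], vectorized; \code{NA} is an
#'   error — no-replicate datasets rank by fold-change instead
#'   (\code{\link{rank_genes}}).
#' @param p_cap lower cap on the adjusted p-value (> 0).
#' @return Numeric vector of signed pi-values.
#' @examples
#' pi_value(2, 0.01)    # 4
#' pi_value(1, 1e-30)   # 20, capped
#' @export
pi_value <- function(lfc, adj_p, p_cap = 1e-20) {
  stopifnot(is.numeric(lfc), is.numeric(adj_p),
            is.numeric(p_cap), length(p_cap) == 1L, p_cap > 0)
  if (any(is.na(adj_p))) {
    stop("pi_value: adj_p is missing; no-replicate comparisons rank by lfc",
         call. = FALSE)
  }
  if (any(adj_p < 0 | adj_p > 1)) {
    stop("pi_value: adj_p outside [0, 1]", call. = FALSE)
  }
  -log10(pmax(adj_p, p_cap)) * lfc
}

#' Rank a comparison's DEGs by pi-value (or fold-change)
#'
#' Genes passing the DEG thresholds (\code{\link{call_degs}}) are split by
#' direction and ranked: up-regulated genes by descending score, down by
#' ascending (most negative first). The score is the signed pi-value for
#' replicated datasets and the log2 fold-change for no-replicate datasets.
#' Ties break by descending |lfc|, then lexicographic gene id, so rankings
#' are deterministic.
#'
#' @param tab a \code{\link{comparison_table}}.
#' @param cfg an \code{\link{analysis_config}}.
#' @return List with tibbles \code{up} and \code{down}, columns
#'   \code{gene_id}, \code{score}, \code{lfc}, \code{rank}.
#' @export
rank_genes <- function(tab, cfg = analysis_config()) {
  stopifnot(inherits(tab, "comparison_table"))
  if (nrow(tab$records) == 0L) {
    stop("rank_genes: empty comparison table", call. = FALSE)
  }
  calls <- call_degs(tab, cfg)
  rec <- tab$records[match(calls$gene_id, tab$records$gene_id), ]
  score <- if (tab$has_replicates) {
    pi_value(rec$lfc, rec$adj_p, cfg$p_cap)
  } else {
    rec$lfc
  }
  one_direction <- function(dir) {
    sel <- calls$direction == dir
    d <- tibble::tibble(gene_id = rec$gene_id[sel], score = score[sel],
                        lfc = rec$lfc[sel])
    ord <- if (dir == "up") {
      order(-d$score, -abs(d$lfc), d$gene_id)
    } else {
      order(d$score, -abs(d$lfc), d$gene_id)
    }
    d <- d[ord, , drop = FALSE]
    d$rank <- seq_len(nrow(d))
    d
  }
  list(up = one_direction("up"), down = one_direction("down"))
}

#' Top-k occurrence frequency across a group's comparisons
#'
#' Extracts the top-k ranked genes of each direction from every comparison
#' in a group and counts, per gene, in how many comparisons it appears. The
#' denominator is the group's full comparison count, without conditioning on
#' whether the gene was detected in each comparison.
#'
#' @param ranked list of \code{\link{rank_genes}} results (one per
#'   comparison in the group).
#' @param k ranking depth (>= 1); lists shorter than \code{k} contribute all
#'   their genes.
#' @return Tibble with columns \code{direction}, \code{gene_id},
#'   \code{count}, \code{denominator}, ordered by decreasing count.
#' @export
topk_frequency <- function(ranked, k) {
  if (length(ranked) == 0L) {
    stop("topk_frequency: empty group", call. = FALSE)
  }
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
  denom <- length(ranked)
  per_dir <- function(dir) {
    hits <- unlist(lapply(ranked, function(r) {
      head(r[[dir]]$gene_id, k)
    }), use.names = FALSE)
    if (length(hits) == 0L) {
      return(tibble::tibble(direction = character(), gene_id = character(),
                            count = integer(), denominator = integer()))
    }
    tab <- table(hits)
    tibble::tibble(direction = dir, gene_id = names(tab),
                   count = as.integer(tab), denominator = denom)
  }
  out <- rbind(per_dir("up"), per_dir("down"))
  out[order(out$direction, -out$count, out$gene_id), , drop = FALSE]
}
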