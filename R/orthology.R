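#' Build and classify mouse-rat ortholog clusters
#'
#' Connected components of the thresholded bipartite similarity graph
#' between mouse and rat genes, augmented with identical-symbol edges (the
#' rodent convention gives one-to-one orthologs the same symbol, so
#' same-name genes are linked even without a similarity entry). Genes with
#' no retained edge form singleton species-specific clusters. Components
#' are classified: \code{single-copy} (exactly one gene per species),
#' \code{multi-copy} (both species present, more than two genes total),
#' \code{species-specific} (one species absent).
#'
#' @param similarity data frame with columns \code{mouse_gene},
#'   \code{rat_gene}, \code{score}; duplicate pairs keep the maximum score
#'   (reported with a message).
#' @param min_score retain similarity edges with score >= this threshold.
#' @param mouse_genes,rat_genes optional full gene universes per species;
#'   genes appearing only here become singleton species-specific clusters.
#' @param same_symbol_edges also link identical symbols (case-insensitive,
#'   default \code{TRUE}).
#' @return An object of class \code{ortho_clusters}: tibble with columns
#'   \code{cluster_id}, \code{class}, \code{mouse_members} and
#'   \code{rat_members} (list columns of character vectors).
#' @export
build_clusters <- function(similarity, min_score,
                           mouse_genes = NULL, rat_genes = NULL,
                           same_symbol_edges = TRUE) {
  similarity <- tibble::as_tibble(similarity)
  need <- c("mouse_gene", "rat_gene", "score")
  miss <- setdiff(need, names(similarity))
  if (length(miss)) {
    stop("build_clusters: similarity lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(similarity$score))) {
    stop("build_clusters: non-finite similarity score", call. = FALSE)
  }
  key <- paste(similarity$mouse_gene, similarity$rat_gene, sep = "\r")
  if (anyDuplicated(key)) {
    message("build_clusters: ", sum(duplicated(key)),
            " duplicate similarity pair(s); keeping max score")
    ord <- order(key, -similarity$score)
    similarity <- similarity[ord, , drop = FALSE]
    similarity <- similarity[!duplicated(key[ord]), , drop = FALSE]
  }
  mouse_all <- unique(c(similarity$mouse_gene, mouse_genes))
  rat_all <- unique(c(similarity$rat_gene, rat_genes))
  # prefixed node names keep the two species' symbol spaces apart
  m_node <- function(g) paste0("m\r", g)
  r_node <- function(g) paste0("r\r", g)
  kept <- similarity[similarity$score >= min_score, , drop = FALSE]
  edges <- matrix(character(0), ncol = 2L)
  if (nrow(kept)) {
    edges <- cbind(m_node(kept$mouse_gene), r_node(kept$rat_gene))
  }
  if (same_symbol_edges) {
    shared <- mouse_all[tolower(mouse_all) %in% tolower(rat_all)]
    rmatch <- rat_all[match(tolower(shared), tolower(rat_all))]
    if (length(shared)) {
      edges <- rbind(edges, cbind(m_node(shared), r_node(rmatch)))
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(mouse_all) + length(rat_all),
                            name = c(m_node(mouse_all), r_node(rat_all)))
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  vnames <- igraph::V(g)$name
  species <- substr(vnames, 1L, 1L)
  symbol <- substr(vnames, 3L, nchar(vnames))
  members <- split(seq_along(vnames), comp$membership)
  rows <- lapply(seq_along(members), function(i) {
    idx <- members[[i]]
    mm <- sort(symbol[idx][species[idx] == "m"])
    rm_ <- sort(symbol[idx][species[idx] == "r"])
    tibble::tibble(cluster_id = sprintf("OC%05d", i),
                   class = classify_cluster(length(mm), length(rm_)),
                   mouse_members = list(mm), rat_members = list(rm_))
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("ortho_clusters", class(out)))
}

classify_cluster <- function(n_mouse, n_rat) {
  if (n_mouse == 0L || n_rat == 0L) return("species-specific")
  if (n_mouse == 1L && n_rat == 1L) return("single-copy")
  "multi-copy"
}

#' Map robust DEG sets onto ortholog clusters
#'
#' A cluster is robust in a direction for a species when at least one of its
#' member genes is in that species' robust set (any-member rule, matching
#' cluster-level reporting of multi-copy DEGs). Robust genes that belong to
#' no cluster are counted in an \code{unclustered} bucket.
#'
#' @param clusters an \code{ortho_clusters} from \code{\link{build_clusters}}.
#' @param mouse_robust,rat_robust lists with \code{robust_up} and
#'   \code{robust_down} character vectors (as from \code{\link{robust_sets}}).
#' @return List with \code{status} (tibble: cluster_id, class, mouse_up,
#'   mouse_down, rat_up, rat_down), \code{counts} (tibble of robust-cluster
#'   counts per class, species, direction), and \code{unclustered} (list of
#'   gene ids per species/direction).
#' @export
map_robust <- function(clusters, mouse_robust, rat_robust) {
  stopifnot(inherits(clusters, "ortho_clusters"))
  any_in <- function(members, set) {
    vapply(members, function(g) any(g %in% set), logical(1))
  }
  status <- tibble::tibble(
    cluster_id = clusters$cluster_id,
    class = clusters$class,
    mouse_up = any_in(clusters$mouse_members, mouse_robust$robust_up),
    mouse_down = any_in(clusters$mouse_members, mouse_robust$robust_down),
    rat_up = any_in(clusters$rat_members, rat_robust$robust_up),
    rat_down = any_in(clusters$rat_members, rat_robust$robust_down)
  )
  counts <- do.call(rbind, lapply(c("mouse", "rat"), function(sp) {
    do.call(rbind, lapply(c("up", "down"), function(dir) {
      col <- paste(sp, dir, sep = "_")
      agg <- tapply(status[[col]], status$class, sum)
      tibble::tibble(species = sp, direction = dir,
                     class = names(agg), n_robust_clusters = as.integer(agg))
    }))
  }))
  clustered_mouse <- unlist(clusters$mouse_members, use.names = FALSE)
  clustered_rat <- unlist(clusters$rat_members, use.names = FALSE)
  unclustered <- list(
    mouse_up = setdiff(mouse_robust$robust_up, clustered_mouse),
    mouse_down = setdiff(mouse_robust$robust_down, clustered_mouse),
    rat_up = setdiff(rat_robust$robust_up, clustered_rat),
    rat_down = setdiff(rat_robust$robust_down, clustered_rat)
  )
  n_out <- sum(lengths(unclustered))
  if (n_out > 0L) {
    message("map_robust: ", n_out,
            " robust gene(s) not present in any cluster")
  }
  list(status = status, counts = counts, unclustered = unclustered)
}

#' Per-gene vote and expression summaries for one group
#'
#' Support statistics consumed by \code{\link{call_preference}}: for every
#' gene observed in a group, its robust direction, up-vote ratio
#' (fraction of the group's N comparisons calling it up), median |lfc| and
#' median injury-side expression across the comparisons where it was
#' measured.
#'
#' @param tables list of \code{\link{comparison_table}} objects (one group,
#'   already gated).
#' @param cfg an \code{\link{analysis_config}}.
#' @return Tibble: gene_id, robust, up_ratio, median_abs_lfc,
#'   median_expr_injury (NA when no expression columns were supplied).
#' @export
group_gene_stats <- function(tables, cfg = analysis_config()) {
  rs <- robust_sets(tables, cfg, gate = FALSE)
  votes <- rs$votes
  all_rec <- do.call(rbind, lapply(tables, `[[`, "records"))
  med_by <- function(v) {
    tapply(v, all_rec$gene_id, function(x) {
      x <- x[!is.na(x)]
      if (length(x)) median(x) else NA_real_
    })
  }
  med_lfc <- med_by(abs(all_rec$lfc))
  med_expr <- med_by(all_rec$expr_injury)
  tibble::tibble(
    gene_id = votes$gene_id,
    robust = votes$robust,
    up_ratio = votes$n_up / votes$n,
    median_abs_lfc = as.numeric(med_lfc[votes$gene_id]),
    median_expr_injury = as.numeric(med_expr[votes$gene_id])
  )
}

#' Call conserved and species-preference clusters
#'
#' Applied to the injury model available in both species (sciatic nerve
#' injury in the full design). A cluster is \code{conserved-up} when robust
#' up-regulated in both species (\code{conserved-down} symmetrically). It is
#' \code{mouse-preference} when robust up in mouse while the rat side shows
#' essentially no response: rat up-vote ratio below
#' \code{cfg$other_species_max_ratio} and, additionally, either a small rat
#' fold-change (median |lfc| below log2 of the fold-change threshold) or low
#' rat injury expression (below \code{cfg$low_expr}); \code{rat-preference}
#' is symmetric. When the expression columns are unavailable the preference
#' is still callable from votes and fold-changes, with
#' \code{expression_flag = "unknown"}.
#'
#' @param clusters an \code{ortho_clusters}.
#' @param mouse_stats,rat_stats per-gene summaries from
#'   \code{\link{group_gene_stats}} for the two species' groups of the same
#'   injury model.
#' @param cfg an \code{\link{analysis_config}}.
#' @return Tibble: cluster_id, class, status, expression_flag plus the
#'   per-species support columns used by the rule.
#' @export
call_preference <- function(clusters, mouse_stats, rat_stats,
                            cfg = analysis_config()) {
  stopifnot(inherits(clusters, "ortho_clusters"))
  lfc_min <- log2(cfg$fc_threshold)
  side <- function(members, stats) {
    idx <- lapply(members, function(g) match(g, stats$gene_id))
    list(
      robust_up = vapply(idx, function(i) {
        any(stats$robust[i[!is.na(i)]] == "up")
      }, logical(1)),
      robust_down = vapply(idx, function(i) {
        any(stats$robust[i[!is.na(i)]] == "down")
      }, logical(1)),
      up_ratio = vapply(idx, function(i) {
        i <- i[!is.na(i)]
        if (length(i)) max(stats$up_ratio[i]) else 0
      }, numeric(1)),
      med_lfc = vapply(idx, function(i) {
        i <- i[!is.na(i)]
        v <- stats$median_abs_lfc[i]
        v <- v[!is.na(v)]
        if (length(v)) median(v) else NA_real_
      }, numeric(1)),
      med_expr = vapply(idx, function(i) {
        i <- i[!is.na(i)]
        v <- stats$median_expr_injury[i]
        v <- v[!is.na(v)]
        if (length(v)) max(v) else NA_real_
      }, numeric(1))
    )
  }
  m <- side(clusters$mouse_members, mouse_stats)
  r <- side(clusters$rat_members, rat_stats)
  n <- nrow(clusters)
  status <- rep("none", n)
  flag <- rep("none", n)
  # quiet-other-side test: other species' change small OR expression low
  quiet <- function(other, i) {
    small <- !is.na(other$med_lfc[i]) && other$med_lfc[i] < lfc_min
    low <- !is.na(other$med_expr[i]) && other$med_expr[i] < cfg$low_expr
    unknown_expr <- is.na(other$med_expr[i])
    # membership absent entirely counts as small change (nothing measured)
    if (is.na(other$med_lfc[i])) small <- TRUE
    fired <- if (unknown_expr) "unknown" else if (small && low) "both"
             else if (small) "small_change" else if (low) "low_expr"
             else "none"
    list(ok = small || low, flag = fired)
  }
  for (i in seq_len(n)) {
    if (m$robust_up[i] && r$robust_up[i]) {
      status[i] <- "conserved-up"
    } else if (m$robust_down[i] && r$robust_down[i]) {
      status[i] <- "conserved-down"
    } else if (m$robust_up[i] && r$up_ratio[i] < cfg$other_species_max_ratio) {
      q <- quiet(r, i)
      if (q$ok) { status[i] <- "mouse-preference"; flag[i] <- q$flag }
    } else if (r$robust_up[i] && m$up_ratio[i] < cfg$other_species_max_ratio) {
      q <- quiet(m, i)
      if (q$ok) { status[i] <- "rat-preference"; flag[i] <- q$flag }
    }
  }
  tibble::tibble(
    cluster_id = clusters$cluster_id, class = clusters$class,
    status = status, expression_flag = flag,
    mouse_robust_up = m$robust_up, rat_robust_up = r$robust_up,
    mouse_up_ratio = m$up_ratio, rat_up_ratio = r$up_ratio,
    mouse_median_abs_lfc = m$med_lfc, rat_median_abs_lfc = r$med_lfc,
    mouse_expr_injury = m$med_expr, rat_expr_injury = r$med_expr
  )
}
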