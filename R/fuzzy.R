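#' Row-standardize a time-series expression matrix
#'
#' Each gene's profile is centred to mean 0 and scaled to unit population
#' standard deviation (divisor n), the usual preprocessing before fuzzy
#' c-means so clusters reflect profile shape rather than expression level.
#' Zero-variance rows cannot be scaled and are dropped with a message.
#'
#' @param x numeric matrix, genes x timepoints, with gene ids as row names.
#' @return The standardized matrix (possibly with fewer rows).
#' @export
standardize_rows <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 3L) {
    stop("standardize_rows: need at least three timepoints", call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop("standardize_rows: non-finite values", call. = FALSE)
  }
  mu <- rowMeans(x)
  centred <- x - mu
  sd_pop <- sqrt(rowMeans(centred^2))
  keep <- sd_pop > 0
  if (any(!keep)) {
    message("standardize_rows: dropped ", sum(!keep),
            " zero-variance row(s)")
  }
  centred[keep, , drop = FALSE] / sd_pop[keep]
}

#' Fuzzy c-means clustering of expression profiles
#'
#' Classical fuzzy c-means: alternating updates of cluster centres and
#' memberships minimizing \eqn{\sum_{i,k} u_{ik}^m \, d_{ik}^2} with
#' memberships constrained to sum to 1 per gene. Centres are initialized
#' from \code{c} distinct rows chosen by the seeded RNG (or supplied
#' directly), so results are deterministic given the seed. Iteration stops
#' when the largest centre displacement falls below \code{tol} or after
#' \code{max_iter} sweeps; the objective value after every sweep is
#' recorded and is non-increasing.
#'
#' @param x numeric matrix, genes x timepoints (typically
#'   \code{\link{standardize_rows}} output), row names = gene ids.
#' @param c number of clusters (<= number of rows).
#' @param m fuzzifier, > 1 (default 2).
#' @param seed integer seed for centre initialization.
#' @param tol convergence tolerance on centre displacement (default 1e-6).
#' @param max_iter iteration cap (default 300).
#' @param centers optional c x timepoints matrix of initial centres,
#'   overriding the seeded initialization (forces a single start).
#' @param nstart number of seeded restarts; the fit with the lowest final
#'   objective is returned (default 5). Alternating FCM updates only find a
#'   local optimum, so a few restarts guard against a poor draw of initial
#'   genes.
#' @return Object of class \code{fuzzy_clustering}: list with
#'   \code{membership} (genes x c, rows sum to 1), \code{centers},
#'   \code{hard} (named integer vector, argmax membership, ties to the
#'   lowest cluster index), \code{objective} (per-iteration values of the
#'   returned start), \code{m}, \code{iterations}, \code{converged}.
#' @export
fuzzy_cmeans <- function(x, c, m = 2, seed = 1L, tol = 1e-6,
                         max_iter = 300L, centers = NULL, nstart = 5L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (c > n) stop("fuzzy_cmeans: more clusters than genes", call. = FALSE)
  stopifnot(c >= 1L, m > 1, tol > 0, max_iter >= 1L, nstart >= 1L)
  if (!is.null(centers)) {
    centers <- as.matrix(centers)
    stopifnot(nrow(centers) == c, ncol(centers) == ncol(x))
    return(fcm_single(x, c, m, tol, max_iter, centers))
  }
  inits <- with_seed(seed, {
    lapply(seq_len(nstart), function(r) sample.int(n, c))
  })
  best <- NULL
  for (idx in inits) {
    fit <- fcm_single(x, c, m, tol, max_iter, x[idx, , drop = FALSE])
    if (is.null(best) ||
        min(fit$objective) < min(best$objective) - 1e-12) {
      best <- fit
    }
  }
  best
}

fcm_single <- function(x, c, m, tol, max_iter, centers) {
  objective <- numeric(0)
  converged <- FALSE
  u <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- pmax(dist2_to_centers(x, centers), 1e-300)
    # u_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1)), i.e. w = d2^(-1/(m-1))
    w <- d2^(-1 / (m - 1))
    u <- w / rowSums(w)
    um <- u^m
    new_centers <- (t(um) %*% x) / colSums(um)
    objective <- c(objective, sum(um * d2))
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) { converged <- TRUE; break }
  }
  # final memberships consistent with the returned centres
  d2 <- pmax(dist2_to_centers(x, centers), 1e-300)
  w <- d2^(-1 / (m - 1))
  u <- w / rowSums(w)
  rownames(u) <- rownames(x)
  hard <- apply(u, 1L, which.max)  # which.max ties -> lowest index
  structure(
    list(membership = u, centers = centers, hard = hard,
         objective = objective, m = m, iterations = length(objective),
         converged = converged),
    class = "fuzzy_clustering"
  )
}

dist2_to_centers <- function(x, centers) {
  # n x c matrix of squared Euclidean distances
  xn <- rowSums(x^2)
  cn <- rowSums(centers^2)
  outer(xn, cn, "+") - 2 * x %*% t(centers)
}

#' @export
print.fuzzy_clustering <- function(x, ...) {
  cat(sprintf(
    "<fuzzy_clustering> %d genes, %d clusters, m = %g, %d iteration(s)%s\n",
    nrow(x$membership), ncol(x$membership), x$m, x$iterations,
    if (x$converged) " (converged)" else " (max_iter reached)"))
  invisible(x)
}

#' Cluster correspondence between a reference and other datasets
#'
#' For each non-reference dataset, counts the genes shared between every
#' reference hard cluster and every other-dataset hard cluster; edges with
#' fewer shared genes than \code{min_shared} are suppressed. This maps how
#' temporal expression groups discovered in one dataset recur in the
#' others.
#'
#' @param ref named integer vector of hard cluster assignments (names =
#'   gene ids), e.g. the \code{hard} element of a
#'   \code{\link{fuzzy_cmeans}} fit on the reference dataset.
#' @param others named list of such vectors for the other datasets.
#' @param min_shared minimum shared gene count for an edge (default 10).
#' @return Tibble: ref_cluster, other_dataset, other_cluster,
#'   shared_gene_count. Warns and returns no edges for datasets sharing no
#'   genes with the reference.
#' @export
cluster_correspondence <- function(ref, others, min_shared = 10L) {
  stopifnot(!is.null(names(ref)), length(others) >= 1L)
  if (is.null(names(others))) {
    names(others) <- paste0("dataset", seq_along(others))
  }
  out <- list()
  for (ds in names(others)) {
    oth <- others[[ds]]
    shared_genes <- intersect(names(ref), names(oth))
    if (length(shared_genes) == 0L) {
      warning("cluster_correspondence: no shared genes with `", ds, "`",
              call. = FALSE)
      next
    }
    tab <- table(ref_cluster = ref[shared_genes],
                 other_cluster = oth[shared_genes])
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    df <- df[df$Freq >= min_shared, , drop = FALSE]
    if (nrow(df)) {
      out[[ds]] <- tibble::tibble(
        ref_cluster = as.integer(df$ref_cluster),
        other_dataset = ds,
        other_cluster = as.integer(df$other_cluster),
        shared_gene_count = as.integer(df$Freq)
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(ref_cluster = integer(), other_dataset = character(),
                          other_cluster = integer(),
                          shared_gene_count = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$other_dataset, res$ref_cluster, res$other_cluster), ,
      drop = FALSE]
}
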