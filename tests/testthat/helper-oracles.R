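# Independent brute-force oracles, deliberately naive: they re-derive each
# quantity from first principles and never call the implementation paths
# they are used to check.

# Count-difference vote scorer with an explicit loop.
oracle_vote <- function(calls, robust_fraction = 0.5) {
  score <- 0L
  for (v in calls) {
    if (v == "up") score <- score + 1L
    if (v == "down") score <- score - 1L
  }
  n <- length(calls)
  robust <- "none"
  if (score >= robust_fraction * n) robust <- "up"
  if (-score >= robust_fraction * n) robust <- "down"
  list(score = score, n = n, robust = robust)
}

# All length-n vectors over {up, down, none}.
all_call_vectors <- function(n) {
  tokens <- c("up", "down", "none")
  grid <- do.call(expand.grid,
                  c(rep(list(tokens), n), stringsAsFactors = FALSE))
  lapply(seq_len(nrow(grid)), function(i) as.character(grid[i, ]))
}

# Naive fuzzy c-means: explicit loops over genes and clusters.
oracle_fcm <- function(x, c, m, centers, tol = 1e-6, max_iter = 300L) {
  n <- nrow(x)
  obj <- NA_real_
  for (it in seq_len(max_iter)) {
    u <- matrix(0, n, c)
    for (i in seq_len(n)) {
      d2 <- numeric(c)
      for (k in seq_len(c)) d2[k] <- max(sum((x[i, ] - centers[k, ])^2), 1e-300)
      for (k in seq_len(c)) {
        u[i, k] <- 1 / sum((d2[k] / d2)^(1 / (m - 1)))
      }
    }
    new_centers <- centers
    for (k in seq_len(c)) {
      w <- u[, k]^m
      new_centers[k, ] <- colSums(w * x) / sum(w)
    }
    obj <- 0
    for (i in seq_len(n)) {
      for (k in seq_len(c)) {
        obj <- obj + u[i, k]^m * sum((x[i, ] - centers[k, ])^2)
      }
    }
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) break
  }
  list(objective = obj, centers = centers)
}

# Union-find components over a bipartite edge list; returns the partition
# of node labels into clusters (as sorted member vectors).
oracle_components <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(a) {
    while (parent[[a]] != a) a <- parent[[a]]
    a
  }
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      ra <- find(edges[i, 1L]); rb <- find(edges[i, 2L])
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots <- vapply(nodes, find, character(1))
  unname(lapply(split(nodes, roots), function(v) sort(unname(v))))
}

# Hard-cluster purity against a planted archetype truth table.
cluster_purity <- function(hard, truth) {
  tab <- table(truth$archetype[match(names(hard), truth$gene_id)], hard)
  sum(apply(tab, 2L, max)) / sum(tab)
}

# Small handmade replicated comparison table.
toy_table <- function(id = "cmp1",
                      genes = c("Atf3", "Gal", "Npy", "Scn10a"),
                      lfc = c(3, 2, 1, -1.5),
                      adj_p = c(1e-8, 1e-4, 0.2, 0.001)) {
  comparison_table(id, tibble::tibble(gene_id = genes, lfc = lfc,
                                      adj_p = adj_p))
}
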