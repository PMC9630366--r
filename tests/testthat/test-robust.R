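test_that("DEG calls apply the significance and fold-change thresholds", {
  tab <- comparison_table("c1", tibble::tibble(
    gene_id = c("A", "B", "C", "D"),
    lfc = c(1.0, 0.3, -0.7, 0.7),
    adj_p = c(0.01, 1e-9, 0.01, 0.2)
  ))
  calls <- call_degs(tab)
  expect_identical(calls$direction,
                   c("up",    # 1.0 >= log2 1.5 and p <= 0.05
                     "none",  # significant but fails fold-change
                     "down",
                     "none")) # fold-change ok but p > 0.05

  norep <- comparison_table("c2", tibble::tibble(
    gene_id = c("A", "B"), lfc = c(-0.7, 0.3), adj_p = NA_real_
  ), has_replicates = FALSE)
  expect_identical(call_degs(norep)$direction, c("down", "none"))
})

test_that("the Atf3 gate keeps only injured-state comparisons", {
  pass <- comparison_table("p", tibble::tibble(
    gene_id = c("Atf3", "Gal"), lfc = c(3, 1), adj_p = c(1e-8, 0.01)
  ))
  fail <- comparison_table("f", tibble::tibble(
    gene_id = c("Atf3", "Gal"), lfc = c(0.2, 1), adj_p = c(0.5, 0.01)
  ))
  expect_true(atf3_gate(pass))
  expect_false(atf3_gate(fail))
  noatf3 <- comparison_table("n", tibble::tibble(
    gene_id = "Gal", lfc = 1, adj_p = 0.01
  ))
  expect_warning(res <- atf3_gate(noatf3), "Atf3")
  expect_false(res)
  expect_message(kept <- apply_atf3_gate(list(pass, fail)), "excluded 1")
  expect_length(kept, 1L)
  expect_identical(kept[[1]]$comparison_id, "p")
})

test_that("vote_score equals the exhaustive count-difference oracle (N <= 4)", {
  for (n in 1:4) {
    for (calls in all_call_vectors(n)) {
      got <- vote_score(calls)
      want <- oracle_vote(calls)
      expect_identical(got$score, want$score)
      expect_identical(got$robust, want$robust)
    }
  }
  # spot checks from enumerating length-8 call vectors with the oracle
  expect_identical(vote_score(rep("up", 8))$robust, "up")       # 8 >= 4
  v <- vote_score(c(rep("up", 4), rep("none", 4)))
  expect_identical(v[c("score", "robust")],
                   list(score = 4L, robust = "up"))             # inclusive >=
  v2 <- vote_score(c(rep("up", 5), rep("down", 3)))
  expect_identical(v2[c("score", "robust")],
                   list(score = 2L, robust = "none"))           # 2 < 4
})

test_that("robust_sets votes over the fixed group size with absent genes as 0", {
  mk <- function(id, genes, lfc) {
    comparison_table(id, tibble::tibble(
      gene_id = c("Atf3", genes), lfc = c(3, lfc),
      adj_p = rep(1e-6, length(genes) + 1L)
    ))
  }
  # gene up in 1 of 7 comparisons: score 1 < ceil(3.5), not robust
  tabs <- c(list(mk("a", "Stac2", 2)),
            lapply(2:7, function(i) mk(paste0("x", i), "Other", 2)))
  rs <- robust_sets(tabs)
  expect_equal(rs$n, 7L)
  expect_false("Stac2" %in% rs$robust_up)
  stac2 <- rs$votes[rs$votes$gene_id == "Stac2", ]
  expect_equal(stac2$score, 1L)
  # Atf3 up in all 7
  expect_true("Atf3" %in% rs$robust_up)
  expect_error(robust_sets(list()), "no comparisons")
})

test_that("adding an up call never removes a gene from robust_up", {
  base <- lapply(1:4, function(i) {
    comparison_table(paste0("c", i), tibble::tibble(
      gene_id = c("Atf3", "G1"), lfc = c(3, c(2, 2, -2, 0.1)[i]),
      adj_p = c(1e-8, 1e-4)
    ))
  })
  extra <- comparison_table("c5", tibble::tibble(
    gene_id = c("Atf3", "G1"), lfc = c(3, 2), adj_p = c(1e-8, 1e-4)
  ))
  before <- robust_sets(base)
  after <- robust_sets(c(base, list(extra)))
  expect_true(all(before$robust_up %in% after$robust_up))
})

test_that("noiseless synthetic groups recover the planted sets exactly", {
  cfg_gen <- generator_config(n_genes = 300L, dropout = 0, noise_sd = 0,
                              seed = 21L)
  sim <- generate_comparisons(cfg_gen)
  grp <- group_comparisons(sim$catalog)
  truth <- sim$truth
  for (g in names(grp)) {
    species <- sub("_.*", "", g)
    tl <- if (species == "mouse") truth$lfc_mouse else truth$lfc_rat
    rs <- robust_sets(sim$tables[grp[[g]]])
    expect_setequal(rs$robust_up, truth$gene_id[tl > 0])
    expect_setequal(rs$robust_down, truth$gene_id[tl < 0])
  }
})

test_that("robust_up and robust_down are disjoint at any robust_fraction", {
  sim <- generate_comparisons(generator_config(n_genes = 150L, seed = 2L))
  grp <- group_comparisons(sim$catalog)
  for (frac in c(0.5, 0.75)) {
    cfg <- analysis_config(robust_fraction = frac)
    rs <- robust_sets(sim$tables[grp$mouse_SNI], cfg)
    expect_length(intersect(rs$robust_up, rs$robust_down), 0L)
  }
})

test_that("intersect_groups computes conserved sets and pairwise overlaps", {
  sets <- list(a = c("x", "y"), b = c("x", "y"))
  expect_setequal(intersect_groups(sets)$conserved, c("x", "y"))

  res <- intersect_groups(list(g1 = c("a", "b", "c"), g2 = c("b", "c", "d")))
  expect_setequal(res$conserved, c("b", "c"))
  expect_equal(res$pairwise$shared, 2L)
  expect_equal(res$pairwise$pct_of_a, 100 * 2 / 3, tolerance = 1e-12)
  expect_error(intersect_groups(list(a = "x")), "two groups")

  # four noiseless synthetic groups share exactly the planted conserved set
  sim <- generate_comparisons(generator_config(n_genes = 300L, dropout = 0,
                                               noise_sd = 0, seed = 13L))
  grp <- group_comparisons(sim$catalog)
  ups <- lapply(grp, function(ids) robust_sets(sim$tables[ids])$robust_up)
  cons <- intersect_groups(ups)
  planted <- sim$truth$gene_id[sim$truth$class == "conserved-up"]
  expect_setequal(cons$conserved, planted)
})
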