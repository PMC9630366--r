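test_that("cluster building covers the three copy-number classes", {
  sim <- tibble::tibble(mouse_gene = "Atf3", rat_gene = "Atf3", score = 90)
  oc <- build_clusters(sim, min_score = 50)
  expect_equal(nrow(oc), 1L)
  expect_identical(oc$class, "single-copy")

  # two mouse paralogs hitting one rat gene form one multi-copy cluster
  sim2 <- tibble::tibble(mouse_gene = c("A1", "B1"), rat_gene = "X1",
                         score = c(80, 70))
  oc2 <- build_clusters(sim2, min_score = 50)
  expect_identical(oc2$class, "multi-copy")
  expect_setequal(oc2$mouse_members[[1]], c("A1", "B1"))

  # a mouse gene with no surviving edge is a species-specific singleton
  sim3 <- tibble::tibble(mouse_gene = "Lonely1", rat_gene = "Far1",
                         score = 10)
  oc3 <- build_clusters(sim3, min_score = 50)
  expect_setequal(oc3$class, rep("species-specific", 2L))
})

test_that("identical symbols are linked even without a similarity edge", {
  oc <- build_clusters(
    tibble::tibble(mouse_gene = character(), rat_gene = character(),
                   score = numeric()),
    min_score = 50, mouse_genes = c("Atf3", "Mspec1"),
    rat_genes = c("Atf3", "Rspec1")
  )
  cls <- oc$class[vapply(oc$mouse_members, function(m) "Atf3" %in% m,
                         logical(1))]
  expect_identical(cls, "single-copy")
  expect_equal(sum(oc$class == "species-specific"), 2L)
})

test_that("duplicate similarity pairs keep the maximum score", {
  sim <- tibble::tibble(mouse_gene = c("A", "A"), rat_gene = c("X", "X"),
                        score = c(10, 80))
  expect_message(oc <- build_clusters(sim, min_score = 50), "duplicate")
  expect_identical(oc$class, "single-copy")  # the score-80 edge survived
})

test_that("cluster classes partition all genes", {
  set.seed(31)
  mouse <- sprintf("M%03d", 1:60)
  rat <- sprintf("R%03d", 1:50)
  sim <- tibble::tibble(
    mouse_gene = sample(mouse, 80, replace = TRUE),
    rat_gene = sample(rat, 80, replace = TRUE),
    score = runif(80, 0, 100)
  )
  sim <- sim[!duplicated(paste(sim$mouse_gene, sim$rat_gene)), ]
  oc <- build_clusters(sim, min_score = 40, mouse_genes = mouse,
                       rat_genes = rat)
  expect_equal(sum(lengths(oc$mouse_members)) + sum(lengths(oc$rat_members)),
               length(mouse) + length(rat))
  expect_equal(anyDuplicated(unlist(oc$mouse_members)), 0L)
  expect_equal(anyDuplicated(unlist(oc$rat_members)), 0L)
})

test_that("components match a brute-force union-find oracle", {
  set.seed(17)
  for (rep in 1:5) {
    n_m <- sample(20:100, 1); n_r <- sample(20:100, 1)
    mouse <- sprintf("m%03d", seq_len(n_m))
    rat <- sprintf("r%03d", seq_len(n_r))
    n_e <- sample(10:150, 1)
    sim <- tibble::tibble(
      mouse_gene = sample(mouse, n_e, replace = TRUE),
      rat_gene = sample(rat, n_e, replace = TRUE),
      score = runif(n_e, 0, 100)
    )
    sim <- sim[!duplicated(paste(sim$mouse_gene, sim$rat_gene)), ]
    min_score <- 30
    oc <- build_clusters(sim, min_score, mouse_genes = mouse,
                         rat_genes = rat, same_symbol_edges = FALSE)
    tag <- function(prefix, xs) {
      if (length(xs)) paste0(prefix, xs) else character(0)
    }
    got <- lapply(seq_len(nrow(oc)), function(i) {
      sort(c(tag("M:", oc$mouse_members[[i]]),
             tag("R:", oc$rat_members[[i]])))
    })
    kept <- sim[sim$score >= min_score, ]
    want <- oracle_components(
      c(paste0("M:", mouse), paste0("R:", rat)),
      cbind(paste0("M:", kept$mouse_gene), paste0("R:", kept$rat_gene))
    )
    key <- function(xs) sort(vapply(xs, paste, character(1), collapse = "|"))
    expect_identical(key(got), key(want))
  }
})

test_that("map_robust applies the any-member rule per species", {
  oc <- build_clusters(
    tibble::tibble(mouse_gene = c("A", "P1", "P2"),
                   rat_gene = c("A", "X", "X"),
                   score = 90),
    min_score = 50, mouse_genes = "Monly", rat_genes = character()
  )
  res <- map_robust(
    oc,
    mouse_robust = list(robust_up = c("A", "P2"), robust_down = character()),
    rat_robust = list(robust_up = "A", robust_down = character())
  )
  st <- res$status
  single <- st[st$class == "single-copy", ]
  expect_true(single$mouse_up && single$rat_up)
  multi <- st[st$class == "multi-copy", ]
  expect_true(multi$mouse_up)   # one of two paralogs suffices
  expect_false(multi$rat_up)
  spec <- st[st$class == "species-specific", ]
  expect_false(any(spec$rat_up, spec$rat_down))

  # enumerate member-status combinations for a 2-paralog cluster: the
  # cluster is robust-up iff at least one member is
  for (combo in list(c(TRUE, TRUE), c(TRUE, FALSE),
                     c(FALSE, TRUE), c(FALSE, FALSE))) {
    r <- map_robust(oc, list(robust_up = c("P1", "P2")[combo],
                             robust_down = character()),
                    list(robust_up = character(), robust_down = character()))
    expect_identical(r$status$mouse_up[r$status$class == "multi-copy"],
                     any(combo))
  }
})

test_that("robust genes outside any cluster land in the unclustered bucket", {
  oc <- build_clusters(
    tibble::tibble(mouse_gene = "A", rat_gene = "A", score = 90),
    min_score = 50
  )
  expect_message(
    res <- map_robust(oc, list(robust_up = c("A", "Ghost"),
                               robust_down = character()),
                      list(robust_up = character(),
                           robust_down = character())),
    "not present"
  )
  expect_identical(res$unclustered$mouse_up, "Ghost")
})

test_that("preference calls follow the vote-ratio and quiet-side rule", {
  oc <- build_clusters(
    tibble::tibble(mouse_gene = c("Cons1", "Gpr151", "Ambig1"),
                   rat_gene = c("Cons1", "Gpr151", "Ambig1"), score = 90),
    min_score = 50
  )
  mouse_stats <- tibble::tibble(
    gene_id = c("Cons1", "Gpr151", "Ambig1"),
    robust = c("up", "up", "up"),
    up_ratio = c(1, 1, 1),
    median_abs_lfc = c(2, 3, 2),
    median_expr_injury = c(10, 8, 10)
  )
  rat_stats <- tibble::tibble(
    gene_id = c("Cons1", "Gpr151", "Ambig1"),
    robust = c("up", "none", "none"),
    up_ratio = c(1, 0, 3 / 7),        # Gpr151: 0/7 rat comparisons up
    median_abs_lfc = c(2, 0.1, 2),
    median_expr_injury = c(10, 0.2, 10)
  )
  pc <- call_preference(oc, mouse_stats, rat_stats)
  expect_identical(pc$status[match("Cons1", mouse_stats$gene_id)],
                   "conserved-up")
  gp <- which(vapply(oc$mouse_members, function(m) "Gpr151" %in% m,
                     logical(1)))
  expect_identical(pc$status[gp], "mouse-preference")
  expect_identical(pc$expression_flag[gp], "both")
  # rat up in 3/7 comparisons: ratio 0.43 >= 0.2 -> ambiguous, no call
  am <- which(vapply(oc$mouse_members, function(m) "Ambig1" %in% m,
                     logical(1)))
  expect_identical(pc$status[am], "none")
})

test_that("missing expression still allows a preference call, flagged unknown", {
  oc <- build_clusters(
    tibble::tibble(mouse_gene = "Lipn", rat_gene = "Lipn", score = 90),
    min_score = 50
  )
  mouse_stats <- tibble::tibble(gene_id = "Lipn", robust = "up",
                                up_ratio = 1, median_abs_lfc = 2,
                                median_expr_injury = NA_real_)
  rat_stats <- tibble::tibble(gene_id = "Lipn", robust = "none",
                              up_ratio = 0, median_abs_lfc = 0.1,
                              median_expr_injury = NA_real_)
  pc <- call_preference(oc, mouse_stats, rat_stats)
  expect_identical(pc$status, "mouse-preference")
  expect_identical(pc$expression_flag, "unknown")
})

test_that("planted preference genes are recovered with high precision", {
  n_seeds <- 8L
  precisions <- vapply(seq_len(n_seeds), function(s) {
    sim <- generate_comparisons(generator_config(n_genes = 400L, seed = 100L + s))
    grp <- group_comparisons(sim$catalog)
    cfg <- analysis_config()
    mouse_tabs <- apply_atf3_gate(sim$tables[grp$mouse_ScNI], cfg)
    rat_tabs <- apply_atf3_gate(sim$tables[grp$rat_ScNI], cfg)
    mouse_stats <- group_gene_stats(mouse_tabs, cfg)
    rat_stats <- group_gene_stats(rat_tabs, cfg)
    genes <- sim$truth$gene_id
    oc <- build_clusters(
      tibble::tibble(mouse_gene = character(), rat_gene = character(),
                     score = numeric()),
      min_score = 50, mouse_genes = genes, rat_genes = genes
    )
    pc <- call_preference(oc, mouse_stats, rat_stats, cfg)
    called_m <- unlist(oc$mouse_members[pc$status == "mouse-preference"])
    called_r <- unlist(oc$rat_members[pc$status == "rat-preference"])
    truth_m <- sim$truth$gene_id[sim$truth$class == "mouse-preference"]
    truth_r <- sim$truth$gene_id[sim$truth$class == "rat-preference"]
    n_called <- length(called_m) + length(called_r)
    if (n_called == 0L) return(NA_real_)
    (sum(called_m %in% truth_m) + sum(called_r %in% truth_r)) / n_called
  }, numeric(1))
  expect_true(all(!is.na(precisions)))
  expect_true(mean(precisions) >= 0.9)
})
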