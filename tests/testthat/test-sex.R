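test_that("sex calls follow the 3-of-4 marker rule", {
  m <- setNames(c(0, 0, 0, 0), Y_MARKERS)
  expect_identical(infer_sex(m)$call, "female")
  expect_identical(infer_sex(m + 50)$call, "male")
  # enumerate all 16 above/below patterns against the >=3 rule
  for (bits in 0:15) {
    above <- as.logical(bitwAnd(bits, c(1L, 2L, 4L, 8L)) > 0L)
    expr <- setNames(ifelse(above, 50, 0), Y_MARKERS)
    want <- if (sum(above) >= 3) "male" else if (sum(!above) >= 3) "female"
            else "ambiguous"
    expect_identical(infer_sex(expr)$call, want)
  }
})

test_that("unmeasured markers count as below threshold, with warnings", {
  # rat annotation: Ddx3 aliases Ddx3y
  expect_identical(
    infer_sex(c(Uty = 40, Eif2s3y = 30, Kdm5d = 25, Ddx3 = 35))$call,
    "male"
  )
  expect_warning(
    res <- infer_sex(c(Uty = 40, Eif2s3y = 30, Kdm5d = 25)),
    "unmeasured"
  )
  expect_identical(res$call, "male")  # 3 above suffice despite the dropout
  expect_warning(res0 <- infer_sex(c(NotAMarker = 3)), "no Y marker")
  expect_identical(res0$call, "ambiguous")
})

test_that("synthetic samples are sexed perfectly and mixing is flagged", {
  for (s in 1:20) {
    sx <- generate_sexed(generator_config(n_genes = 300L,
                                          n_injury_only = 50L,
                                          n_sex_only = 10L, seed = 200L + s))
    batch <- infer_sex_batch(sx$samples)
    expect_identical(batch$calls$call, sx$samples$sex_true)
  }
  sx <- generate_sexed(generator_config(n_genes = 300L, n_injury_only = 50L,
                                        n_sex_only = 10L, seed = 99L))
  cons <- infer_sex_batch(sx$samples)$consistency
  # the generator's last dataset mixes male and female replicates
  expect_false(cons$consistent[nrow(cons)])
  expect_true(all(cons$consistent[-nrow(cons)]))
})

test_that("four-way partition labels are exclusive and follow the schema", {
  sx <- generate_sexed(generator_config(seed = 42L))
  part <- four_way_partition(sx$tables)
  expect_false(any(duplicated(part$gene_id)))
  truth <- sx$truth
  cls <- truth$class[match(part$gene_id, truth$gene_id)]
  # planted injury-only genes dominate the injury-only label and vice versa
  expect_gt(mean(part$label[cls == "injury-only"] == "injury-only"), 0.9)
  expect_true(all(part$label[cls == "male-marker"] == "sex-only"))
  expect_gt(mean(part$label[cls == "sex-only"] == "sex-only"), 0.9)
  # every DE gene gets exactly one of the four labels
  expect_true(all(part$label %in% c("injury-only", "sex-only", "mixed",
                                    "none")))
  expect_error(four_way_partition(sx$tables[-1]), "female_injury")
})

test_that("direction conflicts and category overlaps are labeled mixed", {
  mk <- function(id, lfc_g) {
    comparison_table(id, tibble::tibble(
      gene_id = c("G", "H"), lfc = c(lfc_g, 0), adj_p = c(1e-6, 0.9)
    ))
  }
  # G up in female injury, down in male injury, silent in sex comparisons
  tabs <- list(female_injury = mk("fi", 2), male_injury = mk("mi", -2),
               sex_control = mk("sc", 0), sex_injury = mk("si", 0))
  part <- four_way_partition(tabs)
  expect_identical(part$label[part$gene_id == "G"], "mixed")
  # G up in both injury comparisons and in a sex comparison -> mixed
  tabs2 <- list(female_injury = mk("fi", 2), male_injury = mk("mi", 2),
                sex_control = mk("sc", 2), sex_injury = mk("si", 0))
  expect_identical(four_way_partition(tabs2)$label[1], "mixed")
  # up in both injury comparisons only -> injury-only
  tabs3 <- list(female_injury = mk("fi", 2), male_injury = mk("mi", 2),
                sex_control = mk("sc", 0), sex_injury = mk("si", 0))
  expect_identical(four_way_partition(tabs3)$label[1], "injury-only")
})

test_that("injury-only correlation behaves at the identities and on synthetic data", {
  x <- c(1, 2, 3, -1)
  expect_equal(injury_only_correlation(x, x)$r, 1)
  expect_equal(injury_only_correlation(x, -x)$r, -1)
  expect_error(injury_only_correlation(1:2, 1:2), "at least 3")

  sx <- generate_sexed(generator_config(seed = 77L))
  part <- four_way_partition(sx$tables)
  io <- part$gene_id[part$label == "injury-only"]
  f <- sx$tables$female_injury$records
  m <- sx$tables$male_injury$records
  res <- injury_only_correlation(f$lfc[match(io, f$gene_id)],
                                 m$lfc[match(io, m$gene_id)])
  expect_gt(res$r, 0.95)
  expect_lt(res$p_value, 1e-4)
})

test_that("octant_split maps the nine sign/threshold patterns distinctly", {
  expect_identical(as.character(octant_split(2, 2)), "up-up")
  expect_identical(as.character(octant_split(2, 0.1)), "female-up-only")
  grid <- expand.grid(f = c(-2, -0.1, 0.1, 2), m = c(-2, -0.1, 0.1, 2))
  labs <- octant_split(grid$f, grid$m)
  big <- abs(grid$f) >= log2(1.5) | abs(grid$m) >= log2(1.5)
  expect_true(all(labs[!big] == "none"))
  # the 8 non-centre regions are all realized and mutually distinct
  expect_setequal(as.character(unique(labs[big])),
                  setdiff(levels(labs), "none"))
  # region labels agree with the sign pattern
  expect_identical(as.character(octant_split(-2, 2)), "down-up")
  expect_identical(as.character(octant_split(-2, -0.2)), "female-down-only")
  expect_identical(as.character(octant_split(0.2, -2)), "male-down-only")
})
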