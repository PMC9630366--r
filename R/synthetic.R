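#' Synthetic-data generator configuration
#'
#' Defines the study conditions the generator emulates: four species x
#' injury-model groups with 8 (mouse SNI), 20 (mouse ScNI), 7 (rat ScNI)
#' and 5 (rat SpNI) comparisons; 53 conserved up-regulated genes (Atf3
#' among them) and a single conserved down-regulated gene (Vstm2b); 34
#' mouse-preference and 42 rat-preference genes; planted effects of
#' |log2FC| = 2 with Gaussian observation noise (sd 0.3) and a 20% chance,
#' per comparison, that an effect gene behaves as a null (dropout);
#' adjusted p-values for true effects drawn log-uniformly between the
#' p-value cap and 1e-4, nulls uniform on [0, 1]; one no-replicate
#' comparison (rat ScNI) emitted without p-values. Time-series datasets
#' cover 9 h, 1 d, 3 d and 7 d post-injury with four temporal archetypes;
#' sexed datasets plant Y-marker effects of log2FC 6 and a shared
#' injury program with between-sex noise sd 0.1.
#'
#' @param n_genes total genes per comparison table (default 2000).
#' @param groups named integer vector of comparisons per species x model
#'   group (names \code{"<species>_<model>"}).
#' @param n_conserved_up,n_conserved_down,n_mouse_pref,n_rat_pref planted
#'   class sizes (defaults 53, 1, 34, 42).
#' @param effect_lfc planted |log2 fold-change| for injury effects
#'   (default 2).
#' @param noise_sd Gaussian sd on observed log2 fold-changes (default 0.3).
#' @param dropout per-comparison probability that an effect gene behaves as
#'   a null (default 0.2); never applied to Atf3 so timepoint gating
#'   stays exercised.
#' @param p_cap,p_max range of the log-uniform adjusted-p draw for true
#'   effects (defaults 1e-20, 1e-4).
#' @param n_norep number of no-replicate comparisons, taken from the rat
#'   ScNI group (default 1).
#' @param timepoints_h time-series sampling times in hours (default 9, 24,
#'   72, 168).
#' @param n_ts_datasets number of time-series datasets (default 2).
#' @param n_per_archetype genes per temporal archetype (default 60).
#' @param ts_noise_sdlog sdlog of the multiplicative lognormal noise on
#'   time-series profiles (default 0.2).
#' @param n_injury_only,n_sex_only planted gene counts for the
#'   sex-dimorphism design (defaults 200, 40).
#' @param sex_noise_sd Gaussian sd on sexed-design fold-changes
#'   (default 0.1).
#' @param marker_lfc planted male-vs-female log2 fold-change of the Y
#'   markers (default 6).
#' @param n_sex_datasets datasets in the sex-inference sample sheet
#'   (default 4; the last one has mixed-sex replicates so the consistency
#'   report has something to flag).
#' @param seed integer seed; all generators are bit-reproducible given it.
#' @return Object of class \code{generator_config}.
#' @export
generator_config <- function(n_genes = 2000L,
                             groups = c(mouse_SNI = 8L, mouse_ScNI = 20L,
                                        rat_ScNI = 7L, rat_SpNI = 5L),
                             n_conserved_up = 53L,
                             n_conserved_down = 1L,
                             n_mouse_pref = 34L,
                             n_rat_pref = 42L,
                             effect_lfc = 2,
                             noise_sd = 0.3,
                             dropout = 0.2,
                             p_cap = 1e-20,
                             p_max = 1e-4,
                             n_norep = 1L,
                             timepoints_h = c(9, 24, 72, 168),
                             n_ts_datasets = 2L,
                             n_per_archetype = 60L,
                             ts_noise_sdlog = 0.2,
                             n_injury_only = 200L,
                             n_sex_only = 40L,
                             sex_noise_sd = 0.1,
                             marker_lfc = 6,
                             n_sex_datasets = 4L,
                             seed = 1L) {
  cfg <- as.list(environment())
  n_planted <- n_conserved_up + n_conserved_down + n_mouse_pref + n_rat_pref
  if (n_planted > n_genes) {
    stop("generator_config: planted class sizes (", n_planted,
         ") exceed n_genes (", n_genes, ")", call. = FALSE)
  }
  if (length(timepoints_h) < 3L) {
    stop("generator_config: need at least three timepoints", call. = FALSE)
  }
  if (is.null(names(groups)) || !all(grepl("_", names(groups)))) {
    stop("generator_config: groups must be named '<species>_<model>'",
         call. = FALSE)
  }
  if (dropout < 0 || dropout >= 1) {
    stop("generator_config: dropout must be in [0, 1)", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

# Planted truth: gene ids, class labels and per-species true log2FC.
make_truth <- function(cfg) {
  ids_cu <- c("Atf3", sprintf("Cup%03d", seq_len(cfg$n_conserved_up - 1L)))
  ids_cd <- if (cfg$n_conserved_down >= 1L) {
    c("Vstm2b", sprintf("Cdn%03d", seq_len(cfg$n_conserved_down - 1L)))
  } else character()
  ids_mp <- sprintf("Mpref%03d", seq_len(cfg$n_mouse_pref))
  ids_rp <- sprintf("Rpref%03d", seq_len(cfg$n_rat_pref))
  n_null <- cfg$n_genes - length(ids_cu) - length(ids_cd) -
    length(ids_mp) - length(ids_rp)
  ids_null <- sprintf("Gene%05d", seq_len(n_null))
  tibble::tibble(
    gene_id = c(ids_cu, ids_cd, ids_mp, ids_rp, ids_null),
    class = c(rep("conserved-up", length(ids_cu)),
              rep("conserved-down", length(ids_cd)),
              rep("mouse-preference", length(ids_mp)),
              rep("rat-preference", length(ids_rp)),
              rep("null", n_null)),
    lfc_mouse = c(rep(cfg$effect_lfc, length(ids_cu)),
                  rep(-cfg$effect_lfc, length(ids_cd)),
                  rep(cfg$effect_lfc, length(ids_mp)),
                  rep(0, length(ids_rp)), rep(0, n_null)),
    lfc_rat = c(rep(cfg$effect_lfc, length(ids_cu)),
                rep(-cfg$effect_lfc, length(ids_cd)),
                rep(0, length(ids_mp)),
                rep(cfg$effect_lfc, length(ids_rp)), rep(0, n_null))
  )
}

#' Generate a synthetic study catalog with per-comparison DEG tables
#'
#' Emulates the cross-study design: per-group comparison counts, planted
#' conserved and species-preference genes, noisy observed log2
#' fold-changes, small adjusted p-values for true effects, per-comparison
#' dropout, no-replicate tables without p-values, and Atf3 always planted
#' conserved-up so every comparison passes the injury gate. Expression
#' columns are emitted (lognormal around class-specific means; the
#' non-responding species of a preference gene is lowly expressed) so the
#' preference filters are exercisable.
#'
#' @param cfg a \code{\link{generator_config}}.
#' @return List with \code{catalog} (\code{\link{study_catalog}}),
#'   \code{tables} (named list of \code{\link{comparison_table}}),
#'   \code{truth} (tibble: gene_id, class, lfc_mouse, lfc_rat), and
#'   \code{config}.
#' @export
generate_comparisons <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    truth <- make_truth(cfg)
    # per-gene baseline expression: preference genes are lowly expressed in
    # the species where they do not respond
    base_expr <- rlnorm(cfg$n_genes, meanlog = log(5), sdlog = 1)
    low_expr_base <- rlnorm(cfg$n_genes, meanlog = log(0.3), sdlog = 0.3)
    tp_cycle <- c(24, 72, 168, 9)
    rows <- list(); tables <- list()
    norep_left <- cfg$n_norep
    for (grp in names(cfg$groups)) {
      parts <- strsplit(grp, "_", fixed = TRUE)[[1L]]
      species <- parts[1L]; model <- parts[2L]
      n_comp <- cfg$groups[[grp]]
      true_lfc <- if (species == "mouse") truth$lfc_mouse else truth$lfc_rat
      other_lfc <- if (species == "mouse") truth$lfc_rat else truth$lfc_mouse
      pref_silent <- truth$class %in% c("mouse-preference", "rat-preference") &
        true_lfc == 0
      gene_base <- ifelse(pref_silent, low_expr_base, base_expr)
      for (j in seq_len(n_comp)) {
        cid <- sprintf("%s_c%02d", grp, j)
        norep <- grp == "rat_ScNI" && j > n_comp - norep_left
        is_effect <- true_lfc != 0
        dropped <- is_effect & truth$gene_id != "Atf3" &
          runif(cfg$n_genes) < cfg$dropout
        eff <- ifelse(is_effect & !dropped, true_lfc, 0)
        lfc_obs <- eff + rnorm(cfg$n_genes, sd = cfg$noise_sd)
        adj_p <- ifelse(
          eff != 0,
          10^runif(cfg$n_genes, log10(cfg$p_cap), log10(cfg$p_max)),
          runif(cfg$n_genes)
        )
        expr_control <- gene_base * exp(rnorm(cfg$n_genes, sd = 0.1))
        rec <- tibble::tibble(
          gene_id = truth$gene_id, lfc = lfc_obs,
          adj_p = if (norep) NA_real_ else adj_p,
          expr_control = expr_control,
          expr_injury = expr_control * 2^lfc_obs
        )
        tables[[cid]] <- comparison_table(cid, rec,
                                          has_replicates = !norep)
        rows[[cid]] <- tibble::tibble(
          comparison_id = cid,
          dataset_accession = sprintf("SYND%03d", length(rows) + 1L),
          species = species, model = model,
          timepoint_h = tp_cycle[(j - 1L) %% length(tp_cycle) + 1L],
          tissue = if (j %% 3L == 0L) "neuron" else "tissue",
          sex = "mixed", has_replicates = !norep
        )
      }
    }
    list(catalog = study_catalog(do.call(rbind, rows)),
         tables = tables, truth = truth, config = cfg)
  })
}

# Temporal archetype templates anchored at 9 h, 1 d, 3 d, 7 d; values at
# other timepoints come from linear interpolation (flat beyond the anchors).
ARCHETYPE_ANCHORS <- list(
  `early-up` = c(0.10, 1.00, 0.90, 0.80),  # Atf3-like: up by 1 d
  `late-up`  = c(0.00, 0.15, 1.00, 0.90),  # Gap43-like: up by 3 d
  down       = c(1.00, 0.50, 0.25, 0.15),  # ion-channel-like decline
  immune     = c(0.00, 0.00, 0.35, 1.00)   # immune: rises 3-7 d
)

archetype_template <- function(archetype, timepoints_h) {
  anchors_t <- c(9, 24, 72, 168)
  stats::approx(anchors_t, ARCHETYPE_ANCHORS[[archetype]],
                xout = timepoints_h, rule = 2)$y
}

#' Generate synthetic time-series expression with planted archetypes
#'
#' Each gene follows one of four temporal archetypes (early-up by 1 d,
#' late-up by 3 d, monotone decline, immune-like rise at 3-7 d); its
#' profile is the archetype template (plus a small baseline) scaled by a
#' gene-specific lognormal amplitude under multiplicative lognormal noise.
#' The same genes are regenerated in every dataset so cluster
#' correspondence across datasets is testable.
#'
#' @param cfg a \code{\link{generator_config}}.
#' @return List with \code{datasets} (named list of genes x timepoints
#'   matrices), \code{truth} (tibble: gene_id, archetype), and
#'   \code{config}.
#' @export
generate_timeseries <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  if (length(cfg$timepoints_h) < 3L) {
    stop("generate_timeseries: need at least three timepoints",
         call. = FALSE)
  }
  with_seed(cfg$seed + 1L, {
    archetypes <- names(ARCHETYPE_ANCHORS)
    truth <- tibble::tibble(
      gene_id = sprintf("TS%s_%03d",
                        rep(c("eu", "lu", "dn", "im"),
                            each = cfg$n_per_archetype),
                        rep(seq_len(cfg$n_per_archetype), 4L)),
      archetype = rep(archetypes, each = cfg$n_per_archetype)
    )
    templates <- vapply(archetypes, archetype_template,
                        numeric(length(cfg$timepoints_h)),
                        timepoints_h = cfg$timepoints_h)
    datasets <- list()
    for (d in seq_len(cfg$n_ts_datasets)) {
      amp <- rlnorm(nrow(truth), meanlog = log(5), sdlog = 0.3)
      tmpl <- t(templates[, truth$archetype, drop = FALSE]) + 0.05
      noise <- matrix(
        rlnorm(nrow(truth) * length(cfg$timepoints_h),
               meanlog = 0, sdlog = cfg$ts_noise_sdlog),
        nrow = nrow(truth)
      )
      x <- amp * tmpl * noise
      dimnames(x) <- list(truth$gene_id,
                          paste0("t", cfg$timepoints_h, "h"))
      datasets[[sprintf("ts_dataset_%02d", d)]] <- x
    }
    list(datasets = datasets, truth = truth, config = cfg)
  })
}

#' Generate the four-comparison sexed design with marker expression
#'
#' Builds the four comparison tables of the sex-dimorphism schema (female
#' injury vs female control, male injury vs male control, male vs female
#' in control, male vs female in injury). Injury-only genes share one true
#' log2 fold-change across sexes (observed with independent noise of sd
#' \code{sex_noise_sd}); sex-only genes respond only in the two
#' male-vs-female comparisons; the four Y markers are planted at log2FC
#' \code{marker_lfc} with underflowed (zero) adjusted p-values in the sex
#' comparisons, mirroring their absence in females. A per-sample Y-marker
#' expression sheet with known sexes accompanies the tables; its last
#' dataset mixes male and female replicates so the consistency report is
#' exercised.
#'
#' @param cfg a \code{\link{generator_config}}.
#' @return List with \code{tables} (named per \code{four_way_partition}'s
#'   schema), \code{samples} (tibble: sample_id, dataset, sex_true and one
#'   column per Y marker), \code{truth} (tibble: gene_id, class,
#'   true_lfc), and \code{config}.
#' @export
generate_sexed <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed + 2L, {
    n_null <- cfg$n_genes - 4L - cfg$n_injury_only - cfg$n_sex_only
    stopifnot(n_null >= 0L)
    ids_inj <- c("Atf3", sprintf("Inj%03d", seq_len(cfg$n_injury_only - 1L)))
    ids_sex <- sprintf("Sexg%03d", seq_len(cfg$n_sex_only))
    ids_null <- sprintf("Gene%05d", seq_len(n_null))
    sign_inj <- ifelse(runif(cfg$n_injury_only) < 0.6, 1, -1)
    sign_inj[1L] <- 1  # Atf3 is up-regulated upon injury
    lfc_inj <- sign_inj * runif(cfg$n_injury_only, 0.8, 3)
    lfc_sex <- ifelse(runif(cfg$n_sex_only) < 0.5, 1, -1) *
      runif(cfg$n_sex_only, 0.8, 2)
    truth <- tibble::tibble(
      gene_id = c(Y_MARKERS, ids_inj, ids_sex, ids_null),
      class = c(rep("male-marker", 4L),
                rep("injury-only", cfg$n_injury_only),
                rep("sex-only", cfg$n_sex_only),
                rep("null", n_null)),
      true_lfc = c(rep(cfg$marker_lfc, 4L), lfc_inj, lfc_sex,
                   rep(0, n_null))
    )
    n <- nrow(truth)
    draw_table <- function(cid, true_eff, p_zero = rep(FALSE, n)) {
      lfc_obs <- true_eff + rnorm(n, sd = cfg$sex_noise_sd)
      adj_p <- ifelse(
        true_eff != 0,
        10^runif(n, log10(cfg$p_cap), log10(cfg$p_max)),
        runif(n)
      )
      adj_p[p_zero] <- 0  # underflow, floored later by the pi-value cap
      comparison_table(cid, tibble::tibble(
        gene_id = truth$gene_id, lfc = lfc_obs, adj_p = adj_p
      ), has_replicates = TRUE)
    }
    inj_eff <- ifelse(truth$class == "injury-only", truth$true_lfc, 0)
    sex_eff <- ifelse(truth$class %in% c("male-marker", "sex-only"),
                      truth$true_lfc, 0)
    markers <- truth$class == "male-marker"
    tables <- list(
      female_injury = draw_table("female_injury", inj_eff),
      male_injury = draw_table("male_injury", inj_eff),
      sex_control = draw_table("sex_control", sex_eff, p_zero = markers),
      sex_injury = draw_table("sex_injury", sex_eff, p_zero = markers)
    )
    comp <- rep(c("male", "male", "female", "mixed"),
                length.out = cfg$n_sex_datasets)
    samples <- list()
    for (d in seq_len(cfg$n_sex_datasets)) {
      sexes <- switch(comp[d],
                      male = rep("male", 4L),
                      female = rep("female", 4L),
                      mixed = c("male", "male", "female", "female"))
      for (s in seq_along(sexes)) {
        if (sexes[s] == "male") {
          expr <- rlnorm(4L, meanlog = log(50), sdlog = 0.5)
        } else {
          expr <- ifelse(runif(4L) < 0.8, 0, runif(4L, 0, 0.3))
        }
        samples[[length(samples) + 1L]] <- tibble::tibble(
          sample_id = sprintf("SXD%02d_s%d", d, s),
          dataset = sprintf("SXD%02d", d),
          sex_true = sexes[s],
          Uty = expr[1L], Eif2s3y = expr[2L], Kdm5d = expr[3L],
          Ddx3y = expr[4L]
        )
      }
    }
    list(tables = tables, samples = do.call(rbind, samples),
         truth = truth, config = cfg)
  })
}
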