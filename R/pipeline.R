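#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run: the synthetic-cohort
#' configuration, the significance thresholds used downstream (chi-squared
#' quantile for the shift test, enrichment p threshold, tau and
#' focal-fraction cuts for tissue specificity), and stage toggles.
#'
#' @param outdir run directory (created if missing).
#' @param seed master seed; also seeds the cohort config unless a custom
#'   `sim` is given.
#' @param sim a [sim_config()].
#' @param sig_quantile chi-squared quantile for shift significance
#'   (default 0.95).
#' @param enrichment_threshold p threshold for reporting enriched terms
#'   (default 0.05).
#' @param tau_min,liver_frac tissue-specificity cuts (defaults 0.6, 0.9).
#' @param n_perm permutations for the complex label test.
#' @param stages character vector of stages to run, in order.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L, sim = sim_config(seed = seed),
                            sig_quantile = 0.95,
                            enrichment_threshold = 0.05,
                            tau_min = 0.6, liver_frac = 0.9,
                            n_perm = 2000L,
                            stages = c(
                              "simulate", "filter", "normalize",
                              "shift_test", "classify", "context", "stats"
                            )) {
  for (thr in c(sig_quantile, enrichment_threshold, tau_min, liver_frac)) {
    if (thr <= 0 || thr >= 1) {
      abort("Thresholds must lie in (0, 1).", class = "ohnoshift_config_error")
    }
  }
  structure(
    list(
      outdir = outdir, seed = as.integer(seed), sim = sim,
      sig_quantile = sig_quantile,
      enrichment_threshold = enrichment_threshold,
      tau_min = tau_min, liver_frac = liver_frac,
      n_perm = as.integer(n_perm), stages = stages
    ),
    class = "pipeline_config"
  )
}

write_stage <- function(x, dir, name) {
  readr::write_tsv(x, file.path(dir, name))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes simulate -> filter -> normalize -> shift-test -> classify ->
#' context -> stats, writing each stage's tables as TSV into the run
#' directory together with a manifest (config hash, seeds, per-stage row
#' counts, file checksums). Re-running with the same config reproduces all
#' outputs exactly; a completed run directory is left untouched unless
#' `force = TRUE`.
#'
#' @param config a [pipeline_config()].
#' @param force re-run even if the directory already holds a completed
#'   manifest.
#' @return The manifest (a list), invisibly.
#' @export
run_pipeline <- function(config, force = FALSE) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(config$outdir, "manifest.json")
  if (file.exists(manifest_path) && !force) {
    inform("Run directory already complete; skipping (use force = TRUE).")
    return(invisible(jsonlite::read_json(manifest_path)))
  }
  counts <- list()
  stages <- config$stages

  # --- simulate ------------------------------------------------------------
  if (!"simulate" %in% stages) {
    abort("The synthetic pipeline requires the simulate stage.")
  }
  tree <- simulate_species_tree(config$sim)
  roles <- attr(tree, "roles")
  species_roles <- attr(tree, "species_roles")
  sims <- simulate_orthogroups(config$sim, tree)
  panel <- simulate_expression(sims, tree, config$sim)
  ctx <- simulate_genomic_context(sims, config$sim)

  writeLines(serialize_newick(tree), file.path(config$outdir, "species_tree.nwk"))
  write_stage(
    tibble::tibble(
      orthogroup = names(sims$trees),
      newick = vapply(sims$trees, serialize_newick, character(1))
    ),
    config$outdir, "gene_trees.tsv"
  )
  expr_tbl <- tibble::as_tibble(panel$values, rownames = "gene")
  write_stage(expr_tbl, config$outdir, "expression_tpm.tsv")
  write_stage(panel$samples, config$outdir, "sample_map.tsv")
  write_stage(sims$truth, config$outdir, "truth.tsv")
  write_stage(ctx$promoters, config$outdir, "promoters.tsv")
  if (nrow(ctx$tes)) write_stage(ctx$tes, config$outdir, "te_intervals.tsv")
  write_stage(ctx$bound_sites, config$outdir, "bound_sites.tsv")
  write_stage(ctx$pathways, config$outdir, "pathway_annotation.tsv")
  write_stage(ctx$complexes, config$outdir, "complex_annotation.tsv")
  counts$simulate <- list(
    trees = length(sims$trees), genes = nrow(sims$truth),
    samples = ncol(panel$values)
  )

  # --- filter --------------------------------------------------------------
  status <- dplyr::bind_rows(lapply(names(sims$trees), function(og) {
    cls <- classify_tree(sims$trees[[og]], species_roles)
    if (cls$status != "rejected") {
      ef <- expression_filters(
        sims$trees[[og]], panel, species_roles,
        sister_anchor = roles$sister_anchor,
        distant_anchors = roles$distant_anchors
      )
      if (ef$status == "rejected") {
        cls$status <- "rejected"
        cls$reason <- ef$reason
      }
    }
    dplyr::bind_cols(tibble::tibble(orthogroup = og), cls)
  }))
  write_stage(status, config$outdir, "tree_status.tsv")
  counts$filter <- as.list(table(status$status))
  accepted <- status$orthogroup[status$status != "rejected"]

  # --- normalize -----------------------------------------------------------
  singleton_ogs <- status$orthogroup[startsWith(status$status, "singleton")]
  singleton_map <- sims$truth[
    sims$truth$orthogroup %in% singleton_ogs,
    c("orthogroup", "species", "gene")
  ]
  panel <- normalize_within_species(panel)
  panel <- normalize_between_species(panel, singleton_map)
  panel <- log_transform(panel)
  write_stage(panel$factors, config$outdir, "normalization_factors.tsv")
  counts$normalize <- list(factors = nrow(panel$factors))

  # --- shift test ----------------------------------------------------------
  calls <- dplyr::bind_rows(lapply(accepted, function(og) {
    units <- extract_test_units(sims$trees[[og]], species_roles, og)
    dplyr::bind_rows(lapply(units, function(u) {
      run_orthogroup(u, panel, tree, roles$ingroup, config$sig_quantile)
    }))
  }))
  write_stage(calls, config$outdir, "shift_calls.tsv")
  counts$shift_test <- list(
    units = nrow(calls), tested = sum(calls$status == "tested")
  )

  # --- classify ------------------------------------------------------------
  pairs <- classify_ohnolog_pairs(calls)
  if (nrow(pairs)) {
    focal_sp <- ctx$planted$focal_species
    pairs$asymmetry <- vapply(pairs$orthogroup, function(og) {
      tr <- sims$truth[sims$truth$orthogroup == og, ]
      expression_asymmetry(
        tr[tr$copy == "a" & !is.na(tr$copy), c("gene", "species")],
        tr[tr$copy == "b" & !is.na(tr$copy), c("gene", "species")],
        panel
      )
    }, numeric(1))
    pairs$gene_1 <- vapply(pairs$orthogroup, function(og) {
      tr <- sims$truth
      g <- tr$gene[tr$orthogroup == og & tr$species == focal_sp &
        tr$copy == "a" & !is.na(tr$copy)]
      if (length(g)) g[1] else NA_character_
    }, character(1))
    pairs$gene_2 <- vapply(pairs$orthogroup, function(og) {
      tr <- sims$truth
      g <- tr$gene[tr$orthogroup == og & tr$species == focal_sp &
        tr$copy == "b" & !is.na(tr$copy)]
      if (length(g)) g[1] else NA_character_
    }, character(1))
    pairs <- rank_pair_by_shift(
      pairs[!is.na(pairs$gene_1) & !is.na(pairs$gene_2), ]
    )
  }
  write_stage(pairs, config$outdir, "ohnolog_pairs.tsv")
  counts$classify <- list(pairs = nrow(pairs))

  # --- context -------------------------------------------------------------
  te_load <- overlap_fraction(ctx$promoters, ctx$tes)
  names(te_load)[1] <- "gene"
  write_stage(te_load, config$outdir, "promoter_te_load.tsv")
  liver_tfs <- ctx$tf_info$tf[ctx$tf_info$liver_specific]
  bsc <- count_bound_sites(
    ctx$bound_sites, unique(ctx$bound_sites$gene),
    mode = "sites"
  )
  write_stage(bsc, config$outdir, "bound_site_counts.tsv")
  counts$context <- list(
    promoters = nrow(ctx$promoters), te_load_rows = nrow(te_load)
  )

  # --- stats ---------------------------------------------------------------
  stat_rows <- list()
  dc <- pairs[pairs$category == "down+cons", ]
  if (nrow(dc) >= 3) {
    down_gene <- ifelse(dc$direction_1 == "down", dc$gene_1, dc$gene_2)
    cons_gene <- ifelse(dc$direction_1 == "down", dc$gene_2, dc$gene_1)
    lf <- setNames(te_load$fraction, te_load$gene)
    wt <- wilcoxon_signed_rank(
      unname(lf[down_gene]), unname(lf[cons_gene]), "greater"
    )
    stat_rows$te_load <- tibble::tibble(
      test = "te_load_down_vs_cons", statistic = wt$statistic, p = wt$p,
      n = wt$n
    )
  }
  down_cats <- c("down+cons", "down+down", "up+down")
  down_ogs <- pairs$orthogroup[pairs$category %in% down_cats]
  bg_genes <- unique(ctx$pathways$gene)
  set_genes <- intersect(
    bg_genes,
    sims$truth$gene[sims$truth$orthogroup %in% down_ogs]
  )
  if (length(set_genes)) {
    enr <- pathway_enrichment(set_genes, bg_genes, ctx$pathways)
    write_stage(enr, config$outdir, "pathway_enrichment.tsv")
    stat_rows$enrichment <- tibble::tibble(
      test = "top_pathway_enrichment", statistic = NA_real_,
      p = enr$p[1], n = length(set_genes)
    )
  }
  labels <- setNames(
    ifelse(
      sims$truth$tree_class[match(
        unique(ctx$complexes$gene), sims$truth$gene
      )] == "ohnolog", "ohnolog", "singleton"
    ),
    unique(ctx$complexes$gene)
  )
  perm <- complex_label_permutation(
    ctx$complexes[, c("complex", "gene")], labels,
    n_perm = config$n_perm, statistic = "n_only_ohnolog",
    seed = stage_seed(config$seed, "perm")
  )
  stat_rows$complex <- tibble::tibble(
    test = "complex_only_ohnolog", statistic = perm$observed, p = perm$p,
    n = perm$n_perm
  )
  stats_tbl <- dplyr::bind_rows(stat_rows)
  write_stage(stats_tbl, config$outdir, "stats.tsv")
  counts$stats <- list(tests = nrow(stats_tbl))

  # --- manifest ------------------------------------------------------------
  files <- sort(setdiff(list.files(config$outdir), "manifest.json"))
  manifest <- list(
    package = "ohnoshift",
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "outdir")]),
    counts = counts,
    files = as.list(setNames(
      unname(tools::md5sum(file.path(config$outdir, files))), files
    ))
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Summarize a completed pipeline run
#'
#' Reads the stage outputs back and produces the report tables: per-class
#' proportions of trees with a significant expression shift (split by
#' shift direction), ohnolog pair category counts, and asymmetry
#' summaries per category.
#'
#' @param run_dir a directory written by [run_pipeline()].
#' @return List of tibbles: `shift_proportions`, `category_counts`,
#'   `asymmetry`, `stats`.
#' @export
summarize_run <- function(run_dir) {
  read_stage <- function(name) {
    readr::read_tsv(file.path(run_dir, name), show_col_types = FALSE)
  }
  status <- read_stage("tree_status.tsv")
  calls <- read_stage("shift_calls.tsv")
  pairs <- read_stage("ohnolog_pairs.tsv")
  stats_tbl <- read_stage("stats.tsv")

  calls <- dplyr::left_join(
    calls, status[, c("orthogroup", "status")],
    by = "orthogroup", suffix = c("", "_tree")
  )
  per_tree <- dplyr::summarise(
    dplyr::group_by(calls[calls$status == "tested", ], .data$orthogroup),
    tree_class = .data$status_tree[1],
    any_significant = any(.data$significant),
    any_up = any(.data$significant & .data$direction == "up"),
    any_down = any(.data$significant & .data$direction == "down"),
    .groups = "drop"
  )
  shift_proportions <- dplyr::summarise(
    dplyr::group_by(per_tree, .data$tree_class),
    n_trees = dplyr::n(),
    prop_shifted = mean(.data$any_significant),
    prop_up = mean(.data$any_up),
    prop_down = mean(.data$any_down),
    .groups = "drop"
  )
  category_counts <- dplyr::count(pairs, .data$category, name = "n")
  asymmetry <- dplyr::summarise(
    dplyr::group_by(pairs, .data$category),
    n = dplyr::n(),
    median_asymmetry = median(.data$asymmetry, na.rm = TRUE),
    .groups = "drop"
  )
  list(
    shift_proportions = shift_proportions,
    category_counts = category_counts,
    asymmetry = asymmetry,
    stats = stats_tbl
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; a `sim` block
#' mirrors [sim_config()].
#'
#' @param path YAML file path.
#' @param outdir run directory (overrides any `outdir` in the file if
#'   given).
#' @return A validated [pipeline_config()].
#' @export
pipeline_config_from_yaml <- function(path, outdir = NULL) {
  raw <- yaml::read_yaml(path)
  if (!is.null(outdir)) raw$outdir <- outdir
  if (!is.null(raw$sim)) {
    sim_raw <- raw$sim
    if (!is.null(sim_raw$shift_spec)) {
      sim_raw$shift_spec <- dplyr::bind_rows(
        lapply(sim_raw$shift_spec, tibble::as_tibble)
      )
    }
    raw$sim <- do.call(sim_config, sim_raw)
  }
  do.call(pipeline_config, raw)
}
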