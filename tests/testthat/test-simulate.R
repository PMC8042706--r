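test_that("sim_config validates the study design knobs", {
  expect_error(sim_config(n_species_ingroup = 1), class = "ohnoshift_config_error")
  expect_error(sim_config(n_outgroups = 0), class = "ohnoshift_config_error")
  expect_error(sim_config(replicates_per_species = 1), class = "ohnoshift_config_error")
  expect_error(sim_config(alpha = -1), class = "ohnoshift_config_error")
  expect_error(
    sim_config(shift_spec = tibble::tibble(
      category = c("up+cons", "down+cons"), fraction = c(0.7, 0.6),
      delta_theta = 2
    )),
    class = "ohnoshift_config_error"
  )
  expect_warning(sim_config(frac_partial = 1.4), "clamped")
})

test_that("the species tree is ultrametric with a marked duplicated lineage", {
  cfg <- sim_config(seed = 3)
  tr <- simulate_species_tree(cfg)
  expect_equal(ape::Ntip(tr), 7L)
  depths <- ape::node.depth.edgelength(tr)[seq_len(7)]
  expect_equal(depths, rep(1, 7), tolerance = 1e-9) # root depth normalized
  expect_true(all(tr$edge.length > 0))
  roles <- attr(tr, "species_roles")
  ing <- names(roles)[roles == "ingroup"]
  expect_length(ing, 4L)
  expect_true(ape::is.monophyletic(tr, ing))
  # determinism: identical Newick under the same config
  expect_identical(
    serialize_newick(simulate_species_tree(cfg)),
    serialize_newick(tr)
  )
  # alternative design sizes
  tr2 <- simulate_species_tree(sim_config(n_species_ingroup = 5, n_outgroups = 2))
  expect_equal(ape::Ntip(tr2), 7L)
})

test_that("orthogroup simulation respects class counts and partial labels", {
  cfg <- sim_config(seed = 11, n_singleton_trees = 20, n_ohnolog_trees = 30)
  tr <- simulate_species_tree(cfg)
  sims <- simulate_orthogroups(cfg, tr)
  expect_length(sims$trees, 50L)
  info <- sims$tree_info
  expect_equal(sum(info$tree_class == "singleton"), 20L)
  expect_equal(sum(info$tree_class == "ohnolog"), 30L)
  roles <- attr(tr, "species_roles")
  ing <- names(roles)[roles == "ingroup"]
  # complete/partial labels match an independent recount of tips per clade
  for (og in info$orthogroup) {
    gt <- sims$trees[[og]]
    sp_in <- species_of(gt$tip.label)
    n_in_tips <- sum(sp_in %in% ing)
    expected_tips <- if (info$tree_class[info$orthogroup == og] == "ohnolog") 8 else 4
    if (info$complete[info$orthogroup == og]) {
      expect_equal(n_in_tips, expected_tips)
    } else {
      expect_lt(n_in_tips, expected_tips)
    }
    # classifier agrees with the emitted class
    cls <- classify_tree(gt, roles)
    expect_equal(
      sub("-.*", "", cls$status),
      info$tree_class[info$orthogroup == og]
    )
    expect_equal(
      cls$status,
      paste0(
        info$tree_class[info$orthogroup == og],
        if (info$complete[info$orthogroup == og]) "-complete" else "-partial"
      )
    )
  }
  # frac_partial = 0 gives only complete trees; no ohnologs -> no 2-clade tree
  cfg0 <- sim_config(seed = 2, frac_partial = 0, n_ohnolog_trees = 0)
  sims0 <- simulate_orthogroups(cfg0, simulate_species_tree(cfg0))
  expect_true(all(sims0$tree_info$complete))
  expect_true(all(sims0$tree_info$tree_class == "singleton"))
})

test_that("every emitted gene appears in the truth table exactly once", {
  cfg <- sim_config(seed = 21, n_singleton_trees = 10, n_ohnolog_trees = 10)
  tr <- simulate_species_tree(cfg)
  sims <- simulate_orthogroups(cfg, tr)
  tree_genes <- unlist(lapply(sims$trees, function(t) t$tip.label))
  expect_setequal(tree_genes, sims$truth$gene)
  expect_equal(anyDuplicated(sims$truth$gene), 0L)
  panel <- simulate_expression(sims, tr, cfg)
  expect_setequal(rownames(panel$values), sims$truth$gene)
  ctx <- simulate_genomic_context(sims, cfg)
  expect_true(all(ctx$promoters$name %in% sims$truth$gene))
  expect_true(all(ctx$pathways$gene %in% sims$truth$gene))
})

test_that("simulated expression is deterministic and respects planted regimes", {
  cfg <- sim_config(seed = 31, n_singleton_trees = 5, n_ohnolog_trees = 5)
  tr <- simulate_species_tree(cfg)
  sims <- simulate_orthogroups(cfg, tr)
  p1 <- simulate_expression(sims, tr, cfg)
  p2 <- simulate_expression(sims, tr, cfg)
  expect_identical(p1$values, p2$values) # bitwise under the same seed
  expect_true(all(p1$values >= 0, na.rm = TRUE))
  # all-conserved spec plants no shift anywhere
  cfg0 <- sim_config(
    seed = 32,
    shift_spec = tibble::tibble(
      category = "up+cons", fraction = 0, delta_theta = 2
    )
  )
  sims0 <- simulate_orthogroups(cfg0, simulate_species_tree(cfg0))
  expect_true(all(sims0$truth$delta_theta == 0))
  expect_true(all(sims0$truth$copy_direction == "cons"))
})

test_that("strong pull pushes the ingroup mean to the planted optimum", {
  # alpha large: ingroup log2 mean - outgroup log2 mean approaches the
  # planted delta within Monte-Carlo error
  cfg <- sim_config(
    seed = 41, n_singleton_trees = 300, n_ohnolog_trees = 0,
    alpha = 60, sigma2 = 60 * 2 * 0.04, beta = 0.25,
    shift_spec = tibble::tibble(
      category = "up", fraction = 1, delta_theta = 2
    ),
    frac_partial = 0
  )
  tr <- simulate_species_tree(cfg)
  sims <- simulate_orthogroups(cfg, tr)
  panel <- log_transform(simulate_expression(sims, tr, cfg))
  roles <- attr(tr, "species_roles")
  ing_cols <- panel$samples$sample[
    panel$samples$species %in% names(roles)[roles == "ingroup"]
  ]
  out_cols <- setdiff(colnames(panel$values), ing_cols)
  diffs <- vapply(sims$tree_info$orthogroup, function(og) {
    genes <- sims$truth$gene[sims$truth$orthogroup == og]
    m <- panel$values[genes, , drop = FALSE]
    mean(m[, ing_cols], na.rm = TRUE) - mean(m[, out_cols], na.rm = TRUE)
  }, numeric(1))
  expect_equal(mean(diffs), 2, tolerance = 0.1)
})

test_that("species-mean covariance matches the OU covariance on a 2-tip tree", {
  # direct distributional check of the generator's MVN draw
  cfg <- sim_config(seed = 51)
  tr2 <- parse_newick("(A:1,B:1);")
  s <- cfg$sigma2 / (2 * cfg$alpha)
  withr::with_seed(52, {
    u <- chol(s * exp(-cfg$alpha * ape::cophenetic.phylo(tr2)))
    draws <- t(vapply(
      seq_len(4000),
      function(i) drop(t(u) %*% rnorm(2)),
      numeric(2)
    ))
  })
  emp <- cov(draws)
  expect_equal(emp[1, 1], s, tolerance = 0.05)
  expect_equal(emp[1, 2], s * exp(-cfg$alpha * 2), tolerance = 0.05)
})

test_that("genomic context plants the advertised biases", {
  cfg <- sim_config(seed = 61, n_singleton_trees = 30, n_ohnolog_trees = 120)
  tr <- simulate_species_tree(cfg)
  sims <- simulate_orthogroups(cfg, tr)
  ctx <- simulate_genomic_context(sims, cfg)

  # planted pathway attains the smallest enrichment p among down genes
  focal <- ctx$planted$focal_species
  down_genes <- sims$truth$gene[
    sims$truth$species == focal & sims$truth$copy_direction == "down"
  ]
  bg <- unique(ctx$pathways$gene)
  enr <- pathway_enrichment(intersect(down_genes, bg), bg, ctx$pathways)
  expect_equal(enr$term[1], ctx$planted$enriched_pathway)

  # te_rate = 0 silences TE load entirely
  cfg0 <- sim_config(seed = 62, n_singleton_trees = 5, n_ohnolog_trees = 5, te_rate = 0)
  sims0 <- simulate_orthogroups(cfg0, simulate_species_tree(cfg0))
  ctx0 <- simulate_genomic_context(sims0, cfg0)
  expect_equal(nrow(ctx0$tes), 0L)
  frac0 <- overlap_fraction(ctx0$promoters, ctx0$tes)
  expect_true(all(frac0$fraction == 0))

  # TE load is elevated in promoters of down-shifted copies
  te_load <- overlap_fraction(ctx$promoters, ctx$tes)
  down_load <- te_load$fraction[te_load$name %in% down_genes]
  cons_load <- te_load$fraction[!(te_load$name %in% down_genes)]
  expect_gt(mean(down_load), mean(cons_load))

  # bound-site table is internally consistent
  expect_true(all(
    (ctx$bound_sites$te_superfamily == "") == !ctx$bound_sites$te_overlap
  ))
})
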