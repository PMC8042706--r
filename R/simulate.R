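#' Configuration for the synthetic study cohort
#'
#' Bundles every knob of the synthetic-data generator: the species design
#' (four duplicated-lineage "ingroup" species, three outgroups, four
#' replicates each — the study design the package targets), the orthogroup
#' mix, the planted expression-shift spectrum, the OU process parameters,
#' and the genomic-context rates. The generator draws every stage from a
#' sub-stream derived deterministically from `seed`, so identical configs
#' give byte-identical cohorts and stages can be re-run independently.
#'
#' `shift_spec` rows plant true optimum shifts: pair categories
#' (`up+cons`, `down+cons`, `up+up`, `down+down`, `up+down`) apply to
#' ohnolog trees and single categories (`up`, `down`) to singleton trees;
#' within each tree class the fractions must sum to at most 1 and the
#' remainder is fully conserved (`cons+cons` / `cons`). `delta_theta` is the
#' shift magnitude in log2 units (sign comes from the direction in the
#' category name).
#'
#' @param seed integer master seed.
#' @param n_species_ingroup number of ingroup species (>= 2, default 4).
#' @param n_outgroups number of outgroup species (>= 1, default 3).
#' @param replicates_per_species biological replicates per species (>= 2,
#'   default 4).
#' @param n_singleton_trees,n_ohnolog_trees orthogroup counts per class.
#' @param frac_partial share of trees with at least one ingroup tip deleted
#'   (clamped to \[0, 1\] with a warning).
#' @param shift_spec data frame `category`, `fraction`, `delta_theta`.
#' @param alpha,sigma2,beta OU parameters (see [ou_params()]); defaults give
#'   pull `alpha * root depth = 2`, stationary variance 0.5 log2^2, and a
#'   within-species variance ratio of 0.3.
#' @param theta_base_mean,theta_base_sd distribution of baseline optima
#'   (log2 TPM units).
#' @param promoter_len promoter length in bases (upstream + downstream
#'   window, default 2200 = 2000/200).
#' @param te_rate expected TE insertions per promoter.
#' @param te_down_bias multiplicative TE-rate factor for down-shifted
#'   copies (the planted TE-load bias; 1 = no bias).
#' @param tfbs_rate expected TFBS rows per promoter.
#' @param tfbs_up_bias multiplicative rate factor for bound liver-TF sites
#'   in up-shifted copies.
#' @param n_pathways,n_complexes annotation pool sizes.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_species_ingroup = 4L,
                       n_outgroups = 3L,
                       replicates_per_species = 4L,
                       n_singleton_trees = 60L,
                       n_ohnolog_trees = 90L,
                       frac_partial = 0.25,
                       shift_spec = default_shift_spec(),
                       alpha = 2, sigma2 = 2, beta = 0.3,
                       theta_base_mean = 5, theta_base_sd = 1.5,
                       promoter_len = 2200L,
                       te_rate = 1.5,
                       te_down_bias = 2.5,
                       tfbs_rate = 12,
                       tfbs_up_bias = 2,
                       n_pathways = 8L,
                       n_complexes = 12L) {
  if (n_species_ingroup < 2L || n_outgroups < 1L) {
    abort("Need at least 2 ingroup species and 1 outgroup.",
      class = "ohnoshift_config_error"
    )
  }
  if (replicates_per_species < 2L) {
    abort("Need at least 2 replicates per species.",
      class = "ohnoshift_config_error"
    )
  }
  if (alpha <= 0 || sigma2 <= 0 || beta <= 0 || te_rate < 0 ||
    tfbs_rate < 0 || promoter_len <= 0) {
    abort("Rate and variance parameters must be positive.",
      class = "ohnoshift_config_error"
    )
  }
  if (frac_partial < 0 || frac_partial > 1) {
    warn("`frac_partial` clamped to [0, 1].")
    frac_partial <- min(max(frac_partial, 0), 1)
  }
  shift_spec <- tibble::as_tibble(shift_spec)
  stopifnot(all(c("category", "fraction", "delta_theta") %in% names(shift_spec)))
  pair_cats <- c("up+cons", "down+cons", "up+up", "down+down", "up+down")
  single_cats <- c("up", "down")
  bad <- setdiff(shift_spec$category, c(pair_cats, single_cats))
  if (length(bad)) {
    abort(paste0("Unknown shift categories: ", paste(bad, collapse = ", ")),
      class = "ohnoshift_config_error"
    )
  }
  for (cls in list(pair_cats, single_cats)) {
    tot <- sum(shift_spec$fraction[shift_spec$category %in% cls])
    if (tot > 1 + 1e-12) {
      abort("shift_spec fractions must sum to <= 1 within a tree class.",
        class = "ohnoshift_config_error"
      )
    }
  }
  structure(
    list(
      seed = as.integer(seed),
      n_species_ingroup = as.integer(n_species_ingroup),
      n_outgroups = as.integer(n_outgroups),
      replicates_per_species = as.integer(replicates_per_species),
      n_singleton_trees = as.integer(n_singleton_trees),
      n_ohnolog_trees = as.integer(n_ohnolog_trees),
      frac_partial = frac_partial,
      shift_spec = shift_spec,
      alpha = alpha, sigma2 = sigma2, beta = beta,
      theta_base_mean = theta_base_mean, theta_base_sd = theta_base_sd,
      promoter_len = as.integer(promoter_len),
      te_rate = te_rate, te_down_bias = te_down_bias,
      tfbs_rate = tfbs_rate, tfbs_up_bias = tfbs_up_bias,
      n_pathways = as.integer(n_pathways),
      n_complexes = as.integer(n_complexes)
    ),
    class = "sim_config"
  )
}

#' Default planted shift spectrum
#'
#' Mostly conserved pairs with a down-biased asymmetric remainder, echoing
#' the down-bias observed after duplication; shift magnitude 2 log2 units.
#'
#' @return Tibble `category`, `fraction`, `delta_theta`.
#' @export
default_shift_spec <- function() {
  tibble::tibble(
    category = c(
      "up+cons", "down+cons", "up+up", "down+down", "up+down",
      "up", "down"
    ),
    fraction = c(0.10, 0.15, 0.05, 0.07, 0.03, 0.10, 0.08),
    delta_theta = 2
  )
}

sim_species_names <- function(config) {
  ingroup_pool <- c("Ssal", "Omyk", "Salp", "Okis", "Tthy", "Hhuc")
  outgroup_pool <- c("Eluc", "Drer", "Olat", "Gacu", "Locu")
  n_in <- config$n_species_ingroup
  n_out <- config$n_outgroups
  ingroup <- if (n_in <= length(ingroup_pool)) {
    ingroup_pool[seq_len(n_in)]
  } else {
    c(ingroup_pool, sprintf("Ing%02d", seq_len(n_in - length(ingroup_pool))))
  }
  outgroup <- if (n_out <= length(outgroup_pool)) {
    outgroup_pool[seq_len(n_out)]
  } else {
    c(outgroup_pool, sprintf("Out%02d", seq_len(n_out - length(outgroup_pool))))
  }
  list(
    ingroup = ingroup,
    sister_anchor = outgroup[1],
    distant_anchors = if (n_out >= 3) outgroup[2:3] else outgroup[-1],
    outgroup = outgroup
  )
}

# ladder subtree over `tips`: t_join gives the length(tips) - 1 join
# times, deepest first (tips[1] joins at t_join[1]); all tips end at age
# t_tip. Returns the newick fragment without a trailing ";".
ladder_newick <- function(tips, t_join, t_tip) {
  if (length(tips) == 1L) {
    return(list(str = tips, t = t_tip))
  }
  sub <- list(str = tips[length(tips)], t = t_tip)
  for (i in rev(seq_along(t_join))) {
    left <- tips[i]
    t0 <- t_join[i]
    sub <- list(
      str = paste0(
        "(", left, ":", format(t_tip - t0, digits = 10), ",",
        sub$str, ":", format(sub$t - t0, digits = 10), ")"
      ),
      t = t0
    )
  }
  sub
}

#' Simulate the species tree
#'
#' Builds the rooted ultrametric species tree for the synthetic cohort:
#' root depth normalized to 1 time unit, outgroups branching off on a
#' ladder between the root and 0.3, the ingroup crown at 0.7 (so the
#' ingroup stem — the WGD/shift branch — spans 0.3 to 0.7), and ingroup
#' splits laddered between 0.7 and the tips. Fully deterministic given the
#' config.
#'
#' @param config a [sim_config()].
#' @return A `phylo` with attributes `species_roles` (named vector of
#'   `"ingroup"`/`"outgroup"`), `roles` (ingroup / sister / distant anchor
#'   lists), and `wgd_time` (0.55, the duplication node age used for
#'   ohnolog gene trees).
#' @export
simulate_species_tree <- function(config) {
  sp <- sim_species_names(config)
  n_in <- config$n_species_ingroup
  n_out <- config$n_outgroups
  t_crown <- 0.7
  in_joins <- if (n_in > 1) {
    seq(t_crown, 0.9, length.out = n_in)[seq_len(n_in - 1)]
  } else {
    numeric()
  }
  ing <- ladder_newick(sp$ingroup, in_joins, 1)
  out_joins <- if (n_out > 1) seq(0, 0.3, length.out = n_out) else 0
  # attach the sister outgroup first (deepest join at 0.3), then
  # progressively more distant outgroups down to the root at time 0
  cur <- ing
  cur_t <- t_crown
  for (k in seq_len(n_out)) {
    og <- sp$outgroup[k]
    t0 <- out_joins[n_out - k + 1]
    cur <- list(
      str = paste0(
        "(", og, ":", format(1 - t0, digits = 10), ",",
        cur$str, ":", format(cur_t - t0, digits = 10), ")"
      ),
      t = t0
    )
    cur_t <- t0
  }
  tree <- parse_newick(paste0(cur$str, ";"))
  roles <- setNames(
    c(
      rep("ingroup", n_in),
      rep("outgroup", n_out)
    ),
    c(sp$ingroup, sp$outgroup)
  )
  attr(tree, "species_roles") <- roles
  attr(tree, "roles") <- sp
  attr(tree, "wgd_time") <- 0.55
  tree
}

pair_copy_directions <- function(category) {
  parts <- strsplit(category, "+", fixed = TRUE)[[1]]
  if (length(parts) == 1L) {
    return(parts)
  }
  parts
}

#' Simulate orthogroup gene trees with known truth
#'
#' Emits singleton gene trees (the species tree with gene tip labels) and
#' ohnolog gene trees (the ingroup stem split at the duplication node into
#' two duplicate clades, outgroups unduplicated). A `frac_partial` share of
#' trees has 1 or more tips deleted from one duplicate clade (never
#' breaking monophyly); those trees are `partial`. True shift categories
#' are drawn from `config$shift_spec`, with the shifted copy chosen at
#' random for asymmetric categories.
#'
#' @param config a [sim_config()].
#' @param tree the species tree from [simulate_species_tree()].
#' @return List with `trees` (named list of `phylo`), `truth` (tibble, one
#'   row per gene: `orthogroup`, `gene`, `species`, `tree_class`, `copy`,
#'   `category`, `copy_direction`, `theta_base`, `delta_theta` (signed),
#'   `complete`), and `tree_info` (per-tree class/label tibble).
#' @export
simulate_orthogroups <- function(config, tree) {
  sp <- attr(tree, "roles")
  wgd_time <- attr(tree, "wgd_time") %||% 0.55
  n_in <- config$n_species_ingroup
  with_seed(stage_seed(config$seed, "orthogroups"), {
    spec <- config$shift_spec
    pair_cats <- c("up+cons", "down+cons", "up+up", "down+down", "up+down")
    draw_cat <- function(n, cats, base) {
      f <- spec$fraction[match(cats, spec$category)]
      f[is.na(f)] <- 0
      probs <- c(f, 1 - sum(f))
      sample(c(cats, base), n, replace = TRUE, prob = probs)
    }
    n_s <- config$n_singleton_trees
    n_o <- config$n_ohnolog_trees
    og_ids <- sprintf("OG%05d", seq_len(n_s + n_o))
    classes <- c(rep("singleton", n_s), rep("ohnolog", n_o))
    cats <- character(n_s + n_o)
    if (n_s > 0) cats[seq_len(n_s)] <- draw_cat(n_s, c("up", "down"), "cons")
    if (n_o > 0) cats[n_s + seq_len(n_o)] <- draw_cat(n_o, pair_cats, "cons+cons")
    partial <- runif(n_s + n_o) < config$frac_partial
    theta_base <- rnorm(n_s + n_o, config$theta_base_mean, config$theta_base_sd)

    delta_of <- function(cat, dir) {
      if (dir == "cons") {
        return(0)
      }
      d <- spec$delta_theta[match(cat, spec$category)]
      if (is.na(d)) d <- 2
      if (dir == "down") -d else d
    }

    trees <- vector("list", n_s + n_o)
    truth_rows <- vector("list", n_s + n_o)
    info_rows <- vector("list", n_s + n_o)
    ingroup_times <- seq(0.7, 0.9, length.out = n_in)[seq_len(max(n_in - 1, 0))]

    for (i in seq_along(og_ids)) {
      og <- og_ids[i]
      if (classes[i] == "singleton") {
        keep_in <- sp$ingroup
        if (partial[i] && n_in > 1) {
          n_drop <- sample.int(n_in - 1, 1)
          keep_in <- sample(sp$ingroup, n_in - n_drop)
          keep_in <- sp$ingroup[sp$ingroup %in% keep_in]
        }
        gt <- ape::keep.tip(tree, c(keep_in, sp$outgroup))
        gt$tip.label <- paste0(gt$tip.label, "|", og)
        dirs <- setNames(cats[i], "a")
        copies <- list(a = paste0(keep_in, "|", og))
      } else {
        # duplicate the ingroup subtree at the duplication node
        keep_a <- sp$ingroup
        keep_b <- sp$ingroup
        if (partial[i] && n_in > 1) {
          n_drop <- sample.int(n_in - 1, 1)
          drop_from_b <- sample(sp$ingroup, n_drop)
          keep_b <- setdiff(sp$ingroup, drop_from_b)
        }
        clade_a <- ladder_newick(
          paste0(keep_a, "|", og, "a"),
          ingroup_times[seq_len(length(keep_a) - 1)], 1
        )
        clade_b <- if (length(keep_b) >= 2) {
          ladder_newick(
            paste0(keep_b, "|", og, "b"),
            seq(0.7, 0.9, length.out = length(keep_b))[seq_len(length(keep_b) - 1)], 1
          )
        } else {
          list(str = paste0(keep_b, "|", og, "b"), t = 1)
        }
        dup <- list(
          str = paste0(
            "(", clade_a$str, ":", format(clade_a$t - wgd_time, digits = 10),
            ",", clade_b$str, ":", format(clade_b$t - wgd_time, digits = 10),
            ")"
          ),
          t = wgd_time
        )
        cur <- dup
        cur_t <- wgd_time
        out_joins <- if (config$n_outgroups > 1) {
          seq(0, 0.3, length.out = config$n_outgroups)
        } else {
          0
        }
        for (k in seq_len(config$n_outgroups)) {
          ogn <- sp$outgroup[k]
          t0 <- out_joins[config$n_outgroups - k + 1]
          cur <- list(
            str = paste0(
              "(", ogn, "|", og, ":", format(1 - t0, digits = 10), ",",
              cur$str, ":", format(cur_t - t0, digits = 10), ")"
            ),
            t = t0
          )
          cur_t <- t0
        }
        gt <- parse_newick(paste0(cur$str, ";"))
        cat_dirs <- pair_copy_directions(cats[i])
        # random copy assignment for asymmetric categories
        if (length(cat_dirs) == 2L && runif(1) < 0.5) cat_dirs <- rev(cat_dirs)
        dirs <- setNames(cat_dirs, c("a", "b"))
        copies <- list(
          a = paste0(keep_a, "|", og, "a"),
          b = paste0(keep_b, "|", og, "b")
        )
      }
      complete <- !partial[i]
      trees[[i]] <- gt
      info_rows[[i]] <- tibble::tibble(
        orthogroup = og, tree_class = classes[i], category = cats[i],
        complete = complete
      )
      gene_rows <- lapply(names(copies), function(cp) {
        genes <- copies[[cp]]
        dir <- dirs[[cp]]
        tibble::tibble(
          orthogroup = og, gene = genes, species = species_of(genes),
          tree_class = classes[i], copy = cp, category = cats[i],
          copy_direction = dir, theta_base = theta_base[i],
          delta_theta = vapply(
            rep(cats[i], length(genes)),
            function(cc) delta_of(cc, dir), numeric(1)
          ),
          complete = complete
        )
      })
      out_genes <- paste0(sp$outgroup, "|", og)
      gene_rows <- c(gene_rows, list(tibble::tibble(
        orthogroup = og, gene = out_genes, species = sp$outgroup,
        tree_class = classes[i], copy = NA_character_, category = cats[i],
        copy_direction = "cons", theta_base = theta_base[i],
        delta_theta = 0, complete = complete
      )))
      truth_rows[[i]] <- dplyr::bind_rows(gene_rows)
    }
    names(trees) <- og_ids
    list(
      trees = trees,
      truth = dplyr::bind_rows(truth_rows),
      tree_info = dplyr::bind_rows(info_rows)
    )
  })
}

#' Simulate replicate expression for a cohort
#'
#' For every orthogroup, gene-level species means are drawn from the
#' multivariate normal implied by the OU model on that orthogroup's gene
#' tree: mean vector from the true regime painting (each shifted copy's
#' clade, stem included, pulled towards `theta_base + delta_theta`) and
#' stationary covariance `sigma2/(2*alpha) * exp(-alpha * d)`. For ohnolog
#' trees the duplicate clades and outgroups are drawn jointly on the
#' duplicated tree, so the two copies share outgroup data exactly as in the
#' analysis. Replicates add independent within-species noise of variance
#' `beta * sigma2 / (2*alpha)`. Values are stored on the TPM scale via the
#' inverse of `log2(x + 0.01)`, floored at zero (floor events are counted
#' in the `n_floored` attribute).
#'
#' @param sims output of [simulate_orthogroups()].
#' @param tree the species tree.
#' @param config a [sim_config()].
#' @return An [expression_panel()] (state `"raw"`, TPM scale).
#' @export
simulate_expression <- function(sims, tree, config) {
  if (config$alpha <= 0 || config$sigma2 <= 0) {
    abort("`alpha` and `sigma2` must be positive.",
      class = "ohnoshift_config_error"
    )
  }
  sp <- attr(tree, "roles")
  reps <- config$replicates_per_species
  species <- c(sp$ingroup, sp$outgroup)
  samples <- tibble::tibble(
    sample = paste0(rep(species, each = reps), "_r", seq_len(reps)),
    species = rep(species, each = reps)
  )
  all_genes <- sims$truth$gene
  vals <- matrix(NA_real_, length(all_genes), nrow(samples),
    dimnames = list(all_genes, samples$sample)
  )
  s_stat <- config$sigma2 / (2 * config$alpha)
  sd_rep <- sqrt(config$beta * s_stat)

  with_seed(stage_seed(config$seed, "expression"), {
    for (og in names(sims$trees)) {
      gt <- sims$trees[[og]]
      tr_truth <- sims$truth[sims$truth$orthogroup == og, ]
      tr_truth <- tr_truth[match(gt$tip.label, tr_truth$gene), ]
      theta0 <- tr_truth$theta_base[1]
      m <- rep(theta0, ape::Ntip(gt))
      names(m) <- gt$tip.label
      # additive shifted-regime weights per copy (disjoint clades)
      for (cp in c("a", "b")) {
        rows <- tr_truth$copy == cp & !is.na(tr_truth$copy)
        if (!any(rows)) next
        delta <- tr_truth$delta_theta[rows][1]
        if (delta == 0) next
        shift_tips <- tr_truth$gene[rows]
        painting <- paint_shift_clade(gt, shift_tips)
        w <- ou_regime_weights(gt, painting, config$alpha)[, 2]
        m <- m + delta * w
      }
      d <- ape::cophenetic.phylo(gt)
      v_sp <- s_stat * exp(-config$alpha * d)
      u <- chol(v_sp)
      z <- rnorm(nrow(v_sp))
      gene_means <- m[rownames(v_sp)] + drop(t(u) %*% z)
      for (g in gt$tip.label) {
        g_sp <- species_of(g)
        cols <- samples$sample[samples$species == g_sp]
        vals[g, cols] <- gene_means[g] + rnorm(length(cols), 0, sd_rep)
      }
    }
  })
  tpm <- 2^vals - 0.01
  n_floored <- sum(tpm < 0, na.rm = TRUE)
  tpm[tpm < 0] <- 0
  panel <- expression_panel(tpm, samples)
  attr(panel, "n_floored") <- n_floored
  panel
}

#' Read a cohort configuration from YAML
#'
#' Reads a YAML file whose keys mirror the [sim_config()] arguments
#' (`shift_spec` as a list of `category`/`fraction`/`delta_theta`
#' records); unset keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A validated [sim_config()].
#' @export
sim_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$shift_spec)) {
    raw$shift_spec <- dplyr::bind_rows(lapply(raw$shift_spec, tibble::as_tibble))
  }
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste0("Unknown config keys: ", paste(unknown, collapse = ", ")),
      class = "ohnoshift_config_error"
    )
  }
  do.call(sim_config, raw)
}
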