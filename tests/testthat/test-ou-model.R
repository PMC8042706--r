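tree7 <- default_tree()
ing7 <- ingroup_tips(tree7)
paint7 <- paint_shift_clade(tree7, ing7)
sm7 <- setNames(rep(4L, 7), tree7$tip.label)

test_that("ou_params validates its domain", {
  expect_error(ou_params(5, -1, 1, 1), class = "ohnoshift_domain_error")
  expect_error(ou_params(5, 1, 0, 1), class = "ohnoshift_domain_error")
  expect_error(ou_params(Inf, 1, 1, 1))
})

test_that("regime painting marks the stem branch and all descendants", {
  p <- paint_shift_clade(tree7, ing7)
  shifted_children <- tree7$edge[p$edge_regime == 1L, 2]
  tip_ids <- match(ing7, tree7$tip.label)
  expect_true(all(tip_ids %in% shifted_children))
  # shifted branches form a connected rooted subtree: exactly one shifted
  # edge has an unshifted parent edge (the stem)
  shifted_parents <- tree7$edge[p$edge_regime == 1L, 1]
  stem_count <- sum(!(shifted_parents %in% shifted_children))
  expect_equal(stem_count, 1L)
  expect_error(paint_shift_clade(tree7, tree7$tip.label)) # not proper subset
})

test_that("ou_mean_vector hits its closed forms", {
  # uniform painting: every tip sits exactly at theta, any alpha
  for (alpha in c(0.1, 1, 7)) {
    m <- ou_mean_vector(
      tree7, paint_uniform(tree7), ou_params(5, alpha, 1, 0.5)
    )
    expect_equal(unname(m), rep(5, 7), tolerance = 1e-12)
  }
  # single shifted terminal branch of length t:
  # mean = theta0 * exp(-alpha*t) + theta1 * (1 - exp(-alpha*t))
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  p1 <- paint_shift_clade(tr, "A")
  alpha <- 0.9
  m <- ou_mean_vector(tr, p1, ou_params(c(2, 6), alpha, 1, 0.5))
  expect_equal(
    m[["A"]], 2 * exp(-alpha) + 6 * (1 - exp(-alpha)),
    tolerance = 1e-12
  )
  expect_equal(m[["B"]], 2, tolerance = 1e-12)
  # strong-pull limit: shifted tips at theta1, others at theta0
  m_inf <- ou_mean_vector(tree7, paint7, ou_params(c(2, 6), 500, 1, 0.5))
  expect_equal(unname(m_inf[ing7]), rep(6, 4), tolerance = 1e-4)
  expect_equal(unname(m_inf[setdiff(tree7$tip.label, ing7)]), rep(2, 3),
    tolerance = 1e-4
  )
})

test_that("ou_covariance equals element-wise brute force and its anchors", {
  tr <- parse_newick("((A:0.6,B:0.6):0.4,(C:0.5,D:0.5):0.5);")
  sm <- setNames(c(2L, 1L, 3L, 2L), c("A", "B", "C", "D"))
  params <- ou_params(5, 0.5, 2, 0.25)
  v <- ou_covariance(tr, params, sm)
  bf <- brute_force_ou(tr, paint_uniform(tr), params, sm)
  expect_equal(unname(v), unname(bf$cov), tolerance = 1e-12)
  s <- 2 / (2 * 0.5)
  # same-species replicates share the full species variance
  expect_equal(v["A.1", "A.2"], s, tolerance = 1e-12)
  expect_equal(v["A.1", "A.1"], s * 1.25, tolerance = 1e-12)
  # distant tips decorrelate
  expect_lt(v["A.1", "C.1"], v["A.1", "B.1"])
  ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
})

test_that("log-likelihood matches brute-force MVN evaluation", {
  # one species, one replicate, uniform regime: a plain normal density
  tr1 <- parse_newick("((A:1,B:1):1,C:2);")
  p <- ou_params(4, 1.2, 1.5, 0.6)
  sm1 <- c(A = 1L)
  s <- 1.5 / (2 * 1.2)
  ll <- ou_log_likelihood(2.5, tr1, paint_uniform(tr1), p, sm1)
  expect_equal(ll, dnorm(2.5, 4, sqrt(s * 1.6), log = TRUE),
    tolerance = 1e-10
  )

  # random trees vs explicitly assembled mean/covariance
  for (seed in 1:20) {
    tr <- random_ultrametric(sample(3:6, 1), seed + 300)
    withr::with_seed(seed, {
      n_rep <- sample(1:3, ape::Ntip(tr), replace = TRUE)
      sm <- setNames(pmax(n_rep, 1L), tr$tip.label)
      params <- ou_params(
        c(rnorm(1, 3, 1), rnorm(1, 3, 1)),
        exp(runif(1, -1, 2)), exp(runif(1, -1, 1)), exp(runif(1, -2, 1))
      )
      shift_tips <- sample(tr$tip.label, sample(seq_len(ape::Ntip(tr) - 1), 1))
      painting <- paint_shift_clade(tr, shift_tips)
      y <- rnorm(sum(sm), 3, 1.5)
    })
    bf <- brute_force_ou(tr, painting, params, sm)
    expect_equal(
      ou_log_likelihood(y, tr, painting, params, sm),
      dmvnorm_log(y, bf$mean, bf$cov),
      tolerance = 1e-8
    )
  }
})

test_that("log-likelihood is invariant to permuting replicates within species", {
  withr::with_seed(8, y <- rnorm(28, 5, 1))
  p <- ou_params(c(5, 6), 2, 2, 0.3)
  base <- ou_log_likelihood(y, tree7, paint7, p, sm7)
  y2 <- y
  y2[1:4] <- y[c(3, 1, 4, 2)] # permute replicates of the first species
  expect_equal(ou_log_likelihood(y2, tree7, paint7, p, sm7), base,
    tolerance = 1e-10
  )
})

test_that("single-theta fit handles constant data and is a fixed point", {
  y <- rep(3.7, 28)
  fit <- fit_single_theta(y, tree7, sm7)
  expect_true(fit$converged)
  expect_equal(unname(fit$params$theta), 3.7, tolerance = 1e-6)
  expect_true(is.finite(fit$logL))
  # refit on data simulated at the ML point stays at least as good
  withr::with_seed(9, y2 <- rnorm(28, 5, 0.7))
  f2 <- fit_single_theta(y2, tree7, sm7)
  ll_at_ml <- ou_log_likelihood(
    y2, tree7, paint_uniform(tree7), f2$params, sm7
  )
  expect_equal(f2$logL, ll_at_ml, tolerance = 1e-6)
  expect_error(
    fit_single_theta(rnorm(2), tree7, sm7[1:2]),
    class = "ohnoshift_model_error"
  )
})

test_that("single-theta estimates are unbiased over genes", {
  p_true <- ou_params(5, 2, 2, 0.3)
  withr::with_seed(10, {
    thetas <- vapply(1:60, function(i) {
      y <- simulate_ou_gene(tree7, paint_uniform(tree7), p_true, sm7)
      unname(fit_single_theta(y, tree7, sm7)$params$theta)
    }, numeric(1))
  })
  expect_lt(abs(median(thetas) - 5), 0.15)
})

test_that("two-theta fit nests the null and recovers direction", {
  withr::with_seed(12, {
    for (i in 1:10) {
      y <- simulate_ou_gene(
        tree7, paint7, ou_params(c(5, 5), 2, 2, 0.3), sm7
      )
      f1 <- fit_single_theta(y, tree7, sm7)
      f2 <- fit_two_theta(y, tree7, paint7, sm7)
      expect_gte(f2$logL, f1$logL - 1e-6)
    }
  })
  # strong planted shift: direction up, large LRT
  withr::with_seed(13, {
    y_up <- simulate_ou_gene(
      tree7, paint7, ou_params(c(4, 8), 2, 2, 0.3), sm7
    )
  })
  call <- two_theta_test(y_up, tree7, paint7, sm7)
  expect_equal(call$status, "tested")
  expect_true(call$significant)
  expect_equal(call$direction, "up")
  expect_equal(call$p, pchisq(call$lrt, 1, lower.tail = FALSE))
  expect_equal(qchisq(0.95, 1), 3.8415, tolerance = 1e-4)
})

test_that("run_orthogroup tests each duplicate clade with shared outgroups", {
  cfg <- sim_config(
    seed = 5, n_singleton_trees = 2, n_ohnolog_trees = 3,
    frac_partial = 0
  )
  tree <- simulate_species_tree(cfg)
  sims <- simulate_orthogroups(cfg, tree)
  panel <- log_transform(simulate_expression(sims, tree, cfg))
  roles <- attr(tree, "roles")
  species_roles <- attr(tree, "species_roles")
  og <- sims$tree_info$orthogroup[sims$tree_info$tree_class == "ohnolog"][1]
  units <- extract_test_units(sims$trees[[og]], species_roles, og)
  calls <- dplyr::bind_rows(lapply(units, function(u) {
    run_orthogroup(u, panel, tree, roles$ingroup)
  }))
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$status, rep("tested", 2))
  expect_equal(calls$clade, 1:2)
  # a singleton orthogroup yields one tested call
  og_s <- sims$tree_info$orthogroup[sims$tree_info$tree_class == "singleton"][1]
  u_s <- extract_test_units(sims$trees[[og_s]], species_roles, og_s)
  expect_length(u_s, 1L)
  call_s <- run_orthogroup(u_s[[1]], panel, tree, roles$ingroup)
  expect_equal(call_s$status, "tested")
  # unit genes missing from the panel is a data-integrity error
  bad_unit <- units[[1]]
  bad_unit$genes$gene[1] <- "not_a_gene"
  expect_error(
    run_orthogroup(bad_unit, panel, tree, roles$ingroup),
    class = "ohnoshift_data_integrity"
  )
})

test_that("tidy and glance methods expose fit results", {
  withr::with_seed(14, y <- rnorm(28, 5, 0.7))
  fit <- fit_two_theta(y, tree7, paint7, sm7)
  td <- tidy(fit)
  expect_setequal(
    td$term, c("theta_base", "theta_shift", "alpha", "sigma2", "beta")
  )
  gl <- glance(fit)
  expect_equal(gl$n_obs, 28L)
  expect_equal(gl$n_regimes, 2L)
})
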