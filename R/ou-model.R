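#' Ornstein-Uhlenbeck parameters for expression evolution
#'
#' The model treats a gene's log2 expression level as evolving along the
#' phylogeny under an Ornstein-Uhlenbeck (OU) process: random drift with
#' variance rate `sigma2`, pulled towards an optimum `theta` with strength
#' `alpha` (both in the time units of the tree's branch lengths). At
#' stationarity the between-species variance is `sigma2 / (2 * alpha)`.
#' Replicate individuals within a species add independent noise whose
#' variance is `beta` times the stationary between-species variance.
#'
#' @param theta optimum log2 expression level(s): length 1 for a single
#'   regime, length 2 (`base`, `shift`) for the two-optima model.
#' @param alpha pull strength (> 0, units 1/time).
#' @param sigma2 drift variance rate (> 0, units log2-expression squared per
#'   time).
#' @param beta within-species to between-species variance ratio (> 0,
#'   dimensionless).
#' @return A list of class `ou_params`.
#' @export
ou_params <- function(theta, alpha, sigma2, beta) {
  if (!is.numeric(theta) || !length(theta) %in% 1:2 || any(!is.finite(theta))) {
    abort("`theta` must be 1 or 2 finite values.")
  }
  if (alpha <= 0 || sigma2 <= 0 || beta <= 0) {
    abort("`alpha`, `sigma2` and `beta` must be positive.",
      class = "ohnoshift_domain_error"
    )
  }
  theta_num <- as.numeric(theta)
  names(theta_num) <- names(theta)
  structure(
    list(theta = theta_num, alpha = alpha, sigma2 = sigma2, beta = beta),
    class = "ou_params"
  )
}

# parent lookup and node ages (distance from root) for a rooted phylo
tree_times <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  list(
    depth = depth,
    parent = tree$edge[, 1], child = tree$edge[, 2],
    root = ape::Ntip(tree) + 1L
  )
}

#' Paint a shifted regime onto a clade
#'
#' Marks the stem branch of the most recent common ancestor of `shift_tips`
#' and every branch below it as regime 1 ("shifted"); all other branches,
#' and the root state, stay in regime 0 ("base"). This is the painting used
#' to test for an expression optimum shift in the ancestor of a duplicate
#' clade.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param shift_tips tip labels of the shifted clade (a proper, non-empty
#'   subset of the tips).
#' @return An object of class `regime_painting`: `edge_regime` (0/1 per row
#'   of `tree$edge`) and `root_regime` (always 0).
#' @export
paint_shift_clade <- function(tree, shift_tips) {
  tips <- tree$tip.label
  if (!all(shift_tips %in% tips)) {
    abort("`shift_tips` must be tip labels of `tree`.")
  }
  if (length(shift_tips) == 0L || length(shift_tips) >= length(tips)) {
    abort("`shift_tips` must be a proper, non-empty subset of the tips.")
  }
  node <- if (length(shift_tips) == 1L) {
    match(shift_tips, tips)
  } else {
    ape::getMRCA(tree, shift_tips)
  }
  # stem edge plus everything below the mrca
  in_clade <- logical(ape::Ntip(tree) + tree$Nnode)
  in_clade[node] <- TRUE
  ord <- reorder(tree, "cladewise")$edge # parents before children
  for (i in seq_len(nrow(ord))) {
    if (in_clade[ord[i, 1]]) in_clade[ord[i, 2]] <- TRUE
  }
  edge_regime <- as.integer(in_clade[tree$edge[, 2]])
  structure(
    list(edge_regime = edge_regime, root_regime = 0L, shift_node = node),
    class = "regime_painting"
  )
}

#' Single-regime painting (all branches in the base regime)
#'
#' @param tree a rooted `phylo`.
#' @return A `regime_painting` with every branch in regime 0.
#' @export
paint_uniform <- function(tree) {
  structure(
    list(
      edge_regime = integer(nrow(tree$edge)), root_regime = 0L,
      shift_node = NA_integer_
    ),
    class = "regime_painting"
  )
}

# Flatten every root-to-tip path into one segment table (tip index, tip
# age, segment start/end ages, regime). Computed once per tree/painting so
# the weight matrix can be re-evaluated cheaply across alpha values during
# optimization.
ou_path_segments <- function(tree, painting) {
  tt <- tree_times(tree)
  n_tip <- ape::Ntip(tree)
  parent_of <- integer(n_tip + tree$Nnode)
  edge_of <- integer(n_tip + tree$Nnode)
  parent_of[tt$child] <- tt$parent
  edge_of[tt$child] <- seq_along(tt$child)
  tip_i <- integer()
  t0 <- t1 <- numeric()
  reg <- integer()
  for (tip in seq_len(n_tip)) {
    node <- tip
    while (node != tt$root) {
      tip_i <- c(tip_i, tip)
      t1 <- c(t1, tt$depth[node])
      t0 <- c(t0, tt$depth[parent_of[node]])
      reg <- c(reg, painting$edge_regime[edge_of[node]])
      node <- parent_of[node]
    }
  }
  list(
    tip = tip_i, t_tip = tt$depth[tip_i], t0 = t0, t1 = t1, regime = reg,
    tip_depth = tt$depth[seq_len(n_tip)],
    root_regime = painting$root_regime,
    n_tip = n_tip, n_reg = max(painting$edge_regime) + 1L,
    tip_labels = tree$tip.label
  )
}

weights_from_segments <- function(seg, alpha) {
  contrib <- exp(-alpha * (seg$t_tip - seg$t1)) -
    exp(-alpha * (seg$t_tip - seg$t0))
  w <- matrix(0, seg$n_tip, seg$n_reg,
    dimnames = list(seg$tip_labels, NULL)
  )
  for (r in seq_len(seg$n_reg)) {
    sel <- seg$regime + 1L == r
    if (any(sel)) {
      v <- tapply(
        contrib[sel],
        factor(seg$tip[sel], levels = seq_len(seg$n_tip)), sum
      )
      v[is.na(v)] <- 0
      w[, r] <- w[, r] + as.numeric(v)
    }
  }
  w[, seg$root_regime + 1L] <- w[, seg$root_regime + 1L] +
    exp(-alpha * seg$tip_depth)
  w
}

# tips x regimes weight matrix W(alpha): expected tip value = W %*% theta.
# Each branch segment [t0, t1] on the root-to-tip path contributes
# exp(-alpha*(T - t1)) - exp(-alpha*(T - t0)) to its regime's weight; the
# root state (stationary at the base optimum) contributes exp(-alpha*T) to
# regime 0. Rows sum to 1.
ou_regime_weights <- function(tree, painting, alpha) {
  weights_from_segments(ou_path_segments(tree, painting), alpha)
}

#' Expected tip values under a painted OU process
#'
#' Closed-form per-tip expectation of the OU process whose optimum follows
#' the regime painting, with the root drawn from the stationary distribution
#' around the base optimum. With a uniform painting every tip expectation
#' equals `theta` exactly; in the strong-pull limit shifted-clade tips
#' approach the shifted optimum.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param painting a [paint_shift_clade()] / [paint_uniform()] painting.
#' @param params an [ou_params()]; `theta` must supply one value per regime.
#' @return Named numeric vector over tips.
#' @export
ou_mean_vector <- function(tree, painting, params) {
  if (params$alpha <= 0) {
    abort("`alpha` must be positive.", class = "ohnoshift_domain_error")
  }
  n_reg <- max(painting$edge_regime) + 1L
  if (length(params$theta) < n_reg) {
    abort("`theta` must supply one optimum per regime in the painting.")
  }
  w <- ou_regime_weights(tree, painting, params$alpha)
  drop(w %*% params$theta[seq_len(ncol(w))])
}

# expand a species-level quantity to individuals; sample_map is a named
# integer vector (species -> replicate count) whose order fixes the layout
expand_sample_map <- function(tree, sample_map) {
  if (is.null(names(sample_map)) || !all(names(sample_map) %in% tree$tip.label)) {
    abort("`sample_map` must be named by tip labels of the tree.")
  }
  if (any(sample_map < 1)) abort("Replicate counts must be >= 1.")
  rep(names(sample_map), times = sample_map)
}

#' Individual-level OU covariance matrix
#'
#' Stationary OU covariance between species i and j is
#' `sigma2/(2*alpha) * exp(-alpha * d_ij)` with `d_ij` the patristic
#' distance; replicate individuals of one species share that species-level
#' value off the diagonal and add `beta * sigma2/(2*alpha)` of
#' within-species variance on the diagonal.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param params an [ou_params()].
#' @param sample_map named integer vector, species (tip label) -> replicate
#'   count; its order fixes the row/column layout (replicates of a species
#'   are contiguous).
#' @return Symmetric positive-definite matrix of size `sum(sample_map)`,
#'   with dimnames `species.replicate`.
#' @export
ou_covariance <- function(tree, params, sample_map) {
  ind_sp <- expand_sample_map(tree, sample_map)
  d <- ape::cophenetic.phylo(tree)
  s <- params$sigma2 / (2 * params$alpha)
  v <- s * exp(-params$alpha * d[ind_sp, ind_sp, drop = FALSE])
  diag(v) <- diag(v) + params$beta * s
  ids <- unlist(lapply(sample_map, seq_len))
  dimnames(v) <- rep(list(paste(ind_sp, ids, sep = ".")), 2)
  v
}

#' OU log-likelihood of replicate expression values
#'
#' Multivariate normal log density of the individual-level data under the
#' painted OU model: mean from [ou_mean_vector()] expanded to replicates,
#' covariance from [ou_covariance()]. Evaluated through a species-mean
#' sufficient-statistic factorization (replicate means carry the
#' phylogenetic covariance, within-species sums of squares the replicate
#' noise), which is algebraically identical to the direct evaluation but
#' factorizes the problem by species. Invariant to permuting replicates
#' within a species.
#'
#' @param y numeric vector of individual values, laid out as in
#'   [ou_covariance()] (replicates of each species contiguous, species in
#'   `sample_map` order).
#' @param tree,painting,params,sample_map as in [ou_covariance()] and
#'   [ou_mean_vector()].
#' @return Log density (scalar); `-Inf` if the covariance is numerically
#'   singular.
#' @export
ou_log_likelihood <- function(y, tree, painting, params, sample_map) {
  st <- ou_suff_stats(y, tree, painting, sample_map)
  alpha <- params$alpha
  beta <- params$beta
  s <- params$sigma2 / (2 * alpha)
  c_mat <- exp(-alpha * st$d_sp)
  diag(c_mat) <- diag(c_mat) + beta / st$n_s
  u <- tryCatch(chol(c_mat), error = function(e) NULL)
  if (is.null(u)) {
    return(-Inf)
  }
  n_reg <- max(painting$edge_regime) + 1L
  m <- drop(st$w_fun(alpha) %*% params$theta[seq_len(n_reg)])
  r <- backsolve(u, st$ybar - m, transpose = TRUE)
  n <- sum(st$n_s)
  k <- length(st$ybar)
  -0.5 * (
    n * log(2 * pi) + k * log(s) + 2 * sum(log(diag(u))) + sum(r^2) / s +
      sum((st$n_s - 1) * log(beta * s)) + sum(st$ssw) / (beta * s) +
      sum(log(st$n_s))
  )
}

# ---- maximum-likelihood fitting ------------------------------------------

# Profile negative log-likelihood over (log alpha, log beta), computed on
# the species-level sufficient statistics: replicate means carry the
# phylogenetic structure (covariance s * [exp(-alpha D) + beta diag(1/n_s)])
# while within-species sums of squares enter through the iid replicate
# noise (variance beta * s). Given alpha and beta, theta is the GLS
# solution (the mean is linear in theta) and the stationary-variance scale
# s = sigma2/(2 alpha) has the closed-form ML estimate. Returns the full
# fit when details = TRUE. `st` holds the per-gene statistics:
# ybar (species means, tree tip subset order), ssw (within sums of
# squares), n_s (replicate counts), d_sp (species distance matrix), w_fun.
ou_profile_nll <- function(par, st, details = FALSE) {
  alpha <- exp(par[1])
  beta <- exp(par[2])
  n <- sum(st$n_s)
  k <- length(st$ybar)
  c_mat <- exp(-alpha * st$d_sp)
  diag(c_mat) <- diag(c_mat) + beta / st$n_s
  u <- tryCatch(chol(c_mat), error = function(e) NULL)
  if (is.null(u)) {
    return(if (details) NULL else 1e10)
  }
  a_mat <- st$w_fun(alpha)
  ty <- backsolve(u, st$ybar, transpose = TRUE)
  ta <- backsolve(u, a_mat, transpose = TRUE)
  theta <- tryCatch(qr.solve(ta, ty), error = function(e) NULL)
  if (is.null(theta)) {
    return(if (details) NULL else 1e10)
  }
  rss <- sum((ty - ta %*% theta)^2)
  s <- max((rss + sum(st$ssw) / beta) / n, 1e-12)
  nll <- 0.5 * (
    n * log(2 * pi) + n * log(s) + n +
      2 * sum(log(diag(u))) +
      sum((st$n_s - 1) * log(beta)) + sum(log(st$n_s))
  )
  if (!is.finite(nll)) {
    return(if (details) NULL else 1e10)
  }
  if (!details) {
    return(nll)
  }
  list(
    theta = as.numeric(theta), alpha = alpha, beta = beta,
    s = s, sigma2 = 2 * alpha * s, logL = -nll
  )
}

# per-gene sufficient statistics for ou_profile_nll
ou_suff_stats <- function(y, tree, painting, sample_map) {
  ind_sp <- expand_sample_map(tree, sample_map)
  if (length(y) != length(ind_sp)) {
    abort("`y` must have one value per individual in `sample_map`.")
  }
  sp <- names(sample_map)
  ybar <- vapply(sp, function(s) mean(y[ind_sp == s]), numeric(1))
  ssw <- vapply(sp, function(s) {
    v <- y[ind_sp == s]
    sum((v - mean(v))^2)
  }, numeric(1))
  d <- ape::cophenetic.phylo(tree)
  seg <- ou_path_segments(tree, painting)
  sp_idx <- match(sp, tree$tip.label)
  list(
    ybar = ybar, ssw = ssw, n_s = as.numeric(sample_map),
    d_sp = d[sp, sp, drop = FALSE],
    w_fun = function(alpha) {
      weights_from_segments(seg, alpha)[sp_idx, , drop = FALSE]
    }
  )
}

fit_ou_ml <- function(y, tree, painting, sample_map) {
  st <- ou_suff_stats(y, tree, painting, sample_map)
  n_reg <- max(painting$edge_regime) + 1L
  ind_sp <- expand_sample_map(tree, sample_map)
  t_root <- max(ape::node.depth.edgelength(tree))

  # deterministic multi-start grid; beta start also taken from a one-way
  # within/between variance decomposition of the data
  sp_means <- tapply(y, ind_sp, mean)
  v_within <- mean(tapply(y, ind_sp, function(z) {
    if (length(z) > 1) var(z) else NA_real_
  }), na.rm = TRUE)
  v_between <- var(as.numeric(sp_means))
  beta_emp <- if (is.finite(v_within) && is.finite(v_between) &&
    v_within > 0 && v_between > 0) {
    v_within / v_between
  } else {
    0.5
  }
  starts <- expand.grid(
    la = log(c(0.5, 2, 8) / t_root),
    lb = log(c(0.2, beta_emp))
  )
  lower <- c(log(1e-3 / t_root), log(1e-4))
  upper <- c(log(2e3 / t_root), log(1e4))

  best <- NULL
  n_used <- 0L
  for (i in seq_len(nrow(starts))) {
    n_used <- n_used + 1L
    opt <- tryCatch(
      optim(
        par = as.numeric(starts[i, ]), fn = ou_profile_nll, st = st,
        method = "L-BFGS-B", lower = lower, upper = upper,
        control = list(maxit = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e10) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    return(structure(
      list(
        params = NULL, logL = -Inf, converged = FALSE,
        n_restarts_used = n_used, n_obs = length(y),
        n_species = length(sample_map), n_regimes = n_reg
      ),
      class = "eve_fit"
    ))
  }
  det <- ou_profile_nll(best$par, st, details = TRUE)
  theta <- det$theta
  names(theta) <- if (n_reg == 2L) c("base", "shift") else "base"
  structure(
    list(
      params = ou_params(theta, det$alpha, det$sigma2, det$beta),
      logL = det$logL, converged = best$convergence == 0,
      n_restarts_used = n_used, n_obs = length(y),
      n_species = length(sample_map), n_regimes = n_reg
    ),
    class = "eve_fit"
  )
}

#' Fit the single-optimum OU null model
#'
#' Maximum likelihood over (theta, alpha, sigma2, beta) with one expression
#' optimum for the whole tree. The optimum and the variance scale are
#' profiled out analytically, leaving a 2-D bounded quasi-Newton search over
#' (log alpha, log beta) from a deterministic multi-start grid.
#'
#' @param y numeric vector of individual log2 expression values (replicates
#'   of each species contiguous, species in `sample_map` order).
#' @param tree a rooted `phylo` with branch lengths.
#' @param sample_map named integer vector, species -> replicate count.
#' @return An `eve_fit` object: `params` ([ou_params()]), `logL`,
#'   `converged`, `n_restarts_used`.
#' @export
fit_single_theta <- function(y, tree, sample_map) {
  if (length(sample_map) < 3L) {
    abort("At least 3 species with data are required.",
      class = "ohnoshift_model_error"
    )
  }
  fit_ou_ml(y, tree, paint_uniform(tree), sample_map)
}

#' Fit the two-optima OU model
#'
#' As [fit_single_theta()], but with separate optima for the painted shifted
#' clade (stem branch included) and the background. The null model is nested
#' within this model, so at the optimum the log-likelihood is never below
#' the single-optimum fit (up to numerical tolerance).
#'
#' @inheritParams fit_single_theta
#' @param painting a two-regime [paint_shift_clade()] painting.
#' @return An `eve_fit` with `params$theta = c(base, shift)`.
#' @export
fit_two_theta <- function(y, tree, painting, sample_map) {
  if (length(sample_map) < 3L) {
    abort("At least 3 species with data are required.",
      class = "ohnoshift_model_error"
    )
  }
  if (max(painting$edge_regime) != 1L) {
    abort("`painting` must have exactly two regimes.")
  }
  fit_ou_ml(y, tree, painting, sample_map)
}

#' @export
print.eve_fit <- function(x, ...) {
  if (is.null(x$params)) {
    cat("<eve_fit> non-converged\n")
    return(invisible(x))
  }
  cat(
    "<eve_fit> ", x$n_regimes, "-regime OU fit, logL = ",
    format(x$logL, digits = 6), "\n  theta: ",
    paste(format(x$params$theta, digits = 4), collapse = ", "),
    "  alpha: ", format(x$params$alpha, digits = 4),
    "  sigma2: ", format(x$params$sigma2, digits = 4),
    "  beta: ", format(x$params$beta, digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.eve_fit <- function(x, ...) {
  if (is.null(x$params)) {
    return(tibble::tibble(
      term = character(), estimate = double()
    ))
  }
  th <- x$params$theta
  tibble::tibble(
    term = c(paste0("theta_", names(th)), "alpha", "sigma2", "beta"),
    estimate = c(unname(th), x$params$alpha, x$params$sigma2, x$params$beta)
  )
}

#' @export
glance.eve_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$logL, converged = x$converged,
    n_restarts_used = x$n_restarts_used, n_obs = x$n_obs,
    n_species = x$n_species, n_regimes = x$n_regimes
  )
}

#' Likelihood-ratio test for an expression optimum shift
#'
#' Fits the single-optimum null and the two-optima alternative and compares
#' them by the likelihood ratio statistic `2 * (logL_alt - logL_null)`
#' (clamped at zero). The statistic is referred to a chi-squared
#' distribution with one degree of freedom; calls above the 95% quantile
#' (3.8415) are significant by default. The shift direction is the sign of
#' `theta_shift - theta_base`, reported only for significant calls.
#'
#' @inheritParams fit_two_theta
#' @param sig_quantile chi-squared quantile used as the significance cut
#'   (default 0.95).
#' @return One-row tibble: `lrt`, `p`, `significant`, `direction`
#'   (`"up"`/`"down"`/`"none"`), the alternative-fit parameter estimates
#'   (`theta_base`, `theta_shift`, `alpha`, `sigma2`, `beta`), `logL_null`,
#'   `logL_alt`, and `status` (`"tested"`/`"untested"`).
#' @export
two_theta_test <- function(y, tree, painting, sample_map,
                           sig_quantile = 0.95) {
  null_fit <- fit_single_theta(y, tree, sample_map)
  alt_fit <- fit_two_theta(y, tree, painting, sample_map)
  if (is.null(null_fit$params) || is.null(alt_fit$params) ||
    !is.finite(null_fit$logL) || !is.finite(alt_fit$logL)) {
    return(shift_call_untested("non-converged fit"))
  }
  lrt <- max(0, 2 * (alt_fit$logL - null_fit$logL))
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  significant <- lrt > qchisq(sig_quantile, df = 1)
  dtheta <- alt_fit$params$theta[["shift"]] - alt_fit$params$theta[["base"]]
  direction <- if (!significant || dtheta == 0) {
    "none"
  } else if (dtheta > 0) "up" else "down"
  tibble::tibble(
    lrt = lrt, p = p, significant = significant, direction = direction,
    theta_base = alt_fit$params$theta[["base"]],
    theta_shift = alt_fit$params$theta[["shift"]],
    alpha = alt_fit$params$alpha, sigma2 = alt_fit$params$sigma2,
    beta = alt_fit$params$beta,
    logL_null = null_fit$logL, logL_alt = alt_fit$logL,
    status = "tested", reason = NA_character_
  )
}

shift_call_untested <- function(reason) {
  tibble::tibble(
    lrt = NA_real_, p = NA_real_, significant = NA, direction = NA_character_,
    theta_base = NA_real_, theta_shift = NA_real_, alpha = NA_real_,
    sigma2 = NA_real_, beta = NA_real_, logL_null = NA_real_,
    logL_alt = NA_real_, status = "untested", reason = reason
  )
}

#' Shift test for one test unit of an orthogroup
#'
#' Runs the two-optima test for a single duplicate clade: prunes the species
#' tree to the species with data in the unit, paints the ingroup stem and
#' all descendant branches as shifted, assembles the replicate data from the
#' logged panel and calls [two_theta_test()]. Ohnolog orthogroups contribute
#' two units that share the same outgroup data.
#'
#' @param unit one element of [extract_test_units()] output: a list with
#'   `orthogroup`, `clade`, and `genes` (tibble `gene`, `species`).
#' @param panel a logged [expression_panel()] containing all unit genes.
#' @param species_tree the species `phylo`.
#' @param ingroup_species character vector of ingroup (duplicated-lineage)
#'   species names.
#' @param sig_quantile passed to [two_theta_test()].
#' @return One-row tibble as [two_theta_test()], prefixed with `orthogroup`
#'   and `clade` columns.
#' @export
run_orthogroup <- function(unit, panel, species_tree, ingroup_species,
                           sig_quantile = 0.95) {
  panel_require_state(panel, "logged")
  genes <- tibble::as_tibble(unit$genes)
  missing <- setdiff(genes$gene, rownames(panel$values))
  if (length(missing)) {
    abort(
      paste0("Panel lacks unit genes: ", paste(missing, collapse = ", ")),
      class = "ohnoshift_data_integrity"
    )
  }
  res_meta <- tibble::tibble(orthogroup = unit$orthogroup, clade = unit$clade)
  sp_used <- character()
  y <- numeric()
  counts <- integer()
  for (i in seq_len(nrow(genes))) {
    sp <- genes$species[i]
    cols <- panel$samples$sample[panel$samples$species == sp]
    vals <- panel$values[genes$gene[i], cols]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) next
    sp_used <- c(sp_used, sp)
    y <- c(y, vals)
    counts <- c(counts, length(vals))
  }
  if (length(sp_used) < 3L) {
    return(dplyr::bind_cols(
      res_meta,
      shift_call_untested("fewer than 3 species with data")
    ))
  }
  sample_map <- setNames(counts, sp_used)
  tree <- prune_species_tree(species_tree, sp_used)
  shift_sp <- intersect(sp_used, ingroup_species)
  if (length(shift_sp) == 0L || length(shift_sp) == length(sp_used)) {
    return(dplyr::bind_cols(
      res_meta,
      shift_call_untested("no two-regime painting possible")
    ))
  }
  painting <- paint_shift_clade(tree, shift_sp)
  dplyr::bind_cols(
    res_meta,
    two_theta_test(y, tree, painting, sample_map, sig_quantile)
  )
}
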