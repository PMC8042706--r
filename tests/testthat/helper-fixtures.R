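# shared fixture builders; everything is generated in code

default_tree <- function() {
  simulate_species_tree(sim_config(seed = 1))
}

ingroup_tips <- function(tree) {
  roles <- attr(tree, "species_roles")
  names(roles)[roles == "ingroup"]
}

# small random ultrametric tree with n tips labelled t1..tn
random_ultrametric <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rcoal(n, tip.label = paste0("t", seq_len(n)))
    tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
    tr
  })
}

# panel with one gene per species per orthogroup, constant values unless
# noise added
toy_panel <- function(genes, species, n_rep = 2, value = 10, seed = 1) {
  samples <- tibble::tibble(
    sample = paste0(rep(species, each = n_rep), "_r", seq_len(n_rep)),
    species = rep(species, each = n_rep)
  )
  withr::with_seed(seed, {
    m <- matrix(value * exp(rnorm(length(genes) * nrow(samples), 0, 0.1)),
      length(genes), nrow(samples),
      dimnames = list(genes, samples$sample)
    )
  })
  expression_panel(m, samples)
}

# direct MVN log density from explicitly assembled mean and covariance;
# independent of the package's reduced-form computation
dmvnorm_log <- function(y, m, v) {
  p <- length(y)
  ev <- eigen(v, symmetric = TRUE)
  if (any(ev$values <= 0)) {
    return(-Inf)
  }
  r <- crossprod(ev$vectors, y - m)
  -0.5 * (p * log(2 * pi) + sum(log(ev$values)) + sum(r^2 / ev$values))
}

# brute-force OU mean and covariance assembled element by element from the
# tree's distance matrix and root-to-tip paths (loops, no linear algebra
# shared with the implementation)
brute_force_ou <- function(tree, painting, params, sample_map) {
  tips <- tree$tip.label
  n_tip <- length(tips)
  depth <- ape::node.depth.edgelength(tree)
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of <- integer(n_tip + tree$Nnode)
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- n_tip + 1L
  mean_tip <- numeric(n_tip)
  for (i in seq_len(n_tip)) {
    t_tip <- depth[i]
    node <- i
    acc <- 0
    while (node != root) {
      reg <- painting$edge_regime[edge_of[node]]
      th <- params$theta[reg + 1]
      acc <- acc + th * (exp(-params$alpha * (t_tip - depth[node])) -
        exp(-params$alpha * (t_tip - depth[parent[node]])))
      node <- parent[node]
    }
    mean_tip[i] <- acc + params$theta[1] * exp(-params$alpha * t_tip)
  }
  names(mean_tip) <- tips
  d <- ape::cophenetic.phylo(tree)
  s <- params$sigma2 / (2 * params$alpha)
  ind_sp <- rep(names(sample_map), times = sample_map)
  n <- length(ind_sp)
  v <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      v[i, j] <- s * exp(-params$alpha * d[ind_sp[i], ind_sp[j]])
      if (i == j) v[i, j] <- v[i, j] + params$beta * s
    }
  }
  list(mean = mean_tip[ind_sp], cov = v)
}

# simulate one gene under the OU model on `tree` with a given painting
simulate_ou_gene <- function(tree, painting, params, sample_map) {
  bf <- brute_force_ou(tree, painting, params, sample_map)
  ev <- eigen(bf$cov, symmetric = TRUE)
  z <- rnorm(length(bf$mean))
  drop(bf$mean + ev$vectors %*% (sqrt(pmax(ev$values, 0)) * z))
}
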