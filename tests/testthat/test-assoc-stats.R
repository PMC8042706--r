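# exhaustive sign-enumeration oracle for the signed-rank test
enumerate_signed_rank_p <- function(d, alternative) {
  stopifnot(all(d != 0))
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  switch(alternative,
    greater = mean(v_all >= v_obs),
    less = mean(v_all <= v_obs),
    two.sided = min(1, 2 * min(mean(v_all >= v_obs), mean(v_all <= v_obs)))
  )
}

test_that("signed-rank p equals exhaustive sign enumeration for n <= 12", {
  # all-positive n = 5 closed form
  res <- wilcoxon_signed_rank(2:6, 1:5, "greater")
  expect_equal(res$p, 1 / 32)
  expect_true(res$exact)
  # x = y -> p = 1 with a warning
  expect_warning(res0 <- wilcoxon_signed_rank(1:4, 1:4), "zero")
  expect_equal(res0$p, 1)

  for (seed in 1:15) {
    withr::with_seed(seed, {
      n <- sample(4:12, 1)
      x <- rnorm(n)
      y <- rnorm(n)
      alt <- sample(c("greater", "less", "two.sided"), 1)
    })
    got <- wilcoxon_signed_rank(x, y, alt)
    expect_true(got$exact)
    expect_equal(got$p, enumerate_signed_rank_p(x - y, alt),
      tolerance = 1e-12
    )
  }
})

test_that("signed-rank stays exact under ties and approximates at large n", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(0, 1, 2, 3, 4, 4) # tie among |differences|
  res <- wilcoxon_signed_rank(x, y, "greater")
  expect_true(res$exact)
  expect_equal(res$p, enumerate_signed_rank_p(x - y, "greater"),
    tolerance = 1e-12
  )
  # matches wilcox.test exact mode when there are no ties
  withr::with_seed(11, {
    a <- rnorm(15)
    b <- rnorm(15)
  })
  expect_equal(
    wilcoxon_signed_rank(a, b, "two.sided")$p,
    wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value,
    tolerance = 1e-12
  )
  big <- wilcoxon_signed_rank(rnorm(30) + 0.5, rnorm(30), "greater")
  expect_false(big$exact)
  expect_true(big$p > 0 && big$p < 1)
})

# hypergeometric enumeration oracle for a 2x2 table, alternative greater
enumerate_fisher_greater <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  sum(vapply(tab[1, 1]:min(m, k), function(x) {
    choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }, numeric(1)))
}

test_that("fisher_exact matches hypergeometric enumeration and symmetry", {
  t1 <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE)
  expect_equal(fisher_exact(t1, "greater")$p, 17 / 70, tolerance = 1e-12)
  expect_equal(
    fisher_exact(t1, "greater")$p, enumerate_fisher_greater(t1),
    tolerance = 1e-12
  )
  # [[0, n], [n, 0]] at n = 2: greater tail is the full mass, 1
  t2 <- matrix(c(0, 2, 2, 0), 2, byrow = TRUE)
  expect_equal(fisher_exact(t2, "greater")$p, 1, tolerance = 1e-12)
  # the opposite corner [[n,0],[0,n]] has greater-tail 1/C(2n, n) = 1/6
  t3 <- matrix(c(2, 0, 0, 2), 2, byrow = TRUE)
  expect_equal(fisher_exact(t3, "greater")$p, 1 / 6, tolerance = 1e-12)
  # transpose symmetry of the two-sided p
  for (seed in 1:10) {
    withr::with_seed(seed, tab <- matrix(rpois(4, 6), 2))
    expect_equal(
      fisher_exact(tab, "two.sided")$p,
      fisher_exact(t(tab), "two.sided")$p,
      tolerance = 1e-12
    )
  }
  # one-sided p monotone in the diagonal excess at fixed margins
  ps <- vapply(0:4, function(x) {
    fisher_exact(matrix(c(x, 4 - x, 4 - x, x), 2), "greater")$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  # empty margin
  expect_equal(fisher_exact(matrix(c(0, 0, 3, 5), 2, byrow = TRUE))$p, 1)
})

test_that("pathway_enrichment equals direct hypergeometric arithmetic", {
  annotation <- tibble::tibble(
    gene = c("g1", "g2", "g3", "g4", "g5", "g6", "g7", "g9"),
    term = c(rep("pwA", 4), rep("pwB", 4))
  )
  background <- paste0("g", 1:20)
  gene_set <- c("g1", "g2", "g3", "g8")
  res <- pathway_enrichment(gene_set, background, annotation)
  # pwA: K = 4, k = 3, n = 4, N = 20
  expect_equal(
    res$p[res$term == "pwA"],
    phyper(2, 4, 16, 4, lower.tail = FALSE),
    tolerance = 1e-12
  )
  # pwB: k = 0 -> p = 1
  expect_equal(res$k[res$term == "pwB"], 0)
  expect_equal(res$p[res$term == "pwB"], 1)
  # gene_set = background -> all p = 1 (k = K for every term)
  res_all <- pathway_enrichment(background, background, annotation)
  expect_true(all(res_all$p == 1))
  expect_error(pathway_enrichment("not_there", background, annotation))
})

test_that("complex label permutation matches exhaustive enumeration on a toy", {
  # 6 genes, 2 complexes of 3; 3 singletons / 3 ohnologs
  membership <- tibble::tibble(
    complex = rep(c("c1", "c2"), each = 3),
    gene = paste0("g", 1:6)
  )
  labels <- setNames(
    rep(c("singleton", "ohnolog"), each = 3), paste0("g", 1:6)
  )
  obs <- 1 # c1 is all-singleton
  # exhaustive: all C(6,3) = 20 placements of the singleton labels
  combos <- combn(6, 3)
  stats <- apply(combos, 2, function(ix) {
    lab <- rep("ohnolog", 6)
    lab[ix] <- "singleton"
    sum(all(lab[1:3] == "singleton"), all(lab[4:6] == "singleton"))
  })
  p_exact <- mean(stats >= obs)
  res <- complex_label_permutation(
    membership, labels,
    n_perm = 4000, statistic = "n_only_singleton", seed = 42
  )
  expect_equal(res$observed, obs)
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(res$p - p_exact), 3 * se + 1 / 4001)
  # determinism under the same seed
  res2 <- complex_label_permutation(
    membership, labels,
    n_perm = 4000, statistic = "n_only_singleton", seed = 42
  )
  expect_identical(res$p, res2$p)
  # single 1-gene complex: statistic constant -> p = 1
  res3 <- complex_label_permutation(
    tibble::tibble(complex = "c1", gene = "g1"),
    c(g1 = "singleton"),
    n_perm = 200, statistic = "n_only_singleton", seed = 1
  )
  expect_equal(res3$p, 1)
})

test_that("permutation p-values are super-uniform under an exchangeable null", {
  withr::with_seed(7, {
    ps <- replicate(40, {
      genes <- paste0("g", 1:12)
      membership <- tibble::tibble(
        complex = rep(c("c1", "c2", "c3"), each = 4),
        gene = genes
      )
      labels <- setNames(sample(rep(c("singleton", "ohnolog"), 6)), genes)
      complex_label_permutation(
        membership, labels,
        n_perm = 300, statistic = "n_only_ohnolog",
        seed = sample.int(1e6, 1)
      )$p
    })
  })
  # conservative add-one estimator: P(p <= q) <= q for all q
  for (q in c(0.1, 0.25, 0.5)) {
    expect_lte(mean(ps <= q), q + 3 * sqrt(q * (1 - q) / 40))
  }
})

test_that("fractionation bias test equals binomial tail summation", {
  blocks <- tibble::tibble(
    block = c("b1", "b2", "b3", "b4"),
    losses_a = c(5, 10, 0, 7),
    losses_b = c(5, 0, 0, 2)
  )
  res <- fractionation_bias_test(blocks)
  expect_equal(res$p[1], 1)
  expect_equal(res$p[2], 2 * 0.5^10, tolerance = 1e-12)
  expect_equal(res$status[3], "untested")
  expect_true(is.na(res$p[3]))
  # direct two-sided tail summation oracle
  two_sided_binom <- function(a, n) {
    probs <- dbinom(0:n, n, 0.5)
    sum(probs[probs <= dbinom(a, n, 0.5) + 1e-12])
  }
  for (seed in 1:10) {
    withr::with_seed(seed, {
      a <- rpois(1, 6)
      b <- rpois(1, 3)
    })
    if (a + b == 0) next
    got <- fractionation_bias_test(
      tibble::tibble(block = "x", losses_a = a, losses_b = b)
    )
    expect_equal(got$p, two_sided_binom(a, a + b), tolerance = 1e-9)
  }
  expect_equal(attr(res, "n_significant"), sum(res$significant))
})

test_that("spearman correlation hits anchors and the exact small-n tail", {
  x <- c(1, 3, 4, 7, 9, 12, 15, 20)
  expect_equal(spearman_correlation(x, x^2)$rho, 1)
  expect_equal(spearman_correlation(x, -x)$rho, -1)
  # n = 8 exact permutation p: compare against enumeration over ranks
  withr::with_seed(5, y <- rnorm(8))
  got <- spearman_correlation(x, y, "greater")
  # enumeration oracle over all 8! rank permutations
  perms <- function(v) {
    if (length(v) == 1) {
      return(list(v))
    }
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  rho_of <- function(r1, r2) cor(r1, r2)
  r_obs <- cor(rank(x), rank(y))
  all_rho <- vapply(
    perms(1:8), function(p) rho_of(seq_len(8), p), numeric(1)
  )
  p_exact <- mean(all_rho >= r_obs - 1e-12)
  expect_equal(got$p, p_exact, tolerance = 1e-10)
  expect_error(
    spearman_correlation(rep(1, 5), 1:5),
    class = "ohnoshift_domain_error"
  )
})
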