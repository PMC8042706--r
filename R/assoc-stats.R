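#' Paired Wilcoxon signed-rank test
#'
#' Signed-rank test on the pairwise differences `x - y`. Zero differences
#' are dropped. For n <= 25 the p-value is exact — equivalent to
#' enumerating all 2^n sign assignments (tied absolute differences take
#' average ranks), computed by convolution over the rank values — and a
#' tie- and continuity-corrected normal approximation is used above.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param alternative `"greater"` (x tends above y), `"less"`, or
#'   `"two.sided"`.
#' @return Tibble: `statistic` (V, the sum of positive-signed ranks), `p`,
#'   `n` (pairs after dropping zeros), `alternative`, `exact`.
#' @examples
#' wilcoxon_signed_rank(2:6, 1:5, "greater") # all positive, p = 1/32
#' @export
wilcoxon_signed_rank <- function(x, y,
                                 alternative = c(
                                   "greater", "less", "two.sided"
                                 )) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length.")
  }
  d <- x - y
  d <- d[!is.na(d)]
  n_nonzero <- sum(d != 0)
  if (n_nonzero == 0L) {
    warn("All paired differences are zero; p = 1.")
    return(tibble::tibble(
      statistic = 0, p = 1, n = 0L,
      alternative = alternative, exact = TRUE
    ))
  }
  dd <- d[d != 0]
  r <- rank(abs(dd))
  v_obs <- sum(r[dd > 0])
  use_exact <- n_nonzero <= 25L
  if (use_exact) {
    # exact null by counting sign assignments with a convolution over the
    # (doubled, hence integer even with average ranks) rank values
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- numeric(total + 1) # counts[v + 1] = #assignments with sum v
    counts[1] <- 1
    for (rr in r2) {
      shifted <- c(rep(0, rr), counts[seq_len(total + 1 - rr)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n_nonzero
    v2 <- round(2 * v_obs)
    p_ge <- sum(probs[(v2 + 1):(total + 1)])
    p_le <- sum(probs[1:(v2 + 1)])
    p <- switch(alternative,
      greater = p_ge,
      less = p_le,
      two.sided = min(1, 2 * min(p_ge, p_le))
    )
  } else {
    res <- suppressWarnings(wilcox.test(
      x, y,
      paired = TRUE, alternative = alternative,
      exact = FALSE, correct = TRUE
    ))
    p <- res$p.value
  }
  tibble::tibble(
    statistic = v_obs, p = p, n = n_nonzero,
    alternative = alternative, exact = use_exact
  )
}

#' Fisher's exact test on a 2x2 table
#'
#' One-sided p-values are hypergeometric tail probabilities; the two-sided
#' p-value sums the probabilities of all tables (at fixed margins) no more
#' probable than the observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative `"two.sided"`, `"greater"`, or `"less"`.
#' @return Tibble: `p`, `odds_ratio` (conditional MLE), `alternative`.
#' @export
fisher_exact <- function(table,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0)) {
    abort("`table` must be a 2x2 matrix of non-negative counts.")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(tibble::tibble(
      p = 1, odds_ratio = NA_real_, alternative = alternative
    ))
  }
  res <- fisher.test(table, alternative = alternative)
  tibble::tibble(
    p = res$p.value, odds_ratio = unname(res$estimate),
    alternative = alternative
  )
}

#' Hypergeometric over-representation test per annotation term
#'
#' For each term, tests whether the gene set contains more term members
#' than expected from the background (one-sided hypergeometric upper
#' tail): with `K` term genes among `N` background genes and `k` of the
#' `n`-gene set annotated, `p = P(X >= k)`. Terms with no gene-set member
#' report p = 1; terms absent from the background are skipped.
#'
#' @param gene_set character vector (must be a subset of `background`).
#' @param background character vector of all tested genes.
#' @param annotation tibble `gene`, `term`.
#' @return Tibble per term: `term`, `k`, `K`, `n`, `N`, `p`, sorted by `p`.
#' @export
pathway_enrichment <- function(gene_set, background, annotation) {
  if (!all(gene_set %in% background)) {
    abort("`gene_set` must be a subset of `background`.")
  }
  annotation <- tibble::as_tibble(annotation)
  annotation <- annotation[annotation$gene %in% background, ]
  n_bg <- length(unique(background))
  n_set <- length(unique(gene_set))
  terms <- sort(unique(annotation$term))
  rows <- lapply(terms, function(tm) {
    term_genes <- unique(annotation$gene[annotation$term == tm])
    big_k <- length(term_genes)
    k <- length(intersect(gene_set, term_genes))
    p <- if (k == 0) {
      1
    } else {
      phyper(k - 1, big_k, n_bg - big_k, n_set, lower.tail = FALSE)
    }
    tibble::tibble(term = tm, k = k, K = big_k, n = n_set, N = n_bg, p = p)
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$p, .data$term)
}

#' Label-permutation test for complex composition bias
#'
#' Tests whether protein complexes contain only singleton (or only
#' ohnolog) genes more often than chance by permuting the
#' singleton/ohnolog labels over genes `n_perm` times and recomputing the
#' count of homogeneous complexes. The empirical p-value uses the add-one
#' estimator `(1 + #{perm >= observed}) / (1 + n_perm)`, which can never
#' be exactly zero.
#'
#' @param complex_membership tibble `complex`, `gene`.
#' @param labels named character vector gene -> `"singleton"`/`"ohnolog"`,
#'   covering every gene in the complexes.
#' @param n_perm number of permutations (default 10000).
#' @param statistic `"n_only_singleton"` or `"n_only_ohnolog"`.
#' @param seed integer seed for the permutation stream.
#' @return Tibble: `statistic`, `observed`, `p`, `n_perm`.
#' @export
complex_label_permutation <- function(complex_membership, labels,
                                      n_perm = 10000L,
                                      statistic = c(
                                        "n_only_singleton", "n_only_ohnolog"
                                      ),
                                      seed = 1L) {
  statistic <- match.arg(statistic)
  complex_membership <- tibble::as_tibble(complex_membership)
  genes <- unique(complex_membership$gene)
  if (!all(genes %in% names(labels))) {
    abort("`labels` must cover every gene in the complexes.")
  }
  if (n_perm < 100L) warn("Fewer than 100 permutations is unreliable.")
  target <- if (statistic == "n_only_singleton") "singleton" else "ohnolog"
  cx <- split(
    match(complex_membership$gene, genes),
    complex_membership$complex
  )
  stat_fun <- function(lab) {
    sum(vapply(cx, function(ix) all(lab[ix] == target), logical(1)))
  }
  lab0 <- unname(labels[genes])
  observed <- stat_fun(lab0)
  with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(i) {
      stat_fun(sample(lab0))
    }, numeric(1))
    p <- (1 + sum(perm >= observed)) / (1 + n_perm)
  })
  tibble::tibble(
    statistic = statistic, observed = observed, p = p, n_perm = n_perm
  )
}

#' Per-block binomial test for biased fractionation
#'
#' Within each syntenic duplicate block, tests whether gene losses are
#' split unevenly between the two homeologous copies: under no bias the
#' losses on copy A follow Binomial(A + B, 1/2). Two-sided exact binomial
#' p per block; blocks with no losses are untested.
#'
#' @param blocks tibble with columns `block`, `losses_a`, `losses_b`.
#' @param threshold significance threshold for the summary count (default
#'   0.05).
#' @return Tibble per block (`block`, `losses_a`, `losses_b`, `p`,
#'   `significant`, `status`), with attribute `n_significant`.
#' @export
fractionation_bias_test <- function(blocks, threshold = 0.05) {
  blocks <- tibble::as_tibble(blocks)
  if (any(blocks$losses_a < 0 | blocks$losses_b < 0)) {
    abort("Loss counts must be non-negative.")
  }
  res <- dplyr::mutate(
    blocks,
    p = purrr::map2_dbl(.data$losses_a, .data$losses_b, function(a, b) {
      if (a + b == 0) {
        return(NA_real_)
      }
      binom.test(a, a + b, 0.5, alternative = "two.sided")$p.value
    }),
    status = ifelse(.data$losses_a + .data$losses_b == 0,
      "untested", "tested"
    ),
    significant = !is.na(.data$p) & .data$p < threshold
  )
  attr(res, "n_significant") <- sum(res$significant)
  res
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks on ties. The p-value is exact
#' (permutation distribution) for n <= 10 without ties, and a
#' t-approximation otherwise.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @param alternative `"two.sided"`, `"greater"`, or `"less"`.
#' @return Tibble: `rho`, `p`, `n`, `alternative`.
#' @export
spearman_correlation <- function(x, y,
                                 alternative = c(
                                   "two.sided", "greater", "less"
                                 )) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y) || length(x) < 3L) {
    abort("Need paired vectors with n >= 3.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Constant vector: rank correlation undefined.",
      class = "ohnoshift_domain_error"
    )
  }
  ties <- any(duplicated(x)) || any(duplicated(y))
  res <- suppressWarnings(cor.test(x, y,
    method = "spearman", alternative = alternative,
    exact = length(x) <= 10L && !ties
  ))
  tibble::tibble(
    rho = unname(res$estimate), p = res$p.value, n = length(x),
    alternative = alternative
  )
}
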