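#' Combine two per-copy shift calls into a pair category
#'
#' Each copy's state is `cons` (no significant shift), `up`, or `down`; the
#' unordered pair of states gives one of six categories: `cons+cons`,
#' `up+cons`, `down+cons`, `up+up`, `down+down`, `up+down`. Symmetric under
#' swapping the two calls.
#'
#' @param call_a,call_b one-row shift-call tibbles (from
#'   [two_theta_test()] / [run_orthogroup()]); both must have
#'   `status == "tested"`.
#' @return The category string.
#' @export
classify_pair <- function(call_a, call_b) {
  state_of <- function(call) {
    if (!identical(call$status, "tested")) {
      abort("Both calls must be tested to classify a pair.",
        class = "ohnoshift_untested_call"
      )
    }
    if (!isTRUE(call$significant)) {
      return("cons")
    }
    if (identical(call$direction, "none")) {
      return("cons")
    }
    call$direction
  }
  states <- c(state_of(call_a), state_of(call_b))
  ord <- c(up = 1L, down = 2L, cons = 3L)
  paste(states[order(ord[states])], collapse = "+")
}

#' Pair table from per-clade shift calls
#'
#' Groups the shift-call table by orthogroup, keeps orthogroups with
#' exactly two tested clades, and assigns each pair its category. Pairs
#' with an untested clade are excluded with a reason column in the
#' `excluded` attribute.
#'
#' @param calls tibble of shift calls with `orthogroup` and `clade`
#'   columns (from [run_orthogroup()] rows bound together).
#' @return Tibble with one row per ohnolog pair: `orthogroup`, the two
#'   clades' p-values and directions, and `category`.
#' @export
classify_ohnolog_pairs <- function(calls) {
  calls <- tibble::as_tibble(calls)
  pair_ogs <- names(which(table(calls$orthogroup) == 2L))
  rows <- list()
  excluded <- list()
  for (og in pair_ogs) {
    sub <- calls[calls$orthogroup == og, ]
    sub <- sub[order(sub$clade), ]
    if (any(sub$status != "tested")) {
      excluded[[og]] <- tibble::tibble(
        orthogroup = og, reason = "untested clade"
      )
      next
    }
    rows[[og]] <- tibble::tibble(
      orthogroup = og,
      clade_1 = sub$clade[1], clade_2 = sub$clade[2],
      p_1 = sub$p[1], p_2 = sub$p[2],
      direction_1 = ifelse(sub$significant[1], sub$direction[1], "cons"),
      direction_2 = ifelse(sub$significant[2], sub$direction[2], "cons"),
      category = classify_pair(sub[1, ], sub[2, ])
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "excluded") <- dplyr::bind_rows(excluded)
  out
}

#' Expression asymmetry of an ohnolog pair
#'
#' Absolute value of the mean difference between the two copies' log2
#' expression levels across all ingroup (duplicated-lineage) samples. The
#' difference is taken within species — copy A's gene minus copy B's gene
#' in each species with both copies measured — then averaged over all such
#' samples before taking the absolute value. Invariant to adding a
#' constant to both copies.
#'
#' @param genes_a,genes_b tibbles (`gene`, `species`) for the two copies'
#'   ingroup genes.
#' @param panel a logged [expression_panel()].
#' @return Non-negative scalar (log2 units), or `NA` if no species has both
#'   copies measured.
#' @export
expression_asymmetry <- function(genes_a, genes_b, panel) {
  panel_require_state(panel, "logged")
  genes_a <- tibble::as_tibble(genes_a)
  genes_b <- tibble::as_tibble(genes_b)
  shared <- intersect(genes_a$species, genes_b$species)
  diffs <- numeric()
  for (sp in shared) {
    ga <- genes_a$gene[genes_a$species == sp][1]
    gb <- genes_b$gene[genes_b$species == sp][1]
    cols <- panel$samples$sample[panel$samples$species == sp]
    d <- panel$values[ga, cols] - panel$values[gb, cols]
    diffs <- c(diffs, d[!is.na(d)])
  }
  if (length(diffs) == 0L) {
    return(NA_real_)
  }
  abs(mean(diffs))
}

#' Tissue concordance counts for a shifted/conserved ohnolog pair
#'
#' Over all non-focal tissues, counts in how many the shifted copy is
#' strictly lower and in how many strictly higher than the conserved copy.
#' Ties count in neither.
#'
#' @param gene_shift,gene_cons row names in `tissues` for the shifted and
#'   conserved copy.
#' @param tissues genes x tissues expression matrix with column names.
#' @param focal name of the focal tissue (excluded from the counts).
#' @return Named integer vector `c(n_lower, n_higher)`.
#' @export
tissue_concordance <- function(gene_shift, gene_cons, tissues, focal) {
  if (!focal %in% colnames(tissues)) {
    abort("`focal` must be a tissue column.", class = "ohnoshift_config_error")
  }
  other <- setdiff(colnames(tissues), focal)
  xs <- tissues[gene_shift, other]
  xc <- tissues[gene_cons, other]
  c(
    n_lower = sum(xs < xc, na.rm = TRUE),
    n_higher = sum(xs > xc, na.rm = TRUE)
  )
}

#' Tissue specificity score (tau)
#'
#' `tau = sum(1 - x_i / max(x)) / (N - 1)` on the linear expression scale:
#' 0 for perfectly uniform expression, 1 for single-tissue expression.
#' Invariant to global positive scaling.
#'
#' @param x non-negative per-tissue expression vector with `max(x) > 0`.
#' @return Value in \[0, 1\].
#' @examples
#' tau_score(c(8, 2, 2, 2, 2)) # 0.75
#' @export
tau_score <- function(x) {
  if (any(x < 0, na.rm = TRUE)) {
    abort("`x` must be non-negative.")
  }
  x <- x[!is.na(x)]
  m <- max(x)
  if (m == 0) {
    abort("All-zero expression vector: tau undefined.",
      class = "ohnoshift_domain_error"
    )
  }
  sum(1 - x / m) / (length(x) - 1)
}

#' Filter genes for focal-tissue-specific expression
#'
#' Keeps genes whose focal-tissue expression is at least `min_frac` of
#' their maximum across tissues and whose tau score exceeds `tau_min` —
#' the definition of "liver-specific" genes used to select tissue-specific
#' regulators and targets. All-zero genes are excluded. The alternative
#' `rule = "quantile"` interprets the expression cut as the `min_frac`
#' quantile of the gene's per-tissue values instead of a fraction of the
#' maximum.
#'
#' @param genes character vector of row names to consider.
#' @param tissues genes x tissues expression matrix (linear scale).
#' @param focal focal tissue column name.
#' @param min_frac expression cut (default 0.9).
#' @param tau_min tau cut (default 0.6, strict inequality).
#' @param rule `"max"` (default) or `"quantile"`.
#' @return Character vector: the genes passing both cuts.
#' @export
liver_specific_filter <- function(genes, tissues, focal, min_frac = 0.9,
                                  tau_min = 0.6, rule = c("max", "quantile")) {
  rule <- match.arg(rule)
  if (!focal %in% colnames(tissues)) {
    abort("`focal` must be a tissue column.", class = "ohnoshift_config_error")
  }
  keep <- vapply(genes, function(g) {
    x <- tissues[g, ]
    x <- x[!is.na(x)]
    if (max(x) == 0) {
      return(FALSE)
    }
    cut <- switch(rule,
      "max" = min_frac * max(x),
      "quantile" = quantile(x, min_frac, names = FALSE)
    )
    tissues[g, focal] >= cut && tau_score(x) > tau_min
  }, logical(1))
  genes[keep]
}
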