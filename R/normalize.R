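#' Parameters for trimmed mean of M-values (TMM) scale factors
#'
#' TMM estimates a relative scale factor between two expression columns from
#' the weighted mean of per-gene log ratios (M-values), after trimming the
#' most extreme M-values and the most extreme average log expressions
#' (A-values). Because the inputs here are TPM — sequencing depth is already
#' divided out — the default library-size rule treats the two columns as
#' having equal nominal totals, so M is simply `log2(test/ref)`.
#'
#' @param logratio_trim fraction trimmed from each tail of the M-value
#'   distribution (default 0.30).
#' @param abs_expr_trim fraction trimmed from each tail of the A-value
#'   distribution (default 0.05).
#' @param libsize_rule `"nominal"` (equal nominal totals, default for TPM) or
#'   `"column-sum"` (totals are the column sums, the convention for raw
#'   counts).
#' @param nominal_libsize the nominal total used when `libsize_rule =
#'   "nominal"`; 1e6 is TPM's natural scale.
#' @param min_genes fewest genes allowed to survive trimming before the
#'   factor falls back to the untrimmed weighted mean (with a warning).
#' @return A list of class `tmm_params`.
#' @export
tmm_params <- function(logratio_trim = 0.30, abs_expr_trim = 0.05,
                       libsize_rule = c("nominal", "column-sum"),
                       nominal_libsize = 1e6, min_genes = 10) {
  if (logratio_trim < 0 || logratio_trim >= 0.5 ||
    abs_expr_trim < 0 || abs_expr_trim >= 0.5) {
    abort("Trim fractions must lie in [0, 0.5).")
  }
  structure(
    list(
      logratio_trim = logratio_trim, abs_expr_trim = abs_expr_trim,
      libsize_rule = match.arg(libsize_rule),
      nominal_libsize = nominal_libsize, min_genes = min_genes
    ),
    class = "tmm_params"
  )
}

#' TMM scale factor of one expression column against a reference column
#'
#' Genes with a zero in either column are removed pairwise (M is undefined
#' at zero). The surviving genes are doubly trimmed — the central
#' `1 - 2*logratio_trim` span of M and the central `1 - 2*abs_expr_trim`
#' span of A are kept — and the factor is `2^f` where `f` is the
#' precision-weighted mean of the kept M-values, weighted by the inverse
#' asymptotic binomial variance of each gene's log ratio.
#'
#' @param test_col,ref_col non-negative numeric vectors of equal length.
#' @param params a [tmm_params()] object.
#' @return A single positive scale factor; multiplying `ref_col` by it
#'   matches the scale of `test_col` (identical columns give exactly 1).
#' @examples
#' x <- rexp(200, 1 / 50)
#' tmm_factor(2 * x, x) # 2
#' @export
tmm_factor <- function(test_col, ref_col, params = tmm_params()) {
  if (length(test_col) != length(ref_col)) {
    abort("`test_col` and `ref_col` must have equal length.")
  }
  test_col <- as.numeric(test_col)
  ref_col <- as.numeric(ref_col)
  if (anyNA(test_col) || anyNA(ref_col)) {
    keep <- !is.na(test_col) & !is.na(ref_col)
    test_col <- test_col[keep]
    ref_col <- ref_col[keep]
  }
  if (any(test_col < 0) || any(ref_col < 0)) {
    abort("Expression values must be non-negative.")
  }
  if (all(test_col == 0) || all(ref_col == 0)) {
    abort("A column of all zeros has no TMM factor.")
  }
  n_test <- switch(params$libsize_rule,
    "nominal" = params$nominal_libsize,
    "column-sum" = sum(test_col)
  )
  n_ref <- switch(params$libsize_rule,
    "nominal" = params$nominal_libsize,
    "column-sum" = sum(ref_col)
  )
  pos <- test_col > 0 & ref_col > 0
  obs <- test_col[pos]
  ref <- ref_col[pos]
  if (length(obs) == 0L) {
    warn("No genes expressed in both columns; TMM factor set to 1.")
    return(1)
  }
  log_r <- log2((obs / n_test) / (ref / n_ref))
  abs_e <- (log2(obs / n_test) + log2(ref / n_ref)) / 2
  v <- (n_test - obs) / (n_test * obs) + (n_ref - ref) / (n_ref * ref)

  if (max(abs(log_r)) < 1e-6) {
    return(1)
  }

  n <- length(log_r)
  lo_l <- floor(n * params$logratio_trim) + 1
  hi_l <- n + 1 - lo_l
  lo_s <- floor(n * params$abs_expr_trim) + 1
  hi_s <- n + 1 - lo_s
  rl <- rank(log_r)
  rs <- rank(abs_e)
  keep <- rl >= lo_l & rl <= hi_l & rs >= lo_s & rs <= hi_s
  if (sum(keep) < params$min_genes) {
    warn(paste0(
      "Only ", sum(keep), " genes survive TMM trimming; ",
      "falling back to the untrimmed weighted mean."
    ))
    keep <- rep(TRUE, n)
  }
  f <- sum(log_r[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

# upper-quartile rule for picking the reference column: the column whose
# 75th percentile (over genes expressed in that column) is closest to the
# mean 75th percentile across columns
tmm_reference_column <- function(mat) {
  uq <- apply(mat, 2, function(x) {
    x <- x[!is.na(x)]
    quantile(x[x > 0], 0.75, names = FALSE)
  })
  which.min(abs(uq - mean(uq)))
}

#' Within-species TMM normalization of replicates
#'
#' For each species, one replicate is chosen as the reference (upper-quartile
#' rule), a TMM factor is computed for every replicate against it, the
#' factors are centered to a geometric mean of 1 within the species, and
#' each replicate column is divided by its centered factor.
#'
#' @param panel an [expression_panel()] in state `"raw"`.
#' @param params a [tmm_params()] object.
#' @return The panel with state `"within-normalized"`; applied factors are
#'   appended to `panel$factors`.
#' @export
normalize_within_species <- function(panel, params = tmm_params()) {
  panel_require_state(panel, "raw")
  vals <- panel$values
  fac_rows <- list()
  for (sp in unique(panel$samples$species)) {
    cols <- panel$samples$sample[panel$samples$species == sp]
    sub <- vals[, cols, drop = FALSE]
    measured <- rowSums(!is.na(sub)) > 0
    sub <- sub[measured, , drop = FALSE]
    if (length(cols) == 1L || nrow(sub) == 0L) {
      inform(paste0(
        "Species '", sp, "' has a single replicate; factor fixed at 1."
      ))
      f <- rep(1, length(cols))
    } else {
      ref_i <- tmm_reference_column(sub)
      f <- vapply(
        seq_along(cols),
        function(i) tmm_factor(sub[, i], sub[, ref_i], params),
        numeric(1)
      )
      f <- f / geometric_mean(f)
    }
    vals[, cols] <- sweep(vals[, cols, drop = FALSE], 2, f, "/")
    fac_rows[[sp]] <- tibble::tibble(
      sample = cols, species = sp, stage = "within", factor = f
    )
  }
  panel$values <- vals
  panel$factors <- dplyr::bind_rows(c(list(panel$factors), unname(fac_rows)))
  panel$state <- "within-normalized"
  panel
}

#' Between-species TMM normalization anchored on singleton orthogroups
#'
#' Builds a singleton-orthogroup x species matrix of replicate-mean
#' expression (singleton orthogroups have exactly one gene per species, so
#' their profiles are directly comparable across species), computes one TMM
#' factor per species against a reference species, centers the factors to a
#' geometric mean of 1, and divides all replicates of each species by that
#' species' factor. Ohnolog genes never enter the factor computation.
#'
#' @param panel an [expression_panel()] in state `"within-normalized"`.
#' @param singleton_map data frame with columns `orthogroup`, `species`,
#'   `gene`: the singleton orthogroup membership (one gene per species per
#'   orthogroup; incomplete orthogroups are allowed and contribute only the
#'   species they cover).
#' @param params a [tmm_params()] object.
#' @return The panel with state `"between-normalized"`.
#' @export
normalize_between_species <- function(panel, singleton_map,
                                      params = tmm_params()) {
  panel_require_state(panel, "within-normalized")
  singleton_map <- tibble::as_tibble(singleton_map)
  if (nrow(singleton_map) == 0L) {
    abort("Between-species normalization needs a non-empty singleton set.")
  }
  if (any(duplicated(singleton_map[c("orthogroup", "species")]))) {
    abort("Singleton orthogroups must have one gene per species.")
  }
  species <- unique(panel$samples$species)
  # replicate-mean expression of each singleton gene in its own species
  sp_means <- vapply(species, function(sp) {
    cols <- panel$samples$sample[panel$samples$species == sp]
    rowMeans(panel$values[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(panel$values)))
  og <- sort(unique(singleton_map$orthogroup))
  mat <- matrix(NA_real_, length(og), length(species),
    dimnames = list(og, species)
  )
  idx <- singleton_map$gene %in% rownames(panel$values)
  sm <- singleton_map[idx, ]
  mat[cbind(
    match(sm$orthogroup, og),
    match(sm$species, species)
  )] <- sp_means[cbind(match(sm$gene, rownames(panel$values)), match(sm$species, species))]
  ref_i <- tmm_reference_column(mat)
  f <- vapply(seq_along(species), function(i) {
    keep <- !is.na(mat[, i]) & !is.na(mat[, ref_i])
    tmm_factor(mat[keep, i], mat[keep, ref_i], params)
  }, numeric(1))
  f <- f / geometric_mean(f)
  for (i in seq_along(species)) {
    cols <- panel$samples$sample[panel$samples$species == species[i]]
    panel$values[, cols] <- panel$values[, cols, drop = FALSE] / f[i]
  }
  panel$factors <- dplyr::bind_rows(
    panel$factors,
    tibble::tibble(
      sample = NA_character_, species = species,
      stage = "between", factor = f
    )
  )
  panel$state <- "between-normalized"
  panel
}

#' Log transform expression values
#'
#' Applies `log2(value + 0.01)` — the small offset keeps zeros finite
#' (`log2(0.01)` is about -6.64) while leaving well-expressed genes nearly
#' unchanged.
#'
#' @param panel an [expression_panel()]; normally in state
#'   `"between-normalized"`, but earlier states are accepted for
#'   diagnostics.
#' @return The panel on the log2 scale, state `"logged"`.
#' @export
log_transform <- function(panel) {
  if (identical(panel$state, "logged")) {
    abort("Panel is already logged.", class = "ohnoshift_state_error")
  }
  if (any(panel$values < 0, na.rm = TRUE)) {
    abort("Negative expression values cannot be log transformed.",
      class = "ohnoshift_data_integrity"
    )
  }
  panel$values <- log2(panel$values + 0.01)
  panel$state <- "logged"
  panel
}
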