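#' Expression panel: a genes x samples matrix with species structure
#'
#' Container for the multi-species replicate expression data. The numeric
#' core is a genes x samples matrix (TPM scale until [log_transform()] is
#' applied); `samples` maps each column to a species. A small state machine
#' tracks normalization progress so stages cannot be applied twice or out of
#' order: `raw -> within-normalized -> between-normalized -> logged`.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). All values must be >= 0 (TPM scale);
#'   `NA` marks samples of species in which a gene is not annotated (each
#'   gene belongs to one species in a multi-species panel).
#' @param samples data frame with columns `sample` and `species`; one row per
#'   column of `values`, in any order.
#' @return An object of class `expression_panel` with fields `values`,
#'   `samples` (tibble), `state`, and `factors` (a tibble of applied
#'   normalization factors, initially empty).
#' @examples
#' m <- matrix(rexp(12, 1 / 50), 3, 4,
#'   dimnames = list(paste0("g", 1:3), paste0("s", 1:4))
#' )
#' smp <- data.frame(sample = paste0("s", 1:4), species = rep(c("A", "B"), 2))
#' expression_panel(m, smp)
#' @export
expression_panel <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have gene rownames and sample colnames.")
  }
  if (any(values < 0, na.rm = TRUE)) {
    abort("TPM values must be non-negative.", class = "ohnoshift_data_integrity")
  }
  samples <- tibble::as_tibble(samples)
  if (!all(c("sample", "species") %in% names(samples))) {
    abort("`samples` needs columns `sample` and `species`.")
  }
  if (!setequal(samples$sample, colnames(values)) ||
    anyDuplicated(samples$sample) > 0) {
    abort("`samples$sample` must match the columns of `values` exactly.")
  }
  samples <- samples[match(colnames(values), samples$sample), ]
  structure(
    list(
      values = values,
      samples = samples,
      state = "raw",
      factors = tibble::tibble(
        sample = character(), species = character(),
        stage = character(), factor = double()
      )
    ),
    class = "expression_panel"
  )
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(
    "<expression_panel> ", nrow(x$values), " genes x ", ncol(x$values),
    " samples (", dplyr::n_distinct(x$samples$species), " species), state: ",
    x$state, "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
dim.expression_panel <- function(x) dim(x$values)

panel_require_state <- function(panel, state) {
  if (!identical(panel$state, state)) {
    abort(
      paste0(
        "Panel is in state '", panel$state, "'; this stage requires '",
        state, "'."
      ),
      class = "ohnoshift_state_error"
    )
  }
}

#' Turn an expression panel into a long tibble
#'
#' @param x an [expression_panel()].
#' @param ... unused.
#' @return Tibble with columns `gene`, `sample`, `species`, `value`.
#' @export
tidy.expression_panel <- function(x, ...) {
  out <- tibble::as_tibble(x$values, rownames = "gene")
  out <- tidyr::pivot_longer(out, -"gene",
    names_to = "sample", values_to = "value"
  )
  dplyr::left_join(out, x$samples, by = "sample")[
    ,
    c("gene", "sample", "species", "value")
  ]
}

#' One-line summary of an expression panel
#'
#' @param x an [expression_panel()].
#' @param ... unused.
#' @return One-row tibble with gene/sample/species counts and the
#'   normalization state.
#' @export
glance.expression_panel <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$values),
    n_samples = ncol(x$values),
    n_species = dplyr::n_distinct(x$samples$species),
    state = x$state
  )
}
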