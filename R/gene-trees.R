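#' Parse a Newick string into a rooted gene tree
#'
#' Thin wrapper around `ape::read.tree()` with up-front bracket validation
#' so malformed input fails with the character offset of the first
#' imbalance rather than a downstream surprise. Round-trips with
#' [serialize_newick()] preserving topology and branch lengths.
#'
#' @param text a single Newick string (with branch lengths).
#' @return A `phylo` object.
#' @examples
#' parse_newick("((A:1,B:1):1,C:2);")
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L) {
    abort("`text` must be a single Newick string.")
  }
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) {
      abort(paste0("Unbalanced ')' at character ", i, "."),
        class = "ohnoshift_parse_error"
      )
    }
  }
  if (depth != 0L) {
    abort(paste0(
      "Unbalanced '(': ", depth, " unclosed at end of string."
    ), class = "ohnoshift_parse_error")
  }
  tree <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    abort("Could not parse Newick string.", class = "ohnoshift_parse_error")
  }
  tree
}

#' Serialize a tree back to Newick
#'
#' @param tree a `phylo` object.
#' @return A Newick string.
#' @export
serialize_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Extract species names from gene tip labels
#'
#' Tip labels follow the `SPECIES|geneid` convention by default; the
#' delimiter is configurable.
#'
#' @param labels character vector of tip labels.
#' @param sep delimiter between species and gene id (default `"|"`).
#' @return Character vector of species names.
#' @export
species_of <- function(labels, sep = "|") {
  vapply(
    strsplit(labels, sep, fixed = TRUE),
    function(x) x[[1]], character(1)
  )
}

#' Classify a gene tree by its duplicate-clade topology
#'
#' Applies the topology filters: a tree is rejected if it has more than two
#' maximal ingroup (duplicated-lineage) clades, if any ingroup clade
#' contains two genes from one species (within-clade paralogs), or if any
#' outgroup species appears more than once. Otherwise the tree is a
#' `singleton` (one ingroup clade) or `ohnolog` (two clades), and
#' `complete` when every expected ingroup species is present in each clade
#' (`partial` otherwise).
#'
#' @param tree a rooted `phylo` gene tree with `SPECIES|gene` tip labels.
#' @param species_roles named character vector mapping each species to
#'   `"ingroup"` or `"outgroup"`; must cover every species in the tree.
#' @return One-row tibble: `status` (one of `singleton-complete`,
#'   `singleton-partial`, `ohnolog-complete`, `ohnolog-partial`,
#'   `rejected`), `reason` (NA unless rejected), `n_ingroup_clades`.
#' @export
classify_tree <- function(tree, species_roles) {
  sp <- species_of(tree$tip.label)
  unknown <- setdiff(unique(sp), names(species_roles))
  if (length(unknown)) {
    abort(
      paste0("Unknown species in tree: ", paste(unknown, collapse = ", ")),
      class = "ohnoshift_config_error"
    )
  }
  ingroup <- names(species_roles)[species_roles == "ingroup"]
  clades <- ingroup_clade_tips(tree, ingroup)
  reject <- function(reason) {
    tibble::tibble(
      status = "rejected", reason = reason,
      n_ingroup_clades = length(clades)
    )
  }
  if (length(clades) > 2L) {
    return(reject("excess_clades"))
  }
  if (length(clades) == 0L) {
    return(reject("no_ingroup_clade"))
  }
  for (cl in clades) {
    cl_sp <- species_of(cl)
    if (anyDuplicated(cl_sp) > 0) {
      return(reject("ingroup_paralogs"))
    }
  }
  out_sp <- sp[!(sp %in% ingroup)]
  if (anyDuplicated(out_sp) > 0) {
    return(reject("outgroup_paralogs"))
  }
  complete <- all(vapply(
    clades,
    function(cl) setequal(species_of(cl), ingroup),
    logical(1)
  ))
  status <- paste0(
    if (length(clades) == 1L) "singleton" else "ohnolog",
    if (complete) "-complete" else "-partial"
  )
  tibble::tibble(
    status = status, reason = NA_character_,
    n_ingroup_clades = length(clades)
  )
}

# Maximal ingroup-only subtrees, each split once at its top node when it
# holds more than one gene of some species: that node is the duplication
# (WGD) node joining the two duplicate clades, so the split yields the
# per-copy clades. A clade still holding duplicated species after the
# split marks within-clade paralogs (handled by the caller).
ingroup_clade_tips <- function(tree, ingroup) {
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  sp <- species_of(tree$tip.label)
  is_in <- sp %in% ingroup
  pure <- logical(n_all)
  pure[seq_len(n_tip)] <- is_in
  pure[(n_tip + 1L):n_all] <- TRUE
  post <- reorder(tree, "postorder")$edge
  for (i in seq_len(nrow(post))) {
    pure[post[i, 1]] <- pure[post[i, 1]] && pure[post[i, 2]]
  }
  parent <- integer(n_all)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- n_tip + 1L
  candidates <- c(root, reorder(tree, "cladewise")$edge[, 2])
  maximal <- candidates[vapply(candidates, function(nd) {
    pure[nd] && (nd == root || !pure[parent[nd]])
  }, logical(1))]
  tips_below <- function(nd) {
    if (nd <= n_tip) {
      return(tree$tip.label[nd])
    }
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    unlist(lapply(kids, tips_below))
  }
  out <- list()
  for (nd in maximal) {
    tips <- tips_below(nd)
    if (!any(species_of(tips) %in% ingroup)) next
    if (anyDuplicated(species_of(tips)) > 0 && nd > n_tip) {
      kids <- tree$edge[tree$edge[, 1] == nd, 2]
      out <- c(out, lapply(kids, tips_below))
    } else {
      out <- c(out, list(tips))
    }
  }
  out
}

#' Expression-based inclusion filters for an accepted gene tree
#'
#' Rejects trees where (1) any duplicate clade has no expressed gene, (2)
#' the sister-outgroup anchor species is missing from the tree or
#' unexpressed, or (3) both distant-outgroup anchor species are missing or
#' unexpressed. "Not expressed" means every replicate is at or below
#' `threshold` (default exactly zero, i.e. zero mapped reads). Only one of
#' the two distant anchors is required.
#'
#' @param tree an accepted gene tree (`phylo`).
#' @param panel an [expression_panel()] (TPM scale) containing all tree
#'   genes.
#' @param species_roles as in [classify_tree()].
#' @param sister_anchor species name of the closest outgroup anchor.
#' @param distant_anchors character vector (normally length 2) of distant
#'   outgroup anchor species.
#' @param threshold expression level at or below which a gene counts as
#'   unexpressed (default 0).
#' @return One-row tibble `status`/`reason`: `status = "pass"` when
#'   retained, `"rejected"` with a machine-readable reason otherwise.
#' @export
expression_filters <- function(tree, panel, species_roles, sister_anchor,
                               distant_anchors, threshold = 0) {
  genes <- tree$tip.label
  missing_genes <- setdiff(genes, rownames(panel$values))
  if (length(missing_genes)) {
    abort(
      paste0(
        "Panel lacks tree genes: ",
        paste(missing_genes, collapse = ", ")
      ),
      class = "ohnoshift_data_integrity"
    )
  }
  expressed <- function(gene) {
    sp <- species_of(gene)
    cols <- panel$samples$sample[panel$samples$species == sp]
    vals <- panel$values[gene, cols]
    vals <- vals[!is.na(vals)]
    length(vals) > 0 && any(vals > threshold)
  }
  ingroup <- names(species_roles)[species_roles == "ingroup"]
  clades <- ingroup_clade_tips(tree, ingroup)
  for (cl in clades) {
    if (!any(vapply(cl, expressed, logical(1)))) {
      return(tibble::tibble(status = "rejected", reason = "unexpressed_clade"))
    }
  }
  sp <- species_of(genes)
  sister_genes <- genes[sp %in% sister_anchor]
  if (length(sister_genes) == 0L ||
    !any(vapply(sister_genes, expressed, logical(1)))) {
    return(tibble::tibble(status = "rejected", reason = "sister_anchor_absent"))
  }
  distant_genes <- genes[sp %in% distant_anchors]
  if (length(distant_genes) == 0L ||
    !any(vapply(distant_genes, expressed, logical(1)))) {
    return(tibble::tibble(
      status = "rejected",
      reason = "distant_anchors_absent"
    ))
  }
  tibble::tibble(status = "pass", reason = NA_character_)
}

#' Split an accepted gene tree into per-clade test units
#'
#' A singleton tree yields one unit containing every gene. An ohnolog tree
#' yields two units, each holding one duplicate clade plus all outgroup
#' genes — each duplicate clade is tested separately with the other clade
#' removed, so both units share the outgroup data.
#'
#' @param tree an accepted gene tree (`phylo`).
#' @param species_roles as in [classify_tree()].
#' @param orthogroup id recorded on each unit.
#' @return List of units; each unit is a list with `orthogroup`, `clade`
#'   (integer), and `genes` (tibble `gene`, `species`).
#' @export
extract_test_units <- function(tree, species_roles, orthogroup = NA_character_) {
  ingroup <- names(species_roles)[species_roles == "ingroup"]
  clades <- ingroup_clade_tips(tree, ingroup)
  if (length(clades) == 0L || length(clades) > 2L) {
    abort("Tree must have 1 or 2 ingroup clades (run classify_tree first).")
  }
  sp <- species_of(tree$tip.label)
  outgroup_genes <- tree$tip.label[!(sp %in% ingroup)]
  lapply(seq_along(clades), function(i) {
    genes <- c(clades[[i]], outgroup_genes)
    list(
      orthogroup = orthogroup, clade = i,
      genes = tibble::tibble(gene = genes, species = species_of(genes))
    )
  })
}

#' Prune a species tree to a subset of tips
#'
#' Drops all other tips, collapsing degree-2 internal nodes with summed
#' branch lengths, so patristic distances among the kept tips are exactly
#' preserved.
#'
#' @param tree a `phylo`.
#' @param keep tip labels to retain (at least 3; the OU model is
#'   unidentifiable below that).
#' @return The pruned `phylo`.
#' @export
prune_species_tree <- function(tree, keep) {
  if (!all(keep %in% tree$tip.label)) {
    abort("`keep` must be a subset of the tree's tips.")
  }
  if (length(unique(keep)) < 3L) {
    abort("Refusing to prune below 3 tips (model unidentifiable).",
      class = "ohnoshift_model_error"
    )
  }
  if (setequal(keep, tree$tip.label)) {
    return(tree)
  }
  ape::keep.tip(tree, unique(keep))
}
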