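#' Build promoter intervals around transcription start sites
#'
#' Strand-aware windows: on the `+` strand a promoter spans
#' `[pos - upstream, pos + downstream)`; on the `-` strand
#' `[pos - downstream, pos + upstream)`. Coordinates are 0-based
#' half-open and clipped to `[0, chromosome size)`. Records on chromosomes
#' absent from `chrom_sizes` are skipped with a warning.
#'
#' @param tss tibble with columns `gene`, `chrom`, `pos`, `strand`.
#' @param window `c(upstream, downstream)` in bases.
#' @param chrom_sizes tibble with columns `chrom`, `size`.
#' @return Interval tibble: `chrom`, `start`, `end`, `strand`, `name` (the
#'   gene id).
#' @examples
#' tss <- tibble::tibble(gene = "g1", chrom = "chr1", pos = 10000, strand = "+")
#' sizes <- tibble::tibble(chrom = "chr1", size = 1e6)
#' make_promoters(tss, c(3000, 200), sizes) # [7000, 10200)
#' @export
make_promoters <- function(tss, window, chrom_sizes) {
  tss <- tibble::as_tibble(tss)
  if (!all(tss$strand %in% c("+", "-"))) {
    abort("TSS records must carry strand ('+'/'-').")
  }
  known <- tss$chrom %in% chrom_sizes$chrom
  if (any(!known)) {
    warn(paste0(
      sum(!known), " TSS record(s) on unknown chromosomes skipped."
    ))
    tss <- tss[known, ]
  }
  size <- chrom_sizes$size[match(tss$chrom, chrom_sizes$chrom)]
  up <- window[1]
  down <- window[2]
  start <- ifelse(tss$strand == "+", tss$pos - up, tss$pos - down)
  end <- ifelse(tss$strand == "+", tss$pos + down, tss$pos + up)
  tibble::tibble(
    chrom = tss$chrom,
    start = as.integer(pmax(0, start)),
    end = as.integer(pmin(size, end)),
    strand = tss$strand,
    name = tss$gene
  )
}

#' Fraction of each interval covered by another interval set
#'
#' For every record in `a` (e.g. promoters), computes the fraction of its
#' bases covered by the union of `b` (e.g. TE annotations): overlapping `b`
#' intervals are merged before measuring, so double-covered bases count
#' once. Overlap is strand-blind. Zero-length `a` records (possible after
#' clipping) are excluded.
#'
#' @param a interval tibble (`chrom`, `start`, `end`, `name`).
#' @param b interval tibble on the same coordinate system.
#' @param by column of `a` naming each record in the output (default
#'   `"name"`).
#' @return Tibble with the `by` column and `fraction` in \[0, 1\].
#' @export
overlap_fraction <- function(a, b, by = "name") {
  a <- tibble::as_tibble(a)
  b <- tibble::as_tibble(b)
  a <- a[a$end > a$start, ]
  out <- vector("list", length(unique(a$chrom)))
  res <- numeric(nrow(a))
  for (ch in unique(a$chrom)) {
    ai <- which(a$chrom == ch)
    bi <- b$chrom == ch
    # IRanges is closed 1-based; shift half-open starts by 1
    ar <- IRanges::IRanges(a$start[ai] + 1L, a$end[ai])
    if (!any(bi)) {
      res[ai] <- 0
      next
    }
    br <- IRanges::reduce(IRanges::IRanges(b$start[bi] + 1L, b$end[bi]))
    ov <- IRanges::findOverlaps(ar, br)
    cov <- numeric(length(ar))
    if (length(ov)) {
      qi <- S4Vectors::queryHits(ov)
      si <- S4Vectors::subjectHits(ov)
      w <- IRanges::width(IRanges::pintersect(ar[qi], br[si]))
      cov <- as.numeric(tapply(w, factor(qi, levels = seq_along(ar)), sum))
      cov[is.na(cov)] <- 0
    }
    res[ai] <- cov / IRanges::width(ar)
  }
  out <- tibble::tibble(a[[by]], fraction = res)
  names(out)[1] <- by
  out
}

#' Count bound TFBS rows per gene
#'
#' Two modes: `"sites"` counts bound rows per gene; `"tfs"` counts distinct
#' transcription factors with at least one bound row per gene. Optionally
#' restricted to a TF subset. Genes with no bound rows report 0.
#'
#' @param sites bound-site tibble with columns `gene`, `tf`, `bound`.
#' @param genes character vector of genes to report.
#' @param tf_filter optional character vector of TFs to restrict to.
#' @param mode `"sites"` or `"tfs"`.
#' @return Tibble `gene`, `count`.
#' @export
count_bound_sites <- function(sites, genes, tf_filter = NULL,
                              mode = c("sites", "tfs")) {
  mode <- match.arg(mode)
  sites <- tibble::as_tibble(sites)
  sites <- sites[sites$bound & sites$gene %in% genes, ]
  if (!is.null(tf_filter)) sites <- sites[sites$tf %in% tf_filter, ]
  counts <- if (mode == "sites") {
    dplyr::count(sites, .data$gene, name = "count")
  } else {
    dplyr::count(dplyr::distinct(sites, .data$gene, .data$tf),
      .data$gene,
      name = "count"
    )
  }
  out <- tibble::tibble(gene = genes)
  out <- dplyr::left_join(out, counts, by = "gene")
  out$count[is.na(out$count)] <- 0L
  out
}

#' Order ohnolog pair copies by shift-test p-value
#'
#' Adds `copy_low_p` / `copy_high_p` gene columns: the copy with the lower
#' OU-test p-value first; exact ties broken by lexicographic gene id.
#' Stable under row shuffling of the input.
#'
#' @param pairs tibble with columns `gene_1`, `gene_2`, `p_1`, `p_2`.
#' @return The input with `copy_low_p` and `copy_high_p` columns appended.
#' @export
rank_pair_by_shift <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  first_low <- ifelse(
    pairs$p_1 == pairs$p_2,
    pairs$gene_1 <= pairs$gene_2,
    pairs$p_1 < pairs$p_2
  )
  dplyr::mutate(
    pairs,
    copy_low_p = ifelse(first_low, .data$gene_1, .data$gene_2),
    copy_high_p = ifelse(first_low, .data$gene_2, .data$gene_1)
  )
}

#' Count TE-overlapping bound liver-TF sites per ohnolog pair
#'
#' For each up+cons pair, counts bound sites of the given (liver-specific)
#' TFs whose position overlaps a TE insertion, separately for the
#' up-shifted and the conserved copy; optionally split by TE superfamily.
#' These per-pair counts feed the paired one-sided Wilcoxon test of
#' TE-mediated binding-site gain.
#'
#' @param pairs tibble with `gene_up` and `gene_cons` columns.
#' @param sites bound-site tibble (`gene`, `tf`, `bound`, `te_overlap`,
#'   `te_superfamily`).
#' @param tf_set character vector of (liver-specific) TFs to count.
#' @param group_by `"none"` or `"superfamily"`.
#' @return Tibble with one row per pair (`gene_up`, `gene_cons`,
#'   `count_up`, `count_cons`), plus a `superfamily` column when grouped;
#'   grouped counts sum to the ungrouped counts.
#' @export
te_site_overlap_by_copy <- function(pairs, sites, tf_set,
                                    group_by = c("none", "superfamily")) {
  group_by <- match.arg(group_by)
  pairs <- tibble::as_tibble(pairs)
  sites <- tibble::as_tibble(sites)
  sites <- sites[sites$bound & sites$te_overlap & sites$tf %in% tf_set, ]
  count_for <- function(gene, fam = NULL) {
    s <- sites[sites$gene == gene, ]
    if (!is.null(fam)) s <- s[s$te_superfamily == fam, ]
    as.numeric(nrow(s))
  }
  if (group_by == "none") {
    return(dplyr::mutate(
      pairs,
      count_up = unname(vapply(.data$gene_up, count_for, numeric(1))),
      count_cons = unname(vapply(.data$gene_cons, count_for, numeric(1)))
    ))
  }
  fams <- sort(unique(sites$te_superfamily))
  out <- lapply(fams, function(fam) {
    dplyr::mutate(
      pairs,
      superfamily = fam,
      count_up = unname(vapply(
        .data$gene_up, function(g) count_for(g, fam), numeric(1)
      )),
      count_cons = unname(vapply(
        .data$gene_cons, function(g) count_for(g, fam), numeric(1)
      ))
    )
  })
  dplyr::bind_rows(out)
}

#' Reconstruct the focal-tissue regulatory network for up-shifted ohnologs
#'
#' The filter cascade used to nominate tissue-specific regulators of
#' ohnologs with a focal-tissue gain in expression:
#'
#' 1. candidate TFs: per motif, the top `top_hits` homology hits with
#'    E-value below `evalue_max` and alignment length above `aln_min`;
#' 2. keep TFs with a bound site in at least `min_targets` target
#'    promoters;
#' 3. keep TFs with focal-tissue-specific expression
#'    ([liver_specific_filter()]).
#'
#' The network is then reduced: per motif the TF with the strongest
#' expression shift (largest |LRT|) is kept; motifs whose target sets
#' overlap by more than `merge_overlap` (overlap coefficient) are merged,
#' keeping the stronger-shift TF; TFs with several motifs collapse into
#' one node; and TFs are ranked by up-shift bias (bound up-copies minus
#' bound conserved copies, ties by total bound targets then name), keeping
#' the `top_n` for display. Edges are TF -> gene for every bound target
#' promoter. Output is invariant to input row order.
#'
#' @param targets tibble `gene`, `copy` (`"up"`/`"cons"`): the target genes
#'   (both copies of each up+cons pair).
#' @param sites bound-site tibble (`gene`, `tf`, `motif`, `bound`).
#' @param tf_candidates tibble `tf`, `motif`, `evalue`, `aln_length`.
#' @param tissues genes x tissues matrix holding TF expression rows.
#' @param focal focal tissue column name.
#' @param tf_shift tibble `tf`, `lrt`: each TF's expression shift statistic.
#' @param min_targets,evalue_max,aln_min,top_hits,merge_overlap,top_n
#'   cascade thresholds (defaults 20, 1e-10, 100, 4, 0.8, 9).
#' @return List: `stages` (named list of TF sets after each stage),
#'   `edges` (tibble `tf`, `gene`, `motif`), `nodes` (tibble `node`,
#'   `type`, `in_degree`, `up_bias`), `empty_stage` (name of the first
#'   stage that emptied the set, or `NA`).
#' @export
build_liver_network <- function(targets, sites, tf_candidates, tissues,
                                focal, tf_shift,
                                min_targets = 20L, evalue_max = 1e-10,
                                aln_min = 100L, top_hits = 4L,
                                merge_overlap = 0.8, top_n = 9L) {
  targets <- dplyr::arrange(tibble::as_tibble(targets), .data$gene)
  sites <- tibble::as_tibble(sites)
  tf_candidates <- tibble::as_tibble(tf_candidates)
  tf_shift <- tibble::as_tibble(tf_shift)
  empty_result <- function(stage, stages) {
    list(
      stages = stages,
      edges = tibble::tibble(
        tf = character(), gene = character(), motif = character()
      ),
      nodes = tibble::tibble(
        node = character(), type = character(),
        in_degree = integer(), up_bias = integer()
      ),
      empty_stage = stage
    )
  }
  stages <- list()

  # stage 1: homology-filtered candidates, top hits per motif
  cand <- tf_candidates[
    tf_candidates$evalue < evalue_max & tf_candidates$aln_length > aln_min,
  ]
  cand <- dplyr::slice_min(
    dplyr::group_by(cand, .data$motif),
    order_by = .data$evalue, n = top_hits, with_ties = FALSE
  )
  cand <- dplyr::ungroup(cand)
  stages$candidates <- sort(unique(cand$tf))
  if (nrow(cand) == 0L) {
    return(empty_result("candidates", stages))
  }

  bound <- sites[sites$bound &
    sites$gene %in% targets$gene &
    sites$tf %in% cand$tf, ]

  # stage 2: bound in enough target promoters
  per_tf <- dplyr::count(
    dplyr::distinct(bound, .data$tf, .data$gene), .data$tf
  )
  kept2 <- sort(per_tf$tf[per_tf$n >= min_targets])
  stages$bound_targets <- kept2
  if (length(kept2) == 0L) {
    return(empty_result("bound_targets", stages))
  }

  # stage 3: focal-tissue-specific expression
  kept3 <- liver_specific_filter(
    kept2[kept2 %in% rownames(tissues)], tissues, focal
  )
  stages$liver_specific <- sort(kept3)
  if (length(kept3) == 0L) {
    return(empty_result("liver_specific", stages))
  }

  lrt_of <- function(tf) {
    v <- abs(tf_shift$lrt[match(tf, tf_shift$tf)])
    ifelse(is.na(v), 0, v)
  }
  bound3 <- bound[bound$tf %in% kept3, ]

  # reduction a: per motif, strongest-shift TF
  motif_tf <- dplyr::distinct(cand[cand$tf %in% kept3, ], .data$motif, .data$tf)
  motif_tf <- dplyr::slice_max(
    dplyr::group_by(motif_tf, .data$motif),
    order_by = lrt_of(.data$tf), n = 1L, with_ties = FALSE
  )
  motif_tf <- dplyr::arrange(dplyr::ungroup(motif_tf), .data$motif)

  # reduction b: merge motifs with highly similar target sets
  motif_targets <- lapply(setNames(motif_tf$motif, motif_tf$motif), function(m) {
    sort(unique(bound3$gene[bound3$motif == m & bound3$tf %in% motif_tf$tf]))
  })
  motifs <- motif_tf$motif
  dropped <- character()
  for (i in seq_along(motifs)) {
    for (j in seq_along(motifs)) {
      if (i >= j) next
      mi <- motifs[i]
      mj <- motifs[j]
      if (mi %in% dropped || mj %in% dropped) next
      ti <- motif_targets[[mi]]
      tj <- motif_targets[[mj]]
      if (length(ti) == 0 || length(tj) == 0) next
      ov <- length(intersect(ti, tj)) / min(length(ti), length(tj))
      if (ov > merge_overlap) {
        tf_i <- motif_tf$tf[motif_tf$motif == mi]
        tf_j <- motif_tf$tf[motif_tf$motif == mj]
        weaker <- if (lrt_of(tf_i) >= lrt_of(tf_j)) mj else mi
        dropped <- c(dropped, weaker)
      }
    }
  }
  motif_tf <- motif_tf[!(motif_tf$motif %in% dropped), ]

  # reduction c+d: collapse multi-motif TFs, rank by up-shift bias
  final_tfs <- sort(unique(motif_tf$tf))
  up_genes <- targets$gene[targets$copy == "up"]
  cons_genes <- targets$gene[targets$copy == "cons"]
  tf_stats <- dplyr::bind_rows(lapply(final_tfs, function(tf) {
    tg <- unique(bound3$gene[bound3$tf == tf &
      bound3$motif %in% motif_tf$motif])
    tibble::tibble(
      tf = tf,
      n_up = sum(tg %in% up_genes),
      n_cons = sum(tg %in% cons_genes),
      n_total = length(tg)
    )
  }))
  tf_stats$up_bias <- tf_stats$n_up - tf_stats$n_cons
  tf_stats <- dplyr::arrange(
    tf_stats, dplyr::desc(.data$up_bias), dplyr::desc(.data$n_total), .data$tf
  )
  show_tfs <- head(tf_stats$tf, top_n)
  stages$displayed <- show_tfs

  edges <- dplyr::distinct(
    bound3[bound3$tf %in% show_tfs & bound3$motif %in% motif_tf$motif, ],
    .data$tf, .data$gene, .data$motif
  )
  edges <- dplyr::arrange(edges, .data$tf, .data$gene, .data$motif)
  in_deg <- dplyr::count(dplyr::distinct(edges, .data$tf, .data$gene),
    .data$gene,
    name = "in_degree"
  )
  nodes <- dplyr::bind_rows(
    tibble::tibble(
      node = show_tfs, type = "tf", in_degree = NA_integer_,
      up_bias = tf_stats$up_bias[match(show_tfs, tf_stats$tf)]
    ),
    tibble::tibble(
      node = in_deg$gene, type = "gene", in_degree = in_deg$in_degree,
      up_bias = NA_integer_
    )
  )
  list(
    stages = stages, edges = edges, nodes = nodes, empty_stage = NA_character_
  )
}
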