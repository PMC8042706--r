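#' Simulate genomic context tables for a cohort
#'
#' Generates the fixture tables the genomic-context and association modules
#' consume, for the genes of the focal ingroup species (the species with
#' promoter/TE/TFBS annotations in a real study): TSS positions and
#' promoter intervals, TE insertions (planted at `te_down_bias` times the
#' base rate in promoters of truly down-shifted copies), bound-TFBS rows
#' with tissue-specific TF labels (bound liver-TF sites planted at
#' `tfbs_up_bias` times the base rate in up-shifted copies), and pathway /
#' protein-complex annotations with one planted pathway enrichment among
#' down-shifted orthogroups and a planted homogeneity bias in complex
#' composition.
#'
#' @param sims output of [simulate_orthogroups()].
#' @param config a [sim_config()].
#' @return List with tibbles `tss`, `promoters`, `tes`, `bound_sites`,
#'   `pathways` (`gene`, `term`), `complexes` (`complex`, `gene`, `class`),
#'   `tf_info` (`tf`, `motif`, `liver_specific`), `chrom_sizes`, and
#'   `planted` (the ground-truth plantings).
#' @export
simulate_genomic_context <- function(sims, config) {
  truth <- sims$truth
  focal <- truth$species[1] # first ingroup species carries the annotations
  genes <- truth[truth$species == focal, ]
  n <- nrow(genes)
  up_len <- config$promoter_len - 200L

  with_seed(stage_seed(config$seed, "context"), {
    n_chr <- 5L
    chrom <- paste0("chr", rep_len(seq_len(n_chr), n))
    idx_on_chr <- stats::ave(seq_len(n), chrom, FUN = seq_along)
    tss_pos <- 5000L + (idx_on_chr - 1L) * 10000L
    strand <- rep_len(c("+", "-"), n)
    tss <- tibble::tibble(
      gene = genes$gene, chrom = chrom, pos = tss_pos, strand = strand
    )
    chrom_sizes <- dplyr::summarise(
      dplyr::group_by(tss, .data$chrom),
      size = max(.data$pos) + 20000L, .groups = "drop"
    )
    promoters <- make_promoters(tss, window = c(up_len, 200L), chrom_sizes)

    # TE insertions, elevated in promoters of truly down-shifted copies
    te_superfams <- c("TcMar-Tc1", "L1", "Gypsy", "PiggyBac")
    te_rows <- vector("list", n)
    down <- genes$copy_direction == "down"
    for (i in seq_len(n)) {
      rate <- config$te_rate * if (down[i]) config$te_down_bias else 1
      k <- stats::rpois(1, rate)
      if (k == 0) {
        next
      }
      p <- promoters[promoters$name == genes$gene[i], ]
      len <- pmin(50L + stats::rgeom(k, 1 / 150), p$end - p$start - 1L)
      start <- p$start + floor(runif(k, 0, p$end - p$start - len))
      te_rows[[i]] <- tibble::tibble(
        chrom = p$chrom, start = as.integer(start),
        end = as.integer(start + len), strand = ".",
        name = paste0("TE_", genes$gene[i], "_", seq_len(k)),
        superfamily = sample(te_superfams, k,
          replace = TRUE,
          prob = c(0.35, 0.3, 0.2, 0.15)
        ),
        gene = genes$gene[i]
      )
    }
    tes <- dplyr::bind_rows(te_rows)
    if (nrow(tes) == 0L) {
      tes <- tibble::tibble(
        chrom = character(), start = integer(), end = integer(),
        strand = character(), name = character(),
        superfamily = character(), gene = character()
      )
    }

    # TF pool; the first third are liver-specific
    n_tf <- 30L
    tf_info <- tibble::tibble(
      tf = sprintf("TF%02d", seq_len(n_tf)),
      motif = sprintf("MA%04d.1", seq_len(n_tf)),
      liver_specific = seq_len(n_tf) <= 10L
    )
    liver_share <- 1 / 3
    up <- genes$copy_direction == "up"
    site_rows <- vector("list", n)
    for (i in seq_len(n)) {
      p <- promoters[promoters$name == genes$gene[i], ]
      rate_liver <- config$tfbs_rate * liver_share *
        if (up[i]) config$tfbs_up_bias else 1
      rate_other <- config$tfbs_rate * (1 - liver_share)
      k_l <- stats::rpois(1, rate_liver)
      k_o <- stats::rpois(1, rate_other)
      if (k_l + k_o == 0) next
      tf_idx <- c(
        sample(which(tf_info$liver_specific), k_l, replace = TRUE),
        sample(which(!tf_info$liver_specific), k_o, replace = TRUE)
      )
      start <- p$start + floor(runif(k_l + k_o, 0, p$end - p$start - 12))
      site <- tibble::tibble(
        gene = genes$gene[i],
        chrom = p$chrom, start = as.integer(start),
        end = as.integer(start + 12L),
        tf = tf_info$tf[tf_idx], motif = tf_info$motif[tf_idx],
        bound = runif(k_l + k_o) < 0.6
      )
      g_tes <- tes[tes$gene == genes$gene[i], ]
      if (nrow(g_tes)) {
        ov <- vapply(seq_len(nrow(site)), function(j) {
          hit <- which(
            g_tes$start < site$end[j] & g_tes$end > site$start[j]
          )
          if (length(hit)) hit[1] else NA_integer_
        }, integer(1))
        site$te_overlap <- !is.na(ov)
        site$te_superfamily <- ifelse(
          is.na(ov), "", g_tes$superfamily[ifelse(is.na(ov), 1L, ov)]
        )
      } else {
        site$te_overlap <- FALSE
        site$te_superfamily <- ""
      }
      site_rows[[i]] <- site
    }
    bound_sites <- dplyr::bind_rows(site_rows)

    # pathway annotations at the orthogroup level, one planted enrichment
    # among down-shifted ohnolog orthogroups
    og_info <- sims$tree_info
    pw_ids <- sprintf("pw%02d", seq_len(config$n_pathways))
    planted_pw <- pw_ids[1]
    down_cats <- c("down+cons", "down+down", "up+down")
    pw_rows <- lapply(seq_len(nrow(og_info)), function(i) {
      og <- og_info$orthogroup[i]
      is_down <- og_info$category[i] %in% down_cats
      terms <- pw_ids[runif(config$n_pathways) < 0.08]
      if (is_down && runif(1) < 0.5) terms <- union(terms, planted_pw)
      if (length(terms) == 0) {
        return(NULL)
      }
      tibble::tibble(orthogroup = og, term = terms)
    })
    pathway_og <- dplyr::bind_rows(pw_rows)
    pathways <- dplyr::inner_join(
      pathway_og,
      genes[, c("orthogroup", "gene")],
      by = "orthogroup", relationship = "many-to-many"
    )[, c("gene", "term")]

    # protein complexes with a planted homogeneity bias: most complexes
    # draw all members from one tree class
    og_class <- setNames(og_info$tree_class, og_info$orthogroup)
    cx_rows <- lapply(seq_len(config$n_complexes), function(ci) {
      k <- sample(3:6, 1)
      homogeneous <- runif(1) < 0.7
      pool <- if (homogeneous) {
        cls <- sample(c("singleton", "ohnolog"), 1)
        names(og_class)[og_class == cls]
      } else {
        names(og_class)
      }
      members <- sample(pool, min(k, length(pool)))
      tibble::tibble(
        complex = sprintf("CPX%03d", ci), orthogroup = members,
        class = unname(og_class[members])
      )
    })
    complexes_og <- dplyr::bind_rows(cx_rows)
    complexes <- dplyr::inner_join(
      complexes_og, genes[, c("orthogroup", "gene")],
      by = "orthogroup", relationship = "many-to-many"
    )[, c("complex", "gene", "class")]

    list(
      tss = tss, promoters = promoters, tes = tes,
      bound_sites = bound_sites, pathways = pathways,
      pathway_orthogroups = pathway_og,
      complexes = complexes, tf_info = tf_info, chrom_sizes = chrom_sizes,
      planted = list(
        te_down_bias = config$te_down_bias,
        tfbs_up_bias = config$tfbs_up_bias,
        enriched_pathway = planted_pw,
        focal_species = focal
      )
    )
  })
}
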