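#' Reference-population state frequencies for one gene
#'
#' Computes, over the subjects of a designated reference population only,
#' the frequency of each genotype state at each retained site of a gene:
#' two states (alleles 0/1) for mitochondrial genes, three states (hom-ref,
#' het, hom-alt) for nuclear genes. States never observed in the reference
#' have frequency 0.
#'
#' @param block A filtered [genotype_block()].
#' @param panel Panel tibble (`subject`, `population`).
#' @param ref_pop Reference population code; must appear in the panel.
#' @return Tibble with columns `site_id`, `state`, `freq`; per site the
#'   frequencies sum to 1 over the state alphabet.
#' @export
reference_frequencies <- function(block, panel, ref_pop) {
  ref_ids <- ref_subjects(panel, ref_pop)
  states <- block$states[intersect(block$subject_ids, ref_ids), , drop = FALSE]
  alphabet <- if (block$genome_class == "mitochondrial") 0:1 else 0:2
  out <- purrr::map_dfr(alphabet, function(s) {
    tibble::tibble(site_id = block$sites$site_id, state = s,
                   freq = unname(colMeans(states == s)))
  })
  out <- dplyr::arrange(out, match(.data$site_id, block$sites$site_id), .data$state)
  attr(out, "ref_pop") <- ref_pop
  attr(out, "genome_class") <- block$genome_class
  out
}

#' Joint reference frequencies for all site pairs of a gene pair
#'
#' For every (mitochondrial site, nuclear site) pair, the reference
#' frequency of each of the six joint states (mt allele 0/1 crossed with
#' nuclear hom-ref/het/hom-alt). Intended for small blocks and for checking
#' the vectorized pair scorer; [build_feature_table()] never materializes
#' this table.
#'
#' @param mt_block,nuc_block Filtered genotype blocks over the same subjects.
#' @inheritParams reference_frequencies
#' @return Tibble `mt_site`, `nuc_site`, `mt_state`, `nuc_state`, `freq`.
#' @export
joint_reference_frequencies <- function(mt_block, nuc_block, panel, ref_pop) {
  ref_ids <- ref_subjects(panel, ref_pop)
  ids <- intersect(mt_block$subject_ids, ref_ids)
  A <- mt_block$states[ids, , drop = FALSE]
  B <- nuc_block$states[ids, , drop = FALSE]
  grid <- tidyr::expand_grid(mt_site = mt_block$sites$site_id,
                             nuc_site = nuc_block$sites$site_id,
                             mt_state = 0:1, nuc_state = 0:2)
  grid$freq <- purrr::pmap_dbl(grid, function(mt_site, nuc_site, mt_state, nuc_state) {
    mean(A[, mt_site] == mt_state & B[, nuc_site] == nuc_state)
  })
  attr(grid, "ref_pop") <- ref_pop
  grid
}

ref_subjects <- function(panel, ref_pop) {
  ids <- panel$subject[panel$population == ref_pop]
  if (length(ids) == 0) {
    abort(sprintf("reference population '%s' absent from panel", ref_pop))
  }
  ids
}

#' Frequency score of one subject for one gene
#'
#' The gene-level frequency score is the subject's mean distance from the
#' reference population: the average, over the gene's retained SNVs, of one
#' minus the reference frequency of the state the subject carries. A score
#' of 0 means every state the subject carries is fixed in the reference; a
#' score of 1 means none of them was ever seen there.
#'
#' @param block A filtered, nonempty [genotype_block()].
#' @param ref_table Output of [reference_frequencies()] for the same block.
#' @param subject Subject id present in the block.
#' @return A score in `[0, 1]`.
#' @export
gene_score <- function(block, ref_table, subject) {
  if (ncol(block$states) == 0) abort("empty genotype block has no score")
  if (!subject %in% block$subject_ids) abort(sprintf("subject %s not in block", subject))
  st <- block$states[subject, ]
  key <- paste(block$sites$site_id, st)
  f <- setNames(ref_table$freq, paste(ref_table$site_id, ref_table$state))[key]
  mean(1 - f)
}

#' Frequency score of one subject for a gene pair
#'
#' The pair-level score averages, over all (mt site, nuc site) pairs of the
#' two genes, one minus the reference frequency of the subject's joint state
#' (mt allele combined with nuclear genotype; six states).
#'
#' @param mt_block,nuc_block Filtered, nonempty genotype blocks sharing the
#'   subject set.
#' @param joint_ref_table Output of [joint_reference_frequencies()].
#' @param subject Subject id present in both blocks.
#' @return A score in `[0, 1]`.
#' @export
pair_score <- function(mt_block, nuc_block, joint_ref_table, subject) {
  if (!subject %in% mt_block$subject_ids || !subject %in% nuc_block$subject_ids) {
    abort(sprintf("subject %s missing from a block", subject))
  }
  a <- mt_block$states[subject, ]
  g <- nuc_block$states[subject, ]
  key <- paste(joint_ref_table$mt_site, joint_ref_table$nuc_site,
               joint_ref_table$mt_state, joint_ref_table$nuc_state)
  f <- setNames(joint_ref_table$freq, key)
  grid <- tidyr::expand_grid(i = seq_along(a), j = seq_along(g))
  want <- paste(mt_block$sites$site_id[grid$i], nuc_block$sites$site_id[grid$j],
                a[grid$i], g[grid$j])
  mean(1 - f[want])
}

## N x n_ref matrix of per-gene state-agreement counts between every scored
## subject and every reference subject. The workhorse identity behind the
## fast scorer: with f(s) the reference frequency of state s at a site,
##   sum_sites f(state carried) = (1/n_ref) * sum_ref #matching sites,
## so gene scores are 1 - rowSums(G)/(n_ref*M) and pair scores are
## 1 - rowSums(G_mt * G_nuc)/(n_ref*M*K) without touching site pairs.
agreement_matrix <- function(block, ref_ids) {
  A <- block$states
  R <- block$states[ref_ids, , drop = FALSE]
  G <- matrix(0, nrow = nrow(A), ncol = length(ref_ids),
              dimnames = list(rownames(A), ref_ids))
  alphabet <- if (block$genome_class == "mitochondrial") 0:1 else 0:2
  for (s in alphabet) {
    G <- G + (A == s) %*% t(R == s)
  }
  G
}

#' Build the subjects-by-features frequency-score table
#'
#' Scores every subject in the panel (including the reference population's
#' own subjects) against reference-population state frequencies, producing
#' one feature column per gene (`mode = "mt"` or `"nuc"`) or per
#' (mitochondrial gene, nuclear gene) pair (`mode = "pair"`, columns named
#' `"MTGENE+NUCGENE"`, mitochondrial-major order). Pair scores are computed
#' through per-gene agreement matrices, so the cost is linear in sites, not
#' in site pairs.
#'
#' @param blocks Named list of filtered genotype blocks.
#' @param panel Panel tibble.
#' @param ref_pop Reference population code.
#' @param mode `"mt"`, `"nuc"` or `"pair"`.
#' @return Tibble with columns `subject`, `population`, then one numeric
#'   score column in `[0,1]` per feature; attributes `ref_pop` and `mode`.
#' @export
build_feature_table <- function(blocks, panel, ref_pop, mode = c("mt", "nuc", "pair")) {
  mode <- match.arg(mode)
  blocks <- check_blocks(blocks)
  ref_ids <- ref_subjects(panel, ref_pop)
  classes <- vapply(blocks, function(b) b$genome_class, character(1))
  blocks <- lapply(blocks, subset_subjects, subjects = panel$subject)

  score_block <- function(b) {
    G <- agreement_matrix(b, ref_ids)
    unname(1 - rowSums(G) / (length(ref_ids) * ncol(b$states)))
  }

  out <- tibble::tibble(subject = panel$subject, population = panel$population)
  if (mode %in% c("mt", "nuc")) {
    want <- if (mode == "mt") "mitochondrial" else "nuclear"
    use <- blocks[classes == want]
    if (length(use) == 0) abort(sprintf("no %s blocks available for mode '%s'", want, mode))
    for (nm in names(use)) out[[nm]] <- score_block(use[[nm]])
  } else {
    mt <- blocks[classes == "mitochondrial"]
    nuc <- blocks[classes == "nuclear"]
    if (length(mt) == 0 || length(nuc) == 0) {
      abort("pair mode needs at least one mitochondrial and one nuclear block")
    }
    G_mt <- lapply(mt, agreement_matrix, ref_ids = ref_ids)
    G_nuc <- lapply(nuc, agreement_matrix, ref_ids = ref_ids)
    for (m in names(mt)) {
      for (k in names(nuc)) {
        denom <- length(ref_ids) * ncol(mt[[m]]$states) * ncol(nuc[[k]]$states)
        out[[paste0(m, "+", k)]] <- unname(1 - rowSums(G_mt[[m]] * G_nuc[[k]]) / denom)
      }
    }
  }
  attr(out, "ref_pop") <- ref_pop
  attr(out, "mode") <- mode
  out
}

#' Write a feature table as TSV
#'
#' @param features Output of [build_feature_table()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_feature_table <- function(features, path) {
  readr::write_tsv(features, path)
  invisible(path)
}
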