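#' Population-specific features by list intersection
#'
#' A feature (gene or gene pair) is specific to a population when it appears
#' in the optimal feature list of every classification experiment involving
#' that population — with three populations, the four experiments where the
#' population is either the reference or the target (e.g. for GBR: GBR vs
#' FIN, GBR vs TSI, FIN vs GBR, TSI vs GBR).
#'
#' @param results Named list of `rf_experiment`s for one mode, covering all
#'   ordered population pairs.
#' @param population Population code.
#' @return A `specificity_report`: list with `population`, `mode`,
#'   `specific_features` (character, possibly empty) and `experiments`
#'   (contributing experiment names).
#' @export
population_specific <- function(results, population) {
  pops <- unique(unlist(lapply(results, function(r) c(r$ref_pop, r$target_pop))))
  others <- setdiff(pops, population)
  if (length(others) == 0) abort(sprintf("no experiments involve population %s", population))
  wanted <- c(paste0(population, "_vs_", others), paste0(others, "_vs_", population))
  missing <- setdiff(wanted, names(results))
  if (length(missing) > 0) {
    abort(sprintf("missing experiments: %s", paste(missing, collapse = ", ")))
  }
  lists <- lapply(results[wanted], function(r) r$optimal_features)
  structure(
    list(population = population,
         mode = results[[wanted[1]]]$mode,
         specific_features = Reduce(intersect, lists),
         experiments = wanted),
    class = "specificity_report"
  )
}

#' @export
print.specificity_report <- function(x, ...) {
  cat(sprintf("<specificity_report> %s, mode %s (%d experiments)\n",
              x$population, x$mode, length(x$experiments)))
  if (length(x$specific_features) == 0) {
    cat("  no population-specific features\n")
  } else {
    cat("  ", paste(x$specific_features, collapse = ", "), "\n")
  }
  invisible(x)
}

## Split "MT-X+NUC" pair feature names into constituents at the first "+".
split_pair <- function(pair) {
  parts <- regmatches(pair, regexpr("+", pair, fixed = TRUE), invert = TRUE)
  tibble::tibble(pair = pair,
                 mt_gene = vapply(parts, `[[`, character(1), 1),
                 nuc_gene = vapply(parts, `[[`, character(1), 2))
}

#' Genes that gain classification power in combination
#'
#' Compares the pair-mode experiment for one (reference, target) orientation
#' with the two single-genome experiments and reports (i) gene pairs whose
#' importance exceeds that of both constituent genes, and (ii) pairs
#' recruited into the optimal pair-mode list while at least one constituent
#' was not selected in its own single-mode optimal list. The two lists are
#' disjoint (a pair qualifying for (ii) is reported there only).
#'
#' Importances are normalized within each model, so comparing them across
#' models is an interpretive choice. The default compares the raw normalized
#' scores (a pair must carry more importance in the pair model than each
#' constituent does in its own model — conservative, since pair models
#' spread importance over many more features). `method = "rank"` compares
#' rank percentiles instead; note it systematically favors the larger
#' feature space.
#'
#' @param mt_exp,nuc_exp,pair_exp `rf_experiment`s for the same (ref, target)
#'   pair in the three modes.
#' @param method `"raw"` (default) or `"rank"`.
#' @return Tibble `pair`, `mt_gene`, `nuc_gene`, `gain_type`
#'   (`"importance"` for (i), `"recruitment"` for (ii)).
#' @export
combination_gains <- function(mt_exp, nuc_exp, pair_exp, method = c("raw", "rank")) {
  method <- match.arg(method)
  for (e in list(mt_exp, nuc_exp, pair_exp)) {
    if (!inherits(e, "rf_experiment")) abort("all three mode experiments are required")
  }
  same <- function(a, b) a$ref_pop == b$ref_pop && a$target_pop == b$target_pop
  if (!same(mt_exp, pair_exp) || !same(nuc_exp, pair_exp)) {
    abort("experiments must share the same (reference, target) orientation")
  }
  if (length(pair_exp$optimal_features) == 0) {
    return(tibble::tibble(pair = character(0), mt_gene = character(0),
                          nuc_gene = character(0), gain_type = character(0)))
  }
  pairs <- split_pair(pair_exp$importance$feature)
  strength <- function(exp) {
    v <- if (method == "rank") {
      1 - (exp$importance$rank - 0.5) / nrow(exp$importance)
    } else {
      exp$importance$importance
    }
    setNames(v, exp$importance$feature)
  }
  s_pair <- strength(pair_exp); s_mt <- strength(mt_exp); s_nuc <- strength(nuc_exp)
  gain_i <- pairs$pair[s_pair[pairs$pair] > s_mt[pairs$mt_gene] &
                         s_pair[pairs$pair] > s_nuc[pairs$nuc_gene]]
  sel <- split_pair(pair_exp$optimal_features)
  gain_ii <- sel$pair[!(sel$mt_gene %in% mt_exp$optimal_features) |
                        !(sel$nuc_gene %in% nuc_exp$optimal_features)]
  gain_i <- setdiff(intersect(gain_i, pair_exp$optimal_features), gain_ii)
  out <- dplyr::bind_rows(
    dplyr::mutate(split_pair(gain_i), gain_type = "importance"),
    dplyr::mutate(split_pair(gain_ii), gain_type = "recruitment")
  )
  if (nrow(out) == 0) {
    out <- tibble::tibble(pair = character(0), mt_gene = character(0),
                          nuc_gene = character(0), gain_type = character(0))
  }
  out
}

## Joint-state feature matrix for all (mt site, nuc site) pairs between the
## mt blocks and one nuclear block: a single integer 0..5 per feature,
## 3 * mt_allele + nuc_dosage, in the canonical six-state order.
snv_pair_features <- function(nuc_block, mt_blocks, subjects) {
  nuc <- subset_subjects(nuc_block, subjects)
  cols <- list()
  for (mb in mt_blocks) {
    mt <- subset_subjects(mb, subjects)
    for (i in seq_len(ncol(mt$states))) {
      a <- mt$states[, i]
      block_cols <- 3L * a + nuc$states
      colnames(block_cols) <- paste0(mt$sites$site_id[i], "+", nuc$sites$site_id)
      cols[[length(cols) + 1L]] <- block_cols
    }
  }
  do.call(cbind, cols)
}

#' SNV-pair-level random-forest analysis for one nuclear gene
#'
#' Treats every (mitochondrial SNV, nuclear SNV) pair between all
#' mitochondrial genes and one nuclear gene as a feature — the subject's
#' joint state encoded as a single category 0-5 (mt allele crossed with
#' nuclear genotype) — and runs one binary random-forest classifier per
#' unordered population pair, without any reference population. The top
#' `top_k` pairs by importance are retained per experiment, and a pair is
#' called specific to a population when it appears in the top lists of both
#' experiments involving that population.
#'
#' @param nuc_block Filtered genotype block of the nuclear gene.
#' @param mt_blocks Named list of filtered mitochondrial blocks.
#' @param panel Panel tibble.
#' @param top_k Size of the retained importance list (default 100; if fewer
#'   features exist, all are kept with a message).
#' @param n_trees,n_folds,seed Protocol parameters.
#' @return List with `experiments` (per population pair: `accuracy`,
#'   `top` tibble of `feature`, `importance`, `rank`) and `specific`
#'   (per population: character vector of pair features).
#' @export
snv_pair_mode <- function(nuc_block, mt_blocks, panel, top_k = 100,
                          n_trees = 500, n_folds = 10, seed = 1L) {
  mt_blocks <- check_blocks(mt_blocks)
  x <- snv_pair_features(nuc_block, mt_blocks, panel$subject)
  if (ncol(x) < top_k) {
    inform(sprintf("only %d SNV-pair features; retaining all of them", ncol(x)))
    top_k <- ncol(x)
  }
  pops <- unique(panel$population)
  pairs <- combn(pops, 2, simplify = FALSE)
  experiments <- lapply(pairs, function(pp) {
    rows <- panel$population %in% pp
    sub <- data.frame(x[rows, , drop = FALSE], check.names = FALSE)
    res <- cv_accuracy(sub, panel$population[rows], n_trees, n_folds,
                       derive_seed(seed, paste0("snv:", paste(pp, collapse = ":"))))
    ord <- order(-res$importance, names(res$importance))
    top <- tibble::tibble(feature = names(res$importance)[ord],
                          importance = unname(res$importance)[ord],
                          rank = seq_along(ord))[seq_len(top_k), ]
    list(populations = pp, accuracy = res$accuracy, top = top)
  })
  names(experiments) <- vapply(pairs, paste, character(1), collapse = "_vs_")
  specific <- lapply(pops, function(p) {
    involving <- experiments[vapply(experiments, function(e) p %in% e$populations, logical(1))]
    Reduce(intersect, lapply(involving, function(e) e$top$feature))
  })
  names(specific) <- pops
  list(experiments = experiments, specific = specific, top_k = top_k)
}
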