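#' Squared-correlation linkage disequilibrium between two sites
#'
#' r-squared computed as the squared Pearson correlation of allele dosages
#' (0/1 haploid, 0/1/2 diploid).
#'
#' @param a,b Dosage vectors of equal length; both must be polymorphic.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(a, b) {
  if (var(a) == 0 || var(b) == 0) abort("monomorphic site passed to ld_r2")
  cor(a, b)^2
}

#' Sliding-window LD pruning
#'
#' Greedy pruning over windows of `window` contiguous SNVs: pairs are
#' scanned in position order and the later site of any pair with
#' r-squared above `threshold` is removed; the window then slides forward by
#' `step` SNVs and the pass repeats. Removed sites stay removed. Defaults
#' (50 / 10 / 0.1) follow common practice for population-structure analyses.
#'
#' @param block A filtered [genotype_block()].
#' @param window,step Window size and slide, in SNV counts.
#' @param threshold r-squared above which the later site of a pair is
#'   dropped.
#' @return The pruned genotype block (a subset of the input sites); applying
#'   the same pruning again is a no-op.
#' @export
prune_ld <- function(block, window = 50, step = 10, threshold = 0.1) {
  m <- ncol(block$states)
  if (m <= 1) return(block)
  keep <- rep(TRUE, m)
  for (start in seq(1, m, by = step)) {
    win <- start:min(start + window - 1, m)
    win <- win[keep[win]]
    if (length(win) > 1) {
      for (ui in seq_len(length(win) - 1)) {
        u <- win[ui]
        if (!keep[u]) next
        for (v in win[(ui + 1):length(win)]) {
          if (keep[v] && ld_r2(block$states[, u], block$states[, v]) > threshold) {
            keep[v] <- FALSE
          }
        }
      }
    }
    if (start + window - 1 >= m) break
  }
  subset_sites(block, which(keep))
}

## Per-site Weir-Cockerham variance components for two populations.
## Diploid sites use the full a/b/c decomposition (with the heterozygosity
## term); haploid sites the mean-squares form, returned on the same
## (among, total) scale so loci combine as a ratio of sums.
fst_components <- function(dos, grp, haploid) {
  pops <- unique(grp)
  stopifnot(length(pops) == 2)
  g1 <- grp == pops[1]; g2 <- grp == pops[2]
  n1 <- sum(g1); n2 <- sum(g2)
  r <- 2
  n_bar <- (n1 + n2) / 2
  n_c <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  if (haploid) {
    p1 <- colMeans(dos[g1, , drop = FALSE]); p2 <- colMeans(dos[g2, , drop = FALSE])
    p_bar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    msa <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / (r - 1)
    msw <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (n1 - 1 + n2 - 1)
    a <- (msa - msw) / n_c
    list(among = a, total = a + msw)
  } else {
    p1 <- colMeans(dos[g1, , drop = FALSE]) / 2
    p2 <- colMeans(dos[g2, , drop = FALSE]) / 2
    h1 <- colMeans(dos[g1, , drop = FALSE] == 1)
    h2 <- colMeans(dos[g2, , drop = FALSE] == 1)
    p_bar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
    h_bar <- (n1 * h1 + n2 * h2) / (n1 + n2)
    a <- (n_bar / n_c) *
      (s2 - (p_bar * (1 - p_bar) - s2 * (r - 1) / r - h_bar / 4) / (n_bar - 1))
    b <- (n_bar / (n_bar - 1)) *
      (p_bar * (1 - p_bar) - s2 * (r - 1) / r - h_bar * (2 * n_bar - 1) / (4 * n_bar))
    cc <- h_bar / 2
    list(among = a, total = a + b + cc)
  }
}

fst_from_matrix <- function(dos, grp, haploid) {
  comp <- fst_components(dos, grp, haploid)
  poly <- comp$total != 0 & !is.na(comp$total)
  if (!any(poly)) return(NA_real_)
  sum(comp$among[poly]) / sum(comp$total[poly])
}

#' Pairwise Weir-Cockerham Fst between two populations
#'
#' Multi-locus variance-components estimator of genetic differentiation:
#' the ratio of summed among-population components to summed total
#' components over all sites (ratio of sums, not an average of per-site
#' ratios). Diploid (nuclear) blocks use the full decomposition including
#' the heterozygosity term; haploid (mitochondrial) blocks use the haploid
#' mean-squares form — the two are not interchangeable, and a haploid block
#' recoded as homozygous diploid will not in general give the same estimate.
#' Slightly negative estimates are possible (and expected) when the true
#' differentiation is near zero.
#'
#' @param block A [genotype_block()] or list of blocks of one genome class.
#' @param panel Panel tibble.
#' @param pop_a,pop_b Population codes, each with at least 2 subjects.
#' @return The theta estimate, or `NA` (with a warning) when no site is
#'   polymorphic between the pair.
#' @export
fst <- function(block, panel, pop_a, pop_b) {
  blocks <- if (inherits(block, "genotype_block")) list(block) else block
  classes <- unique(vapply(blocks, function(b) b$genome_class, character(1)))
  if (length(classes) != 1) abort("cannot combine genome classes in one Fst estimate")
  subjects <- panel$subject[panel$population %in% c(pop_a, pop_b)]
  grp <- panel$population[match(subjects, panel$subject)]
  if (min(table(grp)) < 2) abort("both populations need at least 2 subjects")
  dos <- do.call(cbind, lapply(blocks, function(b) subset_subjects(b, subjects)$states))
  theta <- fst_from_matrix(dos, grp, haploid = classes == "mitochondrial")
  if (is.na(theta)) warn("no polymorphic site between the pair; Fst undefined")
  theta
}

#' Permutation-calibrated Fst for one gene
#'
#' Computes the observed pairwise theta and recomputes it under `n_perm`
#' random reassignments of the pooled subjects to the two population labels
#' (group sizes preserved). The empirical p-value is the tail proportion
#' `(#{theta_perm >= theta_obs} + 1) / (n_perm + 1)`, the standard
#' add-one permutation estimate, which lies in `(0, 1]`.
#'
#' @inheritParams fst
#' @param n_perm Number of label permutations (default 200).
#' @param seed Integer seed; permutations are reproducible.
#' @return An `fst_result`: list with `gene`, `pop_a`, `pop_b`, `theta`,
#'   `perm_values` (length `n_perm`), `p_value`.
#' @export
fst_permutation_p <- function(block, panel, pop_a, pop_b, n_perm = 200, seed = 1L) {
  blocks <- if (inherits(block, "genotype_block")) list(block) else block
  gene <- paste(vapply(blocks, function(b) b$gene, character(1)), collapse = "+")
  classes <- unique(vapply(blocks, function(b) b$genome_class, character(1)))
  if (length(classes) != 1) abort("cannot combine genome classes in one Fst estimate")
  haploid <- classes == "mitochondrial"
  subjects <- panel$subject[panel$population %in% c(pop_a, pop_b)]
  grp <- panel$population[match(subjects, panel$subject)]
  dos <- do.call(cbind, lapply(blocks, function(b) subset_subjects(b, subjects)$states))
  theta <- fst_from_matrix(dos, grp, haploid)
  if (is.na(theta)) abort("observed Fst undefined: no polymorphic site between the pair")
  perm <- with_seed(derive_seed(seed, paste0("fstperm:", gene, pop_a, pop_b)), {
    vapply(seq_len(n_perm), function(i) {
      fst_from_matrix(dos, sample(grp), haploid)
    }, numeric(1))
  })
  structure(
    list(gene = gene, pop_a = pop_a, pop_b = pop_b, theta = theta,
         perm_values = perm,
         p_value = (sum(perm >= theta, na.rm = TRUE) + 1) / (n_perm + 1)),
    class = "fst_result"
  )
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("<fst_result> %s: %s vs %s  theta = %.4f  p = %.4f (%d permutations)\n",
              x$gene, x$pop_a, x$pop_b, x$theta, x$p_value, length(x$perm_values)))
  invisible(x)
}

#' Per-gene Fst specificity calls
#'
#' Applies the empirical-p-value rules to the three pairwise Fst results of
#' each gene: a gene is specific to population P when both P-involving
#' p-values are below `alpha` and the third is not; specific to all
#' populations when all three are; otherwise no call.
#'
#' @param results Tibble with columns `gene`, `pop_a`, `pop_b`, `p_value`
#'   (three rows per gene), e.g. stacked from [fst_permutation_p()] results
#'   via [tidy.fst_result()].
#' @param alpha Significance level (default 0.05).
#' @return Tibble `gene`, `call` (a population code, `"all"`, or `"none"`).
#' @export
fst_specificity <- function(results, alpha = 0.05) {
  purrr::map_dfr(split(results, results$gene), function(df) {
    pops <- unique(c(df$pop_a, df$pop_b))
    if (nrow(df) != length(pops) * (length(pops) - 1) / 2) {
      abort(sprintf("gene %s lacks results for some population pairs", df$gene[1]))
    }
    sig <- df$p_value < alpha
    call <- "none"
    if (all(sig)) {
      call <- "all"
    } else {
      for (p in pops) {
        inv <- df$pop_a == p | df$pop_b == p
        if (all(sig[inv]) && !any(sig[!inv])) call <- p
      }
    }
    tibble::tibble(gene = df$gene[1], call = call)
  })
}

#' Discriminant analysis of principal components
#'
#' Centers the dosage matrix, retains `n_pca` principal components, and runs
#' linear discriminant analysis on the retained components, yielding at most
#' (number of populations - 1) discriminant axes. Population centroids on
#' the (up to) first two axes and their pairwise Euclidean distances
#' quantify between-group divergence.
#'
#' @param block A [genotype_block()] or list of blocks (concatenated).
#' @param panel Panel tibble.
#' @param n_pca Number of principal components to retain; default is the
#'   smallest number explaining at least 90% of variance, capped at a third
#'   of the subject count. Must be smaller than the subject count.
#' @param scale Scale dosage columns to unit variance before the PCA
#'   rotation (default `FALSE`).
#' @return A `dapc_result`: list with `coords` (tibble `subject`,
#'   `population`, one column per discriminant axis), `centroids`,
#'   `centroid_dist` (tibble `pop_a`, `pop_b`, `distance`), `n_pca`,
#'   `var_explained`.
#' @export
dapc <- function(block, panel, n_pca = NULL, scale = FALSE) {
  blocks <- if (inherits(block, "genotype_block")) list(block) else block
  dos <- do.call(cbind, lapply(blocks, function(b) subset_subjects(b, panel$subject)$states))
  grp <- factor(panel$population)
  if (nrow(dos) < nlevels(grp)) abort("need at least as many subjects as populations")
  pc <- prcomp(dos, center = TRUE, scale. = scale)
  ev <- pc$sdev^2
  cum <- cumsum(ev) / sum(ev)
  if (is.null(n_pca)) {
    n_pca <- min(which(cum >= 0.9), max(1L, floor(nrow(dos) / 3)))
  }
  if (n_pca >= nrow(dos)) abort("n_pca must be smaller than the subject count")
  n_pca <- min(n_pca, sum(ev > 1e-12))
  scores <- pc$x[, seq_len(n_pca), drop = FALSE]
  ld <- tryCatch({
    fit <- MASS::lda(scores, grouping = grp)
    predict(fit, scores)$x
  }, error = function(e) {
    if (!grepl("identical", conditionMessage(e))) stop(e)
    # degenerate case: all group means coincide, so there is no
    # between-group direction; every centroid sits at the origin
    matrix(0, nrow = nrow(scores), ncol = min(nlevels(grp) - 1L, 2L),
           dimnames = list(NULL, paste0("LD", seq_len(min(nlevels(grp) - 1L, 2L)))))
  })
  n_axes <- min(ncol(ld), 2L)
  coords <- tibble::as_tibble(ld[, seq_len(n_axes), drop = FALSE])
  coords <- dplyr::bind_cols(tibble::tibble(subject = panel$subject,
                                            population = panel$population), coords)
  centroids <- coords |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("LD"), mean), .groups = "drop")
  cm <- as.matrix(centroids[, -1, drop = FALSE])
  rownames(cm) <- centroids$population
  dd <- as.matrix(stats::dist(cm))
  pairs <- combn(rownames(cm), 2)
  centroid_dist <- tibble::tibble(pop_a = pairs[1, ], pop_b = pairs[2, ],
                                  distance = dd[cbind(pairs[1, ], pairs[2, ])])
  structure(
    list(coords = coords, centroids = centroids, centroid_dist = centroid_dist,
         n_pca = n_pca, var_explained = cum[n_pca]),
    class = "dapc_result"
  )
}

#' @export
print.dapc_result <- function(x, ...) {
  cat(sprintf("<dapc_result> %d PCs retained (%.1f%% variance), %d discriminant axes\n",
              x$n_pca, 100 * x$var_explained, sum(startsWith(names(x$coords), "LD"))))
  print(x$centroid_dist)
  invisible(x)
}
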