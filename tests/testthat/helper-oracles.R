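# Fixture builders and independent brute-force oracles. The oracles are
# deliberately naive (per-subject loops over sites and site pairs) so they
# share no code path with the vectorized implementations they check.

make_block <- function(states, genome_class = "mitochondrial", gene = "G1",
                       chrom = if (genome_class == "mitochondrial") "MT" else "1") {
  n_sites <- ncol(states)
  if (is.null(rownames(states))) {
    rownames(states) <- sprintf("S%03d", seq_len(nrow(states)))
  }
  sites <- tibble::tibble(chrom = chrom, pos = 10L * seq_len(n_sites),
                          site_id = sprintf("%s_s%03d", gene, seq_len(n_sites)),
                          ref = "A", alt = "G")
  genotype_block(gene, chrom, 10L, 10L * n_sites + 9L, genome_class, sites, states)
}

make_panel <- function(block, populations) {
  tibble::tibble(subject = block$subject_ids, population = populations)
}

random_block <- function(n_subj, n_sites, genome_class, seed) {
  set.seed(seed)
  max_state <- if (genome_class == "mitochondrial") 1L else 2L
  repeat {
    states <- matrix(sample(0:max_state, n_subj * n_sites, replace = TRUE),
                     n_subj, n_sites)
    if (all(apply(states, 2, function(x) length(unique(x)) > 1))) break
  }
  make_block(states, genome_class, gene = paste0("R", seed))
}

# Mean reference rarity of the subject's states, site by site.
oracle_gene_score <- function(block, panel, ref_pop, subject) {
  ref <- panel$subject[panel$population == ref_pop]
  total <- 0
  for (j in seq_len(ncol(block$states))) {
    f <- mean(block$states[ref, j] == block$states[subject, j])
    total <- total + (1 - f)
  }
  total / ncol(block$states)
}

# Full double loop over all (mt site, nuc site) pairs.
oracle_pair_score <- function(mt_block, nuc_block, panel, ref_pop, subject) {
  ref <- panel$subject[panel$population == ref_pop]
  total <- 0
  for (i in seq_len(ncol(mt_block$states))) {
    for (j in seq_len(ncol(nuc_block$states))) {
      f <- mean(mt_block$states[ref, i] == mt_block$states[subject, i] &
                  nuc_block$states[ref, j] == nuc_block$states[subject, j])
      total <- total + (1 - f)
    }
  }
  total / (ncol(mt_block$states) * ncol(nuc_block$states))
}

# Literal transcription of the sliding-window pruning rule.
oracle_prune <- function(states, window = 50, step = 10, threshold = 0.1) {
  m <- ncol(states)
  keep <- rep(TRUE, m)
  start <- 1
  repeat {
    win <- intersect(start:(start + window - 1), 1:m)
    for (u in win) {
      for (v in win) {
        if (u < v && keep[u] && keep[v] &&
            cor(states[, u], states[, v])^2 > threshold) {
          keep[v] <- FALSE
        }
      }
    }
    if (start + window - 1 >= m) break
    start <- start + step
  }
  which(keep)
}

# Minimal stand-in experiment object for intersection logic tests.
mock_experiment <- function(ref, target, optimal, mode = "mt") {
  structure(list(ref_pop = ref, target_pop = target, mode = mode,
                 optimal_features = optimal),
            class = "rf_experiment")
}

null_config <- function(seed, n_mt = 3, n_nuc = 7, n_sites = 10,
                        pop_sizes = c(P1 = 100, P2 = 100, P3 = 100), fst = 0) {
  genes <- tibble::tibble(
    gene = c(sprintf("MTG%d", seq_len(n_mt)), sprintf("NUC%d", seq_len(n_nuc))),
    genome_class = rep(c("mitochondrial", "nuclear"), c(n_mt, n_nuc)),
    n_sites = n_sites, fst = fst
  )
  sim_config(pop_sizes = pop_sizes, genes = genes, seed = seed)
}
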