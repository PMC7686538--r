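test_that("ld_r2 matches hand-computed squared correlations", {
  expect_equal(ld_r2(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1)
  expect_equal(ld_r2(c(0, 1, 0, 1), c(0, 0, 1, 1)), 0)
  expect_equal(ld_r2(c(0, 1, 0, 1), 1 - c(0, 1, 0, 1)), 1)  # sign-invariant
  expect_equal(ld_r2(c(0, 1, 2, 0), c(2, 1, 0, 2)), 1)
  expect_error(ld_r2(c(1, 1, 1), c(0, 1, 0)), "monomorphic")
})

test_that("pruning keeps one of a set of identical sites and leaves independent ones", {
  set.seed(5)
  base <- sample(0:1, 40, replace = TRUE)
  dup <- make_block(matrix(rep(base, 5), ncol = 5), "mitochondrial")
  pruned <- prune_ld(dup)
  expect_equal(ncol(pruned$states), 1L)
  expect_equal(pruned$sites$site_id, dup$sites$site_id[1])  # earlier site kept

  ind <- random_block(500, 8, "nuclear", 7)  # big n: sampling r2 well below 0.1
  expect_identical(prune_ld(ind), ind)
})

test_that("pruning equals the naive reference on window-straddling correlated clusters", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 80
    m <- 60
    states <- matrix(sample(0:1, n * m, replace = TRUE), n, m)
    # two correlated clusters, one crossing the first window boundary
    for (j in 46:55) states[, j] <- states[, 45]
    for (j in 2:4) states[, j] <- states[, 1]
    block <- make_block(states, "mitochondrial")
    block <- filter_invariant(block)
    pruned <- prune_ld(block, window = 50, step = 10, threshold = 0.1)
    keep <- oracle_prune(block$states, 50, 10, 0.1)
    expect_equal(pruned$sites$site_id, block$sites$site_id[keep])
    # idempotence and subset property
    expect_identical(prune_ld(pruned, 50, 10, 0.1), pruned)
    expect_true(all(pruned$sites$site_id %in% block$sites$site_id))
  }
})

test_that("Weir-Cockerham theta is 1 at fixed differences for both ploidies", {
  nuc <- make_block(rbind(matrix(0L, 10, 4), matrix(2L, 10, 4)), "nuclear")
  panel <- make_panel(nuc, rep(c("A", "B"), each = 10))
  expect_equal(fst(nuc, panel, "A", "B"), 1)
  mt <- make_block(rbind(matrix(0L, 10, 4), matrix(1L, 10, 4)), "mitochondrial")
  expect_equal(fst(mt, make_panel(mt, rep(c("A", "B"), each = 10)), "A", "B"), 1)
})

test_that("identical state distributions give non-positive theta", {
  states <- rbind(matrix(c(0L, 1L, 2L, 1L), 4, 3), matrix(c(0L, 1L, 2L, 1L), 4, 3))
  block <- make_block(states, "nuclear")
  panel <- make_panel(block, rep(c("A", "B"), each = 4))
  expect_lte(fst(block, panel, "A", "B"), 0)
})

test_that("the haploid and diploid component branches are genuinely different formulas", {
  set.seed(31)
  alleles <- matrix(rbinom(40 * 6, 1, rep(c(0.2, 0.6), each = 20 * 6)), 40, 6)
  mt <- make_block(alleles, "mitochondrial")
  panel <- make_panel(mt, rep(c("A", "B"), each = 20))
  # recoding each haploid allele as a homozygous diploid genotype is the h=0
  # reduction of the diploid components and reproduces the haploid estimate...
  dip_hom <- make_block(2L * alleles, "nuclear", gene = "G1")
  expect_equal(fst(mt, panel, "A", "B"), fst(dip_hom, panel, "A", "B"))
  # ...but misreading the 0/1 allele matrix as diploid dosages (implying
  # heterozygotes and halved allele frequencies) does not
  dip_mis <- make_block(alleles, "nuclear", gene = "G2")
  expect_false(isTRUE(all.equal(fst(mt, panel, "A", "B"),
                                fst(dip_mis, panel, "A", "B"))))
})

test_that("theta recovers the Balding-Nichols differentiation parameter", {
  genes <- tibble::tibble(gene = "BN", genome_class = "nuclear",
                          n_sites = 1000L, fst = 0.1)
  cfg <- sim_config(pop_sizes = c(A = 100, B = 100), genes = genes, seed = 17)
  d <- simulate_dataset(cfg)
  block <- filter_invariant(d$blocks$BN)
  expect_lt(abs(fst(block, d$panel, "A", "B") - 0.1), 0.02)
})

test_that("monomorphic-between-pair data yields a missing estimate with a warning", {
  block <- make_block(cbind(c(0L, 0L, 0L, 0L, 1L, 1L)), "nuclear")
  panel <- make_panel(block, c("A", "A", "B", "B", "C", "C"))
  expect_warning(theta <- fst(block, panel, "A", "B"), "undefined")
  expect_true(is.na(theta))
})

test_that("permutation p-values follow the add-one tail formula and are reproducible", {
  # strong differentiation: observed theta above every permuted value
  nuc <- make_block(rbind(matrix(0L, 15, 6), matrix(2L, 15, 6)), "nuclear")
  panel <- make_panel(nuc, rep(c("A", "B"), each = 15))
  res <- fst_permutation_p(nuc, panel, "A", "B", n_perm = 200, seed = 5)
  expect_equal(res$p_value, 1 / 201)
  expect_length(res$perm_values, 200L)
  expect_true(all(res$perm_values < res$theta))
  # balanced minimal-theta configuration: every permutation is >= observed
  mt <- make_block(cbind(c(0L, 1L, 0L, 1L)), "mitochondrial")
  panel2 <- make_panel(mt, c("A", "A", "B", "B"))
  res2 <- fst_permutation_p(mt, panel2, "A", "B", n_perm = 50, seed = 2)
  expect_equal(res2$p_value, 1)
  # seed-reproducibility
  again <- fst_permutation_p(nuc, panel, "A", "B", n_perm = 200, seed = 5)
  expect_identical(tidy(res), tidy(again))
  expect_identical(res$perm_values, again$perm_values)
})

test_that("Fst specificity rules classify the three p-value patterns", {
  mk <- function(p) tibble::tibble(
    gene = "G", pop_a = c("FIN", "FIN", "TSI"), pop_b = c("TSI", "GBR", "GBR"),
    p_value = p)
  expect_equal(fst_specificity(mk(c(0.01, 0.02, 0.50)))$call, "FIN")
  expect_equal(fst_specificity(mk(c(0.01, 0.01, 0.01)))$call, "all")
  expect_equal(fst_specificity(mk(c(0.01, 0.50, 0.50)))$call, "none")
  expect_error(fst_specificity(mk(c(0.1, 0.1, 0.1))[1:2, ]), "pairs")
})

test_that("DAPC yields at most groups-1 axes and coincident centroids for identical groups", {
  cfg <- null_config(23, n_mt = 0, n_nuc = 1, n_sites = 30,
                     pop_sizes = c(A = 40, B = 40, C = 40), fst = 0.05)
  d <- simulate_dataset(cfg)
  block <- filter_invariant(d$blocks$NUC1)
  res <- dapc(block, d$panel)
  expect_lte(sum(startsWith(names(res$coords), "LD")), 2L)
  expect_equal(nrow(res$centroid_dist), 3L)
  expect_s3_class(autoplot(res), "ggplot")

  # one population duplicated under two labels -> centroids coincide
  dup_states <- rbind(block$states[1:40, ], block$states[1:40, ])
  rownames(dup_states) <- sprintf("D%03d", 1:80)
  dup <- make_block(dup_states, "nuclear")
  dup_panel <- make_panel(dup, rep(c("X", "Y"), each = 40))
  res2 <- dapc(dup, dup_panel, n_pca = 5)
  expect_lt(res2$centroid_dist$distance, 1e-8)

  expect_error(dapc(block, d$panel, n_pca = 500), "smaller")
})
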