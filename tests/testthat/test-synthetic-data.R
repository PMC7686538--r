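test_that("Balding-Nichols frequencies have the stated moments and degenerate limits", {
  genes <- tibble::tibble(gene = c("BN", "FLAT"),
                          genome_class = c("nuclear", "nuclear"),
                          n_sites = c(10000L, 50L), fst = c(0.5, 0))
  cfg <- sim_config(pop_sizes = c(A = 5, B = 5), genes = genes,
                    ancestral_range = c(0.5, 0.5), seed = 11)
  freqs <- simulate_frequencies(cfg)
  bn <- dplyr::filter(freqs, gene == "BN")
  # Beta(p(1-F)/F, (1-p)(1-F)/F) has mean p and variance p(1-p)F
  expect_equal(mean(bn$A), 0.5, tolerance = 0.02 / 0.5)
  expect_lt(abs(mean(bn$A) - 0.5), 0.02)
  expect_lt(abs(var(bn$A) - 0.5 * 0.5 * 0.5), 0.01)
  # F = 0: every population shares the ancestral frequency exactly
  flat <- dplyr::filter(freqs, gene == "FLAT")
  expect_equal(flat$A, flat$ancestral)
  expect_equal(flat$B, flat$ancestral)

  genes$fst <- c(1e-4, 0)
  tiny <- simulate_frequencies(
    sim_config(pop_sizes = c(A = 5, B = 5), genes = genes,
               ancestral_range = c(0.5, 0.5), seed = 11))
  expect_lt(var(dplyr::filter(tiny, gene == "BN")$A), 1e-3)
})

test_that("degenerate ancestral frequencies are rejected", {
  genes <- tibble::tibble(gene = "G", genome_class = "nuclear",
                          n_sites = 5L, fst = 0.1)
  expect_error(sim_config(pop_sizes = c(A = 2, B = 2), genes = genes,
                          ancestral_range = c(0, 0.5)))
  expect_error(sim_config(pop_sizes = c(A = 2, B = 2), genes = genes,
                          ancestral_range = c(0.5, 1)))
  genes$fst <- 1
  expect_error(sim_config(pop_sizes = c(A = 2, B = 2), genes = genes), "fst")
})

test_that("nuclear genotypes follow Hardy-Weinberg within population", {
  genes <- tibble::tibble(gene = "HW", genome_class = "nuclear",
                          n_sites = 1L, fst = 0)
  cfg <- sim_config(pop_sizes = c(A = 10000, B = 10), genes = genes,
                    ancestral_range = c(0.3, 0.3), seed = 4)
  d <- simulate_dataset(cfg)
  states <- d$blocks$HW$states[d$panel$subject[d$panel$population == "A"], 1]
  expect_lt(abs(mean(states == 1) - 2 * 0.3 * 0.7), 0.02)
  expect_lt(abs(mean(states) / 2 - 0.3), 0.02)
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- null_config(21, n_mt = 2, n_nuc = 2, n_sites = 5,
                     pop_sizes = c(A = 20, B = 20))
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$blocks, d2$blocks)
  expect_identical(d1$panel, d2$panel)
})

interaction_fixture <- function(seed, delta, n_copies = 1) {
  genes <- tibble::tibble(
    gene = c("MTG", "NUC"),
    genome_class = c("mitochondrial", "nuclear"),
    n_sites = c(3L, 3L), fst = 0,
    ld_copies = c(1L, n_copies), ld_noise = 0
  )
  cfg <- sim_config(
    pop_sizes = c(P1 = 60, P2 = 60), genes = genes,
    interactions = list(list(mt_gene = "MTG", mt_site = 1, nuc_gene = "NUC",
                             nuc_site = 1, delta = delta, population = "P1")),
    ancestral_range = c(0.4, 0.6), seed = seed
  )
  cfg
}

test_that("planting an interaction preserves every marginal state count exactly", {
  cfg <- interaction_fixture(5, delta = 1)
  before <- simulate_genotypes(simulate_frequencies(cfg), cfg)
  after <- simulate_dataset(cfg)
  for (pop in c("P1", "P2")) {
    ids <- before$panel$subject[before$panel$population == pop]
    for (g in names(before$blocks)) {
      pre <- apply(before$blocks[[g]]$states[ids, , drop = FALSE], 2, tabulate, nbins = 3)
      post <- apply(after$blocks[[g]]$states[ids, , drop = FALSE], 2, tabulate, nbins = 3)
      expect_identical(pre, post)
    }
  }
  # the mitochondrial block is untouched entirely
  expect_identical(before$blocks$MTG$states, after$blocks$MTG$states)
})

test_that("delta = 1 attains the maximal coupling given the realized marginals", {
  cfg <- interaction_fixture(9, delta = 1)
  d <- simulate_dataset(cfg)
  ids <- d$panel$subject[d$panel$population == "P1"]
  a <- d$blocks$MTG$states[ids, 1]
  g <- d$blocks$NUC$states[ids, 1]
  # sort-matching oracle: mt-alt subjects receive the largest dosages available
  coupled <- sort(unname(g), decreasing = TRUE)[seq_len(sum(a == 1))]
  expect_equal(sort(unname(g[a == 1])), sort(coupled))
  # and in the unaffected population mt and nuc stay unassociated
  ids2 <- d$panel$subject[d$panel$population == "P2"]
  expect_lt(abs(cor(d$blocks$MTG$states[ids2, 1], d$blocks$NUC$states[ids2, 1])), 0.35)
})

test_that("delta = 0 leaves the joint close to the product of marginals", {
  cors <- vapply(1:20, function(s) {
    cfg <- interaction_fixture(s, delta = 0)
    d <- simulate_dataset(cfg)
    ids <- d$panel$subject[d$panel$population == "P1"]
    cor(d$blocks$MTG$states[ids, 1], d$blocks$NUC$states[ids, 1])
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.08)
})

test_that("out-of-range coupling is rejected with the feasible bound", {
  cfg <- interaction_fixture(5, delta = 1)
  d <- simulate_genotypes(simulate_frequencies(cfg), cfg)
  spec <- cfg$interactions[[1]]
  spec$delta <- 1.5
  expect_error(plant_interaction(d$blocks, d$panel, spec), "\\[0,1\\].*maximum")
})

test_that("fixtures round-trip exactly through the VCF reader", {
  genes <- tibble::tibble(
    gene = c("MTG1", "MTG2", "NUC1"),
    genome_class = c("mitochondrial", "mitochondrial", "nuclear"),
    n_sites = c(4L, 3L, 6L), fst = c(0.1, 0, 0.2)
  )
  cfg <- sim_config(pop_sizes = c(A = 15, B = 15), genes = genes, seed = 33)
  d <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_fixture(d$blocks, d$panel, dir)
  vcf_lines <- readLines(paths$vcf)
  expect_equal(vcf_lines[1], "##fileformat=VCFv4.2")
  n_fields <- length(strsplit(grep("^#CHROM", vcf_lines, value = TRUE), "\t")[[1]])
  expect_equal(n_fields, 9 + 30)

  back <- read_dataset(paths$vcf, paths$panel, paths$regions, filter = FALSE)
  expect_equal(back$panel, d$panel)
  for (g in names(d$blocks)) {
    expect_identical(back$blocks[[g]]$states, d$blocks[[g]]$states)
    expect_equal(back$blocks[[g]]$genome_class, d$blocks[[g]]$genome_class)
  }
})

test_that("YAML configs reproduce the in-code constructor", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "pop_sizes: {P1: 20, P2: 20}",
    "genes:",
    "  - {gene: MTG, genome_class: mitochondrial, n_sites: 3, fst: 0.1}",
    "  - {gene: NUC, genome_class: nuclear, n_sites: 4, fst: 0.0}",
    "interactions:",
    "  - {mt_gene: MTG, mt_site: 1, nuc_gene: NUC, nuc_site: 1, delta: 0.5, population: P1}",
    "ancestral_range: [0.2, 0.8]",
    "seed: 12"
  ), path)
  cfg <- sim_config_from_yaml(path)
  ref <- sim_config(
    pop_sizes = c(P1 = 20L, P2 = 20L),
    genes = tibble::tibble(gene = c("MTG", "NUC"),
                           genome_class = c("mitochondrial", "nuclear"),
                           n_sites = c(3L, 4L), fst = c(0.1, 0)),
    interactions = list(list(mt_gene = "MTG", mt_site = 1L, nuc_gene = "NUC",
                             nuc_site = 1L, delta = 0.5, population = "P1")),
    ancestral_range = c(0.2, 0.8), seed = 12
  )
  expect_identical(simulate_dataset(cfg)$blocks, simulate_dataset(ref)$blocks)
  writeLines("pop_sizes: {P1: 20}", path)
  expect_error(sim_config_from_yaml(path), "genes")
})

test_that("ld_copies produces duplicated, optionally noisy, linked columns", {
  genes <- tibble::tibble(gene = "NUC", genome_class = "nuclear",
                          n_sites = 2L, fst = 0, ld_copies = 3L, ld_noise = 0)
  cfg <- sim_config(pop_sizes = c(A = 30, B = 30), genes = genes, seed = 2)
  d <- simulate_dataset(cfg)
  st <- d$blocks$NUC$states
  expect_equal(ncol(st), 6L)
  expect_identical(st[, 1], st[, 2])
  expect_identical(st[, 1], st[, 3])
  expect_false(identical(st[, 1], st[, 4]) && identical(st[, 2], st[, 5]))
})
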