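#' Configure a synthetic three-population genotype dataset
#'
#' Builds the configuration for the synthetic genotype generator. Populations
#' diverge under the Balding-Nichols model: for a site with ancestral allele
#' frequency `p` and per-gene differentiation `F`, each population draws its
#' own frequency from `Beta(p(1-F)/F, (1-p)(1-F)/F)` — a distribution with
#' mean `p` and variance `p(1-p)F`, so `F` equals the expected Fst between
#' populations. Mitochondrial sites are haploid; nuclear sites are diploid
#' under within-population Hardy-Weinberg equilibrium.
#'
#' @param pop_sizes Named vector of subjects per population. The default,
#'   100/100/97 across three populations, mirrors a 297-subject
#'   three-population study design.
#' @param genes Tibble with one row per gene: `gene` (name), `genome_class`
#'   (`"mitochondrial"`/`"nuclear"`), `n_sites`, `fst` (the Balding-Nichols
#'   `F`, in `[0,1)`). Optional columns `ld_copies` (each simulated site is
#'   replicated this many times to create within-gene linkage blocks;
#'   default 1) and `ld_noise` (per-subject probability that a replicated
#'   column is redrawn from the population frequency instead of copied;
#'   default 0).
#' @param interactions List of planted mitonuclear interactions, each a list
#'   with `mt_gene`, `mt_site`, `nuc_gene`, `nuc_site` (site indices),
#'   `delta` in `[0,1]` and `population`; see [plant_interaction()].
#' @param ancestral_range Range of the uniform law for ancestral allele
#'   frequencies (default `c(0.05, 0.95)`, keeping sites comfortably
#'   polymorphic).
#' @param seed Integer seed; fully determines the generated dataset.
#' @return A `sim_config` list.
#' @export
sim_config <- function(pop_sizes = c(GBR = 100, FIN = 100, TSI = 97),
                       genes,
                       interactions = list(),
                       ancestral_range = c(0.05, 0.95),
                       seed = 1L) {
  stopifnot(length(pop_sizes) >= 2, all(pop_sizes >= 1), !is.null(names(pop_sizes)))
  genes <- tibble::as_tibble(genes)
  need <- c("gene", "genome_class", "n_sites", "fst")
  if (!all(need %in% names(genes))) {
    abort(sprintf("`genes` must have columns %s", paste(need, collapse = ", ")))
  }
  if (!all(genes$fst >= 0 & genes$fst < 1)) abort("per-gene `fst` must lie in [0,1)")
  if (!"ld_copies" %in% names(genes)) genes$ld_copies <- 1L
  if (!"ld_noise" %in% names(genes)) genes$ld_noise <- 0
  stopifnot(ancestral_range[1] > 0, ancestral_range[2] < 1,
            ancestral_range[1] <= ancestral_range[2])
  structure(list(pop_sizes = pop_sizes, genes = genes,
                 interactions = interactions,
                 ancestral_range = ancestral_range, seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' The YAML file mirrors [sim_config()]: top-level `pop_sizes` (a named
#' mapping), `genes` (a list of records with `gene`, `genome_class`,
#' `n_sites`, `fst` and optional `ld_copies`/`ld_noise`), optional
#' `interactions` (records with `mt_gene`, `mt_site`, `nuc_gene`,
#' `nuc_site`, `delta`, `population`), optional `ancestral_range`, and
#' `seed`.
#'
#' @param path Path to the YAML file.
#' @return A `sim_config`.
#' @export
sim_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  for (fld in c("pop_sizes", "genes", "seed")) {
    if (is.null(y[[fld]])) abort(sprintf("YAML config lacks `%s`", fld))
  }
  sim_config(
    pop_sizes = unlist(y$pop_sizes),
    genes = dplyr::bind_rows(lapply(y$genes, tibble::as_tibble)),
    interactions = y$interactions %||% list(),
    ancestral_range = unlist(y$ancestral_range %||% c(0.05, 0.95)),
    seed = y$seed
  )
}

#' Draw per-population allele frequencies (Balding-Nichols)
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `gene`, `site` (index within gene),
#'   `ancestral`, one frequency column per population.
#' @export
simulate_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pops <- names(config$pop_sizes)
  with_seed(derive_seed(config$seed, "frequencies"), {
    purrr::pmap_dfr(config$genes[, c("gene", "n_sites", "fst")], function(gene, n_sites, fst) {
      p <- runif(n_sites, config$ancestral_range[1], config$ancestral_range[2])
      if (any(p <= 0 | p >= 1)) abort("ancestral frequencies must lie strictly in (0,1)")
      out <- tibble::tibble(gene = gene, site = seq_len(n_sites), ancestral = p)
      for (pop in pops) {
        out[[pop]] <- if (fst > 0) {
          rbeta(n_sites, p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
        } else {
          p
        }
      }
      out
    })
  })
}

#' Simulate genotype blocks from per-population frequencies
#'
#' Mitochondrial sites draw one Bernoulli allele per subject; nuclear sites
#' draw two independent Bernoulli alleles and collapse them to alt-allele
#' dosage (Hardy-Weinberg within population). When a gene requests
#' `ld_copies > 1`, each simulated base site is expanded into a block of
#' correlated columns (copies, each entry independently redrawn from the
#' population frequency with probability `ld_noise`).
#'
#' @param freqs Output of [simulate_frequencies()].
#' @param config The same [sim_config()].
#' @return `list(blocks = named list of genotype blocks, panel = tibble)`.
#' @export
simulate_genotypes <- function(freqs, config) {
  stopifnot(inherits(config, "sim_config"))
  pops <- names(config$pop_sizes)
  panel <- tibble::tibble(
    subject = sprintf("S%04d", seq_len(sum(config$pop_sizes))),
    population = rep(pops, config$pop_sizes)
  )
  blocks <- with_seed(derive_seed(config$seed, "genotypes"), {
    out <- vector("list", nrow(config$genes))
    names(out) <- config$genes$gene
    mt_cursor <- 1L; nuc_cursor <- 1L; nuc_chrom <- 0L
    for (gi in seq_len(nrow(config$genes))) {
      g <- config$genes[gi, ]
      f <- dplyr::filter(freqs, .data$gene == g$gene)
      haploid <- g$genome_class == "mitochondrial"
      copies <- max(1L, as.integer(g$ld_copies))
      n_cols <- g$n_sites * copies
      states <- matrix(0L, nrow = nrow(panel), ncol = n_cols)
      for (pop in pops) {
        rows <- which(panel$population == pop)
        q <- f[[pop]]
        for (s in seq_len(g$n_sites)) {
          base <- if (haploid) rbinom(length(rows), 1L, q[s]) else rbinom(length(rows), 2L, q[s])
          for (cp in seq_len(copies)) {
            col <- (s - 1L) * copies + cp
            v <- base
            if (cp > 1L && g$ld_noise > 0) {
              redraw <- runif(length(rows)) < g$ld_noise
              if (any(redraw)) {
                v[redraw] <- if (haploid) rbinom(sum(redraw), 1L, q[s]) else rbinom(sum(redraw), 2L, q[s])
              }
            }
            states[rows, col] <- v
          }
        }
      }
      if (haploid) {
        chrom <- "MT"; start <- mt_cursor; mt_cursor <- mt_cursor + 10L * n_cols
      } else {
        nuc_chrom <- nuc_chrom + 1L
        chrom <- as.character(nuc_chrom); start <- nuc_cursor
        nuc_cursor <- nuc_cursor + 10L * n_cols
      }
      pos <- start + 10L * (seq_len(n_cols) - 1L)
      sites <- tibble::tibble(chrom = chrom, pos = pos,
                              site_id = sprintf("%s_s%03d", g$gene, seq_len(n_cols)),
                              ref = "A", alt = "G")
      rownames(states) <- panel$subject
      out[[g$gene]] <- genotype_block(g$gene, chrom, min(pos), max(pos) + 9L,
                                      g$genome_class, sites, states)
    }
    out
  })
  list(blocks = blocks, panel = panel)
}

#' Plant a marginal-preserving mitonuclear interaction
#'
#' Tilts, in one population only, the joint distribution of (mitochondrial
#' allele at one site, nuclear genotype at another) toward the coupling that
#' pairs the alt mitochondrial allele with high nuclear alt dosage — while
#' leaving every per-site marginal state count exactly unchanged. This is
#' achieved by permuting whole nuclear-gene rows among the affected
#' population's subjects: a fraction `delta` of subjects receives the
#' maximally coupled assignment (nuclear rows sorted by target-site dosage
#' matched to subjects sorted by mitochondrial allele), the rest a random
#' assignment. `delta = 0` leaves mt and nuc independent; `delta = 1` gives
#' the Frechet-maximal association attainable with the realized marginals.
#' Permuting whole rows (rather than one column) also preserves within-gene
#' linkage, so sites correlated with the target site become coupled too.
#'
#' @param blocks Named list of genotype blocks.
#' @param panel Panel tibble.
#' @param spec List with `mt_gene`, `mt_site`, `nuc_gene`, `nuc_site` (column
#'   indices), `delta` in `[0,1]`, `population`.
#' @param seed Integer seed for the residual random assignment.
#' @return The blocks list with the nuclear gene's rows permuted in the
#'   affected population.
#' @export
plant_interaction <- function(blocks, panel, spec, seed = 1L) {
  for (fld in c("mt_gene", "mt_site", "nuc_gene", "nuc_site", "delta", "population")) {
    if (is.null(spec[[fld]])) abort(sprintf("interaction spec lacks `%s`", fld))
  }
  if (spec$delta < 0 || spec$delta > 1) {
    abort("coupling `delta` must lie in [0,1] (1 is the feasible Frechet maximum)")
  }
  mt <- blocks[[spec$mt_gene]]; nuc <- blocks[[spec$nuc_gene]]
  if (is.null(mt) || is.null(nuc)) abort("interaction names a gene with no block")
  if (spec$mt_site > ncol(mt$states) || spec$nuc_site > ncol(nuc$states)) {
    abort("interaction targets a site index outside the gene block")
  }
  subjects <- panel$subject[panel$population == spec$population]
  if (length(subjects) == 0) abort(sprintf("population %s not in panel", spec$population))
  idx <- match(subjects, nuc$subject_ids)
  a <- mt$states[subjects, spec$mt_site]
  rows <- nuc$states[idx, , drop = FALSE]
  n <- length(subjects)
  with_seed(derive_seed(seed, paste0("plant:", spec$mt_gene, ":", spec$nuc_gene)), {
    n_coupled <- round(spec$delta * n)
    coupled <- sample(n, n_coupled)
    rest <- setdiff(seq_len(n), coupled)
    assign <- integer(n)
    if (n_coupled > 0) {
      # mt alt-allele subjects receive the highest-dosage nuclear rows
      subj_order <- coupled[order(a[coupled], decreasing = TRUE)]
      row_order <- coupled[order(rows[coupled, spec$nuc_site], sample(n_coupled),
                                 decreasing = TRUE)]
      assign[subj_order] <- row_order
    }
    if (length(rest) > 0) assign[rest] <- rest[sample(length(rest))]
    blocks[[spec$nuc_gene]]$states[idx, ] <- rows[assign, , drop = FALSE]
  })
  blocks
}

#' Simulate a full dataset
#'
#' Runs [simulate_frequencies()], [simulate_genotypes()] and plants every
#' interaction in the configuration.
#'
#' @param config A [sim_config()].
#' @return `list(blocks, panel, freqs)`.
#' @export
simulate_dataset <- function(config) {
  freqs <- simulate_frequencies(config)
  gen <- simulate_genotypes(freqs, config)
  for (k in seq_along(config$interactions)) {
    gen$blocks <- plant_interaction(gen$blocks, gen$panel, config$interactions[[k]],
                                    seed = derive_seed(config$seed, paste0("interaction", k)))
  }
  list(blocks = gen$blocks, panel = gen$panel, freqs = freqs)
}

#' Write a simulated dataset as VCF + panel + region fixtures
#'
#' Emits a VCF v4.2 file (haploid `0`/`1` calls on the mitochondrial contig,
#' phased diploid calls elsewhere, heterozygotes written `0|1`), a
#' two-column panel file and a 4-column region table, so that the dataset
#' round-trips exactly through [read_dataset()].
#'
#' @param blocks Named list of genotype blocks.
#' @param panel Panel tibble.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list of the three file paths (`vcf`, `panel`,
#'   `regions`).
#' @export
write_fixture <- function(blocks, panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf_path <- file.path(dir, "genotypes.vcf")
  panel_path <- file.path(dir, "panel.tsv")
  regions_path <- file.path(dir, "regions.tsv")

  subjects <- blocks[[1]]$subject_ids
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mitonuclear-simulator",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            subjects), collapse = "\t")
  )
  body <- purrr::map(blocks, function(b) {
    stopifnot(identical(b$subject_ids, subjects))
    gt <- if (b$genome_class == "mitochondrial") {
      matrix(as.character(b$states), nrow = nrow(b$states))
    } else {
      matrix(c("0|0", "0|1", "1|1")[b$states + 1L], nrow = nrow(b$states))
    }
    vapply(seq_len(ncol(b$states)), function(j) {
      paste(c(b$sites$chrom[j], b$sites$pos[j], b$sites$site_id[j],
              b$sites$ref[j], b$sites$alt[j], ".", "PASS", ".", "GT", gt[, j]),
            collapse = "\t")
    }, character(1))
  })
  ## VCF records must be position-sorted within chromosome
  recs <- unlist(body, use.names = FALSE)
  chroms <- sub("\t.*", "", recs)
  pos <- as.integer(vapply(strsplit(recs, "\t", fixed = TRUE), `[[`, character(1), 2))
  ord <- order(match(chroms, unique(chroms)), pos)
  writeLines(c(header, recs[ord]), vcf_path)

  readr::write_tsv(panel, panel_path, col_names = FALSE)
  regions <- purrr::map_dfr(blocks, function(b) {
    tibble::tibble(name = b$gene, chrom = b$chrom, start = b$start, end = b$end)
  })
  readr::write_tsv(regions, regions_path)
  invisible(list(vcf = vcf_path, panel = panel_path, regions = regions_path))
}
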