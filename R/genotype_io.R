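MT_CHROMS <- c("MT", "chrM", "chrMT", "M", "NC_012920.1")

#' Read a gene-region table
#'
#' Reads a tab-delimited table of gene regions with columns `name`, `chrom`,
#' `start`, `end` (1-based inclusive bounds). The genome class of each region
#' is derived from the chromosome label: the mitochondrial contig (`MT`,
#' `chrM`, ...) is `"mitochondrial"`, everything else `"nuclear"`.
#'
#' @param path Path to a 4-column TSV (header `name`, `chrom`, `start`, `end`).
#' @return A tibble with columns `name`, `chrom`, `start`, `end`,
#'   `genome_class`.
#' @export
read_gene_regions <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("name", "chrom", "start", "end")
  if (!all(need %in% names(raw))) {
    abort(sprintf("region table must have columns %s", paste(need, collapse = ", ")))
  }
  start <- suppressWarnings(as.integer(raw$start))
  end <- suppressWarnings(as.integer(raw$end))
  bad <- which(is.na(start) | is.na(end) | is.na(raw$name) | is.na(raw$chrom))
  if (length(bad) > 0) {
    abort(sprintf("malformed region row at line %d of %s", bad[1] + 1L, path))
  }
  rev <- which(start > end)
  if (length(rev) > 0) {
    abort(sprintf("start > end for region '%s' (line %d)", raw$name[rev[1]], rev[1] + 1L))
  }
  tibble::tibble(
    name = raw$name, chrom = raw$chrom, start = start, end = end,
    genome_class = ifelse(raw$chrom %in% MT_CHROMS, "mitochondrial", "nuclear")
  )
}

#' Read a sample-population panel
#'
#' Reads a whitespace- or tab-delimited panel mapping subject ids to
#' population codes, compatible with the 1000 Genomes panel layout (first
#' two columns `sample`, `pop`; extra columns and a header line are
#' tolerated).
#'
#' @param path Path to the panel file.
#' @return A tibble with columns `subject`, `population`.
#' @export
read_panel <- function(path) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = paste0("V", 1:10), fill = TRUE)[, 1:2]
  names(raw) <- c("subject", "population")
  if (tolower(raw$subject[1]) %in% c("sample", "subject", "id")) {
    raw <- raw[-1, , drop = FALSE]
  }
  panel <- tibble::as_tibble(raw)
  if (length(unique(panel$population)) < 2) {
    abort("panel must contain at least two distinct population codes")
  }
  panel
}

#' Read one gene region from a VCF into a genotype block
#'
#' Extracts biallelic SNVs inside a gene region from a VCF (v4.x) and maps
#' calls to genotype states: haploid 0/1 on the mitochondrial contig (a
#' diploid-coded homozygous call such as `1|1` is accepted as allele 1; a
#' heterozygous mitochondrial call is an error), and alt-allele dosage
#' 0/1/2 for nuclear diploid calls, with `0|1` and `1|0` merged into one
#' heterozygous state. Multiallelic records, non-SNVs and sites with any
#' missing call are excluded with a message.
#'
#' @param vcf_path Path to the VCF file.
#' @param region One row of a [read_gene_regions()] table (or a list with
#'   `name`, `chrom`, `start`, `end`, `genome_class`).
#' @param panel Panel tibble from [read_panel()]; every VCF subject must be
#'   present in it.
#' @return A [genotype_block()]; zero sites (with a warning) when the region
#'   contains no usable SNVs.
#' @export
read_vcf_block <- function(vcf_path, region, panel) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcf@gt
  subjects <- colnames(gt)[-1]  # first column is FORMAT
  missing <- setdiff(subjects, panel$subject)
  if (length(missing) > 0) {
    abort(sprintf("VCF subjects absent from panel: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  pos <- as.integer(fix$POS)
  in_region <- fix$CHROM == region$chrom & pos >= region$start & pos <= region$end
  keep <- which(in_region)
  n_multi <- 0L; n_missing <- 0L; n_nonsnv <- 0L
  rows <- integer(0)
  states <- NULL
  if (length(keep) > 0) {
    sub <- keep[order(pos[keep])]
    calls <- sub("^([^:]*).*$", "\\1", gt[sub, -1, drop = FALSE])
    is_multi <- grepl(",", fix$ALT[sub])
    is_snv <- nchar(fix$REF[sub]) == 1 & nchar(fix$ALT[sub]) == 1 & !is_multi
    n_multi <- sum(is_multi)
    n_nonsnv <- sum(!is_snv & !is_multi)
    has_missing <- apply(calls, 1L, function(x) any(is.na(x) | grepl("\\.", x)))
    ok <- is_snv & !has_missing
    n_missing <- sum(is_snv & has_missing)
    rows <- sub[ok]
    calls <- calls[ok, , drop = FALSE]
    states <- apply(calls, c(1, 2), map_call, haploid = region$genome_class == "mitochondrial")
    if (length(rows) == 1L) states <- matrix(states, nrow = 1L)
  }
  if (n_multi + n_missing + n_nonsnv > 0) {
    inform(sprintf("%s: excluded %d multiallelic, %d non-SNV, %d with missing calls",
                   region$name, n_multi, n_nonsnv, n_missing))
  }
  if (length(rows) == 0L) {
    warn(sprintf("no usable sites in region %s (%s:%d-%d)",
                 region$name, region$chrom, region$start, region$end))
    states_mat <- matrix(integer(0), nrow = length(subjects), ncol = 0,
                         dimnames = list(subjects, NULL))
    sites <- tibble::tibble(chrom = character(0), pos = integer(0),
                            site_id = character(0), ref = character(0),
                            alt = character(0))
  } else {
    id <- fix$ID[rows]
    id[is.na(id) | id == "."] <- paste0(fix$CHROM[rows], ":", fix$POS[rows])[is.na(id) | id == "."]
    sites <- tibble::tibble(chrom = fix$CHROM[rows], pos = as.integer(fix$POS[rows]),
                            site_id = id, ref = fix$REF[rows], alt = fix$ALT[rows])
    states_mat <- t(states)
    dimnames(states_mat) <- list(subjects, sites$site_id)
    storage.mode(states_mat) <- "integer"
  }
  genotype_block(region$name, region$chrom, region$start, region$end,
                 region$genome_class, sites, states_mat)
}

## Map a single GT string to a state. Haploid: allele 0/1 (homozygous
## diploid coding tolerated); diploid: alt dosage 0/1/2, phase discarded.
map_call <- function(call, haploid) {
  alleles <- strsplit(call, "[|/]")[[1]]
  a <- suppressWarnings(as.integer(alleles))
  if (any(is.na(a)) || !all(a %in% 0:1)) {
    abort(sprintf("unsupported genotype call '%s'", call))
  }
  if (haploid) {
    if (length(a) == 1L) return(a)
    if (a[1] != a[2]) {
      abort(sprintf("heterozygous mitochondrial call '%s'; heteroplasmy is not supported", call))
    }
    return(a[1])
  }
  if (length(a) != 2L) abort(sprintf("haploid call '%s' at a nuclear site", call))
  sum(a)
}

#' Read all gene regions of a dataset into genotype blocks
#'
#' Convenience wrapper: reads the region table, panel and VCF, returning one
#' (invariant-filtered, if requested) genotype block per region.
#'
#' @param vcf_path,panel_path,regions_path File paths.
#' @param filter Drop invariant sites (default `TRUE`).
#' @return Named list of [genotype_block()]s plus the panel, as
#'   `list(blocks=, panel=, regions=)`.
#' @export
read_dataset <- function(vcf_path, panel_path, regions_path, filter = TRUE) {
  regions <- read_gene_regions(regions_path)
  panel <- read_panel(panel_path)
  blocks <- lapply(seq_len(nrow(regions)), function(i) {
    b <- read_vcf_block(vcf_path, regions[i, ], panel)
    if (filter) b <- filter_invariant(b)
    b
  })
  names(blocks) <- regions$name
  list(blocks = blocks, panel = panel, regions = regions)
}

#' Gene panel used in the cold-adaptation case study
#'
#' Returns the 13 mitochondrial and 28 nuclear (brown-adipose-tissue /
#' cold-adaptation candidate) gene regions analysed in the case study, with
#' the number of SNVs retained per gene after invariant filtering in the
#' 297-subject GBR/FIN/TSI sample. Coordinates are GRCh38 (nuclear) and the
#' rCRS mitochondrial reference.
#'
#' @return A tibble with columns `name`, `chrom`, `start`, `end`,
#'   `genome_class`, `n_snvs`.
#' @export
cold_adaptation_genes <- function() {
  path <- system.file("extdata", "cold_adaptation_genes.tsv", package = "mitonuclear")
  regions <- read_gene_regions(path)
  counts <- readr::read_tsv(path, col_types = "cciii", progress = FALSE)
  regions$n_snvs <- as.integer(counts$n_snvs)
  regions
}

#' Size of the SNV-pair feature space
#'
#' For every (mitochondrial gene, nuclear gene) pair, the number of
#' SNV-pair features is the product of the two genes' retained SNV counts.
#' This is the combinatorial blow-up that motivates gene-level frequency
#' scores: individual pairs range from ~1e4 to >1e7 features.
#'
#' @param genes Tibble with columns `name`, `genome_class`, `n_snvs`
#'   (default [cold_adaptation_genes()]).
#' @return Tibble `mt_gene`, `nuc_gene`, `n_pairs`, sorted by descending
#'   `n_pairs`.
#' @export
pair_feature_space <- function(genes = cold_adaptation_genes()) {
  mt <- dplyr::filter(genes, .data$genome_class == "mitochondrial")
  nuc <- dplyr::filter(genes, .data$genome_class == "nuclear")
  tidyr::expand_grid(mt_gene = mt$name, nuc_gene = nuc$name) |>
    dplyr::left_join(dplyr::select(mt, mt_gene = "name", mt_snvs = "n_snvs"), by = "mt_gene") |>
    dplyr::left_join(dplyr::select(nuc, nuc_gene = "name", nuc_snvs = "n_snvs"), by = "nuc_gene") |>
    dplyr::mutate(n_pairs = as.double(.data$mt_snvs) * .data$nuc_snvs) |>
    dplyr::arrange(dplyr::desc(.data$n_pairs))
}
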