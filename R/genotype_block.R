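#' Genotype blocks
#'
#' A genotype block holds the genotype states of a set of subjects at the
#' retained biallelic SNVs of one gene region. Mitochondrial states are
#' haploid alleles coded 0/1; nuclear states are unordered diploid genotypes
#' coded as alt-allele dosage 0 (hom-ref), 1 (het, merging `0|1` and `1|0`),
#' 2 (hom-alt). Phase is discarded on construction.
#'
#' @param gene Gene symbol.
#' @param chrom Chromosome label.
#' @param start,end 1-based inclusive region bounds.
#' @param genome_class `"mitochondrial"` or `"nuclear"`.
#' @param sites Tibble with columns `chrom`, `pos`, `site_id`, `ref`, `alt`,
#'   sorted by `pos`, one row per retained SNV.
#' @param states Integer matrix, subjects x sites; values in `{0,1}`
#'   (mitochondrial) or `{0,1,2}` (nuclear). Row names are subject ids,
#'   column names the `site_id`s.
#' @return An object of class `genotype_block`.
#' @export
genotype_block <- function(gene, chrom, start, end, genome_class, sites, states) {
  genome_class <- match.arg(genome_class, c("mitochondrial", "nuclear"))
  stopifnot(is.matrix(states))
  sites <- tibble::as_tibble(sites)
  if (nrow(sites) != ncol(states)) {
    abort("`sites` must have one row per column of `states`.")
  }
  if (nrow(sites) > 0) {
    if (anyDuplicated(sites$site_id)) abort("site ids must be unique within a block")
    if (is.unsorted(sites$pos)) abort("sites must be sorted by position")
    if (any(sites$pos < 1)) abort("positions are 1-based; pos >= 1 required")
    colnames(states) <- sites$site_id
  }
  alphabet <- if (genome_class == "mitochondrial") 0:1 else 0:2
  if (nrow(sites) > 0 && !all(states %in% alphabet)) {
    abort(sprintf("states outside the %s alphabet {%s}",
                  genome_class, paste(alphabet, collapse = ",")))
  }
  if (is.null(rownames(states))) abort("`states` needs subject ids as row names")
  structure(
    list(gene = gene, chrom = chrom, start = start, end = end,
         genome_class = genome_class, sites = sites,
         states = states, subject_ids = rownames(states)),
    class = "genotype_block"
  )
}

#' @export
print.genotype_block <- function(x, ...) {
  cat(sprintf("<genotype_block> %s (%s) %s:%d-%d\n",
              x$gene, x$genome_class, x$chrom, x$start, x$end))
  cat(sprintf("  %d subjects x %d sites\n", nrow(x$states), ncol(x$states)))
  invisible(x)
}

#' @export
dim.genotype_block <- function(x) dim(x$states)

#' Drop invariant sites from a genotype block
#'
#' Removes every site whose state is constant across all pooled subjects,
#' so that only SNVs that actually vary in the sample are retained. Site
#' order is preserved and the operation is idempotent.
#'
#' @param block A [genotype_block()].
#' @return The block with invariant site columns removed. If every site is
#'   invariant the result has zero sites and a warning is raised.
#' @export
filter_invariant <- function(block) {
  stopifnot(inherits(block, "genotype_block"))
  if (ncol(block$states) == 0L) return(block)
  keep <- apply(block$states, 2L, function(col) length(unique(col)) > 1L)
  if (!any(keep)) {
    warn(sprintf("all %d sites in %s are invariant; returning an empty block",
                 ncol(block$states), block$gene))
  }
  if (all(keep)) return(block)
  subset_sites(block, which(keep))
}

## Subset a block to site (column) indices, keeping metadata in sync.
subset_sites <- function(block, idx) {
  block$states <- block$states[, idx, drop = FALSE]
  block$sites <- block$sites[idx, , drop = FALSE]
  block
}

## Subset a block to a set of subjects (by id), preserving the given order.
subset_subjects <- function(block, subjects) {
  missing <- setdiff(subjects, block$subject_ids)
  if (length(missing) > 0) {
    abort(sprintf("subjects absent from block %s: %s",
                  block$gene, paste(head(missing, 5), collapse = ", ")))
  }
  block$states <- block$states[subjects, , drop = FALSE]
  block$subject_ids <- subjects
  block
}

## Shared validation for lists of blocks keyed by gene name.
check_blocks <- function(blocks) {
  stopifnot(is.list(blocks), length(blocks) > 0)
  if (is.null(names(blocks)) || any(!nzchar(names(blocks)))) {
    names(blocks) <- vapply(blocks, function(b) b$gene, character(1))
  }
  for (b in blocks) {
    if (ncol(b$states) == 0L) {
      abort(sprintf("gene %s has an empty genotype block", b$gene))
    }
  }
  blocks
}
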