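#' Configure an end-to-end pipeline run
#'
#' Bundles the inputs and every method parameter of the full analysis: the
#' random-forest protocol (500 trees, stratified 10-fold cross-validation,
#' 1% parsimony tolerance), the permutation count of the Fst null (200),
#' the LD-pruning parameters (window 50, step 10, r-squared 0.1) and the
#' size of retained SNV-pair importance lists (100).
#'
#' @param sim A [sim_config()], or `NULL` when reading real data.
#' @param paths `list(vcf=, panel=, regions=)` when `sim` is `NULL`.
#' @param modes Feature modes to run.
#' @param snv_gene Nuclear gene for the SNV-pair-level analysis, or `NULL`
#'   to skip it.
#' @param seed Pipeline seed; every stage derives its own stream from it.
#' @param n_trees,n_folds,tolerance,n_perm,ld_window,ld_step,ld_threshold,top_k
#'   Method parameters (see above for defaults).
#' @param run_baselines Run LD pruning + Fst + DAPC baselines.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL, paths = NULL,
                            modes = c("mt", "nuc", "pair"),
                            snv_gene = NULL, seed = 1L,
                            n_trees = 500, n_folds = 10, tolerance = 0.01,
                            n_perm = 200, ld_window = 50, ld_step = 10,
                            ld_threshold = 0.1, top_k = 100,
                            run_baselines = TRUE) {
  if (is.null(sim) && is.null(paths)) abort("provide either `sim` or `paths`")
  stopifnot(n_trees > 0, n_folds > 1, tolerance >= 0, n_perm > 0, top_k > 0)
  structure(list(sim = sim, paths = paths, modes = modes, snv_gene = snv_gene,
                 seed = as.integer(seed), n_trees = n_trees, n_folds = n_folds,
                 tolerance = tolerance, n_perm = n_perm, ld_window = ld_window,
                 ld_step = ld_step, ld_threshold = ld_threshold, top_k = top_k,
                 run_baselines = run_baselines),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Loads (or simulates) the genotype data, filters invariant sites, then for
#' every requested mode runs all reference/target classification experiments,
#' derives per-population specific features, tabulates combination gains
#' (when all three modes are present), optionally runs the SNV-pair-level
#' analysis for one nuclear gene, and computes the population-genetics
#' baselines (LD-pruned per-gene Fst with permutation p-values, specificity
#' calls, and per-gene DAPC centroid distances). The whole run is a
#' deterministic function of the configuration and its seed.
#'
#' @param config A [pipeline_config()].
#' @return A `mitonuclear_bundle`: list with `accuracy` (tibble),
#'   `experiments` (per mode), `specificity` (per mode x population),
#'   `gains`, `snv`, `fst`, `fst_calls`, `dapc_dist`, `seed`, `config_hash`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
    message(sprintf("[%s] %.1fs", name, as.numeric(Sys.time() - t0, units = "secs")))
    out
  }

  data <- stage("load", {
    if (!is.null(config$sim)) {
      simulate_dataset(config$sim)
    } else {
      read_dataset(config$paths$vcf, config$paths$panel, config$paths$regions)
    }
  })
  blocks <- lapply(data$blocks, filter_invariant)
  blocks <- blocks[vapply(blocks, function(b) ncol(b$states) > 0, logical(1))]
  panel <- data$panel
  pops <- unique(panel$population)

  experiments <- stage("classify", {
    out <- lapply(config$modes, function(m) {
      run_experiment_set(blocks, panel, pops, m, config$n_trees, config$n_folds,
                         config$tolerance, config$seed)
    })
    names(out) <- config$modes
    out
  })
  accuracy <- purrr::map_dfr(experiments, accuracy_matrix)

  specificity <- stage("specificity", {
    purrr::map(experiments, function(res) {
      reports <- lapply(pops, function(p) population_specific(res, p))
      names(reports) <- pops
      reports
    })
  })

  gains <- NULL
  if (all(c("mt", "nuc", "pair") %in% config$modes)) {
    gains <- stage("gains", {
      purrr::map_dfr(names(experiments$pair), function(nm) {
        g <- combination_gains(experiments$mt[[nm]], experiments$nuc[[nm]],
                               experiments$pair[[nm]])
        if (nrow(g) > 0) {
          g$ref_pop <- experiments$pair[[nm]]$ref_pop
          g$target_pop <- experiments$pair[[nm]]$target_pop
        }
        g
      })
    })
  }

  snv <- NULL
  if (!is.null(config$snv_gene)) {
    snv <- stage("snv_pairs", {
      mt_blocks <- blocks[vapply(blocks, function(b) b$genome_class == "mitochondrial",
                                 logical(1))]
      snv_pair_mode(blocks[[config$snv_gene]], mt_blocks, panel, config$top_k,
                    config$n_trees, config$n_folds, config$seed)
    })
  }

  fst_tbl <- NULL; fst_calls <- NULL; dapc_dist <- NULL
  if (isTRUE(config$run_baselines)) {
    pruned <- stage("ld_prune", {
      lapply(blocks, prune_ld, window = config$ld_window, step = config$ld_step,
             threshold = config$ld_threshold)
    })
    pruned <- pruned[vapply(pruned, function(b) ncol(b$states) > 0, logical(1))]
    fst_tbl <- stage("fst", {
      pair_set <- combn(pops, 2, simplify = FALSE)
      purrr::map_dfr(pruned, function(b) {
        purrr::map_dfr(pair_set, function(pp) {
          tidy(fst_permutation_p(b, panel, pp[1], pp[2], config$n_perm, config$seed))
        })
      })
    })
    fst_calls <- fst_specificity(fst_tbl)
    dapc_dist <- stage("dapc", {
      purrr::map_dfr(pruned, function(b) {
        d <- dapc(b, panel)
        dplyr::mutate(d$centroid_dist, gene = b$gene, .before = 1)
      })
    })
  }

  structure(
    list(accuracy = accuracy, experiments = experiments, specificity = specificity,
         gains = gains, snv = snv, fst = fst_tbl, fst_calls = fst_calls,
         dapc_dist = dapc_dist, seed = config$seed,
         config_hash = rlang::hash(unclass(config))),
    class = "mitonuclear_bundle"
  )
}

#' @export
print.mitonuclear_bundle <- function(x, ...) {
  cat(sprintf("<mitonuclear_bundle> seed %d, config %s\n", x$seed, x$config_hash))
  print(x$accuracy)
  invisible(x)
}

#' Write a result bundle as TSV + markdown reports
#'
#' Emits the accuracy matrix, per-population specificity lists (with explicit
#' `none` rows when a population has no specific features), the
#' combination-gain table, Fst and DAPC baseline tables, and a markdown
#' summary. Every file carries the seed and configuration hash in a header
#' comment.
#'
#' @param bundle A `mitonuclear_bundle`.
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("# seed=%d config=%s", bundle$seed, bundle$config_hash)
  paths <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    writeLines(stamp, path)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
    paths <<- c(paths, path)
  }
  emit(bundle$accuracy, "accuracy_matrix.tsv")
  spec_tbl <- purrr::map_dfr(names(bundle$specificity), function(m) {
    purrr::map_dfr(bundle$specificity[[m]], function(rep) {
      feats <- rep$specific_features
      tibble::tibble(mode = m, population = rep$population,
                     feature = if (length(feats) == 0) "none" else feats)
    })
  })
  emit(spec_tbl, "population_specific.tsv")
  if (!is.null(bundle$gains)) emit(bundle$gains, "combination_gains.tsv")
  if (!is.null(bundle$fst)) {
    emit(bundle$fst, "fst.tsv")
    emit(bundle$fst_calls, "fst_specificity.tsv")
  }
  if (!is.null(bundle$dapc_dist)) emit(bundle$dapc_dist, "dapc_centroid_distances.tsv")
  if (!is.null(bundle$snv)) {
    snv_tbl <- purrr::map_dfr(names(bundle$snv$experiments), function(nm) {
      dplyr::mutate(bundle$snv$experiments[[nm]]$top, experiment = nm, .before = 1)
    })
    emit(snv_tbl, "snv_pair_top.tsv")
    snv_spec <- purrr::map_dfr(names(bundle$snv$specific), function(p) {
      feats <- bundle$snv$specific[[p]]
      tibble::tibble(population = p,
                     feature = if (length(feats) == 0) "none" else feats)
    })
    emit(snv_spec, "snv_pair_specific.tsv")
  }
  json <- file.path(out_dir, "bundle.json")
  jsonlite::write_json(
    list(seed = bundle$seed, config = bundle$config_hash,
         accuracy = bundle$accuracy, specificity = spec_tbl,
         fst = bundle$fst, fst_calls = bundle$fst_calls),
    json, auto_unbox = TRUE, digits = NA, null = "null")
  paths <- c(paths, json)
  md <- file.path(out_dir, "summary.md")
  lines <- c(
    "# Pipeline summary", "",
    sprintf("- seed: %d", bundle$seed),
    sprintf("- config hash: %s", bundle$config_hash), "",
    "## Classification accuracy (reference vs target)", "",
    knit_table(bundle$accuracy), "",
    "## Population-specific features", "",
    knit_table(spec_tbl)
  )
  writeLines(lines, md)
  invisible(c(paths, md))
}

## Minimal markdown table renderer (no extra dependency).
knit_table <- function(df) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric), ~ round(.x, 4)))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}
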