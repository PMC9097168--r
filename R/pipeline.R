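# End-to-end orchestration: one config drives classify -> intersect ->
# enrich -> clump -> sweep-test -> direction -> MR -> coloc, with per-stage
# seeds, TSV/JSON artifacts and an md5 manifest so a rerun with the same
# config is byte-identical.

#' Pipeline run configuration
#'
#' In simulate mode a [sim_config()] generates every input; in real mode the
#' file paths must exist. Thresholds default to the analysis conventions:
#' frequency 0.90 (stringent across metapopulations), clump r-squared 0.1
#' in a 250 kb window, 1,000 permutations, MR top-hit p 5e-4, alpha 0.05.
#'
#' @param mode `"simulate"` or `"real"`.
#' @param sim a [sim_config()] (simulate mode).
#' @param paths named list of input paths (real mode): `catalog`, `eqtls`,
#'   `panel`, `windows`, `gwas` (a vector of per-trait files).
#' @param freq_threshold,stringent classification settings.
#' @param r2_threshold,clump_kb clumping settings.
#' @param n_perm permutations for the sweep overlap test.
#' @param mr_p_threshold instrument-selection p threshold.
#' @param alpha significance level for residual flags and MR survivors.
#' @param coloc_priors named vector `p1`, `p2`, `p12`.
#' @param n_sampling resamples for the region-specificity sampling test.
#' @param seed master seed (fanned out per stage).
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "real"),
                       sim = sim_config(),
                       paths = list(),
                       freq_threshold = 0.90,
                       stringent = TRUE,
                       r2_threshold = 0.1,
                       clump_kb = 250,
                       n_perm = 1000,
                       mr_p_threshold = 5e-4,
                       alpha = 0.05,
                       coloc_priors = c(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5),
                       n_sampling = 100,
                       seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "simulate" && !inherits(sim, "sim_config"))
    stop_config("simulate mode needs a sim_config")
  if (mode == "real") {
    need <- c("catalog", "eqtls", "panel", "windows", "gwas")
    miss <- setdiff(need, names(paths))
    if (length(miss))
      stop_config("real mode needs paths: ", paste(miss, collapse = ", "))
    files <- unlist(paths[need], use.names = FALSE)
    absent <- files[!file.exists(files)]
    if (length(absent))
      stop_config("missing input file(s): ", paste(absent, collapse = ", "))
  }
  if (freq_threshold <= 0.5 || freq_threshold > 1)
    stop_config("freq_threshold must lie in (0.5, 1]")
  if (r2_threshold <= 0 || r2_threshold > 1)
    stop_config("r2_threshold must lie in (0, 1]")
  structure(list(mode = mode, sim = sim, paths = paths,
                 freq_threshold = freq_threshold, stringent = stringent,
                 r2_threshold = r2_threshold, clump_kb = clump_kb,
                 n_perm = as.integer(n_perm),
                 mr_p_threshold = mr_p_threshold, alpha = alpha,
                 coloc_priors = coloc_priors,
                 n_sampling = as.integer(n_sampling),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; a `simulate:` block
#' holds [sim_config()] arguments.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulate)) do.call(sim_config, y$simulate)
         else sim_config()
  args <- y[setdiff(names(y), "simulate")]
  if (!is.null(args$chrom_lengths)) args$chrom_lengths <- NULL
  do.call(run_config, c(list(sim = sim), args))
}

.load_inputs <- function(config) {
  if (config$mode == "simulate") {
    inputs <- simulate_inputs(config$sim)
  } else {
    catalog <- read_catalog(config$paths$catalog)
    panel <- read_panel(config$paths$panel)
    eqtls <- read_eqtls(config$paths$eqtls)
    windows <- read_bed(config$paths$windows)
    if (!"source" %in% names(windows)) windows$source <- "sweep"
    gwas_files <- config$paths$gwas
    gwas <- lapply(gwas_files, read_gwas)
    names(gwas) <- if (!is.null(names(gwas_files))) names(gwas_files)
                   else tools::file_path_sans_ext(basename(gwas_files))
    if (!"qval_pass" %in% names(eqtls))
      eqtls$qval_pass <- p.adjust(eqtls$pval_nominal, "BH") < 0.05
    if (!"slope_se" %in% names(eqtls)) eqtls$slope_se <- NA_real_
    inputs <- list(panel = panel, catalog = catalog, truth = NULL,
                   eqtls = eqtls, windows = windows, gwas = gwas)
  }
  inputs
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order, writing intermediate artifacts and a
#' `manifest.json` with md5 hashes into `out_dir`. A rerun with the same
#' configuration reproduces every artifact byte for byte. A stage failure
#' aborts with the failing stage named; artifacts already written are
#' preserved.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir = tempfile("paleoqtl_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- stage_seeds(config$seed, 8)
  results <- list(config = config)
  artifacts <- character(0)
  emit <- function(obj, name, writer = .write_tsv) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    artifacts <<- c(artifacts, path)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # inputs
  inputs <- stage("inputs", .load_inputs(config))
  if (config$mode == "simulate") {
    emit(inputs$catalog, "catalog.tsv")
    emit(inputs$eqtls, "eqtls.tsv")
    emit(inputs$windows, "sweep_windows.bed", write_bed)
  }
  genome <- if (config$mode == "simulate") config$sim$chrom_lengths
            else {
              lens <- tapply(c(inputs$catalog$pos, inputs$windows$end),
                             c(inputs$catalog$chrom, inputs$windows$chrom), max)
              ceiling(lens * 1.05)
            }

  # classify
  classified <- stage("classify",
    classify_variants(inputs$catalog, threshold = config$freq_threshold,
                      stringent = config$stringent))
  emit(classified, "classified.tsv")
  results$classified <- classified

  # intersect
  inter <- stage("intersect", eqtl_intersect(classified, inputs$eqtls))
  results$intersect <- inter
  n_hf_eqtl_variants <- length(unique(inter$focal$variant_id))
  n_egenes <- length(unique(inter$focal$gene_id))

  # enrichment
  results$tissue_test <- stage("enrich",
    tissue_composition_test(inter$focal, inter$background,
                            alpha = config$alpha))
  results$category_test <- stage("enrich", tryCatch(
    category_composition_test(inter$focal, inter$background,
                              alpha = config$alpha),
    error = function(e) NULL))

  # clumping
  clumped <- stage("clump",
    clump_by_tissue(inter$focal, classified, inputs$panel,
                    r2_threshold = config$r2_threshold,
                    window_kb = config$clump_kb))
  emit(clumped, "clumped.tsv")
  results$clumped <- clumped
  idx <- clumped[clumped$is_index, , drop = FALSE]
  counts <- table(idx$tissue)
  samples <- attr(inputs$eqtls, "samples") %||%
    gtex_brain_samples()[names(counts)]
  results$specific_counts <- tissue_specific_counts(clumped)
  results$sample_size <- stage("clump", tryCatch(
    sample_size_correlation(setNames(as.numeric(counts), names(counts)),
                            samples),
    error = function(e) NULL))
  results$sampling_test <- stage("clump",
    region_specific_sampling_test(idx, n_resamples = config$n_sampling,
                                  seed = seeds[3]))

  # sweep overlap (unclumped focal variants)
  pos_df <- stage("sweep", {
    u <- inter$focal[!duplicated(inter$focal$variant_id), , drop = FALSE]
    m <- match(u$variant_id, classified$rsid)
    data.frame(chrom = classified$chrom[m], pos = classified$pos[m],
               variant_id = u$variant_id, stringsAsFactors = FALSE)
  })
  sources <- sort(unique(inputs$windows$source))
  results$sweep_tests <- stage("sweep", {
    out <- lapply(sources, function(s) {
      sweep_permutation_test(pos_df,
                             inputs$windows[inputs$windows$source == s, ],
                             genome, n_perm = config$n_perm,
                             seed = seeds[4] + match(s, sources))
    })
    names(out) <- sources
    out
  })
  eq_pos <- stage("sweep", {
    m <- match(inter$focal$variant_id, classified$rsid)
    cbind(inter$focal, chrom = classified$chrom[m], pos = classified$pos[m])
  })
  results$per_region <- stage("sweep",
    per_region_counts(eq_pos, inputs$windows))
  results$source_comparison <- stage("sweep", tryCatch(
    if (length(sources) == 2) compare_sweep_sources(results$per_region$rates),
    error = function(e) NULL))

  # directionality: unclumped, clumped, ancestral-major control
  results$direction <- stage("direction", {
    unclumped <- orient_slopes(inter$focal, classified, "derived")
    idx_set <- inter$focal[inter$focal$variant_id %in%
                             idx$variant_id, , drop = FALSE]
    clumped_or <- orient_slopes(idx_set, classified, "derived")
    control <- build_control_set(classified, inputs$eqtls,
                                 threshold = config$freq_threshold)
    list(unclumped = direction_test(unclumped, alpha = config$alpha),
         clumped = direction_test(clumped_or, alpha = config$alpha),
         control = if (nrow(control)) direction_test(control,
                                                     alpha = config$alpha))
  })
  results$clustering <- stage("direction", tryCatch(
    tissue_clustering(orient_slopes(inter$focal, classified, "derived"),
                      value = "slope"),
    error = function(e) NULL))
  if (!is.null(results$clustering))
    emit(data.frame(newick = results$clustering$newick), "tissue_tree.nwk",
         function(d, p) writeLines(d$newick, p))

  # Mendelian randomization + colocalization
  instruments <- stage("mr",
    select_instruments(inputs$eqtls, classified,
                       p_threshold = config$mr_p_threshold))
  results$mr <- stage("mr", mr_wald(instruments, inputs$gwas))
  if (!is.null(results$mr) && nrow(results$mr)) emit(results$mr, "mr.tsv")

  results$coloc <- stage("coloc", {
    surv <- results$mr
    if (is.null(surv) || !nrow(surv)) NULL
    else {
      surv <- surv[surv$p_bonferroni < config$alpha, , drop = FALSE]
      if (!nrow(surv)) NULL
      else {
        pr <- config$coloc_priors
        out <- lapply(seq_len(nrow(surv)), function(i) {
          g <- surv$gene_id[i]; t <- surv$tissue[i]; tr <- surv$trait[i]
          eq <- inputs$eqtls[inputs$eqtls$gene_id == g &
                               inputs$eqtls$tissue == t, , drop = FALSE]
          gw <- inputs$gwas[[tr]]
          gw <- gw[gw$SNP %in% eq$variant_id, , drop = FALSE]
          if (nrow(gw) < 2) return(NULL)
          res <- coloc_abf(
            data.frame(snp = eq$variant_id, beta = eq$slope,
                       se = eq$slope_se),
            data.frame(snp = gw$SNP, beta = gw$beta, se = gw$se),
            p1 = pr[["p1"]], p2 = pr[["p2"]], p12 = pr[["p12"]])
          data.frame(gene_id = g, tissue = t, trait = tr,
                     t(res$summary), stringsAsFactors = FALSE)
        })
        out <- do.call(rbind, out)
        if (!is.null(out)) rownames(out) <- NULL
        out
      }
    }
  })
  if (!is.null(results$coloc) && nrow(results$coloc))
    emit(results$coloc, "coloc.tsv")

  # summary + manifest
  summary <- list(
    n_variants = nrow(inputs$catalog),
    n_derived_hf = sum(classified$is_derived_hf),
    n_hf_eqtl_variants = n_hf_eqtl_variants,
    n_egenes = n_egenes,
    n_clumped = nrow(idx),
    n_region_specific = sum(results$specific_counts),
    sweep_p = lapply(results$sweep_tests, function(x)
      c(observed = x$observed, expected = x$expected, p = x$p.value)),
    direction_p = list(
      unclumped = results$direction$unclumped$p.value,
      clumped = results$direction$clumped$p.value,
      control = if (!is.null(results$direction$control))
        results$direction$control$p.value),
    n_mr_tests = if (!is.null(results$mr)) nrow(results$mr) else 0L,
    n_mr_survivors = if (!is.null(results$mr))
      sum(results$mr$p_bonferroni < config$alpha) else 0L,
    max_pp4 = if (!is.null(results$coloc)) max(results$coloc$PP4) else NULL)
  results$summary <- summary
  emit(summary, "summary.json", function(obj, p)
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA, pretty = TRUE))

  hashes <- tools::md5sum(artifacts)
  manifest <- data.frame(file = basename(names(hashes)),
                         md5 = unname(hashes), stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
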