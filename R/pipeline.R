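#' Run the full CUP analysis pipeline
#'
#' Orchestrates the stages in the order of the underlying analysis: IQR
#' filtering, LOOCV grid-search training of the tissue-of-origin classifier,
#' CUP prediction (with optional sex-specific prior masking), leave-one-out
#' QDA outlier scoring with the error-rate curve, paired CUP-vs-MOKO
#' differential expression with core-set extraction, gene-set overlap
#' testing, GSEA of a chromosomal-instability signature, instability scoring
#' and the outlier-instability correlation. All result tables are written
#' tab-delimited into `out_dir` together with a JSON run manifest recording
#' every resolved parameter and input checksum.
#'
#' The configuration is a plain named list (or a YAML file with the same
#' structure). Recognised keys:
#' \describe{
#'   \item{seed}{integer; drives simulation and permutation stages.}
#'   \item{simulate}{list of [cohort_config()] overrides; used when no input
#'     paths are given.}
#'   \item{matrix, samples, annotation, gene_sets}{input file paths
#'     (tab-delimited matrix / sample table / annotation, GMT gene sets);
#'     all must exist at load time.}
#'   \item{iqr_threshold}{IQR filter threshold (default 0.8).}
#'   \item{cutoff_grid}{F-test p-value grid (default `10^-(2:12)`).}
#'   \item{sex_map}{named class -> sex vector for prior masking.}
#'   \item{n_bins, degree}{error-curve binning and polynomial degree
#'     (defaults 10, 2).}
#'   \item{p_cutoff}{core-set p cut-off (default 1e-8).}
#'   \item{variance_keep_fraction}{instability-score variance filter
#'     (default 0.5).}
#'   \item{n_perm}{GSEA permutations (default 1000).}
#'   \item{cin_set}{name of the instability gene set (default
#'     "CIN_SIGNATURE").}
#' }
#' Unknown keys are rejected.
#'
#' @param config named list or path to a YAML file.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results (`grid`,
#'   `model`, `cup_predictions`, `outliers`, `bins`, `error_curve`, `de`,
#'   `core_set`, `overlap`, `gsea`, `instability`, `correlation`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- .load_pipeline_config(config)
  if (missing(out_dir) || is.null(out_dir))
    stop("'out_dir' is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message(format(Sys.time(), "%H:%M:%S "),
                                   sprintf(...))
  stage <- "load-inputs"
  res <- list()
  tryCatch({
    if (!is.null(cfg$matrix)) {
      expr <- read_expression_matrix(cfg$matrix)
      samples <- read_sample_table(cfg$samples)
      annotation <- utils::read.delim(cfg$annotation,
                                      stringsAsFactors = FALSE)
      gene_sets <- read_gmt(cfg$gene_sets)
      checksums <- vapply(c(cfg$matrix, cfg$samples, cfg$annotation,
                            cfg$gene_sets),
                          function(f) unname(tools::md5sum(f)), character(1))
    } else {
      stage <- "simulate"
      sim_args <- cfg$simulate %||% list()
      sim_args$seed <- sim_args$seed %||% cfg$seed
      ccfg <- do.call(cohort_config, sim_args)
      cohort <- simulate_cohort(ccfg)
      expr <- cohort$expr
      samples <- cohort$samples
      annotation <- cohort$annotation
      gene_sets <- simulate_gene_sets(cohort, seed = cfg$seed)
      checksums <- NULL
      log_msg("simulated cohort: %d probes x %d samples",
              nrow(expr), ncol(expr))
    }

    stage <- "iqr-filter"
    expr_f <- iqr_filter(expr, cfg$iqr_threshold)
    log_msg("IQR filter (>= %.2f): %d of %d probes retained",
            cfg$iqr_threshold, nrow(expr_f), nrow(expr))

    labelled <- samples$class_label != "unknown"
    x_tr <- expr_f[, samples$sample_id[labelled], drop = FALSE]
    cls_tr <- samples$class_label[labelled]

    stage <- "train"
    grid <- loocv_grid_search(x_tr, cls_tr, cfg$cutoff_grid)
    log_msg("grid search: best cut-off %g, LOOCV accuracy %.3f",
            grid$best_cutoff, grid$best_accuracy)
    fs <- f_statistics(x_tr, cls_tr)
    sel <- fs$probe_id[fs$p < grid$best_cutoff]
    if (!length(sel)) sel <- fs$probe_id[order(fs$p)][1]
    model <- gda(x_tr[sel, , drop = FALSE], cls_tr, method = "lda")
    res$grid <- grid
    res$model <- model

    stage <- "predict-cup"
    cup_ids <- samples$sample_id[samples$group == "CUP"]
    if (length(cup_ids)) {
      pr <- predict(model, expr_f[sel, cup_ids, drop = FALSE],
                    sex = samples$sex[match(cup_ids, samples$sample_id)],
                    sex_map = cfg$sex_map)
      cup_pred <- data.frame(sample_id = cup_ids,
                             predicted = as.character(pr$class),
                             outlier_score = NA_real_,
                             stringsAsFactors = FALSE)
      res$cup_predictions <- cup_pred
    }

    stage <- "outlier"
    tumour <- labelled & samples$group %in% c("primary", "metastasis")
    x_os <- expr_f[sel, samples$sample_id[tumour], drop = FALSE]
    outl <- loocv_outlier_scores(x_os, samples$class_label[tumour])
    res$outliers <- outl
    qda_model <- gda(x_os, samples$class_label[tumour], method = "qda")
    if (length(cup_ids)) {
      cup_os <- outlier_score(qda_model,
                              expr_f[sel, cup_ids, drop = FALSE])
      res$cup_predictions$outlier_score <- unname(cup_os)
    }
    stage <- "error-curve"
    res$bins <- bin_error_rates(outl, cfg$n_bins)
    res$error_curve <- fit_error_curve(res$bins, cfg$degree)

    stage <- "differential"
    if (length(cup_ids)) {
      moko <- samples$group == "metastasis"
      ids_de <- c(cup_ids, samples$sample_id[moko])
      grp_de <- c(rep("CUP", length(cup_ids)),
                  rep("MOKO", sum(moko)))
      cls_de <- c(res$cup_predictions$predicted,
                  samples$class_label[moko])
      de <- paired_class_test(expr_f[, ids_de, drop = FALSE], grp_de, cls_de)
      res$de <- de
      res$core_set <- extract_core_set(de, annotation, cfg$p_cutoff)
      log_msg("core set: %d up / %d down probes at p < %g",
              length(res$core_set$up_probes),
              length(res$core_set$down_probes), cfg$p_cutoff)

      stage <- "enrichment"
      universe <- unique(annotation$gene_symbol[
        annotation$probe_id %in% rownames(expr_f)])
      query <- intersect(res$core_set$up_genes, universe)
      if (length(query))
        res$overlap <- overlap_test(query, gene_sets, universe)

      stage <- "gsea"
      if (cfg$cin_set %in% names(gene_sets)) {
        res$gsea <- gsea(expr_f[, ids_de, drop = FALSE],
                         grp_de, gene_sets[[cfg$cin_set]], annotation,
                         n_perm = cfg$n_perm, seed = cfg$seed)
      }

      stage <- "instability"
      if (cfg$cin_set %in% names(gene_sets)) {
        inst <- instability_score(expr_f, gene_sets[[cfg$cin_set]],
                                  annotation, cfg$variance_keep_fraction)
        res$instability <- inst
        os_all <- rbind(outl[, c("sample_id", "os")],
                        data.frame(sample_id = cup_ids,
                                   os = res$cup_predictions$outlier_score))
        res$correlation <- correlate_outlier_instability(os_all, inst)
        log_msg("outlier~instability: r = %.3f, p = %.3g",
                res$correlation$r, res$correlation$p)
      }
    }

    stage <- "write-results"
    wr <- function(obj, name)
      utils::write.table(obj, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    wr(data.frame(cutoff = as.numeric(names(grid$accuracy)),
                  accuracy = unname(grid$accuracy)), "grid_search.tsv")
    wr(outl, "outlier_scores.tsv")
    wr(res$bins, "error_bins.tsv")
    if (!is.null(res$cup_predictions))
      wr(res$cup_predictions, "cup_predictions.tsv")
    if (!is.null(res$de)) wr(res$de, "differential_expression.tsv")
    if (!is.null(res$overlap)) wr(res$overlap, "gene_set_overlap.tsv")
    if (!is.null(res$instability)) wr(res$instability,
                                      "instability_scores.tsv")
    if (!is.null(res$core_set)) {
      write_gmt(list(CUP_CORE_UP = res$core_set$up_genes,
                     CUP_CORE_DOWN = res$core_set$down_genes),
                file.path(out_dir, "cup_core_set.gmt"))
    }

    manifest <- list(
      package = "cuporigin",
      version = as.character(utils::packageVersion("cuporigin")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      parameters = cfg[setdiff(names(cfg), "sex_map")],
      sex_map = as.list(cfg$sex_map %||% list()),
      input_checksums = as.list(checksums %||% list()),
      stages = names(res)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    res$manifest <- manifest
    invisible(res)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

# Validate/normalise a pipeline configuration (list or YAML path).
.load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("'config' must be a list or a YAML file path")
  known <- c("seed", "simulate", "matrix", "samples", "annotation",
             "gene_sets", "iqr_threshold", "cutoff_grid", "sex_map",
             "n_bins", "degree", "p_cutoff", "variance_keep_fraction",
             "n_perm", "cin_set")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  paths <- c("matrix", "samples", "annotation", "gene_sets")
  given <- paths[paths %in% names(config)]
  if (length(given) && length(given) < length(paths))
    stop("when loading from files, all of ",
         paste(paths, collapse = ", "), " must be given")
  for (f in given) {
    if (!file.exists(config[[f]]))
      stop("input file not found: ", config[[f]])
  }
  defaults <- list(seed = 1L, iqr_threshold = 0.8,
                   cutoff_grid = 10^-(2:12), sex_map = NULL,
                   n_bins = 10L, degree = 2L, p_cutoff = 1e-8,
                   variance_keep_fraction = 0.5, n_perm = 1000L,
                   cin_set = "CIN_SIGNATURE")
  for (k in names(defaults))
    if (is.null(config[[k]])) config[k] <- defaults[k]
  if (!is.null(config$sex_map)) config$sex_map <- unlist(config$sex_map)
  config
}
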