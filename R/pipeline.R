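# End-to-end orchestration: (simulate ->) preprocess -> exploratory PCA ->
# noise-component removal and reconstruction -> technical-replicate
# averaging -> final PCA with ellipses and loading selection -> rDCV PLS-DA
# (-> permutation test) -> VIP selection -> pathway enrichment.

#' Run the full chemometric pipeline
#'
#' Executes the analysis stages in their canonical order on a feature table
#' (a synthetic one is generated when none is given). The exploratory PCA
#' uses all samples including QCs and technical replicates; after the
#' requested components are subtracted and the data reconstructed,
#' technical replicates are averaged, QC samples are excluded (by default)
#' and the final PCA, classification and enrichment run on the averaged
#' treatment samples. The reconstructed matrix is not re-autoscaled before
#' the final PCA: columns remain near unit scale and re-scaling would
#' partially undo the removal.
#'
#' @param table A `feature_table`, or NULL to simulate one from
#'   `sim_config`. Ground truth from the simulation is never consumed here.
#' @param sim_config A [simulation_config()] used when `table` is NULL.
#' @param recipe A [preprocess_recipe()].
#' @param n_pcs Components for the exploratory PCA.
#' @param drop_pcs Integer indices of exploratory PCs to remove (e.g. `2`);
#'   NULL removes none. The choice is deliberately explicit;
#'   [rank_components_by_covariate()] can inform it but nothing is dropped
#'   automatically.
#' @param include_qc_final Keep QC samples in the final model (default
#'   FALSE).
#' @param confidence Hotelling ellipse confidence level.
#' @param loading_threshold Relative loading-selection threshold.
#' @param outer,inner,repeats,max_A rDCV parameters.
#' @param permutations Permutation count B (0 skips the test).
#' @param vip_threshold VIP cutoff for frequency counting.
#' @param vip_frequency_min Minimum selection frequency for a feature to
#'   enter the enrichment list.
#' @param pathway_library A `pathway_library` (default: the bundled
#'   five-pathway example library).
#' @param alpha Significance level for enrichment.
#' @param seed Master seed for every stochastic stage.
#' @param out_dir Optional directory; when given, scores/loadings/metrics/
#'   VIP/enrichment CSVs and a JSON report are written there.
#' @return Object of class `pipeline_report` (a list; see elements
#'   `pca_initial`, `pca_final`, `ellipses`, `loading_selection`, `rdcv`,
#'   `permutation`, `vip_table`, `enrichment`, `settings`).
#' @export
run_pipeline <- function(table = NULL, sim_config = simulation_config(),
                         recipe = preprocess_recipe(),
                         n_pcs = 5, drop_pcs = NULL,
                         include_qc_final = FALSE,
                         confidence = 0.95, loading_threshold = 0.5,
                         outer = 10, inner = 10, repeats = 10, max_A = 6,
                         permutations = 0, vip_threshold = 1,
                         vip_frequency_min = 0.5,
                         pathway_library = NULL, alpha = 0.05,
                         seed = 1L, out_dir = NULL) {
  seed <- as.integer(seed)
  stage <- "simulate"
  report <- tryCatch({
    if (is.null(table)) {
      sim_config$seed <- seed
      table <- generate_dataset(sim_config)$table
    }
    stopifnot(inherits(table, "feature_table"))

    stage <- "preprocess"
    prep <- preprocess(table$intensities, classes = table$samples$class,
                       recipe = recipe)
    X <- prep$X

    stage <- "pca_initial"
    A0 <- min(n_pcs, nrow(X) - 1L, ncol(X))
    pca0 <- fit_pca(X, A0)

    stage <- "reconstruct"
    X_rec <- remove_components_and_reconstruct(X, pca0, drop_pcs)

    stage <- "average_replicates"
    avg <- average_replicates(X_rec, table$samples$bio_rep, table$samples)
    keep <- if (include_qc_final) rep(TRUE, nrow(avg$X)) else !avg$metadata$qc
    Xf <- avg$X[keep, , drop = FALSE]
    meta_f <- avg$metadata[keep, , drop = FALSE]
    y <- meta_f$class

    stage <- "pca_final"
    Af <- min(n_pcs, nrow(Xf) - 1L, ncol(Xf))
    pcaf <- fit_pca(Xf, Af)

    stage <- "ellipses"
    ellipses <- lapply(split(seq_len(nrow(Xf)), y), function(idx) {
      if (length(idx) >= 4) {
        hotelling_ellipse(pcaf$scores[idx, 1:2, drop = FALSE], confidence)
      } else NULL
    })

    stage <- "select_loadings"
    cls_means <- do.call(rbind, lapply(split(seq_len(nrow(Xf)), y),
                                       function(idx)
      colMeans(Xf[idx, , drop = FALSE])))
    sel <- select_loadings(pcaf, loading_threshold, class_means = cls_means)

    stage <- "rdcv"
    cv <- rdcv(Xf, y, outer = min(outer, nrow(Xf)), inner = inner,
               repeats = repeats, max_A = max_A, seed = seed + 1L,
               scale = TRUE, vip_threshold = vip_threshold)

    perm <- NULL
    if (permutations > 0) {
      stage <- "permutation"
      perm <- permutation_test(Xf, y, B = permutations, seed = seed + 2L,
                               outer = min(outer, nrow(Xf)), inner = inner,
                               max_A = max_A, scale = TRUE)
    }

    stage <- "vip_selection"
    vip_tab <- data.frame(feature_id = names(cv$vip_frequency),
                          frequency = as.numeric(cv$vip_frequency),
                          stringsAsFactors = FALSE)
    vip_tab <- vip_tab[order(-vip_tab$frequency), ]
    selected_features <- vip_tab$feature_id[vip_tab$frequency >= vip_frequency_min]

    stage <- "enrichment"
    enrichment <- NULL
    if ("hmdb_id" %in% names(table$features)) {
      hmdb <- table$features$hmdb_id[match(selected_features,
                                           table$features$feature_id)]
      hmdb <- hmdb[!is.na(hmdb)]
      if (length(hmdb)) {
        if (is.null(pathway_library)) pathway_library <- bundled_pathway_library()
        hmdb <- intersect(hmdb, pathway_library$universe)
        if (length(hmdb)) {
          enrichment <- enrich(hmdb, pathway_library, alpha = alpha)
        }
      }
    }

    structure(list(
      pca_initial = list(explained = pca0$explained, A = pca0$A),
      pca_final = pcaf,
      dropped_pcs = drop_pcs %||% integer(0),
      ellipses = ellipses,
      loading_selection = sel,
      rdcv = cv,
      permutation = perm,
      vip_table = vip_tab,
      selected_features = selected_features,
      enrichment = enrichment,
      settings = list(n_pcs = n_pcs, drop_pcs = drop_pcs,
                      include_qc_final = include_qc_final,
                      confidence = confidence,
                      loading_threshold = loading_threshold,
                      outer = outer, inner = inner, repeats = repeats,
                      max_A = max_A, permutations = permutations,
                      vip_threshold = vip_threshold,
                      vip_frequency_min = vip_frequency_min,
                      alpha = alpha, seed = seed)),
      class = "pipeline_report")
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

#' Write pipeline artifacts to a directory
#'
#' @param report A `pipeline_report`.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_report <- function(report, out_dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pf <- report$pca_final
  utils::write.csv(as.data.frame(pf$scores), file.path(out_dir, "scores.csv"))
  utils::write.csv(as.data.frame(pf$loadings), file.path(out_dir, "loadings.csv"))
  utils::write.csv(data.frame(component = seq_along(pf$explained),
                              explained_fraction = pf$explained),
                   file.path(out_dir, "explained_variance.csv"),
                   row.names = FALSE)
  utils::write.csv(report$vip_table, file.path(out_dir, "vip_table.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$rdcv$misclassification),
                   file.path(out_dir, "misclassification.csv"))
  if (!is.null(report$enrichment)) {
    utils::write.csv(report$enrichment, file.path(out_dir, "enrichment.csv"),
                     row.names = FALSE)
  }
  cv <- report$rdcv
  summary <- list(
    explained_initial = report$pca_initial$explained,
    explained_final = pf$explained,
    dropped_pcs = report$dropped_pcs,
    accuracy_mean = cv$accuracy_mean, accuracy_sd = cv$accuracy_sd,
    sensitivity_mean = as.list(cv$sensitivity$mean),
    sensitivity_sd = as.list(cv$sensitivity$sd),
    specificity_mean = as.list(cv$specificity$mean),
    specificity_sd = as.list(cv$specificity$sd),
    permutation_p = if (!is.null(report$permutation))
      report$permutation$p_value else NULL,
    n_selected_features = length(report$selected_features),
    settings = report$settings)
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Chemometric pipeline report\n")
  cat(sprintf("  initial PCA: %s\n",
              paste0(sprintf("%.1f%%", 100 * x$pca_initial$explained),
                     collapse = " ")))
  if (length(x$dropped_pcs)) {
    cat("  dropped PC(s):", paste(x$dropped_pcs, collapse = ", "), "\n")
  }
  cat(sprintf("  final PCA: %s\n",
              paste0(sprintf("%.1f%%", 100 * x$pca_final$explained),
                     collapse = " ")))
  cat(sprintf("  rDCV accuracy: %.2f +/- %.2f %%\n",
              x$rdcv$accuracy_mean,
              if (is.na(x$rdcv$accuracy_sd)) 0 else x$rdcv$accuracy_sd))
  if (!is.null(x$permutation)) {
    cat(sprintf("  permutation p: %.4g (B = %d)\n",
                x$permutation$p_value, x$permutation$B))
  }
  if (!is.null(x$enrichment)) {
    sig <- x$enrichment[x$enrichment$significant, , drop = FALSE]
    cat("  enriched pathways:",
        if (nrow(sig)) paste(sig$pathway, collapse = ", ") else "none", "\n")
  }
  invisible(x)
}
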