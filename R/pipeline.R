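# End-to-end orchestration: simulate -> extract -> fuse -> project ->
# regress over the six analysis data sets, with a deterministic run
# manifest (seeds, config hash, per-artifact checksums).

ALL_FEATURE_SETS <- c("etongue", "enose", "direct", "weighted",
                      "direct_vif", "weighted_vif")

#' Pipeline run configuration
#'
#' Bundles every knob of a full run. All randomness flows from the three
#' named seeds: `dataset_seed` (signal synthesis), `split_seed`
#' (train/test partition) and `elm_seed` (ELM input weights).
#'
#' @param dataset_seed,split_seed,elm_seed integer seeds.
#' @param age_specs list of [age_class_spec()]s (default: 5 classes x 40).
#' @param vif_threshold VIF limit for the optimized sets.
#' @param n_train,n_test per-class split counts (defaults 25 / 15).
#' @param params a [model_params()].
#' @param sets subset of `"etongue"`, `"enose"`, `"direct"`, `"weighted"`,
#'   `"direct_vif"`, `"weighted_vif"` to evaluate.
#' @param out_dir output directory for artifacts; `NULL` writes to a
#'   temporary directory (checksums are still recorded).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(dataset_seed = 1, split_seed = 2, elm_seed = 3,
                            age_specs = default_age_specs(),
                            vif_threshold = 10,
                            n_train = 25, n_test = 15,
                            params = model_params(),
                            sets = ALL_FEATURE_SETS,
                            out_dir = NULL) {
  bad <- setdiff(sets, ALL_FEATURE_SETS)
  if (length(bad)) {
    stopf("unknown feature set(s): %s (valid: %s)",
          paste(bad, collapse = ", "), paste(ALL_FEATURE_SETS, collapse = ", "))
  }
  structure(
    list(dataset_seed = dataset_seed, split_seed = split_seed,
         elm_seed = elm_seed, age_specs = age_specs,
         vif_threshold = vif_threshold, n_train = n_train, n_test = n_test,
         params = params, sets = sets, out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Build the six analysis feature data sets
#'
#' From the two single-device tables: standardized e-tongue (18 features),
#' standardized e-nose (24), direct fusion (42), weighted fusion (42, with
#' the e-tongue block scaled by W = 16/9), and the VIF-pruned versions of
#' the two fused tables.
#'
#' @param etongue,enose labelled [feature_table()]s.
#' @param vif_threshold VIF limit (default 10).
#' @param sets which of the six sets to build.
#' @return Named list of [feature_table()]s; VIF-pruned entries carry the
#'   audit in attribute `"vif_audit"`.
#' @export
build_feature_sets <- function(etongue, enose, vif_threshold = 10,
                               sets = ALL_FEATURE_SETS) {
  out <- list()
  if ("etongue" %in% sets) out$etongue <- standardize(etongue)
  if ("enose" %in% sets) out$enose <- standardize(enose)
  need_direct <- any(c("direct", "direct_vif") %in% sets)
  need_weighted <- any(c("weighted", "weighted_vif") %in% sets)
  if (need_direct) {
    direct <- fuse(etongue, enose, fusion_spec("direct"))
    if ("direct" %in% sets) out$direct <- direct
    if ("direct_vif" %in% sets) {
      v <- vif_eliminate(direct, vif_threshold)
      out$direct_vif <- v$table
      attr(out$direct_vif, "vif_audit") <- v$audit
    }
  }
  if (need_weighted) {
    weighted <- fuse(etongue, enose, fusion_spec("weighted"))
    if ("weighted" %in% sets) out$weighted <- weighted
    if ("weighted_vif" %in% sets) {
      v <- vif_eliminate(weighted, vif_threshold)
      out$weighted_vif <- v$table
      attr(out$weighted_vif, "vif_audit") <- v$audit
    }
  }
  out[intersect(sets, names(out))]
}

write_scores_csv <- function(result, table, path) {
  df <- data.frame(sample_id = rownames(result$scores), result$scores,
                   row.names = NULL, check.names = FALSE)
  if (!is.null(table$age_years)) df$age_years <- table$age_years
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Simulates the labelled dataset, extracts area features for both
#' instruments, builds the requested feature data sets, and produces per
#' set: the feature CSV, 2-D PCA and LPP score CSVs, and a regression
#' report (train/test R-squared and MSE for PLSR, ELM and SVR). The run
#' manifest records the package version, a hash of the configuration, all
#' seeds and an MD5 checksum of every artifact, so identical configurations
#' yield identical manifests.
#'
#' @param config a [pipeline_config()].
#' @return A `pipeline_manifest` (list) with elements `version`,
#'   `config_hash`, `seeds`, `sets` (per set: `files`, `checksums`,
#'   `n_features`, `report`, `vif_audit` where applicable).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  out_dir <- config$out_dir %||% tempfile("flavorfuse_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- "simulate"
  manifest <- tryCatch({
    ds <- simulate_dataset(config$age_specs, seed = config$dataset_seed)

    stage <- "extract"
    etongue <- extract_etongue_features(ds$traces, labels = ds$labels)
    enose <- extract_enose_features(ds$traces, labels = ds$labels)

    stage <- "fuse"
    sets <- build_feature_sets(etongue, enose,
                               vif_threshold = config$vif_threshold,
                               sets = config$sets)

    set_entries <- list()
    for (nm in names(sets)) {
      ft <- sets[[nm]]
      stage <- paste0("project/", nm)
      pca <- pca_fit(ft, k = 2)
      lpp <- lpp_fit(ft, k = 2)
      stage <- paste0("regress/", nm)
      split <- stratified_split(ft, n_train = config$n_train,
                                n_test = config$n_test,
                                seed = config$split_seed)
      report <- evaluate_models(split$train, split$test, config$params,
                                elm_seed = config$elm_seed)
      stage <- paste0("write/", nm)
      files <- c(
        features = file.path(out_dir, paste0(nm, "_features.csv")),
        pca_scores = file.path(out_dir, paste0(nm, "_pca_scores.csv")),
        lpp_scores = file.path(out_dir, paste0(nm, "_lpp_scores.csv")),
        report = file.path(out_dir, paste0(nm, "_report.json"))
      )
      write_features_csv(ft, files[["features"]])
      write_scores_csv(pca, ft, files[["pca_scores"]])
      write_scores_csv(lpp, ft, files[["lpp_scores"]])
      jsonlite::write_json(report, files[["report"]], digits = NA,
                           dataframe = "rows", pretty = TRUE)
      audit <- attr(ft, "vif_audit")
      set_entries[[nm]] <- list(
        n_features = ncol(ft$features),
        files = as.list(files),
        checksums = as.list(unname(tools::md5sum(files))) |>
          stats::setNames(names(files)),
        report = report,
        vif_audit = if (!is.null(audit)) {
          list(removed = audit$elimination_order$feature,
               surviving = audit$surviving_features,
               max_final_vif = max(audit$final_vifs))
        }
      )
    }

    cfg_txt <- paste(deparse(config[setdiff(names(config), "out_dir")]),
                     collapse = "\n")
    cfg_file <- file.path(out_dir, "config.txt")
    writeLines(cfg_txt, cfg_file)
    structure(
      list(version = as.character(utils::packageVersion("flavorfuse")),
           config_hash = unname(tools::md5sum(cfg_file)),
           seeds = list(dataset = config$dataset_seed,
                        split = config$split_seed, elm = config$elm_seed),
           out_dir = out_dir,
           sets = set_entries),
      class = "pipeline_manifest"
    )
  }, error = function(e) {
    stopf("pipeline failed at stage '%s' (out_dir %s): %s",
          stage, out_dir, conditionMessage(e))
  })
  manifest
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat(sprintf("<pipeline_manifest> flavorfuse %s, %d feature set(s)\n",
              x$version, length(x$sets)))
  print(summarize_reports(x))
  invisible(x)
}

#' Summarize one or more run manifests as a flat comparison table
#'
#' @param ... `pipeline_manifest` objects (or a single list of them).
#' @return Data frame with columns `data_set`, `model`, `split`, `r2`,
#'   `mse` (one row per data set x model x partition).
#' @export
summarize_reports <- function(...) {
  manifests <- list(...)
  if (length(manifests) == 1 && !inherits(manifests[[1]], "pipeline_manifest")) {
    manifests <- manifests[[1]]
  }
  rows <- list()
  for (m in manifests) {
    for (nm in names(m$sets)) {
      rep <- m$sets[[nm]]$report
      if (is.null(rep) || nrow(rep) == 0) next
      rows[[length(rows) + 1L]] <- cbind(data_set = nm, rep)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(data_set = character(0), model = character(0),
                      split = character(0), r2 = numeric(0),
                      mse = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot 2-D projection scores by age class
#'
#' Convenience ggplot of PCA or LPP scores coloured by marked age. Requires
#' the ggplot2 package.
#'
#' @param result a `projection_result` with at least 2 components.
#' @param table the [feature_table()] the projection was fitted on (for
#'   age labels).
#' @return A ggplot object.
#' @export
plot_scores <- function(result, table) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stopf("plot_scores requires the ggplot2 package")
  }
  df <- data.frame(comp1 = result$scores[, 1], comp2 = result$scores[, 2],
                   age = factor(table$age_years))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$comp1, y = .data$comp2,
                                   colour = .data$age, shape = .data$age)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = paste0(toupper(result$method), "1"),
                  y = paste0(toupper(result$method), "2"),
                  colour = "age (years)", shape = "age (years)") +
    ggplot2::theme_minimal()
}
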