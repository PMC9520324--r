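#' Write / read a feature table as delimited text
#'
#' Feature tables travel as CSV with the modality encodings (`PW-1` .. `PP-4`)
#' as column names, plus `athlete_id`, `anchor_date` and `label`.
#'
#' @param table A `modal_feature_table`.
#' @param path CSV file path.
#' @param frequency Frequency tag restored on read (`"A"` or `"B"`).
#' @return The path / the table.
#' @export
write_feature_table <- function(table, path) {
  readr::write_csv(as_tibble(table), path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, frequency) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  df$label <- as.integer(df$label)
  new_modal_feature_table(df, frequency)
}

pipeline_defaults <- function() {
  list(
    seed = 1,
    cohort = list(),
    smote = list(k = 5, target_ratio = "balanced",
                 direction = "toward_neighbor"),
    model = list(),
    evaluation = list(k = 10, frequency = "A",
                      baselines = c("DC", "LR", "SVM", "KNN", "NB", "DT",
                                    "RF", "XGBoost")),
    interpretation = list(nsim = 20, edge_threshold = 0.3, max_rows = 400),
    stages = c("simulate", "featurize", "train", "evaluate", "baselines",
               "dca", "explain", "network")
  )
}

load_pipeline_config <- function(config) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) {
      abort(sprintf("Config file not found: %s", config),
            class = "lenci_io_error")
    }
    yaml::read_yaml(config)
  } else {
    config
  }
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    abort(sprintf("Unknown config key: %s", paste(unknown, collapse = ", ")),
          class = "lenci_config_error")
  }
  if (!"cohort" %in% names(cfg)) {
    abort("Missing config key: cohort", class = "lenci_config_error")
  }
  out <- utils::modifyList(defaults, cfg)
  bad_cohort <- setdiff(names(out$cohort), names(formals(cohort_config)))
  if (length(bad_cohort)) {
    abort(sprintf("Unknown config key: cohort$%s",
                  paste(bad_cohort, collapse = ", ")),
          class = "lenci_config_error")
  }
  out
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates simulate -> featurize (A and B) -> train (weekly fusion, then
#' the daily substitution) -> evaluate (stratified CV of the fusion recipe) ->
#' baselines -> decision-curve analysis -> explain (submodel and feature
#' weights) -> network, writing every artefact as delimited text or JSON under
#' `out_dir` and returning a manifest with a content hash per file. Stages can
#' be re-run selectively; later stages load earlier artefacts from `out_dir`.
#'
#' @param config Path to a YAML file or a named list. Sections: `seed`,
#'   `cohort` (arguments of [cohort_config()]; required), `smote`, `model`
#'   (arguments of [fusion_params()]), `evaluation` (`k`, `frequency`,
#'   `baselines`), `interpretation` (`nsim`, `edge_threshold`, `max_rows`),
#'   `stages`.
#' @param out_dir Output directory.
#' @param seed Overrides the config seed.
#' @param stages Overrides the config's stage list.
#' @return A `run_manifest` tibble: stage, file, md5 hash, with timing and
#'   config snapshot attributes.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, stages = NULL) {
  cfg <- load_pipeline_config(config)
  seed <- as.integer(seed %||% cfg$seed)
  stages <- stages %||% cfg$stages
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  t0 <- Sys.time()
  written <- list()
  note <- function(stage, files) {
    written[[length(written) + 1]] <<- tibble(stage = stage, file = files)
  }
  path <- function(...) file.path(out_dir, ...)

  ccfg <- do.call(cohort_config, cfg$cohort)
  params <- do.call(fusion_params, c(cfg$model, list(seed = seed)))
  scfg <- do.call(smote_config, c(cfg$smote, list(seed = seed)))

  if ("simulate" %in% stages) {
    cohort <- generate_cohort(ccfg, seed = seed)
    note("simulate", write_cohort(cohort, path("cohort")))
  } else {
    cohort <- read_cohort(path("cohort"))
  }

  if ("featurize" %in% stages) {
    table_a <- assemble_dataset(cohort, "A")
    table_b <- assemble_dataset(cohort, "B")
    note("featurize", c(
      write_feature_table(table_a, path("dataset_A.csv")),
      write_feature_table(table_b, path("dataset_B.csv"))
    ))
  } else {
    table_a <- read_feature_table(path("dataset_A.csv"), "A")
    table_b <- read_feature_table(path("dataset_B.csv"), "B")
  }

  if ("train" %in% stages) {
    wfusion <- build_wfusion(table_a, params)
    dfusion <- build_dfusion(wfusion, table_b)
    save_fusion(wfusion, path("wfusion"))
    save_fusion(dfusion, path("dfusion"))
    note("train", c(list.files(path("wfusion"), full.names = TRUE),
                    list.files(path("dfusion"), full.names = TRUE)))
  } else {
    dfusion <- load_fusion(path("dfusion"))
  }

  eval_table <- if (cfg$evaluation$frequency == "B") table_b else table_a
  if ("evaluate" %in% stages) {
    cv <- cross_validate(recipe_fusion(params), eval_table,
                         k = cfg$evaluation$k, smote = scfg, seed = seed)
    readr::write_csv(cv$folds, path("cv_folds.csv"))
    jsonlite::write_json(list(model = cv$model, k = cv$k,
                              summary = cv$summary),
                         path("cv_summary.json"), auto_unbox = TRUE,
                         digits = NA)
    note("evaluate", path(c("cv_folds.csv", "cv_summary.json")))
  }

  if ("baselines" %in% stages) {
    bl <- integration_baselines(eval_table,
                                classifiers = cfg$evaluation$baselines,
                                k = cfg$evaluation$k, smote = scfg,
                                seed = seed)
    readr::write_csv(bl, path("baselines.csv"))
    note("baselines", path("baselines.csv"))
  }

  if ("dca" %in% stages) {
    curve <- dca_curve(dfusion, table_b)
    readr::write_csv(as_tibble(curve), path("dca_curve.csv"))
    note("dca", path("dca_curve.csv"))
  }

  explain_rows <- utils::head(table_b, cfg$interpretation$max_rows)
  if ("explain" %in% stages) {
    sw <- submodel_weights(dfusion, explain_rows,
                           nsim = cfg$interpretation$nsim, seed = seed)
    readr::write_csv(as_tibble(sw), path("submodel_weights.csv"))
    fw <- purrr::map_dfr(names(MODALITIES), function(m) {
      sh <- submodel_shap(dfusion$submodels[[m]], explain_rows)
      purrr::map_dfr(names(sh), function(cl) {
        mutate(mean_abs_shap(sh[[cl]]), class = cl, submodel = m)
      })
    })
    readr::write_csv(fw, path("feature_weights.csv"))
    note("explain", path(c("submodel_weights.csv", "feature_weights.csv")))
  }

  if ("network" %in% stages) {
    shap_by_class <- class_shap_matrices(dfusion, explain_rows)
    files <- character()
    for (cl in names(shap_by_class)) {
      if (nrow(shap_by_class[[cl]]) < 3) next
      net <- build_network(shap_by_class, cl, reference_class = "0",
                           edge_threshold = cfg$interpretation$edge_threshold)
      fn <- path(sprintf("network_class%s", cl))
      readr::write_csv(net$nodes, paste0(fn, "_nodes.csv"))
      readr::write_csv(net$edges, paste0(fn, "_edges.csv"))
      write_network_graphml(net, paste0(fn, ".graphml"))
      files <- c(files, paste0(fn, c("_nodes.csv", "_edges.csv", ".graphml")))
    }
    note("network", files)
  }

  files <- bind_rows(written)
  manifest <- mutate(files,
                     md5 = unname(tools::md5sum(.data$file)))
  manifest <- structure(manifest, class = c("run_manifest", class(manifest)),
                        config = cfg, seed = seed,
                        elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                        units = "secs")),
                        package_version =
                          as.character(utils::packageVersion("lencifusion")))
  jsonlite::write_json(
    list(seed = seed, elapsed_s = attr(manifest, "elapsed_s"),
         package_version = attr(manifest, "package_version"),
         files = manifest),
    path("manifest.json"), auto_unbox = TRUE, digits = NA)
  manifest
}

#' Per-class SHAP matrices over all monitoring features
#'
#' For each realised severity class, the class-slice SHAP values of the rows
#' truly in that class, concatenated across the four submodels into one
#' samples x 18-features matrix — the input of [build_network()].
#'
#' @param model A `fusion_model`.
#' @param table Feature table with a `label` column.
#' @return Named list of samples x features matrices, one per class present.
#' @export
class_shap_matrices <- function(model, table) {
  shap <- lapply(names(MODALITIES), function(m) {
    submodel_shap(model$submodels[[m]], table)
  })
  out <- list()
  for (cl in as.character(model$classes)) {
    rows <- which(table$label == as.integer(cl))
    if (!length(rows)) next
    out[[cl]] <- do.call(cbind, lapply(shap, function(s) {
      s[[cl]][rows, , drop = FALSE]
    }))
  }
  out
}
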