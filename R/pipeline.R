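# Orchestration: one configured, seeded, logged run of
# synth -> quantify -> classify -> screen -> stats.

#' Default pipeline configuration
#'
#' @param seed Top-level seed; every stage derives its own seed from it.
#' @param n_clones,n_planted,planted_penetrance,n_animals Screen design.
#' @param method Measurement method for the screen (`"top5"` is the
#'   screen-stage protocol).
#' @param k Visibility constant (dispersions above background median).
#' @param f Top-fraction excluded in the beta-cell fate correction.
#' @return A named list usable by [run_pipeline()], serializable to YAML.
#' @export
pipeline_config <- function(seed = 1, n_clones = 4, n_planted = 1,
                            planted_penetrance = 0.9, n_animals = 20,
                            method = "top5", k = 5, f = 0.1) {
  list(seed = seed, n_clones = n_clones, n_planted = n_planted,
       planted_penetrance = planted_penetrance, n_animals = n_animals,
       method = method, k = k, f = f)
}

validate_config <- function(config) {
  req <- c("seed", "n_clones", "n_planted", "planted_penetrance",
           "n_animals", "method", "k", "f")
  missing <- setdiff(req, names(config))
  if (length(missing)) stop("config fields missing: ", paste(missing, collapse = ", "))
  if (config$f < 0 || config$f >= 1) stop("f must be in [0, 1)")
  if (config$planted_penetrance < 0 || config$planted_penetrance > 1) {
    stop("planted_penetrance must be in [0, 1]")
  }
  if (!config$method %in% c("top5", "sumproj_bgcorr")) {
    stop("method must be 'top5' or 'sumproj_bgcorr'")
  }
  invisible(config)
}

#' Run the full analysis pipeline
#'
#' Generates a synthetic screen dataset, names cells, fits the AC-like
#' threshold on negative-control ACs, runs the screen hit calling, compares
#' conditions with Mann-Whitney U tests, and writes all artifacts (per-cell
#' CSV, per-clone CSV, threshold JSON, screen summary JSON, stats CSV, the
#' archived config with its hash, and a MANIFEST). Deterministic given
#' `config$seed`. On a stage failure the partial outputs are retained and
#' the MANIFEST records the failed stage.
#'
#' @param config A configuration list (see [pipeline_config()]), or a path
#'   to a YAML file holding one.
#' @param out_dir Output directory.
#' @return The output directory path, invisibly; the loaded results as the
#'   attribute `"results"`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  config_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, config_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("acvu")),
    r_version = R.version.string,
    config_md5 = unname(tools::md5sum(config_path)),
    stages = character()
  )
  write_manifest <- function(failed = NULL) {
    if (!is.null(failed)) manifest$failed_stage <<- failed
    jsonlite::write_json(manifest, file.path(out_dir, "MANIFEST.json"),
                         auto_unbox = TRUE)
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      write_manifest(failed = name)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages <<- c(manifest$stages, name)
    res
  }

  dataset <- stage("synth+quantify", {
    design <- screen_design(
      n_clones = config$n_clones, n_planted = config$n_planted,
      planted_penetrance = config$planted_penetrance,
      n_animals = config$n_animals
    )
    make_screen_dataset(design, seed = config$seed)
  })

  cells <- stage("classify", {
    cells <- name_cells(dataset$cells)
    ctrl_ac <- cells$gfp_value[cells$type == "negative_control" &
                                 cells$role == "alpha1" & !cells$excluded]
    model <- fit_ac_threshold(ctrl_ac)
    jsonlite::write_json(unclass(model),
                         file.path(out_dir, "threshold.json"),
                         auto_unbox = TRUE, digits = NA)
    cells$ac_like <- cells$gfp_value > model$threshold
    cells
  })

  report <- stage("screen", run_screen(dataset, k = config$k))

  stats_tbl <- stage("stats", {
    ctrl <- cells$gfp_value[cells$type == "negative_control" &
                              cells$role == "alpha2" & !cells$excluded]
    purrr::map_dfr(
      unique(cells$clone_id[cells$type == "experimental"]),
      function(cl) {
        trt <- cells$gfp_value[cells$clone_id == cl &
                                 cells$role == "alpha2" & !cells$excluded]
        if (length(trt) < 2) return(NULL)
        res <- mann_whitney_u(trt, ctrl, mode = "auto")
        res$comparison <- paste0(cl, " vs lacZ (alpha2)")
        res
      }
    )
  })

  stage("report", {
    out_cells <- dplyr::select(cells, -dplyr::any_of("n_per_group"))
    write_report(out_cells, report$clones, out_dir,
                 summary = list(
                   seed = config$seed,
                   n_hits = sum(report$clones$hit),
                   rounds_valid = sum(report$qc$round_valid)
                 ))
    if (nrow(stats_tbl)) {
      readr::write_csv(
        dplyr::select(stats_tbl, "comparison", "method", "statistic", "p_value"),
        file.path(out_dir, "stats.csv")
      )
    }
  })
  write_manifest()

  res <- list(dataset = dataset, cells = cells, report = report,
              stats = stats_tbl)
  invisible(structure(out_dir, results = res))
}

#' @rdname run_pipeline
#' @export
run_all <- run_pipeline
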