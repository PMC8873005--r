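#' Run the full phenotyping pipeline from a config
#'
#' Orchestrates the study's analysis order: (optionally) simulate a
#' labelled cohort, extract per-cell features from every recording,
#' aggregate them into the feature table, compare genotypes per measure
#' and week, and write the report. Deterministic given the config and
#' its seeds; per-cell failures are caught, flagged in the QC column and
#' the run continues.
#'
#' @param config A named list, or the path of a YAML or JSON document,
#'   with blocks:
#'   \describe{
#'     \item{simulate}{`n_per_condition`, `weeks`, `seed`, `noise_sd` --
#'       cohort simulation (see [cohort_spec()]).}
#'     \item{input}{alternatively, `dir`: a directory of sweep-set files
#'       written by [write_sweep_set()].}
#'     \item{protocols}{`gap_free_duration_s`, `gap_free_fs` overrides.}
#'     \item{output}{`dir` (required); tables are TSV, the report JSON.}
#'   }
#' @param quiet Suppress stage-timing messages.
#'
#' @return Invisibly, a list: `features`, `trajectory` (tibbles) and
#'   `paths` of the written artifacts.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop("config must be a list or a file path", call. = FALSE)
  if (is.null(config$output$dir)) stop("config$output$dir is required", call. = FALSE)
  if (is.null(config$simulate) && is.null(config$input)) {
    stop("config needs a 'simulate' or an 'input' block", call. = FALSE)
  }
  if (!is.null(config$simulate)) {
    n <- config$simulate$n_per_condition %||% 0
    if (n < 1) stop("validation: simulate.n_per_condition must be >= 1", call. = FALSE)
  }
  out_dir <- config$output$dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    say("[%s] %.1f s", stage, timings[[stage]])
    res
  }

  features <- clock("extract", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      spec <- cohort_spec(
        n_per_condition = sim$n_per_condition,
        weeks = sim$weeks %||% c(5, 7, 11),
        seed = sim$seed %||% 1,
        noise_sd = sim$noise_sd %||% 2
      )
      gp <- gapfree_protocol(
        duration_s = config$protocols$gap_free_duration_s %||% 120,
        fs = config$protocols$gap_free_fs %||% 5000
      )
      gt <- draw_cohort(spec)
      feats <- purrr::map_dfr(seq_len(nrow(gt)), function(i) {
        tryCatch({
          rec <- simulate_cell(gt[i, ], spec$noise_sd, gap_proto = gp)
          extract_cell_features(cc = rec$cc, vc = rec$vc, syn = rec$syn,
                                cell_id = gt$cell_id[i],
                                genotype = gt$genotype[i], week = gt$week[i])
        }, error = function(e) {
          warning("cell ", gt$cell_id[i], " failed in extract: ",
                  conditionMessage(e), call. = FALSE)
          tibble::tibble(cell_id = gt$cell_id[i], genotype = gt$genotype[i],
                         week = gt$week[i],
                         qc = list(paste0("stage_error:extract:",
                                          conditionMessage(e))))
        })
      })
      attr(feats, "ground_truth") <- gt
      feats
    } else {
      files <- list.files(config$input$dir, pattern = "\\.json$",
                          full.names = TRUE)
      if (length(files) == 0) stop("validation: no trace files in input dir", call. = FALSE)
      sets <- lapply(files, read_sweep_set)
      ids <- unique(vapply(sets, function(s) s$cell_id, character(1)))
      purrr::map_dfr(ids, function(id) {
        mine <- sets[vapply(sets, function(s) s$cell_id == id, logical(1))]
        modes <- vapply(mine, function(s) s$protocol$mode, character(1))
        first_or_null <- function(lst) if (length(lst) > 0) lst[[1]] else NULL
        tryCatch(
          extract_cell_features(
            cc = first_or_null(mine[modes == "current_clamp_steps"]),
            vc = first_or_null(mine[modes == "voltage_clamp_steps"]),
            syn = if (any(modes == "gap_free")) {
              mine[modes == "gap_free"][[1]]$traces[[1]]
            } else NULL,
            cell_id = id),
          error = function(e) {
            warning("cell ", id, " failed in extract: ", conditionMessage(e),
                    call. = FALSE)
            tibble::tibble(cell_id = id,
                           qc = list(paste0("stage_error:extract:",
                                            conditionMessage(e))))
          })
      })
    }
  })

  trajectory <- clock("compare", {
    if (length(unique(features$genotype[!is.na(features$genotype)])) >= 2) {
      trajectory_table(features)
    } else NULL
  })

  paths <- clock("report", {
    p <- list(features = file.path(out_dir, "features.tsv"),
              report = file.path(out_dir, "report.json"))
    write_features(features, p$features)
    gt <- attr(features, "ground_truth")
    if (!is.null(gt)) {
      p$ground_truth <- file.path(out_dir, "ground_truth.tsv")
      readr::write_tsv(gt, p$ground_truth)
    }
    if (!is.null(trajectory)) {
      p$trajectory <- file.path(out_dir, "trajectory.tsv")
      readr::write_tsv(as.data.frame(trajectory), p$trajectory)
    }
    counts <- NULL
    if (!is.null(trajectory)) {
      counts <- trajectory[, c("week", "measure", "n_a", "n_b")]
    }
    report <- list(
      package_version = as.character(utils::packageVersion("clampkit")),
      config_hash = rlang::hash(config),
      seed = config$simulate$seed %||% NA,
      n_cells = nrow(features),
      qc_flags = table(unlist(features$qc)),
      group_sizes = counts,
      timings_s = timings
    )
    jsonlite::write_json(report, p$report, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    p
  })
  invisible(list(features = features, trajectory = trajectory, paths = paths))
}
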