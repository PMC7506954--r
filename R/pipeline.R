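# End-to-end pipeline: simulate -> features -> select -> evaluate ->
# report. All randomness flows from the generator config's seed, so a
# full run is reproducible byte for byte.

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates a cohort, extracts the 538-feature matrix, then for every
#' requested problem x feature-set cell runs adaptive floating feature
#' selection once (pooled mode) and evaluates the requested classifiers by
#' leave-participant-out cross-validation. When `out_dir` is given, the
#' feature matrix (CSV), per-cell selection results (JSON) and the report
#' (JSON) are written there; re-running with the same configuration
#' reproduces the files byte for byte.
#'
#' @param n_participants Cohort size (default 10).
#' @param cfg A [generator_config()]; its `seed` drives the whole run.
#' @param problems Problem ids to evaluate.
#' @param feature_sets Feature sets to evaluate.
#' @param classifiers Classifiers to evaluate per cell.
#' @param selection_mode `"pooled"` (selection before CV, default) or
#'   `"per_fold"`.
#' @param out_dir Optional output directory.
#' @return List of class `pipeline_run`: the cohort `config`, `features`,
#'   `results` (list of [lopo_cv()] results) and `report`
#'   ([pipeline_report()]).
#' @export
run_pipeline <- function(n_participants = 10,
                         cfg = generator_config(),
                         problems = c("P1", "P2", "P3", "P4", "P5"),
                         feature_sets = c("inertial", "emg", "both"),
                         classifiers = CLASSIFIERS,
                         selection_mode = "pooled",
                         out_dir = NULL) {
  cohort <- generate_cohort(n_participants, cfg)
  features <- cohort_features(cohort)
  results <- list()
  for (pr in problems) {
    for (fs in feature_sets) {
      sel <- NULL
      for (cl in classifiers) {
        res <- lopo_cv(features, pr, fs, cl,
          selection_mode = selection_mode,
          selection = sel, seed = cfg$seed
        )
        if (selection_mode == "pooled") sel <- res$selection
        results[[paste(pr, fs, cl, sep = "_")]] <- res
      }
    }
  }
  report <- pipeline_report(results)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_matrix(features, file.path(out_dir, "features.csv"))
    for (pr in problems) {
      for (fs in feature_sets) {
        res <- results[[paste(pr, fs, classifiers[1], sep = "_")]]
        if (res$selection_mode == "pooled") {
          write_selection_json(
            res$selection,
            file.path(out_dir, paste0("selection_", pr, "_", fs, ".json"))
          )
        }
      }
    }
    write_report_json(report, file.path(out_dir, "report.json"))
  }
  structure(
    list(config = cfg, features = features, results = results, report = report),
    class = "pipeline_run"
  )
}

#' Summarize cross-validation results
#'
#' Builds (a) the full grid of evaluated cells (problem, feature set,
#' classifier, number of selected features, mean accuracy), (b) a
#' condensed one-row-per-problem table using the conventional
#' classifier-per-feature-set choice (the regression-rounded classifier
#' for inertial and combined features, the linear SVM for EMG-only, the
#' sets on which those classifiers perform best), and (c) the top-5
#' selected features per problem in inclusion order.
#'
#' @param results List of `cv_result` objects ([lopo_cv()]).
#' @return List of class `pipeline_report` with `cells`, `summary` and
#'   `top_features`.
#' @export
pipeline_report <- function(results) {
  if (length(results) == 0) {
    return(structure(
      list(
        cells = data.frame(
          problem = character(0), feature_set = character(0),
          classifier = character(0), n_selected = integer(0),
          mean_accuracy = numeric(0)
        ),
        summary = data.frame(), top_features = list()
      ),
      class = "pipeline_report"
    ))
  }
  n_sel <- function(r) {
    if (r$selection_mode == "pooled") {
      length(r$selection$selected)
    } else {
      round(mean(vapply(r$selection, function(s) length(s$selected), numeric(1))))
    }
  }
  cells <- do.call(rbind, lapply(unname(results), function(r) {
    data.frame(
      problem = r$problem_id, feature_set = r$feature_set,
      classifier = r$classifier, n_selected = n_sel(r),
      mean_accuracy = r$mean_accuracy
    )
  }))
  convention <- c(inertial = "REG", emg = "SVM", both = "REG")
  problems <- unique(cells$problem)
  summary_rows <- list()
  for (pr in problems) {
    row <- list(problem = pr)
    for (fs in c("inertial", "emg", "both")) {
      hit <- cells$problem == pr & cells$feature_set == fs &
        cells$classifier == convention[[fs]]
      row[[paste0(fs, "_n")]] <- if (any(hit)) cells$n_selected[hit][1] else NA_integer_
      row[[paste0(fs, "_accuracy")]] <- if (any(hit)) cells$mean_accuracy[hit][1] else NA_real_
    }
    summary_rows[[pr]] <- as.data.frame(row)
  }
  top_features <- list()
  for (pr in problems) {
    pick <- NULL
    for (fs in c("both", "inertial", "emg")) {
      idx <- which(vapply(results, function(r) {
        r$problem_id == pr && r$feature_set == fs && r$selection_mode == "pooled"
      }, logical(1)))
      if (length(idx)) {
        pick <- results[[idx[1]]]$selection
        break
      }
    }
    if (!is.null(pick)) top_features[[pr]] <- utils::head(pick$selected, 5)
  }
  structure(
    list(
      cells = cells,
      summary = do.call(rbind, summary_rows),
      top_features = top_features
    ),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Leave-participant-out classification accuracy (%)\n")
  if (nrow(x$cells) == 0) {
    cat(" (no results)\n")
    return(invisible(x))
  }
  if (!is.null(x$summary) && nrow(x$summary) > 0) {
    df <- x$summary
    for (fs in c("inertial", "emg", "both")) {
      a <- df[[paste0(fs, "_accuracy")]]
      n <- df[[paste0(fs, "_n")]]
      df[[fs]] <- ifelse(is.na(a), "-", sprintf("%d, %.1f%%", n, a))
      df[[paste0(fs, "_n")]] <- NULL
      df[[paste0(fs, "_accuracy")]] <- NULL
    }
    print(df, row.names = FALSE)
  }
  if (length(x$top_features)) {
    cat("\nTop selected features (inclusion order):\n")
    for (pr in names(x$top_features)) {
      cat(" ", pr, ": ", paste(x$top_features[[pr]], collapse = "; "), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' @param report A `pipeline_report`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  doc <- list(
    format_version = "1.0",
    cells = report$cells,
    summary = report$summary,
    top_features = report$top_features
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
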