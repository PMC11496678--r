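#' Default pipeline run configuration
#'
#' A flat, YAML-serializable list of stage parameters covering simulation,
#' segmentation, cleaning, vertex detection, statistics and the classifier.
#' Unknown keys passed in `...` are rejected.
#'
#' @param ... named overrides of the default values.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1,
    # simulate
    n_cases_per_grade = 6, beats_per_case = 30, noise_sd = 0.3,
    artifact_rate = 0.1, sampling_rate = 250, mean_rr = 0.8,
    # clean
    kshape_k = 2, minority_frac = 0.2, mad_mult = 5,
    # vertices
    smooth = TRUE, smooth_width = 11,
    # stats
    alpha = 0.05,
    # classifier
    classifier = FALSE, n_blocks = 1, n_heads = 2, head_size = 16,
    epochs = 10, batch_size = 128, learning_rate = 1e-3,
    train_fraction = 0.6
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = c("run_config", "list"))
}

#' Write / read a run configuration as YAML
#' @param config a [run_config()] list.
#' @param path file path.
#' @return `read_run_config` returns the `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the analysis pipeline end to end
#'
#' Executes simulate -> segment -> clean -> vertices -> indices -> stats
#' (and optionally train -> explain) and writes every stage result as CSV/JSON
#' into `out_dir`, together with the serialized configuration. All stages are
#' seeded from `config$seed`, so a rerun with the same config reproduces the
#' deterministic outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param cohort optionally, an existing `cvp_cohort` to analyse instead of
#'   simulating one.
#' @param stages character vector prefix of
#'   c("simulate","segment","clean","vertices","indices","stats","train","explain").
#' @return invisibly, a list with the stage results.
#' @export
run_pipeline <- function(config = run_config(), out_dir, cohort = NULL,
                         stages = c("simulate", "segment", "clean", "vertices",
                                    "indices", "stats")) {
  all_stages <- c("simulate", "segment", "clean", "vertices", "indices",
                  "stats", "train", "explain")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_run_config(config, file.path(out_dir, "run_config.yaml"))
  res <- list()
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  if (is.null(cohort) && "simulate" %in% stages) {
    cohort <- step("simulate", generate_cohort(sim_config(
      n_cases_per_grade = config$n_cases_per_grade,
      beats_per_case = config$beats_per_case, noise_sd = config$noise_sd,
      artifact_rate = config$artifact_rate, sampling_rate = config$sampling_rate,
      mean_rr = config$mean_rr, seed = config$seed
    )))
    write_cohort(cohort, file.path(out_dir, "cohort"))
  }
  res$cohort <- cohort
  if (!"segment" %in% stages) return(invisible(res))
  beats <- step("segment", segment_beats(cohort))
  readr::write_csv(beats$info[, c("case_id", "beat_index", "window_start_s",
                                  "window_end_s")],
                   file.path(out_dir, "beats.csv"))
  res$beats <- beats
  if ("clean" %in% stages) {
    cleaning <- step("clean", clean_beats(beats, k = config$kshape_k,
                                          seed = config$seed,
                                          minority_frac = config$minority_frac,
                                          mad_mult = config$mad_mult))
    readr::write_csv(cleaning, file.path(out_dir, "cleaning.csv"))
    beats <- drop_artifacts(beats, cleaning)
    res$cleaning <- cleaning; res$clean_beats <- beats
  }
  if (!"vertices" %in% stages) return(invisible(res))
  vertices <- step("vertices", detect_vertices(beats, smooth = config$smooth,
                                               smooth_width = config$smooth_width))
  readr::write_csv(vertices, file.path(out_dir, "vertices.csv"))
  res$vertices <- vertices
  if (!"indices" %in% stages) return(invisible(res))
  indices <- step("indices", compute_indices(vertices, cohort$cases))
  readr::write_csv(indices$cases, file.path(out_dir, "indices.csv"))
  res$indices <- indices
  if ("stats" %in% stages) {
    stats_res <- step("stats", index_statistics(indices, alpha = config$alpha))
    readr::write_csv(stats_res$trend, file.path(out_dir, "trend_tests.csv"))
    if (length(stats_res$pairwise)) {
      pw <- dplyr::bind_rows(stats_res$pairwise, .id = "index")
      readr::write_csv(pw, file.path(out_dir, "pairwise_tests.csv"))
    }
    if (length(stats_res$roc)) {
      roc_tab <- dplyr::bind_rows(lapply(names(stats_res$roc), function(nm) {
        r <- stats_res$roc[[nm]]
        tibble::tibble(index = nm, auc = r$auc, ci_lower = r$ci[1],
                       ci_upper = r$ci[2], cutoff = r$cutoff,
                       sensitivity = r$sensitivity, specificity = r$specificity)
      }))
      readr::write_csv(roc_tab, file.path(out_dir, "roc.csv"))
    }
    res$stats <- stats_res
  }
  if ("train" %in% stages) {
    res$training <- step("train", pipeline_train(cohort, beats, config, out_dir))
    if ("explain" %in% stages && !is.null(res$training)) {
      sal <- step("explain", explain_beats(res$training$fit$model,
                                           res$training$x_val[seq_len(min(20, nrow(res$training$x_val))), ,
                                                              drop = FALSE]))
      readr::write_csv(tibble::as_tibble(sal, .name_repair = "minimal"),
                       file.path(out_dir, "saliency.csv"))
      res$saliency <- sal
    }
  }
  invisible(res)
}

# Train the none-vs-severe classifier on the cleaned beats of a cohort.
pipeline_train <- function(cohort, beats, config, out_dir) {
  keep_cases <- cohort$cases$case_id[cohort$cases$tr_grade %in% c("none", "severe")]
  sel <- beats$info$case_id %in% keep_cases
  if (!any(sel)) stop("no beats in the none/severe classes")
  x <- beats$norm[sel, , drop = FALSE]
  cid <- beats$info$case_id[sel]
  grade <- cohort$cases$tr_grade[match(cid, cohort$cases$case_id)]
  ylab <- factor(ifelse(grade == "severe", "severe", "none"),
                 levels = c("none", "severe"))
  case_tab <- unique(tibble::tibble(case_id = cid,
                                    label = as.character(ylab)))
  manifest <- split_cases(case_tab$case_id, case_tab$label,
                          train_fraction = config$train_fraction,
                          seed = config$seed)
  readr::write_csv(tibble::as_tibble(manifest),
                   file.path(out_dir, "split_manifest.csv"))
  ccfg <- classifier_config(n_blocks = config$n_blocks, n_heads = config$n_heads,
                            head_size = config$head_size, epochs = config$epochs,
                            batch_size = config$batch_size,
                            learning_rate = config$learning_rate,
                            train_fraction = config$train_fraction,
                            seed = config$seed)
  fit <- train_and_evaluate(x, ylab, cid, manifest, ccfg)
  jsonlite::write_json(
    list(accuracy = fit$accuracy,
         confusion = as.data.frame(fit$confusion),
         loss_history = fit$loss_history),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  va <- manifest$case_id[manifest$split == "validation"]
  list(fit = fit, manifest = manifest,
       x_val = x[cid %in% va, , drop = FALSE])
}
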