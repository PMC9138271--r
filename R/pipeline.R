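#' Default end-to-end run configuration
#'
#' Master configuration for [run_pipeline()]. Per-stage sub-seeds are derived
#' from the master seed as `seed * 100 + stage index` (simulate = 1,
#' preprocess = 2, mi = 3, score_resp = 4, classify = 5, predict = 6,
#' controls = 7), so stages are independently reproducible.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param n_low,n_high Cohort group sizes.
#' @param night_min Minutes of EEG per subject.
#' @param stages Named logical toggles for the pipeline stages.
#' @param ica Whether to run ICA artifact removal during preprocessing.
#' @param resp_signals Whether to synthesize and score respiratory channels.
#' @return A named list (class `run_config`).
#' @export
run_config <- function(out_dir = tempfile("pacsleep_run_"), seed = 1,
                       n_low = 42, n_high = 44, night_min = 10,
                       stages = c(simulate = TRUE, preprocess = TRUE,
                                  mi = TRUE, score_resp = FALSE,
                                  classify = TRUE, predict = TRUE,
                                  controls = TRUE),
                       ica = FALSE, resp_signals = FALSE) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), n_low = n_low,
              n_high = n_high, night_min = night_min,
              stages = stages, ica = ica, resp_signals = resp_signals)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  needed <- c("out_dir", "seed", "n_low", "n_high", "night_min", "stages")
  miss <- setdiff(needed, names(cfg))
  if (length(miss)) stop("config missing field(s): ", paste(miss, collapse = ", "))
  known <- c("simulate", "preprocess", "mi", "score_resp", "classify",
             "predict", "controls")
  if (!all(names(cfg$stages) %in% known)) stop("unknown stage toggle")
  deps <- list(preprocess = "simulate", mi = "preprocess",
               score_resp = "simulate", classify = "mi", predict = "mi",
               controls = "mi")
  on <- names(cfg$stages)[cfg$stages]
  for (s in on) {
    d <- deps[[s]]
    if (!is.null(d) && !(d %in% on)) {
      stop("stage '", s, "' requires stage '", d, "' to be enabled")
    }
  }
  invisible(cfg)
}

#' Load a run configuration from YAML
#' @param path YAML file with [run_config()] fields.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

stage_seed <- function(cfg, stage) {
  idx <- match(stage, c("simulate", "preprocess", "mi", "score_resp",
                        "classify", "predict", "controls"))
  cfg$seed * 100L + idx
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order — simulate a cohort,
#' preprocess EEG, compute stage MI, score respiratory events, classify
#' stages, predict clinical scores, run control statistics — writing
#' per-stage CSV/JSON outputs and a manifest (package version, configuration,
#' derived seeds) to the output directory. Re-running with the same
#' configuration reproduces the outputs.
#'
#' @param cfg A `run_config`.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(cfg = run_config()) {
  validate_run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  on <- function(s) isTRUE(cfg$stages[[s]])
  res <- list()
  wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (on("simulate")) {
    res$cohort <- wrap("simulate", generate_cohort(cohort_spec(
      n_low = cfg$n_low, n_high = cfg$n_high, night_min = cfg$night_min,
      target_rdi_signals = isTRUE(cfg$resp_signals),
      seed = stage_seed(cfg, "simulate"))))
    utils::write.csv(res$cohort$subjects,
                     file.path(cfg$out_dir, "subjects.csv"), row.names = FALSE)
  }

  if (on("preprocess")) {
    res$decomps <- wrap("preprocess", lapply(seq_along(res$cohort$recordings),
      function(i) {
        rec <- antialias_and_detrend(res$cohort$recordings[[i]])
        if (isTRUE(cfg$ica)) {
          rec <- remove_artifact_components(
            rec, seed = stage_seed(cfg, "preprocess"))$recording
        }
        split_bands(rec)
      }))
    names(res$decomps) <- res$cohort$subjects$id
  }

  if (on("mi")) {
    res$stage_mi <- wrap("mi", {
      out <- lapply(names(res$decomps), function(id) {
        stage_mi(res$decomps[[id]], res$cohort$hypnograms[[id]])
      })
      stats::setNames(out, names(res$decomps))
    })
    tab <- do.call(rbind, lapply(names(res$stage_mi), function(id) {
      cbind(subject = id, res$stage_mi[[id]])
    }))
    utils::write.csv(tab, file.path(cfg$out_dir, "stage_mi.csv"),
                     row.names = FALSE)
  }

  if (on("score_resp")) {
    res$events <- wrap("score_resp", {
      lapply(names(res$cohort$resp), function(id) {
        rb <- res$cohort$resp[[id]]
        ev <- score_events(rb$airflow, rb$fs_air, rb$spo2, rb$fs_spo2,
                           rb$arousals, res$cohort$hypnograms[[id]])
        rdi <- compute_rdi(ev, res$cohort$hypnograms[[id]])
        list(events = ev, rdi = rdi)
      })
    })
    names(res$events) <- names(res$cohort$resp)
    ev_tab <- do.call(rbind, lapply(names(res$events), function(id) {
      ev <- res$events[[id]]$events
      if (nrow(ev)) cbind(subject = id, ev)
    }))
    utils::write.csv(ev_tab, file.path(cfg$out_dir, "events.csv"),
                     row.names = FALSE)
  }

  sfeat <- NULL
  if (on("classify") || on("predict") || on("controls")) {
    sfeat <- subject_feature_table(res$stage_mi, res$cohort$subjects)
  }

  if (on("classify")) {
    res$classification <- wrap("classify", {
      wf <- do.call(rbind, lapply(names(res$decomps), function(id) {
        window_feature_table(res$decomps[[id]], res$cohort$hypnograms[[id]])
      }))
      classify_stages(wf, seed = stage_seed(cfg, "classify"))
    })
    jsonlite::write_json(
      list(accuracy = res$classification$accuracy,
           mean_accuracy = res$classification$mean_accuracy,
           confusion = as.data.frame.matrix(res$classification$confusion)),
      file.path(cfg$out_dir, "classification.json"), auto_unbox = TRUE,
      digits = NA)
  }

  if (on("predict")) {
    res$prediction <- wrap("predict", {
      thr <- accuracy_threshold(
        unlist(lapply(res$stage_mi, function(s) s$mi)))
      list(rdi = predict_clinical(sfeat, "rdi",
                                  seed = stage_seed(cfg, "predict")),
           ess = predict_clinical(sfeat, "ess",
                                  seed = stage_seed(cfg, "predict") + 50L),
           threshold = thr)
    })
    jsonlite::write_json(
      list(rdi_accuracy = res$prediction$rdi$accuracy,
           ess_accuracy = res$prediction$ess$accuracy,
           threshold = res$prediction$threshold),
      file.path(cfg$out_dir, "prediction.json"), auto_unbox = TRUE,
      digits = NA)
  }

  if (on("controls")) {
    res$controls <- wrap("controls", {
      corr <- control_correlations(sfeat)
      tg_n1 <- grep("^mi\\.theta-gamma\\.N1$", names(sfeat), value = TRUE)
      post <- if (length(tg_n1) == 1) {
        g <- sfeat$group == unique(sfeat$group[sfeat$rdi <= 15])
        bayesian_group_posterior(sfeat[[tg_n1]][g], sfeat[[tg_n1]][!g],
                                 seed = stage_seed(cfg, "controls"))
      }
      list(correlations = corr, posterior = post)
    })
    jsonlite::write_json(
      list(correlations = res$controls$correlations,
           hdi = as.list(res$controls$posterior$hdi),
           sufficient_sample =
             unname(res$controls$posterior$sufficient_sample)),
      file.path(cfg$out_dir, "controls.json"), auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package = "pacsleep",
    version = as.character(utils::packageVersion("pacsleep")),
    seed = cfg$seed,
    stage_seeds = stats::setNames(
      lapply(names(cfg$stages)[cfg$stages], function(s) stage_seed(cfg, s)),
      names(cfg$stages)[cfg$stages]),
    config = cfg[setdiff(names(cfg), "out_dir")])
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
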