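#' Configuration of an end-to-end pipeline run
#'
#' One configuration object drives the whole analysis: simulate (or read)
#' data, compute percent chosen, run the intersubject-correlation test per
#' condition, compute feature scores at all four levels, fit the relational
#' model grid, and — in season mode — the early-similarity models. Every
#' random process derives its seed from the single `seed` here, and all
#' seeds and decisions are echoed into the summary JSON.
#'
#' @param seed Master integer seed.
#' @param out_dir Output directory (created if needed).
#' @param transcript,trials Optional file paths; when `NULL` a synthetic
#'   study is simulated from `world`.
#' @param world A [world_config()] for simulation-backed runs.
#' @param features,levels Feature/level grid for the relational models.
#' @param isc_B,isc_method ISC null iterations and resampling mode.
#' @param model Model-fitting settings ([model_spec()]).
#' @param bf_method Bayes-factor method.
#' @param similarity_mode Dyadic similarity pooling mode.
#' @param season Optional list for the early-similarity stage:
#'   `list(episodes = 1:5, world = world_config(...))`; `NULL` skips it.
#' @return A list of class `convrel_run_config`.
#' @export
run_config <- function(seed, out_dir,
                       transcript = NULL, trials = NULL,
                       world = world_config(),
                       features = c("similarity", "sentiment", "clout"),
                       levels = c("gist_specific", "recent_specific",
                                  "gist_general", "recent_general"),
                       isc_B = 10000L, isc_method = "resample",
                       model = model_spec(), bf_method = "savage_dickey",
                       similarity_mode = "pooled", season = NULL) {
  structure(
    list(seed = as.integer(seed), out_dir = out_dir, transcript = transcript,
         trials = trials, world = world, features = features, levels = levels,
         isc_B = as.integer(isc_B), isc_method = isc_method, model = model,
         bf_method = bf_method, similarity_mode = similarity_mode,
         season = season),
    class = "convrel_run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields map directly onto [run_config()] arguments; `world` and
#' `model` sub-maps are passed to [world_config()] and [model_spec()].
#'
#' @param path YAML file path.
#' @return A `convrel_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$world)) y$world <- do.call(world_config, y$world)
  if (!is.null(y$model)) y$model <- do.call(model_spec, y$model)
  do.call(run_config, y)
}

stage_log <- function(stage, ...) message("[", stage, "] ", ...)

#' Run the full analysis pipeline
#'
#' Stage order: simulate or load data; percent chosen (pooled for ISC,
#' per-block for the models); ISC per condition; feature scores for every
#' dyad, clip, feature, and level; one relational model pair (interaction
#' and main-effects) per feature-by-level cell with marginal effects and a
#' Bayes factor; optionally the two season-mode early-similarity models.
#' Tidy TSV tables and a versioned machine-readable `summary.json` are
#' written under `config$out_dir`; every stage logs row counts and drop
#' reasons. On a stage error the run halts with the stage name; outputs of
#' completed stages are preserved.
#'
#' @param config A [run_config()].
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "convrel_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(schema_version = "1.0", seed = config$seed,
                  decisions = list(similarity_mode = config$similarity_mode,
                                   isc_method = config$isc_method,
                                   bf_method = config$bf_method))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline halted at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## ---- data ----
  sim <- NULL
  stage("data", {
    if (is.null(config$transcript)) {
      sim <- simulate_study(config$world, seed = config$seed)
      utterances <- sim$utterances
      trials <- sim$trials
      ros <- sim$world$roster
      readr::write_tsv(sim$world$affinity, file.path(config$out_dir, "truth_affinity.tsv"),
                       progress = FALSE)
    } else {
      speakers <- unique(readr::read_tsv(config$transcript, show_col_types = FALSE)$speaker)
      ros <- roster(sort(speakers))
      utterances <- read_transcript(config$transcript, ros)
      trials <- as_trials(readr::read_tsv(config$trials, show_col_types = FALSE))
    }
    stage_log("data", nrow(utterances), " utterances, ", nrow(trials), " trials")
  })

  ## ---- percent chosen ----
  stage("percent_chosen", {
    pct_pooled <- percent_chosen(trials, pool_blocks = TRUE)
    pct_clip <- percent_chosen(trials, pool_blocks = FALSE)
    readr::write_tsv(pct_pooled, file.path(config$out_dir, "percent_chosen.tsv"),
                     progress = FALSE)
    stage_log("percent_chosen", nrow(pct_pooled), " pooled rows, ",
              nrow(pct_clip), " per-clip rows")
  })

  ## ---- ISC ----
  stage("isc", {
    isc_results <- lapply(c("friend", "rival", "win"), function(cond) {
      vec <- response_matrix(pct_pooled, cond, ros)
      res <- bootstrap_null(vec, B = config$isc_B,
                            seed = config$seed + match(cond, c("friend", "rival", "win")),
                            method = config$isc_method)
      write_isc(res, file.path(config$out_dir, paste0("isc_", cond, ".json")),
                matrix_path = file.path(config$out_dir, paste0("isc_", cond, "_matrix.tsv")))
      res
    })
    names(isc_results) <- c("friend", "rival", "win")
    summary$isc <- lapply(isc_results, function(r) {
      list(observed_median = r$observed_median, observed_sd = r$observed_sd,
           p_value = r$p_value, B = r$B, seed = r$seed)
    })
    stage_log("isc", paste(sprintf("%s r=%.3f p=%.4g", names(isc_results),
                                   vapply(isc_results, `[[`, 0, "observed_median"),
                                   vapply(isc_results, `[[`, 0, "p_value")),
                           collapse = "; "))
  })

  ## ---- features ----
  stage("features", {
    feats <- feature_table(utterances, ros, features = config$features,
                           levels = config$levels,
                           similarity_mode = config$similarity_mode)
    readr::write_tsv(feats, file.path(config$out_dir, "features.tsv"),
                     progress = FALSE)
    stage_log("features", nrow(feats), " scores (",
              sum(is.na(feats$value)), " absent)")
  })

  ## ---- relational models ----
  stage("models", {
    grid <- expand.grid(feature = config$features, level = config$levels,
                        stringsAsFactors = FALSE)
    model_rows <- list()
    summary$models <- list()
    for (i in seq_len(nrow(grid))) {
      fe <- grid$feature[i]; lv <- grid$level[i]
      tab <- assemble_model_table(pct_clip, feats, fe, lv)
      fit_seed <- config$seed + 100L + i
      full <- fit_model(tab, config$model, seed = fit_seed)
      red_spec <- config$model; red_spec$include_interaction <- FALSE
      reduced <- fit_model(tab, red_spec, seed = fit_seed + 1L)
      me <- marginal_effects(full)
      bf <- bayes_factor(full, reduced, method = config$bf_method)
      int_col <- grep(":x$", colnames(full$main[[1]]), value = TRUE)
      int_sum <- summary(full)
      int_row <- int_sum[int_sum$parameter == int_col, ]
      key <- paste(fe, lv, sep = ".")
      summary$models[[key]] <- list(
        n = nrow(tab), seed = fit_seed,
        interaction = list(b = int_row$median, l95 = int_row$l95, u95 = int_row$u95),
        bf = bf$bf, bf_evidence = bf$evidence,
        marginal = stats::setNames(
          lapply(seq_len(nrow(me)), function(r) {
            list(b = me$estimate[r], l95 = me$l95[r], u95 = me$u95[r])
          }), me$condition),
        escalated = full$escalated,
        max_rhat = max(full$diagnostics$rhat))
      model_rows[[key]] <- tibble::tibble(
        feature = fe, level = lv, n = nrow(tab),
        interaction_b = int_row$median, interaction_l95 = int_row$l95,
        interaction_u95 = int_row$u95, bf = bf$bf,
        marginal_friend = me$estimate[me$condition == "friend"],
        marginal_rival = me$estimate[me$condition == "rival"])
      stage_log("models", key, ": interaction b=",
                sprintf("%.3f", int_row$median), ", BF=", sprintf("%.3g", bf$bf))
    }
    readr::write_tsv(dplyr::bind_rows(model_rows),
                     file.path(config$out_dir, "model_summary.tsv"),
                     progress = FALSE)
  })

  ## ---- season mode (early similarity) ----
  if (!is.null(config$season)) {
    stage("season", {
      season_world <- generate_world(config$season$world, seed = config$seed + 500L)
      season_utt <- generate_transcript(season_world)
      episodes <- config$season$episodes %||% 1:5
      summary$season <- list(episodes = episodes)
      early_rows <- list()
      for (mode in c("general", "specific")) {
        early <- early_similarity(season_utt, ros, mode = mode,
                                  episodes = episodes,
                                  similarity_mode = config$similarity_mode)
        tab <- dplyr::inner_join(
          pct_pooled[pct_pooled$condition %in% c("friend", "rival"), ],
          early[!is.na(early$value), c("dyad", "value")], by = "dyad")
        names(tab)[names(tab) == "value"] <- "x"
        fit_seed <- config$seed + 600L + match(mode, c("general", "specific"))
        full <- fit_model(tab, config$model, seed = fit_seed)
        red_spec <- config$model; red_spec$include_interaction <- FALSE
        reduced <- fit_model(tab, red_spec, seed = fit_seed + 10L)
        me <- marginal_effects(full)
        bf <- bayes_factor(full, reduced, method = config$bf_method)
        int_col <- grep(":x$", colnames(full$main[[1]]), value = TRUE)
        s <- summary(full); int_row <- s[s$parameter == int_col, ]
        summary$season[[mode]] <- list(
          n = nrow(tab), seed = fit_seed,
          interaction = list(b = int_row$median, l95 = int_row$l95, u95 = int_row$u95),
          bf = bf$bf,
          marginal = stats::setNames(
            lapply(seq_len(nrow(me)), function(r) list(b = me$estimate[r])),
            me$condition))
        early_rows[[mode]] <- dplyr::mutate(early, mode = mode)
        stage_log("season", mode, ": interaction b=",
                  sprintf("%.3f", int_row$median), ", BF=", sprintf("%.3g", bf$bf))
      }
      readr::write_tsv(dplyr::bind_rows(early_rows),
                       file.path(config$out_dir, "early_similarity.tsv"),
                       progress = FALSE)
    })
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
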