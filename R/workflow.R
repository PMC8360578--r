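# stable sub-seed derivation: every stochastic stage receives its own seed
derive_seed <- function(global_seed, ...) {
  parts <- c(global_seed, ...)
  h <- 0
  for (p in parts) h <- (h * 1000003 + (as.numeric(p) %% 2147483647)) %% 2147483647
  as.integer(h %% 2147483629 + 1)
}

stage_hash <- function(cfg) rlang::hash(cfg)

#' Execute an end-to-end workflow
#'
#' Runs a list of stages in order (`simulate`, `normalize`, `train`,
#' `extract`, `score`, `analyze`), writing each stage's outputs under
#' `out_dir` and recording a JSON manifest (stage, config hash, seed,
#' outputs, status). Re-running with an unchanged configuration skips
#' stages whose hash matches the previous manifest and whose outputs still
#' exist. A stage failure aborts the run with the manifest marking the
#' failed stage.
#'
#' Stage configurations:
#' * `simulate`: `config` ([cell_config()] or flat override list),
#'   `duration`, `sample_interval`.
#' * `normalize`: `interval_frames` (default 5).
#' * `train`: `shapes_per_class`, `epochs`, `lr`, `batch_size` for the
#'   geometry-proxy classifier (omit the stage to supply `classifier`
#'   directly to `extract`).
#' * `extract`: `classifier` (optional if a `train` stage ran).
#' * `score`: `reference` (a [reference_means()] table).
#' * `analyze`: `n_points`, `msd` flags.
#'
#' @param stages Named list of stage configurations, in execution order.
#' @param out_dir Output directory (created if missing).
#' @param seed Global integer seed; per-stage seeds are derived from it.
#' @return The manifest as a tibble (also written to
#'   `file.path(out_dir, "manifest.json")`), with an attribute `state`
#'   holding the in-memory stage products.
#' @export
execute_workflow <- function(stages, out_dir, seed = 1L) {
  stopifnot(is.list(stages), length(stages) >= 1, !is.null(names(stages)))
  known <- c("simulate", "normalize", "train", "extract", "score", "analyze")
  bad <- setdiff(names(stages), known)
  if (length(bad)) stop("unknown workflow stage(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  prev <- if (file.exists(manifest_path)) {
    tibble::as_tibble(jsonlite::read_json(manifest_path, simplifyVector = TRUE))
  } else NULL

  state <- new.env(parent = emptyenv())
  rows <- list()
  for (nm in names(stages)) {
    cfg <- stages[[nm]]
    sseed <- derive_seed(seed, match(nm, known))
    h <- stage_hash(list(nm, cfg, sseed))
    cached <- !is.null(prev) && nm %in% prev$stage &&
      prev$hash[prev$stage == nm][1] == h
    res <- tryCatch({
      run_stage(nm, cfg, state, out_dir, sseed, cached)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[nm]] <- tibble::tibble(stage = nm, hash = h, seed = sseed,
                                   status = "failed",
                                   outputs = conditionMessage(res))
      manifest <- dplyr::bind_rows(rows)
      jsonlite::write_json(manifest, manifest_path, auto_unbox = FALSE)
      stop("workflow stage '", nm, "' failed: ", conditionMessage(res))
    }
    rows[[nm]] <- tibble::tibble(stage = nm, hash = h, seed = sseed,
                                 status = res$status,
                                 outputs = paste(res$outputs, collapse = ";"))
  }
  manifest <- dplyr::bind_rows(rows)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = FALSE)
  attr(manifest, "state") <- state
  manifest
}

run_stage <- function(nm, cfg, state, out_dir, sseed, cached) {
  p <- function(...) file.path(out_dir, paste0(...))
  switch(nm,
    simulate = {
      outs <- c(p("masks.tif"), p("centroid.csv"))
      if (cached && all(file.exists(outs))) {
        state$series <- read_mask_stack(outs[1],
          frame_interval = cfg$sample_interval, label = "sim")
        state$centroid <- utils::read.csv(outs[2])
        return(list(status = "skipped", outputs = outs))
      }
      config <- cfg$config %||% cell_config()
      if (!inherits(config, "cell_config")) {
        config <- update_config(cell_config(), config)
      }
      traj <- run_simulation(config, cfg$duration, cfg$sample_interval,
                             seed = sseed)
      state$trajectory <- traj
      state$series <- trajectory_masks(traj)
      state$centroid <- traj$centroid
      write_mask_stack(state$series, outs[1])
      utils::write.csv(traj$centroid, outs[2], row.names = FALSE)
      list(status = "completed", outputs = outs)
    },
    normalize = {
      outs <- c(p("normalized.tif"), p("motion.csv"))
      if (is.null(state$series)) stop("normalize stage needs a simulate stage")
      norm <- normalize_series(state$series,
                               interval_frames = cfg$interval_frames %||% 5L)
      state$normalized <- norm
      write_mask_stack(norm, outs[1])
      utils::write.csv(norm$info, outs[2], row.names = FALSE)
      list(status = "completed", outputs = outs)
    },
    train = {
      outs <- p("training_history.csv")
      data <- geometry_proxy_classes(cfg$shapes_per_class %||% 60L,
                                     seed = sseed)
      fit <- train_shape_classifier(data, classifier_config(
        epochs = cfg$epochs %||% 30L, lr = cfg$lr %||% 1e-3,
        batch_size = cfg$batch_size %||% 32L, seed = sseed))
      state$classifier <- fit
      utils::write.csv(fit$history, outs, row.names = FALSE)
      list(status = "completed", outputs = outs)
    },
    extract = {
      outs <- p("features.csv")
      clf <- cfg$classifier %||% state$classifier
      if (is.null(clf)) stop("extract stage needs a classifier")
      state$classifier <- clf
      if (is.null(state$normalized)) stop("extract stage needs a normalize stage")
      ft <- extract_features(clf, state$normalized)
      state$features <- ft
      utils::write.csv(ft, outs, row.names = FALSE)
      list(status = "completed", outputs = outs)
    },
    score = {
      outs <- p("scores.csv")
      if (is.null(state$features)) stop("score stage needs an extract stage")
      cand <- dplyr::summarise(state$features,
                               dplyr::across(dplyr::matches("^F\\d+$"), mean))
      cand$candidate <- "run"
      sc <- similarity_score(cand, cfg$reference)
      state$scores <- sc
      utils::write.csv(sc, outs, row.names = FALSE)
      list(status = "completed", outputs = outs)
    },
    analyze = {
      outs <- c(p("msd.json"), p("kymograph.csv"), p("events.csv"))
      if (is.null(state$series)) stop("analyze stage needs a simulate stage")
      msd <- msd_persistence(tibble::as_tibble(state$centroid))
      kym <- protrusion_speed_kymograph(state$series,
                                        n_points = cfg$n_points %||% 128L)
      ev <- detect_pseudopod_events(kym)
      state$msd <- msd; state$kymograph <- kym; state$events <- ev
      jsonlite::write_json(c(as.list(glance(msd)),
                             list(lags = msd$lags, msd = msd$msd)),
                           outs[1], auto_unbox = TRUE, digits = NA)
      utils::write.csv(tidy(kym), outs[2], row.names = FALSE)
      utils::write.csv(ev, outs[3], row.names = FALSE)
      list(status = "completed", outputs = outs)
    }
  )
}

#' Synthetic geometry proxy classes for classifier training
#'
#' Builds three linearly separable shape classes from the geometry
#' machinery: compact disks, vertically elongated (2:1) bars, and laterally
#' elongated (1:2) bars, each with seeded size/aspect jitter, normalized
#' through the standard pipeline.
#'
#' @param n_per_class Masks per class.
#' @param seed Integer seed.
#' @return A [labeled_masks()] tibble (classes `compact`, `vertical`,
#'   `lateral`; `series` groups of ~10 masks for per-series averaging).
#' @export
geometry_proxy_classes <- function(n_per_class = 200L, seed = 1L) {
  set.seed(seed)
  one <- function(aspect_range, cls) {
    masks <- lapply(seq_len(n_per_class), function(i) {
      asp <- stats::runif(1, aspect_range[1], aspect_range[2])
      rot <- stats::runif(1, -5, 5)
      normalize_mask(ellipse_mask(asp, rotation = rot, dim = 128L),
                     direction = c(1, 0))
    })
    labeled_masks(masks, rep(cls, n_per_class),
                  series = paste0(cls, "_", (seq_len(n_per_class) - 1L) %/% 10L))
  }
  dplyr::bind_rows(one(c(0.85, 1.18), "compact"),
                   one(c(0.33, 0.6), "vertical"),
                   one(c(1.7, 3.0), "lateral"))
}

#' Parameter sweep around a base configuration
#'
#' Runs the simulator over the Cartesian grid of the supplied parameter
#' values with `n_replicates` seeds per condition, normalizes each run,
#' extracts features, and aggregates the per-condition mean feature vector
#' (the unweighted mean of per-run time-averaged F). Conditions that fail
#' are logged and the sweep continues.
#'
#' @param base_config A [cell_config()].
#' @param grid Named list of parameter values, e.g.
#'   `list(a_W = c(0.8, 2.4), W_tot = c(70, 80))`; names must be valid flat
#'   configuration keys.
#' @param classifier A trained `shape_classifier`.
#' @param duration,sample_interval Simulation length and sampling (s).
#' @param n_replicates Replicate seeds per condition (default 2).
#' @param seed Global seed.
#' @param pca Optional `shape_pca`; adds PC1/PC2 to the aggregate.
#' @param interval_frames Normalization lookback.
#' @return A list: `aggregate` (tibble: condition, parameters, mean F, PCs),
#'   `runs` (per-run tibble), `failures` (tibble of failed conditions).
#' @export
parameter_sweep <- function(base_config, grid, classifier, duration,
                            sample_interval, n_replicates = 2L, seed = 1L,
                            pca = NULL, interval_frames = 5L) {
  stopifnot(is.list(grid), !is.null(names(grid)))
  conds <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  runs <- list(); fails <- list()
  for (ci in seq_len(nrow(conds))) {
    overrides <- as.list(conds[ci, , drop = FALSE])
    cfg <- update_config(base_config, overrides)
    for (r in seq_len(n_replicates)) {
      sseed <- derive_seed(seed, ci, r)
      res <- tryCatch({
        traj <- run_simulation(cfg, duration, sample_interval, seed = sseed)
        norm <- normalize_series(trajectory_masks(traj), interval_frames)
        mf <- mean_feature_vector(classifier, norm)
        dplyr::bind_cols(tibble::as_tibble(overrides),
                         tibble::tibble(condition = ci, replicate = r,
                                        seed = sseed), mf)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        fails[[length(fails) + 1L]] <- dplyr::bind_cols(
          tibble::as_tibble(overrides),
          tibble::tibble(condition = ci, replicate = r, seed = sseed,
                         error = conditionMessage(res)))
      } else {
        runs[[length(runs) + 1L]] <- res
      }
    }
  }
  runs <- if (length(runs)) dplyr::bind_rows(runs) else tibble::tibble()
  agg <- if (nrow(runs)) {
    runs |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c("condition",
                                                    names(grid))))) |>
      dplyr::summarise(n_runs = dplyr::n(),
                       dplyr::across(dplyr::matches("^F\\d+$"), mean),
                       .groups = "drop")
  } else tibble::tibble()
  if (!is.null(pca) && nrow(agg)) agg <- project_features(pca, agg)
  list(aggregate = agg, runs = runs,
       failures = if (length(fails)) dplyr::bind_rows(fails) else
         tibble::tibble())
}
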