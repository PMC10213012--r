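#' Experiment configuration
#'
#' A fully serializable description of an end-to-end experiment: phantom
#' population, projection/noise settings, dataset splits, training setup and
#' evaluation options, plus one global seed that fans out deterministically
#' to every stage (see [derive_seed()]).
#'
#' @param n_cases number of phantom cases.
#' @param phantom named list of [phantom_spec()] arguments (per-case seeds
#'   are derived from the global seed).
#' @param noise list with `i0`.
#' @param pose_bounds list with `rotation` (deg) and `translation` (mm).
#' @param splits named split fractions.
#' @param training named list of [training_config()] arguments.
#' @param evaluation list with `sweep_n`.
#' @param seed global integer seed.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(n_cases = 8,
                              phantom = list(grid_shape = c(64, 64, 64),
                                             spacing = c(3, 3, 3),
                                             n_bones = 1, n_muscles = 2,
                                             asymmetry_factor = 0.85),
                              noise = list(i0 = 1e4),
                              pose_bounds = list(rotation = c(3, 3, 3),
                                                 translation = c(6, 6, 6)),
                              splits = c(train = 0.5, val = 0.25,
                                         test = 0.25),
                              training = list(variant = "proposed2",
                                              epochs = 4, image_size = 64,
                                              base_width = 8,
                                              residual_blocks = 2),
                              evaluation = list(sweep_n = 41),
                              seed = 1) {
  structure(list(n_cases = n_cases, phantom = phantom, noise = noise,
                 pose_bounds = pose_bounds, splits = splits,
                 training = training, evaluation = evaluation,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Read / write an experiment configuration as YAML
#' @param config an [experiment_config()].
#' @param path YAML file path.
#' @return `write_config` returns the path invisibly; `read_config` the
#'   config.
#' @export
write_config <- function(config, path) {
  l <- unclass(config)
  l$splits <- as.list(l$splits)   # yaml drops names of atomic vectors
  yaml::write_yaml(l, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  l <- yaml::read_yaml(path)
  l$splits <- unlist(l$splits)
  do.call(experiment_config, l)
}

config_specs <- function(config) {
  lapply(seq_len(config$n_cases), function(i) {
    do.call(phantom_spec,
            c(config$phantom, list(seed = derive_seed(config$seed, 100 + i))))
  })
}

stage_stamp_path <- function(out_root, stage) {
  file.path(out_root, stage, "stage.json")
}

stage_done <- function(out_root, stage, hash) {
  p <- stage_stamp_path(out_root, stage)
  if (!file.exists(p)) return(FALSE)
  old <- jsonlite::read_json(p)
  if (!identical(old$hash, hash)) {
    stop("outputs for stage '", stage, "' exist with a different ",
         "configuration hash; refusing to overwrite")
  }
  TRUE
}

stamp_stage <- function(out_root, stage, hash) {
  dir.create(file.path(out_root, stage), recursive = TRUE,
             showWarnings = FALSE)
  jsonlite::write_json(list(stage = stage, hash = hash,
                            time = format(Sys.time())),
                       stage_stamp_path(out_root, stage), auto_unbox = TRUE)
}

#' Run the experiment pipeline
#'
#' Executes the requested stages in order, writing each stage's artifacts
#' under `out_root/<stage>/` together with a stamp holding the configuration
#' hash. Re-running with an unchanged configuration skips completed stages;
#' a changed configuration over existing outputs is refused rather than
#' silently overwritten. A stage whose prerequisites are neither on disk nor
#' produced earlier in the same call raises an error naming the missing
#' stage.
#'
#' @param config an [experiment_config()].
#' @param stages subset of `c("generate", "project", "train", "decompose",
#'   "evaluate")` (kept in canonical order).
#' @param out_root output directory.
#' @return (invisibly) a list with the produced objects (`manifest`,
#'   `state`, `decompositions`, `report` — those requested).
#' @export
run_pipeline <- function(config,
                         stages = c("generate", "project", "train",
                                    "decompose", "evaluate"),
                         out_root = "xdecomp_out") {
  all_stages <- c("generate", "project", "train", "decompose", "evaluate")
  stages <- all_stages[all_stages %in% stages]
  if (length(stages) == 0) stop("no valid stages requested")
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  res <- list()

  specs <- config_specs(config)
  h_gen <- object_hash(list(config$phantom, config$n_cases, config$seed))

  if ("generate" %in% stages) {
    if (!stage_done(out_root, "generate", h_gen)) {
      pdir <- file.path(out_root, "generate")
      for (i in seq_along(specs)) {
        write_phantom(generate_phantom(specs[[i]]), pdir, i)
      }
      stamp_stage(out_root, "generate", h_gen)
    }
  }

  h_proj <- object_hash(list(h_gen, config$noise, config$pose_bounds,
                             config$splits))
  if ("project" %in% stages) {
    if (!stage_done(out_root, "project", h_proj)) {
      manifest <- build_dataset(specs, noise = config$noise,
                                pose_bounds = config$pose_bounds,
                                splits = config$splits,
                                seed = derive_seed(config$seed, 2),
                                dir = file.path(out_root, "project"))
      stamp_stage(out_root, "project", h_proj)
      res$manifest <- manifest
    } else {
      res$manifest <- read_manifest(file.path(out_root, "project"))
    }
  }

  need_manifest <- function() {
    if (!is.null(res$manifest)) return(res$manifest)
    mdir <- file.path(out_root, "project")
    if (!file.exists(file.path(mdir, "manifest.json")))
      stop("missing prerequisite artifacts of stage 'project'")
    res$manifest <<- read_manifest(mdir)
    res$manifest
  }

  h_train <- object_hash(list(h_proj, config$training))
  state_path <- file.path(out_root, "train", "state.rds")
  if ("train" %in% stages) {
    if (!stage_done(out_root, "train", h_train)) {
      manifest <- need_manifest()
      cfg <- do.call(training_config,
                     c(config$training,
                       list(seed = derive_seed(config$seed, 3))))
      state <- train(manifest, cfg)
      dir.create(dirname(state_path), recursive = TRUE, showWarnings = FALSE)
      saveRDS(state, state_path)
      utils::write.csv(loss_history(state),
                       file.path(out_root, "train", "history.csv"),
                       row.names = FALSE)
      # JSON-lines loss log, one record per step
      hl <- loss_history(state)
      writeLines(vapply(seq_len(nrow(hl)), function(i)
        jsonlite::toJSON(as.list(hl[i, ]), auto_unbox = TRUE,
                         digits = NA), ""),
        file.path(out_root, "train", "losses.jsonl"))
      stamp_stage(out_root, "train", h_train)
      res$state <- state
    } else {
      res$state <- readRDS(state_path)
    }
  }

  need_state <- function() {
    if (!is.null(res$state)) return(res$state)
    if (!file.exists(state_path))
      stop("missing prerequisite artifacts of stage 'train'")
    res$state <<- readRDS(state_path)
    res$state
  }

  h_dec <- object_hash(list(h_train, "decompose"))
  dec_path <- file.path(out_root, "decompose", "decompositions.rds")
  if ("decompose" %in% stages) {
    if (!stage_done(out_root, "decompose", h_dec)) {
      manifest <- need_manifest()
      state <- need_state()
      test_ids <- manifest_split(manifest, "test")
      decs <- lapply(test_ids, function(ci)
        decompose(manifest$data[[ci]]$radiograph, state))
      dir.create(dirname(dec_path), recursive = TRUE, showWarnings = FALSE)
      saveRDS(list(cases = test_ids, decompositions = decs), dec_path)
      stamp_stage(out_root, "decompose", h_dec)
      res$decompositions <- decs
      res$dec_cases <- test_ids
    } else {
      d <- readRDS(dec_path)
      res$decompositions <- d$decompositions
      res$dec_cases <- d$cases
    }
  }

  if ("evaluate" %in% stages) {
    h_eval <- object_hash(list(h_dec, config$evaluation))
    if (!stage_done(out_root, "evaluate", h_eval)) {
      if (is.null(res$decompositions)) {
        if (!file.exists(dec_path))
          stop("missing prerequisite artifacts of stage 'decompose'")
        d <- readRDS(dec_path)
        res$decompositions <- d$decompositions
        res$dec_cases <- d$cases
      }
      manifest <- need_manifest()
      report <- evaluate_decomposition(manifest, res$decompositions,
                                       cases = res$dec_cases,
                                       sweep_n = config$evaluation$sweep_n)
      write_report(report, file.path(out_root, "evaluate"))
      stamp_stage(out_root, "evaluate", h_eval)
      res$report <- report
    } else {
      res$report <- NULL
    }
  }
  invisible(res)
}
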