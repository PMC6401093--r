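#' Write / read a volume as NIfTI-1
#'
#' @param volume 3D (or 4D) numeric array.
#' @param grid a [volume_grid()] supplying voxel size and affine.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly (write) or a list `volume`, `grid` (read).
#' @export
write_volume <- function(volume, grid, path) {
  img <- RNifti::asNifti(volume)
  img <- RNifti::`sform<-`(img, structure(grid$origin_affine, code = 2L))
  RNifti::pixdim(img) <- c(grid$voxel_size_mm,
                           rep(1, length(dim(volume)) - 3))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), dimnames = NULL)
  d <- dim(img)
  grid <- volume_grid(d[1:3], RNifti::pixdim(img)[1:3], origin_affine = aff)
  list(volume = array(as.numeric(img), d), grid = grid)
}

#' Write / read an event design as BIDS-style TSV
#'
#' Columns `onset`, `duration`, `run`, `trial_type`; timing metadata
#' (TR, volumes per run, condition set) goes to a JSON sidecar next to
#' the TSV.
#'
#' @param design an [build_design()] design.
#' @param path TSV path; sidecar is `<path without .tsv>.json`.
#' @return `path` (write) or an `event_design` (read).
#' @export
write_events_tsv <- function(design, path) {
  tab <- data.frame(onset = design$onset, duration = design$duration,
                    run = design$run, trial_type = design$condition)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(tr_s = attr(design, "tr_s"),
               n_vols_per_run = attr(design, "n_vols_per_run"),
               n_runs = attr(design, "n_runs"),
               conditions = attr(design, "conditions"))
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "run", "trial_type")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("events file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  side_path <- sidecar_path(path)
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path, simplifyVector = TRUE)
    else list(tr_s = 2, n_vols_per_run = NULL, n_runs = max(tab$run),
              conditions = unique(tab$trial_type))
  d <- data.frame(onset = tab$onset, duration = tab$duration, run = tab$run,
                  condition = tab$trial_type, stringsAsFactors = FALSE)
  nv <- side$n_vols_per_run
  if (is.null(nv))
    nv <- as.integer(ceiling(max(tab$onset + 30) / side$tr_s))
  structure(d, n_runs = as.integer(side$n_runs), tr_s = side$tr_s,
            n_vols_per_run = as.integer(nv),
            conditions = as.character(side$conditions),
            class = c("event_design", "data.frame"))
}

sidecar_path <- function(path) sub("\\.tsv$", ".json", path)

#' Write / read per-trial ratings as CSV
#'
#' @param ratings ratings data.frame as [sample_ratings()].
#' @param path CSV path.
#' @export
write_ratings_csv <- function(ratings, path) {
  write.csv(ratings, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratings_csv
#' @export
read_ratings_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial", "positivity", "negativity")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("ratings file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  tab
}

#' Serialise a subject's trial patterns
#'
#' Patterns go to a 4D NIfTI (trial axis last), the mask to a 3D NIfTI,
#' and the per-trial labels/runs/ratings to a sidecar CSV.
#'
#' @param patterns a [trial_pattern_set()].
#' @param prefix output path prefix; writes `<prefix>_patterns.nii.gz`,
#'   `<prefix>_mask.nii.gz`, `<prefix>_trials.csv`.
#' @return named vector of the written paths.
#' @export
write_patterns <- function(patterns, prefix) {
  shp <- patterns$grid$shape
  n <- nrow(patterns$values)
  vol4 <- array(0, c(shp, n))
  for (i in seq_len(n)) {
    v <- array(0, shp)
    v[patterns$mask] <- patterns$values[i, ]
    vol4[, , , i] <- v
  }
  paths <- c(patterns = paste0(prefix, "_patterns.nii.gz"),
             mask = paste0(prefix, "_mask.nii.gz"),
             trials = paste0(prefix, "_trials.csv"))
  write_volume(vol4, patterns$grid, paths["patterns"])
  write_volume(array(as.numeric(patterns$mask), shp), patterns$grid,
               paths["mask"])
  tr <- data.frame(trial = seq_len(n), condition = patterns$condition,
                   run = patterns$run)
  if (!is.null(patterns$ratings)) {
    tr$positivity <- patterns$ratings$positivity
    tr$negativity <- patterns$ratings$negativity
  }
  write.csv(tr, paths["trials"], row.names = FALSE)
  paths
}

#' Load a subject dataset from disk
#'
#' Reads NIfTI volumes plus the events TSV and ratings CSV, validating
#' grid consistency (affines must agree to 1e-4 mm) and table schemas;
#' errors name the offending file or column.
#'
#' @param paths named list/vector with elements `patterns` (or `bold`),
#'   `mask`, `events`, and optionally `ratings` or `trials`.
#' @return a `subject_dataset` (patterns mode) ready for analysis.
#' @export
load_subject <- function(paths) {
  paths <- as.list(paths)
  if (is.null(paths$mask)) stop("paths$mask is required")
  mk <- read_volume(paths$mask)
  mask <- mk$volume > 0.5
  grid <- mk$grid
  check_affine <- function(other, name) {
    if (max(abs(other$origin_affine - grid$origin_affine)) > 1e-4)
      stop("grid mismatch: affine of ", name,
           " differs from the mask affine by more than 1e-4 mm")
    if (!identical(other$shape, grid$shape))
      stop("grid mismatch: ", name, " shape differs from the mask")
  }
  design <- if (!is.null(paths$events)) read_events_tsv(paths$events)
  ratings <- NULL
  out <- list(grid = grid, mask = mask, design = design, mode = "patterns")
  if (!is.null(paths$patterns)) {
    pv <- read_volume(paths$patterns)
    check_affine(pv$grid, paths$patterns)
    n <- dim(pv$volume)[4]
    vals <- t(apply(pv$volume, 4, function(v) v[mask]))
    if (!is.null(paths$trials)) {
      tr <- read.csv(paths$trials, stringsAsFactors = FALSE)
      cond <- tr$condition
      run <- tr$run
      if (all(c("positivity", "negativity") %in% names(tr))) ratings <- tr
    } else {
      stopifnot(!is.null(design), nrow(design) == n)
      cond <- design$condition
      run <- design$run
    }
    out$patterns <- trial_pattern_set(vals, cond, run, grid, mask,
                                      ratings = ratings)
  } else if (!is.null(paths$bold)) {
    bv <- read_volume(paths$bold)
    check_affine(bv$grid, paths$bold)
    bold <- t(apply(bv$volume, 4, function(v) v[mask]))
    if (is.null(design)) stop("bold input requires paths$events")
    attr(bold, "tr_s") <- attr(design, "tr_s")
    out$bold <- bold
    out$mode <- "bold"
  } else stop("one of paths$patterns or paths$bold is required")
  if (is.null(ratings) && !is.null(paths$ratings))
    ratings <- read_ratings_csv(paths$ratings)
  out$ratings <- ratings
  if (!is.null(out$patterns) && is.null(out$patterns$ratings))
    out$patterns$ratings <- ratings
  structure(out, class = "subject_dataset")
}

#' Read a pipeline run configuration
#'
#' YAML fields override the documented defaults; unknown fields error.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @param overrides named list applied after the file (flag-style
#'   precedence).
#' @return a validated `run_config` list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  for (src in list(user, overrides)) {
    unknown <- setdiff(names(src), names(cfg))
    if (length(unknown))
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    cfg[names(src)] <- src
  }
  stopifnot(cfg$n_subjects >= 1, cfg$radius_mm >= 0, cfg$alpha > 0,
            cfg$alpha < 1, cfg$n_perm >= 1, cfg$n_draws >= 1,
            cfg$valence_bin_width > 0)
  if (!is.numeric(cfg$seed)) stop("a seed is required for stochastic stages")
  structure(cfg, class = "run_config")
}

default_run_config <- function() {
  list(out_dir = "gustotope_out", preset = "exp1", n_subjects = 6L,
       grid_shape = c(20L, 24L, 18L), voxel_size_mm = 2, mode = "patterns",
       taste_amp = 0.08, valence_amp = 0.06, noise_sd = 1, rating_sd = 1.5,
       radius_mm = 4, fwhm_univariate_mm = 6, fwhm_group_mm = 4,
       alpha = 0.05, n_perm = 1000L, n_draws = 2000L,
       pair_scheme = "all-pairs", valence_bin_width = 1,
       stages = c("simulate", "glm", "univariate", "searchlight", "group",
                  "rsa"),
       seed = 1L)
}

#' Run the full analysis pipeline on synthetic subjects
#'
#' Executes the requested stage prefix of
#' simulate -> glm -> univariate -> searchlight -> group -> rsa on a
#' seeded synthetic cohort, writing stage outputs beneath
#' `config$out_dir` and a JSON manifest recording parameters, seeds,
#' per-stage timings and md5 hashes of every output file.  Stages must
#' form a prefix of the pipeline: requesting a later stage without its
#' predecessors raises a dependency error.  Rerunning an identical
#' config reproduces identical output hashes.
#'
#' @param config a `run_config` from [read_run_config()].
#' @return the manifest, invisibly; also written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  all_stages <- default_run_config()$stages
  stages <- config$stages
  if (!all(stages %in% all_stages))
    stop("unknown stage(s): ", paste(setdiff(stages, all_stages), collapse = ", "))
  idx <- sort(match(stages, all_stages))
  if (!identical(idx, seq_len(length(idx))))
    stop("dependency error: stages must form a prefix of ",
         paste(all_stages, collapse = " -> "))
  stages <- all_stages[idx]
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("gustotope")),
                   config = unclass(config), stages = list())
  state <- new.env(parent = emptyenv())
  on.exit(jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                               auto_unbox = TRUE, digits = NA, pretty = TRUE),
          add = TRUE)
  for (st in stages) {
    t0 <- proc.time()[["elapsed"]]
    outputs <- tryCatch(
      run_stage(st, config, state),
      error = function(e) {
        manifest$stages[[st]] <<- list(status = "failed",
                                       error = conditionMessage(e))
        stop("stage '", st, "' failed: ", conditionMessage(e))
      })
    manifest$stages[[st]] <- list(
      status = "ok", seconds = round(proc.time()[["elapsed"]] - t0, 2),
      seed = config$seed,
      outputs = lapply(outputs, function(p)
        list(path = p, md5 = unname(tools::md5sum(p)))))
  }
  invisible(manifest)
}

# one pipeline stage; returns the paths it wrote
run_stage <- function(st, cfg, state) {
  od <- cfg$out_dir
  switch(st,
    simulate = {
      grid <- volume_grid(cfg$grid_shape, rep(cfg$voxel_size_mm, 3))
      model <- ground_truth_model(grid, conditions = design_preset(cfg$preset)$conditions,
                                  taste_amp = cfg$taste_amp,
                                  valence_amp = cfg$valence_amp,
                                  noise_sd = cfg$noise_sd,
                                  rating_sd = cfg$rating_sd)
      state$model <- model
      state$subjects <- lapply(seq_len(cfg$n_subjects), function(s) {
        design <- build_design(cfg$preset, seed = cfg$seed + 1000L + s)
        generate_subject(design, model, mode = cfg$mode, seed = cfg$seed + s)
      })
      p1 <- file.path(od, "sub-01_task-taste_events.tsv")
      write_events_tsv(state$subjects[[1]]$design, p1)
      p2 <- file.path(od, "sub-01_task-taste_ratings.csv")
      write_ratings_csv(state$subjects[[1]]$ratings, p2)
      c(p1, sidecar_path(p1), p2)
    },
    glm = {
      state$patterns <- lapply(state$subjects, function(su) {
        if (su$mode == "bold") fit_trialwise(su) else demean_patterns(su$patterns)
      })
      p <- file.path(od, "sub-01_desc-trialpatterns_summary.csv")
      v <- state$patterns[[1]]$values
      write.csv(data.frame(trial = seq_len(nrow(v)),
                           condition = state$patterns[[1]]$condition,
                           mean = rowMeans(v), sd = apply(v, 1, sd)),
                p, row.names = FALSE)
      p
    },
    univariate = {
      mats <- lapply(state$patterns, split_half_matrix)
      stats_tab <- same_diff_stats(mats)
      p <- file.path(od, "group_desc-splithalf_stats.csv")
      write.csv(stats_tab, p, row.names = FALSE)
      p
    },
    searchlight = {
      spec <- sphere_offsets(cfg$radius_mm, cfg$voxel_size_mm)
      state$maps <- lapply(state$patterns, discriminability_maps, spec = spec,
                           scheme = cfg$pair_scheme)
      paths <- character(0)
      for (ta in names(state$maps[[1]])) {
        p <- file.path(od, paste0("sub-01_desc-acc-", ta, ".nii.gz"))
        write_volume(state$maps[[1]][[ta]]$acc, state$model$grid, p)
        paths <- c(paths, p)
      }
      paths
    },
    group = {
      tastes <- names(state$maps[[1]])
      state$group <- lapply(stats::setNames(tastes, tastes), function(ta) {
        signflip_onesample(lapply(state$maps, function(m) m[[ta]]$acc),
                           state$model$mask, fwhm_mm = cfg$fwhm_group_mm,
                           voxel_size_mm = cfg$voxel_size_mm,
                           alpha = cfg$alpha, n_perm = cfg$n_perm,
                           seed = cfg$seed + match(ta, tastes))
      })
      state$conj <- conjunction_count(state$group)
      p1 <- file.path(od, "group_desc-conjunction.nii.gz")
      write_volume(array(as.numeric(state$conj), dim(state$conj)),
                   state$model$grid, p1)
      p2 <- file.path(od, "group_desc-maxt_null.csv")
      nulls <- lapply(state$group, `[[`, "max_t_null")
      write.csv(data.frame(taste = rep(tastes, lengths(nulls)),
                           max_t = unlist(nulls)),
                p2, row.names = FALSE)
      c(p1, p2)
    },
    rsa = {
      roi <- state$conj >= 1
      roi[is.na(roi)] <- FALSE
      # small demo cohorts may leave the conjunction empty; fall back to
      # the generator's planted taste regions so the stage stays runnable
      if (sum(roi) < 10) {
        tastes <- taste_labels(state$model$conditions)
        roi <- Reduce(`|`, state$model$regions[tastes])
      }
      rdms <- lapply(state$patterns, neural_rdm, roi = roi)
      d_mean <- Reduce(`+`, lapply(rdms, `[[`, "d")) / length(rdms)
      p1 <- file.path(od, "group_desc-neural_rdm.csv")
      write.csv(d_mean, p1)
      cells <- lapply(state$patterns, similarity_cells, roi = roi,
                      bin_width = cfg$valence_bin_width)
      an <- rm_anova_2x2(cells)
      p2 <- file.path(od, "group_desc-anova.json")
      jsonlite::write_json(an[c("F_taste", "p_taste", "F_valence", "p_valence",
                                "F_interaction", "p_interaction", "levene_p",
                                "n_subjects")],
                           p2, auto_unbox = TRUE, digits = NA)
      c(p1, p2)
    })
}
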