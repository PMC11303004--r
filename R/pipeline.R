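## Pipeline orchestration: configuration, stage sequencing
## (simulate -> align -> average/refine -> subtract -> pick -> dedup),
## run report.

#' Build a pipeline configuration
#'
#' All stage parameters with their defaults; a run is reproducible from the
#' configuration plus inputs plus the single seed (per-stage child seeds are
#' derived from it with a fixed affine rule).
#'
#' @param seed master seed.
#' @param input_stack path to an MRC stack (ignored when `simulate` is
#'   enabled).
#' @param stages character vector of enabled stages, in order, among
#'   `simulate`, `align`, `average`, `subtract`, `pick_template`,
#'   `pick_classify`, `dedup`.
#' @param simulate list of [simulate_tube_dataset()] arguments.
#' @param align list: [align_config()] arguments plus `refine_iters`.
#' @param average list: `z_fraction`, `eps`.
#' @param subtract list: `mask_frac`.
#' @param pick_template list: `threshold`, `n_rot`, `min_separation_px`,
#'   `template_radius_A` (template drawn as a Gaussian blob of this radius).
#' @param pick_classify list: `divisions`, `subbox_size`, `k`, `rounds`,
#'   `n_iter`, `rot_step_deg`, `max_shift_px`, `n_good`.
#' @param dedup list: `dist_px`, `ncc_threshold`, `max_shift_px`,
#'   `box_size`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, input_stack = NULL,
                            stages = c("simulate", "align", "average",
                                       "subtract", "pick_template",
                                       "pick_classify", "dedup"),
                            simulate = list(), align = list(),
                            average = list(), subtract = list(),
                            pick_template = list(), pick_classify = list(),
                            dedup = list()) {
  cfg <- list(seed = seed, input_stack = input_stack, stages = stages,
              simulate = simulate, align = align, average = average,
              subtract = subtract, pick_template = pick_template,
              pick_classify = pick_classify, dedup = dedup)
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

## fixed fan-out of the master seed into per-stage child seeds (kept < 2^31)
stage_seed <- function(seed, stage) {
  idx <- match(stage, c("simulate", "align", "average", "subtract",
                        "pick_template", "pick_classify", "dedup"))
  as.integer((as.numeric(seed) * 48271 + idx * 104729) %% 2147483647)
}

validate_config <- function(cfg) {
  known <- c("simulate", "align", "average", "subtract", "pick_template",
             "pick_classify", "dedup")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  needs <- list(average = "align", subtract = "average",
                pick_template = "subtract", pick_classify = "subtract",
                dedup = c("pick_template", "pick_classify"))
  for (st in cfg$stages) {
    dep <- needs[[st]]
    if (!is.null(dep) && !any(dep %in% cfg$stages))
      stop("stage '", st, "' requires stage(s) ",
           paste(dep, collapse = " or "), " to be enabled")
  }
  if (!"simulate" %in% cfg$stages && is.null(cfg$input_stack))
    stop("no input: enable the simulate stage or set input_stack")
  invisible(cfg)
}

#' Read / write pipeline configuration as YAML
#' @param cfg a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the full tube-subtraction pipeline
#'
#' Executes the enabled stages in order, writing each stage's outputs and a
#' machine-readable JSON run report into `run_dir`. Stage failure stops the
#' run with the stage name in the error.
#'
#' @param config a [pipeline_config()].
#' @param run_dir output directory (created).
#' @param verbose print per-stage summary lines.
#' @return the run report (list), invisibly; also written to
#'   `run_dir/report.json`.
#' @export
run_pipeline <- function(config, run_dir, verbose = TRUE) {
  validate_config(config)
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, stages = config$stages, counts = list())
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  truth <- NULL
  if ("simulate" %in% config$stages) {
    stage("simulate", {
      args <- config$simulate
      args$seed <- stage_seed(config$seed, "simulate")
      sim <- do.call(simulate_tube_dataset, args)
      stack <- sim$stack; truth <- sim$truth
      write_stack(stack, file.path(run_dir, "segments.mrc"))
      truth_json <- truth[c("segments", "particles", "visible")]
      jsonlite::write_json(truth_json,
                           file.path(run_dir, "ground_truth.json"),
                           dataframe = "columns", digits = NA, null = "null")
    })
    report$counts$segments_in <- n_images(stack)
    report$counts$true_particles <-
      if (is.null(truth$particles)) 0 else nrow(truth$particles)
    say("simulate: %d segments, %d particles", n_images(stack),
        report$counts$true_particles)
  } else {
    stack <- stage("input", read_stack(config$input_stack))
    report$counts$segments_in <- n_images(stack)
  }
  picks_t <- picks_c <- NULL
  if ("align" %in% config$stages) {
    stage("align", {
      aargs <- config$align
      refine_iters <- aargs$refine_iters %||% 1
      aargs$refine_iters <- NULL
      acfg <- do.call(align_config, aargs)
      stack <- align_stack(stack, acfg,
                            seed = stage_seed(config$seed, "align"))
    })
    report$counts$segments_aligned <- sum(stack$metadata$align_ok)
    say("align: %d/%d segments aligned", sum(stack$metadata$align_ok),
        n_images(stack))
  }
  avg <- NULL
  if ("average" %in% config$stages) {
    stage("average", {
      zf <- config$average$z_fraction %||% 0.8
      refine_iters <- config$align$refine_iters %||% 2
      os <- config$average$oversample %||% 1
      if (refine_iters > 0) {
        rl <- refine_loop(stack, z_fraction = zf, max_iter = refine_iters,
                          oversample = os)
        stack <- rl$stack; avg <- rl$average
        report$counts$refine_iterations <- rl$iterations
      } else {
        avg <- smooth_z(reconstruct_average(stack,
                           eps = config$average$eps %||% 0.001,
                           oversample = os), zf)
      }
      write_volume(avg, file.path(run_dir, "azimuthal_average.mrc"))
      report$qc$cylindricity <- cylindricity(avg)
    })
    say("average: cylindricity %.4f", report$qc$cylindricity)
  }
  if ("subtract" %in% config$stages) {
    stage("subtract", {
      stack <- subtract_stack(stack, avg,
                              mask_frac = config$subtract$mask_frac %||% 0.1,
                              match_bandlimit =
                                config$subtract$match_bandlimit %||% FALSE,
                              projection =
                                config$subtract$projection %||% "profile")
      write_stack(stack, file.path(run_dir, "subtracted.mrc"))
    })
    ok <- stack$metadata$align_ok == 1
    report$qc$mean_residual_rms <- mean(stack$metadata$residual_rms[ok])
    report$qc$mean_scale_alpha <- mean(stack$metadata$scale_alpha[ok])
    say("subtract: mean alpha %.3f, mean residual RMS %.4g",
        report$qc$mean_scale_alpha, report$qc$mean_residual_rms)
  }
  if ("pick_template" %in% config$stages) {
    stage("pick_template", {
      pt <- config$pick_template
      tpl_r <- pt$template_radius_A %||% 85
      tpl <- particle_projection(
        gaussian_particle(radius_A = tpl_r, pixel_size = stack$pixel_size))
      picks_t <- pick_stack_by_template(stack, tpl,
        threshold = pt$threshold %||% 0.15,
        min_separation_px = pt$min_separation_px,
        n_rot = pt$n_rot %||% 24)
      write_picks(picks_t, file.path(run_dir, "picks_template.txt"))
    })
    report$counts$picks_template <- nrow(picks_t)
    say("pick_template: %d picks", nrow(picks_t))
  }
  if ("pick_classify" %in% config$stages) {
    stage("pick_classify", {
      pc <- config$pick_classify
      sb <- pc$subbox_size %||% round(dim(stack$data)[1] / 4)
      picks_c <- pick_by_classification(stack,
        divisions = pc$divisions %||% 6, subbox_size = sb,
        k = pc$k %||% 6, rounds = pc$rounds %||% 1,
        n_iter = pc$n_iter %||% 8,
        rot_step_deg = pc$rot_step_deg %||% 90,
        max_shift_px = pc$max_shift_px,
        seed = stage_seed(config$seed, "pick_classify"),
        n_good = pc$n_good)
      write_picks(picks_c, file.path(run_dir, "picks_classify.txt"))
    })
    report$counts$picks_classify <- nrow(picks_c)
    say("pick_classify: %d picks", nrow(picks_c))
  }
  if ("dedup" %in% config$stages) {
    stage("dedup", {
      dd <- config$dedup
      bs <- dd$box_size %||% (2 * round(
        (config$pick_template$template_radius_A %||% 85) /
          stack$pixel_size))
      for (nm in c("template", "classify")) {
        p <- if (nm == "template") picks_t else picks_c
        if (is.null(p)) next
        boxes <- extract_boxes(stack, p, bs)
        kept <- eliminate_duplicates(p, boxes, dist_px = dd$dist_px,
                                     ncc_threshold =
                                       dd$ncc_threshold %||% 0.8,
                                     max_shift_px = dd$max_shift_px %||% 2)
        write_picks(kept, file.path(run_dir,
                                    paste0("picks_", nm, "_dedup.txt")))
        report$counts[[paste0("picks_", nm, "_dedup")]] <- nrow(kept)
        if (nm == "template") picks_t <- kept else picks_c <- kept
        say("dedup (%s): %d -> %d picks", nm, nrow(p), nrow(kept))
      }
    })
  }
  jsonlite::write_json(report, file.path(run_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize a pipeline run directory
#'
#' Re-reads the JSON run report and the pick files and returns a counts
#' table analogous to a data-collection statistics table (segments in/out,
#' picks before/after duplicate removal). Regeneration is idempotent.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return list with `report` (the stored report) and `counts` (data
#'   frame).
#' @export
pipeline_report <- function(run_dir) {
  rj <- file.path(run_dir, "report.json")
  if (!file.exists(rj)) stop("no run report found in ", run_dir)
  report <- jsonlite::read_json(rj, simplifyVector = TRUE)
  cnt <- report$counts
  counts <- data.frame(quantity = names(cnt),
                       value = unlist(cnt, use.names = FALSE))
  list(report = report, counts = counts)
}
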