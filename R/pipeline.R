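#' Algorithm variant specification
#'
#' @param algorithm "GD" or "MLEM".
#' @param support Use finite-support enforcement?
#' @param trunc_mod Use the truncation modification?
#' @param name Optional label; default encodes the flags, e.g. `"GD+S+T"`.
#' @return A list of class `variant_spec`.
#' @export
variant_spec <- function(algorithm = c("GD", "MLEM"), support = FALSE,
                         trunc_mod = FALSE, name = NULL) {
  algorithm <- match.arg(algorithm)
  if (is.null(name))
    name <- paste0(algorithm, if (support) "+S" else "",
                   if (trunc_mod) "+T" else "")
  structure(list(name = name, algorithm = algorithm, support = support,
                 trunc_mod = trunc_mod), class = "variant_spec")
}

#' The eight algorithm variants
#'
#' GD and MLEM, each naive, with support, with truncation modification, and
#' with both.
#'
#' @return List of eight `variant_spec` objects.
#' @export
all_variants <- function() {
  out <- list()
  for (alg in c("GD", "MLEM"))
    for (su in c(FALSE, TRUE))
      for (tm in c(FALSE, TRUE))
        out[[length(out) + 1L]] <- variant_spec(alg, su, tm)
  out
}

#' Monte Carlo run configuration
#'
#' Describes one end-to-end solvability-map experiment. Data generation runs
#' on a fine grid (`fine_factor` times the reconstruction resolution, with a
#' matching finer detector) and the reconstruction on the coarse grid, so the
#' forward models for simulation and inversion are never the same operator.
#'
#' @param recon_n Reconstruction grid side (pixels, pixel size 1).
#' @param det_bins,det_offset Physical detector bin count and centre offset
#'   at reconstruction scale (bin width 1 = pixel size).
#' @param n_views,start_deg,step_deg View sampling over 180 degrees.
#' @param n_phantoms Number of random phantoms.
#' @param base_seed Base seed; phantom m uses seed `base_seed + m` and an
#'   independent noise stream `base_seed + m + 1000000`.
#' @param fine_factor Fine-grid refinement and detector bin-down factor.
#' @param noise_enabled,counts_per_unit Poisson noise switch and scale.
#' @param variants List of `variant_spec`s (default [all_variants()]).
#' @param gd_iterations,mlem_iterations,gd_alpha Solver settings
#'   (`gd_alpha = NULL` selects the power-iteration step).
#' @param n_ellipses,param_ranges,smooth_sigma Phantom settings
#'   (see [generate_phantom()]).
#' @param output_dir Optional directory for maps, PNGs and the JSON report.
#' @return An object of class `run_config`.
#' @export
run_config <- function(recon_n = 128L, det_bins = 107L, det_offset = 39,
                       n_views = 180L, start_deg = 0, step_deg = NULL,
                       n_phantoms = 1000L, base_seed = 1L,
                       fine_factor = 3L,
                       noise_enabled = TRUE, counts_per_unit = 500,
                       variants = all_variants(),
                       gd_iterations = 200L, mlem_iterations = 100L,
                       gd_alpha = NULL,
                       n_ellipses = 4L, param_ranges = list(),
                       smooth_sigma = 1.0,
                       output_dir = NULL) {
  if (is.null(step_deg)) step_deg <- 180 / n_views
  stopifnot(n_phantoms >= 1, length(variants) >= 1)
  if (!all(vapply(variants, inherits, logical(1), "variant_spec")))
    stop("run_config: variants must be variant_spec objects")
  structure(list(recon_n = as.integer(recon_n), det_bins = as.integer(det_bins),
                 det_offset = det_offset, n_views = as.integer(n_views),
                 start_deg = start_deg, step_deg = step_deg,
                 n_phantoms = as.integer(n_phantoms),
                 base_seed = as.integer(base_seed),
                 fine_factor = as.integer(fine_factor),
                 noise_enabled = noise_enabled,
                 counts_per_unit = counts_per_unit,
                 variants = variants,
                 gd_iterations = as.integer(gd_iterations),
                 mlem_iterations = as.integer(mlem_iterations),
                 gd_alpha = gd_alpha,
                 n_ellipses = as.integer(n_ellipses),
                 param_ranges = param_ranges, smooth_sigma = smooth_sigma,
                 output_dir = output_dir),
            class = "run_config")
}

#' Preset experiment profiles
#'
#' `"full"` is the publication-scale protocol (128 x 128 reconstruction,
#' 384 x 384 phantoms, 180 views, 1000 phantoms); `"test"` a desk-scale
#' reduction (64 x 64 reconstruction, 192 x 192 phantoms, 90 views, 50
#' phantoms, halved iteration counts). `truncated = TRUE` selects the
#' asymmetric interior-problem detector (107 bins offset +39 at full scale,
#' 53 bins offset +19 at test scale), `FALSE` the symmetric detector that
#' sees the whole object (185 / 93 bins).
#'
#' @param profile "full" or "test".
#' @param truncated Truncated asymmetric detector?
#' @param ... Overrides passed to [run_config()].
#' @return A `run_config`.
#' @export
run_profile <- function(profile = c("test", "full"), truncated = TRUE, ...) {
  profile <- match.arg(profile)
  base <- if (profile == "full") {
    list(recon_n = 128L, n_views = 180L, n_phantoms = 1000L,
         gd_iterations = 200L, mlem_iterations = 100L,
         det_bins = if (truncated) 107L else 185L,
         det_offset = if (truncated) 39 else 0)
  } else {
    list(recon_n = 64L, n_views = 90L, n_phantoms = 50L,
         gd_iterations = 100L, mlem_iterations = 50L,
         det_bins = if (truncated) 53L else 93L,
         det_offset = if (truncated) 19 else 0)
  }
  args <- utils::modifyList(base, list(...))
  do.call(run_config, args)
}

# geometries + operators implied by a config
.build_operators <- function(cfg) {
  f <- cfg$fine_factor
  views <- view_set(cfg$n_views, cfg$start_deg, cfg$step_deg)
  coarse_g <- make_geometry(image_grid(cfg$recon_n, cfg$recon_n, 1.0),
                            detector(cfg$det_bins, 1.0, cfg$det_offset),
                            views)
  fine_g <- make_geometry(image_grid(cfg$recon_n * f, cfg$recon_n * f, 1 / f),
                          detector(cfg$det_bins * f, 1 / f, cfg$det_offset),
                          views)
  # inverse-crime guard: the simulation and reconstruction operators must be
  # distinct discretizations
  stopifnot(fine_g$grid$n_rows != coarse_g$grid$n_rows)
  list(coarse_g = coarse_g, fine_g = fine_g,
       coarse_op = projection_operator(coarse_g),
       fine_op = projection_operator(fine_g))
}

# simulate measurements for phantom m; returns list(truth, sino)
.simulate_phantom <- function(cfg, ops, m) {
  ph <- generate_phantom(cfg$base_seed + m, ops$fine_g$grid,
                         n_ellipses = cfg$n_ellipses,
                         param_ranges = cfg$param_ranges,
                         sigma = cfg$smooth_sigma)
  truth <- downsample_truth(ph, cfg$fine_factor)
  s <- forward_project(ops$fine_op, ph$image)
  if (cfg$noise_enabled)
    s <- add_poisson_noise(s, cfg$counts_per_unit,
                           seed = cfg$base_seed + m + 1000000L)
  list(truth = truth, sino = bin_down(s, cfg$fine_factor))
}

#' Run the Monte Carlo solvability-map experiment
#'
#' For each phantom: generate the fine-grid phantom, forward project with the
#' fine operator, add Poisson noise, bin down 3:1 to the reconstruction-scale
#' detector, reconstruct with every requested algorithm variant on the coarse
#' operator, and accumulate the squared-error images into one solvability map
#' per variant.
#'
#' @param cfg A `run_config`.
#' @param checkpoint Optional path to a checkpoint file, written after every
#'   phantom; see [resume_experiment()].
#' @param progress Print per-phantom progress to stderr?
#' @param stop_after Simulate an interruption: stop (returning `NULL`) once
#'   this many phantoms have been processed and checkpointed. The run can
#'   then be completed with [resume_experiment()].
#' @param .start_state Internal (used by [resume_experiment()]).
#' @return An object of class `run_report`: `maps` (named list of
#'   `solvability_map`s), `table` (one row per variant with min/max/n),
#'   `roi` (Kirillov ROI mask of the coarse geometry), `mean_truth`
#'   (across-phantom mean of the downsampled truths), `config`, `elapsed_sec`,
#'   and `files` when `output_dir` is set.
#' @export
run_experiment <- function(cfg, checkpoint = NULL, progress = FALSE,
                           stop_after = Inf, .start_state = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()
  ops <- .build_operators(cfg)
  vnames <- vapply(cfg$variants, `[[`, character(1), "name")
  if (anyDuplicated(vnames)) stop("run_experiment: duplicate variant names")
  accs <- lapply(vnames, function(nm) map_accumulator(cfg$recon_n, cfg$recon_n))
  names(accs) <- vnames
  truth_acc <- map_accumulator(cfg$recon_n, cfg$recon_n)
  first <- 1L
  if (!is.null(.start_state)) {
    for (nm in vnames) accs[[nm]]$restore(.start_state$accs[[nm]])
    truth_acc$restore(.start_state$truth)
    first <- .start_state$last_done + 1L
  }
  for (m in seq(first, length.out = max(0L, cfg$n_phantoms - first + 1L))) {
    sim <- .simulate_phantom(cfg, ops, m)
    supp <- support_from_truth(sim$truth)
    for (v in cfg$variants) {
      rc <- recon_config(
        algorithm = v$algorithm,
        n_iterations = if (v$algorithm == "GD") cfg$gd_iterations
                       else cfg$mlem_iterations,
        step_size_alpha = if (v$algorithm == "GD") cfg$gd_alpha else NULL,
        use_support = v$support,
        use_truncation_modification = v$trunc_mod,
        support_mask = if (v$support) supp else NULL)
      res <- reconstruct(sim$sino, ops$coarse_op, rc)
      accs[[v$name]]$add(squared_error_image(res$image, sim$truth))
    }
    truth_acc$add(sim$truth)
    if (!is.null(checkpoint)) {
      st <- list(config = cfg, last_done = m,
                 accs = lapply(accs, function(a) a$state()),
                 truth = truth_acc$state())
      saveRDS(st, checkpoint)
    }
    if (progress)
      message(sprintf("phantom %d/%d done", m, cfg$n_phantoms))
    if (m >= stop_after && m < cfg$n_phantoms) {
      if (is.null(checkpoint))
        stop("run_experiment: stop_after without a checkpoint would lose the run")
      return(invisible(NULL))
    }
  }
  maps <- lapply(accs, function(a) a$result())
  tab <- data.frame(
    variant = vnames,
    algorithm = vapply(cfg$variants, `[[`, character(1), "algorithm"),
    support = vapply(cfg$variants, `[[`, logical(1), "support"),
    trunc_mod = vapply(cfg$variants, `[[`, logical(1), "trunc_mod"),
    n = cfg$n_phantoms,
    min = vapply(maps, function(m) m$summary$min, numeric(1)),
    max = vapply(maps, function(m) m$summary$max, numeric(1)),
    row.names = NULL)
  rep <- structure(list(maps = maps, table = tab, roi = roi_mask(ops$coarse_g),
                        mean_truth = truth_acc$result()$values,
                        config = cfg,
                        elapsed_sec = as.numeric(difftime(Sys.time(), t0,
                                                          units = "secs")),
                        files = NULL),
                   class = "run_report")
  if (!is.null(cfg$output_dir)) rep$files <- write_report(rep, cfg$output_dir)
  rep
}

#' Resume an interrupted experiment from a checkpoint
#'
#' Restores the running error sums and continues with the remaining phantoms;
#' because per-phantom seeds are derived from the base seed, the final maps
#' are identical to an uninterrupted run. The checkpoint must have been
#' written for an identical configuration.
#'
#' @param cfg The `run_config` of the original run.
#' @param checkpoint Path to the checkpoint file written by
#'   [run_experiment()]. A missing file behaves as a fresh run.
#' @param progress Print progress?
#' @return A `run_report`.
#' @export
resume_experiment <- function(cfg, checkpoint, progress = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  if (!file.exists(checkpoint))
    return(run_experiment(cfg, checkpoint = checkpoint, progress = progress))
  st <- readRDS(checkpoint)
  cfg_nc <- cfg; cfg_nc$output_dir <- NULL
  st_nc <- st$config; st_nc$output_dir <- NULL
  if (!identical(st_nc, cfg_nc))
    stop("resume_experiment: checkpoint was written for a different configuration")
  run_experiment(cfg, checkpoint = checkpoint, progress = progress,
                 .start_state = st)
}

#' Write a run report to disk
#'
#' Per-variant raw map TIFF + display PNG + JSON sidecar, plus `report.json`
#' with the min/max table, configuration echo and timing.
#'
#' @param rep A `run_report`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths.
#' @export
write_report <- function(rep, dir) {
  stopifnot(inherits(rep, "run_report"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("write_report: cannot create output directory ", dir)
  files <- character(0)
  for (nm in names(rep$maps)) {
    base <- file.path(dir, gsub("[^A-Za-z0-9]+", "_", nm))
    files <- c(files, save_map(rep$maps[[nm]], base))
  }
  cfg <- rep$config
  cfg$variants <- lapply(cfg$variants, unclass)
  report_path <- file.path(dir, "report.json")
  jsonlite::write_json(list(table = rep$table, config = unclass(cfg),
                            elapsed_sec = rep$elapsed_sec),
                       report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  c(files, report_path)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d phantoms, %d variants, %.1f s\n",
              x$config$n_phantoms, nrow(x$table), x$elapsed_sec))
  print(x$table, digits = 4)
  invisible(x)
}

#' Read a run configuration from YAML or JSON
#'
#' Expected keys: `geometry{grid{rows,cols,pixel_size}, detector{bins,
#' bin_width, offset}, views{count, start_deg, step_deg}}`,
#' `phantom{count, seed_base, n_ellipses}`, `noise{enabled, counts_per_unit}`,
#' `recon{gd_iterations, mlem_iterations, variants}` (variants as strings
#' like "GD", "MLEM+S+T"), `output_dir`. Only the reconstruction-scale
#' geometry is given; the fine simulation geometry is derived from it.
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cf <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  geo <- cf$geometry
  if (!is.null(geo$grid$rows) && !is.null(geo$grid$cols) &&
      geo$grid$rows != geo$grid$cols)
    stop("read_run_config: reconstruction grid must be square")
  parse_variant <- function(s) {
    parts <- strsplit(s, "+", fixed = TRUE)[[1]]
    variant_spec(parts[1], support = "S" %in% parts[-1],
                 trunc_mod = "T" %in% parts[-1], name = s)
  }
  args <- list()
  if (!is.null(geo$grid$rows)) args$recon_n <- geo$grid$rows
  if (!is.null(geo$detector$bins)) args$det_bins <- geo$detector$bins
  if (!is.null(geo$detector$offset)) args$det_offset <- geo$detector$offset
  if (!is.null(geo$views$count)) args$n_views <- geo$views$count
  if (!is.null(geo$views$start_deg)) args$start_deg <- geo$views$start_deg
  if (!is.null(geo$views$step_deg)) args$step_deg <- geo$views$step_deg
  if (!is.null(cf$phantom$count)) args$n_phantoms <- cf$phantom$count
  if (!is.null(cf$phantom$seed_base)) args$base_seed <- cf$phantom$seed_base
  if (!is.null(cf$phantom$n_ellipses)) args$n_ellipses <- cf$phantom$n_ellipses
  if (!is.null(cf$noise$enabled)) args$noise_enabled <- cf$noise$enabled
  if (!is.null(cf$noise$counts_per_unit))
    args$counts_per_unit <- cf$noise$counts_per_unit
  if (!is.null(cf$recon$gd_iterations))
    args$gd_iterations <- cf$recon$gd_iterations
  if (!is.null(cf$recon$mlem_iterations))
    args$mlem_iterations <- cf$recon$mlem_iterations
  if (!is.null(cf$recon$variants))
    args$variants <- lapply(unlist(cf$recon$variants), parse_variant)
  if (!is.null(cf$output_dir)) args$output_dir <- cf$output_dir
  do.call(run_config, args)
}
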