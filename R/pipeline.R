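#' Study configuration
#'
#' Factorial augmentation study: synthetic open-cell structures at several
#' porosities x cement viscosity x injection direction, each combination
#' replicated with independent injection seeds.  Per-run seeds are derived
#' deterministically from `base_seed` and the factor indices, so a study is
#' reproducible bit-for-bit.
#'
#' The default injected volume is "auto": the volume that fills the same
#' fraction of the simulation domain as 4 ml fills a 65 x 65 x 40 mm
#' specimen (about 2.37%), so that desk-scale domains see the same relative
#' cement dose as the full-size injection scenario.  Pass `V_cement_ml`
#' explicitly (e.g. `4`) for full-size domains.
#'
#' @param porosities Target porosities of the generated structures.
#' @param shape Grid dimensions (voxels) of each structure.
#' @param voxel_size Voxel edge length, mm.
#' @param correlation_length Strut length scale of the generator, voxels.
#' @param wall_thickness Lateral BONE padding, voxels.
#' @param viscosities Subset of `c("high", "low")`.
#' @param directions Subset of `c("vertical", "diagonal")`.
#' @param replicates Injection replicates per condition.
#' @param base_seed Master seed.
#' @param V_cement_ml Injected volume in ml, or `NULL` for auto scaling.
#' @param fe An [fe_config()] used for baseline and augmented solves.
#' @param max_steps_per_particle Walk length per particle.
#'
#' @return An object of class `study_config`.
#' @export
study_config <- function(porosities = c(0.85, 0.79, 0.69),
                         shape = c(64, 64, 64), voxel_size = 0.16,
                         correlation_length = 3, wall_thickness = 0,
                         viscosities = c("high", "low"),
                         directions = c("vertical", "diagonal"),
                         replicates = 2, base_seed = 1,
                         V_cement_ml = NULL,
                         fe = fe_config(solver_tol = 1e-4),
                         max_steps_per_particle = 200) {
  stopifnot(length(porosities) >= 1, replicates >= 1,
            all(viscosities %in% c("high", "low")),
            all(directions %in% c("vertical", "diagonal")),
            length(viscosities) >= 1, length(directions) >= 1)
  if (is.null(V_cement_ml)) {
    domain_ml <- prod(shape) * voxel_size^3 / 1000
    V_cement_ml <- domain_ml * 4 / (65 * 65 * 40 / 1000)
  }
  structure(
    list(
      porosities = porosities, shape = as.integer(shape),
      voxel_size = voxel_size, correlation_length = correlation_length,
      wall_thickness = as.integer(wall_thickness),
      viscosities = viscosities, directions = directions,
      replicates = as.integer(replicates), base_seed = as.integer(base_seed),
      V_cement_ml = V_cement_ml, fe = fe,
      max_steps_per_particle = as.integer(max_steps_per_particle)
    ),
    class = "study_config"
  )
}

#' Read a study configuration from YAML
#'
#' Recognized keys mirror the arguments of [study_config()]; `fe` may be a
#' nested mapping with [fe_config()] arguments.
#'
#' @param path YAML file.
#' @return A [study_config()].
#' @export
study_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  fe_args <- y$fe %||% list()
  y$fe <- do.call(fe_config, fe_args)
  do.call(study_config, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an augmentation study
#'
#' For every structure the pipeline generates the open-cell grid, solves the
#' unaugmented baseline compression, then for each viscosity x direction x
#' replicate runs the particle injection, re-solves the augmented grid
#' (warm-started from the baseline displacement field) and computes cement
#' cloud metrics.  Per-run failures (blocked injections, singular systems)
#' are recorded in the `error` column without aborting the sweep.
#'
#' @param config A [study_config()].
#' @param progress Print one line per run.
#' @return An object of class `study_result`: a list with `records`
#'   (one tibble row per run) and the `config` echo.
#' @export
#' @examples
#' \donttest{
#' cfg <- study_config(porosities = 0.85, shape = c(24, 24, 24),
#'                     replicates = 1, directions = "vertical")
#' res <- run_study(cfg)
#' res$records$improvement_pct
#' }
run_study <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  rows <- list()
  for (s in seq_along(config$porosities)) {
    por <- config$porosities[s]
    sseed <- derive_seed(config$base_seed, 91, s)
    spec <- structure_spec(
      shape = config$shape, target_porosity = por,
      correlation_length = config$correlation_length, seed = sseed,
      wall_thickness = config$wall_thickness, voxel_size = config$voxel_size
    )
    grid <- generate_open_cell(spec)
    base_sol <- fe_solve(grid, config$fe)
    entry <- find_entry(grid)
    sid <- sprintf("P%02.0f", 100 * por)

    for (v in seq_along(config$viscosities)) {
      for (dr in seq_along(config$directions)) {
        for (r in seq_len(config$replicates)) {
          run_seed <- derive_seed(config$base_seed, s, v, dr, r)
          rec <- run_one(grid, base_sol, entry, sid, por, spec,
                         config$viscosities[v], config$directions[dr], r,
                         run_seed, config)
          if (progress) {
            cat(sprintf("%s %-4s %-8s rep %d: dE = %s\n", sid,
                        config$viscosities[v], config$directions[dr], r,
                        format(rec$improvement_pct, digits = 4)))
          }
          rows[[length(rows) + 1L]] <- rec
        }
      }
    }
  }
  structure(
    list(records = dplyr::bind_rows(rows), config = config),
    class = "study_result"
  )
}

run_one <- function(grid, base_sol, entry, sid, por, spec,
                    viscosity, direction, replicate, run_seed, config) {
  rec <- tibble::tibble(
    structure_id = sid,
    porosity_target = por,
    porosity_achieved = attr(grid, "interior_porosity"),
    viscosity = viscosity,
    direction = direction,
    replicate = replicate,
    seed = run_seed,
    E_base = base_sol$apparent_modulus,
    E_aug = NA_real_,
    improvement_pct = NA_real_,
    sphericity = NA_real_,
    n_components = NA_integer_,
    n_requested = NA_real_,
    n_settled = NA_real_,
    n_blocked = NA_real_,
    fill_fraction = NA_real_,
    elapsed_s = NA_real_,
    error = NA_character_
  )
  t_start <- Sys.time()
  tryCatch({
    icfg <- injection_config(
      V_cement_ml = config$V_cement_ml, viscosity = viscosity,
      direction = direction, entry = entry, seed = run_seed,
      max_steps_per_particle = config$max_steps_per_particle
    )
    inj <- run_injection(grid, icfg)
    aug_sol <- fe_solve(inj$grid, config$fe)
    met <- cloud_metrics(inj$grid)
    rec$E_aug <- aug_sol$apparent_modulus
    rec$improvement_pct <- improvement(aug_sol$apparent_modulus,
                                       base_sol$apparent_modulus)
    rec$sphericity <- met$sphericity
    rec$n_components <- met$n_components
    rec$n_requested <- inj$result$n_requested
    rec$n_settled <- inj$result$n_settled
    rec$n_blocked <- inj$result$n_blocked
    rec$fill_fraction <- fill_fraction(grid, inj$grid)
    rec$elapsed_s <- as.numeric(Sys.time() - t_start, units = "secs")
    rec
  }, error = function(e) {
    rec$error <- conditionMessage(e)
    rec$elapsed_s <- as.numeric(Sys.time() - t_start, units = "secs")
    rec
  })
}

#' Condition-level summary of a study
#'
#' Mean and spread of the improvement and sphericity per
#' (structure, viscosity, direction) condition.  Two spread measures are
#' reported: the sample standard deviation (n - 1 denominator, `NA` for a
#' single replicate) and the half-range `(max - min) / 2`.
#'
#' @param result A `study_result` from [run_study()].
#' @return A tibble with one row per condition.
#' @export
summarize_study <- function(result) {
  stopifnot(inherits(result, "study_result"))
  rec <- dplyr::filter(result$records, is.na(.data$error))
  if (nrow(rec) == 0) stop("no successful runs to summarize", call. = FALSE)
  dplyr::summarise(
    dplyr::group_by(rec, .data$structure_id, .data$porosity_target,
                    .data$viscosity, .data$direction),
    n = dplyr::n(),
    mean_improvement = mean(.data$improvement_pct),
    sd_improvement = sd(.data$improvement_pct),
    halfrange_improvement =
      (max(.data$improvement_pct) - min(.data$improvement_pct)) / 2,
    mean_sphericity = mean(.data$sphericity),
    sd_sphericity = sd(.data$sphericity),
    .groups = "drop"
  )
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d runs (%d failed)\n",
              nrow(x$records), sum(!is.na(x$records$error))))
  print(summarize_study(x))
  invisible(x)
}

#' @export
tidy.study_result <- function(x, ...) x$records

#' @export
glance.study_result <- function(x, ...) {
  rec <- dplyr::filter(x$records, is.na(.data$error))
  tibble::tibble(
    n_runs = nrow(x$records),
    n_failed = sum(!is.na(x$records$error)),
    mean_improvement = mean(rec$improvement_pct),
    min_improvement = min(rec$improvement_pct),
    max_improvement = max(rec$improvement_pct),
    mean_sphericity = mean(rec$sphericity)
  )
}

#' Write study outputs to a directory
#'
#' Emits `records.csv`, `summary.csv` and `config.json` (configuration echo
#' with package version for provenance).
#'
#' @param result A `study_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(result, dir) {
  stopifnot(inherits(result, "study_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$records, file.path(dir, "records.csv"), row.names = FALSE)
  write.csv(summarize_study(result), file.path(dir, "summary.csv"),
            row.names = FALSE)
  cfg <- result$config
  cfg$fe <- unclass(cfg$fe)
  echo <- c(unclass(cfg), list(voxcem_version = as.character(utils::packageVersion("voxcem"))))
  jsonlite::write_json(echo, file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
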