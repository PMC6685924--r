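#' Run configuration for the end-to-end pipeline
#'
#' Collects every knob of the workflow: the ADD, packing size, target ECS
#' fraction, replicate count, seeds, solver resolution and sweep
#' parameters. All randomness is driven by the explicit `seeds` vector.
#'
#' @param add An [add_spec()] (default: the calibrated white-matter-like
#'   fixture ADD).
#' @param n_discs Discs per replicate geometry.
#' @param alpha_target Target ECS fraction reached by shrinking.
#' @param n_replicates Number of replicate geometries.
#' @param seeds Integer seeds, one per replicate (default `1:n_replicates`).
#' @param fill If `TRUE`, run the void-filling stage before shrinking (the
#'   full workflow); if `NULL` (default) it runs only when `alpha_target`
#'   is below the packed ECS fraction, since shrinking alone can reach any
#'   higher fraction.
#' @param alpha_fill_stop Void-filling target (only used when filling).
#' @param resolution Flow-solver cell size (um).
#' @param n_divisions,n_used RVE sweep parameters.
#' @param plateau_tol,cv_tol RVE selection tolerances.
#' @param entrance_length,exit_length Channel margins (um; `NULL` = one
#'   channel height).
#' @param out_dir Output directory for artefacts.
#' @return A `run_config`.
#' @export
run_config <- function(add = calibrated_add(), n_discs = 500,
                       alpha_target = 0.30, n_replicates = 2,
                       seeds = seq_len(n_replicates), fill = NULL,
                       alpha_fill_stop = 0.15, resolution = 0.04,
                       n_divisions = 20, n_used = 16,
                       plateau_tol = 0.05, cv_tol = 0.05,
                       entrance_length = NULL, exit_length = NULL,
                       out_dir = tempfile("axonperm_run_")) {
  stopifnot(inherits(add, "add_spec"))
  if (alpha_target <= 0.15 || alpha_target >= 0.9)
    stop("run_config: alpha_target must lie in (0.15, 0.9)", call. = FALSE)
  if (length(seeds) != n_replicates)
    stop("run_config: need one seed per replicate", call. = FALSE)
  structure(list(add = add, n_discs = n_discs, alpha_target = alpha_target,
                 n_replicates = n_replicates, seeds = as.integer(seeds),
                 fill = fill, alpha_fill_stop = alpha_fill_stop,
                 resolution = resolution, n_divisions = n_divisions,
                 n_used = n_used, plateau_tol = plateau_tol, cv_tol = cv_tol,
                 entrance_length = entrance_length,
                 exit_length = exit_length, out_dir = out_dir),
            class = "run_config")
}

stage_log <- function(stage, seed, elapsed, ...) {
  extra <- paste(vapply(list(...), function(z) paste(z, collapse = ","),
                        character(1)),
                 collapse = " ")
  message(sprintf("[axonperm] stage=%s seed=%s elapsed=%.2fs %s",
                  stage, paste(seed, collapse = ","), elapsed, extra))
}

#' Run the full permeability pipeline
#'
#' Executes, per replicate seed: advancing-front packing, (optionally)
#' skeleton-guided void filling, shrinking to the target ECS fraction and a
#' spatial-randomness check of the disc centres; then solves creeping flow
#' through every replicate, runs the nested-window permeability sweep and
#' selects the RVE. All artefacts are written under `config$out_dir` and
#' listed in the returned manifest. Re-running with the same configuration
#' reproduces the geometry files byte for byte.
#'
#' @param config A [run_config()].
#' @return A `run_manifest` list: per-stage status, artefact paths, the
#'   sweep, the RVE selection and a summary.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config, stages = list(), artefacts = list())
  geoms <- vector("list", config$n_replicates)

  # --- geometry stage -------------------------------------------------
  t0 <- proc.time()[3]
  stage_ok <- TRUE
  for (i in seq_len(config$n_replicates)) {
    sd <- config$seeds[i]
    res <- tryCatch({
      g <- advancing_front_pack(config$add, config$n_discs, seed = sd)
      do_fill <- if (is.null(config$fill)) config$alpha_target < g$alpha
                 else isTRUE(config$fill)
      if (do_fill)
        g <- fill_voids(g, config$add, alpha_stop = config$alpha_fill_stop,
                        seed = sd)
      if (config$alpha_target > g$alpha)
        g <- shrink_to_porosity(g, config$alpha_target)
      g
    }, error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages$geometry <- list(status = "failed",
                                       error = conditionMessage(res))
      stage_ok <- FALSE
      break
    }
    geoms[[i]] <- res
    path <- file.path(config$out_dir, sprintf("geometry_seed%03d.csv", sd))
    write_geometry(res, path)
    manifest$artefacts$geometry <- c(manifest$artefacts$geometry, path)
  }
  if (stage_ok) {
    manifest$stages$geometry <- list(
      status = "ok",
      alpha = vapply(geoms, function(g) g$alpha, numeric(1)))
    stage_log("geometry", config$seeds, proc.time()[3] - t0,
              sprintf("n_discs=%d", config$n_discs),
              sprintf("alpha=%s",
                      paste(signif(manifest$stages$geometry$alpha, 4),
                            collapse = ",")))
  } else {
    manifest$stages$spatial <- manifest$stages$flow <-
      manifest$stages$sweep <- list(status = "skipped")
    class(manifest) <- "run_manifest"
    return(manifest)
  }

  # --- spatial stage --------------------------------------------------
  t0 <- proc.time()[3]
  spatial <- lapply(seq_along(geoms), function(i) {
    g <- geoms[[i]]
    pp <- point_pattern(as.matrix(g$discs[, c("x", "y")]), g$domain)
    cls <- csr_classify(pp)
    path <- file.path(config$out_dir,
                      sprintf("ripley_seed%03d.csv", config$seeds[i]))
    write_ripley_result(cls$result, path)
    list(slope = cls$slope, classification = cls$classification, path = path)
  })
  manifest$stages$spatial <- list(
    status = "ok",
    slope = vapply(spatial, `[[`, numeric(1), "slope"),
    classification = vapply(spatial, `[[`, character(1), "classification"))
  manifest$artefacts$ripley <- vapply(spatial, `[[`, character(1), "path")
  stage_log("spatial", config$seeds, proc.time()[3] - t0,
            sprintf("slope=%s",
                    paste(signif(manifest$stages$spatial$slope, 4),
                          collapse = ",")))

  # --- flow + sweep stage ---------------------------------------------
  t0 <- proc.time()[3]
  bc <- flow_bc()
  sweep <- tryCatch(
    rve_sweep(geoms, bc, resolution = config$resolution,
              n_divisions = config$n_divisions, n_used = config$n_used,
              entrance_length = config$entrance_length,
              exit_length = config$exit_length),
    error = function(e) e)
  if (inherits(sweep, "error")) {
    manifest$stages$flow <- list(status = "failed",
                                 error = conditionMessage(sweep))
    manifest$stages$sweep <- list(status = "skipped")
    class(manifest) <- "run_manifest"
    return(manifest)
  }
  manifest$stages$flow <- list(status = "ok")
  sel <- tryCatch(
    select_rve(sweep, plateau_tol = config$plateau_tol,
               cv_tol = config$cv_tol),
    error = function(e)
      list(found = FALSE,
           criteria = list(plateau_tol = config$plateau_tol,
                           cv_tol = config$cv_tol),
           note = conditionMessage(e)))
  csv <- file.path(config$out_dir, "rve_sweep.csv")
  jsn <- file.path(config$out_dir, "rve_selection.json")
  write_rve_sweep(sweep, sel, csv, jsn)
  manifest$artefacts$sweep <- csv
  manifest$artefacts$selection <- jsn
  manifest$stages$sweep <- list(status = "ok", found = sel$found)
  manifest$sweep <- sweep
  manifest$selection <- sel
  manifest$summary <- list(
    alpha = vapply(geoms, function(g) g$alpha, numeric(1)),
    csr_slope = manifest$stages$spatial$slope,
    rve_um = if (isTRUE(sel$found)) sel$rve_um else NA_real_,
    k_m2 = if (isTRUE(sel$found)) sel$k_m2 else NA_real_)
  stage_log("sweep", config$seeds, proc.time()[3] - t0,
            sprintf("rve=%s k=%s", format(manifest$summary$rve_um),
                    format(manifest$summary$k_m2)))
  jsonlite::write_json(manifest$summary,
                       file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  class(manifest) <- "run_manifest"
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("axonperm pipeline manifest\n")
  for (s in names(x$stages))
    cat(sprintf("  %-8s %s\n", s, x$stages[[s]]$status))
  if (!is.null(x$summary)) {
    cat(sprintf("  alpha: %s\n",
                paste(signif(x$summary$alpha, 4), collapse = ", ")))
    if (is.finite(x$summary$rve_um))
      cat(sprintf("  RVE %.3g um, k = %.4g m^2\n",
                  x$summary$rve_um, x$summary$k_m2))
  }
  invisible(x)
}
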