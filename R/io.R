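#' Write / read a disc geometry (CSV + JSON sidecar)
#'
#' The CSV holds `id,x_um,y_um,r_um`; the sidecar (`<path>.json`) records
#' the domain, ECS fraction, seed, provenance and the ADD parameters.
#'
#' @param geom A [geometry()].
#' @param path CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "geometry"))
  d <- geom$discs
  df <- data.frame(id = seq_len(nrow(d)), x_um = d$x, y_um = d$y, r_um = d$r)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(domain = geom$domain, alpha = geom$alpha,
               seed = if (is.na(geom$seed)) NULL else geom$seed,
               provenance = geom$provenance, gap_tol = geom$gap_tol)
  if (!is.null(geom$add))
    meta$add <- geom$add[c("family", "meanlog", "sdlog", "d_min", "d_max",
                           "myelin_offset")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_geometry
#' @param check Passed to [geometry()].
#' @export
read_geometry <- function(path, check = TRUE) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  add <- NULL
  if (!is.null(meta$add) && identical(meta$add$family, "lognormal"))
    add <- add_spec("lognormal", meanlog = meta$add$meanlog,
                    sdlog = meta$add$sdlog, d_min = meta$add$d_min,
                    d_max = meta$add$d_max,
                    myelin_offset = meta$add$myelin_offset)
  geometry(data.frame(x = df$x_um, y = df$y_um, r = df$r_um),
           domain = as.numeric(meta$domain),
           seed = if (is.null(meta$seed)) NA_integer_ else as.integer(meta$seed),
           provenance = meta$provenance, add = add,
           gap_tol = if (is.null(meta$gap_tol)) 1e-4 else meta$gap_tol,
           check = check)
}

#' Export a binary ECS mask as a PNG image plus JSON metadata
#'
#' White pixels are ECS. The resolution and origin go to `<path>.json`.
#'
#' @param mask A `binary_mask`.
#' @param path PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  # image row 1 = top of the domain
  img <- t(mask$mask)[ncol(mask$mask):1, , drop = FALSE]
  png::writePNG(img * 1, path)
  jsonlite::write_json(list(resolution_um = mask$resolution,
                            origin = mask$origin, domain = mask$domain),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a point pattern / Ripley result to CSV
#' @param pattern A [point_pattern()].
#' @param path CSV path (`x,y` columns; window in `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_point_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "point_pattern"))
  write.csv(data.frame(x = pattern$points[, 1], y = pattern$points[, 2]),
            path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(window = pattern$window), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_point_pattern
#' @export
read_point_pattern <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  point_pattern(cbind(df$x, df$y), as.numeric(meta$window))
}

#' @rdname write_point_pattern
#' @param result A `ripley_result`.
#' @export
write_ripley_result <- function(result, path) {
  stopifnot(inherits(result, "ripley_result"))
  write.csv(data.frame(t = result$t, R = result$R, L = result$L),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a flow solution on its grid as a legacy-VTK file
#'
#' Writes `STRUCTURED_POINTS` ASCII VTK with cell-centred `u`, `v`
#' velocities (m/s) and pressure (Pa; solid cells carry 0).
#'
#' @param sol A `flow_solution`.
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_flow_vtk <- function(sol, path) {
  stopifnot(inherits(sol, "flow_solution"))
  uc <- cell_velocity(sol)
  vc <- (sol$v[, 1:sol$ny, drop = FALSE] +
           sol$v[, 2:(sol$ny + 1), drop = FALSE]) / 2
  p <- sol$p; p[is.na(p)] <- 0
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "axonperm creeping-flow solution", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", sol$nx, sol$ny),
               sprintf("ORIGIN %g %g 0", sol$h / 2, sol$h / 2),
               sprintf("SPACING %g %g 1", sol$h, sol$h),
               sprintf("POINT_DATA %d", sol$nx * sol$ny),
               "SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(as.numeric(p), digits = 9), con)
  writeLines(c("VECTORS velocity double"), con)
  vel <- cbind(as.numeric(uc), as.numeric(vc), 0)
  writeLines(apply(vel, 1, function(z) paste(format(z, digits = 9),
                                             collapse = " ")), con)
  invisible(path)
}

#' Write an RVE sweep and its selection to CSV / JSON
#' @param sweep An `rve_sweep`.
#' @param selection A [select_rve()] result.
#' @param csv_path,json_path Output paths.
#' @return `csv_path`, invisibly.
#' @export
write_rve_sweep <- function(sweep, selection, csv_path, json_path) {
  stopifnot(inherits(sweep, "rve_sweep"))
  write.csv(data.frame(size_um = sweep$sizes, k_mean_m2 = sweep$k_mean,
                       k_std_m2 = sweep$k_sd, n = sweep$n),
            csv_path, row.names = FALSE, quote = FALSE)
  out <- if (isTRUE(selection$found))
    list(rve_um = selection$rve_um, k_m2 = selection$k_m2,
         criteria = selection$criteria)
  else list(rve_um = NULL, k_m2 = NULL, criteria = selection$criteria,
            note = "no window size met the RVE criteria")
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(csv_path)
}

#' Flat key-value run configuration
#'
#' Plain-text `key = value` lines (TOML-like scalars only; `#` comments).
#' Unit-bearing keys carry the unit in their name, e.g.
#' `inlet_velocity_m_per_s`.
#'
#' @param path File path.
#' @return Named list with numbers parsed as numeric.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("read_config: bad line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else gsub('^"|"$', "", val)
  }
  out
}

#' @rdname read_config
#' @param config Named list of scalar values.
#' @export
write_config <- function(config, path) {
  fmt <- vapply(names(config), function(k) {
    v <- config[[k]]
    if (is.character(v)) sprintf('%s = "%s"', k, v)
    else sprintf("%s = %.17g", k, as.numeric(v))
  }, character(1))
  writeLines(fmt, path)
  invisible(path)
}
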