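#' Write a cone mosaic to CSV with a JSON metadata sidecar
#'
#' The CSV has header `x_um,y_um`; metadata (rmf, laterality, occlusion
#' radius, provenance) goes to `<path-without-ext>.json`.
#'
#' @param mosaic A [cone_mosaic].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mosaic <- function(mosaic, path) {
  stopifnot(inherits(mosaic, "cone_mosaic"))
  df <- data.frame(x_um = mosaic$x, y_um = mosaic$y)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(rmf_um_per_deg = mosaic$rmf, laterality = mosaic$laterality,
               occlusion_radius_um = mosaic$occlusion_radius,
               provenance = mosaic$provenance)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read a cone mosaic from CSV (+ optional JSON sidecar)
#'
#' @param path CSV path with header `x_um,y_um`. A sidecar JSON (same name,
#'   `.json` extension) supplies metadata; when absent, defaults are used
#'   with a warning (rmf 291 um/deg, laterality `"synthetic"`).
#' @return A [cone_mosaic].
#' @export
read_mosaic <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  if (!identical(names(df), c("x_um", "y_um")))
    stop("mosaic CSV must have exactly the header `x_um,y_um`")
  bad <- which(!is.finite(df$x_um) | !is.finite(df$y_um))
  if (length(bad))
    stop("malformed (non-finite) coordinates at line(s): ",
         paste(bad + 1L, collapse = ", "))
  dup <- which(duplicated(df))
  if (length(dup))
    stop("duplicate coordinates at line(s): ",
         paste(dup + 1L, collapse = ", "))
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    cone_mosaic(df$x_um, df$y_um,
                rmf = meta$rmf_um_per_deg %||% 291,
                laterality = meta$laterality %||% "synthetic",
                occlusion_radius = meta$occlusion_radius_um,
                provenance = meta$provenance %||% path)
  } else {
    warning("no metadata sidecar found; using defaults (rmf = 291 um/deg)")
    cone_mosaic(df$x_um, df$y_um, provenance = path)
  }
}

#' Write / read a density profile as CSV with a JSON sidecar
#'
#' @param profile A [density_profile].
#' @param path Output CSV path (`eccentricity_um,density`).
#' @return `path` invisibly ([write_profile()]); a [density_profile]
#'   ([read_profile()]).
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "density_profile"))
  df <- data.frame(eccentricity_um = profile$eccentricity,
                   density = profile$density)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(kind = profile$kind, bin_width_um = profile$bin_width,
               normalized = profile$normalized, d0_ref = profile$d0_ref)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  sc <- sidecar_path(path)
  meta <- if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE)
  else list()
  density_profile(df$eccentricity_um, df$density,
                  kind = meta$kind %||% "radial",
                  bin_width = meta$bin_width_um %||% NA_real_,
                  normalized = isTRUE(meta$normalized),
                  d0_ref = meta$d0_ref %||% NA_real_)
}

#' Coefficient of determination of a simple linear regression
#'
#' R-squared of ordinary least squares of `y` on `x`; symmetric in its
#' arguments for simple regression.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return R-squared in \[0, 1\].
#' @export
metric_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3")
  if (stats::sd(x) == 0) stop("x is constant; R^2 is undefined")
  summary(stats::lm(y ~ x))$r.squared
}

#' Run the full topography pipeline on a synthetic cohort
#'
#' Generates a cohort of synthetic fellow-eye mosaic pairs (central
#' densities correlated between fellow eyes), and for each eye computes the
#' density map, topography metrics (PCD, CDC, D0, top-20% area), the radial
#' profile, its sigmoid fit, and the rugosity at selected eccentricities.
#' The left-eye radial profiles feed a normative reference. Artifacts are
#' written under `out_dir` when given.
#'
#' @param n_subjects Number of subjects (two eyes each), default 2.
#' @param seed Integer RNG seed driving the whole cohort.
#' @param field_radius Mosaic field radius (um), default 180.
#' @param grid_spacing Density map grid spacing (um), default 3.
#' @param d0_mean,d0_sd Cohort central-density distribution (cones/mm^2).
#' @param fellow_eye_cor Correlation of fellow-eye central densities
#'   (default 0.97).
#' @param rugosity_amplitude Generator angular modulation (default 0.15).
#' @param rugosity_ecc Eccentricities (um) for the rugosity analysis.
#' @param out_dir Output directory for per-eye artifacts, or `NULL`.
#' @return A `cohort_summary`: per-eye data frame `eyes`, list `metrics`,
#'   list `fits`, the `reference` (or `NULL` if fewer than 3 left eyes),
#'   and `fellow_eye_r2` for D0 (when `n_subjects >= 3`).
#' @export
run_pipeline <- function(n_subjects = 2, seed = 1, field_radius = 180,
                         grid_spacing = 3, d0_mean = 175474, d0_sd = 20543,
                         fellow_eye_cor = 0.97, rugosity_amplitude = 0.15,
                         rugosity_ecc = c(40, 90),
                         out_dir = NULL) {
  stopifnot(n_subjects >= 1)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  d0s <- with_seed(seed, {
    z1 <- stats::rnorm(n_subjects)
    z2 <- fellow_eye_cor * z1 +
      sqrt(1 - fellow_eye_cor^2) * stats::rnorm(n_subjects)
    cbind(OS = d0_mean + d0_sd * z1, OD = d0_mean + d0_sd * z2)
  })
  d0s <- pmin(pmax(d0s, 120000), 230000)

  eyes <- list(); metrics <- list(); fits <- list(); profiles <- list()
  rug <- list()
  eye_id <- 0L
  for (s in seq_len(n_subjects)) for (lat in c("OS", "OD")) {
    eye_id <- eye_id + 1L
    cfg <- generator_config(d0 = d0s[s, lat], field_radius = field_radius,
                            rugosity_amplitude = rugosity_amplitude,
                            seed = seed * 1000L + eye_id)
    mosaic <- generate_mosaic(cfg)
    mosaic$laterality <- lat
    map <- compute_density_map(mosaic, grid_spacing = grid_spacing)
    tm <- compute_cdc(map)
    rp <- radial_profile(map, tm$cdc_location)
    ft <- fit_profile(rp, fix_d0 = tm$d0)
    rg <- try(analyze_rugosity(map, tm$cdc_location, tm$d0,
                               eccentricities = rugosity_ecc), silent = TRUE)
    if (inherits(rg, "try-error")) rg <- NULL
    tag <- sprintf("S%02d_%s", s, lat)
    if (!is.null(out_dir)) {
      write_mosaic(mosaic, file.path(out_dir, paste0(tag, "_mosaic.csv")))
      write_profile(rp, file.path(out_dir, paste0(tag, "_radial.csv")))
      jsonlite::write_json(
        list(pcd = tm$pcd, cdc = tm$cdc_location, d0 = tm$d0,
             isoa_top20 = tm$isoa_top20,
             fit = unclass(ft$params),
             mean_abs_rel_error = ft$mean_abs_rel_error),
        file.path(out_dir, paste0(tag, "_metrics.json")),
        auto_unbox = TRUE, digits = NA)
    }
    eyes[[eye_id]] <- data.frame(
      subject = s, laterality = lat, true_d0 = d0s[s, lat],
      n_cones = n_cones(mosaic), pcd = tm$pcd, d0 = tm$d0,
      isoa_top20 = tm$isoa_top20,
      fit_a = ft$params$a, fit_b = ft$params$b, fit_c = ft$params$c,
      fit_error = ft$mean_abs_rel_error)
    metrics[[eye_id]] <- tm
    fits[[eye_id]] <- ft
    profiles[[eye_id]] <- rp
    rug[[eye_id]] <- rg
  }
  eyes <- do.call(rbind, eyes)
  os <- eyes$laterality == "OS"
  reference <- if (sum(os) >= 3) {
    # resample left-eye profiles onto a common grid before pooling
    common <- seq(0, min(vapply(profiles[os], function(p)
      max(p$eccentricity), numeric(1))), by = grid_spacing)
    pr <- lapply(profiles[os], function(p)
      density_profile(common,
                      stats::approx(p$eccentricity, p$density, common)$y,
                      kind = "radial", bin_width = grid_spacing))
    radii <- c(25, 75)
    radii <- radii[radii + 50 <= max(common)]
    if (length(radii))
      build_normative_reference(pr, eyes$d0[os], radii = radii)
    else NULL
  } else NULL
  r2 <- if (n_subjects >= 3)
    metric_correlation(eyes$d0[os], eyes$d0[!os]) else NA_real_
  structure(list(eyes = eyes, metrics = metrics, fits = fits,
                 rugosity = rug, reference = reference,
                 fellow_eye_r2_d0 = r2, seed = seed),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary: %d eyes\n", nrow(x$eyes)))
  print(x$eyes[, c("subject", "laterality", "n_cones", "pcd", "d0",
                   "fit_a", "fit_b", "fit_c", "fit_error")],
        row.names = FALSE)
  if (!is.na(x$fellow_eye_r2_d0))
    cat(sprintf("fellow-eye D0 R^2 = %.3f\n", x$fellow_eye_r2_d0))
  invisible(x)
}
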