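#' Plan a few-view reconstruction experiment
#'
#' Describes a grid of (view count, scheme) reconstruction runs under a
#' shared fan-beam geometry and phantom. Defaults reproduce the reference
#' study conditions: a 128 x 128 modified Shepp-Logan phantom on a 20 cm
#' field, source radius 57 cm, a 128-element detector of length 20 cm,
#' view counts 25/35/45/55, p = 1, a 20000-iteration budget and a 0.1
#' percent RRE stopping threshold. The plan defaults to `alpha0 = 1`: the
#' operator-norm bound behind [estimate_alpha] is tight for this projector
#' (bound/true-norm ratio about 1.03 by power iteration), so `alpha0 = 2`
#' over-relaxes the definitional step scale by a factor of two and the
#' iteration stalls; the method's own calibration rule — reduce `alpha0`
#' until the iteration converges — lands at 1.0 for the study runs.
#'
#' @param view_counts integer vector of projection counts.
#' @param schemes character vector of scheme labels (see [reconstruct]).
#' @param noise_level Gaussian noise level as a fraction of the maximum
#'   measurement (0 = noise-free; 0.001 = "0.1 percent noise").
#' @param n phantom grid side (pixels).
#' @param n_detectors,source_radius,detector_length,fov geometry, see
#'   [fan_geometry].
#' @param p,alpha0,max_iter,rre_stop solver settings, see [reconstruct].
#' @param seed RNG seed for the noise realization.
#' @return An `experiment_plan` list.
#' @export
experiment_plan <- function(view_counts = c(25L, 35L, 45L, 55L),
                            schemes = c("A", "B", "C"),
                            noise_level = 0, n = 128L, n_detectors = 128L,
                            source_radius = 57, detector_length = 20,
                            fov = 20, p = 1, alpha0 = 1,
                            max_iter = 20000L, rre_stop = 0.1, seed = 1L) {
  if (length(view_counts) && any(view_counts < 1)) {
    stop("`view_counts` must be positive", call. = FALSE)
  }
  if (noise_level < 0) stop("`noise_level` must be >= 0", call. = FALSE)
  structure(
    list(view_counts = as.integer(view_counts), schemes = schemes,
         noise_level = noise_level, n = as.integer(n),
         n_detectors = as.integer(n_detectors),
         source_radius = source_radius, detector_length = detector_length,
         fov = fov, p = p, alpha0 = alpha0,
         max_iter = as.integer(max_iter), rre_stop = rre_stop,
         seed = as.integer(seed)),
    class = "experiment_plan")
}

#' Run a few-view reconstruction experiment
#'
#' For each view count the fan-beam system matrix is built once and the
#' phantom's sinogram simulated (with Gaussian noise added when the plan
#' asks for it); every scheme in the plan is then run on that data and its
#' stopping iteration and final RRE recorded, one table row per (views,
#' scheme) cell. Noisy runs are labelled with an `N` suffix (`AN`, `BN`,
#' ...). When `out_dir` is given, the summary table, per-run convergence
#' logs (CSV) and windowed image renderings (PNG, display window
#' `[0, 0.5]`; requires the `png` package) are written there. A run that
#' errors (e.g. diverges) keeps its row with `NA` results; completed rows
#' are preserved.
#'
#' @param plan an [experiment_plan].
#' @param out_dir output directory, or `NULL` for no files.
#' @param verbose print one line per run.
#' @return A tibble with columns `views`, `scheme`, `stop_iteration`,
#'   `final_rre_percent`.
#' @export
run_experiment <- function(plan, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(plan, "experiment_plan"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  truth <- shepp_logan(plan$n, fov = plan$fov)
  noisy <- plan$noise_level > 0
  rows <- list()
  for (v in plan$view_counts) {
    geom <- fan_geometry(v, plan$n_detectors, plan$source_radius,
                         plan$detector_length)
    sys <- build_system_matrix(geom, plan$n, fov = plan$fov)
    g <- forward_project(sys, truth)
    if (noisy) {
      g <- add_noise(g, plan$noise_level, seed = plan$seed + v)
    }
    for (sc in plan$schemes) {
      label <- if (noisy) paste0(sc, "N") else sc
      rec <- tryCatch(
        reconstruct(sys, g, scheme = sc, f_true = truth, p = plan$p,
                    alpha0 = plan$alpha0, max_iter = plan$max_iter,
                    rre_stop = plan$rre_stop),
        error = function(e) {
          warning(sprintf("run %s/%d views failed: %s", label, v,
                          conditionMessage(e)), call. = FALSE)
          NULL
        })
      it <- if (is.null(rec)) NA_integer_ else rec$iterations
      err <- if (is.null(rec)) NA_real_ else rec$final_rre
      rows[[length(rows) + 1L]] <- tibble::tibble(
        views = v, scheme = label, stop_iteration = it,
        final_rre_percent = err)
      if (verbose) {
        message(sprintf("views %3d scheme %-3s -> %s (%s)", v, label,
                        if (is.na(it)) "failed" else it,
                        if (is.na(err)) "-" else sprintf("%.4f%%", err)))
      }
      if (!is.null(out_dir) && !is.null(rec)) {
        stem <- file.path(out_dir, sprintf("views%02d_scheme%s", v, label))
        utils::write.csv(tidy(rec), paste0(stem, "_convergence.csv"),
                         row.names = FALSE)
        if (requireNamespace("png", quietly = TRUE)) {
          png::writePNG(render_image(rec$image, c(0, 0.5)),
                        paste0(stem, ".png"))
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    tibble::tibble(views = integer(), scheme = character(),
                   stop_iteration = integer(), final_rre_percent = double())
  }
  if (!is.null(out_dir)) {
    utils::write.csv(out, file.path(out_dir, "results.csv"), row.names = FALSE)
  }
  out
}
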