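#' Default demo pipeline configuration
#'
#' @param seed master seed.
#' @param size scene size (small by default so the demo runs in seconds).
#' @return Nested configuration list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L, size = 48L) {
  list(seed = seed,
       scene = list(size = size, n_sites = 25L),
       stages = list(simulate = TRUE, ratios = TRUE, converge = TRUE,
                     field = TRUE, stats = TRUE, diffmap = TRUE),
       field = list(grid = 20L, plane = c(1L, 2L)),
       diffmap = list(threshold = 15, dim = 1.5))
}

#' Run the full analysis pipeline
#'
#' simulate -> ratios -> converge -> field -> stats -> diffmap, writing all
#' artifacts plus a manifest to `out_dir`.  Deterministic for a fixed
#' configuration: re-running into a fresh directory yields byte-identical
#' files.  Stage failures are recorded in the manifest and dependent stages
#' are skipped rather than aborting the run.
#'
#' @param config configuration list (see [default_pipeline_config()]), or a
#'   path to a YAML/JSON file with the same structure.
#' @param out_dir output directory (created if needed).
#' @param cal monitor calibration.
#' @return The manifest (invisibly), also written as `manifest.json`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir,
                         cal = default_monitor()) {
  if (is.character(config)) config <- read_config_file(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  manifest <- list(package_version = as.character(utils::packageVersion("glavenstats")),
                   seed = config$seed, config = config, stages = list())
  wjson <- function(x, f) {
    jsonlite::write_json(x, file.path(out_dir, f), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    f
  }
  note <- function(name, status, outputs = character(0), message = "") {
    manifest$stages[[name]] <<- list(status = status, outputs = outputs,
                                     message = message)
  }

  scene <- NULL
  if (isTRUE(stages$simulate)) {
    res <- try({
      sp <- scene_spec(size = config$scene$size, n_sites = config$scene$n_sites,
                       seed = config$seed)
      scene <- simulate_glass_scene(sp, cal = cal)
      outs <- c("unfiltered.txt", "filtered.txt")
      write_color_image_txt(scene$unfiltered, file.path(out_dir, outs[1]))
      write_color_image_txt(scene$filtered, file.path(out_dir, outs[2]))
      for (m in names(scene$masks)) {
        f <- sprintf("mask_%s.png", m)
        write_mask_png(scene$masks[[m]], file.path(out_dir, f))
        outs <- c(outs, f)
      }
      outs <- c(outs, wjson(list(seed = config$seed,
                                 effects = scene$truth$effects), "truth.json"))
      note("simulate", "completed", outs)
    }, silent = TRUE)
    if (inherits(res, "try-error")) note("simulate", "failed", message = as.character(res))
  } else note("simulate", "skipped")

  if (isTRUE(stages$ratios) && !is.null(scene)) {
    res <- try({
      lms <- convert_space(scene$filtered, "LMS", cal)
      obj <- scene$masks$object
      bg <- background_mask(obj)
      out <- list(rmc = as.numeric(rmc(lms, obj, bg)),
                  rsd = as.numeric(rsd(lms, obj, bg)),
                  robust = unclass(robust_ratio(lms, obj, bg))[c("tau", "u", "v", "delta", "msd_channel")],
                  n_filtered = sum(obj), n_unfiltered = sum(bg))
      note("ratios", "completed", wjson(out, "ratios.json"))
    }, silent = TRUE)
    if (inherits(res, "try-error")) note("ratios", "failed", message = as.character(res))
  } else note("ratios", if (is.null(scene)) "skipped_missing_input" else "skipped")

  if (isTRUE(stages$converge) && !is.null(scene)) {
    res <- try({
      tab <- converge_report(scene, cal = cal)
      f <- "converge.csv"
      utils::write.csv(tab, file.path(out_dir, f), row.names = FALSE)
      note("converge", "completed", f)
    }, silent = TRUE)
    if (inherits(res, "try-error")) note("converge", "failed", message = as.character(res))
  } else note("converge", if (is.null(scene)) "skipped_missing_input" else "skipped")

  if (isTRUE(stages$field) && !is.null(scene)) {
    res <- try({
      smp <- build_field(scene$unfiltered, scene$filtered, scene$masks$object,
                         space = "MBDKL", cal = cal)
      gf <- interpolate_field(project_field(smp, config$field$plane),
                              n_per_axis = config$field$grid)
      sl <- trace_streamlines(gf)
      f1 <- "field_grid.csv"
      utils::write.csv(data.frame(cell = seq_len(nrow(gf$vectors)),
                                  v1 = gf$vectors[, 1], v2 = gf$vectors[, 2],
                                  count = gf$counts),
                       file.path(out_dir, f1), row.names = FALSE)
      ends <- t(vapply(sl, function(s) s$points[nrow(s$points), ], numeric(2)))
      f2 <- "streamline_endpoints.csv"
      utils::write.csv(data.frame(x = ends[, 1], y = ends[, 2],
                                  termination = vapply(sl, `[[`, "", "termination")),
                       file.path(out_dir, f2), row.names = FALSE)
      note("field", "completed", c(f1, f2))
    }, silent = TRUE)
    if (inherits(res, "try-error")) note("field", "failed", message = as.character(res))
  } else note("field", if (is.null(scene)) "skipped_missing_input" else "skipped")

  lab <- NULL
  if (isTRUE(stages$stats) && !is.null(scene)) {
    res <- try({
      lab <- convert_space(scene$filtered, "LAB", cal)
      obj <- scene$masks$object; hl <- scene$masks$highlight
      stats_out <- list(mean = mean_lab_color(lab, obj),
                        white_point = white_point(lab, obj, hl),
                        most_saturated = most_saturated(lab, obj, hl),
                        most_frequent = most_frequent(lab, obj, hl))
      df <- do.call(rbind, lapply(names(stats_out), function(nm) {
        s <- stats_out[[nm]]
        data.frame(statistic = nm, L = s[1], a = s[2], b = s[3],
                   n_pixels = attr(s, "n_pixels_used"))
      }))
      f <- "summary_colors.csv"
      utils::write.csv(df, file.path(out_dir, f), row.names = FALSE)
      note("stats", "completed", f)
    }, silent = TRUE)
    if (inherits(res, "try-error")) note("stats", "failed", message = as.character(res))
  } else note("stats", if (is.null(scene)) "skipped_missing_input" else "skipped")

  if (isTRUE(stages$diffmap) && !is.null(scene) && !is.null(lab)) {
    res <- try({
      ref <- as.numeric(mean_lab_color(lab, scene$masks$object))
      dm <- ciede_map(scene$filtered, scene$masks$object, ref,
                      threshold = config$diffmap$threshold,
                      dim = config$diffmap$dim, cal = cal)
      f <- "diffmap.png"
      write_image_png(dm, file.path(out_dir, f), cal)
      note("diffmap", "completed", f)
    }, silent = TRUE)
    if (inherits(res, "try-error")) note("diffmap", "failed", message = as.character(res))
  } else {
    note("diffmap", if (is.null(scene) || is.null(lab)) "skipped_missing_input" else "skipped")
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}

read_config_file <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is needed to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
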