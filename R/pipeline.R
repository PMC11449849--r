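#' Pipeline configuration
#'
#' Bundles every stage's parameters. The resolved configuration is written
#' as YAML next to the outputs of each run for provenance.
#'
#' @param input Path to a volume readable by [read_volume()], or an
#'   [angio_volume()] / [enface_image()] given in memory.
#' @param layout Optional layout list for [read_volume()].
#' @param out_dir Output directory, or `NULL` to write nothing.
#' @param doi Which depth layers to quantify: "both", "1", "2", or "none"
#'   (no depth split; project the whole signal range).
#' @param reconstruction A [reconstruction_params()] (used for 4D input).
#' @param smooth_window,z_min Depth-profile parameters ([split_doi()]).
#' @param bam A [bam_params()].
#' @param prune_px,min_len_px Skeleton parameters ([skeletonize()],
#'   [decompose_segments()]).
#' @param kernel_px Heatmap kernel width ([local_heatmap()]).
#' @param pixel_geometry A [pixel_geometry()] overriding the input metadata,
#'   or `NULL`.
#' @param seed Seed threaded to any stochastic component (phantom
#'   generation); the analysis stages are deterministic.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, layout = NULL, out_dir = NULL,
                            doi = c("both", "1", "2", "none"),
                            reconstruction = reconstruction_params(),
                            smooth_window = 9L, z_min = NULL,
                            bam = bam_params(),
                            prune_px = 5L, min_len_px = 5,
                            kernel_px = 51L,
                            pixel_geometry = NULL, seed = 1L) {
  doi <- match.arg(doi)
  stopifnot(inherits(reconstruction, "reconstruction_params"),
            inherits(bam, "bam_params"))
  if (!is.null(pixel_geometry))
    stopifnot(inherits(pixel_geometry, "pixel_geometry"))
  structure(list(input = input, layout = layout, out_dir = out_dir,
                 doi = doi, reconstruction = reconstruction,
                 smooth_window = as.integer(smooth_window), z_min = z_min,
                 bam = bam, prune_px = as.integer(prune_px),
                 min_len_px = min_len_px, kernel_px = as.integer(kernel_px),
                 pixel_geometry = pixel_geometry, seed = as.integer(seed)),
            class = "pipeline_config")
}

resolved_config_list <- function(config) {
  list(doi = config$doi,
       reconstruction = unclass(config$reconstruction),
       smooth_window = config$smooth_window,
       z_min = config$z_min,
       bam = unclass(config$bam),
       prune_px = config$prune_px, min_len_px = config$min_len_px,
       kernel_px = config$kernel_px,
       pixel_geometry = if (is.null(config$pixel_geometry)) NULL
                        else unclass(config$pixel_geometry),
       seed = config$seed,
       package_version = as.character(utils::packageVersion("octaq")))
}

#' Run the full quantification pipeline
#'
#' Stages: (4D input) clutter-filter reconstruction; depth-of-interest
#' split; maximum intensity projection per DOI; mask + skeleton + segment
#' decomposition; metrics; moving-kernel heatmaps. When `out_dir` is set,
#' each DOI's en face projection, BAM, BVS, TI skeleton map and three
#' heatmaps are written along with the metrics reports (JSON + CSV), the
#' resolved configuration (YAML) and a log file; runs with identical input
#' and configuration produce byte-identical reports.
#'
#' @param config A [pipeline_config()]; `config$input` may be a file path,
#'   an [angio_volume()] (3D or 4D) or an [enface_image()] (2D, `doi` must
#'   then be "none").
#' @return Named list of `metrics_report`s (one per DOI), invisibly carrying
#'   the intermediate maps as attribute `details` and the split as `split`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  logit <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  obj <- config$input
  if (is.character(obj)) obj <- stage("read", read_volume(obj, config$layout))
  if (!is.null(config$pixel_geometry) && inherits(obj, "angio_volume"))
    obj$pixel_geometry <- config$pixel_geometry
  geom <- if (inherits(obj, c("angio_volume", "enface_image")))
    obj$pixel_geometry else pixel_geometry()

  if (inherits(obj, "angio_volume4d")) {
    logit("reconstructing angiography volume (%s)",
          config$reconstruction$method)
    obj <- stage("reconstruct", reconstruct(obj, config$reconstruction))
  }

  projections <- list()
  split <- NULL
  if (inherits(obj, "enface_image")) {
    if (config$doi != "none")
      stop("[stage doi] DOI requires a volume; got a 2D image", call. = FALSE)
    projections[["full"]] <- obj
  } else if (config$doi == "none") {
    prof <- depth_profile(obj, config$smooth_window)
    end_excl <- stage("doi", find_end_depth(prof)) + 1L
    projections[["full"]] <- mip(obj, seq_len(end_excl))
  } else {
    sp <- stage("doi", split_doi(obj, config$smooth_window, config$z_min))
    split <- sp$split
    logit("DOI split: separation %d, end %d",
          split$separation_depth, split$end_depth)
    if (config$doi %in% c("both", "1")) projections[["DOI 1"]] <- mip(sp$doi1)
    if (config$doi %in% c("both", "2")) projections[["DOI 2"]] <- mip(sp$doi2)
  }

  out <- list()
  details <- list()
  for (label in names(projections)) {
    proj <- projections[[label]]
    q <- stage("quantify",
               quantify_enface(proj, config$bam, geom, config$prune_px,
                               config$min_len_px, doi_label = label))
    hm <- stage("heatmap", list(
      density = local_heatmap(q$bam, config$kernel_px, "density"),
      diameter = local_heatmap(q$dfield, config$kernel_px, "diameter") *
        geom$lateral_pixel_um,
      ti = local_heatmap(q$ti_map, config$kernel_px, "ti")))
    logit("%s: VAD %.2f%%, VSD %.2f%%, VDI %.2f um, WTI %.2f", label,
          q$report$vad_percent, q$report$vsd_percent, q$report$vdi_um,
          q$report$wti)
    q$heatmaps <- hm
    q$projection <- proj
    out[[label]] <- q$report
    details[[label]] <- q
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_outputs(details, split, config, log_lines)
  }
  structure(out, details = details, split = split)
}

write_outputs <- function(details, split, config, log_lines) {
  od <- config$out_dir
  yaml::write_yaml(resolved_config_list(config), file.path(od, "config.yaml"))
  if (!is.null(split))
    jsonlite::write_json(unclass(split), file.path(od, "doi_split.json"),
                         auto_unbox = TRUE, digits = NA)
  for (label in names(details)) {
    tag <- gsub("[^A-Za-z0-9]+", "", tolower(label))
    q <- details[[label]]
    write_enface(q$projection, file.path(od, paste0(tag, "_enface.tif")), 16L)
    write_mask(q$bam, file.path(od, paste0(tag, "_bam.png")))
    write_mask(q$bvs, file.path(od, paste0(tag, "_bvs.png")))
    if (max(q$ti_map$values) > 0)
      write_enface(q$ti_map$values, file.path(od, paste0(tag, "_timap.tif")),
                   16L)
    for (h in names(q$heatmaps))
      write_enface(q$heatmaps[[h]],
                   file.path(od, paste0(tag, "_heatmap_", h, ".tif")), 16L)
    write_report(q$report, file.path(od, paste0(tag, "_report.json")))
    write_report(q$report, file.path(od, paste0(tag, "_report.csv")))
    utils::write.csv(as.data.frame(q$segments),
                     file.path(od, paste0(tag, "_segments.csv")),
                     row.names = FALSE)
  }
  writeLines(log_lines, file.path(od, "run.log"))
  invisible(od)
}

#' Scan-rescan repeatability report
#'
#' Runs the pipeline on each scan (or accepts precomputed metric reports)
#' and computes the coefficient of variation of each metric between scans,
#' per depth layer.
#'
#' @param scans A list where each element is either an input accepted by
#'   [run_pipeline()] (path / volume / image) or a named list of
#'   `metrics_report`s as returned by it.
#' @param config A [pipeline_config()] applied to every scan.
#' @return Data frame: doi, metric, one value column per scan, cv.
#' @export
run_repeatability <- function(scans, config = pipeline_config()) {
  if (length(scans) < 2L) stop("repeatability requires >= 2 scans")
  reports <- lapply(scans, function(s) {
    if (is.list(s) && all(vapply(s, inherits, logical(1), "metrics_report")))
      return(s)
    cfg <- config
    cfg$input <- s
    cfg$out_dir <- NULL
    run_pipeline(cfg)
  })
  labels <- names(reports[[1]])
  if (!all(vapply(reports, function(r) identical(names(r), labels),
                  logical(1))))
    stop("scans produced mismatched DOI layouts")
  metrics <- c(VAD = "vad_percent", VSD = "vsd_percent", VDI = "vdi_um",
               WTI = "wti")
  rows <- list()
  for (label in labels) {
    for (m in names(metrics)) {
      vals <- vapply(reports, function(r) r[[label]][[metrics[m]]],
                     numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        doi = label, metric = m,
        t(stats::setNames(vals, paste0("scan", seq_along(vals)))),
        cv = coefficient_of_variation(vals))
    }
  }
  do.call(rbind, rows)
}
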