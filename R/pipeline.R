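# Orchestration: configuration, per-image processing with fault
# isolation, and a deterministic parallel batch runner with a manifest.

#' Pipeline configuration
#'
#' All tunable parameters of the measurement pipeline, validated on
#' construction.
#'
#' @param threshold global segmentation threshold in \[0,1\].
#' @param marker_diameter_mm known physical diameter of the circular
#'   scale marker (mm).
#' @param root_class one of `"monocot"`, `"dicot"`, `"excised"`,
#'   `"all"`; trait families of other classes are marked
#'   not-applicable.
#' @param trait_selection `"all"` or a character vector of registry ids.
#' @param f_top,f_btm depth-fraction bands for the top/bottom boundary
#'   angles.
#' @param f_stem depth fraction of the stem band for stem diameter.
#' @param c_min minimum circularity (isoperimetric quotient) for the
#'   scale marker.
#' @param a_min minimum marker area (px).
#' @param a_root minimum component area (px) counted as root material.
#' @param min_spur_len skeleton spur-pruning length (px).
#' @param bin_width dominant-angle histogram bin width (degrees).
#' @param tangent_window secant window (points) for path tangents.
#' @param max_hole_area largest interior mask hole (px) filled before
#'   skeletonization.
#' @param output_dir where batch artifacts are written.
#' @param workers parallel worker count for batches.
#' @param debug_artifacts write intermediate-step images per image.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(threshold = 0.5,
                            marker_diameter_mm = 20,
                            root_class = "all",
                            trait_selection = "all",
                            f_top = 0.3, f_btm = 0.3, f_stem = 0.05,
                            c_min = 0.7, a_min = 200, a_root = 200,
                            min_spur_len = 10, bin_width = 10,
                            tangent_window = 9, max_hole_area = 20,
                            output_dir = "rootcrown_out",
                            workers = 1,
                            debug_artifacts = FALSE) {
  cfg <- list(threshold = threshold, marker_diameter_mm = marker_diameter_mm,
              root_class = root_class, trait_selection = trait_selection,
              f_top = f_top, f_btm = f_btm, f_stem = f_stem,
              c_min = c_min, a_min = a_min, a_root = a_root,
              min_spur_len = min_spur_len, bin_width = bin_width,
              tangent_window = tangent_window, max_hole_area = max_hole_area,
              output_dir = output_dir, workers = workers,
              debug_artifacts = debug_artifacts)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  bad <- character(0)
  chk <- function(name, ok) if (!isTRUE(ok)) bad <<- c(bad, name)
  in01 <- function(x) is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1
  pos <- function(x) is.numeric(x) && length(x) == 1 && x > 0
  chk("threshold", in01(cfg$threshold))
  chk("marker_diameter_mm", pos(cfg$marker_diameter_mm))
  chk("root_class", cfg$root_class %in% c("dicot", "monocot", "excised", "all"))
  chk("trait_selection", identical(cfg$trait_selection, "all") ||
        (is.character(cfg$trait_selection) &&
           all(cfg$trait_selection %in% trait_registry()$trait)))
  chk("f_top", in01(cfg$f_top)); chk("f_btm", in01(cfg$f_btm))
  chk("f_stem", in01(cfg$f_stem))
  chk("c_min", in01(cfg$c_min))
  chk("a_min", pos(cfg$a_min)); chk("a_root", pos(cfg$a_root))
  chk("min_spur_len", is.numeric(cfg$min_spur_len) && cfg$min_spur_len >= 0)
  chk("max_hole_area", is.numeric(cfg$max_hole_area) && cfg$max_hole_area >= 0)
  chk("bin_width", pos(cfg$bin_width))
  chk("tangent_window", pos(cfg$tangent_window))
  chk("workers", pos(cfg$workers))
  if (length(bad) > 0) {
    abort(paste0("invalid configuration value(s) for: ",
                 paste(bad, collapse = ", ")),
          class = "rootcrown_config_error")
  }
  invisible(cfg)
}

#' Load a configuration with layered resolution
#'
#' Resolution order: package defaults, then a flat `key=value` (or
#' YAML-like `key: value`) configuration file, then explicit flags in
#' `...`. The resolved configuration is echoed into every batch
#' manifest.
#'
#' @param file optional configuration file path.
#' @param ... named overrides, as accepted by [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
load_config <- function(file = NULL, ...) {
  args <- list()
  if (!is.null(file)) {
    lines <- readr::read_lines(file, progress = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "[=:]", fixed = FALSE)[[1]]
      if (length(kv) < 2) next
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = ":"))
      num <- suppressWarnings(as.numeric(val))
      if (identical(val, "TRUE") || identical(val, "true")) val <- TRUE
      else if (identical(val, "FALSE") || identical(val, "false")) val <- FALSE
      else if (!is.na(num)) val <- num
      args[[key]] <- val
    }
  }
  flags <- list(...)
  args[names(flags)] <- flags
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration key(s): ",
                 paste(unknown, collapse = ", ")),
          class = "rootcrown_config_error")
  }
  do.call(pipeline_config, args)
}

#' Process a single root-crown image
#'
#' Runs load, mask, component labeling, scene classification, scale
#' calibration, skeletonization, path extraction and trait computation,
#' writing the masked image and RSML as artifacts. Stage failures are
#' contained: the returned status names the failing stage and never
#' propagates an error.
#'
#' @param path image file path (or a `root_image`).
#' @param config a [pipeline_config()].
#' @param artifact_dir directory for artifacts, or `NULL` to skip
#'   writing them.
#' @return list with `record` (a `trait_record` or `NULL`), `status`
#'   (`"ok"`, `"no-root"`, `"no-marker(px-units)"`, or
#'   `"failed:<stage>"`), `image_id`, and `artifacts` (paths).
#' @export
process_image <- function(path, config = pipeline_config(),
                          artifact_dir = NULL) {
  stage <- "load"
  res <- tryCatch({
    img <- if (inherits(path, "root_image")) path else load_image(path)
    stage <- "mask"
    mask <- binary_mask(img, config$threshold)
    stage <- "components"
    comps <- label_components(mask)
    stage <- "classify"
    scene <- classify_components(comps, img, config)
    stage <- "traits"
    rec <- compute_all(scene, config)
    artifacts <- character(0)
    if (!is.null(artifact_dir)) {
      stage <- "artifacts"
      dir.create(artifact_dir, recursive = TRUE, showWarnings = FALSE)
      mask_path <- file.path(artifact_dir, paste0(img$source_id, "_mask.png"))
      write_image(mask$mask, mask_path)
      rsml_path <- file.path(artifact_dir, paste0(img$source_id, ".rsml"))
      st <- attr(rec, "structure")
      scale <- if (!is.na(attr(rec, "pixels_per_mm")))
        list(pixels_per_mm = attr(rec, "pixels_per_mm")) else NULL
      if (!is.null(st) && nrow(st$paths) > 0) {
        write_rsml(st$paths, scale, list(label = img$source_id), rsml_path)
      } else {
        write_rsml(list(), scale, list(label = img$source_id), rsml_path)
      }
      artifacts <- c(mask_path, rsml_path)
      if (isTRUE(config$debug_artifacts) && !is.null(st)) {
        skl_path <- file.path(artifact_dir, paste0(img$source_id, "_skeleton.png"))
        write_image(st$skel$mask, skl_path)
        artifacts <- c(artifacts, skl_path)
      }
    }
    status <- if (is.na(scene$marker_label)) "no-marker(px-units)" else "ok"
    list(record = rec, status = status, image_id = img$source_id,
         artifacts = artifacts)
  }, rootcrown_no_root = function(e) {
    id <- if (inherits(path, "root_image")) path$source_id
          else tools::file_path_sans_ext(basename(path))
    list(record = NULL, status = "no-root", image_id = id,
         artifacts = character(0))
  }, error = function(e) {
    id <- if (inherits(path, "root_image")) path$source_id
          else tools::file_path_sans_ext(basename(path))
    list(record = NULL, status = paste0("failed:", stage), image_id = id,
         artifacts = character(0))
  })
  res
}

#' Process a directory of images in parallel
#'
#' Images are processed independently across workers; the output CSV row
#' order follows the sorted input file names regardless of worker count
#' or completion order, so reruns and different worker counts give
#' byte-identical trait tables. A failing image yields a failed manifest
#' entry and never aborts the batch.
#'
#' @param input_dir directory containing PNG/JPEG/TIFF images.
#' @param config a [pipeline_config()].
#' @param workers parallel worker count (defaults to `config$workers`).
#' @param metadata optional metadata tibble from [read_metadata_csv()].
#' @return list with `csv_path`, `manifest_path` and the `manifest`
#'   tibble (one entry per input image).
#' @export
process_batch <- function(input_dir, config = pipeline_config(),
                          workers = config$workers, metadata = NULL) {
  files <- sort(list.files(input_dir,
                           pattern = "\\.(png|jpg|jpeg|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0) {
    stop_input(paste0("no image files found in ", input_dir))
  }
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  art_dir <- file.path(out_dir, "artifacts")

  run_one <- function(f) process_image(f, config, artifact_dir = art_dir)
  results <- if (workers > 1 && requireNamespace("parallel", quietly = TRUE) &&
                   .Platform$OS.type == "unix") {
    parallel::mclapply(files, run_one, mc.cores = workers)
  } else {
    lapply(files, run_one)
  }

  records <- purrr::compact(lapply(results, `[[`, "record"))
  csv_path <- file.path(out_dir, "traits.csv")
  write_traits_csv(records, trait_registry(), metadata, csv_path)

  manifest <- tibble(
    file = basename(files),
    image_id = vapply(results, `[[`, character(1), "image_id"),
    status = vapply(results, `[[`, character(1), "status")
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(
      pipeline = "rootcrown",
      version = as.character(utils::packageVersion("rootcrown")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
      config = unclass(config),
      images = manifest
    ),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  list(csv_path = csv_path, manifest_path = manifest_path,
       manifest = manifest)
}
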