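# Dataset discovery, image I/O, run configuration and pipeline orchestration.

.image_exts <- c("tif", "tiff", "png")

#' Read a grayscale image from TIFF or PNG
#'
#' Images are returned as numeric matrices on the `[0, 1]` double scale used
#' by the underlying readers.  Multi-channel inputs are converted to
#' luminance with the fixed weighting `0.2989 R + 0.5870 G + 0.1140 B`.
#' The texture descriptor is invariant to positive intensity scaling, so
#' this scale convention does not affect ILQP codes; the deep preprocessing
#' rescales explicitly anyway.
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @return numeric matrix.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% .image_exts)
    stop(sprintf("unsupported image format '%s' (%s)", ext, path))
  img <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 3) {
    w <- c(0.2989, 0.5870, 0.1140)
    nch <- min(dim(img)[3], 3)
    img <- Reduce(`+`, lapply(seq_len(nch), function(k) w[k] * img[, , k])) /
      sum(w[seq_len(nch)])
  }
  img
}

#' Scan a directory-per-class dataset
#'
#' The root must contain one subdirectory per class; classes and files are
#' ordered lexicographically so repeated scans of an unchanged tree give an
#' identical index.  A stray non-image file or an empty class directory is
#' an error, never silently skipped.
#'
#' @param root dataset root directory.
#' @return data frame with columns `image_id`, `path`, `label`.
#' @export
scan_dataset <- function(root) {
  if (!dir.exists(root)) stop(sprintf("dataset root does not exist: %s", root))
  classes <- sort(basename(list.dirs(root, recursive = FALSE)))
  if (length(classes) == 0) stop(sprintf("no class subdirectories under %s", root))
  rows <- list()
  for (cl in classes) {
    files <- sort(list.files(file.path(root, cl)))
    exts <- tolower(tools::file_ext(files))
    bad <- files[!exts %in% .image_exts]
    if (length(bad) > 0)
      stop(sprintf("non-image files in class '%s': %s", cl,
                   paste(bad, collapse = ", ")))
    if (length(files) == 0)
      stop(sprintf("class directory '%s' contains no images", cl))
    paths <- file.path(root, cl, files)
    unreadable <- paths[file.access(paths, 4) != 0]
    if (length(unreadable) > 0)
      stop(sprintf("unreadable files: %s", paste(unreadable, collapse = ", ")))
    rows[[cl]] <- data.frame(
      image_id = paste(cl, tools::file_path_sans_ext(files), sep = "/"),
      path = paths, label = cl)
  }
  idx <- do.call(rbind, rows)
  rownames(idx) <- NULL
  if (anyDuplicated(idx$image_id)) stop("duplicate image ids in dataset")
  idx
}

#' Assemble a validated run configuration
#'
#' Bundles the descriptor, deep-extractor, and fusion settings plus the
#' seeds driving every stochastic stage.  The default backbone is a small
#' four-block network (2 layers per block, growth 8, 64 px input) sized for
#' routine desk runs; the standard variants 121/169/201/264 are available
#' via `variant`.
#'
#' @param scales list of `c(P, R)` descriptor scales.
#' @param gmad_mode,gsv_denominator see [global_mad()], [global_sv()].
#' @param variant named DenseNet variant, or `NULL` to use `block_layers`.
#' @param block_layers,growth_rate,input_side backbone shape when
#'   `variant` is `NULL`.
#' @param taps dense blocks to tap (`NULL` = blocks 2-4).
#' @param weights `"random"`, `"zero"`, or a path to saved weights.
#' @param finetune if `TRUE`, run one-vs-rest focal-loss fine-tuning before
#'   extraction.
#' @param epochs,batch_size fine-tuning schedule knobs (see
#'   [train_schedule()] for the rest).
#' @param kinds classifier kinds for the bank.
#' @param k_folds cross-validation folds.
#' @param seed master seed.
#' @return object of class `"run_config"`.
#' @export
run_config <- function(scales = list(c(8, 1)),
                       gmad_mode = "mad_of_lmads",
                       gsv_denominator = "valid",
                       variant = NULL, block_layers = c(2L, 2L, 2L, 2L),
                       growth_rate = 8L, input_side = 64L,
                       taps = NULL, weights = "random", finetune = FALSE,
                       epochs = 2L, batch_size = 10L,
                       kinds = c("1-NN", "3-NN", "5-NN", "MLP", "RF", "SVM"),
                       k_folds = 5L, seed = 0L) {
  cfg <- if (!is.null(variant)) densenet_config(variant = variant)
  else densenet_config(block_layers = block_layers, growth_rate = growth_rate,
                       initial_channels = 2L * growth_rate,
                       input_side = input_side)
  structure(list(scales = scales, gmad_mode = gmad_mode,
                 gsv_denominator = gsv_denominator,
                 net = cfg, taps = taps, weights = weights,
                 finetune = isTRUE(finetune), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 kinds = kinds, k_folds = as.integer(k_folds),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param config a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(args$scales)) args$scales <- lapply(args$scales, unlist)
  do.call(run_config, args)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  y <- list(scales = lapply(config$scales, as.integer),
            gmad_mode = config$gmad_mode,
            gsv_denominator = config$gsv_denominator,
            variant = if (is.na(config$net$variant)) NULL else config$net$variant,
            block_layers = config$net$block_layers,
            growth_rate = config$net$growth_rate,
            input_side = config$net$input_side,
            taps = config$taps, weights = config$weights,
            finetune = config$finetune, epochs = config$epochs,
            batch_size = config$batch_size, kinds = config$kinds,
            k_folds = config$k_folds, seed = config$seed)
  yaml::write_yaml(y[!vapply(y, is.null, logical(1))], path)
  invisible(path)
}

# Evaluation report as plain lists, ready for JSON serialization.
.report_as_list <- function(report) {
  stopifnot(inherits(report, "evaluation_report"))
  res <- lapply(report$results, function(r) list(
    folds = r$folds,
    accuracy = as.list(r$accuracy),
    macro_precision = as.list(r$macro_precision),
    macro_recall = as.list(r$macro_recall),
    macro_f1 = as.list(r$macro_f1),
    confusions = lapply(r$confusions, function(cm) {
      dimnames(cm) <- NULL
      cm
    })))
  list(k_folds = report$k_folds, seed = report$seed, n = report$n,
       classes = report$classes, results = res)
}

#' Write an evaluation report to JSON
#'
#' @param report an `"evaluation_report"` from [cross_validate()].
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(.report_as_list(report), path, auto_unbox = TRUE,
                       digits = 10)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes the four stages end to end: ILQP texture extraction, deep
#' multilayer feature extraction, fusion, and cross-validated evaluation of
#' the classifier bank.  Inputs come either from a directory-per-class
#' `dataset_root` or from in-memory `images` + `labels`.  With `out_dir`
#' given, feature CSVs, the report JSON, and a manifest (configuration,
#' seeds, package version, config hash) are written; runs are idempotent
#' for a fixed configuration and seed.
#'
#' @param config a [run_config()].
#' @param dataset_root directory-per-class dataset root (alternative to
#'   `images`).
#' @param images named list of grayscale matrices (alternative to
#'   `dataset_root`).
#' @param labels factor of labels, required with `images`.
#' @param out_dir optional artifact directory.
#' @param verbose print per-stage progress.
#' @return object of class `"cellpheno_run"`: the evaluation report plus
#'   the texture, deep and fused feature matrices and the manifest.
#' @export
run_pipeline <- function(config = run_config(), dataset_root = NULL,
                         images = NULL, labels = NULL, out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t1 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    say("stage %-14s %6.1fs", name, proc.time()[["elapsed"]] - t1)
    out
  }
  if (is.null(images)) {
    if (is.null(dataset_root)) stop("give either dataset_root or images")
    idx <- stage("scan", scan_dataset(dataset_root))
    images <- stage("read", lapply(stats::setNames(idx$path, idx$image_id),
                                   read_gray_image))
    labels <- factor(idx$label)
  } else {
    if (is.null(labels)) stop("labels are required with in-memory images")
    labels <- as.factor(labels)
    if (is.null(names(images)))
      names(images) <- sprintf("img_%04d", seq_along(images))
  }
  texture <- stage("extract-ilqp", ilqp_feature_matrix(
    images, scales = config$scales, gmad_mode = config$gmad_mode,
    gsv_denominator = config$gsv_denominator))
  net <- stage("build-net", {
    if (config$weights %in% c("random", "zero"))
      build_densenet(config$net, weights = config$weights, seed = config$seed)
    else load_densenet_weights(config$weights)
  })
  if (config$finetune)
    net <- stage("finetune", ovr_finetune(
      net, images, labels,
      schedule = train_schedule(epochs = config$epochs,
                                batch_size = config$batch_size),
      seed = config$seed))
  deep <- stage("extract-deep", extract_multilayer_features(
    net, images, taps = config$taps))
  rownames(texture) <- names(images)
  rownames(deep) <- names(images)
  fused <- stage("fuse", fuse_features(texture, deep))
  report <- stage("cross-validate", cross_validate(
    fused, labels, k_folds = config$k_folds, seed = config$seed,
    kinds = config$kinds))
  manifest <- list(package = "cellpheno",
                   version = as.character(utils::packageVersion("cellpheno")),
                   seed = config$seed,
                   n_images = length(images),
                   classes = levels(labels),
                   feature_dims = list(texture = ncol(texture),
                                       deep = ncol(deep),
                                       fused = ncol(fused)))
  run <- structure(list(report = report, texture = texture, deep = deep,
                        fused = fused, labels = labels, config = config,
                        manifest = manifest),
                   class = "cellpheno_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg_path <- file.path(out_dir, "config.yaml")
    write_run_config(config, cfg_path)
    manifest$config_hash <- unname(tools::md5sum(cfg_path))
    write_feature_csv(texture, labels, file.path(out_dir, "features_ilqp.csv"),
                      metadata = list(scales = config$scales,
                                      gmad_mode = config$gmad_mode,
                                      gsv_denominator = config$gsv_denominator))
    write_feature_csv(deep, labels, file.path(out_dir, "features_deep.csv"),
                      metadata = list(taps = .resolve_taps(config$net, config$taps),
                                      weights = config$weights))
    write_report_json(report, file.path(out_dir, "report.json"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = 10)
    run$manifest <- manifest
  }
  say("total %.1fs", proc.time()[["elapsed"]] - t0)
  run
}

#' @export
print.cellpheno_run <- function(x, ...) {
  cat(sprintf("cellpheno pipeline run: %d images, %d classes\n",
              x$manifest$n_images, length(x$manifest$classes)))
  cat(sprintf("  features: texture %d + deep %d = fused %d\n",
              x$manifest$feature_dims$texture, x$manifest$feature_dims$deep,
              x$manifest$feature_dims$fused))
  print(x$report)
  invisible(x)
}

#' Write a feature matrix as CSV with a sidecar metadata file
#'
#' One row per image with columns `image_id`, `label`, then the features;
#' the sidecar `<path>.meta.json` records how the features were produced.
#'
#' @param features numeric matrix with rownames as image ids.
#' @param labels factor of labels, one per row.
#' @param path output CSV path.
#' @param metadata named list written to the sidecar.
#' @export
write_feature_csv <- function(features, labels, path, metadata = list()) {
  df <- data.frame(image_id = rownames(features), label = as.character(labels),
                   features, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(metadata, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a feature CSV written by [write_feature_csv()]
#'
#' @param path CSV path.
#' @return list with `features` (matrix, image ids as rownames) and
#'   `labels` (factor).
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df$image_id
  list(features = m, labels = factor(df$label))
}
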