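#' Write a dataset manifest CSV
#'
#' Columns: `id,path,concentration_ng_per_ml,split,seed`.
#'
#' @param manifest manifest data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a dataset manifest CSV
#'
#' @param path CSV path with the documented header.
#' @return manifest data.frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_with("manifest", "no such manifest: %s", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(man)
  man
}

validate_manifest <- function(man) {
  need <- c("id", "path", "concentration_ng_per_ml", "split", "seed")
  missing <- setdiff(need, names(man))
  if (length(missing)) {
    stop_with("manifest", "missing manifest column(s): %s",
              paste(missing, collapse = ", "))
  }
  if (anyDuplicated(man$id)) {
    stop_with("manifest", "duplicate id: %s",
              man$id[anyDuplicated(man$id)])
  }
  bad <- setdiff(unique(man$split), c("train", "validation", "test"))
  if (length(bad)) {
    stop_with("manifest", "unknown split tag: %s", bad[1])
  }
  invisible(man)
}

#' End-to-end surface-sensitivity measurement
#'
#' Renders `n_per_conc` specklegrams at each concentration of the linear
#' sub-panel plus the 0 ng/mL reference, preprocesses them, computes the
#' ZNCC of each frame against the reference, and fits the OLS line of mean
#' ZNCC against concentration. The magnitude of the slope is the surface
#' sensitivity in (ng/mL)^-1.
#'
#' @param config a `speckle_config`.
#' @param seed run seed (scene and all frames derive from it).
#' @param concs concentrations of the linear range, ng/mL.
#' @param n_per_conc frames per concentration.
#' @return list with `sensitivity`, `fit` (a `linear_fit`), and `curve`
#'   (a `correlation_curve`).
#' @export
surface_sensitivity_run <- function(config = default_config(), seed = 1L,
                                    concs = c(1, 5, 10, 20, 30, 50),
                                    n_per_conc = 10L) {
  scene <- build_scene(config, seed = seed)
  pp <- function(img) {
    preprocess_image(img, factor = config$preprocess$downsample_factor,
                     norm = config$preprocess$norm,
                     bit_depth = config$camera$bit_depth)
  }
  ref <- pp(render_reference(scene)$intensity)
  rows <- list(); vals <- list()
  for (ci in seq_along(concs)) {
    z <- vapply(seq_len(n_per_conc), function(j) {
      img <- render_specklegram(concs[ci], seed = fan_seed(seed, "sens", ci, j),
                                scene = scene)
      zncc(ref, pp(img$intensity))
    }, numeric(1))
    vals[[ci]] <- z
  }
  curve <- data.frame(
    concentration_ng_per_ml = concs,
    mean_zncc = vapply(vals, mean, numeric(1)),
    sd_zncc = vapply(vals, stats::sd, numeric(1)),
    n = rep(n_per_conc, length(concs))
  )
  class(curve) <- c("correlation_curve", "data.frame")
  fit <- fit_linear_sensitivity(curve, c_min = min(concs), c_max = max(concs))
  list(sensitivity = fit$sensitivity, fit = fit, curve = curve)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> correlate -> calibrate -> train ->
#' evaluate from one configuration and seed, and assembles the headline
#' metrics: dataset counts, the ZNCC dose-response curve with its logistic
#' and linear fits, and the CNN evaluation (maximum relative error and the
#' decoded-versus-true slope).
#'
#' @param config a `speckle_config`.
#' @param seed global seed; stage seeds are derived by stable hashing.
#' @param out_dir optional directory; when given, images, manifest, curve
#'   CSV, fit JSON and the metrics report JSON are written there.
#' @param verbose print stage progress.
#' @return a list of class `metrics_report`.
#' @export
run_all <- function(config = default_config(), seed = config$seed,
                    out_dir = NULL, verbose = FALSE) {
  validate_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  img_dir <- if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    file.path(out_dir, "images")
  }
  say("stage simulate: rendering dataset")
  ds <- generate_dataset(config, seed = seed, dir = img_dir)
  counts <- table(factor(ds$manifest$split,
                         levels = c("train", "validation", "test")))

  say("stage correlate: ZNCC curve over %d classes",
      length(config$dataset$panel))
  pp <- function(img) {
    preprocess_image(img, factor = config$preprocess$downsample_factor,
                     norm = config$preprocess$norm,
                     bit_depth = config$camera$bit_depth)
  }
  ref <- pp(ds$reference$intensity)
  curve <- correlation_curve(ref, ds$manifest, images = ds$images,
                             preprocess = pp)

  say("stage calibrate: logistic + linear fits")
  # the 4PL needs at least 4 concentrations; smaller panels get the
  # linear sensitivity fit only
  logi <- if (nrow(curve) >= 4L) fit_logistic(curve) else NULL
  lin <- fit_linear_sensitivity(curve, config$calibration$c_min,
                                config$calibration$c_max)

  say("stage train: CNN on %d training images", counts[["train"]])
  data <- prepare_cnn_data(ds, config)
  ccfg <- cnn_config(
    input_shape = dim(data$train$x)[1:2],
    panel = sort(config$dataset$panel),
    conv_filters = config$cnn$conv_filters,
    kernel = config$cnn$kernel, pool = config$cnn$pool,
    dense_width = config$cnn$dense_width,
    learning_rate = config$cnn$learning_rate,
    batch_size = config$cnn$batch_size, epochs = config$cnn$epochs,
    patience = config$cnn$patience,
    seed = config$cnn$seed %||% fan_seed(seed, "cnn")
  )
  model <- build_model(ccfg)
  model <- train_cnn(model, data$train$x, data$train$y,
                     data$validation$x, data$validation$y, verbose = verbose)

  say("stage evaluate: %d test images", counts[["test"]])
  ev <- evaluate_cnn(model, data$test$x, data$test$conc, ids = data$test$ids)

  report <- structure(
    list(
      counts = list(total = nrow(ds$manifest),
                    train = unname(counts[["train"]]),
                    validation = unname(counts[["validation"]]),
                    test = unname(counts[["test"]])),
      surface_sensitivity = lin$sensitivity,
      linear_fit = lin,
      logistic_fit = logi,
      curve = curve,
      max_rel_error_pct = ev$max_rel_error_pct,
      slope = ev$slope,
      intercept = ev$intercept,
      evaluation = ev,
      history = model$history,
      model = model,
      provenance = list(config_hash = config_hash(config), seed = seed,
                        r_version = R.version.string,
                        timestamp = format(Sys.time(), tz = "UTC"))
    ),
    class = "metrics_report"
  )
  if (!is.null(out_dir)) {
    utils::write.csv(curve, file.path(out_dir, "curve.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(
        counts = report$counts,
        surface_sensitivity = lin$sensitivity,
        logistic_fit = logi[c("lower_asymptote", "upper_asymptote",
                              "midpoint", "slope_factor", "r_squared")],
        linear_fit = lin[c("slope", "intercept", "sensitivity", "r_squared")],
        max_rel_error_pct = ev$max_rel_error_pct,
        slope = ev$slope, intercept = ev$intercept,
        per_class_accuracy = as.list(ev$per_class_accuracy),
        provenance = report$provenance
      ),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA
    )
  }
  report
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report>\n"))
  cat(sprintf("  dataset: %d images (train %d / validation %d / test %d)\n",
              x$counts$total, x$counts$train, x$counts$validation,
              x$counts$test))
  cat(sprintf("  surface sensitivity: %.5g (ng/mL)^-1 over [%g, %g] ng/mL\n",
              x$surface_sensitivity, x$linear_fit$fit_range[1],
              x$linear_fit$fit_range[2]))
  cat(sprintf("  CNN: max rel. error %.4f%%, decoded~true slope %.5f\n",
              x$max_rel_error_pct, x$slope))
  invisible(x)
}
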