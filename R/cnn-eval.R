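#' Decode class probabilities to a continuous concentration
#'
#' Expected-value decoding: `chat = sum_k P_k * c_k` over the concentration
#' panel, so the estimate is continuous and always lies within the panel
#' span. The argmax class is reported alongside.
#'
#' @param model a trained `cnn_model`.
#' @param x one preprocessed image (matrix) or a batch array
#'   `height x width x 1 x n`.
#' @param ids optional image identifiers.
#' @param true_concentration optional true labels in ng/mL.
#' @return a data.frame (one row per image): `id`, `decoded_ng_per_ml`,
#'   `argmax_class`, `argmax_ng_per_ml`, `max_prob`, and
#'   `true_ng_per_ml` when supplied; the probability matrix is attached as
#'   attribute `"probabilities"`.
#' @export
predict_concentration <- function(model, x, ids = NULL,
                                  true_concentration = NULL) {
  probs <- predict_proba(model, x)
  bad <- abs(colSums(probs) - 1) > 1e-6 | apply(probs < 0, 2, any)
  if (any(bad)) {
    stop_with("model-output", "probability vector fails normalization")
  }
  panel <- model$config$panel
  chat <- as.vector(crossprod(probs, panel))
  amax <- max.col(t(probs))
  out <- data.frame(
    id = ids %||% sprintf("img%04d", seq_along(chat)),
    decoded_ng_per_ml = chat,
    argmax_class = amax,
    argmax_ng_per_ml = panel[amax],
    max_prob = apply(probs, 2, max)
  )
  if (!is.null(true_concentration)) out$true_ng_per_ml <- true_concentration
  attr(out, "probabilities") <- probs
  out
}

#' Evaluate the CNN quantifier on a test split
#'
#' Decodes every test image, computes per-image relative errors
#' `|chat - c_true| / c_true * 100`, their maximum, the OLS line of decoded
#' versus true concentration, per-class argmax accuracy and the confusion
#' table.
#'
#' @param model a trained `cnn_model`.
#' @param x test images, array `height x width x 1 x n`.
#' @param true_concentration true ng/mL labels (length n, all > 0).
#' @param ids optional identifiers.
#' @return an object of class `cnn_evaluation`: `predictions` (data.frame),
#'   `max_rel_error_pct`, `mean_rel_error_pct`, `slope`, `intercept`,
#'   `per_class_accuracy`, `confusion`.
#' @export
evaluate_cnn <- function(model, x, true_concentration, ids = NULL) {
  n <- dim(x)[4]
  if (n < 1L) stop_with("data", "test split is empty")
  if (any(true_concentration <= 0)) {
    stop_with("domain", "relative error undefined at zero true concentration")
  }
  pred <- predict_concentration(model, x, ids = ids,
                                true_concentration = true_concentration)
  rel <- abs(pred$decoded_ng_per_ml - true_concentration) /
    true_concentration * 100
  pred$rel_error_pct <- rel
  fit <- stats::lm(pred$decoded_ng_per_ml ~ true_concentration)
  cf <- stats::coef(fit)
  panel <- model$config$panel
  true_class <- match(true_concentration, panel)
  conf <- table(
    true = factor(true_class, levels = seq_along(panel), labels = panel),
    predicted = factor(pred$argmax_class, levels = seq_along(panel),
                       labels = panel)
  )
  pca <- diag(conf) / pmax(rowSums(conf), 1)
  structure(
    list(predictions = pred,
         max_rel_error_pct = max(rel),
         mean_rel_error_pct = mean(rel),
         slope = unname(cf[2]), intercept = unname(cf[1]),
         per_class_accuracy = pca, confusion = conf, n = n),
    class = "cnn_evaluation"
  )
}

#' @export
print.cnn_evaluation <- function(x, ...) {
  cat(sprintf(paste0(
    "<cnn_evaluation> n = %d  max rel. error %.4f%%  ",
    "decoded~true slope %.5f (intercept %.4g)\n"),
    x$n, x$max_rel_error_pct, x$slope, x$intercept))
  cat(sprintf("  mean per-class argmax accuracy %.3f\n",
              mean(x$per_class_accuracy)))
  invisible(x)
}

#' Assemble CNN input arrays from a dataset
#'
#' Applies the preprocessing chain (grayscale, unit normalization, block
#' mean downsampling by `preprocess$downsample_factor * cnn$downsample_factor`)
#' to every image of a [generate_dataset()] result and stacks the splits into
#' `height x width x 1 x n` arrays. Split identifiers are checked to be
#' pairwise disjoint.
#'
#' @param dataset a `speckle_dataset` (in-memory or on-disk).
#' @param config the pipeline `speckle_config` the dataset was built with.
#' @return named list with one element per split (`train`, `validation`,
#'   `test`), each a list `x` (array), `y` (class index), `conc` (ng/mL),
#'   `ids`.
#' @export
prepare_cnn_data <- function(dataset, config) {
  man <- dataset$manifest
  splits <- split(seq_len(nrow(man)), man$split)
  for (a in c("train", "validation", "test")) {
    for (b in setdiff(c("train", "validation", "test"), a)) {
      if (length(intersect(man$id[splits[[a]]], man$id[splits[[b]]]))) {
        stop_with("data", "split identifiers are not disjoint")
      }
    }
  }
  factor <- config$preprocess$downsample_factor * config$cnn$downsample_factor
  panel <- sort(config$dataset$panel)
  get_img <- function(i) {
    raw <- if (!is.null(dataset$images)) {
      dataset$images[[man$id[i]]]
    } else {
      read_specklegram(man$path[i])
    }
    preprocess_image(raw, factor = factor, norm = config$preprocess$norm,
                     bit_depth = config$camera$bit_depth)
  }
  shape <- dim(get_img(1L))
  lapply(splits[c("train", "validation", "test")], function(rows) {
    x <- array(NA_real_, dim = c(shape, 1L, length(rows)))
    for (j in seq_along(rows)) x[, , 1L, j] <- get_img(rows[j])
    list(x = x,
         y = match(man$concentration_ng_per_ml[rows], panel),
         conc = man$concentration_ng_per_ml[rows],
         ids = man$id[rows])
  })
}

#' Expected-value decoding of a probability vector
#'
#' `chat = sum_k P_k * c_k` for each probability column over the panel.
#'
#' @param probs probability vector (length = panel) or `class_count x n`
#'   matrix with columns summing to 1.
#' @param panel concentration panel in ng/mL.
#' @return numeric vector of decoded concentrations.
#' @export
decode_concentration <- function(probs, panel) {
  if (is.vector(probs)) probs <- matrix(probs, ncol = 1)
  if (nrow(probs) != length(panel)) {
    stop_with("dimension", "probability rows must match panel length")
  }
  as.vector(crossprod(probs, panel))
}
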