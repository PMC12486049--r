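# Estimator surface: data splits, sample weights, training, metrics, and
# the EPR-vs-RoR comparison, with broom-style accessors for the fit.

#' Grouped random train/validation split
#'
#' Samples are split 80/20 (by default) independently within each geometry
#' group (fetal depth in the simulation arm), so every depth is represented
#' in both partitions.
#'
#' @param data Sample tibble.
#' @param frac Training fraction.
#' @param seed RNG seed.
#' @param group Column name holding the geometry group (default `"dm"`);
#'   `NULL` for an ungrouped split.
#' @return List of integer row indices `train` and `validation`.
#' @export
random_split <- function(data, frac = 0.8, seed = 1, group = "dm") {
  n <- nrow(data)
  g <- if (is.null(group)) rep(1, n) else data[[group]]
  set.seed(seed)
  train <- integer(0)
  for (lev in unique(g)) {
    idx <- which(g == lev)
    if (length(idx) < 5) {
      abort("Each group needs at least 5 samples to split.",
            class = "tfo_error_split")
    }
    train <- c(train, sample(idx, round(frac * length(idx))))
  }
  train <- sort(train)
  list(train = train, validation = setdiff(seq_len(n), train))
}

#' Temporal split into contiguous folds
#'
#' Partitions time-ordered samples of one recording round into `k`
#' contiguous blocks whose sizes differ by at most one; block `fold` is the
#' validation set.
#'
#' @param n Number of time-ordered samples (or a data frame, whose row
#'   count is used).
#' @param k Number of folds.
#' @param fold Zero-based validation fold index, `0 <= fold < k`.
#' @return List of integer indices `train` and `validation` (one contiguous
#'   run).
#' @export
temporal_split <- function(n, k = 5, fold = 0) {
  if (is.data.frame(n)) n <- nrow(n)
  if (n < k) abort("Fewer samples than folds.", class = "tfo_error_split")
  stopifnot(fold >= 0, fold < k)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  val <- seq(starts[fold + 1], ends[fold + 1])
  list(train = setdiff(seq_len(n), val), validation = val)
}

#' Inverse-count sample weights across rounds
#'
#' Each sample is weighted inversely to its round's size, normalized so the
#' total weight equals the total sample count; every round then carries
#' equal total weight.
#'
#' @param round_id Vector of round identifiers, one per sample.
#' @return Numeric weight per sample.
#' @export
round_weights <- function(round_id) {
  if (length(round_id) == 0) abort("Empty rounds.", class = "tfo_error_split")
  sizes <- table(round_id)
  w <- 1 / as.numeric(sizes[as.character(round_id)])
  w * length(round_id) / sum(w)
}

#' Validation metrics
#'
#' Mean absolute error, standard deviation of the absolute errors, and
#' Pearson correlation (with the two-sided p-value of the zero-correlation
#' test) between predictions and reference saturations, all in percent.
#'
#' @param labels Reference fSaO2, percent.
#' @param predictions Estimated fSpO2, percent.
#' @return One-row tibble: `mae`, `std`, `r`, `p`, `n`.
#' @export
evaluate_predictions <- function(labels, predictions) {
  stopifnot(length(labels) == length(predictions), length(labels) >= 2)
  err <- abs(labels - predictions)
  if (sd(predictions) == 0 || sd(labels) == 0) {
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- cor.test(labels, predictions)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  tibble::tibble(mae = mean(err), std = sd(err), r = r, p = p,
                 n = length(err))
}

#' Fit the multi-detector fusion estimator
#'
#' Trains the MLP on the feature columns of `data` against the percent
#' saturation label with (optionally weighted) MSE loss, early stopping on
#' the validation loss, and best-weights restore. Metrics are computed on
#' the validation samples only.
#'
#' @param data Sample tibble (one row per sample).
#' @param split A [random_split()] / [temporal_split()] result.
#' @param cfg A [train_config()].
#' @param features Character vector of feature column names; default: all
#'   columns starting with `"epr_"` or `"ror_"`.
#' @param label Label column (percent), default `"label"`.
#' @param weights Optional per-sample training weights (length `nrow(data)`),
#'   e.g. from [round_weights()].
#' @return A `tfo_fit`: the trained model, validation predictions, metrics,
#'   and training history.
#' @export
fit_fspo2 <- function(data, split, cfg = train_config(),
                      features = NULL, label = "label", weights = NULL) {
  features <- features %||%
    grep("^(epr|ror)_", names(data), value = TRUE)
  stopifnot(length(features) >= 1, label %in% names(data))
  X <- as.matrix(data[features])
  y <- data[[label]]
  if (anyNA(X) || anyNA(y)) abort("Missing values in features or labels.",
                                  class = "tfo_error_data")
  model <- build_model(cfg, ncol(X))
  model <- mlp_train(model,
                     X[split$train, , drop = FALSE], y[split$train],
                     X[split$validation, , drop = FALSE], y[split$validation],
                     w_tr = weights[split$train])
  pred <- predict(model, X[split$validation, , drop = FALSE])
  metrics <- evaluate_predictions(y[split$validation], pred)
  structure(list(model = model, features = features, label = label,
                 split = split, cfg = cfg,
                 validation = tibble::tibble(
                   row = split$validation, label = y[split$validation],
                   prediction = pred),
                 metrics = metrics, history = model$history,
                 best_epoch = model$best_epoch),
            class = "tfo_fit")
}

#' @export
print.tfo_fit <- function(x, ...) {
  cat("<tfo_fit> ", length(x$features), " features, ",
      length(x$split$train), "/", length(x$split$validation),
      " train/validation\n", sep = "")
  cat(sprintf("  validation MAE %.2f%%, |err| sd %.2f%%, Pearson r %.3f\n",
              x$metrics$mae, x$metrics$std, x$metrics$r))
  invisible(x)
}

#' @rdname fit_fspo2
#' @param x,object A `tfo_fit`.
#' @param ... Unused.
#' @method tidy tfo_fit
#' @export
tidy.tfo_fit <- function(x, ...) x$validation

#' @rdname fit_fspo2
#' @method glance tfo_fit
#' @export
glance.tfo_fit <- function(x, ...) {
  dplyr::bind_cols(x$metrics,
                   tibble::tibble(epochs = length(x$history),
                                  best_epoch = x$best_epoch))
}

#' @rdname fit_fspo2
#' @export
predict.tfo_fit <- function(object, newdata, ...) {
  predict(object$model, as.matrix(newdata[object$features]))
}

#' @rdname fit_fspo2
#' @method autoplot tfo_fit
#' @export
autoplot.tfo_fit <- function(object, ...) {
  ggplot2::ggplot(object$validation,
                  ggplot2::aes(x = .data$label, y = .data$prediction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "reference fSaO2 (%)", y = "estimated fSpO2 (%)",
                  title = sprintf("validation MAE %.2f%%, r = %.2f",
                                  object$metrics$mae, object$metrics$r)) +
    ggplot2::theme_minimal()
}

#' Compare EPR and RoR feature sets
#'
#' Trains the same network on paired EPR and RoR datasets (identical
#' samples, identical split) `trials` times with different weight
#' initializations, averages the validation metrics, and reports the
#' percent improvement of EPR over RoR:
#' `(MAE_RoR - MAE_EPR) / MAE_RoR * 100` (and likewise for the error std;
#' the correlation improvement is `(r_EPR - r_RoR) / r_RoR * 100`).
#'
#' @param data_epr,data_ror Paired sample tibbles over identical rows.
#' @param split A shared split.
#' @param cfg A [train_config()]; trial `i` uses `cfg$seed + i - 1`.
#' @param trials Number of differently initialized trainings per feature
#'   set.
#' @param weights Optional per-sample training weights.
#' @return List: `metrics` (per feature type, averaged), `improvement`
#'   (one-row tibble), `trials` (per-trial metrics).
#' @export
run_comparison <- function(data_epr, data_ror, split, cfg = train_config(),
                           trials = 5, weights = NULL) {
  if (nrow(data_epr) != nrow(data_ror)) {
    abort("Paired datasets must cover identical samples.", class = "tfo_error_data")
  }
  one <- function(data, type) {
    purrr::map_dfr(seq_len(trials), function(i) {
      cfg_i <- cfg; cfg_i$seed <- cfg$seed + i - 1
      fit <- fit_fspo2(data, split, cfg_i, weights = weights)
      dplyr::bind_cols(tibble::tibble(type = type, trial = i), fit$metrics)
    })
  }
  per_trial <- dplyr::bind_rows(one(data_epr, "epr"), one(data_ror, "ror"))
  metrics <- per_trial |>
    group_by(.data$type) |>
    summarise(mae = mean(.data$mae), std = mean(.data$std),
              r = mean(.data$r), .groups = "drop")
  m_epr <- metrics[metrics$type == "epr", ]
  m_ror <- metrics[metrics$type == "ror", ]
  improvement <- tibble::tibble(
    mae = (m_ror$mae - m_epr$mae) / m_ror$mae * 100,
    std = (m_ror$std - m_epr$std) / m_ror$std * 100,
    r = (m_epr$r - m_ror$r) / m_ror$r * 100)
  list(metrics = metrics, improvement = improvement, trials = per_trial)
}
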