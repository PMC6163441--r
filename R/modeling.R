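# Linear calibration of physical magnitudes from image measurements
# (axis length in px -> mm, pixel area -> g) and the error metrics used to
# judge the estimates on external validation sets.

#' Fit a linear calibration model
#'
#' Ordinary least squares y = slope * x + intercept, mapping an image
#' measurement (pixels or pixel area) to a physical magnitude (mm or g).
#'
#' @param x Image-unit values (length >= 3, not all equal).
#' @param y Physical-unit values, same length.
#' @param feature One of `"major_axis"`, `"minor_axis"`, `"mass"`.
#' @param variety_tag Free-text tag, e.g. a variety name or
#'   `"variety-independent"` for a model fitted on pooled training sets.
#' @param through_origin Force intercept 0 (off by default; the published
#'   fits are affine).
#' @return Object of class `calibration_model`: slope, intercept, r_squared,
#'   n_train, feature, variety_tag, through_origin.
#' @export
fit_linear <- function(x, y, feature = "mass", variety_tag = "unspecified",
                       through_origin = FALSE) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 training points", call. = FALSE)
  if (diff(range(x)) == 0) {
    stop("degenerate design: x values are all equal", call. = FALSE)
  }
  fit <- if (through_origin) lm(y ~ x + 0) else lm(y ~ x)
  cf <- coef(fit)
  # summary.lm warns on noiseless ("essentially perfect") fits; those are a
  # legitimate calibration input here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(feature = feature,
                 slope = unname(if (through_origin) cf["x"] else cf["x"]),
                 intercept = unname(if (through_origin) 0 else cf["(Intercept)"]),
                 r_squared = r2,
                 n_train = length(x),
                 variety_tag = variety_tag,
                 through_origin = through_origin),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("calibration model [%s, %s]: y = %.6g * x + %.6g (R^2 = %.4f, n = %d)\n",
              x$feature, x$variety_tag, x$slope, x$intercept, x$r_squared,
              x$n_train))
  invisible(x)
}

#' Predict physical magnitudes from image measurements
#'
#' @param object A `calibration_model`.
#' @param x Image-unit values.
#' @param ... Unused.
#' @return slope * x + intercept, elementwise.
#' @export
predict.calibration_model <- function(object, x, ...) {
  object$slope * x + object$intercept
}

#' Write/read a calibration model as JSON
#'
#' @param model A `calibration_model`.
#' @param path JSON file path.
#' @return `path` (write) or the model (read).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(m[c("feature", "slope", "intercept", "r_squared", "n_train",
                "variety_tag", "through_origin")],
            class = "calibration_model")
}

#' Error metrics of physical-magnitude estimates
#'
#' For predictions \eqn{\hat y_i} against references \eqn{y_i > 0}:
#' \itemize{
#'   \item RMSE, in the physical unit;
#'   \item SE, the RMSE relative to the mean reference value, in percent;
#'   \item |E|, the absolute value of the SUM of signed errors relative to
#'     the summed reference values, in percent — signed errors are summed
#'     BEFORE taking the absolute value, so over- and under-estimates cancel
#'     (this differs materially from a mean absolute error);
#'   \item the individual relative errors \eqn{e_i = \hat y_i / y_i}.
#' }
#'
#' @param y_hat Predicted values.
#' @param y Reference values (all > 0), same length.
#' @return List: `rmse`, `se_pct`, `abs_e_pct`, `n`, `relative_errors`.
#' @export
compute_metrics <- function(y_hat, y) {
  if (length(y_hat) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(y) < 1) stop("need at least one pair", call. = FALSE)
  if (any(y <= 0)) stop("all reference values must be positive", call. = FALSE)
  err <- y_hat - y
  rmse <- sqrt(sum(err^2) / length(y))
  list(rmse = rmse,
       se_pct = rmse / mean(y) * 100,
       abs_e_pct = abs(sum(err)) / sum(y) * 100,
       n = length(y),
       relative_errors = y_hat / y)
}

#' Split paired data into training and external validation sets
#'
#' Seeded, reproducible selection of `train_n` rows; the remainder is the
#' validation set. With `stratify_by`, rows are binned into quartiles of that
#' column and the training quota is spread across bins (largest-remainder
#' apportionment, per-bin counts differing by at most 1 from proportionality),
#' so the training set is representative of the feature's variability.
#'
#' @param df Data frame of paired rows.
#' @param train_n Training-set size (< nrow(df)).
#' @param seed Integer seed.
#' @param stratify_by Optional column name to stratify on.
#' @return List with data frames `train` and `validation`.
#' @export
train_eval_split <- function(df, train_n = 50L, seed = 0L, stratify_by = NULL) {
  n <- nrow(df)
  if (train_n >= n) stop("train_n must be smaller than the number of rows",
                         call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (is.null(stratify_by)) {
    idx <- sort(sample.int(n, train_n))
  } else {
    v <- df[[stratify_by]]
    qs <- quantile(v, probs = c(0.25, 0.5, 0.75), type = 7)
    bin <- findInterval(v, qs, left.open = FALSE) + 1L   # 1..4
    sizes <- tabulate(bin, nbins = 4L)
    exact <- train_n * sizes / n
    take <- floor(exact)
    rem <- train_n - sum(take)
    if (rem > 0) {
      ord <- order(exact - take, decreasing = TRUE)
      take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1L
    }
    idx <- integer()
    for (b in 1:4) {
      inb <- which(bin == b)
      if (take[b] > length(inb)) take[b] <- length(inb)
      idx <- c(idx, sample(inb, take[b]))
    }
    idx <- sort(idx)
  }
  list(train = df[idx, , drop = FALSE],
       validation = df[setdiff(seq_len(n), idx), , drop = FALSE])
}

# Preserve caller RNG state around seeded helpers.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
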