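#' CNN decoder configuration
#'
#' All decoders share one architecture: three Conv1D layers with 64, 128
#' and 64 filters, kernel size 3, "same" padding, ReLU activation, batch
#' normalization after each conv layer, global average pooling over time,
#' and a single sigmoid output unit, trained with Adam (default step size
#' 1e-3) on binary cross-entropy.  Epochs and batch size follow the model:
#' state decoding `cnn1` (100 epochs, batch 128), encoding-performance
#' `cnn2a`/`cnn2b` (150, 128), recall-performance `cnn3` (100, 32).
#'
#' @param model One of `"cnn1"`, `"cnn2a"`, `"cnn2b"`, `"cnn3"`.
#' @param epochs,batch_size Override the model defaults (e.g. reduced
#'   epochs for calibration studies).
#' @param lr Adam step size.
#' @param seed Integer seed for weight initialization and batch order.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(model = c("cnn2b", "cnn1", "cnn2a", "cnn3"),
                       epochs = NULL, batch_size = NULL, lr = 1e-3,
                       seed = 1L) {
  model <- match.arg(model)
  defaults <- list(cnn1 = c(100L, 128L), cnn2a = c(150L, 128L),
                   cnn2b = c(150L, 128L), cnn3 = c(100L, 32L))[[model]]
  structure(list(model = model,
                 conv_units = c(64L, 128L, 64L), kernel_size = 3L,
                 epochs = as.integer(epochs %||% defaults[1]),
                 batch_size = as.integer(batch_size %||% defaults[2]),
                 lr = lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-7,
                 seed = as.integer(seed)),
            class = "cnn_config")
}

# glorot-uniform draw for a fan_in x fan_out pair
glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize CNN weights
#'
#' Glorot-uniform conv and dense kernels, zero biases, unit batch-norm
#' scale.  Deterministic given `config$seed`.
#'
#' @param n_rows Input channels (tensor rows).
#' @param config A [cnn_config()].
#' @return Weight list consumed by [train_cnn()] / [predict_cnn()].
#' @export
build_cnn <- function(n_rows, config) {
  stopifnot(n_rows > 0)
  set.seed(config$seed)
  units <- config$conv_units
  k <- config$kernel_size
  cin <- c(n_rows, units[1], units[2])
  w <- list()
  for (l in 1:3) {
    fan_in <- cin[l] * k
    fan_out <- units[l] * k
    w[[paste0("W", l)]] <- glorot(units[l], cin[l] * k, fan_in, fan_out)
    w[[paste0("b", l)]] <- numeric(units[l])
    w[[paste0("gamma", l)]] <- rep(1, units[l])
    w[[paste0("beta", l)]] <- numeric(units[l])
    w[[paste0("run_mean", l)]] <- numeric(units[l])
    w[[paste0("run_var", l)]] <- rep(1, units[l])
  }
  w$Wd <- glorot(1, units[3], units[3], 1)
  w$bd <- 0
  w
}

dataset_cube <- function(dataset) {
  x <- dataset$tensors
  storage.mode(x) <- "double"
  x
}

#' Train a CNN decoder on a labeled dataset
#'
#' Mini-batch order is drawn from R's RNG (seeded from `config$seed`), so
#' training is bit-reproducible.  No early stopping and no validation
#' split: a fixed number of epochs, as configured.
#'
#' @param dataset A `labeled_dataset` with both classes present.
#' @param config A [cnn_config()].
#' @param weights Optional initial weights (default [build_cnn()]).
#' @return A `memburst_cnn` model object.
#' @export
train_cnn <- function(dataset, config = cnn_config(), weights = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (length(unique(dataset$labels)) < 2)
    stop("training requires both classes present")
  n <- n_trials(dataset)
  set.seed(config$seed)
  if (is.null(weights)) weights <- build_cnn(dim(dataset$tensors)[1], config)
  perm <- t(vapply(seq_len(config$epochs), function(e) sample.int(n),
                   integer(n)))
  trained <- cnn_train_cpp(dataset_cube(dataset),
                           as.numeric(dataset$labels), weights, perm,
                           config$batch_size, config$lr, config$beta1,
                           config$beta2, config$eps)
  structure(list(weights = trained, config = config,
                 input_shape = dim(dataset$tensors)[1:2]),
            class = "memburst_cnn")
}

#' Predict class probabilities
#'
#' @param model A `memburst_cnn`.
#' @param dataset A `labeled_dataset` with the model's input shape.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_cnn <- function(model, dataset) {
  stopifnot(inherits(model, "memburst_cnn"))
  d <- dim(dataset$tensors)
  if (!all(d[1:2] == model$input_shape))
    stop("tensor shape ", d[1], "x", d[2], " does not match model input ",
         model$input_shape[1], "x", model$input_shape[2])
  as.numeric(cnn_predict_cpp(dataset_cube(dataset), model$weights))
}

#' @export
print.memburst_cnn <- function(x, ...) {
  cat(sprintf("memburst CNN (%s): input %d x %d, conv %s, %d epochs\n",
              x$config$model, x$input_shape[1], x$input_shape[2],
              paste(x$config$conv_units, collapse = "-"), x$config$epochs))
  invisible(x)
}
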