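#' Fit the glycosylation-site predictor on a labelled window table
#'
#' End-to-end training: assembles the 173-coefficient feature vector
#' for every window, fits the standardiser on these training rows
#' only, and trains the back-propagation network.
#'
#' @param windows Window table (data frame with `window` and integer
#'   0/1 `label` columns; see [read_window_table()]).
#' @param config An `nglyc_config` from [train_config()].
#' @return Object of class `nglyc_model`: `net`, `scaler`, `config`
#'   and the training `state`.
#' @export
nglyc_fit <- function(windows, config = train_config()) {
  stopifnot(is.data.frame(windows),
            all(c("window", "label") %in% names(windows)))
  y <- as.numeric(windows$label)
  if (anyNA(y)) stop("all training windows must be labelled 0/1")
  X <- feature_matrix(windows)
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  net <- init_network(c(ncol(X), config$hidden, 1L), seed = config$seed)
  fit <- mlp_train(net, Xs, y, config)
  structure(list(net = fit$params, scaler = scaler, config = config,
                 state = fit$state),
            class = "nglyc_model")
}

#' @export
print.nglyc_model <- function(x, ...) {
  st <- x$state
  cat(sprintf(
    "<nglyc_model> layers %s | %d epochs, final loss %.3g (%d rejected steps)\n",
    paste(x$net$sizes, collapse = "-"), st$epochs,
    st$loss_history[length(st$loss_history)], st$rejected))
  invisible(x)
}

#' Score or classify windows with a fitted model
#'
#' @param object An `nglyc_model`.
#' @param newdata Window table, a vector of 41-letter window strings,
#'   or a raw (unscaled) 173-column feature matrix.
#' @param type `"class"` for 0/1 labels (threshold from the training
#'   config) or `"score"` for raw sigmoid scores.
#' @param ... Unused.
#' @return Numeric scores or integer labels, one per window.
#' @export
predict.nglyc_model <- function(object, newdata,
                                type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  Xs <- apply_scaler(object$scaler, X)
  scores <- mlp_forward(object$net, Xs)
  if (type == "score") scores
  else as.integer(scores >= object$config$threshold)
}

#' Save / load a fitted model as versioned JSON
#'
#' The full parameter set — layer sizes, weights, biases, scaler and
#' training configuration — is written at full precision, so reloaded
#' models reproduce predictions bit for bit.
#'
#' @param model An `nglyc_model`.
#' @param path Output (or input) JSON path.
#' @return `save_model()` invisibly returns `path`; `load_model()`
#'   returns the restored `nglyc_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "nglyc_model"))
  obj <- list(
    format = "nglyc_model",
    version = 1L,
    sizes = model$net$sizes,
    W = lapply(model$net$W, function(w) as.vector(t(w))),
    b = model$net$b,
    scaler = list(center = as.numeric(model$scaler$center),
                  scale = as.numeric(model$scaler$scale)),
    config = unclass(model$config),
    state = model$state)
  # I(17) = 17 significant digits: exact decimal round-trip for doubles
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "nglyc_model") {
    stop("not an nglyc model file: ", path)
  }
  sizes <- as.integer(obj$sizes)
  W <- lapply(seq_len(length(sizes) - 1L), function(l) {
    matrix(obj$W[[l]], nrow = sizes[l + 1L], ncol = sizes[l],
           byrow = TRUE)
  })
  b <- lapply(obj$b, as.numeric)
  net <- structure(list(sizes = sizes, W = W, b = b),
                   class = "nglyc_net")
  scaler <- structure(list(center = obj$scaler$center,
                           scale = obj$scaler$scale),
                      class = "nglyc_scaler")
  cfg <- do.call(train_config, obj$config[c("hidden", "gamma0", "inc",
                                            "dec", "max_epochs", "tol",
                                            "seed", "threshold")])
  structure(list(net = net, scaler = scaler, config = cfg,
                 state = obj$state),
            class = "nglyc_model")
}
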