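# The sequence scorer in its three roles -- scan, prediction, strand --
# plus the score-adjustment transform.

#' Configure a sequence-scoring model
#'
#' The scorer is a 1-D residual convolutional network over one-hot DNA
#' windows: residual blocks of conv / batch norm / leaky ReLU with average
#' pooling, then global average pooling, dropout on the feature vector, a
#' dense layer and softmax. The default is a desk-scale configuration that
#' trains in minutes on one CPU; deeper/wider configurations (e.g. the
#' five-block variant) are available through the same arguments.
#'
#' @param n_res_blocks number of residual blocks.
#' @param channels convolution channels per block (recycled); the default
#'   ramps 8-16-32 so the full-resolution first block stays cheap.
#' @param kernel odd convolution kernel width in bp.
#' @param pool average-pooling stride per block (recycled); the default
#'   pools hardest at full resolution where compute is most expensive.
#' @param dropout_keep keep probability of the feature-vector dropout.
#' @param weight_decay L2 coefficient on convolution/dense weights.
#' @param lr Adam learning rate.
#' @param leaky_slope negative slope of the leaky ReLU.
#' @param n_outputs 2 (positive vs negative) or 3 (strand: +, -, .).
#' @param window_len odd input window length in bp.
#' @param seed seed for parameter initialization.
#' @return an object of class `model_config`.
#' @export
model_config <- function(n_res_blocks = 3L, channels = c(8L, 16L, 32L),
                         kernel = 9L, pool = c(8L, 4L, 2L), dropout_keep = 0.5,
                         weight_decay = 1e-4, lr = 1e-3,
                         leaky_slope = 0.01, n_outputs = 2L,
                         window_len = 1001L, seed = 1L) {
  if (n_res_blocks < 1L) stop("n_res_blocks must be >= 1")
  if (dropout_keep <= 0 || dropout_keep > 1) {
    stop("dropout_keep must lie in (0, 1]")
  }
  if (!n_outputs %in% c(2L, 3L)) stop("n_outputs must be 2 or 3")
  if (window_len %% 2L == 0L) stop("window_len must be odd")
  structure(list(n_res_blocks = as.integer(n_res_blocks),
                 channels = as.integer(channels), kernel = as.integer(kernel),
                 pool = as.integer(pool), dropout_keep = dropout_keep,
                 weight_decay = weight_decay, lr = lr,
                 leaky_slope = leaky_slope, n_outputs = as.integer(n_outputs),
                 window_len = as.integer(window_len),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Build an (untrained) scorer from a configuration
#'
#' @param config a [model_config()].
#' @param role one of `"scan"`, `"prediction"`, `"strand"`.
#' @return an object of class `scorer` holding the configuration, the
#'   network geometry and the (seeded) initial parameters.
#' @export
build_model <- function(config, role = c("scan", "prediction", "strand")) {
  stopifnot(inherits(config, "model_config"))
  role <- match.arg(role)
  if (role == "strand" && config$n_outputs != 3L) {
    stop("a strand scorer needs n_outputs = 3")
  }
  geom <- nn_build(config)
  params <- nn_init_params(config, geom)
  structure(list(config = config, geom = geom, params = params,
                 role = role, trained = FALSE),
            class = "scorer")
}

#' @export
print.scorer <- function(x, ...) {
  cat("scorer (role:", x$role, if (x$trained) ", trained" else ", untrained",
      ")\n", sep = "")
  cat("  ", x$config$n_res_blocks, " residual blocks, channels ",
      paste(rep_len(x$config$channels, x$config$n_res_blocks),
            collapse = "/"),
      ", kernel ", x$config$kernel, ", window ", x$config$window_len,
      " bp, ", x$config$n_outputs, " outputs\n", sep = "")
  invisible(x)
}

# Internal: class-probability matrix (n_outputs x B) for an encoded batch.
scorer_probs <- function(scorer, X) {
  if (nrow(X) != 4L * scorer$config$window_len) {
    stop("input length ", nrow(X) / 4, " does not match the model window (",
         scorer$config$window_len, " bp)")
  }
  nn_predict(scorer$geom, scorer$params, scorer$config, X)
}

#' Score a batch of windows
#'
#' Inference mode: dropout off, batch norm on its running statistics, so
#' scoring is deterministic and batch-size invariant.
#'
#' @param scorer a [build_model()] scorer (role scan or prediction).
#' @param windows either a `(4*L) x B` one-hot matrix, a list of `4 x L`
#'   one-hot matrices, or a character vector of window sequences.
#' @return numeric vector of positive-class scores in `[0, 1]`.
#' @export
score_batch <- function(scorer, windows) {
  stopifnot(inherits(scorer, "scorer"))
  X <- encode_any(windows, scorer$config$window_len)
  if (ncol(X) == 0L) return(numeric())
  probs <- scorer_probs(scorer, X)
  probs[1L, ]
}

encode_any <- function(windows, L) {
  if (is.character(windows)) {
    if (length(windows) == 0L) return(matrix(0, 4L * L, 0L))
    return(encode_seqs(windows))
  }
  if (is.list(windows)) {
    if (length(windows) == 0L) return(matrix(0, 4L * L, 0L))
    return(do.call(cbind, lapply(windows, as.vector)))
  }
  if (is.matrix(windows)) {
    if (nrow(windows) == 4L * L) return(windows)
    if (nrow(windows) == 4L && ncol(windows) == L) {
      return(matrix(as.vector(windows), ncol = 1L))
    }
    stop("input length ", ncol(windows),
         " does not match the model window (", L, " bp)")
  }
  stop("cannot interpret windows argument")
}

#' Call the strand of a window
#'
#' Argmax of the 3-class softmax (+, -, .); exact ties break by the fixed
#' class order +, -, .
#'
#' @param scorer a strand-role scorer (3 outputs).
#' @param windows as in [score_batch()].
#' @return character vector over `+`, `-`, `.`.
#' @export
strand_call <- function(scorer, windows) {
  stopifnot(inherits(scorer, "scorer"))
  if (scorer$config$n_outputs != 3L) {
    stop("strand_call needs a 3-output scorer")
  }
  X <- encode_any(windows, scorer$config$window_len)
  if (ncol(X) == 0L) return(character())
  probs <- scorer_probs(scorer, X)
  c("+", "-", ".")[apply(probs, 2, which.max)]
}

#' Adjust a softmax score for comparison with expression strength
#'
#' Softmax pushes scores toward 0 or 1; the transform
#' `log(1 + s / (1 - s))`, analytically equal to `-log(1 - s)`, undoes the
#' saturation. Strictly increasing on `[0, 1)`.
#'
#' @param s score(s) in `[0, 1)`.
#' @return adjusted score(s).
#' @export
adjust_score <- function(s) {
  if (any(s < 0 | s >= 1)) stop("scores must lie in [0, 1)")
  log(1 + s / (1 - s))
}

#' Save / load a scorer checkpoint
#'
#' The configuration is echoed as JSON next to the parameter blob so a
#' checkpoint is self-describing.
#'
#' @param scorer a `scorer`.
#' @param path checkpoint path (an `.rds` file; `<path>.json` is written
#'   alongside).
#' @return `path` ([save_scorer]) or the scorer ([load_scorer]).
#' @export
save_scorer <- function(scorer, path) {
  stopifnot(inherits(scorer, "scorer"))
  saveRDS(list(config = unclass(scorer$config), params = scorer$params,
               role = scorer$role, trained = scorer$trained), path)
  jsonlite::write_json(c(unclass(scorer$config), list(role = scorer$role)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_scorer
#' @export
load_scorer <- function(path) {
  blob <- readRDS(path)
  config <- do.call(model_config, blob$config)
  geom <- nn_build(config)
  structure(list(config = config, geom = geom, params = blob$params,
                 role = blob$role, trained = blob$trained),
            class = "scorer")
}
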