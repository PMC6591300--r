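#' LSTM regressor configuration
#'
#' Configuration of the small sequence-to-one regression LSTM that turns a
#' trial's windowed CSP feature sequence into one learned scalar feature.
#' Defaults follow the architecture used by the predictor: two stacked LSTM
#' layers with 100 and 20 hidden units, a fully connected layer, and a
#' regression output trained by stochastic gradient descent with momentum
#' for 100 epochs.
#'
#' @param input_dim features per time step (default 6 = 2 x 3 CSP pairs).
#' @param hidden_units integer vector of hidden sizes, one per LSTM layer.
#' @param learn_rate initial learning rate of SGD with momentum.
#' @param l2 L2 penalty on the weights (not biases).
#' @param momentum momentum coefficient.
#' @param max_epochs training epochs.
#' @param batch_size mini-batch size.
#' @param init_seed seed for weight initialization and epoch shuffling.
#' @return An `lstm_config` list.
#' @export
lstm_config <- function(input_dim = 6, hidden_units = c(100, 20),
                        learn_rate = 1e-2, l2 = 1e-4, momentum = 0.9,
                        max_epochs = 100, batch_size = 16, init_seed = 1) {
  if (length(hidden_units) < 1L) stop("hidden_units must be non-empty")
  if (learn_rate <= 0 || l2 < 0 || momentum < 0 || momentum >= 1) {
    stop("invalid optimizer settings")
  }
  structure(
    list(input_dim = as.integer(input_dim),
         hidden_units = as.integer(hidden_units),
         learn_rate = learn_rate, l2 = l2, momentum = momentum,
         max_epochs = as.integer(max_epochs),
         batch_size = as.integer(batch_size),
         init_seed = as.integer(init_seed)),
    class = "lstm_config"
  )
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Glorot-uniform matrix
glorot <- function(n_out, n_in) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in)
}

# Orthogonal H x H matrix via QR of a Gaussian matrix
orthogonal <- function(H) {
  q <- qr.Q(qr(matrix(stats::rnorm(H * H), H)))
  q * sign(diag(q))[col(q)]
}

#' Initialize an untrained LSTM regressor
#'
#' Glorot-uniform input weights, orthogonal recurrent weights (per gate),
#' zero biases except the forget-gate bias at 1. Gate row order within the
#' stacked weight matrices is input, forget, cell-candidate, output.
#'
#' @param config an [lstm_config()].
#' @return An `lstm_regressor` with untrained weights.
#' @export
init_lstm <- function(config) {
  stopifnot(inherits(config, "lstm_config"))
  with_seed(config$init_seed, {
    dims <- c(config$input_dim, config$hidden_units)
    layers <- lapply(seq_along(config$hidden_units), function(l) {
      d_in <- dims[l]; H <- dims[l + 1L]
      Wx <- do.call(rbind, lapply(1:4, function(g) glorot(H, d_in)))
      Wh <- do.call(rbind, lapply(1:4, function(g) orthogonal(H)))
      b <- rep(0, 4L * H)
      b[(H + 1L):(2L * H)] <- 1        # forget-gate bias
      list(Wx = Wx, Wh = Wh, b = b, H = H)
    })
    H_top <- config$hidden_units[length(config$hidden_units)]
    structure(
      list(layers = layers,
           fc_w = drop(glorot(1L, H_top)), fc_b = 0,
           config = config, classes = NULL, training_curve = numeric(0)),
      class = "lstm_regressor"
    )
  })
}

# Stack a list of N x d sequence matrices into a d x B x N array
# (columns = sequences, slices = time steps).
seq_list_to_array <- function(sequences) {
  N <- nrow(sequences[[1L]]); d <- ncol(sequences[[1L]])
  for (s in sequences) {
    if (nrow(s) != N || ncol(s) != d) {
      stop("all sequences must share the same length and feature dimension")
    }
  }
  arr <- array(0, c(d, length(sequences), N))
  for (i in seq_along(sequences)) arr[, i, ] <- t(sequences[[i]])
  arr
}

# Batched forward pass through the compiled core. X: d x N x B.
lstm_forward_batch <- function(model, X) {
  as.numeric(.lstm_forward_cpp(model$layers, model$fc_w, model$fc_b, X))
}

#' Mean-squared-error loss and analytic gradients
#'
#' Evaluates the training loss of a model on a batch of sequences and the
#' analytic gradient of that loss with respect to every weight, as used by
#' the training loop (without the L2 term). Exposed for gradient
#' verification.
#'
#' @param model an `lstm_regressor`.
#' @param sequences list of N x d sequence matrices.
#' @param targets numeric regression target per sequence.
#' @return List with `loss` and gradients (`layers`, `fc_w`, `fc_b`) shaped
#'   like the model parameters.
#' @export
lstm_loss_grad <- function(model, sequences, targets) {
  stopifnot(inherits(model, "lstm_regressor"))
  X <- seq_list_to_array(sequences)
  out <- .lstm_loss_grad_cpp(model$layers, model$fc_w, model$fc_b, X,
                             targets)
  out$fc_w <- as.numeric(out$fc_w)
  out$layers <- lapply(out$layers, function(g) {
    g$b <- as.numeric(g$b)
    g
  })
  out
}

#' LSTM forward evaluation of one sequence
#'
#' Standard gated recurrence (sigmoid input/forget/output gates, tanh cell
#' candidate and cell output, zero initial hidden and cell state), applied
#' layer by layer; the fully connected layer reads the top layer's hidden
#' state at the last time step.
#'
#' @param model an `lstm_regressor`.
#' @param seq an N x d sequence feature matrix (rows = windows in time
#'   order).
#' @return One real number.
#' @export
lstm_forward <- function(model, seq) {
  stopifnot(inherits(model, "lstm_regressor"))
  seq <- as.matrix(seq)
  if (ncol(seq) != model$config$input_dim) {
    stop("sequence has ", ncol(seq), " features, model expects ",
         model$config$input_dim)
  }
  lstm_forward_batch(model, seq_list_to_array(list(seq)))
}

#' Train the regression LSTM on per-trial feature sequences
#'
#' Minimizes the mean squared error between the network output and the
#' target encoding of each trial's class (+1 for the first class, -1 for
#' the second) by mini-batch stochastic gradient descent with momentum and
#' an L2 penalty on the weights. Training is deterministic given
#' `config$init_seed`.
#'
#' @param sequences list of N x d sequence feature matrices (equal shapes).
#' @param labels class id per sequence (two classes), or NULL when
#'   `targets` is given.
#' @param config an [lstm_config()].
#' @param classes optional length-2 vector fixing which class maps to +1.
#' @param targets optional numeric regression targets overriding the
#'   class encoding.
#' @return A trained `lstm_regressor`; `$training_curve` holds the per-epoch
#'   root-mean-squared training error.
#' @export
train_lstm_regressor <- function(sequences, labels = NULL, config = lstm_config(),
                                 classes = NULL, targets = NULL) {
  stopifnot(inherits(config, "lstm_config"))
  if (length(sequences) < 2L) stop("need at least 2 sequences")
  if (is.null(targets)) {
    labels <- as.character(labels)
    if (is.null(classes)) classes <- unique(labels)
    if (length(classes) != 2L) stop("labels must contain exactly two classes")
    targets <- ifelse(labels == classes[1L], 1, -1)
  }
  if (length(targets) != length(sequences)) {
    stop("targets length must match number of sequences")
  }
  X <- seq_list_to_array(sequences)
  if (dim(X)[1L] != config$input_dim) {
    stop("sequences have ", dim(X)[1L], " features, config expects ",
         config$input_dim)
  }
  model <- init_lstm(config)
  model$classes <- classes
  B_all <- length(sequences)
  perms <- with_seed(config$init_seed + 1L,
                     vapply(seq_len(config$max_epochs),
                            function(e) sample.int(B_all),
                            integer(B_all)))
  res <- .lstm_train_cpp(model$layers, model$fc_w, model$fc_b, X,
                         as.numeric(targets),
                         matrix(as.integer(perms), nrow = B_all),
                         config$learn_rate, config$l2, config$momentum,
                         config$batch_size)
  model$layers <- lapply(res$layers, function(ly) {
    list(Wx = ly$Wx, Wh = ly$Wh, b = as.numeric(ly$b), H = as.integer(ly$H))
  })
  model$fc_w <- as.numeric(res$fc_w)
  model$fc_b <- as.numeric(res$fc_b)
  model$training_curve <- as.numeric(res$curve)
  model
}

#' The learned LSTM scalar feature of one trial
#'
#' Identical to [lstm_forward()]; named for its role as the second feature
#' fed to the SVM.
#'
#' @inheritParams lstm_forward
#' @return One real number.
#' @export
lstm_feature <- function(model, seq) lstm_forward(model, seq)

#' @export
print.lstm_regressor <- function(x, ...) {
  cat("<lstm_regressor> layers:",
      paste(x$config$hidden_units, collapse = " -> "),
      "units; input_dim =", x$config$input_dim, "\n")
  if (length(x$training_curve)) {
    cat("trained ", length(x$training_curve), " epochs, final RMSE ",
        signif(utils::tail(x$training_curve, 1L), 4), "\n", sep = "")
  } else cat("untrained\n")
  invisible(x)
}
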