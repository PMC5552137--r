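# Run code under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit(if (had) assign(".Random.seed", old, envir = env)
          else suppressWarnings(rm(".Random.seed", envir = env)))
  set.seed(seed)
  force(code)
}

#' Training configuration for the back-propagation network
#'
#' @param hidden Integer vector of hidden-layer sizes (default one
#'   layer of 20 logistic units).
#' @param gamma0 Initial learning rate (> 0).
#' @param inc Learning-rate increase factor applied after an accepted
#'   epoch (> 1).
#' @param dec Learning-rate decrease factor applied after a rejected
#'   epoch (in (0, 1)).
#' @param max_epochs Maximum number of epochs.
#' @param tol Stop once the accepted mean-squared-error loss falls to
#'   or below this value.
#' @param seed Seed for weight initialisation.
#' @param threshold Decision threshold on the sigmoid output score;
#'   scores `>= threshold` are called positive.
#' @return List of class `nglyc_config`.
#' @export
train_config <- function(hidden = 20L, gamma0 = 0.5, inc = 1.05,
                         dec = 0.7, max_epochs = 500L, tol = 1e-6,
                         seed = 1L, threshold = 0.5) {
  stopifnot(gamma0 > 0, inc > 1, dec > 0, dec < 1,
            max_epochs >= 1, tol >= 0, all(hidden >= 1))
  structure(list(hidden = as.integer(hidden), gamma0 = gamma0,
                 inc = inc, dec = dec,
                 max_epochs = as.integer(max_epochs), tol = tol,
                 seed = as.integer(seed), threshold = threshold),
            class = "nglyc_config")
}

#' Initialise network parameters
#'
#' Weights are drawn uniformly in `(-1, 1) / sqrt(fan_in)` per layer,
#' reproducibly from the seed; biases start at zero.
#'
#' @param layout Integer vector of layer sizes, input first, e.g.
#'   `c(173, 20, 1)`.
#' @param seed RNG seed.
#' @return List of class `nglyc_net` with elements `sizes`, `W`
#'   (weight matrices, rows = output units) and `b` (bias vectors).
#' @export
init_network <- function(layout, seed = 1L) {
  layout <- as.integer(layout)
  if (length(layout) < 2L || any(layout < 1L)) {
    stop("layout needs at least input and output sizes, all >= 1")
  }
  with_seed(seed, {
    W <- vector("list", length(layout) - 1L)
    b <- vector("list", length(layout) - 1L)
    for (l in seq_along(W)) {
      fan_in <- layout[l]
      W[[l]] <- matrix(stats::runif(layout[l + 1L] * fan_in, -1, 1) /
                         sqrt(fan_in),
                       nrow = layout[l + 1L], ncol = fan_in)
      b[[l]] <- numeric(layout[l + 1L])
    }
    structure(list(sizes = layout, W = W, b = b), class = "nglyc_net")
  })
}

# Forward pass returning every layer's activation (input first).
mlp_activations <- function(net, X) {
  if (!is.matrix(X)) X <- rbind(X)
  if (ncol(X) != net$sizes[1L]) {
    stop("input has ", ncol(X), " features, network expects ",
         net$sizes[1L])
  }
  A <- vector("list", length(net$W) + 1L)
  A[[1L]] <- X
  for (l in seq_along(net$W)) {
    Z <- A[[l]] %*% t(net$W[[l]])
    Z <- sweep(Z, 2L, net$b[[l]], "+")
    A[[l + 1L]] <- stats::plogis(Z)
  }
  A
}

#' Forward pass: score windows with a network
#'
#' @param net An `nglyc_net`.
#' @param X Feature matrix (rows = windows) or a single feature vector,
#'   already standardised as at training time.
#' @return Numeric vector of sigmoid scores, strictly in (0, 1).
#' @export
mlp_forward <- function(net, X) {
  A <- mlp_activations(net, X)
  as.numeric(A[[length(A)]])
}

# Mean squared error of the network on (X, y).
mlp_loss <- function(net, X, y) {
  mean((mlp_forward(net, X) - y)^2)
}

#' Back-propagated gradient of the mean-squared-error loss
#'
#' Full-batch analytic gradient with respect to every weight and bias.
#'
#' @param net An `nglyc_net`.
#' @param X Feature matrix.
#' @param y Numeric 0/1 targets.
#' @return List with `W` and `b` gradient lists matching the network
#'   shapes, plus the current `loss`.
#' @export
mlp_gradient <- function(net, X, y) {
  if (!is.matrix(X)) X <- rbind(X)
  if (nrow(X) == 0L) stop("cannot train on empty data")
  stopifnot(length(y) == nrow(X))
  A <- mlp_activations(net, X)
  L <- length(net$W)
  n <- nrow(X)
  out <- A[[L + 1L]]
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- (2 / n) * (out - y) * out * (1 - out)
  for (l in L:1) {
    gW[[l]] <- t(delta) %*% A[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% net$W[[l]]) * A[[l]] * (1 - A[[l]])
    }
  }
  list(W = gW, b = gb, loss = mean((as.numeric(out) - y)^2))
}

# theta - gamma * grad, elementwise over all layers.
mlp_step <- function(net, grad, gamma) {
  for (l in seq_along(net$W)) {
    net$W[[l]] <- net$W[[l]] - gamma * grad$W[[l]]
    net$b[[l]] <- net$b[[l]] - gamma * grad$b[[l]]
  }
  net
}

#' One full-batch gradient-descent epoch
#'
#' Computes the batch gradient at the current parameters and returns
#' the candidate parameters `theta - gamma * grad` together with the
#' pre-step loss.  With `gamma = 0` the parameters are unchanged.
#'
#' @inheritParams mlp_gradient
#' @param gamma Learning rate for this epoch.
#' @return List with `params` (candidate `nglyc_net`) and `loss`
#'   (loss at the incoming parameters).
#' @export
train_epoch <- function(net, X, y, gamma) {
  grad <- mlp_gradient(net, X, y)
  list(params = mlp_step(net, grad, gamma), loss = grad$loss)
}

#' Train a network by gradient descent with adaptive learning rate
#'
#' Full-batch back-propagation.  After each epoch the candidate step is
#' accepted only if it does not increase the loss, in which case the
#' learning rate is multiplied by `config$inc`; otherwise the step is
#' discarded (weights restored) and the rate is multiplied by
#' `config$dec`.  The accepted-loss history is therefore non-increasing
#' by construction.  Training stops at `max_epochs` or when the loss
#' reaches `tol`.
#'
#' @param net Initial `nglyc_net` (see [init_network()]).
#' @param X Standardised feature matrix.
#' @param y Numeric 0/1 targets.
#' @param config An `nglyc_config` from [train_config()].
#' @return List with `params` (trained net) and `state`: epochs run,
#'   final learning rate, `loss_history` (accepted losses, element 1 =
#'   the initial loss) and the count of rejected steps.
#' @export
mlp_train <- function(net, X, y, config = train_config()) {
  if (!is.matrix(X)) X <- rbind(X)
  if (nrow(X) == 0L) stop("cannot train on empty data")
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  gamma <- config$gamma0
  cur_loss <- mlp_loss(net, X, y)
  if (!is.finite(cur_loss)) stop("non-finite loss at initialisation")
  history <- numeric(config$max_epochs + 1L)
  history[1L] <- cur_loss
  rejected <- 0L
  epoch <- 0L
  while (epoch < config$max_epochs && cur_loss > config$tol) {
    epoch <- epoch + 1L
    grad <- mlp_gradient(net, X, y)
    cand <- mlp_step(net, grad, gamma)
    cand_loss <- mlp_loss(cand, X, y)
    if (!is.finite(cand_loss)) {
      stop("non-finite loss at epoch ", epoch,
           " (learning rate ", format(gamma), "): diverged")
    }
    if (cand_loss <= cur_loss) {
      net <- cand
      cur_loss <- cand_loss
      gamma <- gamma * config$inc
    } else {
      rejected <- rejected + 1L
      gamma <- gamma * config$dec
    }
    history[epoch + 1L] <- cur_loss
  }
  list(params = net,
       state = list(epochs = epoch, gamma = gamma,
                    loss_history = history[seq_len(epoch + 1L)],
                    rejected = rejected))
}

#' Threshold network scores into class labels
#'
#' @param net Trained `nglyc_net`.
#' @param X Standardised feature matrix or vector.
#' @param threshold Decision threshold; scores `>= threshold` are
#'   positive (ties go to the positive class).
#' @return Integer vector of 0/1 labels.
#' @export
mlp_predict <- function(net, X, threshold = 0.5) {
  as.integer(mlp_forward(net, X) >= threshold)
}
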