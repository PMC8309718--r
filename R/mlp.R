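#' Multilayer perceptron specification
#'
#' Architecture and training control for the diagnostic MLP: two hidden layers
#' of 50 and 25 tanh units by default, a logistic output unit thresholded at
#' 0.5, mean-squared-error loss, and the stopping rules max epochs 500, loss
#' goal 0, minimum gradient 1e-7 and at most 6 validation failures on a
#' stratified 15% validation split of the training data.
#'
#' `optimizer = "lm"` is Levenberg-Marquardt on the residual Jacobian with the
#' damping schedule `mu` (initial 0.001, decrease x0.1 on accepted steps,
#' increase x10 on rejected ones, cap 1e10). LM is exact but its normal
#' equations scale with the square of the parameter count, so `"auto"`
#' (default) uses LM for networks up to `lm_max_params` parameters and
#' resilient backpropagation (iRprop-) — a standard first-order batch method
#' with the same stopping criteria — beyond that.
#'
#' @param hidden Integer vector of hidden-layer sizes.
#' @param max_epochs,goal,max_val_fail,min_gradient Stopping criteria.
#' @param mu,mu_dec,mu_inc,mu_max LM damping schedule.
#' @param optimizer `"auto"`, `"lm"` or `"rprop"`.
#' @param val_fraction Fraction of training data held out for the validation
#'   stop (0 disables it).
#' @param lm_max_params Parameter-count cutoff for `"auto"`.
#' @param seed Default seed for weight initialization and the validation split.
#' @return A list of class `rccad_mlp_spec`.
#' @export
mlp_spec <- function(hidden = c(50, 25), max_epochs = 500, goal = 0,
                     max_val_fail = 6, min_gradient = 1e-7,
                     mu = 0.001, mu_dec = 0.1, mu_inc = 10, mu_max = 1e10,
                     optimizer = c("auto", "lm", "rprop"),
                     val_fraction = 0.15, lm_max_params = 2000, seed = 17) {
  if (any(hidden < 1)) abort("hidden layer sizes must be positive")
  if (max_epochs < 1) abort("max_epochs must be >= 1")
  if (mu > mu_max) abort("initial mu must not exceed mu_max")
  structure(list(hidden = as.integer(hidden), max_epochs = as.integer(max_epochs),
                 goal = goal, max_val_fail = max_val_fail,
                 min_gradient = min_gradient, mu = mu, mu_dec = mu_dec,
                 mu_inc = mu_inc, mu_max = mu_max,
                 optimizer = match.arg(optimizer),
                 val_fraction = val_fraction,
                 lm_max_params = lm_max_params, seed = as.integer(seed)),
            class = "rccad_mlp_spec")
}

n_params <- function(sizes) {
  sum(sizes[-length(sizes)] * sizes[-1]) + sum(sizes[-1])
}

init_weights <- function(sizes, seed) {
  set.seed(seed)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    s <- sqrt(6 / (sizes[l] + sizes[l + 1]))
    W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1], -s, s), sizes[l], sizes[l + 1])
    b[[l]] <- runif(sizes[l + 1], -s, s)
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, X) {
  L <- length(par$W)
  A <- list(X)
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% par$W[[l]], 2, par$b[[l]], "+")
    A[[l + 1]] <- if (l < L) tanh(Z) else 1 / (1 + exp(-Z))
  }
  A
}

# gradients of SSE/n (mean squared error) wrt all parameters
mlp_gradients <- function(par, A, y) {
  L <- length(par$W)
  n <- nrow(A[[1]])
  out <- A[[L + 1]]
  delta <- (2 / n) * (out - y) * out * (1 - out)
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) delta <- (delta %*% t(par$W[[l]])) * (1 - A[[l]]^2)
  }
  list(W = gW, b = gb)
}

flatten_par <- function(par) unlist(c(par$W, par$b), use.names = FALSE)

unflatten_par <- function(v, sizes) {
  L <- length(sizes) - 1
  W <- list(); b <- list()
  pos <- 0L
  for (l in seq_len(L)) {
    k <- sizes[l] * sizes[l + 1]
    W[[l]] <- matrix(v[pos + seq_len(k)], sizes[l], sizes[l + 1])
    pos <- pos + k
  }
  for (l in seq_len(L)) {
    k <- sizes[l + 1]
    b[[l]] <- v[pos + seq_len(k)]
    pos <- pos + k
  }
  list(W = W, b = b)
}

# residual Jacobian d(out)/d(params), n x P, column order matching flatten_par
mlp_jacobian <- function(par, A) {
  L <- length(par$W)
  n <- nrow(A[[1]])
  out <- A[[L + 1]]
  deltas <- vector("list", L)
  deltas[[L]] <- out * (1 - out) # d out / d z_L
  for (l in rev(seq_len(L - 1))) {
    deltas[[l]] <- (deltas[[l + 1]] %*% t(par$W[[l + 1]])) * (1 - A[[l + 1]]^2)
  }
  blocksW <- lapply(seq_len(L), function(l) {
    p_in <- ncol(A[[l]]); p_out <- ncol(deltas[[l]])
    A[[l]][, rep(seq_len(p_in), times = p_out), drop = FALSE] *
      deltas[[l]][, rep(seq_len(p_out), each = p_in), drop = FALSE]
  })
  do.call(cbind, c(blocksW, deltas))
}

#' Train the diagnostic MLP
#'
#' Binary classifier on standardized features (z-scores computed from the
#' supplied training data only, so cross-validation folds stay leak-free).
#' Deterministic for a given seed.
#'
#' @param x Numeric feature matrix (subjects x features).
#' @param y Binary labels: logical, 0/1, or a two-level factor.
#' @param spec A [mlp_spec()].
#' @param seed Overrides `spec$seed` for initialization and validation split.
#' @return An object of class `rccad_mlp` with the fitted weights, the
#'   standardization constants and a training history.
#' @export
mlp_train <- function(x, y, spec = mlp_spec(), seed = spec$seed) {
  x <- as.matrix(x)
  if (is.factor(y)) {
    levels_ <- levels(y)
    if (length(levels_) != 2) abort("y must have exactly two classes")
    yb <- as.numeric(y == levels_[2])
  } else {
    levels_ <- c("0", "1")
    yb <- as.numeric(as.logical(y) | y == 1)
  }
  if (length(unique(yb)) < 2) abort("training set contains a single class")
  if (min(table(yb)) < 2) abort("need at least 2 subjects per class")
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")

  n <- nrow(xs)
  use_val <- spec$val_fraction > 0 && is.finite(spec$max_val_fail) && n >= 10
  set.seed(seed)
  val_idx <- integer(0)
  if (use_val) {
    for (cl in unique(yb)) {
      ic <- which(yb == cl)
      k <- max(1L, round(spec$val_fraction * length(ic)))
      k <- min(k, length(ic) - 2L) # keep >= 2 per class in training
      if (k > 0) val_idx <- c(val_idx, sample(ic, k))
    }
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- xs[tr_idx, , drop = FALSE]; ytr <- yb[tr_idx]
  Xva <- xs[val_idx, , drop = FALSE]; yva <- yb[val_idx]

  sizes <- c(ncol(xs), spec$hidden, 1L)
  par <- init_weights(sizes, seed)
  P <- n_params(sizes)
  optimizer <- spec$optimizer
  if (optimizer == "auto") optimizer <- if (P <= spec$lm_max_params) "lm" else "rprop"

  fit <- if (optimizer == "lm") {
    train_lm(par, sizes, Xtr, ytr, Xva, yva, spec)
  } else {
    train_rprop(par, sizes, Xtr, ytr, Xva, yva, spec)
  }
  structure(list(weights = fit$par, sizes = sizes, center = center,
                 scale = scale_, levels = levels_, optimizer = optimizer,
                 history = fit$history, stopped_by = fit$stopped_by,
                 seed = seed),
            class = "rccad_mlp")
}

mse_of <- function(par, X, y) {
  out <- mlp_forward(par, X)[[length(par$W) + 1]]
  mean((out - y)^2)
}

check_val <- function(state, par, Xva, yva, spec) {
  if (!length(yva)) return(state)
  v <- mse_of(par, Xva, yva)
  if (v < state$best_val - 1e-12) {
    state$best_val <- v
    state$best_par <- par
    state$fails <- 0L
  } else {
    state$fails <- state$fails + 1L
  }
  state$val <- v
  state
}

train_rprop <- function(par, sizes, Xtr, ytr, Xva, yva, spec) {
  v <- flatten_par(par)
  step <- rep(0.01, length(v))
  g_old <- numeric(length(v))
  state <- list(best_val = Inf, best_par = par, fails = 0L, val = NA_real_)
  history <- list()
  stopped_by <- "max_epochs"
  for (epoch in seq_len(spec$max_epochs)) {
    par <- unflatten_par(v, sizes)
    A <- mlp_forward(par, Xtr)
    loss <- mean((A[[length(sizes)]] - ytr)^2)
    g <- mlp_gradients(par, A, ytr)
    gv <- flatten_par(g)
    state <- check_val(state, par, Xva, yva, spec)
    history[[epoch]] <- c(epoch = epoch, train = loss, val = state$val)
    if (loss <= spec$goal) { stopped_by <- "goal"; break }
    if (max(abs(gv)) < spec$min_gradient) { stopped_by <- "min_gradient"; break }
    if (length(yva) && state$fails > spec$max_val_fail) { stopped_by <- "val_fail"; break }
    s <- gv * g_old
    step[s > 0] <- pmin(step[s > 0] * 1.2, 50)
    step[s < 0] <- pmax(step[s < 0] * 0.5, 1e-9)
    gv[s < 0] <- 0
    v <- v - sign(gv) * step
    g_old <- gv
  }
  final_par <- if (length(yva) && stopped_by == "val_fail") state$best_par else unflatten_par(v, sizes)
  list(par = final_par, history = history_tbl(history), stopped_by = stopped_by)
}

train_lm <- function(par, sizes, Xtr, ytr, Xva, yva, spec) {
  mu <- spec$mu
  n <- nrow(Xtr)
  state <- list(best_val = Inf, best_par = par, fails = 0L, val = NA_real_)
  history <- list()
  stopped_by <- "max_epochs"
  v <- flatten_par(par)
  sse <- sum((mlp_forward(par, Xtr)[[length(sizes)]] - ytr)^2)
  for (epoch in seq_len(spec$max_epochs)) {
    par <- unflatten_par(v, sizes)
    A <- mlp_forward(par, Xtr)
    r <- as.numeric(A[[length(sizes)]] - ytr)
    J <- mlp_jacobian(par, A)
    g <- 2 * crossprod(J, r)
    state <- check_val(state, par, Xva, yva, spec)
    history[[epoch]] <- c(epoch = epoch, train = mean(r^2), val = state$val)
    if (mean(r^2) <= spec$goal) { stopped_by <- "goal"; break }
    if (max(abs(g)) < spec$min_gradient) { stopped_by <- "min_gradient"; break }
    if (length(yva) && state$fails > spec$max_val_fail) { stopped_by <- "val_fail"; break }
    JtJ <- crossprod(J)
    Jtr <- crossprod(J, r)
    accepted <- FALSE
    while (!accepted && mu <= spec$mu_max) {
      d <- tryCatch(solve(JtJ + diag(mu, ncol(J)), Jtr), error = function(e) NULL)
      if (!is.null(d)) {
        v_try <- v - as.numeric(d)
        sse_try <- sum((mlp_forward(unflatten_par(v_try, sizes), Xtr)[[length(sizes)]] - ytr)^2)
        if (sse_try < sse) {
          v <- v_try
          sse <- sse_try
          mu <- max(mu * spec$mu_dec, 1e-20)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * spec$mu_inc
    }
    if (!accepted) { stopped_by <- "mu_max"; break }
  }
  final_par <- if (length(yva) && stopped_by == "val_fail") state$best_par else unflatten_par(v, sizes)
  list(par = final_par, history = history_tbl(history), stopped_by = stopped_by)
}

history_tbl <- function(history) {
  tibble::as_tibble(as.data.frame(do.call(rbind, history)))
}

#' Predict with a trained MLP
#'
#' @param object A `rccad_mlp`.
#' @param newdata Feature matrix with the training columns.
#' @param type `"prob"` for the logistic output, `"class"` for the 0.5
#'   threshold decision.
#' @param ... Unused.
#' @export
predict.rccad_mlp <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  p <- as.numeric(mlp_forward(object$weights, xs)[[length(object$sizes)]])
  if (type == "prob") return(p)
  factor(object$levels[(p > 0.5) + 1L], levels = object$levels)
}

#' @export
print.rccad_mlp <- function(x, ...) {
  cat(sprintf("<MLP> layers %s, optimizer %s, %d epochs, stopped by %s\n",
              paste(x$sizes, collapse = "-"), x$optimizer,
              nrow(x$history), x$stopped_by))
  invisible(x)
}
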