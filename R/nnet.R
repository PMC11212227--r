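# Minimal feed-forward binary classifier: two ReLU hidden layers, sigmoid
# output, Adam optimiser, minibatch training. Written in plain matrix code
# so the rule-weighted cross-entropy (csl/ctl) can drive the gradient
# directly: the gradient of the weighted BCE w.r.t. the output logit is
# w * (p - y) with w = alpha + 1 on samples whose rule verdict matches the
# label, 1 otherwise.

.nn_init <- function(n_in, hidden, seed) {
  set.seed(seed)
  sizes <- c(n_in, hidden, 1L)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    # He initialisation for the ReLU layers
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                  sd = sqrt(2 / sizes[l])),
                     nrow = sizes[l], ncol = sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b)
}

.nn_forward <- function(par, X) {
  A <- list(X)
  L <- length(par$W)
  for (l in seq_len(L - 1)) {
    Z <- sweep(A[[l]] %*% par$W[[l]], 2, par$b[[l]], `+`)
    A[[l + 1]] <- pmax(Z, 0)
  }
  z_out <- drop(A[[L]] %*% par$W[[L]]) + par$b[[L]]
  p <- 1 / (1 + exp(-z_out))
  list(A = A, p = p)
}

# One Adam step on a minibatch; returns updated parameters and moments.
.nn_step <- function(par, mom, X, y, w, lr, t, beta1 = 0.9, beta2 = 0.999,
                     adam_eps = 1e-8) {
  L <- length(par$W)
  fw <- .nn_forward(par, X)
  n <- nrow(X)
  delta <- matrix(w * (fw$p - y) / n, ncol = 1)   # dLoss/dz_out
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in seq(L, 1)) {
    gW[[l]] <- t(fw$A[[l]]) %*% delta
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(par$W[[l]])) * (fw$A[[l]] > 0)
    }
  }
  for (l in seq_len(L)) {
    mom$mW[[l]] <- beta1 * mom$mW[[l]] + (1 - beta1) * gW[[l]]
    mom$vW[[l]] <- beta2 * mom$vW[[l]] + (1 - beta2) * gW[[l]]^2
    mom$mb[[l]] <- beta1 * mom$mb[[l]] + (1 - beta1) * gb[[l]]
    mom$vb[[l]] <- beta2 * mom$vb[[l]] + (1 - beta2) * gb[[l]]^2
    mhW <- mom$mW[[l]] / (1 - beta1^t); vhW <- mom$vW[[l]] / (1 - beta2^t)
    mhb <- mom$mb[[l]] / (1 - beta1^t); vhb <- mom$vb[[l]] / (1 - beta2^t)
    par$W[[l]] <- par$W[[l]] - lr * mhW / (sqrt(vhW) + adam_eps)
    par$b[[l]] <- par$b[[l]] - lr * mhb / (sqrt(vhb) + adam_eps)
  }
  list(par = par, mom = mom)
}

.nn_train <- function(X, y, r = NULL, hidden = c(12, 8), batch_size = 20,
                      epochs = 24, lr = 1e-3, alpha = 3,
                      loss = c("standard", "custom"), seed = 1) {
  loss <- match.arg(loss)
  n <- nrow(X)
  w <- rep(1, n)
  if (loss == "custom") {
    if (is.null(r)) stop("custom loss requires a rule vector")
    w[!is.na(r) & r == y] <- alpha + 1
  }
  par <- .nn_init(ncol(X), hidden, seed)
  zeros <- function(x) lapply(x, function(m) m * 0)
  mom <- list(mW = zeros(par$W), vW = zeros(par$W),
              mb = zeros(par$b), vb = zeros(par$b))
  t_step <- 0
  for (ep in seq_len(epochs)) {
    set.seed(seed + 1000L * ep)
    idx <- sample.int(n)
    starts <- seq(1, n, by = batch_size)
    for (s in starts) {
      take <- idx[s:min(s + batch_size - 1, n)]
      t_step <- t_step + 1
      st <- .nn_step(par, mom, X[take, , drop = FALSE], y[take], w[take],
                     lr, t_step)
      par <- st$par; mom <- st$mom
    }
  }
  par
}
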