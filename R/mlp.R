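# Internal fully-connected network engine: ReLU hidden layers with
# inverted dropout, sigmoid/softmax heads, Adam on (binary) cross-entropy.
# Matrix-only implementation; sized for feature vectors, not images.

mlp_init <- function(sizes, out_units) {
  dims <- c(sizes, out_units)
  W <- vector("list", length(dims) - 1)
  b <- vector("list", length(dims) - 1)
  for (l in seq_along(W)) {
    fan_in <- dims[l]
    W[[l]] <- matrix(stats::rnorm(fan_in * dims[l + 1], 0,
                                  sqrt(2 / fan_in)),
                     fan_in, dims[l + 1])
    b[[l]] <- rep(0, dims[l + 1])
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, X, dropout = 0, training = FALSE) {
  L <- length(par$W)
  A <- vector("list", L + 1)
  M <- vector("list", L)       # dropout masks on hidden activations
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% par$W[[l]], 2, par$b[[l]], "+")
    if (l < L) {
      H <- pmax(Z, 0)
      if (training && dropout > 0) {
        m <- matrix(stats::runif(length(H)) >= dropout, nrow(H), ncol(H))
        H <- H * m / (1 - dropout)
        M[[l]] <- m
      }
      A[[l + 1]] <- H
    } else {
      A[[l + 1]] <- Z           # head activation applied by caller
    }
  }
  list(A = A, M = M, Z_out = A[[L + 1]])
}

mlp_head <- function(Z, output) {
  if (output == "sigmoid") {
    1 / (1 + exp(-Z))
  } else {
    E <- exp(Z - apply(Z, 1, max))
    E / rowSums(E)
  }
}

# Gradient of mean cross-entropy wrt Z_out is (P - Y) / n for both heads.
mlp_backward <- function(par, fw, Y, P, dropout = 0) {
  L <- length(par$W)
  n <- nrow(Y)
  dZ <- (P - Y) / n
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fw$A[[l]], dZ)
    gb[[l]] <- colSums(dZ)
    if (l > 1) {
      dH <- dZ %*% t(par$W[[l]])
      if (dropout > 0 && !is.null(fw$M[[l - 1]]))
        dH <- dH * fw$M[[l - 1]] / (1 - dropout)
      dZ <- dH * (fw$A[[l]] > 0)
    }
  }
  list(W = gW, b = gb)
}

mlp_loss <- function(P, Y) {
  eps <- 1e-12
  -mean(rowSums(Y * log(P + eps) + if (ncol(Y) == 1) (1 - Y) * log(1 - P + eps)
                else 0))
}

adam_state <- function(par) {
  zero <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x))
                      else rep(0, length(x))
  list(mW = lapply(par$W, zero), vW = lapply(par$W, zero),
       mb = lapply(par$b, zero), vb = lapply(par$b, zero), t = 0)
}

adam_step <- function(par, grad, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (l in seq_along(par$W)) {
    st$mW[[l]] <- beta1 * st$mW[[l]] + (1 - beta1) * grad$W[[l]]
    st$vW[[l]] <- beta2 * st$vW[[l]] + (1 - beta2) * grad$W[[l]]^2
    par$W[[l]] <- par$W[[l]] -
      lr * (st$mW[[l]] / c1) / (sqrt(st$vW[[l]] / c2) + eps)
    st$mb[[l]] <- beta1 * st$mb[[l]] + (1 - beta1) * grad$b[[l]]
    st$vb[[l]] <- beta2 * st$vb[[l]] + (1 - beta2) * grad$b[[l]]^2
    par$b[[l]] <- par$b[[l]] -
      lr * (st$mb[[l]] / c1) / (sqrt(st$vb[[l]] / c2) + eps)
  }
  list(par = par, st = st)
}

# One-hot (multiclass) or single-column (binary) response matrix.
response_matrix <- function(y, levels, output) {
  if (output == "sigmoid") {
    matrix(as.numeric(y == levels[2]), ncol = 1)
  } else {
    Y <- matrix(0, length(y), length(levels))
    Y[cbind(seq_along(y), match(y, levels))] <- 1
    Y
  }
}

mlp_fit <- function(X, y, spec, epochs = 200, batch_size = 32, lr = 1e-3,
                    patience = 20, val_frac = 0.1) {
  levels <- sort(unique(as.character(y)))
  output <- if (length(levels) == 2 && spec$output == "sigmoid") "sigmoid"
            else "softmax"
  out_units <- if (output == "sigmoid") 1L else length(levels)
  par <- mlp_init(c(ncol(X), spec$hidden_sizes), out_units)
  st <- adam_state(par)
  n <- nrow(X)

  n_val <- if (patience > 0) max(2L, round(val_frac * n)) else 0L
  idx <- sample.int(n)
  val_idx <- idx[seq_len(n_val)]
  tr_idx <- if (n_val > 0) idx[-seq_len(n_val)] else idx
  Xtr <- X[tr_idx, , drop = FALSE]
  Ytr <- response_matrix(y[tr_idx], levels, output)
  Xval <- X[val_idx, , drop = FALSE]
  Yval <- response_matrix(y[val_idx], levels, output)

  best <- list(par = par, loss = Inf, wait = 0)
  ntr <- nrow(Xtr)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(ntr)
    for (start in seq(1, ntr, by = batch_size)) {
      bi <- ord[start:min(start + batch_size - 1, ntr)]
      fw <- mlp_forward(par, Xtr[bi, , drop = FALSE], spec$dropout_rate,
                        training = TRUE)
      P <- mlp_head(fw$Z_out, output)
      gr <- mlp_backward(par, fw, Ytr[bi, , drop = FALSE], P,
                         spec$dropout_rate)
      upd <- adam_step(par, gr, st, lr)
      par <- upd$par
      st <- upd$st
    }
    if (n_val > 0) {
      Pv <- mlp_head(mlp_forward(par, Xval)$Z_out, output)
      vl <- mlp_loss(Pv, Yval)
      if (vl < best$loss - 1e-6) {
        best <- list(par = par, loss = vl, wait = 0)
      } else {
        best$wait <- best$wait + 1
        if (best$wait >= patience) break
      }
    }
  }
  if (n_val > 0) par <- best$par
  structure(list(par = par, levels = levels, output = output, spec = spec),
            class = "dmlp_model")
}

mlp_predict_proba <- function(model, X) {
  P <- mlp_head(mlp_forward(model$par, X)$Z_out, model$output)
  if (model$output == "sigmoid") {
    cbind(1 - P[, 1], P[, 1])
  } else P
}
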