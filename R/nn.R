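# Internal neural-network engine.
#
# Each ensemble member is a small multi-task CNN: one-hot input (L x 4) ->
# convolution (F1 filters, width w1, optionally initialized from motif
# log-odds) -> ReLU -> member-specific convolution (F2 filters, width w2) ->
# ReLU -> global max pooling over positions -> dense sigmoid head with one
# output per class. Convolutions are evaluated as im2col patch matrices times
# weight matrices so the heavy lifting is BLAS matrix multiplication; training
# is mini-batch Adam on binary cross-entropy with early stopping on
# validation loss.
#
# Layouts (all row-major over (n, p) pairs, position fastest):
#   codes  : N x L integer matrix, A=1 C=2 G=3 T=4 N=5
#   Xcol   : (N*P1) x (4*w1); row r = (n-1)*P1 + p; col = (j-1)*4 + base
#   A1     : (N*P1) x F1 feature map after layer 1
#   A1col  : (N*P2) x (F1*w2) patches of A1 for layer 2
#   A2     : (N*P2) x F2; pooled to G: N x F2

seq_to_code <- function(sequences) {
  n <- length(sequences)
  L <- nchar(sequences[1])
  flat <- match(
    unlist(strsplit(toupper(sequences), "", fixed = TRUE), use.names = FALSE),
    c(DNA_BASES, "N")
  )
  if (anyNA(flat)) stop_pe("sequences contain characters outside {A,C,G,T,N}")
  matrix(flat, nrow = n, ncol = L, byrow = TRUE)
}

# im2col for the one-hot input; N bases contribute 0.25 per channel.
nn_xcol <- function(codes, w1) {
  N <- nrow(codes); L <- ncol(codes)
  P1 <- L - w1 + 1L
  X <- matrix(0, N * P1, 4L * w1)
  for (j in seq_len(w1)) {
    v <- as.vector(t(codes[, j:(j + P1 - 1L), drop = FALSE]))
    off <- (j - 1L) * 4L
    for (b in 1:4) {
      hit <- v == b
      if (any(hit)) X[hit, off + b] <- 1
    }
    amb <- v == 5L
    if (any(amb)) X[amb, off + (1:4)] <- 0.25
  }
  X
}

# Motif log-odds initialization for the first convolution: log2((p+eps)/0.25),
# centered within the filter width, zero elsewhere. PWMs are recycled when
# there are more filters than motifs.
motif_filters <- function(pwms, w1, n_filters, pseudocount = 0.01) {
  W <- matrix(0, 4L * w1, n_filters)
  for (k in seq_len(n_filters)) {
    p <- pwms[[((k - 1L) %% length(pwms)) + 1L]]
    m <- p$matrix
    Lm <- min(nrow(m), w1)
    offset <- floor((w1 - Lm) / 2)
    lo <- log2((m[seq_len(Lm), , drop = FALSE] + pseudocount) / 0.25)
    for (j in seq_len(Lm)) {
      W[(offset + j - 1L) * 4L + (1:4), k] <- lo[j, ]
    }
  }
  W
}

nn_init <- function(L, C, F1, w1, F2, w2, seed, motif_pwms = NULL) {
  if (w1 > L || (L - w1 + 1L) < w2) {
    stop_pe("filter widths (", w1, ", ", w2, ") too large for window length ",
            L)
  }
  params <- with_seed(seed, {
    W1 <- if (!is.null(motif_pwms)) {
      motif_filters(motif_pwms, w1, F1)
    } else {
      matrix(rnorm(4L * w1 * F1, sd = sqrt(2 / (4 * w1))), 4L * w1, F1)
    }
    list(
      W1 = W1,
      b1 = numeric(F1),
      W2 = matrix(rnorm(F1 * w2 * F2, sd = sqrt(2 / (F1 * w2))), F1 * w2, F2),
      b2 = numeric(F2),
      # near-zero head keeps initial predictions near 0.5 regardless of the
      # scale of motif-initialized convolution activations
      Wd = matrix(rnorm(F2 * C, sd = 0.01), F2, C),
      bd = numeric(C)
    )
  })
  list(L = as.integer(L), C = as.integer(C), F1 = as.integer(F1),
       w1 = as.integer(w1), F2 = as.integer(F2), w2 = as.integer(w2),
       params = params)
}

nn_forward <- function(net, codes, keep_cache = FALSE) {
  p <- net$params
  N <- nrow(codes)
  P1 <- net$L - net$w1 + 1L
  P2 <- P1 - net$w2 + 1L
  Xcol <- nn_xcol(codes, net$w1)
  Z1 <- sweep(Xcol %*% p$W1, 2, p$b1, "+")
  A1 <- Z1 * (Z1 > 0)
  base <- rep(seq_len(N) - 1L, each = P2) * P1 + rep(seq_len(P2), N)
  A1col <- matrix(0, N * P2, net$F1 * net$w2)
  for (j in seq_len(net$w2)) {
    A1col[, (j - 1L) * net$F1 + seq_len(net$F1)] <-
      A1[base + (j - 1L), , drop = FALSE]
  }
  Z2 <- sweep(A1col %*% p$W2, 2, p$b2, "+")
  A2 <- Z2 * (Z2 > 0)
  G <- matrix(0, N, net$F2)
  amax <- matrix(0L, N, net$F2)
  for (f in seq_len(net$F2)) {
    m <- matrix(A2[, f], nrow = P2)           # (p, n)
    pid <- max.col(t(m), ties.method = "first")
    G[, f] <- m[cbind(pid, seq_len(N))]
    amax[, f] <- (seq_len(N) - 1L) * P2 + pid
  }
  logits <- sweep(G %*% p$Wd, 2, p$bd, "+")
  probs <- 1 / (1 + exp(-logits))
  out <- list(probs = probs)
  if (keep_cache) {
    out$cache <- list(Xcol = Xcol, Z1 = Z1, A1col = A1col, Z2 = Z2, G = G,
                      amax = amax, base = base, N = N, P1 = P1, P2 = P2)
  }
  out
}

# Backward pass from d(loss)/d(logits); returns parameter gradients and,
# optionally, the gradient with respect to the one-hot input (for saliency).
nn_backward <- function(net, cache, dlogits, input_grad = FALSE) {
  p <- net$params
  N <- cache$N; P2 <- cache$P2
  dWd <- crossprod(cache$G, dlogits)
  dbd <- colSums(dlogits)
  dG <- dlogits %*% t(p$Wd)
  dA2 <- matrix(0, N * P2, net$F2)
  for (f in seq_len(net$F2)) {
    dA2[cbind(cache$amax[, f], f)] <- dG[, f]
  }
  dZ2 <- dA2 * (cache$Z2 > 0)
  dW2 <- crossprod(cache$A1col, dZ2)
  db2 <- colSums(dZ2)
  dA1col <- dZ2 %*% t(p$W2)
  dA1 <- matrix(0, N * cache$P1, net$F1)
  for (j in seq_len(net$w2)) {
    rows <- cache$base + (j - 1L)
    dA1[rows, ] <- dA1[rows, , drop = FALSE] +
      dA1col[, (j - 1L) * net$F1 + seq_len(net$F1), drop = FALSE]
  }
  dZ1 <- dA1 * (cache$Z1 > 0)
  dW1 <- crossprod(cache$Xcol, dZ1)
  db1 <- colSums(dZ1)
  grads <- list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, Wd = dWd, bd = dbd)
  if (input_grad) {
    dXcol <- dZ1 %*% t(p$W1)
    dX <- array(0, dim = c(N, net$L, 4L))
    P1 <- cache$P1
    n_idx <- rep(seq_len(N), each = P1)
    p_idx <- rep(seq_len(P1), N)
    for (j in seq_len(net$w1)) {
      pos <- p_idx + (j - 1L)
      for (b in 1:4) {
        dX[cbind(n_idx, pos, b)] <- dX[cbind(n_idx, pos, b)] +
          dXcol[, (j - 1L) * 4L + b]
      }
    }
    grads$X <- dX
  }
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

nn_bce <- function(probs, labels) {
  p <- clip01(probs, 1e-7)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

nn_predict <- function(net, codes, batch_size = 512L) {
  N <- nrow(codes)
  out <- matrix(0, N, net$C)
  for (s in seq(1L, N, by = batch_size)) {
    e <- min(s + batch_size - 1L, N)
    out[s:e, ] <- nn_forward(net, codes[s:e, , drop = FALSE])$probs
  }
  out
}

# Train one member. Returns the trained net plus a per-epoch log. Early
# stopping: stop when validation loss has not improved for `patience`
# consecutive epochs; the best-epoch weights are restored.
nn_train <- function(net, codes, labels, val_codes = NULL, val_labels = NULL,
                     epochs = 5, patience = 2, batch_size = 256,
                     learning_rate = 1e-3, seed = 1) {
  state <- adam_init(net$params)
  has_val <- !is.null(val_codes) && nrow(val_codes) > 0
  best_loss <- Inf
  best_params <- net$params
  stale <- 0L
  log <- list()
  N <- nrow(codes)
  for (epoch in seq_len(epochs)) {
    ord <- with_seed(child_seed(seed, epoch), sample.int(N))
    train_loss <- 0; n_batch <- 0L
    for (s in seq(1L, N, by = batch_size)) {
      idx <- ord[s:min(s + batch_size - 1L, N)]
      fwd <- nn_forward(net, codes[idx, , drop = FALSE], keep_cache = TRUE)
      y <- labels[idx, , drop = FALSE]
      train_loss <- train_loss + nn_bce(fwd$probs, y)
      n_batch <- n_batch + 1L
      dlogits <- (fwd$probs - y) / length(y)
      grads <- nn_backward(net, fwd$cache, dlogits)
      upd <- adam_step(net$params, grads, state, lr = learning_rate)
      net$params <- upd$params
      state <- upd$state
    }
    val_loss <- if (has_val) {
      nn_bce(nn_predict(net, val_codes), val_labels)
    } else NA_real_
    log[[epoch]] <- tibble(epoch = epoch,
                           train_loss = train_loss / n_batch,
                           validation_loss = val_loss)
    if (has_val) {
      if (val_loss < best_loss - 1e-12) {
        best_loss <- val_loss
        best_params <- net$params
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= patience) break
      }
    }
  }
  if (has_val) net$params <- best_params
  list(net = net, log = dplyr::bind_rows(log))
}
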