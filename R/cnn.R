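# A compact convolutional text classifier: learned token embeddings, one
# 1-D convolution layer (ReLU), max-pooling over positions and a logistic
# head, trained with Adam. Sized for corpora of hundreds of documents.

cnn_defaults <- function(hp = list()) {
  list(
    dim = hp$dim %||% 16L,            # embedding dimension
    filters = hp$filters %||% 24L,    # convolution filters
    window = hp$window %||% 3L,       # convolution window (tokens)
    max_len = hp$max_len %||% 80L,    # truncation length (tokens)
    epochs = hp$epochs %||% 15L,
    lr = hp$lr %||% 0.01,
    batch = hp$batch %||% 8L,
    min_count = hp$min_count %||% 1L
  )
}

cnn_encode <- function(texts, vocab, max_len) {
  lapply(bow_tokens(texts), function(t) {
    ids <- match(t, vocab)
    ids[is.na(ids)] <- 0L
    utils::head(as.integer(ids), max_len)
  })
}

train_cnn <- function(train, dev, hp, seed) {
  cfg <- cnn_defaults(hp)
  toks <- bow_tokens(train$text)
  totals <- table(unlist(toks, use.names = FALSE))
  vocab <- sort(names(totals)[totals >= cfg$min_count])
  ids_train <- cnn_encode(train$text, vocab, cfg$max_len)
  ids_dev <- cnn_encode(dev$text, vocab, cfg$max_len)
  y <- as.numeric(train$label)
  V <- length(vocab)
  d <- cfg$dim; nf <- cfg$filters; w <- cfg$window

  par <- with_seed(seed, list(
    E = matrix(stats::rnorm(V * d, sd = 0.1), nrow = V),
    W = matrix(stats::rnorm(nf * w * d, sd = sqrt(2 / (w * d))), nrow = nf),
    b = rep(0, nf),
    u = stats::rnorm(nf, sd = 0.1),
    c0 = 0
  ))
  # Adam state, one slot per parameter block.
  adam <- lapply(par, function(p) list(m = p * 0, v = p * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  best <- list(f = -1, par = par)

  order_seq <- with_seed(cycle_seed(seed, 7L), {
    lapply(seq_len(cfg$epochs), function(e) sample.int(length(ids_train)))
  })

  for (epoch in seq_len(cfg$epochs)) {
    idx_all <- order_seq[[epoch]]
    batches <- split(idx_all, ceiling(seq_along(idx_all) / cfg$batch))
    for (bt in batches) {
      grad <- lapply(par, function(p) p * 0)
      for (i in bt) {
        g <- cnn_doc_grad(ids_train[[i]], y[i], par, w, d, nf)
        for (nm in names(grad)) grad[[nm]] <- grad[[nm]] + g[[nm]]
      }
      step <- step + 1L
      for (nm in names(par)) {
        gnm <- grad[[nm]] / length(bt)
        adam[[nm]]$m <- beta1 * adam[[nm]]$m + (1 - beta1) * gnm
        adam[[nm]]$v <- beta2 * adam[[nm]]$v + (1 - beta2) * gnm^2
        mhat <- adam[[nm]]$m / (1 - beta1^step)
        vhat <- adam[[nm]]$v / (1 - beta2^step)
        par[[nm]] <- par[[nm]] - cfg$lr * mhat / (sqrt(vhat) + eps)
      }
    }
    dev_scores <- vapply(ids_dev, function(ids) {
      cnn_forward(ids, par, w, d, nf)$prob
    }, numeric(1))
    f <- dev_f(dev$label, dev_scores >= (hp$threshold %||% 0.5))
    if (f > best$f) best <- list(f = f, par = par)
  }
  c(best$par, list(vocab = vocab, cfg = cfg, dev_f = best$f))
}

# Forward pass for one document; returns activations needed for backprop.
cnn_forward <- function(ids, par, w, d, nf) {
  L <- max(length(ids), w)
  X <- matrix(0, nrow = L, ncol = d)
  nz <- which(ids > 0)
  if (length(nz) > 0) X[nz, ] <- par$E[ids[nz], , drop = FALSE]
  Tn <- L - w + 1L
  C <- matrix(0, nrow = Tn, ncol = w * d)
  for (j in seq_len(w)) {
    C[, ((j - 1) * d + 1):(j * d)] <- X[j:(j + Tn - 1), , drop = FALSE]
  }
  A <- C %*% t(par$W) + matrix(par$b, nrow = Tn, ncol = nf, byrow = TRUE)
  H <- pmax(A, 0)
  tstar <- max.col(t(H), ties.method = "first")
  p <- H[cbind(tstar, seq_len(nf))]
  z <- sum(par$u * p) + par$c0
  list(prob = stats::plogis(z), C = C, A = A, p = p, tstar = tstar, Tn = Tn)
}

cnn_doc_grad <- function(ids, y, par, w, d, nf) {
  fw <- cnn_forward(ids, par, w, d, nf)
  dz <- fw$prob - y
  du <- dz * fw$p
  dc0 <- dz
  dp <- dz * par$u
  active <- fw$A[cbind(fw$tstar, seq_len(nf))] > 0
  dh <- ifelse(active, dp, 0)
  dW <- matrix(0, nrow = nf, ncol = w * d)
  db <- dh
  dC <- matrix(0, nrow = fw$Tn, ncol = w * d)
  for (f in which(dh != 0)) {
    t0 <- fw$tstar[f]
    dW[f, ] <- dh[f] * fw$C[t0, ]
    dC[t0, ] <- dC[t0, ] + dh[f] * par$W[f, ]
  }
  dE <- matrix(0, nrow = nrow(par$E), ncol = d)
  rows <- which(rowSums(abs(dC)) > 0)
  for (t0 in rows) {
    for (j in seq_len(w)) {
      pos <- t0 + j - 1L
      if (pos <= length(ids) && ids[pos] > 0) {
        dE[ids[pos], ] <- dE[ids[pos], ] + dC[t0, ((j - 1) * d + 1):(j * d)]
      }
    }
  }
  list(E = dE, W = dW, b = db, u = du, c0 = dc0)
}

score_cnn <- function(state, text) {
  cfg <- state$cfg
  ids <- cnn_encode(text, state$vocab, cfg$max_len)
  vapply(ids, function(id) {
    cnn_forward(id, state, cfg$window, cfg$dim, cfg$filters)$prob
  }, numeric(1))
}
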