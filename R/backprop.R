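# Batched forward/backward pass used for joint training.  Sequences in a
# batch share one length T; rows of the (B*T) x d activation matrices are
# sample-major (sample b occupies rows (b-1)*T + 1 .. b*T).  Position-wise
# operations (layer norm, projections, feed-forward, heads) act on the full
# stacked matrix; only the attention score/softmax/value step loops over
# samples and heads.  All gradients are derived by hand and verified against
# central finite differences in the test suite.

bln_fwd <- function(x, ln, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  y <- sweep(xhat, 2L, ln$g, `*`) +
    matrix(ln$b, nrow(x), length(ln$b), byrow = TRUE)
  list(y = y, xhat = xhat, inv = inv)
}

bln_bwd <- function(dy, cache, g) {
  dxhat <- sweep(dy, 2L, g, `*`)
  dg <- colSums(dy * cache$xhat)
  db <- colSums(dy)
  dx <- cache$inv *
    (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dx = dx, dg = dg, db = db)
}

brep <- function(b, n) matrix(b, n, length(b), byrow = TRUE)

# Forward through one pre-norm block for the stacked batch; returns the new
# activations plus every intermediate the backward pass needs.
block_fwd <- function(x, lp, n_heads, B, Tn) {
  d <- ncol(x)
  dh <- d %/% n_heads
  c1 <- bln_fwd(x, lp$ln1)
  A <- c1$y
  Q <- A %*% lp$attn$Wq + brep(lp$attn$bq, nrow(A))
  K <- A %*% lp$attn$Wk + brep(lp$attn$bk, nrow(A))
  V <- A %*% lp$attn$Wv + brep(lp$attn$bv, nrow(A))
  O <- matrix(0, nrow(A), d)
  Plist <- vector("list", B * n_heads)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * Tn + 1L):(b * Tn)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      S <- (Q[rows, cols, drop = FALSE] %*%
              t(K[rows, cols, drop = FALSE])) / sqrt(dh)
      P <- softmax_rows(S)
      Plist[[(b - 1L) * n_heads + h]] <- P
      O[rows, cols] <- P %*% V[rows, cols, drop = FALSE]
    }
  }
  Yo <- O %*% lp$attn$Wo + brep(lp$attn$bo, nrow(O))
  x1 <- x + Yo
  c2 <- bln_fwd(x1, lp$ln2)
  H1 <- c2$y %*% lp$ffn$W1 + brep(lp$ffn$b1, nrow(x1))
  R <- pmax(H1, 0)
  x2 <- x1 + R %*% lp$ffn$W2 + brep(lp$ffn$b2, nrow(x1))
  list(x_out = x2,
       cache = list(c1 = c1, c2 = c2, A = A, Q = Q, K = K, V = V, O = O,
                    H1 = H1, R = R, Plist = Plist))
}

block_bwd <- function(dx2, x_cache, lp, n_heads, B, Tn) {
  d <- ncol(dx2)
  dh <- d %/% n_heads
  ca <- x_cache
  g <- list()

  # feed-forward branch
  dW2 <- t(ca$R) %*% dx2
  db2 <- colSums(dx2)
  dR <- dx2 %*% t(lp$ffn$W2)
  dH1 <- dR * (ca$H1 > 0)
  dW1 <- t(ca$c2$y) %*% dH1
  db1 <- colSums(dH1)
  dFin <- dH1 %*% t(lp$ffn$W1)
  ln2b <- bln_bwd(dFin, ca$c2, lp$ln2$g)
  dx1 <- dx2 + ln2b$dx

  # attention branch
  dYo <- dx1
  dWo <- t(ca$O) %*% dYo
  dbo <- colSums(dYo)
  dO <- dYo %*% t(lp$attn$Wo)
  dQ <- matrix(0, nrow(dO), d)
  dK <- matrix(0, nrow(dO), d)
  dV <- matrix(0, nrow(dO), d)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * Tn + 1L):(b * Tn)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      P <- ca$Plist[[(b - 1L) * n_heads + h]]
      dOb <- dO[rows, cols, drop = FALSE]
      Vb <- ca$V[rows, cols, drop = FALSE]
      dP <- dOb %*% t(Vb)
      dV[rows, cols] <- t(P) %*% dOb
      dS <- P * (dP - rowSums(dP * P))
      dQ[rows, cols] <- (dS %*% ca$K[rows, cols, drop = FALSE]) / sqrt(dh)
      dK[rows, cols] <- (t(dS) %*% ca$Q[rows, cols, drop = FALSE]) / sqrt(dh)
    }
  }
  dWq <- t(ca$A) %*% dQ; dbq <- colSums(dQ)
  dWk <- t(ca$A) %*% dK; dbk <- colSums(dK)
  dWv <- t(ca$A) %*% dV; dbv <- colSums(dV)
  dA <- dQ %*% t(lp$attn$Wq) + dK %*% t(lp$attn$Wk) + dV %*% t(lp$attn$Wv)
  ln1b <- bln_bwd(dA, ca$c1, lp$ln1$g)
  dx <- dx1 + ln1b$dx

  list(
    dx = dx,
    grads = list(
      ln1 = list(g = ln1b$dg, b = ln1b$db),
      attn = list(Wq = dWq, bq = dbq, Wk = dWk, bk = dbk,
                  Wv = dWv, bv = dbv, Wo = dWo, bo = dbo),
      ln2 = list(g = ln2b$dg, b = ln2b$db),
      ffn = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
    )
  )
}

pool_rows <- function(B, Tn, pooling) {
  switch(pooling,
         mean = NULL,
         first_token = seq(1L, by = Tn, length.out = B),
         last_token = seq(Tn, by = Tn, length.out = B))
}

pool_fwd <- function(x, B, Tn, pooling) {
  if (pooling == "mean") {
    rowsum(x, group = rep(seq_len(B), each = Tn), reorder = FALSE) / Tn
  } else {
    x[pool_rows(B, Tn, pooling), , drop = FALSE]
  }
}

pool_bwd <- function(dS, B, Tn, pooling) {
  if (pooling == "mean") {
    dS[rep(seq_len(B), each = Tn), , drop = FALSE] / Tn
  } else {
    dx <- matrix(0, B * Tn, ncol(dS))
    dx[pool_rows(B, Tn, pooling), ] <- dS
    dx
  }
}

# Full batched forward: returns per-exit probability matrices plus caches.
batched_forward <- function(par, cfg, ids) {
  B <- nrow(ids); Tn <- ncol(ids)
  ids_flat <- as.vector(t(ids))
  x <- par$tok[ids_flat, , drop = FALSE] +
    par$pos[rep(seq_len(Tn), B), , drop = FALSE]
  if (!is.null(par$type)) x <- x + brep(par$type[1L, ], nrow(x))
  ce <- NULL
  if (!is.null(par$ln_e)) {
    ce <- bln_fwd(x, par$ln_e)
    x <- ce$y
  }
  M <- cfg$n_layers
  caches <- vector("list", M)
  probs <- vector("list", M)
  pooled <- vector("list", M)   # input actually fed to each head (post pooler)
  pool_in <- vector("list", M)  # pooled state before the pooler
  lnf_cache <- NULL
  for (m in seq_len(M)) {
    fw <- block_fwd(x, par$layers[[m]], cfg$n_heads, B, Tn)
    x <- fw$x_out
    caches[[m]] <- fw$cache
    xh <- x
    if (!is.null(par$ln_f) && m == M) {
      lnf_cache <- bln_fwd(x, par$ln_f)
      xh <- lnf_cache$y
    }
    S <- pool_fwd(xh, B, Tn, cfg$pooling)
    pool_in[[m]] <- S
    Z <- S
    if (!is.null(par$pooler)) {
      Z <- tanh(S %*% par$pooler$W + brep(par$pooler$b, B))
    }
    pooled[[m]] <- Z
    logits <- Z %*% par$heads[[m]]$W + brep(par$heads[[m]]$b, B)
    probs[[m]] <- softmax_rows(logits)
  }
  list(probs = probs, caches = caches, pooled = pooled, pool_in = pool_in,
       lnf_cache = lnf_cache, emb_cache = ce, ids_flat = ids_flat,
       B = B, Tn = Tn)
}

# Joint loss and full gradient for one batch.  labels: length-B integer
# vector of 1-based classes; w: positive per-layer weights.
batched_backward <- function(par, cfg, fw, labels, w) {
  B <- fw$B; Tn <- fw$Tn
  M <- cfg$n_layers
  wn <- w / sum(w)
  floor_p <- 1e-12

  loss <- 0
  dlogits <- vector("list", M)
  for (m in seq_len(M)) {
    P <- fw$probs[[m]]
    picked <- P[cbind(seq_len(B), labels)]
    loss <- loss + wn[m] * mean(-log(pmax(picked, floor_p)))
    Y <- matrix(0, B, cfg$n_classes)
    Y[cbind(seq_len(B), labels)] <- 1
    dlogits[[m]] <- (P - Y) * (wn[m] / B)
  }

  zeros_like <- function(p) {
    if (is.list(p)) purrr::map(p, zeros_like)
    else if (is.matrix(p)) matrix(0, nrow(p), ncol(p))
    else numeric(length(p))
  }
  g <- zeros_like(par)

  dx <- matrix(0, B * Tn, cfg$hidden_size)
  for (m in rev(seq_len(M))) {
    hd <- par$heads[[m]]
    Z <- fw$pooled[[m]]
    dW <- t(Z) %*% dlogits[[m]]
    db <- colSums(dlogits[[m]])
    g$heads[[m]]$W <- dW
    g$heads[[m]]$b <- db
    dZ <- dlogits[[m]] %*% t(hd$W)
    if (!is.null(par$pooler)) {
      dZp <- dZ * (1 - Z^2)
      g$pooler$W <- g$pooler$W + t(fw$pool_in[[m]]) %*% dZp
      g$pooler$b <- g$pooler$b + colSums(dZp)
      dS <- dZp %*% t(par$pooler$W)
    } else {
      dS <- dZ
    }
    dxh <- pool_bwd(dS, B, Tn, cfg$pooling)
    if (!is.null(par$ln_f) && m == M) {
      lb <- bln_bwd(dxh, fw$lnf_cache, par$ln_f$g)
      g$ln_f$g <- lb$dg
      g$ln_f$b <- lb$db
      dxh <- lb$dx
    }
    dx <- dx + dxh
    bb <- block_bwd(dx, fw$caches[[m]], par$layers[[m]], cfg$n_heads, B, Tn)
    dx <- bb$dx
    g$layers[[m]] <- bb$grads
  }

  if (!is.null(par$ln_e)) {
    lb <- bln_bwd(dx, fw$emb_cache, par$ln_e$g)
    g$ln_e$g <- lb$dg
    g$ln_e$b <- lb$db
    dx <- lb$dx
  }
  dtok_rows <- rowsum(dx, group = fw$ids_flat, reorder = FALSE)
  used <- as.integer(rownames(dtok_rows))
  g$tok[used, ] <- dtok_rows
  dpos_rows <- rowsum(dx, group = rep(seq_len(Tn), B), reorder = FALSE)
  g$pos[seq_len(Tn), ] <- dpos_rows[order(as.integer(rownames(dpos_rows))), ,
                                    drop = FALSE]
  if (!is.null(par$type)) g$type[1L, ] <- colSums(dx)

  list(loss = loss, grads = g)
}
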