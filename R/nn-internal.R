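# Internal neural-network primitives with hand-written forward/backward
# passes. Feature maps are (B*H*W) x C matrices (B stacked segments, rows
# enumerate spatial positions h-fastest); the heavy gather/scatter steps
# (im2col/col2im, max-pooling) live in C++, the matrix products go through
# BLAS.

BN_EPS <- 1e-5
LN_EPS <- 1e-5
# variance floor for fused-feature standardization: early running estimates
# come from few samples, and near-constant features must not be amplified
# into instability
FUSION_EPS <- 1e-4

# Fused-feature standardization uses pooled running moments over every
# fused vector seen during training (deterministic, stable after a few
# batches); the scale part is deferred until enough rows have been pooled.
.fusionScale <- function(st, D) {
  if (is.null(st) || st$n == 0)
    return(list(mean = rep(0, D), invsd = rep(1, D)))
  mean <- st$sum / st$n
  if (st$n < 8) return(list(mean = mean, invsd = rep(1, D)))
  v <- pmax(st$sumsq / st$n - mean^2, 0)
  list(mean = mean, invsd = 1 / sqrt(v + FUSION_EPS))
}

.softmaxRows <- function(L) {
  m <- apply(L, 1, max)
  e <- exp(L - m)
  e / rowSums(e)
}

# Row-wise layer norm ------------------------------------------------------
.lnFwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  invsd <- 1 / sqrt(rowMeans(xc^2) + LN_EPS)
  xhat <- xc * invsd
  list(out = sweep(sweep(xhat, 2, g, "*"), 2, b, "+"),
       xhat = xhat, invsd = invsd)
}

.lnBwd <- function(dY, cache, g) {
  D <- ncol(dY)
  dxhat <- sweep(dY, 2, g, "*")
  dX <- (cache$invsd / D) *
    (D * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
  list(dX = dX, dg = colSums(dY * cache$xhat), db = colSums(dY))
}

# Column-wise batch norm: debiased moving statistics for eval mode (the
# EMA starts at zero, so it is divided by 1 - decay^count before use).
.bnMovingStats <- function(st, C) {
  if (is.null(st) || st$count == 0) return(list(mean = rep(0, C), var = rep(1, C)))
  if (isTRUE(st$calibrated)) return(list(mean = st$mean, var = st$var))
  corr <- 1 - st$decay^st$count
  list(mean = st$mean / corr, var = pmax(st$var / corr, 0))
}

# Sinusoidal positional encodings for positions 0..(n-1) (optional).
.posEncoding <- function(n, d) {
  pos <- matrix(0:(n - 1), n, d)
  i <- matrix(rep(seq_len(d) - 1, each = n), n, d)
  angle <- pos / 10000^(2 * (i %/% 2) / d)
  ifelse(i %% 2 == 0, sin(angle), cos(angle))
}

# CNN tower ----------------------------------------------------------------
# X: (B*H0*W0) x 1 matrix of stacked segment embeddings; returns B x C3
# segment vectors. `state` entries are read in eval mode; in train mode the
# batch statistics and the updated moving statistics are part of the cache.
.cnnForward <- function(X, B, H0, W0, prefix, P, state, cfg, mode,
                        keepCache = FALSE) {
  kk <- cfg$conv_kernel
  pk <- cfg$pool_kernel
  M <- X
  H <- H0; W <- W0
  caches <- vector("list", 3)
  bnUpdates <- list()
  for (l in 1:3) {
    Wl <- P[[sprintf("%s.conv%d.W", prefix, l)]]
    gamma <- P[[sprintf("%s.bn%d.gamma", prefix, l)]]
    beta <- P[[sprintf("%s.bn%d.beta", prefix, l)]]
    col <- cpp_im2col(M, B, H, W, kk, kk)
    Z <- col %*% Wl
    key <- sprintf("%s.bn%d", prefix, l)
    if (mode == "train") {
      st <- state[[key]]
      stats <- cpp_bn_stats(Z)
      upd <- updateBnStatistics(stats$mean, stats$var, st$mean, st$var,
                                st$decay)
      bnUpdates[[key]] <- list(mean = upd$mean, var = upd$var,
                               count = st$count + 1L, decay = st$decay,
                               batch_mean = stats$mean, batch_var = stats$var)
      mv <- stats
    } else {
      mv <- .bnMovingStats(state[[key]], ncol(Z))
    }
    bn <- cpp_bn_relu_fwd(Z, gamma, beta, mv$mean, mv$var, BN_EPS, TRUE)
    A <- bn$out
    lc <- list(col = if (keepCache) col,
               bn = if (keepCache) list(Z = Z, mean = mv$mean,
                                        invsd = bn$invsd),
               H = H, W = W)
    if (l < 3) {
      pl <- cpp_maxpool(A, B, H, W, pk[1], pk[2])
      M <- pl$out
      lc$argmax <- if (keepCache) pl$argmax
      lc$nrow_in <- nrow(A)
      H <- pl$H; W <- pl$W
    } else {
      M <- A
    }
    caches[[l]] <- lc
  }
  HW3 <- H * W
  grp <- rep(seq_len(B), each = HW3)
  out <- rowsum(M, grp, reorder = FALSE) / HW3
  list(out = out, cache = if (keepCache)
    list(layers = caches, B = B, HW3 = HW3, grp = grp),
    bnUpdates = bnUpdates)
}

.cnnBackward <- function(dOut, cache, prefix, P, cfg, needInputGrad = FALSE) {
  grads <- list()
  B <- cache$B
  dM <- dOut[cache$grp, , drop = FALSE] / cache$HW3
  for (l in 3:1) {
    lc <- cache$layers[[l]]
    if (l < 3) dM <- cpp_maxpool_bwd(dM, lc$argmax, lc$nrow_in)
    gamma <- P[[sprintf("%s.bn%d.gamma", prefix, l)]]
    beta <- P[[sprintf("%s.bn%d.beta", prefix, l)]]
    # dM is freshly allocated above, so the in-place transform to dZ is safe
    bn <- cpp_bn_relu_bwd(dM, lc$bn$Z, lc$bn$mean, lc$bn$invsd, gamma,
                          beta, TRUE)
    grads[[sprintf("%s.bn%d.gamma", prefix, l)]] <- bn$dgamma
    grads[[sprintf("%s.bn%d.beta", prefix, l)]] <- bn$dbeta
    Wl <- P[[sprintf("%s.conv%d.W", prefix, l)]]
    grads[[sprintf("%s.conv%d.W", prefix, l)]] <- crossprod(lc$col, dM)
    if (l > 1 || needInputGrad) {
      dcol <- tcrossprod(dM, Wl)
      dM <- cpp_col2im(dcol, B, lc$H, lc$W,
                       ncol(dcol) / (cfg$conv_kernel^2),
                       cfg$conv_kernel, cfg$conv_kernel)
    } else dM <- NULL
  }
  list(grads = grads, dX = dM)
}

# Transformer encoder ------------------------------------------------------
# segMat: B x d_model segment vectors; valid: logical length B. Prepends the
# tower's CLS vector, runs n layers, returns the final CLS row.
.tfForward <- function(segMat, valid, prefix, P, cfg, keepCache = FALSE) {
  dm <- cfg$tower_dim
  nl <- cfg$n_transformer_layers
  h <- cfg$n_heads
  dk <- cfg$head_dim
  S <- rbind(P[[paste0(prefix, ".cls")]], segMat)
  if (isTRUE(cfg$use_positional_encoding))
    S <- S + .posEncoding(nrow(S), dm)
  ok <- c(TRUE, valid)
  layers <- vector("list", nl)
  for (l in seq_len(nl)) {
    pre <- sprintf("%s.L%d", prefix, l)
    Q0 <- S %*% P[[paste0(pre, ".Wq")]]
    K0 <- S %*% P[[paste0(pre, ".Wk")]]
    V0 <- S %*% P[[paste0(pre, ".Wv")]]
    heads <- vector("list", h)
    Hcat <- matrix(0, nrow(S), h * dk)
    for (hh in seq_len(h)) {
      hp <- sprintf("%s.head%d", pre, hh)
      Qh <- Q0 %*% P[[paste0(hp, ".Aq")]]
      Kh <- K0 %*% P[[paste0(hp, ".Ak")]]
      Vh <- V0 %*% P[[paste0(hp, ".Av")]]
      L <- tcrossprod(Qh, Kh) / sqrt(dk)
      if (!all(ok)) L[, !ok] <- -Inf
      Pm <- .softmaxRows(L)
      Hcat[, ((hh - 1) * dk + 1):(hh * dk)] <- Pm %*% Vh
      if (keepCache) heads[[hh]] <- list(Qh = Qh, Kh = Kh, Vh = Vh, P = Pm)
    }
    A <- Hcat %*% P[[paste0(pre, ".Wo")]]
    ln1 <- .lnFwd(S + A, P[[paste0(pre, ".ln1.g")]], P[[paste0(pre, ".ln1.b")]])
    S1 <- ln1$out
    Fpre <- sweep(S1 %*% P[[paste0(pre, ".ffn.W1")]], 2,
                  P[[paste0(pre, ".ffn.b1")]], "+")
    Fact <- Fpre * (Fpre > 0)
    F2 <- sweep(Fact %*% P[[paste0(pre, ".ffn.W2")]], 2,
                P[[paste0(pre, ".ffn.b2")]], "+")
    ln2 <- .lnFwd(S1 + F2, P[[paste0(pre, ".ln2.g")]], P[[paste0(pre, ".ln2.b")]])
    if (keepCache)
      layers[[l]] <- list(S = S, Q0 = Q0, K0 = K0, V0 = V0, heads = heads,
                          Hcat = Hcat, ln1 = ln1[c("xhat", "invsd")], S1 = S1,
                          relu = (Fpre > 0), Fact = Fact,
                          ln2 = ln2[c("xhat", "invsd")])
    S <- ln2$out
  }
  list(cls = S[1, ], out = S,
       cache = if (keepCache) list(layers = layers, ok = ok))
}

.tfBackward <- function(dCls, cache, prefix, P, cfg) {
  grads <- list()
  nl <- cfg$n_transformer_layers
  h <- cfg$n_heads
  dk <- cfg$head_dim
  n <- nrow(cache$layers[[1]]$S)
  dS <- matrix(0, n, cfg$tower_dim)
  dS[1, ] <- dCls
  for (l in nl:1) {
    pre <- sprintf("%s.L%d", prefix, l)
    lc <- cache$layers[[l]]
    ln2 <- .lnBwd(dS, lc$ln2, P[[paste0(pre, ".ln2.g")]])
    grads[[paste0(pre, ".ln2.g")]] <- ln2$dg
    grads[[paste0(pre, ".ln2.b")]] <- ln2$db
    dS1 <- ln2$dX             # residual branch
    dF2 <- ln2$dX
    grads[[paste0(pre, ".ffn.W2")]] <- crossprod(lc$Fact, dF2)
    grads[[paste0(pre, ".ffn.b2")]] <- colSums(dF2)
    dFact <- tcrossprod(dF2, P[[paste0(pre, ".ffn.W2")]]) * lc$relu
    grads[[paste0(pre, ".ffn.W1")]] <- crossprod(lc$S1, dFact)
    grads[[paste0(pre, ".ffn.b1")]] <- colSums(dFact)
    dS1 <- dS1 + tcrossprod(dFact, P[[paste0(pre, ".ffn.W1")]])
    ln1 <- .lnBwd(dS1, lc$ln1, P[[paste0(pre, ".ln1.g")]])
    grads[[paste0(pre, ".ln1.g")]] <- ln1$dg
    grads[[paste0(pre, ".ln1.b")]] <- ln1$db
    dS <- ln1$dX              # residual into S
    dA <- ln1$dX
    grads[[paste0(pre, ".Wo")]] <- crossprod(lc$Hcat, dA)
    dHcat <- tcrossprod(dA, P[[paste0(pre, ".Wo")]])
    dQ0 <- matrix(0, n, dk); dK0 <- dQ0; dV0 <- dQ0
    for (hh in seq_len(h)) {
      hp <- sprintf("%s.head%d", pre, hh)
      hc <- lc$heads[[hh]]
      dHh <- dHcat[, ((hh - 1) * dk + 1):(hh * dk), drop = FALSE]
      dP <- tcrossprod(dHh, hc$Vh)
      dVh <- crossprod(hc$P, dHh)
      dL <- hc$P * (dP - rowSums(dP * hc$P))
      dQh <- (dL %*% hc$Kh) / sqrt(dk)
      dKh <- (crossprod(dL, hc$Qh)) / sqrt(dk)
      grads[[paste0(hp, ".Aq")]] <- crossprod(lc$Q0, dQh)
      grads[[paste0(hp, ".Ak")]] <- crossprod(lc$K0, dKh)
      grads[[paste0(hp, ".Av")]] <- crossprod(lc$V0, dVh)
      dQ0 <- dQ0 + tcrossprod(dQh, P[[paste0(hp, ".Aq")]])
      dK0 <- dK0 + tcrossprod(dKh, P[[paste0(hp, ".Ak")]])
      dV0 <- dV0 + tcrossprod(dVh, P[[paste0(hp, ".Av")]])
    }
    grads[[paste0(pre, ".Wq")]] <- crossprod(lc$S, dQ0)
    grads[[paste0(pre, ".Wk")]] <- crossprod(lc$S, dK0)
    grads[[paste0(pre, ".Wv")]] <- crossprod(lc$S, dV0)
    dS <- dS + tcrossprod(dQ0, P[[paste0(pre, ".Wq")]]) +
      tcrossprod(dK0, P[[paste0(pre, ".Wk")]]) +
      tcrossprod(dV0, P[[paste0(pre, ".Wv")]])
  }
  grads[[paste0(prefix, ".cls")]] <- dS[1, ]
  list(grads = grads, dSeg = dS[-1, , drop = FALSE])
}

# Fusion MLP ---------------------------------------------------------------
.mlpForward <- function(z, P, keepCache = FALSE) {
  zr <- matrix(z, 1)
  Hpre <- zr %*% P[["mlp.W1"]] + matrix(P[["mlp.b1"]], 1)
  Hact <- Hpre * (Hpre > 0)
  logits <- as.vector(Hact %*% P[["mlp.W2"]]) + P[["mlp.b2"]]
  m <- max(logits)
  p <- exp(logits - m)
  p <- p / sum(p)
  list(p = p, cache = if (keepCache) list(z = zr, relu = (Hpre > 0),
                                          Hact = Hact))
}

.mlpBackward <- function(dlogits, cache, P) {
  grads <- list()
  dl <- matrix(dlogits, 1)
  grads[["mlp.W2"]] <- crossprod(cache$Hact, dl)
  grads[["mlp.b2"]] <- as.vector(dl)
  dH <- tcrossprod(dl, P[["mlp.W2"]]) * cache$relu
  grads[["mlp.W1"]] <- crossprod(cache$z, dH)
  grads[["mlp.b1"]] <- as.vector(dH)
  dz <- as.vector(tcrossprod(dH, P[["mlp.W1"]]))
  list(grads = grads, dz = dz)
}

.accumGrads <- function(acc, g) {
  for (nm in names(g))
    acc[[nm]] <- if (is.null(acc[[nm]])) g[[nm]] else acc[[nm]] + g[[nm]]
  acc
}
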