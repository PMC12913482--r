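# Training protocol: cross-entropy + L2 objective, Adam with (beta1, beta2),
# global-norm gradient clipping, mini-batching with a seeded shuffle, and
# batch-norm moving statistics.

#' Training configuration
#'
#' Defaults are the full-scale protocol: 200 epochs of Adam
#' (lr 1e-4, beta1 0.9, beta2 0.999), batch size 32, L2 coefficient 1e-3,
#' gradient clipping at global norm 5.0, and batch-norm moving-average
#' decay 0.999.
#'
#' @param epochs training epochs.
#' @param learning_rate Adam step size.
#' @param beta1,beta2 Adam moment decays.
#' @param batch_size mini-batch size.
#' @param l2_coefficient weight of the L2 penalty added to the loss
#'   (applied to weight matrices; normalization parameters, biases and CLS
#'   vectors are excluded).
#' @param grad_clip_threshold global gradient-norm clip threshold.
#' @param bn_moving_decay decay of the batch-norm moving statistics.
#' @param seed RNG seed for shuffling (and any stochastic layer).
#' @param validation_fraction optional fraction of pairs held out for
#'   per-epoch validation metrics (0 = train on everything, the default
#'   protocol).
#' @param early_stop_accuracy optional training-accuracy level at which to
#'   stop early (e.g. 1.0 for memorization checks); NULL trains all epochs.
#' @param recalibrate after the last epoch, re-estimate the batch-norm
#'   population statistics (and the fused-feature moments) from the
#'   training data under the final weights (default TRUE). With short
#'   training runs the exponential moving average still reflects early,
#'   very different weights; re-estimation makes eval-mode features
#'   consistent with what the classifier head was fitted on.
#' @return a validated `TrainConfig` list.
#' @export
trainConfig <- function(epochs = 200L, learning_rate = 1e-4, beta1 = 0.9,
                        beta2 = 0.999, batch_size = 32L,
                        l2_coefficient = 1e-3, grad_clip_threshold = 5.0,
                        bn_moving_decay = 0.999, seed = 1L,
                        validation_fraction = 0,
                        early_stop_accuracy = NULL, recalibrate = TRUE) {
  cfg <- list(epochs = as.integer(epochs), learning_rate = learning_rate,
              beta1 = beta1, beta2 = beta2, batch_size = as.integer(batch_size),
              l2_coefficient = l2_coefficient,
              grad_clip_threshold = grad_clip_threshold,
              bn_moving_decay = bn_moving_decay, seed = as.integer(seed),
              validation_fraction = validation_fraction,
              early_stop_accuracy = early_stop_accuracy,
              recalibrate = isTRUE(recalibrate))
  .assertCount(cfg$epochs, "epochs")
  .assertCount(cfg$batch_size, "batch_size")
  for (nm in c("learning_rate", "beta1", "beta2", "bn_moving_decay"))
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)
      .phnStop("config", sprintf("'%s' must be positive", nm))
  if (cfg$l2_coefficient < 0 || cfg$grad_clip_threshold <= 0)
    .phnStop("config", "l2_coefficient must be >= 0 and grad_clip_threshold > 0")
  if (cfg$validation_fraction < 0 || cfg$validation_fraction >= 1)
    .phnStop("config", "validation_fraction must be in [0, 1)")
  class(cfg) <- c("TrainConfig", "list")
  cfg
}

# Parameter names subject to L2 decay: weight matrices only.
.l2Names <- function(P)
  names(P)[grepl("\\.(W[12qkvo]?|A[qkv])$", names(P))]

#' Cross-entropy loss with L2 penalty
#'
#' `-log p[label] + l2 * sum(w^2)` over the supplied weight arrays;
#' probabilities are clamped at 1e-12 before the log so the loss is always
#' finite.
#'
#' @param p probability vector `(p_non_match, p_match)` (e.g. from
#'   [forwardPair()]).
#' @param label `"match"`/`"non-match"`, or 1/0.
#' @param weights optional list of weight arrays entering the penalty.
#' @param l2 penalty coefficient.
#' @return scalar loss.
#' @export
#' @examples
#' computeLoss(c(0.5, 0.5), "match")  # log(2)
computeLoss <- function(p, label, weights = NULL, l2 = 0) {
  lab <- .asLabel(label)
  pl <- max(if (lab == 1L) p[[2]] else p[[1]], 1e-12)
  pen <- if (l2 > 0 && length(weights))
    l2 * sum(vapply(weights, function(w) sum(w^2), numeric(1))) else 0
  -log(pl) + pen
}

.asLabel <- function(label) {
  if (is.character(label)) {
    if (!label %in% c("match", "non-match"))
      .phnStop("contract", "label must be 'match' or 'non-match' (or 1/0)")
    return(if (label == "match") 1L else 0L)
  }
  if (!label %in% c(0, 1)) .phnStop("contract", "label must be 0 or 1")
  as.integer(label)
}

#' Clip gradients by global L2 norm
#'
#' If the global norm exceeds `threshold`, every gradient is scaled by
#' `threshold / norm`; otherwise gradients pass through unchanged. NaN or
#' infinite gradients abort with a training error.
#'
#' @param grads a named list of gradient arrays (or a single numeric array).
#' @param threshold clip threshold (default 5.0).
#' @return the (possibly rescaled) gradients, with the pre-clip global norm
#'   attached as attribute `"global_norm"`.
#' @export
clipGradients <- function(grads, threshold = 5.0) {
  single <- !is.list(grads)
  gl <- if (single) list(grads) else grads
  sq <- 0
  for (g in gl) {
    if (anyNA(g) || any(!is.finite(g)))
      .phnStop("data", "non-finite gradient encountered")
    sq <- sq + sum(g^2)
  }
  gnorm <- sqrt(sq)
  if (gnorm > threshold) {
    sc <- threshold / gnorm
    gl <- lapply(gl, function(g) g * sc)
  }
  out <- if (single) gl[[1]] else gl
  attr(out, "global_norm") <- gnorm
  out
}

#' Update batch-norm moving statistics
#'
#' `moving <- decay * moving + (1 - decay) * batch`, the exponential moving
#' average accumulated during training whose (debiased) value normalizes
#' activations at test time.
#'
#' @param batch_mean,batch_var mini-batch statistics.
#' @param moving_mean,moving_var current moving statistics.
#' @param decay decay rate (default 0.999).
#' @return list with elements `mean` and `var`.
#' @export
#' @examples
#' updateBnStatistics(1, 1, 0, 0)$mean  # 0.001
updateBnStatistics <- function(batch_mean, batch_var, moving_mean,
                               moving_var, decay = 0.999) {
  list(mean = decay * moving_mean + (1 - decay) * batch_mean,
       var = decay * moving_var + (1 - decay) * batch_var)
}

# One training mini-batch: all phage genomes (and all host genomes) of the
# batch are stacked through their CNN tower in a single pass, so batch-norm
# statistics are computed across the whole mini-batch (per-genome
# normalization would cancel exactly the genome-level compositional shifts
# the classifier needs). The Transformer and the MLP head then run per
# pair. Returns summed CE, per-pair correctness, gradients and BN updates.
.batchGradient <- function(P, state, cfg, gxPs, gxHs, labels) {
  pfxP <- .towerPrefixes(cfg, "phage")
  pfxH <- .towerPrefixes(cfg, "host")
  npair <- length(labels)
  stack <- function(gxs) {
    Bs <- vapply(gxs, function(g) g$B, integer(1))
    list(X = do.call(rbind, lapply(gxs, function(g) g$X)), Bs = Bs,
         off = cumsum(c(0L, Bs)), H = gxs[[1]]$H, W = gxs[[1]]$W)
  }
  sp <- stack(gxPs); sh <- stack(gxHs)
  cnnP <- .cnnForward(sp$X, sum(sp$Bs), sp$H, sp$W, pfxP$cnn, P, state,
                      cfg, "train", keepCache = TRUE)
  cnnH <- .cnnForward(sh$X, sum(sh$Bs), sh$H, sh$W, pfxH$cnn, P, state,
                      cfg, "train", keepCache = TRUE)
  dm <- cfg$tower_dim
  dSegP <- matrix(0, sum(sp$Bs), dm)
  dSegH <- matrix(0, sum(sh$Bs), dm)
  grads <- list()
  ce <- numeric(npair)
  correct <- logical(npair)
  bnUpdates <- c(cnnP$bnUpdates, cnnH$bnUpdates)
  # tower globals for the whole batch, then fused-feature statistics
  tfPs <- vector("list", npair); tfHs <- vector("list", npair)
  Zraw <- matrix(0, npair, 2 * dm)
  for (i in seq_len(npair)) {
    rowsP <- (sp$off[i] + 1):sp$off[i + 1]
    rowsH <- (sh$off[i] + 1):sh$off[i + 1]
    segP <- cnnP$out[rowsP, , drop = FALSE]
    segH <- cnnH$out[rowsH, , drop = FALSE]
    if (cfg$use_transformer) {
      tfPs[[i]] <- .tfForward(segP, rep(TRUE, nrow(segP)), pfxP$tf, P, cfg, TRUE)
      tfHs[[i]] <- .tfForward(segH, rep(TRUE, nrow(segH)), pfxH$tf, P, cfg, TRUE)
      Zraw[i, ] <- c(tfPs[[i]]$cls, tfHs[[i]]$cls)
    } else {
      Zraw[i, ] <- c(colMeans(segP), colMeans(segH))
    }
  }
  if (cfg$normalize_fusion) {
    st <- state[["fusion.stats"]]
    st <- list(sum = st$sum + colSums(Zraw),
               sumsq = st$sumsq + colSums(Zraw^2),
               n = st$n + npair)
    bnUpdates[["fusion.stats"]] <- st
    fs <- .fusionScale(st, 2 * dm)
    fmean <- fs$mean
    finvsd <- fs$invsd
  } else {
    fmean <- rep(0, 2 * dm); finvsd <- rep(1, 2 * dm)
  }
  for (i in seq_len(npair)) {
    rowsP <- (sp$off[i] + 1):sp$off[i + 1]
    rowsH <- (sh$off[i] + 1):sh$off[i + 1]
    mlp <- .mlpForward((Zraw[i, ] - fmean) * finvsd, P, keepCache = TRUE)
    lab <- .asLabel(labels[i])
    ce[i] <- -log(max(mlp$p[lab + 1L], 1e-12))
    correct[i] <- (which.max(mlp$p) - 1L) == lab
    onehot <- c(0, 0); onehot[lab + 1L] <- 1
    mb <- .mlpBackward(mlp$p - onehot, mlp$cache, P)
    grads <- .accumGrads(grads, mb$grads)
    dz <- mb$dz * finvsd  # running statistics are constants to the graph
    if (cfg$use_transformer) {
      tbP <- .tfBackward(dz[1:dm], tfPs[[i]]$cache, pfxP$tf, P, cfg)
      tbH <- .tfBackward(dz[(dm + 1):(2 * dm)], tfHs[[i]]$cache, pfxH$tf, P, cfg)
      grads <- .accumGrads(grads, tbP$grads)
      grads <- .accumGrads(grads, tbH$grads)
      dSegP[rowsP, ] <- tbP$dSeg
      dSegH[rowsH, ] <- tbH$dSeg
    } else {
      dSegP[rowsP, ] <- matrix(dz[1:dm] / length(rowsP),
                               length(rowsP), dm, byrow = TRUE)
      dSegH[rowsH, ] <- matrix(dz[(dm + 1):(2 * dm)] / length(rowsH),
                               length(rowsH), dm, byrow = TRUE)
    }
  }
  needX <- !cfg$use_pretrained_embedding
  cbP <- .cnnBackward(dSegP, cnnP$cache, pfxP$cnn, P, cfg, needInputGrad = needX)
  cbH <- .cnnBackward(dSegH, cnnH$cache, pfxH$cnn, P, cfg, needInputGrad = needX)
  grads <- .accumGrads(grads, cbP$grads)
  grads <- .accumGrads(grads, cbH$grads)
  if (needX) {
    # unstack (sum(Bs)*H*W) x 1 gradients back to token rows, pool by id
    dE <- matrix(0, nrow(P[["emb.E"]]), cfg$d_embed)
    addEmb <- function(st, gxs, dX) {
      HW <- st$H * st$W
      for (i in seq_along(gxs)) {
        gx <- gxs[[i]]
        rows0 <- st$off[i] * HW
        dTok <- matrix(0, gx$B * gx$H, gx$W)
        for (b in seq_len(gx$B))
          dTok[((b - 1) * gx$H + 1):(b * gx$H), ] <-
            matrix(dX[rows0 + ((b - 1) * HW + 1):(b * HW), 1], gx$H, gx$W)
        rs <- rowsum(dTok, gx$ids)
        idx <- as.integer(rownames(rs))
        dE[idx, ] <<- dE[idx, ] + rs
      }
    }
    addEmb(sp, gxPs, cbP$dX)
    addEmb(sh, gxHs, cbH$dX)
    dE[nrow(dE), ] <- 0  # UNK stays pinned
    grads[["emb.E"]] <- dE
  }
  list(ce = ce, correct = correct, grads = grads, bnUpdates = bnUpdates)
}

#' Train the dual-tower model
#'
#' Runs seeded-shuffled mini-batch training with Adam, L2 regularization
#' inside the loss, global-norm gradient clipping and batch-norm
#' moving-statistic updates. Fully reproducible given the seed.
#'
#' @param model a [SiameseHostModel-class] from [initModel()].
#' @param pairs data.frame with `phage_id`, `host_id`, `label` (1/0), or a
#'   [PhageHostDataSet-class] (its pairs and genomes are used).
#' @param genomes named character vector or `DNAStringSet` resolving every
#'   id in `pairs` (ignored when `pairs` is a dataset).
#' @param table a [KmerEmbedding-class] (required unless the model trains
#'   its own embedding).
#' @param config a [trainConfig()].
#' @param verbose print per-epoch progress.
#' @return list with elements `model` (trained) and `history` (one row per
#'   completed epoch: loss, accuracy, gradient-norm statistics).
#' @export
trainModel <- function(model, pairs, genomes = NULL, table = NULL,
                       config = trainConfig(), verbose = FALSE) {
  stopifnot(methods::is(model, "SiameseHostModel"),
            inherits(config, "TrainConfig"))
  if (methods::is(pairs, "PhageHostDataSet")) {
    genomes <- as.character(genomeSequences(pairs))
    pairs <- as.data.frame(interactionPairs(pairs))
  }
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0) .phnStop("data", "empty training pair set")
  if (is.null(genomes)) .phnStop("data", "genomes must be supplied")
  genomes <- stats::setNames(as.character(genomes), names(genomes))
  missing <- setdiff(unique(c(pairs$phage_id, pairs$host_id)), names(genomes))
  if (length(missing))
    .phnStop("data", sprintf("pair ids without genomes: %s",
                             paste(missing, collapse = ", ")))
  cfg <- model@config
  P <- model@params
  state <- model@state
  for (nm in grep("^cnn\\..*\\.bn[123]$", names(state), value = TRUE))
    state[[nm]]$decay <- config$bn_moving_decay
  E <- if (cfg$use_pretrained_embedding) .embeddingMatrix(model, table)
  # Precompute per-genome inputs once (embedding lookups are frozen); with a
  # trainable embedding only token ids are cached and X is rebuilt per step.
  usedIds <- unique(c(pairs$phage_id, pairs$host_id))
  gxCache <- new.env(parent = emptyenv())
  getGX <- function(id) {
    g <- get0(id, envir = gxCache)
    if (is.null(g)) {
      Emat <- if (cfg$use_pretrained_embedding) E else P[["emb.E"]]
      g <- .genomeToX(genomes[[id]], cfg, Emat)
      if (cfg$use_pretrained_embedding) assign(id, g, envir = gxCache)
    } else if (!cfg$use_pretrained_embedding) {
      g$X <- .stackXFromIds(g$ids, g$B, g$H, g$W, P[["emb.E"]])
    }
    g
  }
  l2n <- .l2Names(P)
  opt <- state$opt %||% list(m = list(), v = list(), t = 0L)
  history <- data.frame()
  nval <- floor(config$validation_fraction * nrow(pairs))
  .withSeed(config$seed, {
    if (nval > 0) {
      vidx <- sample.int(nrow(pairs), nval)
      valPairs <- pairs[vidx, , drop = FALSE]
      pairs <- pairs[-vidx, , drop = FALSE]
    }
    n <- nrow(pairs)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0); accs <- logical(0); gnorms <- numeric(0)
      for (bstart in seq(1, n, by = config$batch_size)) {
        bidx <- ord[bstart:min(bstart + config$batch_size - 1L, n)]
        pg <- .batchGradient(P, state, cfg,
                             lapply(pairs$phage_id[bidx], getGX),
                             lapply(pairs$host_id[bidx], getGX),
                             pairs$label[bidx])
        for (k in names(pg$bnUpdates)) state[[k]] <- pg$bnUpdates[[k]]
        accs <- c(accs, pg$correct)
        bl <- sum(pg$ce)
        nb <- length(bidx)
        acc <- lapply(pg$grads, function(g) g / nb)
        l2pen <- 0
        if (config$l2_coefficient > 0) {
          for (nm in l2n) {
            acc[[nm]] <- acc[[nm]] + 2 * config$l2_coefficient * P[[nm]]
            l2pen <- l2pen + sum(P[[nm]]^2)
          }
        }
        acc <- clipGradients(acc, config$grad_clip_threshold)
        gnorms <- c(gnorms, min(attr(acc, "global_norm"),
                                config$grad_clip_threshold))
        # Adam update
        opt$t <- opt$t + 1L
        bc1 <- 1 - config$beta1^opt$t
        bc2 <- 1 - config$beta2^opt$t
        for (nm in names(acc)) {
          g <- acc[[nm]]
          m <- opt$m[[nm]]; v <- opt$v[[nm]]
          if (is.null(m)) { m <- g * 0; v <- g * 0 }
          m <- config$beta1 * m + (1 - config$beta1) * g
          v <- config$beta2 * v + (1 - config$beta2) * g^2
          opt$m[[nm]] <- m; opt$v[[nm]] <- v
          P[[nm]] <- P[[nm]] - config$learning_rate *
            (m / bc1) / (sqrt(v / bc2) + 1e-8)
        }
        if (!cfg$use_pretrained_embedding) P[["emb.E"]][nrow(P[["emb.E"]]), ] <- 0
        losses <- c(losses, bl / nb + config$l2_coefficient * l2pen)
      }
      row <- data.frame(epoch = epoch, loss = mean(losses),
                        accuracy = mean(accs),
                        grad_norm_mean = mean(gnorms),
                        grad_norm_max = max(gnorms))
      if (!all(is.finite(row$loss)))
        .phnStop("data", sprintf("non-finite loss at epoch %d", epoch))
      history <- rbind(history, row)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.3f  |g| %.3f",
                        epoch, row$loss, row$accuracy, row$grad_norm_mean))
      if (!is.null(config$early_stop_accuracy) &&
          row$accuracy >= config$early_stop_accuracy) break
    }
  })
  if (config$recalibrate) {
    # Pass A: pooled batch-norm population statistics under final weights.
    accum <- list()
    nAll <- nrow(pairs)
    for (bstart in seq(1, nAll, by = config$batch_size)) {
      bidx <- bstart:min(bstart + config$batch_size - 1L, nAll)
      for (side in c("phage", "host")) {
        ids <- if (side == "phage") pairs$phage_id[bidx] else pairs$host_id[bidx]
        gxs <- lapply(ids, getGX)
        Bs <- vapply(gxs, function(g) g$B, integer(1))
        X <- do.call(rbind, lapply(gxs, function(g) g$X))
        pfx <- .towerPrefixes(cfg, side)$cnn
        fw <- .cnnForward(X, sum(Bs), gxs[[1]]$H, gxs[[1]]$W, pfx, P, state,
                          cfg, "train")
        for (k in names(fw$bnUpdates)) {
          u <- fw$bnUpdates[[k]]
          a <- accum[[k]] %||% list(sm = 0, s2 = 0, nb = 0L)
          accum[[k]] <- list(sm = a$sm + u$batch_mean,
                             s2 = a$s2 + u$batch_var + u$batch_mean^2,
                             nb = a$nb + 1L)
        }
      }
    }
    for (k in names(accum)) {
      a <- accum[[k]]
      mu <- a$sm / a$nb
      state[[k]] <- list(mean = mu, var = pmax(a$s2 / a$nb - mu^2, 0),
                         count = state[[k]]$count, decay = state[[k]]$decay,
                         calibrated = TRUE)
    }
    # Pass B: fused-feature moments in eval mode (per unique genome).
    if (cfg$normalize_fusion) {
      evalGlobal <- function(id, side) {
        gx <- getGX(id)
        pfx <- .towerPrefixes(cfg, side)
        cnn <- .cnnForward(gx$X, gx$B, gx$H, gx$W, pfx$cnn, P, state, cfg,
                           "eval")
        if (cfg$use_transformer)
          .tfForward(cnn$out, rep(TRUE, gx$B), pfx$tf, P, cfg)$cls
        else colMeans(cnn$out)
      }
      pid <- unique(pairs$phage_id); hid <- unique(pairs$host_id)
      Cp <- vapply(pid, evalGlobal, numeric(cfg$tower_dim), side = "phage")
      Ch <- vapply(hid, evalGlobal, numeric(cfg$tower_dim), side = "host")
      colnames(Cp) <- pid; colnames(Ch) <- hid
      Z <- t(vapply(seq_len(nAll), function(i)
        c(Cp[, pairs$phage_id[i]], Ch[, pairs$host_id[i]]),
        numeric(2 * cfg$tower_dim)))
      state[["fusion.stats"]] <- list(sum = colSums(Z), sumsq = colSums(Z^2),
                                      n = nAll)
    }
  }
  state$opt <- opt
  state$steps <- (model@state$steps %||% 0L) + opt$t
  out <- new("SiameseHostModel", config = cfg, params = P, state = state)
  list(model = out, history = history)
}

.stackXFromIds <- function(ids, B, H, W, E) {
  X <- matrix(E[ids, ], ncol = W)
  Xs <- matrix(0, B * H * W, 1)
  for (b in seq_len(B)) {
    block <- X[((b - 1) * H + 1):(b * H), , drop = FALSE]
    Xs[((b - 1) * H * W + 1):(b * H * W), 1] <- as.vector(block)
  }
  Xs
}
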