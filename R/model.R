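# The dual-tower model: per-segment CNN feature extractors, Transformer
# encoders aggregating segment vectors through a learnable CLS token, and
# the fusion MLP classifier. The two towers share one architecture but have
# independent parameters by default (pseudo-Siamese); a flag enables true
# weight sharing.

#' Architectural configuration of the dual-tower model
#'
#' Defaults are the full-scale architecture: 2000 bp segments, k = 3,
#' 64-dimensional skip-gram embeddings, three conv blocks ending in a
#' 256-channel global-average-pooled tower vector, six Transformer layers
#' with four 64-dimensional heads (d_model = 256), and an MLP classifier
#' 512 -> 4096 -> 2.
#'
#' @param segment_length segment width in bp.
#' @param k k-mer length.
#' @param d_embed embedding dimension d.
#' @param tower_dim CNN output / Transformer d_model.
#' @param n_transformer_layers encoder depth.
#' @param n_heads,head_dim attention heads; `n_heads * head_dim` must equal
#'   `tower_dim`.
#' @param ffn_dim inner width of the position-wise feed-forward network.
#' @param mlp_hidden hidden width of the fusion classifier.
#' @param n_classes output classes (2: non-match, match).
#' @param conv_channels integer vector of 3 channel counts; the last must
#'   equal `tower_dim`.
#' @param conv_kernel odd spatial kernel size (default 3).
#' @param pool_kernel max-pooling window applied after conv blocks 1 and 2;
#'   one integer (square window) or two (position axis, embedding axis).
#' @param normalize_fusion standardize the fused feature vector with
#'   running per-feature statistics before the MLP (default TRUE). The raw
#'   fused features carry a large constant activation offset (from the
#'   ReLU/pooling stages) on top of a small genome-specific signal;
#'   standardizing conditions the classifier's optimization without
#'   changing what it can express.
#' @param share_tower_weights TRUE for a true-Siamese variant.
#' @param use_positional_encoding add sinusoidal encodings to the segment
#'   sequence (off by default: segments are treated as an unordered set).
#' @param use_transformer FALSE replaces the encoder with a mask-weighted
#'   mean of segment vectors (ablation).
#' @param use_pretrained_embedding FALSE trains a randomly initialized
#'   embedding table jointly with the classifier (ablation).
#' @return a validated `ModelConfig` list.
#' @export
modelConfig <- function(segment_length = 2000L, k = 3L, d_embed = 64L,
                        tower_dim = 256L, n_transformer_layers = 6L,
                        n_heads = 4L, head_dim = 64L, ffn_dim = 1024L,
                        mlp_hidden = 4096L, n_classes = 2L,
                        conv_channels = c(64L, 128L, 256L),
                        conv_kernel = 3L, pool_kernel = 2L,
                        normalize_fusion = TRUE,
                        share_tower_weights = FALSE,
                        use_positional_encoding = FALSE,
                        use_transformer = TRUE,
                        use_pretrained_embedding = TRUE) {
  cfg <- list(segment_length = as.integer(segment_length), k = as.integer(k),
              d_embed = as.integer(d_embed), tower_dim = as.integer(tower_dim),
              n_transformer_layers = as.integer(n_transformer_layers),
              n_heads = as.integer(n_heads), head_dim = as.integer(head_dim),
              ffn_dim = as.integer(ffn_dim), mlp_hidden = as.integer(mlp_hidden),
              n_classes = as.integer(n_classes),
              conv_channels = as.integer(conv_channels),
              conv_kernel = as.integer(conv_kernel),
              pool_kernel = {
                pkn <- as.integer(pool_kernel)
                if (length(pkn) == 1) pkn <- c(pkn, pkn)
                pkn
              },
              normalize_fusion = isTRUE(normalize_fusion),
              share_tower_weights = isTRUE(share_tower_weights),
              use_positional_encoding = isTRUE(use_positional_encoding),
              use_transformer = isTRUE(use_transformer),
              use_pretrained_embedding = isTRUE(use_pretrained_embedding))
  for (nm in c("segment_length", "k", "d_embed", "tower_dim",
               "n_transformer_layers", "n_heads", "head_dim", "ffn_dim",
               "mlp_hidden", "conv_kernel"))
    .assertCount(cfg[[nm]], nm)
  if (length(cfg$pool_kernel) != 2 || !all(vapply(cfg$pool_kernel, .isCount,
                                                  logical(1))))
    .phnStop("config", "pool_kernel must be one or two positive integers")
  if (cfg$n_heads * cfg$head_dim != cfg$tower_dim)
    .phnStop("config", "n_heads * head_dim must equal tower_dim")
  if (length(cfg$conv_channels) != 3)
    .phnStop("config", "conv_channels must have length 3")
  if (cfg$conv_channels[3] != cfg$tower_dim)
    .phnStop("config", "conv_channels[3] must equal tower_dim")
  if (cfg$conv_kernel %% 2 == 0)
    .phnStop("config", "conv_kernel must be odd (same-padding)")
  if (cfg$n_classes != 2L)
    .phnStop("config", "the classifier is binary (n_classes = 2)")
  class(cfg) <- c("ModelConfig", "list")
  cfg
}

#' Reduced desk-scale configuration
#'
#' A scaled-down architecture used by the package's own experiments and
#' acceptance checks: 8-dimensional embeddings, conv channels 16/32/64
#' into a 64-dimensional tower, two Transformer layers with two heads, and
#' 8x2 pooling. Same topology as the full model at a fraction of the
#' compute.
#'
#' @param ... overrides passed on to [modelConfig()].
#' @return a `ModelConfig` list.
#' @export
reducedModelConfig <- function(...) {
  args <- list(d_embed = 8L, tower_dim = 64L,
               conv_channels = c(16L, 32L, 64L),
               n_transformer_layers = 2L, n_heads = 2L, head_dim = 32L,
               ffn_dim = 128L, mlp_hidden = 512L, pool_kernel = c(8L, 2L))
  do.call(modelConfig, utils::modifyList(args, list(...)))
}

.towerPrefixes <- function(cfg, tower) {
  tower <- match.arg(tower, c("phage", "host"))
  t <- if (cfg$share_tower_weights) "shared" else tower
  list(cnn = paste0("cnn.", t), tf = paste0("tf.", t))
}

.initTowerParams <- function(cfg, t) {
  P <- list()
  K <- cfg$conv_kernel^2
  cin <- c(1L, cfg$conv_channels[1:2])
  for (l in 1:3) {
    fan <- K * cin[l]
    P[[sprintf("cnn.%s.conv%d.W", t, l)]] <-
      matrix(rnorm(fan * cfg$conv_channels[l], sd = sqrt(2 / fan)),
             fan, cfg$conv_channels[l])
    P[[sprintf("cnn.%s.bn%d.gamma", t, l)]] <- rep(1, cfg$conv_channels[l])
    P[[sprintf("cnn.%s.bn%d.beta", t, l)]] <- rep(0, cfg$conv_channels[l])
  }
  dm <- cfg$tower_dim; dk <- cfg$head_dim
  P[[sprintf("tf.%s.cls", t)]] <- rnorm(dm, sd = 0.02)
  for (l in seq_len(cfg$n_transformer_layers)) {
    pre <- sprintf("tf.%s.L%d", t, l)
    for (w in c("Wq", "Wk", "Wv"))
      P[[paste0(pre, ".", w)]] <- matrix(rnorm(dm * dk, sd = sqrt(1 / dm)), dm, dk)
    for (hh in seq_len(cfg$n_heads)) {
      hp <- sprintf("%s.head%d", pre, hh)
      for (w in c("Aq", "Ak", "Av"))
        P[[paste0(hp, ".", w)]] <- matrix(rnorm(dk * dk, sd = sqrt(1 / dk)), dk, dk)
    }
    P[[paste0(pre, ".Wo")]] <- matrix(rnorm(dm * dm, sd = sqrt(1 / dm)), dm, dm)
    P[[paste0(pre, ".ln1.g")]] <- rep(1, dm)
    P[[paste0(pre, ".ln1.b")]] <- rep(0, dm)
    P[[paste0(pre, ".ffn.W1")]] <-
      matrix(rnorm(dm * cfg$ffn_dim, sd = sqrt(2 / dm)), dm, cfg$ffn_dim)
    P[[paste0(pre, ".ffn.b1")]] <- rep(0, cfg$ffn_dim)
    P[[paste0(pre, ".ffn.W2")]] <-
      matrix(rnorm(cfg$ffn_dim * dm, sd = sqrt(1 / cfg$ffn_dim)), cfg$ffn_dim, dm)
    P[[paste0(pre, ".ffn.b2")]] <- rep(0, dm)
    P[[paste0(pre, ".ln2.g")]] <- rep(1, dm)
    P[[paste0(pre, ".ln2.b")]] <- rep(0, dm)
  }
  P
}

#' Initialize a dual-tower model
#'
#' All weights are drawn from seeded scaled-normal initializers (He for
#' layers feeding ReLU); the CLS vectors start at N(0, 0.02); batch-norm
#' moving statistics start at zero with zero update count.
#'
#' @param cfg a [modelConfig()].
#' @param seed RNG seed.
#' @param bn_moving_decay decay used for batch-norm moving statistics
#'   during later training (stored in the model state).
#' @return a [SiameseHostModel-class].
#' @export
initModel <- function(cfg, seed = 1L, bn_moving_decay = 0.999) {
  stopifnot(inherits(cfg, "ModelConfig"))
  P <- .withSeed(seed, {
    P <- list()
    towers <- if (cfg$share_tower_weights) "shared" else c("phage", "host")
    for (t in towers) P <- c(P, .initTowerParams(cfg, t))
    fusion <- 2L * cfg$tower_dim
    P[["mlp.W1"]] <- matrix(rnorm(fusion * cfg$mlp_hidden,
                                  sd = sqrt(2 / fusion)), fusion, cfg$mlp_hidden)
    P[["mlp.b1"]] <- rep(0, cfg$mlp_hidden)
    P[["mlp.W2"]] <- matrix(rnorm(cfg$mlp_hidden * cfg$n_classes,
                                  sd = sqrt(1 / cfg$mlp_hidden)),
                            cfg$mlp_hidden, cfg$n_classes)
    P[["mlp.b2"]] <- rep(0, cfg$n_classes)
    if (!cfg$use_pretrained_embedding) {
      nv <- as.integer(4^cfg$k)
      E <- matrix(rnorm(nv * cfg$d_embed, sd = 0.1), nv, cfg$d_embed)
      P[["emb.E"]] <- rbind(E, 0)  # UNK pinned to zero
    }
    P
  })
  state <- list(steps = 0L, seed = as.integer(seed))
  state[["fusion.stats"]] <- list(sum = rep(0, 2 * cfg$tower_dim),
                                  sumsq = rep(0, 2 * cfg$tower_dim),
                                  n = 0L)
  towers <- if (cfg$share_tower_weights) "shared" else c("phage", "host")
  for (t in towers)
    for (l in 1:3)
      state[[sprintf("cnn.%s.bn%d", t, l)]] <-
        list(mean = rep(0, cfg$conv_channels[l]),
             var = rep(0, cfg$conv_channels[l]),
             count = 0L, decay = bn_moving_decay)
  new("SiameseHostModel", config = unclass(cfg), params = P, state = state)
}

# Embedding lookup for one genome: stacked (B*H*W) x 1 matrix of segment
# embeddings plus bookkeeping. The embedding matrix comes either from the
# pretrained table or from the model's own trainable table (ablation).
.genomeToX <- function(sequence, cfg, E) {
  segs <- segmentGenome(sequence, cfg$segment_length)
  H <- cfg$segment_length - cfg$k + 1L
  ids <- lapply(segs, .tokenIds, k = cfg$k)
  X <- matrix(E[unlist(ids), ], ncol = cfg$d_embed)
  # reorder to column-major per segment: rows are (h, w) h-fastest
  B <- length(segs)
  Xs <- matrix(0, B * H * cfg$d_embed, 1)
  for (b in seq_len(B)) {
    block <- X[((b - 1) * H + 1):(b * H), , drop = FALSE]
    Xs[((b - 1) * H * cfg$d_embed + 1):(b * H * cfg$d_embed), 1] <- as.vector(block)
  }
  list(X = Xs, B = B, H = H, W = cfg$d_embed, ids = unlist(ids))
}

.embeddingMatrix <- function(model, table) {
  cfg <- model@config
  if (!cfg$use_pretrained_embedding) return(model@params[["emb.E"]])
  if (is.null(table))
    .phnStop("config", "a KmerEmbedding table is required when use_pretrained_embedding is TRUE")
  stopifnot(methods::is(table, "KmerEmbedding"))
  if (table@k != cfg$k || table@dim != cfg$d_embed)
    .phnStop("config", "embedding table (k, d) does not match the model config")
  table@vectors
}

# Full tower pass: sequence -> segment vectors -> global vector.
.towerForward <- function(model, sequence, tower, table, mode,
                          keepCache = FALSE) {
  cfg <- model@config
  pfx <- .towerPrefixes(cfg, tower)
  E <- .embeddingMatrix(model, table)
  gx <- .genomeToX(sequence, cfg, E)
  cnn <- .cnnForward(gx$X, gx$B, gx$H, gx$W, pfx$cnn, model@params,
                     model@state, cfg, mode, keepCache = keepCache)
  valid <- rep(TRUE, gx$B)
  if (cfg$use_transformer) {
    tf <- .tfForward(cnn$out, valid, pfx$tf, model@params, cfg,
                     keepCache = keepCache)
    global <- tf$cls
  } else {
    tf <- NULL
    global <- colMeans(cnn$out)
  }
  list(global = global, segments = cnn$out, gx = gx, cnnCache = cnn$cache,
       tfCache = if (!is.null(tf)) tf$cache, bnUpdates = cnn$bnUpdates,
       prefixes = pfx)
}

#' Run one CNN tower on a segment embedding matrix
#'
#' Applies conv/batch-norm/ReLU three times with max pooling after the
#' first two blocks, then global average pooling, returning the
#' `tower_dim`-length segment feature vector. In eval mode batch
#' normalization uses the stored moving statistics and the map is
#' deterministic.
#'
#' @param X a `(segment_length - k + 1) x d_embed` segment embedding matrix.
#' @param tower `"phage"` or `"host"`.
#' @param model a [SiameseHostModel-class].
#' @param mode `"eval"` or `"train"`.
#' @return numeric vector of length `tower_dim`.
#' @export
cnnTowerForward <- function(X, tower = c("phage", "host"), model,
                            mode = c("eval", "train")) {
  mode <- match.arg(mode)
  tower <- match.arg(tower)
  cfg <- model@config
  if (!is.matrix(X) || ncol(X) != cfg$d_embed)
    .phnStop("contract", sprintf("X must have %d columns (d_embed)", cfg$d_embed))
  pfx <- .towerPrefixes(cfg, tower)
  Xs <- matrix(as.vector(X), ncol = 1)
  out <- .cnnForward(Xs, 1L, nrow(X), ncol(X), pfx$cnn, model@params,
                     model@state, cfg, mode)
  as.vector(out$out)
}

#' Transformer aggregation of segment vectors into a global CLS vector
#'
#' Prepends the tower's learnable CLS vector, runs the stacked
#' self-attention/feed-forward layers with residual connections and layer
#' norm, and returns the final CLS row. Masked positions receive -Inf
#' attention logits (zero attention weight everywhere).
#'
#' @param segment_vectors a `c x tower_dim` matrix (one row per segment).
#' @param mask logical vector of length `c`; `FALSE` marks padding
#'   segments. Default all valid.
#' @param tower `"phage"` or `"host"`.
#' @param model a [SiameseHostModel-class].
#' @return numeric vector of length `tower_dim` (C_phage or C_host).
#' @export
transformerEncode <- function(segment_vectors, mask = NULL,
                              tower = c("phage", "host"), model) {
  tower <- match.arg(tower)
  cfg <- model@config
  if (is.null(dim(segment_vectors)))
    segment_vectors <- matrix(segment_vectors, nrow = 1)
  if (nrow(segment_vectors) < 1)
    .phnStop("contract", "at least one segment vector is required")
  if (ncol(segment_vectors) != cfg$tower_dim)
    .phnStop("contract", sprintf("segment vectors must have %d columns",
                                 cfg$tower_dim))
  if (is.null(mask)) mask <- rep(TRUE, nrow(segment_vectors))
  if (length(mask) != nrow(segment_vectors))
    .phnStop("contract", "mask length must match the number of segments")
  if (!any(mask)) .phnStop("contract", "mask excludes every segment")
  pfx <- .towerPrefixes(cfg, tower)
  .tfForward(segment_vectors, mask, pfx$tf, model@params, cfg)$cls
}

#' Scaled dot-product attention for one head
#'
#' `softmax(Q K' / sqrt(d_k)) V`; each output row is a convex combination
#' of the value rows. The post-softmax weight matrix is attached as
#' attribute `"weights"`.
#'
#' @param Q,K,V query/key/value matrices (rows = positions); `Q` and `K`
#'   must share column count, `K` and `V` row count.
#' @param d_k scaling dimension (defaults to `ncol(K)`).
#' @return the attention output matrix.
#' @export
attentionHead <- function(Q, K, V, d_k = ncol(K)) {
  if (!is.numeric(d_k) || length(d_k) != 1 || d_k <= 0)
    .phnStop("config", "d_k must be a positive scalar")
  if (ncol(Q) != ncol(K) || nrow(K) != nrow(V))
    .phnStop("contract", "non-conforming Q/K/V shapes")
  W <- .softmaxRows(tcrossprod(Q, K) / sqrt(d_k))
  out <- W %*% V
  attr(out, "weights") <- W
  out
}

#' Fuse tower outputs and classify
#'
#' Concatenates the phage and host global vectors to a fused feature of
#' length `2 * tower_dim`, applies the ReLU MLP (hidden width
#' `mlp_hidden`), and softmaxes to a match probability distribution.
#'
#' @param C_phage,C_host tower global vectors (length `tower_dim`).
#' @param model a [SiameseHostModel-class].
#' @return named numeric: `p_non_match`, `p_match` (sums to 1).
#' @export
fuseAndClassify <- function(C_phage, C_host, model) {
  cfg <- model@config
  if (length(C_phage) != cfg$tower_dim || length(C_host) != cfg$tower_dim)
    .phnStop("contract", sprintf("tower vectors must have length %d",
                                 cfg$tower_dim))
  z <- c(C_phage, C_host)
  if (isTRUE(cfg$normalize_fusion)) {
    fs <- .fusionScale(model@state[["fusion.stats"]], length(z))
    z <- (z - fs$mean) * fs$invsd
  }
  p <- .mlpForward(z, model@params)$p
  stats::setNames(p, c("p_non_match", "p_match"))
}

#' Score one phage-host pair end to end
#'
#' Full pipeline: segmentation, k-mer tokenization, embedding lookup,
#' per-segment CNN (phage tower for the phage genome, host tower for the
#' host genome), per-tower Transformer CLS aggregation, fusion MLP. With
#' `use_transformer = FALSE` the global vector is the mean of the segment
#' vectors instead.
#'
#' @param model a [SiameseHostModel-class].
#' @param phage,host genome sequences (character scalars, `DNAString`s, or
#'   records with a `$sequence` field).
#' @param table a [KmerEmbedding-class] (ignored when the model trains its
#'   own embedding).
#' @param mode `"eval"` (deterministic, moving BN statistics) or `"train"`
#'   (batch BN statistics).
#' @return named numeric: `p_non_match`, `p_match`.
#' @export
forwardPair <- function(model, phage, host, table = NULL,
                        mode = c("eval", "train")) {
  mode <- match.arg(mode)
  seqOf <- function(x) if (is.list(x)) x$sequence else as.character(x)
  cp <- .towerForward(model, seqOf(phage), "phage", table, mode)$global
  ch <- .towerForward(model, seqOf(host), "host", table, mode)$global
  fuseAndClassify(cp, ch, model)
}
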