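# The deep multi-head attention network: configuration, initialization,
# forward passes and component-level operations. The dense numerics live in
# compiled code (src/nn.cpp); this layer owns shapes, validation, and
# sequence encoding.

#' Build a network configuration
#'
#' Defaults follow the published architecture: 21-nt piRNA, 31-nt mRNA
#' segment (extension l = 15), 128 convolution filters of width 5 per
#' branch, squeeze-and-excitation reduction 4, 16 attention heads scaled by
#' sqrt(21), a 512-wide residual feed-forward block, classifier widths
#' 32 and 8 per mRNA position, dropout 0.3 (SE and attention blocks) and
#' 0.75 (classifier). The classifier widths scale with the mRNA segment
#' length when \code{extension_l} is changed (supported values include
#' 10, 15 and 20).
#'
#' @param pirna_len piRNA length (21).
#' @param extension_l degradation recovery extension; segment length 2l + 1.
#' @param n_filters,kernel_size convolution branch dimensions.
#' @param se_reduction squeeze-and-excitation reduction factor.
#' @param n_heads attention heads; must divide \code{n_filters}.
#' @param dropout_se,dropout_attn,dropout_cls dropout rates.
#' @param pure_cnn build the ablation without the attention layer?
#' @return a \linkS4class{NetConfig}.
#' @export
netConfig <- function(pirna_len = 21L, extension_l = 15L, n_filters = 128L,
                      kernel_size = 5L, se_reduction = 4L, n_heads = 16L,
                      dropout_se = 0.3, dropout_attn = 0.3, dropout_cls = 0.75,
                      pure_cnn = FALSE) {
  mrna_len <- 2L * as.integer(extension_l) + 1L
  new("NetConfig",
      pirna_len = as.integer(pirna_len), mrna_len = mrna_len,
      n_filters = as.integer(n_filters), kernel_size = as.integer(kernel_size),
      se_reduction = as.integer(se_reduction), n_heads = as.integer(n_heads),
      ff_hidden = 4L * as.integer(n_filters),
      fc1_width = 32L * mrna_len, fc2_width = 8L * mrna_len,
      attn_scale_d = as.numeric(pirna_len),
      dropout_se = dropout_se, dropout_attn = dropout_attn,
      dropout_cls = dropout_cls, pure_cnn = pure_cnn)
}

# NetConfig -> plain list for the C++ boundary
.cfgList <- function(cfg) {
  sn <- slotNames(cfg)
  stats::setNames(lapply(sn, function(s) slot(cfg, s)), sn)
}

.uinit <- function(nr, nc) matrix(runif(nr * nc, -1, 1) / sqrt(nc), nr, nc)

#' Initialize a network
#'
#' Creates all weight tensors: fan-in scaled uniform for convolution and
#' fully connected weights, PReLU slopes at 0.25, batch/layer-norm gains at
#' 1, running batch-norm statistics at (0, 1). Deterministic given
#' \code{seed}.
#'
#' @param config a \linkS4class{NetConfig}.
#' @param seed integer seed for the initializers.
#' @return an untrained \linkS4class{PiRBindModel}.
#' @export
initNetwork <- function(config = netConfig(), seed = 1L) {
  stopifnot(is(config, "NetConfig"))
  validObject(config)
  Fn <- config@n_filters; ks <- config@kernel_size; red <- config@se_reduction
  ffh <- config@ff_hidden; fc1 <- config@fc1_width; fc2 <- config@fc2_width
  D <- config@mrna_len * Fn
  # ablation: pooled piRNA features rejoin at the second FC layer
  fc2_in <- fc1 + if (config@pure_cnn) Fn else 0L
  p <- .withSeed(seed, {
    p <- list()
    for (b in c("pi", "mr")) {
      p[[paste0(b, "_conv_W")]] <- .uinit(Fn, ks * 4L)
      p[[paste0(b, "_conv_b")]] <- rep(0, Fn)
      p[[paste0(b, "_bn_gamma")]] <- rep(1, Fn)
      p[[paste0(b, "_bn_beta")]] <- rep(0, Fn)
      p[[paste0(b, "_bn_rmean")]] <- rep(0, Fn)
      p[[paste0(b, "_bn_rvar")]] <- rep(1, Fn)
      p[[paste0(b, "_prelu")]] <- rep(0.25, Fn)
      p[[paste0(b, "_se_W1")]] <- .uinit(Fn %/% red, Fn)
      p[[paste0(b, "_se_b1")]] <- rep(0, Fn %/% red)
      p[[paste0(b, "_se_W2")]] <- .uinit(Fn, Fn %/% red)
      p[[paste0(b, "_se_b2")]] <- rep(0, Fn)
    }
    if (!config@pure_cnn) {
      p$att_Wq <- .uinit(Fn, Fn); p$att_Wk <- .uinit(Fn, Fn)
      p$att_Wv <- .uinit(Fn, Fn); p$att_Wh <- .uinit(Fn, Fn)
      p$att_bh <- rep(0, Fn)
    }
    p$ln1_gamma <- rep(1, Fn); p$ln1_beta <- rep(0, Fn)
    p$ff_W1 <- .uinit(ffh, Fn); p$ff_b1 <- rep(0, ffh); p$ff_prelu1 <- rep(0.25, ffh)
    p$ff_W2 <- .uinit(Fn, ffh); p$ff_b2 <- rep(0, Fn); p$ff_prelu2 <- rep(0.25, Fn)
    p$ln2_gamma <- rep(1, Fn); p$ln2_beta <- rep(0, Fn)
    p$cls_W1 <- .uinit(fc1, D); p$cls_b1 <- rep(0, fc1)
    p$cls_bn1_gamma <- rep(1, fc1); p$cls_bn1_beta <- rep(0, fc1)
    p$cls_bn1_rmean <- rep(0, fc1); p$cls_bn1_rvar <- rep(1, fc1)
    p$cls_prelu1 <- rep(0.25, fc1)
    p$cls_W2 <- .uinit(fc2, fc2_in); p$cls_b2 <- rep(0, fc2)
    p$cls_bn2_gamma <- rep(1, fc2); p$cls_bn2_beta <- rep(0, fc2)
    p$cls_bn2_rmean <- rep(0, fc2); p$cls_bn2_rvar <- rep(1, fc2)
    p$cls_prelu2 <- rep(0.25, fc2)
    p$cls_W3 <- .uinit(2L, fc2); p$cls_b3 <- rep(0, 2)
    p
  })
  new("PiRBindModel", config = config, params = p, trained = FALSE,
      log = list(), version = "piRBind-1")
}

# encode pair sequence columns into 0-based integer matrices
.encodePairs <- function(pirna_seqs, segment_seqs, cfg) {
  list(pi = .seqMatrix(rnaCanonicalize(pirna_seqs), cfg@pirna_len),
       mr = .seqMatrix(rnaCanonicalize(segment_seqs), cfg@mrna_len))
}

#' Full forward pass on one piRNA--segment pair
#'
#' Runs one-hot encoding, both convolution + squeeze-excitation branches,
#' the 16-head attention layer, the residual feed-forward block and the
#' classifier. Evaluation mode is deterministic (dropout off, batch-norm on
#' running statistics).
#'
#' @param model a \linkS4class{PiRBindModel}.
#' @param pirna_seq,mrna_seq sequences matching the configured lengths.
#' @param mode \code{"eval"} (deterministic) or \code{"train"}.
#' @param seed RNG seed for dropout in train mode.
#' @return list with \code{prob} (named probabilities, negative/positive) and
#'   \code{attention} (an \linkS4class{AttentionOutput}; NULL for pure-CNN
#'   models).
#' @export
forwardFull <- function(model, pirna_seq, mrna_seq, mode = c("eval", "train"),
                        seed = 1L) {
  mode <- match.arg(mode)
  cfg <- model@config
  enc <- .encodePairs(pirna_seq, mrna_seq, cfg)
  res <- nn_forward_cpp(model@params, .cfgList(cfg), enc$pi, enc$mr,
                        training = (mode == "train"),
                        return_attention = !cfg@pure_cnn, seed = as.integer(seed))
  prob <- stats::setNames(as.numeric(res$prob[1, ]), c("negative", "positive"))
  att <- NULL
  if (!cfg@pure_cnn) {
    perHead <- res$attention[, , , 1, drop = TRUE]
    dim(perHead) <- c(cfg@mrna_len, cfg@pirna_len, cfg@n_heads)
    att <- new("AttentionOutput", perHead = perHead,
               H = res$H, R = res$R)
  }
  list(prob = prob, attention = att)
}

#' Forward pass of the pure-CNN ablation
#'
#' Identical pipeline with the multi-head attention layer removed (the
#' residual input reduces to the mRNA features); the piRNA branch re-enters
#' as globally pooled squeeze-excitation features concatenated into the
#' second fully connected layer, so the ablation remains a two-sequence
#' classifier while carrying strictly fewer parameters than the attention
#' model.
#'
#' @inheritParams forwardFull
#' @return list with \code{prob} (named probabilities).
#' @export
forwardPureCNN <- function(model, pirna_seq, mrna_seq, mode = c("eval", "train"),
                           seed = 1L) {
  if (!model@config@pure_cnn)
    stop("model was not built with pure_cnn = TRUE; use netConfig(pure_cnn = TRUE)")
  forwardFull(model, pirna_seq, mrna_seq, mode = mode, seed = seed)
}

#' Predict binding probabilities for a pair table
#'
#' @param model a trained \linkS4class{PiRBindModel}.
#' @param pairs data.frame with columns \code{pirna_seq} and
#'   \code{segment_seq}.
#' @return numeric vector of positive-class probabilities.
#' @export
predictPairs <- function(model, pairs) {
  cfg <- model@config
  enc <- .encodePairs(pairs$pirna_seq, pairs$segment_seq, cfg)
  res <- nn_forward_cpp(model@params, .cfgList(cfg), enc$pi, enc$mr,
                        training = FALSE, return_attention = FALSE)
  as.numeric(res$prob[, 2])
}

#' Train a network
#'
#' Mini-batch Adam with cross-entropy loss, a reduce-on-plateau learning
#' rate schedule monitoring validation loss (patience 5, factor 0.1, floor
#' 1e-6) and no early stopping; the final-epoch weights are returned. The
#' published protocol uses 60 epochs at batch size 512 and learning rate
#' 0.001; \code{epochs} may be reduced for desk-scale runs.
#'
#' @param model an initialized \linkS4class{PiRBindModel}.
#' @param train_pairs,val_pairs data.frames with columns \code{pirna_seq},
#'   \code{segment_seq}, \code{label} ("positive"/"negative" or 1/0).
#' @param epochs,batch_size,lr,patience,factor,min_lr optimizer settings.
#' @param seed seed for shuffling and dropout.
#' @param verbose print per-epoch progress?
#' @return the trained model; the per-epoch log is in \code{epochLog(model)}.
#' @export
trainModel <- function(model, train_pairs, val_pairs = NULL, epochs = 60L,
                       batch_size = 512L, lr = 0.001, patience = 5L,
                       factor = 0.1, min_lr = 1e-6, seed = 1L, verbose = FALSE) {
  stopifnot(is(model, "PiRBindModel"))
  if (is.null(train_pairs) || nrow(train_pairs) == 0) stop("empty train split")
  cfg <- model@config
  tr <- .encodePairs(train_pairs$pirna_seq, train_pairs$segment_seq, cfg)
  ytr <- .labels01(train_pairs$label)
  if (!is.null(val_pairs) && nrow(val_pairs)) {
    va <- .encodePairs(val_pairs$pirna_seq, val_pairs$segment_seq, cfg)
    yva <- .labels01(val_pairs$label)
  } else {
    va <- list(pi = matrix(0L, 0, cfg@pirna_len), mr = matrix(0L, 0, cfg@mrna_len))
    yva <- integer()
  }
  res <- nn_train_cpp(model@params, .cfgList(cfg), tr$pi, tr$mr, ytr,
                      va$pi, va$mr, yva,
                      epochs = as.integer(epochs),
                      batch_size = as.integer(batch_size), lr = lr,
                      patience = as.integer(patience), factor = factor,
                      min_lr = min_lr, seed = as.integer(seed),
                      verbose = verbose)
  new("PiRBindModel", config = cfg, params = res$params, trained = TRUE,
      log = list(train_loss = res$train_loss, train_acc = res$train_acc,
                 val_loss = res$val_loss, val_acc = res$val_acc, lr = res$lr),
      version = model@version)
}

.labels01 <- function(label) {
  if (is.character(label) || is.factor(label)) {
    label <- as.character(label)
    bad <- !label %in% c("positive", "negative")
    if (any(bad)) stop("labels must be 'positive'/'negative' or 0/1")
    as.integer(label == "positive")
  } else {
    if (!all(label %in% c(0, 1))) stop("labels must be 'positive'/'negative' or 0/1")
    as.integer(label)
  }
}

# ---------------------------------------------------------------------------
# component-level operations (evaluation mode, single example)

#' Convolutional motif extraction on a one-hot matrix
#'
#' Zero-padded 1D convolution (output length equals input length) followed
#' optionally by batch normalization (running statistics) and PReLU.
#'
#' @param E L x 4 (one-hot or real-valued) encoding matrix.
#' @param weights named list with \code{W} (n_filters x 4*kernel_size,
#'   column order position-major), \code{b}, and for the normalization/
#'   activation steps \code{bn_gamma, bn_beta, bn_rmean, bn_rvar, prelu}.
#' @param with_bn,with_act apply the batch-norm / PReLU stages?
#' @return L x n_filters feature matrix.
#' @export
convMotifExtract <- function(E, weights, with_bn = TRUE, with_act = TRUE) {
  Fn <- nrow(weights$W)
  dft <- function(nm, v) if (!is.null(weights[[nm]])) weights[[nm]] else v
  nn_conv_cpp(E, weights$W, dft("b", rep(0, Fn)),
              dft("bn_gamma", rep(1, Fn)), dft("bn_beta", rep(0, Fn)),
              dft("bn_rmean", rep(0, Fn)), dft("bn_rvar", rep(1, Fn)),
              dft("prelu", rep(0.25, Fn)), with_bn, with_act)
}

#' Squeeze-and-excitation block
#'
#' Channel-wise gating: squeeze to per-channel means, excite through a
#' bottleneck (ReLU then sigmoid), and rescale every channel of the input
#' (Hadamard product broadcast across positions).
#'
#' @param C L x n_filters feature matrix.
#' @param weights named list with \code{W1} (bottleneck x n_filters),
#'   \code{b1}, \code{W2} (n_filters x bottleneck), \code{b2}.
#' @return list with \code{F} (gated features), \code{excitation} and
#'   \code{squeeze} vectors.
#' @export
seBlock <- function(C, weights) {
  if (ncol(weights$W1) != ncol(C))
    stop("SE weights do not match the channel count")
  nn_se_cpp(C, weights$W1,
            if (is.null(weights$b1)) rep(0, nrow(weights$W1)) else weights$b1,
            weights$W2,
            if (is.null(weights$b2)) rep(0, nrow(weights$W2)) else weights$b2)
}

#' One attention head
#'
#' Scaled dot-product attention of mRNA-position queries against
#' piRNA-position keys/values: softmax((M Wq)(P Wk)^T / sqrt(d)) (P Wv).
#' The scale uses d = piRNA length, as specified for this architecture.
#'
#' @param M,P mRNA and piRNA feature matrices (positions x channels).
#' @param weights list with \code{Wq}, \code{Wk}, \code{Wv} (channels x
#'   head width).
#' @param d softmax scale length (default: number of piRNA positions).
#' @return list with \code{H} (attended features) and \code{weights}
#'   (row-stochastic mrna_len x pirna_len matrix).
#' @export
attentionHead <- function(M, P, weights, d = nrow(P)) {
  if (d <= 0) stop("attention scale d must be positive")
  nn_attention_head_cpp(M, P, weights$Wq, weights$Wk, weights$Wv, d)
}

#' Multi-head attention layer
#'
#' Runs \code{n_heads} parallel attention heads on disjoint channel blocks
#' and recombines the concatenated outputs through the summary projection:
#' H = (H_1 + ... + H_k concatenated) W_h^T.
#'
#' @param M,P feature matrices.
#' @param weights list with full-width \code{Wq}, \code{Wk}, \code{Wv},
#'   \code{Wh} (channels x channels) and optional bias \code{bh}.
#' @param n_heads number of heads (channel count must be divisible).
#' @param d softmax scale length.
#' @return list with \code{H} and per-head \code{weights}
#'   (mrna_len x pirna_len x n_heads array).
#' @export
multiHead <- function(M, P, weights, n_heads = 16L, d = nrow(P)) {
  bh <- if (is.null(weights$bh)) rep(0, ncol(M)) else weights$bh
  res <- nn_multi_head_cpp(M, P, weights$Wq, weights$Wk, weights$Wv,
                           weights$Wh, bh, as.integer(n_heads), d)
  res
}

#' Residual feed-forward block
#'
#' K = H + M, layer-normalized; a two-layer position-wise feed-forward map
#' with PReLU activations; second residual addition and layer
#' normalization.
#'
#' @param H,M attention output and mRNA features (same shape).
#' @param weights list with \code{ln1_gamma, ln1_beta, W1, b1, prelu1, W2,
#'   b2, prelu2, ln2_gamma, ln2_beta}.
#' @return the block output matrix R.
#' @export
residualFF <- function(H, M, weights) {
  w <- weights
  Fn <- ncol(M); ffh <- nrow(w$W1)
  dft <- function(nm, v) if (!is.null(w[[nm]])) w[[nm]] else v
  nn_residual_ff_cpp(H, M,
                     dft("ln1_gamma", rep(1, Fn)), dft("ln1_beta", rep(0, Fn)),
                     w$W1, dft("b1", rep(0, ffh)), dft("prelu1", rep(0.25, ffh)),
                     w$W2, dft("b2", rep(0, Fn)), dft("prelu2", rep(0.25, Fn)),
                     dft("ln2_gamma", rep(1, Fn)), dft("ln2_beta", rep(0, Fn)))
}

#' Classification head
#'
#' Flattens the block output position-major, applies two fully connected
#' layers (batch-norm on running statistics + PReLU) and a final 2-unit
#' linear map with softmax.
#'
#' @param R block output matrix (positions x channels) or an
#'   already-flattened numeric vector / matrix of rows.
#' @param weights list with \code{W1, b1, bn1_gamma, bn1_beta, bn1_rmean,
#'   bn1_rvar, prelu1, W2, b2, bn2_*, prelu2, W3, b3}.
#' @return named probability vector (negative, positive).
#' @export
classifyFeatures <- function(R, weights) {
  x <- if (is.matrix(R) && ncol(R) != ncol(weights$W1))
    matrix(as.numeric(t(R)), nrow = 1) else matrix(as.numeric(R), nrow = 1)
  w <- weights
  fc1 <- nrow(w$W1); fc2 <- nrow(w$W2)
  dft <- function(nm, v) if (!is.null(w[[nm]])) w[[nm]] else v
  p <- nn_classify_cpp(x, w$W1, dft("b1", rep(0, fc1)),
                       dft("bn1_gamma", rep(1, fc1)), dft("bn1_beta", rep(0, fc1)),
                       dft("bn1_rmean", rep(0, fc1)), dft("bn1_rvar", rep(1, fc1)),
                       dft("prelu1", rep(0.25, fc1)),
                       w$W2, dft("b2", rep(0, fc2)),
                       dft("bn2_gamma", rep(1, fc2)), dft("bn2_beta", rep(0, fc2)),
                       dft("bn2_rmean", rep(0, fc2)), dft("bn2_rvar", rep(1, fc2)),
                       dft("prelu2", rep(0.25, fc2)),
                       w$W3, dft("b3", rep(0, 2)))
  stats::setNames(as.numeric(p[1, ]), c("negative", "positive"))
}
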