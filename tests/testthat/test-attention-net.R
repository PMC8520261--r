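# Network-level behavior: degenerate-weight identities, shape bookkeeping
# across segment lengths, eval-mode determinism, gradient flow and the
# analytic backward pass.

small_cfg_list <- function(pure = FALSE, Lp = 7L, Lm = 9L, Fn = 8L) {
  list(pirna_len = Lp, mrna_len = Lm, n_filters = Fn, kernel_size = 3L,
       se_reduction = 4L, n_heads = 2L, ff_hidden = 16L,
       fc1_width = 12L, fc2_width = 6L, attn_scale_d = as.numeric(Lp),
       dropout_se = 0, dropout_attn = 0, dropout_cls = 0, pure_cnn = pure)
}

small_params <- function(cfgl, seed = 42) {
  cfg <- netConfig(pirna_len = cfgl$pirna_len,
                   extension_l = (cfgl$mrna_len - 1L) %/% 2L,
                   n_filters = cfgl$n_filters, kernel_size = cfgl$kernel_size,
                   se_reduction = cfgl$se_reduction, n_heads = cfgl$n_heads,
                   dropout_se = cfgl$dropout_se, dropout_attn = cfgl$dropout_attn,
                   dropout_cls = cfgl$dropout_cls, pure_cnn = cfgl$pure_cnn)
  # override the derived widths with the small test dimensions
  cfg@ff_hidden <- cfgl$ff_hidden
  cfg@fc1_width <- cfgl$fc1_width
  cfg@fc2_width <- cfgl$fc2_width
  initNetwork(cfg, seed = seed)
}

test_that("degenerate weights reproduce the layer identities", {
  # all-zero kernel with identity BN gives a zero channel (PReLU(0) = 0)
  L <- 8L; Fn <- 4L
  z <- convMotifExtract(oneHotEncode(rand_seq(L)),
                        list(W = matrix(0, Fn, 12), b = rep(0, Fn)))
  expect_true(all(z == 0))
  # delta kernel at the window center on channel A over poly-A: ones
  W <- matrix(0, 1, 12); W[1, 4 + 1] <- 1   # center tap, channel A
  pre <- convMotifExtract(oneHotEncode("AAAAA"), list(W = W),
                          with_bn = FALSE, with_act = FALSE)
  expect_identical(unname(pre[, 1]), rep(1, 5))
  # SE gating at exactly 1 (huge bias) and exactly 0.5 (zero pre-sigmoid)
  C <- matrix(rnorm(40), 10, 4)
  se1 <- seBlock(C, list(W1 = matrix(0, 1, 4), b1 = 0,
                         W2 = matrix(0, 4, 1), b2 = rep(50, 4)))
  expect_equal(se1$F, C, tolerance = 1e-12)
  se5 <- seBlock(C, list(W1 = matrix(0, 1, 4), b1 = 0,
                         W2 = matrix(0, 4, 1), b2 = rep(0, 4)))
  expect_equal(se5$F, C / 2, tolerance = 1e-12)
  # identical piRNA feature rows give uniform attention regardless of M
  M <- matrix(rnorm(9 * 4), 9)
  P <- matrix(rep(rnorm(4), each = 7), 7)   # identical rows
  hw <- list(Wq = matrix(rnorm(8), 4), Wk = matrix(rnorm(8), 4),
             Wv = matrix(rnorm(8), 4))
  got <- attentionHead(M, P, hw, d = 21)
  expect_equal(unname(got$weights), matrix(1 / 7, 9, 7), tolerance = 1e-12)
  # zero value projection zeroes the attended output
  hw$Wv <- matrix(0, 4, 2)
  expect_true(all(attentionHead(M, P, hw, d = 21)$H == 0))
  # one head with identity summary equals the head output
  mw <- list(Wq = matrix(rnorm(16), 4), Wk = matrix(rnorm(16), 4),
             Wv = matrix(rnorm(16), 4), Wh = diag(4))
  mh <- multiHead(M, P, mw, n_heads = 1, d = 21)
  oh <- attentionHead(M, P, list(Wq = mw$Wq, Wk = mw$Wk, Wv = mw$Wv), d = 21)
  expect_equal(mh$H, oh$H, tolerance = 1e-12)
  # zero FF weights reduce the residual block to the double-normalized skip
  Fn2 <- 6L
  H0 <- matrix(0, 5, Fn2); Mm <- matrix(rnorm(5 * Fn2), 5)
  w0 <- list(W1 = matrix(0, 8, Fn2), W2 = matrix(0, Fn2, 8))
  got <- residualFF(H0, Mm, w0)
  want <- oracle_ln(oracle_ln(Mm, rep(1, Fn2), rep(0, Fn2)),
                    rep(1, Fn2), rep(0, Fn2))
  expect_equal(got, want, tolerance = 1e-10)
  # zero classifier weights give the coin-flip posterior
  cw <- list(W1 = matrix(0, 4, 30), W2 = matrix(0, 3, 4),
             W3 = matrix(0, 2, 3))
  expect_equal(unname(classifyFeatures(matrix(rnorm(30), 5, 6), cw)),
               c(0.5, 0.5), tolerance = 1e-12)
  # extreme final logits saturate the softmax
  cwb <- cw; cwb$b3 <- c(10, -10)
  p <- classifyFeatures(matrix(0, 5, 6), cwb)
  expect_lt(abs(p[["negative"]] - 1), 1e-4)
})

test_that("shapes track the mRNA extension length l in {10, 15, 20}", {
  set.seed(20)
  for (l in c(10L, 15L, 20L)) {
    cfg <- netConfig(extension_l = l)
    expect_identical(cfg@mrna_len, 2L * l + 1L)
    expect_identical(cfg@fc1_width, 32L * (2L * l + 1L))
    expect_identical(cfg@fc2_width, 8L * (2L * l + 1L))
    m <- initNetwork(cfg, seed = l)
    expect_identical(dim(m@params$cls_W1), c(32L * (2L * l + 1L),
                                             (2L * l + 1L) * 128L))
    fw <- forwardFull(m, rand_seq(21), rand_seq(2L * l + 1L))
    expect_identical(dim(fw$attention@perHead), c(2L * l + 1L, 21L, 16L))
    expect_identical(dim(fw$attention@R), c(2L * l + 1L, 128L))
    # attention rows are stochastic
    for (h in c(1, 16))
      expect_equal(rowSums(fw$attention@perHead[, , h]),
                   rep(1, 2L * l + 1L), tolerance = 1e-5)
    expect_equal(sum(fw$prob), 1, tolerance = 1e-6)
  }
  expect_error(initNetwork(netConfig(n_heads = 7L)), "divisible")
})

test_that("eval mode is deterministic and a random net is calibrated near 0.5", {
  set.seed(21)
  m <- initNetwork(netConfig(), seed = 3)
  p1 <- rand_seq(21); s1 <- rand_seq(31)
  f1 <- forwardFull(m, p1, s1); f2 <- forwardFull(m, p1, s1)
  expect_identical(f1$prob, f2$prob)
  expect_identical(f1$attention@perHead, f2$attention@perHead)
  # balanced random batch scores near 0.5 on average under random init
  pairs <- data.frame(pirna_seq = replicate(200, rand_seq(21)),
                      segment_seq = replicate(200, rand_seq(31)))
  pp <- predictPairs(m, pairs)
  expect_lt(abs(mean(pp) - 0.5), 0.1)
})

test_that("the pure-CNN ablation drops parameters but stays a two-input model", {
  full <- initNetwork(netConfig(), seed = 1)
  pure <- initNetwork(netConfig(pure_cnn = TRUE), seed = 1)
  expect_lt(nParams(pure), nParams(full))
  expect_error(forwardPureCNN(full, rand_seq(21), rand_seq(31)), "pure_cnn")
  f <- forwardPureCNN(pure, rand_seq(21), rand_seq(31))
  expect_equal(sum(f$prob), 1, tolerance = 1e-6)
  expect_null(f$attention)
  # the piRNA sequence still reaches the classifier: changing it moves p
  set.seed(22)
  s <- rand_seq(31)
  p_a <- forwardPureCNN(pure, rand_seq(21), s)$prob
  p_b <- forwardPureCNN(pure, rand_seq(21), s)$prob
  expect_false(identical(p_a, p_b))
})

test_that("analytic gradients match finite differences on a small net", {
  for (pure in c(FALSE, TRUE)) {
    set.seed(30 + pure)
    cfgl <- small_cfg_list(pure)
    par <- small_params(cfgl)@params
    B <- 4L
    pi <- matrix(sample(0:3, B * cfgl$pirna_len, TRUE), B)
    mr <- matrix(sample(0:3, B * cfgl$mrna_len, TRUE), B)
    y <- c(0L, 1L, 1L, 0L)
    res <- piRBind:::nn_loss_grads_cpp(par, cfgl, pi, mr, y)
    eps <- 1e-5
    skip_nm <- grepl("_rmean$|_rvar$", names(par))
    for (nm in names(par)[!skip_nm]) {
      idx <- sample(length(par[[nm]]), min(3, length(par[[nm]])))
      for (i in idx) {
        pp <- par; pp[[nm]][i] <- pp[[nm]][i] + eps
        lp <- piRBind:::nn_loss_grads_cpp(pp, cfgl, pi, mr, y, FALSE)$loss
        pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
        lm <- piRBind:::nn_loss_grads_cpp(pp, cfgl, pi, mr, y, FALSE)$loss
        num <- (lp - lm) / (2 * eps)
        ana <- as.numeric(res$grads[[nm]])[i]
        expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-3)
      }
    }
  }
})

test_that("one optimizer step moves every trainable tensor", {
  set.seed(31)
  cfgl <- small_cfg_list(FALSE)
  m <- small_params(cfgl)
  pairs <- data.frame(pirna_seq = replicate(16, rand_seq(cfgl$pirna_len)),
                      segment_seq = replicate(16, rand_seq(cfgl$mrna_len)),
                      label = rep(c("positive", "negative"), 8))
  # dropout active: exercise the full training path
  m@config@dropout_se <- 0.3; m@config@dropout_attn <- 0.3
  m@config@dropout_cls <- 0.5
  m2 <- trainModel(m, pairs, NULL, epochs = 1, batch_size = 16, seed = 1)
  trainable <- setdiff(names(m@params),
                       grep("_rmean$|_rvar$", names(m@params), value = TRUE))
  for (nm in trainable)
    expect_false(identical(m@params[[nm]], m2@params[[nm]]), info = nm)
})

test_that("a short training run is sane and the scheduler respects its floor", {
  set.seed(32)
  world <- genWorld(synthSpec(n_transcripts = 80L,
                              transcript_len_range = c(400L, 700L),
                              n_pirnas = 80L, n_planted_sites = 300L,
                              seed = 17L))
  gt <- genPairDataset(world, n_pos = 256, n_neg = 256, seed = 1,
                       compute_energy = FALSE)
  pairs <- pairTable(gt)
  m <- trainModel(initNetwork(netConfig(), seed = 1), pairs, pairs[1:100, ],
                  epochs = 2, batch_size = 256, seed = 1)
  log <- epochLog(m)
  expect_true(all(is.finite(log$train_loss)))
  expect_gt(utils::tail(log$train_acc, 1), 0.4)
  expect_true(isTrained(m))
  # plateaued validation loss triggers reduce-on-plateau down to the floor:
  # random labels cannot be fit, so the loss stalls and the rate decays
  noise <- pairs[1:128, ]
  set.seed(33)
  noise$label <- sample(noise$label)
  m2 <- trainModel(initNetwork(netConfig(), seed = 2), noise, noise,
                   epochs = 10, batch_size = 128, lr = 1e-3, patience = 1,
                   factor = 0.1, min_lr = 1e-5, seed = 1)
  lrs <- epochLog(m2)$lr
  expect_true(any(lrs < 1e-3))          # at least one reduction fired
  expect_true(all(lrs >= 1e-5 - 1e-12)) # floored at min_lr
  expect_true(all(diff(lrs) <= 1e-12))  # never increases
  expect_error(trainModel(initNetwork(netConfig(), seed = 1), pairs[0, ]),
               "empty train split")
})

test_that("checkpoints round-trip through save and load", {
  m <- initNetwork(netConfig(extension_l = 10L), seed = 9)
  path <- tempfile(fileext = ".rds")
  saveModel(m, path)
  m2 <- loadModel(path)
  expect_identical(m2@version, m@version)
  expect_identical(m2@config@mrna_len, 21L)
  expect_identical(m2@params, m@params)
  s <- rand_seq(21); seg <- rand_seq(21)
  expect_identical(forwardFull(m, s, seg)$prob, forwardFull(m2, s, seg)$prob)
})
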