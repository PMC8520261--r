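# Memoized heavy fixtures shared across test files (trained networks are
# expensive; each is built once per test run). Sizes and training protocols
# are the package's desk-scale study conditions, fixed ahead of time.

.heavy <- new.env(parent = emptyenv())

default_world <- function() {
  if (is.null(.heavy$world)) .heavy$world <- genWorld(synthSpec())
  .heavy$world
}

# planted-rule learnability run: generator defaults (3500 + 3500 pairs,
# seed 0), explicit stratified 5000/1000/1000 split, 20 epochs
strong_model_fixture <- function() {
  if (is.null(.heavy$strong)) {
    gt <- genPairDataset(default_world(), seed = 0, compute_energy = FALSE)
    pairs <- pairTable(gt)
    set.seed(0)
    ip <- sample(which(pairs$label == "positive"))
    ineg <- sample(which(pairs$label == "negative"))
    tr <- pairs[c(ip[1:2500], ineg[1:2500]), ]
    va <- pairs[c(ip[2501:3000], ineg[2501:3000]), ]
    te <- pairs[c(ip[3001:3500], ineg[3001:3500]), ]
    model <- trainModel(initNetwork(netConfig(), seed = 1), tr, va,
                        epochs = 20, batch_size = 512, seed = 1)
    .heavy$strong <- list(model = model, train = tr, val = va, test = te,
                          auc = evaluateModel(model, te)$auc)
  }
  .heavy$strong
}

# ablation runs: 5 seeds, 1250 + 1250 pairs each, 8:1:1 split, full vs
# pure-CNN at 15 epochs / batch 128
ablation_fixture <- function() {
  if (is.null(.heavy$ablation)) {
    world <- default_world()
    seeds <- 1:5
    aucs <- matrix(NA_real_, 2, length(seeds),
                   dimnames = list(c("full", "pure"), NULL))
    fulls <- tests <- trains <- vector("list", length(seeds))
    for (k in seq_along(seeds)) {
      sd <- seeds[k]
      gt <- genPairDataset(world, n_pos = 1250, n_neg = 1250, seed = sd,
                           compute_energy = FALSE)
      pairs <- pairTable(gt)
      sp <- makeRandomSplits(pairs$label, n_repeats = 1, seed = sd)[[1]]
      tr <- pairs[sp$train, ]; va <- pairs[sp$val, ]; te <- pairs[sp$test, ]
      mf <- trainModel(initNetwork(netConfig(), seed = sd), tr, va,
                       epochs = 15, batch_size = 128, seed = sd)
      mp <- trainModel(initNetwork(netConfig(pure_cnn = TRUE), seed = sd),
                       tr, va, epochs = 15, batch_size = 128, seed = sd)
      aucs["full", k] <- evaluateModel(mf, te)$auc
      aucs["pure", k] <- evaluateModel(mp, te)$auc
      fulls[[k]] <- mf; tests[[k]] <- te; trains[[k]] <- tr
    }
    .heavy$ablation <- list(aucs = aucs, fulls = fulls, tests = tests,
                            trains = trains, seeds = seeds)
  }
  .heavy$ablation
}

# feature-based MLP baseline on the same per-seed datasets as the ablation
mlp_fixture <- function() {
  if (is.null(.heavy$mlp)) {
    abl <- ablation_fixture()
    aucs <- vapply(seq_along(abl$seeds), function(k) {
      ftr <- featureTable(abl$trains[[k]])
      fte <- featureTable(abl$tests[[k]])
      mlp <- trainMlpBaseline(ftr, ftr$label, seed = abl$seeds[k])
      rocAuc(fte$label, predictMlp(mlp, fte))$auc
    }, 0)
    .heavy$mlp <- aucs
  }
  .heavy$mlp
}
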