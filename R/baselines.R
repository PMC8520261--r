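# Whole-sequence baseline scores: CG content, nucleotide composition,
# k-mer tandem-repeat summaries (k = 2, 3, 4) and the duplex energy --
# 18 features in total -- plus single-feature ROC baselines and a small
# feed-forward MLP trained on the standardized feature vectors.

#' Nucleotide composition features
#'
#' @param segment an RNA sequence.
#' @return named vector: \code{cg_content} and the four base fractions
#'   \code{comp_A}, \code{comp_U}, \code{comp_C}, \code{comp_G} (summing
#'   to 1).
#' @export
compositionFeatures <- function(segment) {
  segment <- rnaCanonicalize(segment)
  if (!nchar(segment)) stop("empty sequence")
  ch <- strsplit(segment, "", fixed = TRUE)[[1]]
  n <- length(ch)
  f <- vapply(c("A", "U", "C", "G"), function(b) sum(ch == b) / n, 0)
  c(cg_content = unname(f["C"] + f["G"]),
    comp_A = unname(f["A"]), comp_U = unname(f["U"]),
    comp_C = unname(f["C"]), comp_G = unname(f["G"]))
}

#' Tandem-repeat summaries for one k
#'
#' Greedy left-to-right scan for maximal head-to-tail runs of a k-mer
#' repeated at least twice (e.g. AUAUAU is one run of unit AU with
#' multiplicity 3). Reported summaries: number of repeat loci, maximum
#' repeat multiplicity, fraction of positions covered by repeat runs, and
#' the number of distinct repeat units.
#'
#' @param segment an RNA sequence with \code{nchar >= 2k}.
#' @param k unit length, one of 2, 3, 4.
#' @return named vector \code{n_loci}, \code{max_count}, \code{covered},
#'   \code{distinct}.
#' @export
tandemRepeatFeatures <- function(segment, k) {
  if (!k %in% 2:4) stop("k must be 2, 3 or 4")
  segment <- rnaCanonicalize(segment)
  n <- nchar(segment)
  if (n < 2 * k) stop("segment shorter than 2k")
  loci <- 0L; maxc <- 0L; covered <- 0L; units <- character()
  i <- 1L
  while (i <= n - 2L * k + 1L) {
    unit <- substr(segment, i, i + k - 1L)
    r <- 1L
    while (i + (r + 1L) * k - 1L <= n &&
           substr(segment, i + r * k, i + (r + 1L) * k - 1L) == unit)
      r <- r + 1L
    if (r >= 2L) {
      loci <- loci + 1L
      maxc <- max(maxc, r)
      covered <- covered + r * k
      units <- union(units, unit)
      i <- i + r * k
    } else i <- i + 1L
  }
  c(n_loci = loci, max_count = maxc, covered = covered / n,
    distinct = length(units))
}

#' The 18-dimensional baseline feature vector of one pair
#'
#' 17 whole-sequence mRNA statistics (CG content, 4 base compositions, 4
#' tandem-repeat summaries for each k in 2, 3, 4) plus the piRNA--mRNA
#' duplex energy.
#'
#' @param pirna_seq,segment_seq the pair sequences.
#' @param engine energy engine (see \code{\link{duplexEnergy}}).
#' @return named numeric vector of length 18.
#' @export
pairFeatures <- function(pirna_seq, segment_seq, engine = "internal") {
  comp <- compositionFeatures(segment_seq)
  tr <- unlist(lapply(2:4, function(k) {
    v <- tandemRepeatFeatures(segment_seq, k)
    stats::setNames(v, paste0("k", k, "_", names(v)))
  }))
  c(comp, tr, duplex_energy = duplexEnergy(pirna_seq, segment_seq,
                                           engine = engine))
}

#' Feature table for a pair set
#'
#' @param pairs labeled pair data.frame (or \linkS4class{GroundTruth}).
#' @return data.frame of the 18 features plus \code{label}.
#' @export
featureTable <- function(pairs) {
  if (is(pairs, "GroundTruth")) pairs <- pairTable(pairs)
  feats <- t(vapply(seq_len(nrow(pairs)), function(i)
    pairFeatures(pairs$pirna_seq[i], pairs$segment_seq[i]),
    numeric(18L)))
  out <- as.data.frame(feats)
  out$label <- pairs$label
  out
}

#' Single-feature ROC baseline
#'
#' Uses one raw feature as the classification score, auto-orienting its
#' sign so the reported AUC is at least 0.5.
#'
#' @param features feature data.frame from \code{\link{featureTable}}.
#' @param feature_name column to evaluate.
#' @return list with \code{roc}, \code{auc} and \code{flipped} (TRUE when
#'   the score was negated).
#' @export
singleFeatureAuc <- function(features, feature_name) {
  x <- features[[feature_name]]
  if (is.null(x)) stop("unknown feature: ", feature_name)
  if (length(unique(x)) < 2) stop("feature '", feature_name, "' is constant")
  roc <- rocAuc(features$label, x)
  flipped <- FALSE
  if (roc$auc < 0.5) { roc <- rocAuc(features$label, -x); flipped <- TRUE }
  list(roc = roc, auc = roc$auc, flipped = flipped)
}

# ---------------------------------------------------------------------------
# feature-based MLP baseline (18 -> 128 -> 128 -> 128 -> 2)

.mlpInit <- function(dims) {
  W <- list(); b <- list()
  for (i in seq_len(length(dims) - 1L)) {
    W[[i]] <- .uinit(dims[i + 1L], dims[i])
    b[[i]] <- rep(0, dims[i + 1L])
  }
  list(W = W, b = b)
}

#' Train the feature-based MLP baseline
#'
#' Three hidden layers of 128 ReLU units with dropout 0.1 and Adam at
#' learning rate 0.00026, on z-score standardized features (statistics
#' estimated on the training data). Deterministic given \code{seed}.
#'
#' @param features numeric matrix or data.frame (18 columns).
#' @param labels 0/1 or "negative"/"positive".
#' @param hidden hidden layer widths.
#' @param dropout,lr,epochs,batch_size optimizer settings.
#' @param seed RNG seed.
#' @return model object of class \code{pirbindMLP} for
#'   \code{\link{predictMlp}}.
#' @export
trainMlpBaseline <- function(features, labels, hidden = c(128L, 128L, 128L),
                             dropout = 0.1, lr = 0.00026, epochs = 60L,
                             batch_size = 64L, seed = 1L) {
  X <- as.matrix(features[, setdiff(colnames(features), "label"), drop = FALSE])
  if (!all(is.finite(X))) stop("features contain non-finite values")
  y <- .labels01(labels)
  ctr <- colMeans(X); scl <- apply(X, 2, sd); scl[scl == 0] <- 1
  X <- scale(X, ctr, scl)
  dims <- c(ncol(X), hidden, 2L)
  .withSeed(seed, {
    net <- .mlpInit(dims)
    nl <- length(net$W)
    mW <- lapply(net$W, function(w) w * 0); vW <- mW
    mb <- lapply(net$b, function(v) v * 0); vb <- mb
    adam_t <- 0
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nrow(X))
      for (s in seq(1, nrow(X), by = batch_size)) {
        idx <- ord[s:min(s + batch_size - 1L, nrow(X))]
        if (length(idx) < 2) next
        a <- X[idx, , drop = FALSE]
        acts <- list(a); masks <- list()
        for (i in seq_len(nl)) {
          z <- a %*% t(net$W[[i]]) + rep(net$b[[i]], each = nrow(a))
          if (i < nl) {
            z[z < 0] <- 0
            m <- matrix(runif(length(z)) >= dropout, nrow(z)) / (1 - dropout)
            z <- z * m
            masks[[i]] <- m
          }
          a <- z
          acts[[i + 1L]] <- a
        }
        p <- exp(a - apply(a, 1, max)); p <- p / rowSums(p)
        d <- p; d[cbind(seq_along(idx), y[idx] + 1L)] <-
          d[cbind(seq_along(idx), y[idx] + 1L)] - 1
        d <- d / length(idx)
        adam_t <- adam_t + 1
        for (i in rev(seq_len(nl))) {
          gW <- t(d) %*% acts[[i]]; gb <- colSums(d)
          if (i > 1) {
            d <- d %*% net$W[[i]]
            d <- d * masks[[i - 1L]]
            d[acts[[i]] == 0] <- 0
          }
          mW[[i]] <- 0.9 * mW[[i]] + 0.1 * gW
          vW[[i]] <- 0.999 * vW[[i]] + 0.001 * gW^2
          mb[[i]] <- 0.9 * mb[[i]] + 0.1 * gb
          vb[[i]] <- 0.999 * vb[[i]] + 0.001 * gb^2
          bc1 <- 1 - 0.9^adam_t; bc2 <- 1 - 0.999^adam_t
          net$W[[i]] <- net$W[[i]] - lr * (mW[[i]] / bc1) / (sqrt(vW[[i]] / bc2) + 1e-8)
          net$b[[i]] <- net$b[[i]] - lr * (mb[[i]] / bc1) / (sqrt(vb[[i]] / bc2) + 1e-8)
        }
      }
    }
    structure(list(net = net, center = ctr, scale = scl, dims = dims),
              class = "pirbindMLP")
  })
}

#' Predict with the MLP baseline
#'
#' @param model a \code{pirbindMLP}.
#' @param features feature matrix/data.frame as used in training.
#' @return positive-class probabilities.
#' @export
predictMlp <- function(model, features) {
  X <- as.matrix(features[, setdiff(colnames(features), "label"), drop = FALSE])
  a <- scale(X, model$center, model$scale)
  nl <- length(model$net$W)
  for (i in seq_len(nl)) {
    a <- a %*% t(model$net$W[[i]]) + rep(model$net$b[[i]], each = nrow(a))
    if (i < nl) a[a < 0] <- 0
  }
  p <- exp(a - apply(a, 1, max)); p <- p / rowSums(p)
  p[, 2]
}
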