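# Independent reference implementations used as oracles: plain-R double-loop
# translations of the layer formulas, written directly from their definitions
# and kept separate from the compiled implementation they check.

rand_seq <- function(n) paste(sample(c("A", "U", "G", "C"), n, TRUE), collapse = "")

oracle_conv <- function(E, W, b) {
  L <- nrow(E); Fn <- nrow(W); ks <- ncol(W) / 4L; m <- (ks - 1L) / 2L
  C <- matrix(0, L, Fn)
  for (j in seq_len(L))
    for (n in seq_len(Fn)) {
      acc <- b[n]
      for (w in seq_len(ks))
        for (r in 1:4) {
          q <- j + w - 1L - m
          if (q >= 1 && q <= L) acc <- acc + W[n, (w - 1L) * 4L + r] * E[q, r]
        }
      C[j, n] <- acc
    }
  C
}

oracle_bn_eval <- function(X, gamma, beta, rmean, rvar, eps = 1e-5) {
  Y <- X
  for (j in seq_len(ncol(X)))
    Y[, j] <- (X[, j] - rmean[j]) / sqrt(rvar[j] + eps) * gamma[j] + beta[j]
  Y
}

oracle_prelu <- function(X, slope) {
  Y <- X
  for (j in seq_len(ncol(X)))
    Y[, j] <- ifelse(X[, j] > 0, X[, j], slope[j] * X[, j])
  Y
}

oracle_se <- function(C, W1, b1, W2, b2) {
  s <- colMeans(C)
  z1 <- pmax(as.numeric(W1 %*% s) + b1, 0)
  e <- 1 / (1 + exp(-(as.numeric(W2 %*% z1) + b2)))
  Fm <- C
  for (j in seq_len(ncol(C))) Fm[, j] <- C[, j] * e[j]
  list(F = Fm, excitation = e)
}

oracle_softmax_rows <- function(S) {
  A <- S
  for (i in seq_len(nrow(S))) {
    z <- exp(S[i, ] - max(S[i, ]))
    A[i, ] <- z / sum(z)
  }
  A
}

oracle_attention_head <- function(M, P, Wq, Wk, Wv, d) {
  Q <- M %*% Wq; K <- P %*% Wk; V <- P %*% Wv
  A <- oracle_softmax_rows(Q %*% t(K) / sqrt(d))
  list(H = A %*% V, weights = A)
}

oracle_multi_head <- function(M, P, Wq, Wk, Wv, Wh, bh, heads, d) {
  Fn <- ncol(M); hd <- Fn / heads
  Hcat <- matrix(0, nrow(M), Fn)
  for (h in seq_len(heads)) {
    cs <- ((h - 1L) * hd + 1L):(h * hd)
    r <- oracle_attention_head(M, P, Wq[, cs, drop = FALSE],
                               Wk[, cs, drop = FALSE], Wv[, cs, drop = FALSE], d)
    Hcat[, cs] <- r$H
  }
  H <- Hcat %*% t(Wh)
  for (j in seq_len(ncol(H))) H[, j] <- H[, j] + bh[j]
  H
}

oracle_ln <- function(X, gamma, beta, eps = 1e-5) {
  Y <- X
  for (i in seq_len(nrow(X))) {
    mu <- mean(X[i, ]); v <- mean((X[i, ] - mu)^2)
    Y[i, ] <- (X[i, ] - mu) / sqrt(v + eps) * gamma + beta
  }
  Y
}

oracle_residual_ff <- function(H, M, w) {
  K <- H + M
  Kn <- oracle_ln(K, w$ln1_gamma, w$ln1_beta)
  A1 <- Kn %*% t(w$W1)
  for (j in seq_len(ncol(A1))) A1[, j] <- A1[, j] + w$b1[j]
  A1 <- oracle_prelu(A1, w$prelu1)
  A2 <- A1 %*% t(w$W2)
  for (j in seq_len(ncol(A2))) A2[, j] <- A2[, j] + w$b2[j]
  A2 <- oracle_prelu(A2, w$prelu2)
  oracle_ln(Kn + A2, w$ln2_gamma, w$ln2_beta)
}

oracle_classify <- function(x, w) {
  lin <- function(v, W, b) as.numeric(W %*% v) + b
  h <- lin(x, w$W1, w$b1)
  h <- (h - w$bn1_rmean) / sqrt(w$bn1_rvar + 1e-5) * w$bn1_gamma + w$bn1_beta
  h <- ifelse(h > 0, h, w$prelu1 * h)
  h <- lin(h, w$W2, w$b2)
  h <- (h - w$bn2_rmean) / sqrt(w$bn2_rvar + 1e-5) * w$bn2_gamma + w$bn2_beta
  h <- ifelse(h > 0, h, w$prelu2 * h)
  z <- lin(h, w$W3, w$b3)
  e <- exp(z - max(z))
  e / sum(e)
}

# trapezoidal AUC from the ROC points (oracle for the rank formulation)
oracle_trapezoid_auc <- function(labels, scores) {
  y <- as.integer(labels == "positive" | labels == 1)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1) / sum(y == 1), 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / sum(y == 0), 0)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# exhaustive mismatch scan oracle
oracle_scan <- function(query, subject, max_mm) {
  q <- strsplit(query, "")[[1]]; s <- strsplit(subject, "")[[1]]
  out <- list()
  for (off in 0:(length(s) - length(q))) {
    mm <- sum(q != s[(off + 1):(off + length(q))])
    if (mm <= max_mm) out[[length(out) + 1L]] <- c(off, mm)
  }
  if (!length(out)) matrix(integer(), 0, 2) else do.call(rbind, out)
}
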