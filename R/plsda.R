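# Partial least squares discriminant analysis via NIPALS PLS2.
#
# The class membership is coded as a binary dummy response matrix (one
# column per class, 1 if the row belongs to the class). Latent variables are
# extracted by the NIPALS algorithm with deflation of both the predictor and
# response blocks; prediction assigns each sample to the class whose
# predicted response is largest.

pls2_nipals <- function(X, Y, n_lv, tol = 1e-10, max_iter = 500) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  n_lv <- min(n_lv, n - 1L, p)
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Q <- matrix(0, q, n_lv); TT <- matrix(0, n, n_lv)
  Xd <- X; Yd <- Y
  for (a in seq_len(n_lv)) {
    u <- Yd[, which.max(colSums(Yd^2))]
    t_old <- rep(0, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) break
      w <- w / nw
      t <- Xd %*% w
      qv <- crossprod(Yd, t) / sum(t^2)
      u <- Yd %*% qv / sum(qv^2)
      if (sqrt(sum((t - t_old)^2)) < tol * max(1, sqrt(sum(t^2)))) break
      t_old <- t
    }
    if (nw < 1e-14) { n_lv <- a - 1L; break }
    pv <- crossprod(Xd, t) / sum(t^2)
    Xd <- Xd - tcrossprod(t, pv)
    Yd <- Yd - tcrossprod(t, qv)
    W[, a] <- w; P[, a] <- pv; Q[, a] <- qv; TT[, a] <- t
  }
  if (n_lv == 0) stop("PLS-DA: predictor block has no variance", call. = FALSE)
  W <- W[, seq_len(n_lv), drop = FALSE]
  P <- P[, seq_len(n_lv), drop = FALSE]
  Q <- Q[, seq_len(n_lv), drop = FALSE]
  # regression coefficients on the (centred) original X scale
  B <- W %*% solve(crossprod(P, W), t(Q))
  list(W = W, P = P, Q = Q, scores = TT[, seq_len(n_lv), drop = FALSE],
       B = B, n_lv = n_lv)
}

fit_plsda <- function(X, labels, n_lv) {
  labels <- droplevels(as.factor(labels))
  lev <- levels(labels)
  Y <- outer(as.character(labels), lev, `==`) * 1
  colnames(Y) <- lev
  ym <- colMeans(Y)
  fit <- pls2_nipals(X, sweep(Y, 2, ym), n_lv)
  fit$y_means <- ym
  fit$levels <- lev
  fit
}

predict_plsda <- function(fit, X_centred) {
  Yhat <- sweep(as.matrix(X_centred) %*% fit$B, 2, fit$y_means, `+`)
  factor(fit$levels[max.col(Yhat, ties.method = "first")],
         levels = fit$levels)
}
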