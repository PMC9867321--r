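# K-nearest-neighbour classifier with a distance-ordered tie-break: when the
# majority vote among the k nearest training points ties, the class of the
# single nearest neighbour wins. Euclidean distances; neighbour ties at equal
# distance resolve by training order (stable sort).

fit_knn <- function(X, labels, k) {
  labels <- droplevels(as.factor(labels))
  if (k < 1 || k > nrow(X)) stop("invalid k for KNN", call. = FALSE)
  list(X = as.matrix(X), labels = labels, k = k, levels = levels(labels))
}

predict_knn <- function(fit, Xnew) {
  Xnew <- as.matrix(Xnew)
  tr <- fit$X
  # squared Euclidean distance matrix: new x train
  d2 <- outer(rowSums(Xnew^2), rep(1, nrow(tr))) +
    outer(rep(1, nrow(Xnew)), rowSums(tr^2)) - 2 * tcrossprod(Xnew, tr)
  out <- character(nrow(Xnew))
  for (i in seq_len(nrow(Xnew))) {
    ord <- order(d2[i, ])[seq_len(fit$k)]
    votes <- table(fit$labels[ord])
    top <- names(votes)[votes == max(votes)]
    out[i] <- if (length(top) == 1L) top
              else as.character(fit$labels[ord[1L]])
  }
  factor(out, levels = fit$levels)
}
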