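# independent stump oracle: literal enumeration of every (feature, midpoint)
# split, scoring the weighted squared error directly
stump_oracle_sse <- function(X, y, w) {
  best <- sum(w * (y - sum(w * y) / sum(w))^2)  # constant stump
  for (j in seq_len(ncol(X))) {
    xs <- sort(unique(X[, j]))
    if (length(xs) < 2) next
    for (k in seq_len(length(xs) - 1)) {
      thr <- (xs[k] + xs[k + 1]) / 2
      left <- X[, j] <= thr
      yl <- sum(w[left] * y[left]) / sum(w[left])
      yr <- sum(w[!left] * y[!left]) / sum(w[!left])
      f <- ifelse(left, yl, yr)
      best <- min(best, sum(w * (y - f)^2))
    }
  }
  best
}

stump_sse <- function(st, X, y, w) {
  f <- ifelse(X[, st$feature] <= st$threshold, st$left, st$right)
  sum(w * (y - f)^2)
}
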