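# Independent brute-force oracles used by several test files.

# enumerate every maximal same-direction run meeting the cutoff and length
# rules; independent of the rle-based implementation in the package
bump_oracle <- function(coef, clusters, cutoff = 1, min_cpgs = 2) {
  n <- length(coef)
  qualifies <- function(s, e, sign) {
    all(clusters[s:e] == clusters[s]) &&
      all(!is.na(coef[s:e])) &&
      (if (sign > 0) all(coef[s:e] >= cutoff) else all(coef[s:e] <= -cutoff))
  }
  out <- list()
  for (sign in c(1, -1)) {
    for (s in 1:n) for (e in s:n) {
      if (e - s + 1 < min_cpgs) next
      if (!qualifies(s, e, sign)) next
      left_ext <- s > 1 && qualifies(s - 1, e, sign)
      right_ext <- e < n && qualifies(s, e + 1, sign)
      if (!left_ext && !right_ext)
        out[[length(out) + 1]] <- data.frame(
          index_start = s, index_end = e,
          direction = if (sign > 0) "hyper" else "hypo",
          value = mean(coef[s:e]), area = sum(abs(coef[s:e])))
    }
  }
  if (length(out) == 0)
    return(data.frame(index_start = integer(0), index_end = integer(0),
                      direction = character(0), value = numeric(0),
                      area = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$index_start), , drop = FALSE]
}

# exhaustive hypergeometric tail: enumerate every draw of n from N
hyper_oracle <- function(k, n, K, N) {
  draws <- combn(N, n)
  mean(apply(draws, 2, function(d) sum(d <= K) >= k))
}
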