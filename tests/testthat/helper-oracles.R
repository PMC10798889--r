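# Independent brute-force oracles. These deliberately avoid the package's
# code paths: library implementations (kruskal.test, p.adjust) or direct
# enumeration, used to freeze expected values and for the oracle-equivalence
# acceptance criterion.

oracle_kruskal <- function(values, groups) {
  kt <- stats::kruskal.test(values, factor(groups))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

oracle_silhouette <- function(labels, D) {
  D <- as.matrix(D)
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- setdiff(which(labels == labels[i]), i)
    if (!length(same)) {
      s[i] <- 0
      next
    }
    a <- mean(D[i, same])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(D[i, labels == cl]))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# P(X >= k) for X ~ Hypergeometric(white = m, black = n, drawn = kk),
# by direct summation of the pmf.
oracle_hyper_tail <- function(k, m, n, kk) {
  i <- max(k, max(0, kk - n)):min(m, kk)
  sum(choose(m, i) * choose(n, kk - i)) / choose(m + n, kk)
}

oracle_bh <- function(p) stats::p.adjust(p, method = "BH")

all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_permutations(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# Best percent overlap over every one-to-one matching of cluster labels.
oracle_overlap <- function(a, b) {
  ct <- unclass(table(a, b))
  if (nrow(ct) > ncol(ct)) ct <- t(ct)
  n_big <- ncol(ct)
  best <- 0
  for (perm in all_permutations(seq_len(n_big))) {
    sel <- perm[seq_len(nrow(ct))]
    best <- max(best, sum(ct[cbind(seq_len(nrow(ct)), sel)]))
  }
  100 * best / sum(ct)
}

oracle_ari <- function(a, b) {
  # pair-counting definition, computed literally over all object pairs
  n <- length(a)
  both <- neither <- only_a <- only_b <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) both <- both + 1
      else if (sa) only_a <- only_a + 1
      else if (sb) only_b <- only_b + 1
      else neither <- neither + 1
    }
  }
  total <- choose(n, 2)
  expected <- (both + only_a) * (both + only_b) / total
  maxi <- ((both + only_a) + (both + only_b)) / 2
  if (maxi == expected) return(1)
  (both - expected) / (maxi - expected)
}
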