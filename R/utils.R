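#' @useDynLib csfsubtypes, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All stochastic operations in the package go through
# this so that pipelines are reproducible without clobbering the user session.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a stream-specific 32-bit seed from a master seed, so that independent
# stages (signatures vs. cohort draws vs. NMF runs) use decorrelated streams.
derive_seed <- function(seed, salt) {
  as.integer((as.double(seed) * 48271 + salt * 9973) %% 2147483629) + 1L
}

geometric_mean <- function(x) exp(mean(log(x)))

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects:
#' 1 for identical partitions (up to relabeling), approximately 0 for
#' independent ones.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A single numeric value in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  ct <- table(a, b)
  n <- sum(ct)
  sum_ij <- sum(choose(ct, 2))
  sum_i <- sum(choose(rowSums(ct), 2))
  sum_j <- sum(choose(colSums(ct), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  denom <- (sum_i + sum_j) / 2 - expected
  if (denom == 0) return(1)  # both partitions trivial and identical in structure
  (sum_ij - expected) / denom
}

# Exact minimum-cost assignment (Hungarian algorithm with potentials, O(n^3)).
# `cost` must have nrow(cost) <= ncol(cost); returns for each row the matched
# column index. Community/cluster counts in this package are small, so an R
# implementation is plenty fast.
hungarian_min <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  stopifnot(n <= m, all(is.finite(cost)))
  u <- numeric(n + 1)
  v <- numeric(m + 1)
  p <- integer(m + 1)    # p[j + 1]: row matched to column j (0 = free)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j + 1] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  match <- integer(n)
  for (j in seq_len(m)) {
    if (p[j + 1] > 0L) match[p[j + 1]] <- j
  }
  match
}

# Maximum-weight one-to-one matching over a (possibly rectangular) weight
# matrix; returns row -> column indices (0 for unmatched rows when
# nrow > ncol).
assignment_max <- function(weights) {
  n <- nrow(weights)
  m <- ncol(weights)
  k <- max(n, m)
  cost <- matrix(0, k, k)
  cost[seq_len(n), seq_len(m)] <- -weights
  match <- hungarian_min(cost)
  out <- match[seq_len(n)]
  out[out > m] <- 0L
  out
}
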