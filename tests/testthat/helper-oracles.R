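# Independent brute-force oracles used across the suite.

# all-pairs shortest paths by exhaustive simple-path enumeration (<= 8 nodes)
brute_shortest_paths <- function(len) {
  n <- nrow(len)
  d <- matrix(Inf, n, n); diag(d) <- 0
  paths <- function(from, to, visited, acc) {
    if (from == to) return(acc)
    best <- Inf
    for (nxt in seq_len(n)) {
      if (visited[nxt] || !is.finite(len[from, nxt])) next
      v <- visited; v[nxt] <- TRUE
      best <- min(best, paths(nxt, to, v, acc + len[from, nxt]))
    }
    best
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    vis <- rep(FALSE, n); vis[i] <- TRUE
    d[i, j] <- paths(i, j, vis, 0)
  }
  d
}

# global efficiency by exhaustive path enumeration
brute_global_efficiency <- function(w) {
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf); diag(len) <- 0
  d <- brute_shortest_paths(len)
  inv <- 1 / d; diag(inv) <- 0; inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

# local efficiency by exhaustive enumeration within each neighborhood
brute_local_efficiency <- function(w) {
  n <- nrow(w)
  out <- numeric(n)
  for (u in seq_len(n)) {
    nb <- which(w[u, ] > 0)
    k <- length(nb)
    if (k < 2) next
    sub <- w[nb, nb, drop = FALSE]
    len <- ifelse(sub > 0, 1 / sub, Inf); diag(len) <- 0
    d <- brute_shortest_paths(len)
    acc <- 0
    for (a in seq_len(k)) for (b in seq_len(k))
      if (a != b && is.finite(d[a, b]) && d[a, b] > 0)
        acc <- acc + (w[u, nb[a]] * w[u, nb[b]] / d[a, b])^(1 / 3)
    out[u] <- acc / (k * (k - 1))
  }
  out
}

# naive per-term Bernoulli log-likelihood
naive_loglik <- function(omega, X, y) {
  eta <- as.numeric(X %*% omega)
  sum(y * eta - log(1 + exp(eta)))
}

# trinomial tail by full enumeration (N <= 12)
brute_tokeshi_pc <- function(N, h, n_l, n_r) {
  total <- 0
  for (i in 0:N) for (j in 0:(N - i)) {
    if (i >= n_l && j >= n_r)
      total <- total + stats::dmultinom(c(i, j, N - i - j),
                                        prob = c(h, h, 1 - 2 * h))
  }
  total
}

# small all-analysis-electrode session on a toy 4-electrode layout
tiny_layout <- function(n = 4) {
  mea_layout(paste0("e", seq_len(n)),
             cbind(seq_len(n) * 100, rep(0, n)))
}
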