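#' Cross-correlation functional connectivity matrix
#'
#' Bins each analysis electrode's spikes (default 10 ms in vitro, 1 ms in
#' silico) and computes zero-lag Pearson correlation between binned count
#' sequences. Negative correlations are clipped to 0, the diagonal is zeroed,
#' and weights below the configured floor (default 0.005) are set to 0.
#' Electrodes with constant (zero-variance) count sequences get zero
#' rows/columns with a warning.
#'
#' @param session a [recording_session()].
#' @param bin_ms correlation bin width in milliseconds.
#' @param weight_floor weights below this are zeroed (default 0.005).
#' @param max_lag_bins optional lag window; when > 0 the weight is the
#'   maximum correlation over lags \code{-L..L} (off by default).
#' @return symmetric matrix in [0, 1] over analysis electrodes with zero
#'   diagonal, class \code{"connectivity_matrix"}, attribute
#'   \code{bin_width_ms}.
#' @export
connectivity_matrix <- function(session, bin_ms = 10, weight_floor = 0.005,
                                max_lag_bins = 0) {
  trains <- session_trains(session)
  if (length(trains) < 2) stop("need at least 2 analysis electrodes")
  w <- bin_ms / 1000
  nb <- floor(session$duration / w)
  counts <- vapply(trains, function(st)
    tabulate(pmin(floor(st / w) + 1L, nb + 1L), nbins = nb + 1L)[seq_len(nb)],
    integer(nb))
  vars <- apply(counts, 2, var)
  if (any(vars == 0))
    warning("constant spike-count train(s): ",
            paste(colnames(counts)[vars == 0], collapse = ", "),
            "; rows/columns set to 0")
  n <- ncol(counts)
  m <- matrix(0, n, n, dimnames = list(names(trains), names(trains)))
  ok <- which(vars > 0)
  if (length(ok) >= 2) {
    if (max_lag_bins == 0) {
      cc <- suppressWarnings(cor(counts[, ok, drop = FALSE]))
      m[ok, ok] <- cc
    } else {
      for (a in ok) for (b in ok[ok > a]) {
        best <- -Inf
        for (l in -max_lag_bins:max_lag_bins) {
          xa <- counts[max(1, 1 - l):min(nb, nb - l), a]
          xb <- counts[max(1, 1 + l):min(nb, nb + l), b]
          r <- suppressWarnings(cor(xa, xb))
          if (is.finite(r) && r > best) best <- r
        }
        m[a, b] <- best; m[b, a] <- best
      }
    }
  }
  m[!is.finite(m)] <- 0
  m[m < 0] <- 0
  m[m < weight_floor] <- 0
  m[m > 1] <- 1
  diag(m) <- 0
  structure(m, bin_width_ms = bin_ms, class = c("connectivity_matrix",
                                                "matrix", "array"))
}

# weighted shortest-path distance matrix; lengths are 1/weight
.sp_dist <- function(w) {
  n <- nrow(w)
  if (n == 0) return(matrix(numeric(0), 0, 0))
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) > 0)
    igraph::E(g)$weight <- 1 / igraph::E(g)$weight
  igraph::distances(g)
}

#' Global efficiency of a weighted graph
#'
#' Mean inverse shortest-path length over all ordered node pairs, with edge
#' lengths taken as the inverse of connection weights. Disconnected pairs
#' contribute 0; an empty graph has efficiency 0. Equals 1 for a complete
#' graph of unit weights.
#'
#' @param w symmetric non-negative weight matrix, zero diagonal.
#' @return scalar in [0, 1].
#' @export
global_efficiency <- function(w) {
  w <- unclass(as.matrix(w))
  n <- nrow(w)
  if (n < 2) return(0)
  d <- .sp_dist(w)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Weighted local efficiency per node
#'
#' For each node u with neighbors N(u), the local efficiency is
#' \deqn{E_{loc}(u) = \frac{1}{k_u (k_u - 1)} \sum_{j \ne k \in N(u)}
#'   \left(w_{uj} w_{uk} / d_{jk}(N_u)\right)^{1/3}}
#' where \eqn{d_{jk}(N_u)} is the shortest-path length between j and k within
#' the subgraph induced by N(u) (edge lengths 1/weight) — the cube-root
#' weighted form of the standard brain-connectivity-toolbox formulation.
#' Nodes with fewer than two neighbors have local efficiency 0. Equals 1 at
#' every node of a complete unit-weight graph.
#'
#' @param w symmetric non-negative weight matrix in [0, 1], zero diagonal.
#' @return named numeric vector of per-node efficiencies in [0, 1].
#' @export
local_efficiency <- function(w) {
  w <- unclass(as.matrix(w))
  n <- nrow(w)
  out <- setNames(numeric(n), rownames(w))
  for (u in seq_len(n)) {
    nb <- which(w[u, ] > 0)
    k <- length(nb)
    if (k < 2) next
    d <- .sp_dist(w[nb, nb, drop = FALSE])
    acc <- 0
    for (a in seq_len(k)) for (b in seq_len(k)) {
      if (a == b || !is.finite(d[a, b]) || d[a, b] == 0) next
      acc <- acc + (w[u, nb[a]] * w[u, nb[b]] / d[a, b])^(1 / 3)
    }
    out[u] <- acc / (k * (k - 1))
  }
  out
}
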