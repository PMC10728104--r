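#' Encode binary burstlet trains as a marked point-process sequence
#'
#' Drops electrodes with fewer than \code{min_burstlets} active bins (default
#' 30), then maps every time bin to its ensemble state: the set of electrodes
#' bursting in that bin, with the empty set as the zero state. States are
#' held sparsely (only observed patterns are materialized), so the full
#' \code{2^C} table is never built.
#'
#' @param trains 0/1 matrix (electrodes x bins), rows named.
#' @param min_burstlets activity threshold per electrode.
#' @return object of class \code{"mark_sequence"}: list with
#'   \code{electrodes}, \code{T}, \code{pattern} (character per bin, comma
#'   separated electrode indices, \code{""} for the zero state),
#'   \code{counts} (named table of observed non-zero patterns),
#'   \code{order} (named integer, pattern sizes), \code{q} (per-electrode
#'   marginal burst probability).
#' @export
encode_marks <- function(trains, min_burstlets = 30) {
  if (is.null(rownames(trains)))
    rownames(trains) <- paste0("e", seq_len(nrow(trains)))
  keep <- rowSums(trains) >= min_burstlets
  trains <- trains[keep, , drop = FALSE]
  C <- nrow(trains); T <- ncol(trains)
  pattern <- apply(trains, 2, function(col)
    paste(which(col == 1), collapse = ","))
  nz <- pattern[pattern != ""]
  counts <- if (length(nz)) table(nz) else table(character(0))
  ord <- vapply(names(counts), function(p)
    length(strsplit(p, ",")[[1]]), integer(1))
  structure(list(electrodes = rownames(trains), T = T, pattern = pattern,
                 counts = counts, order = ord,
                 q = rowSums(trains) / T),
            class = "mark_sequence")
}

# elementary symmetric polynomial e_r of a vector, by the standard recurrence
.esp <- function(x, r) {
  e <- c(1, rep(0, r))
  for (v in x)
    for (k in min(r, length(e) - 1):1)
      e[k + 1] <- e[k + 1] + v * e[k]
  e[r + 1]
}

#' Fit the marked point-process model, optionally with one order constrained
#'
#' The full model is the saturated categorical maximum likelihood: each
#' state's probability equals its empirical frequency. The reduced model for
#' order r fixes the rate parameters of every r-order mark at the value
#' expected under independent electrodes (log-odds sum of the per-electrode
#' marginals) and re-maximizes the remaining rates in closed form. The sum
#' over all \code{choose(C, r)} fixed marks enters only through an elementary
#' symmetric polynomial of the marginal odds, so no exponential table is
#' needed.
#'
#' @param marks a [encode_marks()] result.
#' @param constrained_order \code{NULL} for the unconstrained (full) model,
#'   or the order r whose marks are fixed at independence.
#' @return list with \code{loglik} and, for the full model, \code{prob}
#'   (named empirical state probabilities; the zero state is named
#'   \code{"(zero)"}).
#' @export
fit_mkpp <- function(marks, constrained_order = NULL) {
  T <- marks$T
  k <- as.numeric(marks$counts)          # observed non-zero pattern counts
  names(k) <- names(marks$counts)
  k0 <- T - sum(k)                       # zero-state count
  if (is.null(constrained_order)) {
    ll <- sum(k * log(k / T)) + (if (k0 > 0) k0 * log(k0 / T) else 0)
    prob <- c(k / T, setNames(k0 / T, "(zero)"))
    return(list(loglik = ll, prob = prob))
  }
  r <- constrained_order
  C <- length(marks$electrodes)
  if (r > C) stop("order r exceeds the number of active electrodes")
  q <- pmin(pmax(marks$q, 1e-12), 1 - 1e-12)
  odds <- q / (1 - q)
  S_F <- .esp(odds, r)                   # sum of e^mu over all r-order marks
  fixed <- marks$order == r
  k_fix <- k[fixed]
  # independence-expected rate parameter of an observed r-order pattern
  f_fix <- vapply(names(k_fix), function(p) {
    idx <- as.integer(strsplit(p, ",")[[1]])
    sum(log(odds[idx]))
  }, numeric(1))
  k_free <- k[!fixed]
  D_free <- sum(k_free) / T
  if (D_free >= 1 - 1e-12) D_free <- 1 - 1e-12
  Z <- (1 + S_F) / (1 - D_free)
  ll <- sum(k_fix * f_fix) - T * log(Z)
  if (length(k_free))
    ll <- ll + sum(k_free * log(k_free * Z / T))
  list(loglik = ll)
}

#' Test for excess r-wise simultaneous bursting
#'
#' Compares the saturated mark model with the reduced model whose r-order
#' rates are fixed at independence, via the deviance difference
#' \code{D = 2 [L(full) - L(reduced)]}. Detection is one-sided: if the
#' observed count of r-order bins does not exceed its independence
#' expectation the p-value is 1; otherwise the p-value comes from a
#' parametric Monte Carlo null (independent Bernoulli trains with the
#' plug-in marginal burst probabilities).
#'
#' @param marks a [encode_marks()] result.
#' @param r synchrony order (2 <= r <= number of active electrodes).
#' @param n_null Monte Carlo null simulations (default 200).
#' @return list with \code{D}, \code{p}, \code{observed} (r-order bin
#'   count), \code{expected} (independence expectation).
#' @export
test_order <- function(marks, r, n_null = 200) {
  C <- length(marks$electrodes)
  if (r > C) stop("order r exceeds the number of active electrodes")
  if (r < 2) stop("order r must be at least 2")
  D <- 2 * (fit_mkpp(marks)$loglik - fit_mkpp(marks, r)$loglik)
  D <- max(0, D)
  q <- marks$q
  # Poisson-binomial pmf at r: probability that exactly r electrodes burst
  pmf <- 1
  for (qq in q) pmf <- c(pmf * (1 - qq), 0) + c(0, pmf * qq)
  p_r <- pmf[r + 1]
  observed <- sum(as.numeric(marks$counts)[marks$order == r])
  expected <- marks$T * p_r
  if (observed <= expected)
    return(list(D = D, p = 1, observed = observed, expected = expected))
  Dnull <- numeric(n_null)
  for (b in seq_len(n_null)) {
    sim <- matrix(rbinom(C * marks$T, 1, rep(q, marks$T)), nrow = C)
    rownames(sim) <- marks$electrodes
    msim <- encode_marks(sim, min_burstlets = 0)
    # guard against electrodes dropping out of the simulated encoding
    msim$q <- rowSums(sim) / marks$T
    Dnull[b] <- max(0, 2 * (fit_mkpp(msim)$loglik -
                              fit_mkpp(msim, r)$loglik))
  }
  p <- (1 + sum(Dnull >= D)) / (n_null + 1)
  list(D = D, p = p, observed = observed, expected = expected)
}

#' Catalog higher-order synchrony across all orders
#'
#' Runs [test_order()] for r = 2..C, adjusts p-values across orders with
#' Benjamini-Hochberg at \code{alpha}, and, for each significant order,
#' extracts detected groups: the r-order patterns whose empirical count
#' exceeds their independence expectation.
#'
#' @param trains 0/1 matrix (electrodes x bins), rows named with electrode
#'   ids.
#' @param layout optional [mea_layout()] providing electrode positions for
#'   the groups.
#' @param config a [pipeline_config()].
#' @return object of class \code{"synchrony_catalog"}: list with
#'   \code{orders} (data.frame r, D, p, p_adj, significant, observed,
#'   expected), \code{groups} (list of electrode-id sets with \code{order}
#'   and \code{order_class}), \code{marks}.
#' @export
synchrony_catalog <- function(trains, layout = NULL,
                              config = pipeline_config()) {
  marks <- encode_marks(trains, config$sync_min_burstlets)
  C <- length(marks$electrodes)
  if (C < 2) stop("fewer than 2 electrodes pass the activity threshold")
  res <- lapply(2:C, function(r) {
    tst <- test_order(marks, r, n_null = config$sync_n_null)
    data.frame(r = r, D = tst$D, p = tst$p, observed = tst$observed,
               expected = tst$expected)
  })
  orders <- do.call(rbind, res)
  orders$p_adj <- p.adjust(orders$p, method = "BH")
  orders$significant <- orders$p_adj <= config$sync_alpha
  groups <- list()
  q <- marks$q
  for (r in orders$r[orders$significant]) {
    pats <- names(marks$counts)[marks$order == r]
    for (p in pats) {
      idx <- as.integer(strsplit(p, ",")[[1]])
      expect <- marks$T * prod(q[idx]) * prod(1 - q[-idx])
      if (as.numeric(marks$counts[p]) > expect) {
        ids <- marks$electrodes[idx]
        groups[[length(groups) + 1]] <-
          list(electrodes = ids, order = r,
               order_class = order_class(r),
               positions = if (!is.null(layout))
                 layout$positions[ids, , drop = FALSE] else NULL)
      }
    }
  }
  structure(list(orders = orders, groups = groups, marks = marks),
            class = "synchrony_catalog")
}

#' Order-of-synchrony class
#'
#' Classes: low (2-8), intermediate (9-15), high (16+).
#'
#' @param r integer order(s).
#' @return character vector of class labels.
#' @export
order_class <- function(r) {
  ifelse(r <= 8, "low", ifelse(r <= 15, "intermediate", "high"))
}

#' Spatial dispersion of synchronous groups
#'
#' For every detected group, subtracts the group centroid (arithmetic mean of
#' member electrode positions) and pools the relative positions by order
#' class. Radial distances to the centroid are included for two-sample KS
#' comparison between classes or timepoints.
#'
#' @param catalog a [synchrony_catalog()] built with a layout.
#' @param layout an [mea_layout()] (used when the catalog lacks positions).
#' @return data.frame with \code{order_class}, \code{dx}, \code{dy} (um) and
#'   \code{radius}.
#' @export
dispersion <- function(catalog, layout = NULL) {
  rows <- list()
  for (g in catalog$groups) {
    pos <- g$positions
    if (is.null(pos)) {
      if (is.null(layout)) stop("electrode positions unavailable")
      pos <- layout$positions[g$electrodes, , drop = FALSE]
    }
    ctr <- colMeans(pos)
    rel <- sweep(pos, 2, ctr)
    rows[[length(rows) + 1]] <-
      data.frame(order_class = g$order_class, dx = rel[, 1], dy = rel[, 2],
                 radius = sqrt(rowSums(rel^2)))
  }
  if (!length(rows))
    return(data.frame(order_class = character(0), dx = numeric(0),
                      dy = numeric(0), radius = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
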