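#' Tokeshi's test of bimodality
#'
#' Classifies a binned frequency distribution (here, counts of detected
#' synchrony orders per class) as Uniform, Unimodal, Bimodal, Strongly or
#' Weakly bimodal. Two candidate modes are picked: the peak among the
#' lower-order classes (\code{m_l}) and the peak among the higher-order
#' classes (\code{m_r}), with frequencies \code{n_l}, \code{n_r}. Under the
#' null hypothesis that each of the N samples falls in any of the 1/h classes
#' with equal probability h, three tail probabilities are computed: the joint
#' probability \code{P_c} of obtaining at least \code{n_l} and at least
#' \code{n_r} in the two candidate classes (trinomial double tail), and the
#' marginal binomial tails \code{P_l}, \code{P_r}. The auxiliary quantity
#' \code{rho(t) = (1 - max(P_l, P_r))^t} judges whether the weaker peak is
#' locally significant: t is the number of consecutive classes adjacent to
#' the weaker mode with frequencies lower than that mode's, and the peak is
#' locally significant when \code{rho(t) < 0.1}.
#'
#' Classification (first matching row):
#' \itemize{
#'   \item Uniform: \code{P_c >= 0.05}
#'   \item Unimodal: \code{P_l < 0.05, P_r >= 0.9} or \code{P_l >= 0.9,
#'     P_r < 0.05}
#'   \item Strongly bimodal: \code{P_l < 0.05, P_r < 0.05}
#'   \item Bimodal: \code{P_l < 0.25, P_r < 0.25}
#'   \item Weakly bimodal: \code{P_l < 0.5, P_r < 0.5}; or one-sided
#'     (\code{P_l >= 0.5, P_r < 0.05} or \code{P_l < 0.05, P_r >= 0.5}) with
#'     \code{rho(t) < 0.1}
#'   \item otherwise Unimodal (a single departure from uniformity without a
#'     second local peak)
#' }
#'
#' @param frequencies integer counts per synchrony-order class, in class
#'   order.
#' @param bin_width number of consecutive classes merged before testing
#'   (default 3); class counts already binned can pass \code{bin_width = 1}.
#' @return object of class \code{"tokeshi_result"}: list with
#'   \code{binned}, \code{N}, \code{h}, \code{m_l}, \code{m_r}, \code{n_l},
#'   \code{n_r}, \code{P_c}, \code{P_l}, \code{P_r}, \code{rho}, \code{t},
#'   \code{classification}.
#' @export
tokeshi_test <- function(frequencies, bin_width = 1) {
  frequencies <- as.numeric(frequencies)
  if (bin_width > 1) {
    grp <- ceiling(seq_along(frequencies) / bin_width)
    frequencies <- as.numeric(tapply(frequencies, grp, sum))
  }
  k <- length(frequencies)
  if (k < 3) stop("need at least 3 classes after binning")
  N <- sum(frequencies)
  if (N == 0) stop("empty frequency distribution")
  h <- 1 / k
  lower <- seq_len(floor(k / 2))
  upper <- setdiff(seq_len(k), lower)
  m_l <- lower[which.max(frequencies[lower])]
  m_r <- upper[which.max(frequencies[upper])]
  n_l <- frequencies[m_l]; n_r <- frequencies[m_r]
  P_c <- tokeshi_pc(N, h, n_l, n_r)
  P_l <- pbinom(n_l - 1, N, h, lower.tail = FALSE)
  P_r <- pbinom(n_r - 1, N, h, lower.tail = FALSE)
  # local-significance of the weaker peak
  weak <- if (P_l >= P_r) m_l else m_r
  n_weak <- frequencies[weak]
  runlen <- function(idx_seq) {
    t <- 0
    for (i in idx_seq) {
      if (i < 1 || i > k) break
      if (frequencies[i] < n_weak) t <- t + 1 else break
    }
    t
  }
  t_adj <- max(runlen(seq(weak - 1, 1)), runlen(seq(weak + 1, k)))
  rho <- if (t_adj > 0) (1 - max(P_l, P_r))^t_adj else NA_real_
  cls <- classify_tokeshi(P_c, P_l, P_r,
                          rho_significant = is.finite(rho) && rho < 0.1)
  structure(list(binned = frequencies, N = N, h = h, m_l = m_l, m_r = m_r,
                 n_l = n_l, n_r = n_r, P_c = P_c, P_l = P_l, P_r = P_r,
                 rho = rho, t = t_adj, classification = cls),
            class = "tokeshi_result")
}

#' Joint trinomial tail probability of the two candidate modes
#'
#' Probability, under uniform assignment of N samples to 1/h classes, of the
#' two candidate classes receiving at least \code{n_l} and \code{n_r}
#' samples: the double sum of trinomial probabilities over
#' \code{i >= n_l, j >= n_r, i + j <= N}.
#'
#' @param N total samples; \code{h} class probability; \code{n_l}, \code{n_r}
#'   observed candidate-mode frequencies.
#' @return probability in [0, 1].
#' @export
tokeshi_pc <- function(N, h, n_l, n_r) {
  if (n_l + n_r > N) return(0)
  total <- 0
  for (i in n_l:N) {
    jmax <- N - i
    if (jmax < n_r) next
    for (j in n_r:jmax) {
      rest <- N - i - j
      logterm <- lgamma(N + 1) - lgamma(i + 1) - lgamma(j + 1) -
        lgamma(rest + 1) + (i + j) * log(h)
      if (rest > 0) {
        if (1 - 2 * h <= 0) next
        logterm <- logterm + rest * log1p(-2 * h)
      }
      total <- total + exp(logterm)
    }
  }
  min(1, total)
}

#' Classify a distribution from the Tokeshi probabilities
#'
#' Applies the classification table row by row (first match).
#'
#' @param P_c,P_l,P_r tail probabilities from [tokeshi_test()].
#' @param rho_significant logical: is the weaker peak locally significant
#'   (\code{rho(t) < 0.1})?
#' @return one of \code{"Uniform"}, \code{"Unimodal"},
#'   \code{"Strongly bimodal"}, \code{"Bimodal"}, \code{"Weakly bimodal"}.
#' @export
classify_tokeshi <- function(P_c, P_l, P_r, rho_significant = FALSE) {
  if (P_c >= 0.05) return("Uniform")
  if ((P_l < 0.05 && P_r >= 0.9) || (P_l >= 0.9 && P_r < 0.05))
    return("Unimodal")
  if (P_l < 0.05 && P_r < 0.05) return("Strongly bimodal")
  if (P_l < 0.25 && P_r < 0.25) return("Bimodal")
  if (P_l < 0.5 && P_r < 0.5) return("Weakly bimodal")
  if (((P_l >= 0.5 && P_r < 0.05) || (P_l < 0.05 && P_r >= 0.5)) &&
      rho_significant)
    return("Weakly bimodal")
  "Unimodal"
}

#' @export
print.tokeshi_result <- function(x, ...) {
  cat(sprintf(
    "Tokeshi test: %s (P_c = %.4g, P_l = %.4g, P_r = %.4g)\n",
    x$classification, x$P_c, x$P_l, x$P_r))
  invisible(x)
}
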