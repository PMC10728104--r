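#' Build the history design matrix for point-process GC
#'
#' For binary burstlet trains of C electrodes over T bins and a history depth
#' of M bins, the covariate vector at bin t (t = M+1..T) is
#' \code{[1, n_{t-1}^{(1)}, ..., n_{t-M}^{(1)}, n_{t-1}^{(2)}, ...]}: a
#' baseline column followed by one M-column block per electrode, most recent
#' lag first.
#'
#' @param trains integer 0/1 matrix (electrodes x bins), rows named.
#' @param M history depth in bins.
#' @return list with \code{X} ((T-M) x (1 + C M) design), \code{response}
#'   function mapping an electrode index to its response vector, and
#'   \code{block} function mapping an electrode index to its column indices.
#' @export
gc_design <- function(trains, M) {
  C <- nrow(trains); T <- ncol(trains)
  if (T <= M) stop("trains must be longer than the history depth M")
  nr <- T - M
  X <- matrix(0, nr, 1 + C * M)
  X[, 1] <- 1
  for (c in seq_len(C)) for (lag in seq_len(M))
    X[, 1 + (c - 1) * M + lag] <- trains[c, (M + 1 - lag):(T - lag)]
  cn <- c("baseline",
          as.vector(t(outer(seq_len(C), seq_len(M),
                            function(c, l) paste0("e", c, ".lag", l)))))
  colnames(X) <- cn
  list(X = X,
       M = M, C = C,
       response = function(c) as.numeric(trains[c, (M + 1):T]),
       block = function(c) 1 + (c - 1) * M + seq_len(M))
}

#' Bernoulli log-likelihood of a logistic point-process model
#'
#' \code{sum_t [ n_t eta_t - log(1 + exp(eta_t)) ]} with
#' \code{eta_t = omega' x_t}, computed overflow-safely.
#'
#' @param omega dense coefficient vector (length \code{ncol(X)}).
#' @param X design matrix.
#' @param y 0/1 response vector.
#' @return scalar log-likelihood.
#' @export
gc_loglik <- function(omega, X, y) cpp_loglik(X, y, omega)

# contiguous-block CV fold assignment for time-series structure
.cv_blocks <- function(n, k) rep(seq_len(k), each = ceiling(n / k))[seq_len(n)]

# OMP path + blocked CV choice of support size. `candidates` are the columns
# allowed to enter (besides the always-kept baseline).
.omp_cv_fit <- function(X, y, candidates, config) {
  max_add <- min(config$gc_max_support, length(candidates))
  folds <- .cv_blocks(length(y), config$gc_cv_folds)
  held <- matrix(NA_real_, config$gc_cv_folds, max_add + 1)
  for (f in seq_len(config$gc_cv_folds)) {
    tr <- folds != f
    if (sum(tr) < 2 || length(unique(y[tr])) < 1) next
    path <- cpp_omp_path(X[tr, , drop = FALSE], y[tr],
                         keep = 0L, candidates = candidates - 1L,
                         max_add = max_add, ridge = config$gc_ridge,
                         tol = config$gc_newton_tol,
                         maxit = config$gc_newton_maxit)
    for (s in 0:max_add)
      held[f, s + 1] <- cpp_loglik(X[!tr, , drop = FALSE], y[!tr],
                                   path$beta[[s + 1]])
  }
  mean_held <- colMeans(held, na.rm = TRUE)
  size <- which.max(mean_held) - 1L  # ties -> smaller via which.max order
  path <- cpp_omp_path(X, y, keep = 0L, candidates = candidates - 1L,
                       max_add = size, ridge = config$gc_ridge,
                       tol = config$gc_newton_tol,
                       maxit = config$gc_newton_maxit)
  list(omega = path$beta[[size + 1]],
       support = sort(path$support[[size + 1]] + 1L),
       size = size,
       loglik = path$loglik[[size + 1]])
}

#' Fit the full sparse point-process model for one target electrode
#'
#' Maximum-likelihood logistic GLM of the target's burstlet train on the
#' recent history of every electrode (self-history included), estimated by
#' generalized orthogonal matching pursuit. The baseline is always in the
#' support; the number of history covariates is chosen by blocked K-fold
#' cross-validation on held-out log-likelihood (ties resolved toward the
#' smaller support).
#'
#' @param design a [gc_design()].
#' @param target electrode (row) index of the target.
#' @param config a [pipeline_config()].
#' @return list (class \code{"pp_model"}) with \code{omega} (dense
#'   coefficients), \code{support} (1-based column indices), \code{size},
#'   \code{loglik}, \code{target}.
#' @export
gc_fit_full <- function(design, target, config = pipeline_config()) {
  y <- design$response(target)
  fit <- .omp_cv_fit(design$X, y, candidates = 2:ncol(design$X), config)
  structure(c(fit, list(target = target, excluded = NA_integer_)),
            class = "pp_model")
}

#' Fit the reduced model excluding one source electrode's history
#'
#' Same estimator as [gc_fit_full()] but with the source's history block
#' removed from the candidate covariates, at the support size selected for
#' the full model (capped by the number of remaining candidates).
#'
#' @param design a [gc_design()].
#' @param target target electrode index.
#' @param source excluded source electrode index.
#' @param size support size to use (typically the full model's).
#' @param config a [pipeline_config()].
#' @return a \code{"pp_model"} with \code{excluded = source}.
#' @export
gc_fit_reduced <- function(design, target, source, size,
                           config = pipeline_config()) {
  y <- design$response(target)
  candidates <- setdiff(2:ncol(design$X), design$block(source))
  size <- min(size, length(candidates))
  path <- cpp_omp_path(design$X, y, keep = 0L, candidates = candidates - 1L,
                       max_add = size, ridge = config$gc_ridge,
                       tol = config$gc_newton_tol,
                       maxit = config$gc_newton_maxit)
  structure(list(omega = path$beta[[size + 1]],
                 support = sort(path$support[[size + 1]] + 1L),
                 size = size, loglik = path$loglik[[size + 1]],
                 target = target, excluded = source),
            class = "pp_model")
}

#' Deviance difference between nested point-process fits
#'
#' \code{D = 2 [L(full) - L(reduced)]}. The reduced model must be nested in
#' the full model (same target, source excluded); if the greedy full fit ends
#' below the reduced fit's likelihood, the full model is re-refined from the
#' reduced support within the full design so the statistic is non-negative by
#' construction.
#'
#' @param full,reduced \code{"pp_model"} objects from [gc_fit_full()] /
#'   [gc_fit_reduced()].
#' @param design the [gc_design()] both fits used.
#' @param config a [pipeline_config()].
#' @return list with \code{D} and the (possibly re-refined) \code{full} fit.
#' @export
gc_deviance <- function(full, reduced, design, config = pipeline_config()) {
  if (full$target != reduced$target)
    stop("fits must share the target electrode")
  if (is.na(reduced$excluded))
    stop("reduced model must exclude a source (arguments swapped?)")
  if (full$loglik < reduced$loglik - 1e-9) {
    # nesting guard: the reduced support is feasible for the full model
    y <- design$response(full$target)
    refit <- cpp_newton_fit(design$X, y,
                            support0 = sort(unique(c(full$support,
                                                     reduced$support))) - 1L,
                            ridge = config$gc_ridge,
                            tol = config$gc_newton_tol,
                            maxit = config$gc_newton_maxit)
    if (refit$loglik > full$loglik) {
      omega <- numeric(ncol(design$X))
      sup <- sort(unique(c(full$support, reduced$support)))
      omega[sup] <- refit$beta
      full$omega <- omega; full$support <- sup
      full$loglik <- refit$loglik
    }
  }
  list(D = max(0, 2 * (full$loglik - reduced$loglik)), full = full)
}

#' Infer the directed GC network from binary burstlet trains
#'
#' For every ordered electrode pair (source, target), compares the full
#' point-process model of the target with the reduced model excluding the
#' source's history via the deviance difference, converts deviances to
#' p-values under a chi-square null with degrees of freedom equal to the
#' number of removed history covariates (M), and controls the false discovery
#' rate with Benjamini-Hochberg at \code{alpha} (default 0.01). Degenerate
#' (all-zero or all-one) trains are dropped with a warning; self-links are
#' never tested.
#'
#' @param trains 0/1 matrix (electrodes x bins), rows named.
#' @param config a [pipeline_config()].
#' @param alpha BH FDR level; defaults to \code{config$gc_fdr_level}.
#' @param null \code{"chisq"} (default) or \code{"bootstrap"} (parametric
#'   bootstrap from the fitted reduced model, for calibration checks).
#' @param n_boot bootstrap resamples when \code{null = "bootstrap"}.
#' @return object of class \code{"gc_network"}: list with \code{links}
#'   (data.frame source, target, D, p, significant), \code{n_links},
#'   \code{electrodes}, \code{alpha}.
#' @export
gc_infer_network <- function(trains, config = pipeline_config(),
                             alpha = NULL, null = c("chisq", "bootstrap"),
                             n_boot = 200) {
  null <- match.arg(null)
  if (is.null(alpha)) alpha <- config$gc_fdr_level
  if (is.null(rownames(trains)))
    rownames(trains) <- paste0("e", seq_len(nrow(trains)))
  sums <- rowSums(trains)
  degen <- sums == 0 | sums == ncol(trains)
  if (any(degen)) {
    warning("dropping degenerate trains: ",
            paste(rownames(trains)[degen], collapse = ", "))
    trains <- trains[!degen, , drop = FALSE]
  }
  ids <- rownames(trains)
  C <- nrow(trains)
  if (C < 2)
    return(structure(list(links = data.frame(source = character(0),
                                             target = character(0),
                                             D = numeric(0), p = numeric(0),
                                             significant = logical(0)),
                          n_links = 0L, electrodes = ids, alpha = alpha),
                     class = "gc_network"))
  M <- config$gc_history_bins
  design <- gc_design(trains, M)
  rows <- list()
  for (tg in seq_len(C)) {
    full <- gc_fit_full(design, tg, config)
    y <- design$response(tg)
    for (src in seq_len(C)) {
      if (src == tg) next
      red <- gc_fit_reduced(design, tg, src, full$size, config)
      dv <- gc_deviance(full, red, design, config)
      full <- dv$full
      D <- dv$D
      p <- if (null == "chisq") {
        pchisq(D, df = M, lower.tail = FALSE)
      } else {
        eta <- design$X %*% red$omega
        pr <- 1 / (1 + exp(-eta))
        Dstar <- replicate(n_boot, {
          ystar <- rbinom(length(pr), 1, pr)
          lf <- cpp_newton_fit(design$X, ystar, full$support - 1L,
                               config$gc_ridge, config$gc_newton_tol,
                               config$gc_newton_maxit)$loglik
          lr <- cpp_newton_fit(design$X, ystar, red$support - 1L,
                               config$gc_ridge, config$gc_newton_tol,
                               config$gc_newton_maxit)$loglik
          max(0, 2 * (lf - lr))
        })
        (1 + sum(Dstar >= D)) / (n_boot + 1)
      }
      rows[[length(rows) + 1]] <-
        data.frame(source = ids[src], target = ids[tg], D = D, p = p)
    }
  }
  links <- do.call(rbind, rows)
  links$significant <- p.adjust(links$p, method = "BH") <= alpha
  structure(list(links = links, n_links = sum(links$significant),
                 electrodes = ids, alpha = alpha),
            class = "gc_network")
}

#' @export
print.gc_network <- function(x, ...) {
  cat(sprintf("GC network: %d electrodes, %d significant links (FDR %.3g)\n",
              length(x$electrodes), x$n_links, x$alpha))
  invisible(x)
}
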