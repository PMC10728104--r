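test_that("mark encoding drops quiet electrodes and maps bins to patterns", {
  tr <- rbind(e1 = c(1, 1, 0), e2 = c(0, 1, 0))
  m <- encode_marks(tr, min_burstlets = 0)
  expect_equal(m$pattern, c("1", "1,2", ""))
  expect_equal(as.numeric(m$counts[c("1", "1,2")]), c(1, 1))
  expect_equal(m$order[["1,2"]], 2L)
  # all-zero trains: every bin is the zero state
  z <- matrix(0L, 3, 5, dimnames = list(paste0("e", 1:3), NULL))
  mz <- encode_marks(z, min_burstlets = 0)
  expect_true(all(mz$pattern == ""))
  # 29 burstlets is below the default activity threshold, 30 passes
  tr2 <- rbind(e1 = c(rep(1, 29), rep(0, 71)),
               e2 = c(rep(1, 30), rep(0, 70)))
  m2 <- encode_marks(tr2, min_burstlets = 30)
  expect_equal(m2$electrodes, "e2")
})

test_that("saturated mark model reproduces empirical frequencies", {
  # zero: 6, {1}: 2, {2}: 1, {1,2}: 1 over T = 10
  tr <- rbind(e1 = c(1, 1, 0, 1, rep(0, 6)),
              e2 = c(0, 0, 1, 1, rep(0, 6)))
  m <- encode_marks(tr, min_burstlets = 0)
  fit <- fit_mkpp(m)
  expect_equal(unname(fit$prob[c("1", "2", "1,2", "(zero)")]),
               c(0.2, 0.1, 0.1, 0.6))
  expect_equal(sum(fit$prob), 1)
  expect_equal(fit$loglik,
               6 * log(0.6) + 2 * log(0.2) + 2 * log(0.1))
})

test_that("constrained mark model matches a dense brute-force optimizer", {
  set.seed(41)
  C <- 4; T <- 80
  tr <- matrix(rbinom(C * T, 1, 0.3), C, T,
               dimnames = list(paste0("e", 1:C), NULL))
  m <- encode_marks(tr, min_burstlets = 0)
  r <- 2
  got <- fit_mkpp(m, r)$loglik
  # dense oracle: optimize free rate parameters over all 2^C - 1 marks with
  # the r-order marks fixed at the independence value
  pats <- unlist(lapply(1:C, function(k)
    utils::combn(C, k, paste, collapse = ",", simplify = FALSE)),
    recursive = FALSE)
  pats <- vapply(pats, identity, character(1))
  ord <- vapply(strsplit(pats, ","), length, integer(1))
  q <- pmin(pmax(rowSums(tr) / T, 1e-12), 1 - 1e-12)
  odds <- q / (1 - q)
  mu_fix <- vapply(strsplit(pats[ord == r], ","), function(ix)
    sum(log(odds[as.integer(ix)])), numeric(1))
  counts <- setNames(numeric(length(pats)), pats)
  obs <- table(m$pattern[m$pattern != ""])
  counts[names(obs)] <- as.numeric(obs)
  k0 <- T - sum(counts)
  negll <- function(mu_free) {
    mu <- numeric(length(pats))
    mu[ord == r] <- mu_fix
    mu[ord != r] <- mu_free
    -(sum(counts * mu) - T * log(1 + sum(exp(mu))))
  }
  opt <- optim(rep(0, sum(ord != r)), negll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(got, -opt$value, tolerance = 1e-4)
  # nesting: the saturated model is at least as likely for every r
  for (rr in 2:C)
    expect_gte(fit_mkpp(m)$loglik, fit_mkpp(m, rr)$loglik - 1e-8)
})

test_that("mark-model probabilities normalize for arbitrary rates", {
  set.seed(42)
  for (C in 2:4) {
    mu <- rnorm(2^C - 1, 0, 2)
    p <- exp(mu) / (1 + sum(exp(mu)))
    p0 <- 1 / (1 + sum(exp(mu)))
    expect_equal(sum(p) + p0, 1, tolerance = 1e-12)
  }
  # mu = 0 for all marks -> every state probability 1/2^C
  C <- 3
  p <- exp(rep(0, 2^C - 1)) / (1 + sum(exp(rep(0, 2^C - 1))))
  expect_equal(unique(round(c(p, 1 - sum(p)), 12)), round(1 / 2^C, 12))
})

test_that("order tests detect planted synchrony and stay calibrated under
           the null", {
  set.seed(43)
  # power: planted 4-wise synchrony at 0.02/bin, T = 2000
  hits <- 0
  for (i in 1:8) {
    ps <- planted_synchrony_marks(5, 4, 0.1, 0.02, 2000, seed = 100 + i)
    m <- encode_marks(ps$trains, min_burstlets = 0)
    tst <- test_order(m, 4, n_null = 79)
    if (tst$p < 0.05) hits <- hits + 1
  }
  expect_gt(hits / 8, 0.8)
  # empirical joint frequency exceeds the independence product
  ps <- planted_synchrony_marks(5, 4, 0.1, 0.02, 2000, seed = 300)
  m <- encode_marks(ps$trains, min_burstlets = 0)
  tst <- test_order(m, 4, n_null = 19)
  expect_gt(tst$observed, tst$expected)
  # null calibration: detection rate at r = 3 near the nominal level
  rej <- 0; n_runs <- 60
  for (i in seq_len(n_runs)) {
    nul <- matrix(rbinom(5 * 400, 1, 0.15), 5, 400,
                  dimnames = list(paste0("e", 1:5), NULL))
    mn <- encode_marks(nul, min_burstlets = 0)
    if (test_order(mn, 3, n_null = 59)$p < 0.05) rej <- rej + 1
  }
  expect_lte(rej / n_runs, 0.05 + 2 * sqrt(0.05 * 0.95 / n_runs))
  # r beyond the electrode count is an error
  expect_error(test_order(m, 9), "exceeds")
})

test_that("catalog extracts groups and dispersion geometry is exact", {
  set.seed(44)
  ps <- planted_synchrony_marks(5, 4, 0.08, 0.03, 1500, seed = 44)
  cfg <- pipeline_config(sync_min_burstlets = 0, sync_n_null = 79)
  lay <- mea_layout(paste0("e", 1:5),
                    cbind(c(0, 400, 0, 400, 800), c(0, 0, 400, 400, 800)))
  cat_ <- synchrony_catalog(ps$trains, layout = lay, config = cfg)
  expect_true(cat_$orders$significant[cat_$orders$r == 4])
  g4 <- Filter(function(g) g$order == 4, cat_$groups)
  expect_true(any(vapply(g4, function(g)
    setequal(g$electrodes, ps$members), logical(1))))
  expect_true(all(vapply(cat_$groups, function(g)
    length(g$electrodes) == g$order, logical(1))))
  # square of side 400: all radial distances 200 * sqrt(2)
  cat_$groups <- list(list(electrodes = paste0("e", 1:4), order = 4,
                           order_class = "low",
                           positions = lay$positions[1:4, ]))
  disp <- dispersion(cat_)
  expect_equal(disp$radius, rep(200 * sqrt(2), 4))
  expect_equal(mean(disp$dx), 0); expect_equal(mean(disp$dy), 0)
  # identical pooled distributions: KS p = 1
  expect_equal(suppressWarnings(
    ks.test(disp$radius, disp$radius)$p.value), 1)
})
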