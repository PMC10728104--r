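cfg <- pipeline_config()

test_that("design matrix lays out lags most-recent-first", {
  tr <- matrix(c(1, 0, 1, 1), 1, 4, dimnames = list("e1", NULL))
  d <- gc_design(tr, M = 2)
  expect_equal(dim(d$X), c(2, 3))
  expect_equal(unname(d$X[1, ]), c(1, 0, 1))   # x_3 = [1, n_2, n_1]
  expect_equal(unname(d$X[2, ]), c(1, 1, 0))   # x_4 = [1, n_3, n_2]
  expect_equal(d$response(1), c(1, 1))
  # all-zero trains give bare-baseline covariates
  z <- matrix(0L, 2, 10)
  dz <- gc_design(z, 3)
  expect_true(all(dz$X[, -1] == 0))
  expect_true(all(dz$X[, 1] == 1))
  expect_error(gc_design(matrix(0, 1, 3), 3), "longer than")
})

test_that("log-likelihood matches a naive per-term evaluation", {
  set.seed(31)
  tr <- matrix(rbinom(3 * 60, 1, 0.3), 3, 60)
  d <- gc_design(tr, 2)
  y <- d$response(1)
  # omega = 0 -> T' log(1/2)
  expect_equal(gc_loglik(numeric(ncol(d$X)), d$X, y),
               length(y) * log(0.5))
  for (i in 1:5) {
    om <- rnorm(ncol(d$X), 0, 0.7)
    expect_equal(gc_loglik(om, d$X, y), naive_loglik(om, d$X, y),
                 tolerance = 1e-10)
  }
})

test_that("OMP keeps the baseline, nests likelihoods, and finds the driver", {
  set.seed(32)
  om <- list(baseline = rep(-2, 3), kernel = array(0, c(3, 3, 3)))
  om$kernel[2, 1, 1] <- 2.5              # e1 drives e2 at lag 1
  g <- coupled_glm_trains(om, 3000, seed = 32)
  d <- gc_design(g$trains, cfg$gc_history_bins)
  full <- gc_fit_full(d, 2, cfg)
  expect_true(1 %in% full$support)       # baseline always in support
  # the driver's lag-1 column enters the support
  expect_true(d$block(1)[1] %in% full$support)
  # forcing a larger support never lowers the in-sample log-likelihood
  y <- d$response(2)
  path <- cpp_omp_path(d$X, y, keep = 0L,
                       candidates = seq_len(ncol(d$X) - 1),
                       max_add = ncol(d$X) - 1, ridge = cfg$gc_ridge,
                       tol = cfg$gc_newton_tol, maxit = cfg$gc_newton_maxit)
  lls <- unlist(path$loglik)
  expect_true(all(diff(lls) >= -1e-8))
  # independent target: CV picks a (near-)baseline-only model
  nullfit <- gc_fit_full(d, 3, cfg)
  expect_lte(nullfit$size, 2)
})

test_that("deviance is nonnegative, near zero for irrelevant sources, and
           large for true drivers", {
  set.seed(33)
  om <- list(baseline = rep(-2, 3), kernel = array(0, c(3, 3, 3)))
  om$kernel[2, 1, 1] <- 2.5
  g <- coupled_glm_trains(om, 2000, seed = 33)
  d <- gc_design(g$trains, cfg$gc_history_bins)
  full <- gc_fit_full(d, 2, cfg)
  red_true <- gc_fit_reduced(d, 2, 1, full$size, cfg)   # drop the driver
  red_null <- gc_fit_reduced(d, 2, 3, full$size, cfg)   # drop a bystander
  D_true <- gc_deviance(full, red_true, d, cfg)$D
  D_null <- gc_deviance(full, red_null, d, cfg)$D
  expect_gte(D_true, 0); expect_gte(D_null, 0)
  expect_gt(D_true, 50)
  expect_lt(D_null, 10)
  expect_gt(D_true, 20 * max(D_null, 0.5))
  # swapped arguments are rejected by the contract
  expect_error(gc_deviance(red_true, full, d, cfg), "swapped|exclude")
  # deviance grows roughly linearly with T for a true link
  g2 <- coupled_glm_trains(om, 4000, seed = 34)
  d2 <- gc_design(g2$trains, cfg$gc_history_bins)
  f2 <- gc_fit_full(d2, 2, cfg)
  D2 <- gc_deviance(f2, gc_fit_reduced(d2, 2, 1, f2$size, cfg), d2, cfg)$D
  expect_gt(D2, D_true)
})

test_that("network inference recovers a planted chain without the indirect
           link", {
  set.seed(35)
  om <- list(baseline = rep(-2.2, 3), kernel = array(0, c(3, 3, 3)))
  om$kernel[2, 1, 1] <- 2.5; om$kernel[3, 2, 1] <- 2.5
  g <- coupled_glm_trains(om, 3000, seed = 35)
  net <- gc_infer_network(g$trains)
  sig <- net$links[net$links$significant, ]
  expect_true(any(sig$source == "e1" & sig$target == "e2"))
  expect_true(any(sig$source == "e2" & sig$target == "e3"))
  expect_false(any(sig$source == "e1" & sig$target == "e3"))
  # single-electrode input yields an empty network
  one <- matrix(rbinom(100, 1, 0.2), 1, 100, dimnames = list("e1", NULL))
  expect_equal(gc_infer_network(one)$n_links, 0L)
  # degenerate trains are dropped with a warning
  degen <- rbind(g$trains[1:2, ], e9 = rep(0L, 3000))
  expect_warning(gc_infer_network(degen), "degenerate")
})

test_that("shuffling the source train destroys a significant link", {
  set.seed(36)
  om <- list(baseline = rep(-2, 2), kernel = array(0, c(2, 2, 3)))
  om$kernel[2, 1, 1] <- 2.5
  g <- coupled_glm_trains(om, 2500, seed = 36)
  net <- gc_infer_network(g$trains)
  expect_true(any(net$links$significant &
                    net$links$source == "e1" & net$links$target == "e2"))
  shuf <- g$trains
  shuf[1, ] <- sample(shuf[1, ])
  net2 <- gc_infer_network(shuf)
  expect_false(any(net2$links$significant &
                     net2$links$source == "e1" & net2$links$target == "e2"))
})

test_that("bootstrap null gives calibrated p-values on independent trains", {
  set.seed(37)
  tr <- matrix(rbinom(3 * 600, 1, 0.15), 3, 600,
               dimnames = list(paste0("e", 1:3), NULL))
  net <- gc_infer_network(tr, null = "bootstrap", n_boot = 60)
  expect_true(all(net$links$p > 0.01))
  expect_equal(net$n_links, 0L)
})
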