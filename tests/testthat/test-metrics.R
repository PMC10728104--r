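test_that("activity rates are counts over duration", {
  lay <- tiny_layout()
  st <- list(e1 = seq(0.5, 299.5, by = 1))   # 300 spikes in 300 s
  s <- recording_session(st, lay, 300)
  r <- activity_rates(s)
  expect_equal(unname(r$spike_rate["e1"]), 1)
  expect_equal(unname(r$burstlet_rate["e2"]), 0)
  gb <- data.frame(start = 1:6, end = 1:6 + 0.5,
                   n_burstlets = 3L, n_electrodes = 3L)
  r2 <- activity_rates(s, burstlets = session_burstlets(s),
                       global_bursts = gb)
  expect_equal(r2$global_burst_rate, 0.02)
})

test_that("Fano factor matches hand computation and its calibration limits", {
  # counts (2,4,2,4): sample variance 4/3, mean 3 -> FF = 4/9
  sp <- c(rep(0.05, 0), seq(0.01, 0.02, length.out = 2),
          seq(0.11, 0.14, length.out = 4),
          seq(0.21, 0.22, length.out = 2),
          seq(0.31, 0.34, length.out = 4))
  ff <- fano_factor(sort(sp), 0.4)
  expect_equal(ff$counts, c(2L, 4L, 2L, 4L))
  expect_equal(ff$ff, (4 / 3) / 3)
  # Poisson -> 1, periodic aligned to windows -> 0, empty -> undefined
  set.seed(2)
  ffs <- vapply(poisson_trains(10, 300, n = 30, seed = 2),
                function(tr) fano_factor(tr, 300)$ff, numeric(1))
  expect_lt(abs(mean(ffs) - 1), 0.05)
  expect_equal(fano_factor(periodic_trains(0.1, 300)[[1]], 300)$ff, 0)
  expect_false(fano_factor(numeric(0), 300)$defined)
})

test_that("synchrony of firing is symmetric, bounded, and counts overlaps", {
  mk <- function(s, e) data.frame(start = s, end = e)
  a <- mk(c(0, 1, 2, 3, 4), c(0.2, 1.2, 2.2, 3.2, 4.2))
  expect_equal(synchrony_of_firing(a, a)$sf, 1)
  b <- mk(c(10, 11), c(10.2, 11.2))
  expect_equal(synchrony_of_firing(a, b)$sf, 0)
  # x 5 burstlets, y 4, exactly 2 overlapping pairs -> 2/5
  y <- mk(c(0.1, 2.1, 10, 12), c(0.3, 2.3, 10.2, 12.2))
  sf <- synchrony_of_firing(a, y)
  expect_equal(sf$sf, 0.4)
  expect_equal(synchrony_of_firing(y, a)$sf, sf$sf)
  expect_equal(synchrony_of_firing(mk(numeric(0), numeric(0)),
                                   mk(numeric(0), numeric(0)))$sf, 0)
  # brute-force overlap count on random interval sets
  set.seed(33)
  for (i in 1:5) {
    s1 <- sort(runif(6, 0, 10)); s2 <- sort(runif(8, 0, 10))
    bx <- mk(s1, s1 + 0.3); by <- mk(s2, s2 + 0.3)
    small <- if (nrow(bx) <= nrow(by)) bx else by
    big <- if (nrow(bx) <= nrow(by)) by else bx
    brute <- sum(vapply(seq_len(nrow(small)), function(k)
      any(small$start[k] <= big$end & big$start <= small$end[k]),
      logical(1)))
    got <- synchrony_of_firing(bx, by)
    expect_equal(got$b_joint, as.integer(brute))
    expect_lte(got$sf, 1); expect_gte(got$sf, 0)
  }
  # category bins
  expect_equal(synchrony_of_firing(a, mk(0.1, 0.25))$category, "weak")
})

test_that("tracking applies floors and keeps baseline categories", {
  v <- rbind(a = c(2, 1), b = c(0.1, 5), c = c(4, 4))
  colnames(v) <- c("pre", "post")
  tr <- track_metric(v, floor = 0.2)
  expect_equal(tr$pct_change_post[tr$unit == "a"], -50)
  expect_true(is.na(tr$pct_change_post[tr$unit == "b"]))   # below floor
  expect_equal(tr$pct_change_post[tr$unit == "c"], 0)
  # identical pre/post gives 0 everywhere
  v2 <- cbind(pre = c(1, 2, 3), post = c(1, 2, 3))
  rownames(v2) <- letters[1:3]
  expect_true(all(track_metric(v2)$pct_change_post == 0))
  # synchronization category is fixed at baseline
  mk <- function(s, e) data.frame(start = s, end = e)
  base <- synchrony_of_firing(mk(c(0, 1, 2), c(0.2, 1.2, 2.2)),
                              mk(0.1, 0.3))
  expect_equal(base$category, "weak")   # 1/3 at baseline stays weak
})

test_that("MAD filter drops gross outliers and refuses zero MAD", {
  res <- mad_filter(c(2, 3, 4, 5, 100), k = 2)
  expect_equal(res$removed, 100)
  expect_equal(res$kept, c(2, 3, 4, 5))
  expect_warning(all_eq <- mad_filter(rep(3, 5), k = 2), "MAD")
  expect_length(all_eq$kept, 5)
  sym <- mad_filter(c(-3, -1, 0, 1, 3), k = 3)
  expect_equal(sum(sym$keep), 5)
  expect_error(mad_filter(c(1, 2), 2), "3 values")
})

test_that("estimation statistics match a naive bootstrap and separate
           shifted groups", {
  a <- c(1, 2, 3, 4, 5); b <- a + 0
  same <- estimation_difference(a, b, seed = 5)
  expect_gt(same$p, 0.5)
  expect_lte(same$ci[1], 0); expect_gte(same$ci[2], 0)
  far <- estimation_difference(a + 100, b, seed = 5)
  expect_lt(far$p, 1e-6)
  # naive loop oracle under the same seed
  set.seed(77)
  ref <- estimation_difference(a, b + 1, n_iter = 200, seed = 77)
  set.seed(77)
  boot <- numeric(200)
  for (i in 1:200)
    boot[i] <- mean(sample(a, replace = TRUE)) -
      mean(sample(b + 1, replace = TRUE))
  expect_equal(ref$boot, boot)
  expect_equal(ref$ci, unname(quantile(boot, c(0.025, 0.975))))
  # p decreases with separation at fixed n
  set.seed(9)
  g1 <- rnorm(20)
  ps <- vapply(c(0.5, 1.5, 4), function(d)
    estimation_difference(g1 + d, rnorm(20), seed = 3)$p, numeric(1))
  expect_identical(order(ps), 3:1)
})
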