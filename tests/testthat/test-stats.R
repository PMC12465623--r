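test_that("rank-sum p-values match full enumeration on canonical cases", {
  expect_equal(rank_sum_test(1:3, 4:6), 0.1)
  expect_equal(rank_sum_test(1:3, 4:6), enum_rank_sum_p(1:3, 4:6))
  # identical samples: symmetric null, p ~ 1 (ties force the approximation)
  expect_gte(rank_sum_test(c(1, 2, 3), c(1, 2, 3)), 0.99)
  expect_error(rank_sum_test(numeric(0), 1:3), class = "emgait_precondition")

  set.seed(21)
  for (i in 1:10) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    x <- rnorm(na); y <- rnorm(nb, mean = runif(1, -1, 1))
    expect_equal(rank_sum_test(x, y), enum_rank_sum_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact test at n = 10 + 10", {
  set.seed(22)
  for (i in 1:10) {
    x <- rnorm(10); y <- rnorm(10, mean = runif(1, -0.5, 0.5))
    p_exact <- rank_sum_test(x, y)                 # 20 <= threshold: exact
    p_approx <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(p_exact - p_approx), 0.01)
  }
})

test_that("rank-sum statistic is invariant to strictly monotone transforms", {
  set.seed(23)
  x <- rnorm(8); y <- rnorm(9, 0.5)
  expect_equal(rank_sum_test(exp(x), exp(y)), rank_sum_test(x, y))
  expect_equal(rank_sum_test(x^3, y^3), rank_sum_test(x, y))
})

fake_metrics <- function(pre_rms, post_rms, channel = "ReFe_L",
                         session = "without_exo") {
  rbind(
    data.frame(session = session, channel = channel, block = "OFF-PRE",
               cycle_index = seq_along(pre_rms), duration_s = 4.5,
               rms = pre_rms, iemg = pre_rms * 2),
    data.frame(session = session, channel = channel, block = "OFF-POST",
               cycle_index = seq_along(post_rms), duration_s = 4.5,
               rms = post_rms, iemg = post_rms * 2))
}

test_that("compare_blocks computes percent change and skips incomplete channels", {
  set.seed(24)
  pre <- rnorm(12, 100, 1)
  m <- fake_metrics(pre, pre * 1.1)
  rows <- compare_blocks(m)
  r <- rows[rows$metric == "rms", ]
  expect_equal(r$percent_change, 10, tolerance = 1e-9)
  expect_equal(r$n_pre, 12L); expect_equal(r$n_post, 12L)
  expect_equal(sign(r$percent_change), sign(r$mean_post - r$mean_pre))

  same <- compare_blocks(fake_metrics(pre, pre))
  expect_equal(same$percent_change, c(0, 0))
  expect_false(any(same$significant))
  expect_gte(min(same$p_value), 0.99)

  incomplete <- fake_metrics(pre, pre * 1.2)
  extra <- fake_metrics(pre, pre)[1:12, ]
  extra$channel <- "GaLa_L"  # OFF-PRE only
  expect_warning(rows2 <- compare_blocks(rbind(incomplete, extra)),
                 "GaLa_L")
  expect_false("GaLa_L" %in% rows2$channel)
})

test_that("adding a constant to every post sample strictly raises the change", {
  set.seed(25)
  pre <- rnorm(15, 50, 2)
  post <- rnorm(15, 50, 2)
  r0 <- compare_blocks(fake_metrics(pre, post))
  r1 <- compare_blocks(fake_metrics(pre, post + 1))
  for (met in c("rms", "iemg")) {
    expect_gt(r1$mean_post[r1$metric == met], r0$mean_post[r0$metric == met])
    expect_gt(r1$percent_change[r1$metric == met],
              r0$percent_change[r0$metric == met])
  }
})

test_that("Holm adjustment and median centring are available behind flags", {
  set.seed(26)
  pre <- rnorm(12, 100, 1)
  m <- rbind(fake_metrics(pre, pre * 1.08, channel = "ReFe_L"),
             fake_metrics(pre, pre * 1.001, channel = "TiAn_L"))
  plain <- compare_blocks(m)
  holm <- compare_blocks(m, adjust = "holm")
  expect_true(all(holm$p_value >= plain$p_value))
  med <- compare_blocks(m, center = "median")
  r <- med[med$channel == "ReFe_L" & med$metric == "rms", ]
  expect_equal(r$mean_pre, median(pre))
})

test_that("summary table renders signed, starred cells and round-trips via CSV", {
  rows <- data.frame(session = "without_exo", channel = "ReFe_L",
                     metric = "rms", n_pre = 20L, n_post = 20L,
                     mean_pre = 100, mean_post = 106.26,
                     percent_change = 6.26, p_value = 0.01,
                     significant = TRUE, alpha = 0.05)
  class(rows) <- c("emg_comparison", class(rows))
  tab <- summary_table(rows)
  expect_equal(tab$without_exo_rms, "+6.3*")
  rows$p_value <- 0.0005
  expect_equal(summary_table(rows)$without_exo_rms, "+6.3**")
  rows$p_value <- 0.2; rows$significant <- FALSE
  expect_equal(summary_table(rows, mode = "paper")$without_exo_rms, "")
  expect_equal(summary_table(rows, mode = "full")$without_exo_rms, "+6.3")

  set.seed(27)
  many <- compare_blocks(fake_metrics(rnorm(12, 100), rnorm(12, 104)))
  path <- tempfile(fileext = ".csv")
  write_comparison(many, path)
  back <- read_comparison(path)
  expect_equal(as.data.frame(back), as.data.frame(many), tolerance = 1e-12)
})

test_that("the exact test holds its size under the null", {
  # The discrete U statistic cannot reject at exactly 0.05: at m = n = 10
  # the achievable size is P(p < 0.05) under the null, computable a priori
  # from the exact null distribution. 200 null replicates must fall in that
  # size's central 95% binomial band.
  u <- 0:100
  p2 <- pmin(1, 2 * pwilcox(u, 10, 10))
  size <- max(p2[p2 < 0.05])
  set.seed(28)
  n_rep <- 400
  rej <- 0L
  for (i in seq_len(n_rep)) {
    x <- rnorm(10); y <- rnorm(10)
    if (rank_sum_test(x, y) < 0.05) rej <- rej + 1L
  }
  # central 99% band: a fixed-seed check should not fail on band-edge luck
  expect_gte(rej, qbinom(0.005, n_rep, size))
  expect_lte(rej, qbinom(0.995, n_rep, size))
})
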