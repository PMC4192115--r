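test_that("textbook Mann-Whitney cases come out exactly", {
  m <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(m$U, 0)
  expect_equal(m$p, 0.1) # 2/20 orderings, doubled tail
  expect_equal(m$method, "exact")
  ties <- mann_whitney_u(c(1, 1, 1), c(1, 1, 1))
  expect_equal(ties$U, 4.5)
  expect_equal(ties$U, ties$n_a * ties$n_b / 2)
  expect_equal(ties$p, 1)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("exact p equals full enumeration on every small partition", {
  set.seed(5)
  partitions <- list(c(2, 2), c(1, 5), c(3, 3), c(2, 4), c(4, 4), c(3, 5))
  for (pt in partitions) {
    for (rep in 1:3) {
      # draws from a tiny integer pool so that cross-group ties are common
      x <- sample(1:4, pt[1], replace = TRUE)
      y <- sample(1:4, pt[2], replace = TRUE)
      m <- mann_whitney_u(x, y)
      o <- oracle_mw_enum(x, y)
      expect_equal(m$U1, o$U1, info = paste(pt, collapse = "x"))
      expect_equal(m$U, o$U)
      expect_equal(m$p, o$p_two, tolerance = 1e-12)
      expect_equal(mann_whitney_u(x, y, alternative = "less")$p, o$p_le,
                   tolerance = 1e-12)
      expect_equal(mann_whitney_u(x, y, alternative = "greater")$p, o$p_ge,
                   tolerance = 1e-12)
    }
  }
})

test_that("U is a rank statistic: invariances and identities", {
  set.seed(8)
  for (rep in 1:5) {
    x <- sample(1:6, 7, replace = TRUE)
    y <- sample(1:6, 5, replace = TRUE)
    m <- mann_whitney_u(x, y)
    expect_equal(m$U1 + m$U2, m$n_a * m$n_b)
    expect_lte(m$U, m$n_a * m$n_b / 2)
    # strictly monotone transforms of the pooled data change nothing
    mt <- mann_whitney_u(exp(x), exp(y))
    expect_equal(mt$U, m$U)
    expect_equal(mt$p, m$p)
    # swapping the groups leaves U and the two-sided p unchanged
    ms <- mann_whitney_u(y, x)
    expect_equal(ms$U, m$U)
    expect_equal(ms$p, m$p)
  }
})

test_that("the large-sample route matches the classical approximation", {
  set.seed(3)
  x <- rnorm(25); y <- rnorm(20, 0.4)
  m <- mann_whitney_u(x, y, exact_limit = 0)
  expect_equal(m$method, "normal_approx")
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(m$p, ref$p.value, tolerance = 1e-10)
  expect_equal(m$U1, unname(ref$statistic))
  # with heavy ties the tie-corrected variance still agrees
  xt <- sample(1:3, 30, replace = TRUE)
  yt <- sample(1:3, 25, replace = TRUE)
  mt <- mann_whitney_u(xt, yt, exact_limit = 0)
  reft <- suppressWarnings(stats::wilcox.test(xt, yt, exact = FALSE,
                                              correct = TRUE))
  expect_equal(mt$p, reft$p.value, tolerance = 1e-10)
})

test_that("median_and_range uses the standard conventions", {
  expect_equal(median_and_range(c(1, 2, 3)),
               list(median = 2, min = 1, max = 3))
  expect_equal(median_and_range(c(4, 1, 3, 2)),
               list(median = 2.5, min = 1, max = 4))
  expect_error(median_and_range(numeric(0)), "non-empty")
})

test_that("spearman correlation handles monotone and tied data", {
  expect_equal(spearman_rho(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_rho(1:10, rev(1:10))$rho, -1)
  expect_equal(spearman_rho(1:10, (1:10)^3)$p, 0)
  set.seed(2)
  x <- sample(1:5, 12, replace = TRUE)
  y <- x + sample(1:3, 12, replace = TRUE)
  s <- spearman_rho(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(s$rho, unname(ref$estimate))
  expect_gt(s$rho, 0)
  expect_error(spearman_rho(1:4, 1:5), "length mismatch")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})
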