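test_that("average_replicates collapses repeated measurements per unit", {
  d <- data.frame(animal = c("a", "a", "b", "b", "b", "c"),
                  plane = c(1, 2, 1, 2, 3, 1),
                  vasc = c(4, 6, 1, 2, 3, 9),
                  vel = c(1, 1, 2, 4, 6, 5))
  out <- average_replicates(d, by = "animal")
  expect_identical(nrow(out), 3L)
  expect_equal(out$vasc[out$animal == "a"], 5)          # {4, 6} -> 5
  expect_equal(out$vasc[out$animal == "b"], 2)          # 3-plane hand mean
  expect_equal(out$vel[out$animal == "b"], 4)
  expect_equal(out$vasc[out$animal == "c"], 9)          # single plane: identity
  # 'plane' is averaged too unless excluded
  out2 <- average_replicates(d, by = "animal", values = "vasc")
  expect_identical(names(out2), c("animal", "vasc"))
})

test_that("anova_oneway matches hand computation and the base-R oracle", {
  # identical groups -> F = 0
  expect_equal(anova_oneway(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))$value, 0)
  # {1,2,3} vs {4,5,6}: hand computation gives F = 13.5 on (1, 4)
  r <- anova_oneway(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(r$value, 13.5)
  expect_identical(r$df, c(1L, 4L))
  # oracle: stats::anova on random data
  set.seed(2)
  for (rep in 1:5) {
    y <- rnorm(24)
    g <- sample(letters[1:3], 24, replace = TRUE)
    while (min(table(g)) < 2) g <- sample(letters[1:3], 24, replace = TRUE)
    mine <- anova_oneway(y, g)
    base <- anova(lm(y ~ g))
    expect_equal(mine$value, base$`F value`[1], tolerance = 1e-10)
    expect_equal(mine$p_raw, base$`Pr(>F)`[1], tolerance = 1e-10)
  }
  expect_error(anova_oneway(1:4, rep("a", 4)), "two groups")
})

test_that("anova_oneway_summary is algebraically identical to the raw-data form", {
  # printed-summary worked example: F(1,15) ~ 5.47
  r <- anova_oneway_summary(data.frame(n = c(9, 8), mean = c(5.32, 4.82),
                                       sd = c(0.50, 0.36)))
  expect_identical(r$df, c(1L, 15L))
  expect_equal(r$value, 5.4631, tolerance = 1e-4)
  expect_lt(abs(r$value - 5.472) / 5.472, 0.05)  # printed-rounding tolerance

  # equal means -> F = 0
  expect_equal(anova_oneway_summary(data.frame(n = c(5, 7), mean = c(2, 2),
                                               sd = c(1, 2)))$value, 0)

  # equivalence on 100 random small datasets to 1e-10
  set.seed(3)
  for (rep in 1:100) {
    k <- sample(2:4, 1)
    n <- sample(3:8, k, replace = TRUE)
    y <- rnorm(sum(n), sd = runif(1, 0.5, 3))
    g <- rep(seq_len(k), n)
    s <- data.frame(n = n, mean = tapply(y, g, mean), sd = tapply(y, g, sd))
    expect_equal(anova_oneway_summary(s)$value, anova_oneway(y, g)$value,
                 tolerance = 1e-10)
  }
  expect_error(anova_oneway_summary(data.frame(n = c(1, 5), mean = c(0, 1),
                                               sd = c(0, 1))), "n >= 2")
})

test_that("anova_twoway computes sequential Type I tests in B, A, A:B order", {
  set.seed(4)
  # unbalanced 2x3 design (order is material): oracle = anova(lm())
  d <- data.frame(y = rnorm(40),
                  A = sample(c("wt", "tg"), 40, replace = TRUE),
                  B = sample(c("p1", "p2", "p3"), 40, replace = TRUE))
  while (any(table(d$A, d$B) == 0)) {
    d$B <- sample(c("p1", "p2", "p3"), 40, replace = TRUE)
  }
  mine <- anova_twoway(d, "y", "A", "B")
  base <- anova(lm(y ~ B + A + B:A, data = d))
  expect_equal(mine[["B"]]$value, base$`F value`[1], tolerance = 1e-10)
  expect_equal(mine[["A"]]$value, base$`F value`[2], tolerance = 1e-10)
  expect_equal(mine[["A:B"]]$value, base$`F value`[3], tolerance = 1e-10)
  expect_equal(mine[["A"]]$p_raw, base$`Pr(>F)`[2], tolerance = 1e-10)

  # additive construction with a pure A effect
  d2 <- expand.grid(A = c("wt", "tg"), B = c("p1", "p2"), rep = 1:6)
  set.seed(5)
  d2$y <- ifelse(d2$A == "tg", 3, 0) + rnorm(nrow(d2), sd = 0.5)
  m2 <- anova_twoway(d2, "y", "A", "B")
  expect_gt(m2[["A"]]$value, 50)
  expect_lt(m2[["A:B"]]$value, 5)

  # empty cell -> error
  d3 <- d2[!(d2$A == "tg" & d2$B == "p2"), ]
  expect_error(anova_twoway(d3, "y", "A", "B"), "empty cells")
})

test_that("bh_adjust implements the step-up procedure", {
  expect_equal(bh_adjust(0.03), 0.03)                       # single p
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3)) # hand step-up
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))          # all equal
  # oracle: p.adjust and the hand step-up, random vectors
  set.seed(6)
  for (rep in 1:50) {
    p <- runif(sample(1:8, 1))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
    expect_equal(bh_adjust(p), bh_hand(p), tolerance = 1e-12)
    expect_true(all(bh_adjust(p) >= p))                      # >= raw
  }
  # monotone in the order statistics
  p <- c(0.4, 0.01, 0.2, 0.05)
  a <- bh_adjust(p)
  expect_true(all(diff(a[order(p)]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
})

test_that("ks_two_sample computes the exact D with an asymptotic p", {
  expect_equal(ks_two_sample(1:5, 1:5)$value, 0)
  expect_equal(ks_two_sample(1:5, 11:15)$value, 1)
  # D matches brute-force ECDF scan (and ks.test) for n <= 8
  set.seed(7)
  for (rep in 1:30) {
    a <- round(rnorm(sample(2:8, 1)), 2)
    b <- round(rnorm(sample(2:8, 1), 0.5), 2)
    grid <- sort(unique(c(a, b)))
    d_brute <- max(vapply(grid, function(v) abs(mean(a <= v) - mean(b <= v)),
                          numeric(1)))
    mine <- ks_two_sample(a, b)
    expect_equal(mine$value, d_brute, tolerance = 1e-12)
    expect_equal(mine$value,
                 unname(suppressWarnings(ks.test(a, b))$statistic),
                 tolerance = 1e-12)
    expect_true(mine$p_raw >= 0 && mine$p_raw <= 1)
  }
})

test_that("pearson matches cor.test", {
  x <- c(1, 2, 4, 7)
  expect_equal(pearson(x, 2 * x + 1)$value, 1)
  expect_equal(pearson(x, -x)$value, -1)
  # hand 4-point case + oracle
  y <- c(2, 1, 5, 6)
  mine <- pearson(x, y)
  or <- cor.test(x, y)
  expect_equal(mine$value, unname(or$estimate), tolerance = 1e-12)
  expect_equal(mine$p_raw, or$p.value, tolerance = 1e-12)
  expect_equal(mine$df, 2)
  expect_error(pearson(1:2, 1:2), "n >= 3")
  expect_error(pearson(1:5, rep(1, 5)), "zero variance")
})
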