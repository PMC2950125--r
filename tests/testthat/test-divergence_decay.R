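test_that("relative abundance normalises, is scale-invariant, and flags
           all-zero profiles", {
  expect_equal(unname(relative_abundance(c(1, 1, 2))), c(0.25, 0.25, 0.5),
               ignore_attr = TRUE)
  expect_equal(unname(relative_abundance(c(5, 0, 0))), c(1, 0, 0),
               ignore_attr = TRUE)
  set.seed(81)
  for (i in 1:10) {
    x <- rexp(6); c_ <- runif(1, 0.1, 50)
    expect_equal(relative_abundance(x), relative_abundance(c_ * x))
    expect_equal(sum(relative_abundance(x)), 1)
  }
  z <- relative_abundance(c(0, 0, 0))
  expect_true(all(is.na(z)))
  expect_true(attr(z, "undefined"))
  expect_error(relative_abundance(c(-1, 2)), "non-negative")

  m <- ra_matrix(rbind(c(1, 3), c(0, 0)))
  expect_equal(m[1, ], c(0.25, 0.75))
  expect_true(all(is.na(m[2, ])))
})

test_that("divergence is the summed squared RA difference, symmetric and
           bounded", {
  a <- c(t1 = 0.5, t2 = 0.5); b <- c(t1 = 1, t2 = 0)
  expect_equal(expression_divergence(a, a), 0)
  expect_equal(expression_divergence(c(1, 0), c(0, 1)), 2)
  set.seed(82)
  for (i in 1:15) {
    p <- relative_abundance(rexp(5)); q <- relative_abundance(rexp(5))
    manual <- sum(vapply(1:5, function(k) (p[k] - q[k])^2, numeric(1)))
    expect_equal(expression_divergence(p, q), manual)
    expect_equal(expression_divergence(p, q), expression_divergence(q, p))
    expect_lte(expression_divergence(p, q), 2)
  }
  expect_error(expression_divergence(c(a = 1), c(b = 1)), "axis mismatch")
  expect_error(expression_divergence(c(1, 0), c(1, 0, 0)), "axis mismatch")
})

test_that("group comparisons find a planted shift in the X-young group and
           are null on identical groups", {
  x <- rep(c(1.3, 2.2, 4.1), 10)
  same <- group_divergence_compare(c(x, x), rep(c("a", "b"), each = 30))
  expect_equal(same$p_two, 1)

  set.seed(83)
  groups <- rep(c("old_autosome", "old_X", "young_autosome", "young_X"),
                each = 50)
  scores <- rnorm(200)
  scores[groups == "young_X"] <- scores[groups == "young_X"] + 1
  res <- group_divergence_compare(scores, groups)
  vs_yx <- res[res$group1 == "young_X" | res$group2 == "young_X", ]
  p_yx_greater <- ifelse(vs_yx$group1 == "young_X", vs_yx$p_greater,
                         1 - vs_yx$p_greater)
  expect_true(all(p_yx_greater < 0.05))

  expect_error(group_divergence_compare(1:5, rep("only", 5)),
               "at least two")
})

test_that("noiseless decay data are refit to 1e-6 in all three parameters", {
  ages <- branch_midpoints(human_ladder())[as.character(2:12)]
  for (truth in list(c(N = 0.74, r = 0.08, d = 0.42),
                     c(N = 0.90, r = 0.008, d = 0.22))) {
    p <- decay_curve(ages, truth["N"], truth["r"], truth["d"])
    fit <- fit_decay(ages, p)
    expect_lt(max(abs(coef(fit) - truth)), 1e-6)
    expect_true(fit$converged)
    expect_lt(fit$objective, 1e-10)
  }
})

test_that("decay fits are deterministic and respect the model algebra", {
  ages <- seq(-400, -5, length.out = 9)
  p <- decay_curve(ages, 0.6, 0.03, 0.5)
  f1 <- fit_decay(ages, p); f2 <- fit_decay(ages, p)
  expect_identical(coef(f1), coef(f2))   # fixed internal multi-start seed

  # f(0) = N and the deep-time plateau is N * d
  expect_equal(unname(predict(f1, 0)), unname(coef(f1)["N"]))
  expect_equal(unname(predict(f1, -1e9)),
               unname(coef(f1)["N"] * coef(f1)["d"]))

  # monotone non-decreasing toward the present for r > 0, d < 1
  tt <- seq(-500, 0, length.out = 100)
  expect_true(all(diff(decay_curve(tt, 0.8, 0.05, 0.3)) >= 0))

  expect_error(fit_decay(c(-10, -5, -1), c(0.1, 0.2, 0.3)),
               "at least 4 points")
  expect_error(fit_decay(c(-10, -5, -1, 2), rep(0.1, 4)), "<= 0")
  expect_error(fit_decay(c(-10, -5, -2, -1), c(0.1, 0.2, 0.3, 1.3)),
               "\\[0, 1\\]")
})

test_that("the decay_fit object behaves like a standard fitted model", {
  ages <- seq(-300, -3, length.out = 8)
  set.seed(84)
  p <- pmin(pmax(decay_curve(ages, 0.7, 0.05, 0.4) + rnorm(8, 0, 0.02), 0), 1)
  fit <- fit_decay(ages, p, counts = rep(200, 8))
  expect_s3_class(fit, "decay_fit")
  expect_named(coef(fit), c("N", "r", "d"))
  expect_equal(length(fitted(fit)), 8)
  expect_equal(residuals(fit), p - fitted(fit))
  expect_output(print(fit), "Exponential decay fit")
  expect_output(print(summary(fit)), "plateau")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(8L, 3L))
  expect_true(all(sims >= 0 & sims <= 1))
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
  unlink(f)
})

test_that("weighted refits recover the generating parameters from binomially
           noised branch proportions", {
  ages <- branch_midpoints(human_ladder())[as.character(2:12)]
  truth <- c(N = 0.74, r = 0.08, d = 0.42)
  set.seed(85)
  err <- replicate(8, {
    p <- rbinom(length(ages), 300, decay_curve(ages, truth["N"], truth["r"],
                                               truth["d"])) / 300
    unname(coef(fit_decay(ages, p, counts = rep(300, length(ages))))["N"] -
             truth["N"])
  })
  expect_lt(abs(mean(err)), 0.05)       # unbiased recovery on average
  expect_lt(max(abs(err)), 0.15)        # each replicate in a sane band
})
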