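test_that("Fisher-z mean R^2 is a variance-stabilised average", {
  for (x in c(19, 42.8, 69.9)) expect_equal(fisherZMean(rep(x, 5)), x)
  # frozen oracle value computed by direct arithmetic on the z scale
  expect_equal(fisherZMean(c(50, 50, 80)), 62.253127, tolerance = 1e-6)
  v <- c(35, 48, 77, 62)
  expect_gt(fisherZMean(v), min(v)); expect_lt(fisherZMean(v), max(v))
  # close to the arithmetic mean for tightly clustered inputs
  w <- c(54.8, 55.1, 55.3)
  expect_equal(fisherZMean(w), mean(w), tolerance = 1e-3)
  expect_error(fisherZMean(c(50, 100)), "\\(0, 100\\)")
})

test_that("repeated-measures ANOVA agrees with aov and a hand-computed toy", {
  # toy 3 subjects x 2 conditions: paired comparison by explicit sums of squares
  toy <- data.frame(subject = rep(1:3, each = 2), nrem = rep(1:2, 3),
                    r2 = c(10, 14, 20, 22, 30, 36))
  m <- matrix(c(10, 20, 30, 14, 22, 36), ncol = 2)
  d <- m[, 2] - m[, 1]
  Fhand <- mean(d)^2 / (stats::var(d) / 3) # paired t^2 == F(1, n-1)
  res <- rmAnova(toy, "r2", fisherZ = FALSE)
  expect_equal(res$F, Fhand, tolerance = 1e-9)
  expect_equal(res$dfEffect, 1L); expect_equal(res$dfError, 2L)
  # identical columns: no effect
  flat <- data.frame(subject = rep(1:4, each = 3), nrem = rep(1:3, 4),
                     r2 = rep(c(10, 20, 30, 40), each = 3))
  expect_equal(rmAnova(flat, "r2", fisherZ = FALSE)$F, 0)
  # random table cross-checked against stats::aov with an Error stratum
  set.seed(5)
  long <- expand.grid(subject = factor(1:8), nrem = factor(1:4))
  long$r2 <- 50 + as.numeric(long$nrem) * 2 + rnorm(32, 0, 4) +
    rep(rnorm(8, 0, 3), 4)
  fit <- stats::aov(r2 ~ nrem + Error(subject/nrem), data = long)
  Faov <- summary(fit)[["Error: subject:nrem"]][[1]]["nrem", "F value"]
  long2 <- transform(long, subject = as.integer(subject),
                     nrem = as.integer(nrem))
  mine <- rmAnova(long2, "r2", fisherZ = FALSE)
  expect_equal(mine$F, Faov, tolerance = 1e-9)
  expect_true(mine$epsilon > 1 / 3 - 1e-9 && mine$epsilon <= 1)
  # invariance to global and per-subject constant shifts
  shifted <- long2
  shifted$r2 <- shifted$r2 + 7 + rep(1:8 * 3, 4)
  expect_equal(rmAnova(shifted, "r2", fisherZ = FALSE)$F, mine$F,
               tolerance = 1e-9)
  expect_error(rmAnova(long2[-1, ], "r2", fisherZ = FALSE), "incomplete")
})

test_that("polynomial contrasts decompose the episode effect orthogonally", {
  # perfectly linear column means, no subject variation: all linear
  lin <- data.frame(subject = rep(1:5, each = 4), nrem = rep(1:4, 5),
                    ta = rep(c(2, 4, 6, 8), 5))
  tr <- polynomialTrends(lin, "ta", fisherZ = FALSE)
  expect_equal(tr["linear", "percent"], 100)
  expect_equal(tr["quadratic", "percent"], 0)
  expect_equal(tr["cubic", "percent"], 0)
  # brute-force sums-of-squares oracle on a random table
  set.seed(8)
  m <- matrix(rnorm(24, rep(c(5, 6, 9, 8), each = 6), 1), ncol = 4)
  tab <- data.frame(subject = rep(1:6, 4), nrem = rep(1:4, each = 6),
                    ta = as.vector(m))
  tr2 <- polynomialTrends(tab, "ta", fisherZ = FALSE)
  n <- 6
  ssEffect <- n * sum((colMeans(m) - mean(m))^2)
  for (nm in rownames(tr2)) {
    cv <- list(linear = c(-3, -1, 1, 3), quadratic = c(1, -1, -1, 1),
               cubic = c(-1, 3, -3, 1))[[nm]]
    ssC <- n * mean(m %*% cv)^2 / sum(cv^2)
    expect_equal(tr2[nm, "percent"], 100 * ssC / ssEffect, tolerance = 1e-9)
  }
  expect_equal(sum(tr2$percent), 100, tolerance = 1e-9)
})

test_that("the quality table classifies and tabulates per episode", {
  allVG <- data.frame(subject = rep(1:6, each = 4), nrem = rep(1:4, 6),
                      r2 = 70)
  qt <- qualityTable(allVG)
  expect_true(all(qt["VG", ] == 100))
  expect_true(all(qt[c("G", "F", "BF"), ] == 0))
  mixed <- data.frame(subject = rep(1:4, each = 1), nrem = 1,
                      r2 = c(65, 45, 25, 10))
  qm <- qualityTable(mixed)
  expect_true(all(qm[, 1] == 25))
})

test_that("the packaged reference cohort loads as a complete 30 x 4 design", {
  tab <- referenceCohort()
  expect_named(tab, c("subject", "nrem", "ta", "r2"))
  expect_equal(nrow(tab), 120)
  expect_equal(length(unique(tab$subject)), 30)
  expect_true(all(table(tab$subject) == 4))
  expect_true(all(tab$ta >= 1 & tab$ta == round(tab$ta)))
  expect_true(all(tab$r2 > 0 & tab$r2 < 100))
})
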