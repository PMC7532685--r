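# evaluation statistics: closed forms, exhaustive oracles, simulations

test_that("percentage error matches hand-computed values", {
  expect_message(pe0 <- percentage_error(c(10, 0), c(10, 3)), "excluded")
  expect_equal(pe0$errors, 0)
  expect_equal(pe0$n_excluded, 1)
  pe <- percentage_error(10, 11)
  expect_equal(pe$mean, 10)
  ex <- percentage_error(c(5, 5, 5), c(5, 5, 5))
  expect_equal(ex$mean, 0)
  expect_equal(ex$sd, 0)
  set.seed(1)
  x <- sample(1:50, 30, replace = TRUE); y <- sample(0:50, 30, replace = TRUE)
  pe2 <- percentage_error(x, y)
  expect_equal(pe2$mean, mean(100 * abs(y - x) / x), tolerance = 1e-12)
})

test_that("detection metrics handle perfect, empty and swapped predictions", {
  truth <- data.frame(fov = "f1", x = c(10, 30, 50, 70, 90),
                      y = rep(10, 5), radius = 5,
                      phenotype = c("A", "A", "A", "B", "B"))
  perfect <- data.frame(fov = "f1", x = truth$x, y = truth$y,
                        phenotype = truth$phenotype)
  m <- detection_metrics(perfect, truth)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  none <- data.frame(fov = character(0), x = numeric(0), y = numeric(0),
                     phenotype = character(0))
  m0 <- detection_metrics(none, truth)
  expect_equal(m0$sensitivity, 0)
  # one swap: the cell at x=50 is predicted as B instead of A
  swap <- perfect
  swap$phenotype[3] <- "B"
  ms <- detection_metrics(swap, truth)
  expect_equal(ms$sensitivity, 4 / 5)
})

test_that("Passing-Bablok recovers exact lines and the pairwise-slope oracle", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12)
  fit1 <- passing_bablok(x, x)
  expect_equal(fit1$slope, 1)
  expect_equal(fit1$intercept, 0)
  fit2 <- passing_bablok(x, 2 * x + 3)
  expect_equal(fit2$slope, 2)
  expect_equal(fit2$intercept, 3)
  expect_true(fit2$linearity_pass)

  set.seed(9)
  xr <- round(runif(15, 0, 40)); yr <- round(xr * 1.3 + rnorm(15, 0, 3))
  fit <- passing_bablok(xr, yr)
  # exhaustive oracle over all C(15,2) pairwise slopes with the offset K
  S <- c()
  for (i in 1:14) for (j in (i + 1):15) {
    dx <- xr[j] - xr[i]; dy <- yr[j] - yr[i]
    s <- if (dx == 0 && dy == 0) NA else if (dx == 0) sign(dy) * Inf else
      dy / dx
    S <- c(S, s)
  }
  S <- sort(S[!is.na(S) & S != -1])
  K <- sum(S < -1); N <- length(S)
  b_oracle <- if (N %% 2 == 1) S[(N + 1) / 2 + K] else
    0.5 * (S[N / 2 + K] + S[N / 2 + 1 + K])
  expect_equal(fit$slope, b_oracle)
  expect_equal(fit$intercept, median(yr - b_oracle * xr))
  expect_true(fit$slope_ci[1] <= fit$slope && fit$slope <= fit$slope_ci[2])
  expect_error(passing_bablok(1:5, 1:5), "n >= 10")
})

test_that("Bland-Altman matches the direct formulas", {
  x <- c(1, 4, 7, 9, 12, 15)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(unname(ba0$loa), c(0, 0))
  ba2 <- bland_altman(x, x + 2)
  expect_equal(ba2$bias, 2)
  expect_equal(ba2$sd, 0)
  set.seed(12)
  y <- x + rnorm(6, 1, 2)
  ba <- bland_altman(x, y)
  d <- y - x
  expect_equal(ba$bias, mean(d))
  expect_equal(unname(ba$loa), mean(d) + c(-1.96, 1.96) * sd(d))
  expect_lte(ba$loa[1], ba$bias)
  expect_gte(ba$loa[2], ba$bias)
})

test_that("Gwet's AC1 equals 1 on perfect agreement and its formula oracle", {
  a <- c(1, 1, 2, 2, 3)
  expect_equal(gwet_ac1(a, a)$ac1, 1)
  # 10-unit hand-checked table, 2 categories
  ra <- c("p", "p", "p", "n", "n", "p", "n", "p", "n", "p")
  rb <- c("p", "n", "p", "n", "n", "p", "p", "p", "n", "p")
  res <- gwet_ac1(ra, rb)
  pa <- mean(ra == rb)                       # 0.8
  piq <- c(mean(c(ra, rb) == "n"), mean(c(ra, rb) == "p"))
  pe <- sum(piq * (1 - piq)) / (2 - 1)
  expect_equal(res$pa, pa)
  expect_equal(res$pe, pe)
  expect_equal(res$ac1, (pa - pe) / (1 - pe))
  expect_true(res$ac1 >= -1 && res$ac1 <= 1)

  # independent uniform ratings: AC1 near 0 for large n
  set.seed(13)
  u <- sample(c(0, 1), 4000, replace = TRUE)
  v <- sample(c(0, 1), 4000, replace = TRUE)
  expect_lt(abs(gwet_ac1(u, v)$ac1), 0.06)
})

test_that("ZIP nests Poisson and AIC selection recovers the family", {
  set.seed(14)
  g <- rep(0:1, each = 250)
  y_pois <- rpois(500, 3)
  fit <- fit_count_models(y_pois, g)
  tab <- fit$table
  # nesting: ZIP log-likelihood can only improve on Poisson
  expect_gte(tab$loglik[tab$family == "ZIP"],
             tab$loglik[tab$family == "P"] - 1e-4)
  # null case: identical groups, IRR ~ 1 with CI covering 1
  irr_row <- tab[tab$family == "P", ]
  expect_lt(abs(irr_row$irr - 1), 0.2)
  expect_true(irr_row$irr_lo <= 1 && irr_row$irr_hi >= 1)

  # model recovery, clearly separated scenarios
  recover <- function(make, truefam, reps = 30) {
    hits <- 0
    for (r in 1:reps) {
      yy <- make()
      f <- suppressWarnings(fit_count_models(yy, g))
      t <- f$table
      if (truefam == "P" &&
          t$aic[t$family == "P"] <= t$aic[t$family == "ZIP"] + 1e-9) {
        hits <- hits + 1
      }
      if (truefam == "ZIP" &&
          t$aic[t$family == "ZIP"] < t$aic[t$family == "P"]) {
        hits <- hits + 1
      }
    }
    hits / reps
  }
  set.seed(15)
  expect_gte(recover(function() rpois(500, 3), "P"), 0.9)
  set.seed(16)
  expect_gte(recover(function() {
    ifelse(runif(500) < 0.4, 0L, rpois(500, 3))
  }, "ZIP"), 0.9)
})

test_that("optimism-adjusted AUC behaves at its limits", {
  scores <- c(1:10, 11:20)
  labels <- rep(c(0, 1), each = 10)
  r0 <- roc_optimism_auc(scores, labels, B = 0)
  expect_equal(r0$apparent_auc, 1)
  expect_equal(r0$adjusted_auc, r0$apparent_auc)   # B = 0 contract
  set.seed(18)
  s <- rnorm(300); l <- rbinom(300, 1, 0.5)        # independent
  r <- roc_optimism_auc(s, l, B = 200, seed = 2)
  expect_lt(abs(r$adjusted_auc - 0.5), 0.08)
  # reproducible
  r2 <- roc_optimism_auc(s, l, B = 200, seed = 2)
  expect_equal(r$adjusted_auc, r2$adjusted_auc)
})

test_that("Youden cutoff equals exhaustive search and breaks ties low", {
  scores <- c(10, 10, 10, 20, 20, 20)
  labels <- c(0, 0, 0, 1, 1, 1)
  expect_equal(youden_cutoff(scores, labels), 20)
  set.seed(19)
  s <- round(rnorm(60, 5, 2), 1); l <- as.integer(s + rnorm(60) > 5)
  ct <- youden_cutoff(s, l)
  J <- function(c0) {
    p <- as.integer(s >= c0)
    sum(p & l) / sum(l) + sum(!p & !l) / sum(!l) - 1
  }
  best <- max(vapply(sort(unique(s)), J, numeric(1)))
  expect_equal(J(ct), best)
  cands <- sort(unique(s))
  expect_equal(ct, min(cands[vapply(cands, J, numeric(1)) >= best - 1e-12]))
  expect_warning(youden_cutoff(rep(3, 5), c(0, 1, 0, 1, 0)), "single")
})

test_that("diagnostics_2x2 reproduces formulas on random tables", {
  d <- diagnostics_2x2(tp = 5, fp = 0, tn = 7, fn = 0, B = 0)
  expect_equal(unname(d$metrics), rep(1, 5))
  set.seed(20)
  for (r in 1:20) {
    cts <- sample(1:30, 4, replace = TRUE)
    d2 <- diagnostics_2x2(tp = cts[1], fp = cts[2], tn = cts[3],
                          fn = cts[4], B = 0)
    expect_equal(unname(d2$metrics["sensitivity"]),
                 cts[1] / (cts[1] + cts[4]))
    expect_equal(unname(d2$metrics["ppv"]), cts[1] / (cts[1] + cts[2]))
    expect_equal(unname(d2$metrics["npv"]), cts[3] / (cts[3] + cts[4]))
    expect_equal(unname(d2$metrics["accuracy"]), (cts[1] + cts[3]) / sum(cts))
  }
  # score-based form with LOOCV runs and returns coherent counts
  set.seed(23)
  sc <- c(rnorm(15, 0), rnorm(15, 2)); lb <- rep(0:1, each = 15)
  dl <- diagnostics_2x2(scores = sc, labels = lb, B = 100, loocv = TRUE,
                        seed = 3)
  expect_equal(sum(dl$counts), 30)
  expect_equal(sum(dl$loocv$counts), 30)
  expect_true(all(dl$ci[, 1] <= dl$ci[, 2]))
})
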