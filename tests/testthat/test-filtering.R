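# Global scaling and the three-step probe filter.

test_that("global scaling hits the trimmed-mean target and is idempotent", {
  # constant array: every value becomes the target
  lm <- matrix(250, 10, 2, dimnames = list(sprintf("p%02d", 1:10), c("A", "B")))
  d <- make_expr(lm, n_replicates = 2)
  s <- global_scale(d, target = 500, trim = 0.02)
  expect_true(all(s$intensity == 500))
  expect_true(s$normalized)

  # 100 values 1..100 on one array: factor = 500 / mean(values ranked 3..98)
  lm2 <- matrix(as.numeric(1:100), 100, 1, dimnames = list(sprintf("p%03d", 1:100), "A"))
  d2 <- make_expr(lm2, n_replicates = 1)
  s2 <- global_scale(d2, target = 500, trim = 0.02)
  factor_oracle <- 500 / mean(3:98)
  expect_equal(s2$intensity[, 1], lm2[, 1] * factor_oracle,
               ignore_attr = TRUE, tolerance = 1e-12)
  # postcondition: trimmed mean of the scaled array equals the target
  expect_equal(mean(sort(s2$intensity[, 1])[3:98]), 500, tolerance = 1e-9)

  # idempotence
  set.seed(11)
  lm3 <- matrix(rexp(300, 1 / 200), 100, 3,
                dimnames = list(sprintf("p%03d", 1:100), c("A", "B", "C")))
  d3 <- make_expr(lm3, n_replicates = 2, jitter = 5, seed = 3)
  once <- global_scale(d3)
  twice <- global_scale(once)
  expect_equal(twice$intensity, once$intensity, tolerance = 1e-12)

  # all-zero array has no defined scale
  lm4 <- matrix(c(0, 0, 1, 2), 2, 2, dimnames = list(c("p1", "p2"), c("A", "B")))
  expect_error(global_scale(make_expr(lm4, 1)), "trimmed mean")
})

test_that("present filter follows the >= min_present in >= 1 line rule", {
  lm <- matrix(100, 4, 2, dimnames = list(paste0("p", 1:4), c("A", "B")))
  calls <- matrix("A", 4, 12)
  # p1: 4 of 6 present in line A -> retained
  calls[1, 1:4] <- "P"
  # p2: all absent -> removed; p3: exactly 3 P in each line -> removed
  calls[3, c(1:3, 7:9)] <- "P"
  # p4: marginal calls never count as present
  calls[4, 1:6] <- "M"
  d <- make_expr(lm, n_replicates = 6, calls = calls)
  expect_identical(present_filter(d, 4), "p1")
  # invariance to intensities: rescaling changes nothing
  d2 <- d
  d2$intensity <- d2$intensity * 1000
  expect_identical(present_filter(d2, 4), present_filter(d, 4))
})

test_that("ANOVA filter reproduces textbook arithmetic and lm oracle", {
  # 2 lines x 3 replicates {2,3,4} vs {6,7,8}: F = 24, P = pf(24, 1, 4)
  lm <- matrix(0, 1, 2, dimnames = list("p1", c("A", "B")))
  d <- make_expr(lm, n_replicates = 3)
  d$intensity[1, ] <- c(2, 3, 4, 6, 7, 8)
  keep <- anova_filter(d, alpha = 0.05)
  expect_identical(as.character(keep), "p1")
  expect_equal(unname(attr(keep, "p")["p1"]), pf(24, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)

  # random tables vs stats::anova(lm(...)) as independent oracle
  set.seed(21)
  for (i in 1:10) {
    L <- sample(3:5, 1)
    reps <- sample(3:6, 1)
    vals <- matrix(abs(rnorm(L * reps, 100, 30)), 1)
    lmz <- matrix(0, 1, L, dimnames = list("p1", paste0("L", 1:L)))
    dd <- make_expr(lmz, n_replicates = reps)
    dd$intensity[1, ] <- vals
    g <- factor(dd$lines)
    p_oracle <- stats::anova(stats::lm(as.numeric(vals) ~ g))$`Pr(>F)`[1]
    expect_equal(unname(attr(anova_filter(dd), "p")["p1"]), p_oracle,
                 tolerance = 1e-10)
  }

  # degenerate all-identical probe is not significant
  lm2 <- matrix(5, 1, 3, dimnames = list("p1", c("A", "B", "C")))
  d2 <- make_expr(lm2, n_replicates = 3)
  expect_message(keep2 <- anova_filter(d2), "undefined ANOVA")
  expect_length(keep2, 0)
})

test_that("null removal rate of the ANOVA filter is about alpha", {
  set.seed(31)
  n_probes <- 1500
  lm <- matrix(500, n_probes, 5,
               dimnames = list(sprintf("p%04d", 1:n_probes), paste0("L", 1:5)))
  d <- make_expr(lm, n_replicates = 4, jitter = 20, seed = 31)
  kept <- length(anova_filter(d, alpha = 0.05))
  se <- sqrt(0.05 * 0.95 / n_probes)
  expect_lt(abs(kept / n_probes - 0.05), 3 * se + 1e-9)
})

test_that("fold filter boundary is inclusive and handles zero means", {
  lm <- matrix(c(10, 50,      # ratio exactly 5 -> retained
                 20, 20,      # ratio 1 -> removed
                 3, 14,       # 14/3 < 5 -> removed
                 0, 30),      # infinite ratio -> retained, logged
               4, 2, byrow = TRUE,
               dimnames = list(paste0("p", 1:4), c("A", "B")))
  lm3 <- cbind(lm, C = c(30, 20, 7, 10))   # p3 line means {3,7,14}
  d <- make_expr(lm3, n_replicates = 2)
  expect_message(keep <- fold_filter(d, min_ratio = 5), "infinite fold")
  expect_setequal(as.character(keep), c("p1", "p4"))
  expect_equal(unname(attr(keep, "ratio")["p3"]), 14 / 3)
})

test_that("filter steps are nested and the full filter isolates planted probes", {
  cfg <- sim_config(n_probes = 1000, seed = 5)
  prop <- simulate_propensities(cfg)
  expr <- global_scale(simulate_expression(cfg, prop))
  rep1 <- suppressMessages(filter_probes(expr))
  expect_true(all(rep1$steps$anova %in% rep1$steps$present))
  expect_true(all(rep1$steps$fold %in% rep1$steps$anova))
  expect_equal(unname(rep1$counts),
               c(1000, length(rep1$steps$present), length(rep1$steps$anova),
                 length(rep1$steps$fold)))

  # 10 planted variable probes among flat/absent ones survive alone
  set.seed(41)
  n_probes <- 400
  ids <- sprintf("p%04d", 1:n_probes)
  lm <- matrix(200, n_probes, 4, dimnames = list(ids, paste0("L", 1:4)))
  planted <- ids[1:10]
  lm[1:10, ] <- rep(c(50, 120, 200, 300), each = 10)  # 6-fold range
  d <- make_expr(lm, n_replicates = 6, jitter = 3, seed = 41)
  calls <- d$calls
  calls[201:400, ] <- "A"   # half the null probes absent everywhere
  d <- expression_dataset(d$intensity, calls, d$lines, normalized = TRUE)
  rep2 <- suppressMessages(filter_probes(d))
  expect_setequal(rep2$steps$fold, planted)
})

test_that("empty probe sets short-circuit cleanly", {
  lm <- matrix(1, 1, 2, dimnames = list("p1", c("A", "B")))
  calls <- matrix("A", 1, 4)
  d <- make_expr(lm, n_replicates = 2, calls = calls)
  rep0 <- filter_probes(d)
  expect_equal(unname(rep0$counts), c(1, 0, 0, 0))
  expect_length(rep0$steps$fold, 0)
})
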