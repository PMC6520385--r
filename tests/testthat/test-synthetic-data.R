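# The synthetic-data generator: determinism, coupling control, planting,
# call-matrix consistency, methylation construction.

test_that("fixed seed gives byte-identical outputs; seeds differ", {
  cfg <- switch_config(seed = 5, n_probes = 300)
  p1 <- simulate_propensities(cfg)
  p2 <- simulate_propensities(cfg)
  expect_identical(p1, p2)
  e1 <- simulate_expression(cfg, p1)
  e2 <- simulate_expression(cfg, p2)
  expect_identical(e1$intensity, e2$intensity)
  expect_identical(simulate_panel_cts(cfg, p1), simulate_panel_cts(cfg, p2))
  m1 <- simulate_methylation(cfg)
  m2 <- simulate_methylation(cfg)
  expect_identical(m1$beta, m2$beta)
  cfg2 <- switch_config(seed = 6, n_probes = 300)
  expect_false(identical(simulate_propensities(cfg2)$values, p1$values))
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- rnorm(3)
  set.seed(123)
  invisible(simulate_propensities(sim_config(seed = 9)))
  b <- rnorm(3)
  expect_identical(a, b)
})

test_that("realized propensity coupling approximates the targets", {
  cfg <- sim_config(seed = 1)
  reals <- sapply(1:20, function(s) {
    p <- simulate_propensities(sim_config(seed = s))
    c(em = p$coupling_realized[1, 2], me = p$coupling_realized[2, 3])
  })
  expect_lt(abs(mean(reals["em", ]) - (-0.66)), 0.15)
  expect_lt(abs(mean(reals["me", ]) - 0.79), 0.15)

  # independence case: couplings centred at zero
  zero <- sapply(1:20, function(s) {
    p <- simulate_propensities(sim_config(
      coupling = c(ecto_meso = 0, ecto_endo = 0, meso_endo = 0), seed = s))
    p$coupling_realized[1, 2]
  })
  expect_lt(abs(mean(zero)), 0.15)

  # perfect dependence: identical rank vectors
  p1 <- simulate_propensities(sim_config(
    coupling = c(ecto_meso = 1, ecto_endo = 1, meso_endo = 1), seed = 4))
  expect_equal(p1$ranks[, 1], p1$ranks[, 2], ignore_attr = TRUE)
  expect_equal(p1$ranks[, 1], p1$ranks[, 3], ignore_attr = TRUE)

  # infeasible (indefinite) coupling triple is rejected
  expect_error(simulate_propensities(sim_config(
    coupling = c(ecto_meso = 0.9, ecto_endo = -0.9, meso_endo = 0.9))),
    "infeasible")
})

test_that("noiseless planting hits the nearest attainable rank correlation", {
  # attainable grid at n = 8: r = 1 - 6*S/504 with S even
  cfg <- sim_config(n_lines = 8, n_probes = 20, noise_sd = 0, seed = 2,
                    planted_markers = list(
                      planted_marker("P00003", c(ectoderm = 0.9)),
                      planted_marker("P00004", c(endoderm = -1.0))))
  prop <- simulate_propensities(cfg)
  expr <- simulate_expression(cfg, prop)
  realized <- expr$planted$P00003$realized[["ectoderm"]]
  null8 <- exact_null(8)
  nearest <- null8$table$r[which.min(abs(null8$table$r - 0.9))]
  expect_equal(realized, nearest, tolerance = 1e-12)
  expect_equal(expr$planted$P00004$realized[["endoderm"]], -1)
  # and the screen sees exactly those correlations at zero noise
  scr <- screen_markers(expr, c("P00003", "P00004"), rank_lines(prop$values))
  tab <- scr$table
  expect_equal(tab$r_s[tab$probe == "P00003" & tab$lineage == "ectoderm"],
               nearest)
  expect_equal(tab$r_s[tab$probe == "P00004" & tab$lineage == "endoderm"], -1)
})

test_that("call matrix is consistent with the present-filter criterion", {
  cfg <- sim_config(n_probes = 400, absent_fraction = 0.4, seed = 11)
  prop <- simulate_propensities(cfg)
  expr <- simulate_expression(cfg, prop)
  kept <- present_filter(expr, 4)
  absent <- probe_ids(expr)[apply(expr$calls == "A", 1, all)]
  expect_length(intersect(kept, absent), 0)
  expect_setequal(probe_ids(expr), union(kept, absent))
  expect_equal(length(absent), round(0.4 * 400))
})

test_that("planted probe ids are validated", {
  expect_error(sim_config(n_probes = 10, planted_markers = list(
    planted_marker("P99999", c(ectoderm = 1)))), "out of range")
  expect_error(planted_marker("P1", c(ectoderm = 1.2)), "<= 1")
  expect_error(planted_marker("P1", c(somite = 0.5)), "lineages")
  expect_error(sim_config(n_probes = 10, planted_markers = list(
    planted_marker("P00001", c(ectoderm = 1)),
    planted_marker("P00001", c(mesoderm = 1)))), "duplicate planted")
})

test_that("panel layout matches configured sizes and overlaps", {
  cfg <- sim_config()
  panel <- panel_layout(cfg)
  expect_equal(length(unique(panel$gene)), 97)
  sizes <- table(panel$lineage)
  expect_equal(unname(sizes[c("ectoderm", "mesoderm", "endoderm")]),
               c(45, 56, 27), ignore_attr = TRUE)
  counts <- table(panel$gene)
  expect_equal(sum(counts == 3), 3)        # triple-membership genes
  expect_equal(sum(counts == 2), 25)       # pairwise-only overlaps
})

test_that("Ct table structure: duplicates differ only by noise, housekeeping flat", {
  cfg <- sim_config(n_lines = 5, ct_noise_sd = 0, seed = 6)
  prop <- simulate_propensities(cfg)
  ct <- simulate_panel_cts(cfg, prop)
  hk <- ct$ct[ct$gene == "GAPDH"]
  expect_true(all(hk == 20))
  w <- reshape(ct[ct$gene == "ECT01", c("line", "replicate", "well", "ct")],
               idvar = c("line", "replicate"), timevar = "well",
               direction = "wide")
  expect_equal(w$ct.1, w$ct.2)             # zero noise: wells identical
  # Ct decreases with the lineage propensity
  m <- tapply(ct$ct[ct$gene == "ECT01"], ct$line[ct$gene == "ECT01"], mean)
  expect_equal(unname(rank(m[rownames(prop$values)])),
               unname(rank(-prop$values[, "ectoderm"])))
})

test_that("methylation generator plants effects and reports filters", {
  cfg <- sim_config(n_meth_probes = 2000, seed = 19)
  meth <- suppressWarnings(simulate_methylation(cfg))
  planted <- attr(meth, "planted")
  expect_true(all(meth$beta > 0 & meth$beta < 1))
  # planted sets never collide with the unannotated/detection-failed sets
  expect_length(intersect(c(planted$hyper, planted$hypo),
                          c(planted$unannotated, planted$detection_fail)), 0)
  # annotation filter removes exactly the unannotated probes
  retained <- annotation_filter(rownames(meth$beta), meth$manifest)
  expect_setequal(setdiff(rownames(meth$beta), retained), planted$unannotated)
  # detection filter removes exactly the planted failures
  kept <- detection_filter(meth)
  expect_setequal(setdiff(rownames(meth$beta), kept), planted$detection_fail)
  # filters commute
  a <- annotation_filter(detection_filter(meth), meth$manifest)
  b <- intersect(detection_filter(meth),
                 annotation_filter(rownames(meth$beta), meth$manifest))
  expect_setequal(a, b)
  # planted gene-body probes really sit in gene bodies
  grp <- meth$manifest$UCSC_RefGene_Group[match(planted$hyper,
                                                meth$manifest$IlmnID)]
  expect_true(all(grp == "Body"))
})

test_that("beta clipping is counted", {
  cfg <- sim_config(n_meth_probes = 500, meth_effect = 0.9,
                    meth_noise_sd = 0.2, seed = 23)
  expect_warning(meth <- simulate_methylation(cfg), "clipped")
  planted <- attr(meth, "planted")
  expect_gt(planted$clip_count, 0)
  expect_true(all(meth$beta > 0 & meth$beta < 1))
})
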