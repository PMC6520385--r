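# Differential methylation: filters, t tests, BH, classification, regions.

make_meth <- function(beta, detp = NULL, manifest = NULL) {
  if (is.null(detp))
    detp <- matrix(1e-4, nrow(beta), ncol(beta), dimnames = dimnames(beta))
  if (is.null(manifest))
    manifest <- data.frame(IlmnID = rownames(beta), CHR = "chr1",
                           MAPINFO = seq_len(nrow(beta)) * 100,
                           UCSC_RefGene_Name = "GENE",
                           UCSC_RefGene_Group = "Body",
                           Relation_to_UCSC_CpG_Island = "Island")
  methylation_dataset(beta, detp, manifest,
                      rep(c("control", "kd"), each = ncol(beta) / 2))
}

beta_mat <- function(m1, m2, noise = 0, reps = 3, seed = 1) {
  set.seed(seed)
  n <- length(m1)
  b <- cbind(matrix(rep(m1, reps), n), matrix(rep(m2, reps), n)) +
    matrix(rnorm(n * 2 * reps, 0, noise), n)
  b <- pmin(pmax(b, 1e-6), 1 - 1e-6)
  rownames(b) <- sprintf("cg%04d", seq_len(n))
  colnames(b) <- paste(rep(c("control", "kd"), each = reps),
                       rep(seq_len(reps), 2), sep = "_")
  b
}

test_that("detection filter boundary: P = 0.01 in one sample removes a probe", {
  b <- beta_mat(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  detp <- matrix(0.001, 3, 6, dimnames = dimnames(b))
  detp[2, 4] <- 0.01          # exactly at the threshold: removed
  detp[3, 1] <- 0.0099        # just below: retained
  m <- make_meth(b, detp)
  expect_setequal(detection_filter(m), c("cg0001", "cg0003"))
})

test_that("annotation filter keeps only chromosome+locus probes", {
  man <- data.frame(IlmnID = c("a", "b", "c", "d"),
                    CHR = c("chr1", "", "chr2", "chr3"),
                    MAPINFO = c(100, 200, NA, 400),
                    UCSC_RefGene_Name = "", UCSC_RefGene_Group = "",
                    Relation_to_UCSC_CpG_Island = "OpenSea")
  out <- annotation_filter(c("a", "b", "c", "d", "zzz"), man)
  expect_setequal(as.character(out), c("a", "d"))
  expect_equal(attr(out, "missing_from_manifest"), 1)
  expect_length(annotation_filter(character(0), man), 0)
})

test_that("classification thresholds are jointly strict", {
  expect_identical(classify_methylation(0.01, 1.0), "hyper")
  expect_identical(classify_methylation(0.01, -1.0), "hypo")
  expect_identical(classify_methylation(0.05, 1.0), "unchanged")  # q boundary
  expect_identical(classify_methylation(0.01, 0.6), "unchanged")  # lfc boundary
  expect_identical(classify_methylation(0.01, -0.6), "unchanged")
  expect_identical(classify_methylation(0.2, 2.0), "unchanged")
  # log2(0.4/0.3) ~ 0.415 < 0.6: a clear mean shift can still be unchanged
  expect_identical(classify_methylation(0.001, log2(0.4 / 0.3)), "unchanged")
})

test_that("t tests match stats::t.test and fold changes match arithmetic", {
  set.seed(51)
  b <- beta_mat(runif(50, 0.2, 0.8), runif(50, 0.2, 0.8), noise = 0.05,
                seed = 51)
  m <- make_meth(b)
  res <- differential_methylation(m)
  for (i in c(1, 10, 25, 50)) {
    tt <- stats::t.test(b[i, 4:6], b[i, 1:3], var.equal = TRUE)
    expect_equal(res$table$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(res$table$t[i], unname(tt$statistic), tolerance = 1e-12)
  }
  welch <- differential_methylation(m, var_equal = FALSE)
  tt <- stats::t.test(b[7, 4:6], b[7, 1:3])
  expect_equal(welch$table$p[7], tt$p.value, tolerance = 1e-12)
  expect_equal(res$table$lfc,
               log2(rowMeans(b[, 4:6]) / rowMeans(b[, 1:3])),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("BH q-values equal the brute-force definition", {
  set.seed(61)
  b <- beta_mat(runif(200, 0.2, 0.8), runif(200, 0.2, 0.8), noise = 0.04,
                seed = 61)
  res <- differential_methylation(make_meth(b))
  expect_equal(res$table$q, oracle_bh(res$table$p), tolerance = 1e-12)
  # BH monotonicity and q >= p
  o <- order(res$table$p)
  expect_true(all(diff(res$table$q[o]) >= -1e-15))
  expect_true(all(res$table$q >= res$table$p - 1e-15))
})

test_that("class partition identity and excluded probes", {
  b <- beta_mat(runif(20, 0.3, 0.7), runif(20, 0.3, 0.7), noise = 0.03,
                seed = 71)
  m <- make_meth(b)
  res <- differential_methylation(m, probes = rownames(b)[1:15])
  cls <- table(factor(res$table$class,
                      c("hyper", "hypo", "unchanged", "excluded")))
  expect_equal(sum(cls), 20)
  expect_equal(unname(cls["excluded"]), 5, ignore_attr = TRUE)
})

test_that("null data yield (almost) no differential probes after BH", {
  rates <- sapply(1:5, function(s) {
    set.seed(1000 + s)
    base <- runif(500, 0.3, 0.7)
    b <- beta_mat(base, base, noise = 0.05, seed = 100 + s)
    res <- differential_methylation(make_meth(b))
    mean(res$table$class %in% c("hyper", "hypo"))
  })
  expect_lt(mean(rates), 0.01)
})

test_that("summary fractions use the documented denominators", {
  # hand-built: 100 probes, 4 differential of which 3 hyper
  fake <- structure(list(table = data.frame(
    class = c(rep("hyper", 3), "hypo", rep("unchanged", 96))),
    groups = c("g1", "g2")), class = "diff_methylation")
  fr <- summarize_fractions(fake)
  expect_equal(fr$pct_differential, 4)
  expect_equal(fr$pct_hyper_among_differential, 75)
  fake0 <- structure(list(table = data.frame(class = rep("unchanged", 10)),
                          groups = c("g1", "g2")), class = "diff_methylation")
  fr0 <- summarize_fractions(fake0)
  expect_equal(fr0$pct_differential, 0)
  expect_true(is.na(fr0$pct_hyper_among_differential))
})

test_that("region categories follow the promoter-first priority", {
  man <- data.frame(
    IlmnID = paste0("cg", 1:7),
    CHR = "chr1", MAPINFO = 1:7,
    UCSC_RefGene_Name = c("A", "A", "A", "A", "A", "", "A;B"),
    UCSC_RefGene_Group = c("Body", "TSS200;Body", "TSS1500;TSS200",
                           "5'UTR;1stExon", "3'UTR", "", "Body;TSS1500"),
    Relation_to_UCSC_CpG_Island = "OpenSea")
  fake <- structure(list(table = data.frame(
    probe = paste0("cg", 1:7), class = "hyper")), class = "diff_methylation")
  pct <- region_distribution(fake, man, "hyper")
  counts <- attr(pct, "counts")
  expect_equal(unname(counts["Gene body"]), 1)
  expect_equal(unname(counts["TSS200"]), 2)   # cg2 and cg3: TSS200 wins
  expect_equal(unname(counts["5'UTR"]), 1)
  expect_equal(unname(counts["3'UTR"]), 1)
  expect_equal(unname(counts["Intergenic"]), 1)
  expect_equal(unname(counts["TSS1500"]), 1)  # cg7: multi-gene, TSS1500 > Body
  expect_equal(sum(pct), 100, tolerance = 1e-9)
  expect_error(region_distribution(fake, man, "hypo"), "no probes")
})

test_that("gene tracks are position-ordered with raw-P significance", {
  cfg <- sim_config(n_meth_probes = 1000, seed = 33)
  meth <- simulate_methylation(cfg)
  retained <- annotation_filter(detection_filter(meth), meth$manifest)
  res <- differential_methylation(meth, retained)
  tr <- gene_track("WNTL1", meth, res)
  expect_true(all(diff(tr$position) >= 0))
  planted <- attr(meth, "planted")
  body_probes <- tr$probe[tr$probe %in% planted$hyper]
  expect_true(all(tr$significant[tr$probe %in% body_probes]))
  expect_true(any(tr$relation == "Island"))
  expect_error(gene_track("NOSUCHGENE", meth, res), "NOSUCHGENE")
})
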