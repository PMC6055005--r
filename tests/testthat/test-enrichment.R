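test_that("one-tailed Fisher matches hand enumeration on the 3/1/1/3 table", {
  # all tables with margins (4,4)/(4,4): upper tail from a=3 is 17/70
  expect_equal(fisher_one_tailed(3, 1, 1, 3), 17 / 70, tolerance = 1e-12)
  expect_equal(fisher_one_tailed(0, 4, 4, 0), 1.0)
  expect_error(fisher_one_tailed(0, 0, 0, 0), "all-zero")
  expect_error(fisher_one_tailed(-1, 1, 1, 1), "non-negative")
})

test_that("one-tailed Fisher equals the enumeration oracle on all small tables", {
  worst <- 0
  for (n in c(8, 12, 20, 40)) {
    set.seed(n)
    for (rep in 1:40) {
      cts <- as.vector(stats::rmultinom(1, n, rep(0.25, 4)))
      if (sum(cts) == 0) next
      p1 <- fisher_one_tailed(cts[1], cts[2], cts[3], cts[4])
      p2 <- enum_fisher_upper(cts[1], cts[2], cts[3], cts[4])
      worst <- max(worst, abs(p1 - p2))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("one-tailed Fisher agrees with stats::fisher.test(greater)", {
  set.seed(77)
  for (rep in 1:20) {
    cts <- as.vector(stats::rmultinom(1, 60, c(0.1, 0.3, 0.2, 0.4)))
    ft <- stats::fisher.test(matrix(cts, 2, 2, byrow = TRUE),
                             alternative = "greater")$p.value
    expect_equal(fisher_one_tailed(cts[1], cts[2], cts[3], cts[4]), ft,
                 tolerance = 1e-10)
  }
})

test_that("BH adjustment reproduces hand-computed step-up sequences", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.011, 0.02, 0.04, 0.045)),
               c(0.025, 0.0275, 1 / 30, 0.045, 0.045), tolerance = 1e-10)
  expect_error(bh_adjust(c(0.1, 0)), "0, 1")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("BH never decreases p-values; adjusted plateaus are fixed points", {
  set.seed(12)
  for (rep in 1:5) {
    p <- runif(30)
    q <- bh_adjust(p)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    # re-adjustment can only move values up, never down
    expect_true(all(bh_adjust(q) >= q - 1e-15))
  }
  # a fully tied plateau (the step-up fixed point) is idempotent
  expect_equal(bh_adjust(rep(0.04, 4)), rep(0.04, 4))
  expect_equal(bh_adjust(bh_adjust(c(0.01, 0.02, 0.03, 0.04))),
               bh_adjust(c(0.01, 0.02, 0.03, 0.04)))
})

test_that("planted signature categories are exactly the significant set", {
  sim <- generate_expression(synthetic_spec(seed = 4))
  ann <- generate_annotations(sim$truth, seed = 4)
  er <- enrich_cluster_categories(sim$truth, ann$catalog, "synthetic")
  sig <- er[er$significant, ]
  expect_setequal(paste(sig$cluster, sig$category),
                  paste(names(ann$signature_categories),
                        ann$signature_categories))
  expect_true(all(er$p_adj >= er$p_raw - 1e-15))
  expect_identical(er$significant, er$p_adj < 0.045)
})

test_that("a universe restricted to one cluster's own targets kills all contrast", {
  p <- toy_partition()
  cat_ <- toy_catalog()
  one <- partition(sprintf("tf%02d", 1:3), rep("A", 3))
  er <- enrich_cluster_categories(one, cat_, "toy")
  expect_true(all(er$p_raw == 1))
})

test_that("permuting cluster labels destroys the planted significance pattern", {
  sim <- generate_expression(synthetic_spec(seed = 9))
  ann <- generate_annotations(sim$truth, seed = 9)
  planted <- paste(names(ann$signature_categories), ann$signature_categories)
  n_planted_sig <- integer(10)
  for (s in 1:10) {
    set.seed(s)
    pp <- partition(sim$truth$ids, sample(unname(sim$truth$labels)))
    er <- enrich_cluster_categories(pp, ann$catalog, "synthetic")
    sig <- er[er$significant, ]
    # the full planted signature set is never recovered under permutation
    expect_false(setequal(paste(sig$cluster, sig$category), planted))
    n_planted_sig[s] <- sum(paste(sig$cluster, sig$category) %in% planted)
  }
  # signal collapses from 4/4 planted pairs to ~0; regulons move as 5-gene
  # blocks under permutation, so isolated borderline hits can survive
  expect_lte(mean(n_planted_sig), 1)
})

test_that("family enrichment works at the TF level with planted biases", {
  sim <- generate_expression(synthetic_spec(seed = 10))
  ann <- generate_annotations(sim$truth, seed = 10)
  er <- enrich_cluster_families(sim$truth, ann$catalog)
  sig <- er[er$significant, ]
  expect_setequal(paste(sig$cluster, sig$category),
                  paste(names(ann$signature_families), ann$signature_families))
  # a family absent from a cluster has upper-tail p = 1
  expect_true(all(er$p_raw[er$a == 0] == 1))
})

test_that("a family perfectly aligned with one cluster attains the minimal p", {
  tfs <- sprintf("tf%02d", 1:20)
  p <- partition(tfs, rep(c("A", "B"), each = 10))
  cat_ <- annotation_catalog(
    tf_family = stats::setNames(rep(c("famX", "famY"), each = 10), tfs))
  er <- enrich_cluster_families(p, cat_)
  best <- er[1, ]
  expect_true(best$cluster %in% c("A", "B"))
  expect_equal(er$p_raw[er$cluster == "A" & er$category == "famX"],
               min(er$p_raw))
})

test_that("a repressor-biased cluster is detected by mode enrichment", {
  tfs <- sprintf("tf%02d", 1:20)
  p <- partition(tfs, rep(c("A", "B"), each = 10))
  set.seed(30)
  mk <- function(tf, modes) data.frame(tf = tf, gene = paste0(tf, "_", seq_along(modes)),
                                       mode = modes)
  tt <- rbind(
    do.call(rbind, lapply(tfs[1:10], function(t) mk(t, rep("repressor", 5)))),
    do.call(rbind, lapply(tfs[11:20], function(t)
      mk(t, sample(c("activator", "dual"), 5, TRUE)))))
  cat_ <- annotation_catalog(tf_targets = tt,
                             tf_evidence = stats::setNames(rep("strong", 20), tfs))
  er <- enrich_regulatory_mode(p, cat_)
  sig <- er[er$significant, ]
  expect_true(any(sig$cluster == "A" & sig$category == "repressor"))
  # single-interaction cluster stays well-defined
  p2 <- partition(c("tf01", "tf11"), c("A", "B"))
  er2 <- enrich_regulatory_mode(p2, cat_)
  expect_true(all(er2$p_raw > 0 & er2$p_raw <= 1))
})

test_that("uniform mode assignment yields no significant modes", {
  bad <- 0L
  for (s in 1:5) {
    set.seed(s)
    tfs <- sprintf("tf%02d", 1:30)
    p <- partition(tfs, rep(1:3, each = 10))
    tt <- data.frame(tf = rep(tfs, each = 6),
                     gene = sprintf("g%03d", 1:180),
                     mode = sample(c("activator", "repressor", "dual"),
                                   180, TRUE))
    cat_ <- annotation_catalog(tf_targets = tt,
                               tf_evidence = stats::setNames(rep("strong", 30), tfs))
    er <- enrich_regulatory_mode(p, cat_)
    if (any(er$significant)) bad <- bad + 1L
  }
  expect_lte(bad, 1L)
})

test_that("comparing a partition against itself puts the diagonal on top", {
  sim <- generate_expression(synthetic_spec(n_rows = 40, seed = 11))
  p <- sim$truth
  er <- compare_clusterings(p, p, level = "tf")
  for (cl in unique(unname(p$labels))) {
    rows <- er[er$cluster == cl, ]
    expect_equal(rows$category[which.min(rows$p_raw)], cl)
  }
})

test_that("a planted refinement is significant against its parent clusters", {
  ids <- sprintf("tf%02d", 1:40)
  parent <- partition(ids, rep(c("P1", "P2"), each = 20))
  child <- partition(ids, rep(c("c1", "c2", "c3", "c4"), each = 10))
  er <- compare_clusterings(child, parent, level = "tf")
  for (ch in c("c1", "c2")) {
    row <- er[er$cluster == ch & er$category == "P1", ]
    expect_true(row$significant)
  }
})

test_that("random relabelings show no overlap signal", {
  sim <- generate_expression(synthetic_spec(n_rows = 60, seed = 12))
  p1 <- sim$truth
  bad <- 0L
  for (s in 1:8) {
    set.seed(s)
    p2 <- partition(p1$ids, sample(unname(p1$labels)))
    er <- compare_clusterings(p1, p2, level = "tf")
    if (any(er$significant)) bad <- bad + 1L
  }
  expect_lte(bad, 1L)
})

test_that("disjoint universes are rejected", {
  p1 <- partition(c("a", "b"), c(1, 2))
  p2 <- partition(c("x", "y"), c(1, 2))
  expect_error(compare_clusterings(p1, p2, level = "tf"), "disjoint")
})

test_that("type-I error is calibrated under a null catalog", {
  rates <- vapply(1:25, function(s) {
    set.seed(s)
    tfs <- sprintf("tf%03d", 1:60)
    truth <- partition(tfs, rep(1:4, each = 15))
    genes <- sprintf("g%03d", 1:300)
    tt <- data.frame(tf = rep(tfs, each = 5), gene = sample(genes, 300),
                     mode = sample(REGULATORY_MODES <- c("activator",
                                   "repressor", "dual"), 300, TRUE))
    gc <- data.frame(gene = sample(genes, 600, TRUE),
                     category = sample(sprintf("cat%02d", 1:10), 600, TRUE))
    cat_ <- annotation_catalog(tf_targets = tt,
                               tf_evidence = stats::setNames(rep("strong", 60), tfs),
                               gene_categories = list(null = gc))
    mean(enrich_cluster_categories(truth, cat_, "null")$p_raw < 0.05)
  }, numeric(1))
  # FET is discrete hence conservative: mean rate must not exceed nominal,
  # and must not collapse to zero either
  expect_lt(mean(rates), 0.07)
  expect_gt(mean(rates), 0.005)
})
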