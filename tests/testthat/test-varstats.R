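toy_features <- function(m) {
  tibble::as_tibble(cbind(
    tibble::tibble(feature_id = sprintf("F%03d", seq_len(nrow(m)))),
    tibble::as_tibble(m, .name_repair = "minimal")
  ))
}

test_that("log transform is exact and errors name the offending cell", {
  f <- toy_features(matrix(c(1, 10, 100, 1000), 2,
                           dimnames = list(NULL, c("r1", "r2"))))
  out <- log_transform(f)
  expect_equal(out$r1, c(0, 1))
  expect_equal(out$r2, c(2, 3))
  # round trip
  back <- out
  for (col in c("r1", "r2")) back[[col]] <- 10^back[[col]]
  expect_equal(back$r1, f$r1)
  bad <- f
  bad$r2[2] <- 0
  expect_error(log_transform(bad), "F002")
})

test_that("pairwise Pearson matches a two-pass covariance oracle", {
  set.seed(23)
  m <- matrix(rnorm(300), 50, 6, dimnames = list(NULL, paste0("r", 1:6)))
  got <- pairwise_pearson(toy_features(m))
  expect_equal(diag(got), setNames(rep(1, 6), paste0("r", 1:6)))
  expect_equal(got, t(got))
  for (i in 1:5) {
    for (j in (i + 1):6) {
      x <- m[, i]; y <- m[, j]
      cv <- sum((x - mean(x)) * (y - mean(y))) / (length(x) - 1)
      r <- cv / sqrt(var(x) * var(y))
      expect_equal(got[i, j], r, tolerance = 1e-12)
    }
  }
  # duplicated column, and a column against its negation
  dup <- toy_features(cbind(a = m[, 1], b = m[, 1], c = -m[, 1]))
  r <- pairwise_pearson(dup)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
})

test_that("zero-variance runs are flagged as undefined", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_warning(r <- pairwise_pearson(toy_features(m)), "Zero-variance")
  expect_true(is.na(r["a", "b"]))
})

test_that("class summary reproduces the weighted-mean combination", {
  a <- tibble::tibble(class = "experimental", mean_r = 0.72, sd = 0.06, n = 50)
  b <- tibble::tibble(class = "experimental", mean_r = 0.58, sd = 0.05, n = 35)
  comb <- combine_class_summaries(list(a, b))
  expect_equal(round(comb$mean_r, 2), 0.66)
  expect_equal(comb$n, 85)
  # block order must not matter
  comb2 <- combine_class_summaries(list(b, a))
  expect_equal(comb$mean_r, comb2$mean_r)
})

test_that("single-sample designs report other classes as ND", {
  set.seed(31)
  m <- matrix(rnorm(200, 10), 50, 4,
              dimnames = list(NULL, paste0("A_T1_R", 1:4)))
  runs <- tibble::tibble(
    run_id = paste0("A_T1_R", 1:4), subject = "A", timepoint = "T1",
    replicate = paste0("R", 1:4)
  )
  cs <- class_summary(pairwise_pearson(toy_features(m)), runs)
  expect_equal(cs$n[cs$class == "experimental"], 6L)
  expect_true(is.na(cs$mean_r[cs$class == "temporal"]))
  expect_true(is.na(cs$mean_r[cs$class == "subject"]))
  expect_true(is.na(glance(cs)$anova_p))
})

test_that("synthetic design recovers the class ordering and ANOVA signal", {
  des <- study_design(seed = 41)
  fs <- simulate_features(des)
  cs <- class_summary(pairwise_pearson(log_transform(fs$features)), fs$runs)
  t <- tidy(cs)
  expect_gt(
    t$mean_r[t$class == "experimental"], t$mean_r[t$class == "temporal"]
  )
  expect_gt(t$mean_r[t$class == "temporal"], t$mean_r[t$class == "subject"])
  expect_lt(glance(cs)$anova_p, 0.05)
})

test_that("ANOVA across classes is not anti-conservative under a true null", {
  # with subject and temporal effects off the three classes share one mean.
  # Pairwise correlations are treated as independent observations although
  # pairs share runs; under that dependence the F-test is conservative, so
  # the check is one-sided: the rejection rate must not exceed the nominal
  # 5% level (plus Monte-Carlo slack)
  rejections <- 0
  for (seed in 1:100) {
    des <- study_design(
      sigma_subject = 0, sigma_time = 0, sigma_tech = 0.3,
      n_features = 60, seed = seed
    )
    fs <- simulate_features(des)
    cs <- suppressWarnings(
      class_summary(pairwise_pearson(log_transform(fs$features)), fs$runs)
    )
    if (glance(cs)$anova_p < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections, 10)
})

test_that("complete-linkage tree equals the brute-force agglomeration", {
  set.seed(47)
  for (i in 1:20) {
    n <- sample(4:7, 1)
    m <- matrix(rnorm(40 * n), 40, n,
                dimnames = list(NULL, paste0("r", seq_len(n))))
    cm <- pairwise_pearson(toy_features(m))
    hc <- hcluster(cm)
    oracle <- oracle_complete_linkage(1 - cm)
    expect_equal(sort(hc$height), sort(oracle$heights), tolerance = 1e-12)
    got <- sort(vapply(clades_of(hc), paste, character(1), collapse = "+"))
    want <- sort(vapply(oracle$clades, paste, character(1), collapse = "+"))
    expect_identical(got, want)
  }
})

test_that("two identical runs merge at height zero", {
  m <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("x", "y")))
  m <- cbind(m, z = m[, "x"])
  hc <- hcluster(pairwise_pearson(toy_features(m)))
  expect_equal(min(hc$height), 0, tolerance = 1e-12)
})

test_that("clustering is invariant to input column order", {
  set.seed(53)
  m <- matrix(rnorm(240), 40, 6, dimnames = list(NULL, paste0("r", 1:6)))
  cm <- pairwise_pearson(toy_features(m))
  perm <- sample(6)
  hc1 <- hcluster(cm)
  hc2 <- hcluster(cm[perm, perm])
  out <- topology_agreement(hc1, hc2)
  expect_true(out$identical)
  expect_equal(sort(hc1$height), sort(hc2$height))
})

test_that("topology agreement detects identity and is symmetric", {
  set.seed(59)
  m <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("r", 1:10)))
  cm <- pairwise_pearson(toy_features(m))
  hc <- hcluster(cm)
  self <- topology_agreement(hc, hc)
  expect_true(self$identical)
  expect_equal(self$distance, 0)
  for (i in 1:100) {
    ma <- matrix(rnorm(120), 20, 6, dimnames = list(NULL, paste0("r", 1:6)))
    mb <- matrix(rnorm(120), 20, 6, dimnames = list(NULL, paste0("r", 1:6)))
    ha <- hcluster(pairwise_pearson(toy_features(ma)))
    hb <- hcluster(pairwise_pearson(toy_features(mb)))
    ab <- topology_agreement(ha, hb)
    ba <- topology_agreement(hb, ha)
    expect_equal(ab$distance, ba$distance)
  }
  # swapping two leaves across subjects changes the topology
  labs <- hc$labels
  swap <- setNames(labs, labs)
  swap[c("r1", "r9")] <- c("r9", "r1")
  hb <- hc
  hb$labels <- unname(swap[hb$labels])
  out <- topology_agreement(hc, hb)
  expect_false(out$identical)
  expect_gt(out$distance, 0)
  expect_error(
    topology_agreement(hc, hb, leaf_map = c(r1 = "x")), "Unmappable"
  )
})

test_that("partition distance matches an ape-derived clade comparison", {
  skip_if_not_installed("ape")
  clade_strings <- function(hc) {
    pp <- ape::prop.part(ape::as.phylo(hc))
    labs <- attr(pp, "labels")
    unique(vapply(
      pp, function(idx) paste(sort(labs[idx]), collapse = "+"), character(1)
    ))
  }
  set.seed(61)
  for (i in 1:20) {
    ma <- matrix(rnorm(160), 20, 8, dimnames = list(NULL, paste0("r", 1:8)))
    mb <- matrix(rnorm(160), 20, 8, dimnames = list(NULL, paste0("r", 1:8)))
    ha <- hcluster(pairwise_pearson(toy_features(ma)))
    hb <- hcluster(pairwise_pearson(toy_features(mb)))
    got <- topology_agreement(ha, hb)$distance
    ca <- clade_strings(ha)
    cb <- clade_strings(hb)
    ref <- length(setdiff(ca, cb)) + length(setdiff(cb, ca))
    expect_equal(got, ref)
  }
})

test_that("PCA conserves variance and reproduces structure", {
  set.seed(67)
  # rank-1 matrix: PC1 carries all variance
  base <- rnorm(30)
  m1 <- outer(base, c(1, 2, 3, 4))
  colnames(m1) <- paste0("r", 1:4)
  p1 <- pca_runs(toy_features(m1 + 10))
  expect_equal(p1$percent_variance[1], 100, tolerance = 1e-9)
  # percentages always total 100
  m <- matrix(rnorm(1200), 100, 12, dimnames = list(NULL, paste0("r", 1:12)))
  p <- pca_runs(toy_features(m))
  expect_equal(sum(p$percent_variance), 100, tolerance = 1e-9)
  # scores reproduce the centred Gram structure
  centred <- t(scale(t(m), center = TRUE, scale = FALSE))
  gram <- crossprod(centred)
  sc <- as.matrix(p$scores[, -1])
  expect_equal(unname(tcrossprod(sc)), unname(gram), tolerance = 1e-8)
  expect_error(pca_runs(toy_features(m[, 1, drop = FALSE])), "at least 2")
})
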