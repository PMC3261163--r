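make_phylo <- function(n_phylo = 24, n_samples = 12, seed = 1) {
  set.seed(seed)
  m <- matrix(
    10^rnorm(n_phylo * n_samples, 2, 0.8), n_phylo, n_samples,
    dimnames = list(
      sprintf("pt%02d", seq_len(n_phylo)), sprintf("s%02d", seq_len(n_samples))
    )
  )
  m
}

test_that("the critical value is the two-sided 5% normal quantile", {
  expect_equal(round(z_critical(0.05), 2), 1.96)
  expect_equal(z_critical(0.317310507862914), 1, tolerance = 1e-9)
  expect_error(z_critical(0), "alpha")
})

test_that("importance Z-scores are standardized and seeds reproduce", {
  m <- make_phylo(seed = 2)
  y <- rnorm(ncol(m))
  prof <- rf_importance(y, m, seed = 5, n_trees = 100)
  expect_equal(mean(prof$z), 0, tolerance = 1e-12)
  expect_equal(sd(prof$z), 1, tolerance = 1e-12)
  expect_identical(prof$significant, prof$z > attr(prof, "z_cutoff"))
  prof2 <- rf_importance(y, m, seed = 5, n_trees = 100)
  expect_identical(prof, prof2)
  prof3 <- rf_importance(y, m, seed = 6, n_trees = 100)
  expect_false(identical(prof$importance, prof3$importance))
})

test_that("a protein copying one phylotype flags that phylotype on top", {
  m <- make_phylo(seed = 3)
  y <- log10(m["pt07", ]) # exact copy, no noise
  prof <- rf_importance(y, m, seed = 11)
  expect_equal(prof$phylotype_id[which.max(prof$z)], "pt07")
  expect_true(prof$significant[prof$phylotype_id == "pt07"])
})

test_that("a constant protein level yields no significant covariates", {
  m <- make_phylo(seed = 4)
  expect_warning(prof <- rf_importance(rep(1, ncol(m)), m, seed = 7),
                 "Constant")
  expect_false(any(prof$significant))
})

test_that("null flag rate sits near the 2.5% normal tail", {
  # the tail calibration holds in the many-covariate regime the method is
  # used in; with small panels the z-scores of a short, skewed importance
  # sample are heavy-tailed and over-flag
  m <- make_phylo(n_phylo = 150, seed = 8)
  rates <- vapply(1:200, function(i) {
    set.seed(5000 + i)
    y <- rnorm(ncol(m))
    prof <- rf_importance(y, m, seed = 9000 + i, n_trees = 200)
    mean(prof$significant)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.025), 0.015)
})

test_that("Fisher enrichment matches the exhaustive 2x2 enumeration", {
  for (n_total in c(6, 9, 12)) {
    for (m_genus in 1:(n_total - 1)) {
      for (n_sig in 0:n_total) {
        for (k in max(0, n_sig - (n_total - m_genus)):min(m_genus, n_sig)) {
          got <- metaproteomr:::fisher_p(k, m_genus, n_sig, n_total)
          want <- oracle_fisher_greater(k, m_genus, n_sig, n_total)
          expect_equal(got, want, tolerance = 1e-12)
          ref <- stats::fisher.test(
            matrix(c(k, n_sig - k, m_genus - k,
                     n_total - m_genus - (n_sig - k)), 2),
            alternative = "greater"
          )$p.value
          expect_equal(got, ref, tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("enrichment tables behave on the worked example and null case", {
  # a genus of 5 phylotypes, all significant, none of the other 95
  profile <- tibble::tibble(
    phylotype_id = sprintf("pt%03d", 1:100),
    significant = c(rep(TRUE, 5), rep(FALSE, 95))
  )
  genus_map <- tibble::tibble(
    phylotype_id = profile$phylotype_id,
    genus = c(rep("target", 5), rep("other", 95))
  )
  out <- fisher_enrich(profile, genus_map)
  p_target <- out$p[out$genus == "target"]
  expect_equal(p_target, 1 / choose(100, 5), tolerance = 1e-9)
  expect_true(out$enriched[out$genus == "target"])
  # no significant phylotypes anywhere: p = 1 for every genus
  profile$significant <- FALSE
  out0 <- fisher_enrich(profile, genus_map)
  expect_true(all(out0$p == 1))
  expect_false(any(out0$enriched))
  dup <- genus_map[c(1, 1, 2), ]
  expect_error(fisher_enrich(profile, dup), "exactly one genus")
})

test_that("Fisher p-values are super-uniform under label permutation", {
  set.seed(71)
  n_total <- 40
  genus_map <- tibble::tibble(
    phylotype_id = sprintf("pt%02d", 1:n_total),
    genus = rep(paste0("g", 1:8), each = 5)
  )
  pvals <- unlist(lapply(1:500, function(i) {
    sig <- sample(c(rep(TRUE, 6), rep(FALSE, n_total - 6)))
    prof <- tibble::tibble(
      phylotype_id = genus_map$phylotype_id, significant = sig
    )
    fisher_enrich(prof, genus_map)$p
  }))
  # anti-conservative behaviour would give P(p <= a) > a
  for (a in c(0.01, 0.05, 0.1, 0.25)) {
    expect_lte(mean(pvals <= a), a + 2 * sqrt(a * (1 - a) / length(pvals)))
  }
})

test_that("category summaries count enriched pairs with conservation", {
  enr <- tibble::tibble(
    accession = c("p1", "p1", "p2", "p3"),
    genus = c("g1", "g2", "g1", "g3"),
    enriched = c(TRUE, FALSE, TRUE, TRUE)
  )
  cats <- tibble::tibble(
    accession = c("p1", "p2", "p3"),
    category = c("G", "EH", NA)
  )
  out <- summarize_categories(enr, cats)
  expect_equal(out$n_associations[out$genus == "g1" & out$category == "G"], 1)
  expect_equal(out$n_associations[out$genus == "g1" & out$category == "E"], 0.5)
  expect_equal(
    out$n_associations[out$genus == "g3" & out$category == "unclassified"], 1
  )
  expect_equal(sum(out$n_associations), sum(enr$enriched))
})

test_that("planted community associations dominate the category summary", {
  com <- generate_community(community_spec(n_taxa = 12, seed = 31))
  st <- generate_study(
    com, study_design(n_planted_associations = 3, seed = 32)
  )
  res <- associate_proteins(
    st$protein_levels[1:40, ], st$phylotypes, st$genus_map, seed = 33,
    n_trees = 200
  )
  expect_equal(
    res$n_significant_pairs, sum(res$importance$significant)
  )
  expect_true(all(
    c("accession", "genus", "p", "enriched") %in% names(res$enrichment)
  ))
})
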