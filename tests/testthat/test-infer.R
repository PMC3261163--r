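test_that("peptide mapping honours tryptic flanks", {
  params <- digestion_params(missed_cleavages = 1)
  ref <- tibble::tibble(
    accession = c("good_flank", "bad_flank"),
    sequence = c("MKAAAAARG", "MAAAAAARG")
  )
  out <- suppressWarnings(map_peptides("AAAAAR", ref, params))
  expect_equal(out$accession[!is.na(out$accession)], "good_flank")
})

test_that("unmapped peptides are retained with a warning", {
  ref <- tibble::tibble(accession = "p1", sequence = "MKAAAAARG")
  expect_warning(out <- map_peptides(c("AAAAAR", "WWWWWR"), ref), "no reference")
  expect_true(is.na(out$accession[out$peptide == "WWWWWR"]))
})

test_that("mapping is independent of peptide input order", {
  ref <- tibble::tibble(
    accession = c("p1", "p2"),
    sequence = c("MKAAAAARGGGK", "AAAAARGGGKCCCK")
  )
  a <- suppressWarnings(map_peptides(c("AAAAAR", "GGGK", "CCCK"), ref))
  b <- suppressWarnings(map_peptides(c("CCCK", "AAAAAR", "GGGK"), ref))
  expect_identical(a, b)
})

test_that("grouping merges equal sets, absorbs subsets, keeps distinct", {
  pm <- function(...) {
    x <- list(...)
    tibble::tibble(
      accession = rep(names(x), lengths(x)),
      peptide = unlist(x)
    )
  }
  # identical peptide sets collapse to one group
  g <- group_proteins(pm(P1 = c("a", "b"), P2 = c("a", "b")))
  expect_equal(nrow(g), 1)
  expect_setequal(g$members[[1]], c("P1", "P2"))
  # strict subset is absorbed
  g <- group_proteins(pm(P1 = c("a", "b"), P2 = "a"))
  expect_equal(nrow(g), 1)
  expect_setequal(g$members[[1]], c("P1", "P2"))
  expect_setequal(g$peptides[[1]], c("a", "b"))
  # overlapping but distinct sets stay separate
  g <- group_proteins(pm(P1 = c("a", "b"), P2 = c("b", "c")))
  expect_equal(nrow(g), 2)
})

test_that("grouping equals the brute-force closure oracle", {
  set.seed(11)
  for (i in 1:1000) {
    n_prot <- sample(2:12, 1)
    n_pep <- sample(2:15, 1)
    peps <- paste0("pep", seq_len(n_pep))
    sets <- lapply(seq_len(n_prot), function(j) {
      sample(peps, sample(1:min(6, n_pep), 1))
    })
    names(sets) <- paste0("P", sprintf("%02d", seq_len(n_prot)))
    pm <- tibble::tibble(
      accession = rep(names(sets), lengths(sets)),
      peptide = unlist(sets)
    )
    got <- group_proteins(pm)
    want <- oracle_group(sets)
    got_part <- sort(unname(vapply(
      got$members, function(m) paste(sort(m), collapse = "+"), character(1)
    )))
    want_part <- sort(unname(vapply(
      want, function(m) paste(sort(m), collapse = "+"), character(1)
    )))
    expect_identical(got_part, want_part)
    # no group's peptide set nested in another's
    for (a in seq_len(nrow(got))) {
      for (b in seq_len(nrow(got))) {
        if (a == b) next
        expect_false(all(got$peptides[[a]] %in% got$peptides[[b]]))
      }
    }
  }
})

test_that("grouping is idempotent, covering, and order-invariant", {
  set.seed(5)
  n_prot <- 10
  sets <- lapply(seq_len(n_prot), function(j) sample(paste0("pep", 1:12),
                                                     sample(1:5, 1)))
  names(sets) <- paste0("P", sprintf("%02d", seq_len(n_prot)))
  pm <- tibble::tibble(
    accession = rep(names(sets), lengths(sets)), peptide = unlist(sets)
  )
  g1 <- group_proteins(pm)
  # union of members covers every mapped protein
  expect_setequal(unlist(g1$members), unique(pm$accession))
  # regrouping the group representatives' peptide sets changes nothing
  pm2 <- tibble::tibble(
    accession = rep(g1$representative, lengths(g1$peptides)),
    peptide = unlist(g1$peptides)
  )
  g2 <- group_proteins(pm2)
  expect_equal(nrow(g2), nrow(g1))
  expect_identical(
    sort(vapply(g2$peptides, paste, character(1), collapse = "|")),
    sort(vapply(g1$peptides, paste, character(1), collapse = "|"))
  )
  # shuffling the map rows leaves the grouping unchanged
  g3 <- group_proteins(pm[sample(nrow(pm)), ])
  expect_identical(g1$members, g3$members)
  expect_identical(g1$representative, g3$representative)
})

test_that("representative choice follows peptides, database, accession", {
  sets <- list(P1 = c("a", "b", "c", "d", "e"), P2 = c("a", "b", "c"))
  expect_equal(representative_name(c("P1", "P2"), sets), "P1")
  # tie on peptide count: isolate-genome database member wins
  sets <- list(P1 = c("a", "b"), P2 = c("a", "c"))
  db <- c(P1 = "metagenome", P2 = "isolate_genomes")
  expect_equal(
    representative_name(c("P1", "P2"), sets, db, "isolate_genomes"), "P2"
  )
  # full tie: lexicographically smallest accession, any input order
  sets <- list(Pa = c("a", "b"), Pb = c("a", "c"))
  db <- c(Pa = "db1", Pb = "db1")
  expect_equal(representative_name(c("Pb", "Pa"), sets, db), "Pa")
  expect_equal(representative_name(c("Pa", "Pb"), sets, db), "Pa")
})

test_that("spectral counting applies policy and the two-peptide filter", {
  groups <- group_proteins(tibble::tibble(
    accession = c("P1", "P1", "P2", "P2", "P3"),
    peptide = c("u1", "sh", "sh", "u2", "only")
  ))
  runs <- run_labels()
  psms <- tibble::tibble(
    peptide = c(rep("u1", 3), "sh", "only"),
    run_id = c("A_T1_R1", "A_T1_R2", "A_T2_R1", "A_T1_R1", "A_T1_R1")
  )
  shared <- count_spectra(groups, psms, runs, policy = "shared")
  # replicates of A_T1 summed; 3 u1 spectra: 2 in A_T1, 1 in A_T2
  g1 <- shared$group_id[shared$representative == "P1"][1]
  expect_equal(
    shared$n_spectra[shared$group_id == g1 & shared$sample_id == "A_T1"],
    2 + 1 # two u1 + one shared-peptide spectrum
  )
  # the shared peptide counts once in each containing group
  g2 <- shared$group_id[shared$representative == "P2"][1]
  expect_equal(
    shared$n_spectra[shared$group_id == g2 & shared$sample_id == "A_T1"], 1
  )
  uniq <- count_spectra(groups, psms, runs, policy = "unique")
  expect_equal(
    uniq$n_spectra[uniq$group_id == g2 & uniq$sample_id == "A_T1"], 0
  )
  # the single-peptide group P3 is excluded from the report
  expect_false("P3" %in% shared$representative)
  with_p3 <- count_spectra(groups, psms, runs, min_peptides = 1)
  expect_true("P3" %in% with_p3$representative)
})
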