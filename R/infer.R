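#' Map identified peptides back to reference proteins
#'
#' Collects, for every accepted peptide, all proteins that contain it as a
#' fully tryptic peptide (valid cleavage flanks, at most
#' `params$missed_cleavages` internal sites). Matching is performed against
#' the tryptic peptide universe of each protein, which is equivalent to an
#' exact substring search with flank checking.
#'
#' @param peptides Character vector (or data frame with a `peptide` column)
#'   of accepted peptide sequences.
#' @param proteins Reference proteins: data frame with `accession`,
#'   `sequence` and optionally `database_id`, or an AAStringSet. Should be
#'   pre-filtered with [filter_database()].
#' @param params A [digestion_params()] object.
#' @return Tibble with columns `peptide`, `accession` and (if available)
#'   `database_id`; peptides matching nothing are retained with `NA`
#'   accession and reported with a warning.
#' @export
map_peptides <- function(peptides, proteins, params = digestion_params()) {
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  peptides <- unique(as.character(peptides))
  proteins <- as_protein_tbl(proteins)
  has_db <- "database_id" %in% names(proteins)

  lookup <- peptide_lookup(proteins, params)
  out <- lookup[lookup$peptide %in% peptides, , drop = FALSE]
  out <- distinct(out)
  unmapped <- setdiff(peptides, out$peptide)
  if (length(unmapped) > 0) {
    warn(paste0(
      length(unmapped), " peptide(s) matched no reference protein."
    ))
    pad <- tibble(accession = NA_character_, peptide = unmapped)
    if (has_db) pad$database_id <- NA_character_
    out <- bind_rows(out, pad)
  }
  cols <- c("peptide", "accession", if (has_db) "database_id")
  out <- out[, cols]
  arrange(out, .data$peptide, .data$accession)
}

# Tryptic-peptide universe of a reference: one row per (accession, peptide).
# A peptide occurs in a protein as a fully tryptic peptide (valid flanks,
# missed-cleavage budget) exactly when it appears in the protein's digest,
# so substring matching with flank checks reduces to this lookup.
peptide_lookup <- function(proteins, params = digestion_params()) {
  proteins <- as_protein_tbl(proteins)
  digests <- map(proteins$sequence, function(s) {
    unique(digest_protein(s, params)$peptide)
  })
  lookup <- tibble(
    accession = rep(proteins$accession, lengths(digests)),
    peptide = unlist(digests)
  )
  if ("database_id" %in% names(proteins)) {
    lookup$database_id <- rep(proteins$database_id, lengths(digests))
  }
  lookup
}

#' Group proteins that are indistinguishable by their identified peptides
#'
#' Proteins identified by exactly the same peptide set are merged into one
#' group, and any protein whose peptide set is a strict subset of another
#' protein's set is absorbed into that protein's group (it contributes no
#' independent evidence). Absorption iterates to a fixpoint, so subset
#' chains collapse into the maximal set; when several maximal supersets
#' exist, the one with more peptides and then the lexicographically smallest
#' accession hosts the subset protein. The surviving groups have pairwise
#' non-nested peptide sets.
#'
#' @param pep_map Peptide-to-protein map as returned by [map_peptides()]
#'   (`peptide`, `accession`, optional `database_id`); rows with `NA`
#'   accession (unmapped peptides) are ignored.
#' @param db_priority Database precedence used for representative naming,
#'   see [representative_name()].
#' @return Tibble of class `mp_groups` with columns `group_id`, `members`
#'   (list of accessions), `representative`, `peptides` (list),
#'   `n_distinct_peptides`, `n_members`.
#' @export
group_proteins <- function(pep_map, db_priority = character(0)) {
  pep_map <- as_tibble(pep_map)
  pep_map <- pep_map[!is.na(pep_map$accession), , drop = FALSE]
  if (nrow(pep_map) == 0) abort("`pep_map` contains no mapped peptides.")

  sets <- split(pep_map$peptide, pep_map$accession)
  sets <- map(sets, ~ sort(unique(.x)))
  accs <- names(sets)

  # 1) merge identical peptide sets
  key <- map_chr(sets, paste, collapse = "\r")
  groups <- split(accs, key)
  group_sets <- map(groups, ~ sets[[.x[1]]])

  # 2) absorb strict subsets into their maximal superset, to fixpoint
  ord <- order(-lengths(group_sets), map_chr(groups, ~ min(.x)))
  groups <- groups[ord]
  group_sets <- group_sets[ord]
  absorbed <- rep(FALSE, length(groups))
  for (i in seq_along(groups)) {
    if (absorbed[i]) next
    for (j in seq_along(groups)) {
      if (i == j || absorbed[j]) next
      if (length(group_sets[[j]]) < length(group_sets[[i]]) &&
          all(group_sets[[j]] %in% group_sets[[i]])) {
        # host j's members in i (i is the first non-absorbed superset in
        # size-then-accession order, i.e. the maximal one)
        groups[[i]] <- c(groups[[i]], groups[[j]])
        absorbed[j] <- TRUE
      }
    }
  }
  groups <- groups[!absorbed]
  group_sets <- group_sets[!absorbed]

  db_map <- accession_db_map(pep_map)
  reps <- map_chr(groups, function(members) {
    representative_name(members, sets[members], db_map, db_priority)
  })
  ord <- order(reps)
  out <- tibble(
    group_id = sprintf("G%04d", seq_along(groups)),
    members = unname(map(groups[ord], sort)),
    representative = unname(reps[ord]),
    peptides = unname(group_sets[ord]),
    n_distinct_peptides = lengths(group_sets[ord]),
    n_members = lengths(groups[ord])
  )
  class(out) <- c("mp_groups", class(out))
  out
}

accession_db_map <- function(pep_map) {
  if (!"database_id" %in% names(pep_map)) {
    return(setNames(character(0), character(0)))
  }
  first_db <- pep_map |>
    group_by(.data$accession) |>
    summarise(database_id = sort(.data$database_id)[1], .groups = "drop")
  setNames(first_db$database_id, first_db$accession)
}

#' Choose the representative protein of a group
#'
#' The member for which most peptides were identified gives the group its
#' name; ties break by database priority (the reference-isolate collection
#' first), then by lexicographically smallest accession, which makes the
#' choice independent of input order.
#'
#' @param members Character vector of member accessions.
#' @param peptide_sets Named list of each member's identified peptides.
#' @param db_map Named character vector accession -> database id (may be
#'   empty).
#' @param db_priority Character vector of database ids in precedence order.
#' @return The representative accession (length-1 character).
#' @export
representative_name <- function(members, peptide_sets,
                                db_map = character(0),
                                db_priority = character(0)) {
  if (length(members) == 0) abort("Empty protein group.")
  n_pep <- map_int(members, ~ length(peptide_sets[[.x]]))
  dbs <- unname(db_map[members])
  prio <- match(dbs, db_priority)
  prio[is.na(prio)] <- length(db_priority) + 1L
  members[order(-n_pep, prio, members)][1]
}

#' Spectral counting per protein group and sample
#'
#' Attributes each accepted PSM to the groups containing its peptide. Under
#' the default `"shared"` policy a PSM adds one count to every group whose
#' peptide set contains the peptide; under `"unique"` only peptides found in
#' exactly one group are counted. Replicate runs of the same biological
#' sample (subject x time point) are summed. Groups identified by fewer
#' than `min_peptides` distinct peptides are dropped from the report.
#'
#' @param groups An `mp_groups` tibble from [group_proteins()].
#' @param psms Accepted target PSMs (`peptide`, `run_id`).
#' @param runs Run annotation (`run_id`, `subject`, `timepoint`).
#' @param policy `"shared"` (default) or `"unique"`.
#' @param min_peptides Distinct-peptide reporting threshold (default 2).
#' @return Long tibble: `group_id`, `representative`, `n_distinct_peptides`,
#'   `subject`, `timepoint`, `sample_id`, `n_spectra`. Zero-count
#'   group x sample cells are present (complete grid).
#' @export
count_spectra <- function(groups, psms, runs,
                          policy = c("shared", "unique"),
                          min_peptides = 2) {
  policy <- match.arg(policy)
  psms <- as_tibble(psms)
  runs <- as_tibble(runs)
  check_psm_cols(psms, c("peptide", "run_id"))

  pep_groups <- tibble(
    group_id = rep(groups$group_id, lengths(groups$peptides)),
    peptide = unlist(groups$peptides)
  )
  if (policy == "unique") {
    shared <- pep_groups |> count(.data$peptide) |> filter(.data$n > 1)
    pep_groups <- pep_groups[!pep_groups$peptide %in% shared$peptide, ,
                             drop = FALSE]
  }
  unmapped <- setdiff(unique(psms$peptide), pep_groups$peptide)
  if (length(unmapped) > 0 && policy == "shared") {
    inform(paste0(
      length(unmapped), " PSM peptide(s) not in any group; excluded."
    ))
  }
  kept <- groups[groups$n_distinct_peptides >= min_peptides, , drop = FALSE]
  samples <- runs |>
    mutate(sample_id = paste(.data$subject, .data$timepoint, sep = "_"))
  hits <- psms |>
    inner_join(pep_groups, by = "peptide", relationship = "many-to-many") |>
    inner_join(samples[, c("run_id", "sample_id")], by = "run_id") |>
    count(.data$group_id, .data$sample_id, name = "n_spectra")
  grid <- tidyr::expand_grid(
    group_id = kept$group_id,
    sample_id = sort(unique(samples$sample_id))
  )
  out <- grid |>
    left_join(hits, by = c("group_id", "sample_id")) |>
    mutate(n_spectra = tidyr::replace_na(.data$n_spectra, 0L)) |>
    left_join(
      kept[, c("group_id", "representative", "n_distinct_peptides")],
      by = "group_id"
    ) |>
    left_join(
      distinct(samples[, c("sample_id", "subject", "timepoint")]),
      by = "sample_id"
    ) |>
    select(
      "group_id", "representative", "n_distinct_peptides",
      "subject", "timepoint", "sample_id", "n_spectra"
    )
  arrange(out, .data$group_id, .data$sample_id)
}
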