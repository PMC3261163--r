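#' Match a peptide against a lineage-annotated reference
#'
#' Returns all accessions in which the peptide occurs as an exact substring
#' with valid tryptic flanks (the "tryptic peptide rule"): the occurrence
#' must start after a cleavage site or at the protein N-terminus, end on a
#' cleavage site or the C-terminus, and contain at most the configured
#' number of missed cleavage sites. Optionally treats isoleucine and
#' leucine as equivalent (they are isobaric in MS).
#'
#' @param peptide A peptide sequence.
#' @param proteins Reference proteins (data frame `accession`, `sequence`,
#'   or AAStringSet).
#' @param params A [digestion_params()] object.
#' @param il_equivalent Treat I and L as identical (default `FALSE`).
#' @return Character vector of matched accessions (possibly empty).
#' @export
match_peptide <- function(peptide, proteins, params = digestion_params(),
                          il_equivalent = FALSE) {
  proteins <- as_protein_tbl(proteins)
  pep <- peptide
  seqs <- proteins$sequence
  if (il_equivalent) {
    pep <- gsub("I", "L", pep, fixed = TRUE)
    seqs <- gsub("I", "L", seqs, fixed = TRUE)
  }
  hit <- map_lgl(seqs, function(s) {
    locs <- stringr::str_locate_all(s, stringr::fixed(pep))[[1]]
    if (nrow(locs) == 0) return(FALSE)
    any(vapply(
      seq_len(nrow(locs)),
      function(i) is_tryptic_occurrence(s, locs[i, 1], locs[i, 2], params),
      logical(1)
    ))
  })
  proteins$accession[hit]
}

#' Lowest common ancestor of a set of lineages
#'
#' Finds the deepest taxonomic rank at which every lineage carries the same
#' non-missing value; a missing value at a rank in any lineage stops the
#' descent above that rank. Disagreement already at the shallowest rank
#' (superkingdom), or an empty input, yields `"unassigned"`.
#'
#' @param lineages Data frame with one row per matched taxon and the rank
#'   columns `superkingdom`, `phylum`, `class`, `order`, `family`, `genus`,
#'   `species` (missing deep ranks as `NA`).
#' @param ranks Ordered rank ladder, shallow to deep.
#' @return A list with `rank` (rank name or `"unassigned"`), `value` (taxon
#'   name or `NA`), and `lineage` (named character vector of the shared
#'   values down to `rank`, `NA` below).
#' @export
#' @examples
#' lin <- tibble::tibble(
#'   superkingdom = "Bacteria", phylum = "Firmicutes",
#'   class = c("Clostridia", "Clostridia"), order = NA_character_,
#'   family = NA_character_, genus = NA_character_, species = NA_character_
#' )
#' lca_lineages(lin)$rank # "class"
lca_lineages <- function(lineages, ranks = TAX_RANKS) {
  lineages <- as_tibble(lineages)
  shared <- setNames(rep(NA_character_, length(ranks)), ranks)
  if (nrow(lineages) == 0) {
    return(list(rank = "unassigned", value = NA_character_, lineage = shared))
  }
  deepest <- NA_character_
  for (r in ranks) {
    vals <- lineages[[r]]
    if (any(is.na(vals)) || length(unique(vals)) != 1) break
    shared[[r]] <- vals[1]
    deepest <- r
  }
  if (is.na(deepest)) {
    return(list(rank = "unassigned", value = NA_character_, lineage = shared))
  }
  list(rank = deepest, value = shared[[deepest]], lineage = shared)
}

#' Taxonomic assignment of identified peptides
#'
#' Matches every peptide against the reference with [match_peptide()],
#' retrieves the matched taxa's lineages and determines the deepest shared
#' level of taxonomic specification (LCA). Spectral counts per peptide are
#' carried so that assignments can be aggregated by [aggregate_taxa()].
#'
#' @param psms Accepted target PSMs (`peptide`; one row per spectrum).
#' @param proteins Reference proteins (`accession`, `sequence`).
#' @param lineage Lineage table (`accession` + rank columns).
#' @param params A [digestion_params()] object.
#' @param il_equivalent Treat I/L as identical (default `FALSE`).
#' @return Tibble: `peptide`, `spectra`, `n_taxa`, `lca_rank`, `lca_value`,
#'   and one column per rank with the shared value (`NA` below the LCA).
#' @export
assign_taxonomy <- function(psms, proteins, lineage,
                            params = digestion_params(),
                            il_equivalent = FALSE) {
  psms <- as_tibble(psms)
  lineage <- as_tibble(lineage)
  spectra <- psms |> count(.data$peptide, name = "spectra")
  lookup <- peptide_lookup(proteins, params)[, c("accession", "peptide")]
  query <- spectra$peptide
  if (il_equivalent) {
    lookup$peptide <- gsub("I", "L", lookup$peptide, fixed = TRUE)
    query <- gsub("I", "L", query, fixed = TRUE)
  }
  hit_sets <- split(lookup$accession, lookup$peptide)[query]
  res <- map(hit_sets, function(accs) {
    lins <- lineage[lineage$accession %in% accs, TAX_RANKS, drop = FALSE]
    lins <- distinct(lins)
    ans <- lca_lineages(lins)
    c(
      list(n_taxa = nrow(lins), lca_rank = ans$rank, lca_value = ans$value),
      as.list(ans$lineage)
    )
  })
  out <- bind_cols(spectra, bind_rows(res))
  arrange(out, .data$peptide)
}

#' Aggregate peptide taxonomy to a rank-level composition
#'
#' Sums spectra per taxon at the requested rank. Peptides whose LCA is
#' shallower than the rank (including fully unassigned peptides) are
#' reported as `"unassigned"` at that rank, so percentages always total
#' 100.
#'
#' @param assignments Output of [assign_taxonomy()].
#' @param rank Aggregation rank, default `"phylum"`.
#' @return Tibble `taxon`, `n_spectra`, `percent`, with the unassigned
#'   bucket last.
#' @export
aggregate_taxa <- function(assignments, rank = "phylum") {
  if (!rank %in% TAX_RANKS) abort("Unknown rank.")
  assignments <- as_tibble(assignments)
  taxon <- assignments[[rank]]
  taxon[is.na(taxon)] <- "unassigned"
  out <- tibble(taxon = taxon, n_spectra = assignments$spectra) |>
    group_by(.data$taxon) |>
    summarise(n_spectra = sum(.data$n_spectra), .groups = "drop") |>
    mutate(percent = 100 * .data$n_spectra / sum(.data$n_spectra))
  bind_rows(
    arrange(
      out[out$taxon != "unassigned", ], dplyr::desc(.data$n_spectra)
    ),
    out[out$taxon == "unassigned", ]
  )
}

#' Compare metaproteome- and phylotype-derived compositions
#'
#' For each phylum and subject, compares the direction of change between the
#' two time points in a metaproteome-derived composition and a
#' 16S/phylotype-derived composition, flagging whether the trends agree.
#' Zero change in both is counted as agreement.
#'
#' @param proteome Tibble `subject`, `timepoint`, `phylum`, `percent`.
#' @param phylo Tibble of the same shape from the phylotype side. Phylum
#'   sets are aligned by union, missing entries treated as 0.
#' @return Tibble `subject`, `phylum`, `delta_proteome`, `delta_phylo`,
#'   `agree`.
#' @export
compare_composition <- function(proteome, phylo) {
  widen <- function(x, nm) {
    x <- as_tibble(x)
    tps <- sort(unique(x$timepoint))
    if (length(tps) != 2) abort("Exactly two time points are required.")
    x |>
      tidyr::pivot_wider(
        id_cols = c("subject", "phylum"),
        names_from = "timepoint", values_from = "percent",
        values_fill = 0
      ) |>
      mutate(delta = .data[[as.character(tps[2])]] -
               .data[[as.character(tps[1])]]) |>
      select("subject", "phylum", "delta") |>
      setNames(c("subject", "phylum", nm))
  }
  a <- widen(proteome, "delta_proteome")
  b <- widen(phylo, "delta_phylo")
  out <- dplyr::full_join(a, b, by = c("subject", "phylum")) |>
    mutate(
      delta_proteome = tidyr::replace_na(.data$delta_proteome, 0),
      delta_phylo = tidyr::replace_na(.data$delta_phylo, 0),
      agree = sign(.data$delta_proteome) == sign(.data$delta_phylo)
    )
  arrange(out, .data$subject, .data$phylum)
}
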