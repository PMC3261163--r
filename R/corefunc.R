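#' Assign COGs from tabular BLAST hits
#'
#' Keeps, per query protein, the best (minimum E-value) hit at or below the
#' E-value cutoff and assigns its COG. Exact E-value ties break by subject
#' identifier order so the assignment is stable under row shuffling.
#'
#' @param blast_hits Data frame in BLAST outfmt-6 dialect; the columns
#'   `qseqid`, `sseqid`, `evalue` are used (see [read_blast_tab()]).
#' @param cutoff Best-hit E-value cutoff, default `1e-10`.
#' @param cog_table Optional tibble (`cog_id`, `category`, ...) joined onto
#'   the result, e.g. the community's COG pool.
#' @return Tibble `accession`, `cog_id`, `evalue` (+ `category` if
#'   `cog_table` given); queries whose best hit fails the cutoff are absent.
#' @export
assign_cog <- function(blast_hits, cutoff = 1e-10, cog_table = NULL) {
  hits <- as_tibble(blast_hits)
  needed <- c("qseqid", "sseqid", "evalue")
  if (!all(needed %in% names(hits))) {
    abort("`blast_hits` needs columns qseqid, sseqid, evalue.")
  }
  bad <- !is.finite(hits$evalue) | hits$evalue < 0 | is.na(hits$sseqid)
  if (any(bad)) {
    warn(paste0("Skipping ", sum(bad), " malformed BLAST row(s)."))
    hits <- hits[!bad, , drop = FALSE]
  }
  hits <- hits[order(hits$qseqid, hits$evalue, hits$sseqid), , drop = FALSE]
  best <- hits[!duplicated(hits$qseqid), , drop = FALSE]
  best <- best[best$evalue <= cutoff, , drop = FALSE]
  cog <- stringr::str_extract(best$sseqid, "COG\\d+")
  cog[is.na(cog)] <- best$sseqid[is.na(cog)]
  out <- tibble(
    accession = best$qseqid,
    cog_id = cog,
    evalue = best$evalue
  )
  if (!is.null(cog_table)) {
    out <- left_join(out, as_tibble(cog_table), by = "cog_id")
  }
  arrange(out, .data$accession)
}

#' Define the core metaproteome
#'
#' A protein group belongs to the core when it has at least one identified
#' peptide (i.e. at least one accepted PSM) in every subject, at any time
#' point.
#'
#' @param groups `mp_groups` tibble from [group_proteins()].
#' @param psms Accepted target PSMs (`peptide`, `run_id`).
#' @param runs Run annotation (`run_id`, `subject`).
#' @return Tibble `group_id`, `representative`, `n_subjects`, `core`
#'   (logical), one row per group.
#' @export
define_core <- function(groups, psms, runs) {
  runs <- as_tibble(runs)
  subjects <- sort(unique(runs$subject))
  if (length(subjects) < 2) {
    abort("Core definition needs at least two subjects.")
  }
  pep_groups <- tibble(
    group_id = rep(groups$group_id, lengths(groups$peptides)),
    peptide = unlist(groups$peptides)
  )
  evidence <- as_tibble(psms) |>
    inner_join(pep_groups, by = "peptide", relationship = "many-to-many") |>
    inner_join(runs[, c("run_id", "subject")], by = "run_id") |>
    distinct(.data$group_id, .data$subject) |>
    count(.data$group_id, name = "n_subjects")
  out <- groups[, c("group_id", "representative")] |>
    as_tibble() |>
    left_join(evidence, by = "group_id") |>
    mutate(
      n_subjects = tidyr::replace_na(.data$n_subjects, 0L),
      core = .data$n_subjects == length(subjects)
    )
  arrange(out, .data$group_id)
}

#' Rank COGs by their share of core-metaproteome spectra
#'
#' Sums spectral counts of core protein groups per COG (through the group
#' representative's assignment) over all samples and expresses each COG's
#' total as a percentage of all core spectra, ranked in descending order.
#'
#' @param core Output of [define_core()] (only rows with `core = TRUE` are
#'   used).
#' @param counts Spectral counts from [count_spectra()].
#' @param cog CogAssignment from [assign_cog()].
#' @param top_n Number of rows to report, default 25; `Inf` for all.
#' @param cog_table Optional (`cog_id`, `definition`, `category`) metadata.
#' @return Tibble `rank`, `cog_id`, (`definition`, `category`,)
#'   `n_spectra`, `percent_of_core_spectra`.
#' @export
rank_cogs <- function(core, counts, cog, top_n = 25, cog_table = NULL) {
  core_ids <- core$group_id[core$core]
  core_counts <- counts[counts$group_id %in% core_ids, , drop = FALSE]
  total <- sum(core_counts$n_spectra)
  joined <- core_counts |>
    left_join(
      as_tibble(cog)[, c("accession", "cog_id")],
      by = c("representative" = "accession")
    )
  assigned <- joined[!is.na(joined$cog_id), , drop = FALSE]
  if (nrow(assigned) == 0 || total == 0) {
    warn("No core spectra carry a COG assignment.")
    return(tibble(
      rank = integer(0), cog_id = character(0),
      n_spectra = integer(0), percent_of_core_spectra = numeric(0)
    ))
  }
  out <- assigned |>
    group_by(.data$cog_id) |>
    summarise(n_spectra = sum(.data$n_spectra), .groups = "drop") |>
    mutate(percent_of_core_spectra = 100 * .data$n_spectra / total) |>
    arrange(dplyr::desc(.data$n_spectra), .data$cog_id) |>
    mutate(rank = row_number())
  if (!is.null(cog_table)) {
    out <- left_join(out, as_tibble(cog_table), by = "cog_id")
  }
  out <- select(
    out, "rank", "cog_id", dplyr::any_of(c("definition", "category")),
    "n_spectra", "percent_of_core_spectra"
  )
  head(out, top_n)
}

#' Roll spectra up to COG functional-category letters
#'
#' Sums spectra per COG category letter (optionally per phylum). COGs with
#' several category letters (e.g. "EH") split their spectra equally across
#' the letters, so total spectra are conserved; with
#' `multi_letter = "first"` the whole count goes to the first letter.
#' Spectra of proteins without a COG fall in the `"not in COG"` bucket and
#' unknown letters in `"unclassified"`.
#'
#' @param counts Tibble with `cog_id` (NA allowed) and `n_spectra`, and
#'   optionally a `phylum` column; e.g. [rank_cogs()] output joined to
#'   taxonomy, or raw per-group counts joined to assignments.
#' @param cog_table Tibble (`cog_id`, `category`) giving each COG's category
#'   letters as a single string.
#' @param multi_letter `"split"` (default) or `"first"`.
#' @return Tibble `category` (+ `phylum` if supplied), `n_spectra` (may be
#'   fractional under the split rule).
#' @export
rollup_categories <- function(counts, cog_table,
                              multi_letter = c("split", "first")) {
  multi_letter <- match.arg(multi_letter)
  counts <- as_tibble(counts)
  cog_table <- as_tibble(cog_table)
  by_phylum <- "phylum" %in% names(counts)
  x <- left_join(counts, cog_table[, c("cog_id", "category")], by = "cog_id")
  x$category[is.na(x$cog_id)] <- "not in COG"
  x$category[!is.na(x$cog_id) & is.na(x$category)] <- "unclassified"
  letters_list <- strsplit(x$category, "")
  letters_list[x$category %in% c("not in COG", "unclassified")] <-
    as.list(x$category[x$category %in% c("not in COG", "unclassified")])
  if (multi_letter == "first") {
    letters_list <- map(letters_list, ~ .x[1])
  }
  expanded <- tibble(
    category = unlist(letters_list),
    n_spectra = rep(
      x$n_spectra / lengths(letters_list), lengths(letters_list)
    )
  )
  if (by_phylum) {
    expanded$phylum <- rep(x$phylum, lengths(letters_list))
    out <- expanded |>
      group_by(.data$phylum, .data$category) |>
      summarise(n_spectra = sum(.data$n_spectra), .groups = "drop")
  } else {
    out <- expanded |>
      group_by(.data$category) |>
      summarise(n_spectra = sum(.data$n_spectra), .groups = "drop")
  }
  arrange(out, dplyr::desc(.data$n_spectra))
}
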