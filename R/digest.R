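#' Digestion parameters
#'
#' Settings for in-silico proteolytic (tryptic) digestion. Trypsin cleaves
#' C-terminally of lysine (K) and arginine (R); `missed_cleavages` controls
#' how many internal cleavage sites a reported peptide may retain, and
#' `proline_rule` optionally suppresses cleavage when the following residue
#' is proline.
#'
#' @param cleavage_residues Character vector of residues cleaved after
#'   (default `c("K", "R")`).
#' @param missed_cleavages Maximum number of internal missed cleavage sites
#'   per peptide (default 1).
#' @param min_peptide_length Minimum peptide length, in residues, used by
#'   database filtering and peptide mapping (default 5).
#' @param proline_rule If `TRUE`, no cleavage before proline. Default `FALSE`.
#' @return An object of class `digestion_params`.
#' @export
#' @examples
#' digestion_params(missed_cleavages = 0)
digestion_params <- function(cleavage_residues = c("K", "R"),
                             missed_cleavages = 1,
                             min_peptide_length = 5,
                             proline_rule = FALSE) {
  if (!all(cleavage_residues %in% AA_ALPHABET)) {
    abort("`cleavage_residues` must be standard amino acids.")
  }
  if (missed_cleavages < 0) abort("`missed_cleavages` must be >= 0.")
  if (min_peptide_length < 1) abort("`min_peptide_length` must be >= 1.")
  structure(
    list(
      cleavage_residues = cleavage_residues,
      missed_cleavages = as.integer(missed_cleavages),
      min_peptide_length = as.integer(min_peptide_length),
      proline_rule = isTRUE(proline_rule)
    ),
    class = "digestion_params"
  )
}

check_aa <- function(sequence) {
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), AA_ALPHABET)
  if (length(bad) > 0) {
    abort(paste0(
      "Sequence contains non-amino-acid characters: ",
      paste(bad, collapse = ", ")
    ))
  }
  invisible(sequence)
}

# Cleavage positions: indices i such that the bond after residue i is cut.
cleavage_sites <- function(sequence, params) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (n < 2) return(integer(0))
  sites <- which(chars[-n] %in% params$cleavage_residues)
  if (params$proline_rule && length(sites) > 0) {
    sites <- sites[chars[sites + 1] != "P"]
  }
  sites
}

#' In-silico tryptic digestion of a protein sequence
#'
#' Cuts a protein after each cleavage residue (subject to the optional
#' proline rule) and enumerates every fully tryptic peptide with at most
#' `params$missed_cleavages` retained internal cleavage sites. Every peptide
#' starts just after a cleavage site (or at the protein N-terminus) and ends
#' at a cleavage site (or the C-terminus). No length filter is applied here;
#' callers impose `min_peptide_length` where their contract requires it.
#'
#' @param sequence Protein sequence (uppercase amino-acid string).
#' @param params A [digestion_params()] object.
#' @return A tibble with columns `peptide`, `start`, `end` (1-based,
#'   inclusive) and `n_missed`.
#' @export
#' @examples
#' digest_protein("MKAAAAARGGGG", digestion_params(missed_cleavages = 1))
digest_protein <- function(sequence, params = digestion_params()) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0) {
    abort("`sequence` must be a single non-empty string.")
  }
  check_aa(sequence)
  n <- nchar(sequence)
  bounds <- c(0L, cleavage_sites(sequence, params), n)
  k <- length(bounds) - 1L # number of base fragments
  out <- vector("list", 0L)
  for (i in seq_len(k)) {
    for (m in 0:params$missed_cleavages) {
      j <- i + m
      if (j > k) break
      out[[length(out) + 1L]] <- list(
        peptide = substr(sequence, bounds[i] + 1L, bounds[j + 1L]),
        start = bounds[i] + 1L,
        end = bounds[j + 1L],
        n_missed = m
      )
    }
  }
  tibble(
    peptide = map_chr(out, "peptide"),
    start = map_int(out, ~ as.integer(.x$start)),
    end = map_int(out, ~ as.integer(.x$end)),
    n_missed = map_int(out, ~ as.integer(.x$n_missed))
  )
}

#' Filter a protein database for searchability
#'
#' Retains proteins that are at least `min_protein_length` residues long and
#' whose tryptic digest yields at least one fully tryptic peptide of length
#' `params$min_peptide_length` or more. Short proteins and proteins without
#' a usable peptide cannot be identified by the search and are removed
#' before decoy generation.
#'
#' @param proteins A data frame with columns `accession` and `sequence`, or a
#'   [Biostrings::AAStringSet] (headers become accessions).
#' @param min_protein_length Minimum protein length in residues (default 33).
#' @param params A [digestion_params()] object.
#' @return Tibble of retained rows (`accession`, `sequence`), attributes
#'   `n_in` and `n_out`.
#' @export
filter_database <- function(proteins, min_protein_length = 33,
                            params = digestion_params()) {
  proteins <- as_protein_tbl(proteins)
  if (nrow(proteins) == 0) {
    warn("Empty protein database; nothing to retain.")
    return(proteins)
  }
  keep <- map_lgl(proteins$sequence, function(s) {
    if (nchar(s) < min_protein_length) return(FALSE)
    peps <- digest_protein(s, params)
    any(nchar(peps$peptide) >= params$min_peptide_length)
  })
  out <- proteins[keep, , drop = FALSE]
  attr(out, "n_in") <- nrow(proteins)
  attr(out, "n_out") <- nrow(out)
  out
}

as_protein_tbl <- function(proteins) {
  if (inherits(proteins, "AAStringSet")) {
    return(tibble(
      accession = names(proteins),
      sequence = as.character(proteins)
    ))
  }
  proteins <- as_tibble(proteins)
  if (!all(c("accession", "sequence") %in% names(proteins))) {
    abort("`proteins` needs columns `accession` and `sequence`.")
  }
  proteins
}

# Is sequence[start..end] a fully tryptic occurrence under `params`?
is_tryptic_occurrence <- function(sequence, start, end, params) {
  n <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1]]
  cleaves_after <- function(i) {
    i >= 1 && i < n && chars[i] %in% params$cleavage_residues &&
      (!params$proline_rule || chars[i + 1] != "P")
  }
  n_term_ok <- start == 1 || cleaves_after(start - 1)
  c_term_ok <- end == n || cleaves_after(end)
  if (!n_term_ok || !c_term_ok) return(FALSE)
  internal <- if (end - 1 >= start) sum(vapply(start:(end - 1), cleaves_after, logical(1))) else 0L
  internal <= params$missed_cleavages
}
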