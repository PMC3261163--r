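#' Write a synthetic community to disk
#'
#' Writes the reference FASTA (headers = accessions), the lineage table,
#' the protein-to-COG table and the BLAST-tabular hit file.
#'
#' @param community An `mp_community` from [generate_community()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "reference.fasta"),
    lineage = file.path(dir, "lineage.tsv"),
    cogs = file.path(dir, "protein_cogs.tsv"),
    blast = file.path(dir, "blast_hits.tsv")
  )
  seqs <- Biostrings::AAStringSet(
    setNames(community$proteins$sequence, community$proteins$accession)
  )
  Biostrings::writeXStringSet(seqs, paths[["fasta"]])
  readr::write_tsv(community$lineage, paths[["lineage"]])
  readr::write_tsv(
    community$proteins[, c("accession", "taxon_id", "cog_id")],
    paths[["cogs"]]
  )
  readr::write_tsv(
    community$blast_hits, paths[["blast"]], col_names = FALSE
  )
  invisible(paths)
}

#' Read a reference FASTA into a protein table
#'
#' @param path FASTA file path.
#' @return Tibble `accession`, `sequence`.
#' @export
read_fasta_proteins <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  tibble(
    accession = sub("\\s.*$", "", names(seqs)),
    sequence = unname(as.character(seqs))
  )
}

#' Write the synthetic study tables to disk
#'
#' Emits the PSM table, feature matrix, phylotype matrix, genus map,
#' protein-level matrix, run annotation and the ground-truth ledger as
#' TSV files.
#'
#' @param study An `mp_study` from [generate_study()].
#' @param dir Output directory.
#' @return Invisibly, the named vector of file paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    runs = file.path(dir, "runs.tsv"),
    psms = file.path(dir, "psms.tsv"),
    features = file.path(dir, "features.tsv"),
    phylotypes = file.path(dir, "phylotypes.tsv"),
    genus_map = file.path(dir, "genus_map.tsv"),
    protein_levels = file.path(dir, "protein_levels.tsv"),
    truth_core = file.path(dir, "truth_core.tsv"),
    truth_planted = file.path(dir, "truth_planted.tsv"),
    truth_psms = file.path(dir, "truth_psm_false.tsv")
  )
  readr::write_tsv(study$runs, paths[["runs"]])
  readr::write_tsv(study$psms, paths[["psms"]])
  readr::write_tsv(study$features, paths[["features"]])
  readr::write_tsv(study$phylotypes, paths[["phylotypes"]])
  readr::write_tsv(study$genus_map, paths[["genus_map"]])
  readr::write_tsv(study$protein_levels, paths[["protein_levels"]])
  readr::write_tsv(tibble(accession = study$truth$core), paths[["truth_core"]])
  readr::write_tsv(study$truth$planted, paths[["truth_planted"]])
  readr::write_tsv(study$truth$psm_false, paths[["truth_psms"]])
  invisible(paths)
}

#' Read a PSM table
#'
#' @param path TSV with columns `spectrum_id`, `run_id`, `peptide`,
#'   `score`, `database_id`, `is_decoy`.
#' @return Tibble of PSMs.
#' @export
read_psm_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  check_psm_cols(out, c("spectrum_id", "run_id", "peptide", "score",
                        "database_id", "is_decoy"))
  out
}

#' Read a 12-column BLAST tabular (outfmt 6) file
#'
#' @param path File path.
#' @return Tibble with the standard outfmt-6 column names.
#' @export
read_blast_tab <- function(path) {
  readr::read_tsv(
    path,
    col_names = c(
      "qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
      "qstart", "qend", "sstart", "send", "evalue", "bitscore"
    ),
    show_col_types = FALSE
  )
}

#' Export a dendrogram in Newick format
#'
#' @param hc An [stats::hclust] object.
#' @param path Output file.
#' @return Invisibly, the Newick string.
#' @export
write_newick <- function(hc, path) {
  hc <- stats::as.hclust(hc)
  node <- function(i) {
    if (i < 0) return(hc$labels[-i])
    h <- hc$height[i]
    kids <- map_chr(hc$merge[i, ], function(x) {
      child_h <- if (x < 0) 0 else hc$height[x]
      paste0(node(x), ":", format(h - child_h, digits = 8))
    })
    paste0("(", paste(kids, collapse = ","), ")")
  }
  nwk <- paste0(node(nrow(hc$merge)), ";")
  writeLines(nwk, path)
  invisible(nwk)
}
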