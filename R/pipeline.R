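#' Pipeline configuration
#'
#' Collects the thresholds of every stage with their published defaults:
#' 5% PSM-level FDR, two or more distinct peptides per reported protein,
#' best BLAST hit at E <= 1e-10 for COG assignment, phylum-level taxonomy
#' roll-up, a 500-tree random forest with the |Z| > 1.96 importance cutoff
#' and Fisher enrichment at p < 0.05.
#'
#' @param alpha_fdr PSM false discovery rate, default 0.05.
#' @param min_peptides Distinct-peptide reporting filter, default 2.
#' @param blast_cutoff COG best-hit E-value cutoff, default 1e-10.
#' @param lca_rank Taxonomy aggregation rank, default `"phylum"`.
#' @param n_trees Random-forest size, default 500.
#' @param alpha_assoc Significance level of the association stages, 0.05.
#' @param count_policy Spectral counting policy, `"shared"` or `"unique"`.
#' @param db_priority Database precedence for tie-breaks.
#' @param params [digestion_params()] used for digestion and mapping.
#' @param seed Integer seed for the stochastic association stage.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(alpha_fdr = 0.05, min_peptides = 2,
                            blast_cutoff = 1e-10, lca_rank = "phylum",
                            n_trees = 500, alpha_assoc = 0.05,
                            count_policy = "shared",
                            db_priority = "isolate_genomes",
                            params = digestion_params(), seed = 1) {
  if (alpha_fdr <= 0 || alpha_fdr > 1) abort("`alpha_fdr` must be in (0, 1].")
  if (alpha_assoc <= 0 || alpha_assoc > 1) {
    abort("`alpha_assoc` must be in (0, 1].")
  }
  if (blast_cutoff <= 0) abort("`blast_cutoff` must be positive.")
  if (min_peptides < 1) abort("`min_peptides` must be >= 1.")
  if (!lca_rank %in% TAX_RANKS) abort("Unknown `lca_rank`.")
  structure(
    list(
      alpha_fdr = alpha_fdr, min_peptides = as.integer(min_peptides),
      blast_cutoff = blast_cutoff, lca_rank = lca_rank,
      n_trees = as.integer(n_trees), alpha_assoc = alpha_assoc,
      count_policy = count_policy, db_priority = db_priority,
      params = params, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Validate pipeline inputs
#'
#' Checks the study bundle and reference for structural problems without
#' raising: sequence alphabet, PSM column schema and value ranges, feature
#' matrix completeness and positivity, run label consistency, and lineage
#' coverage of the reference accessions.
#'
#' @param study An `mp_study` (or a compatible list of tables).
#' @param community An `mp_community` (or compatible list).
#' @return Tibble `stage`, `problem`; zero rows when everything is
#'   well-formed.
#' @export
validate_inputs <- function(study, community) {
  problems <- list()
  note <- function(stage, msg) {
    problems[[length(problems) + 1L]] <<- tibble(stage = stage, problem = msg)
  }

  prot <- community$proteins
  if (is.null(prot) || !all(c("accession", "sequence") %in% names(prot))) {
    note("identify", "reference proteins missing accession/sequence columns")
  } else {
    bad <- !grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"),
                  prot$sequence)
    if (any(bad)) {
      note("identify", paste0(
        sum(bad), " reference sequence(s) contain non-amino-acid characters"
      ))
    }
    if (anyDuplicated(prot$accession) > 0) {
      note("identify", "duplicated reference accessions")
    }
  }

  lin <- community$lineage
  if (is.null(lin) || !"accession" %in% names(lin) ||
      !"superkingdom" %in% names(lin)) {
    note("taxassign", "lineage table missing or lacks accession/superkingdom")
  } else if (!is.null(prot) && "accession" %in% names(prot)) {
    uncovered <- setdiff(prot$accession, lin$accession)
    if (length(uncovered) > 0) {
      note("taxassign", paste0(
        length(uncovered), " accession(s) missing from the lineage table"
      ))
    }
  }

  psms <- study$psms
  needed <- c("spectrum_id", "run_id", "peptide", "score", "database_id",
              "is_decoy")
  if (is.null(psms) || !all(needed %in% names(psms))) {
    note("identify", "PSM table lacks required columns")
  } else {
    if (any(!is.finite(psms$score) | psms$score <= 0)) {
      note("identify", "PSM table contains non-positive scores")
    }
    if (any(!grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"),
                   psms$peptide))) {
      note("identify", "PSM table contains malformed peptides")
    }
    if (!is.null(study$runs) &&
        length(setdiff(psms$run_id, study$runs$run_id)) > 0) {
      note("identify", "PSM run ids not present in the run annotation")
    }
  }

  feats <- study$features
  if (!is.null(feats)) {
    m <- feats[, feature_run_cols(feats)]
    if (anyNA(m)) note("varstats", "feature matrix has missing cells")
    if (any(unlist(m) <= 0, na.rm = TRUE)) {
      note("varstats", "feature matrix has non-positive intensities")
    }
  } else {
    note("varstats", "feature matrix absent")
  }

  runs <- study$runs
  if (is.null(runs) ||
      !all(c("run_id", "subject", "timepoint") %in% names(runs))) {
    note("varstats", "run annotation missing or incomplete")
  } else if (anyDuplicated(runs$run_id) > 0) {
    note("varstats", "duplicated run ids")
  }

  if (length(problems) == 0) {
    return(tibble(stage = character(0), problem = character(0)))
  }
  bind_rows(problems)
}

#' Run the full metaproteomics pipeline
#'
#' Executes the stages in order: per-database FDR filtering of PSMs,
#' cross-database conflict resolution, peptide-to-protein mapping and
#' grouping, spectral counting, core definition, COG assignment and
#' ranking, category roll-up, peptide taxonomy with phylum aggregation,
#' variance-class correlation analysis (with hierarchical clustering and
#' PCA), and random-forest protein-phylotype association with genus
#' enrichment. Record counts in and out of each filter are logged.
#'
#' @param study An `mp_study` from [generate_study()] (or equivalently
#'   shaped tables read from disk).
#' @param community An `mp_community` reference.
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage messages, default `TRUE`.
#' @return An `mp_report` list with one element per stage output plus
#'   `log` (stage, records_in, records_out) and `config`.
#' @export
run_pipeline <- function(study, community, config = pipeline_config(),
                         quiet = TRUE) {
  log <- list()
  note <- function(stage, n_in, n_out) {
    log[[length(log) + 1L]] <<- tibble(
      stage = stage, records_in = n_in, records_out = n_out
    )
    if (!quiet) inform(sprintf("%s: %d -> %d", stage, n_in, n_out))
  }
  stage_try <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Stage '", stage, "' failed: ", conditionMessage(e)))
    })
  }

  # identify ---------------------------------------------------------------
  reference <- stage_try("identify", filter_database(
    community$proteins, params = config$params
  ))
  accepted <- stage_try("identify", {
    by_db <- split(as_tibble(study$psms), study$psms$database_id)
    filt <- map(by_db, filter_at_fdr, alpha = config$alpha_fdr)
    combined <- bind_rows(map(filt, as_tibble))
    resolve_cross_database(combined, db_priority = config$db_priority)
  })
  note("identify", nrow(study$psms), nrow(accepted))

  # infer ------------------------------------------------------------------
  pep_map <- stage_try("infer", suppressWarnings(map_peptides(
    accepted$peptide, reference, params = config$params
  )))
  groups <- stage_try("infer", group_proteins(
    pep_map, db_priority = config$db_priority
  ))
  counts <- stage_try("infer", suppressMessages(count_spectra(
    groups, accepted, study$runs,
    policy = config$count_policy, min_peptides = config$min_peptides
  )))
  note("infer", nrow(accepted), nrow(groups))

  # corefunc ---------------------------------------------------------------
  core <- stage_try("corefunc", define_core(groups, accepted, study$runs))
  cog <- stage_try("corefunc", assign_cog(
    community$blast_hits, cutoff = config$blast_cutoff,
    cog_table = community$cog_pool
  ))
  cog_ranking <- stage_try("corefunc", rank_cogs(
    core, counts, cog, top_n = 25, cog_table = community$cog_pool
  ))
  categories <- stage_try("corefunc", {
    per_group <- counts |>
      group_by(.data$group_id, .data$representative) |>
      summarise(n_spectra = sum(.data$n_spectra), .groups = "drop") |>
      left_join(cog[, c("accession", "cog_id")],
                by = c("representative" = "accession"))
    rollup_categories(per_group, community$cog_pool)
  })
  note("corefunc", nrow(groups), sum(core$core))

  # taxassign --------------------------------------------------------------
  if (is.null(community$lineage)) {
    abort("Stage 'taxassign' failed: lineage table is missing.")
  }
  taxonomy <- stage_try("taxassign", assign_taxonomy(
    accepted, reference, community$lineage, params = config$params
  ))
  composition <- stage_try(
    "taxassign", aggregate_taxa(taxonomy, rank = config$lca_rank)
  )
  note("taxassign", nrow(taxonomy), nrow(composition))

  # varstats ---------------------------------------------------------------
  logged <- stage_try("varstats", log_transform(study$features))
  cor_mat <- stage_try("varstats", pairwise_pearson(logged))
  variation <- stage_try("varstats", class_summary(cor_mat, study$runs))
  sample_cor <- stage_try("varstats", {
    avg <- average_replicates(logged, study$runs)
    pairwise_pearson(avg)
  })
  tree <- stage_try("varstats", hcluster(sample_cor))
  pca <- stage_try("varstats", pca_runs(logged))
  note("varstats", nrow(study$features), nrow(variation))

  # assoc ------------------------------------------------------------------
  assoc <- stage_try("assoc", associate_proteins(
    study$protein_levels, study$phylotypes, study$genus_map,
    seed = config$seed, n_trees = config$n_trees,
    alpha = config$alpha_assoc
  ))
  cat_map <- tibble(
    accession = community$proteins$accession,
    category = community$cog_pool$category[
      match(community$proteins$cog_id, community$cog_pool$cog_id)
    ]
  )
  assoc_categories <- stage_try("assoc", summarize_categories(
    assoc$enrichment, cat_map
  ))
  note("assoc", nrow(study$protein_levels), assoc$n_enriched_pairs)

  structure(
    list(
      reference = reference, accepted_psms = accepted, peptide_map = pep_map,
      groups = groups, counts = counts, core = core, cog = cog,
      cog_ranking = cog_ranking, categories = categories,
      taxonomy = taxonomy, composition = composition,
      correlations = cor_mat, variation = variation,
      sample_correlations = sample_cor, tree = tree, pca = pca,
      associations = assoc, association_categories = assoc_categories,
      log = bind_rows(log), config = config
    ),
    class = "mp_report"
  )
}

#' Average replicate runs into per-sample profiles
#'
#' @param features (Log) feature tibble.
#' @param runs Run annotation with `run_id`, `subject`, `timepoint`.
#' @return Feature tibble with one column per sample (subject_timepoint).
#' @export
average_replicates <- function(features, runs) {
  features <- as_tibble(features)
  runs <- as_tibble(runs)
  meta_cols <- intersect(names(features), c("feature_id", "mz", "rt"))
  samples <- runs |>
    mutate(sample_id = paste(.data$subject, .data$timepoint, sep = "_"))
  out <- features[, meta_cols]
  for (sid in sort(unique(samples$sample_id))) {
    cols <- samples$run_id[samples$sample_id == sid]
    cols <- intersect(cols, names(features))
    out[[sid]] <- rowMeans(features[, cols, drop = FALSE])
  }
  out
}

#' @export
print.mp_report <- function(x, ...) {
  cat("metaproteomics pipeline report\n")
  cat("  accepted PSMs:     ", nrow(x$accepted_psms), "\n")
  cat("  protein groups:    ", nrow(x$groups), "\n")
  cat("  core groups:       ", sum(x$core$core), "\n")
  cat("  enriched pairs:    ", x$associations$n_enriched_pairs, "\n")
  invisible(x)
}
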