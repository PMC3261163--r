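#' Two-sided standard-normal critical value
#'
#' The Z threshold corresponding to a two-sided significance level `alpha`
#' (1.959964 for `alpha = 0.05`); importances exceeding it are significantly
#' different from zero at `p < alpha`.
#'
#' @param alpha Two-sided significance level, default 0.05.
#' @return Numeric critical value.
#' @export
z_critical <- function(alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  qnorm(1 - alpha / 2)
}

#' Random-forest importance screening of one protein against phylotypes
#'
#' Predicts a protein's per-sample level from the phylotype abundance
#' profiles with a random-forest regression, Z-scores the per-phylotype
#' variable importances (mean 0, SD 1 across phylotypes), and flags as
#' significant the phylotypes whose Z exceeds the two-sided 5% normal
#' critical value (1.96 by default).
#'
#' @param protein_level Numeric vector of the protein's level per sample
#'   (log scale), aligned with the phylotype matrix columns.
#' @param phylotypes Phylotype abundance tibble: `phylotype_id` plus one
#'   column per sample, or a numeric matrix (phylotypes x samples).
#' @param seed Integer seed for the forest (mandatory for reproducibility).
#' @param n_trees Number of trees, default 500.
#' @param importance `"permutation"` (default; mean decrease in accuracy)
#'   or `"impurity"` (mean decrease in node impurity).
#' @param alpha Two-sided level defining the Z cutoff, default 0.05.
#' @return An `mp_importance` tibble: `phylotype_id`, `importance`, `z`,
#'   `significant`; attributes `seed`, `n_trees`, `z_cutoff`.
#' @export
rf_importance <- function(protein_level, phylotypes, seed,
                          n_trees = 500,
                          importance = c("permutation", "impurity"),
                          alpha = 0.05) {
  importance <- match.arg(importance)
  if (missing(seed)) abort("`seed` is required.")
  mat <- phylotype_matrix(phylotypes)
  if (length(protein_level) != ncol(mat)) {
    abort("`protein_level` must have one value per phylotype-matrix column.")
  }
  if (length(protein_level) < 4) abort("Need at least 4 samples.")
  x <- t(mat)
  colnames(x) <- rownames(mat)
  cutoff <- z_critical(alpha)
  if (sd(protein_level) == 0) {
    warn("Constant protein level; no covariate can be significant.")
    out <- tibble(
      phylotype_id = rownames(mat),
      importance = 0, z = NA_real_, significant = FALSE
    )
    return(structure(
      out, seed = seed, n_trees = n_trees, z_cutoff = cutoff,
      class = c("mp_importance", class(out))
    ))
  }
  withr::with_seed(as.integer(seed), {
    fit <- randomForest::randomForest(
      x = x, y = protein_level, ntree = n_trees, importance = TRUE
    )
  })
  # raw (unscaled) permutation importance, the quantity the forest stores;
  # dividing by the permutation SE is an optional extra step that loses
  # power at small sample sizes
  type <- if (importance == "permutation") 1 else 2
  imp <- randomForest::importance(fit, type = type, scale = FALSE)[, 1]
  z <- as.numeric(scale(imp))
  out <- tibble(
    phylotype_id = rownames(mat),
    importance = unname(imp),
    z = z,
    significant = !is.na(z) & z > cutoff
  )
  structure(
    out, seed = seed, n_trees = n_trees, z_cutoff = cutoff,
    class = c("mp_importance", class(out))
  )
}

phylotype_matrix <- function(phylotypes) {
  if (is.matrix(phylotypes)) {
    if (is.null(rownames(phylotypes))) {
      rownames(phylotypes) <- paste0("pt", seq_len(nrow(phylotypes)))
    }
    return(phylotypes)
  }
  phylotypes <- as_tibble(phylotypes)
  if (!"phylotype_id" %in% names(phylotypes)) {
    abort("`phylotypes` needs a `phylotype_id` column.")
  }
  m <- as.matrix(phylotypes[, setdiff(names(phylotypes), "phylotype_id")])
  rownames(m) <- phylotypes$phylotype_id
  m
}

#' @exportS3Method generics::glance
glance.mp_importance <- function(x, ...) {
  tibble(
    n_phylotypes = nrow(x),
    n_significant = sum(x$significant),
    z_cutoff = attr(x, "z_cutoff"),
    n_trees = attr(x, "n_trees"),
    seed = attr(x, "seed")
  )
}

#' Genus-level Fisher exact enrichment of significant phylotypes
#'
#' Tests, per genus-like group, whether the phylotypes flagged significant
#' for a protein are enriched in that genus, using the one-sided
#' (enrichment) Fisher exact test on the 2x2 table significant/other x
#' in-genus/out-of-genus (hypergeometric tail probability). Genera with no
#' phylotypes are skipped.
#'
#' @param profile An `mp_importance` tibble (or any tibble with
#'   `phylotype_id` and `significant`).
#' @param genus_map Tibble `phylotype_id`, `genus`; every phylotype must map
#'   to exactly one genus.
#' @param alpha Significance level, default 0.05.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return Tibble `genus`, `k` (significant in genus), `m` (genus size),
#'   `n_sig` (significant total), `n_total`, `p`, `enriched`.
#' @export
fisher_enrich <- function(profile, genus_map, alpha = 0.05,
                          alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  profile <- as_tibble(profile)
  genus_map <- as_tibble(genus_map)
  if (anyDuplicated(genus_map$phylotype_id) > 0) {
    abort("Every phylotype must map to exactly one genus.")
  }
  x <- inner_join(
    profile[, c("phylotype_id", "significant")], genus_map,
    by = "phylotype_id"
  )
  n_total <- nrow(x)
  n_sig <- sum(x$significant)
  out <- x |>
    group_by(.data$genus) |>
    summarise(
      k = sum(.data$significant),
      m = dplyr::n(),
      .groups = "drop"
    )
  out$n_sig <- n_sig
  out$n_total <- n_total
  out$p <- map_dbl(
    seq_len(nrow(out)),
    function(i) fisher_p(out$k[i], out$m[i], n_sig, n_total, alternative)
  )
  out$enriched <- out$p < alpha
  arrange(out, .data$p, .data$genus)
}

# Exact 2x2 p-value: k significant phylotypes in a genus of size m, n_sig
# significant among n_total. One-sided = hypergeometric upper tail;
# two-sided = sum of table probabilities <= observed (fisher.test rule).
fisher_p <- function(k, m, n_sig, n_total, alternative = "greater") {
  if (alternative == "greater") {
    return(phyper(k - 1, m, n_total - m, n_sig, lower.tail = FALSE))
  }
  support <- max(0, n_sig - (n_total - m)):min(m, n_sig)
  dens <- stats::dhyper(support, m, n_total - m, n_sig)
  obs <- stats::dhyper(k, m, n_total - m, n_sig)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

#' Associate every protein with microbiota phylotypes
#'
#' Runs [rf_importance()] and [fisher_enrich()] for each protein-level row
#' and collects all protein-genus enrichment results. Seeds for individual
#' forests are drawn deterministically from `seed`.
#'
#' @param protein_levels Tibble `accession` plus one column per sample
#'   (log-scale protein levels).
#' @param phylotypes Phylotype abundance tibble (`phylotype_id` + the same
#'   sample columns).
#' @param genus_map Tibble `phylotype_id`, `genus`.
#' @param seed Integer master seed.
#' @param n_trees Trees per forest, default 500.
#' @param alpha Significance level for both stages, default 0.05.
#' @return List of class `mp_assoc`: `importance` (long tibble with
#'   `accession`), `enrichment` (per protein-genus), `n_significant_pairs`
#'   (protein-phylotype flags), `n_enriched_pairs`.
#' @export
associate_proteins <- function(protein_levels, phylotypes, genus_map,
                               seed, n_trees = 500, alpha = 0.05) {
  if (missing(seed)) abort("`seed` is required.")
  protein_levels <- as_tibble(protein_levels)
  mat <- phylotype_matrix(phylotypes)
  sample_cols <- colnames(mat)
  if (!all(sample_cols %in% names(protein_levels))) {
    abort("Protein-level and phylotype matrices must share sample columns.")
  }
  seeds <- as.integer(seed) + seq_len(nrow(protein_levels))
  res <- map(seq_len(nrow(protein_levels)), function(i) {
    y <- as.numeric(protein_levels[i, sample_cols])
    prof <- rf_importance(
      y, mat, seed = seeds[i], n_trees = n_trees, alpha = alpha
    )
    enr <- fisher_enrich(prof, genus_map, alpha = alpha)
    list(
      importance = mutate(
        as_tibble(prof), accession = protein_levels$accession[i],
        .before = 1
      ),
      enrichment = mutate(
        enr, accession = protein_levels$accession[i], .before = 1
      )
    )
  })
  importance <- bind_rows(map(res, "importance"))
  enrichment <- bind_rows(map(res, "enrichment"))
  structure(
    list(
      importance = importance,
      enrichment = enrichment,
      n_significant_pairs = sum(importance$significant),
      n_enriched_pairs = sum(enrichment$enriched)
    ),
    class = "mp_assoc"
  )
}

#' Summarise enriched associations per genus and COG category
#'
#' Counts, per genus and COG functional-category letter, the enriched
#' (protein, genus) pairs; proteins in a multi-letter category split their
#' pairs equally across letters (conserving the total), and proteins
#' without a COG are bucketed as `"unclassified"`. Intended for
#' log10-colour-keyed heatmap display.
#'
#' @param enrichment Enrichment tibble with `accession`, `genus`,
#'   `enriched` (e.g. `associate_proteins()$enrichment`).
#' @param protein_categories Tibble `accession`, `category` (letter string,
#'   NA for no COG).
#' @return Tibble `genus`, `category`, `n_associations` (fractional under
#'   the split rule).
#' @export
summarize_categories <- function(enrichment, protein_categories) {
  enrichment <- as_tibble(enrichment)
  pairs <- enrichment[enrichment$enriched, c("accession", "genus")]
  if (nrow(pairs) == 0) {
    return(tibble(
      genus = character(0), category = character(0),
      n_associations = numeric(0)
    ))
  }
  x <- left_join(pairs, as_tibble(protein_categories), by = "accession")
  x$category[is.na(x$category)] <- "unclassified"
  letters_list <- strsplit(x$category, "")
  letters_list[x$category == "unclassified"] <- list("unclassified")
  out <- tibble(
    genus = rep(x$genus, lengths(letters_list)),
    category = unlist(letters_list),
    w = rep(1 / lengths(letters_list), lengths(letters_list))
  ) |>
    group_by(.data$genus, .data$category) |>
    summarise(n_associations = sum(.data$w), .groups = "drop")
  arrange(out, dplyr::desc(.data$n_associations))
}
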