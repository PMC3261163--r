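#' Log-transform a feature intensity matrix
#'
#' @param features Feature matrix tibble: `feature_id` (plus optional `mz`,
#'   `rt` metadata columns) and one intensity column per run. All
#'   intensities must be strictly positive.
#' @param base Logarithm base, default 10.
#' @return The same tibble with intensity columns log-transformed.
#' @export
log_transform <- function(features, base = 10) {
  features <- as_tibble(features)
  run_cols <- feature_run_cols(features)
  for (col in run_cols) {
    v <- features[[col]]
    if (any(!is.finite(v) | v <= 0)) {
      i <- which(!is.finite(v) | v <= 0)[1]
      abort(paste0(
        "Non-positive intensity in run '", col, "', feature '",
        features$feature_id[i], "'."
      ))
    }
    features[[col]] <- log(v, base = base)
  }
  features
}

feature_run_cols <- function(features) {
  setdiff(names(features), c("feature_id", "mz", "rt"))
}

feature_matrix <- function(features) {
  run_cols <- feature_run_cols(features)
  m <- as.matrix(features[, run_cols])
  rownames(m) <- features$feature_id
  m
}

#' Pairwise Pearson correlations between runs
#'
#' @param features (Log-transformed) feature tibble, runs as columns.
#' @return Symmetric run-by-run correlation matrix with unit diagonal.
#'   Zero-variance runs produce `NA` entries and a warning.
#' @export
pairwise_pearson <- function(features) {
  m <- feature_matrix(as_tibble(features))
  if (nrow(m) < 2) abort("Need at least 2 features.")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    warn(paste0(
      "Zero-variance run(s): ",
      paste(colnames(m)[sds == 0], collapse = ", "),
      "; correlations undefined (NA)."
    ))
  }
  suppressWarnings(cor(m, method = "pearson"))
}

classify_run_pairs <- function(cor_mat, runs) {
  runs <- as_tibble(runs)
  ids <- colnames(cor_mat)
  missing_runs <- setdiff(ids, runs$run_id)
  if (length(missing_runs) > 0) {
    abort(paste0("Unlabelled run(s): ", paste(missing_runs, collapse = ", ")))
  }
  lab <- runs[match(ids, runs$run_id), ]
  pairs <- which(upper.tri(cor_mat), arr.ind = TRUE)
  tibble(
    run_a = ids[pairs[, 1]],
    run_b = ids[pairs[, 2]],
    r = cor_mat[pairs],
    class = dplyr::case_when(
      lab$subject[pairs[, 1]] != lab$subject[pairs[, 2]] ~ "subject",
      lab$timepoint[pairs[, 1]] != lab$timepoint[pairs[, 2]] ~ "temporal",
      TRUE ~ "experimental"
    )
  )
}

#' Variance-class summary of pairwise sample similarities
#'
#' Classifies every off-diagonal run pair as experimental (same subject and
#' time point, different preparation/run), temporal (same subject,
#' different time point) or subject (different subjects), and reports the
#' mean, SD and number of pairwise Pearson correlations per class, together
#' with a one-way ANOVA p-value across classes (each pairwise correlation
#' treated as one observation). Classes without pairs are reported as ND
#' (`NA` values).
#'
#' @param cor_mat Run-by-run correlation matrix from [pairwise_pearson()].
#' @param runs Run annotation (`run_id`, `subject`, `timepoint`).
#' @return An `mp_variation` object: tibble `class`, `mean_r`, `sd`, `n`
#'   with attributes `anova_p` and `pairs` (the per-pair table).
#' @export
class_summary <- function(cor_mat, runs) {
  pairs <- classify_run_pairs(cor_mat, runs)
  lvl <- c("experimental", "temporal", "subject")
  smry <- pairs |>
    group_by(class = factor(.data$class, levels = lvl)) |>
    summarise(
      mean_r = mean(.data$r),
      sd = sd(.data$r),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    tidyr::complete(
      class, fill = list(mean_r = NA_real_, sd = NA_real_, n = 0L)
    ) |>
    mutate(class = as.character(class))
  present <- unique(pairs$class)
  anova_p <- NA_real_
  if (length(present) >= 2) {
    fit <- aov(r ~ class, data = pairs)
    anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  }
  structure(
    smry,
    anova_p = anova_p,
    pairs = pairs,
    class = c("mp_variation", class(smry))
  )
}

#' @exportS3Method generics::tidy
tidy.mp_variation <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "mp_variation")
  out
}

#' @exportS3Method generics::glance
glance.mp_variation <- function(x, ...) {
  tibble(
    anova_p = attr(x, "anova_p"),
    n_pairs = nrow(attr(x, "pairs")),
    n_classes = sum(x$n > 0)
  )
}

#' Combine per-experiment variance-class summaries
#'
#' Combines class means across experiments as the n-weighted mean of the
#' per-experiment means (weights = number of pairwise comparisons), the
#' convention used to merge repeated experimental blocks into a single
#' summary row; SDs are pooled as the n-weighted root mean square.
#'
#' @param summaries List of `mp_variation` objects (or tibbles with `class`,
#'   `mean_r`, `sd`, `n`).
#' @return Tibble `class`, `mean_r`, `sd`, `n` of the combined summary.
#' @export
#' @examples
#' a <- tibble::tibble(class = "experimental", mean_r = 0.72, sd = 0.06, n = 50)
#' b <- tibble::tibble(class = "experimental", mean_r = 0.58, sd = 0.05, n = 35)
#' combine_class_summaries(list(a, b)) # weighted mean 0.66
combine_class_summaries <- function(summaries) {
  stacked <- bind_rows(map(summaries, as_tibble))
  stacked <- stacked[stacked$n > 0 & !is.na(stacked$mean_r), , drop = FALSE]
  stacked |>
    group_by(class = .data$class) |>
    summarise(
      mean_r = sum(.data$mean_r * .data$n) / sum(.data$n),
      sd = sqrt(sum(.data$sd^2 * .data$n) / sum(.data$n)),
      n = sum(.data$n),
      .groups = "drop"
    )
}

#' Hierarchical clustering of runs on correlation distance
#'
#' Complete-linkage agglomerative clustering on the distance
#' `d = 1 - r` (one minus Pearson correlation). Columns are sorted by label
#' before clustering so the merge order — and therefore the tree under
#' distance ties — does not depend on input order.
#'
#' @param cor_mat Run-by-run correlation matrix.
#' @return An [stats::hclust] object.
#' @export
hcluster <- function(cor_mat) {
  if (is.null(colnames(cor_mat))) {
    abort("`cor_mat` must have run labels as dimnames.")
  }
  ord <- order(colnames(cor_mat))
  d <- as.dist(1 - cor_mat[ord, ord])
  hclust(d, method = "complete")
}

hclust_clades <- function(hc) {
  n <- length(hc$labels)
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    take <- function(x) if (x < 0) hc$labels[-x] else members[[x]]
    members[[i]] <- sort(c(take(hc$merge[i, 1]), take(hc$merge[i, 2])))
  }
  members
}

#' Topology agreement between two dendrograms
#'
#' Two rooted trees over the same leaves are compared by their sets of
#' non-trivial clades (the leaf sets below each internal node). They agree
#' when the clade sets are identical; the partition distance is the size of
#' the symmetric difference of the two clade sets (a Robinson-Foulds-style
#' count, 0 for identical topologies).
#'
#' @param a,b [stats::hclust] objects (or anything `as.hclust` handles).
#' @param leaf_map Optional named character vector renaming `b`'s leaves
#'   into `a`'s label space (`names` = b labels, values = a labels).
#' @return A list: `identical` (logical), `distance` (integer),
#'   `n_clades_a`, `n_clades_b`.
#' @export
topology_agreement <- function(a, b, leaf_map = NULL) {
  a <- stats::as.hclust(a)
  b <- stats::as.hclust(b)
  if (!is.null(leaf_map)) {
    unmapped <- setdiff(b$labels, names(leaf_map))
    if (length(unmapped) > 0) {
      abort(paste0("Unmappable leaves: ", paste(unmapped, collapse = ", ")))
    }
    b$labels <- unname(leaf_map[b$labels])
  }
  if (!setequal(a$labels, b$labels)) {
    abort("The two trees must share one leaf set (after mapping).")
  }
  ca <- unique(map_chr(hclust_clades(a), paste, collapse = "\r"))
  cb <- unique(map_chr(hclust_clades(b), paste, collapse = "\r"))
  dist <- length(setdiff(ca, cb)) + length(setdiff(cb, ca))
  list(
    identical = dist == 0,
    distance = dist,
    n_clades_a = length(ca),
    n_clades_b = length(cb)
  )
}

#' Principal component analysis of runs
#'
#' PCA of the runs (observations) over the features (variables), centred
#' per feature, without scaling. Reports scores and the percentage of total
#' variance captured by each component.
#'
#' @param features Log-transformed feature tibble.
#' @return An `mp_pca` object: list with `scores` (tibble `run_id`, `PC1`,
#'   ...), `percent_variance`, and the underlying `prcomp` fit.
#' @export
pca_runs <- function(features) {
  m <- feature_matrix(as_tibble(features))
  if (ncol(m) < 2) abort("PCA needs at least 2 runs.")
  fit <- prcomp(t(m), center = TRUE, scale. = FALSE)
  pv <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  scores <- as_tibble(fit$x, .name_repair = "minimal")
  scores <- bind_cols(tibble(run_id = colnames(m)), scores)
  structure(
    list(scores = scores, percent_variance = pv, fit = fit),
    class = "mp_pca"
  )
}

#' @exportS3Method generics::tidy
tidy.mp_pca <- function(x, ...) {
  tibble(
    component = paste0("PC", seq_along(x$percent_variance)),
    percent_variance = x$percent_variance
  )
}

#' @exportS3Method generics::glance
glance.mp_pca <- function(x, ...) {
  tibble(
    n_components = length(x$percent_variance),
    top2_percent = sum(x$percent_variance[seq_len(min(
      2, length(x$percent_variance)
    ))])
  )
}
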