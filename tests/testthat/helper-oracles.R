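# Independent reference implementations ("oracles") used to validate the
# package's algorithms. Each is a deliberately naive re-derivation from the
# rule's definition, not a call into the code under test.

# Brute-force digestion: enumerate every substring and keep those with valid
# tryptic flanks and at most `mc` internal cleavage sites.
oracle_digest <- function(sequence, cleave = c("K", "R"), mc = 1,
                          proline_rule = FALSE) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  cuts_after <- function(i) {
    i >= 1 && i < n && chars[i] %in% cleave &&
      (!proline_rule || chars[i + 1] != "P")
  }
  out <- list()
  for (s in 1:n) {
    for (e in s:n) {
      if (!(s == 1 || cuts_after(s - 1))) next
      if (!(e == n || cuts_after(e))) next
      internal <- if (e - 1 >= s) sum(vapply(s:(e - 1), cuts_after, logical(1))) else 0
      if (internal > mc) next
      out[[length(out) + 1]] <- data.frame(
        peptide = paste(chars[s:e], collapse = ""),
        start = s, end = e, n_missed = internal
      )
    }
  }
  do.call(rbind, out)
}

# Naive grouping closure: merge equal peptide sets, then attach every
# strictly-subset protein to the maximal superset set (ties: more peptides,
# then smallest accession among proteins carrying that exact set).
oracle_group <- function(sets) {
  sets <- lapply(sets, function(x) sort(unique(x)))
  accs <- names(sets)
  key <- vapply(sets, paste, character(1), collapse = "|")
  distinct_keys <- unique(key)
  set_of_key <- lapply(distinct_keys, function(k) sets[[match(k, key)]])
  names(set_of_key) <- distinct_keys
  min_acc_of_key <- vapply(
    distinct_keys, function(k) min(accs[key == k]), character(1)
  )
  host_key <- vapply(accs, function(a) {
    sup <- distinct_keys[vapply(
      distinct_keys,
      function(k) all(sets[[a]] %in% set_of_key[[k]]),
      logical(1)
    )]
    sizes <- lengths(set_of_key[sup])
    sup <- sup[sizes == max(sizes)]
    sup[order(min_acc_of_key[sup])][1]
  }, character(1))
  split(accs, host_key)
}

# LCA by pairwise path intersection: reduce lineage rows, truncating the
# shared path at the first disagreement or missing value.
oracle_lca <- function(lineages, ranks) {
  if (nrow(lineages) == 0) return(list(rank = "unassigned", value = NA))
  path_of <- function(i) {
    v <- unlist(lineages[i, ranks])
    stop_at <- which(is.na(v))[1]
    if (!is.na(stop_at)) v <- v[seq_len(stop_at - 1)]
    v
  }
  shared <- path_of(1)
  for (i in seq_len(nrow(lineages))[-1]) {
    p <- path_of(i)
    upto <- min(length(shared), length(p))
    agree <- which(shared[seq_len(upto)] != p[seq_len(upto)])[1]
    keep <- if (is.na(agree)) upto else agree - 1
    shared <- shared[seq_len(keep)]
  }
  if (length(shared) == 0) return(list(rank = "unassigned", value = NA))
  list(
    rank = ranks[length(shared)],
    value = unname(shared[length(shared)])
  )
}

# One-sided Fisher enrichment p by exhaustive enumeration of 2x2 tables
# with fixed margins, using binomial coefficients only.
oracle_fisher_greater <- function(k, m, n_sig, n_total) {
  a_vals <- max(0, n_sig - (n_total - m)):min(m, n_sig)
  probs <- vapply(a_vals, function(a) {
    choose(m, a) * choose(n_total - m, n_sig - a) / choose(n_total, n_sig)
  }, numeric(1))
  sum(probs[a_vals >= k])
}

# Brute-force complete-linkage agglomeration over a distance matrix.
# Returns the merge heights and the clade (leaf-set) list.
oracle_complete_linkage <- function(d) {
  labels <- colnames(d)
  clusters <- as.list(labels)
  heights <- numeric(0)
  clades <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        dd <- max(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d) {
          best_d <- dd
          best <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    heights <- c(heights, best_d)
    clades[[length(clades) + 1]] <- merged
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, clades = clades)
}

# Clade (leaf-set) extraction from an hclust object, for comparisons.
clades_of <- function(hc) {
  members <- list()
  out <- list()
  for (i in seq_len(nrow(hc$merge))) {
    take <- function(x) if (x < 0) hc$labels[-x] else members[[x]]
    members[[i]] <- sort(c(take(hc$merge[i, 1]), take(hc$merge[i, 2])))
    out[[i]] <- members[[i]]
  }
  out
}

# Random lineage table over a nested taxonomy with `n_leaves` species.
random_taxonomy <- function(n_leaves, ranks) {
  n_groups <- pmax(1, round(n_leaves / 2^(rev(seq_along(ranks)) - 1)))
  n_groups[1] <- min(n_groups[1], 2) # at most two superkingdoms
  ids <- seq_len(n_leaves)
  cols <- lapply(seq_along(ranks), function(d) {
    g <- ceiling(ids * n_groups[d] / n_leaves)
    paste0(substr(ranks[d], 1, 3), g)
  })
  names(cols) <- ranks
  tibble::as_tibble(cols)
}

run_labels <- function() {
  tidyr::expand_grid(
    subject = c("A", "B", "C"), timepoint = c("T1", "T2"),
    replicate = c("R1", "R2")
  ) |>
    dplyr::mutate(run_id = paste(subject, timepoint, replicate, sep = "_"))
}
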