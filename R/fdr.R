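#' Estimate the false discovery rate at a score threshold
#'
#' Applies the concatenated target-decoy estimator
#' `FDR = 2 * n_reverse / (n_forward + n_reverse)` to the peptide-spectrum
#' matches (PSMs) at or better than `threshold` (scores are E-value-like:
#' lower is better). The estimate is capped at 1.
#'
#' @param psms Data frame of PSMs with at least `score` (> 0, lower is
#'   better) and `is_decoy` (logical).
#' @param threshold Score cutoff; PSMs with `score <= threshold` are counted.
#' @return A one-row tibble: `threshold`, `n_forward`, `n_reverse`, `fdr`.
#' @export
#' @examples
#' psms <- tibble::tibble(
#'   score = c(rep(1e-6, 390), rep(1e-5, 10)),
#'   is_decoy = c(rep(FALSE, 390), rep(TRUE, 10))
#' )
#' estimate_fdr(psms, threshold = 1e-4) # fdr = 2 * 10 / 400 = 0.05
estimate_fdr <- function(psms, threshold) {
  psms <- as_tibble(psms)
  check_psm_cols(psms, c("score", "is_decoy"))
  acc <- psms[psms$score <= threshold, , drop = FALSE]
  if (nrow(acc) == 0) {
    abort("No PSM passes `threshold`; cannot estimate the FDR.")
  }
  n_rev <- sum(acc$is_decoy)
  n_fwd <- sum(!acc$is_decoy)
  tibble(
    threshold = threshold,
    n_forward = n_fwd,
    n_reverse = n_rev,
    fdr = min(1, 2 * n_rev / (n_fwd + n_rev))
  )
}

#' Filter PSMs at a target false discovery rate
#'
#' Scans score cutoffs from best to worst and selects the loosest cutoff
#' whose target-decoy FDR estimate (see [estimate_fdr()]) does not exceed
#' `alpha`, maximising the number of identifications. Decoy hits are dropped
#' from the returned set.
#'
#' @param psms Data frame of PSMs (`score`, `is_decoy`, and any identifier
#'   columns, which are carried through).
#' @param alpha Accepted FDR level, default 0.05.
#' @return Tibble of accepted target PSMs, with attributes `threshold` and
#'   `fdr_estimate` (the [estimate_fdr()] row at that threshold); retrieve
#'   them with [glance()].
#' @export
filter_at_fdr <- function(psms, alpha = 0.05) {
  psms <- as_tibble(psms)
  check_psm_cols(psms, c("score", "is_decoy"))
  if (nrow(psms) == 0) abort("`psms` is empty.")
  if (!any(psms$is_decoy)) {
    warn("`psms` contains no decoy hits; the FDR estimate is 0 everywhere.")
  }
  cutoffs <- sort(unique(psms$score))
  ord <- order(psms$score)
  dec <- psms$is_decoy[ord]
  # cumulative forward/reverse counts at each unique cutoff
  idx <- findInterval(cutoffs, psms$score[ord])
  cum_rev <- cumsum(dec)[idx]
  cum_all <- idx
  fdr <- pmin(1, 2 * cum_rev / cum_all)
  ok <- which(fdr <= alpha)
  if (length(ok) == 0) {
    warn("No score cutoff reaches the requested FDR; returning no PSMs.")
    out <- psms[0, , drop = FALSE]
    attr(out, "threshold") <- NA_real_
    attr(out, "fdr_estimate") <- tibble(
      threshold = NA_real_, n_forward = 0L, n_reverse = 0L, fdr = NA_real_
    )
    class(out) <- c("mp_fdr_filter", class(out))
    return(out)
  }
  thr <- cutoffs[max(ok)]
  out <- psms[psms$score <= thr & !psms$is_decoy, , drop = FALSE]
  out <- out[order(out$score), , drop = FALSE]
  attr(out, "threshold") <- thr
  attr(out, "fdr_estimate") <- estimate_fdr(psms, thr)
  class(out) <- c("mp_fdr_filter", class(out))
  out
}

#' @exportS3Method generics::glance
glance.mp_fdr_filter <- function(x, ...) {
  est <- attr(x, "fdr_estimate")
  tibble(
    threshold = attr(x, "threshold"),
    n_forward = est$n_forward,
    n_reverse = est$n_reverse,
    fdr = est$fdr,
    n_accepted = nrow(x)
  )
}

#' Resolve conflicting identifications of a spectrum across databases
#'
#' When the same spectrum was searched against several databases it may
#' receive different peptide identifications. One record per spectrum is
#' kept: if all candidate peptides agree, the best-scoring record; otherwise
#' the minimum-score hit. Exact score ties break deterministically by
#' lexicographically smaller peptide, then by database priority order, so
#' the result does not depend on input ordering.
#'
#' @param psms Data frame with `spectrum_id`, `peptide`, `score`,
#'   `database_id` (other columns carried through).
#' @param db_priority Character vector giving database precedence for
#'   tie-breaks; databases not listed rank after listed ones,
#'   alphabetically.
#' @return Tibble with one row per spectrum.
#' @export
resolve_cross_database <- function(psms, db_priority = character(0)) {
  psms <- as_tibble(psms)
  check_psm_cols(psms, c("spectrum_id", "peptide", "score", "database_id"))
  if (nrow(psms) == 0) return(psms)
  prio <- match(psms$database_id, db_priority)
  prio[is.na(prio)] <- length(db_priority) + 1L
  ord <- order(
    psms$spectrum_id, psms$score, psms$peptide, prio, psms$database_id
  )
  psms <- psms[ord, , drop = FALSE]
  psms[!duplicated(psms$spectrum_id), , drop = FALSE]
}

check_psm_cols <- function(psms, cols) {
  missing_cols <- setdiff(cols, names(psms))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "PSM table lacks column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  invisible(psms)
}
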