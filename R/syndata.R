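#' Default pool of COG annotations
#'
#' A small pool of real Clusters of Orthologous Groups frequently observed
#' in intestinal metaproteomes (central carbon, amino-acid and energy
#' metabolism, transport, translation, chaperones), with their functional
#' category letters. Used by [community_spec()] when no pool is supplied.
#'
#' @return Tibble `cog_id`, `definition`, `category`.
#' @export
default_cog_pool <- function() {
  tibble::tribble(
    ~cog_id, ~definition, ~category,
    "COG0334", "Glutamate dehydrogenase", "E",
    "COG1866", "Phosphoenolpyruvate carboxykinase (ATP)", "C",
    "COG1653", "ABC-type sugar transport system, periplasmic component", "G",
    "COG2115", "Xylose isomerase", "G",
    "COG0057", "Glyceraldehyde-3-phosphate dehydrogenase", "G",
    "COG0176", "Transaldolase", "G",
    "COG0574", "Phosphoenolpyruvate synthase", "G",
    "COG0183", "Acetyl-CoA acetyltransferase", "I",
    "COG0148", "Enolase", "G",
    "COG3957", "Phosphoketolase", "G",
    "COG0126", "3-phosphoglycerate kinase", "G",
    "COG1882", "Pyruvate-formate lyase", "C",
    "COG0174", "Glutamine synthetase", "E",
    "COG0021", "Transketolase", "G",
    "COG0059", "Ketol-acid reductoisomerase", "EH",
    "COG0480", "Translation elongation factor (GTPase)", "J",
    "COG1454", "Alcohol dehydrogenase, class IV", "C",
    "COG0282", "Acetate kinase", "C",
    "COG1250", "3-hydroxyacyl-CoA dehydrogenase", "I",
    "COG0459", "Chaperonin GroEL (HSP60 family)", "O"
  )
}

#' Specification of a synthetic microbial community
#'
#' Describes the reference community the generator builds: how many taxa,
#' the rank ladder of their taxonomy, how many proteins each taxon encodes,
#' the COG pool proteins are annotated from, and the protein length range.
#'
#' @param n_taxa Number of taxa (species-level leaves), default 30.
#' @param n_proteins_per_taxon Proteins per taxon, default 5.
#' @param ranks Rank ladder, shallow to deep; must be an in-order subset of
#'   superkingdom...species starting at superkingdom.
#' @param cog_pool Tibble `cog_id`, `definition`, `category`
#'   (default [default_cog_pool()]).
#' @param protein_length_range Length-2 integer vector of protein lengths
#'   in amino acids, default `c(60, 300)`.
#' @param p_no_cog Probability that a protein carries no COG, default 0.2.
#' @param seed Integer seed; the same spec regenerates identical output.
#' @return A `community_spec` object.
#' @export
community_spec <- function(n_taxa = 30, n_proteins_per_taxon = 5,
                           ranks = TAX_RANKS,
                           cog_pool = default_cog_pool(),
                           protein_length_range = c(60, 300),
                           p_no_cog = 0.2, seed = 1) {
  pos <- match(ranks, TAX_RANKS)
  if (anyNA(pos) || is.unsorted(pos, strictly = TRUE) ||
      ranks[1] != "superkingdom" || length(ranks) < 2) {
    abort(paste0(
      "Invalid rank ladder: `ranks` must be an in-order subset of ",
      paste(TAX_RANKS, collapse = " > "), " starting at superkingdom."
    ))
  }
  if (n_taxa < 1 || n_proteins_per_taxon < 1) {
    abort("`n_taxa` and `n_proteins_per_taxon` must be >= 1.")
  }
  if (length(protein_length_range) != 2 ||
      protein_length_range[1] > protein_length_range[2] ||
      protein_length_range[1] < 33) {
    abort("`protein_length_range` must be c(min, max) with min >= 33.")
  }
  structure(
    list(
      n_taxa = as.integer(n_taxa),
      n_proteins_per_taxon = as.integer(n_proteins_per_taxon),
      ranks = ranks,
      cog_pool = as_tibble(cog_pool),
      protein_length_range = as.integer(protein_length_range),
      p_no_cog = p_no_cog,
      seed = as.integer(seed)
    ),
    class = "community_spec"
  )
}

#' Study design of the synthetic repeated-measures experiment
#'
#' Mirrors a faecal metaproteomics study design: a few subjects sampled at
#' two time points and measured in technical replicate, with a variance
#' hierarchy in which technical noise is smaller than temporal change,
#' which in turn is smaller than between-subject differences. The sigmas
#' are standard deviations of additive Gaussian effects on the log10
#' intensity/abundance scale.
#'
#' @param n_subjects Number of subjects, default 3.
#' @param n_timepoints Number of time points, default 2.
#' @param n_tech_replicates Technical replicates per sample, default 2.
#' @param sigma_tech,sigma_time,sigma_subject Effect SDs (log10 scale);
#'   defaults 0.3 < 0.45 < 0.65 follow the technical < temporal < subject
#'   hierarchy. Zero is allowed (to switch an effect off); negative is not.
#' @param sigma_feature_base SD of the per-feature baseline shared by all
#'   runs (drives the overall correlation level), default 0.8.
#' @param n_features Number of LC-MS features, default 300.
#' @param decoy_score_shift Separation, in log10 E-value units, between the
#'   score distributions of correct and incorrect matches, default 7.
#' @param prop_incorrect Proportion of incorrect matches among generated
#'   PSMs (split evenly between target and decoy sequences), default 0.4.
#' @param presence_threshold Minimum log10 taxon abundance for its proteins
#'   to be expressed in a sample, default -0.6.
#' @param lambda_psm Mean extra spectra per present protein and run beyond
#'   the guaranteed two, scaled by relative taxon abundance, default 1.
#' @param phylotype_noise_sd SD of log10 lognormal noise on phylotype
#'   abundances, default 0.3.
#' @param n_planted_associations Number of planted protein-phylotype links,
#'   default 5.
#' @param assoc_effect Planted-link effect size as a multiple of the
#'   residual noise SD of the protein level, default 2.
#' @param seed Integer seed.
#' @return A `study_design` object.
#' @export
study_design <- function(n_subjects = 3, n_timepoints = 2,
                         n_tech_replicates = 2,
                         sigma_tech = 0.3, sigma_time = 0.45,
                         sigma_subject = 0.65,
                         sigma_feature_base = 0.8, n_features = 300,
                         decoy_score_shift = 7, prop_incorrect = 0.4,
                         presence_threshold = -0.6, lambda_psm = 1,
                         phylotype_noise_sd = 0.3,
                         n_planted_associations = 5, assoc_effect = 2,
                         seed = 1) {
  sigmas <- c(sigma_tech, sigma_time, sigma_subject, sigma_feature_base)
  if (any(sigmas < 0)) abort("Effect SDs must be non-negative.")
  if (n_subjects < 1 || n_timepoints < 1 || n_tech_replicates < 1) {
    abort("Design counts must be >= 1.")
  }
  if (prop_incorrect < 0 || prop_incorrect >= 1) {
    abort("`prop_incorrect` must be in [0, 1).")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_timepoints = as.integer(n_timepoints),
      n_tech_replicates = as.integer(n_tech_replicates),
      sigma_tech = sigma_tech, sigma_time = sigma_time,
      sigma_subject = sigma_subject,
      sigma_feature_base = sigma_feature_base,
      n_features = as.integer(n_features),
      decoy_score_shift = decoy_score_shift,
      prop_incorrect = prop_incorrect,
      presence_threshold = presence_threshold,
      lambda_psm = lambda_psm,
      phylotype_noise_sd = phylotype_noise_sd,
      n_planted_associations = as.integer(n_planted_associations),
      assoc_effect = assoc_effect,
      seed = as.integer(seed)
    ),
    class = "study_design"
  )
}

# --- community ------------------------------------------------------------

GUT_PHYLA <- c(
  "Firmicutes", "Bacteroidetes", "Actinobacteria", "Proteobacteria"
)

make_taxa <- function(spec) {
  n <- spec$n_taxa
  n_arch <- if (n >= 10) 1L else 0L
  nb <- n - n_arch
  sp <- seq_len(nb)
  n_gen <- max(1L, round(nb / 3))
  n_fam <- max(1L, round(n_gen / 1.5))
  n_ord <- max(1L, round(n_fam / 1.5))
  n_cls <- max(1L, round(n_ord / 1.5))
  n_phy <- min(length(GUT_PHYLA), max(1L, n_cls))
  genus_id <- ceiling(sp * n_gen / nb)
  fam_id <- ceiling(genus_id * n_fam / n_gen)
  ord_id <- ceiling(fam_id * n_ord / n_fam)
  cls_id <- ceiling(ord_id * n_cls / n_ord)
  phy_id <- ceiling(cls_id * n_phy / n_cls)
  taxa <- tibble(
    taxon_id = sprintf("tax%03d", sp),
    superkingdom = "Bacteria",
    phylum = GUT_PHYLA[phy_id],
    class = sprintf("cls_%02d", cls_id),
    order = sprintf("ord_%02d", ord_id),
    family = sprintf("fam_%02d", fam_id),
    genus = sprintf("gen_%02d", genus_id),
    species = sprintf("sp_%03d", sp)
  )
  if (n_arch == 1L) {
    taxa <- bind_rows(taxa, tibble(
      taxon_id = sprintf("tax%03d", n),
      superkingdom = "Archaea", phylum = "Euryarchaeota",
      class = "Methanobacteria", order = "Methanobacteriales",
      family = "Methanobacteriaceae", genus = "Methanobrevibacter",
      species = "M_smithii"
    ))
  }
  taxa[, c("taxon_id", spec$ranks)]
}

# Tryptic building blocks are kept >= 8 residues: with ~20^8 possible
# blocks, incidental peptide sharing between unrelated proteins is
# vanishingly rare, which keeps the presence/core ground truth identifiable
# from peptide evidence.
random_protein_sequence <- function(target_length) {
  non_cleave <- setdiff(AA_ALPHABET, c("K", "R"))
  parts <- character(0)
  len <- 0L
  while (len < target_length) {
    core_len <- sample(7:14, 1)
    block <- paste0(
      paste(sample(non_cleave, core_len, replace = TRUE), collapse = ""),
      sample(c("K", "R"), 1)
    )
    parts <- c(parts, block)
    len <- len + nchar(block)
  }
  paste(parts, collapse = "")
}

#' Generate a synthetic reference community
#'
#' Builds a lineage-annotated protein reference with known ground truth:
#' a nested taxonomy over the configured rank ladder, random protein
#' sequences constructed from tryptic blocks (every protein contains at
#' least one fully tryptic peptide of >= 5 residues), at most one COG per
#' protein, and a synthetic BLAST-tabular hit table from which those COG
#' labels can be re-derived with [assign_cog()].
#'
#' @param spec A [community_spec()] object.
#' @return An `mp_community` list: `proteins` (accession, taxon_id, cog_id,
#'   sequence), `taxa`, `lineage` (per accession), `cog_pool`,
#'   `blast_hits`, `spec`.
#' @export
generate_community <- function(spec = community_spec()) {
  if (!inherits(spec, "community_spec")) {
    abort("`spec` must be a community_spec object.")
  }
  withr::with_seed(spec$seed, {
    taxa <- make_taxa(spec)
    grid <- tidyr::expand_grid(
      taxon_id = taxa$taxon_id,
      j = seq_len(spec$n_proteins_per_taxon)
    )
    lengths_ <- round(runif(
      nrow(grid), spec$protein_length_range[1], spec$protein_length_range[2]
    ))
    proteins <- tibble(
      accession = sprintf("%s_P%02d", grid$taxon_id, grid$j),
      taxon_id = grid$taxon_id,
      sequence = map_chr(lengths_, random_protein_sequence),
      cog_id = ifelse(
        runif(nrow(grid)) < spec$p_no_cog,
        NA_character_,
        sample(spec$cog_pool$cog_id, nrow(grid), replace = TRUE)
      ),
      database_id = "isolate_genomes"
    )
    blast_hits <- make_blast_hits(proteins, spec$cog_pool)
  })
  lineage <- left_join(
    proteins[, c("accession", "taxon_id")], taxa, by = "taxon_id"
  )
  structure(
    list(
      proteins = proteins, taxa = taxa, lineage = lineage,
      cog_pool = spec$cog_pool, blast_hits = blast_hits, spec = spec
    ),
    class = "mp_community"
  )
}

make_blast_hits <- function(proteins, cog_pool) {
  rows <- map(seq_len(nrow(proteins)), function(i) {
    acc <- proteins$accession[i]
    cog <- proteins$cog_id[i]
    len <- nchar(proteins$sequence[i])
    if (!is.na(cog)) {
      true_e <- 10^runif(1, -40, -15)
      other <- sample(setdiff(cog_pool$cog_id, cog), 1)
      other_e <- 10^runif(1, -8, -2)
      tibble(
        qseqid = acc,
        sseqid = c(paste0(cog, "_ref"), paste0(other, "_ref")),
        pident = round(runif(2, 40, 95), 1),
        length = len, mismatch = sample(0:30, 2, replace = TRUE),
        gapopen = sample(0:3, 2, replace = TRUE),
        qstart = 1L, qend = len, sstart = 1L, send = len,
        evalue = c(true_e, other_e),
        bitscore = round(-10 * log10(c(true_e, other_e)), 1)
      )
    } else {
      weak <- sample(cog_pool$cog_id, 1)
      e <- 10^runif(1, -8, -3)
      tibble(
        qseqid = acc, sseqid = paste0(weak, "_ref"),
        pident = round(runif(1, 25, 40), 1),
        length = len, mismatch = sample(10:60, 1),
        gapopen = sample(0:5, 1),
        qstart = 1L, qend = len, sstart = 1L, send = len,
        evalue = e, bitscore = round(-10 * log10(e), 1)
      )
    }
  })
  bind_rows(rows)
}

# --- study ----------------------------------------------------------------

make_runs <- function(design) {
  grid <- tidyr::expand_grid(
    subject = LETTERS[seq_len(design$n_subjects)],
    timepoint = sprintf("T%d", seq_len(design$n_timepoints)),
    replicate = sprintf("R%d", seq_len(design$n_tech_replicates))
  )
  mutate(
    grid,
    run_id = paste(.data$subject, .data$timepoint, .data$replicate,
                   sep = "_"),
    sample_id = paste(.data$subject, .data$timepoint, sep = "_"),
    .before = 1
  )
}

#' Simulate a PSM table with known false labels
#'
#' Generates `n` peptide-spectrum matches of which a proportion
#' `prop_incorrect` are incorrect; incorrect matches are split evenly
#' between target and decoy sequences (the assumption underlying the
#' 2*rev/(fwd+rev) estimator), and their E-value-like scores are drawn from
#' a distribution shifted `decoy_score_shift` log10 units above (worse
#' than) the correct-match distribution. Correct matches draw log10
#' E-values uniformly from [-12, -6].
#'
#' @param n Number of PSMs.
#' @param prop_incorrect Proportion of incorrect matches, default 0.4.
#' @param decoy_score_shift Shift of the incorrect-score distribution in
#'   log10 units, default 7.
#' @param peptides Optional character vector to sample correct peptides
#'   from; random tryptic-looking strings are used when `NULL`.
#' @param seed Integer seed.
#' @return Tibble `spectrum_id`, `run_id`, `peptide`, `score`,
#'   `database_id`, `is_decoy`, `is_false` (ground truth; decoys and
#'   incorrect targets are false).
#' @export
simulate_psms <- function(n, prop_incorrect = 0.4, decoy_score_shift = 7,
                          peptides = NULL, seed = 1) {
  withr::with_seed(as.integer(seed), {
    incorrect <- runif(n) < prop_incorrect
    decoy <- incorrect & (runif(n) < 0.5)
    log_e <- ifelse(
      incorrect,
      runif(n, -12 + decoy_score_shift, -6 + decoy_score_shift),
      runif(n, -12, -6)
    )
    pep <- if (is.null(peptides)) {
      random_peptides(n)
    } else {
      sample(peptides, n, replace = TRUE)
    }
    pep[incorrect] <- random_peptides(sum(incorrect))
  })
  tibble(
    spectrum_id = sprintf("spec%06d", seq_len(n)),
    run_id = "run1",
    peptide = pep,
    score = 10^log_e,
    database_id = "isolate_genomes",
    is_decoy = decoy,
    is_false = incorrect
  )
}

random_peptides <- function(n, len_range = c(7, 14)) {
  non_cleave <- setdiff(AA_ALPHABET, c("K", "R"))
  map_chr(seq_len(n), function(i) {
    len <- sample(len_range[1]:len_range[2], 1)
    paste0(
      paste(sample(non_cleave, len - 1, replace = TRUE), collapse = ""),
      sample(c("K", "R"), 1)
    )
  })
}

#' Simulate an aligned LC-MS feature matrix
#'
#' Log10 feature intensities follow
#' `base_feature + subject effect + time effect + technical noise`, with
#' independent Gaussian effects of SDs `sigma_feature_base`,
#' `sigma_subject`, `sigma_time` and `sigma_tech`; intensities are
#' `10^value` scaled to a realistic magnitude.
#'
#' @param design A [study_design()] object.
#' @param seed Seed override; defaults to `design$seed`.
#' @return List with `features` (tibble `feature_id`, `mz`, `rt`, one
#'   column per run) and `runs`.
#' @export
simulate_features <- function(design, seed = design$seed) {
  runs <- make_runs(design)
  nf <- design$n_features
  withr::with_seed(as.integer(seed), {
    base <- rnorm(nf, 0, design$sigma_feature_base)
    subj_eff <- matrix(
      rnorm(nf * design$n_subjects, 0, design$sigma_subject),
      nrow = nf
    )
    time_eff <- array(
      rnorm(nf * design$n_subjects * design$n_timepoints, 0,
            design$sigma_time),
      dim = c(nf, design$n_subjects, design$n_timepoints)
    )
    m <- matrix(0, nrow = nf, ncol = nrow(runs))
    for (k in seq_len(nrow(runs))) {
      s <- match(runs$subject[k], LETTERS)
      t <- as.integer(sub("T", "", runs$timepoint[k]))
      m[, k] <- 5 + base + subj_eff[, s] + time_eff[, s, t] +
        rnorm(nf, 0, design$sigma_tech)
    }
    mz <- round(runif(nf, 300, 2000), 4)
    rt <- round(runif(nf, 5, 90), 2)
  })
  colnames(m) <- runs$run_id
  features <- bind_cols(
    tibble(
      feature_id = sprintf("F%05d", seq_len(nf)),
      mz = mz, rt = rt
    ),
    as_tibble(10^m, .name_repair = "minimal")
  )
  list(features = features, runs = runs)
}

#' Generate a complete synthetic study with ground truth
#'
#' Produces every input the analysis pipeline consumes — per-run PSM
#' tables with decoys, an aligned LC-MS feature matrix, a phylotype
#' abundance matrix with a genus map, and per-protein log levels — plus a
#' ground-truth ledger recording which PSMs are false, which proteins are
#' truly present per subject, the true core set, and the planted
#' protein-phylotype associations.
#'
#' Composition and proteome are coupled: each taxon's log10 abundance per
#' (subject, time point) is `base + subject effect + time effect`, a
#' taxon's proteins are expressed in a sample when that abundance exceeds
#' the presence threshold, and phylotype profiles are the same abundances
#' with lognormal noise. Every expressed protein contributes at least two
#' distinct-peptide spectra per run so that presence is observable.
#'
#' @param community An `mp_community` from [generate_community()].
#' @param design A [study_design()] object.
#' @return An `mp_study` list: `runs`, `psms`, `features`, `phylotypes`,
#'   `genus_map`, `protein_levels`, `truth` (ledger), `design`.
#' @export
generate_study <- function(community, design = study_design()) {
  if (!inherits(community, "mp_community")) {
    abort("`community` must come from generate_community().")
  }
  if (!inherits(design, "study_design")) {
    abort("`design` must be a study_design object.")
  }
  proteins <- community$proteins
  taxa <- community$taxa
  n_phylo <- nrow(taxa)
  if (design$n_planted_associations > nrow(proteins) * n_phylo) {
    abort("More planted associations than protein x phylotype pairs.")
  }
  runs <- make_runs(design)
  feats <- simulate_features(design, seed = design$seed)

  withr::with_seed(design$seed + 1L, {
    study <- with_study_model(proteins, taxa, runs, design)
  })
  structure(
    c(list(runs = runs, features = feats$features), study,
      list(design = design)),
    class = "mp_study"
  )
}

# everything that shares the abundance model; called inside with_seed()
with_study_model <- function(proteins, taxa, runs, design) {
  n_taxa <- nrow(taxa)
  samples <- distinct(runs[, c("subject", "timepoint", "sample_id")])

  base <- rnorm(n_taxa, 0, 1)
  subj_eff <- matrix(
    rnorm(n_taxa * design$n_subjects, 0, design$sigma_subject), n_taxa
  )
  time_eff <- array(
    rnorm(n_taxa * design$n_subjects * design$n_timepoints, 0,
          design$sigma_time),
    dim = c(n_taxa, design$n_subjects, design$n_timepoints)
  )
  log_abund <- function(s, t) base + subj_eff[, s] + time_eff[, s, t]

  # taxon abundance per sample, presence of proteins
  abund <- map(seq_len(nrow(samples)), function(k) {
    s <- match(samples$subject[k], LETTERS)
    t <- as.integer(sub("T", "", samples$timepoint[k]))
    log_abund(s, t)
  })
  names(abund) <- samples$sample_id

  taxon_idx <- match(proteins$taxon_id, taxa$taxon_id)
  presence <- map(samples$sample_id, function(sid) {
    abund[[sid]][taxon_idx] >= design$presence_threshold
  })
  names(presence) <- samples$sample_id

  # tryptic peptide pools per protein (length >= 5, <= 1 missed cleavage)
  params <- digestion_params()
  pep_pool <- map(proteins$sequence, function(s) {
    p <- digest_protein(s, params)
    unique(p$peptide[nchar(p$peptide) >= params$min_peptide_length])
  })

  psms <- list()
  spec_counter <- 0L
  for (k in seq_len(nrow(runs))) {
    sid <- runs$sample_id[k]
    pres <- presence[[sid]]
    rel <- 10^(abund[[sid]][taxon_idx] - max(abund[[sid]]))
    correct <- list()
    for (i in which(pres)) {
      pool <- pep_pool[[i]]
      n_spec <- 2L + rpois(1, design$lambda_psm * rel[i])
      peps <- if (length(pool) >= 2) {
        c(sample(pool, 2), sample(pool, n_spec - 2L, replace = TRUE))
      } else {
        rep(pool, n_spec)
      }
      correct[[length(correct) + 1L]] <- peps
    }
    correct <- unlist(correct)
    n_corr <- length(correct)
    n_bad <- round(n_corr * design$prop_incorrect / (1 - design$prop_incorrect))
    bad_decoy <- runif(n_bad) < 0.5
    log_e <- c(
      runif(n_corr, -12, -6),
      runif(n_bad, -12 + design$decoy_score_shift,
            -6 + design$decoy_score_shift)
    )
    psms[[k]] <- tibble(
      spectrum_id = sprintf(
        "spec%07d", spec_counter + seq_len(n_corr + n_bad)
      ),
      run_id = runs$run_id[k],
      peptide = c(correct, random_peptides(n_bad)),
      score = 10^log_e,
      database_id = "isolate_genomes",
      is_decoy = c(rep(FALSE, n_corr), bad_decoy),
      is_false = c(rep(FALSE, n_corr), rep(TRUE, n_bad))
    )
    spec_counter <- spec_counter + n_corr + n_bad
  }
  psms <- bind_rows(psms)
  psm_false <- psms[, c("spectrum_id", "is_false")]
  psms$is_false <- NULL

  # phylotypes: one per taxon, abundance + lognormal noise per run
  phylo_m <- matrix(0, n_taxa, nrow(runs))
  for (k in seq_len(nrow(runs))) {
    phylo_m[, k] <- 10^(abund[[runs$sample_id[k]]] +
                          rnorm(n_taxa, 0, design$phylotype_noise_sd))
  }
  colnames(phylo_m) <- runs$run_id
  phylotypes <- bind_cols(
    tibble(phylotype_id = paste0("pt_", taxa$taxon_id)),
    as_tibble(phylo_m, .name_repair = "minimal")
  )
  genus_col <- if ("genus" %in% names(taxa)) taxa$genus else taxa$taxon_id
  genus_map <- tibble(
    phylotype_id = phylotypes$phylotype_id, genus = genus_col
  )

  # protein levels: planted links follow one phylotype, others are noise
  planted_idx <- sample(nrow(proteins), design$n_planted_associations)
  planted <- tibble(
    accession = proteins$accession[planted_idx],
    phylotype_id = phylotypes$phylotype_id[
      sample(n_taxa, design$n_planted_associations, replace = TRUE)
    ]
  )
  lev <- matrix(
    rnorm(nrow(proteins) * nrow(runs)), nrow = nrow(proteins)
  )
  for (i in seq_len(nrow(planted))) {
    row <- planted_idx[i]
    z <- log10(phylo_m[match(planted$phylotype_id[i],
                             phylotypes$phylotype_id), ])
    z <- (z - mean(z)) / sd(z)
    lev[row, ] <- design$assoc_effect * z + rnorm(nrow(runs))
  }
  colnames(lev) <- runs$run_id
  protein_levels <- bind_cols(
    tibble(accession = proteins$accession),
    as_tibble(lev, .name_repair = "minimal")
  )

  presence_tbl <- bind_rows(map(seq_len(nrow(samples)), function(k) {
    tibble(
      accession = proteins$accession,
      subject = samples$subject[k],
      timepoint = samples$timepoint[k],
      present = presence[[samples$sample_id[k]]]
    )
  }))
  by_subject <- presence_tbl |>
    group_by(.data$accession, .data$subject) |>
    summarise(present = any(.data$present), .groups = "drop")
  core <- by_subject |>
    group_by(.data$accession) |>
    summarise(core = all(.data$present), .groups = "drop")

  list(
    psms = psms,
    phylotypes = phylotypes,
    genus_map = genus_map,
    protein_levels = protein_levels,
    truth = list(
      psm_false = psm_false,
      presence = presence_tbl,
      presence_by_subject = by_subject,
      core = sort(core$accession[core$core]),
      planted = planted,
      taxon_log_abundance = {
        la <- do.call(cbind, abund)
        rownames(la) <- taxa$taxon_id
        la
      }
    )
  )
}
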