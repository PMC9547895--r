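# Synthetic paired before/after studies with known ground truth.
#
# Baseline communities are drawn from a Dirichlet-multinomial mixture with
# enterotype-like components (so the fitted enterotyping model class matches
# the generator).  After-samples perturb each subject's baseline composition
# by mixing it with a fresh draw from the subject's component; the mixing
# weight is a monotone function of a planted linear score in the subject's
# baseline AGN, Shannon alpha diversity and log B:F ratio, which makes the
# realised null-model response depend on those covariates with configurable
# signs (negative for AGN, positive for alpha and B:F by default).

#' Configuration of the synthetic study generator
#'
#' Defaults emulate a mid-sized 16S intervention cohort: 4 enterotype-like
#' community clusters, 300 subjects with paired samples, 120 taxa, 5000-15000
#' reads per sample and per-taxon gene counts in the 1500-8000 range.
#'
#' @param n_subjects number of subjects (one before/after pair each).
#' @param n_taxa number of taxa.
#' @param n_enterotypes number of mixture components (default 4).
#' @param reads_range integer length-2 vector, uniform read-depth range per
#'   sample (within \[3000, 1e6\]).
#' @param concentration Dirichlet concentration of each component (larger =
#'   tighter clusters).
#' @param driver_taxa number of high-abundance driver taxa per component.
#' @param driver_boost multiplicative abundance boost of driver taxa.
#' @param effect_agn,effect_alpha,effect_bf planted standardised effects of
#'   baseline AGN, alpha diversity and log B:F on the perturbation score
#'   (defaults -1, +1, +1).
#' @param noise_sd standard deviation of the score's noise term.
#' @param mixing_floor baseline mixing weight applied at score zero; 0 makes
#'   a zero-score subject's after-sample composition identical to baseline.
#' @param mixing_gain increase in mixing weight per unit score.
#' @param prop_species,prop_genus fraction of taxa resolved to species /
#'   only to genus (the remainder is family-level and excluded from AGN).
#' @param seed integer seed; all draws flow through it.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_subjects = 300, n_taxa = 120,
                             n_enterotypes = 4,
                             reads_range = c(5000, 15000),
                             concentration = 30, driver_taxa = 10,
                             driver_boost = 25,
                             effect_agn = -1, effect_alpha = 1,
                             effect_bf = 1, noise_sd = 0.5,
                             mixing_floor = 0.3, mixing_gain = 0.12,
                             prop_species = 0.85, prop_genus = 0.10,
                             seed = 1L) {
  stopifnot(n_enterotypes >= 1, n_taxa >= n_enterotypes,
            length(reads_range) == 2, reads_range[1] >= 3000,
            reads_range[2] <= 1e6, reads_range[1] <= reads_range[2],
            concentration > 0, mixing_floor >= 0, mixing_floor < 1,
            prop_species + prop_genus <= 1)
  structure(as.list(environment()), class = "generator_config")
}

# Taxa scaffold: lineage strings, phylum blocks (Bacteroidetes / Firmicutes /
# other), per-taxon gene counts and the gene-count reference.
make_taxa_pool <- function(cfg, base_weight) {
  n <- cfg$n_taxa
  phyla <- rep(c("Bacteroidetes", "Firmicutes", "Actinobacteria"),
               times = c(ceiling(0.4 * n), ceiling(0.4 * n), n))[seq_len(n)]
  n_sp <- round(cfg$prop_species * n)
  n_ge <- round(cfg$prop_genus * n)
  res <- rep(c("species", "genus", "family"),
             times = c(n_sp, n_ge, n - n_sp - n_ge))
  res <- res[sample.int(n)]
  genus <- sprintf("Genus%03d", seq_len(n))
  species <- sprintf("species%03d", seq_len(n))
  family <- sprintf("%sceae%03d", phyla, seq_len(n))
  labels <- vapply(seq_len(n), function(i) {
    base <- sprintf("p__%s;c__ClassA;o__OrderA;f__%s", phyla[i], family[i])
    switch(res[i],
           species = sprintf("%s;g__%s;s__%s", base, genus[i], species[i]),
           genus = sprintf("%s;g__%s;s__unclassified", base, genus[i]),
           family = sprintf("%s;g__unclassified", base))
  }, character(1))
  # Generalist taxa (broad support / high base weight) carry more genes:
  # gene count is a noisy increasing function of base weight rank, clipped
  # to the observed 1500-8000 range of prokaryote assemblies.
  rk <- rank(base_weight) / n
  genes <- exp(log(1500) + (log(8000) - log(1500)) * rk + rnorm(n, 0, 0.12))
  genes <- pmin(pmax(genes, 1500), 8000)
  ref_rank <- ifelse(res == "species", "species",
                     ifelse(res == "genus", "genus", NA))
  keep <- !is.na(ref_rank)
  ref <- gene_reference(rank = ref_rank[keep],
                        name = ifelse(res == "species", species, genus)[keep],
                        mean_gene_count = round(genes[keep]))
  list(taxa = parse_taxon_labels(labels), phylum = phyla,
       resolution = res, genes = round(genes), reference = ref)
}

#' Generate baseline samples of a synthetic study
#'
#' Subjects are assigned to enterotype components uniformly; each subject's
#' baseline composition is a Dirichlet draw from its component and counts
#' are multinomial at a uniformly drawn read depth.  Component Dirichlet
#' means share a common log-normal backbone (generalist structure) with
#' component-specific driver taxa boosted, giving well-separated clusters.
#'
#' @param cfg a [generator_config()].
#' @return list with `table` (`abundance_table` of baseline samples, ids
#'   `S<k>_T0`), `design` (`study_design`), `reference`
#'   (`gene_reference`) and `truth` (list with per-subject and per-taxon
#'   ground truth, including component Dirichlet means in `component_means`).
#' @export
generate_baseline <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_subjects; tt <- cfg$n_taxa; K <- cfg$n_enterotypes
    base_weight <- exp(rnorm(tt, 0, 1))
    pool <- make_taxa_pool(cfg, base_weight)
    drivers <- matrix(FALSE, K, tt)
    slots <- sample.int(tt)
    for (k in seq_len(K)) {
      idx <- slots[((k - 1) * cfg$driver_taxa + 1):(k * cfg$driver_taxa)]
      drivers[k, idx] <- TRUE
    }
    comp_means <- t(vapply(seq_len(K), function(k) {
      w <- base_weight * ifelse(drivers[k, ], cfg$driver_boost, 1)
      w / sum(w)
    }, numeric(tt)))
    membership <- sample.int(K, n, replace = TRUE)
    depths <- sample(cfg$reads_range[1]:cfg$reads_range[2], n, replace = TRUE)
    comps <- rdirichlet(n, cfg$concentration * comp_means[membership, ,
                                                          drop = FALSE])
    counts <- t(vapply(seq_len(n), function(i) {
      drop(rmultinom(1, depths[i], comps[i, ]))
    }, numeric(tt)))
    subj <- sprintf("S%04d", seq_len(n))
    rownames(counts) <- paste0(subj, "_T0")
    tbl <- abundance_table(counts, pool$taxa)
    design <- study_design(sample_id = rownames(counts), subject_id = subj,
                           intervention = "SYNTH", timepoint = "baseline")
    truth <- list(
      subjects = data.frame(subject_id = subj, enterotype = membership,
                            depth = depths, stringsAsFactors = FALSE),
      taxa = data.frame(label = pool$taxa$label, phylum = pool$phylum,
                        resolution = pool$resolution,
                        gene_count = pool$genes, stringsAsFactors = FALSE),
      component_means = comp_means,
      baseline_compositions = comps)
    list(table = tbl, design = design, reference = pool$reference,
         truth = truth)
  })
}

#' Generate after-intervention samples
#'
#' Each subject's after-sample mixes its true baseline composition with a
#' fresh Dirichlet draw from the subject's own component, in proportion
#' \eqn{w = \mathrm{clip}(floor + gain \cdot score,\ 0,\ 0.95)} where
#' \eqn{score = e_{AGN} z_{AGN} + e_{\alpha} z_{\alpha} + e_{BF} z_{logBF} +
#' \epsilon}.  The map from score to realised beta diversity is therefore
#' monotone by construction.  With all effects, noise and floor at zero and
#' `resample_counts = FALSE`, every after-sample equals its baseline count
#' vector exactly.
#'
#' @param baseline output of [generate_baseline()].
#' @param cfg the same [generator_config()].
#' @param resample_counts logical; if `FALSE` and a subject's mixing weight
#'   is 0, its baseline count vector is copied verbatim (so `after ==
#'   baseline` holds exactly in the degenerate no-effect case).
#' @return list with `table` (baseline + after samples), `design` (both
#'   timepoints), `reference`, and `truth` extended with per-subject
#'   covariate z-scores, planted `score` and mixing weight `w`.
#' @export
generate_after <- function(baseline, cfg, resample_counts = TRUE) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed + 7919L, {
    tbl <- baseline$table
    truth <- baseline$truth
    n <- nrow(truth$subjects)
    comps <- truth$baseline_compositions
    genes <- truth$taxa$gene_count
    phyla <- truth$taxa$phylum
    counts <- tbl$counts
    agn <- drop(counts %*% genes) / rowSums(counts)
    alpha <- apply(counts, 1, shannon)
    b <- rowSums(counts[, phyla == "Bacteroidetes", drop = FALSE])
    f <- rowSums(counts[, phyla == "Firmicutes", drop = FALSE])
    logbf <- log((b + 0.5) / (f + 0.5))
    z <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0
    score <- cfg$effect_agn * z(agn) + cfg$effect_alpha * z(alpha) +
      cfg$effect_bf * z(logbf) + rnorm(n, 0, cfg$noise_sd)
    w <- pmin(pmax(cfg$mixing_floor + cfg$mixing_gain * score, 0), 0.95)
    K_means <- truth$component_means
    K <- nrow(K_means)
    # Perturbation target: a community from a different (random) component,
    # so large mixing weights read as enterotype-scale composition shifts
    # and the realised RC_bray spans its sensitive range instead of
    # saturating at -1.
    other <- if (K > 1) {
      vapply(truth$subjects$enterotype, function(k) {
        sample(setdiff(seq_len(K), k), 1)
      }, integer(1))
    } else truth$subjects$enterotype
    target <- rdirichlet(n, cfg$concentration * K_means[other, , drop = FALSE])
    after_counts <- t(vapply(seq_len(n), function(i) {
      if (w[i] == 0 && !resample_counts) return(as.numeric(counts[i, ]))
      p <- (1 - w[i]) * comps[i, ] + w[i] * target[i, ]
      drop(rmultinom(1, sum(counts[i, ]), p))
    }, numeric(ncol(counts))))
    rownames(after_counts) <- paste0(truth$subjects$subject_id, "_T1")
    all_counts <- rbind(counts, after_counts)
    out_tbl <- abundance_table(all_counts, tbl$taxa)
    design <- study_design(
      sample_id = rownames(all_counts),
      subject_id = rep(truth$subjects$subject_id, 2),
      intervention = "SYNTH",
      timepoint = rep(c("baseline", "after"), each = n))
    truth$subjects$agn_true <- agn
    truth$subjects$alpha_true <- alpha
    truth$subjects$logbf_true <- logbf
    truth$subjects$score_true <- score
    truth$subjects$mixing_w <- w
    list(table = out_tbl, design = design, reference = baseline$reference,
         truth = truth)
  })
}

#' Generate a complete paired synthetic study
#'
#' Convenience wrapper: [generate_baseline()] followed by [generate_after()].
#'
#' @param cfg a [generator_config()].
#' @param resample_counts passed to [generate_after()].
#' @return the [generate_after()] output list.
#' @export
generate_study <- function(cfg = generator_config(), resample_counts = TRUE) {
  generate_after(generate_baseline(cfg), cfg,
                 resample_counts = resample_counts)
}

#' Write a synthetic study to a directory as TSV
#'
#' Emits `abundance.tsv`, `design.tsv`, `gene_reference.tsv` and
#' `ground_truth.tsv` (per-subject truth).
#'
#' @param study output of [generate_study()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_abundance_table(study$table, file.path(dir, "abundance.tsv"))
  write_study_design(study$design, file.path(dir, "design.tsv"))
  write_gene_reference(study$reference, file.path(dir, "gene_reference.tsv"))
  write.table(study$truth$subjects, file.path(dir, "ground_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
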