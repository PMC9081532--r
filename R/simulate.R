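# Synthetic cohorts with known ground truth: Dirichlet-multinomial spectra,
# type-enriched driver mutations, metastatic pairs, cfDNA dilution, and
# clustered-vs-random PPI neighborhoods.

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  s <- sum(g)
  if (s == 0) {
    # pathological all-zero draw; fall back to the normalized alpha
    return(alpha / sum(alpha))
  }
  g / s
}

#' Define a cancer-type generating profile
#'
#' @param type_name Type label.
#' @param exposure_mean Named non-negative vector over catalog signatures
#'   summing to 1 (unnamed signatures are taken as 0).
#' @param specific_signatures Signature names planted as type-specific; each
#'   must have an `exposure_mean` entry of at least 0.15 so the planted
#'   difference clears the downstream selection rule by construction.
#' @param driver_gene_freqs Named vector mapping driver genes to their
#'   per-sample mutation probability.
#' @return An object of class `cancer_type_profile`.
#' @export
cancer_type_profile <- function(type_name, exposure_mean,
                                specific_signatures = character(0),
                                driver_gene_freqs = numeric(0)) {
  stopifnot(is.numeric(exposure_mean), !is.null(names(exposure_mean)),
            all(exposure_mean >= 0))
  if (abs(sum(exposure_mean) - 1) > 1e-9) {
    stop("exposure_mean must sum to 1")
  }
  bad <- specific_signatures[exposure_mean[specific_signatures] < 0.15 |
                               is.na(exposure_mean[specific_signatures])]
  if (length(bad)) {
    stop("planted specific signature(s) below the 0.15 exposure floor: ",
         paste(bad, collapse = ", "))
  }
  stopifnot(all(driver_gene_freqs >= 0 & driver_gene_freqs <= 1))
  structure(list(type_name = type_name, exposure_mean = exposure_mean,
                 specific_signatures = specific_signatures,
                 driver_gene_freqs = driver_gene_freqs),
            class = "cancer_type_profile")
}

#' Random sparse signature catalog
#'
#' Draws `n_signatures` synthetic reference signatures, each concentrated on
#' a random subset of channels with Gamma-distributed weights — sparse,
#' near-orthogonal profiles resembling the sharply peaked entries of real
#' catalogs.
#'
#' @param n_signatures Number of signatures.
#' @param seed Integer seed.
#' @param active_channels Channels carrying mass per signature.
#' @return A [signature_catalog()] with names `S1`, `S2`, ...
#' @export
synthetic_catalog <- function(n_signatures = 12, seed = 1,
                              active_channels = 8) {
  set.seed(seed)
  mat <- matrix(0, n_signatures, 96L)
  for (i in seq_len(n_signatures)) {
    ch <- sample.int(96L, active_channels)
    mat[i, ch] <- stats::rgamma(active_channels, shape = 2)
  }
  mat <- mat / rowSums(mat)
  rownames(mat) <- paste0("S", seq_len(n_signatures))
  signature_catalog(mat)
}

#' Default study profiles: planted type-specific signatures
#'
#' Builds `n_types` profiles over the catalog: type `i` places
#' `specific_weight` on its own planted signature (`S[i]`) and splits the
#' remainder over the last two catalog signatures, which act as shared
#' background processes common to every type (an aging-like and a flat
#' background analogue). Each type also receives `drivers_per_type`
#' consecutive driver genes mutated at `driver_freq`.
#'
#' @param catalog A [signature_catalog()] with at least `n_types + 2`
#'   signatures.
#' @param n_types Number of cancer types.
#' @param specific_weight Mean exposure of the planted signature (>= 0.15).
#' @param shared_weights Two weights for the shared background signatures;
#'   `specific_weight + sum(shared_weights)` must equal 1.
#' @param drivers_per_type,driver_freq Driver-gene planting.
#' @return Named list of [cancer_type_profile()]s.
#' @export
default_type_profiles <- function(catalog, n_types = 10,
                                  specific_weight = 0.35,
                                  shared_weights = c(0.45, 0.20),
                                  drivers_per_type = 3, driver_freq = 0.4) {
  k <- length(catalog$names)
  if (k < n_types + 2L) {
    stop("catalog needs at least n_types + 2 signatures")
  }
  stopifnot(abs(specific_weight + sum(shared_weights) - 1) < 1e-9)
  shared <- catalog$names[c(k - 1L, k)]
  profiles <- lapply(seq_len(n_types), function(i) {
    em <- stats::setNames(numeric(k), catalog$names)
    em[catalog$names[i]] <- specific_weight
    em[shared] <- shared_weights
    drivers <- paste0("GENE", sprintf("%03d", (i - 1L) * drivers_per_type +
                                        seq_len(drivers_per_type)))
    cancer_type_profile(
      type_name = sprintf("TYPE%02d", i),
      exposure_mean = em,
      specific_signatures = catalog$names[i],
      driver_gene_freqs = stats::setNames(rep(driver_freq, drivers_per_type),
                                          drivers)
    )
  })
  stats::setNames(profiles, vapply(profiles, `[[`, "", "type_name"))
}

#' Simulate a labeled tumor cohort
#'
#' Per sample: exposures are drawn from a Dirichlet centered on the type's
#' mean with the given concentration (`Inf` degenerates to the mean
#' exactly); the mutation burden is log-normal with a floor of 10; channel
#' counts are multinomial over the catalog mixture; gene mutations are
#' Bernoulli with type-specific driver frequencies over a background rate.
#'
#' @param profiles List of [cancer_type_profile()]s.
#' @param n_per_type Samples per type (>= 1).
#' @param catalog A [signature_catalog()] covering every profile signature.
#' @param burden_meanlog,burden_sdlog Log-normal burden parameters
#'   (defaults: `log(200)`, `0.8` — exome-scale burdens).
#' @param concentration Dirichlet concentration (> 0, or `Inf`).
#' @param n_genes Size of the background gene pool.
#' @param background_rate Background per-gene mutation probability.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A `synthetic_cohort`: list with `spectra` (samples x 96 counts),
#'   `gene_matrix` (samples x genes binary), `exposures` (true weights),
#'   `truth` (data frame: `sample_id`, `type`, `mutation_count`,
#'   `compartment`, `paired_primary`), `catalog`, `profiles`, `seed`.
#' @export
simulate_cohort <- function(profiles, n_per_type, catalog,
                            burden_meanlog = log(200), burden_sdlog = 0.8,
                            concentration = 50, n_genes = 500,
                            background_rate = 0.01, seed = 1) {
  stopifnot(n_per_type >= 1L, concentration > 0)
  sig_names <- catalog$names
  for (pr in profiles) {
    unknown <- setdiff(names(pr$exposure_mean)[pr$exposure_mean > 0], sig_names)
    if (length(unknown)) {
      stop("profile ", pr$type_name, " references signature(s) absent from ",
           "the catalog: ", paste(unknown, collapse = ", "))
    }
  }
  gene_pool <- paste0("GENE", sprintf("%03d", seq_len(n_genes)))
  extra <- setdiff(unlist(lapply(profiles, function(p) names(p$driver_gene_freqs))),
                   gene_pool)
  gene_pool <- c(gene_pool, extra)

  set.seed(seed)
  n_total <- n_per_type * length(profiles)
  spectra <- matrix(0L, n_total, 96L, dimnames = list(NULL, CHANNELS96))
  gene_matrix <- matrix(0L, n_total, length(gene_pool),
                        dimnames = list(NULL, gene_pool))
  exposures <- matrix(0, n_total, length(sig_names),
                      dimnames = list(NULL, sig_names))
  ids <- character(n_total)
  type_lab <- character(n_total)
  counts_n <- integer(n_total)
  row <- 0L
  for (pr in profiles) {
    mean_full <- stats::setNames(numeric(length(sig_names)), sig_names)
    mean_full[names(pr$exposure_mean)] <- pr$exposure_mean
    p_gene <- stats::setNames(rep(background_rate, length(gene_pool)), gene_pool)
    p_gene[names(pr$driver_gene_freqs)] <- pr$driver_gene_freqs
    for (s in seq_len(n_per_type)) {
      row <- row + 1L
      expo <- if (is.infinite(concentration)) mean_full else
        .rdirichlet1(concentration * mean_full)
      n_mut <- max(10L, as.integer(round(stats::rlnorm(1, burden_meanlog,
                                                       burden_sdlog))))
      channel_p <- drop(crossprod(catalog$matrix, expo))
      spectra[row, ] <- stats::rmultinom(1L, n_mut, channel_p)[, 1L]
      gene_matrix[row, ] <- stats::rbinom(length(gene_pool), 1L, p_gene)
      exposures[row, ] <- expo
      ids[row] <- sprintf("%s_%03d", pr$type_name, s)
      type_lab[row] <- pr$type_name
      counts_n[row] <- n_mut
    }
  }
  rownames(spectra) <- rownames(gene_matrix) <- rownames(exposures) <- ids
  truth <- data.frame(sample_id = ids, type = type_lab,
                      mutation_count = counts_n, compartment = "tissue",
                      paired_primary = NA_character_,
                      stringsAsFactors = FALSE)
  structure(list(spectra = spectra, gene_matrix = gene_matrix,
                 exposures = exposures, truth = truth, catalog = catalog,
                 profiles = profiles, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$spectra), "samples,",
      length(unique(x$truth$type)), "types;",
      "compartments:", paste(names(table(x$truth$compartment)),
                             table(x$truth$compartment),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Add metastatic samples paired to primaries
#'
#' Each metastasis copies its primary's true exposures perturbed by a
#' Dirichlet re-draw with concentration `1/drift` (so small drift means a
#' faithful copy; drift below `1e-10` copies exactly), then resamples the
#' channel counts at the primary's burden. The driver-gene row is inherited.
#'
#' @param cohort A `synthetic_cohort`.
#' @param n_pairs Number of primary/metastasis pairs (at most the number of
#'   tissue samples).
#' @param drift Positive exposure drift.
#' @param seed Integer seed.
#' @param origin_types Optional type labels to restrict the sampled
#'   primaries to.
#' @return The cohort with the metastasis samples appended (compartment
#'   `"metastasis"`, `paired_primary` recorded).
#' @export
simulate_metastases <- function(cohort, n_pairs, drift, seed = 1,
                                origin_types = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (drift <= 0) stop("drift must be positive")
  if (n_pairs == 0L) return(cohort)
  eligible <- cohort$truth$compartment == "tissue"
  if (!is.null(origin_types)) eligible <- eligible & cohort$truth$type %in% origin_types
  pool <- which(eligible)
  if (n_pairs > length(pool)) {
    stop("n_pairs exceeds the number of eligible tissue samples")
  }
  set.seed(seed)
  chosen <- sample(pool, n_pairs)
  add_spec <- matrix(0L, n_pairs, 96L, dimnames = list(NULL, CHANNELS96))
  add_expo <- matrix(0, n_pairs, ncol(cohort$exposures),
                     dimnames = list(NULL, colnames(cohort$exposures)))
  add_gene <- cohort$gene_matrix[chosen, , drop = FALSE]
  ids <- sprintf("%s_met%02d", cohort$truth$sample_id[chosen], seq_len(n_pairs))
  for (i in seq_len(n_pairs)) {
    expo <- cohort$exposures[chosen[i], ]
    if (drift >= 1e-10) expo <- .rdirichlet1(expo / drift)
    n_mut <- cohort$truth$mutation_count[chosen[i]]
    channel_p <- drop(crossprod(cohort$catalog$matrix, expo))
    add_spec[i, ] <- stats::rmultinom(1L, n_mut, channel_p)[, 1L]
    add_expo[i, ] <- expo
  }
  rownames(add_spec) <- rownames(add_expo) <- rownames(add_gene) <- ids
  add_truth <- data.frame(sample_id = ids,
                          type = cohort$truth$type[chosen],
                          mutation_count = cohort$truth$mutation_count[chosen],
                          compartment = "metastasis",
                          paired_primary = cohort$truth$sample_id[chosen],
                          stringsAsFactors = FALSE)
  cohort$spectra <- rbind(cohort$spectra, add_spec)
  cohort$gene_matrix <- rbind(cohort$gene_matrix, add_gene)
  cohort$exposures <- rbind(cohort$exposures, add_expo)
  cohort$truth <- rbind(cohort$truth, add_truth)
  cohort
}

#' Add cfDNA samples as diluted copies of tissue samples
#'
#' cfDNA channel counts are a binomial thinning of the paired tissue
#' spectrum at rate `dilution`; each driver-gene mutation is independently
#' dropped with probability `dropout`. True exposures are inherited.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dilution Retention probability per mutation, in (0, 1].
#' @param dropout Per-gene drop probability, in [0, 1).
#' @param seed Integer seed.
#' @param sample_ids Tissue samples to copy (default: all tissue samples).
#' @return The cohort with cfDNA samples appended (compartment `"cfdna"`).
#' @export
simulate_cfdna <- function(cohort, dilution, dropout = 0, seed = 1,
                           sample_ids = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (dilution <= 0 || dilution > 1) stop("dilution must be in (0, 1]")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  tissue <- cohort$truth$sample_id[cohort$truth$compartment == "tissue"]
  if (is.null(sample_ids)) sample_ids <- tissue
  if (!all(sample_ids %in% tissue)) {
    stop("sample_ids must name tissue samples of the cohort")
  }
  set.seed(seed)
  idx <- match(sample_ids, cohort$truth$sample_id)
  n <- length(idx)
  add_spec <- matrix(0L, n, 96L, dimnames = list(NULL, CHANNELS96))
  add_gene <- matrix(0L, n, ncol(cohort$gene_matrix),
                     dimnames = list(NULL, colnames(cohort$gene_matrix)))
  for (i in seq_len(n)) {
    src <- cohort$spectra[idx[i], ]
    add_spec[i, ] <- stats::rbinom(96L, src, dilution)
    g <- cohort$gene_matrix[idx[i], ]
    keep <- stats::rbinom(length(g), 1L, 1 - dropout)
    add_gene[i, ] <- as.integer(g == 1L & keep == 1L)
  }
  ids <- paste0(sample_ids, "_cf")
  rownames(add_spec) <- rownames(add_gene) <- ids
  add_expo <- cohort$exposures[idx, , drop = FALSE]
  rownames(add_expo) <- ids
  add_truth <- data.frame(sample_id = ids,
                          type = cohort$truth$type[idx],
                          mutation_count = as.integer(rowSums(add_spec)),
                          compartment = "cfdna",
                          paired_primary = sample_ids,
                          stringsAsFactors = FALSE)
  cohort$spectra <- rbind(cohort$spectra, add_spec)
  cohort$gene_matrix <- rbind(cohort$gene_matrix, add_gene)
  cohort$exposures <- rbind(cohort$exposures, add_expo)
  cohort$truth <- rbind(cohort$truth, add_truth)
  cohort
}

#' Simulate a PPI network with a planted functional module
#'
#' Edges inside the module appear with probability `p_in`, every other pair
#' with probability `p_out` (`p_in > p_out` required), mimicking the
#' functionally clustered interactions of driver genes against a sparse
#' background interactome.
#'
#' @param cancer_gene_module Character vector of module gene symbols.
#' @param background_genes Number of background genes (`BG1`, `BG2`, ...).
#' @param p_in,p_out Within-module and background edge probabilities.
#' @param seed Integer seed.
#' @return A [ppi_network()] whose gene universe covers module and
#'   background genes.
#' @export
simulate_ppi <- function(cancer_gene_module, background_genes = 200,
                         p_in, p_out, seed = 1) {
  if (p_in <= p_out) stop("p_in must exceed p_out")
  module <- toupper(trimws(cancer_gene_module))
  genes <- c(module, paste0("BG", seq_len(background_genes)))
  set.seed(seed)
  pairs <- utils::combn(genes, 2L)
  in_module <- pairs[1L, ] %in% module & pairs[2L, ] %in% module
  p <- ifelse(in_module, p_in, p_out)
  present <- stats::rbinom(ncol(pairs), 1L, p) == 1L
  ppi_network(pairs[1L, present], pairs[2L, present], genes = genes)
}
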