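#' Parameters of the synthetic PBMC-like generator
#'
#' Bundles and validates the generator's knobs. Defaults describe a small
#' but realistic droplet-style experiment: 2000 cells, 500 genes, three
#' cell types with 10 markers each boosted 8-fold (`marker_log2fc = 3`,
#' the order of magnitude of canonical PBMC markers), two samples,
#' log-normal library-size variation, negative-binomial noise
#' (variance = mu + mu^2/dispersion) and ~5% mitochondrial content.
#'
#' @param n_cells,n_features,n_types,markers_per_type,n_samples Counts.
#' @param marker_log2fc Log2 fold boost of a type's markers in that type.
#' @param libsize_meanlog,libsize_sdlog Log-normal library-size factor.
#' @param nb_dispersion Negative-binomial size parameter (> 0).
#' @param mito_features Number of `MT-` prefixed features.
#' @param mito_fraction_mean Expected mitochondrial fraction, in (0, 1).
#' @param total_mean Expected total counts per cell at library factor 1.
#' @param type_proportions Optional simplex vector of type proportions
#'   (default: equal).
#' @param seed Integer seed; the generator is a pure function of the
#'   parameters.
#' @return A `SimParams` list.
#' @export
sim_params <- function(n_cells = 2000, n_features = 500, n_types = 3,
                       markers_per_type = 10, marker_log2fc = 3,
                       n_samples = 2, libsize_meanlog = 0, libsize_sdlog = 0.35,
                       nb_dispersion = 1, mito_features = 10,
                       mito_fraction_mean = 0.05, total_mean = 2000,
                       type_proportions = NULL, seed = 42) {
  if (is.null(type_proportions)) type_proportions <- rep(1 / n_types, n_types)
  p <- list(n_cells = n_cells, n_features = n_features, n_types = n_types,
            markers_per_type = markers_per_type, marker_log2fc = marker_log2fc,
            n_samples = n_samples, libsize_meanlog = libsize_meanlog,
            libsize_sdlog = libsize_sdlog, nb_dispersion = nb_dispersion,
            mito_features = mito_features, mito_fraction_mean = mito_fraction_mean,
            total_mean = total_mean, type_proportions = type_proportions,
            seed = as.integer(seed))
  if (length(type_proportions) != n_types || any(type_proportions < 0) ||
      abs(sum(type_proportions) - 1) > 1e-8) {
    err_param("type_proportions must be a simplex vector of length n_types")
  }
  if (nb_dispersion <= 0) err_param("nb_dispersion must be > 0")
  if (mito_fraction_mean <= 0 || mito_fraction_mean >= 1) {
    err_param("mito_fraction_mean must be in (0, 1)")
  }
  if (markers_per_type * n_types > n_features - mito_features) {
    err_param("markers_per_type * n_types must fit among the non-mitochondrial features")
  }
  class(p) <- "SimParams"
  p
}

#' Simulate a PBMC-like single-cell dataset
#'
#' Counts are negative binomial with mean
#' `base_mean[f] * lib[c] * boost(f, c)`: per-feature baseline means are
#' gamma-distributed (markers pinned at the average baseline so fold
#' changes are interpretable), `lib` is a per-cell log-normal library-size
#' factor, and `boost` multiplies a type's marker features by
#' `2^marker_log2fc` in cells of that type. Mitochondrial features (ids
#' `MT-1`, `MT-2`, ...) share `mito_fraction_mean` of the expected library.
#' Cells are assigned to types by `type_proportions` and to samples
#' uniformly. Ground truth lands in `cell_meta` (`true_type`, `sample`) and
#' `feature_meta` (`marker_of`, `is_mito`).
#'
#' @param params A [sim_params()] object.
#' @return A `CellContainer`, reproducible bit-for-bit from `params$seed`.
#' @export
simulate_cells <- function(params = sim_params()) {
  stopifnot(inherits(params, "SimParams"))
  p <- params
  n_nonmito <- p$n_features - p$mito_features
  feature_ids <- c(paste0("gene", seq_len(n_nonmito)),
                   if (p$mito_features > 0) paste0("MT-", seq_len(p$mito_features)))
  types <- paste0("type_", seq_len(p$n_types))
  marker_of <- rep(NA_character_, p$n_features)
  for (t in seq_len(p$n_types)) {
    marker_of[((t - 1) * p$markers_per_type + 1):(t * p$markers_per_type)] <- types[[t]]
  }
  withr::with_seed(p$seed, {
    base <- rgamma(n_nonmito, shape = 0.5, rate = 1)
    nonmito_total <- (1 - p$mito_fraction_mean) * p$total_mean
    base <- base / sum(base) * nonmito_total
    base[!is.na(marker_of[seq_len(n_nonmito)])] <- nonmito_total / n_nonmito
    mito_base <- rep(p$mito_fraction_mean * p$total_mean / max(p$mito_features, 1),
                     p$mito_features)
    base_mean <- c(base, mito_base)

    cell_type <- sample(types, p$n_cells, replace = TRUE, prob = p$type_proportions)
    sample_id <- sample(paste0("sample_", seq_len(p$n_samples)), p$n_cells, replace = TRUE)
    lib <- rlnorm(p$n_cells, meanlog = p$libsize_meanlog, sdlog = p$libsize_sdlog)

    boost <- matrix(1, p$n_features, p$n_cells)
    for (t in seq_len(p$n_types)) {
      owned <- which(!is.na(marker_of) & marker_of == types[[t]])
      boost[owned, cell_type == types[[t]]] <- 2^p$marker_log2fc
    }
    mu <- (base_mean %o% lib) * boost
    counts <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = p$nb_dispersion),
                     nrow = p$n_features)
  })
  cc <- new_container(as_sparse(counts), feature_ids,
                      paste0("cell_", seq_len(p$n_cells)),
                      cell_meta = tibble::tibble(sample = sample_id,
                                                 true_type = cell_type))
  cc$feature_meta$marker_of <- marker_of
  cc$feature_meta$is_mito <- startsWith(feature_ids, "MT-")
  cc
}
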