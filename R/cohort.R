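# Synthetic cohort generator: multivariate-normal ROI time series with a
# community-structured latent covariance, group effects injected as edge
# attenuation at designated target nodes, and cognitive scores coupled to
# realized redundancy in the cognitively normal group only.

# Calibration tables mapping latent edge attenuation at the target nodes to
# the realized standardized group difference (Cohen's d) in a single target
# node's across-density ROI redundancy. Calibrated once by simulation
# (200 draws per arm) at two reference scales: the default study conditions
# (300 nodes, 12 communities) and the reduced simulation scale (100 nodes,
# 10 communities); within/between correlations 0.4/0.05, 140 volumes in
# both. The relation is nonlinear because moderately attenuated
# within-community edges still survive density thresholding, and it is
# scale-dependent because estimation noise grows as the ROI averages over
# fewer partner nodes. Monotone interpolation inverts the nearest-scale
# table for a requested d.
ATTENUATION_CALIBRATION <- list(
  n300 = data.frame(
    attenuation = c(0, 0.05, 0.10, 0.15, 0.20, 0.27, 0.32, 0.36, 0.40, 0.45, 0.50),
    d           = c(0, 0.04, 0.15, 0.28, 0.38, 0.46, 0.58, 0.67, 0.82, 0.97, 1.13)),
  n100 = data.frame(
    attenuation = c(0, 0.05, 0.10, 0.20, 0.30, 0.36, 0.42, 0.48, 0.55),
    d           = c(0, 0.02, 0.13, 0.25, 0.42, 0.57, 0.68, 0.79, 1.00))
)

attenuation_for_d <- function(d, n_nodes = 300) {
  tab <- if (n_nodes >= 200) ATTENUATION_CALIBRATION$n300 else ATTENUATION_CALIBRATION$n100
  if (d > max(tab$d))
    abort_config(sprintf("requested effect size %.2f exceeds the calibrated range (max %.2f)",
                         d, max(tab$d)), field = "effect_size_d")
  stats::approx(tab$d, tab$attenuation, xout = d, ties = "ordered")$y
}

#' Configuration for a synthetic three-group cohort
#'
#' Defaults emulate the study design the analysis pipeline targets: a
#' 300-node functional parcellation, diagnostic groups of 39 cognitively
#' normal (CN), 54 early-MCI and 37 late-MCI subjects, 140 volumes at a 3 s
#' repetition time, a group deficit of Cohen's d = 0.6 confined to two
#' designated "posterior hippocampal" nodes with no eMCI-lMCI difference,
#' and a memory composite coupled to target-node redundancy (standardized
#' slope 0.3) in the CN group only. Cognitive score scales follow the
#' composite conventions: MEM group means 1.01 / 0.47 / 0.07 (SD 0.55), EF
#' means 0.78 / 0.49 / 0.22 (SD 0.85).
#'
#' The latent connectivity model is a stochastic block (community) structure:
#' `n_communities` contiguous blocks with within-community correlation
#' `r_within` (default 0.4) and between-community correlation `r_between`
#' (default 0.05), yielding density-thresholded graphs with realistic hubs
#' and modules. Group effects are injected upstream, as attenuation of
#' latent edge weights incident to the target nodes; the mapping from the
#' requested Cohen's d — defined per target node, on across-density ROI
#' redundancy — to the attenuation fraction is inverted by monotone
#' interpolation from calibration tables measured once by simulation at two
#' reference scales (300 and 100 nodes; e.g. at 300 nodes, realized d of
#' about 0.38 / 0.58 / 0.82 at attenuations 0.20 / 0.32 / 0.40). The
#' relation is nonlinear because moderately attenuated within-community
#' edges still survive density thresholding.
#'
#' @param n_nodes Number of parcellation nodes (default 300).
#' @param group_sizes Named counts per group (default CN 39, eMCI 54,
#'   lMCI 37); all must be at least 2.
#' @param n_volumes Time points per subject (default 140; a conventional
#'   resting-state scan length, not a fixed property of the design).
#' @param tr_seconds Sampling interval in seconds (default 3).
#' @param n_communities Latent communities (default 12).
#' @param r_within,r_between Within/between community correlations.
#' @param target_nodes Indices of the effect-site ("posterior hippocampal")
#'   nodes; default the first two nodes of community 1.
#' @param effect_size_d Standardized CN-vs-MCI difference injected at the
#'   target nodes (default 0.6; must be non-negative).
#' @param emci_lmci_delta Additional effect for the late-MCI group
#'   (default 0: the two MCI groups are equivalent).
#' @param mem_coupling_cn Within-CN standardized slope linking target-node
#'   redundancy to the MEM score (default 0.3); 0 in the MCI groups.
#' @param mem_group_means,mem_sd MEM score means per group and common SD.
#' @param ef_group_means,ef_sd EF score means per group and common SD
#'   (EF is uncoupled to redundancy in every group).
#' @param outlier_rate Per-volume probability of a motion outlier flag.
#' @param covariate_model Distribution parameters for age, sex, education.
#' @param densities Density grid used when the generator computes target-node
#'   redundancy for the MEM coupling.
#' @param max_length Maximum route length for the generator's redundancy
#'   computation (default 4).
#' @param seed RNG seed; all randomness flows from it.
#' @return A validated list of class `redunet_cohort_config`.
#' @export
cohort_config <- function(n_nodes = 300,
                          group_sizes = c(CN = 39, eMCI = 54, lMCI = 37),
                          n_volumes = 140, tr_seconds = 3,
                          n_communities = 12, r_within = 0.4, r_between = 0.05,
                          target_nodes = c(1L, 2L),
                          effect_size_d = 0.6, emci_lmci_delta = 0,
                          mem_coupling_cn = 0.3,
                          mem_group_means = c(CN = 1.01, eMCI = 0.47, lMCI = 0.07),
                          mem_sd = 0.55,
                          ef_group_means = c(CN = 0.78, eMCI = 0.49, lMCI = 0.22),
                          ef_sd = 0.85,
                          outlier_rate = 0.03,
                          covariate_model = list(age_mean = 73, age_sd = 6,
                                                 education_means = c(CN = 16.3, eMCI = 15.8, lMCI = 16.9),
                                                 education_sd = 2.6,
                                                 p_female = 0.5),
                          densities = density_grid(),
                          max_length = 4,
                          seed = 1) {
  cfg <- as.list(environment())
  if (length(group_sizes) < 2 || is.null(names(group_sizes)))
    abort_config("must be a named vector of at least two groups", field = "group_sizes")
  if (any(group_sizes < 2))
    abort_config("every group needs at least 2 subjects", field = "group_sizes")
  if (n_nodes < 4) abort_config("need at least 4 nodes", field = "n_nodes")
  if (length(target_nodes) < 1 || any(target_nodes < 1) ||
      max(target_nodes) > n_nodes)
    abort_config(sprintf("indices must lie in 1..%d", n_nodes), field = "target_nodes")
  if (effect_size_d < 0) abort_config("must be non-negative", field = "effect_size_d")
  if (effect_size_d + emci_lmci_delta < 0)
    abort_config("effect_size_d + emci_lmci_delta must be non-negative",
                 field = "emci_lmci_delta")
  if (abs(mem_coupling_cn) > 1)
    abort_config("standardized coupling must lie in [-1, 1]", field = "mem_coupling_cn")
  if (!(r_within > r_between && r_within < 1 && r_between >= 0))
    abort_config("need 0 <= r_between < r_within < 1", field = "r_within")
  if (n_volumes < 3) abort_config("need at least 3 volumes", field = "n_volumes")
  if (!(outlier_rate >= 0 && outlier_rate < 1))
    abort_config("must lie in [0, 1)", field = "outlier_rate")
  if (n_communities < 2 || n_communities > n_nodes)
    abort_config("need 2 <= n_communities <= n_nodes", field = "n_communities")
  structure(cfg, class = "redunet_cohort_config")
}

community_membership <- function(n_nodes, n_communities) {
  sizes <- rep(n_nodes %/% n_communities, n_communities)
  extra <- n_nodes %% n_communities
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(n_communities), times = sizes)
}

#' Latent block-structured base correlation matrix
#'
#' @param config A [cohort_config()].
#' @return An `n_nodes` x `n_nodes` correlation matrix: `r_within` inside
#'   contiguous communities, `r_between` elsewhere, unit diagonal. Positive
#'   semidefinite by construction.
#' @export
base_covariance <- function(config) {
  stopifnot(inherits(config, "redunet_cohort_config"))
  memb <- community_membership(config$n_nodes, config$n_communities)
  S <- matrix(config$r_between, config$n_nodes, config$n_nodes)
  same <- outer(memb, memb, `==`)
  S[same] <- config$r_within
  diag(S) <- 1
  ids <- default_node_ids(config$n_nodes)
  dimnames(S) <- list(ids, ids)
  S
}

#' Attenuate latent edges incident to target nodes
#'
#' Multiplies every off-diagonal weight on an edge touching at least one
#' target node by `1 - attenuation`, leaving all other entries and the
#' diagonal unchanged. Symmetry is preserved; an edge between two target
#' nodes is attenuated once.
#'
#' @param base_weights Symmetric numeric matrix of latent edge weights.
#' @param target_nodes Node indices to attenuate.
#' @param attenuation Fraction in \[0, 1\].
#' @return The modified weight matrix.
#' @export
inject_node_effect <- function(base_weights, target_nodes, attenuation) {
  if (!(attenuation >= 0 && attenuation <= 1))
    abort_config("must lie in [0, 1]", field = "attenuation")
  n <- nrow(base_weights)
  if (any(target_nodes < 1) || any(target_nodes > n))
    abort_validation(sprintf("target node out of range 1..%d", n))
  hit <- logical(n)
  hit[target_nodes] <- TRUE
  mask <- outer(hit, hit, `|`)
  diag(mask) <- FALSE
  W <- base_weights
  W[mask] <- W[mask] * (1 - attenuation)
  W
}

#' Sample multivariate-normal ROI time series
#'
#' Rows are drawn independently from a zero-mean multivariate normal with the
#' given covariance (factored by eigendecomposition, so rank-deficient
#' covariances are allowed; eigenvalues below `-1e-8` raise an error with
#' diagnostics).
#'
#' @param covariance Symmetric positive-semidefinite matrix.
#' @param n_volumes Number of time points (rows).
#' @param seed Optional RNG seed for a deterministic draw.
#' @return An `n_volumes` x `n_nodes` matrix, columns named after the
#'   covariance dimnames.
#' @export
generate_timeseries <- function(covariance, n_volumes, seed = NULL) {
  fac <- mvn_factor(covariance)
  factored_timeseries(fac, n_volumes, seed)
}

# Symmetric square root of a PSD covariance, computed once per group.
mvn_factor <- function(covariance) {
  if (!isTRUE(all.equal(covariance, t(covariance), tolerance = 1e-10)))
    abort_validation("covariance must be symmetric.")
  eg <- eigen(covariance, symmetric = TRUE)
  if (min(eg$values) < -1e-8)
    rlang::abort(sprintf(
      "covariance is not positive semidefinite (min eigenvalue %.3e, max %.3e).",
      min(eg$values), max(eg$values)), class = "redunet_numeric_error")
  lam <- pmax(eg$values, 0)
  fac <- t(eg$vectors %*% (t(eg$vectors) * sqrt(lam)))
  dimnames(fac) <- dimnames(covariance)
  fac
}

factored_timeseries <- function(fac, n_volumes, seed = NULL) {
  n <- nrow(fac)
  Z <- with_seed(seed, matrix(rnorm(n_volumes * n), n_volumes, n))
  X <- Z %*% fac
  colnames(X) <- colnames(fac)
  X
}

clipped_round <- function(x, lo, hi) pmin(hi, pmax(lo, round(x)))

# Across-density target-ROI redundancy for one subject's time series,
# computed exactly as the analysis pipeline computes it.
target_roi_redundancy <- function(ts, target_nodes, densities, max_length) {
  stk <- density_stack(correlation_matrix(ts), grid = densities)
  per_density <- vapply(stk$adjacencies, function(A)
    mean(roi_redundancy_nodes(A, target_nodes, max_length)), numeric(1))
  mean(per_density)
}

#' Generate a synthetic multi-group cohort
#'
#' Draws per-subject ROI time series from the group-specific latent
#' covariance ([base_covariance()] with target-node attenuation in the MCI
#' groups via [inject_node_effect()]), computes each subject's realized
#' target-node redundancy through the same connectome/metric path the
#' analysis uses, and generates cognitive scores on top: MEM coupled to
#' redundancy (standardized slope `mem_coupling_cn`) within the CN group
#' only, EF uncoupled everywhere, MMSE/age/sex/education from the covariate
#' model. Deterministic for a fixed config (including seed).
#'
#' @param config A [cohort_config()].
#' @return A `redunet_cohort`: list with `subjects` (tibble: id, group, age,
#'   sex, education, mem, ef, mmse, plus the generator's realized
#'   `gen_target_redundancy`), `timeseries` (named list of matrices),
#'   `outlier_flags` (named list of logical vectors), `parcellation`
#'   (tibble: node, x, y, z, network, roi_group), `config`, `seed`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "redunet_cohort_config"))
    abort_config("must be built with cohort_config()", field = "config")
  groups <- names(config$group_sizes)
  n_sub <- sum(config$group_sizes)
  group_of <- rep(groups, times = config$group_sizes)
  subject_ids <- sprintf("sub%03d", seq_len(n_sub))

  a_mci <- attenuation_for_d(config$effect_size_d, config$n_nodes)
  a_lmci <- attenuation_for_d(config$effect_size_d + config$emci_lmci_delta,
                              config$n_nodes)
  S_base <- base_covariance(config)
  # first group is the unaffected (CN) reference; second gets the eMCI
  # attenuation, any further groups the lMCI attenuation
  sigma <- setNames(vector("list", length(groups)), groups)
  sigma[[1L]] <- S_base
  if (length(groups) >= 2)
    sigma[[2L]] <- inject_node_effect(S_base, config$target_nodes, a_mci)
  if (length(groups) >= 3)
    for (k in 3:length(groups))
      sigma[[k]] <- inject_node_effect(S_base, config$target_nodes, a_lmci)

  factors <- lapply(sigma, mvn_factor)
  seeds <- derive_seeds(config$seed, n_sub + 1L)
  ts_list <- vector("list", n_sub)
  red <- numeric(n_sub)
  for (i in seq_len(n_sub)) {
    ts_list[[i]] <- factored_timeseries(factors[[group_of[i]]], config$n_volumes,
                                        seed = seeds[i])
    red[i] <- target_roi_redundancy(ts_list[[i]], config$target_nodes,
                                    config$densities, config$max_length)
  }
  names(ts_list) <- subject_ids

  cm <- config$covariate_model
  drawn <- with_seed(seeds[n_sub + 1L], {
    flags <- lapply(seq_len(n_sub), function(i)
      as.logical(rbinom(config$n_volumes, 1, config$outlier_rate)))
    mem <- ef <- numeric(n_sub)
    for (g in groups) {
      in_g <- group_of == g
      eps <- rnorm(sum(in_g))
      cpl <- if (g == groups[1L]) config$mem_coupling_cn else 0
      zr <- if (sd(red[in_g]) > 0) as.numeric(scale(red[in_g])) else rep(0, sum(in_g))
      mem[in_g] <- config$mem_group_means[[g]] +
        config$mem_sd * (cpl * zr + sqrt(1 - cpl^2) * eps)
      ef[in_g] <- config$ef_group_means[[g]] + config$ef_sd * rnorm(sum(in_g))
    }
    mmse_means <- rep(c(29, 28.3, 27.3), length.out = length(groups))[match(group_of, groups)]
    edu_means <- rep(cm$education_means, length.out = length(groups))[match(group_of, groups)]
    subjects <- tibble::tibble(
      subject_id = subject_ids,
      group = factor(group_of, levels = groups),
      age = clipped_round(rnorm(n_sub, cm$age_mean, cm$age_sd), 60, 90),
      sex = sample(c("F", "M"), n_sub, replace = TRUE,
                   prob = c(cm$p_female, 1 - cm$p_female)),
      education = clipped_round(rnorm(n_sub, edu_means, cm$education_sd), 8, 20),
      mem = mem, ef = ef,
      mmse = as.integer(clipped_round(rnorm(n_sub, mmse_means, 1), 24, 30)),
      gen_target_redundancy = red)
    list(subjects = subjects, flags = flags)
  })
  subjects <- drawn$subjects
  flags <- drawn$flags
  names(flags) <- subject_ids

  structure(
    list(subjects = subjects, timeseries = ts_list, outlier_flags = flags,
         parcellation = make_parcellation(config), config = config,
         seed = config$seed),
    class = "redunet_cohort")
}

#' Parcellation table for a synthetic cohort
#'
#' Node ids, deterministic pseudo-coordinates, network (community) labels,
#' and ROI-group tags. The four "hippocampal" nodes are tagged
#' `hippocampus_posterior_left/right` (the configured target nodes, placed
#' in the first community, which is labelled `default_mode` in keeping with
#' the posterior hippocampus clustering with that network) and
#' `hippocampus_anterior_left/right` (first two nodes of the second
#' community); every other node is tagged `cortex`.
#'
#' @param config A [cohort_config()].
#' @return A tibble: `node`, `x`, `y`, `z`, `network`, `roi_group`.
#' @export
make_parcellation <- function(config) {
  memb <- community_membership(config$n_nodes, config$n_communities)
  ids <- default_node_ids(config$n_nodes)
  nets <- sprintf("net%02d", memb)
  nets[memb == 1L] <- "default_mode"
  nets[memb == 2L] <- "medial_temporal"
  roi_group <- rep("cortex", config$n_nodes)
  tgt <- config$target_nodes
  roi_group[tgt[1L]] <- "hippocampus_posterior_left"
  if (length(tgt) >= 2) roi_group[tgt[2L]] <- "hippocampus_posterior_right"
  ant <- head(setdiff(which(memb == 2L), tgt), 2)
  if (length(ant) >= 1) roi_group[ant[1L]] <- "hippocampus_anterior_left"
  if (length(ant) >= 2) roi_group[ant[2L]] <- "hippocampus_anterior_right"
  coords <- with_seed(config$seed %% 100000L + 17L,
                      matrix(round(stats::runif(3 * config$n_nodes, -70, 70), 1),
                             ncol = 3))
  tibble::tibble(node = ids, x = coords[, 1], y = coords[, 2], z = coords[, 3],
                 network = nets, roi_group = roi_group)
}

#' @export
print.redunet_cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf("<redunet_cohort> %d subjects (%s), %d nodes, %d volumes\n",
              nrow(x$subjects),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              x$config$n_nodes, x$config$n_volumes))
  invisible(x)
}
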