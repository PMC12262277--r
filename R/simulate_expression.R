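#' Expression simulation configuration
#'
#' Parameters of the microregion expression simulator. Each microregion (MR)
#' carries two latent factors in \[0, 1\]: a progression score (normal →
#' invasive) and an inflammation score. Gene log-means are linear in the
#' factors through a sparse loading matrix — three planted gene modules
#' (progression-up, progression-down i.e. melanocytic, inflammation-up) plus
#' unloaded background genes — and counts are negative binomial.
#'
#' @param seed integer RNG seed.
#' @param n_microregions,n_genes dimensions (at least 10 genes; the SOM stage
#'   needs gene modules to exist).
#' @param module_size genes per planted module.
#' @param loading_scale magnitude of nonzero loadings (natural-log fold range).
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); values near 0 approach Poisson.
#' @param baseline_log_mean,baseline_log_sd log-scale baseline expression.
#' @param n_batches number of batches (metadata label; `batch_log_sd` adds a
#'   per-gene per-batch log-normal offset).
#' @param batch_log_sd sd of batch offsets on the log scale (0 = none).
#' @param progression,inflammation optional explicit factor score vectors
#'   (length `n_microregions`, values in \[0, 1\]); when supplied they
#'   override `factor_design`.
#' @param factor_design `"random"` (independent uniform factors) or `"arms"`
#'   (three planted arms: root = low progression / low inflammation,
#'   arm 2 = high progression / low inflammation, arm 3 = high progression /
#'   high inflammation — a branching trajectory).
#' @return object of class `expression_sim_config`.
#' @export
expression_sim_config <- function(seed = 1L, n_microregions = 60,
                                  n_genes = 300, module_size = NULL,
                                  loading_scale = 1.5, dispersion = 0.15,
                                  baseline_log_mean = log(50),
                                  baseline_log_sd = 0.7,
                                  n_batches = 1, batch_log_sd = 0,
                                  progression = NULL, inflammation = NULL,
                                  factor_design = c("random", "arms")) {
  factor_design <- match.arg(factor_design)
  check_factor <- function(f) {
    if (!is.null(f)) {
      stopifnot(length(f) == n_microregions, all(f >= 0), all(f <= 1))
    }
  }
  check_factor(progression); check_factor(inflammation)
  rm(check_factor)
  if (n_genes < 10) {
    stop("expression_sim_config: n_genes must be >= 10", call. = FALSE)
  }
  stopifnot(n_microregions >= 2, dispersion >= 0, loading_scale >= 0)
  if (is.null(module_size)) module_size <- max(3L, floor(n_genes / 6))
  if (3 * module_size > n_genes) {
    stop("expression_sim_config: 3 * module_size exceeds n_genes", call. = FALSE)
  }
  structure(as.list(environment()), class = "expression_sim_config")
}

#' Simulate a microregion expression matrix
#'
#' Gene means follow `mu = exp(baseline + a_g * progression +
#' b_g * inflammation + batch offset)`; counts are negative binomial with the
#' configured dispersion. Loadings are sparse: module 1 loads positively on
#' progression, module 2 negatively (a melanocytic-identity module), module 3
#' positively on inflammation; remaining genes are unloaded background. The
#' full generative truth (factor scores, loadings, module labels, arm labels)
#' is returned alongside the observable matrix.
#'
#' @param config an [expression_sim_config].
#' @return list of class `expression_sim` with elements `matrix`
#'   (an [expression_matrix]) and `truth` (list: `factors`, `loadings`,
#'   `modules`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expression_sim_config"))
  set.seed(config$seed)
  n_mr <- config$n_microregions
  n_g <- config$n_genes

  if (!is.null(config$progression) || !is.null(config$inflammation)) {
    arm <- rep(NA_character_, n_mr)
    progression <- config$progression %||% stats::runif(n_mr)
    inflammation <- config$inflammation %||% stats::runif(n_mr)
  } else if (config$factor_design == "arms") {
    arm <- sample(rep_len(c("root", "arm2", "arm3"), n_mr))
    progression <- ifelse(arm == "root",
                          stats::runif(n_mr, 0, 0.25),
                          stats::runif(n_mr, 0.65, 1))
    inflammation <- ifelse(arm == "arm3",
                           stats::runif(n_mr, 0.65, 1),
                           stats::runif(n_mr, 0, 0.25))
  } else {
    arm <- rep(NA_character_, n_mr)
    progression <- stats::runif(n_mr)
    inflammation <- stats::runif(n_mr)
  }

  ms <- config$module_size
  module <- rep("background", n_g)
  module[seq_len(ms)] <- "progression_up"
  module[ms + seq_len(ms)] <- "progression_down"
  module[2 * ms + seq_len(ms)] <- "inflammation_up"
  a_g <- numeric(n_g); b_g <- numeric(n_g)
  ls <- config$loading_scale
  a_g[module == "progression_up"] <- stats::runif(ms, 0.7, 1) * ls
  a_g[module == "progression_down"] <- -stats::runif(ms, 0.7, 1) * ls
  b_g[module == "inflammation_up"] <- stats::runif(ms, 0.7, 1) * ls

  baseline <- stats::rnorm(n_g, config$baseline_log_mean, config$baseline_log_sd)
  batch <- rep_len(paste0("batch", seq_len(config$n_batches)), n_mr)
  batch_off <- matrix(0, config$n_batches, n_g)
  if (config$batch_log_sd > 0) {
    batch_off[] <- stats::rnorm(config$n_batches * n_g, 0, config$batch_log_sd)
  }

  log_mu <- outer(progression, a_g) + outer(inflammation, b_g) +
    matrix(baseline, n_mr, n_g, byrow = TRUE) +
    batch_off[match(batch, paste0("batch", seq_len(config$n_batches))), , drop = FALSE]
  mu <- exp(log_mu)
  counts <- matrix(
    if (config$dispersion > 0) {
      stats::rnbinom(n_mr * n_g, mu = as.vector(mu), size = 1 / config$dispersion)
    } else {
      stats::rpois(n_mr * n_g, as.vector(mu))
    },
    n_mr, n_g)
  mr_id <- sprintf("MR%03d", seq_len(n_mr))
  rownames(counts) <- mr_id
  colnames(counts) <- sprintf("gene%04d", seq_len(n_g))

  stage_grid <- c("N", "P", "MIS", "RGP", "VGP")
  stage <- stage_grid[pmin(5L, 1L + floor(progression * 5))]
  md <- data.frame(mr_id = mr_id, specimen_id = "SIM1", stage = stage,
                   segment = "tumor", batch = batch,
                   stringsAsFactors = FALSE)

  structure(list(
    matrix = expression_matrix(counts, md),
    truth = list(
      factors = data.frame(mr_id = mr_id, progression = progression,
                           inflammation = inflammation, arm = arm,
                           stringsAsFactors = FALSE),
      loadings = data.frame(gene_id = colnames(counts), a = a_g, b = b_g,
                            module = module, stringsAsFactors = FALSE),
      modules = module)
  ), class = "expression_sim")
}
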