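small_config <- function(seed, theta = 0.3, ...) {
  defaults <- list(seed = seed, theta = theta, field_width = 700,
                   field_height = 600, nest_count = 2,
                   keratinocyte_density = 1500, stromal_density = 400,
                   immune_cluster_count = 3)
  do.call(tissue_sim_config, utils::modifyList(defaults, list(...)))
}

test_that("tissue simulation is a pure function of the config", {
  a <- simulate_tissue(small_config(11))
  b <- simulate_tissue(small_config(11))
  expect_identical(a$cells, b$cells)
  expect_identical(a$truth, b$truth)
  c <- simulate_tissue(small_config(12))
  expect_false(identical(a$cells, c$cells))
})

test_that("theta = 0 gives single-state nests with zero spatial entropy", {
  sim <- simulate_tissue(small_config(3, theta = 0))
  cells <- sim$cells
  cells$tumor_state <- sim$truth$cells$tumor_state
  per_nest <- split(sim$truth$cells$tumor_state[!is.na(sim$truth$cells$nest_id)],
                    sim$truth$cells$nest_id[!is.na(sim$truth$cells$nest_id)])
  expect_true(all(vapply(per_nest, function(s) length(unique(s)) == 1, logical(1))))
  eb <- entropy_by_region(cells, sim$regions)
  expect_true(all(eb$H[eb$status == "ok"] == 0))
})

test_that("per-nest state frequencies match the theta-mixture expectation", {
  theta <- 0.8
  obs_dom <- 0; n_tot <- 0
  for (seed in 1:20) {
    sim <- simulate_tissue(small_config(seed, theta = theta))
    tc <- sim$truth$cells[!is.na(sim$truth$cells$nest_id), ]
    dom <- sim$truth$nests$dominant_state[tc$nest_id]
    obs_dom <- obs_dom + sum(tc$tumor_state == dom)
    n_tot <- n_tot + nrow(tc)
  }
  p_exp <- (1 - theta) + theta / 4
  se <- sqrt(p_exp * (1 - p_exp) / n_tot)
  expect_lt(abs(obs_dom / n_tot - p_exp), 3 * se)
})

test_that("per-compartment cell counts are Poisson with the configured mean", {
  cfg <- tissue_sim_config(seed = 1, field_width = 400, field_height = 400,
                           nest_count = 1, keratinocyte_density = 2000,
                           stromal_density = 300, immune_cluster_count = 1,
                           vessel_count = 1)
  lambda <- cfg$keratinocyte_density * (cfg$field_width * cfg$epidermis_depth) / 1e6
  counts <- vapply(1:100, function(s) {
    cfg$seed <- s
    sum(simulate_tissue(cfg)$truth$cells$compartment == "epidermis")
  }, numeric(1))
  # chi-square GOF against Poisson(lambda), bins from Poisson quantiles
  qs <- unique(qpois(seq(0, 1, length.out = 7), lambda))
  breaks <- c(-Inf, qs[-c(1, length(qs))], Inf)
  obs <- table(cut(counts, breaks))
  pr <- diff(ppois(c(-Inf, qs[-c(1, length(qs))], Inf), lambda))
  expect_gt(chisq.test(obs, p = pr / sum(pr))$p.value, 0.01)
})

test_that("the fraction of heterotypic within-nest edges is non-decreasing in theta", {
  frac_for_theta <- function(theta) {
    mean(vapply(1:5, function(seed) {
      sim <- simulate_tissue(small_config(100 + seed, theta = theta))
      tc <- sim$cells[sim$truth$cells$phenotype == "tumor", ]
      tc$tumor_state <- sim$truth$cells$tumor_state[sim$truth$cells$phenotype == "tumor"]
      g <- build_delaunay_graph(tc, "tumor_state", max_edge = 30)
      het <- g$nodes$attr[g$edges$i] != g$nodes$attr[g$edges$j]
      mean(het)
    }, numeric(1)))
  }
  fr <- vapply(c(0, 0.5, 1), frac_for_theta, numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("infiltrate placement tracks nest theta only when coupled", {
  corr_for <- function(coupling, seeds) {
    vapply(seeds, function(s) {
      cfg <- small_config(s, nest_count = 5, field_width = 1600,
                          field_height = 900, immune_cluster_count = 8)
      sim <- simulate_coupled_infiltrate(cfg, coupling)
      tc <- sim$truth$cells
      nests <- sim$truth$nests
      tdens <- vapply(seq_len(nrow(nests)), function(j) {
        d <- sqrt((tc$x - nests$x[j])^2 + (tc$y - nests$y[j])^2)
        sum(d < nests$radius[j] + 60 &
              tc$phenotype %in% c("CD8 T cell", "Treg"))
      }, numeric(1))
      suppressWarnings(cor(nests$theta, tdens, method = "spearman"))
    }, numeric(1))
  }
  c0 <- corr_for(0, 1:25)
  c8 <- corr_for(12, 1:25)
  expect_lt(abs(mean(c0, na.rm = TRUE)), 0.2)
  expect_gt(mean(c8, na.rm = TRUE), 0.3)
  expect_gt(mean(c8, na.rm = TRUE), mean(c0, na.rm = TRUE))
  expect_error(simulate_coupled_infiltrate(small_config(1), -1), "coupling")
})

test_that("expression simulation honours planted structure", {
  # duplicated factors + near-zero noise -> profiles correlate to ~1
  cfg <- expression_sim_config(seed = 2, n_microregions = 2, n_genes = 60,
                               module_size = 20, dispersion = 0.001,
                               baseline_log_mean = log(2000),
                               progression = c(0.7, 0.7),
                               inflammation = c(0.2, 0.2))
  es <- simulate_expression(cfg)
  expect_gt(cor(log1p(es$matrix$values[1, ]), log1p(es$matrix$values[2, ])), 0.99)

  # planted 3-module loading structure recovered by correlation clustering
  cfg2 <- expression_sim_config(seed = 3, n_microregions = 80, n_genes = 90,
                                module_size = 30)
  es2 <- simulate_expression(cfg2)
  pre <- preprocess_expression(es2$matrix)
  cl <- cutree(hclust(as.dist(1 - cor(pre$values)), method = "average"), k = 3)
  expect_gte(adjusted_rand(cl, es2$truth$modules), 0.9)

  expect_error(expression_sim_config(n_genes = 5), "n_genes")
})

test_that("zero loadings give exchangeable microregions", {
  cfg <- expression_sim_config(seed = 4, n_microregions = 40, n_genes = 60,
                               loading_scale = 0)
  es <- simulate_expression(cfg)
  pre <- preprocess_expression(es$matrix)
  set.seed(1)
  grp <- sample(rep(c(1, 2), 20))
  m1 <- colMeans(pre$values[grp == 1, ])
  m2 <- colMeans(pre$values[grp == 2, ])
  # difference between random group means stays at the noise floor
  pooled_sd <- apply(pre$values, 2, sd)
  expect_lt(max(abs(m1 - m2) / pooled_sd), 4 / sqrt(20))
})
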