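sim_expr <- function(seed = 1, n_mr = 30, n_genes = 240, ...) {
  simulate_expression(expression_sim_config(seed = seed, n_microregions = n_mr,
                                            n_genes = n_genes, ...))
}

# gene means on the quantile-normalized log scale, recomputed independently
attr_gene_means <- function(v) {
  colMeans(t(limma::normalizeQuantiles(t(log10(v + 1)))))
}

test_that("expression preprocessing has its defining properties", {
  es <- sim_expr(2, n_mr = 12, n_genes = 80)
  v <- es$matrix$values
  # duplicated sample rows stay identical after normalization
  v2 <- rbind(v, v[1, , drop = FALSE])
  rownames(v2)[13] <- "MR013b"
  pre2 <- preprocess_expression(v2)
  expect_equal(unname(pre2$values[1, ]), unname(pre2$values[13, ]),
               tolerance = 1e-12)
  pre <- preprocess_expression(es$matrix)
  # gene-wise centering
  expect_true(all(abs(colMeans(pre$values)) < 1e-12))
  # after normalization all samples share one value distribution (exactly so
  # for tie-free data): undo the centering, compare sorted sample profiles
  set.seed(8)
  cont <- matrix(rlnorm(15 * 60), 15, 60)
  prec <- preprocess_expression(cont)
  qn <- sweep(prec$values, 2, -attr_gene_means(cont))
  srt <- apply(qn, 1, sort)
  expect_lt(max(apply(srt, 1, function(r) diff(range(r)))), 1e-10)
  # zero-variance genes are retained and flagged
  v3 <- cbind(v, flatgene = 7)
  pre3 <- preprocess_expression(v3)
  expect_true(pre3$flat_genes["flatgene"])
  expect_equal(ncol(pre3$values), ncol(v) + 1)
})

test_that("a 30 x 30 SOM yields exactly 900 metagenes and trains deterministically", {
  es <- sim_expr(5, n_mr = 20, n_genes = 300)
  pre <- preprocess_expression(es$matrix)
  expect_warning(som <- train_som(t(pre$values), grid = c(30, 30), epochs = 8),
                 "fewer than 2 genes")
  expect_equal(n_metagenes(som), 900)
  expect_equal(nrow(som$codebook), 30 * 30)
  # quantization error at the end does not exceed the start
  expect_lte(som$qe_trace[length(som$qe_trace)], som$qe_trace[1])
  # deterministic retraining
  som2 <- suppressWarnings(train_som(t(pre$values), grid = c(30, 30), epochs = 8))
  expect_equal(som$codebook, som2$codebook, tolerance = 1e-12)
  expect_identical(som$bmu, som2$bmu)
  # every gene maps to exactly one unit
  expect_length(som$bmu, nrow(t(pre$values)))
  expect_error(train_som(matrix(1:10, ncol = 1)), "2 samples")
})

test_that("planted anti-correlated modules land on disjoint connected patches", {
  # two anti-correlated modules (inflammation silenced) in a mostly-unloaded
  # background, as in whole-transcriptome panels where most genes carry no
  # planted signal
  for (seed in c(7, 3)) {
    es <- sim_expr(seed, n_mr = 40, n_genes = 300, module_size = 30,
                   loading_scale = 3, dispersion = 0.05,
                   inflammation = rep(0, 40))
    pre <- preprocess_expression(es$matrix)
    som <- suppressWarnings(train_som(t(pre$values), grid = c(6, 6), epochs = 12))
    mod <- es$truth$modules
    units_up <- unique(som$bmu[mod == "progression_up"])
    units_dn <- unique(som$bmu[mod == "progression_down"])
    expect_length(intersect(units_up, units_dn), 0)
    # "patch": the one-unit (8-neighbourhood) closure of the BMU set is
    # connected, tolerating single-unit holes inside a module's territory
    dilate <- function(units) {
      rc <- som$unit_coords
      which(apply(rc, 1, function(p)
        any(abs(p[1] - rc[units, 1]) <= 1 & abs(p[2] - rc[units, 2]) <= 1)))
    }
    connected <- function(units) {
      if (length(units) <= 1) return(TRUE)
      rc <- som$unit_coords[units, , drop = FALSE]
      adj <- as.matrix(dist(rc, method = "maximum")) <= 1
      reach <- adj[1, ]
      for (k in seq_along(units)) {
        reach <- reach | colSums(adj[reach, , drop = FALSE]) > 0
      }
      all(reach)
    }
    expect_true(connected(dilate(units_up)))
    expect_true(connected(dilate(units_dn)))
  }
})

test_that("portraits obey the mean/difference identities", {
  es <- sim_expr(9, n_mr = 10, n_genes = 120)
  pre <- preprocess_expression(es$matrix)
  som <- train_som(t(pre$values), grid = c(6, 6), epochs = 8)
  s1 <- som$sample_ids[1]
  expect_equal(group_portrait(som, s1), sample_portrait(som, s1))
  expect_true(all(difference_portrait(sample_portrait(som, s1),
                                      sample_portrait(som, s1)) == 0))
  g1 <- group_portrait(som, som$sample_ids[1:4])
  g2 <- group_portrait(som, som$sample_ids[5:10])
  overall <- group_portrait(som, som$sample_ids)
  expect_equal((4 * g1 + 6 * g2) / 10, overall, tolerance = 1e-12)
  expect_error(group_portrait(som, character(0)), "empty")
  expect_error(sample_portrait(som, "nope"), "unknown")
})

test_that("overexpression flags follow the min-max scaling conventions", {
  som <- structure(list(
    grid = c(2, 2),
    codebook = rbind(c(1, 2, 10), c(3, 3, 3), c(5, 4, 3), c(0, 1, 0)),
    unit_coords = cbind(row = c(1, 1, 2, 2), col = c(1, 2, 1, 2)),
    sample_ids = c("s1", "s2", "s3")), class = "som_model")
  oc <- overexpression_clusters(som, threshold = 0.95, scale = "profile")
  # unit 1 has a unique maximum sample -> flagged only there
  expect_equal(unname(oc$flags[1, ]), c(FALSE, FALSE, TRUE))
  # constant metagene profile never flagged
  expect_false(any(oc$flags[2, ]))
  expect_error(overexpression_clusters(som, threshold = 1.5), "threshold")
})

test_that("planted modules produce distinct portrait cluster areas", {
  es <- sim_expr(15, n_mr = 40, n_genes = 220, module_size = 70)
  pre <- preprocess_expression(es$matrix)
  som <- train_som(t(pre$values), grid = c(10, 10), epochs = 12)
  oc <- overexpression_clusters(som, threshold = 0.95, scale = "portrait")
  expect_gte(oc$n_clusters, 2)
  # clusters are disjoint unit sets covering all flagged units
  all_members <- unlist(oc$members)
  expect_false(any(duplicated(all_members)))
  expect_setequal(all_members, which(!is.na(oc$cluster_id)))
})
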