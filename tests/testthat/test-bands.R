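horizontal_reference <- function(y0 = 100, x1 = 1000) {
  region_annotation("epi", rbind(c(0, y0), c(x1, y0)),
                    role = "epidermis_reference", geom_type = "polyline")
}

test_that("distance to the epidermis reference is point-to-geometry Euclidean", {
  ref <- horizontal_reference(100)
  cells <- make_cells(c(50, 50, 2000), c(100, 350, 100))
  d <- distance_to_epidermis(cells, ref)
  expect_equal(d[1], 0)
  expect_equal(d[2], 250)
  expect_equal(d[3], 1000)   # beyond the segment end: distance to endpoint
  expect_error(distance_to_epidermis(cells), "reference")

  # cells inside a reference polygon get 0
  poly <- region_annotation("epi2", rbind(c(0, 0), c(100, 0), c(100, 50), c(0, 50)),
                            role = "epidermis_reference")
  inside <- make_cells(50, 25)
  expect_equal(distance_to_epidermis(inside, poly), 0)
})

test_that("distances agree with a dense point-sampling oracle on a jagged polyline", {
  set.seed(14)
  vx <- seq(0, 500, by = 50)
  vy <- 100 + runif(length(vx), -40, 40)
  ref <- region_annotation("epi", cbind(vx, vy),
                           role = "epidermis_reference", geom_type = "polyline")
  cells <- make_cells(runif(40, 0, 500), runif(40, 0, 600))
  d <- distance_to_epidermis(cells, ref)
  # sample the polyline at 0.1 um steps
  samp <- do.call(rbind, lapply(seq_len(length(vx) - 1), function(s) {
    len <- sqrt((vx[s + 1] - vx[s])^2 + (vy[s + 1] - vy[s])^2)
    t <- seq(0, 1, length.out = ceiling(len * 10) + 1)
    cbind(vx[s] + t * (vx[s + 1] - vx[s]), vy[s] + t * (vy[s + 1] - vy[s]))
  }))
  d_oracle <- vapply(seq_len(nrow(cells)), function(i)
    sqrt(min((samp[, 1] - cells$x[i])^2 + (samp[, 2] - cells$y[i])^2)),
    numeric(1))
  expect_true(all(abs(d - d_oracle) <= 0.5))
})

test_that("band assignment uses half-open 0.2 mm intervals and conserves cells", {
  b <- assign_bands(c(50, 250, 200, 0, 399, 400), band_width = 200)
  expect_equal(b$band, c(0L, 1L, 1L, 0L, 1L, 2L))
  expect_error(assign_bands(c(-1, 5)), "negative")
  expect_error(assign_bands(c(1, 2), band_width = 0), "band_width")
  set.seed(3)
  d <- runif(500, 0, 2000)
  bands <- assign_bands(d)
  expect_equal(sum(table(bands$band)), 500)
})

test_that("entropy by band on a one-band tissue reproduces entropy by region", {
  set.seed(21)
  cells <- make_cells(runif(80, 0, 150), runif(80, 100, 250),
                      label = sample(c("A", "B"), 80, TRUE))
  cells$tumor_state <- cells$state
  rg <- region_annotation("R1", rbind(c(-10, 90), c(160, 90), c(160, 260), c(-10, 260)),
                          stage = "VGP")
  ref <- horizontal_reference(100, 150)
  d <- distance_to_epidermis(cells, ref)
  bands <- assign_bands(d, band_width = 1000)   # everything in band 0
  eb <- entropy_by_band(cells, bands, list(rg))
  er <- entropy_by_region(cells, list(rg))
  expect_equal(nrow(eb), 1)
  expect_equal(eb$H, er$H, tolerance = 1e-12)
})

test_that("planted depth-increasing intermixing yields a positive band trend", {
  set.seed(31)
  mix <- c(0.04, 0.15, 0.3, 0.5)
  rows <- lapply(seq_along(mix), function(k) {
    n <- 120
    y <- runif(n, (k - 1) * 200, k * 200 - 1e-6)
    states <- ifelse(runif(n) < mix[k], "B", "A")
    data.frame(x = runif(n, 0, 300), y = y, state = states)
  })
  d <- do.call(rbind, rows)
  cells <- make_cells(d$x, d$y, label = d$state)
  cells$tumor_state <- cells$state
  rg <- region_annotation("R1", rbind(c(-5, -5), c(305, -5), c(305, 805), c(-5, 805)),
                          stage = "VGP")
  bands <- assign_bands(cells$y, band_width = 200)
  eb <- entropy_by_band(cells, bands, list(rg))
  eb <- eb[eb$status == "ok", ]
  expect_gte(cor(eb$band, eb$H, method = "spearman"), 0.8)
})

test_that("proximity profiles count radius neighborhoods and compare focal states", {
  # planted: state a cells surrounded by T cells, state b cells by stroma
  set.seed(41)
  mk_block <- function(x0, region, focal_state, companion) {
    n <- 40
    data.frame(x = x0 + runif(n, 0, 60), y = runif(n, 0, 60),
               phenotype = rep(c("tumor", companion), n / 2),
               tumor_state = rep(c(focal_state, NA), n / 2),
               region_id = region, stringsAsFactors = FALSE)
  }
  blocks <- list()
  for (r in 1:4) {
    blocks[[2 * r - 1]] <- mk_block(1000 * r, paste0("R", r, "a"), "melanocytic", "T cell")
    blocks[[2 * r]] <- mk_block(1000 * r + 500, paste0("R", r, "b"), "NC-like", "stromal")
  }
  d <- do.call(rbind, blocks)
  d$cell_id <- seq_len(nrow(d)); d$specimen_id <- "S1"; d$M1 <- 1
  cells <- cell_table(d)
  pp <- proximity_profile(cells, "melanocytic", "NC-like", r = 30)
  expect_equal(pp$status, "ok")
  tcell_row <- pp$comparisons[pp$comparisons$phenotype == "T cell", ]
  expect_lt(tcell_row$p_adjusted, 0.05)
  expect_gt(tcell_row$mean_a, tcell_row$mean_b)

  # focal cell with empty neighborhood contributes a zero count vector
  lone <- cell_table(data.frame(
    cell_id = 1:2, specimen_id = "S1", M1 = 1, x = c(0, 5000), y = c(0, 0),
    phenotype = "tumor", tumor_state = c("melanocytic", "NC-like"),
    region_id = "R1"))
  pp2 <- proximity_profile(lone, "melanocytic", "NC-like", r = 15)
  expect_equal(nrow(pp2$per_cell), 2)
  expect_true(all(rowSums(pp2$per_cell[, -(1:3), drop = FALSE]) == 0))

  # absent focal state -> not-computable
  pp3 <- proximity_profile(lone[1, ], "melanocytic", "NC-like", r = 15)
  expect_equal(pp3$status, "not-computable")
})

test_that("null proximity comparisons stay unflagged at FDR 0.05", {
  set.seed(55)
  n <- 600
  cells <- cell_table(data.frame(
    cell_id = 1:n, specimen_id = "S1", M1 = 1,
    x = runif(n, 0, 800), y = runif(n, 0, 800),
    phenotype = sample(c("tumor", "T cell", "stromal"), n, TRUE),
    region_id = paste0("R", sample(1:8, n, TRUE)),
    stringsAsFactors = FALSE))
  st <- sample(c("melanocytic", "NC-like"), n, TRUE)
  cells$tumor_state <- ifelse(cells$phenotype == "tumor", st, NA)
  pp <- proximity_profile(cells, "melanocytic", "NC-like", r = 25)
  expect_true(all(pp$comparisons$p_adjusted > 0.05, na.rm = TRUE))
})

test_that("nearest-neighbor distances match definitions and a brute-force scan", {
  two <- cell_table(data.frame(cell_id = 1:2, specimen_id = "S1", M1 = 1,
                               x = c(0, 7), y = c(0, 0),
                               phenotype = c("A", "B")))
  nn <- nearest_neighbor_distances(two)
  expect_equal(nn$mean_distance[nn$type_a == "A" & nn$type_b == "B"], 7)
  expect_equal(nn$mean_distance[nn$type_a == "B" & nn$type_b == "A"], 7)
  # A = B with a single cell is not computable
  expect_equal(nn$status[nn$type_a == "A" & nn$type_b == "A"], "not-computable")

  set.seed(61)
  n <- 300
  cells <- cell_table(data.frame(
    cell_id = 1:n, specimen_id = "S1", M1 = 1,
    x = runif(n, 0, 200), y = runif(n, 0, 200),
    phenotype = sample(c("A", "B", "C"), n, TRUE)))
  nn2 <- nearest_neighbor_distances(cells)
  for (a in c("A", "B")) for (b in c("B", "C")) {
    ia <- which(cells$phenotype == a)
    ib <- which(cells$phenotype == b)
    brute <- mean(vapply(ia, function(i) {
      tb <- if (a == b) setdiff(ib, i) else ib
      sqrt(min((cells$x[tb] - cells$x[i])^2 + (cells$y[tb] - cells$y[i])^2))
    }, numeric(1)))
    expect_equal(nn2$mean_distance[nn2$type_a == a & nn2$type_b == b], brute)
  }
})
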