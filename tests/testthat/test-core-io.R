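test_that("cell tables convert pixel coordinates and round-trip through CSV", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(CellID = 1:3, X_centroid = c(10, 20, 30),
                   Y_centroid = c(5, 5, 5), DNA = c(1.5, 2.5, 3.5))
  write.csv(df, tmp, row.names = FALSE)
  ct <- read_cell_table(tmp, pixel_size = 0.325)
  expect_equal(ct$x, c(10, 20, 30) * 0.325)
  expect_equal(ct$y, rep(5 * 0.325, 3))

  # micron inputs are taken as-is
  ct2 <- read_cell_table(tmp, units = "microns")
  expect_equal(ct2$x, c(10, 20, 30))

  # write -> read round-trip is value-identical
  set.seed(42)
  big <- cell_table(data.frame(
    cell_id = 1:100, specimen_id = "S1",
    x = runif(100, 0, 1000), y = runif(100, 0, 1000),
    SOX10 = rlnorm(100), MART1 = rlnorm(100), stringsAsFactors = FALSE))
  out <- withr::local_tempfile(fileext = ".csv")
  write_cell_table(big, out)
  back <- read_cell_table(out, units = "microns")
  expect_equal(back$x, big$x)
  expect_equal(back$y, big$y)
  expect_equal(back$SOX10, big$SOX10)
  expect_equal(back$cell_id, big$cell_id)
})

test_that("cell table reading rejects malformed inputs with informative errors", {
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("", empty)
  expect_error(read_cell_table(empty, pixel_size = 1), "empty|mandatory")

  nocol <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(CellID = 1, X_centroid = 1, DNA = 1), nocol,
            row.names = FALSE)
  expect_error(read_cell_table(nocol, pixel_size = 1), "Y_centroid")

  badnum <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("CellID,X_centroid,Y_centroid,DNA", "1,0,0,ok"), badnum)
  expect_error(read_cell_table(badnum, pixel_size = 1), "non-numeric.*DNA")

  expect_error(read_cell_table(withr::local_tempfile(), pixel_size = 1),
               "not found")
})

test_that("region annotations validate geometry and stage vocabulary", {
  square <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))
  r <- region_annotation("R1", square, stage = "MIS")
  expect_s3_class(r, "region_annotation")
  expect_equal(r$stage, "MIS")

  # epidermis reference needs no stage; polyline allowed only there
  expect_silent(region_annotation("epi", rbind(c(0, 0), c(100, 0)),
                                  role = "epidermis_reference",
                                  geom_type = "polyline"))
  expect_error(region_annotation("R2", rbind(c(0, 0), c(100, 0)),
                                 stage = "MIS", geom_type = "polyline"),
               "polyline")

  expect_error(region_annotation("R3", square, stage = "XYZ"), "stage")

  bowtie <- rbind(c(0, 0), c(100, 100), c(100, 0), c(0, 100))
  expect_error(region_annotation("R4", bowtie, stage = "MIS"),
               "self-intersecting")
})

test_that("region annotations round-trip through GeoJSON", {
  square <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))
  regions <- list(
    region_annotation("R1", square, stage = "MIS", til_status = "brisk"),
    region_annotation("epi", rbind(c(0, 50), c(200, 50)),
                      role = "epidermis_reference", geom_type = "polyline"))
  tmp <- withr::local_tempfile(fileext = ".geojson")
  write_region_annotations(regions, tmp)
  back <- read_region_annotations(tmp)
  expect_length(back, 2)
  expect_equal(back[[1]]$stage, "MIS")
  expect_equal(back[[1]]$geometry, unname(square))
  expect_true(is.na(back[[2]]$stage))
  expect_equal(back[[2]]$geom_type, "polyline")
})

test_that("point-in-region is boundary inclusive", {
  square <- region_annotation("R", rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)),
                              stage = "MIS")
  cells <- make_cells(x = c(5, 0, 10, 11, 0), y = c(5, 5, 10, 5, 0))
  expect_equal(points_in_region(cells, square), c(TRUE, TRUE, TRUE, FALSE, TRUE))
})

test_that("expression matrices load identically from CSV and MTX and reject id mismatches", {
  set.seed(1)
  counts <- matrix(rpois(10 * 50, 20), 10, 50,
                   dimnames = list(sprintf("MR%02d", 1:10),
                                   sprintf("g%03d", 1:50)))
  md <- data.frame(mr_id = rownames(counts), specimen_id = "S1",
                   stage = "RGP", segment = "tumor")
  dir <- withr::local_tempdir()
  mdp <- file.path(dir, "md.tsv")
  write.table(md, mdp, sep = "\t", row.names = FALSE, quote = FALSE)
  em <- expression_matrix(counts, md)
  write_expression_matrix(em, file.path(dir, "c.csv"), mdp)
  write_expression_matrix(em, file.path(dir, "c.mtx"), mdp)
  from_csv <- read_expression_matrix(file.path(dir, "c.csv"), mdp)
  from_mtx <- read_expression_matrix(file.path(dir, "c.mtx"), mdp)
  expect_equal(from_csv$values, from_mtx$values)
  expect_equal(from_csv$values, counts, ignore_attr = FALSE)
  expect_equal(from_csv$metadata$stage, md$stage)

  md_short <- md[-3, ]
  mdp2 <- file.path(dir, "md2.tsv")
  write.table(md_short, mdp2, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_expression_matrix(file.path(dir, "c.csv"), mdp2), "MR03")
})

test_that("shuffling cell rows leaves region-level entropy unchanged", {
  sim <- simulate_tissue(tissue_sim_config(seed = 5, field_width = 700,
                                           field_height = 600, nest_count = 2,
                                           keratinocyte_density = 1500,
                                           stromal_density = 400, theta = 0.6))
  cells <- sim$cells
  cells$tumor_state <- sim$truth$cells$tumor_state
  e1 <- entropy_by_region(cells, sim$regions)
  set.seed(9)
  perm <- sample(nrow(cells))
  e2 <- entropy_by_region(cells[perm, ], sim$regions)
  expect_equal(e1$H, e2$H, tolerance = 1e-12)
})
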