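make_disk_image <- function(h, w, centers, radii, level = 10000) {
  ch <- disk_raster(h, w, centers, radii, inside = level, outside = 100)
  labeled_image(list(tf = ch), roles = list(tf = "nuclear_tf"))
}

test_that("flat channels yield zero nuclei with a warning", {
  img <- labeled_image(list(tf = matrix(500, 64, 64)),
                       roles = list(tf = "nuclear_tf"))
  expect_warning(lab <- detect_nuclei(img), "zero variance")
  expect_equal(sum(lab), 0)
  expect_false(is.null(attr(lab, "params_used")))
})

test_that("well-separated synthetic nuclei are detected perfectly", {
  sim <- generate_tumor_image(image_sim_config(n_cells = 50, rng_seed = 7))
  lab <- detect_nuclei(sim$image)
  m <- match_centroids(lab, cbind(sim$truth$cells$row, sim$truth$cells$col))
  expect_gte(m$f1, 0.95)
  expect_equal(sort(unique(lab[lab > 0])), seq_len(max(lab)))
})

test_that("distance-transform watershed splits touching disks", {
  centers <- rbind(c(32, 24), c(32, 41))  # overlap ~30% of radius
  img <- make_disk_image(64, 64, centers, c(10, 10))
  merged <- detect_nuclei(img, declump = FALSE, smoothing_sigma = 0.5)
  expect_equal(max(merged), 1)
  split <- detect_nuclei(img, declump = TRUE, smoothing_sigma = 0.5)
  expect_equal(max(split), 2)
})

test_that("ring mode reproduces brute-force dilation geometry", {
  nuc <- matrix(0L, 48, 48)
  for (r in 1:48) for (cc in 1:48)
    if ((r - 24)^2 + (cc - 24)^2 <= 25) nuc[r, cc] <- 1L
  ring <- propagate_cells(nuc, mode = "ring", ring_width_px = 3)
  expect_identical(ring, nearest_seed_oracle(nuc, 3))
  # cell area = nucleus area + area of the 3-px dilation ring
  expect_equal(sum(ring > 0), sum(nuc > 0) + sum(ring > 0 & nuc == 0))
  expect_gt(sum(ring > 0 & nuc == 0), 0)
})

test_that("contested pixels split along the equidistant line", {
  nuc <- matrix(0L, 32, 32)
  nuc[16, 12] <- 1L
  nuc[16, 16] <- 2L  # 4 px apart
  cells <- propagate_cells(nuc, mode = "ring", ring_width_px = 3)
  expect_identical(cells, nearest_seed_oracle(nuc, 3))
  expect_equal(sum(cells == 1 & cells == 2), 0)
  expect_equal(cells[16, 13], 1L)  # nearer seed 1
  expect_equal(cells[16, 14], 1L)  # equidistant: lower label wins
  expect_equal(cells[16, 15], 2L)
})

test_that("propagation with zero cap returns the nuclei unchanged", {
  sim <- generate_tumor_image(image_sim_config(n_cells = 20, rng_seed = 2,
                                               image_height_px = 256,
                                               image_width_px = 256))
  nuc <- detect_nuclei(sim$image)
  cells <- propagate_cells(nuc, mode = "propagation", max_distance_px = 0)
  expect_equal(cells, unname(nuc), ignore_attr = TRUE)
  cyto <- derive_cytoplasm(cells, nuc)
  expect_equal(sum(cyto), 0)
  expect_setequal(attr(cyto, "empty_cytoplasm_labels"),
                  unique(nuc[nuc > 0]))
})

test_that("cytoplasm is exactly cell minus nucleus and labels must match", {
  sim <- generate_tumor_image(image_sim_config(n_cells = 40, rng_seed = 4))
  seg <- segment_image(sim$image, max_distance_px = 5)
  for (l in unique(seg$cell_labels[seg$cell_labels > 0])) {
    expect_equal(sum(seg$cell_labels == l),
                 sum(seg$nuclei_labels == l) +
                 sum(seg$cytoplasm_labels == l))
  }
  expect_true(all(seg$cytoplasm_labels[seg$nuclei_labels > 0] == 0))
  bad <- seg$cell_labels
  bad[bad == 1] <- max(bad) + 5L
  expect_error(derive_cytoplasm(bad, seg$nuclei_labels), "orphan")
})

test_that("medians are lower medians of compartment pixels", {
  ch <- matrix(0, 8, 8)
  nuc <- matrix(0L, 8, 8)
  nuc[2:4, 2:4] <- 1L          # 9 pixels
  ch[2:4, 2:4] <- 1:9          # odd count: median 5
  nuc[6:7, 6:7] <- 2L          # 4 pixels
  ch[6:7, 6:7] <- c(1, 2, 3, 4)  # even count: lower median 2
  img <- labeled_image(list(m = ch), roles = list(m = "marker"))
  seg <- list(nuclei_labels = nuc, cell_labels = nuc,
              cytoplasm_labels = matrix(0L, 8, 8))
  rec <- measure_cells(img, seg)
  expect_equal(rec$m_nucleus_median, c(5, 2))
  expect_true(all(is.na(rec$m_cytoplasm_median)))
  expect_equal(rec$m_cell_median, c(5, 2))
  # constant compartment
  ch2 <- matrix(7, 8, 8)
  img2 <- labeled_image(list(m = ch2), roles = list(m = "marker"))
  expect_equal(measure_cells(img2, seg)$m_nucleus_median, c(7, 7))
})

test_that("measurement is idempotent and shifts with added constants", {
  sim <- generate_tumor_image(image_sim_config(n_cells = 30, rng_seed = 6,
                                               image_height_px = 256,
                                               image_width_px = 256))
  seg <- segment_image(sim$image, max_distance_px = 5)
  r1 <- measure_cells(sim$image, seg)
  r2 <- measure_cells(sim$image, seg)
  expect_identical(r1, r2)
  img_shift <- sim$image
  img_shift$channels$marker <- img_shift$channels$marker + 123
  r3 <- measure_cells(img_shift, seg)
  for (comp in c("nucleus", "cytoplasm", "cell")) {
    col <- paste0("marker_", comp, "_median")
    expect_equal(r3[[col]], r1[[col]] + 123)
    other <- paste0("tf_", comp, "_median")
    expect_equal(r3[[other]], r1[[other]])
  }
})

test_that("measured marker medians track the generator's true levels", {
  sim <- generate_tumor_image(image_sim_config(n_cells = 100, rng_seed = 13,
                                               marker_loss_fraction = 0.4))
  seg <- segment_image(sim$image, max_distance_px = 5)
  tr <- sim$truth$cells
  m <- match_centroids(seg$nuclei_labels, cbind(tr$row, tr$col))
  rec <- measure_cells(sim$image, seg)
  matched <- match(m$matches, rec$cell_id)
  # recover which truth cell each matched label corresponds to
  h <- nrow(seg$nuclei_labels)
  cent <- t(vapply(m$matches, function(l) {
    idx <- which(seg$nuclei_labels == l)
    c(mean((idx - 1L) %% h + 1L), mean((idx - 1L) %/% h + 1L))
  }, numeric(2)))
  truth_idx <- apply(sqrt(outer(cent[, 1], tr$row, "-")^2 +
                          outer(cent[, 2], tr$col, "-")^2), 1, which.min)
  rho <- cor(rec$marker_cytoplasm_median[matched],
             tr$true_marker[truth_idx], method = "spearman")
  expect_gt(rho, 0.9)
})
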