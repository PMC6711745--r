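# Synthetic multi-channel fluorescence images of tumors with variegated,
# cell-autonomous marker loss, plus the matching per-cell ground truth.

#' Default per-channel intensity models
#'
#' Each channel carries a role and two log-normal intensity states. Nuclear
#' channels use identical "retained" and "lost" parameters (the nuclear
#' transcription factor is unaffected by de-differentiation); the marker
#' channel has a lower "lost" mode emulating variegated loss of a cytoplasmic
#' differentiation marker.
#'
#' @return Named list of channel models. Each model is a list with elements
#'   `role` (one of `"nuclear_stain"`, `"nuclear_tf"`, `"marker"`),
#'   `retained` and `lost` (numeric `c(meanlog, sdlog)`).
#' @export
default_channel_models <- function() {
  list(
    dapi = list(role = "nuclear_stain",
                retained = c(meanlog = log(8000), sdlog = 0.2),
                lost     = c(meanlog = log(8000), sdlog = 0.2)),
    tf = list(role = "nuclear_tf",
              retained = c(meanlog = log(3000), sdlog = 0.3),
              lost     = c(meanlog = log(3000), sdlog = 0.3)),
    marker = list(role = "marker",
                  retained = c(meanlog = log(3000), sdlog = 0.3),
                  lost     = c(meanlog = log(600),  sdlog = 0.4))
  )
}

#' Configuration for the tumor image simulator
#'
#' Defaults describe one field of view of a mouse lung tumor at roughly
#' 0.5 um/px: disk-shaped nuclei (radius ~ Normal(6, 1) px, truncated at
#' 2 px) surrounded by a 5 px cytoplasm, rendered into a 16-bit range with a
#' linear background gradient and Gaussian read noise, acquisition below
#' saturation. A `marker_loss_fraction` of the cells is drawn from each
#' marker channel's "lost" intensity state, independently per cell, so loss
#' is variegated (spatially interspersed) rather than regional.
#'
#' @param image_height_px,image_width_px Image dimensions in pixels.
#' @param n_cells Number of cells to place (non-negative).
#' @param nucleus_radius_mean_px,nucleus_radius_sd_px Nucleus radius
#'   distribution, pixels; radii are truncated below at 2 px.
#' @param cytoplasm_width_px Width of the cytoplasmic rim around each
#'   nucleus, pixels; cells are clipped against neighbours by nearest-seed
#'   assignment.
#' @param genotype_label Genotype tag carried into metadata and records.
#' @param tumor_id Tumor identifier carried into metadata and records.
#' @param marker_loss_fraction Probability in `[0, 1]` that a cell is in the
#'   "lost" state for marker channels.
#' @param channel_models Per-channel intensity models, see
#'   [default_channel_models()].
#' @param inter_channel_rank_correlation Rank correlation of per-cell levels
#'   across channels, induced by a Gaussian copula. Must keep the implied
#'   equicorrelation matrix positive definite.
#' @param background_level Constant background intensity.
#' @param gradient_amplitude Amplitude of a left-to-right linear background
#'   ramp, intensity units.
#' @param read_noise_sd Gaussian read noise standard deviation.
#' @param rng_seed Integer seed; identical seeds give bit-identical output.
#' @return Validated configuration object of class `image_sim_config`.
#' @export
image_sim_config <- function(image_height_px = 512, image_width_px = 512,
                             n_cells = 200,
                             nucleus_radius_mean_px = 6,
                             nucleus_radius_sd_px = 1,
                             cytoplasm_width_px = 5,
                             genotype_label = "BRAF",
                             tumor_id = "tumor_1",
                             marker_loss_fraction = 0,
                             channel_models = default_channel_models(),
                             inter_channel_rank_correlation = 0.25,
                             background_level = 100,
                             gradient_amplitude = 50,
                             read_noise_sd = 30,
                             rng_seed = 1L) {
  cfg <- list(image_height_px = as.integer(image_height_px),
              image_width_px = as.integer(image_width_px),
              n_cells = as.integer(n_cells),
              nucleus_radius_mean_px = nucleus_radius_mean_px,
              nucleus_radius_sd_px = nucleus_radius_sd_px,
              cytoplasm_width_px = cytoplasm_width_px,
              genotype_label = genotype_label,
              tumor_id = tumor_id,
              marker_loss_fraction = marker_loss_fraction,
              channel_models = channel_models,
              inter_channel_rank_correlation = inter_channel_rank_correlation,
              background_level = background_level,
              gradient_amplitude = gradient_amplitude,
              read_noise_sd = read_noise_sd,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "image_sim_config"
  validate_image_sim_config(cfg)
  cfg
}

validate_image_sim_config <- function(cfg) {
  stopifnot(cfg$image_height_px >= 1, cfg$image_width_px >= 1,
            cfg$n_cells >= 0,
            cfg$nucleus_radius_mean_px > 0, cfg$nucleus_radius_sd_px >= 0,
            cfg$cytoplasm_width_px >= 0,
            cfg$background_level >= 0, cfg$gradient_amplitude >= 0,
            cfg$read_noise_sd >= 0)
  if (cfg$marker_loss_fraction < 0 || cfg$marker_loss_fraction > 1)
    stop("marker_loss_fraction must lie in [0, 1]")
  if (abs(cfg$inter_channel_rank_correlation) > 1)
    stop("inter_channel_rank_correlation must lie in [-1, 1]")
  roles <- vapply(cfg$channel_models, `[[`, character(1), "role")
  if (!all(roles %in% c("nuclear_stain", "nuclear_tf", "marker")))
    stop("channel roles must be nuclear_stain, nuclear_tf or marker")
  invisible(cfg)
}

#' Construct a labeled multi-channel image
#'
#' @param channels Named list of numeric matrices sharing one shape.
#' @param roles Character vector of channel roles, same names as `channels`.
#' @param tumor_id,genotype Metadata strings.
#' @return Object of class `labeled_image`.
#' @export
labeled_image <- function(channels, roles, tumor_id = "tumor_1",
                          genotype = "unknown") {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)),
            identical(sort(names(channels)), sort(names(roles))))
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all channels must share the same shape")
  if (any(vapply(channels, function(ch) any(ch < 0), logical(1))))
    stop("channel intensities must be non-negative")
  structure(list(channels = channels,
                 roles = as.list(roles)[names(channels)],
                 metadata = list(tumor_id = tumor_id, genotype = genotype)),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("labeled_image: %d x %d px, %d channel(s)\n", d[1], d[2],
              length(x$channels)))
  for (nm in names(x$channels))
    cat(sprintf("  %-12s role=%s\n", nm, x$roles[[nm]]))
  cat(sprintf("  tumor_id=%s genotype=%s\n", x$metadata$tumor_id,
              x$metadata$genotype))
  invisible(x)
}

# Find the channel name with a given role (first match).
channel_by_role <- function(image, role) {
  hit <- names(image$roles)[vapply(image$roles, identical, logical(1), role)]
  if (length(hit) == 0)
    stop(sprintf("no channel with role '%s'", role))
  hit[1]
}

# Draw per-cell, per-channel intensity levels through a Gaussian copula
# with equicorrelated latents, conditional on the per-cell retained/lost
# state. rho_spearman is the target rank correlation; the latent Pearson
# correlation is 2 sin(pi rho / 6), the exact inversion for a Gaussian
# copula, so tests can dial Spearman targets directly.
draw_cell_levels <- function(n, channel_models, rho_spearman, lost) {
  k <- length(channel_models)
  rho <- 2 * sin(pi * rho_spearman / 6)
  if (k > 1 && rho < 0 && rho < -1 / (k - 1) + 1e-12)
    stop("inter_channel_rank_correlation makes the copula degenerate")
  sigma <- matrix(rho, k, k); diag(sigma) <- 1
  ch <- chol(sigma)
  z <- matrix(stats::rnorm(n * k), n, k) %*% ch
  u <- stats::pnorm(z)
  levels <- matrix(0, n, k, dimnames = list(NULL, names(channel_models)))
  for (j in seq_len(k)) {
    m <- channel_models[[j]]
    p_ret <- m$retained
    p_lost <- m$lost
    ml <- ifelse(lost, p_lost[["meanlog"]], p_ret[["meanlog"]])
    sl <- ifelse(lost, p_lost[["sdlog"]], p_ret[["sdlog"]])
    levels[, j] <- stats::qlnorm(u[, j], meanlog = ml, sdlog = sl)
  }
  levels
}

# Place n non-overlapping disks (center distance > r_i + r_j + gap) by
# rejection sampling; error out after a bounded number of attempts.
place_nuclei <- function(n, h, w, r_mean, r_sd, margin, gap = 2,
                         max_attempts = 500L * max(n, 1L)) {
  radii <- pmax(2, stats::rnorm(n, r_mean, r_sd))
  rows <- numeric(n); cols <- numeric(n)
  placed <- 0L; attempts <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf(
        "nucleus placement failed: could not place %d cells in a %dx%d image",
        n, h, w))
    r <- radii[placed + 1L]
    lo <- 1 + margin + r
    if (lo > h - margin - r || lo > w - margin - r)
      stop("nucleus placement failed: image too small for nucleus + margin")
    cr <- stats::runif(1, lo, h - margin - r)
    cc <- stats::runif(1, lo, w - margin - r)
    if (placed > 0L) {
      d <- sqrt((rows[seq_len(placed)] - cr)^2 +
                (cols[seq_len(placed)] - cc)^2)
      if (any(d <= radii[seq_len(placed)] + r + gap)) next
    }
    placed <- placed + 1L
    rows[placed] <- cr; cols[placed] <- cc
  }
  data.frame(cell_id = seq_len(n), row = rows, col = cols, radius = radii)
}

# Rasterize nuclei and nearest-seed-clipped cells. Returns integer label
# matrices. A pixel belongs to cell i when dist(center_i) - r_i is minimal
# and <= width; nuclei are dist(center_i) <= r_i (non-overlapping by
# construction).
rasterize_cells <- function(centers, width, h, w) {
  nuc <- matrix(0L, h, w)
  cell <- matrix(0L, h, w)
  best <- matrix(Inf, h, w)
  for (i in seq_len(nrow(centers))) {
    cr <- centers$row[i]; cc <- centers$col[i]; r <- centers$radius[i]
    reach <- ceiling(r + width)
    rr <- max(1, floor(cr - reach)):min(h, ceiling(cr + reach))
    cols <- max(1, floor(cc - reach)):min(w, ceiling(cc + reach))
    d <- sqrt(outer((rr - cr)^2, (cols - cc)^2, "+"))
    score <- d - r
    sel <- score <= width & score < best[rr, cols]
    if (any(sel)) {
      idx <- which(sel)
      sub_cell <- cell[rr, cols]; sub_best <- best[rr, cols]
      sub_cell[idx] <- i
      sub_best[idx] <- score[idx]
      cell[rr, cols] <- sub_cell
      best[rr, cols] <- sub_best
    }
    nsel <- d <= r
    if (any(nsel)) {
      sub <- nuc[rr, cols]
      sub[which(nsel)] <- i
      nuc[rr, cols] <- sub
    }
  }
  # nucleus pixels always belong to their own cell
  cell[nuc > 0] <- nuc[nuc > 0]
  list(nuclei = nuc, cells = cell)
}

#' Simulate a tumor image with ground truth
#'
#' Renders disk nuclei with a cytoplasmic rim into one raster per configured
#' channel. Nuclear channels carry signal only on nucleus pixels; marker
#' channels carry signal on all cell pixels. Per-cell levels come from the
#' state-conditional log-normal models coupled across channels by a Gaussian
#' copula; a background ramp and Gaussian read noise are added and
#' intensities are quantized to the 16-bit range.
#'
#' @param config An [image_sim_config()].
#' @return List with elements `image` (a [labeled_image()]) and `truth`, a
#'   list of class `ground_truth` with `cells` (data frame: cell_id, row,
#'   col, radius, state, plus `true_<channel>` mean levels),
#'   `nucleus_pixels` and `cell_pixels` (lists of pixel linear indices).
#' @export
generate_tumor_image <- function(config) {
  validate_image_sim_config(config)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$rng_seed)

  h <- config$image_height_px; w <- config$image_width_px
  n <- config$n_cells
  roles <- vapply(config$channel_models, `[[`, character(1), "role")

  if (n > 0) {
    centers <- place_nuclei(n, h, w,
                            config$nucleus_radius_mean_px,
                            config$nucleus_radius_sd_px,
                            margin = config$cytoplasm_width_px)
    lost <- stats::rbinom(n, 1, config$marker_loss_fraction) == 1
    levels <- draw_cell_levels(n, config$channel_models,
                               config$inter_channel_rank_correlation, lost)
    ras <- rasterize_cells(centers, config$cytoplasm_width_px, h, w)
  } else {
    centers <- data.frame(cell_id = integer(0), row = numeric(0),
                          col = numeric(0), radius = numeric(0))
    lost <- logical(0)
    levels <- matrix(0, 0, length(config$channel_models),
                     dimnames = list(NULL, names(config$channel_models)))
    ras <- list(nuclei = matrix(0L, h, w), cells = matrix(0L, h, w))
  }

  ramp <- matrix(rep(seq(0, 1, length.out = w), each = h), h, w)
  channels <- list()
  for (nm in names(config$channel_models)) {
    role <- roles[[nm]]
    base <- config$background_level + config$gradient_amplitude * ramp
    if (n > 0) {
      lab <- if (role == "marker") ras$cells else ras$nuclei
      sel <- lab > 0
      base[sel] <- base[sel] + levels[lab[sel], nm]
    }
    noisy <- base + stats::rnorm(h * w, sd = config$read_noise_sd)
    channels[[nm]] <- matrix(pmin(65535, pmax(0, round(noisy))), h, w)
  }

  img <- labeled_image(channels, roles, tumor_id = config$tumor_id,
                       genotype = config$genotype_label)
  cells <- centers
  cells$state <- ifelse(lost, "lost", "retained")
  for (nm in colnames(levels)) cells[[paste0("true_", nm)]] <- levels[, nm]
  truth <- structure(
    list(cells = cells,
         nucleus_pixels = split(which(ras$nuclei > 0),
                                ras$nuclei[ras$nuclei > 0]),
         cell_pixels = split(which(ras$cells > 0),
                             ras$cells[ras$cells > 0]),
         nuclei_labels = ras$nuclei,
         cell_labels = ras$cells),
    class = "ground_truth")
  list(image = img, truth = truth)
}

#' Simulate per-cell intensity records without rendering an image
#'
#' Draws per-cell compartment medians straight from the generative model used
#' by [generate_tumor_image()] (state-conditional log-normal levels, Gaussian
#' copula across channels, plus background offset). This is the fast path for
#' calibration studies that only need the statistical layer: the distribution
#' of the returned "medians" matches what the image pipeline measures up to
#' the small median-of-noisy-pixels error.
#'
#' @param n_tumors Number of tumors for this genotype.
#' @param cells_per_tumor Cells per tumor (recycled).
#' @param genotype Genotype label.
#' @param marker_loss_fraction Fraction of cells in the "lost" state.
#' @param channel_models See [default_channel_models()].
#' @param inter_channel_rank_correlation Copula equicorrelation.
#' @param background_level Constant added to every level.
#' @return Data frame shaped like the output of [measure_cells()]: one row
#'   per cell with `<channel>_nucleus_median`, `<channel>_cytoplasm_median`
#'   and `<channel>_cell_median` columns, plus `true_state`.
#' @export
simulate_cell_records <- function(n_tumors = 8, cells_per_tumor = 60,
                                  genotype = "BRAF",
                                  marker_loss_fraction = 0,
                                  channel_models = default_channel_models(),
                                  inter_channel_rank_correlation = 0.25,
                                  background_level = 100) {
  cells_per_tumor <- rep_len(cells_per_tumor, n_tumors)
  out <- vector("list", n_tumors)
  for (t in seq_len(n_tumors)) {
    n <- cells_per_tumor[t]
    lost <- stats::rbinom(n, 1, marker_loss_fraction) == 1
    levels <- draw_cell_levels(n, channel_models,
                               inter_channel_rank_correlation, lost) +
      background_level
    df <- data.frame(cell_id = seq_len(n),
                     tumor_id = sprintf("%s_t%02d", genotype, t),
                     genotype = genotype,
                     true_state = ifelse(lost, "lost", "retained"))
    for (nm in colnames(levels)) {
      df[[paste0(nm, "_nucleus_median")]] <- levels[, nm]
      df[[paste0(nm, "_cytoplasm_median")]] <- levels[, nm]
      df[[paste0(nm, "_cell_median")]] <- levels[, nm]
    }
    out[[t]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
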