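# Nucleus detection, cell construction and compartment measurement: the
# reimplementation of a CellProfiler-style identify/propagate/measure
# pipeline for tumor immunofluorescence.

#' Detect nuclei in a seed channel
#'
#' Concretization of primary-object identification: Gaussian smoothing,
#' global Otsu threshold, hole filling, optional distance-transform
#' watershed declumping, size filtering, and removal of border-touching
#' objects. Nuclei are seeded from the nuclear transcription-factor channel
#' when present, otherwise from the nuclear stain.
#'
#' @param image A [labeled_image()].
#' @param seed_channel_role Channel role used for seeding, or `NULL` to
#'   prefer `"nuclear_tf"` and fall back to `"nuclear_stain"`.
#' @param smoothing_sigma Gaussian smoothing sigma, pixels.
#' @param threshold Either `"otsu"` or a numeric global threshold on the
#'   original intensity scale.
#' @param size_range Two-element numeric, minimum and maximum object area in
#'   pixels (inclusive).
#' @param declump Split touching nuclei by watershed on the distance
#'   transform.
#' @param declump_tolerance Watershed tolerance (object height in the
#'   distance transform below which adjacent maxima merge).
#' @param exclude_border Remove objects touching the image border.
#' @return Integer label matrix (0 = background, labels consecutive from 1)
#'   with attribute `params_used` recording every parameter.
#' @export
detect_nuclei <- function(image, seed_channel_role = NULL,
                          smoothing_sigma = 1,
                          threshold = "otsu",
                          size_range = c(20, 5000),
                          declump = TRUE, declump_tolerance = 1,
                          exclude_border = TRUE) {
  stopifnot(inherits(image, "labeled_image"),
            length(size_range) == 2, size_range[1] < size_range[2])
  role <- seed_channel_role
  if (is.null(role)) {
    role <- if (any(unlist(image$roles) == "nuclear_tf")) "nuclear_tf"
            else "nuclear_stain"
  }
  ch_name <- channel_by_role(image, role)
  x <- image$channels[[ch_name]]
  params <- list(seed_channel = ch_name, seed_channel_role = role,
                 smoothing_sigma = smoothing_sigma, threshold = threshold,
                 size_range = size_range, declump = declump,
                 declump_tolerance = declump_tolerance,
                 exclude_border = exclude_border)

  empty <- matrix(0L, nrow(x), ncol(x))
  attr(empty, "params_used") <- params
  if (stats::var(as.vector(x)) == 0) {
    warning("seed channel has zero variance; no nuclei detected")
    return(empty)
  }

  xn <- x / 65535
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(xn),
                                          sigma = smoothing_sigma))
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  } else threshold / 65535
  mask <- sm > thr
  if (!any(mask)) {
    warning("threshold leaves no foreground; no nuclei detected")
    return(empty)
  }
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask))) > 0

  lab <- if (declump) {
    dm <- EBImage::distmap(EBImage::Image(mask))
    EBImage::imageData(EBImage::watershed(dm, tolerance = declump_tolerance,
                                          ext = 1))
  } else {
    EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  }
  lab <- matrix(as.integer(lab), nrow(x), ncol(x))

  sizes <- tabulate(lab, nbins = max(lab, 0L))
  drop <- which(sizes < size_range[1] | sizes > size_range[2])
  if (exclude_border) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    drop <- union(drop, border[border > 0])
  }
  if (length(drop)) lab[lab %in% drop] <- 0L
  lab <- relabel_consecutive(lab)
  attr(lab, "params_used") <- params
  lab
}

# Relabel positive labels to consecutive 1..k preserving order.
relabel_consecutive <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  if (length(u) == 0) return(lab)
  map <- integer(max(u))
  map[u] <- seq_along(u)
  lab[lab > 0] <- map[lab[lab > 0]]
  lab
}

# Per-label pixel coordinate list from a label matrix.
label_coords <- function(lab) {
  idx <- which(lab > 0)
  if (length(idx) == 0) return(list())
  split(idx, lab[idx])
}

#' Grow cell bodies from nuclei
#'
#' `propagation` mode grows each nucleus outward by nearest-seed assignment
#' (Euclidean distance to the nucleus pixel set) up to `max_distance_px`;
#' `ring` mode dilates each nucleus by `ring_width_px` (a three-pixel ring
#' by default, for diffuse tumors where propagation performs poorly). In
#' both modes contested pixels go to the nearest nucleus with ties broken
#' toward the lower label id, and nucleus pixels keep their own label.
#'
#' @param nuclei Integer label matrix from [detect_nuclei()].
#' @param mode `"propagation"` or `"ring"`.
#' @param max_distance_px Growth cap for propagation mode, pixels.
#' @param ring_width_px Ring width for ring mode, pixels.
#' @return Integer cell label matrix, same shape and label ids as `nuclei`.
#' @export
propagate_cells <- function(nuclei, mode = c("propagation", "ring"),
                            max_distance_px = 10, ring_width_px = 3) {
  mode <- match.arg(mode)
  cap <- if (mode == "propagation") max_distance_px else ring_width_px
  stopifnot(cap >= 0)
  h <- nrow(nuclei); w <- ncol(nuclei)
  cells <- matrix(0L, h, w)
  best <- matrix(Inf, h, w)
  coords <- label_coords(nuclei)
  for (lab_chr in names(coords)) {
    lab <- as.integer(lab_chr)
    idx <- coords[[lab_chr]]
    pr <- (idx - 1L) %% h + 1L
    pc <- (idx - 1L) %/% h + 1L
    rr <- max(1, min(pr) - ceiling(cap)):min(h, max(pr) + ceiling(cap))
    cc <- max(1, min(pc) - ceiling(cap)):min(w, max(pc) + ceiling(cap))
    # min distance from each candidate pixel to the nucleus pixel set
    d2 <- matrix(Inf, length(rr), length(cc))
    for (k in seq_along(idx)) {
      d2 <- pmin(d2, outer((rr - pr[k])^2, (cc - pc[k])^2, "+"))
    }
    d <- sqrt(d2)
    sel <- d <= cap & d < best[rr, cc]
    if (any(sel)) {
      which_sel <- which(sel)
      sub_cells <- cells[rr, cc]; sub_best <- best[rr, cc]
      sub_cells[which_sel] <- lab
      sub_best[which_sel] <- d[which_sel]
      cells[rr, cc] <- sub_cells
      best[rr, cc] <- sub_best
    }
  }
  # nuclei always keep their own label (distance 0, set explicitly so
  # overlapping caps can never steal a nucleus pixel)
  cells[nuclei > 0] <- nuclei[nuclei > 0]
  cells
}

#' Derive cytoplasm compartments
#'
#' Cytoplasm is the cell pixel set minus the nucleus pixel set, per label.
#' Labels with empty cytoplasm are allowed and flagged.
#'
#' @param cells,nuclei Integer label matrices with matching label sets.
#' @return Integer cytoplasm label matrix with attribute
#'   `empty_cytoplasm_labels`.
#' @export
derive_cytoplasm <- function(cells, nuclei) {
  stopifnot(identical(dim(cells), dim(nuclei)))
  lab_c <- sort(unique(cells[cells > 0]))
  lab_n <- sort(unique(nuclei[nuclei > 0]))
  orphans <- c(setdiff(lab_c, lab_n), setdiff(lab_n, lab_c))
  if (length(orphans))
    stop(sprintf("label sets differ between cells and nuclei (orphans: %s)",
                 paste(orphans, collapse = ", ")))
  covered <- nuclei == 0 | cells == nuclei
  if (!all(covered))
    stop("nucleus pixels must lie inside the same-labelled cell")
  cyto <- cells
  cyto[nuclei > 0] <- 0L
  present <- unique(cyto[cyto > 0])
  attr(cyto, "empty_cytoplasm_labels") <- setdiff(lab_c, present)
  cyto
}

#' Segment an image end-to-end
#'
#' Convenience wrapper running [detect_nuclei()], [propagate_cells()] and
#' [derive_cytoplasm()] with shared parameters.
#'
#' @param image A [labeled_image()].
#' @param mode,max_distance_px,ring_width_px See [propagate_cells()].
#' @param ... Passed to [detect_nuclei()].
#' @return List of class `segmentation_result` with `nuclei_labels`,
#'   `cell_labels`, `cytoplasm_labels` and `params_used`.
#' @export
segment_image <- function(image, mode = "propagation", max_distance_px = 10,
                          ring_width_px = 3, ...) {
  nuc <- detect_nuclei(image, ...)
  cells <- propagate_cells(nuc, mode = mode,
                           max_distance_px = max_distance_px,
                           ring_width_px = ring_width_px)
  cyto <- derive_cytoplasm(cells, nuc)
  structure(list(nuclei_labels = nuc, cell_labels = cells,
                 cytoplasm_labels = cyto,
                 params_used = c(attr(nuc, "params_used"),
                                 list(mode = mode,
                                      max_distance_px = max_distance_px,
                                      ring_width_px = ring_width_px))),
            class = "segmentation_result")
}

# Lower median: the lower middle value for even-length input, so the median
# is always an attained pixel value.
median_lower <- function(v) {
  v <- v[!is.na(v)]
  n <- length(v)
  if (n == 0) return(NA_real_)
  sort(v)[ceiling(n / 2)]
}

#' Measure per-cell compartment medians
#'
#' One record per cell label; for every channel and compartment (nucleus,
#' cytoplasm, cell) the median intensity over the compartment's pixels is
#' reported (lower median for even pixel counts). Empty cytoplasm yields
#' `NA` cytoplasm medians. Each cell inherits `tumor_id` from the tumor mask
#' value at its nucleus centroid when a mask is given, otherwise from the
#' image metadata.
#'
#' @param image A [labeled_image()].
#' @param seg A `segmentation_result` from [segment_image()], or a list with
#'   `nuclei_labels`, `cell_labels`, `cytoplasm_labels`.
#' @param tumor_mask Optional integer raster of tumor ids (same shape).
#' @return Data frame with one row per cell: `cell_id`, `tumor_id`,
#'   `genotype`, per-compartment areas, and
#'   `<channel>_<compartment>_median` columns.
#' @export
measure_cells <- function(image, seg, tumor_mask = NULL) {
  stopifnot(inherits(image, "labeled_image"))
  nuc <- seg$nuclei_labels; cells <- seg$cell_labels
  cyto <- seg$cytoplasm_labels
  shape <- dim(image$channels[[1]])
  if (!identical(dim(nuc), shape))
    stop("segmentation shape does not match image shape")
  labs <- sort(unique(cells[cells > 0]))
  n <- length(labs)

  rec <- data.frame(cell_id = labs)
  if (is.null(tumor_mask)) {
    rec$tumor_id <- rep(image$metadata$tumor_id %||% "tumor_1", n)
  } else {
    h <- nrow(nuc)
    cent <- vapply(labs, function(l) {
      idx <- which(nuc == l)
      c(round(mean((idx - 1L) %% h + 1L)), round(mean((idx - 1L) %/% h + 1L)))
    }, numeric(2))
    rec$tumor_id <- tumor_mask[cbind(cent[1, ], cent[2, ])]
  }
  rec$genotype <- rep(image$metadata$genotype %||% "unknown", n)

  comps <- list(nucleus = nuc, cytoplasm = cyto, cell = cells)
  for (comp in names(comps)) {
    sizes <- tabulate(comps[[comp]], nbins = max(labs))
    rec[[paste0(comp, "_area")]] <- sizes[labs]
  }
  for (ch in names(image$channels)) {
    vals <- image$channels[[ch]]
    for (comp in names(comps)) {
      lab <- comps[[comp]]
      idx <- lab > 0
      med <- vapply(split(vals[idx], lab[idx]), median_lower, numeric(1))
      col <- rep(NA_real_, n)
      col[match(as.integer(names(med)), labs)] <- med
      rec[[paste0(ch, "_", comp, "_median")]] <- col
    }
  }
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a
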