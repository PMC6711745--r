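# Readers and writers for the package's external formats: multi-page TIFF
# image stacks with JSON sidecars, 16-bit label rasters, counts/groups CSV,
# GMT gene sets, transcription-factor lists, and JSON reports.

#' Write a labeled image as a multi-page TIFF with JSON sidecar
#'
#' One 16-bit page per channel; channel names, roles, tumor id and genotype
#' go into `<path>.json`.
#'
#' @param image A [labeled_image()].
#' @param path Output TIFF path.
#' @return Invisibly, the sidecar path.
#' @export
write_image_stack <- function(image, path) {
  stopifnot(inherits(image, "labeled_image"))
  pages <- lapply(image$channels, function(ch) ch / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(channels = names(image$channels),
                            roles = image$roles,
                            tumor_id = image$metadata$tumor_id,
                            genotype = image$metadata$genotype),
                       sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(sidecar)
}

#' Read a multi-page TIFF stack with JSON sidecar
#'
#' @param path TIFF path written by [write_image_stack()]; the sidecar is
#'   expected at `<path>.json`.
#' @return A [labeled_image()].
#' @export
read_image_stack <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop(sprintf("missing sidecar '%s'", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(meta$channels))
    stop("page count does not match sidecar channel list")
  channels <- lapply(pages, function(p) round(p * 65535))
  names(channels) <- meta$channels
  labeled_image(channels, as.list(meta$roles)[meta$channels],
                tumor_id = meta$tumor_id, genotype = meta$genotype)
}

#' Write / read a label raster as 16-bit TIFF
#'
#' Label values are stored losslessly for labels up to 65535.
#'
#' @param labels Integer label matrix.
#' @param path TIFF path.
#' @return `write_tiff_labels`: invisibly `path`; `read_tiff_labels`: the
#'   integer label matrix.
#' @export
write_tiff_labels <- function(labels, path) {
  if (max(labels) > 65535) stop("labels exceed the 16-bit range")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_tiff_labels
#' @export
read_tiff_labels <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Read a gene-by-sample counts CSV
#'
#' First column = gene id (must be unique), remaining columns = samples.
#'
#' @param path CSV path with a header row.
#' @return Numeric matrix with gene-id rownames.
#' @export
read_counts_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1]]
  dup <- which(duplicated(ids))
  if (length(dup))
    stop(sprintf("duplicated gene id '%s' at data line %d", ids[dup[1]],
                 dup[1]))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  m
}

#' Write a counts matrix as CSV
#'
#' @param counts Matrix with gene-id rownames.
#' @param path Output path.
#' @export
write_counts_csv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard tab-delimited dialect: set name, description, then member gene
#' ids. Malformed lines are reported with their line number.
#'
#' @param path GMT path.
#' @return Named list of character vectors of unique members.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop(sprintf("malformed GMT line %d: fewer than 3 fields", i))
    sets[[parts[1]]] <- unique(parts[-(1:2)])
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(!is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a transcription-factor list
#'
#' One gene id per line; blank lines and `#` comments ignored.
#'
#' @param path Text file path.
#' @return Character vector of unique gene ids.
#' @export
read_tf_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  unique(lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' Write a JSON report
#'
#' @param report Named list of results.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}
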