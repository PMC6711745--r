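# The two reproducible analysis arms. Each arm takes a single resolved
# configuration, runs its stages in order, writes every artifact (tables as
# CSV, statistics as JSON, plots as PNG) into one output directory along
# with the fully-resolved configuration, and returns the in-memory results.
# One seed in the configuration fans out to per-stage seeds by fixed
# offsets (documented below) so stages are independently reproducible.

stage_seed <- function(rng_seed, stage) {
  offsets <- c(images = 101L, expr = 211L, gsea = 307L, boot = 401L)
  as.integer(rng_seed) + offsets[[stage]]
}

#' Default configuration of the image arm
#'
#' Two genotypes, several tumors each imaged as one field of view, with
#' the de-differentiating genotype losing the marker in half its cells.
#'
#' @param rng_seed Master seed.
#' @param n_tumors_per_genotype Tumors (= images) per genotype.
#' @param loss_fractions Named marker-loss fractions per genotype; the
#'   first genotype is the thresholding reference.
#' @param image_args Overrides passed to [image_sim_config()].
#' @param mode,max_distance_px,ring_width_px Cell construction parameters,
#'   see [propagate_cells()]. The propagation cap defaults to the emulated
#'   cytoplasm width so measured cytoplasm tracks the true cell body.
#' @return Named list, the `config` argument of [run_image_arm()].
#' @export
image_arm_config <- function(rng_seed = 1L, n_tumors_per_genotype = 4,
                             loss_fractions = c(BRAF = 0,
                                                BRAF_PIK3CA = 0.5),
                             image_args = list(image_height_px = 384,
                                               image_width_px = 384,
                                               n_cells = 120),
                             mode = "propagation", max_distance_px = 5,
                             ring_width_px = 3) {
  list(rng_seed = as.integer(rng_seed),
       n_tumors_per_genotype = n_tumors_per_genotype,
       loss_fractions = loss_fractions,
       image_args = image_args,
       mode = mode, max_distance_px = max_distance_px,
       ring_width_px = ring_width_px)
}

#' Run the image arm
#'
#' Simulates (or loads) per-tumor images, segments them, measures cells,
#' aggregates tumors, fits mean - 1 SD thresholds on the reference
#' genotype, classifies quadrants, and runs the genotype statistics
#' (chi-squared on the quadrant table, Wilcoxon on tumor summaries,
#' per-genotype Spearman).
#'
#' @param config From [image_arm_config()].
#' @param out_dir Output directory (created); `NULL` skips writing.
#' @return List with `records`, `summaries`, `rules`, `quadrants`,
#'   `chi_squared`, `wilcoxon`, `spearman`, and `artifacts` (paths).
#' @export
run_image_arm <- function(config, out_dir = NULL) {
  genotypes <- names(config$loss_fractions)
  stopifnot(length(genotypes) >= 2)
  seed0 <- stage_seed(config$rng_seed, "images")

  records <- list(); images <- list()
  k <- 0L
  for (g in genotypes) {
    for (t in seq_len(config$n_tumors_per_genotype)) {
      k <- k + 1L
      args <- config$image_args
      args$genotype_label <- g
      args$tumor_id <- sprintf("%s_t%02d", g, t)
      args$marker_loss_fraction <- config$loss_fractions[[g]]
      args$rng_seed <- seed0 + k
      sim <- generate_tumor_image(do.call(image_sim_config, args))
      seg <- segment_image(sim$image, mode = config$mode,
                           max_distance_px = config$max_distance_px,
                           ring_width_px = config$ring_width_px)
      rec <- measure_cells(sim$image, seg)
      records[[length(records) + 1L]] <- rec
      images[[args$tumor_id]] <- list(image = sim$image, seg = seg)
    }
  }
  records <- do.call(rbind, records)
  summaries <- aggregate_tumors(records)

  img1 <- images[[1]]$image
  tf_ch <- channel_by_role(img1, "nuclear_tf")
  marker_ch <- channel_by_role(img1, "marker")
  reference <- genotypes[1]
  rule_a <- fit_threshold(records, tf_ch, "nucleus", reference)
  rule_b <- fit_threshold(records, marker_ch, "cytoplasm", reference)
  quad <- classify_quadrants(records, rule_a, rule_b)
  chi <- chi_squared_genotype(quad$table)
  wil <- tumor_wilcoxon(summaries, genotypes[1:2], marker_ch, "cytoplasm")
  rho <- spearman_by_genotype(records, tf_ch, "nucleus",
                              marker_ch, "cytoplasm")

  res <- list(records = records, summaries = summaries,
              rules = list(A = rule_a, B = rule_b), quadrants = quad,
              chi_squared = chi, wilcoxon = wil, spearman = rho,
              artifacts = character(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      config = file.path(out_dir, "config.json"),
      records = file.path(out_dir, "cell_records.csv"),
      summaries = file.path(out_dir, "tumor_summaries.csv"),
      classes = file.path(out_dir, "cell_classes.csv"),
      quadrants = file.path(out_dir, "quadrant_table.csv"),
      stats = file.path(out_dir, "stats_report.json"),
      plot = file.path(out_dir, "quadrant_plot.png"))
    write_report_json(config, paths["config"])
    utils::write.csv(records, paths["records"], row.names = FALSE)
    utils::write.csv(summaries, paths["summaries"], row.names = FALSE)
    utils::write.csv(data.frame(cell_id = records$cell_id,
                                tumor_id = records$tumor_id,
                                genotype = records$genotype,
                                class = as.character(quad$classes)),
                     paths["classes"], row.names = FALSE)
    utils::write.csv(as.data.frame.matrix(quad$table), paths["quadrants"])
    write_report_json(list(chi_squared = chi[c("statistic", "df", "p_value")],
                           wilcoxon = wil, spearman = rho,
                           thresholds = list(A = unclass(rule_a),
                                             B = unclass(rule_b)),
                           rng_seed = config$rng_seed),
                      paths["stats"])
    grDevices::png(paths["plot"], width = 900, height = 600)
    print(plot_quadrants(records, rule_a, rule_b))
    grDevices::dev.off()
    # label rasters for the first tumor of each genotype
    for (g in genotypes) {
      id <- sprintf("%s_t01", g)
      p <- file.path(out_dir, sprintf("cell_labels_%s.tif", id))
      write_tiff_labels(images[[id]]$seg$cell_labels, p)
      paths[paste0("labels_", id)] <- p
    }
    res$artifacts <- paths
  }
  res
}

#' Run the expression arm
#'
#' Simulates (or loads) a count matrix, then runs normalization, the NB
#' Wald differential-expression test, marker-set construction from the
#' reference profiles, preranked GSEA over the marker sets, the expression
#' filter and co-expression module detection, marker-module selection, and
#' the three-factor screen.
#'
#' @param config An [expr_sim_config()], optionally with extra fields
#'   overridden via `...`.
#' @param out_dir Output directory (created); `NULL` skips writing.
#' @param n_perm GSEA permutations (must be >= 1).
#' @param min_level Expression-filter floor.
#' @param adjp_cutoff Screen DE cutoff.
#' @param beta,cut_height,min_size Module-detection parameters.
#' @return List with `de`, `enrichment`, `assignment`, `marker_module`,
#'   `candidates`, `marker_sets`, `truth`, `artifacts`.
#' @export
run_expr_arm <- function(config = expr_sim_config(), out_dir = NULL,
                         n_perm = 1000, min_level = 40, adjp_cutoff = 0.2,
                         beta = 3, cut_height = 0.9, min_size = 30) {
  stopifnot(inherits(config, "expr_sim_config"))
  if (n_perm < 1)
    stop("enrichment stage requires n_perm >= 1")
  sim <- generate_expression_matrix(config)
  sf <- size_factors(sim$counts)
  norm <- normalize_counts(sim$counts, sf)
  de <- nb_wald_test(sim$counts, sim$groups$group,
                     group_a = config$group_labels[1],
                     group_b = config$group_labels[2])
  ranked <- ranked_list(de)
  profiles <- generate_celltype_markers(config)
  sets <- build_marker_sets(profiles, k = config$marker_set_size)
  enr <- gsea_collection(ranked, sets, n_perm = n_perm,
                         rng_seed = stage_seed(config$rng_seed, "gsea"))
  expressed <- filter_expressed(norm, min_level = min_level)
  assignment <- coexpression_modules(expressed, beta = beta,
                                     cut_height = cut_height,
                                     min_size = min_size)
  marker_sel <- select_marker_module(
    assignment, sets[c("AT1", "AT2")])
  tf_list <- config$genes$gene_id[config$genes$is_tf]
  candidates <- three_factor_screen(assignment, marker_sel$module,
                                    tf_list, de, adjp_cutoff = adjp_cutoff)

  res <- list(de = de, enrichment = enr, assignment = assignment,
              marker_module = marker_sel, candidates = candidates,
              marker_sets = sets, truth = sim$truth, size_factors = sf,
              artifacts = character(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      config = file.path(out_dir, "config.json"),
      counts = file.path(out_dir, "counts.csv"),
      groups = file.path(out_dir, "groups.csv"),
      de = file.path(out_dir, "de_results.csv"),
      gmt = file.path(out_dir, "marker_sets.gmt"),
      enrichment = file.path(out_dir, "enrichment.csv"),
      modules = file.path(out_dir, "module_assignment.csv"),
      module_markers = file.path(out_dir, "module_marker_counts.csv"),
      candidates = file.path(out_dir, "candidate_table.csv"),
      plot = file.path(out_dir, "enrichment_plot.png"))
    cfg_out <- config
    cfg_out$genes <- NULL  # layout table goes to its own CSV
    write_report_json(cfg_out, paths["config"])
    write_counts_csv(sim$counts, paths["counts"])
    utils::write.csv(sim$groups, paths["groups"], row.names = FALSE)
    de_sorted <- de[order(de$p_value), ]
    utils::write.csv(de_sorted, paths["de"], row.names = FALSE)
    write_gmt(sets, paths["gmt"])
    utils::write.csv(enr, paths["enrichment"], row.names = FALSE)
    utils::write.csv(data.frame(gene_id = names(assignment$modules),
                                module = assignment$modules,
                                row.names = NULL),
                     paths["modules"], row.names = FALSE)
    utils::write.csv(marker_sel$counts, paths["module_markers"],
                     row.names = FALSE)
    utils::write.csv(candidates, paths["candidates"], row.names = FALSE)
    grDevices::png(paths["plot"], width = 700, height = 450)
    print(plot_enrichment(enr))
    grDevices::dev.off()
    res$artifacts <- paths
  }
  res
}
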