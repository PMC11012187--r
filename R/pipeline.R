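write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

manifest_entry <- function(stage, params, outputs) {
  list(stage = stage, params = params, outputs = outputs,
       package_version = as.character(utils::packageVersion("lipidMAE")))
}

#' Emit a full set of synthetic workflow inputs
#'
#' Writes the design file, factorial response table, solvent-screening
#' table, identification fixture and QC table generated by the
#' synthetic-data module into a directory, so every downstream workflow
#' can be exercised from files alone.
#'
#' @param outdir Output directory (created if missing).
#' @param config A `generator_config`.
#' @return Invisibly, a named list of the file paths written.
#' @export
simulate_inputs <- function(outdir, config = generator_config()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  design <- build_full_factorial(mae_factors(), n_center = 3)
  paths <- list(
    design = file.path(outdir, "design.tsv"),
    responses = file.path(outdir, "ffd_responses.tsv"),
    screening = file.path(outdir, "solvent_screening.tsv"),
    identifications = file.path(outdir, "identifications.tsv"),
    qc = file.path(outdir, "qc_areas.tsv")
  )
  write_design(design, paths$design)
  resp <- gen_ffd_responses(design, config)
  write_tsv(cbind(run_id = rownames(resp), resp), paths$responses)
  write_tsv(gen_solvent_screening(config), paths$screening)
  fix <- gen_lipid_fixture()
  write_lipid_table(fix, paths$identifications,
                    areas = 1e5 * (1 + 0.01 * seq_along(fix)))
  qc <- gen_qc_table(config)
  write_tsv(data.frame(standard = rep(names(qc), lengths(qc)),
                       area = unlist(qc, use.names = FALSE)), paths$qc)
  invisible(paths)
}

#' Solvent-screening workflow: scaling, PCA, HCA and PLS-DA
#'
#' Runs the full screening diagnostics on a labelled abundance table:
#' range scaling of the subclass sums, PCA (autoscaled), average-linkage
#' hierarchical clustering on squared Euclidean distances of the
#' range-scaled data, and PLS-DA validated both by double
#' cross-validation and by bootstrap. When `outdir` is given, the score/
#' loading tables, the dendrogram (Newick) and the diagnostic table are
#' written as delimited text.
#'
#' @param screening Data frame with `sample_id`, `solvent` and numeric
#'   subclass columns (see [gen_solvent_screening()]), or a path to such
#'   a file.
#' @param cut_height HCA cut height on the squared-Euclidean scale.
#' @param bootstrap_B Bootstrap replicate count.
#' @param seed Integer seed for fold shuffling and resampling.
#' @param outdir Optional output directory.
#' @return An object of class `screening_report`: list with `pca`,
#'   `hca`, `clusters`, `plsda` (list `double_cv`, `bootstrap`),
#'   `diagnostics` (6 statistics x class x validation-mode long data
#'   frame), `manifest`.
#' @export
run_screening <- function(screening, cut_height = 2, bootstrap_B = 1000,
                          seed = 1, outdir = NULL) {
  if (is.character(screening)) screening <- utils::read.delim(screening)
  stopifnot(all(c("sample_id", "solvent") %in% names(screening)))
  y <- as.factor(screening$solvent)
  if (nlevels(y) < 3L) stop("need 3 solvent classes", call. = FALSE)
  X <- as.matrix(screening[setdiff(names(screening), c("sample_id", "solvent"))])
  if (nrow(X) != length(y)) stop("misaligned labels", call. = FALSE)

  scaled <- range_scale_responses(as.data.frame(X))
  pca_model <- pca(X, center = TRUE, scale = TRUE)
  hca <- hca_average_linkage(stats::setNames(scaled, colnames(X)))
  hca$labels <- screening$sample_id
  hca$hclust$labels <- screening$sample_id
  clusters <- cut_tree(hca, cut_height)

  dcv <- plsda_double_cv(X, y, seed = seed)
  boot <- plsda_bootstrap(X, y, B = bootstrap_B, seed = seed)
  diagnostics <- do.call(rbind, lapply(list(dcv, boot), function(r) {
    long <- as.data.frame(as.table(r$stats), stringsAsFactors = FALSE)
    names(long) <- c("statistic", "class", "value")
    long$mode <- r$mode
    long
  }))

  report <- structure(
    list(pca = pca_model, hca = hca, clusters = clusters,
         plsda = list(double_cv = dcv, bootstrap = boot),
         diagnostics = diagnostics,
         manifest = manifest_entry("screening",
                                   list(cut_height = cut_height,
                                        bootstrap_B = bootstrap_B, seed = seed),
                                   outdir %||% NA_character_)),
    class = "screening_report"
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(data.frame(sample_id = screening$sample_id, solvent = y,
                         pca_model$scores[, 1:2]),
              file.path(outdir, "pca_scores.tsv"))
    write_tsv(data.frame(subclass = rownames(pca_model$loadings),
                         pca_model$loadings[, 1:2]),
              file.path(outdir, "pca_loadings.tsv"))
    hca_to_newick(hca, file.path(outdir, "dendrogram.nwk"))
    write_tsv(data.frame(sample_id = screening$sample_id, cluster = clusters),
              file.path(outdir, "hca_clusters.tsv"))
    write_tsv(diagnostics, file.path(outdir, "plsda_diagnostics.tsv"))
    jsonlite::write_json(report$manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.screening_report <- function(x, ...) {
  cat("<screening_report>\n")
  cat(sprintf("PCA: PC1 %.1f%%, PC2 %.1f%% explained variance\n",
              x$pca$explained_variance_pct[1], x$pca$explained_variance_pct[2]))
  cat("HCA clusters at cut:", max(x$clusters), "\n")
  print(x$plsda$double_cv); print(x$plsda$bootstrap)
  invisible(x)
}

#' Optimization workflow: factorial models, PC surfaces, Pareto front
#'
#' Fits the 8-term factorial model to every (range-scaled) subclass
#' response, keeps the responses whose overall model is significant,
#' runs a PCA on that reduced response set (centered, unscaled — the
#' responses already share the [0, 1] scale), models PC1 and PC2 as
#' interaction surfaces of the three factors, evaluates both surfaces on
#' a dense grid and extracts the Pareto front and the
#' nearest-to-utopia compromise setting.
#'
#' @param design A `design_table` or path to a design file.
#' @param responses Data frame of subclass responses aligned to the
#'   design (or path; a `run_id` column is matched against the design).
#' @param grid_levels Grid levels per factor (default 40, i.e. 64,000
#'   points for 3 factors).
#' @param directions Objective senses for (PC1, PC2); default both
#'   `"max"`. Which lipid groups sit at which end of a PC depends on
#'   the data — inspect the reported loadings to orient the axes.
#' @param keep_if_model_p Model retention threshold (default 0.05).
#' @param scale_responses Range-scale responses before fitting (default
#'   TRUE; set FALSE when the input is already on the scaled scale).
#' @param outdir Optional output directory.
#' @return An object of class `optimization_report`: list with `fits`,
#'   `significance`, `pca`, `surfaces`, `evaluated`, `front` (indices),
#'   `compromise`, `grid_size`, `manifest`.
#' @export
run_optimization <- function(design, responses, grid_levels = 40,
                             directions = c("max", "max"),
                             keep_if_model_p = 0.05,
                             scale_responses = TRUE, outdir = NULL) {
  if (is.character(design)) design <- read_design(design)
  if (is.character(responses)) {
    responses <- utils::read.delim(responses)
  }
  if ("run_id" %in% names(responses)) {
    if (!setequal(responses$run_id, design$run_id)) {
      stop("response run_ids do not match the design", call. = FALSE)
    }
    responses <- responses[match(design$run_id, responses$run_id),
                           setdiff(names(responses), "run_id"), drop = FALSE]
  }
  if (nrow(responses) != nrow(design)) {
    stop("responses do not align with the design rows", call. = FALSE)
  }
  resp <- if (scale_responses) range_scale_responses(responses) else responses

  fits <- fit_ffd_all(design, resp)
  sig <- significance_table(fits, keep_if_model_p)
  if (length(sig$retained) == 0L) {
    stop("no subclass shows a significant dependence on the extraction ",
         "conditions; nothing to optimize", call. = FALSE)
  }
  pca_model <- pca(resp[sig$retained], center = TRUE, scale = FALSE,
                   ncomp = 2)
  colnames(pca_model$scores) <- colnames(pca_model$loadings) <- c("PC1", "PC2")
  surfaces <- fit_pc_surfaces(design, pca_model$scores)
  grid <- build_grid(attr(design, "factors"), grid_levels)
  evaluated <- evaluate_surfaces(grid, surfaces)
  front <- pareto_front(evaluated[c("PC1", "PC2")], directions)
  compromise <- select_compromise(evaluated, front,
                                  objectives = c("PC1", "PC2"),
                                  directions = directions)

  report <- structure(
    list(fits = fits, significance = sig, pca = pca_model,
         surfaces = surfaces, evaluated = evaluated, front = front,
         compromise = compromise, grid_size = grid$n_points,
         manifest = manifest_entry("optimization",
                                   list(grid_levels = grid_levels,
                                        directions = directions,
                                        keep_if_model_p = keep_if_model_p,
                                        scale_responses = scale_responses),
                                   outdir %||% NA_character_)),
    class = "optimization_report"
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_significance_table(sig, file.path(outdir, "significance.tsv"))
    write_tsv(data.frame(run_id = design$run_id, pca_model$scores),
              file.path(outdir, "pc_scores.tsv"))
    write_tsv(data.frame(subclass = rownames(pca_model$loadings),
                         pca_model$loadings),
              file.path(outdir, "pc_loadings.tsv"))
    write_tsv(evaluated[front, ], file.path(outdir, "pareto_front.tsv"))
    write_tsv(compromise$setting, file.path(outdir, "compromise.tsv"))
    jsonlite::write_json(report$manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.optimization_report <- function(x, ...) {
  cat("<optimization_report>", length(x$significance$retained),
      "modelled subclasses;", x$grid_size, "grid points;",
      length(x$front), "front points\n")
  print(x$compromise)
  invisible(x)
}

#' Annotation workflow: inventory summary, method comparison, QC
#'
#' Parses an identification export, summarizes the inventory and
#' optionally compares it against a second export and gates QC replicate
#' areas. More than 5% unparseable names aborts with a line-numbered
#' listing of the failures.
#'
#' @param identifications Path to an identification table (see
#'   [read_lipid_table()]) or a list of `lipid_species`.
#' @param compare_with Optional second table (path or species list).
#' @param qc_areas Optional named list of replicate areas per standard.
#' @param threshold_rsd QC threshold in percent.
#' @param grades Optional grade filter applied when reading files.
#' @param outdir Optional output directory.
#' @return An object of class `annotation_report`: list with `summary`
#'   (a `subclass_summary`), `comparison` (or NULL), `qc` (or NULL),
#'   `failures`, `manifest`.
#' @export
run_annotation <- function(identifications, compare_with = NULL,
                           qc_areas = NULL, threshold_rsd = 20,
                           grades = NULL, outdir = NULL) {
  load_species <- function(x) {
    if (is.character(x)) {
      parsed <- read_lipid_table(x, grades = grades)
      n_bad <- NROW(parsed$failures)
      n_tot <- length(parsed$species) + n_bad
      if (n_tot > 0 && n_bad / n_tot > 0.05) {
        stop("more than 5% of names failed to parse:\n",
             paste(sprintf("  line %d: %s (%s)", parsed$failures$line,
                           parsed$failures$name, parsed$failures$error),
                   collapse = "\n"), call. = FALSE)
      }
      parsed
    } else {
      list(species = x, failures = NULL)
    }
  }
  main <- load_species(identifications)
  summ <- summarize_inventory(main$species)
  comparison <- NULL
  if (!is.null(compare_with)) {
    other <- load_species(compare_with)
    comparison <- compare_methods(main$species, other$species,
                                  labels = c("a", "b"))
  }
  qc <- if (!is.null(qc_areas)) qc_check(qc_areas, threshold_rsd)

  report <- structure(
    list(summary = summ, comparison = comparison, qc = qc,
         failures = main$failures,
         manifest = manifest_entry("annotation",
                                   list(threshold_rsd = threshold_rsd,
                                        grades = grades %||% NA),
                                   outdir %||% NA_character_)),
    class = "annotation_report"
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (summ$n_species > 0) {
      write_tsv(data.frame(subclass = names(summ$subclass_counts),
                           n = summ$subclass_counts),
                file.path(outdir, "subclass_counts.tsv"))
      if (!is.null(summ$tg_positions)) {
        write_tsv(summ$tg_positions, file.path(outdir, "tg_positions.tsv"))
      }
    }
    if (!is.null(comparison)) {
      write_tsv(comparison$counts, file.path(outdir, "method_comparison.tsv"))
    }
    if (!is.null(qc)) write_tsv(qc, file.path(outdir, "qc_report.tsv"))
    jsonlite::write_json(report$manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.annotation_report <- function(x, ...) {
  print(x$summary)
  if (!is.null(x$comparison)) print(x$comparison)
  if (!is.null(x$qc)) {
    cat("QC:", sum(x$qc$pass), "of", nrow(x$qc), "standards pass\n")
  }
  invisible(x)
}
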