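# End-to-end orchestration: matrix validation, subspecies dedup, tree
# pruning, per-character model selection, optional lambda-rescaled stochastic
# mapping, rate matrices, and the correlation screen, with reproducible seeds
# and a structured report.

#' Default character code ranges
#'
#' Cell shape 0-1, cell border 0-4, cell surface 0-3, ridge 0-1, life habit
#' 0-6 (four pure habits plus the three combination states).
#'
#' @return Named list of integer ranges.
#' @export
default_code_ranges <- function() {
  list(cell_shape = 0:1, cell_border = 0:4, cell_surface = 0:3,
       ridge = 0:1, life_habit = 0:6)
}

#' Validate a character matrix
#'
#' Checks codes against per-character ranges, duplicate species rows, and
#' all-unknown rows. Issues are returned, never raised.
#'
#' @param matrix Data frame (`species` column first) or CSV path.
#' @param ranges Named list of allowed codes per column; columns without an
#'   entry are not range-checked.
#' @return Data frame of issues: `row`, `column`, `issue` (zero rows when
#'   clean).
#' @export
validate_matrix <- function(matrix, ranges = default_code_ranges()) {
  if (is.character(matrix)) matrix <- read_character_matrix(matrix)
  stopifnot(is.data.frame(matrix), names(matrix)[1] == "species")
  issues <- list()
  add <- function(row, column, issue)
    issues[[length(issues) + 1]] <<- data.frame(row = row, column = column,
                                                issue = issue,
                                                stringsAsFactors = FALSE)
  dup <- which(duplicated(matrix$species))
  for (r in dup) add(r, "species", "duplicate species")
  chars <- names(matrix)[-1]
  for (cn in chars) {
    if (!cn %in% names(ranges)) next
    bad <- which(!is.na(matrix[[cn]]) & !(matrix[[cn]] %in% ranges[[cn]]))
    for (r in bad)
      add(r, cn, sprintf("code %s out of range", matrix[[cn]][r]))
  }
  all_na <- which(rowSums(!is.na(matrix[, chars, drop = FALSE])) == 0)
  for (r in all_na) add(r, "all", "all characters unknown")
  if (length(issues) == 0)
    return(data.frame(row = integer(0), column = character(0),
                      issue = character(0), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}

#' Default pipeline configuration
#'
#' @param tree Path to a Newick file or a `phylo` object.
#' @param matrix Path to a character-matrix CSV or a data frame.
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in every output.
#' @return Named list of configuration values; see [run_pipeline()].
#' @export
pipeline_config <- function(tree, matrix, out_dir, seed = 1) {
  list(tree = tree, matrix = matrix, images = NULL, out_dir = out_dir,
       seed = seed,
       characters = NULL,                    # NULL = all matrix columns
       structures = c("ER", "SYM", "ARD"),
       transforms = c("none", "lambda"),
       n_starts = 5,
       root_prior = "uniform",
       mapping = list(enabled = TRUE, nsim = 200),
       correlations = list(enabled = TRUE, methods = "pgls", alpha = 0.05),
       signal = TRUE)
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  base <- pipeline_config(config$tree, config$matrix,
                          config$out_dir %||% tempfile("nanophylo_out"),
                          config$seed %||% 1)
  base[names(config)] <- config
  base
}

#' Run the full analysis pipeline
#'
#' Stages: optional image classification; matrix validation; subspecies
#' deduplication; tree pruning to scored taxa and polytomy resolution; Mk
#' model selection per character (all configured structure x transform
#' combinations, AICc/AICw); lambda phylogenetic-signal test; stochastic
#' mapping on the best model's tree (rescaled by the fitted lambda when the
#' best model carries one), with taxa unknown for a character pruned for that
#' character only; rate matrices with sub-1e-6 rates zeroed; and the
#' all-pairs correlation screen. Every stage writes its output under
#' `out_dir` and the combined report is returned (and written as JSON with no
#' timestamps, so identical inputs and seed give byte-identical reports).
#'
#' @param config Configuration list from [pipeline_config()] (possibly
#'   modified) or the path to a YAML file with the same keys.
#' @return List of class `run_report`.
#' @export
run_pipeline <- function(config) {
  cfg <- read_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, ...) {
    message(sprintf("[nanophylo] %s: %s", stage, sprintf(...)))
  }

  tree <- if (inherits(cfg$tree, "phylo")) cfg$tree else read_newick(cfg$tree)
  mat <- if (is.data.frame(cfg$matrix)) cfg$matrix
         else read_character_matrix(cfg$matrix)

  report <- list(seed = cfg$seed,
                 n_input_species = nrow(mat))

  # imaging (optional, independent classification of a directory of images)
  if (!is.null(cfg$images)) {
    paths <- list.files(cfg$images, pattern = "\\.(png|tif|tiff)$",
                        full.names = TRUE, ignore.case = TRUE)
    log_stage("imaging", "%d images", length(paths))
    img_tab <- classify_images(paths)
    utils::write.csv(img_tab, file.path(cfg$out_dir, "imaging.csv"),
                     row.names = FALSE)
    report$imaging <- img_tab
  }

  issues <- validate_matrix(mat)
  utils::write.csv(issues, file.path(cfg$out_dir, "matrix_issues.csv"),
                   row.names = FALSE)
  report$n_matrix_issues <- nrow(issues)
  log_stage("validate", "%d issues", nrow(issues))

  dd <- dedup_subspecies(mat, tree)
  mat <- dd$matrix
  utils::write.csv(dd$log, file.path(cfg$out_dir, "dedup_log.csv"),
                   row.names = FALSE)
  report$n_subspecies_removed <- nrow(dd$log)
  log_stage("dedup", "%d rows removed", nrow(dd$log))

  common <- intersect(tree$tip.label, mat$species)
  if (length(common) < 3) stop("stage 'prune' failed: <3 taxa shared ",
                               "between tree and matrix")
  tree <- resolve_polytomies(prune_to_taxa(tree, common))
  mat <- mat[match(tree$tip.label, mat$species), , drop = FALSE]
  report$n_taxa <- length(common)
  log_stage("prune", "%d taxa", length(common))

  chars <- cfg$characters %||% names(mat)[-1]
  model_rows <- list(); signal_rows <- list()
  best_fits <- list()
  for (ch in chars) {
    states <- stats::setNames(mat[[ch]], mat$species)
    fits <- list()
    for (st in cfg$structures) for (tk in cfg$transforms) {
      f <- tryCatch(
        fit_mk(tree, states, structure = st, transform_kind = tk,
               n_starts = cfg$n_starts, root_prior = cfg$root_prior),
        error = function(e) NULL)
      if (!is.null(f)) fits[[length(fits) + 1]] <- f
    }
    if (length(fits) == 0) {
      log_stage("models", "%s: no fit possible", ch)
      next
    }
    cmp <- compare_models(fits)
    cmp <- cbind(character = ch, cmp)
    model_rows[[ch]] <- cmp
    ord <- order(vapply(fits, `[[`, 0, "AICc"))
    best_fits[[ch]] <- fits[[ord[1]]]
    log_stage("models", "%s: best %s/%s", ch, cmp$Model[1],
              cmp$Transformation[1])
    if (isTRUE(cfg$signal)) {
      sg <- tryCatch(phylo_signal_lambda(tree, states,
                                         structure = cmp$Model[1],
                                         n_starts = cfg$n_starts),
                     error = function(e) NULL)
      if (!is.null(sg))
        signal_rows[[ch]] <- data.frame(character = ch,
                                        lambda_ml = sg$lambda_ml,
                                        lrt = sg$lrt, p = sg$p,
                                        stringsAsFactors = FALSE)
    }
  }
  model_tab <- do.call(rbind, c(model_rows, make.row.names = FALSE))
  utils::write.csv(model_tab, file.path(cfg$out_dir, "models.csv"),
                   row.names = FALSE)
  report$models <- model_tab
  if (length(signal_rows) > 0) {
    signal_tab <- do.call(rbind, c(signal_rows, make.row.names = FALSE))
    utils::write.csv(signal_tab, file.path(cfg$out_dir, "signal.csv"),
                     row.names = FALSE)
    report$signal <- signal_tab
  }

  if (isTRUE(cfg$mapping$enabled)) {
    maps <- list(); rate_mats <- list()
    for (ch in names(best_fits)) {
      bf <- best_fits[[ch]]
      states <- stats::setNames(mat[[ch]], mat$species)
      map_tree <- if (bf$transform == "lambda")
        transform_lambda(tree, bf$coefficient)
      else if (bf$transform != "none")
        transform_tree(tree, bf$transform, bf$coefficient)
      else tree
      hist <- sample_histories(map_tree, states, bf$Q,
                               n_sim = cfg$mapping$nsim,
                               structure = bf$structure,
                               seed = cfg$seed)
      sm <- summarize_histories(hist)
      maps[[ch]] <- sm
      rate_mats[[ch]] <- zero_small_rates(bf$Q)
      utils::write.csv(sm$mean_counts,
                       file.path(cfg$out_dir,
                                 paste0("mapping_counts_", ch, ".csv")))
      utils::write.csv(sm$node_posterior,
                       file.path(cfg$out_dir,
                                 paste0("mapping_posterior_", ch, ".csv")))
      log_stage("mapping", "%s: %d histories", ch, sm$n_histories)
    }
    report$mapping <- lapply(maps, function(m)
      list(mean_counts = m$mean_counts, n_histories = m$n_histories))
    report$rate_matrices <- rate_mats
  }

  if (isTRUE(cfg$correlations$enabled)) {
    corr <- correlation_screen(tree, mat,
                               methods = cfg$correlations$methods,
                               alpha = cfg$correlations$alpha)
    utils::write.csv(corr, file.path(cfg$out_dir, "correlations.csv"),
                     row.names = FALSE)
    report$correlations <- corr
    log_stage("correlations", "%d pairs", nrow(corr))
  }

  class(report) <- "run_report"
  json <- report_json(report)
  writeLines(json, file.path(cfg$out_dir, "report.json"))
  report
}

# Deterministic JSON body of a report (no timestamps or environment info).
report_json <- function(report) {
  clean <- unclass(report)
  clean$rate_matrices <- lapply(clean$rate_matrices, function(m)
    round(m, 10))
  jsonlite::toJSON(clean, auto_unbox = TRUE, digits = 10, dataframe = "rows",
                   na = "null", pretty = TRUE)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("nanophylo run: %d taxa, seed %d\n", x$n_taxa, x$seed))
  if (!is.null(x$signal)) { cat("Phylogenetic signal:\n"); print(x$signal) }
  if (!is.null(x$correlations)) {
    cat("Correlations:\n"); print(x$correlations)
  }
  invisible(x)
}
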