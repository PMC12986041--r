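djb2_hash <- function(s) {
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

#' Configuration for a full coupling analysis run
#'
#' @param spec A [synthetic_spec()] describing data to simulate, or `NULL`
#'   when reading from files.
#' @param expression_path,annotation_path TSV paths used when `spec` is
#'   `NULL`.
#' @param hub Primary hub gene for trajectories and attribution.
#' @param secondary_hub Comparison hub for the divergence ratio.
#' @param categories Gene category tibble.
#' @param stage_order Ordered stages (exactly three).
#' @param classifier Classifier settings, a [classifier_config()].
#' @param background_size,explained_size,path_samples Attribution sizes.
#' @param batch_correct Apply the location/scale batch correction first.
#' @param seed Global seed; per-module seeds are derived deterministically
#'   from it and the module name.
#' @return A `run_config`.
#' @export
run_config <- function(spec = synthetic_spec(),
                       expression_path = NULL,
                       annotation_path = NULL,
                       hub = "DDR2",
                       secondary_hub = "DDR1",
                       categories = panel_categories(),
                       stage_order = stage_levels(),
                       classifier = classifier_config(),
                       background_size = 100L,
                       explained_size = 100L,
                       path_samples = 200L,
                       batch_correct = TRUE,
                       seed = 1L) {
  if (length(stage_order) != 3L) abort("stage_order must have three stages")
  if (is.null(spec)) {
    if (is.null(expression_path) || is.null(annotation_path)) {
      abort("either a spec or expression/annotation paths are required")
    }
    for (p in c(expression_path, annotation_path)) {
      if (!file.exists(p)) abort(paste0("input file does not exist: ", p))
    }
  }
  structure(
    list(
      spec = spec,
      expression_path = expression_path,
      annotation_path = annotation_path,
      hub = hub, secondary_hub = secondary_hub,
      categories = categories, stage_order = stage_order,
      classifier = classifier,
      background_size = as.integer(background_size),
      explained_size = as.integer(explained_size),
      path_samples = as.integer(path_samples),
      batch_correct = isTRUE(batch_correct),
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

config_hash <- function(config) {
  payload <- config
  payload$categories <- as.data.frame(payload$categories)
  djb2_hash(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                             force = TRUE))
}

#' Run the full stage-coupling analysis
#'
#' Executes simulate (or load) -> batch correction -> stage-stratified
#' coexpression -> differential expression -> classifier training and
#' evaluation -> gradient-Shapley attribution, and assembles a consolidated
#' report with a convergence summary checking whether the same hub-target
#' pair tops the coupling-gain, fold-change and interaction rankings.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage-progress messages.
#' @return A `coupling_report`.
#' @export
run_coupling_analysis <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  stage_guard <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  # data
  data <- stage_guard("data", {
    if (!is.null(config$spec)) {
      spec <- config$spec
      spec$seed <- derive_seed(config$seed, "synthetic")
      simulate_expression(spec)
    } else {
      list(expression = read_expression_tsv(config$expression_path),
           annotation = read_annotation_tsv(config$annotation_path))
    }
  })
  genes <- data$expression$gene_id
  panel <- unique(c(config$hub, config$secondary_hub,
                    config$categories$gene))
  extra <- setdiff(setdiff(panel, genes), NA)
  if (length(extra) > 0) {
    abort(paste0("panel genes absent from expression matrix: ",
                 paste(extra, collapse = ", ")))
  }
  say("data: ", length(genes), " genes x ", nrow(data$annotation), " samples")

  # preprocess
  pre <- stage_guard("preprocess", {
    if (config$batch_correct &&
          length(unique(data$annotation$batch)) > 1L) {
      correct_batch_effects(data$expression, data$annotation)
    } else {
      list(corrected = data$expression, model = NULL)
    }
  })
  qc <- qc_cv(pre$corrected)
  say("preprocess: ", sum(qc$flagged), " gene(s) flagged by CV QC")

  # coexpression
  cortab <- stage_guard("coexpression", {
    stage_correlation_table(pre$corrected, data$annotation,
                            stages = config$stage_order)
  })
  trajectories <- coupling_trajectories(cortab, stages = config$stage_order)
  hub_summary <- hub_coupling_summary(cortab, config$hub,
                                      stages = config$stage_order)
  secondary_summary <- hub_coupling_summary(cortab, config$secondary_hub,
                                            stages = config$stage_order)
  divergence <- hub_divergence(cortab, config$hub, config$secondary_hub,
                               stages = config$stage_order)
  say("coexpression: ", nrow(cortab), " pair-stage records")

  # differential expression
  de <- stage_guard("diffexpr", {
    differential_expression(pre$corrected, data$annotation)
  })
  categories <- category_summary(de, config$categories,
                                 from = config$stage_order[1],
                                 to = config$stage_order[3])

  # classifier
  clf <- stage_guard("classifier", {
    split <- stratified_split(data$annotation,
                              config$classifier$split_fractions,
                              seed = derive_seed(config$seed, "split"))
    m <- expr_matrix(pre$corrected)
    train_ids <- split$sample_id[split$split == "train"]
    val_ids <- split$sample_id[split$split == "validation"]
    test_ids <- split$sample_id[split$split == "test"]
    std <- fit_standardizer(pre$corrected, train_ids)
    z <- expr_matrix(apply_standardizer(std, pre$corrected))
    labels <- setNames(
      factor(data$annotation$stage, levels = config$stage_order),
      data$annotation$sample_id
    )
    cfg <- config$classifier
    cfg$seed <- derive_seed(config$seed, "train")
    model <- train_classifier(t(z[, train_ids]), labels[train_ids],
                              t(z[, val_ids]), labels[val_ids], cfg)
    metrics <- evaluate_classifier(model, t(z[, test_ids]), labels[test_ids])
    list(split = split, standardizer = std, model = model,
         metrics = metrics, z = z, labels = labels,
         train_ids = train_ids, test_ids = test_ids)
  })
  say("classifier: test accuracy ", sprintf("%.4f", clf$metrics$accuracy))

  # attribution
  attrib <- stage_guard("attribution", {
    set.seed(derive_seed(config$seed, "explain"))
    bg_ids <- sample(clf$train_ids,
                     min(config$background_size, length(clf$train_ids)))
    ex_ids <- sample(clf$test_ids,
                     min(config$explained_size, length(clf$test_ids)))
    res <- gradient_shap(clf$model,
                         t(clf$z[, bg_ids, drop = FALSE]),
                         t(clf$z[, ex_ids, drop = FALSE]),
                         path_samples = config$path_samples,
                         seed = derive_seed(config$seed, "shap"))
    list(result = res,
         gene_importance = gene_importance(res, config$stage_order[3]),
         interactions = interaction_importance(res, config$hub,
                                               class = config$stage_order[3]))
  })
  say("attribution: top interaction ", attrib$interactions$pair[1])

  # convergence of the three analytical routes
  hub_traj <- trajectories |>
    dplyr::filter(.data$gene_a == config$hub | .data$gene_b == config$hub) |>
    dplyr::mutate(partner = ifelse(.data$gene_a == config$hub,
                                   .data$gene_b, .data$gene_a)) |>
    dplyr::arrange(dplyr::desc(.data$delta_overall))
  top_delta_partner <- hub_traj$partner[1]
  de_folds <- de$pairwise |>
    dplyr::filter(.data$group_a == config$stage_order[1],
                  .data$group_b == config$stage_order[3],
                  .data$gene != config$hub,
                  .data$gene != config$secondary_hub) |>
    dplyr::arrange(dplyr::desc(.data$fold_ratio_log2means))
  top_fold_gene <- de_folds$gene[1]
  top_interaction_partner <- attrib$interactions$gene[1]
  convergence <- tibble::tibble(
    criterion = c("coupling_gain", "fold_change", "interaction_importance"),
    top_gene = c(top_delta_partner, top_fold_gene, top_interaction_partner)
  )
  converged <- length(unique(convergence$top_gene)) == 1L

  structure(
    list(
      provenance = list(
        config_hash = config_hash(config),
        seed = config$seed,
        package_version = as.character(utils::packageVersion("stagecoupling")),
        timestamp = format(Sys.time(), tz = "UTC")
      ),
      annotation = data$annotation,
      qc = qc,
      batch_model = pre$model,
      correlations = cortab,
      trajectories = trajectories,
      hub_summary = hub_summary,
      secondary_hub_summary = secondary_summary,
      divergence = divergence,
      diffexpr = de,
      category_summary = categories,
      split = clf$split,
      classifier = clf$model,
      metrics = clf$metrics,
      attribution = attrib$result,
      gene_importance = attrib$gene_importance,
      interaction_importance = attrib$interactions,
      convergence = convergence,
      converged = converged
    ),
    class = "coupling_report"
  )
}

#' @export
print.coupling_report <- function(x, ...) {
  cat("<coupling_report> seed", x$provenance$seed,
      "| config", x$provenance$config_hash, "\n")
  cat("  hub mean R2:",
      paste(sprintf("%.3f", x$hub_summary$mean_r2), collapse = " -> "),
      sprintf("(%.2f-fold)", x$hub_summary$overall_fold[1]), "\n")
  cat("  test accuracy:", sprintf("%.4f", x$metrics$accuracy), "\n")
  cat("  convergence:", if (x$converged) "all three routes agree" else "routes disagree",
      "on", paste(unique(x$convergence$top_gene), collapse = ", "), "\n")
  invisible(x)
}

#' Write a coupling report to disk
#'
#' Emits the tabular components as TSVs and a JSON summary whose structure
#' follows the schema shipped at
#' `system.file("schema", "coupling_report_schema.json", package =
#' "stagecoupling")`. Every table carries the run's config hash.
#'
#' @param report A `coupling_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "coupling_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hash <- report$provenance$config_hash
  emit <- function(tbl, name) {
    tbl$config_hash <- hash
    readr::write_tsv(tbl, file.path(dir, paste0(name, ".tsv")))
  }
  emit(report$correlations, "correlations")
  emit(report$trajectories, "trajectories")
  emit(dplyr::bind_rows(report$hub_summary, report$secondary_hub_summary),
       "hub_summaries")
  emit(report$diffexpr$genes, "diffexpr_genes")
  emit(report$diffexpr$pairwise, "diffexpr_pairwise")
  emit(report$category_summary, "category_summary")
  emit(report$gene_importance, "gene_importance")
  emit(report$interaction_importance, "interaction_importance")
  emit(attribution_table(report$attribution), "shap_values")

  summary <- list(
    provenance = report$provenance,
    hub_summary = report$hub_summary,
    divergence = report$divergence,
    accuracy = report$metrics$accuracy,
    per_class = report$metrics$per_class,
    convergence = report$convergence,
    converged = report$converged
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' Validate a report summary against the shipped schema
#'
#' Checks the presence and JSON types of every required field declared in
#' the packaged schema file (a minimal structural check, not a full JSON
#' Schema engine).
#'
#' @param path Path to a `report.json` written by [write_report()].
#' @return `TRUE` invisibly, or an error naming the first violation.
#' @export
validate_report_json <- function(path) {
  schema <- jsonlite::read_json(
    system.file("schema", "coupling_report_schema.json",
                package = "stagecoupling")
  )
  doc <- jsonlite::read_json(path)
  check <- function(node, spec, where) {
    for (field in names(spec$properties)) {
      prop <- spec$properties[[field]]
      if (isTRUE(field %in% unlist(spec$required)) && is.null(node[[field]])) {
        abort(paste0("missing required field ", where, field))
      }
      val <- node[[field]]
      if (is.null(val)) next
      type <- prop$type
      ok <- switch(type,
        object = is.list(val) && !is.null(names(val)),
        array = is.list(val) || is.vector(val),
        string = is.character(val),
        number = is.numeric(val),
        boolean = is.logical(val),
        TRUE
      )
      if (!ok) {
        abort(paste0("field ", where, field, " is not of type ", type))
      }
      if (type == "object" && !is.null(prop$properties)) {
        check(val, prop, paste0(where, field, "."))
      }
    }
    invisible(TRUE)
  }
  check(doc, schema, "")
  invisible(TRUE)
}
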