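#' Pipeline configuration
#'
#' Aggregates the stage configurations and the training constants behind one
#' serializable object: preprocessing, candidate detection, feature-selection
#' settings (correlation threshold 0.9, k = 4 folds, box-constraint grid
#' 1..50, bootstrap replicates) and the aggressiveness-banding fraction.
#'
#' @param preprocess a [preprocess_config()].
#' @param detection a [detection_config()].
#' @param rho_max correlation-pruning threshold.
#' @param k_folds CV folds.
#' @param C_grid box-constraint grid.
#' @param n_boot bootstrap replicates for AUC ranking.
#' @param band_fraction indeterminate band width.
#' @param seed master seed for every random stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(preprocess = preprocess_config(),
                            detection = detection_config(),
                            rho_max = 0.9, k_folds = 4L, C_grid = 1:50,
                            n_boot = 1000L, band_fraction = 0.15,
                            seed = 1L) {
  structure(list(preprocess = preprocess, detection = detection,
                 rho_max = rho_max, k_folds = as.integer(k_folds),
                 C_grid = as.integer(C_grid), n_boot = as.integer(n_boot),
                 band_fraction = band_fraction, seed = as.integer(seed)),
            class = "pipeline_config")
}

canonical_json <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

md5_of <- function(txt) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

config_hash <- function(cfg) md5_of(canonical_json(unclass_deep(cfg)))

unclass_deep <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  if (!is.null(attributes(x)) && !is.matrix(x)) attributes(x) <-
      attributes(x)["names"]
  x
}

scorer_to_list <- function(s) {
  list(subset = as.character(s$subset),
       sv = unname(apply(s$sv, 1, as.numeric, simplify = FALSE)),
       n_features = ncol(s$sv),
       coefs = as.numeric(s$coefs), rho = s$rho, gamma = s$gamma,
       coef0 = s$coef0, degree = s$degree, sign = s$sign,
       calibration = s$calibration,
       normalization = if (is.null(s$normalization)) NULL else
         list(feature = names(s$normalization$min),
              min = as.numeric(s$normalization$min),
              max = as.numeric(s$normalization$max)),
       C = s$C, seed = s$seed)
}

list_to_scorer <- function(l) {
  sv <- do.call(rbind, lapply(l$sv, as.numeric))
  norm <- if (is.null(l$normalization)) NULL else
    structure(list(min = stats::setNames(as.numeric(l$normalization$min),
                                         l$normalization$feature),
                   max = stats::setNames(as.numeric(l$normalization$max),
                                         l$normalization$feature)),
              class = "minmax_params")
  structure(list(subset = as.character(l$subset), sv = sv,
                 coefs = as.numeric(l$coefs), rho = l$rho, gamma = l$gamma,
                 coef0 = l$coef0, degree = as.integer(l$degree),
                 sign = l$sign,
                 calibration = list(intercept = l$calibration$intercept,
                                    slope = l$calibration$slope),
                 normalization = norm, C = l$C, seed = as.integer(l$seed)),
            class = "trained_scorer")
}

model_payload <- function(model) {
  list(schema = "pcarad-model/1",
       scorer = scorer_to_list(model$scorer),
       cutoffs = list(youden = model$cutoffs$youden,
                      npv_max = model$cutoffs$npv_max,
                      band_fraction = model$cutoffs$band_fraction),
       subset_size_n = model$fs$subset_size_n,
       seed = model$seed)
}

#' Write a fitted aggressiveness model to JSON
#'
#' The file carries a versioned schema and an MD5 integrity hash of the
#' canonical payload serialization; [read_model_json()] refuses a file whose
#' payload no longer matches its hash.
#'
#' @param model an `agg_model` from [agg_fit()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "agg_model"))
  payload <- model_payload(model)
  obj <- list(payload = payload, md5 = md5_of(canonical_json(payload)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a scoring model from JSON
#'
#' @param path model file written by [write_model_json()].
#' @return List with `scorer` (`trained_scorer`), `cutoffs`
#'   ([cutoff_set()]), `seed`.
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyMatrix = FALSE, simplifyDataFrame = FALSE)
  if (is.null(obj$payload$schema) || obj$payload$schema != "pcarad-model/1")
    stop("unsupported model schema: ", obj$payload$schema)
  if (!identical(unname(md5_of(canonical_json(obj$payload))),
                 unname(obj$md5)))
    stop("model file integrity error: payload hash mismatch (tampered or ",
         "corrupted file)")
  p <- obj$payload
  list(scorer = list_to_scorer(p$scorer),
       cutoffs = cutoff_set(p$cutoffs$youden, p$cutoffs$npv_max,
                            p$cutoffs$band_fraction),
       seed = p$seed)
}

log_stage <- function(stage, msg) {
  message(sprintf("[%s] %-10s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  msg))
}

#' Extract the feature table of a cohort
#'
#' @param cases list of cases, each a list with `bundle` ([case_bundle()]),
#'   `masks` (list of truth masks) and `labels` — the shape returned by
#'   [simulate_cohort()] — or with a single `mask` and `label`.
#' @param cfg a [preprocess_config()].
#' @param verbose log progress per case.
#' @return A [feature_table()]; `patient_id` is the case index.
#' @export
cohort_features <- function(cases, cfg = preprocess_config(),
                            verbose = FALSE) {
  rows <- list(); labs <- integer(0); pid <- integer(0)
  for (ci in seq_along(cases)) {
    cs <- cases[[ci]]
    masks <- if (!is.null(cs$masks)) cs$masks else list(cs$mask)
    labels <- if (!is.null(cs$labels)) cs$labels else cs$label
    for (li in seq_along(masks)) {
      if (verbose) log_stage("extract", sprintf("case %d lesion %d", ci, li))
      rows[[length(rows) + 1L]] <-
        extract_feature_vector(cs$bundle, masks[[li]], cfg)
      labs <- c(labs, labels[li])
      pid <- c(pid, ci)
    }
  }
  feature_table(do.call(rbind, rows), labs, pid)
}

#' Train the end-to-end pipeline on a cohort
#'
#' Runs extraction (92 features per lesion from the confirmed masks),
#' normalization, AUC ranking, correlation pruning, wrapper selection, box
#' constraint grid search, final training and cutoff selection, and writes
#' the model JSON, the feature-selection JSON and a training evaluation CSV
#' to `out_dir`.
#'
#' @param cases cohort as in [cohort_features()].
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param verbose log stages to stderr.
#' @return The fitted `agg_model`, with the output paths in attribute
#'   `"paths"`.
#' @export
run_train <- function(cases, config = pipeline_config(), out_dir = tempdir(),
                      verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  chash <- config_hash(config)
  if (verbose) log_stage("train", paste("config", chash))
  tbl <- cohort_features(cases, config$preprocess, verbose = verbose)
  if (min(table(tbl$labels)) < 2L) stop("need >= 2 lesions per class")
  if (verbose) log_stage("fit", sprintf("%d lesions x %d features",
                                        nrow(tbl$x), ncol(tbl$x)))
  model <- agg_fit(tbl, rho_max = config$rho_max, k_folds = config$k_folds,
                   C_grid = config$C_grid, n_boot = config$n_boot,
                   band_fraction = config$band_fraction, seed = config$seed)
  model_path <- file.path(out_dir, "model.json")
  write_model_json(model, model_path)
  fs_path <- file.path(out_dir, "feature_selection.json")
  jsonlite::write_json(list(
    ranked_features = model$fs$ranked_features,
    removed_correlated = model$pruning$removed,
    subset_size_n = model$fs$subset_size_n,
    train_acc_curve = model$fs$train_acc_curve,
    test_acc_curve = model$fs$test_acc_curve,
    best_C = model$grid$best_C, seed = model$seed,
    config_md5 = chash), fs_path, auto_unbox = TRUE, digits = NA)
  report_path <- file.path(out_dir, "training_report.csv")
  scores <- model$train_scores
  utils::write.csv(data.frame(
    lesion = seq_along(scores), label = model$labels, raw_score = scores,
    normalized_score = scores - model$cutoffs$youden,
    level = as.character(assign_agg_score(scores, model$cutoffs)$level)),
    report_path, row.names = FALSE)
  if (verbose) log_stage("done", model_path)
  structure(model, paths = c(model = model_path, fs = fs_path,
                             report = report_path))
}

#' Score lesions with a saved model
#'
#' Deterministic scoring: the stored normalization and subset are applied,
#' never re-fitted. Feature-name mismatches raise an error listing the
#' missing columns.
#'
#' @param model_path path to a model JSON, or the list from
#'   [read_model_json()].
#' @param features data.frame or matrix of raw feature rows (canonical
#'   names), e.g. from [cohort_features()] (`$x`) or [read_feature_csv()].
#' @return data.frame with `raw_score`, `normalized_score`, `level`.
#' @export
run_score <- function(model_path, features) {
  m <- if (is.character(model_path)) read_model_json(model_path) else
    model_path
  s <- score_lesions(m$scorer, features)
  band <- assign_agg_score(s, m$cutoffs)
  data.frame(raw_score = band$raw_score,
             normalized_score = band$normalized_score,
             level = as.character(band$level))
}

#' Detect candidate lesions in a case and match the reference
#'
#' Convenience wrapper chaining [filter_voxels()], [extract_candidates()]
#' and, when a reference mask is given, [select_lesion()].
#'
#' @param bundle validated [case_bundle()].
#' @param cfg a [detection_config()].
#' @param reference optional truth/confirmed [mask3d()].
#' @return List with `kept` mask, `candidates`, and `selected` (or `NULL`).
#' @export
run_detect <- function(bundle, cfg = detection_config(), reference = NULL) {
  kept <- filter_voxels(bundle, cfg)
  cands <- extract_candidates(kept, cfg)
  sel <- if (!is.null(reference)) select_lesion(cands, reference) else NULL
  list(kept = kept, candidates = cands, selected = sel)
}
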