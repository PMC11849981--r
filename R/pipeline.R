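#' Assemble and validate a pipeline run configuration
#'
#' Collects every knob of the end-to-end analysis
#' (preprocess -> select-k -> decompose -> analyze -> associate -> subpop)
#' into a validated list. `k = "auto"` takes the k proposed by the grid
#' evaluation; `components = "auto"` takes the components significant in the
#' component-wise differential test (and therefore requires labels).
#'
#' @param input coordinate-table TSV path.
#' @param out_dir output directory for all stage outputs and the manifest.
#' @param max_missing_frac QC threshold on per-cell missingness.
#' @param norm normalization mode (`"per_cell_max"` or `"global_max"`).
#' @param k number of components, or `"auto"`.
#' @param k_grid candidate grid evaluated by the selection stage.
#' @param n_inits random restarts for the stability metric.
#' @param tolerance,max_iter NMF solver settings.
#' @param window insulation / directionality window (bins).
#' @param insulation_threshold boundary-call threshold.
#' @param peaks optional protein-peak TSV (BED-like, see
#'   [read_peak_track()]); needs `bin_size` + `region_start`.
#' @param bin_size,region_start genomic metadata for peak mapping.
#' @param gene gene whose `label_<gene>` column provides transcription
#'   labels; NULL disables the association and subpopulation stages.
#' @param components component set for the subpopulation stage, or
#'   `"auto"`.
#' @param quantile contribution quantile for group assignment.
#' @param anchor_bin,target_bins optional anchor-target distance readout.
#' @param fdr_positions,fdr_components FDR thresholds.
#' @param n_perm label permutations for the classifier null.
#' @param seed master integer seed.
#' @return a validated list of class `chromafactor_config`.
#' @export
run_config <- function(input, out_dir, max_missing_frac = 0.8,
                       norm = "per_cell_max", k = "auto", k_grid = 2:8,
                       n_inits = 4, tolerance = 1e-4, max_iter = 200,
                       window = 5, insulation_threshold = 0.05, peaks = NULL,
                       bin_size = NULL, region_start = 0, gene = NULL,
                       components = "auto", quantile = 0.5,
                       anchor_bin = NULL, target_bins = NULL,
                       fdr_positions = 0.05, fdr_components = 0.1,
                       n_perm = 10, seed = 1) {
  if (!file.exists(input)) stop_value("input file '%s' does not exist", input)
  if (!is.null(peaks) && !file.exists(peaks)) {
    stop_value("peaks file '%s' does not exist", peaks)
  }
  if (!is.null(gene)) {
    # fail at config time, before any stage runs, if the labels are absent
    hdr <- strsplit(readLines(input, n = 1), "\t")[[1]]
    if (!paste0("label_", gene) %in% hdr) {
      stop_value("input has no 'label_%s' column; component selection %s requires labels",
                 gene, if (identical(components, "auto")) "\"auto\"" else "")
    }
  }
  cfg <- list(input = input, out_dir = out_dir,
              max_missing_frac = max_missing_frac, norm = norm, k = k,
              k_grid = as.integer(k_grid), n_inits = n_inits,
              tolerance = tolerance, max_iter = max_iter,
              window = as.integer(window),
              insulation_threshold = insulation_threshold, peaks = peaks,
              bin_size = bin_size, region_start = region_start, gene = gene,
              components = components, quantile = quantile,
              anchor_bin = anchor_bin, target_bins = target_bins,
              fdr_positions = fdr_positions,
              fdr_components = fdr_components, n_perm = n_perm,
              seed = as.integer(seed))
  structure(cfg, class = "chromafactor_config")
}

#' Read a pipeline configuration from a flat key-value file
#'
#' Minimal TOML-style format: optional `[section]` headers (ignored beyond
#' grouping), `key = value` lines, `#` comments. Values are parsed as
#' numbers, `true`/`false`, comma-separated vectors, or strings.
#'
#' @param path config file.
#' @param out_dir optional override of the configured output directory.
#' @return a `chromafactor_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop_format("cannot parse config line: '%s'", lines[bad][1])
  vals <- lapply(kv, function(p) parse_config_value(p[2]))
  names(vals) <- vapply(kv, `[`, character(1), 1)
  if (!is.null(out_dir)) vals$out_dir <- out_dir
  do.call(run_config, vals)
}

parse_config_value <- function(s) {
  s <- gsub("^\"|\"$", "", trimws(s))
  if (grepl(",", s)) {
    parts <- trimws(strsplit(s, ",")[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    return(if (anyNA(nums)) parts else nums)
  }
  if (grepl("^-?[0-9.eE+-]+$", s)) {
    num <- suppressWarnings(as.numeric(s))
    if (!is.na(num)) return(num)
  }
  if (s %in% c("true", "false")) return(s == "true")
  if (identical(s, "none")) return(NULL)
  s
}

stage_hash <- function(params) digest::digest(params, algo = "sha256")

file_sha256 <- function(paths) {
  vapply(paths, function(p) digest::digest(file = p, algo = "sha256"),
         character(1))
}

# Run one cached stage: skip when an existing stage manifest carries the
# same parameter hash; timing files are excluded from output hashing so two
# identical runs produce identical manifests.
run_stage <- function(name, dir, params, fn, log) {
  h <- stage_hash(params)
  man_path <- file.path(dir, "stage.json")
  if (file.exists(man_path)) {
    prev <- jsonlite::read_json(man_path, simplifyVector = TRUE)
    if (identical(prev$params_hash, h) && !isTRUE(prev$failed)) {
      log("[%s] up to date, skipped", name)
      prev$skipped <- TRUE
      return(prev)
    }
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  log("[%s] running", name)
  res <- tryCatch(fn(), error = function(e) e)
  if (inherits(res, "error")) {
    jsonlite::write_json(list(stage = name, params_hash = h, failed = TRUE,
                              error = conditionMessage(res)),
                         man_path, auto_unbox = TRUE)
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(res)),
          class = "chromafactor_stage_error")
  }
  outs <- setdiff(list.files(dir, recursive = TRUE),
                  c("stage.json", "timings.tsv"))
  man <- list(stage = name, params_hash = h, failed = FALSE,
              outputs = outs,
              output_hashes = unname(file_sha256(file.path(dir, outs))),
              result = res)
  jsonlite::write_json(man, man_path, auto_unbox = TRUE, digits = NA)
  man$skipped <- FALSE
  man
}

#' Run the full analysis pipeline
#'
#' Executes preprocess -> select-k -> decompose -> analyze -> associate ->
#' subpop from one configuration, with per-stage caching (a stage whose
#' outputs exist under the same parameter hash is skipped) and a manifest
#' tying every output file to the inputs, parameters and seeds that
#' produced it. Stages are chained by hash, so editing any upstream
#' parameter invalidates everything downstream. The association and
#' subpopulation stages run only when a labeled gene is configured.
#'
#' @param config a `chromafactor_config` (see [run_config()]) or the path
#'   to a config file.
#' @param quiet suppress stage log lines on stderr?
#' @return the run manifest (list), invisibly written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "chromafactor_config"))
  log <- function(fmt, ...) {
    if (!quiet) message(sprintf(paste0("chromafactor %s | ", fmt),
                                format(Sys.time(), "%H:%M:%S"), ...))
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  input_hash <- file_sha256(config$input)
  stages <- list()

  # -- preprocess -------------------------------------------------------
  pp_dir <- file.path(out, "preprocess")
  pp_params <- list(input = unname(input_hash),
                    max_missing_frac = config$max_missing_frac,
                    norm = config$norm)
  stages$preprocess <- run_stage("preprocess", pp_dir, pp_params, function() {
    pre <- preprocess_coordinates(config$input, config$max_missing_frac,
                                  config$norm, bin_size = config$bin_size)
    write_tensor(pre$tensor, pp_dir)
    if (!is.null(pre$labels)) {
      lab <- as.data.frame(c(list(cell_id = pre$tensor$cell_ids), pre$labels))
      utils::write.table(lab, file.path(pp_dir, "labels.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    list(n = n_cells(pre$tensor), b = n_bins(pre$tensor),
         genes = names(pre$labels))
  }, log)
  tensor <- read_tensor(pp_dir)
  labels <- NULL
  if (!is.null(config$gene)) {
    lab_path <- file.path(pp_dir, "labels.tsv")
    if (!file.exists(lab_path)) {
      stop_value("gene '%s' requested but the input table has no label columns",
                 config$gene)
    }
    lab <- utils::read.table(lab_path, sep = "\t", header = TRUE,
                             check.names = FALSE)
    if (!config$gene %in% names(lab)) {
      stop_value("no labels for gene '%s' (available: %s)", config$gene,
                 paste(setdiff(names(lab), "cell_id"), collapse = ", "))
    }
    labels <- as.integer(lab[[config$gene]])
  }

  # -- select-k ---------------------------------------------------------
  ks_dir <- file.path(out, "select_k")
  ks_params <- list(upstream = stages$preprocess$params_hash,
                    k_grid = config$k_grid, n_inits = config$n_inits,
                    tolerance = config$tolerance, max_iter = config$max_iter,
                    gene = config$gene, seed = config$seed)
  stages$select_k <- run_stage("select_k", ks_dir, ks_params, function() {
    rep <- evaluate_k_grid(tensor, config$k_grid, n_inits = config$n_inits,
                           labels = labels, seed = config$seed,
                           tolerance = config$tolerance,
                           max_iter = config$max_iter)
    write_kselection(rep, ks_dir)
    list(proposed_k = attr(rep, "proposed_k"))
  }, log)
  k_use <- if (identical(config$k, "auto")) {
    as.integer(stages$select_k$result$proposed_k)
  } else as.integer(config$k)

  # -- decompose --------------------------------------------------------
  dc_dir <- file.path(out, "decompose")
  dc_params <- list(upstream = stages$preprocess$params_hash, k = k_use,
                    tolerance = config$tolerance, max_iter = config$max_iter,
                    seed = config$seed)
  stages$decompose <- run_stage("decompose", dc_dir, dc_params, function() {
    fit <- fit_decomposition(tensor, k_use, tolerance = config$tolerance,
                             max_iter = config$max_iter, seed = config$seed)
    write_decomposition(fit, dc_dir)
    list(k = fit$k, reconstruction_error = fit$reconstruction_error,
         variance_explained = variance_explained(tensor, fit))
  }, log)
  fit <- read_decomposition(dc_dir)

  # -- analyze ----------------------------------------------------------
  an_dir <- file.path(out, "analyze")
  an_params <- list(upstream = stages$decompose$params_hash,
                    window = config$window,
                    insulation_threshold = config$insulation_threshold,
                    peaks = if (!is.null(config$peaks))
                      unname(file_sha256(config$peaks)),
                    bin_size = config$bin_size,
                    region_start = config$region_start)
  stages$analyze <- run_stage("analyze", an_dir, an_params, function() {
    tracks <- purrr::map_dfr(seq_len(fit$k), function(j) {
      M <- fit$templates[, , j]
      ins <- insulation_profile(M, config$window,
                                source = sprintf("template_%d", j))
      di <- directionality_index(M / max(max(M), 1), config$window,
                                 source = sprintf("template_%d", j))
      tibble(template = j, bin = ins$bin, insulation = ins$value,
             directionality = di$value)
    })
    utils::write.table(tracks, file.path(an_dir, "tracks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    bounds <- purrr::map_dfr(seq_len(fit$k), function(j) {
      calls <- call_boundaries(
        insulation_profile(fit$templates[, , j], config$window,
                           source = sprintf("template_%d", j)),
        config$insulation_threshold)
      if (nrow(calls)) tibble(template = j, position = calls$position,
                              value = calls$value)
    })
    utils::write.table(bounds, file.path(an_dir, "boundaries.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res <- list(n_boundaries = nrow(bounds))
    if (!is.null(config$peaks)) {
      if (is.null(config$bin_size)) {
        stop_value("peak colocalization requires bin_size")
      }
      peaks <- read_peak_track(config$peaks, config$bin_size,
                               config$region_start, b = fit$b)
      coloc <- purrr::map_dfr(seq_len(fit$k), function(j) {
        calls <- call_boundaries(
          insulation_profile(fit$templates[, , j], config$window),
          config$insulation_threshold)
        cl <- peak_colocalization(calls, peaks, tolerance_bins = 1)
        dplyr::mutate(cl$per_protein, template = j, .before = 1)
      })
      utils::write.table(coloc, file.path(an_dir, "colocalization.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res$colocalization = "colocalization.tsv"
    }
    res
  }, log)

  # -- associate --------------------------------------------------------
  sig_components <- NULL
  if (!is.null(labels)) {
    as_dir <- file.path(out, "associate")
    as_params <- list(upstream = stages$decompose$params_hash,
                      gene = config$gene,
                      fdr_components = config$fdr_components,
                      n_perm = config$n_perm, seed = config$seed)
    stages$associate <- run_stage("associate", as_dir, as_params, function() {
      diff <- componentwise_differential(fit$weights, labels,
                                         threshold = config$fdr_components)
      utils::write.table(as_tibble(diff), file.path(as_dir, "components.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      keep <- balanced_subset(labels, seed = config$seed)
      clf <- permutation_test(t(fit$weights)[keep, , drop = FALSE],
                              labels[keep], n_perm = config$n_perm,
                              seed = config$seed)
      jsonlite::write_json(
        list(gene = config$gene, accuracy = clf$accuracy,
             feature_importances = clf$feature_importances,
             permutation = clf$permutation_null[c("mean", "sd", "p_value")],
             caveat = "cells from the same sample may not be independent"),
        file.path(as_dir, "classifier.json"), auto_unbox = TRUE, digits = NA)
      list(significant = diff$component[diff$significant],
           accuracy = clf$accuracy,
           permutation_p = clf$permutation_null$p_value)
    }, log)
    sig_components <- as.integer(stages$associate$result$significant)
  }

  # -- subpop -----------------------------------------------------------
  if (!is.null(labels)) {
    comps <- if (identical(config$components, "auto")) sig_components
             else as.integer(config$components)
    sp_dir <- file.path(out, "subpop")
    sp_params <- list(upstream = stages$associate$params_hash,
                      components = comps, quantile = config$quantile,
                      anchor_bin = config$anchor_bin,
                      target_bins = config$target_bins)
    stages$subpop <- run_stage("subpop", sp_dir, sp_params, function() {
      if (!length(comps)) {
        stop_value("no significant components to build subpopulations from")
      }
      groups <- assign_contribution_groups(fit$weights, labels, comps,
                                           quantile = config$quantile)
      utils::write.table(tidy.chromafactor_groups(groups),
                         file.path(sp_dir, "groups.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      cmp <- contrast_groups(tensor, groups, config$anchor_bin,
                             config$target_bins)
      write_matrix_tsv(cmp$median_high, file.path(sp_dir, "median_high.tsv"))
      write_matrix_tsv(cmp$median_low, file.path(sp_dir, "median_low.tsv"))
      write_matrix_tsv(cmp$difference, file.path(sp_dir, "difference.tsv"))
      res <- list(n_high = length(groups$high_indices),
                  n_low = length(groups$low_indices),
                  fraction_of_population = groups$fraction_of_population,
                  components = comps)
      if (!is.null(cmp$distances_high)) {
        res$anchor_target_high <- cmp$distances_high$group_mean
        res$anchor_target_low <- cmp$distances_low$group_mean
      }
      res
    }, log)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("chromafactor")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed, k_used = k_use,
    config = config[setdiff(names(config), "out_dir")],
    stages = lapply(stages, function(s) {
      s[intersect(names(s), c("stage", "params_hash", "outputs",
                              "output_hashes", "result", "skipped"))]
    }))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log("pipeline complete (%d stages)", length(stages))
  invisible(manifest)
}
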