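# I/O, configuration and pipeline orchestration. Counts travel as wide TSV
# (cre_id + <condition>_<time>h columns), intervals as BED (0-based
# half-open), wiring/truth/summaries as JSON.

#' Read a multi-table count set from a wide TSV
#'
#' Expects a header `cre_id` followed by `<condition>_<time>h` columns; all
#' conditions must share the same time grid.
#'
#' @param path TSV path.
#' @param vehicle vehicle condition id (must be present among the columns).
#' @param stimulus stimulus label to record.
#' @return A `multi_table_set` (without intervals; attach them via
#'   [read_bed()] if needed).
#' @export
read_counts <- function(path, vehicle, stimulus = "stimulus") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1] != "cre_id") stopf("first column must be `cre_id`")
  ids <- df$cre_id
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) stopf("duplicate CRE id(s): %s", paste(unique(dup), collapse = ", "))
  cols <- colnames(df)[-1]
  m <- regmatches(cols, regexec("^(.*)_([0-9.]+)h$", cols))
  bad <- cols[vapply(m, length, integer(1)) != 3L]
  if (length(bad) > 0) stopf("malformed column name(s): %s", paste(bad, collapse = ", "))
  cond <- vapply(m, `[`, character(1), 2L)
  tim <- as.numeric(vapply(m, `[`, character(1), 3L))
  conditions <- unique(cond)
  time_points <- sort(unique(tim))
  for (cd in conditions) {
    if (!setequal(tim[cond == cd], time_points)) {
      stopf("condition `%s` does not cover the common time grid", cd)
    }
  }
  if (!vehicle %in% conditions) stopf("vehicle `%s` not among conditions", vehicle)
  conditions <- c(vehicle, setdiff(conditions, vehicle))
  counts <- lapply(conditions, function(cd) {
    sel <- paste0(cd, "_", format_time(time_points))
    mm <- as.matrix(df[, sel, drop = FALSE])
    dimnames(mm) <- list(ids, format_time(time_points))
    mm
  })
  names(counts) <- conditions
  structure(list(stimulus = stimulus, conditions = conditions,
                 vehicle = vehicle, time_points = time_points,
                 counts = counts, cre_intervals = NULL),
            class = "multi_table_set")
}

#' Write a multi-table count set as a wide TSV
#'
#' @param mts a `multi_table_set`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(mts, path) {
  stopifnot(inherits(mts, "multi_table_set"))
  wide <- do.call(cbind, lapply(mts$conditions, function(cond) {
    m <- mts$counts[[cond]]
    colnames(m) <- paste0(cond, "_", colnames(m))
    m
  }))
  df <- data.frame(cre_id = rownames(wide), wide, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED file into a named, sorted GRanges
#'
#' BED coordinates are 0-based half-open; the returned `GRanges` follows the
#' 1-based closed convention (`start + 1`). Records with `start >= end` are
#' rejected with their line number. Intervals are sorted by (contig, start,
#' end); names come from column 4 when present, otherwise are synthesized.
#'
#' @param path BED path (BED3+; `track`/`browser`/`#` lines skipped).
#' @return Named `GRanges`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t| +")
  n <- vapply(fields, length, integer(1))
  if (any(n < 3L)) stopf("line %d: fewer than 3 BED fields", lineno[which(n < 3L)[1]])
  chrom <- vapply(fields, `[`, character(1), 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
  if (anyNA(start0) || anyNA(end)) {
    stopf("line %d: non-numeric coordinates", lineno[which(is.na(start0) | is.na(end))[1]])
  }
  bad <- start0 >= end
  if (any(bad)) stopf("line %d: start >= end", lineno[which(bad)[1]])
  nm <- if (all(n >= 4L)) vapply(fields, `[`, character(1), 4L) else sprintf("region_%d", seq_along(chrom))
  gr <- GenomicRanges::GRanges(factor(chrom, levels = sort(unique(chrom))),
                               IRanges::IRanges(start = start0 + 1, end = end))
  names(gr) <- nm
  sort(gr)
}

#' Write a GRanges as BED
#'
#' Emits BED4 (BED3 when unnamed) with 0-based half-open coordinates.
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  if (!is.null(names(gr))) df$name <- names(gr)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects every tunable of the synthetic end-to-end run: fixture sizes,
#' noise and effect parameters, per-stage seeds and the analysis thresholds.
#'
#' @param out_dir run directory (created if missing).
#' @param n_cres,n_inhibitors,n_kinases,n_programs fixture sizes.
#' @param offtarget_rate,effect_scale,dispersion,depth_sd generator
#'   parameters (see [generate_wiring()], [generate_counts()]).
#' @param fpr,fnr TF peak annotation error rates.
#' @param vehicle,stimulus condition labels.
#' @param sigma invariant-window half-width (normalization).
#' @param n_perm_mfa,alpha MFA dimension-selection parameters.
#' @param threshold perturbation-likelihood call threshold.
#' @param k proximity-graph neighbor count.
#' @param n_perm_assoc permutations for TF association.
#' @param min_var,split,grid classifier parameters; `classify_inhibitor`
#'   picks the inhibitor whose calls are predicted (default: the first).
#' @param seed master seed; per-stage seeds are derived from it.
#' @param force recompute stages whose outputs already exist.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir,
                       n_cres = 2000, n_inhibitors = 12, n_kinases = 8,
                       n_programs = 4, offtarget_rate = 0.1,
                       effect_scale = 1, dispersion = 10, depth_sd = 0.15,
                       fpr = 0.05, fnr = 0.1,
                       vehicle = "DMSO", stimulus = "LPS",
                       sigma = 1, n_perm_mfa = 500, alpha = 0.01,
                       threshold = 1, k = 3, n_perm_assoc = 2000,
                       min_var = 0.01, split = 0.7,
                       classify_inhibitor = NULL, grid = NULL,
                       seed = 1, force = FALSE) {
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' @param path file whose keys override [run_config()] defaults; `out_dir`
#'   is required.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(vals$out_dir)) stopf("config must set `out_dir`")
  do.call(run_config, vals)
}

pipeline_stages <- c("simulate", "normalize", "mfa", "score",
                     "comparative", "enrich", "classify")

stage_outputs <- function(out_dir) {
  list(
    simulate = file.path(out_dir, c("counts.tsv", "cres.bed", "wiring.json",
                                    "truth.json", "tf_peaks")),
    normalize = file.path(out_dir, "normalized.tsv"),
    mfa = file.path(out_dir, c("mfa.json", "compromise_scores.tsv")),
    score = file.path(out_dir, c("scores.tsv", "calls.tsv", "call_summary.json")),
    comparative = file.path(out_dir, c("knn_edges.tsv", "family_test.json")),
    enrich = file.path(out_dir, "tf_association.tsv"),
    classify = file.path(out_dir, c("classifier_metrics.json",
                                    "directional_importance.tsv"))
  )
}

stage_done <- function(files) all(file.exists(files))

#' Run the full synthetic end-to-end pipeline
#'
#' Executes simulate -> normalize -> mfa -> score -> comparative -> enrich ->
#' classify, writing each stage's outputs under `config$out_dir`. Stages
#' whose outputs already exist are skipped unless `config$force` is set
#' (deleting an intermediate forces recomputation of that stage only). A
#' JSON manifest with package version, seeds and per-output MD5 checksums is
#' written at the end.
#'
#' @param config a `run_config`.
#' @return The manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outs <- stage_outputs(out_dir)
  seeds <- as.list(config$seed + seq_along(pipeline_stages) * 101L)
  names(seeds) <- pipeline_stages
  run_stage <- function(name, fun) {
    files <- outs[[name]]
    if (!config$force && stage_done(files)) {
      msgf(name, "outputs present, skipping (use force = TRUE to recompute)")
      return(invisible(NULL))
    }
    msgf(name, "running")
    tryCatch(fun(), error = function(e) {
      stopf("stage `%s` failed: %s", name, conditionMessage(e))
    })
  }

  run_stage("simulate", function() {
    wiring <- generate_wiring(config$n_cres, config$n_inhibitors,
                              config$n_kinases, config$n_programs,
                              offtarget_rate = config$offtarget_rate,
                              seed = seeds$simulate)
    sim <- generate_counts(wiring, dispersion = config$dispersion,
                           effect_scale = config$effect_scale,
                           depth_sd = config$depth_sd,
                           vehicle = config$vehicle,
                           stimulus = config$stimulus,
                           seed = seeds$simulate + 1L)
    peaks <- generate_tf_peaks(wiring, fpr = config$fpr, fnr = config$fnr,
                               seed = seeds$simulate + 2L)
    write_counts(sim$tables, file.path(out_dir, "counts.tsv"))
    write_bed(wiring$cre_intervals, file.path(out_dir, "cres.bed"))
    write_wiring(wiring, file.path(out_dir, "wiring.json"))
    write_truth(sim$truth, file.path(out_dir, "truth.json"))
    pk_dir <- file.path(out_dir, "tf_peaks")
    dir.create(pk_dir, showWarnings = FALSE)
    for (tf in names(peaks)) {
      write_bed(peaks[[tf]], file.path(pk_dir, paste0(tf, ".bed")))
    }
  })

  run_stage("normalize", function() {
    mts <- read_counts(file.path(out_dir, "counts.tsv"), config$vehicle,
                       config$stimulus)
    norm <- normalize_tables(mts, sigma = config$sigma)
    write_counts(norm$tables, file.path(out_dir, "normalized.tsv"))
  })

  load_std <- function() {
    mts <- read_counts(file.path(out_dir, "normalized.tsv"), config$vehicle,
                       config$stimulus)
    standardize_tables(mts)
  }

  run_stage("mfa", function() {
    std <- load_std()
    sel <- select_dims(std, n_perm = config$n_perm_mfa, alpha = config$alpha,
                       seed = seeds$mfa)
    fit <- mfa_fit(std)
    jsonlite::write_json(
      list(selected_dims = sel$selected_dims,
           perm_pvalues = sel$perm_pvalues,
           eigenvalues = fit$eigenvalues,
           sigma1 = as.list(fit$sigma1)),
      file.path(out_dir, "mfa.json"), auto_unbox = FALSE, digits = NA)
    utils::write.table(
      data.frame(cre_id = rownames(fit$compromise_scores),
                 fit$compromise_scores, check.names = FALSE),
      file.path(out_dir, "compromise_scores.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  })

  load_scores <- function() {
    std <- load_std()
    meta <- jsonlite::read_json(file.path(out_dir, "mfa.json"),
                                simplifyVector = TRUE)
    fit <- mfa_fit(std)
    fit$selected_dims <- as.integer(meta$selected_dims)
    dist <- cre_distances(fit, config$vehicle)
    list(std = std, fit = fit,
         scores = score_perturbations(dist, std, config$vehicle))
  }

  run_stage("score", function() {
    sc <- load_scores()
    calls <- call_events(sc$scores, threshold = config$threshold)
    utils::write.table(
      data.frame(cre_id = rownames(sc$scores$score), sc$scores$score,
                 check.names = FALSE),
      file.path(out_dir, "scores.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(cre_id = rownames(calls$calls), calls$calls,
                 check.names = FALSE),
      file.path(out_dir, "calls.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    jsonlite::write_json(calls$summary, file.path(out_dir, "call_summary.json"),
                         auto_unbox = FALSE, digits = NA)
  })

  read_calls <- function() {
    df <- utils::read.delim(file.path(out_dir, "calls.tsv"),
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$cre_id
    structure(list(calls = m,
                   summary = data.frame(inhibitor = colnames(m),
                                        up = colSums(m == "up"),
                                        down = colSums(m == "down"),
                                        row.names = NULL),
                   threshold = config$threshold),
              class = "perturbation_calls")
  }

  run_stage("comparative", function() {
    df <- utils::read.delim(file.path(out_dir, "scores.tsv"),
                            check.names = FALSE, stringsAsFactors = FALSE)
    score <- as.matrix(df[, -1, drop = FALSE])
    rownames(score) <- df$cre_id
    model <- proximity_fit(t(score), k = config$k, seed = seeds$comparative)
    utils::write.table(model$knn_edges, file.path(out_dir, "knn_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    wiring <- read_wiring(file.path(out_dir, "wiring.json"))
    fam <- family_distance_test(model, wiring$family,
                                seed = seeds$comparative + 1L)
    jsonlite::write_json(
      list(observed = fam$observed, p_value = fam$p_value,
           kruskal_p = fam$kruskal_p, n_within_pairs = fam$n_within_pairs),
      file.path(out_dir, "family_test.json"), auto_unbox = TRUE, digits = NA)
  })

  run_stage("enrich", function() {
    calls <- read_calls()
    cres <- read_bed(file.path(out_dir, "cres.bed"))
    pk_dir <- file.path(out_dir, "tf_peaks")
    peak_files <- list.files(pk_dir, pattern = "\\.bed$", full.names = TRUE)
    peaks <- lapply(peak_files, read_bed)
    names(peaks) <- sub("\\.bed$", "", basename(peak_files))
    assoc <- associate_tf_effects(calls, peaks, cres,
                                  n_perm = config$n_perm_assoc,
                                  seed = seeds$enrich)
    utils::write.table(assoc, file.path(out_dir, "tf_association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  run_stage("classify", function() {
    mts <- read_counts(file.path(out_dir, "normalized.tsv"), config$vehicle,
                       config$stimulus)
    calls <- read_calls()
    cres <- rownames(calls$calls)
    pk_dir <- file.path(out_dir, "tf_peaks")
    peak_files <- list.files(pk_dir, pattern = "\\.bed$", full.names = TRUE)
    cre_gr <- read_bed(file.path(out_dir, "cres.bed"))[cres]
    tf_ind <- vapply(peak_files, function(f) {
      as.numeric(interval_overlap(cre_gr, read_bed(f))$indicator)
    }, numeric(length(cres)))
    colnames(tf_ind) <- sub("\\.bed$", "", basename(peak_files))
    rownames(tf_ind) <- cres
    # feature tables: vehicle kinetics (quantitative) + TF peak presence
    tabs <- list(kinetics = mts$counts[[config$vehicle]][cres, , drop = FALSE],
                 tf_peaks = tf_ind)
    fs <- build_feature_space(tabs, min_var = config$min_var,
                              categorical = "tf_peaks")
    inh <- config$classify_inhibitor %||% colnames(calls$calls)[1]
    labels <- calls$calls[rownames(fs$features), inh]
    ev <- train_eval(fs$features, labels, split = config$split,
                     seed = seeds$classify, grid = config$grid)
    jsonlite::write_json(
      list(inhibitor = inh, metrics = ev$metrics,
           best_params = as.list(ev$best_params)),
      file.path(out_dir, "classifier_metrics.json"),
      auto_unbox = TRUE, digits = NA)
    attr_ <- shap_attributions(ev, fs$features[ev$test_idx, , drop = FALSE])
    di <- directional_importance(attr_, fs$features[ev$test_idx, , drop = FALSE])
    utils::write.table(
      data.frame(feature = rownames(di), di, check.names = FALSE),
      file.path(out_dir, "directional_importance.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  })

  files <- sort(unlist(lapply(outs, function(f) {
    f <- f[file.exists(f)]
    unlist(lapply(f, function(x) if (dir.exists(x)) list.files(x, full.names = TRUE) else x))
  }), use.names = FALSE))
  manifest <- list(
    package = "epiperturb",
    version = as.character(utils::packageVersion("epiperturb")),
    stages = pipeline_stages,
    seeds = seeds,
    config = config[setdiff(names(config), c("grid"))],
    checksums = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

write_wiring <- function(wiring, path) {
  x <- wiring
  x$family <- as.list(wiring$family)  # keep inhibitor names as JSON keys
  x$cre_intervals <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(wiring$cre_intervals)),
    start = GenomicRanges::start(wiring$cre_intervals) - 1L,
    end = GenomicRanges::end(wiring$cre_intervals),
    name = names(wiring$cre_intervals))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_wiring <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  iv <- x$cre_intervals
  gr <- GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start + 1, iv$end))
  names(gr) <- iv$name
  x$cre_intervals <- gr
  x$family <- unlist(x$family)
  structure(x, class = "cki_wiring")
}

write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(effect = truth$effect,
         cluster_of = as.list(truth$cluster_of),
         params = truth$params),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
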