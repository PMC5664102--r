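# Pipeline orchestration: configuration, per-pair execution of
# searching -> testing -> screening, per-stage reports and the cross-pair
# summary.

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

.log <- function(config, fmt, ...) {
  if (!identical(config$log_level, "quiet")) {
    message(sprintf(fmt, ...))
  }
}

#' Pipeline run configuration
#'
#' @param network_path path to a STRING-format protein links file (or
#'   canonical edge-list TSV), see [parse_string_links()].
#' @param gene_set_paths named character vector, label -> seed-set file
#'   path ([read_gene_set()] format).
#' @param pairs list of length-2 character vectors of labels; `NULL`
#'   (default) runs all unordered label pairs.
#' @param permutation a [permutation_config()]. Pair `k` of a run uses
#'   root seed `seed + k - 1` so pairs have independent replicate streams
#'   while the whole run remains reproducible from one seed.
#' @param thresholds a [screening_thresholds()].
#' @param min_score optional score filter applied while parsing the
#'   network.
#' @param all_paths logical; count every co-optimal path per seed pair
#'   instead of the single tie-broken path (default `FALSE`).
#' @param output_dir directory for reports; created if missing.
#' @param log_level `"info"` (default) or `"quiet"`.
#' @return a `run_config` list.
#' @export
run_config <- function(network_path, gene_set_paths, pairs = NULL,
                       permutation = permutation_config(),
                       thresholds = screening_thresholds(),
                       min_score = NULL, all_paths = FALSE,
                       output_dir = ".", log_level = "info") {
  stopifnot(is.character(gene_set_paths), !is.null(names(gene_set_paths)),
            all(nzchar(names(gene_set_paths))))
  labels <- names(gene_set_paths)
  if (is.null(pairs)) {
    if (length(labels) < 2L) stop("need at least two gene sets to form a pair")
    cmb <- utils::combn(labels, 2L)
    pairs <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }
  for (p in pairs) {
    if (length(p) != 2L || !all(p %in% labels)) {
      stop("each pair must reference two declared set labels; got: ",
           paste(p, collapse = ","))
    }
  }
  structure(
    list(network_path = network_path, gene_set_paths = gene_set_paths,
         pairs = pairs, permutation = permutation, thresholds = thresholds,
         min_score = min_score, all_paths = all_paths,
         output_dir = output_dir, log_level = log_level),
    class = "run_config"
  )
}

.pair_dir_name <- function(pair) paste0(pair[1L], "--", pair[2L])

#' Run searching, testing and screening for one pair of seed sets
#'
#' Executes the three procedures in order and (when `output_dir` is given)
#' writes the three per-stage TSVs: `shortest_path_genes.tsv` (gene,
#' betweenness), `candidates.tsv` (gene, betweenness, exceed_count, fdr)
#' and `inferred.tsv` (full candidate records restricted to inferred
#' genes).
#'
#' @param network an [interaction_network].
#' @param setC,setCprime mapped [map_gene_set()] objects.
#' @param permutation a [permutation_config()].
#' @param thresholds a [screening_thresholds()].
#' @param all_paths forwarded to [search_all_pairs()].
#' @param output_dir directory for the per-stage TSVs, or `NULL` to skip
#'   writing.
#' @param log_level `"info"` or `"quiet"`.
#' @return a list with `search` ([search_all_pairs()] result), `fdr`
#'   ([permutation_fdr()] result), `records` (screened candidate
#'   data.frame) and `stage_counts` (one-row data.frame: `pair_label`,
#'   `n_shortest_path_genes`, `n_candidates`, `n_inferred`).
#' @export
run_pair <- function(network, setC, setCprime,
                     permutation = permutation_config(),
                     thresholds = screening_thresholds(),
                     all_paths = FALSE, output_dir = NULL,
                     log_level = "info") {
  cfg <- list(log_level = log_level)
  pair_label <- paste0(setC$label, "--", setCprime$label)
  t0 <- proc.time()[["elapsed"]]
  observed <- search_all_pairs(network, setC, setCprime, all_paths = all_paths)
  .log(cfg, "[%s] searching: %d/%d pairs connected (%d skipped), %d shortest-path genes (%.1fs)",
       pair_label, observed$n_pairs_connected, observed$n_pairs_attempted,
       observed$n_pairs_skipped, length(observed$betweenness),
       proc.time()[["elapsed"]] - t0)

  t0 <- proc.time()[["elapsed"]]
  fdr <- permutation_fdr(network, setC, setCprime, observed,
                         config = permutation, all_paths = all_paths)
  records <- candidate_records(network, setC, setCprime, observed, fdr,
                               thresholds = thresholds)
  .log(cfg, "[%s] testing: %d replicates, %d candidates at FDR < %g (%.1fs)",
       pair_label, permutation$n_replicates, nrow(records),
       thresholds$fdr_max, proc.time()[["elapsed"]] - t0)

  inferred <- records[records$inferred, , drop = FALSE]
  .log(cfg, "[%s] screening: %d inferred (BR > %g, Min-Max >= %d)",
       pair_label, nrow(inferred), thresholds$br_min, thresholds$minmax_min)

  stage_counts <- data.frame(
    pair_label = pair_label,
    n_shortest_path_genes = length(observed$betweenness),
    n_candidates = nrow(records),
    n_inferred = nrow(inferred),
    stringsAsFactors = FALSE
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_search_result(observed, file.path(output_dir, "shortest_path_genes.tsv"))
    write_fdr_result(observed, fdr, file.path(output_dir, "candidates.tsv"))
    .write_tsv(inferred, file.path(output_dir, "inferred.tsv"))
  }
  list(search = observed, fdr = fdr, records = records,
       stage_counts = stage_counts)
}

#' Summarize completed pair runs
#'
#' Combines per-pair results into the cross-pair membership summary, the
#' stage-count table and per-pair filtered fractions: the percentage of
#' shortest-path genes removed by the testing procedure and the
#' percentage surviving all the way through screening.
#'
#' @param per_pair named list (pair label -> [run_pair()] result), or a
#'   list with elements `stage_counts` (data.frame) and `inferred` (named
#'   list pair label -> gene vector) for summarizing externally produced
#'   stage outputs.
#' @return a list with `summary` ([cross_pair_summary]), `stage_counts`
#'   (data.frame with added `testing_removal_pct` and
#'   `screening_survival_pct` columns).
#' @export
summarize_pairs <- function(per_pair) {
  if (!is.null(per_pair$stage_counts) && !is.null(per_pair$inferred)) {
    counts <- per_pair$stage_counts
    inferred_sets <- per_pair$inferred
  } else {
    stopifnot(length(per_pair) >= 1L, !is.null(names(per_pair)))
    counts <- do.call(rbind, lapply(per_pair, `[[`, "stage_counts"))
    rownames(counts) <- NULL
    inferred_sets <- lapply(per_pair, function(r) {
      r$records$gene[r$records$inferred]
    })
  }
  sp <- counts$n_shortest_path_genes
  counts$testing_removal_pct <-
    ifelse(sp > 0, 100 * (sp - counts$n_candidates) / sp, NA_real_)
  counts$screening_survival_pct <-
    ifelse(sp > 0, 100 * counts$n_inferred / sp, NA_real_)
  list(summary = cross_pair_summary(inferred_sets), stage_counts = counts)
}

#' Run the full pipeline over all configured pairs
#'
#' Parses the network, maps every seed set, executes
#' searching -> testing -> screening for each configured pair (a failing
#' pair is reported and skipped; the remaining pairs continue), and writes
#' per-pair TSVs plus the global reports `stage_counts.tsv`,
#' `cross_pair_summary.tsv` and a machine-readable `manifest.json`
#' (inputs, seeds, thresholds, mapped/dropped counts) into
#' `config$output_dir`.
#'
#' @param config a [run_config()].
#' @param network optional pre-built [interaction_network]; skips parsing
#'   `config$network_path`.
#' @return a list with `network`, `gene_sets`, `pairs` (named list of
#'   [run_pair()] results), `stage_counts`, `summary` and `errors` (named
#'   character vector of failed pairs).
#' @export
run_pipeline <- function(config, network = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(network)) {
    .log(config, "parsing network from %s", config$network_path)
    network <- parse_string_links(config$network_path, config$min_score)
  }
  .log(config, "network: %d nodes, %d edges", n_nodes(network), n_edges(network))

  gene_sets <- list()
  set_errors <- character(0)
  for (label in names(config$gene_set_paths)) {
    gs <- tryCatch(
      withCallingHandlers(
        map_gene_set(read_gene_set(config$gene_set_paths[[label]]),
                     label, network),
        warning = function(w) {
          .log(config, "%s", conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      ),
      error = function(e) e
    )
    if (inherits(gs, "error")) {
      set_errors[label] <- conditionMessage(gs)
      .log(config, "gene set '%s' FAILED: %s", label, conditionMessage(gs))
    } else {
      gene_sets[[label]] <- gs
    }
  }

  results <- list()
  errors <- character(0)
  for (k in seq_along(config$pairs)) {
    pair <- config$pairs[[k]]
    name <- .pair_dir_name(pair)
    bad <- pair[pair %in% names(set_errors)]
    if (length(bad)) {
      errors[name] <- sprintf("gene set '%s' unavailable: %s",
                              bad[1L], set_errors[[bad[1L]]])
      .log(config, "[%s] FAILED: %s", name, errors[name])
      next
    }
    perm <- config$permutation
    perm$seed <- perm$seed + k - 1L  # independent replicate stream per pair
    out <- tryCatch(
      run_pair(network, gene_sets[[pair[1L]]], gene_sets[[pair[2L]]],
               permutation = perm, thresholds = config$thresholds,
               all_paths = config$all_paths,
               output_dir = file.path(config$output_dir, name),
               log_level = config$log_level),
      error = function(e) e
    )
    if (inherits(out, "error")) {
      errors[name] <- conditionMessage(out)
      .log(config, "[%s] FAILED: %s", name, conditionMessage(out))
    } else {
      results[[name]] <- out
    }
  }

  summary <- NULL
  stage_counts <- NULL
  if (length(results)) {
    sm <- summarize_pairs(results)
    summary <- sm$summary
    stage_counts <- sm$stage_counts
    .write_tsv(stage_counts, file.path(config$output_dir, "stage_counts.tsv"))
    .write_tsv(summary$table, file.path(config$output_dir, "cross_pair_summary.tsv"))
  }

  manifest <- list(
    network_path = config$network_path,
    min_score = config$min_score,
    gene_sets = lapply(gene_sets, function(gs) list(
      label = gs$label, n_requested = length(gs$requested),
      n_mapped = length(gs$mapped), dropped = gs$dropped)),
    pairs = vapply(config$pairs, .pair_dir_name, character(1)),
    n_replicates = config$permutation$n_replicates,
    seed = config$permutation$seed,
    fdr_threshold = config$thresholds$fdr_max,
    br_threshold = config$thresholds$br_min,
    minmax_threshold = config$thresholds$minmax_min,
    all_paths = config$all_paths,
    package_version = as.character(utils::packageVersion("ppibridge")),
    errors = as.list(errors)
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  list(network = network, gene_sets = gene_sets, pairs = results,
       stage_counts = stage_counts, summary = summary, errors = errors)
}
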