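#' @name cli_pipeline
#' @title Battery orchestration: the full multi-strategy assessment
#' @description
#' Drives the complete design: equal-weights parsimony with all-unordered
#' and ordered character settings, implied weighting at K = 3, 6, 9 under
#' both orderings, single-outgroup reruns, and a (scaled-down) Bayesian
#' tip-dating run; then evaluates the clade-definition registry on every
#' resulting consensus and emits the consolidated weak-spot report.
NULL

#' Build the default run manifest
#'
#' The default manifest reproduces the twelve-run design: 2 equal-weights
#' runs (unordered/ordered), 6 implied-weighting runs (K = 3, 6, 9 x
#' unordered/ordered), 3 single-outgroup runs, and 1 Bayesian tip-dating
#' run.
#'
#' @param matrix_path TNT matrix file
#' @param ordered_path file of 1-based ordered character indices
#' @param ages_path TSV tip-age table (needed by the Bayesian run)
#' @param defs_path JSON definition registry
#' @param proxies_path optional TSV proxy map
#' @param root_taxon designated outgroup/root (default "Adriosaurus suessi"
#'   style label must match the matrix)
#' @param outgroups the three outgroup-grade taxa for single-outgroup runs
#' @param seed master seed
#' @param n_replicates search replicates per parsimony run
#' @param generations,sample_interval Bayesian run length controls
#' @param bootstrap_reps bootstrap replicates for the equal-weights runs
#'   (0 disables)
#' @param bremer compute decay indices for the equal-weights runs
#' @return a \code{run_manifest}
#' @export
default_manifest <- function(matrix_path, ordered_path = NULL, ages_path = NULL,
                             defs_path = NULL, proxies_path = NULL,
                             root_taxon, outgroups = NULL, seed = 1L,
                             n_replicates = 25L, generations = 200000L,
                             sample_interval = 500L, bootstrap_reps = 0L,
                             bremer = FALSE) {
  runs <- list(
    list(id = "EQ_UNORD", strategy = "parsimony", ordered = FALSE, weighting = "equal"),
    list(id = "EQ_ORD", strategy = "parsimony", ordered = TRUE, weighting = "equal")
  )
  for (K in c(3, 6, 9)) for (ord in c(FALSE, TRUE)) {
    runs[[length(runs) + 1L]] <- list(id = sprintf("IW%d_%s", K, if (ord) "ORD" else "UNORD"),
                                      strategy = "parsimony", ordered = ord,
                                      weighting = "implied", K = K)
  }
  if (!is.null(outgroups)) for (og in outgroups) {
    runs[[length(runs) + 1L]] <- list(id = paste0("OUT_", gsub("\\W+", "_", og)),
                                      strategy = "single_outgroup", keep = og,
                                      ordered = FALSE, weighting = "equal")
  }
  if (!is.null(ages_path)) {
    runs[[length(runs) + 1L]] <- list(id = "BAYES", strategy = "bayes")
  }
  ids <- vapply(runs, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("run ids must be unique")
  structure(list(matrix_path = matrix_path, ordered_path = ordered_path,
                 ages_path = ages_path, defs_path = defs_path,
                 proxies_path = proxies_path, root_taxon = root_taxon,
                 outgroups = outgroups, seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates),
                 generations = as.integer(generations),
                 sample_interval = as.integer(sample_interval),
                 bootstrap_reps = as.integer(bootstrap_reps), bremer = bremer,
                 runs = runs), class = "run_manifest")
}

#' Single-outgroup rerun
#'
#' Drops the other designated outgroup-grade taxa from the active set,
#' searches, and roots the results on the kept taxon.
#'
#' @param m a \code{\link{character_matrix}}
#' @param settings a \code{\link{parsimony_settings}}
#' @param keep_taxon the outgroup taxon retained
#' @param outgroups all outgroup-grade taxa (the others are removed)
#' @param config a \code{\link{search_config}}
#' @return a \code{tree_set} rooted on \code{keep_taxon}
#' @export
single_outgroup_run <- function(m, settings, keep_taxon, outgroups,
                                config = search_config()) {
  if (!(keep_taxon %in% outgroups)) stop("keep_taxon must be one of the outgroups")
  if (!(keep_taxon %in% m$taxa)) stop("unknown taxon: ", keep_taxon)
  drop <- setdiff(outgroups, keep_taxon)
  m2 <- subset_taxa(m, setdiff(m$taxa, drop))
  config$root <- keep_taxon
  search_battery(m2, settings, config)
}

#' Run the full battery and consolidate the weak-spot report
#'
#' Executes every run in the manifest, writes per-run artifacts under
#' \code{out_dir} (Newick consensus trees, score/support TSVs, Bayesian
#' trace and summaries) and a consolidated weak-spot TSV. A failing run is
#' recorded and the battery continues.
#'
#' @param manifest a \code{run_manifest}
#' @param out_dir output directory (created)
#' @return invisibly, a list: \code{report} (a \code{weak_spot_report} or
#'   NULL when no registry was given), \code{runs} (per-run results),
#'   \code{failures} (named list of error messages; non-empty means a
#'   degraded battery)
#' @export
run_battery <- function(manifest, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  m <- read_tnt_matrix(manifest$matrix_path)
  ordered_idx <- if (!is.null(manifest$ordered_path))
    read_character_indices(manifest$ordered_path) else integer(0)
  defs <- if (!is.null(manifest$defs_path)) read_definitions(manifest$defs_path) else NULL
  proxies <- if (!is.null(manifest$proxies_path)) read_proxy_map(manifest$proxies_path) else NULL
  root <- manifest$root_taxon
  results <- list()
  failures <- list()
  logf <- file.path(out_dir, "battery.log")
  cat("battery started", format(Sys.time()), "\n", file = logf)
  for (run in manifest$runs) {
    rid <- run$id
    res <- tryCatch(execute_run(run, m, ordered_idx, manifest, out_dir),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[rid]] <- conditionMessage(res)
      cat("RUN", rid, "FAILED:", conditionMessage(res), "\n", file = logf, append = TRUE)
    } else {
      results[[rid]] <- res
      cat("RUN", rid, "ok; score:", res$score, "\n", file = logf, append = TRUE)
    }
  }
  report <- NULL
  if (!is.null(defs) && length(results)) {
    runs_for_report <- lapply(results, function(r)
      list(consensus = r$consensus, trees = r$trees))
    report <- weak_spot_report(defs, runs_for_report, proxies)
    write_weak_spot_tsv(report, file.path(out_dir, "weakspots.tsv"))
    jsonlite::write_json(list(status = as.data.frame(report$status),
                              summary = as.list(report$summary)),
                         file.path(out_dir, "weakspots.json"), auto_unbox = TRUE)
  }
  invisible(list(report = report, runs = results, failures = failures))
}

execute_run <- function(run, m, ordered_idx, manifest, out_dir) {
  rdir <- file.path(out_dir, run$id)
  dir.create(rdir, showWarnings = FALSE)
  root <- manifest$root_taxon
  if (identical(run$strategy, "bayes")) {
    ages_df <- read_tip_ages(manifest$ages_path)
    ages <- stats::setNames(ages_df$mean, ages_df$taxon)
    cfg <- mcmc_config(generations = manifest$generations,
                       sample_interval = manifest$sample_interval,
                       seed = manifest$seed)
    ps <- tip_dating_mcmc(m, ages, cfg)
    utils::write.table(ps$params, file.path(rdir, "trace.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pb <- discard_burnin(ps)
    mc <- mcct(pb)
    writeLines(write_newick(mc$phylo), file.path(rdir, "mcct.nwk"))
    hc <- half_compact_consensus(pb)
    writeLines(ape::write.tree(hc), file.path(rdir, "half_compact.nwk"))
    sh <- sampled_ancestor_histogram(pb)
    utils::write.table(data.frame(n_sa = names(sh$counts), prop = as.numeric(sh$counts)),
                       file.path(rdir, "sa_histogram.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    trees <- lapply(pb$trees, dated_to_phylo)
    return(list(kind = "bayes", consensus = mc$phylo, trees = trees,
                score = mc$score, posterior = pb, sa = sh))
  }
  settings <- parsimony_settings(
    ordered = if (isTRUE(run$ordered)) ordered_idx else integer(0),
    weighting = if (identical(run$weighting, "implied")) "implied" else "equal",
    K = if (!is.null(run$K)) run$K else 3)
  config <- search_config(n_replicates = manifest$n_replicates,
                          seed = manifest$seed, root = root)
  ts <- if (identical(run$strategy, "single_outgroup")) {
    single_outgroup_run(m, settings, run$keep, manifest$outgroups, config)
  } else {
    search_battery(m, settings, config)
  }
  cons_root <- if (identical(run$strategy, "single_outgroup")) run$keep else root
  cons <- strict_consensus(ts, cons_root)
  writeLines(ape::write.tree(cons), file.path(rdir, "strict_consensus.nwk"))
  ape::write.nexus(ts$trees, file = file.path(rdir, "mpts.nex"))
  bk <- tree_length(ts$trees[[1L]], if (identical(run$strategy, "single_outgroup"))
    subset_taxa(m, ts$trees[[1L]]$tip.label) else m, settings)
  m_used <- if (identical(run$strategy, "single_outgroup"))
    subset_taxa(m, ts$trees[[1L]]$tip.label) else m
  utils::write.table(
    data.frame(best_score = ts$best_score, n_trees = length(ts$trees),
               n_collapsed_topologies = collapsed_topology_count(ts, m_used, settings),
               total_length = bk$total_length,
               iw_distortion = bk$iw_distortion),
    file.path(rdir, "scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  out <- list(kind = "parsimony", consensus = cons, trees = ts$trees,
              score = ts$best_score, tree_set = ts, breakdown = bk)
  if (identical(run$weighting, "equal") && !identical(run$strategy, "single_outgroup")) {
    if (isTRUE(manifest$bremer)) {
      br <- bremer_support(m, settings, ts, config = search_config(
        n_replicates = 5L, seed = manifest$seed, root = root), root = cons_root)
      utils::write.table(br, file.path(rdir, "bremer.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out$bremer <- br
    }
    if (manifest$bootstrap_reps > 0L) {
      bs <- bootstrap_support(m, settings,
                              config = search_config(n_replicates = 3L, seed = manifest$seed,
                                                     root = root),
                              n_reps = manifest$bootstrap_reps,
                              seed = manifest$seed, root = cons_root)
      utils::write.table(bs, file.path(rdir, "bootstrap.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out$bootstrap <- bs
    }
  }
  out
}
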