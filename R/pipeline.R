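#' Run configuration for the end-to-end pipeline
#'
#' Collects every tunable of the analysis in one validated object. With
#' `simulate = TRUE` (the default demo mode) all inputs are generated by the
#' synthetic-data module; otherwise `profiles_path` (GCT + column-metadata
#' TSV) and `cohort_expr_path`/`cohort_meta_path` must point to real files.
#'
#' @param simulate Generate synthetic inputs instead of reading files.
#' @param profiles_path,profiles_meta_path GCT z-score matrix and its
#'   column-metadata TSV (`col_id`, `cell_line`, `timepoint`); ignored when
#'   simulating.
#' @param cohort_expr_path,cohort_meta_path Cohort expression and metadata
#'   paths; ignored when simulating.
#' @param tau,z_min,timepoint Consensus-signature parameters.
#' @param top_k Genes kept for clustering/scoring; `NULL` keeps all.
#' @param disease_method `"median"` (disease signatures) or `"mean"`
#'   (subgroup markers).
#' @param cluster_k,cluster_distance,cluster_linkage Clustering knobs.
#' @param survival_genes Gene set for the Q4-vs-Q1 survival stage; `NULL`
#'   uses the drug signature's genes.
#' @param expression_scale `"log2"` or `"linear"`; `eps` is the linear-scale
#'   pseudocount.
#' @param n_perm Permutations for the discordance p-value.
#' @param seed Master seed; stage seeds are derived from it by stage name.
#' @param sim Optional list overriding simulation specs:
#'   `perturbation` ([perturbation_sim_spec()]) and `cohort`
#'   ([cohort_sim_spec()]) fields.
#' @return A `run_config` list.
#' @export
run_config <- function(simulate = TRUE,
                       profiles_path = NULL, profiles_meta_path = NULL,
                       cohort_expr_path = NULL, cohort_meta_path = NULL,
                       tau = 0.30, z_min = 2.0, timepoint = "24 h",
                       top_k = NULL, disease_method = c("median", "mean"),
                       cluster_k = 2, cluster_distance = "euclidean",
                       cluster_linkage = "complete",
                       survival_genes = NULL,
                       expression_scale = c("log2", "linear"), eps = 1,
                       n_perm = 1000, seed = 1, sim = list()) {
  disease_method <- match.arg(disease_method)
  expression_scale <- match.arg(expression_scale)
  if (tau <= 0 || tau > 1) abort_validation("tau must be in (0, 1]")
  if (z_min <= 0) abort_validation("z_min must be > 0")
  if (!is.null(top_k) && !is_count(top_k)) abort_validation("top_k must be a count or NULL")
  if (!is_count(cluster_k)) abort_validation("cluster_k must be a count")
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from a JSON or YAML file
#'
#' @param path Config file; `.json` parsed with jsonlite, `.yml`/`.yaml`
#'   with the yaml package.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort_validation("yaml package required for YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(run_config, raw)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input acquisition (simulation or file reads),
#' consensus-signature construction, disease-signature construction,
#' discordance scoring, patient clustering on the signature genes, and the
#' Q4-vs-Q1 survival association. All tables are written as TSV with fixed
#' column order into `out_dir`, plus a `manifest.json` recording the config,
#' its MD5 hash, the seed and package version. Reruns with the same config
#' are bit-identical. A stage failure aborts with the stage name; outputs of
#' completed stages are left in place.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with the in-memory stage results and
#'   `out_dir`.
#' @export
run_full <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "inputs"
  result <- tryCatch({
    if (isTRUE(config$simulate)) {
      psim <- config$sim$perturbation %||%
        perturbation_sim_spec(seed = stage_seed(config$seed, "perturbation"))
      pert <- simulate_perturbation_set(psim)
      profiles <- pert$profiles
    } else {
      profiles <- read_gct(config$profiles_path)
      cmeta <- utils::read.delim(config$profiles_meta_path, stringsAsFactors = FALSE)
      profiles <- matrix_table(profiles$values, row_meta = profiles$row_meta,
                               col_meta = cmeta[match(col_ids(profiles), cmeta$col_id), ,
                                                drop = FALSE])
    }

    stage <- "signature"
    by_line <- collapse_cell_lines(profiles, config$timepoint)
    sig <- build_consensus(by_line, tau = config$tau, z_min = config$z_min,
                           timepoint = config$timepoint)
    if (!is.null(config$top_k)) sig <- top_genes(sig, config$top_k)
    write_signature(sig, file.path(out_dir, "consensus_signature.tsv"),
                    file.path(out_dir, "consensus_signature_params.json"))

    stage <- "cohort"
    if (isTRUE(config$simulate)) {
      csim <- config$sim$cohort %||% cohort_sim_spec(
        n_genes = nrow(profiles$values),
        discordant_subgroup = "G3",
        survival_geneset = signature_genes(sig),
        survival_hazard_ratio = 3, n_patients = 200,
        seed = stage_seed(config$seed, "cohort"))
      cosim <- simulate_cohort(csim, drug_signature = sig)
      cohort <- cosim$cohort
    } else {
      cohort <- read_cohort(config$cohort_expr_path, config$cohort_meta_path,
                            scale = config$expression_scale)
    }

    stage <- "disease-signature"
    dsig <- if (config$disease_method == "median") {
      subgroup_log2fc(cohort, eps = config$eps)
    } else {
      subgroup_markers(cohort, eps = config$eps)
    }
    write_subgroup_signature(dsig, out_dir)

    stage <- "score"
    scores <- discordance_score(sig, dsig, n_perm = config$n_perm,
                                seed = stage_seed(config$seed, "score"))
    write_tsv(scores, file.path(out_dir, "response_scores.tsv"))

    stage <- "cluster"
    clus <- cluster_patients(cohort, signature_genes(sig), k = config$cluster_k,
                             distance = config$cluster_distance,
                             linkage = config$cluster_linkage)
    write_tsv(data.frame(patient = names(clus$labels), cluster = clus$labels,
                         subgroup = cohort$subgroup[names(clus$labels)]),
              file.path(out_dir, "cluster_labels.tsv"))
    jsonlite::write_json(
      list(merge = unclass(clus$tree$merge), height = clus$tree$height,
           labels = clus$tree$labels, distance = clus$distance,
           linkage = clus$linkage),
      file.path(out_dir, "cluster_tree.json"), auto_unbox = TRUE, digits = NA)

    stage <- "survival"
    surv_res <- NULL
    if (!is.null(cohort$survival)) {
      gs <- config$survival_genes %||% signature_genes(sig)
      surv_res <- q4_vs_q1_survival(cohort, gs)
      write_tsv(data.frame(patient = names(surv_res$score),
                           score = surv_res$score,
                           quartile = surv_res$quartile),
                file.path(out_dir, "survival_quartiles.tsv"))
      jsonlite::write_json(
        list(logrank_chi2 = surv_res$logrank_chi2, logrank_p = surv_res$logrank_p,
             n_q1 = surv_res$n_q1, n_q4 = surv_res$n_q4),
        file.path(out_dir, "survival_logrank.json"), auto_unbox = TRUE, digits = NA)
    }

    stage <- "manifest"
    cfg_json <- file.path(out_dir, "config.json")
    cfg_serializable <- config[!vapply(config, is.function, TRUE)]
    class(cfg_serializable) <- NULL
    jsonlite::write_json(cfg_serializable, cfg_json, auto_unbox = TRUE,
                         digits = NA, null = "null", force = TRUE)
    jsonlite::write_json(
      list(config_md5 = unname(tools::md5sum(cfg_json)),
           seed = config$seed,
           package = "sigdiscord",
           version = as.character(utils::packageVersion("sigdiscord"))),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE)

    list(signature = sig, disease_signature = dsig, scores = scores,
         clusters = clus, survival = surv_res, out_dir = out_dir)
  }, sigdiscord_error = function(e) {
    abort("pipeline stage \"%s\" failed: %s", "sigdiscord_stage_error",
          stage, conditionMessage(e))
  }, error = function(e) {
    if (inherits(e, "sigdiscord_stage_error")) stop(e)
    abort("pipeline stage \"%s\" failed: %s", "sigdiscord_stage_error",
          stage, conditionMessage(e))
  })
  invisible(result)
}
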