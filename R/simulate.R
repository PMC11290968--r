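#' Simulation specification for a multi-cell-line perturbation profile set
#'
#' Describes a synthetic stand-in for level-5 LINCS-style differential
#' z-score matrices: `n_genes` genes measured in `n_cell_lines` cell lines at
#' one or more timepoints. A planted set of `n_up` up- and `n_down`
#' downregulated genes responds (mean |z| = `planted_effect`) in a random
#' `responder_fraction` subset of cell lines at the 24-hour timepoint;
#' everything else is Gaussian noise with sd `noise_sd`.
#'
#' @param n_genes,n_cell_lines Counts.
#' @param n_up,n_down Numbers of planted up/down consensus genes
#'   (`n_up + n_down <= n_genes`).
#' @param planted_effect Mean |z| of a planted gene in responding lines.
#' @param responder_fraction Fraction of cell lines in which each planted gene
#'   fires, in (0, 1].
#' @param noise_sd Noise standard deviation in z-score units (> 0).
#' @param timepoints Character vector of timepoint labels; must contain
#'   `"24 h"`.
#' @param seed Integer seed.
#' @return A `perturbation_sim_spec`.
#' @export
perturbation_sim_spec <- function(n_genes = 1000, n_cell_lines = 18,
                                  n_up = 50, n_down = 50,
                                  planted_effect = 4, responder_fraction = 0.5,
                                  noise_sd = 1, timepoints = "24 h", seed = 1) {
  stopifnot(is_count(n_genes), is_count(n_cell_lines))
  if (n_up + n_down > n_genes) {
    abort_validation("n_up + n_down (%d) exceeds n_genes (%d)", n_up + n_down, n_genes)
  }
  if (responder_fraction <= 0 || responder_fraction > 1) {
    abort_validation("responder_fraction must be in (0, 1]")
  }
  if (noise_sd <= 0) abort_validation("noise_sd must be > 0")
  if (!"24 h" %in% timepoints) abort_validation("timepoints must include \"24 h\"")
  structure(as.list(environment()), class = "perturbation_sim_spec")
}

#' Simulate a perturbation profile set with planted consensus genes
#'
#' @param spec A [perturbation_sim_spec()].
#' @return List with `profiles` (a [matrix_table] with one column per
#'   cell line x timepoint, `col_meta` carrying `cell_line` and `timepoint`)
#'   and `truth` (named character vector gene -> `"up"`/`"down"` for planted
#'   genes).
#' @export
simulate_perturbation_set <- function(spec) {
  stopifnot(inherits(spec, "perturbation_sim_spec"))
  with_seed(spec$seed, {
    genes <- sprintf("gene_%04d", seq_len(spec$n_genes))
    lines <- sprintf("line_%02d", seq_len(spec$n_cell_lines))
    cols <- expand.grid(cell_line = lines, timepoint = spec$timepoints,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    col_id <- paste(cols$cell_line, gsub(" ", "", cols$timepoint), sep = "_")
    z <- matrix(stats::rnorm(spec$n_genes * nrow(cols), sd = spec$noise_sd),
                spec$n_genes, nrow(cols), dimnames = list(genes, col_id))
    up <- genes[seq_len(spec$n_up)]
    down <- genes[spec$n_up + seq_len(spec$n_down)]
    n_resp <- max(1L, round(spec$responder_fraction * spec$n_cell_lines))
    at24 <- which(cols$timepoint == "24 h")
    for (g in c(up, down)) {
      resp_lines <- sample(lines, n_resp)
      hit <- at24[cols$cell_line[at24] %in% resp_lines]
      effect <- if (g %in% up) spec$planted_effect else -spec$planted_effect
      z[g, hit] <- z[g, hit] + effect
    }
    truth <- stats::setNames(c(rep("up", spec$n_up), rep("down", spec$n_down)), c(up, down))
    profiles <- matrix_table(z, col_meta = data.frame(
      cell_line = cols$cell_line, timepoint = cols$timepoint, stringsAsFactors = FALSE))
    list(profiles = profiles, truth = truth)
  })
}

#' Simulation specification for a labeled tumor cohort
#'
#' Describes a synthetic expression cohort on the log2 scale with planted
#' subgroup structure and a planted survival effect. Each subgroup receives
#' `n_markers_per_subgroup` marker genes shifted by `marker_log2fc` in its
#' patients. If `discordant_subgroup` is set, that subgroup's markers are
#' taken from a supplied drug signature's genes with the shift sign
#' *opposite* to the signature's consensus z — the structure the discordance
#' scorer is meant to recover. Survival times are exponential; membership in
#' the top quartile of mean `survival_geneset` expression multiplies the
#' hazard by `survival_hazard_ratio` relative to the bottom quartile (middle
#' quartiles get the geometric midpoint).
#'
#' @param n_genes,n_patients Counts.
#' @param subgroup_proportions Named numeric vector of subgroup fractions
#'   summing to 1.
#' @param n_markers_per_subgroup Planted markers per subgroup.
#' @param marker_log2fc Planted shift, log2 units.
#' @param discordant_subgroup Label of the subgroup whose markers anti-align
#'   with the drug signature, or `NULL`.
#' @param survival_geneset Character vector of planted survival-effect gene
#'   ids (subset of the generated `gene_%04d` ids), or `NULL` for no planted
#'   effect beyond noise.
#' @param survival_hazard_ratio Q4-vs-Q1 hazard ratio (> 0); 1 = null.
#' @param censor_rate Expected fraction of censored patients, in [0, 1).
#' @param baseline_median_survival Baseline median overall survival in days.
#' @param seed Integer seed.
#' @return A `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_genes = 500, n_patients = 100,
                            subgroup_proportions = c(WNT = 0.1, SHH = 0.3, G3 = 0.25, G4 = 0.35),
                            n_markers_per_subgroup = 20, marker_log2fc = 2,
                            discordant_subgroup = NULL,
                            survival_geneset = NULL, survival_hazard_ratio = 1,
                            censor_rate = 0.2, baseline_median_survival = 1500,
                            seed = 1) {
  stopifnot(is_count(n_genes), is_count(n_patients))
  if (abs(sum(subgroup_proportions) - 1) > 1e-9) {
    abort_validation("subgroup_proportions must sum to 1")
  }
  if (is.null(names(subgroup_proportions))) {
    abort_validation("subgroup_proportions must be named")
  }
  if (!is.null(discordant_subgroup) &&
      !discordant_subgroup %in% names(subgroup_proportions)) {
    abort_validation("discordant_subgroup \"%s\" not among subgroups %s",
                     discordant_subgroup, paste(names(subgroup_proportions), collapse = ", "))
  }
  if (survival_hazard_ratio <= 0) abort_validation("survival_hazard_ratio must be > 0")
  if (censor_rate < 0 || censor_rate >= 1) abort_validation("censor_rate must be in [0, 1)")
  structure(as.list(environment()), class = "cohort_sim_spec")
}

#' Simulate an expression cohort with planted subgroup and survival structure
#'
#' @param spec A [cohort_sim_spec()].
#' @param drug_signature A [consensus_signature] (required when
#'   `spec$discordant_subgroup` is set); its genes become the discordant
#'   subgroup's markers with anti-aligned shift signs.
#' @return List with `cohort` (an [expression_cohort], log2 scale) and
#'   `truth` (list: `markers` map subgroup -> data frame of gene/shift,
#'   `subgroup` per patient, `survival_quartile` per patient when a survival
#'   gene set is planted).
#' @export
simulate_cohort <- function(spec, drug_signature = NULL) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  if (!is.null(spec$discordant_subgroup) && is.null(drug_signature)) {
    abort_validation("discordant_subgroup requires a drug_signature")
  }
  with_seed(spec$seed, {
    genes <- sprintf("gene_%04d", seq_len(spec$n_genes))
    patients <- sprintf("pt_%03d", seq_len(spec$n_patients))
    labels <- names(spec$subgroup_proportions)
    # deterministic rounded counts; remainder to the largest fractional parts
    raw <- spec$subgroup_proportions * spec$n_patients
    n_sub <- floor(raw)
    extra <- order(raw - n_sub, decreasing = TRUE)
    n_sub[extra[seq_len(spec$n_patients - sum(n_sub))]] <-
      n_sub[extra[seq_len(spec$n_patients - sum(n_sub))]] + 1L
    subgroup <- stats::setNames(rep(labels, n_sub), patients)

    expr <- matrix(stats::rnorm(spec$n_genes * spec$n_patients, mean = 6, sd = 1),
                   spec$n_genes, spec$n_patients, dimnames = list(genes, patients))

    pool <- genes
    markers <- list()
    for (lab in labels) {
      if (identical(lab, spec$discordant_subgroup)) {
        sig_genes <- intersect(signature_genes(drug_signature), genes)
        if (length(sig_genes) == 0L) {
          abort_validation("drug signature shares no genes with the simulated cohort")
        }
        shift <- -sign(drug_signature$entries[
          match(sig_genes, drug_signature$entries$gene), "consensus_z"]) * spec$marker_log2fc
        markers[[lab]] <- data.frame(gene = sig_genes, shift = shift,
                                     stringsAsFactors = FALSE)
        pool <- setdiff(pool, sig_genes)
      } else {
        mg <- sample(pool, min(spec$n_markers_per_subgroup, length(pool)))
        markers[[lab]] <- data.frame(gene = mg, shift = rep(spec$marker_log2fc, length(mg)),
                                     stringsAsFactors = FALSE)
        pool <- setdiff(pool, mg)
      }
      in_sub <- patients[subgroup == lab]
      expr[markers[[lab]]$gene, in_sub] <-
        expr[markers[[lab]]$gene, in_sub] + markers[[lab]]$shift
    }

    surv <- NULL
    truth_q <- NULL
    if (!is.null(spec$survival_geneset)) {
      gs <- intersect(spec$survival_geneset, genes)
      if (length(gs) == 0L) abort_validation("survival_geneset has no genes in the cohort")
      score <- colMeans(expr[gs, , drop = FALSE])
      q <- quartile_stratify(score)
      lambda0 <- log(2) / spec$baseline_median_survival
      hr_step <- spec$survival_hazard_ratio^(1 / 3) # geometric interpolation Q1..Q4
      lam <- lambda0 * hr_step^(match(q, c("Q1", "Q2", "Q3", "Q4")) - 1)
      t_event <- stats::rexp(spec$n_patients, rate = lam)
      censored <- stats::runif(spec$n_patients) < spec$censor_rate
      os_time <- ifelse(censored, t_event * stats::runif(spec$n_patients), t_event)
      surv <- data.frame(sample_id = patients,
                         os_time = pmax(os_time, 1e-6),
                         os_event = as.numeric(!censored),
                         stringsAsFactors = FALSE)
      truth_q <- q
    }

    cohort <- expression_cohort(matrix_table(expr), subgroup,
                                survival = surv, scale = "log2")
    list(cohort = cohort,
         truth = list(markers = markers, subgroup = subgroup,
                      survival_quartile = truth_q))
  })
}

#' Simulation specification for a two-agent synergy surface
#'
#' Single agents follow four-parameter logistic inhibition curves
#' (bottom 0, top 100); each combination cell equals the HSA expectation
#' `max` of the two single-agent inhibitions plus `planted_excess`
#' percentage points plus Gaussian noise, clipped to [0, 110]. The default
#' dose grid and 4PL parameters keep the single-agent margins within
#' roughly 23-75% inhibition, so a noiseless planted excess anywhere in
#' [-23, +35] is untouched by the clipping and recovered exactly by
#' [hsa_score()].
#'
#' @param doses_a,doses_b Strictly ascending dose grids starting at 0.
#' @param ec50_a,ec50_b,hill_a,hill_b Single-agent 4PL parameters.
#' @param planted_excess Percentage points of synergy above the HSA
#'   expectation (negative = antagonism).
#' @param noise_sd Noise sd in percentage points (0 = deterministic).
#' @param seed Integer seed.
#' @return A `synergy_sim_spec`.
#' @export
synergy_sim_spec <- function(doses_a = c(0, 3, 10, 30),
                             doses_b = c(0, 3, 10, 30),
                             ec50_a = 10, ec50_b = 10, hill_a = 1, hill_b = 1,
                             planted_excess = 0, noise_sd = 0, seed = 1) {
  for (d in list(doses_a, doses_b)) {
    if (any(diff(d) <= 0)) abort_validation("dose grids must be strictly ascending")
    if (d[[1L]] != 0) abort_validation("dose grids must start at 0")
  }
  stopifnot(ec50_a > 0, ec50_b > 0, noise_sd >= 0)
  structure(as.list(environment()), class = "synergy_sim_spec")
}

four_pl_inhibition <- function(dose, ec50, hill, bottom = 0, top = 100) {
  ifelse(dose == 0, bottom, bottom + (top - bottom) / (1 + (ec50 / dose)^hill))
}

#' Simulate a combination dose-response surface with planted HSA excess
#'
#' @param spec A [synergy_sim_spec()].
#' @return A [dose_response_surface] on the inhibition scale.
#' @export
simulate_dose_response <- function(spec) {
  stopifnot(inherits(spec, "synergy_sim_spec"))
  with_seed(spec$seed, {
    inh_a <- four_pl_inhibition(spec$doses_a, spec$ec50_a, spec$hill_a)
    inh_b <- four_pl_inhibition(spec$doses_b, spec$ec50_b, spec$hill_b)
    resp <- outer(inh_a, inh_b, pmax)
    comb <- outer(spec$doses_a > 0, spec$doses_b > 0, `&`)
    resp[comb] <- resp[comb] + spec$planted_excess
    if (spec$noise_sd > 0) {
      resp <- resp + matrix(stats::rnorm(length(resp), sd = spec$noise_sd),
                            nrow(resp), ncol(resp))
    }
    resp <- pmin(pmax(resp, 0), 110)
    dose_response_surface(spec$doses_a, spec$doses_b, resp,
                          response_kind = "inhibition")
  })
}

#' Simulate a gene-dependency score table with planted essential genes
#'
#' Mimics combined-RNAi style dependency screens: scores are Gaussian with
#' sd 0.3, centered at -1.5 for planted essential genes and 0 otherwise.
#' More negative means the gene is more required for cell-line survival.
#'
#' @param essential_genes Character vector of planted essential gene ids;
#'   must be a subset of the generated `gene_%04d` ids.
#' @param n_genes,n_cell_lines Counts.
#' @param seed Integer seed.
#' @return A [matrix_table] of dependency scores (genes x cell lines).
#' @export
simulate_dependency_table <- function(essential_genes, n_genes = 100,
                                      n_cell_lines = 20, seed = 1) {
  stopifnot(is_count(n_genes), is_count(n_cell_lines))
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  bad <- setdiff(essential_genes, genes)
  if (length(bad)) {
    abort_validation("essential_genes not among generated ids: %s",
                     paste(utils::head(bad, 3), collapse = ", "))
  }
  with_seed(seed, {
    mu <- ifelse(genes %in% essential_genes, -1.5, 0)
    vals <- matrix(stats::rnorm(n_genes * n_cell_lines, mean = mu, sd = 0.3),
                   n_genes, n_cell_lines,
                   dimnames = list(genes, sprintf("cl_%02d", seq_len(n_cell_lines))))
    matrix_table(vals)
  })
}
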