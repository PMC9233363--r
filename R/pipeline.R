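# End-to-end orchestration: simulate -> ingest -> filter -> test -> index
# -> clock -> classify -> report, plus the sensitivity sweep.

filter_context <- function(results, context_subset) {
  switch(context_subset,
    all = results,
    CpG_only = results[results$context == "CpG", , drop = FALSE],
    nonCpG_only = results[results$context != "CpG", , drop = FALSE],
    rlang::abort('`context_subset` must be "all", "CpG_only" or "nonCpG_only".')
  )
}

# The expensive stage: matrices and per-site tests, computed once and
# reused across sensitivity settings.
pipeline_core <- function(sim, min_coverage = 30) {
  cohort <- sim$cohort
  controls <- cohort$individual_id[cohort$group == "control"]
  mat_nacc <- build_matrix(sim$calls, min_coverage, area = "NAcc")
  mat_pfc <- build_matrix(sim$calls, min_coverage, area = "PFC")
  ctrl_nacc <- subset_matrix(mat_nacc, controls)
  ctrl_pfc <- subset_matrix(mat_pfc, controls)
  list(
    cohort = cohort, controls = controls,
    mats = list(NAcc = mat_nacc, PFC = mat_pfc),
    ba_results = ba_site_tests(ctrl_nacc, ctrl_pfc),
    age_results = list(NAcc = age_site_tests(ctrl_nacc, cohort),
                       PFC = age_site_tests(ctrl_pfc, cohort)),
    du_results = list(NAcc = du_site_tests(mat_nacc, cohort),
                      PFC = du_site_tests(mat_pfc, cohort))
  )
}

# Selection/index/score/evaluate stages for one (alpha, context) setting.
assemble_report <- function(core, alpha_ba = 0.05, alpha_age = 0.05,
                            alpha_du = 0.05, context_subset = "all") {
  cohort <- core$cohort
  controls <- core$controls
  is_control <- function(ids) ids %in% controls

  # --- brain-area index ---
  ba_sel <- select_sites(filter_context(core$ba_results, context_subset),
                         alpha_ba)
  ba_index <- build_index(ba_sel, "BA", alpha_ba, "paired")
  ba_scores <- dplyr::bind_rows(
    score_samples(ba_index, core$mats$NAcc),
    score_samples(ba_index, core$mats$PFC)
  )
  paired_ba <- tidyr::pivot_wider(ba_scores[, c("individual_id", "area", "score")],
                                  names_from = "area", values_from = "score")
  paired_ba <- paired_ba[complete.cases(paired_ba), ]
  ctrl_pairs <- paired_ba[is_control(paired_ba$individual_id), ]
  drug_pairs <- paired_ba[!is_control(paired_ba$individual_id), ]
  ba_contrasts <- tibble::tibble(
    contrast = c("NAcc_vs_PFC_control", "NAcc_vs_PFC_drug",
                 "control_vs_drug_NAcc", "control_vs_drug_PFC"),
    p_value = c(
      paired_wilcoxon(ctrl_pairs$NAcc, ctrl_pairs$PFC)$p_value,
      if (nrow(drug_pairs) >= 5)
        paired_wilcoxon(drug_pairs$NAcc, drug_pairs$PFC)$p_value
      else NA_real_,
      with(ba_scores[ba_scores$area == "NAcc", ],
           mann_whitney(score[is_control(individual_id)],
                        score[!is_control(individual_id)])$p_value),
      with(ba_scores[ba_scores$area == "PFC", ],
           mann_whitney(score[is_control(individual_id)],
                        score[!is_control(individual_id)])$p_value)
    ),
    direction = c(
      sign(median(ctrl_pairs$NAcc - ctrl_pairs$PFC)),
      if (nrow(drug_pairs) >= 1)
        sign(median(drug_pairs$NAcc - drug_pairs$PFC)) else NA_real_,
      NA_real_, NA_real_
    )
  )

  # --- age index and clock, per area ---
  age_part <- lapply(c(NAcc = "NAcc", PFC = "PFC"), function(area) {
    sel <- select_sites(filter_context(core$age_results[[area]], context_subset),
                        alpha_age)
    index <- build_index(sel, "Age", alpha_age, area)
    scores <- score_samples(index, core$mats[[area]])
    info <- cohort_for_matrix(core$mats[[area]], cohort)
    ctrl <- is_control(scores$individual_id)
    clock <- fit_clock(info$age[ctrl], scores$score[ctrl],
                       sample_ids = scores$individual_id[ctrl])
    accel <- age_acceleration(clock, scores$score, info$age,
                              heroin = info$heroin,
                              ids = scores$individual_id)
    contrasts <- dplyr::bind_rows(
      drug_all = acceleration_contrast(accel, info$group),
      ketamine = if (any(info$ketamine))
        acceleration_contrast(accel, info$group, info$ketamine) else NULL,
      ats = if (any(info$ats))
        acceleration_contrast(accel, info$group, info$ats) else NULL,
      .id = "subgroup"
    )
    list(index = index, scores = scores, clock = clock, accel = accel,
         contrasts = contrasts)
  })

  # --- drug-use index and classifier, per area ---
  du_part <- lapply(c(NAcc = "NAcc", PFC = "PFC"), function(area) {
    sel <- select_sites(filter_context(core$du_results[[area]], context_subset),
                        alpha_du)
    index <- build_index(sel, "DU", alpha_du, area)
    scores <- score_samples(index, core$mats[[area]])
    labels <- !is_control(scores$individual_id)
    threshold <- du_threshold(scores$score[!labels])
    eval <- evaluate_classifier(scores$score, labels, threshold)
    roc <- roc_auc(scores$score, labels)
    du_group_p <- mann_whitney(scores$score[!labels],
                               scores$score[labels])$p_value
    list(index = index, scores = scores, threshold = threshold,
         eval = eval, roc = roc, group_p = du_group_p)
  })

  venn <- venn_overlap(list(
    BA_paired = ba_index,
    Age_NAcc = age_part$NAcc$index, Age_PFC = age_part$PFC$index,
    DU_NAcc = du_part$NAcc$index, DU_PFC = du_part$PFC$index
  ))

  list(
    settings = list(alpha_ba = alpha_ba, alpha_age = alpha_age,
                    alpha_du = alpha_du, context_subset = context_subset),
    ba = list(results = core$ba_results, index = ba_index,
              scores = ba_scores, contrasts = ba_contrasts),
    age = age_part, du = du_part, venn = venn
  )
}

#' Run the full methylation-index pipeline on a synthetic dataset
#'
#' Simulates a dataset under `config`, builds per-area methylation
#' matrices, runs the per-site tests, constructs the brain-area, age, and
#' drug-use indices, fits the epigenetic clock, estimates age
#' acceleration, evaluates the drug-use classifier (threshold rule and
#' ROC), counts the index overlaps, and summarises the cohort. All
#' artifacts are optionally written under `output_dir`. A second run with
#' the same config yields byte-identical artifacts.
#'
#' @param config A [simulation_config()].
#' @param output_dir Optional directory for artifact files.
#' @param min_coverage Per-cell coverage filter (default 30).
#' @param alpha_ba,alpha_age,alpha_du Site-selection thresholds.
#' @param context_subset `"all"`, `"CpG_only"`, or `"nonCpG_only"`.
#' @param overwrite Allow clobbering existing artifact files.
#' @return A `run_report` list: `cohort_summary`, `ba`, `age`, `du`,
#'   `venn`, `counts` (sites in/out of each filter), `provenance`.
#' @export
run_pipeline <- function(config = simulation_config(), output_dir = NULL,
                         min_coverage = 30, alpha_ba = 0.05,
                         alpha_age = 0.05, alpha_du = 0.05,
                         context_subset = "all", overwrite = FALSE) {
  sim <- simulate_dataset(config)
  core <- pipeline_core(sim, min_coverage)
  report <- assemble_report(core, alpha_ba, alpha_age, alpha_du,
                            context_subset)
  report$counts <- tibble::tibble(
    stage = c("calls_total", "sites_NAcc", "sites_PFC", "sites_shared",
              "selected_BA", "selected_Age_NAcc", "selected_Age_PFC",
              "selected_DU_NAcc", "selected_DU_PFC"),
    n = c(nrow(sim$calls), nrow(core$mats$NAcc$sites),
          nrow(core$mats$PFC$sites),
          nrow(overlap_sites(core$mats$NAcc, core$mats$PFC)),
          nrow(report$ba$index$entries),
          nrow(report$age$NAcc$index$entries),
          nrow(report$age$PFC$index$entries),
          nrow(report$du$NAcc$index$entries),
          nrow(report$du$PFC$index$entries))
  )
  report$cohort_summary <- cohort_summary(sim$cohort)
  report$truth <- sim$truth
  report$provenance <- list(
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    min_coverage = min_coverage
  )
  class(report) <- "run_report"
  if (!is.null(output_dir)) {
    write_run_report(sim, core, report, output_dir, overwrite = overwrite)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  print(x$counts)
  invisible(x)
}

# Serialise every pipeline artifact as plain text under `dir`.
write_run_report <- function(sim, core, report, dir, overwrite = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_reference(sim$reference, p("reference.fasta"), overwrite = overwrite)
  write_cohort(sim$cohort, p("cohort.tsv"), overwrite = overwrite)
  write_truth(sim$truth, p("truth.json"), overwrite = overwrite)
  readr::write_tsv(core$ba_results, p("ba_site_tests.tsv"))
  for (area in c("NAcc", "PFC")) {
    readr::write_tsv(core$age_results[[area]],
                     p(sprintf("age_site_tests_%s.tsv", area)))
    readr::write_tsv(core$du_results[[area]],
                     p(sprintf("du_site_tests_%s.tsv", area)))
    write_index(report$age[[area]]$index,
                p(sprintf("age_index_%s.json", area)), overwrite = overwrite)
    write_index(report$du[[area]]$index,
                p(sprintf("du_index_%s.json", area)), overwrite = overwrite)
    write_clock(report$age[[area]]$clock,
                p(sprintf("clock_%s.json", area)), overwrite = overwrite)
    readr::write_tsv(report$age[[area]]$accel,
                     p(sprintf("age_acceleration_%s.tsv", area)))
    readr::write_tsv(report$du[[area]]$roc$roc_points,
                     p(sprintf("roc_%s.tsv", area)))
    readr::write_tsv(report$du[[area]]$eval,
                     p(sprintf("classifier_eval_%s.tsv", area)))
  }
  write_index(report$ba$index, p("ba_index.json"), overwrite = overwrite)
  readr::write_tsv(report$ba$scores, p("ba_scores.tsv"))
  readr::write_tsv(report$ba$contrasts, p("ba_contrasts.tsv"))
  readr::write_tsv(report$venn$cells, p("venn_cells.tsv"))
  readr::write_tsv(report$cohort_summary, p("cohort_summary.tsv"))
  readr::write_tsv(report$counts, p("stage_counts.tsv"))
  jsonlite::write_json(report$provenance, p("provenance.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Cohort characteristics table with group-comparison tests
#'
#' Summarises the cohort the way forensic demographic tables are
#' presented: age as mean (SD) compared by Mann-Whitney; alcohol intake,
#' postmortem-interval class, and cause of death as n (%) compared by
#' Pearson chi-square without continuity correction.
#'
#' @param cohort Cohort tibble.
#' @return Tibble: `variable`, `control`, `drug`, `test`, `p_value`.
#' @export
cohort_summary <- function(cohort) {
  ctrl <- cohort[cohort$group == "control", ]
  drug <- cohort[cohort$group == "drug", ]
  if (nrow(ctrl) == 0L || nrow(drug) == 0L) {
    rlang::abort("Both groups must be present.")
  }
  fmt_mean_sd <- function(x) sprintf("%.1f (%.1f)", mean(x), sd(x))
  fmt_n_pct <- function(k, n) sprintf("%d (%.1f)", k, 100 * k / n)
  two_by_two <- function(flag_c, flag_d) {
    rbind(c(sum(flag_c), sum(!flag_c)), c(sum(flag_d), sum(!flag_d)))
  }
  age_p <- mann_whitney(ctrl$age, drug$age)$p_value
  alc_p <- chi_square_independence(two_by_two(ctrl$alcohol, drug$alcohol))$p_value
  pmi_p <- chi_square_independence(
    two_by_two(ctrl$pmi_class == "<=6h", drug$pmi_class == "<=6h")
  )$p_value
  cod_levels <- union(unique(ctrl$cause_of_death), unique(drug$cause_of_death))
  cod_tab <- cbind(
    table(factor(ctrl$cause_of_death, cod_levels)),
    table(factor(drug$cause_of_death, cod_levels))
  )
  cod_tab <- cod_tab[rowSums(cod_tab) > 0, , drop = FALSE]
  cod_p <- chi_square_independence(cod_tab)$p_value
  tibble::tibble(
    variable = c("Age (year), mean (SD)", "Alcohol intake, n (%)",
                 "Postmortem interval <= 6 h, n (%)", "Cause of death"),
    control = c(fmt_mean_sd(ctrl$age),
                fmt_n_pct(sum(ctrl$alcohol), nrow(ctrl)),
                fmt_n_pct(sum(ctrl$pmi_class == "<=6h"), nrow(ctrl)), ""),
    drug = c(fmt_mean_sd(drug$age),
             fmt_n_pct(sum(drug$alcohol), nrow(drug)),
             fmt_n_pct(sum(drug$pmi_class == "<=6h"), nrow(drug)), ""),
    test = c("mann_whitney", "chi_square", "chi_square", "chi_square"),
    p_value = c(age_p, alc_p, pmi_p, cod_p)
  )
}

#' Sensitivity sweep over selection thresholds and sequence contexts
#'
#' Re-runs the selection / index / score / evaluation stages of the
#' pipeline (the per-site tests are computed once) for every combination
#' of p-value threshold and context subset, and summarises whether the
#' qualitative conclusions persist: the direction of the control
#' brain-area contrast, the sign of the median drug-group age
#' acceleration, and the drug-use AUC. Settings whose selection is empty
#' are reported, not fatal.
#'
#' @param config A [simulation_config()].
#' @param alphas P-value thresholds to sweep (applied to all three
#'   indices).
#' @param contexts Context subsets to sweep.
#' @param min_coverage Coverage filter.
#' @return A list with `grid` (one row per setting: site counts, BA
#'   direction and p, median accelerations, AUCs, `empty` flag),
#'   `nesting_ok` (site sets nested across decreasing alphas), and
#'   `stable` (direction/AUC conclusions identical across non-empty
#'   settings).
#' @export
sensitivity_sweep <- function(config = simulation_config(),
                              alphas = c(0.05, 0.02, 0.005),
                              contexts = "all", min_coverage = 30) {
  if (length(alphas) * length(contexts) < 2L) {
    rlang::abort("Need at least 2 sweep settings.")
  }
  sim <- simulate_dataset(config)
  core <- pipeline_core(sim, min_coverage)
  grid <- tidyr::expand_grid(alpha = alphas, context = contexts)
  rows <- purrr::pmap_dfr(grid, function(alpha, context) {
    rep <- tryCatch(
      assemble_report(core, alpha, alpha, alpha, context),
      error = function(e) NULL
    )
    if (is.null(rep)) {
      return(tibble::tibble(
        alpha = alpha, context = context, empty = TRUE,
        n_ba = NA_integer_, n_age_nacc = NA_integer_, n_du_nacc = NA_integer_,
        ba_direction = NA_real_, ba_p = NA_real_,
        accel_median_nacc = NA_real_, auc_nacc = NA_real_, auc_pfc = NA_real_
      ))
    }
    tibble::tibble(
      alpha = alpha, context = context, empty = FALSE,
      n_ba = nrow(rep$ba$index$entries),
      n_age_nacc = nrow(rep$age$NAcc$index$entries),
      n_du_nacc = nrow(rep$du$NAcc$index$entries),
      ba_direction = rep$ba$contrasts$direction[1],
      ba_p = rep$ba$contrasts$p_value[1],
      accel_median_nacc = rep$age$NAcc$contrasts$median_shift[
        rep$age$NAcc$contrasts$subgroup == "drug_all"],
      auc_nacc = rep$du$NAcc$roc$auc,
      auc_pfc = rep$du$PFC$roc$auc
    )
  })
  # selected-site nesting across alphas (within each context, full results)
  nesting_ok <- all(vapply(contexts, function(ctx) {
    res <- filter_context(core$ba_results, ctx)
    sets <- lapply(sort(alphas, decreasing = TRUE), function(a) {
      sel <- select_sites(res, a)
      paste(sel$position, sel$strand)
    })
    all(vapply(seq_len(length(sets) - 1L), function(i) {
      all(sets[[i + 1L]] %in% sets[[i]])
    }, logical(1)))
  }, logical(1)))
  ok <- rows[!rows$empty, ]
  stable <- nrow(ok) > 0 &&
    length(unique(ok$ba_direction)) == 1L &&
    all(ok$auc_nacc > 0.5) == any(ok$auc_nacc > 0.5)
  list(grid = rows, nesting_ok = nesting_ok, stable = stable)
}
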