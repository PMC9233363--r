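#' Configuration for the synthetic bisulfite-call generator
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults describe the study conditions the package is built around:
#' 39 control and 14 drug-use individuals, a 16,569-bp circular genome at
#' 44% GC, a ~2% mean methylation level capped at 8% per site, heavier
#' coverage on the H-chain than the L-chain, and planted brain-area, age,
#' and drug effect sites on the logit scale.
#'
#' @param n_control,n_drug Numbers of control and drug-use individuals.
#' @param genome_length Reference length in bases.
#' @param gc_fraction GC content of the generated reference.
#' @param baseline_mean Mean site-level methylation fraction.
#' @param baseline_max Cap on any single site's mean methylation fraction.
#' @param baseline_logit_sd SD of per-site baseline on the logit scale.
#' @param individual_logit_sd SD of the per-individual, per-site biological
#'   deviation on the logit scale, shared between the two brain areas of an
#'   individual (induces the within-individual pairing correlation real
#'   tissue shows).
#' @param n_ba_sites,n_age_sites,n_du_sites Counts of planted effect sites;
#'   the three sets are pairwise disjoint.
#' @param ba_effect Additive logit shift applied in the NAcc at brain-area
#'   sites.
#' @param age_slope Logit change per year of age at age sites.
#' @param du_effect Additive logit shift in the drug group at drug-use sites.
#' @param drug_age_shift Years added to a drug-group individual's effective
#'   age at the planted age sites, planting an age-acceleration signal
#'   (default 0).
#' @param coverage_mean_H,coverage_mean_L Mean read depth per strand;
#'   H-chain coverage must be at least L-chain coverage.
#' @param coverage_dispersion Negative-binomial size parameter (smaller =
#'   more overdispersed).
#' @param missing_pfc_fraction Fraction of drug-group individuals lacking a
#'   PFC sample.
#' @param seed Integer seed controlling all randomness downstream.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_control = 39L, n_drug = 14L,
                              genome_length = 16569L, gc_fraction = 0.44,
                              baseline_mean = 0.02, baseline_max = 0.08,
                              baseline_logit_sd = 0.5,
                              individual_logit_sd = 0.5,
                              n_ba_sites = 105L, n_age_sites = 70L,
                              n_du_sites = 35L,
                              ba_effect = 1, age_slope = 0.02,
                              du_effect = 1.5, drug_age_shift = 0,
                              coverage_mean_H = 100, coverage_mean_L = 50,
                              coverage_dispersion = 20,
                              missing_pfc_fraction = 1 / 14,
                              seed = 1L) {
  cfg <- list(
    n_control = as.integer(n_control), n_drug = as.integer(n_drug),
    genome_length = as.integer(genome_length), gc_fraction = gc_fraction,
    baseline_mean = baseline_mean, baseline_max = baseline_max,
    baseline_logit_sd = baseline_logit_sd,
    individual_logit_sd = individual_logit_sd,
    n_ba_sites = as.integer(n_ba_sites),
    n_age_sites = as.integer(n_age_sites),
    n_du_sites = as.integer(n_du_sites),
    ba_effect = ba_effect, age_slope = age_slope, du_effect = du_effect,
    drug_age_shift = drug_age_shift,
    coverage_mean_H = coverage_mean_H, coverage_mean_L = coverage_mean_L,
    coverage_dispersion = coverage_dispersion,
    missing_pfc_fraction = missing_pfc_fraction,
    seed = as.integer(seed)
  )
  if (cfg$baseline_mean <= 0 || cfg$baseline_mean >= cfg$baseline_max ||
      cfg$baseline_max >= 1) {
    rlang::abort("Need 0 < baseline_mean < baseline_max < 1.")
  }
  if (cfg$coverage_mean_L <= 0 || cfg$coverage_mean_H < cfg$coverage_mean_L) {
    rlang::abort("Need coverage_mean_H >= coverage_mean_L > 0.")
  }
  counts <- c(cfg$n_control, cfg$n_drug, cfg$n_ba_sites, cfg$n_age_sites,
              cfg$n_du_sites)
  if (any(counts < 0)) rlang::abort("Counts must be nonnegative.")
  if (cfg$missing_pfc_fraction < 0 || cfg$missing_pfc_fraction > 1) {
    rlang::abort("`missing_pfc_fraction` must be in [0, 1].")
  }
  structure(cfg, class = "simulation_config")
}

# Integer split of `n` into parts proportional to `prop` (largest remainder).
proportional_counts <- function(n, prop) {
  raw <- n * prop / sum(prop)
  out <- floor(raw)
  rem <- n - sum(out)
  if (rem > 0) {
    idx <- order(raw - out, decreasing = TRUE)[seq_len(rem)]
    out[idx] <- out[idx] + 1L
  }
  as.integer(out)
}

#' Generate a synthetic forensic cohort table
#'
#' Draws one row per deceased individual: group, drug-exposure flags
#' (heroin, amphetamine-type stimulants, ketamine), age (normal, truncated
#' at the 18-year inclusion bound; controls centred at 54.9 y, SD 21.5;
#' drug users at 37.5 y, SD 12.0), alcohol intake, postmortem-interval
#' class (dichotomised at 6 h), batch, collector, and cause of death.
#' Drug-type composition follows the observed mix (heroin : ATS-only :
#' ketamine-only : ATS+ketamine = 2 : 5 : 3 : 4).
#'
#' @param config A [simulation_config()].
#' @return A tibble with one row per individual.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n_c <- config$n_control
  n_d <- config$n_drug
  with_seed(derive_seed(config$seed, 1L), {
    rtrunc_age <- function(n, mean, sd) {
      if (n == 0L) return(numeric(0))
      out <- numeric(0)
      while (length(out) < n) {
        draw <- rnorm(2L * n, mean, sd)
        out <- c(out, draw[draw >= 18])
      }
      round(out[seq_len(n)], 1)
    }
    ages <- c(rtrunc_age(n_c, 54.9, 21.5), rtrunc_age(n_d, 37.5, 12.0))
    # drug-type mix: heroin / ATS-only / ketamine-only / ATS+ketamine
    mix <- proportional_counts(n_d, c(2, 5, 3, 4))
    type <- rep(c("heroin", "ats", "ketamine", "ats_ketamine"), mix)
    group <- c(rep("control", n_c), rep("drug", n_d))
    heroin <- c(rep(FALSE, n_c), type == "heroin")
    ats <- c(rep(FALSE, n_c), type %in% c("ats", "ats_ketamine"))
    ketamine <- c(rep(FALSE, n_c), type %in% c("ketamine", "ats_ketamine"))
    n <- n_c + n_d
    alcohol <- rbinom(n, 1, ifelse(group == "control", 0.18, 0.143)) == 1
    pmi_class <- ifelse(
      rbinom(n, 1, ifelse(group == "control", 0.82, 0.643)) == 1, "<=6h", ">6h"
    )
    cod_levels <- c("accident", "homicide", "suicide", "natural", "undetermined")
    cod_p_control <- c(17, 3, 2, 15, 2) / 39
    cod_p_drug <- c(4, 5, 3, 1, 1) / 14
    cause <- vapply(group, function(g) {
      sample(cod_levels, 1L,
             prob = if (g == "control") cod_p_control else cod_p_drug)
    }, character(1))
    tibble::tibble(
      individual_id = sprintf("ID%03d", seq_len(n)),
      group = group, heroin = heroin, ats = ats, ketamine = ketamine,
      age = ages, alcohol = alcohol, pmi_class = pmi_class,
      batch = sample(paste0("B", 1:3), n, replace = TRUE),
      collector = sample(paste0("DR", 1:2), n, replace = TRUE),
      cause_of_death = unname(cause)
    )
  })
}

#' Plant ground-truth effect sites on a reference
#'
#' Picks pairwise-disjoint sets of cytosine positions to carry the
#' brain-area, age, and drug-use effects, and records the per-individual
#' ages and group labels, so downstream recovery can be scored against a
#' known truth.
#'
#' @param config A [simulation_config()].
#' @param reference Reference string from [generate_reference()].
#' @param cohort Cohort tibble from [generate_cohort()].
#' @return A `simulation_truth` list with `ba_sites`, `age_sites`,
#'   `du_sites` (tibbles of position/strand/effect) and `individuals`.
#' @export
generate_truth <- function(config, reference, cohort) {
  stopifnot(inherits(config, "simulation_config"))
  sites <- all_cytosines(reference)
  need <- config$n_ba_sites + config$n_age_sites + config$n_du_sites
  if (need > nrow(sites)) {
    rlang::abort("Reference has too few cytosines for the requested planted sites.")
  }
  with_seed(derive_seed(config$seed, 2L), {
    pick <- sample(nrow(sites), need)
  })
  take <- function(idx, effect) {
    dplyr::mutate(
      dplyr::arrange(sites[idx, c("position", "strand")], .data$position, .data$strand),
      effect = effect
    )
  }
  i1 <- seq_len(config$n_ba_sites)
  i2 <- config$n_ba_sites + seq_len(config$n_age_sites)
  i3 <- config$n_ba_sites + config$n_age_sites + seq_len(config$n_du_sites)
  structure(list(
    ba_sites = take(pick[i1], config$ba_effect),
    age_sites = take(pick[i2], config$age_slope),
    du_sites = take(pick[i3], config$du_effect),
    individuals = cohort[, c("individual_id", "group", "age")]
  ), class = "simulation_truth")
}

#' Simulate cytosine-level bisulfite calls for a cohort
#'
#' For every individual and available brain area (NAcc always; PFC omitted
#' for a configured fraction of the drug group), draws per-site coverage
#' from a strand-dependent negative binomial and methylated counts from a
#' binomial whose probability is assembled on the logit scale:
#' site baseline + brain-area shift (NAcc only, at planted BA sites) +
#' age slope x (age - cohort mean age) (at planted age sites) + drug shift
#' (drug group only, at planted DU sites).
#'
#' @param config A [simulation_config()].
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param reference Reference string.
#' @param truth Truth object from [generate_truth()].
#' @return A tibble of calls: `individual_id`, `area`, `position`, `strand`,
#'   `context`, `trinucleotide`, `count_methylated`, `count_unmethylated`.
#' @export
simulate_methylation <- function(config, cohort, reference, truth) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(truth, "simulation_truth"))
  sites <- all_cytosines(reference)
  key <- paste(sites$position, sites$strand)
  check_planted <- function(tbl, label) {
    missing <- setdiff(paste(tbl$position, tbl$strand), key)
    if (length(missing) > 0) {
      rlang::abort(sprintf(
        "Planted %s position(s) absent from reference: %s",
        label, paste(missing, collapse = ", ")
      ))
    }
  }
  check_planted(truth$ba_sites, "brain-area")
  check_planted(truth$age_sites, "age")
  check_planted(truth$du_sites, "drug-use")

  n_sites <- nrow(sites)
  # per-site baseline on logit scale, site mean capped at baseline_max
  base_p <- with_seed(derive_seed(config$seed, 3L), {
    p <- stats::plogis(rnorm(
      n_sites,
      stats::qlogis(config$baseline_mean), config$baseline_logit_sd
    ))
    pmin(p, config$baseline_max)
  })
  eta_base <- stats::qlogis(base_p)

  effect_vec <- function(tbl) {
    v <- numeric(n_sites)
    v[match(paste(tbl$position, tbl$strand), key)] <- tbl$effect
    v
  }
  ba_eff <- effect_vec(truth$ba_sites)
  age_eff <- effect_vec(truth$age_sites)
  du_eff <- effect_vec(truth$du_sites)

  cov_mu <- ifelse(sites$strand == "+", config$coverage_mean_H,
                   config$coverage_mean_L)
  mean_age <- mean(cohort$age)

  # drug individuals missing a PFC sample (deterministic count, first k)
  drug_ids <- cohort$individual_id[cohort$group == "drug"]
  n_missing <- round(config$missing_pfc_fraction * length(drug_ids))
  missing_pfc <- head(drug_ids, n_missing)

  out <- vector("list", 2L * nrow(cohort))
  k <- 0L
  for (i in seq_len(nrow(cohort))) {
    ind <- cohort[i, ]
    areas <- if (ind$individual_id %in% missing_pfc) "NAcc" else c("NAcc", "PFC")
    # biological individual effect, shared between the two areas
    ind_noise <- with_seed(derive_seed(config$seed, 5000L + i), {
      rnorm(n_sites, 0, config$individual_logit_sd %||% 0)
    })
    for (area in areas) {
      eff_age <- ind$age +
        (ind$group == "drug") * (config$drug_age_shift %||% 0)
      eta <- eta_base + ind_noise +
        (area == "NAcc") * ba_eff +
        age_eff * (eff_age - mean_age) +
        (ind$group == "drug") * du_eff
      p <- pmin(pmax(stats::plogis(eta), 1e-8), 1 - 1e-8)
      sub_seed <- derive_seed(config$seed, 100L + 2L * i + (area == "PFC"))
      calls <- with_seed(sub_seed, {
        coverage <- rnbinom(n_sites, size = config$coverage_dispersion,
                            mu = cov_mu)
        meth <- rbinom(n_sites, size = coverage, prob = p)
        list(coverage = coverage, meth = meth)
      })
      k <- k + 1L
      out[[k]] <- tibble::tibble(
        individual_id = ind$individual_id, area = area,
        position = sites$position, strand = sites$strand,
        context = sites$context, trinucleotide = sites$trinucleotide,
        count_methylated = calls$meth,
        count_unmethylated = calls$coverage - calls$meth
      )
    }
  }
  dplyr::bind_rows(out[seq_len(k)])
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [generate_reference()], [generate_cohort()],
#' [generate_truth()], and [simulate_methylation()] under one configuration.
#'
#' @param config A [simulation_config()].
#' @return A list with `reference`, `cohort`, `truth`, and `calls`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  reference <- generate_reference(config$genome_length, config$gc_fraction,
                                  seed = derive_seed(config$seed, 0L))
  cohort <- generate_cohort(config)
  truth <- generate_truth(config, reference, cohort)
  calls <- simulate_methylation(config, cohort, reference, truth)
  list(reference = reference, cohort = cohort, truth = truth, calls = calls)
}
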