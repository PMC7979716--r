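#' Effect configuration for a synthetic neoadjuvant cohort
#'
#' Encodes the effect structure the cohort statistics assume: per-stratum
#' baseline sTIL distributions, a day-15 on-treatment shift concentrated
#' in hormone-receptor-negative disease, a surgery shift conditional on
#' pathological complete response (pCR), per-stratum pCR probabilities,
#' and a set of TIL-linked genes embedded in a null expression panel.
#'
#' Default shifts mirror the reported cohort dynamics: day-15 sTIL rise
#' of +12.5 points in HR-negative vs +2.1 in HR-positive tumours; at
#' surgery -21.5 in pCR vs -0.9 in residual disease. The default
#' TIL-linked genes are the ten consistently sTIL-associated immune
#' genes (MS4A1, PD1, CD8A, CD19, IKBKE, IDO1, TAP1, TYMP, CD3G, LAG3).
#'
#' @param baseline_beta per-HR-stratum `shape1`/`shape2` of the baseline
#'   sTIL beta distribution (rescaled to 0..100).
#' @param day15_shift named numeric: mean day-15 minus baseline shift in
#'   sTIL points per HR stratum.
#' @param surgery_shift named numeric: mean surgery minus day-15 shift
#'   for `pcr` and `rd` (residual disease).
#' @param pcr_prob named pCR probability per HR stratum.
#' @param pam50_prob named list: PAM50 label probabilities per HR stratum
#'   (HER2-enriched dominant, as in HER2+ disease).
#' @param sd_shift subject-level SD of the timepoint shifts.
#' @param til_genes character vector of TIL-linked gene names.
#' @param til_gene_correlation target correlation of TIL-linked gene
#'   log-expression with sTILs.
#' @param n_genes total panel size including TIL-linked and housekeeping
#'   genes (the rest are null genes).
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(
    baseline_beta = list(negative = c(shape1 = 1.6, shape2 = 8),
                         positive = c(shape1 = 1.2, shape2 = 11)),
    day15_shift = c(negative = 12.5, positive = 2.1),
    surgery_shift = c(pcr = -21.5, rd = -0.9),
    pcr_prob = c(negative = 0.45, positive = 0.20),
    pam50_prob = list(
      negative = c(HER2E = 0.78, Basal = 0.12, LumA = 0.03, LumB = 0.05,
                   Normal = 0.02),
      positive = c(HER2E = 0.52, Basal = 0.03, LumA = 0.22, LumB = 0.20,
                   Normal = 0.03)),
    sd_shift = 8,
    til_genes = c("MS4A1", "PD1", "CD8A", "CD19", "IKBKE", "IDO1",
                  "TAP1", "TYMP", "CD3G", "LAG3"),
    til_gene_correlation = 0.5,
    n_genes = 200) {
  for (p in pam50_prob)
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0))
      stop("invalid stratum probabilities")
  if (any(pcr_prob < 0 | pcr_prob > 1)) stop("invalid stratum probabilities")
  stopifnot(til_gene_correlation >= 0, til_gene_correlation < 1,
            n_genes == 0 ||
              n_genes >= length(til_genes) + length(housekeeping_genes()))
  structure(
    list(baseline_beta = baseline_beta, day15_shift = day15_shift,
         surgery_shift = surgery_shift, pcr_prob = pcr_prob,
         pam50_prob = pam50_prob, sd_shift = sd_shift,
         til_genes = til_genes,
         til_gene_correlation = til_gene_correlation, n_genes = n_genes),
    class = "cohort_config"
  )
}

# pathologist scoring granularity: steps of 5 below 10%, of 10 above
round_stils <- function(x) {
  x <- pmin(100, pmax(0, x))
  ifelse(x < 10, round(x / 5) * 5, round(x / 10) * 10)
}

#' Generate a synthetic cohort with expression data
#'
#' Three timepoint rows (baseline, day15, surgery) per patient with
#' HR status, PAM50 label, pCR and pathologist-granularity sTIL scores
#' following the configured effect structure, plus a gene x sample raw
#' count matrix in which the configured TIL-linked genes correlate with
#' sTILs and the remaining genes are null. All randomness is seeded.
#'
#' @param n_patients number of patients (>= 2).
#' @param effect_config a [cohort_config()].
#' @param seed integer seed.
#' @return list with `cohort` (data frame: `patient_id`, `timepoint`,
#'   `hr_status`, `pam50`, `pcr`, `stils_pct`) and `expression` (raw
#'   count matrix, genes x samples; column names `<patient>_<timepoint>`).
#' @export
generate_cohort <- function(n_patients, effect_config = cohort_config(),
                            seed = 1) {
  stopifnot(n_patients >= 2, inherits(effect_config, "cohort_config"))
  cfg <- effect_config
  set.seed(seed)
  hr <- sample(c("negative", "positive"), n_patients, replace = TRUE,
               prob = c(0.45, 0.55))
  pam50 <- vapply(hr, function(h)
    sample(names(cfg$pam50_prob[[h]]), 1, prob = cfg$pam50_prob[[h]]),
    character(1))
  pcr <- stats::runif(n_patients) < cfg$pcr_prob[hr]
  bb <- cfg$baseline_beta
  # latent patient inflammation plus iid measurement noise at every
  # timepoint: under a zero configured shift the timepoints are
  # exchangeable, so rounding and range clipping cannot fake an effect
  theta <- vapply(hr, function(h)
    100 * stats::rbeta(1, bb[[h]]["shape1"], bb[[h]]["shape2"]),
    numeric(1))
  sd_e <- cfg$sd_shift / sqrt(2)
  base_raw <- theta + stats::rnorm(n_patients, sd = sd_e)
  d15_raw <- theta + cfg$day15_shift[hr] +
    stats::rnorm(n_patients, sd = sd_e)
  surg_raw <- theta + cfg$day15_shift[hr] +
    cfg$surgery_shift[ifelse(pcr, "pcr", "rd")] +
    stats::rnorm(n_patients, sd = sd_e)
  cohort <- data.frame(
    patient_id = rep(sprintf("P%03d", seq_len(n_patients)), each = 3),
    timepoint = rep(c("baseline", "day15", "surgery"), n_patients),
    hr_status = rep(hr, each = 3),
    pam50 = rep(pam50, each = 3),
    pcr = rep(pcr, each = 3),
    stils_pct = round_stils(as.numeric(rbind(base_raw, d15_raw, surg_raw))),
    stringsAsFactors = FALSE
  )
  expression <- NULL
  if (cfg$n_genes > 0) {
    hk <- housekeeping_genes()
    n_null <- cfg$n_genes - length(cfg$til_genes) - length(hk)
    genes <- c(cfg$til_genes, hk,
               if (n_null > 0) sprintf("NULLG%03d", seq_len(n_null)))
    ns <- nrow(cohort)
    z <- as.numeric(scale(cohort$stils_pct +
                            stats::rnorm(ns, sd = 1e-6)))  # break ties
    r <- cfg$til_gene_correlation
    lg <- matrix(stats::rnorm(length(genes) * ns), length(genes), ns,
                 dimnames = list(genes, NULL))
    for (g in cfg$til_genes)
      lg[g, ] <- r * z + sqrt(1 - r^2) * stats::rnorm(ns)
    lg <- 8 + 1.2 * lg                     # plausible log2 count scale
    lg[hk, ] <- 10 + 0.05 * lg[hk, ] / 1.2 # stable housekeeping levels
    expression <- round(pmax(2^lg - 1, 0))
    colnames(expression) <- paste(cohort$patient_id, cohort$timepoint,
                                  sep = "_")
  }
  list(cohort = cohort, expression = expression)
}
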