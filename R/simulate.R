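# Seeding: one global seed drives a named sub-stream per generator, so
# adding a generator never perturbs existing streams.
stream_seed <- function(seed, stream) {
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 1000000007
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

with_stream <- function(seed, stream, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, stream))
  force(code)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(paste0("`", name, "` must be a probability in [0, 1]."),
          class = "brcaness_config_error")
  }
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != round(x)) {
    abort(paste0("`", name, "` must be an integer >= ", min, "."),
          class = "brcaness_config_error")
  }
}

#' Configuration for simulated discovery cohorts
#'
#' Describes a two-class discovery cohort of the kind the classifier is
#' derived on: a latent expression phenotype shifts a subset of informative
#' genes, and the recorded copy-number reference label agrees imperfectly
#' with that phenotype. The label is drawn first at the configured
#' prevalence; the expression phenotype then disagrees with it with
#' probability `discordance_pos` (label-positive samples) or
#' `discordance_neg` (label-negative samples), so a classifier that
#' recovers the phenotype perfectly shows sensitivity `1 - discordance_pos`
#' and specificity `1 - discordance_neg` against the label. The defaults
#' emulate a 128-tumour cohort with 48% label prevalence and a 96.7% / 73.1%
#' concordance target.
#'
#' Per-gene shift magnitudes are exponential with mean
#' `effect_size * noise_sd`, all in the same direction; gene-to-gene
#' variation in the shift is what makes the two class centroids
#' distinguishable by a correlation score (a shift constant across genes is
#' invisible to Pearson correlation).
#'
#' @param n_samples,n_genes,n_informative Cohort dimensions
#'   (defaults 128, 2000, 150).
#' @param label_prevalence Fraction of label-positive samples (default 0.48).
#' @param effect_size Mean standardised shift per informative gene
#'   (default 1).
#' @param noise_sd Per-gene residual standard deviation on the log2 scale
#'   (default 1).
#' @param discordance_pos,discordance_neg Probability that the expression
#'   phenotype disagrees with the label for label-positive /
#'   label-negative samples (defaults 0.03, 0.27).
#' @param n_batches Number of biobank batches (default 2).
#' @param batch_shift_sd Scale of additive per-gene batch location shifts
#'   (default 0.3).
#' @param baseline_mean,baseline_sd Distribution of per-gene baseline log2
#'   expression (defaults 7, 1).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `discovery_sim_config` list.
#' @export
discovery_sim_config <- function(n_samples = 128, n_genes = 2000,
                                 n_informative = 150,
                                 label_prevalence = 0.48,
                                 effect_size = 1, noise_sd = 1,
                                 discordance_pos = 0.03,
                                 discordance_neg = 0.27,
                                 n_batches = 2, batch_shift_sd = 0.3,
                                 baseline_mean = 7, baseline_sd = 1,
                                 seed = NULL) {
  check_count(n_samples, "n_samples", min = 4)
  check_count(n_genes, "n_genes")
  check_count(n_informative, "n_informative")
  if (n_informative > n_genes) {
    abort("`n_informative` must not exceed `n_genes`.",
          class = "brcaness_config_error")
  }
  check_prob(label_prevalence, "label_prevalence")
  if (label_prevalence <= 0 || label_prevalence >= 1) {
    abort("`label_prevalence` must lie strictly in (0, 1).",
          class = "brcaness_config_error")
  }
  check_prob(discordance_pos, "discordance_pos")
  check_prob(discordance_neg, "discordance_neg")
  for (nm in c("effect_size", "noise_sd", "batch_shift_sd", "baseline_sd")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1 || is.na(val) || val < 0) {
      abort(paste0("`", nm, "` must be a non-negative number."),
            class = "brcaness_config_error")
    }
  }
  check_count(n_batches, "n_batches")
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 n_informative = n_informative,
                 label_prevalence = label_prevalence,
                 effect_size = effect_size, noise_sd = noise_sd,
                 discordance_pos = discordance_pos,
                 discordance_neg = discordance_neg,
                 n_batches = n_batches, batch_shift_sd = batch_shift_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 seed = seed),
            class = "discovery_sim_config")
}

#' Simulate a labelled discovery cohort
#'
#' Generates background-subtracted linear-scale intensities (the input
#' expected by [preprocess_expression()]) for a two-class cohort as
#' described in [discovery_sim_config()]. The expression structure is built
#' on the log2 scale — per-gene baselines, phenotype shifts on the
#' informative genes, additive per-gene batch offsets (samples assigned to
#' batches round-robin) and Gaussian noise — and converted to the linear
#' scale as `2^x - 10`, so the standard offset-10 log transform recovers it.
#'
#' @param config A [discovery_sim_config()].
#' @return A `discovery_cohort`: list with `expr` (an [expr_matrix] of
#'   linear intensities with batch labels), `samples` (tibble: `sample_id`,
#'   `label`, `latent`, `batch`) and `genes` (tibble: `gene_id`,
#'   `informative`, `effect`).
#' @export
simulate_discovery <- function(config = discovery_sim_config()) {
  if (!inherits(config, "discovery_sim_config")) {
    abort("`config` must come from discovery_sim_config().",
          class = "brcaness_config_error")
  }
  with_stream(config$seed, "discovery", {
    n <- config$n_samples
    g <- config$n_genes
    gene_id <- sprintf("gene_%04d", seq_len(g))
    sample_id <- sprintf("sample_%03d", seq_len(n))

    label <- runif(n) < config$label_prevalence
    flip <- runif(n) < ifelse(label, config$discordance_pos,
                              config$discordance_neg)
    latent <- xor(label, flip)

    informative <- seq_len(config$n_informative)
    effect <- numeric(g)
    effect[informative] <- stats::rexp(config$n_informative,
                                       rate = 1 / max(config$effect_size *
                                                        config$noise_sd,
                                                      .Machine$double.eps))
    baseline <- rnorm(g, config$baseline_mean, config$baseline_sd)
    batch <- paste0("batch_", (seq_len(n) - 1) %% config$n_batches + 1)
    shift <- matrix(rnorm(g * config$n_batches, 0, config$batch_shift_sd),
                    g, config$n_batches)

    log2_expr <- matrix(rnorm(g * n, 0, config$noise_sd), g, n) + baseline +
      outer(effect, as.numeric(latent)) +
      shift[, match(batch, paste0("batch_", seq_len(config$n_batches)))]
    values <- 2^log2_expr - 10
    dimnames(values) <- list(gene_id, sample_id)

    structure(list(
      expr = expr_matrix(values, batch = setNames(batch, sample_id)),
      samples = tibble(sample_id = sample_id, label = label,
                       latent = latent, batch = batch),
      genes = tibble(gene_id = gene_id,
                     informative = seq_len(g) %in% informative,
                     effect = effect)
    ), class = "discovery_cohort")
  })
}

#' @export
print.discovery_cohort <- function(x, ...) {
  cat(sprintf("<discovery_cohort> %d genes x %d samples, %d label-positive\n",
              nrow(x$expr$values), ncol(x$expr$values), sum(x$samples$label)))
  invisible(x)
}

#' Configuration for simulated two-arm trial tables
#'
#' Describes a neoadjuvant two-arm cohort with a dichotomous biomarker:
#' fixed arm sizes, Bernoulli biomarker class, hormone-receptor status drawn
#' conditional on biomarker class (the strong confounding seen in such
#' cohorts), a tumour-size category distribution, and pathologic complete
#' response (pCR) probabilities indexed by arm and biomarker class. The
#' default response probabilities give a biomarker–response odds ratio of
#' about 3.2 in the experimental arm and 0.39 in the control arm.
#'
#' @param n_experimental,n_control Arm sizes (defaults 72, 44).
#' @param p_biomarker_pos Biomarker-positive probability (default 55/116).
#' @param p_hrpos_given_pos,p_hrpos_given_neg Probability of HR+ status
#'   given biomarker class (defaults 8/55 and 48/61).
#' @param pcr_prob Named list of response probabilities with exactly the
#'   four cells `experimental_pos`, `experimental_neg`, `control_pos`,
#'   `control_neg`.
#' @param tumor_size_probs Probabilities over the four tumour-size
#'   categories `0-1`, `>1-2`, `>2-5`, `>5` (cm); must sum to 1.
#' @param p_size_missing Probability that the tumour-size category is
#'   unrecorded (default 3/116).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `trial_sim_config` list.
#' @export
trial_sim_config <- function(n_experimental = 72, n_control = 44,
                             p_biomarker_pos = 55 / 116,
                             p_hrpos_given_pos = 8 / 55,
                             p_hrpos_given_neg = 48 / 61,
                             pcr_prob = list(experimental_pos = 0.516,
                                             experimental_neg = 0.25,
                                             control_pos = 0.143,
                                             control_neg = 0.30),
                             tumor_size_probs = c("0-1" = 0,
                                                  ">1-2" = 1 / 113,
                                                  ">2-5" = 71 / 113,
                                                  ">5" = 41 / 113),
                             p_size_missing = 3 / 116,
                             seed = NULL) {
  check_count(n_experimental, "n_experimental")
  check_count(n_control, "n_control")
  check_prob(p_biomarker_pos, "p_biomarker_pos")
  check_prob(p_hrpos_given_pos, "p_hrpos_given_pos")
  check_prob(p_hrpos_given_neg, "p_hrpos_given_neg")
  check_prob(p_size_missing, "p_size_missing")
  cells <- c("experimental_pos", "experimental_neg", "control_pos",
             "control_neg")
  if (!is.list(pcr_prob) || !setequal(names(pcr_prob), cells)) {
    missing_cells <- setdiff(cells, names(pcr_prob))
    abort(paste0("`pcr_prob` must have exactly the cells ",
                 paste(cells, collapse = ", "),
                 if (length(missing_cells)) {
                   paste0("; missing: ", paste(missing_cells,
                                               collapse = ", "))
                 }),
          class = "brcaness_config_error")
  }
  for (cl in cells) check_prob(pcr_prob[[cl]], paste0("pcr_prob$", cl))
  size_cats <- c("0-1", ">1-2", ">2-5", ">5")
  if (!is.numeric(tumor_size_probs) ||
      !setequal(names(tumor_size_probs), size_cats) ||
      any(tumor_size_probs < 0) ||
      abs(sum(tumor_size_probs) - 1) > 1e-8) {
    abort(paste0("`tumor_size_probs` must be non-negative over categories ",
                 paste(size_cats, collapse = ", "), " and sum to 1."),
          class = "brcaness_config_error")
  }
  structure(list(n_experimental = n_experimental, n_control = n_control,
                 p_biomarker_pos = p_biomarker_pos,
                 p_hrpos_given_pos = p_hrpos_given_pos,
                 p_hrpos_given_neg = p_hrpos_given_neg,
                 pcr_prob = pcr_prob,
                 tumor_size_probs = tumor_size_probs[size_cats],
                 p_size_missing = p_size_missing, seed = seed),
            class = "trial_sim_config")
}

#' Simulate a two-arm trial table
#'
#' @param config A [trial_sim_config()].
#' @return A `trial_table` tibble with columns `patient_id`, `arm`
#'   (control/experimental), `biomarker` (negative/positive), `hr_status`
#'   (HR+/TN), `tumor_size_cat` (may be `NA`) and `pcr` (0/1).
#' @export
simulate_trial <- function(config = trial_sim_config()) {
  if (!inherits(config, "trial_sim_config")) {
    abort("`config` must come from trial_sim_config().",
          class = "brcaness_config_error")
  }
  with_stream(config$seed, "trial", {
    n <- config$n_experimental + config$n_control
    arm <- factor(rep(c("experimental", "control"),
                      c(config$n_experimental, config$n_control)),
                  levels = c("control", "experimental"))
    positive <- runif(n) < config$p_biomarker_pos
    biomarker <- factor(ifelse(positive, "positive", "negative"),
                        levels = c("negative", "positive"))
    p_hr <- ifelse(positive, config$p_hrpos_given_pos,
                   config$p_hrpos_given_neg)
    hr_status <- factor(ifelse(runif(n) < p_hr, "HR+", "TN"),
                        levels = c("HR+", "TN"))
    size_cats <- names(config$tumor_size_probs)
    tumor_size_cat <- factor(
      sample(size_cats, n, replace = TRUE, prob = config$tumor_size_probs),
      levels = size_cats)
    tumor_size_cat[runif(n) < config$p_size_missing] <- NA
    cell <- paste0(ifelse(arm == "experimental", "experimental", "control"),
                   ifelse(positive, "_pos", "_neg"))
    p_pcr <- map_dbl(cell, ~ config$pcr_prob[[.x]])
    pcr <- as.integer(runif(n) < p_pcr)
    out <- tibble(patient_id = sprintf("patient_%03d", seq_len(n)),
                  arm = arm, biomarker = biomarker, hr_status = hr_status,
                  tumor_size_cat = tumor_size_cat, pcr = pcr)
    class(out) <- c("trial_table", class(out))
    out
  })
}
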