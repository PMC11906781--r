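# Seeded generator for synthetic LC-MS feature tables with the statistical
# structure the downstream analysis assumes: four treatment classes,
# biological and technical replicates, pooled QC samples, a rank-one batch
# component, per-replicate dilution and log-normal intensities. The returned
# ground truth is the oracle for recovery tests.

#' Simulation configuration
#'
#' All effects are additive on the log10 scale; intensities are
#' `10^(baseline + class shift + batch + noise) * dilution`, hence
#' log-normal and strictly positive.
#'
#' @param class_labels Treatment group labels; the first label is the
#'   control/reference class.
#' @param n_bio_per_class Biological replicates per class.
#' @param n_tech_reps Technical replicates per biological sample.
#' @param n_qc Pooled QC injections (no class effect).
#' @param n_features Total features.
#' @param n_informative Features carrying a class effect.
#' @param effect_size log10-scale mean shift of an informative feature in
#'   its affected class.
#' @param batch_sd SD of the per-sample scores of the rank-one batch
#'   component (log10 scale).
#' @param dilution_range `(lo, hi)` of the uniform per-technical-replicate
#'   multiplicative dilution factor, `0 < lo <= hi`.
#' @param noise_sd log10-scale residual SD.
#' @param baseline_mean,baseline_sd log10-scale feature baseline
#'   distribution.
#' @param seed Master seed; every random sub-stream derives from it.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(class_labels = c("CTRL", "M", "H2O2", "M+H2O2"),
                              n_bio_per_class = 5, n_tech_reps = 3,
                              n_qc = 6, n_features = 200,
                              n_informative = 20, effect_size = 1.0,
                              batch_sd = 0.5,
                              dilution_range = c(0.8, 1.25),
                              noise_sd = 0.1,
                              baseline_mean = 5, baseline_sd = 1,
                              seed = 1L) {
  counts <- c(length(class_labels), n_bio_per_class, n_tech_reps,
              n_features)
  if (any(counts < 1) || n_qc < 0) {
    stop("configuration error: counts must be >= 1 (n_qc >= 0)", call. = FALSE)
  }
  if (n_informative > n_features) {
    stop("configuration error: n_informative > n_features", call. = FALSE)
  }
  if (length(dilution_range) != 2 || dilution_range[1] <= 0 ||
      dilution_range[1] > dilution_range[2]) {
    stop("configuration error: dilution_range must satisfy 0 < lo <= hi",
         call. = FALSE)
  }
  if (effect_size < 0 || batch_sd < 0 || noise_sd < 0 || baseline_sd < 0) {
    stop("configuration error: scale parameters must be >= 0", call. = FALSE)
  }
  structure(list(class_labels = class_labels,
                 n_bio_per_class = n_bio_per_class,
                 n_tech_reps = n_tech_reps, n_qc = n_qc,
                 n_features = n_features, n_informative = n_informative,
                 effect_size = effect_size, batch_sd = batch_sd,
                 dilution_range = dilution_range, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# HMDB ids of the ten oxidative-stress metabolites used as example
# annotations; the first ten informative features borrow these ids so the
# enrichment stage has realistic input.
.EXAMPLE_HMDB <- c("HMDB0011773", "HMDB0000277", "HMDB0000965",
                   "HMDB0000192", "HMDB0000148", "HMDB0000224",
                   "HMDB0005765", "HMDB0000086", "HMDB0000269",
                   "HMDB0000251")

#' Generate a synthetic feature table with ground truth
#'
#' Treatment samples get their class's log10 shifts on the informative
#' features; each informative feature affects one non-control class
#' (cycling), with alternating shift sign. QC samples are drawn from the
#' global baseline profile — they receive batch, noise and dilution effects
#' but no class shift. The batch component is rank one: per-sample normal
#' scores times a fixed unit loading vector over features.
#'
#' @param config A [simulation_config()].
#' @return List with `table` (a [feature_table()]) and `truth` (class
#'   `ground_truth`: `informative_ids`, `class_shift_matrix`,
#'   `batch_loading` (unit norm), `batch_scores`, `dilution_factors`).
#' @export
generate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cls <- config$class_labels
  K <- length(cls)
  p <- config$n_features
  n_treat <- K * config$n_bio_per_class * config$n_tech_reps
  n <- n_treat + config$n_qc

  feature_ids <- sprintf("F%03d", seq_len(p))
  baseline <- stats::rnorm(p, config$baseline_mean, config$baseline_sd)

  # class shifts: informative feature t affects class 1 + (t mod (K-1)) + 1
  informative <- seq_len(config$n_informative)
  shift <- matrix(0, K, p, dimnames = list(cls, feature_ids))
  if (config$n_informative > 0 && K > 1) {
    for (t in informative) {
      affected <- 2L + (t - 1L) %% (K - 1L)
      shift[affected, t] <- config$effect_size * if (t %% 2L == 1L) 1 else -1
    }
  }

  bl <- stats::rnorm(p)
  batch_loading <- bl / sqrt(sum(bl^2))

  samples <- data.frame(
    sample_id = character(n), class = character(n),
    bio_rep = character(n), tech_rep = integer(n),
    qc = logical(n), injection_order = seq_len(n),
    stringsAsFactors = FALSE)
  i <- 0L
  class_of <- integer(n)
  for (k in seq_len(K)) for (b in seq_len(config$n_bio_per_class)) {
    for (tr in seq_len(config$n_tech_reps)) {
      i <- i + 1L
      samples$sample_id[i] <- sprintf("%s_b%d_t%d", cls[k], b, tr)
      samples$class[i] <- cls[k]
      samples$bio_rep[i] <- sprintf("%s_b%d", cls[k], b)
      samples$tech_rep[i] <- tr
      class_of[i] <- k
    }
  }
  for (q in seq_len(config$n_qc)) {
    i <- i + 1L
    samples$sample_id[i] <- sprintf("QC_%d", q)
    samples$class[i] <- "QC"
    samples$bio_rep[i] <- sprintf("QC_%d", q)
    samples$tech_rep[i] <- 1L
    samples$qc[i] <- TRUE
    class_of[i] <- 0L
  }

  batch_scores <- stats::rnorm(n, 0, config$batch_sd)
  dilution <- stats::runif(n, config$dilution_range[1],
                           config$dilution_range[2])
  noise <- matrix(stats::rnorm(n * p, 0, config$noise_sd), n, p)

  L <- matrix(baseline, n, p, byrow = TRUE)
  treat <- which(class_of > 0L)
  L[treat, ] <- L[treat, ] + shift[class_of[treat], , drop = FALSE]
  L <- L + outer(batch_scores, batch_loading) + noise
  X <- 10^L * dilution

  features <- data.frame(
    feature_id = feature_ids,
    mz = round(stats::runif(p, 70, 800), 5),
    rt_min = round(stats::runif(p, 0.5, 7.5), 3),
    hmdb_id = NA_character_,
    informative = seq_len(p) %in% informative,
    stringsAsFactors = FALSE)
  n_hmdb <- min(length(.EXAMPLE_HMDB), config$n_informative)
  if (n_hmdb > 0) features$hmdb_id[seq_len(n_hmdb)] <- .EXAMPLE_HMDB[seq_len(n_hmdb)]

  truth <- structure(list(
    informative_ids = feature_ids[informative],
    class_shift_matrix = shift[, informative, drop = FALSE],
    batch_loading = stats::setNames(batch_loading, feature_ids),
    batch_scores = stats::setNames(batch_scores, samples$sample_id),
    dilution_factors = stats::setNames(dilution, samples$sample_id),
    baseline = stats::setNames(baseline, feature_ids)),
    class = "ground_truth")

  list(table = feature_table(X, samples, features), truth = truth)
}

#' Add a monotone injection-order drift
#'
#' Emulates instrumental sensitivity drift over an analytical run: every
#' sample's intensities are multiplied by `10^(drift_sd * u)` where the `u`
#' are sorted uniform draws assigned in injection order, so the log10 drift
#' grows monotonically from 0 towards `drift_sd` across the run.
#'
#' @param table A `feature_table` containing at least one QC sample (QCs
#'   are what make drift diagnosable downstream).
#' @param drift_sd Scale of the drift on the log10 axis; 0 leaves the table
#'   unchanged.
#' @param seed Integer seed.
#' @return The drifted `feature_table` (injection order unchanged in the
#'   metadata).
#' @export
qc_drift <- function(table, drift_sd, seed = 1L) {
  stopifnot(inherits(table, "feature_table"), drift_sd >= 0)
  if (!any(table$samples$qc)) {
    stop("no QC samples in table; drift would be undiagnosable", call. = FALSE)
  }
  if (drift_sd == 0) return(table)
  set.seed(seed)
  n <- nrow(table$intensities)
  u <- sort(stats::runif(n))
  ord <- rank(table$samples$injection_order, ties.method = "first")
  factors <- 10^(drift_sd * u[ord])
  feature_table(table$intensities * factors, table$samples, table$features)
}
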