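#' @title Synthetic peptide tables with known ground truth
#' @name synthetic
#' @description Generates random tryptic-like peptide tables from a known
#'   retention-factor table and a known retention model, for parameter
#'   recovery and property testing.  The generator emulates the study
#'   conditions: a calibration-sized table (50 peptides), residue
#'   composition drawn from typical proteome frequencies, descriptors
#'   computed exactly from the generating factors, retention times equal to
#'   the true model prediction plus Gaussian noise at the calibration
#'   residual scale (1.45 min), and Xcorr scores drawn from separated
#'   true/false-match distributions.
NULL

# approximate residue frequencies in a generic bacterial proteome
RESIDUE_FREQ <- c(A = 0.083, R = 0.057, N = 0.044, D = 0.054, C = 0.012,
                  E = 0.062, Q = 0.040, G = 0.072, H = 0.022, I = 0.059,
                  L = 0.097, K = 0.058, M = 0.024, F = 0.039, P = 0.046,
                  S = 0.066, T = 0.054, W = 0.011, Y = 0.029, V = 0.069)

#' Configuration for the synthetic generator
#'
#' @param n_peptides Number of rows (default 50, the calibration-set size).
#' @param length_range Min/max peptide length (default 5-30 residues,
#'   spanning the bundled tables).
#' @param k_table Generating `retention_factors` table (default the solved
#'   package table).
#' @param model Generating `qsrr_model` (default the published reference
#'   coefficients).
#' @param sigma Gaussian retention-time noise, min (default 1.45, the
#'   calibration residual standard error).
#' @param clogp_mean,clogp_sd Normal distribution of the supplied clogP
#'   column (defaults -4 and 2, spanning the bundled range).
#' @param prop_true Proportion of records simulated as true matches.
#' @param xcorr_true,xcorr_false Mean/sd pairs of the (truncated-at-zero)
#'   normal Xcorr distributions for true and false matches.
#' @param residue_freq Named sampling weights over the 20 residues.
#' @param seed Integer seed; fully determines the output.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_peptides = 50L,
                             length_range = c(5L, 30L),
                             k_table = default_retention_factors(),
                             model = published_model(),
                             sigma = 1.45,
                             clogp_mean = -4, clogp_sd = 2,
                             prop_true = 0.7,
                             xcorr_true = c(mean = 3.5, sd = 0.8),
                             xcorr_false = c(mean = 1.2, sd = 0.5),
                             residue_freq = RESIDUE_FREQ,
                             seed = 1L) {
  stopifnot(n_peptides >= 1L, sigma >= 0,
            length_range[1] >= 1L, length_range[2] >= length_range[1],
            prop_true >= 0, prop_true <= 1,
            inherits(k_table, "retention_factors"),
            inherits(model, "qsrr_model"))
  structure(list(n_peptides = as.integer(n_peptides),
                 length_range = as.integer(length_range),
                 k_table = k_table, model = model, sigma = sigma,
                 clogp_mean = clogp_mean, clogp_sd = clogp_sd,
                 prop_true = prop_true,
                 xcorr_true = xcorr_true, xcorr_false = xcorr_false,
                 residue_freq = residue_freq, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic peptide table
#'
#' Peptides are random sequences ending in K or R (tryptic C-terminus);
#' `log_sum_k1` is computed exactly from the generating factor table,
#' `t_r_exp` is the true model prediction plus `N(0, sigma^2)` noise, and
#' each record carries a hidden true/false label determining its Xcorr
#' distribution.  Identical configurations (same seed) give identical
#' tables.
#'
#' @param cfg A `synthetic_config`.
#' @return A list with `table` (a peptide table, stage `"descriptors"`)
#'   and `truth` (the generating `k_table`, `model`, per-row `is_true`
#'   labels and noiseless `t_r_true`).
#' @export
generate_synthetic <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_peptides
  lens <- sample(seq(cfg$length_range[1], cfg$length_range[2]), n,
                 replace = TRUE)
  freq <- cfg$residue_freq[AA_CODES]
  seqs <- vapply(lens, function(L) {
    body <- sample(AA_CODES, L - 1L, replace = TRUE, prob = freq)
    paste0(paste(body, collapse = ""), sample(c("K", "R"), 1L))
  }, character(1))
  ls1 <- vapply(seqs, log_sum_descriptor, numeric(1), kt = cfg$k_table,
                USE.NAMES = FALSE)
  clogp <- stats::rnorm(n, cfg$clogp_mean, cfg$clogp_sd)
  t_true <- predict_rt(cfg$model, ls1, clogp)
  t_exp <- t_true + stats::rnorm(n, 0, cfg$sigma)
  is_true <- stats::runif(n) < cfg$prop_true
  xc <- ifelse(is_true,
               stats::rnorm(n, cfg$xcorr_true["mean"], cfg$xcorr_true["sd"]),
               stats::rnorm(n, cfg$xcorr_false["mean"], cfg$xcorr_false["sd"]))
  xc <- pmax(xc, 0)
  charge <- sample(1:3, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  masses <- amino_acid_masses()
  tab <- data.frame(
    protein = sprintf("synthetic_%03d", seq_len(n)),
    peptide_sequence = seqs,
    mz = vapply(seq_len(n), function(i) mz(seqs[i], charge[i], masses),
                numeric(1)),
    charge = charge,
    xcorr = xc,
    missed_cleavages = vapply(seqs, count_missed_cleavages, integer(1),
                              USE.NAMES = FALSE),
    clogp = clogp,
    log_sum_k1 = ls1,
    t_r_exp = t_exp,
    stringsAsFactors = FALSE
  )
  table_stage(tab) <- "descriptors"
  list(table = tab,
       truth = list(k_table = cfg$k_table, model = cfg$model,
                    is_true = is_true, t_r_true = t_true))
}
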