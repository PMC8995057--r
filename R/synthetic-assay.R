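#' Simulate a saturating-exponential calibration table
#'
#' Generates replicate immunoassay signals following the saturating
#' exponential used throughout the package,
#' \deqn{S(c) = S_\infty - (S_\infty - S_0)\, e^{-kc},}
#' with additive Gaussian replicate noise.  Blank (c = 0) replicates are
#' included whenever 0 is among `concentrations`, as they must be for
#' blank-based LOD estimation.
#'
#' @param s0 blank asymptote (signal at c = 0), a.u.
#' @param s_inf saturation asymptote, a.u.; must exceed `s0`.
#' @param k rate constant per concentration unit (> 0).
#' @param concentrations non-negative concentrations (include 0 for blanks).
#' @param reps replicates per concentration.
#' @param noise_sd replicate noise s.d., a.u.
#' @param rng_seed integer seed.
#' @return data.frame with columns `concentration`, `replicate`, `signal`.
#' @seealso [fit_calibration()], [lod()]
#' @export
simulate_calibration <- function(s0, s_inf, k, concentrations, reps = 3L,
                                 noise_sd = 0, rng_seed = NULL) {
  if (s_inf <= s0) stop("'s_inf' must exceed 's0'")
  if (k <= 0) stop("'k' must be positive")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  stopifnot(reps >= 1L)
  conc <- rep(concentrations, each = reps)
  mu <- s_inf - (s_inf - s0) * exp(-k * conc)
  sig <- with_seed(rng_seed, mu + rnorm(length(mu), sd = noise_sd))
  data.frame(concentration = conc,
             replicate = rep(seq_len(reps), times = length(concentrations)),
             signal = sig)
}

#' Parameters for a two-population diagnostic cohort
#'
#' Scores are drawn from two log-normal distributions (normal on the log
#' scale), the usual shape of serum-biomarker readouts: `mu_*` and
#' `sigma_*` are the log-scale means and s.d.s.  Defaults use the diseased
#' versus healthy cohort sizes typical of a single-centre pilot
#' (50 positive / 19 negative).
#'
#' @param n_pos,n_neg subject counts (>= 1).
#' @param mu_pos,mu_neg log-scale means.
#' @param sigma_pos,sigma_neg log-scale s.d.s (> 0).
#' @param rng_seed integer seed.
#' @return list of class `cohort_params`.
#' @export
cohort_params <- function(n_pos = 50L, n_neg = 19L, mu_pos = 1.5,
                          mu_neg = 0, sigma_pos = 0.6, sigma_neg = 0.6,
                          rng_seed = NULL) {
  stopifnot(n_pos >= 1L, n_neg >= 1L)
  if (sigma_pos <= 0 || sigma_neg <= 0) stop("sigmas must be positive")
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 mu_pos = mu_pos, mu_neg = mu_neg,
                 sigma_pos = sigma_pos, sigma_neg = sigma_neg,
                 rng_seed = rng_seed),
            class = "cohort_params")
}

#' Simulate a labelled diagnostic cohort
#'
#' @param params a [cohort_params()] object.
#' @return data.frame with columns `subject`, `label` ("positive" /
#'   "negative"), `score`.
#' @seealso [roc_curve()]
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  with_seed(params$rng_seed, {
    pos <- rlnorm(params$n_pos, params$mu_pos, params$sigma_pos)
    neg <- rlnorm(params$n_neg, params$mu_neg, params$sigma_neg)
    data.frame(
      subject = sprintf("S%03d", seq_len(params$n_pos + params$n_neg)),
      label = rep(c("positive", "negative"), c(params$n_pos, params$n_neg)),
      score = c(pos, neg))
  })
}
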