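#' Fluorescence enhancement factor
#'
#' Ratio of background-subtracted fluorescence on the plasmonic substrate to
#' that on the plain reference substrate,
#' \deqn{EF = \frac{FI_{sample} - BKGD_{sample}}{FI_{ref} - BKGD_{ref}}.}
#' EF is dimensionless and invariant under a common rescaling of all four
#' intensities.  A non-positive numerator is reported as EF = 0; any EF
#' below 1 (no net enhancement, i.e. quenching) is flagged rather than
#' dropped.
#'
#' @param fi_sample,bkgd_sample fluorescence and background intensity on the
#'   enhancing substrate (a.u.); vectorized.
#' @param fi_ref,bkgd_ref the same on the reference substrate; the
#'   background-subtracted reference must be positive.
#' @return numeric EF vector with logical attribute `quenched` (EF < 1).
#' @examples
#' enhancement_factor(1100, 100, 120, 100)  # 50-fold enhancement
#' @export
enhancement_factor <- function(fi_sample, bkgd_sample, fi_ref, bkgd_ref) {
  den <- fi_ref - bkgd_ref
  if (any(den <= 0))
    stop("non-positive reference signal after background subtraction")
  num <- fi_sample - bkgd_sample
  ef <- pmax(num, 0) / den
  attr(ef, "quenched") <- ef < 1
  ef
}

#' Assemble a conditions x channels enhancement-factor matrix
#'
#' Computes EF per record, averages replicates of the same
#' (condition, channel) cell (retaining the sample s.d.), and pivots to a
#' wide matrix.  Condition-level covariates (e.g. ordinal seeding-density
#' level, precursor level, reducing-power score) are carried along for use
#' as PCA variables.
#'
#' @param records data.frame in long format with columns `condition`,
#'   `channel`, `fi_sample`, `bkgd_sample`, `fi_ref`, `bkgd_ref`, plus any
#'   numeric covariate columns.
#' @return list of class `ef_matrix` with `ef` (conditions x channels
#'   matrix), `sd` (replicate s.d., NA for singletons), `covariates`
#'   (data.frame, one row per condition), and `complete` (logical per
#'   condition: no missing channel).
#' @export
build_ef_matrix <- function(records) {
  req <- c("condition", "channel", "fi_sample", "bkgd_sample",
           "fi_ref", "bkgd_ref")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  records$ef <- as.numeric(enhancement_factor(
    records$fi_sample, records$bkgd_sample,
    records$fi_ref, records$bkgd_ref))
  conds <- unique(as.character(records$condition))
  chans <- unique(as.character(records$channel))
  ef <- sdm <- matrix(NA_real_, length(conds), length(chans),
                      dimnames = list(conds, chans))
  for (i in seq_along(conds)) for (j in seq_along(chans)) {
    v <- records$ef[records$condition == conds[i] &
                      records$channel == chans[j]]
    if (length(v)) {
      ef[i, j] <- mean(v)
      sdm[i, j] <- if (length(v) > 1L) sd(v) else NA_real_
    }
  }
  covar_cols <- setdiff(names(records),
                        c(req, "ef", "replicate"))
  covariates <- NULL
  if (length(covar_cols)) {
    covariates <- unique(records[, c("condition", covar_cols), drop = FALSE])
    covariates <- covariates[match(conds, covariates$condition), ,
                             drop = FALSE]
    rownames(covariates) <- conds
  }
  complete <- !apply(is.na(ef), 1L, any)
  if (any(!complete))
    warning("conditions with missing channels excluded from PCA: ",
            paste(conds[!complete], collapse = ", "))
  structure(list(ef = ef, sd = sdm, covariates = covariates,
                 complete = complete),
            class = "ef_matrix")
}

#' @export
print.ef_matrix <- function(x, ...) {
  cat(sprintf("<ef_matrix> %d conditions x %d channels\n",
              nrow(x$ef), ncol(x$ef)))
  print(round(x$ef, 2))
  invisible(x)
}

#' Correlation-matrix PCA of enhancement factors with Kaiser-Guttman retention
#'
#' Standardizes the variables (EF channels and any numeric covariates), so
#' the analysis runs on the correlation matrix and the eigenvalues sum to
#' the number of variables; components with eigenvalue strictly greater
#' than 1 are retained (the Kaiser-Guttman rule for standardized
#' variables).
#'
#' @param x an [build_ef_matrix()] result, or a plain numeric matrix /
#'   data.frame (rows = conditions, columns = variables).
#' @param include_covariates include the covariate columns of an
#'   `ef_matrix` as additional variables (default `TRUE`).
#' @return list of class `pca_summary` with `eigenvalues`,
#'   `variance_explained`, `scores`, `loadings`, and `retained`.
#' @export
pca_summary <- function(x, include_covariates = TRUE) {
  if (inherits(x, "ef_matrix")) {
    m <- x$ef[x$complete, , drop = FALSE]
    if (include_covariates && !is.null(x$covariates)) {
      cov_num <- x$covariates[x$complete, -1L, drop = FALSE]
      cov_num <- cov_num[, vapply(cov_num, is.numeric, TRUE), drop = FALSE]
      if (ncol(cov_num)) m <- cbind(m, as.matrix(cov_num))
    }
  } else m <- as.matrix(x)
  if (nrow(m) < 3L) stop("need at least 3 complete rows for PCA")
  if (ncol(m) < 2L) stop("need at least 2 variables for PCA")
  sds <- apply(m, 2L, sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  p <- prcomp(m, center = TRUE, scale. = TRUE)
  ev <- p$sdev^2
  structure(list(eigenvalues = ev,
                 variance_explained = ev / sum(ev),
                 scores = p$x,
                 loadings = p$rotation,
                 retained = sum(ev > 1)),
            class = "pca_summary")
}

#' @export
print.pca_summary <- function(x, ...) {
  cat(sprintf("<pca_summary> %d variables; %d retained (eigenvalue > 1)\n",
              length(x$eigenvalues), x$retained))
  cat("eigenvalues:", paste(sprintf("%.3f", x$eigenvalues), collapse = " "),
      "\n")
  cat(sprintf("variance explained by retained components: %.1f%%\n",
              100 * sum(x$variance_explained[seq_len(x$retained)])))
  invisible(x)
}

#' Spectral overlap between substrate extinction and fluorophore emission
#'
#' Quantifies how much of a fluorophore's emission band falls under the
#' substrate's extinction spectrum:
#' \deqn{\mathrm{overlap} = \int \hat{E}(\lambda) F(\lambda)\,d\lambda
#'   \big/ \int F(\lambda)\,d\lambda,}
#' with the extinction peak-normalized to 1 and trapezoidal integration on
#' the emission wavelength grid.  The result is in \[0, 1\]; disjoint
#' wavelength supports give 0 with a warning.
#'
#' @param extinction data.frame with columns `wavelength`, `value`
#'   (non-negative).
#' @param emission data.frame with columns `wavelength`, `value`
#'   (non-negative, not all zero).
#' @return overlap fraction in \[0, 1\].
#' @export
spectral_overlap <- function(extinction, emission) {
  for (s in list(extinction, emission))
    if (!all(c("wavelength", "value") %in% names(s)))
      stop("spectra need 'wavelength' and 'value' columns")
  if (any(extinction$value < 0) || any(emission$value < 0))
    stop("spectral values must be non-negative")
  if (sum(emission$value) == 0) stop("emission spectrum is all zero")
  ext <- extinction[order(extinction$wavelength), ]
  emi <- emission[order(emission$wavelength), ]
  if (max(ext$wavelength) < min(emi$wavelength) ||
      min(ext$wavelength) > max(emi$wavelength)) {
    warning("disjoint wavelength supports: overlap is 0")
    return(0)
  }
  ehat <- ext$value / max(ext$value)
  e_on_f <- approx(ext$wavelength, ehat, xout = emi$wavelength,
                   rule = 1)$y
  e_on_f[is.na(e_on_f)] <- 0
  trapz(emi$wavelength, e_on_f * emi$value) /
    trapz(emi$wavelength, emi$value)
}
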