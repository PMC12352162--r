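#' Assemble per-experiment covariates for the explanatory GLM
#'
#' The covariates: `e_type` electrode type (depth = 0, subdural = 1),
#' `e_num` number of contacts, `hg` / `beta` mean burst SNR per band,
#' `recall_p` the experiment's correct-recall probability, `trials` the
#' word-trial count, and the response `auroc`.  The burst SNRs feed only
#' this model, never the decoders.
#'
#' @param e_type 0 (depth) or 1 (subdural).
#' @param e_num Contact count (>= 1).
#' @param snr_hg,snr_beta Per-channel SNR vectors (averaged here) or
#'   scalars.
#' @param recall_p Correct recall probability in \[0, 1\].
#' @param trials Word-trial count (>= 1).
#' @param auroc Decoder AUROC in \[0, 1\].
#' @return One-row data frame (an `experiment_summary`).
#' @export
summarize_experiment <- function(e_type, e_num, snr_hg, snr_beta, recall_p,
                                 trials, auroc) {
  args <- list(e_type = e_type, e_num = e_num, snr_hg = snr_hg,
               snr_beta = snr_beta, recall_p = recall_p, trials = trials,
               auroc = auroc)
  bad <- names(args)[vapply(args, function(a)
    length(a) == 0 || anyNA(a), TRUE)]
  if (length(bad))
    stop("missing or NA field(s): ", paste(bad, collapse = ", "))
  stopifnot(e_type %in% c(0, 1), e_num >= 1, trials >= 1,
            recall_p >= 0, recall_p <= 1, auroc >= 0, auroc <= 1)
  data.frame(e_type = e_type, e_num = e_num, hg = mean(snr_hg),
             beta = mean(snr_beta), recall_p = recall_p, trials = trials,
             auroc = auroc)
}

#' The default GLM design: 41 curated interaction terms
#'
#' The design couples electrode type, contact count, band SNRs, recall
#' probability and trial count through a curated subset of their
#' interactions (not the complete 6-factor factorial), headlined by the
#' four-way `e_num:hg:beta:recall_p` term.
#'
#' @return Character vector of term labels.
#' @export
glm_terms_default <- function() {
  c("e_type", "e_num", "hg", "beta", "recall_p", "trials",
    "e_type:e_num", "e_type:hg", "e_num:hg", "e_type:beta", "e_num:beta",
    "hg:beta", "e_type:recall_p", "e_num:recall_p", "hg:recall_p",
    "beta:recall_p", "e_type:trials", "e_num:trials", "hg:trials",
    "beta:trials", "recall_p:trials",
    "e_type:e_num:hg", "e_type:e_num:beta", "e_num:hg:beta",
    "e_type:e_num:recall_p", "e_num:hg:recall_p", "hg:beta:recall_p",
    "e_type:e_num:trials", "e_num:hg:trials", "hg:recall_p:trials",
    "beta:recall_p:trials",
    "e_type:e_num:hg:beta", "e_type:e_num:hg:recall_p",
    "e_num:hg:beta:recall_p", "e_type:e_num:hg:trials",
    "e_num:hg:beta:trials", "hg:beta:recall_p:trials",
    "e_type:e_num:hg:beta:recall_p", "e_type:e_num:hg:beta:trials",
    "e_num:hg:beta:recall_p:trials",
    "e_type:e_num:hg:beta:recall_p:trials")
}

#' Fit the normal-identity GLM explaining decoder AUROC
#'
#' Ordinary least squares (gaussian family, identity link, fixed
#' intercept) of AUROC on the experiment covariates with the configured
#' interaction terms; continuous covariates enter raw.  Reports per-term
#' estimates, standard errors, t statistics and p-values, plus the
#' whole-model F test against the intercept-only model.  No random
#' effects.
#'
#' @param summaries Data frame of [summarize_experiment()] rows.
#' @param terms Character vector of term labels (default
#'   [glm_terms_default()]).
#' @param full_factorial If `TRUE`, use the complete 6-factor factorial
#'   (`(e_type + e_num + hg + beta + recall_p + trials)^6`) instead.
#' @return A `glm_fit` list: `coefficients` data frame (Name, Estimate,
#'   SE, tStat, p_value), `F`, `df1`, `df2`, `p_model`, and the underlying
#'   `stats::glm` object as `fit`.
#' @export
fit_auroc_glm <- function(summaries, terms = glm_terms_default(),
                          full_factorial = FALSE) {
  need <- c("e_type", "e_num", "hg", "beta", "recall_p", "trials", "auroc")
  miss <- setdiff(need, names(summaries))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  rhs <- if (full_factorial)
    "(e_type + e_num + hg + beta + recall_p + trials)^6"
  else paste(terms, collapse = " + ")
  n <- nrow(summaries)
  form <- stats::as.formula(paste("auroc ~", rhs))
  n_terms <- length(attr(stats::terms(form), "term.labels"))
  if (n <= n_terms + 1)
    stop("need more experiments (", n, ") than model terms (", n_terms + 1,
         ")")
  fit <- stats::glm(form, data = summaries, family = gaussian("identity"))
  if (fit$rank < length(coef(fit))) {
    aliased <- names(coef(fit))[is.na(coef(fit))]
    stop("design is rank deficient; collinear term(s): ",
         paste(aliased, collapse = ", "))
  }
  sm <- summary(fit)
  ct <- as.data.frame(sm$coefficients)
  names(ct) <- c("Estimate", "SE", "tStat", "p_value")
  ct <- cbind(Name = rownames(ct), ct)
  rownames(ct) <- NULL
  # whole-model F against the intercept-only model
  rss <- sum(fit$residuals^2)
  tss <- sum((summaries$auroc - mean(summaries$auroc))^2)
  df1 <- fit$rank - 1
  df2 <- n - fit$rank
  Fstat <- ((tss - rss) / df1) / (rss / df2)
  structure(list(coefficients = ct, F = Fstat, df1 = df1, df2 = df2,
                 p_model = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
                 fit = fit),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("Normal-identity GLM: F(%d, %d) = %.3g, p = %.3g\n",
              x$df1, x$df2, x$F, x$p_model))
  top <- x$coefficients[order(x$coefficients$p_value), ][1:min(5, nrow(x$coefficients)), ]
  print(top, row.names = FALSE, digits = 3)
  invisible(x)
}
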