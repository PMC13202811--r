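#' Linear epigenetic clock definition
#'
#' A pan-tissue-style clock: an intercept, per-CpG weights, and the adult-age
#' constant of the calibrated age transform.
#'
#' @param intercept linear-predictor intercept.
#' @param weights named numeric vector (names are CpG ids).
#' @param adult_age the transform knot in years (20 for the pan-tissue clock).
#' @return An `mm_clock` object.
#' @export
clock_definition <- function(intercept, weights, adult_age = 20) {
  mm_assert(length(weights) >= 1, "a clock needs at least one weighted CpG")
  mm_assert(!is.null(names(weights)) && all(nzchar(names(weights))),
            "`weights` must be named by CpG id")
  structure(list(intercept = intercept, weights = weights,
                 adult_age = adult_age),
            class = "mm_clock")
}

#' @export
print.mm_clock <- function(x, ...) {
  cat(sprintf("<mm_clock> %d CpGs, intercept %.4g, adult age %.3g\n",
              length(x$weights), x$intercept, x$adult_age))
  invisible(x)
}

#' Calibrated age transform and its inverse
#'
#' The clock is trained on transformed age
#' \eqn{F(a) = \log((a+1)/(A+1))} for \eqn{a \le A} and
#' \eqn{F(a) = (a-A)/(A+1)} above, with adult age \eqn{A}; the inverse maps a
#' linear predictor back to years: \eqn{(A+1)e^L - 1} for \eqn{L < 0} and
#' \eqn{(A+1)L + A} otherwise.
#'
#' @param age chronological age in years.
#' @param adult_age the knot \eqn{A}.
#' @return Transformed age (forward) or years (inverse).
#' @export
horvath_forward <- function(age, adult_age = 20) {
  ifelse(age <= adult_age,
         log((age + 1) / (adult_age + 1)),
         (age - adult_age) / (adult_age + 1))
}

#' @rdname horvath_forward
#' @param L linear predictor value(s).
#' @export
horvath_inverse <- function(L, adult_age = 20) {
  ifelse(L < 0, (adult_age + 1) * exp(L) - 1, (adult_age + 1) * L + adult_age)
}

#' Apply a linear epigenetic clock
#'
#' Computes the linear predictor `intercept + sum(w_i * beta_i)` per sample
#' and maps it to years with [horvath_inverse()]. At least 80% of the clock's
#' CpGs must be present in the matrix; any missing remainder is imputed with
#' the per-sample mean of the available clock CpGs (reported via a message).
#'
#' @param beta CpG x samples Beta-value matrix.
#' @param clock an [clock_definition()].
#' @return Named numeric vector of epigenetic ages (years).
#' @export
apply_clock <- function(beta, clock) {
  mm_assert(inherits(clock, "mm_clock"), "`clock` must be an mm_clock")
  beta <- as.matrix(beta)
  ids <- names(clock$weights)
  present <- ids %in% rownames(beta)
  mm_assert(mean(present) >= 0.8,
            "more than 20% of clock CpGs are missing from the matrix")
  W <- clock$weights[present]
  Bm <- beta[ids[present], , drop = FALSE]
  L <- clock$intercept + as.numeric(t(Bm) %*% W)
  if (any(!present)) {
    message(sum(!present), " clock CpG(s) imputed with per-sample means")
    L <- L + sum(clock$weights[!present]) * colMeans(Bm)
  }
  stats::setNames(horvath_inverse(L, clock$adult_age), colnames(beta))
}

#' Epigenetic age deviation
#'
#' EAD is the residual of the least-squares regression of epigenetic age on
#' chronological age; it is invariant to affine rescaling of the epigenetic
#' ages and sums to zero by construction.
#'
#' @param epi_age epigenetic ages (years).
#' @param chron_age chronological ages (years).
#' @return An `mm_epiage` list: `table` tibble (`sample_id`, `epi_age`,
#'   `chron_age`, `ead`), `r` (Pearson correlation), `mae` (median absolute
#'   error in years).
#' @export
compute_ead <- function(epi_age, chron_age) {
  mm_assert(length(epi_age) == length(chron_age), "length mismatch")
  mm_assert(length(epi_age) >= 3, "need at least 3 samples")
  mm_assert(stats::var(chron_age) > 0, "chronological age must vary")
  fit <- stats::lm(epi_age ~ chron_age)
  structure(list(
    table = tibble::tibble(
      sample_id = names(epi_age) %||% as.character(seq_along(epi_age)),
      epi_age = unname(epi_age), chron_age = unname(chron_age),
      ead = unname(stats::residuals(fit))),
    r = stats::cor(epi_age, chron_age),
    mae = stats::median(abs(epi_age - chron_age))),
    class = "mm_epiage")
}

#' @export
print.mm_epiage <- function(x, ...) {
  cat(sprintf("<mm_epiage> n = %d, r = %.3f, MAE = %.2f years\n",
              nrow(x$table), x$r, x$mae))
  invisible(x)
}

#' Pairwise cluster contrasts of epigenetic age deviation
#'
#' Least-squares fit of EAD on cell-means cluster indicators plus covariates;
#' all pairwise differences of the cluster coefficients with t-based
#' two-sided p-values (equivalent to marginal-means contrasts in the
#' no-interaction model). With no covariates and balanced groups the
#' contrasts are simple differences of group means.
#'
#' @param ead per-sample EAD values (or an `mm_epiage`).
#' @param labels cluster labels.
#' @param covariates optional covariate matrix/data frame (no intercept
#'   needed; cluster indicators span it).
#' @return A tibble: `contrast`, `cluster_a`, `cluster_b`, `estimate`, `se`,
#'   `df`, `p`.
#' @export
ead_cluster_contrasts <- function(ead, labels, covariates = NULL) {
  if (inherits(ead, "mm_epiage")) ead <- ead$table$ead
  mm_assert(length(ead) == length(labels), "`ead` and `labels` must align")
  clusters <- sort(unique(labels))
  k <- length(clusters)
  mm_assert(all(table(labels) >= 1), "every cluster must be non-empty")
  X <- sapply(clusters, function(cl) as.numeric(labels == cl))
  colnames(X) <- paste0("cluster", clusters)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  fit <- stats::lm.fit(X, ead)
  df <- length(ead) - fit$rank
  s2 <- sum(fit$residuals^2) / df
  XtXi <- chol2inv(chol(crossprod(X)))
  pairs <- utils::combn(k, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    est <- fit$coefficients[a] - fit$coefficients[b]
    se <- sqrt(s2 * (XtXi[a, a] + XtXi[b, b] - 2 * XtXi[a, b]))
    tibble::tibble(contrast = paste0(clusters[a], "_vs_", clusters[b]),
                   cluster_a = clusters[a], cluster_b = clusters[b],
                   estimate = unname(est), se = se, df = df,
                   p = 2 * stats::pt(-abs(est / se), df))
  })
}

#' Taxa associations with epigenetic age deviation
#'
#' Differential-abundance regression of genus counts on EAD (exposure in
#' years, not IQR-scaled, so effects read as logFC per year of EAD), with the
#' same sampling-fraction offset, covariate adjustment, BH correction across
#' taxa and pseudo-count sensitivity analysis as [pseudocount_sensitivity()].
#'
#' @param cm genus-level, prevalence-filtered [count_matrix()].
#' @param ead per-sample EAD values (or an `mm_epiage`).
#' @param covariates optional covariates (no cluster columns).
#' @param pseudo_counts pseudo-count array; the largest is the primary.
#' @param alpha FDR level for the sensitivity flags.
#' @return A DA result tibble (see [pseudocount_sensitivity()]).
#' @export
ead_taxa_association <- function(cm, ead, covariates = NULL,
                                 pseudo_counts = c(0.1, 0.5, 1.0),
                                 alpha = 0.05) {
  if (inherits(ead, "mm_epiage")) ead <- ead$table$ead
  pseudocount_sensitivity(cm, exposure = ead, covariates = covariates,
                          pseudo_counts = pseudo_counts, alpha = alpha,
                          scale_exposure = FALSE)
}
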