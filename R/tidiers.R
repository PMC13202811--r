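#' Tidy a PAM cluster solution
#'
#' @param x an `mm_pam`.
#' @param ... unused.
#' @return A tibble: `sample_id`, `cluster`, `is_medoid`.
#' @export
tidy.mm_pam <- function(x, ...) {
  tibble::tibble(sample_id = x$sample_ids,
                 cluster = x$labels,
                 is_medoid = x$sample_ids %in% x$medoid_ids)
}

#' @rdname tidy.mm_pam
#' @return For `glance()`: a one-row tibble with `k`, `n`, `total_cost`,
#'   `metric`.
#' @export
glance.mm_pam <- function(x, ...) {
  tibble::tibble(k = x$k, n = length(x$labels), total_cost = x$total_cost,
                 metric = x$metric %||% NA_character_)
}

#' Tidy an EWAS fit
#'
#' @param x an `mm_ewas_fit`.
#' @param ... unused.
#' @return A long tibble of per-CpG coefficients: `cpg_id`, `term`,
#'   `estimate`, `std_error`.
#' @export
tidy.mm_ewas_fit <- function(x, ...) {
  s <- if (x$moderated) sqrt(x$s2_post) else x$sigma
  co <- x$coefficients
  tibble::tibble(
    cpg_id = rep(x$cpg_ids, times = ncol(co)),
    term = rep(colnames(co), each = nrow(co)),
    estimate = as.numeric(co),
    std_error = as.numeric(x$stdev_unscaled * s))
}

#' @rdname tidy.mm_ewas_fit
#' @return For `glance()`: a one-row tibble with `n_cpgs`, `df_residual`,
#'   `moderated`, `d0`, `s02`.
#' @export
glance.mm_ewas_fit <- function(x, ...) {
  tibble::tibble(n_cpgs = nrow(x$coefficients),
                 df_residual = x$df_residual,
                 moderated = x$moderated,
                 d0 = if (x$moderated) x$d0 else NA_real_,
                 s02 = if (x$moderated) x$s02 else NA_real_)
}

#' Tidy an epigenetic-age result
#'
#' @param x an `mm_epiage`.
#' @param ... unused.
#' @return The per-sample tibble (`sample_id`, `epi_age`, `chron_age`,
#'   `ead`).
#' @export
tidy.mm_epiage <- function(x, ...) x$table

#' @rdname tidy.mm_epiage
#' @return For `glance()`: one row with `n`, `r`, `mae`.
#' @export
glance.mm_epiage <- function(x, ...) {
  tibble::tibble(n = nrow(x$table), r = x$r, mae = x$mae)
}

#' Tidy a permutation-null result
#'
#' @param x an `mm_perm`.
#' @param ... unused.
#' @return A tibble of per-permutation DMP counts.
#' @export
tidy.mm_perm <- function(x, ...) {
  tibble::tibble(permutation = seq_len(x$B), dmp_count = x$perm_counts)
}

#' @rdname tidy.mm_perm
#' @export
glance.mm_perm <- function(x, ...) {
  tibble::tibble(observed = x$observed, B = x$B,
                 empirical_p = x$empirical_p)
}
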