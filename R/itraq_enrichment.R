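#' Detection filter for iTRAQ IP-MS records
#'
#' Removes contaminant and reverse hits, then keeps proteins with at least
#' two unique quantified peptides and at least two ratio observations in
#' *each* of the two channel pairs (116/114 and 117/115) — the "detected"
#' definition for the two-replicate immunoprecipitation design.
#'
#' @param records iTRAQ record tibble from [read_itraq_table()] or
#'   [simulate_itraq()].
#' @param min_peptides Minimum unique quantified peptides. Default 2.
#' @param min_ratios Minimum observations per channel pair. Default 2.
#' @return Filtered tibble, row order preserved.
#' @export
filter_itraq <- function(records, min_peptides = 2L, min_ratios = 2L) {
  dplyr::filter(records,
                !.data$is_contaminant, !.data$is_reverse,
                .data$unique_quantified_peptides >= min_peptides,
                lengths(.data$ratios_116_114) >= min_ratios,
                lengths(.data$ratios_117_115) >= min_ratios)
}

#' Median-normalize iTRAQ ratios and take log2
#'
#' Within each channel pair independently, every ratio observation is
#' divided by the grand median of all of that channel pair's observations
#' pooled across proteins, then log2-transformed. This removes channel-level
#' mixing/labeling offsets so that an unenriched protein is centered at 0.
#'
#' @param records Detected iTRAQ records (see [filter_itraq()]).
#' @return The records with added list-columns `log2_116_114`,
#'   `log2_117_115` and attribute `channel_median` (named vector of the two
#'   grand medians of raw ratios).
#' @export
median_normalize_itraq <- function(records) {
  med <- vapply(c("ratios_116_114", "ratios_117_115"), function(col) {
    pooled <- unlist(records[[col]])
    if (length(pooled) == 0) {
      stop("no ratio observations in channel '", col, "'", call. = FALSE)
    }
    stats::median(pooled)
  }, numeric(1))
  out <- dplyr::mutate(records,
    log2_116_114 = purrr::map(.data$ratios_116_114, ~ log2(.x / med[["ratios_116_114"]])),
    log2_117_115 = purrr::map(.data$ratios_117_115, ~ log2(.x / med[["ratios_117_115"]])))
  attr(out, "channel_median") <- stats::setNames(med, c("116_114", "117_115"))
  out
}

#' Fit the empirical-Bayes variance prior across proteins
#'
#' Estimates the hyperparameters (`d0`, `s0_sq`) of a scaled inverse
#' chi-square prior on the per-protein true variances by moment matching on
#' the log sample variances: under the model, each sample variance follows
#' `s0_sq` times an F distribution with (`df_g`, `d0`) degrees of freedom,
#' so the mean and variance of `log(s_g^2)` determine (`d0`, `s0_sq`)
#' through digamma/trigamma relations. When the observed log variances are
#' no more dispersed than sampling alone explains, `d0` is infinite and the
#' prior collapses to the common variance `s0_sq`.
#'
#' @param sample_vars Positive sample variances, one per protein.
#' @param dfs Residual degrees of freedom per protein (recycled if scalar).
#' @return An `eb_prior` object: list with `d0` (possibly `Inf`), `s0_sq`,
#'   `n_proteins`.
#' @export
fit_eb_prior <- function(sample_vars, dfs) {
  dfs <- rep_len(dfs, length(sample_vars))
  ok <- is.finite(sample_vars) & sample_vars > 0 & dfs > 0
  if (sum(ok) < 2) stop("need at least 2 proteins with positive variance and df",
                        call. = FALSE)
  if (all(sample_vars[is.finite(sample_vars)] == 0)) stop("all variances zero", call. = FALSE)
  s2 <- sample_vars[ok]
  df <- dfs[ok]
  # log s^2 = log s0^2 + log chisq_df/df - log chisq_d0/d0 (independent terms)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  e_mean <- mean(e)
  e_var <- stats::var(e)
  excess <- e_var - mean(trigamma(df / 2))
  if (is.finite(excess) && excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(e_mean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(e_mean)
  }
  structure(list(d0 = d0, s0_sq = s0_sq, n_proteins = length(s2)),
            class = "eb_prior")
}

# Newton solve trigamma(y) = x for y > 0 (monotone decreasing, convex).
trigamma_inverse <- function(x) {
  stopifnot(x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

#' Moderated one-sample t-test for one protein
#'
#' Ordinary one-sample t-statistic with the sample variance replaced by the
#' posterior (squeezed) variance
#' `(d0 * s0_sq + df * s^2) / (d0 + df)`, a precision-weighted compromise
#' between the protein's own variance and the prior fitted across all
#' proteins; the null distribution gains the prior degrees of freedom
#' (`df_total = d0 + df`). With `d0 = 0` this is exactly the ordinary t;
#' with `d0 = Inf` it is the z-form `mean / sqrt(s0_sq / n)`.
#'
#' @param obs Numeric vector of normalized log2 ratio observations for one
#'   protein (both channel pairs pooled), length >= 2.
#' @param prior An `eb_prior` from [fit_eb_prior()] (or a list with `d0`,
#'   `s0_sq`).
#' @return One-row tibble: `n_obs`, `mean_log2`, `sample_var`,
#'   `moderated_var`, `t_mod`, `df_total`, `p`.
#' @export
moderated_t <- function(obs, prior) {
  obs <- obs[!is.na(obs)]
  n <- length(obs)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  m <- mean(obs)
  s2 <- stats::var(obs)
  df <- n - 1
  d0 <- prior$d0
  s2_post <- if (is.infinite(d0)) prior$s0_sq else (d0 * prior$s0_sq + df * s2) / (d0 + df)
  t_mod <- m / sqrt(s2_post / n)
  df_total <- d0 + df
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  tibble::tibble(n_obs = n, mean_log2 = m, sample_var = s2,
                 moderated_var = s2_post, t_mod = t_mod, df_total = df_total,
                 p = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: with the p-values sorted ascending,
#' `q_(i) = min over j >= i of p_(j) * m / j`, capped at 1, returned in the
#' original input order. Input p-values must lie in (0, 1].
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Full moderated-t enrichment analysis of an iTRAQ experiment
#'
#' Runs the per-protein moderated one-sample t-test over the pooled
#' normalized log2 ratios (both channel pairs concatenated), with the
#' empirical-Bayes prior fitted across all proteins, then applies
#' Benjamini-Hochberg FDR control.
#'
#' @param records Median-normalized detected records from
#'   [median_normalize_itraq()].
#' @param prior Optional pre-fitted `eb_prior`; fitted from the data when
#'   `NULL`.
#' @return Tibble with one row per protein: `protein_id`, `n_obs`,
#'   `mean_log2`, `sample_var`, `moderated_var`, `t_mod`, `df_total`, `p`,
#'   `q`; attribute `prior` carries the fitted `eb_prior`.
#' @export
itraq_moderated_test <- function(records, prior = NULL) {
  obs_list <- purrr::map2(records$log2_116_114, records$log2_117_115, c)
  if (is.null(prior)) {
    sv <- vapply(obs_list, stats::var, numeric(1))
    dfs <- lengths(obs_list) - 1
    prior <- fit_eb_prior(sv, dfs)
  }
  out <- purrr::map(obs_list, moderated_t, prior = prior) |>
    purrr::list_rbind()
  out <- dplyr::bind_cols(tibble::tibble(protein_id = records$protein_id), out)
  out$q <- bh_fdr(out$p)
  attr(out, "prior") <- prior
  out
}

#' Call reproducibly enriched proteins
#'
#' Proteins with an FDR-adjusted p-value strictly below `alpha` and a
#' positive mean normalized log2 ratio (enrichment direction) are deemed
#' reproducibly enriched.
#'
#' @param results Tibble from [itraq_moderated_test()].
#' @param alpha FDR threshold. Default 0.02.
#' @return Sorted identifier vector of enriched proteins.
#' @export
call_enriched <- function(results, alpha = 0.02) {
  sort(results$protein_id[results$q < alpha & results$mean_log2 > 0])
}

#' @export
print.eb_prior <- function(x, ...) {
  cat(sprintf("empirical-Bayes variance prior over %d proteins: d0 = %s, s0^2 = %.4g\n",
              x$n_proteins, format(x$d0, digits = 4), x$s0_sq))
  invisible(x)
}

#' @method glance eb_prior
#' @export
glance.eb_prior <- function(x, ...) {
  tibble::tibble(d0 = x$d0, s0_sq = x$s0_sq, n_proteins = x$n_proteins)
}

#' Enrichment scatter of the two iTRAQ replicates
#'
#' Plots each protein's mean normalized log2 ratio in replicate 1 (116/114)
#' against replicate 2 (117/115), coloring reproducibly enriched proteins.
#'
#' @param records Median-normalized records.
#' @param results Tibble from [itraq_moderated_test()].
#' @param alpha FDR threshold for coloring. Default 0.02.
#' @return A ggplot object.
#' @export
plot_itraq_replicates <- function(records, results, alpha = 0.02) {
  enriched <- call_enriched(results, alpha)
  df <- tibble::tibble(
    rep1 = vapply(records$log2_116_114, mean, numeric(1)),
    rep2 = vapply(records$log2_117_115, mean, numeric(1)),
    enriched = records$protein_id %in% enriched
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rep1, y = .data$rep2,
                                   color = .data$enriched)) +
    ggplot2::geom_point(alpha = 0.7, size = 0.9) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey30"),
                                labels = c(`TRUE` = "enriched", `FALSE` = "other"),
                                name = NULL) +
    ggplot2::labs(x = bquote("replicate 1 " * log[2] * "(116/114)"),
                  y = bquote("replicate 2 " * log[2] * "(117/115)")) +
    ggplot2::theme_classic()
}
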