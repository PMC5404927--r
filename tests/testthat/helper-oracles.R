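# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# median-then-log2 normalization, plain loops
oracle_normalize <- function(ratios, ref_ratios) {
  m <- sort(ref_ratios[!is.na(ref_ratios)])
  n <- length(m)
  med <- if (n %% 2 == 1) m[(n + 1) / 2] else (m[n / 2] + m[n / 2 + 1]) / 2
  out <- rep(NA_real_, length(ratios))
  for (i in seq_along(ratios)) {
    if (!is.na(ratios[i])) out[i] <- log(ratios[i] / med, base = 2)
  }
  out
}

# exhaustive threshold sweep; returns the argmax of TPR - FPR with ties
# broken toward the largest threshold
oracle_roc_argmax <- function(scores, is_tp, is_fp) {
  thresholds <- unique(scores)
  best_j <- -Inf
  best_t <- NA_real_
  for (t in thresholds) {
    tpr <- sum(is_tp & scores >= t) / sum(is_tp)
    fpr <- sum(is_fp & scores >= t) / sum(is_fp)
    j <- tpr - fpr
    if (j > best_j || (j == best_j && t > best_t)) {
      best_j <- j
      best_t <- t
    }
  }
  list(threshold = best_t, j = best_j)
}

# Benjamini-Hochberg step-up, literal definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- rep(NA_real_, m)
  for (i in m:1) {
    val <- p[ord[i]] * m / i
    if (i < m) val <- min(val, q_sorted[i + 1])
    q_sorted[i] <- min(val, 1)
  }
  q <- rep(NA_real_, m)
  q[ord] <- q_sorted
  q
}

# squeeze-then-t computation written out independently
oracle_moderated_t <- function(obs, d0, s0_sq) {
  n <- length(obs)
  m <- sum(obs) / n
  s2 <- sum((obs - m)^2) / (n - 1)
  df <- n - 1
  s2_post <- if (is.infinite(d0)) s0_sq else (d0 * s0_sq + df * s2) / (d0 + df)
  tstat <- m / sqrt(s2_post / n)
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df = d0 + df))
}

# small protein-group record builder for unit tests
toy_records <- function(ids, hl, hm, ml = NULL, peptides = 3L,
                        contaminant = FALSE, reverse = FALSE, rep_id = 1L) {
  n <- length(ids)
  tibble::tibble(
    protein_id = ids,
    gene_symbol = ids,
    unique_peptides = rep_len(peptides, n),
    ratio_hl = hl,
    ratio_hm = hm,
    ratio_ml = if (is.null(ml)) rep(NA_real_, n) else ml,
    is_contaminant = rep_len(contaminant, n),
    is_reverse = rep_len(reverse, n),
    replicate_id = rep_len(as.integer(rep_id), n)
  )
}

# closed circular contour tibble
circle_contour <- function(id, r, n = 360, cx = 0, cy = 0, organelle = "mito",
                           er_class = NA_character_) {
  theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  tibble::tibble(contour_id = id, organelle = organelle, er_class = er_class,
                 closed = TRUE, point_index = seq_len(n),
                 x_nm = cx + r * cos(theta), y_nm = cy + r * sin(theta),
                 condition_label = "test")
}

# open straight-line contour tibble
line_contour <- function(id, x0, y0, x1, y1, n = 2, organelle = "er",
                         er_class = "rough") {
  tibble::tibble(contour_id = id, organelle = organelle, er_class = er_class,
                 closed = FALSE, point_index = seq_len(n),
                 x_nm = seq(x0, x1, length.out = n),
                 y_nm = seq(y0, y1, length.out = n),
                 condition_label = "test")
}
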