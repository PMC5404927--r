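#' Simulate a three-state SILAC proximity-labeling experiment
#'
#' Generates two replicates of protein-group records with known class
#' structure, plus the curated lists and annotation catalog the cutoff
#' analysis needs. Each protein draws a latent pair of log2 enrichment
#' effects (H/L, H/M) from a class-dependent normal: true positives are
#' right-shifted by (`tp_shift_hl`, `tp_shift_hm`), false positives and
#' unrelated ("other") proteins sit at zero, and reference (soluble matrix)
#' proteins sit at `reference_shift`, serving as the normalization anchor.
#' Replicate values share the latent effect so that the between-replicate
#' correlation of log2 ratios is `replicate_corr` while the total spread per
#' replicate is `noise_sd`. Records are emitted as raw ratios — each value
#' exponentiated and multiplied by a channel-level scale factor — so the
#' pipeline's reference-median normalization is genuinely exercised.
#' Decoy rows (1-peptide and contaminant) exercise the detection filter.
#'
#' @param n_proteins Number of non-reference proteins. Default 3000.
#' @param class_fractions Named fractions `c(tp =, fp =, other =)` summing
#'   to 1. Default `c(tp = 0.05, fp = 0.10, other = 0.85)`.
#' @param tp_shift_hl,tp_shift_hm True-positive log2 effects. Defaults 2.0
#'   and 1.5.
#' @param noise_sd Per-replicate total SD of log2 ratios about the class
#'   mean. Default 0.5.
#' @param replicate_corr Between-replicate correlation of log2 ratios.
#'   Default 0.85.
#' @param missing_rate Probability each ratio cell is missing. Default 0.05.
#' @param n_reference Number of reference (matrix) proteins. Default 100.
#' @param reference_shift Latent (hl, hm) position of the reference class.
#'   Default `c(hl = 0, hm = 0)`; cutoff selection is invariant to the
#'   common shift this induces after normalization.
#' @param decoy_onepep_frac Fraction of extra 1-peptide decoy rows. Default
#'   0.03.
#' @param decoy_contam_frac Fraction of extra contaminant decoy rows.
#'   Default 0.02.
#' @param channel_scale Multiplicative raw-ratio scale per ratio kind,
#'   `c(hl =, hm =, ml =)`. Default `c(hl = 1.8, hm = 1.3, ml = 0.9)`.
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `replicate1`, `replicate2` (protein-group record
#'   tibbles), `tp_set`, `matrix_set` (identifier sets), `catalog`
#'   (annotation catalog tibble with a `mito` compartment = TP union
#'   reference, plus `OMM`/`matrix` sub-compartments), and `truth` (tibble
#'   `protein_id`, `class`, `true_hl`, `true_hm`).
#' @export
simulate_silac <- function(n_proteins = 3000,
                           class_fractions = c(tp = 0.05, fp = 0.10, other = 0.85),
                           tp_shift_hl = 2.0, tp_shift_hm = 1.5,
                           noise_sd = 0.5, replicate_corr = 0.85,
                           missing_rate = 0.05, n_reference = 100,
                           reference_shift = c(hl = 0, hm = 0),
                           decoy_onepep_frac = 0.03, decoy_contam_frac = 0.02,
                           channel_scale = c(hl = 1.8, hm = 1.3, ml = 0.9),
                           seed = 1L) {
  if (abs(sum(class_fractions) - 1) > 1e-9) {
    stop("class fractions must sum to 1", call. = FALSE)
  }
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  withr_seed(seed)
  n_tp <- round(n_proteins * class_fractions[["tp"]])
  n_fp <- round(n_proteins * class_fractions[["fp"]])
  n_other <- n_proteins - n_tp - n_fp
  classes <- c(rep("tp", n_tp), rep("fp", n_fp), rep("other", n_other),
               rep("reference", n_reference))
  n_all <- length(classes)
  ids <- sprintf("SYN%05d", seq_len(n_all))
  mu_hl <- c(tp = tp_shift_hl, fp = 0, other = 0,
             reference = reference_shift[["hl"]])[classes]
  mu_hm <- c(tp = tp_shift_hm, fp = 0, other = 0,
             reference = reference_shift[["hm"]])[classes]
  sd_shared <- noise_sd * sqrt(replicate_corr)
  sd_resid <- noise_sd * sqrt(1 - replicate_corr)
  lat_hl <- mu_hl + stats::rnorm(n_all, 0, sd_shared)
  lat_hm <- mu_hm + stats::rnorm(n_all, 0, sd_shared)
  lat_ml <- stats::rnorm(n_all, 0, sd_shared)
  truth <- tibble::tibble(protein_id = ids, class = classes,
                          true_hl = mu_hl, true_hm = mu_hm)

  make_rep <- function(rep_id) {
    hl <- lat_hl + stats::rnorm(n_all, 0, sd_resid)
    hm <- lat_hm + stats::rnorm(n_all, 0, sd_resid)
    ml <- lat_ml + stats::rnorm(n_all, 0, sd_resid)
    miss <- function(v) {
      v[stats::runif(n_all) < missing_rate] <- NA_real_
      v
    }
    rec <- tibble::tibble(
      protein_id = ids,
      gene_symbol = ids,
      unique_peptides = 2L + stats::rpois(n_all, 5),
      ratio_hl = miss(2^hl * channel_scale[["hl"]]),
      ratio_hm = miss(2^hm * channel_scale[["hm"]]),
      ratio_ml = miss(2^ml * channel_scale[["ml"]]),
      is_contaminant = FALSE,
      is_reverse = FALSE,
      replicate_id = as.integer(rep_id)
    )
    n_pep1 <- round(n_all * decoy_onepep_frac)
    n_cont <- round(n_all * decoy_contam_frac)
    decoys <- tibble::tibble(
      protein_id = sprintf("DEC%d%04d", rep_id, seq_len(n_pep1 + n_cont)),
      gene_symbol = "",
      unique_peptides = c(rep(1L, n_pep1), 2L + stats::rpois(n_cont, 5)),
      ratio_hl = 2^stats::rnorm(n_pep1 + n_cont, 0, 1) * channel_scale[["hl"]],
      ratio_hm = 2^stats::rnorm(n_pep1 + n_cont, 0, 1) * channel_scale[["hm"]],
      ratio_ml = 2^stats::rnorm(n_pep1 + n_cont, 0, 1) * channel_scale[["ml"]],
      is_contaminant = c(rep(FALSE, n_pep1), rep(TRUE, n_cont)),
      is_reverse = FALSE,
      replicate_id = as.integer(rep_id)
    )
    dplyr::bind_rows(rec, decoys)
  }
  rep1 <- make_rep(1)
  rep2 <- make_rep(2)

  tp_ids <- ids[classes == "tp"]
  ref_ids <- ids[classes == "reference"]
  catalog <- dplyr::bind_rows(
    tibble::tibble(compartment = "mito", id = c(tp_ids, ref_ids)),
    tibble::tibble(compartment = "OMM", id = tp_ids),
    tibble::tibble(compartment = "matrix", id = ref_ids)
  )
  list(replicate1 = rep1, replicate2 = rep2,
       tp_set = id_set(tp_ids, name = "curated_tp"),
       matrix_set = id_set(ref_ids, name = "matrix_reference"),
       catalog = catalog, truth = truth)
}

#' Simulate a two-replicate iTRAQ IP-MS experiment
#'
#' Per-protein true variances are drawn from a scaled inverse chi-square
#' prior with `d0` prior degrees of freedom and scale `s0_sq` (the same
#' model the empirical-Bayes moderated t-test assumes). A fraction
#' `frac_true` of proteins are true interactors with mean log2 enrichment
#' `true_shift` in both channel pairs; the rest are null. Ratio
#' observations are exponentiated and multiplied by channel-level scale
#' factors so the median normalization is exercised.
#'
#' @param n_proteins Number of proteins. Default 2000.
#' @param frac_true Fraction of true interactors. Default 0.05.
#' @param true_shift Mean log2 enrichment of true interactors. Default 2.0.
#' @param n_obs_per_channel Ratio observations per channel pair. Default 2.
#' @param d0 Prior degrees of freedom. Default 4.
#' @param s0_sq Prior variance scale. Default 0.1.
#' @param channel_scale Raw-ratio scale per channel pair. Default
#'   `c(r116_114 = 1.5, r117_115 = 0.8)`.
#' @param seed Integer seed.
#' @return List with `records` (iTRAQ record tibble) and `truth` (tibble
#'   `protein_id`, `is_true`, `true_var`).
#' @export
simulate_itraq <- function(n_proteins = 2000, frac_true = 0.05,
                           true_shift = 2.0, n_obs_per_channel = 2,
                           d0 = 4, s0_sq = 0.1,
                           channel_scale = c(r116_114 = 1.5, r117_115 = 0.8),
                           seed = 1L) {
  stopifnot(n_proteins >= 2, n_obs_per_channel >= 1, d0 > 0, s0_sq > 0)
  withr_seed(seed)
  ids <- sprintf("ITQ%05d", seq_len(n_proteins))
  is_true <- stats::runif(n_proteins) < frac_true
  true_var <- d0 * s0_sq / stats::rchisq(n_proteins, df = d0)
  mu <- ifelse(is_true, true_shift, 0)
  draw <- function(scale) {
    purrr::map2(mu, true_var,
                ~ 2^stats::rnorm(n_obs_per_channel, .x, sqrt(.y)) * scale)
  }
  records <- tibble::tibble(
    protein_id = ids,
    unique_quantified_peptides = 2L + stats::rpois(n_proteins, 4),
    ratios_116_114 = draw(channel_scale[[1]]),
    ratios_117_115 = draw(channel_scale[[2]]),
    is_contaminant = FALSE,
    is_reverse = FALSE
  )
  list(records = records,
       truth = tibble::tibble(protein_id = ids, is_true = is_true,
                              true_var = true_var))
}

#' Simulate a traced field of mitochondria with ER contacts
#'
#' Emits closed near-circular mitochondrial contours on a spatial grid plus
#' open ER arc polylines placed at specified membrane gaps, sized so that
#' the stretch of mitochondrial perimeter lying within `contact_threshold`
#' of each ER arc covers the requested fraction of that perimeter. (An ER
#' terminus is still within threshold of perimeter points slightly beyond
#' the arc's angular span — by the law of cosines the contact zone extends
#' roughly `sqrt(threshold^2 - gap^2)` of arclength past each end — so the
#' drawn arc is trimmed by exactly that spill-over to make the intended
#' contact arc exact.) Gaps at or beyond the threshold produce no contact
#' and are drawn untrimmed; gap pairs straddling the threshold can thus
#' probe the cutoff. Intended contact arcs are recorded as ground truth.
#'
#' @param n_mito Number of mitochondria.
#' @param mito_radius_band Radius range in nm, `c(min, max)`. Default
#'   `c(400, 700)`.
#' @param contact_spec Tibble or data frame with columns `er_class`
#'   (`"rough"`/`"smooth"`/`"unclassified"`), `gap_nm` (> 0) and
#'   `arc_fraction` (in \[0, 1\]); every mitochondrion receives one ER arc
#'   per row. Arc fractions (plus separating margins) must fit on the
#'   circle.
#' @param jitter_sd Radial jitter SD of mitochondrial points in nm.
#'   Default 0.
#' @param n_points Points per mitochondrial contour. Default 180.
#' @param contact_threshold Contact distance convention used to size the
#'   arcs, in nm. Default 80.
#' @param condition_label Label stored on every contour. Default `"wt"`.
#' @param seed Integer seed.
#' @return List with `contours` (contour tibble for [contact_report()]) and
#'   `truth` (tibble `mito_id`, `er_id`, `er_class`, `gap_nm`,
#'   `arc_fraction`, `true_arc_nm` — expected contact arclength, 0 when the
#'   gap is at or beyond the threshold — and `perimeter`).
#' @export
simulate_contour_field <- function(n_mito = 5,
                                   mito_radius_band = c(400, 700),
                                   contact_spec = tibble::tibble(
                                     er_class = "rough", gap_nm = 45,
                                     arc_fraction = 0.25),
                                   jitter_sd = 0, n_points = 180,
                                   contact_threshold = 80,
                                   condition_label = "wt", seed = 1L) {
  contact_spec <- tibble::as_tibble(contact_spec)
  stopifnot(all(contact_spec$gap_nm > 0),
            all(contact_spec$arc_fraction >= 0 & contact_spec$arc_fraction <= 1))
  margin <- 0.02
  if (nrow(contact_spec) > 0 &&
      sum(contact_spec$arc_fraction) + margin * nrow(contact_spec) > 1) {
    stop("requested contact arcs overlap on the mitochondrial perimeter",
         call. = FALSE)
  }
  withr_seed(seed)
  rows <- list()
  truth <- list()
  pitch <- 2 * (max(mito_radius_band) + max(c(contact_spec$gap_nm, 0)) + 500)
  for (m in seq_len(n_mito)) {
    r <- stats::runif(1, mito_radius_band[1], mito_radius_band[2])
    cx <- ((m - 1) %% 5) * pitch
    cy <- ((m - 1) %/% 5) * pitch
    mito_id <- sprintf("mito%03d", m)
    theta <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
    rr <- r + stats::rnorm(n_points, 0, jitter_sd)
    rows[[length(rows) + 1]] <- tibble::tibble(
      contour_id = mito_id, organelle = "mito", er_class = NA_character_,
      closed = TRUE, point_index = seq_len(n_points),
      x_nm = cx + rr * cos(theta), y_nm = cy + rr * sin(theta),
      condition_label = condition_label)
    # place ER arcs sequentially with margins, starting at a random phase
    phase <- stats::runif(1, 0, 2 * pi)
    for (k in seq_len(nrow(contact_spec))) {
      spec <- contact_spec[k, ]
      zone <- spec$arc_fraction * 2 * pi
      r_er <- r + spec$gap_nm
      in_contact <- spec$gap_nm < contact_threshold
      spill <- if (in_contact) {
        acos(pmin(1, (r^2 + r_er^2 - contact_threshold^2) / (2 * r * r_er)))
      } else 0
      span <- zone - 2 * spill
      if (in_contact && span <= 0) {
        stop("arc_fraction ", spec$arc_fraction, " too small for gap ",
             spec$gap_nm, " nm at threshold ", contact_threshold, " nm",
             call. = FALSE)
      }
      er_id <- sprintf("%s_er%02d", mito_id, k)
      n_er <- max(2L, ceiling(span / (2 * pi) * n_points) + 1L)
      th <- seq(phase + spill, phase + spill + span, length.out = n_er)
      rows[[length(rows) + 1]] <- tibble::tibble(
        contour_id = er_id, organelle = "er", er_class = spec$er_class,
        closed = FALSE, point_index = seq_len(n_er),
        x_nm = cx + r_er * cos(th), y_nm = cy + r_er * sin(th),
        condition_label = condition_label)
      truth[[length(truth) + 1]] <- tibble::tibble(
        mito_id = mito_id, er_id = er_id, er_class = spec$er_class,
        gap_nm = spec$gap_nm, arc_fraction = spec$arc_fraction,
        true_arc_nm = if (in_contact) spec$arc_fraction * 2 * pi * r else 0,
        perimeter = 2 * pi * r)
      phase <- phase + zone + margin * 2 * pi
    }
  }
  contours <- purrr::list_rbind(rows)
  validate_contours(contours)
  list(contours = contours,
       truth = if (length(truth) > 0) purrr::list_rbind(truth) else tibble::tibble())
}

# Generators are pure functions of (config, seed): each seeds the RNG once
# at entry so identical calls give identical output.
withr_seed <- function(seed) {
  set.seed(as.integer(seed))
  invisible(seed)
}
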