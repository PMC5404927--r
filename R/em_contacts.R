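#' Polyline perimeter / arclength of a contour
#'
#' Sum of consecutive point-to-point distances, plus the closing edge when
#' the contour is closed.
#'
#' @param contour Contour tibble (rows of one `contour_id`, ordered points
#'   with `x_nm`, `y_nm`, logical `closed`).
#' @return Length in nanometres.
#' @export
perimeter <- function(contour) {
  x <- contour$x_nm
  y <- contour$y_nm
  if (length(x) < 2) stop("contour needs at least 2 points", call. = FALSE)
  len <- sum(sqrt(diff(x)^2 + diff(y)^2))
  if (isTRUE(contour$closed[1])) {
    len <- len + sqrt((x[1] - x[length(x)])^2 + (y[1] - y[length(y)])^2)
  }
  len
}

# Evenly spaced points along a polyline at arclength step <= spacing.
# For closed contours the closing edge is included and the endpoint at
# arclength L (== the start) is dropped.
sample_polyline <- function(contour, spacing) {
  if (spacing <= 0) stop("spacing must be positive", call. = FALSE)
  x <- contour$x_nm; y <- contour$y_nm
  closed <- isTRUE(contour$closed[1])
  if (closed) { x <- c(x, x[1]); y <- c(y, y[1]) }
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  n_step <- max(1L, ceiling(total / spacing))
  step <- total / n_step
  s <- seq(0, total, by = step)
  if (closed) s <- s[-length(s)] else s[length(s)] <- total
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, length(seg))
  frac <- (s - cum[idx]) / seg[idx]
  list(
    s = s, step = step, total = total, closed = closed,
    x = x[idx] + frac * (x[idx + 1] - x[idx]),
    y = y[idx] + frac * (y[idx + 1] - y[idx])
  )
}

# Minimum distance from points (px, py) to a polyline.
min_dist_to_polyline <- function(px, py, contour) {
  x <- contour$x_nm; y <- contour$y_nm
  if (isTRUE(contour$closed[1])) { x <- c(x, x[1]); y <- c(y, y[1]) }
  ax <- x[-length(x)]; ay <- y[-length(y)]
  bx <- x[-1]; by <- y[-1]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  out <- rep(Inf, length(px))
  for (i in seq_along(ax)) {
    t <- ((px - ax[i]) * dx[i] + (py - ay[i]) * dy[i]) / len2[i]
    t <- pmin(pmax(t, 0), 1)
    d2 <- (px - (ax[i] + t * dx[i]))^2 + (py - (ay[i] + t * dy[i]))^2
    out <- pmin(out, d2)
  }
  sqrt(out)
}

split_contours <- function(contours) {
  split(contours, contours$contour_id)
}

# Maximal runs of TRUE in a logical vector; circular when closed.
covered_runs <- function(hit, closed) {
  n <- length(hit)
  if (!any(hit)) return(list())
  if (all(hit)) return(list(list(start = 1L, end = n, full = TRUE)))
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- purrr::map2(starts[r$values], ends[r$values],
                      ~ list(start = .x, end = .y, full = FALSE))
  if (closed && hit[1] && hit[n] && length(runs) > 1) {
    first <- runs[[1]]; last <- runs[[length(runs)]]
    runs[[length(runs)]] <- list(start = last$start, end = first$end + n,
                                 full = FALSE)
    runs <- runs[-1]
  }
  runs
}

#' Detect ER contact segments along a mitochondrial perimeter
#'
#' Samples the mitochondrial contour at evenly spaced arclength positions
#' (step at most `spacing`) and evaluates, at each sample, the minimum
#' Euclidean distance to each ER contour. Maximal runs of consecutive
#' samples closer than `threshold` to the same ER contour form one contact
#' segment; for a closed mitochondrion a run crossing the trace start wraps
#' around. The segment length is the arclength between the first and last
#' qualifying samples (the full perimeter when every sample is in contact),
#' and the mean distance averages the per-sample distances within the run.
#'
#' @param mito One mitochondrial contour (tibble of ordered points).
#' @param ers Contour tibble of ER contours (several `contour_id`s allowed).
#' @param threshold Contact distance threshold in nm. Default 80.
#' @param spacing Target sample spacing in nm. Default 15 (midpoint of the
#'   10–20 nm measurement convention).
#' @return Tibble of segments: `mito_id`, `er_id`, `er_class`, `arc_start`,
#'   `arc_end` (nm along the perimeter; `arc_end` may exceed the perimeter
#'   for a wrapping run), `length`, `mean_distance`, plus attribute
#'   `samples` (the sample grid with per-ER distances) used by
#'   [distance_profile()].
#' @export
contact_segments <- function(mito, ers, threshold = 80, spacing = 15) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  sp <- sample_polyline(mito, spacing)
  er_list <- if (nrow(ers) > 0) split_contours(ers) else list()
  rows <- list()
  dists <- list()
  for (er in er_list) {
    er_id <- er$contour_id[1]
    d <- min_dist_to_polyline(sp$x, sp$y, er)
    dists[[er_id]] <- d
    runs <- covered_runs(d < threshold, sp$closed)
    for (run in runs) {
      idx <- if (run$end > length(sp$s)) {
        c(run$start:length(sp$s), 1:(run$end - length(sp$s)))
      } else {
        run$start:run$end
      }
      len <- if (isTRUE(run$full)) sp$total else (length(idx) - 1) * sp$step
      rows[[length(rows) + 1]] <- tibble::tibble(
        mito_id = mito$contour_id[1],
        er_id = er_id,
        er_class = er$er_class[1],
        arc_start = sp$s[run$start],
        arc_end = sp$s[run$start] + len,
        length = len,
        mean_distance = mean(d[idx])
      )
    }
  }
  out <- if (length(rows) > 0) purrr::list_rbind(rows) else {
    tibble::tibble(mito_id = character(), er_id = character(),
                   er_class = character(), arc_start = numeric(),
                   arc_end = numeric(), length = numeric(),
                   mean_distance = numeric())
  }
  attr(out, "samples") <- c(sp, list(distances = dists, threshold = threshold))
  out
}

#' Per-sample distance profile of a contact segment
#'
#' Returns the minimum distances from each perimeter sample inside one
#' contact segment to the contacting ER contour; their mean equals the
#' segment's `mean_distance` exactly.
#'
#' @param segments Output of [contact_segments()] (carries the sample grid).
#' @param row Which segment (row index). Default 1.
#' @return Numeric vector of distances in nm.
#' @export
distance_profile <- function(segments, row = 1) {
  sp <- attr(segments, "samples")
  if (is.null(sp)) stop("segments lack the sample grid attribute", call. = FALSE)
  seg <- segments[row, ]
  n <- length(sp$s)
  i0 <- which.min(abs(sp$s - seg$arc_start))
  n_pts <- round(seg$length / sp$step) + 1
  if (seg$length >= sp$total) n_pts <- n
  idx <- ((i0 - 1 + seq_len(n_pts) - 1) %% n) + 1
  sp$distances[[seg$er_id]][idx]
}

# Union of covered samples for a subset of ER contours -> total contact
# length on one mitochondrion (never exceeding its perimeter).
union_contact_length <- function(sp, dists, threshold, er_ids) {
  if (length(er_ids) == 0) return(0)
  hit <- rep(FALSE, length(sp$s))
  for (id in er_ids) hit <- hit | (dists[[id]] < threshold)
  runs <- covered_runs(hit, sp$closed)
  if (length(runs) == 0) return(0)
  sum(vapply(runs, function(run) {
    if (isTRUE(run$full)) sp$total else (run$end - run$start) * sp$step
  }, numeric(1)))
}

#' Mitochondria-ER contact report over a traced field
#'
#' Computes, for every mitochondrion, the perimeter and the fraction of it
#' in contact (closer than `threshold`) with ER — in total and stratified by
#' rough and smooth ER — and the aggregate fractions obtained by summing
#' contact lengths over all mitochondria and dividing by the summed
#' perimeters. Overlapping contact runs from distinct ER contours are
#' merged on the mitochondrial arc before summing, so no perimeter stretch
#' is double-counted. Mitochondria touching an ER contour of unclassified
#' type are excluded from the rough/smooth-stratified per-mitochondrion
#' statistics but retained in the total metric.
#'
#' @param contours Contour tibble containing `organelle == "mito"` and
#'   `"er"` contours (see [read_contours()]).
#' @param threshold Contact threshold in nm. Default 80.
#' @param spacing Sample spacing in nm. Default 15.
#' @return A `contact_report` object: tibble `per_mito` (`mito_id`,
#'   `perimeter`, `contact_total`, `contact_rough`, `contact_smooth`,
#'   `fraction_total`, `fraction_rough`, `fraction_smooth`,
#'   `touches_unclassified`), tibble `aggregate` (one row: total perimeter
#'   and the three aggregate fractions), tibble `segments` (all contact
#'   segments), and `distances` (per-segment mean distances summary).
#' @export
contact_report <- function(contours, threshold = 80, spacing = 15) {
  mitos <- dplyr::filter(contours, .data$organelle == "mito")
  ers <- dplyr::filter(contours, .data$organelle == "er")
  mito_list <- split_contours(mitos)
  if (length(mito_list) == 0) stop("need at least one mitochondrion", call. = FALSE)
  seg_all <- list()
  per_rows <- list()
  for (mito in mito_list) {
    segs <- contact_segments(mito, ers, threshold = threshold, spacing = spacing)
    sp <- attr(segs, "samples")
    peri <- sp$total
    er_class_of <- function(cls) unique(segs$er_id[segs$er_class %in% cls])
    len_total <- union_contact_length(sp, sp$distances, threshold,
                                      er_class_of(c("rough", "smooth", "unclassified")))
    len_rough <- union_contact_length(sp, sp$distances, threshold, er_class_of("rough"))
    len_smooth <- union_contact_length(sp, sp$distances, threshold, er_class_of("smooth"))
    per_rows[[length(per_rows) + 1]] <- tibble::tibble(
      mito_id = mito$contour_id[1],
      perimeter = peri,
      contact_total = len_total,
      contact_rough = len_rough,
      contact_smooth = len_smooth,
      fraction_total = len_total / peri,
      fraction_rough = len_rough / peri,
      fraction_smooth = len_smooth / peri,
      touches_unclassified = length(er_class_of("unclassified")) > 0
    )
    seg_all[[length(seg_all) + 1]] <- segs
  }
  per_mito <- purrr::list_rbind(per_rows)
  segments <- purrr::list_rbind(seg_all)
  strat <- dplyr::filter(per_mito, !.data$touches_unclassified)
  agg_frac <- function(tab, col) {
    if (nrow(tab) == 0) return(NA_real_)
    sum(tab[[col]]) / sum(tab$perimeter)
  }
  aggregate <- tibble::tibble(
    total_perimeter = sum(per_mito$perimeter),
    fraction_total = agg_frac(per_mito, "contact_total"),
    fraction_rough = agg_frac(strat, "contact_rough"),
    fraction_smooth = agg_frac(strat, "contact_smooth"),
    stratified_perimeter = sum(strat$perimeter)
  )
  structure(list(per_mito = per_mito, aggregate = aggregate,
                 segments = segments,
                 distances = if (nrow(segments) > 0) {
                   tibble::tibble(mean = mean(segments$mean_distance),
                                  median = stats::median(segments$mean_distance),
                                  n_segments = nrow(segments))
                 } else {
                   tibble::tibble(mean = NA_real_, median = NA_real_, n_segments = 0L)
                 },
                 threshold = threshold, spacing = spacing),
            class = "contact_report")
}

#' @export
print.contact_report <- function(x, ...) {
  cat(sprintf("contact report: %d mitochondria, total perimeter %.0f nm\n",
              nrow(x$per_mito), x$aggregate$total_perimeter))
  cat(sprintf("  aggregate contact fraction: %.2f%% (rough %.2f%%, smooth %.2f%%)\n",
              100 * x$aggregate$fraction_total,
              100 * x$aggregate$fraction_rough,
              100 * x$aggregate$fraction_smooth))
  invisible(x)
}

#' @method tidy contact_report
#' @export
tidy.contact_report <- function(x, ...) x$per_mito

#' @method glance contact_report
#' @export
glance.contact_report <- function(x, ...) x$aggregate

#' Per-mitochondrion contact fraction plot
#'
#' @param object A `contact_report`.
#' @param ... Ignored.
#' @return A ggplot box/jitter plot of per-mitochondrion contact fractions.
#' @method autoplot contact_report
#' @export
autoplot.contact_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_mito,
                            cols = c("fraction_total", "fraction_rough",
                                     "fraction_smooth"),
                            names_to = "metric", names_prefix = "fraction_",
                            values_to = "fraction")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = 100 * .data$fraction)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = NULL, y = "% mitochondrial perimeter in contact with ER") +
    ggplot2::theme_classic()
}
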