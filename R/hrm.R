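## hrm_pipeline: derivative peaks, normalization, difference curves,
## genotype calls, delta-Tm, predicted-vs-observed, concordance

## negative smoothed derivative -dF/dT via local quadratic least squares
## (Savitzky-Golay); smooth_width_c is the half-width of the fit window.
.neg_deriv <- function(curve, smooth_width_c = 0.5) {
  stopifnot(inherits(curve, "melt_curve"))
  step <- diff(curve$temperatures[1:2])
  k <- round(smooth_width_c / step)
  n_win <- 2L * k + 1L
  if (n_win < 7L)
    stop("smoothing window spans only ", n_win, " grid points (< 7); ",
         "increase smooth_width_c or refine the grid")
  if (n_win > length(curve$temperatures))
    stop("smoothing window wider than the curve")
  -signal::sgolayfilt(curve$fluorescence, p = 2, n = n_win, m = 1, ts = step)
}

#' Derivative melting peaks
#'
#' Computes the negative derivative \eqn{-dF/dT} by local quadratic
#' least-squares smoothing (window expressed in degC so estimates are
#' grid-resolution stable), finds local maxima at least
#' \code{threshold_frac} of the tallest peak -- the software baseline
#' threshold below which signals are treated as noise -- and refines each
#' apex by a least-squares parabola fitted to the derivative points within
#' \code{1.4 * smooth_width_c} of the discrete maximum (a wide-stencil
#' parabolic interpolation, chosen over the classic 3-point form because
#' it keeps the apex estimate stable under fluorescence noise). The apex
#' temperature is the melting temperature Tm.
#'
#' @param curve a [melt_curve()].
#' @param smooth_width_c smoothing half-width (degC); the fit window spans
#'   \code{2*round(smooth_width_c/step)+1} points and must cover >= 7.
#' @param threshold_frac peak acceptance threshold as a fraction of the
#'   global maximum derivative.
#' @return data frame of class \code{melt_peaks}, sorted by height
#'   descending: \code{tm_c}, \code{height}, \code{prominence},
#'   \code{width_c} (full width at half prominence).
#' @export
melting_peaks <- function(curve, smooth_width_c = 0.5,
                          threshold_frac = 0.10) {
  d <- .neg_deriv(curve, smooth_width_c)
  tt <- curve$temperatures
  step <- diff(tt[1:2])
  n <- length(d)
  empty <- data.frame(tm_c = numeric(), height = numeric(),
                      prominence = numeric(), width_c = numeric())
  class(empty) <- c("melt_peaks", "data.frame")
  gmax <- max(d)
  ## a numerically flat curve has no melting event: require the derivative
  ## maximum to clear pure floating-point dust relative to the signal
  if (!is.finite(gmax) || gmax <= 1e-8 * max(abs(curve$fluorescence), 1))
    return(empty)
  thr <- threshold_frac * gmax
  i <- 2:(n - 1L)
  is_peak <- d[i] > d[i - 1L] & d[i] >= d[i + 1L] & d[i] >= thr & d[i] > 0
  idx <- i[is_peak]
  if (!length(idx)) return(empty)
  kr <- max(1L, round(1.4 * smooth_width_c / step))
  peaks <- lapply(idx, function(j) {
    ## apex refined by a least-squares parabola over the points within
    ## +/- 1.4 x smooth_width_c of the discrete maximum; averaging over
    ## the stencil keeps the estimate stable under fluorescence noise
    win <- max(2L, j - kr):min(n - 1L, j + kr)
    x <- tt[win] - tt[j]
    fit <- stats::lm.fit(cbind(1, x, x^2), d[win])
    co <- fit$coefficients
    apex_t <- tt[j]
    apex_h <- d[j]
    if (is.finite(co[3]) && co[3] < 0) {
      dt <- -co[2] / (2 * co[3])
      if (abs(dt) <= kr * step) {
        apex_t <- tt[j] + dt
        apex_h <- co[1] - co[2]^2 / (4 * co[3])
      }
    }
    prom <- apex_h - thr
    level <- apex_h - prom / 2
    li <- j
    while (li > 1L && d[li] > level) li <- li - 1L
    t_lo <- if (d[li] <= level)
      tt[li] + step * (level - d[li]) / (d[li + 1L] - d[li]) else tt[1]
    ri <- j
    while (ri < n && d[ri] > level) ri <- ri + 1L
    t_hi <- if (d[ri] <= level)
      tt[ri] - step * (level - d[ri]) / (d[ri - 1L] - d[ri]) else tt[n]
    data.frame(tm_c = apex_t, height = apex_h, prominence = prom,
               width_c = t_hi - t_lo)
  })
  out <- do.call(rbind, peaks)
  out <- out[order(-out$height), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("melt_peaks", "data.frame")
  out
}

## auto window placement: the widest window (up to width_c) at each grid
## end where |-dF/dT| stays within frac of its global maximum, anchored at
## the end of the quiet run nearest the melt transition
.auto_windows <- function(curve, smooth_width_c = 0.5, width_c = 1.5,
                          frac = 0.05) {
  d <- .neg_deriv(curve, smooth_width_c)
  tt <- curve$temperatures
  ## drop the half-window edge points (one-sided derivative fits) and
  ## median-filter so isolated noise spikes cannot masquerade as signal
  step <- diff(tt[1:2])
  k <- round(smooth_width_c / step)
  keep <- (k + 1L):(length(d) - k)
  dr <- d[keep]
  ds <- stats::runmed(dr, 9, endrule = "constant")
  tt <- tt[keep]
  n <- length(ds)
  ## quiet threshold: 5% of the maximum derivative, but never below the
  ## baseline noise floor of the derivative itself (3 x robust sd of the
  ## outer 10% of points), so noisy baselines still read as quiet
  outer <- c(seq_len(max(5L, n %/% 10L)), (n - max(5L, n %/% 10L) + 1L):n)
  noise_floor <- 3 * stats::mad(dr[outer])
  thr <- max(frac * max(abs(ds)), noise_floor)
  ok <- abs(ds) <= thr
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  good <- which(r$values & r$lengths >= 5L)
  pre_cand <- good[starts[good] <= n %/% 2L]
  post_cand <- good[ends[good] > n %/% 2L]
  if (!length(pre_cand) || !length(post_cand))
    stop("curve '", curve$sample_id, "': no quiet baseline at the grid ",
         "ends; supply normalization windows explicitly")
  pre_run <- c(starts[pre_cand[1]], ends[pre_cand[1]])
  last <- post_cand[length(post_cand)]
  post_run <- c(starts[last], ends[last])
  pre_hi <- tt[pre_run[2]]
  pre_lo <- max(tt[pre_run[1]], pre_hi - width_c)
  post_lo <- tt[post_run[1]]
  post_hi <- min(tt[post_run[2]], post_lo + width_c)
  list(pre = c(pre_lo, pre_hi), post = c(post_lo, post_hi))
}

#' Two-window fluorescence normalization
#'
#' Fits straight lines to the fluorescence over a pre-melt and a post-melt
#' temperature window (least squares) and rescales
#' \deqn{N(T) = 100 (F(T) - L_{post}(T)) / (L_{pre}(T) - L_{post}(T))}
#' so every curve reads 100\% before the melt and 0\% after it -- removing
#' per-sample scale and drift so curve shapes can be compared. With
#' \code{pre_window}/\code{post_window} omitted, each window is placed
#' automatically as the widest span (up to \code{window_width_c}) at its
#' grid end where the derivative magnitude stays within 5\% of its
#' maximum.
#'
#' @param curve a [melt_curve()], or a \code{norm_curve} to re-normalize
#'   (normalization is idempotent up to numerical error).
#' @param pre_window,post_window numeric \code{c(lo, hi)} in degC, or
#'   \code{NULL} for automatic placement.
#' @param config a [run_config()] supplying smoothing and window width
#'   defaults.
#' @return a list of class \code{norm_curve}: \code{sample_id},
#'   \code{declared_label}, \code{temperatures}, \code{values} (percent),
#'   \code{pre_window}, \code{post_window}.
#' @export
normalize_curve <- function(curve, pre_window = NULL, post_window = NULL,
                            config = run_config()) {
  if (inherits(curve, "norm_curve")) {
    ## re-normalization: treat percent values as the fluorescence signal
    curve <- structure(list(sample_id = curve$sample_id,
                            declared_label = curve$declared_label,
                            temperatures = curve$temperatures,
                            fluorescence = curve$values),
                       class = "melt_curve")
  }
  stopifnot(inherits(curve, "melt_curve"))
  if (is.null(pre_window) || is.null(post_window)) {
    w <- .auto_windows(curve, config$smooth_width_c, config$window_width_c)
    if (is.null(pre_window)) pre_window <- w$pre
    if (is.null(post_window)) post_window <- w$post
  }
  stopifnot(length(pre_window) == 2L, length(post_window) == 2L,
            pre_window[1] < pre_window[2], post_window[1] < post_window[2])
  if (pre_window[2] >= post_window[1])
    stop("pre-melt window must lie below the post-melt window")
  tt <- curve$temperatures
  ff <- curve$fluorescence
  in_pre <- tt >= pre_window[1] - 1e-9 & tt <= pre_window[2] + 1e-9
  in_post <- tt >= post_window[1] - 1e-9 & tt <= post_window[2] + 1e-9
  if (sum(in_pre) < 2L || sum(in_post) < 2L)
    stop("normalization windows must each cover >= 2 grid points")
  fit_pre <- lm(ff[in_pre] ~ tt[in_pre])
  fit_post <- lm(ff[in_post] ~ tt[in_post])
  l_pre <- coef(fit_pre)[1] + coef(fit_pre)[2] * tt
  l_post <- coef(fit_post)[1] + coef(fit_post)[2] * tt
  span <- l_pre - l_post
  mid <- tt >= pre_window[2] - 1e-9 & tt <= post_window[1] + 1e-9
  if (any(span[mid] <= 0))
    stop("curve '", curve$sample_id, "': degenerate curve, pre-melt ",
         "baseline does not exceed post-melt baseline over the melt region")
  structure(list(sample_id = curve$sample_id,
                 declared_label = curve$declared_label,
                 temperatures = tt,
                 values = 100 * (ff - l_post) / span,
                 pre_window = pre_window, post_window = post_window),
            class = "norm_curve")
}

#' @export
print.norm_curve <- function(x, ...) {
  cat(sprintf("<norm_curve> %s  pre [%.2f, %.2f] post [%.2f, %.2f] degC\n",
              x$sample_id, x$pre_window[1], x$pre_window[2],
              x$post_window[1], x$post_window[2]))
  invisible(x)
}

.check_shared_grid <- function(norms) {
  tt <- norms[[1]]$temperatures
  for (nc in norms)
    if (length(nc$temperatures) != length(tt) ||
        max(abs(nc$temperatures - tt)) > 1e-9)
      stop("normalized curves are not on a shared temperature grid")
  tt
}

#' Difference curves against a reference genotype
#'
#' Subtracts the pointwise mean (centroid) of the reference-labeled
#' normalized curves from every sample, amplifying subtle shape
#' differences relative to the sequence-verified reference group. By
#' construction the reference group's own difference curves average to the
#' zero vector.
#'
#' @param norms list of [normalize_curve()] results on a shared grid.
#' @param reference_label label whose samples define the baseline.
#' @param labels named character vector sample_id -> label identifying the
#'   reference samples; defaults to the curves' declared labels.
#' @return list of class-\code{diff_curve} lists (\code{sample_id},
#'   \code{temperatures}, \code{values}); the reference centroid is in
#'   \code{attr(, "centroid")}.
#' @export
difference_curves <- function(norms, reference_label, labels = NULL) {
  stopifnot(length(norms) >= 1L)
  tt <- .check_shared_grid(norms)
  ids <- vapply(norms, `[[`, character(1), "sample_id")
  if (is.null(labels))
    labels <- setNames(vapply(norms, `[[`, character(1), "declared_label"),
                       ids)
  ref_ids <- names(labels)[labels == reference_label]
  ref_idx <- which(ids %in% ref_ids)
  if (!length(ref_idx))
    stop("no samples carry the reference label '", reference_label, "'")
  mat <- vapply(norms, `[[`, numeric(length(tt)), "values")
  centroid <- rowMeans(mat[, ref_idx, drop = FALSE])
  out <- lapply(seq_along(norms), function(i)
    structure(list(sample_id = ids[i], temperatures = tt,
                   values = mat[, i] - centroid),
              class = "diff_curve"))
  names(out) <- ids
  attr(out, "centroid") <- centroid
  attr(out, "reference_label") <- reference_label
  out
}

## centroid Tm via the derivative apex of the centroid curve itself
.centroid_tm <- function(tt, values, smooth_width_c) {
  cv <- melt_curve("centroid", tt, pmax(values, 0))
  pk <- melting_peaks(cv, smooth_width_c = smooth_width_c)
  if (nrow(pk) == 0L) NA_real_ else pk$tm_c[1]
}

#' Genotype calls from normalized curve shape and Tm
#'
#' Builds a centroid normalized curve per genotype from its labeled
#' reference samples and assigns every sample to the genotype minimizing
#' the RMS deviation between sample and centroid over the analysis range
#' (the inter-window span shrunk by \code{margin} at both ends, so the
#' normalization windows themselves are excluded). Confidence is
#' \code{100 * max(0, r)} with \code{r} the Pearson correlation between
#' sample and assigned centroid over the analysis range -- an analogue of
#' the percent-confidence numbers HRM software reports, under which
#' well-separated clusters score above 98. Distance ties break to the
#' genotype whose centroid Tm is nearest the sample's primary-peak Tm,
#' then lexicographically.
#'
#' @param norms list of [normalize_curve()] results on a shared grid.
#' @param diffs optional [difference_curves()] output, recorded untouched
#'   (calls are made on normalized curves).
#' @param peaks named list sample_id -> [melting_peaks()] data frame; each
#'   sample must have at least one peak (its first row is the primary
#'   peak).
#' @param reference_sets named list label -> character vector of reference
#'   sample ids present in \code{norms}.
#' @param margin degC trimmed off each end of the inter-window range.
#' @param config a [run_config()].
#' @return data frame of class \code{genotype_calls}: \code{sample_id},
#'   \code{declared}, \code{call}, \code{confidence} (0-100),
#'   \code{tm_c}; per-genotype RMS distances in
#'   \code{attr(, "distances")}.
#' @export
call_genotypes <- function(norms, diffs = NULL, peaks, reference_sets,
                           margin = 0.2, config = run_config()) {
  stopifnot(length(norms) >= 1L, is.list(reference_sets),
            !is.null(names(reference_sets)))
  tt <- .check_shared_grid(norms)
  ids <- vapply(norms, `[[`, character(1), "sample_id")
  names(norms) <- ids
  if (any(!lengths(reference_sets)))
    stop("empty reference set for label(s): ",
         paste(names(reference_sets)[!lengths(reference_sets)],
               collapse = ", "))
  missing_refs <- setdiff(unlist(reference_sets), ids)
  if (length(missing_refs))
    stop("reference sample(s) not among the curves: ",
         paste(missing_refs, collapse = ", "))
  for (id in ids)
    if (is.null(peaks[[id]]) || nrow(peaks[[id]]) == 0L)
      stop("sample '", id, "' has no melting peak; cannot call genotype")
  lo <- max(vapply(norms, function(x) x$pre_window[2], numeric(1))) + margin
  hi <- min(vapply(norms, function(x) x$post_window[1], numeric(1))) - margin
  rng <- tt >= lo - 1e-9 & tt <= hi + 1e-9
  if (sum(rng) < 5L) stop("analysis range [", lo, ", ", hi, "] too narrow")
  mat <- vapply(norms, `[[`, numeric(length(tt)), "values")
  labs <- sort(names(reference_sets))
  centroids <- vapply(labs, function(l)
    rowMeans(mat[, reference_sets[[l]], drop = FALSE]),
    numeric(length(tt)))
  centroid_tm <- vapply(labs, function(l)
    .centroid_tm(tt, centroids[, l], config$smooth_width_c), numeric(1))
  dist <- t(vapply(seq_along(ids), function(i)
    sqrt(colMeans((centroids[rng, , drop = FALSE] - mat[rng, i])^2)),
    numeric(length(labs))))
  dimnames(dist) <- list(ids, labs)
  calls <- character(length(ids))
  confidence <- numeric(length(ids))
  tm_c <- vapply(ids, function(id) peaks[[id]]$tm_c[1], numeric(1))
  for (i in seq_along(ids)) {
    di <- dist[i, ]
    best <- which(di <= min(di) + 1e-12)
    if (length(best) > 1L) {
      prox <- abs(centroid_tm[best] - tm_c[i])
      best <- best[order(prox, labs[best])]
    }
    call <- labs[best[1]]
    calls[i] <- call
    confidence[i] <- 100 * max(0, cor(mat[rng, i], centroids[rng, call]))
  }
  out <- data.frame(sample_id = ids,
                    declared = vapply(norms, `[[`, character(1),
                                      "declared_label"),
                    call = calls, confidence = confidence, tm_c = tm_c,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "distances") <- dist
  attr(out, "centroid_tm") <- centroid_tm
  attr(out, "analysis_range") <- c(lo, hi)
  class(out) <- c("genotype_calls", "data.frame")
  out
}

#' Pairwise group melting-temperature differences
#'
#' The screening statistic of the assay: the absolute difference between
#' group mean Tm values, for every unordered pair of groups.
#'
#' @param group_peaks named list label -> numeric vector of per-sample Tm
#'   values, or label -> [melting_peaks()] data frame(s) (their first-row
#'   \code{tm_c} is used).
#' @return data frame: \code{label_a}, \code{label_b}, \code{delta_tm_c}.
#' @export
delta_tm <- function(group_peaks) {
  stopifnot(is.list(group_peaks), length(group_peaks) >= 2L,
            !is.null(names(group_peaks)))
  tm_of <- function(x) {
    if (is.numeric(x)) x
    else if (is.data.frame(x)) x$tm_c
    else vapply(x, function(p) p$tm_c[1], numeric(1))
  }
  tms <- lapply(group_peaks, tm_of)
  if (any(!lengths(tms)))
    stop("empty peak group(s): ",
         paste(names(tms)[!lengths(tms)], collapse = ", "))
  means <- vapply(tms, mean, numeric(1))
  pairs <- combn(names(means), 2)
  data.frame(label_a = pairs[1, ], label_b = pairs[2, ],
             delta_tm_c = abs(means[pairs[1, ]] - means[pairs[2, ]]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Predicted versus observed melting temperatures
#'
#' Compares nearest-neighbor Tm predictions with measured peak Tm values
#' per group and flags whether each deviation lies in the 0.7-1.5 degC
#' band typical of saturating-dye HRM (reported, not asserted).
#'
#' @param predictions named numeric vector label -> predicted Tm (degC).
#' @param observed named numeric vector label -> mean measured Tm (degC).
#' @return data frame: \code{label}, \code{predicted_c}, \code{observed_c},
#'   \code{delta_c} (observed - predicted), \code{in_dye_band}.
#' @export
predicted_vs_observed <- function(predictions, observed) {
  if (!setequal(names(predictions), names(observed)))
    stop("prediction/observation label sets differ")
  labs <- sort(names(predictions))
  delta <- observed[labs] - predictions[labs]
  data.frame(label = labs,
             predicted_c = unname(predictions[labs]),
             observed_c = unname(observed[labs]),
             delta_c = unname(delta),
             in_dye_band = unname(delta >= 0.7 & delta <= 1.5),
             stringsAsFactors = FALSE)
}

#' Concordance between genotype calls and reference identifications
#'
#' @param calls a [call_genotypes()] result (or any data frame with
#'   \code{sample_id}, \code{call} and optionally \code{declared}).
#' @param truth named character vector sample_id -> true label (e.g. from
#'   barcoding identification or a simulation truth table); must cover
#'   every called sample.
#' @return a list of class \code{concordance_summary}:
#'   \code{percent_agreement} (1 decimal, round-half-even),
#'   \code{confusion} (truth x call table), \code{discordant}
#'   (sample ids where call != truth), \code{mislabeled} (sample ids
#'   whose call contradicts their declared label).
#' @export
concordance <- function(calls, truth) {
  stopifnot(all(c("sample_id", "call") %in% names(calls)))
  miss <- setdiff(calls$sample_id, names(truth))
  if (length(miss))
    stop("truth table missing sample(s): ", paste(miss, collapse = ", "))
  tr <- truth[calls$sample_id]
  agree <- calls$call == tr
  mis <- character(0)
  if ("declared" %in% names(calls)) {
    known <- !is.na(calls$declared)
    mis <- calls$sample_id[known & calls$call != calls$declared]
  }
  structure(list(
    percent_agreement = .round1(100 * mean(agree)),
    confusion = table(truth = tr, call = calls$call),
    discordant = calls$sample_id[!agree],
    mislabeled = mis,
    n = nrow(calls)),
    class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("<concordance_summary> %.1f%% agreement over %d samples\n",
              x$percent_agreement, x$n))
  print(x$confusion)
  if (length(x$mislabeled))
    cat("mislabeled (call != declared):",
        paste(x$mislabeled, collapse = ", "), "\n")
  invisible(x)
}

#' One-call HRM authentication workflow
#'
#' Convenience wrapper chaining the pipeline on a cohort of curves:
#' normalization, difference curves against the reference genotype,
#' derivative peaks, and genotype calls.
#'
#' @param curves named list of [melt_curve()].
#' @param reference_sets named list label -> reference sample ids.
#' @param reference_label genotype used as the difference-curve baseline.
#' @param config a [run_config()].
#' @return list with \code{calls}, \code{peaks}, \code{norms},
#'   \code{diffs}, \code{delta_tm} (pairwise group Tm differences using
#'   the called groups).
#' @export
hrm_authenticate <- function(curves, reference_sets,
                             reference_label = names(reference_sets)[1],
                             config = run_config()) {
  norms <- lapply(curves, normalize_curve, config = config)
  peaks <- lapply(curves, melting_peaks,
                  smooth_width_c = config$smooth_width_c,
                  threshold_frac = config$threshold_frac)
  diffs <- difference_curves(
    norms, reference_label,
    labels = setNames(
      rep(names(reference_sets), lengths(reference_sets)),
      unlist(reference_sets)))
  calls <- call_genotypes(norms, diffs, peaks, reference_sets,
                          config = config)
  groups <- split(calls$tm_c, calls$call)
  dt <- if (length(groups) >= 2L) delta_tm(groups) else NULL
  list(calls = calls, peaks = peaks, norms = norms, diffs = diffs,
       delta_tm = dt)
}
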