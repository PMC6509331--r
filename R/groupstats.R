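# Group-level statistics: difference topoplots with max-statistic
# permutation testing, Cz peak analysis, Friedman tests, t-based
# confidence intervals and better-than-chance accuracy thresholds.

# mean absolute pairwise class-difference map for one participant:
# avgs = named list of channels x time matrices -> channels x time
.pairwise_absdiff <- function(avgs) {
  cls <- names(avgs)
  acc <- 0 * avgs[[1]]
  n_pairs <- 0
  for (i in seq_along(cls)) for (j in seq_len(i - 1)) {
    acc <- acc + abs(avgs[[cls[i]]] - avgs[[cls[j]]])
    n_pairs <- n_pairs + 1
  }
  acc / n_pairs
}

# average a channels x time matrix into non-overlapping time segments
.segment_average <- function(m, rate, t0, edges) {
  out <- matrix(0, nrow(m), length(edges) - 1)
  tax <- t0 + (seq_len(ncol(m)) - 1) / rate
  for (s in seq_len(ncol(out))) {
    sel <- tax >= edges[s] & tax < edges[s + 1]
    out[, s] <- rowMeans(m[, sel, drop = FALSE])
  }
  rownames(out) <- rownames(m)
  out
}

#' Difference topoplots
#'
#' For every participant, the trial-averaged potentials of all class
#' combinations are differenced, the absolute values taken (only the
#' intensity of a difference matters, not its polarity), averaged over the
#' class pairs, and then averaged within non-overlapping 250-ms time
#' segments from 0 to 3 s after the class cue. The grand grid is the mean
#' over participants.
#'
#' @param class_averages list (per participant) of named lists (per class)
#'   of channels x time matrices, all on a common channel grid
#'   (interpolate bad channels first, see
#'   [interpolate_bad_channels()]).
#' @param rate sampling rate (Hz).
#' @param t0 time of the first column relative to the class cue (s).
#' @param seg_width segment width in seconds (default 0.25).
#' @param t_range segmented interval (default 0-3 s, giving 12 segments).
#' @return A `difference_topoplot_grid`: list with `values`
#'   (channels x segments, uV, all >= 0), `edges` (segment boundaries, s)
#'   and `mask` (`NULL` until a permutation test fills it).
#' @export
difference_topoplots <- function(class_averages, rate, t0 = 0,
                                 seg_width = 0.25, t_range = c(0, 3)) {
  stopifnot(length(class_averages) >= 1)
  edges <- seq(t_range[1], t_range[2], by = seg_width)
  per_part <- lapply(class_averages, function(avgs) {
    if (length(avgs) < 2) stop("need at least 2 classes")
    .segment_average(.pairwise_absdiff(avgs), rate, t0, edges)
  })
  values <- Reduce(`+`, per_part) / length(per_part)
  structure(list(values = values, edges = edges, mask = NULL,
                 n_participants = length(class_averages)),
            class = "difference_topoplot_grid")
}

#' Thin-plate (biharmonic) spline interpolation of bad channels
#'
#' Replaces flagged channels by the value of the biharmonic smooth surface
#' (radial basis r^2 log r plus an affine term) interpolating the good
#' channels at their 2-D scalp positions. Good channels pass through
#' unchanged; affine maps are reproduced exactly.
#'
#' @param values numeric vector (one per channel) or channels x k matrix.
#' @param positions channels x 2 matrix of scalp coordinates.
#' @param bad logical or integer index of channels to replace.
#' @return `values` with the flagged channels interpolated.
#' @export
interpolate_bad_channels <- function(values, positions, bad) {
  vec_in <- is.null(dim(values))
  V <- if (vec_in) matrix(values, ncol = 1) else as.matrix(values)
  bad <- if (is.logical(bad)) which(bad) else as.integer(bad)
  if (!length(bad)) return(values)
  good <- setdiff(seq_len(nrow(V)), bad)
  if (length(good) < 4) stop("need at least 4 good channels")
  P <- as.matrix(positions)
  tps_kernel <- function(a, b) {
    d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
    k <- 0.5 * d2 * log(pmax(d2, 1e-20))
    k[d2 == 0] <- 0
    k
  }
  K <- tps_kernel(P[good, , drop = FALSE], P[good, , drop = FALSE])
  A <- cbind(1, P[good, , drop = FALSE])
  lhs <- rbind(cbind(K, A), cbind(t(A), matrix(0, 3, 3)))
  rhs <- rbind(V[good, , drop = FALSE], matrix(0, 3, ncol(V)))
  coef <- solve(lhs, rhs)
  Kb <- tps_kernel(P[bad, , drop = FALSE], P[good, , drop = FALSE])
  Ab <- cbind(1, P[bad, , drop = FALSE])
  V[bad, ] <- Kb %*% coef[seq_along(good), , drop = FALSE] +
    Ab %*% coef[length(good) + 1:3, , drop = FALSE]
  if (vec_in) drop(V) else V
}

#' One-tailed max-statistic permutation test for difference topoplots
#'
#' Class labels are shuffled once per participant per permutation (at the
#' trial level) and the difference-topoplot grid recomputed. The test
#' statistic of a cell is its grid value in excess of the permutation mean
#' (the difference between the unshuffled and the shuffled grids, averaged
#' over shuffles); the null distribution is built from the maximum of the
#' equally centred permuted grids over all channels and segments, which
#' controls the family-wise error over the whole grid. A cell is flagged
#' when its observed statistic exceeds the `1 - alpha` quantile of the
#' max-null.
#'
#' @param epoch_sets list of [epoch_set()] objects, one per participant
#'   (trial-level data; rejected trials excluded internally).
#' @param rate sampling rate (Hz) (taken from the data).
#' @param n_perm permutations (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed.
#' @param seg_width,t_range segment layout, see [difference_topoplots()].
#' @return The observed `difference_topoplot_grid` with `mask` filled in
#'   (logical channels x segments), plus `threshold` and `null_max`.
#' @export
permutation_max_stat <- function(epoch_sets, n_perm = 1000, alpha = 0.05,
                                 seed = 1, seg_width = 0.25,
                                 t_range = c(0, 3)) {
  if (length(epoch_sets) < 2)
    stop("need at least 2 participants")
  if (n_perm < 1 / alpha)
    warning("n_perm < 1/alpha: permutation resolution insufficient for ",
            "the requested level")
  eps <- lapply(epoch_sets, drop_rejected)
  rate <- eps[[1]]$rate
  t0 <- eps[[1]]$t0_offset
  grid_of <- function(label_list) {
    avgs <- lapply(seq_along(eps), function(i) {
      e <- eps[[i]]
      labs <- label_list[[i]]
      cls <- sort(unique(labs))
      out <- lapply(cls, function(cl)
        colMeans(e$data[labs == cl, , , drop = FALSE], dims = 1))
      names(out) <- cls
      out
    })
    difference_topoplots(avgs, rate, t0, seg_width, t_range)$values
  }
  obs_labels <- lapply(eps, function(e) e$labels)
  G_obs <- grid_of(obs_labels)
  set.seed(seed)
  perms <- vector("list", n_perm)
  perm_sum <- 0 * G_obs
  for (b in seq_len(n_perm)) {
    shuf <- lapply(obs_labels, sample)
    perms[[b]] <- grid_of(shuf)
    perm_sum <- perm_sum + perms[[b]]
  }
  # centre on the pooled mean including the observed grid, so that the
  # observed and permuted statistics are exchangeable under the null
  perm_mean <- (perm_sum + G_obs) / (n_perm + 1)
  max_null <- vapply(perms, function(G_b) max(G_b - perm_mean), 0)
  observed_stat <- G_obs - perm_mean
  # (B + 1) rank convention with the observed grid in its own pool:
  # exact level under exchangeability
  pool <- c(max(observed_stat), max_null)
  thr <- if (alpha >= 1) -Inf else
    sort(pool)[ceiling((1 - alpha) * length(pool))]
  structure(list(values = G_obs,
                 edges = seq(t_range[1], t_range[2], by = seg_width),
                 mask = observed_stat > thr,
                 observed_stat = observed_stat,
                 threshold = thr, null_max = max_null,
                 n_participants = length(eps)),
            class = "difference_topoplot_grid")
}

#' Positive/negative peak features of a Cz class-average waveform
#'
#' The early positive peak is the maximum within `pos_window` and the
#' later negative peak the minimum within `neg_window` (seconds after the
#' class cue). When the located positive peak does not precede the
#' negative one, or a peak sits on a window boundary, the row is flagged
#' `degenerate`.
#'
#' @param waveform numeric vector, the trial-averaged Cz potential (uV).
#' @param t time axis (s, relative to the class cue).
#' @param pos_window,neg_window search windows (s).
#' @return One-row `data.frame`: `pos_amp`, `pos_lat`, `neg_amp`,
#'   `neg_lat`, `degenerate`.
#' @export
peak_features <- function(waveform, t, pos_window = c(0.2, 0.9),
                          neg_window = c(0.7, 2.5)) {
  stopifnot(length(waveform) == length(t))
  ip <- which(t >= pos_window[1] & t <= pos_window[2])
  im <- which(t >= neg_window[1] & t <= neg_window[2])
  if (!length(ip) || !length(im))
    stop("waveform must cover the peak search windows")
  wp <- ip[which.max(waveform[ip])]
  wm <- im[which.min(waveform[im])]
  degenerate <- t[wp] >= t[wm] ||
    wp %in% range(ip) || wm %in% range(im)
  data.frame(pos_amp = waveform[wp], pos_lat = t[wp],
             neg_amp = waveform[wm], neg_lat = t[wm],
             degenerate = degenerate)
}

#' Friedman test across classes within participants
#'
#' Nonparametric repeated-measures rank test: values are ranked within
#' each participant (ties mid-ranked) and the standard chi-squared
#' statistic with `k - 1` degrees of freedom computed.
#'
#' @param values participants x classes matrix (no missing cells).
#' @return list with `chi2`, `df`, `p`.
#' @export
friedman_by_class <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 2 || ncol(values) < 2)
    stop("need at least 2 participants and 2 classes")
  if (anyNA(values)) stop("missing cells are not allowed")
  ft <- stats::friedman.test(values)
  chi2 <- unname(ft$statistic)
  if (is.nan(chi2)) {           # complete ties carry no evidence
    chi2 <- 0
    return(list(chi2 = 0, df = unname(ft$parameter), p = 1))
  }
  list(chi2 = chi2, df = unname(ft$parameter), p = ft$p.value)
}

#' t-distribution confidence interval of a mean
#'
#' `mean +/- t_{1-alpha/2, n-1} * sd / sqrt(n)` over participants.
#'
#' @param values numeric vector (one value per participant).
#' @param alpha significance level (default 0.05 for a 95% interval).
#' @return list with `mean`, `lo`, `hi`.
#' @export
t_ci <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 2) stop("need n >= 2")
  m <- mean(values)
  half <- stats::qt(1 - alpha / 2, n - 1) * stats::sd(values) / sqrt(n)
  list(mean = m, lo = m - half, hi = m + half)
}

#' Better-than-chance classification accuracy threshold
#'
#' Upper bound of the adjusted Wald (add z^2/2) confidence interval
#' around the chance proportion `1/n_classes`, at level
#' `alpha/n_comparisons` (Bonferroni correction for the number of tested
#' time points), returned in percent.
#'
#' @param n_trials number of classified trials.
#' @param n_classes number of classes (chance = 1/n_classes).
#' @param alpha significance level (default 0.05).
#' @param n_comparisons Bonferroni divisor (default 1).
#' @return Threshold in percent.
#' @export
significance_threshold <- function(n_trials, n_classes, alpha = 0.05,
                                   n_comparisons = 1) {
  stopifnot(n_trials > 0, n_classes >= 2, n_comparisons >= 1)
  a <- alpha / n_comparisons
  z <- stats::qnorm(1 - a / 2)
  p0 <- 1 / n_classes
  x <- n_trials * p0
  nt <- n_trials + z^2
  pt <- (x + z^2 / 2) / nt
  100 * min(1, pt + z * sqrt(pt * (1 - pt) / nt))
}
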