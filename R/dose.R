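# Trace-level statistics: Hill dose-response fits, activity episodes,
# calcium/contraction event pairing.

#' Fit a Hill equation to dose-response data
#'
#' Responses are first normalized to the response at `normalize_at`
#' (interpolated on a log-concentration scale if that exact concentration
#' was not tested), then r(c) = rmax * c^h / (ec50^h + c^h) is fitted by
#' nonlinear least squares with the bottom fixed at 0 (responses are
#' baseline-subtracted amplitudes). Optimization is multi-start over
#' log-spaced ec50 and several Hill-slope initializations, with a
#' Gauss-Newton polish, and the best SSE wins.
#'
#' @param concentrations agonist concentrations (uM), >= 4 distinct values
#' @param responses non-negative responses, same length
#' @param normalize_at reference concentration (uM, default 100); NULL
#'   disables normalization
#' @return object of class `DoseResponseFit`: `ec50`, `h`, `rmax`, `sse`,
#'   `normalized_at`, `constraints`, `fitted` (function of concentration)
#' @export
fit_hill <- function(concentrations, responses, normalize_at = 100) {
  c_ <- as.numeric(concentrations); r <- as.numeric(responses)
  if (length(unique(c_)) < 4L) stop("need >= 4 distinct concentrations")
  if (length(c_) != length(r)) stop("length mismatch")
  if (any(c_ <= 0)) stop("concentrations must be > 0")
  if (any(r < 0)) stop("responses must be >= 0")
  if (!is.null(normalize_at)) {
    ref <- if (any(c_ == normalize_at)) mean(r[c_ == normalize_at])
           else stats::approx(log(c_), r, xout = log(normalize_at), rule = 2)$y
    if (ref <= 0) stop("non-positive reference response; cannot normalize")
    r <- r / ref
  }
  hill <- function(cc, ec50, h, rmax) rmax * cc^h / (ec50^h + cc^h)
  sse_of <- function(p) {
    pr <- hill(c_, exp(p[1]), exp(p[2]), exp(p[3]))
    sum((pr - r)^2)
  }
  starts <- expand.grid(
    ec50 = exp(seq(log(min(c_)), log(max(c_)), length.out = 6)),
    h = c(0.5, 1, 2),
    rmax = max(r, 1e-6)
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- log(as.numeric(starts[i, ]))
    opt <- try(stats::optim(p0, sse_of, method = "Nelder-Mead",
                            control = list(maxit = 500, reltol = 1e-12)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("Hill fit failed to converge from any start")
  # Gauss-Newton polish via nls (port, bounded away from 0)
  p <- exp(best$par)
  pol <- try(suppressWarnings(stats::nls(
    r ~ rmax * c_^h / (ec50^h + c_^h),
    start = list(ec50 = p[1], h = p[2], rmax = p[3]),
    algorithm = "port", lower = c(1e-9, 1e-3, 1e-9),
    control = stats::nls.control(maxiter = 200, warnOnly = TRUE)
  )), silent = TRUE)
  if (!inherits(pol, "try-error")) {
    cf <- stats::coef(pol)
    if (sum((hill(c_, cf[1], cf[2], cf[3]) - r)^2) <= best$value + 1e-15) {
      p <- unname(cf)
    }
  }
  structure(list(
    ec50 = p[1], h = p[2], rmax = p[3],
    sse = sum((hill(c_, p[1], p[2], p[3]) - r)^2),
    normalized_at = normalize_at,
    constraints = "bottom fixed at 0",
    fitted = function(cc) hill(cc, p[1], p[2], p[3])
  ), class = "DoseResponseFit")
}

#' Find enhanced-activity episodes in an event-onset sequence
#'
#' An episode is a maximal run of consecutive events whose inter-onset gaps
#' are all <= `window_s`, containing at least `min_events` events. The
#' defaults implement the enhanced-activity criterion of >= 2 contractions
#' within 90 s; the chaining interpretation makes the result invariant to a
#' global time shift. Quiescent gaps are the complement intervals (episode
#' boundaries, plus recording edges when `t_range` is supplied).
#'
#' @param onsets sorted event onset times (s)
#' @param window_s maximum inter-onset gap within an episode (s)
#' @param min_events minimum events per episode
#' @param t_range optional c(start, end) recording span for edge gaps
#' @return list with `episodes` (data.frame start_s, end_s, n_events) and
#'   `quiescent` (data.frame start_s, end_s)
#' @export
find_activity_episodes <- function(onsets, window_s = 90, min_events = 2L,
                                   t_range = NULL) {
  onsets <- as.numeric(onsets)
  if (length(onsets) && is.unsorted(onsets)) stop("onsets must be sorted")
  empty_ep <- data.frame(start_s = numeric(0), end_s = numeric(0),
                         n_events = integer(0))
  if (!length(onsets)) {
    quiescent <- if (is.null(t_range)) data.frame(start_s = numeric(0), end_s = numeric(0))
                 else data.frame(start_s = t_range[1], end_s = t_range[2])
    return(list(episodes = empty_ep, quiescent = quiescent))
  }
  grp <- cumsum(c(1, as.integer(diff(onsets) > window_s)))
  eps <- do.call(rbind, lapply(split(onsets, grp), function(g) {
    data.frame(start_s = g[1], end_s = g[length(g)], n_events = length(g))
  }))
  rownames(eps) <- NULL
  episodes <- eps[eps$n_events >= min_events, , drop = FALSE]
  rownames(episodes) <- NULL
  # quiescent complement between consecutive episodes (and recording edges)
  qs <- numeric(0); qe <- numeric(0)
  bounds <- episodes
  if (!is.null(t_range)) {
    if (nrow(bounds) == 0L || bounds$start_s[1] > t_range[1]) {
      qs <- c(qs, t_range[1])
      qe <- c(qe, if (nrow(bounds)) bounds$start_s[1] else t_range[2])
    }
  }
  if (nrow(bounds) > 1L) {
    qs <- c(qs, bounds$end_s[-nrow(bounds)])
    qe <- c(qe, bounds$start_s[-1])
  }
  if (!is.null(t_range) && nrow(bounds) && bounds$end_s[nrow(bounds)] < t_range[2]) {
    qs <- c(qs, bounds$end_s[nrow(bounds)]); qe <- c(qe, t_range[2])
  }
  list(episodes = episodes, quiescent = data.frame(start_s = qs, end_s = qe))
}

#' Pair calcium events with contraction events by temporal overlap
#'
#' Greedy matching by maximal overlap of the event intervals
#' [onset, onset + duration]; each event joins at most one pair.
#' Contractions with no overlapping calcium event are flagged "passive"
#' (movement without a corresponding calcium signal), calcium events with
#' no contraction "silent".
#'
#' @param ca_events data.frame(onset_s, duration_s)
#' @param contraction_events data.frame(onset_s, duration_s)
#' @return object of class `EventPairSet`: `pairs` (data.frame ca_onset_s,
#'   ca_duration_s, con_onset_s, con_duration_s, overlap_s), `passive`
#'   (unmatched contractions), `silent` (unmatched calcium events)
#' @export
pair_events <- function(ca_events, contraction_events) {
  na <- nrow(ca_events); nb <- nrow(contraction_events)
  overlap <- function(i, j) {
    a0 <- ca_events$onset_s[i]; a1 <- a0 + ca_events$duration_s[i]
    b0 <- contraction_events$onset_s[j]; b1 <- b0 + contraction_events$duration_s[j]
    max(0, min(a1, b1) - max(a0, b0))
  }
  cand <- expand.grid(i = seq_len(na), j = seq_len(nb))
  if (nrow(cand)) {
    cand$ov <- mapply(overlap, cand$i, cand$j)
    cand <- cand[cand$ov > 0, , drop = FALSE]
    cand <- cand[order(-cand$ov, cand$i, cand$j), , drop = FALSE]
  }
  used_a <- logical(na); used_b <- logical(nb)
  pairs <- data.frame(ca_onset_s = numeric(0), ca_duration_s = numeric(0),
                      con_onset_s = numeric(0), con_duration_s = numeric(0),
                      overlap_s = numeric(0))
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    pairs <- rbind(pairs, data.frame(
      ca_onset_s = ca_events$onset_s[i], ca_duration_s = ca_events$duration_s[i],
      con_onset_s = contraction_events$onset_s[j],
      con_duration_s = contraction_events$duration_s[j], overlap_s = cand$ov[k]))
  }
  structure(list(
    pairs = pairs,
    passive = contraction_events[!used_b, , drop = FALSE],
    silent = ca_events[!used_a, , drop = FALSE]
  ), class = "EventPairSet")
}

#' Correlate paired calcium / contraction durations
#'
#' @param pairset [pair_events()] output with >= 3 pairs
#' @return list with `pearson_r`, `spearman_rho`, `n`
#' @export
correlate_durations <- function(pairset) {
  p <- pairset$pairs
  if (nrow(p) < 3L) stop("need >= 3 pairs")
  if (stats::sd(p$ca_duration_s) == 0 || stats::sd(p$con_duration_s) == 0) {
    stop("zero variance in durations")
  }
  list(pearson_r = stats::cor(p$ca_duration_s, p$con_duration_s),
       spearman_rho = stats::cor(p$ca_duration_s, p$con_duration_s,
                                 method = "spearman"),
       n = nrow(p))
}
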