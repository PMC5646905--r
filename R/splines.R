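#' Cubic B-spline basis on a bin grid
#'
#' Evaluates a B-spline basis with the given knot sites on a grid, with
#' boundary knots replicated to full multiplicity so the basis forms a
#' partition of unity over the knot span.
#'
#' @param knots sorted vector of distinct knot sites (same units as `x`).
#' @param x evaluation grid.
#' @param order spline order (degree + 1); 4 = cubic.
#' @return K x length(x) basis matrix (basis functions in rows), with
#'   attribute `"greville"` giving each basis function's Greville site.
#' @export
build_bspline_basis <- function(knots, x, order = 4L) {
  knots <- sort(unique(as.numeric(knots)))
  if (length(knots) < 2L) stop("need at least 2 distinct knots")
  aug <- c(rep(knots[1L], order - 1L), knots, rep(knots[length(knots)], order - 1L))
  inside <- x >= knots[1L] & x <= knots[length(knots)]
  B <- matrix(0, length(aug) - order, length(x))
  if (any(inside))
    B[, inside] <- t(splines::splineDesign(aug, x[inside], ord = order,
                                           outer.ok = TRUE))
  grev <- vapply(seq_len(nrow(B)), function(j) {
    mean(aug[(j + 1L):(j + order - 1L)])
  }, numeric(1))
  attr(B, "greville") <- grev
  B
}

# lightweight container shared by the history and TAE terms
spline_model <- function(knots, basis, weights, fixed_idx = integer(0),
                         prior_mean = 0, prior_var = 25, order = 4L) {
  K <- nrow(basis)
  structure(
    list(knots = knots, order = order, basis = basis, weights = weights,
         fixed_idx = sort(fixed_idx),
         adjustable_idx = setdiff(seq_len(K), fixed_idx),
         prior_mean = rep(prior_mean, length.out = K),
         prior_var = rep(prior_var, length.out = K)),
    class = "spline_model")
}

#' @export
print.spline_model <- function(x, ...) {
  cat(sprintf("<spline_model> %d basis functions, knots at %s; %d fixed\n",
              nrow(x$basis), paste(signif(x$knots, 3), collapse = ", "),
              length(x$fixed_idx)))
  invisible(x)
}

# curve implied by current weights, over the basis grid
spline_curve <- function(sm) as.numeric(crossprod(sm$basis, sm$weights))

#' Spike-history spline from ISI features
#'
#' Places the refractory-term knots from features of the interspike-interval
#' histogram near zero, where the history term (rather than any biologically
#' plausible oscillation) dominates the ISI shape. With an ISI histogram that
#' rises from a minimum at zero to a first maximum, knots sit at one bin
#' \eqn{\Delta}, the first histogram maximum, the ISI mean, and the 70th and
#' 80th ISI percentiles; the function is tied down by knots at the 97th
#' percentile and at 100 ms whose weights are fixed at zero, constraining
#' the asymptote. If no ISI of one bin occurs, the first weight is fixed at
#' -6 (hard refractoriness cannot be identified from data that never violate
#' it); if the histogram is maximal at zero it is left adjustable.
#'
#' The histogram is formed at 1 ms resolution and smoothed over 3 bins
#' before the first maximum is located, to avoid latching onto noise spikes.
#'
#' @param raster a [spike_raster()].
#' @param max_lag history support, s (weights are zero beyond it).
#' @param prior_var prior variance for adjustable weights.
#' @return a `spline_model` whose basis is evaluated on the lag grid
#'   `dt, 2 dt, ..., max_lag` (columns = lag bins).
#' @export
history_knots_from_isi <- function(raster, max_lag = 0.1, prior_var = 25) {
  isis <- isi(raster, "s")
  if (length(isis) < 10L) stop("too few ISIs to place history knots")
  dt <- raster$dt

  bw <- 0.001
  h <- hist(isis, breaks = seq(0, max(isis) + bw, by = bw), plot = FALSE)
  cnt <- h$counts
  sm <- stats::filter(cnt, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- cnt[is.na(sm)]
  max_at_zero <- which.max(sm) == 1L
  # first local maximum of the smoothed histogram
  first_max_bin <- if (max_at_zero) 1L else {
    cand <- which(diff(sign(diff(c(-Inf, sm)))) < 0)
    if (length(cand)) cand[1L] else which.max(sm)
  }
  first_max <- h$mids[first_max_bin]

  qs <- quantile(isis, c(0.70, 0.80, 0.97), names = FALSE)
  knots <- c(dt, first_max, mean(isis), qs[1L], qs[2L], qs[3L], max_lag)
  knots <- sort(unique(pmin(pmax(knots, dt), max_lag)))

  lag_grid <- seq_len(round(max_lag / dt)) * dt
  B <- build_bspline_basis(knots, lag_grid)
  grev <- attr(B, "greville")
  K <- nrow(B)

  # tail coefficients (support at/right of the 97th-percentile knot) pinned to 0
  p97 <- min(qs[3L], max_lag)
  fixed <- which(grev >= p97 - 1e-12)
  weights <- numeric(K)
  empty_at_delta <- !any(round(isis / dt) <= 1)
  if (empty_at_delta && !max_at_zero) {
    fixed <- union(1L, fixed)
    weights[1L] <- -6
  }
  spline_model(knots, B, weights, fixed_idx = fixed, prior_var = prior_var)
}

#' Trial-average-effect spline by random knot search
#'
#' Chooses TAE knots by randomly varying their number (4 to `max_knots`) and
#' interior locations, keeping the set whose least-squares spline fit to the
#' (Gaussian-smoothed) empirical PSTH has the smallest squared error. The
#' fit target is the log-odds of the per-bin spike probability, the scale on
#' which the TAE enters the model.
#'
#' @param raster a [spike_raster()].
#' @param max_knots knot budget (default 9).
#' @param search_budget number of random proposals.
#' @param smooth_sd PSTH smoothing kernel SD, s.
#' @param seed optional seed.
#' @return a `spline_model` on the trial time grid, all weights adjustable,
#'   weights set to the least-squares fit (a convenient initialisation).
#' @export
tae_knots_from_psth <- function(raster, max_knots = 9L, search_budget = 2000L,
                                smooth_sd = 0.010, seed = NULL) {
  if (max_knots < 4L) stop("max_knots must be at least 4")
  if (!is.null(seed)) set.seed(seed)
  N <- ncol(raster$y); dt <- raster$dt
  tgrid <- (seq_len(N) - 1) * dt
  p <- pmin(pmax(psth(raster, smooth_sd) * dt, 1e-4), 1 - 1e-4)
  target <- qlogis(p)

  fit_sse <- function(knots) {
    B <- build_bspline_basis(knots, tgrid)
    w <- tryCatch(stats::lm.fit(t(B), target)$coefficients,
                  error = function(e) NULL)
    if (is.null(w) || anyNA(w)) return(list(sse = Inf))
    list(sse = sum((as.numeric(crossprod(B, w)) - target)^2), B = B, w = w)
  }

  best <- NULL; best_sse <- Inf; best_knots <- NULL
  for (i in seq_len(search_budget)) {
    k <- sample(4:max_knots, 1L)
    interior <- sort(runif(k - 2L, tgrid[1L], tgrid[N]))
    knots <- unique(c(tgrid[1L], interior, tgrid[N]))
    if (length(knots) < 4L) next
    f <- fit_sse(knots)
    if (f$sse < best_sse) { best_sse <- f$sse; best <- f; best_knots <- knots }
  }
  sm <- spline_model(best_knots, best$B, as.numeric(best$w), prior_var = 25)
  sm$sse <- best_sse
  sm
}
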