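#' Tidy a LOST fit
#'
#' One row per monitored quantity (post-burn-in draws): slowest-pair
#' frequency and modulus, latent amplitude, innovation variance, trial
#' offsets and, for mixture fits, the strong-class strength and weak-class
#' weight.
#'
#' @param x a [lost_fit()].
#' @param ... unused.
#' @return tibble with `term`, `estimate`, `std.error`.
#' @method tidy lost_fit
#' @export
tidy.lost_fit <- function(x, ...) {
  tr <- x$trace[x$trace$iteration > x$config$burn_in, ]
  rows <- list(
    tibble::tibble(term = "freq_hz", estimate = mean(tr$freq_hz),
                   std.error = sd(tr$freq_hz)),
    tibble::tibble(term = "modulus", estimate = mean(tr$modulus),
                   std.error = sd(tr$modulus)),
    tibble::tibble(term = "amplitude", estimate = mean(tr$amplitude),
                   std.error = sd(tr$amplitude)),
    tibble::tibble(term = "sigma2", estimate = mean(tr$sigma2),
                   std.error = sd(tr$sigma2)),
    tibble::tibble(term = sprintf("mu[%d]", seq_along(x$mu_mean)),
                   estimate = x$mu_mean, std.error = NA_real_))
  if (!is.null(x$mixture)) {
    rows <- c(rows, list(
      tibble::tibble(term = "s1", estimate = mean(x$mixture$s1_draws, na.rm = TRUE),
                     std.error = sd(x$mixture$s1_draws, na.rm = TRUE)),
      tibble::tibble(term = "pi1", estimate = pi1_mode(x),
                     std.error = sd(x$mixture$pi1_draws, na.rm = TRUE))))
  }
  do.call(rbind, rows)
}

#' @rdname tidy.lost_fit
#' @method glance lost_fit
#' @export
glance.lost_fit <- function(x, ...) {
  cv <- assess_convergence(x)
  tibble::tibble(
    n_trials = nrow(x$raster$y), n_bins = ncol(x$raster$y),
    iterations = x$config$iterations, kept = x$n_kept,
    freq_hz = cv$freq_mean, modulus = cv$modulus_mean,
    amplitude = cv$amplitude_mean,
    frequency_certain = cv$frequency_certain,
    modulus_certain = cv$modulus_certain,
    amplitude_nontrivial = cv$amplitude_nontrivial)
}

#' @method tidy history_glm
#' @export
tidy.history_glm <- function(x, ...) {
  est <- c(x$intercept, x$a_bar, x$b_bar)
  tibble::tibble(
    term = c("intercept", sprintf("a[%d]", seq_len(x$S)),
             sprintf("b[%d]", seq_len(x$O))),
    estimate = est, std.error = x$se)
}

#' Plot the monitored chain of a LOST fit
#'
#' Faceted traces of the slowest-pair frequency, its modulus and the latent
#' amplitude -- the small subset monitored for convergence.
#' @param object a [lost_fit()].
#' @param ... unused.
#' @method autoplot lost_fit
#' @export
autoplot.lost_fit <- function(object, ...) {
  tr <- object$trace
  df <- rbind(
    data.frame(iteration = tr$iteration, value = tr$freq_hz,
               what = "slowest-pair frequency (Hz)"),
    data.frame(iteration = tr$iteration, value = tr$modulus,
               what = "slowest-pair modulus"),
    data.frame(iteration = tr$iteration, value = tr$amplitude,
               what = "latent amplitude (SD of x)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~what, ncol = 1L, scales = "free_y") +
    ggplot2::labs(x = "Gibbs iteration", y = NULL)
}

#' @method autoplot spike_raster
#' @export
autoplot.spike_raster <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[df$spike == 1L, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$trial)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time (s)", y = "trial")
}

#' @importFrom ggplot2 .data
NULL

#' Human-readable run report
#'
#' Deterministic summary of a completed chain: the monitored trace
#' summaries, convergence verdicts, posterior offsets and, for mixture
#' runs, the weak-class weight mode and per-trial indicators.
#'
#' @param fit a [lost_fit()].
#' @return character vector of report lines (also printed).
#' @export
run_report <- function(fit) {
  cv <- assess_convergence(fit)
  lines <- c(
    sprintf("LOST run: %d trials x %d bins, %d iterations (%d kept)",
            nrow(fit$raster$y), ncol(fit$raster$y),
            fit$config$iterations, fit$n_kept),
    sprintf("slowest-pair frequency: %.2f Hz (sd/mean %.3f) -> %s",
            cv$freq_mean, cv$freq_sd_over_mean,
            ifelse(cv$frequency_certain, "certain", "uncertain")),
    sprintf("slowest-pair modulus: %.4f (sd %.4f) -> %s",
            cv$modulus_mean, cv$modulus_sd,
            ifelse(cv$modulus_certain, "certain", "uncertain")),
    sprintf("latent amplitude: %.3f -> %s",
            cv$amplitude_mean,
            ifelse(cv$amplitude_nontrivial, "non-trivial", "practically flat")),
    sprintf("innovation variance: %.4g", mean(fit$trace$sigma2[
      fit$trace$iteration > fit$config$burn_in])))
  if (!is.null(fit$mixture)) {
    cls <- classify_trials(fit)
    lines <- c(lines,
               sprintf("mixture: pi1 posterior mode %.3f; %d trials weak",
                       pi1_mode(fit), sum(cls$class == "weak")),
               sprintf("per-trial <Z_m1>: %s",
                       paste(sprintf("%.2f", cls$Z1_mean), collapse = " ")))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Write / read a run configuration
#'
#' Declarative YAML round trip for simulation/fit settings so runs are
#' replayable; the resolved list survives serialization unchanged.
#' @param config named list.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) yaml::read_yaml(path)
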