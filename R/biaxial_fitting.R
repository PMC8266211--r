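#' Planar biaxial dataset
#'
#' Container for one sample's biaxial stretch-stress measurements: paired
#' stretches along the fiber and cross-fiber axes with the corresponding
#' experimental Cauchy stresses.
#'
#' @param lambda1,lambda2 stretches (dimensionless), equal length.
#' @param sigma11,sigma22 experimental Cauchy stresses (kPa).
#' @param sample_id identifier string.
#' @return An object of class \code{biaxial_dataset}.
#' @export
biaxial_dataset <- function(lambda1, lambda2, sigma11, sigma22,
                            sample_id = "sample") {
  n <- length(lambda1)
  stopifnot(length(lambda2) == n, length(sigma11) == n, length(sigma22) == n,
            n >= 1)
  if (any(!is.finite(c(lambda1, lambda2, sigma11, sigma22)))) {
    stop("all dataset values must be finite")
  }
  if (any(lambda1 < 1 - 1e-3) || any(lambda2 < 1 - 1e-3)) {
    stop("stretches must be >= 1 (small preconditioning residual tolerated)")
  }
  structure(list(sample_id = as.character(sample_id),
                 lambda1 = as.numeric(lambda1),
                 lambda2 = as.numeric(lambda2),
                 sigma11 = as.numeric(sigma11),
                 sigma22 = as.numeric(sigma22),
                 n = n),
            class = "biaxial_dataset")
}

#' @export
print.biaxial_dataset <- function(x, ...) {
  cat(sprintf("<biaxial_dataset> %s: %d points, peak stress %.1f kPa\n",
              x$sample_id, x$n, max(x$sigma11, x$sigma22)))
  invisible(x)
}

#' Least-squares calibration loss
#'
#' Sum over measurement points of squared residuals between the model's
#' plane-stress biaxial response and the experimental stresses, in both
#' loading directions:
#' \deqn{f = \sum_i [(\sigma_{11}^W - \sigma_{11}^{exp})^2 +
#'                   (\sigma_{22}^W - \sigma_{22}^{exp})^2].}
#'
#' @param params \code{material_params}.
#' @param data \code{biaxial_dataset}.
#' @return Loss in kPa^2.
#' @export
biaxial_loss <- function(params, data) {
  stopifnot(inherits(data, "biaxial_dataset"))
  m <- biaxial_model_stress(params, data$lambda1, data$lambda2)
  sum((m$sigma11 - data$sigma11)^2 + (m$sigma22 - data$sigma22)^2)
}

# loss over a raw parameter vector; non-finite model values map to a large
# finite penalty so L-BFGS-B keeps a usable search direction
.loss_vec <- function(theta, law, data) {
  fake <- structure(list(law = law,
                         params = stats::setNames(pmax(theta, 0),
                                                  law_param_names(law))),
                    class = "material_params")
  m <- biaxial_model_stress(fake, data$lambda1, data$lambda2)
  v <- sum((m$sigma11 - data$sigma11)^2 + (m$sigma22 - data$sigma22)^2)
  if (!is.finite(v)) 1e30 else v
}

#' Fit constitutive parameters to biaxial data
#'
#' Bound-constrained least squares (all parameters >= 0) with seeded
#' multi-start: each restart draws parameters log-uniformly in
#' \code{init_range}, runs L-BFGS-B on the residual loss, and the best
#' optimum is polished with Nelder-Mead. An explicit \code{init} is used as
#' an additional start.
#'
#' @param law one of "W1", "W2", "W3".
#' @param data \code{biaxial_dataset}.
#' @param restarts number of random starts (default 20).
#' @param seed integer seed for the start draws.
#' @param init optional \code{material_params} starting point.
#' @param init_range log-uniform sampling range for starts.
#' @param maxit maximum function evaluations per start.
#' @return An object of class \code{biaxial_fit} with the fitted
#'   \code{material_params}, sse, r_squared, avg_error (RMSE in kPa),
#'   convergence flag and evaluation count.
#' @export
fit_biaxial <- function(law = c("W1", "W2", "W3"), data, restarts = 20,
                        seed = NULL, init = NULL,
                        init_range = c(1e-2, 1e3), maxit = 5000) {
  law <- match.arg(law)
  stopifnot(inherits(data, "biaxial_dataset"))
  npar <- length(law_param_names(law))
  if (data$n < npar) stop("need at least as many points as free parameters")
  if (!is.null(seed)) set.seed(seed)

  starts <- replicate(restarts,
                      exp(stats::runif(npar, log(init_range[1]),
                                       log(init_range[2]))),
                      simplify = FALSE)
  # deterministic starts at the magnitudes typical of exponential
  # soft-tissue laws (matrix stiffness ~1-20 kPa, exponents ~5-80);
  # random restarts then guard against their basins being wrong
  det_starts <- switch(law,
    W1 = list(c(1, 5, 10, 50), c(10, 1, 50, 10)),
    W2 = list(c(1, 10, 5, 50), c(10, 50, 1, 10)),
    W3 = list(c(10, 10, 50), c(1, 50, 5)))
  starts <- c(det_starts, starts)
  if (!is.null(init)) {
    stopifnot(inherits(init, "material_params"), init$law == law)
    starts <- c(list(unname(init$params)), starts)
  }

  best <- NULL
  n_eval <- 0L
  any_conv <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, .loss_vec, law = law, data = data,
                   method = "L-BFGS-B", lower = rep(0, npar),
                   control = list(maxit = maxit, factr = 1e2)),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_eval <- n_eval + fit$counts[["function"]]
    any_conv <- any_conv || fit$convergence == 0
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")

  # derivative-free polish; exponential laws have narrow curved valleys
  pol <- stats::optim(best$par, .loss_vec, law = law, data = data,
                      method = "Nelder-Mead",
                      control = list(maxit = maxit,
                                     reltol = 1e-14))
  n_eval <- n_eval + pol$counts[["function"]]
  if (pol$value < best$value) best <- pol
  # one more bounded refinement from the polished point
  ref <- tryCatch(
    stats::optim(pmax(best$par, 0), .loss_vec, law = law, data = data,
                 method = "L-BFGS-B", lower = rep(0, npar),
                 control = list(maxit = maxit, factr = 1e1)),
    error = function(e) NULL)
  if (!is.null(ref)) {
    n_eval <- n_eval + ref$counts[["function"]]
    if (ref$value < best$value) best <- ref
  }

  pl <- as.list(pmax(best$par, 0))
  names(pl) <- law_param_names(law)
  params <- do.call(material_params, c(list(law = law), pl))
  g <- goodness_of_fit(params, data)
  structure(list(params = params, sse = g$sse, sst = g$sst,
                 r_squared = g$r_squared, avg_error = g$avg_error,
                 converged = any_conv, n_iter = n_eval,
                 sample_id = data$sample_id),
            class = "biaxial_fit")
}

#' @export
print.biaxial_fit <- function(x, ...) {
  r2 <- if (is.na(x$r_squared)) "undefined" else sprintf("%.4f", x$r_squared)
  cat(sprintf("<biaxial_fit> %s on %s: RMSE %.4g kPa, R^2 %s%s\n",
              x$params$law, x$sample_id, x$avg_error, r2,
              if (x$converged) "" else " (not converged)"))
  print(x$params$params)
  invisible(x)
}

#' Goodness of fit of a parameter set on a biaxial dataset
#'
#' \code{r_squared = 1 - SSE/SST} with SST the total sum of squares of the
#' pooled experimental stresses (both directions) about their common mean —
#' one R-squared per sample. \code{avg_error} is the per-sample RMSE
#' \eqn{\sqrt{SSE/(2n)}} in kPa. A zero SST (all stresses identical) yields
#' \code{r_squared = NA} with attribute \code{undefined = TRUE}.
#'
#' @param params \code{material_params}.
#' @param data \code{biaxial_dataset}.
#' @return List with sse, sst, r_squared, avg_error.
#' @export
goodness_of_fit <- function(params, data) {
  stopifnot(inherits(data, "biaxial_dataset"))
  sse <- biaxial_loss(params, data)
  pooled <- c(data$sigma11, data$sigma22)
  sst <- sum((pooled - mean(pooled))^2)
  r2 <- if (sst == 0) NA_real_ else 1 - sse / sst
  list(sse = sse, sst = sst, r_squared = r2,
       avg_error = sqrt(sse / (2 * data$n)))
}

#' Aggregate fits across samples
#'
#' Arithmetic mean and sample standard deviation of the per-sample RMSE,
#' mean R-squared, and the mean of each material parameter — the summary
#' layout used to report a single averaged parameter set per law.
#'
#' @param fits list of \code{biaxial_fit} objects (same law).
#' @return List with law, n_samples, mean_params, avg_error_mean,
#'   avg_error_sd, r_squared_mean.
#' @export
aggregate_fits <- function(fits) {
  if (length(fits) == 0) stop("need at least one fit")
  stopifnot(all(vapply(fits, inherits, logical(1), "biaxial_fit")))
  laws <- vapply(fits, function(f) f$params$law, character(1))
  if (length(unique(laws)) != 1) stop("fits must share one law")
  errs <- vapply(fits, function(f) f$avg_error, numeric(1))
  r2s <- vapply(fits, function(f) f$r_squared, numeric(1))
  pmat <- do.call(rbind, lapply(fits, function(f) f$params$params))
  list(law = laws[1], n_samples = length(fits),
       mean_params = colMeans(pmat),
       avg_error_mean = mean(errs),
       avg_error_sd = if (length(errs) > 1) stats::sd(errs) else 0,
       r_squared_mean = mean(r2s, na.rm = TRUE))
}

#' Read a biaxial sample from CSV
#'
#' Expects columns \code{lambda1,lambda2,sigma11_kPa,sigma22_kPa}; a leading
#' \code{# sample_id} comment line names the sample.
#'
#' @param path CSV file.
#' @return A \code{biaxial_dataset}.
#' @export
read_biaxial_csv <- function(path) {
  first <- readLines(path, n = 1L)
  sid <- if (startsWith(first, "#")) trimws(sub("^#+\\s*", "", first)) else
    sub("\\.csv$", "", basename(path))
  d <- utils::read.csv(path, comment.char = "#")
  biaxial_dataset(d$lambda1, d$lambda2, d$sigma11_kPa, d$sigma22_kPa,
                  sample_id = sid)
}

#' Write a biaxial sample to CSV
#'
#' @param data \code{biaxial_dataset}.
#' @param path output file.
#' @export
write_biaxial_csv <- function(data, path) {
  stopifnot(inherits(data, "biaxial_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", data$sample_id), con)
  utils::write.csv(data.frame(lambda1 = data$lambda1, lambda2 = data$lambda2,
                              sigma11_kPa = data$sigma11,
                              sigma22_kPa = data$sigma22),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize fit results to JSON
#'
#' Writes the per-sample fits plus the aggregate block (mean parameters,
#' mean RMSE +/- SD, mean R-squared).
#'
#' @param fits list of \code{biaxial_fit}.
#' @param path optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
fits_to_json <- function(fits, path = NULL) {
  agg <- aggregate_fits(fits)
  obj <- list(
    fits = lapply(fits, function(f) list(
      sample_id = f$sample_id, law = f$params$law,
      params = as.list(f$params$params), sse = f$sse,
      r_squared = f$r_squared, avg_error = f$avg_error,
      converged = f$converged, n_iter = f$n_iter)),
    aggregate = list(law = agg$law, n_samples = agg$n_samples,
                     mean_params = as.list(agg$mean_params),
                     avg_error_mean = agg$avg_error_mean,
                     avg_error_sd = agg$avg_error_sd,
                     r_squared_mean = agg$r_squared_mean))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
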