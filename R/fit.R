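#' Deterministic starting values for a logistic fit
#'
#' Log-linearisation initialiser: with a provisional asymptote
#' `w_max0 = 1.05 * max(w)`, the model implies
#' `log(w_max0 / w - 1) = log(a) - k * t`, a straight line in `t`. Ordinary
#' least squares on the points with `0 < w < w_max0` gives starting values
#' `(a0, k0)`; the procedure involves no randomness, so fits initialised from
#' it are reproducible.
#'
#' @param t Days after sowing (numeric, one value per observation mean).
#' @param w Per-stem accumulation at `t` (same length, all `>= 0`).
#' @param inflate Multiplier applied to `max(w)` for the provisional
#'   asymptote; default 1.05.
#'
#' @return A [logistic_params()] object with the starting values.
#' @examples
#' p <- logistic_params(3.6, 1e6, 0.1)
#' t <- c(60, 120, 150, 180, 200)
#' logistic_init(t, logistic_value(p, t))
#' @export
logistic_init <- function(t, w, inflate = 1.05) {
  stopifnot(is.numeric(t), is.numeric(w), length(t) == length(w))
  if (!any(w > 0)) stop("initialization error: all accumulations are zero", call. = FALSE)
  w_max0 <- inflate * max(w)
  use <- w > 0 & w < w_max0
  if (sum(use) < 2L) {
    stop("initialization error: fewer than 2 points usable for log-linearization",
         call. = FALSE)
  }
  z <- log(w_max0 / w[use] - 1)
  if (length(unique(t[use])) < 2L) {
    stop("initialization error: need at least 2 distinct times", call. = FALSE)
  }
  b <- coef(lm(z ~ t[use]))
  k0 <- -unname(b[2L])
  a0 <- exp(unname(b[1L]))
  if (!is.finite(k0) || k0 <= 0 || !is.finite(a0) || a0 <= 0) {
    stop("initialization error: degenerate series (no increasing logistic trend)",
         call. = FALSE)
  }
  logistic_params(w_max0, a0, k0)
}

# Average replicate observations to per-time means and validate the series.
series_means <- function(data) {
  stopifnot(is.data.frame(data))
  if (!all(c("t", "w") %in% names(data))) {
    stop("growth series must have columns `t` and `w`", call. = FALSE)
  }
  if (any(!is.finite(data$t)) || any(data$t < 0)) {
    stop("`t` must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(data$w)) || any(data$w < 0)) {
    stop("`w` must be finite and >= 0", call. = FALSE)
  }
  out <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(data), .data$t),
                          w = mean(.data$w), .groups = "drop")
  dplyr::arrange(out, .data$t)
}

#' Fit the logistic accumulation model
#'
#' Bounded Levenberg-Marquardt least squares (via [minpack.lm::nlsLM()]) of
#' `w ~ w_max / (1 + a * exp(-k * t))` with all three parameters constrained
#' positive. Replicate observations at the same time are averaged first, so
#' the fit minimises squared residuals over per-time means, the convention
#' used for stage-sampled trial data. Initialisation comes from
#' [logistic_init()] unless `start` is supplied; the whole procedure is
#' deterministic given the data.
#'
#' @param data A data frame with numeric columns `t` (days after sowing) and
#'   `w` (per-stem accumulation); extra columns (e.g. `replicate`) are
#'   ignored. At least 4 distinct times are required (3 free parameters).
#' @param start Optional [logistic_params()] (or list) overriding the
#'   automatic starting values.
#' @param max_iter Optimizer iteration cap (default 200).
#'
#' @return An object of class `logistic_fit`: a list with `params`
#'   ([logistic_params()]), `r_squared` (1 - SSE/SST over the fitted means),
#'   `converged` (logical), `residuals` (tibble of `t`, `observed`, `fitted`,
#'   `residual`) and `data` (the per-time means used). Non-convergence yields
#'   `converged = FALSE` with a warning, never an error.
#' @examples
#' truth <- logistic_params(3.1812, 109524.11, 0.0862)
#' t <- c(20, 60, 100, 140, 170, 190)
#' fit <- fit_logistic(data.frame(t = t, w = logistic_value(truth, t)))
#' fit$params
#' @export
fit_logistic <- function(data, start = NULL, max_iter = 200L) {
  means <- series_means(data)
  if (nrow(means) < 4L) {
    stop("fitting requires at least 4 distinct time points", call. = FALSE)
  }
  start <- if (is.null(start)) logistic_init(means$t, means$w) else as_logistic_params(start)
  init <- list(w_max = start$w_max, a = start$a, k = start$k)
  eps <- sqrt(.Machine$double.eps)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      w ~ w_max / (1 + a * exp(-k * t)),
      data = means, start = init,
      lower = c(w_max = eps, a = eps, k = eps),
      control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = 1e-12,
                                           ptol = 1e-12)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    warning("logistic fit did not converge: ", conditionMessage(fit), call. = FALSE)
    params <- start
    converged <- FALSE
  } else {
    cf <- coef(fit)
    params <- logistic_params(cf[["w_max"]], cf[["a"]], cf[["k"]])
    converged <- isTRUE(fit$convInfo$isConv)
    if (!converged) {
      warning("logistic fit stopped before convergence (", fit$convInfo$stopMessage,
              ")", call. = FALSE)
    }
  }
  fitted_w <- logistic_value(params, means$t)
  structure(
    list(
      params = params,
      r_squared = rsq_means(means$w, fitted_w),
      converged = converged,
      residuals = tibble::tibble(t = means$t, observed = means$w,
                                 fitted = as.numeric(fitted_w),
                                 residual = means$w - as.numeric(fitted_w)),
      data = means
    ),
    class = "logistic_fit"
  )
}

rsq_means <- function(observed, fitted) {
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("undefined R-squared: zero variance in observations", call. = FALSE)
  1 - sum((observed - fitted)^2) / sst
}

#' @export
print.logistic_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("  R^2 = %.4f over %d time points%s\n", x$r_squared, nrow(x$data),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Coefficient of determination for a logistic fit
#'
#' Computes `1 - SSE/SST` for a fitted (or any candidate) parameter set
#' against a growth series, on per-time means.
#'
#' @param object A `logistic_fit` or [logistic_params()] object.
#' @param data A growth series data frame (`t`, `w`); defaults to the data
#'   stored in the fit.
#' @return `R^2` as a plain number. Errors if the observations have zero
#'   variance.
#' @export
logistic_r_squared <- function(object, data = NULL) {
  params <- if (inherits(object, "logistic_fit")) object$params else as_logistic_params(object)
  if (is.null(data)) {
    if (!inherits(object, "logistic_fit")) {
      stop("`data` is required when `object` is not a fit", call. = FALSE)
    }
    means <- object$data
  } else {
    means <- series_means(data)
  }
  rsq_means(means$w, as.numeric(logistic_value(params, means$t)))
}

#' Fit logistic curves for every treatment in a growth table
#'
#' Groups a long growth table by season, sowing date and variable, fits each
#' group with [fit_logistic()], and returns one coefficient row per group in
#' the layout of published sowing-date coefficient tables. Groups with too few
#' time points (or failed fits) are flagged in the `note` column and do not
#' abort the remaining fits.
#'
#' @param growth A data frame with columns `season`, `sowing_date`,
#'   `variable` (`"dma"`/`"na"`), `days_after_sowing`, `value`, and optionally
#'   `replicate`.
#' @return A tibble with columns `season`, `sowing_date`, `variable`,
#'   `w_max`, `a`, `k`, `r_squared`, `converged`, `n_points`, `note`.
#' @export
fit_growth_table <- function(growth) {
  need <- c("season", "sowing_date", "variable", "days_after_sowing", "value")
  if (!all(need %in% names(growth))) {
    stop("growth table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  groups <- dplyr::group_split(
    dplyr::group_by(tibble::as_tibble(growth),
                    .data$season, .data$sowing_date, .data$variable)
  )
  purrr::map_dfr(groups, function(g) {
    id <- g[1L, c("season", "sowing_date", "variable")]
    series <- tibble::tibble(t = g$days_after_sowing, w = g$value)
    res <- tryCatch(
      withCallingHandlers(
        fit_logistic(series),
        warning = function(w) invokeRestart("muffleWarning")
      ),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      return(dplyr::bind_cols(id, tibble::tibble(
        w_max = NA_real_, a = NA_real_, k = NA_real_, r_squared = NA_real_,
        converged = FALSE, n_points = length(unique(series$t)),
        note = conditionMessage(res)
      )))
    }
    dplyr::bind_cols(id, tibble::tibble(
      w_max = res$params$w_max, a = res$params$a, k = res$params$k,
      r_squared = res$r_squared, converged = res$converged,
      n_points = nrow(res$data),
      note = if (res$converged) NA_character_ else "did not converge"
    ))
  })
}
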