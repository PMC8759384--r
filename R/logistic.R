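#' Logistic accumulation parameters
#'
#' Bundle the three parameters of the logistic accumulation model
#' \deqn{W(t) = \frac{W_{max}}{1 + a e^{-kt}}}{W(t) = Wmax / (1 + a exp(-k t))}
#' used to describe per-stem dry-matter (DMA, g stem^-1) and nitrogen
#' (NA, mg stem^-1) accumulation against days after sowing.
#'
#' @param w_max Asymptotic per-stem accumulation (same unit as the data).
#' @param a Dimensionless shape constant, `> 0`. Controls the horizontal
#'   position of the curve: the inflection sits at `t = log(a)/k`.
#' @param k Relative accumulation rate constant (per day), `> 0`.
#' @param variable Optional label, `"dma"` or `"na"`.
#' @param unit Optional unit label (e.g. `"g_per_stem"`, `"mg_per_stem"`).
#'
#' @return An object of class `logistic_params`: a list with elements
#'   `w_max`, `a`, `k` and optional `variable`/`unit` attributes.
#' @examples
#' p <- logistic_params(3.6217, 4101240.31, 0.0976)
#' logistic_value(p, log(p$a) / p$k)  # half the asymptote at the inflection
#' @export
logistic_params <- function(w_max, a, k, variable = NULL, unit = NULL) {
  for (nm in c("w_max", "a", "k")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("invalid logistic parameter: `", nm, "` must be a finite positive scalar",
           call. = FALSE)
    }
  }
  if (!is.null(variable)) {
    variable <- match.arg(tolower(variable), c("dma", "na"))
  }
  structure(
    list(w_max = as.numeric(w_max), a = as.numeric(a), k = as.numeric(k)),
    variable = variable, unit = unit, class = "logistic_params"
  )
}

#' @export
print.logistic_params <- function(x, ...) {
  v <- attr(x, "variable")
  cat("Logistic accumulation parameters",
      if (!is.null(v)) paste0(" (", toupper(v), ")"), "\n", sep = "")
  cat(sprintf("  W(t) = %.4f / (1 + %.2f * exp(-%.4f * t))\n", x$w_max, x$a, x$k))
  invisible(x)
}

as_logistic_params <- function(x) {
  if (inherits(x, "logistic_params")) return(x)
  if (is.list(x) && all(c("w_max", "a", "k") %in% names(x))) {
    return(logistic_params(x$w_max, x$a, x$k))
  }
  if (is.numeric(x) && length(x) == 3L) {
    return(logistic_params(x[[1]], x[[2]], x[[3]]))
  }
  stop("cannot interpret `params` as logistic parameters", call. = FALSE)
}

#' Evaluate the logistic accumulation curve
#'
#' @param params A [logistic_params()] object (or a list/length-3 numeric with
#'   `w_max`, `a`, `k`).
#' @param t Days after sowing; may be any finite numeric vector, including
#'   negative values for extrapolation before sowing.
#'
#' @return Per-stem accumulation at `t`, strictly increasing in `t` and
#'   bounded in `(0, w_max)`. Extrapolated evaluations (`t < 0`) carry an
#'   `extrapolated` attribute flagging the affected positions.
#' @examples
#' p <- logistic_params(3.6217, 4101240.31, 0.0976)
#' logistic_value(p, c(100, 156, 200))
#' @export
logistic_value <- function(params, t) {
  params <- as_logistic_params(params)
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("`t` must be finite numeric", call. = FALSE)
  }
  w <- params$w_max / (1 + params$a * exp(-params$k * t))
  if (any(t < 0)) attr(w, "extrapolated") <- t < 0
  w
}

#' Characteristic values of the fast accumulation phase
#'
#' Derive, in closed form, the characteristic values ("eigenvalues") of the
#' logistic accumulation curve: the onset `t1` and termination `t2` of the
#' fast accumulation phase (the roots of the third derivative of `W`), its
#' duration `t2 - t1`, the inflection time `tm` where the accumulation rate is
#' maximal (root of the second derivative, where `W = w_max/2`), the maximum
#' rate `vm = k * w_max / 4`, and the mean rate over the fast phase
#' `vt = (w2 - w1)/(t2 - t1)`, with `w1`, `w2` the accumulations at `t1`, `t2`.
#'
#' The closed forms are
#' \deqn{T_m = \ln(a)/k, \quad T_1 = \ln\!\big(a/(2+\sqrt3)\big)/k, \quad
#'       T_2 = \ln\!\big(a/(2-\sqrt3)\big)/k}
#' so the duration `t2 - t1 = 2 ln(2 + sqrt(3))/k` depends on `k` only, and
#' `w1 = w_max/(3 + sqrt(3))`, `w2 = w_max/(3 - sqrt(3))`, hence
#' `vt = w_max / (sqrt(3) * (t2 - t1))`.
#'
#' @inheritParams logistic_value
#' @return An object of class `growth_eigenvalues`: a list with elements
#'   `t1`, `t2`, `duration`, `tm`, `vm`, `vt`, `w1`, `w2` (days and
#'   accumulation-per-day in the unit of `w_max`).
#' @examples
#' growth_eigenvalues(logistic_params(3.6217, 4101240.31, 0.0976))
#' @export
growth_eigenvalues <- function(params) {
  params <- as_logistic_params(params)
  if (params$a <= 2 - sqrt(3)) {
    stop("fast accumulation phase undefined: `a` must exceed 2 - sqrt(3) ",
         "for the phase boundaries to fall after the curve origin", call. = FALSE)
  }
  k <- params$k
  a <- params$a
  w_max <- params$w_max
  tm <- log(a) / k
  t1 <- log(a / (2 + sqrt(3))) / k
  t2 <- log(a / (2 - sqrt(3))) / k
  w1 <- w_max / (3 + sqrt(3))
  w2 <- w_max / (3 - sqrt(3))
  structure(
    list(
      t1 = t1, t2 = t2, duration = t2 - t1, tm = tm,
      vm = k * w_max / 4, vt = (w2 - w1) / (t2 - t1),
      w1 = w1, w2 = w2
    ),
    class = "growth_eigenvalues"
  )
}

#' @export
print.growth_eigenvalues <- function(x, ...) {
  cat("Fast accumulation phase characteristic values\n")
  cat(sprintf("  T1 = %.1f d   T2 = %.1f d   T = %.1f d\n", x$t1, x$t2, x$duration))
  cat(sprintf("  Tm = %.1f d   Vm = %.4f /d  Vt = %.4f /d\n", x$tm, x$vm, x$vt))
  invisible(x)
}

#' Characteristic-value table from fitted coefficients
#'
#' Coefficients-only entry point: map rows of logistic coefficients
#' `(w_max, a, k)` directly to the characteristic values of the fast
#' accumulation phase, without refitting. This reproduces the classic
#' eigenvalue tables of sowing-date trials from their published regression
#' coefficients alone.
#'
#' @param coefs A data frame with numeric columns `w_max`, `a`, `k`; any other
#'   columns (e.g. `season`, `sowing_date`, `variable`) are carried through.
#'
#' @return A tibble with the input identifier columns plus `t1`, `t2`,
#'   `duration`, `vt`, `tm`, `vm`, `w1`, `w2`.
#' @examples
#' eigenvalue_table(trial_logistic_coefficients())
#' @export
eigenvalue_table <- function(coefs) {
  stopifnot(is.data.frame(coefs))
  need <- c("w_max", "a", "k")
  if (!all(need %in% names(coefs))) {
    stop("`coefs` must contain columns w_max, a, k", call. = FALSE)
  }
  ev <- purrr::pmap(coefs[need], function(w_max, a, k) {
    e <- growth_eigenvalues(logistic_params(w_max, a, k))
    tibble::as_tibble(unclass(e))
  })
  dplyr::bind_cols(
    tibble::as_tibble(coefs[setdiff(names(coefs), c("r_squared"))]),
    dplyr::bind_rows(ev)
  )
}
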