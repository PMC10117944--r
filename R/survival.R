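# Single-hit multitarget survival model: S(D) = 1 - (1 - exp(-D/D0))^m,
# least-squares fitting, shoulder dose Dq = D0 * ln(m), and the derived
# sensitivity/effectiveness ratios.

#' Construct a survival curve
#'
#' @param D0 dose (Gy) reducing survival to 37% on the exponential portion.
#' @param m extrapolation number (>= 1), dimensionless.
#' @return a `survival_curve` list with fields `D0`, `m`, `Dq`.
#' @export
survival_curve <- function(D0, m) {
  if (D0 <= 0) stop("D0 must be positive")
  if (m < 1) stop("extrapolation number m must be >= 1")
  structure(list(D0 = D0, m = m, Dq = shoulder_dose(D0, m)),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("<survival_curve> D0 = %.4g Gy, m = %.4g, Dq = %.4g Gy\n",
              x$D0, x$m, x$Dq))
  if (!is.null(x$rss))
    cat(sprintf("  residual sum of squares = %.4g (n = %d)\n", x$rss, x$n))
  invisible(x)
}

#' Survival fraction under the single-hit multitarget model
#'
#' @param D dose (Gy), vectorized.
#' @param curve a [survival_curve()], or `D0` when `m` is given.
#' @param m extrapolation number (alternative scalar interface).
#' @return survival fraction(s) in `[0, 1]`.
#' @export
survival_fraction <- function(D, curve, m = NULL) {
  if (!inherits(curve, "survival_curve")) curve <- survival_curve(curve, m)
  if (any(D < 0)) stop("doses must be >= 0")
  1 - (1 - exp(-D / curve$D0))^curve$m
}

#' Shoulder dose Dq = D0 * ln(m)
#'
#' @param D0 37%-survival dose (Gy), > 0.
#' @param m extrapolation number, >= 1.
#' @return shoulder dose in Gy.
#' @export
shoulder_dose <- function(D0, m) {
  if (D0 <= 0) stop("D0 must be positive")
  if (m < 1) stop("extrapolation number m must be >= 1")
  D0 * log(m)
}

#' Read a dose-response table
#'
#' @param path CSV with columns `dose`, `survivors`, `total`, `replicate`.
#' @return validated data frame.
#' @export
read_dose_response <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dose", "survivors", "total", "replicate")
  if (!all(need %in% names(d)))
    stop("dose-response table must have columns: ",
         paste(need, collapse = ", "))
  validate_dose_response(d)
  d
}

validate_dose_response <- function(d) {
  stopifnot(all(d$dose >= 0), all(d$survivors >= 0),
            all(d$survivors <= d$total), all(d$total > 0))
  invisible(d)
}

#' Fit the single-hit multitarget model by least squares
#'
#' Minimizes the squared error between the model and per-replicate survival
#' fractions. Starting values use the classical graphical construction: the
#' terminal slope of log mean survival gives 1/D0 and its zero-dose
#' intercept gives m. The unweighted fraction-scale objective is the
#' default; binomial weighting is available.
#'
#' @param data dose-response data frame (`dose`, `survivors`, `total`,
#'   `replicate`), or vectors via `dose`/`fraction`.
#' @param weights `"none"` (default) or `"binomial"` (weight n/(p(1-p))
#'   evaluated at the observed mean fractions).
#' @return a `survival_curve` with extra fields `rss`, `n`, `converged`.
#' @export
fit_survival <- function(data, weights = c("none", "binomial")) {
  weights <- match.arg(weights)
  validate_dose_response(data)
  d <- data.frame(dose = data$dose, frac = data$survivors / data$total,
                  n = data$total)
  if (length(unique(d$dose)) < 3)
    stop("at least 3 distinct doses are required")
  if (all(d$frac >= 0.999) || all(d$frac <= 0.001))
    stop("degenerate fit: survival is uniformly complete or uniformly zero")

  # graphical start: log-linear asymptote from the highest doses
  mf <- vapply(split(d$frac, d$dose), mean, numeric(1))
  doses <- as.numeric(names(mf))
  o <- order(doses)
  doses <- doses[o]; mf <- mf[o]
  pos <- mf > 0 & doses > 0
  k <- min(sum(pos), max(3L, ceiling(sum(pos) / 2)))
  idx <- tail(which(pos), k)
  if (length(idx) >= 2) {
    fit0 <- lm(log(mf[idx]) ~ doses[idx])
    D0_0 <- -1 / coef(fit0)[2]
    m_0 <- exp(coef(fit0)[1])
  } else {
    D0_0 <- NA_real_
  }
  if (!is.finite(D0_0) || D0_0 <= 0) D0_0 <- max(d$dose) / 3
  if (!is.finite(m_0) || m_0 < 1) m_0 <- 1.5

  w <- if (weights == "binomial") {
    p <- pmin(pmax(d$frac, 1 / (2 * d$n)), 1 - 1 / (2 * d$n))
    d$n / (p * (1 - p))
  } else rep(1, nrow(d))

  fit <- tryCatch(
    nls(frac ~ 1 - (1 - exp(-dose / D0))^m, data = d,
        start = list(D0 = D0_0, m = max(1, m_0)), weights = w,
        algorithm = "port", lower = c(D0 = 1e-9, m = 1),
        control = list(maxiter = 200, warnOnly = FALSE)),
    error = function(e)
      stop("survival fit did not converge (start D0=", signif(D0_0, 4),
           ", m=", signif(m_0, 4), "): ", conditionMessage(e)))
  est <- coef(fit)
  curve <- survival_curve(unname(est["D0"]), unname(est["m"]))
  curve$rss <- sum(resid(fit)^2)
  curve$n <- nrow(d)
  curve$converged <- TRUE
  curve
}

#' Sensitivity ratio between two shoulder doses
#'
#' How many times more sensitive the test material is than the reference,
#' judged on the shoulder-dose scale.
#'
#' @param Dq_reference,Dq_test shoulder doses in Gy, both > 0.
#' @return fold ratio, rounded to one decimal.
#' @export
sensitivity_ratio <- function(Dq_reference, Dq_test) {
  stopifnot(Dq_reference > 0, Dq_test > 0)
  round(Dq_reference / Dq_test, 1)
}

#' Dose expressed as a percentage of the shoulder dose
#'
#' @param dose dose in Gy.
#' @param Dq shoulder dose in Gy, > 0.
#' @return whole-number percent.
#' @export
dose_fraction <- function(dose, Dq) {
  stopifnot(Dq > 0, all(dose >= 0))
  round(100 * dose / Dq)
}
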