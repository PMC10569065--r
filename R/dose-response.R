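#' Construct an erf dose-response model
#'
#' @param Emin expression floor (AU), \code{>= 0}.
#' @param Emax expression plateau (AU), \code{>= Emin}.
#' @param K half-maximal concentration (uM), \code{> 0}.
#' @param n log10 width (dimensionless, default 1), \code{> 0}.
#' @param convention \code{"halfmax"} (default; \code{Y(K)} is the
#'   floor/plateau midpoint) or \code{"literal"} (\code{Y = Emin +
#'   (Emax - Emin) erf(log10(c/K)/n)}, in which \code{Y(K) = Emin}).
#' @return a [DoseResponseModel-class].
#' @export
#' @examples
#' doseResponseModel(Emin = 1, Emax = 109, K = 1.5)
doseResponseModel <- function(Emin, Emax, K, n = 1,
                              convention = c("halfmax", "literal")) {
  convention <- match.arg(convention)
  methods::new("DoseResponseModel", Emin = as.numeric(Emin),
               Emax = as.numeric(Emax), K = as.numeric(K),
               n = as.numeric(n), convention = convention)
}

#' Predicted reporter expression at given concentrations
#'
#' Evaluates the erf dose-response curve. Under the \code{"halfmax"}
#' convention \code{Y = Emin + (Emax - Emin)(1 + erf(log10(c/K)/n))/2},
#' so \code{Y(0) = Emin}, \code{Y(K) = (Emin + Emax)/2} and
#' \code{Y(Inf) = Emax}. Under \code{"literal"},
#' \code{Y = Emin + (Emax - Emin) erf(log10(c/K)/n)}, with the
#' \code{c -> 0} limit \code{2 Emin - Emax}. \code{c = 0} always returns
#' the analytic limit.
#'
#' @param model a [DoseResponseModel-class].
#' @param c concentrations in uM, \code{>= 0} (vectorized).
#' @return predicted expression (AU), same length as \code{c}.
#' @export
predictResponse <- function(model, c) {
  stopIfNot(all(c >= 0), "'c' must be >= 0")
  dE <- model@Emax - model@Emin
  x <- ifelse(c > 0, log10(c / model@K) / model@n, -Inf)
  e <- ifelse(is.finite(x), erf(x), -1)
  if (model@convention == "halfmax") {
    model@Emin + dE * (1 + e) / 2
  } else {
    model@Emin + dE * e
  }
}

#' Fit the erf dose-response model by multi-start least squares
#'
#' Least squares of the per-concentration replicate means against
#' log10 concentration (rows with \code{c = 0} are pinned to the
#' analytic \code{c -> 0} limit rather than dropped). To enforce the
#' model invariants, the optimizer works on
#' \code{(Emin, dE = Emax - Emin, log10 K, log n)} with \code{Emin} and
#' \code{dE} bounded below by 0. Five starts place \code{log10 K} on a
#' grid spanning the positive concentration range; the best converged
#' start (objective tolerance 1e-8, Levenberg-Marquardt) is kept.
#' Standard errors come from the Jacobian at the optimum.
#' Identifiability warnings are raised when the fitted K falls outside
#' the sampled concentration range or \code{SE(log10 K) > 1}.
#'
#' @param data a data.frame with columns \code{concentration_uM} and
#'   \code{value} (a \code{replicate} column is allowed and ignored);
#'   at least 4 distinct concentrations, at least one positive.
#' @param convention \code{"halfmax"} (default) or \code{"literal"}.
#' @param weights \code{"none"} (default: unweighted means) or
#'   \code{"invVar"} (means weighted by 1/sem^2 where computable).
#' @return a [DoseResponseFit-class].
#' @export
#' @examples
#' m <- doseResponseModel(1, 79, 0.12)
#' fit <- fitDoseResponse(simulateDoseResponse(m, doseDesign(0.12), seed = 1))
#' fittedModel(fit)
fitDoseResponse <- function(data, convention = c("halfmax", "literal"),
                            weights = c("none", "invVar")) {
  convention <- match.arg(convention)
  weights <- match.arg(weights)
  stopIfNot(all(c("concentration_uM", "value") %in% names(data)),
            "'data' needs columns concentration_uM and value")
  stopIfNot(all(data$concentration_uM >= 0), "concentrations must be >= 0")
  conc <- sort(unique(data$concentration_uM))
  stopIfNot(length(conc) >= 4, "need at least 4 distinct concentrations")
  stopIfNot(any(conc > 0), "need at least one positive concentration")
  means <- vapply(conc, function(cc)
    mean(data$value[data$concentration_uM == cc]), numeric(1))
  w <- rep(1, length(conc))
  if (weights == "invVar") {
    sem2 <- vapply(conc, function(cc) {
      v <- data$value[data$concentration_uM == cc]
      if (length(v) >= 2) stats::var(v) / length(v) else NA_real_
    }, numeric(1))
    ok <- is.finite(sem2) & sem2 > 0
    if (any(ok)) w[ok] <- 1 / sem2[ok]
    w <- w / mean(w)
  }

  predict4 <- function(theta) {
    m <- methods::new("DoseResponseModel", Emin = theta[1],
                      Emax = theta[1] + theta[2], K = 10^theta[3],
                      n = exp(theta[4]), convention = convention)
    predictResponse(m, conc)
  }
  resid <- function(theta) sqrt(w) * (means - predict4(theta))

  cpos <- conc[conc > 0]
  starts <- seq(log10(min(cpos)), log10(max(cpos)), length.out = 5)
  emin0 <- max(min(means), 0)
  de0 <- max(max(means) - min(means), 1e-6)
  best <- NULL
  for (lk in starts) {
    theta0 <- c(emin0, de0, lk, 0)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = theta0, fn = resid,
        lower = c(0, 0, -Inf, -Inf),
        control = minpack.lm::nls.lm.control(
          ftol = 1e-8, ptol = 1e-8, maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop("dose-response fit failed to converge from all starts",
         call. = FALSE)
  theta <- best$fit$par
  model <- methods::new("DoseResponseModel", Emin = theta[1],
                        Emax = theta[1] + theta[2], K = 10^theta[3],
                        n = exp(theta[4]), convention = convention)
  # SEs from the Jacobian: cov = sigma^2 (J'J)^-1
  dof <- max(length(conc) - 4, 1)
  sigma2 <- best$rss / dof
  J <- best$fit$hessian  # nls.lm stores J'J here
  se <- rep(NA_real_, 4)
  covm <- tryCatch(solve(J) * sigma2, error = function(e) NULL)
  if (!is.null(covm)) se <- sqrt(pmax(diag(covm), 0))
  names(se) <- c("Emin", "dE", "log10K", "logn")
  warn <- character(0)
  if (model@K < min(cpos) || model@K > max(cpos))
    warn <- c(warn, "fitted K lies outside the sampled concentration range")
  if (is.na(se["log10K"]) || se["log10K"] > 1)
    warn <- c(warn, "K poorly identified (SE(log10 K) > 1 or singular)")
  methods::new("DoseResponseFit", model = model, se = se, rss = best$rss,
               converged = TRUE, warnings = warn,
               data = data.frame(concentration_uM = conc, mean = means))
}

#' Accessors for dose-response fits
#'
#' \code{fittedModel()} returns the fitted [DoseResponseModel-class];
#' \code{fittedK()}, \code{fittedEmax()} the fitted half-maximal
#' concentration and plateau; \code{seLog10K()} the standard error of
#' log10 K.
#'
#' @param fit a [DoseResponseFit-class].
#' @return see description.
#' @export
fittedModel <- function(fit) fit@model

#' @rdname fittedModel
#' @export
fittedK <- function(fit) fit@model@K

#' @rdname fittedModel
#' @export
fittedEmax <- function(fit) fit@model@Emax

#' @rdname fittedModel
#' @export
seLog10K <- function(fit) unname(fit@se["log10K"])

#' Fold ratio of half-maximal concentrations between two fits
#'
#' \code{ratio = K_a / K_b}, with a log10-scale standard error combined
#' by error propagation, \code{sqrt(SE(log10 K_a)^2 + SE(log10 K_b)^2)},
#' and the geometric interval \code{ratio 10^(+/- SE)}.
#'
#' @param fitA,fitB converged [DoseResponseFit-class] objects.
#' @return list with \code{ratio}, \code{seLog10}, \code{ciLow},
#'   \code{ciHigh}.
#' @export
compareK <- function(fitA, fitB) {
  stopIfNot(methods::is(fitA, "DoseResponseFit") && fitA@converged,
            "'fitA' must be a converged fit")
  stopIfNot(methods::is(fitB, "DoseResponseFit") && fitB@converged,
            "'fitB' must be a converged fit")
  ratio <- fitA@model@K / fitB@model@K
  se <- sqrt(seLog10K(fitA)^2 + seLog10K(fitB)^2)
  list(ratio = ratio, seLog10 = se,
       ciLow = ratio / 10^se, ciHigh = ratio * 10^se)
}

#' Fraction of ON cells above a fold-over-background threshold
#'
#' The fraction of expression values at or above
#' \code{fold * background} (default: 10-fold over background).
#'
#' @param values non-empty numeric expression values (AU).
#' @param background background expression (AU), \code{> 0}.
#' @param fold threshold fold (default 10).
#' @return fraction in `[0, 1]`.
#' @export
#' @examples
#' thresholdFraction(c(5, 15, 20, 9, 11), background = 1)  # 0.6
thresholdFraction <- function(values, background, fold = 10) {
  stopIfNot(length(values) >= 1, "'values' must be non-empty")
  stopIfNot(length(background) == 1 && background > 0,
            "'background' must be a single value > 0")
  mean(values >= fold * background)
}
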