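#' Ligand-depletion binding isotherm
#'
#' The quadratic (ligand-depletion) binding equation for a titration of
#' protein `X` against a fixed labeled-RNA concentration `L`:
#'
#' `Y = B + A * (K + L + X - sqrt((K + L + X)^2 - 4 * L * X)) / (2 * L)`
#'
#' where `B` is the unbound baseline (mP), `A` the amplitude (mP), and `K`
#' the equilibrium dissociation constant (same units as `X` and `L`,
#' micromolar here). `Y(0) = B` and `Y -> B + A` as `X -> Inf`; as
#' `L -> 0` the curve converges to the hyperbolic `B + A * X / (K + X)`.
#'
#' @param X Protein concentrations (uM), `X >= 0`.
#' @param B Baseline polarization (mP).
#' @param A Amplitude (mP), `A >= 0`.
#' @param K Dissociation constant (uM), `K > 0`.
#' @param L Labeled RNA concentration (uM), `L > 0`.
#' @return Polarization values, bounded by `[B, B + A]`.
#' @export
fp_isotherm <- function(X, B, A, K, L) {
  if (any(L <= 0)) stop("L must be positive")
  stopifnot(all(X >= 0), all(K > 0))
  S <- K + L + X
  # algebraically identical to (S - sqrt(S^2 - 4*L*X)) / (2*L) but free of
  # the catastrophic cancellation that form suffers for X >> K + L
  B + A * 2 * X / (S + sqrt(S^2 - 4 * L * X))
}

#' Fit the binding isotherm to fluorescence polarization data
#'
#' Nonlinear least squares over `(B, A, K)` with `L` fixed at the known
#' labeled-RNA concentration. Replicates are averaged per concentration
#' before fitting. Initialization: `B = min(Y)`, `A = max(Y) - min(Y)`,
#' `K` = concentration at half amplitude, plus deterministically jittered
#' restarts (K scaled by 1/4 .. 4); the best converged fit by residual sum
#' of squares is returned. Degenerate (flat) data yield `A = 0` with `K`
#' flagged unidentifiable rather than a spurious estimate.
#'
#' @param data A tibble with columns `concentration` (uM) and
#'   `polarization` (mP); an optional `replicate` column is averaged over.
#' @param L Labeled RNA concentration in uM (default 0.1, i.e. 100 nM).
#' @param restarts Number of jittered restarts (default 5).
#' @return An object of class `"isotherm_fit"` with `tidy()`, `glance()`
#'   and `autoplot()` methods; parameters in `$coef` (B, A, K).
#' @export
fit_isotherm <- function(data, L = 0.1, restarts = 5) {
  stopifnot(all(c("concentration", "polarization") %in% names(data)), L > 0)
  avg <- data %>%
    dplyr::group_by(.data$concentration) %>%
    dplyr::summarise(polarization = mean(.data$polarization), .groups = "drop") %>%
    dplyr::arrange(.data$concentration)
  if (nrow(avg) < 5) stop("need >= 5 distinct concentrations")
  Y <- avg$polarization; X <- avg$concentration
  if (sd(Y) == 0) {
    return(structure(list(
      coef = tibble(term = c("B", "A", "K"), estimate = c(Y[1], 0, NA_real_),
                    std.error = NA_real_),
      L = L, data = avg, fit = NULL, converged = FALSE,
      flag = "flat response: A ~ 0, K unidentifiable"
    ), class = "isotherm_fit"))
  }
  B0 <- min(Y); A0 <- max(Y) - min(Y)
  half <- B0 + A0 / 2
  K0 <- X[which.min(abs(Y - half))]
  if (K0 <= 0) K0 <- max(median(X[X > 0]), 1e-3)
  scales <- c(1, 0.5, 2, 0.25, 4)[seq_len(max(1, restarts))]
  best <- NULL
  for (sc in scales) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        polarization ~ fp_isotherm(concentration, B, A, K, L),
        data = avg,
        start = list(B = B0, A = A0, K = K0 * sc),
        lower = c(B = -Inf, A = 0, K = 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    stop("isotherm fit did not converge from any start; inspect the data")
  }
  s <- summary(best$fit)$coefficients
  flag <- NULL
  if (coef(best$fit)[["A"]] < 1e-6) flag <- "A ~ 0: K unidentifiable"
  structure(list(
    coef = tibble(term = rownames(s), estimate = s[, "Estimate"],
                  std.error = s[, "Std. Error"]),
    L = L, data = avg, fit = best$fit, converged = TRUE, flag = flag
  ), class = "isotherm_fit")
}

#' @export
tidy.isotherm_fit <- function(x, ...) x$coef

#' @export
glance.isotherm_fit <- function(x, ...) {
  rss <- if (is.null(x$fit)) NA_real_ else sum(resid(x$fit)^2)
  tibble(K = x$coef$estimate[x$coef$term == "K"],
         rss = rss, n = nrow(x$data), converged = x$converged,
         flag = ifelse(is.null(x$flag), NA_character_, x$flag))
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat(sprintf("Binding isotherm fit (L = %g uM, ligand-depletion form)\n", x$L))
  print(x$coef)
  if (!is.null(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' @export
autoplot.isotherm_fit <- function(object, ...) {
  xs <- object$data$concentration
  grid <- tibble(concentration = exp(seq(log(max(min(xs[xs > 0]), 1e-4) / 2),
                                         log(max(xs) * 2), length.out = 200)))
  cf <- setNames(object$coef$estimate, object$coef$term)
  if (!is.na(cf[["K"]])) {
    grid$polarization <- fp_isotherm(grid$concentration, cf[["B"]], cf[["A"]],
                                     cf[["K"]], object$L)
  }
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$concentration, y = .data$polarization)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "protein (uM)", y = "polarization (mP)",
                  title = "Ligand-depletion binding isotherm") +
    ggplot2::theme_minimal()
  if (!is.na(cf[["K"]])) {
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick")
  }
  p
}
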