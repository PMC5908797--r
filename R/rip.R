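#' RIP enrichment per gene
#'
#' Log2-transforms expression with a pseudo-count of 8 (`y = log2(x + 8)`),
#' quantile-normalizes across all samples to remove nonlinear scaling,
#' averages replicates, and reports enrichment = mean(IP) - mean(input).
#' Non-expressed genes (mean log2 input strictly below `min_input`) are
#' removed before the comparison.
#'
#' @param expr A tibble with a `gene` column plus one numeric column per
#'   sample (linear-scale expression).
#' @param input_samples,ip_samples Column names of the input and IP
#'   samples (at least one each).
#' @param pseudo Pseudo-count (default 8).
#' @param min_input Expression filter on the log2 input mean (default 5).
#' @return A tibble with columns `gene`, `input_mean`, `enrichment`.
#' @export
rip_enrichment <- function(expr, input_samples, ip_samples, pseudo = 8,
                           min_input = 5) {
  if (length(input_samples) == 0) stop("need at least one input sample")
  if (length(ip_samples) == 0) stop("need at least one IP sample")
  stopifnot(all(c(input_samples, ip_samples) %in% names(expr)))
  samples <- c(input_samples, ip_samples)
  y <- expr
  y[, samples] <- log2(as.matrix(expr[, samples]) + pseudo)
  names(y)[names(y) == "gene"] <- "oligo_id" # reuse the array normalizer
  y <- quantile_normalize(y[, c("oligo_id", samples)])
  input_mean <- rowMeans(y[, input_samples, drop = FALSE])
  ip_mean <- rowMeans(y[, ip_samples, drop = FALSE])
  tibble(gene = y$oligo_id, input_mean = input_mean,
         enrichment = ip_mean - input_mean) %>%
    dplyr::filter(.data$input_mean >= min_input)
}

#' Regress RIP enrichment on predicted-site features
#'
#' Ordinary least squares of per-gene enrichment on the 12 (region x
#' strength) site counts, with intercept; the "minimal" columns act as
#' close-to-no-binding controls. Aliased (rank-deficient) columns are
#' dropped and reported.
#'
#' @param enrichment A tibble with columns `gene` (or `transcript_id`) and
#'   `enrichment`.
#' @param features A feature tibble from [site_feature_matrix()].
#' @return An object of class `"lre_rip_fit"` wrapping the `lm` fit, with
#'   [tidy()], [glance()], [autoplot()] and [model_correlation()] methods.
#' @export
fit_site_regression <- function(enrichment, features) {
  key <- if ("gene" %in% names(enrichment)) "gene" else "transcript_id"
  dat <- dplyr::inner_join(
    dplyr::rename(enrichment[, c(key, "enrichment")], transcript_id = !!key),
    features, by = "transcript_id"
  )
  fcols <- setdiff(names(features), "transcript_id")
  if (nrow(dat) < length(fcols) + 1) stop("fewer genes than model parameters")
  fit <- lm(stats::reformulate(sprintf("`%s`", fcols), response = "enrichment"),
            data = dat)
  dropped <- names(coef(fit))[is.na(coef(fit))]
  if (length(dropped)) {
    warning("aliased feature columns dropped: ", paste(dropped, collapse = ", "))
  }
  structure(list(fit = fit, data = dat, features = fcols, dropped = dropped),
            class = "lre_rip_fit")
}

#' @export
tidy.lre_rip_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = gsub("`", "", rownames(s)),
         estimate = unname(s[, "Estimate"]),
         std.error = unname(s[, "Std. Error"]),
         statistic = unname(s[, "t value"]),
         p.value = unname(s[, "Pr(>|t|)"]))
}

#' @export
glance.lre_rip_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r.squared = s$r.squared, sigma = s$sigma,
         r = model_correlation(x), nobs = nrow(x$data),
         df.residual = x$fit$df.residual)
}

#' @export
print.lre_rip_fit <- function(x, ...) {
  cat(sprintf("RIP enrichment ~ site features: %d genes, %d features\n",
              nrow(x$data), length(x$features)))
  cat(sprintf("  r (observed vs fitted) = %.3f\n", model_correlation(x)))
  print(tidy(x))
  invisible(x)
}

#' Correlation between observed and fitted enrichment
#'
#' Pearson correlation of the response with the regression's fitted
#' values -- the model's overall predictive power.
#'
#' @param fit An `"lre_rip_fit"` object.
#' @return A single number, or `NA` (with a warning) for a zero-variance
#'   response or fit.
#' @export
model_correlation <- function(fit) {
  stopifnot(inherits(fit, "lre_rip_fit"))
  obs <- fit$data$enrichment
  pred <- fitted(fit$fit)
  if (sd(obs) == 0 || sd(pred) == 0) {
    warning("zero-variance input: correlation undefined")
    return(NA_real_)
  }
  cor(obs, pred)
}

#' @export
autoplot.lre_rip_fit <- function(object, ...) {
  td <- tidy(object) %>% dplyr::filter(.data$term != "(Intercept)")
  td$term <- factor(td$term, levels = rev(td$term))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$estimate - .data$std.error,
                                          xmax = .data$estimate + .data$std.error)) +
    ggplot2::labs(x = "coefficient (log2 enrichment per site)", y = NULL,
                  title = "RIP enrichment regressed on predicted sites",
                  subtitle = "error bars: +/- 1 SE") +
    ggplot2::theme_minimal()
}
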