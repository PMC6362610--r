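#' Quasi-likelihood AIC
#'
#' \code{QAIC = deviance / c_hat + 2 np}, the quasi-likelihood form of AIC
#' used to compare capture-recapture models when the encounter histories
#' show marginal overdispersion (variance inflation factor \code{c_hat}).
#'
#' @param deviance model deviance (-2 log-likelihood)
#' @param np number of estimated parameters
#' @param c_hat overdispersion factor; values below 1 are clamped to 1
#'   with a warning (underdispersion is not corrected for)
#' @return QAIC value
#' @examples
#' qaic(100, 5)              # AIC when c_hat = 1
#' qaic(24205.87, 114, 1.33)
#' @export
qaic <- function(deviance, np, c_hat = 1) {
  if (any(np < 0)) stop("np must be nonnegative")
  if (c_hat < 1) {
    warning("c_hat < 1 clamped to 1")
    c_hat <- 1
  }
  deviance / c_hat + 2 * np
}

#' Akaike weights
#'
#' \code{w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)}, the relative
#' support of each model in a candidate set given their (Q)AIC
#' differences.  Inputs that are raw (Q)AIC values rather than differences
#' are re-baselined internally, so weights are invariant to adding any
#' constant.
#'
#' @param delta numeric vector of (Q)AIC differences (or raw values)
#' @return numeric vector of weights in (0, 1] summing to 1
#' @examples
#' akaike_weights(c(56.70, 0.58, 33.87, 0.00, 176.34, 8.09, 218.14))
#' @export
akaike_weights <- function(delta) {
  if (!length(delta)) stop("empty model set")
  delta <- delta - min(delta)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' QAIC model-comparison table
#'
#' Builds the standard model-selection table (np, deviance, QAIC,
#' delta-QAIC and Akaike weight) for a set of fitted models, or for a data
#' frame of (np, deviance) pairs, at a given overdispersion factor.
#'
#' @param fits a named list of \code{\link{fit_mevrd}} results, or a data
#'   frame with columns \code{model}, \code{np}, \code{deviance}
#' @param c_hat overdispersion factor (e.g. from
#'   \code{\link{bootstrap_chat}}, or supplied directly)
#' @return data frame of class \code{mevrd_modtab}, sorted by QAIC
#' @export
model_table <- function(fits, c_hat = 1) {
  if (is.data.frame(fits)) {
    if (!all(c("np", "deviance") %in% names(fits)))
      stop("data frame input needs columns np and deviance")
    tab <- data.frame(model = if (!is.null(fits$model)) as.character(fits$model)
                              else as.character(seq_len(nrow(fits))),
                      np = fits$np, deviance = fits$deviance,
                      stringsAsFactors = FALSE)
  } else {
    if (!all(vapply(fits, inherits, logical(1), "mevrd_fit")))
      stop("fits must be mevrd_fit objects or a data frame")
    Ts <- vapply(fits, function(f) f$n_occasions, integer(1))
    if (length(unique(Ts)) > 1L)
      stop("models were fitted on different occasion axes")
    nm <- names(fits)
    if (is.null(nm)) nm <- vapply(fits, function(f) f$structure$label, character(1))
    tab <- data.frame(model = nm,
                      np = vapply(fits, function(f) f$np, numeric(1)),
                      deviance = vapply(fits, function(f) f$deviance, numeric(1)),
                      stringsAsFactors = FALSE)
  }
  tab$QAIC <- qaic(tab$deviance, tab$np, c_hat)
  tab$dQAIC <- tab$QAIC - min(tab$QAIC)
  tab$weight <- akaike_weights(tab$dQAIC)
  tab <- tab[order(tab$QAIC), ]
  rownames(tab) <- NULL
  attr(tab, "c_hat") <- c_hat
  class(tab) <- c("mevrd_modtab", "data.frame")
  tab
}

#' @export
print.mevrd_modtab <- function(x, ...) {
  cat("Model comparison (c_hat =", attr(x, "c_hat"), ")\n")
  y <- as.data.frame(x)
  y$deviance <- round(y$deviance, 2)
  y$QAIC <- round(y$QAIC, 2); y$dQAIC <- round(y$dQAIC, 2)
  y$weight <- round(y$weight, 2)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Overdispersion factor by parametric bootstrap
#'
#' Estimates the variance inflation factor c-hat of an umbrella model by
#' median parametric bootstrap: datasets are simulated at the fitted MLE
#' (conditional on the observed first captures), each is refitted, and
#' \code{c_hat = observed deviance / median(bootstrap deviances)}.  Under
#' a correctly specified model the ratio is close to 1; values above 1
#' indicate extra-multinomial variation in the encounter histories.
#'
#' @param fit a \code{\link{fit_mevrd}} result for the umbrella model
#' @param n_boot number of bootstrap replicates (>= 1)
#' @param seed integer seed
#' @param n_starts starts per refit (refits are also warm-started at the
#'   observed MLE)
#' @param control optimizer control for refits
#' @return list of class \code{mevrd_chat}: \code{c_hat}, the bootstrap
#'   deviances, the number of failed refits, and a reliability flag (set
#'   when more than 20\% of refits failed)
#' @export
bootstrap_chat <- function(fit, n_boot = 100L, seed = NULL, n_starts = 1L,
                           control = list()) {
  stopifnot(inherits(fit, "mevrd_fit"))
  if (n_boot < 1L) stop("n_boot must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  devs <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    sim <- .simulate_conditional(fit$data,
      apply_structure(unname(fit$beta), fit$structure, fit$n_occasions))
    refit <- tryCatch(
      fit_mevrd(sim, fit$structure, n_starts = n_starts,
                start = unname(fit$beta), control = control, hessian = FALSE,
                polish = FALSE),
      error = function(e) NULL)
    if (!is.null(refit)) devs[b] <- refit$deviance
  }
  n_fail <- sum(is.na(devs))
  if (n_fail == n_boot) stop("all bootstrap refits failed")
  c_hat <- fit$deviance / stats::median(devs, na.rm = TRUE)
  out <- list(c_hat = c_hat, boot_deviances = devs, n_boot = n_boot,
              n_fail = n_fail, unreliable = n_fail > 0.2 * n_boot,
              observed_deviance = fit$deviance, seed = seed)
  class(out) <- "mevrd_chat"
  out
}

#' @export
print.mevrd_chat <- function(x, ...) {
  cat("Parametric-bootstrap overdispersion estimate\n")
  cat("  c_hat            :", round(x$c_hat, 3), "\n")
  cat("  observed deviance:", round(x$observed_deviance, 2), "\n")
  cat("  bootstrap median :", round(stats::median(x$boot_deviances, na.rm = TRUE), 2),
      sprintf("(%d replicates, %d failed)\n", x$n_boot, x$n_fail))
  if (x$unreliable) cat("  WARNING: > 20% of refits failed; estimate unreliable\n")
  invisible(x)
}
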