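#' Forward log-likelihood of one encounter history
#'
#' Forward hidden-Markov recursion conditioned on first capture: a history
#' starts in the breeder state with probability 1 and its first event
#' contributes no detection term.  From the occasion after first capture,
#' the forward vector is propagated through the annual transition matrix
#' and multiplied by the event-emission column of the observed event, with
#' per-occasion rescaling so long histories do not underflow.
#'
#' @param events integer vector of event codes (0--7) from first capture
#'   onwards (the first element is the conditioning event)
#' @param params a \code{\link{param_set}} covering the occasion axis
#' @param first occasion index (on the params axis) of the first capture;
#'   \code{first + length(events) - 1} must not exceed
#'   \code{params$n_occasions}
#' @return log probability of the event suffix given first capture; an
#'   impossible history returns \code{-Inf}
#' @examples
#' p <- param_set(phi_B = 0.8, psi_BB = 0.5, m_B = 0.8, m_NB = 0.5,
#'                p_u = 0.6, b_e = 0.7, n_occasions = 2)
#' exp(history_loglik(c(5, 4), p))  # 0.2384
#' @export
history_loglik <- function(events, params, first = 1L) {
  stopifnot(inherits(params, "mevrd_params"))
  L <- length(events)
  if (L < 1L) stop("empty history")
  if (any(is.na(events)) || any(events < 0L | events > 7L))
    stop("event codes must lie in 0..7")
  if (!(events[1L] %in% .breeding_events))
    stop("history must begin with a breeding-season event (1,2,3,5,6,7)")
  last <- first + L - 1L
  if (last > params$n_occasions)
    stop("history extends beyond the parameter occasion axis")
  if (L == 1L) return(0)  # fully conditioned
  Phi <- .transition_array(params)
  Em <- .emission_array(params)
  alpha <- c(1, 0, 0)
  logscale <- 0
  for (k in 2:L) {
    t <- first + k - 1L            # occasion index of this event
    alpha <- as.vector(alpha %*% Phi[, , t - 1L]) * Em[, events[k] + 1L, t - 1L]
    s <- sum(alpha)
    if (s <= 0) return(-Inf)
    alpha <- alpha / s
    logscale <- logscale + log(s)
  }
  logscale
}

#' Brute-force history probability by state-path enumeration
#'
#' Independent check of the forward algorithm: sums, over every latent
#' state path (3^(L-1) paths), the product of transition probabilities and
#' event-emission probabilities, under the same first-capture
#' conditioning.  Exponential in history length; refuses lengths above
#' \code{max_len}.
#'
#' @inheritParams history_loglik
#' @param max_len enumeration cap (default 12)
#' @return probability (not log) of the event suffix
#' @export
brute_force_history_prob <- function(events, params, first = 1L, max_len = 12L) {
  L <- length(events)
  if (L > max_len)
    stop("history of length ", L, " exceeds the enumeration cap (", max_len,
         "); use the forward algorithm")
  if (!(events[1L] %in% .breeding_events))
    stop("history must begin with a breeding-season event (1,2,3,5,6,7)")
  if (L == 1L) return(1)
  Phi <- .transition_array(params)
  Em <- .emission_array(params)
  paths <- expand.grid(rep(list(1:3), L - 1L), KEEP.OUT.ATTRS = FALSE)
  total <- 0
  for (r in seq_len(nrow(paths))) {
    path <- c(1L, as.integer(paths[r, ]))  # start state B
    pr <- 1
    for (k in 2:L) {
      t <- first + k - 1L
      pr <- pr * Phi[path[k - 1L], path[k], t - 1L] *
        Em[path[k], events[k] + 1L, t - 1L]
      if (pr == 0) break
    }
    total <- total + pr
  }
  total
}

#' Total log-likelihood and deviance of a dataset
#'
#' Multiplicity-weighted sum of per-history forward log-likelihoods,
#' evaluated jointly (one vectorized forward pass over all histories).
#'
#' @param data a \code{\link{mevrd_data}}
#' @param params a \code{\link{param_set}} on the same occasion axis
#' @return the total log-likelihood, with attributes \code{deviance}
#'   (-2 log L) and, when some history has probability zero,
#'   \code{impossible} (their ids)
#' @export
total_loglik <- function(data, params) {
  stopifnot(inherits(data, "mevrd_data"), inherits(params, "mevrd_params"))
  if (ncol(data$events) != params$n_occasions)
    stop("data and params disagree on the number of occasions")
  ll <- .dataset_loglik(data, .transition_array(params), .emission_array(params))
  total <- sum(ll * data$count)
  if (any(!is.finite(ll))) {
    total <- -Inf
    attr(total, "impossible") <- data$id[!is.finite(ll)]
  }
  attr(total, "deviance") <- -2 * total
  total
}

# vectorized forward pass: all histories at once, column by column.
# alpha is an n x 3 matrix; rows enter at their first-capture occasion and
# are rescaled each step, accumulating the log scale.
.dataset_loglik <- function(data, Phi, Em) {
  ev <- data$events
  n <- nrow(ev); T <- ncol(ev)
  alpha <- matrix(0, n, 3)
  logl <- numeric(n)
  dead <- logical(n)  # histories that hit probability zero
  for (t in seq_len(T)) {
    entering <- data$first == t
    if (t > 1L) {
      active <- data$first < t & !dead
      if (any(active)) {
        a <- alpha[active, , drop = FALSE] %*% Phi[, , t - 1L]
        e <- ev[active, t]
        a <- a * t(Em[, e + 1L, t - 1L])
        s <- rowSums(a)
        zero <- s <= 0
        if (any(zero)) {
          idx <- which(active)[zero]
          dead[idx] <- TRUE
          logl[idx] <- -Inf
        }
        ok <- !zero
        if (any(ok)) {
          idx <- which(active)[ok]
          alpha[idx, ] <- a[ok, , drop = FALSE] / s[ok]
          logl[idx] <- logl[idx] + log(s[ok])
        }
      }
    }
    if (any(entering)) alpha[entering, ] <- rep(c(1, 0, 0), each = sum(entering))
  }
  logl
}
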