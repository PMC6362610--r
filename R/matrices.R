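.states <- c("B", "NB", "D")

#' Annual state-transition matrix
#'
#' The state process over one year decomposes as a survival step followed
#' by a conditional breeding step: a 3 x 3 survival matrix (diagonal
#' survival with a death column) multiplied by a conditional breeding
#' matrix, giving, with departure states in rows and arrival states in
#' columns (B, NB, D):
#' \deqn{row B = (\phi_B \psi_{B-B},\ \phi_B (1 - \psi_{B-B}),\ 1 - \phi_B)}
#' and analogously for NB; death is absorbing.
#'
#' @param phi_B,phi_NB annual apparent survival by departure state
#' @param psi_BB probability a surviving breeder breeds again next year
#' @param psi_NBB probability a surviving nonbreeder breeds next year
#' @return 3 x 3 row-stochastic matrix with dimnames B, NB, D
#' @examples
#' transition_matrix(0.76, 0.76, 0.84, 0.66)
#' @export
transition_matrix <- function(phi_B, phi_NB, psi_BB, psi_NBB) {
  args <- c(phi_B = phi_B, phi_NB = phi_NB, psi_BB = psi_BB, psi_NBB = psi_NBB)
  if (any(args < 0 | args > 1))
    stop("probabilities must lie in [0, 1]: ",
         paste(names(args)[args < 0 | args > 1], collapse = ", "))
  surv <- matrix(c(phi_B, 0, 1 - phi_B,
                   0, phi_NB, 1 - phi_NB,
                   0, 0, 1), 3, 3, byrow = TRUE)
  breed <- matrix(c(psi_BB, 1 - psi_BB, 0,
                    psi_NBB, 1 - psi_NBB, 0,
                    0, 0, 1), 3, 3, byrow = TRUE)
  out <- surv %*% breed
  dimnames(out) <- list(.states, .states)
  out
}

#' Observation-process event matrices
#'
#' The observation process for one occasion is the product of three
#' row-stochastic matrices applied in the order moult/winter, uneven
#' breeding weeks, even breeding weeks (the order is immaterial to the
#' composite):
#' \itemize{
#'   \item \code{B_M} (3 x 4): state-specific capture outside the breeding
#'     season; columns (M_B, notM_B, M_NB, notM_NB);
#'   \item \code{B_U} (4 x 6): breeder capture in the uneven weeks;
#'     columns (UM, notU.M, U, notU, M_NB, notM_NB) -- nonbreeder rows
#'     have no free parameters because nonbreeders are unavailable for
#'     capture in the breeding season;
#'   \item \code{B_E} (6 x 8): breeder capture in the even weeks; columns
#'     are the eight composite events in code order
#'     NS, MUE, MU, ME, M, UE, U, E.
#' }
#' The composite 3 x 8 matrix \code{B_M \%*\% B_U \%*\% B_E} gives, per
#' latent state, the probability of each composite event; for a breeder it
#' equals the product of three independent Bernoulli detections.
#'
#' @param m_B,m_NB moult/winter capture probability of breeders / nonbreeders
#' @param p_u breeder capture probability over the uneven survey weeks
#' @param b_e breeder capture probability over the even survey weeks
#' @return list with components \code{B_M}, \code{B_U}, \code{B_E},
#'   \code{composite}
#' @examples
#' event_matrices(0.8, 0.5, 0.6, 0.7)$composite
#' @export
event_matrices <- function(m_B, m_NB, p_u, b_e) {
  args <- c(m_B = m_B, m_NB = m_NB, p_u = p_u, b_e = b_e)
  if (any(args < 0 | args > 1))
    stop("probabilities must lie in [0, 1]: ",
         paste(names(args)[args < 0 | args > 1], collapse = ", "))
  B_M <- matrix(c(m_B, 1 - m_B, 0, 0,
                  0, 0, m_NB, 1 - m_NB,
                  0, 0, 0, 1), 3, 4, byrow = TRUE,
                dimnames = list(.states, c("M_B", "notM_B", "M_NB", "notM_NB")))
  B_U <- matrix(c(p_u, 1 - p_u, 0, 0, 0, 0,
                  0, 0, p_u, 1 - p_u, 0, 0,
                  0, 0, 0, 0, 1, 0,
                  0, 0, 0, 0, 0, 1), 4, 6, byrow = TRUE,
                dimnames = list(c("M_B", "notM_B", "M_NB", "notM_NB"),
                                c("UM", "notU.M", "U", "notU", "M_NB", "notM_NB")))
  B_E <- matrix(c(0, b_e, 1 - b_e, 0, 0, 0, 0, 0,
                  0, 0, 0, b_e, 1 - b_e, 0, 0, 0,
                  0, 0, 0, 0, 0, b_e, 1 - b_e, 0,
                  1 - b_e, 0, 0, 0, 0, 0, 0, b_e,
                  0, 0, 0, 0, 1, 0, 0, 0,
                  1, 0, 0, 0, 0, 0, 0, 0), 6, 8, byrow = TRUE,
                dimnames = list(c("UM", "notU.M", "U", "notU", "M_NB", "notM_NB"),
                                event_table()$label))
  composite <- B_M %*% B_U %*% B_E
  list(B_M = B_M, B_U = B_U, B_E = B_E, composite = composite)
}

# per-occasion transition (3 x 3 x (T-1)) and emission (3 x 8 x (T-1)) arrays
.transition_array <- function(params) {
  T1 <- params$n_occasions - 1L
  out <- array(NA_real_, c(3, 3, T1), dimnames = list(.states, .states, NULL))
  for (j in seq_len(T1))
    out[, , j] <- transition_matrix(params$phi["B", j], params$phi["NB", j],
                                    params$psi["B", j], params$psi["NB", j])
  out
}

.emission_array <- function(params) {
  T1 <- params$n_occasions - 1L
  out <- array(NA_real_, c(3, 8, T1),
               dimnames = list(.states, event_table()$label, NULL))
  for (j in seq_len(T1))
    out[, , j] <- event_matrices(params$m["B", j], params$m["NB", j],
                                 params$pu[j], params$be[j])$composite
  out
}
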