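#' Real-scale parameter set
#'
#' Holds every probability of the 3-state model expanded over the occasion
#' axis.  Survival (\code{phi}) and conditional breeding probability
#' (\code{psi}) are indexed by interval (column j = transition from
#' occasion j to j + 1); detection parameters (\code{m}, \code{pu},
#' \code{be}) are indexed by arrival occasion (column j = occasion j + 1,
#' the first occasion carrying a detection term being the one after first
#' capture).
#'
#' @param phi_B,phi_NB annual apparent survival of breeders / nonbreeders
#' @param psi_BB probability that a surviving breeder breeds again
#' @param psi_NBB probability that a surviving nonbreeder breeds
#' @param m_B,m_NB moult/winter capture probability by state
#' @param p_u breeding-season capture probability, "uneven" weeks (breeders)
#' @param b_e breeding-season capture probability, "even" weeks (breeders)
#' @param n_occasions number of primary occasions T (>= 2); scalars are
#'   broadcast over the T - 1 intervals/occasions
#' @return object of class \code{mevrd_params}: matrices \code{phi},
#'   \code{psi}, \code{m} (2 x (T-1), rows B and NB) and vectors
#'   \code{pu}, \code{be} (length T - 1)
#' @export
param_set <- function(phi_B, phi_NB = phi_B, psi_BB, psi_NBB = psi_BB,
                      m_B, m_NB = m_B, p_u, b_e = p_u, n_occasions) {
  T1 <- n_occasions - 1L
  if (T1 < 1L) stop("need at least 2 occasions")
  bc <- function(x, nm) {
    if (length(x) == 1L) x <- rep(x, T1)
    if (length(x) != T1) stop(nm, " must have length 1 or ", T1)
    if (any(x < 0 | x > 1)) stop(nm, " must lie in [0, 1]")
    x
  }
  p <- list(
    phi = rbind(B = bc(phi_B, "phi_B"), NB = bc(phi_NB, "phi_NB")),
    psi = rbind(B = bc(psi_BB, "psi_BB"), NB = bc(psi_NBB, "psi_NBB")),
    m   = rbind(B = bc(m_B, "m_B"), NB = bc(m_NB, "m_NB")),
    pu  = bc(p_u, "p_u"),
    be  = bc(b_e, "b_e"),
    n_occasions = as.integer(n_occasions))
  class(p) <- "mevrd_params"
  p
}

#' @export
print.mevrd_params <- function(x, ...) {
  cat("mevrd parameter set over", x$n_occasions, "occasions\n")
  for (f in c("phi", "psi", "m")) {
    cat(" ", f, ":\n"); print(round(x[[f]], 4))
  }
  cat("  pu:", round(x$pu, 4), "\n  be:", round(x$be, 4), "\n")
  invisible(x)
}

.families <- c("phi", "psi", "m", "pu", "be")
.state_families <- c("phi", "psi", "m")  # pu/be apply to breeders only

#' Declare a model structure
#'
#' A structure says, for each parameter family, whether it varies by state
#' and/or by time, or is fixed at a known value.  Two equivalent input
#' forms are accepted:
#'
#' \itemize{
#'   \item a notation string such as
#'     \code{"phi(.) psi(state*t) m(state*t) pu(t) be(t)"}, with patterns
#'     \code{.} (constant), \code{t} (time), \code{state},
#'     \code{state*t}, or \code{=v} (fixed at probability v);
#'   \item a named list, e.g.
#'     \code{list(phi = list(by_state = FALSE, by_time = FALSE), ...)},
#'     as produced by a YAML config.
#' }
#'
#' Families \code{pu} and \code{be} have no state dimension (nonbreeders
#' are unavailable for capture in the breeding season), so only \code{.},
#' \code{t} and fixed patterns are valid for them.
#'
#' @param x notation string or list as above
#' @return object of class \code{mevrd_structure}
#' @examples
#' model_structure("phi(.) psi(state) m(state) pu(.) be(.)")
#' @export
model_structure <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    toks <- regmatches(x, gregexpr("([a-z]+)\\(([^)]*)\\)", x))[[1L]]
    if (!length(toks)) stop("cannot parse model structure string: ", x,
      "\n  grammar: family(pattern) ..., family in {phi, psi, m, pu, be},",
      "\n  pattern in {., t, state, state*t, =v}")
    fam <- sub("\\(.*", "", toks)
    pat <- sub(".*\\(([^)]*)\\)", "\\1", toks)
    spec <- stats::setNames(as.list(pat), fam)
  } else if (is.list(x)) {
    spec <- lapply(x, function(f) {
      if (is.list(f)) {
        if (!is.null(f$fixed)) return(paste0("=", f$fixed))
        paste0(if (isTRUE(f$by_state)) "state" else "",
               if (isTRUE(f$by_state) && isTRUE(f$by_time)) "*" else "",
               if (isTRUE(f$by_time)) "t" else "") -> p
        if (p == "") "." else p
      } else as.character(f)
    })
  } else stop("x must be a notation string or a list")
  unknown <- setdiff(names(spec), .families)
  if (length(unknown)) stop("unknown parameter family: ",
                            paste(unknown, collapse = ", "))
  missing <- setdiff(.families, names(spec))
  if (length(missing)) stop("structure must cover all families; missing: ",
                            paste(missing, collapse = ", "))
  fams <- lapply(.families, function(f) {
    p <- spec[[f]]
    if (grepl("^=", p)) {
      v <- as.numeric(sub("^=", "", p))
      if (is.na(v) || v < 0 || v > 1) stop("fixed value for ", f,
                                           " must be a probability")
      return(list(fixed = v, by_state = FALSE, by_time = FALSE))
    }
    if (!p %in% c(".", "t", "state", "state*t", "t*state"))
      stop("invalid pattern '", p, "' for ", f,
           "; use ., t, state, state*t or =v")
    by_state <- p %in% c("state", "state*t", "t*state")
    by_time <- p %in% c("t", "state*t", "t*state")
    if (by_state && !f %in% .state_families)
      stop("family ", f, " has no state dimension (breeding-season capture",
           " applies to breeders only)")
    list(fixed = NULL, by_state = by_state, by_time = by_time)
  })
  names(fams) <- .families
  structure(list(families = fams, label = format_structure(fams)),
            class = "mevrd_structure")
}

format_structure <- function(fams) {
  paste(vapply(names(fams), function(f) {
    ff <- fams[[f]]
    pat <- if (!is.null(ff$fixed)) paste0("=", ff$fixed)
      else if (ff$by_state && ff$by_time) "state*t"
      else if (ff$by_state) "state"
      else if (ff$by_time) "t" else "."
    paste0(f, "(", pat, ")")
  }, character(1)), collapse = " ")
}

#' @export
print.mevrd_structure <- function(x, ...) {
  cat("mevrd model structure:", x$label, "\n")
  invisible(x)
}

# slot layout: family-major (phi, psi, m, pu, be), then state (B before NB),
# then time (interval/occasion order).  Stable across versions.
.structure_slots <- function(structure, n_occasions) {
  T1 <- n_occasions - 1L
  out <- list()
  for (f in .families) {
    ff <- structure$families[[f]]
    if (!is.null(ff$fixed)) { out[[f]] <- NULL; next }
    states <- if (f %in% .state_families && ff$by_state) c("B", "NB") else "."
    times  <- if (ff$by_time) seq_len(T1) else 0L  # 0 = all
    out[[f]] <- expand.grid(time = times, state = states,
                            KEEP.OUT.ATTRS = FALSE,
                            stringsAsFactors = FALSE)[, 2:1]
    out[[f]]$family <- f
  }
  slots <- do.call(rbind, out)
  if (is.null(slots) || nrow(slots) == 0L) slots <-
    data.frame(state = character(0), time = integer(0), family = character(0))
  rownames(slots) <- NULL
  slots[c("family", "state", "time")]
}

#' Number of working-scale parameters of a structure
#'
#' Counts the free slots implied by the variation patterns: a family
#' contributes (2 if by state else 1) x (T - 1 if by time else 1) slots;
#' fixed families contribute none.  This is the raw slot count; the
#' numerically estimable dimension (Hessian rank) is reported separately
#' by \code{\link{fit_mevrd}}.
#'
#' @param structure a \code{\link{model_structure}}
#' @param n_occasions number of primary occasions T
#' @return integer
#' @export
n_par <- function(structure, n_occasions) {
  stopifnot(inherits(structure, "mevrd_structure"))
  nrow(.structure_slots(structure, n_occasions))
}

#' Map a working-scale vector to a real-scale parameter set
#'
#' Applies the inverse logit entrywise and broadcasts constant patterns
#' over time and state, following the documented family-major slot layout
#' (family order phi, psi, m, pu, be; within a family state B before NB;
#' within a state, time order).
#'
#' @param beta working-scale (logit) parameter vector
#' @param structure a \code{\link{model_structure}}
#' @param n_occasions number of primary occasions T
#' @return a \code{\link{param_set}}
#' @export
apply_structure <- function(beta, structure, n_occasions) {
  slots <- .structure_slots(structure, n_occasions)
  if (length(beta) != nrow(slots))
    stop("beta has length ", length(beta), " but structure requires ",
         nrow(slots), " working parameters")
  T1 <- n_occasions - 1L
  vals <- stats::plogis(beta)
  get <- function(f, state) {
    ff <- structure$families[[f]]
    if (!is.null(ff$fixed)) return(rep(ff$fixed, T1))
    s <- if (ff$by_state) state else "."
    idx <- which(slots$family == f & slots$state == s)
    v <- vals[idx]
    if (structure$families[[f]]$by_time) v[order(slots$time[idx])] else rep(v, T1)
  }
  param_set(phi_B = get("phi", "B"), phi_NB = get("phi", "NB"),
            psi_BB = get("psi", "B"), psi_NBB = get("psi", "NB"),
            m_B = get("m", "B"), m_NB = get("m", "NB"),
            p_u = get("pu", "."), b_e = get("be", "."),
            n_occasions = n_occasions)
}

# working-scale slot labels, for fit reports
.slot_labels <- function(structure, n_occasions, years = NULL) {
  slots <- .structure_slots(structure, n_occasions)
  if (nrow(slots) == 0L) return(character(0))
  occ <- function(f, t) {
    if (t == 0L) return("all")
    # survival/psi label the interval start year; detection the arrival occasion
    if (is.null(years)) years <- seq_len(n_occasions)
    if (f %in% c("phi", "psi")) as.character(years[t])
    else as.character(years[t + 1L])
  }
  mapply(function(f, s, t) paste0(f, if (s != ".") paste0("_", s) else "",
                                  "[", occ(f, t), "]"),
         slots$family, slots$state, slots$time, USE.NAMES = FALSE)
}
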