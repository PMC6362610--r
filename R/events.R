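#' Composite event codes
#'
#' Annual resightings of a marked female are collapsed into one of eight
#' composite events per "seal year" (September of year t to August of
#' t + 1), according to which of three capture periods produced at least
#' one sighting:
#'
#' \itemize{
#'   \item \code{U} -- the "uneven" breeding-season survey weeks (1, 3, 5, 7),
#'   \item \code{E} -- the "even" breeding-season survey weeks (2, 4, 6, 8),
#'   \item \code{M} -- the moult and winter (all nonbreeding-season sightings).
#' }
#'
#' The eight events are coded 0--7: 0 = NS (not seen), 1 = MUE, 2 = MU,
#' 3 = ME, 4 = M, 5 = UE, 6 = U, 7 = E.  Codes 1--4 imply a moult/winter
#' sighting; 1, 2, 5, 6 a sighting in an uneven week; 1, 3, 5, 7 a
#' sighting in an even week.  Events 1, 2, 3, 5, 6 and 7 involve a
#' breeding-season sighting and so identify the animal as a breeder;
#' event 4 (seen only outside the breeding season) is state-ambiguous.
#'
#' @format A data frame with 8 rows and columns \code{code}, \code{label},
#'   and indicator columns \code{M}, \code{U}, \code{E}.
#' @export
event_table <- function() {
  data.frame(
    code  = 0:7,
    label = c("NS", "MUE", "MU", "ME", "M", "UE", "U", "E"),
    M     = c(0L, 1L, 1L, 1L, 1L, 0L, 0L, 0L),
    U     = c(0L, 1L, 1L, 0L, 0L, 1L, 1L, 0L),
    E     = c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L),
    stringsAsFactors = FALSE
  )
}

# events that include a breeding-season sighting (valid first-capture events)
.breeding_events <- c(1L, 2L, 3L, 5L, 6L, 7L)

#' Classify a survey context into a capture period
#'
#' Maps raw survey context labels to the three collapsed capture periods:
#' odd breeding weeks to \code{"U"}, even breeding weeks to \code{"E"},
#' and moult or winter sightings to \code{"M"}.
#'
#' @param context character vector of context labels; valid labels are
#'   \code{"breed_week_1"} ... \code{"breed_week_8"}, \code{"moult"} and
#'   \code{"winter"}.
#' @return character vector of \code{"U"}, \code{"E"} or \code{"M"}.
#' @examples
#' classify_capture_period(c("breed_week_1", "breed_week_8", "winter"))
#' @export
classify_capture_period <- function(context) {
  context <- as.character(context)
  out <- rep(NA_character_, length(context))
  out[context %in% c("moult", "winter")] <- "M"
  wk <- regmatches(context, regexec("^breed_week_([1-8])$", context))
  wkn <- vapply(wk, function(m) if (length(m) == 2L) as.integer(m[2L]) else NA_integer_,
                integer(1))
  out[!is.na(wkn) & wkn %% 2L == 1L] <- "U"
  out[!is.na(wkn) & wkn %% 2L == 0L] <- "E"
  if (anyNA(out)) {
    bad <- unique(context[is.na(out)])
    stop("unknown survey context label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Collapse the capture periods of one individual-year into an event code
#'
#' A pure function of the *set* of capture periods with at least one
#' sighting: duplicate sightings within a period are ignored and the order
#' of records is irrelevant.  An empty input yields event 0 (not seen).
#'
#' @param periods character vector of capture periods (\code{"U"},
#'   \code{"E"}, \code{"M"}), possibly with repeats; or a character vector
#'   of raw context labels if \code{classify = TRUE}.
#' @param classify if \code{TRUE}, run \code{\link{classify_capture_period}}
#'   on the input first.
#' @return a single integer event code 0--7.
#' @examples
#' collapse_to_event(c("U", "M", "U"))  # MU -> 2
#' collapse_to_event(character(0))      # NS -> 0
#' @export
collapse_to_event <- function(periods, classify = FALSE) {
  if (classify) periods <- classify_capture_period(periods)
  bad <- setdiff(unique(periods), c("U", "E", "M"))
  if (length(bad))
    stop("invalid capture period(s): ", paste(bad, collapse = ", "), call. = FALSE)
  has <- c(M = "M" %in% periods, U = "U" %in% periods, E = "E" %in% periods)
  tab <- event_table()
  tab$code[tab$M == has["M"] & tab$U == has["U"] & tab$E == has["E"]]
}

#' @rdname event_table
#' @param code integer vector of event codes 0--7
#' @return \code{event_label} returns the short labels (NS, MUE, ...).
#' @export
event_label <- function(code) {
  stopifnot(all(code %in% 0:7))
  event_table()$label[code + 1L]
}
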