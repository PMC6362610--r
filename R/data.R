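#' Encounter-history dataset
#'
#' Container for multievent encounter histories on a common occasion
#' (year) axis.  Each history starts at the individual's first
#' breeding-season detection (an event in \{1, 2, 3, 5, 6, 7\}); occasions
#' before first capture are stored as \code{NA}.
#'
#' @param events integer matrix, individuals in rows, occasions in
#'   columns; entries 0--7, \code{NA} before first capture.
#' @param years vector of occasion labels (one per column of
#'   \code{events}); defaults to \code{1:ncol(events)}.
#' @param id character vector of animal identifiers.
#' @param count positive integer multiplicities (identical histories may
#'   be stored once with a count).
#' @return an object of class \code{mevrd_data} with components
#'   \code{events}, \code{years}, \code{id}, \code{first} (index of first
#'   capture per history) and \code{count}.
#' @export
mevrd_data <- function(events, years = NULL, id = NULL, count = NULL) {
  events <- as.matrix(events)
  storage.mode(events) <- "integer"
  n <- nrow(events); T <- ncol(events)
  if (is.null(years)) years <- seq_len(T)
  if (length(years) != T) stop("length(years) must equal ncol(events)")
  if (is.null(id)) id <- as.character(seq_len(n))
  if (is.null(count)) count <- rep(1L, n)
  if (any(count < 1L)) stop("multiplicities must be >= 1")
  obs <- !is.na(events)
  if (any(events[obs] < 0L | events[obs] > 7L))
    stop("event codes must lie in 0..7")
  first <- apply(obs, 1L, function(x) which(x)[1L])
  if (anyNA(first)) stop("history with no observed occasions")
  for (i in seq_len(n)) {
    if (any(!obs[i, first[i]:T]))
      stop("history ", id[i], " has NA after first capture")
    if (!(events[i, first[i]] %in% .breeding_events))
      stop("history ", id[i],
           " does not start with a breeding-season event (1,2,3,5,6,7)")
  }
  structure(
    list(events = events, years = years, id = id,
         first = as.integer(first), count = as.integer(count)),
    class = "mevrd_data")
}

#' @export
print.mevrd_data <- function(x, ...) {
  cat("Multievent encounter histories\n")
  cat("  occasions   :", length(x$years), sprintf("(%s..%s)\n",
      x$years[1], x$years[length(x$years)]))
  cat("  histories   :", nrow(x$events),
      sprintf("(%d individuals with multiplicity)\n", sum(x$count)))
  tab <- table(factor(x$events[!is.na(x$events)], levels = 0:7))
  names(tab) <- event_table()$label
  cat("  event counts:\n")
  print(tab)
  invisible(x)
}

#' @export
summary.mevrd_data <- function(object, ...) print(object, ...)

#' Number of histories / occasions
#' @param data a \code{\link{mevrd_data}} object
#' @return integer
#' @export
n_histories <- function(data) sum(data$count)

#' Build conditioned encounter histories from resight records
#'
#' Collapses raw resight records (one row per sighting) to one composite
#' event per individual per year, then conditions each history on the
#' first breeding-season detection: leading occasions up to (but
#' excluding) the first event in \{1, 2, 3, 5, 6, 7\} are discarded, and
#' individuals never detected in a breeding season are excluded and
#' reported via the \code{"exclusions"} attribute.
#'
#' @param records data frame with columns \code{animal_id}, \code{year}
#'   and \code{context} (see \code{\link{classify_capture_period}} for
#'   valid context labels).
#' @param years the full ordered occasion axis; defaults to
#'   \code{min(year):max(year)} seen in the records.  Record years outside
#'   a supplied axis are an error.
#' @return a \code{\link{mevrd_data}} object with attributes
#'   \code{exclusions} (ids never seen in a breeding season) and
#'   \code{n_truncated} (number of discarded pre-first-capture events that
#'   were nonzero, per retained individual).
#' @export
build_histories <- function(records, years = NULL) {
  req <- c("animal_id", "year", "context")
  if (!all(req %in% names(records)))
    stop("records must have columns ", paste(req, collapse = ", "))
  if (nrow(records) == 0L) {
    if (is.null(years)) stop("no records and no occasion axis supplied")
    warning("no resight records: returning an empty dataset")
    empty <- structure(
      list(events = matrix(integer(0), 0, length(years)), years = years,
           id = character(0), first = integer(0), count = integer(0)),
      class = "mevrd_data")
    attr(empty, "exclusions") <- character(0)
    return(empty)
  }
  records$year <- as.integer(records$year)
  if (is.null(years)) years <- seq(min(records$year), max(records$year))
  if (!all(records$year %in% years)) {
    bad <- sort(unique(records$year[!records$year %in% years]))
    stop("record year(s) outside occasion axis: ", paste(bad, collapse = ", "))
  }
  records$period <- classify_capture_period(records$context)
  T <- length(years)
  ids <- unique(as.character(records$animal_id))
  ev <- matrix(0L, length(ids), T, dimnames = list(ids, years))
  sp <- split(records, list(factor(as.character(records$animal_id), levels = ids),
                            factor(records$year, levels = years)), drop = TRUE)
  for (chunk in sp) {
    i <- as.character(chunk$animal_id[1L])
    j <- match(chunk$year[1L], years)
    ev[i, j] <- collapse_to_event(chunk$period)
  }
  first <- apply(ev, 1L, function(x) {
    w <- which(x %in% .breeding_events)
    if (length(w)) w[1L] else NA_integer_
  })
  excl <- ids[is.na(first)]
  keep <- !is.na(first)
  ev <- ev[keep, , drop = FALSE]; first <- first[keep]; ids <- ids[keep]
  n_trunc <- integer(length(ids))
  for (i in seq_along(ids)) {
    if (first[i] > 1L) {
      pre <- ev[i, seq_len(first[i] - 1L)]
      n_trunc[i] <- sum(pre != 0L)
      ev[i, seq_len(first[i] - 1L)] <- NA_integer_
    }
  }
  out <- mevrd_data(ev, years = years, id = ids)
  attr(out, "exclusions") <- excl
  attr(out, "n_truncated") <- n_trunc
  if (length(excl))
    message(length(excl), " individual(s) never seen in a breeding season were excluded")
  out
}

#' Merge identical histories
#'
#' Collapses rows with identical (first occasion, event sequence) into a
#' single row with summed multiplicity.  The likelihood is unchanged;
#' evaluation gets cheaper.
#'
#' @param data a \code{\link{mevrd_data}} object
#' @return a \code{\link{mevrd_data}} object with unique histories
#' @export
compress_histories <- function(data) {
  key <- apply(data$events, 1L, function(x) paste(ifelse(is.na(x), ".", x), collapse = ""))
  grp <- split(seq_along(key), key)
  idx <- vapply(grp, `[`, integer(1), 1L)
  cnt <- vapply(grp, function(g) sum(data$count[g]), integer(1))
  mevrd_data(data$events[idx, , drop = FALSE], years = data$years,
             id = data$id[idx], count = cnt)
}

# ---- file formats -----------------------------------------------------------

#' Read resight records from CSV
#'
#' Accepts either a headed CSV \code{animal_id,year,context} (context as in
#' \code{\link{classify_capture_period}}), or \code{animal_id,date} (ISO
#' dates) together with a season calendar from which seal year and context
#' are derived: a seal year runs from September of year t through August of
#' t + 1; the eight weekly breeding surveys are anchored on
#' \code{anchor_mmdd} (default September 1), and any sighting outside those
#' eight weeks maps to the moult/winter period.
#'
#' @param path CSV file path
#' @param calendar optional list with element \code{anchor_mmdd} (a
#'   \code{"mm-dd"} string) used when the file has a \code{date} column.
#' @return data frame \code{animal_id,year,context}
#' @export
read_resights <- function(path, calendar = list(anchor_mmdd = "09-01")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("animal_id", "year", "context") %in% names(df))) {
    classify_capture_period(df$context)  # validate early, names offending labels
    return(df[c("animal_id", "year", "context")])
  }
  if (!all(c("animal_id", "date") %in% names(df)))
    stop("resight CSV must have columns animal_id,year,context or animal_id,date")
  d <- as.Date(df$date)
  if (anyNA(d)) stop("unparseable date(s) at row(s): ",
                     paste(which(is.na(d)), collapse = ", "))
  mo <- as.integer(format(d, "%m"))
  yr <- as.integer(format(d, "%Y"))
  seal_year <- ifelse(mo >= 9L, yr, yr - 1L)
  anchor <- as.Date(paste0(seal_year, "-", calendar$anchor_mmdd))
  wk <- as.integer(floor(as.numeric(d - anchor) / 7)) + 1L
  context <- ifelse(wk >= 1L & wk <= 8L, paste0("breed_week_", wk), "moult")
  data.frame(animal_id = as.character(df$animal_id), year = seal_year,
             context = context, stringsAsFactors = FALSE)
}

#' Read / write encounter-history tables
#'
#' The on-disk format is a headed CSV with columns \code{animal_id},
#' \code{count}, then one column per occasion (named by year) holding
#' event codes 0--7, with empty cells before first capture.
#'
#' @param path CSV file path
#' @return \code{read_histories} returns a \code{\link{mevrd_data}}.
#' @export
read_histories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("animal_id", "count") %in% names(df)))
    stop("history CSV must have columns animal_id, count, then one per year")
  yrs <- setdiff(names(df), c("animal_id", "count"))
  ev <- as.matrix(df[yrs]); storage.mode(ev) <- "integer"
  mevrd_data(ev, years = suppressWarnings(as.integer(yrs)),
             id = as.character(df$animal_id), count = df$count)
}

#' @rdname read_histories
#' @param data a \code{\link{mevrd_data}} object
#' @export
write_histories <- function(data, path) {
  df <- data.frame(animal_id = data$id, count = data$count,
                   stringsAsFactors = FALSE)
  ev <- data$events
  colnames(ev) <- data$years
  utils::write.csv(cbind(df, as.data.frame(ev, check.names = FALSE)),
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write histories as MARK-style single-string records
#'
#' One line per unique history: the event codes concatenated into a single
#' string (pre-first-capture occasions as 0), followed by the multiplicity
#' and a terminating semicolon, for interoperability checks with
#' MARK/E-SURGE style input.
#'
#' @param data a \code{\link{mevrd_data}} object
#' @param path output file
#' @export
write_mark_inp <- function(data, path) {
  ev <- data$events
  ev[is.na(ev)] <- 0L
  lines <- paste0(apply(ev, 1L, paste, collapse = ""), " ", data$count, ";")
  writeLines(lines, path)
  invisible(path)
}
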