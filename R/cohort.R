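#' @importFrom stats aggregate ave
NULL

#' Canonical cohort column names
#'
#' Column order of the per-worker cohort table used throughout the package:
#' worker identifier, baseline predictors (age in years, gender `M`/`F`,
#' contracted work hours per week, self-rated health coded poor = 1 to
#' excellent = 4, prior sickness-absence days and episodes accumulated over
#' the two years before baseline, CIS fatigue sum score 20--140) and the
#' 1-year follow-up outcomes (sickness-absence days and episodes).
#'
#' @format Character vector of length 10.
#' @export
cohort_columns <- c(
  "worker_id", "age", "gender", "work_hours", "srh",
  "prior_sa_days", "prior_sa_episodes", "fatigue",
  "fu_sa_days", "fu_sa_episodes"
)

numeric_cohort_columns <- setdiff(cohort_columns, c("worker_id", "gender"))

## Per-field validity ranges; values outside become missing with a warning.
check_cohort_ranges <- function(cohort) {
  bad <- function(col, ok) {
    x <- cohort[[col]]
    idx <- which(!is.na(x) & !ok(x))
    if (length(idx)) {
      warning(sprintf("%d value(s) of '%s' outside the valid range set to missing",
                      length(idx), col), call. = FALSE)
      cohort[[col]][idx] <<- NA
    }
  }
  bad("age", function(x) x > 0 & x < 120)
  bad("work_hours", function(x) x >= 0 & x <= 100)
  bad("srh", function(x) x %in% 1:4)
  bad("prior_sa_days", function(x) x >= 0)
  bad("prior_sa_episodes", function(x) x >= 0)
  bad("fatigue", function(x) x >= 20 & x <= 140)
  bad("fu_sa_days", function(x) x >= 0 & x <= 366)
  bad("fu_sa_episodes", function(x) x >= 0)
  g <- cohort$gender
  idx <- which(!is.na(g) & !(g %in% c("M", "F")))
  if (length(idx)) {
    warning(sprintf("%d value(s) of 'gender' not 'M'/'F' set to missing", length(idx)),
            call. = FALSE)
    cohort$gender[idx] <- NA
  }
  cohort
}

#' Read a cohort table from CSV
#'
#' Reads a per-worker cohort table in the canonical dialect (header names as
#' in [cohort_columns], empty cell = missing, gender coded `M`/`F`).
#' Unparseable or out-of-range cells (e.g. a self-rated health of 5, a fatigue
#' score below 20) are set to missing with a warning; the row count is always
#' preserved.  Missing mandatory columns and duplicated worker identifiers are
#' errors.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` with the columns of [cohort_columns].
#' @seealso [write_cohort()], [complete_cases()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = "")
  missing_cols <- setdiff(cohort_columns, names(raw))
  if (length(missing_cols))
    stop("cohort CSV is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  cohort <- raw[cohort_columns]
  for (col in numeric_cohort_columns) {
    x <- suppressWarnings(as.numeric(cohort[[col]]))
    n_bad <- sum(is.na(x) & !is.na(cohort[[col]]))
    if (n_bad > 0)
      warning(sprintf("%d unparseable value(s) in column '%s' set to missing",
                      n_bad, col), call. = FALSE)
    cohort[[col]] <- x
  }
  if (anyDuplicated(cohort$worker_id))
    stop("duplicate worker_id in cohort: ",
         paste(unique(cohort$worker_id[duplicated(cohort$worker_id)]), collapse = ", "))
  check_cohort_ranges(cohort)
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: missing values become empty cells.
#'
#' @param cohort A cohort `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(all(cohort_columns %in% names(cohort)))
  utils::write.csv(cohort[cohort_columns], path, row.names = FALSE, na = "",
                   quote = FALSE)
  invisible(path)
}

#' Read a sickness-absence episode register from CSV
#'
#' Expects the header `worker_id,start,end` with ISO-8601 dates.  Each row is
#' one recorded absence episode, from the first sick day to return to work.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` with columns `worker_id`, `start`, `end` (`Date`).
#' @export
read_register <- function(path) {
  if (!file.exists(path)) stop("register file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character")
  need <- c("worker_id", "start", "end")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("register CSV is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  reg <- data.frame(worker_id = raw$worker_id,
                    start = as.Date(raw$start),
                    end = as.Date(raw$end),
                    stringsAsFactors = FALSE)
  validate_episodes(reg)
  reg
}

#' Write an episode register to CSV
#'
#' @param register A `data.frame` with columns `worker_id`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_register <- function(register, path) {
  stopifnot(all(c("worker_id", "start", "end") %in% names(register)))
  out <- data.frame(worker_id = register$worker_id,
                    start = as.character(register$start),
                    end = as.character(register$end))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_episodes <- function(episodes) {
  if (any(is.na(episodes$start)) || any(is.na(episodes$end)))
    stop("episode register contains unparseable dates")
  if (any(as.numeric(episodes$end) < as.numeric(episodes$start)))
    stop("episode with end before start")
  invisible(episodes)
}

#' Merge sickness-absence episodes separated by short gaps
#'
#' Register convention: two consecutive episodes of one worker with fewer than
#' `min_gap_days` days strictly between them (the earlier episode's end and
#' the later one's start both excluded) are regarded as a single episode.
#' Merging is transitive and a gap of exactly `min_gap_days` does *not* merge
#' (the rule is a strict `<`).
#'
#' @param episodes A `data.frame` with columns `start` and `end` (`Date` or
#'   numeric day indices) holding the non-overlapping episodes of one worker.
#' @param min_gap_days Minimum number of intervening days required to keep two
#'   episodes separate; default 28.
#' @return A `data.frame` of merged episodes, sorted by start, with the same
#'   `start`/`end` type as the input.
#' @examples
#' ep <- data.frame(start = c(1, 30), end = c(10, 35))
#' merge_episodes(ep)            # one merged episode (gap 19 < 28)
#' ep2 <- data.frame(start = c(1, 39), end = c(10, 40))
#' merge_episodes(ep2)           # two episodes (gap exactly 28)
#' @export
merge_episodes <- function(episodes, min_gap_days = 28) {
  stopifnot(min_gap_days >= 0)
  if (nrow(episodes) &&
      any(as.numeric(episodes$end) < as.numeric(episodes$start)))
    stop("episode with end before start")
  if (nrow(episodes) <= 1) return(episodes)
  grp <- merge_groups(episodes$start, episodes$end, min_gap_days)
  o <- attr(grp, "order")
  ep <- episodes[o, , drop = FALSE]
  g <- grp
  out <- ep[!duplicated(g), , drop = FALSE]
  out$end <- tapply_preserve(ep$end, g, max)
  rownames(out) <- NULL
  out
}

## Assign merge-group ids to episodes of one worker; errors on overlap.
## Returns group ids in start order, with the ordering permutation attached.
merge_groups <- function(start, end, min_gap_days) {
  o <- order(as.numeric(start))
  s <- as.numeric(start)[o]
  e <- as.numeric(end)[o]
  if (any(e < s)) stop("episode with end before start")
  n <- length(s)
  if (n > 1) {
    gap <- s[-1] - e[-n] - 1          # days strictly between the two episodes
    if (any(gap < 0)) stop("overlapping episodes within one worker")
    grp <- cumsum(c(1, as.integer(gap >= min_gap_days)))
  } else grp <- rep(1L, n)
  structure(grp, order = o)
}

## tapply keeping the class (Date arithmetic drops to numeric otherwise)
tapply_preserve <- function(x, g, f) {
  v <- unname(tapply(as.numeric(x), g, f))
  if (inherits(x, "Date")) as.Date(v, origin = "1970-01-01") else v
}

#' Aggregate an episode register into per-worker day and episode counts
#'
#' Per worker, episodes are clipped to the observation window, merged with
#' [merge_episodes()] semantics, and counted.  Day counts are inclusive of
#' both endpoints and sum only the recorded (clipped) constituent episodes:
#' the worked days inside a merged gap are not counted as absence days.
#' Episode counts are the number of *merged* episodes.
#'
#' @param register A `data.frame` with columns `worker_id`, `start`, `end`.
#' @param min_gap_days Merge gap, see [merge_episodes()].
#' @param window Optional length-2 vector (start, end) clipping episodes to an
#'   observation window; episodes entirely outside are dropped.
#' @return A `data.frame` with columns `worker_id`, `sa_days`, `sa_episodes`,
#'   one row per worker present in the (clipped) register.
#' @examples
#' reg <- data.frame(worker_id = "w1", start = c(1, 30), end = c(10, 35))
#' aggregate_register(reg)   # 16 days, 1 episode
#' @export
aggregate_register <- function(register, min_gap_days = 28, window = NULL) {
  stopifnot(all(c("worker_id", "start", "end") %in% names(register)))
  validate_episodes(register)
  reg <- register
  if (!is.null(window)) {
    lo <- as.numeric(window[1]); hi <- as.numeric(window[2])
    keep <- as.numeric(reg$end) >= lo & as.numeric(reg$start) <= hi
    reg <- reg[keep, , drop = FALSE]
    reg$start <- pmax_class(reg$start, window[1])
    reg$end <- pmin_class(reg$end, window[2])
  }
  if (nrow(reg) == 0)
    return(data.frame(worker_id = character(0), sa_days = numeric(0),
                      sa_episodes = numeric(0)))
  by_worker <- split(reg, reg$worker_id)
  out <- lapply(by_worker, function(ep) {
    grp <- merge_groups(ep$start, ep$end, min_gap_days)
    days <- sum(as.numeric(ep$end) - as.numeric(ep$start) + 1)
    data.frame(worker_id = ep$worker_id[1], sa_days = days,
               sa_episodes = max(grp))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

pmax_class <- function(x, v) {
  r <- pmax(as.numeric(x), as.numeric(v))
  if (inherits(x, "Date")) as.Date(r, origin = "1970-01-01") else r
}
pmin_class <- function(x, v) {
  r <- pmin(as.numeric(x), as.numeric(v))
  if (inherits(x, "Date")) as.Date(r, origin = "1970-01-01") else r
}

#' Binary outcome labels for high sickness absence
#'
#' `label_high_sa_days()` is `TRUE` when a worker accumulated at least 30
#' (not necessarily consecutive) sickness-absence days during 1-year
#' follow-up; `label_high_sa_episodes()` when the worker had at least 3
#' merged episodes.  Both are vectorised and preserve `NA`.
#'
#' @param sa_days,sa_episodes Nonnegative counts.
#' @return Logical vector.
#' @export
label_high_sa_days <- function(sa_days) {
  stopifnot(all(sa_days >= 0, na.rm = TRUE))
  sa_days >= 30
}

#' @rdname label_high_sa_days
#' @export
label_high_sa_episodes <- function(sa_episodes) {
  stopifnot(all(sa_episodes >= 0, na.rm = TRUE))
  sa_episodes >= 3
}

#' Add outcome label columns to a cohort
#'
#' Derives the binary columns `high_sa_days` and `high_sa_episodes` from the
#' follow-up counts.
#'
#' @param cohort A cohort `data.frame`.
#' @return The cohort with the two logical columns appended.
#' @export
add_outcome_labels <- function(cohort) {
  cohort$high_sa_days <- label_high_sa_days(cohort$fu_sa_days)
  cohort$high_sa_episodes <- label_high_sa_episodes(cohort$fu_sa_episodes)
  cohort
}

#' Complete-case filter
#'
#' Drops records with a missing value in any of the listed fields (the
#' analysis is complete-case; no imputation).  The number of removed records
#' is reported as a message; an empty result raises a warning.
#'
#' @param cohort A cohort `data.frame`.
#' @param fields Character vector of column names to require; defaults to all
#'   columns.
#' @return The filtered cohort.
#' @export
complete_cases <- function(cohort, fields = names(cohort)) {
  missing_fields <- setdiff(fields, names(cohort))
  if (length(missing_fields))
    stop("unknown field(s): ", paste(missing_fields, collapse = ", "))
  keep <- stats::complete.cases(cohort[fields])
  removed <- sum(!keep)
  if (removed > 0)
    message(sprintf("complete_cases: removed %d of %d records (%.0f%%)",
                    removed, nrow(cohort), 100 * removed / nrow(cohort)))
  out <- cohort[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no complete cases remain", call. = FALSE)
  rownames(out) <- NULL
  out
}
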