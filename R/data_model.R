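#' Build a validated trial table
#'
#' Normalizes a long-format data frame of trial-level reaction times into
#' the canonical trial table used throughout the package: one row per
#' trial with a participant identifier, an optional stimulus identifier,
#' up to two binary condition factors (for example stimulus category and
#' response direction in an approach-avoidance task), a reaction time in
#' milliseconds, and a presentation index giving the order of the trial
#' within the participant's session.
#'
#' @param data a data.frame in long format, one row per trial.
#' @param participant name of the column identifying the participant.
#' @param rt name of the column holding the reaction time (ms). Must be
#'   finite and strictly positive for every trial.
#' @param stimulus optional name of the column identifying the stimulus;
#'   required for stimulus-stratified splitting.
#' @param factor1,factor2 optional names of binary condition-factor
#'   columns (each must have exactly one or two observed levels).
#' @param presentation optional name of an integer column giving the
#'   order of each trial within its participant's session. When absent,
#'   indices are assigned by row order within participant.
#' @return A data.frame of class `trial_table` with canonical columns
#'   `participant`, `stimulus`, `factor1`, `factor2`, `rt`,
#'   `presentation` (absent optional columns are filled with `NA` /
#'   constants). The mapping of original column names is kept in
#'   `attr(x, "column_map")`.
#' @examples
#' d <- data.frame(subj = rep(1:2, each = 4),
#'                 stim = rep(c("a", "b"), 4),
#'                 dir  = rep(c("avoid", "approach"), each = 2, times = 2),
#'                 RT   = 400 + 1:8)
#' tt <- trial_table(d, participant = "subj", rt = "RT",
#'                   stimulus = "stim", factor1 = "dir")
#' @export
trial_table <- function(data, participant, rt, stimulus = NULL,
                        factor1 = NULL, factor2 = NULL,
                        presentation = NULL) {
  stopifnot(is.data.frame(data))
  cols <- c(participant = participant, rt = rt, stimulus = stimulus,
            factor1 = factor1, factor2 = factor2,
            presentation = presentation)
  missing_cols <- setdiff(unname(cols), names(data))
  if (length(missing_cols) > 0L) {
    stop("column(s) not found in data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  rt_raw <- data[[rt]]
  if (!is.numeric(rt_raw)) {
    suppressWarnings(rt_num <- as.numeric(as.character(rt_raw)))
    bad <- which(is.na(rt_num) & !is.na(rt_raw))
    if (length(bad) > 0L) {
      stop("non-numeric RT value(s) at row(s): ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    rt_raw <- rt_num
  }
  bad_rt <- which(!is.finite(rt_raw) | rt_raw <= 0)
  if (length(bad_rt) > 0L) {
    stop("RT must be finite and > 0; offending row(s): ",
         paste(utils::head(bad_rt, 5L), collapse = ", "), call. = FALSE)
  }

  out <- data.frame(
    participant = as.character(data[[participant]]),
    stimulus = if (is.null(stimulus)) NA_character_ else
      as.character(data[[stimulus]]),
    factor1 = if (is.null(factor1)) NA_character_ else
      as.character(data[[factor1]]),
    factor2 = if (is.null(factor2)) NA_character_ else
      as.character(data[[factor2]]),
    rt = rt_raw,
    stringsAsFactors = FALSE
  )

  for (fc in c("factor1", "factor2")) {
    lv <- unique(out[[fc]])
    if (!all(is.na(lv)) && length(lv) > 2L) {
      stop(fc, " must be binary; found levels: ",
           paste(lv, collapse = ", "), call. = FALSE)
    }
  }

  if (is.null(presentation)) {
    out$presentation <- stats::ave(seq_len(nrow(out)), out$participant,
                                   FUN = seq_along)
  } else {
    out$presentation <- as.integer(data[[presentation]])
    dup <- stats::ave(out$presentation, out$participant,
                      FUN = function(x) duplicated(x))
    if (any(dup > 0)) {
      stop("presentation index must be unique within participant",
           call. = FALSE)
    }
  }

  attr(out, "column_map") <- cols
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Read a long-format trial file
#'
#' Reads a CSV or TSV file with a header row and validates it into a
#' [trial_table()]. The separator is taken from the file extension
#' (`.tsv`/`.txt` means tab) unless given explicitly.
#'
#' @param path path to the file.
#' @param participant,rt,stimulus,factor1,factor2,presentation column
#'   names in the file, as in [trial_table()].
#' @param sep field separator; `NULL` (default) chooses by extension.
#' @return a `trial_table`.
#' @export
read_trials <- function(path, participant, rt, stimulus = NULL,
                        factor1 = NULL, factor2 = NULL,
                        presentation = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = NA)
  trial_table(raw, participant = participant, rt = rt,
              stimulus = stimulus, factor1 = factor1, factor2 = factor2,
              presentation = presentation)
}

#' Write a trial table to a long-format file
#'
#' Writes the canonical columns to CSV (or TSV by extension), so that
#' `read_trials()` round-trips losslessly.
#'
#' @param table a `trial_table`.
#' @param path output path.
#' @export
write_trials <- function(table, path) {
  stopifnot(inherits(table, "trial_table"))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(as.data.frame(table), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Exclude trials by a user predicate
#'
#' Removes trials for which `keep` evaluates to `FALSE`. The predicate is
#' a pure, vectorized function of the trial fields (it receives the
#' trial table and must return one logical per row); typical use is
#' removing extreme RTs. A per-participant removal count is attached, and
#' a warning names any participant left without trials in a condition
#' cell they previously had.
#'
#' @param table a `trial_table`.
#' @param keep function of the trial table returning a logical vector,
#'   `TRUE` for trials to retain.
#' @return the filtered `trial_table`; removed counts per participant in
#'   `attr(x, "removed")`.
#' @examples
#' d <- data.frame(s = 1, rt = c(300, 500, 12000))
#' tt <- trial_table(d, participant = "s", rt = "rt")
#' exclude_trials(tt, function(tr) tr$rt < 10000)
#' @export
exclude_trials <- function(table, keep) {
  stopifnot(inherits(table, "trial_table"), is.function(keep))
  mask <- keep(table)
  if (!is.logical(mask) || length(mask) != nrow(table)) {
    stop("keep must return one logical per trial", call. = FALSE)
  }
  mask[is.na(mask)] <- FALSE
  cell_id <- interaction(table$participant, table$factor1, table$factor2,
                         drop = TRUE)
  before <- table(cell_id)
  out <- table[mask, , drop = FALSE]
  after <- table(factor(cell_id[mask], levels = names(before)))
  emptied <- names(before)[after == 0L & before > 0L]
  if (length(emptied) > 0L) {
    who <- unique(vapply(strsplit(emptied, ".", fixed = TRUE), `[[`, "", 1L))
    warning("exclusion emptied required cell(s) for participant(s): ",
            paste(who, collapse = ", "), call. = FALSE)
  }
  removed <- tapply(!mask, table$participant, sum)
  attr(out, "removed") <- removed
  attr(out, "column_map") <- attr(table, "column_map")
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Check that every participant fills the cells a score requires
#'
#' @param table a `trial_table`.
#' @param spec a [score_spec()].
#' @return data.frame with one row per participant x required cell that
#'   is empty (zero rows when the design is complete).
#' @export
validate_cells <- function(table, spec) {
  cells <- required_cells(table, spec)
  parts <- unique(table$participant)
  have <- unique(data.frame(participant = table$participant,
                            cell = cell_index(table, spec)))
  full <- expand.grid(participant = parts, cell = seq_len(cells),
                      stringsAsFactors = FALSE)
  merged <- merge(full, cbind(have, present = TRUE), all.x = TRUE)
  merged[is.na(merged$present), c("participant", "cell"), drop = FALSE]
}
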