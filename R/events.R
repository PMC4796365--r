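# Four-phase passage-event classification and cohort passage statistics.
#
# Event times (frame-resolution, min): cell entry = first frame the cell
# front reaches the constriction entrance; nuclear entry / exit and cell
# exit analogously with the nuclear front, nuclear back and cell back.
# Outcome: "passed" when the cell back clears the exit; "reversed_*"
# when, after entering, the cell front retreats at least eps behind the
# entrance without exiting; "censored" when the movie ends while the
# cell is still engaged. Only the first engagement per movie is scored.

#' Classify the passage event of one track
#'
#' @param track a [build_track()] result.
#' @param geometry a [channel_geometry()].
#' @param eps_reversal_um reversal margin: front retreat (um) behind the
#'   entrance that scores a reversal.
#' @param delta_nuclear_um nuclear-entry threshold: the nuclear front
#'   must exceed the entrance by at least this much (um) to flag entry.
#' @return one-row data.frame (class `passage_event`): the four event
#'   times, outcome, cell/nuclear passage times, non-passage time and
#'   the nuclear-entry flag. Errors with class `NotEncountered` when the
#'   cell front never reaches the entrance.
#' @export
classify_passage <- function(track, geometry, eps_reversal_um = 2,
                             delta_nuclear_um = 0.5) {
  pl <- constriction_planes(geometry)
  dirn <- geometry$migration_direction
  s <- function(x) dirn * x             # signed axial coordinate
  cf <- s(track$cell_front_x_um); cb <- s(track$cell_back_x_um)
  nf <- s(track$nuc_front_x_um); nb <- s(track$nuc_back_x_um)
  sE <- s(pl$entrance); sX <- s(pl$exit)
  t <- track$t_min
  first_at <- function(cond) { i <- which(!is.na(cond) & cond); if (length(i)) i[1] else NA_integer_ }

  i_ce <- first_at(cf >= sE)
  if (is.na(i_ce)) cc_stop("NotEncountered", "cell front never reached the entrance")
  i_ne <- first_at(nf >= sE)
  i_nx <- first_at(nb >= sX)
  i_cx <- first_at(cb >= sX)
  nuclear_entry <- any(nf >= sE + delta_nuclear_um, na.rm = TRUE)

  # reversal: after entry, front retreats >= eps behind the entrance
  after <- seq_along(cf) >= i_ce
  i_rev_done <- first_at(after & cf <= sE - eps_reversal_um)
  outcome <- if (!is.na(i_cx)) "passed"
    else if (!is.na(i_rev_done)) {
      if (nuclear_entry) "reversed_after_nuclear_entry" else "reversed_no_nuclear_entry"
    } else "censored"

  t_rev <- NA_real_
  if (startsWith(outcome, "reversed")) {
    # moment of direction change: last frame (before the retreat is
    # complete) at which the front still sits at its running maximum
    upto <- seq_len(i_rev_done)
    fmax <- max(cf[upto], na.rm = TRUE)
    i_turn <- max(which(!is.na(cf[upto]) & cf[upto] >= fmax - 0.5))
    t_rev <- t[i_turn]
  }
  at <- function(i) if (is.na(i)) NA_real_ else t[i]
  out <- data.frame(
    t_cell_entry = at(i_ce), t_nuc_entry = at(i_ne),
    t_nuc_exit = at(i_nx), t_cell_exit = at(i_cx),
    outcome = outcome,
    cell_passage_time_min = if (outcome == "passed") at(i_cx) - at(i_ce) else NA_real_,
    nuc_passage_time_min = if (outcome == "passed" && !is.na(i_ne) && !is.na(i_nx))
      at(i_nx) - at(i_ne) else NA_real_,
    non_passage_time_min = if (startsWith(outcome, "reversed")) t_rev - at(i_ce) else NA_real_,
    nuclear_entry_flag = nuclear_entry,
    stringsAsFactors = FALSE)
  class(out) <- c("passage_event", "data.frame")
  out
}

#' Cohort passage statistics
#'
#' Percentage of passage (passed / encountered, censored excluded from
#' both numerator and denominator), mean +/- s.e.m. of cell and nuclear
#' passage times and of the non-passage time, and the fraction of
#' non-passers that initiated nuclear entry.
#'
#' @param events data.frame of stacked [classify_passage()] rows.
#' @return list of summary statistics.
#' @export
cohort_passage_stats <- function(events) {
  if (!nrow(events)) cc_stop("EmptyCohort", "no events supplied")
  obs <- events[events$outcome != "censored", , drop = FALSE]
  if (!nrow(obs)) cc_stop("EmptyCohort", "all events censored")
  passed <- obs$outcome == "passed"
  nonp <- startsWith(obs$outcome, "reversed")
  list(
    n_encountered = nrow(obs),
    n_censored = sum(events$outcome == "censored"),
    percentage_passage = 100 * mean(passed),
    cell_passage_time = summarize_or_na(as.numeric(stats::na.omit(obs$cell_passage_time_min))),
    nuc_passage_time = summarize_or_na(as.numeric(stats::na.omit(obs$nuc_passage_time_min))),
    non_passage_time = summarize_or_na(as.numeric(stats::na.omit(obs$non_passage_time_min))),
    frac_nonpassers_nuclear_entry =
      if (any(nonp)) mean(obs$nuclear_entry_flag[nonp]) else NA_real_)
}
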