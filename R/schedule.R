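TAP_CONDITIONS <- c("tap1Hz", "tap4Hz")
IMAGERY_MAIN <- c("ITAP", "noITAP")
IMAGERY_PRACTICE <- c("practiceITAP", "practiceNoITAP")
ALL_CONDITIONS <- c(TAP_CONDITIONS, "rest", IMAGERY_PRACTICE, IMAGERY_MAIN)

#' Construct and validate a block schedule
#'
#' A block schedule lists contiguous, non-overlapping blocks that fill the
#' front of a run. Tapping runs alternate six tapping blocks (1 Hz or 4 Hz)
#' with six rest blocks; imagery runs start with exactly two practice blocks
#' followed by six alternating ITAP/noITAP blocks. Every non-practice block
#' lasts 28-32 s. Scan time after the last block (used to fill the nominal
#' run length) is unlabelled and excluded from training and scoring.
#'
#' @param blocks data.frame with columns `block_id`, `condition`, `onset_s`,
#'   `duration_s`.
#' @param run_kind `"tapping"` or `"imagery"`.
#' @param tr_s repetition time in seconds.
#' @param total_duration_s total run duration; defaults to the end of the
#'   last block. Must be a whole number of TRs.
#' @return object of class `block_schedule`.
#' @export
block_schedule <- function(blocks, run_kind = c("tapping", "imagery"),
                           tr_s = 2, total_duration_s = NULL) {
  run_kind <- match.arg(run_kind)
  stopifnot(is.data.frame(blocks),
            all(c("block_id", "condition", "onset_s", "duration_s") %in% names(blocks)))
  blocks <- blocks[order(blocks$onset_s), , drop = FALSE]
  total_duration_s <- total_duration_s %||%
    (blocks$onset_s[nrow(blocks)] + blocks$duration_s[nrow(blocks)])
  sched <- structure(
    list(blocks = blocks, run_kind = run_kind, tr_s = tr_s,
         total_duration_s = total_duration_s),
    class = "block_schedule")
  validate_schedule(sched)
  sched
}

#' @rdname block_schedule
#' @param schedule a `block_schedule`.
#' @export
validate_schedule <- function(schedule) {
  b <- schedule$blocks
  if (!all(b$condition %in% ALL_CONDITIONS))
    stop("unknown block condition(s): ",
         paste(setdiff(b$condition, ALL_CONDITIONS), collapse = ", "))
  if (b$onset_s[1] != 0) stop("first block must start at 0 s")
  if (nrow(b) > 1) {
    gaps <- b$onset_s[-1] - (b$onset_s[-nrow(b)] + b$duration_s[-nrow(b)])
    if (any(abs(gaps) > 1e-9)) stop("blocks must be contiguous and non-overlapping")
  }
  main <- b$condition %in% c(TAP_CONDITIONS, "rest", IMAGERY_MAIN)
  if (any(b$duration_s[main] < 28 - 1e-9 | b$duration_s[main] > 32 + 1e-9))
    stop("non-practice block durations must lie in [28, 32] s")
  if (schedule$run_kind == "tapping") {
    if (sum(b$condition %in% TAP_CONDITIONS) != 6L || sum(b$condition == "rest") != 6L)
      stop("tapping runs need 6 tapping and 6 rest blocks")
    kind <- ifelse(b$condition %in% TAP_CONDITIONS, "tap", "rest")
    if (any(kind[-1] == kind[-length(kind)]))
      stop("tapping and rest blocks must alternate")
  } else {
    if (!identical(b$condition[1:2], c("practiceITAP", "practiceNoITAP")))
      stop("imagery runs must begin with two practice blocks (ITAP then noITAP)")
    mainb <- b$condition[-(1:2)]
    if (length(mainb) != 6L || !all(mainb == rep(IMAGERY_MAIN, 3)))
      stop("imagery runs need 6 alternating ITAP/noITAP blocks after practice")
  }
  end <- b$onset_s[nrow(b)] + b$duration_s[nrow(b)]
  if (schedule$total_duration_s < end - 1e-9)
    stop("total_duration_s shorter than the block sequence")
  if (abs(schedule$total_duration_s / schedule$tr_s -
          round(schedule$total_duration_s / schedule$tr_s)) > 1e-9)
    stop("total_duration_s must be a whole number of TRs")
  invisible(schedule)
}

#' Number of volumes implied by a schedule
#' @param schedule a `block_schedule`.
#' @export
n_volumes <- function(schedule) as.integer(round(schedule$total_duration_s / schedule$tr_s))

# Draw a block duration from {28, 30, 32} s (whole TRs at TR = 2 s).
draw_block_duration <- function(tr_s) {
  d <- sample(c(28, 30, 32), 1L)
  round(d / tr_s) * tr_s
}

#' Generate the schedule of one tapping run
#'
#' Six tapping blocks alternating with six rest blocks, starting at rest (so
#' the run opens at baseline); tapping speeds alternate 1 Hz / 4 Hz so each
#' run holds three blocks of each speed. Durations are drawn uniformly from
#' \{28, 30, 32\} s, rounded to whole TRs. The same order is used for every
#' subject.
#'
#' @param tr_s repetition time (s).
#' @param total_duration_s run duration (s); default 420 (210 volumes at 2 s).
#' @param seed integer seed; the schedule is deterministic given the seed.
#' @return a [block_schedule()].
#' @export
make_tapping_schedule <- function(tr_s = 2, total_duration_s = 420, seed = NULL) {
  with_seed(seed, {
    conds <- character(0)
    speeds <- rep(c("tap1Hz", "tap4Hz"), 3)
    for (i in 1:6) conds <- c(conds, "rest", speeds[i])
    durs <- vapply(conds, function(cc) draw_block_duration(tr_s), numeric(1))
    onsets <- cumsum(c(0, durs[-length(durs)]))
    block_schedule(
      data.frame(block_id = seq_along(conds), condition = conds,
                 onset_s = onsets, duration_s = durs),
      run_kind = "tapping", tr_s = tr_s, total_duration_s = total_duration_s)
  })
}

#' Generate the schedule of one imagery (neurofeedback) run
#'
#' Two practice blocks (ITAP then noITAP, displaying ideal performance and
#' kick-starting the online analysis) followed by six alternating ITAP/noITAP
#' blocks.
#'
#' @inheritParams make_tapping_schedule
#' @return a [block_schedule()].
#' @export
make_imagery_schedule <- function(tr_s = 2, total_duration_s = 420, seed = NULL) {
  with_seed(seed, {
    conds <- c("practiceITAP", "practiceNoITAP", rep(c("ITAP", "noITAP"), 3))
    durs <- vapply(conds, function(cc) draw_block_duration(tr_s), numeric(1))
    onsets <- cumsum(c(0, durs[-length(durs)]))
    block_schedule(
      data.frame(block_id = seq_along(conds), condition = conds,
                 onset_s = onsets, duration_s = durs),
      run_kind = "imagery", tr_s = tr_s, total_duration_s = total_duration_s)
  })
}

#' Per-TR condition labels of a run
#'
#' TR `t` (1-based) covers `[(t-1)*tr, t*tr)` and is assigned the condition of
#' the block containing its onset; TRs after the last block are `NA`
#' (unlabelled scan time).
#'
#' @param schedule a `block_schedule`.
#' @return character vector of length [n_volumes()].
#' @export
tr_conditions <- function(schedule) {
  nt <- n_volumes(schedule)
  t0 <- (seq_len(nt) - 1) * schedule$tr_s
  cond <- rep(NA_character_, nt)
  for (i in seq_len(nrow(schedule$blocks))) {
    b <- schedule$blocks[i, ]
    sel <- t0 >= b$onset_s - 1e-9 & t0 < b$onset_s + b$duration_s - 1e-9
    cond[sel] <- b$condition
  }
  cond
}
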