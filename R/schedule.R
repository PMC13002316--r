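#' Build a trial schedule for an error-clamp reaching experiment
#'
#' Constructs the per-trial design of a center-out reaching experiment with
#' feedback phases in the canonical order veridical, clamped, no-feedback,
#' veridical (washout). Targets appear at the four cardinal directions
#' (0, 90, 180, 270 degrees); each consecutive block of four trials (a
#' *cycle*) contains every direction exactly once, in a fresh uniform
#' permutation per cycle. Set-break flags mark the first trial after each
#' feedback-phase transition, where the experiment pauses while the upcoming
#' feedback change is announced.
#'
#' The default phase lengths (10, 40, 1, 20 cycles) give the standard design
#' of 40 veridical trials, 160 clamped trials, 4 no-feedback trials and 80
#' washout trials: 71 cycles, 284 trials, with the clamp on cycles 11-50 and
#' the no-feedback aftereffect probe on cycle 51.
#'
#' @param phases named integer vector (or list of `(phase, n_cycles)` pairs)
#'   of cycle counts per phase, names among `"veridical"`, `"clamp"`,
#'   `"none"`. Phases may repeat (e.g. washout is a second `"veridical"`).
#' @param clamp_sign -1 (counterclockwise clamp, the default adapted-against
#'   direction) or +1 (clockwise).
#' @param seed integer seed controlling the within-cycle target permutations.
#' @return an object of class `clamp_schedule`: a data.frame with columns
#'   `trial`, `cycle`, `target_deg`, `feedback`, `clamp_sign`, `post_break`,
#'   plus attributes `cycle_size`, `n_cycles`, `phase_of_cycle`.
#' @examples
#' sch <- make_schedule(seed = 1)
#' nrow(sch)            # 284
#' attr(sch, "n_cycles") # 71
#' @export
make_schedule <- function(phases = c(veridical = 10, clamp = 40, none = 1,
                                     veridical = 20),
                          clamp_sign = -1L, seed = 1L) {
  if (is.list(phases)) {
    nm <- vapply(phases, function(p) as.character(p[[1]]), "")
    phases <- stats::setNames(vapply(phases, function(p) as.integer(p[[2]]), 0L), nm)
  }
  known <- c("veridical", "clamp", "none")
  if (!all(names(phases) %in% known)) {
    stop("unknown phase name(s): ",
         paste(setdiff(names(phases), known), collapse = ", "))
  }
  stopifnot(all(phases >= 0), clamp_sign %in% c(-1L, 1L))
  phases <- phases[phases > 0]
  if (length(phases) == 0) stop("schedule must contain at least one cycle")

  cycle_size <- 4L
  directions <- c(0, 90, 180, 270)
  phase_of_cycle <- rep(names(phases), times = phases)
  n_cycles <- length(phase_of_cycle)

  # set break at the first cycle of every phase after the first
  phase_id <- rep(seq_along(phases), times = phases)
  break_cycle <- c(FALSE, diff(phase_id) != 0)

  target <- with_seed(seed, {
    unlist(lapply(seq_len(n_cycles), function(i) sample(directions)))
  })

  cycle <- rep(seq_len(n_cycles), each = cycle_size)
  feedback <- rep(phase_of_cycle, each = cycle_size)
  trial <- seq_len(n_cycles * cycle_size)
  post_break <- rep(FALSE, length(trial))
  post_break[match(which(break_cycle), cycle)] <- TRUE

  out <- data.frame(
    trial = trial,
    cycle = cycle,
    target_deg = target,
    feedback = feedback,
    clamp_sign = ifelse(feedback == "clamp", as.integer(clamp_sign), NA_integer_),
    post_break = post_break,
    stringsAsFactors = FALSE
  )
  attr(out, "cycle_size") <- cycle_size
  attr(out, "n_cycles") <- n_cycles
  attr(out, "phase_of_cycle") <- phase_of_cycle
  class(out) <- c("clamp_schedule", "data.frame")
  out
}

#' Collapse a trial schedule to one row per cycle
#'
#' The model is routinely fitted at the cycle level (one state-update step
#' per cycle of four trials). This returns the cycle-level view: feedback
#' type, clamp sign and set-break flag per cycle.
#'
#' @param schedule a `clamp_schedule`.
#' @return data.frame with columns `cycle`, `feedback`, `clamp_sign`,
#'   `post_break` (one row per cycle), attribute `level = "cycle"`.
#' @export
schedule_cycles <- function(schedule) {
  stopifnot(inherits(schedule, "clamp_schedule"))
  first <- !duplicated(schedule$cycle)
  out <- data.frame(
    cycle = schedule$cycle[first],
    feedback = schedule$feedback[first],
    clamp_sign = schedule$clamp_sign[first],
    post_break = schedule$post_break[first],
    stringsAsFactors = FALSE
  )
  attr(out, "level") <- "cycle"
  out
}

#' Map cycles to analysis epochs
#'
#' Standard epoch windows: baseline (cycles 6-10), clamp onset (11-12),
#' early learning (13-17), late learning (46-50), aftereffect (51);
#' everything else is `"other"`.
#'
#' @param cycles integer vector of cycle indices.
#' @param windows named list of cycle ranges overriding the defaults.
#' @return character vector of epoch labels.
#' @export
cycle_epochs <- function(cycles,
                         windows = list(baseline = 6:10, onset = 11:12,
                                        early = 13:17, late = 46:50,
                                        aftereffect = 51)) {
  lab <- rep("other", length(cycles))
  for (w in names(windows)) lab[cycles %in% windows[[w]]] <- w
  lab
}
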