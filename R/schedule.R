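#' Schedule configuration for the three-run startle paradigm
#'
#' Defines per-run trial composition and timing for the acoustic startle
#' session: Run 1 carries four extra acclimatisation pulse trials at its head
#' (44 trials total), Runs 2 and 3 have 40 trials each (8 pulse, 8 prepulse,
#' 8 of each prepulse-inhibition SOA). Inter-stimulus intervals (onset to
#' onset) are drawn uniformly on \[isi_min, isi_max\] seconds, giving the
#' design's 15 s mean at the 9--21 s default range.
#'
#' @param counts_run1 named integer vector of trial counts for Run 1.
#' @param counts_run23 named integer vector of trial counts for Runs 2 and 3.
#' @param n_acclim number of leading acclimatisation pulse trials in Run 1;
#'   they are exempt from the no-repeat ordering constraint and are counted
#'   within `counts_run1["pulse"]`.
#' @param isi_min,isi_max inter-stimulus interval range, seconds.
#' @param lead_in onset of the first trial after run start, seconds.
#' @param inter_run_gap gap between runs, seconds.
#' @param max_retries retry budget for the pseudo-random ordering search.
#' @return an object of class `schedule_config`.
#' @export
schedule_config <- function(counts_run1 = c(pulse = 12L, prepulse = 8L,
                                            ppi_30 = 8L, ppi_60 = 8L, ppi_120 = 8L),
                            counts_run23 = c(pulse = 8L, prepulse = 8L,
                                             ppi_30 = 8L, ppi_60 = 8L, ppi_120 = 8L),
                            n_acclim = 4L,
                            isi_min = 9, isi_max = 21,
                            lead_in = 10, inter_run_gap = 180,
                            max_retries = 10000L) {
  stopifnot(all(counts_run1 >= 0), all(counts_run23 >= 0),
            isi_min > 0, isi_max >= isi_min, lead_in >= 0,
            n_acclim >= 0, n_acclim <= counts_run1["pulse"] %||% 0)
  bad <- setdiff(c(names(counts_run1), names(counts_run23)), trial_type_levels())
  if (length(bad))
    stop("unknown trial type(s) in config: ", paste(bad, collapse = ", "))
  structure(list(counts_run1 = counts_run1, counts_run23 = counts_run23,
                 n_acclim = as.integer(n_acclim),
                 isi_min = isi_min, isi_max = isi_max,
                 lead_in = lead_in, inter_run_gap = inter_run_gap,
                 max_retries = as.integer(max_retries)),
            class = "schedule_config")
}

trial_type_levels <- function() c("pulse", "prepulse", "ppi_30", "ppi_60", "ppi_120")

soa_of <- function(trial_type) {
  soa <- c(pulse = NA_real_, prepulse = NA_real_,
           ppi_30 = 30, ppi_60 = 60, ppi_120 = 120)
  unname(soa[trial_type])
}

# startle-eliciting trial types (advance the habituation ordinal)
is_eliciting <- function(trial_type) trial_type %in% c("pulse", "ppi_30", "ppi_60", "ppi_120")

run_counts <- function(config, run) {
  if (run == 1L) config$counts_run1 else config$counts_run23
}

#' Build one pseudo-randomly ordered run of the startle paradigm
#'
#' Orders the run's trials by rejection sampling over random permutations so
#' that no trial type occurs twice in a row; Run 1's leading acclimatisation
#' pulses are fixed at the head and exempt from the constraint (the transition
#' from the last acclimatisation pulse into the randomised block still may not
#' repeat). ISIs are i.i.d. uniform on the configured range. Deterministic
#' given `(run, seed, config)`.
#'
#' @param run run number (1, 2, or 3).
#' @param seed master seed; a per-run sub-seed is derived internally.
#' @param config a [schedule_config()].
#' @return a `run_schedule`: a data.frame with columns `run`, `index_in_run`,
#'   `trial_type`, `soa_ms`, `onset` (s from run start), `isi_after` (s, onset
#'   to next onset).
#' @export
build_run_schedule <- function(run, seed = 1L, config = schedule_config()) {
  stopifnot(run %in% 1:3)
  counts <- run_counts(config, run)
  n_acc <- if (run == 1L) config$n_acclim else 0L
  head_types <- rep("pulse", n_acc)
  rest <- counts
  if (n_acc > 0) rest["pulse"] <- rest["pulse"] - n_acc
  pool <- rep(names(rest), times = rest)
  types <- with_seed(derive_seed(seed, run), {
    ord <- order_no_repeat(pool, config$max_retries,
                           forbid_first = if (n_acc > 0) "pulse" else NULL)
    c(head_types, ord)
  })
  n <- length(types)
  isi <- with_seed(derive_seed(seed, 100L + run),
                   stats::runif(n, config$isi_min, config$isi_max))
  onset <- config$lead_in + cumsum(c(0, isi[-n]))
  out <- data.frame(run = as.integer(run), index_in_run = seq_len(n),
                    trial_type = types, soa_ms = soa_of(types),
                    onset = onset, isi_after = isi)
  attr(out, "seed") <- seed
  attr(out, "config") <- config
  class(out) <- c("run_schedule", "data.frame")
  out
}

# Order `pool` so no two adjacent elements are equal (and the first element
# differs from `forbid_first`, used at the acclimatisation boundary). Random
# sequential construction: each position is drawn among the still-available
# types that differ from the previous one, weighted by remaining counts;
# dead-ends restart, bounded by `max_retries`.
order_no_repeat <- function(pool, max_retries, forbid_first = NULL) {
  n <- length(pool)
  if (n == 0L) return(pool)
  if (n == 1L) {
    if (!is.null(forbid_first) && pool == forbid_first)
      stop("no valid ordering exists: single trial repeats the preceding type")
    return(pool)
  }
  counts0 <- table(pool)
  types <- names(counts0)
  for (retry in seq_len(max_retries)) {
    counts <- as.integer(counts0)
    out <- character(n)
    prev <- forbid_first %||% ""
    ok <- TRUE
    for (i in seq_len(n)) {
      avail <- which(counts > 0L & types != prev)
      if (!length(avail)) { ok <- FALSE; break }
      pick <- if (length(avail) == 1L) avail
              else avail[sample.int(length(avail), 1L, prob = counts[avail])]
      out[i] <- prev <- types[pick]
      counts[pick] <- counts[pick] - 1L
    }
    if (ok) return(out)
  }
  stop("no ordering without repeated trial types found within ", max_retries,
       " retries; the requested composition is likely unsatisfiable")
}

#' Build the full three-run session schedule
#'
#' @param seed master seed; each run draws from a distinct derived sub-seed.
#' @param config a [schedule_config()].
#' @return a `session_schedule`: list with `runs` (list of three
#'   [build_run_schedule()] results), `config`, `seed`.
#' @export
build_session <- function(seed = 1L, config = schedule_config()) {
  runs <- lapply(1:3, build_run_schedule, seed = seed, config = config)
  structure(list(runs = runs, config = config, seed = seed),
            class = "session_schedule")
}

#' @export
print.session_schedule <- function(x, ...) {
  n <- vapply(x$runs, nrow, 0L)
  cat("Startle session schedule: 3 runs,", sum(n), "trials (",
      paste(n, collapse = "/"), ")\n")
  cat("ISI uniform [", x$config$isi_min, ",", x$config$isi_max, "] s; seed",
      x$seed, "\n")
  invisible(x)
}

#' @export
as.data.frame.session_schedule <- function(x, ...) {
  do.call(rbind, lapply(x$runs, function(r) as.data.frame(unclass(r))))
}

#' Validate a run schedule against its design invariants
#'
#' Checks trial composition against the generating config, the no-repeat
#' ordering rule (acclimatisation block exempt), strictly increasing onsets,
#' and the ISI range. Returns an empty data.frame when the schedule is valid.
#'
#' @param s a `run_schedule` (or plain data.frame with the same columns; then
#'   composition is checked only if a `config` attribute is present).
#' @return data.frame with columns `rule`, `index`, `message`; zero rows iff
#'   all invariants hold.
#' @export
validate_schedule <- function(s) {
  v <- list()
  add <- function(rule, index, message)
    v[[length(v) + 1L]] <<- data.frame(rule = rule, index = as.integer(index),
                                       message = message)
  config <- attr(s, "config")
  run <- s$run[1]
  n_acc <- if (!is.null(config) && isTRUE(run == 1L)) config$n_acclim else 0L
  tt <- s$trial_type
  n <- length(tt)
  if (n > 1) {
    rep_at <- which(tt[-1] == tt[-n]) + 1L   # index of the second of the pair
    rep_at <- rep_at[rep_at > n_acc]         # pairs inside the acclim head are exempt
    for (i in rep_at)
      add("repeat", i, sprintf("trial type '%s' repeats at indices %d,%d",
                               tt[i], i - 1L, i))
  }
  if (n > 1 && any(diff(s$onset) <= 0)) {
    bad <- which(diff(s$onset) <= 0) + 1L
    for (i in bad) add("onset_order", i, "onsets not strictly increasing")
  }
  if (!is.null(config)) {
    out_rng <- which(s$isi_after < config$isi_min | s$isi_after > config$isi_max)
    for (i in out_rng)
      add("isi_range", i, sprintf("ISI %.3f s outside [%g, %g]",
                                  s$isi_after[i], config$isi_min, config$isi_max))
    want <- run_counts(config, run)
    got <- table(factor(tt, levels = names(want)))
    for (ty in names(want))
      if (got[[ty]] != want[[ty]])
        add("composition", 0L, sprintf("expected %d '%s' trials, found %d",
                                       want[[ty]], ty, got[[ty]]))
  }
  if (!length(v))
    return(data.frame(rule = character(), index = integer(), message = character()))
  do.call(rbind, v)
}
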