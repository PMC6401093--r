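#' Experiment presets
#'
#' Timing and condition sets for the two session layouts: `exp1` is the
#' 3 T session (5 runs x 20 trials, TR 2 s, 1244 ms solution delivery,
#' 26 s stimulus onset asynchrony, conditions sour/sweet/bitter/salty/
#' tasteless) and `exp2` the 7 T session (TR 0.5 s, 2 s delivery, 25 s
#' SOA, two sweet and two bitter compounds plus tasteless).
#'
#' @param preset `"exp1"` or `"exp2"`.
#' @return list of preset parameters.
#' @export
design_preset <- function(preset = c("exp1", "exp2")) {
  preset <- match.arg(preset)
  switch(preset,
    exp1 = list(n_runs = 5L, trials_per_run = 20L, tr_s = 2, soa_s = 26,
                duration_s = 1.244, first_onset_s = 10, n_vols_per_run = 263L,
                conditions = c("sour", "sweet", "bitter", "salty", "tasteless")),
    exp2 = list(n_runs = 5L, trials_per_run = 20L, tr_s = 0.5, soa_s = 25,
                duration_s = 2, first_onset_s = 10, n_vols_per_run = 1010L,
                conditions = c("sweet1", "sweet2", "bitter1", "bitter2", "tasteless")))
}

#' Build a balanced event design
#'
#' Generates a per-trial event table (onset, duration, run, condition)
#' with every condition presented equally often within each run and the
#' trial order randomised per run.  With the default `exp1` preset this
#' yields 100 taste-solution trials balanced across five runs (20 per
#' condition, 4 per condition per run).
#'
#' @param preset `"exp1"` or `"exp2"`; individual fields can be
#'   overridden via the remaining arguments.
#' @param n_runs,trials_per_run,conditions,tr_s,soa_s,duration_s,first_onset_s
#'   optional overrides of the preset values.
#' @param seed integer seed for the trial-order permutation; `NULL` uses
#'   the current RNG state.
#' @return a `data.frame` of class `event_design` with columns `onset`,
#'   `duration`, `run`, `condition` and attributes `n_runs`, `tr_s`,
#'   `n_vols_per_run`, `conditions`.
#' @export
build_design <- function(preset = "exp1", n_runs = NULL, trials_per_run = NULL,
                         conditions = NULL, tr_s = NULL, soa_s = NULL,
                         duration_s = NULL, first_onset_s = NULL, seed = NULL) {
  p <- design_preset(preset)
  if (!is.null(n_runs)) p$n_runs <- as.integer(n_runs)
  if (!is.null(trials_per_run)) p$trials_per_run <- as.integer(trials_per_run)
  if (!is.null(conditions)) p$conditions <- conditions
  if (!is.null(tr_s)) p$tr_s <- tr_s
  if (!is.null(soa_s)) p$soa_s <- soa_s
  if (!is.null(duration_s)) p$duration_s <- duration_s
  if (!is.null(first_onset_s)) p$first_onset_s <- first_onset_s
  k <- length(p$conditions)
  if (p$trials_per_run %% k != 0)
    stop("invalid design: ", p$trials_per_run, " trials per run cannot be ",
         "balanced over ", k, " conditions")
  per_cond <- p$trials_per_run %/% k
  timing_overridden <- !is.null(trials_per_run) || !is.null(tr_s) ||
    !is.null(soa_s) || !is.null(first_onset_s)
  if (timing_overridden || is.null(p$n_vols_per_run))
    p$n_vols_per_run <-
      as.integer(ceiling((p$first_onset_s + p$trials_per_run * p$soa_s) / p$tr_s))
  use_seed(seed)
  rows <- lapply(seq_len(p$n_runs), function(r) {
    cond <- sample(rep(p$conditions, each = per_cond))
    data.frame(onset = p$first_onset_s + (seq_len(p$trials_per_run) - 1) * p$soa_s,
               duration = p$duration_s, run = r, condition = cond,
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  structure(d, n_runs = p$n_runs, tr_s = p$tr_s,
            n_vols_per_run = p$n_vols_per_run, conditions = p$conditions,
            class = c("event_design", "data.frame"))
}

#' @export
print.event_design <- function(x, ...) {
  cat("<event_design> ", nrow(x), " trials, ", attr(x, "n_runs"),
      " runs, TR ", attr(x, "tr_s"), " s\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Condition labels excluding the tasteless control
#'
#' @param conditions character vector of condition labels.
#' @return the non-tasteless labels, in input order.
#' @export
taste_labels <- function(conditions) {
  conditions[!grepl("^tasteless", conditions)]
}
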