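#' Roving-oddball stimulus design
#'
#' Describes the generative design of a roving-oddball tone sequence: a
#' categorical distribution over the number of tone repetitions per train
#' (a train of `r` repetitions contains `r + 1` tones), the set of tone
#' frequencies, and the target sequence length.
#'
#' The default repetition distribution is the one used in the roving
#' paradigm this package models: trains with zero to ten repetitions occur
#' with probabilities 2.5, 2.5, 3.75, 3.75 and then seven times 12.5 percent.
#' The default frequency set is seven log-spaced pure-tone frequencies from
#' 500 to 800 Hz.
#'
#' @param train_length_probs Numeric probability vector over repetition
#'   counts `0..(length - 1)`. Must be nonnegative and sum to 1.
#' @param frequency_set Tone frequencies in Hz; at least two distinct values
#'   (otherwise no frequency change, hence no deviant, is possible).
#' @param n_tones Target number of tones in the sequence.
#' @return An object of class `stimulus_design`.
#' @export
stimulus_design <- function(train_length_probs = default_train_length_probs(),
                            frequency_set = default_frequency_set(),
                            n_tones = 1600L) {
  if (any(!is.finite(train_length_probs)) || any(train_length_probs < 0)) {
    stop("train_length_probs must be finite and nonnegative", call. = FALSE)
  }
  if (abs(sum(train_length_probs) - 1) > 1e-12) {
    stop("train_length_probs must sum to 1 (within 1e-12)", call. = FALSE)
  }
  if (length(unique(frequency_set)) < 2L) {
    stop("frequency_set needs at least 2 distinct values", call. = FALSE)
  }
  if (any(frequency_set <= 0)) {
    stop("frequencies must be strictly positive", call. = FALSE)
  }
  if (n_tones < 1L) stop("n_tones must be >= 1", call. = FALSE)
  structure(
    list(
      train_length_probs = as.numeric(train_length_probs),
      frequency_set = as.numeric(frequency_set),
      n_tones = as.integer(n_tones)
    ),
    class = "stimulus_design"
  )
}

#' @rdname stimulus_design
#' @export
default_train_length_probs <- function() {
  c(0.025, 0.025, 0.0375, 0.0375, rep(0.125, 7L))
}

#' @rdname stimulus_design
#' @export
default_frequency_set <- function() {
  exp(seq(log(500), log(800), length.out = 7L))
}

#' Generate a roving-oddball tone sequence
#'
#' Draws train lengths i.i.d. from the design's repetition distribution and
#' assigns each train a frequency drawn uniformly from the frequency set
#' excluding the previous train's frequency, so consecutive trains always
#' differ. Generation stops at the first train boundary at or beyond
#' `n_tones` and the sequence is then truncated to exactly `n_tones` tones
#' (possibly cutting the final train short).
#'
#' @param design A [stimulus_design()].
#' @param seed Integer seed; all randomness in the sequence flows from it.
#' @return An object of class `tone_sequence` with elements
#'   `frequencies_hz`, `log_frequencies` (natural log of Hz), `train_id`
#'   (1-based), `seed` and `design`.
#' @export
generate_roving_sequence <- function(design, seed) {
  stopifnot(inherits(design, "stimulus_design"))
  n_tones <- design$n_tones
  freqs <- design$frequency_set
  mean_train <- sum((seq_along(design$train_length_probs)) *
                      design$train_length_probs) # E[r] + 1

  rng <- local_rng(seed)
  on.exit(rng$restore())
  # draw trains in blocks until the target tone count is covered
  reps <- integer(0)
  block <- max(16L, ceiling(1.3 * n_tones / mean_train))
  while (sum(reps + 1L) < n_tones) {
    reps <- c(reps, sample_train_repetitions(design, block))
    block <- max(16L, block %/% 4L)
  }
  n_trains <- which(cumsum(reps + 1L) >= n_tones)[1L]
  reps <- reps[seq_len(n_trains)]
  freq_idx <- sample_train_frequencies(length(freqs), n_trains)

  train_len <- reps + 1L
  freq_hz <- rep(freqs[freq_idx], train_len)[seq_len(n_tones)]
  train_id <- rep(seq_len(n_trains), train_len)[seq_len(n_tones)]
  structure(
    list(
      frequencies_hz = freq_hz,
      log_frequencies = log(freq_hz),
      train_id = train_id,
      seed = as.integer(seed),
      design = design
    ),
    class = "tone_sequence"
  )
}

#' Draw train repetition counts from a stimulus design
#'
#' Vectorized i.i.d. draws from the design's categorical distribution over
#' repetition counts (a train of `r` repetitions has `r + 1` tones). Used
#' internally by [generate_roving_sequence()] and directly when only train
#' statistics are needed.
#'
#' @param design A [stimulus_design()].
#' @param n_trains Number of trains to draw.
#' @param seed Optional integer seed; if `NULL` the draws continue the
#'   caller's RNG stream.
#' @return Integer vector of repetition counts.
#' @export
sample_train_repetitions <- function(design, n_trains, seed = NULL) {
  probs <- design$train_length_probs
  if (!is.null(seed)) {
    rng <- local_rng(seed)
    on.exit(rng$restore())
  }
  sample.int(length(probs), n_trains, replace = TRUE, prob = probs) - 1L
}

# Uniform draws over the frequency set excluding the previous train's
# frequency: the first train is uniform over all; each later train's index
# is the previous index advanced by a uniform offset in 1..(n_freq - 1)
# modulo n_freq, which is uniform over the other frequencies.
sample_train_frequencies <- function(n_freq, n_trains) {
  first <- sample.int(n_freq, 1L)
  if (n_trains == 1L) return(first)
  steps <- sample.int(n_freq - 1L, n_trains - 1L, replace = TRUE)
  (first - 1L + cumsum(c(0L, steps))) %% n_freq + 1L
}

#' Construct a tone sequence from explicit frequencies
#'
#' Builds a `tone_sequence` directly from a vector of tone frequencies,
#' deriving train boundaries from frequency changes. Useful for scripted
#' or externally supplied sequences.
#'
#' @param frequencies_hz Positive tone frequencies, one per trial.
#' @param design Optional [stimulus_design()]; defaults to a design whose
#'   frequency set is the distinct frequencies present.
#' @param seed Seed to record (`NA` for hand-built sequences).
#' @return A `tone_sequence`.
#' @export
tone_sequence <- function(frequencies_hz, design = NULL, seed = NA_integer_) {
  if (length(frequencies_hz) == 0L) stop("empty tone sequence", call. = FALSE)
  if (any(frequencies_hz <= 0)) stop("frequencies must be positive", call. = FALSE)
  if (is.null(design)) {
    fs <- sort(unique(frequencies_hz))
    if (length(fs) < 2L) fs <- c(fs, fs * 2) # placeholder partner frequency
    design <- stimulus_design(frequency_set = fs,
                              n_tones = length(frequencies_hz))
  }
  changes <- c(TRUE, frequencies_hz[-1L] != frequencies_hz[-length(frequencies_hz)])
  structure(
    list(
      frequencies_hz = as.numeric(frequencies_hz),
      log_frequencies = log(frequencies_hz),
      train_id = cumsum(changes),
      seed = seed,
      design = design
    ),
    class = "tone_sequence"
  )
}

#' Annotate a tone sequence with run lengths and deviant/standard labels
#'
#' Computes, for every trial, the run length (number of immediately
#' preceding identical tones: 0 at each train start, incrementing within a
#' train), the deviant flag (first tone after a train of a different
#' frequency; the first tone of the session is not a deviant) and the
#' sixth-presentation "standard" flag (`run_length == 5`).
#'
#' @param seq A `tone_sequence`.
#' @return A `data.frame` of class `trial_table` with columns `trial`
#'   (1-based), `frequency_hz`, `log_frequency`, `train_id`, `run_length`,
#'   `is_deviant`, `is_standard6`.
#' @export
annotate_trials <- function(seq) {
  stopifnot(inherits(seq, "tone_sequence"))
  n <- length(seq$frequencies_hz)
  if (n == 0L) stop("empty tone sequence", call. = FALSE)
  tid <- seq$train_id
  new_train <- c(TRUE, tid[-1L] != tid[-n])
  # run_length resets to 0 at train starts, +1 per within-train step
  run_length <- integer(n)
  run_length[!new_train] <- sequence(rle(tid)$lengths - 1L)
  is_deviant <- new_train
  is_deviant[1L] <- FALSE
  out <- data.frame(
    trial = seq_len(n),
    frequency_hz = seq$frequencies_hz,
    log_frequency = seq$log_frequencies,
    train_id = tid,
    run_length = run_length,
    is_deviant = is_deviant,
    is_standard6 = run_length == 5L
  )
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Write a tone sequence and its trial annotations to TSV
#'
#' Columns: `trial_index` (0-based), `frequency_hz`, `log_frequency`,
#' `train_id`, `run_length`, `is_deviant`, `is_standard6`.
#'
#' @param trials A `trial_table` from [annotate_trials()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  out <- data.frame(
    trial_index = trials$trial - 1L,
    frequency_hz = trials$frequency_hz,
    log_frequency = trials$log_frequency,
    train_id = trials$train_id,
    run_length = trials$run_length,
    is_deviant = trials$is_deviant,
    is_standard6 = trials$is_standard6
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
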