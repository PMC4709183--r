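#' Speller stimulus matrix
#'
#' Describes the character grid of a row/column speller. Stimuli are the
#' rows and columns of the grid: stimulus ids `1..n_rows` flash rows and
#' `n_rows + 1 .. n_rows + n_cols` flash columns, so every flash block
#' contains `n_rows + n_cols` distinct stimuli.
#'
#' @param n_rows,n_cols Grid dimensions; both must be at least 2. The
#'   default 5 x 6 grid flashes 11 stimuli per block.
#' @param symbols Optional character vector of display labels in row-major
#'   order (length `n_rows * n_cols`). Labels are arbitrary strings, so any
#'   alphabet works. Defaults to `"S1".."Sn"`.
#' @return An object of class `speller_matrix`.
#' @examples
#' m <- speller_matrix(5, 6)
#' n_stimuli(m)  # 11
#' @export
speller_matrix <- function(n_rows = 5, n_cols = 6, symbols = NULL) {
  if (n_rows < 2 || n_cols < 2)
    stop("speller matrix needs at least 2 rows and 2 columns", call. = FALSE)
  n <- n_rows * n_cols
  if (is.null(symbols)) symbols <- paste0("S", seq_len(n))
  if (length(symbols) != n)
    stop("need exactly n_rows * n_cols symbols (", n, ")", call. = FALSE)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         symbols = as.character(symbols)),
    class = "speller_matrix")
}

#' Number of distinct stimuli per flash block
#' @param matrix A [speller_matrix()].
#' @return `n_rows + n_cols`.
#' @export
n_stimuli <- function(matrix) matrix$n_rows + matrix$n_cols

# Row / column grid position of a 1-based row-major character index.
char_position <- function(matrix, character_index) {
  k <- as.integer(character_index)
  if (any(k < 1L | k > length(matrix$symbols)))
    stop("character index out of range for this matrix", call. = FALSE)
  list(row = (k - 1L) %/% matrix$n_cols + 1L,
       col = (k - 1L) %% matrix$n_cols + 1L)
}

#' Stimulus ids that contain a character
#'
#' The two target stimuli for a focused character: its row id and its
#' column id (`n_rows + column`).
#' @inheritParams n_stimuli
#' @param character_index 1-based row-major character index.
#' @return Integer vector of length 2 (row stimulus, column stimulus).
#' @export
target_stimuli <- function(matrix, character_index) {
  pos <- char_position(matrix, character_index)
  c(pos$row, matrix$n_rows + pos$col)
}

#' Build a randomized flash schedule for a spelling session
#'
#' One block flashes every row and column exactly once in random order;
#' blocks are repeated `n_repetitions` times per character. Successive
#' flash onsets within a character are separated by exactly `isi` seconds
#' (onset asynchrony; the flash itself lasts `flash_duration` seconds
#' followed by a dark gap). Between characters the display is blank for
#' `inter_character_gap` seconds with no events.
#'
#' @inheritParams n_stimuli
#' @param characters Integer vector of focused character indices (1-based,
#'   row-major), one per run; repeats are allowed.
#' @param n_repetitions Blocks per character (>= 1).
#' @param flash_duration Flash length in seconds (must be positive and no
#'   longer than `isi`).
#' @param isi Inter-stimulus interval (onset-to-onset) in seconds.
#' @param inter_character_gap Blank period between characters, seconds.
#' @param lead_in Quiet time before the first flash, seconds (leaves room
#'   for the pre-stimulus epoch window).
#' @param seed Optional integer; fixes the block randomization.
#' @return An object of class `session_plan` with the stimulus matrix, the
#'   timing parameters and an `events` data frame (one row per flash:
#'   `onset_s`, `stimulus_id`, `is_target`, `character_index`, `block`).
#' @examples
#' plan <- build_schedule(speller_matrix(), characters = 1:14, seed = 1)
#' expected_counts(plan)  # 420 target, 1890 non-target flashes
#' @export
build_schedule <- function(matrix, characters, n_repetitions = 15,
                           flash_duration = 0.150, isi = 0.250,
                           inter_character_gap = 3, lead_in = 2,
                           seed = NULL) {
  stopifnot(inherits(matrix, "speller_matrix"))
  characters <- as.integer(characters)
  char_position(matrix, characters)  # validates
  if (n_repetitions < 1) stop("n_repetitions must be >= 1", call. = FALSE)
  if (flash_duration <= 0 || isi <= 0)
    stop("flash_duration and isi must be positive", call. = FALSE)
  if (flash_duration > isi)
    stop("flash_duration cannot exceed the inter-stimulus interval",
         call. = FALSE)
  ns <- n_stimuli(matrix)
  with_seed(seed, {
    t0 <- lead_in
    rows <- vector("list", length(characters) * n_repetitions)
    b <- 0L
    for (ci in seq_along(characters)) {
      tgt <- target_stimuli(matrix, characters[ci])
      for (rep_i in seq_len(n_repetitions)) {
        order <- sample.int(ns)
        b <- b + 1L
        rows[[b]] <- data.frame(
          onset_s = t0 + (seq_len(ns) - 1) * isi,
          stimulus_id = order,
          is_target = order %in% tgt,
          character_index = characters[ci],
          run = ci,
          block = rep_i)
        t0 <- t0 + ns * isi
      }
      t0 <- t0 + inter_character_gap
    }
    events <- do.call(rbind, rows)
    rownames(events) <- NULL
    structure(
      list(matrix = matrix, characters = characters,
           n_repetitions = as.integer(n_repetitions),
           flash_duration = flash_duration, isi = isi,
           inter_character_gap = inter_character_gap, lead_in = lead_in,
           events = events),
      class = "session_plan")
  })
}

#' Expected target / non-target flash counts for a session
#'
#' Counting identity of the row/column paradigm: every block contains
#' exactly 2 target flashes (the focused character's row and column) and
#' `n_rows + n_cols - 2` non-target flashes, so a session yields
#' `n_characters * n_repetitions * 2` target and
#' `n_characters * n_repetitions * (n_rows + n_cols - 2)` non-target
#' trials.
#'
#' @param plan A [build_schedule()] result.
#' @return Named integer vector `c(n_target, n_nontarget)`.
#' @export
expected_counts <- function(plan) {
  stopifnot(inherits(plan, "session_plan"))
  nc <- length(plan$characters)
  ns <- n_stimuli(plan$matrix)
  c(n_target = nc * plan$n_repetitions * 2L,
    n_nontarget = nc * plan$n_repetitions * (ns - 2L))
}

#' @export
print.session_plan <- function(x, ...) {
  cnt <- expected_counts(x)
  cat(sprintf(
    "<session_plan> %d x %d matrix, %d characters x %d repetitions\n",
    x$matrix$n_rows, x$matrix$n_cols, length(x$characters),
    x$n_repetitions))
  cat(sprintf("  %d flashes (%d target / %d non-target), ISI %.0f ms\n",
              nrow(x$events), cnt[1], cnt[2], x$isi * 1000))
  invisible(x)
}

#' @export
print.speller_matrix <- function(x, ...) {
  cat(sprintf("<speller_matrix> %d x %d (%d stimuli per block)\n",
              x$n_rows, x$n_cols, n_stimuli(x)))
  invisible(x)
}

#' Write / read a flash event table as tab-separated values
#'
#' One row per flash with columns `onset_s`, `stimulus_id`, `is_target`
#' (0/1) and `character_index`, a BIDS-style events dialect shared by the
#' synthetic and real-data paths.
#'
#' @param events A `session_plan`, or a data frame with the columns above.
#' @param path Output file.
#' @return `write_events_tsv` returns `path` invisibly; `read_events_tsv`
#'   returns the events data frame.
#' @export
write_events_tsv <- function(events, path) {
  if (inherits(events, "session_plan")) events <- events$events
  out <- data.frame(onset_s = events$onset_s,
                    stimulus_id = events$stimulus_id,
                    is_target = as.integer(events$is_target),
                    character_index = events$character_index)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- read.table(path, header = TRUE, sep = "\t")
  ev$is_target <- as.logical(ev$is_target)
  ev
}
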