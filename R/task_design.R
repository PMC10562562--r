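#' Direction labels and their screen unit vectors
#'
#' The four erasing directions expressed in screen coordinates. The screen
#' uses a left-handed convention: x increases rightward, y increases
#' downward, so \code{up = (0, -1)}.
#'
#' @return A data frame with columns \code{name}, \code{ux}, \code{uy}.
#' @export
direction_labels <- function() {
  data.frame(
    name = c("up", "down", "left", "right"),
    ux   = c(0, 0, -1, 1),
    uy   = c(-1, 1, 0, 0),
    stringsAsFactors = FALSE
  )
}

#' Unit vector of a direction label
#' @param name One of "up", "down", "left", "right".
#' @return Length-2 numeric vector (screen coordinates, y-down).
#' @export
direction_vector <- function(name) {
  dl <- direction_labels()
  i <- match(name, dl$name)
  if (anyNA(i)) stop("unknown direction label: ", paste(name[is.na(i)], collapse = ", "))
  if (length(name) == 1L) c(dl$ux[i], dl$uy[i]) else cbind(dl$ux[i], dl$uy[i])
}

#' Direction label of a unit vector
#' @param v Length-2 numeric vector; must equal one of the four axis-aligned
#'   unit vectors.
#' @return Direction name.
#' @export
direction_from_vector <- function(v) {
  dl <- direction_labels()
  i <- which(dl$ux == round(v[1]) & dl$uy == round(v[2]))
  if (length(i) != 1L) stop("vector is not an axis-aligned unit vector")
  dl$name[i]
}

#' Opposite of a direction label
#' @param name Direction name.
#' @return Direction name with negated unit vector.
#' @export
opposite_direction <- function(name) {
  opp <- c(up = "down", down = "up", left = "right", right = "left")
  unname(opp[name])
}

#' Context transformation matrices
#'
#' The three visuomotor-adaptation contexts as 2x2 hand-to-cursor
#' transformation matrices in the left-handed (y-down) screen convention:
#' a -90 degree rotation (counterclockwise on screen), a +90 degree rotation
#' (clockwise), and a horizontal mirror reversal. Each entry carries the
#' matrix and its inverse (the cursor-to-hand map).
#'
#' @return Named list of contexts, each a list with \code{name},
#'   \code{matrix} and \code{inverse}.
#' @export
context_transforms <- function() {
  rot_m90 <- matrix(c(0, -1, 1, 0), 2, 2)  # column-major: [[0,1],[-1,0]]
  rot_p90 <- matrix(c(0, 1, -1, 0), 2, 2)  # [[0,-1],[1,0]]
  mirror  <- matrix(c(-1, 0, 0, 1), 2, 2)  # [[-1,0],[0,1]]
  list(
    rot_minus90 = list(name = "rot_minus90", matrix = rot_m90, inverse = rot_p90),
    rot_plus90  = list(name = "rot_plus90",  matrix = rot_p90, inverse = rot_m90),
    mirror      = list(name = "mirror",      matrix = mirror,  inverse = mirror)
  )
}

#' Context names
#' @return Character vector of the three context names.
#' @export
context_names <- function() c("rot_minus90", "rot_plus90", "mirror")

.context <- function(context) {
  ct <- context_transforms()
  if (!context %in% names(ct)) stop("unknown context: ", context)
  ct[[context]]
}

#' Apply a context transform to a hand displacement
#'
#' Maps a hand (mouse) displacement to the resulting cursor displacement on
#' screen under the given adaptation context.
#'
#' @param context Context name.
#' @param hand_displacement Length-2 numeric vector (pixels).
#' @return Length-2 cursor displacement (pixels).
#' @export
apply_context_transform <- function(context, hand_displacement) {
  if (!all(is.finite(hand_displacement))) stop("hand displacement must be finite")
  as.numeric(.context(context)$matrix %*% hand_displacement)
}

# context x direction lookup tables derived once from the transformation
# matrices (row: context, column: input direction).
.mapping_tables <- local({
  tabs <- NULL
  function() {
    if (is.null(tabs)) {
      dl <- direction_labels()
      ct <- context_transforms()
      mk <- function(which_mat) {
        m <- vapply(names(ct), function(cx) vapply(dl$name, function(d) {
          v <- c(dl$ux[dl$name == d], dl$uy[dl$name == d])
          u <- as.numeric(ct[[cx]][[which_mat]] %*% v)
          dl$name[dl$ux == u[1] & dl$uy == u[2]]
        }, ""), character(nrow(dl)))
        rownames(m) <- dl$name
        m
      }
      tabs <<- list(inverse = mk("inverse"), forward = mk("matrix"))
    }
    tabs
  }
})

#' Hand-movement direction required to produce a visual direction
#'
#' Given the adaptation context and the on-screen (visual) direction of the
#' line, returns the hand-movement direction whose transformed cursor motion
#' follows the line: the inverse transform applied to the visual unit
#' vector. Vectorized over both arguments.
#'
#' @param context Context name(s).
#' @param visual Visual direction label(s).
#' @return Movement direction label(s).
#' @export
required_movement <- function(context, visual) {
  tab <- .mapping_tables()$inverse
  out <- tab[cbind(visual, context)]
  if (anyNA(out)) stop("unknown context or direction label")
  unname(out)
}

#' Visual direction produced by a hand-movement direction
#'
#' Forward counterpart of [required_movement()]: the on-screen direction of
#' cursor motion when the hand moves along \code{movement} under the
#' context. Vectorized over both arguments.
#'
#' @param context Context name(s).
#' @param movement Movement direction label(s).
#' @return Visual direction label(s).
#' @export
visual_of_movement <- function(context, movement) {
  tab <- .mapping_tables()$forward
  out <- tab[cbind(movement, context)]
  if (anyNA(out)) stop("unknown context or direction label")
  unname(out)
}

#' The printed continuous-carryover order template for four conditions
#'
#' A type 1 index 1 serially balanced sequence over four condition indices:
#' among its 16 transitions every ordered pair of conditions (self-pairs
#' included) occurs exactly once.
#'
#' @return Integer vector of length 17.
#' @export
carryover_template <- function() {
  c(1L, 2L, 2L, 3L, 4L, 4L, 1L, 1L, 3L, 3L, 1L, 4L, 2L, 4L, 3L, 2L, 1L)
}

#' Generate a continuous-carryover condition sequence
#'
#' For \code{n_conditions = 4} the sequence is the printed template with
#' condition labels permuted by a random bijection (drawn from the current
#' RNG state). For other \code{n_conditions >= 2} the sequence is a random
#' Eulerian circuit of the complete digraph with self-loops on
#' \code{n_conditions} nodes, which has the same serial-balance property.
#'
#' @param n_conditions Number of conditions (>= 2).
#' @param label_map Optional integer permutation of \code{1:n_conditions}
#'   applied to the template/circuit labels; default random.
#' @return Integer vector of length \code{n_conditions^2 + 1} in which every
#'   ordered pair of conditions occurs exactly once among the transitions.
#' @export
generate_carryover_sequence <- function(n_conditions = 4, label_map = NULL) {
  n <- as.integer(n_conditions)
  if (is.na(n) || n < 2L) stop("n_conditions must be an integer >= 2")
  if (is.null(label_map)) label_map <- sample.int(n)
  if (length(label_map) != n || !setequal(label_map, seq_len(n)))
    stop("label_map must be a permutation of 1:n_conditions")
  base <- if (n == 4L) carryover_template() else eulerian_carryover(n)
  as.integer(label_map[base])
}

# Random Eulerian circuit on the complete digraph with self-loops
# (Hierholzer's algorithm); every node has in-degree = out-degree = n.
eulerian_carryover <- function(n) {
  remaining <- lapply(seq_len(n), function(i) sample.int(n))  # out-edges per node
  used <- integer(n)                                          # edges consumed per node
  start <- sample.int(n, 1L)
  stack <- c(start)
  circuit <- integer(0)
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    if (used[v] < n) {
      used[v] <- used[v] + 1L
      stack <- c(stack, remaining[[v]][used[v]])
    } else {
      circuit <- c(circuit, v)
      stack <- stack[-length(stack)]
    }
  }
  rev(circuit)
}

#' Transition-count matrix of a condition sequence
#'
#' @param sequence Integer condition sequence.
#' @param n_conditions Number of conditions.
#' @return \code{n_conditions x n_conditions} matrix of ordered-pair counts;
#'   all-ones for a valid continuous-carryover sequence.
#' @export
transition_counts <- function(sequence, n_conditions = max(sequence)) {
  m <- matrix(0L, n_conditions, n_conditions)
  for (i in seq_len(length(sequence) - 1L))
    m[sequence[i], sequence[i + 1L]] <- m[sequence[i], sequence[i + 1L]] + 1L
  m
}

#' Assign erasing directions to condition indices
#'
#' Maps each of the four condition indices of a carryover sequence to one of
#' the four erasing directions by a random (or supplied) bijection, as the
#' task does when instantiating a block's trial order.
#'
#' @param sequence Integer condition sequence over indices 1..4.
#' @param mapping Optional character vector of four direction names;
#'   \code{mapping[i]} is the direction assigned to condition \code{i}.
#' @return Character vector of direction labels.
#' @export
assign_directions <- function(sequence, mapping = NULL) {
  if (is.null(mapping)) mapping <- sample(direction_labels()$name)
  if (!setequal(mapping, direction_labels()$name))
    stop("mapping must be a permutation of the four direction labels")
  mapping[sequence]
}

#' Timing parameters of a session
#'
#' @param trial_window_s Maximum erasing time per trial (s).
#' @param iti_s Inter-trial interval (s).
#' @param prep_s Duration of the block-initial preparation stimulus (s).
#' @param score_s Duration of the block-final score display (s).
#' @param term_s Duration of the block-termination instruction (s).
#' @param n_blocks Number of blocks per session.
#' @param n_context_reps Repetitions of each context; must be n_blocks / 3.
#' @param n_trials_per_block Trials per block.
#' @param tr_s Scanner repetition time (s).
#' @return List of class \code{timing_params}.
#' @export
timing_params <- function(trial_window_s = 3.5, iti_s = 6, prep_s = 8,
                          score_s = 4, term_s = 1.5, n_blocks = 15,
                          n_context_reps = 5, n_trials_per_block = 17,
                          tr_s = 2.3) {
  tp <- list(trial_window_s = trial_window_s, iti_s = iti_s, prep_s = prep_s,
             score_s = score_s, term_s = term_s, n_blocks = as.integer(n_blocks),
             n_context_reps = as.integer(n_context_reps),
             n_trials_per_block = as.integer(n_trials_per_block), tr_s = tr_s)
  num <- unlist(tp[c("trial_window_s", "iti_s", "prep_s", "score_s", "tr_s")])
  if (any(num <= 0)) stop("timing parameters must be strictly positive")
  if (tp$n_blocks != 3L * tp$n_context_reps)
    stop("n_blocks must equal 3 * n_context_reps")
  structure(tp, class = "timing_params")
}

#' Build a full session design
#'
#' Draws a random block order (each context repeated \code{n_context_reps}
#' times), a fresh carryover trial sequence with a fresh direction assignment
#' for every block, and lays out preparation, trial, score and termination
#' events on a common session clock.
#'
#' @param timing A [timing_params()] object.
#' @param seed Optional integer seed recorded in the design; when supplied
#'   the session is fully reproducible.
#' @return Object of class \code{session_design}: a list with \code{blocks}
#'   (list of per-block descriptors), \code{events} (data frame), the timing
#'   and the seed.
#' @export
build_session <- function(timing = timing_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ctx <- sample(rep(context_names(), timing$n_context_reps))
  block_len <- timing$prep_s +
    timing$n_trials_per_block * (timing$trial_window_s + timing$iti_s) +
    timing$score_s + timing$term_s
  blocks <- vector("list", timing$n_blocks)
  ev <- list()
  for (b in seq_len(timing$n_blocks)) {
    onset <- (b - 1L) * block_len
    cseq <- generate_carryover_sequence(4)
    vis <- assign_directions(cseq)
    if (length(vis) != timing$n_trials_per_block)
      vis <- rep_len(vis, timing$n_trials_per_block)
    mov <- required_movement(rep(ctx[b], length(vis)), vis)
    trial_on <- onset + timing$prep_s +
      (seq_along(vis) - 1L) * (timing$trial_window_s + timing$iti_s)
    score_on <- trial_on[length(vis)] + timing$trial_window_s + timing$iti_s
    blocks[[b]] <- list(block_index = b, context = ctx[b],
                        trial_sequence = vis, onset_s = onset)
    ev[[b]] <- data.frame(
      onset = c(onset, trial_on, score_on, score_on + timing$score_s),
      duration = c(timing$prep_s, rep(timing$trial_window_s, length(vis)),
                   timing$score_s, timing$term_s),
      trial_type = c("preparation", rep("trial", length(vis)), "score",
                     "termination"),
      block = b,
      trial = c(NA, seq_along(vis), NA, NA),
      context = ctx[b],
      visual_direction = c(NA, vis, NA, NA),
      movement_direction = c(NA, mov, NA, NA),
      stringsAsFactors = FALSE
    )
  }
  events <- do.call(rbind, ev)
  structure(list(blocks = blocks, events = events, timing = timing,
                 block_order_seed = seed),
            class = "session_design")
}

#' @export
print.session_design <- function(x, ...) {
  ctx <- vapply(x$blocks, `[[`, "", "context")
  cat("Session design:", length(x$blocks), "blocks,",
      x$timing$n_trials_per_block, "trials per block\n")
  cat("Block order:", paste(ctx, collapse = " "), "\n")
  cat("Duration:", round(session_duration(x), 1), "s (",
      n_scans_for_session(x), "scans at TR", x$timing$tr_s, "s)\n")
  invisible(x)
}

#' Total duration of a session in seconds
#' @param session A \code{session_design}.
#' @return Seconds from first preparation onset to last termination offset.
#' @export
session_duration <- function(session) {
  ev <- session$events
  max(ev$onset + ev$duration)
}

#' Number of scans covering a session
#' @param session A \code{session_design}.
#' @param extra_s Trailing time appended after the last event (s), covering
#'   the hemodynamic tail.
#' @return Integer scan count at the session's TR.
#' @export
n_scans_for_session <- function(session, extra_s = 20) {
  as.integer(ceiling((session_duration(session) + extra_s) / session$timing$tr_s))
}

#' Write or read a session events table
#'
#' Tab-separated events dialect with columns onset, duration, trial_type,
#' block, trial, context, visual_direction, movement_direction.
#'
#' @param session A \code{session_design} (for writing).
#' @param path File path.
#' @return \code{read_events} returns the events data frame.
#' @export
write_events <- function(session, path) {
  ev <- if (inherits(session, "session_design")) session$events else session
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "n/a")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = "n/a",
                          stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type", "block", "trial", "context",
            "visual_direction", "movement_direction")
  missing <- setdiff(need, names(ev))
  if (length(missing) > 0)
    stop("events table at ", path, " lacks columns: ",
         paste(missing, collapse = ", "))
  ev
}
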