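#' State-action-reward history
#'
#' The training set of the MMR policy learner: aligned records of the state
#' observed before an action, the action (additive change of the transformed
#' enzyme levels), and the reward it earned (the change of the response
#' between the two consecutive cultivation rounds).
#'
#' @param states numeric matrix, one row per record (state observed before
#'   the action), or a single numeric vector for one record.
#' @param actions numeric matrix, one row per record, or a vector.
#' @param rewards numeric vector of response deltas.
#' @return an object of class `mmr_history` with elements `states`,
#'   `actions` (matrices) and `rewards`.
#' @export
#' @examples
#' h <- mmr_history(states = diag(2), actions = matrix(1:4, 2), rewards = c(0, 1))
#' length(h)
mmr_history <- function(states, actions, rewards) {
  if (is.vector(states)) states <- matrix(states, nrow = 1L)
  if (is.vector(actions)) actions <- matrix(actions, nrow = 1L)
  states <- as.matrix(states)
  actions <- as.matrix(actions)
  rewards <- as.numeric(rewards)
  if (nrow(states) != nrow(actions) || nrow(states) != length(rewards)) {
    stop("states, actions and rewards must have the same number of records")
  }
  if (length(rewards) > 0L &&
      (!all(is.finite(states)) || !all(is.finite(actions)) || !all(is.finite(rewards)))) {
    stop("history entries must be finite")
  }
  structure(list(states = states, actions = actions, rewards = rewards),
            class = "mmr_history")
}

#' @export
length.mmr_history <- function(x) length(x$rewards)

#' Append records to a history
#'
#' @param h an [mmr_history()] object.
#' @param states,actions,rewards records to append (same shapes as in
#'   [mmr_history()]).
#' @return the extended `mmr_history`; record order is preserved.
#' @export
history_append <- function(h, states, actions, rewards) {
  add <- mmr_history(states, actions, rewards)
  if (length(h) > 0L) {
    if (ncol(add$states) != ncol(h$states) || ncol(add$actions) != ncol(h$actions)) {
      stop("appended records have inconsistent dimensions")
    }
  }
  mmr_history(rbind(h$states, add$states),
              rbind(h$actions, add$actions),
              c(h$rewards, add$rewards))
}

#' @export
print.mmr_history <- function(x, ...) {
  cat(sprintf("<mmr_history: %d records, n_s = %d, n_a = %d>\n",
              length(x), ncol(x$states), ncol(x$actions)))
  invisible(x)
}
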