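#' Markov gating scheme
#'
#' A gating scheme is a finite-state Markov model of channel gating: a set of
#' states, each open or closed with a conducting amplitude (closed states
#' conduct 0 pA), and voltage-dependent rate constants on the allowed
#' transitions. All analytic machinery (transition probabilities, steady
#' state) and the Monte Carlo simulator operate on this object.
#'
#' @param states A data frame with columns `label` (character), `class`
#'   (`"open"` or `"closed"`), and `amplitude` (pA; must be 0 for closed
#'   states).
#' @param rates A data frame with columns `from`, `to` (state labels) and
#'   either a list-column `law` of [rate_law()] objects or numeric columns
#'   `k0` and `z` (a fixed rate is `k0` with `z = 0`).
#' @return An object of class `gating_scheme`.
#' @examples
#' two_state <- gating_scheme(
#'   states = data.frame(label = c("C", "O"), class = c("closed", "open"),
#'                       amplitude = c(0, 10)),
#'   rates = data.frame(from = c("C", "O"), to = c("O", "C"),
#'                      k0 = c(100, 50), z = c(0.5, -0.25))
#' )
#' steady_state_occupancy(two_state, V = 0)
#' @export
gating_scheme <- function(states, rates) {
  states <- tibble::as_tibble(states)
  rates <- tibble::as_tibble(rates)
  stopifnot(all(c("label", "class", "amplitude") %in% names(states)),
            all(c("from", "to") %in% names(rates)))
  states$label <- as.character(states$label)
  if (anyDuplicated(states$label)) abort("duplicate state labels")
  if (!all(states$class %in% c("open", "closed"))) {
    abort("state class must be 'open' or 'closed'")
  }
  if (!any(states$class == "open") || !any(states$class == "closed")) {
    abort("scheme needs at least one open and one closed state")
  }
  closed_amp <- states$amplitude[states$class == "closed"]
  if (any(closed_amp != 0)) abort("closed states must have amplitude 0 pA")

  if (!"law" %in% names(rates)) {
    stopifnot(all(c("k0") %in% names(rates)))
    if (!"z" %in% names(rates)) rates$z <- 0
    rates$law <- purrr::map2(rates$k0, rates$z, rate_law)
  }
  rates$from <- as.character(rates$from)
  rates$to <- as.character(rates$to)
  bad <- setdiff(c(rates$from, rates$to), states$label)
  if (length(bad)) abort(paste("unknown state in rate table:", bad[1]))
  if (any(rates$from == rates$to)) abort("self-transitions are not allowed")

  structure(list(states = states,
                 rates = rates[c("from", "to", "law")]),
            class = "gating_scheme")
}

#' @export
print.gating_scheme <- function(x, ...) {
  cat(sprintf("<gating_scheme> %d states (%d open, %d closed), %d transitions\n",
              nrow(x$states), sum(x$states$class == "open"),
              sum(x$states$class == "closed"), nrow(x$rates)))
  invisible(x)
}

#' Transition-rate matrix of a scheme at a voltage
#'
#' Returns the generator matrix Q (s^-1): off-diagonal `Q[i, j]` is the rate
#' from state i to state j, the diagonal holds minus the total exit rate.
#'
#' @param scheme A [gating_scheme()].
#' @param V Membrane potential in mV.
#' @return A square numeric matrix with state labels as dimnames.
#' @export
scheme_rate_matrix <- function(scheme, V) {
  stopifnot(inherits(scheme, "gating_scheme"), length(V) == 1)
  lab <- scheme$states$label
  n <- length(lab)
  Q <- matrix(0, n, n, dimnames = list(lab, lab))
  for (r in seq_len(nrow(scheme$rates))) {
    k <- rate_at_voltage(scheme$rates$law[[r]], V)
    if (!is.finite(k) || k <= 0) abort("rate must be positive and finite at V")
    Q[scheme$rates$from[r], scheme$rates$to[r]] <-
      Q[scheme$rates$from[r], scheme$rates$to[r]] + k
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition probabilities out of a state
#'
#' Embedded-chain branching probabilities \eqn{p_{ij} = k_{ij} / \sum_j
#' k_{ij}}: given that the channel leaves state i, the probability that it
#' enters state j. Invariant under uniform scaling of the exit rates.
#'
#' @param scheme A [gating_scheme()].
#' @param state State label.
#' @param V Membrane potential in mV.
#' @return A tibble with columns `to` and `p` (nonnegative, summing to 1).
#' @export
transition_probabilities <- function(scheme, state, V) {
  stopifnot(inherits(scheme, "gating_scheme"))
  if (!state %in% scheme$states$label) abort("unknown state")
  idx <- scheme$rates$from == state
  if (!any(idx)) abort(paste0("state '", state, "' has no exits (absorbing)"))
  k <- purrr::map_dbl(scheme$rates$law[idx], rate_at_voltage, V = V)
  tibble::tibble(to = scheme$rates$to[idx], p = k / sum(k))
}

# strong connectivity of the transition graph (reachability both ways from
# state 1); a disconnected scheme has no unique stationary distribution
scheme_is_connected <- function(scheme) {
  lab <- scheme$states$label
  n <- length(lab)
  adj <- matrix(FALSE, n, n, dimnames = list(lab, lab))
  adj[cbind(scheme$rates$from, scheme$rates$to)] <- TRUE
  reach <- function(A) {
    seen <- c(TRUE, rep(FALSE, n - 1))
    repeat {
      new <- (seen %*% A)[1, ] > 0
      if (!any(new & !seen)) break
      seen <- seen | new
    }
    all(seen)
  }
  reach(adj) && reach(t(adj))
}

#' Steady-state occupancy of a scheme
#'
#' Solves the stationary balance equations \eqn{\pi Q = 0}, \eqn{\sum \pi_i =
#' 1} for the scheme's generator at voltage `V`. The scheme must be connected
#' (every state reachable from every other); occupancies are nonnegative and
#' sum to 1.
#'
#' @inheritParams scheme_rate_matrix
#' @return A tibble with columns `state`, `class`, `occupancy`.
#' @seealso [predict_open_probability()] for the closed-form star-scheme case.
#' @export
steady_state_occupancy <- function(scheme, V) {
  stopifnot(inherits(scheme, "gating_scheme"))
  if (!scheme_is_connected(scheme)) abort("scheme is not connected")
  Q <- scheme_rate_matrix(scheme, V)
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  pi <- qr.solve(A, b)
  pi[pi < 0 & pi > -1e-12] <- 0
  tibble::tibble(state = scheme$states$label,
                 class = scheme$states$class,
                 occupancy = as.numeric(pi))
}

#' Open probability of a scheme at steady state
#'
#' Sum of the stationary occupancies of the open states.
#'
#' @inheritParams scheme_rate_matrix
#' @return Scalar in (0, 1).
#' @export
scheme_open_probability <- function(scheme, V) {
  occ <- steady_state_occupancy(scheme, V)
  sum(occ$occupancy[occ$class == "open"])
}

#' Read or write a gating scheme as a text configuration
#'
#' Schemes are serialized as YAML with a `states` block (label, class,
#' amplitude) and a `rates` block (from, to, k0, z); `read_scheme()`
#' round-trips anything written by `write_scheme()`.
#'
#' @param scheme A [gating_scheme()].
#' @param path File path.
#' @return `read_scheme()` returns a [gating_scheme()]; `write_scheme()`
#'   returns `path` invisibly.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "gating_scheme"))
  obj <- list(
    states = purrr::pmap(scheme$states, function(label, class, amplitude) {
      list(label = label, class = class, amplitude = amplitude)
    }),
    rates = purrr::pmap(scheme$rates, function(from, to, law) {
      list(from = from, to = to, k0 = law$k0, z = law$z)
    })
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$states) || is.null(obj$rates)) {
    abort("scheme file must contain 'states' and 'rates' blocks")
  }
  states <- purrr::map_dfr(obj$states, tibble::as_tibble)
  rates <- purrr::map_dfr(obj$rates, tibble::as_tibble)
  gating_scheme(states, rates)
}
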