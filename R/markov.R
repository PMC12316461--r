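#' Fit a first-order transition model to a behavior sequence
#'
#' Counts transitions between consecutive 1-s bins (self-transitions
#' included: dwelling in a behavior is a transition from the state to
#' itself). Row-normalizing the count matrix by the number of outgoing
#' transitions of each state gives the transition probability matrix;
#' expected counts under the zeroth-order (no time dependence) null are the
#' products of the observed margins, \eqn{E_{ij} = n_{i\cdot} n_{\cdot j}/N}.
#'
#' @param seq A [behavior_sequence()], or a character vector of labels.
#'
#' @return An object of class `transition_model` with components `states`,
#'   `O` (count matrix), `P` (row-stochastic probabilities; rows never
#'   visited are `NA`), `E` (expected counts), and `N` (total transitions).
#' @seealso [g_order_test()], [lrx_stationarity_test()], [tidy.transition_model()]
#' @export
#' @examples
#' m <- fit_transitions(behavior_sequence(strsplit("ABABABA", "")[[1]]))
#' m$O
#' m$P
fit_transitions <- function(seq) {
  if (is.character(seq)) seq <- behavior_sequence(seq)
  stopifnot(inherits(seq, "behavior_sequence"))
  labels <- seq$labels
  if (length(labels) < 2L) stop_sociodyn("need at least 2 bins to count transitions")
  states <- seq$alphabet
  from <- factor(labels[-length(labels)], levels = states)
  to <- factor(labels[-1L], levels = states)
  O <- unclass(table(from, to))
  dimnames(O) <- list(from = states, to = states)
  new_transition_model(O, subject = seq$subject, session = seq$session)
}

new_transition_model <- function(O, subject = NA_character_, session = NA_character_) {
  storage.mode(O) <- "double"
  N <- sum(O)
  row_tot <- rowSums(O)
  col_tot <- colSums(O)
  P <- sweep(O, 1L, row_tot, "/")
  P[row_tot == 0, ] <- NA_real_
  E <- outer(row_tot, col_tot) / N
  structure(
    list(states = rownames(O), O = O, P = P, E = E, N = N,
         subject = subject, session = session),
    class = "transition_model"
  )
}

#' @export
print.transition_model <- function(x, ...) {
  cat("<transition_model> ", length(x$states), " states, N = ", x$N,
      " transitions\n", sep = "")
  print(round(x$P, 3))
  invisible(x)
}

#' Tidy a transition model into a long tibble
#'
#' @param x A `transition_model`.
#' @param ... Unused.
#' @return A tibble with one row per (from, to) cell: observed count,
#'   transition probability, and expected count under the zeroth-order null.
#' @method tidy transition_model
#' @export
tidy.transition_model <- function(x, ...) {
  k <- length(x$states)
  tibble::tibble(
    from = rep(x$states, times = k),
    to = rep(x$states, each = k),
    n_obs = as.vector(x$O),
    prob = as.vector(x$P),
    n_expected = as.vector(x$E)
  )
}

#' @method glance transition_model
#' @export
glance.transition_model <- function(x, ...) {
  tibble::tibble(
    n_states = length(x$states),
    n_occupied = sum(rowSums(x$O) + colSums(x$O) > 0),
    n_transitions = x$N
  )
}

# States that actually occur in the sequence underlying a model: nonzero
# row or column margin of the count matrix.
occupied_states <- function(O) rowSums(O) + colSums(O) > 0

#' G-test of first-order transition structure
#'
#' Tests the fitted first-order transition model against the zeroth-order
#' (independence) null via the log-likelihood chi-squared statistic
#' \deqn{G = 2 \sum_j \sum_i O_{ij} \ln(O_{ij}/E_{ij}),}
#' where cells with \eqn{O_{ij} = 0} contribute zero and cells with
#' \eqn{E_{ij} = 0} (unoccupied margins) are excluded. The statistic is
#' referred to a chi-squared distribution with \eqn{(k-1)^2} degrees of
#' freedom, \eqn{k} the number of occupied states. A significant G rejects
#' random (memoryless) transitioning between states.
#'
#' @param model A `transition_model` from [fit_transitions()].
#'
#' @return A `markov_test` object with `statistic`, `df`, `p_value`, `kind`.
#' @export
#' @examples
#' g_order_test(fit_transitions(strsplit("ABABABA", "")[[1]]))
g_order_test <- function(model) {
  stopifnot(inherits(model, "transition_model"))
  if (model$N < 1) stop_sociodyn("no transitions observed")
  O <- model$O
  E <- model$E
  pos <- O > 0 & E > 0
  G <- 2 * sum(O[pos] * log(O[pos] / E[pos]))
  k <- sum(occupied_states(O))
  df <- (k - 1L)^2
  new_markov_test(G, df, kind = "order")
}

new_markov_test <- function(statistic, df, kind) {
  p <- if (df > 0) stats::pchisq(statistic, df = df, lower.tail = FALSE) else NA_real_
  structure(
    list(statistic = statistic, df = as.integer(df), p_value = p, kind = kind),
    class = "markov_test"
  )
}

#' @export
print.markov_test <- function(x, ...) {
  lab <- switch(x$kind, order = "G (first-order vs zeroth-order)",
                stationarity = "LRX (stationarity)")
  cat("<markov_test> ", lab, "\n  statistic = ", format(x$statistic),
      ", df = ", x$df, ", p = ", format.pval(x$p_value), "\n", sep = "")
  invisible(x)
}

#' @method tidy markov_test
#' @export
tidy.markov_test <- function(x, ...) {
  tibble::tibble(kind = x$kind, statistic = x$statistic, df = x$df,
                 p_value = x$p_value)
}

#' Likelihood-ratio test of transition stationarity
#'
#' Splits a behavior sequence into `n_segments` contiguous segments of
#' (near-)equal duration (the earliest segments absorb any remainder bins),
#' fits a transition model within each segment, and compares the per-segment
#' transition probabilities \eqn{\bar p_{ijs}} with the pooled probabilities
#' \eqn{p_{ij}} via
#' \deqn{LRX = 2 \sum_s \sum_j \sum_i f_{ijs} \ln(\bar p_{ijs}/p_{ij}),}
#' where \eqn{f_{ijs}} are per-segment transition counts and terms with
#' \eqn{f_{ijs} = 0} contribute zero. `p_ij` is pooled over the per-segment
#' counts, so LRX is exactly zero when every segment shares the same
#' transition counts and is nonnegative in general. Degrees of freedom are
#' \eqn{(S-1)\,k\,(k-1)} for \eqn{S} segments and \eqn{k} occupied states.
#'
#' @param seq A [behavior_sequence()] or character label vector.
#' @param n_segments Number of equal-duration segments (default 2).
#'
#' @return A `markov_test` with `kind = "stationarity"`, carrying the
#'   per-segment models in attribute `"segments"`.
#' @export
lrx_stationarity_test <- function(seq, n_segments = 2L) {
  if (is.character(seq)) seq <- behavior_sequence(seq)
  stopifnot(inherits(seq, "behavior_sequence"), n_segments >= 2L)
  labels <- seq$labels
  T_bins <- length(labels)
  sizes <- rep(T_bins %/% n_segments, n_segments)
  extra <- T_bins %% n_segments
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  if (any(sizes < 2L)) {
    stop_sociodyn("segment with fewer than 2 bins: no transitions to count")
  }
  bounds <- cumsum(c(0L, sizes))
  states <- seq$alphabet
  k_all <- length(states)
  f <- array(0, dim = c(k_all, k_all, n_segments),
             dimnames = list(from = states, to = states, segment = NULL))
  segments <- vector("list", n_segments)
  for (s in seq_len(n_segments)) {
    seg_labels <- labels[(bounds[s] + 1L):bounds[s + 1L]]
    from <- factor(seg_labels[-length(seg_labels)], levels = states)
    to <- factor(seg_labels[-1L], levels = states)
    O_s <- unclass(table(from, to))
    dimnames(O_s) <- list(from = states, to = states)
    f[, , s] <- O_s
    segments[[s]] <- new_transition_model(O_s, subject = seq$subject,
                                          session = seq$session)
  }
  pooled <- apply(f, c(1L, 2L), sum)
  pooled_row <- rowSums(pooled)
  p <- sweep(pooled, 1L, pooled_row, "/")      # pooled p_ij
  lrx <- 0
  for (s in seq_len(n_segments)) {
    f_s <- f[, , s]
    row_s <- rowSums(f_s)
    p_bar <- sweep(f_s, 1L, row_s, "/")
    pos <- f_s > 0                              # implies row_s > 0, pooled > 0
    lrx <- lrx + 2 * sum(f_s[pos] * log(p_bar[pos] / p[pos]))
  }
  k <- sum(occupied_states(pooled))
  df <- (n_segments - 1L) * k * (k - 1L)
  out <- new_markov_test(max(lrx, 0), df, kind = "stationarity")
  attr(out, "segments") <- segments
  out
}

#' Difference between two transition probability matrices
#'
#' Elementwise \eqn{P_{on} - P_{off}} for one individual's pair of sessions
#' (e.g. photostimulation ON minus OFF). Rows for states never visited in
#' either session are `NA` and should be excluded from group means.
#'
#' @param model_on,model_off `transition_model`s over the same ordered
#'   state set.
#'
#' @return Numeric matrix of probability differences.
#' @export
transition_delta <- function(model_on, model_off) {
  stopifnot(inherits(model_on, "transition_model"),
            inherits(model_off, "transition_model"))
  if (!identical(model_on$states, model_off$states)) {
    stop_sociodyn("state order differs between the two models")
  }
  model_on$P - model_off$P
}

#' Within- and across-state transition probabilities of a two-state model
#'
#' For the social/nonsocial two-state model, within-state transition
#' probabilities are the diagonal of P (social->social, nonsocial->nonsocial)
#' and across-state probabilities the off-diagonal; each row's pair sums
#' to 1.
#'
#' @param model A two-state `transition_model`.
#'
#' @return A tibble with columns `state`, `within`, `across`.
#' @export
state_transition_summary <- function(model) {
  stopifnot(inherits(model, "transition_model"))
  if (length(model$states) != 2L) {
    stop_sociodyn("state_transition_summary needs a two-state model, got ",
                  length(model$states), " states")
  }
  tibble::tibble(
    state = model$states,
    within = unname(diag(model$P)),
    across = unname(model$P[cbind(1:2, 2:1)])
  )
}

#' Heatmap of a transition probability matrix
#'
#' @param object A `transition_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot transition_model
#' @export
autoplot.transition_model <- function(object, ...) {
  dat <- tidy.transition_model(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$to, y = .data$from,
                                    fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$prob)),
                       color = "white", na.rm = TRUE) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey85") +
    ggplot2::scale_y_discrete(limits = rev(object$states)) +
    ggplot2::labs(x = "to state", y = "from state", fill = "P(i → j)") +
    ggplot2::theme_minimal()
}
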