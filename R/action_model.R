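#' Next action generator
#'
#' A small feedforward network (input = flattened MSOM activity pattern,
#' default 100; one logistic hidden layer of 100; logistic output per action)
#' that learns online which actions are feasible in the current map context.
#' Outputs are independent per-action feasibility scores in (0, 1), not a
#' joint distribution; action selection renormalizes over the candidate set.
#' Weights start small and the output biases at zero, so a fresh net scores
#' every action near 0.5 and selection is uniform.
#'
#' Training is online stochastic gradient descent on the binary
#' cross-entropy of the attempted action's score against the attempt outcome
#' (1 = succeeded, 0 = infeasible); only the attempted action's output error
#' is propagated.
#'
#' @param n_in input width (MSOM units), default 100.
#' @param n_hidden hidden width, default 100.
#' @param n_actions output width, default 10.
#' @param lr online learning rate.
#' @param seed weight initialization seed.
#' @return an object of class `feasibility_net`.
#' @export
feasibility_net <- function(n_in = 100, n_hidden = 100, n_actions = 10,
                            lr = 0.01, seed = 1) {
  with_preserved_rng(seed, {
    structure(list(
      W1 = matrix(stats::runif(n_hidden * n_in, -0.1, 0.1), n_hidden, n_in),
      b1 = numeric(n_hidden),
      W2 = matrix(stats::runif(n_actions * n_hidden, -0.01, 0.01), n_actions, n_hidden),
      b2 = numeric(n_actions),
      lr = lr, n_in = n_in, n_hidden = n_hidden, n_actions = n_actions
    ), class = "feasibility_net")
  })
}

#' @export
print.feasibility_net <- function(x, ...) {
  cat(sprintf("<feasibility_net %dx%dx%d, lr=%g>\n",
              x$n_in, x$n_hidden, x$n_actions, x$lr))
  invisible(x)
}

net_forward <- function(net, pattern) {
  h <- stats::plogis(as.vector(net$W1 %*% pattern) + net$b1)
  s <- stats::plogis(as.vector(net$W2 %*% h) + net$b2)
  list(h = h, s = s)
}

#' Per-action feasibility scores
#'
#' @param net a [feasibility_net()].
#' @param pattern MSOM activity pattern (width `n_in`).
#' @return numeric vector of `n_actions` scores in (0, 1).
#' @export
predict_feasibility <- function(net, pattern) {
  if (length(pattern) != net$n_in) stop("pattern width mismatch", call. = FALSE)
  net_forward(net, pattern)$s
}

#' Stochastically select an action from feasibility scores
#'
#' Samples proportionally to the scores restricted to the non-excluded
#' actions.  Within one time step, actions found infeasible are excluded
#' without replacement and selection repeats until one succeeds.
#'
#' @param scores per-action scores.
#' @param excluded integer indices of actions already found infeasible.
#' @return selected action index.
#' @export
select_action <- function(scores, excluded = integer(0)) {
  avail <- setdiff(seq_along(scores), excluded)
  if (length(avail) == 0) {
    stop("exploration deadlock: all actions excluded", call. = FALSE)
  }
  if (length(avail) == 1) return(avail)
  avail[sample.int(length(avail), 1, prob = scores[avail])]
}

#' One online update of the generator
#'
#' A single gradient step on the binary cross-entropy of the attempted
#' action's score against the attempt outcome; other outputs receive no
#' error signal.
#'
#' @param net a [feasibility_net()].
#' @param pattern the MSOM activity pattern the action was selected from.
#' @param action attempted action index.
#' @param succeeded logical outcome of the attempt.
#' @return the updated net.
#' @export
feasibility_update <- function(net, pattern, action, succeeded) {
  fw <- net_forward(net, pattern)
  err <- fw$s[action] - as.numeric(succeeded)   # d BCE / d preactivation
  dh <- net$W2[action, ] * err * fw$h * (1 - fw$h)
  net$W2[action, ] <- net$W2[action, ] - net$lr * err * fw$h
  net$b2[action] <- net$b2[action] - net$lr * err
  net$W1 <- net$W1 - net$lr * outer(dh, pattern)
  net$b1 <- net$b1 - net$lr * dh
  net
}
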