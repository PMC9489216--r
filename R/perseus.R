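#' Alpha-vector (hyperplane) set
#'
#' The value function over beliefs is represented as the upper envelope of a
#' finite set of hyperplanes, `V(b) = max_alpha alpha . b`. Each vector
#' records the action that generated it during a backup.
#'
#' @param coeffs numeric matrix, one column per alpha vector (`n_states`
#'   rows), or a single numeric vector.
#' @param actions character vector of generating actions (recycled if
#'   length 1).
#' @return An object of class `alpha_set`.
#' @export
alpha_set <- function(coeffs, actions = "initial") {
  A <- as.matrix(coeffs)
  if (anyNA(A) || any(!is.finite(A))) {
    stop("alpha vectors must have finite entries", call. = FALSE)
  }
  actions <- rep_len(actions, ncol(A))
  structure(list(A = A, actions = actions), class = "alpha_set")
}

#' @export
print.alpha_set <- function(x, ...) {
  cat(sprintf("<alpha_set> %d vectors over %d states\n", ncol(x$A), nrow(x$A)))
  invisible(x)
}

#' @export
length.alpha_set <- function(x) ncol(x$A)

#' Initial alpha set
#'
#' The single all-zero hyperplane: an admissible lower bound on the value
#' function, since all rewards are nonnegative.
#'
#' @param spec a [build_spec()] object.
#' @return An `alpha_set` with one zero vector.
#' @export
init_alpha_set <- function(spec) {
  alpha_set(matrix(0, spec$n_states, 1), "initial")
}

#' Value of a belief under an alpha set
#'
#' `V(b) = max_{alpha in H} alpha . b`; ties broken by the lowest vector
#' index.
#'
#' @param belief belief vector.
#' @param H an [alpha_set()].
#' @return numeric scalar.
#' @export
value_of <- function(belief, H) {
  stopifnot(inherits(H, "alpha_set"))
  if (ncol(H$A) == 0L) stop("empty alpha set", call. = FALSE)
  max(crossprod(H$A, belief))
}

#' Precompute the alpha_{a,o} table
#'
#' \eqn{\alpha_{a,o}(s) = \sum_{s'} \alpha(s') P(o | s', a) T(s' | s, a)}.
#' With deterministic transitions this reduces to
#' \eqn{\alpha(s'_a(s)) P(o | s'_a(s), a)} with \eqn{s'_a(s)} the successor of
#' `s`. The table must be recomputed whenever `H` changes; [backup()] uses an
#' algebraically identical on-the-fly formulation through the predicted
#' belief, which avoids materialising the table.
#'
#' @param H an [alpha_set()].
#' @param spec a [build_spec()] object.
#' @return nested list `table[[action]][[observation]]`, each element an
#'   `n_states` x `length(H)` matrix.
#' @export
precompute_alpha_ao <- function(H, spec) {
  stopifnot(inherits(H, "alpha_set"), inherits(spec, "pomdp_spec"))
  out <- lapply(spec$actions, function(a) {
    pa <- spec$perm[[a]]
    det_p <- action_det(spec, a)[pa]
    found_p <- as.numeric(pa == spec$origin_index)
    Ap <- H$A[pa, , drop = FALSE]
    list(
      no_detection = Ap * ((1 - det_p) * (1 - found_p)),
      detection = Ap * det_p,
      source_found = Ap * found_p
    )
  })
  names(out) <- spec$actions
  out
}

# Shared per-action quantities for backup()/greedy_action(): the predicted
# belief, Gamma_a, and the envelope scores max_alpha b . alpha_{a,o} for the
# two non-terminal observations (b . alpha_{a,o} = (b_pred * P_o) . alpha).
action_scores <- function(spec, belief, H, action, likelihood_floor = 0) {
  bp <- predicted_belief(spec, belief, action)
  det <- action_det(spec, action, likelihood_floor)
  w_det <- bp * det
  w_no <- bp * (1 - det)
  w_no[spec$origin_index] <- 0
  list(
    bp = bp,
    gamma_a = bp[spec$origin_index],
    s_no = crossprod(H$A, w_no),
    s_det = crossprod(H$A, w_det),
    p_no = sum(w_no),
    p_det = sum(w_det)
  )
}

# All-action version: stacks the 2 * n_actions weighted predicted beliefs
# into one matrix so the alpha-set scores come from a single BLAS-3 product.
# Columns alternate (no_detection, detection) per action.
all_action_scores <- function(spec, belief, A, likelihood_floor = 0) {
  na <- spec$n_actions
  n <- spec$n_states
  W <- matrix(0, n, 2L * na)
  gam <- numeric(na)
  bps <- vector("list", na)
  for (i in seq_len(na)) {
    a <- spec$actions[i]
    bp <- predicted_belief(spec, belief, a)
    det <- action_det(spec, a, likelihood_floor)
    w_no <- bp * (1 - det)
    w_no[spec$origin_index] <- 0
    W[, 2L * i - 1L] <- w_no
    W[, 2L * i] <- bp * det
    gam[i] <- bp[spec$origin_index]
    bps[[i]] <- bp
  }
  list(S = crossprod(A, W), W = W, gamma_a = gam, bps = bps)
}

#' Point-based backup at a belief
#'
#' Produces the best new hyperplane at `belief`:
#' \eqn{\alpha_a^b = r_a + \gamma \sum_{o} \arg\max_{\alpha_{a,o}} b \cdot \alpha_{a,o}}
#' maximised over actions, where \eqn{r_a(s) = 1[s'_a(s) = \mathrm{source}]}
#' is the immediate probability of stepping onto the source and the
#' `source_found` branch carries no continuation (the search ends). Adding
#' the result to `H` never decreases `value_of(belief, H)`.
#'
#' @param H an [alpha_set()].
#' @param belief belief vector.
#' @param spec a [build_spec()] object.
#' @return numeric vector of coefficients with attribute `action` (the
#'   generating action).
#' @export
backup <- function(H, belief, spec) {
  stopifnot(inherits(H, "alpha_set"))
  res <- backup_core(H$A, belief, spec)
  structure(res$alpha, action = res$action)
}

# core backup against a coefficient matrix (possibly with -1e300 filler
# columns, which never win the argmax because real coefficients are >= 0)
backup_core <- function(A, belief, spec) {
  sc <- all_action_scores(spec, belief, A)
  best_val <- -Inf
  best_alpha <- NULL
  best_action <- NA_character_
  for (i in seq_len(spec$n_actions)) {
    a <- spec$actions[i]
    j_no <- which.max(sc$S[, 2L * i - 1L])
    j_det <- which.max(sc$S[, 2L * i])
    pa <- spec$perm[[a]]
    det_p <- action_det(spec, a)[pa]
    found_p <- pa == spec$origin_index
    alpha <- as.numeric(found_p) + spec$gamma * (
      A[pa, j_no] * ((1 - det_p) * !found_p) +
      A[pa, j_det] * det_p
    )
    val <- sum(belief * alpha)
    if (val > best_val + 1e-12) {
      best_val <- val
      best_alpha <- alpha
      best_action <- a
    }
  }
  list(alpha = best_alpha, action = best_action, value = best_val)
}

add_alpha <- function(H, alpha) {
  alpha_set(cbind(H$A, as.numeric(alpha)),
            c(H$actions, attr(alpha, "action") %||% NA_character_))
}

#' Prune dominated hyperplanes
#'
#' Removes exactly the componentwise-dominated alpha vectors (every entry
#' `<=` another vector's within `tol`, with strict inequality somewhere;
#' exact duplicates keep their first occurrence). The upper envelope --
#' `value_of()` at every belief -- is unchanged.
#'
#' @param H an [alpha_set()].
#' @param tol dominance tolerance.
#' @return A pruned [alpha_set()].
#' @export
prune <- function(H, tol = 1e-12) {
  stopifnot(inherits(H, "alpha_set"))
  keep <- keep_undominated(H$A, tol)
  if (!any(keep)) keep[1] <- TRUE
  alpha_set(H$A[, keep, drop = FALSE], H$actions[keep])
}

#' Train a policy by randomized point-based value iteration
#'
#' Grows the alpha set by simulated random exploration: each training episode
#' starts from the prior belief; at every step an action is drawn uniformly,
#' an observation is sampled from the predictive distribution `P(o | b, a)`,
#' the belief is updated by Bayes' rule, and the new belief is backed up into
#' `H`. Episodes end at `points_per_episode` beliefs or as soon as the
#' simulated observation is `source_found`. Dominated vectors are pruned at
#' the end of every episode. Fully reproducible for a fixed `seed`.
#'
#' @param spec a [build_spec()] object.
#' @param prior belief vector used to start every episode.
#' @param n_episodes number of training episodes (0 returns `H` unchanged).
#' @param points_per_episode belief points collected per episode.
#' @param seed integer seed for the exploration stream.
#' @param H optional starting [alpha_set()]; defaults to [init_alpha_set()].
#' @param prune_every prune cadence, in episodes.
#' @return The trained [alpha_set()], with attribute `history`: a tibble
#'   (`episode`, `n_alpha`) tracking the stored-hyperplane count.
#' @export
train <- function(spec, prior, n_episodes, points_per_episode, seed = 1,
                  H = NULL, prune_every = 1) {
  stopifnot(inherits(spec, "pomdp_spec"))
  check_belief(spec, prior)
  if (is.null(H)) H <- init_alpha_set(spec)
  history <- vector("list", n_episodes)
  n <- spec$n_states
  # amortized storage: filler columns sit at -1e300 and never win an argmax
  m <- ncol(H$A)
  cap <- max(64L, 2L * m)
  A <- matrix(-1e300, n, cap)
  A[, seq_len(m)] <- H$A
  acts <- c(H$actions, rep(NA_character_, cap - m))
  if (n_episodes >= 1) {
    withr::with_seed(seed, {
      for (ep in seq_len(n_episodes)) {
        b <- prior
        for (pt in seq_len(points_per_episode)) {
          a <- sample(spec$actions, 1L)
          p_o <- obs_predictive(spec, b, a)
          o <- sample(spec$observations, 1L, prob = p_o)
          b <- belief_update(spec, b, a, o)
          res <- backup_core(A, b, spec)
          m <- m + 1L
          if (m > cap) {
            cap <- 2L * cap
            A2 <- matrix(-1e300, n, cap)
            A2[, seq_len(m - 1L)] <- A[, seq_len(m - 1L)]
            A <- A2
            acts <- c(acts, rep(NA_character_, cap - length(acts)))
          }
          A[, m] <- res$alpha
          acts[m] <- res$action
          if (o == "source_found") break
        }
        if (ep %% prune_every == 0L) {
          Hp <- prune(alpha_set(A[, seq_len(m), drop = FALSE],
                                acts[seq_len(m)]))
          m <- ncol(Hp$A)
          A[] <- -1e300
          A[, seq_len(m)] <- Hp$A
          acts[] <- NA_character_
          acts[seq_len(m)] <- Hp$actions
        }
        history[[ep]] <- tibble::tibble(episode = ep, n_alpha = m)
      }
    })
  }
  H <- alpha_set(A[, seq_len(m), drop = FALSE], acts[seq_len(m)])
  attr(H, "history") <- dplyr::bind_rows(history)
  H
}

#' Greedy action at a belief
#'
#' One-step lookahead under the current value approximation:
#' \eqn{\arg\max_a \{\Gamma_a + \gamma \sum_{o \ne \mathrm{found}} P(o|b,a)\,
#' V(b^{a,o})\}} with ties broken by action order.
#'
#' @param belief belief vector.
#' @param H an [alpha_set()].
#' @param spec a [build_spec()] object.
#' @param likelihood_floor passed to the lookahead's observation model.
#' @return action name (character scalar).
#' @export
greedy_action <- function(belief, H, spec, likelihood_floor = 0) {
  stopifnot(inherits(H, "alpha_set"))
  sc <- all_action_scores(spec, belief, H$A, likelihood_floor)
  # P(o|b,a) * value_of(b^{a,o}) = max_alpha (b_pred * P_o) . alpha
  smax <- apply(sc$S, 2, max)
  q <- sc$gamma_a + spec$gamma * (smax[seq(1, by = 2, length.out = spec$n_actions)] +
                                    smax[seq(2, by = 2, length.out = spec$n_actions)])
  spec$actions[which(q >= max(q) - 1e-12)[1]]
}
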