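# Mean hitting times, harmonic potentials and conditional mean hitting
# times of the random walk, by direct sparse solves of their boundary-value
# systems; plus simulation and enumeration oracles used in testing.

as_transition <- function(P) {
  if (!inherits(P, "Matrix")) P <- Matrix::Matrix(P, sparse = TRUE)
  P <- methods::as(P, "CsparseMatrix")
  if (is.null(rownames(P))) dimnames(P) <- list(as.character(seq_len(nrow(P))),
                                                as.character(seq_len(nrow(P))))
  rs <- Matrix::rowSums(P)
  if (max(abs(rs - 1)) > 1e-8) stop("P is not row-stochastic")
  P
}

resolve_set <- function(P, nodes, what) {
  if (is.numeric(nodes)) nodes <- rownames(P)[nodes]
  ok <- nodes %in% rownames(P)
  if (!all(ok)) stop("unknown ", what, " node(s): ",
                     paste(nodes[!ok], collapse = ", "))
  unique(nodes)
}

# Nodes from which the boundary set is reachable along directed edges of P
# (fixed point of one-step reachability; cheap sparse mat-vec iteration).
reaches <- function(P, boundary) {
  n <- nrow(P)
  reach <- logical(n)
  names(reach) <- rownames(P)
  reach[boundary] <- TRUE
  repeat {
    hits <- as.numeric(P %*% reach) > 0
    new <- hits & !reach
    if (!any(new)) break
    reach[new] <- TRUE
  }
  reach
}

#' Mean hitting time of a node set
#'
#' Expected number of steps for the random walk started at each node to
#' first visit the target set `B`; the minimal nonnegative solution of the
#' linear system with `x = 0` on `B` and `x(a) = 1 + sum_v P(a,v) x(v)`
#' elsewhere, solved as one sparse system over the non-target rows. Raw
#' values are also returned scaled by the largest finite value, so the
#' scaled closeness lies in \[0, 1\].
#'
#' @param P row-stochastic transition matrix with node names.
#' @param target character (or index) vector: the target set `B`.
#' @return A `cipher_hits` object: named `raw` (0 on `B`, `Inf` where `B`
#'   is unreachable), `scaled`, the scaling denominator and the sets used.
#' @export
mean_hitting_time <- function(P, target) {
  P <- as_transition(P)
  B <- resolve_set(P, target, "target")
  if (length(B) == 0) stop("target set is empty")
  ids <- rownames(P)
  raw <- stats::setNames(rep(Inf, nrow(P)), ids)
  raw[B] <- 0
  reach <- reaches(P, B)
  Q <- setdiff(ids[reach], B)
  if (length(Q) > 0) {
    A <- Matrix::Diagonal(length(Q)) - P[Q, Q, drop = FALSE]
    raw[Q] <- as.numeric(Matrix::solve(A, rep(1, length(Q))))
  }
  new_hits(raw, target = B, avoid = character(0))
}

new_hits <- function(raw, target, avoid, undefined = NULL) {
  sc <- scale_hitting(raw)
  if (!is.null(undefined)) {
    raw[undefined] <- NA_real_
    sc$scaled[undefined] <- NA_real_
  }
  structure(list(raw = raw, scaled = sc$scaled, denominator = sc$denominator,
                 target = target, avoid = avoid),
            class = "cipher_hits")
}

#' Scale hitting times to \[0, 1\]
#'
#' Divides by the maximum finite value over all nodes, so the farthest node
#' maps to exactly 1 and targets stay 0. Infinite raw values (unreachable
#' targets) scale to `NA`, carrying an explicit undefined marker.
#'
#' @param raw named numeric vector of raw expectations.
#' @return List with `scaled` and `denominator`.
#' @export
scale_hitting <- function(raw) {
  fin <- is.finite(raw)
  m <- if (any(fin)) max(raw[fin]) else NA_real_
  if (!is.na(m) && m == 0) {
    warning("all finite hitting times are zero; scaled values set to 0")
    scaled <- ifelse(fin, 0, NA_real_)
    names(scaled) <- names(raw)
    return(list(scaled = scaled, denominator = 0))
  }
  scaled <- ifelse(fin, raw / m, NA_real_)
  scaled[fin & raw == m] <- 1  # exact, independent of rounding
  names(scaled) <- names(raw)
  list(scaled = scaled, denominator = m)
}

#' Harmonic potential: probability of hitting one set before another
#'
#' `h(v) = P_v(tau_target < tau_avoid)`: 1 on the target set, 0 on the
#' avoid set, and the `P`-weighted average of its neighbours elsewhere
#' (minimal nonnegative solution of the boundary-value system).
#'
#' @inheritParams mean_hitting_time
#' @param avoid character (or index) vector, disjoint from `target`.
#' @return A `cipher_potential`: named `values` in \[0, 1\], plus the sets.
#' @export
harmonic_potential <- function(P, target, avoid) {
  P <- as_transition(P)
  B <- resolve_set(P, target, "target")
  A <- resolve_set(P, avoid, "avoid")
  if (length(B) == 0 || length(A) == 0) stop("target and avoid must be nonempty")
  if (length(intersect(B, A)) > 0)
    stop("target and avoid sets overlap: ",
         paste(intersect(B, A), collapse = ", "))
  ids <- rownames(P)
  h <- stats::setNames(rep(0, nrow(P)), ids)
  h[B] <- 1
  boundary <- c(B, A)
  reach <- reaches(P, boundary)
  I <- setdiff(ids[reach], boundary)
  if (length(I) > 0) {
    M <- Matrix::Diagonal(length(I)) - P[I, I, drop = FALSE]
    b <- Matrix::rowSums(P[I, B, drop = FALSE])
    h[I] <- pmin(pmax(as.numeric(Matrix::solve(M, b)), 0), 1)
  }
  structure(list(values = h, target = B, avoid = A),
            class = "cipher_potential")
}

#' Conditional mean hitting time
#'
#' Expected time to reach the target set `B`, conditioned on reaching `B`
#' before the avoid set `A`. Computed through the harmonic potential
#' `h = P(tau_B < tau_A)` and the Doob h-transformed system: with
#' `y = h * x`, `y` solves `(I - P_II) y_I = h_I` over the interior, and
#' `x = y / h` wherever `h > 0`. Starts with `h = 0` (the walk cannot reach
#' `B` before `A`) are undefined and reported as `NA`; they are excluded
#' from the scaling maximum.
#'
#' @inheritParams harmonic_potential
#' @return A `cipher_hits` object with an additional `potential` element.
#' @export
conditional_mht <- function(P, target, avoid) {
  P <- as_transition(P)
  B <- resolve_set(P, target, "target")
  A <- resolve_set(P, avoid, "avoid")
  pot <- harmonic_potential(P, B, A)
  h <- pot$values
  ids <- rownames(P)
  reach <- reaches(P, c(B, A))
  I <- setdiff(ids[reach], c(B, A))  # h = 0 (undefined) off this set
  y <- stats::setNames(rep(0, nrow(P)), ids)
  if (length(I) > 0) {
    M <- Matrix::Diagonal(length(I)) - P[I, I, drop = FALSE]
    y[I] <- as.numeric(Matrix::solve(M, h[I]))
  }
  raw <- stats::setNames(rep(NA_real_, nrow(P)), ids)
  raw[B] <- 0
  pos <- I[h[I] > 0]
  raw[pos] <- y[pos] / h[pos]
  undefined <- ids[is.na(raw)]
  # scale over defined entries only
  sc_in <- raw
  sc_in[is.na(sc_in)] <- Inf
  out <- new_hits(sc_in, target = B, avoid = A, undefined = undefined)
  out$potential <- pot
  out
}

#' @export
print.cipher_hits <- function(x, ...) {
  kind <- if (length(x$avoid) > 0) "Conditional mean hitting time" else
    "Mean hitting time"
  cat(kind, "to {", paste(x$target, collapse = ", "), "}",
      if (length(x$avoid) > 0)
        paste0("avoiding {", paste(x$avoid, collapse = ", "), "}"), "\n")
  cat(sprintf("  %d nodes, scaling denominator %.6g, %d undefined\n",
              length(x$raw), x$denominator, sum(is.na(x$scaled))))
  invisible(x)
}

#' Monte-Carlo hitting-time oracle
#'
#' Estimates the (conditional) mean hitting time by simulating random
#' walks; the conditional case uses rejection sampling (walks that touch
#' the avoid set first are discarded). Used as an independent check of the
#' linear-system solvers.
#'
#' @inheritParams harmonic_potential
#' @param avoid optional avoid set (`NULL` for the unconditional time).
#' @param start single start node.
#' @param n_walks number of simulated walks.
#' @param max_steps walks still running after this many steps are censored.
#' @param seed integer seed for the simulation.
#' @return List with `estimate`, `stderr`, `n_accepted`, `n_censored`.
#' @export
mc_hitting_oracle <- function(P, target, avoid = NULL, start,
                              n_walks = 10000, max_steps = 10000, seed = 1) {
  stopifnot(n_walks >= 1)
  P <- as_transition(P)
  B <- resolve_set(P, target, "target")
  A <- if (is.null(avoid)) character(0) else resolve_set(P, avoid, "avoid")
  s0 <- resolve_set(P, start, "start")
  if (length(s0) != 1) stop("start must be a single node")
  if (s0 %in% B)
    return(list(estimate = 0, stderr = 0, n_accepted = n_walks,
                n_censored = 0L))
  ids <- rownames(P)
  Pd <- as.matrix(P)
  set.seed(seed)
  state <- rep(match(s0, ids), n_walks)
  steps <- integer(n_walks)
  status <- rep("running", n_walks)  # running / hit / rejected
  Bi <- match(B, ids); Ai <- match(A, ids)
  for (k in seq_len(max_steps)) {
    act <- which(status == "running")
    if (length(act) == 0) break
    cur <- state[act]
    nxt <- integer(length(act))
    for (s in unique(cur)) {
      sel <- cur == s
      nxt[sel] <- sample.int(length(ids), sum(sel), replace = TRUE,
                             prob = Pd[s, ])
    }
    state[act] <- nxt
    steps[act] <- k
    status[act[nxt %in% Bi]] <- "hit"
    status[act[nxt %in% Ai & !(nxt %in% Bi)]] <- "rejected"
  }
  n_censored <- sum(status == "running")
  hit <- status == "hit"
  if (!any(hit))
    stop("no accepted walks; increase n_walks or max_steps")
  t <- steps[hit]
  list(estimate = mean(t),
       stderr = stats::sd(t) / sqrt(length(t)),
       n_accepted = sum(hit),
       n_censored = n_censored)
}

#' Path-space enumeration oracle for (conditional) mean hitting times
#'
#' Propagates the probability mass of walks that have not yet touched the
#' boundary, accumulating the probability of first entering the target at
#' each step; truncation stops when the surviving interior mass falls below
#' `tol`. Independent of the linear-system route (uses only repeated
#' sparse matrix-vector products), so it serves as an oracle on small
#' graphs.
#'
#' @inheritParams mc_hitting_oracle
#' @param tol surviving-mass truncation threshold.
#' @return List with `estimate` (conditional expectation), `mass`
#'   (probability of hitting target before avoid) and `steps_used`.
#' @export
enumerate_hitting_oracle <- function(P, target, avoid = NULL, start,
                                     tol = 1e-14, max_steps = 100000) {
  P <- as_transition(P)
  B <- resolve_set(P, target, "target")
  A <- if (is.null(avoid)) character(0) else resolve_set(P, avoid, "avoid")
  s0 <- resolve_set(P, start, "start")
  ids <- rownames(P)
  if (s0 %in% B) return(list(estimate = 0, mass = 1, steps_used = 0L))
  if (s0 %in% A) return(list(estimate = NA_real_, mass = 0, steps_used = 0L))
  I <- setdiff(ids, c(B, A))
  PI <- P[I, I, drop = FALSE]
  PB <- P[I, B, drop = FALSE]
  m <- stats::setNames(numeric(length(I)), I)
  m[s0] <- 1
  total_p <- 0; total_kp <- 0; k <- 0L
  while (sum(m) > tol && k < max_steps) {
    k <- k + 1L
    pk <- sum(as.numeric(PB %*% rep(1, length(B))) * m)  # mass entering B now
    total_p <- total_p + pk
    total_kp <- total_kp + k * pk
    m <- as.numeric(m %*% PI)
    names(m) <- I
  }
  if (total_p == 0) return(list(estimate = NA_real_, mass = 0, steps_used = k))
  list(estimate = total_kp / total_p, mass = total_p, steps_used = k)
}
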