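#' Mean first-passage time between state sets
#'
#' Solves the linear system `m_i = tau + sum_j T_ij m_j` with `m = 0` on the
#' target set; the reported value is the stationary-weighted average of `m`
#' over the source states, in physical time (`lag * dt` per step).
#'
#' @param model a `MarkovModel`.
#' @param source,target disjoint, non-empty state index sets (indices into
#'   the model's active states).
#' @return mean first-passage time (same time unit as `dt`, ns by
#'   convention).
#' @export
mfpt <- function(model, source, target) {
  n <- model$n_states
  source <- as.integer(source); target <- as.integer(target)
  if (!length(source) || !length(target)) stop("sets must be non-empty")
  if (length(intersect(source, target))) stop("sets must be disjoint")
  g <- igraph::graph_from_adjacency_matrix(model$T > 0, mode = "directed")
  reach <- igraph::distances(g, v = source, to = target, mode = "out")
  if (any(!is.finite(apply(reach, 1, min))))
    stop("target is unreachable from the source set")
  m <- mfpt_vector(model, target)
  w <- model$pi[source] / sum(model$pi[source])
  sum(w * m[source])
}

# full MFPT-to-target vector (0 on target)
mfpt_vector <- function(model, target) {
  n <- model$n_states
  step <- model$lag * model$dt
  C <- setdiff(seq_len(n), target)
  m <- numeric(n)
  A <- diag(length(C)) - model$T[C, C, drop = FALSE]
  m[C] <- solve(A, rep(step, length(C)))
  m
}

#' Matrix of pairwise mean first-passage times
#'
#' Entry `(i, j)` is the MFPT from state `i` to state `j`; diagonal 0.
#'
#' @param model a `MarkovModel`.
#' @return square matrix in physical time units.
#' @export
mfpt_matrix <- function(model) {
  n <- model$n_states
  M <- matrix(0, n, n)
  for (j in seq_len(n)) M[-j, j] <- mfpt_vector(model, j)[-j]
  M
}

#' Transition path theory between two state sets
#'
#' Computes the forward committor (probability of reaching the sink set `B`
#' before the source set `A`), the backward committor (from the
#' time-reversed chain; `1 - q_plus` for reversible models), the gross
#' reactive flux `F_ij = pi_i q-_i T_ij q+_j`, the net flux
#' `f_ij = max(0, F_ij - F_ji)`, the total A->B flux, and a pathway
#' decomposition of the net-flux graph by iterative widest-path (maximum
#' bottleneck) extraction.
#'
#' @param model a `MarkovModel` (microstate or coarse-grained; any model
#'   whose `T` and `pi` are set).
#' @param A,B disjoint, non-empty source and sink state sets.
#' @param path_tol stop extracting pathways when the remaining flux falls
#'   below `path_tol * total_flux`.
#' @param max_paths safety cap on the number of extracted pathways.
#' @return an object of class `TPTResult`: list with `A`, `B`, `q_plus`,
#'   `q_minus`, `gross_flux`, `net_flux`, `total_flux`, `pathways` (list of
#'   `list(states, flux, fraction)`), `mfpt` (pairwise MFPT matrix).
#' @export
tpt <- function(model, A, B, path_tol = 1e-8, max_paths = 1000L) {
  A <- sort(as.integer(A)); B <- sort(as.integer(B))
  if (!length(A) || !length(B)) stop("A and B must be non-empty")
  if (length(intersect(A, B))) stop("A and B must be disjoint")
  n <- model$n_states
  T <- model$T; pi <- model$pi
  q_plus <- committor(T, A, B)
  q_minus <- if (isTRUE(model$reversible)) 1 - q_plus else {
    Trev <- t(T) * outer(1 / pi, pi)
    1 - committor(Trev, A, B)   # backward committor: reach A before B
  }
  F <- pi * q_minus * T * rep(q_plus, each = n)
  diag(F) <- 0
  f_net <- pmax(F - t(F), 0)
  total <- sum(f_net[A, setdiff(seq_len(n), A), drop = FALSE])
  paths <- decompose_pathways(f_net, A, B, total, path_tol, max_paths)
  structure(list(A = A, B = B, q_plus = q_plus, q_minus = q_minus,
                 gross_flux = F, net_flux = f_net, total_flux = total,
                 pathways = paths, mfpt = mfpt_matrix(model)),
            class = "TPTResult")
}

#' Forward committor of a Markov chain
#'
#' `q = 0` on `A`, `1` on `B`; on intermediate states it solves
#' `q_i = sum_j T_ij q_j`.
#'
#' @param T row-stochastic transition matrix.
#' @param A,B disjoint state sets.
#' @return numeric committor vector in `[0, 1]`.
#' @export
committor <- function(T, A, B) {
  n <- nrow(T)
  q <- numeric(n)
  q[B] <- 1
  C <- setdiff(seq_len(n), c(A, B))
  if (length(C)) {
    M <- diag(length(C)) - T[C, C, drop = FALSE]
    rhs <- rowSums(T[C, B, drop = FALSE])
    q[C] <- solve(M, rhs)
  }
  pmin(pmax(q, 0), 1)
}

# iterative widest-path decomposition of the net flux graph
decompose_pathways <- function(f_net, A, B, total, path_tol, max_paths) {
  paths <- list()
  if (total <= 0) return(paths)
  remaining <- f_net
  extracted <- 0
  while (extracted < total * (1 - path_tol) &&
         length(paths) < max_paths) {
    wp <- widest_path(remaining, A, B)
    if (is.null(wp) || wp$bottleneck <= path_tol * total) break
    for (k in seq_len(length(wp$path) - 1L)) {
      i <- wp$path[k]; j <- wp$path[k + 1L]
      remaining[i, j] <- remaining[i, j] - wp$bottleneck
    }
    paths[[length(paths) + 1L]] <-
      list(states = wp$path, flux = wp$bottleneck,
           fraction = wp$bottleneck / total)
    extracted <- extracted + wp$bottleneck
  }
  paths
}

# Dijkstra-style maximum-bottleneck path from set A to set B
widest_path <- function(cap, A, B) {
  n <- nrow(cap)
  width <- rep(-Inf, n); width[A] <- Inf
  pred <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  repeat {
    u <- which(!visited & width > -Inf)
    if (!length(u)) break
    u <- u[which.max(width[u])]
    visited[u] <- TRUE
    if (u %in% B) break
    for (v in which(cap[u, ] > 0)) {
      w <- min(width[u], cap[u, v])
      if (w > width[v]) {
        width[v] <- w
        pred[v] <- u
      }
    }
  }
  ends <- B[is.finite(width[B]) & width[B] > 0]
  if (!length(ends)) return(NULL)
  end <- ends[which.max(width[ends])]
  path <- end
  while (!is.na(pred[path[1]])) path <- c(pred[path[1]], path)
  list(path = path, bottleneck = width[end])
}
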