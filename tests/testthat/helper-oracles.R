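# Independent oracles used to cross-check package implementations.
# These deliberately share no code with the package internals.

# Quaternion-based optimal superposition RMSD (Horn 1987): independent of
# the package's SVD route.
quaternion_rmsd <- function(mobile, ref) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(ref, 2, colMeans(ref))
  M <- crossprod(A, B)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)
  sqrt(max(0, msd))
}

# Brute-force greedy GROMOS reference: recomputes neighbour counts from an
# RMSD matrix built with the quaternion oracle.
bruteforce_gromos <- function(coord_list, cutoff) {
  n <- length(coord_list)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i)
    D[i, j] <- D[j, i] <- quaternion_rmsd(coord_list[[i]], coord_list[[j]])
  alive <- rep(TRUE, n)
  label <- integer(n)
  k <- 0L
  sizes <- integer(0)
  while (any(alive)) {
    best <- -1L; center <- NA_integer_
    for (i in which(alive)) {
      cnt <- sum(D[i, alive] <= cutoff)
      if (cnt > best) { best <- cnt; center <- i }
    }
    members <- which(alive)[D[center, alive] <= cutoff]
    k <- k + 1L
    label[members] <- k
    sizes[k] <- length(members)
    alive[members] <- FALSE
  }
  ord <- order(-sizes, vapply(seq_len(k), function(c)
    min(which(label == c)), integer(1)))
  relab <- integer(k); relab[ord] <- seq_len(k)
  relab[label]
}

# Base-R Markov chain simulator (independent of the package generator).
sim_chain <- function(T, n, start = NULL, seed = 1L) {
  set.seed(seed)
  k <- nrow(T)
  cum <- t(apply(T, 1, cumsum))
  s <- if (is.null(start)) sample.int(k, 1L) else start
  out <- integer(n)
  u <- runif(n)
  for (t in seq_len(n)) {
    s <- findInterval(u[t], cum[s, ], left.open = TRUE) + 1L
    out[t] <- s
  }
  out
}

# Monte-Carlo reactive A->B flux per step: count, along one long
# trajectory, entries into B whose most recent A-or-B visit was A.
mc_reactive_flux <- function(T, A, B, n_steps, seed = 1L) {
  traj <- sim_chain(T, n_steps, seed = seed)
  ab <- traj[traj %in% c(A, B)]
  inA <- ab %in% A
  sum(inA[-length(inA)] & !inA[-1]) / n_steps
}

# Monte-Carlo committor: fraction of chains from each start state hitting
# B before A (batched, vectorized over runs).
mc_committor <- function(T, A, B, starts, n_runs = 20000L, seed = 1L) {
  set.seed(seed)
  cum <- t(apply(T, 1, cumsum))
  vapply(starts, function(s0) {
    cur <- rep.int(s0, n_runs)
    hitB <- logical(n_runs)
    active <- rep(TRUE, n_runs)
    while (any(active)) {
      idx <- which(active)
      u <- runif(length(idx))
      nxt <- cur[idx]
      for (st in unique(cur[idx])) {
        sel <- cur[idx] == st
        nxt[sel] <- findInterval(u[sel], cum[st, ], left.open = TRUE) + 1L
      }
      cur[idx] <- nxt
      done_b <- idx[nxt %in% B]
      done_a <- idx[nxt %in% A]
      hitB[done_b] <- TRUE
      active[c(done_a, done_b)] <- FALSE
    }
    mean(hitB)
  }, numeric(1))
}

# Monte-Carlo mean first-passage time (steps), batched over runs.
mc_mfpt <- function(T, source, target, n_runs = 1e5L, seed = 1L,
                    max_steps = 1e6L) {
  set.seed(seed)
  cum <- t(apply(T, 1, cumsum))
  cur <- rep.int(source, n_runs)
  steps <- integer(n_runs)
  active <- rep(TRUE, n_runs)
  t <- 0L
  while (any(active) && t < max_steps) {
    t <- t + 1L
    idx <- which(active)
    u <- runif(length(idx))
    nxt <- cur[idx]
    for (st in unique(cur[idx])) {
      sel <- cur[idx] == st
      nxt[sel] <- findInterval(u[sel], cum[st, ], left.open = TRUE) + 1L
    }
    cur[idx] <- nxt
    done <- idx[nxt %in% target]
    steps[done] <- t
    active[done] <- FALSE
  }
  mean(steps)
}

# reversible 3-state ground-truth chain used by the recovery tests:
# detailed balance built in from a symmetric flow matrix
recovery_chain <- function() {
  pi_true <- c(0.5, 0.3, 0.2)
  K <- matrix(0, 3, 3)
  K[1, 2] <- K[2, 1] <- 0.006
  K[1, 3] <- K[3, 1] <- 0.002
  K[2, 3] <- K[3, 2] <- 0.004
  T <- K / pi_true
  diag(T) <- 1 - rowSums(T)
  list(T = T, pi = pi_true,
       means = rbind(c(0, 0), c(4, 0), c(0, 4)),
       cov = diag(0.25, 2))
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# lazy symmetric nearest-neighbour random walk on n states
symmetric_walk <- function(n = 5, p = 0.3) {
  T <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i > 1) T[i, i - 1] <- p
    if (i < n) T[i, i + 1] <- p
    T[i, i] <- 1 - sum(T[i, ])
  }
  T
}

# rigid rotation matrix about an arbitrary axis (for invariance tests)
rotation_matrix <- function(axis = c(1, 2, 3), angle = 1.1) {
  a <- axis / sqrt(sum(axis^2))
  c <- cos(angle); s <- sin(angle)
  outer(a, a) * (1 - c) + diag(c, 3) +
    matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3) * s
}

rotate_ensemble <- function(ens, R = rotation_matrix(), shift = c(5, -3, 2)) {
  for (f in seq_len(n_frames(ens)))
    ens$coords[f, , ] <- frame_coords(ens, f) %*% t(R) +
      matrix(shift, n_atoms(ens), 3, byrow = TRUE)
  ens
}
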