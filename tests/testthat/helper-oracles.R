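# Independent oracles used across the suite. These deliberately take
# different code paths from the package internals they check: explicit
# root-to-tip path enumeration via ape::nodepath(), exhaustive summation
# over node states, and direct formula evaluation.

# Root-to-tip regime segments of a painted tree for one tip, via ape's node
# paths (independent of the package's preorder accumulation).
oracle_tip_segments <- function(map, tip) {
  ntip <- length(map$tip.label)
  root <- ntip + 1L
  nodes <- ape::nodepath(map, from = root, to = tip)
  segs <- data.frame(regime = character(0), dur = numeric(0))
  for (i in seq_len(length(nodes) - 1L)) {
    e <- which(map$edge[, 1] == nodes[i] & map$edge[, 2] == nodes[i + 1L])
    m <- map$maps[[e]]
    segs <- rbind(segs, data.frame(regime = names(m), dur = unname(m)))
  }
  segs
}

# Shared root-ward path segments of two tips: the common prefix of their
# segment sequences (same regime sequence up to the split).
oracle_shared_segments <- function(map, i, j) {
  ntip <- length(map$tip.label)
  root <- ntip + 1L
  pi_ <- ape::nodepath(map, from = root, to = i)
  pj <- ape::nodepath(map, from = root, to = j)
  common <- pi_[pi_ %in% pj] # shared node path from the root to the MRCA
  segs <- data.frame(regime = character(0), dur = numeric(0))
  if (length(common) < 2L) return(segs)
  for (k in seq_len(length(common) - 1L)) {
    e <- which(map$edge[, 1] == common[k] & map$edge[, 2] == common[k + 1L])
    m <- map$maps[[e]]
    segs <- rbind(segs, data.frame(regime = names(m), dur = unname(m)))
  }
  segs
}

# Brute-force BM moments: C[i, j] = sum over shared segments of
# sigma2[regime] * duration; mean = root state.
oracle_bm_moments <- function(map, sigma2, root_state) {
  ntip <- length(map$tip.label)
  C <- matrix(0, ntip, ntip)
  for (i in seq_len(ntip)) for (j in seq_len(i)) {
    segs <- if (i == j) oracle_tip_segments(map, i) else
      oracle_shared_segments(map, i, j)
    v <- if (nrow(segs)) sum(sigma2[segs$regime] * segs$dur) else 0
    C[i, j] <- C[j, i] <- v
  }
  list(mean = rep(root_state, ntip), cov = C)
}

# Brute-force OU moments (shared alpha/sigma2, per-regime theta, root fixed
# at the root regime's optimum): direct evaluation of the path integrals.
oracle_ou_moments <- function(map, alpha, sigma2, theta) {
  ntip <- length(map$tip.label)
  root_regime <- map$node.states[ntip + 1L]
  mu <- numeric(ntip)
  Tdepth <- numeric(ntip)
  for (i in seq_len(ntip)) {
    segs <- oracle_tip_segments(map, i)
    Ti <- sum(segs$dur)
    Tdepth[i] <- Ti
    m <- exp(-alpha * Ti) * theta[root_regime]
    t_end <- cumsum(segs$dur)
    t_start <- t_end - segs$dur
    m <- m + sum(theta[segs$regime] *
                   (exp(-alpha * (Ti - t_end)) - exp(-alpha * (Ti - t_start))))
    mu[i] <- m
  }
  C <- matrix(0, ntip, ntip)
  for (i in seq_len(ntip)) for (j in seq_len(i)) {
    segs <- if (i == j) oracle_tip_segments(map, i) else
      oracle_shared_segments(map, i, j)
    s <- if (nrow(segs)) sum(segs$dur) else 0
    d <- Tdepth[i] + Tdepth[j] - 2 * s
    C[i, j] <- C[j, i] <-
      sigma2 / (2 * alpha) * (1 - exp(-2 * alpha * s)) * exp(-alpha * d)
  }
  list(mean = mu, cov = C)
}

# Exhaustive Mk likelihood: sum over every assignment of states to all nodes
# (tips included, weighted by their priors).
oracle_mk_lik <- function(tree, tip_priors, Q, root_treatment = "uniform",
                          root_prior = NULL) {
  k <- nrow(Q)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  P <- lapply(tree$edge.length, function(t) as.matrix(Matrix::expm(Q * t)))
  pri <- tip_priors[tree$tip.label, , drop = FALSE]
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), nn)))
  tot <- 0
  for (r in seq_len(nrow(combos))) {
    s <- combos[r, ]
    w <- root_prior[s[ntip + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      w <- w * P[[e]][s[tree$edge[e, 1]], s[tree$edge[e, 2]]]
    }
    for (tp in seq_len(ntip)) w <- w * pri[tp, s[tp]]
    tot <- tot + w
  }
  tot
}

# Exhaustive marginal posterior of each node's state (same enumeration).
oracle_mk_marginals <- function(tree, tip_priors, Q, root_prior) {
  k <- nrow(Q)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  P <- lapply(tree$edge.length, function(t) as.matrix(Matrix::expm(Q * t)))
  pri <- tip_priors[tree$tip.label, , drop = FALSE]
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), nn)))
  post <- matrix(0, nn, k)
  for (r in seq_len(nrow(combos))) {
    s <- combos[r, ]
    w <- root_prior[s[ntip + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      w <- w * P[[e]][s[tree$edge[e, 1]], s[tree$edge[e, 2]]]
    }
    for (tp in seq_len(ntip)) w <- w * pri[tp, s[tp]]
    for (v in seq_len(nn)) post[v, s[v]] <- post[v, s[v]] + w
  }
  post / rowSums(post)
}

# Small fixed fixtures shared across files.
fixture_config <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(seed = seed, n_pixels = 400L, n_env_vars = 12L,
                   latent_dim = 2L, noise_sd = 0.3, n_species = 6L,
                   n_taxa = 12L, n_trees = 3L)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

fixture_Q2 <- function(q = 1) {
  matrix(c(-q, q, q, -q), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
}

fixture_Q3 <- function() {
  matrix(c(-0.9, 0.5, 0.4,
           0.3, -0.7, 0.4,
           0.2, 0.6, -0.8), 3, 3, byrow = TRUE,
         dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
}
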