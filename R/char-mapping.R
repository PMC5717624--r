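#' Tip prior probabilities for pollination mode
#'
#' Encodes the uncertainty scheme for pollination syndromes: modes confirmed
#' by field observation get probability 1; a specialist mode inferred from
#' floral shape gets 2/3 on the inferred mode and 1/6 on each other mode; an
#' inferred generalist ("mixed") gets 1/2 on mixed and 1/4 on each
#' specialist mode; species with unknown mode get 1/3 each.
#'
#' @param metadata data.frame with columns `species`, `pollination_mode`
#'   (hummingbird / bat / mixed / unknown) and `mode_status`
#'   (observed / inferred / unknown).
#' @param states state order (default hummingbird, bat, mixed).
#' @return matrix (species x states) of prior probabilities, rows sum to 1.
#' @export
build_tip_priors <- function(metadata,
                             states = c("hummingbird", "bat", "mixed")) {
  k <- length(states)
  out <- matrix(0, nrow(metadata), k,
                dimnames = list(metadata$species, states))
  for (i in seq_len(nrow(metadata))) {
    mode <- as.character(metadata$pollination_mode[i])
    status <- as.character(metadata$mode_status[i])
    if (status == "unknown" || mode == "unknown") {
      out[i, ] <- 1 / k
    } else if (!(mode %in% states)) {
      stopf("species '%s': unrecognized pollination mode '%s'",
            metadata$species[i], mode)
    } else if (status == "observed") {
      out[i, mode] <- 1
    } else if (status == "inferred") {
      if (mode == "mixed") {
        out[i, ] <- 1 / 4
        out[i, "mixed"] <- 1 / 2
      } else {
        out[i, ] <- 1 / 6
        out[i, mode] <- 2 / 3
      }
    } else {
      stopf("species '%s': unrecognized mode status '%s'",
            metadata$species[i], status)
    }
  }
  out
}

#' Tip priors from a single-island assignment
#'
#' @param assignment named character vector (species -> island).
#' @param states island state order.
#' @return degenerate prior matrix (probability 1 on the assigned island).
#' @export
island_tip_priors <- function(assignment,
                              states = island_names()) {
  out <- matrix(0, length(assignment), length(states),
                dimnames = list(names(assignment), states))
  for (i in seq_along(assignment)) {
    if (!(assignment[i] %in% states))
      stopf("species '%s': unknown island '%s'", names(assignment)[i],
            assignment[i])
    out[i, assignment[i]] <- 1
  }
  out
}

#' Randomly resolve multi-island species to one island
#'
#' Evolution-model regimes must be exclusive, so species present on two
#' islands are assigned one of theirs uniformly at random (drawn afresh per
#' replicate iteration); single-island species keep their island.
#'
#' @param metadata data.frame with `species` and `islands` (";"-separated).
#' @param seed integer seed.
#' @return named character vector (species -> island).
#' @export
assign_single_island <- function(metadata, seed = NULL) {
  sets <- strsplit(as.character(metadata$islands), ";", fixed = TRUE)
  if (any(lengths(sets) == 0L))
    stopf("species with empty island set: %s",
          paste(metadata$species[lengths(sets) == 0L], collapse = ", "))
  with_seed(seed, {
    picked <- vapply(sets, function(s) {
      if (length(s) == 1L) s else s[sample.int(length(s), 1L)]
    }, character(1))
    stats::setNames(picked, metadata$species)
  })
}

# Validate a rate matrix: square, named, rows sum to 0, off-diagonals >= 0.
check_Q <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) stopf("'Q' must be square")
  if (is.null(rownames(Q))) stopf("'Q' must have state names as dimnames")
  off <- Q; diag(off) <- 0
  if (any(off < 0)) stopf("'Q' off-diagonal rates must be >= 0")
  if (any(abs(rowSums(Q)) > 1e-8 * max(1, max(abs(Q)))))
    stopf("'Q' rows must sum to 0")
  invisible(TRUE)
}

# Transition probability matrices exp(Q t) for a vector of branch lengths.
# Eigen-decomposition (one factorization, reused for all t) with a
# scaling-and-squaring fallback when the eigenvector basis is ill-conditioned.
mk_transition_mats <- function(Q, ts) {
  k <- nrow(Q)
  e <- tryCatch(eigen(Q), error = function(err) NULL)
  use_eigen <- FALSE
  if (!is.null(e)) {
    Vi <- tryCatch(solve(e$vectors), error = function(err) NULL)
    if (!is.null(Vi)) {
      kap <- sqrt(sum(Mod(e$vectors)^2)) * sqrt(sum(Mod(Vi)^2))
      use_eigen <- is.finite(kap) && kap < 1e8
    }
  }
  if (use_eigen) {
    # vec(P(t)) = M exp(lambda t), with M[, j] = vec(V[, j] %o% Vi[j, ]):
    # all branch lengths in one (possibly complex) matrix multiply, then
    # clamp-and-renormalize rows in bulk.
    M <- sapply(seq_len(k), function(j) as.vector(e$vectors[, j] %o% Vi[j, ]))
    A <- array(Re(M %*% exp(outer(e$values, ts))), c(k, k, length(ts)))
    A[A < 0] <- 0
    rs <- colSums(aperm(A, c(2, 1, 3)))                   # k x E row sums
    A <- A / aperm(array(rs, c(k, length(ts), k)), c(1, 3, 2))
    return(lapply(seq_along(ts), function(i) A[, , i]))
  }
  lapply(ts, function(t) {
    P <- as.matrix(Matrix::expm(Q * t))
    P[P < 0] <- 0
    dimnames(P) <- dimnames(Q)
    P / rowSums(P)
  })
}

# Root prior vector for a given treatment and root partials.
mk_root_prior <- function(Q, L_root, root_treatment) {
  k <- nrow(Q)
  switch(root_treatment,
    uniform = rep(1 / k, k),
    stationary = {
      # stationary distribution solves pi %*% Q = 0: null space of t(Q)
      v <- MASS::Null(t(Q))
      if (ncol(v) < 1L) rep(1 / k, k) else {
        p <- abs(v[, 1]); p / sum(p)
      }
    },
    fitzjohn = {
      s <- sum(L_root)
      if (s <= 0) rep(1 / k, k) else L_root / s
    },
    stopf("unknown root treatment '%s'", root_treatment))
}

# Felsenstein pruning downpass. Returns the per-node (scaled) conditional
# likelihoods, per-node log scaling, the per-edge transition matrices, and
# the log-likelihood under the requested root treatment.
mk_pruning <- function(tree, tip_priors, Q, root_treatment = "fitzjohn",
                       Pmats = NULL) {
  check_Q(Q)
  states <- rownames(Q)
  k <- length(states)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  if (!all(tree$tip.label %in% rownames(tip_priors)))
    stopf("tip priors missing for: %s",
          paste(setdiff(tree$tip.label, rownames(tip_priors)), collapse = ", "))
  pri <- tip_priors[tree$tip.label, states, drop = FALSE]
  if (any(abs(rowSums(pri) - 1) > 1e-9))
    stopf("tip prior rows must sum to 1")
  if (is.null(Pmats)) Pmats <- mk_transition_mats(Q, tree$edge.length)
  po <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  L <- matrix(0, nn, k)
  L[seq_len(ntip), ] <- pri
  L[(ntip + 1):nn, ] <- 1
  logscale <- 0
  for (i in po) {
    par <- tree$edge[i, 1L]; ch <- tree$edge[i, 2L]
    v <- as.vector(Pmats[[i]] %*% L[ch, ])
    s <- max(v)
    if (s <= 0) return(list(loglik = -Inf))
    logscale <- logscale + log(s)
    L[par, ] <- L[par, ] * (v / s)
  }
  root <- ntip + 1L
  pi0 <- mk_root_prior(Q, L[root, ], root_treatment)
  lik <- sum(pi0 * L[root, ])
  list(loglik = log(lik) + logscale, L = L, Pmats = Pmats, root_prior = pi0,
       states = states, postorder = po)
}

#' Mk model log-likelihood on a tree with (possibly soft) tip priors
#'
#' Standard pruning computation with per-branch transition matrices
#' `exp(Q t)`; tip partial likelihoods are the tip prior vectors, so
#' uncertain states enter exactly. Internal rescaling keeps the computation
#' in range for any tree size.
#'
#' @param tree a `phylo` tree.
#' @param tip_priors matrix (species x states) of prior probabilities.
#' @param Q rate matrix with state dimnames.
#' @param root_treatment `"fitzjohn"` (default: root states weighted by their
#'   conditional likelihood), `"uniform"` or `"stationary"`.
#' @return log-likelihood (numeric scalar).
#' @export
mk_loglik <- function(tree, tip_priors, Q, root_treatment = "fitzjohn") {
  mk_pruning(tree, tip_priors, Q, root_treatment)$loglik
}

#' Marginal ancestral-state probabilities
#'
#' Exact per-node marginal posteriors from the pruning recursion
#' (downpass conditional likelihoods combined with an uppass of
#' outside-subtree likelihoods).
#'
#' @inheritParams mk_loglik
#' @return matrix (nodes x states): tips first (rows 1..Ntip), then internal
#'   nodes in ape numbering; each row sums to 1.
#' @export
ancestral_marginals <- function(tree, tip_priors, Q,
                                root_treatment = "fitzjohn") {
  pr <- mk_pruning(tree, tip_priors, Q, root_treatment)
  k <- length(pr$states)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  # edge messages M_i = P_i %*% L[child] (relative scale is enough)
  M <- lapply(seq_len(nrow(tree$edge)), function(i) {
    v <- as.vector(pr$Pmats[[i]] %*% pr$L[tree$edge[i, 2L], ])
    v / max(v)
  })
  child_edges <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  U <- matrix(0, nn, k)
  U[ntip + 1L, ] <- pr$root_prior
  for (i in rev(pr$postorder)) { # preorder
    par <- tree$edge[i, 1L]; ch <- tree$edge[i, 2L]
    G <- U[par, ]
    for (j in child_edges[[as.character(par)]]) {
      if (j != i) G <- G * M[[j]]
    }
    u <- as.vector(t(pr$Pmats[[i]]) %*% G)
    U[ch, ] <- u / max(u)
  }
  post <- U * pr$L
  post <- post / rowSums(post)
  colnames(post) <- pr$states
  rownames(post) <- c(tree$tip.label, ntip + seq_len(tree$Nnode))
  post
}

# Free-rate index matrix for a constraint: entries > 0 index the free rate
# governing each off-diagonal transition.
mk_rate_index <- function(k, constraint) {
  idx <- matrix(0L, k, k)
  if (constraint == "ER") {
    idx[row(idx) != col(idx)] <- 1L
  } else if (constraint == "SYM") {
    r <- 0L
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      r <- r + 1L
      idx[i, j] <- idx[j, i] <- r
    }
  } else if (constraint == "ARD") {
    idx[row(idx) != col(idx)] <- seq_len(k * (k - 1))
  } else stopf("unknown constraint '%s'", constraint)
  idx
}

# Assemble Q from free rates and an index matrix.
mk_build_Q <- function(rates, idx, states) {
  Q <- matrix(0, nrow(idx), ncol(idx), dimnames = list(states, states))
  off <- idx > 0
  Q[off] <- rates[idx[off]]
  diag(Q) <- -rowSums(Q)
  Q
}

#' Fit an Mk model by maximum likelihood
#'
#' Bounded quasi-Newton optimization of the free transition rates on the log
#' scale, with multiple restarts. `ER` fits 1 rate, `SYM` fits k(k-1)/2,
#' `ARD` fits k(k-1).
#'
#' @inheritParams mk_loglik
#' @param constraint `"ER"`, `"SYM"` or `"ARD"`.
#' @param states state order; defaults to the tip-prior columns.
#' @param n_restarts random restarts in addition to the heuristic start.
#' @param seed integer seed for the restart draws.
#' @return object of class `mk_model`: list with `states`, `constraint`,
#'   `Q`, `log_likelihood`, `k` (free rates), `root_treatment`,
#'   `convergence`.
#' @export
fit_mk <- function(tree, tip_priors, constraint = c("SYM", "ER", "ARD"),
                   states = colnames(tip_priors),
                   root_treatment = "fitzjohn", n_restarts = 2L,
                   seed = NULL) {
  constraint <- match.arg(constraint)
  k <- length(states)
  mass <- colSums(tip_priors[tree$tip.label, states, drop = FALSE])
  if (sum(mass > 0) < 2L)
    stopf("need at least 2 states with nonzero tip prior mass")
  idx <- mk_rate_index(k, constraint)
  np <- max(idx)
  tot_len <- sum(tree$edge.length)
  r0 <- k / tot_len # of the order of one expected transition per tree
  lower <- log(1e-8); upper <- log(1e4 / max(tree$edge.length))
  negll <- function(lr) {
    Q <- mk_build_Q(exp(lr), idx, states)
    ll <- tryCatch(mk_loglik(tree, tip_priors, Q, root_treatment),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  starts <- list(rep(log(r0), np))
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      starts[[length(starts) + 1L]] <-
        log(r0) + stats::rnorm(np, sd = 1.5)
    }
    best <- NULL; trace <- character(0)
    for (s in starts) {
      fit <- tryCatch(
        stats::optim(pmin(pmax(s, lower), upper), negll,
                     method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(maxit = 200, factr = 1e8)),
        error = function(e) NULL)
      if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e10) {
        trace <- c(trace, "restart failed or non-finite likelihood")
        next
      }
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    if (is.null(best))
      stopf("Mk fit failed to converge in all restarts:\n%s",
            paste(trace, collapse = "\n"))
    Q <- mk_build_Q(exp(best$par), idx, states)
    out <- list(states = states, constraint = constraint, Q = Q,
                log_likelihood = -best$value, k = np,
                root_treatment = root_treatment,
                convergence = best$convergence)
    class(out) <- "mk_model"
    out
  })
}

#' @export
print.mk_model <- function(x, ...) {
  cat(sprintf("Mk model (%s, %d free rate(s)), logLik = %.4f\n",
              x$constraint, x$k, x$log_likelihood))
  print(round(x$Q, 4))
  invisible(x)
}

#' Sample stochastic character maps
#'
#' Exact posterior draws of full character histories conditional on the tip
#' data and an Mk model: downpass conditional likelihoods, root state drawn
#' from its posterior, node states drawn conditionally on their parents, and
#' each branch's internal history drawn conditional on its endpoint states by
#' rejection sampling of forward paths (capped), with a uniformization
#' sampler as guaranteed-termination fallback.
#'
#' @inheritParams mk_loglik
#' @param model an optional fitted [fit_mk()] model; otherwise supply `Q`.
#' @param Q rate matrix (ignored when `model` is given).
#' @param nsim number of maps to draw.
#' @param seed integer seed.
#' @param rejection_cap forward-simulation attempts per branch before
#'   switching to uniformization (default 1000).
#' @return a single `simmap` when `nsim = 1`, else a list of them.
#' @export
sample_stochastic_map <- function(tree, tip_priors, model = NULL, Q = NULL,
                                  root_treatment = "fitzjohn", nsim = 1L,
                                  seed = NULL, rejection_cap = 1000L) {
  if (!is.null(model)) {
    Q <- model$Q
    root_treatment <- model$root_treatment %||% root_treatment
  }
  if (is.null(Q)) stopf("supply either 'model' or 'Q'")
  pr <- mk_pruning(tree, tip_priors, Q, root_treatment)
  if (!is.finite(pr$loglik)) stopf("tip data have zero likelihood under Q")
  states <- pr$states
  k <- length(states)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  pre <- rev(pr$postorder)
  Lam <- max(-diag(Q))
  Rm <- if (Lam > 0) diag(k) + Q / Lam else diag(k)
  with_seed(seed, {
    draws <- vector("list", nsim)
    for (r in seq_len(nsim)) {
      node_state <- integer(nn)
      node_state[ntip + 1L] <-
        sample.int(k, 1L, prob = pr$root_prior * pr$L[ntip + 1L, ])
      maps <- vector("list", nrow(tree$edge))
      for (i in pre) {
        par <- tree$edge[i, 1L]; ch <- tree$edge[i, 2L]
        w <- pr$Pmats[[i]][node_state[par], ] * pr$L[ch, ]
        node_state[ch] <- sample.int(k, 1L, prob = w)
        maps[[i]] <- sample_branch_path(
          Q, Rm, Lam, node_state[par], node_state[ch],
          tree$edge.length[i], pr$Pmats[[i]], states, rejection_cap)
      }
      draws[[r]] <- as_simmap(tree, maps, states[node_state])
    }
    if (nsim == 1L) draws[[1L]] else draws
  })
}

# Draw one CTMC path on a branch conditional on endpoint states a -> b.
# Returns a named duration vector (rootward segment first).
sample_branch_path <- function(Q, Rm, Lam, a, b, len, P, states,
                               rejection_cap) {
  k <- nrow(Q)
  if (Lam <= 0 || all(abs(Q) < 1e-300)) {
    if (a != b) stopf("zero rate matrix cannot connect different endpoints")
    return(stats::setNames(len, states[a]))
  }
  # rejection sampling of forward paths
  for (att in seq_len(rejection_cap)) {
    s <- a; t <- 0
    segs <- numeric(0); labs <- integer(0)
    ok <- TRUE
    repeat {
      rate <- -Q[s, s]
      dt <- if (rate > 0) rexp(1, rate) else Inf
      if (t + dt >= len) {
        segs <- c(segs, len - t); labs <- c(labs, s)
        break
      }
      segs <- c(segs, dt); labs <- c(labs, s)
      t <- t + dt
      p <- Q[s, ]; p[s] <- 0
      s <- sample.int(k, 1L, prob = p)
      if (length(segs) > 1000L) { ok <- FALSE; break }
    }
    if (ok && s == b) {
      return(collapse_segments(segs, states[labs]))
    }
  }
  # uniformization fallback: exact conditional draw
  pab <- P[a, b]
  Rpow <- list(diag(k))
  u <- runif(1) * pab
  cum <- 0; N <- 0L
  repeat {
    w <- dpois(N, Lam * len) * Rpow[[N + 1L]][a, b]
    cum <- cum + w
    if (cum >= u || N > 5000L) break
    N <- N + 1L
    Rpow[[N + 1L]] <- Rpow[[N]] %*% Rm
  }
  if (N == 0L) return(stats::setNames(len, states[a]))
  times <- sort(runif(N)) * len
  st <- integer(N + 1L); st[1L] <- a
  for (m in seq_len(N)) {
    rem <- N - m
    p <- Rm[st[m], ] * Rpow[[rem + 1L]][, b]
    st[m + 1L] <- sample.int(k, 1L, prob = p)
  }
  bounds <- c(0, times, len)
  collapse_segments(diff(bounds), states[st])
}

# Merge adjacent equal-state segments into a named duration vector.
collapse_segments <- function(durs, labs) {
  keep <- c(TRUE, labs[-1] != labs[-length(labs)])
  grp <- cumsum(keep)
  out <- as.vector(tapply(durs, grp, sum))
  stats::setNames(out, labs[keep])
}
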