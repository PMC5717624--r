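# Multi-regime Brownian-motion / Ornstein-Uhlenbeck models on painted trees.
#
# Parameter sharing follows the model definitions used throughout: BM with
# several regimes lets each regime have its own diffusion rate sigma^2 with a
# shared root state; OU with several regimes lets each regime have its own
# optimum theta with a shared attraction strength alpha and rate sigma^2.
# The OU root is non-stationary: the root state is fixed at the optimum of
# the regime painted at the root (a "stationary_root" variant is available).

# Per-simmap precomputation shared by moments, likelihood and fitting; the
# result is cached on the object (attribute) so repeated fits on the same
# painted tree reuse it.
simmap_summary <- function(x) {
  cached <- attr(x, "simmap_summary")
  if (!is.null(cached)) return(cached)
  S <- simmap_regime_vcv(x)
  Svcv <- Reduce(`+`, S)
  Tt <- diag(Svcv)
  paths <- simmap_tip_paths(x)
  seg <- do.call(rbind, lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    data.frame(tip = i, regime = p$regime, t0 = p$t0, t1 = p$t1,
               stringsAsFactors = FALSE)
  }))
  list(ntip = length(x$tip.label), tips = x$tip.label,
       states = names(S), S = S, Svcv = Svcv, T = Tt,
       D = outer(Tt, Tt, "+") - 2 * Svcv,
       seg = seg, root_state = simmap_root_state(x))
}

# Attach the cached summary (used by fit_model_set / the replicate engine to
# share the precomputation across the six model fits).
cache_simmap_summary <- function(x) {
  attr(x, "simmap_summary") <- simmap_summary(x)
  x
}

# Sum of per-regime 2x2-weighted shared-path matrices, assembled block-wise
# (faster than kronecker() in the optimizer hot loop).
bm_bivariate_vcv <- function(sm, Rl) {
  n <- sm$ntip
  R <- length(Rl)
  B <- list(`11` = 0, `12` = 0, `21` = 0, `22` = 0)
  for (j in seq_len(R)) {
    B$`11` <- B$`11` + Rl[[j]][1, 1] * sm$S[[j]]
    B$`12` <- B$`12` + Rl[[j]][1, 2] * sm$S[[j]]
    B$`22` <- B$`22` + Rl[[j]][2, 2] * sm$S[[j]]
  }
  rbind(cbind(B$`11`, B$`12`), cbind(t(B$`12`), B$`22`))
}

# Hansen weight matrix W(alpha): W[i, r] is the weight of regime r's optimum
# in the expected value of tip i; the root contribution exp(-alpha T_i) goes
# to the root regime's column (root state fixed at that optimum), so rows sum
# to 1 exactly.
ou_weight_matrix <- function(sm, alpha) {
  R <- length(sm$states)
  W <- matrix(0, sm$ntip, R, dimnames = list(sm$tips, sm$states))
  Ttip <- sm$T[sm$seg$tip]
  w <- exp(-alpha * (Ttip - sm$seg$t1)) - exp(-alpha * (Ttip - sm$seg$t0))
  ij <- sm$ntip * (match(sm$seg$regime, sm$states) - 1L) + sm$seg$tip
  add <- rowsum(w, ij)
  W[as.integer(rownames(add))] <- add
  W[, sm$root_state] <- W[, sm$root_state] + exp(-alpha * sm$T)
  W
}

# OU covariance shape (sigma2 = 1) for shared scalar alpha.
ou_vcv_shape <- function(sm, alpha, stationary_root = FALSE) {
  if (stationary_root) {
    exp(-alpha * sm$D) / (2 * alpha)
  } else {
    (-expm1(-2 * alpha * sm$Svcv)) * exp(-alpha * sm$D) / (2 * alpha)
  }
}

# Bivariate OU covariance with diagonal alpha = (a1, a2) and 2x2 rate matrix
# Rmat; trait-major layout (trait 1 tips, then trait 2 tips).
ou_vcv_bivariate <- function(sm, alpha2, Rmat, stationary_root = FALSE) {
  n <- sm$ntip
  A <- lapply(alpha2, function(a) exp(-a * (matrix(sm$T, n, n) - sm$Svcv)))
  V <- matrix(0, 2 * n, 2 * n)
  for (p in 1:2) for (q in 1:2) {
    apq <- alpha2[p] + alpha2[q]
    core <- if (stationary_root) 1 else (-expm1(-apq * sm$Svcv))
    blk <- (Rmat[p, q] / apq) * core * A[[p]] * t(A[[q]])
    V[(p - 1) * n + seq_len(n), (q - 1) * n + seq_len(n)] <- blk
  }
  V
}

#' Model-implied mean and covariance of tip traits
#'
#' Builds the exact multivariate-normal moments of the tip trait vector under
#' a painted BM or OU model. BM: the covariance accumulates each regime's
#' rate over the shared root-to-tip path segments and the mean is the root
#' state. OU (Hansen construction): the expected tip value is the
#' exponentially weighted average of the optima encountered along the
#' root-to-tip path, and the covariance is
#' `sigma2/(2 alpha) * exp(-alpha d_ij) * (1 - exp(-2 alpha s_ij))`
#' with `s_ij` the shared time and `d_ij` the phylogenetic distance
#' (non-stationary root; the stationary-root variant drops the second
#' factor). Bivariate models use the Kronecker-structured generalization with
#' the same regime layout (full 2x2 symmetric rate matrix; diagonal alpha).
#'
#' This is the single source of truth for model moments: the trait simulator
#' ([simulate_traits()]) and the likelihood ([evo_loglik()]) both use it.
#'
#' @param simmap a regime-painted tree ([as_simmap()]).
#' @param family `"BM"` or `"OU"`.
#' @param params list of parameters. BM univariate: `sigma2` (named per
#'   regime, or scalar), `root_state` scalar. BM bivariate: `sigma2` a named
#'   list of 2x2 matrices (or one matrix), `root_state` length 2. OU
#'   univariate: `alpha` scalar, `sigma2` scalar, `theta` named per regime.
#'   OU bivariate: `alpha` length 2, `sigma2` 2x2, `theta` matrix
#'   (regimes x 2). Optional `stationary_root = TRUE` selects the
#'   stationary-root OU variant.
#' @return list with `mean` (named), `cov`, `n_traits`, `trait_names`.
#' @export
model_moments <- function(simmap, family = c("BM", "OU"), params) {
  family <- match.arg(family)
  sm <- simmap_summary(simmap)
  st <- sm$states
  n <- sm$ntip
  statroot <- isTRUE(params$stationary_root)
  if (family == "BM") {
    if (any(unlist(params$sigma2) < 0, na.rm = TRUE))
      stopf("BM 'sigma2' must be positive")
    biv <- length(params$root_state) == 2L
    if (!biv) {
      s2 <- expand_regime_par(params$sigma2, st)
      V <- Reduce(`+`, Map(function(r) s2[r] * sm$S[[r]], st))
      mu <- stats::setNames(rep(params$root_state, n), sm$tips)
      return(list(mean = mu, cov = V, n_traits = 1L, trait_names = NULL))
    }
    Rl <- expand_regime_matpar(params$sigma2, st)
    V <- Reduce(`+`, Map(function(r) kronecker(Rl[[r]], sm$S[[r]]), st))
    mu <- c(rep(params$root_state[1], n), rep(params$root_state[2], n))
    names(mu) <- c(paste0(sm$tips, "|1"), paste0(sm$tips, "|2"))
    return(list(mean = mu, cov = V, n_traits = 2L,
                trait_names = names(params$root_state) %||%
                  c("trait1", "trait2")))
  }
  # OU
  alpha <- params$alpha
  if (any(alpha < 0)) stopf("'alpha' must be >= 0")
  if (length(alpha) == 1L) {
    th <- expand_regime_par(params$theta, st)
    W <- ou_weight_matrix(sm, alpha)
    mu <- stats::setNames(as.vector(W %*% th[st]), sm$tips)
    V <- params$sigma2 * ou_vcv_shape(sm, alpha, statroot)
    return(list(mean = mu, cov = V, n_traits = 1L, trait_names = NULL))
  }
  th <- params$theta
  if (is.null(dim(th))) stopf("bivariate OU 'theta' must be regimes x 2")
  if (!all(st %in% rownames(th)))
    stopf("'theta' rows must cover regimes: %s", paste(st, collapse = ", "))
  th <- th[st, , drop = FALSE]
  mu <- c(as.vector(ou_weight_matrix(sm, alpha[1]) %*% th[, 1]),
          as.vector(ou_weight_matrix(sm, alpha[2]) %*% th[, 2]))
  names(mu) <- c(paste0(sm$tips, "|1"), paste0(sm$tips, "|2"))
  V <- ou_vcv_bivariate(sm, alpha, params$sigma2, statroot)
  list(mean = mu, cov = V, n_traits = 2L,
       trait_names = colnames(th) %||% c("trait1", "trait2"))
}

# Recycle a scalar or named per-regime parameter over the regime set.
expand_regime_par <- function(p, states) {
  if (length(p) == 1L && is.null(names(p)))
    return(stats::setNames(rep(p, length(states)), states))
  if (!all(states %in% names(p)))
    stopf("parameters missing for regime(s): %s",
          paste(setdiff(states, names(p)), collapse = ", "))
  p[states]
}

expand_regime_matpar <- function(p, states) {
  if (is.matrix(p)) {
    out <- rep(list(p), length(states)); names(out) <- states
    return(out)
  }
  if (!all(states %in% names(p)))
    stopf("rate matrices missing for regime(s): %s",
          paste(setdiff(states, names(p)), collapse = ", "))
  p[states]
}

#' Log-likelihood of tip traits under a painted BM/OU model
#'
#' Gaussian log-density of the observed tip traits under the moments from
#' [model_moments()], evaluated through a Cholesky factorization.
#'
#' @inheritParams model_moments
#' @param traits named numeric vector (univariate; names = tip labels) or a
#'   tips x 2 matrix with tip rownames (bivariate).
#' @return log-likelihood (scalar).
#' @export
evo_loglik <- function(simmap, traits, family = c("BM", "OU"), params) {
  mom <- model_moments(simmap, family, params)
  y <- align_traits(traits, simmap$tip.label, mom$n_traits)
  ll <- mvn_loglik(y, mom$mean, mom$cov)
  if (!is.finite(ll)) stopf("model covariance is numerically singular")
  ll
}

# Order trait data to the tip labels; bivariate data are stacked trait-major.
align_traits <- function(traits, tips, n_traits) {
  if (n_traits == 1L) {
    if (is.matrix(traits)) traits <- stats::setNames(traits[, 1],
                                                     rownames(traits))
    if (is.null(names(traits))) stopf("'traits' must be named by tip label")
    if (!all(tips %in% names(traits))) stopf("traits missing for some tips")
    return(as.numeric(traits[tips]))
  }
  if (!is.matrix(traits) || ncol(traits) != 2L)
    stopf("bivariate models need a tips x 2 trait matrix")
  if (is.null(rownames(traits))) stopf("trait matrix must have tip rownames")
  if (!all(tips %in% rownames(traits))) stopf("traits missing for some tips")
  c(traits[tips, 1], traits[tips, 2])
}

# Profiled GLS log-likelihood for y ~ N(X beta, c V0), maximizing over beta
# and the scale c analytically. Rank-deficient designs are handled through
# the QR fit (unidentifiable coefficients come back NA).
gls_profile <- function(V0, X, y, want_beta = TRUE) {
  L <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(L)) return(list(ll = -Inf))
  Xw <- backsolve(L, X, transpose = TRUE)
  yw <- backsolve(L, y, transpose = TRUE)
  qx <- qr(Xw)
  res <- qr.resid(qx, yw)
  n <- length(y)
  q <- sum(res^2)
  scale <- q / n
  if (scale <= 0) scale <- 1e-300
  ll <- -0.5 * (n * log(2 * pi) + n * log(scale) +
                  2 * sum(log(diag(L))) + n)
  beta <- if (want_beta) suppressWarnings(qr.coef(qx, yw)) else NULL
  list(ll = ll, beta = beta, scale = scale)
}

# 2x2 SPD matrix from log-Cholesky parameters; with `fix11` the (1,1)
# Cholesky entry is pinned at 1 (overall scale profiled elsewhere).
par_to_spd2 <- function(p, fix11 = FALSE) {
  Lm <- if (fix11) {
    matrix(c(1, p[1], 0, exp(p[2])), 2, 2)
  } else {
    matrix(c(exp(p[1]), p[2], 0, exp(p[3])), 2, 2)
  }
  Lm %*% t(Lm)
}

# Minimize `fn` over shape parameters from deterministic starts plus random
# perturbations; Nelder-Mead with a BFGS polish for higher dimensions.
optimize_shape <- function(fn, starts, restarts, seed, sd = 1) {
  np <- length(starts[[1]])
  if (np == 1L) {
    opt <- stats::optimize(function(p) fn(p), c(-25, 25), tol = 1e-8)
    if (!is.finite(opt$objective) || opt$objective >= 1e10)
      stopf("shape optimization failed (1-D)")
    return(list(par = opt$minimum, value = opt$objective))
  }
  with_seed(seed, {
    all_starts <- starts
    for (r in seq_len(restarts)) {
      all_starts[[length(all_starts) + 1L]] <-
        starts[[1]] + stats::rnorm(np, sd = sd)
    }
    best <- NULL
    trace <- character(0)
    for (s in all_starts) {
      fit <- tryCatch(
        stats::optim(s, fn, method = "Nelder-Mead",
                     control = list(maxit = 800, reltol = 1e-8)),
        error = function(e) {
          trace <<- c(trace, conditionMessage(e)); NULL
        })
      if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e10) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    if (!is.null(best) && np >= 5L) {
      pol <- tryCatch(
        stats::optim(best$par, fn, method = "BFGS",
                     control = list(maxit = 200)),
        error = function(e) NULL)
      if (!is.null(pol) && is.finite(pol$value) && pol$value < best$value)
        best <- pol
    }
    if (is.null(best))
      stopf("shape optimization failed in all restarts:\n%s",
            paste(unique(trace), collapse = "\n"))
    best
  })
}

#' Fit a BM or OU model of trait evolution on a painted tree
#'
#' Maximum-likelihood fit of the (possibly multi-regime) model implied by the
#' regime painting of `simmap`: BM estimates one diffusion rate per regime
#' (a 2x2 rate matrix per regime for bivariate traits) and a shared root
#' state; OU estimates one optimum per regime with shared attraction strength
#' and rate (diagonal alpha and a full 2x2 rate matrix for bivariate traits).
#' Optima / root states and the overall rate scale are profiled out by
#' generalized least squares; the remaining shape parameters (log alpha, rate
#' ratios, rate-matrix shape) are optimized numerically from deterministic
#' grids plus random restarts.
#'
#' @param simmap a regime-painted tree ([as_simmap()]; use
#'   [paint_constant()] for single-regime fits).
#' @param traits named numeric vector (univariate) or tips x 2 matrix with
#'   tip rownames (bivariate).
#' @param family `"BM"` or `"OU"`.
#' @param restarts extra random starts for the shape optimization
#'   (default 5; single-regime univariate BM is closed form and OU uses a
#'   deterministic log-alpha grid, so restarts only matter for
#'   higher-dimensional shapes).
#' @param alpha_bounds OU attraction-strength bounds; default
#'   `c(1e-4, 50) / tree height`.
#' @param stationary_root use the stationary-root OU variant (default FALSE).
#' @param seed integer seed for the random restarts.
#' @return object of class `evomodel`.
#' @examples
#' cfg <- synthetic_config(seed = 7, n_taxa = 20)
#' tr <- generate_tree(cfg)
#' map <- paint_constant(tr)
#' y <- simulate_traits(map, list(family = "BM", sigma2 = 1, root_state = 0),
#'                      seed = 1)[1, ]
#' fit <- fit_evomodel(map, y, family = "BM")
#' coef(fit)
#' @export
fit_evomodel <- function(simmap, traits, family = c("BM", "OU"),
                         restarts = 5L, alpha_bounds = NULL,
                         stationary_root = FALSE, seed = NULL) {
  family <- match.arg(family)
  sm <- simmap_summary(simmap)
  st <- sm$states
  R <- length(st)
  n_traits <- if (is.matrix(traits) && ncol(traits) == 2L) 2L else 1L
  y <- align_traits(traits, sm$tips, n_traits)
  if (!all(is.finite(y))) stopf("traits must be finite")
  if (sm$ntip < 5L) stopf("need at least 5 tips")
  n <- sm$ntip * n_traits
  h <- max(sm$T)
  if (is.null(alpha_bounds)) alpha_bounds <- c(1e-4, 50) / h
  ones <- rep(1, sm$ntip)

  if (family == "BM" && n_traits == 1L) {
    if (R == 1L) {
      g <- gls_profile(sm$S[[1]], cbind(ones), y)
      est <- list(sigma2 = stats::setNames(g$scale, st),
                  root_state = unname(g$beta[1]))
      return(new_evomodel(simmap, family, n_traits, est, g$ll, k = 2L, n = n,
                          traits = traits, stationary_root = stationary_root))
    }
    negll <- function(p) {
      if (any(abs(p) > 25)) return(1e10)
      w <- c(1, exp(p))
      V0 <- Reduce(`+`, Map(function(j) w[j] * sm$S[[j]], seq_len(R)))
      ll <- gls_profile(V0, cbind(ones), y, want_beta = FALSE)$ll
      if (!is.finite(ll)) 1e10 else -ll
    }
    sol <- optimize_shape(negll, list(rep(0, R - 1)), restarts, seed, sd = 1.5)
    w <- c(1, exp(sol$par))
    V0 <- Reduce(`+`, Map(function(j) w[j] * sm$S[[j]], seq_len(R)))
    g <- gls_profile(V0, cbind(ones), y)
    est <- list(sigma2 = stats::setNames(g$scale * w, st),
                root_state = unname(g$beta[1]))
    return(new_evomodel(simmap, family, n_traits, est, g$ll, k = R + 1L,
                        n = n, traits = traits,
                        stationary_root = stationary_root))
  }

  if (family == "BM" && n_traits == 2L) {
    X <- kronecker(diag(2), cbind(ones))
    np <- 3L * R - 1L
    # warm start from the two univariate fits: per-regime diagonal rates
    warm <- tryCatch({
      u1 <- fit_evomodel(simmap, traits[, 1], "BM", restarts = 0L)
      u2 <- fit_evomodel(simmap, traits[, 2], "BM", restarts = 0L)
      s1 <- u1$estimates$sigma2[st]; s2 <- u2$estimates$sigma2[st]
      p0 <- c(0, 0.5 * log(s2[1] / s1[1]))
      if (R > 1L) for (j in 2:R) {
        p0 <- c(p0, 0.5 * log(s1[j] / s1[1]), 0, 0.5 * log(s2[j] / s1[1]))
      }
      pmin(pmax(p0, -10), 10)
    }, error = function(e) rep(0, np))
    build_Rl <- function(p) {
      Rl <- vector("list", R)
      Rl[[1]] <- par_to_spd2(p[1:2], fix11 = TRUE)
      if (R > 1L) for (j in 2:R) {
        Rl[[j]] <- par_to_spd2(p[3 * j - 4L + 1:3], fix11 = FALSE)
      }
      names(Rl) <- st
      Rl
    }
    negll <- function(p) {
      if (any(abs(p) > 25)) return(1e10)
      V0 <- bm_bivariate_vcv(sm, build_Rl(p))
      ll <- gls_profile(V0, X, y, want_beta = FALSE)$ll
      if (!is.finite(ll)) 1e10 else -ll
    }
    sol <- optimize_shape(negll, list(warm), restarts, seed, sd = 0.75)
    Rl <- build_Rl(sol$par)
    g <- gls_profile(bm_bivariate_vcv(sm, Rl), X, y)
    est <- list(sigma2 = lapply(Rl, function(M) g$scale * M),
                root_state = stats::setNames(as.numeric(g$beta),
                                             c("trait1", "trait2")))
    return(new_evomodel(simmap, family, n_traits, est, g$ll, k = 3L * R + 2L,
                        n = n, traits = traits,
                        stationary_root = stationary_root))
  }

  if (family == "OU" && n_traits == 1L) {
    prof <- function(la, want_beta = FALSE) {
      a <- exp(la)
      V0 <- ou_vcv_shape(sm, a, stationary_root)
      gls_profile(V0, ou_weight_matrix(sm, a), y, want_beta = want_beta)
    }
    lb <- log(alpha_bounds)
    grid <- seq(lb[1], lb[2], length.out = 15L)
    lls <- vapply(grid, function(la) prof(la)$ll, numeric(1))
    i <- which.max(lls)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    opt <- stats::optimize(function(la) -prof(la)$ll, c(lo, hi), tol = 1e-7)
    la <- opt$minimum
    g <- prof(la, want_beta = TRUE)
    theta <- stats::setNames(as.numeric(g$beta), st)
    est <- list(alpha = exp(la), sigma2 = g$scale, theta = theta)
    return(new_evomodel(simmap, family, n_traits, est, g$ll, k = R + 2L,
                        n = n, traits = traits,
                        stationary_root = stationary_root))
  }

  # OU bivariate: p = (log a1, log a2, rate-matrix shape b, c)
  X_of <- function(a2) {
    W1 <- ou_weight_matrix(sm, a2[1])
    W2 <- ou_weight_matrix(sm, a2[2])
    rbind(cbind(W1, matrix(0, sm$ntip, R)),
          cbind(matrix(0, sm$ntip, R), W2))
  }
  lb <- log(alpha_bounds)
  negll <- function(p) {
    if (any(p[1:2] < lb[1] | p[1:2] > lb[2]) || any(abs(p[3:4]) > 25))
      return(1e10)
    a2 <- exp(p[1:2])
    R0 <- par_to_spd2(p[3:4], fix11 = TRUE)
    V0 <- ou_vcv_bivariate(sm, a2, R0, stationary_root)
    ll <- gls_profile(V0, X_of(a2), y, want_beta = FALSE)$ll
    if (!is.finite(ll)) 1e10 else -ll
  }
  # warm start from the two univariate OU fits
  warm <- tryCatch({
    u1 <- fit_evomodel(simmap, traits[, 1], "OU", restarts = 0L,
                       alpha_bounds = alpha_bounds,
                       stationary_root = stationary_root)
    u2 <- fit_evomodel(simmap, traits[, 2], "OU", restarts = 0L,
                       alpha_bounds = alpha_bounds,
                       stationary_root = stationary_root)
    c(log(u1$estimates$alpha), log(u2$estimates$alpha), 0,
      min(10, max(-10, 0.5 * log(u2$estimates$sigma2 / u1$estimates$sigma2))))
  }, error = function(e) c(mean(lb), mean(lb), 0, 0))
  sol <- optimize_shape(negll, list(warm), restarts, seed, sd = 0.75)
  a2 <- exp(sol$par[1:2])
  R0 <- par_to_spd2(sol$par[3:4], fix11 = TRUE)
  g <- gls_profile(ou_vcv_bivariate(sm, a2, R0, stationary_root), X_of(a2), y)
  theta <- matrix(as.numeric(g$beta), R, 2,
                  dimnames = list(st, c("trait1", "trait2")))
  est <- list(alpha = a2, sigma2 = g$scale * R0, theta = theta)
  new_evomodel(simmap, family, n_traits, est, g$ll, k = 2L * R + 5L, n = n,
               traits = traits, stationary_root = stationary_root)
}

new_evomodel <- function(simmap, family, n_traits, est, ll, k, n, traits,
                         stationary_root = FALSE) {
  st <- simmap_states(simmap)
  params <- c(list(family = family, stationary_root = stationary_root), est)
  out <- list(family = family, label = sprintf("%s%d", family, length(st)),
              regimes = st, n_regimes = length(st), n_traits = n_traits,
              estimates = est, params = params, log_likelihood = ll,
              k = as.integer(k), n = as.integer(n), simmap = simmap,
              traits = traits)
  class(out) <- "evomodel"
  out
}

#' @export
print.evomodel <- function(x, ...) {
  cat(sprintf("%s model (%s), %d regime(s), %d trait(s), %d tips\n",
              x$family,
              if (x$family == "OU") "selective optima per regime"
              else "diffusion rate per regime",
              x$n_regimes, x$n_traits, length(x$simmap$tip.label)))
  cat(sprintf("logLik = %.4f  k = %d  n = %d  AICc = %.4f\n",
              x$log_likelihood, x$k, x$n,
              aicc(x$log_likelihood, x$k, x$n)))
  invisible(x)
}

#' @export
summary.evomodel <- function(object, ...) {
  print(object)
  cat("\nEstimates:\n")
  utils::str(object$estimates, digits.d = 4, give.attr = FALSE)
  invisible(object)
}

#' @export
coef.evomodel <- function(object, ...) {
  unlist(object$estimates)
}

#' @export
logLik.evomodel <- function(object, ...) {
  structure(object$log_likelihood, df = object$k, nobs = object$n,
            class = "logLik")
}

#' @export
fitted.evomodel <- function(object, ...) {
  model_moments(object$simmap, object$family, object$params)$mean
}

#' @export
residuals.evomodel <- function(object, ...) {
  y <- align_traits(object$traits, object$simmap$tip.label, object$n_traits)
  mom <- model_moments(object$simmap, object$family, object$params)
  stats::setNames(y - mom$mean, names(mom$mean))
}

#' @export
simulate.evomodel <- function(object, nsim = 1, seed = NULL, ...) {
  simulate_traits(object$simmap, object$params, nsim = nsim, seed = seed)
}

#' Small-sample corrected AIC
#'
#' `AIC = -2 logL + 2k`, plus the correction `2k(k+1)/(n-k-1)` where `k` is
#' the number of estimated parameters and `n` the number of species times the
#' number of variables analysed.
#'
#' @param log_likelihood maximized log-likelihood.
#' @param k number of free parameters.
#' @param n effective sample size (tips x traits).
#' @return AICc value.
#' @export
aicc <- function(log_likelihood, k, n) {
  if (n <= k + 1) stopf("AICc undefined: n (%s) must exceed k + 1 (%s)",
                        n, k + 1)
  -2 * log_likelihood + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights over a model set
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta = AICc - min(AICc)`.
#'
#' @param aicc_values numeric vector of AICc values.
#' @return weights summing to 1 (names preserved).
#' @export
akaike_weights <- function(aicc_values) {
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Fit and compare the six niche-evolution models
#'
#' Fits BM1 and OU1 (one regime across the tree), BM3 and OU3 (regimes from a
#' pollination-mode stochastic map) and BM4 and OU4 (regimes from an island
#' stochastic map) on the same trait data and compares them by AICc weight.
#'
#' @param traits named numeric vector or tips x 2 matrix.
#' @param tree plain `phylo` tree (for the single-regime models).
#' @param pollination_map,island_map painted trees on the same topology and
#'   branch lengths; either may be NULL to skip the corresponding models.
#' @param restarts,stationary_root,seed passed to [fit_evomodel()].
#' @return object of class `evomodel_set`: data.frame (model, family,
#'   regimes, logLik, k, n, AICc, weight) with the fitted `evomodel`s in
#'   attribute `"fits"`.
#' @export
fit_model_set <- function(traits, tree, pollination_map = NULL,
                          island_map = NULL, restarts = 5L,
                          stationary_root = FALSE, seed = NULL) {
  base_map <- if (inherits(tree, "simmap")) tree else
    cache_simmap_summary(paint_constant(tree))
  specs <- list(list(label = "BM1", family = "BM", map = base_map),
                list(label = "OU1", family = "OU", map = base_map))
  if (!is.null(pollination_map)) {
    pollination_map <- cache_simmap_summary(pollination_map)
    specs <- c(specs, list(
      list(label = "BM3", family = "BM", map = pollination_map),
      list(label = "OU3", family = "OU", map = pollination_map)))
  }
  if (!is.null(island_map)) {
    island_map <- cache_simmap_summary(island_map)
    specs <- c(specs, list(
      list(label = "BM4", family = "BM", map = island_map),
      list(label = "OU4", family = "OU", map = island_map)))
  }
  fits <- vector("list", length(specs))
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    f <- fit_evomodel(s$map, traits, family = s$family, restarts = restarts,
                      stationary_root = stationary_root,
                      seed = if (is.null(seed)) NULL
                             else derive_seed(seed, s$label))
    fits[[i]] <- f
    rows[[i]] <- data.frame(model = s$label, family = s$family,
                            regimes = f$n_regimes,
                            logLik = f$log_likelihood, k = f$k, n = f$n,
                            AICc = aicc(f$log_likelihood, f$k, f$n),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$weight <- akaike_weights(out$AICc)
  names(fits) <- out$model
  attr(out, "fits") <- fits
  class(out) <- c("evomodel_set", "data.frame")
  out
}

#' @export
print.evomodel_set <- function(x, ...) {
  df <- as.data.frame(x)
  df$logLik <- round(df$logLik, 3)
  df$AICc <- round(df$AICc, 3)
  df$weight <- round(df$weight, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
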