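#' Configuration for the synthetic-data generators
#'
#' Collects and validates the knobs of the synthetic inputs: a low-rank
#' correlated environmental raster whose first `latent_dim` principal
#' components dominate, Gaussian species niches in PC space that generate
#' occurrence records, birth-death trees with pseudo-posterior branch-length
#' perturbation, Mk regime histories, and regime-dependent BM/OU trait values.
#'
#' @param seed integer root seed; every generator is a pure function of
#'   (config, seed).
#' @param n_pixels number of raster pixels (background points).
#' @param n_env_vars number of environmental variables (default 20: altitude
#'   plus 19 bioclim-style layers).
#' @param latent_dim rank of the latent environmental signal (default 2).
#' @param noise_sd standard deviation of the per-variable independent noise
#'   added on top of the latent mixture (signal factors have unit variance).
#' @param island_offset_sd spread of the per-island mean shift in latent
#'   space; distinct offsets make "same island implies more similar available
#'   environment" an injectable, known effect.
#' @param n_species number of plant species.
#' @param n_occurrences_per_species integer vector of length 2: range
#'   (min, max) of records per species.
#' @param n_taxa number of tree tips.
#' @param birth_rate,death_rate birth-death rates (death < birth).
#' @param tree_depth root-to-tip height of the (ultrametric) tree.
#' @param branch_perturb_sd lognormal sd of node-age perturbation used to
#'   emulate a posterior sample of trees.
#' @param n_trees number of perturbed trees.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_pixels = 3458L, n_env_vars = 20L,
                             latent_dim = 2L, noise_sd = 0.9,
                             island_offset_sd = 1.0, n_species = 35L,
                             n_occurrences_per_species = c(6L, 116L),
                             n_taxa = 35L, birth_rate = 1.0, death_rate = 0.5,
                             tree_depth = 1.0, branch_perturb_sd = 0.1,
                             n_trees = 1000L) {
  cfg <- list(
    seed = check_count(seed, "seed", min = 0L),
    n_pixels = check_count(n_pixels, "n_pixels"),
    n_env_vars = check_count(n_env_vars, "n_env_vars"),
    latent_dim = check_count(latent_dim, "latent_dim"),
    noise_sd = check_pos(noise_sd, "noise_sd"),
    island_offset_sd = as.numeric(island_offset_sd),
    n_species = check_count(n_species, "n_species"),
    n_occurrences_per_species = as.integer(n_occurrences_per_species),
    n_taxa = check_count(n_taxa, "n_taxa", min = 3L),
    birth_rate = check_pos(birth_rate, "birth_rate"),
    death_rate = as.numeric(death_rate),
    tree_depth = check_pos(tree_depth, "tree_depth"),
    branch_perturb_sd = as.numeric(branch_perturb_sd),
    n_trees = check_count(n_trees, "n_trees")
  )
  if (cfg$island_offset_sd < 0) stopf("'island_offset_sd' must be >= 0")
  if (cfg$death_rate < 0) stopf("'death_rate' must be >= 0")
  if (cfg$death_rate >= cfg$birth_rate)
    stopf("'death_rate' must be smaller than 'birth_rate'")
  if (cfg$branch_perturb_sd < 0) stopf("'branch_perturb_sd' must be >= 0")
  if (length(cfg$n_occurrences_per_species) != 2L ||
      any(cfg$n_occurrences_per_species < 1L))
    stopf("'n_occurrences_per_species' must be a (min, max) pair >= 1")
  if (cfg$n_pixels < cfg$n_env_vars)
    stopf("n_pixels (%d) must be >= n_env_vars (%d): the correlation PCA is degenerate otherwise",
          cfg$n_pixels, cfg$n_env_vars)
  class(cfg) <- "synthetic_config"
  cfg
}

# The four retained islands, in decreasing order of (approximate) land share.
island_names <- function() c("Cuba", "Hispaniola", "Jamaica", "PuertoRico")

#' Generate a synthetic background environmental raster
#'
#' Pixels carry `n_env_vars` environmental variables built as linear mixtures
#' of `latent_dim` latent factors plus independent Gaussian noise, so a
#' correlation-matrix PCA concentrates variance on the first `latent_dim`
#' axes. Pixels are partitioned into four contiguous island blocks of unequal
#' sizes, each with its own mean shift in latent space.
#'
#' @param cfg a [synthetic_config()].
#' @return data.frame of class `env_raster`: `pixel_id`, `lon`, `lat`,
#'   `island`, then `env_01 ... env_k`.
#' @export
generate_raster <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(derive_seed(cfg$seed, "raster"), {
    p <- cfg$n_pixels
    shares <- c(0.45, 0.32, 0.13, 0.10)
    counts <- diff(round(cumsum(c(0, shares)) * p))
    counts[4] <- p - sum(counts[1:3])
    island <- rep(island_names(), counts)
    offsets <- matrix(rnorm(4 * cfg$latent_dim, sd = cfg$island_offset_sd),
                      4, cfg$latent_dim,
                      dimnames = list(island_names(), NULL))
    Z <- matrix(rnorm(p * cfg$latent_dim), p, cfg$latent_dim) +
      offsets[island, , drop = FALSE]
    A <- matrix(rnorm(cfg$n_env_vars * cfg$latent_dim),
                cfg$n_env_vars, cfg$latent_dim)
    X <- Z %*% t(A) + matrix(rnorm(p * cfg$n_env_vars, sd = cfg$noise_sd),
                             p, cfg$n_env_vars)
    colnames(X) <- sprintf("env_%02d", seq_len(cfg$n_env_vars))
    # Lay each island out as its own rectangular lon/lat block.
    lon0 <- c(-85, -75, -78.5, -67.5)
    lat0 <- c(19.5, 17.5, 17.7, 17.9)
    lon <- lat <- numeric(p)
    at <- 1L
    for (k in seq_len(4)) {
      nk <- counts[k]
      ncol_k <- ceiling(sqrt(nk * 2))
      ix <- seq_len(nk) - 1L
      lon[at:(at + nk - 1L)] <- lon0[k] + (ix %% ncol_k) * 0.1
      lat[at:(at + nk - 1L)] <- lat0[k] + (ix %/% ncol_k) * 0.1
      at <- at + nk
    }
    out <- data.frame(pixel_id = seq_len(p), lon = lon, lat = lat,
                      island = island, stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(X))
    class(out) <- c("env_raster", "data.frame")
    out
  })
}

#' Simulate an ultrametric birth-death tree
#'
#' Wraps [ape::rphylo()] (conditioned on the number of tips) and rescales the
#' result to `tree_depth`.
#'
#' @param cfg a [synthetic_config()].
#' @return a rooted, ultrametric, binary `phylo` tree with `n_taxa` tips
#'   labelled `sp01, sp02, ...`.
#' @export
generate_tree <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(derive_seed(cfg$seed, "tree"), {
    tr <- ape::rphylo(cfg$n_taxa, birth = cfg$birth_rate,
                      death = cfg$death_rate, T0 = 10)
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * cfg$tree_depth / depth
    tr$tip.label <- sprintf("sp%02d", seq_len(cfg$n_taxa))
    tr
  })
}

#' Perturb branch lengths to emulate a posterior sample of trees
#'
#' Internal node ages are multiplied by independent lognormal noise (sd
#' `branch_perturb_sd`) and clamped below their parent's age, keeping every
#' tree ultrametric with the same depth and topology. With sd 0 all trees are
#' identical to the input.
#'
#' @param tree an ultrametric `phylo` tree.
#' @param cfg a [synthetic_config()] (uses `n_trees`, `branch_perturb_sd`,
#'   `seed`).
#' @return a `multiPhylo` list of `n_trees` trees.
#' @export
perturb_trees <- function(tree, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  ntip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  H <- max(depth)
  age <- H - depth # time before present; tips ~0, root = H
  ord <- reorder_edges_preorder(tree)
  with_seed(derive_seed(cfg$seed, "perturb"), {
    out <- vector("list", cfg$n_trees)
    for (r in seq_len(cfg$n_trees)) {
      a <- age
      if (cfg$branch_perturb_sd > 0) {
        for (i in ord) {
          par <- tree$edge[i, 1L]; ch <- tree$edge[i, 2L]
          if (ch > ntip) { # internal node: jitter its age below the parent's
            prop <- a[ch] * exp(rnorm(1, 0, cfg$branch_perturb_sd))
            a[ch] <- min(prop, 0.99 * a[par])
          }
        }
      }
      tr <- tree
      tr$edge.length <- a[tree$edge[, 1L]] - a[tree$edge[, 2L]]
      out[[r]] <- tr
    }
    class(out) <- "multiPhylo"
    out
  })
}

#' Simulate a discrete character along a tree (forward Mk)
#'
#' Draws the root state from `root_freq`, then evolves a continuous-time
#' Markov chain with generator `Q` along every branch, recording each
#' transition time. The painted history is an exact draw from the model, so
#' it doubles as the ground truth for stochastic-mapping tests.
#'
#' @param tree a `phylo` tree.
#' @param Q transition-rate matrix (rows sum to 0, off-diagonals >= 0) with
#'   state names as dimnames.
#' @param root_freq probability vector over states at the root.
#' @param seed integer seed.
#' @return list with `tip_states` (named character vector) and `history`
#'   (a [as_simmap()] painted tree).
#' @export
simulate_mk <- function(tree, Q, root_freq, seed = NULL) {
  check_Q(Q)
  states <- rownames(Q)
  k <- length(states)
  if (length(root_freq) != k || abs(sum(root_freq) - 1) > 1e-9)
    stopf("'root_freq' must be a length-%d probability vector", k)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  with_seed(seed, {
    node_state <- integer(nn)
    node_state[ntip + 1L] <- sample.int(k, 1L, prob = root_freq)
    maps <- vector("list", nrow(tree$edge))
    for (i in reorder_edges_preorder(tree)) {
      par <- tree$edge[i, 1L]; ch <- tree$edge[i, 2L]
      len <- tree$edge.length[i]
      s <- node_state[par]
      segs <- numeric(0); labs <- character(0)
      t <- 0
      repeat {
        rate <- -Q[s, s]
        dt <- if (rate > 0) rexp(1, rate) else Inf
        if (t + dt >= len) {
          segs <- c(segs, len - t); labs <- c(labs, states[s])
          break
        }
        segs <- c(segs, dt); labs <- c(labs, states[s])
        t <- t + dt
        probs <- Q[s, ]; probs[s] <- 0
        s <- sample.int(k, 1L, prob = probs)
      }
      maps[[i]] <- stats::setNames(segs, labs)
      node_state[ch] <- s
    }
    hist <- as_simmap(tree, maps, states[node_state])
    list(tip_states = hist$states, history = hist)
  })
}

#' Sample species occurrence records from Gaussian niches in PC space
#'
#' For each species, background pixels are sampled (with replacement, so
#' pixels can hold several records, as herbarium data do) with probability
#' proportional to an isotropic Gaussian density centred on the species'
#' niche centre in the 2-D ordination space. Optionally the candidate pixels
#' are restricted to the species' islands, which injects the
#' "same island implies more similar realized niche" effect through shared
#' environmental availability.
#'
#' @param space an [fit_env_space()] object.
#' @param raster the background `env_raster` the space was fitted on.
#' @param niche_centers matrix (species x 2) of niche centres in (PC1, PC2),
#'   with species rownames; centres must lie inside the bounding box of the
#'   background scores.
#' @param niche_sds per-species positive isotropic niche sd (length 1 or
#'   nrow(niche_centers)); 0 selects the single nearest pixel.
#' @param n_per_species records per species (length 1 or n species).
#' @param islands optional named list (by species) of island subsets to
#'   sample from.
#' @param precision_km coordinate precision attached to each record.
#' @param seed integer seed.
#' @return data.frame of class `occurrence_table` with columns `species`,
#'   `lon`, `lat`, `coordinate_precision_km`, `pixel_id`, `island`.
#' @export
generate_occurrences <- function(space, raster, niche_centers, niche_sds,
                                 n_per_species, islands = NULL,
                                 precision_km = 5, seed = NULL) {
  stopifnot(inherits(space, "env_space"))
  sp <- rownames(niche_centers)
  if (is.null(sp)) stopf("'niche_centers' must have species rownames")
  ns <- nrow(niche_centers)
  niche_sds <- rep_len(niche_sds, ns)
  n_per_species <- rep_len(as.integer(n_per_species), ns)
  if (any(n_per_species < 1L)) stopf("'n_per_species' must be >= 1")
  if (any(niche_sds < 0)) stopf("'niche_sds' must be >= 0")
  bg <- space$background_scores
  lo <- apply(bg, 2, min); hi <- apply(bg, 2, max)
  bad <- niche_centers[, 1] < lo[1] | niche_centers[, 1] > hi[1] |
    niche_centers[, 2] < lo[2] | niche_centers[, 2] > hi[2]
  if (any(bad))
    stopf("niche centre(s) outside the background score hull: %s",
          paste(sp[bad], collapse = ", "))
  with_seed(seed, {
    recs <- vector("list", ns)
    for (i in seq_len(ns)) {
      keep <- if (!is.null(islands) && !is.null(islands[[sp[i]]])) {
        which(raster$island %in% islands[[sp[i]]])
      } else seq_len(nrow(bg))
      d2 <- (bg[keep, 1] - niche_centers[i, 1])^2 +
        (bg[keep, 2] - niche_centers[i, 2])^2
      if (niche_sds[i] > 0) {
        lw <- -0.5 * d2 / niche_sds[i]^2
        w <- exp(lw - max(lw))
        pick <- keep[sample.int(length(keep), n_per_species[i],
                                replace = TRUE, prob = w)]
      } else {
        pick <- rep(keep[which.min(d2)], n_per_species[i])
      }
      recs[[i]] <- data.frame(
        species = sp[i],
        lon = raster$lon[pick], lat = raster$lat[pick],
        coordinate_precision_km = precision_km,
        pixel_id = raster$pixel_id[pick],
        island = raster$island[pick],
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    class(out) <- c("occurrence_table", "data.frame")
    out
  })
}

#' Simulate tip trait values on a painted tree
#'
#' Draws tip traits exactly from the multivariate normal implied by the
#' painted BM or OU model, using the same moment construction
#' ([model_moments()]) as the likelihood code: one source of truth, no
#' Euler-discretized SDE paths.
#'
#' @param history a `simmap` painted tree.
#' @param params model parameter list as in [model_moments()]: must contain
#'   `family` ("BM" or "OU") plus `sigma2`, `root_state` (BM) or `alpha`,
#'   `sigma2`, `theta` (OU).
#' @param nsim number of replicate draws.
#' @param seed integer seed.
#' @return for univariate models a matrix (nsim x tips); for bivariate a
#'   list of `nsim` matrices (tips x 2).
#' @export
simulate_traits <- function(history, params, nsim = 1L, seed = NULL) {
  mom <- model_moments(history, params$family, params)
  ntip <- length(history$tip.label)
  with_seed(seed, {
    draws <- MASS::mvrnorm(nsim, mu = mom$mean, Sigma = mom$cov)
    if (nsim == 1L) draws <- matrix(draws, 1L, dimnames = list(NULL, names(mom$mean)))
    if (mom$n_traits == 1L) return(draws)
    lapply(seq_len(nsim), function(r) {
      matrix(draws[r, ], ntip, 2,
             dimnames = list(history$tip.label, mom$trait_names))
    })
  })
}
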