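#' The eight trait sets analysed by the replicate engine
#'
#' Niche identity and breadth on each ordination axis, analysed separately
#' (univariate) and jointly (bivariate).
#'
#' @return named list mapping trait-set label to niche-table column names.
#' @export
default_trait_sets <- function() {
  list("identity_PC1" = "identity_PC1",
       "identity_PC2" = "identity_PC2",
       "identity_PC1+PC2" = c("identity_PC1", "identity_PC2"),
       "breadth_PC1" = "breadth_PC1",
       "breadth_PC2" = "breadth_PC2",
       "breadth_PC1+PC2" = c("breadth_PC1", "breadth_PC2"),
       "identity+breadth_PC1" = c("identity_PC1", "breadth_PC1"),
       "identity+breadth_PC2" = c("identity_PC2", "breadth_PC2"))
}

# Jackknife: keep a random half (at least 2) of each species' deduplicated
# presence records.
jackknife_occurrences <- function(occ, seed = NULL) {
  with_seed(seed, {
    keep <- unlist(lapply(split(seq_len(nrow(occ)), occ$species), function(ix) {
      m <- max(2L, floor(length(ix) / 2))
      if (m >= length(ix)) ix else sort(sample(ix, m))
    }), use.names = FALSE)
    occ[sort(keep), , drop = FALSE]
  })
}

#' Propagate niche and phylogenetic uncertainty through model selection
#'
#' The replicate engine behind the headline model-comparison table: per
#' iteration it takes the next tree from the posterior-style sample,
#' jackknifes 50% of each species' deduplicated presence records, recomputes
#' niche identity and breadth, re-draws the single-island assignment for
#' multi-island species, refits the Mk models (all-rates-different for
#' pollination mode, symmetric for island) and draws one stochastic map for
#' each regime source, fits the six evolution models on every trait set, and
#' records the per-iteration AICc weights. The summary reports the mean
#' weight and the empirical 2.5%/97.5% percentile interval per model and
#' trait set.
#'
#' @param trees a `multiPhylo` list (or single `phylo`) of trees; iteration
#'   `i` uses tree `1 + (i-1) mod length(trees)`.
#' @param occ filtered occurrence table (deduplicated internally).
#' @param metadata species metadata: `species`, `pollination_mode`,
#'   `mode_status`, `islands` (";"-separated).
#' @param space fitted [fit_env_space()] ordination.
#' @param raster background raster table.
#' @param n_iterations number of (tree, jackknife) iterations (default 1000;
#'   tree `i` is paired with jackknife `i`, not crossed).
#' @param trait_sets named list of niche-table column subsets (1 or 2 each);
#'   default [default_trait_sets()].
#' @param seed root seed; all per-iteration draws derive from it.
#' @param evo_restarts,mk_restarts random restarts for the trait-model and
#'   Mk fits within each iteration (defaults 0 and 1: per-iteration trait
#'   fits are warm-started from univariate solutions and deterministic
#'   grids, which reaches the same optima deterministically; raise for final
#'   production runs).
#' @param stationary_root OU root variant flag, passed through.
#' @param max_failure_rate abort when more than this fraction of iterations
#'   fails (default 0.1).
#' @return object of class `replicate_summary`: list with `$summary` (mean
#'   weight and CI per trait set x model), `$iterations` (per-iteration
#'   weights, long format) and `$config`.
#' @export
run_replicates <- function(trees, occ, metadata, space, raster,
                           n_iterations = 1000L,
                           trait_sets = default_trait_sets(), seed = 1L,
                           evo_restarts = 0L, mk_restarts = 1L,
                           stationary_root = FALSE,
                           max_failure_rate = 0.1) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  n_iterations <- check_count(n_iterations, "n_iterations")
  occ <- dedupe_per_pixel(occ)
  bad <- vapply(trait_sets, function(ts) length(ts) < 1L || length(ts) > 2L,
                logical(1))
  if (any(bad)) stopf("trait sets must have 1 or 2 traits")
  poll_states <- c("hummingbird", "bat", "mixed")
  isl_states <- sort(unique(unlist(strsplit(as.character(metadata$islands),
                                            ";", fixed = TRUE))))
  poll_priors <- build_tip_priors(metadata, states = poll_states)
  rows <- vector("list", n_iterations)
  failures <- character(0)
  for (i in seq_len(n_iterations)) {
    res <- tryCatch(
      replicate_once(trees[[1L + (i - 1L) %% length(trees)]], occ, metadata,
                     space, raster, trait_sets, poll_priors, isl_states,
                     iter_seed = derive_seed(seed, "iter", i),
                     evo_restarts = evo_restarts, mk_restarts = mk_restarts,
                     stationary_root = stationary_root),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <- c(failures, sprintf("iteration %d: %s", i, res))
      if (length(failures) > max_failure_rate * n_iterations)
        stopf("replicate engine aborted: %d/%d iterations failed.\n%s",
              length(failures), n_iterations,
              paste(utils::head(failures, 5), collapse = "\n"))
      next
    }
    res$iteration <- i
    rows[[i]] <- res
  }
  iters <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(iters, iters[, c("trait_set", "model")]),
                               function(d) {
    data.frame(trait_set = d$trait_set[1], model = d$model[1],
               mean_weight = mean(d$weight),
               ci_lo = unname(quantile(d$weight, 0.025)),
               ci_hi = unname(quantile(d$weight, 0.975)),
               n_iterations = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  out <- list(summary = agg, iterations = iters,
              failures = failures,
              config = list(n_iterations = n_iterations, seed = seed,
                            evo_restarts = evo_restarts,
                            mk_restarts = mk_restarts,
                            stationary_root = stationary_root,
                            n_trees = length(trees)))
  class(out) <- "replicate_summary"
  out
}

replicate_once <- function(tree, occ, metadata, space, raster, trait_sets,
                           poll_priors, isl_states, iter_seed, evo_restarts,
                           mk_restarts, stationary_root) {
  jk <- jackknife_occurrences(occ, seed = derive_seed(iter_seed, "jack"))
  niches <- species_niche(jk, space, raster)
  tab <- niches$table
  sp <- tab$species
  if (!all(sp %in% tree$tip.label))
    stopf("tree lacks tips for: %s",
          paste(setdiff(sp, tree$tip.label), collapse = ", "))
  if (length(setdiff(tree$tip.label, sp)) > 0L)
    tree <- ape::drop.tip(tree, setdiff(tree$tip.label, sp))
  md <- metadata[match(sp, metadata$species), , drop = FALSE]
  assign <- assign_single_island(md, seed = derive_seed(iter_seed, "island"))
  isl_priors <- island_tip_priors(assign, states = isl_states)
  poll_fit <- fit_mk(tree, poll_priors, constraint = "ARD",
                     n_restarts = mk_restarts,
                     seed = derive_seed(iter_seed, "mkpoll"))
  isl_fit <- fit_mk(tree, isl_priors, constraint = "SYM",
                    n_restarts = mk_restarts,
                    seed = derive_seed(iter_seed, "mkisl"))
  poll_map <- sample_stochastic_map(tree, poll_priors, model = poll_fit,
                                    seed = derive_seed(iter_seed, "mappoll"))
  isl_map <- sample_stochastic_map(tree, isl_priors, model = isl_fit,
                                   seed = derive_seed(iter_seed, "mapisl"))
  # precompute (and share) the per-map summaries across all trait sets
  base_map <- cache_simmap_summary(paint_constant(tree))
  poll_map <- cache_simmap_summary(poll_map)
  isl_map <- cache_simmap_summary(isl_map)
  out <- vector("list", length(trait_sets))
  for (j in seq_along(trait_sets)) {
    cols <- trait_sets[[j]]
    traits <- if (length(cols) == 1L) {
      stats::setNames(tab[[cols]], sp)
    } else {
      matrix(c(tab[[cols[1]]], tab[[cols[2]]]), ncol = 2,
             dimnames = list(sp, cols))
    }
    ms <- fit_model_set(traits, base_map, pollination_map = poll_map,
                        island_map = isl_map, restarts = evo_restarts,
                        stationary_root = stationary_root,
                        seed = derive_seed(iter_seed, "evo", j))
    out[[j]] <- data.frame(trait_set = names(trait_sets)[j],
                           model = ms$model, weight = ms$weight,
                           AICc = ms$AICc, logLik = ms$logLik, k = ms$k,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf(
    "Mean AICc weights over %d iterations (%d trees, 50%% jackknife)\n",
    x$config$n_iterations, x$config$n_trees))
  if (length(x$failures))
    cat(sprintf("(%d iteration(s) failed and were skipped)\n",
                length(x$failures)))
  print(format_weight_table(x), row.names = FALSE)
  invisible(x)
}

# Table-shaped rendering: trait sets as rows, models as columns,
# "mean [lo-hi]" cells.
format_weight_table <- function(x, digits = 2) {
  s <- x$summary
  models <- sort(unique(s$model))
  sets <- unique(s$trait_set)
  out <- data.frame(trait_set = sets, stringsAsFactors = FALSE)
  for (m in models) {
    cells <- vapply(sets, function(ts) {
      r <- s[s$trait_set == ts & s$model == m, ]
      if (nrow(r) == 0L) return("-")
      sprintf("%.*f [%.*f-%.*f]", digits, r$mean_weight, digits, r$ci_lo,
              digits, r$ci_hi)
    }, character(1))
    out[[m]] <- cells
  }
  out
}

#' @export
plot.replicate_summary <- function(x, trait_set = NULL, ...) {
  s <- x$summary
  if (is.null(trait_set)) trait_set <- s$trait_set[1]
  d <- s[s$trait_set == trait_set, ]
  graphics::barplot(stats::setNames(d$mean_weight, d$model),
                    ylab = "mean AICc weight", main = trait_set, ylim = c(0, 1),
                    ...)
  invisible(x)
}
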