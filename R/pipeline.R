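# End-to-end orchestration: synthetic dataset presets, file I/O in standard
# formats, the staged pipeline, and table-shaped reports.

#' Generate a complete synthetic study dataset
#'
#' The `"paper-shape"` preset emulates the shape of the Antillean study
#' system: a 3458-pixel background raster with 20 correlated environmental
#' variables over 4 islands, 35 plant species on an ultrametric 35-tip tree,
#' pollination modes (hummingbird / bat / mixed; mostly observed, some
#' inferred, one unknown) evolved along the tree under an
#' all-rates-different Mk process, island membership evolved under a
#' symmetric Mk process (a few species on two islands), niche centres
#' evolving under a single-optimum OU process in ordination space (the
#' generating model, so the pipeline's model selection has a known truth),
#' per-species niche widths, and occurrence records drawn from Gaussian
#' niches restricted to each species' islands.
#'
#' @param preset currently `"paper-shape"`.
#' @param seed integer root seed.
#' @param n_trees number of perturbed trees to emit (default 1000).
#' @param cfg optional [synthetic_config()] overriding the preset shape.
#' @return list of class `niche_dataset`: `raster`, `occurrences`,
#'   `metadata`, `pollinator_occurrences`, `pollinator_metadata`, `tree`,
#'   `trees`, `space`, `true_params`.
#' @export
simulate_dataset <- function(preset = "paper-shape", seed = 1L,
                             n_trees = 1000L, cfg = NULL) {
  if (!identical(preset, "paper-shape")) stopf("unknown preset '%s'", preset)
  if (is.null(cfg)) {
    cfg <- synthetic_config(seed = seed, n_pixels = 3458L, n_env_vars = 20L,
                            latent_dim = 2L, noise_sd = 0.9,
                            island_offset_sd = 1.0, n_species = 35L,
                            n_taxa = 35L, n_trees = n_trees)
  }
  raster <- generate_raster(cfg)
  space <- fit_env_space(raster)
  tree <- generate_tree(cfg)
  trees <- perturb_trees(tree, cfg)
  sp <- tree$tip.label

  # Pollination mode history: ARD-ish Mk from a hummingbird-specialist root.
  poll_states <- c("hummingbird", "bat", "mixed")
  Qp <- matrix(c(-1.2, 0.4, 0.8,
                 0.1, -0.4, 0.3,
                 0.3, 0.6, -0.9), 3, 3, byrow = TRUE,
               dimnames = list(poll_states, poll_states))
  poll <- simulate_mk(tree, Qp, root_freq = c(1, 0, 0),
                      seed = derive_seed(cfg$seed, "pollination"))
  # Island history: symmetric Mk, then a few species gain a second island.
  isl_states <- island_names()
  Qi <- matrix(0.4, 4, 4, dimnames = list(isl_states, isl_states))
  diag(Qi) <- -1.2
  isl <- simulate_mk(tree, Qi, root_freq = rep(0.25, 4),
                     seed = derive_seed(cfg$seed, "island"))
  # shares mirror the study system: ~4/35 species on two islands,
  # ~15/35 modes inferred from floral shape, one species unknown
  md <- with_seed(derive_seed(cfg$seed, "metadata"), {
    nsp <- length(sp)
    islands <- as.character(isl$tip_states[sp])
    two <- sample(seq_len(nsp), round(nsp * 4 / 35))
    for (i in two) {
      other <- sample(setdiff(isl_states, islands[i]), 1L)
      islands[i] <- paste(sort(c(islands[i], other)), collapse = ";")
    }
    status <- rep("observed", nsp)
    n_inf <- max(1L, round(nsp * 15 / 35))
    status[sample(seq_len(nsp), n_inf)] <- "inferred"
    unk <- sample(which(status == "inferred"), 1L)
    status[unk] <- "unknown"
    mode <- as.character(poll$tip_states[sp])
    mode[unk] <- "unknown"
    data.frame(species = sp, pollination_mode = mode, mode_status = status,
               islands = islands, stringsAsFactors = FALSE)
  })

  # Niche centres evolve under OU1 in (PC1, PC2); niche widths are
  # log-normal around 0.45 with a mild OU1 signal on the log scale.
  h <- cfg$tree_depth
  alpha0 <- log(2) / (0.25 * h) # phylogenetic half-life = quarter depth
  ou_var <- 0.8^2               # stationary sd 0.8 in score units
  base <- paint_constant(tree)
  centers <- sapply(1:2, function(axis) {
    simulate_traits(base, list(family = "OU", alpha = alpha0,
                               sigma2 = 2 * alpha0 * ou_var, theta = 0),
                    seed = derive_seed(cfg$seed, "center", axis))[1, ]
  })
  rownames(centers) <- sp
  # keep centres strictly inside the background score hull
  bg <- space$background_scores
  for (j in 1:2) {
    qs <- quantile(bg[, j], c(0.02, 0.98))
    centers[, j] <- pmin(pmax(centers[, j], qs[1]), qs[2])
  }
  log_sds <- simulate_traits(base, list(family = "OU", alpha = alpha0,
                                        sigma2 = 2 * alpha0 * 0.25^2,
                                        theta = log(0.45)),
                             seed = derive_seed(cfg$seed, "breadth"))[1, ]
  niche_sds <- exp(log_sds[sp])
  n_rec <- with_seed(derive_seed(cfg$seed, "counts"), {
    pmin(pmax(round(stats::rlnorm(length(sp), log(24), 0.55)),
              cfg$n_occurrences_per_species[1]),
         cfg$n_occurrences_per_species[2])
  })
  occurrences <- generate_occurrences(
    space, raster, centers, niche_sds, n_rec,
    islands = stats::setNames(strsplit(md$islands, ";", fixed = TRUE),
                              md$species),
    seed = derive_seed(cfg$seed, "occurrences"))

  # Pollinators: 14 hummingbird and 8 nectarivorous bat species with wide
  # niches spanning all islands, so plant niches sit inside the functional
  # groups' climatic envelopes.
  pol_md <- data.frame(
    species = c(sprintf("hum%02d", 1:14), sprintf("bat%02d", 1:8)),
    functional_group = rep(c("hummingbird", "bat"), c(14, 8)),
    stringsAsFactors = FALSE)
  pol <- with_seed(derive_seed(cfg$seed, "pollinators"), {
    # island ranges vary: about half the pollinators span all four islands
    # (several have distributions wider than the study area), the rest are
    # restricted to 1-3 islands
    pol_md$islands <- vapply(seq_len(nrow(pol_md)), function(i) {
      k <- sample(4, 1, prob = c(0.15, 0.2, 0.15, 0.5))
      paste(sort(sample(island_names(), k)), collapse = ";")
    }, character(1))
    bg <- space$background_scores
    ctr <- matrix(c(stats::rnorm(nrow(pol_md), mean(bg[, 1]), 0.4),
                    stats::rnorm(nrow(pol_md), mean(bg[, 2]), 0.4)),
                  ncol = 2, dimnames = list(pol_md$species, NULL))
    for (j in 1:2) {
      qs <- quantile(bg[, j], c(0.25, 0.75))
      ctr[, j] <- pmin(pmax(ctr[, j], qs[1]), qs[2])
    }
    list(centers = ctr,
         sds = stats::runif(nrow(pol_md), 1.0, 1.8),
         n = pmin(pmax(round(stats::rlnorm(nrow(pol_md), log(60), 0.9)), 8),
                  1219))
  })
  pol_occ <- generate_occurrences(
    space, raster, pol$centers, pol$sds, pol$n,
    islands = stats::setNames(strsplit(pol_md$islands, ";", fixed = TRUE),
                              pol_md$species),
    seed = derive_seed(cfg$seed, "polocc"))
  out <- list(raster = raster, occurrences = occurrences, metadata = md,
              pollinator_occurrences = pol_occ, pollinator_metadata = pol_md,
              tree = tree, trees = trees, space = space,
              true_params = list(
                niche_model = list(family = "OU", alpha = alpha0,
                                   sigma2 = 2 * alpha0 * ou_var, theta = 0),
                breadth_model = list(family = "OU", alpha = alpha0,
                                     sigma2 = 2 * alpha0 * 0.25^2,
                                     theta = log(0.45)),
                Q_pollination = Qp, Q_island = Qi,
                niche_centers = centers, niche_sds = niche_sds,
                config = cfg))
  class(out) <- "niche_dataset"
  out
}

#' @export
print.niche_dataset <- function(x, ...) {
  cat(sprintf(paste0("Synthetic niche dataset: %d pixels, %d species, ",
                     "%d occurrences, %d trees\n"),
              nrow(x$raster), length(x$tree$tip.label),
              nrow(x$occurrences), length(x$trees)))
  invisible(x)
}

# ---- readers / writers -------------------------------------------------

#' Read phylogenies from Newick or NEXUS files
#'
#' Dialect is sniffed from the file header (`#NEXUS`); translate tables are
#' honoured by the NEXUS reader.
#'
#' @param path file with one Newick tree per line, or a NEXUS trees block.
#' @return a `multiPhylo` list (possibly of length 1).
#' @export
read_trees <- function(path) {
  if (!file.exists(path)) stopf("tree file not found: %s", path)
  first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
  trees <- if (startsWith(first, "#NEXUS")) {
    ape::read.nexus(path)
  } else {
    ape::read.tree(path)
  }
  if (is.null(trees)) stopf("could not parse any tree from %s", path)
  if (inherits(trees, "phylo")) {
    trees <- structure(list(trees), class = "multiPhylo")
  }
  trees
}

#' Read an occurrence table
#'
#' @param path CSV with columns `species`, `lon`, `lat` and optionally
#'   `coordinate_precision_km`, `pixel_id`, `island`.
#' @return `occurrence_table` data.frame.
#' @export
read_occurrences <- function(path) {
  occ <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat")
  miss <- setdiff(need, names(occ))
  if (length(miss))
    stopf("occurrence file %s lacks column(s): %s", path,
          paste(miss, collapse = ", "))
  class(occ) <- c("occurrence_table", "data.frame")
  occ
}

#' Read a background raster table
#'
#' @param path CSV with columns `pixel_id`, `lon`, `lat`, `island` and the
#'   environmental variables.
#' @return `env_raster` data.frame.
#' @export
read_raster <- function(path) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pixel_id", "lon", "lat", "island")
  miss <- setdiff(need, names(r))
  if (length(miss))
    stopf("raster file %s lacks column(s): %s", path,
          paste(miss, collapse = ", "))
  if (ncol(r) <= length(need)) stopf("raster file has no environmental columns")
  class(r) <- c("env_raster", "data.frame")
  r
}

#' Read species metadata
#'
#' @param path CSV with columns `species`, `pollination_mode`,
#'   `mode_status`, `islands`.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "pollination_mode", "mode_status", "islands")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stopf("metadata file %s lacks column(s): %s", path,
          paste(miss, collapse = ", "))
  md
}

#' Write a dataset to plain-text files
#'
#' Emits `raster.csv`, `occurrences.csv`, `metadata.csv`, `trees.nwk`
#' (Newick, one per line) and `true_params.json` under `dir`.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$raster, file.path(dir, "raster.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$occurrences, file.path(dir, "occurrences.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  ape::write.tree(dataset$trees, file.path(dir, "trees.nwk"))
  tp <- dataset$true_params
  tp$config <- unclass(tp$config)
  jsonlite::write_json(tp, file.path(dir, "true_params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

write_env_space <- function(space, path) {
  jsonlite::write_json(
    list(means = as.list(space$means), sds = as.list(space$sds),
         loadings = apply(space$loadings, 2, as.numeric, simplify = FALSE),
         explained_variance = space$explained_variance,
         n_components_kept = space$n_components_kept,
         var_names = space$var_names),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- pipeline ----------------------------------------------------------

#' Run the full analysis pipeline
#'
#' Chains every stage on in-memory inputs: ordination fit, occurrence
#' filtering and deduplication, niche summaries, pairwise overlap with the
#' overlap regressions and range-inclusion report, and the replicated
#' model-selection engine. All stage outputs are written as plain-text files
#' under `output_dir` together with a JSON manifest of content checksums, so
#' reruns with the same inputs and seed are byte-identical.
#'
#' @param dataset a `niche_dataset` (from [simulate_dataset()]) or a list
#'   with `raster`, `occurrences`, `metadata`, `trees`.
#' @param output_dir directory for stage outputs.
#' @param seed root seed (mandatory; every stage derives substreams).
#' @param n_iterations replicate iterations (default 1000).
#' @param overlap_R occupancy-grid resolution (default 100).
#' @param overlap_corrected availability-corrected grids (default TRUE).
#' @param precision_km,min_records,min_pixels occurrence filters.
#' @param evo_restarts,mk_restarts optimizer restarts inside the replicate
#'   engine.
#' @param trait_sets trait sets for the model comparison.
#' @return list of class `pipeline_result` with `niches`, `overlap_pairs`,
#'   `overlap_models`, `range_inclusion`, `replicates`, `manifest`.
#' @export
run_pipeline <- function(dataset, output_dir, seed,
                         n_iterations = 1000L, overlap_R = 100L,
                         overlap_corrected = TRUE, precision_km = 10,
                         min_records = 5L, min_pixels = 5L,
                         evo_restarts = 0L, mk_restarts = 1L,
                         trait_sets = default_trait_sets()) {
  if (missing(seed)) stopf("'seed' is mandatory")
  t_all <- proc.time()[["elapsed"]]
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  raster <- dataset$raster
  space <- stage("envspace", dataset$space %||% fit_env_space(raster))
  occ <- stage("filter", apply_filters(dataset$occurrences, raster,
                                       precision_km = precision_km,
                                       min_records = min_records,
                                       min_pixels = min_pixels))
  occ <- dedupe_per_pixel(occ)
  niches <- stage("niches", species_niche(occ, space, raster))
  pairs <- stage("overlap", pairwise_overlap(niches, space, dataset$metadata,
                                             R = overlap_R,
                                             corrected = overlap_corrected))
  models <- stage("overlap_models", fit_overlap_models(pairs))
  pol <- NULL
  if (!is.null(dataset$pollinator_occurrences)) {
    pol <- stage("pollinators", pollinator_stage(
      dataset$pollinator_occurrences, dataset$pollinator_metadata,
      dataset$metadata, niches, space, raster, R = overlap_R,
      corrected = overlap_corrected, precision_km = precision_km))
  }
  reps <- stage("replicates", run_replicates(
    dataset$trees, occ, dataset$metadata, space, raster,
    n_iterations = n_iterations, trait_sets = trait_sets,
    seed = derive_seed(seed, "replicates"), evo_restarts = evo_restarts,
    mk_restarts = mk_restarts))

  write_env_space(space, file.path(output_dir, "env_space.json"))
  utils::write.csv(niches$table, file.path(output_dir, "species_niche.csv"),
                   row.names = FALSE)
  utils::write.csv(pairs, file.path(output_dir, "overlap_pairs.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(models),
                   file.path(output_dir, "overlap_models.csv"),
                   row.names = FALSE)
  if (!is.null(pol)) {
    utils::write.csv(as.data.frame(pol$models),
                     file.path(output_dir, "overlap_models_pollinators.csv"),
                     row.names = FALSE)
    jsonlite::write_json(pol$inclusion,
                         file.path(output_dir, "range_inclusion.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  utils::write.csv(reps$iterations,
                   file.path(output_dir, "replicate_iterations.csv"),
                   row.names = FALSE)
  utils::write.csv(reps$summary,
                   file.path(output_dir, "replicate_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(format_weight_table(reps),
                   file.path(output_dir, "weight_table.csv"),
                   row.names = FALSE)
  outputs <- c("env_space.json", "species_niche.csv", "overlap_pairs.csv",
               "overlap_models.csv", "replicate_iterations.csv",
               "replicate_summary.csv", "weight_table.csv")
  if (!is.null(pol)) outputs <- c(outputs, "overlap_models_pollinators.csv",
                                  "range_inclusion.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("phyloniche")),
    seed = seed, n_iterations = n_iterations,
    filters = list(precision_km = precision_km, min_records = min_records,
                   min_pixels = min_pixels),
    overlap = list(R = overlap_R, corrected = overlap_corrected),
    filter_log = attr(occ, "filter_log"),
    checksums = vapply(outputs, function(f) {
      unname(file_checksum(file.path(output_dir, f)))
    }, character(1)),
    stage_seconds = timings,
    failures = reps$failures,
    total_seconds = round(proc.time()[["elapsed"]] - t_all, 3))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out <- list(space = space, occurrences = occ, niches = niches,
              overlap_pairs = pairs, overlap_models = models,
              pollinators = pol, replicates = reps, manifest = manifest)
  class(out) <- "pipeline_result"
  out
}

# Pollinator leg of the analysis: same filters as plants except the
# species-level minima (no minimum is imposed on pollinator records), niche
# summaries, overlap regressions with "same functional group" in place of
# "same pollination mode", and the range-inclusion check of each plant
# within its pollinator functional group(s).
pollinator_stage <- function(pol_occ, pol_md, plant_md, plant_niches, space,
                             raster, R = 100L, corrected = TRUE,
                             precision_km = 10) {
  occ <- apply_filters(pol_occ, raster, precision_km = precision_km,
                       species_filter = FALSE)
  occ <- dedupe_per_pixel(occ)
  niches <- species_niche(occ, space, raster)
  md2 <- data.frame(species = pol_md$species,
                    pollination_mode = pol_md$functional_group,
                    islands = pol_md$islands, stringsAsFactors = FALSE)
  pairs <- pairwise_overlap(niches, space, metadata = md2, R = R,
                            corrected = corrected)
  models <- fit_overlap_models(pairs)
  group_of <- stats::setNames(pol_md$functional_group, pol_md$species)
  groups <- split(niches$table, group_of[niches$table$species])
  inclusion <- lapply(seq_len(nrow(plant_niches$table)), function(i) {
    row <- plant_niches$table[i, , drop = FALSE]
    mode <- plant_md$pollination_mode[plant_md$species == row$species]
    gr <- switch(if (length(mode)) mode else "unknown",
                 hummingbird = groups[["hummingbird"]],
                 bat = groups[["bat"]],
                 do.call(rbind, groups)) # mixed / unknown: both groups
    inc <- range_inclusion(row, gr)
    list(species = row$species, pollination_mode = mode,
         included = inc$included,
         PC1 = inc$PC1, PC2 = inc$PC2)
  })
  list(niches = niches, pairs = pairs, models = models,
       inclusion = inclusion)
}

# Content checksum that does not depend on file metadata.
file_checksum <- function(path) {
  x <- readBin(path, "raw", file.info(path)$size)
  as.character(sum(as.double(x) * (seq_along(x) %% 997)) %% 2^31)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  cat(sprintf("  species: %d, pairs: %d\n", nrow(x$niches$table),
              nrow(x$overlap_pairs)))
  best <- x$overlap_models$model[x$overlap_models$is_best]
  cat(sprintf("  best overlap model: %s\n", best))
  s <- x$replicates$summary
  top <- s[which.max(s$mean_weight), ]
  cat(sprintf("  top evolution model: %s (mean weight %.2f on %s)\n",
              top$model, top$mean_weight, top$trait_set))
  invisible(x)
}

#' Render report tables from cached stage outputs
#'
#' Reads the stage CSVs written by [run_pipeline()] and renders the three
#' result tables (overlap-regression comparison, pairwise mean overlaps by
#' sharing pattern, and the mean AICc weight table), rounded for display;
#' nothing is recomputed.
#'
#' @param output_dir directory with pipeline outputs.
#' @param digits display rounding (default 2).
#' @return named list of data.frames, invisibly; tables are also written to
#'   `report_*.csv` files in `output_dir`.
#' @export
render_report <- function(output_dir, digits = 2) {
  f <- function(name) file.path(output_dir, name)
  for (need in c("overlap_models.csv", "overlap_pairs.csv",
                 "replicate_summary.csv")) {
    if (!file.exists(f(need))) stopf("missing stage output: %s", f(need))
  }
  om <- utils::read.csv(f("overlap_models.csv"))
  num <- vapply(om, is.numeric, logical(1))
  om[num] <- lapply(om[num], round, digits + 1)
  pairs <- utils::read.csv(f("overlap_pairs.csv"))
  by_island <- data.frame(
    group = c("same island", "different island"),
    mean_D = round(c(mean(pairs$D[pairs$same_island]),
                     mean(pairs$D[!pairs$same_island])), digits),
    n_pairs = c(sum(pairs$same_island), sum(!pairs$same_island)))
  reps <- utils::read.csv(f("replicate_summary.csv"))
  wt <- structure(list(summary = reps), class = "replicate_summary")
  weight_table <- format_weight_table(wt, digits = digits)
  out <- list(overlap_models = om, mean_D_by_island = by_island,
              weight_table = weight_table)
  if (file.exists(f("overlap_models_pollinators.csv"))) {
    pm <- utils::read.csv(f("overlap_models_pollinators.csv"))
    num <- vapply(pm, is.numeric, logical(1))
    pm[num] <- lapply(pm[num], round, digits + 1)
    out$overlap_models_pollinators <- pm
  }
  for (n in names(out)) {
    utils::write.csv(out[[n]], f(sprintf("report_%s.csv", n)),
                     row.names = FALSE)
  }
  invisible(out)
}
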