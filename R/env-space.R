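#' Fit the background environmental ordination
#'
#' Principal component analysis based on the correlation matrix (all
#' variables standardized to mean 0 / sd 1, so each gets the same weight) of
#' the background raster pixels. The first two components define the 2-D
#' environmental niche space; explained variance is reported for all
#' components. The sign of each loading column is fixed by making its
#' largest-magnitude element positive, so scores are reproducible across
#' linear-algebra backends.
#'
#' @param raster an `env_raster` data.frame (columns `pixel_id`, `lon`,
#'   `lat`, `island`, then environmental variables), as from
#'   [generate_raster()] or [read_raster()].
#' @return an object of class `env_space`: list with `means`, `sds`,
#'   `loadings` (variables x components), `explained_variance` (percent, all
#'   components), `background_scores` (pixels x 2), `n_components_kept`,
#'   `var_names`, `pixel_id`, `island`.
#' @export
fit_env_space <- function(raster) {
  X <- env_matrix(raster)
  if (nrow(X) < 3L) stopf("need at least 3 pixels to fit the ordination")
  if (anyNA(X)) stopf("environmental values contain missing data")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stopf("constant environmental variable(s): %s",
          paste(colnames(X)[sds == 0], collapse = ", "))
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  # Sign convention: largest-|loading| element of each column made positive.
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ev <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  out <- list(means = pc$center, sds = pc$scale,
              loadings = pc$rotation,
              explained_variance = ev,
              background_scores = pc$x[, 1:2, drop = FALSE],
              n_components_kept = 2L,
              var_names = colnames(X),
              pixel_id = raster$pixel_id,
              island = raster$island)
  rownames(out$background_scores) <- raster$pixel_id
  class(out) <- "env_space"
  out
}

#' @export
print.env_space <- function(x, ...) {
  cat(sprintf("Environmental space: %d pixels, %d variables\n",
              nrow(x$background_scores), length(x$var_names)))
  cat(sprintf("PC1 %.2f%%, PC2 %.2f%% (first two: %.2f%%)\n",
              x$explained_variance[1], x$explained_variance[2],
              sum(x$explained_variance[1:2])))
  invisible(x)
}

# Environmental columns of a raster table as a matrix.
env_matrix <- function(raster) {
  meta <- c("pixel_id", "lon", "lat", "island")
  cols <- setdiff(colnames(raster), meta)
  as.matrix(raster[, cols, drop = FALSE])
}

#' Project environmental values into the fitted ordination
#'
#' Uses the background standardization constants and loadings; new points
#' never refit the PCA.
#'
#' @param space an [fit_env_space()] object.
#' @param env matrix or data.frame of environmental values with the fitted
#'   variables as columns.
#' @return matrix (rows x 2) of (PC1, PC2) scores.
#' @export
project_env <- function(space, env) {
  stopifnot(inherits(space, "env_space"))
  X <- as.matrix(env[, space$var_names, drop = FALSE])
  Xs <- sweep(sweep(X, 2, space$means, "-"), 2, space$sds, "/")
  Xs %*% space$loadings[, 1:2, drop = FALSE]
}

#' Assign occurrence records to raster pixels
#'
#' Each record is matched to the nearest pixel centre (Euclidean in lon/lat);
#' records farther than half a pixel diagonal from any centre are flagged as
#' outside the raster (`pixel_id` NA). Records that already carry a valid
#' `pixel_id` are left untouched.
#'
#' @param occ occurrence data.frame with `lon`, `lat` columns.
#' @param raster the background raster table.
#' @return `occ` with `pixel_id` and `island` columns filled in.
#' @export
assign_pixels <- function(occ, raster) {
  need <- if ("pixel_id" %in% names(occ)) {
    which(is.na(occ$pixel_id) | !(occ$pixel_id %in% raster$pixel_id))
  } else {
    occ$pixel_id <- NA_integer_
    seq_len(nrow(occ))
  }
  if (!("island" %in% names(occ))) occ$island <- NA_character_
  if (length(need)) {
    # half pixel diagonal from the raster's grid spacing
    step <- median(diff(sort(unique(raster$lon))))
    maxd <- sqrt(2) * step / 2
    for (i in need) {
      d2 <- (raster$lon - occ$lon[i])^2 + (raster$lat - occ$lat[i])^2
      j <- which.min(d2)
      if (sqrt(d2[j]) <= maxd) {
        occ$pixel_id[i] <- raster$pixel_id[j]
        occ$island[i] <- raster$island[j]
      } else {
        occ$pixel_id[i] <- NA_integer_
      }
    }
  }
  ix <- match(occ$pixel_id, raster$pixel_id)
  ok <- !is.na(ix)
  occ$island[ok] <- raster$island[ix[ok]]
  occ
}

#' Filter occurrence records and rare species
#'
#' Applies the acquisition filters: records with coordinate precision
#' strictly greater than `precision_km` are discarded; records falling
#' outside the raster are discarded; species left with fewer than
#' `min_records` records or present in fewer than `min_pixels` distinct
#' pixels are dropped entirely. The species-level filter can be disabled
#' (e.g. for pollinator data, where no minimum is imposed).
#'
#' @param occ occurrence data.frame (will be pixel-assigned if needed).
#' @param raster the background raster table.
#' @param precision_km precision cutoff in km (default 10; strictly greater
#'   is discarded, exactly 10 km is retained).
#' @param min_records,min_pixels species-level minima (default 5 and 5).
#' @param species_filter apply the species-level minima (default TRUE).
#' @return filtered occurrence table; attribute `"filter_log"` holds a list
#'   of counts dropped per rule and the dropped species names.
#' @export
apply_filters <- function(occ, raster, precision_km = 10, min_records = 5L,
                          min_pixels = 5L, species_filter = TRUE) {
  occ <- assign_pixels(occ, raster)
  n0 <- nrow(occ)
  prec <- occ$coordinate_precision_km %||% rep(precision_km, n0)
  keep <- prec <= precision_km # strictly greater than the cutoff is dropped
  n_prec <- sum(!keep)
  occ <- occ[keep, , drop = FALSE]
  out_r <- is.na(occ$pixel_id)
  n_outside <- sum(out_r)
  occ <- occ[!out_r, , drop = FALSE]
  dropped_species <- character(0)
  n_rare <- 0L
  if (species_filter && nrow(occ)) {
    nrec <- table(occ$species)
    npix <- tapply(occ$pixel_id, occ$species, function(p) length(unique(p)))
    bad <- names(nrec)[nrec < min_records | npix[names(nrec)] < min_pixels]
    dropped_species <- bad
    n_rare <- sum(occ$species %in% bad)
    occ <- occ[!(occ$species %in% bad), , drop = FALSE]
  }
  rownames(occ) <- NULL
  attr(occ, "filter_log") <- list(
    n_input = n0,
    n_dropped_precision = n_prec,
    n_dropped_outside_raster = n_outside,
    n_dropped_rare_species = n_rare,
    species_dropped = dropped_species)
  class(occ) <- c("occurrence_table", "data.frame")
  occ
}

#' Keep one presence record per pixel per species
#'
#' Collapses repeated sampling of the same locality (herbarium collectors
#' revisit sites), so niche summaries are not biased by sampling effort.
#'
#' @param occ occurrence table with `pixel_id` assigned.
#' @return deduplicated occurrence table.
#' @export
dedupe_per_pixel <- function(occ) {
  if (!("pixel_id" %in% names(occ))) stopf("'occ' has no 'pixel_id' column")
  out <- occ[!duplicated(occ[, c("species", "pixel_id")]), , drop = FALSE]
  rownames(out) <- NULL
  cls <- class(occ)
  class(out) <- if ("occurrence_table" %in% cls) cls else
    c("occurrence_table", class(out))
  out
}

#' Species niche identity, breadth and range in the ordination space
#'
#' Projects each species' deduplicated presence pixels onto the first two
#' background PCA axes (using the background standardization and loadings)
#' and summarizes them: identity = per-axis mean score, breadth = per-axis
#' sample standard deviation (n - 1 denominator), range = per-axis min/max.
#'
#' @param occ deduplicated, filtered occurrence table.
#' @param space an [fit_env_space()] object.
#' @param raster the background raster table (environmental values are read
#'   from the occupied pixels).
#' @return object of class `niche_set`: list with `$table` (one row per
#'   species: identity, breadth, range, n_pixels) and `$scores` (named list
#'   of per-species score matrices).
#' @export
species_niche <- function(occ, space, raster) {
  stopifnot(inherits(space, "env_space"))
  occ <- dedupe_per_pixel(occ)
  sp <- sort(unique(occ$species))
  scores <- vector("list", length(sp)); names(scores) <- sp
  rows <- vector("list", length(sp))
  ix_env <- match(occ$pixel_id, raster$pixel_id)
  if (anyNA(ix_env)) stopf("occurrence pixel_id not present in the raster")
  all_scores <- space$background_scores[ix_env, , drop = FALSE]
  for (i in seq_along(sp)) {
    s <- all_scores[occ$species == sp[i], , drop = FALSE]
    if (nrow(s) < 2L)
      stopf("species '%s' occupies < 2 pixels: breadth undefined", sp[i])
    rownames(s) <- NULL
    scores[[i]] <- s
    rows[[i]] <- data.frame(
      species = sp[i], n_pixels = nrow(s),
      identity_PC1 = mean(s[, 1]), identity_PC2 = mean(s[, 2]),
      breadth_PC1 = sd(s[, 1]), breadth_PC2 = sd(s[, 2]),
      min_PC1 = min(s[, 1]), max_PC1 = max(s[, 1]),
      min_PC2 = min(s[, 2]), max_PC2 = max(s[, 2]),
      stringsAsFactors = FALSE)
  }
  out <- list(table = do.call(rbind, rows), scores = scores)
  class(out) <- "niche_set"
  out
}

#' @export
print.niche_set <- function(x, ...) {
  cat(sprintf("Species niches: %d species, %d-%d pixels each\n",
              nrow(x$table), min(x$table$n_pixels), max(x$table$n_pixels)))
  print(utils::head(x$table, 10))
  if (nrow(x$table) > 10) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.niche_set <- function(x, ...) x$table
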