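#' Kernel occupancy grid in the 2-D environmental space
#'
#' Gridded, kernel-smoothed occupancy of a species over the background
#' ordination, following the environmental-space overlap method of
#' Broennimann and colleagues: a Gaussian kernel density of the species'
#' deduplicated scores is evaluated at the cell centres of an R x R grid
#' spanning the background scores; optionally (default) the density is
#' divided by the background availability density (floored at its 1st
#' positive percentile to avoid blow-ups) so occupancy reflects preference
#' rather than availability; the result is renormalized to sum to 1.
#'
#' @param scores two-column matrix of (PC1, PC2) points, or a species name
#'   together with a `niche_set`.
#' @param space an [fit_env_space()] object (defines the grid extent).
#' @param R grid resolution per axis (default 100).
#' @param bandwidth per-axis kernel sd; default Silverman's rule
#'   ([stats::bw.nrd0()]) on the species' points, floored at 1/1000 of the
#'   axis extent.
#' @param corrected divide by background availability (default TRUE).
#' @param background optional precomputed background grid (from
#'   [background_grid()]), reused across species for speed.
#' @return object of class `occupancy_grid`: list with `x`, `y` (cell
#'   centres), `z` (R x R, sums to 1), `extent`, `resolution`, `corrected`.
#' @export
occupancy_grid <- function(scores, space, R = 100L, bandwidth = NULL,
                           corrected = TRUE, background = NULL) {
  stopifnot(inherits(space, "env_space"))
  pts <- as.matrix(scores)
  if (ncol(pts) != 2L) stopf("'scores' must have two columns")
  if (nrow(pts) < 2L) stopf("need at least 2 points for an occupancy grid")
  bg <- space$background_scores
  ext <- rbind(range(bg[, 1]), range(bg[, 2]))
  if (any(pts[, 1] < ext[1, 1] | pts[, 1] > ext[1, 2] |
          pts[, 2] < ext[2, 1] | pts[, 2] > ext[2, 2]))
    stopf("points outside the background score extent")
  gx <- seq(ext[1, 1], ext[1, 2], length.out = R)
  gy <- seq(ext[2, 1], ext[2, 2], length.out = R)
  z <- kde_grid(pts, gx, gy, bandwidth)
  if (corrected) {
    if (is.null(background)) background <- background_grid(space, R = R)
    avail <- background$z
    floor_val <- quantile(avail[avail > 0], 0.01)
    z <- z / pmax(avail, floor_val)
  }
  tot <- sum(z)
  if (tot <= 0) stopf("occupancy density is zero everywhere")
  out <- list(x = gx, y = gy, z = z / tot, extent = ext,
              resolution = as.integer(R), corrected = corrected)
  class(out) <- "occupancy_grid"
  out
}

#' Background availability grid
#'
#' Kernel density of all background pixels on the same grid used for species
#' occupancy; cached and shared across species in [pairwise_overlap()].
#'
#' @inheritParams occupancy_grid
#' @return an `occupancy_grid` (uncorrected, normalized).
#' @export
background_grid <- function(space, R = 100L, bandwidth = NULL) {
  bg <- space$background_scores
  ext <- rbind(range(bg[, 1]), range(bg[, 2]))
  gx <- seq(ext[1, 1], ext[1, 2], length.out = R)
  gy <- seq(ext[2, 1], ext[2, 2], length.out = R)
  z <- kde_grid(bg, gx, gy, bandwidth)
  out <- list(x = gx, y = gy, z = z / sum(z), extent = ext,
              resolution = as.integer(R), corrected = FALSE)
  class(out) <- "occupancy_grid"
  out
}

# Product-Gaussian KDE evaluated at the cell centres of (gx, gy).
kde_grid <- function(pts, gx, gy, bandwidth = NULL) {
  if (is.null(bandwidth)) {
    bandwidth <- c(stats::bw.nrd0(pts[, 1]), stats::bw.nrd0(pts[, 2]))
  }
  bandwidth <- rep_len(bandwidth, 2L)
  floor_bw <- c(diff(range(gx)), diff(range(gy))) / 1000
  bandwidth <- pmax(bandwidth, floor_bw)
  D1 <- dnorm(outer(gx, pts[, 1], "-"), sd = bandwidth[1]) # R x n
  D2 <- dnorm(outer(gy, pts[, 2], "-"), sd = bandwidth[2]) # R x n
  D1 %*% t(D2)
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat(sprintf("Occupancy grid %dx%d (%s), mass on %d cells > 1e-6/R^2\n",
              x$resolution, x$resolution,
              if (x$corrected) "availability-corrected" else "uncorrected",
              sum(x$z > 1e-6 / x$resolution^2)))
  invisible(x)
}

#' @export
plot.occupancy_grid <- function(x, ...) {
  graphics::image(x$x, x$y, x$z, xlab = "PC1", ylab = "PC2",
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Schoener's D niche overlap between two occupancy grids
#'
#' `D = 1 - 0.5 * sum(|z1 - z2|)` over cells: 0 for disjoint occupancies,
#' 1 for identical ones; symmetric in its arguments.
#'
#' @param z1,z2 `occupancy_grid` objects on the same extent and resolution.
#' @return numeric in `[0, 1]`.
#' @export
schoener_D <- function(z1, z2) {
  stopifnot(inherits(z1, "occupancy_grid"), inherits(z2, "occupancy_grid"))
  if (z1$resolution != z2$resolution || !isTRUE(all.equal(z1$extent, z2$extent)))
    stopf("occupancy grids have different extent or resolution")
  max(0, min(1, 1 - 0.5 * sum(abs(z1$z - z2$z))))
}

#' Niche overlap for all species pairs
#'
#' Computes one occupancy grid per species and Schoener's D for every
#' unordered pair, annotated with whether the two species share the same
#' pollination mode (NA when either mode is unknown) and whether their island
#' sets intersect.
#'
#' @param niches a `niche_set` from [species_niche()].
#' @param metadata data.frame with `species`, `pollination_mode` (levels
#'   hummingbird / bat / mixed / unknown) and `islands` (character,
#'   ";"-separated), or NULL to skip the annotations.
#' @param R,bandwidth,corrected grid options passed to [occupancy_grid()].
#' @param space the [fit_env_space()] object the niches were projected in.
#' @return data.frame of class `overlap_pairs`: `species_a`, `species_b`,
#'   `D`, `same_pollination`, `same_island`.
#' @export
pairwise_overlap <- function(niches, space, metadata = NULL, R = 100L,
                             bandwidth = NULL, corrected = TRUE) {
  stopifnot(inherits(niches, "niche_set"))
  sp <- names(niches$scores)
  if (length(sp) < 2L) stopf("need at least 2 species")
  bgg <- if (corrected) background_grid(space, R = R) else NULL
  grids <- lapply(niches$scores, occupancy_grid, space = space, R = R,
                  bandwidth = bandwidth, corrected = corrected,
                  background = bgg)
  mode_of <- isl_of <- NULL
  if (!is.null(metadata)) {
    mode_of <- stats::setNames(as.character(metadata$pollination_mode),
                               metadata$species)
    isl_of <- stats::setNames(strsplit(as.character(metadata$islands), ";",
                                       fixed = TRUE), metadata$species)
  }
  pairs <- utils::combn(sp, 2L)
  n <- ncol(pairs)
  D <- numeric(n); same_p <- rep(NA, n); same_i <- rep(NA, n)
  for (k in seq_len(n)) {
    a <- pairs[1, k]; b <- pairs[2, k]
    D[k] <- schoener_D(grids[[a]], grids[[b]])
    if (!is.null(metadata)) {
      ma <- mode_of[[a]]; mb <- mode_of[[b]]
      same_p[k] <- if (is.na(ma) || is.na(mb) || ma == "unknown" ||
                       mb == "unknown") NA else ma == mb
      same_i[k] <- length(intersect(isl_of[[a]], isl_of[[b]])) > 0
    }
  }
  out <- data.frame(species_a = pairs[1, ], species_b = pairs[2, ], D = D,
                    same_pollination = same_p, same_island = same_i,
                    stringsAsFactors = FALSE)
  class(out) <- c("overlap_pairs", "data.frame")
  out
}

#' Linear models explaining niche overlap
#'
#' Fits ordinary least squares for the intercept-only model plus the four
#' candidate models of pairwise D: `D ~ pollination`, `D ~ island`,
#' `D ~ pollination + island`, `D ~ pollination * island` (for pollinator
#' data, read "pollination" as "same functional group"). Models are compared
#' by AIC (Gaussian likelihood, ML variance, k = coefficients + variance,
#' i.e. the standard regression AIC); the best model is the minimum-AIC one,
#' and models within 2 AIC units of it are flagged as not rejectable. Pairs
#' with unknown pollination mode are excluded from models that use the
#' pollination predictor but retained in island-only models; p-values are
#' plain OLS (pairs sharing a species are treated as independent).
#'
#' @param pairs an `overlap_pairs` data.frame from [pairwise_overlap()].
#' @return data.frame of class `overlap_model_set`, one row per model:
#'   AIC, R^2, n, coefficient estimates and p-values, `is_best`,
#'   `within_2_AIC`; attribute `"fits"` holds the `lm` objects.
#' @export
fit_overlap_models <- function(pairs) {
  if (nrow(pairs) < 10L) stopf("need at least 10 pairs")
  forms <- list(
    "D ~ 1" = D ~ 1,
    "D ~ pollination" = D ~ same_pollination,
    "D ~ island" = D ~ same_island,
    "D ~ pollination + island" = D ~ same_pollination + same_island,
    "D ~ pollination * island" = D ~ same_pollination * same_island)
  rows <- vector("list", length(forms)); fits <- list()
  for (i in seq_along(forms)) {
    f <- forms[[i]]
    vars <- all.vars(f)
    dat <- pairs[stats::complete.cases(pairs[, vars, drop = FALSE]), ,
                 drop = FALSE]
    fit <- tryCatch(stats::lm(f, data = dat), error = function(e) NULL)
    if (is.null(fit) || anyNA(coef(fit))) {
      warning(sprintf("model '%s' dropped (collinear or degenerate predictors)",
                      names(forms)[i]))
      next
    }
    sm <- summary(fit)
    r2 <- if (stats::var(dat$D) <= 1e-14 || !is.finite(sm$r.squared)) 0
          else sm$r.squared
    cf <- sm$coefficients
    get_cf <- function(pat) {
      j <- grep(pat, rownames(cf))
      if (length(j) == 1L) c(cf[j, 1], cf[j, 4]) else c(NA_real_, NA_real_)
    }
    poll <- get_cf("^same_pollinationTRUE$")
    isl <- get_cf("^same_islandTRUE$")
    inter <- get_cf(":")
    icpt <- get_cf("\\(Intercept\\)")
    rows[[i]] <- data.frame(
      model = names(forms)[i], n = nrow(dat),
      AIC = stats::AIC(fit), R2 = r2,
      intercept = icpt[1], intercept_p = icpt[2],
      pollination = poll[1], pollination_p = poll[2],
      island = isl[1], island_p = isl[2],
      interaction = inter[1], interaction_p = inter[2],
      stringsAsFactors = FALSE)
    fits[[names(forms)[i]]] <- fit
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$is_best <- out$AIC == min(out$AIC)
  if (sum(out$is_best) > 1L) { # deterministic tie-break: first minimum
    out$is_best <- seq_len(nrow(out)) == which.min(out$AIC)
  }
  out$within_2_AIC <- out$AIC <= min(out$AIC) + 2
  attr(out, "fits") <- fits
  class(out) <- c("overlap_model_set", "data.frame")
  out
}

#' Range inclusion of a plant niche within its pollinator functional group
#'
#' The group range per axis is the union of the pollinator species ranges
#' (min of mins, max of maxs); the plant is included iff its range lies
#' within the group range on both axes. Margins are distances from the plant
#' range limits to the group limits (negative when exceeded).
#'
#' @param plant one species entry of a `niche_set` table (row) or a
#'   `niche_set` with one species.
#' @param pollinator_group a `niche_set` (or its `$table`) for the group.
#' @return list with per-axis `included`, `margins` (lower, upper) and the
#'   overall `included` flag.
#' @export
range_inclusion <- function(plant, pollinator_group) {
  pl <- if (inherits(plant, "niche_set")) plant$table else plant
  gr <- if (inherits(pollinator_group, "niche_set")) pollinator_group$table
        else pollinator_group
  if (nrow(gr) < 1L) stopf("pollinator group is empty")
  if (nrow(pl) != 1L) stopf("'plant' must be a single species")
  res <- list()
  ok <- TRUE
  for (ax in c("PC1", "PC2")) {
    glo <- min(gr[[paste0("min_", ax)]]); ghi <- max(gr[[paste0("max_", ax)]])
    plo <- pl[[paste0("min_", ax)]]; phi <- pl[[paste0("max_", ax)]]
    m <- c(lower = plo - glo, upper = ghi - phi)
    inc <- all(m >= 0)
    ok <- ok && inc
    res[[ax]] <- list(included = inc, margins = m)
  }
  res$included <- ok
  res
}
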