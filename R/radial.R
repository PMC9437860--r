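# Cell-shape-aware radial profiling: concentric shells at 10% increments from
# the cell center to the periphery, cumulative normalized organelle-channel
# intensity per shell, and group comparison of profiles.

#' Select the cell center
#'
#' The center anchors the shell geometry. `manual` validates a supplied
#' click-equivalent point; `centroid` uses the polygon centroid; `nucleus`
#' uses the centroid of a nucleus mask. If a computed center falls outside a
#' non-convex contour the pole of inaccessibility (interior point farthest
#' from the outline, coarse-to-fine grid search) is used instead and a
#' warning is emitted; a manual point outside the contour is an error.
#'
#' @param contour a `cell_contour`.
#' @param mode "centroid", "manual" or "nucleus".
#' @param point length-2 (x, y), required for `mode = "manual"`.
#' @param nucleus_mask logical matrix, required for `mode = "nucleus"`.
#' @return length-2 numeric (x, y) strictly inside the contour.
#' @export
select_center <- function(contour, mode = c("centroid", "manual", "nucleus"),
                          point = NULL, nucleus_mask = NULL) {
  mode <- match.arg(mode)
  poly <- contour$vertices
  if (mode == "manual") {
    if (is.null(point) || length(point) != 2L)
      stop("mode 'manual' requires a length-2 point", call. = FALSE)
    if (!point_in_polygon(point[1L], point[2L], poly))
      stop("center outside contour", call. = FALSE)
    return(as.numeric(point))
  }
  center <- if (mode == "centroid") {
    polygon_centroid(poly)
  } else {
    if (is.null(nucleus_mask))
      stop("mode 'nucleus' requires a nucleus mask", call. = FALSE)
    idx <- which(nucleus_mask)
    if (!length(idx)) stop("nucleus mask is empty", call. = FALSE)
    nr <- nrow(nucleus_mask)
    c(mean((idx - 1L) %/% nr), mean((idx - 1L) %% nr))
  }
  if (!point_in_polygon(center[1L], center[2L], poly)) {
    warning(sprintf("%s center (%.1f, %.1f) falls outside the contour; ",
                    mode, center[1L], center[2L]),
            "falling back to the pole of inaccessibility")
    center <- pole_of_inaccessibility(poly)
  }
  center
}

# Interior point maximising distance to the polygon outline; deterministic
# two-stage grid search (coarse 64 x 64, then 9x refined around the best).
pole_of_inaccessibility <- function(poly, coarse = 64L) {
  bb <- apply(poly, 2L, range)
  search <- function(xs, ys) {
    g <- expand.grid(x = xs, y = ys)
    inside <- point_in_polygon(g$x, g$y, poly)
    g <- g[inside, , drop = FALSE]
    if (!nrow(g)) return(NULL)
    d <- point_polygon_distance(g$x, g$y, poly)
    k <- which.max(d)
    list(p = c(g$x[k], g$y[k]), d = d[k],
         step = c(if (length(xs) > 1) diff(xs[1:2]) else 0,
                  if (length(ys) > 1) diff(ys[1:2]) else 0))
  }
  best <- search(seq(bb[1L, 1L], bb[2L, 1L], length.out = coarse),
                 seq(bb[1L, 2L], bb[2L, 2L], length.out = coarse))
  if (is.null(best)) stop("could not find an interior point", call. = FALSE)
  ref <- search(seq(best$p[1L] - best$step[1L], best$p[1L] + best$step[1L],
                    length.out = 9L),
                seq(best$p[2L] - best$step[2L], best$p[2L] + best$step[2L],
                    length.out = 9L))
  if (!is.null(ref) && ref$d > best$d) ref$p else best$p
}

#' Build concentric shell polygons
#'
#' For each contour vertex `p_periphery(i)` and each distance fraction
#' `d = k / n_increments`, the shell polygon vertex is
#' `p_new(i, d) = p_center + d * (p_periphery(i) - p_center)`, i.e. the
#' contour scaled about the center; `polygon(1.0)` coincides with the
#' contour. Contours that are not star-shaped about the chosen center give
#' non-nested shells; these are detected and flagged (with a warning)
#' rather than dropped.
#'
#' @param contour a `cell_contour`.
#' @param center length-2 (x, y), strictly inside the contour.
#' @param n_increments number of shells (default 10, i.e. 10% increments).
#' @return a `shell_geometry` with fields `center`, `fractions`, `polygons`
#'   (list of m x 2 matrices) and `star_shaped` (FALSE when the contour is
#'   not star-shaped about the center, in which case shells need not nest
#'   and profiles from this geometry carry `flagged = TRUE`).
#' @export
build_shells <- function(contour, center, n_increments = 10) {
  n_increments <- as.integer(n_increments)
  if (n_increments < 2L) stop("n_increments must be >= 2", call. = FALSE)
  poly <- contour$vertices
  if (!point_in_polygon(center[1L], center[2L], poly))
    stop("center outside contour", call. = FALSE)
  fractions <- seq_len(n_increments) / n_increments
  polygons <- lapply(fractions, function(d) {
    cbind(x = center[1L] + d * (poly[, 1L] - center[1L]),
          y = center[2L] + d * (poly[, 2L] - center[2L]))
  })
  polygons[[n_increments]] <- cbind(x = poly[, 1L], y = poly[, 2L])
  # scaling about the center is a similarity, so inner polygons are always
  # simple — but for a contour that is not star-shaped about the center
  # they need not nest inside the contour, which breaks the innermost-shell
  # reading of the profile; detect and flag that instead
  star <- is_star_shaped(poly, center)
  if (!star)
    warning("contour is not star-shaped about the center; inner shell ",
            "polygons need not nest and the cell is flagged")
  structure(list(center = as.numeric(center), fractions = fractions,
                 polygons = polygons, star_shaped = star),
            class = "shell_geometry")
}

#' Cumulative radial intensity profile
#'
#' Each pixel center inside `polygon(1.0)` is assigned to the innermost shell
#' polygon containing it; per-shell intensity sums are accumulated and
#' normalized by the total in-cell intensity so the cumulative curve runs
#' from the center (fraction 0.1) to the periphery (fraction 1.0) and ends at
#' 1. Pixels belonging to the cleaned cluster but left outside
#' `polygon(1.0)` by contour-approximation slack are assigned to the
#' outermost shell.
#'
#' @param image `intensity_image` (organelle channel) or numeric matrix.
#' @param shells a `shell_geometry`.
#' @param cluster optional `cell_cluster` used to recover slack pixels.
#' @param background flat background level subtracted from every pixel before
#'   summation (negative results clamp to 0); default 0 (none).
#' @param cell_id identifier carried into the output.
#' @return a `radial_profile` with fields `cell_id`, `fractions`,
#'   `shell_intensity`, `cumulative`, `valid`, `n_pixels`, `flagged`
#'   (TRUE when the shell geometry self-intersected).
#' @export
cumulative_profile <- function(image, shells, cluster = NULL, background = 0,
                               cell_id = NA) {
  px <- as_pixel_matrix(image)
  nr <- nrow(px); nc <- ncol(px)
  if (!is.null(cluster) && !all(cluster$shape == c(nr, nc)))
    stop("image and cluster are in different coordinate frames", call. = FALSE)
  outer_poly <- shells$polygons[[length(shells$polygons)]]
  bb <- apply(outer_poly, 2L, range)
  xs <- max(0L, floor(bb[1L, 1L])):min(nc - 1L, ceiling(bb[2L, 1L]))
  ys <- max(0L, floor(bb[1L, 2L])):min(nr - 1L, ceiling(bb[2L, 2L]))
  if (bb[1L, 1L] > nc - 1L || bb[2L, 1L] < 0 || bb[1L, 2L] > nr - 1L || bb[2L, 2L] < 0)
    stop("shell geometry lies outside the image frame", call. = FALSE)
  g <- expand.grid(x = xs, y = ys)
  k <- length(shells$fractions)
  assign_k <- rep(NA_integer_, nrow(g))
  for (i in seq_len(k)) {
    todo <- is.na(assign_k)
    if (!any(todo)) break
    inside <- point_in_polygon(g$x[todo], g$y[todo], shells$polygons[[i]])
    assign_k[which(todo)[inside]] <- i
  }
  keep <- !is.na(assign_k)
  pix_x <- g$x[keep]; pix_y <- g$y[keep]; pix_k <- assign_k[keep]
  if (!is.null(cluster)) {
    # cluster pixels missed by polygon(1.0): approximation slack -> outer shell
    in_poly <- paste(pix_x, pix_y)
    cl_key <- paste(cluster$pixels[, "x"], cluster$pixels[, "y"])
    extra <- !(cl_key %in% in_poly)
    if (any(extra)) {
      pix_x <- c(pix_x, cluster$pixels[extra, "x"])
      pix_y <- c(pix_y, cluster$pixels[extra, "y"])
      pix_k <- c(pix_k, rep(k, sum(extra)))
    }
  }
  vals <- pmax(px[cbind(pix_y + 1L, pix_x + 1L)] - background, 0)
  shell_intensity <- vapply(seq_len(k),
                            function(i) sum(vals[pix_k == i]), numeric(1L))
  total <- sum(shell_intensity)
  valid <- total > 0
  cumulative <- if (valid) cumsum(shell_intensity) / total else rep(0, k)
  structure(list(cell_id = cell_id, fractions = shells$fractions,
                 shell_intensity = shell_intensity, cumulative = cumulative,
                 valid = valid, n_pixels = length(pix_k),
                 flagged = !isTRUE(shells$star_shaped)),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("<radial_profile cell %s: %s, %d shells, %d px%s>\n",
              x$cell_id, if (x$valid) "valid" else "INVALID (zero intensity)",
              length(x$fractions), x$n_pixels,
              if (isTRUE(x$flagged)) ", flagged" else ""))
  if (x$valid)
    cat("  cumulative:", paste(sprintf("%.3f", x$cumulative), collapse = " "), "\n")
  invisible(x)
}

#' Area under the cumulative profile
#'
#' Mean of the cumulative values across the fraction grid. A left-shifted
#' (perinuclear) curve has higher AUC; a right-shifted (peripheral) curve has
#' lower AUC.
#'
#' @param profile a valid `radial_profile`.
#' @return score in `[0, 1]`.
#' @export
profile_auc <- function(profile) {
  if (!isTRUE(profile$valid))
    stop("AUC undefined for an invalid (zero-intensity) profile", call. = FALSE)
  mean(profile$cumulative)
}

#' Compare groups of radial profiles
#'
#' Computes per-group mean cumulative curves on the common fraction grid and
#' tests the per-cell AUC: two-sided Welch t-test for 2 groups, one-way ANOVA
#' for more. The shift direction is read from the sign of the mean AUC
#' difference (lower AUC = more peripheral).
#'
#' @param groups named list; each element a list of `radial_profile`s.
#' @param test "t_test" (2 groups) or "anova".
#' @return a `group_comparison` with per-group summaries, `statistic`,
#'   `df`, `p_value` and `shift` (human-readable direction).
#' @export
compare_groups <- function(groups, test = c("t_test", "anova")) {
  test <- match.arg(test)
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  groups <- lapply(groups, function(g) Filter(function(p) isTRUE(p$valid), g))
  ns <- lengths(groups)
  if (any(ns < 2L))
    stop("each group needs at least 2 valid profiles", call. = FALSE)
  fr <- groups[[1L]][[1L]]$fractions
  for (g in groups) for (p in g)
    if (length(p$fractions) != length(fr) || any(abs(p$fractions - fr) > 1e-12))
      stop("profiles are on mismatched fraction grids", call. = FALSE)
  mean_curves <- lapply(groups, function(g)
    colMeans(do.call(rbind, lapply(g, `[[`, "cumulative"))))
  aucs <- lapply(groups, function(g) vapply(g, profile_auc, numeric(1L)))
  mean_auc <- vapply(aucs, mean, numeric(1L))
  if (test == "t_test") {
    if (length(groups) != 2L)
      stop("t_test requires exactly 2 groups (use anova)", call. = FALSE)
    st <- welch_t(aucs[[1L]], aucs[[2L]])
  } else {
    st <- oneway_anova(aucs)
  }
  dmu <- if (length(groups) == 2L) mean_auc[1L] - mean_auc[2L] else NA_real_
  shift <- if (length(groups) != 2L) {
    "multi-group (see p_value)"
  } else if (dmu == 0) {
    "none"
  } else if (dmu > 0) {
    sprintf("peripheral in %s", names(groups)[2L])
  } else {
    sprintf("perinuclear in %s", names(groups)[2L])
  }
  structure(list(groups = names(groups), n = ns, fractions = fr,
                 mean_curves = mean_curves, aucs = aucs, mean_auc = mean_auc,
                 test = test, statistic = st$statistic, df = st$df,
                 p_value = st$p_value, shift = shift),
            class = "group_comparison")
}

# Textbook Welch two-sample t with Welch-Satterthwaite df. Zero pooled
# variance (degenerate constant groups) resolves by the mean difference.
welch_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  dm <- mean(x) - mean(y)
  if (se2 == 0) {
    return(if (dm == 0) list(statistic = 0, df = n1 + n2 - 2, p_value = 1)
           else list(statistic = sign(dm) * Inf, df = n1 + n2 - 2,
                     p_value = 0))
  }
  t <- dm / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

# Classic one-way fixed-effects ANOVA F test.
oneway_anova <- function(groups) {
  k <- length(groups)
  n <- lengths(groups)
  all_x <- unlist(groups)
  grand <- mean(all_x)
  ssb <- sum(n * (vapply(groups, mean, numeric(1L)) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1L)))
  df1 <- k - 1; df2 <- length(all_x) - k
  f <- (ssb / df1) / (ssw / df2)
  list(statistic = f, df = c(df1, df2),
       p_value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison: %s>\n", paste(x$groups, collapse = " vs ")))
  for (i in seq_along(x$groups))
    cat(sprintf("  %s: n = %d, mean AUC = %.4f\n",
                x$groups[i], x$n[i], x$mean_auc[i]))
  cat(sprintf("  %s: statistic = %.4f, p = %.3g; shift: %s\n",
              x$test, x$statistic, x$p_value, x$shift))
  invisible(x)
}

#' Profile one cell from image + contour
#'
#' Convenience wrapper: pick a center, build shells, profile.
#'
#' @inheritParams select_center
#' @inheritParams cumulative_profile
#' @param image organelle-channel `intensity_image`.
#' @param n_increments shells count (default 10).
#' @return a `radial_profile`.
#' @export
profile_cell <- function(image, contour, center_mode = "centroid",
                         center = NULL, n_increments = 10, cluster = NULL,
                         background = 0, cell_id = contour$source_label) {
  ctr <- select_center(contour,
                       mode = if (!is.null(center)) "manual" else center_mode,
                       point = center)
  shells <- build_shells(contour, ctr, n_increments)
  cumulative_profile(image, shells, cluster = cluster,
                     background = background, cell_id = cell_id)
}
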