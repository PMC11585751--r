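#' Configuration for the synthetic H-DAB ROI generator
#'
#' Parameters of a simulated Ki-67 field. Nuclei are rendered as
#' ellipses of roughly equal area (axis ratio up to `axis_ratio_max`),
#' all carrying the haematoxylin optical-density level; positive nuclei
#' additionally carry the DAB level. Optical densities are composed into
#' an 8-bit RGB image through the Beer-Lambert relation and the H-DAB
#' stain vectors, with additive Gaussian pixel noise. Debris specks of
#' sub-nuclear area are rendered with a DAB-dominant, weakly
#' haematoxylin-stained colour -- the grubby background particles that
#' a naive pipeline miscounts as positive cells. A `pleomorphic_fraction`
#' of nuclei can be enlarged to exercise the over-splitting failure mode
#' of watershed segmentation on bizarre nuclei.
#'
#' @param width,height raster size in pixels.
#' @param mpp microns per pixel (default 0.5, i.e. a 20x scan).
#' @param n_nuclei number of nuclei.
#' @param radius_um uniform range of equivalent nuclear radii in microns
#'   (default 2.5-4, typical tumour nuclei).
#' @param axis_ratio_max maximum ellipse axis ratio (default 1.3).
#' @param positive_fraction fraction of nuclei rendered Ki-67 positive;
#'   the positive count is the rounded exact count, so the ground-truth
#'   PI is known by construction.
#' @param min_sep_um minimum centre-to-centre separation in microns
#'   (default 10, keeping default-size nuclei disjoint).
#' @param hematoxylin_od,dab_od stain optical-density levels of rendered
#'   nuclei.
#' @param noise_sd additive Gaussian noise SD in 8-bit intensity counts.
#' @param n_debris number of debris specks.
#' @param debris_area_px integer range of debris areas in pixels.
#' @param pleomorphic_fraction fraction of nuclei enlarged 2x.
#' @param seed RNG seed, or `NULL` to use the current RNG state.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(width = 288, height = 288, mpp = 0.5,
                              n_nuclei = 80, radius_um = c(2.5, 4),
                              axis_ratio_max = 1.3,
                              positive_fraction = 0.1,
                              min_sep_um = 10,
                              hematoxylin_od = 0.7, dab_od = 0.8,
                              noise_sd = 3,
                              n_debris = 6, debris_area_px = c(2, 4),
                              pleomorphic_fraction = 0,
                              seed = NULL) {
  stopifnot(width >= 1, height >= 1, mpp > 0, n_nuclei >= 0,
            length(radius_um) == 2, all(radius_um > 0),
            axis_ratio_max >= 1,
            positive_fraction >= 0, positive_fraction <= 1,
            min_sep_um > 0, hematoxylin_od >= 0, dab_od >= 0,
            noise_sd >= 0, n_debris >= 0,
            pleomorphic_fraction >= 0, pleomorphic_fraction <= 1)
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate one H-DAB ROI image with pixel-level ground truth
#'
#' Draws non-overlapping elliptical nuclei by rejection sampling of
#' centres under the configured minimum separation, assigns exactly
#' `round(positive_fraction * n_nuclei)` of them positive, renders
#' optical densities, composes the RGB image, and adds noise and debris.
#' Deterministic for a fixed `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @return List with `image` (an [rgb_image()]) and `truth`, a list of
#'   `nuclei` (data.frame: id, row, col, radius_px, axis_a, axis_b,
#'   theta, positive), `instance_map` (integer matrix), `n_pos`,
#'   `n_total` and `true_pi` (percent; `NA` when `n_nuclei = 0`).
#' @examples
#' sim <- simulate_roi_image(simulation_config(n_nuclei = 10, seed = 7))
#' sim$truth$true_pi
#' @export
simulate_roi_image <- function(cfg) {
  if (!inherits(cfg, "simulation_config"))
    stop("`cfg` must be a simulation_config")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  H <- cfg$height; W <- cfg$width
  n <- cfg$n_nuclei
  r_px <- cfg$radius_um / cfg$mpp
  sep_px <- cfg$min_sep_um / cfg$mpp
  # largest possible semi-axis, so every nucleus fits fully inside
  margin <- max(r_px) * sqrt(cfg$axis_ratio_max) *
    (if (cfg$pleomorphic_fraction > 0) 2 else 1) + 2
  if (n > 0 && (H - 2 * margin < 1 || W - 2 * margin < 1))
    stop("raster too small for the configured nucleus radius margin")

  # centre placement by capped rejection sampling
  rows <- numeric(n); cols <- numeric(n)
  if (n > 0) {
    placed <- 0L
    attempts <- 0L
    max_attempts <- 400L * n
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop(sprintf(paste0("could not place %d nuclei with %g um minimum ",
                            "separation in a %d x %d px field; enlarge the ",
                            "raster or relax `min_sep_um`"),
                     n, cfg$min_sep_um, H, W))
      r <- runif(1, margin, H - margin)
      c <- runif(1, margin, W - margin)
      if (placed == 0L ||
          all((rows[seq_len(placed)] - r)^2 +
              (cols[seq_len(placed)] - c)^2 >= sep_px^2)) {
        placed <- placed + 1L
        rows[placed] <- r; cols[placed] <- c
      }
    }
  }

  radius <- if (n > 0) runif(n, r_px[1], r_px[2]) else numeric(0)
  if (n > 0 && cfg$pleomorphic_fraction > 0) {
    big <- runif(n) < cfg$pleomorphic_fraction
    radius[big] <- radius[big] * 2
  }
  q <- if (n > 0) runif(n, 1, cfg$axis_ratio_max) else numeric(0)
  axis_a <- radius * sqrt(q)
  axis_b <- radius / sqrt(q)
  theta <- if (n > 0) runif(n, 0, pi) else numeric(0)
  n_pos <- round(cfg$positive_fraction * n)
  positive <- rep(FALSE, n)
  if (n_pos > 0) positive[sample.int(n, n_pos)] <- TRUE

  h_od <- matrix(0, H, W)
  d_od <- matrix(0, H, W)
  inst <- matrix(0L, H, W)
  for (i in seq_len(n)) {
    rr <- max(axis_a[i], axis_b[i])
    r0 <- max(1L, floor(rows[i] - rr)); r1 <- min(H, ceiling(rows[i] + rr))
    c0 <- max(1L, floor(cols[i] - rr)); c1 <- min(W, ceiling(cols[i] + rr))
    gr <- (r0:r1) - 0.5 - (rows[i] - 0.5)
    gc <- (c0:c1) - 0.5 - (cols[i] - 0.5)
    dy <- matrix(gr, length(gr), length(gc))
    dx <- matrix(gc, length(gr), length(gc), byrow = TRUE)
    u <- (dx * cos(theta[i]) + dy * sin(theta[i])) / axis_a[i]
    v <- (-dx * sin(theta[i]) + dy * cos(theta[i])) / axis_b[i]
    inside <- u^2 + v^2 <= 1
    blk_r <- r0:r1; blk_c <- c0:c1
    sub_h <- h_od[blk_r, blk_c]; sub_d <- d_od[blk_r, blk_c]
    sub_i <- inst[blk_r, blk_c]
    new_px <- inside & sub_i == 0L
    sub_h[new_px] <- cfg$hematoxylin_od
    if (positive[i]) sub_d[new_px] <- cfg$dab_od
    sub_i[new_px] <- i
    h_od[blk_r, blk_c] <- sub_h; d_od[blk_r, blk_c] <- sub_d
    inst[blk_r, blk_c] <- sub_i
  }

  # debris: DAB-dominant specks with a weak haematoxylin component,
  # dropped on background pixels only
  if (cfg$n_debris > 0) {
    for (k in seq_len(cfg$n_debris)) {
      area <- sample(cfg$debris_area_px[1]:cfg$debris_area_px[2], 1)
      r <- sample.int(H - 2L, 1) + 1L
      c <- sample.int(W - 2L, 1) + 1L
      px <- cbind(r, c)
      while (nrow(px) < area) {
        step <- px[nrow(px), ] + sample(c(-1L, 0L, 1L), 2, replace = TRUE)
        step <- pmin(pmax(step, 1L), c(H, W))
        px <- rbind(px, step)
      }
      px <- unique(px)
      bg <- inst[px] == 0L
      px <- px[bg, , drop = FALSE]
      d_od[px] <- cfg$dab_od
      h_od[px] <- 0.6 * cfg$hematoxylin_od
    }
  }

  rgb <- od_to_rgb(h_od, d_od)
  if (cfg$noise_sd > 0)
    rgb <- rgb + rnorm(length(rgb), 0, cfg$noise_sd)
  rgb <- pmin(pmax(rgb, 0), 255)

  nuclei <- data.frame(id = seq_len(n), row = rows, col = cols,
                       radius_px = radius, axis_a = axis_a,
                       axis_b = axis_b, theta = theta,
                       positive = positive)
  list(image = rgb_image(rgb, cfg$mpp),
       truth = list(nuclei = nuclei, instance_map = inst,
                    n_pos = sum(positive), n_total = n,
                    true_pi = if (n > 0) 100 * sum(positive) / n else NA_real_))
}

#' Simulate a multi-slide ROI study
#'
#' Generates `n_slides * rois_per_slide` ROI fixtures whose true PIs are
#' drawn from a low-heavy mixture (a `pi_low_fraction` share of ROIs
#' uniform on 0-10%, the remainder uniform on 10-100%), matching the
#' strong skew towards low-proliferation fields seen in routine Ki-67
#' material. Per ROI the positive-nucleus count is the rounded exact
#' count, so the manifest's `true_pi` is exact. Images are only rendered
#' on request; the manifest alone feeds the reader-study statistics.
#'
#' @param n_slides,rois_per_slide study dimensions.
#' @param cfg template [simulation_config()]; `positive_fraction` and
#'   `seed` are overridden per ROI.
#' @param seed study-level RNG seed.
#' @param pi_low_fraction share of ROIs drawn from the 0-10% stratum.
#' @param render if `TRUE`, also generate each ROI's image, ground truth
#'   and a full-frame rectangular ROI polygon.
#' @param dir optional output directory: writes `<roi>.png`,
#'   `<roi>.geojson` and `manifest.csv`.
#' @return List with `manifest` (data.frame: roi_id, slide, true_pi,
#'   n_pos, n_total) and, when rendered, `fixtures` (list of
#'   `image` / `truth` / `roi` per ROI).
#' @examples
#' st <- simulate_study(2, 3, seed = 1)
#' nrow(st$manifest) # 6
#' @export
simulate_study <- function(n_slides, rois_per_slide,
                           cfg = simulation_config(), seed = 1,
                           pi_low_fraction = 0.7,
                           render = FALSE, dir = NULL) {
  stopifnot(n_slides >= 1, rois_per_slide >= 1)
  set.seed(seed)
  n_roi <- n_slides * rois_per_slide
  low <- runif(n_roi) < pi_low_fraction
  true_pi_target <- ifelse(low, runif(n_roi, 0, 10), runif(n_roi, 10, 100))
  n_pos <- round(true_pi_target / 100 * cfg$n_nuclei)
  true_pi <- 100 * n_pos / cfg$n_nuclei
  roi_seeds <- sample.int(.Machine$integer.max - 1L, n_roi)
  manifest <- data.frame(
    roi_id = sprintf("slide%03d_roi%d",
                     rep(seq_len(n_slides), each = rois_per_slide),
                     rep(seq_len(rois_per_slide), n_slides)),
    slide = rep(seq_len(n_slides), each = rois_per_slide),
    true_pi = true_pi, n_pos = n_pos, n_total = cfg$n_nuclei)
  fixtures <- NULL
  if (render) {
    fixtures <- vector("list", n_roi)
    names(fixtures) <- manifest$roi_id
    for (i in seq_len(n_roi)) {
      ci <- cfg
      ci$positive_fraction <- n_pos[i] / cfg$n_nuclei
      ci$seed <- roi_seeds[i]
      sim <- simulate_roi_image(ci)
      roi <- roi_polygon(cbind(c(2, cfg$width - 2, cfg$width - 2, 2),
                               c(2, 2, cfg$height - 2, cfg$height - 2)),
                         id = manifest$roi_id[i])
      fixtures[[i]] <- list(image = sim$image, truth = sim$truth, roi = roi)
    }
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    if (render) {
      for (nm in names(fixtures)) {
        write_image_rgb(fixtures[[nm]]$image, file.path(dir, paste0(nm, ".png")))
        write_roi_annotations(list(fixtures[[nm]]$roi),
                              file.path(dir, paste0(nm, ".geojson")))
      }
    }
  }
  list(manifest = manifest, fixtures = fixtures)
}

#' Visual-reader model
#'
#' Parameterises how one reader scores PIs: an additive bias, Gaussian
#' scoring noise, rounding to the visual-assessment interval, and
#' clamping to \[0, 100\]. Assisted readers score around the AI's output
#' (typically with small noise); unassisted readers score around the
#' true PI (typically with larger noise).
#'
#' @param id reader identifier.
#' @param bias additive bias in percentage points.
#' @param noise_sd scoring noise SD in percentage points.
#' @param rounding scoring interval in pp: 0 (none), 5 or 10. Visual
#'   scoring is conventionally reported at 5-10 pp intervals.
#' @param assisted logical; if `TRUE` the reader anchors on the AI score.
#' @return A list of class `reader_model`.
#' @export
reader_model <- function(id, bias = 0, noise_sd = 5, rounding = 5,
                         assisted = FALSE) {
  stopifnot(noise_sd >= 0, rounding %in% c(0, 5, 10))
  structure(list(id = as.character(id), bias = bias, noise_sd = noise_sd,
                 rounding = rounding, assisted = assisted),
            class = "reader_model")
}

#' Simulate a table of reader scores
#'
#' Applies each [reader_model()] to the true PIs (unassisted readers) or
#' to the AI's scores (assisted readers): score =
#' `clamp(round_to_interval(anchor + bias + noise), 0, 100)`.
#'
#' @param true_pis numeric vector of true PIs in \[0, 100\].
#' @param readers list of [reader_model()] objects.
#' @param ai_scores AI scores per ROI; required if any reader is
#'   assisted.
#' @param seed RNG seed, or `NULL`.
#' @return A [score_table()] (readers x ROIs).
#' @examples
#' tab <- simulate_reader_scores(c(5, 20, 60),
#'   list(reader_model("P1", noise_sd = 5)), seed = 1)
#' tab$scores
#' @export
simulate_reader_scores <- function(true_pis, readers, ai_scores = NULL,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(vapply(readers, function(r) isTRUE(r$assisted), logical(1))) &&
      is.null(ai_scores))
    stop("`ai_scores` is required when any reader is AI-assisted")
  n <- length(true_pis)
  scores <- matrix(NA_real_, length(readers), n)
  ids <- character(length(readers))
  for (i in seq_along(readers)) {
    rd <- readers[[i]]
    if (!inherits(rd, "reader_model")) stop("`readers` must be reader_model objects")
    ids[i] <- rd$id
    anchor <- if (rd$assisted) ai_scores else true_pis
    raw <- anchor + rd$bias + rnorm(n, 0, rd$noise_sd)
    if (rd$rounding > 0) raw <- round(raw / rd$rounding) * rd$rounding
    scores[i, ] <- pmin(pmax(raw, 0), 100)
  }
  score_table(scores, reader_ids = ids,
              roi_ids = names(true_pis) %||% paste0("roi", seq_len(n)))
}

#' Default reader panel for a two-round study simulation
#'
#' Three unassisted readers ("P1", "P2", "P3") and their AI-assisted
#' counterparts ("P1-AI", "P2-AI", "P3-AI"). The unassisted biases
#' (+5.0, -5.1, +0.2 pp) reproduce the between-reader mean differences
#' observed in visual Ki-67 scoring panels (about +10, +4.8 and -5.3 pp
#' pairwise); assisted biases are near zero because assisted readers
#' anchor on a common AI output. Noise SDs default to 10 pp unassisted
#' and 1.8 pp assisted.
#'
#' @param noise_pre,noise_post scoring noise SD (pp) for the unassisted
#'   and assisted rounds.
#' @param rounding scoring interval in pp (0, 5 or 10) applied to both
#'   rounds; 0 keeps the scores continuous.
#' @return List of six [reader_model()] objects.
#' @export
study_reader_models <- function(noise_pre = 10, noise_post = 1.8,
                                rounding = 0) {
  pre_bias <- c(P1 = 5.0, P2 = -5.1, P3 = 0.2)
  post_bias <- c(`P1-AI` = 0.07, `P2-AI` = -0.07, `P3-AI` = 0.08)
  c(mapply(function(id, b) reader_model(id, bias = b, noise_sd = noise_pre,
                                        rounding = rounding),
           names(pre_bias), pre_bias, SIMPLIFY = FALSE),
    mapply(function(id, b) reader_model(id, bias = b, noise_sd = noise_post,
                                        rounding = rounding, assisted = TRUE),
           names(post_bias), post_bias, SIMPLIFY = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
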