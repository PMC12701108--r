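# Seeded synthetic DCE phantom: two breast cross-sections on a thorax
# background, lesions with persistent / plateau / washout time-courses, thin
# vessel distractors and a strongly enhancing cardiac confounder. Ground
# truth masks accompany every stack so each pipeline stage is testable
# without patient data.

#' Phantom generator configuration
#'
#' Defines the geometry, lesion load, kinetics, distractors and noise of one
#' synthetic DCE slice. With a fixed `seed` the generated stack and truth are
#' bit-identical across calls.
#'
#' @param image_shape integer c(rows, cols), default 256 x 256.
#' @param n_lesions number of lesions to place (default 3).
#' @param lesion_size_range target lesion areas in pixels, c(min, max),
#'   default c(10, 60). Ignored when `lesion_sizes` is given.
#' @param lesion_sizes optional explicit vector of target areas (px), length
#'   `n_lesions`; used by the benchmark for deterministic size coverage.
#' @param kinetic_mix named fractions for c(persistent, plateau, washout)
#'   summing to 1; lesion classes are drawn from this mix unless
#'   `kinetic_classes` is given.
#' @param kinetic_classes optional explicit character vector of classes.
#' @param n_vessels number of thin curvilinear vessel distractors (default 2).
#' @param include_thorax_confounder place a strongly enhancing cardiac
#'   region in the thorax band (default TRUE).
#' @param noise_sd Gaussian noise standard deviation relative to the unit
#'   intensity scale, applied to body tissue in every phase (default 0.01).
#' @param n_post_phases number of post-contrast phases (default 6).
#' @param seed integer RNG seed (default 1).
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(image_shape = c(256L, 256L),
                           n_lesions = 3L,
                           lesion_size_range = c(10, 60),
                           lesion_sizes = NULL,
                           kinetic_mix = c(persistent = 1/3, plateau = 1/3, washout = 1/3),
                           kinetic_classes = NULL,
                           n_vessels = 2L,
                           include_thorax_confounder = TRUE,
                           noise_sd = 0.01,
                           n_post_phases = 6L,
                           seed = 1L) {
  if (abs(sum(kinetic_mix) - 1) > 1e-8) stop("kinetic_mix fractions must sum to 1")
  if (!all(names(kinetic_mix) %in% c("persistent", "plateau", "washout")))
    stop("kinetic_mix must be named persistent/plateau/washout")
  if (any(lesion_size_range < 1)) stop("lesion sizes must be >= 1 px")
  if (!is.null(lesion_sizes) && length(lesion_sizes) != n_lesions)
    stop("lesion_sizes must have length n_lesions")
  if (n_post_phases < 3L) stop("need at least 3 post-contrast phases")
  structure(list(
    image_shape = as.integer(image_shape), n_lesions = as.integer(n_lesions),
    lesion_size_range = lesion_size_range, lesion_sizes = lesion_sizes,
    kinetic_mix = kinetic_mix, kinetic_classes = kinetic_classes,
    n_vessels = as.integer(n_vessels),
    include_thorax_confounder = isTRUE(include_thorax_confounder),
    noise_sd = noise_sd, n_post_phases = as.integer(n_post_phases),
    seed = as.integer(seed)), class = "phantom_config")
}

# Kinetic curve value in [0, 1] at post-contrast phase p (p = 0 is Phase 0).
# All classes take up contrast early (the premise of using phases 2 and 3):
# persistent rises fast then keeps rising (concave, strictly monotone);
# plateau reaches its maximum by phase 2 and stays; washout peaks at phase 2
# then strictly decreases.
.kinetic_value <- function(class, p, n_post) {
  if (p == 0) return(0)
  switch(class,
    persistent = 0.85 * min(p / 2, 1) + 0.15 * p / n_post,
    plateau    = min(p / 2, 1),
    washout    = if (p <= 2) p / 2 else 1 - 0.15 * (p - 2),
    stop("unknown kinetic class: ", class))
}

# Smooth unit-range random field (coarse Gaussian noise, blurred).
.smooth_field <- function(shape, sigma = 8) {
  f <- matrix(rnorm(prod(shape)), shape[1L], shape[2L])
  f <- EBImage::gblur(f, sigma = sigma)
  to_unit_range(f)
}

.raster_ellipse <- function(shape, r0, c0, a, b, theta) {
  rr <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
  cc <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
  dr <- rr - r0; dc <- cc - c0
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# Thin curvilinear vessel: a gently wobbling line segment dilated to ~3 px
# width. Returns a logical mask.
.raster_vessel <- function(shape, r0, c0, theta, len, wobble = 1.2) {
  t <- seq(0, len, by = 0.4)
  off <- wobble * sin(t / len * 2 * pi)
  r <- r0 + t * cos(theta) - off * sin(theta)
  c <- c0 + t * sin(theta) + off * cos(theta)
  m <- matrix(FALSE, shape[1L], shape[2L])
  ri <- round(r); ci <- round(c)
  ok <- ri >= 1 & ri <= shape[1L] & ci >= 1 & ci <= shape[2L]
  m[cbind(ri[ok], ci[ok])] <- TRUE
  .as_logical_mask(EBImage::dilate(m * 1, disk_kernel(1)) > 0)
}

#' Generate one synthetic DCE phase stack with ground truth
#'
#' Builds a Phase 0 anatomy image (two half-disk breast cross-sections
#' attached to a flat posterior thorax band over a zero air background) and
#' `n_post_phases` post-contrast phases in which lesions enhance following
#' their assigned kinetic curve, vessels enhance early, the cardiac
#' confounder enhances strongly, and healthy parenchyma enhances mildly.
#' Gaussian noise at `noise_sd` is added to body tissue; the air background
#' stays exactly zero.
#'
#' @param config a [phantom_config()].
#' @return list with elements `stack` (a [dce_stack()]) and `truth`, an
#'   object of class `phantom_truth` with fields `lesion_masks` (list of
#'   logical matrices, each with attributes `kinetic` and `area`),
#'   `vessel_mask`, `breast_mask`, `thorax_mask`, `heart_mask`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  .local_seed(config$seed, {
    shp <- config$image_shape
    nr <- shp[1L]; nc <- shp[2L]
    chest_row <- round(0.62 * nr)                       # posterior chest wall
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)

    # two half-disk breasts, flat side on the chest wall, clear of midline
    cen <- c(round(0.26 * nc), round(0.74 * nc))
    rad <- round(runif(2, 0.17, 0.21) * nr)
    breast_mask <- matrix(FALSE, nr, nc)
    for (i in 1:2) {
      b <- (rr - chest_row)^2 + (cc - cen[i])^2 <= rad[i]^2 & rr <= chest_row
      breast_mask <- breast_mask | b
    }

    # posterior thorax band
    thorax_mask <- rr > chest_row & rr <= min(nr, chest_row + round(0.25 * nr)) &
      cc >= round(0.05 * nc) & cc <= round(0.95 * nc)

    # cardiac confounder: ellipse just behind the chest wall, near midline
    # centred deep in the thorax so only its anterior rim can enter the
    # cropped frame through the posterior crop margin
    heart_mask <- matrix(FALSE, nr, nc)
    if (config$include_thorax_confounder) {
      heart_mask <- .raster_ellipse(shp, chest_row + round(0.12 * nr),
                                    round(0.5 * nc), 0.1 * nr, 0.1 * nc, 0) & thorax_mask
    }

    # lesions: ellipses fully inside a breast, pairwise disjoint
    sizes <- if (!is.null(config$lesion_sizes)) config$lesion_sizes
             else runif(config$n_lesions, config$lesion_size_range[1L], config$lesion_size_range[2L])
    classes <- if (!is.null(config$kinetic_classes)) config$kinetic_classes
               else sample(names(config$kinetic_mix), config$n_lesions,
                           replace = TRUE, prob = config$kinetic_mix)
    occupied <- matrix(FALSE, nr, nc)
    lesion_masks <- vector("list", config$n_lesions)
    for (i in seq_len(config$n_lesions)) {
      placed <- FALSE
      for (try in 1:200) {
        A <- sizes[i]
        # aspect ratio: keep the minor axis >= ~5.6 px for mass-like lesions
        # (masses are roundish; thin elongated shapes are the vessels' role)
        q <- if (A < 16) 1 else runif(1, 1, max(1, min(1.8, A / (pi * 2.8^2))))
        a <- sqrt(A * q / pi); b <- sqrt(A / (pi * q))
        side <- sample(1:2, 1)
        r0 <- runif(1, chest_row - 0.8 * rad[side], chest_row - 0.2 * rad[side])
        c0 <- runif(1, cen[side] - 0.6 * rad[side], cen[side] + 0.6 * rad[side])
        th <- runif(1, 0, pi)
        m <- .raster_ellipse(shp, r0, c0, a, b, th)
        if (!any(m)) next
        # one corrective rescale toward the target pixel count, then keep
        # sub-15 targets strictly below the downstream size rule
        sc <- sqrt(A / sum(m))
        if (abs(sc - 1) > 0.05) m <- .raster_ellipse(shp, r0, c0, a * sc, b * sc, th)
        if (!any(m)) next
        while (A < 15 && sum(m) >= 15) {
          a <- a * 0.93; b <- b * 0.93
          m <- .raster_ellipse(shp, r0, c0, a, b, th)
        }
        if (!any(m)) next
        if (all(breast_mask[m]) && !any(occupied[m])) {
          grown <- .as_logical_mask(EBImage::dilate(m * 1, disk_kernel(6)) > 0)
          occupied <- occupied | grown
          attr(m, "kinetic") <- classes[i]
          attr(m, "area") <- sum(m)
          lesion_masks[[i]] <- m
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place lesion ", i, " disjointly after 200 tries")
    }

    # vessels: thin elongated curves inside the breasts, away from lesions
    vessel_mask <- matrix(FALSE, nr, nc)
    for (i in seq_len(config$n_vessels)) {
      for (try in 1:200) {
        side <- sample(1:2, 1)
        len <- runif(1, 24, 40)
        theta <- runif(1, 0, pi)
        r0 <- runif(1, chest_row - 0.7 * rad[side], chest_row - 0.3 * rad[side])
        c0 <- runif(1, cen[side] - 0.5 * rad[side], cen[side] + 0.5 * rad[side])
        v <- .raster_vessel(shp, r0, c0, theta, len)
        if (any(v) && all(breast_mask[v]) && !any(occupied[v])) {
          occupied <- occupied | .as_logical_mask(EBImage::dilate(v * 1, disk_kernel(3)) > 0)
          vessel_mask <- vessel_mask | v
          break
        }
      }
    }

    # Phase 0 anatomy (unit-scale arbitrary intensities)
    parench <- .smooth_field(shp, sigma = 10)
    base <- matrix(0, nr, nc)
    base[thorax_mask] <- 0.30 + 0.05 * parench[thorax_mask]
    base[heart_mask] <- 0.35
    base[breast_mask] <- 0.35 + 0.08 * parench[breast_mask]
    base[vessel_mask] <- 0.33
    for (m in lesion_masks) base[m] <- 0.38

    # enhancement amplitudes: all lesions are comparably bright in the
    # early phases, the tight spread mirroring early contrast uptake
    les_amp <- runif(config$n_lesions, 0.6, 0.75)
    ves_amp <- runif(max(config$n_vessels, 1L), 0.5, 0.6)
    enh_field <- .smooth_field(shp, sigma = 12)        # mild parenchymal uptake
    body <- breast_mask | thorax_mask

    phases <- vector("list", config$n_post_phases + 1L)
    for (p in 0:config$n_post_phases) {
      img <- base
      if (p > 0) {
        img[breast_mask] <- img[breast_mask] +
          0.12 * enh_field[breast_mask] * min(p / 2, 1)
        img[thorax_mask] <- img[thorax_mask] + 0.04 * (p / config$n_post_phases)
        if (any(heart_mask)) img[heart_mask] <- img[heart_mask] + 0.7 * min(p / 1.5, 1)
        if (any(vessel_mask)) {
          vi <- which(vessel_mask)
          img[vi] <- img[vi] + mean(ves_amp) * min(p, 1)
        }
        for (i in seq_len(config$n_lesions)) {
          k <- .kinetic_value(attr(lesion_masks[[i]], "kinetic"), p, config$n_post_phases)
          img[lesion_masks[[i]]] <- img[lesion_masks[[i]]] + les_amp[i] * k
        }
      }
      if (config$noise_sd > 0) {
        n_body <- sum(body)
        img[body] <- pmax(img[body] + rnorm(n_body, 0, config$noise_sd), 0)
      }
      phases[[p + 1L]] <- img
    }

    truth <- structure(list(lesion_masks = lesion_masks, vessel_mask = vessel_mask,
                            breast_mask = breast_mask, thorax_mask = thorax_mask,
                            heart_mask = heart_mask),
                       class = "phantom_truth")
    list(stack = dce_stack(phases), truth = truth)
  })
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d lesions (%s), vessels %d px, breasts %d px\n",
              length(x$lesion_masks),
              paste(vapply(x$lesion_masks, attr, "", "kinetic"), collapse = ", "),
              sum(x$vessel_mask), sum(x$breast_mask)))
  invisible(x)
}

#' Simulate two-class Gaussian feature clouds
#'
#' Balanced two-class feature matrix whose class means differ by `d_prime`
#' within-class standard deviations along every feature; at the default
#' `d_prime = 4` the clouds are linearly separable for practical purposes
#' (the overall Mahalanobis separation is `d_prime * sqrt(n_features)`),
#' which makes classifier-recovery bounds robust to the seed. Used to
#' validate the classification stack on data of known separability.
#'
#' @param n total samples (balanced).
#' @param n_features feature count (default 8, the size of the selected
#'   pipeline feature set).
#' @param d_prime per-feature standardized class-mean shift (default 4).
#' @param seed RNG seed.
#' @return list(X: n x n_features matrix, y: factor healthy/lesion).
#' @export
simulate_feature_clouds <- function(n = 400L, n_features = 8L, d_prime = 4, seed = 1L) {
  .local_seed(seed, {
    y <- factor(rep(c("healthy", "lesion"), length.out = n),
                levels = c("healthy", "lesion"))
    delta <- d_prime
    X <- matrix(rnorm(n * n_features), n, n_features)
    X[y == "lesion", ] <- X[y == "lesion", ] + delta
    colnames(X) <- paste0("f", seq_len(n_features))
    list(X = X, y = y)
  })
}

#' Generate the reproducible phantom benchmark
#'
#' A deterministic set of phantom slices whose per-slice seeds derive from
#' one master seed. Lesion target sizes cycle through a fixed schedule that
#' spans 10-60 px and places a sub-15-px lesion (to be rejected by the rule
#' stage) in every slice; kinetic classes cycle persistent / plateau /
#' washout.
#'
#' @param n_slices number of slices (default 20).
#' @param seed master seed.
#' @return list of length `n_slices`; each element is the
#'   list(stack, truth) returned by [generate_phantom()].
#' @export
generate_benchmark <- function(n_slices = 20L, seed = 1L) {
  if (n_slices < 1L) stop("n_slices must be >= 1")
  schedule <- list(c(12, 28, 45), c(10, 35, 60), c(14, 25, 50))
  classes <- c("persistent", "plateau", "washout")
  lapply(seq_len(n_slices), function(i) {
    sizes <- schedule[[(i - 1L) %% length(schedule) + 1L]]
    kin <- classes[((i - 1L) + seq_along(sizes) - 1L) %% 3L + 1L]
    cfg <- phantom_config(n_lesions = length(sizes), lesion_sizes = sizes,
                          kinetic_classes = kin, seed = .derive_seed(seed, i))
    generate_phantom(cfg)
  })
}
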