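# Deterministic synthetic imaging fixtures: the three QC computations are
# testable without microscopy data because each generator knows its ground
# truth (erosion fraction, bead speeds, cell counts).

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic design/print mask pair
#'
#' Target: a scaffold-like grid of bars. Experiment: the target eroded by
#' \code{erosion_px} (simulating shrinkage / missing material), optionally
#' shifted (print offset) and with added specks (excess material).
#'
#' @param width,height mask size (px).
#' @param erosion_px erosion radius of the printed copy (px).
#' @param shift integer (dy, dx) print offset (px).
#' @param n_specks number of random excess-material specks.
#' @param seed RNG seed.
#' @return List: \code{target}, \code{experiment} (logical matrices),
#'   \code{truth} (pixel fractions computed from the construction).
#' @export
synth_mask_pair <- function(width = 256, height = 256, erosion_px = 2,
                            shift = c(0, 0), n_specks = 0, seed = 1) {
  with_seed(seed, {
    t_ <- matrix(FALSE, height, width)
    bar <- max(6, round(width / 16))
    gap <- 2 * bar
    for (x0 in seq(bar, width - 2 * bar, by = gap)) {
      t_[seq(bar, height - bar), x0:(x0 + bar - 1)] <- TRUE
    }
    for (y0 in seq(bar, height - 2 * bar, by = 3 * gap)) {
      t_[y0:(y0 + bar - 1), seq(bar, width - bar)] <- TRUE
    }
    e <- t_
    if (erosion_px > 0) {
      brush <- EBImage::makeBrush(2 * erosion_px + 1, "disc")
      e <- as_gray_matrix(EBImage::erode(EBImage::Image(t(e * 1)),
                                         brush)) > 0.5
    }
    if (any(shift != 0)) e <- shift_mask(e, shift[1], shift[2])
    if (n_specks > 0) {
      for (k in seq_len(n_specks)) {
        cy <- sample(5:(height - 5), 1)
        cx <- sample(5:(width - 5), 1)
        e[cy + (-2:2), cx + (-2:2)] <- TRUE
      }
    }
    npx <- length(t_)
    list(target = t_, experiment = e,
         truth = list(yellow = sum(t_ & e) / npx,
                      green = sum(t_ & !e) / npx,
                      red = sum(!t_ & e) / npx,
                      black = sum(!t_ & !e) / npx))
  })
}

#' Synthetic bead time-lapse movie
#'
#' Beads move in straight horizontal lanes at the given speeds, rendered
#' with a Gaussian point-spread function plus Gaussian camera noise. The
#' defaults emulate 1 um fluorescent beads imaged at high magnification
#' with a short exposure: bright, well-sampled spots on a quiet
#' background.
#'
#' @param speeds_mm_s one speed per bead (mm/s).
#' @param n_frames number of frames.
#' @param width,height frame size (px).
#' @param pixel_size um per pixel.
#' @param frame_interval seconds between frames.
#' @param psf_sigma_px PSF standard deviation (px).
#' @param amplitude peak bead intensity.
#' @param noise_sd Gaussian noise SD.
#' @param seed RNG seed.
#' @return List: \code{frames} (y, x, t array), \code{truth} (tibble with
#'   per-bead speeds), and acquisition metadata.
#' @export
synth_bead_movie <- function(speeds_mm_s, n_frames = 15, width = 160,
                             height = NULL, pixel_size = 1,
                             frame_interval = 5e-4, psf_sigma_px = 1.5,
                             amplitude = 0.85, noise_sd = 0.002, seed = 1) {
  nb <- length(speeds_mm_s)
  if (is.null(height)) height <- max(48, 16 * (nb + 1))
  with_seed(seed, {
    px_per_frame <- speeds_mm_s * 1000 * frame_interval / pixel_size
    margin <- 8
    total <- px_per_frame * (n_frames - 1)
    if (any(total > width - 2 * margin)) {
      stop("trajectory exceeds frame width; reduce n_frames or speed")
    }
    x0 <- margin + runif(nb) * (width - 2 * margin - total)
    lane <- height * (seq_len(nb)) / (nb + 1) + runif(nb, -2, 2)
    xs <- matrix(0, height, width)
    Xg <- matrix(rep(seq_len(width), each = height), height, width)
    Yg <- matrix(rep(seq_len(height), width), height, width)
    frames <- array(0, dim = c(height, width, n_frames))
    for (f in seq_len(n_frames)) {
      img <- matrix(0, height, width)
      for (b in seq_len(nb)) {
        bx <- x0[b] + px_per_frame[b] * (f - 1)
        by <- lane[b]
        img <- img + amplitude *
          exp(-((Xg - bx)^2 + (Yg - by)^2) / (2 * psf_sigma_px^2))
      }
      img <- img + matrix(stats::rnorm(height * width, 0, noise_sd),
                          height, width)
      frames[, , f] <- pmin(1, pmax(0, img))
    }
    list(frames = frames,
         truth = tibble::tibble(bead = seq_len(nb),
                                speed_mm_s = speeds_mm_s,
                                px_per_frame = px_per_frame),
         pixel_size = pixel_size, frame_interval = frame_interval)
  })
}

#' Synthetic live/dead image pair
#'
#' Non-touching disks: \code{n_live} in the green channel, \code{n_dead}
#' in the red channel, with randomised intensities. Disk centres are
#' rejection-sampled to keep a minimum separation, so the component
#' counter can recover the exact counts.
#'
#' @param n_live,n_dead disk counts.
#' @param width,height image size (px).
#' @param radius_px disk radius (px).
#' @param seed RNG seed.
#' @return List: \code{green}, \code{red} matrices and \code{truth}
#'   counts.
#' @export
synth_live_dead <- function(n_live = 50, n_dead = 10, width = 400,
                            height = 300, radius_px = 4, seed = 1) {
  with_seed(seed, {
    ncells <- n_live + n_dead
    min_sep <- 2 * radius_px + 4
    centers <- matrix(0, 0, 2)
    guard <- 0
    while (nrow(centers) < ncells && guard < 50000) {
      guard <- guard + 1
      p <- c(runif(1, radius_px + 2, height - radius_px - 2),
             runif(1, radius_px + 2, width - radius_px - 2))
      if (nrow(centers) == 0 ||
          min(sqrt(rowSums(sweep(centers, 2, p)^2))) >= min_sep) {
        centers <- rbind(centers, p)
      }
    }
    if (nrow(centers) < ncells) {
      stop("could not place ", ncells, " non-touching disks; enlarge the ",
           "image or reduce counts")
    }
    draw <- function(idx) {
      img <- matrix(0, height, width)
      for (i in idx) {
        cy <- centers[i, 1]; cx <- centers[i, 2]
        amp <- runif(1, 0.6, 1)
        ys <- max(1, floor(cy - radius_px - 1)):min(height,
                                                    ceiling(cy + radius_px + 1))
        xs <- max(1, floor(cx - radius_px - 1)):min(width,
                                                    ceiling(cx + radius_px + 1))
        for (yy in ys) for (xx in xs) {
          if ((yy - cy)^2 + (xx - cx)^2 <= radius_px^2) img[yy, xx] <- amp
        }
      }
      img
    }
    list(green = draw(seq_len(n_live)),
         red = draw(n_live + seq_len(n_dead)),
         truth = list(live = n_live, dead = n_dead,
                      viability_percent = 100 * n_live / ncells))
  })
}

#' Write synthetic QC fixtures to image files
#'
#' Dispatches to the three generators and writes their images to disk
#' (PNG masks/channels, multi-frame TIFF movies), returning the file
#' paths and the generator ground truth. Output is byte-identical under a
#' fixed seed.
#'
#' @param kind \code{"sem_mask_pair"}, \code{"bead_movie"} or
#'   \code{"live_dead_pair"}.
#' @param params list of arguments for the generator.
#' @param seed RNG seed.
#' @param dir output directory (created if missing).
#' @return List: \code{files} (named paths) and \code{truth}.
#' @export
synth_fixtures <- function(kind, params = list(), seed = 1,
                           dir = tempdir()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (kind == "sem_mask_pair") {
    g <- do.call(synth_mask_pair, c(params, list(seed = seed)))
    files <- c(target = file.path(dir, "target.png"),
               experiment = file.path(dir, "experiment.png"))
    write_gray(g$target * 1, files["target"])
    write_gray(g$experiment * 1, files["experiment"])
    list(files = files, truth = g$truth)
  } else if (kind == "bead_movie") {
    if (is.null(params$speeds_mm_s)) params$speeds_mm_s <- c(1, 2)
    g <- do.call(synth_bead_movie, c(params, list(seed = seed)))
    f <- file.path(dir, "bead_movie.tif")
    stack <- EBImage::Image(aperm(g$frames, c(2, 1, 3)))
    EBImage::writeImage(stack, f, type = "tiff", bits.per.sample = 16L)
    list(files = c(movie = f), truth = g$truth)
  } else if (kind == "live_dead_pair") {
    g <- do.call(synth_live_dead, c(params, list(seed = seed)))
    files <- c(green = file.path(dir, "green.png"),
               red = file.path(dir, "red.png"))
    write_gray(g$green, files["green"])
    write_gray(g$red, files["red"])
    list(files = files, truth = g$truth)
  } else {
    stop("unknown fixture kind: ", kind)
  }
}
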