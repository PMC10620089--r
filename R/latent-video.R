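#' Configuration for the procedurally generated latent-factor video
#'
#' A continuous video built from fixed-length clips. Within a clip the glyph
#' shape stays fixed and exactly one other latent factor (scale, hue or
#' orientation) performs a random walk biased toward adjacent levels; at clip
#' boundaries a new shape and varying factor are drawn. Hue levels are
#' permuted once per run so that temporally adjacent hue transitions do not
#' coincide with adjacent raw intensities; a learner must recover the
#' sequence topology from time, not from pixel similarity. The glyphs
#' (disk, square, triangle, cross) are a parametric stand-in with the same
#' sequence statistics as rendered 3D scenes.
#'
#' @param image_size Frame edge length in pixels (default 32).
#' @param clip_length Frames per clip (default 17).
#' @param n_frames Total number of frames.
#' @param scale_levels,hue_levels,orientation_levels Ordered factor levels:
#'   scale as a fraction of the half-image, hue as glyph intensity in (0, 1],
#'   orientation in degrees.
#' @param hue_permutation_seed Seed for the one-off hue permutation.
#' @param p_adjacent Probability mass of moving to an adjacent level at each
#'   within-clip step (default 0.8); the rest is split between staying and a
#'   uniform jump.
#' @param seed Integer seed or `NULL`.
#' @return An object of class `latent_video_config`.
#' @export
latent_video_config <- function(image_size = 32L, clip_length = 17L,
                                n_frames = 1700L,
                                scale_levels = seq(0.35, 0.85, length.out = 6),
                                hue_levels = seq(0.3, 1, length.out = 8),
                                orientation_levels = seq(0, 157.5, length.out = 8),
                                hue_permutation_seed = 1L,
                                p_adjacent = 0.8, seed = NULL) {
  if (clip_length < 2) stop("'clip_length' must be at least 2")
  if (image_size < 8) stop("image too small to render shapes")
  structure(list(image_size = as.integer(image_size),
                 clip_length = as.integer(clip_length),
                 n_frames = as.integer(n_frames),
                 factor_spec = list(shape = c("disk", "square", "triangle", "cross"),
                                    scale = scale_levels, hue = hue_levels,
                                    orientation = orientation_levels),
                 hue_permutation_seed = as.integer(hue_permutation_seed),
                 p_adjacent = p_adjacent, seed = seed),
            class = "latent_video_config")
}

render_glyph <- function(shape, scale, hue, orientation, image_size) {
  half <- (image_size - 1) / 2
  xy <- seq(-half, half)
  gx <- matrix(xy, image_size, image_size)
  gy <- t(gx)
  th <- orientation * pi / 180
  xr <- cos(th) * gx + sin(th) * gy
  yr <- -sin(th) * gx + cos(th) * gy
  r <- scale * half
  mask <- switch(shape,
    disk = gx^2 + gy^2 <= r^2,
    square = pmax(abs(xr), abs(yr)) <= r * 0.886,
    triangle = {
      ang <- c(90, 210, 330) * pi / 180 + th
      vx <- r * cos(ang); vy <- r * sin(ang)
      inside <- TRUE
      for (k in 1:3) {
        k2 <- k %% 3 + 1
        cross_z <- (vx[k2] - vx[k]) * (gy - vy[k]) - (vy[k2] - vy[k]) * (gx - vx[k])
        inside <- inside & (cross_z >= 0)
      }
      inside
    },
    cross = (abs(xr) <= r / 3 & abs(yr) <= r) | (abs(yr) <= r / 3 & abs(xr) <= r),
    stop("unknown shape: ", shape))
  mask * hue
}

walk_step <- function(level, n_levels, p_adjacent) {
  u <- runif(1)
  if (u < p_adjacent) {
    cand <- c(level - 1L, level + 1L)
    cand <- cand[cand >= 1L & cand <= n_levels]
    cand[sample.int(length(cand), 1L)]
  } else if (u < p_adjacent + 0.1 || n_levels <= 1L) {
    level
  } else {
    sample.int(n_levels, 1L)
  }
}

#' Generate a latent-factor glyph video
#'
#' @param config A [latent_video_config()].
#' @return A list with `frames` (array `image_size` x `image_size` x
#'   `n_frames`, values in `[0, 1]`), `labels` (data frame of per-frame
#'   ground-truth level indices `shape`, `scale`, `hue`, `orientation`, plus
#'   `clip` and `varying` factor), `transitions` (data frame of within-clip
#'   moves of the varying factor: `factor`, `from`, `to`) and
#'   `hue_permutation`.
#' @export
gen_latent_video <- function(config) {
  stopifnot(inherits(config, "latent_video_config"))
  fs <- config$factor_spec
  hue_perm <- local({
    old <- .Random.seed_save()
    set.seed(config$hue_permutation_seed)
    p <- sample.int(length(fs$hue))
    .Random.seed_restore(old)
    p
  })
  if (!is.null(config$seed)) set.seed(config$seed)

  n_clips <- ceiling(config$n_frames / config$clip_length)
  n_levels <- vapply(fs[-1], length, integer(1)) # scale, hue, orientation
  frames <- array(0, c(config$image_size, config$image_size, config$n_frames))
  labels <- data.frame(clip = integer(config$n_frames),
                       shape = integer(config$n_frames),
                       scale = integer(config$n_frames),
                       hue = integer(config$n_frames),
                       orientation = integer(config$n_frames),
                       varying = character(config$n_frames),
                       stringsAsFactors = FALSE)
  trans <- list()
  f <- 0L
  cache <- new.env(parent = emptyenv())
  for (cl in seq_len(n_clips)) {
    shape_idx <- sample.int(length(fs$shape), 1L)
    varying <- sample(names(n_levels), 1L)
    lev <- vapply(n_levels, function(n) sample.int(n, 1L), integer(1))
    for (k in seq_len(config$clip_length)) {
      f <- f + 1L
      if (f > config$n_frames) break
      if (k > 1L) {
        new_lev <- walk_step(lev[[varying]], n_levels[[varying]], config$p_adjacent)
        trans[[length(trans) + 1L]] <- c(lev[[varying]], new_lev)
        lev[[varying]] <- new_lev
      }
      labels$clip[f] <- cl
      labels$shape[f] <- shape_idx
      labels$scale[f] <- lev[["scale"]]
      labels$hue[f] <- lev[["hue"]]
      labels$orientation[f] <- lev[["orientation"]]
      labels$varying[f] <- varying
      key <- paste(shape_idx, lev[["scale"]], lev[["hue"]], lev[["orientation"]],
                   sep = "_")
      img <- cache[[key]]
      if (is.null(img)) {
        img <- render_glyph(fs$shape[shape_idx], fs$scale[lev[["scale"]]],
                            fs$hue[hue_perm[lev[["hue"]]]],
                            fs$orientation[lev[["orientation"]]],
                            config$image_size)
        cache[[key]] <- img
      }
      frames[, , f] <- img
    }
  }
  tr <- if (length(trans)) {
    m <- do.call(rbind, trans)
    data.frame(from = m[, 1], to = m[, 2])
  } else data.frame(from = integer(), to = integer())
  list(frames = frames, labels = labels, transitions = tr,
       hue_permutation = hue_perm)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
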