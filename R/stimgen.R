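#' Grayscale image constructor
#'
#' Wraps a 2-D luminance matrix as a \code{gray_image}. Values are expected in
#' \[0, 1\]. Odd dimensions are cropped by one row/column so that every
#' frequency bin of the 2-D FFT has a clean Hermitian partner, which the
#' phase-scrambling machinery relies on.
#'
#' @param pixels numeric matrix of luminances.
#' @return A \code{gray_image}: the (possibly cropped) matrix with class set.
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix")
  }
  if (any(!is.finite(pixels))) stop("`pixels` must be finite")
  nr <- nrow(pixels) - nrow(pixels) %% 2L
  nc <- ncol(pixels) - ncol(pixels) %% 2L
  if (nr < 2L || nc < 2L) stop("image too small after even-dimension crop")
  structure(pixels[seq_len(nr), seq_len(nc), drop = FALSE],
            class = c("gray_image", "matrix"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("gray_image: %d x %d, range [%.3f, %.3f], mean %.3f\n",
              nrow(x), ncol(x), min(x), max(x), mean(x)))
  invisible(x)
}

#' Read / write grayscale PNG
#'
#' PNGs are read as luminance in \[0, 1\] (color images are converted by
#' channel averaging) and written as 8-bit grayscale.
#'
#' @param path file path.
#' @return [read_gray_png()] returns a \code{gray_image}.
#' @export
read_gray_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3L, dim(a)[3])), drop = FALSE], c(1, 2), mean)
  gray_image(a)
}

#' @param image a \code{gray_image} (values clipped to \[0, 1\] on write).
#' @rdname read_gray_png
#' @export
write_gray_png <- function(image, path) {
  m <- pmin(pmax(unclass(image), 0), 1)
  png::writePNG(m, target = path, dpi = NULL)
  invisible(path)
}

#' Coherence plan
#'
#' An ordered set of phase-coherence fractions plus a base seed, defining the
#' degradation ladder of a stimulus set (the study used 10\% through 60\% in
#' 10\% steps plus a full-structure 100\% condition).
#'
#' @param levels strictly increasing coherence fractions in \[0, 1\].
#' @param seed integer base seed.
#' @export
coherence_plan <- function(levels, seed = 1L) {
  if (length(levels) && (any(levels < 0 | levels > 1) || anyNA(levels))) {
    stop("coherence levels must lie in [0, 1]")
  }
  if (length(levels) > 1 && any(diff(levels) <= 0)) {
    stop("coherence levels must be strictly increasing")
  }
  structure(list(levels = as.numeric(levels), seed = as.integer(seed)),
            class = "coherence_plan")
}

# run fn() under a private RNG stream without disturbing the caller's state
with_private_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Equalize luminance, contrast and amplitude spectra across an image set
#'
#' Replaces every image's Fourier amplitude spectrum by the set-average
#' spectrum while leaving phases untouched. Because the DC magnitude carries
#' the mean luminance and (by Parseval) the non-DC magnitudes carry the pixel
#' variance, this single substitution equalizes mean luminance, RMS contrast
#' (pixel standard deviation) and the full rotational amplitude structure in
#' one step. The result is clipped to \[0, 1\]; the clipped-pixel fraction is
#' reported per image in the \code{clipped_frac} attribute.
#'
#' @param images list of \code{gray_image} with identical dimensions.
#' @return list of matched \code{gray_image}s, each carrying a
#'   \code{clipped_frac} attribute.
#' @export
match_set_statistics <- function(images) {
  if (length(images) < 2L) stop("need at least 2 images")
  images <- lapply(images, gray_image)
  d1 <- dim(images[[1L]])
  for (i in seq_along(images)) {
    if (!identical(dim(images[[i]]), d1)) {
      stop(sprintf("image %d has dimensions %dx%d, expected %dx%d",
                   i, nrow(images[[i]]), ncol(images[[i]]), d1[1], d1[2]))
    }
  }
  ffts <- lapply(images, function(im) stats::fft(unclass(im)))
  mean_amp <- Reduce(`+`, lapply(ffts, Mod)) / length(ffts)
  lapply(ffts, function(F) {
    ph <- Arg(F)
    out <- Re(stats::fft(mean_amp * exp(1i * ph), inverse = TRUE)) / length(F)
    clipped <- mean(out < 0 | out > 1)
    res <- gray_image(pmin(pmax(out, 0), 1))
    attr(res, "clipped_frac") <- clipped
    res
  })
}

# phase mixing along the shortest circular arc; wrap maps to (-pi, pi]
wrap_phase <- function(phi) {
  w <- (phi + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Phase-scramble an image at a given coherence
#'
#' Degrades image structure by mixing the original Fourier phases with a
#' random Hermitian phase field while keeping the amplitude spectrum exactly:
#' \deqn{\phi_{out} = \phi_{orig} + (1 - c)\,\mathrm{wrap}(\phi_{rand} -
#' \phi_{orig}),} interpolation along the shortest circular arc, so coherence
#' \code{c = 1} reproduces the input exactly and \code{c = 0} gives fully
#' randomized phases. The random field is the phase of the FFT of white noise,
#' which is Hermitian by construction, so the inverse transform is real. The
#' DC and Nyquist rows/columns keep their original phases — their
#' self-conjugate bins admit only phases 0/\eqn{\pi} and are never randomized.
#' The output is clipped to \[0, 1\] (attribute \code{clipped_frac}); the
#' amplitude spectrum is preserved exactly up to that final clipping step.
#'
#' @param image a \code{gray_image}.
#' @param coherence fraction of original phase retained, in \[0, 1\].
#' @param seed integer seed for the random phase field.
#' @return scrambled \code{gray_image} with attribute \code{clipped_frac}.
#' @export
phase_scramble <- function(image, coherence, seed) {
  image <- gray_image(image)
  if (!is.numeric(coherence) || length(coherence) != 1L ||
      is.na(coherence) || coherence < 0 || coherence > 1) {
    stop("`coherence` must be a single number in [0, 1]")
  }
  M <- nrow(image); N <- ncol(image)
  F <- stats::fft(unclass(image))
  amp <- Mod(F)
  phi <- Arg(F)
  phi_rand <- with_private_seed(seed, function() {
    Arg(stats::fft(matrix(stats::rnorm(M * N), M, N)))
  })
  mix <- wrap_phase(phi_rand - phi)
  # DC and Nyquist rows/columns are never randomized
  fixed_r <- c(1L, M / 2L + 1L)
  fixed_c <- c(1L, N / 2L + 1L)
  mix[fixed_r, ] <- 0
  mix[, fixed_c] <- 0
  phi_out <- phi + (1 - coherence) * mix
  rec <- stats::fft(amp * exp(1i * phi_out), inverse = TRUE) / (M * N)
  imag_resid <- max(abs(Im(rec))) / max(abs(Re(rec)))
  out <- Re(rec)
  clipped <- mean(out < 0 | out > 1)
  res <- gray_image(pmin(pmax(out, 0), 1))
  attr(res, "clipped_frac") <- clipped
  attr(res, "imag_residual") <- imag_resid
  res
}

# pre-clipping scramble used internally for spectrum checks
phase_scramble_raw <- function(image, coherence, seed) {
  image <- gray_image(image)
  M <- nrow(image); N <- ncol(image)
  F <- stats::fft(unclass(image))
  phi <- Arg(F)
  phi_rand <- with_private_seed(seed, function() {
    Arg(stats::fft(matrix(stats::rnorm(M * N), M, N)))
  })
  mix <- wrap_phase(phi_rand - phi)
  mix[c(1L, M / 2L + 1L), ] <- 0
  mix[, c(1L, N / 2L + 1L)] <- 0
  Re(stats::fft(Mod(F) * exp(1i * (phi + (1 - coherence) * mix)),
                inverse = TRUE)) / (M * N)
}

#' Render a stimulus set across coherence levels
#'
#' Writes one PNG per image x coherence level with deterministic naming and
#' per-cell seeds derived from the plan's base seed, and returns (and writes)
#' a manifest table. Each output image gets an independent random phase field
#' keyed by (image, level, base seed).
#'
#' @param images named list of matched \code{gray_image}s; names are image ids.
#' @param plan a [coherence_plan()].
#' @param outdir output directory (created if needed).
#' @param races character vector of race labels, one per image (defaults to
#'   the part of each image id before the first underscore).
#' @return tibble manifest with columns
#'   \code{image_id, race, coherence, seed, clipped_frac, path}; also written
#'   to \code{manifest.csv} in \code{outdir}.
#' @export
render_stimulus_set <- function(images, plan, outdir, races = NULL) {
  stopifnot(inherits(plan, "coherence_plan"))
  if (is.null(names(images)) && length(images)) {
    names(images) <- sprintf("img%02d", seq_along(images))
  }
  if (is.null(races)) races <- sub("_.*$", "", names(images))
  stopifnot(length(races) == length(images))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  rows <- list()
  for (j in seq_along(plan$levels)) {
    lev <- plan$levels[j]
    for (i in seq_along(images)) {
      cell_seed <- (plan$seed + 1000003 * i + 7919 * j) %% 2147483647
      scr <- phase_scramble(images[[i]], lev, cell_seed)
      fn <- sprintf("%s_c%03d.png", names(images)[i], round(lev * 100))
      path <- file.path(outdir, fn)
      write_gray_png(scr, path)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        image_id = names(images)[i], race = races[i], coherence = lev,
        seed = cell_seed, clipped_frac = attr(scr, "clipped_frac"),
        path = path)
    }
  }
  manifest <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(image_id = character(), race = character(),
                   coherence = numeric(), seed = numeric(),
                   clipped_frac = numeric(), path = character())
  }
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
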