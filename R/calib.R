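# Reflectance calibration: band-wise median denoising, the three reflectance
# recovery routes, and the constrained specular/diffuse decomposition.

# pad a matrix by one pixel of replicated border
padReplicate1 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(0, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- m
  p[1L, ] <- p[2L, ]; p[h + 2L, ] <- p[h + 1L, ]
  p[, 1L] <- p[, 2L]; p[, w + 2L] <- p[, w + 1L]
  p
}

# exact 3x3 median of a matrix via an exchange network sorting the nine
# shifted neighbor planes (replicate-padded borders); fully vectorized
median3x3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- padReplicate1(m)
  v <- vector("list", 9L)
  k <- 0L
  for (dy in 0:2) for (dx in 0:2) {
    k <- k + 1L
    v[[k]] <- as.vector(p[(1L + dx):(h + dx), (1L + dy):(w + dy)])
  }
  sort2 <- function(i, j) {
    lo <- pmin(v[[i]], v[[j]]); hi <- pmax(v[[i]], v[[j]])
    v[[i]] <<- lo; v[[j]] <<- hi
  }
  # full bubble sort of the nine planes; the 5th is the median
  for (pass in 8:1) for (j in seq_len(pass)) sort2(j, j + 1L)
  matrix(v[[5L]], h, w)
}

#' Median-filter every band of a cube
#'
#' Applies an exact 3 x 3 spatial median filter to each band independently
#' (replicated borders), suppressing high-frequency detector noise before
#' reflectance recovery. Dimensions are preserved.
#'
#' @param cube a [SpectralCube] (or [ReflectanceCube]).
#' @return A cube of the same class and dimensions.
#' @export
medianFilterBands <- function(cube) {
  stopifnot(is(cube, "SpectralCube"))
  v <- cube@values
  if (dim(v)[3L] < 1L) stop("cube must have at least one band")
  out <- v
  for (b in seq_len(dim(v)[3L])) out[, , b] <- median3x3(v[, , b])
  res <- cube
  res@values <- out
  res
}

#' Median-filter all cubes of an acquisition set
#' @param set an [IlluminationSet].
#' @return The set with every object and reference cube filtered.
#' @export
medianFilterSet <- function(set) {
  stopifnot(is(set, "IlluminationSet"))
  IlluminationSet(lapply(set@obj, medianFilterBands),
                  lapply(set@ref, medianFilterBands))
}

divideCubes <- function(objv, refv, grid, mode) {
  bad <- apply(refv <= 0, c(1, 2), any)
  r <- objv / refv
  if (any(bad)) r[array(rep(bad, dim(objv)[3L]), dim(objv))] <- NA_real_
  ReflectanceCube(r, grid, mode, invalidMask = bad)
}

#' Flat-field (local) reflectance
#'
#' Reflectance as the pixel- and band-wise ratio of the object cube to the
#' reference-plate cube for a single illumination angle. When given a full
#' [IlluminationSet], the second angle is used, the geometry of the standard
#' 0/45 single-lamp arrangement. Pixels with a non-positive reference are
#' flagged invalid and excluded from downstream masks.
#'
#' @param obj object [SpectralCube], or an [IlluminationSet].
#' @param ref reference [SpectralCube]; ignored when `obj` is a set.
#' @param angle which angle to use from a set (default 2).
#' @return A [ReflectanceCube] with mode `"local"`.
#' @export
reflectanceLocal <- function(obj, ref = NULL, angle = 2L) {
  if (is(obj, "IlluminationSet")) {
    ref <- obj@ref[[angle]]
    obj <- obj@obj[[angle]]
  }
  stopifnot(is(obj, "SpectralCube"), is(ref, "SpectralCube"),
            identical(dim(obj@values), dim(ref@values)))
  divideCubes(obj@values, ref@values, obj@grid, "local")
}

#' Simultaneous-illumination reflectance
#'
#' Models quasi-uniform multi-lamp illumination by summing the pixel-wise
#' object signals over all three angles and dividing by the summed
#' references.
#'
#' @param set an [IlluminationSet].
#' @return A [ReflectanceCube] with mode `"simultaneous"`.
#' @export
reflectanceSimultaneous <- function(set) {
  stopifnot(is(set, "IlluminationSet"))
  objSum <- Reduce(`+`, lapply(set@obj, function(c) c@values))
  refSum <- Reduce(`+`, lapply(set@ref, function(c) c@values))
  divideCubes(objSum, refSum, set@obj[[1L]]@grid, "simultaneous")
}

#' Per-angle reflectance cubes
#'
#' The three single-angle flat-field ratios, the input of the specular/
#' diffuse decomposition (each angle divided by its own reference).
#'
#' @param set an [IlluminationSet].
#' @return list of three [ReflectanceCube]s (mode `"local"`).
#' @export
reflectancePerAngle <- function(set) {
  stopifnot(is(set, "IlluminationSet"))
  lapply(seq_along(set@obj), function(i)
    divideCubes(set@obj[[i]]@values, set@ref[[i]]@values,
                set@obj[[i]]@grid, "local"))
}

#' Specular/diffuse reflectance decomposition from multi-angle data
#'
#' Separates, per pixel, the total reflectance measured under each of the
#' three illumination angles into an angle-independent volume (diffuse)
#' spectrum, a specular spectrum, and per-angle specular amplitudes:
#' `R_i(lambda) = R_vol(lambda) + eps_i * R_surf(lambda)`. The fit minimizes
#' the summed squared misfit over all angles and bands subject to box
#' constraints `R_vol in [0,1]`, `R_surf in [0,0.1]`, `eps in [0,1]`.
#'
#' The model is bilinear in `(eps, R_surf)`, so the constrained problem is
#' solved by projected alternating least squares: each block (`eps`, then
#' `R_surf`, then `R_vol`) has a closed-form unconstrained minimizer that is
#' clipped to its box, which is the exact constrained block minimizer for
#' these separable quadratics. The objective is therefore non-increasing at
#' every sweep. Initialization follows the acquisition protocol: `R_vol`
#' starts at the angle-averaged spectrum, `R_surf` at a constant 0.05, and
#' `eps_i` at the least-squares regression of the angle-i residual onto the
#' initial `R_surf`, clipped to `[0, 1]`.
#'
#' The decomposition has a gauge ambiguity: `(R_vol + b*R_surf, a*R_surf,
#' (eps - b)/a)` reproduces the data equally well within the bounds, so
#' individual components are identifiable only up to this family (the
#' products `eps_i * R_surf` and the reconstruction are invariant). At fruit
#' pixels where at least one angle carries no specular contribution the
#' bounds pin `R_vol` close to the true volume spectrum.
#'
#' @param rAngles list of three per-angle [ReflectanceCube]s (see
#'   [reflectancePerAngle()]), or three H x W x B arrays.
#' @param mask optional logical H x W matrix of pixels to fit (default: all
#'   pixels valid in every angle).
#' @param maxIter maximum alternating sweeps (default 200).
#' @param tol per-pixel objective-decrease tolerance declaring convergence
#'   (default 1e-12).
#' @return A [DecompositionResult]. Pixels that hit `maxIter` keep their best
#'   iterate and are flagged in the convergence map; no error is raised
#'   mid-frame.
#' @export
fitSpecularDecomposition <- function(rAngles, mask = NULL, maxIter = 200L, tol = 1e-12) {
  arrs <- lapply(rAngles, function(r) if (is(r, "SpectralCube")) r@values else r)
  if (length(arrs) != 3L) stop("three per-angle reflectance cubes are required")
  grid <- if (is(rAngles[[1L]], "SpectralCube")) rAngles[[1L]]@grid else
    SpectralGrid(seq_len(dim(arrs[[1L]])[3L]))
  d <- dim(arrs[[1L]])
  h <- d[1L]; w <- d[2L]; nb <- d[3L]

  valid <- Reduce(`&`, lapply(arrs, function(a) !apply(is.na(a), c(1, 2), any)))
  if (is.null(mask)) mask <- valid else mask <- mask & valid
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) stop("no pixels to fit")

  # masked pixels as n x nb matrices, one per angle
  R <- lapply(arrs, function(a) {
    m <- matrix(a, h * w, nb)[idx, , drop = FALSE]
    m
  })

  clip01 <- function(x) pmin(pmax(x, 0), 1)

  # initialization
  rvol <- clip01((R[[1L]] + R[[2L]] + R[[3L]]) / 3)
  rsurf <- matrix(0.05, n, nb)
  eps <- vapply(1:3, function(i) {
    clip01(rowSums((R[[i]] - rvol) * rsurf) / rowSums(rsurf^2))
  }, numeric(n))
  if (n == 1L) eps <- matrix(eps, 1L, 3L)

  objective <- function() {
    o <- numeric(n)
    for (i in 1:3) o <- o + rowSums((R[[i]] - rvol - eps[, i] * rsurf)^2)
    o
  }
  obj <- objective()
  converged <- rep(FALSE, n)

  for (it in seq_len(maxIter)) {
    act <- !converged
    if (!any(act)) break
    # eps block: per-pixel, per-angle scalar regression onto current rsurf
    den <- pmax(rowSums(rsurf^2), 1e-300)
    for (i in 1:3) eps[, i] <- clip01(rowSums((R[[i]] - rvol) * rsurf) / den)
    # rsurf block: per-pixel, per-band regression onto eps
    e2 <- rowSums(eps^2)
    num <- eps[, 1L] * (R[[1L]] - rvol) + eps[, 2L] * (R[[2L]] - rvol) +
      eps[, 3L] * (R[[3L]] - rvol)
    upd <- e2 > 1e-12
    if (any(upd))
      rsurf[upd, ] <- pmin(pmax(num[upd, , drop = FALSE] / e2[upd], 0), 0.1)
    # rvol block: per-pixel, per-band mean of specular-corrected angles
    rvol <- clip01((R[[1L]] - eps[, 1L] * rsurf + R[[2L]] - eps[, 2L] * rsurf +
                      R[[3L]] - eps[, 3L] * rsurf) / 3)
    newObj <- objective()
    converged <- converged | (obj - newObj < tol & newObj <= obj + 1e-15)
    obj <- newObj
  }

  expand <- function(m) {
    out <- array(NA_real_, c(h, w, ncol(m)))
    flat <- matrix(out, h * w, ncol(m))
    flat[idx, ] <- m
    array(flat, c(h, w, ncol(m)))
  }
  resid <- matrix(NA_real_, h, w)
  resid[idx] <- sqrt(obj / (3 * nb))
  conv <- matrix(TRUE, h, w)
  conv[idx] <- converged

  new("DecompositionResult",
      rvol = expand(rvol), rsurf = expand(rsurf), eps = expand(eps),
      residual = resid, converged = conv, mask = mask, grid = grid)
}

#' Sequential-mode reflectance cube from a decomposition
#'
#' Packages the recovered volume (diffuse) reflectance as a
#' [ReflectanceCube] with mode `"sequential"`. Pixels outside the fitted
#' mask are filled with `fill` (default: the angle-averaged reflectance, so
#' the frame remains usable for object masking).
#'
#' @param decomp a [DecompositionResult].
#' @param fill optional H x W x B array for unfitted pixels.
#' @return A [ReflectanceCube] with mode `"sequential"`.
#' @export
sequentialReflectance <- function(decomp, fill = NULL) {
  stopifnot(is(decomp, "DecompositionResult"))
  v <- decomp@rvol
  if (!is.null(fill)) {
    off <- !decomp@mask
    if (any(off)) {
      nb <- dim(v)[3L]
      sel <- array(rep(off, nb), dim(v))
      v[sel] <- fill[sel]
    }
  }
  bad <- is.na(v[, , 1L])
  v[is.na(v)] <- 0
  ReflectanceCube(v, decomp@grid, "sequential", invalidMask = bad)
}
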