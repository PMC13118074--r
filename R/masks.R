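# Object-mask extraction: Otsu thresholding, 8-connected component
# labeling, and the area filter that keeps fruit-sized components.

#' Otsu threshold of a sample set
#'
#' Global threshold maximizing the between-class variance over a 256-bin
#' uniform histogram of the input range. The returned value is the bin edge
#' separating the two classes; ties are broken toward the lowest threshold.
#'
#' @param values numeric samples (`NA` dropped).
#' @param nbins histogram bins (default 256).
#' @return scalar threshold strictly inside the data range.
#' @export
otsuThreshold <- function(values, nbins = 256L) {
  v <- values[is.finite(values)]
  if (length(unique(v)) < 2L)
    stop("Otsu threshold is undefined for constant input")
  lo <- min(v); hi <- max(v)
  edges <- seq(lo, hi, length.out = nbins + 1L)
  cnt <- as.numeric(tabulate(pmin(pmax(findInterval(v, edges,
                                                    rightmost.closed = TRUE),
                                       1L), nbins), nbins))
  mids <- (edges[-1L] + edges[-(nbins + 1L)]) / 2
  w0 <- cumsum(cnt)
  w1 <- sum(cnt) - w0
  s0 <- cumsum(cnt * mids)
  mu0 <- s0 / w0
  mu1 <- (s0[nbins] - s0) / w1
  between <- w0 * w1 * (mu0 - mu1)^2
  between[w0 == 0 | w1 == 0] <- -Inf
  k <- which.max(between[-nbins])  # split after bin k
  edges[k + 1L]
}

# shift a matrix by (dx, dy), filling vacated cells with `fill`
shiftMatrix <- function(m, dx, dy, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  xs <- seq_len(h) - dx; ys <- seq_len(w) - dy
  okx <- xs >= 1L & xs <= h; oky <- ys >= 1L & ys <= w
  out[okx, oky] <- m[xs[okx], ys[oky]]
  out
}

#' 8-connected component labeling
#'
#' Labels connected foreground regions of a binary mask using 8-neighbor
#' connectivity by iterated minimum-label propagation (labels start as pixel
#' indices and each pixel repeatedly takes the minimum over its masked
#' neighbors until a fixed point). Components are renumbered 1..n in order
#' of their smallest pixel index.
#'
#' @param mask logical H x W matrix.
#' @return integer H x W matrix, 0 outside the mask.
#' @export
labelComponents <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(seq_len(h * w), h, w)
  lab[!mask] <- Inf
  shifts <- expand.grid(dx = -1:1, dy = -1:1)
  shifts <- shifts[!(shifts$dx == 0 & shifts$dy == 0), ]
  repeat {
    prev <- lab
    for (s in seq_len(nrow(shifts)))
      lab <- pmin(lab, shiftMatrix(lab, shifts$dx[s], shifts$dy[s], Inf))
    lab[!mask] <- Inf
    if (identical(lab, prev)) break
  }
  out <- matrix(0L, h, w)
  if (any(mask)) {
    ids <- sort(unique(lab[mask]))
    out[mask] <- match(lab[mask], ids)
  }
  out
}

#' Filter labeled components by pixel area
#'
#' Keeps components whose area lies in `[minArea, maxArea]` and renumbers
#' the survivors 1..n. Idempotent: filtering an already-filtered label map
#' changes nothing.
#'
#' @param labels integer H x W component-label matrix (0 = background).
#' @param minArea,maxArea inclusive pixel-count window.
#' @return integer label matrix of retained components.
#' @export
filterComponentsByArea <- function(labels, minArea, maxArea) {
  if (minArea >= maxArea) stop("minArea must be smaller than maxArea")
  n <- max(labels)
  out <- matrix(0L, nrow(labels), ncol(labels))
  if (n == 0L) return(out)
  areas <- tabulate(labels[labels > 0L], n)
  keep <- which(areas >= minArea & areas <= maxArea)
  sel <- labels > 0L & labels %in% keep
  out[sel] <- match(labels[sel], keep)
  out
}

#' Build fruit object masks from a reflectance cube
#'
#' Otsu-binarizes the band nearest `bandNm` (default 750 nm, a
#' high-contrast object/background channel), labels 8-connected bright
#' components, and retains those whose area falls inside
#' `[minArea, maxArea]` (defaults 20,000--40,000 px, the frame area of one
#' fruit at full acquisition scale; scale the window by the squared frame
#' scale for reduced-resolution scenes). Invalid pixels never enter the
#' mask.
#'
#' @param r a [ReflectanceCube].
#' @param bandNm wavelength to threshold, nm.
#' @param minArea,maxArea component area window in px.
#' @return An [ObjectMask]; empty (with a warning) if no component survives.
#' @export
buildObjectMasks <- function(r, bandNm = 750, minArea = 20000, maxArea = 40000) {
  stopifnot(is(r, "ReflectanceCube"))
  plane <- r@values[, , bandIndex(r@grid, bandNm)]
  plane[r@invalidMask] <- NA
  thr <- tryCatch(otsuThreshold(plane), error = function(e) NA_real_)
  fg <- if (is.na(thr)) matrix(FALSE, nrow(plane), ncol(plane))
        else !is.na(plane) & plane > thr
  lab <- labelComponents(fg)
  kept <- filterComponentsByArea(lab, minArea, maxArea)
  areas <- if (max(kept) > 0L) tabulate(kept[kept > 0L], max(kept)) else integer(0)
  if (length(areas) == 0L)
    warning("no connected component fell inside the area window; mask is empty")
  new("ObjectMask", labels = kept, areas = as.integer(areas),
      threshold = thr, bandNm = as.numeric(bandNm))
}

#' Crop per-object reflectance cubes
#'
#' Cuts one tight bounding-box crop per retained mask component, recording
#' the component mask and the crop's frame offset so crops can be placed
#' back exactly.
#'
#' @param r a [ReflectanceCube].
#' @param masks an [ObjectMask] from the same frame.
#' @return list with one element per component: `cube` (cropped
#'   [ReflectanceCube]), `mask` (logical crop), `offset` (row/col of the
#'   crop's top-left corner in the frame), `id` (component id).
#' @export
extractObjectCubes <- function(r, masks) {
  stopifnot(is(r, "ReflectanceCube"), is(masks, "ObjectMask"),
            identical(dim(r@values)[1:2], dim(masks@labels)))
  lapply(seq_along(masks@areas), function(k) {
    sel <- masks@labels == k
    rows <- range(which(rowSums(sel) > 0))
    cols <- range(which(colSums(sel) > 0))
    crop <- r@values[rows[1L]:rows[2L], cols[1L]:cols[2L], , drop = FALSE]
    list(cube = ReflectanceCube(crop, r@grid, r@recoveryMode,
                                invalidMask = r@invalidMask[rows[1L]:rows[2L],
                                                            cols[1L]:cols[2L], drop = FALSE]),
         mask = sel[rows[1L]:rows[2L], cols[1L]:cols[2L], drop = FALSE],
         offset = c(row = rows[1L], col = cols[1L]),
         id = k)
  })
}
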