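#' Area-of-interest configuration
#'
#' Screen regions used to classify gaze position, as half-open pixel
#' rectangles `[x0, x1) x [y0, y1)` with the origin at the top-left of the
#' 1024 x 768 screen. The test-phase regions (`left`, `right`, `center`) must
#' be pairwise disjoint and inside the screen; half-open boundaries make
#' assignment unambiguous. The familiarization regions are the central
#' stimulus rectangle and its `eyes` / `mouth` sub-regions.
#'
#' The default geometry tiles the screen width exactly with the two 380 x 350
#' lateral image squares and a 264-px-wide central strip
#' (380 + 264 + 380 = 1024); the strip spans the full screen height so that
#' "centered" gaze is detected leniently.
#'
#' @param screen `c(width, height)` in pixels.
#' @param left,right,center,stimulus,eyes,mouth Rectangles `c(x0, y0, x1, y1)`.
#' @return An object of class `aoi_config` (a named list of rectangles).
#' @export
aoi_config <- function(screen = c(1024, 768),
                       left = c(0, 209, 380, 559),
                       right = c(644, 209, 1024, 559),
                       center = c(380, 0, 644, 768),
                       stimulus = c(237, 94, 787, 674),
                       eyes = c(337, 214, 687, 344),
                       mouth = c(387, 404, 637, 504)) {
  rects <- list(left = left, right = right, center = center,
                stimulus = stimulus, eyes = eyes, mouth = mouth)
  for (nm in names(rects)) {
    r <- rects[[nm]]
    if (length(r) != 4L || r[1] >= r[3] || r[2] >= r[4]) {
      stop(sprintf("AOI '%s' must be c(x0, y0, x1, y1) with x0 < x1, y0 < y1", nm))
    }
    if (r[1] < 0 || r[2] < 0 || r[3] > screen[1] || r[4] > screen[2]) {
      stop(sprintf("AOI '%s' exceeds the %d x %d screen", nm, screen[1], screen[2]))
    }
  }
  prim <- rects[c("left", "right", "center")]
  for (i in 1:2) for (j in (i + 1):3) {
    a <- prim[[i]]; b <- prim[[j]]
    if (a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4]) {
      stop(sprintf("primary AOIs '%s' and '%s' overlap",
                   names(prim)[i], names(prim)[j]))
    }
  }
  structure(c(list(screen = screen), rects), class = "aoi_config")
}

#' @export
print.aoi_config <- function(x, ...) {
  cat("<aoi_config>", x$screen[1], "x", x$screen[2], "px\n")
  for (nm in setdiff(names(x), "screen")) {
    r <- x[[nm]]
    cat(sprintf("  %-8s [%g,%g) x [%g,%g)\n", nm, r[1], r[3], r[2], r[4]))
  }
  invisible(x)
}

in_rect <- function(x, y, r) {
  !is.na(x) & !is.na(y) & x >= r[1] & x < r[3] & y >= r[2] & y < r[4]
}

#' Assign gaze points to areas of interest
#'
#' Labels each point with the unique containing rectangle among a chosen set
#' of AOIs, or `"outside"`. Rectangles are half-open, so a point exactly on a
#' shared boundary coordinate belongs to the rectangle whose lower edge it
#' lies on.
#'
#' @param x,y Numeric vectors of gaze coordinates in pixels (`NA` allowed).
#' @param aois An [aoi_config()].
#' @param set `"test"` (left / right / center) or `"familiarization"`
#'   (eyes / mouth / stimulus; sub-regions take precedence over the
#'   enclosing stimulus rectangle).
#' @return Character vector of AOI labels.
#' @examples
#' assign_aoi(c(100, 512, 1000), c(400, 400, 400), aoi_config())
#' @export
assign_aoi <- function(x, y, aois, set = c("test", "familiarization")) {
  stopifnot(inherits(aois, "aoi_config"))
  set <- match.arg(set)
  names <- if (set == "test") c("left", "right", "center")
           else c("eyes", "mouth", "stimulus")
  out <- rep("outside", length(x))
  for (nm in rev(names)) out[in_rect(x, y, aois[[nm]])] <- nm
  out
}

rect_center <- function(r) c((r[1] + r[3]) / 2, (r[2] + r[4]) / 2)
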