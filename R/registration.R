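#' Estimate the inter-visit shift from vasculature images
#'
#' Finds the integer translation `(dy, dx)`, bounded by the search
#' radius, that best aligns the moving visit's retinal vasculature onto
#' the reference visit's. The score is the exact zero-normalized cross-
#' correlation (ZNCC) between the reference's central template (reference
#' minus a border of one search radius) and the corresponding window of
#' the moving image, evaluated for every candidate shift at once via
#' FFT cross-correlation plus integral-image window statistics. Ties
#' break toward the smaller `|dy| + |dx|`, then lexicographically.
#'
#' @param moving,reference Vasculature [enface_image()]s of equal shape.
#' @param config A [ccfd_config()] supplying `search_radius_px` and
#'   `zncc_min`.
#' @return A [ccfd_transform()] whose application maps `moving` onto
#'   `reference`.
#' @export
estimate_shift <- function(moving, reference, config = ccfd_config()) {
  stopifnot(inherits(moving, "enface_image"),
            inherits(reference, "enface_image"))
  M <- moving$pixels; R <- reference$pixels
  if (!identical(dim(M), dim(R))) stop("shape mismatch")
  K <- config$search_radius_px
  n <- nrow(R); m <- ncol(R)
  if (n <= 2 * K || m <= 2 * K)
    stop("raster too small for search radius ", K)
  Tm <- R[(K + 1):(n - K), (K + 1):(m - K), drop = FALSE]
  zncc <- zncc_all_shifts(Tm, M)
  # zncc[u+1, v+1] is the score for template placed at offset (u, v)
  # (0-based) in the moving image; the shift is (K - u, K - v).
  best_val <- max(zncc, na.rm = TRUE)
  if (!is.finite(best_val) || best_val < config$zncc_min)
    stop("registration failure: peak ZNCC ",
         formatC(best_val, digits = 3, format = "f"), " below cutoff ",
         config$zncc_min)
  cand <- which(zncc >= best_val - 1e-12, arr.ind = TRUE)
  dy <- K - (cand[, 1] - 1L); dx <- K - (cand[, 2] - 1L)
  ord <- order(abs(dy) + abs(dx), dy, dx)
  ccfd_transform(dy[ord[1]], dx[ord[1]], zncc_peak = best_val)
}

# Exact ZNCC of template Tm against every fully-contained window of M.
# Returns a matrix indexed by 0-based window offset (u, v).
zncc_all_shifts <- function(Tm, M) {
  nt <- nrow(Tm); mt <- ncol(Tm)
  n <- nrow(M); m <- ncol(M)
  npix <- as.numeric(nt) * mt
  # cross-correlation sum(T * window) for all offsets via FFT
  Tpad <- matrix(0, n, m)
  Tpad[1:nt, 1:mt] <- Tm
  cc <- Re(fft(fft(M) * Conj(fft(Tpad)), inverse = TRUE)) / (n * m)
  nu <- n - nt + 1L; nv <- m - mt + 1L
  cross <- cc[1:nu, 1:nv, drop = FALSE]
  # window sums of M and M^2 via integral images
  winsum <- function(X) {
    cs <- apply(apply(X, 2, cumsum), 1, cumsum)  # transposed integral image
    I <- rbind(0, cbind(0, t(cs)))               # (n+1) x (m+1), I[i+1,j+1]=sum
    I[(nt + 1):(n + 1), (mt + 1):(m + 1), drop = FALSE] -
      I[1:nu, (mt + 1):(m + 1), drop = FALSE] -
      I[(nt + 1):(n + 1), 1:nv, drop = FALSE] +
      I[1:nu, 1:nv, drop = FALSE]
  }
  sw <- winsum(M); sw2 <- winsum(M^2)
  st <- sum(Tm); st2 <- sum(Tm^2)
  num <- cross - st * sw / npix
  var_t <- st2 - st^2 / npix
  var_w <- pmax(sw2 - sw^2 / npix, 0)
  den <- sqrt(var_t * var_w)
  out <- num / den
  out[den <= 1e-12 * npix] <- NA_real_  # flat template or window
  out
}

#' Apply a transform to a raster
#'
#' Translates content down by `dy` rows and right by `dx` columns
#' (`out[r, c] = in[r - dy, c - dx]`). Pixels shifted in from outside the
#' field become invalid on CCFD maps; on exclusion-type masks
#' (`exclusion`, `integrated`, `low_signal`) they become `TRUE` (excluded),
#' while on annotation masks (`hypertd`, `vessel`) they become `FALSE`.
#'
#' @param raster A [ccfd_map()] or [mask_image()].
#' @param transform A [ccfd_transform()].
#' @return The translated raster of the same class.
#' @export
apply_transform <- function(raster, transform) {
  stopifnot(inherits(transform, "ccfd_transform"))
  if (inherits(raster, "ccfd_map")) {
    st <- translate_fill(raster$state, transform$dy, transform$dx,
                         fill = CCFD_INVALID)
    storage.mode(st) <- "integer"
    ccfd_map(st, spacing_um = raster$spacing_um)
  } else if (inherits(raster, "mask_image")) {
    fill <- raster$kind %in% c("exclusion", "integrated", "low_signal")
    px <- translate_fill(raster$pixels, transform$dy, transform$dx,
                         fill = fill)
    mask_image(px, kind = raster$kind)
  } else stop("raster must be a ccfd_map or mask_image")
}

# Integer translation with constant fill.
translate_fill <- function(X, dy, dx, fill) {
  n <- nrow(X); m <- ncol(X)
  out <- matrix(fill, n, m)
  src_r <- (1:n) - dy; src_c <- (1:m) - dx
  ok_r <- which(src_r >= 1 & src_r <= n)
  ok_c <- which(src_c >= 1 & src_c <= m)
  if (length(ok_r) && length(ok_c))
    out[ok_r, ok_c] <- X[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

#' Merge registered exclusion masks into the integrated mask
#'
#' The pixelwise union of the per-visit registered exclusion masks,
#' applied to every visit so the same regions are excluded throughout
#' the study period.
#'
#' @param registered_exclusions List of registered exclusion
#'   [mask_image()]s, one per visit.
#' @return A `mask_image` of kind `"integrated"`.
#' @export
integrate_masks <- function(registered_exclusions) {
  if (length(registered_exclusions) == 0) stop("no masks to integrate")
  dims <- lapply(registered_exclusions, function(mk) dim(mk$pixels))
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1)
    stop("mask shape mismatch")
  acc <- Reduce(`|`, lapply(registered_exclusions, `[[`, "pixels"))
  mask_image(acc, kind = "integrated")
}
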