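# Binary morphology on logical 3-D arrays via shifted copies (26-neighbourhood).
shift_array <- function(a, dx, dy, dz, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, dim = d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  fx <- sx - dx; fy <- sy - dy; fz <- sz - dz
  okx <- fx >= 1 & fx <= d[1]; oky <- fy >= 1 & fy <= d[2]; okz <- fz >= 1 & fz <= d[3]
  out[sx[okx], sy[oky], sz[okz]] <- a[fx[okx], fy[oky], fz[okz]]
  out
}

dilate26 <- function(a, iter = 1L) {
  for (r in seq_len(iter)) {
    acc <- a
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      acc <- acc | shift_array(a, dx, dy, dz, FALSE)
    }
    a <- acc
  }
  a
}

erode26 <- function(a, iter = 1L) {
  for (r in seq_len(iter)) {
    acc <- a
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      acc <- acc & shift_array(a, dx, dy, dz, FALSE)
    }
    a <- acc
  }
  a
}

#' Segment the lungs of a CT/CBCT volume by HU thresholding
#'
#' Voxels with HU in the closed window `[hu_low, hu_high]` are kept, then
#' cleaned up: 26-connected components touching the in-plane volume border
#' are discarded (background air), components whose centroid lies within a
#' midline corridor are discarded when `remove_airways` is set (main-stem
#' bronchi / trachea), and finally the two largest remaining components are
#' retained as the lungs.
#'
#' @param volume a [new_volume()] with `intensity_kind == "HU"`.
#' @param hu_low,hu_high HU window bounds (closed interval).
#' @param remove_airways drop midline-corridor components before ranking.
#' @param corridor_halfwidth_frac half-width of the airway corridor as a
#'   fraction of the x extent, centred on the volume's x midline.
#' @return A [new_mask()] on the input grid.
#' @export
segment_lungs <- function(volume, hu_low = -999, hu_high = -250,
                          remove_airways = TRUE,
                          corridor_halfwidth_frac = 0.15) {
  stopifnot(inherits(volume, "ventimap_volume"))
  if (volume$intensity_kind != "HU")
    vm_stop("segment_lungs requires HU intensities", "ventimap_format_error")
  d <- dim(volume$values)
  fg <- volume$values >= hu_low & volume$values <= hu_high
  dim(fg) <- d
  if (!any(fg))
    vm_stop("no voxels inside the HU window", "ventimap_segmentation_error")
  lab <- .label_components_26(as.vector(fg), d)
  dim(lab) <- d
  nlab <- max(lab)
  sizes <- tabulate(lab, nbins = nlab)
  keep <- rep(TRUE, nlab)
  # components touching the in-plane border are background air
  border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ]))
  keep[border[border > 0]] <- FALSE
  if (remove_airways) {
    xs <- (seq_len(d[1]) - 1) * volume$spacing[1]
    x_mid <- mean(range(xs))
    halfw <- corridor_halfwidth_frac * diff(range(xs))
    fgv <- which(lab > 0)
    sums <- rowsum(xs[((fgv - 1L) %% d[1]) + 1L], lab[fgv])
    cx <- rep(NA_real_, nlab)
    cx[as.integer(rownames(sums))] <- sums[, 1] / sizes[as.integer(rownames(sums))]
    keep[!is.na(cx) & abs(cx - x_mid) <= halfw] <- FALSE
  }
  cand <- which(keep & sizes > 0)
  if (length(cand) == 0L)
    vm_stop("lung segmentation is empty after component filtering",
            "ventimap_segmentation_error")
  lungs <- cand[order(sizes[cand], decreasing = TRUE)][seq_len(min(2L, length(cand)))]
  m <- array(lab %in% lungs, dim = d)
  new_mask(m, spacing = volume$spacing, origin = volume$origin)
}
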