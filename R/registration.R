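#' Rigid transform between world spaces
#'
#' A 6-DOF (rotation + translation) map, by convention taking follow-up
#' world coordinates into baseline world space: `x_bl = R x_fu + t`.
#' Rigidity is essential here: growth is the measurand, and any scaling or
#' deformation would silently alter apparent growth.
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1 within 1e-6).
#' @param translation_mm Length-3 translation in mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation_mm = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation_mm <- as.numeric(translation_mm)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation_mm) != 3L)
    stop("rigid transform needs a 3x3 rotation and length-3 translation", call. = FALSE)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("`rotation` must be orthonormal with determinant +1", call. = FALSE)
  structure(list(rotation = rotation, translation_mm = translation_mm),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> angle ", round(rotation_angle_deg(x), 3),
      " deg, translation (", paste(round(x$translation_mm, 3), collapse = ", "),
      ") mm\n", sep = "")
  invisible(x)
}

#' Apply a rigid transform to world points
#' @param transform A [rigid_transform()].
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of transformed coordinates.
#' @export
apply_transform <- function(transform, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  sweep(pts %*% t(transform$rotation), 2L, transform$translation_mm, "+")
}

#' Invert a rigid transform
#' @param transform A [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, -as.vector(rt %*% transform$translation_mm))
}

#' Rotation angle of a rigid transform in degrees
#' @param transform A [rigid_transform()].
#' @return Rotation angle in `[0, 180]` degrees.
#' @export
rotation_angle_deg <- function(transform) {
  ct <- (sum(diag(transform$rotation)) - 1) / 2
  acos(min(1, max(-1, ct))) * 180 / pi
}

# Rx/Ry/Rz composition from angles in degrees
rotation_from_angles <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1L]); sx <- sin(a[1L])
  cy <- cos(a[2L]); sy <- sin(a[2L])
  cz <- cos(a[3L]); sz <- sin(a[3L])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3L)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3L)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3L)
  rz %*% ry %*% rx
}

# transform from optimisation parameters: rotate about `center`, then shift
params_to_transform <- function(angles_deg, shift_mm, center) {
  r <- rotation_from_angles(angles_deg)
  rigid_transform(r, as.numeric(center - r %*% center + shift_mm))
}

#' Dice similarity of two masks on one grid
#' @param a,b [binary_mask()]s or [label_map()]s sharing a shape;
#'   any positive voxel counts as foreground.
#' @return Dice coefficient in `[0, 1]` (1 when both are empty).
#' @export
mask_dice <- function(a, b) {
  ga <- if (inherits(a, c("binary_mask", "label_map"))) a$grid else a
  gb <- if (inherits(b, c("binary_mask", "label_map"))) b$grid else b
  na <- sum(ga > 0L); nb <- sum(gb > 0L)
  if (na + nb == 0L) return(1)
  2 * sum(ga > 0L & gb > 0L) / (na + nb)
}

#' Estimate the rigid liver-to-liver registration
#'
#' Aligns the follow-up examination to the baseline using only the two
#' liver masks. The transform is initialised by centre-of-mass alignment;
#' the rotation is estimated by aligning the principal axes of the two
#' masks (second-moment eigenvectors, signs disambiguated towards the
#' smaller rotation), which is robust to the voxelisation phase artifacts
#' that plague overlap-only rotation search; the translation is then
#' refined by a deterministic coarse-to-fine coordinate descent on a
#' smooth (trilinearly interpolated) liver-overlap score. The estimator
#' can never make things worse: if the refined transform scores a lower
#' full-resolution liver Dice than the centre-of-mass alignment, the
#' latter is returned.
#'
#' @param liver_bl,liver_fu [binary_mask()]s of the liver at baseline and
#'   follow-up (native spaces; geometries may differ).
#' @param max_rotation_deg Trust bound on the estimated rotation, degrees
#'   (default 15): a principal-axes rotation larger than this is rejected
#'   in favour of a translation-only alignment.
#' @param translation_step_mm Finest translation step, mm (default 1).
#' @param max_points Follow-up surface points used during the search;
#'   larger masks are deterministically subsampled (default 20000).
#' @return A list of class `liver_registration` with elements `transform`
#'   (follow-up world to baseline world [rigid_transform()]), `liver_dice`,
#'   `liver_dice_com` (Dice of the centre-of-mass-only alignment) and
#'   `params` (angles in degrees and residual shift in mm).
#' @export
estimate_liver_registration <- function(liver_bl, liver_fu,
                                        max_rotation_deg = 15,
                                        translation_step_mm = 1,
                                        max_points = 20000L) {
  if (!inherits(liver_bl, "binary_mask") || !inherits(liver_fu, "binary_mask"))
    stop("liver masks must be binary_mask objects", call. = FALSE)
  fg_bl <- which(liver_bl$grid > 0L)
  fg_fu <- which(liver_fu$grid > 0L)
  if (!length(fg_bl) || !length(fg_fu)) {
    warning("empty liver mask: falling back to identity registration; ",
            "matching proceeds unregistered", call. = FALSE)
    return(structure(list(transform = rigid_transform(),
                          liver_dice = NA_real_, liver_dice_com = NA_real_,
                          params = c(tx = 0, ty = 0, tz = 0)),
                     class = "liver_registration"))
  }
  pts_fu <- voxel_to_world(linear_to_idx0(fg_fu, liver_fu$geometry$shape),
                           liver_fu$geometry)
  com_bl <- colMeans(voxel_to_world(linear_to_idx0(fg_bl, liver_bl$geometry$shape),
                                    liver_bl$geometry))
  com_fu <- colMeans(pts_fu)
  n_fu <- nrow(pts_fu)
  sub <- if (n_fu > max_points) {
    pts_fu[unique(round(seq(1L, n_fu, length.out = max_points))), , drop = FALSE]
  } else pts_fu
  inv_aff <- solve(liver_bl$geometry$affine)
  shape_bl <- liver_bl$geometry$shape
  grid_bl <- liver_bl$grid
  hits <- function(transform, pts) {
    v <- cbind(apply_transform(transform, pts), 1) %*% t(inv_aff)
    i <- round(v[, 1L]); j <- round(v[, 2L]); k <- round(v[, 3L])
    ok <- i >= 0 & i < shape_bl[1L] & j >= 0 & j < shape_bl[2L] &
      k >= 0 & k < shape_bl[3L]
    if (!any(ok)) return(0L)
    lin <- 1 + i[ok] + shape_bl[1L] * (j[ok] + shape_bl[2L] * k[ok])
    sum(grid_bl[lin] > 0L)
  }
  # smooth objective: trilinear interpolation of the baseline liver mask at
  # the transformed points -- avoids the aliasing plateaus of binary lookup
  soft_hits <- function(transform, pts) {
    v <- cbind(apply_transform(transform, pts), 1) %*% t(inv_aff)
    i0 <- floor(v[, 1L]); j0 <- floor(v[, 2L]); k0 <- floor(v[, 3L])
    fi <- v[, 1L] - i0; fj <- v[, 2L] - j0; fk <- v[, 3L] - k0
    acc <- 0
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      i <- i0 + di; j <- j0 + dj; k <- k0 + dk
      w <- (if (di) fi else 1 - fi) * (if (dj) fj else 1 - fj) *
        (if (dk) fk else 1 - fk)
      ok <- i >= 0 & i < shape_bl[1L] & j >= 0 & j < shape_bl[2L] &
        k >= 0 & k < shape_bl[3L] & w > 0
      if (any(ok)) {
        lin <- 1 + i[ok] + shape_bl[1L] * (j[ok] + shape_bl[2L] * k[ok])
        acc <- acc + sum(w[ok] * (grid_bl[lin] > 0L))
      }
    }
    acc
  }
  full_dice <- function(transform) 2 * hits(transform, pts_fu) / (length(fg_bl) + n_fu)
  com_shift <- com_bl - com_fu
  pts_bl <- voxel_to_world(linear_to_idx0(fg_bl, liver_bl$geometry$shape),
                           liver_bl$geometry)
  r0 <- principal_axes_rotation(pts_bl, pts_fu)
  if (rotation_angle_deg(rigid_transform(r0)) > max_rotation_deg) r0 <- diag(3)
  make <- function(t3) {
    rigid_transform(r0, as.numeric(com_bl - r0 %*% com_fu + t3))
  }
  p <- c(0, 0, 0)
  score <- soft_hits(make(p), sub)
  for (step in c(6, 3, 1, 0.5, 0.25)) {
    trans_step <- max(step * translation_step_mm, translation_step_mm / 4)
    repeat {
      improved <- FALSE
      for (ii in 1:3) {
        for (sgn in c(1, -1)) {
          cand <- p
          cand[ii] <- cand[ii] + sgn * trans_step
          s <- soft_hits(make(cand), sub)
          if (s > score) {
            p <- cand; score <- s; improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
  }
  t_com <- rigid_transform(diag(3), com_shift)
  t_opt <- make(p)
  dice_com <- full_dice(t_com)
  dice_opt <- full_dice(t_opt)
  if (dice_opt < dice_com) {        # contract: never worse than COM alignment
    t_opt <- t_com
    dice_opt <- dice_com
  }
  structure(list(transform = t_opt, liver_dice = dice_opt,
                 liver_dice_com = dice_com,
                 params = stats::setNames(c(p), c("tx", "ty", "tz"))),
            class = "liver_registration")
}

# rotation aligning the principal axes of one point cloud onto another's;
# eigenvector signs are chosen to give the smallest rotation (valid for the
# moderate inter-visit rotations rigid liver alignment deals with)
principal_axes_rotation <- function(pts_ref, pts_mov) {
  if (nrow(pts_ref) < 10L || nrow(pts_mov) < 10L) return(diag(3))
  eref <- eigen(stats::cov(pts_ref), symmetric = TRUE)
  emov <- eigen(stats::cov(pts_mov), symmetric = TRUE)
  if (min(eref$values) < 1e-8 || min(emov$values) < 1e-8) return(diag(3))
  vr <- eref$vectors
  vm <- emov$vectors
  for (k in 1:3) if (sum(vr[, k] * vm[, k]) < 0) vm[, k] <- -vm[, k]
  if (det(vr) * det(vm) < 0) vm[, 3L] <- -vm[, 3L]
  r <- vr %*% t(vm)
  # guard against numerical drift from orthonormality
  sv <- svd(r)
  r <- sv$u %*% t(sv$v)
  if (det(r) < 0) return(diag(3))
  r
}

#' @export
print.liver_registration <- function(x, ...) {
  cat("<liver_registration> liver Dice ", round(x$liver_dice, 4),
      " (centre-of-mass only: ", round(x$liver_dice_com, 4), ")\n", sep = "")
  print(x$transform)
  invisible(x)
}

#' Resample a follow-up label map onto the baseline grid
#'
#' Nearest-neighbour resampling of the follow-up labels into baseline
#' space through a rigid transform; used only to compute overlaps.
#' Nearest neighbour guarantees that output labels are a subset of the
#' input labels (plus background) -- no label is ever invented. Reported
#' sizes are always measured in native space, never on this resampled map.
#'
#' @param map_fu Follow-up [label_map()] (native space).
#' @param transform [rigid_transform()] mapping follow-up world into
#'   baseline world.
#' @param ref_geometry Baseline [image_geometry()] to resample onto.
#' @return A [label_map()] on `ref_geometry`.
#' @export
resample_to_baseline <- function(map_fu, transform, ref_geometry) {
  if (!inherits(map_fu, "label_map")) stop("`map_fu` must be a label_map", call. = FALSE)
  shape <- ref_geometry$shape
  n <- prod(shape)
  idx0 <- linear_to_idx0(seq_len(n), shape)
  world_bl <- voxel_to_world(idx0, ref_geometry)
  world_fu <- apply_transform(invert_transform(transform), world_bl)
  v <- world_to_voxel(world_fu, map_fu$geometry)
  i <- round(v[, 1L]); j <- round(v[, 2L]); k <- round(v[, 3L])
  sf <- map_fu$geometry$shape
  ok <- i >= 0 & i < sf[1L] & j >= 0 & j < sf[2L] & k >= 0 & k < sf[3L]
  out <- integer(n)
  lin_src <- 1 + i[ok] + sf[1L] * (j[ok] + sf[2L] * k[ok])
  out[ok] <- map_fu$grid[lin_src]
  label_map(array(out, shape), ref_geometry)
}
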