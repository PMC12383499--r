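# Fixture builders and independent brute-force oracles used across tests.

tiny_mask <- function(arr, spacing = c(1, 1, 1)) {
  arr <- array(as.integer(arr != 0), dim = dim(arr))
  binary_mask(arr, image_geometry(dim(arr), spacing))
}

# rasterise one sphere by voxel-centre inclusion on a grid just covering it
sphere_mask <- function(radius_mm, spacing = c(1, 1, 1), center_off = c(0, 0, 0),
                        pad = 3) {
  n <- ceiling((2 * radius_mm + 2 * pad * spacing) / spacing) + 1
  geom <- image_geometry(n, spacing)
  ctr <- (n - 1) * spacing / 2 + center_off
  ax <- lapply(1:3, function(a) (seq_len(n[a]) - 1) * spacing[a])
  d2 <- outer(outer((ax[[1]] - ctr[1])^2, (ax[[2]] - ctr[2])^2, "+"),
              (ax[[3]] - ctr[3])^2, "+")
  binary_mask(array(as.integer(d2 <= radius_mm^2), n), geom)
}

# scalar stack-based flood fill: the independent connected-components oracle
flood_fill_labels <- function(arr, connectivity) {
  d <- dim(arr)
  off <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  ord <- rowSums(abs(off))
  off <- off[switch(as.character(connectivity),
                    "6" = ord == 1, "18" = ord >= 1 & ord <= 2, "26" = ord >= 1), ]
  lab <- array(0L, d)
  nxt <- 0L
  for (lin in which(arr != 0)) {
    if (lab[lin] > 0L) next
    nxt <- nxt + 1L
    stack <- lin
    lab[lin] <- nxt
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      v <- arrayInd(cur, d)
      for (r in seq_len(nrow(off))) {
        nb <- v + as.integer(off[r, ])
        if (any(nb < 1L) || any(nb > d)) next
        l2 <- nb[1] + d[1] * ((nb[2] - 1) + d[2] * (nb[3] - 1))
        if (arr[l2] != 0 && lab[l2] == 0L) {
          lab[l2] <- nxt
          stack <- c(stack, l2)
        }
      }
    }
  }
  lab
}

# partition of foreground voxels implied by a labelling, as a canonical
# set-of-sets representation (labelling-invariant)
label_partition <- function(lab) {
  lin <- which(lab > 0L)
  unname(lapply(split(lin, lab[lin]), sort))
}

partition_equal <- function(a, b) {
  key <- function(p) sort(vapply(p, function(v) paste(v, collapse = ","), ""))
  identical(key(a), key(b))
}

# exhaustive assignment oracle: enumerates every one-to-one assignment over
# pairs with dice > 0 and returns the one maximising (n pairs, total dice,
# -total distance)
exhaustive_matching <- function(candidates) {
  cand <- candidates[candidates$dice > 0, , drop = FALSE]
  bl <- sort(unique(cand$baseline_id))
  best <- list(n = -1L, dice = -Inf, dist = Inf, pairs = NULL)
  recurse <- function(i, used_fu, pairs, tot_dice, tot_dist) {
    if (i > length(bl)) {
      n <- nrow(pairs)
      if (n > best$n ||
          (n == best$n && tot_dice > best$dice + 1e-12) ||
          (n == best$n && abs(tot_dice - best$dice) <= 1e-12 &&
           tot_dist < best$dist - 1e-12)) {
        best <<- list(n = n, dice = tot_dice, dist = tot_dist, pairs = pairs)
      }
      return(invisible())
    }
    rows <- cand[cand$baseline_id == bl[i] & !(cand$followup_id %in% used_fu), ,
                 drop = FALSE]
    recurse(i + 1L, used_fu, pairs, tot_dice, tot_dist)  # leave unassigned
    for (r in seq_len(nrow(rows))) {
      recurse(i + 1L, c(used_fu, rows$followup_id[r]),
              rbind(pairs, rows[r, c("baseline_id", "followup_id")]),
              tot_dice + rows$dice[r], tot_dist + rows$distance_mm[r])
    }
  }
  recurse(1L, integer(), cand[0, c("baseline_id", "followup_id")], 0, 0)
  p <- best$pairs
  p[order(p$baseline_id), , drop = FALSE]
}

# small random constellation of overlapping sphere pairs for matching tests
random_constellation <- function(k, seed) {
  set.seed(seed)
  n <- c(40L, 40L, 30L)
  sp <- c(1.5, 1.5, 2)
  geom <- image_geometry(n, sp)
  ext <- (n - 1) * sp
  centers <- matrix(NA_real_, 0, 3)
  radii <- numeric()
  while (nrow(centers) < k) {
    p <- runif(3, 0.2, 0.8) * ext
    r <- runif(1, 2.5, 4.5)
    if (nrow(centers) && any(sqrt(colSums((t(centers) - p)^2)) < (radii + r + 6))) next
    centers <- rbind(centers, p)
    radii <- c(radii, r)
  }
  disp <- matrix(runif(3 * k, -2, 2), ncol = 3)
  ras <- function(ctrs, rads) {
    g <- array(0L, n)
    ax <- lapply(1:3, function(a) (seq_len(n[a]) - 1) * sp[a])
    for (b in seq_along(rads)) {
      d2 <- outer(outer((ax[[1]] - ctrs[b, 1])^2, (ax[[2]] - ctrs[b, 2])^2, "+"),
                  (ax[[3]] - ctrs[b, 3])^2, "+")
      g[d2 <= rads[b]^2] <- 1L
    }
    binary_mask(g, geom)
  }
  list(bl = ras(centers, radii), fu = ras(centers + disp, radii), k = k)
}

# run a named phantom scenario through the full pipeline
track_patient2 <- function(scenario, seed = 1) {
  pair <- phantom_scenario(scenario, seed = seed)
  res <- track_patient(pair$lesions_bl, pair$lesions_fu,
                       pair$liver_bl, pair$liver_fu)
  list(pair = pair, res = res)
}
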