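# Geometry fixtures ---------------------------------------------------------

# digital ball of radius r voxels (optionally anisotropic spacing)
mk_ball <- function(r, pad = 2, spacing = c(1, 1, 1)) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  co <- as.matrix(expand.grid(x = 1:n, y = 1:n, z = 1:n))
  g <- array((co[, 1] - ctr)^2 + (co[, 2] - ctr)^2 + (co[, 3] - ctr)^2 <= r^2,
             c(n, n, n))
  voxel_mask(g, spacing)
}

# random connected blob: largest 26-connected component of thresholded
# smoothed noise
mk_blob <- function(n = 20, seed = 1, frac = 0.3) {
  withr::with_seed(seed, {
    w <- array(rnorm(n^3), c(n, n, n))
    sm <- subgrade:::gauss_smooth3d(w, c(2, 2, 2))
    thr <- quantile(sm, 1 - frac)
    g <- sm > thr
    g[c(1, n), , ] <- FALSE
    g[, c(1, n), ] <- FALSE
    g[, , c(1, n)] <- FALSE
    zones <- subgrade:::.glszm_zones(array(as.integer(g), dim(g)), dim(g))
    # keep the largest component only
    lab <- array(0L, dim(g))
    best <- which.max(zones[, 2])
    # relabel by flood fill in R: reuse zones by masking iteratively
    keep <- array(FALSE, dim(g))
    # simple approach: BFS from the first unvisited voxel of each zone in
    # scan order mirrors .glszm_zones ordering
    seen <- array(FALSE, dim(g))
    zid <- 0L
    for (i in which(g)) {
      if (seen[i]) next
      zid <- zid + 1L
      comp <- flood26(g, i, seen)
      seen <- comp$seen
      if (zid == best) keep[comp$members] <- TRUE
    }
    voxel_mask(keep, c(1, 1, 1))
  })
}

flood26 <- function(g, start, seen) {
  d <- dim(g)
  stack <- start
  members <- integer(0)
  seen[start] <- TRUE
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    members <- c(members, cur)
    co <- arrayInd(cur, d)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      p <- co + c(dx, dy, dz)
      if (any(p < 1) || any(p > d)) next
      j <- p[1] + (p[2] - 1) * d[1] + (p[3] - 1) * d[1] * d[2]
      if (g[j] && !seen[j]) {
        seen[j] <- TRUE
        stack <- c(stack, j)
      }
    }
  }
  list(members = members, seen = seen)
}

# small random discretised volume (levels 1..ng inside a random mask)
mk_disc_toy <- function(n = 6, ng = 3, seed = 1, p_mask = 0.7) {
  withr::with_seed(seed, {
    g <- array(runif(n^3) < p_mask, c(n, n, n))
    if (sum(g) < 2) g[1:2] <- TRUE
    img <- array(0, c(n, n, n))
    img[g] <- sample.int(ng, sum(g), replace = TRUE) * 20 - 20
    list(image = image_volume(img), mask = voxel_mask(g))
  })
}

# Brute-force oracles --------------------------------------------------------

# all-pairs Euclidean distance from each foreground voxel to the nearest
# background voxel (the oracle for the separable distance transform)
oracle_edt <- function(mask) {
  d <- dim(mask)
  sp <- spacing(mask)
  fg <- which(as.logical(mask))
  bg <- which(!as.logical(mask))
  fco <- sweep(arrayInd(fg, d), 2, sp, `*`)
  bco <- sweep(arrayInd(bg, d), 2, sp, `*`)
  out <- array(0, d)
  for (i in seq_along(fg)) {
    dif <- sweep(bco, 2, fco[i, ])
    out[fg[i]] <- sqrt(min(rowSums(dif^2)))
  }
  out
}

# deepest-fraction core by exhaustive sort (ties: z, y, x order)
oracle_core <- function(mask, fraction) {
  dmap <- oracle_edt(mask)
  idx <- which(as.logical(mask))
  co <- arrayInd(idx, dim(mask))
  ord <- idx[order(-dmap[idx], co[, 3], co[, 2], co[, 1])]
  target <- round(fraction * length(idx))
  out <- array(FALSE, dim(mask))
  out[ord[seq_len(target)]] <- TRUE
  out
}

DIRS13 <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
                c(0, 1, 1), c(0, 1, -1),
                c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

lev_at <- function(lv, p) {
  d <- dim(lv)
  if (any(p < 1) || any(p > d)) return(0L)
  lv[p[1], p[2], p[3]]
}

# symmetric pair counting for one offset
oracle_glcm <- function(lv, ng, dir) {
  tab <- matrix(0, ng, ng)
  for (i in which(lv > 0L)) {
    co <- arrayInd(i, dim(lv))
    b <- lev_at(lv, co + dir)
    if (b > 0L) {
      a <- lv[i]
      tab[a, b] <- tab[a, b] + 1
      tab[b, a] <- tab[b, a] + 1
    }
  }
  tab
}

# run tracing for one direction
oracle_glrlm <- function(lv, ng, dir, lmax) {
  tab <- matrix(0, ng, lmax)
  for (i in which(lv > 0L)) {
    co <- arrayInd(i, dim(lv))
    if (lev_at(lv, co - dir) == lv[i]) next # not a run start
    len <- 1L
    p <- co + dir
    while (lev_at(lv, p) == lv[i]) {
      len <- len + 1L
      p <- p + dir
    }
    tab[lv[i], len] <- tab[lv[i], len] + 1
  }
  tab
}

# zone labelling by 26-connected flood fill
oracle_glszm <- function(lv) {
  d <- dim(lv)
  seen <- array(FALSE, d)
  zones <- list()
  for (i in which(lv > 0L)) {
    if (seen[i]) next
    g <- lv == lv[i]
    comp <- flood26(g, i, seen)
    seen <- comp$seen
    zones[[length(zones) + 1L]] <- c(level = lv[i],
                                     size = length(comp$members))
  }
  do.call(rbind, zones)
}

# dependence counting (26-neighbourhood, |di| <= alpha), k = neighbours
oracle_gldm <- function(lv, ng, alpha = 0L) {
  tab <- matrix(0, ng, 27)
  for (i in which(lv > 0L)) {
    co <- arrayInd(i, dim(lv))
    dep <- 0L
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      b <- lev_at(lv, co + c(dx, dy, dz))
      if (b > 0L && abs(b - lv[i]) <= alpha) dep <- dep + 1L
    }
    tab[lv[i], dep + 1L] <- tab[lv[i], dep + 1L] + 1
  }
  tab
}

# neighbourhood grey-tone difference accumulators
oracle_ngtdm <- function(lv, ng) {
  out <- matrix(0, ng, 2)
  for (i in which(lv > 0L)) {
    co <- arrayInd(i, dim(lv))
    nb <- integer(0)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      b <- lev_at(lv, co + c(dx, dy, dz))
      if (b > 0L) nb <- c(nb, b)
    }
    if (!length(nb)) next
    out[lv[i], 1] <- out[lv[i], 1] + 1
    out[lv[i], 2] <- out[lv[i], 2] + abs(lv[i] - mean(nb))
  }
  out
}

# Model-fixture helpers ------------------------------------------------------

# small linearly separable classification toy
mk_separable <- function(n = 40, seed = 5) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), each = n / 2)
    x <- cbind(f1 = ifelse(y == 1, 2, -2) + rnorm(n, sd = 0.3),
               f2 = ifelse(y == 1, 1.5, -1.5) + rnorm(n, sd = 0.3),
               f3 = rnorm(n))
    list(x = x, y = y)
  })
}
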