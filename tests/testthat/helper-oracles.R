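# Independent brute-force oracles. Everything here is a literal, loop-based
# transcription of the defining formulas, deliberately naive, written before
# and kept independent of the package implementation it checks.

# inverse-distance weighted mean of x against reference rows R
oracle_wmean <- function(x, R) {
  nr <- nrow(R)
  dv <- numeric(nr)
  for (l in seq_len(nr)) dv[l] <- sqrt(sum((x - R[l, ])^2))
  w <- numeric(nr)
  if (any(dv < 1e-12)) {
    z <- dv < 1e-12
    w[z] <- 1 / sum(z)
  } else {
    for (l in seq_len(nr)) w[l] <- 1 / dv[l]
    w <- w / sum(w)
  }
  out <- rep(0, ncol(R))
  for (l in seq_len(nr)) out <- out + w[l] * R[l, ]
  out
}

# literal transcription of the nonparametric between/within scatter pair
# (two classes; within-class weighted mean excludes the sample itself)
oracle_scatter <- function(X1, X2) {
  Xs <- list(X1, X2)
  n <- c(nrow(X1), nrow(X2))
  P <- n / sum(n)
  d <- ncol(X1)
  Sb <- Sw <- matrix(0, d, d)
  lam_of <- function(dd) {
    lam <- numeric(length(dd))
    if (any(dd < 1e-12)) {
      z <- dd < 1e-12
      lam[z] <- 1 / sum(z)
    } else {
      for (k in seq_along(dd)) lam[k] <- 1 / dd[k]
      lam <- lam / sum(lam)
    }
    lam
  }
  for (i in 1:2) {
    Xi <- Xs[[i]]
    Xj <- Xs[[3 - i]]
    # between-class terms
    M <- matrix(0, n[i], d)
    dd <- numeric(n[i])
    for (k in seq_len(n[i])) {
      M[k, ] <- oracle_wmean(Xi[k, ], Xj)
      dd[k] <- sqrt(sum((Xi[k, ] - M[k, ])^2))
    }
    lam <- lam_of(dd)
    for (k in seq_len(n[i])) {
      v <- Xi[k, ] - M[k, ]
      Sb <- Sb + P[i] * lam[k] / n[i] * (v %o% v)
    }
    # within-class terms
    Mw <- matrix(0, n[i], d)
    dw <- numeric(n[i])
    for (k in seq_len(n[i])) {
      Mw[k, ] <- oracle_wmean(Xi[k, ], Xi[-k, , drop = FALSE])
      dw[k] <- sqrt(sum((Xi[k, ] - Mw[k, ])^2))
    }
    lamw <- lam_of(dw)
    for (k in seq_len(n[i])) {
      v <- Xi[k, ] - Mw[k, ]
      Sw <- Sw + P[i] * lamw[k] / n[i] * (v %o% v)
    }
  }
  list(Sb = Sb, Sw = Sw)
}

# AUC as exhaustive pairwise concordance (ties count 1/2)
oracle_auc <- function(scores, truth, positive = "suitable") {
  pos <- which(truth == positive)
  neg <- which(truth != positive)
  tot <- 0
  for (i in pos) for (j in neg) {
    if (scores[i] > scores[j]) tot <- tot + 1
    else if (scores[i] == scores[j]) tot <- tot + 0.5
  }
  tot / (length(pos) * length(neg))
}

# entropy by direct histogram summation
oracle_entropy <- function(gray, mask) {
  x <- floor(gray[mask])
  s <- 0
  for (g in 0:255) {
    p <- sum(x == g) / length(x)
    if (p > 0) s <- s - p * log2(p)
  }
  s
}

# co-occurrence energy by O(n^2) pixel-pair enumeration
oracle_glcm_energy <- function(gray, mask, levels = 64, offset = 5) {
  q <- pmin(levels - 1, pmax(0, floor(gray * levels / 256)))
  dim(q) <- dim(gray)
  offs <- rbind(c(0, offset), c(offset, offset), c(offset, 0),
                c(offset, -offset), c(0, -offset), c(-offset, -offset),
                c(-offset, 0), c(-offset, offset))
  counts <- matrix(0, levels, levels)
  nr <- nrow(gray); nc <- ncol(gray)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    for (o in seq_len(nrow(offs))) {
      r2 <- r + offs[o, 1]; c2 <- c + offs[o, 2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && mask[r2, c2])
        counts[q[r, c] + 1, q[r2, c2] + 1] <- counts[q[r, c] + 1, q[r2, c2] + 1] + 1
    }
  }
  M <- counts / sum(counts)
  sum(M^2)
}

# eccentricity from explicit central moments (closed-form eigenvalues)
oracle_eccentricity <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  dimnames(pts) <- NULL
  n <- nrow(pts)
  rbar <- mean(pts[, 1]); cbar <- mean(pts[, 2])
  mu20 <- mu02 <- mu11 <- 0
  for (k in seq_len(n)) {
    dr <- pts[k, 1] - rbar; dc <- pts[k, 2] - cbar
    mu20 <- mu20 + dr * dr
    mu02 <- mu02 + dc * dc
    mu11 <- mu11 + dr * dc
  }
  mu20 <- mu20 / n; mu02 <- mu02 / n; mu11 <- mu11 / n
  disc <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + disc) / 2
  l2 <- (mu20 + mu02 - disc) / 2
  sqrt(1 - l2 / l1)
}

# hull pixel count by triangle-fan decomposition + inclusive barycentric test
oracle_hull_pixel_count <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  hull <- grDevices::chull(pts)
  v <- pts[hull, , drop = FALSE]
  in_tri <- function(p, a, b, c, tol = 1e-9) {
    d <- (b[2] - a[2]) * (c[1] - a[1]) - (c[2] - a[2]) * (b[1] - a[1])
    if (abs(d) < tol) return(FALSE)
    l1 <- ((b[2] - a[2]) * (p[1] - a[1]) - (b[1] - a[1]) * (p[2] - a[2])) / d
    l2 <- ((a[1] - c[1]) * (p[2] - a[2]) - (a[2] - c[2]) * (p[1] - a[1])) / -d
    l1 >= -tol && l2 >= -tol && (l1 + l2) <= 1 + tol
  }
  cnt <- 0
  for (r in min(pts[, 1]):max(pts[, 1]))
    for (c in min(pts[, 2]):max(pts[, 2])) {
      p <- c(r, c)
      hit <- FALSE
      if (nrow(v) == 1) hit <- all(p == v[1, ])
      else if (nrow(v) == 2) {
        # degenerate: on the segment
        hit <- abs((v[2, 2] - v[1, 2]) * (p[1] - v[1, 1]) -
                   (v[2, 1] - v[1, 1]) * (p[2] - v[1, 2])) < 1e-9 &&
               p[1] >= min(v[, 1]) && p[1] <= max(v[, 1]) &&
               p[2] >= min(v[, 2]) && p[2] <= max(v[, 2])
      } else {
        for (k in 2:(nrow(v) - 1)) {
          if (in_tri(p, v[1, ], v[k, ], v[k + 1, ])) { hit <- TRUE; break }
        }
      }
      if (hit) cnt <- cnt + 1
    }
  cnt
}

# naive re-implementation of the binary cleanup sequence for tiny inputs:
# disk closing, border-connected background fill, small-component removal
oracle_cleanup_count <- function(binary, closing_radius, min_area) {
  nr <- nrow(binary); nc <- ncol(binary)
  disk <- function(rad) {
    d <- 2 * rad + 1
    m <- matrix(FALSE, d, d)
    for (r in 1:d) for (c in 1:d)
      if ((r - rad - 1)^2 + (c - rad - 1)^2 <= rad^2) m[r, c] <- TRUE
    m
  }
  dilate <- function(m, se) {
    rad <- (nrow(se) - 1) / 2
    out <- matrix(FALSE, nr, nc)
    for (r in 1:nr) for (c in 1:nc) {
      if (!m[r, c]) next
      for (dr in -rad:rad) for (dc in -rad:rad) {
        if (!se[dr + rad + 1, dc + rad + 1]) next
        r2 <- r + dr; c2 <- c + dc
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) out[r2, c2] <- TRUE
      }
    }
    out
  }
  erode <- function(m, se) {
    rad <- (nrow(se) - 1) / 2
    out <- matrix(FALSE, nr, nc)
    for (r in 1:nr) for (c in 1:nc) {
      all_in <- TRUE
      for (dr in -rad:rad) for (dc in -rad:rad) {
        if (!se[dr + rad + 1, dc + rad + 1]) next
        r2 <- r + dr; c2 <- c + dc
        inside <- r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && m[r2, c2]
        if (!inside) all_in <- FALSE
      }
      if (all_in) out[r, c] <- TRUE
    }
    out
  }
  label8 <- function(m) {
    lab <- matrix(0L, nr, nc)
    cur <- 0L
    for (r in 1:nr) for (c in 1:nc) {
      if (!m[r, c] || lab[r, c] > 0) next
      cur <- cur + 1L
      stack <- list(c(r, c)); lab[r, c] <- cur
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (dr in -1:1) for (dc in -1:1) {
          r2 <- p[1] + dr; c2 <- p[2] + dc
          if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
              m[r2, c2] && lab[r2, c2] == 0) {
            lab[r2, c2] <- cur
            stack[[length(stack) + 1]] <- c(r2, c2)
          }
        }
      }
    }
    lab
  }
  se <- disk(closing_radius)
  m <- erode(dilate(binary, se), se)
  # fill holes: background 4-connected flood from the border
  bg <- !m
  reach <- matrix(FALSE, nr, nc)
  stack <- list()
  for (r in 1:nr) for (c in 1:nc)
    if ((r == 1 || r == nr || c == 1 || c == nc) && bg[r, c] && !reach[r, c]) {
      reach[r, c] <- TRUE
      stack[[length(stack) + 1]] <- c(r, c)
    }
  while (length(stack)) {
    p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r2 <- p[1] + o[1]; c2 <- p[2] + o[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
          bg[r2, c2] && !reach[r2, c2]) {
        reach[r2, c2] <- TRUE
        stack[[length(stack) + 1]] <- c(r2, c2)
      }
    }
  }
  m <- m | (!m & !reach)
  lab <- label8(m)
  if (max(lab) == 0) return(0L)
  keep <- 0L
  for (i in seq_len(max(lab))) if (sum(lab == i) >= min_area) keep <- keep + 1L
  keep
}

# circular disk mask helper used across tests
disk_mask <- function(n, cy, cx, r) {
  m <- matrix(FALSE, n, n)
  for (rr in 1:n) for (cc in 1:n)
    if ((rr - cy)^2 + (cc - cx)^2 <= r^2) m[rr, cc] <- TRUE
  m
}

# ellipse mask helper (axis-aligned unless phi given)
ellipse_mask_test <- function(n, a, b, phi = 0) {
  cy <- cx <- (n + 1) / 2
  m <- matrix(FALSE, n, n)
  for (r in 1:n) for (c in 1:n) {
    xr <- (c - cx) * cos(phi) + (r - cy) * sin(phi)
    yr <- -(c - cx) * sin(phi) + (r - cy) * cos(phi)
    if ((xr / a)^2 + (yr / b)^2 <= 1) m[r, c] <- TRUE
  }
  m
}
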