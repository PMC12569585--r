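# Independent brute-force oracles used to cross-check the package's
# implementations. Deliberately written in the most literal style possible
# (double loops, no shared helpers with the package).

# ---- label maps -----------------------------------------------------------

# 4-connected component labelling by explicit BFS flood fill.
oracle_label4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] != 0 && lab[i, j] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(i, j))
      lab[i, j] <- nxt
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
              mask[q[1], q[2]] != 0 && lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- nxt
            queue[[length(queue) + 1]] <- q
          }
        }
      }
    }
  }
  lab
}

# boundary pixels: object pixels with a 4-neighbour outside the object
oracle_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- NULL
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] != 0) {
      nb <- c(
        if (i > 1) mask[i - 1, j] else 0, if (i < nr) mask[i + 1, j] else 0,
        if (j > 1) mask[i, j - 1] else 0, if (j < nc) mask[i, j + 1] else 0
      )
      if (any(nb == 0)) out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(numeric(), 0, 2) else out
}

# ---- object metrics -------------------------------------------------------

oracle_overlap <- function(pred, truth) {
  kt <- max(truth); kp <- max(pred)
  O <- matrix(0, kt, kp)
  for (i in seq_len(kt)) for (j in seq_len(kp)) {
    O[i, j] <- sum(truth == i & pred == j)
  }
  O
}

oracle_match <- function(pred, truth) {
  kt <- max(truth); kp <- max(pred)
  if (kt == 0 || kp == 0) {
    tp <- 0L
  } else {
    O <- oracle_overlap(pred, truth)
    ta <- sapply(seq_len(kt), function(i) sum(truth == i))
    cand <- NULL
    for (i in seq_len(kt)) for (j in seq_len(kp)) {
      if (O[i, j] > 0.5 * ta[i]) cand <- rbind(cand, c(i, j, O[i, j]))
    }
    tp <- 0L
    if (!is.null(cand)) {
      cand <- cand[order(-cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
      used_t <- used_p <- integer()
      for (r in seq_len(nrow(cand))) {
        if (!(cand[r, 1] %in% used_t) && !(cand[r, 2] %in% used_p)) {
          used_t <- c(used_t, cand[r, 1]); used_p <- c(used_p, cand[r, 2])
          tp <- tp + 1L
        }
      }
    }
  }
  fp <- kp - tp; fn <- kt - tp
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 1
  list(tp = tp, fp = fp, fn = fn, f1 = f1)
}

oracle_object_dice <- function(pred, truth) {
  kt <- max(truth); kp <- max(pred)
  if (kt == 0 && kp == 0) return(1)
  if (kt == 0 || kp == 0) return(0)
  O <- oracle_overlap(pred, truth)
  ta <- sapply(seq_len(kt), function(i) sum(truth == i))
  pa <- sapply(seq_len(kp), function(j) sum(pred == j))
  s1 <- 0
  for (i in seq_len(kt)) {
    j <- which.max(O[i, ])
    d <- if (O[i, j] == 0) 0 else 2 * O[i, j] / (ta[i] + pa[j])
    s1 <- s1 + ta[i] / sum(ta) * d
  }
  s2 <- 0
  for (j in seq_len(kp)) {
    i <- which.max(O[, j])
    d <- if (O[i, j] == 0) 0 else 2 * O[i, j] / (ta[i] + pa[j])
    s2 <- s2 + pa[j] / sum(pa) * d
  }
  (s1 + s2) / 2
}

oracle_hausdorff_pts <- function(a, b) {
  da <- apply(a, 1, function(p) min(sqrt((b[, 1] - p[1])^2 + (b[, 2] - p[2])^2)))
  db <- apply(b, 1, function(p) min(sqrt((a[, 1] - p[1])^2 + (a[, 2] - p[2])^2)))
  max(max(da), max(db))
}

oracle_object_hausdorff <- function(pred, truth) {
  kt <- max(truth); kp <- max(pred)
  if (kt == 0 && kp == 0) return(0)
  diag_len <- sqrt(nrow(truth)^2 + ncol(truth)^2)
  if (kt == 0 || kp == 0) return(diag_len)
  O <- oracle_overlap(pred, truth)
  ta <- sapply(seq_len(kt), function(i) sum(truth == i))
  pa <- sapply(seq_len(kp), function(j) sum(pred == j))
  bt <- lapply(seq_len(kt), function(i) oracle_boundary(truth == i))
  bp <- lapply(seq_len(kp), function(j) oracle_boundary(pred == j))
  s1 <- 0
  for (i in seq_len(kt)) {
    j <- which.max(O[i, ])
    h <- if (O[i, j] > 0) {
      oracle_hausdorff_pts(bt[[i]], bp[[j]])
    } else {
      min(sapply(bp, function(b) oracle_hausdorff_pts(bt[[i]], b)))
    }
    s1 <- s1 + ta[i] / sum(ta) * h
  }
  s2 <- 0
  for (j in seq_len(kp)) {
    i <- which.max(O[, j])
    h <- if (O[i, j] > 0) {
      oracle_hausdorff_pts(bp[[j]], bt[[i]])
    } else {
      min(sapply(bt, function(b) oracle_hausdorff_pts(bp[[j]], b)))
    }
    s2 <- s2 + pa[j] / sum(pa) * h
  }
  (s1 + s2) / 2
}

# ---- morphometry ----------------------------------------------------------

# gift-wrapping convex hull of a point set (returns vertex indices)
oracle_gift_wrap <- function(x, y) {
  n <- length(x)
  start <- which.min(x + y * 1e-9)
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- setdiff(seq_len(n), p)
    best <- cand[1]
    for (q in cand[-1]) {
      cr <- (x[best] - x[p]) * (y[q] - y[p]) - (y[best] - y[p]) * (x[q] - x[p])
      if (cr < 0 ||
          (cr == 0 && (x[q] - x[p])^2 + (y[q] - y[p])^2 >
             (x[best] - x[p])^2 + (y[best] - y[p])^2)) {
        best <- q
      }
    }
    if (best == start) break
    hull <- c(hull, best)
    if (length(hull) > n) break
  }
  hull
}

# point in CLOSED convex polygon: all edge cross products share the
# polygon's winding sign (within tolerance, so on-edge points count)
oracle_pip <- function(px, py, vx, vy) {
  n <- length(vx)
  # winding sign from the polygon's signed area
  area2 <- sum(vx * vy[c(2:n, 1)] - vx[c(2:n, 1)] * vy)
  sgn <- sign(area2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (vx[j] - vx[i]) * (py - vy[i]) - (vy[j] - vy[i]) * (px - vx[i])
    if (cr * sgn < -1e-9) return(FALSE)
  }
  TRUE
}

oracle_features <- function(mask) {
  pts <- which(mask != 0, arr.ind = TRUE)
  rows <- pts[, 1]; cols <- pts[, 2]
  n <- nrow(pts)
  x <- cols; y <- -rows
  mu20 <- sum((x - mean(x))^2) / n + 1 / 12
  mu02 <- sum((y - mean(y))^2) / n + 1 / 12
  mu11 <- sum((x - mean(x)) * (y - mean(y))) / n
  tr2 <- (mu20 + mu02) / 2
  dd <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- tr2 + dd; l2 <- max(tr2 - dd, 0)
  orient <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  if (orient <= -pi / 2) orient <- orient + pi
  # convex hull of all pixel corners, gift wrapping
  cx <- c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5)
  cy <- c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5)
  u <- !duplicated(cbind(cx, cy))
  cx <- cx[u]; cy <- cy[u]
  h <- oracle_gift_wrap(cx, cy)
  conv <- 0L
  for (r in min(rows):max(rows)) for (cc in min(cols):max(cols)) {
    if (oracle_pip(cc, r, cx[h], cy[h]) ||
        any(rows == r & cols == cc)) {
      conv <- conv + 1L
    }
  }
  # filled area: background components not touching the border are holes
  inv <- oracle_label4(!mask)
  border_ids <- unique(c(inv[1, ], inv[nrow(inv), ], inv[, 1], inv[, ncol(inv)]))
  holes <- sum(inv != 0 & !(inv %in% border_ids))
  # Crofton perimeter: explicit 2x2 window loop
  pm <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  pm[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask != 0
  s2 <- sqrt(2)
  lut <- c(pi / 4 * (1 + 1 / s2), pi / (4 * s2), pi / (2 * s2), 0,
           pi / 4 * (1 + 1 / s2), 0, pi / (4 * s2), pi / 4, pi / 2,
           pi / (4 * s2), pi / (4 * s2), pi / 4, pi / 2, 0, 0)
  perim <- 0
  for (i in 1:(nrow(pm) - 1)) for (j in 1:(ncol(pm) - 1)) {
    code <- pm[i + 1, j + 1] + 4 * pm[i + 1, j] + 2 * pm[i, j + 1] + 8 * pm[i, j]
    if (code > 0) perim <- perim + lut[code]
  }
  bh <- max(rows) - min(rows) + 1; bw <- max(cols) - min(cols) + 1
  c(
    area = n,
    major_axis_length = 4 * sqrt(l1),
    minor_axis_length = 4 * sqrt(l2),
    eccentricity = if (l1 > 0) sqrt(max(0, 1 - l2 / l1)) else 0,
    orientation = orient,
    convex_area = conv,
    filled_area = n + holes,
    equivalent_diameter = sqrt(4 * n / pi),
    solidity = n / conv,
    extent = n / (bh * bw),
    perimeter = perim,
    box_aspect_ratio = max(bh, bw) / min(bh, bw),
    compactness = min(1, 4 * pi * n / perim^2)
  )
}

# ---- survival -------------------------------------------------------------

# Efron partial log-likelihood for a single covariate, literal formula.
oracle_cox_loglik1 <- function(beta, x, time, event) {
  ll <- 0
  for (t0 in unique(time[event == 1])) {
    D <- which(time == t0 & event == 1)
    R <- which(time >= t0)
    d <- length(D)
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum(exp(beta * x[R])) - l / d * sum(exp(beta * x[D])))
    }
    ll <- ll + sum(beta * x[D])
  }
  ll
}

oracle_cindex <- function(time, event, risk) {
  conc <- 0; comp <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    usable <- (time[i] < time[j] && event[i] == 1) ||
      (time[i] == time[j] && event[i] == 1 && event[j] == 0)
    if (usable) {
      comp <- comp + 1
      if (risk[i] > risk[j]) conc <- conc + 1
      if (risk[i] == risk[j]) conc <- conc + 0.5
    }
  }
  conc / comp
}

# ---- random fixtures ------------------------------------------------------

random_label_map <- function(nr = 64, nc = 64, n_blobs = 4) {
  m <- matrix(0L, nr, nc)
  for (b in seq_len(n_blobs)) {
    cy <- runif(1, 8, nr - 8); cx <- runif(1, 8, nc - 8)
    r <- runif(1, 3, 9)
    ii <- matrix(seq_len(nr), nr, nc); jj <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    el <- ((ii - cy) / r)^2 + ((jj - cx) / (r * runif(1, 0.6, 1.4)))^2 <= 1
    m[el & m == 0L] <- b
  }
  glandsurv::label_instances(m > 0) # consecutive, 4-connected components
}

random_blob_mask <- function(nr = 48, nc = 48) {
  cy <- runif(1, 14, nr - 14); cx <- runif(1, 14, nc - 14)
  r <- runif(1, 5, 11)
  ii <- matrix(seq_len(nr), nr, nc); jj <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  th <- atan2(ii - cy, jj - cx)
  wob <- 1 + 0.25 * sin(2 * th + runif(1, 0, 6)) + 0.15 * cos(3 * th + runif(1, 0, 6))
  m <- (sqrt((ii - cy)^2 + (jj - cx)^2) <= r * wob)
  lab <- oracle_label4(m)
  if (max(lab) > 1) m <- lab == which.max(tabulate(lab[lab > 0]))
  matrix(as.integer(m), nr, nc)
}
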