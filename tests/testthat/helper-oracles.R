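# Brute-force oracles, written independently of the package's vectorized
# implementations: plain loops over pixels, pairs and partitions.

# --- co-occurrence: exhaustive pair enumeration over the 4 directions ----
oracleGLCMCounts <- function(q, L, d) {
  nr <- nrow(q); nc <- ncol(q)
  cnt <- matrix(0, L, L)
  dirs <- list(c(0, d), c(-d, d), c(-d, 0), c(-d, -d))
  for (r in seq_len(nr)) for (cc in seq_len(nc)) for (dd in dirs) {
    r2 <- r + dd[1]; c2 <- cc + dd[2]
    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
      a <- q[r, cc] + 1; b <- q[r2, c2] + 1
      cnt[a, b] <- cnt[a, b] + 1
      cnt[b, a] <- cnt[b, a] + 1
    }
  }
  cnt
}

oracleGLCMStats <- function(P) {
  L <- nrow(P)
  ene <- 0; con <- 0; hom <- 0; dis <- 0; maxp <- 0; acor <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    ene <- ene + p^2
    con <- con + (i - j)^2 * p
    hom <- hom + p / (1 + (i - j)^2)
    dis <- dis + abs(i - j) * p
    acor <- acor + i * j * p
    if (p > maxp) maxp <- p
  }
  ent <- 0
  for (i in 1:L) for (j in 1:L) if (P[i, j] > 0)
    ent <- ent - P[i, j] * log(P[i, j])
  c(energy = ene, contrast = con, idm = hom, dissimilarity = dis,
    autocorrelation = acor, maximum_probability = maxp, entropy = ent)
}

# --- run lengths: walk every line explicitly -----------------------------
oracleRuns <- function(q, dr, dc) {
  nr <- nrow(q); nc <- ncol(q)
  seen <- matrix(FALSE, nr, nc)
  runs <- list()
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    rp <- r - dr; cp <- cc - dc
    startsLine <- rp < 1 || rp > nr || cp < 1 || cp > nc
    if (!startsLine) next
    rr <- r; c2 <- cc
    while (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc) {
      lvl <- q[rr, c2]; len <- 0
      while (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc &&
             q[rr, c2] == lvl) {
        len <- len + 1; rr <- rr + dr; c2 <- c2 + dc
      }
      runs[[length(runs) + 1]] <- c(level = lvl, length = len)
    }
  }
  do.call(rbind, runs)
}

oracleGLRLM <- function(q) {
  n <- length(q)
  dirs <- list(c(0, 1), c(-1, 1), c(1, 0), c(1, 1))  # 0, 45, 90, 135 deg
  per <- sapply(dirs, function(d) {
    runs <- oracleRuns(q, d[1], d[2])
    l <- runs[, "length"]; g <- runs[, "level"]
    nr <- nrow(runs)
    gln <- sum(table(g)^2) / nr
    rln <- sum(table(l)^2) / nr
    c(sre = sum(1 / l^2) / nr, lre = sum(l^2) / nr, gln = gln,
      rln = rln, rp = nr / n, lglre = sum(1 / (g + 1)^2) / nr)
  })
  rowMeans(per)
}

# --- GLDS: windowed means by direct loops --------------------------------
oracleGLDS <- function(roi, w) {
  nr <- nrow(roi); nc <- ncol(roi)
  h <- (w - 1) / 2
  refl <- function(i, n) {
    while (i < 1 || i > n) i <- ifelse(i < 1, 2 - i, 2 * n - i)
    i
  }
  d <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    s <- 0
    for (dr in -h:h) for (dc in -h:h)
      s <- s + roi[refl(r + dr, nr), refl(cc + dc, nc)]
    d[r, cc] <- abs(roi[r, cc] - s / w^2)
  }
  d
}

# --- NGTDM: per-pixel neighbourhood sums ---------------------------------
oracleNGTDM <- function(q, d) {
  nr <- nrow(q); nc <- ncol(q)
  if (nr < 2 * d + 1 || nc < 2 * d + 1) return(NULL)
  gs <- c(); devs <- c()
  for (r in (d + 1):(nr - d)) for (cc in (d + 1):(nc - d)) {
    s <- 0
    for (dr in -d:d) for (dc in -d:d)
      if (!(dr == 0 && dc == 0)) s <- s + q[r + dr, cc + dc]
    gs <- c(gs, q[r, cc])
    devs <- c(devs, abs(q[r, cc] - s / ((2 * d + 1)^2 - 1)))
  }
  N <- length(gs)
  levels <- sort(unique(gs))
  s_g <- sapply(levels, function(g) sum(devs[gs == g]))
  p_g <- sapply(levels, function(g) sum(gs == g)) / N
  list(levels = levels, s = s_g, p = p_g, N = N)
}

# --- SFM dissimilarity/contrast by direct loops --------------------------
oracleSFMDelta <- function(x, dr, dc) {
  nr <- nrow(x); nc <- ncol(x)
  dsum <- 0; csum <- 0; n <- 0
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    r2 <- r + dr; c2 <- cc + dc
    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
      dd <- x[r, cc] - x[r2, c2]
      dsum <- dsum + abs(dd); csum <- csum + dd^2; n <- n + 1
    }
  }
  c(dis = dsum / n, con = csum / n)
}

# --- complete-linkage clustering: naive agglomeration --------------------
oracleCompleteLinkage <- function(points, maxDist) {
  n <- nrow(points)
  clusters <- as.list(seq_len(n))
  dmat <- as.matrix(dist(points))
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA); bestD <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dd <- max(dmat[clusters[[i]], clusters[[j]]])
      if (dd < bestD) { bestD <- dd; best <- c(i, j) }
    }
    if (bestD > maxDist) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  lab <- integer(n)
  for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
  lab
}

# Compare two partitions up to relabelling.
samePartition <- function(a, b) {
  identical(as.integer(match(a, unique(a))),
            as.integer(match(b, unique(b))))
}

# Small quantized test image with a known level count.
randomQuantized <- function(nr, nc, L, seed) {
  set.seed(seed)
  q <- matrix(sample(0:(L - 1), nr * nc, replace = TRUE), nr, nc)
  storage.mode(q) <- "integer"
  attr(q, "levels") <- as.integer(L)
  q
}
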