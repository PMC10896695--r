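# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: exhaustive enumeration for change points and
# plain rank arithmetic for the nonparametric statistics.

# Exhaustive least-squares change-point search: every placement of k change
# points with segments of at least `min_seg` frames. Returns the best RSS
# and the 0-based change points (first frame of the new segment).
brute_force_steps <- function(y, k, min_seg = 5) {
  n <- length(y)
  seg_rss <- function(a, b) {
    seg <- y[a:b]
    sum((seg - mean(seg))^2)
  }
  if (k == 0) {
    return(list(rss = seg_rss(1, n), cps = integer()))
  }
  best <- list(rss = Inf, cps = integer())
  positions <- utils::combn(seq(min_seg, n - min_seg), k)
  for (j in seq_len(ncol(positions))) {
    cps <- positions[, j, drop = TRUE]
    edges <- c(0, cps, n)
    if (any(diff(edges) < min_seg)) next
    rss <- 0
    for (s in seq_len(length(edges) - 1)) {
      rss <- rss + seg_rss(edges[s] + 1, edges[s + 1])
    }
    if (rss < best$rss - 1e-12) best <- list(rss = rss, cps = cps)
  }
  best
}

# Kruskal-Wallis H by direct rank arithmetic (tie-corrected).
manual_kruskal_h <- function(groups) {
  values <- unlist(groups)
  n <- length(values)
  r <- rank(values)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, function(ri) length(ri) * mean(ri)^2)) -
    3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Dunn z statistics written out longhand for a list of groups.
manual_dunn <- function(groups) {
  values <- unlist(groups)
  labels <- rep(names(groups), lengths(groups))
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  out <- list()
  combos <- utils::combn(names(groups), 2)
  for (j in seq_len(ncol(combos))) {
    g1 <- combos[1, j]
    g2 <- combos[2, j]
    r1 <- r[labels == g1]
    r2 <- r[labels == g2]
    se <- sqrt(
      (n * (n + 1) / 12 - tie_term) * (1 / length(r1) + 1 / length(r2))
    )
    out[[j]] <- data.frame(
      group1 = g1, group2 = g2, z = (mean(r1) - mean(r2)) / se
    )
  }
  do.call(rbind, out)
}

# Mixture-of-binomials fluorophore distribution, enumerated directly.
manual_fluor_pmf <- function(pmf, copies, eff) {
  kmax <- max(as.integer(names(pmf))) * copies
  p <- numeric(kmax + 1)
  for (m_chr in names(pmf)) {
    m <- as.integer(m_chr)
    for (k in 0:(m * copies)) {
      p[k + 1] <- p[k + 1] +
        pmf[[m_chr]] * choose(m * copies, k) * eff^k * (1 - eff)^(m * copies - k)
    }
  }
  p
}

# A noiseless synthetic track built directly: piecewise-constant velocity.
# `segments` is a list of c(duration_s, velocity_um_s).
make_track <- function(track_id, segments, x0 = 100, frame_rate = 2,
                       t0 = 0, movie = 1L, replicate = 1L) {
  dt <- 1 / frame_rate
  total <- sum(vapply(segments, `[`, numeric(1), 1))
  tq <- seq(0, total, by = dt)
  x <- numeric(length(tq))
  pos <- x0
  seg_start <- 0
  j <- 1
  for (i in seq_along(tq)) {
    while (j < length(segments) && tq[i] > seg_start + segments[[j]][1] + 1e-9) {
      pos <- pos + segments[[j]][2] * segments[[j]][1]
      seg_start <- seg_start + segments[[j]][1]
      j <- j + 1
    }
    x[i] <- pos + segments[[j]][2] * (tq[i] - seg_start)
  }
  tibble::tibble(
    track_id = track_id, movie = movie, frame = seq_along(tq) - 1L,
    t = tq + t0, x = x, y = 0, intensity = 52, channel = "A",
    replicate = replicate
  )
}
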