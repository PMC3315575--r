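# Independent oracles used to cross-check the package's own algorithms.
# These deliberately re-derive each quantity from first principles (plain
# definitions, exhaustive search, textbook Dijkstra) and share no code with
# the implementations they check.

# Exhaustive-search three-class Otsu: direct definition of the between-class
# variance, triple loop over all threshold pairs.
oracle_otsu3 <- function(counts, centers = seq_along(counts) - 1) {
  n <- sum(counts)
  mu <- sum(counts * centers) / n
  B <- length(counts)
  best <- -Inf; best_ij <- c(NA, NA)
  for (i in 1:(B - 2)) {
    for (j in (i + 1):(B - 1)) {
      cls <- list(1:i, (i + 1):j, (j + 1):B)
      bcv <- 0
      for (k in cls) {
        wk <- sum(counts[k]) / n
        if (wk > 0) {
          mk <- sum(counts[k] * centers[k]) / sum(counts[k])
          bcv <- bcv + wk * (mk - mu)^2
        }
      }
      if (bcv > best) { best <- bcv; best_ij <- c(i, j) }
    }
  }
  best_ij
}

# Textbook Dijkstra from each seed label separately; pixels take the label of
# the closest seed set, ties resolved to the smaller label.
oracle_propagate <- function(intensity, seeds, lambda, connectivity = 8) {
  H <- nrow(intensity); W <- ncol(intensity); V <- H * W
  labs <- sort(unique(seeds[seeds > 0]))
  nd <- if (connectivity == 8) 8 else 4
  dr <- c(-1, 1, 0, 0, -1, -1, 1, 1)[1:nd]
  dc <- c(0, 0, -1, 1, -1, 1, -1, 1)[1:nd]
  st <- c(1, 1, 1, 1, sqrt(2), sqrt(2), sqrt(2), sqrt(2))[1:nd]
  dist_for <- function(l) {
    dist <- rep(Inf, V); dist[which(seeds == l)] <- 0
    settled <- rep(FALSE, V)
    repeat {
      d <- dist; d[settled] <- Inf
      p <- which.min(d)
      if (!is.finite(d[p])) break
      settled[p] <- TRUE
      r <- (p - 1) %% H + 1; cc <- (p - 1) %/% H + 1
      for (k in seq_len(nd)) {
        rr <- r + dr[k]; c2 <- cc + dc[k]
        if (rr < 1 || rr > H || c2 < 1 || c2 > W) next
        q <- (c2 - 1) * H + rr
        if (settled[q]) next
        w <- sqrt(lambda * st[k]^2 + (intensity[p] - intensity[q])^2)
        if (dist[p] + w < dist[q]) dist[q] <- dist[p] + w
      }
    }
    dist
  }
  D <- vapply(labs, dist_for, numeric(V))
  lab <- labs[max.col(-D, ties.method = "first")]
  lab[!is.finite(apply(D, 1, min))] <- 0L
  matrix(as.integer(lab), H, W)
}

# Octile (8-connected grid geodesic) distance between pixel grids and a
# point: closed form max + (sqrt(2)-1) * min.
octile_dist <- function(H, W, r0, c0) {
  rr <- matrix(rep(1:H, times = W), H, W)
  cc <- matrix(rep(1:W, each = H), H, W)
  a <- abs(rr - r0); b <- abs(cc - c0)
  pmax(a, b) + (sqrt(2) - 1) * pmin(a, b)
}

# Sort-based median (independent of stats::median).
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n == 0L) return(NA_real_)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# Binary disk stamped into a matrix.
disk_mask <- function(H, W, r0, c0, radius) {
  rr <- matrix(rep(1:H, times = W), H, W)
  cc <- matrix(rep(1:W, each = H), H, W)
  (rr - r0)^2 + (cc - c0)^2 <= radius^2
}

# Quiet scene parameters for exact-arithmetic tests (overridable).
exact_params <- function(...) {
  args <- list(content_cv = 0, well_effect_cv = 0, nuclear_bleed_fraction = 0,
               noise_gaussian_sd = 0, poisson_scaling = 0, blur_sigma_px = 0,
               illumination_gradient_amplitude = 0)
  args <- utils::modifyList(args, list(...))
  do.call(scene_params, args)
}
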