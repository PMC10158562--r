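# Independent oracles and small fixtures shared across tests. These are
# deliberately written with different algorithms than the package code.

# Closed-form truncated-normal moments (independent of the package code).
oracle_truncnorm_moments <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  Z <- pnorm(b) - pnorm(a)
  m <- mean + sd * (dnorm(a) - dnorm(b)) / Z
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                 ((dnorm(a) - dnorm(b)) / Z)^2)
  c(mean = m, sd = sqrt(v))
}

# Connected components by boolean matrix powers (reachability), independent
# of the package's BFS.
oracle_components <- function(adj) {
  n <- nrow(adj)
  reach <- diag(TRUE, n) | adj
  repeat {
    new_reach <- reach | ((reach %*% reach) > 0)
    if (identical(new_reach, reach)) break
    reach <- new_reach
  }
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      comp[reach[i, ]] <- cur
    }
  }
  comp
}

# Extent-criterion oracle: direct double-loop scan, spatial components via
# oracle_components.
oracle_extent_mask <- function(p, adj, min_consec, min_adjacent, alpha) {
  E <- nrow(p); Tn <- ncol(p)
  supra <- p < alpha
  combined <- matrix(FALSE, E, Tn)
  for (t in seq_len(Tn)) {
    el <- which(supra[, t])
    if (length(el) == 0L) next
    comp <- oracle_components(adj[el, el, drop = FALSE])
    for (i in seq_along(el)) {
      if (sum(comp == comp[i]) >= min_adjacent) combined[el[i], t] <- TRUE
    }
  }
  mask <- matrix(FALSE, E, Tn)
  for (e in seq_len(E)) {
    t <- 1L
    while (t <= Tn) {
      if (combined[e, t]) {
        len <- 0L
        while (t + len <= Tn && combined[e, t + len]) len <- len + 1L
        if (len >= min_consec) mask[e, t:(t + len - 1L)] <- TRUE
        t <- t + len
      } else t <- t + 1L
    }
  }
  mask
}

# GEV oracle: naive double loop over TFs and electrodes.
oracle_gev <- function(X, templates, labels) {
  E <- nrow(X); Tn <- ncol(X)
  num <- 0; den <- 0
  for (t in seq_len(Tn)) {
    u <- X[, t] - mean(X[, t])
    g <- sqrt(sum(u^2) / E)
    den <- den + g^2
    k <- labels[t]
    if (is.na(k) || k == 0L) next
    v <- templates[, k] - mean(templates[, k])
    r <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    num <- num + (g * r)^2
  }
  num / den
}

# Exhaustive GEV optimum over 2-cluster segmentations with contiguous
# blocks (single boundary), using the same centroid convention as the
# clustering (GFP-weighted, polarity-aligned) but coded independently.
oracle_contiguous_best <- function(X) {
  E <- nrow(X); Tn <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))
  g <- sqrt(colMeans(Xc^2))
  V <- sweep(Xc, 2, g, "/")
  gev_of <- function(lab) {
    num <- 0
    for (k in unique(lab)) {
      Mi <- which(lab == k)
      anchor <- Mi[which.max(g[Mi])]
      s <- sign(crossprod(V[, Mi, drop = FALSE], V[, anchor])); s[s == 0] <- 1
      cen <- V[, Mi, drop = FALSE] %*% (g[Mi] * as.numeric(s))
      cen <- cen - mean(cen)
      gn <- sqrt(mean(cen^2))
      if (gn < 1e-12) next
      cen <- cen / gn
      r <- as.numeric(crossprod(V[, Mi, drop = FALSE], cen)) / E
      num <- num + sum((g[Mi] * r)^2)
    }
    num / sum(g^2)
  }
  best <- -Inf
  for (b in 1:(Tn - 1)) best <- max(best, gev_of(rep(1:2, c(b, Tn - b))))
  best
}

# Pair of centered unit-GFP 4-electrode maps with |r| <= 0.5.
separated_pair_4el <- function() {
  repeat {
    t1 <- rnorm(4); t1 <- t1 - mean(t1); t1 <- t1 / sqrt(mean(t1^2))
    t2 <- rnorm(4); t2 <- t2 - mean(t2); t2 <- t2 / sqrt(mean(t2^2))
    if (abs(mean(t1 * t2)) <= 0.5) return(cbind(t1, t2))
  }
}

# Hand-built ring montage with known adjacency: electrode i neighbors
# i-1 and i+1 (mod n). Used for explicit spatial-extent cases.
ring_montage <- function(n = 8L) {
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  z <- 0.5
  r <- sqrt(1 - z^2)
  pos <- cbind(r * cos(theta), r * sin(theta), z)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    adj[i, if (i == n) 1L else i + 1L] <- TRUE
    adj[i, if (i == 1L) n else i - 1L] <- TRUE
  }
  labels <- sprintf("R%02d", seq_len(n))
  rownames(pos) <- labels
  dimnames(adj) <- list(labels, labels)
  structure(list(labels = labels, pos = pos, adjacency = adj),
            class = "montage")
}

# Subject ERP made of adjacent planted states (each `dur` TFs) with
# raised-cosine ramps and white noise; used in recovery simulations.
planted_state_erp <- function(templates, dur = 50L, amplitude = 3,
                              noise_sd = amplitude / sqrt(10),
                              ramp_tf = 5L) {
  E <- nrow(templates)
  k <- ncol(templates)
  Tt <- k * dur
  X <- matrix(0, E, Tt)
  for (i in seq_len(k)) {
    env <- erpmicro:::state_envelope(Tt, (i - 1L) * dur, i * dur, ramp_tf)
    X <- X + amplitude * tcrossprod(templates[, i], env)
  }
  X + matrix(rnorm(E * Tt, sd = noise_sd), E)
}
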