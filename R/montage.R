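# Electrode montage: identities, 3-D unit-sphere positions, neighbor graph.

#' Construct a synthetic EEG montage
#'
#' Places `n_electrodes` on the upper part of the unit sphere along a
#' Fibonacci spiral, mimicking the coverage of an EEG cap, and builds a
#' neighbor graph by connecting electrodes closer than a distance threshold
#' (grown until the graph is connected). The construction is deterministic.
#'
#' @param n_electrodes Number of electrodes (>= 4). 128 matches a standard
#'   high-density cap; 32 is a convenient scaled-down montage.
#' @param cap_fraction Fraction of the sphere (from the vertex down) covered
#'   by the cap; the default 0.65 leaves the face and neck free.
#' @return An object of class `montage`: `labels`, `pos` (n x 3 unit
#'   vectors), `adjacency` (symmetric, irreflexive logical matrix).
#' @export
make_montage <- function(n_electrodes, cap_fraction = 0.65) {
  stopifnot(n_electrodes >= 4, cap_fraction > 0, cap_fraction <= 1)
  n <- as.integer(n_electrodes)
  i <- seq_len(n)
  # z from the vertex (1) down to 1 - 2*cap_fraction
  z <- 1 - (i - 0.5) / n * 2 * cap_fraction
  golden <- pi * (3 - sqrt(5))
  theta <- golden * i
  r <- sqrt(pmax(0, 1 - z^2))
  pos <- cbind(x = r * cos(theta), y = r * sin(theta), z = z)
  labels <- sprintf("E%03d", i)
  rownames(pos) <- labels
  adjacency <- build_adjacency(pos)
  structure(list(labels = labels, pos = pos, adjacency = adjacency),
            class = "montage")
}

# Distance-threshold neighbor graph; the threshold starts at 1.6x the median
# nearest-neighbor chord distance and grows until the graph is connected.
build_adjacency <- function(pos) {
  n <- nrow(pos)
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  nn <- apply(d, 1L, min)
  thr <- 1.6 * stats::median(nn)
  repeat {
    adj <- d <= thr
    diag(adj) <- FALSE
    if (max(graph_components(adj)) == 1L) break
    thr <- thr * 1.1
  }
  dimnames(adj) <- list(rownames(pos), rownames(pos))
  adj
}

validate_montage <- function(m) {
  stopifnot(inherits(m, "montage"))
  norms <- sqrt(rowSums(m$pos^2))
  if (any(abs(norms - 1) > 1e-6)) stop("montage positions must be unit vectors")
  if (!isTRUE(all(m$adjacency == t(m$adjacency)))) {
    stop("montage adjacency must be symmetric")
  }
  if (any(diag(m$adjacency))) stop("montage adjacency must be irreflexive")
  if (max(graph_components(m$adjacency)) != 1L) {
    stop("montage adjacency graph must be connected")
  }
  invisible(m)
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d electrodes, %d neighbor edges\n",
              nrow(x$pos), sum(x$adjacency) / 2))
  invisible(x)
}

#' Read a montage from a plain-text electrode position file
#'
#' The file has one electrode per line: `label x y z`, whitespace-separated.
#' Positions are renormalized to unit length.
#'
#' @param path File path.
#' @return A `montage` object.
#' @export
read_montage <- function(path) {
  tab <- utils::read.table(path, header = FALSE, col.names = c("label", "x", "y", "z"),
                           stringsAsFactors = FALSE)
  pos <- as.matrix(tab[, c("x", "y", "z")])
  pos <- pos / sqrt(rowSums(pos^2))
  rownames(pos) <- tab$label
  structure(list(labels = tab$label, pos = pos,
                 adjacency = build_adjacency(pos)),
            class = "montage")
}

#' Write a montage to a plain-text electrode position file
#'
#' @param montage A `montage` object.
#' @param path File path.
#' @export
write_montage <- function(montage, path) {
  tab <- data.frame(label = montage$labels, montage$pos)
  utils::write.table(tab, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# Potential of current dipoles in an unbounded homogeneous medium, evaluated
# at the electrode positions. `dip_pos` (k x 3) inside the sphere, `dip_mom`
# (k x 3). Used as the smooth forward model behind synthetic template maps.
dipole_field <- function(montage, dip_pos, dip_mom) {
  dip_pos <- matrix(dip_pos, ncol = 3L)
  dip_mom <- matrix(dip_mom, ncol = 3L)
  v <- numeric(nrow(montage$pos))
  for (k in seq_len(nrow(dip_pos))) {
    rel <- sweep(montage$pos, 2L, dip_pos[k, ], "-")
    dist3 <- rowSums(rel^2)^1.5
    v <- v + as.numeric(rel %*% dip_mom[k, ]) / dist3
  }
  v
}

# --- spherical-spline machinery (Perrin et al. style, order m) -------------

# g(x) = (1/4pi) * sum_{n=1}^{N} (2n+1) / (n (n+1))^m * P_n(x)
# evaluated elementwise on a matrix of cosines of inter-electrode angles.
spline_g <- function(cosang, m = 4L, n_terms = 50L) {
  cosang <- pmin(pmax(cosang, -1), 1)
  p_prev <- array(1, dim = dim(cosang))   # P_0
  p_cur <- cosang                          # P_1
  out <- (2 * 1 + 1) / (1 * 2)^m * p_cur
  for (n in 2:n_terms) {
    p_next <- ((2 * n - 1) * cosang * p_cur - (n - 1) * p_prev) / n
    out <- out + (2 * n + 1) / (n * (n + 1))^m * p_next
    p_prev <- p_cur
    p_cur <- p_next
  }
  out / (4 * pi)
}

# Interpolation operator mapping values at `good` electrode indices to values
# at `bad` indices, by order-m spherical splines with ridge regularization.
spherical_spline_operator <- function(pos, good, bad, m = 4L, lambda = 1e-5) {
  G <- spline_g(pos[good, , drop = FALSE] %*% t(pos[good, , drop = FALSE]), m = m)
  Gb <- spline_g(pos[bad, , drop = FALSE] %*% t(pos[good, , drop = FALSE]), m = m)
  ng <- length(good)
  A <- rbind(cbind(G + diag(lambda, ng), rep(1, ng)),
             c(rep(1, ng), 0))
  Ainv <- solve(A)
  # v_bad = [Gb 1] %*% Ainv %*% [v_good; 0]
  op <- cbind(Gb, rep(1, length(bad))) %*% Ainv
  op[, seq_len(ng), drop = FALSE]
}
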