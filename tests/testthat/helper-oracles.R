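# Independent oracles and small fixture builders shared across the suite.

# Direct transcription of the greedy gromos rule, written independently of
# the package implementation (explicit loops, no vectorized shortcuts).
brute_force_gromos <- function(m, cutoff) {
  remaining <- seq_len(nrow(m))
  clusters <- list()
  while (length(remaining) > 0) {
    best <- NA_integer_
    best_n <- -1L
    for (f in remaining) {
      nb <- 0L
      for (g in remaining) {
        if (g != f && m[f, g] <= cutoff) nb <- nb + 1L
      }
      if (nb > best_n) { # strict '>' keeps the lowest-index frame on ties
        best_n <- nb
        best <- f
      }
    }
    members <- integer(0)
    for (g in remaining) {
      if (g == best || m[best, g] <= cutoff) members <- c(members, g)
    }
    clusters[[length(clusters) + 1]] <- list(members = sort(members),
                                             center = best)
    remaining <- setdiff(remaining, members)
  }
  clusters
}

random_rmsd_like_matrix <- function(n, max_d = 3) {
  m <- matrix(0, n, n)
  v <- runif(n * (n - 1) / 2, 0, max_d)
  m[upper.tri(m)] <- v
  m + t(m)
}

# Numeric rotation-search oracle for the optimal superposition RMSD:
# translation handled by centroid matching (exact for least squares),
# rotation by an Euler-angle grid followed by Nelder-Mead refinement.
rotation_matrix_zyx <- function(a) {
  cz <- cos(a[1]); sz <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cx <- cos(a[3]); sx <- sin(a[3])
  rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  rz %*% ry %*% rx
}

grid_search_min_rmsd <- function(mobile, reference, n_grid = 10) {
  p <- sweep(mobile, 2, colMeans(mobile))
  q <- sweep(reference, 2, colMeans(reference))
  obj <- function(a) {
    d <- p %*% t(rotation_matrix_zyx(a)) - q
    sqrt(mean(rowSums(d^2)))
  }
  grid <- seq(0, 2 * pi, length.out = n_grid + 1)[seq_len(n_grid)]
  best <- c(0, 0, 0)
  best_val <- obj(best)
  for (a1 in grid) for (a2 in grid) for (a3 in grid) {
    v <- obj(c(a1, a2, a3))
    if (v < best_val) {
      best_val <- v
      best <- c(a1, a2, a3)
    }
  }
  opt <- optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  min(best_val, opt$value)
}

# Breadth-first connected components over candidate residues, edges when
# the closest heavy-atom distance is within link_distance.
brute_force_patches <- function(structure, candidates, link_distance) {
  a <- structure$atoms
  heavy <- which(toupper(a$elesy) != "H")
  min_dist <- function(r1, r2) {
    i1 <- heavy[a$res_index[heavy] == r1]
    i2 <- heavy[a$res_index[heavy] == r2]
    best <- Inf
    for (x in i1) for (y in i2) {
      d <- sqrt(sum((structure$xyz[x, ] - structure$xyz[y, ])^2))
      if (d < best) best <- d
    }
    best
  }
  k <- length(candidates)
  adj <- matrix(FALSE, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j) {
      adj[i, j] <- adj[j, i] <- min_dist(candidates[i], candidates[j]) <=
        link_distance
    }
  }
  seen <- rep(FALSE, k)
  comps <- list()
  for (s in seq_len(k)) {
    if (seen[s]) next
    queue <- s
    comp <- integer(0)
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      comp <- c(comp, v)
      queue <- c(queue, which(adj[v, ] & !seen))
    }
    comps[[length(comps) + 1]] <- sort(candidates[comp])
  }
  comps
}

# Minimal hand-built structure: one atom per residue, all carbon, at the
# given coordinates (rows). Used for closed-form contact/SASA checks.
point_structure <- function(xyz, resnames = NULL, atom_names = NULL) {
  n <- nrow(xyz)
  resnames <- resnames %||% rep("ALA", n)
  atom_names <- atom_names %||% rep("CA", n)
  atoms <- data.frame(
    type = "ATOM", eleno = seq_len(n), elety = atom_names,
    resid = resnames, chain = "A", resno = seq_len(n), insert = "",
    elesy = "C", stringsAsFactors = FALSE
  )
  vhhscreen:::new_structure(atoms, xyz, label = "points")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A 4-residue single-strand fixture (5 heavy atoms per residue).
small_strand <- function(resnames = c("LEU", "VAL", "SER", "ALA")) {
  build_peptide(resnames)
}

# Build a trajectory from an explicit list of coordinate matrices.
manual_trajectory <- function(topology, frames) {
  vhhscreen:::new_trajectory(topology, frames,
                             times = seq_along(frames) - 1)
}
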