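# Independent oracles: deliberately simple, brute-force implementations
# used to check the package's optimized paths. They share no code with
# the implementation.

# affine-gap pairwise alignment oracle (Gotoh, three matrices, no tricks);
# a gap of length L costs open + L * ext. type "global" has free nothing;
# type "local" allows restarting at 0. Returns the optimal score.
oracle_affine_score <- function(a, b, submat, open, ext, type = c("global", "local")) {
  type <- match.arg(type)
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # ends in match
  X <- matrix(NEG, n + 1, m + 1)  # ends in gap in b (consume a)
  Y <- matrix(NEG, n + 1, m + 1)  # ends in gap in a (consume b)
  M[1, 1] <- 0
  if (type == "global") {
    for (i in 2:(n + 1)) X[i, 1] <- -(open + ext * (i - 1))
    for (j in 2:(m + 1)) Y[1, j] <- -(open + ext * (j - 1))
  }
  best_local <- 0
  for (i in 1:(n + 1)) for (j in 1:(m + 1)) {
    if (i > 1 && j > 1) {
      s <- submat[a[i - 1], b[j - 1]]
      base <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      if (type == "local") base <- max(base, 0)
      M[i, j] <- base + s
    }
    if (i > 1)
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
    if (j > 1)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    if (type == "local") best_local <- max(best_local, M[i, j])
  }
  if (type == "local") best_local else max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# all-pairs interface scan (no grid)
oracle_interface <- function(protein, rna, cutoff = 5.0) {
  pa <- protein$atom_xyz; ra <- rna$atom_xyz
  pi_ <- integer(); ri <- integer()
  for (i in seq_len(nrow(pa))) {
    d <- sqrt(colSums((t(ra) - pa[i, ])^2))
    hit <- d < cutoff
    if (any(hit)) {
      pi_ <- c(pi_, protein$atom_res[i])
      ri <- c(ri, rna$atom_res[hit])
    }
  }
  list(protein_interface = sort(unique(pi_)), rna_interface = sort(unique(ri)))
}

oracle_count_close <- function(axyz, bxyz, cutoff) {
  n <- 0L
  for (i in seq_len(nrow(axyz)))
    n <- n + sum(sqrt(colSums((t(bxyz) - axyz[i, ])^2)) < cutoff)
  n
}

# numeric rigid-superposition oracle: minimize RMSD over Euler angles and
# translation with Nelder-Mead from several starts
oracle_superpose_rmsd <- function(a, b, n_starts = 8) {
  rotmat <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    Rz %*% Ry %*% Rx
  }
  obj <- function(p) {
    R <- rotmat(p[1:3])
    y <- sweep(a %*% t(R), 2, p[4:6], "+")
    sqrt(mean(rowSums((y - b)^2)))
  }
  best <- Inf
  set.seed(1234)
  for (s in seq_len(n_starts)) {
    p0 <- c(runif(3, -pi, pi), colMeans(b) - colMeans(a))
    o <- optim(p0, obj, method = "Nelder-Mead",
               control = list(maxit = 4000, reltol = 1e-12))
    o <- optim(o$par, obj, method = "Nelder-Mead",
               control = list(maxit = 4000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# exhaustive enumeration of sequential alignments, scored like the
# structural DP: sum of S over matched pairs minus gap * internal gap
# steps (end gaps free)
oracle_best_monotone_alignment <- function(S, gap = 0.6) {
  n <- nrow(S); m <- ncol(S)
  best <- -Inf
  rec <- function(i, j, last_i, last_j, score, npairs) {
    # close the alignment here
    if (npairs > 0 && score > best) best <<- score
    if (i > n || j > m) return()
    for (ii in i:n) for (jj in j:m) {
      pen <- 0
      if (npairs > 0) pen <- gap * ((ii - last_i - 1) + (jj - last_j - 1))
      rec(ii + 1, jj + 1, ii, jj, score + S[ii, jj] - pen, npairs + 1)
    }
  }
  rec(1, 1, 0, 0, 0, 0)
  best
}

# union-find transitive closure over a pairwise relation matrix
oracle_components <- function(rel) {
  n <- nrow(rel)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i < j && rel[i, j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  vapply(seq_len(n), find, 1L)
}

# random rigid transform
random_transform <- function() {
  M <- matrix(rnorm(9), 3, 3)
  q <- qr(M)
  R <- qr.Q(q)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(rotation = R, translation = rnorm(3, 0, 20))
}

rigid_move_chain <- function(chain, tr) {
  chain$atom_xyz <- sweep(chain$atom_xyz %*% t(tr$rotation), 2, tr$translation, "+")
  chain
}

rigid_move_complex <- function(bc, tr) {
  bc$protein <- rigid_move_chain(bc$protein, tr)
  bc$rna <- rigid_move_chain(bc$rna, tr)
  bc
}
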