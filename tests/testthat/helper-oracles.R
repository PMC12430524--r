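# Independent oracle implementations used to validate the package's
# primitives. Each is coded from the definition, on a different code path
# than the implementation it checks.

# Torsion by explicit projection onto the plane normal to the central bond:
# project the outer bonds off b2, then take the signed angle between the
# projections (sign from the right-hand rule about b2).
oracle_torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  u <- b2 / sqrt(sum(b2^2))
  v1 <- -b1 - sum(-b1 * u) * u       # component of p1-p2 direction off b2
  v2 <- b3 - sum(b3 * u) * u
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  cosang <- max(-1, min(1, cosang))
  ang <- acos(cosang) * 180 / pi
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  s <- sum(cr * u)
  out <- if (s < 0) -ang else ang
  torsionForest::wrap_angle(out)
}

# Exhaustive best split by plain double loop over every candidate midpoint,
# recomputing child impurities from scratch with table-style counting. Ties
# are resolved by exact integer cross-multiplication, so the comparison is
# immune to floating-point round-off in either direction.
oracle_best_split <- function(values, labels, min_leaf = 1L) {
  sv <- sort(unique(values))
  if (length(sv) < 2L) return(NULL)
  n <- length(values)
  best <- NULL
  for (i in seq_len(length(sv) - 1L)) {
    thr <- (sv[i] + sv[i + 1L]) / 2
    left <- values <= thr
    nl <- sum(left); nr <- n - nl
    if (nl < min_leaf || nr < min_leaf) next
    A <- function(y) sum(y == 0)^2 + sum(y == 1)^2
    num <- A(labels[left]) * nr + A(labels[!left]) * nl
    den <- nl * nr
    # strictly better iff num/den > best num/den, by exact integer compare
    if (is.null(best) || num * best$den > best$num * den) {
      best <- list(threshold = thr, num = num, den = den)
    }
  }
  if (is.null(best)) return(NULL)
  list(threshold = best$threshold, impurity = 1 - (best$num / best$den) / n)
}

# Exact Shapley values by enumerating all k! feature orderings and averaging
# marginal contributions; the value function is re-derived here from the
# interventional definition (background rows with coalition features set to
# the frame's values).
oracle_shapley <- function(model, frame, background) {
  feats <- model$features
  k <- length(feats)
  v <- function(coal) {
    hy <- background[, feats, drop = FALSE]
    for (f in coal) hy[, f] <- frame[[f]]
    mean(torsionForest::forest_vote_fraction(model, hy))
  }
  perms <- gtools_permutations(k)
  vals <- stats::setNames(numeric(k), feats)
  for (r in seq_len(nrow(perms))) {
    coal <- character(0)
    prev <- v(coal)
    for (j in perms[r, ]) {
      coal <- c(coal, feats[j])
      cur <- v(coal)
      vals[feats[j]] <- vals[feats[j]] + (cur - prev)
      prev <- cur
    }
  }
  vals / nrow(perms)
}

# All permutations of 1..k (k small), without external dependencies.
gtools_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(k - 1L)
  out <- NULL
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# Optimal-rotation RMSD by direct numerical minimisation over Euler angles;
# independent of the closed-form SVD route.
oracle_rmsd <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  rotmat <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1])
    cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  f <- function(a) sqrt(mean(rowSums((Xc - Yc %*% t(rotmat(a)))^2)))
  best <- Inf
  for (start in list(c(0, 0, 0), c(pi / 2, 0, 0), c(0, pi / 2, pi / 2),
                     c(pi, pi / 4, -pi / 4))) {
    o <- stats::optim(start, f, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# Random rigid motion applied to an n x 3 point set.
random_rigid <- function(P) {
  a <- stats::runif(3, -pi, pi)
  cz <- cos(a[1]); sz <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cx <- cos(a[3]); sx <- sin(a[3])
  R <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE) %*%
    matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE) %*%
    matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  t <- stats::runif(3, -20, 20)
  sweep(P %*% t(R), 2, -t)
}
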