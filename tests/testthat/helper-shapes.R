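# fixture builders shared across test files; everything is generated in
# code so the suite carries no data files

# ellipse boundary with semi-axes a (along x) and b, optionally rotated and
# shifted away from the canonical frame
make_ellipse <- function(a, b, m = 512, theta = 0, shift = c(0, 0),
                         leaf_id = "ellipse") {
  t <- seq(0, 2 * pi, length.out = m + 1)[-(m + 1)]
  v <- cbind(a * cos(t), b * sin(t))
  v <- rigid(v, theta, shift)
  # base at t = pi (index m/2 + 1 for even m), apex at t = 0 (index 1)
  leaf_boundary(v, base_index = m / 2 + 1, apex_index = 1,
                leaf_id = leaf_id, check_simple = FALSE)
}

rigid <- function(v, theta, shift) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  sweep(v %*% t(R), 2, -shift)
}

# apply a rigid motion to an existing boundary, keeping the landmarks
transform_boundary <- function(b, theta = 0, shift = c(0, 0)) {
  leaf_boundary(rigid(b$vertices, theta, shift),
                base_index = b$base_index, apex_index = b$apex_index,
                leaf_id = b$leaf_id, check_simple = FALSE)
}

# mirror across the length axis (canonical frame): y -> -y
reflect_boundary <- function(b) {
  v <- b$vertices
  v[, 2] <- -v[, 2]
  leaf_boundary(v, base_index = b$base_index, apex_index = b$apex_index,
                leaf_id = b$leaf_id, check_simple = FALSE)
}

scale_boundary <- function(b, k) {
  leaf_boundary(b$vertices * k, base_index = b$base_index,
                apex_index = b$apex_index, leaf_id = b$leaf_id,
                check_simple = FALSE)
}

# independent profile-REML oracle for the random-intercept model
# y = X beta + Z b + e: dense-matrix REML criterion, numeric optimisation
# over the variance ratio lambda = sigma_alpha^2 / sigma_eps^2
reml_oracle <- function(y, x, site) {
  site <- factor(site)
  X <- cbind(1, x)
  Z <- stats::model.matrix(~ site - 1)
  n <- length(y)
  p <- ncol(X)
  crit <- function(loglam) {
    lam <- exp(loglam)
    V0 <- diag(n) + lam * tcrossprod(Z)
    Vi <- solve(V0)
    XtVX <- t(X) %*% Vi %*% X
    beta <- solve(XtVX, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    s2 <- as.numeric(t(r) %*% Vi %*% r) / (n - p)
    (n - p) * log(s2) + determinant(V0)$modulus + determinant(XtVX)$modulus
  }
  opt <- stats::optimize(crit, c(-20, 20), tol = 1e-10)
  lam <- exp(opt$minimum)
  V0 <- diag(n) + lam * tcrossprod(Z)
  Vi <- solve(V0)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  s2 <- as.numeric(t(r) %*% Vi %*% r) / (n - p)
  list(beta = as.numeric(beta), sigma_eps = sqrt(s2),
       sigma_alpha = sqrt(lam * s2))
}
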