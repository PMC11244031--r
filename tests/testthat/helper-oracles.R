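# Independent oracles and shared fixtures for the test suite.

# Grünwald-Letnikov weights by direct evaluation of the Gamma-ratio formula,
# with Gamma poles (integer order, m > order) taken as the limit 0.
gl_weights_gamma <- function(order, n_terms) {
  vapply(0:n_terms, function(m) {
    a <- order - m + 1
    if (a <= 0 && abs(a - round(a)) < 1e-12) return(0)  # Gamma pole
    (-1)^m * gamma(order + 1) / (factorial(m) * gamma(a))
  }, numeric(1))
}

# brute-force GL backward sum, straight from the definition
gl_derivative_bruteforce <- function(x, order, h = 1) {
  n <- length(x)
  vapply(seq_len(n), function(k) {
    s <- 0
    for (m in 0:(k - 1))
      s <- s + gl_weights_gamma(order, m)[m + 1] * x[k - m]
    s / h^order
  }, numeric(1))
}

# brute-force sliding-window GLCM by explicit pair enumeration; mirrors the
# contract (clipped windows, symmetric accumulation, min-max quantization)
# with plain loops, independently of the compiled path
glcm_bruteforce <- function(image, window, levels, offsets) {
  rng <- range(image, na.rm = TRUE)
  q <- if (rng[2] > rng[1])
    pmin(floor((image - rng[1]) / (rng[2] - rng[1]) * levels), levels - 1)
  else image * 0
  nr <- nrow(image); nc <- ncol(image); half <- window %/% 2
  out <- array(NA_real_, c(nr, nc, 8))
  for (r in 1:nr) for (c in 1:nc) {
    r0 <- max(1, r - half); r1 <- min(nr, r + half)
    c0 <- max(1, c - half); c1 <- min(nc, c + half)
    P <- matrix(0, levels, levels)
    for (o in seq_len(nrow(offsets))) {
      dr <- offsets[o, 1]; dc <- offsets[o, 2]
      for (rr in r0:r1) for (cc in c0:c1) {
        r2 <- rr + dr; c2 <- cc + dc
        if (r2 < r0 || r2 > r1 || c2 < c0 || c2 > c1) next
        a <- q[rr, cc] + 1; b <- q[r2, c2] + 1
        if (is.na(a) || is.na(b)) next
        P[a, b] <- P[a, b] + 1
        P[b, a] <- P[b, a] + 1
      }
    }
    tot <- sum(P)
    if (tot == 0) next
    P <- P / tot
    iv <- row(P) - 1; jv <- col(P) - 1
    mu <- sum(iv * P)
    vr <- sum((iv - mu)^2 * P)
    pl <- P[P > 0]
    corr_num <- sum((iv - mu) * (jv - mu) * P)
    out[r, c, ] <- c(
      mu, vr,
      sum(P / (1 + (iv - jv)^2)),
      sum((iv - jv)^2 * P),
      sum(abs(iv - jv) * P),
      -sum(pl * log(pl)),
      sum(P^2),
      if (vr > 0) corr_num / vr else 0)
  }
  out
}

# small shared synthetic scene, built once per test run
small_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_scene(scene_config(
        rows = 64, cols = 64,
        wavelengths = seq(430.4, 991.3, length.out = 40),
        patch_scale = 12, seed = 42))
    cache
  }
})

small_glcm <- function() glcm_spec(window = 9)

# object-mode feature table of the shared scene, cached
small_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- small_scene()
      cache <<- build_feature_families(sc$cube, sc$object_truth,
                                       sc$class_truth, glcm = small_glcm())
    }
    cache
  }
})

# planted-feature dataset: one perfectly separating feature among noise
planted_dataset <- function(n = 200, n_noise = 20, seed = 0) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * n_noise), n, n_noise)
  planted <- ifelse(y == 0, runif(n, 0, 1), runif(n, 2, 3))
  tab <- data.frame(planted = planted, x, check.names = FALSE)
  names(tab) <- c("F:planted", paste0("F:noise", seq_len(n_noise)))
  tab$label <- y
  tab
}
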