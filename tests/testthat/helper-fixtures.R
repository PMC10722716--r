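# Shared fixture builders; everything is generated in code at test time.

tiny_source_space <- function(spacing = 40, radius = 75) {
  source_space_grid(spacing, radius)
}

# wrap a plain Nv x Nf matrix as a spectro_image
as_spectro_image <- function(P, id = "s") {
  colnames(P) <- band_scheme()$band
  structure(list(power = P, bands = band_scheme(), subject_id = id,
                 unit = "uV^2/M^4/Hz"),
            class = "spectro_image")
}

# spectro images generated from loadings %*% planted flattened maps
images_from_mixing <- function(L, maps_flat, nv, nf) {
  X <- L %*% maps_flat
  lapply(seq_len(nrow(X)), function(s)
    as_spectro_image(matrix(X[s, ], nv, nf), id = s))
}

# sparse nonnegative planted maps in flattened (band-major) space
planted_flat_maps <- function(k, nv, nf, seed, n_active = 60) {
  set.seed(seed)
  t(sapply(seq_len(k), function(i) {
    m <- numeric(nv * nf)
    m[sample(nv * nf, n_active)] <- stats::runif(n_active, 0.5, 1)
    m
  }))
}

# a source space holding explicit points (for symmetry/depth fixtures)
point_source_space <- function(pts) {
  pts <- matrix(pts, ncol = 3, byrow = TRUE,
                dimnames = list(NULL, c("x", "y", "z")))
  structure(list(voxel_coords = pts, n_voxels = nrow(pts),
                 spacing_mm = NA_real_,
                 max_radius_mm = max(sqrt(rowSums(pts^2)))),
            class = "source_space")
}

# independent rank-sum enumeration oracle: exact two-sided p for continuous
# (tie-free) samples by enumerating all C(n1+n2, n1) rank assignments
enum_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(n1)])
  sums <- combn(n1 + n2, n1, FUN = function(i) sum(i))
  mu <- n1 * (n1 + n2 + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# brute-force AUC oracle by pair counting
pair_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
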