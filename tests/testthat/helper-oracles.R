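# Independent brute-force oracles used across the suite.  These are written
# as naive per-pixel / all-pairs loops on purpose: they share no code with
# the implementations they check.

oracle_bce <- function(S, G) {
  eps <- 1e-7
  total <- 0
  for (i in seq_along(S)) {
    s <- min(max(S[i], eps), 1 - eps)
    total <- total - (G[i] * log(s) + (1 - G[i]) * log(1 - s))
  }
  total / length(S)
}

oracle_focal <- function(S, G, gamma, alpha) {
  eps <- 1e-7
  total <- 0
  for (i in seq_along(S)) {
    s <- min(max(S[i], eps), 1 - eps)
    pt <- if (G[i] == 1) s else 1 - s
    at <- if (G[i] == 1) alpha else 1 - alpha
    total <- total - at * (1 - pt)^gamma * log(pt)
  }
  total / length(S)
}

oracle_confusion <- function(P, G) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    if (P[i, j] == 1 && G[i, j] == 1) tp <- tp + 1L
    else if (P[i, j] == 0 && G[i, j] == 0) tn <- tn + 1L
    else if (P[i, j] == 1 && G[i, j] == 0) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

# Boundary of a binary mask by the same 4-connectivity definition, written
# as an explicit loop.
oracle_boundary <- function(mask) {
  pts <- NULL
  h <- nrow(mask); w <- ncol(mask)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (mask[i, j] != 1) next
    nb <- c(if (i > 1) mask[i - 1, j] else 0, if (i < h) mask[i + 1, j] else 0,
            if (j > 1) mask[i, j - 1] else 0, if (j < w) mask[i, j + 1] else 0)
    if (any(nb == 0)) pts <- rbind(pts, c(i, j))
  }
  pts
}

# All-pairs directed boundary distances (brute force).
oracle_surface <- function(P, G) {
  bp <- oracle_boundary(P)
  bg <- oracle_boundary(G)
  dmin <- function(from, to) {
    apply(from, 1, function(p) {
      best <- Inf
      for (k in seq_len(nrow(to)))
        best <- min(best, sqrt(sum((p - to[k, ])^2)))
      best
    })
  }
  d_pg <- dmin(bp, bg)
  d_gp <- dmin(bg, bp)
  list(hd95 = max(quantile(d_pg, 0.95, names = FALSE),
                  quantile(d_gp, 0.95, names = FALSE)),
       assd = mean(c(d_pg, d_gp)))
}

# Random blob-like binary mask with at least one on-pixel.
random_mask <- function(n = 16, p = 0.25) {
  m <- matrix(rbinom(n * n, 1, p), n, n)
  if (sum(m) == 0) m[sample(n, 1), sample(n, 1)] <- 1L
  m
}

tiny_cfg <- function(n_stages = 2) {
  net_config(base_filters = 8, n_stages = n_stages, cbam_reduction = 4,
             dropout = 0)
}

phantom_batch <- function(seeds, ...) {
  lapply(seeds, function(s) generate_phantom(phantom_spec(seed = s, ...)))
}
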