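# Independent oracles, coded naively on purpose so they share no logic with
# the package implementations they check.

# Brute-force amplitude-weighted centroid: explicit loops, no linear algebra.
oracle_weighted_mean <- function(coords, w) {
  out <- c(0, 0, 0)
  for (ax in 1:3) {
    num <- 0
    den <- 0
    for (i in seq_along(w)) {
      num <- num + w[i] * coords[i, ax]
      den <- den + w[i]
    }
    out[ax] <- num / den
  }
  out
}

# Empty-circumcircle check: a triangulation is Delaunay iff no point lies
# strictly inside any triangle's circumcircle.
oracle_is_delaunay <- function(x, y, tris, tol = 1e-7) {
  for (k in seq_len(nrow(tris))) {
    a <- tris[k, 1]; b <- tris[k, 2]; c <- tris[k, 3]
    d <- 2 * (x[a] * (y[b] - y[c]) + x[b] * (y[c] - y[a]) +
                x[c] * (y[a] - y[b]))
    if (abs(d) < 1e-12) next
    a2 <- x[a]^2 + y[a]^2; b2 <- x[b]^2 + y[b]^2; c2 <- x[c]^2 + y[c]^2
    ux <- (a2 * (y[b] - y[c]) + b2 * (y[c] - y[a]) + c2 * (y[a] - y[b])) / d
    uy <- (a2 * (x[c] - x[b]) + b2 * (x[a] - x[c]) + c2 * (x[b] - x[a])) / d
    r <- sqrt((ux - x[a])^2 + (uy - y[a])^2)
    scale <- max(r, 1)
    for (i in seq_along(x)) {
      if (i %in% tris[k, ]) next
      if (sqrt((ux - x[i])^2 + (uy - y[i])^2) < r - tol * scale) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# Per-test difference in group means, computed with base tapply only.
oracle_mean_diffs <- function(long) {
  sapply(split(long, long$test), function(d) {
    mean(d$value[d$group == "LBP"]) - mean(d$value[d$group == "control"])
  })
}

# Small helper: epochs matrix of a session as a list of numeric vectors.
session_epoch_list <- function(session) {
  lapply(seq_len(nrow(session$epochs)), function(i) session$epochs[i, ])
}
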