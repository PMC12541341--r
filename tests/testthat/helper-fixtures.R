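# shared fixtures: built in code, no files on disk

th330 <- thermo_state(330)

# small random trajectory for IO round trips
random_trajectory <- function(seed = 1, n = 5, nf = 5, L = 10) {
  set.seed(seed)
  arr <- array(runif(n * 3 * nf, 0, L), c(n, 3, nf))
  trajectory(sample(c("O", "H", "Ca", "C"), n, replace = TRUE), arr,
             sim_box(rep(L, 3)), times = seq_len(nf) * 0.5, wrapped = TRUE)
}

# deterministic CV table
random_cv_table <- function(seed = 1, n = 50) {
  set.seed(seed)
  cv_table(time = seq_len(n) * 0.1, d = runif(n, 2, 10),
           bias = runif(n, 0, 5), wall = rexp(n, 10))
}

# brute-force minimum image: exhaustive scan over periodic images
# (wide enough to cover points drawn several box lengths apart)
min_image_brute <- function(a, b, box) {
  L <- box$edge_lengths
  best <- NULL
  bestn <- Inf
  for (i in -5:5) for (j in -5:5) for (k in -5:5) {
    d <- (b + c(i, j, k) * L) - a
    if (sum(d^2) < bestn) {
      bestn <- sum(d^2)
      best <- d
    }
  }
  best
}

# exhaustive minimax pass value by enumerating all simple 4-connected paths
minimax_brute <- function(vals, nb, A, B) {
  best <- Inf
  visited <- rep(FALSE, length(vals))
  dfs <- function(i, mx) {
    mx <- max(mx, vals[i])
    if (mx >= best) return()
    if (i %in% B) {
      best <<- min(best, mx)
      return()
    }
    visited[i] <<- TRUE
    for (j in pairfes:::grid_neighbours(i, nb)) {
      if (!visited[j]) dfs(j, mx)
    }
    visited[i] <<- FALSE
  }
  for (a in A) dfs(a, -Inf)
  best
}

# 1D fes grid from values
fes1d <- function(vals, lo = 0, hi = length(vals)) {
  fes_grid(list(list(name = "x", edges = seq(lo, hi, length.out = length(vals) + 1))),
           vals)
}
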