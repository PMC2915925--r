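# shared fixtures: small, fast simulation configs

small_stack_config <- function(...) {
  stack_sim_config(shape = c(16L, 96L, 96L), n_cells = 1L, ...)
}

# brute-force rasterization oracle: test every voxel centre of the grid
# against the sphere inequality directly
brute_force_sphere_count <- function(centre, r, voxel_size, shape) {
  g <- expand.grid(z = seq_len(shape[1]), y = seq_len(shape[2]),
                   x = seq_len(shape[3]))
  pz <- (g$z - 0.5) * voxel_size[1]
  py <- (g$y - 0.5) * voxel_size[2]
  px <- (g$x - 0.5) * voxel_size[3]
  sum((pz - centre[1])^2 + (py - centre[2])^2 + (px - centre[3])^2 <= r^2)
}

# hand oracle for quantile normalization: sort each column, average across
# columns rank-wise, write the averages back in each column's original order
hand_quantile_normalize <- function(mat) {
  ranks <- apply(mat, 2, rank, ties.method = "first")
  target <- rowMeans(apply(mat, 2, sort))
  out <- mat
  for (j in seq_len(ncol(mat))) out[, j] <- target[ranks[, j]]
  out
}

# exhaustive hypergeometric oracle: enumerate all size-n subsets of a
# universe of size N with K marked elements, count those with >= k marks
exhaustive_hyper_tail <- function(k, K, n, N) {
  sets <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(sets, 2, function(s) sum(s %in% marked))
  mean(hits >= k)
}
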