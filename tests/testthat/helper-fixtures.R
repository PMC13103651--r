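# Shared fixtures and independent oracles. Everything is built in code at
# test time; the oracles deliberately avoid the implementation's code paths
# (igraph, vectorized correlation, sparse smoothers).

# Small meshes reused across files. Subdivision 2 (162 vertices) keeps
# exhaustive oracles fast; 3 (642) is the pipeline's working resolution.
tiny_mesh <- function() make_mesh(1, 50)
small_mesh <- function() make_mesh(2, 80)
work_mesh <- function() make_mesh(3, 80)

# A path-graph "mesh" with unit edges along the x axis: degenerate
# triangles are avoided by zig-zagging a second row of helper vertices.
path_mesh <- function(n = 6) {
  v <- cbind(c(seq_len(n) - 1, seq_len(n - 1) - 0.5),
             c(rep(0, n), rep(0.8, n - 1)), 0)
  tri <- cbind(seq_len(n - 1), seq_len(n - 1) + 1, n + seq_len(n - 1))
  surface_mesh(v, tri)
}

# O(V^2) Dijkstra over an explicit edge list -- the shortest-path oracle,
# independent of igraph.
oracle_dijkstra <- function(vertices, edges, from) {
  n <- nrow(vertices)
  w <- sqrt(rowSums((vertices[edges[, 1], , drop = FALSE] -
                     vertices[edges[, 2], , drop = FALSE])^2))
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- rbind(adj[[i]], c(j, w[k]))
    adj[[j]] <- rbind(adj[[j]], c(i, w[k]))
  }
  dist <- rep(Inf, n)
  dist[from] <- 0
  done <- rep(FALSE, n)
  for (iter in seq_len(n)) {
    u <- which(!done & dist == min(dist[!done]))[1]
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    nb <- adj[[u]]
    if (is.null(nb)) next
    for (k in seq_len(nrow(nb))) {
      v <- nb[k, 1]
      if (dist[u] + nb[k, 2] < dist[v]) dist[v] <- dist[u] + nb[k, 2]
    }
  }
  dist
}

# Fixed working field/truth for cohort-level tests.
work_field <- function(mesh = work_mesh()) connectivity_field(mesh)
work_truth <- function(mesh = work_mesh(), ...) {
  cohort_truth(work_field(mesh), ...)
}

# Monte-Carlo seed policy: k-seed sweeps always use seeds 1..k.
mc_seeds <- function(k = 20) seq_len(k)

# 95% sampling band of a Pearson correlation around true rho at sample
# size n, via the Fisher transform.
r_sampling_band <- function(rho, n) {
  tanh(atanh(rho) + c(-1, 1) * stats::qnorm(0.975) / sqrt(n - 3))
}
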