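# shared fixture builders; everything is generated in code at test time

rms <- function(a) sqrt(mean(a^2))

# geometric cylinder volume (no tree machinery), axis-aligned with identical
# cross-section offsets so axis permutations are exactly symmetric
cylinder_volume <- function(dims = c(40, 40, 40), spacing = c(0.4, 0.4, 0.4),
                            axis = 3, radius = 0.6, offs = c(8.11, 7.93),
                            vessel = 300, background = 100) {
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 1) * spacing[a])
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  oth <- setdiff(1:3, axis)
  d2 <- (g[[oth[1]]] - offs[1])^2 + (g[[oth[2]]] - offs[2])^2
  scalar_volume(array(background + (vessel - background) * (d2 <= radius^2),
                      dim = dims), spacing = spacing)
}

# tube-shaped binary mask along an axis (radius in voxels)
tube_mask <- function(dims = c(32, 32, 32), axis = 3, radius_vox = 1.3,
                      center = NULL, span = NULL) {
  if (is.null(center)) center <- (dims[setdiff(1:3, axis)] + 1) / 2
  if (is.null(span)) span <- c(4, dims[axis] - 4)
  idx <- lapply(dims, seq_len)
  oth <- setdiff(1:3, axis)
  g <- expand.grid(i = idx[[1]], j = idx[[2]], k = idx[[3]])
  d2 <- (g[[oth[1]]] - center[1])^2 + (g[[oth[2]]] - center[2])^2
  inside <- d2 <= radius_vox^2 & g[[axis]] >= span[1] & g[[axis]] <= span[2]
  array(inside, dim = dims)
}

# bimodal "enhanced" case: vessel voxels >= 0.8, background <= 0.2 inside an
# ellipsoidal ROI; the true vessel set is known exactly
bimodal_case <- function(seed = 1, dims = c(24, 24, 24),
                         spacing = c(0.4, 0.4, 0.4)) {
  set.seed(seed)
  vessel <- tube_mask(dims, axis = 3, radius_vox = 1.6)
  vals <- array(runif(prod(dims), 0, 0.2), dim = dims)
  vals[vessel] <- runif(sum(vessel), 0.8, 1.0)
  lab <- array(1L, dim = dims)
  list(enhanced = scalar_volume(vals, spacing = spacing),
       roi = region_mask(lab, c(roi = 1L), spacing = spacing),
       vessel = vessel)
}

# phantom tree rendered noise-free plus a parent-artery rooting sphere
clean_tree_case <- function(seed, dims = c(80, 80, 80),
                            spacing = c(0.4, 0.4, 0.4),
                            root_radius = 0.65, n_generations = 2L,
                            n_trunks = 1L, ...) {
  ext <- dims * spacing
  spec <- vessel_tree_spec(root_position = c(0.5, 0.5, 0.08) * ext,
                           root_radius = root_radius,
                           n_generations = n_generations,
                           n_trunks = n_trunks, seed = seed, ...)
  tree <- suppressWarnings(
    generate_vessel_tree(spec, bounds = rbind(c(0, 0, 0), ext - spacing)))
  rend <- render_angiogram(tree, dims = dims, spacing = spacing,
                           noise_sigma = 0, bias_amplitude = 0)
  parent <- array(FALSE, dims)
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 1) * spacing[a])
  for (seg in tree$segments) {
    if (!is.na(seg$parent)) next
    ctr <- seg$points[1, ]
    d2 <- outer(outer((ax[[1]] - ctr[1])^2, (ax[[2]] - ctr[2])^2, `+`),
                (ax[[3]] - ctr[3])^2, `+`)
    parent[d2 <= 1.6^2] <- TRUE
  }
  list(tree = tree, truth = rend$truth, volume = rend$volume,
       parent = parent, spacing = spacing)
}

# independent 26-connectivity component labelling oracle (plain R BFS)
label_components_oracle <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  nxt <- 0L
  idx <- which(mask)
  for (s in idx) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      k <- cur - 1L
      x <- k %% d[1]; y <- (k %/% d[1]) %% d[2]; z <- k %/% (d[1] * d[2])
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        nx <- x + dx; ny <- y + dy; nz <- z + dz
        if (nx < 0 || ny < 0 || nz < 0 ||
            nx >= d[1] || ny >= d[2] || nz >= d[3]) next
        q <- 1L + nx + d[1] * (ny + d[2] * nz)
        if (mask[q] && lab[q] == 0L) { lab[q] <- nxt; queue <- c(queue, q) }
      }
    }
  }
  lab
}

# two-way ANOVA mean squares via stats::aov, as an independent ICC oracle
icc_a1_oracle <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  df <- data.frame(y = as.vector(tab),
                   subj = factor(rep(seq_len(n), times = k)),
                   meas = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + meas, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}
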