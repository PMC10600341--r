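# Independent oracles used across tests. These deliberately avoid the
# package's own implementation paths: neighborhoods are enumerated by index
# clamping, rank-sum p-values by exhaustive partition enumeration, and so
# on.

# Per-pixel local statistic with explicit neighborhood enumeration and
# border clamping (equivalent to replicate padding).
oracle_local_stat <- function(m, radius, stat, shape = "disk") {
  h <- nrow(m); w <- ncol(m)
  r <- floor(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  if (shape == "disk") g <- g[g$dy^2 + g$dx^2 <= radius^2, ]
  out <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) {
    ys <- pmin(pmax(i + g$dy, 1L), h)
    for (j in seq_len(w)) {
      xs <- pmin(pmax(j + g$dx, 1L), w)
      out[i, j] <- stat(m[cbind(ys, xs)])
    }
  }
  out
}

oracle_bernsen <- function(m, radius, contrast_min, midgray) {
  lmax <- oracle_local_stat(m, radius, max)
  lmin <- oracle_local_stat(m, radius, min)
  mid <- (lmax + lmin) / 2
  ifelse((lmax - lmin) >= contrast_min, m > mid, mid >= midgray)
}

oracle_local_mean <- function(m, radius, c = 0) {
  lmean <- oracle_local_stat(m, radius, mean)
  m > (lmean - c)
}

# Exhaustive two-sided rank-sum p over all C(n+m, n) group assignments
# (tie-free data only).
oracle_wilcox_exact <- function(xa, xb) {
  n <- length(xa)
  pooled <- c(xa, xb)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(length(pooled), n)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Flood fill of the background from the border (4-connectivity), for hole
# counting, written as a plain queue-based BFS.
oracle_fill_holes <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  visited <- matrix(FALSE, h, w)
  queue <- which(!mask & (row(mask) %in% c(1, h) | col(mask) %in% c(1, w)))
  visited[queue] <- TRUE
  while (length(queue)) {
    idx <- queue[1]; queue <- queue[-1]
    i <- (idx - 1) %% h + 1; j <- (idx - 1) %/% h + 1
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      y <- i + d[1]; x <- j + d[2]
      if (y >= 1 && y <= h && x >= 1 && x <= w &&
          !mask[y, x] && !visited[y, x]) {
        visited[y, x] <- TRUE
        queue <- c(queue, (x - 1) * h + y)
      }
    }
  }
  mask | (!mask & !visited)
}

# Toy expression matrix with planted per-phase correlation structure: each
# phase gets a latent cell profile; "good" genes follow it, "bad" genes are
# independent noise.
planted_phase_toy <- function(n_cells = 30, good_per_phase = 2,
                              bad_phases = c("G1/S", "S"), seed = 42) {
  set.seed(seed)
  phases <- cc_phases()
  latent <- matrix(rnorm(n_cells * 5), n_cells, 5,
                   dimnames = list(NULL, phases))
  genes <- list()
  for (p in phases) {
    gs <- list()
    for (k in seq_len(good_per_phase)) {
      gs[[sprintf("%s.good%d", phase_token(p), k)]] <-
        latent[, p] + rnorm(n_cells, 0, 0.3)
    }
    if (p %in% bad_phases) {
      gs[[sprintf("%s.bad", phase_token(p))]] <- rnorm(n_cells)
    }
    genes <- c(genes, gs)
  }
  values <- do.call(cbind, genes)
  rownames(values) <- sprintf("c%02d", seq_len(n_cells))
  sets <- lapply(setNames(nm = phases), function(p)
    grep(paste0("^", phase_token(p), "\\."), colnames(values), value = TRUE))
  # avoid G1S genes matching the G1S prefix of other phases: tokens are
  # G1S, S, G2, G2M, MG1 -- "S." would match nothing else; check anyway
  stopifnot(!anyDuplicated(unlist(sets)), all(lengths(sets) > 0))
  list(expr = expr_matrix(values), sets = phase_gene_sets(sets))
}

# Drop the params attribute a mask carries, keeping only dim.
strip_mask <- function(m) {
  out <- as.logical(m)
  dim(out) <- dim(m)
  out
}
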