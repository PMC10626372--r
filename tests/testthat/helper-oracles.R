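# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (per-voxel loops, full enumeration) and never share code
# with the implementation they check.

make_volume <- function(arr, spacing = c(1, 1, 1)) {
  suv_volume(arr, spacing_mm = spacing)
}

make_mask <- function(arr, spacing = c(1, 1, 1), label = "lesion") {
  binary_mask(arr, spacing_mm = spacing, label = label)
}

random_volume <- function(dims = c(8, 8, 8), spacing = c(1, 1, 1)) {
  make_volume(array(runif(prod(dims), 0, 10), dims), spacing)
}

random_mask <- function(dims = c(8, 8, 8), p = 0.5, spacing = c(1, 1, 1),
                        label = "lesion") {
  make_mask(array(runif(prod(dims)) < p, dims), spacing, label)
}

# per-voxel scan: inclusive band of suv_max inside the search mask
oracle_isocontour <- function(vals, search, lower, upper, suv_max) {
  out <- array(FALSE, dim(vals))
  for (i in which(search)) {
    v <- vals[i]
    if (v >= lower * suv_max && v <= upper * suv_max) out[i] <- TRUE
  }
  out
}

oracle_dice <- function(a, b) {
  inter <- sum(a & b)
  2 * inter / (sum(a) + sum(b))
}

oracle_jaccard <- function(a, b) {
  sum(a & b) / sum(a | b)
}

# exhaustive cutpoint search for Youden's J (direction: higher = positive)
oracle_youden <- function(scores, pos, direction = "greater") {
  cands <- sort(unique(c(scores, -Inf, Inf,
                         scores + 1e-9, scores - 1e-9)))
  best <- -Inf
  for (th in cands) {
    pred <- if (direction == "greater") scores > th else scores <= th
    j <- sum(pred & pos) / sum(pos) + sum(!pred & !pos) / sum(!pos) - 1
    if (j > best) best <- j
  }
  best
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
oracle_mw_exact_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(ix) {
    ux <- sum(r[ix]) - nx * (nx + 1) / 2
    min(ux, nx * ny - ux)
  }
  u_obs <- u_of(seq_len(nx))
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, u_of)
  mean(us <= u_obs + 1e-12)  # two-sided via symmetry of min(U, U')
}

# all permutations, iterative construction (distinct from the package's
# recursive generator)
oracle_permutations <- function(n) {
  out <- matrix(1L, 1, 1)
  for (k in 2:n) {
    grown <- vector("list", k)
    for (pos in seq_len(k)) {
      block <- matrix(0L, nrow(out), k)
      block[, pos] <- k
      block[, -pos] <- out
      grown[[pos]] <- block
    }
    out <- do.call(rbind, grown)
  }
  out
}

# exact two-sided Spearman permutation p
oracle_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  pm <- oracle_permutations(length(x))
  rhos <- apply(pm, 1, function(ix) cor(rx, ry[ix]))
  mean(abs(rhos) >= obs - 1e-12)
}

# 26-connected components via igraph on the voxel adjacency graph
oracle_components <- function(arr) {
  idx <- which(arr)
  if (length(idx) == 0) return(array(0L, dim(arr)))
  co <- arrayInd(idx, dim(arr))
  edges <- integer(0)
  if (length(idx) > 1) {
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (b <= a) next
        if (all(abs(co[a, ] - co[b, ]) <= 1)) edges <- c(edges, a, b)
      }
    }
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  out <- array(0L, dim(arr))
  out[idx] <- comp
  out
}

# two disjoint axis-aligned blobs for lesion-selection tests
two_blob_mask <- function(dims = c(12, 12, 6), size_a = c(5, 5, 4),
                          size_b = c(4, 4, 2)) {
  arr <- array(FALSE, dims)
  arr[1:size_a[1], 1:size_a[2], 1:size_a[3]] <- TRUE
  arr[(dims[1] - size_b[1] + 1):dims[1],
      (dims[2] - size_b[2] + 1):dims[2],
      (dims[3] - size_b[3] + 1):dims[3]] <- TRUE
  arr
}

# a small, quick-to-render phantom spec (isotropic 1 mm grid)
small_phantom <- function(v_central = 0.3, v_peripheral = 1.2, suv_max = 3,
                          gap_fraction = 0.25, ...) {
  phantom_spec(v_central = v_central, v_peripheral = v_peripheral,
               gap_fraction = gap_fraction, suv_max = suv_max,
               grid_shape = c(40, 40, 40), spacing_mm = c(1, 1, 1), ...)
}

# small-lesion cohort parameters that fit a compact grid (for I/O and
# pipeline tests where rendering speed matters more than calibration)
small_cohort_params <- function(n_mut = 3L, n_wt = 3L, seed = 1L, ...) {
  cohort_params(
    n_mut = n_mut, n_wt = n_wt,
    log_median_cu_mut = log(3), log_median_cu_wt = log(1.6),
    sigma_log_cu = 0.2, median_vc_mut = 0.15, median_vc_wt = 0.15,
    sigma_log_vc = 0.2, grid_shape = c(40, 40, 32),
    spacing_mm = c(1, 1, 1), seed = seed, ...)
}
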