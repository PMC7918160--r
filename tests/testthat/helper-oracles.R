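## Independent brute-force oracles and fixture builders. Everything here is
## deliberately written against explicit voxel index sets and plain R loops,
## not against the package's own code paths.

## -- fixtures ---------------------------------------------------------------

## random non-empty mask on a grid: union of 1-3 random balls plus salt voxels
random_mask <- function(grid, seed) {
  set.seed(seed)
  n <- gridShape(grid)
  v <- array(FALSE, dim = n)
  extent <- (n - 1) * gridSpacing(grid)
  for (b in seq_len(sample(1:3, 1))) {
    ctr <- gridOrigin(grid) + runif(3) * extent
    r <- runif(1, 0.15, 0.4) * min(extent)
    ax <- lapply(1:3, function(a)
      gridOrigin(grid)[a] + (seq_len(n[a]) - 1) * gridSpacing(grid)[a])
    d2 <- outer(outer((ax[[1]] - ctr[1])^2, (ax[[2]] - ctr[2])^2, "+"),
                (ax[[3]] - ctr[3])^2, "+")
    v <- v | (d2 <= r^2)
  }
  salt <- sample(length(v), 5)
  v[salt] <- TRUE
  BinaryMask(grid, v)
}

full_region <- function(grid) BinaryMask(grid, array(TRUE, dim = gridShape(grid)))

## -- overlap oracle ---------------------------------------------------------

## confusion counts via explicit voxel-index sets
oracle_confusion <- function(test, reference, region) {
  t_idx <- which(maskVoxels(test))
  r_idx <- which(maskVoxels(reference))
  e_idx <- which(maskVoxels(region))
  list(tp = length(intersect(t_idx, r_idx)),
       fp = length(setdiff(t_idx, r_idx)),
       fn = length(setdiff(r_idx, t_idx)),
       tn = length(setdiff(e_idx, union(t_idx, r_idx))))
}

oracle_metrics <- function(cc) {
  rat <- function(a, b) if (b > 0) a / b else NA_real_
  list(dsc = rat(2 * cc$tp, 2 * cc$tp + cc$fp + cc$fn),
       precision = rat(cc$tp, cc$tp + cc$fp),
       sensitivity = rat(cc$tp, cc$tp + cc$fn),
       specificity = rat(cc$tn, cc$tn + cc$fp))
}

## -- surface / DTA oracle ---------------------------------------------------

## face-exposed surface voxels by explicit neighbour lookup in a padded array
oracle_surface_points <- function(mask) {
  v <- maskVoxels(mask)
  n <- dim(v)
  pad <- array(FALSE, dim = n + 2)
  pad[2:(n[1] + 1), 2:(n[2] + 1), 2:(n[3] + 1)] <- v
  idx <- which(v, arr.ind = TRUE)
  keep <- logical(nrow(idx))
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ] + 1  # padded coords
    for (o in 1:6) {
      q <- p + offs[o, ]
      if (!pad[q[1], q[2], q[3]]) { keep[r] <- TRUE; break }
    }
  }
  sp <- gridSpacing(mask); og <- gridOrigin(mask)
  sweep(sweep(idx[keep, , drop = FALSE] - 1, 2, sp, "*"), 2, og, "+")
}

## directed mean/max surface distance (cm) by all-pairs minimum distance
oracle_dta <- function(test, reference) {
  pt <- oracle_surface_points(test)
  pr <- oracle_surface_points(reference)
  mins <- vapply(seq_len(nrow(pt)), function(i) {
    min(sqrt((pr[, 1] - pt[i, 1])^2 + (pr[, 2] - pt[i, 2])^2 +
             (pr[, 3] - pt[i, 3])^2))
  }, numeric(1))
  list(mean_cm = mean(mins) / 10, max_cm = max(mins) / 10)
}

## -- rank-sum oracle --------------------------------------------------------

## exact two-sided rank-sum p by full enumeration of subset assignments
## (mid-ranks applied, so also usable to sanity-check tied inputs)
oracle_wilcoxon_exact <- function(x, y) {
  nx <- length(x)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(nx)])
  subsets <- utils::combn(length(ranks), nx)
  w_all <- apply(subsets, 2, function(s) sum(ranks[s]))
  p <- min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
  list(w = w_obs, p = p)
}
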